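#' Global leave-one-out cross-validation of the association scorer
#'
#' Each known association (i, j) is held out in turn: the edge is removed
#' from A, the Gaussian interaction-profile kernels and integrated
#' similarities are recomputed on the modified network (the model never
#' sees the held-out edge), the full scoring pipeline is rerun, and the
#' held-out miRNA is ranked (midrank ties) against the candidate miRNAs of
#' disease i -- those with no verified association in the ORIGINAL
#' network, so the disease's other true positives are neither candidates
#' nor test items in that fold. Fold ranks are aggregated into a ROC curve
#' and its AUC by [roc_from_ranks()].
#'
#' A disease whose only association is held out keeps a fully defined
#' score row: the rating side is zero but the similarity projection still
#' scores it through related diseases.
#'
#' @inheritParams mda_fit
#' @param folds_limit Optionally evaluate only a random subset of this
#'   many folds (for scaled-down runs); sampled with `seed`.
#' @param seed RNG seed for fold subsampling.
#' @param static_kernels If `TRUE`, compute the kernels once on the full
#'   network instead of per fold (a cheaper variant; the default
#'   recomputes per fold).
#' @return Object of class `mda_loocv`: `folds` tibble (`disease`,
#'   `mirna`, `rank`, `candidate_count`), `roc` tibble (`fpr`, `tpr`),
#'   `auc`, and the call parameters.
#' @export
#' @examples
#' sim <- simulate_mda(n_d = 8, n_m = 12, n_blocks = 2, seed = 1)
#' cv <- mda_loocv(sim$network, mirna_sim = sim$mirna_sim, dag = sim$dag)
#' glance(cv)
mda_loocv <- function(network, mirna_sim = NULL, dag = NULL, disease_sim = NULL,
                      delta = 0.5, gamma_d = 1, gamma_m = 1,
                      norm = c("l2", "l1"), log_base = exp(1),
                      similarity_threshold = 0,
                      folds_limit = NULL, seed = NULL,
                      static_kernels = FALSE) {
  norm <- match.arg(norm)
  if (is.data.frame(network)) network <- as_mda_network(network)
  A <- network$adjacency
  if (sum(A) == 0) {
    abort("network has no known associations to cross-validate",
          class = "mirec_contract_error")
  }
  params <- list(delta = delta, gamma_d = gamma_d, gamma_m = gamma_m,
                 norm = norm, log_base = log_base,
                 similarity_threshold = similarity_threshold)
  DS <- resolve_disease_sim(network, dag, disease_sim, params)

  edges <- which(A == 1L, arr.ind = TRUE)
  if (!is.null(folds_limit) && folds_limit < nrow(edges)) {
    pick <- withr::with_seed(seed %||% 1L, sample.int(nrow(edges), folds_limit))
    edges <- edges[pick, , drop = FALSE]
  }

  if (static_kernels) {
    KD0 <- gip_kernel(network, "disease", gamma_d)
    KR0 <- gip_kernel(network, "mirna", gamma_m)
  }

  folds <- purrr::map(seq_len(nrow(edges)), function(f) {
    i <- edges[f, 1]; j <- edges[f, 2]
    A2 <- A
    A2[i, j] <- 0L
    net2 <- new_mda_network(A2)
    if (static_kernels) {
      KD <- KD0; KR <- KR0
    } else {
      KD <- gip_kernel(net2, "disease", gamma_d)
      KR <- gip_kernel(net2, "mirna", gamma_m)
    }
    Sm <- integrate_similarity(mirna_sim, KR, threshold = similarity_threshold)
    Sd <- integrate_similarity(DS, KD, threshold = similarity_threshold)
    R <- score_pipeline(net2, Sm, Sd, params)$R
    cand <- which(A[i, ] == 0L)
    pool <- c(R[i, cand], held_out = R[i, j])
    r <- rank_desc(pool)[length(pool)]
    tibble(disease = rownames(A)[i], mirna = colnames(A)[j],
           rank = unname(r), candidate_count = length(cand))
  }) |> purrr::list_rbind()

  res <- roc_from_ranks(folds$rank, folds$candidate_count)
  structure(list(folds = folds, roc = res$roc, auc = res$auc, params = params,
                 n_folds = nrow(folds)),
            class = "mda_loocv")
}

#' ROC curve and AUC from per-fold candidate ranks
#'
#' Builds the cross-validation ROC from the midrank of each held-out
#' positive among its fold's candidates. Thresholds are pooled across
#' folds on the per-fold normalized rank scale `x = (rank - 1) /
#' candidate_count`: at threshold x the true-positive rate is the fraction
#' of folds whose positive is ranked within the top x of its candidate
#' pool, and the expected fraction of each fold's negatives inside the top
#' x is x itself, so the false-positive rate equals the threshold. The
#' trapezoidal area of this curve equals the mean over folds of
#' `(candidate_count + 1 - rank) / candidate_count`, which is exactly the
#' within-fold Mann-Whitney statistic (probability that the positive
#' outranks a random candidate negative, ties counted half).
#'
#' @param ranks Numeric vector of per-fold midranks (1 <= rank <=
#'   candidate_count + 1).
#' @param candidate_counts Integer vector of per-fold candidate pool
#'   sizes.
#' @return List with `roc` (tibble `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1)) and `auc`.
#' @export
roc_from_ranks <- function(ranks, candidate_counts) {
  if (length(ranks) == 0) {
    abort("no folds supplied", class = "mirec_contract_error")
  }
  if (length(candidate_counts) != length(ranks)) {
    abort("ranks and candidate_counts must have equal length",
          class = "mirec_contract_error")
  }
  if (any(ranks < 1 - 1e-9) || any(ranks > candidate_counts + 1 + 1e-9)) {
    abort("fold ranks must lie in [1, candidate_count + 1]",
          class = "mirec_contract_error")
  }
  rho <- (ranks - 1) / candidate_counts
  auc <- mean((candidate_counts + 1 - ranks) / candidate_counts)
  xs <- sort(unique(rho))
  tpr_after <- vapply(xs, function(x) mean(rho <= x), numeric(1))
  tpr_before <- c(0, tpr_after[-length(tpr_after)])
  roc <- tibble(
    fpr = c(0, rep(xs, each = 2), 1),
    tpr = c(0, as.vector(rbind(tpr_before, tpr_after)), 1)
  ) |> dplyr::distinct()
  list(roc = roc, auc = auc)
}

#' @export
print.mda_loocv <- function(x, ...) {
  cat(sprintf("<mda_loocv> %d folds, AUC = %.4f\n", x$n_folds, x$auc))
  invisible(x)
}

#' @describeIn mda_loocv Per-fold tibble (`disease`, `mirna`, `rank`,
#'   `candidate_count`).
#' @param x An `mda_loocv`.
#' @param ... Unused.
#' @export
tidy.mda_loocv <- function(x, ...) x$folds

#' @describeIn mda_loocv One-row summary with the AUC and fold count.
#' @export
glance.mda_loocv <- function(x, ...) {
  tibble(auc = x$auc, n_folds = x$n_folds,
         mean_candidates = mean(x$folds$candidate_count))
}

#' Top-k validation of ranked candidates against reference sets
#'
#' Replicates the three case-study protocols used to confirm ranked
#' candidates against independent association databases:
#' `"standard"` ranks the candidates of a disease (known associations
#' excluded) on the full network; `"remove-disease"` first deletes every
#' known association of the disease and then ranks ALL miRNAs, the
#' zero-knowledge mode for diseases with no known associations;
#' `"cross-version"` is computationally the standard protocol run on an
#' older association snapshot with newer databases as references.
#'
#' @inheritParams mda_fit
#' @param disease Disease whose candidates are validated.
#' @param reference_sets Named list of reference association tables, each
#'   a data frame with `disease` and `mirna` columns (names normalized).
#' @param k Depth of the ranked list to annotate (default 50).
#' @param protocol One of `"standard"`, `"remove-disease"`,
#'   `"cross-version"`.
#' @return Tibble with `rank`, `mirna`, `score`, one logical column per
#'   reference source, and `confirmed` (any source). Attributes
#'   `n_confirmed_topk` and `n_confirmed_top10` carry the headline counts.
#' @export
topk_validation <- function(network, mirna_sim = NULL, dag = NULL,
                            disease_sim = NULL, disease, reference_sets = list(),
                            k = 50, protocol = c("standard", "remove-disease",
                                                 "cross-version"), ...) {
  protocol <- match.arg(protocol)
  if (is.data.frame(network)) network <- as_mda_network(network)
  disease <- normalize_names(disease)
  if (!disease %in% network$diseases) {
    abort(sprintf("unknown disease '%s'", disease), class = "mirec_lookup_error")
  }
  if (protocol == "remove-disease") {
    A <- network$adjacency
    A[disease, ] <- 0L
    network_run <- new_mda_network(A)
  } else {
    network_run <- network
  }
  fit <- mda_fit(network_run, mirna_sim = mirna_sim, dag = dag,
                 disease_sim = disease_sim, ...)
  top <- predict(fit, disease = disease, k = k)
  out <- tibble(rank = top$rank, mirna = top$mirna, score = top$score)
  confirmed_any <- rep(FALSE, nrow(out))
  for (src in names(reference_sets)) {
    ref <- as.data.frame(reference_sets[[src]])
    hit <- normalize_names(ref$mirna)[normalize_names(ref$disease) == disease]
    col <- out$mirna %in% hit
    out[[src]] <- col
    confirmed_any <- confirmed_any | col
  }
  out$confirmed <- confirmed_any
  attr(out, "n_confirmed_topk") <- sum(confirmed_any)
  attr(out, "n_confirmed_top10") <- sum(confirmed_any[seq_len(min(10, nrow(out)))])
  out
}

#' Read a reference association set
#'
#' Flat TSV with `disease` and `mirna` columns (dbDEMC / miR2Disease-style
#' confirmation lists), names normalized to match the network.
#'
#' @param path File path.
#' @return Tibble `disease`, `mirna`.
#' @export
read_reference_set <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("disease", "mirna") %in% names(df))) {
    names(df)[1:2] <- c("disease", "mirna")
  }
  tibble(disease = normalize_names(df$disease),
         mirna = normalize_names(df$mirna)) |> dplyr::distinct()
}
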