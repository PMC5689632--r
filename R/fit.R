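#' Personalized TF-IDF-like weight matrices
#'
#' For each disease d(i) and miRNA m(j), the disease-side weight counts how
#' many of d(i)'s known miRNAs also resemble m(j) and discounts diseases
#' with many similar neighbours:
#' `W_d(i, j) = n_tal * log(N_a / n_a)`, where `RM_i` is the set of miRNAs
#' known for d(i), `n_tal = |{k in RM_i : Sm(k, j) > threshold}|`,
#' `n_a = |{t : Sd(t, i) > threshold}|` (the entity itself included, since
#' the integrated diagonal is 1) and `N_a` is the total number of miRNAs.
#' The miRNA-side weight `W_m` is the fully dual construction with the
#' roles of the two sides swapped (`N_a` = number of diseases); it has
#' shape miRNAs x diseases.
#'
#' Entries with `n_tal = 0` are exactly 0; a disease (or miRNA) with no
#' known associations gets an all-zero row. If `n_a` ever exceeds `N_a`
#' the logarithm goes negative; a warning is raised and downstream row
#' normalization will refuse rows with negative sums.
#'
#' @param network An [as_mda_network()] (or pairs data frame).
#' @param Sm,Sd Integrated similarity matrices label-aligned with the
#'   network.
#' @param side `"disease"` for W_d (diseases x miRNAs), `"mirna"` for W_m
#'   (miRNAs x diseases).
#' @param threshold Similarity count cut (default 0, strict).
#' @param log_base Base of the logarithm (default natural).
#' @return Weight matrix.
#' @export
personalized_weights <- function(network, Sm, Sd, side = c("disease", "mirna"),
                                 threshold = 0, log_base = exp(1)) {
  side <- match.arg(side)
  if (is.data.frame(network)) network <- as_mda_network(network)
  A <- network$adjacency
  storage.mode(A) <- "double"
  Smm <- unclass(Sm); Sdd <- unclass(Sd)
  if (side == "disease") {
    n_a <- colSums(Sdd > threshold)            # per disease i: |{t : Sd(t,i)>thr}|
    n_tal <- A %*% (Smm > threshold)           # (i,j): |{k in RM_i : Sm(k,j)>thr}|
    N_a <- network$n_m
  } else {
    n_a <- colSums(Smm > threshold)            # per miRNA i: |{k : Sm(k,i)>thr}|
    n_tal <- t(A) %*% (Sdd > threshold)        # (i,j): |{t in RM'_i : Sd(t,j)>thr}|
    N_a <- network$n_d
  }
  if (any(n_a > N_a)) {
    warn(sprintf("%d entit(ies) have more positive-similarity neighbours (n_a) than the opposing dimension N_a = %d; their log factor is negative (it cancels in row normalization)",
                 sum(n_a > N_a), N_a),
         .frequency = "once", .frequency_id = "mirec_negative_log_weight")
  }
  W <- n_tal * log(N_a / n_a, base = log_base)
  W
}

#' Row-sum normalize a weight matrix into a rating submatrix
#'
#' Divides each row of W by its row sum; all-zero rows stay zero (never
#' NaN). Because the specificity log factor in [personalized_weights()] is
#' constant within a row, normalization cancels it exactly -- each nonzero
#' row reduces to the non-negative neighbour-count profile `n_tal / sum
#' n_tal` and sums to 1 even when the raw weights are negative (the
#' `n_a > N_a` regime, unavoidable whenever there are more miRNAs than
#' diseases and similarity is dense).
#'
#' @param W Weight matrix.
#' @return Rating submatrix with nonzero rows summing to 1.
#' @export
rating_submatrix <- function(W) {
  row_sum_normalize(W)
}

#' Combine the disease-side and miRNA-side rating submatrices
#'
#' `Z(i, j) = Z_m(i, j) / ||Z_m(i)|| + Z_d(i, j) / ||Z_d(i)||`, with row
#' norms (Euclidean by default) and zero-norm rows contributing zero. The
#' miRNA submatrix must already be oriented diseases x miRNAs (transpose
#' of [personalized_weights()] side `"mirna"` output).
#'
#' @param Z_d,Z_m_t Rating submatrices, both diseases x miRNAs.
#' @param norm `"l2"` (Euclidean) or `"l1"`.
#' @return Combined rating matrix Z (diseases x miRNAs).
#' @export
combine_ratings <- function(Z_d, Z_m_t, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  if (!all(dim(Z_d) == dim(Z_m_t))) {
    abort("rating submatrices must share shape (did you transpose the miRNA side?)",
          class = "mirec_contract_error")
  }
  row_normalize(Z_m_t, norm) + row_normalize(Z_d, norm)
}

#' Similarity projection of the association network
#'
#' Smooths the adjacency matrix by the integrated similarities on each
#' side: `K_m = A %*% Sm` (each disease's profile diffused over similar
#' miRNAs) and `K_d = Sd %*% A` (each miRNA's profile diffused over
#' similar diseases), both diseases x miRNAs. The projection is the sum of
#' the row-normalized pieces:
#' `K(i, j) = K_m(i, j) / ||K_m(i)|| + K_d(i, j) / ||K_d(i)||`.
#'
#' @inheritParams personalized_weights
#' @param norm `"l2"` or `"l1"` row norm.
#' @param pieces Return the list (K_m, K_d, K) instead of K only.
#' @return Matrix K (diseases x miRNAs), or a list when `pieces = TRUE`.
#' @export
similarity_projection <- function(network, Sm, Sd, norm = c("l2", "l1"), pieces = FALSE) {
  norm <- match.arg(norm)
  if (is.data.frame(network)) network <- as_mda_network(network)
  A <- network$adjacency
  storage.mode(A) <- "double"
  K_m <- A %*% unclass(Sm)
  K_d <- unclass(Sd) %*% A
  K <- row_normalize(K_m, norm) + row_normalize(K_d, norm)
  if (pieces) list(K_m = K_m, K_d = K_d, K = K) else K
}

# Final score: row-normalized sum of the projection and rating matrices.
prediction_matrix <- function(K, Z, norm = "l2") {
  if (!all(dim(K) == dim(Z))) {
    abort("K and Z must share shape", class = "mirec_contract_error")
  }
  row_normalize(K, norm) + row_normalize(Z, norm)
}

# Full scoring pipeline on a prepared set of inputs. Returns all
# intermediates; the cheap core reused verbatim by LOOCV folds.
score_pipeline <- function(network, Sm, Sd, params) {
  W_d <- personalized_weights(network, Sm, Sd, "disease",
                              threshold = params$similarity_threshold,
                              log_base = params$log_base)
  W_m <- personalized_weights(network, Sm, Sd, "mirna",
                              threshold = params$similarity_threshold,
                              log_base = params$log_base)
  Z_d <- rating_submatrix(W_d)
  Z_m <- rating_submatrix(W_m)
  Z <- combine_ratings(Z_d, t(Z_m), norm = params$norm)
  proj <- similarity_projection(network, Sm, Sd, norm = params$norm, pieces = TRUE)
  R <- prediction_matrix(proj$K, Z, norm = params$norm)
  list(W_d = W_d, W_m = W_m, Z_d = Z_d, Z_m = Z_m, Z = Z,
       K_m = proj$K_m, K_d = proj$K_d, K = proj$K, R = R)
}

#' Fit the personalized-recommendation association scorer
#'
#' Runs the whole scoring pipeline on a known miRNA-disease association
#' network: Gaussian interaction-profile kernels on both sides, semantic
#' similarity from the disease DAG (when supplied), integration into Sm
#' and Sd, the personalized rating matrices, the similarity projection,
#' and the final prediction matrix R. Scores are comparable within a
#' disease row and used to rank candidate miRNAs.
#'
#' @param network An [as_mda_network()] object or a pairs data frame with
#'   `disease` and `mirna` columns.
#' @param mirna_sim Curated miRNA functional similarity (role MS), or
#'   `NULL` to rely on the kernel only.
#' @param dag Disease DAG ([mda_dag()]) for semantic similarity, or `NULL`.
#' @param disease_sim Precomputed disease semantic similarity (role DS);
#'   overrides `dag`.
#' @param delta Semantic decay factor, default 0.5.
#' @param gamma_d,gamma_m Kernel bandwidth parameters, default 1.
#' @param norm Row norm for the combination steps, `"l2"` or `"l1"`.
#' @param log_base Logarithm base for weights and model-2 contributions.
#' @param similarity_threshold Count cut for "has similarity", default 0.
#' @param mirna_mask,disease_mask Optional availability-mask overrides.
#' @return Object of class `mda_fit` holding the prediction matrix `R`,
#'   every intermediate matrix, the network and the resolved parameters.
#' @export
#' @examples
#' sim <- simulate_mda(n_d = 10, n_m = 15, n_blocks = 2, seed = 1)
#' fit <- mda_fit(sim$network, mirna_sim = sim$mirna_sim, dag = sim$dag)
#' head(tidy(fit))
mda_fit <- function(network, mirna_sim = NULL, dag = NULL, disease_sim = NULL,
                    delta = 0.5, gamma_d = 1, gamma_m = 1,
                    norm = c("l2", "l1"), log_base = exp(1),
                    similarity_threshold = 0,
                    mirna_mask = NULL, disease_mask = NULL) {
  norm <- match.arg(norm)
  if (is.data.frame(network)) network <- as_mda_network(network)
  params <- list(delta = delta, gamma_d = gamma_d, gamma_m = gamma_m,
                 norm = norm, log_base = log_base,
                 similarity_threshold = similarity_threshold)
  DS <- resolve_disease_sim(network, dag, disease_sim, params)
  KD <- gip_kernel(network, "disease", gamma_d)
  KR <- gip_kernel(network, "mirna", gamma_m)
  Sm <- integrate_similarity(mirna_sim, KR, mask = mirna_mask,
                             threshold = similarity_threshold)
  Sd <- integrate_similarity(DS, KD, mask = disease_mask,
                             threshold = similarity_threshold)
  parts <- score_pipeline(network, Sm, Sd, params)
  structure(c(list(network = network, DS = DS, KD = KD, KR = KR,
                   Sm = Sm, Sd = Sd, params = params), parts),
            class = "mda_fit")
}

resolve_disease_sim <- function(network, dag, disease_sim, params) {
  if (!is.null(disease_sim)) return(disease_sim)
  if (is.null(dag)) return(NULL)
  semantic_similarity(dag, network$diseases, delta = params$delta,
                      model = "combined", log_base = params$log_base)
}

#' @export
print.mda_fit <- function(x, ...) {
  cat(sprintf("<mda_fit> %d diseases x %d miRNAs (%d known associations)\n",
              x$network$n_d, x$network$n_m, sum(x$network$adjacency)))
  cat(sprintf("  params: delta=%g gamma_d=%g gamma_m=%g norm=%s log_base=%g threshold=%g\n",
              x$params$delta, x$params$gamma_d, x$params$gamma_m,
              x$params$norm, x$params$log_base, x$params$similarity_threshold))
  invisible(x)
}

#' Tidy a fitted scorer into a long prediction table
#'
#' One row per disease-miRNA pair with the prediction score, the known
#' flag, and (for candidates, i.e. pairs with no known association) the
#' within-disease midrank by descending score.
#'
#' @param x An `mda_fit`.
#' @param ... Unused.
#' @return Tibble with columns `disease`, `mirna`, `score`, `known`,
#'   `rank`.
#' @export
tidy.mda_fit <- function(x, ...) {
  prediction_table(x$R, x$network)
}

prediction_table <- function(R, network) {
  if (!all(dim(R) == dim(network$adjacency))) {
    abort("prediction matrix shape does not match the network",
          class = "mirec_contract_error")
  }
  A <- network$adjacency
  tibble(disease = rep(rownames(A), times = ncol(A)),
         mirna = rep(colnames(A), each = nrow(A)),
         score = as.vector(R),
         known = as.integer(as.vector(A))) |>
    dplyr::group_by(.data$disease) |>
    dplyr::mutate(rank = {
      r <- rep(NA_real_, dplyr::n())
      cand <- .data$known == 0L
      if (any(cand)) r[cand] <- rank_desc(.data$score[cand])
      r
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$disease, .data$known == 1L, .data$rank, .data$mirna)
}

#' @describeIn mda_fit One-row model summary.
#' @param x An `mda_fit`.
#' @param ... Unused.
#' @export
glance.mda_fit <- function(x, ...) {
  tibble(n_diseases = x$network$n_d, n_mirnas = x$network$n_m,
         n_associations = sum(x$network$adjacency),
         delta = x$params$delta, gamma_d = x$params$gamma_d,
         gamma_m = x$params$gamma_m, norm = x$params$norm,
         log_base = x$params$log_base,
         similarity_threshold = x$params$similarity_threshold)
}

#' Ranked candidate miRNAs for one disease
#'
#' Candidates are the miRNAs with no known association to the disease;
#' they are ordered by descending prediction score with midrank ties
#' (display order breaks ties lexicographically by miRNA name).
#'
#' @param object An `mda_fit`.
#' @param disease Disease name (normalized internally); `NULL` returns all
#'   diseases via [tidy.mda_fit()].
#' @param k Optionally keep only the top k candidates.
#' @param include_known Keep known pairs (flagged, unranked) in the output.
#' @param ... Unused.
#' @return Tibble `disease`, `mirna`, `score`, `known`, `rank`.
#' @export
predict.mda_fit <- function(object, disease = NULL, k = NULL,
                            include_known = FALSE, ...) {
  tab <- tidy(object)
  if (!is.null(disease)) {
    disease <- normalize_names(disease)
    if (!disease %in% object$network$diseases) {
      abort(sprintf("unknown disease '%s'", disease), class = "mirec_lookup_error")
    }
    tab <- dplyr::filter(tab, .data$disease == !!disease)
  }
  if (!include_known || !is.null(k)) {
    tab <- dplyr::filter(tab, .data$known == 0L)
  }
  if (!is.null(k)) {
    tab <- tab |>
      dplyr::group_by(.data$disease) |>
      dplyr::arrange(.data$rank, .data$mirna, .by_group = TRUE) |>
      dplyr::slice_head(n = k) |>
      dplyr::ungroup()
  }
  tab
}

#' Alias for ranking candidates of one disease
#' @inheritParams predict.mda_fit
#' @param fit An `mda_fit`.
#' @export
rank_for_disease <- function(fit, disease, k = NULL) {
  predict(fit, disease = disease, k = k)
}

#' Write / read a prediction table
#'
#' Serializes predictions as a five-column TSV (`disease`, `mirna`,
#' `score`, `rank`, `known`): candidates ranked per disease by descending
#' score with midrank ties, known pairs flagged 1 and unranked. Scores are
#' written with round-trippable precision.
#'
#' @param x An `mda_fit`, or a prediction matrix (then `network` is
#'   required), or a tibble as from [tidy.mda_fit()].
#' @param path Output path.
#' @param network Network matching a raw prediction matrix.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(x, path, network = NULL) {
  tab <- if (inherits(x, "mda_fit")) {
    tidy(x)
  } else if (is.matrix(x)) {
    if (is.null(network)) {
      abort("a raw prediction matrix needs the matching network",
            class = "mirec_contract_error")
    }
    prediction_table(x, network)
  } else {
    as_tibble(x)
  }
  readr::write_tsv(tab[, c("disease", "mirna", "score", "rank", "known")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(disease = "c", mirna = "c",
                                          score = "d", rank = "d", known = "i"))
}
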