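#' Per-ancestor semantic contributions of a disease term
#'
#' Decomposes the semantic value of a disease D over its ancestor closure
#' T(D) under one of two models.
#'
#' Model 1 (decay): the self-contribution is 1 and each ancestor d
#' contributes `max(delta * contribution(d'))` over its children d' inside
#' T(D), so contributions decay geometrically with distance from D. The
#' semantic value SV1(D) is the sum of all contributions.
#'
#' Model 2 (DAG frequency): the self-contribution is 1 and an ancestor d
#' contributes `-log(n_dt / n_d)`, where `n_dt` is the number of disease
#' DAGs (among the `diseases` under study) whose closure contains d and
#' `n_d` is the number of diseases under study. Rare, specific ancestors
#' therefore contribute more than ubiquitous ones.
#'
#' @param dag An [mda_dag()].
#' @param disease Term whose decomposition is wanted.
#' @param model 1 or 2.
#' @param delta Decay factor in (0, 1) for model 1 (default 0.5).
#' @param diseases Ordered character vector of diseases under study,
#'   required for model 2 (defines `n_dt` counts and `n_d`).
#' @param log_base Base of the logarithm in model 2 (default `exp(1)`).
#' @return A list with `disease`, `model`, `contributions` (named numeric
#'   over T(D)) and `semantic_value`.
#' @export
#' @examples
#' dag <- mda_dag(data.frame(parent = c("a", "b"), child = c("b", "c")))
#' semantic_contributions(dag, "c", model = 1, delta = 0.5)
semantic_contributions <- function(dag, disease, model = 1, delta = 0.5,
                                   diseases = NULL, log_base = exp(1)) {
  disease <- normalize_names(disease)
  closure <- dag_ancestors(dag, disease)
  if (model == 1) {
    if (delta <= 0 || delta >= 1) {
      abort("delta must lie strictly between 0 and 1", class = "mirec_contract_error")
    }
    contrib <- model1_contributions(dag, disease, closure, delta)
  } else if (model == 2) {
    if (is.null(diseases)) {
      abort("model 2 needs the vector of diseases under study", class = "mirec_contract_error")
    }
    diseases <- normalize_names(diseases)
    counts <- closure_membership_counts(dag, diseases)
    contrib <- model2_contributions(disease, closure, counts, length(diseases), log_base)
  } else {
    abort("model must be 1 or 2", class = "mirec_contract_error")
  }
  list(disease = disease, model = model, contributions = contrib,
       semantic_value = sum(contrib))
}

# Memoized recursion: contribution(D) = 1; contribution(d) =
# max(delta * contribution(d')) over children d' of d inside T(D).
model1_contributions <- function(dag, disease, closure, delta) {
  memo <- new.env(parent = emptyenv())
  assign(disease, 1, envir = memo)
  rec <- function(d) {
    got <- get0(d, envir = memo)
    if (!is.null(got)) return(got)
    kids <- intersect(dag_children(dag, d), closure)
    val <- delta * max(vapply(kids, rec, numeric(1)))
    assign(d, val, envir = memo)
    val
  }
  setNames(vapply(closure, rec, numeric(1)), closure)
}

model2_contributions <- function(disease, closure, counts, n_d, log_base) {
  n_dt <- counts[closure]
  if (anyNA(n_dt) || any(n_dt == 0)) {
    abort("a closure term appears in no disease DAG; membership counts inconsistent",
          class = "mirec_contract_error")
  }
  contrib <- -log(n_dt / n_d, base = log_base)
  contrib[closure == disease] <- 1
  setNames(as.numeric(contrib), closure)
}

# n_dt per DAG term: number of study diseases whose closure contains it.
closure_membership_counts <- function(dag, diseases) {
  present <- diseases[diseases %in% dag$terms]
  counts <- setNames(numeric(length(dag$terms)), dag$terms)
  for (d in present) {
    cl <- dag_ancestors(dag, d)
    counts[cl] <- counts[cl] + 1
  }
  counts
}

#' Disease semantic similarity over a vocabulary DAG
#'
#' Pairwise semantic similarity between diseases, computed from the overlap
#' of their ancestor closures: the similarity of d(i) and d(j) is the sum
#' of both diseases' contributions over the shared ancestors, divided by
#' the sum of the two semantic values. `model = "1"` uses decay
#' contributions, `model = "2"` DAG-frequency contributions, and
#' `model = "combined"` (the default used by the predictor) the
#' element-wise mean of the two.
#'
#' Diseases absent from the DAG are permitted: their rows are zero
#' off-diagonal (diagonal 1) and a warning lists them; downstream they fall
#' back to the Gaussian interaction-profile kernel.
#'
#' @param dag An [mda_dag()].
#' @param diseases Ordered character vector of diseases (defines matrix
#'   order; also the universe for model 2 counts).
#' @inheritParams semantic_contributions
#' @param model `"combined"`, `"1"`, or `"2"`.
#' @return An [mda_similarity()] with role DS, DS1 or DS2.
#' @export
semantic_similarity <- function(dag, diseases, delta = 0.5,
                                model = c("combined", "1", "2"),
                                log_base = exp(1)) {
  model <- match.arg(as.character(model), c("combined", "1", "2"))
  diseases <- normalize_names(diseases)
  if (anyDuplicated(diseases)) {
    abort("disease list contains duplicates", class = "mirec_contract_error")
  }
  missing <- setdiff(diseases, dag$terms)
  if (length(missing) > 0) {
    warn(sprintf("%d disease(s) absent from the DAG get zero semantic similarity: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  if (model == "combined") {
    ds1 <- semantic_similarity_one(dag, diseases, delta, 1, log_base)
    ds2 <- semantic_similarity_one(dag, diseases, delta, 2, log_base)
    return(combine_semantic(ds1, ds2))
  }
  semantic_similarity_one(dag, diseases, delta, as.integer(model), log_base)
}

semantic_similarity_one <- function(dag, diseases, delta, model, log_base) {
  n <- length(diseases)
  out <- diag(1, n)
  dimnames(out) <- list(diseases, diseases)
  present <- diseases[diseases %in% dag$terms]
  if (length(present) >= 1) {
    counts <- if (model == 2) closure_membership_counts(dag, diseases) else NULL
    decomp <- lapply(present, function(d) {
      closure <- dag_ancestors(dag, d)
      contrib <- if (model == 1) {
        model1_contributions(dag, d, closure, delta)
      } else {
        model2_contributions(d, closure, counts, length(diseases), log_base)
      }
      list(contrib = contrib, sv = sum(contrib))
    })
    names(decomp) <- present
    if (length(present) >= 2) {
      for (a in seq_len(length(present) - 1)) {
        for (b in seq(a + 1, length(present))) {
          di <- decomp[[a]]; dj <- decomp[[b]]
          shared <- intersect(names(di$contrib), names(dj$contrib))
          val <- if (length(shared) == 0) 0 else
            sum(di$contrib[shared] + dj$contrib[shared]) / (di$sv + dj$sv)
          out[present[a], present[b]] <- out[present[b], present[a]] <- val
        }
      }
    }
  }
  mda_similarity(out, role = if (model == 1) "DS1" else "DS2", check = FALSE)
}

#' Average the two semantic similarity models
#'
#' Element-wise mean of the decay-model and frequency-model similarity
#' matrices; both must share label order.
#'
#' @param ds1,ds2 [mda_similarity()] matrices (roles DS1 and DS2).
#' @return An [mda_similarity()] with role DS.
#' @export
combine_semantic <- function(ds1, ds2) {
  check_labels_equal(ds1, ds2, "DS1 and DS2")
  mda_similarity((unclass(ds1) + unclass(ds2)) / 2, role = "DS", check = FALSE)
}
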