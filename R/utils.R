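# Internal helpers shared across modules.

#' Normalize entity names
#'
#' Disease and miRNA identifiers are matched across files (association list,
#' DAG, curated similarity, reference sets) by exact string equality after
#' normalization: trim leading/trailing whitespace, lowercase, and collapse
#' internal whitespace runs to a single space.
#'
#' @param x Character vector of raw names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_names(c("  Colon   Neoplasms ", "hsa-mir-21"))
normalize_names <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

# Row-wise normalization used throughout the rating pipeline.
# l2: divide each row by its Euclidean norm; l1: by its absolute sum.
# Zero-norm rows stay zero (never NaN).
row_normalize <- function(m, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  s <- if (norm == "l2") sqrt(rowSums(m^2)) else rowSums(abs(m))
  s[s == 0] <- 1
  m / s
}

# Divide each row by its plain sum, zero rows untouched. A row whose sign
# is uniformly negative (possible when the specificity log factor is
# negative) normalizes to the same non-negative ratios as a positive row:
# the per-row constant factor cancels.
row_sum_normalize <- function(m) {
  s <- rowSums(m)
  s[s == 0] <- 1
  m / s
}

stopifnot_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("%s must be square, got %d x %d", what, NROW(m), NCOL(m)),
          class = "mirec_format_error")
  }
}

check_labels_equal <- function(a, b, what = "matrices") {
  if (!identical(rownames(a), rownames(b)) || !identical(colnames(a), colnames(b))) {
    abort(sprintf("label mismatch: %s must share identical label order", what),
          class = "mirec_contract_error")
  }
}

# Midrank of each score when ranking descending (ties share the average rank).
rank_desc <- function(scores) {
  rank(-scores, ties.method = "average")
}
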