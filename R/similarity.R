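#' Labeled symmetric similarity matrix container
#'
#' All similarity matrices in the pipeline (curated miRNA functional
#' similarity MS, semantic similarity DS1/DS2/DS, Gaussian
#' interaction-profile kernels KD/KR, and the integrated matrices Sm/Sd)
#' are square, symmetric, label-aligned matrices with entries in \[0, 1\].
#' The container is a plain base matrix with a `role` attribute and class
#' `mda_sim`, so ordinary matrix algebra keeps working.
#'
#' @param values Square numeric matrix with identical row/column labels.
#' @param role One of `"MS"`, `"DS1"`, `"DS2"`, `"DS"`, `"KD"`, `"KR"`,
#'   `"Sm"`, `"Sd"`.
#' @param check Validate symmetry/range/diagonal invariants (default TRUE).
#' @return The matrix with class `mda_sim`.
#' @export
mda_similarity <- function(values, role = c("MS", "DS1", "DS2", "DS", "KD", "KR", "Sm", "Sd"),
                           check = TRUE) {
  role <- match.arg(role)
  values <- as.matrix(values)
  stopifnot_square(values, sprintf("%s similarity matrix", role))
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- sprintf("e%03d", seq_len(nrow(values)))
  }
  if (check) {
    if (!identical(rownames(values), colnames(values))) {
      abort("similarity row and column labels must match", class = "mirec_format_error")
    }
    if (max(abs(values - t(values))) > 1e-12) {
      abort(sprintf("%s matrix is not symmetric within 1e-12", role),
            class = "mirec_format_error")
    }
    if (min(values) < -1e-12 || max(values) > 1 + 1e-12) {
      abort(sprintf("%s entries must lie in [0, 1]", role), class = "mirec_format_error")
    }
    if (role %in% c("DS1", "DS2", "DS", "KD", "KR") &&
        max(abs(diag(values) - 1)) > 1e-12) {
      abort(sprintf("%s diagonal must equal 1", role), class = "mirec_format_error")
    }
  }
  structure(values, role = role, class = c("mda_sim", class(values)))
}

sim_role <- function(x) attr(x, "role") %||% "MS"

#' @export
print.mda_sim <- function(x, ...) {
  cat(sprintf("<mda_sim role=%s> %d x %d\n", sim_role(x), nrow(x), ncol(x)))
  if (nrow(x) <= 8) print(unclass(x)) else print(unclass(x)[1:5, 1:5])
  invisible(x)
}

#' Read a labeled similarity matrix from TSV/CSV
#'
#' Expects a numeric table with a header row and a leading label column,
#' row labels equal to column labels (such as a MISIM miRNA functional
#' similarity export). The matrix is symmetrized by averaging with its
#' transpose; asymmetries larger than `1e-6` raise a warning. Labels are
#' normalized with [normalize_names()].
#'
#' @param path File path; delimiter chosen by extension (`.csv` comma,
#'   otherwise tab).
#' @param role Role tag for the result, default `"MS"`.
#' @return An [mda_similarity()] matrix.
#' @export
read_similarity_matrix <- function(path, role = "MS") {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols(.default = "c"))
  if (ncol(df) < 2) {
    abort(sprintf("similarity file '%s' has no data columns", path),
          class = "mirec_format_error")
  }
  labels <- normalize_names(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    abort(sprintf("similarity table in '%s' is not square (%d rows, %d value columns)",
                  path, nrow(m), ncol(m)),
          class = "mirec_format_error")
  }
  vals <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric similarity value at row %d ('%s'), column %d ('%s')",
                  bad[1], labels[bad[1]], bad[2], colnames(df)[-1][bad[2]]),
          class = "mirec_format_error")
  }
  col_labels <- normalize_names(colnames(df)[-1])
  if (!identical(labels, col_labels)) {
    # allow same set in different order; reorder columns to match rows
    if (setequal(labels, col_labels) && !anyDuplicated(labels)) {
      vals <- vals[, match(labels, col_labels), drop = FALSE]
    } else {
      abort(sprintf("row labels and column labels disagree in '%s'", path),
            class = "mirec_format_error")
    }
  }
  asym <- max(abs(vals - t(vals)))
  if (asym > 1e-6) {
    warn(sprintf("similarity matrix in '%s' is asymmetric (max |S - t(S)| = %.3g); symmetrized by averaging",
                 path, asym))
  }
  vals <- (vals + t(vals)) / 2
  dimnames(vals) <- list(labels, labels)
  mda_similarity(vals, role = role, check = FALSE)
}

#' Write a similarity matrix as TSV
#'
#' @param sim An [mda_similarity()] (or plain labeled matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  df <- as.data.frame(unclass(sim))
  df <- cbind(name = rownames(sim), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}
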