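#' Build a miRNA-disease association network from a pairs table
#'
#' Collapses a long table of (disease, miRNA) association records into a
#' labeled binary bipartite adjacency matrix A with diseases on rows and
#' miRNAs on columns: `A[i, j] = 1` when disease i has an experimentally
#' supported association with miRNA j. Duplicate records collapse to a
#' single 1. Names are normalized (see [normalize_names()]) and both axes
#' are ordered lexicographically, so the result is independent of input
#' row order.
#'
#' @param pairs Data frame with one association per row.
#' @param disease_col,mirna_col Column names (or integer positions) holding
#'   the disease and miRNA identifiers.
#' @return An object of class `mda_network`: a list with `adjacency`
#'   (binary matrix, dimnames set), `diseases`, `mirnas`, `n_d`, `n_m`.
#' @export
#' @examples
#' as_mda_network(data.frame(mirna = c("m1", "m1", "m2"),
#'                           disease = c("dA", "dA", "dB")))
as_mda_network <- function(pairs, disease_col = "disease", mirna_col = "mirna") {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) {
    abort("association table is empty", class = "mirec_empty_input_error")
  }
  get_col <- function(col) {
    if (is.numeric(col)) {
      if (col > ncol(pairs)) {
        abort(sprintf("column index %d out of range", col), class = "mirec_format_error")
      }
      pairs[[col]]
    } else {
      if (!col %in% names(pairs)) {
        abort(sprintf("required column '%s' is missing from the association table", col),
              class = "mirec_format_error")
      }
      pairs[[col]]
    }
  }
  diseases <- normalize_names(get_col(disease_col))
  mirnas <- normalize_names(get_col(mirna_col))
  keep <- nzchar(diseases) & nzchar(mirnas)
  diseases <- diseases[keep]
  mirnas <- mirnas[keep]
  if (length(diseases) == 0) {
    abort("association table holds no usable records", class = "mirec_empty_input_error")
  }
  d_names <- sort(unique(diseases))
  m_names <- sort(unique(mirnas))
  A <- matrix(0L, length(d_names), length(m_names),
              dimnames = list(d_names, m_names))
  A[cbind(match(diseases, d_names), match(mirnas, m_names))] <- 1L
  new_mda_network(A)
}

new_mda_network <- function(A) {
  structure(
    list(adjacency = A,
         diseases = rownames(A),
         mirnas = colnames(A),
         n_d = nrow(A),
         n_m = ncol(A)),
    class = "mda_network"
  )
}

#' Construct a network directly from a binary adjacency matrix
#'
#' @param A Binary matrix, diseases on rows and miRNAs on columns; dimnames
#'   are used as entity names (generated when absent).
#' @return An `mda_network`.
#' @export
mda_network_from_adjacency <- function(A) {
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) {
    abort("adjacency entries must all be 0 or 1", class = "mirec_format_error")
  }
  if (is.null(rownames(A))) rownames(A) <- sprintf("d%03d", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- sprintf("m%03d", seq_len(ncol(A)))
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A))) {
    abort("adjacency dimnames must be unique", class = "mirec_format_error")
  }
  storage.mode(A) <- "integer"
  new_mda_network(A)
}

#' Read a tab-delimited association list (HMDD-style dialect)
#'
#' Reads flat files of experimentally supported miRNA-disease associations,
#' one pair per line, such as the HMDD V2.0 `alldata.txt` export. The
#' columns holding the miRNA and disease names are configurable by name or
#' position, so both headered and positional dialects are supported.
#'
#' @param path Path to a tab-delimited text file.
#' @param disease_col,mirna_col Column names or 1-based positions.
#' @param col_names Logical; does the file carry a header line? Defaults to
#'   `TRUE` when character column selectors are used.
#' @return An [as_mda_network()] object.
#' @export
read_associations <- function(path, disease_col = "disease", mirna_col = "mirna",
                              col_names = !is.numeric(disease_col)) {
  df <- tryCatch(
    readr::read_tsv(path, col_names = col_names, show_col_types = FALSE,
                    progress = FALSE, col_types = readr::cols(.default = "c")),
    error = function(e) abort(sprintf("cannot read association file '%s': %s", path,
                                      conditionMessage(e)),
                              class = "mirec_format_error")
  )
  if (nrow(df) == 0) {
    abort(sprintf("association file '%s' is empty", path),
          class = "mirec_empty_input_error")
  }
  as_mda_network(df, disease_col = disease_col, mirna_col = mirna_col)
}

#' @export
print.mda_network <- function(x, ...) {
  cat(sprintf("<mda_network> %d diseases x %d miRNAs, %d known associations\n",
              x$n_d, x$n_m, sum(x$adjacency)))
  invisible(x)
}

#' @describeIn as_mda_network Return the association pairs as a tibble
#'   (`disease`, `mirna`), one row per known association.
#' @param x An `mda_network`.
#' @param ... Unused.
#' @export
tidy.mda_network <- function(x, ...) {
  idx <- which(x$adjacency == 1L, arr.ind = TRUE)
  tibble(disease = x$diseases[idx[, 1]], mirna = x$mirnas[idx[, 2]]) |>
    dplyr::arrange(.data$disease, .data$mirna)
}

#' @describeIn as_mda_network One-row summary (sizes, association count,
#'   density).
#' @export
glance.mda_network <- function(x, ...) {
  tibble(n_diseases = x$n_d, n_mirnas = x$n_m,
         n_associations = sum(x$adjacency),
         density = mean(x$adjacency))
}
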