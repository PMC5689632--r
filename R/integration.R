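#' Availability mask of a curated similarity matrix
#'
#' Marks the entity pairs for which curated similarity evidence exists: both
#' entities appear in the curated matrix and the stored value exceeds
#' `threshold` (default 0 -- a stored 0 is read as "no evidence", the same
#' epistemic state as an absent pair, and falls back to the kernel). The
#' diagonal is available wherever the entity appears in the curated matrix.
#'
#' @param curated Curated similarity matrix (e.g. role MS or DS), possibly
#'   covering only a subset of `labels`.
#' @param labels Full ordered label set of the target matrix.
#' @param threshold Availability cut on stored values, default 0
#'   (strictly greater than).
#' @return Logical symmetric matrix over `labels`.
#' @export
availability_mask <- function(curated, labels, threshold = 0) {
  labels <- normalize_names(labels)
  mask <- matrix(FALSE, length(labels), length(labels),
                 dimnames = list(labels, labels))
  if (is.null(curated)) return(mask)
  present <- intersect(labels, rownames(curated))
  if (length(present) > 0) {
    sub <- unclass(curated)[present, present, drop = FALSE] > threshold
    mask[present, present] <- sub
    mask[cbind(present, present)] <- TRUE
  }
  mask
}

#' Integrate curated and kernel similarity
#'
#' The integrated similarity uses the curated value wherever the
#' availability mask is true and the Gaussian interaction-profile kernel
#' value otherwise (a hard switch, not a blend). `integrate_similarity`
#' dispatches the result role from the kernel role: KR yields Sm
#' (integrated miRNA similarity), KD yields Sd (integrated disease
#' similarity).
#'
#' @param curated Curated similarity ([mda_similarity()], role MS or DS),
#'   or `NULL` to use the kernel everywhere.
#' @param kernel Kernel similarity (role KR or KD) over the full label set.
#' @param mask Logical availability matrix as from [availability_mask()];
#'   derived automatically from `curated` when `NULL`.
#' @param threshold Availability cut used when deriving the mask.
#' @return An [mda_similarity()] with role Sm or Sd.
#' @export
integrate_similarity <- function(curated, kernel, mask = NULL, threshold = 0) {
  labels <- rownames(kernel)
  if (is.null(mask)) {
    mask <- availability_mask(curated, labels, threshold = threshold)
  } else {
    check_labels_equal(mask, kernel, "mask and kernel")
  }
  out <- unclass(kernel)
  if (!is.null(curated)) {
    present <- intersect(labels, rownames(curated))
    if (length(present) == 0 && any(mask)) {
      abort("availability mask marks pairs but no curated labels match the kernel labels",
            class = "mirec_contract_error")
    }
    if (length(present) > 0) {
      cur_full <- matrix(0, length(labels), length(labels),
                         dimnames = list(labels, labels))
      cur_full[present, present] <- unclass(curated)[present, present]
      out[mask] <- cur_full[mask]
    }
  }
  out <- (out + t(out)) / 2
  mda_similarity(out, role = if (sim_role(kernel) == "KR") "Sm" else "Sd", check = FALSE)
}
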