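#' Gaussian interaction-profile kernel similarity
#'
#' The interaction profile IP of a disease is its row of the binary
#' adjacency matrix A (which miRNAs it is associated with); the profile of
#' a miRNA is its column. The kernel similarity between two entities is
#' `exp(-gamma * ||IP_i - IP_j||^2)` with squared Euclidean distance. The
#' bandwidth is normalized by the mean squared profile norm:
#' `gamma = gamma_prime / mean_i(||IP_i||^2)`, i.e. by the average number
#' of known associations per entity.
#'
#' @param network An [as_mda_network()] object (or binary adjacency matrix).
#' @param margin `"disease"` for the disease-disease kernel KD (profiles =
#'   rows of A), `"mirna"` for the miRNA-miRNA kernel KR (columns of A).
#' @param gamma_prime Raw bandwidth parameter, default 1.
#' @return An [mda_similarity()] with role KD or KR.
#' @export
#' @examples
#' net <- mda_network_from_adjacency(matrix(c(1, 0, 0, 1), 2, 2))
#' gip_kernel(net, "disease")
gip_kernel <- function(network, margin = c("disease", "mirna"), gamma_prime = 1) {
  margin <- match.arg(margin)
  A <- if (inherits(network, "mda_network")) network$adjacency else as.matrix(network)
  P <- if (margin == "disease") A else t(A)
  storage.mode(P) <- "double"
  if (gamma_prime <= 0) {
    abort("gamma_prime must be positive", class = "mirec_contract_error")
  }
  sq <- rowSums(P^2)
  if (all(sq == 0)) {
    abort("all interaction profiles are zero; the kernel bandwidth is undefined -- guard the caller (e.g. empty LOOCV fold network)",
          class = "mirec_contract_error")
  }
  gamma <- gamma_prime / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0 # numerical floor
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  mda_similarity(K, role = if (margin == "disease") "KD" else "KR", check = FALSE)
}
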