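#' Simulate a planted-block miRNA-disease study
#'
#' Generates every input the pipeline consumes -- a bipartite association
#' network, a curated miRNA functional-similarity matrix with an
#' availability mask, and a disease vocabulary DAG -- with planted
#' co-module structure embodying the guilt-by-association hypothesis:
#' functionally similar miRNAs associate with semantically similar
#' diseases. Diseases and miRNAs are partitioned into `n_blocks` paired
#' co-modules; associations are Bernoulli(`p_in`) within a co-module and
#' Bernoulli(`p_out`) between; curated similarity is `s_in` (within) or
#' `s_out` (between) plus Gaussian noise, clipped to \[0, 1\], symmetrized,
#' diagonal 1; availability is drawn at `mask_density`; and the DAG hangs
#' one random tree per block off a common root so same-block diseases
#' share ancestors.
#'
#' All draws run through one seeded local RNG, so outputs are bit-identical
#' for a given seed and the session RNG state is untouched.
#'
#' @param n_d,n_m Numbers of diseases and miRNAs (default 40 x 60).
#' @param n_blocks Number of co-modules (default 4).
#' @param p_in,p_out Within/between-block association probabilities
#'   (defaults 0.3 / 0.02; requires `p_out < p_in`).
#' @param s_in,s_out Mean curated similarity within/between blocks
#'   (defaults 0.7 / 0.1).
#' @param noise_sd Gaussian noise SD on curated similarity (default 0.1).
#' @param mask_density Fraction of miRNA pairs with curated similarity
#'   available (default 0.7).
#' @param seed RNG seed (default 1).
#' @return List with `network` ([as_mda_network()] object), `mirna_sim`
#'   (role MS), `mask` (logical matrix), `dag` ([mda_dag()]), and
#'   `blocks` (tibble mapping each entity to its block).
#' @export
#' @examples
#' sim <- simulate_mda(n_d = 10, n_m = 15, n_blocks = 2, seed = 7)
#' sim$network
simulate_mda <- function(n_d = 40, n_m = 60, n_blocks = 4,
                         p_in = 0.3, p_out = 0.02,
                         s_in = 0.7, s_out = 0.1, noise_sd = 0.1,
                         mask_density = 0.7, seed = 1) {
  if (n_d < n_blocks || n_m < n_blocks || n_d <= 0 || n_m <= 0) {
    abort("sizes must be positive and at least one entity per block",
          class = "mirec_validation_error")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort("need 0 <= p_out < p_in <= 1 for recoverable planted structure",
          class = "mirec_validation_error")
  }
  if (!(s_out >= 0 && s_out < s_in && s_in <= 1)) {
    abort("need 0 <= s_out < s_in <= 1", class = "mirec_validation_error")
  }
  withr::with_seed(seed, {
    d_names <- sprintf("disease%03d", seq_len(n_d))
    m_names <- sprintf("mirna%03d", seq_len(n_m))
    d_block <- sort(rep(seq_len(n_blocks), length.out = n_d))
    m_block <- sort(rep(seq_len(n_blocks), length.out = n_m))

    same_dm <- outer(d_block, m_block, "==")
    P <- ifelse(same_dm, p_in, p_out)
    A <- matrix(rbinom(n_d * n_m, 1L, as.vector(P)), n_d, n_m,
                dimnames = list(d_names, m_names))
    storage.mode(A) <- "integer"

    same_mm <- outer(m_block, m_block, "==")
    MS <- ifelse(same_mm, s_in, s_out) + matrix(rnorm(n_m * n_m, 0, noise_sd), n_m, n_m)
    MS[lower.tri(MS)] <- t(MS)[lower.tri(MS)]
    MS <- pmin(pmax(MS, 0), 1)
    diag(MS) <- 1
    dimnames(MS) <- list(m_names, m_names)

    mask <- matrix(runif(n_m * n_m) < mask_density, n_m, n_m)
    mask[lower.tri(mask)] <- t(mask)[lower.tri(mask)]
    diag(mask) <- TRUE
    dimnames(mask) <- list(m_names, m_names)
    MS[!mask] <- 0 # unavailable pairs carry no curated evidence

    dag <- random_block_dag(d_names, d_block)

    list(network = new_mda_network(A),
         mirna_sim = mda_similarity(MS, role = "MS", check = FALSE),
         mask = mask,
         dag = dag,
         blocks = tibble(entity = c(d_names, m_names),
                         kind = rep(c("disease", "mirna"), c(n_d, n_m)),
                         block = c(d_block, m_block)))
  })
}

# One random tree per block under a shared root: each disease's parent is
# drawn among the block root and earlier same-block diseases.
random_block_dag <- function(d_names, d_block) {
  blocks <- sort(unique(d_block))
  edges <- purrr::map(blocks, function(b) {
    broot <- sprintf("blockroot%02d", b)
    members <- d_names[d_block == b]
    parents <- vapply(seq_along(members), function(i) {
      pool <- c(broot, members[seq_len(i - 1)])
      pool[sample.int(length(pool), 1)]
    }, character(1))
    tibble(parent = c("root", parents), child = c(broot, members))
  }) |> purrr::list_rbind()
  mda_dag(edges)
}

#' Degree-preserving rewiring of an association network
#'
#' Null control that destroys block structure while preserving every
#' disease and miRNA degree exactly, via repeated checkerboard swaps: pick
#' two associations (i1, j1), (i2, j2) with A(i1, j2) = A(i2, j1) = 0 and
#' replace them by the swapped pair.
#'
#' @param network An [as_mda_network()] object.
#' @param seed RNG seed.
#' @param n_swaps Number of attempted swaps (default 10x the association
#'   count).
#' @return A rewired `mda_network` with identical row and column sums.
#' @export
shuffle_network <- function(network, seed = 1, n_swaps = NULL) {
  if (is.data.frame(network)) network <- as_mda_network(network)
  A <- network$adjacency
  n_swaps <- n_swaps %||% (10L * sum(A))
  withr::with_seed(seed, {
    edges <- which(A == 1L, arr.ind = TRUE)
    for (s in seq_len(n_swaps)) {
      pick <- sample.int(nrow(edges), 2)
      e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
      if (e1[1] == e2[1] || e1[2] == e2[2]) next
      if (A[e1[1], e2[2]] == 1L || A[e2[1], e1[2]] == 1L) next
      A[e1[1], e1[2]] <- 0L; A[e2[1], e2[2]] <- 0L
      A[e1[1], e2[2]] <- 1L; A[e2[1], e1[2]] <- 1L
      edges[pick[1], 2] <- e2[2]
      edges[pick[2], 2] <- e1[2]
    }
    new_mda_network(A)
  })
}

# Fraction of associations falling inside a disease-miRNA co-module; the
# block-modularity statistic used to verify that rewiring destroys the
# planted structure.
within_block_fraction <- function(network, blocks) {
  A <- network$adjacency
  d_block <- blocks$block[match(rownames(A), blocks$entity)]
  m_block <- blocks$block[match(colnames(A), blocks$entity)]
  same <- outer(d_block, m_block, "==")
  sum(A[same]) / sum(A)
}
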