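pos_sim <- function(n, labels, value = 0.5) {
  S <- matrix(value, n, n, dimnames = list(labels, labels))
  diag(S) <- 1
  S
}

hand_instance <- function() {
  A <- matrix(c(1L, 0L, 1L, 1L, 0L, 1L), 2, 3,
              dimnames = list(c("d1", "d2"), c("m1", "m2", "m3")))
  list(net = mda_network_from_adjacency(A),
       Sm = pos_sim(3, c("m1", "m2", "m3")),
       Sd = pos_sim(2, c("d1", "d2")))
}

test_that("disease-side weights match the hand evaluation", {
  h <- hand_instance()
  W <- personalized_weights(h$net, h$Sm, h$Sd, "disease")
  # disease 1: n_a = 2, N_a = 3, n_tal = 2 for every miRNA
  expect_equal(unname(W[1, ]), rep(2 * log(3 / 2), 3), tolerance = 1e-9)
  expect_equal(unname(W[1, 1]), 0.810930, tolerance = 1e-6)

  # miRNA m3 similar only to itself: n_tal for (d1, m3) counts k in {m1, m2}
  Sm2 <- h$Sm
  Sm2["m3", ] <- Sm2[, "m3"] <- 0
  Sm2["m3", "m3"] <- 1
  W2 <- personalized_weights(h$net, Sm2, h$Sd, "disease")
  expect_equal(W2["d1", "m3"], 0)
  expect_gt(W2["d1", "m1"], 0)
})

test_that("weights vanish for entities with no associations", {
  h <- hand_instance()
  A <- h$net$adjacency
  A["d2", ] <- 0L
  net <- mda_network_from_adjacency(A)
  W <- personalized_weights(net, h$Sm, h$Sd, "disease")
  expect_equal(unname(W["d2", ]), rep(0, 3))
  Wm <- personalized_weights(net, h$Sm, h$Sd, "mirna")
  # m3 now has no associated disease
  expect_equal(unname(Wm["m3", ]), rep(0, 2))
})

test_that("the miRNA side is the exact dual of the disease side", {
  inst <- random_instance(6, 9, seed = 11)
  net <- mda_network_from_adjacency(inst$A)
  net_t <- mda_network_from_adjacency(t(inst$A))
  W_m <- personalized_weights(net, inst$Sm, inst$Sd, "mirna")
  W_d_dual <- personalized_weights(net_t, inst$Sd, inst$Sm, "disease")
  expect_equal(unname(W_m), unname(W_d_dual), tolerance = 1e-12)
})

test_that("rating rows normalize to 1, zero rows stay zero", {
  Z <- rating_submatrix(matrix(c(2, 2, 2, 0, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(Z[1, ], rep(1 / 3, 3))
  expect_equal(Z[2, ], rep(0, 3))

  h <- hand_instance()
  W <- personalized_weights(h$net, h$Sm, h$Sd, "disease")
  Zd <- rating_submatrix(W)
  expect_equal(unname(Zd[1, ]), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("negative specificity factors cancel in normalization with a warning", {
  rlang::reset_warning_verbosity("mirec_negative_log_weight")
  inst <- random_instance(4, 8, seed = 13, sim_zero_frac = 0)
  net <- mda_network_from_adjacency(inst$A)
  expect_warning(Wm <- personalized_weights(net, inst$Sm, inst$Sd, "mirna"),
                 "negative")
  Zm <- rating_submatrix(Wm)
  nonzero <- rowSums(abs(Zm)) > 0
  expect_true(all(Zm >= 0))
  expect_equal(unname(rowSums(Zm)[nonzero]), rep(1, sum(nonzero)),
               tolerance = 1e-12)
})

test_that("rating combination and row norms follow the hand example", {
  Zr <- matrix(1 / 3, 1, 3)
  Z <- combine_ratings(Zr, Zr)
  expect_equal(unname(Z[1, ]), rep(2 / sqrt(3), 3), tolerance = 1e-9)
  expect_equal(Z[1, 1], 1.154701, tolerance = 1e-6)

  # zero miRNA side leaves the row-normalized disease side
  Z2 <- combine_ratings(Zr, 0 * Zr)
  expect_equal(unname(Z2[1, ]), rep(1 / sqrt(3), 3), tolerance = 1e-12)

  # invariance to positive row rescaling
  Z3 <- combine_ratings(5 * Zr, 0.1 * Zr)
  expect_equal(Z3, Z, tolerance = 1e-12)

  expect_error(combine_ratings(Zr, matrix(1, 2, 2)),
               class = "mirec_contract_error")
})

test_that("similarity projection matches identity and hand cases", {
  A <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("d1", "d2"), c("m1", "m2")))
  net <- mda_network_from_adjacency(A)
  I2 <- diag(2); dimnames(I2) <- list(c("d1", "d2"), c("d1", "d2"))
  I2m <- diag(2); dimnames(I2m) <- list(c("m1", "m2"), c("m1", "m2"))
  K <- similarity_projection(net, I2m, I2)
  expect_equal(unname(K), 2 * unname(A), tolerance = 1e-12)

  h <- hand_instance()
  Sd <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("d1", "d2"), c("d1", "d2")))
  I3 <- diag(3); dimnames(I3) <- list(c("m1", "m2", "m3"), c("m1", "m2", "m3"))
  parts <- similarity_projection(h$net, I3, Sd, pieces = TRUE)
  expect_equal(unname(parts$K_d[1, ]), c(1, 1.5, 0.5))
  Kd_norm <- parts$K_d[1, ] / sqrt(3.5)
  expect_equal(unname(Kd_norm), c(0.534522, 0.801784, 0.267261), tolerance = 1e-6)
  expect_equal(unname(parts$K_m[1, ]), c(1, 1, 0))
})

test_that("final combination handles equal and degenerate inputs", {
  K <- matrix(c(3, 4, 0, 0), 2, 2, byrow = TRUE)
  R <- mirec:::prediction_matrix(K, K)
  expect_equal(R[1, ], 2 * c(3, 4) / 5, tolerance = 1e-12)
  Z <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  R2 <- mirec:::prediction_matrix(0 * K, Z)
  expect_equal(R2[2, ], c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("vectorized pipeline equals the per-entry loop oracle", {
  for (s in 1:20) {
    inst <- random_instance(sample(5:15, 1), sample(6:20, 1), seed = 300 + s)
    net <- mda_network_from_adjacency(inst$A)
    params <- list(similarity_threshold = 0, log_base = exp(1), norm = "l2")
    got <- suppressWarnings(mirec:::score_pipeline(net, inst$Sm, inst$Sd, params))
    want <- suppressWarnings(oracle_scores(inst$A, inst$Sm, inst$Sd))
    expect_equal(max(abs(got$R - want)), 0, tolerance = 1e-12)
    expect_true(all(is.finite(got$R)))
  }
})

test_that("scores are jointly permutation-equivariant and deterministic", {
  inst <- random_instance(8, 11, seed = 77)
  net <- mda_network_from_adjacency(inst$A)
  params <- list(similarity_threshold = 0, log_base = exp(1), norm = "l2")
  R1 <- suppressWarnings(mirec:::score_pipeline(net, inst$Sm, inst$Sd, params))$R
  R1b <- suppressWarnings(mirec:::score_pipeline(net, inst$Sm, inst$Sd, params))$R
  expect_identical(R1, R1b)

  pd <- withr::with_seed(2, sample(8)); pm <- withr::with_seed(3, sample(11))
  net_p <- mda_network_from_adjacency(inst$A[pd, pm])
  R2 <- suppressWarnings(mirec:::score_pipeline(net_p, inst$Sm[pm, pm],
                                                inst$Sd[pd, pd], params))$R
  expect_equal(unname(R2), unname(R1[pd, pm]), tolerance = 1e-12)
})

test_that("candidate ranking excludes knowns and midranks ties", {
  A <- matrix(c(1L, 0L, 0L, 0L), 1, 4,
              dimnames = list("dx", paste0("m", 1:4)))
  net <- mda_network_from_adjacency(A)
  sim <- simulate_mda(n_d = 6, n_m = 8, n_blocks = 2, seed = 2)
  fit <- suppressWarnings(mda_fit(sim$network, mirna_sim = sim$mirna_sim,
                                  dag = sim$dag))
  top <- predict(fit, disease = sim$network$diseases[1])
  expect_true(all(top$known == 0L))
  expect_equal(sort(top$rank), sort(rank(-top$score)))
  expect_error(predict(fit, disease = "not a disease"),
               class = "mirec_lookup_error")

  # disease fully associated -> empty candidate list
  A2 <- matrix(1L, 2, 3, dimnames = list(c("da", "db"), c("m1", "m2", "m3")))
  A2["db", 1] <- 0L
  fit2 <- suppressWarnings(mda_fit(mda_network_from_adjacency(A2),
                                   mirna_sim = NULL, dag = NULL))
  expect_equal(nrow(predict(fit2, disease = "da")), 0)
})
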