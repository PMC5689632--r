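test_that("single-fold ROC endpoints behave as expected", {
  # held-out positive at the very top of 11 candidates
  res <- roc_from_ranks(1, 11)
  expect_equal(res$auc, 1)
  # positive at the exact middle
  res <- roc_from_ranks((10 + 2) / 2, 10)
  expect_equal(res$auc, 0.5)
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(res$roc$tpr[1], 0)
  expect_equal(res$roc$fpr[nrow(res$roc)], 1)
  expect_equal(res$roc$tpr[nrow(res$roc)], 1)
})

test_that("ROC invariants hold and trapezoid equals the reported AUC", {
  for (s in 1:20) {
    withr::with_seed(400 + s, {
      n <- sample(3:40, 1)
      counts <- sample(5:30, n, replace = TRUE)
      ranks <- 1 + floor(runif(n) * (counts + 1))
    })
    res <- roc_from_ranks(ranks, counts)
    expect_true(all(diff(res$roc$fpr) >= -1e-12))
    expect_true(all(diff(res$roc$tpr) >= -1e-12))
    expect_equal(trapezoid_area(res$roc), res$auc, tolerance = 1e-12)
  }
})

test_that("AUC equals the pairwise-comparison oracle on random score pools", {
  for (s in 1:100) {
    pools <- withr::with_seed(600 + s, {
      n_folds <- sample(2:15, 1)
      tie_prone <- s %% 2 == 0
      lapply(seq_len(n_folds), function(f) {
        c <- sample(4:25, 1)
        if (tie_prone) {
          vals <- sample(seq(0, 1, by = 0.25), c + 1, replace = TRUE)
        } else {
          vals <- runif(c + 1)
        }
        list(pos = vals[1], neg = vals[-1])
      })
    })
    ranks <- vapply(pools, function(p)
      unname(rank(-c(p$neg, p$pos), ties.method = "average")[length(p$neg) + 1]),
      numeric(1))
    counts <- vapply(pools, function(p) length(p$neg), numeric(1))
    res <- roc_from_ranks(ranks, counts)
    tol <- if (s %% 2 == 0) 1e-9 else 1e-12
    expect_equal(res$auc, oracle_pairwise_auc(pools), tolerance = tol)
  }
})

test_that("roc_from_ranks validates its contract", {
  expect_error(roc_from_ranks(numeric(0), numeric(0)),
               class = "mirec_contract_error")
  expect_error(roc_from_ranks(c(1, 12), c(10, 10)),
               class = "mirec_contract_error")
  expect_error(roc_from_ranks(1, c(10, 10)), class = "mirec_contract_error")
})

test_that("LOOCV ranks held-out pairs against original-network candidates", {
  sim <- simulate_mda(n_d = 8, n_m = 12, n_blocks = 2, seed = 5)
  cv <- suppressWarnings(mda_loocv(sim$network, mirna_sim = sim$mirna_sim,
                                   dag = sim$dag))
  A <- sim$network$adjacency
  expect_equal(cv$n_folds, sum(A))
  # candidate pool excludes the disease's other positives
  expected_counts <- (ncol(A) - rowSums(A))[cv$folds$disease]
  expect_equal(cv$folds$candidate_count, unname(expected_counts))
  expect_true(all(cv$folds$rank >= 1 &
                    cv$folds$rank <= cv$folds$candidate_count + 1))
  expect_true(cv$auc >= 0 && cv$auc <= 1)
})

test_that("LOOCV AUC is invariant under joint relabeling", {
  sim <- simulate_mda(n_d = 6, n_m = 9, n_blocks = 2, seed = 6)
  cv <- suppressWarnings(mda_loocv(sim$network, mirna_sim = sim$mirna_sim,
                                   dag = sim$dag))
  A <- sim$network$adjacency
  rownames(A) <- paste0("zz ", rownames(A))
  # relabel diseases consistently in network and DAG
  edges <- sim$dag$edges
  edges$parent <- ifelse(edges$parent %in% sim$network$diseases,
                         paste("zz", edges$parent), edges$parent)
  edges$child <- ifelse(edges$child %in% sim$network$diseases,
                        paste("zz", edges$child), edges$child)
  cv2 <- suppressWarnings(mda_loocv(mda_network_from_adjacency(A),
                                    mirna_sim = sim$mirna_sim,
                                    dag = mda_dag(edges)))
  expect_equal(cv2$auc, cv$auc, tolerance = 1e-12)
})

test_that("a single-association disease is scored via the projection path", {
  sim <- simulate_mda(n_d = 6, n_m = 9, n_blocks = 2, seed = 9)
  A <- sim$network$adjacency
  A[1, ] <- 0L
  A[1, 3] <- 1L # exactly one association; its fold leaves a zero row
  net <- mda_network_from_adjacency(A)
  cv <- suppressWarnings(mda_loocv(net, mirna_sim = sim$mirna_sim, dag = sim$dag))
  f <- dplyr::filter(cv$folds, disease == rownames(A)[1])
  expect_equal(nrow(f), 1)
  expect_true(is.finite(f$rank) && f$rank >= 1)
})

test_that("static kernels change folds but agree on the full-data fit", {
  sim <- simulate_mda(n_d = 6, n_m = 9, n_blocks = 2, seed = 10)
  cv_full <- suppressWarnings(mda_loocv(sim$network, mirna_sim = sim$mirna_sim,
                                        dag = sim$dag))
  cv_static <- suppressWarnings(mda_loocv(sim$network, mirna_sim = sim$mirna_sim,
                                          dag = sim$dag, static_kernels = TRUE))
  expect_equal(cv_static$n_folds, cv_full$n_folds)
  expect_true(all(cv_static$folds$candidate_count ==
                    cv_full$folds$candidate_count))
})

test_that("folds_limit subsamples reproducibly", {
  sim <- simulate_mda(n_d = 8, n_m = 12, n_blocks = 2, seed = 11)
  cv1 <- suppressWarnings(mda_loocv(sim$network, mirna_sim = sim$mirna_sim,
                                    dag = sim$dag, folds_limit = 5, seed = 3))
  cv2 <- suppressWarnings(mda_loocv(sim$network, mirna_sim = sim$mirna_sim,
                                    dag = sim$dag, folds_limit = 5, seed = 3))
  expect_equal(cv1$folds, cv2$folds)
  expect_equal(cv1$n_folds, 5)
})

test_that("LOOCV refuses an empty network", {
  net <- mda_network_from_adjacency(matrix(0L, 2, 2))
  expect_error(mda_loocv(net), class = "mirec_contract_error")
})

test_that("top-k validation annotates confirmations per reference source", {
  sim <- simulate_mda(n_d = 8, n_m = 12, n_blocks = 2, seed = 12)
  d <- sim$network$diseases[1]
  all_ref <- tibble::tibble(disease = d, mirna = sim$network$mirnas)
  out <- suppressWarnings(
    topk_validation(sim$network, mirna_sim = sim$mirna_sim, dag = sim$dag,
                    disease = d, reference_sets = list(full = all_ref), k = 5))
  expect_equal(attr(out, "n_confirmed_topk"), nrow(out)) # everything confirmed
  out0 <- suppressWarnings(
    topk_validation(sim$network, mirna_sim = sim$mirna_sim, dag = sim$dag,
                    disease = d,
                    reference_sets = list(none = data.frame(disease = character(),
                                                            mirna = character())),
                    k = 5))
  expect_equal(attr(out0, "n_confirmed_topk"), 0)
})

test_that("removal protocol equals the standard one for an unknown-free disease", {
  sim <- simulate_mda(n_d = 8, n_m = 12, n_blocks = 2, seed = 13)
  A <- sim$network$adjacency
  A[2, ] <- 0L
  net <- mda_network_from_adjacency(A)
  d <- rownames(A)[2]
  a <- suppressWarnings(topk_validation(net, mirna_sim = sim$mirna_sim,
                                        dag = sim$dag, disease = d, k = 6,
                                        protocol = "standard"))
  b <- suppressWarnings(topk_validation(net, mirna_sim = sim$mirna_sim,
                                        dag = sim$dag, disease = d, k = 6,
                                        protocol = "remove-disease"))
  expect_equal(a$mirna, b$mirna)
  expect_equal(a$score, b$score, tolerance = 1e-12)
})

test_that("planted hold-out edges are recovered by top-k enumeration", {
  sim <- simulate_mda(n_d = 8, n_m = 12, n_blocks = 2, p_in = 0.6,
                      p_out = 0.02, seed = 14)
  # hide one disease's associations, use them as the reference set
  d <- sim$network$diseases[1]
  known <- tidy(sim$network) |> dplyr::filter(disease == d)
  out <- suppressWarnings(
    topk_validation(sim$network, mirna_sim = sim$mirna_sim, dag = sim$dag,
                    disease = d, reference_sets = list(heldout = known),
                    k = 12, protocol = "remove-disease"))
  hits_enumerated <- sum(out$mirna[seq_len(nrow(out))] %in% known$mirna)
  expect_equal(attr(out, "n_confirmed_topk"), hits_enumerated)
})
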