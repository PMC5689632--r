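# Independent brute-force oracles. Everything here is written with explicit
# loops and set operations, deliberately avoiding the package's vectorized
# code paths, so agreement between the two is evidence of correctness.

# --- DAG oracles -----------------------------------------------------------

# Ancestor closure by iterated parent expansion on the raw edge list.
oracle_closure <- function(edges, term) {
  members <- term
  repeat {
    parents <- unique(edges$parent[edges$child %in% members])
    grown <- union(members, parents)
    if (length(grown) == length(members)) return(sort(members))
    members <- grown
  }
}

# Decay contribution of every closure member d to disease D: enumerate all
# downward paths d -> ... -> D and take max(delta^length); independent of
# the package's memoized child-max recursion.
oracle_d1 <- function(edges, D, delta) {
  closure <- oracle_closure(edges, D)
  paths_max <- function(from) {
    if (from == D) return(1)
    best <- -Inf
    kids <- edges$child[edges$parent == from]
    for (k in kids) {
      if (k %in% closure) {
        v <- delta * paths_max(k)
        if (v > best) best <- v
      }
    }
    best
  }
  setNames(vapply(closure, paths_max, numeric(1)), closure)
}

oracle_sv1 <- function(edges, D, delta) sum(oracle_d1(edges, D, delta))

oracle_ds1 <- function(edges, diseases, delta) {
  n <- length(diseases)
  out <- diag(1, n); dimnames(out) <- list(diseases, diseases)
  dec <- lapply(diseases, function(d) oracle_d1(edges, d, delta))
  names(dec) <- diseases
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- intersect(names(dec[[i]]), names(dec[[j]]))
    out[i, j] <- if (length(shared) == 0) 0 else
      sum(dec[[i]][shared] + dec[[j]][shared]) / (sum(dec[[i]]) + sum(dec[[j]]))
  }
  out
}

oracle_d2 <- function(edges, D, diseases) {
  closure <- oracle_closure(edges, D)
  n_d <- length(diseases)
  n_dt <- vapply(closure, function(t) {
    sum(vapply(diseases, function(d) t %in% oracle_closure(edges, d), logical(1)))
  }, numeric(1))
  contrib <- -log(n_dt / n_d)
  contrib[closure == D] <- 1
  setNames(contrib, closure)
}

oracle_ds2 <- function(edges, diseases) {
  n <- length(diseases)
  out <- diag(1, n); dimnames(out) <- list(diseases, diseases)
  dec <- lapply(diseases, function(d) oracle_d2(edges, d, diseases))
  names(dec) <- diseases
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- intersect(names(dec[[i]]), names(dec[[j]]))
    out[i, j] <- if (length(shared) == 0) 0 else
      sum(dec[[i]][shared] + dec[[j]][shared]) / (sum(dec[[i]]) + sum(dec[[j]]))
  }
  out
}

# Random DAG on n nodes: each node past the first picks 1-2 earlier parents.
random_dag_edges <- function(n, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("t%02d", seq_len(n))
    parent <- character(); child <- character()
    for (i in 2:n) {
      k <- sample(1:min(2, i - 1), 1)
      for (p in sample(nodes[seq_len(i - 1)], k)) {
        parent <- c(parent, p); child <- c(child, nodes[i])
      }
    }
    list(edges = data.frame(parent = parent, child = child), nodes = nodes)
  })
}

# --- kernel oracle ---------------------------------------------------------

oracle_gip <- function(A, margin, gamma_prime = 1) {
  P <- if (margin == "disease") A else t(A)
  n <- nrow(P)
  sq <- numeric(n)
  for (i in seq_len(n)) sq[i] <- sum(P[i, ]^2)
  gamma <- gamma_prime / (sum(sq) / n)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  }
  K
}

# --- recommender oracle (literal per-entry loops) --------------------------

oracle_weights_d <- function(A, Sm, Sd, thr = 0) {
  n_d <- nrow(A); n_m <- ncol(A)
  W <- matrix(0, n_d, n_m)
  for (i in seq_len(n_d)) {
    RM <- which(A[i, ] == 1)
    n_a <- sum(Sd[, i] > thr)
    for (j in seq_len(n_m)) {
      n_tal <- sum(vapply(RM, function(k) Sm[k, j] > thr, logical(1)))
      W[i, j] <- n_tal * log(n_m / n_a)
    }
  }
  W
}

oracle_weights_m <- function(A, Sm, Sd, thr = 0) {
  n_d <- nrow(A); n_m <- ncol(A)
  W <- matrix(0, n_m, n_d)
  for (i in seq_len(n_m)) {
    RD <- which(A[, i] == 1)
    n_a <- sum(Sm[, i] > thr)
    for (j in seq_len(n_d)) {
      n_tal <- sum(vapply(RD, function(t) Sd[t, j] > thr, logical(1)))
      W[i, j] <- n_tal * log(n_d / n_a)
    }
  }
  W
}

oracle_row_sum_norm <- function(W) {
  Z <- W
  for (i in seq_len(nrow(W))) {
    s <- sum(W[i, ])
    if (s != 0) Z[i, ] <- W[i, ] / s
  }
  Z
}

oracle_row_l2 <- function(M) {
  out <- M
  for (i in seq_len(nrow(M))) {
    nrm <- sqrt(sum(M[i, ]^2))
    out[i, ] <- if (nrm == 0) 0 * M[i, ] else M[i, ] / nrm
  }
  out
}

# Full scoring pipeline, one entry at a time.
oracle_scores <- function(A, Sm, Sd, thr = 0) {
  Zd <- oracle_row_sum_norm(oracle_weights_d(A, Sm, Sd, thr))
  Zm <- oracle_row_sum_norm(oracle_weights_m(A, Sm, Sd, thr))
  Z <- oracle_row_l2(t(Zm)) + oracle_row_l2(Zd)
  Km <- matrix(0, nrow(A), ncol(A))
  Kd <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    Km[i, j] <- sum(A[i, ] * Sm[, j])
    Kd[i, j] <- sum(Sd[i, ] * A[, j])
  }
  K <- oracle_row_l2(Km) + oracle_row_l2(Kd)
  oracle_row_l2(K) + oracle_row_l2(Z)
}

# --- evaluation oracle -----------------------------------------------------

# Pairwise-comparison AUC from raw score pools: probability that the
# positive outscores a random candidate negative of its own fold, ties 1/2.
oracle_pairwise_auc <- function(pools) {
  mean(vapply(pools, function(p) {
    (sum(p$pos > p$neg) + 0.5 * sum(p$pos == p$neg)) / length(p$neg)
  }, numeric(1)))
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

# --- random instances ------------------------------------------------------

# Random binary network plus sparse-ish random similarity matrices with
# genuine zeros (so the n_tal/n_a counting rules are exercised both ways).
random_instance <- function(n_d, n_m, seed, density = 0.25, sim_zero_frac = 0.3) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(rbinom(n_d * n_m, 1, density), n_d, n_m)
      if (sum(A) > 0) break
    }
    dimnames(A) <- list(sprintf("d%02d", 1:n_d), sprintf("m%02d", 1:n_m))
    rs <- function(n) {
      S <- matrix(runif(n * n), n, n)
      S[matrix(runif(n * n) < sim_zero_frac, n, n)] <- 0
      S[lower.tri(S)] <- t(S)[lower.tri(S)]
      diag(S) <- 1
      S
    }
    Sm <- rs(n_m); dimnames(Sm) <- list(colnames(A), colnames(A))
    Sd <- rs(n_d); dimnames(Sd) <- list(rownames(A), rownames(A))
    list(A = A, Sm = Sm, Sd = Sd)
  })
}
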