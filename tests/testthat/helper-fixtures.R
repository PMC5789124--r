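# Shared fixture builders.  Everything is generated in code with fixed
# seeds; no fixture files.

# random irreducible column-stochastic matrix (strictly positive entries)
random_stochastic <- function(n, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n, min = 0.05, max = 1), n, n)
  sweep(M, 2, colSums(M), "/")
}

# random valid latent model with strictly positive factors
random_latent_model <- function(n, K, seed) {
  set.seed(seed)
  lam <- matrix(stats::runif(n * K, min = 0.01, max = 1), n, K)
  lam <- sweep(lam, 2, colSums(lam), "/")
  gamma <- matrix(stats::runif(K * n, min = 0.01, max = 1), K, n)
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  latent_model(gamma, lam)
}

# block-diagonal 6-state counts: two 3-state blocks, within-block counts only
block_diag_counts <- function(seed = 42) {
  set.seed(seed)
  A1 <- matrix(stats::rpois(9, 20) + 1, 3)
  A2 <- matrix(stats::rpois(9, 20) + 1, 3)
  N <- rbind(cbind(A1, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), A2))
  transition_counts(N)
}

# independent oracle: stationary vector as the solution of the linear
# system (Lambda - I) mu = 0, sum(mu) = 1, via least squares -- no
# eigendecomposition involved
stationary_lsq <- function(Lambda) {
  Lambda <- as.matrix(Lambda)
  n <- nrow(Lambda)
  A <- rbind(Lambda - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  as.numeric(qr.solve(A, b))
}

# independent oracle: exact likelihood of a hard assignment at its optimal
# emission matrix, L = sum_k sum_i A_k[i] log(A_k[i] / T_k)
hard_assignment_loglik <- function(N, assign, K) {
  N <- as.matrix(N)
  ll <- 0
  for (k in seq_len(K)) {
    Ak <- rowSums(N[, assign == k, drop = FALSE])
    Tk <- sum(Ak)
    if (Tk > 0) ll <- ll + sum(Ak[Ak > 0] * log(Ak[Ak > 0] / Tk))
  }
  ll
}

# adjusted Rand index between two partitions (closed form from the
# pair-counting contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  e1 <- sum_comb(rowSums(tab))
  e2 <- sum_comb(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  (idx - expected) / ((e1 + e2) / 2 - expected)
}

# 30-state chain with a one-way trap (state 29) occupying `trap_frac` of
# the frames: a 6-block metastable main chain followed by a terminal trap
# segment, emulating an MD trajectory absorbed in a terminal conformation
trap_trajectory <- function(n_frames = 1e5, trap_frac = 0.01, seed = 3) {
  op <- block_chain_operator(c(5, 5, 5, 5, 5, 4), eps = 0.02)
  n_trap <- round(trap_frac * n_frames)
  main <- sample_markov_chain(op, n_frames - n_trap, start = 0, seed = seed)
  discrete_trajectory(c(main$labels, rep(29L, n_trap)), n_states = 30L)
}

expect_prob_vector <- function(mu, tol = 1e-12) {
  expect_true(all(mu >= 0))
  expect_lt(abs(sum(mu) - 1), tol)
}
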