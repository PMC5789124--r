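#' Simulate the Lorenz-63 system
#'
#' Integrates the Lorenz equations `x' = sigma (y - x)`,
#' `y' = x (rho - z) - y`, `z' = x y - beta z` with the classical
#' fixed-step fourth-order Runge-Kutta scheme at step `dt`, discards the
#' first `burn_in` steps (to land on the attractor) and returns every
#' `sample_stride`-th remaining state.  Deterministic given the parameters.
#'
#' @param n_steps total number of integration steps (`> burn_in`).
#' @param sigma,rho,beta Lorenz parameters; defaults are the standard
#'   chaotic setting (10, 28, 8/3).
#' @param dt integration step in model time units.
#' @param burn_in number of initial steps discarded.
#' @param sample_stride keep every `sample_stride`-th post-burn-in state,
#'   so the sampling interval is `tau = sample_stride * dt`.
#' @param init initial 3-vector.
#' @return Numeric matrix with columns `x`, `y`, `z`, one retained sample
#'   per row, and the sampling interval in `attr(, "tau")`.
#' @examples
#' xyz <- simulate_lorenz(2000, burn_in = 1000)
#' dim(xyz)  # 1000 x 3
#' @export
simulate_lorenz <- function(n_steps, sigma = 10, rho = 28, beta = 8 / 3,
                            dt = 1e-3, burn_in = 10000L, sample_stride = 1L,
                            init = c(1, 1, 1)) {
  n_steps <- as.integer(n_steps)
  burn_in <- as.integer(burn_in)
  sample_stride <- as.integer(sample_stride)
  if (!is.finite(dt) || dt <= 0) stop_input("dt must be positive")
  if (is.na(burn_in) || burn_in < 0L) stop_input("burn_in must be >= 0")
  if (is.na(n_steps) || n_steps <= burn_in)
    stop_input("n_steps must exceed burn_in")
  if (is.na(sample_stride) || sample_stride < 1L)
    stop_input("sample_stride must be >= 1")
  if (length(init) != 3L || any(!is.finite(init)))
    stop_input("init must be a finite 3-vector")

  deriv <- function(t, y, p) {
    list(c(p[1L] * (y[2L] - y[1L]),
           y[1L] * (p[2L] - y[3L]) - y[2L],
           y[1L] * y[2L] - p[3L] * y[3L]))
  }
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  out <- deSolve::ode(y = as.numeric(init), times = times, func = deriv,
                      parms = c(sigma, rho, beta), method = "rk4")
  states <- unname(out[-1L, 2:4, drop = FALSE])
  if (any(!is.finite(states))) {
    bad <- which(rowSums(!is.finite(states)) > 0L)[1L]
    stop_numerical("non-finite state encountered at integration step %d", bad)
  }
  kept <- states[seq.int(burn_in + 1L, n_steps, by = sample_stride), ,
                 drop = FALSE]
  colnames(kept) <- c("x", "y", "z")
  attr(kept, "tau") <- dt * sample_stride
  kept
}

# per-column cumulative distributions for categorical sampling
cum_columns <- function(M) apply(as.matrix(M), 2, cumsum)

#' Sample a trajectory from a full Markov chain
#'
#' Realizes the master equation generatively: `X(0)` is drawn from the
#' stationary measure (or fixed), and `X(s+1)` is drawn from column
#' `X(s)` of the operator.  Deterministic given `seed`.
#'
#' @param op a [transfer_operator()] or column-stochastic matrix.
#' @param length number of frames to generate.
#' @param start `"stationary"` (default) or a 0-based starting state.
#' @param seed integer seed.
#' @param lag time step recorded on the trajectory.
#' @return A [discrete_trajectory()].
#' @export
sample_markov_chain <- function(op, length, start = "stationary", seed = 1L,
                                lag = 1) {
  Lambda <- if (inherits(op, "transfer_operator")) op$Lambda else op
  undefined <- if (inherits(op, "transfer_operator")) op$undefined else
    rep(FALSE, ncol(Lambda))
  n <- ncol(Lambda)
  length <- as.integer(length)
  if (length < 1L) stop_input("length must be >= 1")
  cum <- cum_columns(Lambda)

  set.seed(seed)
  if (identical(start, "stationary")) {
    mu <- invariant_measure_full(op, method = "power")
    cur <- findInterval(stats::runif(1), cumsum(mu)) + 1L
  } else {
    cur <- as.integer(start) + 1L
    if (is.na(cur) || cur < 1L || cur > n)
      stop_input("start state must lie in [0, %d)", n)
  }
  u <- stats::runif(length - 1L)
  labels <- integer(length)
  labels[1L] <- cur
  for (s in seq_len(length - 1L)) {
    if (undefined[cur])
      stop_numerical("reached source state %d, whose column is undefined", cur - 1L)
    cur <- findInterval(u[s], cum[, cur]) + 1L
    if (cur > n) cur <- n   # guard against cumsum rounding at 1
    labels[s + 1L] <- cur
  }
  discrete_trajectory(labels - 1L, n_states = n, lag = lag)
}

#' Sample a trajectory from a latent Markov model
#'
#' Generative reading of the factorized master equation: from state
#' `X(s) = j`, a latent state `k` is drawn from column `j` of `gamma`,
#' then `X(s+1)` is drawn from column `k` of `lam`; the induced chain has
#' transition matrix `lam %*% gamma`.  Deterministic given `seed`.
#'
#' @param model a [latent_model()].
#' @param length number of frames.
#' @param start 0-based starting state.
#' @param seed integer seed.
#' @param lag time step recorded on the trajectory.
#' @return A [discrete_trajectory()].
#' @export
sample_latent_chain <- function(model, length, start = 0L, seed = 1L, lag = 1) {
  stopifnot(inherits(model, "latent_model"))
  length <- as.integer(length)
  if (length < 1L) stop_input("length must be >= 1")
  cur <- as.integer(start) + 1L
  if (is.na(cur) || cur < 1L || cur > model$n)
    stop_input("start state must lie in [0, %d)", model$n)
  cum_g <- cum_columns(model$gamma)   # K x n
  cum_l <- cum_columns(model$lam)     # n x K
  K <- model$K

  set.seed(seed)
  ug <- stats::runif(length - 1L)
  ul <- stats::runif(length - 1L)
  labels <- integer(length)
  labels[1L] <- cur
  for (s in seq_len(length - 1L)) {
    k <- findInterval(ug[s], cum_g[, cur]) + 1L
    if (k > K) k <- K
    cur <- findInterval(ul[s], cum_l[, k]) + 1L
    if (cur > model$n) cur <- model$n
    labels[s + 1L] <- cur
  }
  discrete_trajectory(labels - 1L, n_states = model$n, lag = lag)
}

#' Planted hard latent model for recovery experiments
#'
#' Partitions the n observed states into K near-equal groups.  Emission
#' column k places mass `separation` uniformly on group k and leaks the
#' remaining `1 - separation` uniformly over the other states, so
#' `separation = 1` gives disjoint supports.  The hard affiliation maps
#' each state to a latent destination drawn from a diagonally dominant
#' K x K stochastic template whose rows are permuted by a seeded random
#' permutation; the planted affiliation (the recovery target) is stored in
#' `attr(, "assignments")` and the group labels in `attr(, "groups")`.
#'
#' @param n number of observed states.
#' @param K number of latent states (`K <= n`).
#' @param separation emission concentration in `(0, 1]`.
#' @param seed integer seed.
#' @param diag_weight dominant-diagonal weight of the affiliation template.
#' @return A hard [latent_model()].
#' @export
make_planted_model <- function(n, K, separation = 0.9, seed = 1L,
                               diag_weight = 0.8) {
  n <- as.integer(n)
  K <- as.integer(K)
  if (K < 1L || K > n) stop_input("K must satisfy 1 <= K <= n")
  if (!(separation > 0 && separation <= 1))
    stop_input("separation must lie in (0, 1]")
  sizes <- rep(n %/% K, K)
  if (n %% K) sizes[seq_len(n %% K)] <- sizes[seq_len(n %% K)] + 1L
  groups <- rep(seq_len(K), times = sizes)

  lam <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ink <- groups == k
    lam[ink, k] <- separation / sum(ink)
    if (any(!ink) && separation < 1)
      lam[!ink, k] <- (1 - separation) / sum(!ink)
    lam[, k] <- lam[, k] / sum(lam[, k])
  }

  set.seed(seed)
  if (K == 1L) {
    tpl <- matrix(1, 1, 1)
  } else {
    tpl <- matrix((1 - diag_weight) / (K - 1), K, K)
    diag(tpl) <- diag_weight
    tpl <- tpl[sample.int(K), , drop = FALSE]
  }
  assign <- integer(n)
  for (j in seq_len(n))
    assign[j] <- sample.int(K, 1L, prob = tpl[, groups[j]])

  gamma <- matrix(0, K, n)
  gamma[cbind(assign, seq_len(n))] <- 1
  model <- latent_model(gamma, lam, hard = TRUE)
  attr(model, "assignments") <- assign
  attr(model, "groups") <- groups
  model
}

#' Metastable block-structured transfer operator
#'
#' Builds a column-stochastic operator whose states fall into blocks:
#' from any state of block b the chain moves uniformly within b with
#' probability `1 - eps` and uniformly over all n states with probability
#' `eps`.  All columns of a block are identical, so the blocks are exact
#' latent aggregates; small `eps` makes them metastable.
#'
#' @param sizes integer vector of block sizes.
#' @param eps inter-block mixing weight in (0, 1).
#' @return A [transfer_operator()] with the block id of each state in
#'   `attr(, "blocks")`.
#' @export
block_chain_operator <- function(sizes, eps = 0.02) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop_input("block sizes must be positive")
  if (!(eps > 0 && eps < 1)) stop_input("eps must lie in (0, 1)")
  n <- sum(sizes)
  blocks <- rep(seq_along(sizes), times = sizes)
  Lambda <- matrix(eps / n, n, n)
  for (b in seq_along(sizes)) {
    inb <- blocks == b
    Lambda[inb, inb] <- eps / n + (1 - eps) / sizes[b]
  }
  op <- transfer_operator(Lambda / rep(colSums(Lambda), each = n))
  attr(op, "blocks") <- blocks
  op
}
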