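#' Latent Markov model (factorized transfer operator)
#'
#' The pair of rectangular column-stochastic matrices factorizing the
#' transfer operator through a K-dimensional latent categorical process:
#' `gamma[k, j] = P[Xhat(s+tau) = xhat(k) | X(s) = x(j)]` (K x n) and
#' `lam[i, k] = P[X(s) = x(i) | Xhat(s) = xhat(k)]` (n x K).  The induced
#' one-step operator on the observed states is the product `lam %*% gamma`,
#' which is never materialized by the package's algorithms.
#'
#' @param gamma K x n column-stochastic matrix.
#' @param lam n x K column-stochastic matrix.
#' @param hard logical; `TRUE` when every column of `gamma` is a 0/1 unit
#'   vector (the hard-clustering case).  Detected from `gamma` if omitted.
#' @return An object of class `latent_model` with fields `gamma`, `lam`,
#'   `K`, `n` and `hard`.
#' @export
latent_model <- function(gamma, lam, hard = NULL) {
  gamma <- as.matrix(gamma)
  lam <- as.matrix(lam)
  K <- nrow(gamma)
  n <- ncol(gamma)
  if (!identical(dim(lam), c(n, K)))
    stop_input("lam must be %d x %d to match gamma (got %d x %d)",
               n, K, nrow(lam), ncol(lam))
  if (K < 1L || K > n) stop_input("latent dimension K must satisfy 1 <= K <= n")
  if (min(gamma) < 0 || min(lam) < 0)
    stop_input("latent model matrices must be nonnegative")
  dg <- max(abs(colSums(gamma) - 1))
  dl <- max(abs(colSums(lam) - 1))
  if (dg > 1e-12)
    stop_input("columns of gamma must sum to 1 (max deviation %.3g)", dg)
  if (dl > 1e-12)
    stop_input("columns of lam must sum to 1 (max deviation %.3g)", dl)
  if (is.null(hard))
    hard <- all(colSums(gamma == 1) == 1L & colSums(gamma == 0) == K - 1L)
  if (hard && !all(colSums(gamma == 1) == 1L & colSums(gamma == 0) == K - 1L))
    stop_input("hard model requires every gamma column to be a 0/1 unit vector")
  structure(list(gamma = gamma, lam = lam, K = K, n = n, hard = hard),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("latent_model: n = %d observed states, K = %d latent states (%s)\n",
              x$n, x$K, if (x$hard) "hard" else "soft"))
  prov <- attr(x, "provenance")
  if (!is.null(prov))
    cat(sprintf("  fitted by %s, seed %s, log-likelihood %.6g\n",
                prov$fitter %||% "?", format(prov$seed %||% NA), prov$loglik %||% NA))
  invisible(x)
}

# hard-model cluster assignment (1-based), NULL for soft models
model_assignments <- function(model) {
  if (!model$hard) return(NULL)
  apply(model$gamma, 2, which.max)
}

#' Reduced transfer operator
#'
#' Forms the K x K column-stochastic operator `P_K = gamma %*% lam` that
#' governs the latent process.  Accumulated rounding is removed by
#' renormalizing each column.
#'
#' @param model a [latent_model()].
#' @return K x K column-stochastic matrix.
#' @export
reduced_operator <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  P <- model$gamma %*% model$lam
  cs <- colSums(P)
  if (any(abs(cs - 1) > 1e-9))
    stop_numerical("reduced operator columns deviate from stochasticity by %.3g",
                   max(abs(cs - 1)))
  sweep(P, 2, cs, "/")
}

#' Propagate a probability vector through the factorized master equation
#'
#' Applies one step of the latent master equation
#' `pi(s+tau) = lam %*% (gamma %*% pi(s))`, computed as two rectangular
#' products so the n x n operator is never formed.
#'
#' @param model a [latent_model()].
#' @param pi nonnegative probability vector of length n (sum within `1e-9`
#'   of 1).
#' @return Probability vector of length n.
#' @export
propagate <- function(model, pi) {
  stopifnot(inherits(model, "latent_model"))
  pi <- as.numeric(pi)
  if (length(pi) != model$n)
    stop_input("pi has length %d but the model has %d states", length(pi), model$n)
  if (any(!is.finite(pi)) || min(pi) < -1e-12 || abs(sum(pi) - 1) > 1e-9)
    stop_input("pi must be a probability vector summing to 1")
  as.numeric(model$lam %*% (model$gamma %*% pi))
}

# dominant eigenvector of a small column-stochastic matrix; errors when
# eigenvalue 1 is (numerically) multiple
dominant_reduced_vector <- function(P, tol = 1e-9) {
  K <- nrow(P)
  if (K == 1L) return(1)
  check_irreducible(P, what = "reduced operator P_K (latent blocks)")
  E <- eigen(P)
  near1 <- which(Re(E$values) > 1 - tol & abs(Im(E$values)) < tol)
  if (length(near1) > 1L)
    stop_numerical("reduced operator has %d eigenvalues within %g of 1",
                   length(near1), tol)
  if (length(near1) == 0L)
    near1 <- which.max(Re(E$values))
  v <- Re(E$vectors[, near1[1L]])
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8 * max(abs(v)))
    stop_numerical("dominant eigenvector of the reduced operator has mixed signs")
  v <- pmax(v, 0)
  v / sum(v)
}

#' Invariant measure from a latent Markov model
#'
#' Computes the reduced stationary vector `mu_K` as the dominant
#' eigenvector of `P_K = gamma %*% lam` (a dense K x K eigenproblem) and
#' lifts it to the full state space through the Perron-Frobenius identity
#' `mu = lam %*% mu_K / sum(mu_K)`.  For `K = 1` this reduces to the
#' empirical probability density of the data the model was fitted to.
#'
#' @param model a [latent_model()].
#' @param tol tolerance used to decide whether eigenvalue 1 is unique.
#' @return A list with `measure` (length-n invariant measure) and
#'   `reduced` (the length-K stationary vector of `P_K`).
#' @export
latent_invariant_measure <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "latent_model"))
  P <- reduced_operator(model)
  mu_K <- dominant_reduced_vector(P, tol = tol)
  mu <- as.numeric(model$lam %*% mu_K)
  mu <- pmax(mu, 0)
  mu <- mu / sum(mu)
  list(measure = mu, reduced = mu_K)
}

#' Spectral components of the latent operator
#'
#' Eigen-decomposes the reduced operator `P_K` and lifts each eigenvector
#' `v` to the full state space as `lam %*% v`; for a nonzero eigenvalue
#' `lambda` the lift satisfies `(lam gamma)(lam v) = lambda (lam v)`, so
#' the subdominant lifted vectors describe the slow probability flows
#' (metastability) of the full chain without ever forming the n x n
#' operator.  The second invariant measure ratio `psi2` -- the second
#' lifted vector divided entrywise by the invariant measure where it is
#' positive, zero elsewhere -- separates metastable sets by its sign
#' structure.
#'
#' @param model a [latent_model()].
#' @param n_components number of eigenpairs to return (`<= K`).
#' @return An object of class `spectral_components`: list with `values`
#'   (eigenvalues sorted by decreasing modulus), `vectors` (n x
#'   n_components lifted eigenvectors, each scaled so its largest-modulus
#'   entry is positive real), `reduced_vectors` (K x n_components), `psi2`
#'   and `measure`.
#' @export
spectrum <- function(model, n_components = 2L) {
  stopifnot(inherits(model, "latent_model"))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > model$K)
    stop_input("n_components must lie in [1, K = %d]", model$K)
  P <- reduced_operator(model)
  E <- eigen(P)
  ord <- order(-Mod(E$values), -Re(E$values))
  values <- E$values[ord][seq_len(n_components)]
  V <- matrix(E$vectors[, ord, drop = FALSE][, seq_len(n_components), drop = FALSE],
              nrow = model$K)
  mu <- latent_invariant_measure(model)$measure

  lifted <- (model$lam + 0i) %*% V
  for (m in seq_len(n_components)) {
    idx <- which.max(Mod(lifted[, m]))
    ph <- lifted[idx, m]
    if (Mod(ph) > 0) lifted[, m] <- lifted[, m] * Conj(ph) / Mod(ph)
  }
  if (max(abs(Im(values))) < 1e-12 && max(abs(Im(lifted))) < 1e-9) {
    lifted <- Re(lifted)
    values <- Re(values)
    V <- Re(V)
  } else {
    warning("complex subdominant eigenvalues returned as-is (no realification)")
  }

  psi2 <- NULL
  if (n_components >= 2L) {
    psi2 <- lifted[, 2L]
    psi2 <- ifelse(mu > 0, psi2 / mu, 0)
  }
  structure(list(values = values, vectors = lifted, reduced_vectors = V,
                 psi2 = psi2, measure = mu),
            class = "spectral_components")
}

#' @export
print.spectral_components <- function(x, ...) {
  cat("spectral_components: eigenvalues",
      paste(format(x$values, digits = 6), collapse = ", "), "\n")
  invisible(x)
}
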