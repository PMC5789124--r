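# Soft latent-model fitting by expectation-maximisation on the same
# factorized likelihood (the conditional form of probabilistic latent
# semantic analysis, with source states playing the role of documents and
# destination states the role of words).

plsa_core <- function(tri, n, K, gamma, lam, tol, max_iter) {
  ti <- tri$i; tj <- tri$j; tx <- tri$x
  col_tot <- numeric(n)
  agg <- rowsum(tx, tj)
  col_tot[as.integer(rownames(agg))] <- agg
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    # E-step: responsibilities r[k | i, j] over the nonzero count entries
    Pk <- lam[ti, , drop = FALSE] * t(gamma)[tj, , drop = FALSE]
    denom <- rowSums(Pk)
    ll <- sum(tx * log(denom))
    trace <- c(trace, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * max(1, abs(ll_old))) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    W <- (tx / denom) * Pk              # responsibility-weighted counts
    # M-step: column-renormalized aggregations of W by destination / source
    lam_new <- matrix(0, n, K)
    agg_i <- rowsum(W, ti)
    lam_new[as.integer(rownames(agg_i)), ] <- agg_i
    lam <- sweep(lam_new, 2, pmax(colSums(lam_new), .Machine$double.xmin), "/")

    gam_t <- matrix(0, n, K)
    agg_j <- rowsum(W, tj)
    gam_t[as.integer(rownames(agg_j)), ] <- agg_j
    seen <- col_tot > 0
    gam_t[seen, ] <- gam_t[seen, , drop = FALSE] / col_tot[seen]
    gam_t[!seen, ] <- 1 / K             # no data: leave the column uniform
    gamma <- t(gam_t)
    # guard against drift from finite-precision normalization
    gamma <- sweep(gamma, 2, colSums(gamma), "/")
  }
  list(gamma = gamma, lam = lam, loglik = trace[length(trace)], trace = trace,
       iterations = length(trace), converged = converged)
}

#' Fit a soft latent Markov model by EM (probabilistic latent semantic
#' analysis)
#'
#' Maximizes the same factorized log-likelihood as [fit_dbmr()] over
#' unconstrained column-stochastic factors.  The E-step computes latent
#' responsibilities `r[k | i, j]` proportional to `lam[i, k] * gamma[k, j]`
#' for every observed transition; the M-step re-estimates both factors from
#' responsibility-weighted counts with column renormalization.  The
#' likelihood trace is monotone non-decreasing (standard EM guarantee) and
#' iteration stops when its relative change drops below `tol`.  The best of
#' `restarts` seeded random column-stochastic initializations is returned.
#'
#' @inheritParams fit_dbmr
#' @return A list with `model` (a soft [latent_model()]) and `diagnostics`
#'   as in [fit_dbmr()].
#' @export
fit_plsa <- function(counts, K, restarts = 10L, seed = 1L,
                     tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(counts, "transition_counts"))
  n <- counts$n
  K <- as.integer(K)
  if (K < 1L || K > n) stop_input("K must satisfy 1 <= K <= n = %d", n)
  if (counts$total <= 0) stop_input("count matrix has no observed transitions")
  tri <- count_triplets(counts)

  best <- NULL
  best_idx <- NA_integer_
  for (r in seq_len(max(1L, restarts))) {
    set.seed(seed + r)
    gamma0 <- matrix(stats::runif(K * n), K, n)
    gamma0 <- sweep(gamma0, 2, colSums(gamma0), "/")
    lam0 <- matrix(stats::runif(n * K), n, K)
    lam0 <- sweep(lam0, 2, colSums(lam0), "/")
    run <- plsa_core(tri, n, K, gamma0, lam0, tol = tol, max_iter = max_iter)
    if (is.null(best) || run$loglik > best$loglik) {
      best <- run
      best_idx <- r
    }
  }

  model <- latent_model(best$gamma, best$lam, hard = FALSE)
  attr(model, "provenance") <- list(fitter = "plsa", seed = seed,
                                    loglik = best$loglik)
  diagnostics <- list(trace = best$trace, loglik = best$loglik,
                      iterations = best$iterations,
                      restarts = max(1L, restarts), best_init = best_idx,
                      converged = best$converged, seed = seed)
  list(model = model, diagnostics = diagnostics)
}
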