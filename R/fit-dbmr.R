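# Hard latent-model fitting by direct Bayesian model reduction: coordinate
# ascent on the factorized log-likelihood sum_ij N_ij log((lam gamma)_ij)
# under the constraint that every gamma column is a 0/1 unit vector.  With
# a hard gamma the likelihood at the optimal lam for a given assignment has
# the closed form sum_k sum_i A_k[i] log(A_k[i]/T_k), where A_k aggregates
# the count columns assigned to latent state k -- i.e. the assignment step
# is a minimum-weighted-entropy clustering of source columns.

# scores[j, k] = sum_i N[i, j] * log(lam[i, k]); -Inf marks an observed
# transition given probability zero (no epsilon flooring in scoring).
hard_scores <- function(N, lam) {
  loglam <- log(lam)           # -Inf where lam == 0; lam <= 1 so no +Inf
  as.matrix(Matrix::crossprod(N, loglam))
}

# one coordinate-ascent run from a given assignment (1-based, length n)
dbmr_core <- function(N, K, assign, tol, max_iter) {
  n <- ncol(N)
  Npat <- NULL
  trace <- numeric(0)
  ll_old <- -Inf
  repairs <- 0L
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    # lam update given assignments, with empty-cluster repair: the source
    # column with the worst per-column likelihood contribution (among
    # clusters keeping >= 2 members) is moved into the empty cluster; the
    # donor's members can only improve once lam is re-optimized, so the
    # recorded likelihood stays monotone.
    repeat {
      A <- matrix(0, n, K)
      agg <- Matrix::sparseMatrix(i = assign, j = seq_len(n), x = 1,
                                  dims = c(K, n))
      A[] <- as.matrix(N %*% Matrix::t(agg))
      Tk <- colSums(A)
      empty <- which(Tk == 0)
      if (!length(empty)) break
      lam_tmp <- sweep(A, 2, pmax(Tk, 1), "/")
      S_tmp <- hard_scores(N, lam_tmp)
      contrib <- S_tmp[cbind(seq_len(n), assign)]
      sizes <- tabulate(assign, K)
      cand <- which(sizes[assign] > 1L & colSums(N)[seq_len(n)] > 0)
      if (!length(cand)) cand <- which(sizes[assign] > 1L)
      if (!length(cand)) break    # K > number of occupied columns; give up
      j_star <- cand[which.min(contrib[cand])]
      assign[j_star] <- empty[1L]
      repairs <- repairs + 1L
    }
    lam <- sweep(A, 2, pmax(Tk, 1), "/")

    S <- hard_scores(N, lam)
    ll <- sum(S[cbind(seq_len(n), assign)])
    trace <- c(trace, ll)

    new_assign <- max.col(S, ties.method = "first")
    best <- S[cbind(seq_len(n), new_assign)]
    bad <- which(!is.finite(best))
    if (length(bad)) {
      # every latent state scores -Inf for these columns: fall back to the
      # latent state whose emission support overlaps the column's counts most
      if (is.null(Npat)) Npat <- methods::as(N, "lMatrix") * 1
      ov <- as.matrix(Matrix::crossprod(Npat, (lam > 0) * 1))
      new_assign[bad] <- max.col(ov[bad, , drop = FALSE], ties.method = "first")
    }

    if (all(new_assign == assign)) { converged <- TRUE; break }
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * max(1, abs(ll_old))) {
      assign <- new_assign
      converged <- TRUE
      break
    }
    assign <- new_assign
    ll_old <- ll
  }
  list(assign = assign, lam = lam, loglik = trace[length(trace)],
       trace = trace, iterations = length(trace), converged = converged,
       repairs = repairs)
}

# Spectral initialization: cluster source states on the subdominant
# eigenvectors of the *reversibilized* empirical operator (counts
# symmetrized as (N + N')/2), the standard metastability embedding.  Two
# features of short-lag data make this seed necessary: self-transition
# dominance turns every assignment into a near-fixed-point of the
# coordinate ascent (random restarts stall), and strong non-reversibility
# (e.g. rotation on an attractor) gives the raw operator complex
# subdominant eigenvalues that mask the slow metastable modes.
# Symmetrizing removes the rotational part, leaves a real spectrum, and is
# only ever used to seed the (non-reversible) likelihood ascent.  Returns
# NULL when no embedding is available; the caller just skips the seed.
spectral_seed <- function(N, K, seed, dense_limit = 2000L, max_matvec = 40000L) {
  n <- ncol(N)
  if (K < 2L || K > n - 1L) return(NULL)
  Ns <- (N + Matrix::t(N)) / 2
  d <- Matrix::colSums(Ns)
  s <- ifelse(d > 0, 1 / sqrt(pmax(d, 1e-300)), 0)
  Dh <- Matrix::Diagonal(n, s)
  S <- Dh %*% Ns %*% Dh            # symmetric, similar to the operator

  emb <- tryCatch({
    if (n <= dense_limit) {
      E <- eigen(as.matrix(S), symmetric = TRUE)   # values sorted decreasing
      E$vectors[, 2:K, drop = FALSE]
    } else {
      # subspace (block power) iteration with Rayleigh-Ritz extraction;
      # convergence is monitored through the stability of the induced
      # k-means-free sign pattern of the leading subdominant vector
      set.seed(seed)
      V <- cbind(sqrt(pmax(d, 0)), matrix(stats::rnorm(n * (K - 1L)), n))
      V <- qr.Q(qr(V))
      prev <- NULL
      done <- 0L
      W <- NULL
      while (done < max_matvec) {
        for (b in seq_len(50L)) V <- as.matrix(S %*% V)
        done <- done + 50L
        V <- qr.Q(qr(V))
        B <- crossprod(V, as.matrix(S %*% V))
        done <- done + 1L
        EB <- eigen((B + t(B)) / 2, symmetric = TRUE)
        W <- V %*% EB$vectors[, 2:K, drop = FALSE]
        ref <- which.max(abs(W[, 1L]))
        sig <- sign(W[, 1L] * sign(W[ref, 1L]))
        if (!is.null(prev) && mean(sig == prev) >= 1 - 0.5 / n) break
        prev <- sig
      }
      W
    }
  }, error = function(e) NULL)
  if (is.null(emb) || any(!is.finite(emb))) return(NULL)
  emb <- emb * s                   # back-transform to eigenvectors that are
                                   # constant on metastable sets

  set.seed(seed)
  km <- tryCatch(stats::kmeans(emb, centers = K, nstart = 10L, iter.max = 50L),
                 error = function(e) NULL)
  if (is.null(km) || length(unique(km$cluster)) < K) return(NULL)
  as.integer(km$cluster)
}

#' Fit a hard latent Markov model (direct Bayesian model reduction)
#'
#' Maximizes the factorized log-likelihood
#' \eqn{\sum_{ij} N_{ij} \log((\hat\lambda\hat\Gamma)_{ij})} over hard
#' models -- each source state is assigned to exactly one latent state --
#' by alternating two exact coordinate-ascent steps: (a) given the
#' assignment, the optimal emission matrix aggregates the count columns of
#' each cluster, `lam[i, k] = sum_{j in k} N[i, j] / T_k`; (b) given
#' `lam`, each source column moves to the latent state maximizing its
#' log-score `sum_i N[i, j] log lam[i, k]` (lowest index wins ties).  The
#' iteration stops at an exact assignment fixed point, on a relative
#' likelihood change below `tol`, or after `max_iter` sweeps.
#'
#' Several initializations are run and the best final likelihood wins: a
#' deterministic seed assigning column `j` to `j mod K` (which for `K = n`
#' is the identity, reproducing the empirical frequency estimator
#' exactly), a spectral seed clustering states on the subdominant
#' eigenvectors of the empirical operator, and `restarts` seeded
#' uniform-random assignments.
#'
#' @param counts a [transition_counts()] with at least one positive entry.
#' @param K latent dimension, `1 <= K <= n`.
#' @param restarts number of random initializations (default 10).
#' @param seed integer seed controlling all random initializations.
#' @param tol relative log-likelihood change for convergence.
#' @param max_iter maximum alternating sweeps per initialization.
#' @param init optional explicit initial assignment (integer vector of
#'   length n with values in `1..K`), run in addition to the built-in
#'   initializations.  Seeding the `K+1` fit from a refinement of the best
#'   `K`-partition guarantees a training likelihood non-decreasing in K.
#' @return A list with `model` (a hard [latent_model()] carrying the
#'   cluster assignment in `attr(, "assignments")`) and `diagnostics`
#'   (log-likelihood `trace` of the winning run, `loglik`, `iterations`,
#'   `restarts`, `best_init`, `converged`, `repairs`, `seed`).
#' @examples
#' op <- block_chain_operator(c(3, 3), eps = 0.05)
#' tr <- sample_markov_chain(op, 5000, seed = 1)
#' fit <- fit_dbmr(count_transitions(tr), K = 2, seed = 1)
#' attr(fit$model, "assignments")
#' @export
fit_dbmr <- function(counts, K, restarts = 10L, seed = 1L,
                     tol = 1e-8, max_iter = 500L, init = NULL) {
  stopifnot(inherits(counts, "transition_counts"))
  n <- counts$n
  K <- as.integer(K)
  if (K < 1L || K > n) stop_input("K must satisfy 1 <= K <= n = %d", n)
  if (counts$total <= 0) stop_input("count matrix has no observed transitions")
  N <- Matrix::drop0(counts$N)

  inits <- list(deterministic = ((seq_len(n) - 1L) %% K) + 1L)
  if (!is.null(init)) {
    init <- as.integer(init)
    if (length(init) != n || any(is.na(init)) || any(init < 1L | init > K))
      stop_input("init must be a length-%d assignment with values in 1..%d", n, K)
    inits$user <- init
  }
  sp <- spectral_seed(N, K, seed = seed)
  if (!is.null(sp)) inits$spectral <- sp
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    inits[[paste0("random", r)]] <- sample.int(K, n, replace = TRUE)
  }

  best <- NULL
  best_name <- NULL
  for (nm in names(inits)) {
    run <- dbmr_core(N, K, inits[[nm]], tol = tol, max_iter = max_iter)
    if (is.null(best) || run$loglik > best$loglik) {
      best <- run
      best_name <- nm
    }
  }

  gamma <- matrix(0, K, n)
  gamma[cbind(best$assign, seq_len(n))] <- 1
  model <- latent_model(gamma, best$lam, hard = TRUE)
  attr(model, "assignments") <- best$assign
  attr(model, "provenance") <- list(fitter = "dbmr", seed = seed,
                                    loglik = best$loglik)
  diagnostics <- list(trace = best$trace, loglik = best$loglik,
                      iterations = best$iterations,
                      restarts = length(inits), best_init = best_name,
                      converged = best$converged, repairs = best$repairs,
                      seed = seed)
  list(model = model, diagnostics = diagnostics)
}
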