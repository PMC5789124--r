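#' Observational log-likelihood of a transition model
#'
#' Evaluates `sum_ij N_ij log(P_ij)` over the observed (nonzero) count
#' entries, where `P` is either a full transfer operator or the factorized
#' probability `(lam %*% gamma)_ij` of a latent model, computed per entry
#' from the factors without materializing the n x n product.  Returns
#' `-Inf` when any observed transition is assigned probability zero: this
#' is scoring, and no silent flooring is applied.
#'
#' @param counts a [transition_counts()].
#' @param object a [transfer_operator()], a plain column-stochastic matrix,
#'   or a [latent_model()].
#' @return A single numeric log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(counts, object) {
  stopifnot(inherits(counts, "transition_counts"))
  tri <- count_triplets(counts)
  if (inherits(object, "latent_model")) {
    if (object$n != counts$n)
      stop_input("model has %d states but counts have %d", object$n, counts$n)
    p <- rowSums(object$lam[tri$i, , drop = FALSE] *
                   t(object$gamma)[tri$j, , drop = FALSE])
  } else {
    Lambda <- if (inherits(object, "transfer_operator")) object$Lambda else object
    if (nrow(Lambda) != counts$n || ncol(Lambda) != counts$n)
      stop_input("operator is %d x %d but counts have %d states",
                 nrow(Lambda), ncol(Lambda), counts$n)
    p <- as.numeric(Lambda[cbind(tri$i, tri$j)])
  }
  if (any(p <= 0)) return(-Inf)
  sum(tri$x * log(p))
}

#' Free parameters of full and latent transition models
#'
#' A full column-stochastic n x n operator has `n (n - 1)` free
#' parameters.  A latent model with dimension K has `K (n - 1)` free
#' parameters in its n x K emission factor plus `n (K - 1)` in its K x n
#' affiliation factor (one entry per column is fixed by stochasticity).
#' The latent count stays below the full count exactly when
#' `K < n^2 / (2 n - 1)` -- see [max_latent_dim()].
#'
#' @param kind `"full"` or `"latent"`.
#' @param n number of observed states.
#' @param K latent dimension (required for `kind = "latent"`).
#' @return Integer parameter count.
#' @export
free_parameters <- function(kind = c("full", "latent"), n, K = NULL) {
  kind <- match.arg(kind)
  n <- as.numeric(n)
  if (is.na(n) || n < 1) stop_input("n must be a positive integer")
  if (kind == "full") return(n * (n - 1))
  K <- as.numeric(K)
  if (is.null(K) || is.na(K) || K < 1 || K > n)
    stop_input("latent K must satisfy 1 <= K <= n")
  K * (n - 1) + n * (K - 1)
}

#' Overfitting bound on the latent dimension
#'
#' The largest integer K for which the latent factorization has strictly
#' fewer free parameters than the full transfer operator, i.e. the largest
#' K with `K < n^2 / (2 n - 1)`.
#'
#' @param n number of observed states (`n >= 1`).
#' @return Integer bound (0 for `n = 1`).
#' @examples
#' max_latent_dim(200)  # 100
#' @export
max_latent_dim <- function(n) {
  n <- as.numeric(n)
  if (is.na(n) || n < 1) stop_input("n must be a positive integer")
  # exact integer arithmetic: floor((n^2 - 1) / (2n - 1)) is the largest
  # integer strictly below n^2 / (2n - 1)
  as.integer((n * n - 1) %/% (2 * n - 1))
}

#' Score candidate models by information criteria
#'
#' Computes, for each candidate, the observational log-likelihood on
#' `counts`, the free-parameter count, and `AIC = -2 loglik + 2 p` and
#' `BIC = -2 loglik + p log(M)`, where the sample size `M` is the number
#' of observed transitions.  A model assigning probability zero to an
#' observed transition receives infinite criteria and is flagged rather
#' than raising an error.
#'
#' @param counts a [transition_counts()].
#' @param models named list of [transfer_operator()] / [latent_model()]
#'   objects (plain column-stochastic matrices are treated as full
#'   operators).
#' @param criterion sort key, `"bic"` (default) or `"aic"`.
#' @return A `data.frame` with columns `label`, `K` (`NA` for full
#'   models), `loglik`, `p`, `AIC`, `BIC`, `M` and `flag`, sorted
#'   ascending by the chosen criterion.
#' @export
score_models <- function(counts, models, criterion = c("bic", "aic")) {
  stopifnot(inherits(counts, "transition_counts"))
  criterion <- match.arg(criterion)
  if (!length(models)) stop_input("no models to score")
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  M <- counts$total
  if (M <= 0) stop_input("count matrix has no observed transitions")

  rows <- lapply(names(models), function(lab) {
    obj <- models[[lab]]
    ll <- log_likelihood(counts, obj)
    if (inherits(obj, "latent_model")) {
      K <- obj$K
      p <- free_parameters("latent", counts$n, K)
    } else {
      K <- NA_integer_
      p <- free_parameters("full", counts$n)
    }
    data.frame(label = lab, K = K, loglik = ll, p = p,
               AIC = -2 * ll + 2 * p, BIC = -2 * ll + p * log(M),
               M = M, flag = !is.finite(ll), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$AIC[out$flag] <- Inf
  out$BIC[out$flag] <- Inf
  out[order(out[[if (criterion == "bic") "BIC" else "AIC"]]), , drop = FALSE]
}
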