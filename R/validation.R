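# floor a dense column-stochastic probability matrix at eps/n and
# renormalize each column; used only when scoring validation data
floor_renorm <- function(P, eps) {
  if (eps <= 0) return(P)
  n <- nrow(P)
  P <- pmax(P, eps / n)
  sweep(P, 2, colSums(P), "/")
}

#' Select the latent dimension by temporal cross-validation
#'
#' Splits the trajectory into a contiguous training segment (the first
#' `split_fraction` of frames) and a validation segment, fits one latent
#' model per candidate K on the training counts, and scores each fitted
#' model -- together with the full empirical-estimator baseline -- on the
#' validation counts.  Validation probabilities are floored at
#' `reg_eps / n` and column-renormalized so that transitions unseen in
#' training do not produce infinite scores; training is never regularized.
#' The split is contiguous (not shuffled) to respect temporal dependence.
#'
#' @param traj a [discrete_trajectory()].
#' @param Ks integer vector of candidate latent dimensions.
#' @param fitter `"dbmr"` or `"plsa"`.
#' @param split_fraction fraction of frames in the training segment.
#' @param reg_eps validation floor; `reg_eps = 0` disables flooring, in
#'   which case unseen transitions yield `-Inf` scores that are flagged.
#' @param seed integer seed passed to the fitters.
#' @param restarts restarts per fit.
#' @param lag_multiple transition lag, as in [count_transitions()].
#' @return A `data.frame` with columns `label`, `K`, `fold`, `train_ll`,
#'   `val_ll` and `flag` (one row per candidate plus a `"full"` baseline
#'   row), with the best latent K (highest validation score) in
#'   `attr(, "best_K")`.
#' @export
cross_validate <- function(traj, Ks, fitter = c("dbmr", "plsa"),
                           split_fraction = 0.5, reg_eps = 1e-6,
                           seed = 1L, restarts = 5L, lag_multiple = 1L) {
  stopifnot(inherits(traj, "discrete_trajectory"))
  fitter <- match.arg(fitter)
  if (!(split_fraction > 0 && split_fraction < 1))
    stop_input("split_fraction must lie in (0, 1)")
  L <- length(traj$labels)
  cut <- floor(split_fraction * L)
  if (cut <= lag_multiple || L - cut <= lag_multiple)
    stop_input("trajectory too short to split at fraction %g", split_fraction)
  train <- discrete_trajectory(traj$labels[seq_len(cut)],
                               n_states = traj$n_states, lag = traj$lag)
  val <- discrete_trajectory(traj$labels[(cut + 1L):L],
                             n_states = traj$n_states, lag = traj$lag)
  if (!length(intersect(unique(train$labels), unique(val$labels))))
    stop_input("training and validation segments visit disjoint state sets")
  counts_tr <- count_transitions(train, lag_multiple)
  counts_va <- count_transitions(val, lag_multiple)

  val_score <- function(P_dense) {
    P_dense <- floor_renorm(P_dense, reg_eps)
    tri <- count_triplets(counts_va)
    p <- P_dense[cbind(tri$i, tri$j)]
    if (any(p <= 0)) return(-Inf)
    sum(tri$x * log(p))
  }

  full_op <- empirical_estimator(counts_tr)
  rows <- list(data.frame(label = "full", K = NA_integer_, fold = 1L,
                          train_ll = log_likelihood(counts_tr, full_op),
                          val_ll = val_score(as.matrix(full_op$Lambda)),
                          stringsAsFactors = FALSE))
  for (K in Ks) {
    fit <- if (fitter == "dbmr") {
      fit_dbmr(counts_tr, K, restarts = restarts, seed = seed + K)
    } else {
      fit_plsa(counts_tr, K, restarts = restarts, seed = seed + K)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(label = sprintf("%s-K%d", fitter, K), K = as.integer(K),
                 fold = 1L,
                 train_ll = fit$diagnostics$loglik,
                 val_ll = val_score(fit$model$lam %*% fit$model$gamma),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$flag <- !is.finite(out$val_ll)
  latent <- out[!is.na(out$K), , drop = FALSE]
  attr(out, "best_K") <- latent$K[which.max(latent$val_ll)]
  out
}

#' Bootstrap confidence intervals for the invariant measure
#'
#' Standard nonparametric bootstrap at the level of the likelihood's
#' independent units: the `M` observed transition pairs are resampled with
#' replacement (equivalently, the nonzero counts are redrawn from a
#' multinomial with `M` trials), the latent model is refitted on each
#' replicate, and the invariant measure recomputed.  States absent from a
#' replicate receive measure zero in that replicate; replicates whose
#' reduced operator is reducible are dropped and counted.
#'
#' @param traj a [discrete_trajectory()].
#' @param K latent dimension of the refitted models.
#' @param n_boot number of bootstrap replicates (`>= 2`).
#' @param seed integer seed; replicate `b` uses `seed + b`.
#' @param fitter `"dbmr"` or `"plsa"`.
#' @param restarts restarts per refit (kept small for speed).
#' @param conf two-sided coverage of the quantile envelopes.
#' @param lag_multiple transition lag.
#' @return A `data.frame` with columns `state` (0-based), `point` (full-
#'   data estimate), `lower` and `upper` (empirical quantiles across
#'   replicates); the number of dropped replicates is in
#'   `attr(, "dropped")` and the replicate measures in
#'   `attr(, "replicates")` (n x n_kept matrix).
#' @export
bootstrap_measure <- function(traj, K, n_boot = 100L, seed = 1L,
                              fitter = c("dbmr", "plsa"), restarts = 3L,
                              conf = 0.95, lag_multiple = 1L) {
  stopifnot(inherits(traj, "discrete_trajectory"))
  fitter <- match.arg(fitter)
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) stop_input("n_boot must be at least 2")
  counts <- count_transitions(traj, lag_multiple)
  tri <- count_triplets(counts)
  M <- counts$total
  n <- counts$n
  fit_fun <- if (fitter == "dbmr") fit_dbmr else fit_plsa

  point_fit <- fit_fun(counts, K, restarts = restarts, seed = seed)
  point <- latent_invariant_measure(point_fit$model)$measure

  reps <- matrix(NA_real_, n, n_boot)
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(seed + b)
    x_new <- as.numeric(stats::rmultinom(1, M, tri$x))
    keep <- x_new > 0
    Nb <- Matrix::sparseMatrix(i = tri$i[keep], j = tri$j[keep],
                               x = x_new[keep], dims = c(n, n))
    mu_b <- tryCatch({
      fit_b <- fit_fun(transition_counts(Nb), K, restarts = restarts,
                       seed = seed + b)
      latent_invariant_measure(fit_b$model)$measure
    }, lmm_numerical_error = function(e) NULL)
    if (is.null(mu_b)) dropped <- dropped + 1L else reps[, b] <- mu_b
  }
  reps <- reps[, colSums(is.na(reps)) == 0L, drop = FALSE]
  if (!ncol(reps))
    stop_numerical("all %d bootstrap replicates were reducible", n_boot)
  alpha <- (1 - conf) / 2
  out <- data.frame(state = seq_len(n) - 1L, point = point,
                    lower = apply(reps, 1, stats::quantile, probs = alpha),
                    upper = apply(reps, 1, stats::quantile, probs = 1 - alpha))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "replicates") <- reps
  out
}
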