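#' Discrete trajectory of state labels
#'
#' The universal input of the estimators: an ordered sequence of 0-based
#' integer state labels observed at a fixed time step `tau`.
#'
#' @param labels integer vector of state labels in `[0, n_states)`.
#' @param n_states number of states `n`; defaults to `max(labels) + 1`.
#' @param lag time step `tau > 0` between consecutive observations.
#' @return An object of class `discrete_trajectory` with fields `labels`,
#'   `n_states` and `lag`.
#' @export
discrete_trajectory <- function(labels, n_states = NULL, lag = 1) {
  if (length(labels) < 1L) stop_input("trajectory must contain at least one label")
  if (any(!is.finite(labels)) || any(labels != floor(labels)))
    stop_input("state labels must be integers")
  labels <- as.integer(labels)
  if (is.null(n_states)) n_states <- max(labels) + 1L
  n_states <- as.integer(n_states)
  if (any(labels < 0L) || any(labels >= n_states))
    stop_input("state labels must lie in [0, %d)", n_states)
  if (!is.finite(lag) || lag <= 0) stop_input("lag must be positive")
  structure(list(labels = labels, n_states = n_states, lag = as.numeric(lag)),
            class = "discrete_trajectory")
}

#' @export
print.discrete_trajectory <- function(x, ...) {
  cat(sprintf("discrete_trajectory: %d frames, %d states, lag %g\n",
              length(x$labels), x$n_states, x$lag))
  invisible(x)
}

#' Count observed transitions
#'
#' Builds the sparse transition-count matrix `N` with
#' `N[i, j] = #\{s : X(s + m tau) = i, X(s) = j\}` over a sliding window of
#' stride one, where `m` is `lag_multiple`.  Rows index destinations and
#' columns index sources.
#'
#' @param traj a [discrete_trajectory()].
#' @param lag_multiple positive integer `m`; transitions are counted
#'   between frames `m` steps apart.
#' @return An object of class `transition_counts`: a list with the sparse
#'   n x n count matrix `N`, the state count `n` and `total`, the number of
#'   counted transitions (`length(labels) - lag_multiple`).
#' @examples
#' tr <- discrete_trajectory(c(0, 1, 0, 1))
#' count_transitions(tr)$N  # N[2,1] = 2, N[1,2] = 1 (1-based printing)
#' @export
count_transitions <- function(traj, lag_multiple = 1L) {
  stopifnot(inherits(traj, "discrete_trajectory"))
  m <- as.integer(lag_multiple)
  if (is.na(m) || m < 1L) stop_input("lag_multiple must be a positive integer")
  L <- length(traj$labels)
  if (L <= m)
    stop_input("trajectory of length %d is too short for lag_multiple %d", L, m)
  src <- traj$labels[seq_len(L - m)]
  dst <- traj$labels[seq_len(L - m) + m]
  N <- Matrix::sparseMatrix(i = dst + 1L, j = src + 1L, x = 1,
                            dims = c(traj$n_states, traj$n_states))
  transition_counts(N, total = L - m)
}

#' Transition-count container
#'
#' Wraps a square nonnegative integer matrix of observed transition counts
#' (destination rows, source columns).  Usually produced by
#' [count_transitions()] or [read_counts_mtx()].
#'
#' @param N square matrix (dense or sparse) of nonnegative integers.
#' @param total total transition count; defaults to `sum(N)`.
#' @return An object of class `transition_counts`.
#' @export
transition_counts <- function(N, total = NULL) {
  N <- methods::as(methods::as(N, "CsparseMatrix"), "generalMatrix")
  if (nrow(N) != ncol(N)) stop_input("count matrix must be square")
  N <- Matrix::drop0(N)
  if (length(N@x)) {
    if (any(N@x < 0)) stop_input("transition counts must be nonnegative")
    if (any(abs(N@x - round(N@x)) > 1e-9))
      stop_input("transition counts must be integers")
    N@x <- round(N@x)
  }
  tot <- sum(N@x)
  if (is.null(total)) total <- tot
  if (abs(total - tot) > 1e-9)
    stop_input("declared total (%g) does not match the sum of counts (%g)",
               total, tot)
  structure(list(N = N, n = nrow(N), total = as.numeric(total)),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf("transition_counts: %d states, %g transitions, %d nonzero entries\n",
              x$n, x$total, length(x$N@x)))
  invisible(x)
}

# counts as triplets (1-based i, j and the count x), zeros dropped
count_triplets <- function(counts) {
  Tm <- methods::as(counts$N, "TsparseMatrix")
  keep <- Tm@x != 0
  list(i = Tm@i[keep] + 1L, j = Tm@j[keep] + 1L, x = Tm@x[keep])
}
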