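#' Column-stochastic transfer operator
#'
#' Container for the matrix of conditional transition probabilities
#' `Lambda[i, j] = P[X(s+tau) = x(i) | X(s) = x(j)]`.  Columns flagged in
#' `undefined` had no observed outgoing transitions; their values were
#' filled by the estimator's policy and should be interpreted with care.
#'
#' @param Lambda square matrix (dense or sparse) with nonnegative entries
#'   and columns summing to one within `1e-12`.
#' @param undefined logical vector flagging source columns whose
#'   distribution was imputed rather than estimated.
#' @return An object of class `transfer_operator`.
#' @export
transfer_operator <- function(Lambda, undefined = rep(FALSE, ncol(Lambda))) {
  if (nrow(Lambda) != ncol(Lambda)) stop_input("transfer operator must be square")
  if (min(Lambda) < -1e-12) stop_input("transfer operator entries must be nonnegative")
  cs <- Matrix::colSums(Lambda)
  if (any(abs(cs - 1) > 1e-12))
    stop_input("transfer operator columns must sum to 1 (max deviation %.3g)",
               max(abs(cs - 1)))
  structure(list(Lambda = Lambda, n = nrow(Lambda),
                 undefined = as.logical(undefined)),
            class = "transfer_operator")
}

#' @export
print.transfer_operator <- function(x, ...) {
  cat(sprintf("transfer_operator: %d x %d, %d undefined column(s)\n",
              x$n, x$n, sum(x$undefined)))
  invisible(x)
}

#' Empirical frequency estimator of the transfer operator
#'
#' The maximum-likelihood estimator under independent transitions: each
#' source column of the count matrix is normalized by its total,
#' `Lambda[i, j] = N[i, j] / sum_i N[i, j]`.  Source states never observed
#' to leave (zero column total) have no maximum-likelihood distribution;
#' they are filled by `policy` and flagged `undefined` so downstream
#' analyses can see the pathology (such absorbing-like states are exactly
#' the ones that distort invariant measures).
#'
#' @param counts a [transition_counts()] object.
#' @param policy fill for zero-count source columns: `"uniform"` (mass
#'   `1/n` on every destination, the default) or `"selfloop"` (all mass on
#'   the state itself).
#' @return A [transfer_operator()].
#' @examples
#' tr <- discrete_trajectory(c(0, 1, 0, 1))
#' empirical_estimator(count_transitions(tr))
#' @export
empirical_estimator <- function(counts, policy = c("uniform", "selfloop")) {
  stopifnot(inherits(counts, "transition_counts"))
  policy <- match.arg(policy)
  if (counts$total <= 0) stop_input("count matrix has no observed transitions")
  n <- counts$n
  cs <- Matrix::colSums(counts$N)
  undef <- cs == 0
  Lambda <- counts$N %*% Matrix::Diagonal(n, x = ifelse(undef, 0, 1 / pmax(cs, 1))) # nolint
  if (any(undef)) {
    idx <- which(undef)
    fill <- if (policy == "selfloop") {
      Matrix::sparseMatrix(i = idx, j = idx, x = 1, dims = c(n, n))
    } else {
      Matrix::sparseMatrix(i = rep(seq_len(n), length(idx)),
                           j = rep(idx, each = n),
                           x = 1 / n, dims = c(n, n))
    }
    Lambda <- Lambda + fill
  }
  transfer_operator(Lambda, undefined = undef)
}

# Closed communicating classes of the support graph of a stochastic matrix.
# A class is closed iff it has no edge leaving it; the number of closed
# classes equals the multiplicity of eigenvalue 1.
closed_classes <- function(M, tol = 0) {
  A <- methods::as(M, "CsparseMatrix")
  A <- methods::as(A, "generalMatrix")      # expand symmetric storage
  A <- methods::as(Matrix::drop0(A, tol = tol), "TsparseMatrix")
  g <- igraph::graph_from_edgelist(cbind(A@j + 1L, A@i + 1L), directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, nrow(M) - igraph::vcount(g)))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  closed <- rep(TRUE, comp$no)
  leaves <- memb[A@j + 1L] != memb[A@i + 1L]
  closed[unique(memb[A@j[leaves] + 1L])] <- FALSE
  lapply(which(closed), function(cl) which(memb == cl) - 1L)
}

check_irreducible <- function(Lambda, what = "transfer operator") {
  cls <- closed_classes(Lambda)
  if (length(cls) > 1L) {
    desc <- vapply(cls, function(s) {
      s <- sort(s)
      shown <- paste(utils::head(s, 8L), collapse = ",")
      if (length(s) > 8L) shown <- paste0(shown, ",...")
      sprintf("{%s} (%d states)", shown, length(s))
    }, character(1))
    stop_numerical(
      "%s is reducible: eigenvalue 1 has multiplicity %d; closed blocks: %s",
      what, length(cls), paste(desc, collapse = "; "), data = cls)
  }
  invisible(TRUE)
}

#' Invariant measure of a full transfer operator
#'
#' Computes the stationary probability vector `mu = Lambda mu` of a
#' column-stochastic operator, the third step of Ulam's approach.  Method
#' `"eig"` uses a dense eigendecomposition for moderate dimensions (and
#' falls back to power iteration above `dense_limit`); `"power"` iterates
#' the master equation from the uniform vector until the successive-iterate
#' l1 change drops below `tol`.  If several eigenvalues lie within `1e-9`
#' of 1 the chain is reducible and the function refuses, naming the
#' disconnected closed blocks, rather than silently returning one basin.
#'
#' @param op a [transfer_operator()] (or plain column-stochastic matrix).
#' @param method `"eig"` or `"power"`.
#' @param tol convergence/negativity tolerance.
#' @param max_iter maximum power iterations.
#' @param dense_limit dimension above which `"eig"` silently switches to
#'   power iteration (dense eigendecomposition cost grows cubically).
#' @return Numeric probability vector of length n with attributes
#'   `residual` (l1 residual of stationarity), `iterations` and `method`.
#' @examples
#' op <- transfer_operator(matrix(c(0.9, 0.1, 0.2, 0.8), 2))
#' invariant_measure_full(op)  # 2/3, 1/3
#' @export
invariant_measure_full <- function(op, method = c("eig", "power"),
                                   tol = 1e-13, max_iter = 100000L,
                                   dense_limit = 600L) {
  method <- match.arg(method)
  if (inherits(op, "transfer_operator")) {
    if (any(op$undefined))
      warning(sprintf("%d undefined column(s) were filled by the estimator policy; the invariant measure depends on that fill",
                      sum(op$undefined)))
    Lambda <- op$Lambda
  } else {
    Lambda <- op
  }
  n <- nrow(Lambda)
  check_irreducible(Lambda)

  if (method == "eig" && n <= dense_limit) {
    E <- eigen(as.matrix(Lambda))
    close1 <- which(Mod(E$values - 1) < 1e-9)
    if (length(close1) > 1L)
      stop_numerical("eigenvalue 1 has numerical multiplicity %d", length(close1))
    if (length(close1) == 0L)
      close1 <- which.min(Mod(E$values - 1))
    v <- E$vectors[, close1[1L]]
    if (max(abs(Im(v))) > 1e-9 * max(Mod(v)))
      stop_numerical("dominant eigenvector has a non-negligible imaginary part")
    v <- Re(v)
    if (sum(v) < 0) v <- -v
    if (min(v) < -1e-8 * max(abs(v)))
      stop_numerical("dominant eigenvector has mixed signs (min %.3g); chain may be reducible",
                     min(v))
    mu <- pmax(v, 0)
    mu <- mu / sum(mu)
    near1 <- sort(Mod(E$values - 1))
    if (length(near1) > 1L && near1[2L] < 1e-6)
      warning(sprintf("small spectral gap: second eigenvalue within %.2g of 1; the measure is poorly conditioned",
                      near1[2L]))
    res <- sum(abs(as.numeric(Lambda %*% mu) - mu))
    return(structure(mu, residual = res, iterations = NA_integer_, method = "eig"))
  }

  # power iteration of the master equation, started from the uniform vector
  mu <- rep(1 / n, n)
  it <- 0L
  repeat {
    it <- it + 1L
    mu_new <- as.numeric(Lambda %*% mu)
    delta <- sum(abs(mu_new - mu))
    mu <- mu_new / sum(mu_new)
    if (delta < tol) break
    if (it >= max_iter)
      stop_numerical("power iteration did not converge in %d iterations (l1 change %.3g)",
                     max_iter, delta)
  }
  mu <- pmax(mu, 0)
  mu <- mu / sum(mu)
  res <- sum(abs(as.numeric(Lambda %*% mu) - mu))
  structure(mu, residual = res, iterations = it, method = "power")
}
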