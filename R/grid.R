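#' Uniform box grid over a rectangular phase-space region
#'
#' Defines the box discretization used by Ulam's approach: each dimension
#' is divided into `bins` equal-width half-open intervals `[lo, hi)`, the
#' last bin of each dimension being closed so that the upper boundary
#' belongs to the grid.
#'
#' @param lower,upper numeric vectors of per-dimension bounds
#'   (`upper > lower` elementwise).
#' @param bins positive integer vector of per-dimension bin counts
#'   (recycled to the common dimension).
#' @return An object of class `grid_spec` with fields `lower`, `upper`,
#'   `bins`, the dimension `d` and the total box count `n = prod(bins)`.
#' @examples
#' g <- grid_spec(c(0, 0), c(1, 1), c(10, 10))
#' g$n  # 100
#' @export
grid_spec <- function(lower, upper, bins) {
  d <- max(length(lower), length(upper), length(bins))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  bins  <- rep_len(as.integer(bins), d)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop_input("grid bounds must be finite")
  if (any(upper <= lower))
    stop_input("grid upper bound must exceed lower bound in every dimension")
  if (any(is.na(bins)) || any(bins < 1L))
    stop_input("bin counts must be positive integers")
  structure(list(lower = lower, upper = upper, bins = bins,
                 d = d, n = prod(as.numeric(bins))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d dimensions, %s boxes (%s)\n", x$d,
              format(x$n, big.mark = ","), paste(x$bins, collapse = " x ")))
  invisible(x)
}

#' Build a grid around observed data
#'
#' Convenience constructor taking per-dimension bounds from the data's
#' bounding box, enlarged by a relative padding so that trajectory points
#' on the hull fall strictly inside.
#'
#' @param points numeric matrix (one observation per row).
#' @param bins per-dimension bin counts.
#' @param pad relative padding of the bounding box (default 1\%).
#' @return A [grid_spec()].
#' @export
grid_from_data <- function(points, bins, pad = 0.01) {
  points <- as.matrix(points)
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  span <- pmax(hi - lo, .Machine$double.eps)
  grid_spec(lo - pad * span, hi + pad * span, bins)
}

#' Discretize a continuous trajectory on a box grid
#'
#' Maps each d-dimensional point to the linearized index of its containing
#' box.  Linearization is row-major with the first coordinate varying
#' slowest, so labels are portable across implementations.  Points outside
#' the grid bounds are clamped into the nearest boundary bin and a single
#' warning reports how many were clamped.
#'
#' @param points numeric matrix or data frame, one time frame per row.
#' @param grid a [grid_spec()] whose dimension matches `ncol(points)`.
#' @param compact if `TRUE`, only visited boxes receive labels
#'   `0..n_visited-1`; the original (full-grid) box index of each compact
#'   label is returned in the `box_map` attribute.
#' @param lag time step `tau` between consecutive rows (metadata carried by
#'   the resulting trajectory; default 1).
#' @return A [discrete_trajectory()] with attributes `grid` and (when
#'   `compact`) `box_map`.
#' @examples
#' g <- grid_spec(0, 1, 4)
#' discretize(matrix(c(0.1, 0.6, 0.6, 0.9)), g)$labels  # 0 2 2 3
#' @export
discretize <- function(points, grid, compact = FALSE, lag = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != grid$d)
    stop_input("points have dimension %d but grid has dimension %d",
               ncol(points), grid$d)
  if (nrow(points) < 1L) stop_input("empty point sequence")

  n_out <- 0L
  label <- rep(0, nrow(points))
  for (j in seq_len(grid$d)) {
    w <- (grid$upper[j] - grid$lower[j]) / grid$bins[j]
    idx <- floor((points[, j] - grid$lower[j]) / w)
    # the upper boundary belongs to the last (closed) bin; only points
    # strictly outside [lower, upper] count as clamped
    out <- points[, j] < grid$lower[j] | points[, j] > grid$upper[j]
    n_out <- n_out + sum(out)
    idx <- pmin(pmax(idx, 0), grid$bins[j] - 1L)
    label <- label * grid$bins[j] + idx
  }
  if (n_out > 0L)
    warning(sprintf("%d point coordinate(s) outside grid bounds were clamped into boundary bins",
                    n_out))

  if (compact) {
    visited <- sort(unique(label))
    traj <- discrete_trajectory(match(label, visited) - 1L,
                                n_states = length(visited), lag = lag)
    attr(traj, "box_map") <- as.numeric(visited)
  } else {
    if (grid$n > .Machine$integer.max)
      stop_input("full grid has %.0f boxes; use compact = TRUE", grid$n)
    traj <- discrete_trajectory(as.integer(label), n_states = as.integer(grid$n),
                                lag = lag)
  }
  attr(traj, "grid") <- grid
  traj
}

#' Centers of grid boxes
#'
#' @param grid a [grid_spec()].
#' @param boxes numeric vector of 0-based linearized (full-grid) box
#'   indices, e.g. the `box_map` attribute of a compact trajectory.
#' @return Matrix with one row per box and `grid$d` columns of box-center
#'   coordinates.
#' @export
box_centers <- function(grid, boxes) {
  stopifnot(inherits(grid, "grid_spec"))
  boxes <- as.numeric(boxes)
  if (any(boxes < 0 | boxes >= grid$n)) stop_input("box index out of range")
  centers <- matrix(0, length(boxes), grid$d)
  rem <- boxes
  for (j in rev(seq_len(grid$d))) {
    idx <- rem %% grid$bins[j]
    rem <- (rem - idx) / grid$bins[j]
    w <- (grid$upper[j] - grid$lower[j]) / grid$bins[j]
    centers[, j] <- grid$lower[j] + (idx + 0.5) * w
  }
  centers
}
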