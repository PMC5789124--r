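# Plain-text interchange formats: discrete trajectories (one label per
# line with an optional "# n=<n> lag=<tau>" header), Matrix Market
# coordinate files for count and model matrices, TSV for measures, JSON
# manifests for fitted models.  Everything round-trips losslessly.

#' Read / write a discrete trajectory
#'
#' The on-disk format is one integer state label per line, optionally
#' preceded by a header line `# n=<n> lag=<tau>` carrying the metadata.
#' Reading validates every token (a parse error names the offending line)
#' and checks labels against `[0, n)`.
#'
#' @param path file path.
#' @return `read_discrete_trajectory` returns a [discrete_trajectory()].
#' @export
read_discrete_trajectory <- function(path) {
  lines <- readLines(path)
  n <- NULL
  lag <- 1
  start <- 1L
  if (length(lines) && grepl("^#", lines[1L])) {
    m <- regmatches(lines[1L],
                    regexec("^#\\s*n=(\\d+)\\s+lag=([0-9.eE+-]+)\\s*$", lines[1L]))[[1L]]
    if (length(m) != 3L)
      stop_input("malformed header at line 1: %s", lines[1L])
    n <- as.integer(m[2L])
    lag <- as.numeric(m[3L])
    start <- 2L
  }
  body <- lines[seq.int(start, length(lines))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop_input("no state labels in %s", path)
  ok <- grepl("^\\s*[+-]?\\d+\\s*$", body)
  if (any(!ok))
    stop_input("non-integer token '%s' at line %d of %s",
               trimws(body[!ok][1L]), which(!ok)[1L] + start - 1L, path)
  labels <- as.integer(body)
  discrete_trajectory(labels, n_states = n, lag = lag)
}

#' @rdname read_discrete_trajectory
#' @param traj a [discrete_trajectory()].
#' @export
write_discrete_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "discrete_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d lag=%.17g", traj$n_states, traj$lag), con)
  writeLines(format(traj$labels, scientific = FALSE, trim = TRUE), con)
  invisible(path)
}

# minimal Matrix Market coordinate writer; Matrix::writeMM cannot emit the
# integer field nor guarantee full-precision reals, so we write directly
write_mtx <- function(M, path, field = c("integer", "real")) {
  field <- match.arg(field)
  Tm <- methods::as(methods::as(methods::as(M, "CsparseMatrix"),
                                "generalMatrix"), "TsparseMatrix")
  keep <- Tm@x != 0
  i <- Tm@i[keep] + 1L
  j <- Tm@j[keep] + 1L
  x <- Tm@x[keep]
  vals <- if (field == "integer") sprintf("%d", as.integer(round(x)))
          else sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general", field),
               sprintf("%d %d %d", nrow(M), ncol(M), length(i)),
               paste(i, j, vals)), con)
  invisible(path)
}

#' Read / write transition counts in Matrix Market format
#'
#' Coordinate-format `.mtx` files with an integer field; indices are
#' 1-based on disk and 0-based state labels in memory.  Reading validates
#' that the matrix is square with nonnegative integer entries.
#'
#' @param path file path.
#' @return `read_counts_mtx` returns a [transition_counts()].
#' @export
read_counts_mtx <- function(path) {
  M <- tryCatch(Matrix::readMM(path),
                error = function(e) stop_input("cannot parse %s as Matrix Market: %s",
                                               path, conditionMessage(e)))
  if (nrow(M) != ncol(M))
    stop_input("count matrix in %s is %d x %d, not square", path, nrow(M), ncol(M))
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  M <- Matrix::drop0(M)
  if (length(M@x)) {
    if (any(M@x < 0)) stop_input("negative transition count in %s", path)
    if (any(abs(M@x - round(M@x)) > 1e-9))
      stop_input("real-valued (non-integer) entries in %s", path)
  }
  transition_counts(M)
}

#' @rdname read_counts_mtx
#' @param counts a [transition_counts()].
#' @export
write_counts_mtx <- function(counts, path) {
  stopifnot(inherits(counts, "transition_counts"))
  write_mtx(counts$N, path, field = "integer")
}

#' Write an invariant measure as two-column TSV
#'
#' Columns are the 0-based state label and the probability.
#'
#' @param mu numeric probability vector.
#' @param path file path.
#' @export
write_measure <- function(mu, path) {
  df <- data.frame(state = seq_along(mu) - 1L,
                   probability = sprintf("%.17g", as.numeric(mu)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted latent model
#'
#' A model directory contains `gamma.mtx` and `lam.mtx` (Matrix Market,
#' real field, full precision) plus `manifest.json` with the dimensions,
#' the hard flag and the fit provenance (fitter, seed, log-likelihood).
#' Loading re-validates all model invariants, so a tampered file (e.g. a
#' column no longer summing to one) is rejected.
#'
#' @param model a [latent_model()].
#' @param dir directory path (created if missing).
#' @return `load_model` returns a [latent_model()].
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "latent_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mtx(model$gamma, file.path(dir, "gamma.mtx"), field = "real")
  write_mtx(model$lam, file.path(dir, "lam.mtx"), field = "real")
  prov <- attr(model, "provenance")
  manifest <- list(K = model$K, n = model$n, hard = model$hard,
                   provenance = prov)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_input("no manifest.json in %s", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  gamma <- as.matrix(Matrix::readMM(file.path(dir, "gamma.mtx")))
  lam <- as.matrix(Matrix::readMM(file.path(dir, "lam.mtx")))
  if (nrow(gamma) != manifest$K || ncol(gamma) != manifest$n ||
      nrow(lam) != manifest$n || ncol(lam) != manifest$K)
    stop_input("matrix shapes in %s do not match the manifest (K=%s, n=%s)",
               dir, manifest$K, manifest$n)
  model <- latent_model(gamma, lam, hard = manifest$hard)
  if (!is.null(manifest$provenance) && length(manifest$provenance))
    attr(model, "provenance") <- as.list(manifest$provenance)
  model
}
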