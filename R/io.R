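#' Read a trajectory from delimited text
#'
#' Expects two columns — an integer time index and a position — separated
#' by commas, tabs or whitespace (auto-detected), with an optional header
#' line. Time indices must be consecutive integers (a skipped index means a
#' gap in the recording, which the TAMSD definition cannot absorb, so gappy
#' files are rejected). Analyses here are one-dimensional; files with more
#' than two columns are rejected rather than silently reduced.
#'
#' @param path path to the file.
#' @return an `spt_trajectory`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("%s: fewer than 2 data rows", path), call. = FALSE)
  delim <- if (grepl(",", lines[1])) "," else
           if (grepl("\t", lines[1])) "\t" else "[[:space:]]+"
  split_row <- function(l) strsplit(trimws(l), delim)[[1]]
  first <- split_row(lines[1])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  start <- if (has_header) 2L else 1L
  if (length(lines) - start + 1L < 2L)
    stop(sprintf("%s: fewer than 2 data rows", path), call. = FALSE)
  n <- length(lines) - start + 1L
  t_idx <- numeric(n); x <- numeric(n)
  for (i in seq_len(n)) {
    ln <- start + i - 1L
    f <- split_row(lines[ln])
    if (length(f) != 2L)
      stop(sprintf("%s, line %d: expected 2 columns (time, position), got %d",
                   path, ln, length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("%s, line %d: non-numeric value", path, ln),
           call. = FALSE)
    t_idx[i] <- v[1]; x[i] <- v[2]
  }
  if (any(t_idx != round(t_idx)))
    stop(sprintf("%s: time indices must be integers", path), call. = FALSE)
  dt <- diff(t_idx)
  bad <- which(dt != 1)
  if (length(bad) > 0L)
    stop(sprintf(
      "%s, line %d: time index jumps from %d to %d (gaps are not supported)",
      path, start + bad[1L], as.integer(t_idx[bad[1L]]),
      as.integer(t_idx[bad[1L] + 1L])), call. = FALSE)
  new_trajectory(x)
}

#' Write a trajectory as delimited text
#'
#' Two comma-separated columns with a `t,x` header; the time index is
#' 0-based and positions are written at full double precision, so a
#' write/read round trip is lossless.
#'
#' @param traj an `spt_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "spt_trajectory"))
  writeLines(c("t,x", sprintf("%d,%.17g",
                              seq_along(traj$positions) - 1L,
                              traj$positions)),
             path)
  invisible(path)
}

#' Re-derive the recommended-lag table by simulation
#'
#' Runs a scaled-down Monte-Carlo sweep for every cell of the reference
#' table ([tau_table()]): each (`alpha`, `sigma`) pair at trajectory
#' lengths 100 and 1000. For each cell it extracts the sweep's own optimal
#' maximal lag and the precision both there and at the tabulated
#' recommendation, giving a side-by-side check of how close the table is
#' to optimal under re-simulation. Precision ridges are flat near their
#' maximum, so the argmax itself is seed-sensitive; the meaningful
#' comparison is the precision gap.
#'
#' @param n_reps trajectories per cell (>= 100; default 300 keeps the full
#'   24-cell run at desk scale).
#' @param seed master integer seed.
#' @param alphas,sigmas,L_grid grids to cover; defaults are the reference
#'   table's.
#' @return a data.frame with one row per cell: `alpha`, `sigma`, `L`,
#'   `tau_recommended`, `tau_optimal`, `phi_recommended`, `phi_optimal`,
#'   `phi_gap` (optimal minus recommended), `bias_optimal`.
#' @export
benchmark_tau_table <- function(n_reps = 300, seed,
                                alphas = c(0.3, 0.7, 1.3, 1.7),
                                sigmas = c(0.1, 0.5, 1),
                                L_grid = c(100L, 1000L)) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 100L)
    stop("n_reps must be >= 100", call. = FALSE)
  out <- list()
  k <- 0L
  for (a in alphas) for (s in sigmas) {
    mp <- sweep_precision(a, s, L_grid, n_reps = n_reps,
                          seed = derive_seed(seed, k))
    k <- k + 1L
    for (L in L_grid) {
      opt <- optimal_tau(mp, L)
      tau_rec <- suppressWarnings(lookup_tau(a, s, L))
      cell <- mp$grid[mp$grid$L == L & mp$grid$tau_M == tau_rec, ]
      out[[length(out) + 1L]] <- data.frame(
        alpha = a, sigma = s, L = L,
        tau_recommended = tau_rec, tau_optimal = opt$tau_M,
        phi_recommended = cell$phi, phi_optimal = opt$phi,
        phi_gap = opt$phi - cell$phi, bias_optimal = opt$bias)
    }
  }
  do.call(rbind, out)
}
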