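#' Deterministic uniform fan of rays
#'
#' An `M x N` regular grid of rays over `[-y_max, y_max] x [-theta_max,
#' theta_max]`. A single-count axis collapses to its maximum value, so
#' `uniform_rays(y_max = 0, theta_max = a, M = 1, N = k)` is a fan of `k`
#' angles from a single on-axis point.
#'
#' @param y_max Half-extent of heights (mm).
#' @param theta_max Half-extent of angles (rad).
#' @param M Number of heights (>= 1).
#' @param N Number of angles per height (>= 1).
#' @return A [rays()] collection of `M * N` rays.
#' @export
uniform_rays <- function(y_max = 0, theta_max = 0, M = 1, N = 1) {
  if (M < 1 || N < 1) stop("ray counts M and N must be at least 1")
  axis_vals <- function(mx, k)
    if (k == 1L) mx else seq(-mx, mx, length.out = k)
  ys <- axis_vals(y_max, as.integer(M))
  ths <- axis_vals(theta_max, as.integer(N))
  g <- expand.grid(theta = ths, y = ys)
  rays(g$y, g$theta, distribution = "uniform-grid",
       y_range = c(-abs(y_max), abs(y_max)),
       theta_range = c(-abs(theta_max), abs(theta_max)))
}

#' Random rays with uniform height and angle distributions
#'
#' Independent draws `y ~ U[y_min, y_max]`, `theta ~ U[theta_min,
#' theta_max]`. With a `seed`, the ensemble is exactly reproducible and the
#' global RNG state is left untouched; with `seed = NULL` the current RNG
#' stream is used (each call then differs).
#'
#' @param y_max,y_min Height range (mm); `y_min` defaults to `-y_max`.
#' @param theta_max,theta_min Angle range (rad); default `[-pi/2, pi/2]`.
#' @param n Number of rays (>= 1).
#' @param seed Optional integer seed.
#' @return A [rays()] collection.
#' @export
random_uniform_rays <- function(y_max = 0, y_min = -y_max,
                                theta_max = pi / 2, theta_min = -theta_max,
                                n = 1000, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (y_min > y_max || theta_min > theta_max)
    stop("inverted range: min must not exceed max")
  with_local_seed(seed, {
    rays(stats::runif(n, y_min, y_max), stats::runif(n, theta_min, theta_max),
         distribution = "random-uniform", seed = seed,
         y_range = c(y_min, y_max), theta_range = c(theta_min, theta_max))
  })
}

#' Random rays with a Lambertian angular distribution
#'
#' Angles follow the meridional Lambertian law, density proportional to
#' `cos(theta)` on `[-theta_max, theta_max]`, sampled by inversion:
#' `theta = asin((2u - 1) sin(theta_max))`. Heights are uniform.
#'
#' @param y_max,y_min Height range (mm).
#' @param theta_max Angular half-range (rad), in `(0, pi/2]`.
#' @param n Number of rays.
#' @param seed Optional integer seed.
#' @return A [rays()] collection.
#' @export
random_lambertian_rays <- function(y_max = 0, y_min = -y_max,
                                   theta_max = pi / 2, n = 1000,
                                   seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (y_min > y_max) stop("inverted height range")
  if (!(theta_max > 0 && theta_max <= pi / 2))
    stop("theta_max must be in (0, pi/2]")
  with_local_seed(seed, {
    u <- stats::runif(n)
    rays(stats::runif(n, y_min, y_max), asin((2 * u - 1) * sin(theta_max)),
         distribution = "random-lambertian", seed = seed,
         y_range = c(y_min, y_max), theta_range = c(-theta_max, theta_max))
  })
}

#' Trace a ray collection through an imaging path
#'
#' Vectorized equivalent of [trace_path()] over a whole ensemble: every
#' ray's height is checked against each finite aperture (at the element's
#' entrance plane, via the cumulative object-to-plane matrices) and the
#' first violation blocks it there. Transmitted rays carry their exit state;
#' blocked rays are returned separately, frozen at their blocking plane.
#'
#' @param path An [imaging_path()].
#' @param ensemble A [rays()] collection at `z = 0`.
#' @return A list of class `"trace_result"`: `transmitted` and `blocked`
#'   [rays()] collections, `blocked_index` (per input ray, the element index
#'   that blocked it or `NA`), and `blocked_counts` (named per-element
#'   tally).
#' @export
trace_many_through <- function(path, ensemble) {
  stopifnot(inherits(path, "imaging_path"), is.data.frame(ensemble))
  planes <- path_planes(path)
  ent <- planes$entrance
  y0 <- ensemble$y; th0 <- ensemble$theta
  n <- length(y0)
  blocked_idx <- rep(NA_integer_, n)
  open <- rep(TRUE, n)
  for (i in finite_aperture_idx(planes)) {
    yk <- ent$A[i] * y0 + ent$B[i] * th0
    hit <- open & (abs(yk) > ent$aperture[i] / 2 * (1 + 1e-9))
    blocked_idx[hit] <- i
    open <- open & !hit
  }
  fin <- planes$final
  out <- rays(fin$A * y0[open] + fin$B * th0[open],
              fin$C * y0[open] + fin$D * th0[open],
              z = planes$z_end, distribution = "traced")
  bi <- blocked_idx[!open]
  blk <- rays(ent$A[bi] * y0[!open] + ent$B[bi] * th0[!open],
              ent$C[bi] * y0[!open] + ent$D[bi] * th0[!open],
              z = ent$z[bi], distribution = "blocked")
  if (nrow(blk)) {
    blk$blocked <- TRUE
    blk$blocked_at <- ent$z[bi]
  }
  counts <- table(factor(blocked_idx, levels = seq_len(nrow(ent))))
  names(counts) <- ifelse(nzchar(ent$label), ent$label,
                          sprintf("element %d (%s, z=%g)",
                                  seq_len(nrow(ent)), ent$kind, ent$z))
  structure(list(transmitted = out, blocked = blk,
                 blocked_index = blocked_idx,
                 blocked_counts = counts, n_input = n),
            class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("<trace_result> %d rays in: %d transmitted, %d blocked\n",
              x$n_input, nrow(x$transmitted), nrow(x$blocked)))
  nz <- x$blocked_counts[x$blocked_counts > 0]
  for (nm in names(nz)) cat(sprintf("  blocked at %s: %d\n", nm, nz[[nm]]))
  invisible(x)
}

#' Monte-Carlo transmission efficiency
#'
#' Fraction of input rays that reach the end of the path unblocked.
#'
#' @param path An [imaging_path()].
#' @param ensemble A non-empty [rays()] collection.
#' @return A fraction in `[0, 1]`.
#' @export
transmission_efficiency <- function(path, ensemble) {
  if (!is.data.frame(ensemble) || nrow(ensemble) == 0L)
    stop("ensemble must contain at least one ray")
  res <- trace_many_through(path, ensemble)
  nrow(res$transmitted) / res$n_input
}

#' Intensity histogram of ray heights
#'
#' Bins ray heights into equal-width bins spanning the observed range, the
#' ray-count analogue of an intensity profile at a plane.
#'
#' @param ensemble A non-empty [rays()] collection (e.g. the `transmitted`
#'   component of a [trace_many_through()] result).
#' @param bins Number of bins (>= 1, default 100).
#' @return A list of class `"intensity_histogram"` with `bin_edges` (length
#'   `bins + 1`), `counts` and `total`.
#' @export
intensity_histogram <- function(ensemble, bins = 100) {
  if (!is.data.frame(ensemble) || nrow(ensemble) == 0L)
    stop("ensemble must contain at least one ray")
  if (bins < 1) stop("bins must be at least 1")
  bins <- as.integer(bins)
  y <- ensemble$y
  rng <- range(y)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  idx <- findInterval(y, edges, all.inside = TRUE)
  structure(list(bin_edges = edges, counts = tabulate(idx, bins),
                 total = length(y)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d rays in %d bins over [%g, %g] mm\n",
              x$total, length(x$counts), min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Write a ray collection to CSV
#'
#' Columns `y`, `theta` and, when any ray is blocked, `blocked_at`.
#'
#' @param ensemble A [rays()] collection.
#' @param file Path to write.
#' @export
write_rays_csv <- function(ensemble, file) {
  df <- data.frame(y = ensemble$y, theta = ensemble$theta)
  if (any(ensemble$blocked)) df$blocked_at <- ensemble$blocked_at
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
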