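#' Create a paraxial ray
#'
#' A ray is the state `(y, theta)` of a light ray at an axial position `z`:
#' `y` is the height above the optical axis in millimetres and `theta` the
#' (paraxial) angle with the axis in radians. No trigonometric transform is
#' ever applied to `theta` inside the engine; the small-angle approximation
#' `sin(theta) ~ theta` is what makes propagation linear.
#'
#' A ray can be *blocked* by a finite aperture; once blocked, its state is
#' frozen at the blocking plane and subsequent elements leave it unchanged.
#'
#' @param y Height relative to the optical axis (mm).
#' @param theta Angle relative to the optical axis (rad).
#' @param z Axial position (mm). Defaults to 0 (the object plane).
#' @param blocked Logical; whether the ray has been stopped by an aperture.
#' @param blocked_at Axial position of the blocking aperture (mm), or `NA`.
#' @return An object of class `"ray"`.
#' @examples
#' r <- ray(y = 1, theta = 0.05)
#' transform_ray(lens(f = 50), r)
#' @export
ray <- function(y, theta, z = 0, blocked = FALSE, blocked_at = NA_real_) {
  stopifnot(is.numeric(y), is.numeric(theta), is.numeric(z),
            length(y) == 1L, length(theta) == 1L, length(z) == 1L)
  structure(list(y = as.numeric(y), theta = as.numeric(theta),
                 z = as.numeric(z), blocked = isTRUE(blocked),
                 blocked_at = as.numeric(blocked_at)),
            class = "ray")
}

#' @export
print.ray <- function(x, ...) {
  cat(sprintf("<ray> y = %g mm, theta = %g rad, z = %g mm%s\n",
              x$y, x$theta, x$z,
              if (x$blocked) sprintf(" [blocked at z = %g]", x$blocked_at)
              else ""))
  invisible(x)
}

#' Create a collection of rays
#'
#' A thin wrapper around a data frame with columns `y`, `theta`, `z`,
#' `blocked`, `blocked_at`. Ray collections are the unit of Monte-Carlo
#' tracing; see [random_uniform_rays()], [random_lambertian_rays()] and
#' [uniform_rays()] for generators.
#'
#' @param y,theta Numeric vectors (recycled to common length).
#' @param z Axial position(s), default 0.
#' @param distribution Optional tag describing how the rays were generated.
#' @param seed Optional integer seed recorded as metadata.
#' @param y_range,theta_range Optional declared ranges, recorded as metadata.
#' @return A data frame of class `"rays"`.
#' @export
rays <- function(y, theta, z = 0, distribution = "manual", seed = NULL,
                 y_range = NULL, theta_range = NULL) {
  n <- max(length(y), length(theta))   # z is metadata and may be scalar
  df <- data.frame(y = rep_len(as.numeric(y), n),
                   theta = rep_len(as.numeric(theta), n),
                   z = rep_len(as.numeric(z), n),
                   blocked = rep_len(FALSE, n),
                   blocked_at = rep_len(NA_real_, n))
  attr(df, "distribution") <- distribution
  attr(df, "seed") <- seed
  attr(df, "y_range") <- y_range
  attr(df, "theta_range") <- theta_range
  class(df) <- c("rays", "data.frame")
  df
}

#' @export
print.rays <- function(x, ...) {
  cat(sprintf("<rays> %d rays (%s)%s\n", nrow(x),
              attr(x, "distribution") %||% "manual",
              if (any(x$blocked)) sprintf(", %d blocked", sum(x$blocked))
              else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more\n", nrow(x) - 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression with a locally seeded RNG, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
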