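# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized tracing and closed-form stop solvers: they apply the
# ray recurrence y' = A y + B theta, theta' = C y + D theta element by
# element, and find stops by the literal scan-until-blocked procedure.

# 2x2 numeric matrix of an element (column-major base R matrix)
as_mat <- function(e) matrix(c(e$A, e$C, e$B, e$D), 2)

# brute-force product of an element list, in propagation order
bf_product <- function(elements) {
  m <- diag(2)
  for (e in elements) m <- as_mat(e) %*% m
  m
}

# literal per-ray trace: index of the first blocking element, or NA
bf_first_block <- function(path, y0, th0) {
  y <- y0; th <- th0
  idx <- rep(NA_integer_, length(y))
  open <- rep(TRUE, length(y))
  for (i in seq_along(path$elements)) {
    e <- path$elements[[i]]
    if (is.finite(e$aperture)) {
      hit <- open & abs(y) > e$aperture / 2
      idx[hit] <- i
      open <- open & !hit
    }
    ynew <- e$A * y + e$B * th
    th <- e$C * y + e$D * th
    y <- ynew
  }
  idx
}

# exit state of an unblocked ray, traced element by element
bf_exit <- function(path, y0, th0) {
  y <- y0; th <- th0
  for (e in path$elements) {
    ynew <- e$A * y + e$B * th
    th <- e$C * y + e$D * th
    y <- ynew
  }
  c(y = y, theta = th)
}

# scan-until-blocked aperture stop: raise the on-axis angle until a ray is
# blocked, bisect to the threshold, and name the blocking element.
bf_aperture_stop_index <- function(path, theta_hi = 100) {
  grid <- seq(theta_hi / 2000, theta_hi, length.out = 2000)
  blocked <- !is.na(bf_first_block(path, rep(0, length(grid)), grid))
  k <- which(blocked)[1L]
  if (is.na(k)) return(NA_integer_)
  lo <- if (k == 1L) 0 else grid[k - 1L]
  hi <- grid[k]
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (is.na(bf_first_block(path, 0, mid))) lo <- mid else hi <- mid
  }
  # probe just above the threshold so only the limiting element blocks
  bf_first_block(path, 0, hi * (1 + 1e-8))
}

# chief-ray direction from an object height, found by linearity of the
# height at a given element's entrance plane (two trial traces)
bf_chief_theta <- function(path, as_index, y0) {
  height_at <- function(th) {
    y <- y0; t <- th
    for (i in seq_len(as_index - 1L)) {
      e <- path$elements[[i]]
      ynew <- e$A * y + e$B * t
      t <- e$C * y + e$D * t
      y <- ynew
    }
    y
  }
  h0 <- height_at(0); h1 <- height_at(1)
  -h0 / (h1 - h0)
}

# scan-until-blocked field stop: chief rays of increasing object height
bf_field_stop_index <- function(path, as_index, y_hi = 1000) {
  blocked_at_h <- function(h) {
    bf_first_block(path, h, bf_chief_theta(path, as_index, h))
  }
  grid <- seq(y_hi / 2000, y_hi, length.out = 2000)
  blocked <- vapply(grid, function(h) !is.na(blocked_at_h(h)), logical(1))
  k <- which(blocked)[1L]
  if (is.na(k)) return(NA_integer_)
  lo <- if (k == 1L) 0 else grid[k - 1L]
  hi <- grid[k]
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (is.na(blocked_at_h(mid))) lo <- mid else hi <- mid
  }
  blocked_at_h(hi * (1 + 1e-8))
}

# random lens-and-aperture system with a leading object space and a camera
random_system <- function(seed) {
  set.seed(seed)
  nl <- sample(2:4, 1)
  els <- list(optical_space(runif(1, 20, 80)))
  for (j in seq_len(nl)) {
    els <- c(els,
             list(lens(runif(1, 30, 120), diameter = runif(1, 8, 40),
                       label = sprintf("L%d", j))),
             list(optical_space(runif(1, 40, 150))))
  }
  els <- c(els, list(aperture(runif(1, 5, 25), label = "camera")))
  imaging_path(elements = els)
}

# a random system on which both stop solvers are well posed
random_stoppable_system <- function(seed) {
  for (s in seed + 0:50 * 7919) {
    path <- random_system(s)
    ok <- tryCatch({
      aperture_stop(path); field_stop(path); axial_ray(path)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(path)
  }
  stop("no valid random system found")
}

# Lambertian CDF on [-theta_max, theta_max]
lambertian_cdf <- function(theta_max) {
  force(theta_max)
  function(q) (sin(pmin(pmax(q, -theta_max), theta_max)) + sin(theta_max)) /
    (2 * sin(theta_max))
}
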