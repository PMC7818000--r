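#' Gaussian beam described by its complex q parameter
#'
#' Minimal coherent-beam support on top of the same ray matrices: a TEM00
#' Gaussian beam is encoded by the complex curvature parameter `q` with
#' `1/q = 1/R - i lambda / (pi n w^2)`, where `R` is the wavefront radius of
#' curvature and `w` the 1/e^2 beam radius. At a waist `w0`,
#' `q = i z_R` with Rayleigh range `z_R = pi n w0^2 / lambda`. Consistent
#' with the engine's physical-angle convention, the index enters through
#' the width-recovery formula and the interface matrices.
#'
#' @param wavelength Vacuum wavelength (mm).
#' @param waist Beam waist radius `w0` (mm); the beam starts at its waist.
#'   Give either `waist` or `q`.
#' @param q Complex curvature parameter (mm), alternative to `waist`.
#' @param n Refractive index of the current medium.
#' @param z Axial position (mm).
#' @return An object of class `"gaussian_beam"`.
#' @examples
#' b <- gaussian_beam(wavelength = 0.001, waist = 1)
#' b2 <- propagate_beam(optical_space(3141.59), b)
#' beam_parameters(b2)$w   # w0 * sqrt(2) one Rayleigh range from the waist
#' @export
gaussian_beam <- function(wavelength, waist = NULL, q = NULL, n = 1, z = 0) {
  if (wavelength <= 0) stop("wavelength must be positive")
  if (is.null(q)) {
    if (is.null(waist) || waist <= 0)
      stop("provide a positive waist or a complex q")
    q <- complex(real = 0, imaginary = pi * n * waist^2 / wavelength)
  }
  q <- as.complex(q)
  if (Im(q) == 0) stop("Im(q) must be nonzero for a physical beam")
  structure(list(q = q, wavelength = wavelength, n = n, z = z),
            class = "gaussian_beam")
}

#' Propagate a Gaussian beam through an element or a path
#'
#' Applies the bilinear (ABCD) transform `q' = (A q + B) / (C q + D)` and
#' advances `z` by the element length. For an [imaging_path()] the elements
#' are applied in order. Aperture clipping does not apply to beams (rays
#' only are clipped).
#'
#' @param M An `rt_matrix` or an [imaging_path()].
#' @param beam A [gaussian_beam()].
#' @return The propagated [gaussian_beam()].
#' @export
propagate_beam <- function(M, beam) {
  stopifnot(inherits(beam, "gaussian_beam"))
  if (inherits(M, "imaging_path")) {
    for (e in M$elements) beam <- propagate_beam(e, beam)
    return(beam)
  }
  stopifnot(inherits(M, "rt_matrix"))
  den <- M$C * beam$q + M$D
  if (Mod(den) < 1e-12)
    stop("beam focused to a point at the exit plane (C q + D = 0)")
  gaussian_beam(wavelength = beam$wavelength,
                q = (M$A * beam$q + M$B) / den,
                n = M$n_back, z = beam$z + M$L)
}

#' Width, curvature and waist of a Gaussian beam
#'
#' Inverts `1/q = 1/R - i lambda / (pi n w^2)`: returns the local 1/e^2
#' radius `w`, the wavefront radius of curvature `R` (infinite at a waist),
#' the waist radius `w0` and the signed distance `z_to_waist` from the
#' current plane to the waist (positive when the waist lies downstream).
#'
#' @param beam A [gaussian_beam()].
#' @return A list with `w`, `R`, `w0`, `z_to_waist`, `rayleigh_range` (mm).
#' @export
beam_parameters <- function(beam) {
  stopifnot(inherits(beam, "gaussian_beam"))
  invq <- 1 / beam$q
  w <- sqrt(-beam$wavelength / (pi * beam$n * Im(invq)))
  R <- if (abs(Re(invq)) < 1e-15) Inf else 1 / Re(invq)
  zR <- Im(beam$q)
  w0 <- sqrt(zR * beam$wavelength / (pi * beam$n))
  list(w = w, R = R, w0 = w0, z_to_waist = -Re(beam$q), rayleigh_range = zR)
}

#' @export
print.gaussian_beam <- function(x, ...) {
  p <- beam_parameters(x)
  cat(sprintf(
    "<gaussian_beam> z = %g mm: w = %g mm, R = %g mm (w0 = %g mm, zR = %g mm)\n",
    x$z, p$w, p$R, p$w0, p$rayleigh_range))
  invisible(x)
}
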