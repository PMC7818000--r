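#' Ray-transfer (ABCD) matrix element
#'
#' The general 2x2 ray-transfer matrix, augmented with the physical length of
#' the element along the axis, the refractive indices before and after it, and
#' a clear aperture diameter. All optical elements are instances of this class.
#'
#' The matrix maps a ray `(y, theta)` at the entrance plane to
#' `(A y + B theta, C y + D theta)` at the exit plane; angles are physical
#' angles, so the determinant `A D - B C` equals `n_front / n_back` (1 when
#' the indices match).
#'
#' @param A,B,C,D Matrix entries. `A`, `D` are dimensionless, `B` is in mm,
#'   `C` in 1/mm.
#' @param L Physical length along the axis (mm, >= 0).
#' @param n_front,n_back Refractive indices before and after the element
#'   (>= 1).
#' @param aperture Clear aperture diameter (mm); `Inf` for an unbounded
#'   element. A ray with `|y| > aperture / 2` at the entrance plane is
#'   blocked; the edge itself transmits, with a relative grace of 1e-9 so
#'   that solved grazing rays (marginal, axial, principal) survive
#'   floating-point round-off.
#' @param label Optional text label.
#' @param kind Internal element tag used for serialization and conjugate
#'   search ("space", "lens", ...).
#' @return An object of class `"rt_matrix"`.
#' @seealso [optical_space()], [lens()], [thick_lens()],
#'   [dielectric_interface()], [aperture()], [compose()]
#' @export
rt_matrix <- function(A, B, C, D, L = 0, n_front = 1, n_back = 1,
                      aperture = Inf, label = "", kind = "generic") {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), is.numeric(D))
  if (L < 0) stop("element length L must be non-negative")
  if (n_front < 1 || n_back < 1) stop("refractive indices must be >= 1")
  if (!is.numeric(aperture) || is.na(aperture) || aperture <= 0)
    stop("aperture diameter must be positive (use Inf for none)")
  det <- A * D - B * C
  if (abs(det - n_front / n_back) > 1e-8)
    stop(sprintf("determinant %.12g does not equal n_front/n_back = %.12g",
                 det, n_front / n_back))
  structure(list(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C),
                 D = as.numeric(D), L = as.numeric(L),
                 n_front = as.numeric(n_front), n_back = as.numeric(n_back),
                 aperture = as.numeric(aperture),
                 label = as.character(label), kind = kind),
            class = "rt_matrix")
}

#' @export
print.rt_matrix <- function(x, ...) {
  cat(sprintf("<rt_matrix%s> [[%g, %g], [%g, %g]]  L = %g mm",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$A, x$B, x$C, x$D, x$L))
  if (is.finite(x$aperture)) cat(sprintf("  aperture %g mm", x$aperture))
  if (x$n_front != 1 || x$n_back != 1)
    cat(sprintf("  n %g -> %g", x$n_front, x$n_back))
  cat("\n")
  invisible(x)
}

#' Free-space propagation
#'
#' @param d Propagation distance (mm, >= 0).
#' @param n Refractive index of the medium (>= 1). Because the engine stores
#'   physical angles, the index does not appear in the matrix itself; it
#'   enters only through interface elements and the optical invariant.
#' @param label Optional label.
#' @return An `rt_matrix` `[[1, d], [0, 1]]` with length `d`.
#' @export
optical_space <- function(d, n = 1, label = "") {
  if (d < 0) stop("propagation distance must be non-negative")
  rt_matrix(1, d, 0, 1, L = d, n_front = n, n_back = n,
            label = label, kind = "space")
}

#' Thin lens
#'
#' @param f Focal length (mm, nonzero; negative for a diverging lens).
#' @param diameter Clear diameter (mm), `Inf` by default.
#' @param label Optional label.
#' @return An `rt_matrix` `[[1, 0], [-1/f, 1]]`.
#' @export
lens <- function(f, diameter = Inf, label = "") {
  if (f == 0) stop("focal length must be nonzero")
  rt_matrix(1, 0, -1 / f, 1, L = 0, aperture = diameter,
            label = label, kind = "lens")
}

#' Spherical dielectric interface
#'
#' Refraction at a single spherical surface between media of index `n1` and
#' `n2`, in the paraxial limit of Snell's law. The radius of curvature is
#' positive when the center of curvature lies after the surface (light
#' travels toward +z).
#'
#' @param R Radius of curvature (mm, nonzero); `Inf` for a flat interface.
#' @param n1,n2 Refractive indices before and after the surface (>= 1).
#' @param diameter Clear diameter (mm).
#' @param label Optional label.
#' @return An `rt_matrix` with `C = (n1 - n2) / (n2 R)`, `D = n1 / n2`.
#' @export
dielectric_interface <- function(R = Inf, n1 = 1, n2 = 1, diameter = Inf,
                                 label = "") {
  if (!is.infinite(R) && R == 0) stop("radius of curvature must be nonzero")
  C <- if (is.infinite(R)) 0 else (n1 - n2) / (n2 * R)
  rt_matrix(1, 0, C, n1 / n2, L = 0, n_front = n1, n_back = n2,
            aperture = diameter, label = label, kind = "interface")
}

#' Thick lens from its surface prescription
#'
#' Composes entrance surface, glass propagation and exit surface, so the
#' resulting focal length follows the thick-lens Lensmaker equation
#' `1/f = (n - 1) (1/R1 - 1/R2 + (n - 1) t / (n R1 R2))`.
#'
#' @param n Glass index (>= 1).
#' @param R1,R2 Front and back surface radii of curvature (mm, nonzero;
#'   `Inf` for flat).
#' @param thickness Center thickness (mm, >= 0).
#' @param diameter Clear diameter (mm), checked at the entrance plane.
#' @param label Optional label.
#' @return An `rt_matrix` of physical length `thickness` in air on both sides.
#' @export
thick_lens <- function(n, R1, R2, thickness, diameter = Inf, label = "") {
  m <- compose(list(dielectric_interface(R1, 1, n),
                    optical_space(thickness, n),
                    dielectric_interface(R2, n, 1)))
  m$aperture <- diameter
  m$label <- label
  m$kind <- "thicklens"
  m
}

#' Finite aperture (iris, pinhole, camera sensor)
#'
#' Optically the identity: its only effect is the blocking rule. A ray with
#' `|y| > diameter / 2` at the aperture plane is blocked; a ray exactly at
#' the edge is transmitted, so that marginal rays (defined as hitting the
#' stop edge) trace as transmitted.
#'
#' @param diameter Clear diameter (mm, > 0, finite).
#' @param label Optional label.
#' @return An identity `rt_matrix` with a finite aperture.
#' @export
aperture <- function(diameter, label = "") {
  if (!is.finite(diameter) || diameter <= 0)
    stop("aperture diameter must be positive and finite")
  rt_matrix(1, 0, 0, 1, L = 0, aperture = diameter,
            label = label, kind = "aperture")
}

#' Microscope objective as a focal-to-focal black box
#'
#' Minimal model of an infinity-corrected objective consistent with its
#' catalog parameters: a focal-plane-to-focal-plane transfer
#' `[[0, f], [-1/f, 0]]` stretched over the physical `focus_to_focus` length,
#' with the back aperture as the only clear-diameter constraint.
#'
#' @param f Focal length (mm, > 0).
#' @param na Numerical aperture (informational).
#' @param focus_to_focus Distance from front focal plane to back focal plane
#'   (mm); the element's physical length.
#' @param back_aperture Clear diameter of the back aperture (mm).
#' @param working_distance,magnification,field_number Informational catalog
#'   fields, carried on the element.
#' @param label Optional label.
#' @return An `rt_matrix` of kind `"objective"`.
#' @export
objective_lens <- function(f, na = NA_real_, focus_to_focus = 2 * f,
                           back_aperture = Inf, working_distance = NA_real_,
                           magnification = NA_real_, field_number = NA_real_,
                           label = "") {
  if (f <= 0) stop("objective focal length must be positive")
  m <- rt_matrix(0, f, -1 / f, 0, L = focus_to_focus,
                 aperture = back_aperture, label = label, kind = "objective")
  m$f <- f; m$na <- na; m$working_distance <- working_distance
  m$magnification <- magnification; m$field_number <- field_number
  m
}

# 2x2 product helper: m2 applied after m1 (propagation order m1 then m2).
mat_after <- function(m2, m1) {
  list(A = m2$A * m1$A + m2$B * m1$C,
       B = m2$A * m1$B + m2$B * m1$D,
       C = m2$C * m1$A + m2$D * m1$C,
       D = m2$C * m1$B + m2$D * m1$D)
}

#' Compose optical elements into a single transfer matrix
#'
#' Multiplies the element matrices right-to-left in propagation order (the
#' first element of the list is applied first to a ray). Adjacent elements
#' must agree on the refractive index at their shared plane. The composed
#' matrix has the summed physical length and determinant
#' `n_front(first) / n_back(last)`; any aperture information of the parts is
#' deliberately dropped (blocking is not a linear operation and is handled
#' by [trace_path()] on the element sequence, not on the product).
#'
#' @param elements A non-empty list of `rt_matrix` objects (nested lists are
#'   flattened), or a single `rt_matrix`.
#' @return A single `rt_matrix`.
#' @export
compose <- function(elements) {
  elements <- flatten_elements(elements)
  if (length(elements) == 0L) stop("cannot compose an empty element list")
  acc <- elements[[1L]]
  if (length(elements) == 1L) return(acc)
  for (i in 2L:length(elements)) {
    e <- elements[[i]]
    if (abs(acc$n_back - e$n_front) > 1e-12)
      stop(sprintf(
        "index mismatch between elements %d and %d (n_back = %g, n_front = %g)",
        i - 1L, i, acc$n_back, e$n_front))
    p <- mat_after(e, acc)
    acc <- rt_matrix(p$A, p$B, p$C, p$D, L = acc$L + e$L,
                     n_front = acc$n_front, n_back = e$n_back,
                     kind = "composite")
  }
  acc
}

flatten_elements <- function(x) {
  if (inherits(x, "rt_matrix")) return(list(x))
  if (!is.list(x)) stop("elements must be rt_matrix objects")
  out <- list()
  for (e in x) out <- c(out, flatten_elements(e))
  out
}

#' Apply a transfer matrix to a ray
#'
#' Computes `y' = A y + B theta`, `theta' = C y + D theta` and advances `z`
#' by the element length. If the element has a finite aperture, the clear
#' diameter is checked at the entrance plane: a ray with `|y| > aperture/2`
#' is flagged blocked at that plane and its state frozen. Already-blocked
#' rays pass through unchanged.
#'
#' @param M An `rt_matrix`.
#' @param r A [ray()].
#' @return The transformed [ray()].
#' @export
transform_ray <- function(M, r) {
  stopifnot(inherits(M, "rt_matrix"), inherits(r, "ray"))
  if (r$blocked) return(r)
  if (is.finite(M$aperture) && abs(r$y) > M$aperture / 2 * (1 + 1e-9)) {
    r$blocked <- TRUE
    r$blocked_at <- r$z
    return(r)
  }
  ray(M$A * r$y + M$B * r$theta,
      M$C * r$y + M$D * r$theta,
      z = r$z + M$L)
}

#' Optical invariant of two rays
#'
#' For any two rays evaluated at the same axial position the quantity
#' `n (y1 theta2 - y2 theta1)` is conserved through any paraxial system;
#' it is the optical invariant, and equals the Lagrange invariant `H` when
#' the two rays are the principal and axial rays.
#'
#' @param r1,r2 Two [ray()] objects at the same `z`.
#' @param n Refractive index at that position.
#' @return The invariant (mm rad).
#' @export
optical_invariant <- function(r1, r2, n = 1) {
  stopifnot(inherits(r1, "ray"), inherits(r2, "ray"))
  if (abs(r1$z - r2$z) > 1e-9)
    stop("rays must be evaluated at the same axial position")
  n * (r1$y * r2$theta - r2$y * r1$theta)
}

#' Closed-form system properties of a transfer matrix
#'
#' Focal lengths, focal distances, principal planes and imaging diagnostics
#' of an arbitrary `rt_matrix`. With physical-angle bookkeeping
#' (`det = n1/n2`): the back effective focal length is `-1/C`, the front one
#' `-(n1/n2)/C`; the back focal distance is `-A/C` from the exit plane, the
#' front `-D/C` from the entrance plane; principal planes sit at
#' `LPPf = (n1/n2 - D)/C` after the entrance and `LPPb = (1 - A)/C` after
#' the exit plane. An afocal system (`C = 0`) reports infinite focal
#' quantities rather than raising. The matrix is imaging (`is_imaging`) when
#' `|B| < 1e-9` mm, in which case `A` is the transverse and `D` the angular
#' magnification.
#'
#' @param M An `rt_matrix`.
#' @return A list of class `"system_properties"`.
#' @export
system_properties <- function(M) {
  stopifnot(inherits(M, "rt_matrix"))
  nr <- M$n_front / M$n_back
  afocal <- M$C == 0
  efl_back <- if (afocal) Inf else -1 / M$C
  efl_front <- if (afocal) Inf else -nr / M$C
  bfd <- if (afocal) Inf else -M$A / M$C
  ffd <- if (afocal) Inf else -M$D / M$C
  ppf <- if (afocal) Inf else (nr - M$D) / M$C
  ppb <- if (afocal) Inf else (1 - M$A) / M$C
  imaging <- abs(M$B) < 1e-9
  structure(list(
    effective_focal_length_back = efl_back,
    effective_focal_length_front = efl_front,
    back_focal_distance = bfd,
    front_focal_distance = ffd,
    principal_plane_front = ppf,
    principal_plane_back = ppb,
    is_imaging = imaging,
    transverse_magnification = if (imaging) M$A else NA_real_,
    angular_magnification = if (imaging) M$D else NA_real_
  ), class = "system_properties")
}

#' @export
print.system_properties <- function(x, ...) {
  cat(sprintf("<system_properties> EFL back %g mm, front %g mm\n",
              x$effective_focal_length_back, x$effective_focal_length_front))
  cat(sprintf("  focal distances: back %g, front %g; principal planes: front %g, back %g\n",
              x$back_focal_distance, x$front_focal_distance,
              x$principal_plane_front, x$principal_plane_back))
  if (x$is_imaging)
    cat(sprintf("  imaging: magnification %g (transverse), %g (angular)\n",
                x$transverse_magnification, x$angular_magnification))
  invisible(x)
}

#' Gauss's law of imaging from the matrix formalism
#'
#' For an object a distance `do` in front of a thin lens of focal length `f`,
#' finds the image distance `di` at which the composed matrix
#' `space(do) -> lens(f) -> space(di)` has `B = 0`. `B(di)` is linear in
#' `di`, so the root is solved exactly; the result satisfies
#' `1/do + 1/di = 1/f`, and the magnification is the `A` entry of the
#' composed matrix. For `do = f` the image is at infinity.
#'
#' @param f Thin-lens focal length (mm, nonzero).
#' @param do Object distance (mm, > 0).
#' @return A list with `di` (mm; can be negative for a virtual image, `Inf`
#'   when `do = f`) and `magnification`.
#' @export
gauss_image_solve <- function(f, do) {
  if (f == 0) stop("focal length must be nonzero")
  if (do <= 0) stop("object distance must be positive")
  # space(do) -> lens(f) -> space(di) composes to
  # [[1 - di/f, do + di (1 - do/f)], [-1/f, 1 - do/f]];
  # B(di) is linear in di, so the imaging condition B = 0 solves exactly.
  slope <- 1 - do / f
  if (abs(slope) < 1e-15)
    return(list(di = Inf, magnification = -Inf))
  di <- -do / slope
  list(di = di, magnification = 1 - di / f)
}
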