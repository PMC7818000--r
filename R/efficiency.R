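#' Decompose a ray onto the principal/axial ray basis
#'
#' Any ray can be written as `a * principal + b * axial` because the two
#' special rays span the phase plane (their invariant, the Lagrange
#' invariant `H`, is nonzero). The coefficients are ratios of optical
#' invariants, solved exactly (Cramer):
#' `a = n (y theta_a - y_a theta) / H`,
#' `b = n (y_p theta - y theta_p) / H`, with
#' `H = n (y_p theta_a - y_a theta_p)`.
#' They are dimensionless, conserved along any unblocked trace, and measure
#' where the ray sits inside the design envelope: `|a| <= 1` and `|b| <= 1`
#' means within the field of view and the acceptance cone.
#'
#' @param r The [ray()] to decompose.
#' @param principal,axial Basis rays (e.g. [principal_ray()] and
#'   [axial_ray()]), at the same `z` as `r`.
#' @param n Refractive index at that plane.
#' @return A list with `a` (principal-ray weight) and `b` (axial-ray
#'   weight); reconstruction is exact.
#' @export
decompose_ray <- function(r, principal, axial, n = 1) {
  stopifnot(inherits(r, "ray"), inherits(principal, "ray"),
            inherits(axial, "ray"))
  if (max(abs(c(r$z - principal$z, r$z - axial$z))) > 1e-9)
    stop("all three rays must be at the same axial position")
  H <- n * (principal$y * axial$theta - axial$y * principal$theta)
  if (abs(H) < 1e-12)
    stop("degenerate basis: principal and axial rays are linearly dependent")
  list(a = n * (r$y * axial$theta - axial$y * r$theta) / H,
       b = n * (principal$y * r$theta - r$y * principal$theta) / H)
}

# vectorized decomposition of an ensemble at the object plane
decompose_many <- function(y, theta, principal, axial, n = 1) {
  H <- n * (principal$y * axial$theta - axial$y * principal$theta)
  if (abs(H) < 1e-12)
    stop("degenerate basis: principal and axial rays are linearly dependent")
  list(a = n * (y * axial$theta - axial$y * theta) / H,
       b = n * (principal$y * theta - y * principal$theta) / H,
       H = H)
}

#' Classify traced rays as transmitted, expected-blocked or vignetted
#'
#' Each input ray is decomposed onto the principal/axial basis at the object
#' plane and traced. A blocked ray with `max(|a|, |b|) > 1` lies outside the
#' design envelope (beyond the FOV or the acceptance cone) and is *expected*
#' to be blocked; a blocked ray with `max(|a|, |b|) <= 1` should have made
#' it through, so the element that stopped it is causing *vignetting*.
#'
#' @param path An [imaging_path()] with solvable stops.
#' @param ensemble A [rays()] collection at the object plane.
#' @return A data frame with the input `y`, `theta`, coefficients `a`, `b`,
#'   `status` (factor: transmitted / expected_blocked / vignetted),
#'   `blocked_index` and `blocked_label`.
#' @export
classify_rays <- function(path, ensemble) {
  stopifnot(inherits(path, "imaging_path"), is.data.frame(ensemble))
  pr <- principal_ray(path)
  ax <- axial_ray(path)
  dec <- decompose_many(ensemble$y, ensemble$theta, pr, ax,
                        n = path$object_index)
  res <- trace_many_through(path, ensemble)
  blocked <- !is.na(res$blocked_index)
  inside <- pmax(abs(dec$a), abs(dec$b)) <= 1
  status <- ifelse(!blocked, "transmitted",
                   ifelse(inside, "vignetted", "expected_blocked"))
  ent <- path_planes(path)$entrance
  lab <- ifelse(nzchar(ent$label), ent$label,
                sprintf("element %d (%s, z=%g)", seq_len(nrow(ent)),
                        ent$kind, ent$z))
  data.frame(
    y = ensemble$y, theta = ensemble$theta, a = dec$a, b = dec$b,
    status = factor(status,
                    levels = c("transmitted", "expected_blocked", "vignetted")),
    blocked_index = res$blocked_index,
    blocked_label = ifelse(blocked, lab[res$blocked_index], NA_character_),
    stringsAsFactors = FALSE)
}

#' Efficiency and vignetting report for an imaging path
#'
#' Aggregates the system characterization in one object: stop positions and
#' diameters, field of view, object-space numerical aperture, Lagrange
#' invariant, per-element blocked-ray counts from a Monte-Carlo ensemble,
#' the transmitted / expected-blocked / vignetted tallies, and the element
#' responsible for most vignetting (if any). On a path without a finite
#' aperture the stop analysis is impossible; the report then carries an
#' error note and the (trivially all-transmitted) tallies.
#'
#' @param path An [imaging_path()].
#' @param ensemble A non-empty [rays()] collection at the object plane.
#' @return An object of class `"efficiency_report"`.
#' @export
report_efficiency <- function(path, ensemble) {
  if (!is.data.frame(ensemble) || nrow(ensemble) == 0L)
    stop("ensemble must contain at least one ray")
  total <- nrow(ensemble)
  base <- list(label = path$label, n_rays = total)
  cls <- tryCatch(classify_rays(path, ensemble), error = function(e) e)
  if (inherits(cls, "error")) {
    res <- trace_many_through(path, ensemble)
    rep_ <- c(base, list(
      aperture_stop = NULL, field_stop = NULL,
      fov = NA_real_, object_na = NA_real_, lagrange_h = NA_real_,
      blocked_counts = res$blocked_counts,
      transmitted_count = nrow(res$transmitted),
      expected_blocked_count = NA_integer_,
      vignetted_count = NA_integer_,
      vignetting_element = NA_character_,
      note = conditionMessage(cls)))
    return(structure(rep_, class = "efficiency_report"))
  }
  res <- trace_many_through(path, ensemble)
  vg <- cls[cls$status == "vignetted", ]
  vignetting_element <- if (nrow(vg)) {
    names(sort(table(vg$blocked_label), decreasing = TRUE))[1L]
  } else NA_character_
  rep_ <- c(base, list(
    aperture_stop = aperture_stop(path),
    field_stop = field_stop(path),
    fov = field_of_view(path),
    object_na = object_na(path),
    lagrange_h = lagrange_invariant(path),
    blocked_counts = res$blocked_counts,
    transmitted_count = sum(cls$status == "transmitted"),
    expected_blocked_count = sum(cls$status == "expected_blocked"),
    vignetted_count = sum(cls$status == "vignetted"),
    vignetting_element = vignetting_element,
    note = NA_character_))
  structure(rep_, class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("Efficiency report%s (%d rays)\n",
              if (nzchar(x$label %||% "")) paste0(": ", x$label) else "",
              x$n_rays))
  if (!is.null(x$aperture_stop)) {
    cat(sprintf("  Aperture stop: z = %g mm, D = %g mm %s\n",
                x$aperture_stop$z, x$aperture_stop$diameter,
                x$aperture_stop$label))
    cat(sprintf("  Field stop:    z = %g mm, D = %g mm %s\n",
                x$field_stop$z, x$field_stop$diameter, x$field_stop$label))
    cat(sprintf("  FOV %g mm | NA %g | Lagrange H %g mm rad\n",
                x$fov, x$object_na, x$lagrange_h))
  } else {
    cat(sprintf("  Stop analysis unavailable: %s\n", x$note))
  }
  cat(sprintf("  Transmitted %s | expected blocked %s | vignetted %s\n",
              x$transmitted_count, x$expected_blocked_count,
              x$vignetted_count))
  if (!is.na(x$vignetting_element %||% NA))
    cat(sprintf("  Vignetting caused by: %s\n", x$vignetting_element))
  nz <- x$blocked_counts[x$blocked_counts > 0]
  for (nm in names(nz))
    cat(sprintf("  blocked at %s: %d\n", nm, nz[[nm]]))
  invisible(x)
}

#' Serialize an efficiency report to JSON
#'
#' @param report An [report_efficiency()] result.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string (class `json`).
#' @export
report_as_json <- function(report, pretty = TRUE) {
  stopifnot(inherits(report, "efficiency_report"))
  stop_list <- function(s)
    if (is.null(s)) NULL else list(z = s$z, diameter = s$diameter,
                                   label = s$label)
  jsonlite::toJSON(list(
    label = report$label,
    nRays = report$n_rays,
    apertureStop = stop_list(report$aperture_stop),
    fieldStop = stop_list(report$field_stop),
    fov = report$fov,
    objectNA = report$object_na,
    lagrangeH = report$lagrange_h,
    perElementBlockedCounts = as.list(report$blocked_counts),
    transmittedCount = report$transmitted_count,
    expectedBlockedCount = report$expected_blocked_count,
    vignettedCount = report$vignetted_count,
    vignettingElement = report$vignetting_element,
    note = report$note
  ), auto_unbox = TRUE, pretty = pretty, na = "null", null = "null")
}
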