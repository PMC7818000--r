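#' 4f relay as an element group
#'
#' Two thin lenses separated by the sum of their focal lengths, relaying the
#' front focal plane of the first lens to the back focal plane of the second
#' with magnification `-f2/f1`: `space(f1), lens(f1), space(f1+f2),
#' lens(f2), space(f2)`.
#'
#' @param f1,f2 Focal lengths (mm).
#' @param diameter1,diameter2 Lens clear diameters (mm).
#' @param label1,label2 Lens labels.
#' @return A list of five elements, suitable for [imaging_path()].
#' @export
system4f <- function(f1, f2 = f1, diameter1 = Inf, diameter2 = Inf,
                     label1 = "", label2 = "") {
  list(optical_space(f1), lens(f1, diameter1, label1),
       optical_space(f1 + f2), lens(f2, diameter2, label2),
       optical_space(f2))
}

#' 2f (focus-to-focus) system as an element group
#'
#' One thin lens with a focal-length space on each side: propagates front
#' focal plane to back focal plane (a Fourier transform plane pair).
#'
#' @param f Focal length (mm).
#' @param diameter Lens clear diameter (mm).
#' @param label Lens label.
#' @return A list of three elements.
#' @export
system2f <- function(f, diameter = Inf, label = "") {
  list(optical_space(f), lens(f, diameter, label), optical_space(f))
}

#' Synthetic 60x/1.2 water-immersion objective model
#'
#' A fixture objective with the catalog parameters of a typical
#' high-numerical-aperture 60x water objective (f = 180/60 = 3 mm, NA 1.2,
#' focus-to-focus length 40 mm, back aperture 7 mm), represented as the
#' focal-to-focal black box of [objective_lens()]. The internal matrix is a
#' synthetic minimal model consistent with those parameters, not vendor
#' data.
#'
#' @return An `rt_matrix`.
#' @export
objective_60x_water <- function() {
  objective_lens(f = 180 / 60, na = 1.2, focus_to_focus = 40,
                 back_aperture = 7, working_distance = 0.28,
                 magnification = 60, field_number = 22,
                 label = "60x/1.2W objective (synthetic)")
}

#' Confocal detection path from the focal spot to the pinhole plane
#'
#' The descanned detection path of a confocal laser scanning microscope:
#' the focal spot sits `focal_spot_position` before an f = 5 mm objective
#' (modeled as a thin lens), followed by an f = 100 mm relay lens and two 4f
#' relays (100/75 then 40/50). The path ends at the pinhole plane, which is
#' conjugate to the focal spot with magnification
#' `(-20) x (-0.75) x (-1.25) = -18.75`.
#'
#' @param focal_spot_position Distance (mm) from the focal spot to the
#'   objective lens; 5 (the focal length) puts the spot in focus, other
#'   values defocus it.
#' @return An [imaging_path()].
#' @export
clsm_detection_path <- function(focal_spot_position = 5) {
  imaging_path(
    optical_space(focal_spot_position),
    lens(5, label = "Objective (thin-lens model)"),
    optical_space(105),
    lens(100, label = "Relay"),
    optical_space(100),
    system4f(100, 75),
    system4f(40, 50),
    object_height = 0.0005,
    label = "CLSM detection path")
}

#' Optimal confocal pinhole diameter
#'
#' The pinhole that exactly fits the image of the focal spot: the focal spot
#' diameter (`2 * focal_radius`) times the magnitude of the magnification at
#' the last conjugate plane of the detection path (the pinhole plane).
#'
#' @param focal_radius Focal spot radius (mm); default 0.25 um, a 0.5 um
#'   diffraction-limited spot.
#' @return Pinhole diameter (mm).
#' @export
optimal_pinhole_size <- function(focal_radius = 0.000250) {
  planes <- intermediate_conjugates(clsm_detection_path())
  mag <- planes$magnification[nrow(planes)]
  abs(mag * 2 * focal_radius)
}

#' Pinhole transmission versus focal-spot defocus
#'
#' Monte-Carlo sweep of the confocal axial response: for each defocus the
#' detection path is rebuilt with the focal spot displaced, a seeded uniform
#' ray ensemble (heights within the focal spot, angles over the full
#' meridional range) is traced to the pinhole, and the transmitted fraction
#' recorded. The same input ensemble is reused at every position and
#' pinhole size, so curves for nested pinholes are pointwise ordered by
#' construction.
#'
#' @param pinhole_factor Pinhole diameter as a multiple of
#'   [optimal_pinhole_size()] (e.g. 1/3, 1, 3).
#' @param positions_nm Defocus values in nanometres (displacement of the
#'   focal spot along the axis).
#' @param n Rays per position (>= 1000).
#' @param seed Integer seed for the input ensemble.
#' @param focal_radius Focal spot radius (mm).
#' @return A data frame with `position_nm` and `efficiency`.
#' @export
transmission_vs_defocus <- function(pinhole_factor = 1,
                                    positions_nm = c(-1000, -800, -500, -300,
                                                     -150, -100, -50, -25, 0,
                                                     25, 50, 100, 150, 300,
                                                     500, 800, 1000),
                                    n = 10000, seed = 1,
                                    focal_radius = 0.000250) {
  if (n < 1000) stop("use at least 1000 rays per position")
  pin <- optimal_pinhole_size(focal_radius) * pinhole_factor
  input <- random_uniform_rays(y_max = focal_radius, n = n, seed = seed)
  eff <- vapply(positions_nm, function(znm) {
    p <- clsm_detection_path(focal_spot_position = 5 + znm * 1e-6)
    p <- path_append(p, aperture(pin, label = "Pinhole"))
    transmission_efficiency(p, input)
  }, numeric(1))
  data.frame(position_nm = positions_nm, efficiency = eff)
}

#' Confocal scan path from the polygonal mirror to the sample
#'
#' The illumination path between the scanning polygon and the sample: a
#' 40/75 relay, a 100/100 relay, and the objective ([objective_60x_water()])
#' reached through its front-focal spacing. The object is the laser beam at
#' the polygon plane; the scan position at the sample is linear in the scan
#' angle with zero crossing at zero angle.
#'
#' @return An [imaging_path()].
#' @export
clsm_scan_path <- function() {
  imaging_path(
    system4f(40, 75, diameter1 = 24.5, diameter2 = 24.5),
    system4f(100, 100, diameter1 = 24.5, diameter2 = 24.5),
    optical_space(180 / 40),
    objective_60x_water(),
    optical_space(180 / 40),
    object_height = 0.0005,
    label = "CLSM scan path")
}

#' Scan position at the sample versus polygon scan angle
#'
#' Traces an on-axis fan of scan angles through [clsm_scan_path()] and
#' returns the focal-spot position at the sample plane for each angle.
#'
#' @param scan_angle_deg Half-range of scan angles (degrees).
#' @param n Number of angles in the fan.
#' @return A data frame with `angle_deg` and `position_um` (micrometres).
#' @export
scan_position_curve <- function(scan_angle_deg = 10, n = 101) {
  fan <- uniform_rays(y_max = 0, theta_max = scan_angle_deg * pi / 180,
                      M = 1, N = n)
  res <- trace_many_through(clsm_scan_path(), fan)
  keep <- is.na(res$blocked_index)
  data.frame(angle_deg = fan$theta[keep] * 180 / pi,
             position_um = res$transmitted$y * 1000)
}

#' Koehler illumination path of a conventional widefield microscope
#'
#' Collector (f = 10), field diaphragm, condenser, objective, tube lens and
#' eyepiece (all f = 30), and an f = 2 eye model, with the standard
#' spacings. The lamp filament sits at z = 20/3 mm (inside the leading
#' space) and the specimen at z = 120 mm (one condenser focal length past
#' the condenser); [kohler_source_z()] and [kohler_sample_z()] return these
#' positions. Koehler's defining property: the source is imaged into the
#' condenser front focal plane, never onto the specimen, so each source
#' point illuminates the specimen with a parallel bundle.
#'
#' @return An [imaging_path()].
#' @export
kohler_path <- function() {
  imaging_path(
    optical_space(20),
    lens(10, diameter = 25.4, label = "Collector"),
    optical_space(30),
    aperture(2, label = "Field diaphragm"),
    optical_space(10 + 30),
    lens(30, diameter = 25.4, label = "Condenser"),
    optical_space(30 + 30),
    lens(30, diameter = 25.4, label = "Objective"),
    optical_space(30 + 30),
    lens(30, diameter = 25.4, label = "Tube"),
    optical_space(30 + 30),
    lens(30, diameter = 25.4, label = "Eyepiece"),
    optical_space(30 + 2),
    lens(2, diameter = 10, label = "Eye entrance"),
    optical_space(2),
    label = "Koehler illumination")
}

#' @rdname kohler_path
#' @export
kohler_source_z <- function() 20 / 3

#' @rdname kohler_path
#' @export
kohler_sample_z <- function() 120

#' Conjugate planes of the Koehler source and sample
#'
#' Computes the conjugate planes of the lamp (from `z =`
#' [kohler_source_z()]) and of the specimen (from `z =`
#' [kohler_sample_z()]) along [kohler_path()]. In a correct Koehler layout
#' the two sets are disjoint: the source is never in focus where the sample
#' is, which is what makes the illumination uniform.
#'
#' @return A list with data frames `source` and `sample` (columns `z`
#'   relative to the full path origin, and `magnification`).
#' @export
kohler_conjugates <- function() {
  path <- kohler_path()
  conj_from <- function(z0) {
    sub <- subpath_from(path, z0)
    df <- intermediate_conjugates(sub)
    df$z <- df$z + z0
    df
  }
  list(source = conj_from(kohler_source_z()),
       sample = conj_from(kohler_sample_z()))
}

#' Widefield 4f imaging path with a camera aperture
#'
#' The stop-placement study system: a 50/50 4f relay with lens diameters
#' `d1`, `d2` and a 10 mm camera aperture at the image plane. The relative
#' lens sizes move the aperture and field stops around:
#' \describe{
#'   \item{`d1 = d2` (small)}{AS at the first lens, FS at the second lens:
#'     the field stop is not at the camera, so the image is vignetted.}
#'   \item{`d1 > d2`}{AS at the second lens, FS at the camera: no
#'     vignetting, but the late aperture stop wastes light.}
#'   \item{`d1 < d2`}{AS at the first lens, FS at the camera: no
#'     vignetting and the best throughput of the three.}
#' }
#'
#' @param d1,d2 Lens clear diameters (mm).
#' @param camera Camera aperture diameter (mm).
#' @return An [imaging_path()].
#' @seealso [widefield_scenarios()]
#' @export
widefield_path <- function(d1 = 10, d2 = 10, camera = 10) {
  imaging_path(
    system4f(50, 50, diameter1 = d1, diameter2 = d2,
             label1 = "First lens", label2 = "Second lens"),
    aperture(camera, label = "Camera"),
    object_height = 10,
    label = sprintf("Widefield 4f (d1=%g, d2=%g)", d1, d2))
}

#' Fixture diameters for the three widefield stop-placement scenarios
#'
#' Diameter pairs realizing the three qualitative layouts of
#' [widefield_path()]. Chosen so that the stated stop placements hold and
#' the two well-placed-FS layouts are strictly free of vignetting over the
#' whole design envelope (every other aperture clears
#' `|y_principal| + |y_axial|` at its plane).
#'
#' @return A named list of `c(d1, d2)` pairs: `equal`, `first_larger`,
#'   `second_larger`.
#' @export
widefield_scenarios <- function() {
  list(equal = c(10, 10),
       first_larger = c(40, 12),
       second_larger = c(16, 40))
}
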