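#' Sequential optical system with an object plane
#'
#' An imaging path is an ordered list of elements with the object plane at
#' `z = 0`; element positions are the cumulative sums of the element lengths.
#' It is the unit of analysis for stop detection, special rays, invariants,
#' conjugate planes and Monte-Carlo tracing.
#'
#' @param ... `rt_matrix` elements, or (nested) lists of them such as the
#'   output of [system4f()].
#' @param elements Alternatively, a list of elements.
#' @param object_height Full height of the object (mm); informational, used
#'   by display-style summaries.
#' @param object_index Refractive index at the object plane (>= 1).
#' @param label Optional text label.
#' @return An object of class `"imaging_path"`.
#' @examples
#' path <- imaging_path(
#'   optical_space(50), lens(50, diameter = 10), optical_space(100),
#'   lens(50, diameter = 10), optical_space(50), aperture(10, "Camera"))
#' aperture_stop(path)
#' field_of_view(path)
#' @export
imaging_path <- function(..., elements = NULL, object_height = 10,
                         object_index = 1, label = "") {
  els <- if (is.null(elements)) list(...) else elements
  els <- flatten_elements(els)
  structure(list(elements = els, object_height = object_height,
                 object_index = object_index, label = label),
            class = "imaging_path")
}

#' Append elements to an imaging path
#'
#' @param path An [imaging_path()].
#' @param ... Elements or nested lists of elements.
#' @return The extended path.
#' @export
path_append <- function(path, ...) {
  stopifnot(inherits(path, "imaging_path"))
  path$elements <- c(path$elements, flatten_elements(list(...)))
  path
}

#' Total physical length of a path (mm)
#' @param path An [imaging_path()].
#' @export
path_length <- function(path) {
  sum(vapply(path$elements, function(e) e$L, numeric(1)))
}

#' @export
print.imaging_path <- function(x, ...) {
  cat(sprintf("<imaging_path%s> %d elements, length %g mm\n",
              if (nzchar(x$label)) paste0(" \"", x$label, "\"") else "",
              length(x$elements), path_length(x)))
  z <- 0
  for (e in x$elements) {
    cat(sprintf("  z = %8.3f  %-10s %s%s\n", z, e$kind,
                if (is.finite(e$aperture)) sprintf("D = %g mm ", e$aperture)
                else "",
                e$label))
    z <- z + e$L
  }
  invisible(x)
}

# Cumulative object->entrance matrices for each element, plus the full
# product. Every analysis operation is a linear function of these.
path_planes <- function(path) {
  stopifnot(inherits(path, "imaging_path"))
  k <- length(path$elements)
  if (k == 0L) stop("imaging path has no elements")
  A <- B <- C <- D <- z <- ap <- numeric(k)
  nloc <- numeric(k)
  lab <- character(k); kind <- character(k)
  cur <- list(A = 1, B = 0, C = 0, D = 1)
  zcur <- 0
  for (i in seq_len(k)) {
    e <- path$elements[[i]]
    A[i] <- cur$A; B[i] <- cur$B; C[i] <- cur$C; D[i] <- cur$D
    z[i] <- zcur; ap[i] <- e$aperture
    nloc[i] <- e$n_front
    lab[i] <- e$label; kind[i] <- e$kind
    cur <- mat_after(e, cur)
    zcur <- zcur + e$L
  }
  list(entrance = data.frame(z = z, A = A, B = B, C = C, D = D,
                             aperture = ap, n = nloc, label = lab,
                             kind = kind, stringsAsFactors = FALSE),
       final = cur, z_end = zcur)
}

#' Trace a single ray through an imaging path
#'
#' Applies each element in order, recording the ray state at the object
#' plane and after every element. The clear diameter of each element is
#' checked at its entrance plane; the first violation blocks the ray, whose
#' state is then frozen (later samples advance in `z` only).
#'
#' @param path An [imaging_path()].
#' @param r A [ray()] at `z = 0`.
#' @return A list of class `"trace_record"` with `samples` (data frame of
#'   `z`, `y`, `theta`, `n`), `blocked`, `blocked_at` and the exit `ray`.
#' @export
trace_path <- function(path, r) {
  stopifnot(inherits(path, "imaging_path"), inherits(r, "ray"))
  if (abs(r$z) > 1e-12) stop("input ray must start at the object plane z = 0")
  k <- length(path$elements)
  zs <- ys <- ths <- ns <- numeric(k + 1L)
  zs[1L] <- 0; ys[1L] <- r$y; ths[1L] <- r$theta; ns[1L] <- path$object_index
  cur <- r
  for (i in seq_len(k)) {
    e <- path$elements[[i]]
    cur <- transform_ray(e, cur)
    if (cur$blocked) {
      # frozen state, but z still advances through the remaining geometry
      zs[i + 1L] <- zs[i] + e$L
    } else {
      zs[i + 1L] <- cur$z
    }
    ys[i + 1L] <- cur$y; ths[i + 1L] <- cur$theta
    ns[i + 1L] <- e$n_back
  }
  structure(list(
    samples = data.frame(z = zs, y = ys, theta = ths, n = ns),
    blocked = cur$blocked, blocked_at = cur$blocked_at, ray = cur),
    class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("<trace_record> %d samples%s\n", nrow(x$samples),
              if (x$blocked) sprintf(", blocked at z = %g", x$blocked_at)
              else ""))
  print(x$samples)
  invisible(x)
}

finite_aperture_idx <- function(planes) which(is.finite(planes$entrance$aperture))

stop_info <- function(planes, idx) {
  e <- planes$entrance[idx, ]
  structure(list(z = e$z, diameter = e$aperture,
                 label = e$label, index = idx),
            class = "stop_info")
}

#' @export
print.stop_info <- function(x, ...) {
  cat(sprintf("<stop> z = %g mm, diameter = %g mm%s (element %d)\n",
              x$z, x$diameter,
              if (nzchar(x$label)) paste0(", \"", x$label, "\"") else "",
              x$index))
  invisible(x)
}

# first index achieving the maximum ratio, within a relative tolerance
# (ties resolved toward smallest z, i.e. the earliest element).
argmax_ratio <- function(ratio) {
  m <- max(ratio)
  which(ratio >= m * (1 - 1e-9))[1L]
}

#' Aperture stop of an imaging path
#'
#' The aperture stop (AS) is the physical aperture that limits the
#' acceptance cone from the on-axis object point. It is found by tracing the
#' axial test ray `(y = 0, theta = 1)` (any angle gives the same answer by
#' linearity) and selecting the finite-aperture element where the ratio of
#' ray height to aperture radius `|y_k| / (D_k / 2)` is largest; ties are
#' broken toward the smallest `z`.
#'
#' @param path An [imaging_path()].
#' @return A `"stop_info"` with `z`, `diameter`, `label`, `index`.
#' @export
aperture_stop <- function(path) {
  planes <- path_planes(path)
  fin <- finite_aperture_idx(planes)
  if (length(fin) == 0L) stop("no aperture stop: the path has no finite aperture")
  y <- planes$entrance$B[fin]                    # height of (0, 1) test ray
  ratio <- abs(y) / (planes$entrance$aperture[fin] / 2)
  stop_info(planes, fin[argmax_ratio(ratio)])
}

#' Axial ray
#'
#' The unique on-axis object ray that grazes the edge of the aperture stop;
#' its angle is the largest on-axis angle the system transmits and sets the
#' object-space numerical aperture.
#'
#' @param path An [imaging_path()].
#' @return A [ray()] `(0, theta_a)` with `theta_a > 0`.
#' @export
axial_ray <- function(path) {
  planes <- path_planes(path)
  as_ <- aperture_stop(path)
  yAS <- planes$entrance$B[as_$index]
  if (abs(yAS) < 1e-9)
    stop("aperture stop is conjugate to the object; axial ray undefined")
  ray(0, (as_$diameter / 2) / abs(yAS))
}

#' Marginal rays from an object height
#'
#' The two rays leaving object height `y0` that cross the aperture-stop
#' plane exactly at its upper and lower edges, solved linearly from the
#' object-to-stop submatrix.
#'
#' @param path An [imaging_path()].
#' @param y0 Object height (mm); `y0 = 0` reduces to the +/- axial rays.
#' @return A list of two [ray()] objects (upper edge first).
#' @export
marginal_rays <- function(path, y0 = 0) {
  planes <- path_planes(path)
  as_ <- aperture_stop(path)
  A <- planes$entrance$A[as_$index]; B <- planes$entrance$B[as_$index]
  if (abs(B) < 1e-9)
    stop("object is conjugate to the aperture stop; marginal rays undefined")
  h <- as_$diameter / 2
  list(ray(y0, (h - A * y0) / B), ray(y0, (-h - A * y0) / B))
}

#' Chief ray from an object height
#'
#' The ray from object height `y0` that crosses the aperture stop at its
#' center, `theta0 = -A y0 / B` with `A`, `B` from the object-to-stop
#' submatrix.
#'
#' @param path An [imaging_path()].
#' @param y0 Object height (mm).
#' @return A [ray()].
#' @export
chief_ray <- function(path, y0) {
  planes <- path_planes(path)
  as_ <- aperture_stop(path)
  A <- planes$entrance$A[as_$index]; B <- planes$entrance$B[as_$index]
  if (abs(B) < 1e-9)
    stop("object is conjugate to the aperture stop; chief ray undefined")
  ray(y0, -A * y0 / B)
}

#' Field stop of an imaging path
#'
#' The field stop (FS) is the aperture that limits the field of view: the
#' element that first blocks chief rays of increasing object height. By
#' linearity this is found in closed form from the unit chief ray
#' (`y0 = 1`): the FS is the finite-aperture element maximizing
#' `|y_k| / (D_k / 2)`, ties toward smallest `z`. The aperture stop cannot
#' win, since the chief ray crosses it at zero height.
#'
#' @param path An [imaging_path()].
#' @return A `"stop_info"`.
#' @export
field_stop <- function(path) {
  planes <- path_planes(path)
  cr <- chief_ray(path, 1)
  fin <- finite_aperture_idx(planes)
  y <- planes$entrance$A[fin] * cr$y + planes$entrance$B[fin] * cr$theta
  ratio <- abs(y) / (planes$entrance$aperture[fin] / 2)
  if (max(ratio) < 1e-9)
    stop("no aperture limits the chief ray: infinite field of view")
  stop_info(planes, fin[argmax_ratio(ratio)])
}

#' Principal ray
#'
#' The extreme chief ray: the chief ray from the largest object height that
#' still clears the field stop (it grazes the FS edge). Its origin height is
#' half the field of view.
#'
#' @param path An [imaging_path()].
#' @return A [ray()] with positive origin height.
#' @export
principal_ray <- function(path) {
  planes <- path_planes(path)
  fs <- field_stop(path)
  cr <- chief_ray(path, 1)
  yFS <- planes$entrance$A[fs$index] * cr$y + planes$entrance$B[fs$index] * cr$theta
  chief_ray(path, (fs$diameter / 2) / abs(yFS))
}

#' Field of view at the object plane
#'
#' Twice the principal ray's origin height (mm, a diameter at the object).
#'
#' @param path An [imaging_path()].
#' @return FOV diameter (mm).
#' @export
field_of_view <- function(path) 2 * principal_ray(path)$y

#' Lagrange invariant of an imaging path
#'
#' The optical invariant evaluated on the principal and axial rays at the
#' object plane, `H = n (y_p theta_a - y_a theta_p)`. It is conserved at
#' every plane of the system and bounds the throughput (FOV x NA product);
#' reported positive by orientation convention.
#'
#' @param path An [imaging_path()].
#' @return `H` in mm rad.
#' @export
lagrange_invariant <- function(path) {
  abs(optical_invariant(principal_ray(path), axial_ray(path),
                        n = path$object_index))
}

#' Object-space numerical aperture
#'
#' `n sin(theta_a)` with `theta_a` the axial-ray angle. (The engine itself is
#' paraxial and uses `theta_a` directly; the sine enters only in this
#' reported figure of merit.)
#'
#' @param path An [imaging_path()].
#' @return The numerical aperture (dimensionless).
#' @export
object_na <- function(path) path$object_index * sin(axial_ray(path)$theta)

#' Conjugate planes of the object
#'
#' Scans the path for planes where the cumulative object-to-plane matrix has
#' `B = 0`, i.e. planes on which the object is imaged. Inside free-space
#' elements `B` varies linearly with distance, so zero crossings are solved
#' exactly; other elements are checked at their exit boundary. The object
#' plane itself (`z = 0`) is excluded.
#'
#' @param path An [imaging_path()].
#' @param tol Imaging tolerance on `|B|` (mm) for boundary checks.
#' @return A data frame with columns `z` and `magnification` (the `A` entry
#'   at the conjugate plane), possibly empty.
#' @export
intermediate_conjugates <- function(path, tol = 1e-9) {
  stopifnot(inherits(path, "imaging_path"))
  cur <- list(A = 1, B = 0, C = 0, D = 1)
  zcur <- 0
  zs <- mags <- numeric(0)
  push <- function(z, mag) {
    if (z > 1e-9 && !any(abs(zs - z) < 1e-6)) {
      zs <<- c(zs, z); mags <<- c(mags, mag)
    }
  }
  for (e in path$elements) {
    if (e$kind == "space" && e$L > 0 && cur$D != 0) {
      d_star <- -cur$B / cur$D
      if (d_star > 1e-12 && d_star <= e$L + 1e-12)
        push(zcur + d_star, cur$A + d_star * cur$C)
    }
    cur <- mat_after(e, cur)
    zcur <- zcur + e$L
    if (abs(cur$B) < tol) push(zcur, cur$A)
  }
  data.frame(z = zs, magnification = mags)
}

#' Extract the tail of a path starting at an interior plane
#'
#' Returns a new imaging path whose object plane is at axial position `z0`
#' of the original path. Free-space elements straddling `z0` are split;
#' `z0` may not fall strictly inside a non-space element.
#'
#' @param path An [imaging_path()].
#' @param z0 Axial position (mm) of the new object plane.
#' @param object_index Refractive index at the new object plane (defaults to
#'   the local medium).
#' @return An [imaging_path()].
#' @export
subpath_from <- function(path, z0, object_index = NULL) {
  stopifnot(inherits(path, "imaging_path"))
  out <- list()
  zcur <- 0
  n0 <- path$object_index
  for (e in path$elements) {
    zend <- zcur + e$L
    if (zend <= z0 + 1e-12) {
      n0 <- e$n_back
    } else if (zcur >= z0 - 1e-12) {
      out <- c(out, list(e))
    } else {
      if (e$kind != "space")
        stop("z0 falls inside a non-space element; cannot split")
      out <- c(out, list(optical_space(zend - z0, n = e$n_front,
                                       label = e$label)))
      n0 <- e$n_front
    }
    zcur <- zend
  }
  if (length(out) == 0L) stop("z0 is beyond the end of the path")
  imaging_path(elements = out, object_height = path$object_height,
               object_index = object_index %||% n0,
               label = sprintf("%s [from z=%g]", path$label, z0))
}
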