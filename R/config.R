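#' Read a declarative optical-system description
#'
#' Parses a YAML (or JSON; YAML is a superset) system description into a
#' validated configuration object. The document has the shape:
#'
#' ```yaml
#' label: Simple example
#' object:
#'   height: 10
#'   index: 1
#' elements:
#'   - {kind: space, d: 50}
#'   - {kind: lens, f: 50, diameter: 25, label: First lens}
#'   - {kind: space, d: 100}
#'   - {kind: lens, f: 50, diameter: 25, label: Second lens}
#'   - {kind: space, d: 50}
#' ```
#'
#' All lengths are millimetres and angles radians (no unit declarations).
#' Refractive indices use the key `index` (a bare `n` is a YAML 1.1
#' boolean). Recognized kinds and their parameters:
#' `space` (`d`, optional `index`), `lens` (`f`, optional `diameter`),
#' `thicklens` (`index`, `R1`, `R2`, `t`, optional `diameter`),
#' `interface` (`R`, `n1`, `n2`, optional `diameter`),
#' `aperture` (`diameter`), `objective` (`f`, `focus_to_focus`,
#' `back_aperture`, optional `na`), `system2f` (`f`, optional `diameter`)
#' and `system4f` (`f1`, `f2`, optional `diameter1`, `diameter2`).
#' Unknown kinds and missing parameters are rejected with the element index.
#'
#' @param file Path to a config file, or a literal YAML string containing a
#'   newline.
#' @return A validated list of class `"system_config"`.
#' @seealso [build_path()], [write_system_config()]
#' @export
read_system_config <- function(file) {
  doc <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    yaml::read_yaml(file) else yaml::yaml.load(paste(file, collapse = "\n"))
  validate_system_config(doc)
}

config_kinds <- list(
  space = list(required = "d", optional = c("index", "label")),
  lens = list(required = "f", optional = c("diameter", "label")),
  thicklens = list(required = c("index", "R1", "R2", "t"),
                   optional = c("diameter", "label")),
  interface = list(required = c("R", "n1", "n2"),
                   optional = c("diameter", "label")),
  aperture = list(required = "diameter", optional = "label"),
  objective = list(required = c("f", "focus_to_focus", "back_aperture"),
                   optional = c("na", "label")),
  system2f = list(required = "f", optional = c("diameter", "label")),
  system4f = list(required = c("f1", "f2"),
                  optional = c("diameter1", "diameter2", "label"))
)

validate_system_config <- function(doc) {
  if (!is.list(doc)) stop("config must be a mapping")
  els <- doc$elements
  if (is.null(els) || length(els) == 0L)
    stop("config must declare a non-empty 'elements' list")
  for (i in seq_along(els)) {
    e <- els[[i]]
    if (!is.list(e) || is.null(e$kind))
      stop(sprintf("element %d: missing 'kind'", i))
    sch <- config_kinds[[e$kind]]
    if (is.null(sch))
      stop(sprintf("element %d: unknown kind '%s'", i, e$kind))
    missing <- setdiff(sch$required, names(e))
    if (length(missing))
      stop(sprintf("element %d (%s): missing parameter(s) %s",
                   i, e$kind, paste(missing, collapse = ", ")))
    extra <- setdiff(names(e), c("kind", sch$required, sch$optional))
    if (length(extra))
      stop(sprintf("element %d (%s): unknown parameter(s) %s",
                   i, e$kind, paste(extra, collapse = ", ")))
  }
  structure(list(label = doc$label %||% "",
                 object = list(height = doc$object$height %||% 10,
                               index = doc$object$index %||% 1),
                 elements = els),
            class = "system_config")
}

#' Build an imaging path from a configuration
#'
#' Expands every config element to its primitive(s) (`system4f` and
#' `system2f` entries expand to their lens/space groups) and assembles an
#' [imaging_path()] equivalent to programmatic construction.
#'
#' @param config A `"system_config"` from [read_system_config()].
#' @return An [imaging_path()].
#' @export
build_path <- function(config) {
  stopifnot(inherits(config, "system_config"))
  lab <- function(e) e$label %||% ""
  dia <- function(x) x %||% Inf
  els <- lapply(config$elements, function(e) {
    switch(e$kind,
      space = optical_space(e$d, n = e$index %||% 1, label = lab(e)),
      lens = lens(e$f, diameter = dia(e$diameter), label = lab(e)),
      thicklens = thick_lens(e$index, e$R1, e$R2, e$t,
                             diameter = dia(e$diameter), label = lab(e)),
      interface = dielectric_interface(e$R, e$n1, e$n2,
                                       diameter = dia(e$diameter),
                                       label = lab(e)),
      aperture = aperture(e$diameter, label = lab(e)),
      objective = objective_lens(e$f, na = e$na %||% NA_real_,
                                 focus_to_focus = e$focus_to_focus,
                                 back_aperture = e$back_aperture,
                                 label = lab(e)),
      system2f = system2f(e$f, diameter = dia(e$diameter), label = lab(e)),
      system4f = system4f(e$f1, e$f2, diameter1 = dia(e$diameter1),
                          diameter2 = dia(e$diameter2)))
  })
  imaging_path(elements = els, object_height = config$object$height,
               object_index = config$object$index, label = config$label)
}

#' Serialize a system configuration to YAML
#'
#' Inverse of [read_system_config()]: `read_system_config(
#' write_system_config(cfg))` reproduces `cfg` exactly.
#'
#' @param config A `"system_config"`.
#' @param file Optional path to write; with `NULL` the YAML text is
#'   returned.
#' @return The YAML string (invisibly when written to a file).
#' @export
write_system_config <- function(config, file = NULL) {
  stopifnot(inherits(config, "system_config"))
  txt <- yaml::as.yaml(list(label = config$label,
                            object = config$object,
                            elements = config$elements))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
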