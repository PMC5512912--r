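#' Default media table
#'
#' Named refractive indices used when resolving prescription media.  The
#' published lens tables name media only; indices follow standard
#' schematic-eye values at the 555 nm photopic peak: cornea 1.376,
#' aqueous/vitreous humor 1.336, homogeneous crystalline lens equivalent
#' 1.42, IOL acrylic (the tables' ACRYLIC_SPECIAL) 1.4918, air 1.
#'
#' @return Named numeric vector mapping medium name to refractive index.
#' @export
default_media <- function() {
  c(air = 1, cornea = 1.376, humor = 1.336, lens = 1.42, acrylic = 1.4918)
}

#' Optical prescription of an eye (or any centred conic system)
#'
#' An ordered surface list from object side to image side.  Exactly one
#' surface must be flagged as the aperture stop and the last surface is the
#' terminal image (retina) surface with zero thickness.
#'
#' @param name Label for the system.
#' @param surfaces List of [conic_surface()] objects, object to image side.
#' @param object_distance Distance from the object to the first surface in
#'   mm; `Inf` (default) for a collimated object at infinity.  Negative
#'   values place a virtual object behind the first surface.
#' @param pupil_diameter Traced beam diameter at the stop in mm.
#' @param wavelength Design wavelength in nm.
#' @return An object of class `eye_prescription`.
#' @seealso [builtin_prescription()], [read_prescription()]
#' @export
eye_prescription <- function(name, surfaces, object_distance = Inf,
                             pupil_diameter = 6, wavelength = 555) {
  p <- structure(list(
    name = as.character(name),
    surfaces = surfaces,
    object_distance = as.numeric(object_distance),
    pupil_diameter = as.numeric(pupil_diameter),
    wavelength = as.numeric(wavelength)
  ), class = "eye_prescription")
  validate_prescription(p)
  p
}

#' Validate an eye prescription
#'
#' Checks the structural invariants: at least three surfaces, exactly one
#' stop, a terminal image surface of zero thickness, and per-surface sag
#' realness over each clear aperture.
#'
#' @param p An `eye_prescription`.
#' @return `p`, invisibly; errors describe the first violated invariant.
#' @export
validate_prescription <- function(p) {
  if (!inherits(p, "eye_prescription"))
    stop("not an eye_prescription", call. = FALSE)
  ns <- length(p$surfaces)
  if (ns < 3) stop("prescription needs at least 3 surfaces", call. = FALSE)
  for (s in p$surfaces) validate_surface(s)
  stops <- vapply(p$surfaces, function(s) s$stop, logical(1))
  if (sum(stops) != 1)
    stop("prescription must flag exactly one stop surface", call. = FALSE)
  if (p$surfaces[[ns]]$thickness != 0)
    stop("terminal image surface must have zero thickness", call. = FALSE)
  if (!is.finite(p$pupil_diameter) || p$pupil_diameter <= 0)
    stop("pupil diameter must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.eye_prescription <- function(x, ...) {
  cat(sprintf("<eye_prescription> %s: %d surfaces, pupil %g mm, %g nm, object at %s\n",
              x$name, length(x$surfaces), x$pupil_diameter, x$wavelength,
              if (is.finite(x$object_distance))
                sprintf("%g mm", x$object_distance) else "infinity"))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
as.data.frame.eye_prescription <- function(x, ...) {
  data.frame(
    surface = seq_along(x$surfaces),
    curvature = vapply(x$surfaces, `[[`, numeric(1), "curvature"),
    conic = vapply(x$surfaces, `[[`, numeric(1), "conic"),
    thickness = vapply(x$surfaces, `[[`, numeric(1), "thickness"),
    medium = vapply(x$surfaces, `[[`, character(1), "medium"),
    index = vapply(x$surfaces, `[[`, numeric(1), "index"),
    semi_aperture = vapply(x$surfaces, `[[`, numeric(1), "semi_aperture"),
    stop = vapply(x$surfaces, `[[`, logical(1), "stop")
  )
}

#' Index of the stop surface
#' @param p An `eye_prescription`.
#' @return Integer position of the stop surface.
#' @export
stop_index <- function(p) {
  which(vapply(p$surfaces, function(s) s$stop, logical(1)))[1]
}

#' Axial vertex positions
#'
#' Cumulative z position of each surface vertex, with the first surface
#' vertex at z = 0 and light travelling in +z.
#'
#' @param p An `eye_prescription`.
#' @return Numeric vector of vertex z positions in mm.
#' @export
vertex_positions <- function(p) {
  th <- vapply(p$surfaces, `[[`, numeric(1), "thickness")
  cumsum(c(0, th[-length(th)]))
}

# decimal text that reads back to the identical double: the short form
# when it round-trips, else 17 significant digits; Inf spelled the YAML way
.num_chr <- function(x) {
  if (is.infinite(x)) return(if (x > 0) ".inf" else "-.inf")
  s <- as.character(x)
  if (identical(as.numeric(s), as.numeric(x))) s else sprintf("%.17g", x)
}

#' Write a prescription file
#'
#' Serialises a prescription to the package's plain-text (YAML)
#' prescription format: a header with `name`, `wavelength_nm`,
#' `pupil_diameter_mm`, `object_distance`, then one record per surface with
#' keys `type`, `curvature`, `conic`, `thickness`, `medium`,
#' `semi_aperture`, `stop`.  Numbers are written with the shortest
#' representation that reads back to the identical double, so write/read
#' round-trips are bit-exact.
#'
#' @param p An `eye_prescription`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prescription <- function(p, path) {
  validate_prescription(p)
  ln <- c(
    sprintf("name: %s", p$name),
    sprintf("wavelength_nm: %s", .num_chr(p$wavelength)),
    sprintf("pupil_diameter_mm: %s", .num_chr(p$pupil_diameter)),
    sprintf("object_distance: %s", .num_chr(p$object_distance)),
    "surfaces:")
  for (s in p$surfaces) {
    ln <- c(ln, sprintf(
      "- {type: %s, curvature: %s, conic: %s, thickness: %s, medium: %s, semi_aperture: %s, stop: %s}",
      if (s$conic == 0) "sphere" else "conic",
      .num_chr(s$curvature), .num_chr(s$conic), .num_chr(s$thickness),
      s$medium, .num_chr(s$semi_aperture),
      if (s$stop) "true" else "false"))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a prescription file
#'
#' Parses the plain-text prescription format written by
#' [write_prescription()], resolving medium names to refractive indices
#' through a media table.
#'
#' @param path Prescription file path.
#' @param media Named index table (see [default_media()]), or a path to a
#'   YAML media table file mapping medium name to index.
#' @return An `eye_prescription`.
#' @export
read_prescription <- function(path, media = default_media()) {
  if (is.character(media) && length(media) == 1 && file.exists(media))
    media <- read_media(media)
  doc <- yaml::read_yaml(path)
  need <- c("name", "wavelength_nm", "pupil_diameter_mm",
            "object_distance", "surfaces")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop(sprintf("%s: missing header key(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  surfs <- lapply(seq_along(doc$surfaces), function(i) {
    r <- doc$surfaces[[i]]
    for (k in c("curvature", "thickness", "medium", "semi_aperture"))
      if (is.null(r[[k]]))
        stop(sprintf("%s: surface %d: missing key '%s'", path, i, k),
             call. = FALSE)
    if (!r$medium %in% names(media))
      stop(sprintf("%s: surface %d: medium '%s' not in media table",
                   path, i, r$medium), call. = FALSE)
    conic_surface(r$curvature, if (is.null(r$conic)) 0 else r$conic,
                  r$thickness, r$medium, media[[r$medium]],
                  r$semi_aperture, isTRUE(r$stop))
  })
  eye_prescription(doc$name, surfs,
                   object_distance = as.numeric(doc$object_distance),
                   pupil_diameter = doc$pupil_diameter,
                   wavelength = doc$wavelength_nm)
}

#' Write / read a media table file
#'
#' A media table is a flat YAML mapping of medium name to refractive index.
#'
#' @param media Named numeric vector of indices.
#' @param path File path.
#' @return `write_media`: `path` invisibly; `read_media`: named numeric
#'   vector.
#' @export
write_media <- function(media, path) {
  writeLines(sprintf("%s: %s", names(media),
                     vapply(media, .num_chr, character(1))), path)
  invisible(path)
}

#' @rdname write_media
#' @export
read_media <- function(path) {
  m <- yaml::read_yaml(path)
  unlist(m)
}
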