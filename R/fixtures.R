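# Published schematic-eye and IOL prescriptions, transcribed from the
# source tables.  "Y Radius" columns are read uniformly as vertex CURVATURE
# in 1/mm (0.1287 mm^-1 is the familiar 7.77 mm anterior corneal radius),
# not as radius.  Conic constants are printed only for the IOL surfaces
# (#4 and #6); the cornea and humor surfaces carry K = 0 here.

# shared anterior segment: cornea front/back, aqueous gap, aperture stop
.anterior_segment <- function(media) {
  list(
    conic_surface(0.1287, 0, 0.6,   "cornea", media[["cornea"]], 4.6712),
    conic_surface(0.1563, 0, 5.195, "humor",  media[["humor"]],  4.3066),
    conic_surface(0,      0, 0,     "humor",  media[["humor"]],  3, stop = TRUE)
  )
}

.iol_tables <- list(
  # c4, K4, t4, sa4, t5, sa5, c6, K6, sa6, sa_image
  codev_5mm = list(c4 = 0.0707, K4 = -24.88, t4 = 0.0915, sa4 = 2.0413,
                   t5 = 1.2623, sa5 = 2.2640, c6 = -0.0853, K6 = 1.37,
                   sa6 = 2.6105, sa_img = 7.7009),
  ga_5mm    = list(c4 = 0.0755, K4 = -27.2,  t4 = 0.9283, sa4 = 2.0408,
                   t5 = 1.0016, sa5 = 2.2688, c6 = -0.0849, K6 = 1.69,
                   sa6 = 2.5282, sa_img = 7.6499),
  codev_6mm = list(c4 = 0.0819, K4 = -11.24, t4 = 0.9763, sa4 = 2.0413,
                   t5 = 1.2627, sa5 = 2.2640, c6 = -0.0702, K6 = -3.85,
                   sa6 = 2.6105, sa_img = 7.7009),
  ga_6mm    = list(c4 = 0.0791, K4 = -12.68, t4 = 1.1739, sa4 = 2.0408,
                   t5 = 1.1021, sa5 = 2.2688, c6 = -0.0723, K6 = -4.32,
                   sa6 = 2.5282, sa_img = 7.6499)
)

#' Built-in schematic-eye and IOL prescriptions
#'
#' Returns one of the packaged prescriptions transcribed from the published
#' lens tables:
#' \describe{
#'   \item{`initial_eye`}{Schematic eye with the printed initial crystalline
#'     lens (anterior surface plane, "posterior" curvature 0.0806 mm^-1,
#'     part thicknesses 1.59 and 2.43 mm).  Note: the printed 0.0806 mm^-1
#'     equals the cited schematic eye's \emph{anterior} lens curvature
#'     (1/12.40 mm), so the printed anterior/posterior labels appear
#'     swapped or truncated; the fixture follows the printed table.}
#'   \item{`myopic_eye`}{`initial_eye` with 550 degrees myopia and 175
#'     degrees astigmatism applied through [apply_refractive_error()].}
#'   \item{`codev_5mm`, `ga_5mm`, `codev_6mm`, `ga_6mm`}{Eye with IOL after
#'     the built-in (CODE V-style damped-least-squares) and
#'     genetic-algorithm optimisations, for 5 and 6 mm pupils.}
#' }
#' All six share the anterior segment (cornea, aqueous, 3 mm semi-aperture
#' stop) and the curved retina image surface (curvature -0.0909 mm^-1).
#'
#' @param name One of `"initial_eye"`, `"myopic_eye"`, `"codev_5mm"`,
#'   `"ga_5mm"`, `"codev_6mm"`, `"ga_6mm"`.
#' @param pupil_diameter Pupil diameter in mm; defaults to the pupil the
#'   design was published for (5 or 6), and 6 for the initial/myopic eyes.
#' @param media Named refractive-index table; see [default_media()].
#' @param error_mode Perturbation convention forwarded to
#'   [apply_refractive_error()] for `myopic_eye`.
#' @return An `eye_prescription`.
#' @examples
#' builtin_prescription("ga_6mm")
#' @export
builtin_prescription <- function(name, pupil_diameter = NULL,
                                 media = default_media(),
                                 error_mode = c("thickness", "curvature")) {
  name <- match.arg(name, c("initial_eye", "myopic_eye", names(.iol_tables)))
  if (is.null(pupil_diameter))
    pupil_diameter <- if (grepl("_5mm$", name)) 5 else 6
  if (name == "initial_eye" || name == "myopic_eye") {
    surfs <- c(.anterior_segment(media), list(
      # crystalline lens, printed initial values; topology mirrors the IOL
      # tables (#4 anterior, #5 internal interface, #6 posterior)
      conic_surface(0,      0, 1.59,  "lens",  media[["lens"]],  3),
      conic_surface(0,      0, 2.43,  "lens",  media[["lens"]],  3),
      conic_surface(0.0806, 0, 16.27, "humor", media[["humor"]], 3),
      conic_surface(-0.0909, 0, 0,    "humor", media[["humor"]], 7.7009)
    ))
    p <- eye_prescription(name, surfs, Inf, pupil_diameter)
    # the natural-lens eye is emmetropic by construction: its vitreous
    # depth (not printed anywhere) is set so the paraxial focus falls on
    # the retina; the pseudophakic designs use their printed 16.27 mm
    p$surfaces[[6]]$thickness <- paraxial_trace(p, 1e-9)$image_distance
    validate_prescription(p)
    if (name == "myopic_eye")
      p <- apply_refractive_error(p, refractive_error_spec(550, 175),
                                  mode = match.arg(error_mode))
    return(p)
  }
  tb <- .iol_tables[[name]]
  na <- media[["acrylic"]]
  surfs <- c(.anterior_segment(media), list(
    conic_surface(tb$c4, tb$K4, tb$t4, "acrylic", na, tb$sa4),
    conic_surface(0,     0,     tb$t5, "acrylic", na, tb$sa5),
    conic_surface(tb$c6, tb$K6, 16.27, "humor", media[["humor"]], tb$sa6),
    conic_surface(-0.0909, 0, 0, "humor", media[["humor"]], tb$sa_img)
  ))
  eye_prescription(name, surfs, Inf, pupil_diameter)
}

#' Names of the built-in prescriptions
#' @return Character vector of fixture names accepted by
#'   [builtin_prescription()].
#' @export
builtin_prescription_names <- function() {
  c("initial_eye", "myopic_eye", names(.iol_tables))
}
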