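#' Spot diagram
#'
#' Image-plane intersection points of a pupil-filling ray bundle, with the
#' reference point used for RMS statistics: either the bundle centroid
#' (default) or the chief-ray intersection.
#'
#' @param points n x 2 matrix (or data.frame) of image-plane (x, y) in mm;
#'   rows with `NA` (vignetted rays) are dropped.
#' @param reference `"centroid"` or `"chief"`.
#' @param chief_point Chief-ray image point, required for
#'   `reference = "chief"`.  When `points` come from [pupil_ray_fan()] the
#'   first row is the chief ray.
#' @param pupil_diameter,field_angle Bookkeeping; recorded in the object.
#' @return An object of class `spot_diagram`.
#' @export
spot_diagram <- function(points, reference = c("centroid", "chief"),
                         chief_point = NULL, pupil_diameter = NA,
                         field_angle = 0) {
  reference <- match.arg(reference)
  pts <- as.matrix(points)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 1) stop("empty spot diagram", call. = FALSE)
  ref <- if (reference == "centroid") colMeans(pts) else {
    if (is.null(chief_point))
      stop("chief_point required for reference = 'chief'", call. = FALSE)
    as.numeric(chief_point)
  }
  structure(list(points = pts, reference = ref, reference_mode = reference,
                 pupil_diameter = pupil_diameter,
                 field_angle = field_angle),
            class = "spot_diagram")
}

#' RMS spot radius
#'
#' Root-mean-square radial distance of the spot's rays from its reference
#' point:
#' \deqn{R_{RMS} = \sqrt{\sum_i [(x_i - x_0)^2 + (y_i - y_0)^2] / n}.}
#'
#' @param spot A [spot_diagram()].
#' @return RMS radius in mm.
#' @export
rms_spot <- function(spot) {
  stopifnot(inherits(spot, "spot_diagram"))
  dx <- spot$points[, 1] - spot$reference[1]
  dy <- spot$points[, 2] - spot$reference[2]
  sqrt(mean(dx^2 + dy^2))
}

#' Geometric modulation transfer function
#'
#' Geometric (ray-based) MTF: the Fourier magnitude of the spot's
#' point-spread sample along one orientation,
#' \deqn{M(f) = \left| \frac{1}{n} \sum_k e^{-2\pi i f u_k} \right|}
#' where \eqn{u_k} are the spot coordinates along the chosen axis
#' (tangential = y, sagittal = x) in mm and f is in cycles/mm (line pairs
#' per mm).  Rigid translation of the spot only changes the phase, so the
#' modulation is translation-invariant; M(0) = 1 by construction.
#' Diffraction is not modelled.
#'
#' @param spot A [spot_diagram()].
#' @param frequencies Spatial frequencies in cycles/mm (>= 0).
#' @param orientation `"tangential"` or `"sagittal"`.
#' @return An object of class `mtf_curve`: data.frame-like list with
#'   `frequency`, `modulation`, `orientation`.
#' @export
geometric_mtf <- function(spot, frequencies = c(10, 20, 30),
                          orientation = c("tangential", "sagittal")) {
  stopifnot(inherits(spot, "spot_diagram"))
  orientation <- match.arg(orientation)
  if (any(frequencies < 0)) stop("frequencies must be >= 0", call. = FALSE)
  u <- spot$points[, if (orientation == "tangential") 2 else 1]
  mod <- vapply(frequencies, function(f)
    Mod(mean(exp(-2i * pi * f * u))), numeric(1))
  structure(list(frequency = as.numeric(frequencies),
                 modulation = pmin(mod, 1),
                 orientation = orientation),
            class = "mtf_curve")
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> %s\n", x$orientation))
  print(data.frame(frequency_lp_mm = x$frequency,
                   modulation = x$modulation),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Improvement rate between two metric values
#'
#' Percentage improvement of a proposed design's metric `X` over a
#' reference design's metric `Y`:
#' \describe{
#'   \item{aberration mode (smaller is better)}{
#'     \eqn{D = (|Y| - |X|)/|Y| \times 100}: positive when the proposed
#'     value is smaller in magnitude.}
#'   \item{resolution mode (larger is better, used for MTF)}{
#'     \eqn{D = (X - Y)/X \times 100}: positive when the proposed value is
#'     larger.}
#' }
#'
#' @param X Metric value after the proposed method.
#' @param Y Reference metric value.
#' @param mode `"aberration"` or `"resolution"`.
#' @return Improvement in percent.
#' @examples
#' improvement_rate(0.014618, 0.01, "aberration")   # -46.18
#' improvement_rate(0.901, 0.768, "resolution")     #  14.76
#' @export
improvement_rate <- function(X, Y, mode = c("aberration", "resolution")) {
  mode <- match.arg(mode)
  if (mode == "aberration") {
    if (abs(Y) == 0) stop("zero reference value", call. = FALSE)
    (abs(Y) - abs(X)) / abs(Y) * 100
  } else {
    if (X == 0) stop("zero proposed value", call. = FALSE)
    (X - Y) / X * 100
  }
}

#' Improvement report for paired metrics
#'
#' Tabulates [improvement_rate()] for named metric pairs, with the
#' absolute difference of magnitudes, as used when comparing an optimised
#' design against a reference optimisation.
#'
#' @param metrics Character vector of metric names.
#' @param X Proposed-design values (same length).
#' @param Y Reference values (same length).
#' @param mode Single mode or vector per metric.
#' @return data.frame with columns `metric`, `X`, `Y`, `difference`
#'   (`||Y|-|X||`), `improvement_pct`, `mode`.
#' @export
improvement_report <- function(metrics, X, Y, mode = "aberration") {
  stopifnot(length(X) == length(metrics), length(Y) == length(metrics))
  mode <- rep_len(mode, length(metrics))
  data.frame(
    metric = metrics, X = X, Y = Y,
    difference = abs(abs(X) - abs(Y)),
    improvement_pct = mapply(improvement_rate, X, Y, mode),
    mode = mode
  )
}

#' Evaluate the image quality of a design
#'
#' One-call bundle of the package's metrics for a prescription:
#' paraxial/Seidel SA and TCO (chief ray at `field_angle_deg`), and an
#' on-axis real-ray spot with its RMS radius and geometric MTF at the
#' requested spatial frequencies.  Deterministic for a fixed grid.
#'
#' @param p An `eye_prescription`.
#' @param grid Pupil sampling grid for [pupil_ray_fan()].
#' @param field_angle_deg Field angle for the Seidel chief ray (degrees).
#' @param frequencies MTF spatial frequencies in cycles/mm.
#' @param reference Spot reference mode, `"centroid"` or `"chief"`.
#' @return An object of class `design_evaluation`: list with `SA`, `TCO`,
#'   `RMS`, `MTF` (an `mtf_curve`), `spot`, `seidel`, `n_rays`,
#'   `n_vignetted`.
#' @export
evaluate_design <- function(p, grid = list(pattern = "hexapolar",
                                           rings_or_n = 8),
                            field_angle_deg = 5,
                            frequencies = c(10, 20, 30),
                            reference = "centroid") {
  sez <- seidel_aberrations(p, paraxial_trace(p, field_angle_deg))
  rays <- pupil_ray_fan(p, grid, field_angle = 0)
  tr <- trace_rays(p, rays)
  if (all(tr$vignetted))
    stop("all rays vignetted: design is not traceable", call. = FALSE)
  spot <- spot_diagram(tr$image_points, reference = reference,
                       chief_point = tr$image_points[1, ],
                       pupil_diameter = p$pupil_diameter)
  structure(list(
    name = p$name,
    SA = sez$SA, TCO = sez$TCO,
    RMS = rms_spot(spot),
    MTF = geometric_mtf(spot, frequencies),
    spot = spot, seidel = sez,
    n_rays = length(rays), n_vignetted = sum(tr$vignetted)
  ), class = "design_evaluation")
}

#' @export
print.design_evaluation <- function(x, ...) {
  cat(sprintf("<design_evaluation> %s\n", x$name))
  cat(sprintf("  SA  %.6g   TCO %.6g   RMS %.6g mm\n", x$SA, x$TCO, x$RMS))
  cat(sprintf("  MTF (%s): %s\n", x$MTF$orientation,
              paste(sprintf("%g lp/mm: %.3f", x$MTF$frequency,
                            x$MTF$modulation), collapse = ", ")))
  cat(sprintf("  rays traced %d, vignetted %d\n", x$n_rays, x$n_vignetted))
  invisible(x)
}
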