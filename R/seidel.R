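#' Seidel third-order aberration sums
#'
#' Computes the classical per-surface Seidel sums S_I..S_V over the
#' refracting conic surfaces of a prescription, including the conic
#' (fourth-order asphericity) contribution proportional to
#' \eqn{K c^3 y^4} at each surface, from a paraxial marginal/chief ray
#' pair.  The headline scalars are reported on the transverse-ray scale at
#' the image (mm):
#' \deqn{SA = S_I / (2 n_k' u_k'), \qquad TCO = 3 S_{II} / (2 n_k' u_k')}
#' with \eqn{n_k' u_k'} the image-space marginal ray, a sign convention
#' under which SA equals the real marginal ray's third-order transverse
#' aberration at the paraxial focus; the chief ray's field angle (recorded
#' in the result) sets the TCO normalisation.  These are
#' classical Seidel values under this package's stated normalisation; they
#' are not calibrated to any proprietary optical-design code's conventions.
#'
#' @param p An `eye_prescription`.
#' @param par A [paraxial_trace()] of `p`; computed at the default 5 degree
#'   field when omitted.
#' @return An object of class `seidel_summary`: `per_surface` matrix,
#'   `totals`, `SA`, `TCO`, `normalization` string, plus the field angle
#'   and pupil radius used.
#' @export
seidel_aberrations <- function(p, par = NULL) {
  if (is.null(par)) par <- paraxial_trace(p)
  if (!inherits(par, "paraxial_trace"))
    stop("par must be a paraxial_trace", call. = FALSE)
  if (!is.finite(par$u_img) || par$u_img == 0)
    stop("degenerate paraxial trace (afocal image space)", call. = FALSE)
  structure(list(
    per_surface = par$S,
    totals = par$totals,
    SA = par$SA,
    TCO = par$TCO,
    field_angle_deg = par$field_angle_deg,
    pupil_radius = par$pupil_radius,
    normalization = paste0(
      "Seidel sums with real-angle paraxial rays; SA = S1/(2 n'u'), ",
      "TCO = 3 S2/(2 n'u') at the image-space marginal ray; chief ray at ",
      par$field_angle_deg, " deg"),
    prescription = par$prescription
  ), class = "seidel_summary")
}

#' @export
print.seidel_summary <- function(x, ...) {
  cat(sprintf("<seidel_summary> %s (pupil radius %g mm, field %g deg)\n",
              x$prescription, x$pupil_radius, x$field_angle_deg))
  cat(sprintf("  SA  = %.6g\n  TCO = %.6g\n", x$SA, x$TCO))
  cat(sprintf("  totals: S1 %.4g  S2 %.4g  S3 %.4g  S4 %.4g  S5 %.4g\n",
              x$totals[1], x$totals[2], x$totals[3], x$totals[4],
              x$totals[5]))
  cat(" ", x$normalization, "\n")
  invisible(x)
}
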