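#' Refractive error specification
#'
#' Myopia and astigmatism magnitudes in "degrees" as used clinically in
#' East Asia: 100 degrees = 1 dioptre, so 550 degrees myopia with 175
#' degrees astigmatism is -5.50 D sphere / 1.75 D cylinder.  Astigmatism is
#' treated as a scalar (rotationally symmetric) perturbation; no cylinder
#' axis is modelled.
#'
#' @param myopia_degrees Myopia magnitude M (>= 0).
#' @param astigmatism_degrees Astigmatism magnitude N (>= 0).
#' @return An object of class `refractive_error_spec`.
#' @export
refractive_error_spec <- function(myopia_degrees = 0, astigmatism_degrees = 0) {
  M <- as.numeric(myopia_degrees); N <- as.numeric(astigmatism_degrees)
  if (!is.finite(M) || M < 0 || !is.finite(N) || N < 0)
    stop("myopia and astigmatism degrees must be finite and non-negative",
         call. = FALSE)
  structure(list(myopia_degrees = M, astigmatism_degrees = N),
            class = "refractive_error_spec")
}

#' Cornea and humor modifiers for a refractive error
#'
#' Maps (M, N) degrees of myopia and astigmatism to the two scalar model
#' perturbations:
#' \deqn{\mathrm{cornea} = (N/100)\times 0.1, \qquad
#'       \mathrm{humor} = \frac{M + N/2}{100}\times 0.37.}
#' The humor coefficient 0.37 per 100 degrees (i.e. per dioptre) matches
#' the familiar ~0.37 mm of axial elongation per dioptre of myopia.
#'
#' @param spec A [refractive_error_spec()].
#' @return Named numeric vector `c(cornea = ..., humor = ...)`.
#' @examples
#' refractive_error_modifiers(refractive_error_spec(550, 175))
#' @export
refractive_error_modifiers <- function(spec) {
  M <- spec$myopia_degrees; N <- spec$astigmatism_degrees
  c(cornea = (N / 100) * 0.1,
    humor = (M + N / 2) / 100 * 0.37)
}

#' Apply a refractive error to a prescription
#'
#' Perturbs the cornea and the humor of a schematic eye by the two scalar
#' modifiers of [refractive_error_modifiers()], under one of two
#' conventions:
#' \describe{
#'   \item{`"thickness"` (default)}{Both modifiers are read as mm of axial
#'     growth: the cornea modifier is added to the corneal gap thickness
#'     (first surface whose following medium is the cornea) and the humor
#'     modifier to the last vitreous-humor gap before the image (axial
#'     elongation, the dominant anatomical correlate of myopia).}
#'   \item{`"curvature"`}{Both modifiers are read as 1/mm of curvature
#'     steepening: added to the anterior cornea curvature and to the last
#'     humor-boundary curvature.  Large errors can steepen a surface until
#'     its conic sag is no longer real over the full clear aperture; the
#'     semi-aperture is then clamped to 99.9% of the real extent, with a
#'     warning.}
#' }
#' The perturbation is additive, so applying a spec and then re-applying
#' with `negate = TRUE` restores the original parameters exactly.  The mode
#' used is recorded in the prescription name.
#'
#' @param p An `eye_prescription` containing cornea and humor surfaces.
#' @param spec A [refractive_error_spec()].
#' @param mode `"thickness"` or `"curvature"`.
#' @param negate Logical; subtract the modifiers instead of adding them.
#' @return A new `eye_prescription`.
#' @export
apply_refractive_error <- function(p, spec,
                                   mode = c("thickness", "curvature"),
                                   negate = FALSE) {
  mode <- match.arg(mode)
  mods <- refractive_error_modifiers(spec)
  if (negate) mods <- -mods
  media <- vapply(p$surfaces, `[[`, character(1), "medium")
  ns <- length(p$surfaces)
  i_cornea <- which(media == "cornea")[1]
  # last humor surface before the terminal image surface (the vitreous
  # chamber boundary); the image surface itself has zero thickness
  i_humor <- utils::tail(which(media == "humor" & seq_len(ns) < ns), 1)
  if (!length(i_humor))
    i_humor <- utils::tail(which(media == "humor"), 1)
  if (is.na(i_cornea) || !length(i_humor))
    stop("prescription has no identifiable cornea/humor surfaces",
         call. = FALSE)
  surfs <- p$surfaces
  if (mode == "thickness") {
    surfs[[i_cornea]]$thickness <- surfs[[i_cornea]]$thickness + mods[["cornea"]]
    surfs[[i_humor]]$thickness <- surfs[[i_humor]]$thickness + mods[["humor"]]
    if (surfs[[i_cornea]]$thickness < 0 || surfs[[i_humor]]$thickness < 0)
      stop("refractive-error perturbation drove a thickness negative",
           call. = FALSE)
  } else {
    surfs[[i_cornea]]$curvature <- surfs[[i_cornea]]$curvature + mods[["cornea"]]
    surfs[[i_humor]]$curvature <- surfs[[i_humor]]$curvature + mods[["humor"]]
    for (i in c(i_cornea, i_humor)) {
      s <- surfs[[i]]
      if (s$conic > -1 && (1 + s$conic) * s$curvature^2 * s$semi_aperture^2 > 1) {
        surfs[[i]]$semi_aperture <-
          0.999 / (sqrt(1 + s$conic) * abs(s$curvature))
        warning(sprintf(
          "surface %d semi-aperture clamped to %.4f mm (sag real extent)",
          i, surfs[[i]]$semi_aperture), call. = FALSE)
      }
    }
  }
  newname <- if (negate && grepl(" \\[", p$name)) sub(" \\[.*$", "", p$name)
             else sprintf("%s [M=%g N=%g %s]", p$name, spec$myopia_degrees,
                          spec$astigmatism_degrees, mode)
  eye_prescription(newname, surfs, p$object_distance,
                   p$pupil_diameter, p$wavelength)
}
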