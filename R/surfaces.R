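#' Conic refracting surface
#'
#' A single rotationally symmetric refracting interface described by its
#' vertex curvature \eqn{c} (1/mm, signed; 0 is a plane), conic constant
#' \eqn{K} (0 sphere, -1 paraboloid, < -1 hyperboloid), the axial gap to the
#' next surface, the medium that follows the surface, and a clear
#' semi-aperture.  Positive curvature places the centre of curvature on the
#' image side; light travels in +z; all lengths are in mm.
#'
#' @param curvature Vertex curvature in 1/mm (signed; 0 = plane).
#' @param conic Conic constant \eqn{K} (dimensionless).
#' @param thickness Axial distance to the next surface in mm (>= 0; the
#'   terminal image surface uses 0).
#' @param medium Name of the medium following the surface (e.g. `"cornea"`,
#'   `"humor"`, `"acrylic"`).
#' @param index Refractive index of that medium (1 to 2.5).
#' @param semi_aperture Clear semi-aperture in mm (> 0).
#' @param stop Logical; is this the aperture stop?
#' @return An object of class `conic_surface`.
#' @examples
#' cornea <- conic_surface(0.1287, 0, 0.6, "cornea", 1.376, 4.6712)
#' @export
conic_surface <- function(curvature = 0, conic = 0, thickness = 0,
                          medium = "air", index = 1, semi_aperture = 1,
                          stop = FALSE) {
  s <- structure(list(
    curvature = as.numeric(curvature),
    conic = as.numeric(conic),
    thickness = as.numeric(thickness),
    medium = as.character(medium),
    index = as.numeric(index),
    semi_aperture = as.numeric(semi_aperture),
    stop = isTRUE(stop)
  ), class = "conic_surface")
  validate_surface(s)
  s
}

validate_surface <- function(s) {
  stopifnot(is.finite(s$curvature), is.finite(s$conic))
  if (!is.finite(s$thickness) || s$thickness < 0)
    stop("surface thickness must be finite and non-negative", call. = FALSE)
  if (!is.finite(s$index) || s$index < 1 || s$index > 2.5)
    stop("refractive index must lie in [1, 2.5]", call. = FALSE)
  if (!is.finite(s$semi_aperture) || s$semi_aperture <= 0)
    stop("semi-aperture must be positive", call. = FALSE)
  # the sag must be real over the full clear aperture
  if (s$conic > -1 &&
      (1 + s$conic) * s$curvature^2 * s$semi_aperture^2 > 1)
    stop("conic sag is not real over the clear aperture ",
         "(|c|*semi_aperture too large for this conic constant)",
         call. = FALSE)
  invisible(s)
}

#' @export
print.conic_surface <- function(x, ...) {
  cat(sprintf(
    "<conic_surface> c=%g mm^-1  K=%g  t=%g mm  %s (n=%g)  sa=%g mm%s\n",
    x$curvature, x$conic, x$thickness, x$medium, x$index,
    x$semi_aperture, if (x$stop) "  [stop]" else ""))
  invisible(x)
}

#' Sag of a conic surface
#'
#' Axial depth \eqn{z} of a conic surface at radial height `x` from its
#' vertex, in the curvature form
#' \deqn{z = \frac{c x^2}{1 + \sqrt{1 - (1+K) c^2 x^2}}}
#' which is algebraically equivalent to the radius form
#' \eqn{z = x^2 / (R + \sqrt{R^2 - (1+K) x^2})} with \eqn{c = 1/R}.
#'
#' @param x Radial height(s) in mm.
#' @param curvature Vertex curvature in 1/mm.
#' @param conic Conic constant \eqn{K}.
#' @return Sag(s) in mm; 0 everywhere for a plane (`curvature = 0`).
#' @examples
#' conic_sag(1, 0.1, 0)            # spherical sag, R = 10 mm
#' conic_sag(2, 0.05, -1)          # paraboloid: exactly c x^2 / 2
#' @export
conic_sag <- function(x, curvature, conic = 0) {
  if (curvature == 0) return(rep(0, length(x)))
  rad <- 1 - (1 + conic) * curvature^2 * x^2
  if (any(rad < 0))
    stop("point outside the real extent of the conic surface", call. = FALSE)
  curvature * x^2 / (1 + sqrt(rad))
}
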