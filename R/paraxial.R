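# Fast paraxial y-nu + Seidel core over plain vectors (no S3 overhead).
# The genetic algorithm evaluates thousands of candidate lenses through
# this function, so it works directly on the prescription's surface
# vectors: curvature curv, conic K, thickness thick (mm), index after each
# surface nafter, stop position istop, pupil radius at the stop (mm), and
# the chief-ray field tangent tanf.
#
# Conventions: real (not reduced) angles u = dy/dz; refraction
# n'u' = n u - y c (n' - n); transfer y' = y + t u'.  Seidel sums follow
# the standard per-surface form
#   S_I = -sum A^2 y d(u/n),  S_II = -sum A Abar y d(u/n), ...
# with the refraction invariant A = n (y c + u), plus the conic
# (fourth-order asphericity) contribution K c^3 (n'-n) y^4 scaled by
# chief/marginal height ratios.  SA and TCO are reported on the
# transverse-ray-aberration scale at the image: SA = S_I / (2 n_k u_k),
# TCO = 3 S_II / (2 n_k u_k) with n_k u_k the image-space marginal ray;
# with this sign SA equals the real marginal ray's third-order transverse
# aberration at the paraxial focus.
.paraxial_seidel_core <- function(curv, conic, thick, nafter, istop,
                                  objdist, pupil_r, tanf) {
  ns <- length(curv)
  nin <- c(1, nafter[-ns])
  nout <- nafter
  nout[ns] <- nin[ns]                    # image surface does not refract

  sweep_ray <- function(y1, u0) {
    y <- numeric(ns); uin <- numeric(ns); uout <- numeric(ns)
    yy <- y1; u <- u0
    for (i in seq_len(ns)) {
      y[i] <- yy
      uin[i] <- u
      if (i < ns) {
        u <- (nin[i] * u - yy * curv[i] * (nout[i] - nin[i])) / nout[i]
        uout[i] <- u
        yy <- yy + thick[i] * u
      } else uout[i] <- u
    }
    list(y = y, uin = uin, uout = uout)
  }

  # marginal ray: fill the stop to pupil_r
  m0 <- if (is.finite(objdist)) sweep_ray(objdist, 1) else sweep_ray(1, 0)
  if (abs(m0$y[istop]) < 1e-15)
    stop("degenerate system: marginal ray has zero height at the stop",
         call. = FALSE)
  sc <- pupil_r / m0$y[istop]
  marg <- lapply(m0, `*`, sc)

  # chief ray: field tangent tanf through the stop centre (linear solve)
  c0 <- sweep_ray(0, tanf)
  c1 <- sweep_ray(1, tanf)
  dy <- c1$y[istop] - c0$y[istop]
  if (abs(dy) < 1e-15)
    stop("degenerate system: chief ray cannot be aimed at the stop",
         call. = FALSE)
  y1c <- -c0$y[istop] / dy
  chief <- Map(function(a, b) a + y1c * (b - a), c0, c1)

  # focal length from a unit collimated ray
  aux <- if (is.finite(objdist)) sweep_ray(1, 0) else m0
  u_img_aux <- aux$uout[ns - 1]
  efl <- if (abs(u_img_aux) < 1e-15) Inf else -aux$y[1] / u_img_aux

  refr <- which(nout != nin | curv != 0)
  k <- if (length(refr)) max(refr[refr < ns]) else ns - 1L  # last refracting surface
  u_img <- marg$uout[k]
  n_img <- nout[k]
  img_dist <- if (abs(u_img) < 1e-15) Inf else -marg$y[k] / u_img

  H <- nin[1] * (chief$uin[1] * marg$y[1] - marg$uin[1] * chief$y[1])

  S <- matrix(0, ns, 5,
              dimnames = list(NULL, c("S1", "S2", "S3", "S4", "S5")))
  for (i in seq_len(ns - 1)) {
    dn <- nout[i] - nin[i]
    if (dn == 0) next
    y <- marg$y[i]; yb <- chief$y[i]
    A <- nin[i] * (y * curv[i] + marg$uin[i])
    Ab <- nin[i] * (yb * curv[i] + chief$uin[i])
    du <- marg$uout[i] / nout[i] - marg$uin[i] / nin[i]
    dln <- 1 / nout[i] - 1 / nin[i]
    s1 <- -A^2 * y * du
    s2 <- -A * Ab * y * du
    s3 <- -Ab^2 * y * du
    s4 <- -H^2 * curv[i] * dln
    s5 <- if (abs(A) > 1e-12) (Ab / A) * (s3 + s4) else 0
    if (conic[i] != 0 && y != 0) {
      d1 <- conic[i] * curv[i]^3 * dn * y^4
      r <- yb / y
      s1 <- s1 + d1; s2 <- s2 + d1 * r; s3 <- s3 + d1 * r^2
      s5 <- s5 + d1 * r^3
    }
    S[i, ] <- c(s1, s2, s3, s4, s5)
  }
  tot <- colSums(S)
  denom <- 2 * n_img * u_img
  list(S = S, totals = tot,
       SA = if (denom != 0) tot[["S1"]] / denom else NaN,
       TCO = if (denom != 0) 3 * tot[["S2"]] / denom else NaN,
       marginal = marg, chief = chief, H = H,
       efl = efl, image_distance = img_dist,
       n_img = n_img, u_img = u_img)
}

# decompose a prescription into the plain vectors the core consumes
.rx_vectors <- function(p) {
  list(
    curv = vapply(p$surfaces, `[[`, numeric(1), "curvature"),
    conic = vapply(p$surfaces, `[[`, numeric(1), "conic"),
    thick = vapply(p$surfaces, `[[`, numeric(1), "thickness"),
    nafter = vapply(p$surfaces, `[[`, numeric(1), "index"),
    istop = stop_index(p)
  )
}

#' Paraxial marginal and chief ray trace
#'
#' Standard y-nu paraxial trace: the marginal ray is launched from the
#' axial object point (or collimated for an infinite conjugate) and scaled
#' to fill the stop to `pupil_radius`; the chief ray enters at the field
#' angle and is aimed exactly through the stop centre by a linear solve.
#'
#' @param p An `eye_prescription`.
#' @param field_angle_deg Chief-ray field angle in degrees (default 5; the
#'   tangential-coma Seidel sum is identically zero on axis).
#' @param pupil_radius Marginal ray height at the stop in mm; defaults to
#'   `p$pupil_diameter / 2`.
#' @return An object of class `paraxial_trace`: per-surface marginal and
#'   chief heights/angles, Lagrange invariant `H`, system focal length
#'   `efl` (`Inf` flags an afocal/zero-power system), image distance after
#'   the last refracting surface, and the image-space marginal `n_img`,
#'   `u_img`.
#' @export
paraxial_trace <- function(p, field_angle_deg = 5, pupil_radius = NULL) {
  v <- .rx_vectors(p)
  if (is.null(pupil_radius)) pupil_radius <- p$pupil_diameter / 2
  core <- .paraxial_seidel_core(v$curv, v$conic, v$thick, v$nafter, v$istop,
                                p$object_distance, pupil_radius,
                                tan(field_angle_deg * pi / 180))
  structure(c(core[c("marginal", "chief", "H", "efl", "image_distance",
                     "n_img", "u_img")],
              list(S = core$S, totals = core$totals,
                   SA = core$SA, TCO = core$TCO,
                   field_angle_deg = field_angle_deg,
                   pupil_radius = pupil_radius,
                   prescription = p$name)),
            class = "paraxial_trace")
}

#' @export
print.paraxial_trace <- function(x, ...) {
  cat(sprintf("<paraxial_trace> %s: EFL %.4f mm, image distance %.4f mm, H = %.6g\n",
              x$prescription, x$efl, x$image_distance, x$H))
  df <- data.frame(surface = seq_along(x$marginal$y),
                   y = x$marginal$y, u = x$marginal$uout,
                   y_chief = x$chief$y, u_chief = x$chief$uout)
  print(df, row.names = FALSE, digits = 6)
  invisible(x)
}
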