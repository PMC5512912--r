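#' Geometric ray
#'
#' A ray is a point of origin (mm), a unit direction vector with positive
#' z component (light travels in +z), and a wavelength.
#'
#' @param origin Numeric length-3 origin in mm.
#' @param direction Numeric length-3 direction; normalised internally.
#' @param wavelength Wavelength in nm.
#' @return An object of class `ray`.
#' @export
ray <- function(origin, direction, wavelength = 555) {
  d <- as.numeric(direction)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("ray direction cannot be zero", call. = FALSE)
  d <- d / nrm
  if (d[3] <= 0)
    stop("ray direction must have positive z component", call. = FALSE)
  structure(list(origin = as.numeric(origin), direction = d,
                 wavelength = wavelength), class = "ray")
}

# Intersection of a ray with a conic surface whose vertex sits at vertex_z
# on the optical axis.  The conic z = sag(r) satisfies the implicit quadric
#   c (x^2 + y^2 + (1+K) z^2) - 2 z = 0     (z local to the vertex)
# which is solved in closed form along the ray; the sag branch (the sheet
# through the vertex) is identified by 1 - (1+K) c z >= 0.
#
# Returns list(point, normal, t) or NULL when the ray misses.
intersect_conic <- function(origin, direction, curvature, conic, vertex_z) {
  o <- c(origin[1], origin[2], origin[3] - vertex_z)
  d <- direction
  if (abs(curvature) < 1e-12) {          # analytic plane
    if (abs(d[3]) < 1e-15) return(NULL)
    t <- -o[3] / d[3]
    if (t < -1e-9) return(NULL)
    pt <- o + t * d
    return(list(point = c(pt[1], pt[2], pt[3] + vertex_z),
                normal = c(0, 0, -1), t = t))
  }
  k1 <- 1 + conic
  a <- curvature * (d[1]^2 + d[2]^2 + k1 * d[3]^2)
  b <- curvature * (o[1] * d[1] + o[2] * d[2] + k1 * o[3] * d[3]) - d[3]
  f0 <- curvature * (o[1]^2 + o[2]^2 + k1 * o[3]^2) - 2 * o[3]
  disc <- b^2 - a * f0
  if (disc < 0) return(NULL)
  s <- sqrt(disc)
  ts <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-15) return(NULL)
    -f0 / (2 * b)
  } else if (abs(b) > 1e-14) {
    q <- -(b + sign(b) * s)
    c(q / a, f0 / q)
  } else {
    c(s / a, -s / a)
  }
  best <- NULL
  for (t in ts) {
    if (!is.finite(t) || t < -1e-9) next
    zl <- o[3] + t * d[3]
    if (1 - k1 * curvature * zl > -1e-10) {   # sag branch only
      if (is.null(best) || t < best) best <- t
    }
  }
  if (is.null(best)) return(NULL)
  pt <- o + best * d
  g <- c(2 * curvature * pt[1], 2 * curvature * pt[2],
         2 * curvature * k1 * pt[3] - 2)
  g <- g / sqrt(sum(g^2))
  list(point = c(pt[1], pt[2], pt[3] + vertex_z), normal = g, t = best)
}

#' Vector refraction (Snell's law)
#'
#' Refracts a unit direction at an interface with unit normal, from index
#' `n1` into `n2`.  The normal's orientation is immaterial (it is flipped
#' internally so that it opposes the incoming ray).  Returns `NULL` on
#' total internal reflection.
#'
#' @param direction Unit incoming direction.
#' @param normal Unit surface normal.
#' @param n1,n2 Refractive indices before / after the interface.
#' @return Unit refracted direction, or `NULL` for TIR.
#' @export
refract <- function(direction, normal, n1, n2) {
  n <- normal
  ci <- -sum(direction * n)
  if (ci < 0) { n <- -n; ci <- -ci }
  eta <- n1 / n2
  k <- 1 - eta^2 * (1 - ci^2)
  if (k < 0) return(NULL)                 # total internal reflection
  t <- eta * direction + (eta * ci - sqrt(k)) * n
  t / sqrt(sum(t^2))
}

#' Trace one ray through a prescription
#'
#' Sequentially intersects and refracts the ray through every surface, in
#' order, starting in air.  A ray is flagged vignetted when it misses a
#' surface, strikes it outside the clear semi-aperture, or undergoes total
#' internal reflection; the offending surface index is recorded.  The
#' terminal image surface is intersected but not refracted.
#'
#' @param p An `eye_prescription`.
#' @param r A [ray()] starting in object space (origin z below the first
#'   vertex at z = 0).
#' @param clip Logical; enforce semi-apertures (default `TRUE`).
#' @param through Optional surface index at which to stop tracing
#'   (inclusive); used e.g. to trace only up to the stop.
#' @param n_start Refractive index of the starting (object-space) medium;
#'   1 (air) unless tracing e.g. a reversed system.
#' @return An object of class `trace_result`: list with `points` (matrix,
#'   one row per surface reached), `image_point` (x, y on the final traced
#'   surface), `vignetted`, `vignette_surface`, `tir`, `total_path` (mm).
#' @export
trace_ray <- function(p, r, clip = TRUE, through = NULL, n_start = 1) {
  vz <- vertex_positions(p)
  ns <- length(p$surfaces)
  last <- if (is.null(through)) ns else min(through, ns)
  o <- r$origin; d <- r$direction
  n_cur <- n_start
  pts <- matrix(NA_real_, last, 3)
  path <- 0
  vign <- FALSE; vsurf <- NA_integer_; tir <- FALSE
  for (i in seq_len(last)) {
    s <- p$surfaces[[i]]
    hit <- intersect_conic(o, d, s$curvature, s$conic, vz[i])
    if (is.null(hit)) { vign <- TRUE; vsurf <- i; break }
    if (clip && sqrt(hit$point[1]^2 + hit$point[2]^2) >
          s$semi_aperture + 1e-9) {
      vign <- TRUE; vsurf <- i; break
    }
    pts[i, ] <- hit$point
    path <- path + hit$t
    o <- hit$point
    if (i < ns) {                        # image surface: no refraction
      if (s$index != n_cur) {
        d2 <- refract(d, hit$normal, n_cur, s$index)
        if (is.null(d2)) { vign <- TRUE; tir <- TRUE; vsurf <- i; break }
        d <- d2
      }
      n_cur <- s$index
    }
  }
  done <- !vign
  structure(list(
    points = pts,
    image_point = if (done) pts[last, 1:2] else c(NA_real_, NA_real_),
    direction = d,
    vignetted = vign, vignette_surface = vsurf, tir = tir,
    total_path = path
  ), class = "trace_result")
}

# trace up to the stop without clipping and return the (x, y) hit there
.stop_hit <- function(p, origin, direction, istop) {
  tr <- trace_ray(p, structure(list(origin = origin, direction = direction,
                                    wavelength = 555), class = "ray"),
                  clip = FALSE, through = istop)
  if (tr$vignetted) return(NULL)
  tr$points[istop, 1:2]
}

#' Pupil-filling ray fan
#'
#' Builds a bundle of rays that samples the stop aperture uniformly over
#' the requested pupil diameter at a given field angle.  The prescriptions
#' keep the stop's physical semi-aperture fixed (3 mm in the packaged
#' tables); 5 or 6 mm pupils are realised by aiming the traced beam so that
#' it fills exactly `pupil_diameter` at the stop.  Each ray is aimed
#' individually (quasi-Newton iteration on its entrance coordinates with a
#' shared finite-difference Jacobian, tolerance 1e-10 mm), so the returned
#' rays pass the stop at the grid points by construction.  Only infinite
#' (collimated) object conjugates are supported.
#'
#' @param p An `eye_prescription` with `object_distance = Inf`.
#' @param grid List with `pattern` (`"hexapolar"` or `"square"`) and
#'   `rings_or_n`: hexapolar ring count r (1 + sum 6k rays, k = 1..r), or
#'   points per side of a square grid clipped to the pupil circle.
#' @param field_angle Field angle in degrees (beam tilt in the y-z plane).
#' @return List of [ray()] objects; the first is the chief ray (stop
#'   centre).
#' @export
pupil_ray_fan <- function(p, grid = list(pattern = "hexapolar",
                                         rings_or_n = 8),
                          field_angle = 0) {
  if (is.finite(p$object_distance))
    stop("pupil_ray_fan supports collimated (infinite) conjugates only",
         call. = FALSE)
  pattern <- match.arg(grid$pattern, c("hexapolar", "square"))
  m <- grid$rings_or_n
  R <- p$pupil_diameter / 2
  if (pattern == "hexapolar") {
    if (is.null(m) || m < 0) stop("empty grid", call. = FALSE)
    gx <- 0; gy <- 0
    if (m >= 1) for (k in seq_len(m)) {
      th <- 2 * pi * seq_len(6 * k) / (6 * k)
      gx <- c(gx, (k / m) * R * cos(th))
      gy <- c(gy, (k / m) * R * sin(th))
    }
  } else {
    if (is.null(m) || m < 1) stop("empty grid", call. = FALSE)
    u <- if (m == 1) 0 else seq(-R, R, length.out = m)
    gg <- expand.grid(x = u, y = u)
    keep <- gg$x^2 + gg$y^2 <= R^2 + 1e-12
    gx <- gg$x[keep]; gy <- gg$y[keep]
    if (!length(gx)) stop("empty grid", call. = FALSE)
  }
  th <- field_angle * pi / 180
  d <- c(0, sin(th), cos(th))
  istop <- stop_index(p)
  z0 <- -1                               # launch plane 1 mm before vertex 1
  vz <- vertex_positions(p)
  zs <- vz[istop]
  # starting guess: entrance offset that would hit the stop in a homogeneous
  # medium, then quasi-Newton with a shared FD Jacobian
  base <- c(-d[1], -d[2]) / d[3] * (zs - z0)
  f <- function(e) .stop_hit(p, c(e[1] + base[1], e[2] + base[2], z0), d, istop)
  h <- 1e-4
  f0 <- f(c(0, 0))
  if (is.null(f0)) stop("chief ray cannot reach the stop", call. = FALSE)
  fx <- f(c(h, 0)); fy <- f(c(0, h))
  if (is.null(fx) || is.null(fy))
    stop("stop aiming failed (Jacobian probe vignetted)", call. = FALSE)
  J <- cbind((fx - f0) / h, (fy - f0) / h)
  Jinv <- solve(J)
  aim <- function(target) {
    e <- as.numeric(Jinv %*% (target - f0))
    for (it in 1:50) {
      hit <- f(e)
      if (is.null(hit))
        stop("stop aiming failed (ray missed a surface)", call. = FALSE)
      err <- target - hit
      if (max(abs(err)) < 1e-10) break
      e <- e + as.numeric(Jinv %*% err)
    }
    c(e[1] + base[1], e[2] + base[2], z0)
  }
  lapply(seq_along(gx), function(i) {
    ray(aim(c(gx[i], gy[i])), d, p$wavelength)
  })
}

#' Trace a bundle of rays to the image surface
#'
#' Convenience wrapper: traces each ray with [trace_ray()] and collects
#' image-plane intersections.
#'
#' @param p An `eye_prescription`.
#' @param rays List of [ray()] objects.
#' @return List with `image_points` (n x 2 matrix, vignetted rays `NA`),
#'   `vignetted` (logical vector), `traces` (list of `trace_result`).
#' @export
trace_rays <- function(p, rays) {
  traces <- lapply(rays, function(r) trace_ray(p, r))
  list(
    image_points = do.call(rbind, lapply(traces, `[[`, "image_point")),
    vignetted = vapply(traces, `[[`, logical(1), "vignetted"),
    traces = traces
  )
}
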