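test_that("rays intersect planes and spheres where geometry says", {
  p <- single_surface_rx(0, n2 = 1.5, image_distance = 10)
  # parallel ray at height 1 onto a plane: hits at height 1, at the vertex z
  tr <- trace_ray(p, ray(c(0, 1, -1), c(0, 0, 1)))
  expect_equal(tr$points[1, ], c(0, 1, 0), tolerance = 1e-12)
  # line-sphere intersection oracle: sphere c = 0.1 (centre at z = 10)
  ps <- single_surface_rx(0.1, n2 = 1.5)
  for (h in c(0.5, 1.5, 3, -2)) {
    tr <- trace_ray(ps, ray(c(0, h, -1), c(0, 0, 1)))
    # quadratic formula for |P - (0,0,10)| = 10 along x=0, y=h
    z_oracle <- 10 - sqrt(100 - h^2)
    expect_equal(tr$points[1, ], c(0, h, z_oracle), tolerance = 1e-10)
  }
  # axial ray hits the vertex of any conic
  pc <- single_surface_rx(0.08, conic = -4, n2 = 1.5, image_distance = 20)
  tr <- trace_ray(pc, ray(c(0, 0, -1), c(0, 0, 1)))
  expect_equal(tr$points[1, ], c(0, 0, 0), tolerance = 1e-12)
  # intersections satisfy the sag equation
  tr <- trace_ray(pc, ray(c(0.4, 1.2, -1), c(0.01, -0.03, 1)))
  r1 <- sqrt(sum(tr$points[1, 1:2]^2))
  expect_equal(tr$points[1, 3], conic_sag(r1, 0.08, -4), tolerance = 1e-10)
})

test_that("vector refraction obeys Snell's law", {
  nrm <- c(0, 0, -1)
  d <- c(0, 0, 1)
  # equal indices and normal incidence leave the ray unchanged
  expect_equal(refract(d, nrm, 1.5, 1.5), d, tolerance = 1e-15)
  expect_equal(refract(d, nrm, 1, 1.7), d, tolerance = 1e-15)
  # 30 degrees from n=1 into n=1.5: sin(theta2) = 1/3
  th1 <- 30 * pi / 180
  d1 <- c(0, sin(th1), cos(th1))
  out <- refract(d1, nrm, 1, 1.5)
  expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-12)
  expect_equal(asin(out[2]) * 180 / pi, 19.4712206, tolerance = 1e-6)
  # Snell's law holds for random geometries, tangential plane preserved
  set.seed(11)
  for (i in 1:50) {
    d <- c(stats::rnorm(2, 0, 0.3), 1); d <- d / sqrt(sum(d^2))
    n <- c(stats::rnorm(2, 0, 0.3), -1); n <- n / sqrt(sum(n^2))
    # into the denser medium, so refraction always exists
    n1 <- stats::runif(1, 1, 1.3); n2 <- stats::runif(1, 1.4, 1.8)
    out <- refract(d, n, n1, n2)
    s1 <- sqrt(sum((d - sum(d * n) * n)^2))
    s2 <- sqrt(sum((out - sum(out * n) * n)^2))
    expect_equal(n1 * s1, n2 * s2, tolerance = 1e-12)
  }
  # total internal reflection is signalled, not silently refracted
  steep <- c(0, sin(80 * pi / 180), cos(80 * pi / 180))
  expect_null(refract(steep, nrm, 1.5, 1.0))
})

test_that("sequential tracing matches paraxial optics and symmetry", {
  # on-axis ray through any centred builtin lands on the axis
  for (nm in c("initial_eye", "codev_6mm", "ga_5mm")) {
    p <- builtin_prescription(nm)
    tr <- trace_ray(p, ray(c(0, 0, -1), c(0, 0, 1)))
    expect_false(tr$vignetted)
    expect_equal(tr$image_point, c(0, 0), tolerance = 1e-9)
  }
  # meridional ray at tiny height crosses the axis at n2 / (c (n2 - n1))
  c0 <- 0.1287; n2 <- 1.336
  f <- n2 / (c0 * (n2 - 1))
  p <- single_surface_rx(c0, n2 = n2, image_distance = f)
  tr <- trace_ray(p, ray(c(0, 0.01, -1), c(0, 0, 1)))
  # crossing distance from the vertex: z where y = 0
  y1 <- tr$points[1, 2]; u <- (tr$points[3, 2] - y1) / (tr$points[3, 3] - tr$points[1, 3])
  z_cross <- tr$points[1, 3] - y1 / u
  expect_equal(z_cross, f, tolerance = f * 1e-3)
  # mirror-symmetric rays land mirror-symmetrically
  p6 <- builtin_prescription("codev_6mm")
  up <- trace_ray(p6, ray(c(0.4, 0.9, -1), c(0, 0.001, 1)))
  dn <- trace_ray(p6, ray(c(0.4, -0.9, -1), c(0, -0.001, 1)))
  expect_equal(up$image_point[1], dn$image_point[1], tolerance = 1e-10)
  expect_equal(up$image_point[2], -dn$image_point[2], tolerance = 1e-10)
})

test_that("pupil fans sample the stop as requested", {
  p <- builtin_prescription("codev_6mm")
  expect_length(pupil_ray_fan(p, list(pattern = "hexapolar", rings_or_n = 0)), 1)
  expect_length(pupil_ray_fan(p, list(pattern = "hexapolar", rings_or_n = 3)), 37)
  expect_length(pupil_ray_fan(p, list(pattern = "hexapolar", rings_or_n = 8)),
                1 + sum(6 * (1:8)))
  expect_error(pupil_ray_fan(p, list(pattern = "hexapolar", rings_or_n = -1)),
               "empty")
  # every fan ray passes the stop within its semi-aperture (+1e-9)
  istop <- stop_index(p)
  for (fld in c(0, 5)) {
    fan <- pupil_ray_fan(p, list(pattern = "hexapolar", rings_or_n = 4),
                         field_angle = fld)
    hits <- t(vapply(fan, function(r) {
      tr <- trace_ray(p, r, clip = FALSE, through = istop)
      tr$points[istop, 1:2]
    }, numeric(2)))
    expect_true(all(sqrt(rowSums(hits^2)) <=
                      p$surfaces[[istop]]$semi_aperture + 1e-9))
  }
  # chief ray goes through the stop centre
  chief <- pupil_ray_fan(p, list(pattern = "hexapolar", rings_or_n = 0),
                         field_angle = 5)[[1]]
  trc <- trace_ray(p, chief, clip = FALSE, through = istop)
  expect_equal(trc$points[istop, 1:2], c(0, 0), tolerance = 1e-9)
})

test_that("real rays agree with the paraxial trace at vanishing aperture", {
  for (nm in builtin_prescription_names()) {
    p <- builtin_prescription(nm)
    pr <- p$pupil_diameter / 2 * 1e-3
    par <- paraxial_trace(p, field_angle_deg = 1e-9, pupil_radius = pr)
    y_par <- abs(par$marginal$y[length(p$surfaces)])
    p2 <- p; p2$pupil_diameter <- 2 * pr
    fan <- pupil_ray_fan(p2, list(pattern = "hexapolar", rings_or_n = 1))
    tr <- trace_rays(p, fan)
    expect_false(any(tr$vignetted))
    rad <- sqrt(rowSums(tr$image_points[-1, ]^2))
    expect_equal(mean(rad), y_par, tolerance = 1e-4, label = nm)
  }
})

test_that("every launched ray is traced or flagged with a surface index", {
  p <- builtin_prescription("ga_6mm")
  fan <- pupil_ray_fan(p, list(pattern = "hexapolar", rings_or_n = 8))
  tr <- trace_rays(p, fan)
  n_done <- sum(!tr$vignetted)
  n_vign <- sum(tr$vignetted)
  expect_identical(n_done + n_vign, length(fan))
  expect_true(n_vign > 0)  # the published IOL apertures clip the 6 mm beam
  for (t in tr$traces[tr$vignetted])
    expect_true(is.finite(t$vignette_surface) && t$vignette_surface >= 1)
  for (t in tr$traces[!tr$vignetted])
    expect_false(any(is.na(t$points)))
})

test_that("tracing backward through the mirrored system recovers the ray", {
  p <- builtin_prescription("codev_6mm")
  ns <- length(p$surfaces)
  Z <- vertex_positions(p)[ns]
  n_back <- p$surfaces[[ns - 1]]$index
  prev <- reverse_rx(p)
  set.seed(4)
  for (i in 1:10) {
    r0 <- ray(c(stats::runif(2, -0.8, 0.8), -1), c(stats::rnorm(2, 0, 0.01), 1))
    tr <- trace_ray(p, r0, clip = FALSE)
    P <- tr$points[ns, ]; dI <- tr$direction
    rrev <- ray(c(P[1], P[2], Z - P[3] - 1e-9), c(-dI[1], -dI[2], dI[3]))
    trr <- trace_ray(prev, rrev, clip = FALSE, n_start = n_back)
    expect_false(trr$vignetted)
    expect_equal(trr$points[ns, 1:2], tr$points[1, 1:2], tolerance = 1e-8)
  }
})
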