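# small optical systems and independent oracles used across tests

# single refracting conic surface with its stop at the surface, a plane at
# the paraxial focus (or a given image distance), and a terminal image
# surface
single_surface_rx <- function(curvature = 0.1, conic = 0, n2 = 1.5,
                              image_distance = NULL, pupil = 2,
                              object_distance = Inf, semi_ap = 5) {
  if (is.null(image_distance))
    image_distance <- n2 / (curvature * (n2 - 1))
  p <- eye_prescription("single", list(
    conic_surface(curvature, conic, image_distance, "glass", n2, semi_ap,
                  stop = TRUE),
    conic_surface(0, 0, 0, "glass", n2, 100),
    conic_surface(0, 0, 0, "glass", n2, 100)
  ), object_distance = object_distance, pupil_diameter = pupil)
  # collapse the dummy pre-image plane onto the image
  p$surfaces[[2]]$thickness <- 0
  p
}

# thin lens in air (two surfaces, tiny central thickness), stop at lens
thin_lens_rx <- function(c1, c2, n = 1.5, thickness = 1e-8,
                         image_distance = 10, pupil = 2) {
  eye_prescription("thinlens", list(
    conic_surface(c1, 0, thickness, "glass", n, 4, stop = TRUE),
    conic_surface(c2, 0, image_distance, "air", 1, 4),
    conic_surface(0, 0, 0, "air", 1, 100)
  ), Inf, pupil_diameter = pupil)
}

# Coddington/shape-factor closed form for the Seidel spherical sum of a
# thin lens in air with the stop at the lens and the object at infinity
# (conjugate factor C = -1 in this sign convention)
coddington_thin_lens_S1 <- function(c1, c2, n = 1.5, y = 1) {
  phi <- (n - 1) * (c1 - c2)
  B <- (c1 + c2) / (c1 - c2)
  C <- -1
  (y^4 * phi^3 / 4) * ((n / (n - 1))^2 +
    (n + 2) / (n * (n - 1)^2) * (B + 2 * (n^2 - 1) / (n + 2) * C)^2 -
    n / (n + 2) * C^2)
}

# mirror a prescription end-for-end (for backward tracing); the returned
# system is traced with n_start = index of the original pre-image medium
reverse_rx <- function(p) {
  ns <- length(p$surfaces)
  idx <- vapply(p$surfaces, `[[`, numeric(1), "index")
  th <- vapply(p$surfaces, `[[`, numeric(1), "thickness")
  cs <- vapply(p$surfaces, `[[`, numeric(1), "curvature")
  Ks <- vapply(p$surfaces, `[[`, numeric(1), "conic")
  sa <- vapply(p$surfaces, `[[`, numeric(1), "semi_aperture")
  med <- vapply(p$surfaces, `[[`, character(1), "medium")
  nbefore <- c(1, idx[-ns])
  surfs <- lapply(ns:1, function(i) conic_surface(
    -cs[i], Ks[i], if (i > 1) th[i - 1] else 0, med[i], nbefore[i],
    sa[i] + 1, stop = (i == ns)))
  eye_prescription("reversed", surfs, Inf, p$pupil_diameter)
}
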