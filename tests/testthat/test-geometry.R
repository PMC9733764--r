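test_that("forward projection matches closed forms and is linear", {
  # zero image -> zero sinogram
  geom <- projection_geometry(32, 8, fov = 32)
  z <- radon_forward(image_grid(32), geom)
  expect_equal(z$values, matrix(0, 8, 32))

  # uniform unit disk: chord length 2*sqrt(R^2 - r^2), same at every angle
  # (up to rasterization of the disk)
  g <- disk_image(64, 20)
  geom <- projection_geometry(64, 12, fov = 64)
  p <- radon_forward(g, geom)
  r <- geom_offsets(geom)
  chord <- ifelse(abs(r) < 20, 2 * sqrt(pmax(20^2 - r^2, 0)), 0)
  expect_lt(max(abs(t(p$values) - chord)) / max(chord), 0.05)
  expect_lt(max(apply(p$values, 2, sd)) / max(chord), 0.03)

  # superposition to float tolerance
  g1 <- random_image(32, 1)
  g2 <- random_image(32, 2)
  gs <- image_grid(32, values = 2 * g1$values - 0.5 * g2$values)
  geom <- projection_geometry(32, 16, fov = 32)
  expect_equal(radon_forward(gs, geom)$values,
               2 * radon_forward(g1, geom)$values -
                 0.5 * radon_forward(g2, geom)$values,
               tolerance = 1e-12)

  # mismatched fov is a configuration error
  expect_error(radon_forward(image_grid(32, fov = 10),
                             projection_geometry(32, 8, fov = 32)),
               "fov")
})

test_that("forward projection agrees with a dense ray-sampling oracle", {
  geom <- projection_geometry(16, 8, fov = 16)
  for (seed in 1:20) {
    img <- random_image(16, seed)
    p <- radon_forward(img, geom)$values
    o <- oracle_radon(img, geom, oversample = 800)
    expect_lt(sqrt(mean((p - o)^2)) / sqrt(mean(o^2)), 1e-3)
  }
})

test_that("partial line integrals tile rays and hit analytic segment chords", {
  g <- disk_image(64, 20)
  geom <- projection_geometry(64, 12, fov = 64)
  p <- radon_forward(g, geom)

  # single window spanning the fov reproduces the sinogram exactly
  st1 <- stage_spec(1, 12, 64, fov = 64)
  q1 <- partial_line_integrals(g, st1)
  expect_equal(q1$values[1, , ] * st1$alpha, p$values, tolerance = 1e-10)

  # windows tile the ray: alpha * sum_t q == p for several stages
  for (nt in c(2, 4, 8)) {
    st <- stage_spec(nt, 12, 64, fov = 64)
    q <- partial_line_integrals(g, st)
    psum <- apply(q$values, c(2, 3), sum) * st$alpha
    expect_lt(max(abs(psum - p$values)) / max(p$values), 1e-3)
  }

  # ray through the disk center, 4 windows: analytic circle-segment clipping
  # (window [t0, t1] contributes the clipped chord length |[t0,t1] ^ [-R,R]|)
  st <- stage_spec(4, 12, 64, fov = 64)
  q <- partial_line_integrals(g, st)
  mid <- 32L   # channel nearest r = -0.5 (offset grid is half-integer)
  r0 <- geom_offsets(geom)[mid]
  half_chord <- sqrt(20^2 - r0^2)
  edges <- -32 + (0:4) * st$alpha
  expected <- vapply(1:4, function(j) {
    lo <- max(edges[j], -half_chord)
    hi <- min(edges[j + 1], half_chord)
    max(hi - lo, 0) / st$alpha
  }, numeric(1))
  expect_equal(q$values[, 1, mid], expected, tolerance = 0.06)

  # invalid window width
  expect_error(partial_line_integrals(g, stage_spec(4, 12, 64, fov = 32)),
               "fov")
})

test_that("FBP reconstructs phantoms and is a linear operator", {
  # zero sinogram -> zero image
  geom <- projection_geometry(32, 16, fov = 32)
  z <- fbp_reconstruct(sinogram(matrix(0, 16, 32), geom), image_grid(32))
  expect_equal(z$values, matrix(0, 32, 32))

  # round trip on the head phantom; regression threshold from the first
  # implementation run (measured 0.133)
  g <- image_grid(128, fov = 128)
  ph <- shepp_logan(g)
  geom <- projection_geometry(128, 180, fov = 128)
  rec <- fbp_reconstruct(radon_forward(ph, geom), g)
  expect_lt(rmse(ph, rec), 0.2)

  # linearity to float tolerance
  geom <- projection_geometry(32, 24, fov = 32)
  s1 <- matrix(rnorm(24 * 32), 24, 32)
  s2 <- matrix(rnorm(24 * 32), 24, 32)
  f1 <- fbp_reconstruct(sinogram(s1, geom), image_grid(32))$values
  f2 <- fbp_reconstruct(sinogram(s2, geom), image_grid(32))$values
  f12 <- fbp_reconstruct(sinogram(3 * s1 - 2 * s2, geom),
                         image_grid(32))$values
  expect_equal(f12, 3 * f1 - 2 * f2, tolerance = 1e-10)
})

test_that("reconstruction error shrinks with angular sampling", {
  g <- disk_image(64, 20)
  err <- vapply(c(90, 360), function(na) {
    geom <- projection_geometry(64, na, fov = 64)
    rmse(g, fbp_reconstruct(radon_forward(g, geom), image_grid(64)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("anisotropic-grid FBP matches its marginal case and rotates", {
  g <- disk_image(64, 20)
  geom <- projection_geometry(64, 90, fov = 64)
  sino <- radon_forward(g, geom)

  # pixel-sized depth bins at angle zero = the isotropic reconstruction
  stf <- stage_spec(64, 1, 64, fov = 64)
  expect_equal(fbp_anisotropic(sino, stf, 1),
               fbp_reconstruct(sino, image_grid(64))$values)

  # angle index bounds
  expect_error(fbp_anisotropic(sino, stf, 2), "out of range")

  # reconstructing the original phantom at stage angle theta_k equals
  # reconstructing the phantom rotated by -theta_k at angle zero
  st <- stage_spec(16, 4, 64, fov = 64)
  th2 <- stage_angles(st)[2]
  pars <- data.frame(intensity = c(1, 0.5), a = c(0.5, 0.2), b = c(0.3, 0.2),
                     x0 = c(0.1, -0.3), y0 = c(-0.2, 0.25), phi = c(20, 0))
  rot <- pars
  ang <- atan2(pars$y0, pars$x0) - th2
  rho <- sqrt(pars$x0^2 + pars$y0^2)
  rot$x0 <- rho * cos(ang)
  rot$y0 <- rho * sin(ang)
  rot$phi <- pars$phi - th2 * 180 / pi
  grid <- image_grid(64, fov = 64)
  geom64 <- projection_geometry(64, 64, fov = 64)
  s1 <- radon_forward(rasterize_phantom(ellipse_phantom(pars, 64), grid, 2L),
                      geom64)
  s2 <- radon_forward(rasterize_phantom(ellipse_phantom(rot, 64), grid, 2L),
                      geom64)
  lab_a <- fbp_anisotropic(s1, st, 2)
  lab_b <- fbp_anisotropic(s2, st, 1)
  expect_lt(sqrt(mean((lab_a - lab_b)^2)) / sd(lab_a), 0.02)
})

test_that("containers validate their invariants", {
  expect_error(image_grid(8, 16), "square")
  expect_error(sinogram(matrix(0, 3, 3), projection_geometry(4, 3)),
               "n_angles x n_channels")
  expect_error(sinogram(matrix(c(NA, rep(0, 11)), 3, 4),
                        projection_geometry(4, 3)), "finite")
  st <- stage_spec(4, 6, 8, fov = 8)
  expect_error(partial_stack(array(0, c(4, 6, 7)), st), "dim")
  ps <- partial_stack(array(0, c(4, 6, 8)), st)
  expect_equal(ps$alpha, 2)
  expect_equal(ps$t, c(-3, -1, 1, 3))
})
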