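test_that("tooth-line fitting matches the orthogonal-regression oracle", {
  # collinear and two-point cases are exact
  fit <- fit_tooth_line(cbind(c(0, 5, 10), c(2, 2, 2)))
  expect_equal(fit$direction, c(1, 0), tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-12)
  fit2 <- fit_tooth_line(cbind(c(0, 10), c(0, 0)))
  expect_equal(abs(fit2$direction), c(1, 0), tolerance = 1e-12)

  # TLS residuals against an independent eigen/SVD oracle
  set.seed(99)
  for (i in 1:10) {
    pts <- cbind(sort(runif(6, 0, 10)), rnorm(6, 3, 0.4))
    fit <- fit_tooth_line(pts)
    cen <- sweep(pts, 2, colMeans(pts))
    sv <- svd(cen)
    oracle_rms <- sv$d[2] / sqrt(nrow(pts)) # smallest singular value
    expect_equal(fit$rms_residual, oracle_rms, tolerance = 1e-9)
  }

  expect_error(fit_tooth_line(cbind(c(1, 1, 1), c(2, 2, 2))),
               class = "geometry_error")
})

test_that("optimum gape reproduces hand trigonometry and degenerate cases", {
  # constructed to mirror a basal metriorhynchine: h = 7.04, d = 36.21, L = 88
  g <- optimum_gape(toy_landmarks(),
                    measurements = data.frame(specimen_id = "S1",
                                              mandible_length_cm = 88))
  expect_equal(g$prey_depth_cm, 7.04, tolerance = 1e-9)
  expect_equal(g$gape_angle_deg, atan(7.04 / 36.21) * 180 / pi, tolerance = 1e-9)
  expect_equal(round(g$gape_angle_deg), 11)
  expect_equal(round(g$prey_depth_fraction, 2), 0.08)

  # glenoid on the tooth line: zero angle and depth
  lm0 <- toy_landmarks()
  lm0$y[lm0$label == "glenoid"] <- 7.04
  g0 <- optimum_gape(lm0, measurements = data.frame(specimen_id = "S1",
                                                    mandible_length_cm = 88))
  expect_equal(g0$gape_angle_deg, 0, tolerance = 1e-9)
  expect_equal(g0$prey_depth_cm, 0, tolerance = 1e-9)

  # glenoid anterior to the posterior-most tooth along the line: d <= 0
  lmr <- toy_landmarks()
  lmr$x[lmr$label == "glenoid"] <- 200
  expect_error(optimum_gape(lmr, measurements = data.frame(
    specimen_id = "S1", mandible_length_cm = 88)), class = "geometry_error")

  # no mandible length available anywhere
  expect_error(optimum_gape(toy_landmarks()), class = "validation_error")
})

test_that("noiseless generator round-trips angle and fraction exactly", {
  for (ang in c(5, 11, 24)) {
    sim <- sim_mandible(true_gape_angle_deg = ang,
                        posterior_tooth_offset_fraction = 0.45,
                        mandible_length_cm = 132.2,
                        landmark_noise_sd = 0, seed = 1)
    g <- optimum_gape(sim$landmarks,
                      measurements = data.frame(specimen_id = "sim",
                                                mandible_length_cm = 132.2))
    expect_equal(g$gape_angle_deg, ang, tolerance = 1e-9)
    expect_equal(g$prey_depth_fraction, 0.45 * tan(ang * pi / 180),
                 tolerance = 1e-9)
  }
  # mandible length can also come from the landmark chord
  sim <- sim_mandible(true_gape_angle_deg = 24, landmark_noise_sd = 0, seed = 1)
  g <- optimum_gape(sim$landmarks)
  expect_equal(g$mandible_length_cm, 132.2, tolerance = 1e-9)
})

test_that("gape metrics are invariant to rigid motion and equivariant to scale", {
  sim <- sim_mandible(true_gape_angle_deg = 19, landmark_noise_sd = 0.003,
                      seed = 21)
  meas <- data.frame(specimen_id = "sim", mandible_length_cm = 132.2)
  g0 <- optimum_gape(sim$landmarks, measurements = meas)
  # rigid motions leave everything unchanged
  for (tr in list(c(33, -4, 7), c(-120, 5, -2), c(178, 0.3, 0.1))) {
    lm2 <- transform_landmarks(sim$landmarks, tr[1], tr[2], tr[3])
    g2 <- optimum_gape(lm2, measurements = meas)
    expect_equal(g2$gape_angle_deg, g0$gape_angle_deg, tolerance = 1e-9)
    expect_equal(g2$prey_depth_cm, g0$prey_depth_cm, tolerance = 1e-9)
    expect_equal(g2$prey_depth_fraction, g0$prey_depth_fraction, tolerance = 1e-9)
  }
  # scaling by c scales the depth, not the angle or fraction
  c_ <- 3.7
  lm3 <- transform_landmarks(sim$landmarks, scale = c_)
  g3 <- optimum_gape(lm3, measurements = data.frame(
    specimen_id = "sim", mandible_length_cm = 132.2 * c_))
  expect_equal(g3$gape_angle_deg, g0$gape_angle_deg, tolerance = 1e-9)
  expect_equal(g3$prey_depth_fraction, g0$prey_depth_fraction, tolerance = 1e-9)
  expect_equal(g3$prey_depth_cm, g0$prey_depth_cm * c_, tolerance = 1e-9)
})

test_that("gape angle is strictly increasing in prey depth at fixed d", {
  angles <- vapply(seq(1, 20, by = 2), function(h) {
    lm <- toy_landmarks()
    lm$y[2:3] <- h
    optimum_gape(lm, measurements = data.frame(
      specimen_id = "S1", mandible_length_cm = 88))$gape_angle_deg
  }, 0)
  expect_true(all(diff(angles) > 0))
})

test_that("prey depth standardization matches published arithmetic", {
  expect_equal(prey_depth_at_length(0.21, 60), 12.6)
  expect_equal(prey_depth_at_length(0.15, 87.5), 13.125) # reported half-up as 13.13
  expect_equal(prey_depth_at_length(0, 55), 0)
  expect_error(prey_depth_at_length(-0.1, 60), class = "domain_error")
  expect_error(prey_depth_at_length(0.2, -1), class = "domain_error")
})

test_that("mandible generator is deterministic under its seed", {
  a <- sim_mandible(seed = 5, landmark_noise_sd = 0.01)
  b <- sim_mandible(seed = 5, landmark_noise_sd = 0.01)
  c_ <- sim_mandible(seed = 6, landmark_noise_sd = 0.01)
  expect_identical(a$landmarks, b$landmarks)
  expect_false(identical(a$landmarks$x, c_$landmarks$x))
})
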