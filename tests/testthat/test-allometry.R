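test_that("basicranial estimation reproduces the reference-ratio arithmetic", {
  ref <- allometric_reference()
  expect_equal(ref$ratio, 76.8 / 80.9, tolerance = 1e-12)
  # identity on the reference specimen
  expect_equal(estimate_basicranial(80.9, ref), 76.8, tolerance = 1e-9)
  # the two published large-mandible estimates at printed precision
  expect_equal(round(estimate_basicranial(87.5, ref), 1), 83.1)
  expect_equal(round(estimate_basicranial(132.2, ref), 1), 125.5)
  # linear homogeneity: f(c m) = c f(m)
  for (c_ in c(0.5, 2, 13.7)) {
    expect_equal(estimate_basicranial(c_ * 87.5, ref),
                 c_ * estimate_basicranial(87.5, ref), tolerance = 1e-12)
  }
  expect_error(estimate_basicranial(-5), class = "domain_error")
})

test_that("body-length model calibrates exactly through two anchors", {
  m <- calibrate_body_length_model(
    data.frame(basicranial_cm = c(100, 125.5), total_length_cm = c(542, 683)))
  expect_equal(m$slope, 141 / 25.5, tolerance = 1e-9)
  expect_equal(m$max_residual_cm, 0, tolerance = 1e-9)
  expect_equal(predict_total_length(m, 100)$total_length_m, 5.42, tolerance = 1e-9)

  m2 <- calibrate_body_length_model(
    data.frame(basicranial_cm = c(0, 1), total_length_cm = c(0, 1)))
  expect_equal(m2$slope, 1, tolerance = 1e-12)
  expect_equal(m2$intercept, 0, tolerance = 1e-12)

  expect_error(calibrate_body_length_model(
    data.frame(basicranial_cm = c(100, 100), total_length_cm = c(542, 683))),
    class = "singular_fit_error")
})

test_that("the three published anchors are collinear to under a centimetre", {
  m <- calibrate_body_length_model(body_length_anchors())
  expect_lt(m$max_residual_cm, 1.0)
})

test_that("leave-one-out on published anchors predicts within 0.02 m", {
  anchors <- body_length_anchors()
  for (i in seq_len(nrow(anchors))) {
    m <- calibrate_body_length_model(anchors[-i, ])
    pred <- predict_total_length(m, anchors$basicranial_cm[i])$total_length_m
    expect_lt(abs(pred - anchors$total_length_cm[i] / 100), 0.02)
  }
  # the headline cross-prediction at printed precision
  m <- calibrate_body_length_model(anchors[2:3, ])
  expect_equal(round(predict_total_length(m, 83.1)$total_length_m, 2), 4.49)
})

test_that("prediction is invariant to anchor ordering and flags extrapolation", {
  anchors <- body_length_anchors()
  m1 <- calibrate_body_length_model(anchors)
  m2 <- calibrate_body_length_model(anchors[c(3, 1, 2), ])
  xs <- c(70, 90, 110, 140)
  expect_equal(predict_total_length(m1, xs)$total_length_m,
               predict_total_length(m2, xs)$total_length_m, tolerance = 1e-12)
  p <- predict_total_length(m1, c(70, 100, 140))
  expect_identical(p$extrapolated, c(TRUE, FALSE, TRUE))
})

test_that("tidy and glance expose the model in broom style", {
  m <- calibrate_body_length_model(body_length_anchors())
  td <- tidy(m)
  expect_identical(td$term, c("intercept", "slope"))
  gl <- glance(m)
  expect_equal(gl$n_anchors, 3)
  expect_gt(gl$slope, 0)
})
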