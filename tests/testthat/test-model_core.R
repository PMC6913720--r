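# Piecewise walking-power model: regressors, branches, coefficient algebra.

test_that("kinetic power matches hand arithmetic and is linear/quadratic as built", {
  expect_equal(kinetic_power(70, 0, 1.0), 0)
  expect_equal(kinetic_power(70, 1.5, 1.0), 2 * 70 * 1.5^2 * 1.0)  # 315 W
  # linear in frequency and mass, quadratic in speed
  expect_equal(kinetic_power(70, 1.5, 2.0), 2 * kinetic_power(70, 1.5, 1.0))
  expect_equal(kinetic_power(140, 1.5, 1.0), 2 * kinetic_power(70, 1.5, 1.0))
  expect_equal(kinetic_power(70, 3.0, 1.0), 4 * kinetic_power(70, 1.5, 1.0))
  expect_error(kinetic_power(70, -1, 1), "nonnegative")
})

test_that("potential power matches hand arithmetic and is antisymmetric in the gradient", {
  expect_equal(potential_power(70, 1.5, 0), 0)
  expect_equal(potential_power(70, 1.5, 4),
               70 * 9.80665 * 1.5 * sin(4 * pi / 180))  # ~71.83 W
  for (th in c(2, 7.5, 14, 30))
    expect_equal(potential_power(80, 1.2, -th), -potential_power(80, 1.2, th))
  expect_error(potential_power(0, 1.5, 4), "positive")
  expect_error(potential_power(70, 1.5, 95), "<= 90")
})

test_that("model prediction reproduces hand-evaluated branch values", {
  cw <- reference_coefficients("female")
  s <- subject("female", 57, 1.61, 43.6)
  # degenerate input isolates the constant offset
  expect_equal(predict_net_power(cw, s, walk_condition(0, 0, 0)), cw$p0)
  # flat branch, independent hand evaluation
  pk <- 2 * 57 * 1.4^2 * 1.0857 / 4184
  expect_equal(predict_net_power(cw, s, walk_condition(1.4, 0, 1.0857)),
               0.662 * pk + 0.042, tolerance = 1e-12)
  # downhill branch including the quadratic term
  pu <- 57 * 9.80665 * 1.4 * sin(-9 * pi / 180) / 4184
  expect_equal(predict_net_power(cw, s, walk_condition(1.4, -9, 1.0857)),
               0.662 * pk + 1.591 * pu + 0.575 * pu^2 / 0.042 + 0.042,
               tolerance = 1e-12)
  expect_equal(round(predict_net_power(cw, s, walk_condition(1.4, 0, 1.0857)), 4), 0.0804)
  expect_equal(round(predict_net_power(cw, s, walk_condition(1.4, -9, 1.0857)), 4), 0.0456)
})

test_that("branches are continuous at zero gradient and uphill power increases with gradient", {
  for (sex in c("female", "male")) {
    cf <- reference_coefficients(sex)
    s <- subject(sex, 68, 1.68, 40)
    pk <- kinetic_power(68, 1.4, 1.05) / 4184
    up <- gaitpower:::model_predict(cf, pk, 0, 0)
    dn <- cf$gamma * pk + cf$b0 * 0 + cf$b1 * 0 / cf$p0 + cf$p0
    expect_lt(abs(up - dn), 1e-12)
    # strictly increasing on theta >= 0
    theta <- seq(0, 14, by = 0.5)
    p <- vapply(theta, function(th)
      predict_net_power(cf, s, walk_condition(1.4, th, 1.05)), numeric(1))
    expect_true(all(diff(p) > 0))
  }
})

test_that("downhill power has an interior minimum on the calibrated gradient range", {
  # minimum at b0 + 2 b1 P_U / P0 = 0; location scales with 1/(M v)
  for (sex in c("female", "male")) {
    cf <- reference_coefficients(sex)
    mass <- if (sex == "female") 61 else 74
    s <- subject(sex, mass, 1.7, 40)
    theta <- seq(-14, 0, by = 0.05)
    p <- vapply(theta, function(th)
      predict_net_power(cf, s, walk_condition(2.0, th, 1.2)), numeric(1))
    i <- which.min(p)
    expect_gt(i, 1)            # not at -14
    expect_lt(i, length(theta)) # not at 0
    pu_star <- -cf$b0 * cf$p0 / (2 * cf$b1)
    th_star <- asin(pu_star * 4184 / (mass * 9.80665 * 2.0)) * 180 / pi
    expect_equal(theta[i], th_star, tolerance = 0.1)
  }
})

test_that("predictions are invariant to the internal power unit", {
  # assemble the model in watts and convert at the end; must agree to 1e-12
  cf <- reference_coefficients("male")
  s <- subject("male", 80, 1.80, 35)
  for (th in c(-12, -4, 0, 4, 12)) {
    pk_w <- kinetic_power(80, 1.6, 1.1)
    pu_w <- potential_power(80, 1.6, th)
    p0_w <- cf$p0 * 4184
    p_w <- cf$gamma * pk_w + cf$b0 * pu_w + cf$p0 * 4184 +
      (if (th < 0) cf$b1 * pu_w^2 / p0_w else 0)
    expect_equal(predict_net_power(cf, s, walk_condition(1.6, th, 1.1)),
                 p_w / 4184, tolerance = 1e-12)
  }
})

test_that("kcal/min convenience scale is exactly 60x the kcal/s rate", {
  s <- subject("female", 57, 1.61, 43.6)
  cond <- walk_condition(1.4, 4, 1.05)
  for (sex in c("female", "male")) {
    cf <- reference_coefficients(sex)
    expect_equal(predict_net_kcal_min(cf, s, cond),
                 60 * predict_net_power(cf, s, cond))
  }
  expect_equal(predict_net_kcal_min(reference_coefficients("female"),
                                    s, walk_condition(0, 0, 0)), 2.52)
  expect_equal(predict_net_kcal_min(reference_coefficients("male"),
                                    s, walk_condition(0, 0, 0)), 3.48)
})

test_that("leg-speed ratio beta follows from the coefficient decomposition", {
  # men's published coefficients reproduce the printed ratio 1.36
  expect_equal(round(beta_from_coefficients(0.517, 0.165, 1.694), 2), 1.36)
  # algebraic round trip: gamma = alpha beta^2 b0
  for (g in c(0.3, 0.517, 0.662, 1.1)) {
    b <- beta_from_coefficients(g, 0.185, 1.591)
    expect_equal(0.185 * b^2 * 1.591, g, tolerance = 1e-12)
  }
  # the women's decomposition evaluates near 1.50 from the fitted inputs
  expect_equal(beta_from_coefficients(0.662, 0.185, 1.591), 1.4997,
               tolerance = 1e-4)
  expect_error(beta_from_coefficients(-1, 0.165, 1.7), "positive")
})

test_that("constructors validate their invariants", {
  expect_error(subject("female", -5, 1.6, 30), "positive")
  expect_error(subject("female", 60, 2.6, 30), "height")
  expect_error(walk_condition(-1, 0, 1), "nonnegative")
  expect_warning(walk_condition(1.4, 20, 1), "calibrated range")
  expect_error(coefficient_set(0.5, 1.5, 0.5, 0), "p0")
  expect_warning(coefficient_set(-0.5, 1.5, 0.5, 0.04), "negative")
  expect_error(gaitpower:::model_predict(
    structure(list(gamma = 1, b0 = 1, b1 = 1, p0 = 0),
              class = "gp_coefficients"), 0.1, -0.1, -5), "p0")
})

test_that("coefficient files round-trip and reject missing keys", {
  f <- tempfile(fileext = ".yml")
  cf <- reference_coefficients("male")
  write_coefficients(cf, f)
  back <- read_coefficients(f)
  expect_equal(back$gamma, cf$gamma)
  expect_equal(back$b0, cf$b0)
  expect_equal(back$b1, cf$b1)
  expect_equal(back$p0, cf$p0)
  expect_equal(back$sex, "male")
  writeLines(c("gamma: 0.5", "b0: 1.6", "sex: male"), f)
  expect_error(read_coefficients(f), "missing key")
})
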