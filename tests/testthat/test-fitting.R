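# Two-stage calibration and metrics.

make_exact_trials <- function(n, coeffs, sex = "female", seed = 1) {
  simulate_model_trials(n, coeffs, sex, seed = seed, noise_sd_kcal_s = 0)
}

test_that("stage 1 recovers exact coefficients from noiseless uphill data", {
  cf <- reference_coefficients("female")
  tr <- make_exact_trials(60, cf)
  s1 <- stage1_fit(tr)
  expect_equal(s1$gamma, cf$gamma, tolerance = 1e-10)
  expect_equal(s1$b0, cf$b0, tolerance = 1e-10)
  expect_equal(s1$p0, cf$p0, tolerance = 1e-10)
  expect_equal(s1$adj_r2, 1, tolerance = 1e-8)
})

test_that("stage 1 equals the normal-equations oracle on small noisy designs", {
  set.seed(31)
  for (k in 1:10) {
    tr <- simulate_model_trials(20, reference_coefficients("male"), "male",
                                seed = 300 + k)
    d <- tr[tr$incline_deg >= 0, ]
    s1 <- stage1_fit(tr)
    ref <- oracle_ols(cbind(1, d$p_k_kcal_s, d$p_u_kcal_s),
                      d$p_measured_kcal_s)
    expect_equal(c(s1$p0, s1$gamma, s1$b0), ref, tolerance = 1e-8)
  }
})

test_that("stage 1 recovers generating coefficients within 5% under calibration noise", {
  cf <- reference_coefficients("male")
  tr <- simulate_model_trials(1000, cf, "male", seed = 77,
                              noise_sd_kcal_s = 0.016)
  s1 <- stage1_fit(tr)
  expect_lt(abs(s1$gamma / cf$gamma - 1), 0.05)
  expect_lt(abs(s1$b0 / cf$b0 - 1), 0.05)
  expect_lt(abs(s1$p0 / cf$p0 - 1), 0.05)
})

test_that("stage 1 rejects undersized or rank-deficient designs", {
  tr <- make_exact_trials(50, reference_coefficients("female"))
  expect_error(stage1_fit(tr[tr$incline_deg >= 0, ][1:2, ]), "at least 3")
  d <- tr[tr$incline_deg >= 0, ][1:10, ]
  d$p_u_kcal_s <- 2 * d$p_k_kcal_s  # collinear regressors
  expect_error(stage1_fit(d), "rank-deficient")
})

test_that("stage 2 closed form matches hand values, the grid oracle, and exact recovery", {
  # single downhill record: b1 is the one-point ratio r/u
  one <- data.frame(incline_deg = -9, p_u_kcal_s = NA, p_k_kcal_s = 0,
                    p_measured_kcal_s = NA)
  p0 <- 0.05
  one$p_u_kcal_s <- -sqrt(0.02 * p0)   # so u = pu^2/p0 = 0.02
  one$p_measured_kcal_s <- 0 + 1.0 * one$p_u_kcal_s + p0 + 0.01
  expect_equal(stage2_fit(one, gamma = 0, b0 = 1.0, p0 = p0), 0.5)
  # noiseless exact recovery
  cf <- reference_coefficients("male")
  tr <- make_exact_trials(200, cf, "male", seed = 4)
  expect_equal(stage2_fit(tr, cf$gamma, cf$b0, cf$p0), cf$b1,
               tolerance = 1e-10)
  # grid-search oracle agreement on noisy data
  tr <- simulate_model_trials(200, cf, "male", seed = 5)
  d <- tr[tr$incline_deg <= 0, ]
  u <- d$p_u_kcal_s^2 / cf$p0
  r <- d$p_measured_kcal_s - cf$gamma * d$p_k_kcal_s -
    cf$b0 * d$p_u_kcal_s - cf$p0
  expect_equal(stage2_fit(tr, cf$gamma, cf$b0, cf$p0),
               oracle_grid_b1(r, u), tolerance = 1e-4)
})

test_that("stage 2 ignores flat records and rejects all-flat input", {
  cf <- reference_coefficients("female")
  tr <- simulate_model_trials(300, cf, "female", seed = 6)
  with_flat <- stage2_fit(tr, cf$gamma, cf$b0, cf$p0)
  no_flat <- stage2_fit(tr[tr$incline_deg != 0, ], cf$gamma, cf$b0, cf$p0)
  expect_equal(with_flat, no_flat, tolerance = 1e-12)
  flat_only <- tr[tr$incline_deg == 0, ]
  expect_error(stage2_fit(flat_only, cf$gamma, cf$b0, cf$p0), "downhill")
  expect_error(stage2_fit(tr, cf$gamma, cf$b0, 0), "p0 > 0")
})

test_that("per-sex fitting recovers each generating coefficient set", {
  trials <- rbind(
    simulate_model_trials(800, reference_coefficients("female"), "female",
                          seed = 21)[, -1],
    simulate_model_trials(800, reference_coefficients("male"), "male",
                          seed = 22)[, -1])
  fits <- fit_by_gender(trials)
  expect_setequal(names(fits), c("female", "male"))
  for (sx in names(fits)) {
    truth <- ref_vals(sx)
    got <- fits[[sx]]$coeffs
    expect_lt(abs(got$gamma / truth[["gamma"]] - 1), 0.10)
    expect_lt(abs(got$b0 / truth[["b0"]] - 1), 0.10)
    expect_lt(abs(got$p0 / truth[["p0"]] - 1), 0.15)
    expect_lt(abs(got$b1 / truth[["b1"]] - 1), 0.25)
    expect_lt(abs(fits[[sx]]$rmsd_kcal_s / 0.016 - 1), 0.15)
    expect_gt(fits[[sx]]$adj_r2_stage1, 0.8)
  }
  expect_warning(fit_by_gender(trials[trials$sex == "female", ]),
                 "no trials for male")
  expect_error(fit_by_gender(trials[0, ]), "empty")
})

test_that("mean recovered coefficients over replicates are unbiased within 5%", {
  # 20 seeded replicates of a 1,000-trial study per sex; the replicate
  # means isolate estimator bias from single-study sampling noise
  for (sx in c("female", "male")) {
    cf <- reference_coefficients(sx)
    rec <- sapply(1:20, function(k) {
      tr <- simulate_model_trials(1000, cf, sx, seed = 500 + k)
      s1 <- stage1_fit(tr)
      c(s1$gamma, s1$b0, s1$p0, stage2_fit(tr, s1$gamma, s1$b0, s1$p0))
    })
    m <- rowMeans(rec)
    truth <- c(cf$gamma, cf$b0, cf$p0, cf$b1)
    expect_true(all(abs(m / truth - 1) < 0.05))
  }
})

test_that("rmsd and percent error match their definitions", {
  expect_equal(rmsd(1:5, 1:5), 0)
  expect_equal(rmsd(c(1, 2) + 0.3, c(1, 2)), 0.3, tolerance = 1e-12)
  expect_equal(rmsd(c(0.01, -0.01), c(0, 0)), 0.01, tolerance = 1e-12)
  expect_error(rmsd(1:3, 1:4), "equal length")
  expect_equal(percent_error(1.12, 1.0), 12)
  expect_equal(percent_error(2.5, 2.5), 0)
  expect_error(percent_error(1, 0), "zero reference")
  # median of an error distribution matches a direct sort-based median
  set.seed(8)
  pred <- runif(101, 0.5, 1.5); ref <- runif(101, 0.8, 1.2)
  pe <- percent_error(pred, ref)
  expect_equal(median(pe), sort(pe)[51])
})

test_that("cadence regression recovers the generating line", {
  v <- seq(0.8, 2.0, length.out = 50)
  h <- rep(1.7, 50)
  exact <- data.frame(speed_mps = v, height_m = h,
                      step_freq_hz = (0.52 * v + 1.02) / h)
  fit <- cadence_regression(exact)
  expect_equal(fit$slope, 0.52, tolerance = 1e-10)
  expect_equal(fit$intercept, 1.02, tolerance = 1e-10)
  noisy <- sample_cadence_records(500, seed = 12)
  fit2 <- cadence_regression(noisy)
  expect_equal(fit2$slope, 0.52, tolerance = 0.05 / 0.52)
  expect_error(cadence_regression(exact[c(1, 1), ]), "distinct speeds")
})

test_that("adjusted R^2 matches the textbook two-pass computation", {
  set.seed(9)
  y <- rnorm(40); yhat <- y + rnorm(40, 0, 0.3)
  expect_equal(adjusted_r2(y, yhat, 2), oracle_adj_r2(y, yhat, 2),
               tolerance = 1e-12)
  expect_equal(adjusted_r2(y, y, 2), 1)
  expect_lte(adjusted_r2(y, rep(mean(y), 40), 2), 0)
  expect_error(adjusted_r2(y[1:3], y[1:3], 2), "requires n")
})

test_that("trials CSV reader computes the power regressors internally", {
  tr <- simulate_model_trials(20, reference_coefficients("female"),
                              "female", seed = 14)
  f <- tempfile(fileext = ".csv")
  data.table::fwrite(tr[, c("subject_id", "sex", "mass_kg", "height_m",
                            "speed_mps", "incline_deg", "step_freq_hz",
                            "p_measured_kcal_s")], f)
  back <- read_trials(f)
  expect_equal(back$p_k_kcal_s, tr$p_k_kcal_s, tolerance = 1e-9)
  expect_equal(back$p_u_kcal_s, tr$p_u_kcal_s, tolerance = 1e-9)
  expect_true(all(sign(back$p_u_kcal_s) == sign(back$incline_deg)))
  data.table::fwrite(tr[, 1:4], f)
  expect_error(read_trials(f), "missing column")
})
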