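# Bioanalytical QC: calibration fitting and back-calculation, QC accuracy and
# precision arithmetic, acceptance rules and matrix effect / recovery.

test_that("calibration recovers an exact line under all weightings", {
  x <- c(6, 12, 18.75, 25, 37.5, 50, 75, 100, 150, 200)
  std <- data.frame(nominal = x, response = 0.0116 * x + 0.1429)
  for (w in c("1/x^2", "1/x", "none")) {
    fit <- fit_calibration(std, weighting = w)
    expect_equal(fit$slope, 0.0116, tolerance = 1e-12)
    expect_equal(fit$intercept, 0.1429, tolerance = 1e-12)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
  }
  # duplicating a standard leaves an exact fit unchanged
  fit2 <- fit_calibration(rbind(std, std[3, ]))
  expect_equal(fit2$slope, 0.0116, tolerance = 1e-12)
  expect_error(fit_calibration(data.frame(nominal = c(5, 5),
                                          response = c(1, 2))), "distinct")
  expect_error(fit_calibration(data.frame(nominal = c(5, 10),
                                          response = c(1, 1))), "degenerate")
})

test_that("1/x^2 weighting follows the low end under heteroscedastic error", {
  # proportional noise: the weighted fit must track the low standards better
  set.seed(12)
  x <- c(6, 12, 18.75, 25, 37.5, 50, 75, 100, 150, 200)
  y <- (0.0116 * x + 0.1429) * (1 + rnorm(length(x), 0, 0.06))
  fw <- fit_calibration(data.frame(nominal = x, response = y), "1/x^2")
  fn <- fit_calibration(data.frame(nominal = x, response = y), "none")
  err_low <- function(fit) abs(back_calculate(fit, 0.0116 * 6 + 0.1429) - 6)
  expect_lt(err_low(fw), err_low(fn))
})

test_that("back-calculation inverts the curve and matches the worked value", {
  curve <- calibration_curve(0.0116, 0.1429)
  conc <- c(6, 20, 80, 140, 200)
  expect_equal(back_calculate(curve, predict(curve, conc)), conc,
               tolerance = 1e-12)
  expect_equal(back_calculate(curve, 1.303), 100.0, tolerance = 1e-3)
  expect_warning(back_calculate(curve, 0), "below zero")
  expect_error(back_calculate(calibration_curve(0, 1), 2), "zero")
})

test_that("QC accuracy and RSD match hand arithmetic", {
  # single-day batch: accuracy 100*77/80 = 96.25%, RSD 100*4/127 = 3.15%
  batch <- data.frame(day = 1, conc = c(77, 77, 77))
  qc <- qc_statistics(batch, nominal = 80)
  expect_equal(qc$inter$accuracy, 96.25, tolerance = 1e-12)
  expect_equal(100 * 4 / 127, 3.15, tolerance = 1e-2)
  # constructed three-day batch with known components
  b3 <- data.frame(day = rep(1:3, each = 2),
                   conc = c(98, 102, 103, 107, 93, 97))
  q3 <- qc_statistics(b3, nominal = 100)
  expect_equal(q3$inter$mean, 100)
  expect_equal(q3$inter$accuracy, 100)
  expect_equal(q3$inter$sd, sd(b3$conc), tolerance = 1e-12)
  # pooled within-day SD: each day has SD sqrt(8) -> pooled sqrt(8)
  expect_equal(q3$intra$sd, sqrt(8), tolerance = 1e-12)
  expect_equal(q3$intra$mean, mean(c(100, 105, 95)))
  # the ANOVA estimator agrees on the within-day component here
  qa <- qc_statistics(b3, nominal = 100, method = "anova")
  expect_equal(qa$intra$sd, sqrt(8), tolerance = 1e-12)
  expect_gte(qa$inter$sd, qa$intra$sd)
})

test_that("qc statistics are scale-equivariant", {
  b <- data.frame(day = rep(1:3, each = 4),
                  conc = c(19, 21, 20, 22, 18, 20, 21, 19, 20, 23, 19, 20))
  q1 <- qc_statistics(b, nominal = 20)
  b2 <- b; b2$conc <- b2$conc * 7
  q2 <- qc_statistics(b2, nominal = 140)
  expect_equal(q1$inter$accuracy, q2$inter$accuracy, tolerance = 1e-12)
  expect_equal(q1$inter$rsd, q2$inter$rsd, tolerance = 1e-12)
  expect_equal(q1$intra$rsd, q2$intra$rsd, tolerance = 1e-12)
})

test_that("LLOQ, carryover and selectivity rules enforce their boundaries", {
  ok <- lloq_check(list(accuracy = 100, rsd = 10), snr = 15)
  expect_true(ok$pass)
  # accuracy window is inclusive, RSD and S/N limits behave as documented
  expect_true(lloq_check(list(accuracy = 80, rsd = 19.99), snr = 10)$pass)
  expect_false(lloq_check(list(accuracy = 79.9, rsd = 10), snr = 15)$pass)
  expect_false(lloq_check(list(accuracy = 100, rsd = 20), snr = 15)$pass)
  bad <- lloq_check(list(accuracy = 130, rsd = 25), snr = 5)
  expect_false(bad$pass)
  expect_length(bad$reasons, 3)
  # carryover < 20% of LLOQ, selectivity < 2%
  expect_true(carryover_selectivity_check(19, 100, "carryover")$pass)
  expect_false(carryover_selectivity_check(20, 100, "carryover")$pass)
  expect_true(carryover_selectivity_check(1.9, 100, "selectivity")$pass)
  expect_false(carryover_selectivity_check(2, 100, "selectivity")$pass)
  expect_error(carryover_selectivity_check(1, 0, "carryover"), "positive")
})

test_that("matrix effect and recovery normalize to 1 with a co-suppressed IS", {
  mb <- generate_matrix_batch(matrix_effect = 0.7, recovery = 0.5,
                              noise_cv = 0, seed = 10)
  res <- matrix_recovery(mb)
  expect_equal(res$matrix_effect, 0.7, tolerance = 1e-12)
  expect_equal(res$recovery, 0.5, tolerance = 1e-12)
  expect_equal(res$is_normalized_me, 1, tolerance = 1e-12)
  expect_equal(res$is_normalized_recovery, 1, tolerance = 1e-12)
  expect_equal(res$matrix_effect_rsd, 0, tolerance = 1e-9)
  # with noise the raw estimates stay near truth and the IS-normalized ones
  # near 1 (Monte Carlo, wide tolerance)
  mbn <- generate_matrix_batch(matrix_effect = 0.7, recovery = 0.5,
                               n_matrices = 50, noise_cv = 0.04, seed = 11)
  rn <- matrix_recovery(mbn)
  expect_lt(abs(rn$matrix_effect - 0.7), 0.05)
  expect_lt(abs(rn$recovery - 0.5), 0.05)
  expect_lt(abs(rn$is_normalized_me - 1), 0.05)
  expect_gt(rn$matrix_effect_rsd, 0)
})

test_that("qc_statistics consumes raw batches through a calibration curve", {
  des <- bio_batch_design(noise_cv = 0, day_sd = 0, bias = 0)
  b <- generate_bio_batch(des, seed = 3)
  curve <- fit_calibration(b)
  for (lev in c(20, 80, 140)) {
    qc <- qc_statistics(b, nominal = lev, curve = curve)
    expect_equal(qc$inter$accuracy, 100, tolerance = 1e-8)
    expect_equal(qc$n, 18)
    expect_equal(qc$n_days, 3)
  }
})
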