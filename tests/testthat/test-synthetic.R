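# Synthetic cohort and bioanalytical batch generators: structure,
# determinism, sampling-window behavior, calibration of the defaults, and
# noise propagation.

test_that("the default cohort reproduces the study structure", {
  d <- generate_cohort(seed = 42)
  obs <- d[d$EVID == 0, ]
  expect_equal(length(unique(d$ID)), 14)
  expect_equal(nrow(obs), 53)            # one subject keeps only +6 h
  per <- table(obs$ID)
  expect_equal(sort(unique(as.integer(per))), c(1L, 4L))
  expect_equal(sum(per == 1L), 1L)
  # doses: 13 subjects on 30 mg, one inhibitor-free subject on 60 mg
  dose_by_id <- tapply(d$AMT[d$EVID == 1], d$ID[d$EVID == 1], unique)
  expect_equal(sum(dose_by_id == 60), 1)
  expect_equal(sum(dose_by_id == 30), 13)
  hi <- as.integer(names(dose_by_id)[dose_by_id == 60])
  expect_equal(unique(d$CYP3A4I[d$ID == hi]), 0L)
  # observations live within 15 min of their nominal offsets; predose early
  expect_true(all(abs(obs$TIME - (max(d$TIME[d$EVID == 1]) + obs$NTIME))
                  <= 0.25 + 1e-12))
  pre <- obs[obs$NTIME == 0, ]
  expect_true(all(pre$TIME <= max(d$TIME[d$EVID == 1])))
  expect_true(all(obs$DV >= 0))
  expect_true(all(obs$BLQ == 0L))
})

test_that("the generator is deterministic in the seed and grid-exact without jitter", {
  a <- generate_cohort(seed = 5)
  b <- generate_cohort(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(seed = 6)))
  des <- study_design(jitter_halfwidth = 0, missing_pattern = FALSE)
  g <- generate_cohort(des, seed = 3)
  obs <- g[g$EVID == 0, ]
  t_last <- max(g$TIME[g$EVID == 1])
  expect_equal(sort(unique(obs$TIME - t_last)), c(0, 2, 4, 6))
  expect_equal(nrow(obs), 14 * 4)
})

test_that("design validation rejects out-of-window jitter and bad offsets", {
  expect_error(study_design(jitter_halfwidth = 0.3), "0.25")
  expect_error(study_design(sampling_offsets = c(0, 4, 2)), "increasing")
  expect_error(generate_cohort(study_design()), "seed")
})

test_that("default cohort parameters hit the published timepoint means within 40%", {
  # large-cohort means at the nominal offsets must track 82/129/141/120 ng/mL
  des <- study_design(n_subjects = 200, jitter_halfwidth = 0,
                      missing_pattern = FALSE, high_dose_mg = 30)
  d <- generate_cohort(des, seed = 2024)
  tp <- nca_summary(d)$timepoint_summary
  target <- c(82, 129, 141, 120)
  expect_equal(tp$NTIME, c(0, 2, 4, 6))
  expect_true(all(abs(tp$mean / target - 1) < 0.40))
  # and the noiseless typical profile is within 10% (the calibration target)
  typ <- steady_state_profile(default_cohort_parameters(),
                              dosing_regimen(30, 24), c(0, 2, 4, 6))
  expect_true(all(abs(typ / target - 1) < 0.10))
})

test_that("covariate frequencies match the design (binomial 3 SE)", {
  des <- study_design(n_subjects = 500, missing_pattern = FALSE,
                      high_dose_mg = 30)
  d <- generate_cohort(des, seed = 77)
  first <- d[!duplicated(d$ID), ]
  for (spec in list(c("SEX", 0.64), c("CYP3A4I", 0.79), c("FOOD", 1))) {
    p <- as.numeric(spec[2])
    x <- if (spec[1] == "SEX") mean(first$SEX == "F") else mean(first[[spec[1]]])
    expect_lt(abs(x - p), 3 * sqrt(p * (1 - p) / 500) + 1e-12)
  }
})

test_that("a noiseless bio batch lies exactly on the response line", {
  des <- bio_batch_design(noise_cv = 0, day_sd = 0, bias = 0)
  b <- generate_bio_batch(des, seed = 1)
  ratio <- b$analyte_area / b$is_area
  expect_equal(ratio, 0.0116 * b$level + 0.1429, tolerance = 1e-12)
  expect_equal(nrow(b), 10 + 3 * 6 * 3)
  curve <- fit_calibration(b)
  expect_equal(curve$slope, 0.0116, tolerance = 1e-10)
  expect_equal(curve$intercept, 0.1429, tolerance = 1e-10)
})

test_that("bias and noise in the batch design propagate to QC statistics", {
  # a -8% proportional bias with no noise gives exactly 92% accuracy
  des <- bio_batch_design(noise_cv = 0, day_sd = 0, bias = -0.08)
  b <- generate_bio_batch(des, seed = 1)
  curve <- fit_calibration(b)
  qc <- qc_statistics(b, nominal = 80, curve = curve)
  expect_equal(qc$inter$accuracy, 92, tolerance = 1e-6)
  expect_equal(qc$inter$rsd, 0, tolerance = 1e-8)
  # with noise, the inter-day RSD recovers the total CV (Monte Carlo)
  des2 <- bio_batch_design(noise_cv = 0.05, day_sd = 0, bias = 0,
                           replicates_per_level = 200, n_days = 3)
  b2 <- generate_bio_batch(des2, seed = 8)
  qc2 <- qc_statistics(b2, nominal = 140, curve = calibration_curve(0.0116, 0.1429))
  # response CV 5% inflates slightly on back-calculation via the intercept
  expect_lt(abs(qc2$inter$rsd - 5 * (0.0116 * 140 + 0.1429) / (0.0116 * 140)),
            0.5)
})

test_that("matrix batch encodes suppression and recovery on both channels", {
  mb <- generate_matrix_batch(matrix_effect = 0.7, recovery = 0.5,
                              noise_cv = 0, seed = 4)
  neat <- mb[mb$preparation == "neat" & mb$level == 80, ][1, ]
  post <- mb[mb$preparation == "post" & mb$level == 80 & mb$matrix ==
               neat$matrix, ]
  pre <- mb[mb$preparation == "pre" & mb$level == 80 & mb$matrix ==
              neat$matrix, ]
  expect_equal(post$analyte_area / neat$analyte_area, 0.7, tolerance = 1e-12)
  expect_equal(pre$analyte_area / post$analyte_area, 0.5, tolerance = 1e-12)
  expect_equal(post$is_area / neat$is_area, 0.7, tolerance = 1e-12)
})
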