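# Structural model: closed-form correctness, superposition, mass balance,
# steady state, random effects and residual simulation.

bateman <- function(f, d_mg, ka, ke, v, t) {
  f * d_mg * 1000 * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

test_that("disconnected peripheral compartments reduce to the Bateman form", {
  p <- pk_parameters(cl = 1, v2 = 100, v3 = 10, v4 = 10, q3 = 0, q4 = 0,
                     ka = 1.68, f1 = 1)
  reg <- dosing_regimen(30, 24, n_doses = 1)
  tt <- c(0, 0.25, 1, 2, 4, 8, 24, 72, 200)
  expect_equal(concentration_profile(p, reg, tt),
               bateman(1, 30, 1.68, 0.01, 100, tt), tolerance = 1e-9)
  # the single worked value: ~289.6 ng/mL at 4 h
  expect_equal(concentration_profile(p, reg, 4), 289.6,
               tolerance = 1e-3)
})

test_that("zero dose gives zero concentration and doubling the dose doubles it", {
  p <- default_pk_parameters()
  tt <- c(1, 6, 30)
  expect_equal(concentration_profile(p, dosing_regimen(0, 24, 3), tt),
               rep(0, 3))
  c30 <- concentration_profile(p, dosing_regimen(30, 24, 3), tt)
  c60 <- concentration_profile(p, dosing_regimen(60, 24, 3), tt)
  expect_equal(c60, 2 * c30, tolerance = 1e-12)
})

test_that("superposition is invariant to a common shift of all dose times", {
  p <- default_pk_parameters()
  base <- quizpk:::conc_superposition(p, c(0, 24, 48), rep(30, 3),
                                      c(1, 25, 60))
  shifted <- quizpk:::conc_superposition(p, c(0, 24, 48) + 7, rep(30, 3),
                                         c(1, 25, 60) + 7)
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("mass balance holds to 1e-6 relative at all times", {
  p <- default_pk_parameters()
  reg <- dosing_regimen(30, 24, n_doses = 3)
  tt <- c(0, 0.5, 1, 12, 24.1, 47.9, 48.5, 100, 400)
  amt <- compartment_amounts(p, reg, tt)
  dosed <- vapply(tt, function(t) sum(t >= c(0, 24, 48)), numeric(1)) *
    p$f1 * 30 * 1000
  expect_true(all(abs(rowSums(amt) - dosed) <= 1e-6 * pmax(dosed, 1)))
  expect_true(all(amt >= -1e-9))
})

test_that("ke is exactly cl/v2 and the terminal half-life tracks the slow eigenvalue", {
  p <- default_pk_parameters()
  expect_identical(pk_ke(p), p$cl / p$v2)
  # 1-compartment reduction: terminal half-life is log(2)/ke exactly
  p1 <- pk_parameters(cl = 2, v2 = 50, v3 = 1, v4 = 1, q3 = 0, q4 = 0,
                      ka = 1, f1 = 1)
  expect_equal(pk_terminal_halflife(p1), log(2) / (2 / 50), tolerance = 1e-12)
})

test_that("parameter validation rejects non-physical values", {
  expect_error(pk_parameters(cl = -1, v2 = 1, v3 = 1, v4 = 1, q3 = 0, q4 = 0,
                             ka = 1, f1 = 0.5), "strictly positive")
  expect_error(pk_parameters(cl = 1, v2 = 1, v3 = 1, v4 = 1, q3 = 0, q4 = 0,
                             ka = 1, f1 = 1.2), "f1")
  expect_error(pk_parameters(cl = 1, v2 = Inf, v3 = 1, v4 = 1, q3 = 0, q4 = 0,
                             ka = 1, f1 = 1), "finite")
  expect_error(concentration_profile(default_pk_parameters(),
                                     dosing_regimen(30, 24, 1), c(-1, 2)),
               "non-negative")
})

test_that("steady-state profile is periodic and matches the geometric-series form", {
  p <- default_pk_parameters()
  reg <- dosing_regimen(30, 24)
  ss <- steady_state_profile(p, reg, c(0, 2, 4, 6, 24))
  expect_equal(ss[5], ss[1], tolerance = 1e-6)
  # 1-compartment reduction against the explicit accumulation closed form
  p1 <- pk_parameters(cl = 1, v2 = 100, v3 = 1, v4 = 1, q3 = 0, q4 = 0,
                      ka = 1.68, f1 = 1)
  ke <- 0.01; ka <- 1.68; tau <- 24
  tt <- c(0, 3, 12, 23)
  closed <- 30 * 1000 * ka / (100 * (ka - ke)) *
    (exp(-ke * tt) / (1 - exp(-ke * tau)) -
       exp(-ka * tt) / (1 - exp(-ka * tau)))
  expect_equal(steady_state_profile(p1, dosing_regimen(30, 24), tt), closed,
               tolerance = 1e-9)
  # fast elimination: accumulation ratio tends to 1
  pf <- pk_parameters(cl = 80, v2 = 20, v3 = 1, v4 = 1, q3 = 0, q4 = 0,
                      ka = 6, f1 = 1)
  one <- concentration_profile(pf, dosing_regimen(30, 24, 1), c(1, 2, 4))
  ssf <- steady_state_profile(pf, dosing_regimen(30, 24), c(1, 2, 4))
  expect_equal(ssf, one, tolerance = 1e-6)
})

test_that("population prediction agrees with the steady-state profile after many doses", {
  p <- default_cohort_parameters()
  d <- generate_cohort(study_design(n_subjects = 2, jitter_halfwidth = 0,
                                    missing_pattern = FALSE),
                       params = p, seed = 9)
  pred <- population_predict(d, p)
  ss <- steady_state_profile(p, dosing_regimen(30, 24), c(0, 2, 4, 6))
  doses <- tapply(d$AMT[d$EVID == 1], d$ID[d$EVID == 1], unique)
  expected <- unlist(lapply(unique(d$ID), function(id) ss * doses[[as.character(id)]] / 30))
  expect_equal(pred, expected, tolerance = 1e-6)
})

test_that("the ODE fallback agrees with the degenerate ka = ke closed form", {
  # ka equal to the elimination rate: repeated pole, t*exp(-k t) solution
  k <- 0.5
  p <- pk_parameters(cl = k * 100, v2 = 100, v3 = 1, v4 = 1, q3 = 0, q4 = 0,
                     ka = k, f1 = 1)
  tt <- c(0.5, 1, 2, 5)
  got <- concentration_profile(p, dosing_regimen(30, 24, 1), tt)
  expect_equal(got, 30 * 1000 * k * tt * exp(-k * tt) / 100, tolerance = 1e-7)
})

test_that("apply_iiv realizes log-normal effects and keeps identities", {
  p <- default_pk_parameters()
  m <- random_effects()
  id <- apply_iiv(p, c(0, 0, 0), m)
  expect_identical(unclass(id$realized), unclass(p))
  dbl <- apply_iiv(p, c(log(2), 0, 0), m)
  expect_equal(dbl$realized$cl, 2 * p$cl, tolerance = 1e-15)
  expect_error(apply_iiv(p, c(0, 0), m), "length")
})

test_that("sampled etas reproduce omega (Monte Carlo, 3 SE)", {
  m <- random_effects(omega = c(cl = 0.09, v2 = 0.04, f1 = 0.0225))
  set.seed(101)
  e <- sample_etas(1e5, m)
  v <- apply(e, 2, var)
  se <- diag(m$omega) * sqrt(2 / (1e5 - 1))   # SE of a normal variance
  expect_true(all(abs(v - diag(m$omega)) < 3 * se))
  expect_lt(max(abs(colMeans(e))), 3 * sqrt(max(diag(m$omega)) / 1e5))
})

test_that("simulated observations honour the residual model and the seed", {
  p <- default_cohort_parameters()
  reg <- dosing_regimen(30, 24, 10)
  tt <- 9 * 24 + c(0, 2, 4, 6)
  m0 <- random_effects(sigma_prop = 0, sigma_add = 0)
  expect_warning(dv0 <- simulate_observations(p, reg, tt, m0, seed = 1),
                 "noiseless")
  expect_equal(dv0, concentration_profile(p, reg, tt))
  m <- random_effects(sigma_prop = 0.2, sigma_add = 1)
  a <- simulate_observations(p, reg, tt, m, seed = 7)
  b <- simulate_observations(p, reg, tt, m, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_observations(p, reg, tt, m, seed = 8)))
  # empirical CV at one timepoint approaches sigma_prop (additive SD off)
  mcv <- random_effects(sigma_prop = 0.2, sigma_add = 0)
  set.seed(2)
  reps <- replicate(1e4, quizpk:::add_residual_noise(150, mcv, "keep"))
  cv <- sd(reps) / mean(reps)
  expect_lt(abs(cv - 0.2), 3 * 0.2 / sqrt(2 * 1e4))
})

test_that("MAP estimate recovers a known eta from noiseless data", {
  p <- default_cohort_parameters()
  m2 <- random_effects(omega = c(cl = 0.09, v2 = 0.09),
                       sigma_prop = 0.002, sigma_add = 0)
  eta_true <- c(cl = 0.25, v2 = -0.3)
  d <- noiseless_subject(p, eta_true, m2)
  fit <- map_estimate(as.data.frame(d), p, m2)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$eta - eta_true)), 1e-3)
})

test_that("MAP limits: strong prior shrinks to zero, weak prior interpolates", {
  p <- default_cohort_parameters()
  mgen <- random_effects(omega = c(cl = 0.09, v2 = 0.09),
                         sigma_prop = 0.002, sigma_add = 0)
  d <- noiseless_subject(p, c(cl = 0.2, v2 = -0.2), mgen)
  tiny <- random_effects(omega = c(cl = 1e-8, v2 = 1e-8),
                         sigma_prop = 0.2, sigma_add = 1)
  fit0 <- map_estimate(as.data.frame(d), p, tiny)
  expect_lt(max(abs(fit0$eta)), 1e-4)
  pred <- population_predict(d, p)
  expect_equal(fit0$ipred, pred, tolerance = 1e-4)
  wide <- random_effects(omega = c(cl = 25, v2 = 25),
                         sigma_prop = 0.002, sigma_add = 0)
  fitw <- map_estimate(as.data.frame(d), p, wide)
  obs <- d$DV[d$EVID == 0]
  expect_equal(fitw$ipred, obs, tolerance = 1e-4)
})

test_that("MAP estimate is invariant to observation order and needs data", {
  p <- default_cohort_parameters()
  m2 <- random_effects(omega = c(cl = 0.09, v2 = 0.09),
                       sigma_prop = 0.1, sigma_add = 1)
  d <- as.data.frame(noiseless_subject(p, c(cl = 0.1, v2 = 0.1), m2))
  obs <- which(d$EVID == 0)
  d$DV[obs] <- d$DV[obs] * c(1.1, 0.9, 1.05, 0.98)   # add some misfit
  fit1 <- map_estimate(d, p, m2)
  d2 <- d[c(setdiff(seq_len(nrow(d)), obs), rev(obs)), ]
  fit2 <- map_estimate(d2, p, m2)
  expect_equal(fit1$eta, fit2$eta, tolerance = 1e-6)
  expect_error(map_estimate(d[d$EVID == 1, ], p, m2), "observation")
})
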