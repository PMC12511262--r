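# Population (PRED) and individual empirical-Bayes (IPRED) prediction, and
# observation-level simulation under the residual-error model.

subject_split <- function(dataset) {
  split(as.data.frame(dataset), factor(dataset$ID, levels = unique(dataset$ID)))
}

conc_for_subject <- function(sub, params) {
  dose <- sub[sub$EVID == 1, , drop = FALSE]
  obs <- sub[sub$EVID == 0, , drop = FALSE]
  if (nrow(obs) == 0L) return(numeric(0))
  conc_superposition(params, dose$TIME, dose$AMT, obs$TIME)
}

#' Population predictions (PRED)
#'
#' Typical-value predictions (all random effects at zero) at every
#' observation row's actual dose history and time.
#'
#' @param dataset A [cohort_dataset()].
#' @param params A [pk_parameters()] object (the fixed population values).
#' @return Numeric vector of PRED (ng/mL), one per observation row
#'   (`EVID == 0`), in dataset order.
#' @export
population_predict <- function(dataset, params) {
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(params, "pk_parameters"))
  preds <- lapply(subject_split(dataset), function(sub) {
    tryCatch(conc_for_subject(sub, params), error = function(e) {
      stop(sprintf("prediction failed for subject %s: %s",
                   sub$ID[1], conditionMessage(e)), call. = FALSE)
    })
  })
  unlist(preds, use.names = FALSE)
}

#' MAP empirical-Bayes estimation of individual random effects
#'
#' Minimizes the maximum a posteriori objective
#' `sum_j [ (DV_j - C_j(eta))^2 / var_j + log var_j ] + eta' Omega^{-1} eta`
#' where `var_j = (sigma_prop * C_j)^2 + sigma_add^2`, starting at `eta = 0`
#' (BFGS). On non-convergence, three additional jittered starts are tried and
#' the lowest objective wins; the returned fit carries convergence
#' diagnostics either way.
#'
#' @param subject_data Rows of a single subject (dosing and observation rows,
#'   cohort-dataset columns).
#' @param params A [pk_parameters()] object (population typical values).
#' @param model A [random_effects()] object; `omega` must be positive definite.
#' @return A list of class `map_fit`: `eta` (named vector), `ipred`
#'   (ng/mL at the subject's observation rows), `objective`, `converged`,
#'   `n_obs`, `starts_used`.
#' @export
map_estimate <- function(subject_data, params, model) {
  stopifnot(inherits(params, "pk_parameters"), inherits(model, "random_effects"))
  sub <- as.data.frame(subject_data)
  names(sub) <- toupper(names(sub))
  obs <- sub[sub$EVID == 0 & sub$MDV == 0 & !is.na(sub$DV), , drop = FALSE]
  if (nrow(obs) == 0L) {
    stop("MAP estimation needs at least one non-missing observation",
         call. = FALSE)
  }
  dose <- sub[sub$EVID == 1, , drop = FALSE]
  omega_inv <- tryCatch(solve(model$omega), error = function(e) {
    stop("omega must be positive definite for MAP estimation", call. = FALSE)
  })
  if (model$sigma_prop == 0 && model$sigma_add == 0) {
    stop("MAP estimation needs a non-degenerate residual-error model",
         call. = FALSE)
  }
  all_obs <- sub[sub$EVID == 0, , drop = FALSE]
  dv <- obs$DV
  fit_times <- obs$TIME
  objective <- function(eta) {
    ind <- tryCatch(apply_iiv(params, eta, model), error = function(e) NULL)
    if (is.null(ind)) return(1e10)
    cc <- conc_superposition(ind$realized, dose$TIME, dose$AMT, fit_times)
    v <- (model$sigma_prop * cc)^2 + model$sigma_add^2
    if (any(v <= 0) || any(!is.finite(cc))) return(1e10)
    sum((dv - cc)^2 / v + log(v)) + drop(t(eta) %*% omega_inv %*% eta)
  }
  p <- length(model$eta_names)
  sd_diag <- sqrt(pmax(diag(model$omega), 1e-4))
  starts <- list(rep(0, p))
  best <- NULL
  s <- 0L
  while (s < length(starts)) {
    s <- s + 1L
    fit <- stats::optim(starts[[s]], objective, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12,
                                       ndeps = rep(1e-6, p)))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (s == 1L && best$convergence != 0) {
      # deterministic jittered restarts on non-convergence
      starts <- c(starts, list(0.5 * sd_diag, -0.5 * sd_diag, sd_diag))
    }
  }
  # polish with Nelder-Mead from the best point (robust near kinks)
  pol <- stats::optim(best$par, objective,
                      control = list(maxit = 2000, reltol = 1e-13))
  if (pol$value < best$value) best <- pol
  eta_hat <- stats::setNames(best$par, model$eta_names)
  ind <- apply_iiv(params, eta_hat, model)
  ipred <- conc_superposition(ind$realized, dose$TIME, dose$AMT, all_obs$TIME)
  structure(list(eta = eta_hat, ipred = ipred, objective = best$value,
                 converged = best$convergence == 0, n_obs = nrow(obs),
                 starts_used = length(starts)),
            class = "map_fit")
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("MAP fit on %d observations (%s)\n  eta: %s\n  objective %.6g\n",
              x$n_obs, if (x$converged) "converged" else "NOT converged",
              paste(sprintf("%s=%.4g", names(x$eta), x$eta), collapse = "  "),
              x$objective))
  invisible(x)
}

#' Individual predictions (IPRED) for a whole cohort
#'
#' Runs [map_estimate()] per subject and collects IPRED for every observation
#' row, in dataset order.
#'
#' @inheritParams population_predict
#' @param model A [random_effects()] object.
#' @return A list: `ipred` (numeric, one per observation row), `eta` (matrix,
#'   one row per subject), `converged` (logical per subject).
#' @export
individual_predict <- function(dataset, params, model) {
  subs <- subject_split(dataset)
  fits <- lapply(subs, map_estimate, params = params, model = model)
  if (any(!vapply(fits, `[[`, logical(1), "converged"))) {
    warning("MAP optimizer did not converge for ",
            sum(!vapply(fits, `[[`, logical(1), "converged")), " subject(s)",
            call. = FALSE)
  }
  list(ipred = unlist(lapply(fits, `[[`, "ipred"), use.names = FALSE),
       eta = do.call(rbind, lapply(fits, `[[`, "eta")),
       converged = vapply(fits, `[[`, logical(1), "converged"))
}

add_residual_noise <- function(conc, model, negative_policy = "resample") {
  n <- length(conc)
  draw <- function(idx) {
    conc[idx] * (1 + stats::rnorm(length(idx), 0, model$sigma_prop)) +
      stats::rnorm(length(idx), 0, model$sigma_add)
  }
  dv <- draw(seq_len(n))
  if (negative_policy == "resample") {
    for (it in 1:100) {
      neg <- which(dv < 0)
      if (!length(neg)) break
      dv[neg] <- draw(neg)
    }
    dv[dv < 0] <- 0
  } else if (negative_policy == "truncate") {
    dv <- pmax(dv, 0)
  }
  dv
}

#' Simulate observed concentrations under the residual-error model
#'
#' `DV = C * (1 + eps_prop) + eps_add` at the individual's model-predicted
#' concentrations; negative draws are resampled by default (or truncated at
#' zero). Reproducible for a given seed.
#'
#' @param ind An [apply_iiv()] result (or a bare [pk_parameters()] object,
#'   taken as eta = 0).
#' @param regimen A [dosing_regimen()].
#' @param times Observation times, hours since first dose.
#' @param model A [random_effects()] object (residual SDs used).
#' @param seed Integer seed; required for reproducibility.
#' @param negative_policy `"resample"` (default), `"truncate"` or `"keep"`.
#' @return Numeric DV vector (ng/mL).
#' @export
simulate_observations <- function(ind, regimen, times, model, seed,
                                  negative_policy = c("resample", "truncate",
                                                      "keep")) {
  negative_policy <- match.arg(negative_policy)
  pars <- if (inherits(ind, "individual_parameters")) ind$realized else ind
  stopifnot(inherits(pars, "pk_parameters"))
  conc <- concentration_profile(pars, regimen, times)
  if (model$sigma_prop == 0 && model$sigma_add == 0) {
    warning("both residual SDs are zero: returning the noiseless profile",
            call. = FALSE)
    return(conc)
  }
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  add_residual_noise(conc, model, negative_policy)
}

#' Simulate replicate cohorts under the fixed model
#'
#' For each replicate, new random effects are drawn per subject and new
#' residual errors per observation, at the dataset's actual dose histories and
#' observation times. This is the simulation engine behind [npde_compute()]
#' and [pcvpc()].
#'
#' @param dataset A [cohort_dataset()].
#' @param params Population [pk_parameters()].
#' @param model A [random_effects()] object.
#' @param nsim Number of replicate cohorts.
#' @param seed Integer seed.
#' @return A matrix (`n_observations` x `nsim`) of simulated DV; rows align
#'   with the dataset's observation rows.
#' @export
simulate_replicates <- function(dataset, params, model, nsim, seed) {
  stopifnot(inherits(dataset, "cohort_dataset"), nsim >= 1)
  set.seed(seed)
  subs <- subject_split(dataset)
  # precompute per-subject dose schedules and observation times once
  sched <- lapply(subs, function(sub) {
    dose <- sub[sub$EVID == 1, c("TIME", "AMT")]
    list(dose_times = dose$TIME, dose_amt = dose$AMT,
         t_obs = sub$TIME[sub$EVID == 0])
  })
  sched <- sched[vapply(sched, function(s) length(s$t_obs) > 0, logical(1))]
  n_obs <- sum(vapply(sched, function(s) length(s$t_obs), integer(1)))
  base <- unclass(params)
  nm <- model$eta_names
  out <- matrix(NA_real_, n_obs, nsim)
  for (k in seq_len(nsim)) {
    etas <- sample_etas(length(sched), model)
    row0 <- 0L
    for (i in seq_along(sched)) {
      s <- sched[[i]]
      pars <- base
      for (j in seq_along(nm)) pars[[nm[j]]] <- pars[[nm[j]]] * exp(etas[i, j])
      cc <- conc_superposition(pars, s$dose_times, s$dose_amt, s$t_obs)
      m <- length(s$t_obs)
      out[row0 + seq_len(m), k] <- add_residual_noise(cc, model, "resample")
      row0 <- row0 + m
    }
  }
  out
}
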