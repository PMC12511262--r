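# Closed-form solution of the mamillary 3-compartment oral model.
#
# States: a1 depot, a2 central (V2), a3 peripheral (V3, via Q3),
# a4 peripheral (V4, via Q4). First-order absorption KA from depot,
# linear elimination CL from central. The system matrix is constant, so the
# impulse response is a sum of exponentials obtained by eigendecomposition;
# an ODE integrator is used only when the eigendecomposition is numerically
# degenerate (e.g. KA coinciding with a disposition rate).

# mg -> microgram so that amount / volume(L) = ug/L = ng/mL. Applied exactly
# once, here, on the depot dose.
MG_TO_UG <- 1000

system_matrix <- function(p) {
  k20 <- p$cl / p$v2
  k23 <- p$q3 / p$v2; k32 <- p$q3 / p$v3
  k24 <- p$q4 / p$v2; k42 <- p$q4 / p$v4
  matrix(c(-p$ka, 0, 0, 0,
           p$ka, -(k20 + k23 + k24), k32, k42,
           0, k23, -k32, 0,
           0, k24, 0, -k42),
         nrow = 4, byrow = TRUE)
}

disposition_eigenvalues <- function(p) {
  k20 <- p$cl / p$v2
  k23 <- p$q3 / p$v2; k32 <- p$q3 / p$v3
  k24 <- p$q4 / p$v2; k42 <- p$q4 / p$v4
  A3 <- matrix(c(-(k20 + k23 + k24), k32, k42,
                 k23, -k32, 0,
                 k24, 0, -k42), nrow = 3, byrow = TRUE)
  Re(eigen(A3, only.values = TRUE)$values)
}

# Analytic modal expansion of the central-compartment impulse response:
# poles are -ka plus the disposition roots (closed-form quadratic/cubic, all
# real and negative for a mamillary model); residues come from the Laplace
# partial fractions A2(s) = ka * prod(s + kp2) / prod(s - pole). Returns
# NULL on pole collisions (caller falls back to the eigendecomposition/ODE).
central_modes <- function(p) {
  k20 <- p$cl / p$v2
  periph_in <- c(if (p$q3 > 0) p$q3 / p$v2, if (p$q4 > 0) p$q4 / p$v2)
  periph_out <- c(if (p$q3 > 0) p$q3 / p$v3, if (p$q4 > 0) p$q4 / p$v4)
  np <- length(periph_in)
  lam <- if (np == 0L) {
    -k20
  } else if (np == 1L) {
    # lambda^2 + (k20+k2p+kp2) lambda + k20*kp2 = 0
    b <- k20 + periph_in + periph_out
    disc <- b * b - 4 * k20 * periph_out
    if (disc <= 0) return(NULL)
    r1 <- -(b + sqrt(disc)) / 2
    c(r1, k20 * periph_out / r1)
  } else {
    a2 <- k20 + sum(periph_in) + sum(periph_out)
    a1 <- k20 * sum(periph_out) + periph_in[1] * periph_out[2] +
      periph_in[2] * periph_out[1] + periph_out[1] * periph_out[2]
    a0 <- k20 * periph_out[1] * periph_out[2]
    # depressed cubic, trigonometric three-real-root form
    pp <- a1 - a2 * a2 / 3
    qq <- 2 * a2^3 / 27 - a2 * a1 / 3 + a0
    if (pp >= 0) return(NULL)
    arg <- 3 * qq / (2 * pp) * sqrt(-3 / pp)
    arg <- min(1, max(-1, arg))
    m <- 2 * sqrt(-pp / 3)
    m * cos(acos(arg) / 3 - 2 * pi * (0:2) / 3) - a2 / 3
  }
  poles <- c(-p$ka, lam)
  # pole collision or repeated root: modal expansion invalid
  sp <- sort(poles)
  if (any(diff(sp) < 1e-9 * (abs(sp[-1]) + 1e-12))) return(NULL)
  res <- vapply(seq_along(poles), function(i) {
    s <- poles[i]
    num <- p$ka * prod(s + periph_out)
    num / prod(s - poles[-i])
  }, numeric(1))
  list(lambda = poles, c2 = res)
}

# Eigen machinery for the impulse response of a unit amount in the depot.
# Peripheral compartments with zero inter-compartmental clearance are dropped
# (they never receive mass), so the degenerate 2- and 1-compartment reductions
# keep the exact closed form. Returns NULL when the decomposition is
# numerically unreliable (caller falls back to the ODE integrator).
pk_modes <- function(p) {
  active <- c(TRUE, TRUE, p$q3 > 0, p$q4 > 0)
  A <- system_matrix(p)[active, active, drop = FALSE]
  e <- tryCatch(eigen(A), error = function(err) NULL)
  if (is.null(e)) return(NULL)
  lam <- e$values
  if (any(abs(Im(lam)) > 1e-9 * (abs(Re(lam)) + 1))) return(NULL)
  lam <- Re(lam)
  # repeated eigenvalues break the modal expansion
  sl <- sort(lam)
  if (any(diff(sl) < 1e-9 * (abs(sl[-1]) + 1e-12))) return(NULL)
  V <- Re(e$vectors)
  co <- tryCatch(solve(V, c(1, rep(0, sum(active) - 1L))),
                 error = function(err) NULL)
  if (is.null(co) || any(!is.finite(co))) return(NULL)
  # state coefficient matrix: amounts(t) = W %*% exp(lam * t), unit depot dose
  W <- matrix(0, 4L, length(lam))
  W[active, ] <- V * rep(co, each = sum(active))
  list(lambda = lam, W = W)
}

# ODE fallback: amounts over `times` given dose events (amounts already in ug).
ode_amounts <- function(p, dose_times, dose_amts, times) {
  A <- system_matrix(p)
  deriv <- function(t, y, parms) list(as.vector(A %*% y))
  ev <- data.frame(var = "a1", time = dose_times, value = dose_amts,
                   method = "add")
  tt <- sort(unique(c(0, dose_times, times)))
  out <- deSolve::ode(y = c(a1 = 0, a2 = 0, a3 = 0, a4 = 0), times = tt,
                      func = deriv, parms = NULL, events = list(data = ev),
                      rtol = 1e-10, atol = 1e-10)
  out[match(times, out[, 1]), 2:5, drop = FALSE]
}

check_times <- function(times) {
  if (!is.numeric(times) || any(!is.finite(times))) {
    stop("times must be finite numbers", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative hours", call. = FALSE)
}

dose_schedule <- function(params, regimen) {
  n <- regimen$n_doses
  if (identical(n, "auto")) {
    lam <- disposition_eigenvalues(params)
    slow <- abs(max(lam[lam < -1e-12]))
    n <- min(5000L, max(1L, ceiling(log(1e-9) / (-slow * regimen$interval))))
  }
  list(times = regimen$interval * (seq_len(n) - 1L),
       amts = rep(regimen$dose * params$f1 * MG_TO_UG, n))
}

# Superposition over arbitrary dose history. dose_amts in mg *before*
# bioavailability; depot receives f1 * dose * 1000 ug.
conc_superposition <- function(params, dose_times, dose_mg, times) {
  amts <- params$f1 * dose_mg * MG_TO_UG
  cm <- central_modes(params)
  if (is.null(cm)) {
    cm <- pk_modes(params)
    if (!is.null(cm)) cm <- list(lambda = cm$lambda, c2 = cm$W[2, ])
  }
  if (is.null(cm)) {
    a <- ode_amounts(params, dose_times, amts, times)
    return(a[, 2] / params$v2)
  }
  c2 <- cm$c2
  lam <- cm$lambda
  n <- length(dose_times)
  # uniform repeated schedule: geometric partial sum per exponential mode,
  # evaluated backwards from the most recent dose for numerical stability
  uniform <- n > 3L && length(unique(amts)) == 1L &&
    diff(range(diff(dose_times))) < 1e-9
  if (uniform) {
    tau <- dose_times[2] - dose_times[1]
    amt <- amts[1]
    geom <- 1 - exp(lam * tau)   # lam < 0 always (cl, ka > 0)
    out <- numeric(length(times))
    for (i in seq_along(times)) {
      tt <- times[i]
      k <- min(n, floor((tt - dose_times[1]) / tau + 1e-12) + 1L)
      if (k < 1L) next
      u <- tt - dose_times[k]                  # time since last applicable dose
      out[i] <- amt * sum(c2 * exp(lam * u) * (1 - exp(lam * k * tau)) / geom)
    }
    return(out / params$v2)
  }
  vapply(times, function(tt) {
    dt <- tt - dose_times
    keep <- dt >= 0
    if (!any(keep)) return(0)
    sum(vapply(which(keep), function(d) {
      amts[d] * sum(c2 * exp(lam * dt[d]))
    }, numeric(1)))
  }, numeric(1)) / params$v2
}

#' Concentration-time profile under repeated dosing
#'
#' Central-compartment concentration `C(t) = amount_central(t) / V2` in ng/mL
#' for the three-compartment oral model, by superposition of the closed-form
#' impulse response over all administered doses. Doses are given at
#' `0, interval, 2*interval, ...` per the regimen; `times` are hours since the
#' first dose.
#'
#' @param params A [pk_parameters()] object.
#' @param regimen A [dosing_regimen()] object; with `n_doses = "auto"` enough
#'   doses are given to reach numerical steady state at the last interval.
#' @param times Numeric vector of non-negative times (h since first dose).
#' @return Numeric vector of concentrations (ng/mL), one per time.
#' @examples
#' p <- default_pk_parameters()
#' concentration_profile(p, dosing_regimen(30, 24, n_doses = 1), c(1, 4, 24))
#' @export
concentration_profile <- function(params, regimen, times) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dosing_regimen"))
  check_times(times)
  if (regimen$dose == 0) return(numeric(length(times)) + 0)
  sched <- dose_schedule(params, regimen)
  conc_superposition(params, sched$times, rep(regimen$dose, length(sched$times)),
                     times)
}

#' Compartment amounts and cumulative elimination
#'
#' Amounts (microgram) in depot, central and the two peripheral compartments
#' plus the cumulative amount eliminated, under the regimen's dose schedule.
#' At any time the five columns sum to `f1 * total dose administered so far`
#' (mass balance of the linear system).
#'
#' @inheritParams concentration_profile
#' @return A matrix with columns `depot`, `central`, `periph3`, `periph4`,
#'   `eliminated` (all microgram) and one row per time.
#' @export
compartment_amounts <- function(params, regimen, times) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dosing_regimen"))
  check_times(times)
  sched <- dose_schedule(params, regimen)
  modes <- pk_modes(params)
  out <- matrix(0, length(times), 5,
                dimnames = list(NULL, c("depot", "central", "periph3",
                                        "periph4", "eliminated")))
  if (regimen$dose == 0) return(out)
  if (is.null(modes)) {
    a <- ode_amounts(params, sched$times, sched$amts, times)
    dosed <- vapply(times, function(tt) sum(sched$amts[sched$times <= tt]),
                    numeric(1))
    out[, 1:4] <- a
    out[, 5] <- dosed - rowSums(a)
    return(out)
  }
  lam <- modes$lambda
  W <- modes$W
  c2 <- W[2, ]
  ke <- params$cl / params$v2
  for (i in seq_along(times)) {
    dt <- times[i] - sched$times
    keep <- which(dt >= 0)
    for (d in keep) {
      edt <- exp(lam * dt[d])
      out[i, 1:4] <- out[i, 1:4] + sched$amts[d] * as.vector(W %*% edt)
      # cumulative elimination: ke * integral of central amount
      nz <- abs(lam) > 1e-14
      elim <- sum(c2[nz] * (edt[nz] - 1) / lam[nz]) +
        sum(c2[!nz]) * dt[d]
      out[i, 5] <- out[i, 5] + sched$amts[d] * ke * elim
    }
  }
  out
}

#' Steady-state concentration profile within one dosing interval
#'
#' The within-interval profile after infinitely many doses, from the
#' geometric-series closed form `sum_i c_i exp(lambda_i t) / (1 - exp(lambda_i
#' tau))`. When the closed form is unavailable the profile is obtained by
#' simulating successive doses until two consecutive intervals agree to a
#' relative tolerance of 1e-8.
#'
#' @param params A [pk_parameters()] object.
#' @param regimen A [dosing_regimen()]; only `dose` and `interval` are used.
#' @param times_after_dose Times within the interval, hours after a
#'   steady-state dose (0 = predose trough).
#' @param max_doses Cap for the simulated-accumulation fallback.
#' @return Numeric vector of concentrations (ng/mL).
#' @export
steady_state_profile <- function(params, regimen, times_after_dose,
                                 max_doses = 100000L) {
  stopifnot(inherits(params, "pk_parameters"), inherits(regimen, "dosing_regimen"))
  check_times(times_after_dose)
  if (any(times_after_dose > regimen$interval)) {
    stop("times_after_dose must lie within one dosing interval", call. = FALSE)
  }
  if (regimen$dose == 0) return(numeric(length(times_after_dose)) + 0)
  tau <- regimen$interval
  amt <- params$f1 * regimen$dose * MG_TO_UG
  modes <- central_modes(params)
  if (is.null(modes)) {
    modes <- pk_modes(params)
    if (!is.null(modes)) modes <- list(lambda = modes$lambda, c2 = modes$W[2, ])
  }
  if (!is.null(modes)) {
    c2 <- modes$c2
    lam <- modes$lambda
    live <- abs(c2) > 1e-12 * max(abs(c2))
    if (all(lam[live] < 0)) {
      acc <- vapply(times_after_dose, function(tt) {
        sum(c2[live] * exp(lam[live] * tt) / (1 - exp(lam[live] * tau)))
      }, numeric(1))
      return(amt * acc / params$v2)
    }
  }
  # accumulation fallback: dose until successive intervals converge
  prev <- NULL
  achieved <- Inf
  n <- 0L
  repeat {
    n <- n + 50L
    if (n > max_doses) {
      stop(sprintf(paste0("steady state not reached within %d doses ",
                          "(last relative change %.3g)"),
                   max_doses, achieved), call. = FALSE)
    }
    dose_times <- tau * (seq_len(n) - 1L)
    cur <- conc_superposition(params, dose_times, rep(regimen$dose, n),
                              tau * (n - 1L) + times_after_dose)
    if (!is.null(prev)) {
      achieved <- max(abs(cur - prev) / pmax(abs(cur), 1e-12))
      if (achieved < 1e-8) return(cur)
    }
    prev <- cur
  }
}
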