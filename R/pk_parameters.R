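#' Structural pharmacokinetic parameters
#'
#' Constructs the fixed structural parameter vector of the mamillary
#' three-compartment oral-absorption model: apparent clearance `cl` (L/h),
#' central volume `v2` (L), peripheral volumes `v3` and `v4` (L),
#' inter-compartmental clearances `q3` and `q4` (L/h), first-order absorption
#' rate `ka` (1/h) and bioavailability fraction `f1`. The elimination rate
#' constant `ke = cl / v2` and the terminal half-life (from the slowest
#' disposition eigenvalue) are derived, never stored.
#'
#' Units are fixed package-wide: dose mg, volume L, clearance L/h,
#' concentration ng/mL. The single mg-to-microgram conversion that makes
#' amount/volume come out in ng/mL lives inside the profile engine.
#'
#' @param cl Apparent clearance, L/h. Must be > 0.
#' @param v2 Central volume of distribution, L. Must be > 0.
#' @param v3 First peripheral volume, L. Must be > 0.
#' @param v4 Second peripheral volume, L. Must be > 0.
#' @param q3 Inter-compartmental clearance central to first peripheral, L/h.
#'   Must be >= 0 (0 disconnects the compartment).
#' @param q4 Inter-compartmental clearance central to second peripheral, L/h.
#'   Must be >= 0.
#' @param ka First-order absorption rate constant, 1/h. Must be > 0.
#' @param f1 Oral bioavailability fraction, in (0, 1].
#'
#' @return An object of class `pk_parameters`.
#' @seealso [default_pk_parameters()], [concentration_profile()]
#' @examples
#' p <- default_pk_parameters()
#' p$cl / p$v2   # elimination rate constant
#' pk_ke(p)
#' @export
pk_parameters <- function(cl, v2, v3, v4, q3, q4, ka, f1) {
  vals <- c(cl, v2, v3, v4, q3, q4, ka, f1)
  names(vals) <- c("cl", "v2", "v3", "v4", "q3", "q4", "ka", "f1")
  if (any(!is.finite(vals))) {
    stop("all pharmacokinetic parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals[c("cl", "v2", "v3", "v4", "ka")] <= 0)) {
    stop("cl, v2, v3, v4 and ka must be strictly positive", call. = FALSE)
  }
  if (q3 < 0 || q4 < 0) stop("q3 and q4 must be non-negative", call. = FALSE)
  if (f1 <= 0 || f1 > 1) stop("f1 must lie in (0, 1]", call. = FALSE)
  structure(as.list(vals), class = "pk_parameters")
}

#' Default structural parameters of the fixed quizartinib model
#'
#' The median parameter values the validation fixes the model to:
#' CL 1.76 L/h, V2 227.32 L, V3 176.03 L, V4 39.30 L, Q3 26.56 L/h,
#' Q4 0.56 L/h, KA 1.68 1/h, F1 0.75. All overridable; the source model,
#' not this package, is the authority for them.
#'
#' @return A `pk_parameters` object.
#' @export
default_pk_parameters <- function() {
  pk_parameters(cl = 1.76, v2 = 227.32, v3 = 176.03, v4 = 39.30,
                q3 = 26.56, q4 = 0.56, ka = 1.68, f1 = 0.75)
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Three-compartment oral PK parameters\n")
  cat(sprintf("  CL %.4g L/h   V2 %.5g L   V3 %.5g L   V4 %.4g L\n",
              x$cl, x$v2, x$v3, x$v4))
  cat(sprintf("  Q3 %.4g L/h   Q4 %.4g L/h   KA %.4g 1/h   F1 %.3g\n",
              x$q3, x$q4, x$ka, x$f1))
  cat(sprintf("  derived: KE %.5g 1/h   terminal t1/2 %.4g h\n",
              pk_ke(x), pk_terminal_halflife(x)))
  invisible(x)
}

#' Derived elimination rate constant
#'
#' `ke = cl / v2`, exactly.
#'
#' @param params A [pk_parameters()] object.
#' @return Elimination rate constant in 1/h.
#' @export
pk_ke <- function(params) {
  stopifnot(inherits(params, "pk_parameters"))
  params$cl / params$v2
}

#' Terminal half-life from the disposition eigenvalues
#'
#' `log(2)` divided by the smallest-magnitude (slowest) non-zero eigenvalue of
#' the disposition system, i.e. the terminal slope of the impulse response.
#'
#' @param params A [pk_parameters()] object.
#' @return Terminal half-life in hours.
#' @export
pk_terminal_halflife <- function(params) {
  lam <- disposition_eigenvalues(params)
  lam <- lam[lam < -1e-12]
  log(2) / abs(max(lam))
}

#' Dosing regimen
#'
#' @param dose Dose amount in mg (>= 0).
#' @param interval Dosing interval in hours (> 0); default once daily.
#' @param n_doses Number of doses administered before the profile is read out,
#'   or `"auto"` to dose until the contribution of the earliest dose to the
#'   trough is below a 1e-9 relative tolerance (capped at 5000 doses).
#' @return An object of class `dosing_regimen`.
#' @export
dosing_regimen <- function(dose = 30, interval = 24, n_doses = "auto") {
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0 || !is.finite(dose)) {
    stop("dose must be a single non-negative number (mg)", call. = FALSE)
  }
  if (!is.numeric(interval) || interval <= 0) {
    stop("interval must be a positive number of hours", call. = FALSE)
  }
  if (!identical(n_doses, "auto") &&
      (!is.numeric(n_doses) || n_doses < 1 || n_doses != round(n_doses))) {
    stop("n_doses must be \"auto\" or a positive integer", call. = FALSE)
  }
  structure(list(dose = dose, interval = interval, n_doses = n_doses),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("Oral regimen: %g mg every %g h (n_doses = %s)\n",
              x$dose, x$interval, format(x$n_doses)))
  invisible(x)
}

# Parameters that may carry a log-normal random effect.
ETA_PARAMS <- c("cl", "v2", "f1", "ka")

#' Inter-individual variability and residual-error model
#'
#' Log-normal random effects on a subset of \{cl, v2, f1, ka\} with
#' variance-covariance `omega`, plus a combined residual-error model
#' `DV = C * (1 + eps_prop) + eps_add`.
#'
#' The default magnitudes (30% CV on CL and V2, 20% on F1; proportional
#' residual SD 20%, additive 1 ng/mL) are repository defaults chosen to give
#' a realistic sparse-TDM cohort; the source publication does not report them.
#'
#' @param omega Either a named numeric vector of log-scale variances (diagonal
#'   omega) or a named square variance-covariance matrix; names from
#'   \{"cl","v2","f1","ka"\}. A 30% CV corresponds to variance `log(1 + 0.3^2)`
#'   for small CVs approximately `0.3^2`; plain `cv^2` is the convention used
#'   here.
#' @param sigma_prop Proportional residual SD as a fraction (>= 0).
#' @param sigma_add Additive residual SD in ng/mL (>= 0).
#' @return An object of class `random_effects`.
#' @export
random_effects <- function(omega = c(cl = 0.3^2, v2 = 0.3^2, f1 = 0.2^2),
                           sigma_prop = 0.2, sigma_add = 1) {
  if (is.matrix(omega)) {
    nm <- rownames(omega)
    if (is.null(nm) || !identical(nm, colnames(omega))) {
      stop("omega matrix must have matching row/column names", call. = FALSE)
    }
    om <- omega
  } else {
    nm <- names(omega)
    if (is.null(nm)) stop("omega must be named", call. = FALSE)
    om <- diag(as.numeric(omega), nrow = length(omega))
    dimnames(om) <- list(nm, nm)
  }
  if (!all(nm %in% ETA_PARAMS)) {
    stop("omega names must be among: ", paste(ETA_PARAMS, collapse = ", "),
         call. = FALSE)
  }
  if (any(abs(om - t(om)) > 1e-12)) stop("omega must be symmetric", call. = FALSE)
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("omega must be positive semidefinite", call. = FALSE)
  if (sigma_prop < 0 || sigma_add < 0) {
    stop("residual SDs must be non-negative", call. = FALSE)
  }
  structure(list(omega = om, eta_names = nm,
                 sigma_prop = sigma_prop, sigma_add = sigma_add),
            class = "random_effects")
}

#' @export
print.random_effects <- function(x, ...) {
  cat("Random-effects model (log-normal IIV)\n")
  cat("  omega diagonal:",
      paste(sprintf("%s=%.4g", x$eta_names, diag(x$omega)), collapse = "  "),
      "\n")
  cat(sprintf("  residual: proportional SD %.3g, additive SD %.3g ng/mL\n",
              x$sigma_prop, x$sigma_add))
  invisible(x)
}

#' Apply individual random effects to base parameters
#'
#' Realizes individual parameters as `base * exp(eta)` componentwise on the
#' parameters named by the random-effects model; all other parameters are
#' copied. `eta = 0` returns the base parameters identically. A realized
#' individual bioavailability may exceed 1 (log-normal variability on a
#' relative bioavailability); only the typical value is bounded by 1.
#'
#' @param base A [pk_parameters()] object (the typical values).
#' @param eta Numeric vector of log-scale random effects, in the order of
#'   `model$eta_names` (names, if present, must match).
#' @param model A [random_effects()] object.
#' @return An object of class `individual_parameters` with elements `base`,
#'   `eta` and `realized` (a `pk_parameters`).
#' @export
apply_iiv <- function(base, eta, model) {
  stopifnot(inherits(base, "pk_parameters"), inherits(model, "random_effects"))
  nm <- model$eta_names
  if (length(eta) != length(nm)) {
    stop(sprintf("eta has length %d but the model carries %d random effects",
                 length(eta), length(nm)), call. = FALSE)
  }
  if (!is.null(names(eta)) && !identical(names(eta), nm)) {
    stop("names of eta do not match the random-effects model", call. = FALSE)
  }
  realized <- unclass(base)
  for (i in seq_along(nm)) realized[[nm[i]]] <- realized[[nm[i]]] * exp(eta[i])
  # individual bioavailability under log-normal IIV is relative and may
  # exceed 1; only the typical value is bounded by 1
  f1 <- realized$f1
  realized$f1 <- min(f1, 1)
  realized <- do.call(pk_parameters, realized)
  realized$f1 <- f1
  structure(list(base = base, eta = stats::setNames(as.numeric(eta), nm),
                 realized = realized),
            class = "individual_parameters")
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat("Individual parameters (base * exp(eta)):\n  eta:",
      paste(sprintf("%s=%.4g", names(x$eta), x$eta), collapse = "  "), "\n")
  print(x$realized)
  invisible(x)
}

#' Draw random-effect vectors from the population model
#'
#' @param n Number of subjects.
#' @param model A [random_effects()] object.
#' @return An `n` by `length(eta)` matrix of log-scale effects, columns named.
#' @export
sample_etas <- function(n, model) {
  stopifnot(inherits(model, "random_effects"))
  om <- model$omega
  p <- ncol(om)
  # matrix square root via symmetric eigendecomposition (omega may be singular)
  e <- eigen(om, symmetric = TRUE)
  rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
  z <- matrix(stats::rnorm(n * p), n, p)
  eta <- z %*% rt
  colnames(eta) <- model$eta_names
  eta
}
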