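# Synthetic stand-in for the clinical validation cohort: a sparse
# steady-state TDM design (predose/+2/+4/+6 h, once-daily oral dosing, mostly
# 30 mg, covariate mix per the study population) plus raw bioanalytical
# batches for the method-validation statistics.

#' Study design for the synthetic validation cohort
#'
#' Defaults emulate the validation study: 14 subjects on 30 mg once daily with
#' food (one CYP3A4-inhibitor-free subject on 60 mg), steady-state sampling at
#' predose and +2/+4/+6 h with a +/-15 min collection window, 64% female and
#' 79% on a strong CYP3A4 inhibitor, and one subject contributing only the
#' +6 h sample (53 rather than 56 observations).
#'
#' @param n_subjects Number of subjects.
#' @param dose_mg Standard daily dose, mg.
#' @param high_dose_mg Dose for the single inhibitor-free subject, mg
#'   (set equal to `dose_mg` to disable).
#' @param interval Dosing interval, h.
#' @param sampling_offsets Hours after the steady-state dose; 0 = predose.
#' @param jitter_halfwidth Half-width of the uniform sampling-time jitter, h
#'   (never exceeding 0.25 h = 15 min). The predose sample is jittered only
#'   backwards (a trough is drawn before dose intake).
#' @param p_female,p_inhibitor,p_food Covariate frequencies.
#' @param missing_pattern If `TRUE`, one randomly chosen subject keeps only
#'   the last sampling offset.
#' @param n_doses Doses administered before the sampling interval, or
#'   `"auto"` (enough to be at numerical steady state).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 14, dose_mg = 30, high_dose_mg = 60,
                         interval = 24, sampling_offsets = c(0, 2, 4, 6),
                         jitter_halfwidth = 0.25,
                         p_female = 0.64, p_inhibitor = 0.79, p_food = 1,
                         missing_pattern = TRUE, n_doses = "auto") {
  if (is.unsorted(sampling_offsets, strictly = TRUE)) {
    stop("sampling_offsets must be strictly increasing", call. = FALSE)
  }
  if (jitter_halfwidth < 0 || jitter_halfwidth > 0.25) {
    stop("jitter_halfwidth must lie in [0, 0.25] h (15 min window)",
         call. = FALSE)
  }
  stopifnot(n_subjects >= 1, dose_mg >= 0, interval > 0,
            p_female >= 0, p_female <= 1, p_inhibitor >= 0, p_inhibitor <= 1,
            p_food >= 0, p_food <= 1)
  structure(list(n_subjects = n_subjects, dose_mg = dose_mg,
                 high_dose_mg = high_dose_mg, interval = interval,
                 sampling_offsets = sampling_offsets,
                 jitter_halfwidth = jitter_halfwidth,
                 p_female = p_female, p_inhibitor = p_inhibitor,
                 p_food = p_food, missing_pattern = missing_pattern,
                 n_doses = n_doses),
            class = "study_design")
}

#' Default structural parameters of the cohort emulation
#'
#' The fixed published model overpredicts this cohort's concentrations
#' several-fold, so the generator keeps the published distribution structure
#' (V2, V3, V4, Q3, Q4, KA) but uses an effective clearance of 6.72 L/h and an
#' effective bioavailability of 0.568, fitted once by log-least-squares of the
#' typical steady-state profile to the study's printed timepoint means
#' (82/129/141/120 ng/mL at 0/2/4/6 h). These are repository defaults for data
#' emulation, not published parameter values.
#'
#' @return A `pk_parameters` object.
#' @seealso [default_pk_parameters()] for the published median values.
#' @export
default_cohort_parameters <- function() {
  pk_parameters(cl = 6.72, v2 = 227.32, v3 = 176.03, v4 = 39.30,
                q3 = 26.56, q4 = 0.56, ka = 1.68, f1 = 0.568)
}

#' Generate a synthetic validation cohort
#'
#' Per subject: covariates are drawn at the design frequencies, log-normal
#' random effects are sampled, daily doses are laid down to steady state, the
#' nominal sampling offsets are jittered within the collection window and DV
#' is simulated under the residual-error model. The single high-dose subject
#' is always CYP3A4-inhibitor negative (the design's dose-reduction logic run
#' in reverse).
#'
#' @param design A [study_design()].
#' @param params Population [pk_parameters()]; defaults to
#'   [default_cohort_parameters()].
#' @param model A [random_effects()] object.
#' @param seed Integer seed (required; the generator is deterministic in it).
#' @return A [cohort_dataset()] with columns ID, TIME, NTIME, AMT, EVID, MDV,
#'   DV, CMT, SEX, CYP3A4I, FOOD, BLQ.
#' @export
generate_cohort <- function(design = study_design(),
                            params = default_cohort_parameters(),
                            model = random_effects(), seed) {
  stopifnot(inherits(design, "study_design"), inherits(params, "pk_parameters"))
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  ns <- design$n_subjects
  inhibitor <- stats::rbinom(ns, 1, design$p_inhibitor)
  if (all(inhibitor == 1) && design$high_dose_mg != design$dose_mg) {
    inhibitor[sample.int(ns, 1)] <- 0L
  }
  female <- stats::rbinom(ns, 1, design$p_female)
  food <- stats::rbinom(ns, 1, design$p_food)
  dose <- rep(design$dose_mg, ns)
  if (design$high_dose_mg != design$dose_mg && any(inhibitor == 0)) {
    dose[sample(which(inhibitor == 0), 1)] <- design$high_dose_mg
  }
  etas <- sample_etas(ns, model)
  reduced <- if (design$missing_pattern) sample.int(ns, 1) else 0L
  regimen0 <- dosing_regimen(design$dose_mg, design$interval, design$n_doses)
  sched <- dose_schedule(params, regimen0)   # dose count from typical values
  n_doses <- length(sched$times)
  t_last <- design$interval * (n_doses - 1L)
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    offsets <- design$sampling_offsets
    if (i == reduced) offsets <- offsets[length(offsets)]
    jit <- stats::runif(length(offsets), -design$jitter_halfwidth,
                        design$jitter_halfwidth)
    jit[offsets == 0] <- -abs(jit[offsets == 0])   # predose drawn before dose
    t_obs <- t_last + offsets + jit
    ind <- apply_iiv(params, etas[i, ], model)
    dose_times <- design$interval * (seq_len(n_doses) - 1L)
    conc <- conc_superposition(ind$realized, dose_times, rep(dose[i], n_doses),
                               t_obs)
    dv <- if (model$sigma_prop == 0 && model$sigma_add == 0) conc else
      add_residual_noise(conc, model, "resample")
    sub <- data.frame(
      ID = i,
      TIME = c(dose_times, t_obs),
      NTIME = c(rep(NA_real_, n_doses), offsets),
      AMT = c(rep(dose[i], n_doses), rep(NA_real_, length(t_obs))),
      EVID = c(rep(1L, n_doses), rep(0L, length(t_obs))),
      MDV = c(rep(1L, n_doses), rep(0L, length(t_obs))),
      DV = c(rep(NA_real_, n_doses), dv),
      CMT = c(rep(1L, n_doses), rep(2L, length(t_obs))),
      SEX = ifelse(female[i] == 1, "F", "M"),
      CYP3A4I = inhibitor[i],
      FOOD = food[i],
      BLQ = c(rep(NA_integer_, n_doses), rep(0L, length(t_obs)))
    )
    rows[[i]] <- sub
  }
  cohort_dataset(do.call(rbind, rows))
}

#' Bioanalytical batch design
#'
#' Defaults mirror the method-validation layout: a 10-level calibration ladder
#' from 6 to 200 ng/mL, QC levels 20/80/140 ng/mL, six replicates per level on
#' three days, and a response model `ratio = slope * conc + intercept` with
#' multiplicative noise, an additive log-scale day effect on QC responses, and
#' an optional fixed proportional bias.
#'
#' @param standard_levels Calibration standard concentrations, ng/mL.
#' @param qc_levels QC concentrations, ng/mL.
#' @param replicates_per_level,n_days QC replication (defaults 6 x 3 = 18).
#' @param true_slope,true_intercept Response model of the area ratio.
#' @param noise_cv Multiplicative (intra-day) noise CV of the response.
#' @param day_sd SD of the log-scale day effect (inter-day component).
#' @param bias Fixed proportional measurement bias (e.g. -0.08 for -8%).
#' @param is_area Nominal internal-standard peak area.
#' @return An object of class `bio_batch_design`.
#' @export
bio_batch_design <- function(standard_levels = c(6, 12, 18.75, 25, 37.5, 50,
                                                 75, 100, 150, 200),
                             qc_levels = c(20, 80, 140),
                             replicates_per_level = 6, n_days = 3,
                             true_slope = 0.0116, true_intercept = 0.1429,
                             noise_cv = 0.05, day_sd = 0.06, bias = -0.08,
                             is_area = 1e5) {
  stopifnot(length(standard_levels) >= 2, all(standard_levels > 0),
            all(qc_levels > 0), replicates_per_level >= 2, n_days >= 1,
            true_slope > 0, noise_cv >= 0, day_sd >= 0, is_area > 0)
  structure(list(standard_levels = standard_levels, qc_levels = qc_levels,
                 replicates_per_level = replicates_per_level, n_days = n_days,
                 true_slope = true_slope, true_intercept = true_intercept,
                 noise_cv = noise_cv, day_sd = day_sd, bias = bias,
                 is_area = is_area),
            class = "bio_batch_design")
}

mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  out <- 1 + stats::rnorm(n, 0, cv)
  for (it in 1:100) {             # resample non-physical negative responses
    neg <- which(out <= 0)
    if (!length(neg)) break
    out[neg] <- 1 + stats::rnorm(length(neg), 0, cv)
  }
  out
}

#' Generate a raw bioanalytical batch
#'
#' Returns peak-area rows for calibration standards (one per level, noise
#' only) and QC replicates (per level, day and replicate, with day effect and
#' bias). Area ratios follow the design's linear response model.
#'
#' @param design A [bio_batch_design()].
#' @param seed Integer seed.
#' @return A data.frame with columns `type` ("standard"/"qc"), `level`
#'   (nominal ng/mL), `day`, `replicate`, `analyte_area`, `is_area`.
#' @export
generate_bio_batch <- function(design = bio_batch_design(), seed) {
  stopifnot(inherits(design, "bio_batch_design"))
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  ratio_of <- function(conc) design$true_slope * conc + design$true_intercept
  std <- data.frame(type = "standard", level = design$standard_levels,
                    day = 1L, replicate = 1L)
  std$is_area <- design$is_area * mult_noise(nrow(std), design$noise_cv / 4)
  std$analyte_area <- ratio_of(std$level) *
    mult_noise(nrow(std), design$noise_cv) * std$is_area
  qc <- expand.grid(replicate = seq_len(design$replicates_per_level),
                    day = seq_len(design$n_days),
                    level = design$qc_levels)
  qc <- data.frame(type = "qc", level = qc$level, day = qc$day,
                   replicate = qc$replicate)
  day_eff <- stats::rnorm(design$n_days, 0, design$day_sd)
  qc$is_area <- design$is_area * mult_noise(nrow(qc), design$noise_cv / 4)
  qc$analyte_area <- ratio_of(qc$level * (1 + design$bias)) *
    exp(day_eff[qc$day]) * mult_noise(nrow(qc), design$noise_cv) * qc$is_area
  rbind(std, qc[, names(std)])
}

#' Generate matrix-effect / recovery area tables
#'
#' Three preparations at each QC level for each donor matrix: neat standard
#' solutions, blank extracts spiked after extraction (post), and samples
#' spiked before extraction (pre). Analyte and internal standard are
#' suppressed by the same matrix factor and lose the same fraction to
#' extraction, so the IS-normalized matrix effect and recovery are 1 by
#' construction (up to noise).
#'
#' @param matrix_effect True post/neat area ratio (ion suppression).
#' @param recovery True pre/post area ratio (extraction efficiency).
#' @param levels QC levels, ng/mL.
#' @param n_matrices Number of donor matrices.
#' @param noise_cv Multiplicative area noise CV.
#' @param seed Integer seed.
#' @return A data.frame with columns `level`, `matrix`, `preparation`
#'   ("neat"/"post"/"pre"), `analyte_area`, `is_area`.
#' @export
generate_matrix_batch <- function(matrix_effect = 0.70, recovery = 0.50,
                                  levels = c(20, 80, 140), n_matrices = 3,
                                  noise_cv = 0.04, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  base_is <- 1e5
  grid <- expand.grid(level = levels, matrix = seq_len(n_matrices),
                      preparation = c("neat", "post", "pre"),
                      stringsAsFactors = FALSE)
  fac <- c(neat = 1, post = matrix_effect, pre = matrix_effect * recovery)
  n <- nrow(grid)
  grid$analyte_area <- (0.0116 * grid$level + 0.1429) * base_is *
    fac[grid$preparation] * mult_noise(n, noise_cv)
  grid$is_area <- base_is * fac[grid$preparation] * mult_noise(n, noise_cv)
  grid
}
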