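# Statistical content of the LC-MS/MS method validation: weighted linear
# calibration and back-calculation, intra/inter-day accuracy and precision of
# QC replicate batches, LLOQ / carryover / selectivity acceptance rules, and
# matrix effect / extraction recovery with internal-standard normalization.

#' Fit a weighted linear calibration curve
#'
#' Weighted least squares of the analyte/IS response ratio on nominal
#' concentration. Weighting `1/x^2` (the default, standard for wide dynamic
#' ranges), `1/x` or `none`, with weights on nominal concentration.
#'
#' @param standards A data.frame with columns `nominal` (ng/mL) and `response`
#'   (area ratio), or a [generate_bio_batch()] table (standard rows are used
#'   and the ratio computed from the areas).
#' @param weighting `"1/x^2"`, `"1/x"` or `"none"`.
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `r2` (weighted), `weighting` and the standards used.
#' @export
fit_calibration <- function(standards, weighting = c("1/x^2", "1/x", "none")) {
  weighting <- match.arg(weighting)
  if (!("response" %in% names(standards)) &&
      all(c("analyte_area", "is_area") %in% names(standards))) {
    std <- standards[standards$type == "standard", , drop = FALSE]
    standards <- data.frame(nominal = std$level,
                            response = std$analyte_area / std$is_area)
  }
  stopifnot(all(c("nominal", "response") %in% names(standards)))
  x <- standards$nominal; y <- standards$response
  if (length(unique(x)) < 2) {
    stop("need at least two distinct nominal levels", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("degenerate fit: identical responses at distinct levels",
         call. = FALSE)
  }
  w <- switch(weighting, "none" = rep(1, length(x)), "1/x" = 1 / x,
              "1/x^2" = 1 / x^2)
  fit <- stats::lm(y ~ x, weights = w)
  # weighted R^2 computed directly (summary.lm warns on exact fits)
  ybar <- stats::weighted.mean(y, w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (y - ybar)^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 weighting = weighting,
                 standards = data.frame(nominal = x, response = y)),
            class = "calibration_curve")
}

#' Manually specify a calibration curve
#'
#' @param slope,intercept Coefficients of `response = slope * conc + intercept`.
#' @return A `calibration_curve` (without standards or r2).
#' @export
calibration_curve <- function(slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept, r2 = NA_real_,
                 weighting = NA_character_, standards = NULL),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: y = %.6gx + %.6g  (weighting %s, r2 %s)\n",
              x$slope, x$intercept, x$weighting,
              ifelse(is.na(x$r2), "-", sprintf("%.4f", x$r2))))
  invisible(x)
}

#' Predicted response at a nominal concentration
#'
#' @param object A `calibration_curve`.
#' @param conc Concentration(s), ng/mL.
#' @param ... Unused.
#' @return Response ratio(s).
#' @export
predict.calibration_curve <- function(object, conc, ...) {
  object$slope * conc + object$intercept
}

#' Back-calculate concentration from a response ratio
#'
#' `x = (response - intercept) / slope`; the exact algebraic inverse of
#' [predict.calibration_curve()]. Negative results are flagged with a warning
#' but retained (QC arithmetic needs the raw value).
#'
#' @param curve A `calibration_curve`.
#' @param response Response ratio(s).
#' @return Concentration(s), ng/mL.
#' @examples
#' back_calculate(calibration_curve(0.0116, 0.1429), 1.303)
#' @export
back_calculate <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  x <- (response - curve$intercept) / curve$slope
  if (any(x < 0)) {
    warning(sum(x < 0), " back-calculated concentration(s) below zero",
            call. = FALSE)
  }
  x
}

#' Intra- and inter-day accuracy and precision of a QC level
#'
#' Replicate concentrations measured on several days are summarised two ways:
#' intra-day as the mean of the day means with the pooled within-day SD, and
#' inter-day as the grand mean and total SD over all replicates. Accuracy is
#' `100 * mean / nominal`, RSD is `100 * SD / mean`. An alternative one-way
#' ANOVA variance decomposition is available (`method = "anova"`): within-day
#' SD from the residual mean square, inter-day SD from the sum of the within-
#' and between-day variance components.
#'
#' @param batch A data.frame with columns `day` and `conc` (ng/mL); or a
#'   [generate_bio_batch()] table plus a `curve` to back-calculate the QC rows
#'   at this nominal level.
#' @param nominal Nominal QC concentration, ng/mL.
#' @param curve Optional `calibration_curve` for raw-area input.
#' @param method `"pooled"` (default) or `"anova"`.
#' @return An object of class `qc_batch`: `level`, `n`, `n_days`, and `intra`
#'   / `inter` lists with `mean`, `sd`, `rsd`, `accuracy`.
#' @export
qc_statistics <- function(batch, nominal, curve = NULL,
                          method = c("pooled", "anova")) {
  method <- match.arg(method)
  stopifnot(nominal > 0)
  if (!("conc" %in% names(batch))) {
    stopifnot(!is.null(curve))
    qc <- batch[batch$type == "qc" & batch$level == nominal, , drop = FALSE]
    batch <- data.frame(day = qc$day,
                        conc = back_calculate(curve,
                                              qc$analyte_area / qc$is_area))
  }
  stopifnot(all(c("day", "conc") %in% names(batch)), nrow(batch) >= 2)
  days <- split(batch$conc, batch$day)
  if (any(vapply(days, length, integer(1)) < 2)) {
    warning("some days have fewer than 2 replicates; statistics computed on ",
            "available data", call. = FALSE)
  }
  day_means <- vapply(days, mean, numeric(1))
  if (method == "pooled") {
    intra_mean <- mean(day_means)
    day_vars <- vapply(days, stats::var, numeric(1))
    intra_sd <- sqrt(mean(day_vars, na.rm = TRUE))
  } else {
    fit <- stats::aov(conc ~ factor(day), data = batch)
    ms <- summary(fit)[[1]]$`Mean Sq`
    n_per <- mean(vapply(days, length, integer(1)))
    intra_mean <- mean(day_means)
    intra_sd <- sqrt(ms[2])
    sig_b2 <- max(0, (ms[1] - ms[2]) / n_per)
  }
  inter_mean <- mean(batch$conc)
  inter_sd <- if (method == "pooled") stats::sd(batch$conc) else
    sqrt(intra_sd^2 + sig_b2)
  mk <- function(m, s) list(mean = m, sd = s, rsd = 100 * s / m,
                            accuracy = 100 * m / nominal)
  structure(list(level = nominal, n = nrow(batch), n_days = length(days),
                 method = method,
                 intra = mk(intra_mean, intra_sd),
                 inter = mk(inter_mean, inter_sd)),
            class = "qc_batch")
}

#' @export
print.qc_batch <- function(x, ...) {
  cat(sprintf("QC level %g ng/mL (%d replicates over %d days, %s estimator)\n",
              x$level, x$n, x$n_days, x$method))
  for (side in c("intra", "inter")) {
    s <- x[[side]]
    cat(sprintf("  %s-day: mean %.2f +/- %.2f  RSD %.2f%%  accuracy %.2f%%\n",
                side, s$mean, s$sd, s$rsd, s$accuracy))
  }
  invisible(x)
}

#' LLOQ acceptance check
#'
#' Passes when signal-to-noise >= its minimum, accuracy lies within the
#' 80-120% window (inclusive) and RSD is strictly below its maximum.
#'
#' @param level_stats A [qc_statistics()] result at the candidate LLOQ level,
#'   or a list with `accuracy` and `rsd` (%).
#' @param snr Signal-to-noise ratio at the LLOQ.
#' @param thresholds A [threshold_config()].
#' @return A list: `pass` (logical) and `reasons` (character, failures only).
#' @export
lloq_check <- function(level_stats, snr, thresholds = threshold_config()) {
  acc <- if (inherits(level_stats, "qc_batch")) level_stats$inter$accuracy
         else level_stats$accuracy
  rsd <- if (inherits(level_stats, "qc_batch")) level_stats$inter$rsd
         else level_stats$rsd
  reasons <- character(0)
  if (!(snr >= thresholds$lloq_snr_min)) {
    reasons <- c(reasons, sprintf("signal-to-noise %.3g below %g", snr,
                                  thresholds$lloq_snr_min))
  }
  rng <- thresholds$lloq_accuracy_range
  if (!(acc >= rng[1] && acc <= rng[2])) {
    reasons <- c(reasons, sprintf("accuracy %.4g%% outside [%g, %g]%%", acc,
                                  rng[1], rng[2]))
  }
  if (!(rsd < thresholds$lloq_rsd_max)) {
    reasons <- c(reasons, sprintf("RSD %.4g%% not below %g%%", rsd,
                                  thresholds$lloq_rsd_max))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Carryover and selectivity acceptance checks
#'
#' Pass when the blank signal is strictly below 20% (carryover) or 2%
#' (selectivity) of the LLOQ signal.
#'
#' @param blank_signal Signal in the blank, area units.
#' @param lloq_signal Signal at the LLOQ (> 0).
#' @param mode `"carryover"` or `"selectivity"`.
#' @param thresholds A [threshold_config()].
#' @return A list: `pass`, `ratio`, `limit`.
#' @export
carryover_selectivity_check <- function(blank_signal, lloq_signal,
                                        mode = c("carryover", "selectivity"),
                                        thresholds = threshold_config()) {
  mode <- match.arg(mode)
  if (lloq_signal <= 0) stop("LLOQ signal must be positive", call. = FALSE)
  ratio <- blank_signal / lloq_signal
  limit <- if (mode == "carryover") thresholds$carryover_max_frac else
    thresholds$selectivity_max_frac
  list(pass = ratio < limit, ratio = ratio, limit = limit)
}

#' Matrix effect and extraction recovery with IS normalization
#'
#' Matrix effect is the mean analyte-area ratio of post-extraction-spiked
#' samples to neat standard solutions; recovery is the mean ratio of
#' pre-extraction to post-extraction spiked samples. The IS-normalized
#' versions divide the analyte ratio by the corresponding internal-standard
#' ratio, so equal suppression/losses of analyte and IS normalize to 1.
#'
#' @param neat,post_spiked,pre_spiked Data.frames with columns `analyte_area`
#'   and `is_area` (and optionally `level` / `matrix` used for matching);
#'   rows must correspond across the three preparations. Alternatively pass a
#'   [generate_matrix_batch()] table as `neat` alone.
#' @return An object of class `matrix_recovery_result`: `matrix_effect`,
#'   `is_normalized_me`, `recovery`, `is_normalized_recovery`, and the RSD
#'   (%) of each.
#' @export
matrix_recovery <- function(neat, post_spiked = NULL, pre_spiked = NULL) {
  if (is.null(post_spiked) && "preparation" %in% names(neat)) {
    key <- function(d) order(d$level, d$matrix)
    batch <- neat
    neat <- batch[batch$preparation == "neat", , drop = FALSE]
    post_spiked <- batch[batch$preparation == "post", , drop = FALSE]
    pre_spiked <- batch[batch$preparation == "pre", , drop = FALSE]
    neat <- neat[key(neat), ]; post_spiked <- post_spiked[key(post_spiked), ]
    pre_spiked <- pre_spiked[key(pre_spiked), ]
  }
  stopifnot(nrow(neat) == nrow(post_spiked), nrow(neat) == nrow(pre_spiked))
  ok <- neat$analyte_area > 0 & neat$is_area > 0 & post_spiked$analyte_area > 0
  if (any(!ok)) {
    message(sum(!ok), " pair(s) with zero areas excluded")
    neat <- neat[ok, ]; post_spiked <- post_spiked[ok, ]
    pre_spiked <- pre_spiked[ok, ]
  }
  me <- post_spiked$analyte_area / neat$analyte_area
  me_is <- post_spiked$is_area / neat$is_area
  rec <- pre_spiked$analyte_area / post_spiked$analyte_area
  rec_is <- pre_spiked$is_area / post_spiked$is_area
  rsd <- function(x) 100 * stats::sd(x) / mean(x)
  structure(list(matrix_effect = mean(me), matrix_effect_rsd = rsd(me),
                 is_normalized_me = mean(me / me_is),
                 is_normalized_me_rsd = rsd(me / me_is),
                 recovery = mean(rec), recovery_rsd = rsd(rec),
                 is_normalized_recovery = mean(rec / rec_is),
                 is_normalized_recovery_rsd = rsd(rec / rec_is),
                 n = nrow(neat)),
            class = "matrix_recovery_result")
}

#' @export
print.matrix_recovery_result <- function(x, ...) {
  cat(sprintf(paste0("Matrix effect %.3f (RSD %.1f%%), IS-normalized %.3f\n",
                     "Recovery %.3f (RSD %.1f%%), IS-normalized %.3f\n"),
              x$matrix_effect, x$matrix_effect_rsd, x$is_normalized_me,
              x$recovery, x$recovery_rsd, x$is_normalized_recovery))
  invisible(x)
}
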