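# External-validation statistics: relative prediction errors, their median
# summaries (MdPE bias, MdAPE imprecision), the F20/F30 accuracy fractions,
# stratified errors, R squared, and the predefined acceptability gates.

#' Acceptability thresholds and assay limits
#'
#' The predefined external-validation gates (MdPE within -20% to 20%,
#' MdAPE <= 30%, F20 >= 35%, F30 >= 50%), the concentration band edges for
#' stratified errors (100 and 150 ng/mL), and the bioanalytical acceptance
#' limits (carryover < 20% and selectivity < 2% of the LLOQ signal; LLOQ
#' accuracy 80-120%, RSD < 20%, signal-to-noise >= 10).
#'
#' @param mdpe_low,mdpe_high Bias gate bounds, %.
#' @param mdape_max Imprecision gate, %.
#' @param f20_min,f30_min Accuracy gates, %.
#' @param band_edges Concentration cut points (ng/mL) for stratified errors;
#'   bands are `[0, e1)`, `[e1, e2]`, `(e2, Inf)`.
#' @param carryover_max_frac,selectivity_max_frac Blank-to-LLOQ signal limits.
#' @param lloq_accuracy_range Accuracy window at the LLOQ, %.
#' @param lloq_rsd_max RSD limit at the LLOQ, % (strict).
#' @param lloq_snr_min Minimum signal-to-noise ratio at the LLOQ.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(mdpe_low = -20, mdpe_high = 20, mdape_max = 30,
                             f20_min = 35, f30_min = 50,
                             band_edges = c(100, 150),
                             carryover_max_frac = 0.20,
                             selectivity_max_frac = 0.02,
                             lloq_accuracy_range = c(80, 120),
                             lloq_rsd_max = 20, lloq_snr_min = 10) {
  stopifnot(mdpe_low < mdpe_high, mdape_max > 0,
            length(band_edges) == 2, band_edges[1] < band_edges[2])
  structure(list(mdpe_low = mdpe_low, mdpe_high = mdpe_high,
                 mdape_max = mdape_max, f20_min = f20_min, f30_min = f30_min,
                 band_edges = band_edges,
                 carryover_max_frac = carryover_max_frac,
                 selectivity_max_frac = selectivity_max_frac,
                 lloq_accuracy_range = lloq_accuracy_range,
                 lloq_rsd_max = lloq_rsd_max, lloq_snr_min = lloq_snr_min),
            class = "threshold_config")
}

#' Relative prediction error
#'
#' `PE (%) = (Cpred - Cobs) / Cobs * 100`. Vectorized.
#'
#' @param cpred Predicted concentration(s), ng/mL.
#' @param cobs Observed concentration(s), ng/mL; must be > 0.
#' @return Prediction error(s) in percent.
#' @examples
#' prediction_error(90, 100)   # -10
#' @export
prediction_error <- function(cpred, cobs) {
  if (any(cobs <= 0)) {
    stop("prediction error is undefined for non-positive observations",
         call. = FALSE)
  }
  (cpred - cobs) / cobs * 100
}

#' Assemble per-observation prediction records
#'
#' Aligns observed DV with population and individual predictions for the
#' dataset's observation rows.
#'
#' @param dataset A [cohort_dataset()].
#' @param pred PRED vector (e.g. from [population_predict()]).
#' @param ipred Optional IPRED vector (e.g. from [individual_predict()]).
#' @param npde Optional NPDE vector.
#' @return A data.frame with columns `ID`, `TIME`, `NTIME` (if present), `DV`,
#'   `PRED`, `IPRED`, `NPDE`.
#' @export
prediction_records <- function(dataset, pred, ipred = NULL, npde = NULL) {
  obs <- dataset[dataset$EVID == 0, , drop = FALSE]
  stopifnot(length(pred) == nrow(obs))
  out <- data.frame(ID = obs$ID, TIME = obs$TIME,
                    NTIME = if ("NTIME" %in% names(obs)) obs$NTIME else NA,
                    DV = obs$DV, PRED = pred,
                    IPRED = if (is.null(ipred)) NA_real_ else ipred,
                    NPDE = if (is.null(npde)) NA_real_ else npde)
  out[obs$MDV == 0, , drop = FALSE]
}

band_of <- function(dv, edges) {
  cut(dv, breaks = c(-Inf, edges[1] - .Machine$double.eps * edges[1],
                     edges[2], Inf),
      labels = c(sprintf("<%g", edges[1]),
                 sprintf("%g-%g", edges[1], edges[2]),
                 sprintf(">%g", edges[2])))
}

#' External-validation metric suite
#'
#' Computes, at the chosen prediction level, the mean prediction error
#' `MPE = mean(Cpred - Cobs)` (ng/mL, with SD and a one-sample test p-value),
#' the median relative prediction error MdPE (%, bias), the median absolute
#' relative prediction error MdAPE (%, imprecision), the fractions F20/F30 of
#' observations predicted within +/-20%/+/-30%, the MdPE stratified by
#' concentration band, and the squared Pearson correlation of observed versus
#' predicted. Records with `Cobs = 0` are excluded with a message.
#'
#' @param records A [prediction_records()] data.frame (columns DV and
#'   PRED/IPRED).
#' @param level `"population"` (uses PRED) or `"individual"` (uses IPRED).
#' @param thresholds A [threshold_config()]; band edges and gates come from it.
#' @param mpe_test `"t"` (one-sample t-test, default) or `"wilcoxon"`
#'   (signed-rank) for the MPE p-value.
#' @return An object of class `validation_report`.
#' @export
metric_suite <- function(records, level = c("population", "individual"),
                         thresholds = threshold_config(),
                         mpe_test = c("t", "wilcoxon")) {
  level <- match.arg(level)
  mpe_test <- match.arg(mpe_test)
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  cpred <- if (level == "population") records$PRED else records$IPRED
  cobs <- records$DV
  keep <- !is.na(cobs) & !is.na(cpred)
  if (any(keep & cobs <= 0)) {
    message(sum(keep & cobs <= 0),
            " record(s) with non-positive DV excluded from relative errors")
    keep <- keep & cobs > 0
  }
  if (!any(keep)) stop("no usable records", call. = FALSE)
  cpred <- cpred[keep]; cobs <- cobs[keep]
  resid <- cpred - cobs
  pe <- prediction_error(cpred, cobs)
  ape <- abs(pe)
  mpe_p <- if (length(resid) >= 2 && stats::sd(resid) > 0) {
    if (mpe_test == "t") stats::t.test(resid)$p.value
    else stats::wilcox.test(resid)$p.value
  } else NA_real_
  bands <- band_of(cobs, thresholds$band_edges)
  strat <- tapply(pe, bands, stats::median)
  r2 <- if (length(cobs) >= 2 && stats::sd(cobs) > 0 && stats::sd(cpred) > 0) {
    stats::cor(cobs, cpred)^2
  } else if (all(resid == 0)) 1 else NA_real_
  report <- structure(list(
    n_obs = length(cobs),
    prediction_level = level,
    mpe = mean(resid), mpe_sd = stats::sd(resid), mpe_p = mpe_p,
    mdpe = stats::median(pe), mdape = stats::median(ape),
    f20 = 100 * mean(ape <= 20), f30 = 100 * mean(ape <= 30),
    r2 = r2,
    stratified_mdpe = strat,
    thresholds = thresholds
  ), class = "validation_report")
  report$gates <- acceptability_gate(report, thresholds)
  report
}

#' Acceptability gate verdicts
#'
#' Applies the predefined criteria: bias passes when MdPE lies within the
#' configured bounds, precision when MdAPE does not exceed its maximum, and
#' F20/F30 when they meet their minima; `overall` is the conjunction.
#'
#' @param report A [metric_suite()] result, or any list with numeric elements
#'   `mdpe`, `mdape`, `f20`, `f30`.
#' @param thresholds A [threshold_config()].
#' @return Named logical vector: `bias`, `precision`, `f20`, `f30`, `overall`.
#' @examples
#' acceptability_gate(list(mdpe = -9.86, mdape = 33.28, f20 = 24.5, f30 = 43.4))
#' @export
acceptability_gate <- function(report, thresholds = threshold_config()) {
  v <- c(bias = report$mdpe >= thresholds$mdpe_low &&
           report$mdpe <= thresholds$mdpe_high,
         precision = report$mdape <= thresholds$mdape_max,
         f20 = report$f20 >= thresholds$f20_min,
         f30 = report$f30 >= thresholds$f30_min)
  c(v, overall = all(v))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("External validation (%s predictions), n = %d\n",
              x$prediction_level, x$n_obs))
  cat(sprintf("  MPE  %8.3f ng/mL (SD %.2f, p = %.3f)\n", x$mpe, x$mpe_sd,
              x$mpe_p))
  cat(sprintf("  MdPE %8.2f %%    MdAPE %.2f %%\n", x$mdpe, x$mdape))
  cat(sprintf("  F20  %8.1f %%    F30   %.1f %%    R2 %.4f (%.2f %%)\n",
              x$f20, x$f30, x$r2, 100 * x$r2))
  cat("  stratified MdPE (%):",
      paste(sprintf("%s: %s", names(x$stratified_mdpe),
                    ifelse(is.na(x$stratified_mdpe), "absent",
                           sprintf("%.2f", x$stratified_mdpe))),
            collapse = "  "), "\n")
  g <- x$gates
  cat("  gates:", paste(sprintf("%s %s", names(g),
                                ifelse(g, "pass", "FAIL")), collapse = "  "),
      "\n")
  invisible(x)
}

report_flat <- function(report) {
  strat <- as.numeric(report$stratified_mdpe)
  names(strat) <- paste0("stratified_mdpe_", c("low", "mid", "high"))
  c(n_obs = report$n_obs, mpe = report$mpe, mpe_sd = report$mpe_sd,
    mpe_p = report$mpe_p, mdpe = report$mdpe, mdape = report$mdape,
    f20 = report$f20, f30 = report$f30, r2 = report$r2, strat,
    gate_bias = as.numeric(report$gates[["bias"]]),
    gate_precision = as.numeric(report$gates[["precision"]]),
    gate_f20 = as.numeric(report$gates[["f20"]]),
    gate_f30 = as.numeric(report$gates[["f30"]]),
    gate_overall = as.numeric(report$gates[["overall"]]))
}

#' Write a validation report to JSON or CSV
#'
#' JSON carries the metrics, the gate verdicts and the threshold configuration
#' used; CSV is a flat `metric,value` table that round-trips through
#' [read_report()].
#'
#' @param report A [metric_suite()] result.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (is.null(report$n_obs) || !isTRUE(report$n_obs >= 1) ||
      !is.finite(report$mdpe)) {
    stop("refusing to write an empty or unpopulated report", call. = FALSE)
  }
  if (format == "json") {
    payload <- list(
      n_obs = report$n_obs, prediction_level = report$prediction_level,
      mpe = report$mpe, mpe_sd = report$mpe_sd, mpe_p = report$mpe_p,
      mdpe = report$mdpe, mdape = report$mdape,
      f20 = report$f20, f30 = report$f30, r2 = report$r2,
      stratified_mdpe = as.list(report$stratified_mdpe),
      gates = as.list(report$gates),
      thresholds = unclass(report$thresholds)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    flat <- report_flat(report)
    utils::write.csv(data.frame(metric = names(flat),
                                value = unname(flat)),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a flat CSV validation report
#'
#' @param path Path written by [write_report()] with `format = "csv"`.
#' @return Named numeric vector of metrics.
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$metric)
}

#' Linear trapezoidal area under the curve
#'
#' AUC over the observed span only (no extrapolation).
#'
#' @param times Strictly increasing times, h (>= 2 points).
#' @param conc Non-negative concentrations, ng/mL.
#' @return AUC in ng*h/mL.
#' @examples
#' auc_trapezoid(c(0, 2, 4, 6), c(82, 129, 141, 120))
#' @export
auc_trapezoid <- function(times, conc) {
  if (length(times) < 2 || length(conc) != length(times)) {
    stop("need >= 2 matching time/concentration points", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0) || any(!is.finite(conc))) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
}

#' Non-compartmental summary of a cohort
#'
#' Per-subject trapezoidal AUC from first to last observation, and mean/SD of
#' DV at each nominal sampling time.
#'
#' @param dataset A [cohort_dataset()] with an `NTIME` column for the
#'   timepoint summaries (skipped otherwise).
#' @return A list with `per_subject` (ID, n, auc_0_last) and
#'   `timepoint_summary` (NTIME, n, mean, sd) data.frames.
#' @export
nca_summary <- function(dataset) {
  obs <- observation_rows(dataset)
  per <- do.call(rbind, lapply(split(obs, obs$ID), function(s) {
    s <- s[order(s$TIME), ]
    s <- s[!duplicated(s$TIME), , drop = FALSE]
    data.frame(ID = s$ID[1], n = nrow(s),
               auc_0_last = if (nrow(s) >= 2)
                 auc_trapezoid(s$TIME, s$DV) else NA_real_)
  }))
  rownames(per) <- NULL
  tp <- NULL
  if ("NTIME" %in% names(obs) && !all(is.na(obs$NTIME))) {
    tp <- do.call(rbind, lapply(split(obs, obs$NTIME), function(s) {
      data.frame(NTIME = s$NTIME[1], n = nrow(s), mean = mean(s$DV),
                 sd = stats::sd(s$DV))
    }))
    rownames(tp) <- NULL
  }
  list(per_subject = per, timepoint_summary = tp)
}
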