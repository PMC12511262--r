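# NONMEM-conventional long-format dataset: one row per dose or observation.
# Canonical columns (upper case): ID, TIME, AMT, EVID, MDV, DV; optional CMT,
# NTIME (nominal sampling time), BLQ, and arbitrary covariate columns which
# pass through untouched (e.g. SEX, CYP3A4I, FOOD, DOSEGRP).

REQUIRED_COLS <- c("ID", "TIME", "AMT", "EVID", "MDV", "DV")

#' Construct and validate a cohort dataset
#'
#' Normalizes column names to the NONMEM-conventional upper-case dialect,
#' sorts rows by subject then time, and enforces the schema invariants:
#' dosing rows (`EVID = 1`) carry `AMT > 0` and no `DV`; observation rows
#' (`EVID = 0`) carry `DV >= 0` (unless `MDV = 1`) and no `AMT`; times are
#' non-negative and non-decreasing within subject; every subject has at least
#' one dosing row at or before its first observation.
#'
#' @param df A data.frame with (case-insensitive) columns ID, TIME, AMT, EVID,
#'   MDV, DV; extra columns are kept.
#' @return A validated `cohort_dataset` (a data.frame subclass).
#' @export
cohort_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  names(df) <- toupper(names(df))
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[order(match(df$ID, unique(df$ID)), df$TIME, -df$EVID), , drop = FALSE]
  rownames(df) <- NULL
  validate_dataset(df)
  structure(df, class = c("cohort_dataset", "data.frame"))
}

validate_dataset <- function(df) {
  if (!all(df$EVID %in% c(0L, 1L))) {
    stop("EVID must be 0 (observation) or 1 (dose)", call. = FALSE)
  }
  if (any(!is.finite(df$TIME)) || any(df$TIME < 0)) {
    stop("TIME must be finite and non-negative", call. = FALSE)
  }
  dose <- df$EVID == 1
  if (any(dose & (is.na(df$AMT) | df$AMT <= 0))) {
    stop("dosing rows (EVID=1) must have AMT > 0", call. = FALSE)
  }
  if (any(dose & !is.na(df$DV))) {
    stop("dosing rows (EVID=1) must not carry a DV value", call. = FALSE)
  }
  obs <- df$EVID == 0
  if (any(obs & !is.na(df$AMT) & df$AMT != 0)) {
    stop("observation rows (EVID=0) must not carry a dose amount", call. = FALSE)
  }
  bad_dv <- obs & df$MDV == 0 & (is.na(df$DV) | df$DV < 0)
  if (any(bad_dv)) {
    stop("observation rows with MDV=0 must have DV >= 0", call. = FALSE)
  }
  for (id in unique(df$ID)) {
    sub <- df[df$ID == id, , drop = FALSE]
    if (is.unsorted(sub$TIME)) {
      stop(sprintf("times are not non-decreasing within subject %s", id),
           call. = FALSE)
    }
    first_obs <- which(sub$EVID == 0)
    first_dose <- which(sub$EVID == 1)
    if (length(first_obs) && (!length(first_dose) ||
                              sub$TIME[first_dose[1]] > sub$TIME[first_obs[1]])) {
      stop(sprintf("subject %s has an observation before any dose", id),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a NONMEM-style cohort dataset from CSV
#'
#' Columns are matched case-insensitively; missing values may be empty fields
#' or `.` (the NONMEM convention). A short parse report (rows, subjects,
#' observations) is emitted as a message.
#'
#' @param path Path to a comma-separated UTF-8 file with a header row.
#' @param quiet Suppress the parse report.
#' @return A [cohort_dataset()].
#' @export
read_dataset <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, na.strings = c("NA", "", "."),
                        stringsAsFactors = FALSE)
  ds <- cohort_dataset(df)
  if (!quiet) {
    message(sprintf("read %d rows: %d subjects, %d observations, %d doses",
                    nrow(ds), length(unique(ds$ID)), sum(ds$EVID == 0),
                    sum(ds$EVID == 1)))
  }
  ds
}

#' Write a cohort dataset to CSV
#'
#' Missing values are written as `.` so the file round-trips through
#' [read_dataset()] unchanged.
#'
#' @param dataset A [cohort_dataset()].
#' @param path Output file path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, na = ".")
  invisible(path)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("Cohort dataset: %d subjects, %d observations, %d dosing rows\n",
              length(unique(x$ID)), sum(x$EVID == 0), sum(x$EVID == 1)))
  NextMethod()
}

# observation rows with a usable DV
observation_rows <- function(dataset) {
  dataset[dataset$EVID == 0 & dataset$MDV == 0, , drop = FALSE]
}
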