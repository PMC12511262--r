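# Shared fixtures, built in code.

# a tiny hand-written two-subject dataset: one dose + two observations each
tiny_dataset <- function() {
  cohort_dataset(data.frame(
    ID = c(1, 1, 1, 2, 2, 2),
    TIME = c(0, 2, 6, 0, 2, 6),
    AMT = c(30, NA, NA, 30, NA, NA),
    EVID = c(1, 0, 0, 1, 0, 0),
    MDV = c(1, 0, 0, 1, 0, 0),
    DV = c(NA, 100, 80, NA, 120, 90)
  ))
}

# prediction records with prescribed relative prediction errors at DV = 100
records_with_pe <- function(pe) {
  data.frame(ID = seq_along(pe), TIME = 1, NTIME = 1,
             DV = 100, PRED = 100 * (1 + pe / 100),
             IPRED = 100 * (1 + pe / 100), NPDE = NA_real_)
}

# noiseless single-subject dataset at a known eta, for MAP recovery
noiseless_subject <- function(params, eta, model, offsets = c(0, 2, 4, 6)) {
  ind <- apply_iiv(params, eta, model)
  reg <- dosing_regimen(30, 24, "auto")
  n <- length(quizpk:::dose_schedule(params, reg)$times)
  dose_times <- 24 * (seq_len(n) - 1)
  t_obs <- 24 * (n - 1) + offsets
  dv <- quizpk:::conc_superposition(ind$realized, dose_times, rep(30, n), t_obs)
  cohort_dataset(data.frame(
    ID = 1, TIME = c(dose_times, t_obs),
    NTIME = c(rep(NA, n), offsets),
    AMT = c(rep(30, n), rep(NA, length(t_obs))),
    EVID = c(rep(1L, n), rep(0L, length(t_obs))),
    MDV = c(rep(1L, n), rep(0L, length(t_obs))),
    DV = c(rep(NA, n), dv)
  ))
}
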