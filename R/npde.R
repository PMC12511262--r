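# Normalized prediction distribution errors: each subject's observation
# vector and its model simulations are decorrelated with the simulated mean
# and the Cholesky factor of the simulated covariance; the rank of each
# decorrelated observation among its decorrelated simulations, inverse-normal
# transformed, is N(0,1) under a correct model.

#' Compute normalized prediction distribution errors
#'
#' @param records A [prediction_records()] data.frame (column `ID` groups
#'   subjects, `DV` holds the observations); rows must align with the rows of
#'   `simulated`.
#' @param simulated An `nrow(records)` x K matrix of simulated DV under the
#'   fixed model (see [simulate_replicates()]).
#' @param seed Integer seed for the uniform tie-breaking jitter.
#' @param min_k Minimum number of replicates accepted (rank resolution).
#' @return Numeric NPDE vector, one per record. Subjects whose simulated
#'   covariance is numerically singular fall back to variance-only
#'   decorrelation with a warning.
#' @export
npde_compute <- function(records, simulated, seed, min_k = 100L) {
  stopifnot(is.data.frame(records), is.matrix(simulated),
            nrow(simulated) == nrow(records))
  K <- ncol(simulated)
  if (K < min_k) {
    stop(sprintf("%d simulation replicates are too few; at least %d required",
                 K, min_k), call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  npde <- rep(NA_real_, nrow(records))
  idx <- split(seq_len(nrow(records)),
               factor(records$ID, levels = unique(records$ID)))
  fallback <- 0L
  for (rows in idx) {
    y <- records$DV[rows]
    sims <- simulated[rows, , drop = FALSE]
    m <- rowMeans(sims)
    centered <- sims - m
    if (length(rows) > 1L) {
      V <- tcrossprod(centered) / (K - 1)
      L <- tryCatch(t(chol(V)), error = function(e) NULL)
      # chol can succeed on a numerically rank-deficient covariance with a
      # near-zero pivot; treat that as singular too
      if (!is.null(L) && any(diag(L) < 1e-6 * max(diag(L)))) L <- NULL
    } else {
      L <- matrix(stats::sd(sims[1, ]))
      if (!is.finite(L[1]) || L[1] <= 0) L <- NULL
    }
    if (is.null(L)) {
      fallback <- fallback + 1L
      sdv <- apply(sims, 1, stats::sd)
      sdv[sdv <= 0] <- 1
      ystar <- (y - m) / sdv
      sstar <- centered / sdv
    } else {
      ystar <- forwardsolve(L, y - m)
      sstar <- forwardsolve(L, centered)
    }
    pde <- vapply(seq_along(rows), function(j) {
      below <- sum(sstar[j, ] < ystar[j])
      ties <- sum(sstar[j, ] == ystar[j])
      cnt <- below + if (ties) stats::runif(1) * ties else 0
      min(max(cnt, 0.5), K - 0.5) / K
    }, numeric(1))
    npde[rows] <- stats::qnorm(pde)
  }
  if (fallback > 0L) {
    warning(fallback, " subject(s) used variance-only decorrelation ",
            "(singular simulated covariance)", call. = FALSE)
  }
  npde
}

#' Summary tests of the NPDE null distribution
#'
#' Under a correct model NPDE is standard normal: returns the mean, variance,
#' a t-test of mean zero, and a Kolmogorov-Smirnov test against N(0,1).
#'
#' @param npde NPDE vector.
#' @return A list: `mean`, `var`, `t_p`, `ks_p`, `n`.
#' @export
npde_tests <- function(npde) {
  npde <- npde[is.finite(npde)]
  list(mean = mean(npde), var = stats::var(npde),
       t_p = stats::t.test(npde)$p.value,
       ks_p = suppressWarnings(stats::ks.test(npde, "pnorm")$p.value),
       n = length(npde))
}
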