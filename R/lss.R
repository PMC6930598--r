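#' Describe a linear-gradient HPLC run
#'
#' Geometry of one linear-gradient reversed-phase run. Defaults mirror the
#' instrument configuration used for the packaged isoxazolone data: a
#' 20-98% methanol gradient, a column dead time of 1.401 min and a dwell
#' time of 0.780 min at 1 mL/min.
#'
#' @param tG Gradient time (min).
#' @param phi0,phiF Initial and final organic volume fraction (0-1),
#'   `phiF > phi0`.
#' @param t0 Column dead time (min).
#' @param tD Dwell time (min), i.e. dwell volume over flow.
#' @param flow Flow rate (mL/min); metadata only.
#' @return A `gradient_run` list.
#' @export
gradient_run <- function(tG, phi0 = 0.20, phiF = 0.98, t0 = 1.401,
                         tD = 0.780, flow = 1) {
  if (tG <= 0) abort("gradient time tG must be positive")
  if (phiF <= phi0) abort("phiF must exceed phi0")
  if (t0 <= 0 || tD < 0) abort("t0 must be positive and tD non-negative")
  structure(list(tG = tG, phi0 = phi0, phiF = phiF, t0 = t0, tD = tD,
                 flow = flow),
            class = "gradient_run")
}

#' Retention time under the linear-solvent-strength gradient model
#'
#' Forward model for gradient elution under the linear-solvent-strength
#' (LSS) assumption `log k = log k_w - S phi`. The analyte migrates with
#' fractional velocity `dx/dt = 1 / (t0 (1 + k(phi(t))))`, where the
#' mobile-phase composition it experiences is `phi0` during the dwell time
#' `tD`, ramps linearly to `phiF` over the gradient time `tG`, and stays
#' at `phiF` afterwards (the within-column lag of the gradient front is
#' neglected, as usual for the two-run method). All three phases integrate
#' in closed form - during the gradient `k(t) = k0 exp(-beta (t - tD))`
#' with `k0 = 10^(log k_w - S phi0)` and
#' `beta = S (phiF - phi0) ln(10) / tG`, and the migration integral
#' inverts analytically - so the model is exact, not the classic
#' well-retained approximation: an unretained analyte (`k0 = 0`) elutes at
#' the dead time `t0`, and the `S -> 0` limit recovers isocratic elution
#' at `t0 (1 + k0)`.
#'
#' @param logkw Retention factor (log10) extrapolated to pure water;
#'   vectorized. `-Inf` encodes an unretained analyte.
#' @param S Solvent-strength slope per unit organic fraction (> 0);
#'   vectorized.
#' @param run A [gradient_run()].
#' @return Retention time(s) in minutes.
#' @examples
#' lss_retention_time(3, 4, gradient_run(tG = 20))
#' @export
lss_retention_time <- function(logkw, S, run) {
  stopifnot(inherits(run, "gradient_run"))
  if (any(S <= 0)) abort("S must be positive for reversed-phase behavior")
  n <- max(length(logkw), length(S))
  logkw <- rep_len(logkw, n)
  S <- rep_len(S, n)
  vapply(seq_len(n), function(i) {
    lss_tr_one(10^(logkw[i] - S[i] * run$phi0), S[i], run)
  }, numeric(1))
}

# exact single-analyte elution time given k0 at the initial composition
lss_tr_one <- function(k0, S, run) {
  t_iso <- run$t0 * (1 + k0)
  if (t_iso <= run$tD) return(t_iso) # elutes before the gradient front arrives
  xA <- run$tD / t_iso               # fraction migrated during the dwell
  beta <- S * (run$phiF - run$phi0) * log(10) / run$tG
  Cm <- run$t0 * (1 - xA)
  # solve tau + (1/beta) log((1 + k0 e^{-beta tau}) / (1 + k0)) = Cm:
  # tau = (1/beta) log((1 + k0) e^{beta Cm} - k0), in overflow-safe form
  tau <- (log1p(k0) + beta * Cm +
            log1p(-k0 * exp(-beta * Cm) / (1 + k0))) / beta
  if (tau <= run$tG) return(run$tD + tau)
  # gradient exhausted: finish isocratically at phiF
  FtG <- run$tG + (log1p(k0 * exp(-beta * run$tG)) - log1p(k0)) / beta
  xB <- xA + FtG / run$t0
  kF <- k0 * 10^(-S * (run$phiF - run$phi0))
  run$tD + run$tG + (1 - xB) * run$t0 * (1 + kF)
}

#' Recover (log k_w, S) from two gradient runs
#'
#' Inverts the LSS forward model given the retention times of each
#' compound in two linear-gradient runs that differ in gradient time. For
#' a trial `S`, `k0` (hence `log k_w`) is recovered from the first run's
#' retention time by bracketed root finding on the strictly increasing
#' forward model; `S` is then located the same way on the second run's
#' predicted retention time. The procedure is deterministic and
#' derivative-free, and the round-trip residual (max discrepancy of the
#' refitted retention times, min) is reported per compound.
#'
#' @param data Data frame with columns `compound`, `tR1`, `tR2` (min), or
#'   a two-column data frame `tR1`, `tR2`.
#' @param run1,run2 The two [gradient_run()] geometries (`tG` must
#'   differ). Defaults are the packaged 20 min and 40 min runs.
#' @param s_range Search interval for `S` (per unit fraction).
#' @return A tibble: `compound`, `logkw`, `S`, `converged`, `residual`.
#'   Retention at or below the dead time, or a pair of identical retention
#'   times at or below `t0 + tD` (gradient-insensitive), is an unretained
#'   error; compounds with no root in `s_range` come back with
#'   `converged = FALSE` and `NA` estimates.
#' @examples
#' r1 <- gradient_run(20); r2 <- gradient_run(40)
#' d <- tibble::tibble(compound = 1, tR1 = lss_retention_time(3, 4, r1),
#'                     tR2 = lss_retention_time(3, 4, r2))
#' estimate_lss_from_two_gradients(d, r1, r2)
#' @export
estimate_lss_from_two_gradients <- function(data, run1 = gradient_run(20),
                                            run2 = gradient_run(40),
                                            s_range = c(0.05, 50)) {
  stopifnot(inherits(run1, "gradient_run"), inherits(run2, "gradient_run"))
  if (run1$tG == run2$tG) abort("the two runs must differ in gradient time")
  data <- tibble::as_tibble(data)
  if (!all(c("tR1", "tR2") %in% names(data))) abort("data needs tR1 and tR2 columns")
  if (!"compound" %in% names(data)) data$compound <- seq_len(nrow(data))
  if (any(data$tR1 <= run1$t0) || any(data$tR2 <= run2$t0)) {
    abort("retention at or below the dead time: unretained analyte")
  }
  insensitive <- abs(data$tR1 - data$tR2) < 1e-9 &
    data$tR1 <= run1$t0 + run1$tD & data$tR2 <= run2$t0 + run2$tD
  if (any(insensitive)) {
    abort(paste0("unretained (gradient-insensitive) analyte(s): compound ",
                 paste(data$compound[insensitive], collapse = ", ")))
  }
  res <- purrr::map2(data$tR1, data$tR2, invert_lss_pair,
                     run1 = run1, run2 = run2, s_range = s_range)
  tibble::tibble(
    compound = data$compound,
    logkw = purrr::map_dbl(res, "logkw"),
    S = purrr::map_dbl(res, "S"),
    converged = purrr::map_lgl(res, "converged"),
    residual = purrr::map_dbl(res, "residual")
  )
}

# k0 from one run's retention time at trial S (forward model is strictly
# increasing in k0)
k0_from_tr <- function(tR, S, run, lk0_range = c(-6, 14)) {
  f <- function(lk0) lss_tr_one(10^lk0, S, run) - tR
  lo <- f(lk0_range[1]); hi <- f(lk0_range[2])
  if (lo > 0 || hi < 0) return(NA_real_)
  10^uniroot(f, lower = lk0_range[1], upper = lk0_range[2], tol = 1e-13)$root
}

invert_lss_pair <- function(tR1, tR2, run1, run2, s_range) {
  fail <- list(logkw = NA_real_, S = NA_real_, converged = FALSE,
               residual = NA_real_)
  g <- function(S) {
    k0 <- k0_from_tr(tR1, S, run1)
    if (is.na(k0)) return(NA_real_)
    logkw <- log10(k0) + S * run1$phi0
    lss_retention_time(logkw, S, run2) - tR2
  }
  grid <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = 60))
  gv <- vapply(grid, g, numeric(1))
  ok <- which(!is.na(gv))
  if (length(ok) < 2) return(fail)
  sgn <- sign(gv[ok])
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) {
    zero <- ok[gv[ok] == 0]
    if (!length(zero)) return(fail)
    S <- grid[zero[1]]
  } else {
    S <- uniroot(g, lower = grid[ok[flip[1]]], upper = grid[ok[flip[1] + 1]],
                 tol = 1e-12)$root
  }
  k0 <- k0_from_tr(tR1, S, run1)
  logkw <- log10(k0) + S * run1$phi0
  residual <- max(
    abs(lss_retention_time(logkw, S, run1) - tR1),
    abs(lss_retention_time(logkw, S, run2) - tR2)
  )
  list(logkw = logkw, S = S, converged = residual < 1e-6,
       residual = residual)
}
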