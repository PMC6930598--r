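#' Convert a TLC retardation factor to the R_M retention measure
#'
#' `R_M = log10(1/R_F - 1)` linearizes thin-layer retention so that it can
#' be regressed on the organic-modifier fraction of the mobile phase.
#'
#' @param rf Retardation factor(s), strictly inside (0, 1).
#' @return Numeric vector of R_M values.
#' @examples
#' rm_from_rf(c(0.25, 0.5, 0.8))
#' @export
rm_from_rf <- function(rf) {
  if (any(!is.finite(rf) | rf <= 0 | rf >= 1)) {
    abort("R_F values must lie strictly between 0 and 1")
  }
  log10(1 / rf - 1)
}

#' Fit the Soczewinski-Wachtmeister retention line for one compound
#'
#' Ordinary least squares of `R_M` on the organic-modifier volume fraction
#' `C` (dimensionless, 0-1): `R_M = R_M0 - m C`. The intercept `R_M0`
#' extrapolates retention to pure water, the slope magnitude `m` is the
#' hydrophobic constant, and their ratio `C0 = R_M0 / m` is the modifier
#' fraction at which the analyte partitions 1:1 between the phases.
#'
#' @param rm Numeric vector of R_M values at each modifier fraction.
#' @param fractions Modifier volume fractions (same length, >= 3, not all
#'   equal), on the 0-1 scale (not percent).
#' @return An `sw_fit` object with fields `rm0`, `m`, `c0`, `r`, `r2`, `F`,
#'   `s` (residual standard error), `n`, and `perfect` (TRUE when the fit is
#'   exact and the F statistic is infinite). [tidy()] and [glance()] methods
#'   return one-row tibbles.
#' @examples
#' fr <- seq(0.4, 0.9, by = 0.1)
#' fit_sw(2 - 3 * fr, fr)
#' @export
fit_sw <- function(rm, fractions) {
  if (length(rm) != length(fractions)) abort("rm and fractions lengths differ")
  if (length(rm) < 3) abort("need at least 3 modifier fractions")
  if (var(fractions) < 1e-300) abort("zero variance in modifier fractions")
  fit <- lm(rm ~ fractions)
  sm <- suppressWarnings(summary(fit)) # exact fits trip a harmless warning
  n <- length(rm)
  r2 <- sm$r.squared
  perfect <- (1 - r2) < 1e-12
  Fstat <- if (perfect) Inf else r2 / (1 - r2) * (n - 2)
  structure(
    list(
      rm0 = unname(coef(fit)[1]),
      m   = -unname(coef(fit)[2]),
      c0  = unname(coef(fit)[1] / -coef(fit)[2]),
      r   = unname(sign(coef(fit)[2]) * sqrt(r2)),
      r2  = r2, F = Fstat, s = sm$sigma, n = n, perfect = perfect
    ),
    class = "sw_fit"
  )
}

#' @export
print.sw_fit <- function(x, ...) {
  cat(sprintf(
    "Soczewinski-Wachtmeister fit: R_M0 = %.4f, m = %.4f, C0 = %.4f (R2 = %.4f, n = %d)\n",
    x$rm0, x$m, x$c0, x$r2, x$n
  ))
  invisible(x)
}

#' @export
tidy.sw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rm0", "m", "c0"),
    estimate = c(x$rm0, x$m, x$c0)
  )
}

#' @export
glance.sw_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r2, statistic = x$F, sigma = x$s,
                 nobs = x$n, perfect = x$perfect)
}

#' TLC lipophilicity index table from a retardation-factor matrix
#'
#' For each compound: the Soczewinski-Wachtmeister intercept `rm0`, slope
#' magnitude `m`, ratio `c0`, the mean R_M across modifier fractions
#' (`mean_rm`), and the first principal-component score `pc1` of the
#' compounds x fractions R_M matrix (column-mean-centered, unscaled). The
#' sign of PC1 is oriented so that it correlates negatively with `rm0`,
#' i.e. lipophilic compounds get negative scores. The share of retention
#' variance carried by PC1 is attached as the `variance_explained`
#' attribute (percent) and reported by `glance()`.
#'
#' @param rf_data Data frame with a `compound` column and one column of
#'   retardation factors per modifier fraction.
#' @param fractions Modifier volume fractions (0-1) for the R_F columns; by
#'   default parsed from the column names.
#' @return A `tlc_index_table` tibble: `compound`, `rm0`, `m`, `c0`,
#'   `mean_rm`, `pc1`, plus per-fit statistics `r2`, `F`, `s`.
#' @examples
#' plate <- gen_tlc_plate(n_compounds = 6, seed = 1)
#' tlc_index_table(plate$rf, plate$fractions)
#' @export
tlc_index_table <- function(rf_data, fractions = NULL) {
  rf_data <- tibble::as_tibble(rf_data)
  if (!"compound" %in% names(rf_data)) abort("rf_data needs a `compound` column")
  rf_cols <- setdiff(names(rf_data), "compound")
  if (is.null(fractions)) {
    fractions <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", rf_cols)))
    if (anyNA(fractions)) abort("cannot parse fractions from column names; pass `fractions`")
    if (any(fractions > 1)) fractions <- fractions / 100
  }
  if (any(diff(fractions) <= 0)) abort("fractions must be strictly increasing")
  rf <- as.matrix(rf_data[rf_cols])
  bad <- which(!is.finite(rf) | rf <= 0 | rf >= 1, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(paste0(
      "invalid R_F at compound ", rf_data$compound[bad[1, 1]],
      ", fraction ", fractions[bad[1, 2]], " (value ", rf[bad[1, , drop = FALSE]], ")"
    ))
  }
  rm <- rm_from_rf(rf)
  fits <- apply(rm, 1, fit_sw, fractions = fractions)
  # PC1 of the centered, unscaled R_M matrix (all columns share log units)
  pc <- prcomp(rm, center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1]
  ve <- 100 * pc$sdev[1]^2 / sum(pc$sdev^2)
  rm0 <- purrr::map_dbl(fits, "rm0")
  if (cor(pc1, rm0) > 0) pc1 <- -pc1
  out <- tibble::tibble(
    compound = rf_data$compound,
    rm0 = rm0,
    m = purrr::map_dbl(fits, "m"),
    c0 = purrr::map_dbl(fits, "c0"),
    mean_rm = rowMeans(rm),
    pc1 = unname(pc1),
    r2 = purrr::map_dbl(fits, "r2"),
    F = purrr::map_dbl(fits, "F"),
    s = purrr::map_dbl(fits, "s")
  )
  structure(out, variance_explained = ve,
            class = c("tlc_index_table", class(out)))
}

#' @export
glance.tlc_index_table <- function(x, ...) {
  tibble::tibble(
    n_compounds = nrow(x),
    variance_explained = attr(x, "variance_explained"),
    min_r2 = min(x$r2)
  )
}

#' Congenericity regression of R_M0 on the hydrophobic constant m
#'
#' A tight linear relation between the intercept and the slope of the
#' Soczewinski-Wachtmeister line across compounds indicates that the series
#' behaves as a family of chromatographically related congeners. Reports
#' the OLS line together with sign-invariant fit statistics.
#'
#' @param index_table A [tlc_index_table()] result, or any data frame with
#'   `rm0` and `m` columns (>= 3 rows).
#' @return One-row tibble: `slope`, `intercept`, `r2`, `F`, `s`, `n`,
#'   `perfect` (flagged TRUE for an exact collinear fit, where `F` is
#'   infinite).
#' @export
congener_regression <- function(index_table) {
  if (!all(c("rm0", "m") %in% names(index_table))) {
    abort("index_table needs `rm0` and `m` columns")
  }
  if (nrow(index_table) < 3) abort("need at least 3 compounds")
  if (var(index_table$m) < 1e-300) abort("degenerate variance in m")
  fit <- lm(rm0 ~ m, data = index_table)
  sm <- suppressWarnings(summary(fit))
  n <- nrow(index_table)
  r2 <- sm$r.squared
  perfect <- (1 - r2) < 1e-12
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = r2,
    F = if (perfect) Inf else r2 / (1 - r2) * (n - 2),
    s = sm$sigma, n = n, perfect = perfect
  )
}
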