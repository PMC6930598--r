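qsrr_values <- function(X) {
  X <- tibble::as_tibble(X)
  as.matrix(X[setdiff(names(X), "compound")])
}

#' Pre-select molecular descriptors for QSRR modeling
#'
#' Applies three stringent filters to a compounds x descriptors table
#' before variable selection: (i) drop descriptors with any missing value;
#' (ii) drop near-constant descriptors with relative standard deviation
#' (100 sd / |mean|) below `rsd_min` percent; (iii) resolve redundant
#' pairs (|Pearson r| above `r_cut`) by keeping, in each pair, the member
#' more correlated in absolute value with the response. Redundant pairs
#' are processed greedily in order of decreasing |r|, skipping pairs where
#' a member has already been removed, so the filter is deterministic and
#' idempotent.
#'
#' @param X Data frame or matrix of descriptors (a `compound` column is
#'   ignored if present).
#' @param y Response vector (the retention endpoint), one value per row of
#'   `X`.
#' @param rsd_min Minimum relative standard deviation in percent (default
#'   5).
#' @param r_cut Absolute pairwise correlation above which a pair is
#'   redundant (default 0.5).
#' @return A `preselection` list: `survivors` (descriptor names),
#'   `removed_missing`, `removed_low_rsd`, and `removed_redundant` (a
#'   tibble of removed/kept partners with the pair correlation and both
#'   correlations with `y`).
#' @export
preselect_descriptors <- function(X, y, rsd_min = 5, r_cut = 0.5) {
  vals <- qsrr_values(X)
  if (ncol(vals) == 0) abort("X has no descriptor columns")
  if (nrow(vals) != length(y)) abort("X and y sizes differ")
  nm <- colnames(vals)
  removed_missing <- nm[apply(vals, 2, anyNA)]
  alive <- setdiff(nm, removed_missing)
  rsd <- vapply(alive, function(j) {
    mu <- mean(vals[, j])
    if (abs(mu) < 1e-300) Inf else 100 * sd(vals[, j]) / abs(mu)
  }, numeric(1))
  removed_low_rsd <- alive[rsd < rsd_min]
  alive <- setdiff(alive, removed_low_rsd)
  removed_redundant <- tibble::tibble(
    removed = character(), kept = character(), r_pair = numeric(),
    r_removed_y = numeric(), r_kept_y = numeric()
  )
  if (length(alive) > 1) {
    cm <- cor(vals[, alive, drop = FALSE])
    ry <- abs(cor(vals[, alive, drop = FALSE], y))[, 1]
    pairs <- which(upper.tri(cm) & abs(cm) > r_cut, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(-abs(cm[pairs]))
      pairs <- pairs[ord, , drop = FALSE]
      dead <- character(0)
      for (k in seq_len(nrow(pairs))) {
        a <- alive[pairs[k, 1]]; b <- alive[pairs[k, 2]]
        if (a %in% dead || b %in% dead) next
        drop <- if (ry[[a]] < ry[[b]]) a else b
        keep <- setdiff(c(a, b), drop)
        dead <- c(dead, drop)
        removed_redundant <- dplyr::bind_rows(removed_redundant, tibble::tibble(
          removed = drop, kept = keep,
          r_pair = cm[pairs[k, 1], pairs[k, 2]],
          r_removed_y = ry[[drop]], r_kept_y = ry[[keep]]
        ))
      }
      alive <- setdiff(alive, dead)
    }
  }
  if (!length(alive)) abort("all descriptors removed by pre-selection")
  structure(
    list(survivors = alive, removed_missing = removed_missing,
         removed_low_rsd = removed_low_rsd,
         removed_redundant = removed_redundant,
         rsd_min = rsd_min, r_cut = r_cut),
    class = "preselection"
  )
}

#' @export
print.preselection <- function(x, ...) {
  cat(sprintf(
    "Descriptor pre-selection: %d survivors (%d missing, %d low-RSD, %d redundant removed)\n",
    length(x$survivors), length(x$removed_missing), length(x$removed_low_rsd),
    nrow(x$removed_redundant)
  ))
  invisible(x)
}

#' @export
glance.preselection <- function(x, ...) {
  tibble::tibble(
    n_survivors = length(x$survivors),
    n_missing = length(x$removed_missing),
    n_low_rsd = length(x$removed_low_rsd),
    n_redundant = nrow(x$removed_redundant)
  )
}

#' Kennard-Stone training/validation split
#'
#' Deterministic max-min-distance sample selection on Euclidean distances
#' over the autoscaled descriptor matrix: the first two training samples
#' are the most distant pair, and each further sample maximizes its
#' minimal distance to the already-selected set. Ties are broken by lowest
#' row index; exact duplicate rows are reported with a warning.
#'
#' @param X Data frame or matrix of descriptors (optional `compound`
#'   column supplies ids).
#' @param fraction Training fraction; the training set size is
#'   `floor(fraction * n)` (default 0.7).
#' @return A `ks_split` list: `train` and `test` ids (disjoint,
#'   exhaustive) and `fraction`.
#' @export
kennard_stone_split <- function(X, fraction = 0.7) {
  vals <- qsrr_values(X)
  n <- nrow(vals)
  if (n < 3) abort("need at least 3 samples")
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  ids <- if (is.data.frame(X) && "compound" %in% names(X)) X$compound else seq_len(n)
  scl <- apply(vals, 2, sd); scl[scl < 1e-12] <- 1
  Z <- scale(vals, scale = scl)
  D <- as.matrix(dist(Z))
  if (any(D[upper.tri(D)] < 1e-12)) warn("duplicate rows in X; ties broken by lowest index")
  n_train <- floor(fraction * n)
  first <- which(D == max(D), arr.ind = TRUE)[1, ]
  sel <- sort(unname(first))[1:2]
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    dmin <- apply(D[cand, sel, drop = FALSE], 1, min)
    sel <- c(sel, cand[which.max(dmin)])
  }
  structure(
    list(train = ids[sel], test = ids[setdiff(seq_len(n), sel)],
         fraction = fraction),
    class = "ks_split"
  )
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split: %d train / %d test (fraction %.2f)\n",
              length(x$train), length(x$test), x$fraction))
  invisible(x)
}

#' Fit a PLS1 regression model
#'
#' Univariate partial least squares (NIPALS) with `lv` latent variables.
#' Descriptors are autoscaled and the response centered inside the fit;
#' coefficients are reported on the original scale.
#'
#' @param X Descriptor data frame or matrix (optional `compound` column
#'   ignored).
#' @param y Response vector.
#' @param lv Number of latent variables, at most `min(n - 2, p)`.
#' @return A `pls_model` with `coefficients`, `intercept`, `lv`, `fitted`,
#'   and `rmsec`; supports `predict(model, newdata)`.
#' @export
pls_fit <- function(X, y, lv) {
  vals <- qsrr_values(X)
  check_lv(lv, nrow(vals), ncol(vals))
  fitted <- cpp_pls_train_predict(vals, y, vals, lv)[, lv]
  # recover the (linear) coefficient vector by probing unit displacements
  base <- cpp_pls_train_predict(vals, y, matrix(0, 1, ncol(vals)), lv)[, lv]
  probes <- cpp_pls_train_predict(vals, y, diag(ncol(vals)), lv)[, lv]
  beta <- probes - base
  structure(
    list(coefficients = setNames(beta, colnames(vals)), intercept = base,
         lv = lv, fitted = fitted, y = y,
         rmsec = sqrt(mean((y - fitted)^2)),
         X = vals),
    class = "pls_model"
  )
}

check_lv <- function(lv, n, p) {
  if (lv < 1 || lv > min(n - 2, p)) {
    abort(paste0("lv must lie in 1..min(n - 2, p) = ", min(n - 2, p)))
  }
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  vals <- qsrr_values(newdata)
  drop(vals %*% object$coefficients) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d LV, %d descriptors, RMSEC %.4g\n",
              x$lv, length(x$coefficients), x$rmsec))
  invisible(x)
}

#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' Leave-one-out cross-validation error of PLS models
#'
#' For each number of latent variables up to `lv_max`, refits the PLS
#' model with one sample left out at a time (autoscaling redone per fold)
#' and reports the root mean square error of the cross-validated
#' predictions (RMSECV) together with the calibration error (RMSEC).
#'
#' @inheritParams pls_fit
#' @param lv_max Largest number of latent variables to evaluate.
#' @return A tibble: `lv`, `rmsecv`, `rmsec`.
#' @export
pls_loo_rmsecv <- function(X, y, lv_max) {
  vals <- qsrr_values(X)
  check_lv(lv_max, nrow(vals), ncol(vals))
  loo <- cpp_pls_loo(vals, y, lv_max)
  fit <- cpp_pls_train_predict(vals, y, vals, lv_max)
  tibble::tibble(
    lv = seq_len(lv_max),
    rmsecv = sqrt(colMeans((y - loo)^2)),
    rmsec = sqrt(colMeans((y - fit)^2))
  )
}

#' Cross-validated ANOVA significance of a latent-variable model
#'
#' Tests whether a model's leave-one-out predictive residuals are
#' significantly smaller than those of the mean-only (null) predictor,
#' whose LOO prediction for sample i is the mean of the remaining
#' samples. The F statistic compares the reduction of the predictive
#' residual sum of squares per fitted component against the model's
#' predictive mean square:
#' `F = ((PRESS0 - PRESS) / A) / (PRESS / (n - A - 1))` with `A` latent
#' variables, referred to an F(A, n - A - 1) distribution. A model whose
#' cross-validated predictions do not beat the null gives p = 1.
#'
#' @param y Observed response.
#' @param y_loo Leave-one-out predictions of the model under test.
#' @param n_lv Number of latent variables the model used.
#' @return One-row tibble: `F`, `df1`, `df2`, `p`, `press_model`,
#'   `press_null`, and `zero_residual` (TRUE when the model's predictive
#'   residuals vanish, in which case `p` is reported as < 1e-16).
#' @export
cv_anova <- function(y, y_loo, n_lv) {
  n <- length(y)
  if (length(y_loo) != n) abort("y and y_loo lengths differ")
  if (n_lv >= n - 1) abort("too many latent variables for CV-ANOVA")
  # LOO prediction of the mean-only model: mean of the other n - 1 values
  null_loo <- (sum(y) - y) / (n - 1)
  press0 <- sum((y - null_loo)^2)
  press <- sum((y - y_loo)^2)
  zero_res <- press < 1e-300
  if (zero_res) {
    return(tibble::tibble(F = Inf, df1 = n_lv, df2 = n - n_lv - 1,
                          p = 1e-16, press_model = press, press_null = press0,
                          zero_residual = TRUE))
  }
  Fstat <- ((press0 - press) / n_lv) / (press / (n - n_lv - 1))
  p <- if (Fstat <= 0) 1 else pf(Fstat, n_lv, n - n_lv - 1, lower.tail = FALSE)
  tibble::tibble(F = Fstat, df1 = n_lv, df2 = n - n_lv - 1, p = p,
                 press_model = press, press_null = press0,
                 zero_residual = FALSE)
}
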