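#' Pairwise Pearson correlation matrix of measures
#'
#' Pearson correlations between all pairs of measures over complete pairs
#' of observations, with per-pair sample sizes and (optionally) two-sided
#' p-values. Zero-variance columns give undefined correlations, reported
#' as `NA`.
#'
#' @param m A `lipo_matrix` or data frame with a `compound` column and
#'   numeric measures (>= 3 compounds).
#' @param p_values Attach two-sided correlation-test p-values (default
#'   TRUE).
#' @return A `cor_report` with matrices `r`, `n`, and optionally `p`;
#'   `tidy()` returns the long pair table.
#' @export
pearson_matrix <- function(m, p_values = TRUE) {
  vals <- if (inherits(m, "lipo_matrix")) measure_values(m) else {
    as.matrix(tibble::as_tibble(m)[setdiff(names(m), "compound")])
  }
  if (nrow(vals) < 3) abort("need at least 3 compounds")
  constant <- apply(vals, 2, function(x) var(x, na.rm = TRUE) < 1e-300)
  r <- suppressWarnings(cor(vals, use = "pairwise.complete.obs"))
  r[constant, ] <- NA; r[, constant] <- NA
  diag(r)[!constant] <- 1
  nmat <- crossprod(!is.na(vals))
  p <- NULL
  if (p_values) {
    k <- ncol(vals)
    p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j && !is.na(r[i, j])) {
        ok <- stats::complete.cases(vals[, c(i, j)])
        p[i, j] <- cor.test(vals[ok, i], vals[ok, j])$p.value
      }
    }
  }
  structure(list(r = r, n = nmat, p = p), class = "cor_report")
}

#' @export
tidy.cor_report <- function(x, ...) {
  long <- as.data.frame(as.table(x$r), stringsAsFactors = FALSE)
  names(long) <- c("measure_1", "measure_2", "r")
  long$n <- as.vector(x$n)
  if (!is.null(x$p)) long$p <- as.vector(x$p)
  tibble::as_tibble(long[long$measure_1 != long$measure_2, ])
}

#' @export
print.cor_report <- function(x, ...) {
  cat("<cor_report> ", ncol(x$r), " measures; r range [",
      round(min(x$r[upper.tri(x$r)], na.rm = TRUE), 3), ", ",
      round(max(x$r[upper.tri(x$r)], na.rm = TRUE), 3), "]\n", sep = "")
  invisible(x)
}

#' Sigma-rule outlier screen on a bivariate relation
#'
#' Regresses `y` on `x` by OLS and flags observations whose studentized
#' residual exceeds `threshold` in absolute value (the "2.5 sigma rule" at
#' the default threshold). By default the screen is iterative: after
#' flagging the single worst point the line is refitted and the rule is
#' reapplied until no point exceeds the threshold, which lets masked
#' outliers surface one at a time. The correlation before and after
#' pruning is reported.
#'
#' @param data Data frame holding the two variables (and optionally a
#'   `compound` id column used to label flagged points).
#' @param x,y Column names (strings) of the predictor and response.
#' @param threshold Residual threshold in sigma units (default 2.5);
#'   `Inf` flags nothing.
#' @param iterative Refit after each removal (default TRUE); FALSE flags
#'   all exceedances of the single initial fit.
#' @param residuals `"studentized"` (externally studentized, default),
#'   `"standardized"` (leverage-adjusted), or `"raw"` (residual over
#'   residual SD).
#' @return An `outlier_screen` list: `flagged` (ids in flagging order),
#'   `r_full`, `r_pruned`, `threshold`, `n_retained`.
#' @examples
#' m <- assemble_matrix()
#' sigma_outliers(m, "PBE0_6311Gpp2df2dp", "HPLC_logkw")
#' @export
sigma_outliers <- function(data, x, y, threshold = 2.5, iterative = TRUE,
                           residuals = c("studentized", "standardized", "raw")) {
  residuals <- match.arg(residuals)
  data <- tibble::as_tibble(data)
  if (!all(c(x, y) %in% names(data))) abort("x and y must name columns of data")
  ids <- if ("compound" %in% names(data)) data$compound else seq_len(nrow(data))
  xv <- data[[x]]; yv <- data[[y]]
  if (length(xv) < 4) abort("need at least 4 points")
  res_fun <- switch(residuals,
    studentized = function(f) rstudent(f),
    standardized = function(f) rstandard(f),
    raw = function(f) resid(f) / sd(resid(f))
  )
  r_full <- cor(xv, yv)
  keep <- seq_along(xv)
  flagged <- integer(0)
  repeat {
    if (length(keep) < 4) abort("fewer than 4 points retained; screen aborted")
    fit <- lm(yv[keep] ~ xv[keep])
    # (near-)perfect fit: no outliers (summary itself warns on exact fits)
    if (suppressWarnings(summary(fit))$sigma < 1e-10) break
    z <- res_fun(fit)
    exceed <- which(abs(z) > threshold)
    if (!length(exceed)) break
    if (iterative) {
      worst <- exceed[which.max(abs(z[exceed]))]
      flagged <- c(flagged, keep[worst])
      keep <- keep[-worst]
    } else {
      flagged <- keep[exceed]
      keep <- keep[-exceed]
      break
    }
  }
  if (length(keep) < 3) abort("fewer than 3 points retained after pruning")
  structure(
    list(
      x = x, y = y,
      flagged = ids[flagged],
      retained = ids[keep],
      r_full = r_full,
      r_pruned = cor(xv[keep], yv[keep]),
      threshold = threshold,
      residuals = residuals,
      n_retained = length(keep)
    ),
    class = "outlier_screen"
  )
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf(
    "Sigma screen of %s ~ %s (|%s residual| > %g): flagged {%s}; r %.3f -> %.3f\n",
    x$y, x$x, x$residuals, x$threshold,
    paste(x$flagged, collapse = ", "), x$r_full, x$r_pruned
  ))
  invisible(x)
}

#' @export
glance.outlier_screen <- function(x, ...) {
  tibble::tibble(r_full = x$r_full, r_pruned = x$r_pruned,
                 n_flagged = length(x$flagged), n_retained = x$n_retained,
                 threshold = x$threshold)
}

#' Principal component overview of the measures
#'
#' PCA of the compounds x measures table, by default on standardized
#' columns (unit variance, zero mean) since measures live on different
#' scales. Constant columns are refused before standardization.
#'
#' @param m A `lipo_matrix` or data frame with a `compound` column.
#' @param standardize Scale columns to unit variance (default TRUE).
#' @return A `pca_overview` list: `scores` (tibble with `compound` and
#'   `PC1..`), `loadings` (tibble with `measure` and `PC1..`),
#'   `variance_fraction` (per component), and the underlying `prcomp`
#'   object.
#' @export
pca_overview <- function(m, standardize = TRUE) {
  vals <- if (inherits(m, "lipo_matrix")) measure_values(m) else {
    as.matrix(tibble::as_tibble(m)[setdiff(names(m), "compound")])
  }
  if (anyNA(vals)) abort("matrix must be complete")
  constant <- apply(vals, 2, function(x) var(x) < 1e-300)
  if (any(constant)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(vals)[constant], collapse = ", ")))
  }
  pc <- prcomp(vals, center = TRUE, scale. = standardize)
  ids <- if (is.data.frame(m) && "compound" %in% names(m)) m$compound else seq_len(nrow(vals))
  structure(
    list(
      scores = dplyr::bind_cols(tibble::tibble(compound = ids),
                                tibble::as_tibble(pc$x)),
      loadings = dplyr::bind_cols(tibble::tibble(measure = colnames(vals)),
                                  tibble::as_tibble(unclass(pc$rotation))),
      variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
      prcomp = pc
    ),
    class = "pca_overview"
  )
}

#' @export
print.pca_overview <- function(x, ...) {
  vf <- 100 * x$variance_fraction
  cat(sprintf("PCA overview: %d components; PC1 %.2f%%, PC1+PC2 %.2f%%\n",
              length(vf), vf[1], vf[1] + vf[2]))
  invisible(x)
}
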