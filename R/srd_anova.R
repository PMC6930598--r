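#' Long-format design for ANOVA of cross-validated SRD scores
#'
#' Stacks the sevenfold-CV SRD scores obtained under each data pretreatment
#' into one long table with two categorical factors: the pretreatment
#' (`F1`: STD, IS, RNK) and the descriptor class of each measure (`F2`:
#' the nine-level grouping from [measure_metadata()]). With the packaged 31
#' measures, three pretreatments, and seven folds the design has
#' 31 x 3 x 7 = 651 rows.
#'
#' @param cv_list Named list of [sevenfold_cv()] results, one per
#'   pretreatment; names (or the objects' recorded pretreatments) become
#'   the `F1` levels.
#' @param meta Measure metadata with `measure_id` and `anova_class`.
#' @return A tibble: `measure`, `pretreatment`, `anova_class`, `fold`,
#'   `srd_pct`.
#' @export
build_design <- function(cv_list, meta = measure_metadata()) {
  if (inherits(cv_list, "srd_cv")) cv_list <- list(cv_list)
  nm <- names(cv_list) %||% purrr::map_chr(cv_list, ~ attr(.x, "pretreatment") %||% NA_character_)
  if (anyNA(nm)) abort("pretreatment labels missing; name the list elements")
  design <- purrr::map2_dfr(cv_list, nm, function(cv, lab) {
    dplyr::mutate(tibble::as_tibble(cv), pretreatment = lab)
  })
  design <- dplyr::left_join(design, meta, by = c(measure = "measure_id"))
  if (anyNA(design$anova_class)) {
    abort(paste0("unlabeled measure(s): ",
                 paste(unique(design$measure[is.na(design$anova_class)]),
                       collapse = ", ")))
  }
  dplyr::select(design, "measure", "pretreatment", "anova_class", "fold",
                "srd_pct")
}

#' Two-way factorial ANOVA of SRD scores with interaction
#'
#' Fixed-effects decomposition `SRD ~ F1 + F2 + F1:F2` of the
#' cross-validated SRD scores, with the pretreatment (`F1`) and the
#' descriptor class (`F2`) as categorical factors. Sums of squares are
#' sequential (model-comparison, F1 entered first, then F2, then the
#' interaction), which is what an unbalanced-across-classes design calls
#' for; on a balanced design they coincide with marginal sums of squares.
#' The intercept row carries the sum of squares of the grand mean
#' (`n * mean^2`), tested against the error mean square; the total row is
#' the corrected total.
#'
#' @param design A [build_design()] table (columns `pretreatment`,
#'   `anova_class`, `srd_pct`).
#' @return An `anova_table` tibble: `term`, `df`, `ss`, `ms`, `F`, `p` for
#'   intercept, F1, F2, F1 x F2, error and total. For a constant response
#'   all effect sums of squares are 0 and p is reported as 1.
#' @export
anova_full_interaction <- function(design) {
  need <- c("pretreatment", "anova_class", "srd_pct")
  if (!all(need %in% names(design))) {
    abort("design needs pretreatment, anova_class and srd_pct columns")
  }
  design <- dplyr::mutate(design,
    pretreatment = factor(.data$pretreatment),
    anova_class = factor(.data$anova_class)
  )
  cells <- dplyr::count(design, .data$pretreatment, .data$anova_class)
  full_grid <- nlevels(design$pretreatment) * nlevels(design$anova_class)
  if (nrow(cells) < full_grid) {
    have <- paste(cells$pretreatment, cells$anova_class)
    grid <- expand.grid(levels(design$pretreatment), levels(design$anova_class))
    missing <- paste(grid[[1]], grid[[2]])[!paste(grid[[1]], grid[[2]]) %in% have]
    abort(paste0("empty design cell(s): ", paste(missing, collapse = ", ")))
  }
  y <- design$srd_pct
  n <- length(y)
  constant <- var(y) < 1e-300
  fit <- lm(srd_pct ~ pretreatment * anova_class, data = design)
  # sequential (Type I) sums of squares; a constant response trips a
  # harmless perfect-fit warning and its p-values are overwritten below
  a <- suppressWarnings(anova(fit))
  ss <- c(n * mean(y)^2, a$`Sum Sq`)
  df <- c(1L, a$Df)
  ms <- ss / df
  err_ms <- ms[5]
  Fv <- c(ms[1:4] / err_ms, NA, NA)
  pv <- pf(Fv[1:4], df[1:4], df[5], lower.tail = FALSE)
  if (constant) {
    Fv[2:4] <- 0
    pv[2:4] <- 1
  }
  out <- tibble::tibble(
    term = c("intercept", "F1 (pretreatment)", "F2 (descriptor class)",
             "F1 x F2", "error", "total"),
    df = c(df, n - 1L),
    ss = c(ss, sum(ss[2:5])),
    ms = c(ms, NA),
    F = c(Fv[1:4], NA, NA),
    p = c(pv, NA, NA)
  )
  structure(out, class = c("anova_table", class(out)))
}

#' Pairwise descriptor-class mean comparisons (Fisher LSD and Tukey HSD)
#'
#' Post-hoc comparison of the descriptor-class (`F2`) level means of
#' cross-validated SRD scores: unadjusted pairwise t tests sharing the
#' one-way error term (Fisher's least significant difference) and Tukey's
#' honest significant difference. Fisher's procedure is the more liberal
#' of the two.
#'
#' @param design A [build_design()] table.
#' @return A tibble of class pairs with `diff` (difference of means),
#'   `p_fisher` and `p_tukey`.
#' @export
class_mean_comparisons <- function(design) {
  design <- dplyr::mutate(design, anova_class = factor(.data$anova_class))
  fit <- aov(srd_pct ~ anova_class, data = design)
  tk <- TukeyHSD(fit)$anova_class
  mse <- sum(resid(fit)^2) / fit$df.residual
  means <- tapply(design$srd_pct, design$anova_class, mean)
  ns <- tapply(design$srd_pct, design$anova_class, length)
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  p_fisher <- purrr::map_dbl(pairs, function(p) {
    se <- sqrt(mse * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    tstat <- (means[[p[1]]] - means[[p[2]]]) / se
    2 * pt(abs(tstat), fit$df.residual, lower.tail = FALSE)
  })
  tibble::tibble(
    class_1 = purrr::map_chr(pairs, 1),
    class_2 = purrr::map_chr(pairs, 2),
    diff = unname(tk[, "diff"]),
    p_fisher = p_fisher,
    p_tukey = unname(tk[, "p adj"])
  )
}
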