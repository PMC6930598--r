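#' Sevenfold jackknife-like cross-validation of SRD scores
#'
#' Partitions the compounds at random into seven folds of near-equal size
#' (for 26 compounds: five folds of 4 and two of 3), removes one fold at a
#' time, and recomputes the full SRD analysis on the retained compounds -
#' consensus reference, ranks, and normalization constant included. The
#' seven normalized scores per measure quantify how stable each measure's
#' distance to the consensus is under perturbation of the compound set.
#'
#' @param m A `lipo_matrix` or data frame accepted by [srd_scores()].
#' @param seed Integer seed for the random fold assignment (recorded in the
#'   output; identical seeds give identical partitions).
#' @param n_folds Number of folds (default 7).
#' @inheritParams srd_scores
#' @return An `srd_cv` object: a long tibble (`measure`, `fold`,
#'   `srd_pct`), with the fold assignment (`folds` attribute, a tibble of
#'   `compound` and `fold`) and `seed` attached.
#' @examples
#' cv <- sevenfold_cv(pretreat(assemble_matrix(), "STD"), seed = 1)
#' dplyr::count(cv, measure)
#' @export
sevenfold_cv <- function(m, seed = 1, n_folds = 7,
                         reference = c("row_means", "gold"), gold = NULL) {
  reference <- match.arg(reference)
  n <- nrow(m)
  if (n < n_folds) abort(paste0("need at least ", n_folds, " compounds"))
  sizes <- rep(n %/% n_folds, n_folds)
  sizes[seq_len(n %% n_folds)] <- sizes[seq_len(n %% n_folds)] + 1L
  assignment <- with_local_seed(seed, sample(rep(seq_len(n_folds), times = sizes)))
  per_fold <- purrr::map(seq_len(n_folds), function(f) {
    keep <- assignment != f
    sc <- srd_scores(m[keep, , drop = FALSE], reference = reference,
                     gold = gold[keep])
    tibble::tibble(measure = sc$measure, fold = f, srd_pct = sc$srd_pct)
  })
  out <- dplyr::bind_rows(per_fold)
  compound <- if ("compound" %in% names(m)) m$compound else seq_len(n)
  structure(out,
    folds = tibble::tibble(compound = compound, fold = assignment),
    seed = seed, n_folds = n_folds,
    pretreatment = attr(m, "pretreatment"),
    class = c("srd_cv", class(out))
  )
}

#' @export
glance.srd_cv <- function(x, ...) {
  tibble::tibble(
    n_measures = dplyr::n_distinct(x$measure),
    n_folds = attr(x, "n_folds"),
    seed = attr(x, "seed"),
    pretreatment = attr(x, "pretreatment") %||% NA_character_
  )
}

#' Order measures by cross-validated SRD and group them by pairwise tests
#'
#' Measures are sorted by the median of their cross-validated SRD scores
#' (best, i.e. closest to the consensus, first). A group boundary is drawn
#' between two adjacent measures only when both the exact sign test and the
#' Wilcoxon matched-pairs test reject equality of their paired fold scores
#' at `alpha`; measures not separated share a group label.
#'
#' @param cv An [sevenfold_cv()] result.
#' @param alpha Significance level for both tests (default 0.05).
#' @return A tibble ordered by median SRD: `measure`, `median`, `group`
#'   (integer labels from best to worst), and the p-values of the two tests
#'   against the previous measure (`p_sign`, `p_wilcoxon`).
#' @export
pairwise_grouping <- function(cv, alpha = 0.05) {
  stopifnot(inherits(cv, "srd_cv"))
  wide <- tidyr::pivot_wider(tibble::as_tibble(cv), names_from = "fold",
                             values_from = "srd_pct")
  vals <- as.matrix(wide[-1])
  med <- apply(vals, 1, median)
  ord <- order(med)
  wide <- wide[ord, ]; vals <- vals[ord, , drop = FALSE]; med <- med[ord]
  k <- nrow(vals)
  p_sign <- p_wil <- rep(NA_real_, k)
  for (i in seq_len(k)[-1]) {
    d <- vals[i, ] - vals[i - 1, ]
    nz <- d[d != 0]
    if (!length(nz)) {
      warn(paste0("identical fold scores for ", wide[[1]][i], " and ",
                  wide[[1]][i - 1], "; pairwise tests undefined, grouped together"))
      p_sign[i] <- p_wil[i] <- 1
    } else {
      p_sign[i] <- binom.test(sum(nz > 0), length(nz))$p.value
      p_wil[i] <- suppressWarnings(
        wilcox.test(vals[i, ], vals[i - 1, ], paired = TRUE)$p.value
      )
    }
  }
  boundary <- !is.na(p_sign) & p_sign < alpha & p_wil < alpha
  tibble::tibble(
    measure = wide[[1]],
    median = med,
    group = cumsum(c(TRUE, boundary[-1])),
    p_sign = p_sign,
    p_wilcoxon = p_wil
  )
}
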