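#' Column-wise ranking with average ties
#'
#' Ranks a vector in increasing order, replacing tied values by the average
#' of the ranks they span (fractional ranks), the convention used
#' throughout the SRD machinery.
#'
#' @param values Finite numeric vector.
#' @return Numeric ranks summing to `n (n + 1) / 2`.
#' @examples
#' rank_with_ties(c(1, 2, 2, 3))
#' @export
rank_with_ties <- function(values) {
  if (any(!is.finite(values))) abort("values must be finite")
  rank(values, ties.method = "average")
}

#' Maximum attainable sum of ranking differences
#'
#' The normalization constant for SRD: the city-block distance between a
#' ranking of `n` objects and its reversal, `n^2 / 2` for even `n` and
#' `(n^2 - 1) / 2` for odd `n`.
#'
#' @param n Number of ranked objects.
#' @return A single number.
#' @export
srd_max <- function(n) {
  if (n %% 2 == 0) n^2 / 2 else (n^2 - 1) / 2
}

#' Sum of ranking differences against a consensus reference
#'
#' Ranks every measure (column) and the reference over the compounds
#' (rows), then scores each measure by the sum of absolute rank differences
#' from the reference ranking. By default the reference is the row-wise
#' arithmetic mean of all measures (consensus), which partially cancels the
#' individual methods' systematic and random errors; a gold-standard
#' reference vector can be supplied instead. Scores are also normalized to
#' percent of the maximum attainable SRD, so 0 is perfect agreement with
#' the reference and 100 is the exactly reversed ranking.
#'
#' @param m A `lipo_matrix` (see [assemble_matrix()], usually after
#'   [pretreat()]) or a data frame with a `compound` column and numeric
#'   measure columns.
#' @param reference `"row_means"` (consensus, default) or `"gold"`.
#' @param gold Reference values per compound when `reference = "gold"`.
#' @return An `srd_result` tibble: `measure`, `srd`, `srd_pct`, ordered as
#'   the input columns, with attributes `n`, `srd_max`, and `reference`
#'   (a tibble of per-compound reference values and ranks).
#' @examples
#' srd_scores(pretreat(assemble_matrix(), "STD"))
#' @export
srd_scores <- function(m, reference = c("row_means", "gold"), gold = NULL) {
  reference <- match.arg(reference)
  vals <- if (inherits(m, "lipo_matrix")) measure_values(m) else {
    as.matrix(tibble::as_tibble(m)[setdiff(names(m), "compound")])
  }
  n <- nrow(vals)
  if (n < 2) abort("need at least 2 compounds")
  if (ncol(vals) < 2 && reference == "row_means") {
    warn("single measure: reference equals the measure, SRD is trivially 0")
  }
  ref_values <- switch(reference,
    row_means = rowMeans(vals),
    gold = {
      if (is.null(gold) || length(gold) != n) abort("gold must have one value per compound")
      gold
    }
  )
  ref_rank <- rank_with_ties(ref_values)
  ranks <- apply(vals, 2, rank_with_ties)
  srd <- colSums(abs(ranks - ref_rank))
  out <- tibble::tibble(
    measure = colnames(vals),
    srd = unname(srd),
    srd_pct = 100 * unname(srd) / srd_max(n)
  )
  structure(out,
    n = n, srd_max = srd_max(n),
    reference = tibble::tibble(
      compound = if (is.data.frame(m) && "compound" %in% names(m)) m$compound else seq_len(n),
      value = ref_values, rank = ref_rank
    ),
    class = c("srd_result", class(out))
  )
}

#' @export
glance.srd_result <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), srd_max = attr(x, "srd_max"),
                 n_measures = nrow(x))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Null distribution of SRD under random rankings (CRRN)
#'
#' Distribution of the normalized SRD between a random permutation of `n`
#' objects and a fixed tie-free reference ranking: the yardstick for
#' deciding whether a measure ranks objects better than chance. Exact
#' enumeration of all `n!` permutations is used for `n <= 8`; above that, a
#' seeded Monte-Carlo sample of random permutations. One-sided p-values
#' `P(SRD_random <= observed)` are available through `crrn_p_value()`.
#'
#' @param n Number of ranked objects (>= 2).
#' @param n_sim Number of Monte-Carlo draws (ignored for exact
#'   enumeration); fewer than 1000 draws triggers a warning.
#' @param seed Integer seed for the Monte-Carlo sampler.
#' @param method `"auto"` (exact for `n <= 8`), `"exact"`, or
#'   `"monte_carlo"`.
#' @return A `crrn_dist` object: summary statistics of the normalized SRD
#'   null (`mean`, `sd`, `median`, `q5`, `q95`, percent of the maximum
#'   SRD), the raw-score distribution, and bookkeeping fields (`n`,
#'   `method`, `n_sim`, `seed`).
#' @examples
#' crrn_distribution(4)           # exact: mean 62.5%
#' crrn_distribution(26, 1e4, 1)  # Monte-Carlo
#' @export
crrn_distribution <- function(n, n_sim = 1e5, seed = 1,
                              method = c("auto", "exact", "monte_carlo")) {
  method <- match.arg(method)
  if (n < 2) abort("n must be at least 2")
  if (method == "auto") method <- if (n <= 8) "exact" else "monte_carlo"
  mx <- srd_max(n)
  if (method == "exact") {
    perms <- all_permutations(n)
    srd <- rowSums(abs(sweep(perms, 2, seq_len(n))))
    dist <- as.data.frame(table(srd), stringsAsFactors = FALSE)
    dist <- tibble::tibble(srd = as.numeric(dist$srd),
                           prob = dist$Freq / sum(dist$Freq))
    stats <- dist_stats(dist$srd, dist$prob, mx)
    p_fun <- function(srd_obs) {
      vapply(srd_obs, function(s) sum(dist$prob[dist$srd <= s]), numeric(1))
    }
    n_sim <- NA_integer_
  } else {
    if (n_sim < 1e3) warn("fewer than 1000 Monte-Carlo draws; null summary will be noisy")
    samples <- with_local_seed(seed, {
      vapply(seq_len(n_sim), function(i) sum(abs(sample.int(n) - seq_len(n))),
             numeric(1))
    })
    dist <- tibble::tibble(srd = samples)
    stats <- dist_stats(samples, rep(1 / n_sim, n_sim), mx)
    p_fun <- function(srd_obs) {
      vapply(srd_obs, function(s) mean(samples <= s), numeric(1))
    }
  }
  structure(
    c(stats, list(n = n, srd_max = mx, method = method, n_sim = n_sim,
                  seed = seed, dist = dist, p_value = p_fun)),
    class = "crrn_dist"
  )
}

dist_stats <- function(values, probs, mx) {
  pct <- 100 * values / mx
  mu <- sum(pct * probs)
  sdv <- sqrt(sum(probs * (pct - mu)^2))
  cdf <- cumsum(probs[order(pct)])
  spct <- sort(pct)
  qtl <- function(p) spct[which(cdf >= p)[1]]
  list(mean = mu, sd = sdv, median = qtl(0.5), q5 = qtl(0.05),
       q95 = qtl(0.95))
}

#' One-sided CRRN p-value for observed SRD scores
#'
#' @param dist A [crrn_distribution()] object.
#' @param srd Observed raw SRD score(s).
#' @return `P(SRD_random <= srd)` for each observed score.
#' @export
crrn_p_value <- function(dist, srd) {
  stopifnot(inherits(dist, "crrn_dist"))
  dist$p_value(srd)
}

#' @export
print.crrn_dist <- function(x, ...) {
  cat(sprintf(
    "CRRN null for n = %d (%s%s): mean %.2f%%, sd %.2f%%, median %.2f%%, 5-95%% [%.2f, %.2f]\n",
    x$n, x$method,
    if (x$method == "monte_carlo") paste0(", ", x$n_sim, " draws") else "",
    x$mean, x$sd, x$median, x$q5, x$q95
  ))
  invisible(x)
}

#' @export
tidy.crrn_dist <- function(x, ...) {
  tibble::tibble(n = x$n, method = x$method, mean = x$mean, sd = x$sd,
                 median = x$median, q5 = x$q5, q95 = x$q95)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
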