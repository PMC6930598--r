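#' Configuration of the genetic-algorithm variable selection
#'
#' Hyper-parameters of the binary GA that searches descriptor subsets for
#' PLS retention models. Defaults follow common chemometric practice for
#' small descriptor pools: a population of 20 chromosomes, single-point
#' crossover applied to 80% of each new generation, uniform bit mutation
#' at rate 0.2, tournament selection of size 2, one elite individual, and
#' independent restarts (`n_runs`) whose best chromosomes define the
#' percentage of selection of every descriptor. Generations per run and
#' the early-stop stall window bound the run time of one restart.
#'
#' @param pop_size Population size.
#' @param crossover_fraction Fraction of non-elite children produced by
#'   single-point crossover (the rest are mutation-only children).
#' @param mutation_rate Per-bit flip probability of uniform mutation.
#' @param tournament_size Tournament size for parent selection.
#' @param n_runs Number of independent GA restarts.
#' @param generations Maximum generations per restart.
#' @param stall_generations Stop a restart early after this many
#'   generations without improvement of the best fitness.
#' @param elite_count Chromosomes copied unchanged into the next
#'   generation.
#' @param lv_max Largest number of PLS latent variables scored inside the
#'   fitness (capped at `n - 2` of the training set).
#' @param seed Master seed; restart r uses `seed + r - 1`.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 20, crossover_fraction = 0.8,
                      mutation_rate = 0.2, tournament_size = 2,
                      n_runs = 1000, generations = 30,
                      stall_generations = 10, elite_count = 1,
                      lv_max = 10, seed = 1) {
  stopifnot(
    pop_size >= 2, crossover_fraction >= 0, crossover_fraction <= 1,
    mutation_rate >= 0, mutation_rate <= 1, tournament_size >= 1,
    n_runs >= 1, generations >= 1, elite_count >= 0,
    elite_count < pop_size, lv_max >= 1
  )
  structure(as.list(environment()), class = "ga_config")
}

#' Genetic-algorithm descriptor selection scored by PLS LOO error
#'
#' Runs `n_runs` independent restarts of a binary genetic algorithm over
#' descriptor subsets. Each chromosome encodes the included descriptors;
#' its fitness is the minimum leave-one-out RMSECV over 1..`lv_max` latent
#' variables of the PLS model restricted to those descriptors (empty
#' chromosomes get infinite fitness and are never returned). Each restart
#' records its best chromosome; the fraction of restarts selecting each
#' descriptor is the percentage of selection used by [consensus_model()].
#'
#' @param X Pre-selected descriptor table for the training set (optional
#'   `compound` column ignored).
#' @param y Training response.
#' @param config A [ga_config()].
#' @return A `ga_pls_result`: `pct_selection` (tibble `descriptor`,
#'   `pct`), `selection` (logical `n_runs` x p matrix of best chromosomes),
#'   `best_fitness` (per restart), and `config`.
#' @export
ga_pls <- function(X, y, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  vals <- qsrr_values(X)
  p <- ncol(vals)
  n <- nrow(vals)
  if (n != length(y)) abort("X and y sizes differ")
  lv_max <- min(config$lv_max, n - 2)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fitness <- function(bits) {
    if (!any(bits)) return(Inf)
    key <- paste(which(bits), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    loo <- cpp_pls_loo(vals[, bits, drop = FALSE], y, lv_max)
    val <- sqrt(min(colMeans((y - loo)^2)))
    cache[[key]] <- val
    val
  }
  selection <- matrix(FALSE, config$n_runs, p,
                      dimnames = list(NULL, colnames(vals)))
  best_fitness <- numeric(config$n_runs)
  for (run in seq_len(config$n_runs)) {
    res <- with_local_seed(config$seed + run - 1L,
                           ga_run(fitness, p, config))
    selection[run, ] <- res$best
    best_fitness[run] <- res$fitness
  }
  structure(
    list(
      pct_selection = tibble::tibble(descriptor = colnames(vals),
                                     pct = unname(100 * colMeans(selection))),
      selection = selection,
      best_fitness = best_fitness,
      config = config
    ),
    class = "ga_pls_result"
  )
}

# one GA restart; assumes the RNG is already seeded
ga_run <- function(fitness, p, config) {
  ps <- config$pop_size
  pop <- matrix(runif(ps * p) < 0.5, ps, p)
  empty <- !apply(pop, 1, any)
  for (i in which(empty)) pop[i, sample.int(p, 1)] <- TRUE
  fit <- apply(pop, 1, fitness)
  best_fit_hist <- min(fit)
  stall <- 0L
  tournament <- function() {
    cand <- sample.int(ps, config$tournament_size, replace = TRUE)
    cand[which.min(fit[cand])]
  }
  for (gen in seq_len(config$generations)) {
    ord <- order(fit)
    n_child <- ps - config$elite_count
    n_cross <- round(config$crossover_fraction * n_child)
    children <- matrix(FALSE, n_child, p)
    for (i in seq_len(n_child)) {
      if (i <= n_cross) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        pt <- if (p > 1) sample.int(p - 1L, 1) else 1L
        children[i, ] <- c(p1[seq_len(pt)], p2[seq(pt + 1L, length.out = p - pt)])
      } else {
        parent <- pop[tournament(), ]
        flip <- runif(p) < config$mutation_rate
        children[i, ] <- xor(parent, flip)
      }
    }
    new_pop <- rbind(pop[ord[seq_len(config$elite_count)], , drop = FALSE],
                     children)
    pop <- new_pop
    fit <- apply(pop, 1, fitness)
    if (min(fit) < best_fit_hist - 1e-12) {
      best_fit_hist <- min(fit)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$stall_generations) break
    }
  }
  best <- which.min(fit)
  list(best = pop[best, ], fitness = fit[best])
}

#' @export
print.ga_pls_result <- function(x, ...) {
  top <- dplyr::slice_max(x$pct_selection, .data$pct, n = 5)
  cat(sprintf("GA-PLS selection over %d runs; top descriptors: %s\n",
              nrow(x$selection),
              paste0(top$descriptor, " (", round(top$pct), "%)",
                     collapse = ", ")))
  invisible(x)
}

#' @export
tidy.ga_pls_result <- function(x, ...) x$pct_selection

#' Consensus GA-PLS retention model
#'
#' Builds the final QSRR model from the descriptors whose percentage of
#' selection across GA restarts exceeds the mean percentage of selection,
#' refits PLS on the training samples with the latent-variable count
#' minimizing the leave-one-out RMSECV, and evaluates it on the held-out
#' validation samples. Statistical significance of the cross-validated
#' predictions is assessed by [cv_anova()].
#'
#' @param ga_result A [ga_pls()] result.
#' @param X Full descriptor table (all samples; must carry the descriptors
#'   the GA saw). A `compound` column supplies ids.
#' @param y Full response vector.
#' @param split A [kennard_stone_split()] (or compatible list with `train`
#'   and `test` ids).
#' @param lv_max Cap on latent variables for the final model; defaults to
#'   the GA configuration's.
#' @return A `consensus_qsrr` object: `consensus` (descriptor names),
#'   `pct_selection`, final `model` ([pls_fit()]), `lv`, `rmsec`,
#'   `rmsecv`, `rmse_train`, `rmse_test`, `cv_anova` (one-row tibble),
#'   and `predictions` (tibble `compound`, `set`, `y`, `y_hat`).
#' @export
consensus_model <- function(ga_result, X, y, split, lv_max = NULL) {
  stopifnot(inherits(ga_result, "ga_pls_result"))
  pct <- ga_result$pct_selection
  consensus <- pct$descriptor[pct$pct > mean(pct$pct)]
  if (!length(consensus)) abort("empty consensus descriptor set")
  X <- tibble::as_tibble(X)
  ids <- if ("compound" %in% names(X)) X$compound else seq_len(nrow(X))
  tr <- ids %in% split$train
  te <- ids %in% split$test
  Xc <- X[consensus]
  lv_max <- min(lv_max %||% ga_result$config$lv_max, sum(tr) - 2,
                length(consensus))
  cv <- pls_loo_rmsecv(Xc[tr, ], y[tr], lv_max)
  lv <- cv$lv[which.min(cv$rmsecv)]
  model <- pls_fit(Xc[tr, ], y[tr], lv)
  y_hat_tr <- model$fitted
  y_hat_te <- predict(model, Xc[te, , drop = FALSE])
  loo <- cpp_pls_loo(as.matrix(Xc[tr, ]), y[tr], lv)[, lv]
  structure(
    list(
      consensus = consensus,
      pct_selection = pct,
      model = model,
      lv = lv,
      rmsec = model$rmsec,
      rmsecv = min(cv$rmsecv),
      rmse_train = sqrt(mean((y[tr] - y_hat_tr)^2)),
      rmse_test = sqrt(mean((y[te] - y_hat_te)^2)),
      cv_anova = cv_anova(y[tr], loo, lv),
      predictions = tibble::tibble(
        compound = c(ids[tr], ids[te]),
        set = rep(c("train", "test"), c(sum(tr), sum(te))),
        y = c(y[tr], y[te]),
        y_hat = c(y_hat_tr, y_hat_te)
      )
    ),
    class = "consensus_qsrr"
  )
}

#' @export
print.consensus_qsrr <- function(x, ...) {
  cat(sprintf(
    "Consensus GA-PLS model: %d descriptors, %d LV; RMSECV %.3f, RMSE train %.3f / test %.3f (CV-ANOVA p = %.3g)\n",
    length(x$consensus), x$lv, x$rmsecv, x$rmse_train, x$rmse_test,
    x$cv_anova$p
  ))
  invisible(x)
}

#' @export
glance.consensus_qsrr <- function(x, ...) {
  tibble::tibble(
    n_consensus = length(x$consensus), lv = x$lv, rmsec = x$rmsec,
    rmsecv = x$rmsecv, rmse_train = x$rmse_train, rmse_test = x$rmse_test,
    cv_anova_p = x$cv_anova$p
  )
}

#' @export
tidy.consensus_qsrr <- function(x, ...) x$predictions
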