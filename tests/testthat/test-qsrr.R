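test_that("pre-selection applies its three filters as specified by hand", {
  set.seed(10)
  n <- 20
  base <- rnorm(n)
  X <- tibble::tibble(
    keepA = base + rnorm(n, sd = 1.5),          # informative, kept
    dupA  = NA_real_,                           # placeholder, set below
    lowv  = 100 + rnorm(n, sd = 0.1),           # RSD << 5%, removed
    miss  = c(NA, rnorm(n - 1)),                # missing, removed
    indep = rnorm(n)                            # independent, kept
  )
  X$dupA <- X$keepA + rnorm(n, sd = 0.05)       # redundant with keepA
  y <- base
  sel <- preselect_descriptors(X, y)
  expect_equal(sel$removed_missing, "miss")
  expect_equal(sel$removed_low_rsd, "lowv")
  expect_equal(nrow(sel$removed_redundant), 1)
  # the member less correlated with y loses
  ry <- abs(cor(cbind(X$keepA, X$dupA), y))
  loser <- c("keepA", "dupA")[which.min(ry)]
  expect_equal(sel$removed_redundant$removed, loser)
  expect_setequal(sel$survivors, setdiff(c("keepA", "dupA", "indep"), loser))
})

test_that("pre-selection is idempotent and protects against emptiness", {
  d <- gen_descriptor_dataset(n = 24, p = 12, correlated_fraction = 0.25,
                              seed = 21)
  s1 <- preselect_descriptors(d$X, d$y)
  X2 <- d$X[c("compound", s1$survivors)]
  s2 <- preselect_descriptors(X2, d$y)
  expect_setequal(s2$survivors, s1$survivors)
  expect_equal(nrow(s2$removed_redundant), 0)
  flat <- tibble::tibble(a = rep(1, 10))
  expect_error(preselect_descriptors(flat, rnorm(10)), "all descriptors removed")
})

test_that("duplicated columns lose exactly one member each", {
  d <- gen_descriptor_dataset(n = 30, p = 10, correlated_fraction = 0.5,
                              seed = 33)
  sel <- preselect_descriptors(d$X, d$y)
  dup_pairs <- grep("_dup$", names(d$X), value = TRUE)
  for (dup in dup_pairs) {
    orig <- sub("_dup$", "", dup)
    expect_equal(sum(c(dup, orig) %in% sel$survivors), 1)
  }
})

test_that("Kennard-Stone split is deterministic with the max-distance seed pair", {
  d <- gen_descriptor_dataset(n = 26, p = 8, seed = 2)
  sp <- kennard_stone_split(d$X, 0.7)
  expect_equal(length(sp$train), 18)
  expect_equal(length(sp$test), 8)
  expect_setequal(c(sp$train, sp$test), 1:26)
  expect_identical(sp, kennard_stone_split(d$X, 0.7))
  # two well-separated clusters: the seed pair spans them
  clust <- rbind(matrix(rnorm(10, mean = 0, sd = 0.1), 5),
                 matrix(rnorm(10, mean = 50, sd = 0.1), 5))
  sp2 <- kennard_stone_split(tibble::as_tibble(as.data.frame(clust)), 0.5)
  expect_equal(sort(c(sum(sp2$train[1:2] <= 5), sum(sp2$train[1:2] > 5))),
               c(1, 1))
})

test_that("PLS collapses to exact and OLS limits", {
  set.seed(12)
  n <- 16; p <- 5
  X <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n)))
  # a single-descriptor model is fit exactly with one latent variable
  x1 <- X[, 1, drop = FALSE]
  fit <- pls_fit(x1, 2 * X[[1]] + 1, 1)
  expect_lt(fit$rmsec, 1e-8)
  # with full rank the PLS fit equals ordinary least squares
  y <- rnorm(n)
  full <- pls_fit(X, y, p)
  ols <- lm(y ~ ., data = X)
  expect_equal(unname(full$fitted), unname(fitted(ols)), tolerance = 1e-8)
  expect_error(pls_fit(X, y, p + 20), "lv must lie")
})

test_that("leave-one-out predictions equal the explicit refit oracle", {
  set.seed(13)
  n <- 14; p <- 6
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("D", 1:p)))
  y <- X[, 2] - 0.5 * X[, 5] + rnorm(n, sd = 0.3)
  tab <- pls_loo_rmsecv(tibble::as_tibble(as.data.frame(X)), y, 4)
  for (lv in 1:4) {
    oracle <- oracle_pls_loo(X, y, lv)
    expect_equal(tab$rmsecv[lv], sqrt(mean((y - oracle)^2)), tolerance = 1e-10)
  }
})

test_that("PLS predictions agree with an independent reference implementation", {
  set.seed(14)
  n <- 15; p <- 6
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("D", 1:p)))
  y <- X[, 1] + 0.5 * X[, 3] + rnorm(n, sd = 0.3)
  fit <- pls_fit(tibble::as_tibble(as.data.frame(X)), y, 3)
  mo <- suppressMessages(mixOmics::pls(X, y, ncomp = 3, mode = "regression"))
  ref <- predict(mo, X)$predict[, 1, 3]
  expect_equal(unname(fit$fitted), unname(ref), tolerance = 1e-10)
})

test_that("CV-ANOVA hits its degenerate and strong-signal endpoints", {
  set.seed(15)
  n <- 18
  y <- rnorm(n)
  null_loo <- (sum(y) - y) / (n - 1)
  expect_equal(cv_anova(y, null_loo, 2)$p, 1)
  # strong planted signal
  X <- matrix(rnorm(n * 8), n)
  ys <- 2 * X[, 1] + rnorm(n, sd = 0.1)
  loo <- oracle_pls_loo(X, ys, 2)
  expect_lt(cv_anova(ys, loo, 2)$p, 1e-4)
  zero <- cv_anova(ys, ys, 2)
  expect_true(zero$zero_residual)
  expect_lte(zero$p, 1e-16)
})
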