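test_that("a single-descriptor problem selects its only descriptor", {
  set.seed(20)
  X <- tibble::tibble(D1 = rnorm(15))
  y <- 2 * X$D1 + rnorm(15, sd = 0.1)
  res <- ga_pls(X, y, ga_config(n_runs = 3, generations = 5, seed = 4))
  expect_equal(res$pct_selection$pct, 100)
  expect_true(all(res$selection))
})

test_that("the selection profile is a deterministic function of the master seed", {
  d <- gen_descriptor_dataset(n = 20, p = 12, seed = 8)
  cfg <- ga_config(n_runs = 5, generations = 8, seed = 99)
  a <- ga_pls(d$X, d$y, cfg)
  b <- ga_pls(d$X, d$y, cfg)
  expect_identical(a$selection, b$selection)
  expect_identical(a$best_fitness, b$best_fitness)
})

test_that("longer evolution never returns a worse best fitness", {
  d <- gen_descriptor_dataset(n = 20, p = 15, seed = 5)
  short <- ga_pls(d$X, d$y, ga_config(n_runs = 4, generations = 1,
                                      stall_generations = 50, seed = 7))
  long <- ga_pls(d$X, d$y, ga_config(n_runs = 4, generations = 25,
                                     stall_generations = 50, seed = 7))
  expect_true(all(long$best_fitness <= short$best_fitness + 1e-12))
})

test_that("planted descriptors dominate the selection profile", {
  d <- gen_descriptor_dataset(n = 26, p = 30, k_informative = 3, sigma = 0.1,
                              seed = 3)
  split <- kennard_stone_split(d$X, 0.7)
  tr <- d$X$compound %in% split$train
  res <- ga_pls(d$X[tr, ], d$y[tr], ga_config(n_runs = 25, seed = 11))
  ranked <- dplyr::arrange(res$pct_selection, dplyr::desc(.data$pct))
  expect_setequal(head(ranked$descriptor, 3), d$truth$planted)
  cm <- consensus_model(res, d$X, d$y, split)
  expect_true(all(d$truth$planted %in% cm$consensus))
  expect_lt(cm$cv_anova$p, 1e-4)
  expect_equal(sort(unique(cm$predictions$set)), c("test", "train"))
})

test_that("unanimous runs give a two-point selection profile", {
  sel <- matrix(c(TRUE, TRUE, FALSE), 4, 3, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c")))
  res <- structure(
    list(pct_selection = tibble::tibble(descriptor = colnames(sel),
                                        pct = 100 * colMeans(sel)),
         selection = sel, best_fitness = rep(0.1, 4),
         config = ga_config(n_runs = 4)),
    class = "ga_pls_result"
  )
  expect_setequal(res$pct_selection$pct, c(100, 100, 0))
  set.seed(30)
  X <- tibble::tibble(compound = 1:20, a = rnorm(20), b = rnorm(20),
                      c = rnorm(20))
  y <- X$a - X$b + rnorm(20, sd = 0.1)
  split <- kennard_stone_split(X, 0.7)
  cm <- consensus_model(res, X, y, split)
  expect_setequal(cm$consensus, c("a", "b"))
})

test_that("a null selection profile yields no usable consensus", {
  res <- structure(
    list(pct_selection = tibble::tibble(descriptor = c("a", "b"),
                                        pct = c(50, 50)),
         selection = NULL, best_fitness = NULL,
         config = ga_config(n_runs = 2)),
    class = "ga_pls_result"
  )
  X <- tibble::tibble(compound = 1:10, a = rnorm(10), b = rnorm(10))
  expect_error(
    consensus_model(res, X, rnorm(10),
                    list(train = 1:7, test = 8:10)),
    "empty consensus"
  )
})
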