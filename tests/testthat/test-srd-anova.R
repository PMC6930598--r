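cv_design <- function(seed = 1) {
  m <- assemble_matrix()
  cvl <- lapply(setNames(nm = c("STD", "IS", "RNK")),
                function(k) sevenfold_cv(pretreat(m, k), seed = seed))
  build_design(cvl)
}

test_that("the fixture design has nine classes with the expected cell sizes", {
  design <- cv_design()
  expect_equal(nrow(design), 651)
  expect_equal(dplyr::n_distinct(design$anova_class), 9)
  counts <- dplyr::count(design, .data$anova_class)
  expect_equal(counts$n[counts$anova_class == "Comp_DFT"], 126) # 6 x 3 x 7
  expect_equal(counts$n[counts$anova_class == "MEKC"], 21)      # 1 x 3 x 7
  expect_equal(as.vector(table(design$pretreatment)), rep(217L, 3))
})

test_that("unlabeled measures are refused when building the design", {
  m <- fixture_matrix("STD")
  cv <- sevenfold_cv(m, seed = 1)
  meta <- measure_metadata()[-1, ]
  expect_error(build_design(list(STD = cv), meta), "unlabeled")
})

test_that("ANOVA degrees of freedom match the factorial layout", {
  a <- anova_full_interaction(cv_design())
  expect_equal(a$df, c(1L, 2L, 8L, 16L, 624L, 650L))
  # additivity of sequential sums of squares in a corrected-total sense
  expect_equal(a$ss[6], sum(a$ss[2:5]))
  # qualitative pattern: descriptor class matters, pretreatment does not
  expect_lt(a$p[3], 0.05)
  expect_gt(a$p[2], 0.05)
  expect_gt(a$p[4], 0.05)
})

test_that("sequential sums of squares match an explicit projection oracle", {
  set.seed(8)
  toy <- expand.grid(pretreatment = c("a", "b", "c"),
                     anova_class = c("x", "y"),
                     rep = 1:3)
  toy$srd_pct <- rnorm(nrow(toy), mean = ifelse(toy$anova_class == "x", 0, 2))
  a <- anova_full_interaction(toy)
  # oracle: residual sums of squares of nested least-squares fits
  rss <- function(form) sum(resid(lm(form, data = toy))^2)
  r0 <- rss(srd_pct ~ 1)
  r1 <- rss(srd_pct ~ pretreatment)
  r2 <- rss(srd_pct ~ pretreatment + anova_class)
  r3 <- rss(srd_pct ~ pretreatment * anova_class)
  expect_equal(a$ss[2], r0 - r1, tolerance = 1e-8)
  expect_equal(a$ss[3], r1 - r2, tolerance = 1e-8)
  expect_equal(a$ss[4], r2 - r3, tolerance = 1e-8)
  expect_equal(a$ss[5], r3, tolerance = 1e-8)
})

test_that("on balanced designs sequential and marginal sums of squares agree", {
  set.seed(9)
  toy <- expand.grid(pretreatment = c("a", "b"), anova_class = c("x", "y", "z"),
                     rep = 1:4)
  toy$srd_pct <- rnorm(nrow(toy))
  a <- anova_full_interaction(toy)
  swapped <- anova_full_interaction(
    dplyr::rename(toy, anova_class = "pretreatment", pretreatment = "anova_class"))
  expect_equal(a$ss[2], swapped$ss[3], tolerance = 1e-10)
  expect_equal(a$ss[3], swapped$ss[2], tolerance = 1e-10)
})

test_that("observation order is irrelevant and empty cells are named", {
  design <- cv_design()
  shuffled <- design[sample(nrow(design)), ]
  expect_equal(anova_full_interaction(design), anova_full_interaction(shuffled))
  broken <- design[!(design$pretreatment == "IS" & design$anova_class == "MEKC"), ]
  expect_error(anova_full_interaction(broken), "IS MEKC")
  flat <- dplyr::mutate(design, srd_pct = 5)
  a <- anova_full_interaction(flat)
  expect_equal(a$ss[2:4], rep(0, 3), tolerance = 1e-18)
  expect_equal(a$p[2:4], rep(1, 3))
})

test_that("class-mean comparisons rank chromatographic classes as closest to consensus", {
  design <- cv_design()
  cmp <- class_mean_comparisons(design)
  expect_equal(nrow(cmp), choose(9, 2))
  expect_true(all(cmp$p_fisher <= cmp$p_tukey + 1e-12))
  means <- tapply(design$srd_pct, design$anova_class, mean)
  expect_equal(names(which.max(means)), "MEKC")
})
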