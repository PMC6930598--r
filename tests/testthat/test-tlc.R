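test_that("R_F to R_M transform matches its closed form and domain", {
  expect_equal(rm_from_rf(0.5), 0)
  expect_equal(rm_from_rf(0.25), log10(3))
  expect_equal(rm_from_rf(0.8), log10(0.25))
  expect_error(rm_from_rf(0), "strictly between")
  expect_error(rm_from_rf(1), "strictly between")
})

test_that("noiseless retention lines are recovered exactly", {
  fr <- seq(0.4, 0.9, by = 0.1)
  fit <- fit_sw(2.0 - 3.0 * fr, fr)
  expect_equal(fit$rm0, 2.0)
  expect_equal(fit$m, 3.0)
  expect_equal(fit$r2, 1)
  expect_true(fit$perfect)
  expect_equal(fit$F, Inf)
  expect_error(fit_sw(c(1, 2), c(0.4, 0.5)), "at least 3")
  expect_error(fit_sw(c(1, 2, 3), rep(0.5, 3)), "zero variance")
})

test_that("fit statistics obey the C0 and F-R2 identities", {
  set.seed(11)
  fr <- seq(0.4, 0.9, by = 0.1)
  for (i in 1:20) {
    rm <- 2.5 - 3.2 * fr + rnorm(6, sd = 0.08)
    fit <- fit_sw(rm, fr)
    expect_lt(abs(fit$c0 * fit$m - fit$rm0), 1e-9)
    expect_lt(abs(fit$F - fit$r2 / (1 - fit$r2) * (fit$n - 2)), 1e-6)
  }
})

test_that("simulated plates recover the true line parameters on average", {
  set.seed(123)
  fr <- seq(0.4, 0.9, by = 0.1)
  est <- vapply(1:500, function(i) {
    rm <- 2.0 - 3.0 * fr + rnorm(6, sd = 0.05)
    fit <- fit_sw(rm, fr)
    c(fit$rm0, fit$m)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 2.0), 0.05)
  expect_lt(abs(mean(est[2, ]) - 3.0), 0.05)
})

test_that("index table reproduces printed C0 and orients PC1 against rm0", {
  chrom <- lipo_fixtures("chromatographic")
  expect_equal(round(chrom$C8_RM0[1] / chrom$C8_m[1], 3), 0.681)
  plate <- gen_tlc_plate(n_compounds = 12, sigma = 0.03, seed = 5)
  tab <- tlc_index_table(plate$rf, plate$fractions)
  expect_lt(cor(tab$pc1, tab$rm0), 0)
  expect_equal(tab$mean_rm,
               rowMeans(rm_from_rf(as.matrix(plate$rf[-1]))))
})

test_that("PC1 equals an SVD oracle up to sign, with rank-1 at 100%", {
  plate <- gen_tlc_plate(n_compounds = 10, sigma = 0.05, seed = 9)
  tab <- tlc_index_table(plate$rf, plate$fractions)
  rm <- rm_from_rf(as.matrix(plate$rf[-1]))
  ctr <- scale(rm, scale = FALSE)
  sv <- svd(ctr)
  oracle <- sv$u[, 1] * sv$d[1]
  expect_true(max(abs(tab$pc1 - oracle)) < 1e-8 ||
                max(abs(tab$pc1 + oracle)) < 1e-8)
  # rank-1 plate: every compound shares one profile, shifted
  fr <- seq(0.4, 0.9, by = 0.1)
  rf1 <- 1 / (1 + 10^outer(seq(1, 2.5, length.out = 6), 2.5 * fr, "-"))
  colnames(rf1) <- fr
  tab1 <- tlc_index_table(
    dplyr::bind_cols(tibble::tibble(compound = 1:6), tibble::as_tibble(rf1)),
    fr
  )
  expect_equal(attr(tab1, "variance_explained"), 100)
})

test_that("invalid retardation factors are located precisely", {
  plate <- gen_tlc_plate(n_compounds = 4, seed = 2)
  plate$rf[[3]][2] <- 1.2
  expect_error(tlc_index_table(plate$rf, plate$fractions),
               "compound 2")
})

test_that("increasing all R_F decreases every R_M and the intercept", {
  plate <- gen_tlc_plate(n_compounds = 6, sigma = 0, seed = 4)
  tab <- tlc_index_table(plate$rf, plate$fractions)
  shifted <- plate$rf
  shifted[-1] <- 1 - (1 - as.matrix(shifted[-1])) * 0.8 # push R_F towards 1
  tab2 <- tlc_index_table(shifted, plate$fractions)
  expect_true(all(tab2$rm0 < tab$rm0))
})

test_that("congenericity regression reproduces both printed determination coefficients", {
  chrom <- lipo_fixtures("chromatographic")
  c8 <- congener_regression(tibble::tibble(rm0 = chrom$C8_RM0, m = chrom$C8_m))
  c18 <- congener_regression(tibble::tibble(rm0 = chrom$C18_RM0, m = chrom$C18_m))
  expect_equal(round(c8$r2, 3), 0.912)
  expect_equal(round(c18$r2, 3), 0.954)
  # collinear input is flagged as a perfect fit instead of overflowing
  perfect <- congener_regression(tibble::tibble(m = 1:10, rm0 = 0.9 * (1:10) + 0.1))
  expect_true(perfect$perfect)
  expect_equal(perfect$F, Inf)
  expect_error(congener_regression(tibble::tibble(rm0 = 1:5, m = rep(1, 5))),
               "degenerate")
})
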