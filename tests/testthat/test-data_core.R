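test_that("fixture tables have the published shapes and anchor values", {
  fx <- lipo_fixtures()
  expect_equal(dim(fx$software), c(26, 14))        # compound + 13 measures
  expect_equal(dim(fx$dft), c(26, 7))              # compound + 6 measures
  expect_equal(dim(fx$chromatographic), c(26, 13)) # compound + 12 measures
  # spot checks against the printed tables
  expect_identical(fx$software$logPV_Spartan[12], 4.72)
  expect_identical(fx$dft$PBE0_6311Gpp2df2dp[14], -1.10)
  expect_identical(fx$chromatographic$C18_RM0[2], 3.702)
  expect_false(anyNA(fx$software) || anyNA(fx$dft) || anyNA(fx$chromatographic))
})

test_that("corrupted fixture files fail their checksum", {
  tmp <- file.path(tempdir(), "software_logp.csv")
  writeLines("compound,x\n1,2", tmp)
  expect_error(liporank:::check_fixture_checksum(tmp), "checksum failure")
})

test_that("fixture tables survive a write-read round trip unchanged", {
  fx <- lipo_fixtures("chromatographic")
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(fx, tmp, row.names = FALSE)
  back <- tibble::as_tibble(utils::read.csv(tmp, check.names = FALSE))
  expect_equal(back, fx)
})

test_that("assembled matrix has 31 measures with the documented class counts", {
  m <- assemble_matrix()
  expect_s3_class(m, "lipo_matrix")
  expect_equal(dim(m), c(26, 32)) # compound id + 31 measures
  counts <- table(attr(m, "meta")$anova_class)
  expect_equal(
    counts[c("Comp_A", "Comp_F", "Comp_P", "Comp_M", "Comp_DFT")],
    c(Comp_A = 3, Comp_F = 6, Comp_P = 3, Comp_M = 1, Comp_DFT = 6),
    ignore_attr = TRUE
  )
  expect_equal(
    counts[c("TLC_C8", "TLC_C18", "HPLC_C18", "MEKC")],
    c(TLC_C8 = 5, TLC_C18 = 5, HPLC_C18 = 1, MEKC = 1),
    ignore_attr = TRUE
  )
  # one table alone keeps only its own measures
  m1 <- assemble_matrix(lipo_fixtures("software"))
  expect_equal(ncol(m1) - 1L, 13)
})

test_that("misaligned compound sets are refused with the offenders named", {
  a <- tibble::tibble(compound = 1:5, x = rnorm(5))
  b <- tibble::tibble(compound = 2:6, y = rnorm(5))
  expect_error(assemble_matrix(list(a, b)), "do not align")
  withNA <- tibble::tibble(compound = 1:5, x = c(1, NA, 3, 4, 5))
  expect_error(assemble_matrix(list(withNA)), "missing values")
  dropped <- assemble_matrix(list(withNA), na_action = "drop")
  expect_equal(nrow(dropped), 4)
})

test_that("pretreatments satisfy their column-wise invariants exactly", {
  m <- assemble_matrix()
  std <- liporank:::measure_values(pretreat(m, "STD"))
  expect_lt(max(abs(colMeans(std))), 1e-12)
  expect_lt(max(abs(apply(std, 2, sd) - 1)), 1e-12)
  is <- liporank:::measure_values(pretreat(m, "IS"))
  expect_equal(unname(apply(is, 2, min)), rep(0, ncol(is)))
  expect_equal(unname(apply(is, 2, max)), rep(1, ncol(is)))
  rnk <- liporank:::measure_values(pretreat(m, "RNK"))
  expect_equal(unname(colSums(rnk)), rep(26 * 27 / 2, ncol(rnk)))
  expect_equal(rank_with_ties(c(1, 2, 2, 3)), c(1, 2.5, 2.5, 4))
})

test_that("constant columns are refused under STD and IS but not RNK", {
  tbl <- tibble::tibble(compound = 1:5, a = rnorm(5), flat = rep(2, 5))
  m <- assemble_matrix(list(tbl))
  expect_error(pretreat(m, "STD"), "flat")
  expect_error(pretreat(m, "IS"), "flat")
  rnk <- pretreat(m, "RNK")
  expect_equal(liporank:::measure_values(rnk)[, "flat"], rep(3, 5),
               ignore_attr = TRUE)
})

test_that("SRD against a fixed reference is invariant to rank pretreatment", {
  # with a fixed reference the tie-free rank structure fully determines SRD;
  # the consensus reference is excluded on purpose, since row means change
  # under pretreatment (which is exactly why several pretreatments are run)
  set.seed(7)
  tbl <- tibble::tibble(compound = 1:12, a = rnorm(12), b = rnorm(12),
                        c = rnorm(12))
  gold <- rnorm(12)
  m <- assemble_matrix(list(tbl))
  raw <- srd_scores(m, reference = "gold", gold = gold)
  rnk <- srd_scores(pretreat(m, "RNK"), reference = "gold", gold = gold)
  expect_equal(raw$srd, rnk$srd)
})
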