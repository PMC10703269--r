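test_that("closed form matches hand evaluation and an independent oracle", {
  # hand evaluation: delta -20, C:N 4 -> correction +1.789
  expect_equal(lipid_normalize_d13c(-20.0, 4.0), -18.2113, tolerance = 1e-4)

  set.seed(1)
  cn <- runif(1000, 3.2, 15)
  delta <- runif(1000, -30, -10)
  expect_equal(lipid_normalize_d13c(delta, cn),
               oracle_lipid_correction(delta, cn), tolerance = 1e-9)
})

test_that("correction is strictly increasing in C:N and zero when D = 0", {
  cn <- seq(3.2, 15, by = 0.01)
  corr <- lipid_correction_term(cn)
  expect_true(all(diff(corr) > 0))
  expect_true(all(corr > 0))   # corrected >= input at defaults

  const0 <- lipid_norm_constants(D = 0)
  expect_equal(lipid_normalize_d13c(c(-25, -18), 4.2, const0), c(-25, -18))
})

test_that("C:N at or below the validity threshold is rejected by name", {
  thr <- cn_validity_threshold()
  expect_equal(thr, 0.775 / 0.246)
  expect_error(lipid_normalize_d13c(-20, thr), "threshold")
  expect_error(lipid_normalize_d13c(-20, 2.5), "threshold")
})

test_that("implied C:N inverts the correction and matches the diet pair", {
  # the high-lipid diet raw/lipid-corrected pair implies C:N near 4.85
  cn_hi <- implied_cn(-20.48, -17.76)
  expect_equal(cn_hi, 4.85, tolerance = 0.02)
  expect_equal(lipid_normalize_d13c(-20.48, cn_hi), -17.76, tolerance = 1e-8)
  cn_lo <- implied_cn(-17.75, -16.27)
  expect_equal(lipid_normalize_d13c(-17.75, cn_lo), -16.27, tolerance = 1e-8)
})

test_that("table-level correction preserves rows and flags invalid C:N", {
  empty <- data.frame(d13c = numeric(0), cn_ratio = numeric(0))
  out <- apply_lipid_correction(empty)
  expect_equal(nrow(out), 0)

  one <- data.frame(d13c = -20.0, cn_ratio = 4.0)
  out <- apply_lipid_correction(one)
  expect_equal(out$d13c_lc, -18.2113, tolerance = 1e-4)

  # shared C:N means a constant offset
  tab <- data.frame(d13c = c(-22, -20, -17), cn_ratio = 4.4)
  out <- apply_lipid_correction(tab)
  expect_equal(length(unique(round(out$d13c_lc - out$d13c, 10))), 1)

  # invalid rows: NA in output, count flagged, originals untouched
  tab <- data.frame(d13c = c(-20, -20, -20), cn_ratio = c(4, 2.9, NA))
  expect_message(out <- apply_lipid_correction(tab), "2 row")
  expect_equal(attr(out, "n_excluded"), 2L)
  expect_equal(sum(is.na(out$d13c_lc)), 2)
  expect_equal(out$d13c, tab$d13c)
  expect_equal(nrow(out), 3)
})
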