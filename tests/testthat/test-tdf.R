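test_that("compute_tdf is the mean tissue-food offset with sample SD", {
  # tissue equal to food: zero offset, zero SD
  r <- compute_tdf(rep(8.19, 5), 8.19)
  expect_equal(r$mean, 0)
  expect_equal(r$sd, 0)
  expect_equal(r$n, 5)

  # low-lipid diet mean and a tissue mean of 12.28 give 4.09
  tissue <- 12.28 + c(-0.2, -0.1, 0, 0.1, 0.2)
  expect_equal(compute_tdf(tissue, 8.19)$mean, 4.09)
  expect_equal(compute_tdf(tissue, 8.19)$sd, sd(tissue))

  # translation invariance
  set.seed(4)
  x <- rnorm(30, 12, 0.3)
  expect_equal(compute_tdf(x + 5, 8.19 + 5)$mean, compute_tdf(x, 8.19)$mean)

  expect_error(compute_tdf(numeric(0), 8.19), "at least one")
})

test_that("pooled rows are n-weighted arm means; equal-weight rows are not", {
  trial <- make_trial(seed = 11)
  fit <- fit_tdf(trial$fish, trial$diets)
  for (iso in unique(fit$arms$isotope)) {
    for (d in unique(fit$arms$diet)) {
      a <- fit$arms[fit$arms$isotope == iso & fit$arms$diet == d, ]
      p <- fit$pooled[fit$pooled$isotope == iso & fit$pooled$diet == d, ]
      g <- fit$grand[fit$grand$isotope == iso & fit$grand$diet == d, ]
      expect_equal(p$mean, sum(a$mean * a$n) / sum(a$n), tolerance = 1e-12)
      expect_equal(p$n, sum(a$n))
      expect_equal(g$mean, mean(a$mean), tolerance = 1e-12)
    }
  }
})

test_that("identical arms collapse pooled and equal-weight summaries", {
  d <- expand.grid(diet = "low_lipid", temperature = c(6, 8, 10, 12),
                   fish = 1:10, stringsAsFactors = FALSE)
  d$tank <- paste0("t", d$temperature)
  d$isotope <- "d15n"
  d$delta <- rep(c(4.0, 4.1), length.out = nrow(d))
  s <- summarize_treatments(d[c("diet", "temperature", "tank", "isotope",
                                "delta")])
  expect_equal(s$pooled$mean, s$grand$mean)
})

test_that("equal-weight averages of the reported arm means match the text", {
  ref <- cod_tdf_reference()
  ew <- function(col, diet) mean(ref[[col]][ref$diet == diet])
  expect_lt(abs(ew("d15n_mean", "high_lipid") - 3.40), 0.02)
  expect_lt(abs(ew("d15n_mean", "low_lipid") - 4.09), 0.02)
  expect_lt(abs(ew("d13c_mean", "high_lipid") - 0.75), 0.02)
  expect_lt(abs(ew("d13c_mean", "low_lipid") - (-0.18)), 0.02)
  expect_lt(abs(ew("d13c_lc_mean", "high_lipid") - 0.36), 0.02)
  expect_lt(abs(ew("d13c_lc_mean", "low_lipid") - 0.00), 0.02)
})

test_that("zero-noise trials are recovered exactly; noisy arms are unbiased", {
  trial <- make_trial(seed = 1, noise_scale = 0)
  fit <- fit_tdf(trial$fish, trial$diets)
  ref <- cod_tdf_reference()
  for (iso in c("d15n", "d13c_lc")) {
    m <- merge(fit$arms[fit$arms$isotope == iso, ], ref,
               by = c("diet", "temperature"))
    expect_equal(m$mean, m[[paste0(iso, "_mean")]], tolerance = 1e-10)
  }

  # parameter recovery: mean absolute arm error below 2 SD / sqrt(n)
  errs <- vapply(1:100, function(s) {
    tr <- make_trial(seed = s)
    f <- fit_tdf(tr$fish, tr$diets)
    m <- merge(f$arms[f$arms$isotope == "d15n", ], ref,
               by = c("diet", "temperature"))
    abs(m$mean - m$d15n_mean)
  }, numeric(8))
  ref_o <- ref[order(ref$diet, ref$temperature), ]
  bound <- 2 * ref_o$d15n_sd / sqrt(ref_o$n)
  expect_true(all(rowMeans(errs) <= bound))
})

test_that("arm bias vanishes at very large n without tank effects", {
  tn <- data.frame(diet = c("high_lipid", "low_lipid"), temperature = 6,
                   n = 5000)
  cfg <- trial_config(temperatures = 6, fish_per_tank = 2500,
                      terminal_n = tn, seed = 8)
  trial <- generate_trial(cfg, sim_truth(tank_sd = 0))
  fit <- fit_tdf(trial$fish, trial$diets)
  m <- merge(fit$arms[fit$arms$isotope == "d15n", ], cod_tdf_reference(),
             by = c("diet", "temperature"))
  expect_equal(m$mean, m$d15n_mean, tolerance = 0.01)
})

test_that("tdf_fit methods are coherent with the arm table", {
  trial <- make_trial(seed = 21)
  fit <- fit_tdf(trial$fish, trial$diets)

  tab <- summary(fit)
  expect_equal(nrow(tab), 8 + 2 + 2)
  expect_true(all(c("d15n_mean", "d13c_sd", "d13c_lc_mean") %in% names(tab)))

  cf <- coef(fit)
  expect_equal(nrow(cf), 8)
  a <- fit$arms[fit$arms$isotope == "d15n", ]
  expect_equal(cf$d15n, a$mean[match(paste(cf$diet, cf$temperature),
                                     paste(a$diet, a$temperature))])

  pr <- predict(fit, data.frame(diet = "low_lipid", temperature = 8))
  expect_equal(pr, a$mean[a$diet == "low_lipid" & a$temperature == 8])

  res <- residuals(fit)
  expect_equal(mean(res), 0, tolerance = 1e-10)

  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), sum(a$n))
})
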