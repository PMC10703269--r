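test_that("mass trajectory reproduces exact exponential growth", {
  days <- c(0, 19, 31, 56)
  mass <- 2.6 * exp(0.019 * days)
  traj <- fit_mass_trajectory(days, mass)
  expect_equal(traj$mass_g, 2.6 * exp(0.019 * 0:56), tolerance = 1e-9)
  expect_equal(attr(traj, "rate"), 0.019, tolerance = 1e-10)

  # two points: fitted curve passes through both exactly
  t2 <- fit_mass_trajectory(c(0, 56), c(2.6, 7.6))
  expect_equal(t2$mass_g[t2$day == 0], 2.6, tolerance = 1e-12)
  expect_equal(t2$mass_g[t2$day == 56], 7.6, tolerance = 1e-12)

  expect_error(fit_mass_trajectory(5, 2.6), "two census days")
  expect_error(fit_mass_trajectory(c(0, 56), c(-1, 7.6)), "positive")
})

test_that("growth-rate estimates are unbiased on noisy trajectories", {
  days <- c(0, 19, 31, 56)
  g <- log(7.6 / 2.6) / 56
  set.seed(1)
  rates <- replicate(100, {
    mass <- 2.6 * exp(g * days) * exp(rnorm(4, 0, 0.02))
    attr(fit_mass_trajectory(days, mass), "rate")
  })
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - g), 3 * se)
})

test_that("composition trajectory extrapolates day 0 and clamps", {
  days <- c(15, 24, 56)
  # constant input: constant output everywhere including day 0
  cst <- fit_composition_trajectory(days, rep(0.78, 3))
  expect_equal(cst$frac, rep(0.78, 57))
  # exact line: closed-form day-0 intercept
  line <- fit_composition_trajectory(days, 0.70 + 0.001 * days)
  expect_equal(line$frac[line$day == 0], 0.70, tolerance = 1e-12)
  # negative extrapolation clamped and flagged
  expect_message(
    cl <- fit_composition_trajectory(days, 0.001 + 0.005 * (days - 15)),
    "clamped")
  expect_equal(cl$frac[cl$day == 0], 0)
  expect_gt(attr(cl, "clamped"), 0)
  expect_error(fit_composition_trajectory(15, 0.7), "two sampling days")
})

test_that("assimilation and energy-rate arithmetic is exact", {
  expect_equal(assimilated_dry_mass(10, 0.30, loss_coefficients(0.15, 0.10)),
               2.295)
  expect_equal(assimilated_dry_mass(7.5, 0.30, loss_coefficients(0, 0)),
               7.5 * 0.30)
  expect_equal(assimilated_dry_mass(0, 0.30), 0)

  expect_equal(energy_assimilated_rate(2.0, 5.6, 20), 0.56)
  expect_equal(energy_assimilated_rate(0, 5.6, 20), 0)
  expect_equal(energy_assimilated_rate(4.0, 5.6, 40),
               energy_assimilated_rate(2.0, 5.6, 20))
  expect_error(energy_assimilated_rate(2, 5.6, 0), "positive")
})

test_that("percent change matches the reported growth arithmetic", {
  expect_equal(percent_change(2.6, 7.6), 192)
  expect_equal(percent_change(67.3, 93.8), 39)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 5), "positive")
})

test_that("budgets satisfy mass balance on synthetic trials", {
  for (s in 1:3) {
    b <- compute_mass_budget(make_trial(seed = s))
    tk <- b$tanks
    expect_true(all(tk$dry_assimilated_g > 0))
    expect_true(all(tk$change_protein_g <= tk$protein_assimilated_perfish_g))
    expect_true(all(tk$change_lipid_g <= tk$lipid_assimilated_perfish_g))
    expect_true(all(tk$protein_retention >= 0 & tk$protein_retention <= 1))
    expect_true(all(tk$lipid_retention >= 0 & tk$lipid_retention <= 1))
    # assimilated protein below consumed protein (losses are positive)
    consumed_protein <- tk$consumed_wet_g *
      ifelse(tk$diet == "high_lipid", 0.132, 0.205) / tk$n_fish
    expect_true(all(tk$protein_assimilated_perfish_g < consumed_protein))
  }
})

test_that("budgets are linear in the feeding records", {
  trial <- make_trial(seed = 5)
  b1 <- compute_mass_budget(trial)
  trial2 <- trial
  trial2$feeding$offered_wet_g <- 2 * trial2$feeding$offered_wet_g
  trial2$feeding$uneaten_wet_g <- 2 * trial2$feeding$uneaten_wet_g
  b2 <- compute_mass_budget(trial2)
  expect_equal(b2$tanks$dry_assimilated_g, 2 * b1$tanks$dry_assimilated_g)
  expect_equal(b2$tanks$protein_assimilated_g,
               2 * b1$tanks$protein_assimilated_g)
})

test_that("zero-noise budgets match the generator's bookkeeping", {
  trial <- make_trial(seed = 1, noise_scale = 0)
  b <- compute_mass_budget(trial)
  i <- match(b$tanks$tank, trial$bookkeeping$tank)
  expect_equal(b$tanks$change_dry_g, trial$bookkeeping$true_dry_change[i],
               tolerance = 1e-6)
  expect_equal(b$tanks$dry_assimilated_g,
               trial$bookkeeping$dry_assimilated[i], tolerance = 1e-6)
})

test_that("missing feeding days are reported as gaps", {
  trial <- make_trial(seed = 2)
  trial$feeding <- trial$feeding[trial$feeding$day != 30, ]
  expect_error(compute_mass_budget(trial), "day\\(s\\) 30")
})
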