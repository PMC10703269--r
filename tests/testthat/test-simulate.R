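test_that("a fixed seed reproduces the trial bundle exactly", {
  a <- make_trial(seed = 42)
  b <- make_trial(seed = 42)
  for (nm in c("feeding", "census", "proximate", "fish", "diets")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c2 <- make_trial(seed = 43)
  expect_false(identical(a$fish$d15n, c2$fish$d15n))
})

test_that("zero TDFs and zero noise pin tissue values to the diet means", {
  ref <- cod_tdf_reference()
  ref$d15n_mean <- 0
  ref$d13c_lc_mean <- 0
  trial <- generate_trial(trial_config(seed = 2),
                          sim_truth(tdf_truth = ref, noise_scale = 0))
  food <- aggregate(trial$diets[c("d15n", "d13c_lc")], trial$diets["diet"],
                    mean)
  for (d in food$diet) {
    fish_d <- trial$fish[trial$fish$diet == d, ]
    expect_equal(fish_d$d15n, rep(food$d15n[food$diet == d], nrow(fish_d)))
    lc <- lipid_normalize_d13c(fish_d$d13c, fish_d$cn_ratio)
    expect_equal(lc, rep(food$d13c_lc[food$diet == d], nrow(fish_d)))
  }
})

test_that("arm sizes, mortality and record invariants match the design", {
  trial <- make_trial(seed = 7)
  cfg <- trial$config
  counts <- aggregate(list(n = trial$fish$fish_id),
                      trial$fish[c("diet", "temperature")], length)
  m <- merge(counts, cfg$terminal_n, by = c("diet", "temperature"))
  expect_equal(m$n.x, m$n.y)
  expect_equal(sum(counts$n), 92 + 94)

  # feeding: 0 <= uneaten <= offered, complete day coverage
  expect_true(all(trial$feeding$uneaten_wet_g >= 0))
  expect_true(all(trial$feeding$uneaten_wet_g <= trial$feeding$offered_wet_g))
  expect_setequal(unique(trial$feeding$day), 0:56)

  # proximate fractions valid
  px <- trial$proximate
  expect_true(all(px$moisture_frac + px$lipid_frac + px$protein_frac <= 1))
  expect_true(all(unlist(px[c("moisture_frac", "lipid_frac",
                              "protein_frac")]) >= 0))
  expect_true(all(trial$census$wet_mass_g > 0))
  expect_true(all(trial$census$length_mm > 0))
  expect_true(all(trial$fish$cn_ratio > cn_validity_threshold()))
})

test_that("terminal n beyond the stocked fish is rejected", {
  tn <- cod_tdf_reference()[, c("diet", "temperature", "n")]
  tn$n[1] <- 51
  expect_error(trial_config(terminal_n = tn), "exceeds")
})

test_that("expected growth rises from ~2.6 g toward the arm final means", {
  trial <- make_trial(seed = 3, noise_scale = 0)
  cen <- aggregate(list(mass = trial$census$wet_mass_g),
                   trial$census[c("tank", "day")], mean)
  for (tk in unique(cen$tank)) {
    m <- cen[cen$tank == tk, ]
    m <- m[order(m$day), ]
    expect_true(all(diff(m$mass) > 0))
  }
  overall0 <- mean(cen$mass[cen$day == 0])
  expect_equal(overall0, 2.65, tolerance = 0.05)  # mean of arm initials
})

test_that("the incorporation trajectory obeys its closed form", {
  # k + m = 0: frozen at the initial value
  expect_equal(simulate_isotope_trajectory(10, 8, 3, 0, 0, c(0, 5, 500)),
               rep(10, 3))
  # t = 0 returns delta0 exactly
  expect_identical(simulate_isotope_trajectory(-19, -17, 0.5, 0.03, 0.02, 0),
                   -19)
  # ten half-lives: within 0.001 of the asymptote
  km <- log(2) / 14
  expect_equal(simulate_isotope_trajectory(10, 8, 3, km, 0, 140), 11,
               tolerance = 0.001)
  # one half-life: exactly halfway between delta0 and the asymptote
  expect_equal(simulate_isotope_trajectory(10, 8, 3, km / 2, km / 2, 14),
               (10 + 11) / 2)
  # monotone approach
  tt <- seq(0, 100, by = 1)
  path <- simulate_isotope_trajectory(10, 8, 3, km, 0, tt)
  expect_true(all(diff(path) > 0))
  expect_true(all(path <= 11))
})

test_that("C:N from proximate composition behaves like the elemental form", {
  expect_equal(cn_from_proximate(1, 0), 0.53 / 0.17)
  # strictly increasing in lipid at fixed protein
  cn <- cn_from_proximate(0.65, seq(0, 0.4, by = 0.05))
  expect_true(all(diff(cn) > 0))
  # scale invariance
  expect_equal(cn_from_proximate(0.6, 0.2), cn_from_proximate(1.2, 0.4))
  expect_error(cn_from_proximate(0, 0.1), "protein")
})
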