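test_that("with zero tank variance the mixed fit returns plain cell means", {
  # balanced cells, residuals symmetric within every tank, so tank
  # variance is estimated at zero and cell means are exact group means;
  # a strong interaction makes the interaction model win the AIC race
  arms <- expand.grid(diet = c("high_lipid", "low_lipid"),
                      temperature = c(6, 8, 10, 12),
                      stringsAsFactors = FALSE)
  arms$mu <- c(3.3, 4.0, 3.5, 4.4, 3.2, 4.9, 3.6, 4.1)
  d <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    data.frame(diet = arms$diet[i], temperature = arms$temperature[i],
               tank = paste0("t", i, "_", rep(1:2, each = 8)),
               delta = arms$mu[i] + rep(c(-0.1, 0.1), 8), isotope = "d15n",
               stringsAsFactors = FALSE)
  }))
  fit <- fit_and_select(d)
  expect_equal(fit$selected, "diet * temperature")
  expect_lt(fit$ranef_sd, 1e-6)
  lt <- tukey_letters(fit)
  key <- paste(lt$diet, lt$temperature)
  expect_equal(lt$emmean[match(paste(arms$diet, arms$temperature), key)],
               arms$mu, tolerance = 1e-8)
})

test_that("duplicating every row changes AIC but not the point estimates", {
  set.seed(2)
  d <- make_deltas(arm_means = c(3.3, 3.4, 3.5, 3.3, 4.0, 4.1, 4.1, 4.0),
                   arm_sds = rep(0.15, 8), arm_ns = rep(20, 8))
  f1 <- fit_and_select(d)
  f2 <- fit_and_select(rbind(d, d))
  expect_false(isTRUE(all.equal(f1$candidates$AIC, f2$candidates$AIC)))
  # compare the common candidate structure under ML on both datasets
  m1 <- lme4::lmer(delta ~ diet * temperature + (1 | tank),
                   data = f1$data, REML = FALSE)
  m2 <- lme4::lmer(delta ~ diet * temperature + (1 | tank),
                   data = f2$data, REML = FALSE)
  expect_equal(lme4::fixef(m1), lme4::fixef(m2), tolerance = 1e-6)
})

test_that("a diet represented by a single tank is rejected", {
  set.seed(3)
  d <- make_deltas(arm_means = rep(3.5, 8), arm_sds = rep(0.15, 8),
                   arm_ns = rep(10, 8))
  d$tank[d$diet == "low_lipid"] <- "only_tank"
  expect_error(fit_and_select(d), "two tanks")
})

test_that("model selection favours the diet effect when truth has one", {
  # diet effect 0.7 permil, no temperature effect, reported arm sizes
  ns <- cod_tdf_reference()$n
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    d <- make_deltas(arm_means = rep(c(3.4, 4.1), each = 4),
                     arm_sds = rep(0.15, 8), arm_ns = ns)
    sel <- fit_and_select(d)$selected
    sel %in% c("diet", "diet + temperature")
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("extreme separation yields distinct letters; letters are stable", {
  set.seed(5)
  d <- make_deltas(arm_means = rep(c(0, 10), each = 4),
                   arm_sds = rep(1, 8), arm_ns = rep(20, 8))
  fit <- fit_and_select(d)
  lt <- tukey_letters(fit)
  hi <- lt$letters[lt$diet == "high_lipid"]
  lo <- lt$letters[lt$diet == "low_lipid"]
  expect_length(intersect(strsplit(hi[1], "")[[1]],
                          strsplit(lo[1], "")[[1]]), 0)
  expect_identical(lt, tukey_letters(fit))   # deterministic given the fit
})

test_that("insert-and-absorb agrees with the multcomp lettering", {
  # same significance pattern in, same letter-sharing partition out
  share_matrix <- function(lets, groups) {
    outer(lets, lets, Vectorize(function(a, b) {
      length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
    }))
  }
  ia_mine <- function(groups, sig) {
    codtdf:::insert_absorb(groups, sig)
  }
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    groups <- paste0("g", seq_len(k))
    sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        sig[i, j] <- sig[j, i] <- runif(1) < 0.4
      }
    }
    mine <- ia_mine(groups, sig)
    pairs <- which(upper.tri(sig), arr.ind = TRUE)
    x <- setNames(sig[pairs],
                  paste(groups[pairs[, 1]], groups[pairs[, 2]], sep = "-"))
    theirs <- multcomp:::insert_absorb(x, lvl_order = groups)$Letters
    expect_equal(share_matrix(unname(mine[groups]), groups),
                 share_matrix(unname(theirs[groups]), groups))
  }
})

test_that("temperature spread reproduces the reported within-diet ranges", {
  ref <- cod_tdf_reference()
  arm <- data.frame(diet = ref$diet, temperature = ref$temperature,
                    mean = ref$d15n_mean)
  sp <- temperature_spread(arm)
  expect_equal(sp$spread[sp$diet == "high_lipid"], 0.22)
  expect_equal(sp$spread[sp$diet == "low_lipid"], 0.12)
  expect_equal(
    temperature_spread(data.frame(diet = "x", temperature = c(6, 8),
                                  mean = c(1, 1)))$spread, 0)
  expect_error(temperature_spread(data.frame(diet = "x", temperature = 6,
                                             mean = 1)), "two temperature")
})
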