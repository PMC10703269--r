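#' Configuration of a synthetic feeding trial
#'
#' Describes the design of a crossed diet-by-temperature tank trial:
#' treatment levels, replication, stocking, sampling schedule and the
#' random seed.  Defaults reproduce the juvenile Pacific cod trial this
#' package models: 4 temperatures x 2 diets x 2 replicate tanks, ~25
#' fish per tank with mortality down to the reported terminal arm sizes,
#' censuses on days 0/19/31/56 and proximate sampling on days 15/24/56.
#'
#' The census and proximate schedules are deliberately independent
#' configuration entries (the source protocols used different day lists
#' for growth and composition sampling).
#'
#' @param temperatures water temperatures, deg C.
#' @param diets diet arm names.
#' @param tanks_per_arm replicate tanks per diet x temperature arm.
#' @param fish_per_tank fish stocked per tank at day 0.
#' @param terminal_n data frame (`diet`, `temperature`, `n`) with the
#'   number of fish surviving to the terminal sampling in each arm, or
#'   `NULL` to use the reported arm sizes where the arm matches the
#'   reference design (full survival otherwise).
#' @param census_days days on which length/weight censuses occur.
#' @param proximate_days days on which tank-mean proximate composition
#'   is sampled.
#' @param feeding_days days on which food is offered (default 0:56).
#' @param seed integer random seed (mandatory; fixes the whole bundle).
#' @return A list of class `trial_config`.
#' @seealso [sim_truth()], [generate_trial()]
#' @export
trial_config <- function(temperatures = c(6, 8, 10, 12),
                         diets = c("high_lipid", "low_lipid"),
                         tanks_per_arm = 2, fish_per_tank = 25,
                         terminal_n = NULL,
                         census_days = c(0, 19, 31, 56),
                         proximate_days = c(15, 24, 56),
                         feeding_days = 0:56, seed = 1) {
  stopifnot(length(temperatures) >= 1, length(diets) >= 1,
            tanks_per_arm >= 1, fish_per_tank >= 1,
            is.numeric(seed), length(seed) == 1, is.finite(seed))
  last_day <- max(feeding_days)
  for (d in list(census_days, proximate_days)) {
    if (is.unsorted(d) || any(d < 0) || any(d > last_day)) {
      stop("day lists must be sorted and within [0, ", last_day, "]",
           call. = FALSE)
    }
  }
  arms <- expand.grid(diet = diets, temperature = temperatures,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.null(terminal_n)) {
    ref <- cod_tdf_reference()
    terminal_n <- merge(arms, ref[, c("diet", "temperature", "n")],
                        by = c("diet", "temperature"), all.x = TRUE)
    terminal_n$n[is.na(terminal_n$n)] <- tanks_per_arm * fish_per_tank
  }
  stopifnot(all(c("diet", "temperature", "n") %in% names(terminal_n)))
  if (any(terminal_n$n > tanks_per_arm * fish_per_tank)) {
    stop("terminal_n exceeds the number of stocked fish in at least one arm",
         call. = FALSE)
  }
  if (any(terminal_n$n < 1)) stop("terminal_n must be >= 1", call. = FALSE)
  structure(list(temperatures = temperatures, diets = diets,
                 tanks_per_arm = tanks_per_arm, fish_per_tank = fish_per_tank,
                 terminal_n = terminal_n, census_days = census_days,
                 proximate_days = proximate_days, feeding_days = feeding_days,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Ground truth for the synthetic feeding trial
#'
#' Collects every quantity the generator treats as true: per-arm TDFs and
#' per-fish isotope SDs, diet composition and isotope batch distributions,
#' growth endpoints and rations, body-composition trajectories, loss
#' coefficients, and nuisance noise scales.  Defaults are configured from
#' the reported trial summaries ([cod_tdf_reference()],
#' [cod_diet_spec()], [cod_growth_reference()]); body-composition and
#' noise defaults are realistic values documented in the methods
#' vignette.
#'
#' Terminal tissue isotopes are drawn, by default, at dietary
#' equilibrium: realized diet batch grand mean + true TDF + tank effect +
#' per-fish noise (the fish roughly tripled in mass over the trial, so
#' tissues are at or near isotopic steady state).  Setting
#' `isotope_mode = "trajectory"` instead runs the two-rate incorporation
#' model of [simulate_isotope_trajectory()] from `initial_d15n` /
#' `initial_d13c_lc` with combined turnover-plus-growth half-life
#' `turnover_half_life` (days).
#'
#' @param tdf_truth data frame in the shape of [cod_tdf_reference()]:
#'   per-arm true `d15n_mean`, `d13c_lc_mean` and per-fish SDs.
#' @param diet_spec data frame in the shape of [cod_diet_spec()].
#' @param growth list in the shape of [cod_growth_reference()].
#' @param tank_sd SD of the tank-level random intercept on each isotope,
#'   per mil.
#' @param mass_cv persistent between-fish CV of wet mass; `census_cv`
#'   adds independent per-census measurement scatter.
#' @param census_cv see `mass_cv`.
#' @param length_cv between-fish CV of total length.
#' @param proximate_sd SD of tank-mean proximate fractions (tank means
#'   average ~20 fish, hence small).
#' @param fish_lipid_sd,fish_protein_sd per-fish SD of dry-basis lipid
#'   and protein fractions (drive between-fish C:N variation).
#' @param moisture length-2 vector: wet-basis moisture fraction at day 0
#'   and day 56 (linear in between).
#' @param lipid_wet named list per diet: wet-basis lipid fraction at
#'   day 0 and day 56.
#' @param protein_wet length-2 vector: wet-basis protein fraction at
#'   day 0 and day 56.
#' @param diet_moisture moisture fraction of the composed diets
#'   (converts printed wet-basis composition to dry basis).
#' @param losses [loss_coefficients()] assumed when translating rations
#'   into assimilated dry mass.
#' @param appetite_ratio mean fraction of offered food that is eaten.
#' @param isotope_mode `"equilibrium"` or `"trajectory"` (see Details).
#' @param turnover_half_life days; half-life of the combined turnover +
#'   growth-dilution rate `k + m` in trajectory mode (midpoint of the
#'   9-22 d range reported for juvenile fish muscle).
#' @param initial_d15n,initial_d13c_lc day-0 tissue values (trajectory
#'   mode), per mil; defaults reflect a hatchery pellet diet.
#' @param noise_scale master multiplier on every SD/CV above; 0 gives a
#'   fully deterministic trial.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(tdf_truth = cod_tdf_reference(),
                      diet_spec = cod_diet_spec(),
                      growth = cod_growth_reference(),
                      tank_sd = 0.05,
                      mass_cv = 0.06, census_cv = 0.03, length_cv = 0.03,
                      proximate_sd = 0.001,
                      fish_lipid_sd = 0.012, fish_protein_sd = 0.02,
                      moisture = c(0.80, 0.77),
                      lipid_wet = list(high_lipid = c(0.026, 0.055),
                                       low_lipid = c(0.026, 0.0175)),
                      protein_wet = c(0.124, 0.150),
                      diet_moisture = 0.75,
                      losses = loss_coefficients(),
                      appetite_ratio = 0.8,
                      isotope_mode = c("equilibrium", "trajectory"),
                      turnover_half_life = 14,
                      initial_d15n = 11.5, initial_d13c_lc = -18.5,
                      noise_scale = 1) {
  isotope_mode <- match.arg(isotope_mode)
  stopifnot(noise_scale >= 0, tank_sd >= 0, mass_cv >= 0, proximate_sd >= 0,
            turnover_half_life > 0, appetite_ratio > 0, appetite_ratio <= 1)
  sds <- c("d15n_sd", "d13c_sd", "d13c_lc_sd")
  stopifnot(all(unlist(tdf_truth[sds]) >= 0),
            all(unlist(diet_spec[sds]) >= 0))
  ns <- noise_scale
  structure(list(
    tdf_truth = tdf_truth, diet_spec = diet_spec, growth = growth,
    tank_sd = tank_sd * ns, mass_cv = mass_cv * ns,
    census_cv = census_cv * ns, length_cv = length_cv * ns,
    proximate_sd = proximate_sd * ns,
    fish_lipid_sd = fish_lipid_sd * ns, fish_protein_sd = fish_protein_sd * ns,
    noise_scale = ns,
    moisture = moisture, lipid_wet = lipid_wet, protein_wet = protein_wet,
    diet_moisture = diet_moisture, losses = losses,
    appetite_ratio = appetite_ratio, isotope_mode = isotope_mode,
    turnover_half_life = turnover_half_life,
    initial_d15n = initial_d15n, initial_d13c_lc = initial_d13c_lc
  ), class = "sim_truth")
}

#' Two-rate isotopic incorporation trajectory
#'
#' Exponential approach of a tissue's \eqn{\delta} value to its dietary
#' asymptote \eqn{\delta_{diet} + \Delta} under combined metabolic
#' turnover (`k`) and growth dilution (`m`):
#' \deqn{\delta(t) = (\delta_{diet} + \Delta) -
#'   \left[(\delta_{diet} + \Delta) - \delta_0\right] e^{-(k+m)t}.}
#'
#' @param delta0 tissue value at `t = 0`, per mil.
#' @param delta_diet diet value, per mil.
#' @param delta_true true trophic discrimination factor, per mil.
#' @param k metabolic turnover rate, per day (>= 0).
#' @param m growth rate (specific, per day; >= 0).
#' @param t time, days (>= 0); vectorized.
#' @return \eqn{\delta(t)}, per mil.
#' @export
#' @examples
#' # halfway to the asymptote after one half-life
#' simulate_isotope_trajectory(10, 8, 3, k = log(2) / 14, m = 0, t = 14)
simulate_isotope_trajectory <- function(delta0, delta_diet, delta_true,
                                        k, m, t) {
  stopifnot(k >= 0, m >= 0, all(t >= 0))
  asym <- delta_diet + delta_true
  asym - (asym - delta0) * exp(-(k + m) * t)
}

#' Elemental constants linking proximate composition to C:N
#'
#' Literature-typical mass fractions of carbon in protein (`cP`) and
#' lipid (`cL`) and of nitrogen in protein (`nP`), used to derive a bulk
#' mass C:N ratio from dry-basis proximate composition.
#'
#' @param cP,cL,nP mass fractions (defaults 0.53, 0.77, 0.17).
#' @return Named list of class `cn_constants`.
#' @export
cn_constants <- function(cP = 0.53, cL = 0.77, nP = 0.17) {
  stopifnot(cP > 0, cL > 0, nP > 0)
  structure(list(cP = cP, cL = cL, nP = nP), class = "cn_constants")
}

#' Bulk mass C:N ratio from dry-basis proximate composition
#'
#' `C:N = (cP * protein + cL * lipid) / (nP * protein)`.  Nitrogen is
#' assumed to reside in protein only; the ratio is scale invariant in
#' the two fractions.
#'
#' @param protein_frac,lipid_frac dry-mass protein and lipid fractions;
#'   vectorized.  `protein_frac` must be strictly positive.
#' @param constants a [cn_constants()] list.
#' @return Mass C:N ratio(s).
#' @export
#' @examples
#' cn_from_proximate(0.65, 0.24)
cn_from_proximate <- function(protein_frac, lipid_frac,
                              constants = cn_constants()) {
  if (any(!is.finite(protein_frac)) || any(protein_frac <= 0)) {
    stop("protein_frac must be > 0 (C:N undefined otherwise)", call. = FALSE)
  }
  stopifnot(all(lipid_frac >= 0))
  (constants$cP * protein_frac + constants$cL * lipid_frac) /
    (constants$nP * protein_frac)
}

# linear interpolation of a (day0, day56) pair at arbitrary days
.interp_day <- function(endpoints, day, last = 56) {
  endpoints[1] + (endpoints[2] - endpoints[1]) * day / last
}

#' Generate a complete synthetic feeding trial
#'
#' Simulates the full record set of a diet x temperature tank trial with
#' known ground truth: daily feeding records (offered/uneaten wet mass
#' per tank), per-fish censuses (length, wet mass), tank-mean proximate
#' composition, terminal per-fish isotope records, and the diet batch
#' table.  Every downstream stage of the package can be run on the
#' result, and because the truth is known, estimators can be checked for
#' exact recovery (at zero noise) or statistical recovery (via repeated
#' seeds).
#'
#' Key construction choices (full detail in the methods vignette):
#' * Growth is exponential per arm between the day-0 and day-56 mean
#'   weights; mortality removes fish uniformly at random before day 19
#'   until the configured terminal arm sizes are reached.
#' * Diet batches (days 0/27/50) draw isotope values around the diet
#'   means; tissue values are anchored to the *realized* batch grand
#'   mean, so a zero-noise trial is recovered exactly downstream.
#' * Each diet carries the C:N implied by its raw and lipid-corrected
#'   \eqn{\delta^{13}}C pair ([implied_cn()]); fish C:N derives from
#'   per-fish dry-basis composition via [cn_from_proximate()].
#' * Raw tissue \eqn{\delta^{13}}C is built by subtracting each fish's
#'   lipid-correction term from its simulated lipid-corrected value, so
#'   the correction stage inverts it exactly.
#' * Daily rations are proportional to live biomass and scaled so the
#'   assimilated dry mass per terminal fish matches the arm's reference
#'   value under the assumed loss coefficients.
#'
#' @param config a [trial_config()].
#' @param truth a [sim_truth()].
#' @return A list of class `cod_trial` with data frames `feeding`,
#'   `census`, `proximate`, `fish`, `diets`, plus the `config`, `truth`
#'   and a `bookkeeping` table of per-tank true quantities (growth and
#'   assimilation totals) for consistency checks.
#' @export
#' @examples
#' trial <- generate_trial(trial_config(seed = 42), sim_truth())
#' head(trial$fish)
generate_trial <- function(config = trial_config(), truth = sim_truth()) {
  stopifnot(inherits(config, "trial_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed)
  last_day <- max(config$feeding_days)
  lipid_const <- lipid_norm_constants()

  # --- diet batch table -----------------------------------------------------
  spec <- truth$diet_spec
  spec <- spec[spec$diet %in% config$diets, , drop = FALSE]
  if (!all(config$diets %in% spec$diet)) {
    stop("truth$diet_spec lacks a row for some configured diet", call. = FALSE)
  }
  batch_days <- c(0, 27, 50)
  diets <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    cn <- implied_cn(s$d13c_mean, s$d13c_lc_mean, lipid_const)
    d15n <- rnorm(length(batch_days), s$d15n_mean,
                  s$d15n_sd * truth$noise_scale)
    d13c <- rnorm(length(batch_days), s$d13c_mean,
                  s$d13c_sd * truth$noise_scale)
    data.frame(diet = s$diet, day = batch_days, d15n = d15n, d13c = d13c,
               cn_ratio = cn,
               d13c_lc = lipid_normalize_d13c(d13c, cn, lipid_const),
               energy_kj_g_wet = s$energy_kj_g_wet,
               protein_frac_wet = s$protein_frac_wet,
               lipid_frac_wet = s$lipid_frac_wet,
               moisture_frac = truth$diet_moisture,
               stringsAsFactors = FALSE)
  }))
  rownames(diets) <- NULL
  food_mean <- aggregate(diets[c("d15n", "d13c_lc")], diets["diet"], mean)

  # --- arms, tanks, fish ----------------------------------------------------
  arms <- merge(
    expand.grid(diet = config$diets, temperature = config$temperatures,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    config$terminal_n, by = c("diet", "temperature"))
  tdf_cols <- c("diet", "temperature", "d15n_mean", "d15n_sd",
                "d13c_lc_mean", "d13c_lc_sd")
  arms <- merge(arms, truth$tdf_truth[, tdf_cols],
                by = c("diet", "temperature"), all.x = TRUE)
  arms <- merge(arms, truth$growth$arms,
                by = c("diet", "temperature"), all.x = TRUE)
  # arms outside the reference design fall back to overall growth endpoints
  w_ref <- truth$growth$weight_g
  arms$initial_weight_g[is.na(arms$initial_weight_g)] <- w_ref[["day0"]]
  arms$final_weight_g[is.na(arms$final_weight_g)] <- w_ref[["day56"]]
  arms$dry_assimilated_g[is.na(arms$dry_assimilated_g)] <-
    mean(truth$growth$arms$dry_assimilated_g)
  if (any(is.na(arms$d15n_mean)) || any(is.na(arms$d13c_lc_mean))) {
    stop("truth$tdf_truth lacks a row for some configured arm", call. = FALSE)
  }
  arms <- arms[order(arms$diet, arms$temperature), ]
  arms$arm_id <- seq_len(nrow(arms))

  l_ref <- truth$growth$length_mm
  g_len <- log(l_ref[["day56"]] / l_ref[["day0"]]) / last_day

  feeding <- census <- proximate <- fish <- book <- list()
  dry_frac_diet <- 1 - truth$diet_moisture
  f <- truth$losses$egestion_frac
  u <- truth$losses$excretion_frac

  for (a in seq_len(nrow(arms))) {
    arm <- arms[a, ]
    g_mass <- log(arm$final_weight_g / arm$initial_weight_g) / last_day
    n_stocked <- config$tanks_per_arm * config$fish_per_tank
    # split terminal n across tanks as evenly as possible
    n_term <- diff(round(seq(0, arm$n, length.out = config$tanks_per_arm + 1)))
    # choose which fish die, uniformly at random, death day in [1, 18]
    for (tk in seq_len(config$tanks_per_arm)) {
      tank_id <- sprintf("%s_T%g_%d", arm$diet, arm$temperature, tk)
      nf <- config$fish_per_tank
      fish_ids <- sprintf("%s_f%02d", tank_id, seq_len(nf))
      dies <- rep(FALSE, nf)
      dies[sample.int(nf, nf - n_term[tk])] <- TRUE
      death_day <- ifelse(dies, sample(1:18, nf, replace = TRUE), Inf)
      size_f <- exp(rnorm(nf, 0, truth$mass_cv))      # persistent size factor
      lens_f <- exp(rnorm(nf, 0, truth$length_cv))

      # censuses
      for (d in config$census_days) {
        alive <- death_day > d
        mass <- arm$initial_weight_g * exp(g_mass * d) * size_f *
          exp(rnorm(nf, 0, truth$census_cv))
        len <- l_ref[["day0"]] * exp(g_len * d) * lens_f
        census[[length(census) + 1]] <- data.frame(
          tank = tank_id, day = d, fish_id = fish_ids[alive],
          length_mm = len[alive],
          wet_mass_g = mass[alive], stringsAsFactors = FALSE)
      }

      # tank-mean proximate composition (wet basis)
      lip_end <- truth$lipid_wet[[arm$diet]]
      for (d in config$proximate_days) {
        proximate[[length(proximate) + 1]] <- data.frame(
          tank = tank_id, day = d,
          moisture_frac = .interp_day(truth$moisture, d, last_day) +
            rnorm(1, 0, truth$proximate_sd),
          lipid_frac = .interp_day(lip_end, d, last_day) +
            rnorm(1, 0, truth$proximate_sd),
          protein_frac = .interp_day(truth$protein_wet, d, last_day) +
            rnorm(1, 0, truth$proximate_sd), stringsAsFactors = FALSE)
      }

      # daily feeding: consumption proportional to expected live biomass,
      # scaled so assimilated dry mass per terminal fish hits the arm truth
      alive_n <- vapply(config$feeding_days,
                        function(d) sum(death_day > d), numeric(1))
      biomass <- alive_n * arm$initial_weight_g * exp(g_mass * config$feeding_days)
      target_dry <- arm$dry_assimilated_g * n_term[tk]
      total_wet <- target_dry / (dry_frac_diet * (1 - f) * (1 - u))
      w <- biomass * exp(rnorm(length(biomass), 0, 0.1 * truth$noise_scale))
      consumed <- total_wet * w / sum(w)
      offered <- consumed / pmin(1, truth$appetite_ratio *
        exp(rnorm(length(consumed), 0, 0.05 * truth$noise_scale)))
      feeding[[length(feeding) + 1]] <- data.frame(
        tank = tank_id, day = config$feeding_days,
        offered_wet_g = offered, uneaten_wet_g = offered - consumed,
        stringsAsFactors = FALSE)

      # terminal per-fish records
      surv <- which(!dies)
      nS <- length(surv)
      moist56 <- .interp_day(truth$moisture, last_day, last_day)
      lip_dry <- pmax(0.01, .interp_day(lip_end, last_day, last_day) /
                        (1 - moist56) + rnorm(nS, 0, truth$fish_lipid_sd))
      prot_dry <- pmax(0.3, .interp_day(truth$protein_wet, last_day, last_day) /
                         (1 - moist56) + rnorm(nS, 0, truth$fish_protein_sd))
      cn <- cn_from_proximate(prot_dry, lip_dry)
      tank_eff_n <- rnorm(1, 0, truth$tank_sd)
      tank_eff_c <- rnorm(1, 0, truth$tank_sd)
      food <- food_mean[food_mean$diet == arm$diet, ]
      asym_n <- food$d15n + arm$d15n_mean
      asym_c <- food$d13c_lc + arm$d13c_lc_mean
      if (truth$isotope_mode == "trajectory") {
        km <- log(2) / truth$turnover_half_life
        k <- max(0, km - g_mass)
        mu_n <- simulate_isotope_trajectory(truth$initial_d15n, food$d15n,
                                            arm$d15n_mean, k, g_mass, last_day)
        mu_c <- simulate_isotope_trajectory(truth$initial_d13c_lc,
                                            food$d13c_lc, arm$d13c_lc_mean,
                                            k, g_mass, last_day)
      } else {
        mu_n <- asym_n
        mu_c <- asym_c
      }
      d15n <- mu_n + tank_eff_n +
        rnorm(nS, 0, arm$d15n_sd * truth$noise_scale)
      d13c_lc <- mu_c + tank_eff_c +
        rnorm(nS, 0, arm$d13c_lc_sd * truth$noise_scale)
      d13c <- d13c_lc - lipid_correction_term(cn, lipid_const)
      mass56 <- arm$initial_weight_g * exp(g_mass * last_day) * size_f[surv] *
        exp(rnorm(nS, 0, truth$census_cv))
      fish[[length(fish) + 1]] <- data.frame(
        fish_id = fish_ids[surv], tank = tank_id, diet = arm$diet,
        temperature = arm$temperature, d15n = d15n, d13c = d13c,
        cn_ratio = cn, lipid_frac = lip_dry, protein_frac = prot_dry,
        wet_mass_g = mass56, stringsAsFactors = FALSE)

      # true per-tank quantities for consistency checks
      book[[length(book) + 1]] <- data.frame(
        tank = tank_id, diet = arm$diet, temperature = arm$temperature,
        n_terminal = n_term[tk],
        mean_wet_0 = arm$initial_weight_g,
        mean_wet_56 = arm$final_weight_g,
        moisture_0 = truth$moisture[1], moisture_56 = truth$moisture[2],
        true_dry_change = arm$final_weight_g * (1 - truth$moisture[2]) -
          arm$initial_weight_g * (1 - truth$moisture[1]),
        consumed_wet_total = total_wet,
        dry_assimilated = target_dry, stringsAsFactors = FALSE)
    }
  }

  out <- list(feeding = do.call(rbind, feeding),
              census = do.call(rbind, census),
              proximate = do.call(rbind, proximate),
              fish = do.call(rbind, fish),
              diets = diets,
              config = config, truth = truth,
              bookkeeping = do.call(rbind, book))
  for (nm in c("feeding", "census", "proximate", "fish", "bookkeeping")) {
    rownames(out[[nm]]) <- NULL
  }
  class(out) <- "cod_trial"
  out
}

#' @export
print.cod_trial <- function(x, ...) {
  cat("Synthetic feeding trial (seed ", x$config$seed, ")\n", sep = "")
  cat("  arms   : ", length(x$config$diets), " diet(s) x ",
      length(x$config$temperatures), " temperature(s) x ",
      x$config$tanks_per_arm, " tank(s)\n", sep = "")
  cat("  fish   : ", nrow(x$fish), " terminal records\n", sep = "")
  cat("  days   : feeding ", min(x$config$feeding_days), "-",
      max(x$config$feeding_days), ", censuses ",
      paste(x$config$census_days, collapse = "/"), "\n", sep = "")
  invisible(x)
}
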