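#' Fecal and urinary loss coefficients
#'
#' Fractions of intake lost to egestion (fecal, `f`) and of absorbed
#' material lost to excretion (urinary, `u`) when converting consumed
#' food to assimilated mass.  The defaults (0.15 and 0.10) are
#' documented placeholders in the range typical for juvenile marine
#' fish on fish-based diets; they are deliberately prominent in the
#' configuration and echoed in every report header because assimilation
#' scales directly with them.
#'
#' @param egestion_frac fecal loss fraction `f`, in `[0, 1)`.
#' @param excretion_frac urinary loss fraction `u`, in `[0, 1)`.
#' @return A list of class `loss_coefficients`.
#' @export
loss_coefficients <- function(egestion_frac = 0.15, excretion_frac = 0.10) {
  stopifnot(egestion_frac >= 0, egestion_frac < 1,
            excretion_frac >= 0, excretion_frac < 1)
  structure(list(egestion_frac = egestion_frac,
                 excretion_frac = excretion_frac),
            class = "loss_coefficients")
}

#' Daily wet-mass trajectory from census points
#'
#' Fits a growth regression to tank-mean wet masses observed on census
#' days and predicts every day of the trial.  The default form is
#' log-linear (exponential growth, the standard juvenile-fish
#' assumption); a straight line on the original scale is available via
#' `form = "linear"`.
#'
#' @param days census days (>= 2 distinct values).
#' @param mass tank-mean wet masses, g (> 0 for the log-linear form).
#' @param form `"log-linear"` or `"linear"`.
#' @param days_out days at which to predict (default 0:56).
#' @return A data frame `day`, `mass_g`, with the fitted `lm` attached
#'   as attribute `model` and the daily growth rate (log-linear slope)
#'   as attribute `rate`.
#' @export
#' @examples
#' fit_mass_trajectory(c(0, 19, 31, 56), 2.6 * exp(0.019 * c(0, 19, 31, 56)))
fit_mass_trajectory <- function(days, mass, form = c("log-linear", "linear"),
                                days_out = 0:56) {
  form <- match.arg(form)
  stopifnot(length(days) == length(mass))
  if (length(unique(days)) < 2) {
    stop("at least two census days are required", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("masses must be positive and finite", call. = FALSE)
  }
  df <- data.frame(day = days, mass = mass)
  if (form == "log-linear") {
    m <- lm(log(mass) ~ day, data = df)
    pred <- exp(predict(m, data.frame(day = days_out)))
    rate <- unname(coef(m)["day"])
  } else {
    m <- lm(mass ~ day, data = df)
    pred <- predict(m, data.frame(day = days_out))
    rate <- unname(coef(m)["day"])
    if (any(pred <= 0)) {
      stop("linear mass trajectory predicts non-positive mass", call. = FALSE)
    }
  }
  structure(data.frame(day = days_out, mass_g = pred),
            model = m, rate = rate)
}

#' Daily body-composition trajectory from proximate sampling days
#'
#' Straight-line regression of a proximate fraction (moisture, lipid or
#' protein) on sampling day, predicted for every trial day including the
#' day-0 extrapolation.  Predictions outside `[0, 1]` are clamped and
#' the clamping is reported via `message()` and attribute `clamped`.
#'
#' @param days sampling days (>= 2 distinct values).
#' @param frac observed tank-mean fractions, in `[0, 1]`.
#' @param days_out days at which to predict (default 0:56).
#' @return A data frame `day`, `frac`, with attributes `model` and
#'   `clamped` (number of clamped predictions).
#' @export
fit_composition_trajectory <- function(days, frac, days_out = 0:56) {
  stopifnot(length(days) == length(frac))
  if (length(unique(days)) < 2) {
    stop("at least two sampling days are required", call. = FALSE)
  }
  stopifnot(all(is.finite(frac)), all(frac >= 0), all(frac <= 1))
  m <- lm(frac ~ day, data = data.frame(day = days, frac = frac))
  pred <- predict(m, data.frame(day = days_out))
  n_clamp <- sum(pred < 0 | pred > 1)
  if (n_clamp > 0) {
    message(n_clamp, " composition prediction(s) clamped to [0, 1]")
    pred <- pmin(1, pmax(0, pred))
  }
  structure(data.frame(day = days_out, frac = pred),
            model = m, clamped = n_clamp)
}

#' Dry mass assimilated from wet consumption
#'
#' `consumed_wet * food_dry_frac * (1 - f) * (1 - u)`: egestion applies
#' to intake, excretion to the absorbed remainder.
#'
#' @param consumed_wet wet mass of food consumed, g (>= 0); vectorized.
#' @param food_dry_frac dry-matter fraction of the food, in `(0, 1]`.
#' @param losses a [loss_coefficients()] list.
#' @return Dry mass assimilated, g.
#' @export
#' @examples
#' assimilated_dry_mass(10, 0.30, loss_coefficients(0.15, 0.10))  # 2.295
assimilated_dry_mass <- function(consumed_wet, food_dry_frac,
                                 losses = loss_coefficients()) {
  stopifnot(all(consumed_wet >= 0), food_dry_frac > 0, food_dry_frac <= 1)
  consumed_wet * food_dry_frac *
    (1 - losses$egestion_frac) * (1 - losses$excretion_frac)
}

#' Mass-specific energy assimilation rate
#'
#' `(dry_assimilated * energy_density) / biomass`, in kJ per g dry fish
#' per day when the inputs are a daily dry assimilation, the food energy
#' density (on the basis chosen in the configuration) and the tank's dry
#' biomass.
#'
#' @param dry_assimilated dry mass assimilated that day, g.
#' @param energy_density food energy density, kJ/g.
#' @param biomass tank dry biomass, g (> 0).
#' @return kJ per g dry biomass per day; vectorized.
#' @export
energy_assimilated_rate <- function(dry_assimilated, energy_density, biomass) {
  if (any(!is.finite(biomass)) || any(biomass <= 0)) {
    stop("biomass must be positive", call. = FALSE)
  }
  stopifnot(all(dry_assimilated >= 0), energy_density >= 0)
  dry_assimilated * energy_density / biomass
}

#' Percent change between two positive quantities
#'
#' `100 * (final - initial) / initial`.
#'
#' @param initial starting value (> 0).
#' @param final ending value.
#' @param digits rounding of the reported percentage (`NULL` for none).
#' @return Percent change.
#' @export
#' @examples
#' percent_change(2.6, 7.6)    # 192
#' percent_change(67.3, 93.8)  # 39
percent_change <- function(initial, final, digits = 0) {
  if (any(!is.finite(initial)) || any(initial <= 0)) {
    stop("initial value must be positive", call. = FALSE)
  }
  out <- 100 * (final - initial) / initial
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Consumption-to-retention mass budget of a feeding trial
#'
#' Implements the accounting chain for each tank: daily wet consumption
#' from the feeding records, conversion to assimilated dry mass
#' ([assimilated_dry_mass()]), macronutrient assimilation via the diet's
#' dry-basis composition, daily energy assimilation rates
#' ([energy_assimilated_rate()]), and day-0 to day-56 changes in body
#' dry mass, protein and lipid obtained from regression-interpolated
#' wet-mass ([fit_mass_trajectory()]) and composition
#' ([fit_composition_trajectory()]) trajectories.  Retention fractions
#' are retained mass / assimilated mass.
#'
#' Per-fish quantities divide tank totals by the number of fish present
#' at the terminal sampling.  Body-mass changes are computed on the
#' mean-fish basis (tank-mean masses), matching how such trials report
#' them.
#'
#' @param trial a `cod_trial` bundle (or any list with `feeding`,
#'   `census`, `proximate` and `fish` tables using the same schemas).
#' @param diets diet table with wet-basis composition columns
#'   `protein_frac_wet`, `lipid_frac_wet`, `energy_kj_g_wet` (one row or
#'   batch rows per diet, as produced by [generate_trial()] or
#'   [cod_diet_spec()]).
#' @param losses a [loss_coefficients()] list.
#' @param diet_moisture moisture fraction of the composed diets (the
#'   trial protocol reports composition wet-basis; dry-basis fractions
#'   are `wet / (1 - diet_moisture)`).
#' @param energy_basis `"dry"` (default) converts the wet-basis energy
#'   density to dry basis before computing rates; `"wet"` uses it as
#'   printed.
#' @param mass_form regression form for the wet-mass trajectory.
#' @return An object of class `mass_budget`: data frame `tanks` (one
#'   row per tank) plus `arms` (means over the replicate tanks), the
#'   per-day assimilation table `daily`, and the configuration used.
#' @export
compute_mass_budget <- function(trial, diets = NULL,
                                losses = loss_coefficients(),
                                diet_moisture = 0.75,
                                energy_basis = c("dry", "wet"),
                                mass_form = c("log-linear", "linear")) {
  energy_basis <- match.arg(energy_basis)
  mass_form <- match.arg(mass_form)
  stopifnot(is.list(trial),
            all(c("feeding", "census", "proximate", "fish") %in% names(trial)))
  if (is.null(diets)) diets <- trial$diets
  if ("moisture_frac" %in% names(diets)) {
    diet_moisture <- diets$moisture_frac[1]
  }
  comp <- aggregate(
    diets[c("protein_frac_wet", "lipid_frac_wet", "energy_kj_g_wet")],
    diets["diet"], mean)
  dry_frac <- 1 - diet_moisture
  comp$protein_dry <- comp$protein_frac_wet / dry_frac
  comp$lipid_dry <- comp$lipid_frac_wet / dry_frac
  comp$energy <- if (energy_basis == "dry") {
    comp$energy_kj_g_wet / dry_frac
  } else {
    comp$energy_kj_g_wet
  }

  feeding <- trial$feeding
  all_days <- sort(unique(feeding$day))
  first_day <- min(all_days); last_day <- max(all_days)
  tanks <- unique(trial$fish[c("tank", "diet", "temperature")])
  tank_rows <- list(); daily_rows <- list()
  for (i in seq_len(nrow(tanks))) {
    tk <- tanks$tank[i]
    fd <- feeding[feeding$tank == tk, ]
    fd <- fd[order(fd$day), ]
    gaps <- setdiff(seq(first_day, last_day), fd$day)
    if (length(gaps) > 0) {
      stop("tank ", tk, " is missing feeding records for day(s) ",
           paste(head(gaps, 10), collapse = ", "), call. = FALSE)
    }
    if (any(fd$uneaten_wet_g < 0) || any(fd$uneaten_wet_g > fd$offered_wet_g)) {
      stop("tank ", tk, ": uneaten mass outside [0, offered]", call. = FALSE)
    }
    consumed <- fd$offered_wet_g - fd$uneaten_wet_g

    cen <- trial$census[trial$census$tank == tk, ]
    mean_mass <- aggregate(list(mass = cen$wet_mass_g), cen["day"], mean)
    traj <- fit_mass_trajectory(mean_mass$day, mean_mass$mass,
                                form = mass_form,
                                days_out = seq(first_day, last_day))
    px <- trial$proximate[trial$proximate$tank == tk, ]
    moist <- fit_composition_trajectory(px$day, px$moisture_frac,
                                        days_out = seq(first_day, last_day))
    lip <- fit_composition_trajectory(px$day, px$lipid_frac,
                                      days_out = seq(first_day, last_day))
    prot <- fit_composition_trajectory(px$day, px$protein_frac,
                                       days_out = seq(first_day, last_day))

    n_fish <- sum(trial$fish$tank == tk)
    cm <- comp[comp$diet == tanks$diet[i], ]
    dry_assim_daily <- assimilated_dry_mass(consumed, dry_frac, losses)
    # tank dry biomass per day: mean fish dry mass x terminal count
    fish_dry <- traj$mass_g * (1 - moist$frac)
    energy_rate <- energy_assimilated_rate(dry_assim_daily, cm$energy,
                                           fish_dry[match(fd$day, traj$day)] *
                                             n_fish)
    body <- function(day) {
      j <- match(day, traj$day)
      c(dry = traj$mass_g[j] * (1 - moist$frac[j]),
        protein = traj$mass_g[j] * prot$frac[j],
        lipid = traj$mass_g[j] * lip$frac[j])
    }
    b0 <- body(first_day); b1 <- body(last_day)

    tot_dry <- sum(dry_assim_daily)
    row <- data.frame(
      tank = tk, diet = tanks$diet[i], temperature = tanks$temperature[i],
      n_fish = n_fish,
      consumed_wet_g = sum(consumed),
      dry_assimilated_g = tot_dry,
      protein_assimilated_g = tot_dry * cm$protein_dry,
      lipid_assimilated_g = tot_dry * cm$lipid_dry,
      energy_total_kj_gdry = sum(energy_rate),
      dry_assimilated_perfish_g = tot_dry / n_fish,
      protein_assimilated_perfish_g = tot_dry * cm$protein_dry / n_fish,
      lipid_assimilated_perfish_g = tot_dry * cm$lipid_dry / n_fish,
      initial_mass_g = traj$mass_g[traj$day == first_day],
      final_mass_g = traj$mass_g[traj$day == last_day],
      change_dry_g = unname(b1["dry"] - b0["dry"]),
      change_protein_g = unname(b1["protein"] - b0["protein"]),
      change_lipid_g = unname(b1["lipid"] - b0["lipid"]),
      stringsAsFactors = FALSE)
    row$protein_retention <- row$change_protein_g /
      row$protein_assimilated_perfish_g
    row$lipid_retention <- row$change_lipid_g / row$lipid_assimilated_perfish_g
    tank_rows[[i]] <- row
    daily_rows[[i]] <- data.frame(
      tank = tk, day = fd$day, consumed_wet_g = consumed,
      dry_assimilated_g = dry_assim_daily,
      energy_rate_kj_gdry_day = energy_rate, stringsAsFactors = FALSE)
  }
  tanks_df <- do.call(rbind, tank_rows)
  num <- names(tanks_df)[vapply(tanks_df, is.numeric, logical(1))]
  arms_df <- aggregate(tanks_df[setdiff(num, "temperature")],
                       tanks_df[c("diet", "temperature")], mean)
  structure(list(tanks = tanks_df, arms = arms_df,
                 daily = do.call(rbind, daily_rows),
                 losses = losses, diet_moisture = diet_moisture,
                 energy_basis = energy_basis, mass_form = mass_form),
            class = "mass_budget")
}

#' @export
print.mass_budget <- function(x, digits = 3, ...) {
  cat("Feeding-trial mass budget (", nrow(x$tanks), " tanks; f = ",
      x$losses$egestion_frac, ", u = ", x$losses$excretion_frac,
      ", diet moisture = ", x$diet_moisture, ")\n\n", sep = "")
  cols <- c("diet", "temperature", "dry_assimilated_perfish_g",
            "protein_assimilated_perfish_g", "change_protein_g",
            "protein_retention", "lipid_retention")
  df <- x$arms[cols]
  nm <- vapply(df, is.numeric, logical(1))
  df[nm] <- lapply(df[nm], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
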