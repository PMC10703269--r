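#' Trophic discrimination factor from tissue and food values
#'
#' \eqn{\Delta = \mathrm{mean}(\delta_{tissue} - \delta_{food})}: the
#' mean per-individual difference between tissue \eqn{\delta} values and
#' the (single) mean \eqn{\delta} value of the food, with the sample SD
#' of the per-individual differences (n - 1 denominator).
#'
#' @param tissue_deltas per-individual tissue \eqn{\delta} values, per
#'   mil; at least one, all finite.
#' @param food_mean mean \eqn{\delta} value of the food, per mil.
#' @return A list with elements `n`, `mean` and `sd` (SD is `NA` for a
#'   single individual).
#' @export
#' @examples
#' compute_tdf(c(12.2, 12.3, 12.4), 8.19)
compute_tdf <- function(tissue_deltas, food_mean) {
  tissue_deltas <- tissue_deltas[!is.na(tissue_deltas)]
  if (length(tissue_deltas) == 0) {
    stop("at least one tissue value is required", call. = FALSE)
  }
  stopifnot(is.finite(food_mean), all(is.finite(tissue_deltas)))
  d <- tissue_deltas - food_mean
  list(n = length(d), mean = mean(d),
       sd = if (length(d) > 1) sd(d) else NA_real_)
}

#' Summarize per-fish TDFs by treatment arm
#'
#' Produces the two summary styles used for crossed diet x temperature
#' designs, side by side:
#' * per-arm (diet x temperature) n / mean / SD plus per-tank means;
#' * a pooled per-diet row over all fish in the diet ("All"); and
#' * an equal-weight per-diet grand mean: the unweighted average of the
#'   temperature-arm means.  The two differ whenever arm sizes are
#'   unequal; both are reported because each answers a different
#'   question (average fish vs average treatment).
#'
#' @param deltas data frame of per-fish TDFs with columns `diet`,
#'   `temperature`, `tank`, `isotope`, `delta`.  Rows with missing
#'   `delta` are dropped with a message.
#' @return A list of class `tdf_summary` with data frames `arms`
#'   (per diet/temperature/isotope), `pooled` (per diet/isotope),
#'   `grand` (equal-weight per diet/isotope) and `tank_means`.
#' @export
summarize_treatments <- function(deltas) {
  need <- c("diet", "temperature", "tank", "isotope", "delta")
  stopifnot(is.data.frame(deltas), all(need %in% names(deltas)))
  drop <- !is.finite(deltas$delta)
  if (any(drop)) {
    message(sum(drop), " fish with missing values omitted from TDF summaries")
    deltas <- deltas[!drop, , drop = FALSE]
  }
  if (nrow(deltas) == 0) stop("no usable per-fish TDFs", call. = FALSE)

  agg <- function(by) {
    n <- aggregate(list(n = deltas$delta), by, length)
    m <- aggregate(list(mean = deltas$delta), by, mean)
    s <- aggregate(list(sd = deltas$delta), by, sd)
    merge(merge(n, m), s)
  }
  arms <- agg(deltas[c("isotope", "diet", "temperature")])
  arms <- arms[order(arms$isotope, arms$diet, arms$temperature), ]
  pooled <- agg(deltas[c("isotope", "diet")])
  tank_means <- aggregate(list(mean = deltas$delta),
                          deltas[c("isotope", "diet", "temperature", "tank")],
                          mean)
  grand <- merge(
    aggregate(list(mean = arms$mean), arms[c("isotope", "diet")], mean),
    aggregate(list(n_arms = arms$mean), arms[c("isotope", "diet")], length))
  rownames(arms) <- rownames(pooled) <- rownames(grand) <- NULL
  structure(list(arms = arms, pooled = pooled, grand = grand,
                 tank_means = tank_means),
            class = "tdf_summary")
}

# food means per diet from a batch table or a *_mean spec table
.food_means <- function(diets, constants) {
  stopifnot(is.data.frame(diets), "diet" %in% names(diets))
  if ("d15n" %in% names(diets)) {            # batch samples
    if (!"d13c_lc" %in% names(diets)) {
      diets <- apply_lipid_correction(diets, constants = constants)
    }
    out <- aggregate(diets[c("d15n", "d13c", "d13c_lc")], diets["diet"],
                     mean, na.rm = TRUE)
  } else {                                   # mean-style specification
    out <- data.frame(diet = diets$diet, d15n = diets$d15n_mean,
                      d13c = diets$d13c_mean, d13c_lc = diets$d13c_lc_mean,
                      stringsAsFactors = FALSE)
  }
  out
}

#' Fit trophic discrimination factors to a feeding trial
#'
#' The central estimator of the package.  For every fish, computes the
#' offset between its tissue \eqn{\delta} value and the mean
#' \eqn{\delta} value of its diet for three isotope systems --
#' \eqn{\Delta^{15}}N, \eqn{\Delta^{13}}C, and lipid-corrected
#' \eqn{\Delta^{13}}C (tissue and diet both normalized via
#' [lipid_normalize_d13c()]) -- and summarizes them per treatment arm
#' with pooled and equal-weight per-diet grand means
#' ([summarize_treatments()]).
#'
#' Fish whose C:N ratio falls at or below the validity threshold of the
#' lipid correction are excluded from the lipid-corrected isotope system
#' only (count reported and kept in the object).
#'
#' @param fish per-fish terminal table: columns `fish_id`, `tank`,
#'   `diet`, `temperature`, `d15n`, `d13c`, `cn_ratio` (and optionally a
#'   precomputed `d13c_lc`, which is then used as is).
#' @param diets diet table: either batch samples (columns `diet`,
#'   `d15n`, `d13c` and `cn_ratio` or `d13c_lc`) or a specification with
#'   `*_mean` columns as in [cod_diet_spec()].
#' @param constants [lipid_norm_constants()] for both tissue and diet.
#' @return An object of class `tdf_fit`: list with `deltas` (per-fish
#'   long table), `arms`, `pooled`, `grand`, `tank_means`, `food` (diet
#'   means used), `n_excluded_lc`, and the matched `call`.  Methods:
#'   [print()], [summary()], [coef()], [predict()], [residuals()],
#'   [plot()], [simulate()].
#' @seealso [fit_and_select()] for mixed-effects treatment comparison.
#' @export
#' @examples
#' trial <- generate_trial(trial_config(seed = 7), sim_truth())
#' fit <- fit_tdf(trial$fish, trial$diets)
#' fit
#' coef(fit)
fit_tdf <- function(fish, diets, constants = lipid_norm_constants()) {
  cl <- match.call()
  need <- c("tank", "diet", "temperature", "d15n", "d13c", "cn_ratio")
  stopifnot(is.data.frame(fish), all(need %in% names(fish)))
  if (!"fish_id" %in% names(fish)) fish$fish_id <- seq_len(nrow(fish))
  food <- .food_means(diets, constants)
  if (!all(unique(fish$diet) %in% food$diet)) {
    stop("diet table lacks a diet present in the fish table", call. = FALSE)
  }
  n_excl <- 0L
  if (!"d13c_lc" %in% names(fish)) {
    fish <- suppressMessages(apply_lipid_correction(fish, constants = constants))
    n_excl <- attr(fish, "n_excluded")
  }
  idx <- match(fish$diet, food$diet)
  base <- fish[c("fish_id", "tank", "diet", "temperature")]
  deltas <- rbind(
    cbind(base, isotope = "d15n", delta = fish$d15n - food$d15n[idx]),
    cbind(base, isotope = "d13c", delta = fish$d13c - food$d13c[idx]),
    cbind(base, isotope = "d13c_lc", delta = fish$d13c_lc - food$d13c_lc[idx])
  )
  rownames(deltas) <- NULL
  smry <- suppressMessages(summarize_treatments(deltas))
  structure(c(list(deltas = deltas), unclass(smry),
              list(food = food, n_excluded_lc = n_excl, call = cl)),
            class = "tdf_fit")
}

#' @export
print.tdf_fit <- function(x, digits = 2, ...) {
  cat("Trophic discrimination factors (per mil)\n")
  cat("Fish:", length(unique(x$deltas$fish_id)), " Diets:",
      paste(x$food$diet, collapse = ", "), "\n\n")
  g <- x$grand
  wide <- reshape(g[c("isotope", "diet", "mean")], idvar = "diet",
                  timevar = "isotope", direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  cat("Equal-weight grand means of the temperature-arm estimates:\n")
  print(format(wide, digits = digits), row.names = FALSE)
  if (x$n_excluded_lc > 0) {
    cat("\n(", x$n_excluded_lc,
        " fish excluded from the lipid-corrected system: invalid C:N)\n",
        sep = "")
  }
  invisible(x)
}

#' Treatment-table summary of a TDF fit
#'
#' Builds the publication-shaped wide table: one row per diet x
#' temperature arm and, per diet, a pooled `All` row (all fish) and an
#' `All (equal wt)` row (unweighted mean of the arm means), for each of
#' the three isotope systems.
#'
#' @param object a [fit_tdf()] result.
#' @param digits digits used by the print method.
#' @param ... unused.
#' @return A data frame of class `summary.tdf_fit` with columns `diet`,
#'   `temperature`, `n`, and `<isotope>_mean` / `<isotope>_sd` triples.
#' @export
summary.tdf_fit <- function(object, digits = 2, ...) {
  isos <- c("d15n", "d13c", "d13c_lc")
  widen <- function(df, label) {
    if (!"temperature" %in% names(df)) df$temperature <- NA
    if (!"n" %in% names(df)) df$n <- NA_integer_
    if (!"sd" %in% names(df)) df$sd <- NA_real_
    key <- unique(df[c("diet", "temperature")])
    kid <- paste(key$diet, key$temperature)
    out <- key
    out$n <- df$n[match(kid, paste(df$diet, df$temperature))]
    for (iso in isos) {
      part <- df[df$isotope == iso, , drop = FALSE]
      m <- match(kid, paste(part$diet, part$temperature))
      out[[paste0(iso, "_mean")]] <- part$mean[m]
      out[[paste0(iso, "_sd")]] <- part$sd[m]
    }
    out$temperature <- if (is.null(label)) {
      as.character(out$temperature)
    } else {
      label
    }
    out
  }
  grand <- object$grand
  names(grand)[names(grand) == "n_arms"] <- "n"
  out <- rbind(widen(object$arms, NULL),
               widen(object$pooled, "All"),
               widen(grand, "All (equal wt)"))
  out <- out[order(out$diet), ]
  rownames(out) <- NULL
  structure(out, class = c("summary.tdf_fit", "data.frame"), digits = digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.tdf_fit <- function(x, ...) {
  cat("Per-arm trophic discrimination factors (per mil)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, attr(x, "digits") %||% 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tdf_fit <- function(object, ...) {
  a <- object$arms
  out <- reshape(a[c("isotope", "diet", "temperature", "mean")],
                 idvar = c("diet", "temperature"), timevar = "isotope",
                 direction = "wide")
  names(out) <- sub("^mean\\.", "", names(out))
  rownames(out) <- NULL
  out
}

#' @export
predict.tdf_fit <- function(object, newdata = NULL,
                            isotope = c("d15n", "d13c", "d13c_lc"), ...) {
  isotope <- match.arg(isotope)
  a <- object$arms[object$arms$isotope == isotope, ]
  if (is.null(newdata)) newdata <- a[c("diet", "temperature")]
  idx <- match(interaction(newdata$diet, newdata$temperature),
               interaction(a$diet, a$temperature))
  a$mean[idx]
}

#' @export
residuals.tdf_fit <- function(object, isotope = c("d15n", "d13c", "d13c_lc"),
                              ...) {
  isotope <- match.arg(isotope)
  d <- object$deltas[object$deltas$isotope == isotope, ]
  d$delta - predict(object, d, isotope = isotope)
}

#' Draw new per-fish TDF tables from a fitted model
#'
#' Parametric simulation: per arm, draws `n` fish from a normal
#' distribution with the fitted arm mean and SD, preserving the design
#' (tanks split evenly).  Useful for parametric-bootstrap checks of
#' downstream statistics.
#'
#' @param object a [fit_tdf()] result.
#' @param nsim number of replicate tables.
#' @param seed optional seed.
#' @param isotope which isotope system to simulate.
#' @param ... unused.
#' @return A list of `nsim` data frames shaped like `object$deltas`
#'   (single isotope).
#' @export
simulate.tdf_fit <- function(object, nsim = 1, seed = NULL,
                             isotope = c("d15n", "d13c", "d13c_lc"), ...) {
  isotope <- match.arg(isotope)
  if (!is.null(seed)) set.seed(seed)
  a <- object$arms[object$arms$isotope == isotope, ]
  replicate(nsim, simplify = FALSE, {
    do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
      n <- a$n[i]
      data.frame(fish_id = seq_len(n),
                 tank = paste0(a$diet[i], "_T", a$temperature[i], "_",
                               rep_len(1:2, n)),
                 diet = a$diet[i], temperature = a$temperature[i],
                 isotope = isotope,
                 delta = rnorm(n, a$mean[i], a$sd[i]),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Plot per-arm TDF estimates
#'
#' Base-graphics panel per isotope system: arm means with +/- 1 SD bars
#' against temperature, one line per diet.
#'
#' @param x a [fit_tdf()] result.
#' @param isotopes subset of isotope systems to draw.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.tdf_fit <- function(x, isotopes = c("d15n", "d13c", "d13c_lc"), ...) {
  labs <- c(d15n = expression(Delta^15 * N ~ "(per mil)"),
            d13c = expression(Delta^13 * C ~ "(per mil)"),
            d13c_lc = expression(Delta ~ LC^13 * C ~ "(per mil)"))
  old <- par(mfrow = c(1, length(isotopes)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (iso in isotopes) {
    a <- x$arms[x$arms$isotope == iso, ]
    diets <- unique(a$diet)
    cols <- setNames(seq_along(diets) + 1, diets)
    ylim <- range(a$mean - a$sd, a$mean + a$sd)
    plot(NA, xlim = range(a$temperature) + c(-0.5, 0.5), ylim = ylim,
         xlab = "Temperature (deg C)", ylab = labs[[iso]], ...)
    for (d in diets) {
      ad <- a[a$diet == d, ]
      off <- 0.1 * (match(d, diets) - 1.5)
      points(ad$temperature + off, ad$mean, col = cols[d], pch = 19,
             type = "b")
      arrows(ad$temperature + off, ad$mean - ad$sd, ad$temperature + off,
             ad$mean + ad$sd, angle = 90, code = 3, length = 0.03,
             col = cols[d])
    }
    if (iso == isotopes[1]) {
      legend("topleft", legend = diets, col = cols, pch = 19, bty = "n")
    }
  }
  invisible(x)
}
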