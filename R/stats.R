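#' Mixed-effects treatment comparison with AIC model selection
#'
#' Fits the three candidate fixed-effect structures for per-fish TDFs --
#' `diet`, `diet + temperature`, `diet * temperature` -- each with a
#' tank-level random intercept, compares them by AIC, and refits the
#' winner for reporting.  Candidates are fitted by maximum likelihood
#' (AIC across different fixed-effect structures is only meaningful
#' under ML); the selected structure is refitted by REML for the
#' reported estimates, the standard convention for mixed models.
#' Temperature is treated as a categorical factor, matching the
#' arm-wise treatment structure of the design.
#'
#' @param object a [fit_tdf()] result, or a per-fish TDF data frame with
#'   columns `diet`, `temperature`, `tank`, `delta` (and optionally
#'   `isotope`).
#' @param isotope isotope system to analyse when `object` carries
#'   several.
#' @param alpha significance level carried through to
#'   [tukey_letters()].
#' @return An object of class `tdf_lmm`: list with `candidates` (data
#'   frame: `structure`, `npar`, `logLik`, `AIC`, `dAIC`), `selected`
#'   (structure string), `model` (the REML refit, a `lmerMod`),
#'   `ranef_sd` (tank random-intercept SD), `data`, `isotope`, `alpha`.
#' @export
#' @examples
#' trial <- generate_trial(trial_config(seed = 3), sim_truth())
#' fit <- fit_tdf(trial$fish, trial$diets)
#' fit_and_select(fit, "d15n")
fit_and_select <- function(object, isotope = c("d15n", "d13c", "d13c_lc"),
                           alpha = 0.05) {
  isotope <- match.arg(isotope)
  d <- if (inherits(object, "tdf_fit")) object$deltas else object
  stopifnot(is.data.frame(d),
            all(c("diet", "temperature", "tank", "delta") %in% names(d)))
  if ("isotope" %in% names(d) && length(unique(d$isotope)) > 1) {
    d <- d[d$isotope == isotope, , drop = FALSE]
  }
  d <- d[is.finite(d$delta), , drop = FALSE]
  if (any(is.na(d$tank))) stop("every fish must be assigned to a tank",
                               call. = FALSE)
  d$diet <- factor(d$diet)
  d$temperature <- factor(d$temperature)
  d$tank <- factor(d$tank)
  tanks_per_diet <- rowsum(rep(1, nrow(unique(d[c("diet", "tank")]))),
                           unique(d[c("diet", "tank")])$diet)
  if (any(tanks_per_diet < 2)) {
    stop("singular design: each diet needs at least two tanks", call. = FALSE)
  }

  structures <- c("diet", "diet + temperature", "diet * temperature")
  fits_ml <- lapply(structures, function(s) {
    suppressMessages(suppressWarnings(
      lme4::lmer(as.formula(paste("delta ~", s, "+ (1 | tank)")),
                 data = d, REML = FALSE)))
  })
  cand <- data.frame(
    structure = structures,
    npar = vapply(fits_ml, function(f) attr(logLik(f), "df"), numeric(1)),
    logLik = vapply(fits_ml, function(f) as.numeric(logLik(f)), numeric(1)),
    AIC = vapply(fits_ml, AIC, numeric(1)), stringsAsFactors = FALSE)
  cand$dAIC <- cand$AIC - min(cand$AIC)
  sel <- which.min(cand$AIC)
  model <- suppressMessages(suppressWarnings(
    lme4::lmer(as.formula(paste("delta ~", structures[sel], "+ (1 | tank)")),
               data = d, REML = TRUE)))
  # cell-mean model for arm-wise displays (see tukey_letters)
  model_cells <- if (sel == 3 || nlevels(d$temperature) < 2) {
    model
  } else {
    suppressMessages(suppressWarnings(
      lme4::lmer(delta ~ diet * temperature + (1 | tank), data = d,
                 REML = TRUE)))
  }
  vc <- as.data.frame(lme4::VarCorr(model))
  ranef_sd <- vc$sdcor[vc$grp == "tank"]
  structure(list(candidates = cand, selected = structures[sel],
                 model = model, model_cells = model_cells,
                 ranef_sd = ranef_sd, data = d,
                 isotope = isotope, alpha = alpha),
            class = "tdf_lmm")
}

#' @export
print.tdf_lmm <- function(x, digits = 3, ...) {
  cat("Mixed-effects TDF comparison (", x$isotope, ")\n", sep = "")
  cat("Random effect: (1 | tank), SD =", signif(x$ranef_sd, digits), "\n\n")
  cand <- x$candidates
  cand[c("logLik", "AIC", "dAIC")] <-
    lapply(cand[c("logLik", "AIC", "dAIC")], round, 2)
  print(cand, row.names = FALSE)
  cat("\nSelected (lowest AIC):", x$selected, "\n")
  invisible(x)
}

#' @export
summary.tdf_lmm <- function(object, ...) {
  list(candidates = object$candidates, selected = object$selected,
       fixed = lme4::fixef(object$model), ranef_sd = object$ranef_sd,
       letters = tukey_letters(object))
}

# Insert-and-absorb compact letter display.
# groups: character labels ordered for display; signif: logical matrix
# (TRUE where the pair differs significantly), dimnames = groups.
insert_absorb <- function(groups, signif) {
  cols <- list(setNames(rep(TRUE, length(groups)), groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !signif[groups[i], groups[j]]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[groups[i]] && col[groups[j]]) {
          c1 <- col; c1[groups[i]] <- FALSE
          c2 <- col; c2[groups[j]] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1]] <- c2
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[b] &&
              all(cols[[b]] | !cols[[a]]) && !identical(cols[[a]], cols[[b]])) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  ord <- order(vapply(cols, function(col) which(col)[1], numeric(1)))
  cols <- cols[ord]
  vapply(groups, function(g) {
    paste(letters[which(vapply(cols, function(col) col[g], logical(1)))],
          collapse = "")
  }, character(1))
}

#' Tukey-adjusted compact letter display for treatment arms
#'
#' All-pairs comparisons of treatment-arm cell means with family-wise
#' Tukey adjustment, converted to letters by the standard
#' insert-and-absorb procedure: arms sharing a letter are not
#' significantly different at `alpha`.  Cell means and contrasts come
#' from [emmeans::emmeans()] on a REML fit.
#'
#' By default the display is computed on the full diet x temperature
#' cell-mean structure (the interaction REML fit) even when AIC picked
#' a more parsimonious structure for inference: an arm-wise letter
#' display must be able to express different within-diet patterns per
#' diet, which an additive fit cannot.  `cells = "selected"` instead
#' uses the AIC-selected structure; arms then inherit letters from the
#' cells that model distinguishes.
#'
#' @param fit a [fit_and_select()] result.
#' @param alpha significance level (defaults to the one stored in
#'   `fit`).
#' @param scope `"all"` compares all diet x temperature arms in one
#'   family (default); `"within_diet"` runs a separate family per diet.
#' @param cells `"interaction"` (default) or `"selected"`; see Details.
#' @return Data frame: `diet`, `temperature`, `emmean`, `SE`,
#'   `letters`.
#' @export
tukey_letters <- function(fit, alpha = NULL, scope = c("all", "within_diet"),
                          cells = c("interaction", "selected")) {
  stopifnot(inherits(fit, "tdf_lmm"))
  scope <- match.arg(scope)
  cells <- match.arg(cells)
  alpha <- alpha %||% fit$alpha
  model <- if (cells == "interaction") {
    fit$model_cells %||% fit$model
  } else {
    fit$model
  }
  vars <- intersect(c("diet", "temperature"), all.vars(formula(model)))
  emm <- emmeans::emmeans(
    model, as.formula(paste("~", paste(vars, collapse = " * "))))
  cells <- as.data.frame(emm)
  key <- do.call(paste, c(cells[vars], sep = ":"))

  letter_block <- function(cell_idx, prs) {
    k <- length(cell_idx)
    sig <- matrix(FALSE, k, k, dimnames = list(key[cell_idx], key[cell_idx]))
    for (r in seq_len(nrow(prs))) {
      pair <- strsplit(prs$contrast[r], " - ", fixed = TRUE)[[1]]
      pair <- gsub("[()]", "", gsub(" ", ":", trimws(pair)))
      # emmeans prefixes numeric-looking levels with the factor name
      pair <- gsub("temperature", "", pair, fixed = TRUE)
      if (all(pair %in% rownames(sig))) {
        sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <-
          prs$p.value[r] < alpha
      }
    }
    ord <- cell_idx[order(cells$emmean[cell_idx])]
    setNames(insert_absorb(key[ord], sig)[key[cell_idx]], key[cell_idx])
  }

  if (scope == "within_diet" && all(c("diet", "temperature") %in% vars)) {
    prs_by <- as.data.frame(emmeans::contrast(emm, "pairwise", by = "diet",
                                              adjust = "tukey"))
    lets <- character(nrow(cells))
    for (dd in unique(cells$diet)) {
      idx <- which(cells$diet == dd)
      p <- prs_by[prs_by$diet == dd, , drop = FALSE]
      tkey <- as.character(cells$temperature[idx])
      sig <- matrix(FALSE, length(idx), length(idx),
                    dimnames = list(tkey, tkey))
      for (r in seq_len(nrow(p))) {
        pair <- trimws(strsplit(p$contrast[r], " - ", fixed = TRUE)[[1]])
        pair <- gsub("^temperature", "", pair)
        if (all(pair %in% tkey)) {
          sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <-
            p$p.value[r] < alpha
        }
      }
      l <- insert_absorb(tkey[order(cells$emmean[idx])], sig)
      lets[idx] <- l[tkey]
    }
  } else {
    prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
    lets <- letter_block(seq_len(nrow(cells)), prs)
  }

  out <- cells[vars]
  out$emmean <- cells$emmean
  out$SE <- cells$SE
  out$letters <- unname(lets)
  # expand to the full arm grid when the model dropped temperature
  if (!"temperature" %in% vars) {
    arms <- unique(fit$data[c("diet", "temperature")])
    arms <- arms[order(arms$diet, as.numeric(as.character(arms$temperature))), ]
    idx <- match(arms$diet, out$diet)
    out <- data.frame(diet = arms$diet, temperature = arms$temperature,
                      emmean = out$emmean[idx], SE = out$SE[idx],
                      letters = out$letters[idx], stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Maximum spread of arm means across temperatures
#'
#' For each diet (and isotope system, if present), the largest absolute
#' pairwise difference between temperature-arm means -- the quantity
#' used to judge whether temperature moves TDFs by an ecologically
#' meaningful amount.
#'
#' @param x a [fit_tdf()] result, or a data frame of arm means with
#'   columns `diet`, `temperature`, `mean` (and optionally `isotope`).
#' @return Data frame with columns (`isotope`,) `diet`, `spread`.
#' @export
#' @examples
#' temperature_spread(data.frame(diet = "high_lipid",
#'                               temperature = c(6, 8, 10, 12),
#'                               mean = c(3.35, 3.54, 3.42, 3.32)))
temperature_spread <- function(x) {
  a <- if (inherits(x, "tdf_fit")) x$arms else x
  stopifnot(is.data.frame(a),
            all(c("diet", "temperature", "mean") %in% names(a)))
  by <- a[intersect(c("isotope", "diet"), names(a))]
  counts <- aggregate(list(k = a$mean), by, length)
  if (any(counts$k < 2)) {
    stop("at least two temperature arms per diet are required",
         call. = FALSE)
  }
  out <- aggregate(list(spread = a$mean), by,
                   function(v) max(v) - min(v))
  out
}
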