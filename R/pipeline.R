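# CSV schemas shared by the generator, readers and reports
.schemas <- list(
  feeding = c("tank", "day", "offered_wet_g", "uneaten_wet_g"),
  census = c("tank", "day", "fish_id", "length_mm", "wet_mass_g"),
  proximate = c("tank", "day", "moisture_frac", "lipid_frac", "protein_frac"),
  fish = c("fish_id", "tank", "diet", "temperature", "d15n", "d13c",
           "cn_ratio", "lipid_frac", "protein_frac", "wet_mass_g"),
  diets = c("diet", "day", "d15n", "d13c", "cn_ratio", "energy_kj_g_wet",
            "protein_frac_wet", "lipid_frac_wet", "moisture_frac")
)

.check_schema <- function(df, what, file = what) {
  missing <- setdiff(.schemas[[what]], names(df))
  if (length(missing) > 0) {
    stop("file '", file, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- setdiff(.schemas[[what]], c("tank", "fish_id", "diet"))
  for (cl in num) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad) > 0) {
      stop("file '", file, "', column '", cl, "': non-numeric or missing ",
           "value at row ", bad[1], call. = FALSE)
    }
  }
  invisible(df)
}

#' Write a trial bundle to CSV files
#'
#' Writes the five tables of a trial bundle (`feeding.csv`,
#' `census.csv`, `proximate.csv`, `fish.csv`, `diets.csv`) at full
#' precision.
#'
#' @param trial a `cod_trial` bundle or compatible list of tables.
#' @param dir output directory (created if needed).
#' @return The vector of file paths, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(.schemas)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(trial[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a trial bundle from CSV files
#'
#' Reads and schema-checks the five trial CSVs written by
#' [write_trial()] (or assembled from bench records in the same
#' layout).  Any missing column or non-numeric value raises an error
#' naming the file, column and row.
#'
#' @param dir directory containing `feeding.csv`, `census.csv`,
#'   `proximate.csv`, `fish.csv`, `diets.csv`.
#' @return A list of class `cod_trial` (without generator truth).
#' @export
read_trial <- function(dir) {
  out <- list()
  for (nm in names(.schemas)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop("missing input file '", p, "'", call. = FALSE)
    out[[nm]] <- .check_schema(read.csv(p, stringsAsFactors = FALSE), nm, p)
  }
  class(out) <- "cod_trial"
  out
}

.config_hash <- function(config) {
  config$outdir <- NULL              # hash analysis settings, not destination
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.report_header <- function(config, seed, losses, constants) {
  c("# codtdf report",
    paste0("# seed: ", seed),
    paste0("# config_hash: ", .config_hash(config)),
    paste0("# losses: f=", losses$egestion_frac,
           " u=", losses$excretion_frac),
    paste0("# lipid_norm: D=", constants$D, " I=", constants$I,
           " a=", constants$a, " b=", constants$b,
           " scale=", constants$scale, " saturation=", constants$saturation))
}

.write_report <- function(df, path, header, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE)
  path
}

#' Run the full feeding-trial analysis pipeline
#'
#' Orchestrates simulate (or load) -> lipid-correct -> TDF estimation ->
#' mass budget -> mixed-model statistics from a single configuration,
#' and optionally writes a publication-shaped report bundle.  The run is
#' deterministic given the seed; every report file starts with comment
#' lines recording the seed, a configuration hash, the loss coefficients
#' and the lipid-normalization constants.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized entries:
#'   \describe{
#'     \item{generator}{list of overrides for [trial_config()] (and
#'       optionally a `truth` sublist of [sim_truth()] overrides);
#'       `seed` is mandatory.  Mutually exclusive with `inputs`.}
#'     \item{inputs}{list with `dir`: directory of trial CSVs
#'       ([read_trial()]).  Mutually exclusive with `generator`.}
#'     \item{constants}{overrides for [lipid_norm_constants()].}
#'     \item{losses}{overrides for [loss_coefficients()].}
#'     \item{diet_moisture, energy_basis, mass_form}{budget settings,
#'       see [compute_mass_budget()].}
#'     \item{alpha}{significance level for letters (default 0.05).}
#'     \item{scope}{`"all"` or `"within_diet"`, see [tukey_letters()].}
#'     \item{outdir}{report directory; omit to skip writing files.}
#'   }
#' @return A list of class `codtdf_run`: `trial`, `tdf` (a
#'   [fit_tdf()] object), `tdf_table` (the wide per-arm report),
#'   `budget`, `stats` (per-isotope [fit_and_select()] results),
#'   `letters`, `spread`, `files` (paths written) and `log` (character
#'   vector of run events).
#' @export
#' @examples
#' run <- run_pipeline(list(generator = list(seed = 11)))
#' run$tdf
run_pipeline <- function(config = list(generator = list(seed = 1))) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_gen <- !is.null(config$generator)
  has_in <- !is.null(config$inputs)
  if (has_gen == has_in) {
    stop("config must contain exactly one of 'generator' or 'inputs'",
         call. = FALSE)
  }
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  constants <- do.call(lipid_norm_constants,
                       config$constants %||% list())
  losses <- do.call(loss_coefficients, config$losses %||% list())
  alpha <- config$alpha %||% 0.05
  scope <- config$scope %||% "all"

  if (has_gen) {
    gen <- config$generator
    if (is.null(gen$seed)) stop("generator config requires a seed",
                                call. = FALSE)
    truth <- do.call(sim_truth, gen$truth %||% list())
    gen$truth <- NULL
    cfg <- do.call(trial_config, gen)
    trial <- generate_trial(cfg, truth)
    seed <- cfg$seed
    note("generated synthetic trial, seed ", seed)
  } else {
    trial <- read_trial(config$inputs$dir)
    seed <- NA
    note("loaded trial from ", config$inputs$dir)
  }
  n_in <- nrow(trial$fish)

  # lipid correction (guard against double application by column name)
  if (!"d13c_lc" %in% names(trial$fish)) {
    trial$fish <- withCallingHandlers(
      apply_lipid_correction(trial$fish, constants = constants),
      message = function(m) {
        note(trimws(conditionMessage(m))); invokeRestart("muffleMessage")
      })
  } else {
    note("fish table already carries d13c_lc; correction not reapplied")
  }
  n_excl <- attr(trial$fish, "n_excluded") %||% 0L
  note("fish rows in: ", n_in, "; excluded from LC: ", n_excl)

  tdf <- fit_tdf(trial$fish, trial$diets, constants = constants)
  tdf_table <- summary(tdf)

  budget <- withCallingHandlers(
    compute_mass_budget(trial, losses = losses,
                        diet_moisture = config$diet_moisture %||% 0.75,
                        energy_basis = config$energy_basis %||% "dry",
                        mass_form = config$mass_form %||% "log-linear"),
    message = function(m) {
      note(trimws(conditionMessage(m))); invokeRestart("muffleMessage")
    })

  isos <- c("d15n", "d13c", "d13c_lc")
  stats <- lapply(setNames(isos, isos), function(iso) {
    fit_and_select(tdf, iso, alpha = alpha)
  })
  letters_df <- do.call(rbind, lapply(isos, function(iso) {
    cbind(isotope = iso,
          tukey_letters(stats[[iso]], scope = scope),
          selected = stats[[iso]]$selected)
  }))
  spread <- temperature_spread(tdf)
  note("selected models: ",
       paste(vapply(stats, `[[`, "", "selected"), collapse = " | "))

  files <- character(0)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- .report_header(config, seed, losses, constants)
    out <- function(df, nm, digits = NULL) {
      files <<- c(files, .write_report(
        df, file.path(config$outdir, nm), hdr, digits))
    }
    out(tdf_table, "tdf_table.csv", digits = 2)
    out(budget$tanks, "budget_tanks.csv")
    out(budget$arms, "budget_arms.csv")
    out(budget$daily, "daily_assimilation.csv")
    out(do.call(rbind, lapply(isos, function(iso) {
      cbind(isotope = iso, stats[[iso]]$candidates)
    })), "model_comparison.csv")
    out(letters_df, "letters.csv")
    out(spread, "temperature_spread.csv")
    writeLines(c(hdr, log), file.path(config$outdir, "run_log.txt"))
    files <- c(files, file.path(config$outdir, "run_log.txt"))
    note("wrote ", length(files), " files to ", config$outdir)
  }

  structure(list(trial = trial, tdf = tdf, tdf_table = tdf_table,
                 budget = budget, stats = stats, letters = letters_df,
                 spread = spread, files = files, log = log),
            class = "codtdf_run")
}

#' @export
print.codtdf_run <- function(x, ...) {
  cat("codtdf pipeline run\n\n")
  print(x$tdf)
  cat("\nSelected mixed models:\n")
  for (iso in names(x$stats)) {
    cat("  ", format(iso, width = 8), x$stats[[iso]]$selected, "\n")
  }
  invisible(x)
}
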