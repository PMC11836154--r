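#' Default simulator configuration
#'
#' Nested list with blocks `cohort`, `falls`, `impact`, `strength`, `trial`,
#' `convergence`; every value is overridable from a YAML or JSON file via
#' [load_config()].
#'
#' @return A named list of class `hf_config`.
#' @export
default_config <- function() {
  structure(list(
    cohort = list(
      n_patients = 1238L, abmd_mean = 0.722, abmd_sd = 0.096,
      height_mean = 1.60, height_sd = 0.06,
      weight_mean = 66, weight_sd = 11,
      rho_abmd = 0.4, rho_hw = 0.5,
      stt_a = -10, stt_b = 1.2, seed = 1L
    ),
    falls = list(lam = 0.65),
    impact = list(
      g = 9.81, hip_height_fraction = 0.51, effective_mass_fraction = 0.35,
      contact_stiffness = 50000, attenuation_per_mm = 0.02,
      attenuation_floor = 0.3, flooring_factor = 1.0, velocity_noise_cv = 0.1
    ),
    strength = list(c0 = 6.5, c1 = 3.4, residual_cv = 0.2,
                    modulation_amplitude = 0.2),
    trial = list(years = 3L, n_realizations = 10L, master_seed = 1L),
    convergence = list(threshold = 0.01, bootstrap_b = 10000L)
  ), class = "hf_config")
}

#' Load and validate a simulator configuration
#'
#' Reads a YAML (or, by extension, JSON) configuration file, fills every
#' missing key from [default_config()], and rejects unknown blocks or keys
#' by name. An empty file yields all documented defaults (fall rate 0.65
#' falls/year, 3 years of follow-up, 10 realizations, 1% convergence
#' threshold).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `hf_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  user <- user %||% list()
  defaults <- default_config()
  bad_blocks <- setdiff(names(user), names(defaults))
  if (length(bad_blocks)) {
    stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "))
  }
  cfg <- defaults
  for (blk in names(user)) {
    bad_keys <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
    if (length(bad_keys)) {
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(bad_keys, collapse = ", ")))
    }
    cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$falls$lam >= 0, "falls.lam must be >= 0")
  chk(cfg$cohort$n_patients >= 1, "cohort.n_patients must be >= 1")
  chk(cfg$cohort$abmd_mean > 0 && cfg$cohort$abmd_sd > 0,
      "cohort aBMD target must be positive")
  chk(cfg$trial$years >= 1, "trial.years must be >= 1")
  chk(cfg$trial$n_realizations >= 1, "trial.n_realizations must be >= 1")
  chk(cfg$convergence$threshold > 0 && cfg$convergence$threshold < 1,
      "convergence.threshold must be in (0, 1)")
  chk(cfg$impact$flooring_factor > 0 && cfg$impact$flooring_factor <= 1,
      "impact.flooring_factor must be in (0, 1]")
  chk(all(unlist(cfg$impact[c("g", "hip_height_fraction",
                              "effective_mass_fraction",
                              "contact_stiffness")]) > 0),
      "impact parameters must be strictly positive")
  chk(cfg$strength$residual_cv >= 0, "strength.residual_cv must be >= 0")
  if (length(errs)) stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  structure(cfg, class = "hf_config")
}

#' Save a configuration to YAML
#'
#' @param config An `hf_config` list.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Assemble the typed parameter objects from a configuration
#'
#' @param config An `hf_config` list.
#' @return A list with `target` ([cohort_target()]), `anthro`
#'   ([anthro_params()]), `surrogate` ([surrogate_params()]), and `trial`
#'   ([trial_config()]).
#' @export
config_objects <- function(config) {
  im <- config$impact
  st <- config$strength
  co <- config$cohort
  list(
    target = cohort_target(co$n_patients, co$abmd_mean, co$abmd_sd),
    anthro = anthro_params(co$height_mean, co$height_sd, co$weight_mean,
                           co$weight_sd, co$rho_abmd, co$rho_hw),
    surrogate = surrogate_params(st$c0, st$c1, st$residual_cv,
                                 st$modulation_amplitude),
    trial = trial_config(
      lam = config$falls$lam, years = config$trial$years,
      n_realizations = config$trial$n_realizations,
      convergence_threshold = config$convergence$threshold,
      master_seed = config$trial$master_seed,
      impact = impact_params(im$g, im$hip_height_fraction,
                             im$effective_mass_fraction, im$contact_stiffness,
                             im$attenuation_per_mm, im$attenuation_floor,
                             im$flooring_factor, im$velocity_noise_cv),
      bootstrap_b = config$convergence$bootstrap_b
    )
  )
}

#' Write trial results to a directory
#'
#' Writes `summary.json` (the [glance()] row plus configuration),
#' `realizations.csv`, `fractures.csv`, `per_year.csv`, `convergence.csv`
#' and `manifest.json` (seeds, file inventory, package version, timestamp).
#'
#' @param trial An `hf_trial` from [run_trial()].
#' @param outdir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(trial, outdir) {
  stopifnot(inherits(trial, "hf_trial"))
  if (nrow(trial$realizations) < 1) stop("empty trial result")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c("summary.json", "realizations.csv", "fractures.csv",
             "per_year.csv", "convergence.csv", "manifest.json")
  readr::write_csv(trial$realizations, file.path(outdir, "realizations.csv"))
  readr::write_csv(trial$fractures, file.path(outdir, "fractures.csv"))
  readr::write_csv(trial$per_year, file.path(outdir, "per_year.csv"))
  if (!is.null(trial$convergence)) {
    conv <- tibble::as_tibble(trial$convergence)
    readr::write_csv(conv, file.path(outdir, "convergence.csv"))
  } else {
    files <- setdiff(files, "convergence.csv")
  }
  g <- glance(trial)
  jsonlite::write_json(
    c(as.list(g), list(n_patients = trial$n_patients,
                       years = trial$config$years,
                       lam = trial$config$lam)),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  manifest <- list(
    package = "hipfracsim",
    version = as.character(utils::packageVersion("hipfracsim")),
    master_seed = trial$config$master_seed,
    cohort_seed = trial$cohort_seed,
    n_realizations = trial$config$n_realizations,
    convergence_threshold = trial$config$convergence_threshold,
    converged_at = if (is.null(trial$convergence)) NA else
      attr(trial$convergence, "converged_at"),
    files = files,
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(outdir, files))
}

#' Read back trial result tables written by [write_results()]
#'
#' @param outdir Directory written by [write_results()].
#' @return A list with tibbles `realizations`, `fractures`, `per_year`,
#'   optionally `convergence`, plus `summary` and `manifest` lists.
#' @export
read_results <- function(outdir) {
  out <- list(
    realizations = readr::read_csv(file.path(outdir, "realizations.csv"),
                                   show_col_types = FALSE),
    fractures = readr::read_csv(file.path(outdir, "fractures.csv"),
                                show_col_types = FALSE),
    per_year = readr::read_csv(file.path(outdir, "per_year.csv"),
                               show_col_types = FALSE),
    summary = jsonlite::read_json(file.path(outdir, "summary.json"),
                                  simplifyVector = TRUE),
    manifest = jsonlite::read_json(file.path(outdir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
  conv_path <- file.path(outdir, "convergence.csv")
  if (file.exists(conv_path)) {
    out$convergence <- readr::read_csv(conv_path, show_col_types = FALSE)
  }
  out
}
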