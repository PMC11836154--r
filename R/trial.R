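#' Trial follow-up configuration
#'
#' @param lam Mean fall rate (falls/year), default 0.65.
#' @param years Follow-up duration in 1-year steps, default 3.
#' @param n_realizations Number of realizations of the stochastic follow-up
#'   process, default 10.
#' @param convergence_threshold Relative-difference threshold for the
#'   bootstrap convergence check, default 0.01.
#' @param master_seed Master seed from which all realization- and
#'   patient-level substreams are derived.
#' @param impact An [impact_params()] object.
#' @param bootstrap_b Bootstrap resamples used by the convergence check.
#' @return A list of class `hf_trial_config`.
#' @export
trial_config <- function(lam = 0.65, years = 3, n_realizations = 10,
                         convergence_threshold = 0.01, master_seed = 1,
                         impact = impact_params(), bootstrap_b = 10000) {
  stopifnot(lam >= 0, years >= 1, years == round(years),
            n_realizations >= 1, n_realizations == round(n_realizations),
            convergence_threshold > 0, convergence_threshold < 1,
            inherits(impact, "hf_impact_params"), bootstrap_b >= 1)
  structure(list(lam = lam, years = as.integer(years), timestep = 1L,
                 n_realizations = as.integer(n_realizations),
                 convergence_threshold = convergence_threshold,
                 master_seed = as.integer(master_seed), impact = impact,
                 bootstrap_b = as.integer(bootstrap_b)),
            class = "hf_trial_config")
}

# Lean base-R core of one realization. Patients start active; for each year
# and each active patient, falls are processed in draw order; the patient
# fractures on the first fall whose attenuated impact force strictly exceeds
# the direction-specific failure load, their remaining falls are discarded,
# and they are excluded from later years (absorbing state). Every processed
# fall costs exactly one strength evaluation.
#
# All of a patient's event draws for the whole follow-up come from one
# substream derived from (master_seed, realization, patient index), and are
# drawn regardless of fracture, so event streams are common random numbers
# across strength scalings and across cohorts sharing the master seed.
realization_core <- function(cohort, config, realization,
                             surfaces = NULL) {
  ip <- config$impact
  n <- nrow(cohort)
  years <- config$years
  v0 <- sqrt(2 * ip$g * ip$hip_height_fraction * cohort$height)
  fmul <- sqrt(ip$contact_stiffness * ip$effective_mass_fraction * cohort$weight)
  att <- ip$flooring_factor *
    pmax(1 - ip$attenuation_per_mm * cohort$soft_tissue_thickness,
         ip$attenuation_floor)
  cv <- ip$velocity_noise_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  mod <- attr(cohort, "modulation")
  s0 <- cohort$strength_s0

  frac_patient <- integer(0); frac_year <- integer(0)
  frac_alpha <- integer(0); frac_beta <- integer(0)
  frac_force <- numeric(0); frac_fl <- numeric(0)
  n_eval <- 0L

  for (j in seq_len(n)) {
    set.seed(derive_seed(config$master_seed, realization, j))
    counts <- stats::rpois(years, config$lam)
    total <- sum(counts)
    if (total == 0L) next
    alpha <- sample(-30:30, total, replace = TRUE)
    beta <- sample(0:30, total, replace = TRUE)
    noise <- if (sdlog > 0) {
      stats::rlnorm(total, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, total)
    }
    force <- v0[j] * noise * fmul[j] * att[j]
    fl <- if (is.null(surfaces)) {
      s0[j] * mod[cbind(alpha + 31L, beta + 1L)]
    } else {
      surfaces[[j]][cbind(alpha + 31L, beta + 1L)]
    }
    hit <- which(force > fl)
    if (length(hit) > 0L) {
      k <- hit[1L]
      n_eval <- n_eval + k
      yr <- rep.int(seq_len(years), counts)[k]
      frac_patient <- c(frac_patient, j)
      frac_year <- c(frac_year, yr)
      frac_alpha <- c(frac_alpha, alpha[k])
      frac_beta <- c(frac_beta, beta[k])
      frac_force <- c(frac_force, force[k])
      frac_fl <- c(frac_fl, fl[k])
    } else {
      n_eval <- n_eval + total
    }
  }
  list(patient = frac_patient, year = frac_year, alpha = frac_alpha,
       beta = frac_beta, force = frac_force, failure_load = frac_fl,
       n_evaluations = n_eval)
}

#' Simulate one realization of the trial follow-up
#'
#' Runs the absorbing-chain follow-up once: yearly Poisson fall counts per
#' patient, a sampled impact direction and attenuated impact force per fall,
#' one strength evaluation per processed fall, and fracture on the first
#' fall whose force strictly exceeds the direction-specific failure load
#' (force exactly equal to the failure load is not a fracture). Fractured
#' patients are excluded from all subsequent falls and years.
#'
#' @param cohort An `hf_cohort` from [build_cohort()], optionally carrying a
#'   list-column `strength_surface` of explicit `hf_strength_surface`
#'   objects used instead of the surrogate scale.
#' @param config An [trial_config()] object.
#' @param realization Realization index (selects the substream family).
#' @return A list with `fractures` (tibble: `patient_id`, `year`, `alpha`,
#'   `beta`, `force`, `failure_load`) and `n_evaluations` (count of strength
#'   lookups performed).
#' @export
#' @examples
#' x <- generate_atlas_training(fixture_spec(), seed = 1)
#' cohort <- build_cohort(fit_atlas(x), cohort_target(100, 0.72, 0.09), seed = 2)
#' r <- simulate_realization(cohort, trial_config(master_seed = 3))
#' r$n_evaluations
simulate_realization <- function(cohort, config = trial_config(),
                                 realization = 1) {
  stopifnot(inherits(cohort, "hf_cohort"), inherits(config, "hf_trial_config"))
  surfaces <- if ("strength_surface" %in% names(cohort)) {
    lapply(cohort$strength_surface, unclass)
  } else {
    NULL
  }
  core <- with_seed(1, realization_core(cohort, config, realization, surfaces))
  list(
    fractures = tibble::tibble(
      patient_id = cohort$id[core$patient],
      year = core$year,
      alpha = core$alpha,
      beta = core$beta,
      force = core$force,
      failure_load = core$failure_load
    ),
    n_evaluations = core$n_evaluations
  )
}

#' Run the full trial: all realizations plus convergence diagnostics
#'
#' Each realization restarts the same cohort fully active and uses
#' independent substreams derived from the master seed, so re-running with
#' the same master seed reproduces the result exactly.
#'
#' @param cohort An `hf_cohort`.
#' @param config An [trial_config()].
#' @return An object of class `hf_trial`: a list with `realizations`
#'   (tibble: `realization`, `n_fractures`, `n_evaluations`), `fractures`
#'   (per-fracture records across realizations), `per_year` (tibble:
#'   `realization`, `year`, `n_fractures`), `convergence`
#'   (an `hf_convergence` trace), `config` and `n_patients`.
#' @export
#' @examples
#' x <- generate_atlas_training(fixture_spec(), seed = 1)
#' cohort <- build_cohort(fit_atlas(x), cohort_target(100, 0.72, 0.09), seed = 2)
#' trial <- run_trial(cohort, trial_config(n_realizations = 3, master_seed = 3))
#' glance(trial)
run_trial <- function(cohort, config = trial_config()) {
  stopifnot(inherits(cohort, "hf_cohort"), inherits(config, "hf_trial_config"))
  surfaces <- if ("strength_surface" %in% names(cohort)) {
    lapply(cohort$strength_surface, unclass)
  } else {
    NULL
  }
  reals <- with_seed(1, lapply(seq_len(config$n_realizations), function(r) {
    realization_core(cohort, config, r, surfaces)
  }))
  counts <- vapply(reals, function(x) length(x$patient), integer(1))
  evals <- vapply(reals, function(x) x$n_evaluations, integer(1))
  fractures <- purrr::map_dfr(seq_along(reals), function(r) {
    x <- reals[[r]]
    tibble::tibble(
      realization = r,
      patient_id = cohort$id[x$patient],
      year = x$year, alpha = x$alpha, beta = x$beta,
      force = x$force, failure_load = x$failure_load
    )
  })
  per_year <- tidyr::expand_grid(realization = seq_len(config$n_realizations),
                                 year = seq_len(config$years)) |>
    dplyr::left_join(
      dplyr::count(fractures, .data$realization, .data$year, name = "n_fractures"),
      by = c("realization", "year")
    ) |>
    dplyr::mutate(n_fractures = tidyr::replace_na(.data$n_fractures, 0L))
  convergence <- if (config$n_realizations >= 2) {
    convergence_check(counts, threshold = config$convergence_threshold,
                      b = config$bootstrap_b,
                      seed = derive_seed(config$master_seed, 999331))
  } else {
    NULL
  }
  structure(
    list(
      realizations = tibble::tibble(realization = seq_len(config$n_realizations),
                                    n_fractures = counts,
                                    n_evaluations = evals),
      fractures = fractures,
      per_year = per_year,
      convergence = convergence,
      config = config,
      n_patients = nrow(cohort),
      cohort_seed = attr(cohort, "seed")
    ),
    class = "hf_trial"
  )
}

#' @export
print.hf_trial <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<hf_trial> %d patients, %d years, %d realizations\n",
              x$n_patients, x$config$years, x$config$n_realizations))
  cat(sprintf("  fractures: %.1f +/- %.1f (min %d, max %d); incidence %.2f%%\n",
              g$mean_fractures, g$sd_fractures, g$min_fractures,
              g$max_fractures, 100 * g$incidence))
  cat(sprintf("  strength evaluations per realization: %.0f (mean)\n",
              g$mean_evaluations))
  if (!is.null(x$convergence)) {
    ca <- attr(x$convergence, "converged_at")
    cat(sprintf("  convergence: %s\n",
                if (is.na(ca)) "not reached" else sprintf("at realization %d", ca)))
  }
  invisible(x)
}
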