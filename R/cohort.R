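#' Target total-hip aBMD distribution for a virtual cohort
#'
#' @param n_patients Cohort size (>= 1).
#' @param abmd_mean Target mean total-hip aBMD (g/cm^2).
#' @param abmd_sd Target SD (g/cm^2), strictly positive.
#' @return An object of class `hf_cohort_target`.
#' @export
#' @examples
#' cohort_target(1238, 0.722, 0.096)
cohort_target <- function(n_patients, abmd_mean, abmd_sd) {
  stopifnot(n_patients >= 1, n_patients == round(n_patients),
            abmd_mean > 0, abmd_sd > 0)
  structure(list(n_patients = as.integer(n_patients),
                 abmd_mean = abmd_mean, abmd_sd = abmd_sd),
            class = "hf_cohort_target")
}

#' Anthropometry model parameters
#'
#' Marginals default to postmenopausal-women reference values; the Gaussian
#' copula links height and weight to femoral-neck aBMD with a Pearson
#' correlation of 0.4 each, and to each other with 0.5.
#'
#' @param height_mean,height_sd Height marginal (m).
#' @param weight_mean,weight_sd Weight marginal (kg).
#' @param rho_abmd Copula correlation of height and of weight with neck aBMD.
#' @param rho_hw Mutual height-weight copula correlation.
#' @return A list of class `hf_anthro_params`.
#' @export
anthro_params <- function(height_mean = 1.60, height_sd = 0.06,
                          weight_mean = 66, weight_sd = 11,
                          rho_abmd = 0.4, rho_hw = 0.5) {
  stopifnot(height_mean > 0, height_sd > 0, weight_mean > 0, weight_sd > 0,
            abs(rho_abmd) < 1, abs(rho_hw) < 1)
  # full 3x3 correlation matrix (height, weight, aBMD) must be positive definite
  r <- matrix(c(1, rho_hw, rho_abmd,
                rho_hw, 1, rho_abmd,
                rho_abmd, rho_abmd, 1), 3, 3)
  ok <- tryCatch({ chol(r); TRUE }, error = function(e) FALSE)
  if (!ok) stop("correlation structure (rho_abmd, rho_hw) is not positive definite")
  structure(list(height_mean = height_mean, height_sd = height_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 rho_abmd = rho_abmd, rho_hw = rho_hw),
            class = "hf_anthro_params")
}

#' Sample subject height, weight and BMI correlated with neck aBMD
#'
#' Height and weight are drawn from a Gaussian copula with configurable
#' correlation to femoral-neck aBMD (default 0.4) and to each other
#' (default 0.5). The aBMD margin enters through rank-based normal scores, so
#' the stated copula correlation is recovered for any continuous aBMD
#' distribution. Non-positive draws are rejected and resampled.
#'
#' @param neck_abmd Numeric vector of femoral-neck aBMD values (g/cm^2),
#'   strictly positive.
#' @param params An [anthro_params()] object.
#' @param eps Optional `n x 2` matrix of standard-normal innovations for the
#'   conditional (height, weight) draw, to run the copula on externally
#'   managed random streams. Drawn internally when `NULL`.
#' @return A tibble with columns `height` (m), `weight` (kg), `bmi`
#'   (kg/m^2), one row per input value.
#' @export
#' @examples
#' set.seed(1)
#' sample_anthropometry(rnorm(5, 0.6, 0.1))
sample_anthropometry <- function(neck_abmd, params = anthro_params(), eps = NULL) {
  stopifnot(all(neck_abmd > 0))
  n <- length(neck_abmd)
  ra <- params$rho_abmd
  # conditional covariance of (z_height, z_weight) given z_abmd
  cv <- params$rho_hw - ra^2
  vr <- 1 - ra^2
  ch <- chol(matrix(c(vr, cv, cv, vr), 2, 2))
  z_a <- stats::qnorm((rank(neck_abmd, ties.method = "average") - 0.5) / n)
  if (is.null(eps)) {
    eps <- matrix(stats::rnorm(2 * n), n, 2)
  } else {
    eps <- as.matrix(eps)
    stopifnot(nrow(eps) == n, ncol(eps) == 2)
  }
  e <- eps %*% ch
  height <- params$height_mean + params$height_sd * (ra * z_a + e[, 1])
  weight <- params$weight_mean + params$weight_sd * (ra * z_a + e[, 2])
  bad <- which(height <= 0.5 | weight <= 20)
  for (i in bad) {
    repeat {
      e2 <- stats::rnorm(2) %*% ch
      h2 <- params$height_mean + params$height_sd * (ra * z_a[i] + e2[1])
      w2 <- params$weight_mean + params$weight_sd * (ra * z_a[i] + e2[2])
      if (h2 > 0.5 && w2 > 20) { height[i] <- h2; weight[i] <- w2; break }
    }
  }
  tibble::tibble(height = height, weight = weight, bmi = weight / height^2)
}

#' Trochanteric soft-tissue thickness from BMI
#'
#' Linear relationship `STT = a + b * BMI`, clipped below at a physiological
#' floor. Monotone non-decreasing in BMI.
#'
#' @param bmi Body mass index (kg/m^2), strictly positive.
#' @param a Intercept (mm), default -10.
#' @param b Slope (mm per kg/m^2), default 1.2; must be non-negative.
#' @param floor_mm Lower clip (mm), default 2.
#' @return Soft-tissue thickness (mm), vectorised over `bmi`.
#' @export
#' @examples
#' soft_tissue_thickness(25) # 20 mm
soft_tissue_thickness <- function(bmi, a = -10, b = 1.2, floor_mm = 2) {
  stopifnot(all(bmi > 0), b >= 0, floor_mm > 0)
  pmax(a + b * bmi, floor_mm)
}

#' Build a virtual cohort matched to a target aBMD distribution
#'
#' Samples candidate subjects from the atlas and thins them by
#' accept/reject so that the accepted total-hip aBMD values follow the
#' Gaussian target: a kernel-density estimate of the proposal aBMD
#' distribution is fitted to an initial calibration batch, and each proposal
#' is accepted with probability `target(x) / (M * kde(x))` where the
#' envelope `M` is 1.2 times the maximum density ratio over the proposal
#' support. Anthropometry, soft-tissue thickness and the surrogate strength
#' scale are then attached per patient from substreams derived from the
#' cohort seed and the patient index, so patient-level draws are common
#' random numbers across cohorts built with the same seed.
#'
#' @param atlas An [fit_atlas()] object whose feature space contains columns
#'   `abmd_total_hip` and `abmd_neck` (the surrogate-mode aBMD features).
#' @param target A [cohort_target()].
#' @param seed Integer cohort seed.
#' @param anthro An [anthro_params()] object.
#' @param surrogate A [surrogate_params()] object.
#' @param stt_a,stt_b Soft-tissue-thickness coefficients (mm, mm per
#'   kg/m^2), see [soft_tissue_thickness()].
#' @param batch_size Proposals drawn per accept/reject batch.
#' @param max_batches Abort after this many batches if the cohort is not
#'   filled; combined with `batch_size` this bounds the minimum tolerated
#'   acceptance rate (about 1e-4 at the defaults).
#' @return A tibble of class `hf_cohort`, one row per patient, with columns
#'   `id`, `total_hip_abmd`, `neck_abmd`, `height`, `weight`, `bmi`,
#'   `soft_tissue_thickness`, `strength_s0`; attributes carry the target,
#'   seed, acceptance rate, surrogate parameters and the shared directional
#'   modulation grid.
#' @export
#' @examples
#' x <- generate_atlas_training(fixture_spec(), seed = 1)
#' atlas <- fit_atlas(x)
#' cohort <- build_cohort(atlas, cohort_target(50, 0.72, 0.09), seed = 2)
#' nrow(cohort)
build_cohort <- function(atlas, target, seed = 1,
                         anthro = anthro_params(),
                         surrogate = surrogate_params(),
                         stt_a = -10, stt_b = 1.2,
                         batch_size = 2000, max_batches = 200) {
  stopifnot(inherits(atlas, "hf_atlas"), inherits(target, "hf_cohort_target"))
  abmd_col <- match("abmd_total_hip", atlas$feature_names)
  neck_col <- match("abmd_neck", atlas$feature_names)
  if (is.na(abmd_col) || is.na(neck_col)) {
    stop("atlas features must include 'abmd_total_hip' and 'abmd_neck'")
  }
  res <- with_seed(derive_seed(seed, 101), {
    calib <- sample_patient_features(atlas, n = 20000)[, abmd_col]
    kde <- stats::density(calib, n = 2048)
    kde_fun <- stats::approxfun(kde$x, kde$y, yleft = 0, yright = 0)
    grid_ok <- kde$y > 1e-3 * max(kde$y)
    ratio <- stats::dnorm(kde$x[grid_ok], target$abmd_mean, target$abmd_sd) /
      kde$y[grid_ok]
    m_env <- 1.2 * max(ratio)

    acc_hip <- numeric(0); acc_neck <- numeric(0)
    proposed <- 0L; batches <- 0L
    while (length(acc_hip) < target$n_patients && batches < max_batches) {
      batches <- batches + 1L
      f <- sample_patient_features(atlas, n = batch_size)
      hip <- f[, abmd_col]; neck <- f[, neck_col]
      proposed <- proposed + batch_size
      q <- kde_fun(hip)
      p_acc <- ifelse(q > 0,
                      pmin(stats::dnorm(hip, target$abmd_mean, target$abmd_sd) /
                             (m_env * q), 1), 0)
      keep <- stats::runif(batch_size) < p_acc & hip > 0 & neck > 0
      acc_hip <- c(acc_hip, hip[keep]); acc_neck <- c(acc_neck, neck[keep])
    }
    list(hip = acc_hip, neck = acc_neck, proposed = proposed)
  })
  rate <- length(res$hip) / res$proposed
  if (length(res$hip) < target$n_patients) {
    stop(sprintf(paste0("cohort target appears infeasible for this atlas: ",
                        "acceptance rate %.2g after %d proposals"),
                 rate, res$proposed))
  }
  n <- target$n_patients
  hip <- res$hip[seq_len(n)]
  neck <- res$neck[seq_len(n)]
  # assign patient indices in aBMD rank order: patient j then sits at the
  # same aBMD quantile in any cohort built with this seed, so per-patient
  # substreams give comonotone common-random-numbers coupling across targets
  ord <- order(hip)
  hip <- hip[ord]
  neck <- neck[ord]
  # patient-level innovations from per-patient substreams (common random
  # numbers across cohorts sharing `seed`)
  innov <- t(vapply(seq_len(n), function(j) {
    with_seed(derive_seed(seed, 202, j), stats::rnorm(3))
  }, numeric(3)))
  anth <- sample_anthropometry(neck, anthro, eps = innov[, 1:2])
  stt <- soft_tissue_thickness(anth$bmi, a = stt_a, b = stt_b)
  sdlog <- sqrt(log(1 + surrogate$residual_cv^2))
  resid <- exp(sdlog * innov[, 3] - sdlog^2 / 2)
  s0 <- exp(surrogate$c0 + surrogate$c1 * hip) * resid
  cohort <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    total_hip_abmd = hip,
    neck_abmd = neck,
    height = anth$height,
    weight = anth$weight,
    bmi = anth$bmi,
    soft_tissue_thickness = stt,
    strength_s0 = s0
  )
  class(cohort) <- c("hf_cohort", class(cohort))
  attr(cohort, "target") <- target
  attr(cohort, "seed") <- seed
  attr(cohort, "acceptance_rate") <- rate
  attr(cohort, "surrogate") <- surrogate
  attr(cohort, "anthro") <- anthro
  attr(cohort, "modulation") <- direction_modulation(surrogate)
  cohort
}

#' Direction-specific strength surface of one cohort patient
#'
#' @param cohort An `hf_cohort`.
#' @param id Patient id (or integer row index).
#' @return An `hf_strength_surface` (61 x 31 grid of failure loads, N).
#' @export
patient_strength_surface <- function(cohort, id) {
  j <- if (is.character(id)) match(id, cohort$id) else as.integer(id)
  if (is.na(j) || j < 1 || j > nrow(cohort)) stop("unknown patient id")
  strength_surface(cohort$strength_s0[j] * attr(cohort, "modulation"))
}

#' Write a cohort table to CSV
#'
#' @param cohort An `hf_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- tibble::as_tibble(cohort)
  out$seed <- attr(cohort, "seed")
  readr::write_csv(out, path)
  invisible(path)
}
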