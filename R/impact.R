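#' Side-fall impact model parameters
#'
#' Single-degree-of-freedom mass-spring model of the body-floor impact:
#' the hip centre free-falls from a fixed fraction of body height, a
#' configurable fraction of body mass is engaged at impact against a linear
#' contact stiffness, and trochanteric soft tissue plus flooring attenuate
#' the transmitted peak force. Muscle contraction is not modelled (falls are
#' too fast for elderly subjects to brace).
#'
#' @param g Gravitational acceleration (m/s^2).
#' @param hip_height_fraction Hip-centre height as a fraction of body height.
#' @param effective_mass_fraction Fraction of body mass engaged at impact.
#' @param contact_stiffness Body-floor contact stiffness (N/m).
#' @param attenuation_per_mm Fractional force reduction per mm of
#'   trochanteric soft tissue.
#' @param attenuation_floor Lower bound on the soft-tissue transmission
#'   factor (the attenuation never removes more than this fraction leaves).
#' @param flooring_factor Multiplier in (0, 1] for flooring materials and
#'   wearable protectors (1 = rigid floor, no protector).
#' @param velocity_noise_cv Coefficient of variation of the lognormal
#'   impact-velocity noise (0 = deterministic velocity).
#' @return A list of class `hf_impact_params`.
#' @export
impact_params <- function(g = 9.81,
                          hip_height_fraction = 0.51,
                          effective_mass_fraction = 0.35,
                          contact_stiffness = 50000,
                          attenuation_per_mm = 0.02,
                          attenuation_floor = 0.3,
                          flooring_factor = 1.0,
                          velocity_noise_cv = 0.1) {
  stopifnot(g > 0, hip_height_fraction > 0, effective_mass_fraction > 0,
            contact_stiffness > 0, attenuation_per_mm >= 0,
            attenuation_floor > 0, attenuation_floor <= 1,
            flooring_factor > 0, flooring_factor <= 1,
            velocity_noise_cv >= 0)
  structure(list(g = g, hip_height_fraction = hip_height_fraction,
                 effective_mass_fraction = effective_mass_fraction,
                 contact_stiffness = contact_stiffness,
                 attenuation_per_mm = attenuation_per_mm,
                 attenuation_floor = attenuation_floor,
                 flooring_factor = flooring_factor,
                 velocity_noise_cv = velocity_noise_cv),
            class = "hf_impact_params")
}

#' Hip impact velocity for a side fall
#'
#' Free-fall velocity from hip-centre height,
#' `v = sqrt(2 g f h)`, times a mean-one lognormal noise with the configured
#' coefficient of variation.
#'
#' @param height Body height (m), vectorised.
#' @param params An [impact_params()] object.
#' @param noise Optional multiplicative noise vector overriding the internal
#'   draw (use `1` for a deterministic velocity).
#' @return Impact velocity (m/s).
#' @export
#' @examples
#' impact_velocity(1.60, impact_params(velocity_noise_cv = 0), noise = 1)
impact_velocity <- function(height, params = impact_params(), noise = NULL) {
  stopifnot(all(height > 0))
  v0 <- sqrt(2 * params$g * params$hip_height_fraction * height)
  if (is.null(noise)) {
    cv <- params$velocity_noise_cv
    noise <- if (cv == 0) 1 else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(length(v0), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  }
  v0 * noise
}

#' Peak impact force of the body-floor contact
#'
#' Undamped single-degree-of-freedom mass-spring impact:
#' `F = v * sqrt(k * m_eff)` with `m_eff` the effective fraction of body
#' mass. Monotone increasing in velocity, mass and stiffness.
#'
#' @param weight Body mass (kg), vectorised.
#' @param v Impact velocity (m/s), vectorised.
#' @param params An [impact_params()] object.
#' @return Peak force (N).
#' @export
#' @examples
#' peak_impact_force(weight = 25 / 0.35, v = 3,
#'                   impact_params(contact_stiffness = 50000))
peak_impact_force <- function(weight, v, params = impact_params()) {
  stopifnot(all(weight > 0), all(v >= 0))
  v * sqrt(params$contact_stiffness * params$effective_mass_fraction * weight)
}

#' Attenuate an impact force through soft tissue and flooring
#'
#' `F_att = F * flooring * max(1 - attenuation_per_mm * thickness, floor)`.
#' Attenuation can only reduce the force, never amplify it.
#'
#' @param force Unattenuated peak force (N), non-negative.
#' @param soft_tissue_mm Trochanteric soft-tissue thickness (mm), positive.
#' @param params An [impact_params()] object.
#' @return Attenuated force (N), `0 <= F_att <= F`.
#' @export
#' @examples
#' attenuate_force(3000, 20, impact_params(attenuation_per_mm = 0.02))
attenuate_force <- function(force, soft_tissue_mm, params = impact_params()) {
  stopifnot(all(force >= 0), all(soft_tissue_mm > 0))
  force * params$flooring_factor *
    pmax(1 - params$attenuation_per_mm * soft_tissue_mm, params$attenuation_floor)
}

#' The discrete grid of side-fall impact directions
#'
#' Intra-extra rotation `alpha` spans -30..30 degrees and
#' abduction-adduction `beta` spans 0..30 degrees, both in 1-degree steps:
#' 61 x 31 = 1891 possible force directions, stored row-major in
#' `(alpha, beta)`.
#'
#' @return A tibble with columns `alpha`, `beta` and 1891 rows.
#' @export
direction_grid <- function() {
  tidyr::expand_grid(alpha = -30:30, beta = 0:30)
}

#' Sample side-fall impact directions
#'
#' `alpha` is uniform over the 61 integers -30..30 and `beta` uniform over
#' the 31 integers 0..30, drawn independently (equiprobability and mutual
#' independence of the two angles).
#'
#' @param n Number of directions to draw.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with columns `alpha`, `beta` (degrees).
#' @export
#' @examples
#' sample_fall_direction(3, seed = 1)
sample_fall_direction <- function(n = 1, seed = NULL) {
  draw <- function() tibble::tibble(
    alpha = sample(-30:30, n, replace = TRUE),
    beta = sample(0:30, n, replace = TRUE)
  )
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
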