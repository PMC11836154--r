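# Shared fixtures, built in code once per test run.

shared_atlas <- local({
  x <- generate_atlas_training(fixture_spec(), seed = 1)
  fit_atlas(x)
})

# Minimal strain field with an explicit node set (no elements needed by the
# evaluator); all nodes on the surface.
point_strain_field <- function(nodes, eps_t, eps_c) {
  strain_field(
    nodes = nodes,
    elements = matrix(integer(0), nrow = 0, ncol = 10),
    surface = rep(TRUE, nrow(nodes)),
    eps_t = eps_t, eps_c = eps_c
  )
}

# Hand-built cohort for engine-level tests: deterministic anthropometry and
# explicit per-patient strength surfaces.
make_toy_cohort <- function(surfaces, height = 1.6, weight = 66, stt = 20,
                            abmd = 0.72) {
  n <- length(surfaces)
  bmi <- weight / height^2
  cohort <- tibble::tibble(
    id = sprintf("P%04d", seq_len(n)),
    total_hip_abmd = rep(abmd, n),
    neck_abmd = rep(0.6, n),
    height = rep(height, n),
    weight = rep(weight, n),
    bmi = rep(bmi, n),
    soft_tissue_thickness = rep(stt, n),
    strength_s0 = rep(1, n),
    strength_surface = surfaces
  )
  class(cohort) <- c("hf_cohort", class(cohort))
  attr(cohort, "seed") <- 0L
  attr(cohort, "modulation") <- matrix(1, 61, 31)
  cohort
}

flat_surface <- function(value) strength_surface(matrix(value, 61, 31))
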