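test_that("no fractures occur when strength always exceeds the capped force", {
  cohort <- make_toy_cohort(replicate(20, flat_surface(1e5), simplify = FALSE))
  trial <- run_trial(cohort, trial_config(n_realizations = 3, master_seed = 2))
  expect_true(all(trial$realizations$n_fractures == 0))
  expect_identical(nrow(trial$fractures), 0L)
})

test_that("zero fall rate yields no falls, fractures or evaluations", {
  cohort <- make_toy_cohort(replicate(10, flat_surface(10), simplify = FALSE))
  r <- simulate_realization(cohort, trial_config(lam = 0, master_seed = 1))
  expect_identical(nrow(r$fractures), 0L)
  expect_identical(r$n_evaluations, 0L)
})

test_that("a guaranteed-fracture patient fractures in year 1 of every realization", {
  cohort <- make_toy_cohort(list(flat_surface(1e-3 + 1e-6)))
  cfg <- trial_config(lam = 15, n_realizations = 5, master_seed = 9)
  trial <- run_trial(cohort, cfg)
  expect_true(all(trial$realizations$n_fractures == 1))
  expect_true(all(trial$fractures$year == 1))
  expect_true(all(trial$realizations$n_evaluations == 1))
})

test_that("with force always exceeding strength the incidence matches 1 - exp(-3 lam)", {
  n <- 2000
  cohort <- make_toy_cohort(replicate(n, flat_surface(1e-3), simplify = FALSE))
  r <- simulate_realization(cohort, trial_config(lam = 0.65, master_seed = 4))
  p <- 1 - exp(-3 * 0.65)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(nrow(r$fractures) / n - p), 3 * se)
  # every fractured patient stops at their first fall: one evaluation each,
  # plus zero for never-fallers
  expect_identical(r$n_evaluations, nrow(r$fractures))
})

test_that("fracture is an absorbing state with at most one record per patient", {
  x <- generate_atlas_training(fixture_spec(), seed = 1)
  cohort <- build_cohort(fit_atlas(x), cohort_target(300, 0.65, 0.10), seed = 2)
  trial <- run_trial(cohort, trial_config(n_realizations = 4, master_seed = 6))
  per_patient <- dplyr::count(trial$fractures, realization, patient_id)
  expect_true(all(per_patient$n == 1))
  # per-year counts sum to the realization totals
  sums <- dplyr::summarise(dplyr::group_by(trial$per_year, realization),
                           total = sum(n_fractures))
  expect_equal(sums$total, trial$realizations$n_fractures)
})

test_that("uniformly stronger femurs never fracture more, pathwise", {
  cohort <- make_toy_cohort(replicate(200, flat_surface(2200), simplify = FALSE))
  cfg <- trial_config(n_realizations = 5, master_seed = 12)
  base <- run_trial(cohort, cfg)
  stronger <- make_toy_cohort(replicate(200, flat_surface(2200 * 1.5),
                                        simplify = FALSE))
  up <- run_trial(stronger, cfg)
  expect_true(all(up$realizations$n_fractures <= base$realizations$n_fractures))
  expect_gt(sum(base$realizations$n_fractures), 0)
})

test_that("identical master seeds reproduce the trial bit-identically", {
  x <- generate_atlas_training(fixture_spec(), seed = 1)
  cohort <- build_cohort(fit_atlas(x), cohort_target(150, 0.70, 0.10), seed = 3)
  cfg <- trial_config(n_realizations = 3, master_seed = 77)
  a <- run_trial(cohort, cfg)
  b <- run_trial(cohort, cfg)
  expect_identical(a$realizations, b$realizations)
  expect_identical(a$fractures, b$fractures)
})

test_that("a single realization reports zero-width spread", {
  cohort <- make_toy_cohort(replicate(10, flat_surface(1e5), simplify = FALSE))
  trial <- run_trial(cohort, trial_config(n_realizations = 1, master_seed = 1))
  g <- glance(trial)
  expect_equal(g$sd_fractures, 0)
  expect_equal(g$min_fractures, g$max_fractures)
  expect_equal(g$min_fractures, g$mean_fractures)
})

test_that("the simulator matches the exact absorbing-chain probability on a toy setup", {
  # 5 patients, 2 years, deterministic forces; each patient's surface puts a
  # chosen number of the 1891 direction cells strictly below their force, so
  # the per-fall fracture probability is m/1891 exactly and
  # P(fracture) = 1 - exp(-2 lam m / 1891) in closed form.
  lam <- 0.65
  p_det <- impact_params(velocity_noise_cv = 0)
  v <- impact_velocity(1.6, p_det, noise = 1)
  force <- attenuate_force(peak_impact_force(66, v, p_det), 20, p_det)
  cells <- c(0, 189, 473, 946, 1891) # 0%, 10%, 25%, 50%, 100% of the grid
  surfaces <- lapply(cells, function(m) {
    fl <- matrix(force + 1, 61, 31) # ties are not fractures
    if (m > 0) fl[seq_len(m)] <- force * 0.9
    strength_surface(fl)
  })
  cohort <- make_toy_cohort(surfaces)
  p_exact <- 1 - exp(-2 * lam * cells / 1891)
  expected <- sum(p_exact)

  cfg <- trial_config(lam = lam, years = 2, master_seed = 13,
                      impact = p_det)
  n_real <- 50000
  totals <- vapply(seq_len(n_real), function(r) {
    length(hipfracsim:::realization_core(cohort, cfg, r,
                                         lapply(surfaces, unclass))$patient)
  }, integer(1))
  se <- sqrt(sum(p_exact * (1 - p_exact)) / n_real)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("force equal to the failure load is not a fracture", {
  p_det <- impact_params(velocity_noise_cv = 0)
  v <- impact_velocity(1.6, p_det, noise = 1)
  force <- attenuate_force(peak_impact_force(66, v, p_det), 20, p_det)
  cohort <- make_toy_cohort(list(flat_surface(force)))
  cfg <- trial_config(lam = 10, n_realizations = 3, master_seed = 3,
                      impact = p_det)
  trial <- run_trial(cohort, cfg)
  expect_true(all(trial$realizations$n_fractures == 0))
})

test_that("tidy and glance summarise realizations coherently", {
  x <- generate_atlas_training(fixture_spec(), seed = 1)
  cohort <- build_cohort(fit_atlas(x), cohort_target(200, 0.68, 0.10), seed = 8)
  trial <- run_trial(cohort, trial_config(n_realizations = 4, master_seed = 21))
  td <- tidy(trial)
  g <- glance(trial)
  expect_identical(nrow(td), 4L)
  expect_equal(mean(td$n_fractures), g$mean_fractures)
  expect_equal(g$incidence, g$mean_fractures / 200)
  expect_equal(g$min_fractures, min(td$n_fractures))
})
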