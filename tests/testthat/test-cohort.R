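test_that("build_cohort hits the target size and aBMD distribution", {
  tgt <- cohort_target(400, 0.722, 0.096)
  cohort <- build_cohort(shared_atlas, tgt, seed = 7)
  expect_identical(nrow(cohort), 400L)
  expect_true(all(cohort$total_hip_abmd > 0))
  expect_true(all(cohort$soft_tissue_thickness > 0))
  # sample mean close to target (3 SE band)
  expect_lt(abs(mean(cohort$total_hip_abmd) - 0.722), 3 * 0.096 / sqrt(400))
  expect_gt(attr(cohort, "acceptance_rate"), 1e-4)
})

test_that("an infeasible target outside the atlas support aborts", {
  expect_error(
    build_cohort(shared_atlas, cohort_target(50, 2.5, 0.05), seed = 1,
                 batch_size = 500, max_batches = 5),
    "infeasible"
  )
})

test_that("BMI is weight over height squared for every patient", {
  cohort <- build_cohort(shared_atlas, cohort_target(150, 0.72, 0.10), seed = 3)
  expect_lt(max(abs(cohort$bmi - cohort$weight / cohort$height^2)), 1e-9)
})

test_that("anthropometry copula recovers the configured aBMD correlation", {
  set.seed(11)
  neck <- rnorm(20000, 0.60, 0.11)
  neck <- neck[neck > 0]
  anth <- sample_anthropometry(neck)
  expect_lt(abs(cor(anth$weight, neck) - 0.4), 0.02)
  expect_lt(abs(cor(anth$height, neck) - 0.4), 0.02)
  expect_lt(abs(cor(anth$height, anth$weight) - 0.5), 0.03)
})

test_that("zero copula correlation decouples anthropometry from aBMD", {
  set.seed(12)
  neck <- rnorm(20000, 0.60, 0.11)
  neck <- neck[neck > 0]
  anth <- sample_anthropometry(neck, anthro_params(rho_abmd = 0))
  expect_lt(abs(cor(anth$height, neck)), 0.02)
})

test_that("anthropometry honours the BMI definition deterministically", {
  anth <- sample_anthropometry(0.6, eps = matrix(0, 1, 2))
  expect_equal(anth$bmi, anth$weight / anth$height^2)
  expect_equal(sample_anthropometry(c(0.5, 0.6, 0.7),
                                    eps = matrix(0, 3, 2))$bmi[2],
               anth$bmi)
})

test_that("impossible correlation structures are rejected", {
  expect_error(anthro_params(rho_abmd = 0.9, rho_hw = -0.9),
               "positive definite")
})

test_that("soft-tissue thickness follows the linear BMI relationship", {
  expect_equal(soft_tissue_thickness(25), 20)
  expect_equal(soft_tissue_thickness(c(10, 20, 30), b = 0, a = 15),
               rep(15, 3))
  # below the floor: -10 + 1.2 * 5 = -4 -> clipped to 2 mm
  expect_equal(soft_tissue_thickness(5), 2)
  bmi <- seq(15, 40, by = 0.5)
  expect_true(all(diff(soft_tissue_thickness(bmi)) >= 0))
})

test_that("cohort CSV export carries the documented columns", {
  cohort <- build_cohort(shared_atlas, cohort_target(30, 0.72, 0.10), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(c("id", "total_hip_abmd", "neck_abmd", "height", "weight",
                    "bmi", "soft_tissue_thickness", "seed") %in% names(back)))
  expect_equal(back$total_hip_abmd, cohort$total_hip_abmd)
})

test_that("cohort building is reproducible from its seed", {
  tgt <- cohort_target(60, 0.72, 0.10)
  a <- build_cohort(shared_atlas, tgt, seed = 99)
  b <- build_cohort(shared_atlas, tgt, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("patient strength surfaces scale with the patient strength factor", {
  cohort <- build_cohort(shared_atlas, cohort_target(20, 0.72, 0.10), seed = 5)
  s <- patient_strength_surface(cohort, cohort$id[3])
  expect_s3_class(s, "hf_strength_surface")
  expect_equal(max(s) / cohort$strength_s0[3],
               max(attr(cohort, "modulation")))
  expect_error(patient_strength_surface(cohort, "nope"), "unknown patient")
})
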