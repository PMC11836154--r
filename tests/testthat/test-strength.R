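test_that("sphere averaging is the identity on constant fields", {
  f <- generate_toy_strainfield("constant")
  out <- sphere_average_strains(f, radius = 3)
  ids <- which(out$surface)
  expect_equal(out$eps_t_avg[ids], f$eps_t[ids])
  expect_equal(out$eps_c_avg[ids], f$eps_c[ids])
})

test_that("two nodes within the radius average pairwise, outside stay apart", {
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0))
  f <- point_strain_field(nodes, eps_t = c(0.004, 0.008), eps_c = c(0, 0))
  near <- sphere_average_strains(f, radius = 3)
  expect_equal(near$eps_t_avg, c(0.006, 0.006))
  far <- sphere_average_strains(f, radius = 1)
  expect_equal(far$eps_t_avg, c(0.004, 0.008))
})

test_that("failure load hits the reference load at the strain limits", {
  n <- 10
  nodes <- cbind(seq(0, 90, length.out = n), 0, 0) # spaced beyond averaging
  at_limit <- point_strain_field(nodes, rep(0.0073, n), rep(0, n))
  expect_equal(failure_load_from_strains(at_limit), 1000)
  half <- point_strain_field(nodes, rep(0.00365, n), rep(0, n))
  expect_equal(failure_load_from_strains(half), 2000)
  # one dominant compressive node: 1000 * 0.0104 / 0.0208 = 500
  eps_c <- rep(0.002, n); eps_c[4] <- 0.0208
  comp <- point_strain_field(nodes, rep(0.001, n), eps_c)
  expect_equal(failure_load_from_strains(comp), 500)
})

test_that("toy fixtures carry ground truths the evaluator reproduces", {
  for (pattern in c("constant", "hotspot", "gradient")) {
    f <- generate_toy_strainfield(pattern)
    expect_equal(failure_load_from_strains(f), attr(f, "ground_truth_fl"),
                 info = pattern)
  }
  expect_lt(nrow(generate_toy_strainfield("gradient")$nodes), 500)
})

test_that("failure load is inverse-homogeneous in strain scaling", {
  f <- generate_toy_strainfield("gradient")
  base <- failure_load_from_strains(f)
  for (s in c(0.5, 2, 10)) {
    g <- f
    g$eps_t <- s * f$eps_t
    g$eps_c <- s * f$eps_c
    expect_equal(failure_load_from_strains(g), base / s, tolerance = 1e-12)
  }
})

test_that("the evaluator is invariant to node reordering", {
  f <- generate_toy_strainfield("gradient")
  set.seed(8)
  perm <- sample(nrow(f$nodes))
  g <- strain_field(f$nodes[perm, ], f$elements, f$surface[perm],
                    f$eps_t[perm], f$eps_c[perm])
  expect_equal(failure_load_from_strains(g), failure_load_from_strains(f))
})

test_that("an all-zero strain field is rejected as degenerate", {
  nodes <- cbind(0:3 * 10, 0, 0)
  f <- point_strain_field(nodes, rep(0, 4), rep(0, 4))
  expect_error(failure_load_from_strains(f), "degenerate")
})

test_that("zero modulation amplitude gives a direction-independent surface", {
  s <- surrogate_strength_surface(0.72,
                                  surrogate_params(modulation_amplitude = 0),
                                  residual = 1)
  expect_equal(max(s), min(s))
  expect_equal(unname(min(s)), exp(6.5 + 3.4 * 0.72), tolerance = 1e-12)
})

test_that("surrogate population median matches the log-linear calibration", {
  set.seed(14)
  p <- surrogate_params()
  sdlog <- sqrt(log(1 + p$residual_cv^2))
  s0 <- exp(p$c0 + p$c1 * 0.72) * rlnorm(5000, -sdlog^2 / 2, sdlog)
  expect_lt(abs(median(s0) / exp(p$c0 + p$c1 * 0.72) - exp(-sdlog^2 / 2)), 0.02)
  # full surfaces at the neutral direction reproduce S0 times the peak factor
  s <- surrogate_strength_surface(0.72, p, residual = 1)
  expect_equal(lookup_failure_load(s, 0, 0),
               exp(p$c0 + p$c1 * 0.72) * (1 + p$modulation_amplitude))
})

test_that("strength increases stochastically with aBMD", {
  set.seed(15)
  abmd <- rnorm(2000, 0.72, 0.10)
  abmd <- abmd[abmd > 0.3][1:1500]
  p <- surrogate_params()
  sdlog <- sqrt(log(1 + p$residual_cv^2))
  s0 <- exp(p$c0 + p$c1 * abmd) * rlnorm(length(abmd), -sdlog^2 / 2, sdlog)
  expect_gt(cor(abmd, s0, method = "spearman"), 0.5)
})

test_that("failure-load lookup matches direct indexing and rejects off-grid queries", {
  set.seed(16)
  m <- matrix(runif(61 * 31, 2000, 6000), 61, 31)
  s <- strength_surface(m)
  expect_equal(lookup_failure_load(s, -30, 0), m[1, 1])
  expect_equal(lookup_failure_load(s, 30, 30), m[61, 31])
  for (i in 1:20) {
    a <- sample(-30:30, 1); b <- sample(0:30, 1)
    expect_equal(lookup_failure_load(s, a, b), m[a + 31, b + 1])
  }
  flat <- flat_surface(3000)
  g <- direction_grid()
  expect_true(all(lookup_failure_load(flat, g$alpha, g$beta) == 3000))
  expect_error(lookup_failure_load(s, 31, 0), "grid")
  expect_error(lookup_failure_load(s, 0, -1), "grid")
  expect_error(lookup_failure_load(s, 0.5, 3), "grid")
})

test_that("strength surfaces validate shape and positivity", {
  expect_error(strength_surface(matrix(1, 10, 10)), "61 x 31")
  bad <- matrix(3000, 61, 31); bad[5, 5] <- -1
  expect_error(strength_surface(bad), "positive")
})

test_that("strain fields round-trip through the plain-text trio", {
  f <- generate_toy_strainfield("gradient")
  dir <- withr::local_tempdir()
  write_strain_field(f, dir)
  g <- read_strain_field(dir)
  expect_equal(g$nodes, f$nodes)
  expect_equal(g$elements, f$elements)
  expect_equal(g$surface, f$surface)
  expect_equal(g$eps_t, f$eps_t)
  expect_equal(g$eps_c, f$eps_c)
  expect_equal(failure_load_from_strains(g), attr(f, "ground_truth_fl"))
})

test_that("strength surfaces round-trip through CSV", {
  s <- surrogate_strength_surface(0.68, residual = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_strength_surface(s, path)
  back <- read_strength_surface(path)
  expect_equal(unclass(back), unclass(s), tolerance = 1e-12)
})
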