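test_that("rectifier and positive count follow their definitions", {
  expect_equal(positive_part(c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(positive_part(c(-3, -1)), c(0, 0))
  expect_equal(count_positive(c(-1, 0, 2)), 1)
  expect_equal(count_positive(numeric(3)), 0)
  # strict sign test, no epsilon
  expect_equal(count_positive(c(1e-300, -1e-300)), 1)
})

test_that("sparsity projection zeroes the smallest positives, ties low-index first", {
  expect_equal(project_sparsity_set(c(3, 1, 2, -5), 1), c(3, 0, 0, -5))
  expect_identical(project_sparsity_set(c(-1, -2), 0), c(-1, -2))
  expect_equal(project_sparsity_set(c(5, 5, 5), 2), c(0, 5, 5))
  expect_error(project_sparsity_set(1:3, -1), "nonnegative")
  expect_error(project_sparsity_set(1:3, 5), "exceed")
})

test_that("sparsity projection is a global nearest point (exhaustive oracle)", {
  set.seed(101)
  for (i in 1:300) {
    m <- sample(2:8, 1)
    y <- round(rnorm(m, sd = 3), 2)
    budget <- sample(0:m, 1)
    z <- project_sparsity_set(y, budget)
    expect_lte(count_positive(z), budget)
    # untouched components identical, removed ones exactly zero
    expect_true(all(z == y | (z == 0 & y > 0)))
    expect_equal(sum((z - y)^2), oracle_sparsity_dist2(y, budget),
                 tolerance = 1e-12)
  }
})

test_that("dose-volume projection shifts, projects and shifts back", {
  up <- pvc_spec(1 / 3, rep(20, 3), "upper")
  expect_equal(project_dvc(c(25, 21, 22), up), c(25, 20, 20))
  lo <- pvc_spec(1 / 3, rep(65, 3), "lower")
  expect_equal(project_dvc(c(50, 64, 66), lo), c(50, 65, 66))
  # already within budget: identity
  expect_identical(project_dvc(c(25, 19, 18), up), c(25, 19, 18))
  expect_error(project_dvc(c(1, 2), up), "shape")
})

test_that("dose-volume projection is nearest-point and idempotent (oracle)", {
  set.seed(202)
  for (i in 1:300) {
    m <- sample(2:8, 1)
    sense <- sample(c("upper", "lower"), 1)
    base <- round(rnorm(m, 10, 2), 1)
    spec <- pvc_spec(runif(1), base, sense, m)
    v <- round(rnorm(m, 10, 4), 2)
    z <- project_dvc(v, spec)
    expect_true(dvc_members(z, base, sense, spec$budget))
    expect_equal(sum((z - v)^2),
                 oracle_dvc_dist2(v, base, sense, spec$budget),
                 tolerance = 1e-12)
    expect_equal(project_dvc(z, spec), z)
  }
})

test_that("literal removal rule floors the fractional excess", {
  # m = 3, alpha = 0.5: alpha*m = 1.5, budget = 1
  spec <- pvc_spec(0.5, rep(0, 3), "upper", m = 3)
  v <- c(3, 2, 1)
  # member rule removes 3 - 1 = 2 components
  expect_equal(project_dvc(v, spec, rule = "member"), c(3, 0, 0))
  # literal rule removes floor(3 - 1.5) = 1, leaving ceil(alpha*m) positives
  expect_equal(project_dvc(v, spec, rule = "literal"), c(3, 2, 0))
})

test_that("alpha = 1 makes the sparsity constraint vacuous", {
  set.seed(5)
  spec <- pvc_spec(1, rnorm(6), "upper", 6)
  for (i in 1:20) {
    v <- rnorm(6, sd = 10)
    expect_identical(project_dvc(v, spec), v)
  }
})

test_that("prescription rules map to blocks with solved beta and alpha", {
  presc <- phantom_default()$prescription
  blocks <- prescription_to_blocks(presc)
  expect_length(blocks, 4)
  senses <- vapply(blocks, `[[`, character(1), "sense")
  expect_equal(senses, c("upper", "upper", "lower", "upper"))
  # avoidance A: (1 + beta) * 20 = 25
  expect_equal(blocks[[1]]$bound[1], 20)
  expect_equal(blocks[[1]]$beta, 0.25)
  expect_equal(blocks[[1]]$alpha, 0.10)
  expect_equal(blocks[[1]]$eff_bound[1], 25)
  # avoidance B: (1 + beta) * 30 = 40
  expect_equal(blocks[[2]]$bound[1], 30)
  expect_equal(blocks[[2]]$beta, 1 / 3)
  expect_equal(blocks[[2]]$alpha, 0.25)
  expect_equal(blocks[[2]]$eff_bound[1], 40)
  # target lower: (1 - beta) * 65 = 60, alpha = 1 - 90/100
  expect_equal(blocks[[3]]$bound[1], 65)
  expect_equal(blocks[[3]]$beta, 1 / 13)
  expect_equal(blocks[[3]]$alpha, 0.10)
  expect_equal(blocks[[3]]$eff_bound[1], 60)
  # target upper: hard bound only, no PVC
  expect_equal(blocks[[4]]$bound[1], 70)
  expect_equal(blocks[[4]]$beta, 0)
  expect_true(is.na(blocks[[4]]$alpha))
  # the two target blocks cover the same structure
  expect_equal(blocks[[3]]$name, blocks[[4]]$name)
})

test_that("inconsistent prescriptions are rejected", {
  expect_error(
    prescription_to_blocks(prescription(
      s = list(dmax = 20, dvc = list(list(V = 10, dose = 25,
                                          type = "upper"))))),
    "exceeds Dmax")
  expect_error(
    prescription_to_blocks(prescription(
      s = list(dmin = 60, dvc = list(list(V = 90, dose = 55,
                                          type = "lower"))))),
    "below Dmin")
  expect_error(prescription(s = list(dmax = 10, extra = 1)), "unknown field")
})

test_that("translation keeps plain blocks convex and PVC blocks budgeted", {
  A <- matrix(abs(rnorm(12)), 4, 3)
  plain <- block_constraint(A, bound = 10, sense = "upper")
  pvcb <- block_constraint(A, bound = 10, sense = "upper", beta = 0.25,
                           alpha = 0.5)
  prob <- translate_lfp_pvc(list(plain, pvcb))
  expect_null(prob$blocks[[1]]$pvc)
  expect_s3_class(prob$blocks[[2]]$pvc, "pvc_spec")
  expect_equal(prob$blocks[[2]]$pvc$budget, 2L)
  expect_equal(prob$blocks[[2]]$eff_bound, rep(12.5, 4))
  expect_error(block_constraint(A, 10, "upper", beta = 1), "beta")
  expect_error(block_constraint(A, 10, "upper", alpha = 1.2), "alpha")
})
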