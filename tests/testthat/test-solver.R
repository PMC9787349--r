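test_that("string plans are validated for fitness, weights and length", {
  expect_silent(validate_string_plan(string_plan(list(1:3)), 3))
  expect_silent(
    validate_string_plan(string_plan(list(1L, 2L, 3L)), 3))
  expect_error(validate_string_plan(string_plan(list(1L, 2L)), 3),
               "fitness")
  expect_error(
    validate_string_plan(string_plan(list(1:3), weights = 0.5), 3),
    "sum to 1")
  expect_error(
    validate_string_plan(string_plan(list(1:3, 4:5)), 3), "1..3")
  expect_error(
    validate_string_plan(string_plan(list(1:3), max_len = 2), 3),
    "length")
})

test_that("block operator composes the Landweber factor and the row sweep", {
  prob <- toy_problem(seed = 3)
  x <- abs(rnorm(6, 2))
  # scripted composition oracle: apply the factors by hand
  bl <- prob$blocks[[1]]
  spec <- landweber_spec(bl$gamma, bl$norm_sq)
  xv <- landweber_step(x, bl$A, function(v) project_dvc(v, bl$pvc), spec)
  for (i in seq_len(bl$m)) {
    h <- halfspace_constraint(bl$A[i, ], bl$bound[i], bl$sense, bl$beta)
    xv <- project_halfspace(xv, h, lam = bl$lambda)
  }
  expect_equal(block_operator(x, 1, prob), xv, tolerance = 1e-12)
  # swapped order differs in general
  expect_false(isTRUE(all.equal(block_operator(x, 1, prob),
                                block_operator(x, 1, prob,
                                               dvc_first = FALSE))))
  expect_error(block_operator(x, 9, prob), "index")
})

test_that("block operator fixed points satisfy the block's constraints", {
  set.seed(31)
  for (i in 1:50) {
    n <- 3
    A <- matrix(abs(rnorm(9)), 3, 3)
    bl <- block_constraint(A, bound = 2, sense = "upper", beta = 0.1,
                           alpha = 1 / 3)
    prob <- prepare_problem(translate_lfp_pvc(list(bl)))
    x <- abs(rnorm(3))
    fx <- block_operator(x, 1, prob)
    if (isTRUE(all.equal(fx, x, tolerance = 1e-12))) {
      v <- as.numeric(A %*% x)
      expect_true(all(v <= bl$eff_bound + 1e-9))
      expect_lte(sum(v > bl$bound + 1e-12), prob$blocks[[1]]$pvc$budget)
    }
  }
})

test_that("string application composes block operators in order", {
  prob <- toy_problem(seed = 5)
  x <- abs(rnorm(6))
  expect_identical(apply_string(x, 1L, prob), block_operator(x, 1, prob))
  expect_identical(apply_string(x, c(1L, 2L), prob),
                   block_operator(block_operator(x, 1, prob), 2, prob))
  # composition order matters: two oblique half-space blocks
  b1 <- block_constraint(matrix(c(1, 0), 1), bound = 0, sense = "upper")
  b2 <- block_constraint(matrix(c(1, 1), 1), bound = 0, sense = "upper")
  pr2 <- prepare_problem(translate_lfp_pvc(list(b1, b2), nonneg = FALSE))
  z <- c(1, 1)
  expect_equal(apply_string(z, c(1L, 2L), pr2), c(-0.5, 0.5))
  expect_equal(apply_string(z, c(2L, 1L), pr2), c(0, 0))
})

test_that("string averaging combines endpoints convexly", {
  prob <- toy_problem(seed = 8)
  x <- abs(rnorm(6))
  single <- string_plan(list(c(1L, 2L)))
  expect_equal(sa_iterate(x, single, prob), apply_string(x, 1:2, prob))
  # two identical strings: any weights give the single-string result
  dup <- string_plan(list(c(1L, 2L), c(1L, 2L)), weights = c(0.4, 0.6))
  expect_equal(sa_iterate(x, dup, prob), apply_string(x, 1:2, prob),
               tolerance = 1e-14)
  # equal weights over (1) and (2): the midpoint, componentwise
  half <- string_plan(list(1L, 2L))
  mid <- 0.5 * block_operator(x, 1, prob) + 0.5 * block_operator(x, 2, prob)
  expect_equal(sa_iterate(x, half, prob), mid, tolerance = 1e-14)
})

test_that("string evaluation order does not change the average", {
  prob <- toy_problem(seed = 13)
  x <- abs(rnorm(6))
  w <- c(0.2, 0.3, 0.5)
  plan <- string_plan(list(1:2, c(2L, 1L), 2:1), weights = w)
  perm <- c(3L, 1L, 2L)
  plan_p <- string_plan(plan$strings[perm], weights = w[perm])
  expect_equal(sa_iterate(x, plan, prob), sa_iterate(x, plan_p, prob),
               tolerance = 1e-12)
})

test_that("the iteration is Fejer monotone and solves consistent convex LFPs", {
  lfp <- consistent_lfp(seed = 97, rows = 50, n = 10)
  prob <- prepare_problem(lfp$problem)
  plan <- string_plan(list(1:2))
  # Fejer monotonicity toward the known feasible point, step by step
  x <- rnorm(10, sd = 2)
  d_prev <- sqrt(sum((x - lfp$feasible)^2))
  for (k in 1:50) {
    x <- sa_iterate(x, plan, prob)
    d <- sqrt(sum((x - lfp$feasible)^2))
    expect_lte(d, d_prev + 1e-10)
    d_prev <- d
  }
  # full run drives the residual down
  st <- run_dynamic_sa(rnorm(10, sd = 2), plan, prob, max_cycles = 500,
                       resid_tol = 1e-6)
  expect_lt(st$history$max_residual[nrow(st$history)], 1e-6)
})

test_that("solutions are stationary and plan schedules may vary", {
  lfp <- consistent_lfp(seed = 55, rows = 20, n = 8)
  prob <- prepare_problem(lfp$problem)
  w <- lfp$feasible
  expect_equal(sa_iterate(w, string_plan(list(1:2)), prob), w)
  st <- run_dynamic_sa(w, string_plan(list(1:2)), prob, max_cycles = 3)
  expect_equal(st$x, w)
  # alternating two different admissible plans is accepted
  st2 <- run_dynamic_sa(rnorm(8), list(string_plan(list(1:2)),
                                       string_plan(list(1L, 2L))),
                        prob, max_cycles = 4)
  expect_equal(st2$cycle, 4L)
  expect_error(run_dynamic_sa(w, list(), prob), "configuration")
})

test_that("one sequential cycle equals the full-length string plus the clamp", {
  prob <- toy_problem(seed = 21)
  x0 <- rep(1, 6)
  st <- run_sequential_rttp(prob, x0 = x0, n_cycles = 1)
  manual <- pmax(sa_iterate(x0, string_plan(list(1:2)), prob), 0)
  expect_identical(st$x, manual)
  expect_error(run_sequential_rttp(prob, n_cycles = 0), "parameter")
})

test_that("seeded random orders are reproducible and leave the RNG alone", {
  prob <- toy_problem(seed = 2)
  a <- run_sequential_rttp(prob, n_cycles = 3, block_order = "random",
                           voxel_order = "random", seed = 99)
  set.seed(123)
  before <- .Random.seed
  b <- run_sequential_rttp(prob, n_cycles = 3, block_order = "random",
                           voxel_order = "random", seed = 99)
  expect_identical(before, .Random.seed)
  expect_identical(a$x, b$x)
  expect_identical(a$history, b$history)
})
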