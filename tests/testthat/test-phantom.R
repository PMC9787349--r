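small_spec <- function(...) {
  phantom_spec(grid = c(32L, 32L), n_kernels = 16L, sigma = 4,
               target_mean = 10, ...)
}

test_that("kernels are isotropic Gaussians on a uniform lattice", {
  spec <- phantom_spec(grid = c(33L, 33L), n_kernels = 1L, sigma = 5,
                       target_mean = 1)
  bank <- generate_kernels(spec)
  expect_equal(nrow(bank$centers), 1L)
  expect_equal(unname(bank$centers[1, ]), c(16.5, 16.5))
  km <- kernel_map(bank, 1)
  map <- numeric(33 * 33)
  map[km$idx] <- km$values
  m <- matrix(map, 33, 33, byrow = TRUE)
  # maximum at the center pixel
  expect_equal(which.max(map), (16 * 33) + 17)
  # radial symmetry
  expect_equal(m[17, 1:33], m[1:33, 17], tolerance = 1e-12)
  expect_equal(m, t(m), tolerance = 1e-12)
  # closed form at distance sigma from the center
  expect_equal(m[17, 22] / m[17, 17], exp(-1 / 2), tolerance = 1e-12)
  expect_error(phantom_spec(c(32L, 32L), 15, 4, 10), "perfect square")
})

test_that("the default lattice has 1156 kernels arranged 34 x 34", {
  bank <- generate_kernels(phantom_default()$spec)
  expect_equal(nrow(bank$centers), 1156L)
  expect_equal(length(unique(bank$centers[, 1])), 34L)
  expect_equal(length(unique(bank$centers[, 2])), 34L)
})

test_that("amplitude calibration hits the target mean and scales linearly", {
  bank <- generate_kernels(small_spec())
  amp <- calibrate_amplitude(bank)
  expect_equal(mean(summed_map(bank, amp)), 10, tolerance = 1e-10)
  expect_equal(calibrate_amplitude(bank, 20), 2 * amp, tolerance = 1e-12)
  expect_equal(calibrate_amplitude(bank, 0), 0)
})

test_that("matrix assembly flattens kernels row-major into sparse columns", {
  # single off-center kernel on a tiny grid: hand-flattening oracle
  spec <- phantom_spec(grid = c(4L, 4L), n_kernels = 1L, sigma = 1,
                       target_mean = 1, truncation_radius = 10)
  bank <- generate_kernels(spec)
  dim_obj <- assemble_matrix(bank, amplitude = 1)
  expect_equal(dim(dim_obj$A), c(16L, 1L))
  r0 <- bank$centers[1, 1]
  c0 <- bank$centers[1, 2]
  expected <- as.numeric(t(outer(0:3 + 0.5 - r0, 0:3 + 0.5 - c0,
                                 function(dr, dc) exp(-(dr^2 + dc^2) / 2))))
  expect_equal(as.numeric(dim_obj$A[, 1]), expected, tolerance = 1e-12)
  # nonnegativity and truncation sparsity
  bank2 <- generate_kernels(small_spec())
  d2 <- assemble_matrix(bank2, 1)
  expect_true(all(d2$A@x >= 0))
  expect_lt(Matrix::nnzero(d2$A) / length(d2$A), 1)
})

test_that("structure blocks pick out the structure's rows", {
  spec <- small_spec(structures = list(
    left = list(rows = c(8L, 16L), cols = c(2L, 10L)),
    all_col = list(rows = c(20L, 24L), cols = c(0L, 32L))))
  bank <- generate_kernels(spec)
  dim_obj <- assemble_matrix(bank, 1)
  expect_equal(length(dim_obj$structure_rows$left), 64L)
  B <- structure_matrix(dim_obj, "left")
  expect_equal(dim(B), c(64L, 16L))
  expect_equal(B[1, ], as.numeric(dim_obj$A[8L * 32L + 3L, ]))
  expect_error(structure_matrix(dim_obj, "nope"), "unknown structure")
  expect_error(phantom_spec(c(32L, 32L), 16L, 4, 10, structures = list(
    a = list(rows = c(0L, 8L), cols = c(0L, 8L)),
    b = list(rows = c(4L, 12L), cols = c(4L, 12L)))), "disjoint")
})

test_that("scaling the target mean scales the matrix linearly", {
  spec <- small_spec(structures = list(
    s = list(rows = c(8L, 16L), cols = c(8L, 16L))))
  bank <- generate_kernels(spec)
  a1 <- calibrate_amplitude(bank, 10)
  a2 <- calibrate_amplitude(bank, 30)
  A1 <- assemble_matrix(bank, a1)$A
  A2 <- assemble_matrix(bank, a2)$A
  expect_equal(A2@x, 3 * A1@x, tolerance = 1e-12)
})

test_that("the summed scaled-default map is homogeneous in the interior", {
  cfg <- phantom_small()
  bank <- generate_kernels(cfg$spec)
  amp <- calibrate_amplitude(bank)
  m <- matrix(summed_map(bank, amp), 128, 128, byrow = TRUE)
  interior <- m[33:96, 33:96]
  expect_lt(stats::sd(interior) / mean(interior), 0.01)
  expect_equal(mean(m), 50, tolerance = 1e-10)
})

test_that("the packaged configurations carry the documented prescription", {
  cfg <- phantom_default()
  expect_equal(cfg$spec$grid, c(512L, 512L))
  expect_equal(cfg$spec$n_kernels, 1156L)
  expect_equal(cfg$spec$sigma, 20)
  expect_equal(cfg$cycles, 40L)
  expect_equal(cfg$lambda, 1)
  # 4 hard bounds, 3 DVCs
  n_hard <- sum(vapply(cfg$prescription, function(r) {
    (!is.null(r$dmax)) + (!is.null(r$dmin))
  }, numeric(1)))
  n_dvc <- sum(vapply(cfg$prescription, function(r) length(r$dvc),
                      numeric(1)))
  expect_equal(n_hard, 4)
  expect_equal(n_dvc, 3)
  # quarter-scale variant is spatially proportional
  sm <- phantom_small()
  expect_equal(sm$spec$grid, cfg$spec$grid / 4L)
  expect_equal(sm$spec$sigma, cfg$spec$sigma / 4)
  for (nm in names(cfg$spec$structures)) {
    expect_equal(sm$spec$structures[[nm]]$rows,
                 cfg$spec$structures[[nm]]$rows / 4L)
    expect_equal(sm$spec$structures[[nm]]$cols,
                 cfg$spec$structures[[nm]]$cols / 4L)
  }
})
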