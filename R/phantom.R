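#' Synthetic pseudo-dose phantom specification
#'
#' Describes a two-dimensional phantom: a pixel grid, a uniform lattice of
#' isotropic Gaussian pseudo-dose kernels (one per beamlet), a common
#' target mean intensity for the superimposed map, a truncation radius
#' beyond which kernel values are set to zero (keeping the dose-influence
#' matrix sparse), and named, pairwise disjoint axis-aligned rectangular
#' structures. Pixel coordinates are 0-based; structure ranges are
#' half-open `[from, to)`.
#'
#' @param grid Integer pair `(rows, cols)`.
#' @param n_kernels Perfect-square number of kernels, laid out on a uniform
#'   `sqrt(n_kernels)` by `sqrt(n_kernels)` lattice.
#' @param sigma Kernel standard deviation in pixels.
#' @param target_mean Target mean of the calibrated summed map.
#' @param truncation_radius Sparsity cutoff in pixels; `Inf` disables
#'   truncation (dense mode, for oracle comparison). Default `4 * sigma`.
#' @param structures Named list; each element a list with integer pairs
#'   `rows = c(from, to)` and `cols = c(from, to)` (0-based, half-open).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, n_kernels, sigma, target_mean,
                         truncation_radius = 4 * sigma,
                         structures = list()) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) {
    stop("'grid' must be two positive integers", call. = FALSE)
  }
  side <- sqrt(n_kernels)
  if (side != floor(side)) {
    stop("parameter error: 'n_kernels' must be a perfect square",
         call. = FALSE)
  }
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (target_mean < 0) stop("'target_mean' must be nonnegative", call. = FALSE)
  if (truncation_radius <= 0) {
    stop("'truncation_radius' must be positive", call. = FALSE)
  }
  if (length(structures)) {
    if (is.null(names(structures)) || any(names(structures) == "")) {
      stop("structures must be named", call. = FALSE)
    }
    masks <- lapply(structures, function(s) {
      if (any(s$rows < 0) || any(s$cols < 0) ||
          s$rows[2] > grid[1] || s$cols[2] > grid[2] ||
          s$rows[1] >= s$rows[2] || s$cols[1] >= s$cols[2]) {
        stop("specification error: structure rectangle outside grid or empty",
             call. = FALSE)
      }
      structure_rows_idx(s, grid)
    })
    all_idx <- unlist(masks)
    if (anyDuplicated(all_idx)) {
      stop("specification error: structures must be pairwise disjoint",
           call. = FALSE)
    }
  }
  structure(
    list(grid = grid, n_kernels = as.integer(n_kernels), sigma = sigma,
         target_mean = target_mean, truncation_radius = truncation_radius,
         structures = structures),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d grid, %d kernels (sigma %g px, trunc %g px), mean %g\n",
    x$grid[1], x$grid[2], x$n_kernels, x$sigma, x$truncation_radius,
    x$target_mean))
  for (nm in names(x$structures)) {
    s <- x$structures[[nm]]
    cat(sprintf("  %s: rows [%d, %d), cols [%d, %d)\n", nm,
                s$rows[1], s$rows[2], s$cols[1], s$cols[2]))
  }
  invisible(x)
}

# Flat (row-major, 1-based) pixel indices of a structure rectangle.
structure_rows_idx <- function(s, grid) {
  rr <- seq.int(s$rows[1], s$rows[2] - 1L)
  cc <- seq.int(s$cols[1], s$cols[2] - 1L)
  as.integer(outer(rr * grid[2], cc + 1L, "+"))
}

#' Generate the Gaussian kernel bank
#'
#' Places `n_kernels` isotropic Gaussian kernels
#' \eqn{\exp(-((r-r_0)^2 + (c-c_0)^2) / (2\sigma^2))} (unit amplitude) on a
#' uniform lattice over the grid, truncated to zero beyond the truncation
#' radius. Kernel maps are computed lazily via [kernel_map()].
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `kernel_bank` with the lattice `centers`
#'   (pixel coordinates of the kernel centers, one row per kernel, in
#'   row-major lattice order).
#' @export
generate_kernels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  side <- as.integer(sqrt(spec$n_kernels))
  sp_r <- spec$grid[1] / side
  sp_c <- spec$grid[2] / side
  centers_r <- (seq_len(side) - 0.5) * sp_r
  centers_c <- (seq_len(side) - 0.5) * sp_c
  centers <- cbind(r = rep(centers_r, each = side),
                   c = rep(centers_c, times = side))
  structure(list(spec = spec, centers = centers),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("<kernel_bank> %d kernels on a %d x %d lattice\n",
              nrow(x$centers), as.integer(sqrt(nrow(x$centers))),
              as.integer(sqrt(nrow(x$centers)))))
  invisible(x)
}

#' Pixel map of one kernel
#'
#' Unit-amplitude values of kernel `k` at the pixels inside its truncation
#' radius. Pixel centers sit at integer coordinate + 0.5.
#'
#' @param bank A [generate_kernels()] bank.
#' @param k Kernel index.
#' @return List with `idx` (flat row-major 1-based pixel indices) and
#'   `values`.
#' @export
kernel_map <- function(bank, k) {
  spec <- bank$spec
  grid <- spec$grid
  r0 <- bank$centers[k, 1]
  c0 <- bank$centers[k, 2]
  trunc <- spec$truncation_radius
  if (!is.finite(trunc)) trunc <- sqrt(sum(grid^2)) + 1
  rmin <- max(0L, floor(r0 - trunc))
  rmax <- min(grid[1] - 1L, ceiling(r0 + trunc))
  cmin <- max(0L, floor(c0 - trunc))
  cmax <- min(grid[2] - 1L, ceiling(c0 + trunc))
  rr <- rmin:rmax
  cc <- cmin:cmax
  d2 <- outer((rr + 0.5 - r0)^2, (cc + 0.5 - c0)^2, "+")
  keep <- d2 <= trunc^2
  loc <- which(keep, arr.ind = TRUE)
  list(idx = as.integer(rr[loc[, 1]] * grid[2] + cc[loc[, 2]] + 1L),
       values = exp(-d2[keep] / (2 * spec$sigma^2)))
}

#' Superimposed kernel map
#'
#' The sum of all kernel contributions at amplitude `amplitude`, as a full
#' grid vector (flat, row-major).
#'
#' @param bank A [generate_kernels()] bank.
#' @param amplitude Common kernel amplitude.
#' @return Numeric vector of length `prod(grid)`.
#' @export
summed_map <- function(bank, amplitude = 1) {
  acc <- numeric(prod(bank$spec$grid))
  for (k in seq_len(nrow(bank$centers))) {
    km <- kernel_map(bank, k)
    acc[km$idx] <- acc[km$idx] + km$values
  }
  amplitude * acc
}

#' Calibrate the common kernel amplitude
#'
#' Finds the single scalar amplitude such that the mean over all grid
#' pixels of the superimposed kernel map equals the spec's target mean.
#'
#' @param bank A [generate_kernels()] bank.
#' @param target_mean Target mean; defaults to the spec's.
#' @return Positive scalar amplitude.
#' @export
calibrate_amplitude <- function(bank, target_mean = bank$spec$target_mean) {
  stopifnot(inherits(bank, "kernel_bank"))
  total <- 0
  for (k in seq_len(nrow(bank$centers))) {
    total <- total + sum(kernel_map(bank, k)$values)
  }
  if (total == 0) {
    stop("calibration error: kernel bank sums to zero", call. = FALSE)
  }
  target_mean * prod(bank$spec$grid) / total
}

#' Assemble the dose-influence matrix
#'
#' Column `j` is the flattened (row-major) pixel map of kernel `j` at the
#' calibrated amplitude; rows are grid pixels. Per-structure row-index sets
#' are taken from the spec's rectangles.
#'
#' @param bank A [generate_kernels()] bank.
#' @param amplitude Common kernel amplitude (see [calibrate_amplitude()]).
#' @return An object of class `dose_influence`: sparse matrix `A`
#'   (`prod(grid)` by `n_kernels`), `structure_rows` (named list of row
#'   index vectors) and the `spec`.
#' @export
assemble_matrix <- function(bank, amplitude) {
  stopifnot(inherits(bank, "kernel_bank"))
  spec <- bank$spec
  nk <- nrow(bank$centers)
  ti <- vector("list", nk)
  tj <- vector("list", nk)
  tx <- vector("list", nk)
  for (k in seq_len(nk)) {
    km <- kernel_map(bank, k)
    ti[[k]] <- km$idx
    tj[[k]] <- rep.int(k, length(km$idx))
    tx[[k]] <- amplitude * km$values
  }
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(prod(spec$grid), nk))
  dose_influence(A, lapply(spec$structures, structure_rows_idx,
                           grid = spec$grid), spec = spec)
}

#' Dose-influence matrix with structure row sets
#'
#' Container pairing the full (sparse) dose-influence matrix with named
#' per-structure row-index sets.
#'
#' @param A Matrix (pixels by kernels), base or `Matrix`.
#' @param structure_rows Named list of integer row-index vectors, each a
#'   subset of `1:nrow(A)`.
#' @param spec Optional originating [phantom_spec()].
#' @return An object of class `dose_influence`.
#' @export
dose_influence <- function(A, structure_rows, spec = NULL) {
  if (length(structure_rows)) {
    if (is.null(names(structure_rows)) || any(names(structure_rows) == "")) {
      stop("'structure_rows' must be named", call. = FALSE)
    }
    for (idx in structure_rows) {
      if (length(idx) == 0L) {
        stop("load error: empty structure block", call. = FALSE)
      }
      if (any(idx < 1L | idx > nrow(A))) {
        stop("load error: structure row index outside the matrix",
             call. = FALSE)
      }
    }
  }
  structure(list(A = A, structure_rows = structure_rows, spec = spec),
            class = "dose_influence")
}

#' @export
print.dose_influence <- function(x, ...) {
  cat(sprintf("<dose_influence> %d x %d (%d structures)\n",
              nrow(x$A), ncol(x$A), length(x$structure_rows)))
  for (nm in names(x$structure_rows)) {
    cat(sprintf("  %s: %d rows\n", nm, length(x$structure_rows[[nm]])))
  }
  invisible(x)
}

#' Dense submatrix of one structure
#'
#' @param dim_obj A [dose_influence()].
#' @param name Structure name.
#' @return Base dense matrix of the structure's rows.
#' @export
structure_matrix <- function(dim_obj, name) {
  stopifnot(inherits(dim_obj, "dose_influence"))
  idx <- dim_obj$structure_rows[[name]]
  if (is.null(idx)) {
    stop(sprintf("unknown structure '%s'", name), call. = FALSE)
  }
  as.matrix(dim_obj$A[idx, , drop = FALSE])
}

#' Packaged default phantom and prescription
#'
#' The packaged two-dimensional reference configuration: a 512 x 512 grid,
#' 1156 Gaussian kernels on a 34 x 34 lattice with sigma = 20 px (truncated
#' at 4 sigma), calibrated to a homogeneous summed map of mean 50 intensity
#' units, three disjoint 96 px square structures (two avoidance regions,
#' left and right, and one central target, all at mid-height; the
#' rectangles are package choices), and the prescription: Avoidance A
#' Dmax = 25 with D10% <= 20; Avoidance B Dmax = 40 with D25% <= 30; Target
#' Dmin = 60, Dmax = 70 with D90% >= 65. Solver defaults: lambda = 1 on
#' every block, gamma = 1 / ||A_l||^2 (midrange mode), 40 cycles.
#'
#' @return List with elements `spec` ([phantom_spec()]), `prescription`
#'   ([prescription()]), `lambda`, `gamma_mode` and `cycles`.
#' @seealso [phantom_small()] for a proportionally scaled-down variant.
#' @export
phantom_default <- function() {
  spec <- phantom_spec(
    grid = c(512L, 512L), n_kernels = 1156L, sigma = 20, target_mean = 50,
    structures = list(
      avoidance_a = list(rows = c(208L, 304L), cols = c(32L, 128L)),
      target      = list(rows = c(208L, 304L), cols = c(208L, 304L)),
      avoidance_b = list(rows = c(208L, 304L), cols = c(384L, 480L))))
  presc <- prescription(
    avoidance_a = list(dmax = 25,
                       dvc = list(list(V = 10, dose = 20, type = "upper"))),
    avoidance_b = list(dmax = 40,
                       dvc = list(list(V = 25, dose = 30, type = "upper"))),
    target = list(dmin = 60, dmax = 70,
                  dvc = list(list(V = 90, dose = 65, type = "lower"))))
  list(spec = spec, prescription = presc, lambda = 1,
       gamma_mode = "midrange", cycles = 40L)
}

#' Scaled-down default phantom
#'
#' A quarter-scale variant of [phantom_default()] for fast runs: every
#' spatial length is divided by four (128 x 128 grid, sigma = 5 px, 24 px
#' square structures at the same relative positions), the kernel count
#' follows the 17 x 17 lattice (289 kernels), and the mean-50 calibration
#' and prescription are unchanged.
#'
#' @return Same shape as [phantom_default()].
#' @export
phantom_small <- function() {
  cfg <- phantom_default()
  cfg$spec <- phantom_spec(
    grid = c(128L, 128L), n_kernels = 289L, sigma = 5, target_mean = 50,
    structures = list(
      avoidance_a = list(rows = c(52L, 76L), cols = c(8L, 32L)),
      target      = list(rows = c(52L, 76L), cols = c(52L, 76L)),
      avoidance_b = list(rows = c(52L, 76L), cols = c(96L, 120L))))
  cfg
}

#' Build a ready-to-solve problem from a phantom configuration
#'
#' Convenience wrapper: generates kernels, calibrates the amplitude,
#' assembles the dose-influence matrix, converts the prescription to
#' blocks and translates everything into a [feasibility_problem()].
#'
#' @param cfg A configuration as returned by [phantom_default()] or
#'   [phantom_small()].
#' @return List with `problem` (a prepared [feasibility_problem()]),
#'   `dim_obj` (the [dose_influence()]) and `amplitude`.
#' @export
build_phantom_problem <- function(cfg) {
  bank <- generate_kernels(cfg$spec)
  amp <- calibrate_amplitude(bank)
  dim_obj <- assemble_matrix(bank, amp)
  blocks <- prescription_to_blocks(cfg$prescription, dim_obj,
                                   lambda = cfg$lambda)
  problem <- prepare_problem(translate_lfp_pvc(blocks),
                             gamma_mode = cfg$gamma_mode)
  list(problem = problem, dim_obj = dim_obj, amplitude = amp)
}
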