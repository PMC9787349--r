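#' Load and validate a run configuration
#'
#' Reads a YAML configuration and fills every omitted setting from the
#' packaged defaults ([phantom_default()]), so an empty file yields the
#' default reference run. Unknown keys anywhere in the file are rejected
#' with the offending field path.
#'
#' Top-level schema: exactly one input source between `phantom` (grid,
#' n_kernels, sigma, target_mean, truncation_radius, structures) and
#' `matrix` (paths `matrix`, `blocks` — a named map of row-index files —
#' and nothing else); `prescription` (structure name to dmax/dmin/dvc
#' list); `solver` (cycles, lambda, gamma_mode, block_order, voxel_order,
#' seed, stop_on_zero, dvc_first, rule); `output` (directory).
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: config file '%s' not found", path),
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("config error: unknown key '%s.%s'", where, bad[1]),
           call. = FALSE)
    }
  }
  check_keys(raw, c("phantom", "matrix", "prescription", "solver", "output"),
             "config")
  if (!is.null(raw$phantom) && !is.null(raw$matrix)) {
    stop("config error: give exactly one of 'phantom' and 'matrix'",
         call. = FALSE)
  }
  defaults <- phantom_default()

  phantom <- NULL
  matrix_paths <- NULL
  if (!is.null(raw$matrix)) {
    check_keys(raw$matrix, c("matrix", "blocks"), "config.matrix")
    if (is.null(raw$matrix$matrix) || is.null(raw$matrix$blocks)) {
      stop("config error: 'matrix' needs fields 'matrix' and 'blocks'",
           call. = FALSE)
    }
    for (f in c(raw$matrix$matrix, unlist(raw$matrix$blocks))) {
      if (!file.exists(f)) {
        stop(sprintf("I/O error: referenced file '%s' not found", f),
             call. = FALSE)
      }
    }
    matrix_paths <- raw$matrix
  } else {
    ph <- raw$phantom
    check_keys(ph, c("grid", "n_kernels", "sigma", "target_mean",
                     "truncation_radius", "structures"), "config.phantom")
    d <- defaults$spec
    structures <- if (!is.null(ph$structures)) {
      lapply(ph$structures, function(s) {
        check_keys(s, c("rows", "cols"), "config.phantom.structures")
        list(rows = as.integer(s$rows), cols = as.integer(s$cols))
      })
    } else {
      d$structures
    }
    sigma <- ph$sigma %||% d$sigma
    phantom <- phantom_spec(
      grid = ph$grid %||% d$grid,
      n_kernels = ph$n_kernels %||% d$n_kernels,
      sigma = sigma,
      target_mean = ph$target_mean %||% d$target_mean,
      truncation_radius = ph$truncation_radius %||% (4 * sigma),
      structures = structures)
  }

  presc <- if (!is.null(raw$prescription)) {
    prescription(lapply(raw$prescription, function(r) {
      r$dvc <- lapply(r$dvc, as.list)
      r
    }))
  } else {
    defaults$prescription
  }

  sv <- raw$solver
  check_keys(sv, c("cycles", "lambda", "gamma_mode", "block_order",
                   "voxel_order", "seed", "stop_on_zero", "dvc_first",
                   "rule"), "config.solver")
  solver <- list(
    cycles = as.integer(sv$cycles %||% defaults$cycles),
    lambda = sv$lambda %||% defaults$lambda,
    gamma_mode = sv$gamma_mode %||% defaults$gamma_mode,
    block_order = sv$block_order %||% "asis",
    voxel_order = sv$voxel_order %||% "ascending",
    seed = sv$seed,
    stop_on_zero = isTRUE(sv$stop_on_zero),
    dvc_first = sv$dvc_first %||% TRUE,
    rule = sv$rule %||% "member")
  if (solver$lambda <= 0 || solver$lambda >= 2) {
    stop("config error: solver.lambda must lie in the open interval (0, 2)",
         call. = FALSE)
  }
  if (solver$cycles < 1L) {
    stop("config error: solver.cycles must be at least 1", call. = FALSE)
  }
  if (!solver$gamma_mode %in% c("midrange", "strict")) {
    stop("config error: solver.gamma_mode must be 'midrange' or 'strict'",
         call. = FALSE)
  }
  if (!solver$block_order %in% c("asis", "random") ||
      !solver$voxel_order %in% c("ascending", "random")) {
    stop("config error: invalid solver ordering", call. = FALSE)
  }
  if (!solver$rule %in% c("member", "literal")) {
    stop("config error: solver.rule must be 'member' or 'literal'",
         call. = FALSE)
  }
  structure(
    list(phantom = phantom, matrix_paths = matrix_paths,
         prescription = presc, solver = solver,
         output = raw$output %||% "sacq-output"),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a problem's inputs to files
#'
#' Writes the dose-influence matrix in MatrixMarket coordinate format
#' (1-based indices per that standard; values at full precision), one row
#' per line per-structure row-index files (1-based), the prescription as
#' YAML and, when the spec is known, the structure masks as an
#' integer-labelled grid in TSV form (0 = background).
#'
#' @param dim_obj A [dose_influence()].
#' @param presc A [prescription()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_problem <- function(dim_obj, presc, dir) {
  stopifnot(inherits(dim_obj, "dose_influence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_path <- file.path(dir, "matrix.mtx")
  write_mm_full(methods::as(dim_obj$A, "TsparseMatrix"), mat_path)
  block_paths <- list()
  for (nm in names(dim_obj$structure_rows)) {
    p <- file.path(dir, paste0("rows_", nm, ".txt"))
    writeLines(as.character(dim_obj$structure_rows[[nm]]), p)
    block_paths[[nm]] <- p
  }
  presc_path <- file.path(dir, "prescription.yaml")
  yaml::write_yaml(unclass(presc), presc_path)
  mask_path <- NULL
  if (!is.null(dim_obj$spec)) {
    mask_path <- file.path(dir, "masks.tsv")
    grid <- dim_obj$spec$grid
    mask <- matrix(0L, grid[1], grid[2])
    for (si in seq_along(dim_obj$structure_rows)) {
      idx <- dim_obj$structure_rows[[si]]
      mask[cbind((idx - 1L) %/% grid[2] + 1L, (idx - 1L) %% grid[2] + 1L)] <-
        si
    }
    utils::write.table(mask, mask_path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(list(matrix = mat_path, blocks = block_paths,
                 prescription = presc_path, masks = mask_path))
}

# MatrixMarket coordinate writer with full double precision (the stock
# writer prints too few digits for bit-faithful round trips).
write_mm_full <- function(T, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(T), ncol(T), length(T@x))), con)
  writeLines(sprintf("%d %d %.17g", T@i + 1L, T@j + 1L, T@x), con)
}

#' Read a problem from files
#'
#' Loads a MatrixMarket matrix, per-structure row-index files and a YAML
#' prescription, and assembles the same [feasibility_problem()] that
#' [build_phantom_problem()] would build in memory from equal data.
#'
#' @param matrix_path MatrixMarket file of the full dose-influence matrix.
#' @param block_paths Named list/vector of row-index files (one 1-based row
#'   index per line).
#' @param prescription_path YAML prescription file.
#' @param lambda Half-space relaxation for every block.
#' @return List with `problem` (unprepared [feasibility_problem()]) and
#'   `dim_obj`.
#' @export
read_problem <- function(matrix_path, block_paths, prescription_path,
                         lambda = 1) {
  A <- Matrix::readMM(matrix_path)
  A <- methods::as(A, "CsparseMatrix")
  structure_rows <- lapply(block_paths, function(p) {
    idx <- as.integer(readLines(p))
    if (anyNA(idx)) stop("load error: bad row index file", call. = FALSE)
    idx
  })
  names(structure_rows) <- names(block_paths)
  dim_obj <- dose_influence(A, structure_rows)
  presc <- prescription(lapply(yaml::read_yaml(prescription_path),
                               function(r) {
                                 r$dvc <- lapply(r$dvc, as.list)
                                 r
                               }))
  missing <- setdiff(names(presc), names(structure_rows))
  if (length(missing)) {
    stop(sprintf("load error: no row set for structure '%s'", missing[1]),
         call. = FALSE)
  }
  blocks <- prescription_to_blocks(presc, dim_obj, lambda = lambda)
  list(problem = translate_lfp_pvc(blocks), dim_obj = dim_obj)
}

#' Write a per-cycle violation log
#'
#' Appends the solver history as CSV (header written once).
#'
#' @param state A `solver_state` from [run_dynamic_sa()] or
#'   [run_sequential_rttp()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_violation_log <- function(state, path) {
  stopifnot(inherits(state, "solver_state"))
  utils::write.table(state$history, path, sep = ",",
                     row.names = FALSE, col.names = !file.exists(path),
                     append = file.exists(path))
  invisible(path)
}

#' Write per-structure DVH curves as CSV
#'
#' @param x Intensity vector.
#' @param problem A [feasibility_problem()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_dvh_csv <- function(x, problem, path) {
  utils::write.csv(dvh_table(x, problem), path, row.names = FALSE)
  invisible(path)
}
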