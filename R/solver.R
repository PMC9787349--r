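#' String plan for the string-averaging iteration
#'
#' A set of index vectors ("strings") over the blocks `1..p`, with convex
#' weights. A plan is \emph{fit} when every block index appears in at least
#' one string; admissible plans additionally keep every weight at least
#' `delta` and every string length at most `max_len`.
#'
#' @param strings List of integer vectors of block indices.
#' @param weights Positive weights summing to 1; defaults to uniform.
#' @param delta Weight floor in `(0, 1/p)`; defaults (at validation time) to
#'   `min(1/(2p), min(weights))`.
#' @param max_len String length cap, at least `p`; defaults to
#'   `max(p, longest string)`.
#' @return An object of class `string_plan`.
#' @examples
#' string_plan(list(1:3))                      # fully sequential
#' string_plan(list(1L, 2L, 3L))               # fully simultaneous
#' @export
string_plan <- function(strings, weights = NULL, delta = NULL,
                        max_len = NULL) {
  if (!is.list(strings) || length(strings) == 0L) {
    stop("'strings' must be a nonempty list of index vectors", call. = FALSE)
  }
  strings <- lapply(strings, as.integer)
  if (any(vapply(strings, length, integer(1)) == 0L)) {
    stop("strings must be nonempty", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1 / length(strings), length(strings))
  if (length(weights) != length(strings) || any(weights <= 0)) {
    stop("weight error: need one positive weight per string", call. = FALSE)
  }
  structure(list(strings = strings, weights = as.numeric(weights),
                 delta = delta, max_len = max_len),
            class = "string_plan")
}

#' @export
print.string_plan <- function(x, ...) {
  cat(sprintf("<string_plan> %d string(s)\n", length(x$strings)))
  for (i in seq_along(x$strings)) {
    cat(sprintf("  w = %.4g: (%s)\n", x$weights[i],
                paste(x$strings[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Validate a string plan against a problem with p blocks
#'
#' Checks fitness (every block index `1..p` occurs in some string), weight
#' normalization (sum 1 to within 1e-12), the weight floor `delta` and the
#' string length cap `max_len`.
#'
#' @param plan A [string_plan()].
#' @param p Number of blocks.
#' @return The plan, with `delta` and `max_len` defaults filled in;
#'   errors otherwise.
#' @export
validate_string_plan <- function(plan, p) {
  stopifnot(inherits(plan, "string_plan"))
  p <- as.integer(p)
  if (p < 1L) stop("'p' must be at least 1", call. = FALSE)
  idx <- unlist(plan$strings)
  if (any(idx < 1L | idx > p)) {
    stop(sprintf("index error: string entries must lie in 1..%d", p),
         call. = FALSE)
  }
  if (!setequal(unique(idx), seq_len(p))) {
    stop("fitness error: every block index must appear in some string",
         call. = FALSE)
  }
  if (abs(sum(plan$weights) - 1) > 1e-12) {
    stop("weight error: weights must sum to 1", call. = FALSE)
  }
  if (is.null(plan$delta)) plan$delta <- min(1 / (2 * p), min(plan$weights))
  if (plan$delta <= 0 || plan$delta >= 1 / p) {
    stop("weight error: 'delta' must lie in (0, 1/p)", call. = FALSE)
  }
  if (any(plan$weights < plan$delta)) {
    stop("weight error: every weight must be at least 'delta'", call. = FALSE)
  }
  lens <- vapply(plan$strings, length, integer(1))
  if (is.null(plan$max_len)) plan$max_len <- max(p, lens)
  if (plan$max_len < p) {
    stop("length error: 'max_len' must be at least p", call. = FALSE)
  }
  if (any(lens > plan$max_len)) {
    stop("length error: string longer than 'max_len'", call. = FALSE)
  }
  plan
}

# Landweber factor V_l of one block: a step toward A_l x in Q_l.
# Returns x exactly when the block has no PVC or A_l x is already in Q_l.
block_landweber <- function(x, bl, rule = "member") {
  if (is.null(bl$pvc)) return(x)
  if (is.null(bl$gamma)) {
    stop("block has no Landweber step size; call prepare_problem() first",
         call. = FALSE)
  }
  spec <- landweber_spec(bl$gamma, bl$norm_sq)
  landweber_step(x, bl$A, function(v) project_dvc(v, bl$pvc, rule = rule),
                 spec)
}

# Sequential sweep U_l of the block's relaxed half-space projections
# (ascending row order by default, or a supplied permutation).
block_sweep <- function(x, bl, voxel_perm = NULL) {
  A <- bl$A
  eff <- bl$eff_bound
  aa <- bl$row_norm_sq
  lam <- bl$lambda
  upper <- bl$sense == "upper"
  rows <- if (is.null(voxel_perm)) seq_len(bl$m) else voxel_perm
  for (i in rows) {
    a <- A[i, ]
    ax <- sum(a * x)
    if (if (upper) ax > eff[i] else ax < eff[i]) {
      x <- x + lam * (eff[i] - ax) / aa[i] * a
    }
  }
  x
}

#' Apply one block operator
#'
#' The operator \eqn{R_\ell = U_\ell V_\ell} of block `block_index`:
#' first the Landweber-type factor \eqn{V_\ell} (a step toward the block's
#' dose-volume set, skipped for blocks without a PVC), then \eqn{U_\ell},
#' the sequential sweep of relaxed half-space projections over the block's
#' rows (the rightmost factor of the composition acts first). Set
#' `dvc_first = FALSE` to swap the factors.
#'
#' @param x Numeric intensity vector.
#' @param block_index Block index in `1..p`.
#' @param problem A prepared [feasibility_problem()] (see
#'   [prepare_problem()]).
#' @param voxel_perm Optional row permutation for the sweep.
#' @param dvc_first Apply the Landweber factor before the sweep (default).
#' @param rule Dose-volume projection rule, see [project_dvc()].
#' @return Updated intensity vector.
#' @export
block_operator <- function(x, block_index, problem, voxel_perm = NULL,
                           dvc_first = TRUE, rule = "member") {
  stopifnot(inherits(problem, "feasibility_problem"))
  block_index <- as.integer(block_index)
  if (block_index < 1L || block_index > length(problem$blocks)) {
    stop("index error: invalid block index", call. = FALSE)
  }
  bl <- problem$blocks[[block_index]]
  if (dvc_first) {
    x <- block_landweber(x, bl, rule = rule)
    block_sweep(x, bl, voxel_perm)
  } else {
    x <- block_sweep(x, bl, voxel_perm)
    block_landweber(x, bl, rule = rule)
  }
}

#' Apply a string of block operators
#'
#' The composition \eqn{R_{t_q} \circ \cdots \circ R_{t_1}}: the first
#' entry of `t` is applied first.
#'
#' @param x Numeric intensity vector.
#' @param t Integer vector of block indices.
#' @param problem A prepared [feasibility_problem()].
#' @param ... Passed to [block_operator()].
#' @return The string's end point.
#' @export
apply_string <- function(x, t, problem, ...) {
  for (idx in t) x <- block_operator(x, idx, problem, ...)
  x
}

# Kahan-compensated convex combination of the rows of `endpoints`
# (one row per string), so the result is independent of summation order
# to well below 1e-12.
kahan_combine <- function(endpoints, weights) {
  acc <- numeric(ncol(endpoints))
  comp <- numeric(ncol(endpoints))
  for (s in seq_len(nrow(endpoints))) {
    term <- weights[s] * endpoints[s, ] - comp
    tot <- acc + term
    comp <- (tot - acc) - term
    acc <- tot
  }
  acc
}

#' One string-averaging iteration
#'
#' Evaluates every string of the plan independently from the same input and
#' returns the convex combination of the string end points with the plan's
#' weights. String evaluations do not interact, so the result is identical
#' whatever order they are computed in (the combination uses compensated
#' summation).
#'
#' @param x Numeric intensity vector.
#' @param plan A [string_plan()] (validated against the problem).
#' @param problem A prepared [feasibility_problem()].
#' @param ... Passed to [block_operator()].
#' @return The averaged iterate.
#' @export
sa_iterate <- function(x, plan, problem, ...) {
  plan <- validate_string_plan(plan, length(problem$blocks))
  endpoints <- matrix(0, nrow = length(plan$strings), ncol = length(x))
  for (s in seq_along(plan$strings)) {
    endpoints[s, ] <- apply_string(x, plan$strings[[s]], problem, ...)
  }
  if (nrow(endpoints) == 1L) return(endpoints[1L, ])
  kahan_combine(endpoints, plan$weights)
}

#' Attach Landweber step sizes to a problem
#'
#' Computes each PVC block's squared spectral norm and step size
#' \eqn{\gamma_\ell} using [landweber_gamma()]. Blocks that already carry a
#' `gamma` keep it.
#'
#' @param problem A [feasibility_problem()].
#' @param gamma_mode `"midrange"` (\eqn{1/\|A_\ell\|^2}) or `"strict"`
#'   (\eqn{1/(2\|A_\ell\|^2)}).
#' @return The problem with `gamma` and `norm_sq` filled in on every block.
#' @export
prepare_problem <- function(problem, gamma_mode = c("midrange", "strict")) {
  stopifnot(inherits(problem, "feasibility_problem"))
  gamma_mode <- match.arg(gamma_mode)
  problem$blocks <- lapply(problem$blocks, function(bl) {
    if (is.null(bl$norm_sq)) bl$norm_sq <- spectral_norm_sq(bl$A)
    if (is.null(bl$gamma)) {
      bl$gamma <- landweber_gamma(bl$norm_sq, mode = gamma_mode)
    }
    bl
  })
  problem
}

# Largest residual of the hard (effective-bound) constraints at x.
max_hard_residual <- function(x, problem) {
  res <- 0
  for (bl in problem$blocks) {
    v <- as.numeric(bl$A %*% x)
    r <- if (bl$sense == "upper") v - bl$eff_bound else bl$eff_bound - v
    res <- max(res, r, 0)
  }
  res
}

new_solver_state <- function(x, history) {
  # history row 1 is the starting point (cycle 0)
  structure(list(x = x, cycle = nrow(history) - 1L, history = history),
            class = "solver_state")
}

#' @export
print.solver_state <- function(x, ...) {
  cat(sprintf("<solver_state> %d cycle(s), n = %d\n", x$cycle, length(x$x)))
  if (x$cycle > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(
      "  final: total violations %d, max hard residual %.3g\n",
      last$total, last$max_residual))
  }
  invisible(x)
}

cycle_record <- function(cycle, x, problem) {
  rep_ <- count_violations(x, problem)
  data.frame(cycle = cycle,
             hdc_min = rep_$counts[["hdc_min"]],
             hdc_max = rep_$counts[["hdc_max"]],
             dvc_lower = rep_$counts[["dvc_lower"]],
             dvc_upper = rep_$counts[["dvc_upper"]],
             total = rep_$total,
             base_lower = rep_$base_counts[["lower"]],
             base_upper = rep_$base_counts[["upper"]],
             max_residual = max_hard_residual(x, problem))
}

#' Run the dynamic string-averaging CQ iteration
#'
#' Iterates [sa_iterate()], cycling through a schedule of admissible string
#' plans (strings and weights may change from cycle to cycle). When the
#' problem carries the nonnegativity constraint, negative intensities are
#' clamped to zero at the end of each cycle. Stops after `max_cycles`
#' cycles, or earlier when the maximum hard-constraint residual falls below
#' `resid_tol` (if given) or the total violation count reaches zero (if
#' `stop_on_zero`).
#'
#' @param x0 Starting intensity vector.
#' @param plan_schedule A [string_plan()] or list of plans, recycled over
#'   cycles.
#' @param problem A [feasibility_problem()]; step sizes are attached with
#'   [prepare_problem()] if missing.
#' @param max_cycles Cycle cap.
#' @param resid_tol Optional residual stopping tolerance.
#' @param stop_on_zero Stop when no constraint is violated.
#' @param gamma_mode Step-size rule for [prepare_problem()].
#' @param ... Passed to [block_operator()].
#' @return A `solver_state`: final `x`, cycle count and per-cycle history
#'   (violation counts by category and maximum hard residual; cycle 0 is
#'   the starting point).
#' @export
run_dynamic_sa <- function(x0, plan_schedule, problem,
                           max_cycles = 40L, resid_tol = NULL,
                           stop_on_zero = FALSE,
                           gamma_mode = c("midrange", "strict"), ...) {
  if (inherits(plan_schedule, "string_plan")) {
    plan_schedule <- list(plan_schedule)
  }
  if (!is.list(plan_schedule) || length(plan_schedule) == 0L) {
    stop("configuration error: empty plan schedule", call. = FALSE)
  }
  problem <- prepare_problem(problem, match.arg(gamma_mode))
  p <- length(problem$blocks)
  plan_schedule <- lapply(plan_schedule, validate_string_plan, p = p)
  x <- as.numeric(x0)
  history <- cycle_record(0L, x, problem)
  for (k in seq_len(max_cycles)) {
    plan <- plan_schedule[[(k - 1L) %% length(plan_schedule) + 1L]]
    x <- sa_iterate(x, plan, problem, ...)
    if (problem$nonneg) x <- pmax(x, 0)
    history <- rbind(history, cycle_record(k, x, problem))
    last <- history[nrow(history), ]
    if (!is.null(resid_tol) && last$max_residual < resid_tol) break
    if (stop_on_zero && last$total == 0L) break
  }
  new_solver_state(x, history)
}

#' Fully sequential inverse-planning run
#'
#' The fully sequential specialization of the string-averaging iteration
#' with unit weights: each cycle traverses the blocks once without
#' replacement (in the given order, or a seeded random permutation), each
#' block applies its operator \eqn{R_\ell = U_\ell V_\ell} with the row
#' sweep in ascending or seeded random order, and after all projections of
#' the cycle any negative beamlet intensities are set to zero. Runs exactly
#' `n_cycles` cycles unless `stop_on_zero` fires earlier.
#'
#' @param problem A [feasibility_problem()].
#' @param x0 Starting intensity vector; defaults to all ones.
#' @param n_cycles Positive number of cycles (default 40).
#' @param block_order `"asis"` or `"random"`.
#' @param voxel_order `"ascending"` or `"random"`.
#' @param seed Optional integer seed driving both random orders.
#' @param stop_on_zero Stop early when no constraint is violated.
#' @param gamma_mode Step-size rule for [prepare_problem()].
#' @param dvc_first Apply the Landweber factor before the sweep (default).
#' @param rule Dose-volume projection rule, see [project_dvc()].
#' @return A `solver_state` (see [run_dynamic_sa()]).
#' @export
run_sequential_rttp <- function(problem, x0 = NULL, n_cycles = 40L,
                                block_order = c("asis", "random"),
                                voxel_order = c("ascending", "random"),
                                seed = NULL, stop_on_zero = FALSE,
                                gamma_mode = c("midrange", "strict"),
                                dvc_first = TRUE, rule = "member") {
  stopifnot(inherits(problem, "feasibility_problem"))
  block_order <- match.arg(block_order)
  voxel_order <- match.arg(voxel_order)
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) {
    stop("parameter error: 'n_cycles' must be a positive integer",
         call. = FALSE)
  }
  problem <- prepare_problem(problem, match.arg(gamma_mode))
  p <- length(problem$blocks)
  if (is.null(x0)) x0 <- rep(1, problem$n)
  x <- as.numeric(x0)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  history <- cycle_record(0L, x, problem)
  for (k in seq_len(n_cycles)) {
    blocks_k <- if (block_order == "random") sample.int(p) else seq_len(p)
    for (bi in blocks_k) {
      perm <- if (voxel_order == "random") {
        sample.int(problem$blocks[[bi]]$m)
      } else {
        NULL
      }
      x <- block_operator(x, bi, problem, voxel_perm = perm,
                          dvc_first = dvc_first, rule = rule)
    }
    if (problem$nonneg) x <- pmax(x, 0)
    history <- rbind(history, cycle_record(k, x, problem))
    if (stop_on_zero && history$total[nrow(history)] == 0L) break
  }
  new_solver_state(x, history)
}
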