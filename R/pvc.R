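#' Positive part (rectifier)
#'
#' Componentwise `max(0, y)`.
#'
#' @param y Numeric vector.
#' @return Nonnegative numeric vector of the same length.
#' @export
positive_part <- function(y) pmax(0, y)

#' Count strictly positive entries
#'
#' \eqn{\|y^+\|_0}, the number of entries with `y > 0`. The sign test is
#' strict and uses no epsilon: boundary zeros never count.
#'
#' @param y Numeric vector.
#' @return Nonnegative integer.
#' @export
count_positive <- function(y) sum(y > 0)

#' Projection onto a sparsity set
#'
#' Euclidean projection of `y` onto
#' \eqn{\{z : \|z^+\|_0 \le \mathrm{budget}\}}: if at most `budget` entries
#' are positive the vector is unchanged; otherwise the smallest positive
#' entries are zeroed until the budget is met, leaving every other entry
#' untouched. Ties among equal smallest positive values are broken by
#' zeroing the lowest index first, which makes the (generally non-unique)
#' projection deterministic.
#'
#' By default `count_positive(y) - budget` entries are removed, which
#' guarantees the result is a member of the set. `n_remove` overrides the
#' removal count (used by the literal dose-volume projection rule, which
#' floors the possibly fractional excess before removal and can therefore
#' leave one extra positive entry).
#'
#' @param y Numeric vector.
#' @param budget Nonnegative integer, at most `length(y)`.
#' @param n_remove Optional override of how many positive entries to zero.
#' @return Numeric vector of the same length as `y`.
#' @export
project_sparsity_set <- function(y, budget, n_remove = NULL) {
  if (!is.numeric(budget) || length(budget) != 1L || budget < 0) {
    stop("'budget' must be a nonnegative integer", call. = FALSE)
  }
  if (budget > length(y)) {
    stop("'budget' must not exceed length(y)", call. = FALSE)
  }
  npos <- count_positive(y)
  if (is.null(n_remove)) n_remove <- npos - budget
  n_remove <- as.integer(floor(n_remove))
  if (n_remove <= 0L) return(y)
  pos_idx <- which(y > 0)
  # ascending by value, then by index: lowest index zeroed first among ties
  ord <- pos_idx[order(y[pos_idx], pos_idx)]
  y[ord[seq_len(min(n_remove, length(ord)))]] <- 0
  y
}

#' Percentage-violation constraint specification
#'
#' Describes the nonconvex dose-space constraint attached to one block: up
#' to a fraction `alpha` of the block's `m` rows may exceed (sense
#' `"upper"`) or fall short of (sense `"lower"`) the base bound. The integer
#' violation budget is `floor(alpha * m)`.
#'
#' @param alpha Fraction in `[0, 1]` of rows allowed to violate.
#' @param base_bound Numeric vector of base bounds (length `m`), or a scalar
#'   recycled to length `m`.
#' @param sense `"upper"` or `"lower"`.
#' @param m Number of rows in the block; defaults to `length(base_bound)`.
#' @return An object of class `pvc_spec` with a `budget` field.
#' @export
pvc_spec <- function(alpha, base_bound, sense = c("upper", "lower"),
                     m = length(base_bound)) {
  sense <- match.arg(sense)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be a positive integer", call. = FALSE)
  base_bound <- rep_len(as.numeric(base_bound), m)
  budget <- floor(alpha * m)
  structure(
    list(alpha = alpha, base_bound = base_bound, sense = sense, m = m,
         budget = as.integer(budget)),
    class = "pvc_spec"
  )
}

#' @export
print.pvc_spec <- function(x, ...) {
  cat(sprintf("<pvc_spec> sense %s, m = %d, alpha = %g (budget %d)\n",
              x$sense, x$m, x$alpha, x$budget))
  invisible(x)
}

#' Projection onto a dose-volume-constraint set
#'
#' Projects a dose vector `v` onto the nonconvex set of vectors that
#' violate the base bound in at most `floor(alpha * m)` components. The
#' projection shifts into excess (upper: `v - b`) or deficit (lower:
#' `c - v`) coordinates, applies the sparsity-set projection
#' [project_sparsity_set()] there, and shifts back.
#'
#' `rule = "member"` (default) removes enough positive components that the
#' result is always a member of the set. `rule = "literal"` floors the
#' possibly fractional excess `count - alpha*m` before removal, which for
#' fractional `alpha*m` can leave `ceiling(alpha*m)` violations.
#'
#' @param v Numeric dose vector of length `spec$m`.
#' @param spec A [pvc_spec()].
#' @param rule `"member"` or `"literal"`.
#' @return Numeric vector of length `spec$m`.
#' @export
project_dvc <- function(v, spec, rule = c("member", "literal")) {
  stopifnot(inherits(spec, "pvc_spec"))
  rule <- match.arg(rule)
  if (length(v) != spec$m) {
    stop("shape error: length(v) must equal spec$m", call. = FALSE)
  }
  y <- if (spec$sense == "upper") v - spec$base_bound else spec$base_bound - v
  n_remove <- if (rule == "literal") {
    floor(count_positive(y) - spec$alpha * spec$m)
  } else {
    NULL
  }
  py <- project_sparsity_set(y, spec$budget, n_remove = n_remove)
  if (identical(py, y)) return(v)  # identity: no shift round-off
  out <- v
  changed <- py != y               # zeroed components land on the base bound
  out[changed] <- spec$base_bound[changed]
  out
}

#' Block of linear constraints with optional percentage-violation relaxation
#'
#' One structure's block: the rows of the dose-influence matrix that fall in
#' the structure, a base bound per row, the inequality sense, the
#' per-row relaxation `beta` (so the hard, effective bound is
#' `(1 +/- beta) * bound`), an optional violation fraction `alpha` (absent
#' means a plain hard-bound block), the half-space relaxation `lambda` and
#' an optional Landweber step `gamma` (computed from the block norm when
#' first needed).
#'
#' @param A Numeric matrix (rows = block constraints), or `NULL` for a
#'   parameter-only block (prescription bookkeeping before a matrix is
#'   attached).
#' @param bound Scalar or length-`nrow(A)` base bound vector.
#' @param sense `"upper"` or `"lower"`.
#' @param beta Relaxation fraction in `[0, 1)`.
#' @param alpha Violation fraction in `[0, 1]`, or `NA` for no PVC.
#' @param lambda Half-space relaxation in (0, 2).
#' @param gamma Optional Landweber step size.
#' @param name Optional structure label.
#' @return An object of class `block_constraint`.
#' @export
block_constraint <- function(A = NULL, bound, sense = c("upper", "lower"),
                             beta = 0, alpha = NA_real_, lambda = 1,
                             gamma = NULL, name = NULL) {
  sense <- match.arg(sense)
  if (!is.numeric(beta) || beta < 0 || beta >= 1) {
    stop("'beta' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.na(alpha) && (alpha < 0 || alpha > 1)) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(lambda) || lambda <= 0 || lambda >= 2) {
    stop("'lambda' must lie in the open interval (0, 2)", call. = FALSE)
  }
  m <- if (!is.null(A)) nrow(A) else length(bound)
  bound <- rep_len(as.numeric(bound), m)
  bl <- structure(
    list(A = A, bound = bound, sense = sense, beta = beta, alpha = alpha,
         lambda = lambda, gamma = gamma, name = name,
         m = as.integer(m),
         eff_bound = if (sense == "upper") (1 + beta) * bound
                     else (1 - beta) * bound,
         row_norm_sq = if (!is.null(A)) rowSums(as.matrix(A)^2) else NULL),
    class = "block_constraint"
  )
  bl
}

#' @export
print.block_constraint <- function(x, ...) {
  cat(sprintf(
    "<block_constraint> %s%s, m = %d, base bound %g, beta %g%s, lambda %g\n",
    if (is.null(x$name)) "" else paste0(x$name, ", "),
    x$sense, x$m, x$bound[1], x$beta,
    if (is.na(x$alpha)) ", no PVC" else sprintf(", alpha %g", x$alpha),
    x$lambda))
  invisible(x)
}

#' Translate a block linear feasibility problem with PVCs
#'
#' Assembles a [feasibility_problem()] from a list of
#' [block_constraint()]s: each block contributes its family of relaxed
#' half-space rows (effective bound `(1 +/- beta) * bound`) and, when
#' `alpha` is set, the nonconvex sparsity-set constraint bounding the number
#' of rows that may violate the base bound. Blocks without `alpha` revert to
#' plain hard-bound constraints.
#'
#' @param blocks List of [block_constraint()]s, all with matrices attached
#'   and equal column counts.
#' @param nonneg Enforce componentwise nonnegativity of the intensity
#'   vector (clamped at the end of each solver cycle).
#' @return A [feasibility_problem()].
#' @export
translate_lfp_pvc <- function(blocks, nonneg = TRUE) {
  feasibility_problem(blocks, nonneg = nonneg)
}

#' Feasibility problem over intensity vectors
#'
#' An ordered collection of [block_constraint()]s sharing an unknown
#' intensity vector of length `n`, plus a nonnegativity flag. Each block
#' with a violation fraction `alpha` carries its [pvc_spec()].
#'
#' @param blocks List of [block_constraint()]s with matrices attached.
#' @param nonneg Logical; clamp negative intensities at cycle end.
#' @return An object of class `feasibility_problem`.
#' @export
feasibility_problem <- function(blocks, nonneg = TRUE) {
  if (!is.list(blocks) || length(blocks) == 0L) {
    stop("'blocks' must be a nonempty list of block_constraint", call. = FALSE)
  }
  if (!all(vapply(blocks, inherits, logical(1), "block_constraint"))) {
    stop("every element of 'blocks' must be a block_constraint", call. = FALSE)
  }
  ncols <- vapply(blocks, function(b) {
    if (is.null(b$A)) stop("block has no matrix attached", call. = FALSE)
    ncol(b$A)
  }, integer(1))
  if (length(unique(ncols)) != 1L) {
    stop("all blocks must share the same column count", call. = FALSE)
  }
  blocks <- lapply(blocks, function(b) {
    if (!is.na(b$alpha)) {
      b$pvc <- pvc_spec(b$alpha, b$bound, sense = b$sense, m = b$m)
    } else {
      b$pvc <- NULL
    }
    b
  })
  structure(list(blocks = blocks, n = ncols[[1]], nonneg = nonneg),
            class = "feasibility_problem")
}

#' @export
print.feasibility_problem <- function(x, ...) {
  cat(sprintf("<feasibility_problem> %d blocks, n = %d, nonneg = %s\n",
              length(x$blocks), x$n, x$nonneg))
  for (b in x$blocks) print(b)
  invisible(x)
}

#' Dose prescription
#'
#' Structure-level dose rules: per structure at most one maximum hard dose
#' constraint (`dmax`), at most one minimum (`dmin`), and any number of
#' dose-volume constraints, each a list with elements `V` (volume percent),
#' `dose` and `type` (`"upper"` for a D_V% <= dose rule on an avoidance
#' structure, `"lower"` for D_V% >= dose on a target).
#'
#' @param ... Named structure rules; each a list with optional `dmax`,
#'   `dmin` and `dvc` (list of DVC entries).
#' @return An object of class `prescription`.
#' @examples
#' prescription(
#'   avoidance_a = list(dmax = 25, dvc = list(list(V = 10, dose = 20,
#'                                                 type = "upper"))))
#' @export
prescription <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && is.null(names(rules)) && is.list(rules[[1]]) &&
      !is.null(names(rules[[1]]))) {
    rules <- rules[[1]]
  }
  if (is.null(names(rules)) || any(names(rules) == "")) {
    stop("every structure rule must be named", call. = FALSE)
  }
  for (nm in names(rules)) {
    r <- rules[[nm]]
    bad <- setdiff(names(r), c("dmax", "dmin", "dvc"))
    if (length(bad)) {
      stop(sprintf("prescription error: unknown field '%s' in structure '%s'",
                   bad[1], nm), call. = FALSE)
    }
    for (d in r$dvc) {
      if (!all(c("V", "dose", "type") %in% names(d)) ||
          !d$type %in% c("upper", "lower")) {
        stop(sprintf(
          "prescription error: DVC in '%s' needs V, dose and type", nm),
          call. = FALSE)
      }
      if (d$V <= 0 || d$V > 100) {
        stop("prescription error: DVC volume percent must be in (0, 100]",
             call. = FALSE)
      }
    }
  }
  structure(rules, class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat("<prescription>\n")
  for (nm in names(x)) {
    r <- x[[nm]]
    parts <- c(
      if (!is.null(r$dmax)) sprintf("Dmax = %g", r$dmax),
      if (!is.null(r$dmin)) sprintf("Dmin = %g", r$dmin),
      vapply(r$dvc, function(d) {
        sprintf("D%g%% %s %g", d$V, if (d$type == "upper") "<=" else ">=",
                d$dose)
      }, character(1)))
    cat(sprintf("  %s: %s\n", nm, paste(parts, collapse = ", ")))
  }
  invisible(x)
}

#' Convert a prescription into constraint blocks
#'
#' Maps structure-level dose rules onto [block_constraint()]s. A DVC
#' `D_V% <= dose` with hard bound `Dmax` becomes an upper block with base
#' bound `dose`, relaxation `beta` solved from `(1 + beta) * dose = Dmax`,
#' and violation fraction `alpha = V / 100`. A lower DVC `D_V% >= dose` with
#' hard bound `Dmin` becomes a lower block with `(1 - beta) * dose = Dmin`
#' and `alpha = 1 - V / 100` (the fraction of the structure allowed below
#' the DVC dose). Hard bounds without a DVC become plain blocks with
#' `beta = 0` and no PVC. A structure carrying both senses contributes two
#' blocks over the same rows.
#'
#' @param presc A [prescription()].
#' @param dim_obj Optional [dose_influence()]; when supplied, each block
#'   gets its dense submatrix of rows.
#' @param lambda Half-space relaxation applied to every block.
#' @return List of [block_constraint()]s, DVC-bearing blocks first within
#'   each structure.
#' @export
prescription_to_blocks <- function(presc, dim_obj = NULL, lambda = 1) {
  stopifnot(inherits(presc, "prescription"))
  blocks <- list()
  for (nm in names(presc)) {
    r <- presc[[nm]]
    dvcs <- r$dvc
    seen_upper <- FALSE
    seen_lower <- FALSE
    A <- if (!is.null(dim_obj)) structure_matrix(dim_obj, nm) else NULL
    for (d in dvcs) {
      if (d$type == "upper") {
        if (is.null(r$dmax)) {
          beta <- 0
        } else {
          if (d$dose > r$dmax) {
            stop(sprintf(
              "prescription error: upper DVC dose %g exceeds Dmax %g in '%s'",
              d$dose, r$dmax, nm), call. = FALSE)
          }
          beta <- r$dmax / d$dose - 1
        }
        blocks[[length(blocks) + 1L]] <- block_constraint(
          A = A, bound = d$dose, sense = "upper", beta = beta,
          alpha = d$V / 100, lambda = lambda, name = nm)
        seen_upper <- TRUE
      } else {
        if (is.null(r$dmin)) {
          beta <- 0
        } else {
          if (d$dose < r$dmin) {
            stop(sprintf(
              "prescription error: lower DVC dose %g is below Dmin %g in '%s'",
              d$dose, r$dmin, nm), call. = FALSE)
          }
          beta <- 1 - r$dmin / d$dose
        }
        blocks[[length(blocks) + 1L]] <- block_constraint(
          A = A, bound = d$dose, sense = "lower", beta = beta,
          alpha = 1 - d$V / 100, lambda = lambda, name = nm)
        seen_lower <- TRUE
      }
    }
    if (!is.null(r$dmin) && !seen_lower) {
      blocks[[length(blocks) + 1L]] <- block_constraint(
        A = A, bound = r$dmin, sense = "lower", beta = 0, lambda = lambda,
        name = nm)
    }
    if (!is.null(r$dmax) && !seen_upper) {
      blocks[[length(blocks) + 1L]] <- block_constraint(
        A = A, bound = r$dmax, sense = "upper", beta = 0, lambda = lambda,
        name = nm)
    }
  }
  blocks
}
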