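#' Dose delivered to one structure
#'
#' The dose vector \eqn{A_\ell x} of a block.
#'
#' @param x Intensity vector.
#' @param block A [block_constraint()] with a matrix attached.
#' @return Numeric dose vector of length `block$m`.
#' @export
structure_dose <- function(x, block) {
  stopifnot(inherits(block, "block_constraint"))
  if (is.null(block$A)) stop("block has no matrix attached", call. = FALSE)
  if (ncol(block$A) != length(x)) {
    stop("shape error: length(x) must equal ncol(block$A)", call. = FALSE)
  }
  as.numeric(block$A %*% x)
}

#' Cumulative dose-volume histogram
#'
#' For each threshold dose `d`, the percentage of the structure receiving
#' at least `d`: `100 * #{i : dose_i >= d} / m`. The curve is
#' non-increasing and starts at 100 for thresholds at or below the minimum
#' dose.
#'
#' @param dose Nonempty numeric dose vector.
#' @param thresholds Increasing dose thresholds; defaults to 512 evenly
#'   spaced points from 0 to 1.05 times the maximum dose.
#' @return An object of class `dvh_curve` with fields `thresholds` and
#'   `volume_fraction`; `as.data.frame()` gives a two-column table.
#' @export
compute_dvh <- function(dose, thresholds = NULL) {
  if (length(dose) == 0L) {
    stop("evaluation error: empty structure", call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- seq(0, 1.05 * max(dose, 0), length.out = 512L)
  }
  if (is.unsorted(thresholds)) {
    stop("'thresholds' must be increasing", call. = FALSE)
  }
  # count of dose >= d via the sorted-dose complement
  sorted <- sort(dose)
  below <- findInterval(thresholds, sorted, left.open = TRUE)
  vf <- 100 * (length(dose) - below) / length(dose)
  structure(list(thresholds = as.numeric(thresholds), volume_fraction = vf),
            class = "dvh_curve")
}

#' @export
as.data.frame.dvh_curve <- function(x, ...) {
  data.frame(threshold = x$thresholds, volume_fraction = x$volume_fraction)
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d thresholds on [%g, %g]\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds)))
  invisible(x)
}

#' Dose at volume (D_V%)
#'
#' The dose received by at least `V_percent` of the structure, by the
#' order-statistic convention: the `ceiling(V * m / 100)`-th largest dose
#' (no interpolation), so `dose_at_volume(dose, 100)` is the minimum dose.
#'
#' @param dose Nonempty numeric dose vector.
#' @param V_percent Volume percentage in (0, 100].
#' @return Scalar dose.
#' @export
dose_at_volume <- function(dose, V_percent) {
  if (!is.numeric(V_percent) || length(V_percent) != 1L ||
      V_percent <= 0 || V_percent > 100) {
    stop("parameter error: 'V_percent' must lie in (0, 100]", call. = FALSE)
  }
  if (length(dose) == 0L) {
    stop("evaluation error: empty structure", call. = FALSE)
  }
  k <- ceiling(V_percent * length(dose) / 100)
  sort(dose, decreasing = TRUE)[k]
}

#' Count constraint violations
#'
#' Per-category violation counts of an intensity vector against an
#' assembled problem. Hard-dose categories (`hdc_max`, `hdc_min`) count
#' voxels whose dose exceeds (falls below) the effective, relaxed bound
#' `(1 +/- beta) * base` — which equals the prescribed Dmax/Dmin when the
#' blocks come from [prescription_to_blocks()]. DVC categories
#' (`dvc_upper`, `dvc_lower`) count, per PVC block, the excess of
#' base-bound violations over the allowed budget `floor(alpha * m)`,
#' summed by sense. Raw beyond-base-bound counts are reported alongside.
#'
#' Comparisons use an absolute slack of `tol` on the residual, so doses
#' landing on a bounding hyperplane to rounding error do not count.
#'
#' @param x Intensity vector.
#' @param problem A [feasibility_problem()].
#' @param tol Absolute residual tolerance (default 1e-9).
#' @return An object of class `violation_report`: `counts` (named integer
#'   vector over the four categories), `total` (their sum), `pct`
#'   (percentages of each category's voxel population), `base_counts`
#'   (raw beyond-base counts by sense) and a per-block `detail` data frame.
#' @export
count_violations <- function(x, problem, tol = 1e-9) {
  stopifnot(inherits(problem, "feasibility_problem"))
  detail <- data.frame(block = integer(), name = character(),
                       sense = character(), m = integer(),
                       hdc = integer(), beyond_base = integer(),
                       budget = integer(), dvc_excess = integer())
  for (bi in seq_along(problem$blocks)) {
    bl <- problem$blocks[[bi]]
    v <- structure_dose(x, bl)
    if (bl$sense == "upper") {
      hdc <- sum(v > bl$eff_bound + tol)
      beyond <- sum(v > bl$bound + tol)
    } else {
      hdc <- sum(v < bl$eff_bound - tol)
      beyond <- sum(v < bl$bound - tol)
    }
    budget <- if (is.null(bl$pvc)) NA_integer_ else bl$pvc$budget
    excess <- if (is.null(bl$pvc)) NA_integer_ else max(0L, beyond - budget)
    detail <- rbind(detail, data.frame(
      block = bi, name = if (is.null(bl$name)) NA_character_ else bl$name,
      sense = bl$sense, m = bl$m, hdc = hdc, beyond_base = beyond,
      budget = budget, dvc_excess = excess))
  }
  upper <- detail$sense == "upper"
  pvc <- !is.na(detail$budget)
  counts <- c(
    hdc_min = sum(detail$hdc[!upper]),
    hdc_max = sum(detail$hdc[upper]),
    dvc_lower = sum(detail$dvc_excess[pvc & !upper]),
    dvc_upper = sum(detail$dvc_excess[pvc & upper]))
  pop <- c(
    hdc_min = sum(detail$m[!upper]),
    hdc_max = sum(detail$m[upper]),
    dvc_lower = sum(detail$m[pvc & !upper]),
    dvc_upper = sum(detail$m[pvc & upper]))
  pct <- ifelse(pop > 0, 100 * counts / pop, 0)
  structure(
    list(counts = counts, total = sum(counts), pct = pct,
         base_counts = c(lower = sum(detail$beyond_base[!upper]),
                         upper = sum(detail$beyond_base[upper])),
         detail = detail),
    class = "violation_report"
  )
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf(
    "<violation_report> total %d (hdc_min %d, hdc_max %d, dvc_lower %d, dvc_upper %d)\n",
    x$total, x$counts[["hdc_min"]], x$counts[["hdc_max"]],
    x$counts[["dvc_lower"]], x$counts[["dvc_upper"]]))
  invisible(x)
}

#' Per-structure DVH table for a solved plan
#'
#' Computes each block's dose and DVH on a shared threshold axis.
#'
#' @param x Intensity vector.
#' @param problem A [feasibility_problem()].
#' @param n_thresholds Number of threshold points.
#' @return Data frame with columns `structure`, `sense`, `threshold`,
#'   `volume_fraction`.
#' @export
dvh_table <- function(x, problem, n_thresholds = 512L) {
  stopifnot(inherits(problem, "feasibility_problem"))
  doses <- lapply(problem$blocks, function(bl) structure_dose(x, bl))
  thr <- seq(0, 1.05 * max(unlist(doses), 0), length.out = n_thresholds)
  out <- lapply(seq_along(problem$blocks), function(bi) {
    bl <- problem$blocks[[bi]]
    curve <- compute_dvh(doses[[bi]], thr)
    data.frame(
      structure = if (is.null(bl$name)) paste0("block", bi) else bl$name,
      sense = bl$sense, threshold = thr,
      volume_fraction = curve$volume_fraction)
  })
  do.call(rbind, out)
}
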