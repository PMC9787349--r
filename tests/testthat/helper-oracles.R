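# Independent oracles and small fixtures, built in code at test time.

# Exhaustive nearest-point oracle for the sparsity set
# {z : count(z > 0) <= budget}: enumerate every subset of positive entries
# allowed to stay positive; the rest are clipped to <= 0 at distance
# max(0, y_i). Returns the minimal squared distance.
oracle_sparsity_dist2 <- function(y, budget) {
  pos <- which(y > 0)
  if (length(pos) <= budget) return(0)
  best <- Inf
  keep_sizes <- 0:budget
  for (k in keep_sizes) {
    subsets <- if (k == 0) list(integer(0)) else
      utils::combn(pos, k, simplify = FALSE)
    for (S in subsets) {
      drop <- setdiff(pos, S)
      d2 <- sum(y[drop]^2)
      if (d2 < best) best <- d2
    }
  }
  best
}

# Exhaustive nearest-point oracle for the dose-volume set: vectors allowed
# to exceed the base bound (sense upper) / fall short (sense lower) in at
# most `budget` components.
oracle_dvc_dist2 <- function(v, base, sense, budget) {
  y <- if (sense == "upper") v - base else base - v
  oracle_sparsity_dist2(y, budget)
}

dvc_members <- function(z, base, sense, budget) {
  y <- if (sense == "upper") z - base else base - z
  sum(y > 0) <= budget
}

# Nearest-point projection onto {z : <a, z> <= b} by constrained
# optimization (independent of the closed-form implementation).
oracle_halfspace_qp <- function(x, a, b) {
  if (sum(a * x) <= b) return(x)
  z0 <- x - (max(0, sum(a * x) - b) / sum(a * a) + 1e-3) * a
  fit <- stats::constrOptim(
    theta = z0,
    f = function(z) sum((z - x)^2),
    grad = function(z) 2 * (z - x),
    ui = matrix(-a, nrow = 1), ci = -b,
    outer.eps = 1e-12)
  fit$par
}

# A small dense feasibility problem with one PVC block and one plain
# block, deterministic for a given seed.
toy_problem <- function(seed = 1, n = 6, m = 5, nonneg = TRUE) {
  set.seed(seed)
  A1 <- matrix(abs(rnorm(m * n)), m, n)
  A2 <- matrix(abs(rnorm(m * n)), m, n)
  blocks <- list(
    block_constraint(A1, bound = 2, sense = "upper", beta = 0.2,
                     alpha = 0.4, name = "avoid"),
    block_constraint(A2, bound = 1, sense = "lower", beta = 0,
                     name = "target"))
  prepare_problem(translate_lfp_pvc(blocks, nonneg = nonneg))
}

# A consistent convex LFP (upper bounds only, no PVC) with a known
# feasible point.
consistent_lfp <- function(seed, rows = 50, n = 10, blocks = 2) {
  set.seed(seed)
  A <- matrix(rnorm(rows * n), rows, n)
  w <- abs(rnorm(n))
  slack <- c(rep(0, 5), abs(rnorm(rows - 5)))  # a few tight rows
  b <- as.numeric(A %*% w) + slack
  idx <- split(seq_len(rows), rep(seq_len(blocks), length.out = rows))
  bls <- lapply(idx, function(i) {
    block_constraint(A[i, , drop = FALSE], bound = b[i], sense = "upper")
  })
  list(problem = translate_lfp_pvc(unname(bls), nonneg = FALSE),
       feasible = w)
}
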