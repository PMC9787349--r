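#' Half-space constraint
#'
#' A single linear inequality \eqn{\langle a, x\rangle \le (1+\beta)b}
#' (sense \code{"upper"}) or \eqn{\langle a, x\rangle \ge (1-\beta)c}
#' (sense \code{"lower"}). The factor \eqn{\beta \in [0,1)} is the
#' percentage-violation relaxation applied to the base bound; the relaxed
#' value is called the \emph{effective bound}.
#'
#' @param coefficients Numeric vector of inequality coefficients (not all
#'   zero).
#' @param bound Scalar base bound (the unrelaxed \eqn{b} or \eqn{c}).
#' @param sense `"upper"` or `"lower"`.
#' @param beta Relaxation fraction in `[0, 1)`; 0 means no relaxation.
#' @return An object of class `halfspace_constraint`.
#' @examples
#' h <- halfspace_constraint(c(1, 0), bound = 0, sense = "upper")
#' project_halfspace(c(2, 3), h)
#' @export
halfspace_constraint <- function(coefficients, bound,
                                 sense = c("upper", "lower"), beta = 0) {
  sense <- match.arg(sense)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) == 0L || all(coefficients == 0)) {
    stop("invalid constraint: coefficient vector is zero", call. = FALSE)
  }
  if (!is.numeric(bound) || length(bound) != 1L || !is.finite(bound)) {
    stop("'bound' must be a finite scalar", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta >= 1) {
    stop("'beta' must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(coefficients = coefficients, bound = bound, sense = sense,
         beta = beta),
    class = "halfspace_constraint"
  )
}

#' @export
print.halfspace_constraint <- function(x, ...) {
  op <- if (x$sense == "upper") "<=" else ">="
  cat(sprintf("<halfspace_constraint> n = %d, <a, x> %s %g (base %g, beta %g)\n",
              length(x$coefficients), op, effective_bound(x), x$bound,
              x$beta))
  invisible(x)
}

#' Effective (relaxed) bound of a half-space constraint
#'
#' \eqn{(1+\beta)b} for an upper constraint, \eqn{(1-\beta)c} for a lower
#' one.
#'
#' @param h A [halfspace_constraint()].
#' @return Scalar effective bound.
#' @export
effective_bound <- function(h) {
  stopifnot(inherits(h, "halfspace_constraint"))
  if (h$sense == "upper") (1 + h$beta) * h$bound else (1 - h$beta) * h$bound
}

#' Relaxed projection onto a half-space
#'
#' Projects `x` onto the half-space defined by `h`, relaxed by
#' `lam` \eqn{\in (0,2)}. If `x` already satisfies the effective bound it is
#' returned unchanged; otherwise the point moves along the constraint normal
#' by `lam` times the exact projection step, so `lam = 1` lands on the
#' bounding hyperplane and `lam = 2` reflects through it.
#'
#' @param x Numeric vector, same length as `h$coefficients`.
#' @param h A [halfspace_constraint()].
#' @param lam Relaxation parameter in the open interval (0, 2).
#' @return Numeric vector of the same length as `x`.
#' @export
project_halfspace <- function(x, h, lam = 1) {
  stopifnot(inherits(h, "halfspace_constraint"))
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0 || lam >= 2) {
    stop("'lam' must lie in the open interval (0, 2)", call. = FALSE)
  }
  a <- h$coefficients
  if (length(x) != length(a)) {
    stop("length(x) must equal length(h$coefficients)", call. = FALSE)
  }
  eff <- effective_bound(h)
  ax <- sum(a * x)
  violated <- if (h$sense == "upper") ax > eff else ax < eff
  if (!violated) return(x)
  x + lam * (eff - ax) / sum(a * a) * a
}

#' Squared spectral norm of a matrix
#'
#' Largest eigenvalue of \eqn{A^T A}, i.e. the squared largest singular
#' value \eqn{\|A\|^2}, computed by power iteration with a deterministic
#' all-ones start vector. Used to bound the Landweber step size
#' \eqn{\gamma \in (0, 1/\|A\|^2]}.
#'
#' @param A Numeric matrix (base or `Matrix`), not identically zero.
#' @param tol Relative convergence tolerance on the Rayleigh quotient.
#' @param max_iter Iteration cap.
#' @return Positive scalar, \eqn{\|A\|^2}.
#' @export
spectral_norm_sq <- function(A, tol = 1e-8, max_iter = 10000L) {
  if (is.null(dim(A))) A <- matrix(as.numeric(A), nrow = 1L)
  nrm <- function(v) sqrt(sum(v * v))
  v <- rep(1, ncol(A))
  w <- as.numeric(A %*% v)
  if (sum(w * w) == 0 && all(A == 0)) {
    stop("degenerate operator: matrix is identically zero", call. = FALSE)
  }
  lam_old <- 0
  for (it in seq_len(max_iter)) {
    u <- as.numeric(Matrix::crossprod(A, A %*% v)) # A^T A v
    nu <- nrm(u)
    if (nu == 0) {
      # start vector lies in the null space; perturb deterministically
      v <- v + seq_along(v) / length(v)
      next
    }
    lam <- sum(v * u) / sum(v * v)
    v <- u / nu
    if (abs(lam - lam_old) <= tol * max(lam, .Machine$double.eps)) {
      return(lam)
    }
    lam_old <- lam
  }
  lam_old
}

#' Landweber step specification
#'
#' Holds the step size \eqn{\gamma} and squared operator norm
#' \eqn{L = \|A\|^2} of a Landweber-type operator
#' \eqn{V = \mathrm{Id} - \gamma A^T(\mathrm{Id} - T)A}. The theory asks for
#' \eqn{\gamma \in (0, 1/L)}; `gamma = 1/L` (the closed endpoint) is
#' additionally accepted because it is the customary practical choice.
#'
#' @param gamma Positive step size, at most `1/norm_sq`.
#' @param norm_sq Positive squared operator norm \eqn{\|A\|^2}.
#' @return An object of class `landweber_spec`.
#' @seealso [landweber_gamma()] for the two packaged step-size rules.
#' @export
landweber_spec <- function(gamma, norm_sq) {
  if (!is.numeric(norm_sq) || length(norm_sq) != 1L || norm_sq <= 0) {
    stop("'norm_sq' must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 ||
      gamma > 1 / norm_sq + 1e-15 / norm_sq) {
    stop("'gamma' must lie in (0, 1/norm_sq]", call. = FALSE)
  }
  structure(list(gamma = gamma, norm_sq = norm_sq),
            class = "landweber_spec")
}

#' Landweber step sizes
#'
#' Two packaged rules for the step \eqn{\gamma} given \eqn{L = \|A\|^2}:
#' `"midrange"` returns \eqn{1/L} (the customary practical value, used by
#' the packaged default run) and `"strict"` returns \eqn{1/(2L)}, the
#' midpoint of the open interval \eqn{(0, 1/L)} that the convergence theory
#' requires.
#'
#' @param norm_sq Positive scalar \eqn{\|A\|^2}.
#' @param mode `"midrange"` or `"strict"`.
#' @return Positive scalar step size.
#' @export
landweber_gamma <- function(norm_sq, mode = c("midrange", "strict")) {
  mode <- match.arg(mode)
  if (mode == "midrange") 1 / norm_sq else 1 / (2 * norm_sq)
}

#' One Landweber-type step
#'
#' Computes \eqn{x - \gamma A^T (Ax - P_Q(Ax))} where `q_projector`
#' implements \eqn{P_Q} in the image (dose) space. When \eqn{Ax} is a fixed
#' point of `q_projector` the input is returned exactly unchanged; the fixed
#' points of the step are precisely the preimages under `A` of the fixed
#' points of \eqn{P_Q}.
#'
#' @param x Numeric vector of length `ncol(A_block)`.
#' @param A_block Numeric matrix (base or `Matrix`).
#' @param q_projector Function mapping length-`nrow(A_block)` vectors to
#'   vectors of the same length.
#' @param spec A [landweber_spec()].
#' @return Numeric vector of the same length as `x`.
#' @export
landweber_step <- function(x, A_block, q_projector, spec) {
  stopifnot(inherits(spec, "landweber_spec"))
  if (is.null(dim(A_block))) A_block <- matrix(as.numeric(A_block), nrow = 1L)
  if (ncol(A_block) != length(x)) {
    stop("shape error: ncol(A_block) must equal length(x)", call. = FALSE)
  }
  v <- as.numeric(A_block %*% x)
  pv <- q_projector(v)
  if (length(pv) != length(v)) {
    stop("shape error: q_projector changed the vector length", call. = FALSE)
  }
  resid <- v - pv
  if (all(resid == 0)) return(x)
  x - spec$gamma * as.numeric(Matrix::crossprod(A_block, resid))
}
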