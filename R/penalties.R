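#' Penalty specifications for proximal regularization
#'
#' Constructs a penalty specification used by every proximal operator, the
#' optimizer, and the linear/network fitting functions. Twelve penalties are
#' supported: the power family \eqn{L_q} for
#' \eqn{q \in \{0, 1/2, 2/3, 1, 4/3, 3/2, 2, 3, 4, \infty\}} plus the smoothly
#' clipped absolute deviation (SCAD) and the minimax concave penalty (MCP).
#'
#' For the separable power penalties the regularizer is
#' \eqn{R(w) = \sum_j |w_j|^q} (number of nonzeros for \eqn{q = 0}, the maximum
#' absolute value for \eqn{q = \infty}) and the penalty term is
#' \eqn{\lambda R(w)}. SCAD and MCP carry \eqn{\lambda} inside their usual
#' piecewise definitions, with shape parameters `scad_a` (> 2) and `mcp_gamma`
#' (> 1).
#'
#' All proximal operators in this package use the canonical
#' \eqn{\frac{1}{2}}-quadratic convention
#' \eqn{\mathrm{prox}_f(z) = \arg\min_x f(x) + \frac{1}{2}(x - z)^2}.
#'
#' @param kind One of `"l0"`, `"l1/2"`, `"l2/3"`, `"l1"`, `"l4/3"`, `"l3/2"`,
#'   `"l2"`, `"l3"`, `"l4"`, `"linf"`, `"scad"`, `"mcp"` (case-insensitive).
#' @param lambda Non-negative penalty strength \eqn{\lambda}. `lambda = 0`
#'   makes every proximal operator the identity.
#' @param scad_a SCAD shape parameter, must exceed 2. Default 3.7.
#' @param mcp_gamma MCP shape parameter, must exceed 1. Default 3.0.
#' @return An object of class `"penalty_spec"`.
#' @examples
#' sp <- penalty_spec("l1", lambda = 1)
#' penalty_value(sp, c(1, -2, 0))
#' prox_scalar(sp, 3)
#' @export
penalty_spec <- function(kind, lambda, scad_a = 3.7, mcp_gamma = 3.0) {
  kind <- match.arg(tolower(kind), penalty_kinds())
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("`lambda` must be a single finite non-negative number")
  if (!is.numeric(scad_a) || length(scad_a) != 1L || !is.finite(scad_a) || scad_a <= 2)
    stop("`scad_a` must be a single finite number > 2")
  if (!is.numeric(mcp_gamma) || length(mcp_gamma) != 1L || !is.finite(mcp_gamma) || mcp_gamma <= 1)
    stop("`mcp_gamma` must be a single finite number > 1")
  structure(
    list(kind = kind, lambda = as.numeric(lambda),
         scad_a = as.numeric(scad_a), mcp_gamma = as.numeric(mcp_gamma)),
    class = "penalty_spec"
  )
}

#' Canonical penalty names
#'
#' @return Character vector of the twelve canonical penalty names.
#' @export
penalty_kinds <- function() {
  c("l0", "l1/2", "l2/3", "l1", "l4/3", "l3/2", "l2", "l3", "l4",
    "linf", "scad", "mcp")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat("Penalty: ", x$kind, "  lambda = ", format(x$lambda), sep = "")
  if (x$kind == "scad") cat("  (a = ", format(x$scad_a), ")", sep = "")
  if (x$kind == "mcp") cat("  (gamma = ", format(x$mcp_gamma), ")", sep = "")
  cat("\n")
  invisible(x)
}

# kinds whose prox can return exact zeros for nonzero input
thresholding_kinds <- function() c("l0", "l1/2", "l2/3", "l1", "scad", "mcp")
# convex members (prox is firmly nonexpansive)
convex_kinds <- function() c("l1", "l4/3", "l3/2", "l2", "l3", "l4", "linf")

check_spec <- function(spec) {
  if (!inherits(spec, "penalty_spec")) stop("`spec` must be a penalty_spec")
  spec
}

# SCAD penalty value p_lambda(x), elementwise (lambda embedded)
scad_pen <- function(x, lam, a) {
  ax <- abs(x)
  out <- ifelse(ax <= lam, lam * ax,
         ifelse(ax <= a * lam,
                (2 * a * lam * ax - ax^2 - lam^2) / (2 * (a - 1)),
                lam^2 * (a + 1) / 2))
  out
}

# MCP penalty value, elementwise (lambda embedded)
mcp_pen <- function(x, lam, g) {
  ax <- abs(x)
  ifelse(ax <= g * lam, lam * ax - ax^2 / (2 * g), g * lam^2 / 2)
}

#' Penalty term value
#'
#' Evaluates the full penalty term of the training objective,
#' \eqn{\lambda R(w)} for the power family (`l0` counts nonzero entries,
#' `linf` takes the maximum absolute entry) and the standard piecewise SCAD /
#' MCP penalties summed over entries.
#'
#' @param spec A [penalty_spec()].
#' @param w Numeric vector of (finite) weights.
#' @return A single non-negative number.
#' @export
penalty_value <- function(spec, w) {
  check_spec(spec)
  if (!is.numeric(w)) stop("`w` must be numeric")
  if (length(w) && any(!is.finite(w))) stop("non-finite values in `w`")
  if (length(w) == 0L) return(0)
  lam <- spec$lambda
  switch(spec$kind,
    "l0"   = lam * sum(w != 0),
    "l1/2" = lam * sum(abs(w)^0.5),
    "l2/3" = lam * sum(abs(w)^(2 / 3)),
    "l1"   = lam * sum(abs(w)),
    "l4/3" = lam * sum(abs(w)^(4 / 3)),
    "l3/2" = lam * sum(abs(w)^1.5),
    "l2"   = lam * sum(w^2),
    "l3"   = lam * sum(abs(w)^3),
    "l4"   = lam * sum(w^4),
    "linf" = lam * max(abs(w)),
    "scad" = sum(scad_pen(w, lam, spec$scad_a)),
    "mcp"  = sum(mcp_pen(w, lam, spec$mcp_gamma))
  )
}

# ---- internal vectorized prox solvers ----------------------------------------
# All solve argmin_x  scale * pen(x) + (x - z)^2 / 2  elementwise, where
# pen() includes lambda. `t` below is scale * lambda for the power family.

# safeguarded Newton for x + q*t*x^(q-1) = a on [0, a], vectorized.
# g(x) is strictly increasing for q > 1, so the root is unique.
newton_power <- function(a, t, q, tol = 1e-12, maxit = 100L) {
  x <- pmin(a, (pmax(a, .Machine$double.eps) / pmax(q * t, .Machine$double.eps))^(1 / (q - 1)))
  x <- pmax(pmin(x, a), 0)
  lo <- rep(0, length(a)); hi <- a
  for (it in seq_len(maxit)) {
    g  <- x + q * t * x^(q - 1) - a
    lo <- ifelse(g < 0, x, lo)
    hi <- ifelse(g > 0, x, hi)
    dg <- 1 + q * (q - 1) * t * x^(q - 2)
    step <- g / dg
    xn <- x - step
    bad <- !is.finite(xn) | xn <= lo | xn >= hi
    xn[bad] <- (lo[bad] + hi[bad]) / 2
    if (max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  x
}

# half-thresholding: largest root of u^3 - a*u + t/2 = 0 (u = sqrt(x)),
# then 0-vs-root objective comparison; ties go to 0.
prox_half <- function(a, t) {
  out <- numeric(length(a))
  disc <- 4 * a^3 - 27 * (t / 2)^2          # > 0 <=> three real roots
  ok <- disc > 0 & a > 0
  if (any(ok)) {
    aa <- a[ok]; tt <- t[ok]
    # roots of u^3 + p u + q, p = -a, q = t/2; largest root k = 0
    arg <- pmin(1, pmax(-1, (3 * (tt / 2)) / (2 * (-aa)) * sqrt(3 / aa)))
    u <- 2 * sqrt(aa / 3) * cos(acos(arg) / 3)
    x <- u * u
    keep <- tt * sqrt(x) + (x - aa)^2 / 2 < aa^2 / 2   # strict: tie -> 0
    out[ok] <- ifelse(keep, x, 0)
  }
  out
}

# two-thirds thresholding: u = x^(1/3) solves u^4 - a*u + c = 0, c = 2t/3.
# Resolvent cubic w^3 - 4c w - a^2 = 0 (unique positive root w = s^2), then
# u = (s + sqrt(2a/s - s^2)) / 2; 0-vs-root objective comparison.
prox_two_thirds <- function(a, t) {
  out <- numeric(length(a))
  out[t == 0] <- a[t == 0]
  ok <- a > 0 & t > 0
  if (any(ok)) {
    aa <- a[ok]; cc <- 2 * t[ok] / 3
    P <- -4 * cc; Q <- -aa^2
    D <- (Q / 2)^2 + (P / 3)^3
    w <- numeric(length(aa))
    pos <- D >= 0
    if (any(pos)) {
      rt <- sqrt(D[pos])
      w[pos] <- sign(-Q[pos] / 2 + rt) * abs(-Q[pos] / 2 + rt)^(1 / 3) +
                sign(-Q[pos] / 2 - rt) * abs(-Q[pos] / 2 - rt)^(1 / 3)
    }
    if (any(!pos)) {
      m <- sqrt(-P[!pos] / 3)
      arg <- pmin(1, pmax(-1, 3 * Q[!pos] / (2 * P[!pos]) * sqrt(-3 / P[!pos])))
      w[!pos] <- 2 * m * cos(acos(arg) / 3)
    }
    s <- sqrt(pmax(w, 0))
    rad <- 2 * aa / s - s^2
    have <- is.finite(s) & s > 0 & rad >= 0
    u <- ifelse(have, (s + sqrt(pmax(rad, 0))) / 2, 0)
    x <- u^3
    keep <- have & (t[ok] * x^(2 / 3) + (x - aa)^2 / 2 < aa^2 / 2)
    out[ok] <- ifelse(keep, x, 0)
  }
  out
}

# SCAD prox at metric scale s: evaluate the exact objective at every
# piecewise-stationary candidate plus region boundaries; ties prefer 0.
prox_scad <- function(a, s, lam, A) {
  n <- length(a)
  cand <- matrix(0, n, 6L)
  cand[, 2L] <- pmin(pmax(a - s * lam, 0), lam)              # inner region
  mid <- (a * (A - 1) - s * A * lam) / (A - 1 - s)           # middle region
  mid[!is.finite(mid)] <- 0
  cand[, 3L] <- pmin(pmax(mid, lam), A * lam)
  cand[, 4L] <- pmax(a, A * lam)                             # outer region
  cand[, 5L] <- lam
  cand[, 6L] <- A * lam
  obj <- s * scad_pen(cand, lam, A) + (cand - a)^2 / 2
  best <- max.col(-obj, ties.method = "first")               # col 1 is x = 0
  x <- cand[cbind(seq_len(n), best)]
  x[obj[, 1L] <= obj[cbind(seq_len(n), best)] + 1e-15] <- 0  # tie -> 0
  x
}

# MCP prox at metric scale s, same candidate-evaluation strategy.
prox_mcp <- function(a, s, lam, g) {
  n <- length(a)
  cand <- matrix(0, n, 5L)
  inner <- (a - s * lam) * g / (g - s)
  inner[!is.finite(inner)] <- 0
  cand[, 2L] <- pmin(pmax(inner, 0), g * lam)
  cand[, 3L] <- pmax(a, g * lam)
  cand[, 4L] <- g * lam
  cand[, 5L] <- pmin(a, g * lam)
  obj <- s * mcp_pen(cand, lam, g) + (cand - a)^2 / 2
  best <- max.col(-obj, ties.method = "first")
  x <- cand[cbind(seq_len(n), best)]
  x[obj[, 1L] <= obj[cbind(seq_len(n), best)] + 1e-15] <- 0
  x
}

# elementwise prox on magnitudes; z, scale vectors of equal length
prox_vec <- function(spec, z, scale) {
  a <- abs(z); sg <- sign(z)
  lam <- spec$lambda
  t <- rep_len(scale * lam, length(a))
  mag <- switch(spec$kind,
    "l0"   = ifelse(a > sqrt(2 * t), a, 0),
    "l1/2" = prox_half(a, t),
    "l2/3" = prox_two_thirds(a, t),
    "l1"   = pmax(a - t, 0),
    "l4/3" = {  # u = x^(1/3) solves u^3 + (4/3) t u - a = 0 (Cardano, one real root)
      p <- 4 * t / 3
      rt <- sqrt(a^2 / 4 + p^3 / 27)
      u <- (a / 2 + rt)^(1 / 3) - (pmax(rt - a / 2, 0))^(1 / 3)
      u^3
    },
    "l3/2" = ((-1.5 * t + sqrt(2.25 * t^2 + 4 * a)) / 2)^2,
    "l2"   = a / (1 + 2 * t),
    "l3"   = ifelse(t > 0, (-1 + sqrt(1 + 12 * t * a)) / (6 * t), a),
    "l4"   = newton_power(a, t, 4),
    "linf" = stop("`linf` prox is not separable; use prox_linf()"),
    "scad" = if (lam == 0) a else prox_scad(a, scale, lam, spec$scad_a),
    "mcp"  = if (lam == 0) a else prox_mcp(a, scale, lam, spec$mcp_gamma)
  )
  sg * mag
}

#' Scalar proximal operator
#'
#' Computes \eqn{\mathrm{prox}(z) = \arg\min_x \, s\,\mathrm{pen}(x) +
#' \frac{1}{2}(x - z)^2} where `pen` is the penalty of `spec` (including
#' \eqn{\lambda}) and `s = scale` is the effective per-coordinate metric
#' multiplier (\eqn{\alpha_t / (c_i + \delta)} in the preconditioned update).
#' Closed forms are used for every kind except `l4`, which uses a safeguarded
#' Newton bracket on \eqn{[0, |z|]}. For the non-convex kinds a tie between
#' the zero and nonzero local minimizers returns 0 (the sparser solution).
#'
#' @param spec A [penalty_spec()]. `kind = "linf"` is rejected here because
#'   the max-norm prox is not separable; use [prox_linf()].
#' @param z Finite numeric scalar.
#' @param scale Positive finite scalar.
#' @return The proximal point; always satisfies `|prox(z)| <= |z|` and
#'   `sign(prox(z)) %in% c(0, sign(z))`.
#' @export
prox_scalar <- function(spec, z, scale = 1) {
  check_spec(spec)
  if (spec$kind == "linf")
    stop("`linf` prox is vector-valued and not separable; use prox_linf()")
  if (length(z) != 1L || !is.finite(z)) stop("`z` must be a finite scalar")
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a positive finite scalar")
  prox_vec(spec, z, scale)
}

#' Elementwise proximal operator under a diagonal metric
#'
#' Applies [prox_scalar()] coordinatewise: `out[i]` minimizes
#' \eqn{\mathrm{scale}_i\,\mathrm{pen}(x) + \frac{1}{2}(x - z_i)^2}. This is
#' the exact diagonal-metric prox for every separable penalty; `linf` must go
#' through [prox_linf()] instead. Thresholding penalties return bit-exact
#' zeros.
#'
#' @param spec A [penalty_spec()] with a separable kind.
#' @param z Finite numeric vector.
#' @param scale Positive scalar or vector the same length as `z`.
#' @return Numeric vector the same length as `z`.
#' @export
prox_elementwise <- function(spec, z, scale = 1) {
  check_spec(spec)
  if (spec$kind == "linf")
    stop("`linf` prox is not separable; use prox_linf()")
  if (!is.numeric(z) || any(!is.finite(z))) stop("`z` must be finite numeric")
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("`scale` must be strictly positive and finite")
  if (length(scale) != 1L && length(scale) != length(z))
    stop("`scale` must be scalar or match length(z)")
  scale <- rep_len(scale, length(z))
  out <- prox_vec(spec, as.numeric(z), scale)
  dim(out) <- dim(z)
  out
}

#' Proximal operator of the max-norm penalty
#'
#' Solves \eqn{\arg\min_x \; \ell \max_i |x_i| + \frac{1}{2} \sum_i w_i (x_i -
#' z_i)^2} exactly (\eqn{\ell} = `lam_scale`, \eqn{w} = `weights`). The
#' optimum clamps each coordinate to \eqn{[-s^\ast, s^\ast]} where the clamp
#' level \eqn{s^\ast} is the root of the piecewise-linear decreasing function
#' \eqn{\ell - \sum_i w_i(|z_i| - s)_+}, located by sorting the \eqn{|z_i|}
#' breakpoints. In the unweighted case the result satisfies the Moreau
#' identity `prox(z) + proj_L1ball(z, radius = lam_scale) == z`.
#'
#' @param lam_scale Positive effective penalty strength (\eqn{\lambda} times
#'   any step scaling).
#' @param z Nonempty finite numeric vector.
#' @param weights Strictly positive vector of diagonal metric entries
#'   (all ones for the unweighted case).
#' @return Numeric vector the same length as `z`.
#' @export
prox_linf <- function(lam_scale, z, weights = rep(1, length(z))) {
  if (length(z) == 0L) stop("`z` must be nonempty")
  if (!all(is.finite(z))) stop("`z` must be finite")
  if (length(lam_scale) != 1L || !is.finite(lam_scale) || lam_scale < 0)
    stop("`lam_scale` must be a single non-negative number")
  weights <- rep_len(weights, length(z))
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("`weights` must be strictly positive and finite")
  if (lam_scale == 0) return(z)
  a <- abs(z)
  if (sum(weights * a) <= lam_scale) return(rep(0, length(z)))
  o <- order(a, decreasing = TRUE)
  ao <- a[o]; wo <- weights[o]
  cw <- cumsum(wo); cwa <- cumsum(wo * ao)
  s_cand <- (cwa - lam_scale) / cw
  nxt <- c(ao[-1L], 0)
  j <- which(s_cand >= nxt)[1L]
  s <- max(s_cand[j], 0)
  pmin(pmax(z, -s), s)
}

#' Brute-force proximal oracle
#'
#' Independent grid-search minimizer of the scalar prox objective
#' \eqn{\mathrm{scale}\cdot\mathrm{pen}(x) + \frac{1}{2}(x - z)^2}, used to
#' validate the closed-form operators. A dense grid over
#' \eqn{[-|z| - h,\, |z| + h]} at `coarse_step` (always including the
#' candidates 0 and `z`) is followed by golden-section refinement around the
#' best grid point. Documented accuracy is bounded by `coarse_step`; in
#' practice the refinement reaches the local optimum to ~1e-8. A tie between
#' 0 and the refined point (within 1e-12 in objective) returns 0.
#'
#' @param spec A [penalty_spec()] (any kind; `linf` reduces to `l1` in one
#'   dimension).
#' @param z Finite scalar.
#' @param scale Positive scalar.
#' @param grid_halfwidth Extension of the search interval beyond `|z|`.
#' @param coarse_step Positive grid spacing.
#' @return The grid-optimal proximal point.
#' @export
prox_oracle_scalar <- function(spec, z, scale = 1, grid_halfwidth = 1,
                               coarse_step = 1e-3) {
  check_spec(spec)
  if (length(z) != 1L || !is.finite(z)) stop("`z` must be a finite scalar")
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be positive and finite")
  if (!is.finite(coarse_step) || coarse_step <= 0) stop("`coarse_step` must be > 0")
  lam <- spec$lambda
  obj1 <- function(x) {
    pen <- switch(spec$kind,
      "l0"   = lam * (x != 0),
      "l1/2" = lam * abs(x)^0.5,
      "l2/3" = lam * abs(x)^(2 / 3),
      "l1"   = lam * abs(x),
      "l4/3" = lam * abs(x)^(4 / 3),
      "l3/2" = lam * abs(x)^1.5,
      "l2"   = lam * x^2,
      "l3"   = lam * abs(x)^3,
      "l4"   = lam * x^4,
      "linf" = lam * abs(x),
      "scad" = scad_pen(x, lam, spec$scad_a),
      "mcp"  = mcp_pen(x, lam, spec$mcp_gamma))
    scale * pen + (x - z)^2 / 2
  }
  hw <- abs(z) + abs(grid_halfwidth)
  grid <- seq(-hw, hw, by = coarse_step)
  grid <- c(grid, 0, z)
  vals <- obj1(grid)
  best <- grid[which.min(vals)]
  x <- best
  if (spec$kind != "l0") {   # piecewise-smooth away from 0: refine locally
    lo <- best - coarse_step; hi <- best + coarse_step
    brackets <- if (lo < 0 && hi > 0) list(c(lo, 0), c(0, hi)) else list(c(lo, hi))
    for (b in brackets) {
      op <- stats::optimize(obj1, lower = b[1L], upper = b[2L], tol = 1e-10)
      if (op$objective < obj1(x)) x <- op$minimum
    }
  }
  if (obj1(0) <= obj1(x) + 1e-12) x <- 0
  if (abs(x) < coarse_step * 1e-6) x <- 0
  x
}
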