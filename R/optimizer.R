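#' Configuration of the adaptive proximal-gradient optimizer
#'
#' The optimizer combines an Adam-style diagonally preconditioned momentum
#' step with a proximal mapping applied to the penalized parameter arrays:
#' \deqn{m_t = \beta_1 m_{t-1} + (1 - \beta_1) g_t, \quad
#'       v_t = \beta_2 v_{t-1} + (1 - \beta_2) g_t^2,}
#' \deqn{\theta_{t+1} = \mathrm{prox}^{C_t + \delta I}_{\alpha \lambda R(\cdot)}
#'       \left(\theta_t - \alpha\, (C_t + \delta I)^{-1} \hat m_t\right),}
#' with \eqn{C_t = \sqrt{\hat v_t}}. With `bias_correction = TRUE` (default)
#' the Adam initialization-bias correction
#' \eqn{\hat m_t = m_t / (1 - \beta_1^t)}, \eqn{\hat v_t = v_t / (1 - \beta_2^t)}
#' is applied; with `FALSE` the raw moments are used. The second moment is
#' accumulated on \eqn{v_t} (squared scale) and the preconditioner is its
#' square root, the Adam-lineage convention.
#'
#' The defaults \eqn{\beta_1 = 0.1}, \eqn{\beta_2 = 0.999} are the momentum
#' settings used for the proximal networks in this package; the unpenalized
#' Adam baseline uses \eqn{\beta_1 = 0.9}.
#'
#' @param alpha Positive learning rate \eqn{\alpha} (constant).
#' @param beta1 First-moment decay in `[0, 1)`.
#' @param beta2 Second-moment decay in `[0, 1)`.
#' @param delta Small positive metric floor \eqn{\delta}.
#' @param bias_correction Logical; apply the Adam bias correction.
#' @return An object of class `"opt_config"`.
#' @export
opt_config <- function(alpha, beta1 = 0.1, beta2 = 0.999, delta = 1e-8,
                       bias_correction = TRUE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0,
            is.numeric(beta1), beta1 >= 0, beta1 < 1,
            is.numeric(beta2), beta2 >= 0, beta2 < 1,
            is.numeric(delta), delta > 0,
            is.logical(bias_correction), length(bias_correction) == 1L)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, delta = delta,
                 bias_correction = bias_correction),
            class = "opt_config")
}

#' Initialize optimizer state
#'
#' Creates the zero-initialized first- and second-moment accumulators matching
#' a named list of parameter arrays, with the step counter at 0.
#'
#' @param params Named list of numeric arrays (the model parameters).
#' @return An object of class `"opt_state"` with fields `t`, `m`, `v`.
#' @export
opt_state_init <- function(params) {
  stopifnot(is.list(params), length(params) > 0L, !is.null(names(params)))
  zeros <- lapply(params, function(p) { z <- p; z[] <- 0; z })
  structure(list(t = 0L, m = zeros, v = zeros), class = "opt_state")
}

#' One step of the stochastic adaptive proximal-gradient update
#'
#' Advances the optimizer by one iteration: updates both moment accumulators,
#' takes the preconditioned gradient half-step on every parameter array, and
#' then applies the proximal operator of `penalty` to the arrays named in
#' `penalized` with effective per-coordinate scale
#' \eqn{\alpha / (C_t + \delta)} (the exact diagonal-metric prox for
#' separable penalties; the max-norm penalty is proximized jointly per array
#' with metric weights \eqn{(C_t + \delta)/\alpha}). Unpenalized arrays take
#' only the gradient half-step. Thresholding penalties produce bit-exact
#' zeros.
#'
#' @param state An [opt_state_init()] state.
#' @param params Named list of numeric arrays.
#' @param grads Named list of gradients with shapes matching `params`.
#' @param cfg An [opt_config()].
#' @param penalty A [penalty_spec()] or `NULL` for no proximal step.
#' @param penalized Character vector naming the arrays that receive the prox
#'   step (defaults to all arrays when a penalty is supplied).
#' @return List with updated `params` and `state`.
#' @export
opt_step <- function(state, params, grads, cfg, penalty = NULL,
                     penalized = if (is.null(penalty)) character(0) else names(params)) {
  stopifnot(inherits(state, "opt_state"), inherits(cfg, "opt_config"))
  if (!identical(names(params), names(state$m)))
    stop("parameter names do not match optimizer state")
  if (!all(names(params) %in% names(grads)))
    stop("missing gradients for: ",
         paste(setdiff(names(params), names(grads)), collapse = ", "))
  t_new <- state$t + 1L
  bc1 <- if (cfg$bias_correction) 1 - cfg$beta1^t_new else 1
  bc2 <- if (cfg$bias_correction) 1 - cfg$beta2^t_new else 1
  do_prox <- !is.null(penalty) && penalty$lambda > 0
  if (do_prox) check_spec(penalty)
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (length(g) != length(params[[nm]]))
      stop("gradient shape mismatch for parameter `", nm, "`")
    if (any(!is.finite(g)))
      stop("non-finite gradient for parameter `", nm, "`")
    m <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    v <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    denom <- sqrt(v / bc2) + cfg$delta
    u <- params[[nm]] - cfg$alpha * (m / bc1) / denom
    if (do_prox && nm %in% penalized) {
      if (penalty$kind == "linf") {
        xn <- prox_linf(penalty$lambda, as.vector(u),
                        weights = as.vector(denom) / cfg$alpha)
        dim(xn) <- dim(u)
        u <- xn
      } else {
        u <- prox_elementwise(penalty, u, scale = cfg$alpha / denom)
      }
    }
    params[[nm]] <- u
  }
  state$t <- t_new
  list(params = params, state = state)
}

#' Full penalized training objective
#'
#' Evaluates \eqn{F(\theta) = L(\theta) + \lambda R(\theta_{\mathrm{pen}})}
#' where `loss_fn` returns the empirical loss on the current parameters and
#' the penalty term is computed on the concatenation of the penalized arrays.
#' Used by convergence diagnostics and by the objective traces of the fitting
#' functions.
#'
#' @param loss_fn Function of `params` returning a finite scalar loss.
#' @param params Named list of numeric arrays.
#' @param penalty A [penalty_spec()] or `NULL`.
#' @param penalized Character vector of penalized array names.
#' @return A single finite number.
#' @export
full_objective <- function(loss_fn, params, penalty = NULL,
                           penalized = names(params)) {
  L <- loss_fn(params)
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L))
  if (is.null(penalty) || penalty$lambda == 0) return(as.numeric(L))
  w <- unlist(params[penalized], use.names = FALSE)
  as.numeric(L) + penalty_value(penalty, w)
}
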