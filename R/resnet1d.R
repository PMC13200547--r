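#' Architecture plan for a 1D residual network of a given depth
#'
#' Maps a nominal depth to a concrete plan under the weighted-layer
#' accounting convention of this package:
#' \deqn{\mathrm{depth} = \#\mathrm{stem\ convs} + (\mathrm{convs/block}
#'   \times \#\mathrm{blocks}) + 1\ (\mathrm{final\ fully\ connected}),}
#' with basic blocks (2 convolutions) for `depth <= 18` and bottleneck blocks
#' (3 convolutions) beyond, unless overridden. Basic:
#' `B = floor((depth - 2) / 2)` blocks and `1 + ((depth - 2) %% 2)` stem
#' convolutions; bottleneck: `B = floor((depth - 2) / 3)` and
#' `1 + ((depth - 2) %% 3)` stems. Projection shortcuts are not counted.
#' Blocks are spread over at most `n_stages` stages as evenly as possible
#' (earlier stages receive the remainder); each stage transition doubles the
#' channel width and applies stride 2 in the first block of the stage.
#'
#' @param depth Integer depth, at least 4. The depths explored by the result
#'   tables are 5, 10, 15, 18, 20, 25.
#' @param base_width Channels of the first stage (default 16).
#' @param n_stages Maximum number of stages (default 4).
#' @param block `"auto"` (basic for depth <= 18, bottleneck above),
#'   `"basic"`, or `"bottleneck"`.
#' @return A list with `depth`, `block`, `n_stem`, `n_blocks`,
#'   `stage_blocks`, `stage_widths`, `block_strides`, and `weighted_layers`
#'   (always equal to `depth`).
#' @examples
#' depth_to_plan(18)$n_blocks   # 8 basic blocks
#' depth_to_plan(20)$n_blocks   # 6 bottleneck blocks
#' @export
depth_to_plan <- function(depth, base_width = 16L, n_stages = 4L,
                          block = c("auto", "basic", "bottleneck")) {
  block <- match.arg(block)
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 4L) stop("`depth` must be an integer >= 4")
  if (n_stages < 1L) stop("`n_stages` must be >= 1")
  if (block == "auto") block <- if (depth <= 18L) "basic" else "bottleneck"
  cpb <- if (block == "basic") 2L else 3L
  B <- (depth - 2L) %/% cpb
  n_stem <- 1L + (depth - 2L) %% cpb
  if (B < 1L) stop("`depth` too small for ", block, " blocks")
  n_used <- min(as.integer(n_stages), B)
  base_ct <- B %/% n_used
  rem <- B %% n_used
  stage_blocks <- base_ct + as.integer(seq_len(n_used) <= rem)
  stage_widths <- as.integer(base_width * 2^(seq_len(n_used) - 1L))
  block_strides <- lapply(seq_len(n_used), function(s) {
    st <- rep(1L, stage_blocks[s])
    if (s > 1L) st[1L] <- 2L
    st
  })
  list(depth = depth, block = block, n_stem = n_stem, n_blocks = B,
       stage_blocks = stage_blocks, stage_widths = stage_widths,
       block_strides = block_strides,
       weighted_layers = n_stem + cpb * B + 1L)
}

#' Model configuration for a 1D residual network
#'
#' @param depth Network depth (see [depth_to_plan()]).
#' @param block Block kind; `"auto"` selects basic for depth <= 18 and
#'   bottleneck beyond.
#' @param base_width First-stage channel count.
#' @param kernel_size Odd convolution kernel size. The default 1 follows the
#'   1x1-convolution design of the basic blocks; since 1x1 convolutions mix
#'   channels but not positions, `kernel_size = 3` is available for
#'   position-mixing variants.
#' @param n_stages Maximum number of stages (<= 4 by default).
#' @param mid_kernel Kernel of the middle bottleneck convolution (default 3).
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `"resnet_config"`.
#' @export
resnet_config <- function(depth = 5L, block = "auto", base_width = 16L,
                          kernel_size = 1L, n_stages = 4L, mid_kernel = 3L,
                          seed = 1L) {
  if (kernel_size %% 2L != 1L || kernel_size < 1L)
    stop("`kernel_size` must be a positive odd integer")
  if (mid_kernel %% 2L != 1L || mid_kernel < 1L)
    stop("`mid_kernel` must be a positive odd integer")
  plan <- depth_to_plan(depth, base_width = base_width, n_stages = n_stages,
                        block = block)
  structure(list(depth = as.integer(depth), block = plan$block,
                 base_width = as.integer(base_width),
                 kernel_size = as.integer(kernel_size),
                 n_stages = as.integer(n_stages),
                 mid_kernel = as.integer(mid_kernel),
                 seed = as.integer(seed), plan = plan),
            class = "resnet_config")
}

#' Build an untrained 1D residual network
#'
#' Instantiates the parameter arrays and batch-normalization state for a
#' [resnet_config()]. The network maps a `(batch, p)` marker matrix, encoded
#' as a single-channel 1D signal over the (fixed, arbitrary) marker order,
#' to scalar predictions: stem convolution(s), the planned residual blocks,
#' adaptive average pooling to length 1, and a fully connected output layer.
#' Residual blocks follow the identity formulation
#' \eqn{X_{l+1} = \mathrm{shortcut}(X_l) + E(X_l)}, where the basic-block
#' branch is conv-BN-ReLU-conv-BN and a projection shortcut (1x1 convolution
#' plus BN, not counted in the depth) is used exactly when the shape changes.
#' Initialization is He-style and fully determined by `cfg$seed`.
#'
#' @param cfg A [resnet_config()].
#' @return An object of class `"resnet_model"` with fields `arch`, `params`
#'   (named list of arrays), `bn` (running statistics), `penalized` (names of
#'   the convolution and fully connected weight arrays), `min_len`, `cfg`.
#' @export
build_resnet1d <- function(cfg) {
  stopifnot(inherits(cfg, "resnet_config"))
  plan <- cfg$plan
  k <- cfg$kernel_size
  arch <- list(stems = list(), blocks = list(), fc_in = NA_integer_)
  params <- list()
  bn <- list()
  add_bn <- function(name, C) bn[[name]] <<- list(mean = numeric(C), var = rep(1, C))

  with_seed(cfg$seed, {
    C_prev <- 1L
    for (i in seq_len(plan$n_stem)) {
      nm <- paste0("stem", i)
      C_out <- plan$stage_widths[1L]
      arch$stems[[i]] <- list(name = nm, C_in = C_prev, C_out = C_out,
                              k = k, stride = 1L)
      params[[paste0(nm, ".W")]] <- init_conv(C_out, C_prev, k)
      params[[paste0(nm, ".bn.g")]] <- rep(1, C_out)
      params[[paste0(nm, ".bn.b")]] <- numeric(C_out)
      add_bn(paste0(nm, ".bn"), C_out)
      C_prev <- C_out
    }
    expansion <- if (plan$block == "bottleneck") 4L else 1L
    bi <- 0L
    for (s in seq_along(plan$stage_blocks)) {
      width <- plan$stage_widths[s]
      C_out <- width * expansion
      for (b in seq_len(plan$stage_blocks[s])) {
        bi <- bi + 1L
        nm <- paste0("s", s, "b", b)
        stride <- plan$block_strides[[s]][b]
        has_proj <- (C_prev != C_out) || (stride != 1L)
        blk <- list(name = nm, kind = plan$block, C_in = C_prev,
                    width = width, C_out = C_out, stride = stride,
                    has_proj = has_proj)
        if (plan$block == "basic") {
          params[[paste0(nm, ".c1.W")]] <- init_conv(width, C_prev, k)
          params[[paste0(nm, ".bn1.g")]] <- rep(1, width)
          params[[paste0(nm, ".bn1.b")]] <- numeric(width)
          add_bn(paste0(nm, ".bn1"), width)
          params[[paste0(nm, ".c2.W")]] <- init_conv(width, width, k)
          params[[paste0(nm, ".bn2.g")]] <- rep(1, width)
          params[[paste0(nm, ".bn2.b")]] <- numeric(width)
          add_bn(paste0(nm, ".bn2"), width)
        } else {
          params[[paste0(nm, ".c1.W")]] <- init_conv(width, C_prev, 1L)
          params[[paste0(nm, ".bn1.g")]] <- rep(1, width)
          params[[paste0(nm, ".bn1.b")]] <- numeric(width)
          add_bn(paste0(nm, ".bn1"), width)
          params[[paste0(nm, ".c2.W")]] <- init_conv(width, width, cfg$mid_kernel)
          params[[paste0(nm, ".bn2.g")]] <- rep(1, width)
          params[[paste0(nm, ".bn2.b")]] <- numeric(width)
          add_bn(paste0(nm, ".bn2"), width)
          params[[paste0(nm, ".c3.W")]] <- init_conv(C_out, width, 1L)
          params[[paste0(nm, ".bn3.g")]] <- rep(1, C_out)
          params[[paste0(nm, ".bn3.b")]] <- numeric(C_out)
          add_bn(paste0(nm, ".bn3"), C_out)
        }
        if (has_proj) {
          params[[paste0(nm, ".sc.W")]] <- init_conv(C_out, C_prev, 1L)
          params[[paste0(nm, ".scbn.g")]] <- rep(1, C_out)
          params[[paste0(nm, ".scbn.b")]] <- numeric(C_out)
          add_bn(paste0(nm, ".scbn"), C_out)
        }
        arch$blocks[[bi]] <- blk
        C_prev <- C_out
      }
    }
    arch$fc_in <- C_prev
    params[["fc.W"]] <- stats::rnorm(C_prev, sd = 1 / sqrt(C_prev))
    params[["fc.b"]] <- 0
  })
  n_stride2 <- sum(unlist(plan$block_strides) == 2L)
  structure(list(arch = arch, params = params, bn = bn,
                 penalized = grep("\\.W$", names(params), value = TRUE),
                 min_len = 2L^n_stride2, cfg = cfg),
            class = "resnet_model")
}

#' Exact parameter count of a network configuration
#'
#' @param x A [resnet_config()] or built `resnet_model`.
#' @return Total number of trainable parameters (deterministic for a given
#'   configuration).
#' @export
resnet_param_count <- function(x) {
  model <- if (inherits(x, "resnet_config")) build_resnet1d(x) else x
  stopifnot(inherits(model, "resnet_model"))
  sum(vapply(model$params, length, 1L))
}

# full forward pass; returns prediction vector, caches (training) and
# updated bn state
net_fwd <- function(model, params, bn, x, training) {
  caches <- list()
  h <- x
  for (st in model$arch$stems) {
    nm <- st$name
    cv <- conv_fwd(h, params[[paste0(nm, ".W")]], st$stride)
    b <- bn_fwd(cv$y, params[[paste0(nm, ".bn.g")]],
                params[[paste0(nm, ".bn.b")]], bn[[paste0(nm, ".bn")]],
                training)
    bn[[paste0(nm, ".bn")]] <- b$run
    r <- relu_fwd(b$y)
    caches[[nm]] <- list(cv = cv$cache, bn = b$cache, relu = r$cache)
    h <- r$y
  }
  for (blk in model$arch$blocks) {
    nm <- blk$name
    cc <- list(input_dim = dim(h))
    c1 <- conv_fwd(h, params[[paste0(nm, ".c1.W")]],
                   if (blk$kind == "basic") blk$stride else 1L)
    b1 <- bn_fwd(c1$y, params[[paste0(nm, ".bn1.g")]],
                 params[[paste0(nm, ".bn1.b")]], bn[[paste0(nm, ".bn1")]],
                 training)
    bn[[paste0(nm, ".bn1")]] <- b1$run
    r1 <- relu_fwd(b1$y)
    c2 <- conv_fwd(r1$y, params[[paste0(nm, ".c2.W")]],
                   if (blk$kind == "basic") 1L else blk$stride)
    b2 <- bn_fwd(c2$y, params[[paste0(nm, ".bn2.g")]],
                 params[[paste0(nm, ".bn2.b")]], bn[[paste0(nm, ".bn2")]],
                 training)
    bn[[paste0(nm, ".bn2")]] <- b2$run
    cc$c1 <- c1$cache; cc$bn1 <- b1$cache; cc$r1 <- r1$cache
    cc$c2 <- c2$cache; cc$bn2 <- b2$cache
    if (blk$kind == "basic") {
      branch <- b2$y
    } else {
      r2 <- relu_fwd(b2$y)
      c3 <- conv_fwd(r2$y, params[[paste0(nm, ".c3.W")]], 1L)
      b3 <- bn_fwd(c3$y, params[[paste0(nm, ".bn3.g")]],
                   params[[paste0(nm, ".bn3.b")]], bn[[paste0(nm, ".bn3")]],
                   training)
      bn[[paste0(nm, ".bn3")]] <- b3$run
      cc$r2 <- r2$cache; cc$c3 <- c3$cache; cc$bn3 <- b3$cache
      branch <- b3$y
    }
    if (blk$has_proj) {
      sc <- conv_fwd(h, params[[paste0(nm, ".sc.W")]], blk$stride)
      sb <- bn_fwd(sc$y, params[[paste0(nm, ".scbn.g")]],
                   params[[paste0(nm, ".scbn.b")]], bn[[paste0(nm, ".scbn")]],
                   training)
      bn[[paste0(nm, ".scbn")]] <- sb$run
      cc$sc <- sc$cache; cc$scbn <- sb$cache
      shortcut <- sb$y
    } else shortcut <- h
    h <- shortcut + branch
    caches[[nm]] <- cc
  }
  pl <- pool_fwd(h)
  pred <- as.vector(crossprod(pl$y, params[["fc.W"]])) + params[["fc.b"]]
  caches[["pool"]] <- pl$cache
  caches[["pooled"]] <- pl$y
  list(pred = pred, caches = caches, bn = bn)
}

# full backward pass; dpred is dLoss/dprediction (length B)
net_bwd <- function(model, params, caches, dpred) {
  grads <- list()
  pooled <- caches[["pooled"]]
  grads[["fc.W"]] <- as.vector(pooled %*% dpred)
  grads[["fc.b"]] <- sum(dpred)
  dpooled <- outer(params[["fc.W"]], dpred)
  dh <- pool_bwd(dpooled, caches[["pool"]])
  for (blk in rev(model$arch$blocks)) {
    nm <- blk$name
    cc <- caches[[nm]]
    dbranch <- dh
    dshort <- dh
    if (blk$kind == "bottleneck") {
      b3 <- bn_bwd(dbranch, cc$bn3)
      grads[[paste0(nm, ".bn3.g")]] <- b3$dgamma
      grads[[paste0(nm, ".bn3.b")]] <- b3$dbeta
      c3 <- conv_bwd(b3$dx, params[[paste0(nm, ".c3.W")]], cc$c3)
      grads[[paste0(nm, ".c3.W")]] <- c3$dW
      dbranch <- relu_bwd(c3$dx, cc$r2)
    }
    b2 <- bn_bwd(dbranch, cc$bn2)
    grads[[paste0(nm, ".bn2.g")]] <- b2$dgamma
    grads[[paste0(nm, ".bn2.b")]] <- b2$dbeta
    c2 <- conv_bwd(b2$dx, params[[paste0(nm, ".c2.W")]], cc$c2)
    grads[[paste0(nm, ".c2.W")]] <- c2$dW
    dr1 <- relu_bwd(c2$dx, cc$r1)
    b1 <- bn_bwd(dr1, cc$bn1)
    grads[[paste0(nm, ".bn1.g")]] <- b1$dgamma
    grads[[paste0(nm, ".bn1.b")]] <- b1$dbeta
    c1 <- conv_bwd(b1$dx, params[[paste0(nm, ".c1.W")]], cc$c1)
    grads[[paste0(nm, ".c1.W")]] <- c1$dW
    dx_branch <- c1$dx
    if (blk$has_proj) {
      sb <- bn_bwd(dshort, cc$scbn)
      grads[[paste0(nm, ".scbn.g")]] <- sb$dgamma
      grads[[paste0(nm, ".scbn.b")]] <- sb$dbeta
      scb <- conv_bwd(sb$dx, params[[paste0(nm, ".sc.W")]], cc$sc)
      grads[[paste0(nm, ".sc.W")]] <- scb$dW
      dh <- dx_branch + scb$dx
    } else {
      dh <- dx_branch + dshort
    }
  }
  for (st in rev(model$arch$stems)) {
    nm <- st$name
    cc <- caches[[nm]]
    dr <- relu_bwd(dh, cc$relu)
    b <- bn_bwd(dr, cc$bn)
    grads[[paste0(nm, ".bn.g")]] <- b$dgamma
    grads[[paste0(nm, ".bn.b")]] <- b$dbeta
    cv <- conv_bwd(b$dx, params[[paste0(nm, ".W")]], cc$cv)
    grads[[paste0(nm, ".W")]] <- cv$dW
    dh <- cv$dx
  }
  grads
}

to_tensor <- function(X) {
  array(t(X), dim = c(1L, ncol(X), nrow(X)))
}

#' Fit a proximal-regularized 1D residual network
#'
#' Trains a [build_resnet1d()] network on a marker matrix by stochastic
#' adaptive proximal-gradient descent ([opt_step()]): mini-batches are drawn
#' in seeded shuffled order each epoch, the mean-squared-error loss is
#' back-propagated, and the proximal operator of `penalty` is applied to the
#' convolution and fully connected weight arrays after every preconditioned
#' gradient step. Biases and batch-normalization parameters are never
#' penalized and are excluded from sparsity counts. With `lambda = 0` (or
#' `penalty = NULL`) the optimizer reduces to plain Adam and the fit is the
#' non-regularized baseline; the momentum default is then
#' \eqn{\beta_1 = 0.9} instead of the 0.1 used for proximal training.
#'
#' @param x Numeric matrix (n samples by p markers), already standardized.
#' @param y Numeric response of length n (standardized).
#' @param depth Network depth (see [depth_to_plan()]); ignored if `config`
#'   is supplied.
#' @param penalty Penalty kind, [penalty_spec()], or `NULL` for the
#'   unregularized baseline.
#' @param lambda Penalty strength (ignored when `penalty` is a spec).
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size (must not exceed n).
#' @param alpha Learning rate.
#' @param beta1,beta2,delta Optimizer moment parameters; `beta1 = NULL`
#'   selects 0.1 for penalized and 0.9 for unpenalized training.
#' @param validation Optional `list(x = , y = )` evaluated after each epoch.
#' @param seed Seed controlling the mini-batch order (weight initialization
#'   is controlled by the configuration seed).
#' @param config Optional [resnet_config()] overriding `depth`/`...`.
#' @param scad_a,mcp_gamma Shape parameters forwarded to [penalty_spec()]
#'   when `penalty` is given by name.
#' @param ... Further arguments passed to [resnet_config()].
#' @return An object of class `"resnet1d"`: the fitted `model`, the penalty
#'   `spec`, per-epoch `trace` (`train_mse`, `val_mse`), and the final
#'   `zero_fraction` of penalized weights.
#' @export
resnet1d <- function(x, y, depth = 5L, penalty = NULL, lambda = 0,
                     epochs = 15L, batch_size = 32L, alpha = 1e-3,
                     beta1 = NULL, beta2 = 0.999, delta = 1e-8,
                     validation = NULL, seed = 1L, config = NULL,
                     scad_a = 3.7, mcp_gamma = 3.0, ...) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  batch_size <- min(as.integer(batch_size), n)
  spec <- if (is.null(penalty)) NULL
          else if (inherits(penalty, "penalty_spec")) penalty
          else penalty_spec(penalty, lambda, scad_a = scad_a,
                            mcp_gamma = mcp_gamma)
  regularized <- !is.null(spec) && spec$lambda > 0
  if (is.null(beta1)) beta1 <- if (regularized) 0.1 else 0.9
  cfg <- if (!is.null(config)) config else resnet_config(depth = depth, ...)
  model <- build_resnet1d(cfg)
  if (p < model$min_len)
    stop("input length ", p, " too short for the stride plan; minimum is ",
         model$min_len)
  ocfg <- opt_config(alpha = alpha, beta1 = beta1, beta2 = beta2,
                     delta = delta)
  state <- opt_state_init(model$params)
  params <- model$params
  bn <- model$bn
  penalized <- model$penalized
  trace <- data.frame(epoch = seq_len(epochs), train_mse = NA_real_,
                      val_mse = NA_real_)
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
        xb <- to_tensor(x[idx, , drop = FALSE])
        yb <- y[idx]
        fw <- net_fwd(model, params, bn, xb, training = TRUE)
        bn <- fw$bn
        loss <- mean((fw$pred - yb)^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", e, ", batch ", bi)
        dpred <- 2 * (fw$pred - yb) / length(yb)
        grads <- net_bwd(model, params, fw$caches, dpred)
        upd <- opt_step(state, params, grads, ocfg,
                        penalty = if (regularized) spec else NULL,
                        penalized = penalized)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      trace$train_mse[e] <- ep_loss / ep_n
      if (!is.null(validation)) {
        pv <- net_predict(model, params, bn, as.matrix(validation$x))
        trace$val_mse[e] <- mse(validation$y, pv)
      }
    }
  })
  model$params <- params
  model$bn <- bn
  w <- unlist(params[penalized], use.names = FALSE)
  structure(
    list(model = model, spec = spec, trace = trace,
         zero_fraction = sparsity(w)$zero_fraction,
         opt = ocfg, epochs = epochs, batch_size = batch_size, seed = seed,
         n = n, p = p, call = match.call()),
    class = "resnet1d"
  )
}

net_predict <- function(model, params, bn, X, batch_size = 512L) {
  n <- nrow(X)
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    fw <- net_fwd(model, params, bn, to_tensor(X[idx, , drop = FALSE]),
                  training = FALSE)
    out[idx] <- fw$pred
  }
  out
}

#' @export
predict.resnet1d <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p)
    stop("`newdata` has ", ncol(X), " markers; model expects ", object$p)
  net_predict(object$model, object$model$params, object$model$bn, X)
}

#' @export
print.resnet1d <- function(x, ...) {
  plan <- x$model$cfg$plan
  cat("1D ResNet (depth ", plan$depth, ", ", plan$block, " blocks: ",
      plan$n_stem, " stem + ", plan$n_blocks, " blocks + fc)\n", sep = "")
  if (!is.null(x$spec))
    cat("  penalty: ", x$spec$kind, " lambda = ", format(x$spec$lambda),
        "\n", sep = "")
  else cat("  unregularized (Adam baseline)\n")
  cat("  parameters: ", resnet_param_count(x$model),
      ", penalized-weight zero fraction: ",
      sprintf("%.1f%%", 100 * x$zero_fraction), "\n", sep = "")
  cat("  final train MSE: ",
      format(utils::tail(x$trace$train_mse, 1L)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.resnet1d <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.resnet1d <- function(object, ...) {
  unlist(object$model$params[object$model$penalized], use.names = FALSE)
}

#' @export
plot.resnet1d <- function(x, ...) {
  tr <- x$trace
  ylim <- range(c(tr$train_mse, tr$val_mse), na.rm = TRUE)
  graphics::plot(tr$epoch, tr$train_mse, type = "l", ylim = ylim,
                 xlab = "epoch", ylab = "MSE", main = "Training trace", ...)
  if (any(!is.na(tr$val_mse)))
    graphics::lines(tr$epoch, tr$val_mse, lty = 2)
  invisible(x)
}
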