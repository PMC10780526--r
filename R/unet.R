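# Encoder-decoder (U-net style) reconstruction network.
#
# Parameters are a flat named list of arrays; convolution weights are
# matrices (k*k*Cin x Cout) in the layout the C++ kernels expect, transposed
# convolutions are (Cin x 4*Cout). Feature maps are (H, W, C) arrays.

relu <- function(x) { x[x < 0] <- 0; x }

# Channel bookkeeping per level.
unet_dims <- function(cfg) {
  ch <- cfg$encoder_channels
  d <- cfg$depth
  enc_in <- c(1L, ch[-d])  # the input image has one channel
  dec_in <- if (cfg$skip_connections) 2L * ch else ch
  list(ch = ch, depth = d, enc_in = enc_in, dec_in = dec_in)
}

#' Initialize network parameters
#'
#' He-normal initialization (sd `sqrt(2 / fan_in)`) of all convolution and
#' transposed-convolution weights, zero biases; seeded and reproducible.
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed.
#' @return Flat named list of parameter arrays.
#' @export
unet_init <- function(cfg, seed = 1) {
  dims <- unet_dims(cfg)
  k <- cfg$kernel_size
  p <- list()
  with_seed(seed, {
    he <- function(nr, nc, fan_in)
      matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
    for (l in seq_len(dims$depth)) {
      cin <- dims$enc_in[l]; cout <- dims$ch[l]
      p[[sprintf("enc%d_w1", l)]] <- he(k * k * cin, cout, k * k * cin)
      p[[sprintf("enc%d_b1", l)]] <- numeric(cout)
      p[[sprintf("enc%d_w2", l)]] <- he(k * k * cout, cout, k * k * cout)
      p[[sprintf("enc%d_b2", l)]] <- numeric(cout)
    }
    for (l in seq_len(dims$depth - 1)) {
      cup_in <- dims$ch[l + 1]; cup_out <- dims$ch[l]
      p[[sprintf("dec%d_upw", l)]] <- he(cup_in, 4 * cup_out, cup_in)
      p[[sprintf("dec%d_upb", l)]] <- numeric(cup_out)
      cin <- dims$dec_in[l]; cout <- dims$ch[l]
      p[[sprintf("dec%d_w1", l)]] <- he(k * k * cin, cout, k * k * cin)
      p[[sprintf("dec%d_b1", l)]] <- numeric(cout)
      p[[sprintf("dec%d_w2", l)]] <- he(k * k * cout, cout, k * k * cout)
      p[[sprintf("dec%d_b2", l)]] <- numeric(cout)
    }
    p[["out_w"]] <- he(dims$ch[1], cfg$output_channels, dims$ch[1])
    p[["out_b"]] <- numeric(cfg$output_channels)
  })
  p
}

# Forward pass; returns list(y, cache) when want_cache.
unet_forward <- function(params, cfg, x, want_cache = FALSE) {
  dims <- unet_dims(cfg)
  k <- cfg$kernel_size
  d <- dims$depth
  a <- array(x, dim = c(nrow(x), ncol(x), 1))
  skip <- vector("list", d)
  cache <- list(conv_in = list(), act = list(), pool_idx = vector("list", d),
                up_in = vector("list", d), up_out = vector("list", d))
  for (l in seq_len(d)) {
    cache$conv_in[[sprintf("enc%d_1", l)]] <- a
    a1 <- relu(conv_fwd_cpp(a, params[[sprintf("enc%d_w1", l)]],
                            params[[sprintf("enc%d_b1", l)]], k))
    cache$conv_in[[sprintf("enc%d_2", l)]] <- a1
    a2 <- relu(conv_fwd_cpp(a1, params[[sprintf("enc%d_w2", l)]],
                            params[[sprintf("enc%d_b2", l)]], k))
    cache$act[[sprintf("enc%d_2", l)]] <- a2
    skip[[l]] <- a2
    if (l < d) {
      pl <- maxpool_fwd_cpp(a2)
      cache$pool_idx[[l]] <- pl$idx
      a <- pl$y
    }
  }
  a <- skip[[d]]
  for (l in seq(d - 1, 1)) {
    cache$up_in[[l]] <- a
    u <- upconv_fwd_cpp(a, params[[sprintf("dec%d_upw", l)]],
                        params[[sprintf("dec%d_upb", l)]])
    cache$up_out[[l]] <- u
    ur <- relu(u)
    cat_in <- if (cfg$skip_connections) {
      ar <- array(0, dim = c(dim(ur)[1], dim(ur)[2],
                             dim(ur)[3] + dim(skip[[l]])[3]))
      ar[, , seq_len(dim(skip[[l]])[3])] <- skip[[l]]
      ar[, , dim(skip[[l]])[3] + seq_len(dim(ur)[3])] <- ur
      ar
    } else ur
    cache$conv_in[[sprintf("dec%d_1", l)]] <- cat_in
    a1 <- relu(conv_fwd_cpp(cat_in, params[[sprintf("dec%d_w1", l)]],
                            params[[sprintf("dec%d_b1", l)]], k))
    cache$conv_in[[sprintf("dec%d_2", l)]] <- a1
    a <- relu(conv_fwd_cpp(a1, params[[sprintf("dec%d_w2", l)]],
                           params[[sprintf("dec%d_b2", l)]], k))
    cache$act[[sprintf("dec%d_2", l)]] <- a
  }
  cache$conv_in[["out"]] <- a
  y <- conv_fwd_cpp(a, params[["out_w"]], params[["out_b"]], 1L)
  if (want_cache) list(y = y, cache = cache) else y
}

# Backward pass: gradient of the scalar loss w.r.t. every parameter, given
# dL/dy. Relu gradients use the cached post-activation sign.
unet_backward <- function(params, cfg, cache, dy) {
  dims <- unet_dims(cfg)
  k <- cfg$kernel_size
  d <- dims$depth
  grads <- list()
  # output 1x1 conv
  res <- conv_bwd_cpp(cache$conv_in[["out"]], params[["out_w"]], dy, 1L)
  grads[["out_w"]] <- res$dw; grads[["out_b"]] <- res$db
  da <- res$dx
  dskip <- vector("list", d)
  # decoder levels in reverse execution order (l = 1 .. d-1)
  for (l in seq_len(d - 1)) {
    a2 <- cache$act[[sprintf("dec%d_2", l)]]
    dz2 <- da * (a2 > 0)
    res <- conv_bwd_cpp(cache$conv_in[[sprintf("dec%d_2", l)]],
                        params[[sprintf("dec%d_w2", l)]], dz2, k)
    grads[[sprintf("dec%d_w2", l)]] <- res$dw
    grads[[sprintf("dec%d_b2", l)]] <- res$db
    a1 <- cache$conv_in[[sprintf("dec%d_2", l)]]
    dz1 <- res$dx * (a1 > 0)
    res <- conv_bwd_cpp(cache$conv_in[[sprintf("dec%d_1", l)]],
                        params[[sprintf("dec%d_w1", l)]], dz1, k)
    grads[[sprintf("dec%d_w1", l)]] <- res$dw
    grads[[sprintf("dec%d_b1", l)]] <- res$db
    dcat <- res$dx
    nskip <- if (cfg$skip_connections) dims$ch[l] else 0L
    if (cfg$skip_connections) {
      dskip[[l]] <- dcat[, , seq_len(nskip), drop = FALSE]
      dur <- dcat[, , nskip + seq_len(dim(dcat)[3] - nskip), drop = FALSE]
    } else dur <- dcat
    du <- dur * (cache$up_out[[l]] > 0)
    res <- upconv_bwd_cpp(cache$up_in[[l]],
                          params[[sprintf("dec%d_upw", l)]], du)
    grads[[sprintf("dec%d_upw", l)]] <- res$dw
    grads[[sprintf("dec%d_upb", l)]] <- res$db
    da <- res$dx  # gradient w.r.t. the level-(l+1) decoder output
  }
  # `da` is now the gradient w.r.t. the bottleneck (encoder level d output)
  dnext <- NULL
  for (l in seq(d, 1)) {
    a2 <- cache$act[[sprintf("enc%d_2", l)]]
    da2 <- if (l == d) da else {
      contrib <- maxpool_bwd_cpp(dnext, cache$pool_idx[[l]],
                                 dim(a2)[1], dim(a2)[2])
      if (cfg$skip_connections && !is.null(dskip[[l]]))
        contrib + dskip[[l]] else contrib
    }
    dz2 <- da2 * (a2 > 0)
    res <- conv_bwd_cpp(cache$conv_in[[sprintf("enc%d_2", l)]],
                        params[[sprintf("enc%d_w2", l)]], dz2, k)
    grads[[sprintf("enc%d_w2", l)]] <- res$dw
    grads[[sprintf("enc%d_b2", l)]] <- res$db
    a1 <- cache$conv_in[[sprintf("enc%d_2", l)]]
    dz1 <- res$dx * (a1 > 0)
    res <- conv_bwd_cpp(cache$conv_in[[sprintf("enc%d_1", l)]],
                        params[[sprintf("enc%d_w1", l)]], dz1, k)
    grads[[sprintf("enc%d_w1", l)]] <- res$dw
    grads[[sprintf("enc%d_b1", l)]] <- res$db
    dnext <- res$dx
  }
  grads
}

#' Train the reconstruction network
#'
#' Minimizes the mean squared error between network outputs and affinely
#' scaled permittivity labels with the adaptive-moment (Adam) optimizer.
#' Parameter initialization and batch sampling are seeded through
#' `tcfg$seed`, so two runs with identical inputs and seeds produce
#' identical loss histories on one platform.
#'
#' @param inputs List of input maps (square matrices of side
#'   `cfg$input_size`, as from [preprocess_signals()], possibly reduced).
#' @param labels List of ground-truth permittivity images of the same side.
#' @param cfg A [net_config()] (its `input_size` must match the data).
#' @param tcfg A [train_config()].
#' @param steps Number of optimization steps; default
#'   `epochs * ceiling(n / batch_size)`.
#' @param params Optional warm-start parameters (as from [unet_init()]).
#' @param verbose Print the loss every 50 steps.
#' @return Object of class `emtomo_unet` with elements `params`, `config`,
#'   `train_config` and `loss_history` (one MSE per step, on the scaled
#'   labels).
#' @export
train_unet <- function(inputs, labels, cfg = net_config(),
                       tcfg = train_config(), steps = NULL, params = NULL,
                       verbose = FALSE) {
  n <- length(inputs)
  if (n == 0) stop("empty training set", call. = FALSE)
  if (length(labels) != n)
    stop("inputs and labels differ in length", call. = FALSE)
  side <- cfg$input_size
  if (!all(vapply(inputs, function(m) all(dim(m) == c(side, side)),
                  logical(1))))
    stop("input maps do not match cfg$input_size", call. = FALSE)
  off <- tcfg$label_scaling["offset"]; sc <- tcfg$label_scaling["scale"]
  y <- lapply(labels, function(m) (m - off) / sc)
  if (is.null(params)) params <- unet_init(cfg, seed = tcfg$seed)
  if (is.null(steps)) steps <- tcfg$epochs * ceiling(n / tcfg$batch_size)

  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  b1 <- tcfg$adam_beta1; b2 <- tcfg$adam_beta2; eps <- tcfg$adam_eps
  loss_history <- numeric(steps)
  with_seed(tcfg$seed + 1L, {
    for (step in seq_len(steps)) {
      batch <- if (tcfg$batch_size >= n) seq_len(n)
               else sample.int(n, tcfg$batch_size)
      grads <- NULL
      loss <- 0
      for (i in batch) {
        fw <- unet_forward(params, cfg, inputs[[i]], want_cache = TRUE)
        err <- fw$y[, , 1] - y[[i]]
        loss <- loss + mean(err^2)
        dy <- array(2 * err / (length(err) * length(batch)),
                    dim = dim(fw$y))
        g <- unet_backward(params, cfg, fw$cache, dy)
        grads <- if (is.null(grads)) g
                 else Map(`+`, grads, g[names(grads)])
      }
      loss <- loss / length(batch)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at step %d", step),
             call. = FALSE)
      loss_history[step] <- loss
      for (nm in names(params)) {
        m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * grads[[nm]]
        m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- m1[[nm]] / (1 - b1^step)
        vhat <- m2[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] -
          tcfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      if (verbose && step %% 50 == 0)
        message(sprintf("step %d: mse %.5g", step, loss))
    }
  })
  fit <- list(params = params, config = cfg, train_config = tcfg,
              loss_history = loss_history, n_train = n)
  class(fit) <- "emtomo_unet"
  fit
}

#' Build an untrained network
#'
#' Convenience constructor returning an `emtomo_unet` with freshly
#' initialized parameters and an empty loss history; usable directly with
#' [predict.emtomo_unet()] or as a warm start for [train_unet()].
#'
#' @param cfg A [net_config()].
#' @param tcfg A [train_config()] (supplies the seed and label scaling).
#' @return Object of class `emtomo_unet`.
#' @export
build_unet <- function(cfg = net_config(), tcfg = train_config()) {
  fit <- list(params = unet_init(cfg, seed = tcfg$seed), config = cfg,
              train_config = tcfg, loss_history = numeric(0), n_train = 0L)
  class(fit) <- "emtomo_unet"
  fit
}

#' Predict a permittivity image
#'
#' Forward pass followed by the inverse label scaling back to permittivity
#' units.
#'
#' @param object An `emtomo_unet`.
#' @param newdata A single input-map matrix or a list of them.
#' @param ... Unused.
#' @return A permittivity matrix (or list of matrices).
#' @export
predict.emtomo_unet <- function(object, newdata, ...) {
  one <- function(x) {
    side <- object$config$input_size
    if (!all(dim(x) == c(side, side)))
      stop("input map does not match the network input size", call. = FALSE)
    y <- unet_forward(object$params, object$config, x)[, , 1]
    off <- object$train_config$label_scaling["offset"]
    sc <- object$train_config$label_scaling["scale"]
    y * sc + off
  }
  if (is.list(newdata)) lapply(newdata, one) else one(newdata)
}

#' @export
print.emtomo_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("Encoder-decoder reconstruction network (depth %d, channels %s)\n",
              x$config$depth, paste(x$config$encoder_channels,
                                    collapse = "-")))
  cat(sprintf("  input %dx%d -> bottleneck %dx%dx%d; %s parameters\n",
              x$config$input_size, x$config$input_size,
              min(encoder_sizes(x$config)), min(encoder_sizes(x$config)),
              max(x$config$encoder_channels), format(np, big.mark = ",")))
  if (length(x$loss_history))
    cat(sprintf("  trained %d steps on %d cases; final mse %.5g\n",
                length(x$loss_history), x$n_train,
                tail(x$loss_history, 1)))
  else cat("  untrained (initialized parameters)\n")
  invisible(x)
}

#' @export
summary.emtomo_unet <- function(object, ...) {
  print(object)
  if (length(object$loss_history)) {
    lh <- object$loss_history
    cat(sprintf("  loss: initial %.5g, min %.5g, final %.5g (%d steps)\n",
                lh[1], min(lh), tail(lh, 1), length(lh)))
  }
  invisible(object)
}

#' @export
plot.emtomo_unet <- function(x, ...) {
  if (!length(x$loss_history))
    stop("no loss history: network is untrained", call. = FALSE)
  plot(x$loss_history, type = "l", log = "y", xlab = "step",
       ylab = "batch MSE (scaled labels)", main = "Training loss", ...)
  invisible(x)
}

#' @export
coef.emtomo_unet <- function(object, ...) object$params

#' Save / load a trained network
#'
#' The checkpoint is a single serialized file holding parameters and both
#' configurations.
#'
#' @param object An `emtomo_unet`.
#' @param path Checkpoint file path.
#' @return `load_unet` returns the `emtomo_unet`.
#' @export
save_unet <- function(object, path) {
  stopifnot(inherits(object, "emtomo_unet"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "emtomo_unet"))
    stop("file is not a network checkpoint", call. = FALSE)
  obj
}
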