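#' Estimator configuration
#'
#' Hyperparameters of the residual convolutional Zernike regressor. Two
#' architectures are provided: `"resnet_small"` (default), a compact
#' 3-stage residual CNN sized so the full pipeline trains on one CPU, and
#' `"resnet50"`, a bottleneck residual network with stage depths
#' (3, 4, 6, 3) and a 10-unit linear head for full-scale runs. The small
#' network ends in a flatten + linear head rather than global average
#' pooling: two of the regression targets are the carrier tilts, i.e. a
#' spatial position in the Fourier channel, and average pooling would
#' discard exactly that information.
#'
#' The loss is mean squared error over the ten outputs after dividing each
#' coefficient by its `divisors` entry (by default the half-range it was
#' sampled from), so the carrier terms — roughly 600 times larger than the
#' high-order terms in raw radians — do not dominate the gradient.
#'
#' @param architecture `"resnet_small"` or `"resnet50"`.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate; decays by `lr_factor` at 60% and 85% of
#'   the epochs.
#' @param lr_factor multiplicative decay factor.
#' @param weight_decay decoupled L2 weight decay applied to convolution and
#'   linear weights (not biases or batch-norm parameters).
#' @param loss only `"mse"`.
#' @param divisors optional 10-vector of per-coefficient target scales;
#'   default derived from the dataset's sampling ranges.
#' @param input_size raster side fed to the network (default 32 for
#'   `resnet_small`, 224 for `resnet50`); triplets are resampled to it.
#' @param fourier_log input compression constant `a` for the Fourier
#'   channel: the channel is remapped by `log1p(a x) / log1p(a)` (monotone,
#'   \[0,1\] to \[0,1\]) before entering the network. The diffraction-ring
#'   tails that encode a dark-field carrier span several decades of
#'   intensity, so after min-max normalization they occupy only the bottom
#'   few percent of the linear range; logarithmic display is the standard
#'   remedy for Fourier magnitudes and it is applied here as model-input
#'   preprocessing. Set to 0 to disable.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return object of class `estimator_config`.
#' @export
estimator_config <- function(architecture = c("resnet_small", "resnet50"),
                             epochs = 30L, batch_size = 32L, lr = 2e-3,
                             lr_factor = 0.3, weight_decay = 3e-4,
                             loss = "mse", divisors = NULL,
                             input_size = NULL, fourier_log = 1000,
                             seed = 1L) {
  architecture <- match.arg(architecture)
  if (epochs < 1) stop("epochs must be >= 1")
  if (!identical(loss, "mse")) stop("only mse loss is supported")
  if (!is.null(divisors) && any(divisors <= 0)) stop("divisors must be > 0")
  if (fourier_log < 0) stop("fourier_log must be >= 0")
  if (is.null(input_size))
    input_size <- if (architecture == "resnet50") 224L else 32L
  structure(list(architecture = architecture, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_factor = lr_factor, weight_decay = weight_decay,
                 loss = loss, divisors = divisors,
                 input_size = as.integer(input_size),
                 fourier_log = fourier_log, seed = as.integer(seed)),
            class = "estimator_config")
}

# ---- architecture builders -------------------------------------------------
# A network is a flat list of primitive ops; residual connections are
# expressed with "push" (remember the activation) and "add" (pop and add,
# through an optional 1x1 projection when shape changes).

op_conv <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad,
       W = NULL, b = NULL)
}
op_bn <- function(ch) list(type = "bn", ch = ch, gamma = NULL, beta = NULL,
                           run_mean = NULL, run_var = NULL)
op <- function(type, ...) c(list(type = type), list(...))

basic_block <- function(ch) {
  c(list(op("push")),
    list(op_conv(ch, ch, 3L), op_bn(ch), op("relu"),
         op_conv(ch, ch, 3L), op_bn(ch),
         op("add", proj = NULL), op("relu")))
}

bottleneck_block <- function(in_ch, mid, out_ch, stride) {
  proj <- if (in_ch != out_ch || stride != 1L)
    list(conv = op_conv(in_ch, out_ch, 1L, stride, 0L), bn = op_bn(out_ch))
  c(list(op("push")),
    list(op_conv(in_ch, mid, 1L, stride, 0L), op_bn(mid), op("relu"),
         op_conv(mid, mid, 3L), op_bn(mid), op("relu"),
         op_conv(mid, out_ch, 1L, 1L, 0L), op_bn(out_ch),
         op("add", proj = proj), op("relu")))
}

build_arch <- function(architecture, in_ch = 3L, input_size = 32L) {
  if (architecture == "resnet_small") {
    widths <- c(16L, 32L, 64L)
    ops <- list(op_conv(in_ch, widths[1], 5L, 2L, 2L), op_bn(widths[1]),
                op("relu"))
    ops <- c(ops, basic_block(widths[1]))
    for (i in 2:3) {
      ops <- c(ops, list(op_conv(widths[i - 1], widths[i], 3L, 2L, 1L),
                         op_bn(widths[i]), op("relu")))
      ops <- c(ops, basic_block(widths[i]))
    }
    # flatten head: the targets include the carrier position, so the final
    # feature map is flattened rather than globally pooled — average pooling
    # would discard exactly the spatial information the tilt terms encode.
    s <- input_size
    for (i in 1:3) s <- (s - 1L) %/% 2L + 1L   # three stride-2 convs
    c(ops, list(op("flatten"),
                op("fc", in_ch = widths[3] * s * s, out_ch = 10L,
                   W = NULL, b = NULL)))
  } else {  # resnet50-style: bottleneck stages (3, 4, 6, 3)
    depths <- c(3L, 4L, 6L, 3L)
    mids <- c(64L, 128L, 256L, 512L)
    ops <- list(op_conv(in_ch, 64L, 7L, 2L, 3L), op_bn(64L), op("relu"),
                op("maxpool", k = 3L, stride = 2L))
    ch <- 64L
    for (s in 1:4) {
      for (b in seq_len(depths[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        ops <- c(ops, bottleneck_block(ch, mids[s], mids[s] * 4L, stride))
        ch <- mids[s] * 4L
      }
    }
    c(ops, list(op("gap"), op("fc", in_ch = ch, out_ch = 10L,
                              W = NULL, b = NULL)))
  }
}

init_params <- function(ops) {
  init_conv <- function(o) {
    fan_in <- o$in_ch * o$k^2
    o$W <- matrix(stats::rnorm(o$out_ch * fan_in, sd = sqrt(2 / fan_in)),
                  o$out_ch, fan_in)
    o$b <- numeric(o$out_ch)
    o
  }
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    if (o$type == "conv") ops[[i]] <- init_conv(o)
    if (o$type == "bn") {
      ops[[i]]$gamma <- rep(1, o$ch); ops[[i]]$beta <- numeric(o$ch)
      ops[[i]]$run_mean <- numeric(o$ch); ops[[i]]$run_var <- rep(1, o$ch)
    }
    if (o$type == "fc") {
      ops[[i]]$W <- matrix(stats::rnorm(o$out_ch * o$in_ch,
                                        sd = sqrt(1 / o$in_ch)),
                           o$out_ch, o$in_ch)
      ops[[i]]$b <- numeric(o$out_ch)
    }
    if (o$type == "add" && !is.null(o$proj)) {
      ops[[i]]$proj$conv <- init_conv(o$proj$conv)
      ops[[i]]$proj$bn$gamma <- rep(1, o$proj$bn$ch)
      ops[[i]]$proj$bn$beta <- numeric(o$proj$bn$ch)
      ops[[i]]$proj$bn$run_mean <- numeric(o$proj$bn$ch)
      ops[[i]]$proj$bn$run_var <- rep(1, o$proj$bn$ch)
    }
  }
  ops
}

# ---- batchnorm (training-mode batch stats, running stats for inference) ----

bn_fwd <- function(x, o, training, momentum = 0.9) {
  r <- bn_fwd_cpp(x, o$gamma, o$beta, o$run_mean, o$run_var, training, 1e-5)
  if (training) {
    o$run_mean <- momentum * o$run_mean + (1 - momentum) * r$mu
    o$run_var <- momentum * o$run_var + (1 - momentum) * r$var
  }
  list(out = r$out, cache = list(xhat = r$xhat, sd = r$sd), op = o)
}

bn_bwd <- function(dout, o, cache) {
  bn_bwd_cpp(dout, cache$xhat, cache$sd, o$gamma)
}

# ---- forward / backward through the op list --------------------------------

net_forward <- function(ops, x, training = FALSE) {
  caches <- vector("list", length(ops))
  stack <- list()
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    if (o$type == "conv") {
      r <- conv_fwd(x, o$W, o$b, o$k, o$stride, o$pad, training)
      caches[[i]] <- list(xdim = dim(x), cols = r$cols)
      x <- r$out
    } else if (o$type == "bn") {
      r <- bn_fwd(x, o, training)
      ops[[i]] <- r$op
      caches[[i]] <- r$cache
      x <- r$out
    } else if (o$type == "relu") {
      x <- pmax(x, 0)
      caches[[i]] <- list(mask = x > 0)
    } else if (o$type == "maxpool") {
      r <- maxpool_fwd(x, o$k, o$stride)
      caches[[i]] <- list(xdim = dim(x), argmax = r$argmax)
      x <- r$out
    } else if (o$type == "push") {
      stack[[length(stack) + 1L]] <- x
    } else if (o$type == "add") {
      skip <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (!is.null(o$proj)) {
        pr <- conv_fwd(skip, o$proj$conv$W, o$proj$conv$b, o$proj$conv$k,
                       o$proj$conv$stride, o$proj$conv$pad, training)
        pb <- bn_fwd(pr$out, o$proj$bn, training)
        ops[[i]]$proj$bn <- pb$op
        caches[[i]] <- list(skip_dim = dim(skip), cols = pr$cols,
                            bn_cache = pb$cache)
        skip <- pb$out
      }
      x <- x + skip
    } else if (o$type == "gap") {
      d <- dim(x)
      caches[[i]] <- list(xdim = d)
      x <- matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
    } else if (o$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(xdim = d)
      x <- matrix(x, d[1] * d[2] * d[3], d[4])
    } else if (o$type == "fc") {
      caches[[i]] <- list(xin = x)
      x <- o$W %*% x + o$b
    }
  }
  list(out = x, caches = caches, ops = ops)
}

net_backward <- function(ops, caches, dout) {
  grads <- vector("list", length(ops))
  stack <- list()   # gradients waiting for their "push"
  dx <- dout
  for (i in rev(seq_along(ops))) {
    o <- ops[[i]]
    if (o$type == "conv") {
      r <- conv_bwd(dx, caches[[i]]$cols, o$W, caches[[i]]$xdim,
                    o$k, o$stride, o$pad)
      grads[[i]] <- list(W = r$dW, b = r$db)
      dx <- r$dx
    } else if (o$type == "bn") {
      r <- bn_bwd(dx, o, caches[[i]])
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dx <- r$dx
    } else if (o$type == "relu") {
      dx <- dx * caches[[i]]$mask
    } else if (o$type == "maxpool") {
      dx <- maxpool_bwd(dx, caches[[i]]$argmax, caches[[i]]$xdim)
    } else if (o$type == "add") {
      dskip <- dx
      if (!is.null(o$proj)) {
        ca <- caches[[i]]
        rb <- bn_bwd(dskip, o$proj$bn, ca$bn_cache)
        rc <- conv_bwd(rb$dx, ca$cols, o$proj$conv$W, ca$skip_dim,
                       o$proj$conv$k, o$proj$conv$stride, o$proj$conv$pad)
        grads[[i]] <- list(proj_conv_W = rc$dW, proj_conv_b = rc$db,
                           proj_bn_gamma = rb$dgamma, proj_bn_beta = rb$dbeta)
        dskip <- rc$dx
      }
      stack[[length(stack) + 1L]] <- dskip
    } else if (o$type == "push") {
      dx <- dx + stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
    } else if (o$type == "gap") {
      d <- caches[[i]]$xdim
      dx <- array(rep(as.vector(dx), each = d[1] * d[2]) / (d[1] * d[2]), d)
    } else if (o$type == "flatten") {
      dx <- array(dx, caches[[i]]$xdim)
    } else if (o$type == "fc") {
      grads[[i]] <- list(W = dx %*% t(caches[[i]]$xin), b = rowSums(dx))
      dx <- t(o$W) %*% dx
    }
  }
  grads
}

# ---- Adam over the op list -------------------------------------------------

adam_init <- function(ops) {
  lapply(ops, function(o) NULL)
}

param_names <- function(o) {
  switch(o$type,
         conv = c("W", "b"), fc = c("W", "b"), bn = c("gamma", "beta"),
         add = if (!is.null(o$proj))
           c("proj_conv_W", "proj_conv_b", "proj_bn_gamma", "proj_bn_beta"),
         NULL)
}

get_param <- function(o, nm) {
  switch(nm,
         proj_conv_W = o$proj$conv$W, proj_conv_b = o$proj$conv$b,
         proj_bn_gamma = o$proj$bn$gamma, proj_bn_beta = o$proj$bn$beta,
         o[[nm]])
}

set_param <- function(o, nm, val) {
  switch(nm,
         proj_conv_W = { o$proj$conv$W <- val; o },
         proj_conv_b = { o$proj$conv$b <- val; o },
         proj_bn_gamma = { o$proj$bn$gamma <- val; o },
         proj_bn_beta = { o$proj$bn$beta <- val; o },
         { o[[nm]] <- val; o })
}

adam_step <- function(ops, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  decayed <- c("W", "proj_conv_W")
  for (i in seq_along(ops)) {
    nms <- param_names(ops[[i]])
    if (is.null(nms) || is.null(grads[[i]])) next
    if (is.null(state[[i]])) state[[i]] <- list()
    for (nm in nms) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      p <- get_param(ops[[i]], nm)
      if (nm %in% decayed && weight_decay > 0) p <- p * (1 - lr * weight_decay)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
      ops[[i]] <- set_param(ops[[i]], nm, p)
      state[[i]][[nm]] <- st
    }
  }
  list(ops = ops, state = state)
}

# ---- data plumbing ---------------------------------------------------------

#' Stack diffraction triplets into a network input array
#'
#' @param triplets list of [render_triplet()] results.
#' @param size raster side after resampling.
#' @return array \[size, size, 3, N\].
#' @export
triplets_to_array <- function(triplets, size) {
  N <- length(triplets)
  X <- array(0, c(size, size, 3L, N))
  for (i in seq_len(N)) {
    img <- triplets[[i]]$image
    for (ch in 1:3) X[, , ch, i] <- resample_to(img[, , ch], size)
  }
  X
}

resolve_dataset <- function(data) {
  if (is.character(data)) data <- load_dataset(data)
  if (is.list(data) && !is.null(data$triplets)) return(data)
  if (is.list(data) && all(vapply(data, inherits, TRUE, "diffraction_triplet")))
    return(list(triplets = data,
                labels = data.frame(id = seq_along(data),
                                    t(vapply(data, function(t) t$label,
                                             numeric(10))))))
  stop("data must be a dataset manifest, directory, or list of triplets")
}

default_divisors <- function(ranges) {
  c(ranges$z0, ranges$tilt, ranges$tilt, rep(ranges$high_order, 7))
}

# monotone log compression of the Fourier channel (see estimator_config)
apply_input_transform <- function(X, fourier_log) {
  if (is.null(fourier_log) || fourier_log <= 0) return(X)
  X[, , 1, ] <- log1p(fourier_log * X[, , 1, ]) / log1p(fourier_log)
  X
}

# ---- fitting ---------------------------------------------------------------

#' Fit the residual CNN Zernike-coefficient regressor
#'
#' Trains a convolutional network to regress the ten Zernike coefficients of
#' the illumination aberration from a three-channel diffraction image
#' (Fourier / focal / out-of-focus intensities). Targets are scaled by
#' per-coefficient divisors; the loss is MSE on the scaled targets; the
#' optimizer is Adam with step decay. Validation loss is computed on the
#' held-out split after every epoch, and also once before training (epoch
#' 0), which serves as the untrained baseline.
#'
#' Training is deterministic for a fixed `config$seed` on a single-threaded
#' BLAS; multi-threaded BLAS backends may reorder floating-point sums.
#'
#' @param data a [build_dataset()] manifest (in-memory or directory), a
#'   dataset directory path, or a list of triplets.
#' @param config an [estimator_config()].
#' @param split fraction of samples used for training, in (0, 1); the rest
#'   validate.
#' @param verbose print per-epoch losses.
#' @return object of class `zernike_estimator` with elements `ops` (the
#'   trained weights), `history` (data.frame epoch/train_loss/val_loss),
#'   `divisors`, `config`, `input_size`, `val_index`, and the
#'   per-coefficient validation MSE in raw coefficient units (radians^2)
#'   before training (`val_mse0`, the untrained epoch-0 network) and after
#'   (`val_mse`).
#' @export
fit_zernike_estimator <- function(data, config = estimator_config(),
                                  split = 0.8, verbose = FALSE) {
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)")
  data <- resolve_dataset(data)
  if (length(data$triplets) == 0) stop("empty dataset")
  divisors <- config$divisors
  if (is.null(divisors))
    divisors <- if (!is.null(data$ranges))
      default_divisors(data$ranges) else default_divisors(sampling_ranges())

  set.seed(config$seed)
  S <- config$input_size
  X <- apply_input_transform(triplets_to_array(data$triplets, S),
                             config$fourier_log)
  Y <- t(vapply(data$triplets, function(t) as.numeric(t$label), numeric(10)))
  Ys <- t(Y) / divisors                       # 10 x N, scaled
  N <- dim(X)[4]
  n_train <- floor(split * N)
  if (n_train < 1 || n_train >= N) stop("split leaves an empty partition")
  perm <- sample.int(N)
  idx_tr <- perm[seq_len(n_train)]
  idx_va <- perm[(n_train + 1):N]

  ops <- init_params(build_arch(config$architecture,
                                input_size = config$input_size))
  state <- adam_init(ops)
  decay_at <- unique(pmax(1L, floor(config$epochs * c(0.6, 0.85))))

  val_loss <- function(ops) {
    bs <- 128L
    tot <- 0
    for (b in split(idx_va, ceiling(seq_along(idx_va) / bs))) {
      fw <- net_forward(ops, X[, , , b, drop = FALSE], training = FALSE)
      tot <- tot + sum((fw$out - Ys[, b, drop = FALSE])^2)
    }
    tot / (10 * length(idx_va))
  }
  # per-coefficient validation MSE in raw coefficient units (radians^2)
  val_mse_raw <- function(ops) {
    sse <- numeric(10)
    for (b in split(idx_va, ceiling(seq_along(idx_va) / 128L))) {
      fw <- net_forward(ops, X[, , , b, drop = FALSE], training = FALSE)
      sse <- sse + rowSums((fw$out * divisors - t(Y[b, , drop = FALSE]))^2)
    }
    stats::setNames(sse / length(idx_va), paste0("c", 0:9))
  }
  val_mse0 <- val_mse_raw(ops)

  history <- data.frame(epoch = 0L, train_loss = NA_real_,
                        val_loss = val_loss(ops))
  lr <- config$lr
  t_step <- 0L
  for (ep in seq_len(config$epochs)) {
    if (ep %in% decay_at) lr <- lr * config$lr_factor
    ord <- sample(idx_tr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (b in batches) {
      fw <- net_forward(ops, X[, , , b, drop = FALSE], training = TRUE)
      ops <- fw$ops                            # BN running stats
      resid <- fw$out - Ys[, b, drop = FALSE]
      tr_loss <- tr_loss + sum(resid^2)
      dout <- 2 * resid / length(resid)
      grads <- net_backward(ops, fw$caches, dout)
      t_step <- t_step + 1L
      upd <- adam_step(ops, grads, state, lr, t_step,
                       weight_decay = config$weight_decay)
      ops <- upd$ops; state <- upd$state
    }
    history <- rbind(history,
                     data.frame(epoch = ep,
                                train_loss = tr_loss / (10 * length(ord)),
                                val_loss = val_loss(ops)))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      history$train_loss[ep + 1], history$val_loss[ep + 1]))
  }

  structure(list(ops = ops, history = history, divisors = divisors,
                 config = config, input_size = S,
                 n_train = length(idx_tr), n_val = length(idx_va),
                 val_index = idx_va,
                 val_mse0 = val_mse0, val_mse = val_mse_raw(ops)),
            class = "zernike_estimator")
}

#' @export
print.zernike_estimator <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("zernike_estimator (%s, input %dpx): %d train / %d val,",
                     " %d epochs\n  val loss %.5f -> %.5f (scaled MSE)\n"),
              x$config$architecture, x$input_size, x$n_train, x$n_val,
              max(h$epoch), h$val_loss[1], h$val_loss[nrow(h)]))
  invisible(x)
}

#' @export
plot.zernike_estimator <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_loss, type = "l", col = "blue",
                 xlab = "epoch", ylab = "scaled MSE loss",
                 ylim = range(c(h$val_loss, h$train_loss), na.rm = TRUE), ...)
  graphics::lines(h$epoch[-1], h$train_loss[-1], col = "red")
  graphics::legend("topright", c("train", "validation"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Predict Zernike coefficients from diffraction images
#'
#' @param object a fitted [fit_zernike_estimator()] model.
#' @param newdata a `diffraction_triplet`, a list of them, or an array
#'   \[S, S, 3, N\]; channel layout must match training (Fourier, focal,
#'   out-of-focus).
#' @param ... unused.
#' @return numeric matrix N x 10 of coefficients in radians (a named vector
#'   for a single triplet); row order follows the input order.
#' @export
predict.zernike_estimator <- function(object, newdata, ...) {
  single <- inherits(newdata, "diffraction_triplet")
  if (single) newdata <- list(newdata)
  if (is.list(newdata) && !is.array(newdata))
    newdata <- triplets_to_array(newdata, object$input_size)
  d <- dim(newdata)
  if (length(d) == 3L) newdata <- array(newdata, c(d, 1L))
  if (dim(newdata)[3] != 3L) stop("expected 3 channels")
  if (dim(newdata)[1] != object$input_size) {
    res <- array(0, c(object$input_size, object$input_size, 3L, dim(newdata)[4]))
    for (i in seq_len(dim(newdata)[4]))
      for (ch in 1:3)
        res[, , ch, i] <- resample_to(newdata[, , ch, i], object$input_size)
    newdata <- res
  }
  newdata <- apply_input_transform(newdata, object$config$fourier_log)
  preds <- NULL
  for (b in split(seq_len(dim(newdata)[4]),
                  ceiling(seq_len(dim(newdata)[4]) / 128))) {
    fw <- net_forward(object$ops, newdata[, , , b, drop = FALSE],
                      training = FALSE)
    preds <- cbind(preds, fw$out * object$divisors)
  }
  out <- t(preds)
  colnames(out) <- paste0("c", 0:9)
  if (single) zernike_coefficients(out[1, ]) else out
}

#' Per-coefficient error table of a fitted estimator
#'
#' @param model a `zernike_estimator`.
#' @param data labeled test data (manifest, directory, or triplet list).
#' @param out_csv optional path: write the table as CSV.
#' @return data.frame with columns sample_id, n, true, predicted, abs_err,
#'   rel_err; aggregates (per-coefficient mean/max absolute error) in
#'   attribute `"aggregates"`.
#' @export
evaluate_estimator <- function(model, data, out_csv = NULL) {
  data <- resolve_dataset(data)
  truth <- t(vapply(data$triplets, function(t) as.numeric(t$label),
                    numeric(10)))
  pred <- predict(model, data$triplets)
  tab <- data.frame(sample_id = rep(seq_len(nrow(truth)), each = 10L),
                    n = rep(0:9, times = nrow(truth)),
                    true = as.vector(t(truth)),
                    predicted = as.vector(t(pred)))
  tab$abs_err <- abs(tab$predicted - tab$true)
  tab$rel_err <- tab$abs_err / pmax(abs(tab$true), .Machine$double.eps)
  agg <- do.call(rbind, lapply(0:9, function(n) {
    e <- tab$abs_err[tab$n == n]
    data.frame(n = n, mean_abs_err = mean(e), max_abs_err = max(e))
  }))
  attr(tab, "aggregates") <- agg
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}

#' Save / load a fitted estimator artifact
#'
#' The artifact directory holds `architecture.json` (architecture name,
#' config, scaling constants) and `weights.rds` (the op list); predictions
#' are reproducible from the artifact alone.
#'
#' @param model a `zernike_estimator`.
#' @param dir artifact directory.
#' @return `dir` / the reloaded model.
#' @export
save_estimator <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(architecture = model$config$architecture,
                            input_size = model$input_size,
                            divisors = model$divisors,
                            config = unclass(model$config)),
                       file.path(dir, "architecture.json"),
                       digits = NA, auto_unbox = TRUE)
  saveRDS(model$ops, file.path(dir, "weights.rds"))
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  cfgl <- meta$config
  cfgl$divisors <- unlist(cfgl$divisors)
  cfg <- do.call(estimator_config, cfgl)
  hist <- tryCatch(utils::read.csv(file.path(dir, "history.csv")),
                   error = function(e) NULL)
  structure(list(ops = readRDS(file.path(dir, "weights.rds")),
                 history = hist, divisors = unlist(meta$divisors),
                 config = cfg, input_size = meta$input_size,
                 n_train = NA_integer_, n_val = NA_integer_),
            class = "zernike_estimator")
}
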