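#' Configuration for the residual CNN regressors
#'
#' Defaults follow the training recipe used for the full-size networks:
#' 224 x 224 x 3 input, batch size 16, Adam at learning rate 1e-3, up to
#' 1000 epochs, a composite MSE + lambda * L1 loss, and a
#' squeeze-and-excitation channel reduction of 1/8. The `tiny` variant is a
#' three-stage reduction of the same design (about 10^5 parameters,
#' 64 x 64 input, 30 epochs by default) sized so that training completes in
#' minutes on one CPU core; it is the default for experiments in this
#' package.
#'
#' @param variant `"full"` (50-layer bottleneck layout) or `"tiny"`
#'   (3-stage basic-block layout).
#' @param input_size square input size in pixels (default 224; tiny: 64).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 1000; tiny: 30).
#' @param lambda_l1 weight of the L1 term in the composite
#'   MSE + lambda * L1 loss (default 1: equally weighted).
#' @param lr_decay per-epoch learning-rate schedule: `"cosine"` (default)
#'   anneals from the initial rate to zero over the run, which settles the
#'   late-training oscillation of a constant-rate Adam; `"constant"` keeps
#'   the initial rate throughout.
#' @param se_reduction SE channel reduction ratio r (default 8, i.e. a
#'   compression rate of 1/8); must divide every gated channel count.
#' @param target_scale masses (mg) are divided by this during training for
#'   optimiser stability and rescaled at prediction (default 500 mg).
#' @param bn_momentum running-statistics momentum of batch normalisation.
#' @param seed RNG seed controlling weight initialisation and shuffling.
#' @return Object of class `regressor_config`.
#' @export
regressor_config <- function(variant = c("full", "tiny"),
                             input_size = NULL, batch_size = 16L,
                             learning_rate = 1e-3, epochs = NULL,
                             lambda_l1 = 1, se_reduction = 8L,
                             lr_decay = c("cosine", "constant"),
                             target_scale = 500, bn_momentum = 0.1,
                             seed = 1L) {
  variant <- match.arg(variant)
  lr_decay <- match.arg(lr_decay)
  input_size <- as.integer(input_size %||%
                             if (variant == "tiny") 64L else 224L)
  epochs <- as.integer(epochs %||% if (variant == "tiny") 30L else 1000L)
  if (input_size < 32L) stop("`input_size` must be >= 32", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (lambda_l1 < 0) stop("`lambda_l1` must be >= 0", call. = FALSE)
  if (se_reduction < 1L) stop("`se_reduction` must be >= 1", call. = FALSE)
  structure(list(variant = variant, input_size = input_size,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = epochs,
                 lambda_l1 = lambda_l1,
                 se_reduction = as.integer(se_reduction),
                 lr_decay = lr_decay,
                 target_scale = target_scale, bn_momentum = bn_momentum,
                 seed = as.integer(seed)),
            class = "regressor_config")
}

# Architecture tables. A block descriptor holds its unit names so that
# forward, backward and initialisation all walk the same structure.
cnn_arch <- function(variant, kind, se_reduction) {
  se <- identical(kind, "se_resnet")
  if (variant == "tiny") {
    blocks <- list(
      list(type = "basic", name = "s1b1", cin = 16L, cout = 16L, stride = 1L),
      list(type = "basic", name = "s2b1", cin = 16L, cout = 32L, stride = 2L),
      list(type = "basic", name = "s3b1", cin = 32L, cout = 64L, stride = 2L)
    )
    stem <- list(k = 3L, stride = 2L, pad = 1L, cout = 16L, maxpool = FALSE)
    head_ch <- 64L
  } else {
    mids <- c(64L, 128L, 256L, 512L)
    counts <- c(3L, 4L, 6L, 3L)
    blocks <- list()
    cin <- 64L
    for (s in 1:4) {
      for (b in seq_len(counts[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        cout <- 4L * mids[s]
        blocks[[length(blocks) + 1L]] <- list(
          type = "bottleneck", name = sprintf("s%db%d", s, b),
          cin = cin, mid = mids[s], cout = cout, stride = stride)
        cin <- cout
      }
    }
    stem <- list(k = 7L, stride = 2L, pad = 3L, cout = 64L, maxpool = TRUE)
    head_ch <- 2048L
  }
  if (se) {
    for (i in seq_along(blocks)) {
      if (blocks[[i]]$cout %% se_reduction != 0L) {
        stop(sprintf(paste0("SE reduction r = %d does not divide the gated ",
                            "channel count %d of block %s"),
                     se_reduction, blocks[[i]]$cout, blocks[[i]]$name),
             call. = FALSE)
      }
      blocks[[i]]$se <- TRUE
    }
  } else {
    for (i in seq_along(blocks)) blocks[[i]]$se <- FALSE
  }
  list(stem = stem, blocks = blocks, head_ch = head_ch, se = se)
}

he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

init_conv_bn <- function(store, name, cin, k, cout) {
  store$params[[paste0(name, ".W")]] <- he_init(cin * k * k,
                                                c(cin, k, k, cout))
  store$params[[paste0(name, ".b")]] <- numeric(cout)
  store$params[[paste0(name, ".gamma")]] <- rep(1, cout)
  store$params[[paste0(name, ".beta")]] <- numeric(cout)
  store$running[[paste0(name, ".mean")]] <- numeric(cout)
  store$running[[paste0(name, ".var")]] <- rep(1, cout)
  invisible(store)
}

init_se <- function(store, name, C, r) {
  cr <- C %/% r
  store$params[[paste0(name, ".se.w1")]] <- matrix(
    stats::rnorm(cr * C, sd = sqrt(2 / C)), cr, C)
  store$params[[paste0(name, ".se.b1")]] <- numeric(cr)
  store$params[[paste0(name, ".se.w2")]] <- matrix(
    stats::rnorm(C * cr, sd = sqrt(2 / cr)), C, cr)
  store$params[[paste0(name, ".se.b2")]] <- numeric(C)
  invisible(store)
}

#' Build a residual CNN regressor
#'
#' Constructs an untrained residual network mapping an RGB sponge crop to a
#' single Hb-mass scalar. The `resnet` kind is a plain residual network:
#' a strided stem convolution, batch-normalised residual blocks arranged in
#' stages, global average pooling and a one-unit linear head. The
#' `se_resnet` kind inserts a squeeze-and-excitation channel-attention block
#' after the final convolution of every residual block, before the residual
#' addition. The `full` variant follows the standard 50-layer bottleneck
#' layout (stages of 3/4/6/3 blocks); the `tiny` variant keeps the same
#' design at three basic-block stages for CPU-scale experiments.
#'
#' @param kind `"resnet"` or `"se_resnet"`.
#' @param config a [regressor_config()].
#' @return Object of class `hb_cnn` (untrained; see [train_hb_cnn()]).
#' @export
build_regressor <- function(kind = c("resnet", "se_resnet"),
                            config = regressor_config(variant = "tiny")) {
  kind <- match.arg(kind)
  arch <- cnn_arch(config$variant, kind, config$se_reduction)
  store <- new.env(parent = emptyenv())
  store$params <- list()
  store$running <- list()
  with_seed(config$seed, {
    init_conv_bn(store, "stem", 3L, arch$stem$k, arch$stem$cout)
    for (blk in arch$blocks) {
      if (blk$type == "basic") {
        init_conv_bn(store, paste0(blk$name, ".conv1"), blk$cin, 3L, blk$cout)
        init_conv_bn(store, paste0(blk$name, ".conv2"), blk$cout, 3L, blk$cout)
      } else {
        init_conv_bn(store, paste0(blk$name, ".conv1"), blk$cin, 1L, blk$mid)
        init_conv_bn(store, paste0(blk$name, ".conv2"), blk$mid, 3L, blk$mid)
        init_conv_bn(store, paste0(blk$name, ".conv3"), blk$mid, 1L, blk$cout)
      }
      if (blk$stride != 1L || blk$cin != blk$cout) {
        init_conv_bn(store, paste0(blk$name, ".down"), blk$cin, 1L, blk$cout)
      }
      if (blk$se) init_se(store, blk$name, blk$cout, config$se_reduction)
    }
    store$params[["head.W"]] <- matrix(
      stats::rnorm(arch$head_ch, sd = sqrt(1 / arch$head_ch)), 1L,
      arch$head_ch)
    store$params[["head.b"]] <- 0
  })
  structure(list(kind = kind, config = config, arch = arch,
                 params = store$params, running = store$running,
                 trained = FALSE, history = NULL),
            class = "hb_cnn")
}

# conv + bn (+ optional relu) unit. Returns out, caches, running updates.
unit_forward <- function(params, running, name, x, stride, pad, training,
                         momentum, keep_cache) {
  cv <- conv_forward(x, params[[paste0(name, ".W")]],
                     params[[paste0(name, ".b")]], stride, pad, keep_cache)
  bn <- bn_forward(cv$out, params[[paste0(name, ".gamma")]],
                   params[[paste0(name, ".beta")]],
                   running[[paste0(name, ".mean")]],
                   running[[paste0(name, ".var")]],
                   training, momentum, keep_cache = keep_cache)
  list(out = bn$out,
       cache = list(conv = cv$cache, bn = bn$cache),
       running = list(mean = bn$running_mean, var = bn$running_var))
}

unit_backward <- function(dout, cache, name, grads) {
  bnb <- bn_backward(dout, cache$bn)
  grads[[paste0(name, ".gamma")]] <- bnb$dgamma
  grads[[paste0(name, ".beta")]] <- bnb$dbeta
  cvb <- conv_backward(bnb$dx, cache$conv)
  grads[[paste0(name, ".W")]] <- cvb$dW
  grads[[paste0(name, ".b")]] <- cvb$db
  list(dx = cvb$dx, grads = grads)
}

net_forward <- function(model, x, training = FALSE, keep_cache = training) {
  params <- model$params
  running <- model$running
  mom <- model$config$bn_momentum
  arch <- model$arch
  caches <- list(blocks = vector("list", length(arch$blocks)))

  u <- unit_forward(params, running, "stem", x, arch$stem$stride,
                    arch$stem$pad, training, mom, keep_cache)
  running[["stem.mean"]] <- u$running$mean
  running[["stem.var"]] <- u$running$var
  r <- relu_forward(u$out)
  caches$stem <- list(unit = u$cache, relu = r$cache)
  h <- r$out
  if (arch$stem$maxpool) {
    mp <- maxpool_forward(h, keep_cache = keep_cache)
    caches$stem$pool <- mp$cache
    h <- mp$out
  }

  for (i in seq_along(arch$blocks)) {
    blk <- arch$blocks[[i]]
    bc <- list()
    identity_in <- h
    if (blk$type == "basic") {
      u1 <- unit_forward(params, running, paste0(blk$name, ".conv1"), h,
                         blk$stride, 1L, training, mom, keep_cache)
      r1 <- relu_forward(u1$out)
      u2 <- unit_forward(params, running, paste0(blk$name, ".conv2"), r1$out,
                         1L, 1L, training, mom, keep_cache)
      body <- u2$out
      bc$u1 <- u1$cache; bc$r1 <- r1$cache; bc$u2 <- u2$cache
      run_updates <- list(u1 = u1$running, u2 = u2$running)
      unit_names <- paste0(blk$name, c(".conv1", ".conv2"))
    } else {
      u1 <- unit_forward(params, running, paste0(blk$name, ".conv1"), h,
                         1L, 0L, training, mom, keep_cache)
      r1 <- relu_forward(u1$out)
      u2 <- unit_forward(params, running, paste0(blk$name, ".conv2"), r1$out,
                         blk$stride, 1L, training, mom, keep_cache)
      r2 <- relu_forward(u2$out)
      u3 <- unit_forward(params, running, paste0(blk$name, ".conv3"), r2$out,
                         1L, 0L, training, mom, keep_cache)
      body <- u3$out
      bc$u1 <- u1$cache; bc$r1 <- r1$cache; bc$u2 <- u2$cache
      bc$r2 <- r2$cache; bc$u3 <- u3$cache
      run_updates <- list(u1 = u1$running, u2 = u2$running, u3 = u3$running)
      unit_names <- paste0(blk$name, c(".conv1", ".conv2", ".conv3"))
    }
    for (j in seq_along(unit_names)) {
      running[[paste0(unit_names[j], ".mean")]] <- run_updates[[j]]$mean
      running[[paste0(unit_names[j], ".var")]] <- run_updates[[j]]$var
    }
    if (blk$se) {
      se <- se_forward(body,
                       params[[paste0(blk$name, ".se.w1")]],
                       params[[paste0(blk$name, ".se.b1")]],
                       params[[paste0(blk$name, ".se.w2")]],
                       params[[paste0(blk$name, ".se.b2")]],
                       keep_cache)
      body <- se$out
      bc$se <- se$cache
    }
    if (blk$stride != 1L || blk$cin != blk$cout) {
      ud <- unit_forward(params, running, paste0(blk$name, ".down"),
                         identity_in, blk$stride, 0L, training, mom,
                         keep_cache)
      running[[paste0(blk$name, ".down.mean")]] <- ud$running$mean
      running[[paste0(blk$name, ".down.var")]] <- ud$running$var
      shortcut <- ud$out
      bc$down <- ud$cache
    } else {
      shortcut <- identity_in
    }
    summed <- body + shortcut
    rout <- relu_forward(summed)
    bc$rout <- rout$cache
    caches$blocks[[i]] <- bc
    h <- rout$out
  }

  g <- gap_forward(h)
  caches$gap <- g$cache
  pred <- as.vector(params[["head.W"]] %*% g$out + params[["head.b"]])
  caches$head_in <- g$out
  list(pred = pred, caches = caches, running = running)
}

net_backward <- function(model, caches, dpred) {
  params <- model$params
  arch <- model$arch
  grads <- list()
  N <- length(dpred)

  gout <- caches$head_in
  grads[["head.W"]] <- matrix(dpred, 1L, N) %*% t(gout)
  grads[["head.b"]] <- sum(dpred)
  dg <- t(params[["head.W"]]) %*% matrix(dpred, 1L, N)  # (C, N)
  dh <- gap_backward(dg, caches$gap)

  for (i in rev(seq_along(arch$blocks))) {
    blk <- arch$blocks[[i]]
    bc <- caches$blocks[[i]]
    dsum <- relu_backward(dh, bc$rout)
    dbody <- dsum
    dshort <- dsum
    if (blk$stride != 1L || blk$cin != blk$cout) {
      ub <- unit_backward(dshort, bc$down, paste0(blk$name, ".down"), grads)
      grads <- ub$grads
      dident <- ub$dx
    } else {
      dident <- dshort
    }
    if (blk$se) {
      seb <- se_backward(dbody, bc$se)
      grads[[paste0(blk$name, ".se.w1")]] <- seb$dw1
      grads[[paste0(blk$name, ".se.b1")]] <- seb$db1
      grads[[paste0(blk$name, ".se.w2")]] <- seb$dw2
      grads[[paste0(blk$name, ".se.b2")]] <- seb$db2
      dbody <- seb$dx
    }
    if (blk$type == "basic") {
      ub2 <- unit_backward(dbody, bc$u2, paste0(blk$name, ".conv2"), grads)
      grads <- ub2$grads
      dr1 <- relu_backward(ub2$dx, bc$r1)
      ub1 <- unit_backward(dr1, bc$u1, paste0(blk$name, ".conv1"), grads)
      grads <- ub1$grads
      dh <- ub1$dx + dident
    } else {
      ub3 <- unit_backward(dbody, bc$u3, paste0(blk$name, ".conv3"), grads)
      grads <- ub3$grads
      dr2 <- relu_backward(ub3$dx, bc$r2)
      ub2 <- unit_backward(dr2, bc$u2, paste0(blk$name, ".conv2"), grads)
      grads <- ub2$grads
      dr1 <- relu_backward(ub2$dx, bc$r1)
      ub1 <- unit_backward(dr1, bc$u1, paste0(blk$name, ".conv1"), grads)
      grads <- ub1$grads
      dh <- ub1$dx + dident
    }
  }

  if (model$arch$stem$maxpool) {
    dh <- maxpool_backward(dh, caches$stem$pool)
  }
  dr <- relu_backward(dh, caches$stem$relu)
  ub <- unit_backward(dr, caches$stem$unit, "stem", grads)
  ub$grads
}

#' Standalone squeeze-and-excitation block
#'
#' Applies channel attention to a single feature map: the squeeze step
#' global-average-pools each channel to one scalar; the excitation step maps
#' the C-vector through a bottleneck of width `C / r` with rectification,
#' back to C units, and squashes with the logistic function to gates in
#' (0, 1); each channel of the input is then scaled by its gate.
#'
#' @param feature_map H x W x C array.
#' @param r channel reduction ratio; must divide C.
#' @param weights optional list `w1 (C/r x C), b1, w2 (C x C/r), b2`;
#'   randomly initialised (seeded) when omitted.
#' @param seed seed for random weight initialisation.
#' @return List with `output` (H x W x C), `gates` (length-C vector in
#'   (0, 1)) and `squeeze` (the per-channel means).
#' @export
se_block <- function(feature_map, r = 8L, weights = NULL, seed = 1L) {
  d <- dim(feature_map)
  if (length(d) != 3L) stop("`feature_map` must be H x W x C", call. = FALSE)
  C <- d[3]
  if (C %% r != 0L) {
    stop(sprintf("channel count %d is not divisible by the reduction ratio %d",
                 C, r), call. = FALSE)
  }
  if (is.null(weights)) {
    cr <- C %/% r
    weights <- with_seed(seed, list(
      w1 = matrix(stats::rnorm(cr * C, sd = sqrt(2 / C)), cr, C),
      b1 = numeric(cr),
      w2 = matrix(stats::rnorm(C * cr, sd = sqrt(2 / cr)), C, cr),
      b2 = numeric(C)))
  }
  x <- aperm(feature_map, c(3, 1, 2))
  dim(x) <- c(C, d[1], d[2], 1L)
  fw <- se_forward(x, weights$w1, weights$b1, weights$w2, weights$b2,
                   keep_cache = TRUE)
  out <- fw$out
  dim(out) <- c(C, d[1], d[2])
  list(output = aperm(out, c(2, 3, 1)),
       gates = as.vector(fw$cache$g),
       squeeze = as.vector(fw$cache$s))
}

# Resize an RGB image to (C, S, S) unit-scale tensor slab.
prepare_image <- function(image, input_size) {
  px <- if (inherits(image, "synthetic_image")) image$pixels else image
  img <- as_unit_pixels(px)
  d <- dim(img)
  if (d[1] != input_size || d[2] != input_size) {
    eb <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
    rs <- EBImage::resize(eb, w = input_size, h = input_size)
    img <- aperm(EBImage::imageData(rs), c(2, 1, 3))
  }
  aperm(img, c(3, 1, 2))
}

# Stack a list of images into a (3, S, S, N) tensor.
prepare_batch <- function(images, input_size) {
  n <- length(images)
  x <- array(0, c(3L, input_size, input_size, n))
  for (i in seq_len(n)) x[, , , i] <- prepare_image(images[[i]], input_size)
  x
}

#' Train a residual CNN regressor
#'
#' Minimises the composite loss `MSE + lambda_l1 * L1` between predicted and
#' true Hb masses (both on the `target_scale`-normalised scale) with Adam at
#' the configured learning rate, shuffling each epoch under the model's
#' seed. Per-epoch mean training loss is recorded. Training is fully
#' deterministic: rebuilding and retraining with the same seed reproduces
#' the loss history exactly.
#'
#' @param model an `hb_cnn` from [build_regressor()].
#' @param images list of H x W x 3 arrays (or `synthetic_image` objects);
#'   resized to the configured input size.
#' @param masses true Hb masses (mg), one per image.
#' @param epochs optional override of `config$epochs`.
#' @param verbose print the loss every few epochs.
#' @return The trained `hb_cnn` (with `$history`, a data.frame of
#'   `epoch, loss`).
#' @export
train_hb_cnn <- function(model, images, masses, epochs = NULL,
                         verbose = FALSE) {
  if (!inherits(model, "hb_cnn")) stop("`model` must be an hb_cnn",
                                       call. = FALSE)
  n <- length(images)
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (length(masses) != n) {
    stop("`masses` must have one value per image", call. = FALSE)
  }
  cfg <- model$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  x_all <- prepare_batch(images, cfg$input_size)
  y_all <- masses / cfg$target_scale
  lambda <- cfg$lambda_l1

  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- adam_m
  t_step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  history <- numeric(epochs)

  base_lr <- lr
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      if (identical(cfg$lr_decay %||% "cosine", "cosine")) {
        lr <- base_lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs))
      }
      perm <- sample.int(n)
      ep_loss <- 0
      nb <- ceiling(n / cfg$batch_size)
      for (bi in seq_len(nb)) {
        sel <- perm[((bi - 1L) * cfg$batch_size + 1L):
                      min(bi * cfg$batch_size, n)]
        xb <- x_all[, , , sel, drop = FALSE]
        yb <- y_all[sel]
        B <- length(sel)
        fw <- net_forward(model, xb, training = TRUE, keep_cache = TRUE)
        model$running <- fw$running
        err <- fw$pred - yb
        loss <- mean(err^2) + lambda * mean(abs(err))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d", ep),
               call. = FALSE)
        }
        ep_loss <- ep_loss + loss * B / n
        dpred <- 2 * err / B + lambda * sign(err) / B
        grads <- net_backward(model, fw$caches, dpred)
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (nm in names(grads)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g * g
          model$params[[nm]] <- model$params[[nm]] -
            lr * (adam_m[[nm]] / corr1) / (sqrt(adam_v[[nm]] / corr2) + eps)
        }
      }
      history[ep] <- ep_loss
      if (verbose && (ep == 1L || ep %% 5L == 0L)) {
        message(sprintf("epoch %d/%d: loss %.5f", ep, epochs, ep_loss))
      }
    }
  })
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(epochs), loss = history)
  model
}

#' Predict Hb mass from sponge crops with a trained CNN
#'
#' Resizes each crop to the configured input size, normalises to `[0, 1]`,
#' runs the network in inference mode (batch-norm running statistics) and
#' rescales the output by `target_scale`. Inference is a pure function:
#' identical crops give identical predictions, and batches preserve input
#' order.
#'
#' @param object a trained `hb_cnn`.
#' @param images a single H x W x 3 array or a list of them.
#' @param clamp report negative masses as 0 mg (default `FALSE`: raw model
#'   output, which evaluation metrics use).
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return Numeric vector of predicted Hb masses (mg), in input order.
#' @export
predict.hb_cnn <- function(object, images, clamp = FALSE, batch_size = 32L,
                           ...) {
  if (!isTRUE(object$trained)) {
    stop("model has not been trained; call train_hb_cnn() first",
         call. = FALSE)
  }
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  if (inherits(images, "synthetic_image")) images <- list(images)
  n <- length(images)
  pred <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    xb <- prepare_batch(images[sel], object$config$input_size)
    fw <- net_forward(object, xb, training = FALSE, keep_cache = FALSE)
    pred[sel] <- fw$pred * object$config$target_scale
  }
  if (clamp) pmax(pred, 0) else pred
}

#' @export
print.hb_cnn <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("%s Hb-loss regressor (%s variant, %s, %d parameters)\n",
              if (x$kind == "se_resnet") "SE-ResNet" else "ResNet",
              x$config$variant,
              if (x$trained) "trained" else "untrained", npar))
  if (x$trained) {
    cat(sprintf("  final training loss: %.5f after %d epochs\n",
                utils::tail(x$history$loss, 1), nrow(x$history)))
  }
  invisible(x)
}

#' @export
summary.hb_cnn <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.hb_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot", call. = FALSE)
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "Epoch", ylab = "Training loss (MSE + lambda*L1)",
                 ...)
  invisible(x)
}

#' Save / load a CNN regressor
#'
#' Thin wrappers over R's native serialisation ([saveRDS()]), the standard
#' on-disk format for fitted R model objects.
#'
#' @param model an `hb_cnn`.
#' @param path file path.
#' @export
save_hb_cnn <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_hb_cnn
#' @export
load_hb_cnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hb_cnn")) stop("file does not contain an hb_cnn",
                                       call. = FALSE)
  model
}
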