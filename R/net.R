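# Sequence-regression models: a bidirectional LSTM and a linear (dense
# feed-forward) network mapping standardized 25 Hz sensor matrices (N x C)
# to standardized SJRF targets (N x 3), trained on whole subtrial sequences
# with Adam, mean-squared-error loss and patience-based early stopping.

#' Model and training configuration
#'
#' Defaults follow the reference training protocol: three bidirectional LSTM
#' layers of 128 units per direction, each followed by dropout (p = 0.37) and
#' a ReLU; or a linear network with dense hidden layers of 250 and 100 units,
#' each followed by a ReLU; linear output map to the 3 force components; MSE
#' loss on standardized targets; at most 200 epochs with early stopping after
#' 6 consecutive epochs without validation-loss improvement. Optimizer
#' choices (Adam, learning rate 1e-3, whole-sequence batches of 8, gradient
#' clipping at global norm 1) are this package's documented additions.
#'
#' @param architecture `"bilstm"` or `"linear"`.
#' @param input_width Number of input columns C (32 complete, 20 sparse).
#' @param bilstm_layers,bilstm_units biLSTM depth and units per direction.
#' @param dropout Dropout probability after each biLSTM layer, in `[0, 1)`.
#' @param linear_units Hidden sizes of the linear architecture.
#' @param max_epochs,patience Training-length and early-stopping controls.
#' @param learning_rate,batch_size,grad_clip Optimizer settings.
#' @param seed Integer seed controlling initialization, dropout and shuffling.
#' @return Object of class `sjrf_config`.
#' @export
sjrf_config <- function(architecture = c("bilstm", "linear"),
                        input_width = 32,
                        bilstm_layers = 3, bilstm_units = 128,
                        dropout = 0.37,
                        linear_units = c(250, 100),
                        max_epochs = 200, patience = 6,
                        learning_rate = 1e-3, batch_size = 8,
                        grad_clip = 1, seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(input_width >= 1, bilstm_layers >= 1, bilstm_units >= 1,
            all(linear_units >= 1), max_epochs >= 1,
            patience >= 1, patience < max_epochs,
            dropout >= 0, dropout < 1, learning_rate > 0, batch_size >= 1)
  structure(list(architecture = architecture,
                 input_width = as.integer(input_width),
                 bilstm_layers = as.integer(bilstm_layers),
                 bilstm_units = as.integer(bilstm_units),
                 dropout = dropout,
                 linear_units = as.integer(linear_units),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 grad_clip = grad_clip, seed = as.integer(seed)),
            class = "sjrf_config")
}

#' Closed-form parameter count
#'
#' Linear: `C*h1 + h1 + h1*h2 + h2 + h2*3 + 3`. biLSTM: per layer and
#' direction `D*4U + U*4U + 4U` (one bias vector per direction), with
#' `D = C` for the first layer and `2U` afterwards, plus the `2U*3 + 3`
#' output map.
#'
#' @param config An `sjrf_config`.
#' @return Integer parameter count.
#' @export
n_params <- function(config) {
  C <- config$input_width
  if (config$architecture == "linear") {
    sizes <- c(C, config$linear_units, 3L)
    sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
  } else {
    U <- config$bilstm_units
    total <- 0L
    D <- C
    for (l in seq_len(config$bilstm_layers)) {
      total <- total + 2L * (D * 4L * U + U * 4L * U + 4L * U)
      D <- 2L * U
    }
    total + D * 3L + 3L
  }
}

# ---- parameter plumbing ---------------------------------------------------

runifm <- function(nr, nc, k) {
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

init_params <- function(config) {
  C <- config$input_width
  if (config$architecture == "linear") {
    sizes <- c(C, config$linear_units)
    layers <- lapply(seq_along(config$linear_units), function(l) {
      k <- 1 / sqrt(sizes[l])
      list(W = runifm(sizes[l], sizes[l + 1], k),
           b = stats::runif(sizes[l + 1], -k, k))
    })
    ko <- 1 / sqrt(sizes[length(sizes)])
    out <- list(W = runifm(sizes[length(sizes)], 3, ko),
                b = stats::runif(3, -ko, ko))
  } else {
    U <- config$bilstm_units
    D <- C
    layers <- vector("list", config$bilstm_layers)
    for (l in seq_len(config$bilstm_layers)) {
      k <- 1 / sqrt(U)
      layers[[l]] <- list(Wf = runifm(D, 4 * U, k), Rf = runifm(U, 4 * U, k),
                          bf = stats::runif(4 * U, -k, k),
                          Wb = runifm(D, 4 * U, k), Rb = runifm(U, 4 * U, k),
                          bb = stats::runif(4 * U, -k, k))
      D <- 2 * U
    }
    ko <- 1 / sqrt(D)
    out <- list(W = runifm(D, 3, ko), b = stats::runif(3, -ko, ko))
  }
  list(layers = layers, out = out)
}

# elementwise map over parallel parameter structures
param_map <- function(f, ...) {
  ps <- list(...)
  if (is.list(ps[[1]])) {
    out <- lapply(seq_along(ps[[1]]), function(i) {
      do.call(param_map, c(list(f), lapply(ps, `[[`, i)))
    })
    names(out) <- names(ps[[1]])
    out
  } else {
    do.call(f, ps)
  }
}

param_sumsq <- function(p) {
  if (is.list(p)) sum(vapply(p, param_sumsq, 0)) else sum(p^2)
}

# ---- forward / backward ---------------------------------------------------

forward_pass <- function(params, config, X, training = FALSE) {
  H <- X
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    lp <- params$layers[[l]]
    if (config$architecture == "bilstm") {
      fw <- .lstm_forward_cpp(H, lp$Wf, lp$Rf, lp$bf, FALSE)
      bw <- .lstm_forward_cpp(H, lp$Wb, lp$Rb, lp$bb, TRUE)
      Z <- cbind(fw$H, bw$H)
    } else {
      fw <- bw <- NULL
      Z <- sweep(H %*% lp$W, 2, lp$b, "+")
    }
    mask <- NULL
    if (training && config$architecture == "bilstm" && config$dropout > 0) {
      mask <- matrix(
        (stats::runif(length(Z)) >= config$dropout) / (1 - config$dropout),
        nrow(Z), ncol(Z))
      Z <- Z * mask
    }
    caches[[l]] <- list(input = H, fw = fw, bw = bw, mask = mask, Z = Z)
    H <- pmax(Z, 0)
  }
  Yhat <- sweep(H %*% params$out$W, 2, params$out$b, "+")
  list(Yhat = Yhat, H_last = H, caches = caches)
}

backward_pass <- function(params, config, fwd, dY) {
  g_out <- list(W = crossprod(fwd$H_last, dY), b = colSums(dY))
  dH <- dY %*% t(params$out$W)
  g_layers <- vector("list", length(params$layers))
  for (l in rev(seq_along(params$layers))) {
    cache <- fwd$caches[[l]]
    dZ <- dH * (cache$Z > 0)
    if (!is.null(cache$mask)) dZ <- dZ * cache$mask
    lp <- params$layers[[l]]
    if (config$architecture == "bilstm") {
      U <- config$bilstm_units
      dHf <- dZ[, 1:U, drop = FALSE]
      dHb <- dZ[, (U + 1):(2 * U), drop = FALSE]
      gf <- .lstm_backward_cpp(cache$input, lp$Wf, lp$Rf,
                               cache$fw$I, cache$fw$F, cache$fw$G,
                               cache$fw$O, cache$fw$C, cache$fw$TC, dHf,
                               FALSE)
      gb <- .lstm_backward_cpp(cache$input, lp$Wb, lp$Rb,
                               cache$bw$I, cache$bw$F, cache$bw$G,
                               cache$bw$O, cache$bw$C, cache$bw$TC, dHb,
                               TRUE)
      g_layers[[l]] <- list(Wf = gf$dW, Rf = gf$dR, bf = as.numeric(gf$db),
                            Wb = gb$dW, Rb = gb$dR, bb = as.numeric(gb$db))
      dH <- gf$dX + gb$dX
    } else {
      g_layers[[l]] <- list(W = crossprod(cache$input, dZ), b = colSums(dZ))
      dH <- dZ %*% t(lp$W)
    }
  }
  list(layers = g_layers, out = g_out)
}

# mean squared error over all elements of a list of (Xs, Ys) pairs
eval_loss <- function(params, config, xs, ys) {
  num <- 0
  den <- 0
  for (i in seq_along(xs)) {
    fwd <- forward_pass(params, config, xs[[i]], training = FALSE)
    num <- num + sum((fwd$Yhat - ys[[i]])^2)
    den <- den + length(ys[[i]])
  }
  num / den
}

#' Early-stopping semantics on a validation-loss schedule
#'
#' Pure helper implementing the training stop rule: stop when the validation
#' loss has not decreased below its running minimum for `patience`
#' consecutive epochs, or at `max_epochs`. The stored model is the one at the
#' minimum.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving epochs tolerated.
#' @param max_epochs Epoch cap.
#' @return List with `stop_epoch` and `best_epoch`.
#' @export
early_stopping_trace <- function(val_losses, patience = 6, max_epochs = 200) {
  best <- Inf
  best_epoch <- 0L
  since <- 0L
  n <- as.integer(min(length(val_losses), max_epochs))
  for (e in seq_len(n)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) return(list(stop_epoch = e, best_epoch = best_epoch))
  }
  list(stop_epoch = n, best_epoch = best_epoch)
}

#' Fit a sequence-regression model for SJRF estimation
#'
#' Trains the configured architecture on whole subtrial sequences. Inputs and
#' targets are standardized with statistics fitted on the training samples
#' only (pass a pre-fitted `standardizer` to reuse fold statistics). Batches
#' are sets of whole sequences; the batch gradient weights every sequence by
#' its number of target elements, so the batch loss is the plain MSE over all
#' timesteps. Training stops early when the validation loss has not improved
#' for `config$patience` consecutive epochs; the parameters at the lowest
#' validation loss are restored. Without a validation set the model trains
#' for `max_epochs` and keeps the final parameters.
#'
#' @param train List of `sjrf_sample` (or `list(X, Y)`) training sequences.
#' @param validation Optional list of validation sequences.
#' @param config An [sjrf_config()]; its `input_width` must match the data.
#' @param standardizer Optional pre-fitted [fit_standardizer()] result.
#' @param verbose Print per-epoch losses.
#' @return Object of class `sjrf_net` with elements `config`, `params`
#'   (weights at the best epoch), `standardizer`, `history` (per-epoch train
#'   and validation loss), `best_epoch`, `stopped_epoch`.
#' @export
sjrf_net <- function(train, validation = NULL, config = sjrf_config(),
                     standardizer = NULL, verbose = FALSE) {
  stopifnot(length(train) >= 1)
  if (ncol(train[[1]]$X) != config$input_width) {
    stop(sprintf("config input_width %d does not match data width %d",
                 config$input_width, ncol(train[[1]]$X)), call. = FALSE)
  }
  if (is.null(standardizer)) standardizer <- fit_standardizer(train)
  xs <- lapply(train, function(s) standardize_apply(standardizer, s$X, "x"))
  ys <- lapply(train, function(s) standardize_apply(standardizer, s$Y, "y"))
  has_val <- length(validation) > 0
  if (has_val) {
    vxs <- lapply(validation,
                  function(s) standardize_apply(standardizer, s$X, "x"))
    vys <- lapply(validation,
                  function(s) standardize_apply(standardizer, s$Y, "y"))
  }

  with_seed(config$seed, {
    params <- init_params(config)
    m_state <- param_map(function(p) p * 0, params)
    v_state <- param_map(function(p) p * 0, params)
    step <- 0L
    b1 <- 0.9
    b2 <- 0.999
    eps <- 1e-8

    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- Inf
    best_epoch <- 0L
    best_params <- params
    since <- 0L
    stopped <- config$max_epochs

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(xs))
      ep_num <- 0
      ep_den <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        n_el <- sum(vapply(idx, function(i) length(ys[[i]]), 0))
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          fwd <- forward_pass(params, config, xs[[i]], training = TRUE)
          resid <- fwd$Yhat - ys[[i]]
          w <- length(ys[[i]]) / n_el
          batch_loss <- batch_loss + w * mean(resid^2)
          dY <- (2 * w / length(ys[[i]])) * resid
          g <- backward_pass(params, config, fwd, dY)
          grads <- if (is.null(grads)) g else param_map(`+`, grads, g)
        }
        if (!is.finite(batch_loss)) {
          stop(sprintf(
            "training diverged (non-finite loss) at epoch %d; %s seed %d",
            epoch, config$architecture, config$seed), call. = FALSE)
        }
        gn <- sqrt(param_sumsq(grads))
        if (is.finite(config$grad_clip) && gn > config$grad_clip) {
          grads <- param_map(function(g) g * (config$grad_clip / gn), grads)
        }
        step <- step + 1L
        lr_t <- config$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
        m_state <- param_map(function(m, g) b1 * m + (1 - b1) * g,
                             m_state, grads)
        v_state <- param_map(function(v, g) b2 * v + (1 - b2) * g^2,
                             v_state, grads)
        params <- param_map(function(p, m, v) p - lr_t * m / (sqrt(v) + eps),
                            params, m_state, v_state)
        ep_num <- ep_num + batch_loss * n_el
        ep_den <- ep_den + n_el
      }
      train_loss <- ep_num / ep_den
      val_loss <- if (has_val) eval_loss(params, config, vxs, vys) else NA_real_
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        train_loss, val_loss))
      }
      watch <- if (has_val) val_loss else train_loss
      if (watch < best) {
        best <- watch
        best_epoch <- epoch
        best_params <- params
        since <- 0L
      } else {
        since <- since + 1L
      }
      if (has_val && since >= config$patience) {
        stopped <- epoch
        break
      }
      stopped <- epoch
    }
    if (!has_val) {
      best_params <- params
      best_epoch <- stopped
    }

    structure(list(config = config, params = best_params,
                   standardizer = standardizer, history = history,
                   best_epoch = best_epoch, stopped_epoch = stopped),
              class = "sjrf_net")
  })
}

#' Predict the SJRF series for a subtrial
#'
#' Inference is deterministic (dropout disabled). The prediction is computed
#' on standardized inputs and inverse-transformed to force units with the
#' train-fitted target statistics.
#'
#' @param object An `sjrf_net`.
#' @param newdata An `sjrf_sample` (or `list(X = matrix)`).
#' @param ... Unused.
#' @return N x 3 matrix of predicted Fx, Fy, Fz in N.
#' @export
predict.sjrf_net <- function(object, newdata, ...) {
  X <- newdata$X
  if (ncol(X) != object$config$input_width) {
    stop(sprintf("input width %d does not match model width %d",
                 ncol(X), object$config$input_width), call. = FALSE)
  }
  Xs <- standardize_apply(object$standardizer, X, "x")
  fwd <- forward_pass(object$params, object$config, Xs, training = FALSE)
  out <- standardize_invert(object$standardizer, fwd$Yhat, "y")
  colnames(out) <- c("Fx", "Fy", "Fz")
  out
}

#' @export
print.sjrf_net <- function(x, ...) {
  cfg <- x$config
  arch <- if (cfg$architecture == "bilstm") {
    sprintf("biLSTM (%d layers x %d units/direction, dropout %.2f)",
            cfg$bilstm_layers, cfg$bilstm_units, cfg$dropout)
  } else {
    sprintf("linear (hidden %s)", paste(cfg$linear_units, collapse = ", "))
  }
  cat(sprintf("SJRF sequence regressor: %s\n", arch))
  cat(sprintf("  inputs: %d channels at 25 Hz -> 3 force components\n",
              cfg$input_width))
  cat(sprintf("  parameters: %s\n", format(n_params(cfg), big.mark = ",")))
  cat(sprintf("  trained %d epoch(s), best validation loss at epoch %d\n",
              x$stopped_epoch, x$best_epoch))
  if (nrow(x$history)) {
    cat(sprintf("  final train MSE %.4f, best val MSE %.4f (standardized)\n",
                x$history$train_loss[nrow(x$history)],
                min(x$history$val_loss, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.sjrf_net <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.sjrf_net <- function(object, ...) {
  p <- object$params
  attr(p, "n_params") <- param_count(p)
  p
}

param_count <- function(p) {
  if (is.list(p)) sum(vapply(p, param_count, 0)) else length(p)
}

#' @export
plot.sjrf_net <- function(x, ...) {
  h <- x$history
  rng <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 ylim = rng, xlab = "epoch", ylab = "MSE (standardized)",
                 main = "Training history", ...)
  if (any(is.finite(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, col = "firebrick")
    graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
    graphics::legend("topright", c("train", "validation"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' @export
residuals.sjrf_net <- function(object, newdata, ...) {
  if (missing(newdata)) stop("supply a sample to compute residuals for")
  newdata$Y - predict(object, newdata)
}

#' Fit one cross-validation fold
#'
#' Resolves a split plan against the cohort samples, fits the standardizer on
#' the training subtrials only, and trains the model.
#'
#' @param split An `sjrf_split`.
#' @param samples Named list of `sjrf_sample` (keys as in the manifest).
#' @param config An [sjrf_config()].
#' @param ... Passed to [sjrf_net()].
#' @return The fitted `sjrf_net`.
#' @export
fit_fold <- function(split, samples, config, ...) {
  sjrf_net(train = samples[split$train],
           validation = if (length(split$validation)) samples[split$validation],
           config = config, ...)
}

#' Train one fold for several seeded iterations
#'
#' Re-initializes, trains and evaluates the model `n_iter` times with seeds
#' `base_seed + 0, 1, ...`, mirroring the repeated-initialization protocol
#' (ten iterations by default).
#'
#' @param split An `sjrf_split`.
#' @param samples Named list of `sjrf_sample`.
#' @param config An [sjrf_config()]; its seed is overridden per iteration.
#' @param n_iter Number of iterations (default 10).
#' @param base_seed First iteration seed.
#' @return List of `sjrf_net`, one per iteration.
#' @export
run_iterations <- function(split, samples, config, n_iter = 10,
                           base_seed = config$seed) {
  stopifnot(n_iter >= 1)
  lapply(seq_len(n_iter), function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1L)
    fit_fold(split, samples, cfg)
  })
}
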