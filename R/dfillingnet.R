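# The next-base prediction network: one-hot input -> 1-D convolution (ReLU)
# -> batch norm -> max pool -> dropout -> BiLSTM x2 -> residual sum with a
# width-1 convolutional projection of the pooled conv features -> max pool
# over time -> affine -> softmax over A,C,G,T. Forward, backward and Adam
# training are implemented in-package (see nn_internals.R).

#' Network configuration
#'
#' @param window_len training context length in bases.
#' @param conv_channels convolution output channels.
#' @param kernel_size convolution kernel width (default 3).
#' @param stride convolution stride.
#' @param padding zero padding per side.
#' @param pool_size max-pool window over time.
#' @param dropout_rate dropout probability after pooling (training only).
#' @param bn_epsilon batch-normalisation epsilon.
#' @param lstm_hidden hidden units per LSTM direction.
#' @param n_policy how `N` is one-hot encoded (`"zero"` or `"uniform"`).
#' @return a `model_config` list (always two BiLSTM layers).
#' @export
model_config <- function(window_len = 64L, conv_channels = 64L,
                         kernel_size = 3L, stride = 1L, padding = 1L,
                         pool_size = 2L, dropout_rate = 0.1,
                         bn_epsilon = 1e-5, lstm_hidden = 128L,
                         n_policy = c("zero", "uniform")) {
  n_policy <- match.arg(n_policy)
  stopifnot(window_len >= kernel_size, conv_channels >= 1L, kernel_size >= 1L,
            stride >= 1L, padding >= 0L, pool_size >= 1L,
            dropout_rate >= 0, dropout_rate < 1, bn_epsilon > 0,
            lstm_hidden >= 1L)
  l_out <- (window_len + 2L * padding - kernel_size) %/% stride + 1L
  if (l_out %/% pool_size < 1L) {
    stop("pool_size larger than the convolution output length", call. = FALSE)
  }
  structure(list(window_len = as.integer(window_len),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride), padding = as.integer(padding),
                 pool_size = as.integer(pool_size),
                 dropout_rate = dropout_rate, bn_epsilon = bn_epsilon,
                 lstm_hidden = as.integer(lstm_hidden),
                 n_bilstm_layers = 2L,
                 channel_order = paste(CHANNEL_ORDER, collapse = ""),
                 n_policy = n_policy),
            class = "model_config")
}

#' Training hyperparameters
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum epochs (0 returns the model untrained).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param validation_fraction held-out fraction for early stopping.
#' @param rng_seed seed covering shuffling, splitting and dropout.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 128L,
                            max_epochs = 50L, early_stop_patience = 5L,
                            validation_fraction = 0.1, rng_seed = 42L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, max_epochs >= 0L,
            early_stop_patience >= 1L,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

.xavier <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Build an untrained network
#'
#' Initialises all parameter matrices (Xavier-uniform, forget-gate bias 1)
#' for the architecture fixed by the configuration.
#'
#' @param config a [model_config()].
#' @param init_seed seed for weight initialisation.
#' @return a `dfillingnet` object: `$config`, `$params`, `$state` (batch-norm
#'   running statistics), `$fingerprint`, `$history`.
#' @export
build_model <- function(config, init_seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  C <- config$conv_channels; H <- config$lstm_hidden; K <- config$kernel_size
  .with_seed(init_seed, {
    lstm_b <- function() {
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1    # forget-gate bias
      b
    }
    params <- list(
      W_conv = .xavier(K * 4L, C), b_conv = numeric(C),
      bn_gamma = rep(1, C), bn_beta = numeric(C),
      W_proj = .xavier(C, 2L * H), b_proj = numeric(2L * H),
      l1f_W = .xavier(C + H, 4L * H), l1f_b = lstm_b(),
      l1b_W = .xavier(C + H, 4L * H), l1b_b = lstm_b(),
      l2f_W = .xavier(3L * H, 4L * H), l2f_b = lstm_b(),
      l2b_W = .xavier(3L * H, 4L * H), l2b_b = lstm_b(),
      W_out = .xavier(2L * H, 4L), b_out = numeric(4L)
    )
    structure(list(config = config, params = params,
                   state = list(bn_mean = numeric(C), bn_var = rep(1, C)),
                   fingerprint = NULL, history = NULL),
              class = "dfillingnet")
  })
}

#' Closed-form trainable parameter count for a configuration
#' @param config a [model_config()].
#' @return integer parameter count.
#' @export
n_parameters <- function(config) {
  C <- config$conv_channels; H <- config$lstm_hidden; K <- config$kernel_size
  conv <- K * 4L * C + C
  bn <- 2L * C
  proj <- C * 2L * H + 2L * H
  l1 <- 2L * ((C + H) * 4L * H + 4L * H)
  l2 <- 2L * ((3L * H) * 4L * H + 4L * H)
  out <- 2L * H * 4L + 4L
  conv + bn + proj + l1 + l2 + out
}

# encode a batch of contexts into (B, window_len, 4); shorter contexts are
# left-padded as N (policy rows), longer ones keep their last window_len bases
.encode_batch <- function(contexts, window_len, n_policy = "zero") {
  B <- length(contexts)
  nc <- nchar(contexts)
  padded <- ifelse(
    nc >= window_len,
    substr(contexts, nc - window_len + 1L, nc),
    paste0(strrep("N", window_len - nc), contexts)
  )
  codes <- utf8ToInt(paste(padded, collapse = ""))
  channel <- match(codes, c(65L, 67L, 71L, 84L))   # A C G T
  k <- seq_along(codes)
  b <- (k - 1L) %/% window_len + 1L
  pos <- (k - 1L) %% window_len + 1L
  arr <- array(0, dim = c(B, window_len, 4L))
  def <- !is.na(channel)
  arr[cbind(b[def], pos[def], channel[def])] <- 1
  if (n_policy == "uniform" && any(!def)) {
    for (ch in 1:4) arr[cbind(b[!def], pos[!def], ch)] <- 0.25
  }
  arr
}

# Full forward pass. Returns probabilities plus every cache needed for the
# backward pass; `training` switches batch-norm statistics and dropout.
.net_forward <- function(model, Xarr, training = FALSE) {
  cfg <- model$config; p <- model$params
  C <- cfg$conv_channels; H <- cfg$lstm_hidden
  cf <- .conv1d_forward(Xarr, p$W_conv, p$b_conv, cfg$kernel_size,
                        cfg$stride, cfg$padding)
  B <- cf$B; Lout <- cf$Lout
  relu_mask <- cf$out > 0
  A <- cf$out * relu_mask
  bn <- .bn_forward(A, p$bn_gamma, p$bn_beta, cfg$bn_epsilon, training,
                    model$state$bn_mean, model$state$bn_var)
  feat <- array(bn$out, dim = c(B, Lout, C))
  mp <- .maxpool_forward(feat, cfg$pool_size)
  F0 <- mp$out
  T <- dim(F0)[2L]
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    dmask <- array(stats::rbinom(length(F0), 1L, keep) / keep, dim = dim(F0))
    F0 <- F0 * dmask
  } else dmask <- NULL
  Xs <- lapply(seq_len(T), function(t) F0[, t, , drop = TRUE])
  if (B == 1L) Xs <- lapply(Xs, function(v) matrix(v, nrow = 1L))
  bl1 <- .bilstm_forward(Xs, p$l1f_W, p$l1f_b, p$l1b_W, p$l1b_b, H)
  bl2 <- .bilstm_forward(bl1$hs, p$l2f_W, p$l2f_b, p$l2b_W, p$l2b_b, H)
  proj <- lapply(Xs, function(x) sweep(x %*% p$W_proj, 2L, p$b_proj, "+"))
  Ys <- lapply(seq_len(T), function(t) bl2$hs[[t]] + proj[[t]])
  # global max pool over time
  M <- Ys[[1L]]; argT <- matrix(1L, B, 2L * H)
  if (T > 1L) for (t in 2:T) {
    upd <- Ys[[t]] > M
    M[upd] <- Ys[[t]][upd]
    argT[upd] <- t
  }
  logits <- sweep(M %*% p$W_out, 2L, p$b_out, "+")
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, logits = logits,
       cache = list(cf = cf, relu_mask = relu_mask, bn = bn, mp = mp,
                    dmask = dmask, Xs = Xs, bl1 = bl1, bl2 = bl2,
                    Ys = Ys, M = M, argT = argT, B = B, T = T,
                    Lout = Lout, C = C, H = H))
}

# Cross-entropy gradient for all parameters. targets: integer channel 1..4.
.net_backward <- function(model, fwd, targets) {
  p <- model$params; ch <- fwd$cache
  B <- ch$B; T <- ch$T; H <- ch$H; C <- ch$C
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(B), targets)] <- dlogits[cbind(seq_len(B), targets)] - 1
  dlogits <- dlogits / B
  dW_out <- crossprod(ch$M, dlogits)
  db_out <- colSums(dlogits)
  dM <- dlogits %*% t(p$W_out)
  dYs <- lapply(seq_len(T), function(t) {
    d <- matrix(0, B, 2L * H)
    mask <- ch$argT == t
    d[mask] <- dM[mask]
    d
  })
  # residual: dH2 = dY; projection branch
  dW_proj <- matrix(0, nrow(p$W_proj), ncol(p$W_proj))
  db_proj <- numeric(length(p$b_proj))
  dF_proj <- vector("list", T)
  for (t in seq_len(T)) {
    dW_proj <- dW_proj + crossprod(ch$Xs[[t]], dYs[[t]])
    db_proj <- db_proj + colSums(dYs[[t]])
    dF_proj[[t]] <- dYs[[t]] %*% t(p$W_proj)
  }
  g2 <- .bilstm_backward(ch$bl2, p$l2f_W, p$l2b_W, dYs)
  g1 <- .bilstm_backward(ch$bl1, p$l1f_W, p$l1b_W, g2$dXs)
  dF <- array(0, dim = c(B, T, C))
  for (t in seq_len(T)) dF[, t, ] <- g1$dXs[[t]] + dF_proj[[t]]
  if (!is.null(ch$dmask)) dF <- dF * ch$dmask
  dPooled <- .maxpool_backward(ch$mp, dF)
  dBn <- matrix(dPooled, nrow = B * ch$Lout)
  bnb <- .bn_backward(ch$bn, dBn)
  dA <- bnb$dX * ch$relu_mask
  cb <- .conv1d_backward(ch$cf, dA)
  list(W_conv = cb$dW, b_conv = cb$db,
       bn_gamma = bnb$dgamma, bn_beta = bnb$dbeta,
       W_proj = dW_proj, b_proj = db_proj,
       l1f_W = g1$dWf, l1f_b = g1$dbf, l1b_W = g1$dWb, l1b_b = g1$dbb,
       l2f_W = g2$dWf, l2f_b = g2$dbf, l2b_W = g2$dWb, l2b_b = g2$dbb,
       W_out = dW_out, b_out = db_out)
}

.ce_loss <- function(probs, targets) {
  -mean(log(pmax(probs[cbind(seq_along(targets), targets)], 1e-12)))
}

#' Build a next-base training set from genomes
#'
#' Slides windows of `window_len` bases (with the given step) over every
#' N-free stretch of every record; the target is the base immediately
#' following each window.
#'
#' @param genomes a [scaffold_record()] or list of them.
#' @param window_len context length.
#' @param step window stride.
#' @param rng_seed optional seed; when given, examples are shuffled
#'   deterministically.
#' @param max_examples optional cap applied after shuffling.
#' @return a `training_set` list: `$contexts`, `$targets` (single bases).
#'   Empty, with a warning, when no stretch of `window_len + 1` exists.
#' @export
make_training_set <- function(genomes, window_len, step = 1L, rng_seed = NULL,
                              max_examples = NULL) {
  if (inherits(genomes, "scaffold_record")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1L, window_len >= 1L, step >= 1L)
  ctx <- character(0); tgt <- character(0)
  for (rec in genomes) {
    stretches <- strsplit(rec$sequence, "N+")[[1L]]
    for (s in stretches) {
      n <- nchar(s)
      if (n < window_len + 1L) next
      starts <- seq(1L, n - window_len, by = step)
      ctx <- c(ctx, substring(s, starts, starts + window_len - 1L))
      tgt <- c(tgt, substring(s, starts + window_len, starts + window_len))
    }
  }
  if (length(ctx) == 0L) {
    warning("no N-free stretch of length window_len + 1; empty training set")
  } else if (!is.null(rng_seed)) {
    ord <- .with_seed(rng_seed, sample.int(length(ctx)))
    ctx <- ctx[ord]; tgt <- tgt[ord]
  }
  if (!is.null(max_examples) && length(ctx) > max_examples) {
    ctx <- ctx[seq_len(max_examples)]; tgt <- tgt[seq_len(max_examples)]
  }
  structure(list(contexts = ctx, targets = tgt), class = "training_set")
}

.data_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}

#' Train the network
#'
#' Minimises 4-class cross-entropy on (context, next base) pairs with Adam,
#' holding out `validation_fraction` of the examples for early stopping on
#' validation loss. Fully deterministic given `tc$rng_seed`. The returned
#' model carries the parameters of the best validation epoch, a training
#' history, and a fingerprint (seed + data digest).
#'
#' @param model a [build_model()] output.
#' @param examples a [make_training_set()] output.
#' @param tc a [training_config()].
#' @param verbose print per-epoch losses.
#' @return the trained `dfillingnet`.
#' @export
train_model <- function(model, examples, tc = training_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "dfillingnet"), inherits(examples, "training_set"),
            inherits(tc, "training_config"))
  n <- length(examples$contexts)
  if (n == 0L) stop("empty training set", call. = FALSE)
  targets_all <- match(examples$targets, CHANNEL_ORDER)
  if (anyNA(targets_all)) stop("targets must be in {A,C,G,T}", call. = FALSE)
  cfg <- model$config
  fingerprint <- list(seed = tc$rng_seed,
                      data_digest = .data_digest(examples), n_examples = n)
  model$fingerprint <- fingerprint
  if (tc$max_epochs == 0L) return(model)

  .with_seed(tc$rng_seed, {
    ord <- sample.int(n)
    n_val <- max(1L, floor(tc$validation_fraction * n))
    val_idx <- ord[seq_len(n_val)]
    tr_idx <- ord[-seq_len(n_val)]
    if (length(tr_idx) == 0L) stop("no training examples after split",
                                   call. = FALSE)
    Xval <- .encode_batch(examples$contexts[val_idx], cfg$window_len,
                          cfg$n_policy)
    yval <- targets_all[val_idx]

    st <- .adam_init(model$params)
    best <- list(loss = Inf, params = model$params, state = model$state,
                 epoch = 0L)
    history <- NULL
    stall <- 0L; t_adam <- 0L
    for (epoch in seq_len(tc$max_epochs)) {
      perm <- sample.int(length(tr_idx))
      idx <- tr_idx[perm]
      ep_loss <- 0; ep_n <- 0L
      for (b0 in seq(1L, length(idx), by = tc$batch_size)) {
        bi <- idx[b0:min(b0 + tc$batch_size - 1L, length(idx))]
        Xb <- .encode_batch(examples$contexts[bi], cfg$window_len, cfg$n_policy)
        yb <- targets_all[bi]
        fwd <- .net_forward(model, Xb, training = TRUE)
        loss <- .ce_loss(fwd$probs, yb)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (loss %s at epoch %d)", loss, epoch),
               call. = FALSE)
        }
        grads <- .net_backward(model, fwd, yb)
        t_adam <- t_adam + 1L
        up <- .adam_step(model$params, grads, st, tc$learning_rate, t_adam)
        model$params <- up$params; st <- up$state
        model$state$bn_mean <- fwd$cache$bn$run_mean
        model$state$bn_var <- fwd$cache$bn$run_var
        ep_loss <- ep_loss + loss * length(bi); ep_n <- ep_n + length(bi)
      }
      vfwd <- .net_forward(model, Xval, training = FALSE)
      val_loss <- .ce_loss(vfwd$probs, yval)
      val_acc <- mean(max.col(vfwd$probs, ties.method = "first") == yval)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                  val_loss = val_loss, val_acc = val_acc))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f  val %.4f  acc %.4f",
                        epoch, ep_loss / ep_n, val_loss, val_acc))
      }
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = model$params,
                     state = model$state, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tc$early_stop_patience) break
      }
    }
    model$params <- best$params
    model$state <- best$state
    model$history <- history
    model$fingerprint <- fingerprint
    model
  })
}

#' Next-base probabilities for one context
#'
#' Inference is deterministic: dropout is disabled and batch normalisation
#' uses running statistics. Contexts shorter than the window are left-padded
#' under the N-policy; longer contexts use their last `window_len` bases.
#'
#' @param model a `dfillingnet`.
#' @param context non-empty N-free nucleotide string.
#' @return named probability 4-vector in channel order.
#' @export
predict_next_probs <- function(model, context) {
  stopifnot(is.character(context), length(context) == 1L)
  if (!nzchar(context)) stop("empty context", call. = FALSE)
  drop(predict_probs(model, context))
}

#' Vectorised next-base probabilities
#' @param model a `dfillingnet`.
#' @param contexts character vector of contexts.
#' @return matrix (length(contexts) x 4), columns `A,C,G,T`.
#' @export
predict_probs <- function(model, contexts) {
  stopifnot(inherits(model, "dfillingnet"), length(contexts) >= 1L)
  X <- .encode_batch(contexts, model$config$window_len, model$config$n_policy)
  out <- .net_forward(model, X, training = FALSE)$probs
  colnames(out) <- CHANNEL_ORDER
  out
}

#' Wrap a trained model as a search oracle
#' @param model a `dfillingnet`.
#' @return function usable as the `oracle` of [bscea_search()].
#' @export
model_oracle <- function(model) {
  force(model)
  function(contexts) predict_probs(model, contexts)
}

#' Held-out next-base accuracy
#' @param model a `dfillingnet`.
#' @param examples a `training_set`.
#' @return fraction of examples whose argmax prediction equals the target.
#' @export
next_base_accuracy <- function(model, examples) {
  probs <- predict_probs(model, examples$contexts)
  mean(CHANNEL_ORDER[max.col(probs, ties.method = "first")] == examples$targets)
}

MODEL_FILE_VERSION <- 1L

#' Save / load a trained model
#'
#' The file embeds the configuration (including the one-hot channel order),
#' all parameters, batch-norm running statistics and the training
#' fingerprint. Loading refuses files whose channel order disagrees with the
#' running encoder, and names any missing field.
#'
#' @param model a `dfillingnet`.
#' @param path file path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dfillingnet"))
  obj <- list(format = "gapfillr_model", version = MODEL_FILE_VERSION,
              config = model$config, params = model$params,
              state = model$state, fingerprint = model$fingerprint,
              history = model$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "gapfillr_model")) {
    stop("not a gapfillr model file: ", path, call. = FALSE)
  }
  for (field in c("version", "config", "params", "state")) {
    if (is.null(obj[[field]])) {
      stop("model file missing field '", field, "'", call. = FALSE)
    }
  }
  required_cfg <- c("window_len", "conv_channels", "kernel_size", "stride",
                    "padding", "pool_size", "lstm_hidden", "channel_order",
                    "n_policy")
  missing_cfg <- setdiff(required_cfg, names(obj$config))
  if (length(missing_cfg)) {
    stop("model config missing field '", missing_cfg[[1L]], "'", call. = FALSE)
  }
  if (!identical(obj$config$channel_order, paste(CHANNEL_ORDER, collapse = ""))) {
    stop(sprintf(
      "model channel order '%s' does not match this encoder ('%s'); refusing to load",
      obj$config$channel_order, paste(CHANNEL_ORDER, collapse = "")),
      call. = FALSE)
  }
  structure(list(config = obj$config, params = obj$params, state = obj$state,
                 fingerprint = obj$fingerprint, history = obj$history),
            class = "dfillingnet")
}

#' @export
print.dfillingnet <- function(x, ...) {
  cat(sprintf("<dfillingnet> window %d, conv %d ch, lstm %d/dir, %s\n",
              x$config$window_len, x$config$conv_channels,
              x$config$lstm_hidden,
              if (is.null(x$fingerprint)) "untrained"
              else sprintf("trained (seed %d, %d examples)",
                           x$fingerprint$seed, x$fingerprint$n_examples)))
  invisible(x)
}
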