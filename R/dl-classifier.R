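#' 1-D residual network configuration
#'
#' The default is the standard 18-weighted-layer residual topology with 1-D
#' filters: a stride-2 stem convolution (kernel 7) and max-pool, four stages
#' of two residual blocks each (each block: two kernel-3 convolutions with
#' batch normalization, a ReLU, and a residual connection; the first block
#' of stages 2-4 halves the time resolution and doubles the channels),
#' global average pooling, dropout, and one fully connected logistic output.
#' `reduced = TRUE` quarters all channel counts, the configuration used for
#' desk-scale experiments.
#'
#' @param input_length Classifier input length in samples (1000 for a 5-s
#'   record at 200 Hz).
#' @param stem_channels Channels out of the stem convolution.
#' @param stage_blocks Residual blocks per stage.
#' @param stage_channels Channels per stage.
#' @param stem_kernel,kernel Convolution kernel sizes.
#' @param dropout_rate Dropout rate before the fully connected layer.
#' @param reduced Quarter the channel counts.
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_length = 1000,
                         stem_channels = 64,
                         stage_blocks = c(2, 2, 2, 2),
                         stage_channels = c(64, 128, 256, 512),
                         stem_kernel = 7,
                         kernel = 3,
                         dropout_rate = 0.2,
                         reduced = FALSE) {
  if (reduced) {
    stem_channels <- stem_channels / 4
    stage_channels <- stage_channels / 4
  }
  stopifnot(length(stage_blocks) == length(stage_channels),
            input_length > 0, all(stage_blocks >= 1),
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_length = as.integer(input_length),
                 stem_channels = as.integer(stem_channels),
                 stage_blocks = as.integer(stage_blocks),
                 stage_channels = as.integer(stage_channels),
                 stem_kernel = as.integer(stem_kernel),
                 kernel = as.integer(kernel),
                 dropout_rate = dropout_rate),
            class = "model_config")
}

# Flat list of block descriptors derived from a model_config.
block_plan <- function(config) {
  plan <- list()
  in_ch <- config$stem_channels
  for (s in seq_along(config$stage_blocks)) {
    for (b in seq_len(config$stage_blocks[s])) {
      out_ch <- config$stage_channels[s]
      stride <- if (b == 1 && s > 1) 2L else 1L
      plan[[length(plan) + 1L]] <- list(
        name = sprintf("stage%d.block%d", s, b - 1L),
        in_ch = in_ch, out_ch = out_ch, stride = stride,
        proj = stride != 1L || in_ch != out_ch)
      in_ch <- out_ch
    }
  }
  plan
}

he_mat <- function(k, cin, cout) {
  matrix(rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))), k * cin, cout)
}

#' Build an untrained classifier
#'
#' He-initializes all convolution and fully connected weights (reproducibly
#' under `seed`); batch-norm scales start at 1, shifts at 0, running
#' statistics at the standard normal.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialization.
#' @return A list of class `fast_cnn`: `config`, `params` (flat named list),
#'   `state` (batch-norm running statistics), `history` (empty tibble).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  with_seed(seed, {
    params <- list()
    state <- list()
    add_bn <- function(name, ch) {
      params[[paste0(name, ".gamma")]] <<- rep(1, ch)
      params[[paste0(name, ".beta")]] <<- rep(0, ch)
      state[[paste0(name, ".mean")]] <<- rep(0, ch)
      state[[paste0(name, ".var")]] <<- rep(1, ch)
    }
    params[["stem.conv.W"]] <- he_mat(config$stem_kernel, 1L,
                                      config$stem_channels)
    add_bn("stem.bn", config$stem_channels)
    for (blk in block_plan(config)) {
      nm <- blk$name
      params[[paste0(nm, ".conv1.W")]] <-
        he_mat(config$kernel, blk$in_ch, blk$out_ch)
      add_bn(paste0(nm, ".bn1"), blk$out_ch)
      params[[paste0(nm, ".conv2.W")]] <-
        he_mat(config$kernel, blk$out_ch, blk$out_ch)
      add_bn(paste0(nm, ".bn2"), blk$out_ch)
      if (blk$proj) {
        params[[paste0(nm, ".proj.W")]] <- he_mat(1L, blk$in_ch, blk$out_ch)
        add_bn(paste0(nm, ".projbn"), blk$out_ch)
      }
    }
    c_last <- config$stage_channels[length(config$stage_channels)]
    params[["fc.W"]] <- matrix(rnorm(c_last, 0, sqrt(2 / c_last)), c_last, 1)
    params[["fc.b"]] <- 0
    structure(list(config = config, params = params, state = state,
                   history = tibble::tibble()),
              class = "fast_cnn")
  })
}

#' Parameter count of a classifier
#'
#' @param model A `fast_cnn`.
#' @return Total number of trainable parameters (batch-norm running
#'   statistics excluded).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' @exportS3Method base::print
print.fast_cnn <- function(x, ...) {
  cat(sprintf(
    "<fast_cnn: input %d, stages [%s] x [%s] channels, %s parameters>\n",
    x$config$input_length,
    paste(x$config$stage_blocks, collapse = ","),
    paste(x$config$stage_channels, collapse = ","),
    format(n_parameters(x), big.mark = ",")))
  if (nrow(x$history)) {
    cat(sprintf("  trained %d epochs; best val AUC %.4f (epoch %d)\n",
                nrow(x$history), max(x$history$val_auc),
                which.max(x$history$val_auc)))
  }
  invisible(x)
}

# Full network forward pass. X: [N, input_length] matrix or [N, L, 1] array.
# Returns logits, caches for backward, updated state, and (optionally) the
# activation of the named residual block output.
network_forward <- function(model, X, training = FALSE, capture = NULL,
                            dropout_mask = NULL) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  if (is.matrix(X)) {
    if (ncol(X) != cfg$input_length) {
      abort(sprintf("Input length %d does not match the model input %d.",
                    ncol(X), cfg$input_length))
    }
    dim(X) <- c(nrow(X), cfg$input_length, 1L)
  }
  caches <- list()
  captured <- NULL

  run_bn <- function(name, A) {
    r <- bn_fwd(A, p[[paste0(name, ".gamma")]], p[[paste0(name, ".beta")]],
                st[[paste0(name, ".mean")]], st[[paste0(name, ".var")]],
                training)
    st[[paste0(name, ".mean")]] <<- r$rmean
    st[[paste0(name, ".var")]] <<- r$rvar
    r
  }

  cv <- conv1d_fwd(X, p[["stem.conv.W"]], cfg$stem_kernel, 2L,
                   (cfg$stem_kernel - 1L) %/% 2L)
  bn <- run_bn("stem.bn", cv$out)
  rl <- relu_fwd(bn$out)
  mp <- maxpool_fwd(rl$out)
  caches$stem <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache,
                      pool = mp$cache)
  A <- mp$out

  plan <- block_plan(cfg)
  caches$blocks <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    blk <- plan[[i]]
    nm <- blk$name
    pd <- (cfg$kernel - 1L) %/% 2L
    c1 <- conv1d_fwd(A, p[[paste0(nm, ".conv1.W")]], cfg$kernel,
                     blk$stride, pd)
    b1 <- run_bn(paste0(nm, ".bn1"), c1$out)
    r1 <- relu_fwd(b1$out)
    c2 <- conv1d_fwd(r1$out, p[[paste0(nm, ".conv2.W")]], cfg$kernel, 1L, pd)
    b2 <- run_bn(paste0(nm, ".bn2"), c2$out)
    if (blk$proj) {
      cp <- conv1d_fwd(A, p[[paste0(nm, ".proj.W")]], 1L, blk$stride, 0L)
      bp <- run_bn(paste0(nm, ".projbn"), cp$out)
      sc <- bp$out
      sc_cache <- list(conv = cp$cache, bn = bp$cache)
    } else {
      sc <- A
      sc_cache <- NULL
    }
    s <- b2$out + sc
    r2 <- relu_fwd(s)
    caches$blocks[[i]] <- list(name = nm, blk = blk,
                               conv1 = c1$cache, bn1 = b1$cache,
                               relu1 = r1$cache, conv2 = c2$cache,
                               bn2 = b2$cache, sc = sc_cache,
                               relu2 = r2$cache)
    A <- r2$out
    if (!is.null(capture)) {
      # a bare block id probes the block's first convolutional layer; the
      # second convolution and the post-residual output are addressable
      # with explicit suffixes
      if (identical(capture, nm) ||
          identical(capture, paste0(nm, ".conv1"))) {
        captured <- r1$out
      }
      if (identical(capture, paste0(nm, ".conv2"))) captured <- b2$out
      if (identical(capture, paste0(nm, ".out"))) captured <- A
    }
  }
  if (!is.null(capture) && is.null(captured) &&
      !identical(capture, "input")) {
    abort(sprintf("Unknown layer id '%s'.", capture))
  }

  gp <- gap_fwd(A)
  H <- gp$out
  if (training && cfg$dropout_rate > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        (runif(length(H)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
        nrow(H), ncol(H))
    }
    H <- H * dropout_mask
  }
  z <- as.numeric(H %*% p[["fc.W"]] + p[["fc.b"]])
  caches$head <- list(gap = gp$cache, H = H, dropout_mask = dropout_mask)
  list(logits = z, caches = caches, state = st, captured = captured)
}

# Backward pass from d(loss)/d(logit). Returns flat gradient list matching
# params, plus the gradient arriving at the captured block output and at the
# input (for guided saliency).
network_backward <- function(model, fwd, dz, capture = NULL,
                             guided = FALSE) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  captured_grad <- NULL

  H <- fwd$caches$head$H
  grads[["fc.W"]] <- crossprod(H, dz)
  grads[["fc.b"]] <- sum(dz)
  dH <- dz %*% t(p[["fc.W"]])
  if (!is.null(fwd$caches$head$dropout_mask)) {
    dH <- dH * fwd$caches$head$dropout_mask
  }
  dA <- gap_bwd(dH, fwd$caches$head$gap)

  plan <- block_plan(cfg)
  for (i in rev(seq_along(plan))) {
    cb <- fwd$caches$blocks[[i]]
    nm <- cb$name
    if (!is.null(capture) && identical(capture, paste0(nm, ".out"))) {
      captured_grad <- dA
    }
    dsum <- relu_bwd(dA, cb$relu2, guided)
    db2 <- bn_bwd(dsum, cb$bn2)
    if (!is.null(capture) && identical(capture, paste0(nm, ".conv2"))) {
      captured_grad <- dsum
    }
    grads[[paste0(nm, ".bn2.gamma")]] <- db2$dgamma
    grads[[paste0(nm, ".bn2.beta")]] <- db2$dbeta
    dc2 <- conv1d_bwd(db2$dX, cb$conv2)
    grads[[paste0(nm, ".conv2.W")]] <- dc2$dW
    dr1 <- relu_bwd(dc2$dX, cb$relu1, guided)
    if (!is.null(capture) && (identical(capture, nm) ||
                              identical(capture, paste0(nm, ".conv1")))) {
      captured_grad <- dc2$dX
    }
    db1 <- bn_bwd(dr1, cb$bn1)
    grads[[paste0(nm, ".bn1.gamma")]] <- db1$dgamma
    grads[[paste0(nm, ".bn1.beta")]] <- db1$dbeta
    dc1 <- conv1d_bwd(db1$dX, cb$conv1)
    grads[[paste0(nm, ".conv1.W")]] <- dc1$dW
    if (cb$blk$proj) {
      dbp <- bn_bwd(dsum, cb$sc$bn)
      grads[[paste0(nm, ".projbn.gamma")]] <- dbp$dgamma
      grads[[paste0(nm, ".projbn.beta")]] <- dbp$dbeta
      dcp <- conv1d_bwd(dbp$dX, cb$sc$conv)
      grads[[paste0(nm, ".proj.W")]] <- dcp$dW
      dA <- dc1$dX + dcp$dX
    } else {
      dA <- dc1$dX + dsum
    }
  }

  cs <- fwd$caches$stem
  dA <- maxpool_bwd(dA, cs$pool)
  dA <- relu_bwd(dA, cs$relu, guided)
  dbs <- bn_bwd(dA, cs$bn)
  grads[["stem.bn.gamma"]] <- dbs$dgamma
  grads[["stem.bn.beta"]] <- dbs$dbeta
  dcs <- conv1d_bwd(dbs$dX, cs$conv)
  grads[["stem.conv.W"]] <- dcs$dW

  list(grads = grads, captured_grad = captured_grad, dinput = dcs$dX)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p_hat, y, eps = 1e-12) {
  p_hat <- pmin(pmax(p_hat, eps), 1 - eps)
  -mean(y * log(p_hat) + (1 - y) * log(1 - p_hat))
}

#' Training configuration
#'
#' Binary cross-entropy loss minimized with Adam; He initialization; either
#' a reduce-on-plateau learning-rate schedule (factor 0.5, patience 3, on
#' validation AUC) or cosine annealing.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial Adam learning rate.
#' @param epochs Training epochs.
#' @param scheduler `"plateau"` or `"cosine"`.
#' @param plateau_factor,plateau_patience Plateau schedule parameters.
#' @param seed Seed controlling initialization, shuffling, dropout and
#'   augmentation draws.
#' @param pos_weight Weight on positive-class terms of the loss (1 = none).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 64, learning_rate = 1e-3,
                         epochs = 30, scheduler = c("plateau", "cosine"),
                         plateau_factor = 0.5, plateau_patience = 3,
                         seed = 1L, pos_weight = 1) {
  scheduler <- match.arg(scheduler)
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), scheduler = scheduler,
                 plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 seed = as.integer(seed), pos_weight = pos_weight),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train the classifier
#'
#' Minimizes binary cross-entropy with Adam over mini-batches, optionally
#' augmenting each training trace per epoch via [augment_pipeline()].
#' Validation AUC is evaluated after every epoch and the checkpoint with the
#' best validation AUC is returned. The whole run is deterministic under
#' `train_cfg$seed`.
#'
#' @param x_train,y_train Training matrix (rows = preprocessed length-1000
#'   traces in \[0, 1\]) and binary labels.
#' @param x_val,y_val Validation set (patient-disjoint from training).
#' @param config A [model_config()].
#' @param train_cfg A [train_config()].
#' @param restore_best Return the checkpoint with the best validation AUC
#'   (default) instead of the final-epoch parameters.
#' @param augment_cfg Optional [augment_config()]; `NULL` disables
#'   augmentation.
#' @return A trained `fast_cnn` with `history` (tibble: `epoch`,
#'   `train_loss`, `val_auc`, `lr`) and `best_epoch`.
#' @export
train_model <- function(x_train, y_train, x_val, y_val,
                        config = model_config(reduced = TRUE),
                        train_cfg = train_config(),
                        augment_cfg = NULL, restore_best = TRUE) {
  y_train <- as.integer(as.logical(y_train))
  y_val <- as.integer(as.logical(y_val))
  if (length(unique(y_train)) < 2) {
    abort("Training set must contain both classes.")
  }
  model <- build_model(config, seed = train_cfg$seed)
  opt <- adam_init(model$params)
  lr <- train_cfg$learning_rate
  n <- nrow(x_train)
  best_auc <- -Inf
  best <- NULL
  best_epoch <- 0L
  stall <- 0L
  history <- vector("list", train_cfg$epochs)

  with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs)) {
      if (train_cfg$scheduler == "cosine") {
        lr <- train_cfg$learning_rate * 0.5 *
          (1 + cos(pi * (epoch - 1) / train_cfg$epochs))
      }
      idx <- sample.int(n)
      losses <- numeric(0)
      for (b0 in seq(1, n, by = train_cfg$batch_size)) {
        bi <- idx[b0:min(b0 + train_cfg$batch_size - 1L, n)]
        xb <- x_train[bi, , drop = FALSE]
        if (!is.null(augment_cfg)) {
          for (r in seq_len(nrow(xb))) {
            xb[r, ] <- augment_pipeline(xb[r, ], augment_cfg)$values
          }
        }
        yb <- y_train[bi]
        fwd <- network_forward(model, xb, training = TRUE)
        model$state <- fwd$state
        p_hat <- sigmoid(fwd$logits)
        w <- ifelse(yb == 1, train_cfg$pos_weight, 1)
        losses <- c(losses, bce_loss(p_hat, yb))
        dz <- matrix(w * (p_hat - yb) / length(yb), ncol = 1)
        bwd <- network_backward(model, fwd, dz)
        upd <- adam_step(model$params, bwd$grads, opt, lr)
        model$params <- upd$params
        opt <- upd$opt
      }
      val_scores <- predict_cnn(model, x_val)
      val_auc <- if (length(unique(y_val)) > 1) {
        auc_rank(val_scores, y_val)
      } else NA_real_
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(losses), val_auc = val_auc,
        lr = lr)
      if (!is.na(val_auc) && val_auc > best_auc + 1e-9) {
        best_auc <- val_auc
        best <- list(params = model$params, state = model$state)
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (train_cfg$scheduler == "plateau" &&
            stall >= train_cfg$plateau_patience) {
          lr <- lr * train_cfg$plateau_factor
          stall <- 0L
        }
      }
    }
  })

  if (restore_best && !is.null(best)) {
    model$params <- best$params
    model$state <- best$state
  }
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- best_epoch
  model$train_cfg <- train_cfg
  model
}

#' Hyper-parameter grid search with patient-level cross-validation
#'
#' Evaluates every combination of batch size, learning rate and scheduler
#' by k-fold cross-validation over patients, reporting the mean validation
#' AUC per combination. The searched grid defaults to batch size
#' 32/64/128, learning rate 1e-2/1e-3/1e-4, and the plateau or cosine
#' schedule.
#'
#' @param x Numeric matrix of preprocessed traces.
#' @param y Binary labels.
#' @param patient_ids Patient id per record (folds never split a patient).
#' @param config A [model_config()].
#' @param batch_sizes,learning_rates,schedulers Grid axes.
#' @param epochs Training epochs per fit.
#' @param n_folds Cross-validation folds.
#' @param augment_cfg Optional [augment_config()].
#' @param seed Base seed.
#' @return Tibble with one row per combination: `batch_size`,
#'   `learning_rate`, `scheduler`, `mean_auc`, `sd_auc`, sorted by
#'   decreasing `mean_auc`.
#' @export
grid_search_cnn <- function(x, y, patient_ids,
                            config = model_config(reduced = TRUE),
                            batch_sizes = c(32, 64, 128),
                            learning_rates = c(1e-2, 1e-3, 1e-4),
                            schedulers = c("plateau", "cosine"),
                            epochs = 5, n_folds = 3,
                            augment_cfg = NULL, seed = 1L) {
  grid <- expand.grid(batch_size = batch_sizes,
                      learning_rate = learning_rates,
                      scheduler = schedulers,
                      stringsAsFactors = FALSE)
  fold_id <- patient_folds(patient_ids, n_folds, seed = seed)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(n_folds), function(f) {
      te <- fold_id == f
      if (length(unique(y[!te])) < 2 || length(unique(y[te])) < 2) {
        return(NA_real_)
      }
      m <- train_model(
        x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE], y[te],
        config = config,
        train_cfg = train_config(batch_size = grid$batch_size[g],
                                 learning_rate = grid$learning_rate[g],
                                 scheduler = grid$scheduler[g],
                                 epochs = epochs, seed = seed + g),
        augment_cfg = augment_cfg)
      auc_rank(predict_cnn(m, x[te, , drop = FALSE]), y[te])
    }, numeric(1))
    tibble::tibble(batch_size = grid$batch_size[g],
                   learning_rate = grid$learning_rate[g],
                   scheduler = grid$scheduler[g],
                   mean_auc = mean(aucs, na.rm = TRUE),
                   sd_auc = sd(aucs, na.rm = TRUE))
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$mean_auc))
}

# Batched evaluation-mode probabilities.
predict_cnn <- function(model, x, batch = 256L) {
  n <- nrow(x)
  out <- numeric(n)
  for (b0 in seq(1, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    fwd <- network_forward(model, x[bi, , drop = FALSE], training = FALSE)
    out[bi] <- sigmoid(fwd$logits)
  }
  out
}

#' Predict FaST probabilities
#'
#' @param object A trained `fast_cnn`.
#' @param newdata Matrix of preprocessed traces (rows), or a single numeric
#'   vector.
#' @param ... Unused.
#' @return Numeric probabilities in \[0, 1\], one per row.
#' @export
predict.fast_cnn <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1)
  }
  predict_cnn(object, newdata)
}
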