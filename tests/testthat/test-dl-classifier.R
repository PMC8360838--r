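# Small configuration used throughout: full topology, tiny widths.
tiny_config <- function(len = 200) {
  model_config(input_length = len, stem_channels = 4,
               stage_blocks = c(1, 1), stage_channels = c(4, 8),
               dropout_rate = 0.2)
}

# Toy task with matched global statistics: every record carries the same
# periodic dips and the same positive lobes; in class 0 the lobe sits
# immediately before each dip (RS-like), in class 1 the lobes sit at random
# positions away from the dips (QS-like). Only the local arrangement
# separates the classes, so raw-sample linear models have little to work
# with while a convolutional model can learn the compound shape.
toy_task <- function(n, len = 200, seed = 1) {
  with_seed(seed, {
    x <- matrix(0, n, len)
    y <- rbinom(n, 1, 0.5)
    for (i in seq_len(n)) {
      base <- rnorm(len, 0, 0.05)
      amp <- runif(1, 0.5, 1.2)
      pos <- round(seq(runif(1, 8, 40), len - 12, by = 40))
      for (p in pos) {
        base[p + 4:10] <- base[p + 4:10] - amp * sin(pi * (0:6) / 6)
      }
      bumps <- if (y[i] == 0) pos else round(runif(length(pos), 12, len - 12))
      for (q in bumps) {
        base[q + 0:3] <- base[q + 0:3] + 0.5 * amp * sin(pi * (0:3) / 3)
      }
      x[i, ] <- minmax_scale(base)
    }
    list(x = x, y = y)
  })
}

test_that("the network builds reproducibly with the documented topology", {
  m1 <- build_model(tiny_config(), seed = 5)
  m2 <- build_model(tiny_config(), seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_config(), seed = 6)
  expect_false(identical(m1$params, m3$params))

  # forward on all-zeros input is a single probability strictly inside (0,1)
  p <- predict(m1, matrix(0, 1, 200))
  expect_length(p, 1)
  expect_gt(p, 0)
  expect_lt(p, 1)

  expect_error(predict(m1, matrix(0, 1, 150)), "length")

  # parameter count equals the closed-form layer arithmetic
  expect_identical(
    n_parameters(build_model(model_config(), seed = 1)),
    expected_param_count(64, c(2, 2, 2, 2), c(64, 128, 256, 512)))
  expect_identical(
    n_parameters(build_model(model_config(reduced = TRUE), seed = 1)),
    expected_param_count(16, c(2, 2, 2, 2), c(16, 32, 64, 128)))
  expect_identical(n_parameters(m1), expected_param_count(4, c(1, 1), c(4, 8)))
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(input_length = 64, stem_channels = 4,
                      stage_blocks = c(1, 1), stage_channels = c(4, 8),
                      dropout_rate = 0)
  m <- build_model(cfg, seed = 1)
  X <- with_seed(42, matrix(runif(2 * 64), 2, 64))
  y <- c(0, 1)
  loss_of <- function(mm) {
    fwd <- fastegm:::network_forward(mm, X, training = TRUE)
    fastegm:::bce_loss(fastegm:::sigmoid(fwd$logits), y)
  }
  fwd <- fastegm:::network_forward(m, X, training = TRUE)
  p <- fastegm:::sigmoid(fwd$logits)
  bwd <- fastegm:::network_backward(m, fwd, matrix((p - y) / 2, ncol = 1))
  for (nm in c("stem.conv.W", "stage1.block0.conv1.W",
               "stage2.block0.proj.W", "stage2.block0.bn2.gamma",
               "stage1.block0.bn1.beta", "fc.W", "fc.b")) {
    g <- bwd$grads[[nm]]
    i <- which.max(abs(g))
    eps <- 1e-5
    m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    m3 <- m; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
    num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
    expect_lt(abs(g[i] - num) / max(abs(num), 1e-12), 1e-8)
  }
})

test_that("prediction is batch-order invariant and deterministic", {
  m <- build_model(tiny_config(), seed = 2)
  x <- with_seed(3, matrix(runif(6 * 200), 6, 200))
  p <- predict(m, x)
  expect_true(all(p >= 0 & p <= 1))
  # identical rows give identical outputs
  xx <- x[c(1, 1, 1), ]
  expect_equal(predict(m, xx), rep(p[1], 3))
  # permuting the batch permutes the outputs
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(predict(m, x[perm, ]), p[perm])
})

test_that("training learns the arrangement task and is seed-reproducible", {
  tr <- toy_task(240, seed = 11)
  te <- toy_task(120, seed = 12)
  cfg <- train_config(batch_size = 32, learning_rate = 1e-3, epochs = 14,
                      seed = 21)
  m <- train_model(tr$x, tr$y, te$x, te$y, tiny_config(), cfg)
  expect_identical(nrow(m$history), 14L)
  auc <- roc_auc(predict(m, te$x), te$y)$auc
  expect_gt(auc, 0.9)

  # exact determinism of the whole run
  m2 <- train_model(tr$x, tr$y, te$x, te$y, tiny_config(), cfg)
  expect_equal(m$history$val_auc, m2$history$val_auc, tolerance = 1e-6)
  expect_equal(predict(m, te$x), predict(m2, te$x), tolerance = 1e-6)

  expect_error(train_model(tr$x, rep(1, 240), te$x, te$y, tiny_config(),
                           cfg),
               "both classes")
})

test_that("training on permuted labels generalizes at chance level", {
  tr <- toy_task(240, seed = 11)
  te <- toy_task(120, seed = 12)
  te_big <- toy_task(400, seed = 14)
  yperm <- with_seed(31, sample(tr$y))
  # trained to convergence the permuted-label model approaches a constant
  # predictor; its final-epoch AUC on fresh data sits at chance
  mnull <- train_model(tr$x, yperm, te$x, te$y, tiny_config(),
                       train_config(batch_size = 32, epochs = 25, seed = 22),
                       restore_best = FALSE)
  auc_null <- roc_auc(predict(mnull, te_big$x), te_big$y)$auc
  expect_gt(auc_null, 0.4)
  expect_lt(auc_null, 0.6)
})

test_that("classic baselines produce usable scores and sane errors", {
  expect_error(fit_baseline("knn", matrix(0, 2, 4), c(0, 1), knn_k = 10),
               "exceeds")
  expect_error(fit_baseline("boosting", matrix(0, 4, 4), c(0, 1, 0, 1)))

  # logistic regression separates a linearly separable toy set
  with_seed(41, {
    x <- matrix(rnorm(60 * 5), 60, 5)
    y <- as.integer(x[, 1] + x[, 2] > 0)
  })
  lr <- fit_baseline("logistic_regression", x, y, lambda = 1e-4)
  expect_equal(roc_auc(predict(lr, x), y)$auc, 1.0)

  sv <- fit_baseline("svm", x, y, svm_degree = 3)
  expect_gt(roc_auc(predict(sv, x), y)$auc, 0.9)

  kn <- fit_baseline("knn", x, y, knn_k = 10)
  sc <- predict(kn, x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(roc_auc(sc, y)$auc, 0.8)
})

test_that("the hyper-parameter grid search ranks combinations by CV AUC", {
  tr <- toy_task(180, seed = 61)
  pat <- rep(sprintf("P%02d", 1:6), each = 30)
  res <- grid_search_cnn(tr$x, tr$y, pat, config = tiny_config(),
                         batch_sizes = 32, learning_rates = c(1e-3, 1e-5),
                         schedulers = "plateau", epochs = 3, n_folds = 3,
                         seed = 62)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$mean_auc >= 0 & res$mean_auc <= 1))
  # results arrive sorted best-first
  expect_true(!is.unsorted(rev(res$mean_auc)))
})

test_that("the network beats the raw-sample logistic baseline", {
  tr <- toy_task(240, seed = 11)
  te <- toy_task(120, seed = 12)
  m <- train_model(tr$x, tr$y, te$x, te$y, tiny_config(),
                   train_config(batch_size = 32, epochs = 14, seed = 21))
  auc_nn <- roc_auc(predict(m, te$x), te$y)$auc
  lr <- fit_baseline("logistic_regression", tr$x, tr$y)
  auc_lr <- roc_auc(predict(lr, te$x), te$y)$auc
  expect_gt(auc_nn, auc_lr)

  gl <- glance(m)
  expect_identical(gl$epochs, 14L)
  expect_equal(gl$best_val_auc, max(m$history$val_auc))
})
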