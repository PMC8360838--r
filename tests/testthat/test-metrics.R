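test_that("rank AUC equals pair counting and the reference implementation", {
  # worked example: 3 of 4 positive-negative pairs correctly ranked
  sc <- c(0.1, 0.4, 0.35, 0.8)
  lb <- c(0, 0, 1, 1)
  expect_equal(roc_auc(sc, lb)$auc, 0.75)

  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  with_seed(19, {
    for (rep in 1:20) {
      n <- sample(5:60, 1)
      s <- sample(round(runif(n), 2), n, replace = TRUE)  # forces ties
      l <- rbinom(n, 1, 0.4)
      if (length(unique(l)) < 2) next
      expect_equal(roc_auc(s, l)$auc, brute_force_auc(s, l))
      expect_equal(roc_auc(s, l)$auc,
                   as.numeric(pROC::auc(pROC::roc(
                     l, s, quiet = TRUE, direction = "<",
                     levels = c(0, 1)))))
    }
  })

  # bootstrap CI brackets the point estimate and is seed-stable
  s <- with_seed(7, c(rnorm(40, 1), rnorm(60)))
  l <- rep(c(1, 0), c(40, 60))
  a1 <- roc_auc(s, l, ci = TRUE, n_boot = 500, seed = 3)
  a2 <- roc_auc(s, l, ci = TRUE, n_boot = 500, seed = 3)
  expect_identical(a1, a2)
  expect_lte(a1$ci_lower, a1$auc)
  expect_gte(a1$ci_upper, a1$auc)
})

test_that("sensitivity-targeted thresholds are the largest feasible", {
  # perfect classifier: the threshold separates the classes cleanly
  s <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  l <- c(0, 0, 0, 1, 1)
  th <- threshold_at_sensitivity(s, l, 0.9)
  m <- metrics_at_threshold(s, l, th)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  # 10 distinct positives at target 0.9: admit exactly 9 or 10, never 8
  with_seed(23, {
    for (rep in 1:20) {
      sp <- sort(runif(10))
      sn <- runif(15)
      s <- c(sp, sn)
      l <- rep(c(1, 0), c(10, 15))
      th <- threshold_at_sensitivity(s, l, 0.9)
      n_admit <- sum(sp >= th)
      expect_gte(n_admit, 9)
      # achieved sensitivity is the minimum achievable >= target
      # (exhaustive sweep over all candidate thresholds)
      cand <- sort(unique(s), decreasing = TRUE)
      achieved <- vapply(cand, function(t0) mean(sp >= t0), 1)
      expect_equal(mean(sp >= th), min(achieved[achieved >= 0.9]))
    }
  })

  expect_equal(threshold_at_sensitivity(c(0.2, 0.5, 0.9), c(1, 1, 1), 1),
               0.2)
})

test_that("operating-point metrics satisfy the exact identities", {
  with_seed(29, {
    s <- runif(200)
    l <- rbinom(200, 1, 0.3)
    for (th in c(0.2, 0.5, 0.8)) {
      m <- metrics_at_threshold(s, l, th)
      expect_equal(m$f1, 2 * m$ppv * m$sensitivity /
                     (m$ppv + m$sensitivity))
      expect_equal(m$accuracy,
                   m$prevalence * m$sensitivity +
                     (1 - m$prevalence) * m$specificity)
      expect_identical(m$tp + m$fp + m$tn + m$fn, 200L)
    }
  })

  perfect <- metrics_at_threshold(c(0.9, 0.8, 0.1), c(1, 1, 0), 0.5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f1, 1)
  expect_error(metrics_at_threshold(numeric(0), numeric(0), 0.5), "Empty")

  ops <- operating_points(c(0.9, 0.8, 0.7, 0.2, 0.1),
                          c(1, 1, 1, 0, 0))
  expect_identical(nrow(ops), 3L)
  expect_true(all(ops$sensitivity >= ops$target_sensitivity))
})

test_that("Cohen's kappa matches hand computation and null behaviour", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)

  # TP=40 FP=10 FN=10 TN=40: p_o = 0.8, p_e = 0.5, kappa = 0.6
  a <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  b <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(cohen_kappa(a, b), 0.6)

  # independent raters at 50/50 marginals: kappa near zero
  with_seed(31, {
    x <- rbinom(10000, 1, 0.5)
    y <- rbinom(10000, 1, 0.5)
    expect_lt(abs(cohen_kappa(x, y)), 0.05)
  })

  expect_equal(cohen_kappa(c(1, 1), c(1, 1)), 1)
  expect_error(cohen_kappa(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("patient-level cross-validation keeps folds disjoint", {
  pat <- rep(sprintf("P%02d", 1:6), each = 10)
  folds <- patient_folds(pat, 3, seed = 2)
  expect_identical(sort(unique(folds)), 1:3)
  for (f in 1:3) {
    expect_length(intersect(unique(pat[folds == f]),
                            unique(pat[folds != f])), 0L)
  }
  expect_error(patient_folds(rep("P1", 5), 3), "Fewer patients")

  # five seeds give five recorded (generally distinct) assignments, and a
  # fast surrogate classifier exercises the full loop
  with_seed(37, {
    x <- matrix(rnorm(60 * 8), 60, 8)
    y <- rbinom(60, 1, 0.5)
    x[y == 1, 1] <- x[y == 1, 1] + 3
  })
  cv <- cross_validate(
    x, y, pat, cv_plan(n_folds = 3, n_seeds = 5),
    fit = function(x, y, seed) suppressWarnings(
      glm.fit(cbind(1, x), y, family = binomial())),
    score = function(m, x) as.numeric(cbind(1, x) %*% m$coefficients),
    seed = 11)
  expect_identical(length(unique(cv$folds$seed)), 5L)
  expect_identical(nrow(glance(cv)), 1L)
  expect_gt(glance(cv)$mean_auc, 0.8)
  expect_identical(nrow(tidy(cv)), nrow(cv$folds))
})

test_that("training-size subsampling produces the expected learning trend", {
  # a noisy linear task where more training data visibly helps
  pat <- rep(sprintf("P%02d", 1:12), each = 30)
  with_seed(43, {
    x <- matrix(rnorm(360 * 20), 360, 20)
    p <- plogis(0.5 * x[, 1] + 0.5 * x[, 2] - 0.3 * x[, 3])
    y <- rbinom(360, 1, p)
  })
  cv <- cross_validate(
    x, y, pat,
    cv_plan(n_folds = 3, n_seeds = 2,
            subsample_fractions = c(0.25, 1.0)),
    fit = function(x, y, seed) suppressWarnings(
      glm.fit(cbind(1, x), y, family = binomial())),
    score = function(m, x) as.numeric(cbind(1, x) %*% m$coefficients),
    seed = 19)
  gl <- glance(cv)
  expect_identical(nrow(gl), 2L)
  # mean AUC with the full training set is not below the quarter-sized
  # runs by more than one pooled standard deviation
  full <- gl$mean_auc[gl$fraction == 1.0]
  quarter <- gl$mean_auc[gl$fraction == 0.25]
  pooled_sd <- sqrt(mean(gl$sd_auc^2))
  expect_gte(full, quarter - pooled_sd)
})

test_that("record and manifest files round-trip", {
  dir <- withr::local_tempdir()
  r <- synth_record("PERIODIC_RS", seed = 41)
  path <- file.path(dir, "rec.tsv")
  write_record(r$record, path, r$truth)
  back <- read_record(path)
  expect_identical(back$record_id, r$record$record_id)
  expect_identical(back$sampling_rate, r$record$sampling_rate)
  expect_lt(max(abs(back$unipolar - r$record$unipolar)), 1e-9)
  expect_lt(max(abs(back$bipolar - r$record$bipolar)), 1e-9)
  expect_identical(attr(back, "class_name"), "PERIODIC_RS")
  expect_identical(attr(back, "label"), 0L)

  # missing header key
  lines <- readLines(path)
  writeLines(lines[-3], file.path(dir, "bad.tsv"))
  expect_error(read_record(file.path(dir, "bad.tsv")), "sampling_rate_hz")

  # ragged body line
  lines2 <- lines
  lines2[10] <- "1\t2"
  writeLines(lines2, file.path(dir, "ragged.tsv"))
  expect_error(read_record(file.path(dir, "ragged.tsv")), "3 tab-separated")

  # duplicate manifest paths are flagged
  mf <- tibble::tibble(record_path = c("a", "a"), patient_id = c("P", "P"),
                       label = c(0L, 1L), class_name = c("X", "Y"))
  write_manifest(mf, file.path(dir, "manifest.tsv"))
  expect_error(read_manifest(file.path(dir, "manifest.tsv")), "duplicate")

  # whole-cohort round trip through the on-disk layout
  co <- synth_cohort(4, seed = 43)
  man <- write_cohort(co, file.path(dir, "cohort"))
  man2 <- read_manifest(file.path(dir, "cohort", "manifest.tsv"))
  expect_identical(man2$label, co$manifest$label)
  r2 <- read_record(man2$record_path[2])
  expect_lt(max(abs(r2$unipolar - co$records[[2]]$unipolar)), 1e-9)
})
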