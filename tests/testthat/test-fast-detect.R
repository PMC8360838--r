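test_that("the bipolar envelope isolates the activation-rate line", {
  fs <- 1000
  # zero in, zero out
  expect_equal(preprocess_bipolar(numeric(5000), fs), numeric(5000))

  # a pure 100 Hz carrier has no sub-20 Hz modulation: its rectified
  # envelope is constant, which the 0.5 Hz high-pass removes
  x <- sin(2 * pi * 100 * (0:4999) / fs)
  env <- preprocess_bipolar(x, fs)
  expect_lt(sd(env[500:4500]), 0.05 * sd(x))

  # 100 Hz bursts repeating at CL 200 ms modulate the envelope at 5 Hz
  burst <- sin(2 * pi * 100 * (0:9) / fs)
  x2 <- numeric(5000)
  for (t0 in seq(1, 4801, by = 200)) x2[t0:(t0 + 9)] <- burst
  env2 <- preprocess_bipolar(x2, fs)
  expect_equal(dominant_freq(env2[500:4500], fs), 5.0, tolerance = 0.2)

  expect_error(preprocess_bipolar(numeric(1000), fs), "2 s")
  expect_error(preprocess_bipolar(numeric(5000), 400), "too low")
})

test_that("spectral periodicity recovers the cycle length in-window only", {
  fs <- 1000
  cfg <- clean_config()
  # noiseless synthetic trains across the physiologic window
  for (cl in c(100, 150, 200, 250)) {
    r <- synth_record("FAST_QS", cfg, seed = 3, cl = cl)
    p <- spectral_periodicity(preprocess_bipolar(r$record$bipolar, fs), fs)
    expect_true(p$is_periodic)
    expect_equal(p$periodicity_cl, cl, tolerance = 5 / cl)
  }

  # a train at CL 500 ms is outside the 100-250 ms window: even though its
  # 4 Hz harmonic lies inside, the record must not be called periodic
  x <- numeric(5000)
  for (t0 in seq(50, 4950, by = 500)) {
    x[t0:(t0 + 16)] <- x[t0:(t0 + 16)] + 0.8 * bipolar_kernel(fs)
  }
  p <- spectral_periodicity(preprocess_bipolar(x, fs), fs)
  expect_false(p$is_periodic)

  # white noise: peak power fraction below the 10% criterion
  noise <- with_seed(42, rnorm(5000, 0, 0.05))
  pn <- spectral_periodicity(preprocess_bipolar(noise, fs), fs)
  expect_false(pn$is_periodic)
  expect_lt(pn$peak_power_fraction, 0.10)

  # all-zero envelope is not an error
  p0 <- spectral_periodicity(numeric(5000), fs)
  expect_false(p0$is_periodic)
  expect_equal(p0$peak_power_fraction, 0)
})

test_that("candidate detection enforces the amplitude and slew thresholds", {
  fs <- 1000
  expect_length(detect_candidates(numeric(5000), fs), 0)

  # single deflection below the 0.05 mV noise threshold is rejected
  deflect <- function(amp, width_ms) {
    x <- numeric(3000)
    t <- seq(-width_ms, width_ms)
    x[1500 + t] <- amp * exp(-t^2 / (2 * (width_ms / 3)^2))
    x
  }
  expect_length(detect_candidates(deflect(0.04, 6), fs), 0)
  expect_length(detect_candidates(deflect(0.06, 6), fs), 1)

  # 1 mV deflection with max slew 0.010 mV/ms rejected; sharpened accepted
  slow <- deflect(1, 150)  # max slew ~ 1/(150/3) * 0.6 ~ 0.012 mV/ms
  expect_lt(max(abs(diff(slow))), 0.014)
  expect_length(detect_candidates(slow, fs), 0)
  sharp <- deflect(1, 60)
  expect_gt(max(abs(diff(sharp))), 0.014)
  expect_length(detect_candidates(sharp, fs), 1)

  # refractory spacing and monotone ordering on a periodic train
  x <- numeric(5000)
  for (t0 in seq(100, 4900, by = 150)) {
    x[t0 + 0:16] <- x[t0 + 0:16] + bipolar_kernel(fs)
  }
  cand <- detect_candidates(x, fs)
  expect_true(all(diff(cand) >= 50))
  expect_length(cand, 33)

  # raising the noise threshold never increases the candidate count
  p_lo <- fast_params(noise_threshold = 0.05)
  p_hi <- fast_params(noise_threshold = 0.4)
  y <- with_seed(9, x * runif(1, 0.5, 1) + rnorm(5000, 0, 0.01))
  expect_lte(length(detect_candidates(y, fs, p_hi)),
             length(detect_candidates(y, fs, p_lo)))
})

test_that("graph search matches exhaustive enumeration", {
  # worked examples
  tr <- select_periodic_train(c(100, 300, 500, 700, 950), 200)
  expect_equal(tr$chain, c(100, 300, 500, 700))
  expect_equal(tr$total_cost, 0)

  tr1 <- select_periodic_train(100, 200)
  expect_equal(tr1$chain, 100)
  expect_equal(tr1$chain_length, 1L)

  tr0 <- select_periodic_train(numeric(0), 200)
  expect_equal(tr0$chain_length, 0L)

  # two disjoint length-3 chains: the cheaper one wins
  a <- c(100, 306, 512)        # cost |206-200| + |206-200| = 12
  b <- c(2000, 2202, 2404)     # cost 2 + 2 = 4
  tr2 <- select_periodic_train(sort(c(a, b)), 200)
  expect_equal(tr2$chain, b)
  expect_equal(tr2$total_cost, 4)

  # property: DP equals brute force on random candidate sets
  with_seed(77, {
    for (rep in 1:60) {
      n <- sample(0:12, 1)
      cl <- runif(1, 100, 250)
      cand <- sort(runif(n, 0, 3000))
      got <- select_periodic_train(cand, cl)
      want <- brute_force_chain(cand, cl)
      expect_equal(got$chain, want$chain)
      expect_equal(got$total_cost, want$cost, tolerance = 1e-9)
    }
  })
})

test_that("unipolar morphology is measured against a local baseline", {
  fs <- 1000
  p_exact <- fast_params(morphology_smooth_ms = 0)
  place <- function(kind, ratio, amp = 1) {
    x <- numeric(2000)
    tm <- egm_template(kind, 40, amp, ratio, fs)
    x[991:(990 + length(tm))] <- tm  # onset at 1000 ms, like the generator
    x
  }
  m1 <- classify_morphology(place("rS", 0.05), fs, 1000, p_exact)
  expect_equal(m1$rs_ratio, 0.05, tolerance = 1e-6)
  expect_true(m1$is_qs)

  m2 <- classify_morphology(place("QS", 0), fs, 1000, p_exact)
  expect_equal(m2$rs_ratio, 0)
  expect_true(m2$is_qs)

  m3 <- classify_morphology(place("RS", 0.2), fs, 1000, p_exact)
  expect_equal(m3$rs_ratio, 0.2, tolerance = 1e-6)
  expect_false(m3$is_qs)

  # a DC baseline offset does not change the measurement
  m4 <- classify_morphology(place("RS", 0.2) + 3.7, fs, 1000, p_exact)
  expect_equal(m4$rs_ratio, 0.2, tolerance = 1e-6)

  # sub-noise complexes are flagged indeterminate
  m5 <- classify_morphology(place("QS", 0, amp = 0.04), fs, 1000, p_exact)
  expect_true(m5$indeterminate)

  expect_identical(nrow(classify_morphology(numeric(2000), fs,
                                            numeric(0))), 0L)
})

test_that("the hierarchical decision composes the stages correctly", {
  fs <- 1000
  r <- synth_record("FAST_QS", seed = 101, cl = 200)
  d <- classify_fast(r$record)
  expect_true(d$is_fast)
  expect_gte(d$qs_fraction, 0.9)
  expect_true(d$sustained)

  rsw <- synth_record("SWITCHING", seed = 102, cl = 200)
  dsw <- classify_fast(rsw$record)
  expect_false(dsw$is_fast)
  expect_equal(dsw$qs_fraction, 0.72, tolerance = 0.06)

  # pure-noise record: non-periodic short-circuit with no morphology calls
  rap <- structure(
    list(record_id = "NOISE", patient_id = "P000", sampling_rate = fs,
         duration = 5,
         unipolar = with_seed(103, rnorm(5000, 0, 0.05)),
         bipolar = with_seed(104, rnorm(5000, 0, 0.02))),
    class = "egm_record")
  dap <- classify_fast(rap)
  expect_false(dap$is_fast)
  expect_false(dap$periodicity$is_periodic)
  expect_identical(nrow(dap$calls), 0L)

  short <- r$record
  short$unipolar <- short$unipolar[1:1000]
  expect_error(classify_fast(short), "2 s")

  # scale invariance: amplifying both traces never flips a decision made
  # with margin above the absolute thresholds
  for (k in c(1, 2, 5)) {
    rs <- r$record
    rs$unipolar <- rs$unipolar * k
    rs$bipolar <- rs$bipolar * k
    expect_true(classify_fast(rs)$is_fast)
  }

  td <- tidy(d)
  expect_identical(nrow(td), 1L)
  expect_true(td$is_fast)
})

test_that("detector agrees with ground truth across a mixed cohort", {
  co <- synth_cohort(120, seed = 55)
  det <- detect_cohort(co$records)
  agreement <- mean(det$is_fast == (co$manifest$label == 1))
  expect_gte(agreement, 0.95)
})
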