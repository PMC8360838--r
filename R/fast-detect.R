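#' Parameters of the rule-based FaST algorithm
#'
#' Defaults follow the published operating values: bipolar band-pass
#' 40-250 Hz, rectification, then 0.5-20 Hz; a spectral peak holding at
#' least 10% of total spectral power within the 100-250 ms cycle-length
#' window declares periodicity; candidate activations must exceed 0.05 mV
#' and a slew rate of 0.014 mV/ms; a site is FaST when the periodic train is
#' sustained and more than 90% of its unipolar complexes are QS
#' (R/S ratio < 0.1).
#'
#' @param band1 First bipolar band-pass (Hz).
#' @param band2 Post-rectification band-pass (Hz).
#' @param power_fraction_threshold Minimum fraction of total spectral power
#'   in the peak for periodicity.
#' @param cl_min,cl_max Physiologic atrial cycle-length window (ms).
#' @param noise_threshold Candidate amplitude threshold (mV).
#' @param slew_threshold Candidate slew-rate threshold (mV/ms).
#' @param rs_ratio_threshold R/S ratio below which a complex is QS.
#' @param qs_fraction_threshold Fraction of QS complexes required for FaST.
#' @param chain_tolerance_fraction Allowed deviation of a chain interval from
#'   the periodicity cycle length, as a fraction of it.
#' @param min_refractory Minimum spacing between candidates (ms).
#' @param morphology_window Window around the transposed onset in which R and
#'   S amplitudes are measured (ms, relative).
#' @param baseline_window Length of the pre-window segment whose median is
#'   the morphology baseline (ms).
#' @param sustained_coverage_fraction Fraction of expected beats the chain
#'   must cover for the periodicity to count as sustained.
#' @param subharmonic_ratio When a candidate spectral peak at frequency f has
#'   a subharmonic at f/2 or f/3 holding at least this fraction of the peak
#'   power, the subharmonic is taken as the true activation rate (standard
#'   harmonic guard in dominant-frequency analysis of rectified
#'   electrograms, whose pulse-train spectra carry strong harmonics).
#' @param morphology_smooth_ms Width of the moving-average smoother applied
#'   to the unipolar trace before amplitude measurement (ms; 0 disables).
#' @return A list of class `fast_params`.
#' @export
fast_params <- function(band1 = c(40, 250),
                        band2 = c(0.5, 20),
                        power_fraction_threshold = 0.10,
                        cl_min = 100,
                        cl_max = 250,
                        noise_threshold = 0.05,
                        slew_threshold = 0.014,
                        rs_ratio_threshold = 0.1,
                        qs_fraction_threshold = 0.9,
                        chain_tolerance_fraction = 0.25,
                        min_refractory = 50,
                        morphology_window = c(-20, 80),
                        baseline_window = 10,
                        sustained_coverage_fraction = 0.9,
                        subharmonic_ratio = 0.5,
                        morphology_smooth_ms = 7) {
  stopifnot(cl_min < cl_max, cl_min > 0,
            qs_fraction_threshold > 0, qs_fraction_threshold < 1,
            noise_threshold > 0, slew_threshold > 0,
            band1[1] < band1[2], band2[1] < band2[2],
            morphology_window[1] < morphology_window[2])
  structure(as.list(environment()), class = "fast_params")
}

# Zero-phase Butterworth band-pass as a high-pass/low-pass cascade, each
# 4th order, applied forward-backward with signal::filtfilt. The cascade is
# numerically robust for very low normalized corner frequencies (0.5 Hz at
# 1 kHz), where a direct high-order band-pass design is ill-conditioned.
bandpass_zp <- function(x, band, fs) {
  ny <- fs / 2
  if (band[2] >= ny) {
    abort(sprintf("Sampling rate %g Hz too low for band upper edge %g Hz.",
                  fs, band[2]))
  }
  hp <- signal::butter(4, band[1] / ny, type = "high")
  lp <- signal::butter(4, band[2] / ny, type = "low")
  y <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, y)
}

#' Bipolar envelope for spectral periodicity analysis
#'
#' Band-pass filters the bipolar electrogram (40-250 Hz), rectifies, and
#' band-pass filters again (0.5-20 Hz), all zero-phase, producing the
#' envelope whose spectrum is searched for periodicity.
#'
#' @param bipolar Bipolar trace (mV).
#' @param sampling_rate Samples per second.
#' @param params A [fast_params()].
#' @return Numeric envelope, same length as the input.
#' @export
preprocess_bipolar <- function(bipolar, sampling_rate,
                               params = fast_params()) {
  if (length(bipolar) < 2 * sampling_rate) {
    abort("Need at least 2 s of signal.")
  }
  if (sampling_rate <= 2 * params$band1[2]) {
    abort(sprintf(
      "Sampling rate %g Hz too low for the %g-%g Hz band.",
      sampling_rate, params$band1[1], params$band1[2]))
  }
  if (all(bipolar == 0)) return(bipolar)
  y <- bandpass_zp(bipolar, params$band1, sampling_rate)
  bandpass_zp(abs(y), params$band2, sampling_rate)
}

#' Spectral periodicity of the bipolar envelope
#'
#' Finds the largest spectral peak whose cycle length lies in the
#' physiologic window (100-250 ms, i.e. 4-10 Hz), then applies a harmonic
#' guard: if the peak's subharmonic at f/2 or f/3 carries a comparable
#' share of power, the activation rate is taken at the subharmonic, since
#' the rectified envelope of a pulse train puts strong lines at every
#' multiple of the true rate. Periodicity is declared when the resulting
#' peak (plus one adjacent bin on each side) holds at least 10% of the
#' total envelope power over 0.5-20 Hz and its cycle length lies in the
#' window; a fundamental below the window (e.g. a 2 Hz train whose 4 Hz
#' harmonic falls inside it) is thereby rejected.
#'
#' @param envelope Output of [preprocess_bipolar()].
#' @param sampling_rate Samples per second.
#' @param params A [fast_params()].
#' @return A one-row tibble (`periodicity_result`): `is_periodic`,
#'   `peak_frequency` (Hz), `periodicity_cl` (ms), `peak_power_fraction`.
#' @export
spectral_periodicity <- function(envelope, sampling_rate,
                                 params = fast_params()) {
  ps <- power_spectrum(envelope - mean(envelope), sampling_rate)
  in_band <- ps$freq >= params$band2[1] & ps$freq <= params$band2[2]
  total <- sum(ps$power[in_band])

  f_lo <- 1000 / params$cl_max
  f_hi <- 1000 / params$cl_min
  in_win <- which(ps$freq >= f_lo & ps$freq <= f_hi)

  if (total <= 0 || length(in_win) == 0) {
    return(tibble::tibble(is_periodic = FALSE, peak_frequency = NA_real_,
                          periodicity_cl = NA_real_,
                          peak_power_fraction = 0))
  }

  nb_power <- function(i) {
    sum(ps$power[intersect((i - 1L):(i + 1L), seq_along(ps$power))])
  }
  peak <- in_win[which.max(ps$power[in_win])]
  # harmonic guard: a strong line at f/2 or f/3 marks the true rate
  for (k in c(2L, 3L)) {
    f_sub <- ps$freq[peak] / k
    if (f_sub < ps$freq[2]) next
    i_sub <- which.min(abs(ps$freq - f_sub))
    if (nb_power(i_sub) >= params$subharmonic_ratio * nb_power(peak)) {
      peak <- i_sub
      break
    }
  }
  frac <- nb_power(peak) / total
  f_peak <- ps$freq[peak]
  cl <- 1000 / f_peak
  is_periodic <- frac >= params$power_fraction_threshold &&
    cl >= params$cl_min && cl <= params$cl_max

  tibble::tibble(is_periodic = is_periodic,
                 peak_frequency = f_peak,
                 periodicity_cl = cl,
                 peak_power_fraction = frac)
}

#' Candidate local activations on the (filtered) bipolar trace
#'
#' Candidates are local maxima of absolute amplitude, separated by at least
#' the refractory period, whose amplitude exceeds the noise threshold
#' (0.05 mV) and whose maximum absolute slew rate within +/- 10 ms exceeds
#' 0.014 mV/ms. The input is assumed already band-pass filtered (40-250 Hz);
#' [classify_fast()] applies the filter before calling this.
#'
#' @param bipolar Band1-filtered bipolar trace (mV).
#' @param sampling_rate Samples per second.
#' @param params A [fast_params()].
#' @return Strictly increasing numeric vector of candidate times (ms).
#' @export
detect_candidates <- function(bipolar, sampling_rate,
                              params = fast_params()) {
  n <- length(bipolar)
  if (n < 3) return(numeric(0))
  a <- abs(bipolar)
  is_peak <- c(FALSE, a[2:(n - 1)] >= a[1:(n - 2)] &
                 a[2:(n - 1)] >= a[3:n], FALSE) &
    a > params$noise_threshold
  idx <- which(is_peak)
  if (length(idx) == 0) return(numeric(0))

  # slew rate in mV/ms within +/- 10 ms of each peak
  slew <- abs(diff(bipolar)) * sampling_rate / 1000
  half <- round(10 * sampling_rate / 1000)
  keep <- vapply(idx, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n - 1L, i + half - 1L)
    max(slew[lo:hi]) > params$slew_threshold
  }, TRUE)
  idx <- idx[keep]
  if (length(idx) == 0) return(numeric(0))

  # enforce refractory period, keeping larger peaks first
  refr <- params$min_refractory * sampling_rate / 1000
  ord <- idx[order(a[idx], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= refr)) {
      accepted <- c(accepted, i)
    }
  }
  index_to_ms(sort(accepted), sampling_rate)
}

#' Longest periodic chain of candidate activations
#'
#' Dynamic-programming reconstruction of the graph search: among all
#' increasing subsequences of the candidates whose consecutive intervals lie
#' strictly within `periodicity_cl` +/- tolerance, return the longest; ties
#' are broken
#' by minimal total cost (sum of absolute deviations of the intervals from
#' the cycle length), then by the lexicographically earliest time sequence.
#'
#' @param candidates Sorted candidate times (ms).
#' @param periodicity_cl Extracted cycle length (ms).
#' @param params A [fast_params()].
#' @return A list of class `activation_train`: `candidates`, `chain`,
#'   `chain_length`, `total_cost`.
#' @export
select_periodic_train <- function(candidates, periodicity_cl,
                                  params = fast_params()) {
  n <- length(candidates)
  out <- function(chain, cost) {
    structure(list(candidates = candidates, chain = chain,
                   chain_length = length(chain), total_cost = cost),
              class = "activation_train")
  }
  if (n == 0) return(out(numeric(0), 0))
  tol <- params$chain_tolerance_fraction * periodicity_cl

  len <- rep(1L, n)
  cost <- rep(0, n)
  seqs <- lapply(seq_len(n), function(i) candidates[i])

  lex_less <- function(a, b) {
    k <- min(length(a), length(b))
    for (t in seq_len(k)) {
      if (a[t] < b[t]) return(TRUE)
      if (a[t] > b[t]) return(FALSE)
    }
    length(a) < length(b)
  }

  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      d <- candidates[j] - candidates[i]
      if (abs(d - periodicity_cl) < tol) {
        cand_len <- len[i] + 1L
        cand_cost <- cost[i] + abs(d - periodicity_cl)
        better <- cand_len > len[j] ||
          (cand_len == len[j] && (cand_cost < cost[j] - 1e-12 ||
            (abs(cand_cost - cost[j]) <= 1e-12 &&
               lex_less(c(seqs[[i]], candidates[j]), seqs[[j]]))))
        if (better) {
          len[j] <- cand_len
          cost[j] <- cand_cost
          seqs[[j]] <- c(seqs[[i]], candidates[j])
        }
      }
    }
  }

  best <- 1L
  for (j in seq_len(n)) {
    if (len[j] > len[best] ||
        (len[j] == len[best] && (cost[j] < cost[best] - 1e-12 ||
          (abs(cost[j] - cost[best]) <= 1e-12 &&
             lex_less(seqs[[j]], seqs[[best]]))))) {
      best <- j
    }
  }
  out(seqs[[best]], cost[best])
}

#' Unipolar morphology at annotated onsets
#'
#' For each onset transposed from the bipolar chain, measures the R (maximum
#' positive) and S (maximum negative) deviations from a local baseline within
#' the morphology window, and classifies the complex as QS when the R/S
#' ratio is below the threshold. The baseline is the median of the 10 ms
#' preceding the window; the trace is lightly smoothed before measurement so
#' that broadband noise does not masquerade as an R wave. Complexes whose S
#' amplitude is below the noise threshold are flagged indeterminate.
#'
#' @param unipolar Unipolar trace (mV).
#' @param sampling_rate Samples per second.
#' @param onsets Onset times (ms).
#' @param params A [fast_params()].
#' @return Tibble with one row per onset: `onset`, `r_amplitude`,
#'   `s_amplitude`, `rs_ratio`, `is_qs`, `indeterminate`.
#' @export
classify_morphology <- function(unipolar, sampling_rate, onsets,
                                params = fast_params()) {
  empty <- tibble::tibble(onset = numeric(0), r_amplitude = numeric(0),
                          s_amplitude = numeric(0), rs_ratio = numeric(0),
                          is_qs = logical(0), indeterminate = logical(0))
  if (length(onsets) == 0) return(empty)
  n <- length(unipolar)

  x <- unipolar
  kw <- round(params$morphology_smooth_ms * sampling_rate / 1000)
  if (kw >= 3) {
    if (kw %% 2 == 0) kw <- kw + 1L
    x <- stats::filter(unipolar, rep(1 / kw, kw), sides = 2)
    x <- as.numeric(x)
    x[is.na(x)] <- unipolar[is.na(x)]
  }

  rows <- lapply(onsets, function(on) {
    w1 <- ms_to_index(on + params$morphology_window[1], sampling_rate)
    w2 <- ms_to_index(on + params$morphology_window[2], sampling_rate)
    b1 <- ms_to_index(on + params$morphology_window[1] -
                        params$baseline_window, sampling_rate)
    w1c <- max(1L, w1); w2c <- min(n, w2)
    b1c <- max(1L, b1); b2c <- max(1L, min(n, w1 - 1L))
    base <- if (b2c >= b1c) median(x[b1c:b2c]) else 0
    seg <- x[w1c:w2c] - base
    r <- max(0, max(seg))
    s <- max(0, -min(seg))
    ratio <- if (s > 0) r / s else Inf
    tibble::tibble(
      onset = on, r_amplitude = r, s_amplitude = s, rs_ratio = ratio,
      is_qs = s > 0 && ratio < params$rs_ratio_threshold,
      indeterminate = s <= params$noise_threshold)
  })
  dplyr::bind_rows(rows)
}

#' Hierarchical FaST classification of one record
#'
#' Composes the four stages of the rule-based algorithm: bipolar spectral
#' periodicity, candidate activation detection, periodic-chain selection by
#' graph search, and unipolar QS morphology classification at the transposed
#' onsets. A record is FaST when it is periodic within the 100-250 ms window,
#' the chain is sustained (covers at least 90% of the expected beats), and
#' more than 90% of determinate complexes are QS. Non-periodic records
#' short-circuit to a negative call.
#'
#' @param record An `egm_record`.
#' @param params A [fast_params()].
#' @return A list of class `fast_decision`: `is_fast`, `periodicity` (tibble),
#'   `qs_fraction`, `sustained`, `train` (`activation_train`), `calls`
#'   (morphology tibble).
#' @export
classify_fast <- function(record, params = fast_params()) {
  fs <- record$sampling_rate
  if (length(record$unipolar) < 2 * fs) {
    abort("Record shorter than 2 s cannot be classified.")
  }
  dur_ms <- record$duration * 1000

  env <- preprocess_bipolar(record$bipolar, fs, params)
  per <- spectral_periodicity(env, fs, params)

  if (!per$is_periodic) {
    return(structure(
      list(is_fast = FALSE, periodicity = per, qs_fraction = NA_real_,
           sustained = FALSE,
           train = select_periodic_train(numeric(0), params$cl_min, params),
           calls = classify_morphology(record$unipolar, fs, numeric(0),
                                       params)),
      class = "fast_decision"))
  }

  filt <- bandpass_zp(record$bipolar, params$band1, fs)
  cands <- detect_candidates(filt, fs, params)
  train <- select_periodic_train(cands, per$periodicity_cl, params)

  expected_beats <- dur_ms / per$periodicity_cl
  sustained <- train$chain_length >=
    params$sustained_coverage_fraction * expected_beats

  calls <- classify_morphology(record$unipolar, fs, train$chain, params)
  det <- calls[!calls$indeterminate, , drop = FALSE]
  qs_fraction <- if (nrow(det)) mean(det$is_qs) else 0

  structure(
    list(is_fast = per$is_periodic && sustained &&
           qs_fraction > params$qs_fraction_threshold,
         periodicity = per, qs_fraction = qs_fraction,
         sustained = sustained, train = train, calls = calls),
    class = "fast_decision")
}

#' @exportS3Method base::print
print.fast_decision <- function(x, ...) {
  cat(sprintf(
    "<fast_decision: %s | periodic=%s CL=%.1f ms | chain=%d | QS=%.2f>\n",
    if (x$is_fast) "FaST" else "non-FaST",
    x$periodicity$is_periodic,
    x$periodicity$periodicity_cl %||% NA,
    x$train$chain_length,
    if (is.na(x$qs_fraction)) NA else x$qs_fraction))
  invisible(x)
}

#' Run the FaST detector over a cohort
#'
#' @param records List of `egm_record`.
#' @param params A [fast_params()].
#' @return Tibble with one row per record: `record_id`, `is_periodic`,
#'   `periodicity_cl_ms`, `peak_power_fraction`, `chain_length`,
#'   `qs_fraction`, `is_fast`.
#' @export
detect_cohort <- function(records, params = fast_params()) {
  rows <- lapply(records, function(r) {
    d <- classify_fast(r, params)
    tibble::tibble(
      record_id = r$record_id,
      is_periodic = d$periodicity$is_periodic,
      periodicity_cl_ms = d$periodicity$periodicity_cl,
      peak_power_fraction = d$periodicity$peak_power_fraction,
      chain_length = d$train$chain_length,
      qs_fraction = d$qs_fraction,
      is_fast = d$is_fast)
  })
  dplyr::bind_rows(rows)
}
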