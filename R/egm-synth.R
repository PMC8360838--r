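#' Electrogram morphology classes emulated by the generator
#'
#' Names the synthetic record classes and which of them carry a true
#' focal-source (FaST) label. The three FaST classes are sustained periodic
#' unipolar QS trains: typical amplitude (`FAST_QS`), low amplitude near the
#' PV ostium (`LOW_AMP_QS`) and broad, slurred complexes (`SLURRED_QS`).
#' Non-FaST classes cover periodic RS trains, rS trains with small r waves,
#' mid-recording morphology switches, non-sustained QS trains, fractionated
#' activity and aperiodic activity.
#'
#' @return Character vector of class names with a logical attribute
#'   `is_fast` marking the FaST classes.
#' @export
egm_classes <- function() {
  cls <- c("FAST_QS", "LOW_AMP_QS", "SLURRED_QS", "PERIODIC_RS",
           "SMALL_R_RS", "SWITCHING", "NONSUSTAINED_QS", "FRACTIONATED",
           "APERIODIC")
  attr(cls, "is_fast") <- cls %in% c("FAST_QS", "LOW_AMP_QS", "SLURRED_QS")
  cls
}

#' Synthetic electrogram generator configuration
#'
#' Defaults describe 5-s paired unipolar/bipolar recordings sampled at
#' 1,000 Hz during atrial fibrillation. Atrial cycle lengths span the
#' physiologic refractory window (100-250 ms). Amplitudes are in mV.
#'
#' @param sampling_rate Samples per second.
#' @param duration Record length in seconds.
#' @param cl_range Atrial cycle-length window in ms.
#' @param qs_amplitude_range S-wave amplitude range (mV) for typical QS and
#'   RS complexes.
#' @param low_amp_range S-wave amplitude range for the low-amplitude QS class.
#' @param rs_ratio_range R/S amplitude ratio range for the `PERIODIC_RS` class.
#' @param small_r_ratio_range R/S ratio range for the borderline `SMALL_R_RS`
#'   class (above the 0.1 QS cut-off but visually QS-like).
#' @param qs_width_range,slurred_width_range Complex widths in ms.
#' @param jitter_sd,jitter_max Gaussian activation-time jitter sd and
#'   truncation bound, ms.
#' @param noise_sd Additive Gaussian noise sd on the unipolar trace, mV.
#' @param bipolar_noise_sd Noise sd on the bipolar trace, mV.
#' @param baseline_wander_amplitude,baseline_wander_freq Sinusoidal baseline
#'   wander on the unipolar trace (mV, Hz).
#' @param bipolar_amplitude_range Bipolar deflection amplitude range, mV.
#' @param ventricular_cl_range Far-field ventricular cycle-length range, ms.
#' @param ventricular_amplitude Far-field ventricular amplitude, mV.
#' @param ventricular_prob Probability a record carries a ventricular
#'   far-field train.
#' @param prevalence Default fraction of FaST-labelled records in a cohort.
#' @param records_per_patient Records assigned to each synthetic patient.
#' @param patient_scale_range Per-patient multiplicative amplitude scale is
#'   drawn uniformly from this range.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 1000,
                         duration = 5,
                         cl_range = c(100, 250),
                         qs_amplitude_range = c(0.5, 2.0),
                         low_amp_range = c(0.2, 0.35),
                         rs_ratio_range = c(0.3, 0.8),
                         small_r_ratio_range = c(0.15, 0.3),
                         qs_width_range = c(30, 50),
                         slurred_width_range = c(60, 90),
                         jitter_sd = 3,
                         jitter_max = 10,
                         noise_sd = 0.015,
                         bipolar_noise_sd = 0.008,
                         baseline_wander_amplitude = 0.05,
                         baseline_wander_freq = 0.25,
                         bipolar_amplitude_range = c(0.3, 1.5),
                         ventricular_cl_range = c(600, 1000),
                         ventricular_amplitude = 0.2,
                         ventricular_prob = 0.3,
                         prevalence = 0.092,
                         records_per_patient = 50,
                         patient_scale_range = c(0.8, 1.3)) {
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  stopifnot(length(cl_range) == 2, cl_range[1] < cl_range[2],
            cl_range[2] < duration * 1000,
            prevalence >= 0, prevalence <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Waveform template for a single electrogram complex
#'
#' Builds the deterministic morphology templates the generator places at
#' activation times. A QS complex is an inverted raised-cosine dip (no
#' positive excursion); RS/rS complexes prepend a positive half-sine lobe
#' whose peak is `r_to_s_ratio` times the S-wave depth; a fractionated
#' complex is three jittered biphasic sub-deflections; a ventricular
#' far-field complex is a broad (>= 80 ms) low-frequency biphasic wave.
#'
#' @param kind One of `"QS"`, `"RS"`, `"rS"`, `"fractionated"`,
#'   `"ventricular"`.
#' @param width Complex width in ms.
#' @param amplitude S-wave (negative) amplitude in mV.
#' @param r_to_s_ratio R/S amplitude ratio; forced to 0 for `kind = "QS"`.
#' @param sampling_rate Samples per second.
#' @return Numeric vector of mV values.
#' @export
egm_template <- function(kind, width, amplitude, r_to_s_ratio = 0,
                         sampling_rate = 1000) {
  kind <- match.arg(kind, c("QS", "RS", "rS", "fractionated", "ventricular"))
  assert_scalar_num(width, "width", positive = TRUE)
  assert_scalar_num(amplitude, "amplitude", positive = TRUE)
  if (r_to_s_ratio < 0) abort("`r_to_s_ratio` must be >= 0.")
  if (kind == "QS") r_to_s_ratio <- 0
  if (kind == "ventricular") width <- max(width, 80)
  fs <- sampling_rate

  odd_n <- function(ms) {
    n <- max(round(ms * fs / 1000), 5L)
    if (n %% 2 == 0) n + 1L else n
  }
  dip <- function(n, a) -a * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))

  switch(kind,
    QS = dip(odd_n(width), amplitude),
    RS = ,
    rS = {
      nr <- odd_n(width * 0.35)
      ns <- odd_n(width * 0.65)
      r <- r_to_s_ratio * amplitude * sin(pi * seq(0, 1, length.out = nr))
      c(r, dip(ns, amplitude))
    },
    fractionated = {
      n <- odd_n(width)
      t <- seq(0, 1, length.out = n)
      sub <- function(center, scale) {
        w <- 0.28
        u <- (t - center) / w
        env <- ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
        scale * amplitude * sin(2 * pi * 2 * u) * env
      }
      sub(0.2, 0.7) + sub(0.5, 1.0) + sub(0.8, 0.6)
    },
    ventricular = {
      n <- odd_n(width)
      t <- seq(0, 1, length.out = n)
      amplitude * sin(2 * pi * t) * sin(pi * t)
    }
  )
}

# Sharp biphasic bipolar activation kernel (derivative of a Gaussian),
# normalized to unit peak amplitude. sigma_ms controls sharpness.
bipolar_kernel <- function(sampling_rate = 1000, sigma_ms = 2,
                           half_width_ms = 8) {
  t <- seq(-half_width_ms, half_width_ms, by = 1000 / sampling_rate)
  k <- -t * exp(-t^2 / (2 * sigma_ms^2))
  k / max(abs(k))
}

# Add `template` into `signal` starting at sample index `start` (may be
# partially off-record; clipped).
add_at <- function(signal, template, start) {
  n <- length(signal)
  idx <- start:(start + length(template) - 1L)
  keep <- idx >= 1L & idx <= n
  signal[idx[keep]] <- signal[idx[keep]] + template[keep]
  signal
}

truncated_jitter <- function(n, sd, bound) {
  j <- rnorm(n, 0, sd)
  pmin(pmax(j, -bound), bound)
}

#' Default class mixture at a given FaST prevalence
#'
#' Splits the requested prevalence across the three FaST morphology classes
#' and the remainder across the six non-FaST classes, in fixed proportions.
#'
#' @param prevalence Fraction of FaST-labelled records.
#' @return Named numeric vector of class probabilities summing to 1.
#' @export
default_class_mix <- function(prevalence = 0.092) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  fast <- c(FAST_QS = 0.65, LOW_AMP_QS = 0.22, SLURRED_QS = 0.13)
  non <- c(PERIODIC_RS = 0.27, SMALL_R_RS = 0.11, SWITCHING = 0.13,
           NONSUSTAINED_QS = 0.13, FRACTIONATED = 0.17, APERIODIC = 0.19)
  c(fast * prevalence, non * (1 - prevalence))
}

#' Generate one labelled synthetic electrogram record
#'
#' Produces a paired unipolar/bipolar 5-s record of the requested morphology
#' class together with full ground truth (activation times, per-complex
#' morphology, cycle length, FaST label). The unipolar trace is a sum of
#' morphology templates at the activation times plus optional ventricular
#' far-field complexes, baseline wander and Gaussian noise; the bipolar trace
#' carries sharp biphasic deflections at the same times so that candidate
#' detection thresholds are met independently of unipolar morphology.
#' Identical `(class_name, config, seed)` give bit-identical output.
#'
#' @param class_name One of [egm_classes()].
#' @param config A [synth_config()].
#' @param seed Integer seed for this record.
#' @param cl Optional cycle length in ms (drawn from `config$cl_range` when
#'   `NULL`); must lie within the configured range.
#' @param switch_time For the `SWITCHING` class, the time (s) at which
#'   morphology switches from RS to QS. Default 1.4 s.
#' @param record_id,patient_id Identifier strings.
#' @param amplitude_scale Multiplies all deflection amplitudes (used for
#'   patient-specific scaling).
#' @param has_ventricular Force the ventricular far-field train on/off;
#'   `NULL` draws it with probability `config$ventricular_prob`.
#' @return A list with elements `record` (class `egm_record`: `record_id`,
#'   `patient_id`, `sampling_rate`, `duration`, `unipolar`, `bipolar`) and
#'   `truth` (class `egm_truth`: `class_name`, `is_fast`, `cycle_length`,
#'   `activation_times` (bipolar activations, ms), `complex_onsets` (start
#'   of each unipolar complex, 10 ms before the activation),
#'   `per_complex_morphology`, `has_ventricular_farfield`).
#' @export
synth_record <- function(class_name, config = synth_config(), seed = 1L,
                         cl = NULL, switch_time = 1.4,
                         record_id = sprintf("R%06d", seed),
                         patient_id = "P001",
                         amplitude_scale = 1,
                         has_ventricular = NULL) {
  classes <- egm_classes()
  if (!class_name %in% classes) {
    abort(sprintf("Unknown morphology class '%s'.", class_name))
  }
  if (!is.null(cl) &&
      (cl < config$cl_range[1] || cl > config$cl_range[2])) {
    abort(sprintf("Cycle length %g ms outside configured range [%g, %g].",
                  cl, config$cl_range[1], config$cl_range[2]))
  }

  with_seed(seed, {
    fs <- config$sampling_rate
    dur_ms <- config$duration * 1000
    n <- round(fs * config$duration)
    uni <- numeric(n)
    bip <- numeric(n)

    aperiodic <- class_name == "APERIODIC"
    if (!aperiodic && is.null(cl)) {
      cl <- runif(1, config$cl_range[1], config$cl_range[2])
    }

    # Activation times
    if (aperiodic) {
      times <- cumsum(c(runif(1, 20, 200),
                        runif(ceiling(dur_ms / 80), 80, 450)))
      times <- times[times < dur_ms - 20]
      cl_out <- NA_real_
    } else {
      t0 <- runif(1, cl / 4, 3 * cl / 4)
      k <- 0:floor((dur_ms - t0) / cl)
      times <- t0 + k * cl
      times <- times + truncated_jitter(length(times), config$jitter_sd,
                                        config$jitter_max)
      times <- times[times >= 0 & times < dur_ms - 15]
      cl_out <- cl
    }
    coverage <- if (aperiodic) NA_real_ else 1
    if (class_name == "NONSUSTAINED_QS") {
      coverage <- runif(1, 0.4, 0.7)
      times <- times[times < coverage * dur_ms]
    }

    # Per-complex morphology and template parameters
    amp_rng <- switch(class_name,
                      LOW_AMP_QS = config$low_amp_range,
                      config$qs_amplitude_range)
    width_rng <- switch(class_name,
                        SLURRED_QS = config$slurred_width_range,
                        config$qs_width_range)
    ratio_rng <- switch(class_name,
                        PERIODIC_RS = config$rs_ratio_range,
                        SMALL_R_RS = config$small_r_ratio_range,
                        SWITCHING = config$rs_ratio_range,
                        c(0, 0))
    base_amp <- runif(1, amp_rng[1], amp_rng[2]) * amplitude_scale
    base_width <- runif(1, width_rng[1], width_rng[2])
    base_ratio <- runif(1, max(ratio_rng[1], 0), max(ratio_rng[2], 0))

    morph <- switch(class_name,
      FAST_QS = , LOW_AMP_QS = , SLURRED_QS = , NONSUSTAINED_QS =
        rep("QS", length(times)),
      PERIODIC_RS = , SMALL_R_RS = , FRACTIONATED =
        rep("NONQS", length(times)),
      SWITCHING = ifelse(times < switch_time * 1000, "NONQS", "QS"),
      APERIODIC = sample(c("QS", "NONQS"), length(times), replace = TRUE)
    )

    tmpl_kind <- switch(class_name,
      FRACTIONATED = "fractionated",
      PERIODIC_RS = "RS",
      SMALL_R_RS = "rS",
      "QS")

    for (i in seq_along(times)) {
      kind_i <- if (class_name == "SWITCHING") {
        if (morph[i] == "QS") "QS" else "RS"
      } else if (class_name == "APERIODIC") {
        if (morph[i] == "QS") "QS" else "RS"
      } else tmpl_kind
      ratio_i <- if (kind_i %in% c("RS", "rS")) max(base_ratio, 0.15) else 0
      amp_i <- base_amp * runif(1, 0.9, 1.1)
      tmpl <- egm_template(kind_i, base_width, amp_i, ratio_i, fs)
      # unipolar complex onset sits 10 ms before the bipolar activation
      start <- ms_to_index(times[i] - 10, fs)
      uni <- add_at(uni, tmpl, start)
      bamp <- runif(1, config$bipolar_amplitude_range[1],
                    config$bipolar_amplitude_range[2]) * amplitude_scale
      bk <- bamp * bipolar_kernel(fs)
      bip <- add_at(bip, bk, ms_to_index(times[i], fs) -
                      (length(bk) - 1L) %/% 2L)
    }

    # Ventricular far-field train on the unipolar trace (broad, low slew)
    if (is.null(has_ventricular)) {
      has_ventricular <- runif(1) < config$ventricular_prob
    }
    vt <- numeric(0)
    if (has_ventricular) {
      vcl <- runif(1, config$ventricular_cl_range[1],
                   config$ventricular_cl_range[2])
      vt <- seq(runif(1, 0, vcl), dur_ms - 1, by = vcl)
      vtmpl <- egm_template("ventricular", 120,
                            config$ventricular_amplitude * amplitude_scale,
                            sampling_rate = fs)
      for (tv in vt) uni <- add_at(uni, vtmpl, ms_to_index(tv, fs))
    }

    tsec <- (seq_len(n) - 1) / fs
    uni <- uni +
      config$baseline_wander_amplitude *
        sin(2 * pi * config$baseline_wander_freq * tsec + runif(1, 0, 2 * pi)) +
      rnorm(n, 0, config$noise_sd)
    bip <- bip + rnorm(n, 0, config$bipolar_noise_sd)

    qs_frac <- if (length(morph)) mean(morph == "QS") else 0
    sustained <- !is.na(coverage) && coverage >= 0.9
    is_fast <- !is.na(cl_out) && sustained && qs_frac > 0.9

    record <- structure(
      list(record_id = record_id, patient_id = patient_id,
           sampling_rate = fs, duration = config$duration,
           unipolar = uni, bipolar = bip),
      class = "egm_record")
    truth <- structure(
      list(class_name = class_name, is_fast = is_fast,
           cycle_length = cl_out, activation_times = times,
           complex_onsets = times - 10,
           per_complex_morphology = morph,
           has_ventricular_farfield = has_ventricular,
           ventricular_times = vt),
      class = "egm_truth")
    list(record = record, truth = truth)
  })
}

#' Generate a ventricular far-field-only record
#'
#' A control record containing no atrial activity at all: the unipolar
#' trace carries only the broad ventricular far-field train, baseline
#' wander and noise, and the bipolar trace only noise. Used to verify that
#' classifier importance at far-field complexes is low compared with
#' importance at atrial QS complexes on regular records.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param record_id,patient_id Identifier strings.
#' @return A list with `record` (`egm_record`) and `truth` (`egm_truth`
#'   with empty activations and `ventricular_times` set).
#' @export
synth_farfield_record <- function(config = synth_config(), seed = 1L,
                                  record_id = sprintf("V%06d", seed),
                                  patient_id = "P000") {
  with_seed(seed, {
    fs <- config$sampling_rate
    dur_ms <- config$duration * 1000
    n <- round(fs * config$duration)
    uni <- numeric(n)
    vcl <- runif(1, config$ventricular_cl_range[1],
                 config$ventricular_cl_range[2])
    vt <- seq(runif(1, 0, vcl), dur_ms - 1, by = vcl)
    vtmpl <- egm_template("ventricular", 120, config$ventricular_amplitude,
                          sampling_rate = fs)
    for (tv in vt) uni <- add_at(uni, vtmpl, ms_to_index(tv, fs))
    tsec <- (seq_len(n) - 1) / fs
    uni <- uni + config$baseline_wander_amplitude *
      sin(2 * pi * config$baseline_wander_freq * tsec +
            runif(1, 0, 2 * pi)) +
      rnorm(n, 0, config$noise_sd)
    bip <- rnorm(n, 0, config$bipolar_noise_sd)
    record <- structure(
      list(record_id = record_id, patient_id = patient_id,
           sampling_rate = fs, duration = config$duration,
           unipolar = uni, bipolar = bip),
      class = "egm_record")
    truth <- structure(
      list(class_name = "APERIODIC", is_fast = FALSE,
           cycle_length = NA_real_, activation_times = numeric(0),
           complex_onsets = numeric(0),
           per_complex_morphology = character(0),
           has_ventricular_farfield = TRUE, ventricular_times = vt),
      class = "egm_truth")
    list(record = record, truth = truth)
  })
}

#' @exportS3Method base::print
print.egm_record <- function(x, ...) {
  cat(sprintf("<egm_record %s patient %s: %.1f s @ %g Hz>\n",
              x$record_id, x$patient_id, x$duration, x$sampling_rate))
  invisible(x)
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_records` records from a class mixture, assigns them to synthetic
#' patients in blocks (with a per-patient amplitude scale) and returns the
#' records together with a manifest tibble suitable for patient-level splits.
#'
#' @param n_records Number of records (>= 1).
#' @param config A [synth_config()].
#' @param class_mix Named probability vector over [egm_classes()]; defaults
#'   to [default_class_mix()] at `prevalence`.
#' @param prevalence FaST prevalence used when `class_mix` is `NULL`.
#' @param seed Integer seed.
#' @return A list with `manifest` (tibble: `record_id`, `patient_id`,
#'   `class_name`, `label`), `records` (list of `egm_record`) and `truths`
#'   (list of `egm_truth`).
#' @export
synth_cohort <- function(n_records, config = synth_config(),
                         class_mix = NULL, prevalence = config$prevalence,
                         seed = 1L) {
  if (!is.numeric(n_records) || n_records < 1) {
    abort("`n_records` must be >= 1.")
  }
  if (is.null(class_mix)) class_mix <- default_class_mix(prevalence)
  if (length(class_mix) == 0) abort("`class_mix` must not be empty.")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% egm_classes())) {
    abort("`class_mix` must be named with known morphology classes.")
  }
  if (abs(sum(class_mix) - 1) > 1e-9) {
    abort("`class_mix` probabilities must sum to 1.")
  }

  with_seed(seed, {
    n_records <- as.integer(n_records)
    classes <- sample(names(class_mix), n_records, replace = TRUE,
                      prob = class_mix)
    rpp <- config$records_per_patient
    patient_idx <- (seq_len(n_records) - 1L) %/% rpp + 1L
    n_pat <- max(patient_idx)
    scales <- runif(n_pat, config$patient_scale_range[1],
                    config$patient_scale_range[2])
    rec_seeds <- sample.int(.Machine$integer.max - 1L, n_records)

    out <- vector("list", n_records)
    for (i in seq_len(n_records)) {
      out[[i]] <- synth_record(
        classes[i], config, seed = rec_seeds[i],
        record_id = sprintf("R%06d", i),
        patient_id = sprintf("P%04d", patient_idx[i]),
        amplitude_scale = scales[patient_idx[i]])
    }
    records <- lapply(out, `[[`, "record")
    truths <- lapply(out, `[[`, "truth")
    manifest <- tibble::tibble(
      record_id = vapply(records, `[[`, "", "record_id"),
      patient_id = vapply(records, `[[`, "", "patient_id"),
      class_name = classes,
      label = as.integer(vapply(truths, `[[`, TRUE, "is_fast"))
    )
    list(manifest = manifest, records = records, truths = truths)
  })
}
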