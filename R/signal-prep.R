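#' Fourier-domain resampling
#'
#' Resamples a signal by truncating (or zero-padding) its discrete Fourier
#' transform, preserving frequency content below the output Nyquist rate.
#' This is the classic FFT resampling used to take 5-s, 1 kHz electrograms
#' down to 200 Hz (5000 -> 1000 samples).
#'
#' @param signal Numeric vector.
#' @param rate_in,rate_out Input and output sampling rates (Hz).
#' @return Numeric vector of length `round(length(signal) * rate_out /
#'   rate_in)`.
#' @export
resample_fft <- function(signal, rate_in, rate_out) {
  if (rate_out <= 0) abort("`rate_out` must be positive.")
  if (rate_out > rate_in) abort("`rate_out` must not exceed `rate_in`.")
  n <- length(signal)
  m <- as.integer(round(n * rate_out / rate_in))
  fft_resample_len(signal, m)
}

# Fourier resampling to an arbitrary output length (used both for the
# 1000 -> 200 Hz downsampling and for stretching a cut signal back to its
# original length in the resampling augmentation).
fft_resample_len <- function(signal, m) {
  n <- length(signal)
  if (m == n) return(signal)
  if (m < 1) abort("Output would be empty.")

  X <- fft(signal)
  Y <- complex(m)
  k <- min(n, m)
  hp <- (k - 1L) %/% 2L  # strictly positive frequencies carried over intact
  Y[1L] <- X[1L]
  if (hp >= 1L) {
    Y[2L:(hp + 1L)] <- X[2L:(hp + 1L)]
    Y[(m - hp + 1L):m] <- X[(n - hp + 1L):n]
  }
  if (k %% 2L == 0L) {
    nyq <- k %/% 2L + 1L
    if (m < n) {
      # fold the input bins straddling the new Nyquist into one real bin
      Y[nyq] <- complex(real = Re(X[nyq]) + Re(X[n - k %/% 2L + 1L]))
    } else {
      # split the old (real) Nyquist bin across the conjugate pair
      Y[nyq] <- X[nyq] / 2
      Y[m - k %/% 2L + 1L] <- Conj(X[nyq]) / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Min-max feature scaling to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant signal maps to all 0.5 by
#' convention, so downstream layers still receive a well-defined input.
#'
#' @param signal Numeric vector with finite values.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_scale <- function(signal) {
  if (!all(is.finite(signal))) abort("`signal` must be finite.")
  rng <- range(signal)
  if (rng[1] == rng[2]) return(rep(0.5, length(signal)))
  (signal - rng[1]) / (rng[2] - rng[1])
}

#' Augmentation configuration
#'
#' Magnitudes apply to min-max-scaled signals: the baseline shift constant is
#' drawn from N(0, `baseline_shift_sd`); Gaussian noise is i.i.d.
#' N(0, `noise_sd`); cropping zeroes a contiguous segment whose length
#' fraction is drawn uniformly from `crop_fraction_range`; resampling deletes
#' a segment of fraction drawn from `resample_fraction_range` and
#' Fourier-interpolates the remainder back to the original length.
#'
#' @param probability Per-augmentation application probability in the
#'   training pipeline.
#' @param baseline_shift_sd,noise_sd Normal sds (unitless, on scaled traces).
#' @param crop_fraction_range,resample_fraction_range Ordered pairs in
#'   \[0, 1).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(probability = 0.5,
                           baseline_shift_sd = 0.1,
                           noise_sd = 0.05,
                           crop_fraction_range = c(0.05, 0.15),
                           resample_fraction_range = c(0.05, 0.15)) {
  stopifnot(probability >= 0, probability <= 1,
            crop_fraction_range[1] <= crop_fraction_range[2],
            resample_fraction_range[1] <= resample_fraction_range[2],
            crop_fraction_range[2] < 1, resample_fraction_range[2] < 1)
  structure(as.list(environment()), class = "augment_config")
}

#' Apply one stochastic augmentation
#'
#' The four augmentation modes used during training: `baseline_shift` adds a
#' single normal-distributed constant; `gaussian_noise` adds i.i.d. normal
#' noise; `crop` replaces one contiguous segment with zeros; `resample`
#' deletes a contiguous segment and stretches the shorter signal back to the
#' original length by Fourier interpolation. All modes preserve length and
#' are deterministic under a fixed seed.
#'
#' @param signal Numeric vector.
#' @param mode One of `"baseline_shift"`, `"gaussian_noise"`, `"crop"`,
#'   `"resample"`.
#' @param config An [augment_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Numeric vector, same length as `signal`.
#' @export
augment <- function(signal, mode, config = augment_config(), seed = NULL) {
  mode <- match.arg(mode,
                    c("baseline_shift", "gaussian_noise", "crop", "resample"))
  n <- length(signal)
  with_seed(seed, {
    switch(mode,
      baseline_shift = signal + rnorm(1, 0, config$baseline_shift_sd),
      gaussian_noise = signal + rnorm(n, 0, config$noise_sd),
      crop = {
        f <- runif(1, config$crop_fraction_range[1],
                   config$crop_fraction_range[2])
        if (f >= 1) abort("Crop fraction must be < 1.")
        len <- max(1L, as.integer(round(f * n)))
        start <- sample.int(n - len + 1L, 1L)
        signal[start:(start + len - 1L)] <- 0
        signal
      },
      resample = {
        f <- runif(1, config$resample_fraction_range[1],
                   config$resample_fraction_range[2])
        if (f >= 1) abort("Resample fraction must be < 1.")
        len <- max(1L, as.integer(round(f * n)))
        start <- sample.int(n - len + 1L, 1L)
        shorter <- signal[-(start:(start + len - 1L))]
        # stretch back to the original length in the Fourier domain
        fft_resample_len(shorter, n)
      }
    )
  })
}

#' Stochastic augmentation pipeline with final scaling
#'
#' Applies each of the four augmentation modes independently with probability
#' `config$probability` (in the fixed order baseline shift, Gaussian noise,
#' crop, resample), then min-max scales, so the output is always in \[0, 1\].
#' The input is expected at the classifier rate (200 Hz).
#'
#' @param signal Numeric vector at 200 Hz.
#' @param config An [augment_config()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A list of class `preproc_signal`: `values` (in \[0, 1\]),
#'   `sampling_rate`, `applied_augmentations`.
#' @export
augment_pipeline <- function(signal, config = augment_config(),
                             seed = NULL) {
  modes <- c("baseline_shift", "gaussian_noise", "crop", "resample")
  with_seed(seed, {
    fired <- runif(4) < config$probability
    x <- signal
    for (k in which(fired)) x <- augment(x, modes[k], config, seed = NULL)
    structure(list(values = minmax_scale(x), sampling_rate = 200,
                   applied_augmentations = modes[fired]),
              class = "preproc_signal")
  })
}

#' Preprocess a unipolar trace for classification
#'
#' FFT-downsamples the raw unipolar trace to 200 Hz and min-max scales it,
#' producing the length-1000 input representation of the classifier for a
#' 5-s record.
#'
#' @param unipolar Numeric vector (mV).
#' @param rate_in Input sampling rate (Hz).
#' @param rate_out Classifier sampling rate (Hz).
#' @return A `preproc_signal`.
#' @export
preprocess_signal <- function(unipolar, rate_in = 1000, rate_out = 200) {
  structure(list(values = minmax_scale(resample_fft(unipolar, rate_in,
                                                    rate_out)),
                 sampling_rate = rate_out,
                 applied_augmentations = character(0)),
            class = "preproc_signal")
}

#' Preprocess a cohort into a classifier input matrix
#'
#' @param records List of `egm_record`.
#' @param rate_out Classifier sampling rate (Hz).
#' @return Numeric matrix, one row per record.
#' @export
preprocess_cohort <- function(records, rate_out = 200) {
  rows <- lapply(records, function(r) {
    preprocess_signal(r$unipolar, r$sampling_rate, rate_out)$values
  })
  do.call(rbind, rows)
}
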