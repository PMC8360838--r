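#' Grad-CAM importance trace over the input timeline
#'
#' Computes a gradient-weighted class-activation trace from a residual block
#' of the classifier: per-channel weights are the time-averaged gradients of
#' the output logit with respect to that block's activation map, the trace
#' is the rectified weighted sum of the maps, linearly interpolated to the
#' input length and max-normalized. Peaks mark the parts of the trace the
#' classifier relied on -- at a focal-source site these coincide with the
#' periodic unipolar QS complexes. The guided variant multiplies the trace
#' elementwise by a guided-backpropagation saliency at the input resolution.
#'
#' @param model A trained `fast_cnn`.
#' @param signal A `preproc_signal`, or a numeric length-`input_length`
#'   vector in \[0, 1\].
#' @param layer_id Probed layer id. A bare block id such as
#'   `"stage3.block0"` (the default) probes that block's first
#'   convolutional layer (its post-normalization activation); suffixes
#'   `.conv2` and `.out` select the second convolution or the
#'   post-residual block output instead. The capture points localize
#'   differently: the first convolution peaks slightly before the complex
#'   onset, the block output at the recovery edge after it.
#' @param guided Multiply by guided-backprop saliency?
#' @return A list of class `importance_trace`: `values` (length ==
#'   classifier input length, in \[0, 1\]), `cam_max` (the pre-normalization
#'   peak, so absolute importance `values * cam_max` can be compared across
#'   records), `layer_id`, `sampling_rate`.
#' @export
gradcam_trace <- function(model, signal, layer_id = "stage3.block0",
                          guided = FALSE) {
  x <- if (inherits(signal, "preproc_signal")) signal$values else signal
  X <- matrix(x, nrow = 1)
  fwd <- network_forward(model, X, training = FALSE, capture = layer_id)
  bwd <- network_backward(model, fwd, matrix(1, 1, 1), capture = layer_id,
                          guided = guided)
  A <- fwd$captured        # [1, Lc, C]
  dA <- bwd$captured_grad  # [1, Lc, C]
  Lc <- dim(A)[2]
  Amat <- matrix(A, Lc, dim(A)[3])
  Gmat <- matrix(dA, Lc, dim(dA)[3])
  alpha <- colMeans(Gmat)
  cam <- pmax(Amat %*% alpha, 0)

  n <- model$config$input_length
  vals <- if (Lc == 1) rep(cam[1], n) else {
    approx(seq(0, 1, length.out = Lc), cam,
           xout = seq(0, 1, length.out = n))$y
  }
  if (guided) {
    sal <- abs(as.numeric(bwd$dinput))
    if (max(sal) > 0) sal <- sal / max(sal)
    vals <- vals * sal
  }
  cam_max <- max(vals)
  if (cam_max > 0) vals <- vals / cam_max
  structure(list(values = vals, cam_max = cam_max, layer_id = layer_id,
                 sampling_rate = if (inherits(signal, "preproc_signal")) {
                   signal$sampling_rate
                 } else 200),
            class = "importance_trace")
}

#' Select the convolutional layer that best tracks QS complexes
#'
#' Which layer's Grad-CAM trace aligns best with the unipolar complexes
#' varies from one trained model to another, so the interpretability
#' analysis starts by probing a small sample of QS-train records across
#' candidate layers and keeping the one whose importance peaks best track
#' the true complex onsets (pooled fraction of peaks within a quarter cycle
#' length of an onset). The selected layer is then used for the full
#' importance analysis.
#'
#' @param model A trained `fast_cnn`.
#' @param records List of `egm_record` (QS-train probe sample).
#' @param truths Matching list of `egm_truth` (need `complex_onsets` and
#'   `cycle_length`).
#' @param candidates Layer ids to compare.
#' @return A list: `layer` (best id) and `scores` (tibble of pooled hit
#'   fractions per candidate).
#' @export
select_gradcam_layer <- function(model, records, truths,
                                 candidates = c("stage2.block0",
                                                "stage2.block1",
                                                "stage3.block0",
                                                "stage3.block1")) {
  stopifnot(length(records) == length(truths), length(records) >= 1)
  score_one <- function(layer) {
    hits <- numeric(0)
    wts <- numeric(0)
    for (i in seq_along(records)) {
      ps <- preprocess_signal(records[[i]]$unipolar,
                              records[[i]]$sampling_rate)
      tr <- gradcam_trace(model, ps, layer)
      al <- peak_alignment(tr, truths[[i]]$complex_onsets,
                           window = truths[[i]]$cycle_length / 4)
      if (!is.na(al$hit_fraction)) {
        hits <- c(hits, al$hit_fraction)
        wts <- c(wts, al$n_peaks)
      }
    }
    if (!length(hits) || sum(wts) == 0) return(NA_real_)
    sum(hits * wts) / sum(wts)
  }
  scores <- tibble::tibble(
    layer_id = candidates,
    pooled_hit_fraction = vapply(candidates, score_one, numeric(1)))
  best <- scores$layer_id[which.max(scores$pooled_hit_fraction)]
  list(layer = best, scores = scores)
}

#' Peaks of an importance trace
#'
#' Local maxima above `height` of the normalized trace, at least
#' `min_separation_ms` apart (larger peaks kept on conflict).
#'
#' @param trace An `importance_trace`.
#' @param height Minimum normalized height.
#' @param min_separation_ms Minimum peak spacing (ms).
#' @return Numeric vector of peak times (ms).
#' @export
trace_peaks <- function(trace, height = 0.5, min_separation_ms = 50) {
  v <- trace$values
  n <- length(v)
  fs <- trace$sampling_rate
  if (n < 3) return(numeric(0))
  idx <- which(c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] &
                   v[2:(n - 1)] > v[3:n], FALSE) & v > height)
  if (!length(idx)) return(numeric(0))
  refr <- min_separation_ms * fs / 1000
  ord <- idx[order(v[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= refr)) kept <- c(kept, i)
  }
  index_to_ms(sort(kept), fs)
}

#' Alignment of importance peaks with true activation onsets
#'
#' Quantifies how well an importance trace tracks ground-truth complexes:
#' the fraction of trace peaks lying within `window` ms of an onset, the
#' symmetric fraction of onsets hit by a peak, and the median absolute
#' peak-to-nearest-onset distance. With no peaks (e.g. a uniformly zero
#' trace) the statistics are returned as `NA`.
#'
#' @param trace An `importance_trace`.
#' @param truth_onsets Onset times (ms).
#' @param window Matching window (ms).
#' @return A one-row tibble: `n_peaks`, `hit_fraction`, `onset_recall`,
#'   `median_distance_ms`.
#' @export
peak_alignment <- function(trace, truth_onsets, window = 50) {
  if (length(trace$values) == 0) abort("Empty trace.")
  peaks <- trace_peaks(trace)
  if (length(peaks) == 0 || length(truth_onsets) == 0) {
    return(tibble::tibble(n_peaks = length(peaks),
                          hit_fraction = NA_real_,
                          onset_recall = NA_real_,
                          median_distance_ms = NA_real_))
  }
  d_peak <- vapply(peaks, function(p) min(abs(truth_onsets - p)), 1)
  d_onset <- vapply(truth_onsets, function(o) min(abs(peaks - o)), 1)
  tibble::tibble(
    n_peaks = length(peaks),
    hit_fraction = mean(d_peak <= window),
    onset_recall = mean(d_onset <= window),
    median_distance_ms = median(d_peak))
}
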