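# Independent oracles and shared fixtures for the test suite.

# Brute-force periodic-chain search: enumerate every increasing subsequence
# whose consecutive intervals lie within cl +/- tol, and pick the best by
# (max length, min cost, lexicographically earliest times).
brute_force_chain <- function(candidates, cl, tol_fraction = 0.25) {
  n <- length(candidates)
  tol <- tol_fraction * cl
  best <- list(chain = numeric(0), cost = 0)
  better <- function(a_chain, a_cost, b_chain, b_cost) {
    if (length(a_chain) != length(b_chain)) {
      return(length(a_chain) > length(b_chain))
    }
    if (abs(a_cost - b_cost) > 1e-12) return(a_cost < b_cost)
    k <- min(length(a_chain), length(b_chain))
    for (t in seq_len(k)) {
      if (a_chain[t] != b_chain[t]) return(a_chain[t] < b_chain[t])
    }
    FALSE
  }
  extend <- function(chain, cost, next_idx) {
    if (better(chain, cost, best$chain, best$cost)) {
      best <<- list(chain = chain, cost = cost)
    }
    for (j in next_idx) {
      d <- candidates[j] - chain[length(chain)]
      if (abs(d - cl) < tol) {
        extend(c(chain, candidates[j]), cost + abs(d - cl),
               if (j < n) (j + 1):n else integer(0))
      }
    }
  }
  for (i in seq_len(n)) {
    extend(candidates[i], 0, if (i < n) (i + 1):n else integer(0))
  }
  best
}

# Brute-force pairwise AUC: fraction of positive/negative pairs correctly
# ranked, ties counted half.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Dominant frequency of a signal by direct FFT, restricted to [f_lo, f_hi].
dominant_freq <- function(x, fs, f_lo = 0.5, f_hi = 20) {
  n <- length(x)
  X <- Mod(stats::fft(x - mean(x)))^2
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= f_lo & freq <= f_hi
  freq[keep][which.max(X[keep])]
}

# Noise-free generator settings for deterministic fixtures.
clean_config <- function(...) {
  synth_config(noise_sd = 0, bipolar_noise_sd = 0,
               baseline_wander_amplitude = 0, jitter_sd = 0,
               ventricular_prob = 0, ...)
}

# A tiny trained-network cache so several test files can share one model.
.test_cache <- new.env(parent = emptyenv())

# Closed-form parameter count of the residual topology from layer arithmetic.
expected_param_count <- function(stem_ch, stage_blocks, stage_channels,
                                 stem_kernel = 7, kernel = 3) {
  count <- stem_kernel * 1 * stem_ch + 2 * stem_ch  # stem conv + bn
  in_ch <- stem_ch
  for (s in seq_along(stage_blocks)) {
    out_ch <- stage_channels[s]
    for (b in seq_len(stage_blocks[s])) {
      count <- count + kernel * in_ch * out_ch + 2 * out_ch   # conv1+bn1
      count <- count + kernel * out_ch * out_ch + 2 * out_ch  # conv2+bn2
      stride <- if (b == 1 && s > 1) 2 else 1
      if (stride != 1 || in_ch != out_ch) {
        count <- count + in_ch * out_ch + 2 * out_ch          # proj+bn
      }
      in_ch <- out_ch
    }
  }
  as.integer(count + in_ch + 1)  # fully connected
}
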