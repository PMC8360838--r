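#' @importFrom stats fft median rnorm runif sd approx quantile rbinom setNames
#' @importFrom rlang abort %||% .data
#' @importFrom stats predict
NULL

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# t = 0 ms corresponds to sample index 1.
ms_to_index <- function(t_ms, fs) as.integer(round(t_ms * fs / 1000)) + 1L
index_to_ms <- function(i, fs) (i - 1) * 1000 / fs

# One-sided power spectrum of a real signal: tibble-free internal helper.
# Returns list(freq, power) for bins 0 .. fs/2.
power_spectrum <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  nh <- floor(n / 2) + 1L
  list(
    freq = (seq_len(nh) - 1) * fs / n,
    power = Mod(X[seq_len(nh)])^2
  )
}
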