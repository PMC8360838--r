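#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a FaST decision into a one-row tibble
#'
#' @param x A `fast_decision` from [classify_fast()].
#' @param ... Unused.
#' @return One-row tibble: `is_fast`, `is_periodic`, `periodicity_cl_ms`,
#'   `peak_power_fraction`, `chain_length`, `sustained`, `qs_fraction`.
#' @export
tidy.fast_decision <- function(x, ...) {
  tibble::tibble(
    is_fast = x$is_fast,
    is_periodic = x$periodicity$is_periodic,
    periodicity_cl_ms = x$periodicity$periodicity_cl,
    peak_power_fraction = x$periodicity$peak_power_fraction,
    chain_length = x$train$chain_length,
    sustained = x$sustained,
    qs_fraction = x$qs_fraction)
}

#' Tidy / summarize a trained classifier
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary (best validation AUC and epoch, parameter count).
#'
#' @param x A trained `fast_cnn`.
#' @param ... Unused.
#' @export
tidy.fast_cnn <- function(x, ...) x$history

#' @rdname tidy.fast_cnn
#' @export
glance.fast_cnn <- function(x, ...) {
  tibble::tibble(
    n_parameters = n_parameters(x),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_auc = if (nrow(x$history)) max(x$history$val_auc) else NA_real_)
}

#' Tidy / summarize a cross-validation result
#'
#' `tidy()` returns one row per seed x fold (x subsample fraction);
#' `glance()` the pooled mean and standard deviation of the AUC.
#'
#' @param x A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) x$summary

#' Tidy an importance trace
#'
#' @param x An `importance_trace`.
#' @param ... Unused.
#' @return Tibble with columns `t_ms`, `importance`.
#' @export
tidy.importance_trace <- function(x, ...) {
  tibble::tibble(
    t_ms = index_to_ms(seq_along(x$values), x$sampling_rate),
    importance = x$values)
}

#' Tidy an electrogram record into long format
#'
#' @param x An `egm_record`.
#' @param ... Unused.
#' @return Tibble with columns `t_ms`, `channel`, `mv`.
#' @export
tidy.egm_record <- function(x, ...) {
  t_ms <- index_to_ms(seq_along(x$unipolar), x$sampling_rate)
  dplyr::bind_rows(
    tibble::tibble(t_ms = t_ms, channel = "unipolar", mv = x$unipolar),
    tibble::tibble(t_ms = t_ms, channel = "bipolar", mv = x$bipolar))
}
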