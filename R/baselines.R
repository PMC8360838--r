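#' Classic machine-learning baselines
#'
#' Fits one of the reference classifiers on the same preprocessed length-1000
#' traces the network consumes: ridge-penalized logistic regression
#' (`glmnet`; the penalty keeps the fit defined when features outnumber
#' records), a polynomial-kernel support vector machine of degree 3 or 10
#' (`e1071`), or k-nearest-neighbours with k = 10 or 50 (`class`). All
#' produce continuous scores usable for ROC analysis.
#'
#' @param kind `"logistic_regression"`, `"svm"` or `"knn"`.
#' @param x Numeric matrix, one row per record.
#' @param y Binary labels.
#' @param svm_degree Polynomial degree (SVM only; 3 or 10 in the reference
#'   comparison).
#' @param knn_k Neighbour count (KNN only; 10 or 50).
#' @param lambda Ridge penalty for logistic regression.
#' @return A list of class `fast_baseline` with a [predict()] method
#'   returning scores.
#' @export
fit_baseline <- function(kind, x, y, svm_degree = 3, knn_k = 10,
                         lambda = 1e-3) {
  kind <- match.arg(kind, c("logistic_regression", "svm", "knn"))
  y <- as.integer(as.logical(y))
  fit <- switch(kind,
    logistic_regression = glmnet::glmnet(
      x, y, family = "binomial", alpha = 0, lambda = lambda,
      standardize = FALSE),
    svm = e1071::svm(x, factor(y), kernel = "polynomial",
                     degree = svm_degree, scale = FALSE),
    knn = {
      if (knn_k > nrow(x)) {
        abort(sprintf("knn_k = %d exceeds the %d training records.",
                      knn_k, nrow(x)))
      }
      list(x = x, y = y, k = knn_k)
    })
  structure(list(kind = kind, fit = fit, svm_degree = svm_degree,
                 knn_k = knn_k, lambda = lambda),
            class = "fast_baseline")
}

#' @exportS3Method base::print
print.fast_baseline <- function(x, ...) {
  extra <- switch(x$kind, svm = sprintf(" degree %d", x$svm_degree),
                  knn = sprintf(" k = %d", x$knn_k), "")
  cat(sprintf("<fast_baseline: %s%s>\n", x$kind, extra))
  invisible(x)
}

#' @param object A `fast_baseline`.
#' @param newdata Matrix of preprocessed traces.
#' @param ... Unused.
#' @rdname fit_baseline
#' @export
predict.fast_baseline <- function(object, newdata, ...) {
  switch(object$kind,
    logistic_regression = as.numeric(
      predict(object$fit, newdata, type = "response")),
    svm = {
      dv <- attr(predict(object$fit, newdata, decision.values = TRUE),
                 "decision.values")
      s <- as.numeric(dv[, 1])
      # orient decision values so larger = positive class
      if (colnames(dv)[1] == "0/1") -s else s
    },
    knn = {
      pr <- class::knn(object$fit$x, newdata, factor(object$fit$y),
                       k = object$fit$k, prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "1", p_win, 1 - p_win)
    })
}
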