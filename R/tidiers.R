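#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a minimum-Gumbel fit
#'
#' @param x a `gumbel_fit`.
#' @param ... unused.
#' @return one row per parameter with `term` and `estimate`.
#' @export
tidy.gumbel_fit <- function(x, ...) {
  tibble(term = c("location", "scale"), estimate = c(x$location, x$scale))
}

#' @rdname tidy.gumbel_fit
#' @export
glance.gumbel_fit <- function(x, ...) {
  tibble(logLik = x$loglik, cdf_abs_error = x$cdf_abs_error, nobs = x$n)
}

#' Tidy a modified-sigmoid fit
#'
#' @param x a `sigmoid_fit`.
#' @param ... unused.
#' @return one row per parameter with `term` and `estimate`.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' @rdname tidy.sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(rss = x$rss, nobs = x$n)
}

#' Predict the sigmoid log-odds curve of a fit
#'
#' @param object a `sigmoid_fit`.
#' @param newdata optional data frame with a `bin_center` column (the fitted
#'   bins are used when omitted).
#' @param ... unused.
#' @return numeric vector of fitted log-odds.
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata$bin_center
  sigmoid_logodds(x, object$a, object$b, object$c)
}
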