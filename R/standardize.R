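# Feature standardization fitted on training rows only.

#' Fit a feature standardizer
#'
#' Computes per-feature mean and population standard deviation (denominator
#' n, so a two-point column \{0, 2\} maps to \{-1, +1\}) on training rows.
#' Standard deviations are floored at 1e-8 so constant features transform
#' to exactly 0. The fitted object is applied to held-out
#' rows with training statistics only, so held-out columns generally do not
#' have mean 0.
#'
#' @param x Numeric training matrix (rows = observations).
#' @return An object of class `standardizer` with elements `mean`, `sd`
#'   (floored) and `constant` (logical per feature).
#' @export
#' @examples
#' s <- fit_standardizer(matrix(c(0, 2, 5, 5), ncol = 2))
#' apply_standardizer(s, matrix(c(0, 2, 5, 5), ncol = 2))
fit_standardizer <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop_input("fit_standardizer needs at least 2 rows")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu, "-")^2))
  constant <- sdv < 1e-8
  sdv[constant] <- 1e-8
  structure(list(mean = mu, sd = sdv, constant = constant),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param object A fitted `standardizer`.
#' @export
apply_standardizer <- function(object, x) {
  if (!inherits(object, "standardizer")) {
    stop_input("'object' must be a fitted standardizer")
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) != length(object$mean)) {
    stop_dimension(paste0("standardizer fitted on ", length(object$mean),
                          " features, got ", ncol(x)))
  }
  out <- sweep(sweep(x, 2, object$mean, "-"), 2, object$sd, "/")
  if (any(object$constant)) out[, object$constant] <- 0
  out
}
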