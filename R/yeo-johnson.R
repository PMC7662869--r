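#' Apply the Yeo-Johnson power transform
#'
#' The normalizing transform used on the skewed questionnaire items before
#' PCA. For `x >= 0` it is `((x+1)^lambda - 1)/lambda` (or `log(x+1)` at
#' `lambda = 0`); for `x < 0` it is `-(((-x+1)^(2-lambda) - 1)/(2-lambda))`
#' (or `-log(-x+1)` at `lambda = 2`). Monotone increasing in `x` for every
#' `lambda`, and continuous in `lambda` at 0 and 2 (computed via
#' `expm1`/`log1p` so near-boundary lambdas are numerically stable).
#'
#' @param x numeric vector.
#' @param lambda single finite power parameter.
#' @return Transformed vector of the same length.
#' @seealso [fitYeoJohnson()]
#' @export
applyYeoJohnson <- function(x, lambda) {
  stopifnot(is.numeric(x), length(lambda) == 1L, is.finite(lambda))
  if (any(!is.finite(x))) stop("x must be finite")
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos)) {
    lx <- log1p(x[pos])
    out[pos] <- if (lambda == 0) lx else expm1(lambda * lx) / lambda
  }
  if (any(!pos)) {
    lx <- log1p(-x[!pos])
    out[!pos] <- if (lambda == 2) -lx else -expm1((2 - lambda) * lx) / (2 - lambda)
  }
  out
}

#' Profile log-likelihood of the Yeo-Johnson model
#'
#' Gaussian log-likelihood of the transformed data, profiled over mean and
#' variance, including the transform Jacobian
#' `(lambda - 1) * sum(sign(x) * log(|x| + 1))`.
#'
#' @param x numeric data.
#' @param lambda power parameter.
#' @return Log-likelihood value (up to an additive constant in `n`).
#' @export
yeoJohnsonLogLik <- function(x, lambda) {
  n <- length(x)
  z <- applyYeoJohnson(x, lambda)
  v <- sum((z - mean(z))^2) / n
  if (v <= 0) return(-Inf)
  -n / 2 * log(v) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Fit the Yeo-Johnson transform to one item
#'
#' Maximum-likelihood estimate of the power parameter on `[-5, 5]` (coarse
#' grid bracket followed by golden-section refinement), plus the mean and
#' standard deviation of the transformed values so that
#' `(applyYeoJohnson(x, lambda) - center) / scale` has mean 0, sd 1.
#'
#' @param x numeric responses for one item; needs at least 3 distinct finite
#'   values.
#' @param lower,upper search bounds for lambda.
#' @return List with elements `lambda`, `center`, `scale`.
#' @examples
#' set.seed(1)
#' fitYeoJohnson(exp(rnorm(200)))$lambda  # < 1: log-like transform needed
#' @export
fitYeoJohnson <- function(x, lower = -5, upper = 5) {
  if (any(!is.finite(x))) stop("x must be finite")
  if (length(unique(x)) < 3L)
    stop("degenerate item: fewer than 3 distinct values; drop the item")
  coarse <- seq(lower, upper, length.out = 41L)
  ll <- vapply(coarse, function(l) yeoJohnsonLogLik(x, l), numeric(1))
  i <- which.max(ll)
  lo <- coarse[max(1L, i - 1L)]
  hi <- coarse[min(length(coarse), i + 1L)]
  opt <- stats::optimize(function(l) yeoJohnsonLogLik(x, l),
                         lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  z <- applyYeoJohnson(x, lambda)
  s <- stats::sd(z)
  if (!is.finite(s) || s <= 0)
    stop("degenerate item: zero variance after transform; drop the item")
  list(lambda = lambda, center = mean(z), scale = s)
}

#' Fit Yeo-Johnson normalization across all items of a response table
#'
#' Fits one transform per item column; items that are constant (or collapse
#' to zero variance after transform) are dropped with a message, matching a
#' complete-case battery where some items carry no variation.
#'
#' @param responses an [ItemResponseTable-class] or numeric matrix
#'   (subjects x items).
#' @return A [TransformParams-class] for the retained items.
#' @export
fitTransform <- function(responses) {
  X <- if (is(responses, "ItemResponseTable")) responseValues(responses)
       else as.matrix(responses)
  fits <- vector("list", ncol(X))
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    f <- tryCatch(fitYeoJohnson(X[, j]), error = function(e) NULL)
    if (is.null(f)) {
      message("dropping degenerate item: ", colnames(X)[j])
    } else {
      fits[[j]] <- f
      keep[j] <- TRUE
    }
  }
  if (!any(keep)) stop("no item survived the transform fit")
  lam <- vapply(fits[keep], `[[`, numeric(1), "lambda")
  ctr <- vapply(fits[keep], `[[`, numeric(1), "center")
  scl <- vapply(fits[keep], `[[`, numeric(1), "scale")
  names(lam) <- names(ctr) <- names(scl) <- colnames(X)[keep]
  new("TransformParams", lambda = lam, center = ctr, scale = scl)
}

#' Apply fitted normalization parameters to a response matrix
#'
#' Transform-then-standardize: each retained item is Yeo-Johnson transformed
#' with its fitted lambda and z-scored with the fitted mean and sd.
#'
#' @param responses [ItemResponseTable-class] or matrix containing (at least)
#'   the items named in `params`.
#' @param params a [TransformParams-class].
#' @return Numeric matrix, subjects x retained items, standardized.
#' @export
applyTransform <- function(responses, params) {
  X <- if (is(responses, "ItemResponseTable")) responseValues(responses)
       else as.matrix(responses)
  items <- names(params@lambda)
  if (!all(items %in% colnames(X)))
    stop("response table is missing items: ",
         paste(setdiff(items, colnames(X)), collapse = ", "))
  out <- matrix(NA_real_, nrow(X), length(items),
                dimnames = list(rownames(X), items))
  for (j in seq_along(items)) {
    z <- applyYeoJohnson(X[, items[j]], params@lambda[j])
    out[, j] <- (z - params@center[j]) / params@scale[j]
  }
  out
}
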