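#' Model I (ordinary or robust) simple linear regression
#'
#' Least-squares fit of `y = slope * x (+ intercept)`. With `robust = TRUE`
#' the fit is iteratively reweighted least squares with Tukey bisquare
#' weights (tuning constant 4.685) and a median-absolute-deviation residual
#' scale, iterating until the largest coefficient change is below 1e-8 or 50
#' iterations — the conventional automatic-outlier-exclusion behaviour
#' behind common statistics toolboxes.
#'
#' @param x,y Numeric vectors of equal length; `x` must not be constant.
#' @param intercept Fit an intercept (`TRUE`) or force the line through the
#'   origin (`FALSE`).
#' @param robust Use bisquare IRLS instead of plain least squares.
#' @return A `dom_fit` object: list with `slope`, `slope_se`, `intercept`,
#'   `intercept_se` (`NA` for through-origin fits), `r_squared`, `rmse`
#'   (on `df = n - p` denominator), `n`, `df`, `residuals`, `fitted`,
#'   `weights` (robust only), `method`.
#' @export
ols_fit <- function(x, y, intercept = TRUE, robust = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  p <- if (intercept) 2L else 1L
  if (n < p + 1L) stop("too few observations (need n >= ", p + 1, ")",
                       call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; slope undefined", call. = FALSE)

  X <- if (intercept) cbind(1, x) else cbind(x)
  w <- rep(1, n)
  beta <- stats::lm.fit(X, y)$coefficients
  if (robust) {
    for (iter in seq_len(50)) {
      r <- y - drop(X %*% beta)
      s <- stats::median(abs(r)) / 0.6745
      if (s <= .Machine$double.eps) break  # exact fit on the majority
      u <- r / (4.685 * s)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      beta_new <- stats::lm.wfit(X, y, w)$coefficients
      if (max(abs(beta_new - beta)) < 1e-8) {
        beta <- beta_new
        break
      }
      beta <- beta_new
    }
  }
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df <- n - p
  rss <- sum(resid^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tss <- sum((y - mean(y))^2)
  new_dom_fit(
    slope = unname(beta[p]), slope_se = unname(se[p]),
    intercept = if (intercept) unname(beta[1]) else NA_real_,
    intercept_se = if (intercept) unname(se[1]) else NA_real_,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    rmse = sqrt(rss / df), n = n, df = df,
    residuals = resid, fitted = fitted,
    weights = if (robust) w else NULL,
    method = if (robust) "modelI_robust" else "modelI"
  )
}

#' Model II (geometric mean / reduced major axis) regression
#'
#' For relationships where both variables carry error and neither is the
#' controlled one, the geometric-mean regression minimizes offsets along
#' both axes equally: `slope = sign(r) * sd(y) / sd(x)`, intercept through
#' the means. The slope standard error uses the usual geometric-mean
#' approximation `|slope| * sqrt((1 - r^2) / n)`. A zero correlation leaves
#' the slope sign undefined and is an error.
#'
#' @param x,y Numeric vectors of equal length, both non-constant.
#' @return A `dom_fit` object (see [ols_fit()]), `method = "modelII_geometric"`.
#' @export
gm_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("too few observations (need n >= 3)", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y", call. = FALSE)
  r <- stats::cor(x, y)
  if (r == 0) stop("correlation is zero; model II slope sign undefined",
                   call. = FALSE)
  slope <- sign(r) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  resid <- y - fitted
  df <- n - 2L
  tss <- sum((y - mean(y))^2)
  new_dom_fit(
    slope = slope, slope_se = abs(slope) * sqrt((1 - r^2) / n),
    intercept = intercept,
    intercept_se = abs(slope) * sqrt((1 - r^2) / n) *
      sqrt(mean(x^2)),  # delta-method through the mean point
    r_squared = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_,
    rmse = sqrt(sum(resid^2) / df), n = n, df = df,
    residuals = resid, fitted = fitted, weights = NULL,
    method = "modelII_geometric"
  )
}

new_dom_fit <- function(...) structure(list(...), class = "dom_fit")

#' @export
print.dom_fit <- function(x, ...) {
  cat(sprintf("<dom_fit %s> slope %.4f (se %.4f)", x$method, x$slope,
              x$slope_se))
  if (!is.na(x$intercept)) {
    cat(sprintf(", intercept %.4f (se %.4f)", x$intercept, x$intercept_se))
  }
  cat(sprintf("\n  n = %d, R2 = %.4f, RMSE = %.4f\n", x$n, x$r_squared,
              x$rmse))
  invisible(x)
}

#' Predict from a simple-regression fit
#'
#' @param object A `dom_fit`.
#' @param newdata Numeric vector of x values (or data frame with column `x`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.dom_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  b0 <- if (is.na(object$intercept)) 0 else object$intercept
  b0 + object$slope * x
}

#' Goodness-of-fit metrics for paired observed/predicted values
#'
#' `R^2 = 1 - RSS/TSS` with TSS about the observed mean — this can be
#' negative, which signals a model fitting worse than a horizontal line at
#' the mean. RMSE uses the degrees-of-freedom denominator `n - n_params`.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param n_params Number of parameters estimated by the model that produced
#'   `predicted` (0 for a fixed, externally calibrated model).
#' @return A one-row tibble with `r_squared`, `rmse`, `n`, `df`.
#' @export
fit_metrics <- function(observed, predicted, n_params = 0) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  n <- length(observed)
  if (n <= n_params) stop("need n > n_params", call. = FALSE)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("zero total sum of squares; R^2 undefined", call. = FALSE)
  rss <- sum((observed - predicted)^2)
  tibble::tibble(r_squared = 1 - rss / tss,
                 rmse = sqrt(rss / (n - n_params)),
                 n = n, df = n - n_params)
}
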