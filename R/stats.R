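#' Significance stars
#'
#' Maps p-values to the star convention used in the figures:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001,
#' `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "****",
                ifelse(p < 1e-3, "***",
                       ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", "ns")))))
}

test_result <- function(statistic, df, p, method, degenerate = FALSE,
                        adjusted_p = NULL, estimate = NULL) {
  structure(list(statistic = statistic, df = df, p = p,
                 adjusted_p = adjusted_p, method = method,
                 degenerate = degenerate, estimate = estimate,
                 stars = p_stars(if (is.null(adjusted_p)) p else adjusted_p)),
            class = "redox_test")
}

#' @export
print.redox_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g %s%s\n",
              x$method, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p, x$stars,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Student's t-test with degenerate-input handling
#'
#' Two-sided Student's t-test. Unpaired comparisons use the classical
#' pooled-variance form by default (`welch = FALSE`); paired comparisons
#' reduce to a one-sample test on the differences. Zero-variance inputs
#' yield a typed degenerate result instead of `NaN`: identical data give
#' statistic 0 and p 1; a nonzero mean difference with zero variance gives
#' a signed infinite statistic and p 0.
#'
#' @param x,y Numeric vectors (each n >= 2; equal lengths when paired).
#' @param paired Paired test on element-wise differences.
#' @param welch Use the Welch unequal-variance form instead of pooled.
#' @return A `redox_test` with fields `statistic`, `df`, `p`, `estimate`
#'   (mean difference), `degenerate`.
#' @examples
#' t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
t_test <- function(x, y, paired = FALSE, welch = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (paired && length(x) != length(y)) {
    stop("paired test requires equal lengths", call. = FALSE)
  }
  method <- if (paired) "paired t-test" else
    if (welch) "Welch t-test" else "Student t-test"
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        return(test_result(0, length(d) - 1, 1, method, degenerate = TRUE,
                           estimate = 0))
      }
      return(test_result(sign(mean(d)) * Inf, length(d) - 1, 0, method,
                         degenerate = TRUE, estimate = mean(d)))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      df <- length(x) + length(y) - 2
      delta <- mean(x) - mean(y)
      if (delta == 0) {
        return(test_result(0, df, 1, method, degenerate = TRUE, estimate = 0))
      }
      return(test_result(sign(delta) * Inf, df, 0, method,
                         degenerate = TRUE, estimate = delta))
    }
    tt <- stats::t.test(x, y, var.equal = !welch)
  }
  est <- if (paired) unname(tt$estimate) else
    unname(tt$estimate[1] - tt$estimate[2])
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              method, estimate = est)
}

#' Ordinary one-way ANOVA
#'
#' F-test of equal group means with (k-1, N-k) degrees of freedom. All
#' groups need n >= 2. Zero within-group variance is handled as a typed
#' degenerate result (p 1 if all means equal, p 0 otherwise).
#'
#' @param groups List of numeric vectors (>= 2 groups).
#' @return A `redox_test` with the F statistic and a length-2 `df`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- lengths(groups)
  if (any(n < 2)) {
    stop("every group needs n >= 2 (group ",
         paste(which(n < 2), collapse = ", "), " too small)", call. = FALSE)
  }
  k <- length(groups)
  N <- sum(n)
  df <- c(k - 1, N - k)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  means <- vapply(groups, mean, numeric(1))
  if (ssw == 0) {
    degen_p <- if (max(means) == min(means)) 1 else 0
    stat <- if (degen_p == 1) 0 else Inf
    return(test_result(stat, df, degen_p, "one-way ANOVA", degenerate = TRUE))
  }
  vals <- unlist(groups)
  fac <- factor(rep(seq_len(k), n))
  ow <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  test_result(unname(ow$statistic), unname(ow$parameter), ow$p.value,
              "one-way ANOVA")
}

# Monte-Carlo sample of the Dunnett max-|t| statistic for a balanced or
# unbalanced many-to-one design. lambda_i = sqrt(n_i / (n_i + n_0)) gives
# the product correlation structure of the contrast numerators.
dunnett_max_t_draws <- function(lambda, df, ndraws) {
  k <- length(lambda)
  z0 <- stats::rnorm(ndraws)
  maxt <- rep(0, ndraws)
  wscale <- sqrt(stats::rchisq(ndraws, df) / df)
  for (j in seq_len(k)) {
    zj <- lambda[j] * z0 + sqrt(1 - lambda[j]^2) * stats::rnorm(ndraws)
    maxt <- pmax(maxt, abs(zj / wscale))
  }
  maxt
}

#' Dunnett's many-to-one comparisons with Monte-Carlo adjustment
#'
#' Compares every treatment group against a control group using t
#' statistics with the pooled within-group standard deviation (df = N - k),
#' and adjusts the two-sided p-values for family-wise error under the
#' many-to-one multivariate-t null. The adjustment is computed by seeded
#' Monte-Carlo evaluation of the max-|t| statistic (default 1e5 draws), then
#' clamped into the analytic envelope [raw p, min(1, k * raw p)] in which
#' the exact Dunnett p always lies (this also makes the single-contrast
#' case collapse exactly to the raw p).
#'
#' @param groups List of numeric vectors, each n >= 2.
#' @param control_index Index of the control group within `groups`.
#' @param ndraws Monte-Carlo draws (>= 1e4).
#' @param seed Seed for the Monte-Carlo draws; identical seeds give
#'   identical adjusted p-values.
#' @return data.frame with one row per treatment contrast: `contrast`,
#'   `estimate` (treatment - control), `statistic`, `df`, `p`,
#'   `adjusted_p`, `stars`.
#' @examples
#' set.seed(2)
#' g <- list(control = rnorm(4), a = rnorm(4), b = rnorm(4, 3))
#' dunnett(g, control_index = 1)
#' @export
dunnett <- function(groups, control_index = 1, ndraws = 1e5, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2, ndraws >= 1e4)
  if (control_index < 1 || control_index > length(groups)) {
    stop("control_index out of range", call. = FALSE)
  }
  n <- lengths(groups)
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  k_all <- length(groups)
  N <- sum(n)
  df <- N - k_all
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  if (s2 == 0) {
    stop("degenerate input: zero within-group variance everywhere",
         call. = FALSE)
  }
  trt <- setdiff(seq_len(k_all), control_index)
  n0 <- n[control_index]
  m0 <- mean(groups[[control_index]])
  est <- vapply(trt, function(i) mean(groups[[i]]) - m0, numeric(1))
  se <- sqrt(s2 * (1 / n[trt] + 1 / n0))
  tstat <- est / se
  rawp <- 2 * stats::pt(-abs(tstat), df)
  lambda <- sqrt(n[trt] / (n[trt] + n0))
  maxt <- with_seed(seed, dunnett_max_t_draws(lambda, df, ndraws))
  adj <- vapply(abs(tstat), function(t0) mean(maxt >= t0), numeric(1))
  k <- length(trt)
  adj <- pmin(pmax(adj, rawp), pmin(1, k * rawp))
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_len(k_all))
  data.frame(contrast = paste(nms[trt], "-", nms[control_index]),
             estimate = est, statistic = tstat, df = df, p = rawp,
             adjusted_p = adj, stars = p_stars(adj),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simple linear regression with slope inference
#'
#' Ordinary least squares of `y` on `x` with the two-sided t-test of the
#' slope (df = n - 2), as used for dose-response fits and clinical
#' correlations.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); `x` must vary.
#' @param x_name,y_name Labels carried into the result.
#' @return A `regression_result`: list with `slope`, `intercept`,
#'   `r_squared`, `slope_p`, `slope_se`, `n`, `x_name`, `y_name`.
#' @examples
#' linregress(1:5, 3 * (1:5) - 2)
#' @export
linregress <- function(x, y, x_name = "x", y_name = "y") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("x is constant: no design variance for a slope", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate here (identity checks, B = A comparisons);
  # silence the "essentially perfect fit" advisory and handle p below
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- sm$coefficients
  slope_p <- if (nrow(co) >= 2) co[2, 4] else NA_real_
  # exact fit: residual variance 0 -> slope p is 0 by convention
  if (is.nan(slope_p)) slope_p <- 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 slope_p = slope_p,
                 slope_se = unname(co[2, 2]),
                 n = length(x), x_name = x_name, y_name = y_name),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> %s = %.4g * %s + %.4g (n = %d)\n",
              x$y_name, x$slope, x$x_name, x$intercept, x$n))
  cat(sprintf("  R^2 = %.4g, slope p = %.4g %s\n",
              x$r_squared, x$slope_p, p_stars(x$slope_p)))
  invisible(x)
}

#' @export
as.data.frame.regression_result <- function(x, ...) {
  data.frame(x_name = x$x_name, y_name = x$y_name, slope = x$slope,
             intercept = x$intercept, r_squared = x$r_squared,
             slope_p = x$slope_p, n = x$n, stringsAsFactors = FALSE)
}
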