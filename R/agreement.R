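#' Fit a per-parameter linear calibration against a reference method
#'
#' Least-squares fit of `reference = slope * model + intercept` on paired
#' single-cell values, used to correct systematic biases of the automated
#' tracker towards the manual reference.
#'
#' @param model_values values from the model under calibration
#' @param reference_values paired reference (e.g. manual-tracking) values
#' @param parameter name of the calibrated parameter (e.g. `"vsl"`)
#' @return an object of class `linear_calibration`: list with `parameter`,
#'   `slope`, `intercept`, `n`
#' @export
fit_linear_calibration <- function(model_values, reference_values,
                                   parameter = "value") {
  ok <- is.finite(model_values) & is.finite(reference_values)
  x <- model_values[ok]; y <- reference_values[ok]
  if (length(x) != length(model_values) && length(x) < 3L ||
      length(x) < 3L)
    stop("need at least 3 finite pairs", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("model values are constant; cannot fit a line", call. = FALSE)
  fit <- lm(y ~ x)
  structure(list(parameter = parameter,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(x)),
            class = "linear_calibration")
}

#' Apply per-parameter calibrations to kinematic profiles
#'
#' Maps each calibrated parameter affinely; parameters without a calibration
#' pass through with a warning. Non-reported BCF values (`NA`) remain
#' non-reported. By default LIN is calibrated directly like the other
#' parameters (`lin_mode = "direct"`); with `lin_mode = "recompute"` it is
#' recomputed as calibrated VSL / calibrated VCL instead.
#'
#' @param profiles data.frame of kinematic profiles (see [profile_tracks()])
#' @param calibrations a list of [fit_linear_calibration()] objects; names
#'   or `parameter` fields identify the target columns
#' @param lin_mode `"direct"` or `"recompute"`
#' @return the profiles with calibrated columns
#' @export
apply_calibration <- function(profiles, calibrations,
                              lin_mode = c("direct", "recompute")) {
  lin_mode <- match.arg(lin_mode)
  if (inherits(calibrations, "linear_calibration"))
    calibrations <- list(calibrations)
  by_param <- setNames(calibrations,
                       vapply(calibrations, `[[`, character(1), "parameter"))
  out <- profiles
  targets <- c("vsl", "vcl", "vap", "lin", "alh_max", "bcf")
  if (lin_mode == "recompute") targets <- setdiff(targets, "lin")
  for (p in intersect(targets, names(out))) {
    cal <- by_param[[p]]
    if (is.null(cal)) {
      warning(sprintf("no calibration for '%s'; passing through", p))
      next
    }
    v <- out[[p]]
    out[[p]] <- ifelse(is.na(v), NA_real_, cal$slope * v + cal$intercept)
  }
  if (lin_mode == "recompute")
    out$lin <- ifelse(out$vcl > 0, pmin(out$vsl / out$vcl, 1), 0)
  out
}

#' Agreement metrics between paired measurements
#'
#' R-squared as the squared Pearson correlation (identical to the regression
#' R2 of a simple OLS fit with intercept), root-mean-square error and mean
#' absolute error of the paired differences.
#'
#' @param pred predicted/model values
#' @param obs observed/reference values
#' @return list with `r2`, `rmse`, `mae`, `n`
#' @export
agreement <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  n <- length(pred)
  if (n < 2L) stop("need at least 2 finite pairs", call. = FALSE)
  d <- pred - obs
  list(r2 = suppressWarnings(cor(pred, obs))^2,
       rmse = sqrt(mean(d^2)),
       mae = mean(abs(d)),
       n = n)
}

#' Bland-Altman analysis of two methods
#'
#' Differences `d = a - b`, their mean (bias) and sample standard deviation
#' (n - 1 denominator), and limits of agreement `mean +/- multiplier * SD`.
#' The default multiplier is the usual 1.96; small-n comparisons often use
#' the two-sided 97.5% t-quantile instead (2.12 for n = 16). The x
#' coordinate of each pair is the reference value (`x_mode = "reference"`,
#' i.e. `b`) or the mean of the two methods (`x_mode = "mean"`).
#'
#' @param a,b paired measurement vectors (length >= 2)
#' @param multiplier limits-of-agreement multiplier
#' @param x_mode `"reference"` or `"mean"`
#' @return an object of class `bland_altman`: list with `mean_diff`,
#'   `sd_diff`, `multiplier`, `loa_low`, `loa_high`, `x_mode`, `n` and a
#'   `points` data.frame (`x`, `diff`)
#' @export
bland_altman <- function(a, b, multiplier = 1.96,
                         x_mode = c("reference", "mean")) {
  x_mode <- match.arg(x_mode)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  structure(list(mean_diff = m, sd_diff = s, multiplier = multiplier,
                 loa_low = m - multiplier * s,
                 loa_high = m + multiplier * s,
                 x_mode = x_mode, n = length(a),
                 points = data.frame(
                   x = if (x_mode == "reference") b else (a + b) / 2,
                   diff = d)),
            class = "bland_altman")
}

#' Percentage difference between duplicate measurements
#'
#' `100 * |m1 - m2| / mean(m1, m2)`, the symmetric repeatability metric for
#' duplicate measurements of one sample; defined as 0 when both values are
#' zero. Vectorised.
#'
#' @param m1,m2 the two measurements
#' @return percentage difference (non-negative)
#' @export
percentage_difference <- function(m1, m2) {
  avg <- (m1 + m2) / 2
  ifelse(m1 == 0 & m2 == 0, 0, {
    if (any(avg <= 0 & !(m1 == 0 & m2 == 0)))
      stop("mean of the two measurements must be > 0", call. = FALSE)
    100 * abs(m1 - m2) / avg
  })
}

#' Repeatability table for duplicate measurements
#'
#' Computes the percentage difference for every sample/metric pair and the
#' across-sample mean per metric (and per method, when a `method` column is
#' present), all at full precision before any rounding.
#'
#' @param duplicates data.frame with columns `sample`, `metric`, `m1`, `m2`
#'   and optionally `method`
#' @return an object of class `repeatability_result`: list with
#'   `per_sample` (the input plus `pct_diff`) and `means` (per metric
#'   [x method] mean percentage difference)
#' @export
repeatability_table <- function(duplicates) {
  req <- c("sample", "metric", "m1", "m2")
  if (!all(req %in% names(duplicates)))
    stop("duplicates needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (anyNA(duplicates[, c("m1", "m2")]))
    stop("missing duplicate measurement", call. = FALSE)
  per <- duplicates
  per$pct_diff <- percentage_difference(per$m1, per$m2)
  grouping <- if ("method" %in% names(per))
    list(metric = per$metric, method = per$method)
  else list(metric = per$metric)
  means <- aggregate(per$pct_diff, grouping, mean)
  names(means)[ncol(means)] <- "mean_pct_diff"
  structure(list(per_sample = per, means = means),
            class = "repeatability_result")
}
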