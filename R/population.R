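#' WHO 6th-edition motility grade thresholds
#'
#' Grade boundaries on VSL plus an operational immotility rule. WHO6 defines
#' rapid progressive as VSL >= 25 um/s, slow progressive as
#' 5 <= VSL < 25 um/s and non-progressive as VSL < 5 um/s; "no active
#' movement" is made operational here as a maximum excursion below
#' `immotile_max_displacement` together with VCL below `immotile_max_vcl`.
#' Immotile and non-progressive cells are merged (IM&NP) in sample
#' summaries, so the exact immotility cutoffs do not affect the headline
#' three-way split.
#'
#' @param rapid_min_vsl minimum VSL of a rapid progressive cell (um/s,
#'   boundary inclusive)
#' @param slow_min_vsl minimum VSL of a slow progressive cell (um/s,
#'   boundary inclusive)
#' @param immotile_max_displacement maximum excursion from the starting
#'   point of an immotile cell (um)
#' @param immotile_max_vcl maximum VCL of an immotile cell (um/s)
#' @return an object of class `grade_thresholds`
#' @export
grade_thresholds <- function(rapid_min_vsl = 25, slow_min_vsl = 5,
                             immotile_max_displacement = 2,
                             immotile_max_vcl = 10) {
  if (!(rapid_min_vsl > slow_min_vsl && slow_min_vsl > 0))
    stop("need rapid_min_vsl > slow_min_vsl > 0", call. = FALSE)
  structure(list(rapid_min_vsl = rapid_min_vsl, slow_min_vsl = slow_min_vsl,
                 immotile_max_displacement = immotile_max_displacement,
                 immotile_max_vcl = immotile_max_vcl),
            class = "grade_thresholds")
}

#' Grade cells into WHO6 motility categories
#'
#' @param profiles data.frame of kinematic profiles (needs `vsl`, `vcl` and
#'   `max_excursion`; see [profile_tracks()]); a single [kinematic_profile()]
#'   row works too
#' @param thresholds a [grade_thresholds()] object
#' @return character vector with values `"rapid"`, `"slow"`,
#'   `"nonprogressive"`, `"immotile"`
#' @export
grade_cells <- function(profiles, thresholds = grade_thresholds()) {
  vsl <- profiles$vsl
  excur <- if (!is.null(profiles$max_excursion)) profiles$max_excursion
           else vsl * profiles$duration_s
  immotile <- excur < thresholds$immotile_max_displacement &
    profiles$vcl < thresholds$immotile_max_vcl
  out <- ifelse(vsl >= thresholds$rapid_min_vsl, "rapid",
         ifelse(vsl >= thresholds$slow_min_vsl, "slow", "nonprogressive"))
  out[immotile] <- "immotile"
  out
}

#' Per-sample motility summary
#'
#' Grades every profiled cell and aggregates the sample: percentages of
#' rapid progressive, slow progressive and the combined non-progressive plus
#' immotile (IM&NP) group, and population mean +/- SD of each kinematic
#' parameter (BCF averaged over reported values only). Warns when fewer than
#' 200 cells are available, the minimum WHO6 recommends for motility
#' assessment.
#'
#' @inheritParams grade_cells
#' @return an object of class `sample_summary`: a list with `n_cells`,
#'   `pct_rapid`, `pct_slow`, `pct_npim`, `grades` (per-cell), and `stats`
#'   (data.frame: parameter, mean, sd, n)
#' @export
summarize_sample <- function(profiles, thresholds = grade_thresholds()) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    stop("no profiles to summarise", call. = FALSE)
  if (nrow(profiles) < 200L)
    warning(sprintf("only %d cells analysed; WHO6 recommends > 200",
                    nrow(profiles)))
  g <- grade_cells(profiles, thresholds)
  n <- length(g)
  params <- c("vsl", "vcl", "vap", "lin", "alh_max", "bcf")
  stats <- do.call(rbind, lapply(params, function(p) {
    v <- profiles[[p]]
    v <- v[is.finite(v)]
    data.frame(parameter = p,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  structure(list(n_cells = n,
                 pct_rapid = 100 * sum(g == "rapid") / n,
                 pct_slow = 100 * sum(g == "slow") / n,
                 pct_npim = 100 * sum(g %in% c("nonprogressive", "immotile")) / n,
                 grades = g,
                 stats = stats),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("Sample summary: %d cells\n", x$n_cells))
  if (!is.null(x$concentration))
    cat(sprintf("  concentration: %.1f M/mL\n", x$concentration))
  cat(sprintf("  rapid progressive: %.1f%%  slow progressive: %.1f%%  IM&NP: %.1f%%\n",
              x$pct_rapid, x$pct_slow, x$pct_npim))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Fit the count-to-concentration calibration line
#'
#' Ordinary least squares of reference concentration on the mean number of
#' cells tracked in the opening frames of each calibration recording:
#' `concentration = slope * count + intercept`. A dilution series of samples
#' of known (hemocytometer) concentration provides the points.
#'
#' @param counts tracked-cell counts (one per calibration sample; may be
#'   fractional)
#' @param concentrations reference concentrations (M/mL)
#' @return an object of class `concentration_calibration`: list with
#'   `slope`, `intercept`, `r2`, `n`
#' @export
fit_concentration_curve <- function(counts, concentrations) {
  if (length(counts) != length(concentrations))
    stop("counts and concentrations must have equal length", call. = FALSE)
  if (length(unique(counts)) < 2L)
    stop("need at least 2 distinct count values", call. = FALSE)
  fit <- lm(concentrations ~ counts)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    warning("calibration slope is not positive; check the inputs")
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 n = length(counts)),
            class = "concentration_calibration")
}

#' Estimate concentration from a tracked-cell count
#'
#' Applies the affine calibration map and floors the result at zero.
#'
#' @param mean_count mean tracked-cell count over the opening frames
#' @param calib a [fit_concentration_curve()] result
#' @return concentration in M/mL
#' @export
estimate_concentration <- function(mean_count, calib) {
  if (!inherits(calib, "concentration_calibration"))
    stop("calib must be a concentration_calibration", call. = FALSE)
  pmax(0, calib$slope * mean_count + calib$intercept)
}
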