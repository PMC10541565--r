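#' Stage progression rate over time
#'
#' First-difference approximation of the derivative of the molecular
#' stage with respect to time for one series: for each consecutive pair,
#' `(stage[i+1] - stage[i]) / (time[i+1] - time[i])`, reported at the
#' interval midpoint. Telescoping identity: `sum(rate * dt)` equals
#' `stage[n] - stage[1]`.
#'
#' @param time numeric time axis (DOY, DAF or GDD units), strictly
#'   increasing.
#' @param stage integer molecular stages at those times.
#' @return data.frame with `time` (interval midpoints) and `rate`
#'   (stage units per time unit).
#' @export
stage_rate <- function(time, stage) {
  stopifnot(length(time) == length(stage), length(time) >= 2)
  if (any(diff(time) == 0)) stop("duplicate times in stage series")
  if (any(diff(time) < 0)) stop("times must be strictly increasing")
  data.frame(time = (time[-1] + time[-length(time)]) / 2,
             rate = diff(stage) / diff(time))
}

#' Growing degree days
#'
#' Cumulative heat summation above a base temperature:
#' `GDD_t = sum_{u <= t} max(0, T_u - base)`.
#'
#' @param daily_mean_temps daily mean temperatures, degrees C.
#' @param base base temperature, degrees C (default 10, the viticulture
#'   convention).
#' @return cumulative GDD vector, same length as the input.
#' @export
growing_degree_days <- function(daily_mean_temps, base = 10) {
  stopifnot(all(is.finite(daily_mean_temps)))
  cumsum(pmax(0, daily_mean_temps - base))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement statistic penalizing both correlation loss and location or
#' scale shift:
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (denominator n) moments. Ranges from -1 to 1 with
#' perfect agreement at 1; `|rho_c| <= |r|` always holds.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return scalar concordance coefficient.
#' @export
lin_concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("both vectors constant and equal: concordance undefined")
  2 * cxy / denom
}

#' Classify a concordance coefficient
#'
#' McBride's descriptive bins for Lin's coefficient: below 0.90 poor,
#' 0.90 to 0.95 moderate, 0.95 to 0.99 substantial, above 0.99 almost
#' perfect.
#'
#' @param rho_c concordance coefficient in [-1, 1].
#' @return one of `"poor"`, `"moderate"`, `"substantial"`,
#'   `"almost perfect"`.
#' @export
concordance_class <- function(rho_c) {
  stopifnot(rho_c >= -1, rho_c <= 1)
  if (rho_c < 0.90) "poor"
  else if (rho_c < 0.95) "moderate"
  else if (rho_c <= 0.99) "substantial"
  else "almost perfect"
}

#' Stage-shift statistics between two projections
#'
#' Per-sample shift `stage_a - stage_b` between two paired stage
#' assignments (e.g. reduced-panel vs full-core-set projection), with the
#' mean absolute shift, and median and interquartile range of the signed
#' shifts (linear-interpolation quantiles, type 7).
#'
#' @param stages_a,stages_b paired integer stage sequences.
#' @return list with `shifts`, `mean_abs_shift`, `median_shift`, `iqr`.
#' @export
shift_statistics <- function(stages_a, stages_b) {
  if (length(stages_a) != length(stages_b))
    stop("stage sequences have different lengths")
  shifts <- as.numeric(stages_a) - as.numeric(stages_b)
  q <- stats::quantile(shifts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(shifts = shifts,
       mean_abs_shift = mean(abs(shifts)),
       median_shift = q[2],
       iqr = q[3] - q[1])
}

#' Smoothed trend of a trait over molecular stages
#'
#' LOESS (degree 2, span 0.75 by default, shared with the smoothing
#' module) of a trait — e.g. percent reducing sugars or berry weight —
#' against assigned molecular stage; returns the fitted conditional mean
#' at each distinct observed stage.
#'
#' @param stages integer stages (>= 5 pairs).
#' @param trait numeric trait values, same length.
#' @param degree,span LOESS parameters.
#' @return data.frame with `stage` and `fitted`.
#' @export
trait_stage_trend <- function(stages, trait, degree = 2L, span = 0.75) {
  stopifnot(length(stages) == length(trait), length(stages) >= 5)
  fitted <- loess_smooth_gene(stages, trait, degree = degree, span = span)
  data.frame(stage = sort(unique(stages)), fitted = unname(fitted))
}

#' Replicate-consistency profile along the scale
#'
#' Averages the replicate CVs of the core genes within each condition and
#' joins the per-condition mean CV to the condition's assigned stage.
#' Zero-mean conditions (undefined CV) are excluded from the average.
#'
#' @param tensor an `expr_tensor`.
#' @param genes core gene ids over which to average.
#' @param projection a `projection_result` with one row per condition, in
#'   `tensor$conditions` order.
#' @return data.frame with `condition_id`, `stage`, `mean_cv`.
#' @export
replicate_consistency_profile <- function(tensor, genes, projection) {
  stopifnot(nrow(projection) == nrow(tensor$conditions))
  cvm <- replicate_cv_matrix(tensor, genes)
  data.frame(condition_id = tensor$conditions$condition_id,
             stage = projection$stage,
             mean_cv = rowMeans(cvm, na.rm = TRUE),
             stringsAsFactors = FALSE)
}
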