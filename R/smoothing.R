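#' LOESS smoothing of one expression profile
#'
#' Local polynomial regression (Cleveland's LOESS) of expression on the
#' ordinal timepoint, with replicates entering as separate points sharing
#' a predictor value. The local window holds the `ceiling(span * n)`
#' nearest points (point count, replicates included), weighted by the
#' tricube kernel on distance scaled to the window maximum; a local
#' polynomial of the given degree is fit by weighted least squares and
#' evaluated at each distinct timepoint.
#'
#' @param times numeric predictor values, one per observation (replicated
#'   timepoints allowed).
#' @param values numeric response values, same length.
#' @param degree local polynomial degree (default 2).
#' @param span fraction of points in each local window, in (0, 1]
#'   (default 0.75).
#' @return numeric vector of fitted values at the sorted distinct
#'   timepoints, named by timepoint.
#' @export
loess_smooth_gene <- function(times, values, degree = 2L, span = 0.75) {
  L <- loess_smoother_matrix(times, degree = degree, span = span)
  stats::setNames(as.numeric(L %*% values),
                  format(sort(unique(times))))
}

# Linear smoother matrix of the LOESS fit: rows index distinct sorted
# timepoints, columns index observations, so that fitted = L %*% y for any
# response y. Built by passing unit responses through stats::loess, which
# is exact because LOESS (without robustness iterations) is linear in y.
loess_smoother_matrix <- function(times, degree = 2L, span = 0.75) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  n <- length(times)
  distinct <- sort(unique(times))
  if (length(distinct) < degree + 2)
    stop("need at least degree + 2 distinct predictor values")
  window <- ceiling(span * n)
  if (window < degree + 1)
    stop("span window smaller than the local polynomial parameter count")
  key <- paste(format(c(degree, span, times), digits = 17), collapse = ",")
  cached <- .molstage_cache[[key]]
  if (!is.null(cached)) return(cached)
  L <- matrix(0, nrow = length(distinct), ncol = n)
  ctrl <- stats::loess.control(surface = "direct", statistics = "exact")
  for (r in seq_len(n)) {
    y <- numeric(n)
    y[r] <- 1
    # replicated predictors make some local systems rank-deficient; loess
    # falls back to a pseudoinverse there, which is the intended fit
    suppressWarnings({
      fit <- stats::loess(y ~ times, degree = degree, span = span,
                          family = "gaussian", control = ctrl)
      L[, r] <- stats::predict(fit, newdata = data.frame(times = distinct))
    })
  }
  rownames(L) <- format(distinct)
  .molstage_cache[[key]] <- L
  L
}

.molstage_cache <- new.env(parent = emptyenv())

#' Smooth a whole dataset series-by-series
#'
#' Applies [loess_smooth_gene()] independently to every gene within every
#' cultivar x vintage series (replicate-level points against the ordinal
#' timepoint) and assembles the conditions x genes matrix of smoothed
#' expression values. Smoothing is series-local: each series' fit sees
#' only its own timepoints.
#'
#' @param tensor an `expr_tensor`.
#' @param genes gene ids to smooth (the core set F); default all.
#' @param degree,span LOESS parameters (defaults 2 and 0.75).
#' @return numeric matrix, conditions x |genes|, rows in
#'   `tensor$conditions` order.
#' @export
smooth_dataset <- function(tensor, genes = tensor$gene_ids,
                           degree = 2L, span = 0.75) {
  stopifnot(all(genes %in% tensor$gene_ids))
  series_s <- paste(tensor$meta$cultivar, tensor$meta$vintage, sep = "|")
  series_c <- condition_series(tensor)
  out <- matrix(NA_real_, nrow = nrow(tensor$conditions), ncol = length(genes),
                dimnames = list(tensor$conditions$condition_id, genes))
  for (h in unique(series_c)) {
    samp <- which(series_s == h)
    tp <- tensor$meta$timepoint[samp]
    L <- loess_smoother_matrix(tp, degree = degree, span = span)
    fitted <- L %*% t(tensor$values[genes, samp, drop = FALSE])
    rows <- which(series_c == h)
    # smoother rows are in sorted distinct-timepoint order; condition rows
    # are already timepoint-sorted within the series
    stopifnot(identical(sort(unique(tp)), tensor$conditions$timepoint[rows]))
    out[rows, ] <- fitted
  }
  out
}
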