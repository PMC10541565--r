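#' Replicate-level expression tensor
#'
#' Container for a replicate-level expression matrix (genes x samples,
#' RPKM-like non-negative values) together with per-sample metadata. An
#' *experimental condition* is one cultivar x vintage x timepoint
#' combination; a *series* is one cultivar x vintage combination observed
#' over consecutive timepoints. Samples are normalized to
#' (cultivar, vintage, timepoint, replicate) order on construction.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns. All values must be finite and non-negative.
#' @param meta data.frame with one row per sample column, columns
#'   `sample` (matching `colnames(values)`), `cultivar`, `vintage`,
#'   `timepoint` (positive integer, contiguous from 1 within each
#'   cultivar x vintage series), `replicate`, and optionally `doy`
#'   (day of year) and `daf` (days after flowering).
#' @param n_replicates declared replicate count per condition (default 3).
#'   Every condition must have exactly this many samples.
#'
#' @return An object of class `expr_tensor`: a list with elements
#'   `values` (genes x samples matrix in normalized order), `meta`
#'   (normalized sample metadata with an added `condition_id` column),
#'   `gene_ids`, `n_replicates`, and `conditions` (one row per condition,
#'   in normalized order).
#' @export
expression_tensor <- function(values, meta, n_replicates = 3L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values))) stop("`values` must have gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (any(!is.finite(values))) stop("non-numeric or non-finite expression value")
  if (any(values < 0)) stop("negative expression value")

  required <- c("sample", "cultivar", "vintage", "timepoint", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(colnames(values))) stop("`values` must have sample column names")
  unmatched <- setdiff(colnames(values), meta$sample)
  if (length(unmatched))
    stop("sample(s) in expression absent from metadata: ",
         paste(unmatched, collapse = ", "))
  if (anyDuplicated(meta$sample)) stop("duplicate sample ids in metadata")
  meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]

  meta$timepoint <- as.integer(meta$timepoint)
  if (any(meta$timepoint < 1L)) stop("timepoints must be positive integers")
  for (col in c("doy", "daf")) if (!col %in% names(meta)) meta[[col]] <- NA_integer_

  # normalize sample order
  ord <- order(as.character(meta$cultivar), as.character(meta$vintage),
               meta$timepoint, as.character(meta$replicate))
  meta <- meta[ord, , drop = FALSE]
  values <- values[, ord, drop = FALSE]
  rownames(meta) <- NULL

  series_key <- paste(meta$cultivar, meta$vintage, sep = "|")
  for (h in unique(series_key)) {
    tp <- sort(unique(meta$timepoint[series_key == h]))
    if (!identical(tp, seq_len(length(tp))))
      stop("non-contiguous timepoints in series ", h,
           " (expected 1..", length(tp), ", got {",
           paste(tp, collapse = ","), "})")
  }

  cond_key <- paste(series_key, meta$timepoint, sep = "|")
  counts <- table(cond_key)
  if (any(counts != n_replicates))
    stop("unequal replicate counts: every condition must have exactly ",
         n_replicates, " replicates")
  meta$condition_id <- cond_key

  conditions <- unique(meta[, c("condition_id", "cultivar", "vintage",
                                "timepoint", "doy", "daf")])
  rownames(conditions) <- NULL

  structure(
    list(values = values, meta = meta, gene_ids = rownames(values),
         n_replicates = as.integer(n_replicates), conditions = conditions),
    class = "expr_tensor"
  )
}

#' @export
print.expr_tensor <- function(x, ...) {
  cat("<expr_tensor> ", length(x$gene_ids), " genes x ",
      ncol(x$values), " samples (", nrow(x$conditions), " conditions x ",
      x$n_replicates, " replicates)\n", sep = "")
  cat("  series:", paste(unique(paste(x$conditions$cultivar,
                                      x$conditions$vintage)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Series membership of each condition
#'
#' @param tensor an `expr_tensor`.
#' @return character vector, one cultivar x vintage series key per condition
#'   (in `tensor$conditions` order).
#' @export
condition_series <- function(tensor) {
  paste(tensor$conditions$cultivar, tensor$conditions$vintage, sep = "|")
}

#' Replicate-averaged expression matrix
#'
#' Averages the replicate columns of each experimental condition, yielding
#' the conditions x genes matrix of replicate means.
#'
#' @param tensor an `expr_tensor`.
#' @param genes optional character vector of gene ids (default all).
#' @return numeric matrix, conditions x genes, rows in `tensor$conditions`
#'   order.
#' @export
condition_means <- function(tensor, genes = tensor$gene_ids) {
  stopifnot(all(genes %in% tensor$gene_ids))
  grp <- factor(tensor$meta$condition_id, levels = tensor$conditions$condition_id)
  # indicator matrix samples x conditions, each column scaled to mean weights
  ind <- stats::model.matrix(~ 0 + grp)
  ind <- sweep(ind, 2, colSums(ind), "/")
  out <- t(tensor$values[genes, , drop = FALSE] %*% ind)
  rownames(out) <- tensor$conditions$condition_id
  colnames(out) <- genes
  out
}

#' Mean expression of one gene in one condition
#'
#' Arithmetic mean of the replicate values of gene `gene` in condition
#' `condition`.
#'
#' @param tensor an `expr_tensor`.
#' @param gene gene id.
#' @param condition condition id (see `tensor$conditions$condition_id`).
#' @return scalar mean.
#' @export
replicate_mean <- function(tensor, gene, condition) {
  stopifnot(gene %in% tensor$gene_ids,
            condition %in% tensor$conditions$condition_id)
  mean(tensor$values[gene, tensor$meta$condition_id == condition])
}

#' Mean expression of one gene over a whole series
#'
#' Mean over all replicates and all timepoints of one cultivar x vintage
#' series; equals the mean of the per-condition replicate means because
#' every condition carries the same replicate count.
#'
#' @param tensor an `expr_tensor`.
#' @param gene gene id.
#' @param series series key `"cultivar|vintage"`.
#' @return scalar mean.
#' @export
series_mean <- function(tensor, gene, series) {
  stopifnot(gene %in% tensor$gene_ids)
  sel <- paste(tensor$meta$cultivar, tensor$meta$vintage, sep = "|") == series
  if (!any(sel)) stop("empty series: ", series)
  mean(tensor$values[gene, sel])
}

#' Replicate coefficient of variation
#'
#' Sample standard deviation of the replicate values divided by their mean.
#' Undefined (returned as `NA`) when the replicate mean is zero; such
#' conditions are excluded from downstream CV averages.
#'
#' @inheritParams replicate_mean
#' @return scalar CV, or `NA_real_` for a zero-mean condition.
#' @export
replicate_cv <- function(tensor, gene, condition) {
  stopifnot(gene %in% tensor$gene_ids,
            condition %in% tensor$conditions$condition_id)
  x <- tensor$values[gene, tensor$meta$condition_id == condition]
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' All replicate CVs as a conditions x genes matrix
#'
#' Vectorized form of [replicate_cv()] over every gene and condition.
#'
#' @param tensor an `expr_tensor`.
#' @param genes optional gene subset.
#' @return conditions x genes matrix; `NA` where the replicate mean is 0.
#' @export
replicate_cv_matrix <- function(tensor, genes = tensor$gene_ids) {
  grp <- factor(tensor$meta$condition_id, levels = tensor$conditions$condition_id)
  ind <- stats::model.matrix(~ 0 + grp)
  n <- colSums(ind)
  indm <- sweep(ind, 2, n, "/")
  v <- tensor$values[genes, , drop = FALSE]
  m <- v %*% indm                       # genes x conditions means
  m2 <- (v * v) %*% indm                # mean of squares
  # sample variance from moments: n/(n-1) * (E[x^2] - E[x]^2)
  nn <- matrix(n, nrow = nrow(m), ncol = ncol(m), byrow = TRUE)
  s2 <- pmax(m2 - m * m, 0) * nn / (nn - 1)
  # cancellation floor: identical replicates must yield exactly 0
  s2[s2 <= 1e-12 * m * m] <- 0
  cv <- sqrt(s2) / m
  cv[m == 0] <- NA_real_
  out <- t(cv)
  rownames(out) <- tensor$conditions$condition_id
  colnames(out) <- genes
  out
}
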