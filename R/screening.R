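#' Screening configuration
#'
#' Thresholds for the four core-set filters of [screen_genes()]. The
#' filter families mirror what transcriptome screening for developmental
#' staging needs — expression presence, replicate noise, cross-series
#' consistency and external-panel congruence — with thresholds exposed as
#' explicit, configurable package defaults.
#'
#' @param min_mean_expr minimum replicate-mean expression (RPKM-like)
#'   required in at least one condition of *every* series (default 1.0).
#' @param max_replicate_cv maximum median replicate CV across conditions
#'   (default 0.8).
#' @param min_cross_series_corr minimum pairwise Pearson correlation of
#'   the smoothed per-series profiles on a common ordinal grid
#'   (default 0.6).
#' @param min_reference_corr minimum mean Pearson correlation with the
#'   reference-panel stage profiles (default 0.5).
#' @param require_reference_panel error if no reference panel is supplied
#'   (default FALSE).
#' @return object of class `screening_config`.
#' @export
screening_config <- function(min_mean_expr = 1.0, max_replicate_cv = 0.8,
                             min_cross_series_corr = 0.6,
                             min_reference_corr = 0.5,
                             require_reference_panel = FALSE) {
  stopifnot(is.finite(min_mean_expr), min_mean_expr >= 0,
            is.finite(max_replicate_cv), max_replicate_cv > 0,
            is.finite(min_cross_series_corr),
            min_cross_series_corr >= -1, min_cross_series_corr <= 1,
            is.finite(min_reference_corr),
            min_reference_corr >= -1, min_reference_corr <= 1)
  structure(list(min_mean_expr = min_mean_expr,
                 max_replicate_cv = max_replicate_cv,
                 min_cross_series_corr = min_cross_series_corr,
                 min_reference_corr = min_reference_corr,
                 require_reference_panel = isTRUE(require_reference_panel)),
            class = "screening_config")
}

#' Screen genes to the development-associated core set
#'
#' Reduces the transcriptome to the core set F of genes with consistent,
#' development-associated expression. Filters are applied in a fixed
#' order and each rejected gene carries the tag of the first filter it
#' failed:
#'
#' * `no_expression` — replicate-mean expression never reaches
#'   `min_mean_expr` in some series;
#' * `noisy_replicates` — median replicate CV across conditions exceeds
#'   `max_replicate_cv`;
#' * `inconsistent_series` — minimum pairwise Pearson correlation of the
#'   LOESS-smoothed per-series profiles, linearly interpolated to a
#'   common ordinal grid, below `min_cross_series_corr`;
#' * `reference_discordant` — with a reference panel: mean Pearson
#'   correlation between the gene's reference stage profiles and its
#'   training mean profile resampled to the panel's stage count below
#'   `min_reference_corr`.
#'
#' @param tensor training `expr_tensor`.
#' @param reference optional reference `expr_tensor` (several cultivars x
#'   few ordered stages, single vintage) for the congruence filter.
#' @param cfg a [screening_config()].
#' @return list with `core` (ordered retained gene ids) and `report`
#'   (data.frame `gene_id`, `reason`; reason `"retained"` for core
#'   genes).
#' @export
screen_genes <- function(tensor, reference = NULL, cfg = screening_config()) {
  stopifnot(inherits(cfg, "screening_config"))
  if (cfg$require_reference_panel && is.null(reference))
    stop("screening config requires a reference panel")
  genes <- tensor$gene_ids
  reason <- rep(NA_character_, length(genes))
  names(reason) <- genes
  series <- condition_series(tensor)

  # (a) expression presence in every series
  cm <- condition_means(tensor)                    # conditions x genes
  present <- rep(TRUE, length(genes))
  for (h in unique(series)) {
    maxexpr <- apply(cm[series == h, , drop = FALSE], 2, max)
    present <- present & (maxexpr >= cfg$min_mean_expr)
  }
  reason[!present] <- "no_expression"

  # (b) replicate noise
  cvm <- replicate_cv_matrix(tensor)               # conditions x genes, NA at 0-mean
  med_cv <- apply(cvm, 2, stats::median, na.rm = TRUE)
  noisy <- is.na(reason) & (is.na(med_cv) | med_cv > cfg$max_replicate_cv)
  reason[noisy] <- "noisy_replicates"

  # (c) cross-series consistency of smoothed profiles on a common grid
  alive <- genes[is.na(reason)]
  if (length(alive)) {
    sm <- smooth_dataset(tensor, alive)
    grid_n <- min(10L, min(table(series)))
    profiles <- series_profiles_on_grid(sm, tensor, grid_n)
    min_corr <- min_pairwise_corr(profiles)
    bad <- alive[is.na(min_corr) | min_corr < cfg$min_cross_series_corr]
    reason[bad] <- "inconsistent_series"
  }

  # (d) reference-panel congruence
  alive <- genes[is.na(reason)]
  if (!is.null(reference) && length(alive)) {
    shared <- intersect(alive, reference$gene_ids)
    if (!length(intersect(genes, reference$gene_ids)))
      stop("reference panel gene ids disjoint from the training tensor")
    n_stages <- max(reference$conditions$timepoint)
    if (n_stages < 3)
      stop("reference panel has fewer than 3 stages; ",
           "congruence filter is undefined")
    ref_corr <- reference_congruence(tensor, reference, shared, n_stages)
    bad <- shared[is.na(ref_corr) | ref_corr < cfg$min_reference_corr]
    reason[bad] <- "reference_discordant"
    # alive genes absent from the reference cannot be checked; they pass
  }

  reason[is.na(reason)] <- "retained"
  list(core = genes[reason == "retained"],
       report = data.frame(gene_id = genes, reason = unname(reason),
                           stringsAsFactors = FALSE))
}

# per-series smoothed profiles linearly interpolated to a common ordinal
# grid; returns list of series -> grid x genes matrices
series_profiles_on_grid <- function(sm, tensor, grid_n) {
  series <- condition_series(tensor)
  out <- list()
  for (h in unique(series)) {
    rows <- series == h
    tp <- tensor$conditions$timepoint[rows]
    grid <- seq(1, max(tp), length.out = grid_n)
    out[[h]] <- apply(sm[rows, , drop = FALSE], 2, function(y)
      stats::approx(tp, y, xout = grid, ties = "ordered")$y)
  }
  out
}

# minimum pairwise Pearson correlation across series, per gene
min_pairwise_corr <- function(profiles) {
  hs <- names(profiles)
  n_genes <- ncol(profiles[[1]])
  min_corr <- rep(Inf, n_genes)
  for (a in seq_along(hs)) for (b in seq_along(hs)) {
    if (a >= b) next
    r <- suppressWarnings(
      colSums(scale(profiles[[hs[a]]]) * scale(profiles[[hs[b]]])) /
        (nrow(profiles[[1]]) - 1))
    r[!is.finite(r)] <- NA_real_
    min_corr <- pmin(min_corr, r, na.rm = FALSE)
  }
  min_corr
}

# mean Pearson correlation between each reference cultivar's stage
# profile and the training mean profile resampled to n_stages
reference_congruence <- function(tensor, reference, genes, n_stages) {
  if (!length(genes)) return(numeric(0))
  # training profile: mean over series of per-series profiles resampled
  # to n_stages equally spaced ordinal positions
  cm <- condition_means(tensor, genes)
  series <- condition_series(tensor)
  acc <- 0
  for (h in unique(series)) {
    rows <- series == h
    tp <- tensor$conditions$timepoint[rows]
    grid <- seq(1, max(tp), length.out = n_stages)
    acc <- acc + apply(cm[rows, , drop = FALSE], 2, function(y)
      stats::approx(tp, y, xout = grid, ties = "ordered")$y)
  }
  train_prof <- acc / length(unique(series))       # n_stages x genes

  ref_cm <- condition_means(reference, genes)      # ref conditions x genes
  ref_series <- condition_series(reference)
  corrs <- matrix(NA_real_, nrow = length(unique(ref_series)),
                  ncol = length(genes))
  for (k in seq_along(unique(ref_series))) {
    h <- unique(ref_series)[k]
    prof <- ref_cm[ref_series == h, , drop = FALSE] # n_stages x genes
    corrs[k, ] <- suppressWarnings(vapply(seq_along(genes), function(g)
      stats::cor(prof[, g], train_prof[, g]), numeric(1)))
  }
  stats::setNames(colMeans(corrs, na.rm = TRUE), genes)
}
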