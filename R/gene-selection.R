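#' Gradient-boosting variable importances for one gene
#'
#' Fits gradient-boosted regression trees of replicate-level expression
#' on three covariates — cultivar, vintage (year) and molecular stage —
#' and returns the relative influence of each covariate (VIMc, VIMy,
#' VIMs), normalized to sum to 100. Observations are restricted to
#' conditions whose assigned stage is at least `s_min`, the late-development
#' window where stage-correlated markers are sought. Tree-based
#' importances are invariant to gene-wise affine rescaling of the
#' expression values. Constant expression yields all-zero importances by
#' convention.
#'
#' @param expression replicate-level expression values, one per
#'   observation.
#' @param cultivar,vintage per-observation factors.
#' @param stage per-observation molecular stage (integer).
#' @param s_min minimum stage included (default 20).
#' @param n_trees,max_depth,learning_rate,subsample boosting
#'   hyperparameters (defaults 500, 3, 0.05, 1).
#' @param seed RNG seed for the boosting fit (default 1).
#' @return named numeric vector `c(VIMc, VIMy, VIMs)` summing to 100 (or
#'   all zero for a constant gene).
#' @export
gbm_vims <- function(expression, cultivar, vintage, stage, s_min = 20L,
                     n_trees = 500L, max_depth = 3L, learning_rate = 0.05,
                     subsample = 1.0, seed = 1L) {
  keep <- stage >= s_min
  if (!any(keep)) stop("no observations with stage >= ", s_min)
  y <- as.numeric(expression[keep])
  if (sum(keep) < 10) stop("need at least 10 replicate-level observations")
  zero <- c(VIMc = 0, VIMy = 0, VIMs = 0)
  if (stats::sd(y) == 0) return(zero)
  X <- cbind(cultivar = as.numeric(factor(cultivar[keep])),
             vintage = as.numeric(factor(vintage[keep])),
             stage = as.numeric(stage[keep]))
  booster <- xgboost::xgboost(
    x = X, y = y, objective = "reg:squarederror", nrounds = n_trees,
    max_depth = max_depth, learning_rate = learning_rate,
    subsample = subsample, nthreads = 1, seed = seed, verbosity = 0)
  imp <- xgboost::xgb.importance(model = booster)
  gain <- stats::setNames(rep(0, 3), c("cultivar", "vintage", "stage"))
  gain[imp$Feature] <- imp$Gain
  if (sum(gain) == 0) return(zero)
  out <- 100 * gain / sum(gain)
  c(VIMc = unname(out["cultivar"]), VIMy = unname(out["vintage"]),
    VIMs = unname(out["stage"]))
}

#' Variable-importance table for a set of genes
#'
#' Runs [gbm_vims()] for every gene of a tensor against a stage
#' assignment, and adds the Spearman correlation between each gene's
#' standardized expression and the stage over the same window.
#'
#' @param tensor an `expr_tensor`.
#' @param stages named integer vector: stage per condition
#'   (`tensor$conditions$condition_id` names), e.g. a scale's
#'   `training_stages`.
#' @param genes gene subset (default all).
#' @param s_min minimum stage (default 20).
#' @param ... boosting hyperparameters passed to [gbm_vims()].
#' @return data.frame (class `vim_table`): `gene_id`, `VIMc`, `VIMy`,
#'   `VIMs`, `spearman_rho`.
#' @export
vim_table <- function(tensor, stages, genes = tensor$gene_ids,
                      s_min = 20L, ...) {
  stage_per_sample <- stages[tensor$meta$condition_id]
  cond_stage <- stages[tensor$conditions$condition_id]
  out <- data.frame(gene_id = genes, VIMc = NA_real_, VIMy = NA_real_,
                    VIMs = NA_real_, spearman_rho = NA_real_,
                    stringsAsFactors = FALSE)
  cm <- condition_means(tensor, genes)
  for (i in seq_along(genes)) {
    v <- gbm_vims(tensor$values[genes[i], ], tensor$meta$cultivar,
                  tensor$meta$vintage, stage_per_sample, s_min = s_min, ...)
    out$VIMc[i] <- v["VIMc"]; out$VIMy[i] <- v["VIMy"]; out$VIMs[i] <- v["VIMs"]
    out$spearman_rho[i] <- stage_spearman(cm[, i], cond_stage,
                                          interval = c(s_min, max(cond_stage)))
  }
  class(out) <- c("vim_table", "data.frame")
  out
}

#' Select stage-associated genes by importance quantiles
#'
#' Keeps genes whose cultivar importance is at most the `q_c` quantile of
#' VIMc, vintage importance at most the `q_y` quantile of VIMy, and stage
#' importance at least the `q_s` quantile of VIMs (boundaries inclusive;
#' linear-interpolation quantiles, type 7).
#'
#' @param vims a `vim_table`.
#' @param q_c,q_y,q_s quantile levels (defaults 0.10, 0.20, 0.20).
#' @return character vector of selected gene ids (possibly empty, with a
#'   warning).
#' @export
select_stage_genes <- function(vims, q_c = 0.10, q_y = 0.20, q_s = 0.20) {
  thr_c <- stats::quantile(vims$VIMc, q_c, type = 7, names = FALSE)
  thr_y <- stats::quantile(vims$VIMy, q_y, type = 7, names = FALSE)
  thr_s <- stats::quantile(vims$VIMs, q_s, type = 7, names = FALSE)
  sel <- vims$gene_id[vims$VIMc <= thr_c & vims$VIMy <= thr_y &
                        vims$VIMs >= thr_s]
  if (!length(sel)) warning("no genes pass the importance-quantile criteria")
  sel
}

#' Spearman correlation between expression and stage on an interval
#'
#' Rank correlation (ties mid-ranked) between a gene's per-condition
#' expression and the assigned molecular stage, restricted to conditions
#' whose stage lies in `interval`.
#'
#' @param expression per-condition expression values.
#' @param stages per-condition stages, same length.
#' @param interval inclusive stage interval `c(a, b)`.
#' @return Spearman's rho.
#' @export
stage_spearman <- function(expression, stages, interval) {
  keep <- stages >= interval[1] & stages <= interval[2]
  if (sum(keep) < 3) stop("fewer than 3 conditions in the stage interval")
  suppressWarnings(stats::cor(expression[keep], stages[keep],
                              method = "spearman"))
}

#' Build reduced core-set panels from component loadings
#'
#' Constructs marker panels of the requested sizes from the genes most
#' correlated with the three selected components. Per gene and component,
#' `p-corr` is the Pearson correlation between the gene's standardized
#' smoothed profile and the component score vector. About `n_candidates`
#' genes — the highest and lowest correlators with each of the three
#' components, in equal shares per component x sign — are hierarchically
#' clustered on their profiles (distance 1 - Pearson r, average linkage,
#' cut to `n_clusters` clusters). Each
#' panel takes equal pools per component x loading sign (e.g. size 120 =
#' 3 components x 2 signs x 20 genes). Pools draw from a shortlist of the
#' top `2 x pool size` genes of the matching p-corr sign, so that cluster
#' preferences diversify among strong markers without ever admitting
#' weakly correlated ones:
#'
#' * large panels (pool size > 5): shortlisted genes from the most
#'   populated clusters first, then by absolute p-corr, then gene id;
#' * small panels (pool size <= 5): highest-|p-corr| representatives of
#'   *distinct* clusters, to avoid redundant co-expressed markers; the
#'   pool is topped up by pure |p-corr| rank when the shortlist spans
#'   fewer clusters than the pool needs;
#' * the third (lowest-variance) component's pools are ranked purely by
#'   absolute p-corr, ignoring cluster membership.
#'
#' An error is raised when the core set has fewer genes of a loading sign
#' than a pool requires. A gene never appears twice within a panel. Each
#' panel records its loading signs for [project_reduced()].
#'
#' @param scale a `scale_artifact` built by [build_scale()] (its
#'   `smoothed` and `pc_model` attributes supply profiles and scores), or
#'   pass `smoothed` and `scores` explicitly.
#' @param sizes panel sizes, each divisible by 6 (default
#'   `c(120, 60, 30, 12)`).
#' @param n_clusters dendrogram cut (default 20).
#' @param n_candidates pooled top-loading candidate count (default 100).
#' @param smoothed optional conditions x genes smoothed matrix.
#' @param scores optional conditions x 3 score matrix.
#' @return named list of `gene_panel` objects, one per size.
#' @export
select_reduced_core_sets <- function(scale, sizes = c(120, 60, 30, 12),
                                     n_clusters = 20L, n_candidates = 100L,
                                     smoothed = attr(scale, "smoothed"),
                                     scores = NULL) {
  if (is.null(smoothed))
    stop("no smoothed matrix available; pass `smoothed` explicitly")
  if (is.null(scores)) {
    model <- attr(scale, "pc_model")
    if (is.null(model)) stop("no pc_model available; pass `scores` explicitly")
    scores <- model$scores[, scale$pc_indices, drop = FALSE]
  }
  stopifnot(all(sizes %% 6 == 0))
  Z <- standardize_columns(smoothed[, scale$core_gene_ids, drop = FALSE])$Z

  # p-corr: genes x 3 correlation with the three score vectors
  pcorr <- stats::cor(Z, scores)
  rownames(pcorr) <- scale$core_gene_ids
  # candidate list balanced across component x sign groups: the genes
  # with the highest and lowest correlation values with each of the
  # three dimensions (a pooled ranking would be monopolized by the
  # dominant component)
  per_group <- ceiling(n_candidates / 6)
  cand <- character(0)
  for (q in 1:3) for (sgn in c(1, -1)) {
    grp <- scale$core_gene_ids[sign(pcorr[, q]) == sgn]
    grp <- grp[order(-abs(pcorr[grp, q]), grp)]
    cand <- union(cand, utils::head(grp, per_group))
  }

  # cluster candidate profiles: 1 - Pearson distance, average linkage
  cor_mat <- stats::cor(Z[, cand, drop = FALSE])
  hc <- stats::hclust(stats::as.dist(1 - cor_mat), method = "average")
  cl <- stats::cutree(hc, k = min(n_clusters, length(cand)))
  cl_size <- table(cl)

  all_genes <- scale$core_gene_ids
  panels <- list()
  for (size in sizes) {
    pool_n <- size / 6
    chosen <- character(0)
    for (q in 1:3) {
      for (sgn in c(1, -1)) {
        ranked <- all_genes[sign(pcorr[, q]) == sgn & !(all_genes %in% chosen)]
        ranked <- ranked[order(-abs(pcorr[ranked, q]), ranked)]
        if (length(ranked) < pool_n)
          stop("pool for component ", q, " sign ", sgn, " has only ",
               length(ranked), " candidates; ", pool_n, " requested")
        short <- utils::head(ranked, 2 * pool_n)
        clu <- ifelse(short %in% cand, cl[short], NA_integer_)
        if (q == 3) {
          # third component: pure |p-corr| ranking
          picks <- short
        } else if (pool_n > 5) {
          sz <- ifelse(is.na(clu), 0L, as.integer(cl_size[as.character(clu)]))
          picks <- short[order(-sz, -abs(pcorr[short, q]), short)]
        } else {
          picks <- character(0); used_cl <- integer(0)
          for (i in seq_along(short)) {
            if (!is.na(clu[i]) && clu[i] %in% used_cl) next
            picks <- c(picks, short[i])
            if (!is.na(clu[i])) used_cl <- c(used_cl, clu[i])
            if (length(picks) == pool_n) break
          }
          picks <- c(picks, setdiff(short, picks))
        }
        chosen <- c(chosen, picks[seq_len(pool_n)])
      }
    }
    signs <- sign(scale$eigenvectors[chosen, , drop = FALSE])
    signs[signs == 0] <- 1
    panels[[as.character(size)]] <- gene_panel(
      chosen, signs, p_corr = pcorr[chosen, , drop = FALSE],
      provenance = sprintf(
        "top-%d loading candidates, %d clusters, %d genes per component x sign",
        n_candidates, n_clusters, pool_n))
  }
  panels
}
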