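#' Project samples with the full core gene set
#'
#' Maps an observed expression matrix onto a frozen phenology scale. The
#' observed columns are restricted to the scale's core gene set (in scale
#' order), column-standardized within the projected dataset (population
#' moments), multiplied by the eigenvector matrix A to estimate the three
#' component coordinates, and each sample is assigned to the nearest
#' stage mark (Euclidean distance, ties toward the lower stage).
#'
#' Dataset-local standardization follows the scale-construction
#' convention; it is undefined for a single sample, for which
#' `standardize = "training"` applies the scale's stored training means
#' and sds instead.
#'
#' Observed core genes with zero variance in the projected dataset cannot
#' be standardized; they are dropped with a warning and imputed through
#' the reduced-panel path. If any core gene is absent the function stops
#' and directs the caller to [project_reduced()].
#'
#' @param Z_obs numeric matrix, samples x genes, column names = gene ids
#'   (expression on the same scale as the training data, e.g. RPKM).
#' @param scale a `scale_artifact`.
#' @param standardize `"dataset"` (default) or `"training"`.
#' @return object of class `projection_result`: data.frame with columns
#'   `sample`, `stage`, `pc1`, `pc2`, `pc3` (coordinates on the three
#'   selected components, in `scale$pc_indices` order), `mark_distance`;
#'   attribute `panel_mode` is `"full"` or `"reduced"`.
#' @export
project_full <- function(Z_obs, scale, standardize = c("dataset", "training")) {
  standardize <- match.arg(standardize)
  Z_obs <- as.matrix(Z_obs)
  F_set <- scale$core_gene_ids
  missing <- setdiff(F_set, colnames(Z_obs))
  if (length(missing))
    stop(length(missing), " core gene(s) absent from the observed matrix ",
         "(e.g. ", paste(utils::head(missing, 3), collapse = ", "),
         "); use project_reduced() with a gene panel")
  Z <- Z_obs[, F_set, drop = FALSE]
  std <- standardize_obs(Z, scale, standardize)
  degenerate <- std$degenerate
  if (length(degenerate) == ncol(Z)) {
    # every column constant within the dataset: centered values are all
    # exactly zero and the scale carries no information, so the samples
    # sit at the origin of the component space
    warning("all observed columns have zero variance; ",
            "samples mapped to the stage mark nearest the origin")
    Y <- matrix(0, nrow = nrow(Z), ncol = 3)
    return(assemble_projection(Y, scale, rownames(Z_obs), "full"))
  }
  if (length(degenerate)) {
    warning(length(degenerate), " zero-variance core gene(s) dropped and ",
            "imputed by loading sign (e.g. ",
            paste(utils::head(degenerate, 3), collapse = ", "), ")")
    panel <- panel_from_scale(scale, setdiff(F_set, degenerate))
    return(project_reduced(Z[, setdiff(F_set, degenerate), drop = FALSE],
                           panel, scale, standardize = standardize))
  }
  Y <- std$Z %*% scale$eigenvectors
  res <- assemble_projection(Y, scale, rownames(Z_obs), "full")
  res
}

#' Project samples observed on a reduced gene panel
#'
#' Maps samples observed on a small subset of the core gene set onto the
#' scale by loading-sign imputation. The observed panel columns are
#' standardized within the projected dataset; then, for each selected
#' component q, every unobserved core gene is imputed with the sample's
#' average standardized expression over the observed genes whose
#' eigenvector coefficient on component q has the matching sign (positive
#' average for positive-loading genes, negative average for
#' negative-loading genes). The imputed samples x |F| matrix for
#' component q is multiplied by the q-th eigenvector column; the three
#' coordinates are stacked and samples are assigned to the nearest stage
#' mark as in [project_full()].
#'
#' With the panel equal to the full core set no value is imputed and the
#' result equals [project_full()] exactly.
#'
#' @param Z_obs numeric matrix, samples x panel genes.
#' @param panel a `gene_panel` whose genes are a subset of the scale's
#'   core set, with loading signs for each selected component.
#' @param scale a `scale_artifact`.
#' @param standardize `"dataset"` (default) or `"training"`.
#' @return a `projection_result` (see [project_full()]),
#'   `panel_mode = "reduced"` (or `"full"` when the panel is the whole
#'   core set).
#' @export
project_reduced <- function(Z_obs, panel, scale,
                            standardize = c("dataset", "training")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(panel, "gene_panel"), inherits(scale, "scale_artifact"))
  F_set <- scale$core_gene_ids
  if (!all(panel$gene_ids %in% F_set))
    stop("panel contains gene(s) outside the scale's core set")
  Z_obs <- as.matrix(Z_obs)
  missing_obs <- setdiff(panel$gene_ids, colnames(Z_obs))
  if (length(missing_obs))
    stop("panel gene(s) absent from observed matrix: ",
         paste(utils::head(missing_obs, 3), collapse = ", "))
  obs <- panel$gene_ids
  Z <- Z_obs[, obs, drop = FALSE]
  std <- standardize_obs(Z, scale, standardize)
  if (length(std$degenerate)) {
    keep <- setdiff(obs, std$degenerate)
    warning(length(std$degenerate), " zero-variance panel gene(s) dropped")
    panel <- gene_panel(keep, panel$loading_signs[keep, , drop = FALSE],
                        provenance = panel$provenance)
    obs <- keep
    std$Z <- std$Z[, keep, drop = FALSE]
  }
  Zs <- std$Z
  n <- nrow(Zs)

  A <- scale$eigenvectors
  hidden <- setdiff(F_set, obs)
  if (!length(hidden)) {
    # nothing to impute: identical arithmetic to project_full
    Y <- Zs %*% A[obs, , drop = FALSE]
    return(assemble_projection(Y, scale, rownames(Z_obs), "full"))
  }
  Y <- matrix(0, nrow = n, ncol = 3)
  for (q in 1:3) {
    signs <- panel$loading_signs[obs, q]
    if (length(hidden) && !(any(signs > 0) && any(signs < 0)))
      stop("panel not sign-balanced for PC ", scale$pc_indices[q])
    pos_mean <- rowMeans(Zs[, obs[signs > 0], drop = FALSE])
    neg_mean <- rowMeans(Zs[, obs[signs < 0], drop = FALSE])
    # observed contribution
    y <- Zs %*% A[obs, q]
    if (length(hidden)) {
      a_hidden <- A[hidden, q]
      pos_load <- sum(a_hidden[a_hidden >= 0])
      neg_load <- sum(a_hidden[a_hidden < 0])
      y <- y + pos_mean * pos_load + neg_mean * neg_load
    }
    Y[, q] <- y
  }
  mode <- if (length(hidden)) "reduced" else "full"
  assemble_projection(Y, scale, rownames(Z_obs), mode)
}

# standardize observed columns; returns Z (finite columns) + degenerate ids
standardize_obs <- function(Z, scale, standardize) {
  if (standardize == "training") {
    ids <- colnames(Z)
    Zs <- sweep(sweep(Z, 2, scale$column_means[ids]), 2,
                scale$column_sds[ids], "/")
    return(list(Z = Zs, degenerate = character(0)))
  }
  if (nrow(Z) < 2)
    stop("dataset-local standardization is undefined for a single sample; ",
         "use standardize = \"training\"")
  means <- colMeans(Z)
  sds <- sqrt(colMeans(sweep(Z, 2, means)^2))
  degenerate <- colnames(Z)[sds == 0]
  keep <- sds > 0
  Zs <- sweep(sweep(Z[, keep, drop = FALSE], 2, means[keep]), 2,
              sds[keep], "/")
  list(Z = Zs, degenerate = degenerate)
}

# build the gene_panel implied by a scale restricted to `genes`
panel_from_scale <- function(scale, genes) {
  signs <- sign(scale$eigenvectors[genes, , drop = FALSE])
  signs[signs == 0] <- 1
  gene_panel(genes, signs, provenance = "restriction of the full core set")
}

assemble_projection <- function(Y, scale, sample_ids, mode) {
  asg <- nearest_mark(Y, scale$marks)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(Y)))
  res <- data.frame(sample = sample_ids, stage = asg$stage,
                    pc1 = Y[, 1], pc2 = Y[, 2], pc3 = Y[, 3],
                    mark_distance = asg$distance,
                    stringsAsFactors = FALSE)
  attr(res, "panel_mode") <- mode
  class(res) <- c("projection_result", "data.frame")
  res
}

#' Project an expression tensor's condition means
#'
#' Convenience wrapper: averages replicates per condition and projects
#' the conditions x genes matrix with [project_full()].
#'
#' @param tensor an `expr_tensor` containing the scale's core genes.
#' @param scale a `scale_artifact`.
#' @param ... passed to [project_full()].
#' @return a `projection_result`, one row per condition.
#' @export
project_tensor <- function(tensor, scale, ...) {
  M <- condition_means(tensor, intersect(tensor$gene_ids, scale$core_gene_ids))
  project_full(M, scale, ...)
}
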