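#' Column standardization with population moments
#'
#' Centers each column to mean 0 and scales to standard deviation 1 using
#' the population standard deviation (denominator n). Standardization with
#' population moments keeps the PCA eigendecomposition identical to that
#' of the correlation matrix of the input.
#'
#' @param M numeric matrix (rows = conditions/samples, cols = genes).
#' @return list with `Z` (standardized matrix), `means`, `sds`.
#' @export
standardize_columns <- function(M) {
  M <- as.matrix(M)
  means <- colMeans(M)
  sds <- sqrt(colMeans(sweep(M, 2, means)^2))
  if (any(sds == 0)) {
    bad <- colnames(M)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance column(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  Z <- sweep(sweep(M, 2, means), 2, sds, "/")
  list(Z = Z, means = means, sds = sds)
}

#' Principal component analysis of a standardized matrix
#'
#' Singular value decomposition of the standardized conditions x genes
#' matrix. Explained variance percentages are the squared singular values
#' as a share of their total. Each component's sign is oriented so that
#' its score sequence correlates non-negatively (Spearman, pooled across
#' series) with the timepoint order, making "later development" the
#' positive direction wherever a component tracks development at all.
#'
#' @param Z standardized matrix from [standardize_columns()].
#' @param n_pcs number of components to retain (default 6).
#' @param timepoints optional per-row timepoint vector used for sign
#'   orientation; unoriented if omitted.
#' @return object of class `pc_model`: list with `eigenvectors`
#'   (genes x n_pcs), `scores` (conditions x n_pcs),
#'   `explained_variance_pct`, `column_means`, `column_sds` (carried from
#'   attributes if present), `factor_assoc` (filled by
#'   [triage_components()]).
#' @export
fit_pca <- function(Z, n_pcs = 6L, timepoints = NULL) {
  Z <- as.matrix(Z)
  if (n_pcs > min(dim(Z)))
    stop("n_pcs exceeds min(rows, cols) of the matrix")
  sv <- svd(Z)
  expl <- 100 * sv$d^2 / sum(sv$d^2)
  V <- sv$v[, seq_len(n_pcs), drop = FALSE]
  scores <- Z %*% V
  if (!is.null(timepoints)) {
    for (q in seq_len(n_pcs)) {
      rho <- suppressWarnings(
        stats::cor(scores[, q], timepoints, method = "spearman"))
      if (!is.na(rho) && rho < 0) {
        V[, q] <- -V[, q]
        scores[, q] <- -scores[, q]
      }
    }
  }
  rownames(V) <- colnames(Z)
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- rownames(Z)
  structure(list(eigenvectors = V, scores = scores,
                 explained_variance_pct = expl[seq_len(n_pcs)],
                 singular_values = sv$d,
                 factor_assoc = NULL),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("<pc_model> ", ncol(x$scores), " components, explained variance: ",
      paste(sprintf("%.1f%%", x$explained_variance_pct), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$factor_assoc))
    cat("  association:", paste(x$factor_assoc$label, collapse = ", "), "\n")
  invisible(x)
}

#' Associate principal components with experimental factors
#'
#' Attributes each component to the factor that dominates its score
#' variation: eta-squared (between-group share of variance) for cultivar
#' and vintage; for developmental stage, the R-squared of a single cubic
#' polynomial in the within-series normalized timepoint shared across all
#' series. A shared smooth time profile captures non-monotone stage
#' components (the second stage component is typically U-shaped over
#' development, which a pooled rank correlation would miss), while
#' cultivar- or vintage-driven components, whose series differ by offsets
#' rather than by a common time course, score near zero. A component is
#' labelled by its largest effect when the margin over the runner-up is
#' at least `margin`, otherwise "mixed". The default component selection
#' for scale building is the three stage-labelled components ranked by
#' explained variance.
#'
#' @param model a `pc_model`.
#' @param conditions condition table with `cultivar`, `vintage`,
#'   `timepoint` (one row per score row).
#' If fewer than three components earn the "stage" label outright, the
#' remaining slots are filled by "mixed" components whose *largest*
#' effect is nonetheless stage (weak stage components exist in real
#' data: the third stage component typically explains only a few percent
#' of variance). Only when that still leaves fewer than three candidates
#' does selection fail, with advice to set `pc_indices` manually.
#'
#' @param margin required dominance margin on the effect-size scale
#'   (default 0.1).
#' @param select if `TRUE` (default), also pick the three stage
#'   components into `stage_pcs`, erroring when impossible; `FALSE`
#'   computes labels only.
#' @return the model with `factor_assoc` (data.frame: per-PC effect sizes
#'   and label) and, when `select = TRUE`, `stage_pcs` (indices of the
#'   three stage components, by descending explained variance).
#' @export
triage_components <- function(model, conditions, margin = 0.1,
                              select = TRUE) {
  stopifnot(inherits(model, "pc_model"))
  n_pcs <- ncol(model$scores)
  eta2 <- function(x, g) {
    g <- factor(g)
    gm <- tapply(x, g, mean)
    ss_b <- sum(tabulate(g) * (gm - mean(x))^2)
    ss_t <- sum((x - mean(x))^2)
    if (ss_t == 0) 0 else ss_b / ss_t
  }
  tp <- conditions$timepoint
  series <- paste(conditions$cultivar, conditions$vintage, sep = "|")
  max_tp <- stats::ave(tp, series, FUN = max)
  t_norm <- ifelse(max_tp > 1, (tp - 1) / (max_tp - 1), 0)
  poly_df <- min(3L, length(unique(t_norm)) - 1L)
  assoc <- data.frame(pc = seq_len(n_pcs), stage = NA_real_,
                      cultivar = NA_real_, vintage = NA_real_,
                      label = NA_character_)
  for (q in seq_len(n_pcs)) {
    s <- model$scores[, q]
    assoc$cultivar[q] <- eta2(s, conditions$cultivar)
    assoc$vintage[q] <- eta2(s, conditions$vintage)
    assoc$stage[q] <- if (poly_df < 1 || stats::sd(s) == 0) 0 else
      summary(stats::lm(s ~ stats::poly(t_norm, poly_df)))$r.squared
    eff <- c(stage = assoc$stage[q], cultivar = assoc$cultivar[q],
             vintage = assoc$vintage[q])
    top <- sort(eff, decreasing = TRUE)
    assoc$label[q] <- if (top[1] - top[2] >= margin) names(top)[1] else "mixed"
  }
  model$factor_assoc <- assoc
  if (!select) return(model)
  stage_pcs <- assoc$pc[assoc$label == "stage"]
  if (length(stage_pcs) < 3) {
    # fall back on mixed components dominated by the stage effect
    stage_dom <- assoc$pc[assoc$label == "mixed" &
                            assoc$stage > pmax(assoc$cultivar, assoc$vintage)]
    stage_dom <- stage_dom[order(assoc$stage[stage_dom], decreasing = TRUE)]
    stage_pcs <- c(stage_pcs, stage_dom)
  }
  if (length(stage_pcs) < 3)
    stop("fewer than three stage-associated components found; ",
         "set `pc_indices` explicitly")
  stage_pcs <- stage_pcs[1:3]
  ord <- order(model$explained_variance_pct[stage_pcs], decreasing = TRUE)
  model$stage_pcs <- stage_pcs[ord]
  model
}

# Bernstein basis matrix: length(t) x k for a Bezier curve of order k
# (k control points, polynomial degree k - 1)
bernstein_basis <- function(t, k) {
  d <- k - 1
  outer(t, 0:d, function(tt, j) choose(d, j) * tt^j * (1 - tt)^(d - j))
}

#' Evaluate a Bezier curve
#'
#' @param curve a `bezier_curve` (or a k x 3 control-point matrix).
#' @param t parameter values in [0, 1].
#' @return length(t) x 3 matrix of curve points.
#' @export
bezier_points <- function(curve, t) {
  cp <- if (inherits(curve, "bezier_curve")) curve$control_points else as.matrix(curve)
  bernstein_basis(t, nrow(cp)) %*% cp
}

#' Fit a Bezier curve to a 3D point scatter
#'
#' Least-squares fit of an order-k Bezier curve (k control points, degree
#' k - 1) to points with known ordering. Initial curve parameters place
#' each point at its normalized position in its own time series,
#' `(timepoint - 1) / (max timepoint of the series - 1)`; control points
#' solve the linear least-squares problem on the Bernstein basis. The
#' parameters are then refined by foot-point correction: each point is
#' re-assigned the parameter of its nearest point on a dense sampling of
#' the current curve and the control points are re-solved. The iterate
#' with the smallest summed squared residual is returned. The procedure
#' is deterministic and seed-free.
#'
#' @param points n x 3 matrix of PC coordinates.
#' @param init_t initial curve parameter per point, in [0, 1].
#' @param k curve order = number of control points (default 5).
#' @param refine_iters foot-point refinement rounds (default 2).
#' @param dense_n number of curve samples used for foot-point search
#'   (default 2001).
#' @return object of class `bezier_curve`: list with `control_points`
#'   (k x 3), `t` (final per-point parameters), `rss`.
#' @export
fit_bezier <- function(points, init_t, k = 5L, refine_iters = 2L,
                       dense_n = 2001L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 2) stop("curve order k must be at least 2")
  if (n < k) stop("need at least k points")
  if (all(apply(points, 2, function(x) diff(range(x)) == 0)))
    stop("degenerate scatter: all points identical")
  stopifnot(length(init_t) == n, all(init_t >= 0 & init_t <= 1))

  solve_cp <- function(t) {
    B <- bernstein_basis(t, k)
    qr.solve(B, points)                  # least squares via QR
  }
  rss_of <- function(t, cp) sum((bernstein_basis(t, k) %*% cp - points)^2)

  t_cur <- init_t
  cp <- solve_cp(t_cur)
  best <- list(cp = cp, t = t_cur, rss = rss_of(t_cur, cp))
  if (refine_iters > 0) {
    t_grid <- seq(0, 1, length.out = dense_n)
    for (it in seq_len(refine_iters)) {
      dense <- bezier_points(cp, t_grid)
      # nearest dense sample per data point
      d2 <- outer(rowSums(points^2), rowSums(dense^2), "+") -
        2 * points %*% t(dense)
      t_cur <- t_grid[max.col(-d2, ties.method = "first")]
      cp <- solve_cp(t_cur)
      rss <- rss_of(t_cur, cp)
      if (rss < best$rss) best <- list(cp = cp, t = t_cur, rss = rss)
    }
  }
  structure(list(control_points = unname(best$cp), t = best$t,
                 rss = best$rss),
            class = "bezier_curve")
}

#' Place evenly spaced marks along a Bezier curve
#'
#' Computes arc length on a dense polyline sampling of the curve and
#' places `n_marks` marks at equal arc-length fractions 0, 1/(n-1), ...,
#' 1, so that consecutive marks are separated by equal distance along the
#' curve (a linear graduation).
#'
#' @param curve a `bezier_curve`.
#' @param n_marks number of marks (default 30).
#' @param dense_n polyline resolution for arc-length quadrature
#'   (default 10001).
#' @return n_marks x 3 matrix of mark coordinates; attribute `t` carries
#'   the curve parameters of the marks.
#' @export
place_marks <- function(curve, n_marks = 30L, dense_n = 10001L) {
  if (n_marks < 2) stop("n_marks must be at least 2")
  t_grid <- seq(0, 1, length.out = dense_n)
  dense <- bezier_points(curve, t_grid)
  seg <- sqrt(rowSums(diff(dense)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  targets <- seq(0, total, length.out = n_marks)
  # invert the (monotone) arc-length table by linear interpolation
  t_marks <- stats::approx(arc, t_grid, xout = targets, ties = "ordered")$y
  marks <- bezier_points(curve, t_marks)
  attr(marks, "t") <- t_marks
  marks
}

#' Assign points to their nearest stage mark
#'
#' @param Y n x 3 coordinates.
#' @param marks n_marks x 3 mark coordinates.
#' @return list with `stage` (integer, ties broken toward the lower
#'   stage) and `distance` (Euclidean distance to the assigned mark).
#' @keywords internal
nearest_mark <- function(Y, marks) {
  Y <- matrix(as.numeric(Y), ncol = ncol(marks))
  d2 <- outer(rowSums(Y^2), rowSums(marks^2), "+") - 2 * Y %*% t(marks)
  d2 <- pmax(d2, 0)
  stage <- apply(d2, 1, which.min)     # which.min takes the first (lowest) tie
  list(stage = as.integer(stage),
       distance = sqrt(d2[cbind(seq_len(nrow(Y)), stage)]))
}

#' Build a molecular phenology scale from a training tensor
#'
#' End-to-end scale construction: series-local LOESS smoothing of the
#' core genes, column standardization (population moments), PCA with
#' development-oriented signs, selection of the three stage-associated
#' components (automatic triage or explicit `pc_indices`), Bezier fit of
#' the conditions x 3 score scatter, and arc-length graduation into
#' `n_marks` stages. The scale is oriented so that stage 1 is the
#' earliest-development end (pooled correlation of assigned stage with
#' timepoint is non-negative); each training condition's assigned stage
#' is stored in the artifact.
#'
#' @param tensor training `expr_tensor`.
#' @param core_genes the core gene set F (default: all genes of the
#'   tensor; normally the output of [screen_genes()]).
#' @param n_pcs components to extract (default 6).
#' @param pc_indices explicit stage components, or `NULL` for automatic
#'   triage (default `NULL`).
#' @param k Bezier curve order (number of control points, default 5).
#' @param n_marks number of scale marks (default 30).
#' @param degree,span LOESS parameters (defaults 2, 0.75).
#' @param refine_iters,dense_samples Bezier refinement rounds and
#'   arc-length sampling resolution.
#' @return a `scale_artifact`; attributes `pc_model` and `bezier` expose
#'   the intermediate fits.
#' @export
build_scale <- function(tensor, core_genes = tensor$gene_ids,
                        n_pcs = 6L, pc_indices = NULL, k = 5L,
                        n_marks = 30L, degree = 2L, span = 0.75,
                        refine_iters = 2L, dense_samples = 10001L) {
  sm <- smooth_dataset(tensor, core_genes, degree = degree, span = span)
  std <- standardize_columns(sm)
  tp <- tensor$conditions$timepoint
  model <- fit_pca(std$Z, n_pcs = n_pcs, timepoints = tp)
  if (is.null(pc_indices)) {
    # strong genotype/vintage structure can push the third stage
    # component below rank n_pcs; widen the pool until triage succeeds
    repeat {
      triaged <- tryCatch(triage_components(model, tensor$conditions),
                          error = function(e) e)
      if (!inherits(triaged, "error")) break
      if (n_pcs >= min(dim(std$Z))) stop(triaged)
      n_pcs <- min(2L * n_pcs, min(dim(std$Z)))
      model <- fit_pca(std$Z, n_pcs = n_pcs, timepoints = tp)
    }
    model <- triaged
    pc_indices <- model$stage_pcs
  } else {
    model <- tryCatch(triage_components(model, tensor$conditions),
                      error = function(e) model)
    pc_indices <- as.integer(pc_indices)
  }
  scores3 <- model$scores[, pc_indices, drop = FALSE]

  series <- condition_series(tensor)
  max_tp <- stats::ave(tp, series, FUN = max)
  init_t <- ifelse(max_tp > 1, (tp - 1) / (max_tp - 1), 0)
  curve <- fit_bezier(scores3, init_t, k = k, refine_iters = refine_iters)
  marks <- place_marks(curve, n_marks = n_marks, dense_n = dense_samples)

  asg <- nearest_mark(scores3, marks)
  # orient: stage 1 = earliest development
  rho <- suppressWarnings(stats::cor(asg$stage, tp, method = "spearman"))
  if (!is.na(rho) && rho < 0) {
    marks_t <- 1 - rev(attr(marks, "t"))   # reversed curve: B'(t) = B(1 - t)
    marks <- marks[rev(seq_len(n_marks)), , drop = FALSE]
    attr(marks, "t") <- marks_t
    curve$control_points <- curve$control_points[rev(seq_len(k)), , drop = FALSE]
    asg <- nearest_mark(scores3, marks)
  }

  art <- scale_artifact(
    core_gene_ids = colnames(sm),
    column_means = std$means, column_sds = std$sds,
    eigenvectors = model$eigenvectors[, pc_indices, drop = FALSE],
    pc_indices = pc_indices,
    control_points = curve$control_points,
    marks = marks, n_marks = n_marks,
    explained_variance_pct = model$explained_variance_pct[pc_indices],
    training_stages = stats::setNames(asg$stage,
                                      tensor$conditions$condition_id))
  attr(art, "pc_model") <- model
  attr(art, "bezier") <- curve
  attr(art, "smoothed") <- sm
  art
}
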