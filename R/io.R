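#' Read a replicate-level expression dataset
#'
#' Reads a tab-separated expression matrix (genes in rows, first column
#' gene id, one column per sample) and a tab-separated metadata table
#' mapping sample columns to cultivar, vintage, timepoint and replicate
#' (plus optional `doy`, `daf`), and assembles a validated
#' [expression_tensor()].
#'
#' @param path path to the expression TSV (UTF-8, '.' decimal).
#' @param meta_path path to the sample metadata TSV.
#' @param n_replicates declared replicate count (default 3).
#' @return an `expr_tensor`.
#' @export
read_expression <- function(path, meta_path, n_replicates = 3L) {
  expr <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(expr) < 2) stop("expression file must have gene id + sample columns")
  gene_ids <- as.character(expr[[1]])
  mat <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression value in ", path)
  rownames(mat) <- gene_ids
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  expression_tensor(mat, meta, n_replicates = n_replicates)
}

#' Write an expression tensor back to TSV files
#'
#' Inverse of [read_expression()]; full-precision decimal serialization so
#' that read -> write -> read round-trips values exactly.
#'
#' @param tensor an `expr_tensor`.
#' @param path output expression TSV path.
#' @param meta_path output metadata TSV path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(tensor, path, meta_path) {
  df <- data.frame(gene_id = tensor$gene_ids,
                   format_full(tensor$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- tensor$meta[, c("sample", "cultivar", "vintage", "timepoint",
                          "replicate", "doy", "daf")]
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# full-precision decimal text for doubles (round-trips via as.numeric)
format_full <- function(x) {
  out <- vapply(as.vector(x), function(v) sprintf("%.17g", v), character(1))
  if (is.matrix(x)) {
    out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
    out <- as.data.frame(out, stringsAsFactors = FALSE)
  }
  out
}

SCALE_FORMAT_VERSION <- "molstage-scale/1"
PANEL_FORMAT_VERSION <- "molstage-panel/1"

# order-sensitive 32-bit polynomial hash of a character vector, as hex.
# Carried in doubles: h*31 + b < 2^37, exact under IEEE-754.
gene_list_checksum <- function(ids) {
  h <- 17
  for (b in utf8ToInt(paste(ids, collapse = "\n")))
    h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Construct a frozen phenology-scale artifact
#'
#' Bundles everything needed to project new samples: the core gene list,
#' the training column means/sds, the eigenvector matrix of the selected
#' principal components, the Bezier control points and the arc-length
#' mark coordinates.
#'
#' @param core_gene_ids ordered core gene list F.
#' @param column_means,column_sds per-gene standardization constants of the
#'   smoothed training matrix (population sd).
#' @param eigenvectors |F| x 3 matrix A of the selected PC eigenvectors.
#' @param pc_indices the three selected PC indices (e.g. `c(1, 2, 5)`).
#' @param control_points k x 3 Bezier control points.
#' @param marks n_marks x 3 coordinates of the evenly spaced stage marks.
#' @param n_marks number of stage marks (default 30).
#' @param explained_variance_pct optional per-selected-PC explained
#'   variance percentages.
#' @param training_stages optional named integer vector: stage assigned to
#'   each training condition at build time.
#' @return object of class `scale_artifact`.
#' @export
scale_artifact <- function(core_gene_ids, column_means, column_sds,
                           eigenvectors, pc_indices, control_points, marks,
                           n_marks = nrow(marks),
                           explained_variance_pct = NULL,
                           training_stages = NULL) {
  core_gene_ids <- as.character(core_gene_ids)
  if (anyDuplicated(core_gene_ids)) stop("duplicate core gene ids")
  eigenvectors <- as.matrix(eigenvectors)
  if (nrow(eigenvectors) != length(core_gene_ids) || ncol(eigenvectors) != 3)
    stop("eigenvectors must be |F| x 3")
  if (any(abs(crossprod(eigenvectors) - diag(3)) > 1e-8))
    stop("eigenvector columns not orthonormal")
  if (length(column_means) != length(core_gene_ids) ||
      length(column_sds) != length(core_gene_ids))
    stop("means/sds length mismatch with core gene list")
  if (any(!is.finite(column_sds)) || any(column_sds <= 0))
    stop("column sds must be positive")
  marks <- as.matrix(marks)
  if (n_marks < 2 || nrow(marks) != n_marks || ncol(marks) != 3)
    stop("marks must be n_marks x 3 with n_marks >= 2")
  rownames(eigenvectors) <- core_gene_ids
  structure(
    list(core_gene_ids = core_gene_ids,
         column_means = stats::setNames(as.numeric(column_means), core_gene_ids),
         column_sds = stats::setNames(as.numeric(column_sds), core_gene_ids),
         eigenvectors = eigenvectors,
         pc_indices = as.integer(pc_indices),
         control_points = as.matrix(control_points),
         marks = marks,
         n_marks = as.integer(n_marks),
         explained_variance_pct = explained_variance_pct,
         training_stages = training_stages),
    class = "scale_artifact"
  )
}

#' @export
print.scale_artifact <- function(x, ...) {
  cat("<scale_artifact> ", length(x$core_gene_ids), " core genes, PCs (",
      paste(x$pc_indices, collapse = ", "), "), ",
      nrow(x$control_points), " control points, ",
      x$n_marks, " stage marks\n", sep = "")
  invisible(x)
}

#' Write / read a scale artifact (bit-exact JSON round trip)
#'
#' The artifact is stored as a single JSON document with full-precision
#' base-10 numbers, a format version tag and a checksum of the gene list,
#' so that `read_scale(write_scale(a))` reproduces every numeric field
#' bit-for-bit.
#'
#' @param artifact a `scale_artifact`.
#' @param path output file path.
#' @return `write_scale`: invisibly, `path`. `read_scale`: the artifact.
#' @export
write_scale <- function(artifact, path) {
  stopifnot(inherits(artifact, "scale_artifact"))
  doc <- list(
    format = SCALE_FORMAT_VERSION,
    gene_checksum = gene_list_checksum(artifact$core_gene_ids),
    core_gene_ids = artifact$core_gene_ids,
    column_means = unname(artifact$column_means),
    column_sds = unname(artifact$column_sds),
    eigenvectors = artifact$eigenvectors,
    pc_indices = artifact$pc_indices,
    control_points = artifact$control_points,
    marks = artifact$marks,
    n_marks = artifact$n_marks,
    explained_variance_pct = artifact$explained_variance_pct,
    training_stages = as.list(artifact$training_stages)
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_scale
#' @export
read_scale <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupt scale artifact: ",
                                           conditionMessage(e)))
  if (!identical(doc$format, SCALE_FORMAT_VERSION))
    stop("scale artifact version mismatch: expected ", SCALE_FORMAT_VERSION,
         ", found ", if (is.null(doc$format)) "<none>" else doc$format)
  needed <- c("core_gene_ids", "column_means", "column_sds", "eigenvectors",
              "pc_indices", "control_points", "marks", "n_marks")
  if (!all(needed %in% names(doc))) stop("corrupt scale artifact: missing fields")
  if (!identical(doc$gene_checksum, gene_list_checksum(doc$core_gene_ids)))
    stop("corrupt scale artifact: gene list checksum failure")
  ts <- doc$training_stages
  if (length(ts)) ts <- stats::setNames(as.integer(unlist(ts)), names(ts))
  else ts <- NULL
  scale_artifact(doc$core_gene_ids, doc$column_means, doc$column_sds,
                 doc$eigenvectors, doc$pc_indices, doc$control_points,
                 doc$marks, doc$n_marks,
                 explained_variance_pct = doc$explained_variance_pct,
                 training_stages = ts)
}

#' Reduced marker-gene panel
#'
#' An ordered subset of a scale's core gene set with, for each selected
#' principal component, the sign of each gene's eigenvector coefficient
#' (used by the reduced-panel imputation rule of [project_reduced()]).
#'
#' @param gene_ids panel gene ids (subset of the scale's core set).
#' @param loading_signs |panel| x 3 matrix of {-1, +1} loading signs, rows
#'   named by gene id, one column per selected PC.
#' @param p_corr optional |panel| x 3 matrix of gene-score correlations.
#' @param provenance free-text description of how the panel was built.
#' @return object of class `gene_panel`.
#' @export
gene_panel <- function(gene_ids, loading_signs, p_corr = NULL,
                       provenance = "") {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in panel")
  loading_signs <- as.matrix(loading_signs)
  storage.mode(loading_signs) <- "double"
  if (nrow(loading_signs) != length(gene_ids) || ncol(loading_signs) != 3)
    stop("loading_signs must be |panel| x 3")
  if (!all(loading_signs %in% c(-1, 1)))
    stop("loading signs must be -1 or +1")
  rownames(loading_signs) <- gene_ids
  structure(list(gene_ids = gene_ids, loading_signs = loading_signs,
                 p_corr = p_corr, provenance = provenance),
            class = "gene_panel")
}

#' Write / read a gene panel as JSON
#'
#' @param panel a `gene_panel`.
#' @param path file path.
#' @return `write_panel`: invisibly, `path`. `read_panel`: the panel.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  doc <- list(format = PANEL_FORMAT_VERSION, gene_ids = panel$gene_ids,
              loading_signs = panel$loading_signs, p_corr = panel$p_corr,
              provenance = panel$provenance)
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, PANEL_FORMAT_VERSION))
    stop("panel format version mismatch")
  gene_panel(doc$gene_ids, doc$loading_signs, p_corr = doc$p_corr,
             provenance = doc$provenance)
}
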