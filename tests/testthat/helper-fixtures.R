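# Shared fixtures and independent oracles, built in code at test time.

# Small synthetic study used across test files (built once per run),
# following the pipeline order: screen, then build the scale on the core.
fx <- local({
  d <- generate_dataset(n_genes = 600, seed = 11)
  core <- screen_genes(d$tensor)$core
  scale <- build_scale(d$tensor, core)
  list(tensor = d$tensor, truth = d$truth, core = core, scale = scale,
       latent = d$truth$latent[d$tensor$conditions$condition_id])
})

# Construct a tensor from an explicit value function
# f(gene_index, cultivar, vintage, timepoint, replicate) -> value.
make_tensor <- function(n_genes, cultivars, vintages, n_tp, reps = 3,
                        f, gene_ids = paste0("g", seq_len(n_genes))) {
  cols <- list(); meta <- list()
  for (cv in cultivars) for (vt in vintages) for (tp in seq_len(n_tp))
    for (r in seq_len(reps)) {
      nm <- paste(cv, vt, tp, r, sep = "_")
      cols[[nm]] <- vapply(seq_len(n_genes), function(g) f(g, cv, vt, tp, r),
                           numeric(1))
      meta[[nm]] <- data.frame(sample = nm, cultivar = cv, vintage = vt,
                               timepoint = tp, replicate = r,
                               stringsAsFactors = FALSE)
    }
  values <- do.call(cbind, cols)
  rownames(values) <- gene_ids
  expression_tensor(values, do.call(rbind, meta), n_replicates = reps)
}

# Independent textbook LOESS: tricube weights on distance scaled to the
# window maximum, local polynomial by weighted least squares.
loess_oracle <- function(x, y, x0s, degree = 2, span = 0.75) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(x0s, function(x0) {
    d <- abs(x - x0)
    dq <- sort(d)[q]
    w <- if (dq == 0) as.numeric(d == 0) else (1 - pmin(d / dq, 1)^3)^3
    X <- outer(x - x0, 0:degree, "^")
    stats::lm.wfit(X, y, w)$coefficients[1]
  }, numeric(1))
}

# Exhaustive nearest-mark search, independent of the package's kernel.
nearest_mark_oracle <- function(Y, marks) {
  apply(Y, 1, function(p) {
    d <- sqrt(colSums((t(marks) - p)^2))
    which(d == min(d))[1]
  })
}

# Analytic Bezier speed |B'(t)| for quadrature-based arc length.
bezier_speed <- function(cp, t) {
  k <- nrow(cp)
  dcp <- (k - 1) * diff(cp)
  d <- k - 2
  B <- outer(t, 0:d, function(tt, j) choose(d, j) * tt^j * (1 - tt)^(d - j))
  sqrt(rowSums((B %*% dcp)^2))
}

# fraction of non-decreasing consecutive stage pairs within each series
monotone_pair_fraction <- function(stages, tensor) {
  series <- condition_series(tensor)
  ok <- 0; total <- 0
  for (h in unique(series)) {
    s <- stages[series == h]
    ok <- ok + sum(diff(s) >= 0)
    total <- total + length(s) - 1
  }
  ok / total
}
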