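test_that("column standardization uses population moments", {
  M <- cbind(a = c(1, 2, 3), b = c(4, 8, 12))
  std <- standardize_columns(M)
  expect_equal(unname(std$Z[, "a"]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)  # mean 2, population sd sqrt(2/3)
  expect_equal(unname(colMeans(std$Z)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(sqrt(colMeans(std$Z^2))), c(1, 1), tolerance = 1e-10)

  # idempotence
  again <- standardize_columns(std$Z)
  expect_equal(again$Z, std$Z, tolerance = 1e-10)

  expect_error(standardize_columns(cbind(ok = 1:3, flat = c(5, 5, 5))),
               "zero-variance.*flat")
})

test_that("PCA explains variance correctly and reconstructs the matrix", {
  # rank-1: one component carries 100%
  Z1 <- outer(c(-1, 0, 1), rnorm(20))
  m1 <- fit_pca(scale(Z1, scale = FALSE), n_pcs = 2)
  expect_equal(m1$explained_variance_pct[1], 100, tolerance = 1e-8)

  # full reconstruction from all components
  set.seed(21)
  Z <- standardize_columns(matrix(rnorm(500), nrow = 10))$Z
  m <- fit_pca(Z, n_pcs = 10)
  expect_equal(m$scores %*% t(m$eigenvectors), Z, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(m$eigenvectors), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(Z, n_pcs = 11), "n_pcs")

  # planted factors: top components' variance shares track the planted
  # structure of the generator (stage signal dominates)
  sm <- smooth_dataset(fx$tensor)
  md <- fit_pca(standardize_columns(sm)$Z, n_pcs = 6,
                timepoints = fx$tensor$conditions$timepoint)
  expect_gt(md$explained_variance_pct[1], 40)
  expect_true(all(diff(md$explained_variance_pct) <= 1e-10))
  expect_lt(sum(md$explained_variance_pct), 100 + 1e-8)
})

test_that("component triage labels factors by dominant effect", {
  conds <- fx$tensor$conditions
  n <- nrow(conds)
  # synthetic score matrix with known drivers
  scores <- cbind(conds$timepoint + rnorm(n, 0, 1e-6),
                  ifelse(conds$cultivar == "CVA", 1, -1) + rnorm(n, 0, 1e-6),
                  as.numeric(factor(conds$vintage)) + rnorm(n, 0, 1e-6))
  fake <- structure(list(scores = scores,
                         explained_variance_pct = c(50, 30, 20)),
                    class = "pc_model")
  out <- triage_components(fake, conds, select = FALSE)
  expect_identical(out$factor_assoc$label, c("stage", "cultivar", "vintage"))
  expect_error(triage_components(fake, conds), "pc_indices")

  # planted-factor data: 3 stage + cultivar + vintage components recovered
  model <- triage_components(
    fit_pca(standardize_columns(smooth_dataset(fx$tensor))$Z, 6,
            fx$tensor$conditions$timepoint), conds)
  labels <- model$factor_assoc$label
  expect_equal(sum(labels == "stage"), 3)
  expect_gte(sum(labels == "cultivar"), 1)
  expect_gte(sum(labels == "vintage"), 1)
})

test_that("Bezier fitting recovers lines and known curves", {
  # collinear points: an order-5 curve degenerates to the segment
  t <- seq(0, 1, length.out = 12)
  pts <- cbind(t * 10, t * -2, t * 5)
  cv <- fit_bezier(pts, init_t = t, k = 5)
  expect_lt(cv$rss, 1e-10)
  on_curve <- bezier_points(cv, seq(0, 1, length.out = 50))
  # every curve point stays on the segment: cross product with direction ~ 0
  dir <- c(10, -2, 5) / sqrt(sum(c(10, -2, 5)^2))
  proj <- on_curve %*% dir %*% t(dir)
  expect_lt(max(abs(on_curve - proj)), 1e-6)

  # self-consistency: points sampled from a known quartic Bezier at the
  # fit's own initial parameters recover its 5 control points
  set.seed(31)
  cp_true <- matrix(rnorm(15, sd = 3), nrow = 5)
  t0 <- seq(0, 1, length.out = 20)
  pts2 <- bezier_points(cp_true, t0)
  cv2 <- fit_bezier(pts2, init_t = t0, k = 5)
  expect_equal(cv2$control_points, cp_true, tolerance = 1e-6)

  expect_error(fit_bezier(matrix(1, nrow = 10, ncol = 3),
                          init_t = seq(0, 1, length.out = 10)), "degenerate")
  expect_error(fit_bezier(pts, init_t = t, k = 1), "order")
})

test_that("marks are evenly spaced along the curve", {
  # straight segment: marks at x = 0, 1, ..., 29
  seg <- structure(list(control_points = rbind(c(0, 0, 0), c(29, 0, 0))),
                   class = "bezier_curve")
  marks <- place_marks(seg, n_marks = 30)
  expect_equal(unname(marks[, 1]), 0:29, tolerance = 1e-6)
  expect_equal(unname(place_marks(seg, n_marks = 2)[, 1]), c(0, 29),
               tolerance = 1e-10)
  expect_error(place_marks(seg, n_marks = 1), "n_marks")

  # curved Bezier: inter-mark arc lengths uniform within 0.1% and equal
  # to an independent quadrature oracle within 1e-3
  cp <- rbind(c(0, 0, 0), c(2, 4, 0), c(5, 4, 2), c(8, 0, 1), c(10, 1, 3))
  curve <- structure(list(control_points = cp), class = "bezier_curve")
  mk <- place_marks(curve, n_marks = 30)
  tm <- attr(mk, "t")
  arcs <- vapply(seq_len(29), function(i)
    stats::integrate(function(u) bezier_speed(cp, u), tm[i], tm[i + 1],
                     rel.tol = 1e-10)$value, numeric(1))
  expect_lt(diff(range(arcs)) / mean(arcs), 0.001)
  chords <- sqrt(rowSums(diff(mk)^2))
  expect_lt(max(abs(chords - arcs)), 1e-3 * mean(arcs) + 1e-3)
})

test_that("build_scale orders training conditions along development", {
  sc <- fx$scale
  expect_identical(sc$n_marks, 30L)
  expect_identical(nrow(sc$control_points), 5L)
  stages <- sc$training_stages[fx$tensor$conditions$condition_id]
  expect_gte(monotone_pair_fraction(stages, fx$tensor), 0.9)
  # stage 1 is the earliest-development end
  expect_gt(cor(stages, fx$tensor$conditions$timepoint, method = "spearman"), 0)
  # end-to-end latent recovery
  expect_gte(cor(stages, fx$latent, method = "spearman"), 0.95)
})

test_that("rebuilding with permuted gene order changes nothing", {
  set.seed(77)
  perm <- sample(fx$tensor$gene_ids)
  tn <- fx$tensor
  tn$values <- tn$values[perm, ]
  tn$gene_ids <- perm
  sc2 <- build_scale(tn, sample(fx$core))
  expect_equal(unname(sc2$marks[, ]), unname(fx$scale$marks[, ]),
               tolerance = 1e-8)
  expect_identical(sc2$training_stages, fx$scale$training_stages)
  expect_identical(sc2$pc_indices, fx$scale$pc_indices)
})
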