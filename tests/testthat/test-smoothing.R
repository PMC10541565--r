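test_that("replicate and series means follow their definitions", {
  reps <- list(c(3, 4, 5), c(0, 0, 0), c(1, 2, 6), c(1, 1, 1),
               c(3, 3, 3), c(2, 2, 2))
  tn <- make_tensor(1, "A", "y", n_tp = 6, f = function(g, cv, vt, tp, r)
    reps[[tp]][r])
  conds <- tn$conditions$condition_id
  expect_equal(replicate_mean(tn, "g1", conds[1]), 4)
  expect_equal(replicate_mean(tn, "g1", conds[2]), 0)
  expect_equal(replicate_mean(tn, "g1", conds[3]), 3)

  # two-condition series mean and degenerate single condition
  tn2 <- make_tensor(1, "A", "y", n_tp = 2, f = function(g, cv, vt, tp, r)
    c(1, 3)[tp])
  expect_equal(series_mean(tn2, "g1", "A|y"), 2)
  tn3 <- make_tensor(1, "A", "y", n_tp = 1, f = function(g, cv, vt, tp, r) 7)
  expect_equal(series_mean(tn3, "g1", "A|y"),
               replicate_mean(tn3, "g1", tn3$conditions$condition_id[1]))

  # random series: brute-force mean over all 12 replicate values
  set.seed(42)
  vals <- matrix(runif(12, 0, 10), nrow = 4)
  tn4 <- make_tensor(1, "A", "y", n_tp = 4, f = function(g, cv, vt, tp, r)
    vals[tp, r])
  expect_equal(series_mean(tn4, "g1", "A|y"), mean(vals))
})

test_that("replicate CV is sd/mean, undefined at zero mean", {
  reps <- list(c(2, 2, 2), c(1, 2, 3), c(0, 0, 0))
  tn <- make_tensor(1, "A", "y", n_tp = 3, f = function(g, cv, vt, tp, r)
    reps[[tp]][r])
  conds <- tn$conditions$condition_id
  expect_equal(replicate_cv(tn, "g1", conds[1]), 0)
  expect_equal(replicate_cv(tn, "g1", conds[2]), 0.5)  # sample sd 1, mean 2
  expect_true(is.na(replicate_cv(tn, "g1", conds[3])))
  cvm <- replicate_cv_matrix(tn)
  expect_equal(unname(cvm[, 1]), c(0, 0.5, NA))
})

test_that("LOESS reproduces quadratics exactly and matches the textbook oracle", {
  # degree-2 local fits reproduce degree-2 data exactly
  t <- rep(1:10, each = 3)
  y <- 2 + 3 * t + t^2
  fit <- loess_smooth_gene(t, y)
  expect_equal(unname(fit), 2 + 3 * (1:10) + (1:10)^2, tolerance = 1e-8)

  expect_equal(unname(loess_smooth_gene(t, rep(7, length(t)))),
               rep(7, 10), tolerance = 1e-10)

  # noisy sine over 14 timepoints vs independent tricube/degree-2 oracle
  set.seed(3)
  t14 <- rep(1:14, each = 3)
  y14 <- sin(t14 / 3) + rnorm(length(t14), 0, 0.2)
  expect_equal(unname(loess_smooth_gene(t14, y14)),
               unname(loess_oracle(t14, y14, 1:14)), tolerance = 1e-6)

  expect_error(loess_smooth_gene(rep(1:3, each = 3), rnorm(9)),
               "distinct predictor")
  expect_error(loess_smooth_gene(1:10, rnorm(10), span = 1.5), "span")
})

test_that("fitted values are invariant to replicate order", {
  set.seed(5)
  t <- rep(1:8, each = 3)
  y <- rnorm(24)
  perm <- sample(24)
  expect_equal(loess_smooth_gene(t, y),
               loess_smooth_gene(t[perm], y[perm]), tolerance = 1e-10)
})

test_that("smooth_dataset is series-local and matches per-gene smoothing", {
  # condition-wise constant genes: smoothed equals the replicate means
  tn <- make_tensor(3, c("A", "B"), "y", n_tp = 6,
                    f = function(g, cv, vt, tp, r)
                      g * 10 + tp + 5 * (cv == "B"))
  sm <- smooth_dataset(tn)
  expect_equal(unname(sm), unname(condition_means(tn)), tolerance = 1e-8)

  # quadratic profiles over 4 timepoints reproduce the closed form
  tn2 <- make_tensor(1, "A", "y", n_tp = 4,
                     f = function(g, cv, vt, tp, r) 1 + 2 * tp + 0.5 * tp^2)
  sm2 <- smooth_dataset(tn2)
  expect_equal(unname(sm2[, 1]), 1 + 2 * (1:4) + 0.5 * (1:4)^2,
               tolerance = 1e-8)

  # series-locality: agrees with smoothing each series separately
  set.seed(8)
  noisy <- make_tensor(2, c("A", "B"), "y", n_tp = 7,
                       f = function(g, cv, vt, tp, r)
                         abs(sin(tp / 2) * g + rnorm(1, 0, 0.1)))
  smn <- smooth_dataset(noisy)
  series <- condition_series(noisy)
  samp_series <- paste(noisy$meta$cultivar, noisy$meta$vintage, sep = "|")
  for (h in unique(series)) {
    for (g in noisy$gene_ids) {
      sel <- samp_series == h
      ref <- loess_smooth_gene(noisy$meta$timepoint[sel],
                               noisy$values[g, sel])
      expect_equal(unname(smn[series == h, g]), unname(ref),
                   tolerance = 1e-8)
    }
  }

  # 73-condition training-like design produces a conditions x genes matrix
  d <- generate_dataset(n_genes = 20, seed = 2)
  smd <- smooth_dataset(d$tensor)
  expect_identical(dim(smd), c(nrow(d$tensor$conditions), 20L))
})
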