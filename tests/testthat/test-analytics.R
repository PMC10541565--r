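test_that("stage rates are first differences with the telescoping identity", {
  r <- stage_rate(c(150, 157), c(5, 9))
  expect_equal(r$rate, 4 / 7)
  expect_equal(r$time, 153.5)
  expect_equal(stage_rate(c(1, 5, 9), c(4, 4, 4))$rate, c(0, 0))
  expect_error(stage_rate(c(1, 1, 2), c(1, 2, 3)), "duplicate times")

  set.seed(6)
  tt <- cumsum(runif(10, 1, 5)); ss <- cumsum(rpois(10, 2))
  r2 <- stage_rate(tt, ss)
  expect_equal(sum(r2$rate * diff(tt)), ss[10] - ss[1], tolerance = 1e-10)
})

test_that("growing degree days accumulate heat above base", {
  expect_equal(growing_degree_days(c(20, 25, 15)), c(10, 25, 30))
  expect_equal(growing_degree_days(c(5, 8, 9.9)), c(0, 0, 0))
  set.seed(7)
  temps <- runif(100, 0, 35)
  gdd <- growing_degree_days(temps)
  brute <- vapply(seq_along(temps), function(t)
    sum(pmax(0, temps[1:t] - 10)), numeric(1))
  expect_equal(gdd, brute)
  expect_true(all(diff(gdd) >= 0))
})

test_that("Lin's concordance matches its closed form and attenuates Pearson", {
  expect_equal(lin_concordance(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(lin_concordance(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(lin_concordance(c(-1, 0, 1), c(1, 0, -1)), -1)
  expect_error(lin_concordance(c(2, 2), c(2, 2)), "constant")

  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(15); y <- 0.5 * x + rnorm(15, 2, 1)
    expect_lte(abs(lin_concordance(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("concordance classes follow the published bins", {
  expect_identical(concordance_class(0.89), "poor")
  expect_identical(concordance_class(0.90), "moderate")
  expect_identical(concordance_class(0.949), "moderate")
  expect_identical(concordance_class(0.95), "substantial")
  expect_identical(concordance_class(0.97), "substantial")
  expect_identical(concordance_class(0.99), "substantial")
  expect_identical(concordance_class(0.995), "almost perfect")
  expect_identical(concordance_class(1.0), "almost perfect")
})

test_that("shift statistics summarize signed and absolute stage differences", {
  same <- shift_statistics(c(3, 7, 9), c(3, 7, 9))
  expect_equal(same$mean_abs_shift, 0)
  expect_equal(same$median_shift, 0)
  expect_equal(same$iqr, 0)

  s <- shift_statistics(c(2, 1, 5, 5), c(1, 2, 5, 5))  # shifts +1,-1,0,0
  expect_equal(s$mean_abs_shift, 0.5)
  expect_equal(s$median_shift, 0)

  set.seed(9)
  a <- sample(1:30, 25, replace = TRUE); b <- sample(1:30, 25, replace = TRUE)
  st <- shift_statistics(a, b)
  sh <- sort(a - b)
  # brute-force type-7 quantile: linear interpolation between order stats
  q7 <- function(p) {
    h <- (length(sh) - 1) * p + 1
    sh[floor(h)] + (h - floor(h)) * (sh[ceiling(h)] - sh[floor(h)])
  }
  expect_equal(st$median_shift, q7(0.5))
  expect_equal(st$iqr, q7(0.75) - q7(0.25))
  expect_error(shift_statistics(1:3, 1:4), "length")
})

test_that("trait trends over stages behave for linear, constant and saturating traits", {
  stages <- rep(1:12, each = 2)
  lin <- 3 + 0.5 * stages
  fit <- trait_stage_trend(stages, lin)
  expect_equal(fit$fitted, 3 + 0.5 * (1:12), tolerance = 1e-8)

  const <- trait_stage_trend(stages, rep(4, length(stages)))
  expect_equal(const$fitted, rep(4, 12), tolerance = 1e-8)

  # saturating sugar-like curve: fitted trend monotone non-decreasing
  sugar <- 20 / (1 + exp(-(stages - 6) / 3)) + c(-0.1, 0.1)
  sat <- trait_stage_trend(stages, sugar)
  expect_true(all(diff(sat$fitted) >= -1e-8))
})

test_that("replicate-consistency profiles track planted noise structure", {
  clean <- generate_dataset(n_genes = 50, noise_cv = 0, seed = 41)
  pr <- list(stage = seq_len(nrow(clean$tensor$conditions)))
  prof <- replicate_consistency_profile(clean$tensor, clean$tensor$gene_ids,
                                        data.frame(stage = pr$stage))
  expect_equal(prof$mean_cv, rep(0, nrow(prof)))

  # doubling expression leaves CVs unchanged
  noisy <- generate_dataset(n_genes = 50, seed = 41)
  doubled <- noisy$tensor
  doubled$values <- doubled$values * 2
  expect_equal(replicate_cv_matrix(noisy$tensor),
               replicate_cv_matrix(doubled), tolerance = 1e-12)

  # stage-dependent noise: higher CV outside the mid-development window
  ud <- generate_dataset(n_genes = 100, seed = 43,
                         stage_dependent_noise = TRUE)
  lat <- ud$truth$latent[ud$tensor$conditions$condition_id]
  prof2 <- replicate_consistency_profile(
    ud$tensor, ud$tensor$gene_ids,
    data.frame(stage = rank(lat)))
  mid <- lat >= 0.25 & lat <= 0.75
  expect_gt(mean(prof2$mean_cv[!mid]), mean(prof2$mean_cv[mid]))
})
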