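#' Generate a synthetic developmental expression dataset
#'
#' Simulates a replicate-level expression tensor with a known latent
#' developmental trajectory, emulating a multi-season fruit development
#' study: several cultivars sampled over several vintages at roughly
#' weekly timepoints with replicate triplicates. Per series, a latent
#' stage in [0, 1] follows a double-sigmoid in calendar time (slow start,
#' rapid mid-development transition, slow finish), advanced or delayed by
#' a per-vintage shift of up to `vintage_shift_days` and a fixed
#' per-cultivar lag. Non-noise genes follow one of four archetypes
#' evaluated at the latent stage (monotone up, monotone down, transient
#' peak, switch) on a lognormal baseline, with small random cultivar and
#' vintage multiplicative offsets providing genotype- and
#' vintage-specific expression components. Replicates add multiplicative
#' lognormal noise of the given CV, optionally U-shaped in stage (noisier
#' early and late). Noise genes have no stage dependence.
#'
#' The returned truth object scores every downstream recovery test:
#' per-condition latent stages, per-gene archetypes, and each series'
#' rapid-transition time window (where the latent rate exceeds half its
#' peak).
#'
#' @param n_genes total genes (default 2000).
#' @param cultivars number of cultivars (default 2).
#' @param vintages number of vintages (default 3).
#' @param timepoints_range inclusive range of per-series timepoint counts
#'   (default `c(10, 14)`).
#' @param replicates replicates per condition (default 3).
#' @param noise_cv replicate-level coefficient of variation (default 0.15).
#' @param frac_noise_genes fraction of pure-noise genes (default 0.2).
#' @param vintage_shift_days max absolute vintage time shift (default 10).
#' @param cultivar_lag_days fixed inter-cultivar lag (default 6).
#' @param cultivar_sd,vintage_sd sd of per-gene log-scale cultivar and
#'   vintage offsets on non-noise genes (defaults 0.25, 0.2).
#' @param frac_stage_only fraction of non-noise genes whose cultivar and
#'   vintage coefficients are forced to zero — markers driven purely by
#'   developmental stage (default 0; set alongside larger `cultivar_sd`,
#'   `vintage_sd` to plant a marker-selection scenario).
#' @param archetype_pool archetypes available to non-noise genes (default
#'   all four); restrict to the monotone pair for scenarios focused on
#'   late-development markers, where transient and switch genes are
#'   expressionally silent.
#' @param stage_dependent_noise if `TRUE`, the replicate CV is scaled by
#'   a U-shape in latent stage (up to 2x at the extremes).
#' @param seed RNG seed; fully determines the output.
#' @return list with `tensor` (an `expr_tensor`) and `truth` (class
#'   `synthetic_truth`): `latent` (named per-condition latent stage),
#'   `archetype` (named per-gene), `rapid_window` (per-series day
#'   interval of fast transition), `day` (named per-condition calendar
#'   day), and the generator parameters.
#' @export
generate_dataset <- function(n_genes = 2000L, cultivars = 2L, vintages = 3L,
                             timepoints_range = c(10L, 14L), replicates = 3L,
                             noise_cv = 0.15, frac_noise_genes = 0.2,
                             vintage_shift_days = 10, cultivar_lag_days = 6,
                             cultivar_sd = 0.25, vintage_sd = 0.2,
                             frac_stage_only = 0,
                             archetype_pool = c("monotone-up", "monotone-down",
                                                "transient-peak", "switch"),
                             stage_dependent_noise = FALSE, seed = 1L) {
  stopifnot(n_genes > 0, cultivars > 0, vintages > 0, replicates > 0,
            noise_cv >= 0, frac_noise_genes >= 0, frac_noise_genes <= 1,
            frac_stage_only >= 0, frac_stage_only <= 1)
  set.seed(seed)

  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  n_noise <- round(frac_noise_genes * n_genes)
  archetypes <- match.arg(archetype_pool,
                          c("monotone-up", "monotone-down", "transient-peak",
                            "switch"), several.ok = TRUE)
  archetype <- c(sample(archetypes, n_genes - n_noise, replace = TRUE),
                 rep("noise", n_noise))
  archetype <- stats::setNames(sample(archetype), gene_ids)   # shuffle positions

  baseline <- stats::setNames(stats::rlnorm(n_genes, meanlog = 2, sdlog = 1),
                              gene_ids)
  amp <- stats::setNames(stats::runif(n_genes, 1.5, 3), gene_ids)
  peak_center <- stats::setNames(stats::runif(n_genes, 0.3, 0.7), gene_ids)
  switch_center <- stats::setNames(stats::runif(n_genes, 0.35, 0.65), gene_ids)
  # transient peaks span several weekly samples (a multi-week pulse in
  # latent-stage units), the regime where cross-series consistency is
  # observable at the study's sampling density
  peak_width <- 0.18
  cultivar_coef <- stats::setNames(stats::rnorm(n_genes, 0, cultivar_sd), gene_ids)
  vintage_coef <- matrix(stats::rnorm(n_genes * vintages, 0, vintage_sd),
                         nrow = n_genes, dimnames = list(gene_ids, NULL))
  # noise genes carry no structured signal at all
  noise_genes <- names(archetype)[archetype == "noise"]
  cultivar_coef[noise_genes] <- 0
  vintage_coef[noise_genes, ] <- 0
  trajectory_genes <- setdiff(gene_ids, noise_genes)
  # stage-only markers are drawn from the monotone archetypes: transient
  # and switch genes saturate before late development, so only monotone
  # genes remain informative over the whole developmental range
  monotone <- trajectory_genes[archetype[trajectory_genes] %in%
                                 c("monotone-up", "monotone-down")]
  stage_only <- sample(monotone,
                       min(length(monotone),
                           round(frac_stage_only * length(trajectory_genes))))
  cultivar_coef[stage_only] <- 0
  vintage_coef[stage_only, ] <- 0
  if (length(stage_only)) {
    # marker-selection scenario: the non-stage-only trajectory genes are
    # genuinely confound-driven, with effect magnitudes bounded away from
    # zero (a Gaussian draw would leave many of them indistinguishable
    # from the planted stage-only markers)
    conf <- setdiff(trajectory_genes, stage_only)
    cultivar_coef[conf] <- sample(c(-1, 1), length(conf), TRUE) *
      stats::runif(length(conf), 0.5, 1.5) * cultivar_sd
    vintage_coef[conf, ] <- sample(c(-1, 1), length(conf) * vintages, TRUE) *
      stats::runif(length(conf) * vintages, 0.5, 1.5) * vintage_sd
  }

  cult_names <- paste0("CV", LETTERS[seq_len(cultivars)])
  vint_names <- 2011 + seq_len(vintages)
  vintage_shift <- stats::runif(vintages, -vintage_shift_days, vintage_shift_days)
  cultivar_lag <- (seq_len(cultivars) - 1) * cultivar_lag_days

  # latent trajectory over days since series start (~90-day season):
  # a slow early rise, a rapid mid-development transition, then a slow
  # but continuing late progression (development does not freeze before
  # harvest: the late window retains a real, gentler stage gradient)
  latent_of_day <- function(day, shift) {
    u <- day - shift
    0.30 / (1 + exp(-(u - 20) / 9)) +
      0.45 / (1 + exp(-(u - 48) / 5)) +
      0.25 / (1 + exp(-(u - 78) / 14))
  }

  rows <- list(); meta <- list(); latent <- c(); day_of <- c()
  rapid_window <- list()
  for (ci in seq_len(cultivars)) for (vi in seq_len(vintages)) {
    n_tp <- sample(seq(timepoints_range[1], timepoints_range[2]), 1)
    gaps <- stats::runif(n_tp - 1, 7, 10)
    days <- cumsum(c(stats::runif(1, 0, 4), gaps))
    shift <- vintage_shift[vi] + cultivar_lag[ci]
    s <- latent_of_day(days, shift)
    series <- paste(cult_names[ci], vint_names[vi], sep = "|")
    # planted rapid window: latent rate above half its maximum, on a
    # fine day grid spanning the sampled season
    fine <- seq(min(days), max(days), by = 0.25)
    rate <- diff(latent_of_day(fine, shift)) / diff(fine)
    fast <- fine[-1][rate >= max(rate) / 2]
    rapid_window[[series]] <- range(fast)
    for (t in seq_len(n_tp)) {
      cond <- paste(series, t, sep = "|")
      latent[cond] <- s[t]
      day_of[cond] <- days[t]
      meta[[cond]] <- data.frame(
        cultivar = cult_names[ci], vintage = vint_names[vi],
        timepoint = t, doy = round(120 + days[t]),
        daf = round(days[t]), stringsAsFactors = FALSE)
    }
  }
  conds <- names(latent)

  # mean log-expression per gene x condition
  arch_value <- function(a, s, g) {
    switch(a,
      "monotone-up" = s,
      "monotone-down" = 1 - s,
      "transient-peak" = exp(-(s - peak_center[g])^2 / (2 * peak_width^2)),
      "switch" = 1 / (1 + exp(-(s - switch_center[g]) / 0.05)),
      "noise" = 0)
  }
  n_cond <- length(conds)
  mean_log <- matrix(0, nrow = n_genes, ncol = n_cond,
                     dimnames = list(gene_ids, conds))
  cult_of <- vapply(strsplit(conds, "|", fixed = TRUE), `[[`, "", 1)
  vint_of <- vapply(strsplit(conds, "|", fixed = TRUE), `[[`, "", 2)
  cult_sign <- ifelse(match(cult_of, cult_names) == 1, 1, -1)
  vint_idx <- match(vint_of, as.character(vint_names))
  for (g in gene_ids) {
    f <- vapply(seq_len(n_cond),
                function(j) arch_value(archetype[g], latent[j], g), numeric(1))
    mean_log[g, ] <- log(baseline[g]) + amp[g] * (f - 0.5) +
      cultivar_coef[g] * cult_sign + vintage_coef[g, vint_idx]
  }

  # replicate-level multiplicative lognormal noise, mean-preserving
  sample_names <- c(); cols <- list(); meta_rows <- list()
  for (j in seq_len(n_cond)) {
    cv_j <- noise_cv
    if (stage_dependent_noise) cv_j <- noise_cv * (1 + (2 * abs(latent[j] - 0.5))^2)
    sdlog <- sqrt(log(1 + cv_j^2))
    for (r in seq_len(replicates)) {
      nm <- paste0(conds[j], "|r", r)
      eps <- if (sdlog > 0)
        stats::rlnorm(n_genes, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, n_genes)
      cols[[nm]] <- exp(mean_log[, j]) * eps
      m <- meta[[conds[j]]]
      meta_rows[[nm]] <- data.frame(sample = nm, cultivar = m$cultivar,
                                    vintage = m$vintage, timepoint = m$timepoint,
                                    replicate = r, doy = m$doy, daf = m$daf,
                                    stringsAsFactors = FALSE)
      sample_names <- c(sample_names, nm)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- gene_ids
  meta_df <- do.call(rbind, meta_rows)
  tensor <- expression_tensor(values, meta_df, n_replicates = replicates)

  truth <- structure(
    list(latent = latent, archetype = archetype, day = day_of,
         stage_only = stage_only,
         rapid_window = rapid_window, baseline = baseline, amp = amp,
         cultivar_coef = cultivar_coef, vintage_coef = vintage_coef,
         peak_center = peak_center, switch_center = switch_center,
         peak_width = peak_width,
         vintage_shift = vintage_shift, cultivar_lag = cultivar_lag,
         noise_cv = noise_cv, seed = seed,
         params = list(n_genes = n_genes, cultivars = cultivars,
                       vintages = vintages, replicates = replicates,
                       frac_noise_genes = frac_noise_genes)),
    class = "synthetic_truth")
  list(tensor = tensor, truth = truth)
}

#' Generate a reference screening panel
#'
#' Emulates an external multi-cultivar reference dataset: the same genes
#' as a main synthetic dataset, observed for a few ordered developmental
#' stages across several new cultivars in a single vintage. Gene
#' archetypes and per-gene parameters are shared with `truth`, so the
#' panel is congruent with the main tensor for trajectory genes and
#' uninformative for noise genes.
#'
#' @param truth the `synthetic_truth` of the main dataset.
#' @param cultivars number of reference cultivars (default 10).
#' @param stages number of ordered stages (default 4).
#' @param noise_cv replicate noise CV (default: the truth's).
#' @param replicates replicates per condition (default 1).
#' @param seed RNG seed.
#' @return an `expr_tensor` with `stages` timepoints per cultivar.
#' @export
generate_reference_panel <- function(truth, cultivars = 10L, stages = 4L,
                                     noise_cv = truth$noise_cv,
                                     replicates = 1L, seed = truth$seed + 1000L) {
  stopifnot(inherits(truth, "synthetic_truth"), stages >= 1, cultivars >= 1)
  set.seed(seed)
  gene_ids <- names(truth$archetype)
  s_levels <- seq(0.1, 0.9, length.out = stages)
  cult_names <- sprintf("REF%02d", seq_len(cultivars))
  cult_offset <- stats::rnorm(cultivars, 0, 0.3)

  arch_value <- function(a, s, g) {
    switch(a,
      "monotone-up" = s,
      "monotone-down" = 1 - s,
      "transient-peak" = exp(-(s - truth$peak_center[g])^2 / (2 * truth$peak_width^2)),
      "switch" = 1 / (1 + exp(-(s - truth$switch_center[g]) / 0.05)),
      "noise" = 0)
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  cols <- list(); meta_rows <- list()
  for (ci in seq_len(cultivars)) for (t in seq_len(stages)) {
    f <- vapply(gene_ids, function(g)
      arch_value(truth$archetype[g], s_levels[t], g), numeric(1))
    mlog <- log(truth$baseline) + truth$amp * (f - 0.5) +
      truth$cultivar_coef * cult_offset[ci]
    for (r in seq_len(replicates)) {
      nm <- paste(cult_names[ci], "ref", t, r, sep = "|")
      eps <- if (sdlog > 0)
        stats::rlnorm(length(gene_ids), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, length(gene_ids))
      cols[[nm]] <- exp(mlog) * eps
      meta_rows[[nm]] <- data.frame(sample = nm, cultivar = cult_names[ci],
                                    vintage = "ref", timepoint = t,
                                    replicate = r, doy = NA_integer_,
                                    daf = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- gene_ids
  expression_tensor(values, do.call(rbind, meta_rows),
                    n_replicates = replicates)
}
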