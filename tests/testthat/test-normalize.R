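toy_bins <- function(n = 6, chrom = "1", gc = 0.4) {
  bin_set(rep(chrom, n), (seq_len(n) - 1) * 100, seq_len(n) * 100,
          rep_len(gc, n))
}

test_that("autosomal scaling yields proportions and is depth-invariant", {
  bins <- bin_set(c(rep("1", 3), "X"), c(0, 100, 200, 0),
                  c(100, 200, 300, 100), rep(0.4, 4))
  counts <- rbind(s1 = c(500, 6e6, 3999500, 1000),
                  s2 = 2 * c(500, 6e6, 3999500, 1000))
  colnames(counts) <- rownames(bins)
  cm <- count_matrix(counts, data.frame(sample_id = c("s1", "s2"),
                                        plate = "P1"))
  nm <- scale_by_autosomal_total(cm, bins)
  expect_equal(nm$stage, "SCALED")
  # 500 reads on a 1e7 autosomal total -> 5e-5
  expect_equal(nm$values["s1", 1], 5e-5)
  expect_equal(sum(nm$values["s1", 1:3]), 1)
  # proportional counts (2x depth) scale to identical rows
  expect_equal(nm$values["s1", ], nm$values["s2", ])

  zc <- matrix(c(0, 0, 0, 5), nrow = 1,
               dimnames = list("s1", rownames(bins)))
  zero <- count_matrix(zc, data.frame(sample_id = "s1", plate = "P1"))
  expect_error(scale_by_autosomal_total(zero, bins), "zero autosomal")
})

test_that("same genome at two depths scales to agreeing profiles", {
  cfg_lo <- sim_config(depth = 6e6, gc_bias_sd = 0)
  cfg_hi <- sim_config(depth = 2.4e7, gc_bias_sd = 0)
  lo <- simulate_cohort(list(sim_scenario(1, sex = "XX")), cfg_lo, seed = 7)
  hi <- simulate_cohort(list(sim_scenario(1, sex = "XX")), cfg_hi, seed = 8)
  nm_lo <- scale_by_autosomal_total(lo$counts, lo$bins)
  nm_hi <- scale_by_autosomal_total(hi$counts, hi$bins)
  # same expected profile; agreement limited only by sampling noise
  expect_lt(stats::mad(nm_lo$values[1, ] / nm_hi$values[1, ] - 1), 0.05)
})

make_biased_training <- function(n_samples = 30, n_bins = 400, slope = 2,
                                 seed = 11) {
  set.seed(seed)
  gc <- seq(0.25, 0.6, length.out = n_bins)
  bins <- bin_set(rep("1", n_bins), (seq_len(n_bins) - 1) * 100,
                  seq_len(n_bins) * 100, gc)
  base <- 1000 * (1 + slope * (gc - 0.4))
  counts <- t(vapply(seq_len(n_samples), function(i) {
    rpois(n_bins, base)
  }, numeric(n_bins)))
  dimnames(counts) <- list(sprintf("s%02d", seq_len(n_samples)),
                           rownames(bins))
  cm <- count_matrix(counts, data.frame(sample_id = rownames(counts),
                                        plate = "P1"))
  list(cm = cm, bins = bins)
}

test_that("loess GC correction flattens a planted mean x (1+2(gc-0.4)) bias", {
  d <- make_biased_training()
  nm <- scale_by_autosomal_total(d$cm, d$bins)
  model <- fit_gc_model(nm, d$bins)
  corrected <- gc_correct(nm, model, d$bins)
  expect_equal(corrected$stage, "GC_CORRECTED")
  med_before <- apply(nm$values, 2, median)
  med_after <- apply(corrected$values, 2, median)
  expect_gt(abs(cor(med_before, d$bins$gc, method = "spearman")), 0.8)
  expect_lt(abs(cor(med_after, d$bins$gc, method = "spearman")), 0.05)
  # the autosomal total is preserved, so representations stay proportions
  expect_equal(rowSums(corrected$values), rowSums(nm$values))
})

test_that("GC correction on bias-free input is close to the identity", {
  # realistic scale: per-bin depth and bin count as in production data, so
  # the per-sample loess wiggle stays within the 1% identity bound
  d <- make_biased_training(n_samples = 10, n_bins = 2000, slope = 0,
                            seed = 12)
  nm <- scale_by_autosomal_total(d$cm, d$bins)
  model <- fit_gc_model(nm, d$bins)
  corrected <- gc_correct(nm, model, d$bins)
  expect_lt(max(abs(corrected$values / nm$values - 1)), 0.01)
})

test_that("degenerate GC (all bins equal) falls back to identity with warning", {
  d <- make_biased_training(slope = 0)
  bins <- d$bins
  bins$gc <- rep(0.4, nrow(bins))
  nm <- scale_by_autosomal_total(d$cm, bins)
  expect_warning(model <- fit_gc_model(nm, bins), "degenerate")
  expect_equal(gc_correct(nm, model, bins)$values, nm$values)
})

test_that("PCA denoising removes a planted rank-1 artifact but not trisomy bins", {
  set.seed(21)
  genome <- sim_genome(sim_config(n_bins_autosome = 20, n_bins_x = 5,
                                  n_bins_y = 4))
  bins <- genome$bins
  n_bins <- nrow(bins)
  n <- 40
  base <- matrix(rpois(n * n_bins, 2000), n, n_bins,
                 dimnames = list(sprintf("s%02d", 1:n), rownames(bins)))
  v <- rnorm(n_bins)
  u <- rnorm(n, sd = 40)
  arte <- base + outer(u, v)
  arte[arte < 0] <- 0
  cm <- count_matrix(arte, data.frame(sample_id = rownames(base), plate = "P1"))
  nm <- scale_by_autosomal_total(cm, bins)
  nm$stage <- "GC_CORRECTED"
  model <- fit_pca(nm, bins, k = 2)
  den <- pca_denoise(nm, model)
  # residual variance along the planted direction collapses on modeled bins
  vm <- v[model$cols] / sqrt(sum(v[model$cols]^2))
  proj_before <- as.numeric(nm$values[, model$cols] %*% vm)
  proj_after <- as.numeric(den$values[, model$cols] %*% vm)
  expect_lt(var(proj_after) / var(proj_before), 0.05)
  # chromosome 21 bins are outside the model and untouched
  chr21 <- which(bins$chrom == "21")
  expect_equal(den$values[, chr21], nm$values[, chr21])
  # k = 0 is the identity
  model0 <- fit_pca(nm, bins, k = 0)
  expect_equal(pca_denoise(nm, model0)$values, nm$values)
  expect_error(fit_pca(nm, bins, k = n), "training size")
})

test_that("smoothing clamps isolated outliers and leaves structure alone", {
  set.seed(31)
  n_bins <- 60
  bins <- toy_bins(n_bins)
  n <- 30
  vals <- matrix(rpois(n * n_bins, 5000) / 5000, n, n_bins,
                 dimnames = list(sprintf("s%02d", 1:n), rownames(bins)))
  nm <- new_nm_for_test(vals, "DENOISED")
  model <- fit_smooth_model(nm, bins)
  # sample with a single 10x outlier bin
  spike <- vals
  spike[1, 30] <- 10 * median(vals[1, ])
  sm <- smooth_bins(new_nm_for_test(spike, "DENOISED"), model, bins)
  expect_lt(sm$values[1, 30], 1.2 * median(vals[1, ]))
  # constant input is unchanged
  const <- matrix(1, n, n_bins, dimnames = dimnames(vals))
  sm_const <- smooth_bins(new_nm_for_test(const, "DENOISED"), model, bins)
  expect_equal(sm_const$values, const)
  # chromosome totals move by < 2%
  sm_all <- smooth_bins(nm, model, bins)
  expect_lt(max(abs(rowSums(sm_all$values) / rowSums(vals) - 1)), 0.02)
})

test_that("smoothing suppresses artifact-bin noise in chromosome representations", {
  coh <- sep_cohort()
  ref <- std_ref()
  scaled <- scale_by_autosomal_total(coh$counts, ref$bins)
  corrected <- gc_correct(scaled, ref$gc_model, ref$bins)
  den <- pca_denoise(corrected, ref$pca_model)
  eu <- coh$truth$sample_id[coh$truth$aneuploidy == "EUPLOID"]
  # plant sporadic artifact spikes (bad bins hit different samples): the
  # regime bin-level smoothing exists for
  set.seed(17)
  spiked <- den
  for (i in match(eu, rownames(den$values))) {
    hit <- sample(which(ref$bins$chrom %in% as.character(1:22)), 20)
    spiked$values[i, hit] <- spiked$values[i, hit] * runif(20, 3, 8)
  }
  sm <- smooth_bins(spiked, ref$smooth_model, ref$bins)
  mads_raw <- apply(chromosome_representation(spiked, ref$bins)[eu, 1:22],
                    2, mad)
  mads_sm <- apply(chromosome_representation(sm, ref$bins)[eu, 1:22], 2, mad)
  expect_true(all(mads_sm <= mads_raw))
  # per-bin across-sample spread also drops sharply on clean data
  sm_clean <- smooth_bins(den, ref$smooth_model, ref$bins)
  idx <- which(ref$bins$chrom == "1" & ref$bins$usable)
  bin_mad_raw <- mean(apply(den$values[eu, idx], 2, mad))
  bin_mad_sm <- mean(apply(sm_clean$values[eu, idx], 2, mad))
  expect_lt(bin_mad_sm, 0.8 * bin_mad_raw)
})

test_that("the full normalization is idempotent at fixed models", {
  ref <- std_ref()
  coh <- sep_cohort()
  idx <- 1:4
  cm <- count_matrix(coh$counts$counts[idx, ], coh$counts$samples[idx, ])
  once <- normalize_full(cm, ref)
  twice <- normalize_full(once, ref)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  expect_equal(once$stage, "SMOOTHED")
})

test_that("normalization commutes with sample reordering", {
  ref <- std_ref()
  coh <- sep_cohort()
  idx <- 1:6
  cm <- count_matrix(coh$counts$counts[idx, ], coh$counts$samples[idx, ])
  perm <- c(4, 2, 6, 1, 3, 5)
  cm_perm <- count_matrix(coh$counts$counts[idx[perm], ],
                          coh$counts$samples[idx[perm], ])
  a <- normalize_full(cm, ref)
  b <- normalize_full(cm_perm, ref)
  expect_equal(b$values, a$values[perm, ])
})
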