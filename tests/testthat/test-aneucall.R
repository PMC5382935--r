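test_that("chromosome representations are autosomal-total fractions", {
  bins <- bin_set(c("1", "2", "3", "X"), rep(0, 4), rep(100, 4), rep(0.4, 4))
  vals <- rbind(s1 = c(500, 300, 200, 50))
  colnames(vals) <- rownames(bins)
  nm <- new_nm_for_test(vals, "SCALED")
  reps <- chromosome_representation(nm, bins)
  expect_equal(unname(reps[1, c("1", "2", "3")]), c(0.5, 0.3, 0.2))
  expect_equal(unname(reps[1, "X"]), 0.05)
  # all reads on one chromosome
  vals2 <- rbind(s1 = c(1000, 0, 0, 0))
  colnames(vals2) <- rownames(bins)
  expect_equal(unname(chromosome_representation(
    new_nm_for_test(vals2, "SCALED"), bins)[1, "1"]), 1.0)
})

test_that("autosomal representations sum to one for every sample", {
  res <- sep_results()
  reps <- chromosome_representation(res$normalized, std_ref()$bins)
  expect_equal(unname(rowSums(reps[, as.character(1:22)])),
               rep(1, nrow(reps)), tolerance = 1e-12)
})

test_that("Z-scores follow (x - mu) / sigma with positive-sigma guard", {
  expect_equal(zscore(0.0142, 0.0140, 0.0001), 2.0)
  expect_equal(zscore(0.5, 0.5, 0.01), 0)
  expect_error(zscore(0.5, 0.5, 0), "positive")
})

test_that("trisomy classification uses <=4 negative / >8 positive", {
  expect_equal(classify_trisomy(36.96), "POSITIVE")
  expect_equal(classify_trisomy(5.11), "REVIEW")
  expect_equal(classify_trisomy(2.0), "NEGATIVE")
  # boundaries
  expect_equal(classify_trisomy(4), "NEGATIVE")
  expect_equal(classify_trisomy(8), "REVIEW")
})

test_that("euploid cohort Z-scores are centred with unit-scale spread", {
  coh <- simulate_cohort(list(sim_scenario(60, "EUPLOID")), sim_config(),
                         seed = 909)
  res <- call_cohort(coh$counts, std_ref())
  z <- res$z[, as.character(1:22)]
  expect_lt(abs(median(z)), 0.2)
  expect_gt(mad(as.numeric(z)), 0.6)
  expect_lt(mad(as.numeric(z)), 1.5)
})

test_that("Z is invariant to uniform depth rescaling of a sample", {
  ref <- std_ref()
  coh <- sep_cohort()
  cm1 <- count_matrix(coh$counts$counts[1:8, ], coh$counts$samples[1:8, ])
  cm2 <- cm1
  cm2$counts[1, ] <- cm2$counts[1, ] * 3
  z1 <- cohort_zscores(normalize_full(cm1, ref), ref$bins, ref$chrom_ref)
  z2 <- cohort_zscores(normalize_full(cm2, ref), ref$bins, ref$chrom_ref)
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("expected trisomy Z grows monotonically with fetal fraction", {
  ref <- std_ref()
  ffs <- seq(0.02, 0.20, by = 0.02)
  coh <- simulate_cohort(
    c(lapply(ffs, function(f) sim_scenario(2, "T21", ff = f)),
      list(sim_scenario(40, "EUPLOID"))),
    sim_config(), seed = 77)
  res <- call_cohort(coh$counts, ref)
  t21 <- coh$truth$aneuploidy == "T21"
  z21 <- res$z[coh$truth$sample_id[t21], "21"]
  expect_gt(cor(coh$truth$ff[t21], z21, method = "spearman"), 0.95)
})

test_that("a region spanning a whole chromosome matches the chromosome Z", {
  ref <- std_ref()
  bins <- ref$bins
  whole22 <- data.frame(name = "all22", chrom = "22", start = 0,
                        end = max(bins$end[bins$chrom == "22"]))
  train <- std_training()
  preg <- train$truth$subject == "PREGNANT"
  train_cm <- count_matrix(train$counts$counts[preg, ],
                           train$counts$samples[preg, ])
  nm_train <- normalize_full(train_cm, ref)
  rref <- fit_region_reference(nm_train, bins, whole22)
  coh <- sep_cohort()
  cm <- count_matrix(coh$counts$counts[1:10, ], coh$counts$samples[1:10, ])
  nm <- normalize_full(cm, ref)
  rz <- region_zscores(nm, bins, rref)
  cz <- cohort_zscores(nm, bins, ref$chrom_ref)
  expect_equal(unname(rz[, "all22"]), unname(cz[, "22"]), tolerance = 1e-9)
})

test_that("a fetal DiGeorge-like deletion drives the region Z strongly negative", {
  res <- event_results()
  coh <- event_cohort()
  del <- !is.na(coh$truth$fetal_cnv)
  expect_true(all(res$region_z[coh$truth$sample_id[del], "22q11_like"] < -4))
  eu <- coh$truth$aneuploidy == "EUPLOID" & is.na(coh$truth$fetal_cnv) &
    is.na(coh$truth$maternal_dup) & is.na(coh$truth$global_ab)
  expect_true(all(abs(res$region_z[coh$truth$sample_id[eu], ]) < 4))
})

test_that("region scoring refuses regions without enough usable bins", {
  ref <- std_ref()
  tiny <- data.frame(name = "tiny", chrom = "22", start = 0, end = 100)
  res <- sep_results()
  expect_error(region_representation(res$normalized, ref$bins, tiny),
               "fewer than 5")
})

test_that("binary segmentation finds steps and leaves flat tracks whole", {
  set.seed(5)
  flat <- rnorm(100, 1, 0.02)
  seg_flat <- segment_track(flat)
  expect_equal(nrow(seg_flat$segments), 1)
  step <- c(rnorm(40, 1, 0.02), rnorm(20, 1.5, 0.02), rnorm(40, 1, 0.02))
  seg <- segment_track(step)
  expect_equal(nrow(seg$segments), 3)
  expect_equal(seg$segments$start[2], 41, tolerance = 2)
  expect_equal(seg$segments$mean[2], 1.5, tolerance = 0.05)
})

test_that("ideogram tracks show whole-chromosome trisomy as one elevated segment", {
  ref <- std_ref()
  coh <- simulate_cohort(list(sim_scenario(1, "T21", ff = 0.10),
                              sim_scenario(11, "EUPLOID")),
                         sim_config(), seed = 88)
  nm <- normalize_full(coh$counts, ref)
  t21_id <- coh$truth$sample_id[coh$truth$aneuploidy == "T21"]
  tr <- ideogram(nm, "21", ref$bin_medians, ref$bins, sample = t21_id)
  segs <- attr(tr, "segments")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$mean, 1.05, tolerance = 0.01)
  eu_id <- coh$truth$sample_id[coh$truth$aneuploidy == "EUPLOID"][1]
  tr_eu <- ideogram(nm, "21", ref$bin_medians, ref$bins, sample = eu_id)
  segs_eu <- attr(tr_eu, "segments")
  expect_equal(nrow(segs_eu), 1)
  expect_gt(mean(tr_eu$ratio), 0.99)
  expect_lt(mean(tr_eu$ratio), 1.01)
})

test_that("partial-duplication detection separates segmental from whole-chromosome gains", {
  # maternal one-copy gain over 10% of chr21: elevated segment ~1.45
  res <- event_results()
  coh <- event_cohort()
  dup_ids <- coh$truth$sample_id[!is.na(coh$truth$maternal_dup)]
  for (sid in dup_ids) {
    tr <- res$tracks[[paste0(sid, ":21")]]
    expect_false(is.null(tr))
    segs <- attr(tr, "segments")
    expect_true(any(segs$mean > 1.3))
    expect_true(detect_partial_duplication(tr, "POSITIVE"))
  }
  # synthetic whole-chromosome elevation must not flag
  whole <- structure(data.frame(bin = 1:100, start = 1:100,
                                ratio = rep(1.05, 100), segment = 1),
                     segments = data.frame(segment = 1, start = 1, end = 100,
                                           mean = 1.05),
                     class = c("ideogram_track", "data.frame"))
  expect_false(detect_partial_duplication(whole, "POSITIVE"))
  flat <- structure(data.frame(bin = 1:100, start = 1:100,
                               ratio = rep(1, 100), segment = 1),
                    segments = data.frame(segment = 1, start = 1, end = 100,
                                          mean = 1.0),
                    class = c("ideogram_track", "data.frame"))
  expect_false(detect_partial_duplication(flat, "NEGATIVE"))
})

test_that("the global screen needs three off-target chromosomes beyond |Z| = 8", {
  z <- setNames(rep(0, 22), as.character(1:22))
  z[c("3", "9")] <- c(9, 10); z["21"] <- 21
  z[c("4", "6", "11")] <- c(-9, -8.5, -9)
  expect_true(global_screen(z))
  only21 <- setNames(rep(0, 22), as.character(1:22)); only21["21"] <- 21
  expect_false(global_screen(only21))
  two <- only21; two[c("3", "9")] <- 9
  expect_false(global_screen(two))
  three <- two; three["5"] <- -8.1
  expect_true(global_screen(three))
})

test_that("the bundled hg19 microdeletion region asset parses", {
  path <- system.file("extdata", "regions_hg19.tsv", package = "cfnips")
  regs <- load_regions(path)
  expect_setequal(regs$name, c("1p36", "22q11_DiGeorge"))
  expect_true(all(regs$end > regs$start))
  expect_true(all(regs$chrom %in% c("1", "22")))
})
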