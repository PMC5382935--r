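make_adult_counts <- function(y_means, n = 12, autosomal = 5000, plate = "P1") {
  # deterministic counts matching requested Y-bin means exactly
  bins <- bin_set(c("1", rep("Y", length(y_means))),
                  c(0, (seq_along(y_means) - 1) * 100),
                  c(100, seq_along(y_means) * 100),
                  rep(0.4, length(y_means) + 1))
  counts <- cbind(rep(autosomal, n),
                  matrix(rep(y_means, each = n), nrow = n))
  dimnames(counts) <- list(sprintf("s%02d", seq_len(n)), rownames(bins))
  list(cm = count_matrix(counts, data.frame(sample_id = rownames(counts),
                                            plate = plate)),
       bins = bins)
}

test_that("Y-bin selection applies the fivefold and 150-read rules conjunctively", {
  male <- make_adult_counts(c(200, 120, 500))
  female <- make_adult_counts(c(10, 1, 150))
  ref <- select_y_bins(male$cm, female$cm, male$bins)
  # 200 > 5 x 10 and > 150 -> kept; 120 fails 150; 500 fails 5 x 150
  expect_equal(length(ref$bins), 1)
  expect_equal(unname(ref$male_mean), 200)

  none_m <- make_adult_counts(c(100, 100))
  none_f <- make_adult_counts(c(90, 90))
  expect_error(select_y_bins(none_m$cm, none_f$cm, none_m$bins),
               "fold-over-female")
  expect_error(select_y_bins(count_matrix(male$cm$counts[1:5, ],
                                          male$cm$samples[1:5, ]),
                             female$cm, male$bins), ">= 10")
})

test_that("genetic sex calls respond to Y signal and are depth-invariant", {
  ref <- std_ref()
  # female background level -> FEMALE
  expect_equal(call_genetic_sex(ref$y_ref$background, ref$y_ref), "FEMALE")
  coh <- simulate_cohort(list(sim_scenario(3, sex = "XY", ff = 0.10),
                              sim_scenario(3, sex = "XX")),
                         sim_config(), seed = 55)
  y_norm <- normalized_y_count(coh$counts, ref$bins, ref$y_ref)
  calls <- call_genetic_sex(y_norm, ref$y_ref)
  expect_equal(unname(calls[coh$truth$sex_karyotype == "XY"]),
               rep("MALE", 3))
  expect_equal(unname(calls[coh$truth$sex_karyotype == "XX"]),
               rep("FEMALE", 3))
  # 10x depth leaves the normalized Y count, hence the call, unchanged
  cm10 <- coh$counts
  cm10$counts <- cm10$counts * 10
  expect_equal(call_genetic_sex(normalized_y_count(cm10, ref$bins, ref$y_ref),
                                ref$y_ref), calls)
})

test_that("the Y background/slope model recovers a noiseless line exactly", {
  ffx <- c(rep(0, 10), seq(0.05, 0.25, length.out = 10))
  is_male <- c(rep(FALSE, 10), rep(TRUE, 10))
  y <- 0.001 + 0.02 * ifelse(is_male, ffx, 0)
  m <- fit_y_model(y, ffx, is_male)
  expect_equal(m$background, 0.001, tolerance = 1e-9)
  expect_equal(m$slope, 0.02, tolerance = 1e-9)
  expect_error(fit_y_model(y, ffx, rep(FALSE, 20)), "male-fetus")
  expect_error(fit_y_model(y, c(rep(0, 10), rep(0.1, 10)), is_male),
               "range")
})

test_that("the fitted Y slope matches simulation within 5%", {
  ref <- std_ref()
  genome <- std_training()$genome
  # analytic slope: d(normalized Y count)/d(FF) for a male fetus
  tr_f <- data.frame(aneuploidy = "EUPLOID", sex_karyotype = "XY", ff = 0,
                     mosaic = 1, twin_ff2 = NA, twin_aneuploidy2 = NA,
                     twin_sex2 = NA, maternal_dup = NA, global_ab = NA,
                     fetal_cnv = NA, subject = "PREGNANT")
  tr_m <- tr_f; tr_m$ff <- 0.2
  mu0 <- expected_bin_means(genome, tr_f)
  mu1 <- expected_bin_means(genome, tr_m)
  bins <- genome$bins
  sel <- ref$y_ref$bins
  yn <- function(mu) sum(mu[match(sel, rownames(bins))]) /
    sum(mu[bins$chrom %in% as.character(1:22)])
  slope_true <- (yn(mu1) - yn(mu0)) / 0.2
  expect_equal(ref$y_model$slope, slope_true, tolerance = 0.05)
})

test_that("sex-aneuploidy classification follows the mixture-plane geometry", {
  cls <- function(...) classify_sex_aneuploidy(...)
  expect_equal(cls(0.12, 0.12, "MALE")$aneuploidy, "NONE")
  expect_equal(cls(0.003, 0.12, "MALE")$aneuploidy, "47XXY")
  expect_equal(cls(0.10, 0.21, "MALE")$aneuploidy, "47XYY")
  expect_equal(cls(0.16, 0.10, "MALE")$aneuploidy, "REVIEW")
  expect_equal(cls(0.005, 0.002, "FEMALE")$aneuploidy, "NONE")
  expect_equal(cls(0.12, 0.001, "FEMALE")$aneuploidy, "45X")
  xxx <- cls(-0.12, 0.001, "FEMALE")
  expect_equal(xxx$aneuploidy, "47XXX")
  expect_true("MATERNAL_XXX_SUSPECTED" %in% xxx$flags)
  # maternal 45,X mosaicism guard suppresses any fetal call
  guard <- cls(0.55, 0.001, "FEMALE")
  expect_equal(guard$genetic_sex, "SUPPRESSED")
  expect_true("MATERNAL_45X_MOSAIC_SUSPECTED" %in% guard$flags)
})

test_that("simulated sex-aneuploidy cohorts classify accurately, erring only to review", {
  res <- sex_results()
  coh <- sex_cohort()
  want <- c(XX = "NONE", XY = "NONE", X = "45X", XXX = "47XXX",
            XXY = "47XXY", XYY = "47XYY")
  got <- res$sex$aneuploidy[match(coh$truth$sample_id, res$sex$sample_id)]
  truth <- want[coh$truth$sex_karyotype]
  expect_gt(mean(got == truth), 0.95)
  expect_true(all(got[got != truth] == "REVIEW"))
  # genetic sex itself is called correctly
  male_k <- coh$truth$sex_karyotype %in% c("XY", "XXY", "XYY")
  sexes <- res$sex$genetic_sex[match(coh$truth$sample_id, res$sex$sample_id)]
  expect_true(all(sexes[male_k] == "MALE"))
  expect_true(all(sexes[!male_k] %in% c("FEMALE", "SUPPRESSED")))
})

test_that("a simulated 45,X fetus shows ffx near true FF and ffy near zero", {
  res <- sex_results()
  coh <- sex_cohort()
  x45 <- coh$truth$sex_karyotype == "X"
  ids <- coh$truth$sample_id[x45]
  ff <- res$ff[match(ids, res$ff$sample_id), ]
  expect_lt(max(abs(ff$ffx - coh$truth$ff[x45])), 0.02)
  expect_lt(max(abs(ff$ffy)), 0.02)
})
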