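#' Select well-performing Y-chromosome bins
#'
#' Most Y bins attract spurious female reads from homologous sequence. A Y
#' bin is kept only when, in adult training data at comparable depth, its
#' mean male read count exceeds fivefold its mean female read count *and*
#' exceeds 150 reads. The female training means over the selected bins give
#' the mis-mapping background used by the sex caller.
#'
#' @param male_training,female_training [count_matrix] objects of adult male
#'   and adult (non-pregnant or female-fetus-pregnant) female samples, >= 10
#'   each.
#' @param bins The [bin_set].
#' @param fold Male/female mean ratio threshold (default 5).
#' @param min_male_reads Absolute male mean threshold (default 150).
#' @return A `y_bin_reference`: selected bin ids, per-bin training means,
#'   and the normalized female background level and MAD.
#' @export
select_y_bins <- function(male_training, female_training, bins, fold = 5,
                          min_male_reads = 150) {
  if (nrow(male_training$counts) < 10 || nrow(female_training$counts) < 10) {
    stop("need >= 10 adult samples per training group")
  }
  y_idx <- which(bins$chrom == "Y" & bins$usable)
  if (!length(y_idx)) stop("bin set has no usable Y bins")
  ids <- rownames(bins)[y_idx]
  m_mean <- colMeans(male_training$counts[, ids, drop = FALSE])
  f_mean <- colMeans(female_training$counts[, ids, drop = FALSE])
  sel <- m_mean > fold * pmax(f_mean, .Machine$double.eps) &
    m_mean > min_male_reads
  if (!any(sel)) {
    fails_fold <- sum(m_mean <= fold * f_mean)
    stop("no Y bin passes selection (",
         if (fails_fold == length(sel)) "fold-over-female criterion"
         else "male read-count criterion", ")")
  }
  sel_ids <- ids[sel]
  yn <- normalized_y_count(female_training, bins, sel_ids)
  structure(list(bins = sel_ids, male_mean = m_mean[sel],
                 female_mean = f_mean[sel],
                 background = stats::median(yn),
                 background_mad = stats::mad(yn)),
            class = "y_bin_reference")
}

#' Normalized Y count over selected bins
#'
#' Sum of counts on the selected Y bins divided by the sample's autosomal
#' total (depth-invariant).
#'
#' @param cm A [count_matrix].
#' @param bins The [bin_set].
#' @param sel_bins Selected Y bin ids (or a `y_bin_reference`).
#' @return Named numeric vector per sample.
#' @export
normalized_y_count <- function(cm, bins, sel_bins) {
  if (inherits(sel_bins, "y_bin_reference")) sel_bins <- sel_bins$bins
  auto <- bins$chrom %in% AUTOSOMES
  rowSums(cm$counts[, sel_bins, drop = FALSE]) /
    rowSums(cm$counts[, auto, drop = FALSE])
}

#' Call genetic sex from the Y signal
#'
#' Male iff the normalized Y count exceeds the female background plus three
#' background MADs (an absolute Y read-count threshold in normalized units).
#'
#' @param y_norm Normalized Y count(s) from [normalized_y_count()].
#' @param y_ref A `y_bin_reference`.
#' @return `"MALE"` / `"FEMALE"` character vector.
#' @export
call_genetic_sex <- function(y_norm, y_ref) {
  thr <- y_ref$background + 3 * y_ref$background_mad
  ifelse(y_norm > thr, "MALE", "FEMALE")
}

#' Fit the Y background/slope model
#'
#' Least-squares line of normalized Y count against the X-based fetal
#' fraction over a training pool: female-fetus samples pin the background
#' (their FF contribution to Y is zero) and male-fetus samples spanning an
#' FF range give the slope. Used for the Y-based fetal-fraction method.
#'
#' @param y_norm Normalized Y counts for the training pool.
#' @param ffx X-based fetal-fraction estimates for the same samples.
#' @param is_male Logical male-fetus indicator.
#' @return A `y_model` with `background`, `slope` and residual SD.
#' @export
fit_y_model <- function(y_norm, ffx, is_male) {
  if (!any(is_male)) stop("Y slope fit needs male-fetus training samples")
  if (!any(!is_male)) stop("Y background fit needs female-fetus training samples")
  x <- ifelse(is_male, ffx, 0)  # female fetus contributes no Y regardless of FF
  if (diff(range(x[is_male])) < 0.05) {
    stop("male training FF range too narrow (< 0.05) for a stable slope")
  }
  fit <- stats::lm(y_norm ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope) || slope <= 0) stop("Y model slope not positive")
  structure(list(background = unname(stats::coef(fit)[1]), slope = slope,
                 residual_sd = stats::sd(stats::residuals(fit))),
            class = "y_model")
}

#' Classify sex-chromosome aneuploidy in the (FFx, FFy) plane
#'
#' The decision geometry follows the expected mixture representations. With
#' a female fetus the Y-based FF is ~0 and the X-based FF is 0 (XX),
#' +FF (45,X: one fetal X missing) or -FF (47,XXX). With a male fetus the
#' Y-based FF tracks the true FF and the X-based FF is equal to it (XY),
#' ~0 (47,XXY: two fetal X copies) or below it (47,XYY: Y-based reads twice
#' the true FF). `tau` is the half-width of all decision bands. Safeguards:
#' an X-based FF above the maternal guard (default 0.5) suppresses any fetal
#' call as suspected maternal 45,X mosaicism; a clearly negative X-based FF
#' carries a maternal 47,XXX flag.
#'
#' @param ffx X-based fetal fraction.
#' @param ffy Y-based fetal fraction.
#' @param genetic_sex `"MALE"`/`"FEMALE"` from [call_genetic_sex()].
#' @param tau Decision band half-width (default 0.02).
#' @param maternal_guard X-based FF bound for the maternal-mosaicism guard.
#' @return List `genetic_sex` (possibly `"SUPPRESSED"`), `aneuploidy` (one
#'   of `NONE`, `45X`, `47XXX`, `47XXY`, `47XYY`, `REVIEW`) and `flags`.
#' @export
classify_sex_aneuploidy <- function(ffx, ffy, genetic_sex, tau = 0.02,
                                    maternal_guard = 0.5) {
  flags <- character(0)
  if (ffx > maternal_guard) {
    return(list(genetic_sex = "SUPPRESSED", aneuploidy = "REVIEW",
                flags = "MATERNAL_45X_MOSAIC_SUSPECTED"))
  }
  if (genetic_sex == "MALE") {
    aneu <- if (abs(ffx - ffy) <= tau) {
      "NONE"
    } else if (ffx <= tau && ffy > tau) {
      "47XXY"
    } else if (ffx > tau && ffy > ffx + tau) {
      "47XYY"
    } else {
      "REVIEW"
    }
  } else {
    aneu <- if (abs(ffx) <= tau) {
      "NONE"
    } else if (ffx > tau) {
      "45X"
    } else {
      flags <- c(flags, "MATERNAL_XXX_SUSPECTED")
      "47XXX"
    }
  }
  list(genetic_sex = genetic_sex, aneuploidy = aneu, flags = flags)
}
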