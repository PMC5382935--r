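# X/Y bin summaries used by the fetal-fraction estimators. All values are
# per-bin counts normalized by the sample's autosomal total, so every
# estimator is invariant to sequencing depth.
sex_bin_summaries <- function(nm, bins) {
  auto_idx <- which(bins$usable & bins$chrom %in% AUTOSOMES)
  x_idx <- which(bins$usable & bins$chrom == "X")
  denom <- rowSums(nm$values[, auto_idx, drop = FALSE])
  xv <- nm$values[, x_idx, drop = FALSE] / denom
  av <- nm$values[, auto_idx, drop = FALSE] / denom
  list(x_median = apply(xv, 1, stats::median),
       x_mean = rowMeans(xv),
       auto_median = apply(av, 1, stats::median),
       auto_mean = rowMeans(av))
}

#' X-chromosome-based fetal fraction
#'
#' `FF = 2 (1 - X_i / X_f)`, where `X_i` is the sample's median normalized
#' X-bin count and `X_f` the median of the same statistic over female-fetus
#' samples on the run. A male fetus contributes one X per genome instead of
#' two, depressing `X_i` by `FF/2`. Negative values mean X
#' over-representation and are propagated as evidence of maternal X gains
#' (e.g. non-mosaic 47,XXX).
#'
#' @param x_i Sample median normalized X-bin count (from
#'   [sex_bin_summaries()]).
#' @param x_f Female reference level: median over run females, or the
#'   training fallback when the run has none.
#' @return Fetal fraction estimate in (-2, 2).
#' @export
ff_x <- function(x_i, x_f) {
  if (any(x_f <= 0)) stop("non-positive female X reference")
  2 * (1 - x_i / x_f)
}

#' Female X reference level for a run
#'
#' Median of the female-called samples' median X representation on the run;
#' falls back (with a warning) to a training value when no female is
#' available.
#'
#' @param x_median Per-sample median normalized X-bin counts.
#' @param is_female Logical vector of female genetic-sex calls.
#' @param training_x_f Fallback female level from training.
#' @return The reference level `X_f`.
#' @export
run_female_reference <- function(x_median, is_female, training_x_f = NULL) {
  if (any(is_female)) return(stats::median(x_median[is_female]))
  if (is.null(training_x_f)) stop("no female samples on run and no training fallback")
  warning("no female samples on run; using training X reference")
  training_x_f
}

#' The three X-based fetal-fraction variants
#'
#' * `ff_a`: mean-bin formulation, `2 (1 - Xbar / Abar)` with `Xbar` the
#'   average normalized count per X bin and `Abar` the autosomal bin
#'   average, referenced to the run females' ratio.
#' * `ff_b`: median-of-bin formulation of the same contrast (the sample's
#'   median X bin against the run females' median X bin).
#' * `ff_c`: linear interpolation of the sample's X representation between
#'   anchored non-pregnant controls: a two-X-copy female anchor
#'   (FF-equivalent 0) and a single-X-copy male anchor (FF-equivalent 1).
#'
#' @param s Sample summaries ([sex_bin_summaries()] row values): needs
#'   `x_mean`, `x_median`, `auto_mean`.
#' @param run_ref List with `xa_ratio_f` (female mean-bin X/autosome ratio)
#'   and `x_f` (female median X level) for the run.
#' @param anchors List with `x_female` and `x_male` adult-control X levels
#'   (median normalized X-bin count), or `NULL` if unavailable.
#' @return Named list `ff_a`, `ff_b`, `ff_c` (`ff_c` is `NA` without
#'   anchors).
#' @export
ff_x_variants <- function(s, run_ref, anchors = NULL) {
  ff_a <- 2 * (1 - (s$x_mean / s$auto_mean) / run_ref$xa_ratio_f)
  ff_b <- 2 * (1 - s$x_median / run_ref$x_f)
  ff_c <- NA_real_
  if (!is.null(anchors)) {
    if (anchors$x_female <= anchors$x_male) stop("invalid X anchors")
    ff_c <- (anchors$x_female - s$x_median) / (anchors$x_female - anchors$x_male)
  }
  list(ff_a = ff_a, ff_b = ff_b, ff_c = ff_c)
}

#' Y-chromosome-based fetal fraction
#'
#' `ff_d = (normalized Y count - background) / slope`, with background the
#' female-level normalized Y count and slope the increase per unit male
#' fetal fraction, both from [fit_y_model()].
#'
#' @param y_norm Sample normalized Y count over selected Y bins.
#' @param y_model A `y_model` (background, slope).
#' @return Fetal fraction estimate.
#' @export
ff_y <- function(y_norm, y_model) {
  if (y_model$slope <= 0) stop("Y model slope must be positive")
  (y_norm - y_model$background) / y_model$slope
}

#' Median consensus of the four male fetal-fraction methods
#'
#' @param values Numeric vector of available method estimates (NAs dropped);
#'   at least 3 required.
#' @return The median (mean of the middle two when four values).
#' @export
consensus_male_ff <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("need >= 3 fetal-fraction method values, got ", length(values))
  }
  stats::median(values)
}

#' Fit the female-fetus fetal-fraction regression
#'
#' Male-fetus training samples, whose fetal fraction is known from the X/Y
#' consensus, are used to learn an L1-regularized (lasso) linear model of
#' fetal fraction on autosomal bin counts normalized by the sample total but
#' *not* GC-corrected. Bins on chromosomes 13, 18, 21, X and Y are excluded
#' so the features carry no aneuploidy or sex signal. The penalty is chosen
#' by 10-fold cross-validation at `alpha = 1` (`lambda.min`).
#'
#' @param cm Training [count_matrix] of male-fetus samples (>= 50).
#' @param bins The [bin_set].
#' @param ff Consensus fetal fractions for the training samples.
#' @param nfolds CV folds (default 10).
#' @return A `female_ff_model` wrapping the fitted `cv.glmnet` object and
#'   the feature column ids.
#' @export
fit_female_ff_model <- function(cm, bins, ff, nfolds = 10) {
  if (nrow(cm$counts) < 50) stop("need >= 50 male-fetus training samples")
  if (stats::sd(ff) == 0) stop("degenerate training response (constant FF)")
  cols <- which(bins$usable &
                  bins$chrom %in% setdiff(AUTOSOMES, c("13", "18", "21")))
  x <- cm$counts[, cols, drop = FALSE] / rowSums(cm$counts)
  # deterministic fold assignment so a fitted reference does not depend on
  # ambient RNG state
  foldid <- with_seed(1L, sample(rep_len(seq_len(nfolds), nrow(x))))
  fit <- glmnet::cv.glmnet(x, ff, alpha = 1, foldid = foldid)
  structure(list(fit = fit, cols = colnames(cm$counts)[cols]),
            class = "female_ff_model")
}

#' Predict fetal fraction for female-fetus samples
#' @param cm [count_matrix] of samples to predict.
#' @param model A `female_ff_model`.
#' @return Numeric vector of fetal-fraction predictions.
#' @export
ff_female <- function(cm, model) {
  if (!is.null(model$fit)) {
    x <- cm$counts[, model$cols, drop = FALSE] / rowSums(cm$counts)
    return(as.numeric(stats::predict(model$fit, newx = x, s = "lambda.min")))
  }
  # deserialized form: sparse linear predictor
  feats <- as.character(unlist(model$features))
  if (!length(feats)) return(rep(model$intercept, nrow(cm$counts)))
  x <- cm$counts[, feats, drop = FALSE] / rowSums(cm$counts)
  as.numeric(x %*% as.numeric(unlist(model$coef)) + model$intercept)
}

#' Fetal-fraction reporting gate
#'
#' Results are only reported when the final fetal fraction reaches the 5%
#' threshold (inclusive at exactly 0.05).
#'
#' @param ff Final fetal fraction.
#' @param threshold Gate value (default 0.05).
#' @return `"PASS"` or `"LOW_FF"`.
#' @export
ff_gate <- function(ff, threshold = 0.05) {
  ifelse(ff < threshold, "LOW_FF", "PASS")
}
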