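STAGES <- c("SCALED", "GC_CORRECTED", "DENOISED", "SMOOTHED")

new_normalized <- function(values, samples, stage) {
  stopifnot(stage %in% STAGES)
  structure(list(values = values, samples = samples, stage = stage),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix [%s]: %d samples x %d bins\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

stage_index <- function(stage) match(stage, STAGES)

# Stage tags only advance: a stage already applied is skipped, so running the
# full normalization on its own output is an exact no-op.
stage_done <- function(nm, stage) stage_index(nm$stage) >= stage_index(stage)

#' Scale counts by the sample's autosomal total
#'
#' First normalization stage: each bin count is divided by the sum of that
#' sample's counts on chromosomes 1-22, so autosomal values sum to 1 per
#' sample and samples become comparable across sequencing depths.
#'
#' @param cm A [count_matrix].
#' @param bins Matching [bin_set].
#' @return A `normalized_matrix` at stage `SCALED`.
#' @export
scale_by_autosomal_total <- function(cm, bins) {
  check_bins_match(cm, bins)
  auto <- bins$chrom %in% AUTOSOMES
  tot <- rowSums(cm$counts[, auto, drop = FALSE])
  if (any(tot <= 0)) {
    stop("zero autosomal total for sample(s): ",
         paste(rownames(cm$counts)[tot <= 0], collapse = ", "))
  }
  new_normalized(cm$counts / tot, cm$samples, "SCALED")
}

#' Fit the GC-bias reference curve
#'
#' Fits a local polynomial (loess) curve of the per-bin training median
#' scaled count against bin GC fraction, over usable autosomal bins. The
#' curve records the expected count level at each GC value and the observed
#' GC range; evaluation outside the range uses the nearest endpoint.
#'
#' @param nm Training `normalized_matrix` at stage `SCALED`.
#' @param bins The [bin_set].
#' @param span,degree Loess parameters (defaults 0.3, 2).
#' @return A `gc_model` with the fitted curve, span/degree and GC range.
#' @export
fit_gc_model <- function(nm, bins, span = 0.3, degree = 2) {
  use <- bins$usable & bins$chrom %in% AUTOSOMES
  if (sum(use) < 100) stop("need >= 100 usable autosomal bins to fit GC model")
  gc <- bins$gc[use]
  if (stats::sd(gc) == 0) {
    warning("degenerate GC (all bins equal); GC correction will be identity")
    return(structure(list(degenerate = TRUE, span = span, degree = degree),
                     class = "gc_model"))
  }
  med <- apply(nm$values[, use, drop = FALSE], 2, stats::median)
  fit <- stats::loess(med ~ gc, span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(gc), max(gc), length.out = 101)
  structure(list(degenerate = FALSE, span = span, degree = degree,
                 gc_range = range(gc), grid_gc = grid,
                 grid_fit = stats::predict(fit, data.frame(gc = grid))),
            class = "gc_model")
}

# loess prediction with endpoint clamping of gc, as a correction factor
loess_factor <- function(value, gc, span, degree, eval_gc) {
  fit <- stats::loess(value ~ gc, span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  expected <- stats::predict(fit, data.frame(gc = pmin(pmax(eval_gc, min(gc)),
                                                       max(gc))))
  expected
}

#' Correct GC bias
#'
#' GC bias differs from sample to sample (library preparation and flow-cell
#' chemistry drift), so each sample is corrected against its own loess fit of
#' scaled count versus bin GC over usable autosomal bins: corrected value =
#' value x (mean expected level / expected level at the bin's GC). X and Y
#' bins are corrected with the same curve evaluated at their GC (clamped to
#' the fitted GC range). After correction each row is renormalized to its
#' pre-correction autosomal total, so chromosome representation remains a
#' proportion.
#'
#' @param nm A `normalized_matrix` at stage `SCALED`.
#' @param model A `gc_model` from [fit_gc_model()] (supplies span/degree and
#'   the degenerate-GC flag).
#' @param bins The [bin_set].
#' @return A `normalized_matrix` at stage `GC_CORRECTED`.
#' @export
gc_correct <- function(nm, model, bins) {
  if (stage_done(nm, "GC_CORRECTED")) return(nm)
  vals <- nm$values
  if (isTRUE(model$degenerate)) {
    return(new_normalized(vals, nm$samples, "GC_CORRECTED"))
  }
  use <- bins$usable & bins$chrom %in% AUTOSOMES
  corr_cols <- bins$usable  # correct all usable bins, incl. X/Y
  gc_fit <- bins$gc[use]
  gc_all <- bins$gc[corr_cols]
  auto <- bins$chrom %in% AUTOSOMES
  for (i in seq_len(nrow(vals))) {
    pre_total <- sum(vals[i, auto])
    expected <- loess_factor(vals[i, use], gc_fit, model$span, model$degree,
                             gc_all)
    expected <- pmax(expected, 1e-12)
    # global mean expected level, taken over the (autosomal) fit bins
    global_mean <- mean(expected[auto[corr_cols]])
    corrected <- vals[i, corr_cols] * (global_mean / expected)
    corrected[corrected < 0] <- 0
    vals[i, corr_cols] <- corrected
    # preserve the autosomal total so representations stay proportions
    vals[i, auto] <- vals[i, auto] * (pre_total / sum(vals[i, auto]))
  }
  new_normalized(vals, nm$samples, "GC_CORRECTED")
}

#' Fit the PCA artifact model
#'
#' Principal components are fitted on GC-corrected values of presumed-euploid
#' training samples, over usable autosomal bins excluding chromosomes 13, 18
#' and 21 so that trisomy signal cannot be absorbed into the component
#' subspace.
#'
#' @param nm Training `normalized_matrix` at stage `GC_CORRECTED`.
#' @param bins The [bin_set].
#' @param k Number of components to retain (default 5; `k = 0` disables).
#' @param exclude_chroms Chromosomes whose bins are left out of the model.
#' @return A `pca_model` (loadings, training mean, modeled column mask).
#' @export
fit_pca <- function(nm, bins, k = 5, exclude_chroms = c("13", "18", "21")) {
  n <- nrow(nm$values)
  if (k >= n) stop("k (", k, ") must be smaller than the training size (", n, ")")
  use <- bins$usable & bins$chrom %in% setdiff(AUTOSOMES, exclude_chroms)
  x <- nm$values[, use, drop = FALSE]
  center <- colMeans(x)
  rot <- NULL
  if (k > 0) {
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
    rot <- pr$rotation
  }
  structure(list(k = k, rotation = rot, center = center, cols = which(use)),
            class = "pca_model")
}

#' Remove high-order artifacts with a fitted PCA model
#'
#' Each sample (restricted to the modeled bins) is mean-centred, its
#' projection onto the top-k component subspace removed, and the training
#' mean added back. Bins outside the model (chromosomes 13/18/21, sex
#' chromosomes, masked bins) are untouched. `k = 0` is the identity.
#'
#' @param nm A `normalized_matrix` at stage `GC_CORRECTED`.
#' @param model A `pca_model` from [fit_pca()].
#' @return A `normalized_matrix` at stage `DENOISED`.
#' @export
pca_denoise <- function(nm, model) {
  if (stage_done(nm, "DENOISED")) return(nm)
  vals <- nm$values
  if (model$k > 0) {
    x <- vals[, model$cols, drop = FALSE]
    d <- sweep(x, 2, model$center)
    proj <- (d %*% model$rotation) %*% t(model$rotation)
    vals[, model$cols] <- sweep(d - proj, 2, model$center, "+")
    vals[vals < 0] <- 0
  }
  new_normalized(vals, nm$samples, "DENOISED")
}

#' Fit bin-level smoothing limits
#'
#' Records, per chromosome, the training 1st/99th percentiles of the ratio
#' of a bin's value to its local (5-bin rolling-median) level. Expressing
#' limits relative to the local level makes winsorization invariant both to
#' whole-chromosome copy shifts (a trisomic chromosome is uniformly elevated
#' and must not be clamped) and to genuine multi-bin copy-number segments
#' (a maternal segmental duplication must survive so the ideogram can show
#' it), while still taming single-bin outliers.
#'
#' @param nm Training `normalized_matrix` (stage `DENOISED` or earlier).
#' @param bins The [bin_set].
#' @param probs Quantile pair, default `c(0.01, 0.99)`.
#' @param k Rolling-median window used for the local level (default 5).
#' @return A `smooth_model` with per-chromosome ratio limits.
#' @export
fit_smooth_model <- function(nm, bins, probs = c(0.01, 0.99), k = 5) {
  lims <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch & bins$usable)
    if (length(idx) < k) next
    x <- nm$values[, idx, drop = FALSE]
    local <- t(apply(x, 1, stats::runmed, k = k, endrule = "median"))
    ratio <- x / pmax(local, 1e-15)
    lims[[ch]] <- stats::quantile(ratio, probs, names = FALSE)
  }
  structure(list(limits = lims, probs = probs, k = k), class = "smooth_model")
}

#' Winsorize and roll-median bin values
#'
#' Final normalization stage: per chromosome, each sample's bin values are
#' clamped at the training ratio limits (relative to the local rolling
#' median) and passed through a centred rolling median (window `k`).
#' Chromosomes with fewer than `k` usable bins pass through unchanged.
#'
#' @param nm A `normalized_matrix` at stage `DENOISED`.
#' @param model A `smooth_model` from [fit_smooth_model()].
#' @param bins The [bin_set].
#' @param k Rolling-median window (odd, default 5).
#' @return A `normalized_matrix` at stage `SMOOTHED`.
#' @export
smooth_bins <- function(nm, model, bins, k = 5) {
  if (stage_done(nm, "SMOOTHED")) return(nm)
  vals <- nm$values
  for (ch in names(model$limits)) {
    idx <- which(bins$chrom == ch & bins$usable)
    if (length(idx) < k) next
    lim <- model$limits[[ch]]
    for (i in seq_len(nrow(vals))) {
      x <- vals[i, idx]
      local <- stats::runmed(x, k, endrule = "median")
      x <- pmin(pmax(x, lim[1] * local), lim[2] * local)
      vals[i, idx] <- stats::runmed(x, k, endrule = "median")
    }
  }
  new_normalized(vals, nm$samples, "SMOOTHED")
}

#' Run the full normalization pipeline with fitted models
#'
#' scale -> GC-correct -> PCA-denoise -> smooth. Stages already present in
#' the input are skipped (stage tags only advance), so the pipeline is
#' idempotent at fixed models.
#'
#' @param x A [count_matrix] or a partially normalized `normalized_matrix`.
#' @param ref A `nips_reference` from [train_nips()] (or any list with
#'   `bins`, `gc_model`, `pca_model`, `smooth_model`, `config`).
#' @return A `normalized_matrix` at stage `SMOOTHED`.
#' @export
normalize_full <- function(x, ref) {
  nm <- if (inherits(x, "count_matrix")) {
    scale_by_autosomal_total(x, ref$bins)
  } else x
  nm <- gc_correct(nm, ref$gc_model, ref$bins)
  nm <- pca_denoise(nm, ref$pca_model)
  smooth_bins(nm, ref$smooth_model, ref$bins, k = ref$config$smooth_k)
}
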