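SCHEMA_TAG <- "cfnips-reference/1"

#' Serialize a fitted reference to JSON
#'
#' Writes a versioned, documented JSON container holding everything needed
#' to score new samples: the bin table with the fitted usability mask, GC
#' curve knots, PCA loadings and centre, winsorization limits, chromosome
#' and region references, Y-bin reference, Y background/slope model, X
#' anchors and the female fetal-fraction model as its selected
#' coefficients.
#'
#' @param ref A `nips_reference` from [train_nips()].
#' @param path Output JSON path.
#' @export
save_reference <- function(ref, path) {
  fm <- NULL
  if (!is.null(ref$female_ff_model)) {
    cf <- stats::coef(ref$female_ff_model$fit, s = "lambda.min")
    nz <- which(as.numeric(cf)[-1] != 0)
    fm <- list(intercept = as.numeric(cf)[1],
               features = ref$female_ff_model$cols[nz],
               coef = as.numeric(cf)[-1][nz],
               all_cols = ref$female_ff_model$cols)
  }
  obj <- list(
    schema = SCHEMA_TAG,
    config = ref$config,
    bins = as.data.frame(ref$bins),
    gc_model = unclass(ref$gc_model),
    pca_model = list(k = ref$pca_model$k,
                     rotation = ref$pca_model$rotation,
                     center = ref$pca_model$center,
                     cols = ref$pca_model$cols),
    smooth_model = unclass(ref$smooth_model),
    chrom_ref = list(median = as.list(ref$chrom_ref$median),
                     sigma = as.list(ref$chrom_ref$sigma),
                     n_training = ref$chrom_ref$n_training),
    region_ref = if (!is.null(ref$region_ref)) {
      list(median = as.list(ref$region_ref$median),
           sigma = as.list(ref$region_ref$sigma),
           regions = ref$region_ref$regions)
    },
    bin_medians = as.list(ref$bin_medians),
    y_ref = if (!is.null(ref$y_ref)) {
      list(bins = ref$y_ref$bins,
           male_mean = as.list(ref$y_ref$male_mean),
           female_mean = as.list(ref$y_ref$female_mean),
           background = ref$y_ref$background,
           background_mad = ref$y_ref$background_mad)
    },
    y_model = if (!is.null(ref$y_model)) unclass(ref$y_model),
    anchors = ref$anchors,
    training_x_f = ref$training_x_f,
    training_xa_ratio_f = ref$training_xa_ratio_f,
    female_ff_model = fm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_reference
#' @return `load_reference` returns a `nips_reference` equivalent for
#'   scoring (the female model becomes a sparse linear predictor).
#' @export
load_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, SCHEMA_TAG)) {
    stop("unrecognized reference schema: ", obj$schema)
  }
  bins <- bin_set(obj$bins$chrom, obj$bins$start, obj$bins$end, obj$bins$gc,
                  obj$bins$usable)
  pca <- obj$pca_model
  if (!is.null(pca$rotation)) pca$rotation <- as.matrix(pca$rotation)
  class(pca) <- "pca_model"
  gcm <- obj$gc_model
  class(gcm) <- "gc_model"
  sm <- obj$smooth_model
  sm$limits <- lapply(sm$limits, as.numeric)
  class(sm) <- "smooth_model"
  cr <- obj$chrom_ref
  cr$median <- unlist(cr$median); cr$sigma <- unlist(cr$sigma)
  class(cr) <- "chrom_reference"
  rr <- obj$region_ref
  if (!is.null(rr)) {
    rr$median <- unlist(rr$median); rr$sigma <- unlist(rr$sigma)
    class(rr) <- "region_reference"
  }
  yr <- obj$y_ref
  if (!is.null(yr)) {
    yr$male_mean <- unlist(yr$male_mean)
    yr$female_mean <- unlist(yr$female_mean)
    class(yr) <- "y_bin_reference"
  }
  ym <- obj$y_model
  if (!is.null(ym)) class(ym) <- "y_model"
  fm <- obj$female_ff_model
  if (!is.null(fm)) {
    fm <- structure(list(intercept = fm$intercept,
                         features = fm$features, coef = fm$coef,
                         cols = fm$all_cols),
                    class = "female_ff_model")
  }
  structure(list(bins = bins, config = do.call(nips_config, obj$config),
                 gc_model = gcm, pca_model = pca, smooth_model = sm,
                 chrom_ref = cr, region_ref = rr,
                 bin_medians = unlist(obj$bin_medians),
                 y_ref = yr, y_model = ym,
                 female_ff_model = fm, anchors = obj$anchors,
                 training_x_f = obj$training_x_f,
                 training_xa_ratio_f = obj$training_xa_ratio_f),
            class = "nips_reference")
}
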