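#' Default pipeline configuration
#'
#' All operational thresholds in one place, overridable and round-trippable
#' through YAML. Values:
#' \describe{
#'   \item{bin_size}{bin width in bp (50 kb).}
#'   \item{min_total_reads}{read-depth gate for any report (9e6).}
#'   \item{min_sex_reads}{read-depth gate for sex-chromosome analyses (4.5e6).}
#'   \item{cv_threshold}{robust-CV ceiling for bin usability (0.3).}
#'   \item{loess_span, loess_degree}{GC-correction loess parameters.}
#'   \item{pca_k}{retained PCA components for artifact removal.}
#'   \item{smooth_k}{rolling-median window (bins).}
#'   \item{z_negative, z_positive}{Z-score call cutoffs (<=4 negative, >8
#'     positive; in between goes to review).}
#'   \item{ff_threshold}{minimum fetal fraction for reporting (0.05,
#'     inclusive).}
#'   \item{sex_tau}{half-width of the decision bands in the (FFx, FFy)
#'     plane (0.02).}
#'   \item{maternal_ff_guard}{X-based FF above which a 45,X signal is treated
#'     as suspected maternal mosaicism (0.5).}
#'   \item{dup_ratio, dup_span}{partial-duplication flag: an elevated segment
#'     with mean ratio > 1.1 covering < 70\% of usable bins.}
#'   \item{global_min_chroms}{chromosomes outside 13/18/21 with |Z| > 8
#'     needed to flag a global abnormality (3).}
#'   \item{min_plate_for_median}{plate size below which the training median
#'     replaces the plate median (8).}
#' }
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
nips_config <- function(...) {
  cfg <- list(
    bin_size = 5e4,
    min_total_reads = 9e6,
    min_sex_reads = 4.5e6,
    cv_threshold = 0.3,
    loess_span = 0.3,
    loess_degree = 2,
    pca_k = 5,
    pca_exclude = c("13", "18", "21"),
    smooth_k = 5,
    winsor_probs = c(0.01, 0.99),
    z_negative = 4,
    z_positive = 8,
    ff_threshold = 0.05,
    sex_tau = 0.02,
    maternal_ff_guard = 0.5,
    dup_ratio = 1.1,
    dup_span = 0.7,
    global_min_chroms = 3,
    min_plate_for_median = 8
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Read / write a configuration as YAML
#' @param path YAML file path.
#' @return For `load_config`, a config list (defaults filled in).
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(nips_config, vals)
}

#' @rdname load_config
#' @param config A config list from [nips_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
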