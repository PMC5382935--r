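#' Chromosome representations
#'
#' A chromosome's representation is its share of the sample's autosomal
#' signal: the sum of its usable-bin values divided by the sum over all
#' usable autosomal bins. X and Y use the same autosomal denominator, so
#' autosomal representations sum to 1 and sex-chromosome representations are
#' comparable across samples.
#'
#' @param nm A `normalized_matrix` (any stage).
#' @param bins The [bin_set].
#' @return Numeric matrix, samples x chromosomes (`"1"`..`"22"`, `"X"`,
#'   `"Y"`).
#' @export
chromosome_representation <- function(nm, bins) {
  usable <- bins$usable
  chroms <- CHROM_LEVELS[CHROM_LEVELS %in% unique(bins$chrom)]
  auto_idx <- which(usable & bins$chrom %in% AUTOSOMES)
  denom <- rowSums(nm$values[, auto_idx, drop = FALSE])
  if (any(denom <= 0)) stop("zero autosomal denominator")
  reps <- sapply(chroms, function(ch) {
    idx <- which(usable & bins$chrom == ch)
    if (!length(idx)) return(rep(0, nrow(nm$values)))
    rowSums(nm$values[, idx, drop = FALSE]) / denom
  })
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1, dimnames = list(NULL, chroms))
  rownames(reps) <- rownames(nm$values)
  reps
}

#' Fit the chromosome Z-score reference
#'
#' Records, per chromosome, the training-cohort median representation (the
#' fallback location when a plate is too small) and the spread sigma =
#' 1.4826 x MAD of the training representations, so Z approximates standard
#' normal units and the <=4 / >8 cutoffs read as SD multiples.
#'
#' @param nm Fully normalized training `normalized_matrix`.
#' @param bins The [bin_set].
#' @return A `chrom_reference` with `median`, `sigma` (named by chromosome)
#'   and the training size.
#' @export
fit_chrom_reference <- function(nm, bins) {
  reps <- chromosome_representation(nm, bins)
  med <- apply(reps, 2, stats::median)
  sigma <- apply(reps, 2, stats::mad)  # 1.4826-scaled by default
  if (any(sigma[colnames(reps) %in% AUTOSOMES] <= 0)) {
    stop("non-positive training MAD for chromosome(s): ",
         paste(colnames(reps)[sigma <= 0 & colnames(reps) %in% AUTOSOMES],
               collapse = ", "))
  }
  structure(list(median = med, sigma = sigma, n_training = nrow(reps)),
            class = "chrom_reference")
}

#' Robust Z-score
#'
#' `Z = (x - mu) / sigma` with mu the plate median representation and sigma
#' the training MAD (1.4826-scaled).
#'
#' @param x Sample chromosome (or region) representation.
#' @param mu Plate-median representation.
#' @param sigma Training spread; must be positive.
#' @return The Z-score.
#' @export
zscore <- function(x, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  (x - mu) / sigma
}

# Plate-median location per chromosome: plates with fewer than `min_n`
# samples fall back to the training median.
plate_mu <- function(reps, plates, reference, min_n = 8) {
  mu <- matrix(rep(reference$median[colnames(reps)], each = nrow(reps)),
               nrow = nrow(reps), dimnames = dimnames(reps))
  for (p in unique(plates)) {
    idx <- which(plates == p)
    if (length(idx) >= min_n) {
      mu[idx, ] <- rep(apply(reps[idx, , drop = FALSE], 2, stats::median),
                       each = length(idx))
    }
  }
  mu
}

#' Chromosome Z-scores for a cohort
#'
#' @param nm Fully normalized `normalized_matrix` for the cohort.
#' @param bins The [bin_set].
#' @param reference A `chrom_reference` from [fit_chrom_reference()].
#' @param min_plate Minimum plate size for the plate-median location.
#' @return Matrix of Z-scores, samples x chromosomes.
#' @export
cohort_zscores <- function(nm, bins, reference, min_plate = 8) {
  reps <- chromosome_representation(nm, bins)
  mu <- plate_mu(reps, nm$samples$plate, reference, min_plate)
  sweep(reps - mu, 2, reference$sigma[colnames(reps)], "/")
}

#' Classify a trisomy Z-score
#'
#' `Z <= 4` is negative, `Z > 8` positive, anything in between goes to
#' review (boundaries: Z = 4 is negative, Z = 8 is review).
#'
#' @param z Z-score(s).
#' @param z_negative,z_positive Cutoffs (defaults 4 and 8).
#' @return Character vector in `{NEGATIVE, REVIEW, POSITIVE}`.
#' @export
classify_trisomy <- function(z, z_negative = 4, z_positive = 8) {
  ifelse(z <= z_negative, "NEGATIVE", ifelse(z > z_positive, "POSITIVE", "REVIEW"))
}

#' Microdeletion/duplication region definitions
#'
#' Regions are scored like chromosomes, with the predefined interval as the
#' unit: the representation is the sum of usable bins overlapping the region
#' over the autosomal total. The file format is BED-like: name, chrom,
#' start, end (tab-separated, with header).
#'
#' @param path TSV with columns `name`, `chrom`, `start`, `end`.
#' @return `data.frame` of regions.
#' @export
load_regions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(df)))
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df
}

region_bin_index <- function(region, bins) {
  which(bins$usable & bins$chrom == region$chrom &
          bins$start < region$end & bins$end > region$start)
}

#' Region representations for a cohort
#' @param nm Normalized matrix.
#' @param bins The [bin_set].
#' @param regions Region table from [load_regions()].
#' @return Matrix samples x regions of representations.
#' @export
region_representation <- function(nm, bins, regions) {
  auto_idx <- which(bins$usable & bins$chrom %in% AUTOSOMES)
  denom <- rowSums(nm$values[, auto_idx, drop = FALSE])
  out <- sapply(seq_len(nrow(regions)), function(r) {
    idx <- region_bin_index(regions[r, ], bins)
    if (length(idx) < 5) {
      stop("region ", regions$name[r], " overlaps fewer than 5 usable bins")
    }
    rowSums(nm$values[, idx, drop = FALSE]) / denom
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(nm$values), regions$name)
  out
}

#' Fit a Z-score reference for predefined regions
#' @inheritParams region_representation
#' @return A `region_reference` (per-region training median and MAD sigma).
#' @export
fit_region_reference <- function(nm, bins, regions) {
  reps <- region_representation(nm, bins, regions)
  structure(list(median = apply(reps, 2, stats::median),
                 sigma = apply(reps, 2, stats::mad),
                 regions = regions),
            class = "region_reference")
}

#' Region Z-scores for a cohort
#'
#' Negative Z indicates a deletion, positive a duplication.
#'
#' @param nm Normalized matrix.
#' @param bins The [bin_set].
#' @param reference A `region_reference`.
#' @param min_plate Minimum plate size for the plate-median location.
#' @return Matrix samples x regions of Z-scores.
#' @export
region_zscores <- function(nm, bins, reference, min_plate = 8) {
  reps <- region_representation(nm, bins, reference$regions)
  mu <- plate_mu(reps, nm$samples$plate,
                 list(median = reference$median), min_plate)
  sweep(reps - mu, 2, reference$sigma[colnames(reps)], "/")
}

#' Per-bin euploid medians for ideogram tracks
#' @param nm Fully normalized training matrix.
#' @return Named vector of per-bin training medians.
#' @export
fit_bin_medians <- function(nm) apply(nm$values, 2, stats::median)

#' Ideogram track for one chromosome
#'
#' The track is the sample's normalized bin values divided by the euploid
#' training bin medians (euploid expectation 1.0), segmented by recursive
#' binary change-point splitting on segment means.
#'
#' @param nm_row One-sample `normalized_matrix` (or a multi-sample one plus
#'   `sample`).
#' @param chrom Chromosome label.
#' @param bin_medians Training medians from [fit_bin_medians()].
#' @param bins The [bin_set].
#' @param sample Sample id (defaults to the first row).
#' @param penalty Segmentation penalty multiplier (see [segment_track()]).
#' @return An `ideogram_track`: data.frame (`bin`, `start`, `ratio`,
#'   `segment`) plus a `segments` attribute with per-segment means.
#' @export
ideogram <- function(nm_row, chrom, bin_medians, bins, sample = NULL,
                     penalty = 10) {
  idx <- which(bins$usable & bins$chrom == chrom)
  if (!length(idx)) stop("no usable bins on chromosome ", chrom)
  ids <- rownames(bins)[idx]
  if (is.null(bin_medians) || !all(ids %in% names(bin_medians))) {
    stop("training bin medians missing for chromosome ", chrom)
  }
  i <- if (is.null(sample)) 1L else match(sample, rownames(nm_row$values))
  ratio <- as.numeric(nm_row$values[i, ids] / pmax(bin_medians[ids], 1e-15))
  seg <- segment_track(ratio, penalty = penalty)
  df <- data.frame(bin = ids, start = bins$start[idx], ratio = ratio,
                   segment = seg$assignment)
  structure(df, segments = seg$segments, class = c("ideogram_track",
                                                   "data.frame"))
}

#' Segment a ratio track by recursive binary splitting
#'
#' Greedy change-point detection: each candidate split is accepted when the
#' reduction in within-segment sum of squares exceeds
#' `penalty x sigma^2 x log(n)`, with sigma estimated robustly from
#' first differences. The penalty is calibrated so flat noise tracks yield a
#' single segment; ties break toward fewer segments.
#'
#' @param x Numeric track.
#' @param penalty Penalty multiplier (default 10).
#' @param min_len Minimum segment length in bins (default 3).
#' @return List with `assignment` (segment id per bin) and `segments`
#'   (data.frame of start/end indices and mean ratio).
#' @export
segment_track <- function(x, penalty = 10, min_len = 3) {
  n <- length(x)
  # robust noise level; the global MAD guards against the autocorrelation
  # that bin-level smoothing introduces (first differences alone would
  # underestimate the noise of a smoothed track and over-segment it)
  sigma2 <- max((stats::mad(diff(x)) / sqrt(2))^2, stats::mad(x)^2)
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- stats::var(x) + 1e-12
  thresh <- penalty * sigma2 * log(max(n, 2))
  bounds <- list(c(1L, n))
  done <- list()
  while (length(bounds)) {
    b <- bounds[[1]]; bounds <- bounds[-1]
    lo <- b[1]; hi <- b[2]; len <- hi - lo + 1
    if (len < 2 * min_len) { done[[length(done) + 1]] <- b; next }
    seg <- x[lo:hi]
    sse0 <- sum((seg - mean(seg))^2)
    cs <- cumsum(seg); tot <- cs[len]
    ks <- min_len:(len - min_len)
    nl <- ks; nr <- len - ks
    sl <- cs[ks]; sr <- tot - sl
    sse1 <- (sum(seg^2) - sl^2 / nl - sr^2 / nr)
    gain <- sse0 - sse1
    k <- ks[which.max(gain)]
    if (max(gain) > thresh) {
      bounds <- c(bounds, list(c(lo, lo + k - 1L), c(lo + k, hi)))
    } else {
      done[[length(done) + 1]] <- b
    }
  }
  done <- done[order(vapply(done, `[`, integer(1), 1))]
  assignment <- integer(n)
  segs <- data.frame(segment = seq_along(done),
                     start = vapply(done, `[`, integer(1), 1),
                     end = vapply(done, `[`, integer(1), 2))
  segs$mean <- vapply(seq_len(nrow(segs)), function(s) {
    mean(x[segs$start[s]:segs$end[s]])
  }, numeric(1))
  for (s in seq_len(nrow(segs))) assignment[segs$start[s]:segs$end[s]] <- s
  list(assignment = assignment, segments = segs)
}

#' Flag a suspected maternal partial duplication
#'
#' A whole-chromosome trisomy elevates every bin; a maternal segmental
#' duplication elevates only part of the chromosome (and, at low fetal
#' fraction, roughly 1.5x for a one-copy maternal gain). The flag fires when
#' the chromosome call is at least review-level and an elevated segment
#' (mean ratio > `dup_ratio`) covers less than `dup_span` of usable bins
#' while the remaining segments stay within `[0.97, 1.03]`.
#'
#' @param track An `ideogram_track`.
#' @param call The chromosome call (`"REVIEW"` or `"POSITIVE"` are eligible).
#' @param dup_ratio Elevation threshold on segment mean (default 1.1).
#' @param dup_span Maximum fraction of bins an elevated segment may cover
#'   (default 0.7).
#' @return Logical: `TRUE` when a maternal duplication is suspected.
#' @export
detect_partial_duplication <- function(track, call, dup_ratio = 1.1,
                                       dup_span = 0.7) {
  if (!call %in% c("REVIEW", "POSITIVE")) return(FALSE)
  segs <- attr(track, "segments")
  n <- nrow(track)
  elevated <- segs$mean > dup_ratio
  if (!any(elevated) || all(elevated)) return(FALSE)
  span <- sum(segs$end[elevated] - segs$start[elevated] + 1) / n
  rest_ok <- all(segs$mean[!elevated] >= 0.97 & segs$mean[!elevated] <= 1.03)
  span < dup_span && rest_ok
}

#' Screen for global copy-number abnormalities
#'
#' Multi-chromosome aberrant cfDNA signal (e.g. DNA shed by uterine
#' fibroids) invalidates single-chromosome calls. The screen fires when at
#' least `min_chroms` autosomes outside 13/18/21 have `|Z| > 8`; positive
#' calls carrying the flag are downgraded to suspected-maternal status by
#' the reporting layer.
#'
#' @param z Named Z-score vector over autosomes (`"1"`..`"22"`).
#' @param min_chroms Minimum number of off-target aberrant chromosomes
#'   (default 3).
#' @param z_extreme |Z| threshold (default 8).
#' @return Logical flag.
#' @export
global_screen <- function(z, min_chroms = 3, z_extreme = 8) {
  off <- setdiff(names(z)[names(z) %in% AUTOSOMES], c("13", "18", "21"))
  sum(abs(z[off]) > z_extreme) >= min_chroms
}

#' Microdeletion regions for the toy simulated genome
#'
#' Region analogs positioned on the toy genome: a DiGeorge-like region on
#' chromosome 22 and a 1p36-like terminal region on chromosome 1, each
#' spanning 20 of the chromosome's 100 bins. For real hg19-binned data use
#' the bundled asset (`system.file("extdata", "regions_hg19.tsv",
#' package = "cfnips")`).
#'
#' @param bin_size Bin width used by the simulated genome (default 50 kb).
#' @return Region `data.frame` (`name`, `chrom`, `start`, `end`).
#' @export
toy_regions <- function(bin_size = 5e4) {
  data.frame(name = c("22q11_like", "1p36_like"),
             chrom = c("22", "1"),
             start = c(40 * bin_size, 0),
             end = c(60 * bin_size, 20 * bin_size),
             stringsAsFactors = FALSE)
}
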