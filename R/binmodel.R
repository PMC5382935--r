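# Chromosome labels used throughout: autosomes "1".."22", then "X", "Y".
CHROM_LEVELS <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)

#' Construct a validated bin set
#'
#' A bin set is the genome tiling used by the whole pipeline: non-overlapping,
#' sorted, fixed-width-or-not intervals with a GC fraction and a usability
#' mask per bin. Coordinates are 0-based half-open (BED convention).
#'
#' @param chrom Character vector of chromosome labels (`"1"`..`"22"`, `"X"`,
#'   `"Y"`; a leading `"chr"` prefix is stripped).
#' @param start,end Integer base coordinates, 0-based half-open.
#' @param gc GC fraction per bin, in `[0, 1]`.
#' @param usable Logical usability mask (default all `TRUE`).
#' @return A `bin_set`: a `data.frame` with columns `chrom`, `start`, `end`,
#'   `gc`, `usable` and row names `"chrom:start-end"` (the bin ids that key
#'   count-matrix columns).
#' @export
bin_set <- function(chrom, start, end, gc, usable = TRUE) {
  chrom <- sub("^chr", "", as.character(chrom))
  if (!all(chrom %in% CHROM_LEVELS)) {
    stop("unknown chromosome label(s): ",
         paste(unique(setdiff(chrom, CHROM_LEVELS)), collapse = ", "))
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end)) stop("non-numeric bin coordinates")
  if (any(end - start <= 0)) {
    stop("bin with end <= start at index ", which(end - start <= 0)[1])
  }
  if (anyNA(gc) || any(gc < 0 | gc > 1)) {
    stop("gc fraction outside [0, 1] at index ",
         which(is.na(gc) | gc < 0 | gc > 1)[1])
  }
  usable <- rep_len(as.logical(usable), length(chrom))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   gc = as.numeric(gc), usable = usable,
                   stringsAsFactors = FALSE)
  ord <- order(match(df$chrom, CHROM_LEVELS), df$start)
  df <- df[ord, , drop = FALSE]
  # non-overlap within chromosome
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping bins on chromosome ", ch)
    }
  }
  rownames(df) <- bin_ids(df)
  class(df) <- c("bin_set", "data.frame")
  df
}

bin_ids <- function(bins) paste0(bins$chrom, ":", bins$start, "-", bins$end)

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set: %d bins on %d chromosomes (%d usable)\n",
              nrow(x), length(unique(x$chrom)), sum(x$usable)))
  invisible(x)
}

#' Read a bin definition file (BED with GC and usability columns)
#'
#' Expected tab-separated columns: chrom, start, end, gc, usable (0/1).
#' Malformed rows abort with the offending line number.
#'
#' @param path Path to the BED-like file.
#' @return A [bin_set].
#' @export
load_bins <- function(path) {
  if (!file.exists(path)) stop("bin file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 5) stop("bin file needs 5 columns (chrom start end gc usable)")
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  gc <- suppressWarnings(as.numeric(raw[[4]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed coordinates at line ", bad[1], " of ", path)
  bin_set(raw[[1]], start, end, gc, usable = raw[[5]] %in% c("1", "TRUE", "true"))
}

#' Write a bin set to a BED-like file
#' @param bins A [bin_set].
#' @param path Output path.
#' @export
write_bins <- function(bins, path) {
  out <- data.frame(bins$chrom, bins$start, bins$end,
                    format(bins$gc, digits = 15, scientific = FALSE, trim = TRUE),
                    as.integer(bins$usable))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a count matrix
#'
#' The container for per-sample, per-bin read counts. Columns are keyed by
#' bin id and must match the bin set they were counted against; every sample
#' carries a plate (sequencing run/library pool) label used for the
#' plate-median Z-score reference.
#'
#' @param counts Integer matrix, samples x bins; dimnames required
#'   (sample ids x bin ids).
#' @param samples `data.frame` with at least `sample_id` and `plate`;
#'   additional columns (e.g. known karyotype, role) are carried through.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample ids as rownames and bin ids as colnames")
  }
  if (any(counts < 0)) stop("negative counts")
  if (!all(c("sample_id", "plate") %in% names(samples))) {
    stop("samples needs sample_id and plate columns")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!identical(as.character(samples$sample_id), rownames(counts))) {
    samples <- samples[match(rownames(counts), samples$sample_id), , drop = FALSE]
    if (anyNA(samples$sample_id)) stop("samples table does not cover all rows")
  }
  if (anyNA(samples$plate)) stop("every sample needs a plate label")
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d samples x %d bins, %d plates\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$plate))))
  invisible(x)
}

#' Per-sample total read counts
#' @param cm A [count_matrix].
#' @return Named numeric vector of row sums.
#' @export
total_reads <- function(cm) rowSums(cm$counts)

#' Write / read a count matrix as TSV
#'
#' Layout: `sample_id`, `plate`, then one integer column per bin keyed
#' `"chrom:start-end"`.
#'
#' @param cm A [count_matrix].
#' @param path File path.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(sample_id = cm$samples$sample_id,
                   plate = cm$samples$plate,
                   cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
load_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$sample_id
  storage.mode(counts) <- "double"
  count_matrix(counts, data.frame(sample_id = df$sample_id, plate = df$plate,
                                  stringsAsFactors = FALSE))
}

#' Mask unreliable bins from a training cohort
#'
#' Flags bins as unusable when their across-sample robust coefficient of
#' variation (MAD/median of depth-scaled counts) exceeds `cv_threshold`, or
#' when their median raw count is zero. Run on a euploid training series to
#' eliminate bins of shared or homologous sequence whose counts do not track
#' the chromosome they are assigned to.
#'
#' The CV rule applies to autosomal and X bins; Y-bin counts are bimodal
#' across fetal sexes, so their usability is governed by [select_y_bins()]
#' instead (the zero-median rule still applies to Y).
#'
#' @param training A [count_matrix] of presumed-normal samples (>= 20).
#' @param bins The [bin_set] the counts were made against.
#' @param cv_threshold Robust CV ceiling, default 0.3.
#' @return The bin set with `usable` updated (previously-unusable bins stay
#'   masked).
#' @export
fit_usable_bins <- function(training, bins, cv_threshold = 0.3) {
  stopifnot(inherits(training, "count_matrix"))
  if (nrow(training$counts) < 20) {
    stop("need >= 20 training samples, got ", nrow(training$counts))
  }
  check_bins_match(training, bins)
  scaled <- training$counts / rowSums(training$counts)
  med_raw <- apply(training$counts, 2, stats::median)
  med <- apply(scaled, 2, stats::median)
  mad_ <- apply(scaled, 2, stats::mad)
  rcv <- ifelse(med > 0, mad_ / med, Inf)
  is_y <- bins$chrom[match(colnames(training$counts), rownames(bins))] == "Y"
  keep <- med_raw > 0 & (rcv <= cv_threshold | is_y)
  bins$usable <- bins$usable & keep[match(rownames(bins), colnames(training$counts))]
  bins
}

check_bins_match <- function(cm, bins) {
  if (!identical(colnames(cm$counts), rownames(bins))) {
    stop("count matrix columns do not match the bin set")
  }
  invisible(TRUE)
}

#' Sample-level read-depth QC
#'
#' A minimum total read count is required before any result is reported, and
#' a lower bound gates the sex-chromosome analyses. Decisions depend only on
#' the sample's total read count. Thresholds are inclusive: a total exactly
#' at the bound passes.
#'
#' @param total Total read count for one sample.
#' @param min_total Minimum reads for any report (default 9e6).
#' @param min_sex Minimum reads for sex-chromosome analyses (default 4.5e6).
#' @return List with `status` (`"PASS"`, `"NO_REPORT_LOW_READS"` or
#'   `"NO_REPORT_SEX_CHR_LOW_READS"`), `sex_ok` (logical) and `reason`.
#' @export
qc_sample <- function(total, min_total = 9e6, min_sex = 4.5e6) {
  sex_ok <- total >= min_sex
  if (total < min_total) {
    list(status = "NO_REPORT_LOW_READS", sex_ok = sex_ok,
         reason = sprintf("total reads %.3g below minimum %.3g", total, min_total))
  } else if (!sex_ok) {
    list(status = "NO_REPORT_SEX_CHR_LOW_READS", sex_ok = FALSE,
         reason = sprintf("total reads %.3g below sex-chromosome minimum %.3g",
                          total, min_sex))
  } else {
    list(status = "PASS", sex_ok = TRUE, reason = "")
  }
}
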