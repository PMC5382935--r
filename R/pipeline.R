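#' Fit all pipeline references from a training cohort
#'
#' Runs the full training sequence on a cohort of presumed-euploid pregnant
#' samples plus adult (non-pregnant) male and female controls:
#' bin usability mask, GC model, PCA artifact model, smoothing limits,
#' chromosome and region Z-score references, per-bin euploid medians,
#' Y-bin selection, Y background/slope model, female X reference and
#' adult-control anchors, and the female-fetus fetal-fraction regression.
#'
#' @param cm Training [count_matrix].
#' @param bins The [bin_set] counts were made against.
#' @param roles `data.frame` with `sample_id` and `role` in
#'   `{"PREGNANT", "ADULT_MALE", "ADULT_FEMALE"}`. Pregnant samples are
#'   presumed euploid.
#' @param config A [nips_config()].
#' @param regions Optional region table ([load_regions()]); defaults to the
#'   bundled microdeletion regions when they fit the bin set, else none.
#' @return A `nips_reference` list used by [call_cohort()].
#' @export
train_nips <- function(cm, bins, roles, config = nips_config(),
                       regions = NULL) {
  stopifnot(all(roles$role %in% c("PREGNANT", "ADULT_MALE", "ADULT_FEMALE")))
  role <- roles$role[match(cm$samples$sample_id, roles$sample_id)]
  if (anyNA(role)) stop("roles table does not cover all training samples")
  preg <- which(role == "PREGNANT")
  am <- which(role == "ADULT_MALE")
  af <- which(role == "ADULT_FEMALE")
  if (length(preg) < 20) stop("need >= 20 pregnant training samples")

  subset_cm <- function(idx) {
    count_matrix(cm$counts[idx, , drop = FALSE],
                 cm$samples[idx, , drop = FALSE])
  }
  preg_cm <- subset_cm(preg)

  bins <- fit_usable_bins(preg_cm, bins, cv_threshold = config$cv_threshold)

  scaled <- scale_by_autosomal_total(preg_cm, bins)
  gc_model <- fit_gc_model(scaled, bins, span = config$loess_span,
                           degree = config$loess_degree)
  corrected <- gc_correct(scaled, gc_model, bins)
  pca_model <- fit_pca(corrected, bins, k = config$pca_k,
                       exclude_chroms = config$pca_exclude)
  denoised <- pca_denoise(corrected, pca_model)
  smooth_model <- fit_smooth_model(denoised, bins,
                                   probs = config$winsor_probs)
  smoothed <- smooth_bins(denoised, smooth_model, bins, k = config$smooth_k)

  chrom_ref <- fit_chrom_reference(smoothed, bins)
  bin_medians <- fit_bin_medians(smoothed)
  region_ref <- if (!is.null(regions)) {
    fit_region_reference(smoothed, bins, regions)
  }

  # ---- sex-chromosome references -------------------------------------
  y_ref <- NULL
  y_model <- NULL
  female_ff_model <- NULL
  anchors <- NULL
  training_x_f <- NA_real_
  training_xa_ratio_f <- NA_real_
  if (length(am) >= 10 && length(af) >= 10) {
    y_ref <- select_y_bins(subset_cm(am), subset_cm(af), bins)

    sexsum <- sex_bin_summaries(corrected, bins)
    y_norm <- normalized_y_count(preg_cm, bins, y_ref)
    sex_call <- call_genetic_sex(y_norm, y_ref)
    is_female <- sex_call == "FEMALE"
    if (sum(is_female) < 3) stop("training cohort needs female-fetus samples")
    training_x_f <- stats::median(sexsum$x_median[is_female])
    training_xa_ratio_f <- stats::median(
      (sexsum$x_mean / sexsum$auto_mean)[is_female])

    adult_nm <- gc_correct(scale_by_autosomal_total(subset_cm(c(am, af)), bins),
                           gc_model, bins)
    adult_sum <- sex_bin_summaries(adult_nm, bins)
    n_am <- length(am)
    anchors <- list(
      x_male = stats::median(adult_sum$x_median[seq_len(n_am)]),
      x_female = stats::median(adult_sum$x_median[-seq_len(n_am)]))

    ffx_train <- ff_x(sexsum$x_median, training_x_f)
    y_model <- fit_y_model(y_norm, ffx_train, is_male = !is_female)

    males <- which(!is_female)
    if (length(males) >= 50) {
      cons <- vapply(males, function(i) {
        v <- ff_x_variants(lapply(sexsum, `[`, i),
                           list(xa_ratio_f = training_xa_ratio_f,
                                x_f = training_x_f),
                           anchors)
        consensus_male_ff(c(v$ff_a, v$ff_b, v$ff_c,
                            ff_y(y_norm[i], y_model)))
      }, numeric(1))
      female_ff_model <- fit_female_ff_model(subset_cm(preg[males]), bins,
                                             cons)
    }
  }

  structure(list(bins = bins, config = config, gc_model = gc_model,
                 pca_model = pca_model, smooth_model = smooth_model,
                 chrom_ref = chrom_ref, region_ref = region_ref,
                 bin_medians = bin_medians, y_ref = y_ref, y_model = y_model,
                 female_ff_model = female_ff_model, anchors = anchors,
                 training_x_f = training_x_f,
                 training_xa_ratio_f = training_xa_ratio_f),
            class = "nips_reference")
}

#' @export
print.nips_reference <- function(x, ...) {
  cat(sprintf(paste0("nips_reference: %d usable bins, trained on %d samples",
                     "; sex models %s\n"),
              sum(x$bins$usable), x$chrom_ref$n_training,
              if (is.null(x$y_ref)) "absent" else "fitted"))
  invisible(x)
}

# Fetal-fraction block for one cohort: returns a data.frame with the four
# method values, consensus, model value, final FF and gate.
ff_block <- function(cm, corrected, ref, sex_call) {
  bins <- ref$bins
  sexsum <- sex_bin_summaries(corrected, bins)
  y_norm <- normalized_y_count(cm, bins, ref$y_ref)
  n <- nrow(cm$counts)
  plates <- cm$samples$plate
  is_female <- sex_call == "FEMALE"
  ff_model_pred <- if (!is.null(ref$female_ff_model)) {
    ff_female(cm, ref$female_ff_model)
  } else rep(NA_real_, n)

  out <- data.frame(sample_id = cm$samples$sample_id,
                    ffx = NA_real_, ff_a = NA_real_, ff_b = NA_real_,
                    ff_c = NA_real_, ff_d = NA_real_,
                    consensus_male = NA_real_, ff_female_model = ff_model_pred,
                    final = NA_real_, gate = NA_character_,
                    stringsAsFactors = FALSE)
  for (p in unique(plates)) {
    idx <- which(plates == p)
    fem <- idx[is_female[idx]]
    x_f <- if (length(fem) >= 3) {
      stats::median(sexsum$x_median[fem])
    } else ref$training_x_f
    xa_f <- if (length(fem) >= 3) {
      stats::median((sexsum$x_mean / sexsum$auto_mean)[fem])
    } else ref$training_xa_ratio_f
    run_ref <- list(x_f = x_f, xa_ratio_f = xa_f)
    for (i in idx) {
      out$ffx[i] <- ff_x(sexsum$x_median[i], x_f)
      v <- ff_x_variants(lapply(sexsum, `[`, i), run_ref, ref$anchors)
      out$ff_a[i] <- v$ff_a; out$ff_b[i] <- v$ff_b; out$ff_c[i] <- v$ff_c
      out$ff_d[i] <- ff_y(y_norm[i], ref$y_model)
      out$consensus_male[i] <- consensus_male_ff(c(v$ff_a, v$ff_b, v$ff_c,
                                                   out$ff_d[i]))
    }
  }
  out$final <- ifelse(is_female, out$ff_female_model, out$consensus_male)
  out$gate <- ff_gate(out$final, ref$config$ff_threshold)
  out$ffy <- out$ff_d
  out
}

#' Run the full calling pipeline on a cohort
#'
#' Normalizes the cohort against fitted references, computes chromosome and
#' region Z-scores, trisomy calls, ideogram-based maternal-duplication and
#' global-abnormality screens, genetic sex, fetal fractions and
#' sex-aneuploidy calls, and assembles per-sample reports under the
#' reporting precedence.
#'
#' @param cm Cohort [count_matrix] (binned against `ref$bins`).
#' @param ref A `nips_reference` from [train_nips()].
#' @return A `nips_results` list: `reports` (one row per sample), `z`
#'   (chromosome Z matrix), `region_z`, `ff` (fetal-fraction block), `sex`
#'   (sex-call table), `qc`, and `tracks` (ideogram tracks for
#'   review/positive chromosomes).
#' @export
call_cohort <- function(cm, ref) {
  config <- ref$config
  bins <- ref$bins
  totals <- total_reads(cm)
  qc <- lapply(totals, qc_sample, min_total = config$min_total_reads,
               min_sex = config$min_sex_reads)

  scaled <- scale_by_autosomal_total(cm, bins)
  corrected <- gc_correct(scaled, ref$gc_model, bins)
  denoised <- pca_denoise(corrected, ref$pca_model)
  smoothed <- smooth_bins(denoised, ref$smooth_model, bins,
                          k = config$smooth_k)

  z <- cohort_zscores(smoothed, bins, ref$chrom_ref,
                      min_plate = config$min_plate_for_median)
  region_z <- if (!is.null(ref$region_ref)) {
    region_zscores(smoothed, bins, ref$region_ref,
                   min_plate = config$min_plate_for_median)
  }

  sex_available <- !is.null(ref$y_ref) && !is.null(ref$y_model)
  sex_call <- rep(NA_character_, nrow(cm$counts))
  ff <- NULL
  sex <- NULL
  if (sex_available) {
    y_norm <- normalized_y_count(cm, bins, ref$y_ref)
    sex_call <- call_genetic_sex(y_norm, ref$y_ref)
    ff <- ff_block(cm, corrected, ref, sex_call)
    sex <- lapply(seq_along(sex_call), function(i) {
      classify_sex_aneuploidy(ff$ffx[i], ff$ffy[i], sex_call[i],
                              tau = config$sex_tau,
                              maternal_guard = config$maternal_ff_guard)
    })
  }

  targets <- c("13", "18", "21")
  tracks <- list()
  reports <- vector("list", nrow(cm$counts))
  for (i in seq_len(nrow(cm$counts))) {
    sid <- cm$samples$sample_id[i]
    calls <- classify_trisomy(z[i, targets], config$z_negative,
                              config$z_positive)
    dup <- logical(3)
    for (j in seq_along(targets)) {
      if (calls[j] %in% c("REVIEW", "POSITIVE")) {
        tr <- ideogram(smoothed, targets[j], ref$bin_medians, bins,
                       sample = sid)
        dup[j] <- detect_partial_duplication(tr, calls[j],
                                             dup_ratio = config$dup_ratio,
                                             dup_span = config$dup_span)
        tracks[[paste(sid, targets[j], sep = ":")]] <- tr
      }
    }
    trisomy <- data.frame(chrom = targets, z = z[i, targets], call = calls,
                          maternal_dup = dup, stringsAsFactors = FALSE)
    gflag <- global_screen(z[i, ], min_chroms = config$global_min_chroms,
                           z_extreme = config$z_positive)
    sex_i <- if (sex_available && qc[[i]]$sex_ok) sex[[i]] else NULL
    ffv <- if (!is.null(ff)) ff$final[i] else NA_real_
    gate <- if (!is.null(ff)) ff$gate[i] else "PASS"
    reports[[i]] <- render_report(sid, qc[[i]], ffv, gate, trisomy,
                                  global_flag = gflag, sex = sex_i)
  }
  reports <- do.call(rbind, reports)
  sex_df <- if (sex_available) {
    data.frame(sample_id = cm$samples$sample_id, genetic_sex = sex_call,
               aneuploidy = vapply(sex, `[[`, character(1), "aneuploidy"),
               flags = vapply(sex, function(s) paste(s$flags, collapse = ";"),
                              character(1)),
               stringsAsFactors = FALSE)
  }
  structure(list(reports = reports, z = z, region_z = region_z, ff = ff,
                 sex = sex_df, qc = qc, tracks = tracks,
                 normalized = smoothed),
            class = "nips_results")
}

#' Write per-sample results to TSV
#'
#' Emits the report table joined with chromosome Z-scores, fetal-fraction
#' block and sex calls.
#'
#' @param results A `nips_results` from [call_cohort()].
#' @param path Output TSV path.
#' @export
write_results <- function(results, path) {
  df <- results$reports
  zt <- as.data.frame(results$z[, c("13", "18", "21"), drop = FALSE])
  names(zt) <- paste0("z", names(zt))
  df <- cbind(df, zt)
  if (!is.null(results$ff)) {
    df <- cbind(df, results$ff[, c("ffx", "ffy", "consensus_male",
                                   "ff_female_model", "final", "gate")])
  }
  if (!is.null(results$sex)) {
    df$genetic_sex <- results$sex$genetic_sex
    df$sex_aneuploidy <- results$sex$aneuploidy
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
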