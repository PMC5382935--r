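#' Assemble a per-sample report
#'
#' Applies the reporting precedence: read-depth QC failure > low fetal
#' fraction > maternal flags > calls. A positive trisomy call is only
#' reported when the sample passed QC and the fetal-fraction gate and the
#' called chromosome carries neither a suspected-maternal-duplication nor a
#' global-abnormality flag; flagged calls are downgraded to
#' `SUSPECTED_MATERNAL`. Review-range Z-scores surface as `REVIEW` (with
#' the ideogram attached upstream).
#'
#' @param sample_id Sample identifier.
#' @param qc QC result from [qc_sample()].
#' @param ff_final Final fetal fraction (NA when unavailable).
#' @param ff_gate_status `"PASS"` / `"LOW_FF"` from [ff_gate()].
#' @param trisomy `data.frame` with columns `chrom`, `z`, `call`,
#'   `maternal_dup` (logical) for chromosomes 13/18/21.
#' @param global_flag Logical from [global_screen()].
#' @param sex Sex call list from [classify_sex_aneuploidy()] (or `NULL` when
#'   suppressed by QC).
#' @return One-row `data.frame`: `sample_id`, `status`, `result`, `reasons`.
#' @export
render_report <- function(sample_id, qc, ff_final, ff_gate_status, trisomy,
                          global_flag = FALSE, sex = NULL) {
  if (is.null(qc) || is.null(trisomy)) stop("missing pipeline stage output")
  mk <- function(status, result, reasons) {
    data.frame(sample_id = sample_id, status = status, result = result,
               reasons = reasons, stringsAsFactors = FALSE)
  }
  if (qc$status != "PASS") {
    return(mk("NO_REPORT", "", qc$reason))
  }
  if (identical(ff_gate_status, "LOW_FF")) {
    return(mk("NO_REPORT", "",
              sprintf("fetal fraction %.2f%% below reporting threshold",
                      100 * ff_final)))
  }
  reasons <- character(0)
  pos <- trisomy$call == "POSITIVE"
  rev <- trisomy$call == "REVIEW"
  flagged <- trisomy$maternal_dup | global_flag
  maternal_sex <- !is.null(sex) &&
    any(c("MATERNAL_45X_MOSAIC_SUSPECTED") %in% sex$flags)
  if (any(pos & flagged) || any(rev & trisomy$maternal_dup)) {
    which_ch <- trisomy$chrom[(pos | rev) & flagged]
    return(mk("SUSPECTED_MATERNAL", paste0("chr", which_ch, collapse = ","),
              if (global_flag) "global copy-number abnormality"
              else "suspected maternal segmental duplication"))
  }
  if (any(pos)) {
    return(mk("POSITIVE",
              paste0("T", trisomy$chrom[pos], collapse = ","),
              sprintf("Z=%s", paste(round(trisomy$z[pos], 2), collapse = ","))))
  }
  if (maternal_sex) {
    return(mk("SUSPECTED_MATERNAL", "45X-like signal",
              "X-based fetal fraction above maternal-mosaicism guard"))
  }
  if (any(rev)) {
    return(mk("REVIEW", paste0("T", trisomy$chrom[rev], "?", collapse = ","),
              sprintf("intermediate Z=%s",
                      paste(round(trisomy$z[rev], 2), collapse = ","))))
  }
  if (!is.null(sex) && !sex$aneuploidy %in% c("NONE")) {
    status <- if (sex$aneuploidy == "REVIEW") "REVIEW" else "POSITIVE"
    return(mk(status, sex$aneuploidy,
              paste(sex$flags, collapse = ";")))
  }
  mk("NEGATIVE", "", "")
}

#' Positive predictive value from follow-up counts
#'
#' `PPV = 100 x TP / (TP + FP)`, reported to the nearest integer percent.
#'
#' @param tp,fp Confirmed true-positive and false-positive counts.
#' @return PPV as an integer percentage.
#' @export
ppv <- function(tp, fp) {
  if (tp + fp <= 0) stop("PPV undefined: no confirmed follow-up results")
  round(100 * tp / (tp + fp))
}

#' Analytic PPV from sensitivity, specificity and prevalence
#'
#' `PPV = 100 x sens x prev / (sens x prev + (1 - spec) x (1 - prev))`.
#' Returned unrounded (in percent).
#'
#' @param sensitivity,specificity,prevalence All in `[0, 1]`; prevalence
#'   positive.
#' @return PPV percentage.
#' @export
ppv_analytic <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence > 0, prevalence <= 1)
  denom <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  if (denom <= 0) stop("PPV undefined: zero positive rate")
  100 * sensitivity * prevalence / denom
}

#' Format a positive rate the way screening reports print it
#'
#' One decimal place at or above 1%, two below.
#'
#' @param rate_percent Rate in percent.
#' @return Character.
#' @export
format_rate <- function(rate_percent) {
  ifelse(rate_percent >= 1, sprintf("%.1f", rate_percent),
         sprintf("%.2f", rate_percent))
}

#' Cohort summary statistics
#'
#' Positive rates per condition and, when truth (or clinical follow-up) is
#' available, the confirmed/false-positive bookkeeping with PPV and
#' adjusted PPV (which excludes false positives reclassified as
#' suspected-maternal under current reporting rules).
#'
#' @param reports `data.frame` of per-sample reports ([render_report()]
#'   rows).
#' @param truth Optional truth table with `sample_id` and `aneuploidy`.
#' @return List with `n`, `positive_rates` (percent, per condition) and,
#'   given truth, a `follow_up` table with `tp`, `fp`, `ppv`.
#' @export
cohort_stats <- function(reports, truth = NULL) {
  stopifnot(nrow(reports) >= 1)
  n <- nrow(reports)
  conds <- c("T13", "T18", "T21")
  pos_for <- function(cond) {
    reports$status == "POSITIVE" & grepl(cond, reports$result, fixed = TRUE)
  }
  rates <- vapply(conds, function(cond) 100 * sum(pos_for(cond)) / n,
                  numeric(1))
  out <- list(n = n, positive_rates = rates,
              no_report_rate = 100 * sum(reports$status == "NO_REPORT") / n)
  if (!is.null(truth)) {
    tab <- do.call(rbind, lapply(conds, function(cond) {
      pos <- pos_for(cond)
      truth_cond <- truth$aneuploidy[match(reports$sample_id,
                                           truth$sample_id)] == cond
      tp <- sum(pos & truth_cond)
      fp <- sum(pos & !truth_cond)
      data.frame(condition = cond, positives = sum(pos), tp = tp, fp = fp,
                 ppv = if (tp + fp > 0) ppv(tp, fp) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    out$follow_up <- tab
  }
  out
}
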