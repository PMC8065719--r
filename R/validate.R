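# Analytical validation: truth-vs-call classification, performance metrics
# with exact Clopper-Pearson intervals, VAF-threshold scanning, replicate
# condensation and reproducibility.

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval from beta quantiles: the lower bound is the
#' `alpha/2` beta quantile with parameters `(k, n - k + 1)` (exactly 0 when
#' `k = 0`), the upper the `1 - alpha/2` quantile with `(k + 1, n - k)`
#' (exactly 1 when `k = n`).
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)` of proportions.
#' @examples
#' clopper_pearson(164, 180)
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1",
                                    call. = FALSE)
  alpha <- 1 - conf
  low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

#' Classify detection records against the truth set
#'
#' At positive VAF levels an expected variant that is detected is a true
#' positive, an undetected one a false negative. At the 0% level a call is
#' a false positive and an absent call a true negative. Pooled counts sum
#' true positives and false negatives over the positive levels and take the
#' false positives / true negatives once, from the 0% level; per-positive-
#' level rows also carry the 0%-level fp/tn so that level-specific
#' predictive values and accuracy can be computed the same way.
#'
#' @param records Data frame of detection records: `target_id`,
#'   `vaf_level_pct`, `replicate`, `detected`, `measured_freq_pct`.
#' @param truth Truth set: `target_id`, `vaf_level_pct`,
#'   `expected_present` (logical), `expected_vaf_pct`.
#' @return Data frame of confusion counts, one row per level plus a
#'   `"pooled"` row: `level`, `tp`, `fp`, `tn`, `fn`.
#' @export
classify_detections <- function(records, truth) {
  tkey <- paste(truth$target_id, truth$vaf_level_pct, sep = "\r")
  rkey <- paste(records$target_id, records$vaf_level_pct, sep = "\r")
  m <- match(rkey, tkey)
  if (anyNA(m)) {
    stop("record(s) without a truth entry: ",
         paste(unique(rkey[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  expected <- truth$expected_present[m]
  if (nrow(records) == 0) {
    return(data.frame(level = "pooled", tp = 0L, fp = 0L, tn = 0L,
                      fn = 0L, stringsAsFactors = FALSE))
  }
  levels <- sort(unique(records$vaf_level_pct))
  out <- lapply(levels, function(lv) {
    sel <- records$vaf_level_pct == lv
    det <- records$detected[sel]; exp_ <- expected[sel]
    if (lv == 0) {
      data.frame(level = as.character(lv), tp = 0L, fp = sum(det & !exp_),
                 tn = sum(!det & !exp_), fn = 0L, stringsAsFactors = FALSE)
    } else {
      data.frame(level = as.character(lv), tp = sum(det & exp_), fp = 0L,
                 tn = 0L, fn = sum(!det & exp_), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  zero <- out$level == "0"
  fp0 <- if (any(zero)) out$fp[zero] else 0L
  tn0 <- if (any(zero)) out$tn[zero] else 0L
  # positive levels inherit the 0%-level fp/tn for PPV/NPV/accuracy
  out$fp[!zero] <- fp0
  out$tn[!zero] <- tn0
  pooled <- data.frame(level = "pooled", tp = sum(out$tp[!zero]),
                       fp = fp0, tn = tn0, fn = sum(out$fn[!zero]),
                       stringsAsFactors = FALSE)
  rbind(out, pooled)
}

#' Performance metrics with exact confidence intervals
#'
#' Computes sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive
#' predictive value tp/(tp+fp), negative predictive value tn/(tn+fn) and
#' accuracy (tp+tn)/(tp+tn+fp+fn), each x 100, with the exact
#' Clopper-Pearson interval on the defining ratio. A metric with an empty
#' denominator is reported as `NA` with a reason.
#'
#' @param counts A single row of confusion counts (list or one-row data
#'   frame with `tp`, `fp`, `tn`, `fn`).
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `metric`, `value_pct`, `ci_low_pct`, `ci_high_pct`,
#'   `k`, `n`, `note`.
#' @export
confusion_metrics <- function(counts, conf = 0.95) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  defs <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv = c(tp, tp + fp),
    npv = c(tn, tn + fn),
    accuracy = c(tp + tn, tp + tn + fp + fn))
  rows <- lapply(names(defs), function(nm) {
    k <- defs[[nm]][1]; n <- defs[[nm]][2]
    if (n == 0) {
      return(data.frame(metric = nm, value_pct = NA_real_,
                        ci_low_pct = NA_real_, ci_high_pct = NA_real_,
                        k = k, n = n, note = "empty denominator",
                        stringsAsFactors = FALSE))
    }
    ci <- clopper_pearson(k, n, conf)
    data.frame(metric = nm, value_pct = k / n * 100,
               ci_low_pct = ci[["low"]] * 100,
               ci_high_pct = ci[["high"]] * 100, k = k, n = n, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan candidate VAF thresholds
#'
#' For each candidate threshold t, detection is redefined as
#' `measured_freq_pct >= t` and specificity (0% level) and sensitivity
#' (positive levels) are recomputed. The chosen threshold is the smallest
#' candidate whose specificity meets the target; if none does, the
#' candidate with the highest specificity is returned with a warning.
#'
#' @param records Detection records carrying raw `measured_freq_pct`
#'   (pre-threshold).
#' @param truth Truth set (see [classify_detections()]).
#' @param thresholds Candidate grid in percent (default 0.01-0.50 by 0.01).
#' @param target_specificity_pct Specificity target in percent (default 95).
#' @return A list with `curve` (data frame: `threshold_pct`,
#'   `specificity_pct`, `sensitivity_pct`) and `chosen_threshold_pct`.
#' @export
threshold_scan <- function(records, truth,
                           thresholds = seq(0.01, 0.50, by = 0.01),
                           target_specificity_pct = 95) {
  curve <- lapply(thresholds, function(t) {
    rec <- records
    rec$detected <- rec$measured_freq_pct >= t
    cc <- classify_detections(rec, truth)
    pooled <- cc[cc$level == "pooled", ]
    spec <- if (pooled$tn + pooled$fp > 0)
      pooled$tn / (pooled$tn + pooled$fp) * 100 else NA_real_
    sens <- if (pooled$tp + pooled$fn > 0)
      pooled$tp / (pooled$tp + pooled$fn) * 100 else NA_real_
    data.frame(threshold_pct = t, specificity_pct = spec,
               sensitivity_pct = sens)
  })
  curve <- do.call(rbind, curve)
  ok <- !is.na(curve$specificity_pct) &
    curve$specificity_pct >= target_specificity_pct
  if (any(ok)) {
    chosen <- curve$threshold_pct[which(ok)[1]]
  } else {
    chosen <- curve$threshold_pct[which.max(curve$specificity_pct)]
    warning("no candidate threshold reaches the target specificity; ",
            "returning the most specific candidate", call. = FALSE)
  }
  list(curve = curve, chosen_threshold_pct = chosen)
}

#' Condense replicate calls into per-target presence
#'
#' A variant is considered present (or absent) when that finding is backed
#' by at least `k` of the `n` replicates (default 2 of 3).
#'
#' @param records Detection records for one VAF level.
#' @param k Minimum number of supporting replicates (default 2).
#' @param n Expected number of replicates (default 3).
#' @return Data frame: `target_id`, `vaf_level_pct`, `n_replicates`,
#'   `n_detected`, `present`.
#' @export
condense_replicates <- function(records, k = 2L, n = 3L) {
  grp <- split(records,
               paste(records$target_id, records$vaf_level_pct, sep = "\r"))
  out <- lapply(grp, function(g) {
    if (nrow(g) < n) {
      warning(sprintf("target %s at %s%%: only %d replicate(s) available",
                      g$target_id[1], format(g$vaf_level_pct[1]), nrow(g)),
              call. = FALSE)
    }
    data.frame(target_id = g$target_id[1],
               vaf_level_pct = g$vaf_level_pct[1],
               n_replicates = nrow(g), n_detected = sum(g$detected),
               present = sum(g$detected) >= k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$target_id), , drop = FALSE]
}

#' Intra-assay reproducibility
#'
#' A measurement is within range when it lies inside
#' `expected +- tol_frac * expected` (with the defaults, 0.5% +- 0.25%).
#'
#' @param records Detection records measured at a single VAF level.
#' @param expected_vaf_pct Expected frequency in percent.
#' @param tol_frac Half-width of the acceptance band as a fraction of the
#'   expected value (default 0.5).
#' @return A list with `fraction_within_pct` (percentage of measurements in
#'   range) and `flags` (per-record data frame with `within`).
#' @export
reproducibility <- function(records, expected_vaf_pct, tol_frac = 0.5) {
  tol <- tol_frac * expected_vaf_pct
  within <- abs(records$measured_freq_pct - expected_vaf_pct) <= tol
  flags <- cbind(records[, c("target_id", "replicate",
                             "measured_freq_pct")],
                 data.frame(within = within))
  list(fraction_within_pct = mean(within) * 100, flags = flags)
}

#' Build detection records from mutation tables
#'
#' Converts one mutation table per (level, replicate) into the detection
#' records consumed by the validation functions. Detection at the recorded
#' threshold is the table's `pass` flag; `measured_freq_pct` keeps the raw
#' frequency so thresholds can be re-scanned.
#'
#' @param tables Named list: `tables[[as.character(level)]][[replicate]]`
#'   is a mutation table.
#' @param target_ids Whitelist target ids to evaluate (defaults to all
#'   SNV/MNP/INS/DEL rows of the first table).
#' @return Detection-record data frame.
#' @export
detection_records <- function(tables, target_ids = NULL) {
  out <- list()
  for (lv in names(tables)) {
    reps <- tables[[lv]]
    for (r in seq_along(reps)) {
      tab <- reps[[r]]
      sel <- tab$class %in% c("SNV", "MNP", "INS", "DEL")
      if (!is.null(target_ids)) sel <- sel & tab$target_id %in% target_ids
      out[[length(out) + 1L]] <- data.frame(
        target_id = tab$target_id[sel],
        vaf_level_pct = as.numeric(lv), replicate = r,
        detected = tab$pass[sel],
        measured_freq_pct = tab$frequency_pct[sel],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read / write a truth-set TSV
#'
#' @param path TSV with columns `target_id`, `vaf_level_pct`,
#'   `expected_present`, `expected_vaf_pct`.
#' @return Truth-set data frame.
#' @export
read_truth_set <- function(path) {
  df <- read_tsv_strict(path, c("target_id", "vaf_level_pct",
                                "expected_present", "expected_vaf_pct"))
  df$vaf_level_pct <- as.numeric(df$vaf_level_pct)
  df$expected_present <- as.logical(df$expected_present)
  df$expected_vaf_pct <- as.numeric(df$expected_vaf_pct)
  df
}

#' @rdname read_truth_set
#' @param truth Truth-set data frame.
#' @export
write_truth_set <- function(truth, path) {
  write_tsv(truth, path)
}

#' Full validation report
#'
#' Computes per-level and pooled metrics with confidence intervals, the
#' LOD90 logistic fit, the threshold scan and (when a level matches
#' `reproducibility_level_pct`) the reproducibility fraction, and returns
#' them as one report list that can be serialised to JSON.
#'
#' @param records Detection records (see [detection_records()]).
#' @param truth Truth set.
#' @param config A [run_config()].
#' @param reproducibility_level_pct Level used for the reproducibility
#'   assessment (default 0.5).
#' @param out_path Optional path for `metrics_report.json`.
#' @return The report list, invisibly when written to file.
#' @export
metrics_report <- function(records, truth, config = run_config(),
                           reproducibility_level_pct = 0.5,
                           out_path = NULL) {
  counts <- classify_detections(records, truth)
  per_level <- lapply(seq_len(nrow(counts)), function(i) {
    list(level = counts$level[i],
         counts = as.list(counts[i, c("tp", "fp", "tn", "fn")]),
         metrics = confusion_metrics(counts[i, ]))
  })
  names(per_level) <- counts$level

  lod <- tryCatch(lod_fit(records), error = function(e) NULL)
  scan <- threshold_scan(records, truth)
  rep_out <- NULL
  if (reproducibility_level_pct %in% records$vaf_level_pct) {
    rep_out <- reproducibility(
      records[records$vaf_level_pct == reproducibility_level_pct, ,
              drop = FALSE],
      expected_vaf_pct = reproducibility_level_pct)
  }
  report <- list(
    metrics = per_level,
    lod90_pct = if (!is.null(lod)) lod$lod90_pct else NA_real_,
    lod_coefficients = if (!is.null(lod)) as.list(coef(lod)) else NULL,
    chosen_threshold_pct = scan$chosen_threshold_pct,
    threshold_curve = scan$curve,
    reproducibility_fraction_pct =
      if (!is.null(rep_out)) rep_out$fraction_within_pct else NA_real_,
    vaf_threshold_pct = config$vaf_threshold_pct)
  if (!is.null(out_path)) {
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    return(invisible(report))
  }
  report
}
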