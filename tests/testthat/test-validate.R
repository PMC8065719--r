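test_that("classification yields the confusion counts forced by the design", {
  d <- mk_records()
  cc <- classify_detections(d$records, d$truth)
  r05 <- cc[cc$level == "0.5", ]
  expect_equal(r05$tp, 59); expect_equal(r05$fn, 1)
  r0 <- cc[cc$level == "0", ]
  expect_equal(r0$fp, 3); expect_equal(r0$tn, 57)
  pooled <- cc[cc$level == "pooled", ]
  expect_equal(pooled$tp, 164); expect_equal(pooled$fn, 16)
  expect_equal(pooled$fp, 3); expect_equal(pooled$tn, 57)
  # empty record set gives all-zero counts
  empty <- classify_detections(d$records[0, ], d$truth)
  expect_equal(nrow(empty), 1)  # pooled only
  expect_equal(sum(empty[, c("tp", "fp", "tn", "fn")]), 0)
  # records without truth entries are fatal
  bad <- d$records[1, ]; bad$target_id <- "unknown"
  expect_error(classify_detections(bad, d$truth), "truth")
})

test_that("metric formulas follow the confusion-count definitions", {
  m <- confusion_metrics(list(tp = 59, fp = 3, tn = 57, fn = 1))
  expect_equal(m$value_pct[m$metric == "sensitivity"], 59 / 60 * 100)
  expect_equal(m$value_pct[m$metric == "ppv"], 59 / 62 * 100)
  expect_equal(m$value_pct[m$metric == "npv"], 57 / 58 * 100)
  expect_equal(m$value_pct[m$metric == "accuracy"], 116 / 120 * 100)
  # empty denominator reported as absent
  m0 <- confusion_metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(m0$value_pct[m0$metric == "sensitivity"]))
  expect_match(m0$note[m0$metric == "sensitivity"], "denominator")
})

test_that("accuracy identity and trial-weighted pooling hold on random record sets", {
  set.seed(61)
  for (i in 1:10) {
    det <- c("0" = sample(0:10, 1), "0.125" = sample(0:60, 1),
             "0.25" = sample(0:60, 1), "0.5" = sample(0:60, 1))
    d <- mk_records(det)
    cc <- classify_detections(d$records, d$truth)
    pooled <- cc[cc$level == "pooled", ]
    m <- confusion_metrics(pooled)
    expect_equal(m$value_pct[m$metric == "accuracy"],
                 (pooled$tp + pooled$tn) /
                   (pooled$tp + pooled$tn + pooled$fp + pooled$fn) * 100)
    pos <- cc[!(cc$level %in% c("0", "pooled")), ]
    expect_equal(pooled$tp / (pooled$tp + pooled$fn),
                 sum(pos$tp) / sum(pos$tp + pos$fn))
  }
})

test_that("Clopper-Pearson intervals match binom.test exactly", {
  set.seed(62)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    bt <- stats::binom.test(k, n)$conf.int
    expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-12)
  }
  expect_equal(clopper_pearson(0, 10)[["low"]], 0)
  expect_equal(clopper_pearson(10, 10)[["high"]], 1)
  expect_error(clopper_pearson(5, 4), "k")
})

test_that("wider confidence levels nest the narrower ones", {
  for (n in c(1:20, 30, 40, 50)) {
    for (k in 0:n) {
      ci95 <- clopper_pearson(k, n, 0.95)
      ci99 <- clopper_pearson(k, n, 0.99)
      expect_lte(ci99[["low"]], ci95[["low"]])
      expect_gte(ci99[["high"]], ci95[["high"]])
    }
  }
})

test_that("the exact interval covers the true proportion at nominal rate", {
  set.seed(63)
  p <- 0.9; n <- 60
  ks <- stats::rbinom(10000, n, p)
  lows <- ifelse(ks == 0, 0, stats::qbeta(0.025, ks, n - ks + 1))
  highs <- ifelse(ks == n, 1, stats::qbeta(0.975, ks + 1, n - ks))
  coverage <- mean(lows <= p & p <= highs)
  expect_gte(coverage, 0.95 - 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("the threshold scan picks the smallest threshold meeting the target", {
  set.seed(64)
  # noise frequencies all below 0.05%: any candidate above that is fully
  # specific, so the first grid point at or above 0.05 wins
  d <- mk_records(c("0" = 0, "0.5" = 60))
  d$records$measured_freq_pct[d$records$vaf_level_pct == 0] <-
    runif(60, 0, 0.049)
  d$records$measured_freq_pct[d$records$vaf_level_pct == 0.5] <-
    runif(60, 0.4, 0.6)
  scan <- threshold_scan(d$records, d$truth)
  expect_equal(scan$chosen_threshold_pct, 0.05)
  expect_true(all(diff(scan$curve$specificity_pct) >= 0))
  expect_true(all(diff(scan$curve$sensitivity_pct) <= 0))
  # a zero target accepts the smallest grid point
  scan0 <- threshold_scan(d$records, d$truth, target_specificity_pct = 0)
  expect_equal(scan0$chosen_threshold_pct, 0.01)
})

test_that("a calibrated noise floor reproduces the 0.09 percent choice", {
  # construct the 0%-level noise so that exactly 3 of 60 measurements lie
  # at or above 0.09% while more than 5% lie at or above 0.08%
  d <- mk_records(c("0" = 0, "0.125" = 46, "0.25" = 59, "0.5" = 59))
  noise <- c(rep(0.005, 48), rep(0.085, 9), 0.10, 0.11, 0.12)
  d$records$measured_freq_pct[d$records$vaf_level_pct == 0] <- noise
  scan <- threshold_scan(d$records, d$truth,
                         thresholds = seq(0.01, 0.5, by = 0.01))
  expect_equal(scan$chosen_threshold_pct, 0.09)
  spec_at <- scan$curve$specificity_pct[scan$curve$threshold_pct == 0.09]
  expect_equal(spec_at, 95)
})

test_that("replicate condensation follows the two-of-three rule", {
  rec <- data.frame(
    target_id = rep(c("t1", "t2", "t3"), each = 3),
    vaf_level_pct = 0.25, replicate = rep(1:3, 3),
    detected = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    measured_freq_pct = 0.2)
  out <- condense_replicates(rec)
  expect_identical(out$present[out$target_id == "t1"], TRUE)
  expect_identical(out$present[out$target_id == "t2"], FALSE)
  expect_identical(out$present[out$target_id == "t3"], TRUE)
  # fewer replicates than expected warns but still evaluates
  expect_warning(condense_replicates(rec[1:2, ]), "replicate")
})

test_that("reproducibility applies the half-expected acceptance band", {
  rec <- data.frame(target_id = c("t1", "t2", "t3"), replicate = 1,
                    vaf_level_pct = 0.5,
                    measured_freq_pct = c(0.30, 0.20, 0.50),
                    detected = TRUE)
  out <- reproducibility(rec, expected_vaf_pct = 0.5)
  expect_identical(out$flags$within, c(TRUE, FALSE, TRUE))
  expect_equal(out$fraction_within_pct, 2 / 3 * 100)
  rec$measured_freq_pct <- 0.5
  expect_equal(reproducibility(rec, 0.5)$fraction_within_pct, 100)
})

test_that("the logistic fit matches an independent Newton MLE and is scale-free", {
  agg <- data.frame(vaf_level_pct = c(0, 0.125, 0.25, 0.5),
                    n_detected = c(3, 46, 59, 59), n_trials = 60)
  fit <- lod_fit(agg)
  beta <- oracle_logistic_mle(agg$vaf_level_pct, agg$n_detected,
                              agg$n_trials)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-6)
  # doubling all counts at the same rates leaves the fit unchanged
  agg2 <- agg; agg2$n_detected <- agg2$n_detected * 2
  agg2$n_trials <- agg2$n_trials * 2
  expect_equal(lod_fit(agg2)$lod90_pct, fit$lod90_pct, tolerance = 1e-9)
  # predicted probability at the LOD90 is 0.9 by construction
  expect_equal(unname(predict(fit, fit$lod90_pct)), 0.9, tolerance = 1e-9)
})

test_that("perfectly separated detection outcomes refuse to fit", {
  agg <- data.frame(vaf_level_pct = c(0, 0.5), n_detected = c(0, 60),
                    n_trials = 60)
  expect_error(lod_fit(agg), "separat")
})

test_that("the fitted LOD90 recovers a known detection curve", {
  set.seed(65)
  true_b0 <- -2.4; true_b1 <- 25
  true_lod <- (qlogis(0.9) - true_b0) / true_b1
  rel_err <- vapply(1:100, function(s) {
    lv <- c(0, 0.125, 0.25, 0.5)
    k <- rbinom(4, 60, plogis(true_b0 + true_b1 * lv))
    f <- tryCatch(suppressWarnings(
      lod_fit(data.frame(vaf_level_pct = lv, n_detected = k,
                         n_trials = 60))),
      error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    abs(f$lod90_pct - true_lod) / true_lod
  }, numeric(1))
  expect_lte(stats::median(rel_err, na.rm = TRUE), 0.15)
})
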