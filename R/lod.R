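# Limit-of-detection model: a simple logistic regression of per-trial
# detection outcome on VAF (in percent, untransformed), inverted at 90%
# detection probability.

#' Fit the logistic limit-of-detection model
#'
#' Fits detection outcome (0/1 per target x replicate trial) against the
#' nominal VAF level in percent by maximum likelihood:
#' \deqn{\mathrm{logit}\, P(\mathrm{detected}) = \beta_0 + \beta_1 \cdot
#' \mathrm{VAF}}
#' The 90% limit of detection is the VAF where the fitted curve crosses
#' 0.9: \eqn{LOD_{90} = (\mathrm{logit}(0.9) - \beta_0)/\beta_1}. The 0%
#' level is included in the fit — its false-detection floor anchors the
#' curve. The VAF covariate is untransformed by default; `log_vaf = TRUE`
#' regresses on log10(VAF) instead (positive levels only).
#'
#' @param records Detection records (data frame with `vaf_level_pct` and
#'   logical `detected`), or a data frame with columns `vaf_level_pct`,
#'   `n_detected`, `n_trials` for aggregated input.
#' @param log_vaf Regress on log10(VAF) instead of VAF (default `FALSE`).
#' @return An object of class `lod_fit` with components `coefficients`
#'   (intercept, slope), `lod90_pct`, `model` (the underlying `glm`),
#'   `levels` (per-level detection summary) and `log_vaf`.
#' @examples
#' rec <- data.frame(
#'   vaf_level_pct = rep(c(0, 0.125, 0.25, 0.5), each = 60),
#'   detected = unlist(lapply(c(3, 46, 59, 59),
#'                            function(k) rep(c(TRUE, FALSE), c(k, 60 - k)))))
#' fit <- lod_fit(rec)
#' fit
#' @export
lod_fit <- function(records, log_vaf = FALSE) {
  if (all(c("n_detected", "n_trials") %in% names(records))) {
    agg <- data.frame(vaf_level_pct = records$vaf_level_pct,
                      k = records$n_detected, n = records$n_trials)
  } else {
    stopifnot(is.logical(records$detected))
    agg <- do.call(rbind, lapply(
      split(records, records$vaf_level_pct),
      function(g) data.frame(vaf_level_pct = g$vaf_level_pct[1],
                             k = sum(g$detected), n = nrow(g))))
  }
  if (log_vaf) agg <- agg[agg$vaf_level_pct > 0, , drop = FALSE]
  if (nrow(agg) < 2) {
    stop("need at least two distinct VAF levels to fit the detection curve",
         call. = FALSE)
  }
  if (sum(agg$k) == 0 || sum(agg$n - agg$k) == 0) {
    stop("both detection outcomes must be represented across the levels",
         call. = FALSE)
  }
  x <- if (log_vaf) log10(agg$vaf_level_pct) else agg$vaf_level_pct
  # perfect separation check: a finite MLE needs overlapping outcomes
  has0 <- agg$k < agg$n; has1 <- agg$k > 0
  if (max(c(-Inf, x[has1])) < min(c(Inf, x[has0])) ||
      max(c(-Inf, x[has0])) < min(c(Inf, x[has1]))) {
    stop("detection outcomes are perfectly separated by VAF; ",
         "the logistic MLE does not exist - include more levels",
         call. = FALSE)
  }
  fit <- stats::glm(cbind(agg$k, agg$n - agg$k) ~ x,
                    family = stats::binomial())
  b <- unname(stats::coef(fit))
  lod90 <- (stats::qlogis(0.9) - b[1]) / b[2]
  if (log_vaf) lod90 <- 10^lod90
  structure(list(coefficients = c(intercept = b[1], slope = b[2]),
                 lod90_pct = lod90, model = fit,
                 levels = data.frame(vaf_level_pct = agg$vaf_level_pct,
                                     n_detected = agg$k, n_trials = agg$n,
                                     rate = agg$k / agg$n),
                 log_vaf = log_vaf),
            class = "lod_fit")
}

#' @export
print.lod_fit <- function(x, digits = 4, ...) {
  cat("Logistic limit-of-detection model",
      if (x$log_vaf) "(log10 VAF)" else "(VAF in %)", "\n")
  cat(sprintf("  intercept %s, slope %s per %% VAF\n",
              format(x$coefficients[["intercept"]], digits = digits),
              format(x$coefficients[["slope"]], digits = digits)))
  cat(sprintf("  LOD90: %s%% VAF\n", format(x$lod90_pct, digits = digits)))
  invisible(x)
}

#' @export
summary.lod_fit <- function(object, ...) {
  print(object)
  cat("\nPer-level detection rates:\n")
  print(object$levels, row.names = FALSE)
  cat("\nGLM summary:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.lod_fit <- function(object, ...) object$coefficients

#' Predicted detection probability
#'
#' @param object A [lod_fit()] object.
#' @param vaf_pct VAF levels (percent) to predict at.
#' @param ... Unused.
#' @return Vector of detection probabilities.
#' @export
predict.lod_fit <- function(object, vaf_pct, ...) {
  x <- if (object$log_vaf) log10(vaf_pct) else vaf_pct
  b <- object$coefficients
  stats::plogis(b[["intercept"]] + b[["slope"]] * x)
}

#' @export
plot.lod_fit <- function(x, ...) {
  lv <- x$levels
  graphics::plot(lv$vaf_level_pct, lv$rate, pch = 19,
                 xlab = "VAF level (%)", ylab = "detection probability",
                 ylim = c(0, 1), ...)
  xs <- seq(min(lv$vaf_level_pct), max(lv$vaf_level_pct), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  graphics::abline(h = 0.9, lty = 2)
  graphics::abline(v = x$lod90_pct, lty = 2)
  invisible(x)
}
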