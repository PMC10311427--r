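# G-ROP rule-engine comparator and the method-comparison harness.
#
# The G-ROP criteria screen an infant when any of the following fires:
# gestational age below a threshold, birth weight below a threshold,
# weight gain below a window threshold in postnatal days 10-19, 20-29 or
# 30-39, hydrocephalus, or any needed datum missing (a missing datum is
# always resolved toward screening). Day 0 is the birth day. Window
# endpoint weights are obtained by linear interpolation between the
# nearest flanking measurements.

#' G-ROP rule set
#'
#' The rule structure is fixed; the numeric thresholds are configuration.
#' Defaults follow the published G-ROP criteria (GA < 28 weeks,
#' BW < 1051 g, weight gain < 120/180/170 g in days 10-19/20-29/30-39,
#' hydrocephalus); the `"180g"` variant raises every window threshold to
#' 180 g.
#'
#' @param ga_threshold_weeks screen if GA strictly below (default 28).
#' @param bw_threshold_g screen if BW strictly below (default 1051).
#' @param gain_thresholds_g length-3 vector: screen if the window gain is
#'   strictly below (days 10-19, 20-29, 30-39).
#' @param hydrocephalus_rule screen on hydrocephalus (default TRUE).
#' @param variant tag, `"base"` or `"180g"` (setting the variant overrides
#'   `gain_thresholds_g`).
#' @return a `grop_rules` list.
#' @export
grop_rules <- function(ga_threshold_weeks = 28, bw_threshold_g = 1051,
                       gain_thresholds_g = c(120, 180, 170),
                       hydrocephalus_rule = TRUE,
                       variant = c("base", "180g")) {
  variant <- match.arg(variant)
  if (variant == "180g") gain_thresholds_g <- c(180, 180, 180)
  stopifnot(ga_threshold_weeks > 0, bw_threshold_g > 0,
            length(gain_thresholds_g) == 3, all(gain_thresholds_g > 0))
  structure(list(ga_threshold_weeks = ga_threshold_weeks,
                 bw_threshold_g = bw_threshold_g,
                 gain_thresholds_g = gain_thresholds_g,
                 windows = list(c(10, 19), c(20, 29), c(30, 39)),
                 hydrocephalus_rule = hydrocephalus_rule,
                 variant = variant),
            class = "grop_rules")
}

#' Interpolate a daily weight
#'
#' Returns the measured weight if the day was measured, otherwise the
#' linear interpolation between the nearest flanking measurements, or
#' `NA` (missing) when no flanking pair exists.
#'
#' @param weights named numeric vector of grams indexed by postnatal day,
#'   or `NULL`.
#' @param day nonnegative integer day.
#' @return grams, or `NA_real_`.
#' @export
interpolate_weight <- function(weights, day) {
  stopifnot(day >= 0)
  if (is.null(weights) || length(weights) == 0) return(NA_real_)
  d <- as.numeric(names(weights))
  hit <- which(d == day)
  if (length(hit) > 0) return(unname(weights[hit[1]]))
  before <- d[d < day]; after <- d[d > day]
  if (length(before) == 0 || length(after) == 0) return(NA_real_)
  d0 <- max(before); d1 <- min(after)
  w0 <- unname(weights[match(d0, d)]); w1 <- unname(weights[match(d1, d)])
  w0 + (w1 - w0) * (day - d0) / (d1 - d0)
}

#' G-ROP screening decision for one infant
#'
#' `"screen"` iff any criterion fires or any needed datum is missing;
#' criteria fire on strictly-below comparisons (a gain exactly at the
#' threshold does not fire).
#'
#' @param record one-row [rop_cohort()] slice (or a list with `ga_weeks`,
#'   `bw_g`, `weights_g_by_day`, `hydrocephalus`).
#' @param rules a [grop_rules()].
#' @return `"screen"` or `"no_screen"`.
#' @export
grop_screen_decision <- function(record, rules = grop_rules()) {
  ga <- record$ga_weeks[[1]]
  bw <- record$bw_g[[1]]
  hyd <- record$hydrocephalus[[1]]
  w <- record$weights_g_by_day
  if (is.list(w) && !is.numeric(w)) w <- w[[1]]
  if (is.na(ga) || ga < rules$ga_threshold_weeks) return("screen")
  if (is.na(bw) || bw < rules$bw_threshold_g) return("screen")
  if (rules$hydrocephalus_rule && (is.null(hyd) || is.na(hyd) || isTRUE(hyd)))
    return("screen")
  for (i in 1:3) {
    win <- rules$windows[[i]]
    gain <- interpolate_weight(w, win[2]) - interpolate_weight(w, win[1])
    if (is.na(gain) || gain < rules$gain_thresholds_g[i]) return("screen")
  }
  "no_screen"
}

#' G-ROP decisions for a whole cohort
#'
#' @param cohort an [rop_cohort()] with weight series.
#' @param rules a [grop_rules()].
#' @return logical vector: `TRUE` when the infant can be released from
#'   screening (`no_screen`), aligned with discharge indicators of the
#'   risk-model tool.
#' @export
grop_discharge <- function(cohort, rules = grop_rules()) {
  vapply(seq_len(nrow(cohort)), function(i)
    grop_screen_decision(cohort[i, , drop = FALSE], rules) == "no_screen",
    logical(1))
}

#' Compare two screening methods on the same infants
#'
#' Superiority is judged lexicographically: a method that misses a
#' treated infant (sensitivity below 100%) loses outright; among
#' 100%-sensitive methods, the exact sign test on per-infant discharge
#' indicators of never-treated infants decides, favoring the method
#' releasing more infants.
#'
#' @param treated logical outcome vector.
#' @param discharge_a,discharge_b logical discharge indicators of methods
#'   A and B for the same infants.
#' @param level confidence level for the sensitivity/specificity
#'   intervals.
#' @return a `rop_comparison` list: per-method sensitivity and
#'   specificity (`rop_interval`s), the `verdict` (`"A"`, `"B"` or
#'   `"tie"`), its `reason`, and `sign_test` results when applicable.
#' @export
compare_tools <- function(treated, discharge_a, discharge_b, level = 0.95) {
  stopifnot(length(treated) == length(discharge_a),
            length(treated) == length(discharge_b))
  treated <- as.logical(treated)
  a <- as.logical(discharge_a); b <- as.logical(discharge_b)
  n1 <- sum(treated); n0 <- sum(!treated)
  sens <- function(d) clopper_pearson(sum(treated & !d), n1, level)
  spec <- function(d) clopper_pearson(sum(!treated & d), n0, level)
  sens_a <- sens(a); sens_b <- sens(b)
  out <- list(sensitivity = list(A = sens_a, B = sens_b),
              specificity = list(A = spec(a), B = spec(b)),
              sign_test = NULL)
  if (sens_a$point == 1 && sens_b$point < 1) {
    out$verdict <- "A"; out$reason <- "B misses treated infants"
  } else if (sens_b$point == 1 && sens_a$point < 1) {
    out$verdict <- "B"; out$reason <- "A misses treated infants"
  } else if (sens_a$point < 1 && sens_b$point < 1) {
    out$verdict <- "tie"
    out$reason <- "neither method achieves 100% sensitivity"
  } else {
    st <- sign_test(a[!treated], b[!treated])
    out$sign_test <- st
    if (st$p_value < 0.05 && st$n_a_only != st$n_b_only) {
      out$verdict <- if (st$n_a_only > st$n_b_only) "A" else "B"
      out$reason <- sprintf(
        "both 100%% sensitive; sign test on discharges p = %.3g", st$p_value)
    } else {
      out$verdict <- "tie"
      out$reason <- sprintf(
        "both 100%% sensitive; sign test not significant (p = %.3g)",
        st$p_value)
    }
  }
  structure(out, class = "rop_comparison")
}

#' @export
print.rop_comparison <- function(x, ...) {
  cat("Method comparison (A vs B)\n")
  for (m in c("A", "B"))
    cat(sprintf("  %s: sensitivity %.3f (%.3f-%.3f), specificity %.3f (%.3f-%.3f)\n",
                m, x$sensitivity[[m]]$point, x$sensitivity[[m]]$lo,
                x$sensitivity[[m]]$hi, x$specificity[[m]]$point,
                x$specificity[[m]]$lo, x$specificity[[m]]$hi))
  cat(sprintf("  verdict: %s (%s)\n", x$verdict, x$reason))
  invisible(x)
}
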