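# Evaluation harness: confusion metrics with exact intervals, stratified
# 10-fold cross-validation of the full pipeline, temporal (external)
# validation, and calibration curves.

#' Metrics of a decision run with confidence intervals
#'
#' Treating "kept under screening" as the positive prediction for eventual
#' ROP treatment: sensitivity, specificity (final cumulative), cumulative
#' specificity per stage, PPV, NPV, accuracy (all Clopper-Pearson exact
#' intervals) and the AUC of the supplied risk score (Hanley-McNeil
#' interval).
#'
#' @param decisions a `rop_decisions` from [apply_tool()].
#' @param risk_score optional per-infant score (e.g. prescreen risk) for
#'   the AUC; same order as `decisions$infants`.
#' @param level confidence level.
#' @return a `rop_metrics` list of `rop_interval`s plus counts.
#' @export
metrics_report <- function(decisions, risk_score = NULL, level = 0.95) {
  inf <- decisions$infants
  treated <- inf$treated
  kept <- !inf$discharged
  tp <- sum(treated & kept); fn <- sum(treated & !kept)
  tn <- sum(!treated & !kept); fp <- sum(!treated & kept)
  cp <- function(x, n) if (n == 0) interval_estimate(NA, NA, NA, level)
        else clopper_pearson(x, n, level)
  stages <- tool_stages()
  idx <- match(inf$discharge_stage, stages)
  cum <- lapply(seq_along(stages), function(s)
    cp(sum(!treated & !is.na(idx) & idx <= s), sum(!treated)))
  names(cum) <- stages
  auc <- NULL
  if (!is.null(risk_score) && sum(treated) > 0 && sum(!treated) > 0) {
    a <- rank_auc(risk_score, treated)
    n1 <- sum(treated); n0 <- sum(!treated)
    # Hanley-McNeil standard error
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                  (n0 - 1) * (q2 - a^2)) / (n1 * n0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    auc <- interval_estimate(a, max(0, a - z * se), min(1, a + z * se), level)
  }
  structure(list(
    sensitivity = cp(tp, tp + fn),
    specificity = cp(tn, tn + fp),
    cumulative_specificity = cum,
    ppv = cp(tp, tp + fp),
    npv = cp(tn, tn + fn),
    accuracy = cp(tp + tn, nrow(inf)),
    auc = auc,
    n = nrow(inf), n_events = sum(treated),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)
  ), class = "rop_metrics")
}

#' @export
print.rop_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("n = %d (%d treated)\n", x$n, x$n_events))
  show <- function(nm, iv) if (!is.null(iv) && !is.na(iv$point))
    cat(sprintf("  %-22s %.*f (%.*f-%.*f)\n", nm, digits, iv$point,
                digits, iv$lo, digits, iv$hi))
  show("sensitivity", x$sensitivity)
  show("specificity", x$specificity)
  show("ppv", x$ppv)
  show("npv", x$npv)
  show("accuracy", x$accuracy)
  show("auc", x$auc)
  cs <- vapply(x$cumulative_specificity, `[[`, numeric(1), "point")
  cat("  cumulative specificity:",
      paste(sprintf("%s=%.3f", names(cs), cs), collapse = " "), "\n")
  invisible(x)
}

# stratified fold assignment: spreads events and GA strata evenly
make_folds <- function(treated, strata, k, seed) {
  set.seed(seed)
  n <- length(treated)
  fold <- integer(n)
  for (cell in split(seq_len(n), list(treated, strata), drop = TRUE)) {
    cell <- sample(cell)
    fold[cell] <- rep_len(sample(seq_len(k)), length(cell))
  }
  fold
}

# one full pipeline run: fit prescreen + screen on train, calibrate
# cutoffs on train, return fits + table
fit_pipeline <- function(train, interval_weeks = 1,
                         candidates = "sex:pnd", basis = NULL,
                         screen_candidates = "lo:det", epsilon = 1e-6) {
  pre <- fit_prescreen(train, candidates = candidates, basis = basis,
                       interval_weeks = interval_weeks)
  obs <- build_screen_observations(train, pre)
  scr <- fit_screen(obs, candidates = screen_candidates)
  rm_ <- risk_matrix(train, pre, scr)
  ct <- calibrate_cutoffs(rm_, train$treated, ga_stratum(train$ga_weeks),
                          epsilon = epsilon,
                          version = paste(pre$version, scr$version, sep = "+"))
  list(prescreen = pre, screen = scr, cutoffs = ct)
}

#' Cross-validate the full decision pipeline
#'
#' Stratified k-fold cross-validation (folds balanced on treatment
#' outcome and GA stratum): on each training split the prescreen model,
#' the weekly screen models and the 100%-sensitivity cutoffs are refitted,
#' and decisions are taken on the held-out fold. Metrics are pooled over
#' all held-out decisions; per-fold metrics are also returned. The same
#' seed always yields identical folds and metrics.
#'
#' @param cohort an [rop_cohort()].
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param ... passed to the pipeline fit (e.g. `interval_weeks`,
#'   `candidates`, `basis`).
#' @return list with `pooled` (a `rop_metrics` over held-out decisions),
#'   `per_fold` (list of `rop_metrics`), `folds` (assignment vector),
#'   `seed`.
#' @export
cross_validate <- function(cohort, k = 10, seed = 1, ...) {
  stopifnot(k >= 2, k <= nrow(cohort))
  folds <- make_folds(cohort$treated, ga_stratum(cohort$ga_weeks), k, seed)
  all_inf <- vector("list", k)
  all_risk <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train <- cohort[folds != f, , drop = FALSE]
    test <- cohort[folds == f, , drop = FALSE]
    if (nrow(test) == 0) next
    if (sum(train$treated) == 0)
      stopf("fold %d leaves no treatment events for training; use fewer folds", f)
    pl <- fit_pipeline(train, ...)
    dec <- apply_tool(test, pl$prescreen, pl$screen, pl$cutoffs)
    risk <- predict(pl$prescreen, test, type = "p")
    all_inf[[f]] <- dec$infants
    all_risk[[f]] <- risk
    per_fold[[f]] <- metrics_report(dec, risk)
  }
  pooled_dec <- structure(list(infants = do.call(rbind, all_inf)),
                          class = "rop_decisions")
  list(pooled = metrics_report(pooled_dec, unlist(all_risk)),
       per_fold = per_fold, folds = folds, seed = seed)
}

#' Temporal (external) validation
#'
#' Fits the pipeline on the development cohort only and evaluates
#' decisions on a temporally separate validation cohort, reporting the
#' metrics plus GA-stratified discharge fractions.
#'
#' @param development,validation disjoint [rop_cohort()]s.
#' @param ... passed to the pipeline fit.
#' @return list with `metrics` (a `rop_metrics`), `by_ga` (data.frame of
#'   per-stratum discharge fractions among non-treated infants), and the
#'   fitted `pipeline`.
#' @export
temporal_validate <- function(development, validation, ...) {
  if (nrow(validation) == 0) stopf("empty validation cohort")
  pl <- fit_pipeline(development, ...)
  dec <- apply_tool(validation, pl$prescreen, pl$screen, pl$cutoffs)
  risk <- predict(pl$prescreen, validation, type = "p")
  inf <- dec$infants
  by_ga <- do.call(rbind, lapply(split(inf, inf$ga_stratum), function(d)
    data.frame(ga_stratum = d$ga_stratum[1], n = nrow(d),
               discharged = sum(d$discharged),
               fraction = mean(d$discharged))))
  rownames(by_ga) <- NULL
  list(metrics = metrics_report(dec, risk), by_ga = by_ga, pipeline = pl,
       decisions = dec)
}

#' Calibration curve
#'
#' Bins predictions by risk quantiles and reports the mean predicted risk
#' and the observed event rate per bin, ready for plotting against the
#' diagonal.
#'
#' @param predicted predicted probabilities.
#' @param observed 0/1 outcomes.
#' @param n_bins number of quantile bins (default 10).
#' @return data.frame with `bin`, `n`, `mean_predicted`, `observed_rate`.
#' @export
calibration_curve <- function(predicted, observed, n_bins = 10) {
  stopifnot(length(predicted) == length(observed),
            length(predicted) >= n_bins)
  br <- unique(stats::quantile(predicted, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) br <- c(br - 1e-12, br + 1e-12)  # constant predictions
  grp <- cut(predicted, br, include.lowest = TRUE)
  out <- data.frame(
    bin = levels(grp),
    n = as.vector(table(grp)),
    mean_predicted = as.vector(tapply(predicted, grp, mean)),
    observed_rate = as.vector(tapply(as.numeric(observed), grp, mean))
  )
  rownames(out) <- NULL
  out
}
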