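# Statistical primitives: 2x2 odds ratios with Woolf (log) confidence
# limits, covariate-adjusted logistic odds ratios, Miettinen-Nurminen
# score limits for a risk difference, Clopper-Pearson exact binomial
# intervals, ROC/AUC with Youden cutoff search, the Hosmer-Lemeshow test,
# the exact sign test, and Spearman correlation.

#' Interval estimate container
#'
#' @param point point estimate.
#' @param lo,hi confidence limits.
#' @param level confidence level.
#' @return a `rop_interval` list.
#' @export
interval_estimate <- function(point, lo, hi, level = 0.95) {
  structure(list(point = point, lo = lo, hi = hi, level = level),
            class = "rop_interval")
}

#' @export
print.rop_interval <- function(x, digits = 3, ...) {
  cat(sprintf("%.*f (%g%% CI, %.*f-%.*f)\n", digits, x$point,
              100 * x$level, digits, x$lo, digits, x$hi))
  invisible(x)
}

#' Odds ratio for a 2x2 table
#'
#' Point estimate `(a/b)/(c/d)` with the Woolf log-scale confidence
#' interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b exposed events and non-events.
#' @param c,d unexposed events and non-events.
#' @param level confidence level (default 0.95).
#' @param continuity if `TRUE`, add 0.5 to every cell when any cell is
#'   zero (Haldane-Anscombe); otherwise a zero cell is an error.
#' @return a `rop_interval`.
#' @export
#' @examples
#' odds_ratio_2x2(1477, 831, 1340, 5888)  # 7.81 (7.04-8.66)
odds_ratio_2x2 <- function(a, b, c, d, level = 0.95, continuity = FALSE) {
  cells <- c(a = unname(a)[1], b = unname(b)[1], c = unname(c)[1],
             d = unname(d)[1])
  stopifnot(all(cells >= 0), all(is.finite(cells)),
            a + b > 0, c + d > 0)
  if (any(cells == 0)) {
    if (!continuity)
      stopf("zero cell in 2x2 table; set continuity = TRUE for the 0.5 correction")
    cells <- cells + 0.5
  }
  or <- (cells["a"] / cells["b"]) / (cells["c"] / cells["d"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  interval_estimate(unname(or), unname(or * exp(-z * se)),
                    unname(or * exp(z * se)), level)
}

#' Adjusted odds ratios by logistic regression
#'
#' Maximum-likelihood logistic model of a binary outcome on an exposure
#' factor plus adjustment covariates; returns a Wald odds-ratio interval
#' per non-reference exposure level, together with the model AUC.
#'
#' @param data data.frame.
#' @param outcome name of a logical/0-1 outcome column.
#' @param exposure name of a factor exposure column (first level is the
#'   reference).
#' @param adjusters character vector of adjustment columns (numeric or
#'   factor); use `character(0)` for a crude model, which reproduces the
#'   [odds_ratio_2x2()] point estimate for a two-level exposure.
#' @param level confidence level.
#' @return list with `estimates` (named list of `rop_interval` per
#'   exposure level), `auc`, `fit` (the `glm`), and `penalized`.
#' @export
adjusted_or_logistic <- function(data, outcome, exposure,
                                 adjusters = c("ga_weeks", "bw_g", "sex"),
                                 level = 0.95) {
  y <- as.numeric(data[[outcome]])
  # constant adjusters carry no information and would break the fit
  adjusters <- adjusters[vapply(adjusters, function(a)
    length(unique(data[[a]])) > 1, logical(1))]
  rhs <- paste(c(exposure, adjusters), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  df <- data[, unique(c(exposure, adjusters)), drop = FALSE]
  if (!is.numeric(df[[exposure]]))
    df[[exposure]] <- droplevels(as.factor(df[[exposure]]))
  df$y <- y
  g <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  penalized <- FALSE
  beta <- stats::coef(g)
  vc <- stats::vcov(g)
  if (any(!is.finite(beta)) || max(abs(beta), na.rm = TRUE) > 15) {
    warnf("separation in adjusted logistic model; using a ridge-penalized fallback")
    X <- stats::model.matrix(g)
    rg <- ridge_glm(X, y, family = "binomial")
    beta <- rg$coefficients
    vc <- rg$vcov
    penalized <- TRUE
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lev_names <- if (is.numeric(df[[exposure]])) exposure
               else paste0(exposure, levels(df[[exposure]])[-1])
  est <- lapply(lev_names, function(nm) {
    se <- sqrt(vc[nm, nm])
    interval_estimate(exp(beta[[nm]]), exp(beta[[nm]] - z * se),
                      exp(beta[[nm]] + z * se), level)
  })
  names(est) <- lev_names
  eta <- stats::predict(g)
  list(estimates = est, auc = rank_auc(eta, y), fit = g, penalized = penalized)
}

# constrained MLE of p2 under H0: p1 - p2 = delta (Farrington-Manning
# closed-form cubic solution), used by the Miettinen-Nurminen score
fm_constrained_p2 <- function(x1, n1, x2, n2, delta) {
  p1h <- x1 / n1; p2h <- x2 / n2
  theta <- n2 / n1
  a <- 1 + theta
  b <- -(1 + theta + p1h + theta * p2h + delta * (theta + 2))
  cc <- delta^2 + delta * (2 * p1h + theta + 1) + p1h + theta * p2h
  d <- -p1h * delta * (1 + delta)
  v <- b^3 / (27 * a^3) - b * cc / (6 * a^2) + d / (2 * a)
  s <- sqrt(pmax(b^2 / (9 * a^2) - cc / (3 * a), 0))
  u <- ifelse(v > 0, s, -s)
  arg <- ifelse(u == 0, 0, pmin(pmax(v / u^3, -1), 1))
  w <- (pi + acos(arg)) / 3
  p1t <- 2 * u * cos(w) - b / (3 * a)
  p1t <- pmin(pmax(p1t, 1e-12), 1 - 1e-12)
  p2t <- pmin(pmax(p1t - delta, 1e-12), 1 - 1e-12)
  list(p1 = p1t, p2 = p2t)
}

# Miettinen-Nurminen score statistic for p1 - p2 = delta (z^2 scale)
mn_score <- function(x1, n1, x2, n2, delta) {
  p <- fm_constrained_p2(x1, n1, x2, n2, delta)
  N <- n1 + n2
  V <- (p$p1 * (1 - p$p1) / n1 + p$p2 * (1 - p$p2) / n2) * N / (N - 1)
  (x1 / n1 - x2 / n2 - delta)^2 / V
}

#' Miettinen-Nurminen confidence limits for a risk difference
#'
#' Point estimate `x1/n1 - x2/n2`; limits by inverting the
#' Miettinen-Nurminen score statistic (restricted MLE variance with the
#' N/(N-1) factor) by bisection to an absolute tolerance of 1e-8.
#'
#' @param x1,n1 events and size of the exposed group.
#' @param x2,n2 events and size of the reference group.
#' @param level confidence level.
#' @return a `rop_interval` for the risk difference.
#' @export
#' @examples
#' mn_risk_difference(1477, 2308, 1340, 7228)  # about 0.455 (0.43-0.48)
mn_risk_difference <- function(x1, n1, x2, n2, level = 0.95) {
  x1 <- unname(x1)[1]; n1 <- unname(n1)[1]
  x2 <- unname(x2)[1]; n2 <- unname(n2)[1]
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  point <- x1 / n1 - x2 / n2
  crit <- stats::qchisq(level, df = 1)
  f <- function(delta) mn_score(x1, n1, x2, n2, delta) - crit
  # the statistic is 0 at the point estimate and increases toward the
  # boundaries; bisect each side for the crossing, to tolerance 1e-8
  bisect <- function(inside, outside) {
    # invariant: f(inside) <= 0 <= f(outside)
    for (i in 1:80) {
      if (abs(outside - inside) < 1e-10) break
      mid <- (inside + outside) / 2
      if (f(mid) > 0) outside <- mid else inside <- mid
    }
    (inside + outside) / 2
  }
  eps <- 1e-12
  lower <- if (f(-1 + eps) < 0) -1 else bisect(point, -1 + eps)
  upper <- if (f(1 - eps) < 0) 1 else bisect(point, 1 - eps)
  interval_estimate(point, lower, upper, level)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact (Beta-quantile) limits for a binomial proportion. For `x = n` the
#' lower limit has the closed form `(alpha/2)^(1/n)` and the upper limit
#' is 1; symmetrically for `x = 0`.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level.
#' @return a `rop_interval`.
#' @export
#' @examples
#' clopper_pearson(447, 447)  # lower bound 0.9918 -> prints as 99.2%
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  alpha <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  interval_estimate(x / n, lo, hi, level)
}

# rank (trapezoidal) AUC with midrank tie handling; equals the
# Wilcoxon-Mann-Whitney statistic scaled to [0, 1]
rank_auc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis with Youden-index cutoff selection
#'
#' AUC by the rank (trapezoidal) method and, over a candidate cutoff set,
#' the cutoff maximizing the Youden index J = sensitivity + specificity
#' - 1. Classification is positive when `score >= cutoff`. Ties on J are
#' broken toward the smaller cutoff.
#'
#' @param scores numeric predictor (e.g. days of parenteral nutrition).
#' @param outcomes logical/0-1 outcome.
#' @param cutoffs candidate cutoffs; default the sorted unique scores.
#' @return list with `auc`, `best_cutoff`, `best_j`, and the full `table`
#'   of (cutoff, sensitivity, specificity, youden).
#' @export
roc_youden <- function(scores, outcomes, cutoffs = NULL) {
  y <- as.logical(outcomes)
  if (length(unique(y)) < 2) stopf("both outcome classes are required")
  if (is.null(cutoffs)) cutoffs <- sort(unique(scores))
  sens <- vapply(cutoffs, function(ct) mean(scores[y] >= ct), numeric(1))
  spec <- vapply(cutoffs, function(ct) mean(scores[!y] < ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # candidates ascending: ties -> smaller
  list(auc = rank_auc(scores, y), best_cutoff = cutoffs[best],
       best_j = j[best],
       table = data.frame(cutoff = cutoffs, sensitivity = sens,
                          specificity = spec, youden = j))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping of predicted probabilities; the chi-squared
#' statistic is referred to `n_groups - 2` degrees of freedom. Groups left
#' empty by heavy ties are merged with their neighbor (with a warning).
#'
#' @param predicted predicted probabilities.
#' @param observed observed 0/1 outcomes.
#' @param n_groups number of risk groups (default 10).
#' @return list with `statistic`, `df`, `p_value`, and the per-group
#'   `table` (n, mean predicted, observed events, expected events).
#' @export
hosmer_lemeshow <- function(predicted, observed, n_groups = 10) {
  stopifnot(length(predicted) == length(observed),
            length(predicted) >= n_groups)
  y <- as.numeric(observed)
  br <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out =
                                                        n_groups + 1)))
  if (length(br) < 2) br <- c(br - 1e-12, br + 1e-12)  # all predictions tied
  if (length(br) < n_groups + 1)
    warnf("tied predictions: %d of %d risk groups retained",
          max(length(br) - 1, 1), n_groups)
  grp <- cut(predicted, breaks = br, include.lowest = TRUE)
  O <- tapply(y, grp, sum)
  E <- tapply(predicted, grp, sum)
  n <- tapply(y, grp, length)
  pbar <- E / n
  stat <- sum((O - E)^2 / (n * pbar * (1 - pbar)))
  df <- max(length(levels(grp)) - 2, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(n = as.vector(n), mean_predicted = as.vector(E / n),
                          observed = as.vector(O), expected = as.vector(E)))
}

#' Exact sign test on paired binary indicators
#'
#' Two-sided exact binomial test on the discordant pairs, as used to
#' compare per-infant discharge indicators between two screening methods.
#' The p-value is twice the smaller tail probability at p = 1/2, capped
#' at 1 (equivalent to the minimum-likelihood convention for a symmetric
#' binomial).
#'
#' @param a,b paired logical indicators.
#' @return list with `n_discordant`, `n_a_only`, `n_b_only`, `p_value`.
#' @export
sign_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  n10 <- sum(a & !b); n01 <- sum(!a & b)
  m <- n10 + n01
  if (m == 0) {
    warnf("no discordant pairs; sign test is uninformative")
    return(list(n_discordant = 0, n_a_only = 0, n_b_only = 0, p_value = 1))
  }
  k <- min(n10, n01)
  p <- min(1, 2 * stats::pbinom(k, m, 0.5))
  list(n_discordant = m, n_a_only = n10, n_b_only = n01, p_value = p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. Errors on constant input, where the
#' coefficient is undefined.
#'
#' @param x,y numeric vectors (at least 3 complete pairs).
#' @return the correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("Spearman correlation is undefined for constant input")
  stats::cor(rank(x), rank(y))
}
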