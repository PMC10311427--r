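# Screen model: one logistic regression per postnatal week 6-14, combining
# the prescreen risk log-odds with whether and when ROP has been detected
# by that week's examination. Detection is coded "by week w" as first
# diagnosis at or before w (closed at the examination week); the age term
# is (w - age at first detection) for detected infants and 0 otherwise.

SCREEN_WEEKS <- 6:14

#' Build weekly screening observations
#'
#' For each infant and each postnatal week 6-14 at which the infant is
#' still under screening (not yet treated at that week, censoring time not
#' passed), emits one observation carrying the prescreen log-odds, the
#' ROP-detection indicator, the time since first detection, and the
#' eventual treatment outcome.
#'
#' @param cohort an [rop_cohort()].
#' @param prescreen_fit a `digirop_prescreen`; used to compute each
#'   infant's risk log-odds. Alternatively supply precomputed values via
#'   `log_odds`.
#' @param log_odds optional numeric vector (one per infant) overriding the
#'   prescreen computation.
#' @return data.frame with columns `infant_id`, `week`,
#'   `prescreen_log_odds`, `rop_detected`, `weeks_since_detection`,
#'   `outcome_treated`.
#' @export
build_screen_observations <- function(cohort, prescreen_fit = NULL,
                                      log_odds = NULL) {
  if (is.null(log_odds)) {
    stopifnot(!is.null(prescreen_fit))
    log_odds <- predict(prescreen_fit, cohort, type = "log_odds")
  }
  stopifnot(length(log_odds) == nrow(cohort))
  out <- vector("list", length(SCREEN_WEEKS))
  for (j in seq_along(SCREEN_WEEKS)) {
    w <- SCREEN_WEEKS[j]
    # treated before (or at) week w: outcome already realized, excluded
    under <- (!cohort$treated | cohort$treatment_pna_weeks > w) &
      cohort$last_exam_pna_weeks >= w
    detected <- !is.na(cohort$first_rop_dx_pna_weeks) &
      cohort$first_rop_dx_pna_weeks <= w
    out[[j]] <- data.frame(
      infant_id = cohort$infant_id[under],
      week = w,
      prescreen_log_odds = log_odds[under],
      rop_detected = detected[under],
      weeks_since_detection = ifelse(detected[under],
                                     w - cohort$first_rop_dx_pna_weeks[under],
                                     0),
      outcome_treated = cohort$treated[under],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

fit_screen_week <- function(obs, int_cols_candidates = "lo:det") {
  X_full <- cbind(`(Intercept)` = 1,
                  log_odds = obs$prescreen_log_odds,
                  detected = as.numeric(obs$rop_detected),
                  weeks_since_detection = obs$weeks_since_detection,
                  `log_odds:detected` = obs$prescreen_log_odds *
                    as.numeric(obs$rop_detected))
  y <- as.numeric(obs$outcome_treated)
  base_cols <- c("(Intercept)", "log_odds", "detected", "weeks_since_detection")
  sets <- list(base_cols)
  if ("lo:det" %in% int_cols_candidates)
    sets <- c(sets, list(c(base_cols, "log_odds:detected")))
  best <- NULL
  for (cols in sets) {
    X <- X_full[, cols, drop = FALSE]
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                          function(v) stats::var(v) > 0))
    X <- X[, keep, drop = FALSE]
    q <- qr(X)
    if (q$rank < ncol(X))  # drop aliased columns (tiny or degenerate data)
      X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
    g <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) invokeRestart("muffleWarning"))
    ll <- sum(stats::dbinom(y, 1, pmin(pmax(g$fitted.values, 1e-12),
                                       1 - 1e-12), log = TRUE))
    aic <- -2 * ll + 2 * ncol(X)
    if (is.null(best) || aic < best$aic)
      best <- list(glm = g, X = X, aic = aic, loglik = ll)
  }
  if (is.null(best)) stopf("screen design matrix is rank deficient")
  g <- best$glm; X <- best$X
  beta <- g$coefficients
  penalized <- FALSE
  if (any(!is.finite(beta)) || max(abs(beta), na.rm = TRUE) > 15 ||
      !g$converged) {
    warnf("separation in a weekly screen fit; using a ridge-penalized fallback")
    rg <- ridge_glm(X, y, family = "binomial")
    beta <- rg$coefficients
    vc <- rg$vcov
    penalized <- TRUE
  } else {
    w <- g$weights
    vc <- solve(crossprod(X * sqrt(w)))
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  # within-sample AUC of the weekly model
  eta <- drop(X %*% beta)
  auc <- rank_auc(eta, y)
  list(coefficients = stats::setNames(beta, colnames(X)), vcov = vc,
       aic = best$aic, loglik = best$loglik, n = nrow(X),
       n_events = sum(y), auc = auc, penalized = penalized)
}

#' Fit the weekly screen models
#'
#' Fits one maximum-likelihood logistic regression per postnatal week
#' 6-14: treatment outcome on prescreen log-odds, ROP-detection indicator,
#' weeks since first detection, and (AIC-selected) the
#' detection-by-log-odds interaction.
#'
#' @param observations output of [build_screen_observations()].
#' @param candidates interaction candidates; currently `"lo:det"` or
#'   `character(0)`.
#' @return a `digirop_screen` object: list of per-week coefficient blocks
#'   plus a shared `version` fingerprint.
#' @export
fit_screen <- function(observations, candidates = "lo:det") {
  fits <- vector("list", length(SCREEN_WEEKS))
  names(fits) <- paste0("week", SCREEN_WEEKS)
  for (j in seq_along(SCREEN_WEEKS)) {
    w <- SCREEN_WEEKS[j]
    obs <- observations[observations$week == w, , drop = FALSE]
    tab <- table(factor(obs$outcome_treated, c(FALSE, TRUE)))
    if (any(tab == 0))
      stopf("week %d has a single outcome class (%d treated of %d); cannot fit",
            w, tab[["TRUE"]], nrow(obs))
    fits[[j]] <- fit_screen_week(obs, candidates)
  }
  out <- structure(list(weeks = SCREEN_WEEKS, fits = fits, version = NULL),
                   class = "digirop_screen")
  out$version <- fingerprint(lapply(fits, `[[`, "coefficients"))
  out
}

#' Predict weekly treatment probability from the screen model
#'
#' Inverse-logit of the week-specific linear predictor.
#'
#' @param object a `digirop_screen`.
#' @param newdata data.frame with `week`, `prescreen_log_odds`,
#'   `rop_detected`, `weeks_since_detection` (as from
#'   [build_screen_observations()]).
#' @param ... unused.
#' @return numeric vector of probabilities in (0,1).
#' @export
predict.digirop_screen <- function(object, newdata, ...) {
  p <- numeric(nrow(newdata))
  X_full <- cbind(`(Intercept)` = 1,
                  log_odds = newdata$prescreen_log_odds,
                  detected = as.numeric(newdata$rop_detected),
                  weeks_since_detection = newdata$weeks_since_detection,
                  `log_odds:detected` = newdata$prescreen_log_odds *
                    as.numeric(newdata$rop_detected))
  for (w in unique(newdata$week)) {
    key <- paste0("week", w)
    if (!key %in% names(object$fits))
      stopf("no screen fit for week %s", format(w))
    f <- object$fits[[key]]
    rows <- newdata$week == w
    eta <- drop(X_full[rows, names(f$coefficients), drop = FALSE] %*%
                  f$coefficients)
    p[rows] <- stats::plogis(eta)
  }
  pmin(pmax(p, 1e-15), 1 - 1e-15)
}

#' @export
print.digirop_screen <- function(x, ...) {
  cat("DIGIROP 2.0 screen model: weekly logistic fits (postnatal weeks 6-14)\n")
  tab <- data.frame(
    week = x$weeks,
    n = vapply(x$fits, `[[`, numeric(1), "n"),
    events = vapply(x$fits, `[[`, numeric(1), "n_events"),
    auc = round(vapply(x$fits, `[[`, numeric(1), "auc"), 3),
    aic = round(vapply(x$fits, `[[`, numeric(1), "aic"), 1),
    penalized = vapply(x$fits, `[[`, logical(1), "penalized")
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.digirop_screen <- function(object, ...) {
  lapply(object$fits, `[[`, "coefficients")
}
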