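# Prescreen model: time-to-ROP-treatment hazard on split person-time,
# fitted as an extended Poisson regression with a log-exposure offset and a
# restricted cubic spline baseline log-hazard. Per-infant treatment risk by
# 20 postnatal weeks is 1 - exp(-H(20)), with H obtained by numerical
# integration of the fitted hazard.

# fixed centering constants shared by the estimator and the simulator so
# that coefficients are directly comparable across the two
GA_CENTER <- 28.5
BW_CENTER <- 1172

# ---- baseline time basis ----------------------------------------------------

#' Define a baseline-hazard time basis
#'
#' The baseline log-hazard f(t) is a linear combination of basis functions
#' of postnatal time. Supported families: `"ns"` (natural/restricted cubic
#' spline via [splines::ns()]), `"linear"` (a single linear term) and
#' `"constant"` (no time dependence; the intercept alone).
#'
#' @param type one of `"ns"`, `"linear"`, `"constant"`.
#' @param knots internal knot locations in weeks (ns only).
#' @param boundary boundary knots in weeks (ns only).
#' @return a `time_basis` list definition.
#' @export
time_basis <- function(type = c("ns", "linear", "constant"),
                       knots = NULL, boundary = NULL) {
  type <- match.arg(type)
  if (type == "ns") {
    stopifnot(!is.null(knots), !is.null(boundary), length(boundary) == 2)
    knots <- sort(as.numeric(knots))
    boundary <- sort(as.numeric(boundary))
  }
  structure(list(type = type, knots = knots, boundary = boundary),
            class = "time_basis")
}

# evaluate the basis at times t; returns an n x df matrix (0 columns for
# the constant basis), with stable column names t1..tk
eval_time_basis <- function(basis, t) {
  t <- as.numeric(t)
  m <- switch(basis$type,
    constant = matrix(numeric(0), nrow = length(t), ncol = 0),
    linear = matrix(t, ncol = 1),
    ns = unclass(splines::ns(t, knots = basis$knots,
                             Boundary.knots = basis$boundary))
  )
  if (ncol(m) > 0) colnames(m) <- paste0("t", seq_len(ncol(m)))
  m
}

# ---- covariate design -------------------------------------------------------

# full covariate design (all candidate columns); fits select subsets.
# Centering: ga at 28.5 weeks, bw at 1172 g scaled per 100 g.
PRESCREEN_MAIN <- c("ga", "boy", "bw100", "pnd_ge14", "pnd_unknown")
PRESCREEN_INTERACTIONS <- list(
  "sex:pnd" = c("boy:pnd_ge14", "boy:pnd_unknown"),
  "ga:pnd"  = c("ga:pnd_ge14", "ga:pnd_unknown")
)

covariate_design <- function(data) {
  pnd <- if ("pnd_cat" %in% names(data)) data$pnd_cat
         else pnd_category(data$pnd_days)
  boy <- as.numeric(data$sex == "boy")
  ga <- data$ga_weeks - GA_CENTER
  bw100 <- (data$bw_g - BW_CENTER) / 100
  ge14 <- as.numeric(pnd == "ge14")
  unk <- as.numeric(pnd == "unknown")
  cbind(ga = ga, boy = boy, bw100 = bw100,
        pnd_ge14 = ge14, pnd_unknown = unk,
        `boy:pnd_ge14` = boy * ge14, `boy:pnd_unknown` = boy * unk,
        `ga:pnd_ge14` = ga * ge14, `ga:pnd_unknown` = ga * unk)
}

# ---- person-time splitting --------------------------------------------------

#' Split follow-up into person-time intervals
#'
#' Expands each infant's follow-up (from birth to treatment or censoring,
#' truncated at 20 weeks) into intervals of at most `interval_weeks`, the
#' standard device that turns a flexible-baseline hazard model into a
#' Poisson regression with a log-exposure offset. The event indicator is 1
#' on the final interval of infants treated within the horizon.
#'
#' @param cohort an [rop_cohort()] (or data.frame with the same columns).
#' @param interval_weeks positive interval width in weeks (default 1).
#' @return data.frame with columns `infant_id`, `t_start`, `t_stop`,
#'   `t_mid`, `exposure`, `event`, and the covariates `ga_weeks`, `sex`,
#'   `bw_g`, `pnd_cat`.
#' @export
split_person_time <- function(cohort, interval_weeks = 1) {
  stopifnot(interval_weeks > 0)
  if (any(cohort$treated & is.na(cohort$treatment_pna_weeks)))
    stopf("treated infant without a treatment time")
  followup <- ifelse(cohort$treated,
                     cohort$treatment_pna_weeks,
                     pmin(cohort$last_exam_pna_weeks, DIGIROP_HORIZON))
  followup <- pmin(followup, DIGIROP_HORIZON)
  if (any(followup <= 0)) stopf("non-positive follow-up time")
  event <- cohort$treated & (cohort$treatment_pna_weeks <= DIGIROP_HORIZON)

  n_int <- ceiling(followup / interval_weeks - 1e-12)
  idx <- rep(seq_len(nrow(cohort)), n_int)
  k <- sequence(n_int)
  t_start <- (k - 1) * interval_weeks
  t_stop <- pmin(k * interval_weeks, followup[idx])
  last <- k == n_int[idx]
  pnd <- pnd_category(cohort$pnd_days)
  data.frame(
    infant_id = cohort$infant_id[idx],
    t_start = t_start, t_stop = t_stop,
    t_mid = (t_start + t_stop) / 2,
    exposure = t_stop - t_start,
    event = as.integer(last & event[idx]),
    ga_weeks = cohort$ga_weeks[idx],
    sex = cohort$sex[idx],
    bw_g = cohort$bw_g[idx],
    pnd_cat = pnd[idx],
    stringsAsFactors = FALSE
  )
}

# ---- fitting ----------------------------------------------------------------

#' Fit the prescreen treatment-risk hazard model
#'
#' Maximizes the Poisson likelihood of treatment events on split
#' person-time with a log-exposure offset. The linear predictor is
#' `f(t) + x'beta` with `f` the baseline log-hazard on the chosen time
#' basis and covariates gestational age, sex, birth weight (per 100 g) and
#' the three-level parenteral-nutrition-duration category. Candidate
#' interaction sets are fitted exhaustively and the model with the lowest
#' AIC is returned.
#'
#' @param data an [rop_cohort()] or a person-time data.frame from
#'   [split_person_time()].
#' @param covariates main-effect columns to include (default all of
#'   `ga, boy, bw100, pnd_ge14, pnd_unknown`).
#' @param candidates character vector of candidate interaction blocks among
#'   `"sex:pnd"` and `"ga:pnd"`; all subsets are compared by AIC. Use
#'   `character(0)` for no interactions.
#' @param basis a [time_basis()]; `NULL` places a 4-knot restricted cubic
#'   spline at quantiles (0.2, 0.4, 0.6, 0.8) of observed event times with
#'   boundary knots at the 0.01 and 0.99 event-time quantiles.
#' @param interval_weeks splitting granularity when `data` is a cohort.
#' @return object of class `digirop_prescreen` with components
#'   `coefficients`, `vcov`, `basis`, `fit_meta` (log-likelihood, AIC,
#'   convergence and penalization flags), `selection` (AIC table over
#'   candidate sets), `n_events`, and a `version` fingerprint.
#' @seealso [predict.digirop_prescreen()], [cumulative_hazard()]
#' @export
fit_prescreen <- function(data, covariates = PRESCREEN_MAIN,
                          candidates = c("sex:pnd", "ga:pnd"),
                          basis = NULL, interval_weeks = 1) {
  pt <- if (!is.null(data$t_start)) data
        else split_person_time(data, interval_weeks)
  if (sum(pt$event) < 1) stopf("no treatment events in the data")
  # Likelihood refinement: isolate each event in a narrow terminal interval
  # so that the event term tracks the hazard at the event time rather than
  # the interval-averaged hazard (the grouped-data approximation of wide
  # event intervals biases a smooth baseline).
  wide <- which(pt$event == 1 & pt$exposure > 0.2)
  if (length(wide) > 0) {
    head_rows <- pt[wide, ]
    head_rows$t_stop <- head_rows$t_stop - 0.1
    head_rows$event <- 0L
    tail_rows <- pt[wide, ]
    tail_rows$t_start <- tail_rows$t_stop - 0.1
    add <- rbind(head_rows, tail_rows)
    add$exposure <- add$t_stop - add$t_start
    add$t_mid <- (add$t_start + add$t_stop) / 2
    pt <- rbind(pt[-wide, ], add)
  }
  if (is.null(basis)) {
    ev_t <- pt$t_mid[pt$event == 1]
    basis <- time_basis("ns",
                        knots = unique(stats::quantile(ev_t, c(.2, .4, .6, .8))),
                        boundary = stats::quantile(ev_t, c(.01, .99)))
  }
  Tb <- eval_time_basis(basis, pt$t_mid)
  Xc <- covariate_design(pt)
  off <- log(pt$exposure)
  y <- pt$event

  # drop requested covariates that are constant in this data (e.g. a single
  # PND level): the model then degenerates gracefully to a birth model
  keep_main <- covariates[apply(Xc[, covariates, drop = FALSE], 2,
                                function(v) stats::var(v) > 0)]

  subsets <- list(character(0))
  for (cand in candidates)
    subsets <- c(subsets, lapply(subsets, c, cand))
  subsets <- unique(subsets)

  # Effective-exposure refinement. With a smooth baseline f, the exact
  # Poisson intensity of an interval is exp(x'b) * int exp(f(s)) ds. An
  # initial fit evaluates the basis at interval midpoints with width
  # offsets; each refinement then replaces the basis row by its
  # hazard-weighted interval average Beff = int B e^f / int e^f and the
  # offset by log int e^f - Beff . theta (5-node Simpson per unique
  # interval). At the fixed point the estimating equations coincide with
  # the exact continuous-time score, so fits are insensitive to the split
  # granularity.
  int_key <- paste(pt$t_start, pt$t_stop)
  uniq <- !duplicated(int_key)
  u_start <- pt$t_start[uniq]; u_stop <- pt$t_stop[uniq]
  u_idx <- match(int_key, int_key[uniq])
  simp_w <- c(1, 4, 2, 4, 1) / 12
  refine_design <- function(coefs) {
    tn <- grep("^t[0-9]+$", names(coefs), value = TRUE)
    w <- u_stop - u_start
    nodes <- outer(w, c(0, 0.25, 0.5, 0.75, 1)) + u_start
    B <- eval_time_basis(basis, as.vector(nodes))
    f <- drop(if (length(tn)) B[, tn, drop = FALSE] %*% coefs[tn]
              else rep(0, length(nodes)))
    # clamp to keep exp() and its products finite during the iteration
    f <- pmin(pmax(f, -30), 30)
    ef <- matrix(exp(f), nrow = length(w))
    I0 <- w * drop(ef %*% simp_w)
    Beff <- matrix(0, length(w), length(tn),
                   dimnames = list(NULL, tn))
    for (j in seq_along(tn)) {
      Bj <- matrix(B[, tn[j]] * exp(f), nrow = length(w))
      Beff[, j] <- w * drop(Bj %*% simp_w) / I0
    }
    off_new <- log(I0) -
      drop(if (length(tn)) Beff %*% coefs[tn] else rep(0, length(w)))
    list(offset = off_new[u_idx], Beff = Beff[u_idx, , drop = FALSE])
  }

  fit_one <- function(int_set) {
    int_cols <- unlist(PRESCREEN_INTERACTIONS[int_set], use.names = FALSE)
    int_cols <- int_cols[vapply(int_cols, function(cn) {
      parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
      all(parts %in% keep_main) && stats::var(Xc[, cn]) > 0
    }, logical(1))]
    X <- cbind(`(Intercept)` = 1, Tb, Xc[, c(keep_main, int_cols), drop = FALSE])
    if (qr(X)$rank < ncol(X)) return(NULL)
    off_j <- off
    g <- NULL
    ref <- NULL  # damped coefficients driving the refinement
    for (iter in 1:30) {
      st <- if (!is.null(g)) {
        s <- g$coefficients
        s[!is.finite(s)] <- 0
        s
      }
      quiet_glm <- function(start) withCallingHandlers(
        stats::glm.fit(X, y, offset = off_j, family = stats::poisson(),
                       start = start),
        warning = function(w) invokeRestart("muffleWarning"))
      g_new <- tryCatch(quiet_glm(st), error = function(e) NULL)
      if (is.null(g_new) || any(!is.finite(g_new$coefficients)))
        g_new <- quiet_glm(NULL)  # cold restart if the warm start diverged
      done <- !is.null(g) &&
        max(abs(g_new$coefficients - g$coefficients), na.rm = TRUE) < 1e-8
      g <- g_new
      if (done || basis$type == "constant") break
      ref <- if (is.null(ref)) g$coefficients
             else (ref + g$coefficients) / 2
      rd <- refine_design(ref)
      tn <- colnames(rd$Beff)
      X[, tn] <- rd$Beff
      off_j <- rd$offset
    }
    ll <- sum(stats::dpois(y, g$fitted.values, log = TRUE)) # fitted include offset
    aic <- -2 * ll + 2 * ncol(X)
    list(glm = g, X = X, offset = off_j, loglik = ll, aic = aic, set = int_set)
  }
  fits <- Filter(Negate(is.null), lapply(subsets, fit_one))
  if (length(fits) == 0) stopf("design matrix is rank deficient")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[which.min(aics)]]

  g <- best$glm; X <- best$X
  beta <- g$coefficients
  sep <- any(!is.finite(beta)) || max(abs(beta), na.rm = TRUE) > 30
  penalized <- FALSE
  if (sep) {
    warnf("apparent separation in the prescreen fit; using a ridge-penalized fallback")
    rg <- ridge_glm(X, y, offset = best$offset, family = "poisson")
    beta <- rg$coefficients
    vc <- rg$vcov
    mu <- rg$fitted
    penalized <- TRUE
    ll <- sum(stats::dpois(y, mu, log = TRUE))
    aic <- -2 * ll + 2 * ncol(X)
  } else {
    w <- g$weights
    vc <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
    if (is.null(vc)) stopf("singular information matrix in the prescreen fit")
    ll <- best$loglik
    aic <- best$aic
  }
  if (!penalized && !g$converged)
    stopf("prescreen Poisson fit did not converge (deviance trace: %s)",
          paste(format(g$deviance), collapse = " -> "))
  dimnames(vc) <- list(colnames(X), colnames(X))

  sel <- data.frame(
    interactions = vapply(fits, function(f)
      if (length(f$set) == 0) "(none)" else paste(f$set, collapse = " + "), ""),
    aic = aics
  )
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = vc,
    basis = basis,
    fit_meta = list(loglik = ll, aic = aic, n_params = ncol(X),
                    converged = if (penalized) TRUE else g$converged,
                    penalized = penalized),
    selection = sel[order(sel$aic), ],
    n_events = sum(y),
    n_rows = nrow(pt),
    interval_weeks = interval_weeks,
    ga_range = range(pt$ga_weeks),
    bw_range = range(pt$bw_g),
    version = NULL
  ), class = "digirop_prescreen") -> out
  out$version <- fingerprint(out$coefficients)
  out
}

#' Construct a prescreen fit from explicit coefficients
#'
#' Builds a `digirop_prescreen` object directly from a time basis and a
#' named coefficient vector, without fitting. Used to specify ground-truth
#' hazards for simulation, to test against closed-form hazards, and to
#' rehydrate serialized fits.
#'
#' @param basis a [time_basis()].
#' @param coefficients named numeric vector: `(Intercept)`, time-basis
#'   columns `t1..tk`, and any of the covariate columns
#'   `ga, boy, bw100, pnd_ge14, pnd_unknown` and interaction columns such
#'   as `boy:pnd_ge14`.
#' @param vcov optional coefficient covariance matrix.
#' @param meta optional list of fit metadata.
#' @return a `digirop_prescreen` object.
#' @export
new_prescreen_fit <- function(basis, coefficients, vcov = NULL, meta = list()) {
  stopifnot(inherits(basis, "time_basis"), "(Intercept)" %in% names(coefficients))
  out <- structure(list(
    coefficients = coefficients, vcov = vcov, basis = basis,
    fit_meta = utils::modifyList(
      list(loglik = NA_real_, aic = NA_real_,
           n_params = length(coefficients), converged = TRUE,
           penalized = FALSE), meta),
    selection = NULL, n_events = NA_integer_, n_rows = NA_integer_,
    interval_weeks = NA_real_, ga_range = c(-Inf, Inf),
    bw_range = c(-Inf, Inf), version = NULL
  ), class = "digirop_prescreen")
  out$version <- fingerprint(out$coefficients)
  out
}

# names of the time-basis coefficients within a fit
time_coef_names <- function(fit) {
  grep("^t[0-9]+$", names(fit$coefficients), value = TRUE)
}

# baseline log-hazard f(t) + intercept, vectorized over t
baseline_log_hazard <- function(fit, t) {
  tn <- time_coef_names(fit)
  b <- eval_time_basis(fit$basis, t)
  drop(fit$coefficients[["(Intercept)"]] +
         (if (length(tn)) b[, tn, drop = FALSE] %*% fit$coefficients[tn]
          else rep(0, length(t))))
}

# covariate linear predictor x'beta (no intercept, no time terms)
covariate_lp <- function(fit, newdata) {
  cn <- setdiff(names(fit$coefficients), c("(Intercept)", time_coef_names(fit)))
  if (length(cn) == 0) return(rep(0, nrow(newdata)))
  Xc <- covariate_design(newdata)
  missing_cols <- setdiff(cn, colnames(Xc))
  if (length(missing_cols) > 0)
    stopf("cannot build covariates: %s", paste(missing_cols, collapse = ", "))
  drop(Xc[, cn, drop = FALSE] %*% fit$coefficients[cn])
}

# ---- cumulative hazard and risk --------------------------------------------

# integral of exp(baseline log-hazard) over [0, t] by composite Simpson,
# refined until successive halvings agree to rel_tol
baseline_integral <- function(fit, t, rel_tol = 1e-8, max_halvings = 12) {
  if (t == 0) return(0)
  m <- max(2, 2 * ceiling(t / 0.2))  # initial grid step ~0.1 weeks
  simpson <- function(m) {
    s <- seq(0, t, length.out = m + 1)
    f <- exp(baseline_log_hazard(fit, s))
    h <- t / m
    even <- if (m > 2) sum(f[seq(3, m - 1, by = 2)]) else 0
    (h / 3) * (f[1] + f[m + 1] + 4 * sum(f[seq(2, m, by = 2)]) + 2 * even)
  }
  est <- simpson(m)
  for (i in seq_len(max_halvings)) {
    m <- 2 * m
    new <- simpson(m)
    if (abs(new - est) <= rel_tol * max(abs(new), 1e-300)) return(new)
    est <- new
  }
  new
}

#' Cumulative treatment hazard
#'
#' Integrates the fitted hazard numerically (composite Simpson, refined to
#' a relative tolerance of 1e-8) to give H(t | x) for each infant in
#' `newdata`. Under the proportional form the per-infant cumulative hazard
#' factorizes as `exp(x'beta)` times the baseline integral, which is
#' computed once per distinct horizon.
#'
#' @param fit a `digirop_prescreen`.
#' @param newdata cohort-like data.frame of covariates.
#' @param t horizon(s) in weeks, in `[0, 20]`; a scalar or one value per row
#'   of `newdata`.
#' @return numeric vector of cumulative hazards, one per row of `newdata`.
#' @export
cumulative_hazard <- function(fit, newdata, t) {
  t <- as.numeric(t)
  if (any(t < 0 | t > DIGIROP_HORIZON))
    stopf("horizon t must lie in [0, %d] weeks", DIGIROP_HORIZON)
  if (!(length(t) %in% c(1L, nrow(newdata))))
    stopf("t must be a scalar or one value per infant")
  lp <- covariate_lp(fit, newdata)
  ints <- vapply(unique(t), function(tt) baseline_integral(fit, tt), numeric(1))
  names(ints) <- format(unique(t), digits = 15)
  I_t <- ints[format(t, digits = 15)]
  unname(exp(lp) * I_t)
}

#' Predict treatment risk from the prescreen model
#'
#' Computes the probability of ROP treatment by `horizon` weeks as
#' `1 - exp(-H(horizon))` together with its log-odds, the quantity carried
#' forward into the weekly screen models. Covariates outside the training
#' support produce a warning, not an error: the tool must still score
#' every infant.
#'
#' @param object a `digirop_prescreen`.
#' @param newdata cohort-like data.frame (columns `ga_weeks`, `sex`,
#'   `bw_g`, and `pnd_days` or `pnd_cat`).
#' @param horizon horizon in weeks (default 20).
#' @param type `"risk"` for a data.frame with `p_treat` and `log_odds`,
#'   `"p"` or `"log_odds"` for the bare vector.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.digirop_prescreen <- function(object, newdata,
                                      horizon = DIGIROP_HORIZON,
                                      type = c("risk", "p", "log_odds"), ...) {
  type <- match.arg(type)
  out_ga <- newdata$ga_weeks < object$ga_range[1] |
    newdata$ga_weeks > object$ga_range[2]
  out_bw <- newdata$bw_g < object$bw_range[1] | newdata$bw_g > object$bw_range[2]
  if (any(out_ga | out_bw, na.rm = TRUE))
    warnf("%d infant(s) outside the training covariate support; scored anyway",
          sum(out_ga | out_bw, na.rm = TRUE))
  H <- cumulative_hazard(object, newdata, horizon)
  p <- -expm1(-H)
  # keep log-odds finite at the numerical extremes
  p_clip <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  lo <- log(p_clip) - log1p(-p_clip)
  switch(type,
         risk = data.frame(p_treat = p, log_odds = lo),
         p = p,
         log_odds = lo)
}

# ---- methods ---------------------------------------------------------------

#' @export
print.digirop_prescreen <- function(x, ...) {
  cat("DIGIROP 2.0 prescreen model (extended Poisson hazard regression)\n")
  cat(sprintf("  baseline: %s time basis", x$basis$type))
  if (x$basis$type == "ns")
    cat(sprintf(" (knots %s; boundary %s)",
                paste(format(x$basis$knots, digits = 3), collapse = ", "),
                paste(format(x$basis$boundary, digits = 3), collapse = ", ")))
  cat("\n")
  if (!is.na(x$fit_meta$aic))
    cat(sprintf("  events: %d; log-lik: %.2f; AIC: %.2f%s\n",
                x$n_events, x$fit_meta$loglik, x$fit_meta$aic,
                if (x$fit_meta$penalized) " (ridge-penalized)" else ""))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.digirop_prescreen <- function(object, ...) object$coefficients

#' @export
vcov.digirop_prescreen <- function(object, ...) object$vcov

#' @export
logLik.digirop_prescreen <- function(object, ...) {
  structure(object$fit_meta$loglik, df = object$fit_meta$n_params,
            class = "logLik")
}

#' Summarize a prescreen fit
#'
#' Coefficient table with standard errors, hazard ratios with 95% Wald
#' confidence intervals and p-values, plus the AIC model-selection table
#' over the candidate interaction sets.
#'
#' @param object a `digirop_prescreen`.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return a `summary.digirop_prescreen` list with elements `coefficients`
#'   (the table) and `selection`.
#' @export
summary.digirop_prescreen <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  tab <- data.frame(
    estimate = est, se = se, hr = exp(est),
    hr_lo = exp(est - z * se), hr_hi = exp(est + z * se),
    p = 2 * stats::pnorm(-abs(est / se))
  )
  structure(list(coefficients = tab, selection = object$selection,
                 fit_meta = object$fit_meta, level = level),
            class = "summary.digirop_prescreen")
}

#' @export
print.summary.digirop_prescreen <- function(x, ...) {
  cat("Prescreen model coefficients (hazard-ratio scale):\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$selection)) {
    cat("\nAIC over candidate interaction sets:\n")
    print(x$selection, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the fitted baseline hazard
#'
#' Baseline treatment hazard over postnatal weeks 0-20 for the covariate
#' reference profile (girl, GA 28.5 weeks, BW 1172 g, PND < 14 days).
#'
#' @param x a `digirop_prescreen`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.digirop_prescreen <- function(x, ...) {
  t <- seq(0, DIGIROP_HORIZON, by = 0.1)
  graphics::plot(t, exp(baseline_log_hazard(x, t)), type = "l",
                 xlab = "postnatal age (weeks)",
                 ylab = "baseline treatment hazard (per week)", ...)
  invisible(x)
}
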