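# Synthetic registry-like cohort generator with a known ground-truth
# treatment hazard. Treatment event times are simulated by inverting the
# cumulative hazard of exactly the spline-log-hazard family the prescreen
# estimator fits, which makes parameter recovery a well-posed test.
#
# Default marginals emulate the SWEDROP-like cohort structure: GA mean 28.5
# (SD 2.4) weeks truncated to [21.9, 39.4]; BW conditional on GA with
# marginal mean/SD near 1172 (384) g; 45.5% girls; ~28.5% any ROP; ~5.4%
# treated; 14.4% unknown PND; ROP onset median 8.4 weeks; treatment timing
# median near 12.6 weeks.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_cohort()]. Defaults encode the
#' registry-like study conditions; every component can be overridden.
#'
#' @param n number of infants.
#' @param seed integer seed; the same seed and configuration give
#'   byte-identical cohorts.
#' @param ga_mean,ga_sd,ga_range gestational-age distribution (truncated
#'   normal), weeks.
#' @param p_girl proportion of girls.
#' @param bw_slope,bw_resid_sd birth weight model: conditional mean
#'   `1172 + bw_slope * (GA - 28.5)` g with normal residual SD
#'   `bw_resid_sd`, truncated to plausible grams.
#' @param pnd_b log-odds slope of P(PND >= 14 d) per week of GA (negative:
#'   more premature infants stay longer on parenteral nutrition).
#' @param pnd_a intercept of that logit at GA 28.5 weeks.
#' @param p_pnd_unknown probability that PND is masked as unknown.
#' @param informative_missingness if `TRUE`, unknown-PND masking is shifted
#'   toward treated infants (log-odds +1) for robustness experiments;
#'   default `FALSE` (missing completely at random).
#' @param beta named ground-truth covariate log-hazard-ratio vector on the
#'   estimator's design coding (`ga`, `boy`, `bw100`, `pnd_ge14`,
#'   `pnd_unknown`, `boy:pnd_ge14`, ...).
#' @param baseline_level peak level of the ground-truth baseline
#'   log-hazard; calibrated so that about 5.4% of infants are treated under
#'   the default covariate effects.
#' @param basis [time_basis()] for the ground-truth baseline log-hazard.
#' @param rop_a,rop_ga,rop_ge14 any-ROP incidence logit: intercept at GA
#'   28.5 (calibrated to a 28.5% marginal), slope per week of GA below
#'   28.5, and additive effect of PND >= 14 days.
#' @param onset_meanlog,onset_sdlog log-normal ROP onset-time parameters
#'   (median 8.4 weeks).
#' @param dx_tx_gap_mean,dx_tx_gap_sd gamma-distributed gap from first
#'   diagnosis to treatment, weeks.
#' @param weight_noise_sd,weight_missing_frac,weight_days,weight_every
#'   daily-weight series: measurement noise SD (g), fraction of infants
#'   with the whole series missing, last measured day, and measurement
#'   spacing in days.
#' @return a `rop_sim_config` list.
#' @export
sim_config <- function(n, seed = 1,
                       ga_mean = 28.5, ga_sd = 2.4, ga_range = c(21.9, 39.4),
                       p_girl = 0.455,
                       bw_slope = 140, bw_resid_sd = 186,
                       pnd_a = -1.85, pnd_b = -0.85,
                       p_pnd_unknown = 0.144,
                       informative_missingness = FALSE,
                       beta = c(ga = -0.45, boy = 0.30, bw100 = -0.05,
                                pnd_ge14 = 1.2, pnd_unknown = 0.3,
                                `boy:pnd_ge14` = -0.5),
                       baseline_level = -6.257,
                       basis = time_basis("ns", knots = c(9, 12, 15),
                                          boundary = c(2, 19)),
                       rop_a = -1.92, rop_ga = 0.85, rop_ge14 = 0.8,
                       onset_meanlog = log(8.4), onset_sdlog = 0.26,
                       dx_tx_gap_mean = 3.9, dx_tx_gap_sd = 3.0,
                       weight_noise_sd = 15, weight_missing_frac = 0.09,
                       weight_days = 42, weight_every = 3) {
  stopifnot(n >= 0, ga_sd > 0,
            p_girl >= 0, p_girl <= 1,
            p_pnd_unknown >= 0, p_pnd_unknown <= 1,
            weight_missing_frac >= 0, weight_missing_frac <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "rop_sim_config"
  cfg
}

# ground-truth baseline log-hazard: the concave target
# baseline_level - (t - 13)^2 / 18 projected onto the spline basis by least
# squares, so the truth lies exactly in the estimator's model family
truth_time_coefs <- function(cfg) {
  grid <- seq(0, DIGIROP_HORIZON, by = 0.1)
  target <- cfg$baseline_level - (grid - 13)^2 / 18
  B <- cbind(1, eval_time_basis(cfg$basis, grid))
  drop(solve(crossprod(B), crossprod(B, target)))
}

#' Ground-truth prescreen fit implied by a simulation configuration
#'
#' @param cfg a [sim_config()].
#' @return a `digirop_prescreen` holding the generating coefficients.
#' @export
truth_prescreen <- function(cfg) {
  tc <- truth_time_coefs(cfg)
  k <- length(tc) - 1
  co <- c(`(Intercept)` = tc[1],
          stats::setNames(tc[-1], paste0("t", seq_len(k))), cfg$beta)
  new_prescreen_fit(cfg$basis, co)
}

# draw from a truncated normal by quantile inversion
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic screening cohort
#'
#' Draws a cohort of `cfg$n` infants: gestational age, sex, birth weight,
#' parenteral nutrition duration (with an unknown fraction), any-ROP
#' incidence and onset timing, maximum ROP stage, and treatment events
#' simulated from the ground-truth hazard by inversion of the cumulative
#' hazard. Treated infants always have an ROP diagnosis preceding
#' treatment; infants never diagnosed carry stage `none`.
#'
#' @param cfg a [sim_config()] (or `n`, to use all defaults with `seed`).
#' @param seed used only when `cfg` is given as a plain count.
#' @return an [rop_cohort()] with attribute `ground_truth`: a list with the
#'   generating `fit` (a `digirop_prescreen`), the coefficient vector
#'   `beta`, and the per-infant true treatment probabilities `p_treat`.
#' @export
simulate_cohort <- function(cfg, seed = 1) {
  if (is.numeric(cfg)) cfg <- sim_config(n = cfg, seed = seed)
  stopifnot(inherits(cfg, "rop_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  truth <- truth_prescreen(cfg)
  if (n == 0) {
    empty <- rop_cohort(data.frame(ga_weeks = numeric(0), sex = character(0),
                                   bw_g = numeric(0), pnd_days = integer(0),
                                   treated = logical(0)))
    attr(empty, "ground_truth") <- list(fit = truth, beta = cfg$beta,
                                        p_treat = numeric(0))
    return(empty)
  }

  ga <- rtruncnorm(n, cfg$ga_mean, cfg$ga_sd, cfg$ga_range[1], cfg$ga_range[2])
  sex <- ifelse(stats::runif(n) < cfg$p_girl, "girl", "boy")
  bw <- BW_CENTER + cfg$bw_slope * (ga - GA_CENTER) +
    stats::rnorm(n, 0, cfg$bw_resid_sd)
  bw <- pmin(pmax(round(bw), 310), 3540)
  bwsds <- (bw - (BW_CENTER + cfg$bw_slope * (ga - GA_CENTER))) / cfg$bw_resid_sd

  # true PND days: GA-dependent probability of the long-duration group
  p_ge14 <- stats::plogis(cfg$pnd_a + cfg$pnd_b * (ga - GA_CENTER))
  ge14 <- stats::runif(n) < p_ge14
  pnd_true <- integer(n)
  pnd_true[ge14] <- 14 + round(stats::rexp(sum(ge14), rate = 1 / 16.8))
  pnd_true[!ge14] <- pmin(13, round(stats::rgamma(sum(!ge14),
                                                  shape = 1.2, scale = 3.7)))

  # mask PND as unknown before outcomes are drawn. The hazard acts through
  # the OBSERVED category, so the generating model is exactly the family
  # the estimator fits and the unknown level carries its own coefficient;
  # by default masking is independent of everything (and of the outcome).
  p_unk <- rep(cfg$p_pnd_unknown, n)
  unknown <- stats::runif(n) < p_unk
  pnd_obs <- ifelse(unknown, NA_integer_, pnd_true)

  # event times by inverting the cumulative hazard on a fine grid
  grid <- seq(0, DIGIROP_HORIZON, by = 0.05)
  base_haz <- exp(baseline_log_hazard(truth, grid))
  I_grid <- c(0, cumsum((base_haz[-1] + base_haz[-length(base_haz)]) / 2 *
                          diff(grid)))
  df_cov <- data.frame(ga_weeks = ga, sex = factor(sex, c("girl", "boy")),
                       bw_g = bw, pnd_cat = pnd_category(pnd_obs))
  lp <- covariate_lp(truth, df_cov)
  E <- stats::rexp(n)
  H20 <- exp(lp) * I_grid[length(I_grid)]
  treated <- E < H20
  t_event <- rep(NA_real_, n)
  if (any(treated))
    t_event[treated] <- pmax(0.1, stats::approx(I_grid, grid,
                                                xout = E[treated] * exp(-lp[treated]))$y)

  # any-ROP incidence and onset; treated infants are always diagnosed first
  p_rop <- stats::plogis(cfg$rop_a + cfg$rop_ga * (GA_CENTER - ga) +
                           cfg$rop_ge14 * ge14)
  any_rop <- (stats::runif(n) < p_rop) | treated
  onset <- rep(NA_real_, n)
  onset[any_rop] <- pmin(stats::rlnorm(sum(any_rop), cfg$onset_meanlog,
                                       cfg$onset_sdlog), 19.5)
  if (any(treated)) {
    gap_shape <- (cfg$dx_tx_gap_mean / cfg$dx_tx_gap_sd)^2
    gap <- stats::rgamma(sum(treated), shape = gap_shape,
                         rate = gap_shape / cfg$dx_tx_gap_mean)
    onset[treated] <- pmin(pmax(1, t_event[treated] - gap), t_event[treated])
  }

  # maximum stage: treated infants reach stage 3; among other diagnosed
  # infants severity increases with PND and prematurity
  stage <- rep("none", n)
  idx <- which(any_rop & !treated)
  if (length(idx) > 0) {
    sev <- 0.04 * pmin(pnd_true[idx], 60) - 0.1 * (ga[idx] - GA_CENTER) +
      stats::rlogis(length(idx))
    cut1 <- stats::quantile(sev, 0.45)
    cut2 <- stats::quantile(sev, 0.85)
    stage[idx] <- ifelse(sev <= cut1, "1", ifelse(sev <= cut2, "2", "3"))
  }
  stage[treated] <- "3"

  # informative missingness (robustness switch): re-mask with the outcome
  # shifting the masking odds, overriding the default independent masking
  if (cfg$informative_missingness) {
    p_unk2 <- stats::plogis(stats::qlogis(cfg$p_pnd_unknown) + treated)
    unknown <- stats::runif(n) < p_unk2
    pnd_obs <- ifelse(unknown, NA_integer_, pnd_true)
  }

  cohort <- rop_cohort(data.frame(
    infant_id = sprintf("sim%06d", seq_len(n)),
    ga_weeks = round(ga, 1), sex = sex, bw_g = bw, bwsds = round(bwsds, 2),
    pnd_days = pnd_obs,
    first_rop_dx_pna_weeks = round(onset, 1),
    max_rop_stage = stage,
    treated = treated,
    treatment_pna_weeks = round(t_event, 1),
    last_exam_pna_weeks = DIGIROP_HORIZON,
    stringsAsFactors = FALSE
  ))
  attr(cohort, "ground_truth") <- list(
    fit = truth, beta = cfg$beta, p_treat = -expm1(-H20), lp = lp,
    pnd_true = pnd_true
  )
  cohort
}

#' Generate daily postnatal weight series
#'
#' Adds a sparse daily-weight map to each infant for use by the G-ROP
#' comparator: a strictly increasing mean growth curve from birth weight
#' (daily gain ramping from 5 to 25 g/day over the first two weeks) plus
#' independent measurement noise, recorded every `weight_every` days up to
#' day `weight_days`. A configurable fraction of infants has the whole
#' series missing, emulating registry incompleteness.
#'
#' @param cohort an [rop_cohort()].
#' @param cfg a [sim_config()] supplying `weight_noise_sd`,
#'   `weight_missing_frac`, `weight_days`, `weight_every`.
#' @param seed integer seed.
#' @return the cohort with `weights_g_by_day` filled in.
#' @export
simulate_weight_series <- function(cohort, cfg = sim_config(nrow(cohort)),
                                   seed = 1) {
  set.seed(seed)
  n <- nrow(cohort)
  days <- sort(unique(c(0, seq(cfg$weight_every, cfg$weight_days,
                               by = cfg$weight_every))))
  gain <- 5 + 20 * pmin(seq_len(cfg$weight_days), 14) / 14
  mean_curve <- c(0, cumsum(gain))          # indexed by day 0..weight_days
  missing <- stats::runif(n) < cfg$weight_missing_frac
  series <- vector("list", n)
  for (i in seq_len(n)) {
    if (missing[i]) next
    w <- cohort$bw_g[i] + mean_curve[days + 1] +
      stats::rnorm(length(days), 0, cfg$weight_noise_sd)
    series[[i]] <- stats::setNames(round(w), days)
  }
  cohort$weights_g_by_day <- series
  cohort$hydrocephalus <- ifelse(is.na(cohort$hydrocephalus), FALSE,
                                 cohort$hydrocephalus)
  cohort
}
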