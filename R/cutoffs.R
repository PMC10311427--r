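# GA-specific probability cutoffs enforcing 100% training sensitivity, and
# the sequential discharge decision tool they drive.
#
# The decision sequence has ten stages: "prescreen" (once the 14-day PND
# category is known, postnatal day 14) followed by weekly decisions at
# postnatal weeks 6-14. At each stage an infant still under screening is
# discharged iff its model risk falls strictly below the cutoff for its GA
# stratum; the cutoff is the minimum risk among treated infants scored at
# that stratum and stage, minus a safety margin epsilon, so that no
# treated training infant is ever discharged.

#' Calibrate GA-specific cutoffs at 100% training sensitivity
#'
#' For every (GA stratum, stage) cell the cutoff is the minimum risk among
#' treated infants scored at that cell minus `epsilon`; strata without
#' treated infants inherit the pooled (all-strata) minimum for the stage.
#' A stage with no scored treated infants at all gets cutoff 0 (nobody is
#' discharged at that stage). Cutoffs are floored at 0, keeping them in
#' [0, 1).
#'
#' @param risks numeric matrix, one row per infant, one column per stage
#'   (columns named as `prescreen, week6, ..., week14`); `NA` where an
#'   infant is not scored at a stage (already treated or discharged).
#' @param outcomes logical vector: eventual ROP treatment.
#' @param strata factor of GA strata (e.g. from [ga_stratum()]).
#' @param epsilon safety margin on the probability scale (default 1e-6):
#'   ties at the minimum must not discharge a treated infant.
#' @param version optional fingerprint of the fits that produced `risks`.
#' @return a `rop_cutoff_table`: matrix strata x stages with attributes
#'   `epsilon` and `version`.
#' @export
calibrate_cutoffs <- function(risks, outcomes, strata, epsilon = 1e-6,
                              version = NULL) {
  risks <- as.matrix(risks)
  if (nrow(risks) == 0) stopf("empty cohort: no risks to calibrate on")
  stopifnot(length(outcomes) == nrow(risks),
            length(strata) == nrow(risks), epsilon >= 0)
  if (any(!is.finite(risks[!is.na(risks)])))
    stopf("non-finite risks cannot be calibrated")
  stages <- colnames(risks) %||% tool_stages()[seq_len(ncol(risks))]
  # keep every declared stratum level: strata unseen in training inherit
  # the pooled minimum, so later cohorts always find a cutoff row
  strata <- as.factor(strata)
  lv <- levels(strata)
  cut <- matrix(NA_real_, nrow = length(lv), ncol = length(stages),
                dimnames = list(lv, stages))
  treated <- as.logical(outcomes)
  for (s in seq_along(stages)) {
    r <- risks[, s]
    scored <- treated & !is.na(r)
    pooled <- if (any(scored)) min(r[scored]) else NA_real_
    for (g in lv) {
      in_g <- scored & strata == g
      m <- if (any(in_g)) min(r[in_g]) else pooled
      cut[g, s] <- if (is.na(m)) 0 else max(m - epsilon, 0)
    }
  }
  structure(cut, epsilon = epsilon, version = version,
            class = c("rop_cutoff_table", "matrix"))
}

#' @export
print.rop_cutoff_table <- function(x, ...) {
  cat("GA-specific discharge cutoffs (risk < cutoff => discharge)\n")
  cat(sprintf("  epsilon = %g%s\n", attr(x, "epsilon"),
              if (!is.null(attr(x, "version")))
                sprintf("; calibrated against fit version %s",
                        attr(x, "version")) else ""))
  print(round(unclass(x), 5))
  invisible(x)
}

# per-infant per-stage risk matrix under the two fitted models; NA where
# the infant is not under screening at the stage
risk_matrix <- function(cohort, prescreen_fit, screen_fits) {
  stages <- tool_stages()
  pre <- predict(prescreen_fit, cohort, type = "risk")
  m <- matrix(NA_real_, nrow = nrow(cohort), ncol = length(stages),
              dimnames = list(cohort$infant_id, stages))
  m[, "prescreen"] <- pre$p_treat
  obs <- build_screen_observations(cohort, log_odds = pre$log_odds)
  p <- predict(screen_fits, obs)
  idx <- match(obs$infant_id, cohort$infant_id)
  for (w in SCREEN_WEEKS) {
    rows <- obs$week == w
    m[idx[rows], paste0("week", w)] <- p[rows]
  }
  m
}

#' Apply the discharge decision-support tool
#'
#' Sequential policy: a prescreen decision (day 14), then weekly decisions
#' at postnatal weeks 6-14. An infant is discharged at the first stage at
#' which its risk is strictly below the cutoff for its GA stratum;
#' discharged infants receive no later decisions, and an infant already
#' treated is never discharged. By default infants with detected ROP
#' remain eligible for discharge (the screen model encodes detection);
#' `discharge_detected = FALSE` forbids it.
#'
#' @param cohort an [rop_cohort()].
#' @param prescreen_fit,screen_fits fitted models from the same training
#'   run as `cutoffs` (checked via the version fingerprint).
#' @param cutoffs a `rop_cutoff_table`.
#' @param discharge_detected may infants with already-detected ROP be
#'   discharged? Default `TRUE`.
#' @return a `rop_decisions` list: `decisions` (one row per infant per
#'   stage evaluated: `infant_id`, `stage`, `risk`, `cutoff`, `action`)
#'   and `infants` (per-infant `discharged`, `discharge_stage`,
#'   `treated`).
#' @export
apply_tool <- function(cohort, prescreen_fit, screen_fits, cutoffs,
                       discharge_detected = TRUE) {
  v <- attr(cutoffs, "version")
  fits_v <- paste(prescreen_fit$version, screen_fits$version, sep = "+")
  if (!is.null(v) && v != fits_v)
    stopf("cutoff table (version %s) does not match the fitted models (%s)",
          v, fits_v)
  stages <- tool_stages()
  rm_ <- risk_matrix(cohort, prescreen_fit, screen_fits)
  strata <- as.character(ga_stratum(cohort$ga_weeks))
  missing_strata <- setdiff(unique(strata), rownames(cutoffs))
  if (length(missing_strata) > 0)
    stopf("no cutoffs for GA strata: %s", paste(missing_strata, collapse = ", "))

  n <- nrow(cohort)
  discharged <- rep(FALSE, n)
  discharge_stage <- rep(NA_character_, n)
  dec <- vector("list", length(stages))
  stage_week <- c(NA, SCREEN_WEEKS)  # decision week per stage; prescreen first
  for (s in seq_along(stages)) {
    st <- stages[s]
    risk <- rm_[, st]
    active <- !discharged & !is.na(risk)
    # an infant treated before this stage's decision week exits via
    # treatment; risk_matrix already withholds scores after treatment
    if (!discharge_detected && s > 1) {
      det <- !is.na(cohort$first_rop_dx_pna_weeks) &
        cohort$first_rop_dx_pna_weeks <= stage_week[s]
      active <- active & !det
    }
    # infants already treated by this stage carry no score (risk is NA),
    # so they can never be discharged; eventual treatment of a held-out
    # infant after a discharge is exactly a sensitivity failure
    ct <- cutoffs[strata, st]
    discharge_now <- active & (risk < ct)
    if (!any(active)) next
    discharged[discharge_now] <- TRUE
    discharge_stage[discharge_now] <- st
    dec[[s]] <- data.frame(
      infant_id = cohort$infant_id[active],
      stage = st,
      risk = risk[active],
      cutoff = ct[active],
      action = ifelse(discharge_now[active], "discharge",
                      "continue_screening"),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    decisions = do.call(rbind, dec),
    infants = data.frame(
      infant_id = cohort$infant_id,
      ga_stratum = strata,
      treated = cohort$treated,
      discharged = discharged,
      discharge_stage = discharge_stage,
      stringsAsFactors = FALSE
    )
  ), class = "rop_decisions")
}

#' @export
print.rop_decisions <- function(x, ...) {
  inf <- x$infants
  cat(sprintf("Screening decisions for %d infants: %d discharged (%.1f%%)\n",
              nrow(inf), sum(inf$discharged), 100 * mean(inf$discharged)))
  tab <- table(factor(inf$discharge_stage, tool_stages()))
  print(tab)
  invisible(x)
}

#' Sensitivity and cumulative specificity of a decision run
#'
#' Sensitivity is the fraction of treated infants never discharged.
#' Cumulative specificity at stage s is the fraction of never-treated
#' infants discharged at or before s; it is nondecreasing across stages.
#'
#' @param decisions a `rop_decisions` from [apply_tool()].
#' @return list with `sensitivity`, `specificity` (final cumulative),
#'   `cumulative_specificity` (named vector over stages), `n`, `n_treated`.
#' @export
tool_metrics <- function(decisions) {
  inf <- decisions$infants
  treated <- inf$treated
  sens <- if (sum(treated) == 0) NA_real_ else
    sum(treated & !inf$discharged) / sum(treated)
  stages <- tool_stages()
  nt <- sum(!treated)
  cum <- vapply(seq_along(stages), function(s) {
    idx <- match(inf$discharge_stage, stages)
    if (nt == 0) return(NA_real_)
    sum(!treated & !is.na(idx) & idx <= s) / nt
  }, numeric(1))
  names(cum) <- stages
  list(sensitivity = sens,
       specificity = unname(cum[length(cum)]),
       cumulative_specificity = cum,
       n = nrow(inf), n_treated = sum(treated))
}
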