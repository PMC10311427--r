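# High-level workflows: the parenteral-nutrition prognostic analysis, the
# model build + validation pipeline, and the tool comparison. These are
# the programmatic counterparts of the command-line entry points in
# inst/cli/digirop.

# deterministic checksum of a cohort for run manifests
cohort_checksum <- function(cohort) {
  fingerprint(list(nrow(cohort), sum(cohort$ga_weeks), sum(cohort$bw_g),
                   sum(cohort$treated), sum(cohort$pnd_days, na.rm = TRUE)))
}

run_manifest <- function(config, seed, inputs) {
  list(config = config, seed = seed,
       inputs = lapply(inputs, cohort_checksum),
       package_version = as.character(utils::packageVersion("digirop")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Prognostic analysis of parenteral nutrition duration
#'
#' Produces the association table for any ROP and for ROP treatment as
#' outcomes: crude odds ratios per PND category (and per week of PND),
#' adjusted odds ratios (GA, BW, sex), model AUCs, Miettinen-Nurminen
#' crude risk differences for the dichotomized exposure, and the
#' ROC/Youden search for an early PND cutoff over candidate days.
#'
#' @param cohort an [rop_cohort()].
#' @param cutoff_days dichotomization cutoff (default 14).
#' @param roc_days candidate cutoffs for the Youden search (default 7:28).
#' @param out_dir optional directory; when given, writes
#'   `pnd_analysis.csv` (the table) and `pnd_analysis.json` (full
#'   results + manifest).
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return a list with one block per outcome (`any_rop`, `treatment`):
#'   crude and adjusted `rop_interval`s per exposure level, `auc`s,
#'   `risk_difference`, and the shared `youden` block; plus `manifest`.
#' @export
run_pnd_analysis <- function(cohort, cutoff_days = 14, roc_days = 7:28,
                             out_dir = NULL, seed = 0) {
  df <- as.data.frame(cohort)
  df$pnd_cat <- pnd_category(df$pnd_days, cutoff_days)
  df$any_rop <- df$max_rop_stage != "none"
  known <- !is.na(df$pnd_days)

  analyse_outcome <- function(y) {
    tab <- function(level) {
      exp_rows <- df$pnd_cat == level
      ref_rows <- df$pnd_cat == "lt14"
      c(a = sum(y & exp_rows), b = sum(!y & exp_rows),
        c = sum(y & ref_rows), d = sum(!y & ref_rows))
    }
    t14 <- tab("ge14"); tun <- tab("unknown")
    crude <- list()
    if (t14["a"] + t14["b"] > 0)
      crude$ge14 <- odds_ratio_2x2(t14["a"], t14["b"], t14["c"], t14["d"])
    if (tun["a"] + tun["b"] > 0)
      crude$unknown <- odds_ratio_2x2(tun["a"], tun["b"], tun["c"], tun["d"])
    dfy <- df; dfy$y <- y
    multi_level <- nlevels(droplevels(df$pnd_cat)) >= 2
    adj <- if (multi_level)
      adjusted_or_logistic(dfy, "y", "pnd_cat",
                           adjusters = c("ga_weeks", "bw_g", "sex"))
    crude_only <- if (multi_level)
      adjusted_or_logistic(dfy, "y", "pnd_cat", adjusters = character(0))
    # per-week-of-PND continuous exposure among infants with known PND
    dfk <- dfy[known, , drop = FALSE]
    dfk$pnd_weeks <- days_to_weeks(dfk$pnd_days)
    pnd_varies <- stats::var(dfk$pnd_weeks) > 0
    per_week <- if (pnd_varies)
      adjusted_or_logistic(dfk, "y", "pnd_weeks", adjusters = character(0))
    per_week_adj <- if (pnd_varies)
      adjusted_or_logistic(dfk, "y", "pnd_weeks",
                           adjusters = c("ga_weeks", "bw_g", "sex"))
    list(
      crude = crude,
      crude_auc = crude_only$auc,
      adjusted = if (!is.null(adj)) adj$estimates,
      adjusted_auc = if (!is.null(adj)) adj$auc,
      per_week_crude = if (!is.null(per_week)) per_week$estimates[[1]],
      per_week_crude_auc = per_week$auc,
      per_week_adjusted = if (!is.null(per_week_adj))
        per_week_adj$estimates[[1]],
      per_week_adjusted_auc = per_week_adj$auc,
      risk_difference = if (t14["a"] + t14["b"] > 0) mn_risk_difference(
        t14["a"], t14["a"] + t14["b"], t14["c"], t14["c"] + t14["d"]),
      events = c(ge14 = unname(t14["a"]), lt14 = unname(t14["c"]),
                 unknown = unname(tun["a"]))
    )
  }

  res <- list(
    any_rop = analyse_outcome(df$any_rop),
    treatment = analyse_outcome(df$treated),
    youden = roc_youden(df$pnd_days[known], df$treated[known],
                        cutoffs = roc_days),
    spearman = if (stats::var(df$pnd_days[known]) > 0 &&
                     stats::var(as.integer(df$max_rop_stage[known])) > 0)
      spearman_rho(df$pnd_days[known], as.integer(df$max_rop_stage[known]))
      else NA_real_,
    manifest = run_manifest(list(cutoff_days = cutoff_days,
                                 roc_days = range(roc_days)),
                            seed, list(cohort = cohort))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rows <- list()
    for (oc in c("any_rop", "treatment")) {
      b <- res[[oc]]
      fmt <- function(iv) sprintf("%.2f (%.2f-%.2f)", iv$point, iv$lo, iv$hi)
      for (lv in c("ge14", "unknown")) {
        if (is.null(b$crude[[lv]])) next
        aor <- b$adjusted[[paste0("pnd_cat", lv)]]
        rows[[length(rows) + 1]] <- data.frame(
          outcome = oc, exposure = lv,
          events = b$events[[lv]],
          crude_or = fmt(b$crude[[lv]]),
          adjusted_or = if (!is.null(aor)) fmt(aor) else NA)
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "pnd_analysis.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(youden_best_cutoff = res$youden$best_cutoff,
           spearman = res$spearman, manifest = res$manifest),
      file.path(out_dir, "pnd_analysis.json"), auto_unbox = TRUE,
      digits = NA)
  }
  res
}

#' Build and validate the full decision-support pipeline
#'
#' Fits the prescreen and screen models on the development cohort,
#' calibrates 100%-sensitivity cutoffs, reports training metrics,
#' stratified 10-fold cross-validation, and (when a validation cohort is
#' supplied) temporal validation.
#'
#' @param development an [rop_cohort()].
#' @param validation optional disjoint [rop_cohort()]; `NULL` skips
#'   temporal validation.
#' @param k cross-validation folds (default 10).
#' @param seed fold seed, recorded in the manifest.
#' @param out_dir optional directory for serialized fits and the
#'   manifest.
#' @param ... passed to the pipeline fit (`interval_weeks`, `candidates`,
#'   `basis`, `epsilon`, ...).
#' @return list with `pipeline` (fits + cutoffs), `train_metrics`, `cv`,
#'   `temporal` (or `NULL`), `manifest`.
#' @export
run_build_and_validate <- function(development, validation = NULL, k = 10,
                                   seed = 1, out_dir = NULL, ...) {
  pl <- fit_pipeline(development, ...)
  dec <- apply_tool(development, pl$prescreen, pl$screen, pl$cutoffs)
  train_metrics <- metrics_report(dec, predict(pl$prescreen, development,
                                               type = "p"))
  cv <- cross_validate(development, k = k, seed = seed, ...)
  temporal <- if (!is.null(validation) && nrow(validation) > 0)
    temporal_validate(development, validation, ...)
  manifest <- run_manifest(list(k = k, args = list(...)), seed,
                           c(list(development = development),
                             if (!is.null(validation))
                               list(validation = validation)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_digirop(pl$prescreen, file.path(out_dir, "prescreen.json"))
    write_digirop(pl$screen, file.path(out_dir, "screen.json"))
    write_digirop(pl$cutoffs, file.path(out_dir, "cutoffs.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(pipeline = pl, train_metrics = train_metrics, cv = cv,
       temporal = temporal, manifest = manifest)
}

#' Compare the risk-model tool with rule-based criteria
#'
#' Applies the fitted decision tool and the G-ROP rules (base and any
#' extra variants) to the same cohort and judges superiority per
#' [compare_tools()]; externally produced decision vectors (e.g. WINROP)
#' can be supplied as additional columns.
#'
#' @param cohort an [rop_cohort()] with weight series for the G-ROP rules.
#' @param pipeline a fitted pipeline (list with `prescreen`, `screen`,
#'   `cutoffs`) from [run_build_and_validate()].
#' @param rule_sets named list of [grop_rules()] (default base and 180g).
#' @param external optional named list of logical discharge vectors from
#'   other methods.
#' @param seed recorded in the manifest.
#' @return list with `discharge` (named list of indicators, including
#'   `digirop`), `comparisons` (named list of `rop_comparison` of digirop
#'   vs each other method), `manifest`.
#' @export
run_compare <- function(cohort, pipeline,
                        rule_sets = list(grop = grop_rules(),
                                         grop_180g = grop_rules(variant = "180g")),
                        external = NULL, seed = 0) {
  dec <- apply_tool(cohort, pipeline$prescreen, pipeline$screen,
                    pipeline$cutoffs)
  discharge <- c(list(digirop = dec$infants$discharged),
                 lapply(rule_sets, function(r) grop_discharge(cohort, r)),
                 external)
  comparisons <- lapply(discharge[-1], function(d)
    compare_tools(cohort$treated, discharge$digirop, d))
  list(discharge = discharge, comparisons = comparisons,
       manifest = run_manifest(list(methods = names(discharge)), seed,
                               list(cohort = cohort)))
}
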