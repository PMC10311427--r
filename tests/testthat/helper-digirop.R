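# shared fixtures, all built in code

# a tiny hand-written cohort covering the main coding cases
tiny_cohort <- function() {
  rop_cohort(data.frame(
    infant_id = c("a", "b", "c"),
    ga_weeks = c(25.3, 28.0, 31.6),
    sex = c("girl", "boy", "girl"),
    bw_g = c(710, 1100, 1820),
    bwsds = c(-1.2, 0.1, NA),
    pnd_days = c(21L, 5L, NA),
    first_rop_dx_pna_weeks = c(7.4, NA, NA),
    max_rop_stage = c("3", "none", "none"),
    treated = c(TRUE, FALSE, FALSE),
    treatment_pna_weeks = c(12.6, NA, NA),
    last_exam_pna_weeks = c(NA, 20, 15),
    stringsAsFactors = FALSE
  ))
}

# covariate reference profile for hazard predictions
ref_profile <- function(n = 1, ga = 28.5, sex = "girl", bw = 1172,
                        pnd = 5L) {
  data.frame(ga_weeks = rep(ga, n), sex = factor(rep(sex, n),
                                                 c("girl", "boy")),
             bw_g = rep(bw, n), pnd_cat = pnd_category(rep(pnd, n)))
}

# small simulated cohort shared across tests (fitting-scale)
small_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- simulate_cohort(sim_config(4000, seed = 71))
    memo
  }
})

# a fitted pipeline on the shared cohort, computed once
small_pipeline <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- digirop:::fit_pipeline(small_sim(), candidates = "sex:pnd")
    memo
  }
})
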