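test_that("the cutoff is the minimum treated risk minus epsilon", {
  risks <- matrix(c(0.30, 0.12, 0.50, 0.04), ncol = 1,
                  dimnames = list(NULL, "prescreen"))
  treated <- c(TRUE, TRUE, FALSE, FALSE)
  strata <- factor(rep("28", 4))
  ct <- calibrate_cutoffs(risks, treated, strata, epsilon = 1e-6)
  expect_equal(ct["28", "prescreen"], 0.12 - 1e-6)
})

test_that("strata without treated infants inherit the pooled minimum", {
  risks <- matrix(c(0.30, 0.05, 0.02, 0.01), ncol = 1,
                  dimnames = list(NULL, "prescreen"))
  treated <- c(TRUE, TRUE, FALSE, FALSE)
  strata <- factor(c("27", "27", "30", "30"), levels = c("27", "30"))
  ct <- calibrate_cutoffs(risks, treated, strata, epsilon = 1e-6)
  expect_equal(ct["30", "prescreen"], 0.05 - 1e-6)
  # a stage with no treated infants at all discharges nobody
  risks2 <- cbind(risks, week6 = c(NA, NA, 0.01, 0.02))
  ct2 <- calibrate_cutoffs(risks2, treated, strata)
  expect_equal(unname(ct2[, "week6"]), c(0, 0))
})

test_that("an empty cohort is fatal and cutoffs stay within [0, 1)", {
  expect_error(calibrate_cutoffs(matrix(numeric(0), ncol = 1), logical(0),
                                 factor(character(0))), "empty")
  risks <- matrix(c(1e-9, 0.5), ncol = 1)
  ct <- calibrate_cutoffs(risks, c(TRUE, FALSE), factor(c("a", "a")),
                          epsilon = 1e-6)
  expect_gte(min(ct), 0)
  expect_lt(max(ct), 1)
})

test_that("training sensitivity is exactly one on random small cohorts", {
  set.seed(99)
  stages <- digirop:::tool_stages()
  for (rep in 1:100) {
    n <- 60
    risks <- matrix(runif(n * 10), n, 10, dimnames = list(NULL, stages))
    # unscored patches (treated early, etc.)
    risks[sample(length(risks), 40)] <- NA
    treated <- runif(n) < 0.2
    strata <- factor(sample(c("<=24", "27", ">=31"), n, replace = TRUE))
    risks[, 1][is.na(risks[, 1])] <- runif(sum(is.na(risks[, 1])))
    ct <- calibrate_cutoffs(risks, treated, strata)
    # replay the sequential policy directly on the risk matrix
    discharged <- rep(FALSE, n)
    for (s in seq_along(stages)) {
      cuts <- ct[as.character(strata), s]
      hit <- !discharged & !is.na(risks[, s]) & risks[, s] < cuts
      discharged <- discharged | hit
    }
    expect_true(all(!discharged[treated]))
  }
})

test_that("the sequential policy discharges at the first qualifying stage", {
  pl <- small_pipeline()
  co <- small_sim()
  dec <- apply_tool(co, pl$prescreen, pl$screen, pl$cutoffs)
  inf <- dec$infants
  # discharged at prescreen => exactly one decision row
  pre_ids <- inf$infant_id[!is.na(inf$discharge_stage) &
                             inf$discharge_stage == "prescreen"]
  expect_gt(length(pre_ids), 0)
  rows <- dec$decisions[dec$decisions$infant_id %in% pre_ids, ]
  expect_true(all(rows$stage == "prescreen"))
  # treated training infants are never discharged (100% sensitivity)
  expect_true(all(!inf$discharged[inf$treated]))
  m <- tool_metrics(dec)
  expect_equal(m$sensitivity, 1)
  expect_false(is.unsorted(m$cumulative_specificity))
  expect_equal(m$specificity,
               unname(m$cumulative_specificity[["week14"]]))
})

test_that("an all-zero cutoff table discharges nobody", {
  pl <- small_pipeline()
  co <- small_sim()[1:400, ]
  zero <- pl$cutoffs
  zero[, ] <- 0
  dec <- apply_tool(co, pl$prescreen, pl$screen, zero)
  m <- tool_metrics(dec)
  expect_equal(sum(dec$infants$discharged), 0)
  expect_equal(m$specificity, 0)
  expect_equal(m$sensitivity, 1)
})

test_that("a version mismatch between cutoffs and fits is fatal", {
  pl <- small_pipeline()
  stale <- pl$cutoffs
  attr(stale, "version") <- "deadbeef+deadbeef"
  expect_error(apply_tool(small_sim()[1:10, ], pl$prescreen, pl$screen,
                          stale), "version")
})

test_that("lowering epsilon never decreases specificity", {
  pl <- small_pipeline()
  co <- small_sim()
  rm_ <- digirop:::risk_matrix(co, pl$prescreen, pl$screen)
  strata <- ga_stratum(co$ga_weeks)
  spec_at <- function(eps) {
    ct <- calibrate_cutoffs(rm_, co$treated, strata, epsilon = eps,
                            version = attr(pl$cutoffs, "version"))
    tool_metrics(apply_tool(co, pl$prescreen, pl$screen, ct))$specificity
  }
  s <- vapply(c(1e-2, 1e-4, 1e-6), spec_at, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("raising a cutoff above a treated risk breaks training sensitivity", {
  risks <- matrix(c(0.2, 0.6, 0.1), ncol = 1,
                  dimnames = list(NULL, "prescreen"))
  treated <- c(TRUE, TRUE, FALSE)
  strata <- factor(rep("x", 3))
  ct <- calibrate_cutoffs(risks, treated, strata)
  raised <- ct
  raised[1, 1] <- 0.25  # above the smallest treated risk
  discharged <- risks[, 1] < raised[strata, 1]
  expect_true(any(discharged & treated))
})

test_that("forbidding discharge of detected infants is honored", {
  pl <- small_pipeline()
  co <- small_sim()
  dec <- apply_tool(co, pl$prescreen, pl$screen, pl$cutoffs,
                    discharge_detected = FALSE)
  inf <- dec$infants
  det <- !is.na(co$first_rop_dx_pna_weeks)
  # detected infants may only leave at the prescreen stage (before any
  # examination has found ROP) or not at all
  stages <- inf$discharge_stage[det & inf$discharged]
  late_ok <- vapply(which(det & inf$discharged &
                            inf$discharge_stage != "prescreen"),
                    function(i) co$first_rop_dx_pna_weeks[i] >
                      as.integer(sub("week", "", inf$discharge_stage[i])),
                    logical(1))
  expect_true(all(late_ok))
})

test_that("cutoff tables serialize and restore exactly", {
  ct <- small_pipeline()$cutoffs
  path <- withr::local_tempfile(fileext = ".json")
  write_digirop(ct, path)
  back <- read_digirop(path)
  expect_equal(unclass(back), unclass(ct), ignore_attr = TRUE)
  expect_equal(attr(back, "epsilon"), attr(ct, "epsilon"))
  expect_equal(attr(back, "version"), attr(ct, "version"))
})
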