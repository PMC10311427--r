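test_that("weekly observations encode detection with a closed week boundary", {
  co <- rop_cohort(data.frame(
    infant_id = c("dx", "none", "tx"),
    ga_weeks = 27, sex = "girl", bw_g = 1000, pnd_days = 5,
    first_rop_dx_pna_weeks = c(8.4, NA, 7.0),
    max_rop_stage = c("2", "none", "3"),
    treated = c(FALSE, FALSE, TRUE),
    treatment_pna_weeks = c(NA, NA, 12.6)
  ))
  obs <- build_screen_observations(co, log_odds = c(-2, -3, -1))
  dx <- obs[obs$infant_id == "dx", ]
  # first ROP at 8.4 weeks: not detected at week 8, detected at week 9
  expect_false(dx$rop_detected[dx$week == 8])
  expect_true(dx$rop_detected[dx$week == 9])
  expect_equal(dx$weeks_since_detection[dx$week == 9], 0.6)
  # never diagnosed: nine observations, none detected
  none <- obs[obs$infant_id == "none", ]
  expect_equal(nrow(none), 9)
  expect_false(any(none$rop_detected))
  expect_true(all(none$weeks_since_detection == 0))
  # treated at 12.6: weeks 6..12 only (outcome realized from week 13 on)
  tx <- obs[obs$infant_id == "tx", ]
  expect_equal(tx$week, 6:12)
  expect_true(all(tx$outcome_treated))
  # counting oracle
  expect_equal(nrow(obs), 9 + 9 + 7)
})

test_that("screen fits recover a unit slope on the prescreen log-odds", {
  set.seed(11)
  n <- 4000
  obs <- do.call(rbind, lapply(6:14, function(w) {
    lo <- rnorm(n / 9, mean = -3, sd = 1.2)
    data.frame(infant_id = sprintf("i%d_%d", w, seq_along(lo)), week = w,
               prescreen_log_odds = lo, rop_detected = FALSE,
               weeks_since_detection = 0,
               outcome_treated = runif(length(lo)) < plogis(lo))
  }))
  fits <- fit_screen(obs, candidates = character(0))
  for (f in fits$fits) {
    se <- sqrt(diag(f$vcov))[["log_odds"]]
    expect_lt(abs(f$coefficients[["log_odds"]] - 1), 3 * se)
  }
})

test_that("an outcome independent of the predictors gives AUC near 0.5", {
  set.seed(12)
  obs <- data.frame(infant_id = as.character(1:900),
                    week = rep(6:14, each = 100),
                    prescreen_log_odds = rnorm(900),
                    rop_detected = FALSE, weeks_since_detection = 0,
                    outcome_treated = runif(900) < 0.3)
  fits <- fit_screen(obs, candidates = character(0))
  aucs <- vapply(fits$fits, `[[`, numeric(1), "auc")
  expect_lt(max(abs(aucs - 0.5)), 0.2)
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("a week with a single outcome class raises an error", {
  obs <- data.frame(infant_id = as.character(1:90),
                    week = rep(6:14, each = 10),
                    prescreen_log_odds = rnorm(90),
                    rop_detected = FALSE, weeks_since_detection = 0,
                    outcome_treated = rep(c(TRUE, FALSE), 45))
  obs$outcome_treated[obs$week == 10] <- FALSE
  expect_error(fit_screen(obs), "single outcome class")
})

# a screen fit with hand-set coefficients for arithmetic checks
toy_screen <- function(coefs) {
  fits <- lapply(6:14, function(w)
    list(coefficients = coefs, vcov = diag(length(coefs)), aic = NA,
         loglik = NA, n = 0, n_events = 0, auc = NA, penalized = FALSE))
  names(fits) <- paste0("week", 6:14)
  structure(list(weeks = 6:14, fits = fits, version = "toy"),
            class = "digirop_screen")
}

test_that("screen predictions are the inverse logit of the linear predictor", {
  fits <- toy_screen(c(`(Intercept)` = 0, log_odds = 0, detected = 0,
                       weeks_since_detection = 0))
  nd <- data.frame(week = 7, prescreen_log_odds = 2.5, rop_detected = TRUE,
                   weeks_since_detection = 1)
  expect_equal(predict(fits, nd), 0.5)
  fits2 <- toy_screen(c(`(Intercept)` = -1, log_odds = 0.5, detected = 1,
                        weeks_since_detection = 0.25))
  # hand-computed: -1 + 0.5*2.5 + 1 + 0.25*1 = 1.5
  expect_equal(predict(fits2, nd), plogis(1.5), tolerance = 1e-12)
  expect_error(predict(fits2, transform(nd, week = 5)), "no screen fit")
})

test_that("predictions increase in the prescreen log-odds", {
  fits <- small_pipeline()$screen
  lo <- seq(-6, 0, by = 0.5)
  for (w in c(6, 10, 14)) {
    nd <- data.frame(week = w, prescreen_log_odds = lo,
                     rop_detected = FALSE, weeks_since_detection = 0)
    expect_true(all(diff(predict(fits, nd)) > 0), info = paste("week", w))
  }
})

test_that("with detection terms zeroed, weekly ranks follow prescreen risk", {
  fits <- small_pipeline()$screen
  zeroed <- fits
  for (w in names(zeroed$fits)) {
    co <- zeroed$fits[[w]]$coefficients
    co[intersect(names(co), c("detected", "weeks_since_detection",
                              "log_odds:detected"))] <- 0
    zeroed$fits[[w]]$coefficients <- co
  }
  lo <- sort(rnorm(40, -3, 1.5))
  nd <- data.frame(week = 8, prescreen_log_odds = lo,
                   rop_detected = rep(c(TRUE, FALSE), 20),
                   weeks_since_detection = rep(c(2, 0), 20))
  p <- predict(zeroed, nd)
  expect_equal(order(p), order(lo))
  expect_true(all(p > 0 & p < 1))
})

test_that("screen fit bundles survive JSON serialization", {
  fits <- small_pipeline()$screen
  path <- withr::local_tempfile(fileext = ".json")
  write_digirop(fits, path)
  back <- read_digirop(path)
  nd <- data.frame(week = c(6, 9, 14), prescreen_log_odds = c(-4, -2, -1),
                   rop_detected = c(FALSE, TRUE, TRUE),
                   weeks_since_detection = c(0, 0.5, 3))
  expect_equal(predict(back, nd), predict(fits, nd), tolerance = 1e-12)
  expect_equal(back$version, fits$version)
})
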