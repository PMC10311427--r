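test_that("person-time splitting partitions follow-up exactly", {
  co <- tiny_cohort()
  pt <- split_person_time(co, interval_weeks = 1)
  # censored at 20 weeks: 20 rows, no event
  b <- pt[pt$infant_id == "b", ]
  expect_equal(nrow(b), 20)
  expect_true(all(b$event == 0))
  # treated at 12.6 weeks: 13 rows, last row is the event, exposure sums
  a <- pt[pt$infant_id == "a", ]
  expect_equal(nrow(a), 13)
  expect_equal(a$event, c(rep(0L, 12), 1L))
  expect_equal(sum(a$exposure), 12.6)
  # censored at 15 weeks
  expect_equal(sum(pt$infant_id == "c"), 15)
  # counting oracle: total rows = sum of ceil(followup / interval)
  for (iv in c(0.5, 1, 2.4)) {
    pt2 <- split_person_time(co, iv)
    followup <- c(12.6, 20, 15)
    expect_equal(nrow(pt2), sum(ceiling(followup / iv - 1e-12)))
  }
})

test_that("a treated infant without a treatment time is fatal", {
  co <- tiny_cohort()
  co$treatment_pna_weeks[1] <- NA
  expect_error(split_person_time(co), "without a treatment time")
})

test_that("the constant-hazard fit equals the closed-form events/exposure", {
  set.seed(42)
  n <- 2000
  lambda <- 0.012
  t_ev <- rexp(n, lambda)
  co <- rop_cohort(data.frame(
    ga_weeks = 28, sex = "girl", bw_g = 1200, pnd_days = 5,
    treated = t_ev <= 20,
    treatment_pna_weeks = ifelse(t_ev <= 20, pmax(round(t_ev, 2), 0.01), NA),
    first_rop_dx_pna_weeks = ifelse(t_ev <= 20,
                                    pmax(round(t_ev, 2), 0.01) / 2, NA),
    max_rop_stage = ifelse(t_ev <= 20, "3", "none")
  ))
  pt <- split_person_time(co, 1)
  fit <- fit_prescreen(pt, covariates = character(0),
                       candidates = character(0),
                       basis = time_basis("constant"))
  expect_equal(exp(coef(fit)[["(Intercept)"]]),
               sum(pt$event) / sum(pt$exposure), tolerance = 1e-8)
})

test_that("cumulative hazard matches closed forms to 1e-6 relative error", {
  nd <- ref_profile()
  cfit <- new_prescreen_fit(time_basis("constant"),
                            c(`(Intercept)` = log(0.01)))
  for (t in c(0.7, 5, 12.3, 20))
    expect_equal(cumulative_hazard(cfit, nd, t), 0.01 * t,
                 tolerance = 1e-6)
  lfit <- new_prescreen_fit(time_basis("linear"),
                            c(`(Intercept)` = -3, t1 = 0.15))
  for (t in c(1.1, 8, 17.3, 20)) {
    closed <- exp(-3) / 0.15 * (exp(0.15 * t) - 1)
    expect_equal(cumulative_hazard(lfit, nd, t), closed,
                 tolerance = 1e-6)
  }
  # H(0) = 0 and monotonicity on a grid
  expect_equal(cumulative_hazard(lfit, nd, 0), 0)
  H <- vapply(seq(0, 20, 0.5), function(t) cumulative_hazard(lfit, nd, t),
              numeric(1))
  expect_true(all(diff(H) > 0))
  expect_error(cumulative_hazard(lfit, nd, 21), "horizon")
})

test_that("risk prediction follows 1 - exp(-H) with boundary behavior", {
  nd <- ref_profile()
  cfit <- new_prescreen_fit(time_basis("constant"),
                            c(`(Intercept)` = log(0.01)))
  r <- predict(cfit, nd)
  expect_equal(r$p_treat, 1 - exp(-0.2), tolerance = 1e-6)
  expect_equal(r$log_odds, qlogis(r$p_treat), tolerance = 1e-9)
  # H -> 0 gives p -> 0; a huge hazard saturates toward 1, log-odds finite
  tiny <- new_prescreen_fit(time_basis("constant"), c(`(Intercept)` = -40))
  expect_lt(predict(tiny, nd, type = "p"), 1e-15)
  expect_true(is.finite(predict(tiny, nd, type = "log_odds")))
  huge <- new_prescreen_fit(time_basis("constant"), c(`(Intercept)` = 5))
  expect_equal(predict(huge, nd, type = "p"), 1)
  expect_true(is.finite(predict(huge, nd, type = "log_odds")))
})

test_that("fitted risk decreases with gestational age", {
  fit <- small_pipeline()$prescreen
  p <- vapply(c(23, 25, 27, 29, 31), function(g)
    predict(fit, ref_profile(ga = g, bw = 900 + 140 * (g - 26)),
            type = "p"),
    numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("risk predictions are invariant to the split granularity", {
  co <- small_sim()[1:1500, ]
  f1 <- fit_prescreen(co, candidates = character(0), interval_weeks = 1)
  f2 <- fit_prescreen(co, candidates = character(0), interval_weeks = 2.5,
                      basis = f1$basis)
  p1 <- predict(f1, co[1:100, ], type = "p")
  p2 <- predict(f2, co[1:100, ], type = "p")
  expect_lt(max(abs(p1 - p2) / p1), 0.06)
})

test_that("AIC selection rejects a spurious interaction most of the time", {
  hits <- 0
  for (s in 1:4) {
    cfg <- sim_config(2500, seed = 300 + s,
                      beta = c(ga = -0.45, boy = 0.3, bw100 = -0.05,
                               pnd_ge14 = 1.2, pnd_unknown = 0.3))
    co <- simulate_cohort(cfg)
    fit <- fit_prescreen(co, candidates = "ga:pnd", basis = cfg$basis)
    if (fit$selection$interactions[1] == "(none)") hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("a single PND level reduces the model to a birth model", {
  co <- small_sim()[1:2000, ]
  co$pnd_days <- 5L
  fit <- fit_prescreen(co, candidates = c("sex:pnd", "ga:pnd"))
  expect_false(any(grepl("pnd", names(coef(fit)))))
  expect_true(all(c("ga", "boy", "bw100") %in% names(coef(fit))))
})

test_that("the AIC identity and covariance shape hold on a real fit", {
  fit <- small_pipeline()$prescreen
  expect_equal(fit$fit_meta$aic,
               -2 * fit$fit_meta$loglik + 2 * fit$fit_meta$n_params)
  vc <- vcov(fit)
  expect_equal(vc, t(vc))
  expect_true(all(eigen(vc, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  s <- summary(fit)
  expect_true(all(s$coefficients$hr_lo <= s$coefficients$hr))
  expect_true(all(s$coefficients$hr <= s$coefficients$hr_hi))
})

test_that("serialized prescreen fits restore to identical predictions", {
  fit <- small_pipeline()$prescreen
  path <- withr::local_tempfile(fileext = ".json")
  write_digirop(fit, path)
  back <- read_digirop(path)
  nd <- small_sim()[1:50, ]
  expect_equal(predict(back, nd, type = "p"), predict(fit, nd, type = "p"),
               tolerance = 1e-12)
  expect_equal(back$version, fit$version)
})
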