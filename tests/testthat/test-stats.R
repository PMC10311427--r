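test_that("odds ratios honor symmetry, scaling and swap antisymmetry", {
  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$point, 1)
  a <- odds_ratio_2x2(40, 60, 25, 75)
  scaled <- odds_ratio_2x2(80, 120, 25, 75)  # first row doubled
  expect_equal(scaled$point, a$point)
  swapped <- odds_ratio_2x2(25, 75, 40, 60)
  expect_equal(log(swapped$point), -log(a$point))
  expect_error(odds_ratio_2x2(0, 10, 5, 5), "zero cell")
  cc <- odds_ratio_2x2(0, 10, 5, 5, continuity = TRUE)
  expect_true(is.finite(cc$point) && cc$point > 0)
})

test_that("a crude logistic model reproduces the 2x2 odds ratio", {
  df <- data.frame(
    y = rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 60, 25, 75)),
    exp = factor(rep(c("hi", "hi", "lo", "lo"), c(40, 60, 25, 75)),
                 levels = c("lo", "hi"))
  )
  res <- adjusted_or_logistic(df, "y", "exp", adjusters = character(0))
  expect_equal(res$estimates[["exphi"]]$point,
               odds_ratio_2x2(40, 60, 25, 75)$point, tolerance = 1e-6)
})

test_that("adjustment shrinks a confounded odds ratio toward the truth", {
  set.seed(21)
  n <- 20000
  conf <- rnorm(n)
  exposure <- factor(ifelse(runif(n) < plogis(1.5 * conf), "yes", "no"),
                     levels = c("no", "yes"))
  y <- runif(n) < plogis(-1 + 1.2 * conf)  # no direct exposure effect
  df <- data.frame(y = y, exposure = exposure, conf = conf)
  crude <- adjusted_or_logistic(df, "y", "exposure",
                                adjusters = character(0))
  adj <- adjusted_or_logistic(df, "y", "exposure", adjusters = "conf")
  truth <- 1
  expect_gt(abs(log(crude$estimates[[1]]$point)), 0.3)
  expect_lt(abs(log(adj$estimates[[1]]$point)),
            abs(log(crude$estimates[[1]]$point)) / 3)
})

test_that("the adjusted-OR interval covers the null at its nominal rate", {
  set.seed(22)
  hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    n <- 300
    x <- factor(sample(c("a", "b"), n, TRUE), levels = c("a", "b"))
    z <- rnorm(n)
    y <- runif(n) < plogis(-1 + 0.5 * z)
    iv <- adjusted_or_logistic(data.frame(y = y, x = x, z = z), "y", "x",
                               adjusters = "z")$estimates[[1]]
    if (iv$lo <= 1 && 1 <= iv$hi) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.90)
})

test_that("Miettinen-Nurminen limits behave as a score interval should", {
  eq <- mn_risk_difference(10, 100, 10, 100)
  expect_equal(eq$point, 0)
  expect_lt(eq$lo, 0); expect_gt(eq$hi, 0)
  expect_equal(eq$hi, -eq$lo, tolerance = 1e-7)
  iv <- mn_risk_difference(30, 80, 10, 90)
  expect_true(iv$lo <= iv$point && iv$point <= iv$hi)
  # widths shrink roughly like 1/sqrt(n) as counts scale
  w1 <- iv$hi - iv$lo
  big <- mn_risk_difference(300, 800, 100, 900)
  expect_lt(big$hi - big$lo, w1 / 2)
})

# independent grid-inversion oracle for the MN limits
mn_grid_oracle <- function(x1, n1, x2, n2, level = 0.95) {
  crit <- qchisq(level, 1)
  f <- function(d) digirop:::mn_score(x1, n1, x2, n2, d) - crit
  point <- x1 / n1 - x2 / n2
  refine <- function(lo, hi) {
    for (step in 1:8) {
      g <- seq(lo, hi, length.out = 101)
      v <- vapply(g, f, numeric(1))
      i <- which(diff(sign(v)) != 0)[1]
      lo <- g[i]; hi <- g[i + 1]
    }
    (lo + hi) / 2
  }
  c(refine(-1 + 1e-9, point), refine(point, 1 - 1e-9))
}

test_that("MN limits match a fine-grid inversion oracle to 1e-6", {
  cases <- list(c(1477, 2308, 1340, 7228), c(418, 2308, 115, 7228),
                c(30, 80, 10, 90), c(5, 20, 15, 25), c(1, 10, 9, 10))
  for (cs in cases) {
    iv <- mn_risk_difference(cs[1], cs[2], cs[3], cs[4])
    or <- mn_grid_oracle(cs[1], cs[2], cs[3], cs[4])
    expect_equal(iv$lo, or[1], tolerance = 1e-6)
    expect_equal(iv$hi, or[2], tolerance = 1e-6)
  }
})

test_that("Clopper-Pearson limits are exact at the boundaries", {
  expect_equal(clopper_pearson(0, 10)$lo, 0)
  expect_equal(clopper_pearson(0, 10)$hi, 1 - 0.025^(1 / 10),
               tolerance = 1e-12)
  expect_equal(clopper_pearson(10, 10)$lo, 0.025^(1 / 10),
               tolerance = 1e-12)
  expect_equal(clopper_pearson(10, 10)$hi, 1)
  # agrees with the base-R exact binomial test
  bt <- binom.test(7, 20)$conf.int
  iv <- clopper_pearson(7, 20)
  expect_equal(c(iv$lo, iv$hi), as.numeric(bt), tolerance = 1e-9)
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(23)
  for (n in c(10, 100)) {
    p <- 0.3
    x <- rbinom(400, n, p)
    cover <- vapply(x, function(xx) {
      iv <- clopper_pearson(xx, n)
      iv$lo <= p && p <= iv$hi
    }, logical(1))
    expect_gte(mean(cover), 0.94)
  }
})

test_that("ROC and Youden search match brute force on integers", {
  # perfectly separated scores
  perfect <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$best_j, 1)
  # independent scores: AUC near one half
  set.seed(24)
  null <- roc_youden(rnorm(4000), runif(4000) < 0.3)
  expect_lt(abs(null$auc - 0.5), 0.03)
  expect_error(roc_youden(1:5, rep(TRUE, 5)), "both outcome classes")
  # exhaustive oracle over candidate cutoffs 7..28
  set.seed(25)
  days <- sample(0:40, 300, TRUE)
  y <- runif(300) < plogis((days - 14) / 4)
  res <- roc_youden(days, y, cutoffs = 7:28)
  brute <- sapply(7:28, function(ct) {
    mean(days[y] >= ct) + mean(days[!y] < ct) - 1
  })
  expect_equal(res$best_j, max(brute))
  expect_equal(res$best_cutoff, (7:28)[which.max(brute)])
  # pair-counting AUC oracle with tie handling
  pairs <- expand.grid(i = which(y), j = which(!y))
  auc_oracle <- mean(ifelse(days[pairs$i] > days[pairs$j], 1,
                            ifelse(days[pairs$i] == days[pairs$j], 0.5, 0)))
  expect_equal(res$auc, auc_oracle, tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow matches hand arithmetic and degenerates to zero", {
  # constant predictions with a balanced outcome: statistic near zero
  hl0 <- suppressWarnings(
    hosmer_lemeshow(rep(0.5, 100), rep(c(0, 1), 50), n_groups = 2))
  expect_lt(hl0$statistic, 1e-20)
  # two-group toy, computed by hand:
  # group 1: p = 0.2 (n 5, observed 2, expected 1), group 2: p = 0.8
  # (n 5, observed 3, expected 4); each group contributes 1/0.8 = 1.25
  pred <- c(rep(0.2, 5), rep(0.8, 5))
  obs <- c(1, 1, 0, 0, 0, 1, 1, 1, 0, 0)
  hl <- hosmer_lemeshow(pred, obs, n_groups = 2)
  expect_equal(hl$statistic, 2.5, tolerance = 1e-12)
  expect_equal(hl$df, 0)
})

test_that("the sign test reduces to the exact binomial two-sided tail", {
  one_sided <- sign_test(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(one_sided$p_value, 2 * 0.5^10)
  even <- sign_test(c(rep(TRUE, 5), rep(FALSE, 5)),
                    c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(even$p_value, 1)
  expect_warning(sign_test(c(TRUE, FALSE), c(TRUE, FALSE)), "discordant")
  # exhaustive agreement with the base-R exact test for all splits n <= 20
  for (m in 1:20) {
    for (k in 0:m) {
      a <- c(rep(TRUE, k), rep(FALSE, m - k))
      b <- !a
      p <- sign_test(a, b)$p_value
      expect_equal(p, binom.test(k, m, 0.5)$p.value, tolerance = 1e-12,
                   info = sprintf("k=%d m=%d", k, m))
    }
  }
})

test_that("Spearman correlation uses midranks and rejects constants", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  x <- c(1, 2, 2, 3); y <- c(10, 20, 25, 30)
  expect_equal(spearman_rho(x, y),
               cor(c(1, 2.5, 2.5, 4), rank(y)), tolerance = 1e-12)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})
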