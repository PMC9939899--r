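test_that("Kaplan-Meier matches the hand product-limit and the empirical SF", {
  # subjects: 1(event), 2(censored), 3(event), 4(censored)
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km$surv[km$time == 1], 0.75)
  expect_equal(km$surv[km$time == 3], 0.375)
  # no censoring: KM equals the empirical survival function exactly
  set.seed(20)
  t0 <- rexp(40, 1 / 100)
  km2 <- kaplan_meier(t0, rep(1, 40))
  emp <- vapply(km2$time, function(tt) mean(t0 > tt), numeric(1))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
  expect_equal(km2$surv, oracle_km(t0, rep(1, 40))$surv, tolerance = 1e-12)
  # all censored: survival stays at 1
  km3 <- kaplan_meier(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
})

test_that("log-rank equals the Cox score test on random small datasets", {
  set.seed(21)
  for (r in 1:15) {
    n <- sample(20:40, 1)
    grp <- factor(sample(c("high", "low"), n, replace = TRUE))
    if (length(unique(grp)) < 2) next
    tt <- rexp(n, ifelse(grp == "high", 1 / 50, 1 / 100))
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2) next
    lr <- logrank_test(tt, ev, grp)
    cox <- survival::coxph(survival::Surv(tt, ev) ~ grp)
    score_chi2 <- summary(cox)$sctest["test"]
    expect_equal(lr$chi2, unname(score_chi2), tolerance = 1e-6)
  }
})

test_that("log-rank degenerate and identical-group cases behave as documented", {
  tt <- c(3, 5, 8, 12); ev <- c(1, 0, 1, 1)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(c("high", "low"), each = 4))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
})

test_that("univariate Cox recovers a known log-hazard ratio", {
  set.seed(22)
  n <- 300
  # median over replicates: a single draw has SE(beta) ~ 0.12 at this n
  betas <- replicate(5, {
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, exp(1 * x))     # true log-HR = 1, no censoring
    cox_univariate_screen(cbind(grpvar = x), tt, rep(1, n))$beta[1]
  })
  expect_lt(abs(median(betas) - 1), 0.15)
  # constant feature flagged and excluded
  x <- rbinom(n, 1, 0.5); tt <- rexp(n, exp(x))
  scr2 <- cox_univariate_screen(cbind(const = rep(2, n), grpvar = x),
                                tt, rep(1, n))
  expect_identical(scr2$flag[1], "constant")
  expect_false(scr2$kept[1])
  expect_true(scr2$kept[2])
})

test_that("Cox screen keeps ~alpha of features unrelated to the hazard", {
  set.seed(23)
  n <- 80; p <- 200
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%03d", 1:p)))
  tt <- rexp(n, 1 / 100); ev <- rbinom(n, 1, 0.85)
  scr <- cox_univariate_screen(x, tt, ev)
  expect_lt(abs(mean(scr$kept) - 0.05), 3.3 * sqrt(0.05 * 0.95 / p))
})

test_that("td_roc with no censoring equals the static AUC of event-by-t", {
  set.seed(24)
  n <- 80
  score <- rnorm(n)
  tt <- rexp(n, exp(0.8 * score)) * 100
  ev <- rep(1, n)
  for (h in c(50, 120, 300)) {
    if (!any(tt <= h) || !any(tt > h)) next
    lab <- ifelse(tt <= h, "case", "acontrol")  # second level alphabetically
    expect_equal(td_roc(score, tt, ev, h),
                 roc_auc(score, factor(lab, levels = c("acontrol", "case"))),
                 tolerance = 1e-10)
  }
  # beyond follow-up with no controls: flagged NA
  expect_warning(a <- td_roc(score, tt, ev, max(tt) + 1), "undefined")
  expect_true(is.na(a))
})

test_that("td_roc is ~0.5 for an outcome-independent score and high under signal", {
  set.seed(25)
  n <- 200
  tt <- rexp(n, 1 / 150); ev <- rbinom(n, 1, 0.8)
  expect_lt(abs(td_roc(rnorm(n), tt, ev, 90) - 0.5), 0.1)
})

test_that("risk scores are seed-deterministic and track a strong single-feature hazard", {
  set.seed(26)
  n <- 150
  x <- cbind(sig = rnorm(n), noise = rnorm(n))
  tt <- rexp(n, exp(2 * x[, "sig"])) * 50
  ev <- rep(1, n)
  s1 <- fit_risk_score(x, tt, ev, seed = 4, loocv = FALSE, num_trees = 300)
  s2 <- fit_risk_score(x, tt, ev, seed = 4, loocv = FALSE, num_trees = 300)
  expect_identical(s1, s2)
  cindex <- survival::concordance(survival::Surv(tt, ev) ~ s1, reverse = TRUE)$concordance
  expect_gt(cindex, 0.7)
})

test_that("pure-noise risk scores have null concordance", {
  set.seed(27)
  n <- 100
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tt <- rexp(n, 1 / 100); ev <- rep(1, n)
  s <- fit_risk_score(x, tt, ev, seed = 9, loocv = TRUE, num_trees = 150)
  cindex <- survival::concordance(survival::Surv(tt, ev) ~ s, reverse = TRUE)$concordance
  expect_gt(cindex, 0.40)
  expect_lt(cindex, 0.60)
})

test_that("pfs_pipeline separates risk groups on a strong-signal cohort", {
  cc <- quick_cohort(n = 60, p = 10, effect = 1.5, seed = 28, pfs_coef = 2,
                     censor_rate = 0.1)
  m <- drop_constant_features(build_dynamic_matrix(cc$features, kinds = "RCR"))
  pfs <- pfs_pipeline(m, cc$cohort$pfs_days, cc$cohort$event, seed = 3,
                      num_trees = 200)
  expect_lt(pfs$logrank_p, 0.001)
  # median split on distinct scores gives balanced groups
  expect_lte(abs(sum(pfs$group == "high") - sum(pfs$group == "low")), 1)
  expect_true(all(pfs$tdauc >= 0 & pfs$tdauc <= 1, na.rm = TRUE))
  expect_output(print(pfs), "log-rank")
})
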