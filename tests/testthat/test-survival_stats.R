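test_that("feature ranking scales |z| to 0-100 and flags score > 50", {
  set.seed(1)
  n <- 120
  lab <- rep(1:2, each = n / 2)
  x <- cbind(signal = lab + rnorm(n, 0, 1.2),
             weak = lab + rnorm(n, 0, 6),
             noise = rnorm(n))
  rk <- rank_features(x, lab)
  expect_identical(rk$feature, colnames(x))
  expect_equal(max(rk$importance), 100)
  expect_identical(rk$feature[which.max(rk$importance)], "signal")
  expect_true(rk$selected[rk$feature == "signal"])
  expect_false(rk$selected[rk$feature == "noise"])
  expect_lt(rk$importance[rk$feature == "noise"], 25)

  # [DERIVED] scores match an independent glm fit rescaled by hand
  ind <- glm(I(lab - 1) ~ scale(x), family = binomial())
  z <- abs(summary(ind)$coefficients[-1, "z value"])
  expect_equal(rk$importance, (z - min(z)) / (max(z) - min(z)) * 100,
               tolerance = 1e-8, ignore_attr = TRUE)

  # a feature identical across clusters scores ~ 0
  x2 <- cbind(x, flat = rep(2.5, n))
  rk2 <- suppressWarnings(rank_features(x2, lab))
  expect_lt(rk2$importance[rk2$feature == "flat"], 1e-6)
})

test_that("perfect separation triggers the penalized fallback", {
  set.seed(2)
  lab <- rep(1:2, each = 20)
  x <- cbind(sep = ifelse(lab == 2, 5, -5) + rnorm(40, 0, 0.1),
             noise = rnorm(40))
  expect_warning(rk <- rank_features(x, lab), "separation")
  expect_identical(rk$feature[which.max(rk$importance)], "sep")
  expect_true(all(is.finite(rk$importance)))
})

test_that("optimal cutpoint equals exhaustive enumeration via survdiff", {
  set.seed(3)
  for (r in 1:5) {
    n <- 10
    values <- round(rnorm(n), 2)
    time <- rexp(n, 0.1) + 1
    event <- runif(n) > 0.25
    if (sum(event) < 2 || length(unique(values)) < 3) next
    cp <- optimal_cutpoint(values, time, event, min_prop = 0.1)
    # oracle: survdiff chi-square over every admissible split
    cand <- sort(unique(values)); cand <- cand[-length(cand)]
    stats_or <- vapply(cand, function(cc) {
      g <- values <= cc
      if (sum(g) < 1 || sum(!g) < 1) return(-Inf)
      survival::survdiff(survival::Surv(time, event) ~ g)$chisq
    }, numeric(1))
    best <- cand[which.max(stats_or)]
    expect_equal(cp$cutpoint, best)
    expect_equal(cp$statistic^2, max(stats_or), tolerance = 1e-8)
  }
})

test_that("cutpoint separates a cluster indicator exactly; errors are loud", {
  time <- c(100, 120, 90, 800, 900, 950, 1000, 110, 850, 105)
  event <- rep(TRUE, 10)
  values <- as.numeric(time > 500)  # cluster indicator (5 low, 5 high)
  cp <- optimal_cutpoint(values, time, event)
  expect_equal(cp$cutpoint, 0)
  expect_identical(as.integer(cp$groups), as.integer(values) + 1L)

  expect_error(optimal_cutpoint(rep(1, 10), time, event), "constant")
  expect_error(optimal_cutpoint(values, time, rep(FALSE, 10)), "events")
})

test_that("log-rank test matches the textbook O-E computation", {
  # 6-patient worked example, no ties across groups
  time <- c(6, 13, 21, 30, 37, 38)
  event <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  groups <- factor(c("a", "b", "a", "b", "a", "b"))
  res <- log_rank_test(groups, time, event)
  or <- oracle_logrank(groups == "a", time, event)
  expect_equal(res$statistic, or$chisq, tolerance = 1e-10)
  expect_equal(res$p, pchisq(or$chisq, 1, lower.tail = FALSE))

  # identical survival in both groups (duplicated data) -> statistic 0, p 1
  res0 <- log_rank_test(factor(rep(c("a", "b"), each = 6)),
                        rep(time, 2), rep(event, 2))
  expect_lt(res0$statistic, 1e-10)
  expect_equal(res0$p, 1, tolerance = 1e-6)

  # invariance to label swap
  swapped <- log_rank_test(factor(c("b", "a", "b", "a", "b", "a")), time, event)
  expect_equal(swapped$statistic, res$statistic, tolerance = 1e-12)

  expect_error(log_rank_test(factor(rep("a", 6)), time, event), "2 groups")
})

test_that("log-rank power at HR 0.32, n = 500", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    cl <- rep(1:2, c(330, 170))
    lam <- log(2) / 424 * ifelse(cl == 2, 0.32, 1)
    t <- rexp(500, lam)
    log_rank_test(factor(cl), t, rep(TRUE, 500))$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Kaplan-Meier matches hand-multiplied products on a 5-patient toy", {
  time <- c(1, 2, 3, 4, 5)
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  km <- kaplan_meier(time, event)
  # S(1) = 4/5; S(2) = 4/5 * 3/4 = 3/5; t=3 censored; S(4) = 3/5 * 1/2 = 3/10
  s <- km$curves$surv[match(c(1, 2, 4), km$curves$time)]
  expect_equal(s, c(4 / 5, 3 / 5, 3 / 10))

  # no censoring -> empirical survival function
  km2 <- kaplan_meier(time, rep(TRUE, 5))
  expect_equal(km2$curves$surv, 1 - ecdf(time)(sort(time)))

  # all censored -> curve constant at 1
  km3 <- kaplan_meier(time, rep(FALSE, 5))
  expect_true(all(km3$curves$surv == 1))
})

test_that("Cox fit on a binary covariate matches the partial-likelihood oracle", {
  set.seed(4)
  for (r in 1:4) {
    n <- 12
    x <- rep(0:1, each = n / 2)
    time <- round(rexp(n, 0.05 * exp(0.7 * x)), 4) + 0.01  # no ties
    event <- runif(n) > 0.2
    if (sum(event[x == 0]) == 0 || sum(event[x == 1]) == 0) next
    fit <- cox_ph_fit(data.frame(x = x), time, event)
    beta_or <- oracle_cox_binary(x, time, event)
    expect_equal(log(fit$terms$hr), beta_or, tolerance = 1e-4)
    expect_true(fit$terms$lo <= fit$terms$hr && fit$terms$hr <= fit$terms$hi)

    # HR reciprocal under label swap
    fit_sw <- cox_ph_fit(data.frame(x = 1 - x), time, event)
    expect_equal(fit_sw$terms$hr, 1 / fit$terms$hr, tolerance = 1e-6)
  }
})

test_that("Cox null covariate gives HR ~ 1 and HR 0.32 is recovered at n = 1000", {
  set.seed(6)
  n <- 200
  time <- rexp(n, 0.01); event <- runif(n) > 0.2
  x <- rnorm(n)  # independent of survival
  fit <- cox_ph_fit(data.frame(x = x), time, event)
  expect_equal(fit$terms$hr, 1, tolerance = 0.25)
  expect_gt(fit$terms$p, 0.01)

  cfg <- cohort_config(censoring_rate = 0.2)
  set.seed(7)
  cl <- rep(1:2, c(662, 338))
  recs <- lapply(cl, generate_survival, config = cfg)
  fit2 <- cox_ph_fit(data.frame(cluster2 = as.integer(cl == 2)),
                     vapply(recs, `[[`, numeric(1), "os_days"),
                     vapply(recs, `[[`, logical(1), "os_event"))
  expect_gt(fit2$terms$hr, 0.25); expect_lt(fit2$terms$hr, 0.41)
})

test_that("12-month dichotomization excludes early-censored patients", {
  time <- c(100, 400, 200, 370, 50)
  event <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_message(y <- outcome_12mo(time, event), "excluded")
  expect_identical(y, c(1L, 0L, NA_integer_, 0L, NA_integer_))
})

test_that("incremental AUC: trivial identities and nested-model invariant", {
  set.seed(8)
  n <- 80
  z <- rnorm(n)
  y <- as.integer(runif(n) < plogis(z))
  base <- data.frame(z = z)

  # added feature identical to a baseline covariate -> delta = 0
  r0 <- incremental_auc(base, data.frame(z2 = z), y, n_boot = 100, seed = 1)
  expect_equal(r0$delta, 0, tolerance = 1e-10)
  expect_gt(r0$p, 0.5)

  # perfectly predictive added feature -> augmented AUC = 1
  r1 <- suppressWarnings(
    incremental_auc(base, data.frame(oracle = y * 10 + rnorm(n, 0, 1e-3)), y,
                    n_boot = 50, seed = 1))
  expect_equal(r1$auc_augmented$auc, 1)

  # in-sample nesting: the augmented model can only improve the deviance,
  # and its AUC can trail the baseline's only within small reordering slack
  # (the likelihood, not the AUC, is what glm maximizes)
  for (s in 1:5) {
    set.seed(s)
    feat <- data.frame(f = rnorm(n))
    r <- incremental_auc(base, feat, y, n_boot = 10, seed = 1)
    dev_base <- deviance(glm(y ~ z, family = binomial()))
    dev_aug <- deviance(glm(y ~ z + feat$f, family = binomial()))
    expect_lte(dev_aug, dev_base + 1e-8)
    expect_gte(r$auc_augmented$auc, r$auc_baseline$auc - 0.02)
  }

  # informative added feature beats the baseline in nearly all seeds
  wins <- vapply(1:50, function(s) {
    set.seed(s)
    z2 <- rnorm(60); f2 <- rnorm(60)
    y2 <- as.integer(runif(60) < plogis(0.5 * z2 + 1.5 * f2))
    if (length(unique(y2)) < 2) return(NA)
    r <- incremental_auc(data.frame(z = z2), data.frame(f = f2), y2,
                         n_boot = 2, seed = 1)
    r$auc_augmented$auc > r$auc_baseline$auc
  }, logical(1))
  expect_gte(mean(wins, na.rm = TRUE), 0.9)

  expect_error(incremental_auc(base, base, rep(1L, n)), "classes")
})
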