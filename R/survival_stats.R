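#' Rank centroid features by importance in the final clustering
#'
#' Fits a logistic regression of the final cluster label on the standardized
#' centroid features and scores each feature by the absolute Wald z statistic
#' of its coefficient, min-max scaled to \[0, 100\] (the glm variable-importance
#' convention). Features scoring over 50 are flagged as selected. Under
#' (quasi-)perfect separation the unpenalized fit degenerates, so the model is
#' refit with a small ridge penalty and the z statistics are taken from the
#' penalized curvature, with a warning.
#'
#' @param x patients x features numeric matrix (centroid features).
#' @param labels two-level cluster assignment aligned with `x` rows.
#' @param ridge penalty used on fallback refit (default 1e-2).
#' @return data.frame: `feature`, `z`, `importance` (0-100), `selected`.
#' @export
rank_features <- function(x, labels, ridge = 1e-2) {
  x <- standardize_columns(x)
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2) stop("labels must have exactly two non-empty levels")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  # aliased or dropped (zero-variance) features carry no information: z = 0
  coefs <- summary(fit)$coefficients
  z <- stats::setNames(rep(0, ncol(x)), paste0("x", colnames(x)))
  zc <- coefs[-1, "z value"]
  z[names(zc)] <- zc
  separated <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8)
  if (separated) {
    warning("perfect or quasi-perfect separation: refitting with ridge penalty")
    z <- ridge_logistic_z(x, y, lambda = ridge)
  }
  az <- abs(z)
  rng <- range(az)
  importance <- if (diff(rng) < .Machine$double.eps) {
    rep(100, length(az))  # all equally informative: every score maxes out
  } else {
    (az - rng[1]) / diff(rng) * 100
  }
  data.frame(feature = colnames(x), z = unname(z),
             importance = unname(importance),
             selected = unname(importance > 50), row.names = NULL)
}

# Penalized logistic MLE via Newton iterations; z = beta / se from the
# penalized observed information. Used only as the separation fallback.
ridge_logistic_z <- function(x, y, lambda) {
  X <- cbind(1, x)
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(x))))
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  eta <- drop(X %*% beta); p <- 1 / (1 + exp(-eta))
  H <- crossprod(X, X * (p * (1 - p))) + pen
  se <- sqrt(diag(solve(H)))
  (beta / se)[-1]
}

# Standardized log-rank statistic for a binary split, computed from the
# hypergeometric O-E / sqrt(V) form. This is the package's own machinery for
# the maximally-selected cutpoint scan (the cutpoint oracle in the tests uses
# survival::survdiff instead).
logrank_z <- function(in_group, time, event) {
  ut <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & in_group)
    d <- sum(event & time == t); d1 <- sum(event & time == t & in_group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  (O - E) / sqrt(V)
}

#' Maximally selected survival cutpoint for a continuous feature
#'
#' Scans all admissible dichotomizations of `values` (each side keeping at
#' least `min_prop` of the patients) and returns the cutpoint maximizing the
#' absolute standardized log-rank statistic between the two groups — the
#' maximally-selected-rank-statistics rule used to dichotomize features for
#' Kaplan-Meier analysis. Candidate cutpoints are the observed values; the
#' split is `values <= cut` vs `values > cut`. Ties in the statistic are
#' broken toward the smallest cutpoint.
#'
#' @param values numeric feature vector (>= 2 distinct values).
#' @param time,event survival times and event indicators.
#' @param min_prop minimum fraction of patients on each side (default 0.1).
#' @return list: `cutpoint`, `statistic` (absolute standardized log-rank),
#'   `groups` (factor `"low"`/`"high"`).
#' @export
optimal_cutpoint <- function(values, time, event, min_prop = 0.1) {
  stopifnot(length(values) == length(time), length(time) == length(event))
  if (length(unique(values)) < 2) stop("values are constant; no admissible split")
  if (!any(event)) stop("no events; log-rank statistic undefined")
  n <- length(values)
  cand <- sort(unique(values))
  cand <- cand[-length(cand)]  # "x <= max" puts everyone low
  keep <- vapply(cand, function(cc) {
    nl <- sum(values <= cc); nl >= min_prop * n && (n - nl) >= min_prop * n
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) stop("no admissible split under min_prop = ", min_prop)
  stat <- vapply(cand, function(cc)
    abs(logrank_z(values <= cc, time, event)), numeric(1))
  best <- which.max(stat)  # ties -> smallest cutpoint (cand is sorted)
  groups <- factor(ifelse(values <= cand[best], "low", "high"),
                   levels = c("low", "high"))
  list(cutpoint = cand[best], statistic = stat[best], groups = groups)
}

#' Log-rank test between survival groups
#'
#' @param groups factor of group assignments (>= 2 non-empty levels).
#' @param time,event survival times and event indicators.
#' @return list: `statistic` (chi-square), `df`, `p`.
#' @export
log_rank_test <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier estimates per group
#'
#' Product-limit survival curves with right-censoring; patients alive at last
#' follow-up contribute risk time but no event.
#'
#' @param time,event survival data.
#' @param groups optional grouping factor (single curve if omitted).
#' @return list: `fit` (the `survfit` object), `curves` (data.frame with
#'   `group`, `time`, `n_risk`, `n_event`, `surv`), `medians` (named numeric).
#' @export
kaplan_meier <- function(time, event, groups = NULL) {
  if (is.null(groups)) groups <- factor(rep("all", length(time)))
  groups <- droplevels(as.factor(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) rep(levels(groups), length(smry$time))
         else sub("^groups=", "", as.character(smry$strata))
  curves <- data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
                       n_event = smry$n.event, surv = smry$surv)
  tab <- summary(fit)$table
  med <- if (is.matrix(tab)) stats::setNames(tab[, "median"],
                                             sub("^groups=", "", rownames(tab)))
         else stats::setNames(tab[["median"]], levels(groups))
  list(fit = fit, curves = curves, medians = med)
}

#' Cox proportional-hazards fit with per-term hazard ratios
#'
#' Partial-likelihood fit (Efron tie handling by default) of survival on the
#' supplied covariates; per-term hazard ratios with Wald 95% CIs and p-values.
#'
#' @param data data.frame of covariates (factors and numerics).
#' @param time,event survival data aligned with `data` rows.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_model`: data.frame `terms` (term, hr, lo, hi,
#'   p), `loglik`, `n`, `n_event`, and the underlying `fit`.
#' @export
cox_ph_fit <- function(data, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  data <- as.data.frame(data)
  constant <- vapply(data, function(v) length(unique(v)) < 2, logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(names(data)[constant], collapse = ", "))
    data <- data[, !constant, drop = FALSE]
    if (ncol(data) == 0) stop("no non-constant covariates left for the Cox model")
  }
  if (sum(event) < ncol(data))
    warning(sprintf("only %d events for %d model terms; estimates may be unstable",
                    sum(event), ncol(data)))
  df <- cbind(data, .time = time, .event = as.integer(event))
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = ties)
  if (!is.null(fit$info) && isTRUE(fit$info > 0))
    warning("Cox fit did not converge cleanly")
  s <- summary(fit)
  terms <- data.frame(term = rownames(s$coefficients),
                      hr = s$conf.int[, "exp(coef)"],
                      lo = s$conf.int[, "lower .95"],
                      hi = s$conf.int[, "upper .95"],
                      p = s$coefficients[, "Pr(>|z|)"],
                      row.names = NULL)
  structure(list(terms = terms, loglik = fit$loglik[2],
                 n = s$n, n_event = s$nevent, fit = fit),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("cox_model: n = %d, events = %d, loglik = %.3f\n",
              x$n, x$n_event, x$loglik))
  print(transform(x$terms, hr = round(hr, 3), lo = round(lo, 3),
                  hi = round(hi, 3), p = signif(p, 3)))
  invisible(x)
}

#' Dichotomize survival at 12 months
#'
#' Status at 365 days for logistic modelling: 1 if the event occurred by day
#' 365, 0 if event-free with follow-up past 365 days, NA (excluded, with a
#' message) if censored before 365 days.
#'
#' @param time,event survival data.
#' @return integer vector with NAs for indeterminate patients.
#' @export
outcome_12mo <- function(time, event) {
  out <- ifelse(time <= 365 & event, 1L,
                ifelse(time > 365, 0L, NA_integer_))
  if (anyNA(out))
    message(sprintf("%d patient(s) censored before 365 days excluded from 12-month models",
                    sum(is.na(out))))
  out
}

# Mann-Whitney AUC of scores against a binary outcome.
auc_score <- function(scores, outcome) {
  r <- rank(scores)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Incremental discrimination of imaging features over clinical covariates
#'
#' Fits two logistic models for a 12-month outcome — clinical baseline, and
#' baseline plus the selected histogram features — and compares their
#' in-sample ROC AUCs. Confidence intervals are percentile bootstrap (models
#' refit on each resample); the primary comparison is a paired bootstrap test
#' of the AUC difference. `method = "anova"` reproduces the legacy one-way
#' ANOVA comparison across the two bootstrap AUC sets.
#'
#' @param baseline data.frame of clinical covariates.
#' @param features data.frame/matrix of added features (NULL-safe columns).
#' @param outcome binary 0/1 vector (NAs dropped with their rows).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param method `"bootstrap"` (default) or `"anova"` for the comparison p.
#' @return list: `auc_baseline`, `auc_augmented` (each with `auc`, `ci`),
#'   `delta`, `p`, `method`, `n`.
#' @export
incremental_auc <- function(baseline, features, outcome, n_boot = 2000,
                            seed = 1L, method = c("bootstrap", "anova")) {
  method <- match.arg(method)
  keep <- !is.na(outcome)
  baseline <- as.data.frame(baseline)[keep, , drop = FALSE]
  features <- as.data.frame(features)[keep, , drop = FALSE]
  outcome <- outcome[keep]
  if (length(unique(outcome)) != 2) stop("outcome must contain both classes")
  fit_auc <- function(X, y) {
    # bootstrap resamples can collapse a factor to one level; such columns
    # carry no information on that resample and are dropped
    keep_col <- vapply(X, function(v) length(unique(v)) > 1, logical(1))
    X <- X[, keep_col, drop = FALSE]
    if (ncol(X) == 0) return(0.5)
    f <- suppressWarnings(stats::glm(y ~ ., data = cbind(X, y = y),
                                     family = stats::binomial()))
    auc_score(stats::predict(f, type = "response"), y)
  }
  both <- cbind(baseline, features)
  a_base <- fit_auc(baseline, outcome)
  a_aug <- fit_auc(both, outcome)
  set.seed(seed)
  n <- length(outcome)
  boot <- t(vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(outcome[idx])) != 2) return(c(NA_real_, NA_real_))
    c(fit_auc(baseline[idx, , drop = FALSE], outcome[idx]),
      fit_auc(both[idx, , drop = FALSE], outcome[idx]))
  }, numeric(2)))
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  d <- boot[, 2] - boot[, 1]
  p <- if (method == "bootstrap") {
    min(1, 2 * min((1 + sum(d <= 0)) / (nrow(boot) + 1),
                   (1 + sum(d >= 0)) / (nrow(boot) + 1)))
  } else {
    vals <- c(boot[, 1], boot[, 2])
    grp <- factor(rep(c("base", "aug"), each = nrow(boot)))
    summary(stats::aov(vals ~ grp))[[1]][["Pr(>F)"]][1]
  }
  list(auc_baseline = list(auc = a_base,
                           ci = unname(stats::quantile(boot[, 1], c(.025, .975)))),
       auc_augmented = list(auc = a_aug,
                            ci = unname(stats::quantile(boot[, 2], c(.025, .975)))),
       delta = a_aug - a_base, p = p, method = method, n = n)
}
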