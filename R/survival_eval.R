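#' Kaplan-Meier product-limit estimate
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @return data.frame of class `km_curve` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (non-increasing, starting from 1 at time 0).
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one observation")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv, row.names = NULL),
            class = c("km_curve", "data.frame"))
}

#' Logrank (Mantel-Haenszel) test between two risk groups
#'
#' Observed-minus-expected statistic with hypergeometric variance, referred
#' to a chi-square distribution with 1 df.
#'
#' @param group two-level grouping (e.g. low/high risk).
#' @param time,event follow-up and event indicators.
#' @return list with `chi2`, `p`, and per-group `observed`/`expected` counts.
#' @export
logrank_test <- function(group, time, event) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("logrank test needs exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Univariate Cox hazard ratio of high versus low risk
#'
#' @param group factor with levels `low`, `high` (or any two levels; the
#'   second level is the "high" group).
#' @param time,event follow-up and event indicators.
#' @return list with `hr`, `ci` (length-2 Wald 95% CI), `p` (Wald),
#'   `log_hr`, `se` and a `converged` flag (FALSE under monotone likelihood,
#'   when a group has no events; the CI then degenerates toward 0/Inf).
#' @export
cox_hr <- function(group, time, event) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("need two non-empty groups")
  if (sum(event) < 1L) stop("no events")
  high <- as.integer(group == levels(group)[2L])
  monotone <- any(tapply(event, group, sum) == 0)
  if (monotone)
    warning("a group has no events: monotone likelihood, unbounded HR CI")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ high))
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  list(hr = exp(b), ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
       p = 2 * stats::pnorm(-abs(b / se)),
       log_hr = b, se = se, converged = !monotone)
}

#' Harrell's concordance index for censored survival data
#'
#' Direct pair enumeration: a pair is usable when the ordering of the two
#' event times is determined under censoring (the earlier time is an event;
#' at tied times, one event and one censored observation are orderable).
#' Concordant pairs score 1, score ties 0.5. The standard error is the
#' delete-one jackknife over patients of the pair-decomposed estimator, and
#' `p` tests c = 0.5 by a normal approximation.
#'
#' @param score numeric risk scores (higher = higher risk).
#' @param time,event follow-up and event indicators.
#' @return list with `c`, `se`, `p`, `n_pairs` (usable pairs).
#' @export
concordance_index <- function(score, time, event) {
  n <- length(score)
  if (n < 2L) stop("need at least two patients")
  ti <- matrix(time, n, n); tj <- t(ti)
  ei <- matrix(as.logical(event), n, n); ej <- t(ei)
  si <- matrix(score, n, n); sj <- t(si)
  # i determined to fail before j
  usable <- (ti < tj & ei) | (ti == tj & ei & !ej)
  credit <- (si > sj) + 0.5 * (si == sj)
  cred <- ifelse(usable, credit, 0)
  m_pair <- sum(usable)
  if (m_pair == 0L) stop("no usable pairs under censoring")
  cindex <- sum(cred) / m_pair

  # per-patient totals over ordered pairs involving the patient (either role)
  s_i <- rowSums(cred) + colSums(cred)
  m_i <- rowSums(usable) + colSums(usable)
  S <- sum(cred); M <- m_pair
  loo <- ifelse(M - m_i > 0, (S - s_i) / (M - m_i), cindex)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  list(c = cindex, se = se,
       p = if (se > 0) 2 * stats::pnorm(-abs((cindex - 0.5) / se)) else
         as.numeric(cindex == 0.5),
       n_pairs = m_pair)
}

#' Sensitivity, specificity and balanced classification rate at a horizon
#'
#' Cases are patients with an event within `horizon` years; controls are
#' event-free patients followed at least `horizon` years; patients censored
#' earlier are excluded. Sensitivity is the high-risk fraction of cases,
#' specificity the low-risk fraction of controls, BCR their mean; `p` is a
#' two-sided Z-test of BCR against 0.5 using the normal approximation.
#'
#' @param group factor low/high risk.
#' @param time,event follow-up and event indicators.
#' @param horizon classification horizon in years (default 5).
#' @return list with `sensitivity`, `specificity`, `bcr`, `se`, `p`,
#'   `n_cases`, `n_controls`.
#' @export
binary_metrics_at_horizon <- function(group, time, event, horizon = 5) {
  lab <- horizon_labels(time, event, horizon)
  high <- as.factor(group) == "high"
  case <- which(lab == 1L); ctrl <- which(lab == 0L)
  if (length(case) == 0L || length(ctrl) == 0L)
    stop("need at least one case and one control at the horizon")
  sens <- mean(high[case]); spec <- mean(!high[ctrl])
  bcr <- (sens + spec) / 2
  se <- sqrt(sens * (1 - sens) / length(case) +
             spec * (1 - spec) / length(ctrl)) / 2
  p <- if (se > 0) 2 * stats::pnorm(-abs((bcr - 0.5) / se)) else
    as.numeric(bcr == 0.5)
  list(sensitivity = sens, specificity = spec, bcr = bcr, se = se, p = p,
       n_cases = length(case), n_controls = length(ctrl))
}

#' Fixed-effect inverse-variance pooling of per-cohort estimates
#'
#' Pools estimates on the stated scale: log hazard ratios are pooled and may
#' be exponentiated by the caller; concordance and BCR are pooled directly
#' and tested against 0.5, log-HR against 0. A DerSimonian-Laird
#' random-effects option is exposed but off by default.
#'
#' @param estimates,ses numeric vectors of per-cohort estimates and their
#'   standard errors (positive).
#' @param scale one of `"log-hr"`, `"c-index"`, `"bcr"` (determines the null
#'   value for the pooled p).
#' @param random_effects use DerSimonian-Laird between-cohort variance.
#' @return list with `estimate`, `se`, `p` on the input scale.
#' @export
pool_estimates <- function(estimates, ses, scale = c("log-hr", "c-index", "bcr"),
                           random_effects = FALSE) {
  scale <- match.arg(scale)
  if (length(estimates) < 1L) stop("need at least one cohort")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  if (random_effects && length(estimates) > 1L) {
    q <- sum(w * (estimates - est)^2)
    tau2 <- max(0, (q - (length(estimates) - 1)) /
                     (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (ses^2 + tau2)
    est <- sum(w * estimates) / sum(w)
  }
  se <- sqrt(1 / sum(w))
  null <- if (scale == "log-hr") 0 else 0.5
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs((est - null) / se)))
}

#' Evaluate one risk stratification on one cohort
#'
#' Computes the full metric panel of the package for a high/low risk split:
#' Cox hazard ratio with Wald CI and p, Harrell concordance (on `score` when
#' available, else on the binary group), balanced classification rate with
#' sensitivity/specificity at the horizon, and the logrank test.
#'
#' @param group factor low/high.
#' @param time,event follow-up and events.
#' @param score optional continuous risk score for the concordance index.
#' @param horizon classification horizon (default 5).
#' @param cohort_id label carried into the output row.
#' @return one-row data.frame (class `eval_report`).
#' @export
evaluate_stratification <- function(group, time, event, score = NULL,
                                    horizon = 5, cohort_id = "cohort") {
  hr <- cox_hr(group, time, event)
  ci <- concordance_index(if (is.null(score)) as.integer(group == "high")
                          else score, time, event)
  bm <- binary_metrics_at_horizon(group, time, event, horizon)
  lr <- logrank_test(group, time, event)
  structure(data.frame(
    cohort_id = cohort_id, n = length(time), n_events = sum(event),
    hr = hr$hr, hr_lo = hr$ci[1L], hr_hi = hr$ci[2L], hr_p = hr$p,
    log_hr = hr$log_hr, log_hr_se = hr$se,
    cindex = ci$c, cindex_se = ci$se, cindex_p = ci$p,
    sensitivity = bm$sensitivity, specificity = bm$specificity,
    bcr = bm$bcr, bcr_se = bm$se, bcr_p = bm$p,
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    row.names = NULL, stringsAsFactors = FALSE),
    class = c("eval_report", "data.frame"))
}

#' Evaluate a stratification per cohort and pooled
#'
#' Applies [evaluate_stratification()] to each cohort and appends a pooled
#' row combining log-HR, concordance and BCR by fixed-effect inverse-variance
#' weighting; the pooled logrank is computed on the concatenated patients.
#'
#' @param strata named list; one element per cohort, each a list with
#'   `group`, `time`, `event` and optionally `score`.
#' @param horizon classification horizon (default 5).
#' @return data.frame of class `eval_report`, one row per cohort plus a
#'   `pooled` row.
#' @export
evaluate_cohorts <- function(strata, horizon = 5) {
  rows <- mapply(function(s, id)
    evaluate_stratification(s$group, s$time, s$event, s$score, horizon, id),
    strata, names(strata), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  if (nrow(out) > 1L) {
    ph <- pool_estimates(out$log_hr, out$log_hr_se, "log-hr")
    pc <- pool_estimates(out$cindex, out$cindex_se, "c-index")
    pb <- pool_estimates(out$bcr, out$bcr_se, "bcr")
    all_g <- unlist(lapply(strata, function(s) as.character(s$group)))
    all_t <- unlist(lapply(strata, `[[`, "time"))
    all_e <- unlist(lapply(strata, `[[`, "event"))
    lr <- logrank_test(all_g, all_t, all_e)
    pooled <- data.frame(
      cohort_id = "pooled", n = sum(out$n), n_events = sum(out$n_events),
      hr = exp(ph$estimate),
      hr_lo = exp(ph$estimate - stats::qnorm(.975) * ph$se),
      hr_hi = exp(ph$estimate + stats::qnorm(.975) * ph$se),
      hr_p = ph$p, log_hr = ph$estimate, log_hr_se = ph$se,
      cindex = pc$estimate, cindex_se = pc$se, cindex_p = pc$p,
      sensitivity = NA_real_, specificity = NA_real_,
      bcr = pb$estimate, bcr_se = pb$se, bcr_p = pb$p,
      logrank_chi2 = lr$chi2, logrank_p = lr$p,
      row.names = NULL, stringsAsFactors = FALSE)
    out <- rbind(out, pooled)
  }
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Paired bootstrap comparison of two stratifications
#'
#' Tests the difference in a survival metric between two risk stratifications
#' of the *same* patients by a patient-level bootstrap: patients are
#' resampled with replacement, both metrics recomputed on each replicate, and
#' a two-sided p-value obtained from the normal approximation to the
#' bootstrap distribution of the difference.
#'
#' @param metric_fn function `(group, time, event) -> scalar` (e.g. minus log
#'   logrank p, or a wrapped HR).
#' @param stratA,stratB factors low/high on the same patients.
#' @param time,event follow-up and events.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer seed.
#' @return list with `diff` (observed metric(A) - metric(B)), `se`, `p`.
#' @export
compare_paired <- function(metric_fn, stratA, stratB, time, event,
                           n_boot = 200, seed = NULL) {
  if (length(stratA) != length(stratB)) stop("stratifications must align")
  if (!is.null(seed)) set.seed(seed)
  n <- length(time)
  safe <- function(g, t, e) tryCatch(metric_fn(g, t, e),
                                     error = function(err) NA_real_)
  obs <- safe(stratA, time, event) - safe(stratB, time, event)
  diffs <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    safe(stratA[i], time[i], event[i]) - safe(stratB[i], time[i], event[i])
  }, numeric(1))
  diffs <- diffs[is.finite(diffs)]
  se <- stats::sd(diffs)
  if (!is.finite(se) || se == 0) {
    if (!is.finite(obs) || obs == 0) {
      warning("degenerate bootstrap: zero variance")
      return(list(diff = obs, se = 0, p = 1))
    }
    return(list(diff = obs, se = 0, p = 0))
  }
  list(diff = obs, se = se, p = 2 * stats::pnorm(-abs(obs / se)))
}
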