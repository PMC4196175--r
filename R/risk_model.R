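#' Administrative censoring at a horizon
#'
#' Caps follow-up times at `horizon` years; events after the horizon are
#' recoded as censored at the horizon, so the event count can only decrease.
#'
#' @param time non-negative follow-up times (years).
#' @param event 0/1 event indicators.
#' @param horizon censoring horizon in years (> 0).
#' @return list with capped `time` and recoded `event`.
#' @export
censor_at <- function(time, event, horizon) {
  if (any(time < 0)) stop("negative survival times")
  if (length(horizon) != 1L || horizon <= 0) stop("`horizon` must be > 0")
  event <- as.integer(event)
  event[time > horizon] <- 0L
  list(time = pmin(time, horizon), event = event)
}

# map independent (l1, l2) penalty weights onto glmnet's (alpha, lambda):
# penalty = l1*||b||_1 + l2/2*||b||_2^2 = lambda*(a*||b||_1 + (1-a)/2*||b||^2)
l1l2_to_glmnet <- function(l1, l2) {
  lambda <- l1 + l2
  alpha <- if (lambda > 0) l1 / lambda else 1
  c(alpha = alpha, lambda = lambda)
}

#' Fit an elastic-net penalized Cox model on a training cohort
#'
#' Restricts the training cohort's expression to the signature probesets,
#' z-scores each probeset on the training data, and fits a Cox
#' proportional-hazards model under an elastic-net penalty. The penalty is
#' selected by k-fold cross-validation (partial-likelihood deviance, fold
#' assignment controlled by `seed`) over `alpha_grid` with glmnet's internal
#' lambda path, unless an explicit `(l1_grid, l2_grid)` of independent
#' penalty weights is supplied. A zero total penalty is fitted as an
#' unpenalized Cox regression. The decision threshold maximizing the balanced
#' sensitivity/specificity for progression within `horizon` years is then
#' chosen on the training risk scores.
#'
#' @param train a [cohort()] used for training.
#' @param sig a [gene_signature()] on the cohort's platform.
#' @param alpha_grid elastic-net mixing values searched by cross-validation.
#' @param l1_grid,l2_grid optional explicit grids of independent L1/L2 weights;
#'   all pairs are searched (cross-validated unless a single pair is given).
#' @param cv_folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param horizon classification horizon in years for the threshold (default 5).
#' @param standardize default standardization mode stored in the model:
#'   `"cohort"` re-z-scores each scored cohort with its own constants (robust
#'   to MAS5-vs-RMA scale differences), `"training"` reuses the training
#'   constants.
#' @return object of class `risk_model`: named `coefficients`, `alpha`,
#'   `lambda`, training `center`/`scale`, `threshold`, `horizon_years`,
#'   `platform`, `standardize`.
#' @export
fit_penalized_cox <- function(train, sig, alpha_grid = c(0.1, 0.5, 0.9),
                              l1_grid = NULL, l2_grid = NULL, cv_folds = 5,
                              seed = NULL, horizon = 5,
                              standardize = c("cohort", "training")) {
  standardize <- match.arg(standardize)
  ids <- if (inherits(sig, "gene_signature")) sig$probeset_ids else as.character(sig)
  miss <- setdiff(ids, rownames(train$expr))
  if (length(miss))
    stop("signature probesets missing from training expression: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  time <- train$clinical$time_years
  event <- train$clinical$event
  if (sum(event) < cv_folds)
    stop("training cohort has fewer events than CV folds")

  x <- t(train$expr[ids, , drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  y <- survival::Surv(time, event)

  if (!is.null(seed)) set.seed(seed)

  if (!is.null(l1_grid) || !is.null(l2_grid)) {
    if (is.null(l1_grid)) l1_grid <- 0
    if (is.null(l2_grid)) l2_grid <- 0
    pairs <- expand.grid(l1 = l1_grid, l2 = l2_grid)
    al <- t(mapply(l1l2_to_glmnet, pairs$l1, pairs$l2))
    if (nrow(al) == 1L) {
      fit <- fit_cox_at(xs, y, al[1L, "alpha"], al[1L, "lambda"])
      beta <- fit$beta; alpha <- al[1L, "alpha"]; lambda <- al[1L, "lambda"]
    } else {
      foldid <- cv_foldid(length(time), cv_folds)
      best <- NULL
      for (i in seq_len(nrow(al))) {
        dev <- cv_deviance_at(xs, y, al[i, "alpha"], al[i, "lambda"], foldid)
        if (is.null(best) || dev < best$dev)
          best <- list(dev = dev, alpha = al[i, "alpha"], lambda = al[i, "lambda"])
      }
      fit <- fit_cox_at(xs, y, best$alpha, best$lambda)
      beta <- fit$beta; alpha <- best$alpha; lambda <- best$lambda
    }
  } else {
    foldid <- cv_foldid(length(time), cv_folds)
    best <- NULL
    for (a in alpha_grid) {
      cvf <- cv_glmnet_safe(xs, y, a, foldid, cv_folds)
      i <- which.min(cvf$cvm)
      if (is.null(best) || cvf$cvm[i] < best$dev)
        best <- list(dev = cvf$cvm[i], alpha = a, lambda = cvf$lambda[i],
                     fit = cvf$glmnet.fit)
    }
    beta <- as.numeric(glmnet::coef.glmnet(best$fit, s = best$lambda))
    alpha <- best$alpha; lambda <- best$lambda
  }
  names(beta) <- ids

  model <- structure(list(coefficients = beta, alpha = unname(alpha),
                          lambda = unname(lambda),
                          center = stats::setNames(ctr, ids),
                          scale = stats::setNames(scl, ids),
                          threshold = NA_real_, horizon_years = horizon,
                          platform = platform_of(train$expr),
                          standardize = standardize),
                     class = "risk_model")
  scores <- drop(xs %*% beta)
  model$threshold <- select_threshold(scores, time, event, horizon)
  model
}

# fold assignment: balanced random permutation
cv_foldid <- function(n, k) sample(rep(seq_len(k), length.out = n))

# single (alpha, lambda) Cox fit; lambda == 0 -> unpenalized coxph
fit_cox_at <- function(xs, y, alpha, lambda) {
  if (lambda == 0) {
    fit <- survival::coxph(y ~ xs)
    list(beta = unname(stats::coef(fit)))
  } else {
    # decreasing warm-start path ending exactly at the requested lambda
    path <- lambda * c(16, 8, 4, 2, 1)
    fit <- glmnet::glmnet(xs, y, family = "cox", alpha = alpha,
                          lambda = path, standardize = FALSE)
    list(beta = as.numeric(glmnet::coef.glmnet(fit, s = lambda)))
  }
}

# CV partial-likelihood deviance at a fixed (alpha, lambda)
cv_deviance_at <- function(xs, y, alpha, lambda, foldid) {
  cvf <- glmnet::cv.glmnet(xs, y, family = "cox", alpha = alpha,
                           lambda = c(lambda * 2, lambda, lambda / 2 + 1e-12),
                           foldid = foldid, standardize = FALSE,
                           type.measure = "deviance")
  cvf$cvm[which.min(abs(cvf$lambda - lambda))]
}

# cv.glmnet with degenerate-fold protection: folds without events are
# redrawn (with a logged warning), up to 5 attempts
cv_glmnet_safe <- function(xs, y, alpha, foldid, cv_folds, max_tries = 5L) {
  ev <- y[, "status"]
  for (try in seq_len(max_tries)) {
    ok <- all(tapply(ev, foldid, sum) > 0)
    if (ok) {
      res <- tryCatch(
        glmnet::cv.glmnet(xs, y, family = "cox", alpha = alpha,
                          foldid = foldid, standardize = FALSE,
                          type.measure = "deviance"),
        error = function(e) e)
      if (!inherits(res, "error")) return(res)
    }
    warning("degenerate CV folds; resampling fold assignment")
    foldid <- cv_foldid(length(ev), cv_folds)
  }
  stop("cross-validation failed after fold resampling")
}

#' @export
print.risk_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(paste0("risk_model [%s]: %d probesets (%d nonzero), alpha=%.3g, ",
                     "lambda=%.3g, threshold=%.4g @ %gy (%s standardization)\n"),
              x$platform, length(x$coefficients), nz, x$alpha, x$lambda,
              x$threshold, x$horizon_years, x$standardize))
  invisible(x)
}

#' Compute per-patient risk scores
#'
#' Linear predictor `sum(coefficient * standardized expression)` over the
#' model's probesets.
#'
#' @param model a `risk_model`.
#' @param expr expression matrix containing all model probesets.
#' @param standardize `"cohort"` (z-score with this matrix's own constants) or
#'   `"training"` (reuse the training constants); defaults to the mode stored
#'   in the model.
#' @return named numeric vector of scores, one per sample.
#' @export
risk_score <- function(model, expr, standardize = NULL) {
  if (is.null(standardize)) standardize <- model$standardize
  standardize <- match.arg(standardize, c("cohort", "training"))
  ids <- names(model$coefficients)
  miss <- setdiff(ids, rownames(expr))
  if (length(miss))
    stop("model probesets missing from expression: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  x <- t(expr[ids, , drop = FALSE])
  if (standardize == "training") {
    xs <- scale(x, center = model$center, scale = model$scale)
  } else {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd); scl[scl == 0] <- 1
    xs <- scale(x, center = ctr, scale = scl)
  }
  drop(xs %*% model$coefficients)
}

#' Choose the balanced sensitivity/specificity decision threshold
#'
#' Patients with an event within `horizon` years are cases; patients
#' event-free with follow-up of at least `horizon` years are controls;
#' patients censored before the horizon are excluded. The returned cut is the
#' midpoint between consecutive observed scores maximizing
#' `(sensitivity + specificity) / 2` for the rule `high risk <=> score >
#' threshold`; ties are broken toward higher specificity (i.e. the higher
#' cut).
#'
#' @param scores numeric risk scores.
#' @param time,event follow-up and 0/1 event indicator.
#' @param horizon classification horizon in years (default 5).
#' @return a single finite threshold.
#' @export
select_threshold <- function(scores, time, event, horizon = 5) {
  lab <- horizon_labels(time, event, horizon)
  case <- scores[which(lab == 1L)]
  ctrl <- scores[which(lab == 0L)]
  if (length(case) == 0L || length(ctrl) == 0L)
    stop("threshold selection needs at least one case and one control at the horizon")
  u <- sort(unique(scores))
  # candidate cuts: below the minimum, then each observed value (score > cut)
  cand <- c(u[1L] - 1, u)
  sens <- vapply(cand, function(th) mean(case > th), numeric(1))
  spec <- vapply(cand, function(th) mean(ctrl <= th), numeric(1))
  bcr <- (sens + spec) / 2
  best <- which(bcr == max(bcr))
  best <- best[which.max(spec[best] + 1e-9 * seq_along(best))]  # higher spec, then higher cut
  i <- best
  if (i == 1L) return(u[1L] - 1)              # everyone high risk
  j <- i - 1L                                  # index into u
  if (j < length(u)) (u[j] + u[j + 1L]) / 2 else u[length(u)]
}

# 1 = case (event within horizon), 0 = control (event-free, followed past
# horizon), NA = censored before horizon (excluded)
horizon_labels <- function(time, event, horizon) {
  ifelse(event == 1L & time <= horizon, 1L,
         ifelse(time >= horizon, 0L, NA_integer_))
}

#' Classify patients into high/low risk groups
#'
#' @param scores named numeric risk scores (from [risk_score()]).
#' @param model a `risk_model` carrying the decision threshold.
#' @return data.frame with `sample_id`, `score` and `group`
#'   (factor low/high); `high` iff `score > threshold` (a score exactly at
#'   the threshold is low risk).
#' @export
classify <- function(scores, model) {
  if (!is.finite(model$threshold)) stop("model has no decision threshold")
  data.frame(sample_id = if (is.null(names(scores))) seq_along(scores)
                         else names(scores),
             score = as.numeric(scores),
             group = factor(ifelse(scores > model$threshold, "high", "low"),
                            levels = c("low", "high")),
             row.names = NULL, stringsAsFactors = FALSE)
}
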