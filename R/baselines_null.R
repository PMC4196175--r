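#' Draw a random probeset signature
#'
#' Uniform sample without replacement from a platform's probeset universe;
#' used to build null distributions of prognostic performance.
#'
#' @param platform_probesets character vector: the probeset universe.
#' @param size signature size (<= universe size).
#' @param seed integer seed.
#' @param platform platform tag for the returned signature.
#' @return a [gene_signature()].
#' @export
sample_random_signature <- function(platform_probesets, size, seed = NULL,
                                    platform = "unknown") {
  size <- check_count(size, "size")
  if (size > length(platform_probesets))
    stop("size exceeds the probeset universe")
  if (!is.null(seed)) set.seed(seed)
  gene_signature(sample(platform_probesets, size), platform = platform)
}

# one full fit/threshold/classify/metric pipeline pass for a signature;
# returns the requested metric over the validation cohorts
pipeline_metric <- function(sig, train, validations, metric, horizon = 5,
                            fit_args = list(), seed = NULL) {
  model <- do.call(fit_penalized_cox,
                   c(list(train = train, sig = sig, horizon = horizon,
                          seed = seed), fit_args))
  groups <- lapply(validations, function(v) {
    cl <- classify(risk_score(model, v$expr), model)
    list(group = cl$group, time = v$clinical$time_years,
         event = v$clinical$event, score = cl$score)
  })
  if (is.null(names(groups)))
    names(groups) <- vapply(validations, `[[`, "", "cohort_id")
  all_g <- unlist(lapply(groups, function(g) as.character(g$group)))
  all_t <- unlist(lapply(groups, `[[`, "time"))
  all_e <- unlist(lapply(groups, `[[`, "event"))
  switch(metric,
    logrank_logp = -log10(logrank_test(all_g, all_t, all_e)$p),
    hr = {
      rows <- evaluate_cohorts(groups, horizon)
      exp(rows$log_hr[rows$cohort_id == if (length(groups) > 1L) "pooled"
                      else names(groups)[1L]])
    },
    cindex = {
      est <- vapply(groups, function(g)
        unlist(concordance_index(g$score, g$time, g$event)[c("c", "se")]),
        numeric(2))
      pool_estimates(est[1L, ], est[2L, ], "c-index")$estimate
    },
    bcr = {
      est <- vapply(groups, function(g) {
        bm <- binary_metrics_at_horizon(g$group, g$time, g$event, horizon)
        c(bm$bcr, bm$se)
      }, numeric(2))
      pool_estimates(est[1L, ], pmax(est[2L, ], 1e-8), "bcr")$estimate
    },
    stop("unknown metric: ", metric))
}

# metric value carrying no discriminative signal, used when a random
# signature's pipeline fails
no_signal_value <- function(metric)
  switch(metric, logrank_logp = 0, hr = 1, cindex = 0.5, bcr = 0.5)

#' Null distribution of a prognostic metric over random signatures
#'
#' For each of `n_signatures` random signatures of the given size, runs the
#' full prognostic pipeline (penalized Cox fit on the training cohort,
#' threshold selection, classification of the validation cohorts) and records
#' the chosen metric; the observed signature is pushed through the identical
#' pipeline. The empirical p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (n_signatures + 1)` (larger metric = better),
#' so it is never 0 and bottoms out at `1/(n+1)`.
#'
#' @param train training [cohort()].
#' @param validations list of validation [cohort()]s.
#' @param signature the observed [gene_signature()] being benchmarked.
#' @param size random-signature size; defaults to the observed size.
#' @param n_signatures number of random signatures (the reference analysis
#'   uses 1000).
#' @param metric one of `"logrank_logp"`, `"hr"`, `"cindex"`, `"bcr"`.
#' @param seed integer seed.
#' @param universe probeset universe to draw from; defaults to all probesets
#'   of the training cohort (the clinical platform).
#' @param horizon classification horizon (default 5).
#' @param fit_args extra arguments passed to [fit_penalized_cox()] (e.g. a
#'   fixed `l1_grid`/`l2_grid` to skip cross-validation).
#' @return object of class `null_distribution`: `metric`, `observed`,
#'   `null_values`, `n_signatures`, `empirical_p`.
#' @export
null_distribution <- function(train, validations, signature,
                              size = NULL, n_signatures = 1000,
                              metric = c("logrank_logp", "hr", "cindex", "bcr"),
                              seed = NULL, universe = NULL, horizon = 5,
                              fit_args = list()) {
  metric <- match.arg(metric)
  n_signatures <- check_count(n_signatures, "n_signatures")
  if (is.null(universe)) universe <- rownames(train$expr)
  if (is.null(size)) size <- signature$size
  if (!is.null(seed)) set.seed(seed)
  sig_seeds <- sample.int(.Machine$integer.max, n_signatures + 1L)

  run1 <- function(sig, s) {
    tryCatch(pipeline_metric(sig, train, validations, metric, horizon,
                             fit_args, seed = s),
             error = function(e) {
               warning("pipeline failed for a signature (", conditionMessage(e),
                       "); recording the no-signal value")
               no_signal_value(metric)
             })
  }
  observed <- run1(signature, sig_seeds[1L])
  null_values <- vapply(seq_len(n_signatures), function(i) {
    rs <- sample_random_signature(universe, size, seed = sig_seeds[i + 1L],
                                  platform = platform_of(train$expr))
    run1(rs, sig_seeds[i + 1L])
  }, numeric(1))
  structure(list(metric = metric, observed = observed,
                 null_values = null_values, n_signatures = n_signatures,
                 empirical_p = (1 + sum(null_values >= observed)) /
                   (n_signatures + 1)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution [%s]: observed %.4g vs %d random signatures; empirical p = %.4g\n",
              x$metric, x$observed, x$n_signatures, x$empirical_p))
  invisible(x)
}

#' Nottingham Prognostic Index
#'
#' `NPI = 0.2 * size_cm + grade + nodal stage`, with nodal stage 1 for 0
#' positive nodes, 2 for 1-3 and 3 for 4 or more. Bands follow the index's
#' conventional closed-boundary cutoffs: good (NPI <= 3.4), moderate
#' (3.4 < NPI <= 5.4), poor (> 5.4). Because few patients fall in the poor
#' band, moderate and poor are merged into a `high` risk group; good is
#' `low`. All constants are configurable.
#'
#' @param size_cm tumour size in cm (>= 0).
#' @param grade histological grade, 1-3.
#' @param n_nodes number of positive lymph nodes (>= 0).
#' @param size_coef size coefficient (default 0.2).
#' @param cutoffs band cutoffs, `c(good, moderate)` (default `c(3.4, 5.4)`).
#' @param node_breaks nodal staging breaks: stage 1 up to `node_breaks[1]`
#'   nodes (exclusive), stage 2 up to `node_breaks[2]` (exclusive), else 3.
#' @return data.frame of class `npi_record` with `size_cm`, `grade`,
#'   `nodal_stage`, `npi_value`, `band`, `merged_group`.
#' @examples
#' npi_score(2, 2, 1)   # NPI 4.4: moderate band, merged high risk
#' @export
npi_score <- function(size_cm, grade, n_nodes, size_coef = 0.2,
                      cutoffs = c(3.4, 5.4), node_breaks = c(1, 4)) {
  if (any(!grade %in% 1:3)) stop("grade must be 1, 2 or 3")
  if (any(size_cm < 0)) stop("tumour size must be >= 0")
  if (any(n_nodes < 0)) stop("node count must be >= 0")
  stage <- ifelse(n_nodes < node_breaks[1L], 1L,
                  ifelse(n_nodes < node_breaks[2L], 2L, 3L))
  npi <- size_coef * size_cm + grade + stage
  band <- factor(ifelse(npi <= cutoffs[1L], "good",
                        ifelse(npi <= cutoffs[2L], "moderate", "poor")),
                 levels = c("good", "moderate", "poor"))
  structure(data.frame(size_cm = size_cm, grade = as.integer(grade),
                       nodal_stage = stage, npi_value = npi, band = band,
                       merged_group = factor(ifelse(band == "good", "low", "high"),
                                             levels = c("low", "high")),
                       row.names = NULL),
            class = c("npi_record", "data.frame"))
}

#' Cross-classification of NPI and signature risk groups
#'
#' Builds the 2x2 table of merged NPI risk against signature risk on the same
#' patients, reports the reclassified fractions (NPI-high called low by the
#' signature — candidate false positives — and NPI-low called high —
#' candidate false negatives), and exports the four survival subgroups for
#' Kaplan-Meier / logrank follow-up.
#'
#' @param npi_groups factor low/high from merged NPI bands.
#' @param sig_groups factor low/high from the signature risk model.
#' @param time,event follow-up and events.
#' @return list with `table` (NPI x signature counts),
#'   `frac_npi_high_reclassified_low`, `frac_npi_low_reclassified_high`,
#'   and `subgroups` (data.frame with the four-group factor and survival
#'   columns).
#' @export
reclassification <- function(npi_groups, sig_groups, time, event) {
  npi_groups <- factor(as.character(npi_groups), levels = c("low", "high"))
  sig_groups <- factor(as.character(sig_groups), levels = c("low", "high"))
  if (length(npi_groups) != length(sig_groups))
    stop("groupings must cover the same patients")
  tab <- table(npi = npi_groups, signature = sig_groups)
  fr_high_low <- if (sum(tab["high", ]) > 0)
    tab["high", "low"] / sum(tab["high", ]) else NA_real_
  fr_low_high <- if (sum(tab["low", ]) > 0)
    tab["low", "high"] / sum(tab["low", ]) else NA_real_
  subgroups <- data.frame(
    group = interaction(npi_groups, sig_groups, sep = "/", lex.order = TRUE),
    npi = npi_groups, signature = sig_groups,
    time_years = time, event = event, row.names = NULL)
  list(table = tab,
       frac_npi_high_reclassified_low = unname(fr_high_low),
       frac_npi_low_reclassified_high = unname(fr_low_high),
       subgroups = subgroups)
}

#' Assign ER/HER2 breast cancer subtypes
#'
#' Uses clinical ER/HER2 labels when present; otherwise fits a two-component
#' Gaussian mixture per marker gene's expression within the cohort and calls
#' positive the higher-mean component. HER2 positivity takes precedence: the
#' classes are `HER2+`, `ER+/HER2-`, `ER-/HER2-`.
#'
#' @param cohort a [cohort()].
#' @param er_probe,her2_probe probeset ids of the ER (ESR1) and HER2 (ERBB2)
#'   marker genes, needed only when clinical labels are absent.
#' @return factor of subtypes, one per patient.
#' @export
assign_subtype <- function(cohort, er_probe = NULL, her2_probe = NULL) {
  cl <- cohort$clinical
  has_labels <- all(c("er", "her2") %in% names(cl)) &&
    !anyNA(cl$er) && !anyNA(cl$her2)
  if (has_labels) {
    er_pos <- cl$er == "+"; her2_pos <- cl$her2 == "+"
  } else {
    if (is.null(er_probe) || is.null(her2_probe))
      stop("no clinical ER/HER2 labels: provide `er_probe` and `her2_probe`")
    miss <- setdiff(c(er_probe, her2_probe), rownames(cohort$expr))
    if (length(miss))
      stop("marker probesets missing: ", paste(miss, collapse = ", "))
    er_pos <- mixture_positive(cohort$expr[er_probe, ])
    her2_pos <- mixture_positive(cohort$expr[her2_probe, ])
  }
  factor(ifelse(her2_pos, "HER2+",
                ifelse(er_pos, "ER+/HER2-", "ER-/HER2-")),
         levels = c("ER+/HER2-", "ER-/HER2-", "HER2+"))
}

# two-component univariate Gaussian mixture; TRUE = higher-mean component.
# Mclust resolves mclustBIC/mclustModelNames in the calling scope, so they
# must be imported, not just ::-qualified.
#' @importFrom mclust Mclust mclustBIC
mixture_positive <- function(x) {
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) fit <- mclust::Mclust(x, G = 2, modelNames = "E",
                                          verbose = FALSE)
  hi <- which.max(fit$parameters$mean)
  fit$classification == hi
}

#' Score a cohort with an external signature scorer
#'
#' Adapter giving externally defined prognostic models (e.g. published
#' multigene assays with their own scoring rules) the same
#' score/group output shape as [classify()], so [evaluate_cohorts()] and
#' [compare_paired()] apply unchanged. A `risk_model` passes through the
#' package's own scoring; otherwise the scorer must be a list with a
#' `score` function (`cohort -> numeric`) and a `threshold`.
#'
#' @param scorer a `risk_model` or `list(score = function(cohort), threshold =)`.
#' @param cohort a [cohort()].
#' @return data.frame with `sample_id`, `score`, `group` as from [classify()].
#' @export
score_external_signature <- function(scorer, cohort) {
  if (inherits(scorer, "risk_model"))
    return(classify(risk_score(scorer, cohort$expr), scorer))
  if (!is.list(scorer) || !is.function(scorer$score) ||
      is.null(scorer$threshold))
    stop("scorer must be a risk_model or list(score = function, threshold =)")
  s <- scorer$score(cohort)
  if (length(s) != n_patients(cohort))
    stop("scorer returned ", length(s), " scores for ",
         n_patients(cohort), " patients")
  if (is.null(names(s))) names(s) <- cohort$clinical$sample_id
  data.frame(sample_id = names(s), score = as.numeric(s),
             group = factor(ifelse(s > scorer$threshold, "high", "low"),
                            levels = c("low", "high")),
             row.names = NULL, stringsAsFactors = FALSE)
}
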