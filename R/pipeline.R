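#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the workflow's
#' reference defaults: signature size 100, 200 resamplings at a 90/10 split,
#' 5-year classification horizon, 10-year administrative censoring, 1000
#' random null signatures, and the nested patient subsets (all patients,
#' ER+/HER2-, node-negative, untreated).
#'
#' @param k signature size.
#' @param n_resamples resampling count for signature derivation.
#' @param split_fraction training fraction per resampling.
#' @param horizon classification horizon in years.
#' @param censor_horizon administrative censoring horizon in years.
#' @param alpha_grid elastic-net mixing grid for the penalized Cox fit.
#' @param cv_folds cross-validation folds.
#' @param n_null_signatures random signatures per null distribution
#'   (0 skips the null stage).
#' @param seed master seed; all stage seeds derive from it.
#' @param n_lines,n_probes,n_planted,overlap,effect_size,noise_sd cell-line
#'   generator settings (see [gen_cell_line_experiment()]).
#' @param dst_probes,n_genes destination-platform annotation settings.
#' @param n_train,n_valid,n_valid_cohorts cohort sizes for the synthetic
#'   training and validation cohorts.
#' @param hr_per_sd,baseline_rate,censor_rate survival-cohort generator
#'   settings (see [gen_cohort()]).
#' @param subsets nested patient filters evaluated in order.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 100, n_resamples = 200, split_fraction = 0.9,
                            horizon = 5, censor_horizon = 10,
                            alpha_grid = c(0.1, 0.5, 0.9), cv_folds = 5,
                            n_null_signatures = 1000, seed = 1,
                            n_lines = 20, n_probes = 5000, n_planted = 100,
                            overlap = 10, effect_size = 1.0, noise_sd = 0.5,
                            dst_probes = 4000, n_genes = 3000,
                            n_train = 344, n_valid = 300, n_valid_cohorts = 4,
                            hr_per_sd = 2, baseline_rate = 0.08,
                            censor_rate = 0.3,
                            subsets = c("all", "er_pos_her2_neg",
                                        "node_negative", "untreated")) {
  cfg <- as.list(environment())
  num <- cfg[vapply(cfg, is.numeric, TRUE)]
  if (any(unlist(num) < 0)) stop("numeric configuration values must be >= 0")
  for (nm in c("k", "n_resamples", "horizon", "censor_horizon", "cv_folds",
               "n_lines", "n_probes", "n_planted", "n_train", "n_valid",
               "n_valid_cohorts"))
    if (cfg[[nm]] <= 0) stop("`", nm, "` must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Restrict a cohort to a nested clinical subset
#'
#' Filters are nested, mirroring the evaluation's patient strata: each
#' implies the previous. `er_pos_her2_neg` keeps ER+/HER2- patients;
#' `node_negative` additionally requires node-negative status; `untreated`
#' additionally requires no systemic treatment.
#'
#' @param cohort a [cohort()].
#' @param filter one of `"all"`, `"er_pos_her2_neg"`, `"node_negative"`,
#'   `"untreated"`.
#' @return the filtered [cohort()].
#' @export
apply_subset <- function(cohort,
                         filter = c("all", "er_pos_her2_neg",
                                    "node_negative", "untreated")) {
  filter <- match.arg(filter)
  cl <- cohort$clinical
  need <- switch(filter, all = character(),
                 er_pos_her2_neg = c("er", "her2"),
                 node_negative = c("er", "her2", "node_pos"),
                 untreated = c("er", "her2", "node_pos", "treated"))
  missing_col <- setdiff(need, names(cl))
  if (length(missing_col))
    stop("missing clinical column(s): ", paste(missing_col, collapse = ", "))
  keep <- rep(TRUE, nrow(cl))
  if (filter %in% c("er_pos_her2_neg", "node_negative", "untreated"))
    keep <- keep & cl$er == "+" & cl$her2 == "-"
  if (filter %in% c("node_negative", "untreated"))
    keep <- keep & cl$node_pos == 0
  if (filter == "untreated")
    keep <- keep & cl$treated == 0
  cohort_subset(cohort, keep)
}

# internal: row/column subset of a cohort by logical or index
cohort_subset <- function(ch, keep) {
  ex <- ch$expr[, keep, drop = FALSE]
  attr(ex, "platform") <- platform_of(ch$expr)
  class(ex) <- class(ch$expr)
  cohort(ex, ch$clinical[keep, , drop = FALSE], ch$cohort_id)
}

#' Run the end-to-end prognostic-signature pipeline
#'
#' Executes, in order: synthetic cell-line simulation, signature derivation
#' by resampling, cross-platform mapping, synthetic survival-cohort
#' simulation on the clinical platform, administrative censoring, penalized
#' Cox fitting on the training cohort, classification and survival
#' evaluation of the validation cohorts on each nested patient subset,
#' random-signature null distribution, and NPI reclassification. Every stage
#' writes its artifact (delimited text or JSON) plus an md5 checksum
#' manifest under `out_dir`; any stage error aborts with the stage name
#' after writing a partial-report manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return a `run_report` list: `config`, `signature`, `summary`,
#'   `mapping_report`, `model`, `eval` (per-subset [evaluate_cohorts()]
#'   tables), `null_summary`, `reclassification`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("prosig_run_")) {
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config))
  manifest <- list()
  finish_stage <- function(name, files) {
    manifest[[name]] <<- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      jsonlite::write_json(list(failed_stage = name,
                                error = conditionMessage(e),
                                completed = names(manifest)),
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 10L)

  ## 1. simulate the cell-line experiment ---------------------------------
  sim <- stage("simulate_cell_lines", {
    ex <- gen_cell_line_experiment(config$n_lines, config$n_probes,
                                   config$n_planted, config$overlap,
                                   config$effect_size, config$noise_sd,
                                   seed = seeds[1L])
    write_expr_matrix(ex$expr, file.path(out_dir, "cell_line_expr.tsv"))
    write_table_tsv(ex$design, file.path(out_dir, "cell_line_design.tsv"))
    jsonlite::write_json(lapply(unclass(ex$truth), I),
                         file.path(out_dir, "cell_line_truth.json"))
    finish_stage("simulate_cell_lines",
                 file.path(out_dir, c("cell_line_expr.tsv",
                                      "cell_line_design.tsv",
                                      "cell_line_truth.json")))
    ex
  })

  ## 2. derive the signature ----------------------------------------------
  der <- stage("derive_signature", {
    d <- derive_signature(sim$expr, sim$design, c("normoxia", "cychyp"),
                          k = config$k, n_resamples = config$n_resamples,
                          fraction = config$split_fraction, seed = seeds[2L])
    write_signature(d$signature, file.path(out_dir, "signature_src.tsv"))
    write_table_tsv(data.frame(resample = seq_along(d$summary$per_resample_accuracy),
                               accuracy = d$summary$per_resample_accuracy),
                    file.path(out_dir, "resample_accuracy.tsv"))
    finish_stage("derive_signature",
                 file.path(out_dir, c("signature_src.tsv",
                                      "resample_accuracy.tsv")))
    d
  })
  report$signature <- der$signature
  report$summary <- der$summary

  ## 3. map to the clinical platform --------------------------------------
  mp <- stage("map_signature", {
    ann <- gen_annotation(config$n_probes, config$dst_probes, config$n_genes,
                          seed = seeds[3L])
    m <- map_signature(der$signature, ann$src, ann$dst)
    write_signature(m$signature, file.path(out_dir, "signature_dst.tsv"))
    jsonlite::write_json(unclass(m$report),
                         file.path(out_dir, "mapping_report.json"),
                         auto_unbox = TRUE)
    finish_stage("map_signature",
                 file.path(out_dir, c("signature_dst.tsv",
                                      "mapping_report.json")))
    c(m, list(annotation = ann))
  })
  report$mapping_report <- mp$report
  dst_sig <- mp$signature

  ## 4. simulate survival cohorts on the clinical platform ----------------
  cohorts <- stage("simulate_cohorts", {
    universe <- mp$annotation$dst$probeset_id
    mk <- function(n, id, sd) gen_cohort(
      n, dst_sig$probeset_ids, hr_per_sd = config$hr_per_sd,
      baseline_rate = config$baseline_rate, censor_rate = config$censor_rate,
      horizon = config$censor_horizon, universe = universe,
      cohort_id = id, seed = sd)$cohort
    train <- mk(config$n_train, "TRAIN", seeds[4L])
    vals <- lapply(seq_len(config$n_valid_cohorts), function(i)
      mk(config$n_valid, sprintf("VAL%d", i), seeds[4L] %% 1000L + i))
    names(vals) <- vapply(vals, `[[`, "", "cohort_id")
    for (ch in c(list(train), vals)) {
      write_table_tsv(ch$clinical,
                      file.path(out_dir, paste0("clinical_", ch$cohort_id, ".tsv")))
    }
    finish_stage("simulate_cohorts",
                 file.path(out_dir, paste0("clinical_",
                                           c("TRAIN", names(vals)), ".tsv")))
    list(train = train, validations = vals)
  })

  ## 5. censor, fit, classify ---------------------------------------------
  model <- stage("fit_risk_model", {
    tr <- cohorts$train
    cc <- censor_at(tr$clinical$time_years, tr$clinical$event,
                    config$censor_horizon)
    tr$clinical$time_years <- cc$time; tr$clinical$event <- cc$event
    m <- fit_penalized_cox(tr, dst_sig, alpha_grid = config$alpha_grid,
                           cv_folds = config$cv_folds, seed = seeds[5L],
                           horizon = config$horizon)
    write_risk_model(m, file.path(out_dir, "risk_model.json"))
    finish_stage("fit_risk_model", file.path(out_dir, "risk_model.json"))
    m
  })
  report$model <- model

  ## 6. evaluate on nested subsets ----------------------------------------
  report$eval <- stage("evaluate", {
    evals <- list()
    for (f in config$subsets) {
      strata <- list()
      for (v in cohorts$validations) {
        sub <- apply_subset(v, f)
        if (n_patients(sub) < 10L || sum(sub$clinical$event) < 2L) next
        cc <- censor_at(sub$clinical$time_years, sub$clinical$event,
                        config$censor_horizon)
        cl <- classify(risk_score(model, sub$expr), model)
        strata[[sub$cohort_id]] <- list(group = cl$group, score = cl$score,
                                        time = cc$time, event = cc$event)
      }
      if (length(strata) == 0L) next
      tab <- evaluate_cohorts(strata, horizon = config$horizon)
      write_table_tsv(tab, file.path(out_dir, paste0("eval_", f, ".tsv")))
      evals[[f]] <- tab
    }
    finish_stage("evaluate",
                 file.path(out_dir, paste0("eval_", names(evals), ".tsv")))
    evals
  })

  ## 7. random-signature null ---------------------------------------------
  if (config$n_null_signatures > 0) {
    report$null_summary <- stage("null_distribution", {
      tr <- cohorts$train
      cc <- censor_at(tr$clinical$time_years, tr$clinical$event,
                      config$censor_horizon)
      tr$clinical$time_years <- cc$time; tr$clinical$event <- cc$event
      nd <- null_distribution(tr, cohorts$validations, dst_sig,
                              n_signatures = config$n_null_signatures,
                              metric = "logrank_logp", seed = seeds[6L],
                              horizon = config$horizon,
                              fit_args = list(alpha_grid = 0.5,
                                              cv_folds = config$cv_folds))
      write_table_tsv(data.frame(null_logrank_logp = nd$null_values),
                      file.path(out_dir, "null_values.tsv"))
      jsonlite::write_json(list(metric = nd$metric, observed = nd$observed,
                                n_signatures = nd$n_signatures,
                                empirical_p = nd$empirical_p),
                           file.path(out_dir, "null_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      finish_stage("null_distribution",
                   file.path(out_dir, c("null_values.tsv",
                                        "null_summary.json")))
      nd
    })
  } else {
    report$null_summary <- "skipped (n_null_signatures = 0)"
  }

  ## 8. NPI reclassification ----------------------------------------------
  report$reclassification <- stage("npi_reclassification", {
    cls <- lapply(cohorts$validations, function(v)
      classify(risk_score(model, v$expr), model))
    clin <- do.call(rbind, lapply(cohorts$validations, `[[`, "clinical"))
    npi <- npi_score(clin$size_cm, clin$grade, clin$n_nodes)
    rc <- reclassification(npi$merged_group,
                           unlist(lapply(cls, function(x) as.character(x$group))),
                           clin$time_years, clin$event)
    jsonlite::write_json(list(table = as.list(as.data.frame(rc$table)),
                              frac_npi_high_reclassified_low =
                                rc$frac_npi_high_reclassified_low,
                              frac_npi_low_reclassified_high =
                                rc$frac_npi_low_reclassified_high),
                         file.path(out_dir, "reclassification.json"),
                         auto_unbox = TRUE, digits = NA)
    finish_stage("npi_reclassification",
                 file.path(out_dir, "reclassification.json"))
    rc
  })

  report$provenance <- list(seed = config$seed,
                            package_version = as.character(
                              utils::packageVersion("prosig")),
                            r_version = R.version.string,
                            out_dir = out_dir)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("prosig run_report\n")
  cat(sprintf("  signature: %d probesets -> %d on clinical platform\n",
              x$signature$size, x$mapping_report$n_destination_probesets))
  for (f in names(x$eval)) {
    pooled <- x$eval[[f]][x$eval[[f]]$cohort_id == "pooled", ]
    if (nrow(pooled))
      cat(sprintf("  %-16s pooled HR %.2f (p=%.3g), C-index %.3f, BCR %.3f\n",
                  f, pooled$hr, pooled$hr_p, pooled$cindex, pooled$bcr))
  }
  if (inherits(x$null_summary, "null_distribution"))
    cat(sprintf("  null: empirical p = %.4g (%d random signatures)\n",
                x$null_summary$empirical_p, x$null_summary$n_signatures))
  invisible(x)
}
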