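#' Simulate a multi-condition cell-line expression experiment
#'
#' Generates a log2 expression matrix for `n_lines` cell lines profiled under
#' three oxygenation conditions (normoxia, cycling hypoxia, continuous
#' hypoxia), with two planted sets of differential probesets: one shifted
#' under cycling hypoxia, one under continuous hypoxia, sharing `overlap`
#' probesets. Each observation is
#' baseline(probe) + line effect + condition shift + N(0, noise_sd),
#' so the planted probesets have mean log2 shift `effect_size` in their
#' condition versus normoxia.
#'
#' @param n_lines number of cell lines (>= 2); the matrix has `3 * n_lines`
#'   samples, one per line per condition.
#' @param n_probes probeset universe size.
#' @param n_planted number of planted differential probesets per condition.
#' @param overlap number of probesets planted under both hypoxia conditions.
#' @param effect_size mean log2 shift of planted probesets (may be 0).
#' @param noise_sd per-observation Gaussian SD (log2 units).
#' @param line_sd SD of an optional per-line scalar intercept shared across
#'   conditions (adds the paired structure of a real cell-line panel; the
#'   default 0 keeps observations independent so null p-values are exactly
#'   uniform).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with `expr` ([expr_matrix()]), `design` (data.frame
#'   `sample_id`, `condition`, `cell_line`) and `truth`
#'   (`planted_cyc`, `planted_cont`, `effect_size`, `noise_sd`).
#' @examples
#' ex <- gen_cell_line_experiment(n_lines = 4, n_probes = 200, n_planted = 10,
#'                                seed = 1)
#' dim(ex$expr)
#' @export
gen_cell_line_experiment <- function(n_lines = 20, n_probes = 5000,
                                     n_planted = 100, overlap = 10,
                                     effect_size = 1.0, noise_sd = 0.5,
                                     line_sd = 0, seed = NULL) {
  n_lines <- check_count(n_lines, "n_lines", min = 2L)
  n_probes <- check_count(n_probes, "n_probes")
  n_planted <- check_count(n_planted, "n_planted", min = 0L)
  overlap <- check_count(overlap, "overlap", min = 0L)
  if (n_planted > n_probes) stop("n_planted must be <= n_probes")
  if (overlap > n_planted) stop("overlap must be <= n_planted")
  if (noise_sd < 0 || line_sd < 0) stop("standard deviations must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  probes <- sprintf("PS%05d", seq_len(n_probes))
  lines <- sprintf("L%02d", seq_len(n_lines))
  conditions <- c("normoxia", "cychyp", "conthyp")
  design <- data.frame(
    sample_id = paste(rep(lines, each = 3L), rep(conditions, n_lines), sep = "_"),
    condition = rep(conditions, n_lines),
    cell_line = rep(lines, each = 3L),
    stringsAsFactors = FALSE)

  planted_cyc <- sample(probes, n_planted)
  shared <- sample(planted_cyc, overlap)
  planted_cont <- c(shared,
                    sample(setdiff(probes, planted_cyc), n_planted - overlap))

  baseline <- stats::rnorm(n_probes, mean = 7, sd = 1.5)
  line_eff <- stats::rnorm(n_lines, sd = line_sd)

  values <- matrix(stats::rnorm(n_probes * nrow(design), sd = noise_sd),
                   nrow = n_probes, ncol = nrow(design),
                   dimnames = list(probes, design$sample_id))
  values <- values + baseline
  values <- sweep(values, 2L, line_eff[match(design$cell_line, lines)], `+`)
  values[match(planted_cyc, probes), design$condition == "cychyp"] <-
    values[match(planted_cyc, probes), design$condition == "cychyp"] + effect_size
  values[match(planted_cont, probes), design$condition == "conthyp"] <-
    values[match(planted_cont, probes), design$condition == "conthyp"] + effect_size

  truth <- structure(list(planted_cyc = planted_cyc,
                          planted_cont = planted_cont,
                          effect_size = effect_size, noise_sd = noise_sd),
                     class = "cell_line_truth")
  list(expr = expr_matrix(values, platform = "synthST"),
       design = design, truth = truth)
}

#' Simulate a survival cohort driven by a latent signature activity
#'
#' Each patient carries a standard-normal latent activity. Expression of the
#' signature probesets is `loading * activity + N(0, noise_sd)` around a
#' probe-specific baseline; other probesets in `universe` are pure noise.
#' Event times follow an exponential proportional-hazards model with linear
#' predictor `log(hr_per_sd) * activity`, subject to independent exponential
#' censoring scaled so the expected censored fraction is `censor_rate`, and to
#' administrative censoring at `horizon` years. The clinical table carries the
#' covariates needed for Nottingham-index computation (size, grade, nodes) and
#' subset filtering (ER/HER2, node status, treatment); when `clinical_link` is
#' set, grade is positively associated with activity.
#'
#' @param n_patients cohort size.
#' @param signature_probes character vector of probeset ids carrying signal.
#' @param hr_per_sd design hazard ratio per 1 SD of activity (> 0).
#' @param baseline_rate baseline event rate, events per year.
#' @param censor_rate expected fraction randomly censored, in [0, 1).
#' @param horizon administrative censoring horizon in years (default 10).
#' @param clinical_link logical; tie grade to activity quartile.
#' @param noise_sd SD of expression noise around the activity signal.
#' @param loading coefficient linking activity to signature expression.
#' @param universe optional full probeset universe (must contain
#'   `signature_probes`); defaults to the signature probesets alone.
#' @param platform platform tag for the generated matrix.
#' @param cohort_id label.
#' @param seed integer seed.
#' @return list with `cohort` (a [cohort()]) and `truth` (latent activity,
#'   design parameters).
#' @export
gen_cohort <- function(n_patients, signature_probes, hr_per_sd = 2,
                       baseline_rate = 0.08, censor_rate = 0.3, horizon = 10,
                       clinical_link = TRUE, noise_sd = 0.5, loading = 1.0,
                       universe = NULL, platform = "synthHG",
                       cohort_id = "synth", seed = NULL) {
  n_patients <- check_count(n_patients, "n_patients", min = 2L)
  signature_probes <- as.character(signature_probes)
  if (length(signature_probes) == 0L) stop("empty signature probe list")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (hr_per_sd <= 0) stop("hr_per_sd must be > 0")
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (is.null(universe)) universe <- signature_probes
  universe <- as.character(universe)
  if (!all(signature_probes %in% universe))
    stop("`universe` must contain all signature probesets")
  if (!is.null(seed)) set.seed(seed)

  patients <- sprintf("%s_P%04d", cohort_id, seq_len(n_patients))
  activity <- stats::rnorm(n_patients)

  baseline <- stats::rnorm(length(universe), mean = 7, sd = 1)
  values <- matrix(stats::rnorm(length(universe) * n_patients, sd = noise_sd),
                   nrow = length(universe), ncol = n_patients,
                   dimnames = list(universe, patients))
  values <- values + baseline
  sig_rows <- match(signature_probes, universe)
  values[sig_rows, ] <- values[sig_rows, ] +
    rep(loading * activity, each = length(sig_rows))

  beta <- log(hr_per_sd)
  rate <- baseline_rate * exp(beta * activity)
  t_event <- stats::rexp(n_patients, rate = rate)
  if (censor_rate > 0) {
    # marginal censoring prob for exponential competing times:
    # P(C < T) = lam_c / (lam_c + lam_t); solve using the mean event rate
    lam_c <- censor_rate / (1 - censor_rate) * baseline_rate * exp(beta^2 / 2)
    t_cens <- stats::rexp(n_patients, rate = lam_c)
  } else {
    t_cens <- rep(Inf, n_patients)
  }
  time <- pmin(t_event, t_cens, horizon)
  event <- as.integer(t_event <= pmin(t_cens, horizon))

  size_cm <- stats::rlnorm(n_patients, meanlog = 0.7, sdlog = 0.4)
  n_nodes <- stats::rpois(n_patients, lambda = 1)
  if (clinical_link) {
    quart <- findInterval(activity, stats::quantile(activity, c(.25, .5, .75))) + 1L
    gp <- rbind(c(.50, .35, .15), c(.35, .40, .25),
                c(.25, .40, .35), c(.15, .35, .50))
    grade <- vapply(quart, function(q) sample(3L, 1L, prob = gp[q, ]), integer(1))
  } else {
    grade <- sample(3L, n_patients, replace = TRUE, prob = c(.30, .45, .25))
  }
  er <- sample(c("+", "-"), n_patients, replace = TRUE, prob = c(.75, .25))
  her2 <- sample(c("+", "-"), n_patients, replace = TRUE, prob = c(.15, .85))
  node_pos <- as.integer(n_nodes > 0)
  treated <- stats::rbinom(n_patients, 1L, prob = 0.2 + 0.4 * node_pos)

  clinical <- data.frame(
    sample_id = patients, time_years = time, event = event,
    er = er, her2 = her2, node_pos = node_pos, treated = treated,
    size_cm = size_cm, grade = grade, n_nodes = n_nodes,
    stringsAsFactors = FALSE)

  truth <- structure(list(latent_activity = stats::setNames(activity, patients),
                          hr_per_sd = hr_per_sd, loading = loading,
                          signature_probes = signature_probes,
                          baseline_hazard = baseline_rate,
                          censor_rate = censor_rate),
                     class = "cohort_truth")
  list(cohort = cohort(expr_matrix(values, platform = platform),
                       clinical, cohort_id = cohort_id),
       truth = truth)
}

#' Simulate probeset-to-gene annotation for two platforms
#'
#' Builds many-to-one probeset-to-gene maps for a source (discovery) and a
#' destination (clinical) platform over a shared gene set; every gene gets at
#' least one probeset on each platform, remaining probesets are assigned to
#' genes uniformly at random.
#'
#' @param src_probes,dst_probes probeset counts per platform.
#' @param n_genes shared gene universe size (<= each probe count).
#' @param src_platform,dst_platform platform tags.
#' @param seed integer seed.
#' @return list of two [probe_annotation()] tables, `src` and `dst`.
#' @export
gen_annotation <- function(src_probes, dst_probes, n_genes,
                           src_platform = "synthST", dst_platform = "synthHG",
                           seed = NULL) {
  src_probes <- check_count(src_probes, "src_probes")
  dst_probes <- check_count(dst_probes, "dst_probes")
  n_genes <- check_count(n_genes, "n_genes")
  if (n_genes > src_probes || n_genes > dst_probes)
    stop("n_genes must be <= src_probes and <= dst_probes")
  if (!is.null(seed)) set.seed(seed)

  genes <- sprintf("G%05d", seq_len(n_genes))
  one_platform <- function(n, prefix) {
    gene_id <- c(sample(genes),                          # coverage: one each
                 sample(genes, n - n_genes, replace = TRUE))
    data.frame(probeset_id = sprintf("%s%05d", prefix, seq_len(n)),
               gene_id = gene_id, stringsAsFactors = FALSE)
  }
  list(src = probe_annotation(one_platform(src_probes, "PS"), src_platform),
       dst = probe_annotation(one_platform(dst_probes, "QS"), dst_platform))
}
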