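#' Construct an expression matrix
#'
#' A log2 expression matrix with probesets as rows and samples as columns,
#' tagged with the microarray platform it was measured on. This is the common
#' currency of the whole package: signature derivation, platform restriction
#' and risk scoring all operate on it.
#'
#' @param values numeric matrix, probesets x samples, log2 scale.
#' @param platform character scalar naming the platform.
#' @return the matrix with class `expr_matrix` and a `platform` attribute.
#' @export
expr_matrix <- function(values, platform = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyNA(rownames(values)) || any(rownames(values) == ""))
    stop("all probesets must be named (rownames)")
  if (is.null(colnames(values)) || anyNA(colnames(values)) || any(colnames(values) == ""))
    stop("all samples must be named (colnames)")
  if (anyDuplicated(rownames(values))) stop("duplicated probeset ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (!all(is.finite(values))) stop("expression values must be finite")
  attr(values, "platform") <- as.character(platform)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probesets x %d samples [%s]\n",
              nrow(x), ncol(x), platform_of(x)))
  invisible(x)
}

#' Platform of an expression matrix, annotation or signature
#' @param x an object carrying a platform tag.
#' @return character scalar.
#' @export
platform_of <- function(x) {
  p <- attr(x, "platform")
  if (is.null(p)) p <- if (is.list(x) && !is.null(x$platform)) x$platform else "unknown"
  p
}

#' Construct a probeset signature
#'
#' An ordered probeset list on a given platform, optionally carrying the
#' per-probeset ranking score (mean FDR-corrected p-value over resamplings).
#'
#' @param probeset_ids character vector, unique, in rank order.
#' @param platform character scalar.
#' @param scores optional numeric vector of ranking scores, same length.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(probeset_ids, platform = "unknown", scores = NULL) {
  probeset_ids <- as.character(probeset_ids)
  if (anyDuplicated(probeset_ids)) stop("signature probeset ids must be unique")
  if (!is.null(scores)) {
    if (length(scores) != length(probeset_ids))
      stop("`scores` must align with `probeset_ids`")
    scores <- stats::setNames(as.numeric(scores), probeset_ids)
  }
  structure(list(probeset_ids = probeset_ids,
                 platform = as.character(platform),
                 size = length(probeset_ids),
                 scores = scores),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d probesets [%s]\n", x$size, x$platform))
  show <- utils::head(x$probeset_ids, 5L)
  cat("  ", paste(show, collapse = ", "),
      if (x$size > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Construct a probeset-to-gene annotation table
#'
#' Many-to-one map from platform probesets to gene identifiers (e.g. Entrez).
#' Probesets with a missing/blank gene id are allowed and are dropped (with a
#' warning) when a signature is mapped through the annotation.
#'
#' @param map data.frame with columns `probeset_id` and `gene_id` (and
#'   optionally `symbol`).
#' @param platform character scalar.
#' @return data.frame of class `probe_annotation`.
#' @export
probe_annotation <- function(map, platform = "unknown") {
  if (!all(c("probeset_id", "gene_id") %in% names(map)))
    stop("annotation needs columns `probeset_id` and `gene_id`")
  map$probeset_id <- as.character(map$probeset_id)
  map$gene_id <- as.character(map$gene_id)
  if (anyDuplicated(map$probeset_id))
    stop("each probeset may map to at most one gene")
  attr(map, "platform") <- as.character(platform)
  class(map) <- c("probe_annotation", "data.frame")
  map
}

#' Construct a survival cohort
#'
#' Bundles a patient expression matrix with a clinical/survival table. The
#' clinical table uses the package's documented column names: `time_years`,
#' `event`, `er`, `her2`, `node_pos`, `treated`, `size_cm`, `grade`,
#' `n_nodes`.
#'
#' @param expr an [expr_matrix()] with one column per patient.
#' @param clinical data.frame with one row per patient, rownames or a
#'   `sample_id` column matching `colnames(expr)`.
#' @param cohort_id character label for the cohort.
#' @return an object of class `cohort`.
#' @export
cohort <- function(expr, clinical, cohort_id = "cohort") {
  if (!inherits(expr, "expr_matrix")) expr <- expr_matrix(expr)
  if (is.null(clinical$sample_id)) clinical$sample_id <- rownames(clinical)
  clinical$sample_id <- as.character(clinical$sample_id)
  if (!identical(clinical$sample_id, colnames(expr)))
    stop("clinical rows must match expression columns one-to-one (same order)")
  if (!all(c("time_years", "event") %in% names(clinical)))
    stop("clinical table needs `time_years` and `event`")
  if (any(clinical$time_years < 0)) stop("negative survival times")
  if (!all(clinical$event %in% c(0L, 1L))) stop("`event` must be 0/1")
  structure(list(expr = expr, clinical = clinical,
                 cohort_id = as.character(cohort_id)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort '%s': %d patients, %d probesets, %d events\n",
              x$cohort_id, ncol(x$expr), nrow(x$expr), sum(x$clinical$event)))
  invisible(x)
}

# internal: n patients
n_patients <- function(ch) ncol(ch$expr)

# internal: stop unless x is a single positive (integer-ish) count
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}
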