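#' Read / write expression matrices as delimited text
#'
#' Tab-delimited, probesets as rows (first column `probeset_id`), samples as
#' columns with a header row.
#'
#' @param expr an [expr_matrix()].
#' @param path file path.
#' @param platform platform tag applied on read.
#' @return `write_expr_matrix` returns `path` invisibly; `read_expr_matrix`
#'   returns an [expr_matrix()].
#' @export
write_expr_matrix <- function(expr, path) {
  df <- data.frame(probeset_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path, platform = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  expr_matrix(m, platform = platform)
}

#' Read / write clinical and design tables
#'
#' Tab-delimited with a header; clinical tables use the documented column
#' names (`sample_id`, `time_years`, `event`, `er`, `her2`, `node_pos`,
#' `treated`, `size_cm`, `grade`, `n_nodes`).
#'
#' @param x data.frame.
#' @param path file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a two-column probeset annotation file
#'
#' @param path delimited text with columns `probeset_id`, `gene_id`.
#' @param platform platform tag.
#' @return a [probe_annotation()].
#' @export
read_annotation <- function(path, platform = "unknown") {
  probe_annotation(utils::read.delim(path, stringsAsFactors = FALSE), platform)
}

#' Write a signature with its metadata
#'
#' The probeset list (with ranking scores when available) goes to a
#' two-column delimited file; platform/size metadata to a JSON sidecar.
#'
#' @param sig a [gene_signature()].
#' @param path path of the delimited file; metadata goes to `<path>.json`.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(probeset_id = sig$probeset_ids,
                   mean_q = if (is.null(sig$scores)) NA_real_
                            else unname(sig$scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(platform = sig$platform, size = sig$size),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json")) else list(platform = "unknown")
  gene_signature(df$probeset_id, platform = meta$platform,
                 scores = if (all(is.na(df$mean_q))) NULL else df$mean_q)
}

#' Serialize a risk model to JSON
#'
#' @param model a `risk_model`.
#' @param path JSON file path.
#' @export
write_risk_model <- function(model, path) {
  obj <- list(probeset_ids = names(model$coefficients),
              coefficients = unname(model$coefficients),
              alpha = model$alpha, lambda = model$lambda,
              center = unname(model$center), scale = unname(model$scale),
              threshold = model$threshold,
              horizon_years = model$horizon_years,
              platform = model$platform, standardize = model$standardize)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- m$probeset_ids
  structure(list(coefficients = stats::setNames(m$coefficients, ids),
                 alpha = m$alpha, lambda = m$lambda,
                 center = stats::setNames(m$center, ids),
                 scale = stats::setNames(m$scale, ids),
                 threshold = m$threshold, horizon_years = m$horizon_years,
                 platform = m$platform, standardize = m$standardize),
            class = "risk_model")
}
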