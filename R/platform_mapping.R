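#' Transfer a signature to another platform through gene identifiers
#'
#' Maps the signature's probesets to gene ids on the source platform, then
#' collects *all* destination-platform probesets of each mapped gene (no
#' best-probeset collapsing). Source probesets without a gene annotation are
#' dropped with a warning. The destination signature is ordered by the source
#' rank of the gene, then by destination probeset id.
#'
#' @param sig a [gene_signature()] on the source platform.
#' @param annot_src,annot_dst [probe_annotation()] tables for the source and
#'   destination platforms.
#' @return list with `signature` (on the destination platform) and `report`
#'   (class `mapping_report`: `n_source_probesets`, `n_unique_genes`,
#'   `n_genes_on_destination`, `n_destination_probesets`, `dropped`).
#' @export
map_signature <- function(sig, annot_src, annot_dst) {
  if (!inherits(sig, "gene_signature")) stop("`sig` must be a gene_signature")
  if (!identical(sig$platform, platform_of(annot_src)))
    stop(sprintf("signature platform '%s' != source annotation platform '%s'",
                 sig$platform, platform_of(annot_src)))

  src_gene <- annot_src$gene_id[match(sig$probeset_ids, annot_src$probeset_id)]
  src_gene[!is.na(src_gene) & src_gene == ""] <- NA_character_
  dropped <- sig$probeset_ids[is.na(src_gene)]
  if (length(dropped))
    warning(length(dropped), " source probeset(s) lack a gene id and were dropped")

  genes <- unique(src_gene[!is.na(src_gene)])     # in source rank order
  dst <- annot_dst[!is.na(annot_dst$gene_id) & annot_dst$gene_id %in% genes, ,
                   drop = FALSE]
  if (nrow(dst) == 0L)
    stop("empty mapping: no signature gene is present on the destination platform")
  ord <- order(match(dst$gene_id, genes), dst$probeset_id, method = "radix")
  dst <- dst[ord, , drop = FALSE]

  report <- structure(list(
    n_source_probesets = sig$size,
    n_unique_genes = length(genes),
    n_genes_on_destination = length(unique(dst$gene_id)),
    n_destination_probesets = nrow(dst),
    dropped = dropped), class = "mapping_report")
  list(signature = gene_signature(dst$probeset_id,
                                  platform = platform_of(annot_dst)),
       report = report)
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf(paste0("mapping_report: %d source probesets -> %d genes, ",
                     "%d on destination (%d probesets); %d dropped\n"),
              x$n_source_probesets, x$n_unique_genes,
              x$n_genes_on_destination, x$n_destination_probesets,
              length(x$dropped)))
  invisible(x)
}

#' Restrict an expression matrix to a probeset whitelist
#'
#' Keeps only probesets present in `allowed_probesets`, preserving the
#' matrix's original row order (used e.g. to reduce an HGU133plus2 cohort to
#' the probesets shared with HGU133a).
#'
#' @param expr expression matrix.
#' @param allowed_probesets character vector of probeset ids to keep.
#' @return the restricted matrix, same class and platform tag.
#' @export
restrict_platform <- function(expr, allowed_probesets) {
  allowed_probesets <- as.character(allowed_probesets)
  if (length(allowed_probesets) == 0L) stop("`allowed_probesets` is empty")
  keep <- rownames(expr) %in% allowed_probesets
  if (!any(keep)) stop("no probeset of the matrix is in the allowed list")
  out <- expr[keep, , drop = FALSE]
  attr(out, "platform") <- platform_of(expr)
  class(out) <- class(expr)
  out
}
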