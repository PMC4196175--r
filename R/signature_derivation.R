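#' Random train/validation split of a two-condition design
#'
#' Restricts the design to the two conditions of interest and draws
#' `round(fraction * n)` samples uniformly at random as the training set; the
#' remainder is the held-out validation set.
#'
#' @param design design data.frame (`sample_id`, `condition`, `cell_line`).
#' @param condition_pair character(2), the two condition labels to contrast.
#' @param fraction training fraction in (0, 1); default 0.9.
#' @param seed integer seed.
#' @param min_per_condition minimum training samples required per condition;
#'   a draw below it raises a degenerate-split error. The default 1 only
#'   requires both conditions to be represented; [derive_signature()] demands
#'   2, the minimum for its per-split t-test.
#' @return list with `train` and `test` character vectors of sample ids.
#' @export
resample_split <- function(design, condition_pair, fraction = 0.9, seed = NULL,
                           min_per_condition = 1L) {
  if (length(condition_pair) != 2L) stop("`condition_pair` must have length 2")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  keep <- design[design$condition %in% condition_pair, , drop = FALSE]
  if (!all(condition_pair %in% keep$condition))
    stop("both conditions must be present in the design")
  n <- nrow(keep)
  n_train <- round(fraction * n)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, n_train)
  train <- keep$sample_id[idx]
  tab <- table(factor(keep$condition[idx], levels = condition_pair))
  if (any(tab < min_per_condition))
    stop("degenerate split: a condition has fewer than ", min_per_condition,
         " training samples")
  list(train = train, test = setdiff(keep$sample_id, train))
}

#' Per-probeset two-sample t-test
#'
#' Vectorised Welch (default) or pooled-variance t-test of every probeset row
#' between the two groups defined by `labels`. The sign of `t` follows
#' `mean(group2) - mean(group1)` where group1 is the first level.
#'
#' @param expr expression matrix (probesets x samples).
#' @param labels character/factor of length `ncol(expr)` with two levels; the
#'   first level (or first element of `levels`) is the reference group.
#' @param var_equal pooled-variance Student test instead of Welch.
#' @return data.frame with `probeset_id`, `t`, `p`.
#' @export
differential_test <- function(expr, labels, var_equal = FALSE) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("`labels` must define exactly two groups")
  if (length(labels) != ncol(expr)) stop("`labels` must match samples")
  i1 <- which(labels == levels(labels)[1L])
  i2 <- which(labels == levels(labels)[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  x1 <- expr[, i1, drop = FALSE]; x2 <- expr[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  # both groups constant: equal means -> no evidence (p = 1); unequal -> p = 0
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    tt[eq] <- 0; p[eq] <- 1
    ne <- degen & (m1 != m2)
    tt[ne] <- sign(m2 - m1)[ne] * Inf; p[ne] <- 0
  }
  data.frame(probeset_id = rownames(expr), t = tt, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): monotone in the sorted order, each at
#' least its raw p, capped at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order and names.
#' @export
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Held-out nearest-centroid classification accuracy
#'
#' Computes per-condition centroids of the signature probesets on the training
#' samples and classifies each held-out sample to the nearest centroid in
#' Euclidean distance on log2 values.
#'
#' @param train_expr,test_expr expression matrices sharing the signature rows.
#' @param train_labels,test_labels condition labels per column.
#' @param signature a [gene_signature()] or character vector of probeset ids.
#' @return fraction of held-out samples classified into their true condition.
#' @export
holdout_accuracy <- function(train_expr, train_labels, test_expr, test_labels,
                             signature) {
  ids <- if (inherits(signature, "gene_signature")) signature$probeset_ids
         else as.character(signature)
  if (ncol(test_expr) == 0L) stop("empty test set: accuracy undefined")
  miss <- setdiff(ids, intersect(rownames(train_expr), rownames(test_expr)))
  if (length(miss))
    stop("signature probesets missing from expression: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  tr <- train_expr[ids, , drop = FALSE]
  te <- test_expr[ids, , drop = FALSE]
  classes <- sort(unique(as.character(train_labels)))
  centroids <- vapply(classes,
                      function(cl) rowMeans(tr[, train_labels == cl, drop = FALSE]),
                      numeric(length(ids)))
  # squared Euclidean distance of each test column to each centroid
  d2 <- vapply(seq_along(classes),
               function(k) colSums((te - centroids[, k])^2),
               numeric(ncol(te)))
  d2 <- matrix(d2, nrow = ncol(te))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred == as.character(test_labels))
}

#' Derive a discriminative probeset signature by resampling
#'
#' For each of `n_resamples` random `fraction`/(1-`fraction`) splits of the
#' samples in the two conditions, runs a per-probeset t-test on the training
#' split, applies Benjamini-Hochberg FDR correction, and records the corrected
#' p-values; the held-out split is classified by nearest centroid on that
#' split's top-`k` probesets to estimate discrimination accuracy. Probesets
#' are finally ranked by the arithmetic mean corrected p-value across
#' resamplings (ties broken by larger mean |t|, then probeset id) and the top
#' `k` form the signature.
#'
#' @param expr expression matrix (probesets x samples).
#' @param design design data.frame (see [resample_split()]).
#' @param condition_pair character(2); contrast is `pair[2]` versus `pair[1]`.
#' @param k signature size (default 100).
#' @param n_resamples number of random splits (default 200).
#' @param fraction training fraction (default 0.9).
#' @param seed integer seed controlling all splits.
#' @param paired use a paired t-test on cell lines present in both conditions
#'   within the training split, instead of the unpaired Welch test.
#' @return list with `signature` (a [gene_signature()]) and `summary`
#'   (class `resampling_summary`: per-probeset `mean_q`, `mean_abs_t`,
#'   `n_resamples`, `split_fraction`, `per_resample_accuracy`,
#'   `mean_accuracy`).
#' @export
derive_signature <- function(expr, design, condition_pair = c("normoxia", "cychyp"),
                             k = 100, n_resamples = 200, fraction = 0.9,
                             seed = NULL, paired = FALSE) {
  k <- check_count(k, "k")
  n_resamples <- check_count(n_resamples, "n_resamples")
  if (k > nrow(expr)) stop("k must be <= number of probesets")
  keep <- design$condition %in% condition_pair
  design2 <- design[keep, , drop = FALSE]
  expr2 <- expr[, design2$sample_id, drop = FALSE]
  cond <- stats::setNames(design2$condition, design2$sample_id)
  line <- stats::setNames(design2$cell_line, design2$sample_id)

  if (!is.null(seed)) set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max, n_resamples)

  probes <- rownames(expr2)
  q_sum <- stats::setNames(numeric(length(probes)), probes)
  abst_sum <- q_sum
  acc <- numeric(n_resamples)

  for (r in seq_len(n_resamples)) {
    sp <- resample_split(design2, condition_pair, fraction,
                         seed = split_seeds[r], min_per_condition = 2L)
    tr_lab <- factor(cond[sp$train], levels = condition_pair)
    if (paired) {
      dt <- paired_test(expr2[, sp$train, drop = FALSE], tr_lab, line[sp$train])
    } else {
      dt <- differential_test(expr2[, sp$train, drop = FALSE], tr_lab)
    }
    q <- fdr_adjust(dt$p)
    abs_t <- abs(dt$t)
    q_sum <- q_sum + q
    abst_sum <- abst_sum + ifelse(is.finite(abs_t), abs_t, .Machine$double.xmax)
    top_r <- probes[order(q, -abs_t, probes, method = "radix")][seq_len(k)]
    acc[r] <- holdout_accuracy(expr2[, sp$train, drop = FALSE], tr_lab,
                               expr2[, sp$test, drop = FALSE],
                               factor(cond[sp$test], levels = condition_pair),
                               top_r)
  }

  mean_q <- q_sum / n_resamples
  mean_abst <- abst_sum / n_resamples
  ord <- order(mean_q, -mean_abst, probes, method = "radix")
  sig <- gene_signature(probes[ord][seq_len(k)], platform = platform_of(expr),
                        scores = mean_q[ord][seq_len(k)])
  summary <- structure(list(mean_q = mean_q, mean_abs_t = mean_abst,
                            n_resamples = n_resamples,
                            split_fraction = fraction,
                            per_resample_accuracy = acc,
                            mean_accuracy = mean(acc),
                            condition_pair = condition_pair),
                       class = "resampling_summary")
  list(signature = sig, summary = summary)
}

# paired t-test on per-line condition differences (lines with both conditions
# in the split); falls back to Welch when fewer than 2 complete pairs remain
paired_test <- function(expr, labels, lines) {
  labels <- as.factor(labels)
  l1 <- levels(labels)[1L]; l2 <- levels(labels)[2L]
  common <- intersect(lines[labels == l1], lines[labels == l2])
  if (length(common) < 2L) return(differential_test(expr, labels))
  i1 <- match(common, ifelse(labels == l1, lines, NA))
  i2 <- match(common, ifelse(labels == l2, lines, NA))
  d <- expr[, i2, drop = FALSE] - expr[, i1, drop = FALSE]
  n <- length(common)
  md <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - md)^2) / (n - 1))
  tt <- md / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  degen <- sd_d == 0
  tt[degen & md == 0] <- 0; p[degen & md == 0] <- 1
  tt[degen & md != 0] <- sign(md)[degen & md != 0] * Inf
  p[degen & md != 0] <- 0
  data.frame(probeset_id = rownames(expr), t = tt, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expand a signature to all probesets under a mean-q threshold
#'
#' @param summary a `resampling_summary` from [derive_signature()].
#' @param q_threshold mean corrected p-value cutoff in (0, 1].
#' @return character vector of probeset ids with `mean_q < q_threshold`,
#'   sorted by ascending mean q.
#' @export
expand_signature <- function(summary, q_threshold) {
  if (!inherits(summary, "resampling_summary"))
    stop("`summary` must come from derive_signature()")
  if (q_threshold <= 0 || q_threshold > 1)
    stop("`q_threshold` must be in (0, 1]")
  q <- summary$mean_q
  sel <- if (q_threshold >= 1) q else q[q < q_threshold]
  names(sel)[order(sel, names(sel), method = "radix")]
}
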