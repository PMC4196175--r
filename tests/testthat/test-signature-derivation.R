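test_that("resample_split partitions at the requested fraction", {
  design <- data.frame(sample_id = paste0("s", 1:40),
                       condition = rep(c("normoxia", "cychyp"), each = 20),
                       cell_line = paste0("L", rep(1:20, 2)))
  sp <- resample_split(design, c("normoxia", "cychyp"), 0.9, seed = 1)
  expect_length(sp$train, 36L)
  expect_length(sp$test, 4L)
  expect_setequal(c(sp$train, sp$test), design$sample_id)

  small <- design[c(1:2, 21:22), ]
  sp2 <- resample_split(small, c("normoxia", "cychyp"), 0.5, seed = 2)
  expect_length(sp2$train, 2L)
  expect_length(sp2$test, 2L)

  expect_identical(resample_split(design, c("normoxia", "cychyp"), 0.9, seed = 5),
                   resample_split(design, c("normoxia", "cychyp"), 0.9, seed = 5))
  expect_error(resample_split(design[1:20, ], c("normoxia", "cychyp"), 0.9),
               "both conditions")
  expect_error(resample_split(design, c("normoxia", "cychyp"), 1.2), "fraction")
})

test_that("differential_test matches t.test and honours conventions", {
  set.seed(10)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- matrix(rnorm(8 * (n1 + n2)), nrow = 8,
                dimnames = list(paste0("p", 1:8), paste0("s", 1:(n1 + n2))))
    lab <- factor(rep(c("a", "b"), c(n1, n2)))
    dt <- differential_test(x, lab)
    for (i in c(1, 5, 8)) {
      tt <- stats::t.test(x[i, lab == "b"], x[i, lab == "a"])
      expect_equal(dt$t[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(dt$p[i], tt$p.value, tolerance = 1e-12)
    }
  }

  # near-separated groups are highly significant
  x <- rbind(p1 = c(0, 0.001, -0.001, 1, 1.001, 0.999))
  colnames(x) <- paste0("s", 1:6)
  dt <- differential_test(x, factor(rep(c("a", "b"), each = 3)))
  expect_lt(dt$p[1], 1e-3)
  expect_gt(dt$t[1], 0)  # sign follows mean(group2) - mean(group1)

  # identical constant groups: t = 0, p = 1 by convention
  x0 <- matrix(5, 2, 6, dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
  dt0 <- differential_test(x0, factor(rep(c("a", "b"), each = 3)))
  expect_equal(dt0$t, c(0, 0))
  expect_equal(dt0$p, c(1, 1))

  # permuting samples within groups leaves (t, p) unchanged
  set.seed(11)
  x <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  lab <- factor(rep(c("a", "b"), each = 5))
  perm <- c(sample(1:5), sample(6:10))
  expect_equal(differential_test(x, lab)[, c("t", "p")],
               differential_test(x[, perm], lab[perm])[, c("t", "p")],
               tolerance = 1e-12)

  expect_error(differential_test(x[, 1:6], factor(c("a", rep("b", 5)))),
               "at least 2")
})

test_that("fdr_adjust implements the BH step-up rule", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(12)
  for (r in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- fdr_adjust(p)
    expect_lt(max(abs(q - bf_bh(p))), 1e-12)
    expect_true(all(q >= p & q <= 1))
  }
})

test_that("nearest-centroid holdout classification behaves", {
  tr <- cbind(a1 = c(0, 0), a2 = c(0.2, -0.2), b1 = c(3, 3), b2 = c(2.8, 3.2))
  rownames(tr) <- c("p1", "p2")
  # test sample equal to a class centroid is classified into that class
  te <- cbind(t1 = c(0.1, -0.1), t2 = c(2.9, 3.1))
  rownames(te) <- rownames(tr)
  acc <- holdout_accuracy(tr, c("A", "A", "B", "B"), te, c("A", "B"),
                          c("p1", "p2"))
  expect_equal(acc, 1)
  expect_error(holdout_accuracy(tr, c("A", "A", "B", "B"),
                                te[, 0, drop = FALSE], character(0),
                                c("p1", "p2")), "empty test")
  expect_error(holdout_accuracy(tr, c("A", "A", "B", "B"), te, c("A", "B"),
                                c("p1", "zzz")), "missing")
})

test_that("label permutation drives holdout accuracy to chance", {
  set.seed(13)
  accs <- vapply(1:100, function(r) {
    x <- matrix(rnorm(20 * 24), 20, 24,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:24)))
    lab <- sample(rep(c("A", "B"), 12))
    holdout_accuracy(x[, 1:20], lab[1:20], x[, 21:24], lab[21:24],
                     paste0("p", 1:5))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * stats::sd(accs) / 10)
})

test_that("derive_signature ranks by mean corrected p with fixed tie-breaks", {
  ex <- tiny_experiment(seed = 20)
  d <- derive_signature(ex$expr, ex$design, c("normoxia", "cychyp"),
                        k = 12, n_resamples = 10, seed = 21)
  expect_s3_class(d$signature, "gene_signature")
  expect_equal(d$signature$size, 12L)
  expect_length(d$summary$per_resample_accuracy, 10L)
  expect_equal(d$summary$mean_accuracy, mean(d$summary$per_resample_accuracy))
  expect_true(all(d$summary$mean_q >= 0 & d$summary$mean_q <= 1))

  # determinism
  d2 <- derive_signature(ex$expr, ex$design, c("normoxia", "cychyp"),
                         k = 12, n_resamples = 10, seed = 21)
  expect_identical(d$signature$probeset_ids, d2$signature$probeset_ids)
  expect_identical(d$summary$per_resample_accuracy,
                   d2$summary$per_resample_accuracy)

  # row-order invariance of the ranking
  perm <- sample(nrow(ex$expr))
  exp_perm <- ex$expr[perm, ]
  attr(exp_perm, "platform") <- platform_of(ex$expr)
  class(exp_perm) <- class(ex$expr)
  d3 <- derive_signature(exp_perm, ex$design, c("normoxia", "cychyp"),
                         k = 12, n_resamples = 10, seed = 21)
  expect_identical(d$signature$probeset_ids, d3$signature$probeset_ids)
})

test_that("single-resample derivation reduces to the split's q ordering", {
  ex <- tiny_experiment(seed = 30)
  d <- derive_signature(ex$expr, ex$design, c("normoxia", "cychyp"),
                        k = 10, n_resamples = 1, fraction = 0.9, seed = 31)
  # recompute that split directly
  keep <- ex$design$condition %in% c("normoxia", "cychyp")
  design2 <- ex$design[keep, ]
  set.seed(31)
  s1 <- sample.int(.Machine$integer.max, 1)
  sp <- resample_split(design2, c("normoxia", "cychyp"), 0.9, seed = s1)
  dt <- differential_test(ex$expr[, sp$train],
                          factor(design2$condition[match(sp$train, design2$sample_id)],
                                 levels = c("normoxia", "cychyp")))
  q <- fdr_adjust(dt$p)
  ord <- order(q, -abs(dt$t), dt$probeset_id, method = "radix")
  expect_identical(d$signature$probeset_ids, dt$probeset_id[ord][1:10])
})

test_that("planted probesets are recovered and accuracy is near chance under the null", {
  ex <- gen_cell_line_experiment(n_lines = 10, n_probes = 500, n_planted = 25,
                                 overlap = 5, effect_size = 1, noise_sd = 0.5,
                                 seed = 40)
  d <- derive_signature(ex$expr, ex$design, c("normoxia", "cychyp"),
                        k = 25, n_resamples = 25, seed = 41)
  expect_gte(length(intersect(d$signature$probeset_ids, ex$truth$planted_cyc)),
             22L)
  expect_gt(d$summary$mean_accuracy, 0.9)

  # global null: held-out accuracy within 3 SE of 0.5 over 50 replicates
  accs <- vapply(1:50, function(r) {
    ex0 <- gen_cell_line_experiment(n_lines = 5, n_probes = 60, n_planted = 5,
                                    overlap = 1, effect_size = 0,
                                    seed = 100 + r)
    d0 <- derive_signature(ex0$expr, ex0$design, c("normoxia", "cychyp"),
                           k = 5, n_resamples = 4, seed = 200 + r)
    d0$summary$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * stats::sd(accs) / sqrt(50))
})

test_that("expand_signature thresholds the mean q profile", {
  ex <- tiny_experiment(seed = 50)
  d <- derive_signature(ex$expr, ex$design, c("normoxia", "cychyp"),
                        k = 12, n_resamples = 8, seed = 51)
  expect_setequal(expand_signature(d$summary, 1.0), rownames(ex$expr))
  expect_length(expand_signature(d$summary, min(d$summary$mean_q) / 2), 0L)
  expanded <- expand_signature(d$summary, 0.05)
  strong <- d$signature$probeset_ids[d$signature$scores < 0.05]
  expect_true(all(strong %in% expanded))
  # sorted ascending by mean q
  expect_false(is.unsorted(d$summary$mean_q[expanded]))
  expect_error(expand_signature(d$summary, 0), "q_threshold")
})
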