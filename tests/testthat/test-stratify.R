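make_flat_upt <- function(G, C, upt = NULL) {
  gene <- rep(seq_len(G), times = C)
  barcode <- rep(seq_len(C), each = G)
  data.frame(gene = gene, barcode = barcode,
             upt = if (is.null(upt)) rep(1, G * C) else upt)
}

test_that("coverage-resolution weights follow the stated arithmetic", {
  # uniform coverage, full representation: all weights exactly 1
  u <- make_flat_upt(4, 10)
  cl <- rep(c("a", "b"), each = 5)
  st <- count_stack(data.frame(gene = u$gene, barcode = u$barcode, umi = 1L),
                    gene_ids = as.character(1:4),
                    barcode_ids = as.character(1:10))
  rt <- representation_rates(st, cl)
  w <- observation_weights(u, rt, cl)
  expect_true(all(abs(w$w - 1) < 1e-12))

  # ablation: weights never depend on the cluster
  w0 <- observation_weights(u, rt, cl, use_representation = FALSE)
  byg <- tapply(w0$w, list(w0$gene, w0$cluster), mean)
  expect_true(all(abs(byg[, 1] - byg[, 2]) < 1e-12))

  # doubling a gene's coverage at equal CV doubles its weight (ratios are
  # preserved by the mean-1 normalisation)
  set.seed(3)
  noise <- exp(rnorm(10, 0, 0.2))
  u2 <- make_flat_upt(2, 10, upt = c(rbind(2 * noise, noise)))
  st2 <- count_stack(data.frame(gene = u2$gene, barcode = u2$barcode,
                                umi = 1L),
                     gene_ids = c("hi", "lo"),
                     barcode_ids = as.character(1:10))
  rt2 <- representation_rates(st2, cl)
  w2 <- observation_weights(u2, rt2, cl)
  expect_equal(mean(w2$w[w2$gene == 1]) / mean(w2$w[w2$gene == 2]), 2,
               tolerance = 1e-10)
})

test_that("weighted ANOVA reduces to the textbook F with unit weights", {
  set.seed(7)
  y <- rnorm(15)
  cls <- rep(c("a", "b", "c"), each = 5)
  l2 <- data.frame(gene = 1L, barcode = 1:15, log2fc = y)
  res <- weighted_anova(l2, cls)
  oracle <- anova(stats::lm(y ~ factor(cls)))
  expect_equal(res$f_stat, oracle[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p_anova, oracle[1, "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 12)

  # power: well-separated clusters are detected decisively
  y2 <- c(rnorm(30, 0, 0.5), rnorm(30, 3, 0.5))
  l2b <- data.frame(gene = 1L, barcode = 1:60, log2fc = y2)
  res2 <- weighted_anova(l2b, rep(c("a", "b"), each = 30))
  expect_lt(res2$p_anova, 1e-6)

  # untestable gene (one cluster only) gets p = 1
  res3 <- weighted_anova(data.frame(gene = 1L, barcode = 1:5,
                                    log2fc = rnorm(5)),
                         rep("a", 5))
  expect_equal(res3$p_anova, 1)
  expect_false(res3$testable)
})

test_that("weighted ANOVA p-values are uniform under the null", {
  set.seed(17)
  G <- 500; n <- 40
  l2 <- data.frame(gene = rep(seq_len(G), each = n),
                   barcode = rep(seq_len(n), times = G),
                   log2fc = rnorm(G * n))
  cls <- sample(rep(c("a", "b"), each = n / 2))
  res <- weighted_anova(l2, cls)
  ks <- stats::ks.test(res$p_anova, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric()), numeric())
  # a worked step-up case: p * m / rank with monotonicity enforcement
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_equal(bh_adjust(p), c(0.005, 0.02, 0.05125, 0.05125, 0.9))
})

test_that("tolerance-interval benchmark behaves like Howe's factor", {
  set.seed(23)
  r <- rnorm(1e5)
  b <- snr_benchmark(r)
  expect_lt(abs(b$ti_halfwidth / b$sd - qnorm(0.975)), 0.005 * qnorm(0.975))
  expect_equal(snr_benchmark(rep(0, 10))$ti_halfwidth, 0)
  b50 <- snr_benchmark(rnorm(50))
  expect_gt(b50$ti_halfwidth / b50$sd, qnorm(0.975))
  expect_error(snr_benchmark(c(1, 2)), "at least 3")
  # nonparametric variant: 97.5th percentile of |residuals|, which for
  # standard-normal residuals is the 0.9875 normal quantile
  bn <- snr_benchmark(r, method = "nonparametric")
  expect_lt(abs(bn$ti_halfwidth - qnorm(0.9875)), 0.05)
})

test_that("pairwise contrasts equal Welch's t and flag exclusivity", {
  set.seed(29)
  y <- c(rnorm(8, 0), rnorm(12, 1))
  cls <- rep(c("a", "b"), c(8, 12))
  l2 <- data.frame(gene = 1L, barcode = 1:20, log2fc = y)
  pw <- pairwise_contrasts(l2, cls)
  tt <- stats::t.test(y[1:8], y[9:20])
  expect_equal(pw$p, tt$p.value, tolerance = 1e-10)
  expect_equal(pw$delta, unname(diff(rev(tt$estimate))), tolerance = 1e-10)

  # identical clusters: no difference, not exclusive
  l3 <- data.frame(gene = 1L, barcode = 1:20, log2fc = rep(c(1, 2), 10))
  pw3 <- pairwise_contrasts(l3, rep(c("a", "b"), each = 10),
                            ti_halfwidth = 0.5)
  expect_lt(abs(pw3$delta), 1)
  expect_false(pw3$exclusive)

  # separation of 3 tolerance units with tight errors is exclusive
  ti <- 0.4
  y4 <- c(rnorm(30, 0, 0.05), rnorm(30, 3 * ti, 0.05))
  pw4 <- pairwise_contrasts(
    data.frame(gene = 1L, barcode = 1:60, log2fc = y4),
    rep(c("a", "b"), each = 30), ti_halfwidth = ti)
  expect_true(pw4$exclusive)
  expect_lt(pw4$q, 0.05)

  # singleton cluster cannot be contrasted
  pw5 <- pairwise_contrasts(
    data.frame(gene = 1L, barcode = 1:4, log2fc = c(1, 2, 3, 9)),
    c("a", "a", "a", "b"))
  expect_equal(pw5$p, 1)
})

test_that("representation test flags skewed presence and stays calibrated", {
  st <- count_stack(data.frame(gene = rep(1L, 10), barcode = 1:10, umi = 1L),
                    gene_ids = "g", barcode_ids = as.character(1:20))
  rt <- representation_rates(st, rep(c("a", "b"), each = 10))
  res <- representation_test(rt)
  expect_lt(res$p_rep, 1e-3)   # all expression in one cluster

  # fully-represented gene is untestable
  st2 <- count_stack(data.frame(gene = rep(1L, 20), barcode = 1:20, umi = 1L),
                     gene_ids = "g", barcode_ids = as.character(1:20))
  rt2 <- representation_rates(st2, rep(c("a", "b"), each = 10))
  expect_equal(representation_test(rt2)$p_rep, 1)

  # calibration under a binomial null
  set.seed(37)
  G <- 400; C <- 100
  m <- matrix(rbinom(G * C, 1, 0.3), G, C)
  nz <- which(m > 0, arr.ind = TRUE)
  st3 <- count_stack(data.frame(gene = nz[, 1], barcode = nz[, 2], umi = 1L),
                     gene_ids = as.character(1:G),
                     barcode_ids = as.character(1:C))
  rt3 <- representation_rates(st3, rep(c("a", "b"), each = 50))
  p <- representation_test(rt3)$p_rep
  expect_gt(mean(p), 0.4)
  expect_lt(mean(p), 0.6)
})

test_that("the strata ladder recovers planted signatures", {
  fx <- make_ladder_fixture(101)
  gs <- stratify_genes(fx$scores, fx$clusters, fx$stack)
  prof <- gs$strata$members$Profiler
  expect_gte(length(intersect(prof, fx$sig)), 45)
  expect_lte(length(setdiff(prof, fx$sig)), 5)
  # weak 1.2-fold genes are filtered by the SNR benchmark, not carried up
  expect_length(intersect(gs$strata$members$LSTNR, fx$weak), 0)

  # structural nesting of the ladder
  m <- gs$strata$members
  expect_true(all(m$Profiler %in% m$DEGREE))
  expect_true(all(m$DEGREE %in% m$DEG))
  expect_true(all(m$DEG %in% m$LSTNR))
  expect_true(all(m$LSTNR %in% m$SG))
  expect_true(all(diff(unname(gs$strata$counts)) <= 0))

  # Profiler is exactly DEGREE gated by the ablated q-value
  s <- gs$stats
  gate <- s$gene[s$q_unweighted <= 0.05]
  expect_setequal(m$Profiler, intersect(m$DEGREE, gate))

  # retained barcodes are the cells expressing a Profiler gene (here: all)
  expect_equal(gs$strata$retained_barcodes,
               seq_len(fx$stack$n_barcodes))
})

test_that("ladder degenerate and monotonicity contracts hold", {
  fx <- make_ladder_fixture(202, n_sig = 10, n_weak = 20, n_null = 50,
                            cells_per = 20)
  gs <- stratify_genes(fx$scores, fx$clusters, fx$stack)

  # alpha = 0 empties every stratum above facultative
  expect_warning(
    s0 <- stratify(gs$stats, gs$pairwise, gs$benchmark, alpha = 0,
                   stack = fx$stack),
    "empty SG")
  expect_true(all(unname(s0$counts[-1]) == 0))

  # raising alpha never shrinks a stratum
  s1 <- stratify(gs$stats, gs$pairwise, gs$benchmark, alpha = 0.01,
                 stack = fx$stack)
  s2 <- stratify(gs$stats, gs$pairwise, gs$benchmark, alpha = 0.05,
                 stack = fx$stack)
  for (nm in names(s1$members))
    expect_true(all(s1$members[[nm]] %in% s2$members[[nm]]))

  # a gene whose intervals overlap everywhere is excluded from DEG even
  # with a decisive ANOVA
  stats_df <- data.frame(gene = 1L, q_anova = 1e-6, q_unweighted = 1e-6,
                         max_abs_mean = 5)
  pw <- data.frame(gene = 1L, cluster_a = "a", cluster_b = "b",
                   delta = 0.5, p = 1e-6, q = 1e-6, exclusive = FALSE)
  bench <- structure(list(ti_halfwidth = 1), class = "snr_benchmark")
  s3 <- stratify(stats_df, pw, bench, alpha = 0.05)
  expect_equal(unname(s3$strata["1"]), "LSTNR")
})

test_that("null data yield false-discovery counts consistent with BH", {
  set.seed(53)
  sg_counts <- vapply(1:5, function(i) {
    fx <- make_ladder_fixture(300 + i, n_sig = 0, n_weak = 0, n_null = 400,
                              cells_per = 20)
    gs <- suppressWarnings(stratify_genes(fx$scores, fx$clusters, fx$stack))
    length(gs$strata$members$SG)
  }, numeric(1))
  expect_lte(stats::median(sg_counts), 0.05 * 400 * 1.5)
})
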