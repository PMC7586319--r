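# a small scored + clustered fixture shared by the display tests
report_fixture <- function(seed = 9) {
  fx <- make_ladder_fixture(seed, n_sig = 10, n_weak = 0, n_null = 20,
                            k = 4, cells_per = 15)
  emb <- truncated_svd(fx$scores$btheta, rank = 5, seed = seed)
  ca <- ward_cluster(emb, k = 4)
  list(fx = fx, majors = ca)
}

test_that("frosty specs mirror strata nesting and round-trip as JSON", {
  counts <- c(facultative = 3305, SG = 2519, LSTNR = 2519, DEG = 1244,
              DEGREE = 464, Profiler = 462)
  fs <- frosty_spec(counts, n_constitutive = 252, n_rare = 13077,
                    retained_fraction = 0.97)
  expect_equal(fs$head, 252)
  expect_equal(fs$base, 13077)
  expect_equal(fs$left_arm, 1.0)
  expect_true(all(diff(unlist(fs$body)) <= 0))

  dir <- withr::local_tempdir()
  out <- frosty_plot(fs, file.path(dir, "frosty.svg"))
  expect_true(file.exists(out$svg))
  back <- jsonlite::read_json(out$json, simplifyVector = TRUE)
  expect_equal(unlist(back$body), unlist(fs$body))
  expect_equal(back$right_arm, fs$right_arm)

  expect_error(frosty_spec(c(facultative = 10, SG = 20), 5, 5, 0.5),
               "non-increasing")
  expect_error(frosty_spec(counts, 252, 13077, 1.4), "retained_fraction")
})

test_that("knee plot data keep ranks, ties and contiguous regimes", {
  sim <- simulate_stack(small_cfg(19))
  gp <- total_coverage(sim$stack, "gene")
  dat <- knee_plot(gp)
  expect_true(all(diff(dat$total) <= 0))
  expect_equal(sum(unique(dat[, c("total", "n_tied")])$n_tied), nrow(dat))

  part <- structure(list(axis = "gene", lower_bound = 10, upper_bound = 500,
                         low_set = gp$index[gp$total < 10],
                         mid_set = gp$index[gp$total >= 10 & gp$total <= 500],
                         high_set = gp$index[gp$total > 500]),
                    class = "regime_partition")
  dir <- withr::local_tempdir()
  dat2 <- knee_plot(gp, part, file.path(dir, "knee.svg"))
  expect_true(file.exists(file.path(dir, "knee.svg")))
  # ranks are ordered by total, so regimes appear as contiguous blocks
  expect_equal(rle(dat2$regime)$values, c("high", "mid", "low"))

  empty <- structure(gp[0, ], axis = "gene", class = class(gp))
  expect_error(knee_plot(empty), "empty")
})

test_that("topograph composite scores rank majors as documented", {
  rf <- report_fixture()
  sc <- rf$fx$scores
  # gene 1 is a cluster-1 signature: quantile 1 in exactly one major
  tg <- topograph(sc, rf$majors, gene = 1L)
  expect_equal(max(tg$weighed_score, na.rm = TRUE), 1)
  expect_equal(min(tg$weighed_score, na.rm = TRUE), 0)
  best <- names(which.max(tg$weighed_score))
  expect_equal(unname(tg$composite[best]), max(tg$composite, na.rm = TRUE))

  # equal mean log2fc, rates 1.0 vs 0.1: the well-represented major wins
  sc2 <- structure(list(
    upt = data.frame(gene = 1L, barcode = 1:11, upt = 2),
    log2fc = data.frame(gene = 1L, barcode = 1:11, log2fc = 1),
    btheta = data.frame(gene = 1L, barcode = 1:11, btheta = 1),
    ref_mean = c("1" = 1), family = "gaussian_log", flagged = integer(),
    gene_ids = "g", barcode_ids = as.character(1:20),
    n_genes = 1L, n_barcodes = 20L), class = "score_set")
  lab2 <- stats::setNames(rep(1:2, each = 10), 1:20)
  maj2 <- structure(list(labels = lab2, stage = "major", k = 2,
                         layout2d = matrix(0, 20, 2,
                                           dimnames = list(1:20, NULL))),
                    class = "cluster_assignment")
  tg2 <- topograph(sc2, maj2, gene = 1L)
  expect_gt(tg2$weighed_score[["1"]], tg2$weighed_score[["2"]])

  expect_error(topograph(sc, rf$majors, gene = 99999L), "no expressing")
})

test_that("topograph trees agree with a textbook neighbor-joining oracle", {
  rf <- report_fixture()
  dir <- withr::local_tempdir()
  tg <- topograph(rf$fx$scores, rf$majors, gene = 1L,
                  file = file.path(dir, "topo.svg"))
  tree <- ape::read.tree(text = tg$tree)
  expect_equal(length(tree$tip.label), 4)
  # rebuild the centroid distances the same way and check the NJ pairing
  bt <- rf$fx$scores$btheta
  lab <- rf$majors$labels
  lev <- sort(unique(lab))
  M <- t(vapply(lev, function(m) {
    cells <- as.integer(names(lab)[lab == m])
    vapply(split(bt$btheta[bt$barcode %in% cells],
                 bt$gene[bt$barcode %in% cells]), mean, numeric(1))
  }, numeric(length(unique(bt$gene)))))
  D <- as.matrix(dist(M))
  rownames(D) <- colnames(D) <- as.character(lev)
  want <- nj_oracle_pairing(D)
  # the 4-taxon NJ newick is "(a,b,(c,d));": taxon 1 pairs either inside the
  # written cherry or with the other loose tip at the root trifurcation
  pp <- ape::prop.part(tree)
  cherry <- attr(pp, "labels")[pp[[length(pp)]]]
  t1 <- rownames(D)[1]
  got <- if (t1 %in% cherry) setdiff(cherry, t1)
         else setdiff(tree$tip.label, c(cherry, t1))
  expect_equal(got, want)
})

test_that("violin summaries reproduce direct quantiles and tiers", {
  rf <- report_fixture()
  dir <- withr::local_tempdir()
  st <- violin_summary(rf$fx$scores, rf$majors, genes = c(1L, 11L),
                       file = file.path(dir, "violin.svg"))
  expect_true(file.exists(file.path(dir, "violin.tsv")))
  lab <- rf$majors$labels
  l2 <- rf$fx$scores$log2fc
  g1m <- st[st$gene == 1 & st$major == names(which.max(table(lab))), ]
  y <- l2$log2fc[l2$gene == 1 &
                   lab[as.character(l2$barcode)] == g1m$major]
  expect_equal(g1m$n, length(y))
  expect_equal(g1m$median, stats::median(y))
  expect_equal(g1m$q25, stats::quantile(y, 0.25, names = FALSE))
  # tiers exist and high_rep implies high-level membership
  expect_true(all(st$tier %in% c("none", "high", "high_rep")))

  # a gene absent from a major is an n = 0 row
  sc <- rf$fx$scores
  sc$log2fc <- sc$log2fc[!(sc$log2fc$gene == 1 &
                             sc$log2fc$barcode %in% 1:15), ]
  st2 <- violin_summary(sc, rf$majors, genes = 1L)
  expect_true(any(st2$n == 0))
})
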