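toy_specimens <- function(seeds, G = 12, C = 8) {
  sts <- lapply(seeds, function(s) rand_stack(s, G = G, C = C, density = 0.5))
  names(sts) <- paste0("sp", seq_along(sts))
  sts
}

test_that("consensus selection implements the round-intersection rule", {
  des <- replicate_design(paste0("sp", 1:7),
                          c("d1", "d2", "d2", "d3", "d3", "d3", "d4"))
  fac <- list(sp1 = c("A", "B", "C"),
              sp2 = c("A", "B"), sp3 = c("A", "B", "D"),
              sp4 = c("A", "C"), sp5 = c("A", "C"), sp6 = c("A", "B", "C"),
              sp7 = c("B", "C"))
  cons <- consensus_facultative(fac, des)
  # A is batch-consistent on d1, d2, d3 (3 of 4 rounds) -> included at 0.75
  expect_true("A" %in% cons$consensus_genes)
  # B fails d3 (absent from sp4, sp5): only 3 rounds... d1 yes, d2 yes, d4 yes
  expect_true("B" %in% cons$consensus_genes)
  # C fails d2 entirely: rounds d1, d3, d4 -> 3 of 4, included
  expect_true("C" %in% cons$consensus_genes)
  # D is facultative in only one specimen of d2: not batch-consistent anywhere
  expect_false("D" %in% cons$consensus_genes)

  # at min_round_fraction = 1 a gene must hold in every round: only none do
  des_all <- replicate_design(paste0("sp", 1:7),
                              c("d1", "d2", "d2", "d3", "d3", "d3", "d4"),
                              min_round_fraction = 1)
  expect_error(consensus_facultative(fac, des_all), "empty consensus")

  # intersection semantics: facultative in 2 of 3 specimens of a round
  # does not make the round batch-consistent
  expect_false("D" %in% cons$batch_consistent$d2)
})

test_that("consensus equals a brute-force set-algebra oracle", {
  set.seed(67)
  genes <- LETTERS[1:15]
  for (rep_ in 1:5) {
    n_spec <- sample(3:6, 1)
    rounds <- sample(paste0("r", 1:3), n_spec, replace = TRUE)
    # ensure every round label used is non-empty by construction
    des <- replicate_design(paste0("s", 1:n_spec), rounds)
    fac <- lapply(1:n_spec, function(i) sample(genes, sample(5:12, 1)))
    names(fac) <- paste0("s", 1:n_spec)
    need <- ceiling(0.75 * length(unique(rounds)))
    oracle <- Filter(function(g) {
      ok <- vapply(unique(rounds), function(r) {
        all(vapply(which(rounds == r), function(i) g %in% fac[[i]],
                   logical(1)))
      }, logical(1))
      sum(ok) >= need
    }, genes)
    got <- tryCatch(consensus_facultative(fac, des)$consensus_genes,
                    error = function(e) character())
    expect_setequal(got, oracle)
  }
})

test_that("per-specimen focusing is independent and deterministic", {
  sim1 <- simulate_stack(small_cfg(5))
  sts <- list(a = sim1$stack, b = sim1$stack)   # identical duplicates
  des <- replicate_design(c("a", "b"), c("r1", "r1"))
  res <- per_specimen_focus(sts, des, axes = "gene", seed = 10,
                            n_cutoffs = 15)
  # identical inputs with identical derived seeds give identical partitions
  pa <- res$a$gene$partition; pb <- res$b$gene$partition
  expect_equal(pa$lower_bound, pb$lower_bound)
  expect_equal(pa$upper_bound, pb$upper_bound)
  expect_equal(pa$mid_set, pb$mid_set)
})

test_that("integration namespaces barcodes and respects filters", {
  sts <- toy_specimens(c(1, 2))
  cons <- as.character(sts$sp1$gene_ids)   # same dictionary in both
  intg <- assemble_integrated(sts, cons)
  expect_equal(intg$n_barcodes, sts$sp1$n_barcodes + sts$sp2$n_barcodes)
  expect_true(all(grepl("^sp[12]:", intg$barcode_ids)))
  sm <- attr(intg, "specimen_map")
  expect_equal(unname(table(sm)[c("sp1", "sp2")]),
               c(sts$sp1$n_barcodes, sts$sp2$n_barcodes),
               ignore_attr = TRUE)

  # occupancy equals the dense-oracle count over the union
  m1 <- dense_from_stack(sts$sp1); m2 <- dense_from_stack(sts$sp2)
  gk <- match(intg$gene_ids, as.character(sts$sp1$gene_ids))
  expect_equal(nrow(intg$entries),
               sum(m1[gk, ] > 0) + sum(m2[gk, ] > 0))

  # a gene absent from one specimen is excluded by the replicated filter
  e2 <- sts$sp2$entries
  drop_gene <- e2$gene[1]
  sts2 <- sts
  sts2$sp2 <- count_stack(e2[e2$gene != drop_gene, ],
                          sts$sp2$gene_ids, sts$sp2$barcode_ids)
  intg2 <- assemble_integrated(sts2, cons)
  expect_false(as.character(sts$sp2$gene_ids)[drop_gene] %in% intg2$gene_ids)

  # singlet restriction and per-specimen denominators
  singlets <- list(sp1 = 1:4, sp2 = 3:8)
  intg3 <- assemble_integrated(sts, cons, per_specimen_singlets = singlets)
  expect_equal(intg3$n_barcodes, 4 + 6)
  den <- attr(intg3, "denominators")
  expect_equal(unname(den["sp1:c001"]), unname(barcode_totals(sts$sp1)[1]))

  expect_error(assemble_integrated(sts, c("not-a-gene")), "namespace")
})

test_that("post-stratification retention counts and coverage medians", {
  sts <- toy_specimens(c(3, 4))
  cons <- as.character(sts$sp1$gene_ids)
  intg <- assemble_integrated(sts, cons)
  prof <- match(cons[1:3], intg$gene_ids)
  ret <- post_stratification_retention(intg, prof)
  # brute force per barcode
  e <- intg$entries
  expressed <- sort(unique(e$barcode[e$gene %in% prof]))
  expect_equal(ret$retained_barcodes, expressed)
  expect_equal(sum(ret$per_specimen$n_retained), length(expressed))
  # all cells retained when every cell expresses a Profiler gene
  all_prof <- seq_along(intg$gene_ids)
  ret2 <- post_stratification_retention(intg, all_prof)
  expect_equal(ret2$overall_rate, 1)

  # multiplet-like cells: high totals, profiler-poor -> dropped group has
  # larger median coverage than the retained group
  G <- 10
  ent <- rbind(
    data.frame(gene = 1L, barcode = 1:8, umi = 2L),            # retained
    data.frame(gene = rep(2:G, each = 4), barcode = rep(9:12, G - 1),
               umi = 30L))                                     # dropped
  st <- count_stack(ent, gene_ids = as.character(1:G),
                    barcode_ids = as.character(1:12))
  ret3 <- post_stratification_retention(st, 1L)
  expect_gt(ret3$per_specimen$median_total_dropped,
            ret3$per_specimen$median_total_retained)
})
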