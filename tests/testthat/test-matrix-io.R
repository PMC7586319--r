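test_that("hand-written MTX triplets parse exactly, with duplicates summed", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "% a comment",
               "3 2 5",
               "1 1 4", "2 1 1", "3 2 2", "1 2 1",
               "1 1 3"),             # duplicate coordinate: summed
             file.path(dir, "matrix.mtx"))
  writeLines(c("ENSG01\tA", "ENSG02\tB", "ENSG03\tC"),
             file.path(dir, "genes.tsv"))
  writeLines(c("AAAC-1", "TTTG-1"), file.path(dir, "barcodes.tsv"))
  st <- read_mtx_triplets(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "barcodes.tsv"))
  expect_equal(st$n_genes, 3)
  expect_equal(st$n_barcodes, 2)
  expect_equal(nrow(st$entries), 4)          # 5 lines, one duplicate merged
  expect_equal(total_umi(st), 4 + 1 + 2 + 1 + 3)
  e <- st$entries[order(st$entries$gene, st$entries$barcode), ]
  expect_equal(e$umi[e$gene == 1 & e$barcode == 1], 7L)
  expect_equal(attr(st$gene_ids, "symbol"), c("A", "B", "C"))
  expect_equal(st$barcode_ids, c("AAAC-1", "TTTG-1"))

  # gzip-transparent reading gives the same stack
  gz <- file.path(dir, "matrix.mtx.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(file.path(dir, "matrix.mtx")), con)
  close(con)
  st2 <- read_mtx_triplets(gz, file.path(dir, "genes.tsv"),
                           file.path(dir, "barcodes.tsv"))
  expect_equal(st2$entries, st$entries)
})

test_that("empty and malformed matrices are handled per contract", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "5 4 0"),
             file.path(dir, "m.mtx"))
  writeLines(sprintf("g%d", 1:5), file.path(dir, "g.tsv"))
  writeLines(sprintf("b%d", 1:4), file.path(dir, "b.tsv"))
  st <- read_mtx_triplets(file.path(dir, "m.mtx"), file.path(dir, "g.tsv"),
                          file.path(dir, "b.tsv"))
  expect_equal(nrow(st$entries), 0)
  expect_equal(st$n_genes, 5)
  expect_equal(st$n_barcodes, 4)

  # axis-dictionary length must match the header
  writeLines(sprintf("g%d", 1:3), file.path(dir, "g3.tsv"))
  expect_error(read_mtx_triplets(file.path(dir, "m.mtx"),
                                 file.path(dir, "g3.tsv"),
                                 file.path(dir, "b.tsv")),
               "declares")

  writeLines(c("%%MatrixMarket matrix coordinate real general", "2 2 1",
               "1 1 -3"), file.path(dir, "neg.mtx"))
  writeLines(sprintf("g%d", 1:2), file.path(dir, "g2.tsv"))
  writeLines(sprintf("b%d", 1:2), file.path(dir, "b2.tsv"))
  expect_error(read_mtx_triplets(file.path(dir, "neg.mtx"),
                                 file.path(dir, "g2.tsv"),
                                 file.path(dir, "b2.tsv")), "negative")

  writeLines(c("%%MatrixMarket matrix coordinate real general", "2 2 1",
               "1 1 2.5"), file.path(dir, "frac.mtx"))
  expect_error(read_mtx_triplets(file.path(dir, "frac.mtx"),
                                 file.path(dir, "g2.tsv"),
                                 file.path(dir, "b2.tsv")), "non-integer")
})

test_that("sparsity profile agrees with a dense-matrix oracle", {
  # degenerate single-field matrix: one 7-valued entry fills the span
  one <- count_stack(data.frame(gene = 1L, barcode = 1L, umi = 7L), "g", "b")
  sp1 <- sparsity_profile(one)
  expect_equal(sp1$span, 1)
  expect_equal(sp1$occupancy, 1)
  expect_equal(unname(sp1$value_composition["4+"]), 1)

  for (seed in 1:5) {
    st <- rand_stack(seed, G = sample(5:30, 1), C = sample(5:30, 1))
    sp <- sparsity_profile(st)
    m <- dense_from_stack(st)
    expect_equal(sp$span, length(m))
    expect_equal(sp$n_positive, sum(m > 0))
    expect_equal(sp$occupancy, sum(m > 0) / length(m))
    expect_equal(sp$total_umi, sum(m))
    expect_equal(unname(sp$value_composition),
                 c(sum(m == 1), sum(m == 2), sum(m == 3), sum(m >= 4)) /
                   sum(m > 0))
    expect_equal(sp$genes_with_1valued, sum(apply(m == 1, 1, any)))
    expect_equal(sp$genes_with_4plus, sum(apply(m >= 4, 1, any)))
    expect_equal(sum(sp$value_composition), 1, tolerance = 1e-12)
  }
})

test_that("block reports match dense counts and partition to the stack", {
  st <- rand_stack(42, G = 10, C = 10, density = 0.4)
  m <- dense_from_stack(st)
  sp <- sparsity_profile(st)

  full <- block_report(st, label = "identity")
  expect_equal(full$pct_matrix, sp$occupancy)
  expect_equal(full$pct_stack, 1)

  gsub_ <- c(2L, 5L, 7L)
  br <- block_report(st, gene_subset = gsub_, label = "three")
  expect_equal(br$n_fields, sum(m[gsub_, ] > 0))
  expect_equal(br$block_span, 3 * 10)
  expect_equal(br$pct_block_span, sum(m[gsub_, ] > 0) / 30)

  # a partition of the gene axis accounts for every non-zero field
  parts <- split(1:10, rep(1:3, length.out = 10))
  tot <- sum(vapply(parts, function(g)
    block_report(st, gene_subset = g)$n_fields, numeric(1)))
  expect_equal(tot, sp$n_positive)

  expect_error(block_report(st, gene_subset = integer()), "empty block")
})

test_that("stacks and reports survive a write/read round-trip", {
  dir <- withr::local_tempdir()
  st <- rand_stack(7, G = 12, C = 9)
  paths <- write_stack(st, file.path(dir, "out"))
  st2 <- read_mtx_triplets(paths[1], paths[2], paths[3])
  o1 <- st$entries[order(st$entries$gene, st$entries$barcode), ]
  o2 <- st2$entries[order(st2$entries$gene, st2$entries$barcode), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(as.character(st2$gene_ids), as.character(st$gene_ids))
  expect_equal(st2$barcode_ids, st$barcode_ids)

  sp <- sparsity_profile(st)
  f <- write_report(sp, file.path(dir, "sp.tsv"))
  re <- utils::read.delim(f)
  expect_equal(re$value[re$key == "occupancy"], sp$occupancy)
  expect_equal(re$value[re$key == "n_positive"], sp$n_positive)

  blocks <- lapply(1:3, function(i)
    block_report(st, gene_subset = ((i - 1) * 4 + 1):(i * 4),
                 label = paste0("s", i)))
  f2 <- write_report(blocks, file.path(dir, "blocks.tsv"))
  rb <- utils::read.delim(f2)
  expect_equal(nrow(rb), 3)
  expect_equal(rb$pct_block_span,
               vapply(blocks, `[[`, numeric(1), "pct_block_span"))
})
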