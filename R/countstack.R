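#' Zero-free UMI count stack
#'
#' A `count_stack` is the package's only representation of expression data:
#' a triplet stack of strictly positive, deduplicated UMI tallies
#' (gene index, barcode index, count) together with the axis dictionaries.
#' Zeros are never materialised; absence of a (gene, barcode) pair *is* the
#' zero.
#'
#' @param entries data.frame with integer columns `gene`, `barcode`, `umi`
#'   (1-based indices, `umi > 0`). Duplicate (gene, barcode) pairs are an
#'   error; sum them upstream.
#' @param gene_ids character vector of gene identifiers (optionally with a
#'   `symbol` attribute carrying a second annotation column).
#' @param barcode_ids character vector of barcode strings, kept verbatim.
#' @return An object of class `count_stack`.
#' @examples
#' st <- count_stack(data.frame(gene = c(1L, 2L), barcode = c(1L, 1L),
#'                              umi = c(3L, 1L)),
#'                   gene_ids = c("g1", "g2"), barcode_ids = "bc1")
#' total_umi(st)
#' @export
count_stack <- function(entries, gene_ids, barcode_ids) {
  stopifnot(is.data.frame(entries),
            all(c("gene", "barcode", "umi") %in% names(entries)))
  entries <- data.frame(gene = as.integer(entries$gene),
                        barcode = as.integer(entries$barcode),
                        umi = as.integer(entries$umi))
  n_genes <- length(gene_ids)
  n_barcodes <- length(barcode_ids)
  if (nrow(entries)) {
    if (any(entries$umi <= 0L)) stop("count stack entries must have umi > 0")
    if (any(entries$gene < 1L | entries$gene > n_genes))
      stop("gene index out of range")
    if (any(entries$barcode < 1L | entries$barcode > n_barcodes))
      stop("barcode index out of range")
    key <- (entries$gene - 1) * as.double(n_barcodes) + entries$barcode
    if (anyDuplicated(key)) stop("duplicate (gene, barcode) pairs in entries")
  }
  structure(list(entries = entries,
                 gene_ids = gene_ids,
                 barcode_ids = barcode_ids,
                 n_genes = n_genes,
                 n_barcodes = n_barcodes),
            class = "count_stack")
}

#' @export
print.count_stack <- function(x, ...) {
  cat(sprintf("count_stack: %d genes x %d barcodes, %d non-zero fields, %s total UMIs\n",
              x$n_genes, x$n_barcodes, nrow(x$entries),
              format(total_umi(x), big.mark = ",")))
  invisible(x)
}

#' Total UMIs in a stack
#' @param stack a `count_stack`.
#' @return Numeric scalar, the sum of all counts.
#' @export
total_umi <- function(stack) sum(as.double(stack$entries$umi))

#' Read a triplet-format (MatrixMarket + TSV) expression matrix
#'
#' Ingests the 10X-style on-disk dialect: a MatrixMarket coordinate integer
#' file (genes as rows, barcodes as columns, 1-based indices) plus a genes
#' TSV (id and optional symbol column; extra columns ignored) and a barcodes
#' TSV. Gzipped files (`.gz`) are read transparently. Duplicate coordinate
#' lines, which the MatrixMarket format permits, are summed -- matching the
#' aggregation semantics of UMI tallies.
#'
#' @param matrix_path path to `matrix.mtx[.gz]`.
#' @param genes_path path to `genes.tsv[.gz]` (or `features.tsv[.gz]`).
#' @param barcodes_path path to `barcodes.tsv[.gz]`.
#' @return A [count_stack()].
#' @export
read_mtx_triplets <- function(matrix_path, genes_path, barcodes_path) {
  mm <- .read_mm_coord(matrix_path)
  genes <- .read_axis_tsv(genes_path)
  barcodes <- .read_axis_tsv(barcodes_path)
  if (nrow(genes) != mm$nrow)
    stop(sprintf("genes TSV has %d rows but matrix header declares %d genes",
                 nrow(genes), mm$nrow))
  if (nrow(barcodes) != mm$ncol)
    stop(sprintf("barcodes TSV has %d rows but matrix header declares %d barcodes",
                 nrow(barcodes), mm$ncol))
  gene_ids <- genes[[1]]
  if (ncol(genes) >= 2) attr(gene_ids, "symbol") <- genes[[2]]
  count_stack(mm$entries, gene_ids, barcodes[[1]])
}

# MatrixMarket coordinate integer parser (header-validated, duplicates summed).
.read_mm_coord <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", header))
    stop("not a MatrixMarket coordinate file: ", path)
  if (grepl("complex|pattern", header))
    stop("unsupported MatrixMarket field type in ", path)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("missing size line in ", path)
    if (!startsWith(line, "%") && nzchar(trimws(line))) break
  }
  dims <- scan(text = line, quiet = TRUE)
  if (length(dims) != 3 || any(dims < 0) || any(dims != round(dims)))
    stop("malformed MatrixMarket size line in ", path)
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) %% 3 != 0) stop("truncated coordinate section in ", path)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  if (nrow(m) != dims[3])
    stop(sprintf("header declares %d entries but %d found in %s",
                 dims[3], nrow(m), path))
  if (nrow(m)) {
    if (any(m[, 3] != round(m[, 3])))
      stop("non-integer count values in ", path)
    if (any(m[, 3] < 0)) stop("negative count values in ", path)
    if (any(m[, 1] < 1 | m[, 1] > dims[1] | m[, 2] < 1 | m[, 2] > dims[2]))
      stop("coordinate indices out of declared bounds in ", path)
    # sum duplicate coordinates, drop explicit zeros
    key <- (m[, 1] - 1) * dims[2] + m[, 2]
    umi <- rowsum(m[, 3], group = key)
    ukey <- as.numeric(rownames(umi))
    gene <- as.integer(ukey %/% dims[2] + 1)
    barcode <- as.integer(ukey %% dims[2])
    barcode[barcode == 0L] <- as.integer(dims[2])
    gene[ukey %% dims[2] == 0] <- as.integer(ukey[ukey %% dims[2] == 0] %/% dims[2])
    keep <- umi[, 1] > 0
    entries <- data.frame(gene = gene[keep], barcode = barcode[keep],
                          umi = as.integer(umi[keep, 1]))
  } else {
    entries <- data.frame(gene = integer(), barcode = integer(), umi = integer())
  }
  list(nrow = as.integer(dims[1]), ncol = as.integer(dims[2]), entries = entries)
}

.read_axis_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  utils::read.delim(con, header = FALSE, colClasses = "character",
                    quote = "", comment.char = "")
}

#' Sparsity profile of a count stack
#'
#' Exact integer accounting of how the data-positive fields populate the
#' gene x barcode span: occupancy, total UMIs, and the composition of
#' non-zero values binned at 1, 2, 3 and 4-or-more counts (the "4+" bin is
#' `>= 4`).
#'
#' @param stack a [count_stack()].
#' @return An object of class `sparsity_report` with fields `span`,
#'   `n_positive`, `occupancy`, `total_umi`, `value_composition`,
#'   `genes_with_1valued`, `genes_with_4plus`.
#' @export
sparsity_profile <- function(stack) {
  e <- stack$entries
  span <- as.double(stack$n_genes) * stack$n_barcodes
  n_pos <- nrow(e)
  comp <- if (n_pos) {
    bins <- cut(e$umi, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
                labels = c("1", "2", "3", "4+"))
    as.numeric(table(bins)) / n_pos
  } else numeric(4)
  names(comp) <- c("1", "2", "3", "4+")
  structure(list(span = span,
                 n_positive = n_pos,
                 occupancy = if (span > 0) n_pos / span else 0,
                 total_umi = total_umi(stack),
                 value_composition = comp,
                 genes_with_1valued = length(unique(e$gene[e$umi == 1L])),
                 genes_with_4plus = length(unique(e$gene[e$umi >= 4L]))),
            class = "sparsity_report")
}

#' @export
print.sparsity_report <- function(x, ...) {
  cat(sprintf("sparsity_report: %s fields / %s span (occupancy %.2f%%), %s UMIs\n",
              format(x$n_positive, big.mark = ","),
              format(x$span, big.mark = ","), 100 * x$occupancy,
              format(x$total_umi, big.mark = ",")))
  cat("  value composition:",
      paste(sprintf("%s: %.1f%%", names(x$value_composition),
                    100 * x$value_composition), collapse = ", "), "\n")
  invisible(x)
}

#' Block accounting from pre-tallied counts
#'
#' Low-level constructor for the block report arithmetic: given a labelled
#' gene x barcode block and its field count, computes the block span and the
#' three percentages (of the full matrix span, of the full non-zero stack,
#' and occupancy within the block). [block_report()] derives the tallies
#' from a stack; this constructor accepts them directly, e.g. from a
#' published sparsity table.
#'
#' @param label block label.
#' @param block_genes,block_barcodes block dimensions.
#' @param n_fields number of data-positive fields inside the block.
#' @param full_span span of the complete matrix.
#' @param full_n_positive non-zero fields in the complete matrix.
#' @return An object of class `block_report`.
#' @export
block_stats <- function(label, block_genes, block_barcodes, n_fields,
                        full_span, full_n_positive) {
  if (block_genes < 1 || block_barcodes < 1)
    stop("empty block is undefined")
  block_span <- as.double(block_genes) * block_barcodes
  structure(list(block_label = label,
                 block_genes = as.integer(block_genes),
                 block_barcodes = as.integer(block_barcodes),
                 block_span = block_span,
                 n_fields = n_fields,
                 pct_matrix = n_fields / full_span,
                 pct_stack = if (full_n_positive > 0) n_fields / full_n_positive else NA_real_,
                 pct_block_span = n_fields / block_span),
            class = "block_report")
}

#' Sparsity accounting for a gene x barcode block
#'
#' @param stack a [count_stack()].
#' @param gene_subset,barcode_subset integer index vectors (subsets of the
#'   stack's axes); `NULL` means the full axis.
#' @param label block label for reporting.
#' @return A `block_report`; see [block_stats()].
#' @export
block_report <- function(stack, gene_subset = NULL, barcode_subset = NULL,
                         label = "block") {
  if (is.null(gene_subset)) gene_subset <- seq_len(stack$n_genes)
  if (is.null(barcode_subset)) barcode_subset <- seq_len(stack$n_barcodes)
  gene_subset <- unique(as.integer(gene_subset))
  barcode_subset <- unique(as.integer(barcode_subset))
  if (!length(gene_subset) || !length(barcode_subset))
    stop("empty block is undefined")
  if (any(gene_subset < 1L | gene_subset > stack$n_genes) ||
      any(barcode_subset < 1L | barcode_subset > stack$n_barcodes))
    stop("subset indices outside the stack's axes")
  e <- stack$entries
  inb <- e$gene %in% gene_subset & e$barcode %in% barcode_subset
  block_stats(label, length(gene_subset), length(barcode_subset),
              sum(inb),
              full_span = as.double(stack$n_genes) * stack$n_barcodes,
              full_n_positive = nrow(e))
}

#' @export
print.block_report <- function(x, ...) {
  cat(sprintf("block '%s' (%d x %d | %s): %s fields; %.1f%% matrix, %.1f%% stack, %.1f%% block span\n",
              x$block_label, x$block_genes, x$block_barcodes,
              format(x$block_span, big.mark = ","),
              format(x$n_fields, big.mark = ","),
              100 * x$pct_matrix, 100 * x$pct_stack, 100 * x$pct_block_span))
  invisible(x)
}

#' Write a count stack as MatrixMarket triplets plus axis TSVs
#'
#' @param stack a [count_stack()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the three file paths written
#'   (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`).
#' @export
write_stack <- function(stack, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  e <- stack$entries
  con <- file(paths[1], "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", stack$n_genes, stack$n_barcodes, nrow(e))),
             con)
  if (nrow(e)) {
    o <- order(e$barcode, e$gene)
    writeLines(sprintf("%d %d %d", e$gene[o], e$barcode[o], e$umi[o]), con)
  }
  close(con)
  sym <- attr(stack$gene_ids, "symbol")
  gtab <- if (is.null(sym)) data.frame(id = as.character(stack$gene_ids))
          else data.frame(id = as.character(stack$gene_ids), symbol = sym)
  utils::write.table(gtab, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(stack$barcode_ids), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Serialize sparsity / block reports as TSV
#'
#' Sparsity reports serialize to a two-column key/value TSV; a list of block
#' reports to one row per block. Fractions are written at full precision so
#' a re-parse reproduces them exactly.
#'
#' @param x a `sparsity_report`, a `block_report`, or a list of
#'   `block_report`s.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path) {
  if (inherits(x, "sparsity_report")) {
    df <- data.frame(
      key = c("span", "n_positive", "occupancy", "total_umi",
              paste0("composition_", names(x$value_composition)),
              "genes_with_1valued", "genes_with_4plus"),
      value = c(x$span, x$n_positive, x$occupancy, x$total_umi,
                unname(x$value_composition),
                x$genes_with_1valued, x$genes_with_4plus))
  } else {
    if (inherits(x, "block_report")) x <- list(x)
    df <- do.call(rbind, lapply(x, function(b)
      data.frame(block_label = b$block_label, block_genes = b$block_genes,
                 block_barcodes = b$block_barcodes, block_span = b$block_span,
                 n_fields = b$n_fields, pct_matrix = b$pct_matrix,
                 pct_stack = b$pct_stack, pct_block_span = b$pct_block_span)))
  }
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a stack to subsets of its axes
#'
#' Keeps only entries whose gene and barcode fall in the given subsets;
#' axis dictionaries are subset and indices remapped.
#'
#' @param stack a [count_stack()].
#' @param gene_subset,barcode_subset integer index vectors; `NULL` keeps the
#'   full axis.
#' @return A focused [count_stack()]. The mapping back to the parent axes is
#'   kept in attributes `parent_gene_index` / `parent_barcode_index`.
#' @export
focus_stack <- function(stack, gene_subset = NULL, barcode_subset = NULL) {
  gs <- if (is.null(gene_subset)) seq_len(stack$n_genes) else sort(unique(as.integer(gene_subset)))
  bs <- if (is.null(barcode_subset)) seq_len(stack$n_barcodes) else sort(unique(as.integer(barcode_subset)))
  e <- stack$entries
  keep <- e$gene %in% gs & e$barcode %in% bs
  gmap <- integer(stack$n_genes); gmap[gs] <- seq_along(gs)
  bmap <- integer(stack$n_barcodes); bmap[bs] <- seq_along(bs)
  out <- count_stack(data.frame(gene = gmap[e$gene[keep]],
                                barcode = bmap[e$barcode[keep]],
                                umi = e$umi[keep]),
                     gene_ids = stack$gene_ids[gs],
                     barcode_ids = stack$barcode_ids[bs])
  attr(out, "parent_gene_index") <- gs
  attr(out, "parent_barcode_index") <- bs
  out
}
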