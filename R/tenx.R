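#' Read a 10X-style filtered matrix directory
#'
#' Locates `matrix.mtx[.gz]`, `genes.tsv[.gz]` (or `features.tsv[.gz]`) and
#' `barcodes.tsv[.gz]` inside a directory and reads them with
#' [read_mtx_triplets()].
#'
#' @param dir directory containing the triplet files.
#' @return A [count_stack()].
#' @export
read_tenx_dir <- function(dir) {
  pick <- function(names) {
    for (n in names) {
      p <- file.path(dir, n)
      if (file.exists(p)) return(p)
    }
    stop("none of ", paste(names, collapse = ", "), " found in ", dir)
  }
  read_mtx_triplets(pick(c("matrix.mtx", "matrix.mtx.gz")),
                    pick(c("genes.tsv", "genes.tsv.gz",
                           "features.tsv", "features.tsv.gz")),
                    pick(c("barcodes.tsv", "barcodes.tsv.gz")))
}

#' Download the PBMC 3K filtered matrix
#'
#' Fetches the public 10X Genomics PBMC 3K filtered gene-barcode matrix
#' (~7 MB) used as the package's frozen validation dataset, unpacks it and
#' returns the matrix directory. Cached: an existing unpacked copy under
#' `dest_dir` is reused without network access.
#'
#' @param dest_dir cache directory (default
#'   `tools::R_user_dir("scfocus", "cache")`).
#' @return Path to the unpacked `filtered_gene_bc_matrices/hg19` directory.
#' @export
fetch_pbmc3k <- function(dest_dir = tools::R_user_dir("scfocus", "cache")) {
  target <- file.path(dest_dir, "filtered_gene_bc_matrices", "hg19")
  if (dir.exists(target)) return(target)
  dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
  url <- paste0("https://s3-us-west-2.amazonaws.com/10x.files/samples/cell/",
                "pbmc3k/pbmc3k_filtered_gene_bc_matrices.tar.gz")
  tar <- file.path(dest_dir, "pbmc3k_filtered_gene_bc_matrices.tar.gz")
  utils::download.file(url, tar, mode = "wb", quiet = TRUE)
  utils::untar(tar, exdir = dest_dir)
  if (!dir.exists(target)) stop("unexpected archive layout after unpacking")
  target
}
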