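#' Truncated SVD of the score stack
#'
#' Latent embedding of cells from the gene-centered linear-predictor
#' matrix. The triplet stack is held as a sparse matrix (absent entries act
#' as structural zeros in the linear operator; nothing is materialised) and
#' factorised with an implicitly restarted Lanczos bidiagonalization
#' (irlba); gene centering (each gene's mean score over its expressing
#' cells) is applied as an implicit rank-1 update so sparsity is preserved.
#' Small or full-rank problems fall back to a dense LAPACK SVD, which is
#' also the oracle the sparse path is tested against.
#'
#' @param btheta data.frame `gene`, `barcode`, `btheta` (e.g.
#'   `score_set$btheta`), or a `score_set`.
#' @param rank number of components; default `min(50, min(dims) - 1)`.
#' @param seed integer seed for the Lanczos starting vector.
#' @param center apply gene centering (default `TRUE`): each gene's mean
#'   score over *all* cells (absences counting as zero) is subtracted
#'   implicitly, so every gene column has exactly zero mean and the
#'   leading component is not a library-intensity artefact.
#' @return An object of class `latent_embedding`: `coords` (cells x rank,
#'   right singular vectors scaled by singular values; rownames are barcode
#'   axis indices), `d` (non-increasing singular values), `explained`
#'   (per-component fraction of total centered variance), `gene_index`,
#'   `barcode_index` (axis indices of the rows/columns used).
#' @export
truncated_svd <- function(btheta, rank = NULL, seed = NULL, center = TRUE) {
  if (inherits(btheta, "score_set")) btheta <- btheta$btheta
  genes <- sort(unique(btheta$gene))
  cells <- sort(unique(btheta$barcode))
  gi <- match(btheta$gene, genes)
  ci <- match(btheta$barcode, cells)
  # cells x genes, so cell coordinates come out of the left factor
  A <- Matrix::sparseMatrix(i = ci, j = gi, x = btheta$btheta,
                            dims = c(length(cells), length(genes)))
  dims <- dim(A)
  if (is.null(rank)) rank <- min(50L, min(dims) - 1L)
  if (rank < 1 || rank > min(dims))
    stop("rank must lie in [1, min(n_genes, n_barcodes)]")
  ctr <- if (center) as.numeric(Matrix::colSums(A)) / nrow(A)
         else numeric(length(genes))
  # total centered Frobenius norm, computable from the stack alone
  fro2 <- sum((btheta$btheta - ctr[gi])^2) +
    sum(ctr^2 * (nrow(A) - tabulate(gi, nbins = length(genes))))
  if (rank >= min(dims) - 1L || min(dims) <= 10L) {
    Ad <- as.matrix(A)
    if (center) Ad <- sweep(Ad, 2, ctr)
    sv <- svd(Ad, nu = rank, nv = 0)
    u <- sv$u
    d <- sv$d[seq_len(rank)]
  } else {
    if (!is.null(seed)) set.seed(seed)
    sv <- irlba::irlba(A, nv = rank, center = if (center) ctr else NULL,
                       tol = 1e-10, maxit = 1000)
    u <- sv$u
    d <- sv$d
  }
  # deterministic sign: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(u))) {
    if (u[which.max(abs(u[, j])), j] < 0) u[, j] <- -u[, j]
  }
  coords <- u %*% diag(d, nrow = length(d))
  rownames(coords) <- cells
  structure(list(coords = coords, d = d,
                 explained = d^2 / max(fro2, .Machine$double.eps),
                 gene_index = genes, barcode_index = cells),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("latent_embedding: %d cells x %d components (%.1f%% variance)\n",
              nrow(x$coords), length(x$d), 100 * sum(x$explained)))
  invisible(x)
}

#' Ward-linkage hierarchical clustering in latent space
#'
#' Agglomerative clustering of cells with Ward's minimum-variance criterion
#' on Euclidean distances between latent coordinates (`hclust` method
#' `"ward.D2"`). Deterministic for a fixed input; no cells are dropped.
#'
#' @param embedding a [truncated_svd()] embedding.
#' @param k number of clusters (>= 2), or `NULL` to cut at `height`.
#' @param height dendrogram cut height, used when `k` is `NULL`.
#' @param stage label for the assignment stage
#'   (`"prospective"`, `"major"`, `"final"`).
#' @return An object of class `cluster_assignment`: `labels` (integer
#'   vector named by barcode axis index), `stage`, `k`, `linkage_height`
#'   (height of the last merge kept), `layout2d` (first two latent
#'   components), and the `hclust` tree in `$hc`.
#' @export
ward_cluster <- function(embedding, k = NULL, height = NULL,
                         stage = "prospective") {
  n <- nrow(embedding$coords)
  if (is.null(k) && is.null(height)) stop("give k or a cut height")
  if (!is.null(k) && (k < 2 || k > n)) stop("k must lie in [2, n cells]")
  hc <- stats::hclust(stats::dist(embedding$coords), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k)
            else stats::cutree(hc, h = height)
  k_eff <- length(unique(labels))
  lh <- if (k_eff < n) hc$height[n - k_eff] else 0
  structure(list(labels = stats::setNames(as.integer(labels),
                                          rownames(embedding$coords)),
                 stage = stage, k = k_eff, linkage_height = lh,
                 layout2d = embedding$coords[, seq_len(min(2, ncol(embedding$coords))),
                                             drop = FALSE],
                 hc = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d cells in %d clusters\n",
              x$stage, length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}

#' Choose the number of clusters by mean silhouette
#'
#' Cuts the Ward tree at each candidate `k` and returns the `k` with the
#' highest mean silhouette width; near-ties (within 0.01 of the best) break
#' towards the smallest `k`. A flat silhouette profile -- spread below 30%
#' of its peak, which is what unstructured data produce -- carries no
#' cluster-count signal and yields the range minimum. This is the package's
#' default stand-in selection rule; a user-supplied `k` always overrides it
#' downstream.
#'
#' @param embedding a [truncated_svd()] embedding.
#' @param k_range candidate cluster counts (default `2:10`).
#' @return The selected `k` (integer), with the per-`k` mean silhouettes in
#'   attribute `"silhouette"`.
#' @export
choose_k <- function(embedding, k_range = 2:10) {
  if (!length(k_range)) stop("empty k_range")
  n <- nrow(embedding$coords)
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (!length(k_range)) stop("no feasible k in range")
  d <- stats::dist(embedding$coords)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    if (length(unique(lab)) < 2) return(-Inf)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  flat <- max(sil) <= 0 || (max(sil) - min(sil)) < 0.3 * max(sil)
  k <- if (flat) min(k_range) else k_range[which(sil >= max(sil) - 0.01)[1]]
  attr(k, "silhouette") <- stats::setNames(sil, k_range)
  k
}

#' Refine clusters on a gene subset
#'
#' Re-embeds and re-clusters cells using only the score entries of a
#' restricted gene set (LSTNR genes for the "major" stage, Profiler genes
#' for the "final" stage). Cells with no remaining entry are dropped and
#' reported in attribute `"dropped"`.
#'
#' @param scores a [score_set()].
#' @param gene_subset gene axis indices to keep (non-empty).
#' @param k cluster count; `NULL` selects by [choose_k()] over `k_range`.
#' @param k_range candidate range for automatic selection.
#' @param rank,seed,center passed to [truncated_svd()].
#' @param stage stage label (default `"major"`).
#' @return A `cluster_assignment` (see [ward_cluster()]) with the embedding
#'   in attribute `"embedding"` and dropped barcode indices in `"dropped"`.
#' @export
refine_majors <- function(scores, gene_subset, k = NULL, k_range = 2:10,
                          rank = NULL, seed = NULL, center = TRUE,
                          stage = "major") {
  if (!length(gene_subset)) stop("empty gene subset")
  bt <- scores$btheta[scores$btheta$gene %in% gene_subset, ]
  if (!nrow(bt)) stop("all cells dropped: no score entries in the gene subset")
  all_cells <- sort(unique(scores$btheta$barcode))
  kept <- sort(unique(bt$barcode))
  dims <- c(length(unique(bt$gene)), length(kept))
  if (!is.null(rank)) rank <- max(1L, min(rank, min(dims) - 1L))
  emb <- truncated_svd(bt, rank = rank, seed = seed, center = center)
  if (is.null(k)) k <- choose_k(emb, k_range)
  out <- ward_cluster(emb, k = k, stage = stage)
  attr(out, "embedding") <- emb
  attr(out, "dropped") <- setdiff(all_cells, kept)
  out
}
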