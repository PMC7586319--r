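#' Synthetic-fixture simulation configuration
#'
#' Parameters of the seeded gamma-Poisson generator used throughout the
#' test suite. The defaults emulate the structure of droplet scRNA-seq
#' matrices that the workflow targets: power-law-like spread of per-gene
#' coverages in three regimes (rare / facultative / constitutive), planted
#' cell types carried by type-specific facultative signature genes,
#' heavy-tailed per-cell depths, and a near-unary count composition (well
#' over 65% of non-zero entries equal to 1).
#'
#' @param n_cell_types number of planted cell types (default 5).
#' @param cells_per_type singlet cells per type (default 200).
#' @param n_signature_genes_per_type facultative signature genes exclusive
#'   to each type (default 25, of the order of the marker-panel sizes that
#'   separate real cell types).
#' @param n_constitutive,n_rare,n_null_facultative sizes of the
#'   housekeeping, artifact-like and non-DE facultative gene pools
#'   (defaults 40, 2400, 2500).
#' @param signature_fold rate elevation of a signature gene in its own type
#'   over its base rate (default 36, the order of enrichment canonical
#'   markers such as LYZ or CD3D show between their own and other cell
#'   types).
#' @param signature_leakage expression of a signature gene outside its own
#'   type, as a fraction of its base rate (default 0.25: markers are
#'   strongly enriched, not absolutely private -- which is what real
#'   cell-type markers look like and what value-level differential tests
#'   can measure; set to 0 for presence-only markers).
#' @param type_effect_sd log-scale standard deviation of graded per-type
#'   expression effects applied to every non-signature facultative gene
#'   (default 0.4): real cell types differ gradely in most facultative
#'   genes, not only in their markers.
#' @param depth_mean mean library size in UMIs per singlet (default 1500).
#' @param depth_shape heavy-tail control of the lognormal depth law; the
#'   log-scale standard deviation is `1/sqrt(depth_shape)` (default 8).
#' @param ambient_barcodes number of ambient (debris) barcodes (default 0).
#' @param ambient_depth_fraction ambient depth relative to `depth_mean`
#'   (default 0.05).
#' @param doublet_fraction fraction of additional multi-cell barcodes, each
#'   the sum of two random singlets (default 0).
#' @param dispersion gamma overdispersion shape of the per-entry rate noise
#'   (default 3; smaller is noisier).
#' @param seed integer seed (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cell_types = 5, cells_per_type = 200,
                       n_signature_genes_per_type = 25,
                       n_constitutive = 40, n_rare = 2400,
                       n_null_facultative = 2500,
                       signature_fold = 36, signature_leakage = 0.25,
                       type_effect_sd = 0.4, depth_mean = 1500,
                       depth_shape = 8, ambient_barcodes = 0,
                       ambient_depth_fraction = 0.05,
                       doublet_fraction = 0, dispersion = 3, seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_cell_types", "cells_per_type", "n_signature_genes_per_type",
              "n_constitutive", "n_rare", "n_null_facultative",
              "ambient_barcodes")
  if (any(unlist(cfg[counts]) < 0)) stop("counts must be >= 0")
  if (cfg$n_cell_types < 1 || cfg$cells_per_type < 1)
    stop("need at least one cell of one type")
  if (cfg$signature_fold <= 1) stop("signature_fold must exceed 1")
  if (cfg$signature_leakage < 0 || cfg$signature_leakage >= cfg$signature_fold)
    stop("signature_leakage must lie in [0, signature_fold)")
  if (cfg$doublet_fraction < 0 || cfg$doublet_fraction >= 1 ||
      cfg$ambient_depth_fraction < 0 || cfg$ambient_depth_fraction >= 1)
    stop("fractions must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate a count stack with known ground truth
#'
#' Gamma-Poisson count generator over a block-structured rate matrix:
#' per-gene relative rates are lognormal within regime (constitutive genes
#' orders of magnitude above facultative, rare genes far below), per-cell
#' depths are lognormal, per-entry rates get multiplicative gamma noise,
#' and counts are Poisson. Non-signature facultative genes carry graded
#' per-type effects; signature genes are multiplied by `signature_fold` in
#' their own type and leak at `signature_leakage` of base rate elsewhere.
#' Doublets are sums of two random singlet count vectors;
#' ambient barcodes draw from the pooled mean profile at a small fraction
#' of the singlet depth. Fully reproducible for a given seed.
#'
#' @param config a [sim_config()].
#' @return A list with `stack` (a [count_stack()]) and `truth` (class
#'   `ground_truth`): `barcode_class` (ambient/singlet/doublet),
#'   `cell_type` (per singlet), `gene_regime` (rare/facultative/
#'   constitutive), `de_genes` (signature gene indices per type).
#' @export
simulate_stack <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sig <- config$n_cell_types * config$n_signature_genes_per_type
  G <- config$n_rare + config$n_null_facultative + n_sig + config$n_constitutive
  regime <- rep(c("rare", "facultative", "facultative", "constitutive"),
                c(config$n_rare, config$n_null_facultative, n_sig,
                  config$n_constitutive))
  is_sig <- seq_len(G) > config$n_rare + config$n_null_facultative &
    seq_len(G) <= config$n_rare + config$n_null_facultative + n_sig
  sig_type <- integer(G)
  sig_type[is_sig] <- rep(seq_len(config$n_cell_types),
                          each = config$n_signature_genes_per_type)
  base <- numeric(G)
  base[regime == "rare"] <- stats::rlnorm(config$n_rare, log(0.012), 0.9)
  null_fac <- regime == "facultative" & !is_sig
  base[null_fac] <- stats::rlnorm(config$n_null_facultative, log(1), 0.8)
  # markers are well-covered facultative genes: their elevated own-type rate
  # must stay inside the facultative coverage band, not cross into the
  # constitutive regime
  base[is_sig] <- stats::rlnorm(n_sig, log(2.6), 0.25)
  base[regime == "constitutive"] <- stats::rlnorm(config$n_constitutive,
                                                  log(320), 0.5)
  n_singlet <- config$n_cell_types * config$cells_per_type
  type <- rep(seq_len(config$n_cell_types), each = config$cells_per_type)
  sdlog <- 1 / sqrt(config$depth_shape)
  depth <- stats::rlnorm(n_singlet, log(config$depth_mean), sdlog)
  # per-type rate matrix (genes x types)
  rate_type <- matrix(base, nrow = G, ncol = config$n_cell_types)
  if (config$type_effect_sd > 0 && any(null_fac)) {
    rate_type[null_fac, ] <- rate_type[null_fac, , drop = FALSE] *
      exp(matrix(stats::rnorm(sum(null_fac) * config$n_cell_types,
                              0, config$type_effect_sd),
                 nrow = sum(null_fac)))
  }
  for (t in seq_len(config$n_cell_types)) {
    own <- is_sig & sig_type == t
    other <- is_sig & sig_type != t
    rate_type[own, t] <- base[own] * config$signature_fold
    rate_type[other, t] <- base[other] * config$signature_leakage
  }
  rate_type <- sweep(rate_type, 2, colSums(rate_type), "/")
  counts <- matrix(0L, nrow = G, ncol = n_singlet)
  for (t in seq_len(config$n_cell_types)) {
    cols <- which(type == t)
    mu <- outer(rate_type[, t], depth[cols])
    noisy <- mu * matrix(stats::rgamma(length(mu), shape = config$dispersion,
                                       rate = config$dispersion),
                         nrow = G)
    counts[, cols] <- stats::rpois(length(noisy), noisy)
  }
  barcode_class <- rep("singlet", n_singlet)
  cell_type <- type
  n_doub <- round(config$doublet_fraction * n_singlet)
  if (n_doub > 0) {
    pairs <- matrix(sample(n_singlet, 2 * n_doub, replace = TRUE), ncol = 2)
    dcounts <- counts[, pairs[, 1], drop = FALSE] +
      counts[, pairs[, 2], drop = FALSE]
    counts <- cbind(counts, dcounts)
    barcode_class <- c(barcode_class, rep("doublet", n_doub))
    cell_type <- c(cell_type, rep(NA_integer_, n_doub))
  }
  if (config$ambient_barcodes > 0) {
    pool <- rowMeans(rate_type)
    pool <- pool / sum(pool)
    amb_depth <- config$ambient_depth_fraction * config$depth_mean
    mu <- outer(pool, rep(amb_depth, config$ambient_barcodes))
    acounts <- matrix(stats::rpois(length(mu), mu), nrow = G)
    counts <- cbind(counts, acounts)
    barcode_class <- c(barcode_class,
                       rep("ambient", config$ambient_barcodes))
    cell_type <- c(cell_type, rep(NA_integer_, config$ambient_barcodes))
  }
  nz <- which(counts > 0, arr.ind = TRUE)
  stack <- count_stack(data.frame(gene = nz[, 1], barcode = nz[, 2],
                                  umi = counts[nz]),
                       gene_ids = sprintf("G%05d", seq_len(G)),
                       barcode_ids = sprintf("BC%05d", seq_len(ncol(counts))))
  truth <- structure(list(
    barcode_class = barcode_class,
    cell_type = cell_type,
    gene_regime = regime,
    de_genes = split(which(is_sig), sig_type[is_sig])),
    class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Recovery metrics against a planted ground truth
#'
#' Standard comparisons of inferred structure with the generator's truth:
#' adjusted Rand index for label partitions and precision/recall for
#' recovered sets.
#'
#' @param inferred inferred labels (vector) or set (indices).
#' @param truth true labels or set.
#' @param type `"labels"` (ARI + confusion) or `"set"` (precision/recall).
#' @return For `"labels"`, list with `ari` and the confusion `table`; for
#'   `"set"`, list with `precision`, `recall`, `f1`, `n_true_positive`.
#' @export
truth_metrics <- function(inferred, truth, type = c("labels", "set")) {
  type <- match.arg(type)
  if (type == "labels") {
    if (length(inferred) != length(truth))
      stop("label vectors must align")
    list(ari = mclust::adjustedRandIndex(inferred, truth),
         table = table(inferred = inferred, truth = truth))
  } else {
    if (!length(inferred) && !length(truth))
      return(list(precision = 1, recall = 1, f1 = 1, n_true_positive = 0))
    tp <- length(intersect(inferred, truth))
    precision <- if (length(inferred)) tp / length(inferred) else NA_real_
    recall <- if (length(truth)) tp / length(truth) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0))
      2 * precision * recall / (precision + recall) else 0
    list(precision = precision, recall = recall, f1 = f1,
         n_true_positive = tp)
  }
}

#' Write the simulation ground truth beside a stack
#'
#' @param truth a `ground_truth`.
#' @param out_dir output directory.
#' @return Invisibly, the paths written (`barcodes_truth.tsv`,
#'   `genes_truth.tsv`).
#' @export
write_truth <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "barcodes_truth.tsv")
  p2 <- file.path(out_dir, "genes_truth.tsv")
  utils::write.table(data.frame(class = truth$barcode_class,
                                cell_type = truth$cell_type),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- integer(length(truth$gene_regime))
  for (t in names(truth$de_genes)) sig[truth$de_genes[[t]]] <- as.integer(t)
  utils::write.table(data.frame(regime = truth$gene_regime,
                                signature_type = sig),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
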