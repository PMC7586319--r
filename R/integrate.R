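#' Multi-replicate experimental design
#'
#' Describes a set of independently sequenced specimens (biological
#' replicates) grouped into experimental rounds (preparation batches).
#'
#' @param specimen_id character vector of specimen labels (unique).
#' @param round_id round/batch label per specimen.
#' @param min_round_fraction fraction of rounds in which a gene must be
#'   batch-consistent to enter the consensus (default 0.75, i.e. "at least
#'   3 of 4 rounds").
#' @return An object of class `replicate_design`.
#' @export
replicate_design <- function(specimen_id, round_id,
                             min_round_fraction = 0.75) {
  stopifnot(length(specimen_id) == length(round_id),
            !anyDuplicated(specimen_id),
            min_round_fraction > 0, min_round_fraction <= 1)
  structure(list(specimens = data.frame(specimen_id = as.character(specimen_id),
                                        round_id = as.character(round_id)),
                 rounds = split(as.character(specimen_id),
                                as.character(round_id)),
                 min_round_fraction = min_round_fraction),
            class = "replicate_design")
}

#' Per-specimen matrix focusing
#'
#' Runs the coverage sweep and regime inference independently for each
#' specimen (never pooling coverage profiles across specimens), on the gene
#' axis and optionally the barcode axis. Specimens whose fit fails are
#' excluded with a warning, provided at least two remain (one, for a
#' single-specimen design).
#'
#' @param stacks named list of [count_stack()]s, names matching the
#'   design's specimen ids.
#' @param design a [replicate_design()].
#' @param axes axes to focus (`c("gene", "barcode")` by default).
#' @param seed master seed; each specimen's seed is derived from the master
#'   seed and a digest of its coverage totals, so runs are reproducible and
#'   identical specimens are focused identically.
#' @param ... passed to [parametric_sweep()] (e.g. `n_cutoffs`,
#'   `spike_factor`).
#' @return Named list (one element per surviving specimen) of lists with a
#'   `regime_partition` and `coverage_profile` per axis.
#' @export
per_specimen_focus <- function(stacks, design, axes = c("gene", "barcode"),
                               seed = 1, ...) {
  ids <- design$specimens$specimen_id
  stopifnot(all(ids %in% names(stacks)))
  out <- list()
  failed <- character()
  for (i in seq_along(ids)) {
    sp <- ids[i]
    res <- tryCatch({
      per_axis <- lapply(axes, function(ax) {
        prof <- total_coverage(stacks[[sp]], axis = ax)
        sp_seed <- (seed + sum(prof$total) + nrow(prof)) %% 1000003
        sw <- parametric_sweep(prof, seed = sp_seed, ...)
        list(partition = infer_regimes(sw, prof), profile = prof, sweep = sw)
      })
      names(per_axis) <- axes
      per_axis
    }, error = function(e) e)
    if (inherits(res, "error")) failed <- c(failed, sp) else out[[sp]] <- res
  }
  if (length(failed)) {
    if (length(out) < min(2L, length(ids)))
      stop("focusing failed for ", paste(failed, collapse = ", "),
           "; too few specimens remain")
    warning("focusing failed for specimen(s) ",
            paste(failed, collapse = ", "), "; excluded")
  }
  out
}

#' Consensus facultative gene selection
#'
#' Stepwise selection across batches and rounds: a gene is
#' "batch-consistent" for a round when it is facultative in *every*
#' specimen of that round (set intersection); the consensus keeps genes
#' batch-consistent in at least `ceil(min_round_fraction * n_rounds)`
#' rounds.
#'
#' @param per_specimen_facultative named list mapping specimen id to its
#'   facultative gene identifier set (character vectors).
#' @param design a [replicate_design()].
#' @return An object of class `consensus_set`: `per_specimen_facultative`,
#'   `batch_consistent` (per round), `consensus_genes`, `min_rounds`.
#' @export
consensus_facultative <- function(per_specimen_facultative, design) {
  rounds <- design$rounds
  bc <- lapply(rounds, function(sps) {
    sets <- per_specimen_facultative[sps]
    if (any(vapply(sets, is.null, logical(1))))
      stop("missing facultative set for a specimen in the design")
    Reduce(intersect, sets)
  })
  need <- ceiling(design$min_round_fraction * length(rounds))
  tally <- table(unlist(lapply(bc, unique)))
  consensus <- sort(names(tally)[tally >= need])
  if (!length(consensus))
    stop("empty consensus facultative set; relax min_round_fraction")
  structure(list(per_specimen_facultative = per_specimen_facultative,
                 batch_consistent = bc, consensus_genes = consensus,
                 min_rounds = need),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d genes batch-consistent in >= %d round(s)\n",
              length(x$consensus_genes), x$min_rounds))
  invisible(x)
}

#' Assemble the integrated multi-replicate stack
#'
#' Restricts each specimen's stack to (consensus genes, intersected with an
#' optional annotation filter and, by default, with the genes detected in
#' every specimen) x its inferred singlets, then concatenates. Barcodes are
#' namespaced as `"<specimen_id>:<barcode>"` (collision-proof, reversible);
#' per-barcode UPT denominators are computed within each specimen's full
#' stack and never mixed across specimens.
#'
#' @param stacks named list of [count_stack()]s (gene ids must share an
#'   annotation namespace).
#' @param consensus_genes character vector of gene ids to keep.
#' @param per_specimen_singlets named list of barcode axis index vectors
#'   (inferred singlets per specimen); `NULL` keeps all barcodes.
#' @param gene_filter optional further gene id set (e.g. protein-coding,
#'   non-ribosomal annotation), intersected with the consensus.
#' @param replicated_only keep only genes detected (>= 1 UMI) in every
#'   specimen (default `TRUE`).
#' @return A [count_stack()] with attributes `specimen_map` (specimen per
#'   barcode) and `denominators` (full-library totals per namespaced
#'   barcode).
#' @export
assemble_integrated <- function(stacks, consensus_genes,
                                per_specimen_singlets = NULL,
                                gene_filter = NULL, replicated_only = TRUE) {
  ids <- names(stacks)
  genes <- as.character(consensus_genes)
  known <- unique(unlist(lapply(stacks, function(st)
    as.character(st$gene_ids))))
  if (any(!genes %in% known))
    stop("gene ids absent from every specimen; specimens must share an ",
         "annotation namespace")
  if (!is.null(gene_filter)) genes <- intersect(genes, as.character(gene_filter))
  if (replicated_only) {
    detected <- lapply(stacks, function(st)
      as.character(st$gene_ids)[unique(st$entries$gene)])
    genes <- Reduce(intersect, c(list(genes), detected))
  }
  genes <- sort(genes)
  if (!length(genes)) stop("no genes survive the integration filters")
  entries <- list()
  barcode_ids <- character()
  spec_map <- character()
  denoms <- numeric()
  for (sp in ids) {
    st <- stacks[[sp]]
    bkeep <- if (is.null(per_specimen_singlets)) seq_len(st$n_barcodes)
             else sort(unique(per_specimen_singlets[[sp]]))
    full_den <- barcode_totals(st)
    e <- st$entries
    gmap <- match(as.character(st$gene_ids), genes)  # NA -> filtered out
    keep <- !is.na(gmap[e$gene]) & e$barcode %in% bkeep
    boff <- length(barcode_ids)
    bmap <- integer(st$n_barcodes)
    bmap[bkeep] <- seq_along(bkeep) + boff
    entries[[sp]] <- data.frame(gene = gmap[e$gene[keep]],
                                barcode = bmap[e$barcode[keep]],
                                umi = e$umi[keep])
    new_bc <- paste0(sp, ":", st$barcode_ids[bkeep])
    barcode_ids <- c(barcode_ids, new_bc)
    spec_map <- c(spec_map, rep(sp, length(bkeep)))
    denoms <- c(denoms, stats::setNames(unname(full_den[bkeep]), new_bc))
  }
  out <- count_stack(do.call(rbind, entries), gene_ids = genes,
                     barcode_ids = barcode_ids)
  attr(out, "specimen_map") <- stats::setNames(spec_map, barcode_ids)
  attr(out, "denominators") <- denoms
  out
}

#' Singlet retention after gene stratification
#'
#' Which inferred singlets survive the final stratification: a barcode is
#' retained when it carries at least one UMI of a marker-stratum
#' (Profiler) gene. Reports per-specimen retained/dropped counts and the
#' median library size of each group -- dropped cells with systematically
#' larger libraries are the signature of unrecognised multi-cell barcodes.
#'
#' @param stack the integrated [count_stack()] (with `specimen_map` /
#'   `denominators` attributes from [assemble_integrated()], or a plain
#'   stack for a single specimen).
#' @param profiler_genes gene axis indices of the marker stratum.
#' @return An object of class `retention_report`: data.frame per specimen
#'   (`specimen`, `n_retained`, `n_dropped`, `retention_rate`,
#'   `median_total_retained`, `median_total_dropped`) plus the overall rate
#'   and the retained barcode indices.
#' @export
post_stratification_retention <- function(stack, profiler_genes) {
  spec <- attr(stack, "specimen_map")
  if (is.null(spec))
    spec <- stats::setNames(rep("all", stack$n_barcodes), stack$barcode_ids)
  den <- attr(stack, "denominators")
  if (is.null(den)) den <- barcode_totals(stack)
  e <- stack$entries
  present <- sort(unique(e$barcode))
  retained_idx <- sort(unique(e$barcode[e$gene %in% profiler_genes]))
  is_ret <- present %in% retained_idx
  sp <- unname(spec[stack$barcode_ids[present]])
  tot <- unname(den[stack$barcode_ids[present]])
  per <- do.call(rbind, lapply(split(seq_along(present), sp), function(ii) {
    r <- is_ret[ii]
    data.frame(specimen = sp[ii[1]],
               n_retained = sum(r), n_dropped = sum(!r),
               retention_rate = mean(r),
               median_total_retained = if (any(r)) stats::median(tot[ii][r]) else NA_real_,
               median_total_dropped = if (any(!r)) stats::median(tot[ii][!r]) else NA_real_)
  }))
  rownames(per) <- NULL
  structure(list(per_specimen = per,
                 overall_rate = mean(is_ret),
                 retained_barcodes = retained_idx),
            class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("retention_report: %.1f%% of singlets retained\n",
              100 * x$overall_rate))
  print(x$per_specimen)
  invisible(x)
}
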