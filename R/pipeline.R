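#' End-to-end analysis pipeline
#'
#' Runs the full workflow in stage order: sparsity profile; gene-axis (and
#' optionally barcode-axis) focusing; scoring; prospective clustering;
#' first stratification pass (SG / LSTNR against prospective clusters);
#' refinement into cell majors on LSTNR genes; second stratification pass
#' (full ladder against majors); final clustering on Profiler genes;
#' reporting. Each stage's tabular outputs land in `out_dir`, and a
#' manifest (stage, status, wall time, output files with MD5 hashes) is
#' written as JSON lines. Deterministic stages reproduce byte-identical
#' TSVs under an identical config; any stage error leaves a `FAILED` marker
#' beside the partial outputs.
#'
#' @param stack a [count_stack()] (or a directory containing
#'   `matrix.mtx` + `genes.tsv` + `barcodes.tsv` to read).
#' @param out_dir run directory (created).
#' @param seed master seed; per-stage seeds are derived stably from it.
#' @param focus_barcodes also focus the barcode axis (default `FALSE`; the
#'   gene axis is always focused).
#' @param k cluster count, `NULL` for silhouette selection over `k_range`.
#' @param k_range candidate cluster counts.
#' @param alpha stratification significance level.
#' @param rank embedding rank (default 20; enough for the handful of
#'   discriminant directions cell types span, before pure-noise components
#'   start diluting the Ward distances).
#' @param n_cutoffs sweep grid size (default 48 keeps a full run in
#'   seconds-to-minutes at typical fixture scale).
#' @param family UPT scoring family (default `"auto"`).
#' @return Invisibly, a list with the fitted objects of every stage
#'   (`profile`, `gene_partition`, `scores`, `prospective`, `pass1`,
#'   `majors`, `pass2`, `final`, `retention`) and the `manifest` path.
#' @export
run_pipeline <- function(stack, out_dir, seed = 1, focus_barcodes = FALSE,
                         k = NULL, k_range = 2:10, alpha = 0.05,
                         rank = 20, n_cutoffs = 48, family = "auto") {
  if (is.character(stack)) {
    stack <- read_mtx_triplets(file.path(stack, "matrix.mtx"),
                               file.path(stack, "genes.tsv"),
                               file.path(stack, "barcodes.tsv"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "manifest.jsonl")
  if (file.exists(manifest)) unlink(manifest)
  unlink(file.path(out_dir, "FAILED"))
  state <- new.env()
  stage_seed <- function(name) {
    (seed * 1000L + sum(utf8ToInt(name))) %% .Machine$integer.max
  }
  log_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) e)
    ok <- !inherits(res, "error")
    outs <- list.files(out_dir, full.names = TRUE)
    outs <- outs[startsWith(basename(outs), paste0(name, "."))]
    rec <- list(stage = name, status = if (ok) "PASS" else "FAILED",
                elapsed = round(proc.time()[["elapsed"]] - t0, 3),
                outputs = as.list(stats::setNames(
                  unname(tools::md5sum(outs)), basename(outs))))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = manifest, append = TRUE)
    if (!ok) {
      writeLines(paste(name, conditionMessage(res)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    res
  }

  state$profile <- log_stage("profile", function() {
    sp <- sparsity_profile(stack)
    write_report(sp, file.path(out_dir, "profile.sparsity.tsv"))
    sp
  })
  state$gene_partition <- log_stage("focus", function() {
    gp <- total_coverage(stack, "gene")
    sw <- parametric_sweep(gp, n_cutoffs = n_cutoffs,
                           seed = stage_seed("focus"))
    part <- infer_regimes(sw, gp)
    write_partition(part, gp, file.path(out_dir, "focus.genes.tsv"))
    utils::write.table(sw$trace, file.path(out_dir, "focus.trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (focus_barcodes) {
      bp <- total_coverage(stack, "barcode")
      bsw <- parametric_sweep(bp, n_cutoffs = n_cutoffs,
                              seed = stage_seed("focus_bc"))
      bpart <- infer_regimes(bsw, bp)
      write_partition(bpart, bp, file.path(out_dir, "focus.barcodes.tsv"))
      state$barcode_partition <- bpart
    }
    part
  })
  state$scores <- log_stage("score", function() {
    denom <- barcode_totals(stack)
    bc_keep <- if (focus_barcodes && !is.null(state$barcode_partition))
      state$barcode_partition$mid_set else seq_len(stack$n_barcodes)
    foc <- focus_stack(stack, gene_subset = state$gene_partition$mid_set,
                       barcode_subset = bc_keep)
    den_f <- denom[attr(foc, "parent_barcode_index")]
    sc <- score_set(foc, den_f, family = family)
    state$focused <- foc
    utils::write.table(sc$upt, file.path(out_dir, "score.upt.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sc$log2fc, file.path(out_dir, "score.log2fc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc
  })
  state$prospective <- log_stage("cluster", function() {
    dims <- c(length(unique(state$scores$btheta$gene)),
              length(unique(state$scores$btheta$barcode)))
    rk <- if (is.null(rank)) NULL else max(1L, min(rank, min(dims) - 1L))
    emb <- truncated_svd(state$scores, rank = rk,
                         seed = stage_seed("cluster"))
    kk <- if (is.null(k)) choose_k(emb, k_range) else k
    ca <- ward_cluster(emb, k = kk, stage = "prospective")
    utils::write.table(data.frame(barcode = names(ca$labels),
                                  cluster = ca$labels),
                       file.path(out_dir, "cluster.prospective.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ca
  })
  expand_labels <- function(ca) {
    lab <- rep(NA_character_, state$focused$n_barcodes)
    lab[as.integer(names(ca$labels))] <- as.character(ca$labels)
    lab
  }
  state$pass1 <- log_stage("stratify1", function() {
    gs <- stratify_genes(state$scores, expand_labels(state$prospective),
                         state$focused, alpha = alpha)
    utils::write.table(gs$stats, file.path(out_dir, "stratify1.stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gs
  })
  state$majors <- log_stage("majors", function() {
    lstnr <- gs_members <- state$pass1$strata$members$LSTNR
    if (!length(lstnr)) stop("no LSTNR genes; cannot refine majors")
    refine_majors(state$scores, lstnr, k = k, k_range = k_range,
                  rank = rank, seed = stage_seed("majors"), stage = "major")
  })
  state$pass2 <- log_stage("stratify2", function() {
    gs <- stratify_genes(state$scores, expand_labels(state$majors),
                         state$focused, alpha = alpha)
    utils::write.table(data.frame(gene = names(gs$strata$strata),
                                  stratum = gs$strata$strata),
                       file.path(out_dir, "stratify2.strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gs
  })
  state$final <- log_stage("final", function() {
    prof <- state$pass2$strata$members$Profiler
    if (!length(prof)) stop("no Profiler genes; cannot final-cluster")
    refine_majors(state$scores, prof, k = k, k_range = k_range,
                  rank = rank, seed = stage_seed("final"), stage = "final")
  })
  state$retention <- log_stage("report", function() {
    ret <- post_stratification_retention(state$focused,
                                         state$pass2$strata$members$Profiler)
    n_in <- length(unique(state$focused$entries$barcode))
    fs <- frosty_spec(state$pass2$strata,
                      n_constitutive = length(state$gene_partition$high_set),
                      n_rare = length(state$gene_partition$low_set),
                      retained_fraction = ret$overall_rate)
    frosty_plot(fs, file.path(out_dir, "report.frosty.svg"))
    knee_plot(total_coverage(stack, "gene"), state$gene_partition,
              file.path(out_dir, "report.knee.svg"))
    utils::write.table(ret$per_specimen,
                       file.path(out_dir, "report.retention.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ret
  })
  invisible(list(profile = state$profile,
                 gene_partition = state$gene_partition,
                 scores = state$scores, prospective = state$prospective,
                 pass1 = state$pass1, majors = state$majors,
                 pass2 = state$pass2, final = state$final,
                 retention = state$retention, manifest = manifest))
}
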