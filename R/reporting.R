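#' Frosty-plot specification
#'
#' Machine-readable twin of the gene stratification diagram: the
#' constitutive "head", the nested "body" of facultative strata counts, the
#' rare-gene "base", and the two "arms" -- input cell fraction (always 1)
#' and the fraction of cells retained by the marker stratum.
#'
#' @param strata a `gene_strata` (from [stratify()]) or its `counts`.
#' @param n_constitutive,n_rare head and base gene counts.
#' @param retained_fraction fraction of input cells retained by the marker
#'   stratum.
#' @param marker_stratum which stratum the arms flag (default `"Profiler"`).
#' @return A `frosty_spec` list.
#' @export
frosty_spec <- function(strata, n_constitutive, n_rare, retained_fraction,
                        marker_stratum = "Profiler") {
  counts <- if (inherits(strata, "gene_strata")) strata$counts else strata
  body <- as.list(counts)
  if (any(diff(unlist(body)) > 0))
    stop("stratum counts must be non-increasing along the ladder")
  if (retained_fraction < 0 || retained_fraction > 1)
    stop("retained_fraction must lie in [0, 1]")
  structure(list(head = n_constitutive, body = body, base = n_rare,
                 left_arm = 1.0, right_arm = retained_fraction,
                 marker_stratum = marker_stratum),
            class = "frosty_spec")
}

#' Frosty plot of the gene stratification ladder
#'
#' Nested circles with areas proportional to stratum sizes, a head circle
#' for constitutive genes, a base rectangle for rare genes, and arms whose
#' heights are the input and retained cell fractions. Writes an SVG image
#' and its JSON twin; tests assert on the twin, never on pixels.
#'
#' @param spec a [frosty_spec()].
#' @param file output SVG path; the JSON twin replaces the extension.
#' @return Invisibly, a list with the `svg` and `json` paths.
#' @export
frosty_plot <- function(spec, file) {
  json <- sub("\\.svg$", ".json", file)
  jsonlite::write_json(unclass(spec), json, auto_unbox = TRUE, digits = NA)
  grDevices::svg(file, width = 5, height = 7)
  on.exit(grDevices::dev.off())
  counts <- unlist(spec$body)
  r <- sqrt(counts / max(counts, 1))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-2, 2), ylim = c(-2.2, 2.4), asp = 1)
  graphics::symbols(rep(0, length(r)), rep(0, length(r)), circles = r,
                    inches = FALSE, add = TRUE,
                    bg = grDevices::grey(seq(0.95, 0.55, length.out = length(r))))
  rh <- sqrt(spec$head / max(counts, 1))
  graphics::symbols(0, 1 + rh * 0.8, circles = max(rh, 0.02), inches = FALSE,
                    add = TRUE, bg = "black")
  graphics::rect(-1, -2.2, 1, -1.4, col = "dimgray")
  graphics::segments(c(-1.3, 1.3), 0, c(-1.3, 1.3),
                     c(spec$left_arm, spec$right_arm), lwd = 6)
  graphics::text(0, -1.8, sprintf("rare: %d", spec$base), col = "white")
  graphics::title(main = sprintf("%s | retained %.1f%%", spec$marker_stratum,
                                 100 * spec$right_arm))
  invisible(list(svg = file, json = json))
}

#' Knee plot with regime colouring and tie-count depth
#'
#' Rank versus total coverage on log-log axes, colouring the three regimes
#' and sizing points by the number of items sharing a ranking position (the
#' z-axis of the display). Returns its plot-data twin.
#'
#' @param profile a [total_coverage()] profile.
#' @param partition optional [infer_regimes()] partition for colouring.
#' @param file optional SVG path; omit to only return the plot data.
#' @return Invisibly, the plot-data data.frame (`rank`, `total`, `n_tied`,
#'   `regime`).
#' @export
knee_plot <- function(profile, partition = NULL, file = NULL) {
  if (!nrow(profile)) stop("empty coverage profile")
  regime <- if (is.null(partition)) rep("all", nrow(profile)) else
    ifelse(profile$index %in% partition$mid_set, "mid",
           ifelse(profile$index %in% partition$high_set, "high", "low"))
  dat <- data.frame(rank = profile$rank, total = profile$total,
                    n_tied = profile$n_tied, regime = regime)
  if (!is.null(file)) {
    grDevices::svg(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    cols <- c(low = "grey70", mid = "forestgreen", high = "firebrick",
              all = "grey30")
    graphics::plot(dat$rank, dat$total, log = "xy", pch = 16,
                   col = cols[dat$regime],
                   cex = 0.4 + 0.4 * log10(dat$n_tied + 1),
                   xlab = "coverage rank", ylab = "total UMIs")
  }
  invisible(dat)
}

#' Topograph: weighed expression of one gene across majors
#'
#' The composite "weighed expression" display: per major, the mean log2
#' fold change over expressing cells multiplied by the within-major
#' representation rate, converted to a non-parametric quantile across the
#' majors with data (spanning \[0, 1\]). Major centroids (mean
#' linear-predictor vectors) are related by a neighbor-joining tree on
#' their Euclidean distances. Expressing cells are drawn as points on the
#' latent 2D layout.
#'
#' @param scores a [score_set()].
#' @param majors a `cluster_assignment` (labels over barcode indices).
#' @param layout cells x 2 coordinate matrix (rownames = barcode indices);
#'   defaults to the assignment's `layout2d`.
#' @param gene gene axis index to display.
#' @param file optional SVG path.
#' @return Invisibly, a `topograph_spec` list: `gene`, `weighed_score`
#'   (quantile per major), `composite` (raw mean x rate), `expressing_cells`,
#'   `tree` (Newick string), `layout_kind`.
#' @export
topograph <- function(scores, majors, layout = NULL, gene, file = NULL) {
  if (is.null(layout)) layout <- majors$layout2d
  lab <- majors$labels
  l2 <- scores$log2fc[scores$log2fc$gene == gene, ]
  if (!nrow(l2)) stop("gene has no expressing cells in any major")
  cl_of <- lab[as.character(l2$barcode)]
  keep <- !is.na(cl_of)
  l2 <- l2[keep, ]; cl_of <- cl_of[keep]
  if (!nrow(l2)) stop("gene has no expressing cells in any major")
  lev <- sort(unique(lab))
  n_cells <- table(factor(lab, levels = lev))
  mean_fc <- tapply(l2$log2fc, factor(cl_of, levels = lev), mean)
  n_expr <- table(factor(cl_of, levels = lev))
  rate <- as.numeric(n_expr) / as.numeric(n_cells)
  composite <- ifelse(is.na(mean_fc), NA_real_, as.numeric(mean_fc) * rate)
  has <- !is.na(composite)
  qtl <- rep(NA_real_, length(lev))
  if (sum(has) == 1) qtl[has] <- 1 else
    qtl[has] <- (rank(composite[has], ties.method = "average") - 1) /
      (sum(has) - 1)
  names(qtl) <- names(composite) <- lev
  # major centroids in score space -> neighbor-joining tree
  bt <- scores$btheta
  bt_cl <- lab[as.character(bt$barcode)]
  ok <- !is.na(bt_cl)
  genes_all <- sort(unique(bt$gene))
  M <- matrix(0, nrow = length(lev), ncol = length(genes_all),
              dimnames = list(lev, genes_all))
  agg <- stats::aggregate(bt$btheta[ok],
                          by = list(cl = bt_cl[ok],
                                    gene = bt$gene[ok]), FUN = mean)
  M[cbind(as.character(agg$cl), as.character(agg$gene))] <- agg$x
  tree <- if (length(lev) >= 3) ape::nj(stats::dist(M)) else NULL
  spec <- structure(list(gene = gene,
                         weighed_score = qtl,
                         composite = composite,
                         expressing_cells = l2$barcode,
                         tree = if (is.null(tree)) NA_character_
                                else ape::write.tree(tree),
                         layout_kind = "svd_plane"),
                    class = "topograph_spec")
  if (!is.null(file)) {
    json <- sub("\\.svg$", ".json", file)
    jsonlite::write_json(lapply(unclass(spec), function(z)
      if (is.numeric(z) && !is.null(names(z))) as.list(z) else z),
      json, auto_unbox = TRUE, digits = NA)
    grDevices::svg(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    pal <- grDevices::hcl.colors(101, "Cividis")
    cell_cl <- lab[rownames(layout)]
    qcell <- qtl[as.character(cell_cl)]
    graphics::plot(layout[, 1], layout[, 2],
                   col = pal[1 + round(100 * ifelse(is.na(qcell), 0, qcell))],
                   pch = 16, cex = 0.6, xlab = "latent 1", ylab = "latent 2",
                   main = sprintf("gene %s", gene))
    expr_xy <- layout[rownames(layout) %in% as.character(l2$barcode), ,
                      drop = FALSE]
    graphics::points(expr_xy[, 1], expr_xy[, 2], pch = 16, cex = 0.3)
  }
  invisible(spec)
}

#' Violin summary of log2 fold changes per gene and major
#'
#' Per gene x major: number of expressing cells and the quartiles of the
#' log2 fold changes, plus the background shading tiers of the display --
#' majors in the top quartile of mean expression ("high"), and of the
#' composite expression x representation score ("high_rep"). Writes a TSV
#' twin (the testable surface) and optionally an SVG of density violins.
#'
#' @param scores a [score_set()].
#' @param majors a `cluster_assignment`.
#' @param genes gene axis indices to summarise.
#' @param file optional SVG path; the TSV twin replaces the extension.
#' @return Invisibly, the stats data.frame.
#' @export
violin_summary <- function(scores, majors, genes, file = NULL) {
  lab <- majors$labels
  lev <- sort(unique(lab))
  n_cells <- table(factor(lab, levels = lev))
  rows <- list()
  for (g in genes) {
    l2 <- scores$log2fc[scores$log2fc$gene == g, ]
    cl <- factor(lab[as.character(l2$barcode)], levels = lev)
    for (m in lev) {
      y <- l2$log2fc[!is.na(cl) & cl == m]
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, major = m, n = length(y),
        median = if (length(y)) stats::median(y) else NA_real_,
        q25 = if (length(y)) stats::quantile(y, 0.25, names = FALSE) else NA_real_,
        q75 = if (length(y)) stats::quantile(y, 0.75, names = FALSE) else NA_real_,
        mean = if (length(y)) mean(y) else NA_real_,
        rate = length(y) / as.numeric(n_cells[m]))
    }
  }
  st <- do.call(rbind, rows)
  st$tier <- "none"
  for (g in genes) {
    i <- st$gene == g & st$n > 0
    if (!any(i)) next
    hi <- stats::quantile(st$mean[i], 0.75, na.rm = TRUE)
    hic <- stats::quantile(st$mean[i] * st$rate[i], 0.75, na.rm = TRUE)
    st$tier[i & st$mean >= hi] <- "high"
    st$tier[i & st$mean >= hi & st$mean * st$rate >= hic] <- "high_rep"
  }
  if (!is.null(file)) {
    tsv <- sub("\\.svg$", ".tsv", file)
    utils::write.table(st, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    grDevices::svg(file, width = 7, height = 1.5 + 0.6 * length(genes))
    on.exit(grDevices::dev.off())
    graphics::plot.new()
    graphics::plot.window(xlim = range(st$median, na.rm = TRUE) + c(-1, 1),
                          ylim = c(0, nrow(st) + 1))
    ok <- which(st$n > 0)
    graphics::segments(st$q25[ok], ok, st$q75[ok], ok, lwd = 3,
                       col = c(none = "grey80", high = "grey60",
                               high_rep = "grey30")[st$tier[ok]])
    graphics::points(st$median[ok], ok, pch = 16)
    graphics::axis(1)
    graphics::title(xlab = "log2 fold change vs reference mean")
  }
  invisible(st)
}
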