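#' Observation weights for the stratification ANOVA
#'
#' Each (gene, cell) log2 fold-change observation is weighted twice: by a
#' per-gene coverage-resolution weight
#' `w_res(g) = n_expressing(g) * mean_upt(g) / (1 + CV^2(g))`, normalised to
#' mean 1 over genes (well-covered, low-dispersion genes resolve means
#' better), and by the gene's representation rate in the cell's cluster
#' (`use_representation = FALSE` ablates the second factor -- the
#' "stress-test" contract of the Profiler stratum).
#'
#' @param upt_stack data.frame from [compute_upt()].
#' @param rep_table a [representation_rates()] table.
#' @param clusters cluster labels over the barcode axis (as in
#'   [representation_rates()]).
#' @param use_representation multiply by within-cluster representation
#'   rates (default `TRUE`).
#' @return data.frame `gene`, `barcode`, `cluster`, `w` (strictly positive),
#'   aligned with `upt_stack` rows (rows with `NA` cluster are dropped).
#' @export
observation_weights <- function(upt_stack, rep_table, clusters,
                                use_representation = TRUE) {
  g <- upt_stack$gene
  n_g <- tabulate(g)
  sum_g <- rowsum(upt_stack$upt, g)
  idx <- as.integer(rownames(sum_g))
  mu <- sum_g[, 1] / n_g[idx]
  ss <- rowsum((upt_stack$upt - mu[match(g, idx)])^2, g)[, 1]
  v <- ifelse(n_g[idx] > 1, ss / (n_g[idx] - 1), 0)
  cv2 <- ifelse(mu > 0, v / mu^2, 0)
  w_res_g <- n_g[idx] * mu / (1 + cv2)
  w_res_g <- w_res_g / mean(w_res_g)
  w_res <- stats::setNames(w_res_g, idx)
  if (!is.null(names(clusters)) && !is.null(rownames(rep_table$rate)))
    stop("pass clusters as a plain vector over the barcode axis")
  cl <- factor(clusters)
  obs_cl <- cl[upt_stack$barcode]
  keep <- !is.na(obs_cl)
  w <- w_res[as.character(g[keep])]
  if (use_representation) {
    rate <- rep_table$rate[cbind(g[keep], as.integer(obs_cl[keep]))]
    w <- w * rate
  }
  data.frame(gene = g[keep], barcode = upt_stack$barcode[keep],
             cluster = as.character(obs_cl[keep]), w = pmax(unname(w), 1e-12))
}

#' Weighted one-way ANOVA of log2 fold changes across clusters
#'
#' Per-gene weighted F test of cluster differences in log2 fold change. The
#' gene x cluster two-way model decomposes gene-wise because tests are per
#' gene; within a gene this is the exact weighted one-way F:
#' `F = (SSB / (k - 1)) / (SSW / (n - k))` with weighted between- and
#' within-cluster sums of squares and integer-count degrees of freedom.
#' Genes without at least two clusters each holding at least two expressing
#' cells are untestable and get `p = 1`; genes with zero residual variance
#' get `p = 0` and a warning flag.
#'
#' @param log2fc data.frame `gene`, `barcode`, `log2fc`.
#' @param clusters cluster labels over the barcode axis.
#' @param weights data.frame from [observation_weights()] (matched by gene
#'   and barcode), or `NULL` for unit weights.
#' @return data.frame, one row per gene: `gene`, `f_stat`, `p_anova`,
#'   `df1`, `df2`, `testable`, `degenerate`.
#' @export
weighted_anova <- function(log2fc, clusters, weights = NULL) {
  cl <- factor(clusters)
  gene <- log2fc$gene
  y <- log2fc$log2fc
  oc <- cl[log2fc$barcode]
  w <- if (is.null(weights)) rep(1, length(y)) else {
    key <- paste(gene, log2fc$barcode)
    weights$w[match(key, paste(weights$gene, weights$barcode))]
  }
  keep <- !is.na(oc) & !is.na(w)
  gene <- gene[keep]; y <- y[keep]; oc <- oc[keep]; w <- w[keep]
  K <- nlevels(oc)
  gc_key <- (as.double(gene) - 1) * K + as.integer(oc)
  W <- rowsum(w, gc_key)
  Swy <- rowsum(w * y, gc_key)
  Swyy <- rowsum(w * y * y, gc_key)
  n_gc <- rowsum(rep(1L, length(y)), gc_key)
  gc_gene <- as.integer((as.numeric(rownames(W)) - 1) %/% K + 1)
  mK <- Swy[, 1] / W[, 1]
  ssw_gc <- Swyy[, 1] - W[, 1] * mK^2
  genes <- sort(unique(gene))
  gi <- match(gc_gene, genes)
  n_g <- as.numeric(rowsum(n_gc[, 1], gi))
  k_g <- as.numeric(rowsum(rep(1, length(gi)), gi))
  k2_g <- as.numeric(rowsum(as.numeric(n_gc[, 1] >= 2), gi))
  W_g <- as.numeric(rowsum(W[, 1], gi))
  Swy_g <- as.numeric(rowsum(Swy[, 1], gi))
  m_g <- Swy_g / W_g
  ssb <- as.numeric(rowsum(W[, 1] * mK^2, gi)) - W_g * m_g^2
  ssw <- as.numeric(rowsum(ssw_gc, gi))
  testable <- k_g >= 2 & k2_g >= 2
  degenerate <- testable & ssw <= 1e-300
  f <- ifelse(testable & !degenerate,
              (ssb / (k_g - 1)) / (ssw / (n_g - k_g)), NA_real_)
  p <- rep(1, length(genes))
  p[testable & !degenerate] <-
    stats::pf(f[testable & !degenerate],
              (k_g - 1)[testable & !degenerate],
              (n_g - k_g)[testable & !degenerate], lower.tail = FALSE)
  f[degenerate] <- Inf
  p[degenerate] <- ifelse(ssb[degenerate] > 0, 0, 1)
  out <- data.frame(gene = genes, f_stat = f, p_anova = p,
                    df1 = ifelse(testable, k_g - 1, NA_real_),
                    df2 = ifelse(testable, n_g - k_g, NA_real_),
                    testable = testable, degenerate = degenerate)
  if (any(out$degenerate))
    warning(sum(out$degenerate), " gene(s) with zero residual variance")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotonicity enforced), as
#' implemented by [stats::p.adjust()].
#'
#' @param pvals numeric p-values.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Tolerance-interval signal-to-noise benchmark
#'
#' The SNR = 1 yardstick: half-width of the two-sided 95%/95% normal
#' tolerance interval of the pooled log2 fold-change residuals around their
#' cluster means, `ti = k2 * s`, with Howe's approximation of the tolerance
#' factor `k2(n, coverage, confidence) = z_{(1+P)/2} *
#' sqrt(nu (1 + 1/n) / chisq_{1-conf, nu})`. As `n -> Inf`, `k2 -> 1.96`.
#' A nonparametric alternative takes the 97.5th percentile of `|residuals|`.
#'
#' @param residuals pooled residuals (log2 fold change minus fitted cluster
#'   mean); at least 3 values.
#' @param coverage central fraction to cover (default 0.95).
#' @param confidence confidence level of the coverage claim (default 0.95).
#' @param method `"howe"` (normal tolerance factor) or `"nonparametric"`.
#' @return An object of class `snr_benchmark` with `ti_halfwidth`,
#'   `coverage`, `confidence`, `n_residuals`, `sd`, `method`.
#' @export
snr_benchmark <- function(residuals, coverage = 0.95, confidence = 0.95,
                          method = c("howe", "nonparametric")) {
  method <- match.arg(method)
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 3) stop("need at least 3 residuals")
  s <- sqrt(sum(residuals^2) / (n - 1))
  ti <- if (method == "howe") {
    nu <- n - 1
    k2 <- stats::qnorm((1 + coverage) / 2) *
      sqrt(nu * (1 + 1 / n) / stats::qchisq(1 - confidence, nu))
    k2 * s
  } else {
    stats::quantile(abs(residuals), coverage + (1 - coverage) / 2, names = FALSE)
  }
  structure(list(ti_halfwidth = ti, coverage = coverage,
                 confidence = confidence, n_residuals = n, sd = s,
                 method = method),
            class = "snr_benchmark")
}

#' @export
print.snr_benchmark <- function(x, ...) {
  cat(sprintf("snr_benchmark (%s): TI half-width %.4g (n = %d, sd = %.4g)\n",
              x$method, x$ti_halfwidth, x$n_residuals, x$sd))
  invisible(x)
}

# per-gene, per-cluster weighted summaries used by contrasts and the ladder
.cluster_summaries <- function(log2fc, clusters, weights) {
  cl <- factor(clusters)
  gene <- log2fc$gene
  y <- log2fc$log2fc
  oc <- cl[log2fc$barcode]
  w <- if (is.null(weights)) rep(1, length(y)) else {
    key <- paste(gene, log2fc$barcode)
    weights$w[match(key, paste(weights$gene, weights$barcode))]
  }
  keep <- !is.na(oc) & !is.na(w)
  gene <- gene[keep]; y <- y[keep]; oc <- oc[keep]; w <- w[keep]
  K <- nlevels(oc)
  gc_key <- (as.double(gene) - 1) * K + as.integer(oc)
  W <- rowsum(w, gc_key)[, 1]
  Sw2 <- rowsum(w * w, gc_key)[, 1]
  Swy <- rowsum(w * y, gc_key)[, 1]
  Swyy <- rowsum(w * y * y, gc_key)[, 1]
  n <- rowsum(rep(1L, length(y)), gc_key)[, 1]
  ukey <- as.numeric(names(W))
  m <- Swy / W
  ssw <- pmax(Swyy - W * m^2, 0)
  # variance of the weighted mean via reliability weights
  se2 <- ifelse(n > 1, Sw2 / W^2 * ssw / W * n / (n - 1), NA_real_)
  data.frame(gene = as.integer((ukey - 1) %/% K + 1),
             cluster = levels(oc)[as.integer((ukey - 1) %% K + 1)],
             n = as.integer(n), n_eff = W^2 / Sw2, mean = m, se2 = se2)
}

#' Pairwise Welch-style contrasts between cluster means
#'
#' For each gene and each cluster pair, a Welch-type contrast of the
#' weighted cluster means: `t = delta / sqrt(se1^2 + se2^2)` with
#' Welch-Satterthwaite degrees of freedom on effective sample sizes. With
#' unit weights this reduces exactly to Welch's t test. P-values are pooled
#' across all genes x pairs into a single Benjamini-Hochberg family. A pair
#' is "mutually exclusive" when the two clusters' `mean +/- ti` intervals
#' are disjoint, i.e. `|delta| > 2 * ti`.
#'
#' @param log2fc data.frame `gene`, `barcode`, `log2fc`.
#' @param clusters cluster labels over the barcode axis.
#' @param weights data.frame from [observation_weights()] or `NULL`.
#' @param ti_halfwidth the SNR = 1 unit from [snr_benchmark()], used for the
#'   exclusivity intervals.
#' @param rep_table optional [representation_rates()] table; when given,
#'   `delta` is the difference of representation-adjusted ("net") cluster
#'   levels `mean + log2(rate)` -- the within-cluster pseudo-bulk fold
#'   change -- so that a gene expressed everywhere in one major and hardly
#'   anywhere in another counts as mutually exclusive even when its
#'   per-expressing-cell values hardly differ. Without it, `delta` is the
#'   raw difference of weighted means.
#' @return data.frame, one row per gene x cluster pair: `gene`, `cluster_a`,
#'   `cluster_b`, `delta`, `p`, `q`, `exclusive`. Pairs with a singleton
#'   cluster get `p = 1`.
#' @export
pairwise_contrasts <- function(log2fc, clusters, weights = NULL,
                               ti_halfwidth = 0, rep_table = NULL) {
  cs <- .cluster_summaries(log2fc, clusters, weights)
  if (!is.null(rep_table)) {
    rate <- rep_table$rate[cbind(cs$gene,
                                 match(cs$cluster, colnames(rep_table$rate)))]
    cs$level <- cs$mean + log2(pmax(rate, .Machine$double.eps))
  } else cs$level <- cs$mean
  lev <- sort(unique(cs$cluster))
  genes <- sort(unique(cs$gene))
  idx <- cbind(match(cs$gene, genes), match(cs$cluster, lev))
  mk_mat <- function(col, fill = NA_real_) {
    m <- matrix(fill, nrow = length(genes), ncol = length(lev))
    m[idx] <- col
    m
  }
  Mn <- mk_mat(as.numeric(cs$n), 0)
  Mm <- mk_mat(cs$mean)
  Ml <- mk_mat(cs$level)
  Ms <- mk_mat(cs$se2)
  Me <- mk_mat(cs$n_eff)
  if (length(lev) < 2)
    return(data.frame(gene = integer(), cluster_a = character(),
                      cluster_b = character(), delta = numeric(),
                      p = numeric(), q = numeric(), exclusive = logical()))
  pairs <- utils::combn(seq_along(lev), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    has <- Mn[, a] > 0 & Mn[, b] > 0
    if (!any(has)) return(NULL)
    delta <- Ml[has, a] - Ml[has, b]
    vdelta <- Mm[has, a] - Mm[has, b]  # the Welch t is on the value channel
    se2 <- Ms[has, a] + Ms[has, b]
    ok <- !is.na(se2) & Mn[has, a] >= 2 & Mn[has, b] >= 2
    p <- rep(1, sum(has))
    zero_se <- ok & se2 <= 0
    p[zero_se] <- ifelse(abs(vdelta[zero_se]) > 0, 0, 1)
    use <- ok & se2 > 0
    if (any(use)) {
      tt <- vdelta[use] / sqrt(se2[use])
      df <- se2[use]^2 / (Ms[has, a][use]^2 / (Me[has, a][use] - 1) +
                            Ms[has, b][use]^2 / (Me[has, b][use] - 1))
      p[use] <- 2 * stats::pt(-abs(tt), df)
    }
    data.frame(gene = genes[has], cluster_a = lev[a], cluster_b = lev[b],
               delta = delta, p = p,
               exclusive = abs(delta) > 2 * ti_halfwidth)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene = integer(), cluster_a = character(),
                      cluster_b = character(), delta = numeric(),
                      p = numeric(), q = numeric(), exclusive = logical()))
  out <- out[order(out$gene, out$cluster_a, out$cluster_b), ]
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out
}

.STRATA <- c("facultative_only", "SG", "LSTNR", "DEG", "DEGREE", "Profiler")

#' Representation-heterogeneity test per gene
#'
#' Chi-squared test of whether a gene's representation rate (expressing vs
#' non-expressing cells) differs between clusters -- the second channel of
#' the double-weighted differential analysis, capturing the
#' presence/absence information a value-level ANOVA on expressing cells
#' cannot see. Genes expressed everywhere or nowhere are untestable and
#' get `p = 1`.
#'
#' @param rep_table a [representation_rates()] table.
#' @return data.frame `gene`, `x2`, `p_rep` (one row per gene axis index).
#' @export
representation_test <- function(rep_table) {
  ne <- rep_table$n_expressing
  nc <- rep_table$n_cells
  G <- nrow(ne)
  tot_e <- rowSums(ne)
  N <- sum(nc)
  p_hat <- tot_e / N
  # X2 = sum over clusters of (O - E)^2 / E for both rows of the 2 x K table
  E1 <- outer(p_hat, as.numeric(nc))
  E0 <- outer(1 - p_hat, as.numeric(nc))
  with_data <- p_hat > 0 & p_hat < 1
  x2 <- rep(NA_real_, G)
  p <- rep(1, G)
  if (any(with_data)) {
    x2[with_data] <- rowSums((ne[with_data, , drop = FALSE] -
                                E1[with_data, , drop = FALSE])^2 /
                               E1[with_data, , drop = FALSE]) +
      rowSums(((matrix(nc, nrow = sum(with_data), ncol = length(nc),
                       byrow = TRUE) - ne[with_data, , drop = FALSE]) -
                 E0[with_data, , drop = FALSE])^2 /
                E0[with_data, , drop = FALSE])
    p[with_data] <- stats::pchisq(x2[with_data], df = length(nc) - 1,
                                  lower.tail = FALSE)
  }
  data.frame(gene = seq_len(G), x2 = x2, p_rep = p)
}

# Fisher combination of the value-level and representation-level channels
.fisher_combine <- function(p1, p2) {
  p1 <- pmax(pmin(p1, 1), 1e-300)
  p2 <- pmax(pmin(p2, 1), 1e-300)
  stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' Assign genes to the nested reliability strata
#'
#' The stratification ladder, each rung a strict filter on the previous:
#' \describe{
#'   \item{SG}{ANOVA q-value (BH-adjusted, representation-weighted) at or
#'     below `alpha`.}
#'   \item{LSTNR}{SG with mean log2 fold change beyond the SNR = 1
#'     tolerance half-width in at least one cluster.}
#'   \item{DEG}{LSTNR with at least one pairwise contrast that is both
#'     significant (q at or below `alpha`) and mutually exclusive
#'     (disjoint `mean +/- ti` intervals).}
#'   \item{DEGREE}{DEG with a significant pair whose difference exceeds the
#'     SNR = 1 benchmark.}
#'   \item{Profiler}{DEGREE whose ANOVA stays significant when the
#'     representation weights are ablated (`q_unweighted` at or below
#'     `alpha`).}
#' }
#'
#' @param stats per-gene stats with columns `gene`, `q_anova`,
#'   `q_unweighted`, `max_abs_mean` (largest absolute weighted cluster
#'   mean).
#' @param pairwise data.frame from [pairwise_contrasts()].
#' @param benchmark a [snr_benchmark()].
#' @param alpha significance threshold (default 0.05).
#' @param stack optional focused [count_stack()]; when given,
#'   `retained_barcodes` lists cells with at least one UMI in a Profiler
#'   gene.
#' @return An object of class `gene_strata`: `strata` (named character
#'   vector over genes, one of facultative_only/SG/LSTNR/DEG/DEGREE/
#'   Profiler), `counts` (cumulative stratum membership), `members` (index
#'   list per stratum, nested), `retained_barcodes`.
#' @export
stratify <- function(stats, pairwise, benchmark, alpha = 0.05, stack = NULL) {
  ti <- benchmark$ti_halfwidth
  sg <- stats$gene[stats$q_anova <= alpha]
  if (!length(sg)) warning("empty SG set; upper strata are empty")
  lstnr <- intersect(sg, stats$gene[stats$max_abs_mean > ti])
  pw_deg <- pairwise$gene[pairwise$q <= alpha & pairwise$exclusive]
  deg <- intersect(lstnr, pw_deg)
  pw_degree <- pairwise$gene[pairwise$q <= alpha & abs(pairwise$delta) > ti]
  degree <- intersect(deg, pw_degree)
  profiler <- intersect(degree, stats$gene[stats$q_unweighted <= alpha])
  members <- list(SG = sg, LSTNR = lstnr, DEG = deg, DEGREE = degree,
                  Profiler = profiler)
  lab <- stats::setNames(rep("facultative_only", nrow(stats)), stats$gene)
  for (s in names(members)) lab[as.character(members[[s]])] <- s
  counts <- c(facultative = nrow(stats),
              vapply(members, length, numeric(1)))
  retained <- if (!is.null(stack) && length(profiler)) {
    sort(unique(stack$entries$barcode[stack$entries$gene %in% profiler]))
  } else integer()
  structure(list(strata = lab, counts = counts, members = members,
                 alpha = alpha, ti_halfwidth = ti,
                 retained_barcodes = retained),
            class = "gene_strata")
}

#' @export
print.gene_strata <- function(x, ...) {
  cat("gene_strata:",
      paste(sprintf("%s %d", names(x$counts), x$counts), collapse = " > "),
      "\n")
  invisible(x)
}

#' Run the full gene stratification for one clustering
#'
#' The double-weighted differential analysis and the strata ladder. Two
#' information channels are tested per gene: the *value* channel, a
#' coverage-resolution-weighted one-way ANOVA of log2 fold changes among
#' expressing cells across clusters, and the *representation* channel, a
#' chi-squared test of expressing-cell counts across clusters
#' ([representation_test()]); their Fisher combination is the
#' representation-aware p-value behind SG membership, while the ablated
#' analysis (`q_unweighted`, value channel alone) gates the Profiler
#' stratum -- genes that stay significant even when representation rates
#' are ignored. Residuals around cluster means feed the SNR = 1 tolerance
#' benchmark; pairwise contrasts, their BH family and the
#' mutual-exclusivity intervals complete the ladder.
#'
#' @param scores a [score_set()].
#' @param clusters cluster labels over the barcode axis (e.g.
#'   `cluster_assignment$labels` expanded to the axis; a named vector over
#'   barcode ids also works).
#' @param stack the focused [count_stack()] (for representation rates and
#'   barcode retention).
#' @param alpha significance level (default 0.05).
#' @param ti_method passed to [snr_benchmark()].
#' @return An object of class `gene_stratification`: `stats` (per-gene
#'   data.frame), `pairwise`, `benchmark`, `strata` (a [stratify()]
#'   result), `rep_table`, `cluster_means`.
#' @export
stratify_genes <- function(scores, clusters, stack, alpha = 0.05,
                           ti_method = "howe") {
  if (!is.null(names(clusters))) {
    cl <- rep(NA_character_, stack$n_barcodes)
    hit <- match(names(clusters), stack$barcode_ids)
    cl[hit[!is.na(hit)]] <- as.character(clusters[!is.na(hit)])
    clusters <- cl
  }
  rep_table <- representation_rates(stack, clusters)
  w <- observation_weights(scores$upt, rep_table, clusters,
                           use_representation = FALSE)
  an <- weighted_anova(scores$log2fc, clusters, w)
  rt <- representation_test(rep_table)
  an$p_value_channel <- an$p_anova
  an$p_rep <- rt$p_rep[match(an$gene, rt$gene)]
  an$p_anova <- .fisher_combine(an$p_value_channel, an$p_rep)
  an$q_anova <- bh_adjust(an$p_anova)
  an$q_unweighted <- bh_adjust(an$p_value_channel)
  cs <- .cluster_summaries(scores$log2fc, clusters, w)
  mx <- tapply(abs(cs$mean), cs$gene, max)
  an$max_abs_mean <- as.numeric(mx[as.character(an$gene)])
  # pooled residuals around cluster means (cells in clusters with >= 2
  # expressing cells contribute)
  clf <- factor(clusters)
  obs <- data.frame(gene = scores$log2fc$gene,
                    y = scores$log2fc$log2fc,
                    cluster = clf[scores$log2fc$barcode])
  obs <- obs[!is.na(obs$cluster), ]
  ckey <- paste(obs$gene, obs$cluster)
  mkey <- paste(cs$gene, cs$cluster)
  fit <- cs$mean[match(ckey, mkey)]
  nK <- cs$n[match(ckey, mkey)]
  resid <- (obs$y - fit)[nK >= 2]
  benchmark <- snr_benchmark(resid, method = ti_method)
  pw <- pairwise_contrasts(scores$log2fc, clusters, w,
                           ti_halfwidth = benchmark$ti_halfwidth,
                           rep_table = rep_table)
  strata <- stratify(an, pw, benchmark, alpha = alpha, stack = stack)
  structure(list(stats = an, pairwise = pw, benchmark = benchmark,
                 strata = strata, rep_table = rep_table, cluster_means = cs),
            class = "gene_stratification")
}

#' @export
print.gene_stratification <- function(x, ...) {
  print(x$strata)
  print(x$benchmark)
  invisible(x)
}
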