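#' Per-barcode library sizes
#'
#' Total UMIs per barcode over a stack. UPT denominators are taken from the
#' *full* (pre-focusing) stack: "per-thousand total" refers to the cell's
#' whole library, not to the focused block.
#'
#' @param stack a [count_stack()].
#' @return Numeric vector of length `n_barcodes` (0 for barcodes with no
#'   entries), named by barcode id.
#' @export
barcode_totals <- function(stack) {
  out <- numeric(stack$n_barcodes)
  e <- stack$entries
  if (nrow(e)) {
    tot <- rowsum(as.double(e$umi), group = e$barcode)
    out[as.integer(rownames(tot))] <- tot[, 1]
  }
  names(out) <- stack$barcode_ids
  out
}

#' UMIs-per-thousand (UPT) rates
#'
#' Normalises each count to the cell's library:
#' `upt(g, c) = 1000 * umi(g, c) / denominator(c)`. The support (set of
#' data-positive pairs) is unchanged -- zeros are never imputed.
#'
#' @param stack a (typically focused) [count_stack()].
#' @param denominators per-barcode totals, indexed by the stack's barcode
#'   axis, computed on the full stack (see [barcode_totals()]); every
#'   barcode present in `stack` must have a positive denominator.
#' @return data.frame `gene`, `barcode`, `upt`.
#' @export
compute_upt <- function(stack, denominators) {
  e <- stack$entries
  if (length(denominators) < stack$n_barcodes)
    stop("denominators must cover the stack's barcode axis")
  d <- denominators[e$barcode]
  if (any(!is.finite(d) | d <= 0))
    stop("missing or non-positive denominator for a barcode present in the stack")
  data.frame(gene = e$gene, barcode = e$barcode, upt = 1000 * e$umi / d)
}

#' Pseudo-bulk reference means
#'
#' The "bulk" expression level of each gene with all retained cells pooled:
#' `ref_mean(g) = 1000 * sum_c umi(g, c) / sum_c denominator(c)`, summing
#' denominators over the barcodes present in the stack. This is the
#' denominator of the per-cell log2 fold changes.
#'
#' @inheritParams compute_upt
#' @return Named numeric vector over genes with positive totals (gene axis
#'   index as name).
#' @export
reference_means <- function(stack, denominators) {
  e <- stack$entries
  cells <- unique(e$barcode)
  denom_sum <- sum(denominators[cells])
  tot <- rowsum(as.double(e$umi), group = e$gene)
  out <- 1000 * tot[, 1] / denom_sum
  names(out) <- rownames(tot)
  out
}

#' Per-cell log2 fold changes against the reference mean
#'
#' `log2fc(g, c) = log2(upt(g, c) / ref_mean(g))`, defined only on
#' data-positive entries.
#'
#' @param upt_stack data.frame from [compute_upt()].
#' @param ref_mean named vector from [reference_means()].
#' @return data.frame `gene`, `barcode`, `log2fc`.
#' @export
compute_log2fc <- function(upt_stack, ref_mean) {
  rm_ <- ref_mean[as.character(upt_stack$gene)]
  if (any(is.na(rm_))) stop("missing reference mean for a gene in the stack")
  data.frame(gene = upt_stack$gene, barcode = upt_stack$barcode,
             log2fc = log2(upt_stack$upt / unname(rm_)))
}

# closed-form / small-iteration ML fits of candidate positive families
.fit_family <- function(x, family) {
  switch(family,
    gaussian_log = {
      lx <- log(x)
      list(q = function(p) exp(stats::qnorm(p, mean(lx), stats::sd(lx))))
    },
    gamma = {
      m <- mean(x); v <- stats::var(x)
      a <- m^2 / v                       # moment start
      s <- log(m) - mean(log(x))
      for (i in 1:25) {                  # Newton on log(a) - digamma(a) = s
        f <- log(a) - digamma(a) - s
        a <- max(a - f / (1 / a - trigamma(a)), 1e-8)
      }
      list(q = function(p) stats::qgamma(p, shape = a, rate = a / m))
    },
    inverse_gaussian = {
      mu <- mean(x)
      lambda <- length(x) / sum(1 / x - 1 / mu)
      list(q = function(p) statmod::qinvgauss(p, mean = mu, shape = lambda))
    },
    stop("unknown family: ", family))
}

#' GLM linear-predictor expression scores
#'
#' Transforms UPT rates into gene-wise linear-predictor scores that are
#' approximately standard normal within each gene, so they can feed
#' latent-variable extraction. A positive exponential-family model is first
#' chosen library-wide: each candidate (gamma with log link,
#' inverse-Gaussian with log link, Gaussian on log rates) is fit by maximum
#' likelihood to the pooled positive UPT values and scored by the mean
#' squared deviation between model and empirical log quantiles; the best
#' family wins. Per gene, the score is the link-scale deviation from the
#' gene's reference level, standardised by the gene's estimated dispersion:
#' `z = (log upt - eta_g) / s_g`. The anchor `eta_g` is the link of the
#' gene's pseudo-bulk reference mean when `ref_mean` is supplied (the
#' pipeline path: scores then carry the presence signal of sparsely
#' expressed genes, since an expressing cell sits far above a reference
#' that pools the whole library), or the gene's fitted intercept over
#' expressing cells otherwise. Per-gene dispersions are moderated towards
#' the library-wide median (5 pseudo-observations), so sparsely supported
#' genes cannot draw exploding scores from chance-small scale estimates.
#' Genes expressed in a single cell (no dispersion estimable) and
#' zero-variance genes score 0 and are flagged.
#'
#' @param upt_stack data.frame from [compute_upt()].
#' @param ref_mean optional named vector from [reference_means()] used as
#'   the link-scale anchor.
#' @param family `"auto"` (default: select by the quantile criterion) or one
#'   of `"gaussian_log"`, `"gamma"`, `"inverse_gaussian"`.
#' @return An object of class `btheta_scores`: data.frame `scores`
#'   (`gene`, `barcode`, `btheta`), the chosen `family`, the per-family
#'   `criterion` values, and `flagged` gene indices (single-cell or
#'   degenerate genes).
#' @export
fit_btheta <- function(upt_stack, ref_mean = NULL,
                       family = c("auto", "gaussian_log", "gamma",
                                  "inverse_gaussian")) {
  family <- match.arg(family)
  x <- upt_stack$upt
  if (!length(x)) stop("empty UPT support")
  candidates <- c("gaussian_log", "gamma", "inverse_gaussian")
  qs <- seq(0.01, 0.99, by = 0.01)
  emp <- log(stats::quantile(x, qs, type = 8))
  crit <- vapply(candidates, function(fam) {
    fit <- tryCatch(.fit_family(x, fam), error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    mean((log(fit$q(qs)) - emp)^2)
  }, numeric(1))
  chosen <- if (family == "auto") candidates[which.min(crit)] else family
  g <- upt_stack$gene
  lx <- log(x)
  n_g <- tabulate(g)
  mean_g <- rowsum(x, g)[, 1] / n_g[n_g > 0]
  idx_g <- as.integer(rownames(rowsum(x, g)))
  mu <- numeric(max(g)); mu[idx_g] <- mean_g
  # link-scale centre and dispersion scale per gene, by family
  if (chosen == "gaussian_log") {
    eta <- numeric(max(g))
    eta[idx_g] <- rowsum(lx, g)[, 1] / n_g[idx_g]
    ss <- rowsum((lx - eta[g])^2, g)[, 1]
    s2 <- numeric(max(g))
    s2[idx_g] <- ifelse(n_g[idx_g] > 1, ss / pmax(n_g[idx_g] - 1, 1), 0)
  } else {
    eta <- log(pmax(mu, .Machine$double.xmin))
    if (chosen == "gamma") {
      # Pearson dispersion of the gamma GLM; Var(log X) ~ dispersion
      ss <- rowsum((x / mu[g] - 1)^2, g)[, 1]
    } else {
      # inverse-Gaussian unit deviance-based dispersion; Var(log X) ~ phi * mu
      ss <- rowsum((x - mu[g])^2 / (mu[g]^2 * x), g)[, 1] * mu[idx_g]
    }
    s2 <- numeric(max(g))
    s2[idx_g] <- ifelse(n_g[idx_g] > 1, ss / pmax(n_g[idx_g] - 1, 1), 0)
  }
  if (!is.null(ref_mean)) {
    anchor <- log(ref_mean[as.character(idx_g)])
    if (anyNA(anchor)) stop("missing reference mean for a gene in the stack")
    eta[idx_g] <- anchor
  }
  # moderate the per-gene dispersion towards the library-wide value: genes
  # supported by a handful of cells otherwise draw near-zero scale estimates
  # by chance and their scores explode
  n0 <- 5
  informative <- n_g[idx_g] > 1 & s2[idx_g] > 0
  s0_sq <- if (any(informative)) stats::median(s2[idx_g][informative]) else 0
  df_g <- pmax(n_g - 1, 0)
  s2_mod <- ifelse(df_g > 0, (df_g * s2 + n0 * s0_sq) / (df_g + n0), 0)
  s <- sqrt(s2_mod)
  z <- ifelse(n_g[g] > 1 & s2[g] > 0, (lx - eta[g]) / s[g], 0)
  flagged <- idx_g[n_g[idx_g] == 1 | s2[idx_g] == 0]
  structure(list(scores = data.frame(gene = g, barcode = upt_stack$barcode,
                                     btheta = z),
                 family = chosen, criterion = crit, flagged = flagged),
            class = "btheta_scores")
}

#' @export
print.btheta_scores <- function(x, ...) {
  cat(sprintf("btheta_scores: %d entries, family '%s' (criterion %.4g), %d flagged gene(s)\n",
              nrow(x$scores), x$family, x$criterion[[x$family]],
              length(x$flagged)))
  invisible(x)
}

#' Within-cluster gene representation rates
#'
#' The fraction of a cluster's cells carrying at least one UMI of each gene:
#' `rate = n_expressing / n_cells`. This is the one place where absence is
#' materialised -- genes absent from a cluster get an explicit rate of 0.
#'
#' @param stack a (focused) [count_stack()].
#' @param clusters cluster labels for the stack's barcode axis: a vector of
#'   length `n_barcodes` (or a named vector over barcode ids). Barcodes with
#'   `NA` label are ignored.
#' @return An object of class `representation_table`: matrices `rate` and
#'   `n_expressing` (genes x clusters, rows = gene axis indices) and the
#'   per-cluster cell counts `n_cells`.
#' @export
representation_rates <- function(stack, clusters) {
  if (!is.null(names(clusters)))
    clusters <- clusters[match(stack$barcode_ids, names(clusters))]
  if (length(clusters) != stack$n_barcodes)
    stop("clusters must label the stack's barcode axis")
  cl <- if (is.factor(clusters)) clusters else factor(clusters)
  n_cells <- table(cl)
  if (any(n_cells == 0)) stop("cluster with zero cells")
  e <- stack$entries
  keep <- !is.na(cl[e$barcode])
  ne <- matrix(0L, nrow = stack$n_genes, ncol = nlevels(cl),
               dimnames = list(NULL, levels(cl)))
  if (any(keep)) {
    tab <- table(factor(e$gene[keep], levels = seq_len(stack$n_genes)),
                 cl[e$barcode[keep]])
    ne[, colnames(tab)] <- as.integer(tab)
  }
  rate <- sweep(ne, 2, as.numeric(n_cells), "/")
  structure(list(rate = rate, n_expressing = ne,
                 n_cells = stats::setNames(as.integer(n_cells), levels(cl))),
            class = "representation_table")
}

#' Score a focused count stack
#'
#' Orchestrates the normalisation layer: UPT rates against full-library
#' denominators, pseudo-bulk reference means, log2 fold changes, and GLM
#' linear-predictor scores, all on the identical data-positive support.
#'
#' @param focused a focused [count_stack()].
#' @param denominators per-barcode full-library totals aligned to
#'   `focused`'s barcode axis.
#' @param family passed to [fit_btheta()].
#' @return An object of class `score_set` with elements `upt`, `log2fc`,
#'   `btheta` (triplet data.frames on the same support), `ref_mean`,
#'   `family`, `flagged`, and the axis dictionaries.
#' @export
score_set <- function(focused, denominators, family = "auto") {
  upt <- compute_upt(focused, denominators)
  ref <- reference_means(focused, denominators)
  l2 <- compute_log2fc(upt, ref)
  bt <- fit_btheta(upt, ref_mean = ref, family = family)
  structure(list(upt = upt, log2fc = l2, btheta = bt$scores,
                 ref_mean = ref, family = bt$family, flagged = bt$flagged,
                 gene_ids = focused$gene_ids, barcode_ids = focused$barcode_ids,
                 n_genes = focused$n_genes, n_barcodes = focused$n_barcodes),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set: %d entries over %d genes x %d barcodes (family '%s')\n",
              nrow(x$upt), x$n_genes, x$n_barcodes, x$family))
  invisible(x)
}
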