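# Fixtures and brute-force oracles shared across the suite. Oracles are
# written independently of the package's code paths.

toy_stack <- function() {
  count_stack(data.frame(gene = c(1L, 1L, 2L, 3L),
                         barcode = c(1L, 2L, 1L, 2L),
                         umi = c(3L, 1L, 2L, 5L)),
              gene_ids = c("gA", "gB", "gC"),
              barcode_ids = c("bc1", "bc2"))
}

rand_stack <- function(seed, G = 20, C = 15, density = 0.3, max_umi = 6) {
  set.seed(seed)
  n <- round(G * C * density)
  cells <- sample(G * C, n)
  count_stack(data.frame(gene = (cells - 1L) %/% C + 1L,
                         barcode = (cells - 1L) %% C + 1L,
                         umi = sample(max_umi, n, replace = TRUE)),
              gene_ids = sprintf("g%03d", 1:G),
              barcode_ids = sprintf("c%03d", 1:C))
}

dense_from_stack <- function(stack) {
  m <- matrix(0, stack$n_genes, stack$n_barcodes)
  e <- stack$entries
  m[cbind(e$gene, e$barcode)] <- e$umi
  m
}

# reduced simulation for module-level tests (fast; acceptance uses defaults)
small_cfg <- function(seed) {
  sim_config(n_cell_types = 3, cells_per_type = 60,
             n_signature_genes_per_type = 15, n_constitutive = 15,
             n_rare = 500, n_null_facultative = 400, seed = seed)
}

# Lance-Williams agglomeration with the Ward criterion on non-squared
# Euclidean distances (the ward.D2 update), brute force
ward_oracle <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]; b <- active[j]
      h <- d2[a, b]
      if (h < bh) { bh <- h; best <- c(b = a, a = b) }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, sqrt(bh))
    # Lance-Williams update for ward.D2 on squared distances
    for (c_ in setdiff(active, c(a, b))) {
      nab <- size[a] + size[b] + size[c_]
      d2[c_, a] <- d2[a, c_] <-
        ((size[a] + size[c_]) * d2[a, c_] + (size[b] + size[c_]) * d2[b, c_] -
           size[c_] * d2[a, b]) / nab
    }
    size[a] <- size[a] + size[b]
    active <- setdiff(active, b)
  }
  heights
}

# textbook neighbor-joining on a distance matrix; returns, for 4 taxa, the
# taxon paired with taxon 1 in the single internal split
nj_oracle_pairing <- function(D) {
  stopifnot(nrow(D) == 4)
  labs <- rownames(D)
  # for 4 taxa the NJ criterion groups the pair (i,j) minimising
  # Q(i,j) = 2 d(i,j) - sum_k d(i,k) - sum_k d(j,k)
  best <- NULL; bq <- Inf
  for (i in 1:3) for (j in (i + 1):4) {
    q <- 2 * D[i, j] - sum(D[i, ]) - sum(D[j, ])
    if (q < bq) { bq <- q; best <- c(i, j) }
  }
  if (1 %in% best) labs[setdiff(best, 1)] else
    labs[setdiff(1:4, c(1, best))][1]  # 1 pairs with the remaining taxon
}

# planted three-band coverage profile with known regime labels
planted_regime_profile <- function(seed, n_rare = 2000, n_fac = 800,
                                   n_const = 60) {
  set.seed(seed)
  rare <- rpois(n_rare, 2)
  rare <- rare[rare > 0]
  fac <- round(rlnorm(n_fac, log(300), 0.6))
  fac <- pmax(pmin(fac, 4000), 30)
  const <- round(rlnorm(n_const, log(30000), 0.4))
  totals <- c(rare, fac, const)
  labels <- rep(c("rare", "fac", "const"),
                c(length(rare), length(fac), length(const)))
  idx <- seq_along(totals)
  o <- order(-totals, idx)
  prof <- data.frame(index = idx[o], id = as.character(idx[o]),
                     total = totals[o])
  prof$rank <- seq_len(nrow(prof))
  tie_n <- table(prof$total)
  prof$n_tied <- as.integer(tie_n[as.character(prof$total)])
  list(profile = structure(prof, axis = "gene", total_umi = sum(totals),
                           class = c("coverage_profile", "data.frame")),
       labels = labels)
}

# constructed stratification fixture: planted log2 fold changes with full
# representation, so the ladder is exercised at the value level
make_ladder_fixture <- function(seed, n_sig = 50, n_weak = 200, n_null = 500,
                                k = 5, cells_per = 40, sig_lfc = 3,
                                weak_lfc = log2(1.2), noise_sd = 0.5) {
  set.seed(seed)
  G <- n_sig + n_weak + n_null
  C <- k * cells_per
  cluster <- rep(seq_len(k), each = cells_per)
  own <- integer(G)
  own[seq_len(n_sig)] <- (seq_len(n_sig) - 1L) %% k + 1L
  own[n_sig + seq_len(n_weak)] <- (seq_len(n_weak) - 1L) %% k + 1L
  shift <- c(rep(sig_lfc, n_sig), rep(weak_lfc, n_weak), rep(0, n_null))
  y <- matrix(rnorm(G * C, 0, noise_sd), G, C)
  for (g in which(own > 0)) {
    y[g, cluster == own[g]] <- y[g, cluster == own[g]] + shift[g]
  }
  gene <- rep(seq_len(G), times = C)
  barcode <- rep(seq_len(C), each = G)
  lfc <- as.numeric(y[cbind(gene, barcode)])
  scores <- structure(list(
    upt = data.frame(gene = gene, barcode = barcode, upt = 2^lfc),
    log2fc = data.frame(gene = gene, barcode = barcode, log2fc = lfc),
    btheta = data.frame(gene = gene, barcode = barcode,
                        btheta = lfc / noise_sd),
    ref_mean = stats::setNames(rep(1, G), seq_len(G)),
    family = "gaussian_log", flagged = integer(),
    gene_ids = sprintf("g%04d", seq_len(G)),
    barcode_ids = sprintf("c%04d", seq_len(C)),
    n_genes = G, n_barcodes = C), class = "score_set")
  stack <- count_stack(data.frame(gene = gene, barcode = barcode, umi = 1L),
                       gene_ids = sprintf("g%04d", seq_len(G)),
                       barcode_ids = sprintf("c%04d", seq_len(C)))
  list(scores = scores, stack = stack,
       clusters = as.character(cluster),
       sig = seq_len(n_sig), weak = n_sig + seq_len(n_weak),
       null = n_sig + n_weak + seq_len(n_null))
}
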