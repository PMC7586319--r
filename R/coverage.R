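#' Total UMI coverage per gene or per barcode
#'
#' Exact marginal sums of the count stack along one axis. Items with zero
#' total (never observed) are excluded. The profile is ranked by descending
#' total with ties broken by original index (stable, reproducible), and the
#' number of items sharing each ranking position's total is recorded -- the
#' z-axis of the knee plot.
#'
#' @param stack a [count_stack()].
#' @param axis `"gene"` or `"barcode"`.
#' @return An object of class `coverage_profile`: a data.frame with columns
#'   `index`, `id`, `total`, `rank`, `n_tied`, ordered by rank, plus
#'   attributes `axis` and `total_umi`.
#' @export
total_coverage <- function(stack, axis = c("gene", "barcode")) {
  axis <- match.arg(axis)
  e <- stack$entries
  idx <- if (axis == "gene") e$gene else e$barcode
  ids <- if (axis == "gene") stack$gene_ids else stack$barcode_ids
  if (nrow(e)) {
    tot <- rowsum(as.double(e$umi), group = idx)
    index <- as.integer(rownames(tot))
    total <- tot[, 1]
  } else {
    index <- integer()
    total <- numeric()
  }
  o <- order(-total, index)
  df <- data.frame(index = index[o], id = as.character(ids)[index[o]],
                   total = total[o])
  df$rank <- seq_len(nrow(df))
  tie_n <- table(df$total)
  df$n_tied <- as.integer(tie_n[as.character(df$total)])
  structure(df, axis = axis, total_umi = sum(total),
            class = c("coverage_profile", "data.frame"))
}

# geometric thinning of candidate admission cutoffs: all unique observed
# totals when few, otherwise <= n_cutoffs log-spaced unique values
.default_cutoff_grid <- function(totals, n_cutoffs = 200, min_admitted = 50) {
  u <- sort(unique(totals))
  # a cutoff admits items with total > cutoff; never exhaust the data
  ok <- vapply(u, function(c) sum(totals > c) >= min_admitted, logical(1))
  u <- u[ok]
  cand <- c(0, u)
  if (length(cand) > n_cutoffs) {
    lg <- log(cand + 1)
    want <- seq(min(lg), max(lg), length.out = n_cutoffs)
    keep <- unique(vapply(want, function(w) which.min(abs(lg - w)), integer(1)))
    cand <- cand[keep]
  }
  cand
}

#' Parametric sweep over rising admission cutoffs
#'
#' Re-fits the coverage mixture (both the two-component model and the
#' heavy-tailed Frechet projection) at each admission cutoff of a rising
#' grid, records the best-fit parameter traces, and flags "spikes": cutoffs
#' where any scale or shape parameter jumps by more than `spike_factor`
#' relative to the previous cutoff, or where a fit fails to converge. Spikes
#' mark steep transitions between coverage regimes; the windows of
#' spike-free cutoffs between them are the stable regimes used by
#' [infer_regimes()].
#'
#' @param profile a [total_coverage()] profile (or numeric totals).
#' @param cutoff_grid strictly increasing admission cutoffs; by default the
#'   unique observed totals thinned geometrically to at most `n_cutoffs`
#'   values.
#' @param n_cutoffs grid size cap for the default grid.
#' @param spike_factor multiplicative jump (default 2) beyond which a
#'   parameter step is flagged.
#' @param n_quantiles,n_starts passed to [fit_pcpd()]; each cutoff also
#'   warm-starts from the previous cutoff's best fit.
#' @param seed master seed; cutoff `j` uses `seed + j`, so the whole trace
#'   is reproducible.
#' @param min_admitted minimum items a cutoff must admit; the grid is
#'   truncated (with a warning) once the data are exhausted.
#' @return An object of class `pcpd_sweep`: `trace` (one row per cutoff
#'   with both models' parameters, losses and convergence flags),
#'   `spike_flags` (logical matrix, cutoffs x parameters), `spike` (per
#'   cutoff any-flag), `stable_windows` (list of index ranges), `fits`
#'   (list of the per-cutoff `pcpd_fit` pairs).
#' @export
parametric_sweep <- function(profile, cutoff_grid = NULL, n_cutoffs = 200,
                             spike_factor = 2, n_quantiles = 199,
                             n_starts = 4, seed = 1, min_admitted = 50) {
  totals <- if (inherits(profile, "coverage_profile")) profile$total else as.numeric(profile)
  if (is.null(cutoff_grid))
    cutoff_grid <- .default_cutoff_grid(totals, n_cutoffs, min_admitted)
  if (is.unsorted(cutoff_grid, strictly = TRUE))
    stop("cutoff_grid must be strictly increasing")
  feasible <- vapply(cutoff_grid, function(c) sum(totals > c) >= min_admitted,
                     logical(1))
  if (!all(feasible)) {
    warning("cutoff grid exhausts the data; trace truncated to ",
            sum(feasible), " cutoffs")
    cutoff_grid <- cutoff_grid[feasible]
  }
  if (!length(cutoff_grid)) stop("no feasible cutoffs")
  fits <- vector("list", length(cutoff_grid))
  prev <- NULL
  prev_h <- NULL
  for (j in seq_along(cutoff_grid)) {
    fit <- fit_pcpd(totals, min_cutoff = cutoff_grid[j], model = "pcpd_mixture",
                    n_quantiles = n_quantiles, n_starts = n_starts,
                    seed = seed + j, init = prev)
    hfit <- fit_pcpd(totals, min_cutoff = cutoff_grid[j], model = "heavy_frechet",
                     n_quantiles = n_quantiles, n_starts = n_starts,
                     seed = seed + j, init = prev_h)
    fits[[j]] <- list(pcpd = fit, heavy = hfit)
    prev <- fit
    prev_h <- hfit
  }
  pmat <- t(vapply(fits, function(f)
    c(f$pcpd$par[1:4], h_scale_d = unname(f$heavy$par["scale_d"]),
      h_shape_d = unname(f$heavy$par["shape_d"])), numeric(6)))
  trace <- data.frame(cutoff = cutoff_grid,
                      n_admitted = vapply(cutoff_grid,
                                          function(c) sum(totals > c), numeric(1)),
                      pmat,
                      weight_c = vapply(fits, function(f) f$pcpd$par[["weight_c"]],
                                        numeric(1)),
                      loss = vapply(fits, function(f) f$pcpd$loss, numeric(1)),
                      converged = vapply(fits, function(f) f$pcpd$converged,
                                         logical(1)),
                      h_loss = vapply(fits, function(f) f$heavy$loss, numeric(1)),
                      h_converged = vapply(fits, function(f) f$heavy$converged,
                                           logical(1)))
  lr <- abs(apply(log(pmat), 2, function(col) c(0, diff(col))))
  spike_flags <- lr > log(spike_factor)
  # a component carrying (essentially) no mixture weight has unidentifiable
  # parameters; their drift is not a solver instability, so jumps only count
  # when the component holds weight on both sides of the step
  w <- trace$weight_c
  w_lag <- c(w[1], w[-length(w)])
  c_masked <- pmin(w, w_lag) < 0.05
  d_masked <- pmin(1 - w, 1 - w_lag) < 0.05
  spike_flags[c_masked, c("scale_c", "shape_c")] <- FALSE
  spike_flags[d_masked, c("scale_d", "shape_d")] <- FALSE
  spike_flags[!trace$converged | !trace$h_converged, ] <- TRUE
  spike <- rowSums(spike_flags) > 0
  stable <- .runs(!spike)
  structure(list(trace = trace, spike_flags = spike_flags, spike = spike,
                 stable_windows = stable, fits = fits,
                 spike_factor = spike_factor),
            class = "pcpd_sweep")
}

# maximal runs of TRUE as list of c(from, to) index pairs
.runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(c, starts[r$values], ends[r$values])
}

#' @export
print.pcpd_sweep <- function(x, ...) {
  cat(sprintf("pcpd_sweep: %d cutoffs (%g ... %g), %d spike(s), %d stable window(s)\n",
              nrow(x$trace), min(x$trace$cutoff), max(x$trace$cutoff),
              sum(x$spike), length(x$stable_windows)))
  invisible(x)
}

#' @export
plot.pcpd_sweep <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$cutoff + 1, tr[, c("scale_c", "shape_c", "scale_d",
                                          "shape_d", "h_scale_d", "h_shape_d")],
                    type = "l", log = "xy", lty = 1,
                    xlab = "admission cutoff + 1", ylab = "best-fit parameter",
                    ...)
  if (any(x$spike))
    graphics::abline(v = tr$cutoff[x$spike] + 1, col = "grey80", lty = 3)
  invisible(x)
}

# element-wise consensus over a window of fits: geometric mean for scales
# and shapes, arithmetic mean for the mixing weight
.window_consensus <- function(fits, idx) {
  pc <- t(vapply(fits[idx], function(f) f$pcpd$par, numeric(5)))
  hv <- t(vapply(fits[idx], function(f)
    f$heavy$par[c("scale_d", "shape_d")], numeric(2)))
  par <- c(exp(colMeans(log(pc[, 1:4, drop = FALSE]))), mean(pc[, 5]))
  names(par) <- c("scale_c", "shape_c", "scale_d", "shape_d", "weight_c")
  heavy <- exp(colMeans(log(hv)))
  names(heavy) <- c("scale_d", "shape_d")
  list(par = par, heavy = heavy)
}

#' Project coverage regime boundaries from a parametric sweep
#'
#' Combines the best-fit mixture parameters of the widest spike-free window
#' of the sweep into regime boundaries: the lower bound of the middle
#' (facultative / singlet) regime is the smallest integer coverage at which
#' the posterior responsibility of the dominant (Frechet) component reaches
#' 0.5, i.e. `(1 - w) f_Frechet(x) >= w f_Weibull(x)`; the upper bound is
#' the smallest integer coverage whose survival under the heavy-tailed
#' Frechet projection drops to `1/N` (one expected exceedance among the `N`
#' items admitted at the window's cutoff). Items are then partitioned into
#' low / mid / high regimes (rare / facultative / constitutive for genes;
#' ambient / singlet / multiplet for barcodes).
#'
#' @details
#' The two bounds are projected from the two stable fits that flank the
#' middle regime. The *lower* bound uses the earliest stable window (the
#' fit that still sees the low-coverage band, so the Weibull component
#' describes it): the first integer coverage where the dominant component's
#' posterior responsibility reaches 0.5. The *upper* bound uses the last
#' stable window (the fit admitting only the upper coverages, where the
#' Weibull component describes the top of the middle band and the Frechet
#' component the high regime): again the responsibility crossover, accepted
#' only if it falls above that window's own admission cutoff; otherwise the
#' heavy-tailed projection's `1/N` survival quantile is used (`N` the items
#' admitted at the window's first cutoff -- coverages rarer than one
#' expected exceedance belong to the high regime).
#'
#' @param sweep a [parametric_sweep()] result.
#' @param profile the [total_coverage()] profile the sweep was run on.
#' @return An object of class `regime_partition`: `axis`, `lower_bound`,
#'   `upper_bound`, index vectors `low_set`, `mid_set`, `high_set` (indices
#'   on the stack's axis), and `provenance` (the two flanking windows and
#'   their consensus parameters).
#' @export
infer_regimes <- function(sweep, profile) {
  if (!length(sweep$stable_windows))
    stop("no spike-free window in the sweep; re-run with a manual cutoff_grid ",
         "or larger spike_factor")
  win_lo <- sweep$stable_windows[[1]]
  win_hi <- sweep$stable_windows[[length(sweep$stable_windows)]]
  cons_lo <- .window_consensus(sweep$fits, seq(win_lo[1], win_lo[2]))
  cons_hi <- .window_consensus(sweep$fits, seq(win_hi[1], win_hi[2]))
  max_total <- max(profile$total)
  xs <- seq_len(max_total)
  crossover <- function(par) {
    w <- par[["weight_c"]]
    resp <- (1 - w) * dfrechet(xs, par[["scale_d"]], par[["shape_d"]]) >=
      w * stats::dweibull(xs, shape = par[["shape_c"]], scale = par[["scale_c"]])
    if (any(resp)) xs[which(resp)[1]] else NA_integer_
  }
  # lower bound: dominant-component responsibility crossover of the earliest
  # window; if that fit carries no meaningful common component, fall back to
  # the spike cutoff flanking the middle-regime window on the left
  lo_x <- if (cons_lo$par[["weight_c"]] > 0.01) crossover(cons_lo$par) else NA
  lower <- if (!is.na(lo_x) && lo_x > 1) lo_x
           else max(1, sweep$trace$cutoff[win_hi[1]] + 1)
  N <- sweep$trace$n_admitted[win_hi[1]]
  same_window <- identical(win_lo, win_hi)
  pure_common <- cons_hi$par[["weight_c"]] > 0.999 &&
    cons_lo$par[["weight_c"]] > 0.999
  upper <- if (pure_common) max_total else {
    hi_x <- if (!same_window && cons_hi$par[["weight_c"]] > 0.01 &&
                cons_hi$par[["weight_c"]] < 0.999)
      crossover(cons_hi$par) else NA_integer_
    if (!is.na(hi_x) && hi_x > max(lower, sweep$trace$cutoff[win_hi[1]])) hi_x else {
      # heavy-tailed projection: survival 1 - exp(-(x/s)^-k) <= 1/N
      x_star <- cons_hi$heavy[["scale_d"]] *
        (-log(1 - 1 / N))^(-1 / cons_hi$heavy[["shape_d"]])
      min(ceiling(x_star), max_total)
    }
  }
  lower <- min(lower, upper)
  low <- profile$index[profile$total < lower]
  mid <- profile$index[profile$total >= lower & profile$total <= upper]
  high <- profile$index[profile$total > upper]
  structure(list(axis = attr(profile, "axis"),
                 lower_bound = lower, upper_bound = upper,
                 low_set = low, mid_set = mid, high_set = high,
                 provenance = list(
                   lower_window = sweep$trace$cutoff[seq(win_lo[1], win_lo[2])],
                   upper_window = sweep$trace$cutoff[seq(win_hi[1], win_hi[2])],
                   pcpd = par, pcpd_upper = cons_hi$par,
                   heavy = cons_hi$heavy, n_admitted = N)),
            class = "regime_partition")
}

#' @export
print.regime_partition <- function(x, ...) {
  lab <- if (identical(x$axis, "gene")) c("rare", "facultative", "constitutive")
         else c("ambient", "singlet", "multiplet")
  cat(sprintf("regime_partition (%s axis): bounds [%d, %d]\n", x$axis,
              x$lower_bound, x$upper_bound))
  cat(sprintf("  %s: %d  |  %s: %d  |  %s: %d\n",
              lab[1], length(x$low_set), lab[2], length(x$mid_set),
              lab[3], length(x$high_set)))
  invisible(x)
}

#' Write a regime partition as TSV
#'
#' One row per item with positive total: index, id, total UMI, regime label.
#'
#' @param partition a `regime_partition`.
#' @param profile the matching [total_coverage()] profile.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_partition <- function(partition, profile, path) {
  regime <- ifelse(profile$index %in% partition$mid_set, "mid",
                   ifelse(profile$index %in% partition$high_set, "high", "low"))
  utils::write.table(data.frame(index = profile$index, id = profile$id,
                                total_umi = profile$total, regime = regime),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
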