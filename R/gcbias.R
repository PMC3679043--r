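#' Fixed-width window table of GC and coverage
#'
#' Tiles each non-excluded contig with non-overlapping windows of
#' \code{window_size} bp from the contig start (trailing partial windows
#' discarded), dropping any window that contains an \code{N} base. Per
#' window it reports the GC fraction and the window coverage -- the sum of
#' per-base depth over the window -- plus its log2, the quantity plotted in
#' GC-bias analyses (log2 base coverage in 1 kb windows versus GC content).
#' The log2 is \code{NA} for zero-coverage windows.
#'
#' @param tracks a \code{depth_tracks} object.
#' @param genome the matching \code{genome_model}.
#' @param window_size window width in bp, at least 10 (default 1000).
#' @return an object of classes \code{window_table, data.frame} with columns
#'   \code{contig, start, end, gc_fraction, coverage_sum, log2_coverage}.
#' @export
window_table <- function(tracks, genome, window_size = 1000) {
  stopifnot(inherits(tracks, "depth_tracks"),
            inherits(genome, "genome_model"))
  if (window_size < 10) stop("`window_size` must be >= 10", call. = FALSE)
  ws <- as.integer(window_size)
  lens <- contig_lengths(genome)
  rows <- list()
  for (nm in counted_contigs(genome)) {
    nwin <- lens[[nm]] %/% ws
    if (nwin == 0L) next
    start <- (seq_len(nwin) - 1L) * ws
    end <- start + ws
    has_n <- n_count(genome, nm, start, end) > 0L
    if (all(has_n)) next
    start <- start[!has_n]; end <- end[!has_n]
    gc <- gc_count(genome, nm, start, end) / ws
    cum <- c(0, cumsum(as.numeric(tracks[[nm]])))
    cov <- cum[end + 1L] - cum[start + 1L]
    rows[[nm]] <- data.frame(contig = nm, start = start, end = end,
                             gc_fraction = gc, coverage_sum = cov,
                             log2_coverage = ifelse(cov > 0, log2(cov),
                                                    NA_real_))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               gc_fraction = numeric(0), coverage_sum = numeric(0),
               log2_coverage = numeric(0))
  rownames(df) <- NULL
  structure(df, window_size = ws, class = c("window_table", "data.frame"))
}

#' Loess trend of log2 window coverage on GC
#'
#' Locally weighted regression (tricube weights, degree 1) of
#' \code{log2_coverage} on \code{gc_fraction}, the smoothed curve that
#' represents a platform's local coverage trend across GC content.
#' Zero-coverage windows (log2 undefined) are excluded from the fit; the
#' curve is evaluated on a fixed GC grid restricted to the observed support,
#' never extrapolated.
#'
#' @param table a \code{\link{window_table}} with at least 10 positive-
#'   coverage windows.
#' @param span loess span in \code{(0, 1]}; default 0.3, a conventional
#'   smoothing span (recorded in the result).
#' @param grid_step spacing of the evaluation grid in GC-fraction units
#'   (default 0.005, i.e. half a GC percentage point).
#' @return an object of class \code{loess_curve}: list with \code{gc}
#'   (grid), \code{fitted}, \code{span}, \code{support}, \code{n_windows}.
#' @export
fit_loess <- function(table, span = 0.3, grid_step = 0.005) {
  stopifnot(inherits(table, "window_table"))
  if (span <= 0 || span > 1) stop("`span` must lie in (0, 1]", call. = FALSE)
  d <- table[!is.na(table$log2_coverage) & table$coverage_sum > 0, ,
             drop = FALSE]
  if (nrow(d) < 10) {
    stop("need at least 10 windows with positive coverage", call. = FALSE)
  }
  fit <- stats::loess(log2_coverage ~ gc_fraction, data = d, span = span,
                      degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  support <- range(d$gc_fraction)
  lo <- ceiling(support[1] / grid_step) * grid_step
  hi <- floor(support[2] / grid_step) * grid_step
  gc <- unique(c(support[1], seq(lo, hi, by = grid_step), support[2]))
  gc <- sort(gc)
  fitted <- as.numeric(stats::predict(fit, data.frame(gc_fraction = gc)))
  structure(list(gc = gc, fitted = fitted, span = span,
                 support = support, n_windows = nrow(d)),
            class = "loess_curve")
}

#' @export
print.loess_curve <- function(x, ...) {
  cat(sprintf(paste0("loess_curve: span %.2f, %d windows, GC support ",
                     "[%.3f, %.3f]\n"),
              x$span, x$n_windows, x$support[1], x$support[2]))
  invisible(x)
}

#' Sample fitted values from a loess curve on a regular GC grid
#'
#' Reads the fitted trend at \code{gc_min, gc_min + step, ..., <= gc_max},
#' restricted to the curve's observed support (no extrapolation); these
#' sampled coverage values are the inputs of the regime-restricted
#' Kolmogorov-Smirnov comparisons.
#'
#' @param curve a \code{loess_curve}.
#' @param gc_min,gc_max GC-fraction range to sample.
#' @param step grid step (default 0.005 = half a GC percentage point).
#' @return numeric vector of fitted values.
#' @export
sample_curve <- function(curve, gc_min, gc_max, step = 0.005) {
  stopifnot(inherits(curve, "loess_curve"))
  if (gc_max < gc_min) stop("`gc_max` must be >= `gc_min`", call. = FALSE)
  grid <- seq(gc_min, gc_max, by = step)
  grid <- grid[grid >= min(curve$gc) - 1e-12 & grid <= max(curve$gc) + 1e-12]
  if (!length(grid)) {
    stop("requested GC range does not intersect the curve's support",
         call. = FALSE)
  }
  stats::approx(curve$gc, curve$fitted, xout = grid, rule = 2)$y
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test: statistic \eqn{D = \sup_x |F_A(x) -
#' F_B(x)|} over the pooled empirical CDFs with the asymptotic p-value.
#' Differences with \eqn{p \le 0.05} are reported significant.
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @return list with \code{statistic}, \code{p_value}, \code{significant}.
#' @export
ks_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop("both inputs must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       significant = kt$p.value <= 0.05)
}

#' Regime-restricted GC-bias comparison of two platforms
#'
#' The full GC-bias testing procedure for a platform pair: fit a loess
#' trend to each window table, sample both curves on a common GC grid
#' restricted to the GC-poor regime (at most \code{gc_low}) and to the
#' GC-rich regime (at least \code{gc_high}), and compare the sampled
#' coverage values with a two-sample KS test per regime.
#'
#' @param table_a,table_b \code{\link{window_table}} objects for the two
#'   platforms (same genome).
#' @param span loess span (default 0.3).
#' @param gc_low upper bound of the GC-poor regime (default 0.25).
#' @param gc_high lower bound of the GC-rich regime (default 0.60).
#' @param step sampling grid step (default 0.005).
#' @return data.frame with one row per regime: \code{regime, n_grid,
#'   statistic, p_value, significant}.
#' @export
gc_bias_compare <- function(table_a, table_b, span = 0.3, gc_low = 0.25,
                            gc_high = 0.60, step = 0.005) {
  ca <- fit_loess(table_a, span = span, grid_step = step)
  cb <- fit_loess(table_b, span = span, grid_step = step)
  lo <- max(min(ca$gc), min(cb$gc))
  hi <- min(max(ca$gc), max(cb$gc))
  out <- list()
  regimes <- list(low = c(lo, gc_low), high = c(gc_high, hi))
  for (nm in names(regimes)) {
    rg <- regimes[[nm]]
    if (rg[1] > rg[2]) next
    va <- sample_curve(ca, rg[1], rg[2], step)
    vb <- sample_curve(cb, rg[1], rg[2], step)
    ks <- ks_compare(va, vb)
    out[[nm]] <- data.frame(regime = nm, n_grid = length(va),
                            statistic = ks$statistic, p_value = ks$p_value,
                            significant = ks$significant)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
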