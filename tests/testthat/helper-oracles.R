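# Brute-force reference implementations, deliberately naive and independent
# of the package's vectorised code paths.

# per-base membership count
naive_depth <- function(reads, contig, L) {
  d <- integer(L)
  rows <- reads[reads$contig == contig, , drop = FALSE]
  for (b in seq_len(L) - 1L) {
    d[b + 1L] <- sum(rows$start <= b & b < rows$end)
  }
  d
}

# per-base scan for uncovered runs
naive_uncovered <- function(depth, informative, min_reads) {
  low <- informative & depth < min_reads
  runs <- list()
  b <- 1L
  while (b <= length(low)) {
    if (low[b]) {
      s <- b
      while (b <= length(low) && low[b]) b <- b + 1L
      runs[[length(runs) + 1L]] <- c(s - 1L, b - 1L)
    } else b <- b + 1L
  }
  if (!length(runs)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], end = m[, 2])
}

# KS statistic as the sup over the pooled value grid
naive_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(grid, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# ROC by double loop over thresholds and truth positions
naive_roc <- function(truth, calls) {
  z <- zygosity(truth)
  key_c <- paste(calls$contig, calls$pos)
  per_pos <- function(i) {
    j <- match(paste(truth$contig[i], truth$pos[i]), key_c)
    if (is.na(j)) return(c(FALSE, NA))
    nonref <- calls$a1[j] != truth$ref[i] || calls$a2[j] != truth$ref[i]
    c(nonref, calls$depth[j])
  }
  info <- t(vapply(seq_len(nrow(truth)), per_pos, numeric(2)))
  is_var <- z %in% c("het", "hom_alt")
  is_ref <- z == "hom_ref"
  depths <- info[, 2]
  thresholds <- sort(unique(c(0, depths[info[, 1] == 1 & !is.na(depths)])))
  sens <- fpr <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    nv <- 0L
    nf <- 0L
    for (i in seq_len(nrow(truth))) {
      hit <- !is.na(info[i, 2]) && info[i, 1] == 1 && info[i, 2] >= t
      if (is_var[i] && hit) nv <- nv + 1L
      if (is_ref[i] && hit) nf <- nf + 1L
    }
    sens[k] <- nv / sum(is_var)
    fpr[k] <- nf / sum(is_ref)
  }
  list(thresholds = thresholds, sensitivity = sens, fpr = fpr)
}

# direct trapezoid summation over the anchored, extended point list
naive_auc <- function(fpr, sens) {
  o <- order(fpr, sens)
  x <- c(0, fpr[o], 1)
  y <- c(0, sens[o], if (length(sens)) max(sens) else 0)
  a <- 0
  for (k in seq_len(length(x) - 1L)) {
    a <- a + (x[k + 1L] - x[k]) * (y[k] + y[k + 1L]) / 2
  }
  a
}

# least-squares line evaluated at x0 (closed form)
ols_line <- function(x, y, x0) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  a + b * x0
}
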