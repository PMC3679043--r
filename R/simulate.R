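#' Simulate platform-profiled paired-end reads
#'
#' Draws sequencing fragments from a genome with the statistical structure
#' the downstream analyses probe:
#' \itemize{
#'   \item fragments are sampled proportionally to the profile's GC response
#'     \eqn{w(g)} evaluated on the fragment's GC fraction (full fragment, not
#'     just the sequenced ends), optionally overdispersed per candidate start
#'     position via a gamma multiplier (negative-binomial locus counts);
#'   \item fragments never overlap an \code{N} run -- assembly gaps receive
#'     no reads, matching analyses restricted to the non-N reference;
#'   \item each fragment yields two \code{read_length}-bp mates at its ends,
#'     sharing a \code{pair_id};
#'   \item a \code{duplicate_rate} fraction of fragments is flagged duplicate
#'     and reads starting inside \code{low_mappability} regions lose their
#'     unique-mapping flag with probability \code{1 - repeat_mappability};
#'   \item fragments are generated until the reads surviving
#'     \code{\link{filter_reads}} reach the target mean coverage over the
#'     informative, non-excluded genome, so the realized post-filter mean
#'     matches \code{target_mean_coverage} to within one fragment.
#' }
#' The result is deterministic given all arguments and the seed.
#'
#' @param genome a \code{\link{genome_model}}.
#' @param profile a \code{\link{platform_profile}}.
#' @param target_mean_coverage desired post-filter mean coverage (x).
#' @param low_mappability optional \code{\link{region_set}} of repeat-like
#'   regions with degraded mappability.
#' @param seed integer seed.
#' @return a coordinate-sorted \code{\link{read_set}} tagged with the
#'   profile name.
#' @export
simulate_reads <- function(genome, profile, target_mean_coverage,
                           low_mappability = NULL, seed) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(profile, "platform_profile"))
  if (target_mean_coverage <= 0) {
    stop("`target_mean_coverage` must be positive", call. = FALSE)
  }
  lens <- contig_lengths(genome)
  rl <- profile$read_length
  flm <- as.integer(round(profile$fragment_length_mean))
  inf_len <- informative_length(genome)
  target_bases <- target_mean_coverage * inf_len
  counted <- setdiff(names(lens), genome$excluded_contigs)

  lowmap <- if (!is.null(low_mappability)) {
    regions_to_iranges(merge_intervals(low_mappability))
  } else list()

  with_seed(seed, {
    # Per-contig candidate start positions: the mean-length anchor window
    # [s, s + flm) must fit and be N-free. Sampling weight = w(GC of the
    # anchor window) x gamma overdispersion multiplier.
    cand <- list()
    for (nm in names(lens)) {
      L <- lens[[nm]]
      if (L < flm + 1L) next
      s <- 0:(L - flm)
      ok <- n_count(genome, nm, s, s + flm) == 0L
      s <- s[ok]
      if (!length(s)) next
      g <- gc_count(genome, nm, s, s + flm) / flm
      w <- gc_weight(profile, g)
      if (profile$dispersion > 0) {
        w <- w * stats::rgamma(length(w), shape = 1 / profile$dispersion,
                               rate = 1 / profile$dispersion)
      }
      if (sum(w) > 0) cand[[nm]] <- list(start = s, w = w, total = sum(w))
    }
    if (!length(cand)) stop("no sampleable fragments", call. = FALSE)

    n_needed <- ceiling(target_bases / (2 * rl))
    # oversample for duplicates, mappability loss, and excluded contigs
    infl <- 1 / (1 - profile$duplicate_rate) *
      (sum(lens) / max(1, sum(lens[counted]))) * 1.25 + 0.05
    frags <- list()
    got_bases <- 0
    guard <- 0L
    while (got_bases < target_bases && guard < 50L) {
      guard <- guard + 1L
      n_batch <- max(1000L, ceiling((target_bases - got_bases) /
                                      (2 * rl) * infl))
      batch <- draw_fragment_batch(genome, profile, cand, n_batch, lens,
                                   lowmap)
      if (is.null(batch)) break
      frags[[length(frags) + 1L]] <- batch
      pass <- !batch$dup
      got_bases <- got_bases +
        sum((batch$u1[pass] + batch$u2[pass]) * rl *
              (batch$contig[pass] %in% counted))
    }
    all <- do.call(rbind, lapply(frags, as.data.frame))
    # trim to the first k fragments whose passing reads reach the target
    contrib <- ifelse(all$dup, 0, (all$u1 + all$u2) * rl) *
      (all$contig %in% counted)
    k <- findInterval(target_bases - 1e-9, cumsum(contrib)) + 1L
    k <- min(k, nrow(all))
    all <- all[seq_len(k), , drop = FALSE]

    n <- nrow(all)
    reads <- data.frame(
      contig = rep(all$contig, each = 2L),
      start = as.vector(rbind(all$start, all$end - rl)),
      end = as.vector(rbind(all$start + rl, all$end)),
      pair_id = rep(seq_len(n), each = 2L),
      mate = rep(c(1L, 2L), n),
      is_duplicate = rep(all$dup, each = 2L),
      is_unique = as.vector(rbind(all$u1, all$u2)),
      platform = profile$name)
    reads <- reads[order(reads$contig, reads$start, reads$mate), ,
                   drop = FALSE]
    rownames(reads) <- NULL
    read_set(reads)
  })
}

# Draw one batch of n fragments: returns a list of aligned vectors
# (contig, start, end, dup, u1, u2) or NULL when nothing can be drawn.
draw_fragment_batch <- function(genome, profile, cand, n, lens, lowmap) {
  totals <- vapply(cand, `[[`, numeric(1), "total")
  n_per <- stats::rmultinom(1, n, prob = totals)[, 1]
  rl <- profile$read_length
  out <- list()
  for (i in seq_along(cand)) {
    nm <- names(cand)[i]
    k <- n_per[i]
    if (k == 0L) next
    cc <- cand[[nm]]
    L <- lens[[nm]]
    start <- integer(0); end <- integer(0)
    need <- k
    tries <- 0L
    while (need > 0L && tries < 25L) {
      tries <- tries + 1L
      idx <- sample.int(length(cc$start), need, replace = TRUE, prob = cc$w)
      s <- cc$start[idx]
      fl <- pmax(rl + 1L,
                 as.integer(round(stats::rnorm(need,
                                               profile$fragment_length_mean,
                                               profile$fragment_length_sd))))
      e <- s + fl
      ok <- e <= L
      ok[ok] <- n_count(genome, nm, s[ok], e[ok]) == 0L
      start <- c(start, s[ok]); end <- c(end, e[ok])
      need <- k - length(start)
    }
    if (!length(start)) next
    dup <- stats::runif(length(start)) < profile$duplicate_rate
    u1 <- rep(TRUE, length(start))
    u2 <- rep(TRUE, length(start))
    if (nm %in% names(lowmap)) {
      ir <- lowmap[[nm]]
      in1 <- IRanges::overlapsAny(IRanges::IRanges(start + 1L, start + 1L), ir)
      in2 <- IRanges::overlapsAny(IRanges::IRanges(end - rl + 1L,
                                                   end - rl + 1L), ir)
      u1[in1] <- stats::runif(sum(in1)) < profile$repeat_mappability
      u2[in2] <- stats::runif(sum(in2)) < profile$repeat_mappability
    }
    out[[nm]] <- data.frame(contig = nm, start = start, end = end,
                            dup = dup, u1 = u1, u2 = u2)
  }
  if (!length(out)) return(NULL)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
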