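#' Per-base depth tracks
#'
#' \code{compute_depth} turns filtered read placements into one integer
#' depth vector per contig: \code{depth[b]} is the number of reads whose
#' interval contains base \code{b} (0-based). Overlapping mates of the same
#' pair count twice at the overlapped bases, matching pileup-style per-read
#' counting. Tracks are computed for every contig, including excluded ones
#' and \code{N} bases -- those retain their raw counts and are masked out by
#' the summary functions, so region queries on excluded contigs fail loudly
#' instead of silently returning zeros.
#'
#' @param reads a \code{\link{read_set}}, normally already passed through
#'   \code{\link{filter_reads}}.
#' @param genome a \code{\link{genome_model}}; every read contig must exist.
#' @return an object of class \code{depth_tracks}: a named list with one
#'   integer vector per contig.
#' @export
compute_depth <- function(reads, genome) {
  stopifnot(inherits(reads, "read_set"), inherits(genome, "genome_model"))
  lens <- contig_lengths(genome)
  unknown <- setdiff(unique(reads$contig), names(lens))
  if (length(unknown)) {
    stop("read(s) on unknown contig: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(reads) && any(reads$end > lens[reads$contig])) {
    stop("read interval outside contig bounds", call. = FALSE)
  }
  ctg <- reads$contig
  tracks <- lapply(names(lens), function(nm) {
    L <- lens[[nm]]
    idx <- which(ctg == nm)
    if (!length(idx)) return(integer(L))
    cov <- IRanges::coverage(IRanges::IRanges(start = reads$start[idx] + 1L,
                                              end = reads$end[idx]),
                             width = L)
    as.integer(cov)
  })
  names(tracks) <- names(lens)
  structure(tracks, class = "depth_tracks")
}

#' @export
print.depth_tracks <- function(x, ...) {
  cat("depth_tracks:", length(x), "contig(s)\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s bp, raw mean %.2fx, max %d\n", nm,
                fmt_bp(length(x[[nm]])), mean(x[[nm]]), max(x[[nm]])))
  }
  invisible(x)
}

# logical mask of bases entering summaries, per contig
summary_mask <- function(genome, nm) {
  genome$informative[[nm]]
}

counted_contigs <- function(genome) {
  setdiff(names(genome$contigs), genome$excluded_contigs)
}

#' Mean coverage over informative bases
#'
#' Arithmetic mean of depth over informative (non-N) bases of non-excluded
#' contigs only -- the average-base-coverage convention used after duplicate
#' removal.
#'
#' @param tracks a \code{depth_tracks} object.
#' @param genome the matching \code{genome_model}.
#' @return a single number.
#' @export
mean_coverage <- function(tracks, genome) {
  stopifnot(inherits(tracks, "depth_tracks"),
            inherits(genome, "genome_model"))
  tot <- 0; n <- 0
  for (nm in counted_contigs(genome)) {
    m <- summary_mask(genome, nm)
    if (is.null(tracks[[nm]])) stop("missing track for contig ", nm,
                                    call. = FALSE)
    tot <- tot + sum(as.numeric(tracks[[nm]][m]))
    n <- n + sum(m)
  }
  if (n == 0) stop("zero informative bases", call. = FALSE)
  tot / n
}

#' Coverage histogram
#'
#' Counts of informative, non-excluded bases at each observed depth; the
#' counts sum to the number of informative bases.
#'
#' @param tracks a \code{depth_tracks} object.
#' @param genome the matching \code{genome_model}.
#' @return an object of class \code{coverage_histogram}: data.frame with
#'   columns \code{depth, count} (only depths with positive count) and an
#'   attribute \code{total} with the informative base count.
#' @export
depth_histogram <- function(tracks, genome) {
  stopifnot(inherits(tracks, "depth_tracks"),
            inherits(genome, "genome_model"))
  counts <- numeric(0)
  total <- 0
  for (nm in counted_contigs(genome)) {
    m <- summary_mask(genome, nm)
    d <- tracks[[nm]][m]
    total <- total + length(d)
    if (!length(d)) next
    tab <- tabulate(d + 1L, nbins = max(d) + 1L)
    if (length(tab) > length(counts)) {
      counts <- c(counts, numeric(length(tab) - length(counts)))
    }
    counts[seq_along(tab)] <- counts[seq_along(tab)] + tab
  }
  keep <- which(counts > 0)
  df <- data.frame(depth = keep - 1L, count = counts[keep])
  structure(df, total = total, class = c("coverage_histogram", "data.frame"))
}

#' Build a coverage histogram from explicit counts
#'
#' Constructor used by tests and file readers; \code{\link{depth_histogram}}
#' is the usual entry point.
#'
#' @param depth,count parallel vectors of depth values and base counts.
#' @return a \code{coverage_histogram}.
#' @export
coverage_histogram <- function(depth, count) {
  stopifnot(length(depth) == length(count), all(depth >= 0), all(count >= 0))
  o <- order(depth)
  df <- data.frame(depth = as.integer(depth[o]), count = as.numeric(count[o]))
  structure(df, total = sum(df$count),
            class = c("coverage_histogram", "data.frame"))
}

#' @export
print.coverage_histogram <- function(x, ...) {
  cat(sprintf("coverage_histogram: %s bases, depth range [%d, %d]\n",
              fmt_bp(attr(x, "total")),
              if (nrow(x)) min(x$depth) else 0L,
              if (nrow(x)) max(x$depth) else 0L))
  invisible(x)
}

#' Cumulative coverage curve
#'
#' Fraction of informative bases covered with at least \code{d} reads, for
#' every depth \code{d} from 0 to the maximum observed; the curve starts at
#' 1 and is monotone non-increasing.
#'
#' @param hist a \code{coverage_histogram} with positive total.
#' @return data.frame with columns \code{depth, fraction}.
#' @export
cumulative_coverage <- function(hist) {
  stopifnot(inherits(hist, "coverage_histogram"))
  total <- attr(hist, "total")
  if (is.null(total) || total == 0) stop("empty histogram", call. = FALSE)
  max_d <- if (nrow(hist)) max(hist$depth) else 0L
  counts <- numeric(max_d + 1L)
  counts[hist$depth + 1L] <- hist$count
  # fraction >= d: total minus bases strictly below d
  below <- c(0, cumsum(counts))[seq_len(max_d + 1L)]
  data.frame(depth = 0:max_d, fraction = (total - below) / total)
}

#' Bases covered by fewer than k reads
#'
#' @param hist a \code{coverage_histogram}.
#' @param k threshold, at least 1.
#' @return number of informative bases with depth \code{< k}.
#' @export
bases_below <- function(hist, k) {
  stopifnot(inherits(hist, "coverage_histogram"))
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  sum(hist$count[hist$depth < k])
}
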