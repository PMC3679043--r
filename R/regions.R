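#' Region sets (BED semantics)
#'
#' A \code{region_set} is a named collection of genomic intervals in BED
#' convention: 0-based, half-open \code{[start, end)}. Intervals are kept
#' verbatim (duplicates and overlaps allowed); collapsing to a disjoint
#' cover is an explicit operation, \code{\link{merge_intervals}}.
#'
#' @param intervals data.frame with columns \code{contig, start, end}.
#' @param name label for the set (e.g. \code{"cpg_island"}).
#' @return an object of classes \code{region_set, data.frame}.
#' @export
region_set <- function(intervals, name = "regions") {
  stopifnot(is.data.frame(intervals),
            all(c("contig", "start", "end") %in% names(intervals)))
  df <- data.frame(contig = as.character(intervals$contig),
                   start = as.integer(intervals$start),
                   end = as.integer(intervals$end),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("negative interval start", call. = FALSE)
  if (any(df$start >= df$end)) {
    stop("intervals must satisfy start < end", call. = FALSE)
  }
  structure(df, name = name, class = c("region_set", "data.frame"))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d interval(s), %s bp (un-merged)\n",
              attr(x, "name"), nrow(x), fmt_bp(sum(x$end - x$start))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

region_name <- function(x) attr(x, "name") %||% "regions"
`%||%` <- function(a, b) if (is.null(a)) b else a

# split a region_set into per-contig IRanges (1-based closed, IRanges native)
regions_to_iranges <- function(rs) {
  lapply(split(rs[c("start", "end")], rs$contig),
         function(d) IRanges::IRanges(start = d$start + 1L, end = d$end))
}

#' Extract uncovered regions from depth tracks
#'
#' Returns the maximal runs of consecutive informative bases whose depth
#' falls below \code{min_reads} -- by default fewer than three supporting
#' reads, the minimum at which a heterozygous variant is callable (two
#' non-reference reads to rule out single-read artefacts plus one reference
#' read). \code{N} runs terminate regions rather than joining low-coverage
#' flanks across a gap, and excluded contigs contribute nothing.
#'
#' @param tracks a \code{depth_tracks} object (see \code{\link{compute_depth}}).
#' @param genome the \code{genome_model} the tracks were computed against.
#' @param min_reads depth threshold; a base with depth \code{< min_reads} is
#'   uncovered. Use 1 for the strict zero-read variant.
#' @return a \code{\link{region_set}} of 0-based half-open intervals.
#' @export
uncovered_regions <- function(tracks, genome, min_reads = 3) {
  stopifnot(inherits(tracks, "depth_tracks"),
            inherits(genome, "genome_model"))
  if (min_reads < 1) stop("`min_reads` must be >= 1", call. = FALSE)
  keep <- setdiff(names(genome$contigs), genome$excluded_contigs)
  rows <- list()
  for (nm in keep) {
    depth <- tracks[[nm]]
    if (is.null(depth)) stop("no depth track for contig ", nm, call. = FALSE)
    low <- genome$informative[[nm]] & depth < min_reads
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- r$values
    if (any(sel)) {
      rows[[nm]] <- data.frame(contig = nm, start = starts[sel],
                               end = ends[sel])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0))
  rownames(df) <- NULL
  region_set(df, name = sprintf("uncovered_lt%d", as.integer(min_reads)))
}

#' Size distribution of regions
#'
#' Bins region lengths into \code{[e1,e2), [e2,e3), ..., [ek, Inf)} given
#' strictly increasing \code{bin_edges}; the counts sum to the number of
#' regions (every region length must be at least the first edge).
#'
#' @param regions a \code{\link{region_set}}.
#' @param bin_edges strictly increasing numeric vector of lower bin edges.
#' @return data.frame with columns \code{bin, lower, upper, count}.
#' @export
size_distribution <- function(regions, bin_edges) {
  stopifnot(inherits(regions, "region_set"))
  if (length(bin_edges) < 1 || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  widths <- regions$end - regions$start
  if (length(widths) && any(widths < bin_edges[1])) {
    stop("region shorter than the first bin edge", call. = FALSE)
  }
  idx <- findInterval(widths, bin_edges)
  counts <- tabulate(idx, nbins = length(bin_edges))
  upper <- c(bin_edges[-1], Inf)
  data.frame(bin = sprintf("[%g,%g)", bin_edges, upper),
             lower = bin_edges, upper = upper, count = counts)
}

#' Derive CpG-island shores
#'
#' Shores are the 2 kb flanks immediately upstream and downstream of each
#' CpG island, excluding the island bases themselves, clipped at contig
#' bounds. Flanks of different islands may overlap; they are kept verbatim.
#'
#' @param cpg_islands a \code{\link{region_set}} of islands.
#' @param genome a \code{genome_model} (for contig bounds).
#' @param flank flank width in bp (default 2000).
#' @return a \code{\link{region_set}} named \code{"cpg_shore"}.
#' @export
derive_shores <- function(cpg_islands, genome, flank = 2000) {
  stopifnot(inherits(cpg_islands, "region_set"),
            inherits(genome, "genome_model"), flank > 0)
  lens <- contig_lengths(genome)
  check_regions_within(cpg_islands, lens)
  up <- data.frame(contig = cpg_islands$contig,
                   start = pmax(0L, cpg_islands$start - as.integer(flank)),
                   end = cpg_islands$start)
  down <- data.frame(contig = cpg_islands$contig,
                     start = cpg_islands$end,
                     end = pmin(lens[cpg_islands$contig],
                                cpg_islands$end + as.integer(flank)))
  df <- rbind(up, down)
  df <- df[df$start < df$end, , drop = FALSE]
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  region_set(df, name = "cpg_shore")
}

#' Derive promoter regions from transcription start sites
#'
#' A promoter spans 2 kb upstream through 500 bp downstream of the TSS,
#' orientation given by the strand (upstream is to the left on \code{+},
#' to the right on \code{-}), clipped to contig bounds.
#'
#' @param tss_list data.frame with columns \code{contig, tss, strand}
#'   (\code{tss} 0-based, strand \code{"+"} or \code{"-"}).
#' @param genome a \code{genome_model}.
#' @param up bases upstream of the TSS (default 2000).
#' @param down bases downstream (default 500).
#' @return a \code{\link{region_set}} named \code{"promoter"}.
#' @export
derive_promoters <- function(tss_list, genome, up = 2000, down = 500) {
  stopifnot(is.data.frame(tss_list),
            all(c("contig", "tss", "strand") %in% names(tss_list)),
            inherits(genome, "genome_model"))
  if (!all(tss_list$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  lens <- contig_lengths(genome)
  plus <- tss_list$strand == "+"
  start <- ifelse(plus, tss_list$tss - up, tss_list$tss - down)
  end <- ifelse(plus, tss_list$tss + down, tss_list$tss + up)
  df <- data.frame(contig = tss_list$contig,
                   start = pmax(0, start),
                   end = pmin(lens[tss_list$contig], end))
  df <- df[df$start < df$end, , drop = FALSE]
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  region_set(df, name = "promoter")
}

#' Derive introns from transcript exon structures
#'
#' Introns are the gaps between consecutive exons of one transcript
#' (the complement of the exons within the span from first exon start to
#' last exon end); abutting exons yield no intron, overlapping exons within
#' one transcript are an error.
#'
#' @param transcripts list of transcripts, each a list with elements
#'   \code{contig} and \code{exons} (data.frame \code{start, end}, 0-based
#'   half-open).
#' @return a \code{\link{region_set}} named \code{"intron"}.
#' @export
derive_introns <- function(transcripts) {
  stopifnot(is.list(transcripts))
  rows <- list()
  for (tx in transcripts) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons within one transcript", call. = FALSE)
    }
    if (nrow(ex) > 1) {
      s <- ex$end[-nrow(ex)]
      e <- ex$start[-1]
      keep <- s < e
      if (any(keep)) {
        rows[[length(rows) + 1L]] <-
          data.frame(contig = tx$contig, start = s[keep], end = e[keep])
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0))
  rownames(df) <- NULL
  region_set(df, name = "intron")
}

#' Collapse a region set to disjoint intervals
#'
#' Minimal sorted set of disjoint intervals covering exactly the same bases
#' (so overlapping repeat annotations are reduced and not counted twice).
#' Idempotent.
#'
#' @param regions a \code{\link{region_set}}.
#' @return a \code{\link{region_set}} with the same name.
#' @export
merge_intervals <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  if (nrow(regions) == 0) return(regions)
  ir <- regions_to_iranges(regions)
  rows <- lapply(names(ir), function(nm) {
    red <- IRanges::reduce(ir[[nm]])
    data.frame(contig = nm, start = IRanges::start(red) - 1L,
               end = IRanges::end(red))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  region_set(df, name = region_name(regions))
}

#' Fraction of an element's bases falling in uncovered regions
#'
#' Both sets are collapsed with \code{\link{merge_intervals}} first, so
#' duplicated annotation entries do not double-count; the result is
#' overlap bases / element bases, in \code{[0, 1]}.
#'
#' @param uncovered a \code{\link{region_set}} (typically from
#'   \code{\link{uncovered_regions}}).
#' @param element a \code{\link{region_set}} of annotation intervals;
#'   must contain at least one base.
#' @return a single numeric fraction.
#' @export
fraction_uncovered <- function(uncovered, element) {
  stopifnot(inherits(uncovered, "region_set"), inherits(element, "region_set"))
  el <- merge_intervals(element)
  denom <- sum(el$end - el$start)
  if (denom == 0) stop("element set has zero bases", call. = FALSE)
  un <- merge_intervals(uncovered)
  ir_el <- regions_to_iranges(el)
  ir_un <- regions_to_iranges(un)
  overlap <- 0
  for (nm in intersect(names(ir_el), names(ir_un))) {
    overlap <- overlap +
      sum(IRanges::width(IRanges::intersect(ir_el[[nm]], ir_un[[nm]])))
  }
  overlap / denom
}

#' Two-sample t-test on per-sample uncovered fractions
#'
#' Equal-variance two-sided Student's t-test comparing per-sample fractions
#' between two platforms. Groups of fewer than two samples are refused
#' (no p-value is meaningful there), and the degenerate case of two
#' zero-variance groups with equal means is flagged non-informative.
#'
#' @param fractions_a,fractions_b numeric vectors of per-sample values,
#'   each of length >= 2.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{noninformative}.
#' @export
compare_fractions_ttest <- function(fractions_a, fractions_b) {
  if (length(fractions_a) < 2 || length(fractions_b) < 2) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  va <- stats::var(fractions_a); vb <- stats::var(fractions_b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(fractions_a), mean(fractions_b)))) {
      return(list(statistic = NA_real_,
                  df = length(fractions_a) + length(fractions_b) - 2,
                  p_value = NA_real_, noninformative = TRUE))
    }
    return(list(statistic = Inf * sign(mean(fractions_a) - mean(fractions_b)),
                df = length(fractions_a) + length(fractions_b) - 2,
                p_value = 0, noninformative = FALSE))
  }
  tt <- stats::t.test(fractions_a, fractions_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, noninformative = FALSE)
}
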