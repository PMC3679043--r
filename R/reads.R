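#' Read placement sets
#'
#' A \code{read_set} abstracts aligned, coordinate-level read placements:
#' one row per read with 0-based half-open interval, pairing information
#' (\code{pair_id} shared by mates, \code{NA} for singletons), a PCR/optical
#' duplicate flag and a unique-mapping flag. It is what is left of a BAM
#' after alignment details are stripped: exactly the information the
#' coverage analyses consume.
#'
#' @param df data.frame with columns \code{contig, start, end, pair_id,
#'   mate, is_duplicate, is_unique}; an optional \code{platform} column tags
#'   the source technology (preserved by \code{\link{merge_readsets}}).
#' @return an object of classes \code{read_set, data.frame}.
#' @export
read_set <- function(df) {
  need <- c("contig", "start", "end", "pair_id", "mate",
            "is_duplicate", "is_unique")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (!"platform" %in% names(df)) df$platform <- NA_character_
  df <- df[c(need, "platform")]
  df$contig <- as.character(df$contig)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 0)) stop("negative read start", call. = FALSE)
  if (any(df$start >= df$end)) {
    stop("reads must satisfy start < end", call. = FALSE)
  }
  paired <- !is.na(df$pair_id)
  if (any(paired & !df$mate %in% c(1L, 2L))) {
    stop("paired reads need mate index 1 or 2", call. = FALSE)
  }
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf(paste0("read_set: %d read(s) on %d contig(s); %d duplicate, ",
                     "%d non-unique\n"),
              nrow(x), length(unique(x$contig)),
              sum(x$is_duplicate), sum(!x$is_unique)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Filter a read set for depth analysis
#'
#' Keeps exactly the reads every coverage summary is based on: duplicates
#' removed, only uniquely mapping reads considered. Order is preserved.
#'
#' @param reads a \code{\link{read_set}}.
#' @return the filtered \code{read_set}.
#' @export
filter_reads <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  keep <- which(!reads$is_duplicate & reads$is_unique)
  out <- lapply(unclass(reads), `[`, keep)
  attr(out, "row.names") <- seq_along(keep)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Downsample a read set to a lower mean coverage
#'
#' Random removal of read pairs or singletons: each pair (atomically -- no
#' orphaned mates) and each singleton is retained independently with
#' probability \code{target_mean / current_mean}. An exact-count mode
#' retains exactly the rounded expected number of units instead, for
#' reproducibility studies where the realized coverage must not fluctuate.
#'
#' @param reads a \code{\link{read_set}}.
#' @param current_mean current mean coverage of the set.
#' @param target_mean desired mean coverage; must be positive and no larger
#'   than \code{current_mean}.
#' @param seed integer seed.
#' @param exact if \code{TRUE}, keep exactly \code{round(p * n_units)} units
#'   (sampled without replacement) instead of Bernoulli thinning.
#' @return the thinned \code{read_set}, original order preserved.
#' @export
downsample_reads <- function(reads, current_mean, target_mean, seed,
                             exact = FALSE) {
  stopifnot(inherits(reads, "read_set"))
  if (target_mean <= 0 || target_mean > current_mean) {
    stop("need 0 < target_mean <= current_mean", call. = FALSE)
  }
  stop_if_not_flag(exact, "exact")
  p <- target_mean / current_mean
  if (p == 1) return(reads)
  # sampling units: pairs (by pair_id) and singleton reads
  unit <- ifelse(is.na(reads$pair_id), paste0("s", seq_len(nrow(reads))),
                 paste0("p", reads$pair_id))
  units <- unique(unit)
  with_seed(seed, {
    keep_units <- if (exact) {
      sample(units, round(p * length(units)))
    } else {
      units[stats::runif(length(units)) < p]
    }
    out <- reads[unit %in% keep_units, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Merge read sets from several platforms
#'
#' Multiset union of the input sets, preserving each read's source-platform
#' tag; the depth of the merged set is the element-wise sum of the
#' per-set depths. Pair ids are re-keyed per source so pairs from different
#' sets never collide.
#'
#' @param readsets list of \code{\link{read_set}} objects on the same genome.
#' @param genome optional \code{genome_model}; when given, every read's
#'   contig is checked against it.
#' @return a single \code{read_set}.
#' @export
merge_readsets <- function(readsets, genome = NULL) {
  stopifnot(is.list(readsets), length(readsets) >= 1,
            all(vapply(readsets, inherits, logical(1), "read_set")))
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_model"))
    for (rs in readsets) {
      unknown <- setdiff(unique(rs$contig), names(genome$contigs))
      if (length(unknown)) {
        stop("read on contig absent from genome: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
  }
  offset <- 0L
  parts <- lapply(seq_along(readsets), function(i) {
    rs <- as.data.frame(readsets[[i]])
    if (nrow(rs) && any(!is.na(rs$pair_id))) {
      rs$pair_id <- rs$pair_id + offset
      offset <<- max(rs$pair_id, na.rm = TRUE)
    }
    rs
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  read_set(out)
}
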