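#' Genome model
#'
#' A \code{genome_model} holds the reference sequences the analysis runs
#' against: one or more contigs over the alphabet \code{A,C,G,T,N}, a per-base
#' informative mask (\code{TRUE} where the base is not \code{N}), and a set of
#' excluded contigs that are carried along but masked out of every summary
#' (the treatment conventionally applied to chromosome Y in male/female
#' mixed-sample designs). Cumulative GC and N counts are precomputed at
#' construction so window statistics and fragment sampling are O(1) per query.
#'
#' @param sequences named character vector of contig sequences
#'   (upper-case \code{A,C,G,T,N}).
#' @param excluded_contigs contig names to mask from all downstream summaries.
#' @param blocks optional data.frame (\code{contig,start,end,target_gc})
#'   recording the GC-block layout a simulated genome was built from;
#'   consumed by annotation rules in \code{\link{plant_regions}}.
#' @return an object of class \code{genome_model}.
#' @seealso \code{\link{generate_reference}}
#' @export
genome_model <- function(sequences, excluded_contigs = character(0),
                         blocks = NULL) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("`sequences` must be a named character vector with unique names",
         call. = FALSE)
  }
  if (!all(excluded_contigs %in% names(sequences))) {
    stop("`excluded_contigs` must be a subset of the contig names",
         call. = FALSE)
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("contig(s) ", paste(names(sequences)[bad], collapse = ", "),
         " contain letters outside {A,C,G,T,N}", call. = FALSE)
  }
  if (any(nchar(sequences) == 0L)) stop("zero-length contig", call. = FALSE)

  gc_raw <- charToRaw("GC")
  n_raw <- charToRaw("N")
  informative <- list(); gc_cum <- list(); n_cum <- list()
  for (nm in names(sequences)) {
    r <- charToRaw(sequences[[nm]])
    is_gc <- r %in% gc_raw
    is_n <- r == n_raw
    informative[[nm]] <- !is_n
    # length L+1 cumulative counts: count over [i, j) is cum[j+1] - cum[i+1]
    gc_cum[[nm]] <- c(0, cumsum(as.integer(is_gc)))
    n_cum[[nm]] <- c(0, cumsum(as.integer(is_n)))
  }
  g <- structure(
    list(contigs = sequences,
         excluded_contigs = excluded_contigs,
         blocks = blocks,
         informative = informative,
         gc_cum = gc_cum,
         n_cum = n_cum),
    class = "genome_model")
  if (informative_length(g) == 0) {
    stop("genome has no informative (non-N, non-excluded) bases",
         call. = FALSE)
  }
  g
}

#' @export
print.genome_model <- function(x, ...) {
  lens <- contig_lengths(x)
  cat("genome_model:", length(lens), "contig(s),",
      fmt_bp(sum(lens)), "bp total;",
      fmt_bp(informative_length(x)), "informative bp\n")
  for (nm in names(lens)) {
    gc <- (x$gc_cum[[nm]][lens[[nm]] + 1]) /
      max(1, sum(x$informative[[nm]]))
    cat(sprintf("  %s: %s bp, GC %.3f%s\n", nm, fmt_bp(lens[[nm]]), gc,
                if (nm %in% x$excluded_contigs) " [excluded]" else ""))
  }
  invisible(x)
}

#' Contig lengths of a genome model
#' @param genome a \code{genome_model}.
#' @return named integer vector.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  vapply(genome$contigs, nchar, integer(1))
}

#' Number of informative bases (non-N, non-excluded contigs)
#' @param genome a \code{genome_model}.
#' @return integer count.
#' @export
informative_length <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  keep <- setdiff(names(genome$contigs), genome$excluded_contigs)
  sum(vapply(keep, function(nm) sum(genome$informative[[nm]]), numeric(1)))
}

# GC count over 0-based half-open [start, end) given the genome's cumulative
# table; vectorised over equal-length start/end.
gc_count <- function(genome, contig, start, end) {
  cum <- genome$gc_cum[[contig]]
  cum[end + 1L] - cum[start + 1L]
}

n_count <- function(genome, contig, start, end) {
  cum <- genome$n_cum[[contig]]
  cum[end + 1L] - cum[start + 1L]
}

#' Generate a synthetic reference genome with a planted GC-block structure
#'
#' Builds contigs as a succession of blocks with prescribed target GC
#' fraction; each base is drawn independently (G/C with probability
#' \code{target_gc}, split evenly between G and C, likewise A/T), so realized
#' block GC concentrates around the target (binomial standard error
#' \eqn{\sqrt{g(1-g)/L}} for an \eqn{L}-bp block). Runs of \code{N} can be
#' planted to emulate assembly gaps. The block layout is recorded in the
#' returned model so annotation rules (e.g. "CpG islands are the high-GC
#' blocks") can refer to it.
#'
#' @param n_contigs number of contigs; each uses the same block layout.
#' @param contig_length length of every contig in bp.
#' @param gc_block_spec data.frame with columns \code{length} and \code{gc}
#'   (or a list of \code{c(length, gc)} pairs); the blocks are tiled in order,
#'   recycled until the contig is filled, the last block truncated.
#' @param n_gap_spec optional list of \code{list(start=, length=)} gap
#'   placements (0-based), applied to every contig, or a data.frame with
#'   columns \code{contig,start,length}.
#' @param seed integer seed; generation is deterministic given all arguments.
#' @param excluded_contigs names (of the generated contigs) to mark excluded.
#' @return a \code{\link{genome_model}}.
#' @examples
#' g <- generate_reference(1, 10000,
#'                         gc_block_spec = data.frame(length = 5000,
#'                                                    gc = c(0.35, 0.65)),
#'                         seed = 1)
#' g
#' @export
generate_reference <- function(n_contigs, contig_length, gc_block_spec,
                               n_gap_spec = NULL, seed,
                               excluded_contigs = character(0)) {
  stopifnot(n_contigs >= 1)
  if (length(contig_length) != 1L || contig_length <= 0) {
    stop("`contig_length` must be a single positive number", call. = FALSE)
  }
  spec <- normalize_block_spec(gc_block_spec)
  if (any(spec$gc < 0 | spec$gc > 1)) {
    stop("block target GC must lie in [0, 1]", call. = FALSE)
  }
  if (any(spec$length <= 0)) stop("block lengths must be positive",
                                  call. = FALSE)

  with_seed(seed, {
    contig_names <- paste0("contig", seq_len(n_contigs))
    seqs <- character(n_contigs)
    blocks_all <- vector("list", n_contigs)
    for (i in seq_len(n_contigs)) {
      lay <- tile_blocks(spec, contig_length)
      p <- rep(lay$gc, lay$length)
      is_gc <- stats::runif(contig_length) < p
      pick <- stats::runif(contig_length) < 0.5
      base <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
      seqs[i] <- paste(base, collapse = "")
      blocks_all[[i]] <- data.frame(contig = contig_names[i],
                                    start = lay$start, end = lay$end,
                                    target_gc = lay$gc)
    }
    names(seqs) <- contig_names
    seqs <- apply_n_gaps(seqs, n_gap_spec)
    genome_model(seqs, excluded_contigs = excluded_contigs,
                 blocks = do.call(rbind, blocks_all))
  })
}

normalize_block_spec <- function(gc_block_spec) {
  if (is.data.frame(gc_block_spec)) {
    if (!all(c("length", "gc") %in% names(gc_block_spec))) {
      stop("`gc_block_spec` data.frame needs columns `length` and `gc`",
           call. = FALSE)
    }
    data.frame(length = as.numeric(gc_block_spec$length),
               gc = as.numeric(gc_block_spec$gc))
  } else if (is.list(gc_block_spec)) {
    data.frame(length = vapply(gc_block_spec, function(b) as.numeric(b[[1]]),
                               numeric(1)),
               gc = vapply(gc_block_spec, function(b) as.numeric(b[[2]]),
                           numeric(1)))
  } else {
    stop("`gc_block_spec` must be a data.frame or list of (length, gc) pairs",
         call. = FALSE)
  }
}

# Tile the block spec across one contig: 0-based starts/ends, last block
# truncated at the contig boundary.
tile_blocks <- function(spec, contig_length) {
  reps <- ceiling(contig_length / sum(spec$length))
  len <- rep(spec$length, reps)
  gc <- rep(spec$gc, reps)
  end <- cumsum(len)
  keep <- c(TRUE, end[-length(end)] < contig_length)
  len <- len[keep]; gc <- gc[keep]; end <- end[keep]
  end[length(end)] <- min(end[length(end)], contig_length)
  start <- c(0, end[-length(end)])
  list(start = start, end = end, length = end - start, gc = gc)
}

apply_n_gaps <- function(seqs, n_gap_spec) {
  if (is.null(n_gap_spec)) return(seqs)
  gaps <- if (is.data.frame(n_gap_spec)) {
    n_gap_spec
  } else {
    do.call(rbind, lapply(n_gap_spec, function(gp) {
      data.frame(contig = NA_character_, start = gp$start, length = gp$length)
    }))
  }
  for (k in seq_len(nrow(gaps))) {
    targets <- if (is.na(gaps$contig[k])) names(seqs) else gaps$contig[k]
    for (nm in targets) {
      L <- nchar(seqs[[nm]])
      s <- gaps$start[k]; e <- min(L, s + gaps$length[k])
      if (s < 0 || s >= L) stop("N gap outside contig", call. = FALSE)
      substr(seqs[[nm]], s + 1L, e) <- strrep("N", e - s)
    }
  }
  seqs
}

#' Plant truth genotypes on a synthetic genome
#'
#' Emulates an array-based gold-standard genotype set: variant sites (het or
#' hom-alt) are dropped independently per informative base at
#' \code{density_per_bp}, and additional reference-homozygous sites are
#' assayed at \code{hom_ref_per_bp} (arrays genotype many positions at which
#' any one sample is ref/ref; those positions anchor the false-positive-rate
#' denominator of \code{\link{roc_curve}}). No site falls on an \code{N}
#' base; positions are unique per contig.
#'
#' @param genome a \code{genome_model}.
#' @param density_per_bp per-base probability of a variant site (het or
#'   hom-alt), in \code{[0, 1]}.
#' @param het_fraction fraction of variant sites that are heterozygous.
#' @param seed integer seed.
#' @param hom_ref_per_bp per-base probability of a reference-homozygous
#'   assayed site; defaults to twice the variant density.
#' @return a \code{\link{truth_genotypes}} object: data.frame with columns
#'   \code{contig, pos} (0-based), \code{ref, a1, a2}.
#' @export
plant_variants <- function(genome, density_per_bp, het_fraction, seed,
                           hom_ref_per_bp = 2 * density_per_bp) {
  stopifnot(inherits(genome, "genome_model"))
  if (density_per_bp < 0 || density_per_bp > 1) {
    stop("`density_per_bp` must lie in [0, 1]", call. = FALSE)
  }
  if (het_fraction < 0 || het_fraction > 1) {
    stop("`het_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (hom_ref_per_bp < 0 || hom_ref_per_bp > 1) {
    stop("`hom_ref_per_bp` must lie in [0, 1]", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- list()
    for (nm in names(genome$contigs)) {
      inf <- genome$informative[[nm]]
      L <- length(inf)
      u <- stats::runif(L)
      is_var <- inf & u < density_per_bp
      is_ref <- inf & !is_var & u >= density_per_bp &
        u < density_per_bp + hom_ref_per_bp
      pos <- c(which(is_var), which(is_ref)) - 1L
      if (length(pos) == 0L) next
      variant <- rep(c(TRUE, FALSE), c(sum(is_var), sum(is_ref)))
      ref <- strsplit(substring(genome$contigs[[nm]],
                                min(pos) + 1L, max(pos) + 1L), "")[[1]][
                                  pos - min(pos) + 1L]
      a1 <- ref; a2 <- ref
      nv <- sum(variant)
      if (nv > 0) {
        ref_v <- ref[variant]
        # alternate allele: uniform over the three non-reference bases
        alt <- vapply(ref_v, function(r) sample(setdiff(bases, r), 1L),
                      character(1))
        het <- stats::runif(nv) < het_fraction
        a1[variant] <- ifelse(het, ref_v, alt)
        a2[variant] <- alt
      }
      out[[nm]] <- data.frame(contig = nm, pos = pos, ref = ref,
                              a1 = a1, a2 = a2)
    }
    if (length(out) == 0L) {
      return(truth_genotypes(data.frame(contig = character(0),
                                        pos = integer(0), ref = character(0),
                                        a1 = character(0),
                                        a2 = character(0))))
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df <- df[order(df$contig, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    truth_genotypes(df)
  })
}

#' Plant named annotation tracks on a synthetic genome
#'
#' Emulates the BED annotation catalogues real analyses consume (CpG islands,
#' exons, repeat subclasses, low-mappability masks). Each catalogue entry is
#' either a data.frame of explicit 0-based half-open intervals (retained
#' verbatim; overlaps are not merged here) or a generation rule:
#' \describe{
#'   \item{\code{list(rule = "gc_blocks", min_gc =, max_gc =)}}{the planted
#'     GC blocks of a generated genome whose target GC lies in the given
#'     range -- e.g. high-GC blocks standing in for CpG islands.}
#'   \item{\code{list(rule = "random_intervals", n =, width =, seed =)}}{
#'     \code{n} intervals of fixed width placed uniformly on N-free stretches.}
#' }
#'
#' @param genome a \code{genome_model}.
#' @param catalog_spec named list of entries as described above; an empty
#'   list yields an empty catalogue.
#' @return named list of \code{\link{region_set}} objects.
#' @export
plant_regions <- function(genome, catalog_spec) {
  stopifnot(inherits(genome, "genome_model"), is.list(catalog_spec))
  out <- list()
  lens <- contig_lengths(genome)
  for (nm in names(catalog_spec)) {
    entry <- catalog_spec[[nm]]
    if (is.data.frame(entry)) {
      rs <- region_set(entry, name = nm)
      check_regions_within(rs, lens)
      out[[nm]] <- rs
    } else if (is.list(entry) && identical(entry$rule, "gc_blocks")) {
      if (is.null(genome$blocks)) {
        stop("rule 'gc_blocks' needs a genome with recorded block layout",
             call. = FALSE)
      }
      lo <- if (is.null(entry$min_gc)) 0 else entry$min_gc
      hi <- if (is.null(entry$max_gc)) 1 else entry$max_gc
      b <- genome$blocks
      b <- b[b$target_gc >= lo & b$target_gc <= hi, c("contig", "start", "end")]
      rownames(b) <- NULL
      out[[nm]] <- region_set(b, name = nm)
    } else if (is.list(entry) && identical(entry$rule, "random_intervals")) {
      out[[nm]] <- random_intervals(genome, n = entry$n, width = entry$width,
                                    seed = entry$seed, name = nm)
    } else {
      stop("unrecognised catalogue entry for '", nm, "'", call. = FALSE)
    }
  }
  out
}

check_regions_within <- function(rs, lens) {
  unknown <- setdiff(unique(rs$contig), names(lens))
  if (length(unknown)) {
    stop("interval on unknown contig: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(rs$start < 0 | rs$end > lens[rs$contig])) {
    stop("interval outside contig bounds", call. = FALSE)
  }
  invisible(rs)
}

# Uniform placement of fixed-width intervals on N-free stretches.
random_intervals <- function(genome, n, width, seed, name = "random") {
  stopifnot(n >= 0, width >= 1)
  lens <- contig_lengths(genome)
  with_seed(seed, {
    valid <- lapply(names(lens), function(nm) {
      L <- lens[[nm]]
      if (L < width) return(integer(0))
      s <- 0:(L - width)
      s[n_count(genome, nm, s, s + width) == 0L]
    })
    names(valid) <- names(lens)
    weights <- vapply(valid, length, numeric(1))
    if (sum(weights) == 0) stop("no N-free stretch fits the interval width",
                                call. = FALSE)
    ctg <- sample(names(lens), n, replace = TRUE, prob = weights)
    start <- integer(n)
    for (nm in unique(ctg)) {
      idx <- which(ctg == nm)
      start[idx] <- sample(valid[[nm]], length(idx), replace = TRUE)
    }
    df <- data.frame(contig = ctg, start = start, end = start + width)
    df <- df[order(df$contig, df$start), , drop = FALSE]
    rownames(df) <- NULL
    region_set(df, name = name)
  })
}

#' Random transcription start sites
#'
#' Uniformly placed, strand-assigned TSS list on informative bases; the
#' companion of \code{\link{derive_promoters}} in simulated annotation
#' catalogues.
#'
#' @param genome a \code{genome_model}.
#' @param n number of sites.
#' @param seed integer seed.
#' @return data.frame with columns \code{contig, tss, strand}.
#' @export
random_tss <- function(genome, n, seed) {
  rs <- random_intervals(genome, n = n, width = 1L, seed = seed, name = "tss")
  with_seed(seed + 1L, {
    data.frame(contig = rs$contig, tss = rs$start,
               strand = sample(c("+", "-"), nrow(rs), replace = TRUE))
  })
}
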