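# Readers and writers for the standard interchange formats. All interval
# formats use BED semantics on disk (0-based half-open); position-based
# formats (depth, genotypes) are 1-based on disk, converted at the boundary.

#' Write / read a genome as FASTA
#'
#' @param genome a \code{\link{genome_model}}.
#' @param path output file.
#' @return \code{write_genome_fasta} returns \code{path} invisibly;
#'   \code{read_genome_fasta} returns a \code{genome_model} (block metadata
#'   is not representable in FASTA and is absent).
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  x <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param excluded_contigs contig names to mark excluded on read.
#' @export
read_genome_fasta <- function(path, excluded_contigs = character(0)) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  genome_model(seqs, excluded_contigs = excluded_contigs)
}

#' Write / read a region set as BED
#'
#' Three-column BED: contig, 0-based start, half-open end, tab-separated.
#'
#' @param regions a \code{\link{region_set}}.
#' @param path file path.
#' @return \code{write_bed} returns \code{path} invisibly; \code{read_bed}
#'   a \code{region_set}.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  utils::write.table(as.data.frame(regions)[c("contig", "start", "end")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param name label for the loaded set (defaults to the file stem).
#' @export
read_bed <- function(path, name = sub("\\.bed$", "", basename(path))) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  region_set(df, name = name)
}

#' Write / read a read set in the simplified TSV dialect
#'
#' Columns \code{contig, start, end, pair_id, mate, dup, unique, platform}
#' with a header row; intervals 0-based half-open, flags 0/1.
#'
#' @param reads a \code{\link{read_set}}.
#' @param path file path.
#' @return \code{write_reads_tsv} returns \code{path} invisibly;
#'   \code{read_reads_tsv} a \code{read_set}.
#' @export
write_reads_tsv <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  df <- as.data.frame(reads)
  df$dup <- as.integer(df$is_duplicate)
  df$unique <- as.integer(df$is_unique)
  utils::write.table(df[c("contig", "start", "end", "pair_id", "mate",
                          "dup", "unique", "platform")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "NA",
                          colClasses = c(contig = "character",
                                         platform = "character"))
  read_set(data.frame(contig = df$contig, start = df$start, end = df$end,
                      pair_id = df$pair_id, mate = df$mate,
                      is_duplicate = df$dup == 1L,
                      is_unique = df$unique == 1L,
                      platform = df$platform))
}

#' Write / read a read set as SAM
#'
#' Minimal coordinate-level SAM: flag 0x1/0x40/0x80 encode pairing,
#' 0x400 the duplicate flag; non-unique mapping is encoded as mapping
#' quality 0 (unique reads get MAPQ 60). Sequence and quality are omitted
#' (\code{*}), the CIGAR is a full-length match.
#'
#' @param reads a \code{\link{read_set}}.
#' @param genome a \code{\link{genome_model}} (for the @SQ header).
#' @param path file path.
#' @return \code{write_reads_sam} returns \code{path} invisibly;
#'   \code{read_reads_sam} a \code{read_set}.
#' @export
write_reads_sam <- function(reads, genome, path) {
  stopifnot(inherits(reads, "read_set"), inherits(genome, "genome_model"))
  lens <- contig_lengths(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  paired <- !is.na(reads$pair_id)
  flag <- ifelse(paired,
                 1L + ifelse(reads$mate == 1L, 64L, 128L), 0L) +
    ifelse(reads$is_duplicate, 1024L, 0L)
  qname <- ifelse(paired, sprintf("pair%d", reads$pair_id),
                  sprintf("single%d", seq_len(nrow(reads))))
  mapq <- ifelse(reads$is_unique, 60L, 0L)
  cigar <- sprintf("%dM", reads$end - reads$start)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                     qname, flag, reads$contig, reads$start + 1L, mapq,
                     cigar), con)
  invisible(path)
}

#' @rdname write_reads_sam
#' @export
read_reads_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(read_set(data.frame(contig = character(0), start = integer(0),
                               end = integer(0), pair_id = integer(0),
                               mate = integer(0), is_duplicate = logical(0),
                               is_unique = logical(0))))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, character(1), 1)
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  contig <- vapply(f, `[[`, character(1), 3)
  pos1 <- as.integer(vapply(f, `[[`, character(1), 4))
  mapq <- as.integer(vapply(f, `[[`, character(1), 5))
  cigar <- vapply(f, `[[`, character(1), 6)
  len <- as.integer(sub("M$", "", cigar))
  paired <- bitwAnd(flag, 1L) > 0L
  pair_id <- rep(NA_integer_, length(qname))
  pair_id[paired] <- as.integer(sub("^pair", "", qname[paired]))
  mate <- ifelse(!paired, NA_integer_,
                 ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L))
  read_set(data.frame(contig = contig, start = pos1 - 1L,
                      end = pos1 - 1L + len, pair_id = pair_id, mate = mate,
                      is_duplicate = bitwAnd(flag, 1024L) > 0L,
                      is_unique = mapq > 0L))
}

#' Write depth tracks as samtools-depth-style TSV or bedGraph
#'
#' The TSV has one row per base (\code{contig, pos} 1-based, \code{depth});
#' the bedGraph collapses runs of equal depth into 0-based half-open
#' intervals.
#'
#' @param tracks a \code{depth_tracks} object.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_depth_tsv <- function(tracks, path) {
  stopifnot(inherits(tracks, "depth_tracks"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(tracks)) {
    d <- tracks[[nm]]
    writeLines(sprintf("%s\t%d\t%d", nm, seq_along(d), d), con)
  }
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
write_bedgraph <- function(tracks, path) {
  stopifnot(inherits(tracks, "depth_tracks"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(tracks)) {
    r <- rle(tracks[[nm]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", nm, start, end, r$values), con)
  }
  invisible(path)
}

#' Read a depth TSV into depth tracks
#'
#' @param path samtools-depth-style TSV (\code{contig, pos} 1-based,
#'   \code{depth}).
#' @param genome the \code{genome_model} defining contig lengths; bases
#'   absent from the file get depth 0.
#' @return a \code{depth_tracks} object.
#' @export
read_depth_tsv <- function(path, genome) {
  stopifnot(inherits(genome, "genome_model"))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "pos", "depth"),
                          colClasses = c("character", "integer", "integer"))
  lens <- contig_lengths(genome)
  unknown <- setdiff(unique(df$contig), names(lens))
  if (length(unknown)) stop("depth rows on unknown contig: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  tracks <- lapply(names(lens), function(nm) {
    d <- integer(lens[[nm]])
    rows <- df[df$contig == nm, , drop = FALSE]
    d[rows$pos] <- rows$depth
    d
  })
  names(tracks) <- names(lens)
  structure(tracks, class = "depth_tracks")
}

#' Write / read truth genotypes as TSV
#'
#' Columns \code{contig, pos} (1-based, VCF convention), \code{ref, a1, a2};
#' missing array calls have \code{a1 = a2 = NA}.
#'
#' @param truth a \code{\link{truth_genotypes}} object.
#' @param path file path.
#' @return \code{write_truth_tsv} returns \code{path} invisibly;
#'   \code{read_truth_tsv} a \code{truth_genotypes}.
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "truth_genotypes"))
  df <- as.data.frame(truth)
  df$pos <- df$pos + 1L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "NA", colClasses = "character")
  truth_genotypes(data.frame(contig = df$contig,
                             pos = as.integer(df$pos) - 1L,
                             ref = df$ref, a1 = df$a1, a2 = df$a2))
}

#' Write / read call sets as TSV
#'
#' Columns \code{contig, pos} (1-based), \code{a1, a2, depth}.
#'
#' @param calls a \code{\link{call_set}}.
#' @param path file path.
#' @return \code{write_calls_tsv} returns \code{path} invisibly;
#'   \code{read_calls_tsv} a \code{call_set}.
#' @export
write_calls_tsv <- function(calls, path) {
  stopifnot(inherits(calls, "call_set"))
  df <- as.data.frame(calls)
  df$pos <- df$pos + 1L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(contig = "character",
                                         a1 = "character",
                                         a2 = "character"))
  call_set(data.frame(contig = df$contig, pos = df$pos - 1L,
                      a1 = df$a1, a2 = df$a2, depth = df$depth))
}

#' Read a minimal single-sample VCF into a call set
#'
#' Supports the subset of VCF the evaluation needs: SNV records with a
#' single-sample genotype column; \code{GT} resolves the called alleles
#' against REF/ALT, \code{DP} (FORMAT, falling back to INFO) supplies the
#' depth.
#'
#' @param path VCF file (uncompressed).
#' @return a \code{\link{call_set}}.
#' @export
read_calls_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  empty <- data.frame(contig = character(0), pos = integer(0),
                      a1 = character(0), a2 = character(0),
                      depth = integer(0))
  if (!length(lines)) return(call_set(empty))
  f <- strsplit(lines, "\t", fixed = TRUE)
  parse_one <- function(x) {
    if (length(x) < 10) stop("VCF record lacks a sample column",
                             call. = FALSE)
    alleles <- c(x[4], strsplit(x[5], ",", fixed = TRUE)[[1]])
    fmt <- strsplit(x[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(x[10], ":", fixed = TRUE)[[1]]
    gt <- smp[match("GT", fmt)]
    gi <- as.integer(strsplit(gt, "[/|]")[[1]]) + 1L
    dp <- if ("DP" %in% fmt) as.integer(smp[match("DP", fmt)]) else {
      m <- regmatches(x[8], regexpr("DP=[0-9]+", x[8]))
      if (length(m)) as.integer(sub("DP=", "", m)) else 0L
    }
    data.frame(contig = x[1], pos = as.integer(x[2]) - 1L,
               a1 = alleles[gi[1]], a2 = alleles[gi[2]], depth = dp)
  }
  call_set(do.call(rbind, lapply(f, parse_one)))
}
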