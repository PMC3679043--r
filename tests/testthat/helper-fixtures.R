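# Fixture builders shared across tests; everything is generated in code.

flat_profile <- function(dispersion = 0, duplicate_rate = 0,
                         repeat_mappability = 1, read_length = 100,
                         frag_mean = 300, frag_sd = 30) {
  platform_profile("flat", flat_gc_response(),
                   fragment_length_mean = frag_mean,
                   fragment_length_sd = frag_sd,
                   read_length = read_length,
                   duplicate_rate = duplicate_rate,
                   dispersion = dispersion,
                   repeat_mappability = repeat_mappability)
}

# profile whose sampling weight vanishes for fragment GC >= 0.6
gc_dropout_profile <- function() {
  platform_profile("dropout",
                   data.frame(gc = c(0, 0.55, 0.6, 1),
                              weight = c(1, 1, 0, 0)),
                   fragment_length_mean = 300, fragment_length_sd = 30,
                   read_length = 100, duplicate_rate = 0,
                   dispersion = 0, repeat_mappability = 1)
}

# tiny genome from explicit sequences
tiny_genome <- function(...) genome_model(c(...))

# read_set from a matrix-like specification: one row per read
mk_reads <- function(contig, start, end, pair_id = NA_integer_,
                     mate = NA_integer_, dup = FALSE, unique = TRUE) {
  n <- max(length(contig), length(start), length(end))
  read_set(data.frame(contig = rep_len(contig, n),
                      start = rep_len(start, n),
                      end = rep_len(end, n),
                      pair_id = rep_len(pair_id, n),
                      mate = rep_len(mate, n),
                      is_duplicate = rep_len(dup, n),
                      is_unique = rep_len(unique, n)))
}

# depth_tracks directly from vectors (bypassing reads) for summary tests
mk_tracks <- function(...) structure(list(...), class = "depth_tracks")

# genome of given per-contig lengths with all-informative random sequence
random_genome <- function(lens, seed = 1) {
  with_seed_test(seed, {
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- names(lens)
    genome_model(seqs)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# random truth + call instance for ROC/concordance fuzzing
random_truth_calls <- function(n_pos, seed, fp_rate = 0.2, max_depth = 40) {
  with_seed_test(seed, {
    bases <- c("A", "C", "G", "T")
    pos <- sort(sample.int(n_pos * 10, n_pos)) - 1L
    ref <- sample(bases, n_pos, replace = TRUE)
    zyg <- sample(c("hom_ref", "het", "hom_alt"), n_pos, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    a1 <- ifelse(zyg == "het", ref, ifelse(zyg == "hom_alt", alt, ref))
    a2 <- ifelse(zyg == "hom_ref", ref, alt)
    truth <- truth_genotypes(data.frame(contig = "c1", pos = pos, ref = ref,
                                        a1 = a1, a2 = a2))
    called <- runif(n_pos) < ifelse(zyg == "hom_ref", fp_rate, 0.8)
    ca1 <- ifelse(zyg == "hom_ref", ref, ref)
    ca2 <- alt
    calls <- call_set(data.frame(contig = "c1", pos = pos,
                                 a1 = ca1, a2 = ca2,
                                 depth = sample.int(max_depth, n_pos,
                                                    replace = TRUE))[
                                   called, , drop = FALSE])
    list(truth = truth, calls = calls)
  })
}
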