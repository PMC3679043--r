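#' Canonical synthetic study conditions
#'
#' The package's recovery experiments (GC-dropout detection, het-detection
#' calibration, coverage-sensitivity ordering, platform merging) all run on
#' one fixed synthetic design: a 2 Mb genome (two 1 Mb contigs) tiled with
#' 10 kb GC blocks cycling through a human-like mix -- GC-poor stretches
#' (0.20), a balanced bulk (0.30-0.50), and GC-rich CpG-island-like blocks
#' (0.65, 0.75) -- plus one 2 kb assembly gap per contig. The GC-poor and
#' GC-rich blocks guarantee window support in both tails, where the
#' regime-restricted KS comparisons operate.
#'
#' @param seed integer seed for the base-level realization.
#' @return a \code{\link{genome_model}}.
#' @export
study_genome <- function(seed) {
  generate_reference(
    n_contigs = 2, contig_length = 1000000,
    gc_block_spec = data.frame(
      length = 10000,
      gc = c(0.20, 0.35, 0.40, 0.45, 0.50, 0.40,
             0.65, 0.45, 0.35, 0.75, 0.50, 0.30)),
    n_gap_spec = list(list(start = 240000, length = 2000)),
    seed = seed)
}

#' Study profiles for the recovery experiments
#'
#' Two reference profiles used by the calibration experiments: a bias-free
#' profile (\code{"flat"}, constant sampling weight) and the same profile
#' with the sampling weight halved for fragments of at least 60\% GC
#' (\code{"halved_high_gc"}), the planted effect the GC-bias testing
#' procedure must detect. Both share 100 bp paired reads on 300 +/- 30 bp
#' fragments, a 5\% duplicate rate and mild overdispersion (0.05).
#'
#' @param kind \code{"flat"} or \code{"halved_high_gc"}.
#' @return a \code{\link{platform_profile}}.
#' @export
study_profile <- function(kind = c("flat", "halved_high_gc")) {
  kind <- match.arg(kind)
  gr <- if (kind == "flat") flat_gc_response() else
    data.frame(gc = c(0, 0.595, 0.6, 1), weight = c(1, 1, 0.5, 0.5))
  platform_profile(kind, gr,
                   fragment_length_mean = 300, fragment_length_sd = 30,
                   read_length = 100, duplicate_rate = 0.05,
                   dispersion = 0.05, repeat_mappability = 1)
}
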