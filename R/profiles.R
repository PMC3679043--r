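#' Platform sequencing profile
#'
#' Bundles the knobs that give a simulated platform its coverage signature:
#' \itemize{
#'   \item \code{gc_response}: a non-negative piecewise-linear weight
#'     \eqn{w(g)} on fragment GC fraction \eqn{g \in [0,1]}. Fragments are
#'     sampled proportionally to \eqn{w} of their full-fragment GC (it is the
#'     GC of the entire fragment, not just its sequenced ends, that drives
#'     amplification bias), so a declining \eqn{w} above 60\% GC reproduces
#'     the under-coverage of GC-rich regions typical of ligation-based
#'     chemistries.
#'   \item \code{dispersion}: per-locus overdispersion. Sampling weights are
#'     multiplied by i.i.d. Gamma(1/dispersion, 1/dispersion) factors per
#'     candidate start position, making per-locus fragment counts
#'     negative-binomial; dispersion 0 collapses to Poisson and yields the
#'     narrowest possible coverage distribution.
#'   \item \code{duplicate_rate}: fraction of fragments flagged as PCR/optical
#'     duplicates (both mates flagged; removed by \code{\link{filter_reads}}).
#'   \item \code{repeat_mappability}: probability that a read starting inside
#'     a low-mappability region keeps a unique assignment; the rest are
#'     flagged multi-mapping and removed by filtering.
#' }
#'
#' @param name platform label.
#' @param gc_response data.frame with columns \code{gc} and \code{weight};
#'   interpolated linearly, constant beyond the outermost knots.
#' @param fragment_length_mean,fragment_length_sd fragment size distribution
#'   in bp; the mean must exceed the read length.
#' @param read_length read length in bp.
#' @param duplicate_rate fraction in \code{[0, 1]}.
#' @param dispersion non-negative overdispersion parameter.
#' @param repeat_mappability retention probability in \code{[0, 1]}.
#' @return an object of class \code{platform_profile}.
#' @seealso \code{\link{load_platform_profiles}} for the shipped presets.
#' @export
platform_profile <- function(name, gc_response,
                             fragment_length_mean = 300,
                             fragment_length_sd = 30,
                             read_length = 100,
                             duplicate_rate = 0.05,
                             dispersion = 0,
                             repeat_mappability = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.data.frame(gc_response),
            all(c("gc", "weight") %in% names(gc_response)))
  if (any(gc_response$weight < 0)) {
    stop("gc_response weights must be non-negative", call. = FALSE)
  }
  if (any(gc_response$gc < 0 | gc_response$gc > 1)) {
    stop("gc_response knots must lie in [0, 1]", call. = FALSE)
  }
  if (duplicate_rate < 0 || duplicate_rate > 1) {
    stop("`duplicate_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (repeat_mappability < 0 || repeat_mappability > 1) {
    stop("`repeat_mappability` must lie in [0, 1]", call. = FALSE)
  }
  if (dispersion < 0) stop("`dispersion` must be >= 0", call. = FALSE)
  if (fragment_length_mean <= read_length) {
    stop("`fragment_length_mean` must exceed `read_length`", call. = FALSE)
  }
  gr <- gc_response[order(gc_response$gc), , drop = FALSE]
  structure(list(name = name,
                 gc_response = gr,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 read_length = as.integer(read_length),
                 duplicate_rate = duplicate_rate,
                 dispersion = dispersion,
                 repeat_mappability = repeat_mappability),
            class = "platform_profile")
}

#' @export
print.platform_profile <- function(x, ...) {
  cat(sprintf(paste0("platform_profile '%s': %dbp paired reads, fragments ",
                     "%.0f+/-%.0f bp\n  duplicate rate %.3f, dispersion %.3f,",
                     " repeat mappability %.2f\n"),
              x$name, x$read_length, x$fragment_length_mean,
              x$fragment_length_sd, x$duplicate_rate, x$dispersion,
              x$repeat_mappability))
  cat("  gc_response knots:",
      paste(sprintf("(%.2f, %.2f)", x$gc_response$gc, x$gc_response$weight),
            collapse = " "), "\n")
  invisible(x)
}

# Piecewise-linear weight function of the profile, vectorised over g.
gc_weight <- function(profile, g) {
  gr <- profile$gc_response
  if (nrow(gr) == 1L) return(rep(gr$weight, length(g)))
  stats::approx(gr$gc, gr$weight, xout = g, rule = 2)$y
}

#' A flat (bias-free) GC response
#'
#' @param weight constant weight (default 1).
#' @return data.frame usable as \code{gc_response}.
#' @export
flat_gc_response <- function(weight = 1) {
  data.frame(gc = c(0, 1), weight = weight)
}

#' Load platform profile presets from a YAML file
#'
#' The package ships qualitative presets (\code{inst/extdata/
#' platform_profiles.yaml}) emulating four whole-genome platforms: an
#' Illumina-like profile with mild GC bias and tight dispersion, two
#' SOLiD-like profiles with pronounced high-GC dropout, and a Complete
#' Genomics-like profile with the flattest GC response but the broadest
#' coverage dispersion. Users can supply their own file with the same
#' layout to add platforms without touching code.
#'
#' @param path YAML file; defaults to the shipped presets.
#' @return named list of \code{\link{platform_profile}} objects.
#' @export
load_platform_profiles <- function(path = system.file("extdata",
                                                      "platform_profiles.yaml",
                                                      package = "coveval")) {
  spec <- yaml::read_yaml(path)
  profs <- lapply(names(spec), function(nm) {
    p <- spec[[nm]]
    platform_profile(
      name = nm,
      gc_response = data.frame(gc = vapply(p$gc_response, `[[`, numeric(1), 1),
                               weight = vapply(p$gc_response, `[[`,
                                               numeric(1), 2)),
      fragment_length_mean = p$fragment_length_mean,
      fragment_length_sd = p$fragment_length_sd,
      read_length = p$read_length,
      duplicate_rate = p$duplicate_rate,
      dispersion = p$dispersion,
      repeat_mappability = p$repeat_mappability)
  })
  names(profs) <- names(spec)
  profs
}
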