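#' Read an analysis configuration
#'
#' Configurations are YAML files (or equivalent R lists) describing a full
#' evaluation run: the simulated genome and annotation catalogue, the
#' platform profiles and target coverage, downsampling targets, platform
#' combinations to merge, per-stage parameters and a single master seed.
#' See \code{system.file("extdata", "demo_config.yaml", package =
#' "coveval")} for a complete annotated example.
#'
#' @param path YAML file path.
#' @return a list of class \code{analysis_config}.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  need <- c("seed", "genome", "platforms", "mean_coverage")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("config lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be positive",
                                   call. = FALSE)
  cfg$gc_bias <- utils::modifyList(
    list(window_size = 1000, span = 0.3, gc_low = 0.25, gc_high = 0.60,
         grid_step = 0.005), cfg$gc_bias %||% list())
  cfg$uncovered <- utils::modifyList(list(min_reads = 3),
                                     cfg$uncovered %||% list())
  cfg$calls <- utils::modifyList(
    list(alt_read_min = 2, depth_min = 3, fp_rate = 0.001),
    cfg$calls %||% list())
  cfg$size_bins <- cfg$size_bins %||% c(1, 3, 10, 50, 150, 500)
  cfg$downsample <- cfg$downsample %||% numeric(0)
  structure(cfg, class = c("analysis_config", "list"))
}

#' Run the full evaluation pipeline
#'
#' Orchestrates all stages from a single config: simulate the genome,
#' annotations, truth genotypes and per-platform read sets; filter reads
#' and compute depth; GC-bias window tables with pairwise regime-restricted
#' KS comparisons; uncovered-region census with per-element fractions and
#' size distributions; coverage-thresholded ROC per platform, at the
#' configured downsampling targets, and for the configured platform
#' combinations. Per-stage seeds are derived from the master seed by
#' hashing the stage name (\code{\link{derive_seed}}), so reruns with the
#' same config are bit-identical and adding a stage never perturbs the
#' random streams of existing ones.
#'
#' @param config an \code{analysis_config}, a path to one, or a plain list
#'   with the same fields.
#' @param out_dir output directory for the report tables (overrides
#'   \code{config$out_dir}); \code{NULL} suppresses writing.
#' @return a list of class \code{coveval_report} with elements
#'   \code{coverage_summary, gc_bias, uncovered_fractions,
#'   size_distribution, roc_summary, provenance} (data.frames) plus the
#'   simulated objects (\code{genome, annotations, truth}).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  cfg <- validate_config(unclass(config))
  master <- cfg$seed
  out_dir <- out_dir %||% cfg$out_dir

  gspec <- cfg$genome
  genome <- generate_reference(
    n_contigs = gspec$n_contigs %||% 1,
    contig_length = gspec$contig_length,
    gc_block_spec = normalize_block_spec(
      lapply(gspec$gc_blocks, function(b) c(b$length, b$gc))),
    n_gap_spec = gspec$n_gaps,
    seed = derive_seed(master, "genome"))

  annotations <- list()
  if (!is.null(cfg$annotations)) {
    spec <- lapply(names(cfg$annotations), function(nm) {
      e <- cfg$annotations[[nm]]
      if (identical(e$rule, "random_intervals")) {
        # YAML 1.1 parses a bare `n` key as a boolean; configs say `count`
        if (is.null(e$n) || !is.numeric(e$n)) e$n <- e$count
        if (is.null(e$seed)) {
          e$seed <- derive_seed(master, paste0("annot:", nm))
        }
      }
      e
    })
    names(spec) <- names(cfg$annotations)
    annotations <- plant_regions(genome, spec)
  }
  if (!is.null(cfg$tss)) {
    if (is.null(cfg$tss$n) || !is.numeric(cfg$tss$n)) {
      cfg$tss$n <- cfg$tss$count
    }
    tss <- random_tss(genome, n = cfg$tss$n,
                      seed = derive_seed(master, "tss"))
    annotations$promoter <- derive_promoters(tss, genome)
  }
  if (!is.null(cfg$low_mappability) &&
      !cfg$low_mappability %in% names(annotations)) {
    stop("low_mappability must name an annotation category", call. = FALSE)
  }
  lowmap <- if (is.null(cfg$low_mappability)) NULL else
    annotations[[cfg$low_mappability]]

  truth <- NULL
  if (!is.null(cfg$variants)) {
    v <- cfg$variants
    truth <- plant_variants(genome, density_per_bp = v$density_per_bp,
                            het_fraction = v$het_fraction,
                            seed = derive_seed(master, "variants"),
                            hom_ref_per_bp = v$hom_ref_per_bp %||%
                              (2 * v$density_per_bp))
  }

  profiles <- load_platform_profiles(cfg$profiles_file %||%
                                       system.file("extdata",
                                                   "platform_profiles.yaml",
                                                   package = "coveval"))
  unknown <- setdiff(unlist(cfg$platforms), names(profiles))
  if (length(unknown)) {
    stop("unknown platform profile(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  per <- list()
  for (pf in unlist(cfg$platforms)) {
    reads <- simulate_reads(genome, profiles[[pf]],
                            target_mean_coverage = cfg$mean_coverage,
                            low_mappability = lowmap,
                            seed = derive_seed(master, paste0("reads:", pf)))
    flt <- filter_reads(reads)
    tracks <- compute_depth(flt, genome)
    per[[pf]] <- list(reads = flt, tracks = tracks,
                      mean = mean_coverage(tracks, genome),
                      hist = depth_histogram(tracks, genome),
                      wt = window_table(tracks, genome,
                                        cfg$gc_bias$window_size),
                      unc = uncovered_regions(tracks, genome,
                                              cfg$uncovered$min_reads))
  }

  inf_len <- informative_length(genome)
  coverage_summary <- do.call(rbind, lapply(names(per), function(pf) {
    p <- per[[pf]]
    data.frame(platform = pf, coverage = "full",
               mean_coverage = p$mean,
               bases_covered = attr(p$hist, "total") - bases_below(p$hist, 1),
               bases_below_5 = bases_below(p$hist, 5),
               pct_uncovered = 100 * sum(p$unc$end - p$unc$start) / inf_len)
  }))

  gc_rows <- list()
  pfs <- names(per)
  if (length(pfs) >= 2) {
    for (i in seq_len(length(pfs) - 1)) for (j in (i + 1):length(pfs)) {
      cmp <- gc_bias_compare(per[[pfs[i]]]$wt, per[[pfs[j]]]$wt,
                             span = cfg$gc_bias$span,
                             gc_low = cfg$gc_bias$gc_low,
                             gc_high = cfg$gc_bias$gc_high,
                             step = cfg$gc_bias$grid_step)
      cmp <- cbind(pair = paste(pfs[i], pfs[j], sep = " vs "), cmp)
      gc_rows[[length(gc_rows) + 1L]] <- cmp
    }
  }
  gc_bias <- if (length(gc_rows)) do.call(rbind, gc_rows) else NULL

  frac_rows <- list()
  for (pf in pfs) {
    for (el in names(annotations)) {
      frac_rows[[length(frac_rows) + 1L]] <-
        data.frame(platform = pf, coverage = "full", element = el,
                   fraction_uncovered = fraction_uncovered(per[[pf]]$unc,
                                                           annotations[[el]]))
    }
  }

  size_rows <- do.call(rbind, lapply(pfs, function(pf) {
    cbind(platform = pf, size_distribution(per[[pf]]$unc, cfg$size_bins))
  }))

  roc_rows <- list()
  add_roc <- function(label, coverage, tracks) {
    if (is.null(truth)) return(invisible())
    calls <- simulate_calls(tracks, truth,
                            alt_read_min = cfg$calls$alt_read_min,
                            depth_min = cfg$calls$depth_min,
                            fp_rate = cfg$calls$fp_rate,
                            seed = derive_seed(master,
                                               paste0("calls:", label, ":",
                                                      coverage)))
    roc <- roc_curve(truth, calls)
    roc_rows[[length(roc_rows) + 1L]] <<-
      data.frame(platform = label, coverage = coverage,
                 sensitivity = roc$sensitivity[1], fpr = roc$fpr[1],
                 auc = roc$auc)
  }
  for (pf in pfs) add_roc(pf, sprintf("%gx", cfg$mean_coverage),
                          per[[pf]]$tracks)
  for (tgt in unlist(cfg$downsample)) {
    for (pf in pfs) {
      if (tgt >= per[[pf]]$mean) next
      ds <- downsample_reads(per[[pf]]$reads, per[[pf]]$mean, tgt,
                             seed = derive_seed(master,
                                                paste0("ds:", pf, ":", tgt)))
      add_roc(pf, sprintf("%gx", tgt), compute_depth(ds, genome))
    }
  }
  merged_fracs <- list()
  for (mg in cfg$merge %||% list()) {
    parts <- list(); labels <- character(0)
    for (k in seq_along(mg$platforms)) {
      pf <- mg$platforms[[k]]
      cv <- mg$coverages[[k]]
      rd <- per[[pf]]$reads
      if (cv < per[[pf]]$mean) {
        rd <- downsample_reads(rd, per[[pf]]$mean, cv,
                               seed = derive_seed(master,
                                                  paste0("mergeds:", pf, ":",
                                                         cv)))
      }
      parts[[k]] <- rd
      labels <- c(labels, sprintf("%s%gx", pf, cv))
    }
    lab <- paste(mg$platforms, collapse = "+")
    cvlab <- paste(labels, collapse = "+")
    mtracks <- compute_depth(merge_readsets(parts, genome), genome)
    add_roc(lab, cvlab, mtracks)
    munc <- uncovered_regions(mtracks, genome, cfg$uncovered$min_reads)
    for (el in names(annotations)) {
      merged_fracs[[length(merged_fracs) + 1L]] <-
        data.frame(platform = lab, coverage = cvlab, element = el,
                   fraction_uncovered = fraction_uncovered(munc,
                                                           annotations[[el]]))
    }
  }
  uncovered_fractions <- do.call(rbind, c(frac_rows, merged_fracs))
  roc_summary <- if (length(roc_rows)) do.call(rbind, roc_rows) else NULL

  provenance <- data.frame(
    key = c("package_version", "master_seed", "mean_coverage", "platforms",
            "genome_bp", "informative_bp"),
    value = c(as.character(utils::packageVersion("coveval")),
              as.character(master), as.character(cfg$mean_coverage),
              paste(pfs, collapse = ","),
              as.character(sum(contig_lengths(genome))),
              as.character(inf_len)))

  report <- structure(
    list(coverage_summary = coverage_summary, gc_bias = gc_bias,
         uncovered_fractions = uncovered_fractions,
         size_distribution = size_rows, roc_summary = roc_summary,
         provenance = provenance, genome = genome,
         annotations = annotations, truth = truth,
         out_dir = out_dir),
    class = "coveval_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("coverage_summary", "gc_bias", "uncovered_fractions",
              "size_distribution", "roc_summary", "provenance")
  for (nm in tables) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    utils::write.table(tab, file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.coveval_report <- function(x, ...) {
  cat("coveval_report\n==============\n\nCoverage summary:\n")
  print.data.frame(x$coverage_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$gc_bias)) {
    cat("\nGC-bias KS comparisons (regime-restricted):\n")
    print.data.frame(x$gc_bias, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$roc_summary)) {
    cat("\nSNV-calling ROC summary:\n")
    print.data.frame(x$roc_summary, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
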