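#' Truth genotype sets
#'
#' Gold-standard genotypes at assayed positions (the role an SNP array plays
#' against sequencing calls): per record a contig, a 0-based position, the
#' reference allele and the two called alleles. Zygosity is derivable:
#' hom-ref (\code{a1 == a2 == ref}), het, or hom-alt.
#'
#' @param df data.frame with columns \code{contig, pos, ref, a1, a2}.
#' @return an object of classes \code{truth_genotypes, data.frame}.
#' @export
truth_genotypes <- function(df) {
  need <- c("contig", "pos", "ref", "a1", "a2")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[need]
  df$contig <- as.character(df$contig)
  df$pos <- as.integer(df$pos)
  for (col in c("ref", "a1", "a2")) df[[col]] <- as.character(df[[col]])
  bases <- c("A", "C", "G", "T")
  if (!all(df$ref %in% bases)) {
    stop("reference alleles must be A, C, G or T", call. = FALSE)
  }
  ok <- df$a1 %in% bases & df$a2 %in% bases
  if (any(!ok & !(is.na(df$a1) & is.na(df$a2)))) {
    stop("alleles must be A, C, G, T (or both NA for a missing array call)",
         call. = FALSE)
  }
  if (anyDuplicated(df[c("contig", "pos")])) {
    stop("positions must be unique per contig", call. = FALSE)
  }
  class(df) <- c("truth_genotypes", "data.frame")
  df
}

#' Zygosity of truth genotypes
#' @param truth a \code{truth_genotypes} object.
#' @return character vector: \code{"hom_ref"}, \code{"het"},
#'   \code{"hom_alt"}, or \code{NA} for missing array calls.
#' @export
zygosity <- function(truth) {
  stopifnot(inherits(truth, "truth_genotypes"))
  ifelse(is.na(truth$a1), NA_character_,
         ifelse(truth$a1 != truth$a2, "het",
                ifelse(truth$a1 == truth$ref, "hom_ref", "hom_alt")))
}

#' @export
print.truth_genotypes <- function(x, ...) {
  z <- table(factor(zygosity(x), c("hom_ref", "het", "hom_alt")),
             useNA = "ifany")
  cat("truth_genotypes:", nrow(x), "position(s) |",
      paste(names(z), z, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Call sets
#'
#' Variant calls produced by a platform: per called position the two called
#' alleles and the sequencing depth at that position (the independent
#' variable of the coverage-thresholded ROC). Positions without a row are
#' no-calls.
#'
#' @param df data.frame with columns \code{contig, pos, a1, a2, depth}.
#' @return an object of classes \code{call_set, data.frame}.
#' @export
call_set <- function(df) {
  need <- c("contig", "pos", "a1", "a2", "depth")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[need]
  df$contig <- as.character(df$contig)
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  if (any(df$depth < 0)) stop("negative depth", call. = FALSE)
  if (anyDuplicated(df[c("contig", "pos")])) {
    stop("called positions must be unique per contig", call. = FALSE)
  }
  class(df) <- c("call_set", "data.frame")
  df
}

#' Simulate coverage-dependent variant calls
#'
#' A deliberately transparent caller model that reproduces the coverage
#' dependence of real callers: at a truth position with sequencing depth
#' \eqn{d}, the number of non-reference reads is Binomial(\eqn{d},
#' \code{het_allele_fraction}) for het sites and Binomial(\eqn{d},
#' \code{hom_alt_allele_fraction}) for hom-alt sites; the variant is called
#' iff at least \code{alt_read_min} non-reference reads and \code{depth_min}
#' total reads support it (two alt reads to exclude single-read artefacts,
#' three reads minimum overall). The called genotype is het if at least one
#' reference read remains, else hom-alt. At hom-ref truth positions a
#' spurious non-reference call is emitted with probability \code{fp_rate}.
#' Het detection at depth \eqn{d \ge 3} therefore follows the analytic
#' binomial tail \eqn{P(\mathrm{Bin}(d, 0.5) \ge 2)}.
#'
#' @param tracks \code{depth_tracks} of the filtered read set.
#' @param truth a \code{\link{truth_genotypes}} object.
#' @param alt_read_min minimum non-reference reads (default 2).
#' @param depth_min minimum total depth (default 3).
#' @param fp_rate probability of a spurious call at a hom-ref position.
#' @param seed integer seed.
#' @param het_allele_fraction expected alt-read fraction at het sites
#'   (default 0.5; lower values emulate tumor samples with sub-clonal
#'   mutant allele fractions).
#' @param hom_alt_allele_fraction alt-read fraction at hom-alt sites
#'   (default 0.98, allowing rare wrong-allele reads).
#' @return a \code{\link{call_set}} containing only called positions.
#' @export
simulate_calls <- function(tracks, truth, alt_read_min = 2, depth_min = 3,
                           fp_rate = 0, seed,
                           het_allele_fraction = 0.5,
                           hom_alt_allele_fraction = 0.98) {
  stopifnot(inherits(tracks, "depth_tracks"),
            inherits(truth, "truth_genotypes"))
  if (fp_rate < 0 || fp_rate > 1) stop("`fp_rate` must lie in [0, 1]",
                                       call. = FALSE)
  z <- zygosity(truth)
  d <- depth_at(tracks, truth$contig, truth$pos)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    n <- nrow(truth)
    alt_reads <- integer(n)
    is_het <- !is.na(z) & z == "het"
    is_hom <- !is.na(z) & z == "hom_alt"
    alt_reads[is_het] <- stats::rbinom(sum(is_het), d[is_het],
                                       het_allele_fraction)
    alt_reads[is_hom] <- stats::rbinom(sum(is_hom), d[is_hom],
                                       hom_alt_allele_fraction)
    called <- (is_het | is_hom) & alt_reads >= alt_read_min & d >= depth_min
    # alt allele of the truth record: a2 for het (a1 = ref), a2 for hom-alt
    alt_allele <- truth$a2
    ref_left <- d - alt_reads >= 1L
    a1 <- ifelse(ref_left, truth$ref, alt_allele)
    a2 <- alt_allele
    # spurious calls at hom-ref positions
    is_ref <- !is.na(z) & z == "hom_ref"
    fp <- is_ref & stats::runif(n) < fp_rate
    if (any(fp)) {
      a1[fp] <- truth$ref[fp]
      a2[fp] <- vapply(truth$ref[fp],
                       function(r) sample(setdiff(bases, r), 1L),
                       character(1))
      called[fp] <- TRUE
    }
    out <- data.frame(contig = truth$contig, pos = truth$pos,
                      a1 = a1, a2 = a2, depth = d)[called, , drop = FALSE]
    rownames(out) <- NULL
    call_set(out)
  })
}

depth_at <- function(tracks, contig, pos) {
  d <- integer(length(pos))
  for (nm in unique(contig)) {
    idx <- contig == nm
    tr <- tracks[[nm]]
    if (is.null(tr)) stop("no depth track for contig ", nm, call. = FALSE)
    d[idx] <- tr[pos[idx] + 1L]
  }
  d
}

# index calls by truth rows; returns list(called_nonref, depth) aligned
# with truth (NA depth where no call)
match_calls <- function(truth, calls) {
  key_t <- paste(truth$contig, truth$pos)
  key_c <- paste(calls$contig, calls$pos)
  idx <- match(key_t, key_c)
  has <- !is.na(idx)
  nonref <- rep(FALSE, nrow(truth))
  nonref[has] <- calls$a1[idx[has]] != truth$ref[has] |
    calls$a2[idx[has]] != truth$ref[has]
  depth <- rep(NA_integer_, nrow(truth))
  depth[has] <- calls$depth[idx[has]]
  list(has_call = has, called_nonref = nonref, depth = depth)
}

#' Coverage-thresholded ROC curve of variant calling
#'
#' Evaluates a call set against truth genotypes using coverage at the
#' variant position as the independent variable. For each threshold
#' \eqn{t} over the observed depth values (plus 0): sensitivity is the
#' fraction of truth variant positions (het or hom-alt) with a
#' non-reference call at depth \eqn{\ge t}; the false-positive rate is the
#' fraction of truth hom-ref positions with a non-reference call at depth
#' \eqn{\ge t}. The AUC is the trapezoid area over the (FPR, sensitivity)
#' points anchored at (0, 0) and extended horizontally to FPR 1 (the curve's
#' plateau continues as a straight line).
#'
#' @param truth a \code{\link{truth_genotypes}} object with at least one
#'   variant and one hom-ref position.
#' @param calls a \code{\link{call_set}}.
#' @return an object of class \code{roc_curve}: list with
#'   \code{thresholds} (ascending), \code{sensitivity}, \code{fpr}
#'   (aligned, non-increasing), \code{auc}, \code{n_variant},
#'   \code{n_hom_ref}.
#' @export
roc_curve <- function(truth, calls) {
  stopifnot(inherits(truth, "truth_genotypes"), inherits(calls, "call_set"))
  z <- zygosity(truth)
  is_var <- !is.na(z) & z %in% c("het", "hom_alt")
  is_ref <- !is.na(z) & z == "hom_ref"
  if (!any(is_var) || !any(is_ref)) {
    stop("truth needs at least one variant and one hom-ref position",
         call. = FALSE)
  }
  mc <- match_calls(truth, calls)
  var_called <- mc$called_nonref & is_var
  ref_called <- mc$called_nonref & is_ref
  var_depth <- mc$depth[var_called]
  ref_depth <- mc$depth[ref_called]
  thresholds <- sort(unique(c(0L, var_depth, ref_depth)))
  n_var <- sum(is_var); n_ref <- sum(is_ref)
  sens <- vapply(thresholds, function(t) sum(var_depth >= t) / n_var,
                 numeric(1))
  fpr <- vapply(thresholds, function(t) sum(ref_depth >= t) / n_ref,
                numeric(1))
  structure(list(thresholds = thresholds, sensitivity = sens, fpr = fpr,
                 auc = roc_trapezoid(fpr, sens),
                 n_variant = n_var, n_hom_ref = n_ref),
            class = "roc_curve")
}

# trapezoid area over points ordered by descending threshold
# (ascending FPR), anchored at (0,0) and extended to FPR = 1 at max
# sensitivity
roc_trapezoid <- function(fpr, sens) {
  o <- order(fpr, sens)
  x <- c(0, fpr[o], 1)
  y <- c(0, sens[o], max(sens, 0))
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(paste0("roc_curve: %d variant / %d hom-ref truth positions, ",
                     "%d threshold(s)\n  sensitivity(t=0) %.4f, ",
                     "FPR(t=0) %.5f, AUC %.4f\n"),
              x$n_variant, x$n_hom_ref, length(x$thresholds),
              x$sensitivity[1], x$fpr[1], x$auc))
  invisible(x)
}

#' Sensitivity at a coverage threshold
#'
#' Step-function lookup returning the exact fraction of truth variants
#' called with depth at least \code{t}: at a computed threshold, its own
#' value; between thresholds, the value of the next one up (the curve is a
#' right-continuous step in the depth requirement); beyond the largest
#' observed depth, 0.
#'
#' @param roc a \code{roc_curve}.
#' @param t coverage threshold, at least the smallest computed threshold.
#' @return sensitivity fraction.
#' @export
sensitivity_at <- function(roc, t) {
  stopifnot(inherits(roc, "roc_curve"))
  th <- roc$thresholds
  if (t < th[1]) {
    stop("`t` is below the smallest threshold", call. = FALSE)
  }
  idx <- findInterval(t, th)
  if (th[idx] == t) return(roc$sensitivity[idx])
  if (idx < length(th)) roc$sensitivity[idx + 1L] else 0
}

#' Area under the ROC curve
#' @param roc a \code{roc_curve}.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  roc$auc
}

#' Genotype concordance classification
#'
#' Compares each truth genotype (as an allele multiset) with the called
#' allele multiset at the same position; positions without a sequencing
#' call are assumed reference-homozygous (\code{\{ref, ref\}}). Classes:
#' \code{identical} (both alleles match), \code{one_identical} (exactly one
#' matches), \code{no_identical} (none match), and \code{missing} (no array
#' genotype). Counts are split by truth zygosity (hom vs het).
#'
#' @param truth a \code{\link{truth_genotypes}} object.
#' @param calls a \code{\link{call_set}}.
#' @return an object of class \code{concordance_table}: an integer matrix
#'   with rows \code{hom, het} (plus \code{unknown} when the truth contains
#'   missing array calls) and columns \code{identical, one_identical,
#'   no_identical, missing}.
#' @export
classify_genotypes <- function(truth, calls) {
  stopifnot(inherits(truth, "truth_genotypes"), inherits(calls, "call_set"))
  bases <- c("A", "C", "G", "T")
  if (!all(calls$a1 %in% bases & calls$a2 %in% bases)) {
    stop("called alleles must be A, C, G or T", call. = FALSE)
  }
  key_t <- paste(truth$contig, truth$pos)
  key_c <- paste(calls$contig, calls$pos)
  idx <- match(key_t, key_c)
  has <- !is.na(idx)
  c1 <- ifelse(has, calls$a1[idx], truth$ref)
  c2 <- ifelse(has, calls$a2[idx], truth$ref)
  miss <- is.na(truth$a1)
  inter <- integer(nrow(truth))
  for (b in bases) {
    tc <- (truth$a1 == b) + (truth$a2 == b)
    cc <- (c1 == b) + (c2 == b)
    inter <- inter + pmin(tc, cc)
  }
  cls <- ifelse(miss, "missing",
                c("no_identical", "one_identical", "identical")[inter + 1L])
  grp <- ifelse(miss, "unknown", ifelse(truth$a1 == truth$a2, "hom", "het"))
  rows <- c("hom", "het", if (any(miss)) "unknown")
  cols <- c("identical", "one_identical", "no_identical", "missing")
  tab <- table(factor(grp, rows), factor(cls, cols))
  m <- matrix(as.integer(tab), nrow = length(rows),
              dimnames = list(zygosity = rows, class = cols))
  structure(m, class = c("concordance_table", class(m)))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("concordance_table (truth zygosity x call class):\n")
  print(unclass(x))
  invisible(x)
}

#' Paired t-test on per-sample sensitivities
#'
#' Two-sided paired Student's t-test on the per-sample sensitivity
#' differences between two platforms. Zero-variance differences (including
#' identical inputs) carry no information for a t-test and are flagged.
#'
#' @param sens_a,sens_b equal-length (>= 2) vectors of per-sample
#'   sensitivities, paired by sample.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{mean_difference}, \code{noninformative}.
#' @export
paired_sensitivity_test <- function(sens_a, sens_b) {
  if (length(sens_a) != length(sens_b)) {
    stop("inputs must be paired: equal lengths", call. = FALSE)
  }
  if (length(sens_a) < 2) stop("need at least two sample pairs",
                               call. = FALSE)
  d <- sens_a - sens_b
  if (stats::sd(d) == 0) {
    return(list(statistic = NA_real_, df = length(d) - 1,
                p_value = NA_real_, mean_difference = mean(d),
                noninformative = TRUE))
  }
  tt <- stats::t.test(sens_a, sens_b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d),
       noninformative = FALSE)
}

#' Binomial test of allele no-call asymmetry
#'
#' For truth variants a platform failed to genotype correctly, tests
#' whether missing the call on both alleles is as likely as missing it on
#' one allele only: an exact two-sided binomial test of
#' \code{both_alleles_missing} successes in the total at probability 0.5.
#'
#' @param one_allele_missing count of positions with a no-call on exactly
#'   one allele.
#' @param both_alleles_missing count with no-calls on both alleles.
#' @return list with \code{p_value}, \code{estimate} (observed
#'   both-missing share).
#' @export
allele_nocall_binomial <- function(one_allele_missing, both_alleles_missing) {
  if (one_allele_missing < 0 || both_alleles_missing < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- one_allele_missing + both_alleles_missing
  if (n == 0) stop("both counts are zero", call. = FALSE)
  bt <- stats::binom.test(both_alleles_missing, n, p = 0.5)
  list(p_value = bt$p.value,
       estimate = both_alleles_missing / n)
}
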