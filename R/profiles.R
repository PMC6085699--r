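#' clonalpair: clonality testing for tumour pairs
#'
#' Tools to decide whether the two tumours of one patient are clonally
#' related (one progenitor cell, shared founder aberrations) or independent
#' primaries (similarities only through population-recurrent aberrations or
#' chance).  The package covers probe-level similarity indices with
#' cross-patient permutation nulls, distance and dendrogram-cherry tests,
#' exact-breakpoint shared-segment and shared-mutation statistics, fusion
#' breakpoint overlap, histopathological concordance, and Cohen's kappa
#' agreement between callers, plus a seeded synthetic cohort generator.
#'
#' @importFrom stats dist hclust quantile rbinom rnorm runif plogis setNames
#' @importFrom utils read.delim read.csv write.table
#' @keywords internal
"_PACKAGE"

PLATFORMS <- c("copy_number", "expression", "methylation_beta",
               "methylation_intensity", "snp_lrr", "snp_baf")
SCHEMES <- c("cn3", "expr3", "meth3")
SEG_STATUS <- c("loss", "normal", "gain")

#' Normalise chromosome names
#'
#' Strips a leading `"chr"` prefix so that `"chr17"` and `"17"` compare
#' equal; `X` and `Y` are retained as-is.
#'
#' @param x character vector of chromosome names.
#' @return character vector with canonical names `"1".."22","X","Y",...`.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  if (!any(startsWith(x, "chr") | startsWith(x, "Chr")))
    return(x)
  sub("^chr", "", x, ignore.case = TRUE)
}

is_sex_chrom <- function(x) normalize_chrom(x) %in% c("X", "Y")

#' Probe-level profile for one sample
#'
#' An ordered set of genomic probe measurements for a single sample on a
#' single platform: copy-number or expression log2 ratios, methylation beta
#' values or intensity log2 ratios, or SNP-array LRR/BAF values.
#'
#' @param sample_id sample identifier.
#' @param platform one of `"copy_number"`, `"expression"`,
#'   `"methylation_beta"`, `"methylation_intensity"`, `"snp_lrr"`,
#'   `"snp_baf"`.
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based bp) and `value`.  Rows are sorted by (chrom, pos) on
#'   construction.
#' @param check validate invariants and sort (default).  `FALSE` skips
#'   the work for inputs already in canonical order, e.g. from the
#'   cohort simulator.
#' @return an object of class `probe_profile`.
#' @details All values must be finite; beta values must lie in \[0, 1\].
#' @export
probe_profile <- function(sample_id, platform, probes, check = TRUE) {
  if (!check)
    return(structure(list(sample_id = as.character(sample_id),
                          platform = platform, probes = probes),
                     class = "probe_profile"))
  platform <- match.arg(platform, PLATFORMS)
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "chrom", "pos", "value") %in% names(probes)))
  probes$probe_id <- as.character(probes$probe_id)
  probes$chrom <- normalize_chrom(probes$chrom)
  probes$pos <- as.integer(probes$pos)
  probes$value <- as.numeric(probes$value)
  if (anyNA(probes$value) || any(!is.finite(probes$value)))
    stop("probe_profile: non-finite value in sample '", sample_id, "'")
  if (platform == "methylation_beta" &&
      any(probes$value < 0 | probes$value > 1))
    stop("probe_profile: beta value outside [0, 1] in sample '",
         sample_id, "'")
  if (anyDuplicated(probes$probe_id))
    stop("probe_profile: duplicated probe_id in sample '", sample_id, "'")
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 platform = platform,
                 probes = probes),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat("<probe_profile> sample", x$sample_id, "platform", x$platform,
      "-", nrow(x$probes), "probes\n")
  invisible(x)
}

#' Discretized three-state profile
#'
#' Per-probe three-level calls derived from a [probe_profile()]: loss /
#' normal / gain coded -1, 0, +1 for copy-number-like data (`cn3`) and
#' expression (`expr3`), or unmethylated / hemi-methylated / methylated
#' coded `"U"`, `"H"`, `"M"` for beta values (`meth3`).
#'
#' @param sample_id sample identifier.
#' @param scheme `"cn3"`, `"expr3"` or `"meth3"`.
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `state`.
#' @param thresholds numeric `c(low, high)` used for the discretization.
#' @return an object of class `discrete_profile`.
#' @export
discrete_profile <- function(sample_id, scheme, probes, thresholds) {
  scheme <- match.arg(scheme, SCHEMES)
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "chrom", "pos", "state") %in% names(probes)))
  alphabet <- if (scheme == "meth3") c("U", "H", "M") else c(-1L, 0L, 1L)
  if (scheme == "meth3") {
    probes$state <- as.character(probes$state)
  } else {
    probes$state <- as.integer(probes$state)
  }
  if (!all(probes$state %in% alphabet))
    stop("discrete_profile: state outside the '", scheme, "' alphabet")
  structure(list(sample_id = as.character(sample_id), scheme = scheme,
                 probes = probes, thresholds = as.numeric(thresholds)),
            class = "discrete_profile")
}

#' @export
print.discrete_profile <- function(x, ...) {
  cat("<discrete_profile> sample", x$sample_id, "scheme", x$scheme,
      "-", nrow(x$probes), "probes\n")
  invisible(x)
}

#' Segmented copy-number profile
#'
#' Non-overlapping, status-labelled genomic segments for one sample, as
#' produced by a segmentation algorithm upstream (SEG convention: 1-based,
#' inclusive start and end).
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `mean_value` and optionally `status` (`"loss"`, `"normal"`,
#'   `"gain"`).  When `status` is absent it is derived from `mean_value`
#'   with the `loss_thr`/`gain_thr` cut-offs.
#' @param loss_thr,gain_thr thresholds used to label segments when no
#'   status column is supplied (strict inequalities).
#' @param check validate invariants and sort (default); `FALSE` trusts
#'   inputs already in canonical order.
#' @return an object of class `segmented_profile`.
#' @export
segmented_profile <- function(sample_id, segments,
                              loss_thr = -0.3, gain_thr = 0.3,
                              check = TRUE) {
  if (!check)
    return(structure(list(sample_id = as.character(sample_id),
                          segments = segments),
                     class = "segmented_profile"))
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "mean_value") %in%
                names(segments)))
  segments$chrom <- normalize_chrom(segments$chrom)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$mean_value <- as.numeric(segments$mean_value)
  if (any(segments$start > segments$end))
    stop("segmented_profile: start > end in sample '", sample_id, "'")
  if (is.null(segments$status)) {
    segments$status <- ifelse(segments$mean_value < loss_thr, "loss",
                       ifelse(segments$mean_value > gain_thr, "gain",
                              "normal"))
  }
  if (!all(segments$status %in% SEG_STATUS))
    stop("segmented_profile: invalid segment status")
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  n <- nrow(segments)
  if (n > 1L) {
    same <- segments$chrom[-1L] == segments$chrom[-n]
    bad <- same & segments$start[-1L] <= segments$end[-n]
    if (any(bad))
      stop("segmented_profile: overlapping segments in sample '",
           sample_id, "' chromosome ", segments$chrom[which(bad)[1L]])
  }
  rownames(segments) <- NULL
  structure(list(sample_id = as.character(sample_id), segments = segments),
            class = "segmented_profile")
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat("<segmented_profile> sample", x$sample_id, "-", nrow(x$segments),
      "segments\n")
  invisible(x)
}

#' Set of genetic variants for one sample
#'
#' Variants keyed by (chrom, pos, ref, alt); duplicate keys are collapsed
#' with a warning, matching set semantics.
#'
#' @param sample_id sample identifier.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param check validate set semantics and sort (default); `FALSE`
#'   trusts inputs already deduplicated and sorted.
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(sample_id, variants, check = TRUE) {
  if (!check)
    return(structure(list(sample_id = as.character(sample_id),
                          variants = variants),
                     class = "variant_set"))
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants$chrom <- normalize_chrom(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  if (any(variants$ref == variants$alt))
    stop("variant_set: ref == alt in sample '", sample_id, "'")
  key <- variant_key(variants)
  if (anyDuplicated(key)) {
    warning("variant_set: duplicated variants collapsed in sample '",
            sample_id, "'")
    variants <- variants[!duplicated(key), , drop = FALSE]
  }
  variants <- variants[order(variants$chrom, variants$pos, variants$ref,
                             variants$alt), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(sample_id = as.character(sample_id), variants = variants),
            class = "variant_set")
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' @export
print.variant_set <- function(x, ...) {
  cat("<variant_set> sample", x$sample_id, "-", nrow(x$variants),
      "variants\n")
  invisible(x)
}

#' Set of fusion transcripts for one sample
#'
#' Fusions keyed by the exact 5' and 3' partner breakpoints
#' (chrom5, pos5, chrom3, pos3); gene symbols are carried along for
#' reporting but are not part of the identity of a fusion.
#'
#' @param sample_id sample identifier.
#' @param fusions data.frame with columns `chrom5`, `pos5`, `gene5`,
#'   `chrom3`, `pos3`, `gene3`.
#' @return an object of class `fusion_set`.
#' @export
fusion_set <- function(sample_id, fusions) {
  stopifnot(is.data.frame(fusions),
            all(c("chrom5", "pos5", "gene5", "chrom3", "pos3", "gene3")
                %in% names(fusions)))
  fusions$chrom5 <- normalize_chrom(fusions$chrom5)
  fusions$chrom3 <- normalize_chrom(fusions$chrom3)
  fusions$pos5 <- as.integer(fusions$pos5)
  fusions$pos3 <- as.integer(fusions$pos3)
  key <- fusion_key(fusions)
  if (anyDuplicated(key)) {
    warning("fusion_set: duplicated breakpoints collapsed in sample '",
            sample_id, "'")
    fusions <- fusions[!duplicated(key), , drop = FALSE]
  }
  rownames(fusions) <- NULL
  structure(list(sample_id = as.character(sample_id), fusions = fusions),
            class = "fusion_set")
}

fusion_key <- function(f) paste(f$chrom5, f$pos5, f$chrom3, f$pos3,
                                sep = ":")

#' @export
print.fusion_set <- function(x, ...) {
  cat("<fusion_set> sample", x$sample_id, "-", nrow(x$fusions),
      "fusions\n")
  invisible(x)
}
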