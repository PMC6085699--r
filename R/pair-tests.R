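# Per-pair clonality tests: Euclidean distance with a 5th-percentile
# null, single-linkage dendrogram cherries, exact-breakpoint shared
# segments and shared mutations with 95th-percentile nulls, and fusion
# breakpoint overlap.  All nulls are the artificial cross-patient pairs
# of the cohort; percentiles use the empirical quantile with linear
# interpolation (stats::quantile type 7).

MIN_NULL <- 20L  # minimum artificial pairs for a meaningful percentile

# probes x samples value matrix over the probes common to all profiles
value_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  ids <- Reduce(intersect, lapply(profiles, function(p) p$probes$probe_id))
  if (length(ids) < 2L)
    stop("value_matrix: fewer than 2 probes common to all samples")
  m <- vapply(profiles,
              function(p) p$probes$value[match(ids, p$probes$probe_id)],
              numeric(length(ids)))
  dimnames(m) <- list(ids, vapply(profiles, function(p) p$sample_id, ""))
  m
}

#' Euclidean distance between two probe profiles
#'
#' Square root of the summed squared per-probe differences over the
#' probes common to both profiles.
#'
#' @param a,b [probe_profile()] objects on the same platform with at
#'   least 2 common probes.
#' @return nonnegative distance.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(inherits(a, "probe_profile"), inherits(b, "probe_profile"))
  if (a$platform != b$platform)
    stop("euclidean_distance: platform mismatch")
  ids <- intersect(a$probes$probe_id, b$probes$probe_id)
  if (length(ids) < 2L)
    stop("euclidean_distance: fewer than 2 common probes")
  va <- a$probes$value[match(ids, a$probes$probe_id)]
  vb <- b$probes$value[match(ids, b$probes$probe_id)]
  sqrt(sum((va - vb)^2))
}

#' Distance clonality decision for one pair
#'
#' A true pair is called clonal when its distance lies at or below the
#' 5th percentile of the artificial-pair distance distribution.
#'
#' @param d_true Euclidean distance of the true pair.
#' @param null_distances distances of the artificial pairs (at least 20
#'   for an evaluable decision).
#' @return list with `statistic`, `threshold` (the 5th percentile), `p`
#'   (add-one empirical lower-tail p-value) and `call`.
#' @export
distance_test <- function(d_true, null_distances) {
  if (length(null_distances) < MIN_NULL) {
    warning("distance_test: fewer than ", MIN_NULL,
            " artificial pairs; not evaluable")
    return(list(statistic = d_true, threshold = NA_real_, p = NA_real_,
                call = "not_evaluable"))
  }
  thr <- stats::quantile(null_distances, 0.05, names = FALSE)
  list(statistic = d_true, threshold = thr,
       p = (1 + sum(null_distances <= d_true)) /
           (1 + length(null_distances)),
       call = if (d_true <= thr) "clonal" else "independent")
}

#' Distance clonality test for a cohort
#'
#' @param profiles named list of [probe_profile()] objects (one
#'   platform).
#' @param pairs result of [enumerate_pairs()].
#' @param method label recorded in the result.
#' @return data.frame with one row per true pair (columns as
#'   [si_test()], with `p_si = NA`).
#' @export
cohort_distance_test <- function(profiles, pairs, method = "distance") {
  m <- value_matrix(profiles)
  d <- as.matrix(stats::dist(t(m)))
  tp <- pairs$true_pairs
  ap <- pairs$artificial_pairs
  null_d <- d[cbind(ap$sample_a, ap$sample_b)]
  rows <- lapply(seq_len(nrow(tp)), function(i)
    distance_test(d[tp$sample_a[i], tp$sample_b[i]], null_d))
  data.frame(patient_id = tp$patient_id,
             sample_a = tp$sample_a, sample_b = tp$sample_b,
             method = method,
             statistic = vapply(rows, `[[`, 0, "statistic"),
             p_si = NA_real_,
             p = vapply(rows, `[[`, 0, "p"),
             threshold = vapply(rows, `[[`, 0, "threshold"),
             call = vapply(rows, `[[`, "", "call"),
             stringsAsFactors = FALSE)
}

#' Dendrogram cherry clonality test
#'
#' Builds a single-linkage hierarchical clustering of all samples on
#' Euclidean distances and calls a true pair clonal when its two samples
#' form a *cherry*: a terminal dendrogram branch whose merge joins
#' exactly those two leaves.  Samples are ordered lexicographically by
#' id before clustering so that ties in merge distances are resolved
#' deterministically.
#'
#' @param profiles named list of [probe_profile()] objects (one
#'   platform, at least 4 samples).
#' @param pairs result of [enumerate_pairs()].
#' @param method label recorded in the result.
#' @return data.frame with one row per true pair; `statistic` is 1 for
#'   a cherry and 0 otherwise, `threshold` and `p` are `NA`.
#' @export
cluster_cherry_test <- function(profiles, pairs, method = "cluster") {
  if (length(profiles) < 4L)
    stop("cluster_cherry_test: need at least 4 samples")
  ids <- sort(vapply(profiles, function(p) p$sample_id, ""))
  m <- value_matrix(profiles)[, ids, drop = FALSE]
  hc <- stats::hclust(stats::dist(t(m)), method = "single")
  cherry <- hc$merge[hc$merge[, 1L] < 0L & hc$merge[, 2L] < 0L, ,
                     drop = FALSE]
  cherry_keys <- apply(-cherry, 1L, function(k)
    paste(sort(hc$labels[k]), collapse = "\r"))
  tp <- pairs$true_pairs
  pair_keys <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "\r"),
                      tp$sample_a, tp$sample_b)
  is_cherry <- pair_keys %in% cherry_keys
  data.frame(patient_id = tp$patient_id,
             sample_a = tp$sample_a, sample_b = tp$sample_b,
             method = method,
             statistic = as.numeric(is_cherry),
             p_si = NA_real_, p = NA_real_, threshold = NA_real_,
             call = ifelse(is_cherry, "clonal", "independent"),
             stringsAsFactors = FALSE)
}

seg_keys <- function(p) {
  s <- p$segments[p$segments$status != "normal", , drop = FALSE]
  paste(s$chrom, s$start, s$end, s$status, sep = ":")
}

#' Count exact shared segments between two segmented profiles
#'
#' A segment is shared when both profiles contain a segment with the
#' exact same loci at both ends (identical chrom, start and end) and the
#' same aberration direction (both loss or both gain); normal segments
#' never count.  A small breakpoint tolerance can be allowed for
#' cross-platform comparisons; the default 0 bp keeps the exact-locus
#' rule.
#'
#' @param a,b [segmented_profile()] objects.
#' @param tol breakpoint tolerance in bp applied to both ends
#'   (default 0).
#' @return integer count of shared segments.
#' @export
shared_segments <- function(a, b, tol = 0L) {
  stopifnot(inherits(a, "segmented_profile"),
            inherits(b, "segmented_profile"))
  if (tol == 0L)
    return(length(intersect(seg_keys(a), seg_keys(b))))
  sa <- a$segments[a$segments$status != "normal", , drop = FALSE]
  sb <- b$segments[b$segments$status != "normal", , drop = FALSE]
  if (nrow(sa) == 0L || nrow(sb) == 0L) return(0L)
  sum(vapply(seq_len(nrow(sa)), function(i) {
    any(sb$chrom == sa$chrom[i] & sb$status == sa$status[i] &
        abs(sb$start - sa$start[i]) <= tol &
        abs(sb$end - sa$end[i]) <= tol)
  }, NA))
}

percentile_count_test <- function(count_true, null_counts, what) {
  if (length(null_counts) < MIN_NULL) {
    warning(what, ": fewer than ", MIN_NULL,
            " artificial pairs; not evaluable")
    return(list(statistic = count_true, threshold = NA_real_,
                p = NA_real_, call = "not_evaluable"))
  }
  thr <- stats::quantile(null_counts, 0.95, names = FALSE)
  list(statistic = count_true, threshold = thr,
       p = (1 + sum(null_counts >= count_true)) / (1 + length(null_counts)),
       call = if (count_true > thr) "clonal" else "independent")
}

#' Shared-segment clonality decision for one pair
#'
#' A true pair is called clonal when its shared-segment count lies
#' strictly above the 95th percentile of the artificial-pair counts.
#'
#' @param count_true shared-segment count of the true pair.
#' @param null_counts counts over the artificial pairs (at least 20).
#' @return list with `statistic`, `threshold`, `p` (add-one empirical
#'   upper-tail p-value) and `call`.
#' @export
shared_segment_test <- function(count_true, null_counts) {
  percentile_count_test(count_true, null_counts, "shared_segment_test")
}

#' Shared-segment clonality test for a cohort
#'
#' @param profiles named list of [segmented_profile()] objects.
#' @param pairs result of [enumerate_pairs()].
#' @param tol breakpoint tolerance in bp (default 0, exact loci).
#' @param method label recorded in the result.
#' @return data.frame with one row per true pair.
#' @export
cohort_segment_test <- function(profiles, pairs, tol = 0L,
                                method = "segments") {
  counts <- if (tol == 0L) {
    pairwise_shared_counts(lapply(profiles, seg_keys))
  } else {
    pairwise_counts_loop(profiles, function(a, b)
      shared_segments(a, b, tol = tol))
  }
  percentile_cohort_result(counts, pairs, method, shared_segment_test)
}

#' Count shared mutations between two variant sets
#'
#' Number of variants identical in both tumours, i.e. matching on
#' (chrom, pos, ref, alt).  When a panel is supplied, both sets are
#' first restricted to the panel regions (e.g. a breast-cancer and
#' DNA-repair mutation-spot panel).
#'
#' @param a,b [variant_set()] objects.
#' @param panel optional data.frame of regions with columns `chrom`,
#'   `start`, `end` (see [read_panel()]).
#' @return integer count of shared variants.
#' @export
shared_mutations <- function(a, b, panel = NULL) {
  stopifnot(inherits(a, "variant_set"), inherits(b, "variant_set"))
  va <- restrict_to_panel(a$variants, panel)
  vb <- restrict_to_panel(b$variants, panel)
  length(intersect(variant_key(va), variant_key(vb)))
}

restrict_to_panel <- function(v, panel) {
  if (is.null(panel)) return(v)
  stopifnot(all(c("chrom", "start", "end") %in% names(panel)))
  keep <- rep(FALSE, nrow(v))
  pc <- normalize_chrom(panel$chrom)
  for (i in seq_len(nrow(panel)))
    keep <- keep | (v$chrom == pc[i] & v$pos >= panel$start[i] &
                    v$pos <= panel$end[i])
  v[keep, , drop = FALSE]
}

#' Read a mutation-panel region file
#'
#' TSV with columns `chrom`, `start`, `end` and optionally `name`
#' (1-based inclusive coordinates), defining the regions of a
#' user-supplied mutation-spot panel.
#'
#' @param path path to a tab-separated file.
#' @return data.frame of regions.
#' @export
read_panel <- function(path) {
  d <- read_tsv_checked(path, c("chrom", "start", "end"), "read_panel")
  d$start <- check_numeric_col(d, "start", path, "read_panel")
  d$end <- check_numeric_col(d, "end", path, "read_panel")
  if (any(d$end < d$start)) stop("read_panel: region with end < start")
  d$chrom <- normalize_chrom(d$chrom)
  d
}

#' Shared-mutation clonality decision for one pair
#'
#' Same decision rule as [shared_segment_test()]: clonal when the shared
#' count lies strictly above the 95th percentile of the artificial-pair
#' counts.
#'
#' @inheritParams shared_segment_test
#' @return list with `statistic`, `threshold`, `p` and `call`.
#' @export
shared_mutation_test <- function(count_true, null_counts) {
  percentile_count_test(count_true, null_counts, "shared_mutation_test")
}

#' Shared-mutation clonality test for a cohort
#'
#' @param sets named list of [variant_set()] objects.
#' @param pairs result of [enumerate_pairs()].
#' @param panel optional region panel (see [shared_mutations()]).
#' @param method label recorded in the result.
#' @return data.frame with one row per true pair.
#' @export
cohort_mutation_test <- function(sets, pairs, panel = NULL,
                                 method = "mutations") {
  keys <- lapply(sets, function(s)
    variant_key(restrict_to_panel(s$variants, panel)))
  counts <- pairwise_shared_counts(keys)
  percentile_cohort_result(counts, pairs, method, shared_mutation_test)
}

#' Fusion-transcript breakpoint overlap
#'
#' Fusions with identical 5' and 3' partner breakpoints in both tumours.
#' Gene symbols are reported for the shared fusions but matching is on
#' breakpoints only.
#'
#' @param a,b [fusion_set()] objects.
#' @return list with `count` and `shared` (the matching fusions of `a`).
#' @export
fusion_overlap <- function(a, b) {
  stopifnot(inherits(a, "fusion_set"), inherits(b, "fusion_set"))
  hit <- fusion_key(a$fusions) %in% fusion_key(b$fusions)
  list(count = sum(hit), shared = a$fusions[hit, , drop = FALSE])
}

#' Fusion-overlap test for a cohort
#'
#' Counts identical-breakpoint fusions for every true pair.  Exact
#' breakpoint coincidence between unrelated tumours is essentially never
#' observed, so the (descriptive) decision rule is: clonal when at least
#' one fusion is shared.
#'
#' @param sets named list of [fusion_set()] objects.
#' @param pairs result of [enumerate_pairs()].
#' @param method label recorded in the result.
#' @return data.frame with one row per true pair.
#' @export
cohort_fusion_test <- function(sets, pairs, method = "fusions") {
  tp <- pairs$true_pairs
  counts <- mapply(function(a, b) fusion_overlap(sets[[a]], sets[[b]])$count,
                   tp$sample_a, tp$sample_b)
  data.frame(patient_id = tp$patient_id,
             sample_a = tp$sample_a, sample_b = tp$sample_b,
             method = method,
             statistic = as.numeric(counts),
             p_si = NA_real_, p = NA_real_, threshold = 0,
             call = ifelse(counts >= 1L, "clonal", "independent"),
             stringsAsFactors = FALSE)
}

# Pairwise shared-key counts for all samples at once, via a sparse
# incidence matrix crossproduct (samples x samples count matrix).
pairwise_shared_counts <- function(key_list) {
  ids <- names(key_list)
  all_keys <- unique(unlist(key_list, use.names = FALSE))
  n <- vapply(key_list, length, 0L)
  if (length(all_keys) == 0L) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    return(m)
  }
  inc <- Matrix::sparseMatrix(
    i = match(unlist(key_list, use.names = FALSE), all_keys),
    j = rep(seq_along(key_list), n),
    x = 1, dims = c(length(all_keys), length(key_list)))
  m <- as.matrix(Matrix::crossprod(inc))
  dimnames(m) <- list(ids, ids)
  m
}

pairwise_counts_loop <- function(profiles, fun) {
  ids <- names(profiles)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids))
    for (j in seq_len(i - 1L))
      m[i, j] <- m[j, i] <- fun(profiles[[i]], profiles[[j]])
  m
}

percentile_cohort_result <- function(counts, pairs, method, decide) {
  tp <- pairs$true_pairs
  ap <- pairs$artificial_pairs
  null_counts <- counts[cbind(ap$sample_a, ap$sample_b)]
  rows <- lapply(seq_len(nrow(tp)), function(i)
    decide(counts[tp$sample_a[i], tp$sample_b[i]], null_counts))
  data.frame(patient_id = tp$patient_id,
             sample_a = tp$sample_a, sample_b = tp$sample_b,
             method = method,
             statistic = vapply(rows, `[[`, 0, "statistic"),
             p_si = NA_real_,
             p = vapply(rows, `[[`, 0, "p"),
             threshold = vapply(rows, `[[`, 0, "threshold"),
             call = vapply(rows, `[[`, "", "call"),
             stringsAsFactors = FALSE)
}
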