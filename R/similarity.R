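# Discretization and the similarity-index (SI) family.
#
# All thresholds use strict inequalities: a value exactly equal to a
# cut-off falls in the neutral (or hemi-methylated) class.

#' Discretize copy-number-like log2 ratios
#'
#' Three-state calls: heterozygous loss (value < `loss_thr`), normal, and
#' low-level gain (value > `gain_thr`).  Applies to aCGH log2 ratios,
#' methylation-array intensity log2 ratios and SNP-array LRR values.
#'
#' @param profile a [probe_profile()] with platform `copy_number`,
#'   `methylation_intensity` or `snp_lrr`.
#' @param loss_thr,gain_thr strict thresholds (defaults -0.3 / +0.3).
#' @return a [discrete_profile()] with scheme `cn3`.
#' @export
discretize_copy_number <- function(profile, loss_thr = -0.3,
                                   gain_thr = 0.3) {
  stopifnot(inherits(profile, "probe_profile"))
  if (!profile$platform %in% c("copy_number", "methylation_intensity",
                               "snp_lrr"))
    stop("discretize_copy_number: platform '", profile$platform,
         "' is not a copy-number-like platform")
  v <- profile$probes$value
  state <- ifelse(v < loss_thr, -1L, ifelse(v > gain_thr, 1L, 0L))
  p <- profile$probes[, c("probe_id", "chrom", "pos")]
  p$state <- state
  discrete_profile(profile$sample_id, "cn3", p, c(loss_thr, gain_thr))
}

#' Discretize expression log2 ratios
#'
#' Three-state calls with a 1.5-fold-change cut-off: underexpressed
#' (log2 ratio < `-thr`), neutral, overexpressed (log2 ratio > `thr`).
#'
#' @param profile a [probe_profile()] with platform `expression`.
#' @param thr strict threshold (default 0.58).
#' @return a [discrete_profile()] with scheme `expr3`.
#' @export
discretize_expression <- function(profile, thr = 0.58) {
  stopifnot(inherits(profile, "probe_profile"))
  if (profile$platform != "expression")
    stop("discretize_expression: platform must be 'expression'")
  v <- profile$probes$value
  state <- ifelse(v < -thr, -1L, ifelse(v > thr, 1L, 0L))
  p <- profile$probes[, c("probe_id", "chrom", "pos")]
  p$state <- state
  discrete_profile(profile$sample_id, "expr3", p, c(-thr, thr))
}

#' Discretize methylation beta values
#'
#' Beta values > `high` are methylated (`"M"`), < `low` unmethylated
#' (`"U"`), and the closed range `[low, high]` hemi-methylated (`"H"`).
#'
#' @param profile a [probe_profile()] with platform `methylation_beta`.
#' @param low,high strict thresholds (defaults 0.2 / 0.8).
#' @return a [discrete_profile()] with scheme `meth3`.
#' @export
discretize_methylation <- function(profile, low = 0.2, high = 0.8) {
  stopifnot(inherits(profile, "probe_profile"))
  if (profile$platform != "methylation_beta")
    stop("discretize_methylation: platform must be 'methylation_beta'")
  v <- profile$probes$value
  if (any(v < 0 | v > 1))
    stop("discretize_methylation: beta value outside [0, 1]")
  state <- ifelse(v > high, "M", ifelse(v < low, "U", "H"))
  p <- profile$probes[, c("probe_id", "chrom", "pos")]
  p$state <- state
  discrete_profile(profile$sample_id, "meth3", p, c(low, high))
}

common_probes <- function(a, b) {
  ids <- intersect(a$probes$probe_id, b$probes$probe_id)
  list(a = a$probes$state[match(ids, a$probes$probe_id)],
       b = b$probes$state[match(ids, b$probes$probe_id)],
       n = length(ids))
}

#' Count shared, unique and opposite changes between two profiles
#'
#' Per common probe of two `cn3`/`expr3` profiles: both calls aberrant and
#' equal is a shared change (N_S); exactly one aberrant is a unique change
#' (N_U); both aberrant with different sign is an opposite change (N_O);
#' both normal is neutral.  These counts feed [similarity_index()].
#'
#' @param a,b [discrete_profile()] objects with the same scheme (`cn3` or
#'   `expr3`) and at least one common probe.
#' @return an object of class `similarity_counts`: list with integer
#'   fields `n_shared`, `n_unique`, `n_opposite`, `n_neutral`, `n_probes`
#'   and the similarity index `si` (`NA` when no probe is aberrant in
#'   either profile).
#' @export
count_states <- function(a, b) {
  stopifnot(inherits(a, "discrete_profile"),
            inherits(b, "discrete_profile"))
  if (a$scheme != b$scheme)
    stop("count_states: scheme mismatch ('", a$scheme, "' vs '",
         b$scheme, "')")
  if (a$scheme == "meth3")
    stop("count_states: meth3 profiles are compared with ",
         "similarity_index_met()")
  cp <- common_probes(a, b)
  if (cp$n < 1L) stop("count_states: no common probes")
  sa <- cp$a; sb <- cp$b
  shared <- sum(sa != 0L & sa == sb)
  opposite <- sum(sa != 0L & sb != 0L & sa != sb)
  uniq <- sum(xor(sa != 0L, sb != 0L))
  neutral <- sum(sa == 0L & sb == 0L)
  counts <- structure(list(n_shared = shared, n_unique = uniq,
                           n_opposite = opposite, n_neutral = neutral,
                           n_probes = cp$n, si = NA_real_),
                      class = "similarity_counts")
  counts$si <- similarity_index(counts)
  counts
}

#' @export
print.similarity_counts <- function(x, ...) {
  cat("<similarity_counts> N_S =", x$n_shared, " N_U =", x$n_unique,
      " N_O =", x$n_opposite, " neutral =", x$n_neutral,
      " SI =", format(x$si, digits = 4), "\n")
  invisible(x)
}

#' Similarity index from change counts
#'
#' `SI = N_S / (N_S + N_U + N_O)`, ranging from 0 (no shared aberration)
#' to 1 (identical aberration profiles).  Probes that are normal in both
#' tumours do not contribute: sharing the neutral state is not evidence
#' of common origin.  When no probe is aberrant in either tumour the SI
#' is undefined and `NA` is returned; downstream tests propagate this as
#' a `not_evaluable` call.
#'
#' @param counts a `similarity_counts` object from [count_states()].
#' @return the SI in \[0, 1\], or `NA_real_` when undefined.
#' @export
similarity_index <- function(counts) {
  stopifnot(inherits(counts, "similarity_counts"))
  denom <- counts$n_shared + counts$n_unique + counts$n_opposite
  if (denom == 0L) return(NA_real_)
  counts$n_shared / denom
}

#' Methylation similarity index (SI_met)
#'
#' Fraction of common probes whose three-level methylation state
#' (U/H/M) is identical in the two tumours.  Unlike the copy-number SI
#' there is no biologically neutral methylation state, so *all* matching
#' states count, including hemi-methylated ones, and the denominator is
#' the total number of common probes; SI_met is therefore always defined.
#'
#' @param a,b [discrete_profile()] objects with scheme `meth3` and at
#'   least one common probe.
#' @return SI_met in \[0, 1\].
#' @export
similarity_index_met <- function(a, b) {
  stopifnot(inherits(a, "discrete_profile"),
            inherits(b, "discrete_profile"))
  if (a$scheme != "meth3" || b$scheme != "meth3")
    stop("similarity_index_met: both profiles must use the meth3 scheme")
  cp <- common_probes(a, b)
  if (cp$n < 1L) stop("similarity_index_met: no common probes")
  mean(cp$a == cp$b)
}

# States of a list of discrete profiles over their common probe set,
# as a probes x samples matrix (integer for cn3/expr3, character for
# meth3).  Errors when fewer than 2 probes are common to all samples.
state_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  ids <- Reduce(intersect, lapply(profiles, function(p) p$probes$probe_id))
  if (length(ids) < 2L)
    stop("state_matrix: fewer than 2 probes common to all samples")
  m <- vapply(profiles,
              function(p) p$probes$state[match(ids, p$probes$probe_id)],
              profiles[[1L]]$probes$state[seq_along(ids)])
  dimnames(m) <- list(ids, vapply(profiles, function(p) p$sample_id, ""))
  m
}

# All pairwise SI values from a cn3/expr3 state matrix via crossproducts;
# equals count_states()/similarity_index() applied to every sample pair.
pairwise_si_matrix <- function(m) {
  A <- m == 1L
  B <- m == -1L
  shared <- crossprod(A) + crossprod(B)
  opposite <- crossprod(A, B) + crossprod(B, A)
  n_aber <- colSums(A | B)
  denom <- outer(n_aber, n_aber, "+") - shared - opposite
  si <- shared / denom
  si[denom == 0] <- NA_real_
  si
}

# All pairwise SI_met values from a meth3 state matrix.
pairwise_si_met_matrix <- function(m) {
  eq <- Reduce(`+`, lapply(c("U", "H", "M"),
                           function(s) crossprod(m == s)))
  eq / nrow(m)
}

#' Permutation-based P_SI
#'
#' `P_SI = max(0, 100 * (SI - mean(null SI)) / SI)`: the percentage of a
#' pair's similarity that is *not* explained by recurrent aberrations or
#' chance, where the null mean is the average SI over all artificial
#' cross-patient pairs.  A pair whose SI does not exceed the null mean
#' scores 0.
#'
#' @param si_obs observed SI of the true pair.
#' @param mean_null mean SI over the artificial pairs.
#' @return P_SI as a percentage in \[0, 100\] (`NA` if `si_obs` is `NA`).
#' @export
p_si <- function(si_obs, mean_null) {
  ifelse(is.na(si_obs), NA_real_,
         pmax(0, 100 * (si_obs - mean_null) / si_obs))
}

#' Artificial-pair permutation null for the similarity index
#'
#' Computes the SI (or SI_met) of the observed pair and of every
#' artificial cross-patient pair, and summarises the null: its mean, the
#' derived [p_si()] percentage, and an add-one empirical p-value
#' `(1 + #\{null >= observed\}) / (1 + #null)` (one-sided, large SI =
#' evidence for clonality).
#'
#' @param pair list or one-row data.frame with `sample_a`, `sample_b`.
#' @param profiles named list of [discrete_profile()] objects covering
#'   at least two patients.
#' @param artificial_pairs data.frame of artificial pairs from
#'   [enumerate_pairs()].
#' @param statistic `"si"` (cn3/expr3 profiles) or `"si_met"` (meth3).
#' @return list with `si_obs`, `null_si`, `mean_null`, `p_si`,
#'   `p_empirical`.
#' @export
si_permutation <- function(pair, profiles, artificial_pairs,
                           statistic = c("si", "si_met")) {
  statistic <- match.arg(statistic)
  if (nrow(artificial_pairs) < 1L)
    stop("si_permutation: need at least 2 patients to form ",
         "artificial pairs")
  m <- state_matrix(profiles)
  si_mat <- if (statistic == "si") pairwise_si_matrix(m)
            else pairwise_si_met_matrix(m)
  si_obs <- si_mat[pair$sample_a, pair$sample_b]
  null_si <- si_mat[cbind(artificial_pairs$sample_a,
                          artificial_pairs$sample_b)]
  mean_null <- mean(null_si, na.rm = TRUE)
  list(si_obs = si_obs,
       null_si = null_si,
       mean_null = mean_null,
       p_si = p_si(si_obs, mean_null),
       p_empirical = if (is.na(si_obs)) NA_real_ else
         (1 + sum(null_si >= si_obs, na.rm = TRUE)) /
         (1 + sum(!is.na(null_si))))
}

#' Similarity-index clonality test for a cohort
#'
#' Runs the SI (or SI_met) with its artificial-pair permutation null for
#' every true pair; a pair is called clonal when the empirical p-value is
#' below `alpha`.
#'
#' @param profiles named list of [discrete_profile()] objects.
#' @param pairs result of [enumerate_pairs()].
#' @param statistic `"si"` or `"si_met"`.
#' @param alpha significance cut-off (default 0.05).
#' @param method label recorded in the result (defaults to `statistic`).
#' @return data.frame with one row per true pair: `patient_id`,
#'   `sample_a`, `sample_b`, `method`, `statistic` (the SI), `p_si`,
#'   `p` (empirical), `call` (`clonal`/`independent`/`not_evaluable`).
#' @export
si_test <- function(profiles, pairs, statistic = c("si", "si_met"),
                    alpha = 0.05, method = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(method)) method <- statistic
  m <- state_matrix(profiles)
  si_mat <- if (statistic == "si") pairwise_si_matrix(m)
            else pairwise_si_met_matrix(m)
  tp <- pairs$true_pairs
  ap <- pairs$artificial_pairs
  null_si <- si_mat[cbind(ap$sample_a, ap$sample_b)]
  mean_null <- mean(null_si, na.rm = TRUE)
  n_null <- sum(!is.na(null_si))
  si_obs <- si_mat[cbind(tp$sample_a, tp$sample_b)]
  p_emp <- vapply(si_obs, function(s) {
    if (is.na(s)) NA_real_
    else (1 + sum(null_si >= s, na.rm = TRUE)) / (1 + n_null)
  }, 0)
  data.frame(patient_id = tp$patient_id,
             sample_a = tp$sample_a, sample_b = tp$sample_b,
             method = method,
             statistic = si_obs,
             p_si = p_si(si_obs, mean_null),
             p = p_emp,
             threshold = NA_real_,
             call = ifelse(is.na(si_obs), "not_evaluable",
                    ifelse(p_emp < alpha, "clonal", "independent")),
             stringsAsFactors = FALSE)
}

#' Beta-value variability of a sample
#'
#' Spread of the per-probe methylation beta values, measured as the span
#' between their 5th and 95th percentiles.
#'
#' @param profile a [probe_profile()] with platform `methylation_beta`
#'   and at least 20 probes.
#' @return P95 - P5 of the beta values, in \[0, 1\].
#' @export
beta_variability <- function(profile) {
  stopifnot(inherits(profile, "probe_profile"))
  if (profile$platform != "methylation_beta")
    stop("beta_variability: platform must be 'methylation_beta'")
  v <- profile$probes$value
  if (length(v) < 20L)
    stop("beta_variability: need at least 20 probes")
  q <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
  q[2L] - q[1L]
}

#' Per-probe aberration frequencies across a cohort
#'
#' For each probe, the fraction of samples called gained (+1) and lost
#' (-1); a probe is flagged recurrent when either fraction reaches
#' `min_freq`.  Sex-chromosome probes are excluded by default, since
#' population frequencies on X/Y are confounded by patient sex.
#'
#' @param profiles named list of [discrete_profile()] objects (scheme
#'   `cn3`).
#' @param min_freq recurrence cut-off (default 0.25).
#' @param exclude_sex drop probes on chromosomes X and Y (default TRUE).
#' @return data.frame with `probe_id`, `chrom`, `pos`, `gain_freq`,
#'   `loss_freq`, `recurrent`.
#' @export
aberration_frequency <- function(profiles, min_freq = 0.25,
                                 exclude_sex = TRUE) {
  stopifnot(length(profiles) >= 1L)
  if (length(profiles) == 1L) {
    p <- profiles[[1L]]$probes
    m <- matrix(p$state, ncol = 1L, dimnames = list(p$probe_id, NULL))
    ann <- p
  } else {
    m <- state_matrix(profiles)
    ann <- profiles[[1L]]$probes[
      match(rownames(m), profiles[[1L]]$probes$probe_id), ]
  }
  out <- data.frame(probe_id = ann$probe_id, chrom = ann$chrom,
                    pos = ann$pos,
                    gain_freq = rowMeans(m == 1L),
                    loss_freq = rowMeans(m == -1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$recurrent <- out$gain_freq >= min_freq | out$loss_freq >= min_freq
  if (exclude_sex) out <- out[!is_sex_chrom(out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}
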