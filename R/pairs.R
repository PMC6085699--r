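#' Enumerate true and artificial tumour pairs
#'
#' The permutation null of every pair statistic in this package is built
#' from "artificial" pairs: every unordered combination of two tumours
#' from *different* patients.  For `n` patients contributing two tumours
#' each there are `n` true pairs and `2 n (n - 1)` artificial pairs, which
#' together exhaust the `choose(2n, 2)` unordered sample pairs.
#'
#' @param manifest data.frame with columns `patient_id`, `sample_id`,
#'   `tumour_index` (see [read_manifest()]).
#' @param clinical optional `clinical_table`; when given, each true pair
#'   is annotated with its clinical group (BM/BS/IM/IS, see
#'   [assign_group()]).
#' @return list with data.frames `true_pairs` and `artificial_pairs`,
#'   each with columns `patient_id`, `sample_a`, `sample_b`,
#'   `is_true_pair`, `group`.
#' @examples
#' m <- data.frame(patient_id = rep(c("P1", "P2"), each = 2),
#'                 sample_id = c("P1a", "P1b", "P2a", "P2b"),
#'                 tumour_index = c(1, 2, 1, 2))
#' enumerate_pairs(m)
#' @export
enumerate_pairs <- function(manifest, clinical = NULL) {
  manifest <- validate_manifest(manifest)
  manifest <- manifest[order(manifest$patient_id, manifest$tumour_index), ]
  patients <- unique(manifest$patient_id)
  groups <- rep(NA_character_, length(patients))
  if (!is.null(clinical)) {
    idx <- match(patients, clinical$patient_id)
    ok <- !is.na(idx)
    groups[ok] <- assign_group(clinical$laterality[idx[ok]],
                               clinical$interval_days[idx[ok]])
  }
  samp <- split(manifest$sample_id, manifest$patient_id)[patients]
  true_pairs <- data.frame(
    patient_id = patients,
    sample_a = vapply(samp, `[`, "", 1L),
    sample_b = vapply(samp, `[`, "", 2L),
    is_true_pair = TRUE,
    group = groups,
    stringsAsFactors = FALSE, row.names = NULL)

  all_samples <- manifest$sample_id
  owner <- manifest$patient_id
  cmb <- utils::combn(seq_along(all_samples), 2L)
  cross <- owner[cmb[1L, ]] != owner[cmb[2L, ]]
  artificial_pairs <- data.frame(
    patient_id = NA_character_,
    sample_a = all_samples[cmb[1L, cross]],
    sample_b = all_samples[cmb[2L, cross]],
    is_true_pair = FALSE,
    group = NA_character_,
    stringsAsFactors = FALSE)
  list(true_pairs = true_pairs, artificial_pairs = artificial_pairs)
}
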