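# Histopathological concordance between the two tumours of a patient,
# clinical group assignment (BM/BS/IM/IS) and the copy-number-derived
# HER2 call.

CLIN_FEATURES <- c("histology", "er", "her2", "subtype")

#' Assign the clinical group of a tumour pair
#'
#' Groups combine laterality (B = bilateral, I = ipsilateral) with
#' synchronicity: metachronous (M) when the second tumour was diagnosed
#' more than 6 months (interpreted as more than 183 days) after the
#' first, synchronous (S) otherwise.
#'
#' @param laterality `"bilateral"` or `"ipsilateral"` (vectorised).
#' @param interval_days nonnegative days between the two diagnoses.
#' @return character vector of `"BM"`, `"BS"`, `"IM"`, `"IS"`.
#' @examples
#' assign_group("bilateral", 346)   # "BM"
#' assign_group("ipsilateral", 50)  # "IS"
#' @export
assign_group <- function(laterality, interval_days) {
  if (anyNA(laterality) || anyNA(interval_days))
    stop("assign_group: laterality and interval_days are required")
  if (!all(laterality %in% c("bilateral", "ipsilateral")))
    stop("assign_group: laterality must be 'bilateral' or 'ipsilateral'")
  paste0(toupper(substr(laterality, 1L, 1L)),
         ifelse(interval_days > 183, "M", "S"))
}

norm_feature <- function(x) {
  x <- trimws(as.character(x))
  ifelse(toupper(x) == "ND", "ND", tolower(x))
}

#' Feature-level concordance between the two tumours of each patient
#'
#' Compares histology, ER, HER2 and molecular subtype between tumour 1
#' and tumour 2.  Equal values are concordant, unequal values (both
#' determined) discordant; when either side is `"ND"` the feature is not
#' evaluable and does not count towards discordance.  A patient is
#' overall discordant when at least one evaluable feature is discordant.
#' Histology strings are compared verbatim (case-insensitively), so
#' "NOS" and "NST" are distinct subtypes.
#'
#' @param clinical a `clinical_table` (see [read_clinical()]).
#' @return data.frame with one row per patient: `patient_id`, `group`,
#'   per-feature status (`histology`, `er`, `her2`, `subtype`, each
#'   `concordant`/`discordant`/`not_evaluable`), `n_discordant` and
#'   `overall`.
#' @export
feature_concordance <- function(clinical) {
  clinical <- validate_clinical(as.data.frame(clinical))
  status <- sapply(CLIN_FEATURES, function(f) {
    v1 <- norm_feature(clinical[[paste0(f, "_1")]])
    v2 <- norm_feature(clinical[[paste0(f, "_2")]])
    ifelse(v1 == "ND" | v2 == "ND", "not_evaluable",
           ifelse(v1 == v2, "concordant", "discordant"))
  })
  status <- matrix(status, nrow = nrow(clinical),
                   dimnames = list(NULL, CLIN_FEATURES))
  n_disc <- rowSums(status == "discordant")
  out <- data.frame(patient_id = clinical$patient_id,
                    group = assign_group(clinical$laterality,
                                         clinical$interval_days),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(status, stringsAsFactors = FALSE))
  out$n_discordant <- as.integer(n_disc)
  out$overall <- ifelse(n_disc >= 1L, "discordant", "concordant")
  out
}

#' Cohort-level concordance summary
#'
#' Per-feature discordance counts with denominators restricted to the
#' patients in whom the feature was determined for both tumours, plus
#' the overall number of discordant patients and the number with exactly
#' two discordant features.
#'
#' @param clinical a `clinical_table`.
#' @return list with `features` (data.frame: `feature`, `n_discordant`,
#'   `n_evaluable`), `n_patients`, `n_discordant_overall` and
#'   `n_two_discordant`.
#' @export
cohort_concordance_summary <- function(clinical) {
  fc <- feature_concordance(clinical)
  feats <- data.frame(
    feature = CLIN_FEATURES,
    n_discordant = vapply(CLIN_FEATURES,
                          function(f) sum(fc[[f]] == "discordant"), 0L),
    n_evaluable = vapply(CLIN_FEATURES,
                         function(f) sum(fc[[f]] != "not_evaluable"), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  list(features = feats,
       n_patients = nrow(fc),
       n_discordant_overall = sum(fc$overall == "discordant"),
       n_two_discordant = sum(fc$n_discordant == 2L))
}

#' HER2 status from the copy-number log2 ratio at the HER2 locus
#'
#' Positive when the log2 ratio is at least +0.5 (inclusive), negative
#' below.
#'
#' @param log2_ratio finite numeric value(s) at the HER2 locus.
#' @return `"pos"` or `"neg"` (vectorised).
#' @export
her2_from_cn <- function(log2_ratio) {
  if (any(!is.finite(log2_ratio)))
    stop("her2_from_cn: non-finite log2 ratio")
  ifelse(log2_ratio >= 0.5, "pos", "neg")
}
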