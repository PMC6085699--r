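# Cross-method aggregation: Cohen's kappa agreement between clonality
# callers, the pairwise agreement matrix, and per-patient consensus
# tallies.

CALL_LEVELS <- c("clonal", "independent", "not_evaluable")

#' Cohen's kappa between two binary call vectors
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` for two
#' clonality callers, with `p_o` the observed agreement and `p_e` the
#' agreement expected from the marginal call frequencies (unweighted,
#' two categories).  Patients that are `not_evaluable` (or `NA`) in
#' either caller are dropped pairwise.
#'
#' @param calls_a,calls_b character vectors of `"clonal"` /
#'   `"independent"` / `"not_evaluable"` calls, same length.
#' @return kappa in \[-1, 1\]; `NA` when fewer than 2 patients are
#'   evaluable in both callers or when `p_e = 1` (both callers constant
#'   and equal, leaving chance agreement undefined).
#' @examples
#' cohens_kappa(c("clonal", "clonal", "independent"),
#'              c("clonal", "independent", "independent"))
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b))
  ok <- calls_a %in% c("clonal", "independent") &
        calls_b %in% c("clonal", "independent")
  a <- calls_a[ok]; b <- calls_b[ok]
  if (length(a) < 2L) return(NA_real_)
  p_o <- mean(a == b)
  p_e <- mean(a == "clonal") * mean(b == "clonal") +
         mean(a == "independent") * mean(b == "independent")
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Assemble a patient x method call matrix
#'
#' Binds per-method result tables (as returned by the `cohort_*_test`
#' and [si_test()] drivers) into a character matrix with one row per
#' patient and one column per method; patients missing from a method are
#' `not_evaluable`.
#'
#' @param results list of result data.frames; names override the
#'   `method` column as column labels when supplied.
#' @return character matrix of calls with patient row names.
#' @export
call_matrix <- function(results) {
  stopifnot(length(results) >= 1L)
  labels <- names(results)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(results, function(r) r$method[1L], "")
  if (anyDuplicated(labels))
    stop("call_matrix: duplicated method labels")
  patients <- unique(unlist(lapply(results, `[[`, "patient_id")))
  m <- matrix("not_evaluable", length(patients), length(results),
              dimnames = list(patients, labels))
  for (k in seq_along(results)) {
    r <- results[[k]]
    stopifnot(all(r$call %in% CALL_LEVELS))
    m[r$patient_id, k] <- r$call
  }
  m
}

#' Pairwise kappa agreement between methods
#'
#' Symmetric matrix of Cohen's kappa values between every pair of
#' method columns, the per-method mean kappa (excluding self), and the
#' top-agreeing method(s).
#'
#' @param matrix call matrix from [call_matrix()] (at least 2 methods).
#' @return list with `kappa` (symmetric matrix, unit diagonal where
#'   defined), `mean_kappa` (named vector) and `top` (methods attaining
#'   the maximal mean kappa).
#' @export
agreement_matrix <- function(matrix) {
  stopifnot(ncol(matrix) >= 2L)
  k <- ncol(matrix)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(matrix), colnames(matrix))
  for (i in seq_len(k))
    for (j in seq_len(i - 1L))
      out[i, j] <- out[j, i] <- cohens_kappa(matrix[, i], matrix[, j])
  mean_k <- vapply(seq_len(k), function(i)
    mean(out[i, -i], na.rm = TRUE), 0)
  names(mean_k) <- colnames(matrix)
  list(kappa = out, mean_kappa = mean_k,
       top = names(mean_k)[mean_k == max(mean_k, na.rm = TRUE) &
                           !is.na(mean_k)])
}

#' Per-patient consensus tally
#'
#' For every patient, the number of methods calling the pair clonal over
#' the number of methods for which the pair was evaluable.
#'
#' @param matrix call matrix from [call_matrix()].
#' @return data.frame with `patient_id`, `n_clonal`, `n_evaluable` and
#'   the display string `consensus` (`"0/0"` flags a patient no method
#'   could evaluate).
#' @export
consensus_tally <- function(matrix) {
  n_clonal <- rowSums(matrix == "clonal")
  n_eval <- rowSums(matrix != "not_evaluable")
  data.frame(patient_id = rownames(matrix),
             n_clonal = as.integer(n_clonal),
             n_evaluable = as.integer(n_eval),
             consensus = paste0(n_clonal, "/", n_eval),
             stringsAsFactors = FALSE, row.names = NULL)
}
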