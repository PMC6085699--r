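# End-to-end orchestration: run every evaluable clonality test on a
# cohort, assemble the patient x method call matrix and the consensus
# report.  Every threshold, null size and seed that influenced a call is
# recorded in the run log, so that each call is a fully explicit
# artefact of the run.

#' Run all clonality tests on a cohort
#'
#' Executes, for every probe platform supplied, the similarity-index
#' test (SI, or SI_met for beta values), single-linkage dendrogram
#' cherry clustering and the Euclidean distance test, plus the
#' shared-segment, shared-mutation (genome-wide and panel-restricted)
#' and fusion-overlap tests where those inputs are present.  Platforms
#' listed in `platforms` but absent from `probe_data` contribute columns
#' of `not_evaluable` calls rather than failing.
#'
#' @param manifest sample manifest data.frame (see [read_manifest()]).
#' @param probe_data named list of platform -> named list of
#'   [probe_profile()] objects (e.g. a `synthetic_cohort$profiles`).
#' @param segments optional named list of [segmented_profile()] objects.
#' @param variants optional named list of [variant_set()] objects.
#' @param fusions optional named list of [fusion_set()] objects.
#' @param clinical optional `clinical_table`, used to annotate groups
#'   and to add the histopathological concordance column.
#' @param panel optional mutation-panel regions (see [read_panel()]).
#' @param platforms platforms expected in the report (default: those
#'   present in `probe_data`).
#' @param alpha significance cut-off applied to every permutation
#'   p-value (default 0.05).
#' @param max_null optional cap on the number of artificial pairs; when
#'   exceeded, the null is subsampled reproducibly with `seed`.
#' @param seed integer seed recorded in the log and used only for null
#'   subsampling.
#' @param tol shared-segment breakpoint tolerance in bp.
#' @return list of class `clonality_run`: `call_matrix`, `results`
#'   (per-method data.frames), `kappa` ([agreement_matrix()] output, or
#'   `NULL` with < 2 methods), `tally` ([consensus_tally()]), `log`
#'   (character vector).
#' @export
run_clonality <- function(manifest, probe_data = list(), segments = NULL,
                          variants = NULL, fusions = NULL,
                          clinical = NULL, panel = NULL,
                          platforms = names(probe_data),
                          alpha = 0.05, max_null = Inf, seed = 1L,
                          tol = 0L) {
  pairs <- enumerate_pairs(manifest, clinical)
  n_art <- nrow(pairs$artificial_pairs)
  log <- c(sprintf("clonalpair run: %d patients, %d artificial pairs",
                   nrow(pairs$true_pairs), n_art),
           sprintf("alpha = %g, seed = %d, segment tolerance = %d bp",
                   alpha, as.integer(seed), as.integer(tol)))
  if (is.finite(max_null) && n_art > max_null) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    keep <- sort(sample.int(n_art, max_null))
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    pairs$artificial_pairs <- pairs$artificial_pairs[keep, , drop = FALSE]
    log <- c(log, sprintf(
      "null subsampled to %d of %d artificial pairs (seed %d)",
      as.integer(max_null), n_art, as.integer(seed)))
  }

  results <- list()
  note <- function(...) log <<- c(log, sprintf(...))

  for (pl in platforms) {
    profiles <- probe_data[[pl]]
    if (is.null(profiles)) {
      for (stub in paste(c("si", "cluster", "distance"), pl, sep = "_")) {
        results[[stub]] <- not_evaluable_result(pairs$true_pairs, stub)
        note("%s: platform '%s' absent; all pairs not_evaluable",
             stub, pl)
      }
      next
    }
    if (pl == "methylation_beta") {
      disc <- lapply(profiles, discretize_methylation)
      m <- paste("si_met", pl, sep = "_")
      results[[m]] <- si_test(disc, pairs, "si_met", alpha, method = m)
    } else if (pl == "expression") {
      disc <- lapply(profiles, discretize_expression)
      m <- paste("si", pl, sep = "_")
      results[[m]] <- si_test(disc, pairs, "si", alpha, method = m)
    } else {
      disc <- lapply(profiles, discretize_copy_number)
      m <- paste("si", pl, sep = "_")
      results[[m]] <- si_test(disc, pairs, "si", alpha, method = m)
    }
    note("%s: SI null mean over %d artificial pairs, call at p < %g",
         m, nrow(pairs$artificial_pairs), alpha)
    m <- paste("cluster", pl, sep = "_")
    results[[m]] <- cluster_cherry_test(profiles, pairs, method = m)
    note("%s: single linkage, Euclidean distance, cherry rule", m)
    m <- paste("distance", pl, sep = "_")
    results[[m]] <- cohort_distance_test(profiles, pairs, method = m)
    note("%s: 5th-percentile threshold %.4f", m,
         results[[m]]$threshold[1L])
  }

  if (!is.null(segments)) {
    results$segments <- cohort_segment_test(segments, pairs, tol = tol)
    note("segments: 95th-percentile threshold %.4f",
         results$segments$threshold[1L])
  }
  if (!is.null(variants)) {
    results$mutations <- cohort_mutation_test(variants, pairs)
    note("mutations: 95th-percentile threshold %.4f",
         results$mutations$threshold[1L])
    if (!is.null(panel)) {
      results$mutations_panel <-
        cohort_mutation_test(variants, pairs, panel = panel,
                             method = "mutations_panel")
      note("mutations_panel: %d regions, 95th-percentile threshold %.4f",
           nrow(panel), results$mutations_panel$threshold[1L])
    }
  }
  if (!is.null(fusions)) {
    results$fusions <- cohort_fusion_test(fusions, pairs)
    note("fusions: descriptive rule, clonal iff >= 1 shared breakpoint")
  }

  evaluable <- vapply(results, function(r)
    any(r$call != "not_evaluable"), NA)
  if (!any(evaluable))
    stop("run_clonality: no evaluable test for this cohort")

  cm <- call_matrix(results)
  kappa <- if (ncol(cm) >= 2L) agreement_matrix(cm) else NULL
  if (!is.null(kappa))
    note("top-agreeing method(s): %s", paste(kappa$top, collapse = ", "))
  structure(list(call_matrix = cm, results = results, kappa = kappa,
                 tally = consensus_tally(cm), log = log,
                 clinical = if (is.null(clinical)) NULL
                            else feature_concordance(clinical)),
            class = "clonality_run")
}

not_evaluable_result <- function(true_pairs, method) {
  data.frame(patient_id = true_pairs$patient_id,
             sample_a = true_pairs$sample_a,
             sample_b = true_pairs$sample_b,
             method = method, statistic = NA_real_, p_si = NA_real_,
             p = NA_real_, threshold = NA_real_,
             call = "not_evaluable", stringsAsFactors = FALSE)
}

#' @export
print.clonality_run <- function(x, ...) {
  cat("<clonality_run>", nrow(x$call_matrix), "patients x",
      ncol(x$call_matrix), "methods\n")
  print(x$tally)
  invisible(x)
}

#' Write a clonality run report
#'
#' Emits `call_matrix.tsv`, one `results/<method>.tsv` per test,
#' `consensus.tsv`, `kappa.tsv` (when computed) and `run.log`.  The
#' output is a pure function of the run object: re-running the same
#' analysis with the same seed reproduces the report byte for byte.
#'
#' @param run a `clonality_run` from [run_clonality()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  stopifnot(inherits(run, "clonality_run"))
  dir.create(file.path(dir, "results"), showWarnings = FALSE,
             recursive = TRUE)
  cm <- data.frame(patient_id = rownames(run$call_matrix),
                   run$call_matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(cm, file.path(dir, "call_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (m in names(run$results))
    utils::write.table(format(run$results[[m]], digits = 10),
                       file.path(dir, "results", paste0(m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$tally, file.path(dir, "consensus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$kappa)) {
    km <- data.frame(method = rownames(run$kappa$kappa),
                     format(run$kappa$kappa, digits = 10),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(km, file.path(dir, "kappa.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}
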