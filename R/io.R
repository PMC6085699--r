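# Readers and writers for the plain-text interchange formats.
# All genomic coordinates are 1-based with inclusive start and end
# (SEG convention); chromosome names are normalised by stripping any
# "chr" prefix.

read_tsv_checked <- function(path, required, what) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  d
}

check_numeric_col <- function(d, col, path, what) {
  x <- suppressWarnings(as.numeric(d[[col]]))
  bad <- which(is.na(x) & !is.na(d[[col]]))
  if (length(bad))
    stop(what, ": malformed value '", d[[col]][bad[1L]], "' in column '",
         col, "', line ", bad[1L] + 1L, " of ", path)
  if (anyNA(x))
    stop(what, ": missing value in column '", col, "', line ",
         which(is.na(x))[1L] + 1L, " of ", path)
  x
}

#' Read a probe-value matrix
#'
#' Reads a TSV with columns `probe_id`, `chrom`, `pos` followed by one
#' numeric column per sample, and returns one [probe_profile()] per
#' sample column.  Beta-value matrices are range-checked to \[0, 1\].
#'
#' @param path path to a tab-separated file.
#' @param platform platform of the values (see [probe_profile()]).
#' @return named list of `probe_profile` objects (empty, with a warning,
#'   when the file has no data rows).
#' @export
read_probe_matrix <- function(path, platform) {
  platform <- match.arg(platform, PLATFORMS)
  d <- read_tsv_checked(path, c("probe_id", "chrom", "pos"),
                        "read_probe_matrix")
  sample_cols <- setdiff(names(d), c("probe_id", "chrom", "pos"))
  if (nrow(d) == 0L) {
    warning("read_probe_matrix: no data rows in ", path)
    return(stats::setNames(list(), character()))
  }
  if (length(sample_cols) == 0L)
    stop("read_probe_matrix: no sample columns in ", path)
  d$pos <- check_numeric_col(d, "pos", path, "read_probe_matrix")
  out <- lapply(sample_cols, function(s) {
    value <- check_numeric_col(d, s, path, "read_probe_matrix")
    probe_profile(s, platform,
                  data.frame(probe_id = d$probe_id, chrom = d$chrom,
                             pos = d$pos, value = value,
                             stringsAsFactors = FALSE))
  })
  stats::setNames(out, sample_cols)
}

#' Write a probe-value matrix
#'
#' Counterpart of [read_probe_matrix()].  All profiles must share the same
#' probe set.
#'
#' @param profiles list of [probe_profile()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_matrix <- function(profiles, path) {
  stopifnot(length(profiles) >= 1L)
  base <- profiles[[1L]]$probes[, c("probe_id", "chrom", "pos")]
  for (p in profiles) {
    if (!identical(p$probes$probe_id, base$probe_id))
      stop("write_probe_matrix: profiles have different probe sets")
    base[[p$sample_id]] <- p$probes$value
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read segmented copy-number profiles (SEG-style TSV)
#'
#' Columns: `sample_id`, `chrom`, `start`, `end`, optional `n_probes`,
#' `mean_value`, optional `status`.  Coordinates are 1-based inclusive.
#'
#' @param path path to a tab-separated file.
#' @inheritParams segmented_profile
#' @return named list of [segmented_profile()] objects.
#' @export
read_segments <- function(path, loss_thr = -0.3, gain_thr = 0.3) {
  d <- read_tsv_checked(path, c("sample_id", "chrom", "start", "end",
                                "mean_value"), "read_segments")
  d$start <- check_numeric_col(d, "start", path, "read_segments")
  d$end <- check_numeric_col(d, "end", path, "read_segments")
  d$mean_value <- check_numeric_col(d, "mean_value", path, "read_segments")
  out <- lapply(split(d, d$sample_id), function(s) {
    segmented_profile(s$sample_id[1L],
                      s[, setdiff(names(s), "sample_id"), drop = FALSE],
                      loss_thr = loss_thr, gain_thr = gain_thr)
  })
  out[unique(d$sample_id)]
}

#' Write segmented profiles
#' @param profiles list of [segmented_profile()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    cbind(sample_id = p$sample_id, p$segments)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read variant lists (minimal VCF-like TSV)
#'
#' Columns: `sample_id`, `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path path to a tab-separated file.
#' @return named list of [variant_set()] objects.
#' @export
read_variants <- function(path) {
  d <- read_tsv_checked(path, c("sample_id", "chrom", "pos", "ref", "alt"),
                        "read_variants")
  d$pos <- check_numeric_col(d, "pos", path, "read_variants")
  out <- lapply(split(d, d$sample_id), function(s)
    variant_set(s$sample_id[1L], s[, c("chrom", "pos", "ref", "alt")]))
  out[unique(d$sample_id)]
}

#' Write variant lists
#' @param sets list of [variant_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(v)
    cbind(sample_id = v$sample_id, v$variants)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read fusion lists (BEDPE-style TSV)
#'
#' Columns: `sample_id`, `chrom5`, `pos5`, `gene5`, `chrom3`, `pos3`,
#' `gene3`.
#'
#' @param path path to a tab-separated file.
#' @return named list of [fusion_set()] objects.
#' @export
read_fusions <- function(path) {
  d <- read_tsv_checked(path, c("sample_id", "chrom5", "pos5", "gene5",
                                "chrom3", "pos3", "gene3"), "read_fusions")
  d$pos5 <- check_numeric_col(d, "pos5", path, "read_fusions")
  d$pos3 <- check_numeric_col(d, "pos3", path, "read_fusions")
  out <- lapply(split(d, d$sample_id), function(s)
    fusion_set(s$sample_id[1L],
               s[, c("chrom5", "pos5", "gene5", "chrom3", "pos3",
                     "gene3")]))
  out[unique(d$sample_id)]
}

#' Write fusion lists
#' @param sets list of [fusion_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fusions <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(f)
    cbind(sample_id = f$sample_id, f$fusions)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

CLINICAL_COLS <- c("patient_id", "laterality", "interval_days",
                   "histology_1", "er_1", "her2_1", "subtype_1",
                   "histology_2", "er_2", "her2_2", "subtype_2")

#' Read a clinical table
#'
#' CSV with one row per patient: `patient_id`, `laterality`
#' (`bilateral`/`ipsilateral`), `interval_days` (days between the two
#' diagnoses), and histology / ER / HER2 / molecular subtype for each of
#' the two tumours (`_1`, `_2`), with the token `"ND"` for a feature that
#' was not determined.
#'
#' @param path path to a CSV file.
#' @return a validated data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(CLINICAL_COLS, names(d))
  if (length(missing))
    stop("read_clinical: missing column(s) ",
         paste(missing, collapse = ", "))
  validate_clinical(d)
}

validate_clinical <- function(d) {
  if (!all(d$laterality %in% c("bilateral", "ipsilateral")))
    stop("clinical table: laterality must be 'bilateral' or 'ipsilateral'")
  d$interval_days <- as.integer(d$interval_days)
  if (anyNA(d$interval_days) || any(d$interval_days < 0))
    stop("clinical table: interval_days must be a nonnegative integer")
  for (col in c("er_1", "er_2", "her2_1", "her2_2"))
    if (!all(d[[col]] %in% c("pos", "neg", "ND")))
      stop("clinical table: ", col, " must be pos/neg/ND")
  if (anyDuplicated(d$patient_id))
    stop("clinical table: duplicated patient_id")
  class(d) <- c("clinical_table", "data.frame")
  d
}

#' Write a clinical table
#' @param d a `clinical_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(d, path) {
  utils::write.table(as.data.frame(d)[, CLINICAL_COLS], path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' CSV linking samples to patients: columns `patient_id`, `sample_id`,
#' `tumour_index` (1 or 2).  Every patient must contribute exactly two
#' samples.
#'
#' @param path path to a CSV file.
#' @return data.frame with the three columns.
#' @export
read_manifest <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "sample_id", "tumour_index"),
                     names(d))
  if (length(missing))
    stop("read_manifest: missing column(s) ",
         paste(missing, collapse = ", "))
  validate_manifest(d)
}

validate_manifest <- function(d) {
  d$tumour_index <- as.integer(d$tumour_index)
  if (!all(d$tumour_index %in% 1:2))
    stop("manifest: tumour_index must be 1 or 2")
  if (anyDuplicated(d$sample_id))
    stop("manifest: duplicated sample_id")
  counts <- table(d$patient_id)
  bad <- names(counts)[counts != 2L]
  if (length(bad))
    stop("manifest: patient(s) without exactly 2 samples: ",
         paste(bad, collapse = ", "))
  d
}
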