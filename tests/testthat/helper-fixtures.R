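# In-code fixtures shared across the suite.

# probe profile with values on an evenly spaced single-chromosome grid
make_profile <- function(values, sample_id = "S1",
                         platform = "copy_number", chrom = "1") {
  n <- length(values)
  probe_profile(sample_id, platform,
                data.frame(probe_id = sprintf("p%03d", seq_len(n)),
                           chrom = chrom, pos = seq_len(n) * 1000L,
                           value = values))
}

# discrete profile directly from a state vector
make_discrete <- function(states, sample_id = "S1", scheme = "cn3") {
  n <- length(states)
  discrete_profile(sample_id, scheme,
                   data.frame(probe_id = sprintf("p%03d", seq_len(n)),
                              chrom = "1", pos = seq_len(n) * 1000L,
                              state = states),
                   thresholds = c(-0.3, 0.3))
}

make_segments <- function(df, sample_id = "S1") {
  segmented_profile(sample_id, df)
}

# manifest for n patients with samples <P>_T1 / <P>_T2
make_manifest <- function(n) {
  ids <- sprintf("P%02d", seq_len(n))
  data.frame(patient_id = rep(ids, each = 2L),
             sample_id = as.vector(t(outer(ids, c("_T1", "_T2"),
                                           paste0))),
             tumour_index = rep(1:2, n))
}

# random cn3 discrete profiles for n samples over k probes
random_discrete_cohort <- function(n, k, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  out <- lapply(ids, function(s)
    make_discrete(sample(c(-1L, 0L, 1L), k, replace = TRUE),
                  sample_id = s))
  stats::setNames(out, ids)
}

table1_path <- function() {
  system.file("extdata", "clinical_table1.csv", package = "clonalpair")
}

# brute-force per-probe classifier used as the SI oracle
oracle_counts <- function(sa, sb) {
  n_s <- n_u <- n_o <- n_n <- 0L
  for (i in seq_along(sa)) {
    a <- sa[i]; b <- sb[i]
    if (a == 0L && b == 0L) n_n <- n_n + 1L
    else if (a != 0L && b != 0L && a == b) n_s <- n_s + 1L
    else if (a != 0L && b != 0L) n_o <- n_o + 1L
    else n_u <- n_u + 1L
  }
  c(n_s = n_s, n_u = n_u, n_o = n_o, n_n = n_n)
}
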