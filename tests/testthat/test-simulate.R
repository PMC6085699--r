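test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_patients = 4L, n_probes = 100L, seed = 21L,
                           platforms = c("copy_number",
                                         "methylation_beta"))
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1, co2)
  co3 <- simulate_cohort(simulation_config(n_patients = 4L,
                                           n_probes = 100L, seed = 22L,
                                           platforms = "copy_number"))
  expect_false(identical(co1$profiles$copy_number,
                         co3$profiles$copy_number))
})

test_that("simulation leaves the caller RNG stream untouched", {
  set.seed(1234)
  before <- .Random.seed
  invisible(simulate_cohort(simulation_config(n_patients = 2L,
                                              n_probes = 50L)))
  expect_identical(.Random.seed, before)
})

test_that("contradictory configs are rejected", {
  expect_error(simulation_config(n_founder_events = 300L,
                                 n_drift_events = 0L, n_blocks = 220L),
               "exceed")
  expect_error(simulation_config(clonal_fraction = 1.4), "clonal_fraction")
  expect_error(simulation_config(n_variants = 100L,
                                 variant_pool_size = 50L))
})

test_that("hotspot carriage matches the configured population frequency", {
  co <- simulate_cohort(simulation_config(n_patients = 30L,
                                          n_probes = 440L,
                                          n_drift_events = 0L,
                                          clonal_fraction = 0,
                                          noise_sd = 0.05, seed = 77L))
  disc <- lapply(co$profiles$copy_number, discretize_copy_number)
  fr <- aberration_frequency(disc, exclude_sex = FALSE)
  # a probe deep inside the 1q gain hotspot (second half of chrom 1)
  probe_1q <- which(fr$chrom == "1" & fr$pos > 7.5e7)[1L]
  f_hat <- fr$gain_freq[probe_1q]
  band <- 3 * sqrt(0.3 * 0.7 / 60)
  expect_lt(abs(f_hat - 0.3), band)
  # and an 8p loss hotspot probe
  probe_8p <- which(fr$chrom == "8" & fr$pos < 2.5e7)[1L]
  expect_lt(abs(fr$loss_freq[probe_8p] - 0.3), band)
})

test_that("zero-signal true pairs are exchangeable with artificial pairs", {
  # Kolmogorov-Smirnov on pooled shared-segment counts across replicates
  cfg0 <- function(s)
    simulation_config(n_patients = 4L, clonal_fraction = 0,
                      n_probes = 100L, n_blocks = 1000L,
                      n_founder_events = 0L, n_drift_events = 300L,
                      n_variants = 100L, variant_pool_size = 1000L,
                      seed = s)
  true_counts <- NULL; art_counts <- NULL
  for (s in 1:200) {
    co <- simulate_cohort(cfg0(s))
    counts <- clonalpair:::pairwise_shared_counts(
      lapply(co$segments, clonalpair:::seg_keys))
    tp <- co$pairs$true_pairs; ap <- co$pairs$artificial_pairs
    true_counts <- c(true_counts,
                     counts[cbind(tp$sample_a, tp$sample_b)])
    art_counts <- c(art_counts,
                    counts[cbind(ap$sample_a, ap$sample_b)])
  }
  p <- suppressWarnings(stats::ks.test(true_counts, art_counts))$p.value
  expect_gt(p, 0.01)
})

test_that("identical-twin configuration forces SI = 1", {
  co <- simulate_cohort(sim_config_twin(n_patients = 6L, seed = 9L))
  disc <- lapply(co$profiles$copy_number, discretize_copy_number)
  m <- clonalpair:::state_matrix(disc)
  si <- clonalpair:::pairwise_si_matrix(m)
  tp <- co$pairs$true_pairs
  expect_equal(unname(si[cbind(tp$sample_a, tp$sample_b)]),
               rep(1, nrow(tp)))
})

test_that("clonal pairs share the configured number of fusions", {
  co <- simulate_cohort(sim_config_strong(n_patients = 10L, seed = 15L))
  tp <- co$pairs$true_pairs
  truth <- co$truth
  for (i in seq_len(nrow(tp))) {
    ov <- fusion_overlap(co$fusions[[tp$sample_a[i]]],
                         co$fusions[[tp$sample_b[i]]])$count
    expected <- if (truth$is_clonal[truth$patient_id ==
                                    tp$patient_id[i]]) 5L else 0L
    expect_equal(ov, expected)
  }
})

test_that("mean clonal SI is monotone in founder events and noise", {
  mean_si <- function(founders, noise) {
    vals <- vapply(1:4, function(s) {
      co <- simulate_cohort(simulation_config(
        n_patients = 10L, clonal_fraction = 0.5, n_probes = 300L,
        n_founder_events = founders, noise_sd = noise, seed = 100L + s))
      disc <- lapply(co$profiles$copy_number, discretize_copy_number)
      si <- clonalpair:::pairwise_si_matrix(
        clonalpair:::state_matrix(disc))
      tp <- co$pairs$true_pairs
      clonal <- co$truth$is_clonal[match(tp$patient_id,
                                         co$truth$patient_id)]
      mean(si[cbind(tp$sample_a, tp$sample_b)][clonal], na.rm = TRUE)
    }, 0)
    mean(vals)
  }
  by_founders <- vapply(c(2L, 8L, 20L), mean_si, 0, noise = 0.1)
  expect_true(all(diff(by_founders) >= 0))
  # noise grid kept at or below the discretization threshold: past it,
  # concordant random miscalls dominate and the SI rises again towards
  # its chance floor
  by_noise <- vapply(c(0.05, 0.15, 0.3), function(ns)
    mean_si(8L, ns), 0)
  expect_true(all(diff(by_noise) <= 0))
})

test_that("written cohorts round-trip through the package readers", {
  co <- simulate_cohort(simulation_config(n_patients = 3L,
                                          n_probes = 60L, seed = 42L,
                                          platforms = c("copy_number",
                                                        "methylation_beta")))
  dir <- file.path(tempdir(), "cohort42")
  write_cohort(co, dir)
  cn <- read_probe_matrix(file.path(dir, "copy_number.tsv"),
                          "copy_number")
  expect_equal(names(cn), names(co$profiles$copy_number))
  expect_equal(cn[[1L]]$probes$value,
               co$profiles$copy_number[[1L]]$probes$value,
               tolerance = 1e-6)
  segs <- read_segments(file.path(dir, "segments.tsv"))
  expect_equal(length(segs), 6L)
  expect_equal(segs[[1L]]$segments$status,
               co$segments[[names(segs)[1L]]]$segments$status)
  vars <- read_variants(file.path(dir, "variants.tsv"))
  expect_equal(nrow(vars[[1L]]$variants), 1000L)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man, co$manifest)
  cl <- read_clinical(file.path(dir, "clinical.csv"))
  expect_equal(cl$patient_id, co$clinical$patient_id)
})
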