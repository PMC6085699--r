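# Seeded generator of paired-tumour multi-platform cohorts with
# ground-truth clonality.  Clonal pairs share founder aberrations with
# identical breakpoints (plus private subclonal drift); independent
# pairs share aberrations only through population-recurrent hotspots or
# chance coincidence on the aberration grid.

# autosomes in character sort order so that generated tables are
# already in the canonical order the constructors use
SIM_CHROMS <- sort(as.character(1:22))
SIM_CHROM_LEN <- 1e8L  # simplified constant autosome length, bp

#' Simulation configuration
#'
#' Parameters of the synthetic paired-tumour cohort.  The genome is 22
#' autosomes of 10^8 bp, partitioned into `n_blocks` equal candidate
#' aberration blocks; every copy-number event (hotspot, founder, drift)
#' occupies whole blocks, so breakpoints are exactly shared whenever two
#' tumours carry the same event and never otherwise aligned.
#'
#' @param n_patients number of patients (two tumours each).
#' @param clonal_fraction fraction of patients whose pair is clonal.
#' @param n_probes probes genome-wide (split evenly over chromosomes, or
#'   per `chromosome_layout`).
#' @param chromosome_layout optional named integer vector of probes per
#'   chromosome.
#' @param n_blocks candidate aberration blocks genome-wide.
#' @param hotspot_spec data.frame (`chrom`, `start`, `end`, `direction`,
#'   `freq`) of population-recurrent regions, each carried independently
#'   by any tumour with probability `freq`; `NULL` uses ten recurrent
#'   breast-cancer arms (gains on 1q, 8q, 16p, 17q, 20q; losses on 1p,
#'   8p, 11q, 13q, 16q) at frequency 0.3.
#' @param n_founder_events clonal founder copy-number events per patient
#'   (identical breakpoints in both tumours of a clonal pair).
#' @param n_drift_events private subclonal drift events per tumour.
#' @param noise_sd Gaussian probe-level noise SD on log2-ratio
#'   platforms.
#' @param cn_gain,cn_loss segment mean log2 ratios of gains and losses.
#' @param expr_gain expression log2-ratio magnitude induced by an
#'   aberrant block (dosage effect).
#' @param beta_mu_sd SD of the per-probe population mean on the logit
#'   beta scale.
#' @param beta_pair_sd SD of the tumour-level methylation effect; drawn
#'   once per patient for clonal pairs (correlating the two tumours) and
#'   per tumour otherwise.
#' @param beta_noise_scale per-probe logit-scale methylation noise SD.
#' @param n_variants variants per tumour, drawn from a pool of
#'   `variant_pool_size` recurrent polymorphic sites (chance sharing
#'   between unrelated tumours scales as
#'   `n_variants^2 / variant_pool_size`).
#' @param variant_pool_size size of the polymorphic-site pool.
#' @param variant_share_rate_clonal fraction of a clonal pair's variants
#'   that are founder variants present in both tumours.
#' @param n_fusions fusion transcripts per tumour.
#' @param fusion_share_count_clonal fusions with identical breakpoints
#'   in both tumours of a clonal pair.
#' @param platforms probe platforms to emit (subset of `copy_number`,
#'   `expression`, `methylation_beta`, `methylation_intensity`,
#'   `snp_lrr`).
#' @param p_discordant_clonal,p_discordant_independent per-feature
#'   probability that a clinical feature differs between the two tumours
#'   (clinical concordance is only loosely coupled to molecular
#'   clonality).
#' @param seed integer RNG seed; output is bit-identical for a fixed
#'   config.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 20L,
                              clonal_fraction = 0.46,
                              n_probes = 500L,
                              chromosome_layout = NULL,
                              n_blocks = 220L,
                              hotspot_spec = NULL,
                              n_founder_events = 8L,
                              n_drift_events = 3L,
                              noise_sd = 0.15,
                              cn_gain = 0.6,
                              cn_loss = -0.6,
                              expr_gain = 0.8,
                              beta_mu_sd = 1.5,
                              beta_pair_sd = 1.0,
                              beta_noise_scale = 0.5,
                              n_variants = 1000L,
                              variant_pool_size = 20000L,
                              variant_share_rate_clonal = 0.5,
                              n_fusions = 20L,
                              fusion_share_count_clonal = 5L,
                              platforms = "copy_number",
                              p_discordant_clonal = 0.05,
                              p_discordant_independent = 0.3,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              clonal_fraction = clonal_fraction,
              n_probes = as.integer(n_probes),
              chromosome_layout = chromosome_layout,
              n_blocks = as.integer(n_blocks),
              hotspot_spec = hotspot_spec,
              n_founder_events = as.integer(n_founder_events),
              n_drift_events = as.integer(n_drift_events),
              noise_sd = noise_sd, cn_gain = cn_gain, cn_loss = cn_loss,
              expr_gain = expr_gain,
              beta_mu_sd = beta_mu_sd, beta_pair_sd = beta_pair_sd,
              beta_noise_scale = beta_noise_scale,
              n_variants = as.integer(n_variants),
              variant_pool_size = as.integer(variant_pool_size),
              variant_share_rate_clonal = variant_share_rate_clonal,
              n_fusions = as.integer(n_fusions),
              fusion_share_count_clonal = as.integer(fusion_share_count_clonal),
              platforms = match.arg(platforms,
                                    setdiff(PLATFORMS, "snp_baf"),
                                    several.ok = TRUE),
              p_discordant_clonal = p_discordant_clonal,
              p_discordant_independent = p_discordant_independent,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_patients >= 2L, n_probes >= 1L, n_blocks >= 1L,
              clonal_fraction >= 0, clonal_fraction <= 1,
              variant_share_rate_clonal >= 0,
              variant_share_rate_clonal <= 1,
              noise_sd >= 0, n_founder_events >= 0, n_drift_events >= 0,
              n_variants >= 0, n_fusions >= 0,
              fusion_share_count_clonal <= n_fusions,
              n_variants <= variant_pool_size)
  })
  if (cfg$n_founder_events + cfg$n_drift_events > cfg$n_blocks)
    stop("simulation_config: founder plus drift events exceed the ",
         "number of aberration blocks")
  if (!is.null(hotspot_spec))
    stopifnot(all(c("chrom", "start", "end", "direction", "freq") %in%
                  names(hotspot_spec)),
              all(hotspot_spec$direction %in% c("gain", "loss")),
              all(hotspot_spec$freq >= 0 & hotspot_spec$freq <= 1))
  structure(cfg, class = "simulation_config")
}

#' Zero-signal calibration preset
#'
#' All patients independent, with a dense aberration grid and
#' germline-scale variant lists so that the chance-shared segment and
#' mutation counts of artificial pairs have wide, nearly continuous
#' support.  Calibration of a strict percentile threshold is only
#' informative in this regime: with narrow-support counts the attainable
#' rejection level is quantised by the null probability mass function
#' and the tests are conservative by construction.
#'
#' @param n_patients,n_probes,seed see [simulation_config()].
#' @return a `simulation_config`.
#' @export
sim_config_null <- function(n_patients = 20L, n_probes = 500L, seed = 1L) {
  simulation_config(n_patients = n_patients, clonal_fraction = 0,
                    n_probes = n_probes,
                    n_blocks = 4400L, n_founder_events = 0L,
                    n_drift_events = 2000L,
                    n_variants = 3000L, variant_pool_size = 15000L,
                    n_fusions = 20L, fusion_share_count_clonal = 0L,
                    platforms = "copy_number", seed = seed)
}

#' Strong-signal preset
#'
#' Half the patients clonal, eight founder events per clonal pair and
#' low probe noise (SD 0.05): the regime in which the similarity index
#' should recover ground truth nearly perfectly.
#'
#' @param n_patients,seed see [simulation_config()].
#' @return a `simulation_config`.
#' @export
sim_config_strong <- function(n_patients = 20L, seed = 1L) {
  simulation_config(n_patients = n_patients, clonal_fraction = 0.5,
                    n_founder_events = 8L, noise_sd = 0.05, seed = seed)
}

#' Identical-twin preset
#'
#' Degenerate configuration: every pair clonal, no subclonal drift and
#' no measurement noise, and all variants/fusions shared, so both
#' tumours of each patient have identical profiles (SI = 1).
#'
#' @param n_patients,seed see [simulation_config()].
#' @return a `simulation_config`.
#' @export
sim_config_twin <- function(n_patients = 20L, seed = 1L) {
  simulation_config(n_patients = n_patients, clonal_fraction = 1,
                    n_founder_events = 8L, n_drift_events = 0L,
                    noise_sd = 0, variant_share_rate_clonal = 1,
                    fusion_share_count_clonal = 20L, n_fusions = 20L,
                    seed = seed)
}

split_over_chroms <- function(n, chroms = SIM_CHROMS) {
  k <- length(chroms)
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0L) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  stats::setNames(as.integer(out), chroms)
}

default_hotspots <- function() {
  arm_region <- function(chrom, arm) {
    if (arm == "p") c(1L, SIM_CHROM_LEN %/% 2L)
    else c(SIM_CHROM_LEN %/% 2L + 1L, SIM_CHROM_LEN)
  }
  spec <- rbind(
    data.frame(chrom = c("1", "8", "16", "17", "20"),
               arm = c("q", "q", "p", "q", "q"), direction = "gain"),
    data.frame(chrom = c("1", "8", "11", "13", "16"),
               arm = c("p", "p", "q", "q", "q"), direction = "loss"))
  reg <- t(mapply(arm_region, spec$chrom, spec$arm))
  data.frame(chrom = spec$chrom, start = reg[, 1L], end = reg[, 2L],
             direction = spec$direction, freq = 0.3,
             stringsAsFactors = FALSE)
}

# Build the block grid: data.frame(block, chrom, start, end).
build_blocks <- function(n_blocks) {
  per <- split_over_chroms(n_blocks)
  rows <- lapply(SIM_CHROMS, function(ch) {
    k <- per[[ch]]
    if (k == 0L) return(NULL)
    bounds <- round(seq(0L, SIM_CHROM_LEN, length.out = k + 1L))
    data.frame(chrom = ch, start = bounds[-(k + 1L)] + 1L,
               end = bounds[-1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$block <- seq_len(nrow(out))
  out
}

# Probe positions: evenly spaced within each chromosome.
build_probes <- function(n_probes, layout = NULL) {
  per <- if (is.null(layout)) split_over_chroms(n_probes)
         else stats::setNames(as.integer(layout), names(layout))
  rows <- lapply(names(per), function(ch) {
    k <- per[[ch]]
    if (k == 0L) return(NULL)
    pos <- round(seq_len(k) * (SIM_CHROM_LEN / (k + 1L)))
    data.frame(chrom = ch, pos = as.integer(pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$probe_id <- sprintf("probe_%05d", seq_len(nrow(out)))
  out
}

# one hotspot event = the set of grid blocks overlapping its region
hotspot_blocks <- function(spec, blocks) {
  lapply(seq_len(nrow(spec)), function(i) {
    b <- blocks$block[blocks$chrom == normalize_chrom(spec$chrom[i]) &
                      blocks$end >= spec$start[i] &
                      blocks$start <= spec$end[i]]
    list(blocks = b,
         state = if (spec$direction[i] == "gain") 1L else -1L,
         freq = spec$freq[i])
  })
}

#' Simulate a paired-tumour cohort
#'
#' Generates, for each patient, two tumours over every configured
#' platform, plus segmented copy-number profiles, variant and fusion
#' sets, a clinical record, the sample manifest and the ground-truth
#' clonality labels.  Clonal pairs carry their patient's founder events
#' (identical block breakpoints, shared founder variants and fusions)
#' in both tumours; every tumour additionally carries independent
#' hotspot draws and private drift events.  Output is bit-identical for
#' a fixed config; the caller's RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort` with elements `config`,
#'   `manifest`, `clinical`, `pairs`, `profiles` (per platform, named
#'   lists of [probe_profile()]), `segments`, `variants`, `fusions` and
#'   `truth` (data.frame `patient_id`, `is_clonal` plus per-patient
#'   founder manifests in attributes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  cfg <- config
  blocks <- build_blocks(cfg$n_blocks)
  probes <- build_probes(cfg$n_probes, cfg$chromosome_layout)
  spec <- if (is.null(cfg$hotspot_spec)) default_hotspots()
          else cfg$hotspot_spec
  hots <- hotspot_blocks(spec, blocks)
  hot_freqs <- vapply(hots, `[[`, 0, "freq")
  hot_block_ids <- unique(unlist(lapply(hots, `[[`, "blocks")))
  # probe -> block lookup
  probe_block <- integer(nrow(probes))
  for (ch in unique(probes$chrom)) {
    bi <- blocks$chrom == ch
    probe_block[probes$chrom == ch] <-
      blocks$block[bi][findInterval(probes$pos[probes$chrom == ch],
                                    blocks$start[bi])]
  }

  n <- cfg$n_patients
  patient_ids <- sprintf("P%03d", seq_len(n))
  n_clonal <- round(cfg$clonal_fraction * n)
  is_clonal <- sample(c(rep(TRUE, n_clonal), rep(FALSE, n - n_clonal)))
  sample_ids <- as.vector(t(outer(patient_ids, c("_T1", "_T2"), paste0)))
  manifest <- data.frame(patient_id = rep(patient_ids, each = 2L),
                         sample_id = sample_ids,
                         tumour_index = rep(1:2, n),
                         stringsAsFactors = FALSE)

  # variant pool: unique sites with fixed ref/alt
  pool_per <- split_over_chroms(cfg$variant_pool_size)
  pool_chrom <- rep(names(pool_per), pool_per)
  pool_pos <- unlist(lapply(pool_per, function(k)
    if (k > 0L) sort(sample.int(SIM_CHROM_LEN, k)) else integer()),
    use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, cfg$variant_pool_size, replace = TRUE)
  alt_i <- 1L + (ref_i - 1L + sample.int(3L, cfg$variant_pool_size,
                                         replace = TRUE)) %% 4L
  pool <- data.frame(chrom = pool_chrom, pos = pool_pos,
                     ref = bases[ref_i], alt = bases[alt_i],
                     stringsAsFactors = FALSE)

  beta_mu <- rnorm(nrow(probes), 0, cfg$beta_mu_sd)

  founder_of <- vector("list", n)
  names(founder_of) <- patient_ids
  seg_profiles <- list(); var_sets <- list(); fus_sets <- list()
  platf_values <- lapply(cfg$platforms, function(p) list())
  names(platf_values) <- cfg$platforms
  clinical_rows <- list()

  non_hot <- setdiff(blocks$block, hot_block_ids)
  histologies <- c("Invasive carcinoma NST", "Invasive lobular carcinoma",
                   "Invasive carcinoma NOS")
  subtypes <- c("Luminal A", "Luminal B", "Basal-like", "HER2/ER-")

  gene_name <- function(chrom, pos)
    sprintf("GENE%s_%d", chrom, pos %/% 100000L)

  for (pi in seq_len(n)) {
    pid <- patient_ids[pi]
    clonal <- is_clonal[pi]
    founder <- if (clonal && cfg$n_founder_events > 0L) {
      b <- sample(non_hot, cfg$n_founder_events)
      data.frame(block = b,
                 state = sample(c(-1L, 1L), length(b), replace = TRUE))
    } else data.frame(block = integer(), state = integer())
    founder_of[[pid]] <- founder

    n_fv <- if (clonal)
      round(cfg$variant_share_rate_clonal * cfg$n_variants) else 0L
    founder_var <- if (n_fv > 0L)
      sample.int(cfg$variant_pool_size, n_fv) else integer()

    n_sf <- if (clonal) cfg$fusion_share_count_clonal else 0L
    founder_fus <- if (n_sf > 0L) data.frame(
      chrom5 = sample(SIM_CHROMS, n_sf, replace = TRUE),
      pos5 = sample.int(SIM_CHROM_LEN, n_sf),
      chrom3 = sample(SIM_CHROMS, n_sf, replace = TRUE),
      pos3 = sample.int(SIM_CHROM_LEN, n_sf),
      stringsAsFactors = FALSE) else NULL

    beta_pair_eff <- rnorm(1, 0, cfg$beta_pair_sd)
    # a clonal pair inherits its progenitor's hotspot events, so those
    # draws are made once per patient; independent tumours draw their own
    patient_hot <- runif(length(hots)) < hot_freqs

    for (ti in 1:2) {
      sid <- manifest$sample_id[(pi - 1L) * 2L + ti]
      state <- integer(nrow(blocks))
      hot_on <- if (clonal) patient_hot
                else runif(length(hots)) < hot_freqs
      for (h in which(hot_on))
        state[hots[[h]]$blocks] <- hots[[h]]$state
      if (nrow(founder)) state[founder$block] <- founder$state
      if (cfg$n_drift_events > 0L) {
        drift_pool <- setdiff(blocks$block, founder$block)
        db <- sample(drift_pool, cfg$n_drift_events)
        state[db] <- sample(c(-1L, 1L), length(db), replace = TRUE)
      }

      block_mean <- ifelse(state == 1L, cfg$cn_gain,
                    ifelse(state == -1L, cfg$cn_loss, 0))
      seg_profiles[[sid]] <- blocks_to_segments(sid, blocks, state,
                                                cfg$cn_gain, cfg$cn_loss)

      base_signal <- block_mean[match(probe_block, blocks$block)]
      for (pl in cfg$platforms) {
        value <- switch(pl,
          copy_number = ,
          methylation_intensity = ,
          snp_lrr = base_signal + rnorm(nrow(probes), 0, cfg$noise_sd),
          expression = sign(base_signal) * cfg$expr_gain +
            rnorm(nrow(probes), 0, cfg$noise_sd),
          methylation_beta = {
            eff <- if (clonal) beta_pair_eff
                   else rnorm(1, 0, cfg$beta_pair_sd)
            plogis(beta_mu + eff +
                   rnorm(nrow(probes), 0, cfg$beta_noise_scale))
          })
        platf_values[[pl]][[sid]] <- probe_profile(
          sid, pl, data.frame(probe_id = probes$probe_id,
                              chrom = probes$chrom, pos = probes$pos,
                              value = value, stringsAsFactors = FALSE),
          check = FALSE)
      }

      n_priv <- cfg$n_variants - n_fv
      priv_pool <- if (n_fv > 0L)
        setdiff(seq_len(cfg$variant_pool_size), founder_var)
        else seq_len(cfg$variant_pool_size)
      idx <- sort(c(founder_var,
                    if (n_priv > 0L) sample(priv_pool, n_priv)
                    else integer()))
      vs <- pool[idx, , drop = FALSE]
      rownames(vs) <- NULL
      var_sets[[sid]] <- variant_set(sid, vs, check = FALSE)

      n_pf <- cfg$n_fusions - n_sf
      fus <- founder_fus
      if (n_pf > 0L) {
        priv <- data.frame(
          chrom5 = sample(SIM_CHROMS, n_pf, replace = TRUE),
          pos5 = sample.int(SIM_CHROM_LEN, n_pf),
          chrom3 = sample(SIM_CHROMS, n_pf, replace = TRUE),
          pos3 = sample.int(SIM_CHROM_LEN, n_pf),
          stringsAsFactors = FALSE)
        fus <- rbind(fus, priv)
      }
      if (is.null(fus))
        fus <- data.frame(chrom5 = character(), pos5 = integer(),
                          chrom3 = character(), pos3 = integer())
      fus$gene5 <- gene_name(fus$chrom5, fus$pos5)
      fus$gene3 <- gene_name(fus$chrom3, fus$pos3)
      fus_sets[[sid]] <- fusion_set(sid, fus)
    }

    clinical_rows[[pid]] <- simulate_clinical_row(pid, clonal, cfg,
                                                  histologies, subtypes)
  }

  clinical <- validate_clinical(do.call(rbind, clinical_rows))
  truth <- data.frame(patient_id = patient_ids, is_clonal = is_clonal,
                      stringsAsFactors = FALSE, row.names = NULL)
  attr(truth, "founder_blocks") <- founder_of
  structure(list(config = cfg,
                 manifest = manifest,
                 clinical = clinical,
                 pairs = enumerate_pairs(manifest, clinical),
                 profiles = platf_values,
                 segments = seg_profiles,
                 variants = var_sets,
                 fusions = fus_sets,
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$config$n_patients, "patients,",
      sum(x$truth$is_clonal), "clonal;", "platforms:",
      paste(x$config$platforms, collapse = ", "), "\n")
  invisible(x)
}

# aberrant blocks become their own segments; runs of normal blocks are
# merged into one neutral segment
blocks_to_segments <- function(sid, blocks, state, cn_gain, cn_loss) {
  n <- nrow(blocks)
  prev_chrom <- c("", blocks$chrom[-n])
  prev_state <- c(NA_integer_, state[-n])
  new_seg <- blocks$chrom != prev_chrom | state != 0L |
    prev_state != 0L
  new_seg[1L] <- TRUE
  first <- which(new_seg)
  last <- c(first[-1L] - 1L, n)
  st <- state[first]
  segmented_profile(sid, data.frame(
    chrom = blocks$chrom[first],
    start = blocks$start[first],
    end = blocks$end[last],
    mean_value = c(cn_loss, 0, cn_gain)[st + 2L],
    status = c("loss", "normal", "gain")[st + 2L],
    stringsAsFactors = FALSE), check = FALSE)
}

simulate_clinical_row <- function(pid, clonal, cfg, histologies,
                                  subtypes) {
  p_disc <- if (clonal) cfg$p_discordant_clonal
            else cfg$p_discordant_independent
  flip <- function(value, alternatives) {
    if (runif(1) < p_disc)
      sample(setdiff(alternatives, value), 1L) else value
  }
  maybe_nd <- function(value, p_nd) if (runif(1) < p_nd) "ND" else value
  hist1 <- sample(histologies, 1L, prob = c(0.6, 0.25, 0.15))
  er1 <- sample(c("pos", "neg"), 1L, prob = c(0.7, 0.3))
  her2_1 <- sample(c("pos", "neg"), 1L, prob = c(0.2, 0.8))
  sub1 <- sample(subtypes, 1L)
  hist2 <- flip(hist1, histologies)
  er2 <- flip(er1, c("pos", "neg"))
  her2_2 <- flip(her2_1, c("pos", "neg"))
  sub2 <- flip(sub1, subtypes)
  synchronous <- runif(1) < 0.5
  data.frame(patient_id = pid,
             laterality = sample(c("bilateral", "ipsilateral"), 1L),
             interval_days = if (synchronous) sample(0:183, 1L)
                             else sample(184:2500, 1L),
             histology_1 = maybe_nd(hist1, 0.3),
             er_1 = er1, her2_1 = her2_1,
             subtype_1 = maybe_nd(sub1, 0.6),
             histology_2 = maybe_nd(hist2, 0.3),
             er_2 = er2, her2_2 = her2_2,
             subtype_2 = maybe_nd(sub2, 0.6),
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Emits every interchange format of the package: one probe matrix TSV
#' per platform, SEG-style segments, variant and fusion TSVs, the
#' clinical CSV, the sample manifest and a ground-truth table.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pl in names(cohort$profiles))
    write_probe_matrix(cohort$profiles[[pl]],
                       file.path(dir, paste0(pl, ".tsv")))
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  write_variants(cohort$variants, file.path(dir, "variants.tsv"))
  write_fusions(cohort$fusions, file.path(dir, "fusions.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  utils::write.table(cohort$manifest, file.path(dir, "manifest.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score a clonality test against ground truth
#'
#' Runs one clonality test end-to-end on a synthetic cohort and scores
#' its per-patient calls against the generator's ground-truth labels.
#'
#' @param cohort a `synthetic_cohort`.
#' @param method one of `"si"`, `"distance"`, `"cluster"`,
#'   `"segments"`, `"mutations"`, `"fusions"`.
#' @param alpha significance cut-off for the SI empirical p-value.
#' @param platform probe platform used by the probe-level methods.
#' @return list with `accuracy`, `sensitivity`, `specificity` (computed
#'   over evaluable pairs), `n_not_evaluable` and the per-pair `calls`
#'   data.frame (with an `is_clonal` truth column).
#' @export
recover_labels <- function(cohort,
                           method = c("si", "distance", "cluster",
                                      "segments", "mutations", "fusions"),
                           alpha = 0.05, platform = "copy_number") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  method <- match.arg(method)
  pairs <- cohort$pairs
  res <- switch(method,
    si = si_test(lapply(cohort$profiles[[platform]],
                        discretize_copy_number),
                 pairs, statistic = "si", alpha = alpha),
    distance = cohort_distance_test(cohort$profiles[[platform]], pairs),
    cluster = cluster_cherry_test(cohort$profiles[[platform]], pairs),
    segments = cohort_segment_test(cohort$segments, pairs),
    mutations = cohort_mutation_test(cohort$variants, pairs),
    fusions = cohort_fusion_test(cohort$fusions, pairs))
  res$is_clonal <- cohort$truth$is_clonal[
    match(res$patient_id, cohort$truth$patient_id)]
  eval_ok <- res$call != "not_evaluable"
  truth_call <- ifelse(res$is_clonal, "clonal", "independent")
  acc <- mean(res$call[eval_ok] == truth_call[eval_ok])
  sens <- if (any(res$is_clonal & eval_ok))
    mean(res$call[res$is_clonal & eval_ok] == "clonal") else NA_real_
  spec <- if (any(!res$is_clonal & eval_ok))
    mean(res$call[!res$is_clonal & eval_ok] == "independent") else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       n_not_evaluable = sum(!eval_ok), calls = res)
}
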