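test_that("discretization thresholds are strict as printed", {
  p <- make_profile(c(-0.31, -0.3, 0, 0.3, 0.31))
  d <- discretize_copy_number(p)
  expect_equal(d$probes$state, c(-1L, 0L, 0L, 0L, 1L))

  e <- make_profile(c(-0.59, -0.58, 0, 0.58, 0.59, log2(1.5)),
                    platform = "expression")
  de <- discretize_expression(e)
  expect_equal(de$probes$state, c(-1L, 0L, 0L, 0L, 1L, 1L))

  b <- make_profile(c(0, 0.19, 0.2, 0.5, 0.8, 0.81, 1),
                    platform = "methylation_beta")
  db <- discretize_methylation(b)
  expect_equal(db$probes$state, c("U", "U", "H", "H", "H", "M", "M"))
})

test_that("discretization enforces platform preconditions", {
  expect_error(discretize_copy_number(
    make_profile(0.5, platform = "expression")), "platform")
  expect_error(discretize_expression(make_profile(0.5)), "platform")
  expect_error(discretize_methylation(make_profile(0.5)), "platform")
})

test_that("count_states matches the hand-enumerated example", {
  a <- make_discrete(c(1L, 0L, -1L, 1L, 0L), "A")
  b <- make_discrete(c(1L, 1L, 1L, 0L, 0L), "B")
  cs <- count_states(a, b)
  expect_equal(cs$n_shared, 1L)
  expect_equal(cs$n_unique, 2L)
  expect_equal(cs$n_opposite, 1L)
  expect_equal(cs$n_neutral, 1L)
  expect_equal(similarity_index(cs), 0.25)
})

test_that("SI handles identical, all-neutral and mismatched inputs", {
  a <- make_discrete(c(1L, -1L, 1L), "A")
  expect_equal(similarity_index(count_states(a, a)), 1)
  z <- make_discrete(c(0L, 0L, 0L), "Z")
  cs <- count_states(z, z)
  expect_equal(cs$n_neutral, 3L)
  expect_true(is.na(similarity_index(cs)))
  m <- make_discrete(c("M", "H", "U"), "M", scheme = "meth3")
  expect_error(count_states(a, m), "scheme mismatch")
  expect_error(count_states(m, m), "similarity_index_met")
})

test_that("count_states agrees with the brute-force classifier", {
  set.seed(42)
  for (rep in 1:200) {
    k <- sample(3:30, 1L)
    sa <- sample(c(-1L, 0L, 1L), k, replace = TRUE)
    sb <- sample(c(-1L, 0L, 1L), k, replace = TRUE)
    cs <- count_states(make_discrete(sa, "A"), make_discrete(sb, "B"))
    oc <- oracle_counts(sa, sb)
    expect_identical(c(cs$n_shared, cs$n_unique, cs$n_opposite,
                       cs$n_neutral),
                     unname(as.integer(oc)))
  }
})

test_that("SI and SI_met are symmetric and bounded", {
  set.seed(7)
  for (rep in 1:50) {
    a <- make_discrete(sample(c(-1L, 0L, 1L), 20, TRUE), "A")
    b <- make_discrete(sample(c(-1L, 0L, 1L), 20, TRUE), "B")
    s_ab <- similarity_index(count_states(a, b))
    s_ba <- similarity_index(count_states(b, a))
    expect_equal(s_ab, s_ba)
    if (!is.na(s_ab)) expect_true(s_ab >= 0 && s_ab <= 1)
    ma <- make_discrete(sample(c("U", "H", "M"), 20, TRUE), "A", "meth3")
    mb <- make_discrete(sample(c("U", "H", "M"), 20, TRUE), "B", "meth3")
    expect_equal(similarity_index_met(ma, mb),
                 similarity_index_met(mb, ma))
  }
})

test_that("SI_met counts all matching states including hemi-methylated", {
  a <- make_discrete(c("M", "H", "U", "M"), "A", scheme = "meth3")
  b <- make_discrete(c("M", "U", "U", "H"), "B", scheme = "meth3")
  expect_equal(similarity_index_met(a, b), 0.5)
  expect_equal(similarity_index_met(a, a), 1)
  d <- make_discrete(c("U", "M", "H", "U"), "D", scheme = "meth3")
  expect_equal(similarity_index_met(a, d), 0)
})

test_that("matrix SI computation equals the per-pair scalar path", {
  set.seed(11)
  cohort <- random_discrete_cohort(6L, 40L)
  m <- clonalpair:::state_matrix(cohort)
  si <- clonalpair:::pairwise_si_matrix(m)
  for (i in 1:5) for (j in (i + 1):6) {
    s <- similarity_index(count_states(cohort[[i]], cohort[[j]]))
    expect_equal(si[i, j], s)
  }
  meth <- lapply(1:5, function(i)
    make_discrete(sample(c("U", "H", "M"), 40, TRUE),
                  sprintf("S%02d", i), "meth3"))
  names(meth) <- sprintf("S%02d", 1:5)
  sm <- clonalpair:::pairwise_si_met_matrix(
    clonalpair:::state_matrix(meth))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(sm[i, j], similarity_index_met(meth[[i]], meth[[j]]))
})

test_that("P_SI reconstruction is exact arithmetic", {
  expect_equal(p_si(0.580, 0.194), 100 * (0.580 - 0.194) / 0.580,
               tolerance = 1e-12)
  expect_equal(round(p_si(0.580, 0.194), 1), 66.6)
  expect_equal(p_si(0.15, 0.194), 0)   # floored at the null mean
  expect_equal(p_si(0.194, 0.194), 0)
  expect_true(is.na(p_si(NA_real_, 0.2)))
})

test_that("si_permutation summarises the artificial-pair null", {
  set.seed(3)
  cohort <- random_discrete_cohort(8L, 60L,
                                   ids = make_manifest(4L)$sample_id)
  pairs <- enumerate_pairs(make_manifest(4L))
  sp <- si_permutation(pairs$true_pairs[1L, ], cohort,
                       pairs$artificial_pairs)
  expect_length(sp$null_si, nrow(pairs$artificial_pairs))
  expect_equal(sp$mean_null, mean(sp$null_si))
  expect_equal(sp$p_si, p_si(sp$si_obs, sp$mean_null))
  expect_equal(sp$p_empirical,
               (1 + sum(sp$null_si >= sp$si_obs)) /
                 (1 + length(sp$null_si)))
  # null values all equal to the observed SI -> maximal p
  same <- lapply(cohort, function(x) cohort[[1L]])
  for (s in names(same)) same[[s]]$sample_id <- s
  names(same) <- names(cohort)
  sp1 <- si_permutation(pairs$true_pairs[1L, ], same,
                        pairs$artificial_pairs)
  expect_equal(sp1$p_empirical, 1)
})

test_that("empirical SI p-values are calibrated on zero-signal cohorts", {
  # true pairs are exchangeable with artificial pairs under the null,
  # so rejection at alpha = 0.05 should occur for ~5% of true pairs
  n_cohorts <- 120L
  rej <- vapply(seq_len(n_cohorts), function(s) {
    co <- simulate_cohort(sim_config_null(n_patients = 10L,
                                          n_probes = 300L, seed = s))
    r <- recover_labels(co, "si")
    mean(r$calls$call == "clonal")
  }, 0)
  n_dec <- n_cohorts * 10L
  band <- 3 * sqrt(0.05 * 0.95 / n_dec)
  expect_lt(abs(mean(rej) - 0.05), band)
})

test_that("beta variability is the inner-quantile span", {
  expect_equal(beta_variability(make_profile(rep(0.5, 25),
                                             platform = "methylation_beta")),
               0)
  g <- make_profile(seq(0, 1, length.out = 101),
                    platform = "methylation_beta")
  expect_equal(beta_variability(g), 0.9, tolerance = 1e-9)
  # a single outlier among constants barely moves the inner quantiles
  o <- make_profile(c(rep(0.4, 40), 0.99), platform = "methylation_beta")
  expect_lt(beta_variability(o), 0.06)
  expect_error(beta_variability(make_profile(rep(0.2, 5),
                                             platform = "methylation_beta")),
               "at least 20")
})

test_that("aberration frequencies count gains and losses per probe", {
  cohort <- lapply(1:10, function(i)
    make_discrete(c(1L, if (i == 1L) -1L else 0L, 0L),
                  sprintf("S%02d", i)))
  names(cohort) <- sprintf("S%02d", 1:10)
  fr <- aberration_frequency(cohort)
  expect_equal(fr$gain_freq[1L], 1)
  expect_true(fr$recurrent[1L])
  expect_equal(fr$loss_freq[2L], 0.1)
  expect_false(fr$recurrent[2L])
})

test_that("sex-chromosome probes are excluded from frequency plots by default", {
  mk <- function(s) discrete_profile(s, "cn3",
    data.frame(probe_id = c("p1", "p2"), chrom = c("1", "X"),
               pos = c(1L, 1L), state = c(1L, 1L)), c(-0.3, 0.3))
  cohort <- list(A = mk("A"), B = mk("B"))
  expect_equal(nrow(aberration_frequency(cohort)), 1L)
  expect_equal(nrow(aberration_frequency(cohort, exclude_sex = FALSE)),
               2L)
})
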