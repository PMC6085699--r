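test_that("euclidean distance matches the sum-of-squares oracle", {
  a <- make_profile(c(0, 0), "A")
  b <- make_profile(c(3, 4), "B")
  expect_equal(euclidean_distance(a, b), 5)
  expect_equal(euclidean_distance(a, a), 0)
  set.seed(1)
  for (rep in 1:20) {
    va <- rnorm(15); vb <- rnorm(15)
    d <- euclidean_distance(make_profile(va, "A"), make_profile(vb, "B"))
    expect_equal(d, sqrt(sum((va - vb)^2)))
    expect_equal(d, euclidean_distance(make_profile(vb, "B"),
                                       make_profile(va, "A")))
  }
  expect_error(euclidean_distance(a, make_profile(1, "C")),
               "common probes")
})

test_that("distance decision uses the lower 5th percentile inclusively", {
  null_d <- 1:100
  expect_equal(distance_test(0.5, null_d)$call, "clonal")
  thr <- quantile(1:100, 0.05, names = FALSE)
  expect_equal(distance_test(thr, null_d)$call, "clonal")       # <= rule
  expect_equal(distance_test(thr + 1e-9, null_d)$call, "independent")
  expect_equal(distance_test(median(null_d), null_d)$call, "independent")
  expect_warning(r <- distance_test(1, 1:5), "not evaluable")
  expect_equal(r$call, "not_evaluable")
})

test_that("cherry calls equal the mutual-nearest-neighbour oracle", {
  # under single linkage, (x, y) is a cherry iff they are mutual nearest
  # neighbours strictly closer to each other than to any third sample
  set.seed(99)
  mismatches <- 0L
  for (rep in 1:60) {
    n_pat <- sample(2:6, 1L)
    ids <- make_manifest(n_pat)$sample_id
    profs <- lapply(ids, function(s) make_profile(rnorm(8), s))
    names(profs) <- ids
    pairs <- enumerate_pairs(make_manifest(n_pat))
    res <- cluster_cherry_test(profs, pairs)
    d <- as.matrix(dist(t(sapply(profs, function(p) p$probes$value))))
    diag(d) <- Inf
    oracle <- vapply(seq_len(nrow(pairs$true_pairs)), function(i) {
      a <- pairs$true_pairs$sample_a[i]; b <- pairs$true_pairs$sample_b[i]
      d[a, b] < min(d[a, setdiff(colnames(d), c(a, b))]) &&
        d[a, b] < min(d[b, setdiff(colnames(d), c(a, b))])
    }, NA)
    mismatches <- mismatches +
      sum((res$call == "clonal") != oracle)
  }
  expect_equal(mismatches, 0L)
})

test_that("cherry test separates well-separated pairs", {
  ids <- make_manifest(2L)$sample_id
  # P01 is a tight mutual pair; P02_T2 sits nearer to P01 than to P02_T1
  vals <- list(c(0, 0, 0), c(0.1, 0, 0), c(10, 10, 10), c(0.25, 0, 0))
  profs <- Map(function(v, s) make_profile(v, s), vals, ids)
  names(profs) <- ids
  pairs <- enumerate_pairs(make_manifest(2L))
  res <- cluster_cherry_test(profs, pairs)
  expect_equal(res$call[res$patient_id == "P01"], "clonal")
  expect_equal(res$call[res$patient_id == "P02"], "independent")
})

test_that("shared segments require exact breakpoints and same direction", {
  segs_a <- data.frame(
    chrom = c("1", "1", "2", "2", "3"),
    start = c(1L, 5001L, 1L, 7001L, 1L),
    end = c(5000L, 9000L, 7000L, 9000L, 9000L),
    mean_value = c(0.6, -0.6, 0, 0.7, 0))
  a <- make_segments(segs_a, "A")
  b <- make_segments(segs_a, "B")
  expect_equal(shared_segments(a, b), 3L)  # the 3 aberrant segments only
  expect_equal(shared_segments(a, a), 3L)

  shifted <- segs_a
  shifted$start[1L] <- 2L  # one breakpoint off by 1 bp
  expect_equal(shared_segments(a, make_segments(shifted, "C")), 2L)
  # but a 1-bp tolerance recovers it
  expect_equal(shared_segments(a, make_segments(shifted, "C"), tol = 1L),
               3L)

  flipped <- segs_a
  flipped$mean_value[1L] <- -0.6  # same interval, opposite direction
  expect_equal(shared_segments(a, make_segments(flipped, "D")), 2L)
})

test_that("count thresholds are strict above the 95th percentile", {
  null_c <- rep(0:4, each = 20L)
  thr <- quantile(null_c, 0.95, names = FALSE)
  expect_equal(shared_segment_test(max(null_c) + 1L, null_c)$call,
               "clonal")
  expect_equal(shared_segment_test(thr, null_c)$call, "independent")
  expect_equal(shared_mutation_test(0L, null_c)$call, "independent")
  expect_warning(r <- shared_mutation_test(3L, 0:3), "not evaluable")
  expect_equal(r$call, "not_evaluable")
})

test_that("shared mutations intersect on the full variant key", {
  v1 <- data.frame(chrom = c("1", "2", "3"), pos = c(10L, 20L, 30L),
                   ref = c("A", "C", "G"), alt = c("T", "T", "A"))
  v2 <- data.frame(chrom = c("1", "2"), pos = c(10L, 20L),
                   ref = c("A", "C"), alt = c("T", "G"))  # alt differs at 2
  a <- variant_set("A", v1); b <- variant_set("B", v2)
  expect_equal(shared_mutations(a, b), 1L)
  expect_equal(shared_mutations(b, a), 1L)
  expect_equal(shared_mutations(a, a), 3L)
  # disjoint and subset cases
  expect_equal(shared_mutations(a, variant_set("C",
    data.frame(chrom = "9", pos = 1L, ref = "A", alt = "C"))), 0L)
})

test_that("adding a private variant never changes the shared count", {
  set.seed(5)
  for (rep in 1:20) {
    pool <- data.frame(chrom = sample(as.character(1:5), 50L, TRUE),
                       pos = sample.int(1e6, 50L),
                       ref = "A", alt = "T")
    a <- variant_set("A", pool[sample(50L, 20L), ])
    b <- variant_set("B", pool[sample(50L, 20L), ])
    base <- shared_mutations(a, b)
    # brute-force double loop oracle
    brute <- sum(outer(clonalpair:::variant_key(a$variants), clonalpair:::variant_key(b$variants),
                       "=="))
    expect_equal(base, brute)
    a2 <- variant_set("A", rbind(a$variants,
      data.frame(chrom = "X", pos = 99L, ref = "G", alt = "C")))
    expect_equal(shared_mutations(a2, b), base)
  }
})

test_that("panel restriction filters both variant sets", {
  v <- data.frame(chrom = c("1", "1", "2"), pos = c(100L, 900L, 100L),
                  ref = "A", alt = "T")
  a <- variant_set("A", v); b <- variant_set("B", v)
  panel <- data.frame(chrom = "1", start = 1L, end = 500L)
  expect_equal(shared_mutations(a, b, panel = panel), 1L)
  path <- file.path(tempdir(), "panel.tsv")
  write.table(cbind(panel, name = "region1"), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_equal(read_panel(path)$end, 500L)
})

test_that("fusion overlap matches on both breakpoints, not genes", {
  f1 <- data.frame(chrom5 = "1", pos5 = 100L, gene5 = "AAA",
                   chrom3 = "2", pos3 = 200L, gene3 = "BBB")
  a <- fusion_set("A", f1)
  b <- fusion_set("B", f1)
  expect_equal(fusion_overlap(a, b)$count, 1L)
  # same genes, different 3' breakpoint -> no match
  f2 <- f1; f2$pos3 <- 201L
  expect_equal(fusion_overlap(a, fusion_set("C", f2))$count, 0L)
  # constructed overlap of exactly 5 shared among private ones
  shared <- data.frame(chrom5 = "3", pos5 = 1:5 * 10L, gene5 = "S",
                       chrom3 = "4", pos3 = 1:5 * 20L, gene3 = "T")
  a5 <- fusion_set("A5", rbind(f1, shared))
  b5 <- fusion_set("B5", rbind(f2, shared))
  ov <- fusion_overlap(a5, b5)
  expect_equal(ov$count, 5L)
  expect_equal(sort(ov$shared$pos5), 1:5 * 10L)
})

test_that("cohort drivers agree with pairwise scalar statistics", {
  set.seed(31)
  co <- simulate_cohort(simulation_config(n_patients = 4L,
                                          n_probes = 120L, seed = 31L))
  pairs <- co$pairs
  seg_res <- cohort_segment_test(co$segments, pairs)
  for (i in seq_len(nrow(pairs$true_pairs))) {
    a <- co$segments[[pairs$true_pairs$sample_a[i]]]
    b <- co$segments[[pairs$true_pairs$sample_b[i]]]
    expect_equal(seg_res$statistic[i], shared_segments(a, b))
  }
  mut_res <- cohort_mutation_test(co$variants, pairs)
  for (i in seq_len(nrow(pairs$true_pairs))) {
    a <- co$variants[[pairs$true_pairs$sample_a[i]]]
    b <- co$variants[[pairs$true_pairs$sample_b[i]]]
    expect_equal(mut_res$statistic[i], shared_mutations(a, b))
  }
})
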