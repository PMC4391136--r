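test_that("mock genome pools honor marker and invariant-pathway constraints", {
  mk <- small_markers(5)
  pool <- build_genome_pool(n_genomes = 8, n_kos = 60, markers = mk,
                            pathway_kos = c("P1", "P2", "P3"),
                            seed = 2)
  expect_true(all(pool$copies[, mk$ko_ids] == 1))
  # invariant pathway: identical copies across every genome
  for (p in c("P1", "P2", "P3"))
    expect_equal(length(unique(pool$copies[, p])), 1)
  expect_equal(ncol(pool$copies), 60)
  # same seed reproduces byte-identical pools
  pool2 <- build_genome_pool(n_genomes = 8, n_kos = 60, markers = mk,
                             pathway_kos = c("P1", "P2", "P3"),
                             seed = 2)
  expect_identical(pool2$copies, pool$copies)
  expect_identical(pool2$ko_length, pool$ko_length)

  # padding 0, a single 1000 bp marker and nothing else -> length 1000
  mk1 <- marker_set("M1")
  solo <- build_genome_pool(n_genomes = 1, n_kos = 1, markers = mk1,
                            pathway_kos = character(0),
                            ko_length = c(M1 = 1000),
                            padding_fraction = 0, seed = 1)
  expect_equal(unname(solo$genome_length), 1000)
  expect_error(build_genome_pool(n_genomes = 2, n_kos = 3,
                                 markers = small_markers(5),
                                 pathway_kos = character(0), seed = 1),
               "at least 5")
})

test_that("communities are bounded-fold random mixtures", {
  mk <- small_markers(5)
  pool <- build_genome_pool(n_genomes = 12, n_kos = 60, markers = mk,
                            pathway_kos = character(0), seed = 3)
  comm <- sample_community(pool, genomes_per_sample = 6, max_fold = 100,
                           seed = 4)
  expect_length(comm$genome_ids, 6)
  expect_equal(sum(comm$rel_abundance), 1)
  # degenerate range -> exactly equal abundances
  eq <- sample_community(pool, genomes_per_sample = 6, max_fold = 1,
                         seed = 4)
  expect_equal(unname(eq$rel_abundance), rep(1 / 6, 6))
  # fold bound holds across a 1,000-seed sweep
  ratios <- vapply(seq_len(1000), function(s) {
    ab <- sample_community(pool, 6, 100, seed = s)$rel_abundance
    max(ab) / min(ab)
  }, numeric(1))
  expect_true(all(ratios <= 100))
  expect_error(sample_community(pool, 13, 100, seed = 1),
               "exceeds the pool size")
})

test_that("true average copy numbers are abundance-weighted genome copies", {
  mk <- marker_set("M1")
  copies <- rbind(G1 = c(M1 = 1, X = 1), G2 = c(M1 = 1, X = 3))
  pool <- genome_content(copies, genome_length = c(G1 = 2000, G2 = 4000),
                         ko_length = c(M1 = 1000, X = 1000))
  comm <- list(genome_ids = c("G1", "G2"),
               rel_abundance = c(G1 = 0.25, G2 = 0.75))
  truth <- true_average_copy_number(comm, pool)
  expect_equal(unname(truth["X"]), 2.5)
  expect_equal(unname(truth["M1"]), 1)   # exact: single copy everywhere
  # permutation invariance over genome order
  comm_r <- list(genome_ids = c("G2", "G1"),
                 rel_abundance = c(G2 = 0.75, G1 = 0.25))
  expect_equal(true_average_copy_number(comm_r, pool)[names(truth)],
               truth)
})

test_that("read counts follow the multinomial origin model", {
  # single genome, zero padding, perfect annotation: expected count of a
  # KO is n_reads * copies*len / sum(copies*len); check within 4 sigma
  mk <- marker_set("M1")
  copies <- rbind(G1 = c(M1 = 1, A = 2, B = 1))
  len <- c(M1 = 1000, A = 500, B = 2000)
  pool <- genome_content(copies, genome_length = c(G1 = 4000),
                         ko_length = len)
  comm <- list(genome_ids = "G1", rel_abundance = c(G1 = 1))
  sim <- simulate_reads(comm, pool, n_reads = 50000, read_length = 101,
                        seed = 7)
  p <- as.numeric(copies) * len / sum(as.numeric(copies) * len)
  expected <- 50000 * p
  sds <- sqrt(50000 * p * (1 - p))
  expect_true(all(abs(sim$ko_counts[names(len)] - expected) < 4 * sds))
  expect_equal(sum(sim$ko_counts) + sim$n_unassigned, 50000)

  # recall 0 for one KO silences it (no precision noise)
  sim0 <- simulate_reads(comm, pool, n_reads = 5000,
                         annotation_recall = c(M1 = 1, A = 0, B = 1),
                         seed = 8)
  expect_equal(unname(sim0$ko_counts["A"]), 0)
  expect_gt(sim0$ko_counts["B"], 0)

  # precision noise strays reads into never-present KOs
  copies2 <- rbind(G1 = c(M1 = 1, A = 2, B = 1, C = 0))
  pool2 <- genome_content(copies2, genome_length = c(G1 = 4000),
                          ko_length = c(len, C = 700))
  sim2 <- simulate_reads(comm, pool2, n_reads = 20000,
                         annotation_recall = 0.5,
                         annotation_precision_noise = 0.3, seed = 9)
  expect_gt(sim2$ko_counts["C"], 0)
  expect_gt(sim2$n_unassigned, 0)
})

test_that("simulated datasets are reproducible and internally consistent", {
  mk <- small_markers(8)
  pool <- build_genome_pool(n_genomes = 10, n_kos = 80, markers = mk,
                            pathway_kos = sprintf("P%d", 1:4), seed = 5)
  ds1 <- simulate_dataset(pool, n_samples = 4, genomes_per_sample = 5,
                          n_reads = 5000, seed = 77)
  ds2 <- simulate_dataset(pool, n_samples = 4, genomes_per_sample = 5,
                          n_reads = 5000, seed = 77)
  expect_identical(ds1$counts$values, ds2$counts$values)
  expect_identical(ds1$truth, ds2$truth)
  # marker truth is exactly 1 whenever all genomes carry copy 1
  expect_true(all(ds1$truth[mk$ko_ids, ] == 1))
  expect_true(all(colSums(ds1$counts$values) <= 5000))
})

test_that("synthetic property tables encode a known linear bias", {
  mk <- musicc_markers("usicg")
  syn0 <- synth_property_table(mk, n_properties = 10, noise_sd = 0,
                               seed = 6)
  expect_true(all(syn0$true_foldchange == 1))
  syn <- synth_property_table(mk, n_properties = 10,
                              true_weights = c(prop04 = 0.5),
                              noise_sd = 0.1, seed = 6)
  # OLS slope of fold-change on the causal property recovers the weight
  z <- syn$properties$values[, "prop04"]
  slope <- stats::coef(stats::lm(syn$true_foldchange ~ z))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.1)
  syn_b <- synth_property_table(mk, n_properties = 10,
                                true_weights = c(prop04 = 0.5),
                                noise_sd = 0.1, seed = 6)
  expect_identical(syn_b$properties$values, syn$properties$values)
  expect_identical(syn_b$true_foldchange, syn$true_foldchange)
  # property columns are exactly standardized
  expect_lt(max(abs(colMeans(syn$properties$values))), 1e-12)
  expect_lt(max(abs(apply(syn$properties$values, 2, sd) - 1)), 1e-12)
})

test_that("synthetic OTU profiles satisfy the container invariants", {
  p <- synth_otu_profiles(n_samples = 6, n_otus = 10, seed = 9)
  expect_lt(max(abs(colSums(p$otu_rel_abundance) - 1)), 1e-9)
  p2 <- synth_otu_profiles(n_samples = 6, n_otus = 10, seed = 9)
  expect_identical(p2$otu_rel_abundance, p$otu_rel_abundance)
  single <- synth_otu_profiles(n_samples = 3, n_otus = 1, seed = 2)
  expect_true(all(single$otu_rel_abundance == 1))
  expect_true(all(p$nsti >= 0 & p$nsti <= 0.5))
})

test_that("marker normalization of simulated reads recovers true copy numbers", {
  sim <- std_sim(n_reads = 2e4, n_samples = 10, seed = 13)
  ln <- length_normalize(sim$ds$counts, sim$pool$ko_length)
  mus <- inter_musicc(ln, sim$markers)
  ss20 <- slope_vs_truth(mus, sim$ds$truth)
  # more reads tighten the per-sample slopes around 1
  sim2 <- std_sim(n_reads = 2e5, n_samples = 10, seed = 13)
  ln2 <- length_normalize(sim2$ds$counts, sim2$pool$ko_length)
  ss200 <- slope_vs_truth(inter_musicc(ln2, sim2$markers), sim2$ds$truth)
  expect_lt(abs(ss200$mean_slope - 1), abs(ss20$mean_slope - 1) + 0.02)
  expect_lt(ss200$slope_cov, ss20$slope_cov)
  expect_lt(abs(ss200$mean_slope - 1), 0.02)

  # compositional slopes track average genome size; corrected ones do not
  comp <- compositional_normalize(sim2$ds$counts)
  ss_comp <- slope_vs_truth(comp, sim2$ds$truth)
  ags <- sim2$ds$true_avg_genome_size[names(ss_comp$slope)]
  p_comp <- stats::cor.test(ss_comp$slope, ags)$p.value
  p_mus <- stats::cor.test(ss200$slope,
                           sim2$ds$true_avg_genome_size[
                             names(ss200$slope)])$p.value
  expect_lt(p_comp, 0.05)
  expect_gt(p_mus, 0.05)
})
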