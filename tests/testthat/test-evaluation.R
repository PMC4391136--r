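test_that("pathway abundances are member sums", {
  m <- matrix(c(1.5, 2.5, 4, 1, 2, 3), 3, 2,
              dimnames = list(c("K1", "K2", "K3"), c("A", "B")))
  tab <- abundance_table(m)
  pw <- list(p1 = c("K1", "K2"), p2 = "K3")
  pa <- pathway_abundance(tab, pw)
  expect_equal(pa["p1", "A"], 4.0)
  expect_equal(pa["p2", ], m["K3", ])
  # disjoint pathways covering all KOs partition the column sums
  expect_equal(colSums(pa), colSums(m))
  expect_warning(pa2 <- pathway_abundance(tab, list(px = "K9")),
                 "no member KO")
  expect_equal(unname(pa2["px", ]), c(0, 0))
  expect_error(pathway_abundance(tab, list(px = character(0))),
               "empty member set")
})

test_that("rank-sum tests match the exact enumeration oracle", {
  m <- rbind(feat = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- paste0("S", 1:6)
  res <- differential_features(m, paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(res$p_raw, 0.1)   # smallest attainable two-sided p at 3v3
  expect_equal(res$direction, "group2")

  # identical values in both groups -> p = 1
  m2 <- rbind(feat = c(7, 8, 9, 7, 8, 9))
  colnames(m2) <- paste0("S", 1:6)
  res2 <- differential_features(m2, paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(res2$p_raw, 1)

  # random small-group cases against full enumeration
  set.seed(23)
  for (rep in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    vals <- sample(seq_len(50), n1 + n2)   # distinct -> no ties
    mm <- rbind(f = vals)
    colnames(mm) <- paste0("S", seq_len(n1 + n2))
    g1 <- paste0("S", seq_len(n1))
    g2 <- paste0("S", n1 + seq_len(n2))
    got <- differential_features(mm, g1, g2)
    expect_equal(got$p_raw, oracle_ranksum_p(vals[seq_len(n1)],
                                             vals[n1 + seq_len(n2)]),
                 tolerance = 1e-12)
  }

  expect_error(differential_features(m, paste0("S", 1:3),
                                     paste0("S", 3:6)), "overlap")
  expect_error(differential_features(m, paste0("S", 1:2),
                                     paste0("S", 4:6)),
               "at least 3 samples")
})

test_that("multiplicity correction and direction filters behave", {
  set.seed(24)
  m <- matrix(rnorm(20 * 12, 10), 20, 12,
              dimnames = list(sprintf("K%02d", 1:20),
                              sprintf("S%02d", 1:12)))
  m[1:3, 7:12] <- m[1:3, 7:12] + 5   # higher in group2
  g1 <- sprintf("S%02d", 1:6); g2 <- sprintf("S%02d", 7:12)
  res <- differential_features(m, g1, g2, correction = "bh_fdr")
  expect_true(all(res$p_adjusted >= res$p_raw))
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-15))
  bon <- differential_features(m, g1, g2, correction = "bonferroni")
  expect_equal(bon$p_adjusted, pmin(1, bon$p_raw * nrow(m)))
  # the disease-pathway convention: significance requires a higher median
  # in the designated group
  res_g1 <- differential_features(m, g1, g2, require_higher_in = "group1")
  expect_false(any(res_g1$significant[1:3]))
  res_g2 <- differential_features(m, g1, g2, require_higher_in = "group2")
  expect_true(all(res_g2$significant[1:3]))
})

test_that("coefficient of variation and its bootstrap are exact on hand cases", {
  expect_equal(cov_bootstrap(rep(4, 12), 5, 10, seed = 1)$full_cov, 0)
  expect_equal(cov_bootstrap(c(1, 2, 3), 2, 5, seed = 1)$full_cov, 0.5)
  vals <- rnorm(15, 10)
  bs <- cov_bootstrap(vals, subset_size = 15, n_subsets = 20, seed = 2)
  expect_true(all(abs(bs$subset_covs - bs$full_cov) < 1e-12))
  expect_error(cov_bootstrap(c(-1, 0, 1), 3, 5), "mean is zero")
  expect_error(cov_bootstrap(1:3, 5, 5), "exceeds")
})

test_that("per-sample slopes against truth are exact for linear images", {
  truth <- matrix(runif(30, 0.5, 3), 10, 3,
                  dimnames = list(sprintf("K%02d", 1:10),
                                  c("A", "B", "C")))
  tab <- abundance_table(truth, "inter_corrected")
  ss <- slope_vs_truth(tab, truth)
  expect_equal(unname(ss$slope), rep(1, 3), tolerance = 1e-12)
  expect_equal(ss$slope_cov, 0, tolerance = 1e-10)
  tab2 <- abundance_table(2 * truth, "inter_corrected")
  ss2 <- slope_vs_truth(tab2, truth)
  expect_equal(ss2$mean_slope, 2, tolerance = 1e-12)
  # a sample with fewer than 3 usable points is skipped with a warning
  t3 <- truth; t3[3:10, "C"] <- NA
  expect_warning(ss3 <- slope_vs_truth(tab, t3), "skipped")
  expect_setequal(names(ss3$slope), c("A", "B"))
})

osg_fixture <- function() {
  rel <- matrix(c(0.6, 0.4, 0,
                  0.7, 0.3, 0,
                  0.5, 0.2, 0.3,
                  1.0, 0, 0,
                  0.8, 0.2, 0,
                  0.3, 0.7, 0), 3, 6,
                dimnames = list(c("O1", "O2", "O3"), sprintf("S%d", 1:6)))
  copies <- matrix(c(1, 0, 0,   # KX only in O1
                     1, 1, 0,   # KY in O1+O2
                     0, 1, 1),  # KZ in O2+O3
                   3, 3,
                   dimnames = list(c("O1", "O2", "O3"),
                                   c("KX", "KY", "KZ")))
  otu_profiles(rel, copies, nsti = c(O1 = 0, O2 = 0, O3 = 0),
               ko_length = c(KX = 1000, KY = 1000, KZ = 1000))
}

test_that("OTU-specific genes require exactly one present source OTU", {
  p <- osg_fixture()
  osg1 <- identify_osgs(p, "S1")      # O1, O2 present
  expect_equal(osg1, c(KX = "O1", KZ = "O2"))
  osg3 <- identify_osgs(p, "S3")      # all present: KY shared, KZ shared
  expect_equal(osg3, c(KX = "O1"))
  osg4 <- identify_osgs(p, "S4")      # only O1: its whole gene set is OSG
  expect_equal(osg4, c(KX = "O1", KY = "O1"))
})

test_that("OSG-OTU concordance is exact for proportional abundances", {
  p <- osg_fixture()
  # KX abundance proportional to O1 across all samples
  m <- rbind(KX = 3 * p$otu_rel_abundance["O1", ],
             KZ = c(0.4, 0.3, 0.2, 0.0, 0.2, 0.7))
  tab <- abundance_table(m, "inter_corrected")
  rc <- osg_correlation(p, tab, min_samples = 5)
  expect_equal(rc$r[rc$ko == "KX"], 1, tolerance = 1e-12)
  # KZ is an OSG of O2 only while O3 is absent (5 samples), needs all 5
  # positive; S4 has O2 absent -> only 4 usable -> excluded at min 5
  expect_false("KZ" %in% rc$ko)
  rc4 <- osg_correlation(p, tab, min_samples = 4)
  expect_true("KZ" %in% rc4$ko)
})

test_that("fold-change discrepancies compare only consecutive samples", {
  rel <- matrix(c(0.2, 0.8,
                  0.4, 0.6,
                  0.8, 0.2), 2, 3,
                dimnames = list(c("O1", "O2"), c("A", "B", "C")))
  copies <- matrix(c(1, 0), 2, 1, dimnames = list(c("O1", "O2"), "KX"))
  p <- otu_profiles(rel, copies, nsti = c(O1 = 0, O2 = 0),
                    ko_length = c(KX = 500))
  # KX tracks O1 exactly -> all discrepancies 0
  tab <- abundance_table(rbind(KX = 5 * rel["O1", ]), "inter_corrected")
  r0 <- osg_foldchange_ratios(p, tab)
  expect_equal(r0$discrepancy, c(0, 0))
  expect_equal(r0$n_comparisons, 2)   # (n_samples - 1) per OTU with OSGs
  # O1 doubles A->B while KX triples -> |log(3/2)| recorded
  kx <- c(A = 1, B = 3, C = 4.8)
  r1 <- osg_foldchange_ratios(p, abundance_table(rbind(KX = kx),
                                                 "inter_corrected"))
  expect_equal(r1$discrepancy[1], abs(log(3 / 2)), tolerance = 1e-12)
})

test_that("genomic and metagenomic correlation structure agree for linear images", {
  # 3-KO brute-force check
  copies <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  colnames(copies) <- c("Ka", "Kb", "Kc")
  content <- make_content(copies)
  m <- matrix(c(1, 2, 3, 2, 1, 4, 3, 3, 3, 1, 4, 2), 3, 4,
              dimnames = list(c("Ka", "Kb", "Kc"), sprintf("S%d", 1:4)))
  tab <- abundance_table(m, "inter_corrected")
  got <- correlation_structure_similarity(content, tab)
  jac <- function(i, j) {
    a <- copies[, i] >= 1; b <- copies[, j] >= 1
    sum(a & b) / sum(a | b)
  }
  A_ka <- c(jac(1, 2), jac(1, 3))
  B_ka <- c(stats::cor(m[1, ], m[2, ]), stats::cor(m[1, ], m[3, ]))
  expect_equal(unname(got["Ka"]), stats::cor(A_ka, B_ka),
               tolerance = 1e-12)

  # abundances that are exact linear images of genome content score
  # higher than a permuted-label null
  set.seed(26)
  copies2 <- matrix(stats::rbinom(30 * 25, 1, 0.5), 30, 25,
                    dimnames = list(sprintf("G%02d", 1:30),
                                    sprintf("K%03d", 1:25)))
  content2 <- make_content(copies2)
  mix <- matrix(stats::rgamma(30 * 15, 1), 30, 15)
  ab <- t(copies2) %*% mix
  colnames(ab) <- sprintf("S%02d", 1:15)
  tab2 <- abundance_table(ab, "inter_corrected")
  real <- correlation_structure_similarity(content2, tab2)
  perm <- copies2
  rownames(perm) <- rownames(copies2)
  perm <- perm[, sample(ncol(perm))]
  colnames(perm) <- colnames(copies2)
  null <- correlation_structure_similarity(make_content(perm), tab2)
  expect_gt(mean(real), mean(null))
  expect_gt(mean(real), 0.2)
})

test_that("cross-study recovery truncates the alternative hit list", {
  fake_result <- function(ids, p, sig) {
    df <- data.frame(feature_id = ids, statistic = 0, p_raw = p,
                     p_adjusted = p, direction = "group1",
                     significant = sig, stringsAsFactors = FALSE)
    class(df) <- c("differential_result", "data.frame")
    df
  }
  ids <- sprintf("pw%02d", 1:40)
  ref <- fake_result(ids, seq(0.001, 0.4, length.out = 40),
                     c(rep(TRUE, 19), rep(FALSE, 21)))
  # identical analyses recover everything
  expect_equal(cross_study_recovery(ref, ref)$n_recovered, 19)
  # disjoint significant sets recover nothing
  alt0 <- fake_result(ids, seq(0.001, 0.4, length.out = 40),
                      c(rep(FALSE, 19), rep(TRUE, 21)))
  expect_equal(cross_study_recovery(ref, alt0)$n_recovered, 0)
  # 30 significant alternatives truncate to the 19 smallest p-values
  p_alt <- c(seq(0.03, 0.05, length.out = 11),   # pw01..pw11: large p
             seq(0.001, 0.02, length.out = 19))  # pw12..pw30: small p
  alt <- fake_result(ids, c(p_alt, rep(0.9, 10)),
                     c(rep(TRUE, 30), rep(FALSE, 10)))
  out <- cross_study_recovery(ref, alt)
  expect_equal(out$n_reference, 19)
  # top 19 of the alternative are pw12..pw30; overlap with ref's pw01..19
  expect_setequal(out$recovered, sprintf("pw%02d", 12:19))
})

test_that("marker normalization detects a shifted pathway at no larger sample size", {
  mk <- small_markers(20)
  path_kos <- sprintf("P%02d", 1:10)
  mkpool <- function(copy) build_genome_pool(
    n_genomes = 12, n_kos = 150, markers = mk, pathway_kos = path_kos,
    pathway_copy = copy, seed = 41)
  pool_ctl <- mkpool(1)
  pool_case <- mkpool(2)
  n_grid <- c(4, 5, 6, 8)
  min_n <- function(pvals) {
    hit <- which(pvals < 0.05)
    if (length(hit)) n_grid[hit[1]] else max(n_grid) + 2
  }
  res <- t(sapply(1:20, function(seed) {
    ds_ctl <- simulate_dataset(pool_ctl, n_samples = 8,
                               genomes_per_sample = 6, n_reads = 8000,
                               seed = 1000 + seed)
    ds_case <- simulate_dataset(pool_case, n_samples = 8,
                                genomes_per_sample = 6, n_reads = 8000,
                                seed = 5000 + seed)
    p_at_n <- function(norm_fn) {
      a_ctl <- norm_fn(ds_ctl)
      a_case <- norm_fn(ds_case)
      colnames(a_case$values) <- paste0("C", colnames(a_case$values))
      joint <- abundance_table(cbind(a_ctl$values, a_case$values),
                               a_ctl$stage)
      pa <- pathway_abundance(joint, list(pw = path_kos))
      vapply(n_grid, function(n) {
        g1 <- colnames(a_ctl$values)[seq_len(n)]
        g2 <- colnames(a_case$values)[seq_len(n)]
        differential_features(pa, g1, g2)$p_raw
      }, numeric(1))
    }
    mus <- function(ds) inter_musicc(
      length_normalize(ds$counts, pool_ctl$ko_length), mk,
      min_markers_detected = 5)
    comp <- function(ds) compositional_normalize(ds$counts)
    c(min_n(p_at_n(mus)), min_n(p_at_n(comp)))
  }))
  expect_gte(mean(res[, 1] <= res[, 2]), 0.9)
  expect_lte(mean(res[, 1]), mean(res[, 2]))
})
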