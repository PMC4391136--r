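# Shared fixture builders and independent oracles used across test files.
# Everything is generated in code; no binary fixtures.

tiny_table <- function(stage = "counts") {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("K00001", "K00002", "K00003"),
                              c("S1", "S2")))
  abundance_table(m, stage = stage)
}

random_table <- function(n_ko = 100, n_s = 10, seed = 1,
                         stage = "counts") {
  set.seed(seed)
  m <- matrix(round(stats::runif(n_ko * n_s, 0, 1000), 6), n_ko, n_s,
              dimnames = list(sprintf("K%05d", seq_len(n_ko)),
                              sprintf("S%02d", seq_len(n_s))))
  abundance_table(m, stage = stage)
}

small_markers <- function(n = 12, role = "usicg") {
  marker_set(sprintf("K5%04d", seq_len(n)), role = role)
}

# genome_content from an explicit copies matrix given as rows = genomes
make_content <- function(copies, ...) {
  if (is.null(rownames(copies)))
    rownames(copies) <- sprintf("G%02d", seq_len(nrow(copies)))
  if (is.null(colnames(copies)))
    colnames(copies) <- sprintf("K%05d", seq_len(ncol(copies)))
  genome_content(copies, ...)
}

# brute-force Jaccard over all pairs; independent of the crossprod path
oracle_jaccard_pairs <- function(presence, threshold) {
  kos <- colnames(presence)
  out <- list()
  for (i in seq_len(ncol(presence) - 1)) {
    for (j in (i + 1):ncol(presence)) {
      a <- presence[, i]; b <- presence[, j]
      uni <- sum(a | b)
      if (uni == 0) next
      jac <- sum(a & b) / uni
      if (jac > threshold)
        out[[length(out) + 1]] <- data.frame(ko_a = kos[i], ko_b = kos[j],
                                             jaccard = jac)
    }
  }
  if (!length(out))
    return(data.frame(ko_a = character(0), ko_b = character(0),
                      jaccard = numeric(0)))
  do.call(rbind, out)
}

# maximal cliques by subset enumeration (feasible for <= ~18 vertices)
oracle_max_cliques <- function(pairs, min_size) {
  verts <- sort(unique(c(pairs$ko_a, pairs$ko_b)))
  adj <- matrix(FALSE, length(verts), length(verts),
                dimnames = list(verts, verts))
  for (r in seq_len(nrow(pairs))) {
    adj[pairs$ko_a[r], pairs$ko_b[r]] <- TRUE
    adj[pairs$ko_b[r], pairs$ko_a[r]] <- TRUE
  }
  n <- length(verts)
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < min_size) next
    sub <- adj[members, members, drop = FALSE]
    diag(sub) <- TRUE
    if (!all(sub)) next
    cliques[[length(cliques) + 1]] <- members
  }
  # keep maximal only
  keep <- rep(TRUE, length(cliques))
  for (i in seq_along(cliques)) {
    for (j in seq_along(cliques)) {
      if (i != j && all(cliques[[i]] %in% cliques[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  lapply(cliques[keep], function(m) verts[m])
}

# exact two-sided rank-sum p-value by enumerating all group assignments
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  combos <- utils::combn(n1 + n2, n1)
  r <- rank(pooled)
  wstat <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  w_obs <- wstat(seq_len(n1))
  w_all <- apply(combos, 2, wstat)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-regression residual correlation oracle for partial correlation
oracle_partial_cor <- function(x, y, controls) {
  rx <- stats::residuals(stats::lm(x ~ controls))
  ry <- stats::residuals(stats::lm(y ~ controls))
  stats::cor(rx, ry)
}

# standard reduced-scale simulation shared by end-to-end tests:
# 21-genome pool sharing an invariant 35-KO pathway, 20 samples of 10
# genomes at up to 100-fold abundance range
std_sim <- function(n_reads = 1e5, n_samples = 20, seed = 42,
                    markers = musicc_markers("usicg")) {
  path_kos <- sprintf("K7%04d", seq_len(35))
  pool <- build_genome_pool(n_genomes = 21, n_kos = 800,
                            markers = markers, pathway_kos = path_kos,
                            seed = 11)
  ds <- simulate_dataset(pool, n_samples = n_samples,
                         genomes_per_sample = 10, max_fold = 100,
                         n_reads = n_reads, read_length = 101,
                         seed = seed)
  list(pool = pool, ds = ds, markers = markers, pathway_kos = path_kos)
}
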