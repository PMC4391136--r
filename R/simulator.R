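#' Build a pool of mock genomes with known KO content
#'
#' Constructs `n_genomes` synthetic genomes over a shared KO universe.
#' Every genome carries each marker KO at exactly one copy (the
#' single-copy-gene assumption under which the normalization is exact) and
#' each KO of a designated invariant pathway at one shared copy number, so
#' that the pathway's true abundance is identical in every community built
#' from the pool. Remaining "accessory" KOs are present per genome with a
#' genome-specific Bernoulli probability; the per-genome probabilities are
#' evenly spaced across `presence_range`, so the pool spans a wide,
#' reproducible range of genome sizes (more than 3-fold at the defaults).
#' Accessory KOs present in a genome carry 1-3 copies. Genome length is
#' the annotated length
#' (sum of copies x gene length) inflated by `padding_fraction` of
#' intergenic/unannotated DNA.
#'
#' @param n_genomes number of genomes (default 21).
#' @param n_kos total number of KOs in the universe; must cover markers
#'   plus pathway.
#' @param markers a [marker_set()] carried at copy 1 by every genome.
#' @param pathway_kos character vector of invariant-pathway KO ids.
#' @param pathway_copy shared copy number of the pathway KOs (default 1).
#' @param ko_length optional named per-KO length (bp); lengths for KOs not
#'   given are drawn log-normally around 900 bp.
#' @param copy_probs probabilities of 1, 2, 3 copies for an accessory KO
#'   present in a genome.
#' @param presence_range range over which per-genome accessory presence
#'   probabilities are evenly spaced.
#' @param padding_fraction unannotated fraction added to genome length
#'   (default 0.1); reads from padding map to no KO.
#' @param seed integer seed.
#' @return a [genome_content()] with `genome_length` and `ko_length` set
#'   and attributes `marker_ids`, `pathway_ids`, `padding_fraction`.
#' @export
build_genome_pool <- function(n_genomes = 21, n_kos, markers, pathway_kos,
                              pathway_copy = 1, ko_length = NULL,
                              copy_probs = c(0.85, 0.12, 0.03),
                              presence_range = c(0.15, 0.95),
                              padding_fraction = 0.1, seed = 1) {
  stopifnot(inherits(markers, "marker_set"))
  mk <- markers$ko_ids
  pathway_kos <- as.character(pathway_kos)
  if (length(intersect(mk, pathway_kos)))
    stop("marker and pathway KO sets must be disjoint")
  n_fixed <- length(mk) + length(pathway_kos)
  if (n_kos < n_fixed)
    stop("'n_kos' must be at least ", n_fixed,
         " (markers plus pathway KOs)")
  if (padding_fraction < 0) stop("'padding_fraction' must be >= 0")
  set.seed(seed)
  n_acc <- n_kos - n_fixed
  acc <- if (n_acc > 0) sprintf("K9%05d", seq_len(n_acc)) else character(0)
  kos <- c(mk, pathway_kos, acc)
  if (anyDuplicated(kos)) stop("KO id collision with accessory ids")
  if (is.null(ko_length)) ko_length <- numeric(0)
  need <- setdiff(kos, names(ko_length))
  drawn <- stats::setNames(pmax(100, round(stats::rlnorm(
    length(need), meanlog = log(900), sdlog = 0.35))), need)
  len <- c(ko_length[intersect(names(ko_length), kos)], drawn)[kos]
  genomes <- sprintf("G%03d", seq_len(n_genomes))
  copies <- matrix(0L, n_genomes, length(kos),
                   dimnames = list(genomes, kos))
  copies[, mk] <- 1L
  copies[, pathway_kos] <- as.integer(pathway_copy)
  if (n_acc > 0) {
    p_g <- if (n_genomes == 1) mean(presence_range) else
      seq(presence_range[1], presence_range[2], length.out = n_genomes)
    for (g in seq_len(n_genomes)) {
      present <- stats::runif(n_acc) < p_g[g]
      cp <- integer(n_acc)
      cp[present] <- sample.int(3L, sum(present), replace = TRUE,
                                prob = copy_probs)
      copies[g, acc] <- cp
    }
  }
  glen <- round(as.numeric(copies %*% len) * (1 + padding_fraction))
  pool <- genome_content(copies, genome_length = stats::setNames(glen,
                                                                 genomes),
                         ko_length = len)
  attr(pool, "marker_ids") <- mk
  attr(pool, "pathway_ids") <- pathway_kos
  attr(pool, "padding_fraction") <- padding_fraction
  pool
}

#' Draw a random community from a genome pool
#'
#' Selects a uniform random subset of genomes and assigns them relative
#' abundances drawn log-uniformly on [1, `max_fold`], normalized to sum
#' to 1; the ratio of the most to the least abundant genome never exceeds
#' `max_fold`.
#'
#' @param pool a genome pool from [build_genome_pool()].
#' @param genomes_per_sample genomes per community (default 10).
#' @param max_fold maximum abundance fold range (default 100).
#' @param seed integer seed.
#' @return list with `genome_ids` and `rel_abundance` (named, sums to 1).
#' @export
sample_community <- function(pool, genomes_per_sample = 10, max_fold = 100,
                             seed = 1) {
  stopifnot(inherits(pool, "genome_content"))
  n <- nrow(pool$copies)
  if (genomes_per_sample > n)
    stop("'genomes_per_sample' exceeds the pool size (", n, ")")
  if (max_fold < 1) stop("'max_fold' must be >= 1")
  set.seed(seed)
  ids <- sort(sample(rownames(pool$copies), genomes_per_sample))
  raw <- exp(stats::runif(genomes_per_sample, 0, log(max_fold)))
  list(genome_ids = ids,
       rel_abundance = stats::setNames(raw / sum(raw), ids))
}

#' True average genomic copy number of every KO in a community
#'
#' The ground truth the normalization is judged against: per KO, the copy
#' numbers of the community's genomes weighted by their relative (cell)
#' abundances.
#'
#' @param community a community from [sample_community()].
#' @param pool the genome pool it was drawn from.
#' @return named per-KO average copy number.
#' @export
true_average_copy_number <- function(community, pool) {
  stopifnot(inherits(pool, "genome_content"))
  ab <- community$rel_abundance
  if (abs(sum(ab) - 1) > 1e-9) stop("community abundances must sum to 1")
  cp <- pool$copies[community$genome_ids, , drop = FALSE]
  stats::setNames(as.numeric(crossprod(ab, cp)), colnames(cp))
}

#' Simulate origin-tracked shotgun reads from a community
#'
#' Reads are assigned to genomes multinomially with probability
#' proportional to relative abundance times genome length (more abundant
#' and longer genomes contribute more DNA, which is exactly what makes the
#' average genome size a confounder for compositional normalization).
#' Within a genome a read lands on a KO, or on the unannotated padding,
#' with probability proportional to copies times gene length (padding
#' length). A KO-originating read is counted for its KO with probability
#' `annotation_recall[KO]`, miscounted to a uniformly random other KO with
#' probability `annotation_precision_noise`, and is otherwise unassigned
#' (like a read whose alignment fails); padding reads are always
#' unassigned.
#'
#' @param community a community from [sample_community()].
#' @param pool the genome pool.
#' @param n_reads reads to draw (default 500000).
#' @param read_length read length in bp (default 101).
#' @param annotation_recall scalar or named per-KO probability in [0, 1].
#' @param annotation_precision_noise probability of misassignment.
#' @param seed integer seed.
#' @return an object of class `simulated_sample`: `ko_counts` (named,
#'   full KO universe), `true_avg_copy`, `genome_ids`, `rel_abundance`,
#'   `n_reads`, `read_length`, `n_unassigned`, `seed`.
#' @export
simulate_reads <- function(community, pool, n_reads = 500000,
                           read_length = 101, annotation_recall = 1,
                           annotation_precision_noise = 0, seed = 1) {
  stopifnot(inherits(pool, "genome_content"))
  if (n_reads <= 0) stop("'n_reads' must be positive")
  if (annotation_precision_noise < 0 || annotation_precision_noise > 1)
    stop("'annotation_precision_noise' must be in [0, 1]")
  kos <- colnames(pool$copies)
  recall <- if (length(annotation_recall) == 1)
    stats::setNames(rep(annotation_recall, length(kos)), kos) else
    align_named(annotation_recall, kos, "annotation_recall")
  if (any(recall < 0 | recall > 1))
    stop("'annotation_recall' must be in [0, 1]")
  if (any(recall + annotation_precision_noise > 1))
    stop("recall + precision noise must not exceed 1")
  set.seed(seed)
  ab <- community$rel_abundance
  glen <- pool$genome_length[community$genome_ids]
  if (is.null(glen)) stop("pool lacks genome lengths")
  reads_per_genome <- as.vector(stats::rmultinom(1, n_reads,
                                                 ab * glen))
  len <- pool$ko_length
  counts <- stats::setNames(numeric(length(kos)), kos)
  n_unassigned <- 0L
  for (gi in seq_along(community$genome_ids)) {
    ng <- reads_per_genome[gi]
    if (ng == 0) next
    cp <- pool$copies[community$genome_ids[gi], ]
    annotated <- as.numeric(cp) * len
    padding <- max(0, glen[gi] - sum(annotated))
    draw <- as.vector(stats::rmultinom(1, ng, c(annotated, padding)))
    counts <- counts + draw[seq_along(kos)]
    n_unassigned <- n_unassigned + draw[length(draw)]
  }
  # annotation error: per KO, split origin reads into kept / misassigned /
  # lost, then scatter misassigned reads uniformly over the other KOs
  if (any(recall < 1) || annotation_precision_noise > 0) {
    kept <- stats::setNames(numeric(length(kos)), kos)
    strays <- 0L
    stray_pool <- integer(0)
    for (k in which(counts > 0)) {
      p <- c(recall[k], annotation_precision_noise,
             1 - recall[k] - annotation_precision_noise)
      split <- as.vector(stats::rmultinom(1, counts[k], p))
      kept[k] <- split[1]
      if (split[2] > 0)
        stray_pool <- c(stray_pool, rep(k, split[2]))
      n_unassigned <- n_unassigned + split[3]
    }
    if (length(stray_pool)) {
      for (k in stray_pool) {
        target <- sample(seq_along(kos)[-k], 1)
        kept[target] <- kept[target] + 1
      }
    }
    counts <- kept
  }
  structure(list(ko_counts = counts,
                 true_avg_copy = true_average_copy_number(community, pool),
                 genome_ids = community$genome_ids,
                 rel_abundance = community$rel_abundance,
                 n_reads = n_reads, read_length = read_length,
                 n_unassigned = n_unassigned, seed = seed),
            class = "simulated_sample")
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat(sprintf(paste0("simulated_sample: %d genomes, %d reads (%d bp), ",
                     "%d unassigned\n"),
              length(x$genome_ids), x$n_reads, x$read_length,
              x$n_unassigned))
  invisible(x)
}

#' Simulate a full dataset of mock metagenomic samples
#'
#' Draws `n_samples` communities from the pool and simulates reads for
#' each, collecting the per-sample KO counts into an [abundance_table()]
#' and the ground-truth average copy numbers into a matching matrix. All
#' randomness flows from the single `seed`.
#'
#' @param pool a genome pool from [build_genome_pool()].
#' @param n_samples number of samples (default 20).
#' @inheritParams simulate_reads
#' @inheritParams sample_community
#' @return list with `counts` (abundance_table, stage `"counts"`),
#'   `truth` (KO x sample matrix of true average copy numbers),
#'   `samples` (list of `simulated_sample`), and `true_avg_genome_size`
#'   (named per-sample, abundance-weighted over community genomes).
#' @export
simulate_dataset <- function(pool, n_samples = 20, genomes_per_sample = 10,
                             max_fold = 100, n_reads = 500000,
                             read_length = 101, annotation_recall = 1,
                             annotation_precision_noise = 0, seed = 1) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, 2 * n_samples)
  kos <- colnames(pool$copies)
  ids <- sprintf("S%03d", seq_len(n_samples))
  counts <- matrix(0, length(kos), n_samples,
                   dimnames = list(kos, ids))
  truth <- matrix(0, length(kos), n_samples,
                  dimnames = list(kos, ids))
  samples <- vector("list", n_samples)
  ags <- stats::setNames(numeric(n_samples), ids)
  for (i in seq_len(n_samples)) {
    comm <- sample_community(pool, genomes_per_sample, max_fold,
                             seed = sub_seeds[2 * i - 1])
    sim <- simulate_reads(comm, pool, n_reads = n_reads,
                          read_length = read_length,
                          annotation_recall = annotation_recall,
                          annotation_precision_noise =
                            annotation_precision_noise,
                          seed = sub_seeds[2 * i])
    sim$sample_id <- ids[i]
    counts[, i] <- sim$ko_counts
    truth[, i] <- sim$true_avg_copy
    ags[i] <- sum(comm$rel_abundance *
                    pool$genome_length[comm$genome_ids])
    samples[[i]] <- sim
  }
  list(counts = abundance_table(counts, stage = "counts"),
       truth = truth, samples = samples, true_avg_genome_size = ags)
}

#' Synthesize a gene-property table with a known bias model
#'
#' Draws standard-normal property values for the given KOs, standardizes
#' each column to exact mean 0 and unit variance (property tables are
#' consumed standardized), and defines a true per-KO fold-change
#' `1 + sum(w_j * z_j) + N(0, noise_sd)`, floored at 0.05, so that
#' property-bias model fits can be scored against known coefficients.
#'
#' @param markers a [marker_set()] (the KOs the model will be trained on).
#' @param other_kos additional KO ids to cover (corrected but unseen at
#'   training).
#' @param n_properties number of properties (default 35).
#' @param true_weights named numeric vector of nonzero weights; names must
#'   be among the property names `prop01`, `prop02`, ...
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed.
#' @return list with `properties` (a [gene_property_table()]),
#'   `true_foldchange` (named per-KO) and `true_weights`.
#' @export
synth_property_table <- function(markers, other_kos = character(0),
                                 n_properties = 35, true_weights = NULL,
                                 noise_sd = 0, seed = 1) {
  stopifnot(inherits(markers, "marker_set"))
  props <- sprintf("prop%02d", seq_len(n_properties))
  w <- stats::setNames(numeric(n_properties), props)
  if (!is.null(true_weights)) {
    bad <- setdiff(names(true_weights), props)
    if (length(bad))
      stop("true_weights name(s) outside the property set: ",
           paste(bad, collapse = ", "))
    w[names(true_weights)] <- true_weights
  }
  kos <- unique(c(markers$ko_ids, other_kos))
  set.seed(seed)
  Z <- matrix(stats::rnorm(length(kos) * n_properties), length(kos),
              n_properties, dimnames = list(kos, props))
  Z <- scale(Z)
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  fc <- 1 + as.numeric(Z %*% w) +
    stats::rnorm(length(kos), sd = noise_sd)
  fc <- pmax(fc, 0.05)
  list(properties = gene_property_table(Z, standardized = TRUE),
       true_foldchange = stats::setNames(fc, kos),
       true_weights = w)
}

#' Synthesize PICRUSt-style OTU profile bundles
#'
#' Seeded random OTU relative abundances (symmetric Dirichlet), sparse
#' random KO copy content, NSTI values uniform on [0, 0.5], and
#' log-normal KO lengths, packaged as an [otu_profiles()] object.
#'
#' @param n_samples,n_otus dimensions of the bundle.
#' @param n_kos size of the KO universe (default 50).
#' @param seed integer seed.
#' @param presence_prob probability an OTU carries a given KO.
#' @return an [otu_profiles()].
#' @export
synth_otu_profiles <- function(n_samples, n_otus, n_kos = 50, seed = 1,
                               presence_prob = 0.4) {
  set.seed(seed)
  otus <- sprintf("OTU%03d", seq_len(n_otus))
  kos <- sprintf("K8%05d", seq_len(n_kos))
  ids <- sprintf("S%03d", seq_len(n_samples))
  raw <- matrix(stats::rgamma(n_otus * n_samples, shape = 1), n_otus,
                n_samples, dimnames = list(otus, ids))
  rel <- sweep(raw, 2, colSums(raw), "/")
  copies <- matrix(stats::rbinom(n_otus * n_kos, 1, presence_prob) *
                     sample.int(3L, n_otus * n_kos, replace = TRUE,
                                prob = c(0.8, 0.15, 0.05)),
                   n_otus, n_kos, dimnames = list(otus, kos))
  nsti <- stats::setNames(stats::runif(n_otus, 0, 0.5), otus)
  len <- stats::setNames(pmax(100, round(stats::rlnorm(
    n_kos, log(900), 0.35))), kos)
  otu_profiles(rel, copies, nsti, len)
}
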