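#' Pathway abundance matrix
#'
#' Sums, per sample, the abundances of the member KOs of each pathway.
#' Member KOs absent from the table contribute zero; a pathway with no
#' member present yields a zero row and a warning.
#'
#' @param table an [abundance_table()].
#' @param pathways named list mapping pathway id to a character vector of
#'   member KO ids (each non-empty).
#' @return pathway x sample numeric matrix.
#' @export
pathway_abundance <- function(table, pathways) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(names(pathways)) || any(!nzchar(names(pathways))))
    stop("'pathways' must be a named list")
  if (any(lengths(pathways) == 0))
    stop("pathway with empty member set: ",
         names(pathways)[lengths(pathways) == 0][1])
  v <- table$values
  out <- matrix(0, length(pathways), ncol(v),
                dimnames = list(names(pathways), colnames(v)))
  empty <- character(0)
  for (p in names(pathways)) {
    members <- intersect(pathways[[p]], rownames(v))
    if (!length(members)) {
      empty <- c(empty, p)
      next
    }
    out[p, ] <- colSums(v[members, , drop = FALSE])
  }
  if (length(empty))
    warning("pathway(s) with no member KO in the table: ",
            paste(empty, collapse = ", "))
  out
}

#' Differentially abundant features between two sample groups
#'
#' Per feature (gene or pathway), a two-sided Wilcoxon rank-sum test
#' compares the abundance distributions of the two groups; p-values are
#' adjusted by Bonferroni or Benjamini-Hochberg FDR. For small groups
#' (both sizes <= 8, no ties) the exact null distribution is used,
#' otherwise the normal approximation with midrank tie correction and
#' continuity correction. Optionally, significance additionally requires
#' the feature's median to be higher in a designated group (the
#' disease-associated pathway convention).
#'
#' @param x an [abundance_table()] or a feature x sample matrix.
#' @param group1,group2 disjoint character vectors of sample ids, each of
#'   size >= 3.
#' @param correction `"bh_fdr"` (default) or `"bonferroni"`.
#' @param alpha significance level (default 0.05).
#' @param require_higher_in `NULL`, `"group1"` or `"group2"`: if set, a
#'   feature is significant only when its median is strictly higher in
#'   that group.
#' @return data frame of class `differential_result` with columns
#'   `feature_id`, `statistic` (rank-sum W), `p_raw`, `p_adjusted`,
#'   `direction` (which group has the higher median), `significant`.
#' @export
differential_features <- function(x, group1, group2,
                                  correction = c("bh_fdr", "bonferroni"),
                                  alpha = 0.05,
                                  require_higher_in = NULL) {
  correction <- match.arg(correction)
  v <- if (inherits(x, "abundance_table")) x$values else x
  if (!is.matrix(v)) stop("'x' must be an abundance_table or matrix")
  if (length(intersect(group1, group2)))
    stop("sample groups overlap: ",
         paste(intersect(group1, group2), collapse = ", "))
  if (length(group1) < 3 || length(group2) < 3)
    stop("each group needs at least 3 samples")
  miss <- setdiff(c(group1, group2), colnames(v))
  if (length(miss))
    stop("sample(s) not in the table: ", paste(miss, collapse = ", "))
  if (!is.null(require_higher_in))
    require_higher_in <- match.arg(require_higher_in,
                                   c("group1", "group2"))
  n1 <- length(group1); n2 <- length(group2)
  res <- data.frame(feature_id = rownames(v),
                    statistic = NA_real_, p_raw = NA_real_,
                    stringsAsFactors = FALSE)
  dir <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    a <- v[i, group1]; b <- v[i, group2]
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- n1 <= 8 && n2 <= 8 && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    res$statistic[i] <- unname(wt$statistic)
    res$p_raw[i] <- wt$p.value
    ma <- stats::median(a); mb <- stats::median(b)
    dir[i] <- if (ma > mb) "group1" else if (mb > ma) "group2" else "tie"
  }
  res$p_adjusted <- stats::p.adjust(res$p_raw,
                                    method = if (correction == "bh_fdr")
                                      "BH" else "bonferroni")
  res$direction <- dir
  res$significant <- res$p_adjusted < alpha
  if (!is.null(require_higher_in))
    res$significant <- res$significant & res$direction == require_higher_in
  class(res) <- c("differential_result", "data.frame")
  attr(res, "alpha") <- alpha
  attr(res, "correction") <- correction
  res
}

#' Coefficient of variation with subsampling bootstrap
#'
#' The CoV (standard deviation with the n-1 denominator, divided by the
#' mean) over all samples, plus CoVs over repeated random subsets drawn
#' without replacement, quantifying how robust the dispersion estimate is
#' to subsampling.
#'
#' @param values per-sample numeric vector (mean must be nonzero).
#' @param subset_size samples per subset (default 10).
#' @param n_subsets number of subsets (default 100).
#' @param seed integer seed.
#' @return list with `full_cov` and `subset_covs` (length `n_subsets`).
#' @export
cov_bootstrap <- function(values, subset_size = 10, n_subsets = 100,
                          seed = 1) {
  n <- length(values)
  if (subset_size > n) stop("'subset_size' exceeds the number of samples")
  if (n_subsets < 1) stop("'n_subsets' must be >= 1")
  cov1 <- function(x) {
    m <- mean(x)
    if (m == 0) stop("coefficient of variation undefined: mean is zero")
    stats::sd(x) / m
  }
  full <- cov1(values)
  set.seed(seed)
  subs <- vapply(seq_len(n_subsets),
                 function(i) cov1(values[sample.int(n, subset_size)]),
                 numeric(1))
  list(full_cov = full, subset_covs = subs)
}

#' Per-sample regression of corrected abundances on true copy numbers
#'
#' For every sample, fits an ordinary least-squares line of the corrected
#' abundance on the true average copy number over the KOs shared by both
#' inputs. A perfectly calibrated normalization gives slope 1 in every
#' sample; the coefficient of variation of the slopes measures the
#' residual spurious inter-sample variation.
#'
#' @param corrected an [abundance_table()].
#' @param truth KO x sample matrix of true average copy numbers (sample
#'   columns must cover the table's samples).
#' @return list of class `slope_summary`: per-sample `slope`,
#'   `intercept`, `r2`, plus `mean_slope` and `slope_cov`
#'   (= sd(slopes)/mean(slopes)). Samples with fewer than 3 usable points
#'   are skipped with a warning.
#' @export
slope_vs_truth <- function(corrected, truth) {
  stopifnot(inherits(corrected, "abundance_table"), is.matrix(truth))
  kos <- intersect(rownames(corrected$values), rownames(truth))
  if (!length(kos)) stop("no shared KOs between table and truth")
  samples <- intersect(colnames(corrected$values), colnames(truth))
  if (!length(samples)) stop("no shared samples between table and truth")
  slope <- intercept <- r2 <- stats::setNames(rep(NA_real_,
                                                  length(samples)),
                                              samples)
  for (s in samples) {
    x <- truth[kos, s]; y <- corrected$values[kos, s]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      warning("sample '", s, "' skipped: fewer than 3 usable points")
      next
    }
    fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
    slope[s] <- fit$coefficients[2]
    intercept[s] <- fit$coefficients[1]
    ss_tot <- sum((y[ok] - mean(y[ok]))^2)
    r2[s] <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  }
  keep <- !is.na(slope)
  structure(list(slope = slope[keep], intercept = intercept[keep],
                 r2 = r2[keep], mean_slope = mean(slope[keep]),
                 slope_cov = stats::sd(slope[keep]) / mean(slope[keep])),
            class = "slope_summary")
}

#' @export
print.slope_summary <- function(x, ...) {
  cat(sprintf("slope_summary: %d samples, mean slope %.4f, CoV %.4f\n",
              length(x$slope), x$mean_slope, x$slope_cov))
  invisible(x)
}

#' OTU-specific genes of one sample
#'
#' A KO is an OTU-Specific Gene (OSG) of a sample when its predicted copy
#' number is positive in exactly one of the OTUs present (relative
#' abundance > 0) in that sample; its abundance should then track that
#' OTU's abundance, which makes OSGs a validation set for abundance
#' estimates.
#'
#' @param profiles an [otu_profiles()].
#' @param sample_id sample to analyze.
#' @return named character vector mapping each OSG KO id to its OTU id.
#' @export
identify_osgs <- function(profiles, sample_id) {
  stopifnot(inherits(profiles, "otu_profiles"))
  if (!sample_id %in% colnames(profiles$otu_rel_abundance))
    stop("unknown sample '", sample_id, "'")
  present <- profiles$otu_rel_abundance[, sample_id] > 0
  cp <- profiles$otu_ko_copies[present, , drop = FALSE]
  pres <- cp > 0
  n_src <- colSums(pres)
  osg <- which(n_src == 1)
  src <- vapply(osg, function(k) rownames(cp)[which(pres[, k])],
                character(1))
  stats::setNames(src, colnames(cp)[osg])
}

#' Correlation between OSG and OTU abundances
#'
#' For each (KO, OTU) pair such that the KO is an OSG of that OTU, the
#' Pearson correlation between the OTU's relative abundance and the KO's
#' abundance is computed across the samples where the KO is an OSG of the
#' OTU and both abundances are positive. Pairs observed in fewer than
#' `min_samples` such samples are excluded.
#'
#' @param profiles an [otu_profiles()].
#' @param abundances an [abundance_table()] over (at least) the profile's
#'   samples.
#' @param min_samples minimum qualifying samples per pair (default 5).
#' @return data frame with columns `ko`, `otu`, `n_samples`, `r`.
#' @export
osg_correlation <- function(profiles, abundances, min_samples = 5) {
  stopifnot(inherits(profiles, "otu_profiles"),
            inherits(abundances, "abundance_table"))
  samples <- intersect(colnames(profiles$otu_rel_abundance),
                       colnames(abundances$values))
  osg_by_sample <- lapply(stats::setNames(samples, samples),
                          function(s) identify_osgs(profiles, s))
  pair_samples <- list()
  for (s in samples) {
    m <- osg_by_sample[[s]]
    for (ko in names(m)) {
      key <- paste(ko, m[ko], sep = "\r")
      pair_samples[[key]] <- c(pair_samples[[key]], s)
    }
  }
  rows <- list()
  for (key in names(pair_samples)) {
    ko_otu <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ko <- ko_otu[1]; otu <- ko_otu[2]
    if (!ko %in% rownames(abundances$values)) next
    ss <- pair_samples[[key]]
    x <- profiles$otu_rel_abundance[otu, ss]
    y <- abundances$values[ko, ss]
    ok <- x > 0 & y > 0
    if (sum(ok) < min_samples) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    rows[[key]] <- data.frame(ko = ko, otu = otu, n_samples = sum(ok),
                              r = stats::cor(x[ok], y[ok]),
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(ko = character(0), otu = character(0),
                      n_samples = integer(0), r = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold-change discrepancies between OSGs and their OTUs
#'
#' For each OTU, its samples are ordered by the OTU's relative abundance
#' and each consecutive pair of samples is compared: for every KO that is
#' an OSG of the OTU in both samples (with positive OTU and KO abundance
#' in both), the absolute log-ratio of the KO's fold-change to the OTU's
#' fold-change is recorded. Restricting to consecutive pairs avoids
#' counting the same abundance change through transitivity. A perfectly
#' tracking OSG gives discrepancy 0.
#'
#' @param profiles an [otu_profiles()].
#' @param abundances an [abundance_table()].
#' @return list with `discrepancy` (numeric vector of |log(OSG FC / OTU
#'   FC)|), `n_comparisons` and `n_skipped` (pairs skipped for zero
#'   abundance).
#' @export
osg_foldchange_ratios <- function(profiles, abundances) {
  stopifnot(inherits(profiles, "otu_profiles"),
            inherits(abundances, "abundance_table"))
  samples <- intersect(colnames(profiles$otu_rel_abundance),
                       colnames(abundances$values))
  osg_by_sample <- lapply(stats::setNames(samples, samples),
                          function(s) identify_osgs(profiles, s))
  disc <- numeric(0)
  n_skipped <- 0L
  for (otu in rownames(profiles$otu_rel_abundance)) {
    ab <- profiles$otu_rel_abundance[otu, samples]
    ss <- samples[ab > 0]
    if (length(ss) < 2) next
    ss <- ss[order(ab[ss])]
    for (i in seq_len(length(ss) - 1)) {
      s1 <- ss[i]; s2 <- ss[i + 1]
      osgs <- intersect(
        names(osg_by_sample[[s1]])[osg_by_sample[[s1]] == otu],
        names(osg_by_sample[[s2]])[osg_by_sample[[s2]] == otu])
      osgs <- intersect(osgs, rownames(abundances$values))
      if (!length(osgs)) next
      otu_fc <- profiles$otu_rel_abundance[otu, s2] /
        profiles$otu_rel_abundance[otu, s1]
      for (ko in osgs) {
        y1 <- abundances$values[ko, s1]; y2 <- abundances$values[ko, s2]
        if (y1 <= 0 || y2 <= 0) {
          n_skipped <- n_skipped + 1L
          next
        }
        disc <- c(disc, abs(log((y2 / y1) / otu_fc)))
      }
    }
  }
  list(discrepancy = disc, n_comparisons = length(disc),
       n_skipped = n_skipped)
}

#' Agreement between genomic and metagenomic correlation structure
#'
#' For each KO shared between a genome content matrix and an abundance
#' table: vector A holds its Jaccard presence/absence similarity with
#' every other KO across genomes, vector B its Pearson abundance
#' correlation with every other KO across samples (self-comparisons
#' excluded); the returned value is the Pearson correlation of A and B.
#' High values mean the metagenomic abundances recapitulate the genomic
#' co-occurrence structure.
#'
#' @param content a [genome_content()].
#' @param abundances an [abundance_table()].
#' @return named per-KO numeric vector; KOs with zero-variance A or B are
#'   skipped (dropped from the result).
#' @export
correlation_structure_similarity <- function(content, abundances) {
  stopifnot(inherits(content, "genome_content"),
            inherits(abundances, "abundance_table"))
  kos <- intersect(colnames(content$copies), rownames(abundances$values))
  if (length(kos) < 3) stop("need at least 3 shared KOs")
  P <- content$copies[, kos, drop = FALSE] >= 1
  storage.mode(P) <- "double"
  inter <- crossprod(P)
  n <- diag(inter)
  J <- inter / (outer(n, n, "+") - inter)
  V <- abundances$values[kos, , drop = FALSE]
  B <- suppressWarnings(stats::cor(t(V)))
  out <- stats::setNames(rep(NA_real_, length(kos)), kos)
  for (i in seq_along(kos)) {
    a <- J[i, -i]; b <- B[i, -i]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2) next
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) next
    out[i] <- stats::cor(a[ok], b[ok])
  }
  out[!is.na(out)]
}

#' Cross-study recovery of significant pathways
#'
#' Counts how many of a reference analysis's significant pathways are
#' re-discovered by an alternative analysis (for example, the same cases
#' with controls from another study). To avoid inflating recovery by
#' discovering many pathways, the alternative's significant set is first
#' truncated to the `|reference significant|` smallest p-values (ties at
#' the cut broken by feature id, logged).
#'
#' @param reference,alternative `differential_result` objects (see
#'   [differential_features()]) on the same feature universe.
#' @return list with `n_recovered`, `n_reference` and `recovered`
#'   (feature ids).
#' @export
cross_study_recovery <- function(reference, alternative) {
  stopifnot(inherits(reference, "differential_result"),
            inherits(alternative, "differential_result"))
  ref_sig <- reference$feature_id[reference$significant]
  alt <- alternative[alternative$significant, , drop = FALSE]
  ord <- order(alt$p_adjusted, alt$p_raw, alt$feature_id)
  k <- min(length(ref_sig), nrow(alt))
  if (nrow(alt) > length(ref_sig)) {
    cut_p <- alt$p_adjusted[ord][k]
    if (k < nrow(alt) && alt$p_adjusted[ord][k + 1] == cut_p)
      log_msg("info", "truncation tie at adjusted p = ", cut_p,
              "; broken by feature id")
  }
  alt_top <- alt$feature_id[ord][seq_len(k)]
  recovered <- intersect(ref_sig, alt_top)
  list(n_recovered = length(recovered), n_reference = length(ref_sig),
       recovered = recovered)
}
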