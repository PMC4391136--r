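#' OTU profile bundles
#'
#' Packages the 16S-side inputs used to estimate sample-specific
#' properties: per-sample OTU relative abundances, per-OTU predicted KO
#' copy numbers, per-OTU NSTI values (Nearest Sequenced Taxon Index;
#' 1-NSTI is "mappability") and per-KO gene lengths.
#'
#' @param otu_rel_abundance OTU x sample matrix; columns must sum to 1
#'   (within 1e-9).
#' @param otu_ko_copies OTU x KO matrix of predicted copy numbers.
#' @param nsti per-OTU numeric in [0, 1] (named or in OTU order).
#' @param ko_length per-KO gene length in bp (named or in KO order).
#' @return an object of class `otu_profiles`.
#' @export
otu_profiles <- function(otu_rel_abundance, otu_ko_copies, nsti,
                         ko_length) {
  if (!is.matrix(otu_rel_abundance) || !is.matrix(otu_ko_copies))
    stop("'otu_rel_abundance' and 'otu_ko_copies' must be matrices")
  otus <- rownames(otu_rel_abundance)
  if (is.null(otus) || is.null(colnames(otu_rel_abundance)))
    stop("'otu_rel_abundance' must have OTU rownames and sample colnames")
  if (!identical(rownames(otu_ko_copies), otus))
    stop("'otu_ko_copies' rows must match the OTUs of the abundance matrix")
  cs <- colSums(otu_rel_abundance)
  if (any(abs(cs - 1) > 1e-9))
    stop("OTU relative abundance column(s) do not sum to 1: ",
         paste(colnames(otu_rel_abundance)[abs(cs - 1) > 1e-9],
               collapse = ", "))
  nsti <- align_named(nsti, otus, "nsti")
  if (any(nsti < 0 | nsti > 1)) stop("NSTI values must lie in [0, 1]")
  ko_length <- align_named(ko_length, colnames(otu_ko_copies), "ko_length")
  if (any(ko_length <= 0)) stop("KO lengths must be positive")
  structure(list(otu_rel_abundance = otu_rel_abundance,
                 otu_ko_copies = otu_ko_copies, nsti = nsti,
                 ko_length = ko_length),
            class = "otu_profiles")
}

#' @export
print.otu_profiles <- function(x, ...) {
  cat(sprintf("otu_profiles: %d OTUs x %d samples, %d KOs\n",
              nrow(x$otu_rel_abundance), ncol(x$otu_rel_abundance),
              ncol(x$otu_ko_copies)))
  invisible(x)
}

#' Effective genome size of each OTU
#'
#' Sums copy number times gene length over the OTU's predicted KOs,
#' estimating the annotated genome size in bp.
#'
#' @param otu_ko_copies OTU x KO copy matrix (or a single named copy
#'   vector).
#' @param ko_length per-KO gene length in bp.
#' @return per-OTU genome size in bp (a scalar for a vector input).
#'   OTUs with no predicted genes get size 0 and are flagged in the log.
#' @export
otu_genome_size <- function(otu_ko_copies, ko_length) {
  if (!is.matrix(otu_ko_copies))
    otu_ko_copies <- matrix(otu_ko_copies, nrow = 1,
                            dimnames = list("otu",
                                            names(otu_ko_copies)))
  ko_length <- align_named(ko_length, colnames(otu_ko_copies), "ko_length")
  sizes <- as.numeric(otu_ko_copies %*% ko_length)
  names(sizes) <- rownames(otu_ko_copies)
  if (any(sizes == 0))
    log_msg("warn", sum(sizes == 0),
            " OTU(s) with zero predicted gene content (genome size 0)")
  if (length(sizes) == 1 && identical(names(sizes), "otu"))
    unname(sizes) else sizes
}

#' Abundance-weighted average genome size per sample
#'
#' Weights each OTU's estimated genome size (see [otu_genome_size()]) by
#' its relative abundance in the sample; the result is a convex
#' combination of per-OTU sizes.
#'
#' @param profiles an [otu_profiles()].
#' @return named per-sample average genome size in bp.
#' @export
average_genome_size <- function(profiles) {
  stopifnot(inherits(profiles, "otu_profiles"))
  sizes <- otu_genome_size(profiles$otu_ko_copies, profiles$ko_length)
  as.numeric(crossprod(profiles$otu_rel_abundance, sizes)) |>
    stats::setNames(colnames(profiles$otu_rel_abundance))
}

#' Species richness per sample
#'
#' Counts the OTUs whose relative abundance strictly exceeds the detection
#' threshold (default 0: any positive abundance counts).
#'
#' @param profiles an [otu_profiles()].
#' @param detection_threshold non-negative abundance threshold.
#' @return named per-sample integer OTU counts.
#' @export
species_richness <- function(profiles, detection_threshold = 0) {
  stopifnot(inherits(profiles, "otu_profiles"))
  if (detection_threshold < 0) stop("'detection_threshold' must be >= 0")
  colSums(profiles$otu_rel_abundance > detection_threshold)
}

#' Genome mappability per sample
#'
#' The abundance-weighted average of (1 - NSTI) across the OTUs of each
#' sample: 1 means every community member has an identical sequenced
#' reference, lower values mean poorer representation in the reference
#' database.
#'
#' @param profiles an [otu_profiles()].
#' @return named per-sample mappability in [0, 1].
#' @export
mappability <- function(profiles) {
  stopifnot(inherits(profiles, "otu_profiles"))
  present_na <- profiles$otu_rel_abundance > 0 & is.na(profiles$nsti)
  if (any(present_na))
    stop("missing NSTI for present OTU(s): ",
         paste(rownames(profiles$otu_rel_abundance)[
      rowSums(present_na) > 0], collapse = ", "))
  w <- profiles$otu_rel_abundance
  one_minus <- 1 - profiles$nsti
  one_minus[is.na(one_minus)] <- 0  # absent OTUs only; weight is 0
  as.numeric(crossprod(w, one_minus)) |>
    stats::setNames(colnames(w))
}

#' All three sample-specific properties at once
#'
#' @param profiles an [otu_profiles()].
#' @param detection_threshold passed to [species_richness()].
#' @return data frame with columns `sample_id`, `avg_genome_size`,
#'   `richness`, `mappability`.
#' @export
sample_properties <- function(profiles, detection_threshold = 0) {
  data.frame(sample_id = colnames(profiles$otu_rel_abundance),
             avg_genome_size = unname(average_genome_size(profiles)),
             richness = unname(species_richness(profiles,
                                                detection_threshold)),
             mappability = unname(mappability(profiles)),
             stringsAsFactors = FALSE)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the control matrix (with intercept); with no controls it
#' reduces to the ordinary Pearson correlation. The two-sided p-value uses
#' the t-distribution with `n - 2 - k` degrees of freedom, `k` the number
#' of controls.
#'
#' @param x,y numeric vectors of equal length.
#' @param controls numeric matrix of control variables (columns), or
#'   `NULL`.
#' @return list with elements `r` and `p`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  k <- if (is.null(controls)) 0L else ncol(as.matrix(controls))
  if (n < k + 3) stop("need at least ", k + 3, " observations")
  if (k > 0) {
    C <- cbind(1, as.matrix(controls))
    if (qr(C)$rank < ncol(C)) stop("rank-deficient control matrix")
    rx <- stats::lm.fit(C, x)$residuals
    ry <- stats::lm.fit(C, y)$residuals
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  if (stats::var(rx) < 1e-24 || stats::var(ry) < 1e-24) {
    warning("zero-variance residual: partial correlation defined as 0")
    return(list(r = 0, p = 1))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df))
}

#' Correlation of a probe with robust-regression residuals
#'
#' Fits `response ~ regressor` by iteratively reweighted least squares
#' with Tukey bisquare weights (tuning constant 4.685, the conventional
#' 95%-efficiency default) and correlates the residuals with a probe
#' variable, dissecting whether the probe carries signal beyond the
#' regressor.
#'
#' @param response,regressor,probe numeric vectors of equal length
#'   (n >= 4).
#' @return list with elements `r` and `p` (Pearson test on the
#'   residuals).
#' @export
residual_correlation <- function(response, regressor, probe) {
  n <- length(response)
  if (length(regressor) != n || length(probe) != n)
    stop("inputs must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (stats::var(regressor) < 1e-24) stop("constant regressor")
  fit <- MASS::rlm(response ~ regressor, psi = MASS::psi.bisquare,
                   c = 4.685, maxit = 100)
  res <- stats::residuals(fit)
  if (stats::var(res) < 1e-20 * max(1, stats::var(response))) {
    warning("residuals have (near) zero variance: correlation reported as 0")
    return(list(r = 0, p = 1))
  }
  ct <- stats::cor.test(res, probe, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
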