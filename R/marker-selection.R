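#' Genome-by-KO copy-number matrices
#'
#' Holds the gene content of a collection of annotated genomes: an integer
#' copy-number matrix with genomes as rows and KOs as columns, optionally
#' with per-genome lengths (bp) and per-KO gene lengths (bp). This is the
#' basis for marker selection, presence/absence co-occurrence analysis and
#' the mock-community simulator.
#'
#' @param copies non-negative integer-valued matrix, genomes x KOs, with
#'   dimnames.
#' @param genome_length optional per-genome length in bp (named or in row
#'   order).
#' @param ko_length optional per-KO gene length in bp (named or in column
#'   order).
#' @return an object of class `genome_content`.
#' @export
genome_content <- function(copies, genome_length = NULL, ko_length = NULL) {
  if (!is.matrix(copies) || !is.numeric(copies))
    stop("'copies' must be a numeric matrix")
  if (is.null(rownames(copies)) || is.null(colnames(copies)))
    stop("'copies' must have genome rownames and KO colnames")
  if (anyNA(copies) || any(copies < 0) ||
      any(abs(copies - round(copies)) > 1e-8))
    stop("'copies' must be non-negative integers")
  copies <- round(copies)
  if (!is.null(genome_length)) {
    genome_length <- align_named(genome_length, rownames(copies),
                                 "genome_length")
    if (any(genome_length <= 0)) stop("genome lengths must be positive")
  }
  if (!is.null(ko_length)) {
    ko_length <- align_named(ko_length, colnames(copies), "ko_length")
    if (any(ko_length <= 0)) stop("KO lengths must be positive")
  }
  structure(list(copies = copies, genome_length = genome_length,
                 ko_length = ko_length),
            class = "genome_content")
}

#' @export
print.genome_content <- function(x, ...) {
  cat(sprintf("genome_content: %d genomes x %d KOs\n",
              nrow(x$copies), ncol(x$copies)))
  invisible(x)
}

# align a possibly-named vector onto 'ids', erroring on gaps
align_named <- function(v, ids, what) {
  if (!is.null(names(v))) {
    miss <- setdiff(ids, names(v))
    if (length(miss))
      stop(what, " missing for: ", paste(utils::head(miss, 5),
                                         collapse = ", "))
    v <- v[ids]
  } else if (length(v) != length(ids)) {
    stop(what, " has length ", length(v), ", expected ", length(ids))
  } else {
    names(v) <- ids
  }
  v
}

#' Select single-copy marker genes from a genome content matrix
#'
#' A KO is selected when its prevalence (fraction of genomes carrying at
#' least one copy) falls in the band `[prevalence_min, prevalence_max)` and
#' its mean copy number, computed only over the genomes in which it is
#' present, is strictly below `mean_copy_max`. The default band
#' (0.915, none, 1.1) is the universal single-copy criterion; the band
#' (0.85, 0.915, 1.1) yields the semi-universal set, disjoint from the
#' first by construction (closed below, open above).
#'
#' @param content a [genome_content()].
#' @param prevalence_min lower prevalence bound, inclusive.
#' @param prevalence_max upper prevalence bound, exclusive, or `NULL` for
#'   no upper bound.
#' @param mean_copy_max exclusive upper bound on the presence-conditional
#'   mean copy number.
#' @param role role label for the returned [marker_set()].
#' @return a [marker_set()] in the matrix's KO order.
#' @export
select_markers <- function(content, prevalence_min = 0.915,
                           prevalence_max = NULL, mean_copy_max = 1.1,
                           role = c("usicg", "semi_usicg")) {
  stopifnot(inherits(content, "genome_content"))
  role <- match.arg(role)
  cp <- content$copies
  if (nrow(cp) == 0 || ncol(cp) == 0) stop("empty genome content matrix")
  if (prevalence_min <= 0 || prevalence_min > 1)
    stop("'prevalence_min' must be in (0, 1]")
  if (!is.null(prevalence_max) && prevalence_max <= prevalence_min)
    stop("'prevalence_max' must exceed 'prevalence_min'")
  present <- cp >= 1
  prevalence <- colMeans(present)
  n_present <- colSums(present)
  mean_copy <- ifelse(n_present > 0, colSums(cp * present) / n_present, Inf)
  ok <- prevalence >= prevalence_min & mean_copy < mean_copy_max
  if (!is.null(prevalence_max)) ok <- ok & prevalence < prevalence_max
  if (!any(ok))
    stop("no KO satisfies the marker criteria")
  marker_set(colnames(cp)[ok], role = role)
}

#' Presence/absence co-occurrence of genes across genomes
#'
#' Computes the Jaccard similarity of presence/absence patterns (copy number
#' is ignored) for all KO pairs, keeps pairs whose similarity strictly
#' exceeds `threshold`, and reports clusters as maximal cliques of size at
#' least `min_cluster_size` in the graph whose edges are those pairs.
#' Overlapping cliques are all reported. KOs absent from every genome have
#' an undefined Jaccard similarity and are excluded (a message reports how
#' many).
#'
#' @param content a [genome_content()].
#' @param threshold Jaccard similarity cut, in (0, 1]; pairs must strictly
#'   exceed it. Default 0.95.
#' @param min_cluster_size minimum clique size reported, default 5.
#' @return a list with `pairs` (data frame: `ko_a`, `ko_b`, `jaccard`) and
#'   `clusters` (list of character vectors of KO ids).
#' @export
jaccard_cooccurrence <- function(content, threshold = 0.95,
                                 min_cluster_size = 5) {
  stopifnot(inherits(content, "genome_content"))
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  if (min_cluster_size < 2) stop("'min_cluster_size' must be >= 2")
  P <- content$copies >= 1
  empty <- colSums(P) == 0
  if (any(empty)) {
    log_msg("info", sum(empty), " KO(s) absent from every genome excluded",
            " from co-occurrence analysis")
    P <- P[, !empty, drop = FALSE]
  }
  kos <- colnames(P)
  if (length(kos) < 2)
    return(list(pairs = data.frame(ko_a = character(0), ko_b = character(0),
                                   jaccard = numeric(0)),
                clusters = list()))
  storage.mode(P) <- "double"
  inter <- crossprod(P)
  n <- diag(inter)
  union <- outer(n, n, "+") - inter
  J <- inter / union
  idx <- which(upper.tri(J) & J > threshold, arr.ind = TRUE)
  pairs <- data.frame(ko_a = kos[idx[, 1]], ko_b = kos[idx[, 2]],
                      jaccard = J[idx], stringsAsFactors = FALSE)
  clusters <- list()
  if (nrow(pairs)) {
    g <- igraph::graph_from_data_frame(pairs[, 1:2], directed = FALSE)
    cl <- igraph::max_cliques(g, min = min_cluster_size)
    clusters <- lapply(cl, function(v) sort(names(v)))
  }
  list(pairs = pairs, clusters = clusters)
}
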