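#' Length-normalize a table of read counts
#'
#' Divides each KO's counts by its gene length (bp), converting read counts
#' into per-base-pair abundances. The gene length of a KO is conventionally
#' the mean length of the genes annotated to it; lengths arrive as an input
#' vector.
#'
#' @param counts an [abundance_table()] at stage `"counts"`.
#' @param ko_length named numeric vector of gene lengths in bp. Every KO
#'   with a nonzero count must have a length; KOs that are all-zero may
#'   lack one (they stay zero).
#' @return an [abundance_table()] at stage `"length_normalized"`.
#' @export
length_normalize <- function(counts, ko_length) {
  stopifnot(inherits(counts, "abundance_table"))
  if (counts$stage != "counts")
    stop("expected a table at stage 'counts', got '", counts$stage, "'")
  v <- counts$values
  if (is.null(names(ko_length))) stop("'ko_length' must be named by KO")
  nonzero <- rownames(v)[rowSums(v) > 0]
  miss <- setdiff(nonzero, names(ko_length)[is.finite(ko_length) &
                                              ko_length > 0])
  if (length(miss))
    stop("no valid gene length for KO(s) with nonzero counts: ",
         paste(utils::head(miss, 10), collapse = ", "))
  len <- ko_length[rownames(v)]
  len[is.na(len)] <- 1  # all-zero rows only; value is irrelevant
  abundance_table(v / len, stage = "length_normalized")
}

#' Compositional (relative-abundance) normalization
#'
#' Divides each sample column by its total so columns sum to 1. This is the
#' conventional normalization the package exists to improve upon: relative
#' abundances are confounded by average genome size, richness and
#' mappability of the community.
#'
#' @param table an [abundance_table()] at any stage.
#' @return an [abundance_table()] at stage `"compositional"`.
#' @export
compositional_normalize <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  cs <- colSums(v)
  if (any(cs <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(colnames(v)[cs <= 0], collapse = ", "))
  abundance_table(sweep(v, 2, cs, "/"), stage = "compositional")
}

#' Inter-MUSiCC: marker-median normalization to average copy numbers
#'
#' Divides every gene's (length-normalized) abundance in a sample by the
#' median abundance of the universal single-copy marker genes in that
#' sample. Because the markers occur once per genome in essentially every
#' genome, the result estimates the average genomic copy number of each
#' gene across the cells of the community; the marker median is exactly 1
#' in every sample by construction. The transformation is invariant to any
#' per-sample rescaling of the input, which is what removes sequencing
#' depth and compositional artifacts.
#'
#' The median is taken over *all* markers in the set, counting markers
#' undetected in the table as zeros; with 76 markers the median is robust
#' to a few dropouts. A minimum number of detected (nonzero) markers per
#' sample guards degenerate input.
#'
#' @param table an [abundance_table()], normally at stage
#'   `"length_normalized"`.
#' @param markers a [marker_set()].
#' @param min_markers_detected minimum nonzero markers required per sample
#'   (default 10).
#' @param on_low_markers `"error"` (default) or `"drop"`: what to do with
#'   samples failing the minimum; dropping logs the per-sample detected
#'   counts.
#' @return an [abundance_table()] at stage `"inter_corrected"`.
#' @export
inter_musicc <- function(table, markers, min_markers_detected = 10,
                         on_low_markers = c("error", "drop")) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(markers, "marker_set"))
  on_low_markers <- match.arg(on_low_markers)
  v <- table$values
  mk <- markers$ko_ids
  mv <- matrix(0, length(mk), ncol(v),
               dimnames = list(mk, colnames(v)))
  found <- intersect(mk, rownames(v))
  if (!length(found)) stop("none of the marker KOs occur in the table")
  mv[found, ] <- v[found, , drop = FALSE]
  detected <- colSums(mv > 0)
  low <- detected < min_markers_detected
  if (any(low)) {
    detail <- paste(sprintf("%s=%d", colnames(v)[low], detected[low]),
                    collapse = ", ")
    if (on_low_markers == "error")
      stop("sample(s) with fewer than ", min_markers_detected,
           " detected markers: ", detail)
    log_msg("warn", "dropping sample(s) with too few detected markers: ",
            detail)
    v <- v[, !low, drop = FALSE]
    mv <- mv[, !low, drop = FALSE]
  }
  med <- apply(mv, 2, stats::median)
  if (any(med <= 0))
    stop("non-positive marker median in sample(s): ",
         paste(colnames(v)[med <= 0], collapse = ", "))
  abundance_table(sweep(v, 2, med, "/"), stage = "inter_corrected")
}

#' Parameters of the closed-form effective genome size estimator
#'
#' Defaults are the published calibration `a = 21.2`, `b = 4230`,
#' `c = 0.733` with a 101 bp read length.
#'
#' @param a,b,c calibration constants; `b`, `c` must be positive.
#' @param read_length read length L in bp.
#' @return a list of class `egs_params`.
#' @export
egs_params <- function(a = 21.2, b = 4230, c = 0.733, read_length = 101) {
  if (b <= 0 || c <= 0 || read_length <= 0)
    stop("'b', 'c' and 'read_length' must be positive")
  structure(list(a = a, b = b, c = c, read_length = as.integer(read_length)),
            class = "egs_params")
}

#' Effective genome size from marker gene density
#'
#' Evaluates `EGS = (a + b * L^-c) / x`, where `x` is the per-sample marker
#' gene density (see [marker_density()]) and L the read length. The
#' estimate is strictly decreasing in `x` and, for `c > 0`, increasing
#' in L.
#'
#' @param x marker gene density (or vector of densities), must be positive.
#' @param params an [egs_params()].
#' @return effective genome size(s) in bp.
#' @export
raes_egs <- function(x, params = egs_params()) {
  stopifnot(inherits(params, "egs_params"))
  if (any(x <= 0)) stop("marker density must be positive")
  (params$a + params$b * params$read_length^(-params$c)) / x
}

#' Marker gene density of a sample
#'
#' For each read that hit a marker gene, its matched bases are divided by
#' the length of that marker gene; the sum over reads is divided by the
#' total number of bases sequenced in the sample, making the density
#' invariant to sequencing depth.
#'
#' @param hits data frame with columns `ko` (marker hit by the read, or by
#'   a group of reads) and `matched_bases` (total matched bases for that
#'   row; rows may aggregate reads hitting the same marker).
#' @param marker_lengths named numeric vector of marker gene lengths (bp).
#' @param total_bases total bases sequenced in the sample.
#' @return density `x`, a positive scalar.
#' @export
marker_density <- function(hits, marker_lengths, total_bases) {
  if (!is.data.frame(hits) || !all(c("ko", "matched_bases") %in% names(hits)))
    stop("'hits' must be a data frame with columns 'ko' and 'matched_bases'")
  hits <- hits[hits$matched_bases > 0, , drop = FALSE]
  if (!nrow(hits))
    stop("no marker hits: density is zero and EGS undefined")
  miss <- setdiff(unique(hits$ko), names(marker_lengths))
  if (length(miss))
    stop("no length for hit marker(s): ", paste(miss, collapse = ", "))
  if (total_bases <= 0) stop("'total_bases' must be positive")
  sum(hits$matched_bases / marker_lengths[hits$ko]) / total_bases
}

#' Aggregate marker hits from a simulated sample's KO counts
#'
#' Builds the `hits` data frame expected by [marker_density()] from a
#' per-KO read-count vector, treating every read as matching over its full
#' length.
#'
#' @param ko_counts named per-KO read counts.
#' @param markers a [marker_set()].
#' @param read_length read length in bp.
#' @return data frame with columns `ko`, `matched_bases`.
#' @export
marker_hits_from_counts <- function(ko_counts, markers, read_length) {
  stopifnot(inherits(markers, "marker_set"))
  mk <- intersect(markers$ko_ids, names(ko_counts))
  cnt <- ko_counts[mk]
  cnt <- cnt[cnt > 0]
  data.frame(ko = names(cnt), matched_bases = as.numeric(cnt) * read_length,
             stringsAsFactors = FALSE)
}

#' Parameters for marker-based average genome size normalization
#'
#' The alternative scheme estimates, from each of a small panel of
#' universal genes, a per-sample average genome size
#' `G = (g + L - 2m) / f`, with `g` the marker's gene length, L the read
#' length, `m` a minimum alignment overlap, and `f` the marker's relative
#' abundance; the panel's estimates are averaged. The panel of eight
#' universal genes is a configurable input with no packaged default.
#'
#' @param marker_ko_ids character vector of panel KO ids.
#' @param marker_lengths named gene lengths `g` in bp for the panel.
#' @param read_length L in bp (default 75).
#' @param min_overlap m in bp (default 90).
#' @return a list of class `marker_egs_params`.
#' @export
marker_egs_params <- function(marker_ko_ids, marker_lengths,
                              read_length = 75, min_overlap = 90) {
  if (read_length <= 0) stop("'read_length' must be positive")
  if (min_overlap < 0) stop("'min_overlap' must be non-negative")
  marker_lengths <- align_named(marker_lengths, marker_ko_ids,
                                "marker_lengths")
  structure(list(marker_ko_ids = as.character(marker_ko_ids),
                 marker_lengths = marker_lengths,
                 read_length = read_length, min_overlap = min_overlap),
            class = "marker_egs_params")
}

#' Normalize relative abundances by marker-estimated average genome size
#'
#' Per sample, estimates `G_i = (g_i + L - 2m) / f_i` from each panel
#' marker with positive relative abundance `f_i` (markers with `f = 0` are
#' skipped and logged; at least one is required), averages the estimates to
#' an effective genome size, and multiplies the sample's relative
#' abundances by it.
#'
#' @param table an [abundance_table()] at stage `"compositional"`.
#' @param params a [marker_egs_params()].
#' @return an [abundance_table()] at stage `"inter_corrected"` (the values
#'   are genome-size scaled abundances comparable across samples).
#' @export
marker_egs_normalize <- function(table, params) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(params, "marker_egs_params"))
  if (table$stage != "compositional")
    stop("expected a table at stage 'compositional', got '",
         table$stage, "'")
  v <- table$values
  mk <- params$marker_ko_ids
  f <- matrix(0, length(mk), ncol(v), dimnames = list(mk, colnames(v)))
  found <- intersect(mk, rownames(v))
  f[found, ] <- v[found, , drop = FALSE]
  numer <- params$marker_lengths + params$read_length -
    2 * params$min_overlap
  egs <- vapply(seq_len(ncol(v)), function(s) {
    fs <- f[, s]
    use <- fs > 0
    if (!any(use))
      stop("all panel markers absent in sample '", colnames(v)[s], "'")
    if (any(!use))
      log_msg("info", sum(!use), " panel marker(s) absent in sample '",
              colnames(v)[s], "' skipped")
    mean(numer[use] / fs[use])
  }, numeric(1))
  abundance_table(sweep(v, 2, egs, "*"), stage = "inter_corrected")
}
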