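#' KO-by-sample abundance tables
#'
#' An `abundance_table` is the central container of the package: a numeric
#' matrix of non-negative values with KEGG Orthology (KO) identifiers as rows
#' and sample identifiers as columns, plus a `stage` tag recording where the
#' table sits in the normalization pipeline.
#'
#' Stages are: `counts` (raw read counts), `length_normalized` (counts divided
#' by gene length), `compositional` (columns sum to 1), `inter_corrected`
#' (average genomic copy numbers after marker-median normalization) and
#' `intra_corrected` (after gene-property bias correction).
#'
#' @param values numeric matrix, KOs as rows (rownames required), samples as
#'   columns (colnames required). All values must be finite and non-negative;
#'   absences are explicit zeros.
#' @param stage one of `"counts"`, `"length_normalized"`, `"compositional"`,
#'   `"inter_corrected"`, `"intra_corrected"`.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, stage = "counts") {
  stage <- match.arg(stage, musicc_stages())
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must have KO rownames and sample colnames")
  obj <- structure(list(values = values, stage = stage),
                   class = "abundance_table")
  validate_abundance_table(obj)
  obj
}

musicc_stages <- function() {
  c("counts", "length_normalized", "compositional",
    "inter_corrected", "intra_corrected")
}

validate_abundance_table <- function(x) {
  v <- x$values
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at KO '%s', sample '%s'",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]))
  }
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at KO '%s', sample '%s'",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]))
  }
  if (anyDuplicated(rownames(v)))
    stop("duplicate KO identifier: '",
         rownames(v)[duplicated(rownames(v))][1], "'")
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample identifier: '",
         colnames(v)[duplicated(colnames(v))][1], "'")
  if (x$stage == "compositional" && ncol(v) > 0) {
    cs <- colSums(v)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off))
      stop("compositional table has column(s) not summing to 1: ",
           paste(colnames(v)[off], collapse = ", "))
  }
  invisible(x)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d KOs x %d samples [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' @rdname abundance_table
#' @param x an `abundance_table`.
#' @export
ko_ids <- function(x) rownames(x$values)

#' @rdname abundance_table
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a KO abundance table from a tab-delimited file
#'
#' First column holds KO identifiers, header row holds sample identifiers.
#' Comment lines start with `#`; a `#stage=<tag>` line, as written by
#' [write_abundance_table()], sets the stage unless `stage` is given
#' explicitly. Malformed input (duplicate identifiers, negative or
#' non-numeric cells) is rejected with the offending row/column named,
#' never silently coerced.
#'
#' @param path file path.
#' @param stage stage tag; overrides any `#stage=` line. If neither is
#'   present, `"counts"` is assumed.
#' @param transpose if `TRUE` the file has samples as rows and KOs as columns
#'   and is transposed on read.
#' @param empty_as_zero if `TRUE`, empty cells are read as zeros (a warning
#'   reports how many); otherwise they are an error.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, stage = NULL, transpose = FALSE,
                                 empty_as_zero = FALSE) {
  lines <- read_text_lines(path)
  file_stage <- NULL
  is_comment <- startsWith(lines, "#")
  st <- lines[startsWith(lines, "#stage=")]
  if (length(st)) file_stage <- sub("^#stage=", "", st[1])
  lines <- lines[!is_comment]
  if (!length(lines)) stop("no data in '", path, "'")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1) stop("malformed header in '", path, "'")
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifier in header: '",
         samples[duplicated(samples)][1], "'")
  body <- lines[-1]
  ids <- character(length(body))
  vals <- if (length(body))
    matrix(NA_real_, length(body), length(samples)) else
    matrix(numeric(0), 0, length(samples))
  n_empty <- 0L
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad back
    if (length(f) < length(samples) + 1)
      f <- c(f, rep("", length(samples) + 1 - length(f)))
    if (length(f) != length(samples) + 1)
      stop(sprintf("row %d ('%s') has %d fields, expected %d",
                   i, f[1], length(f), length(samples) + 1))
    ids[i] <- f[1]
    cells <- f[-1]
    empty <- !nzchar(trimws(cells))
    if (any(empty)) {
      if (!empty_as_zero)
        stop(sprintf("empty cell at row '%s', column '%s'",
                     f[1], samples[which(empty)[1]]))
      n_empty <- n_empty + sum(empty)
      cells[empty] <- "0"
    }
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num))
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                   cells[which(is.na(num))[1]], f[1],
                   samples[which(is.na(num))[1]]))
    vals[i, ] <- num
  }
  if (n_empty > 0)
    warning(n_empty, " empty cell(s) read as zero")
  if (anyDuplicated(ids))
    stop("duplicate KO identifier: '", ids[duplicated(ids)][1], "'")
  rownames(vals) <- ids
  colnames(vals) <- samples
  if (transpose) vals <- t(vals)
  stage <- stage %||% file_stage %||% "counts"
  abundance_table(vals, stage = stage)
}

#' Write a KO abundance table to a tab-delimited file
#'
#' The stage tag is preserved in a `#stage=` sidecar line; values are
#' serialized with 15 significant digits so a read/write round trip is the
#' identity to well below 1e-10.
#'
#' @param table an [abundance_table()].
#' @param path output file path.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#stage=", table$stage), con)
  writeLines(paste(c("KO", colnames(v)), collapse = "\t"), con)
  if (nrow(v)) {
    body <- vapply(seq_len(nrow(v)), function(i)
      paste(c(rownames(v)[i],
              formatC(v[i, ], digits = 15, format = "g")),
            collapse = "\t"), character(1))
    writeLines(body, con)
  }
  invisible(NULL)
}

#' Marker gene sets
#'
#' A `marker_set` is an ordered, duplicate-free list of KO identifiers with a
#' role label: `"usicg"` for universal single-copy genes (the normalization
#' yardstick) or `"semi_usicg"` for the relaxed prevalence band.
#'
#' @param ko_ids character vector of KO identifiers.
#' @param role `"usicg"` or `"semi_usicg"`.
#' @export
marker_set <- function(ko_ids, role = c("usicg", "semi_usicg")) {
  role <- match.arg(role)
  ko_ids <- as.character(ko_ids)
  if (!length(ko_ids)) stop("marker set must be non-empty")
  if (anyDuplicated(ko_ids))
    stop("duplicate marker id: '", ko_ids[duplicated(ko_ids)][1], "'")
  if (any(!nzchar(ko_ids))) stop("empty marker id")
  structure(list(ko_ids = ko_ids, role = role), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d KOs [role: %s]\n", length(x$ko_ids), x$role))
  invisible(x)
}

#' @export
length.marker_set <- function(x) length(x$ko_ids)

#' Read a marker-gene list (one KO id per line)
#'
#' Comment lines starting with `#` and blank lines are skipped; duplicated
#' identifiers are collapsed to their first occurrence, preserving order.
#'
#' @param path file path.
#' @param role role tag, see [marker_set()].
#' @return a [marker_set()].
#' @export
read_marker_set <- function(path, role = c("usicg", "semi_usicg")) {
  role <- match.arg(role)
  lines <- trimws(read_text_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty marker file: '", path, "'")
  marker_set(unique(lines), role = role)
}

#' Packaged marker lists
#'
#' Returns the marker set shipped with the package. These are synthetic
#' stand-in identifier lists with the canonical cardinalities of the curated
#' sets (76 universal single-copy genes, 72 semi-universal); on real KEGG
#' annotated data users should supply their own curated lists via
#' [read_marker_set()] or derive them from a genome content matrix with
#' [select_markers()].
#'
#' @param role `"usicg"` (76 ids) or `"semi_usicg"` (72 ids).
#' @return a [marker_set()].
#' @export
musicc_markers <- function(role = c("usicg", "semi_usicg")) {
  role <- match.arg(role)
  fn <- if (role == "usicg") "usicg_synthetic.txt" else
    "semi_usicg_synthetic.txt"
  read_marker_set(system.file("extdata", fn, package = "musiccr",
                              mustWork = TRUE), role = role)
}

#' Read a BIOM-format feature table as an abundance table
#'
#' Thin adapter over the `biomformat` package for JSON BIOM files; rows are
#' taken as KOs, columns as samples.
#'
#' @param path path to a JSON BIOM file.
#' @param stage stage tag for the resulting table.
#' @return an [abundance_table()].
#' @export
read_biom_abundance <- function(path, stage = "counts") {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the 'biomformat' package is required for BIOM input")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  abundance_table(m, stage = stage)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  sub("\r$", "", lines)  # accept Windows newlines
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimal timestamped logger
#'
#' Messages at or above `getOption("musiccr.log_level")` (default
#' `"info"`; levels `debug` < `info` < `warn`) are written to `stderr`.
#' @param level message level.
#' @param ... message parts, pasted together.
#' @keywords internal
log_msg <- function(level = "info", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  threshold <- getOption("musiccr.log_level", "info")
  if (levels[[level]] < levels[[threshold]]) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(...)))
  invisible(NULL)
}
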