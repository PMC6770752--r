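#' Construct an expression matrix object
#'
#' A light container for a features-by-samples expression matrix (typically
#' RMA-normalised log2 microarray intensities). Feature and sample
#' identifiers live in the dimnames and must be unique; all values must be
#' finite.
#'
#' @param values Numeric matrix, rows = features, columns = samples, with
#'   complete dimnames.
#' @param feature_kind Either `"probe"` or `"gene"`, recording whether rows
#'   are array probes or collapsed gene symbols.
#' @return An object of class `expression_matrix` with elements `values`
#'   (the matrix) and `feature_kind`.
#' @export
expression_matrix <- function(values, feature_kind = c("probe", "gene")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))])[1:min(3, sum(duplicated(rownames(values))))],
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  structure(list(values = values, feature_kind = feature_kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d %ss x %d samples\n",
              nrow(x$values), x$feature_kind, ncol(x$values)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from TSV or GEO series-matrix text
#'
#' The TSV dialect is a header row of sample ids (with or without a leading
#' id-column name) and a first column of feature ids. The GEO dialect parses
#' only the block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`; all other metadata lines are ignored.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"geo_series_matrix"`.
#' @param feature_kind What the rows are; defaults to `"probe"` (microarray
#'   input). Use `"gene"` when reading an already-collapsed matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "geo_series_matrix"),
                            feature_kind = c("probe", "gene")) {
  format <- match.arg(format)
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
      stop("series-matrix table markers missing or malformed in ", path)
    offset <- begin  # line number of the row before the header
    lines <- lines[(begin + 1L):(end - 1L)]
  } else {
    offset <- 0L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) gsub('^"|"$', "", f))
  header <- fields[[1]]
  body <- fields[-1]
  widths <- lengths(body)
  n_col <- widths[1]
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                 offset + 1L + bad, path, widths[bad], n_col))
  }
  if (length(header) == n_col) {
    samples <- header[-1]
  } else if (length(header) == n_col - 1L) {
    samples <- header  # R-style header without an id-column name
  } else {
    stop(sprintf("malformed header at line %d of %s: %d fields for rows of %d",
                 offset + 1L, path, length(header), n_col))
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))[1]
    stop(sprintf("duplicate feature id '%s' at line %d of %s",
                 ids[bad], offset + 1L + bad, path))
  }
  if (anyDuplicated(samples))
    stop("duplicate sample ids in header of ", path)
  num <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L,
                dimnames = list(ids, samples))
  for (k in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[k]][-1]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell at line %d of %s",
                   offset + 1L + k, path))
    num[k, ] <- v
  }
  expression_matrix(num, feature_kind)
}

#' Write an expression matrix as TSV
#'
#' Values are printed with `%.17g` so a read/write round trip reproduces
#' them exactly.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param id_column Name for the leading feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path, id_column = "feature_id") {
  v <- expr$values
  body <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  lines <- c(paste(c(id_column, colnames(v)), collapse = "\t"),
             paste(rownames(v), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene-symbol mapping table
#'
#' Two-column TSV (`probe_id`, `gene_symbol`); an empty symbol marks an
#' unmapped probe and is preserved as `""`.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   check.names = FALSE, na.strings = NULL)
  if (!all(c("probe_id", "gene_symbol") %in% names(df)))
    stop("probe map must have columns probe_id, gene_symbol: ", path)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id in ", path)
  df[c("probe_id", "gene_symbol")]
}

#' Read a sample annotation table
#'
#' TSV with columns `sample_id` and `fusion_group`; groups must be one of
#' `negative`, `PAX3`, `PAX7` (the fusion status/type labels).
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `sample_id`, `fusion_group`.
#' @export
read_sample_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   check.names = FALSE)
  if (!all(c("sample_id", "fusion_group") %in% names(df)))
    stop("annotation must have columns sample_id, fusion_group: ", path)
  bad <- setdiff(unique(df$fusion_group), c("negative", "PAX3", "PAX7"))
  if (length(bad))
    stop("unknown fusion_group value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path)
  df[c("sample_id", "fusion_group")]
}

# Check that every sample of `expr` has exactly one annotation row.
check_annotation <- function(expr, ann) {
  missing <- setdiff(sample_ids(expr), ann$sample_id)
  if (length(missing))
    stop("samples without annotation: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
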