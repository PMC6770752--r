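#' Collapse probe-level expression to gene level
#'
#' Probes without a gene symbol (empty string in the map, or absent from the
#' map altogether) are removed; the number dropped is reported via
#' `message()`. For each gene the collapsed value is, per sample, the
#' maximum over that gene's probes (`"max-elementwise"`). The alternative
#' `"max-mean-probe"` keeps the single probe with the highest mean
#' expression across samples (ties broken by lexicographically smallest
#' probe id). Output genes are sorted lexicographically.
#'
#' @param expr A probe-level [expression_matrix()].
#' @param map data.frame as returned by [read_probe_map()].
#' @param collapse Collapse rule, see above.
#' @return A gene-level [expression_matrix()].
#' @export
collapse_probes <- function(expr, map,
                            collapse = c("max-elementwise", "max-mean-probe")) {
  collapse <- match.arg(collapse)
  if (expr$feature_kind != "probe")
    stop("collapse_probes expects a probe-level matrix")
  sym <- setNames(map$gene_symbol, map$probe_id)[feature_ids(expr)]
  unmapped <- is.na(sym) | !nzchar(sym)
  if (any(unmapped))
    message(sum(unmapped), " unmapped probe(s) dropped")
  v <- expr$values[!unmapped, , drop = FALSE]
  sym <- as.character(sym[!unmapped])
  if (!nrow(v)) stop("no mapped probes left after dropping unmapped probes")
  genes <- lex_sort(unique(sym))
  idx <- split(seq_len(nrow(v)), factor(sym, levels = genes))
  if (collapse == "max-elementwise") {
    out <- t(vapply(idx, function(i) {
      if (length(i) == 1L) v[i, ] else apply(v[i, , drop = FALSE], 2, max)
    }, numeric(ncol(v))))
  } else {
    pick <- vapply(idx, function(i) {
      m <- rowMeans(v[i, , drop = FALSE])
      cand <- i[m == max(m)]
      cand[lex_order(rownames(v)[cand])[1]]
    }, integer(1))
    out <- v[pick, , drop = FALSE]
  }
  dimnames(out) <- list(genes, colnames(v))
  expression_matrix(out, "gene")
}

#' Remove the lowest-variance features
#'
#' Per-feature sample variance (denominator n - 1) is computed across
#' samples and exactly `floor(n_features * drop_fraction)` features of
#' lowest variance are removed. Ties are broken by lexicographic feature id
#' so the filter is deterministic; zero-variance features always rank
#' lowest. Survivors keep their input order.
#'
#' @param expr An [expression_matrix()] with at least two samples.
#' @param drop_fraction Fraction in `[0, 1)` of features to drop; the
#'   default removes the bottom third, the usual noise filter ahead of
#'   co-expression mining.
#' @return The filtered [expression_matrix()].
#' @export
variance_filter <- function(expr, drop_fraction = 1 / 3) {
  if (!is.numeric(drop_fraction) || length(drop_fraction) != 1L ||
      drop_fraction < 0 || drop_fraction >= 1)
    stop("`drop_fraction` must be in [0, 1)")
  v <- expr$values
  if (ncol(v) < 2L) stop("variance filter needs at least 2 samples")
  n_drop <- floor(nrow(v) * drop_fraction)
  if (n_drop == 0L) return(expr)
  vars <- rowSums((v - rowMeans(v))^2) / (ncol(v) - 1L)
  drop <- lex_order(vars, rownames(v))[seq_len(n_drop)]
  expression_matrix(v[-drop, , drop = FALSE], expr$feature_kind)
}
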