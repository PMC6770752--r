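#' Disjoint (Venn) region decomposition of module memberships
#'
#' Every gene in the union of the named modules is assigned to exactly one
#' region labelled by the subset of modules containing it (ids joined with
#' `&`), so region counts sum to the union size.
#'
#' @param modules A `module_set`.
#' @param ids 2 to 6 module ids to decompose.
#' @return data.frame with columns `region`, `n_modules` (how many modules
#'   the region belongs to), `count`, and `genes` (comma-separated,
#'   lexicographically sorted). Regions are ordered by `n_modules` then
#'   region label.
#' @export
module_overlap <- function(modules, ids) {
  if (length(ids) < 2L || length(ids) > 6L)
    stop("module_overlap supports 2-6 modules")
  missing <- setdiff(ids, names(modules$modules))
  if (length(missing))
    stop("unknown module id(s): ", paste(missing, collapse = ", "))
  sets <- modules$modules[ids]
  genes <- lex_sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) member <- matrix(member, nrow = 1,
                                            dimnames = list(NULL, ids))
  region <- apply(member, 1, function(r) paste(ids[r], collapse = "&"))
  split_genes <- split(genes, region)
  labs <- names(split_genes)
  nmod <- lengths(regmatches(labs, gregexpr("&", labs))) + 1L
  out <- data.frame(region = labs, n_modules = nmod,
                    count = lengths(split_genes),
                    genes = vapply(split_genes, paste, character(1),
                                   collapse = ","))
  out <- out[lex_order(out$n_modules, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes shared by at least k of the named modules
#'
#' @param modules A `module_set`.
#' @param ids Module ids to consider.
#' @param k Minimum number of modules a gene must belong to (>= 2).
#' @return Lexicographically sorted character vector (possibly empty).
#' @export
genes_in_k_modules <- function(modules, ids, k) {
  if (k < 2) stop("k must be >= 2")
  missing <- setdiff(ids, names(modules$modules))
  if (length(missing))
    stop("unknown module id(s): ", paste(missing, collapse = ", "))
  tab <- table(unlist(lapply(modules$modules[ids], unique)))
  lex_sort(names(tab)[tab >= k])
}

#' Fisher exact test of overlap between two gene sets
#'
#' Tests the 2x2 table (in/out of `query`) x (in/out of `target`) over
#' `universe`. The p-value is the exact two-sided Fisher probability (sum
#' of hypergeometric point probabilities at most that of the observed
#' table); one-sided enrichment is available via `alternative`. The odds
#' ratio is the sample odds ratio, with the Haldane 0.5 correction applied
#' to all cells when any cell is zero.
#'
#' @param query,target Character vectors, both subsets of `universe`.
#' @param universe Background gene set (non-empty).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param set_id Optional label carried into the result.
#' @return One-row data.frame: `set_id`, `overlap_count`, `set_size`,
#'   `query_size`, `universe_size`, `odds_ratio`, `p_value`.
#' @export
fisher_overlap <- function(query, target, universe,
                           alternative = c("two.sided", "greater"),
                           set_id = NA_character_) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  target <- unique(as.character(target))
  if (length(setdiff(query, universe)))
    stop("query genes outside the universe")
  if (length(setdiff(target, universe)))
    stop("target genes outside the universe")
  a <- length(intersect(query, target))
  b <- length(query) - a
  c_ <- length(target) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2)
  p <- fisher.test(tab, alternative = alternative)$p.value
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  data.frame(set_id = set_id, overlap_count = a, set_size = length(target),
             query_size = length(query), universe_size = length(universe),
             odds_ratio = or, p_value = min(p, 1))
}

#' Over-representation scan of a query against a gene-set collection
#'
#' Each collection set is restricted to the universe (sets with no
#' universe member are skipped with a warning), tested with
#' [fisher_overlap()], and Benjamini-Hochberg q-values are computed across
#' the tested sets.
#'
#' @param query Character vector of genes (subset of `universe`).
#' @param collections Named list of gene sets, e.g. from [read_gmt()].
#' @param universe Background gene set; conventionally the post-filter
#'   gene list that entered module mining.
#' @param alpha_fdr FDR threshold for the `significant` flag.
#' @param alternative Passed to [fisher_overlap()].
#' @return data.frame of [fisher_overlap()] rows plus `q_value` and
#'   `significant`, sorted by p-value (ties by set id).
#' @export
overrepresentation_scan <- function(query, collections, universe,
                                    alpha_fdr = 0.05,
                                    alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(collections)) stop("empty gene-set collection")
  if (is.null(names(collections)) || any(!nzchar(names(collections))))
    stop("collections must be a named list")
  universe <- unique(as.character(universe))
  trimmed <- lapply(collections, function(s) intersect(s, universe))
  empty <- lengths(trimmed) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) with no universe members skipped")
    trimmed <- trimmed[!empty]
  }
  if (!length(trimmed)) return(data.frame())
  rows <- lapply(names(trimmed), function(nm)
    fisher_overlap(query, trimmed[[nm]], universe,
                   alternative = alternative, set_id = nm))
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < alpha_fdr
  out <- out[lex_order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors, with set descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields in %s", short[1], path))
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) stop("duplicate set names in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  attr(sets, "descriptions") <- setNames(
    vapply(fields, `[[`, character(1), 2L), nms)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
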