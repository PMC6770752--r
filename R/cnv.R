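# Chromosome name normalisation shared by SEG and BED readers: optional
# "chr" prefix stripped case-insensitively, remainder upper-cased, so
# "chr1", "Chr1" and "1" collapse to one key and "x" matches "X".
normalize_chrom <- function(x) toupper(sub("^chr", "", x, ignore.case = TRUE))

#' Read a segmented copy-number (SEG) table
#'
#' Standard SEG columns: sample, chromosome, loc.start, loc.end, seg.mean
#' (a `num.mark` column is tolerated and ignored). Coordinates are 1-based
#' inclusive per the SEG convention. Segments of one sample must not
#' overlap within a chromosome; violations are rejected with the offending
#' line number, as are `start > end` and non-numeric means.
#'
#' @param path Path to the SEG file.
#' @return data.frame of class `segment_table` with columns `sample_id`,
#'   `chrom` (normalised), `start`, `end`, `log2_ratio`.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  nm <- tolower(names(df))
  pick <- function(cands, pos) {
    hit <- which(nm %in% cands)
    if (length(hit)) hit[1] else pos
  }
  i_samp <- pick(c("sample", "id", "sample_id"), 1L)
  i_chrom <- pick(c("chrom", "chromosome", "chr"), 2L)
  i_start <- pick(c("loc.start", "start", "loc_start"), 3L)
  i_end <- pick(c("loc.end", "end", "loc_end"), 4L)
  i_mean <- pick(c("seg.mean", "seg_mean", "mean", "log2_ratio"),
                 ncol(df))
  line_no <- seq_len(nrow(df)) + 1L
  start <- suppressWarnings(as.numeric(df[[i_start]]))
  end <- suppressWarnings(as.numeric(df[[i_end]]))
  mean_ <- suppressWarnings(as.numeric(df[[i_mean]]))
  for (col in list(list(start, "start"), list(end, "end"),
                   list(mean_, "seg.mean"))) {
    if (anyNA(col[[1]]))
      stop(sprintf("non-numeric %s at line %d of %s", col[[2]],
                   line_no[which(is.na(col[[1]]))[1]], path))
  }
  bad <- which(start > end)
  if (length(bad))
    stop(sprintf("start > end at line %d of %s", line_no[bad[1]], path))
  out <- data.frame(sample_id = df[[i_samp]],
                    chrom = normalize_chrom(df[[i_chrom]]),
                    start = start, end = end, log2_ratio = mean_)
  for (key in unique(paste(out$sample_id, out$chrom, sep = "\r"))) {
    rows <- which(paste(out$sample_id, out$chrom, sep = "\r") == key)
    o <- rows[order(out$start[rows])]
    if (length(o) > 1L) {
      ov <- which(out$end[o[-length(o)]] >= out$start[o[-1]])
      if (length(ov))
        stop(sprintf("overlapping segments for sample %s chrom %s (line %d)",
                     out$sample_id[o[1]], out$chrom[o[1]],
                     line_no[o[ov[1] + 1L]]))
    }
  }
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Write a segment table in SEG format
#'
#' @param segs A `segment_table` (or equivalent data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segs, path) {
  df <- data.frame(sample = segs$sample_id, chrom = segs$chrom,
                   loc.start = format(segs$start, scientific = FALSE,
                                      trim = TRUE),
                   loc.end = format(segs$end, scientific = FALSE,
                                    trim = TRUE),
                   seg.mean = sprintf("%.17g", segs$log2_ratio))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation in BED format
#'
#' Columns: chrom, start, end (0-based half-open per BED), gene symbol
#' (name), and optionally a cytoband label in column 5. Gene symbols must
#' be unique and intervals non-degenerate (`start < end`).
#'
#' @param path Path to the BED file.
#' @return data.frame of class `gene_annotation` with columns
#'   `gene_symbol`, `chrom` (normalised), `start`, `end`, `cytoband`.
#' @export
read_gene_bed <- function(path) {
  df <- read.delim(path, header = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 4L) stop("BED gene annotation needs >= 4 columns: ", path)
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinates in ", path)
  if (any(start >= end))
    stop(sprintf("degenerate interval at line %d of %s",
                 which(start >= end)[1], path))
  if (anyDuplicated(df[[4]]))
    stop("duplicate gene symbols in ", path)
  data.frame(gene_symbol = df[[4]], chrom = normalize_chrom(df[[1]]),
             start = start, end = end,
             cytoband = if (ncol(df) >= 5L) df[[5]] else NA_character_)
}

#' Gene-level copy-number values and calls from segments
#'
#' For every gene x sample pair, the value is the overlap-length-weighted
#' mean of the log2 ratios of all segments intersecting the gene (so a
#' gene fully inside one segment inherits its mean exactly). BED gene
#' coordinates (0-based half-open) are converted to the SEG convention
#' (1-based inclusive) before intersection; overlap length for gene
#' [gs, ge] and segment [ss, se] (both 1-based inclusive) is
#' `min(ge, se) - max(gs, ss) + 1`. Genes intersecting no segment get
#' value 0 and `uncovered = TRUE`. Calls use the symmetric threshold:
#' amplification at `value >= threshold`, deletion at
#' `value <= -threshold`, otherwise neutral.
#'
#' @param segs A `segment_table` from [read_seg()].
#' @param genes A gene annotation from [read_gene_bed()].
#' @param threshold Log2-ratio call threshold (default 0.2).
#' @return data.frame of class `gene_cnv_table`: `gene_symbol`,
#'   `sample_id`, `value`, `call` (amplification/deletion/neutral),
#'   `uncovered`; one row per gene x sample.
#' @export
gene_level_cnv <- function(segs, genes, threshold = 0.2) {
  samples <- unique(segs$sample_id)
  g_start <- genes$start + 1L  # BED 0-based half-open -> 1-based inclusive
  g_end <- genes$end
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- segs[segs$sample_id == samples[si], , drop = FALSE]
    value <- numeric(nrow(genes))
    covered <- logical(nrow(genes))
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      sj <- which(s$chrom == ch)
      if (!length(gi)) next
      if (!length(sj)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(g_start[gi], g_end[gi]),
        IRanges::IRanges(s$start[sj], s$end[sj]))
      if (!length(hits)) next
      qi <- gi[S4Vectors::queryHits(hits)]
      sk <- sj[S4Vectors::subjectHits(hits)]
      len <- pmin(g_end[qi], s$end[sk]) - pmax(g_start[qi], s$start[sk]) + 1
      wsum <- tapply(len * s$log2_ratio[sk], qi, sum)
      lsum <- tapply(len, qi, sum)
      idx <- as.integer(names(wsum))
      value[idx] <- wsum / lsum
      covered[idx] <- TRUE
    }
    call <- ifelse(value >= threshold, "amplification",
                   ifelse(value <= -threshold, "deletion", "neutral"))
    out[[si]] <- data.frame(gene_symbol = genes$gene_symbol,
                            sample_id = samples[si], value = value,
                            call = call, uncovered = !covered)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gene_cnv_table", "data.frame")
  res
}

#' Genes carrying a copy-number aberration
#'
#' @param cnv A `gene_cnv_table`.
#' @param samples Optional subset of sample ids to consider.
#' @return Lexicographically sorted gene symbols with a non-neutral call
#'   in at least one (considered) sample.
#' @export
cnv_genes <- function(cnv, samples = NULL) {
  if (!is.null(samples)) cnv <- cnv[cnv$sample_id %in% samples, , drop = FALSE]
  lex_sort(unique(cnv$gene_symbol[cnv$call != "neutral"]))
}

#' Fisher overlap of modules with copy-number-variant genes
#'
#' For each module, the member genes are tested for over-representation of
#' genes with any non-neutral call (in any considered sample) against the
#' universe, via [fisher_overlap()].
#'
#' @param cnv A `gene_cnv_table`.
#' @param modules A `module_set`.
#' @param universe Background gene set; conventionally the post-filter
#'   gene list that entered mining.
#' @param samples Optional subset of CNV sample ids.
#' @param alternative Passed to [fisher_overlap()].
#' @return data.frame with `module_id`, `module_size`, `cnv_overlap`,
#'   `odds_ratio`, `p_value`, one row per module, in module order.
#' @export
cnv_module_overlap <- function(cnv, modules, universe, samples = NULL,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  hit <- intersect(cnv_genes(cnv, samples), universe)
  rows <- lapply(names(modules$modules), function(id) {
    mg <- intersect(modules$modules[[id]], universe)
    fr <- fisher_overlap(mg, hit, universe, alternative = alternative,
                         set_id = id)
    data.frame(module_id = id, module_size = length(mg),
               cnv_overlap = fr$overlap_count, odds_ratio = fr$odds_ratio,
               p_value = fr$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
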