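# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards, so generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic co-expression study
#'
#' Describes a latent-factor expression model emulating the shape of a
#' two-to-three-group microarray study of fusion-positive vs
#' fusion-negative tumours. Each planted module m has one latent factor
#' per sample, `f_ms ~ N(mu_group, 1)` with `mu_group = delta_m` in the
#' fusion-positive groups (scaled per group via `delta_pax7` if desired)
#' and 0 in the negative group; member genes follow
#' `x_gs = baseline_g + loading * f_ms + N(0, noise_sd^2)`; background
#' genes are baseline plus `N(0, background_sd^2)` noise.
#'
#' The defaults are the study conditions used throughout the test suite:
#' 25/26/7 samples (negative/PAX3/PAX7), 2,000 genes, 8 disjoint planted
#' modules of sizes 200/150/100/60/40/25/15/10, loading 0.9, noise sd 0.3,
#' latent shifts (+1.5, -1.5, +1.5, -1.5, +1.5, -1.5, +1.5, 0) so seven
#' modules respond to fusion status (four up, three down) and one is a
#' null control. Copy-number events are planted at 40% of the second
#' module's genes against a 5% background rate.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Named integer vector: samples per group `negative`,
#'   `PAX3`, `PAX7` (a group may be 0).
#' @param module_sizes Planted module sizes (disjoint gene blocks).
#' @param loading Factor loading `a` in (0, 1] shared by all modules.
#' @param noise_sd Residual sd for module genes.
#' @param background_sd Noise sd for background (non-module) genes.
#' @param delta Per-module latent mean shift of the fusion-positive groups
#'   relative to negative, in latent-factor sd units.
#' @param delta_pax7 Optional per-module shift for PAX7 samples; defaults
#'   to `delta` (both positive subtypes shifted alike).
#' @param baseline_range Range of per-gene baseline intensities (log2
#'   scale, drawn uniformly), mimicking RMA-normalised arrays.
#' @param probe_counts,probe_probs Distribution of probes per gene used by
#'   [simulate_probes()].
#' @param unmapped_fraction Fraction of probes without a gene symbol
#'   (emitted as decoy probes so collapsing keeps every gene).
#' @param cnv_background_rate Probability a background gene carries a
#'   planted copy-number event.
#' @param cnv_module Index of the module enriched for copy-number events.
#' @param cnv_module_rate Event probability inside `cnv_module`.
#' @param n_cnv_samples Number of simulated (WGS-like) copy-number
#'   samples.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           n_samples = c(negative = 25, PAX3 = 26, PAX7 = 7),
                           module_sizes = c(200, 150, 100, 60, 40, 25, 15, 10),
                           loading = 0.9, noise_sd = 0.3,
                           background_sd = 0.5,
                           delta = c(1.5, -1.5, 1.5, -1.5, 1.5, -1.5, 1.5, 0),
                           delta_pax7 = NULL,
                           baseline_range = c(4, 10),
                           probe_counts = 1:3,
                           probe_probs = c(0.5, 0.3, 0.2),
                           unmapped_fraction = 0.1,
                           cnv_background_rate = 0.05,
                           cnv_module = 2L,
                           cnv_module_rate = 0.4,
                           n_cnv_samples = 4L) {
  stopifnot(sum(module_sizes) <= n_genes,
            length(delta) == length(module_sizes),
            loading > 0, loading <= 1, noise_sd >= 0,
            all(c("negative", "PAX3", "PAX7") %in% names(n_samples)),
            cnv_background_rate >= 0, cnv_background_rate <= 1,
            cnv_module_rate >= 0, cnv_module_rate <= 1,
            unmapped_fraction >= 0, unmapped_fraction < 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = n_samples,
                 module_sizes = as.integer(module_sizes),
                 loading = loading, noise_sd = noise_sd,
                 background_sd = background_sd,
                 delta = delta,
                 delta_pax7 = delta_pax7 %||% delta,
                 baseline_range = baseline_range,
                 probe_counts = probe_counts, probe_probs = probe_probs,
                 unmapped_fraction = unmapped_fraction,
                 cnv_background_rate = cnv_background_rate,
                 cnv_module = as.integer(cnv_module),
                 cnv_module_rate = cnv_module_rate,
                 n_cnv_samples = as.integer(n_cnv_samples)),
            class = "synthetic_spec")
}

#' Simulate a gene-level expression study
#'
#' Draws the latent-factor model of [synthetic_spec()]: planted modules
#' are disjoint blocks of consecutive genes; a module's genes share its
#' latent factor, which is mean-shifted by `delta_m` in the
#' fusion-positive groups. Deterministic given `(spec, seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with `expr` (gene-level [expression_matrix()]),
#'   `annotation` (data.frame `sample_id`, `fusion_group`) and `truth`
#'   (planted module memberships, per-module `delta`, planted CNV gene
#'   calls, and the seed).
#' @export
simulate_expression <- function(spec, seed = 1L) {
  with_seed(seed, {
    groups <- rep(names(spec$n_samples), spec$n_samples)
    n <- length(groups)
    if (n < 4L) stop("need at least 4 samples")
    samples <- sprintf("S%02d", seq_len(n))
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    nm <- length(spec$module_sizes)
    ends <- cumsum(spec$module_sizes)
    starts <- c(1L, ends[-nm] + 1L)
    membership <- lapply(seq_len(nm), function(m) genes[starts[m]:ends[m]])
    names(membership) <- paste0("block", seq_len(nm))

    baseline <- runif(spec$n_genes, spec$baseline_range[1],
                      spec$baseline_range[2])
    x <- matrix(rnorm(spec$n_genes * n, sd = spec$background_sd),
                nrow = spec$n_genes,
                dimnames = list(genes, samples))
    for (m in seq_len(nm)) {
      shift <- ifelse(groups == "PAX3", spec$delta[m],
                      ifelse(groups == "PAX7", spec$delta_pax7[m], 0))
      f <- rnorm(n) + shift
      rows <- starts[m]:ends[m]
      x[rows, ] <- spec$loading * matrix(f, nrow = length(rows),
                                         ncol = n, byrow = TRUE) +
        matrix(rnorm(length(rows) * n, sd = spec$noise_sd),
               nrow = length(rows))
    }
    x <- x + baseline

    enriched <- if (spec$cnv_module >= 1L && spec$cnv_module <= nm)
      membership[[spec$cnv_module]] else character(0)
    planted <- enriched[runif(length(enriched)) < spec$cnv_module_rate]
    others <- setdiff(genes, enriched)
    planted <- c(planted, others[runif(length(others)) <
                                   spec$cnv_background_rate])
    cnv_calls <- setNames(sample(c("amplification", "deletion"),
                                 length(planted), replace = TRUE),
                          planted)

    truth <- list(modules = membership, delta = spec$delta,
                  delta_pax7 = spec$delta_pax7,
                  cnv_genes = cnv_calls, seed = seed)
    list(expr = expression_matrix(x, "gene"),
         annotation = data.frame(sample_id = samples,
                                 fusion_group = groups),
         truth = truth)
  })
}

#' Expand a gene-level matrix to probe level
#'
#' Each gene becomes `k` probes (`k` drawn from the spec's probes-per-gene
#' distribution). The first probe carries the gene value unchanged; the
#' others subtract a positive per-probe offset, so an element-wise-max
#' collapse recovers the gene matrix exactly. Unmapped probes (empty gene
#' symbol in the map) are emitted as additional decoy probes with noise
#' values, so collapsing never loses a gene.
#'
#' @param expr_gene A gene-level [expression_matrix()].
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with `expr` (probe-level [expression_matrix()]) and `map`
#'   (data.frame `probe_id`, `gene_symbol`, `""` for decoys).
#' @export
simulate_probes <- function(expr_gene, spec, seed = 1L) {
  with_seed(seed, {
    v <- expr_gene$values
    genes <- rownames(v)
    k <- sample(spec$probe_counts, length(genes), replace = TRUE,
                prob = spec$probe_probs)
    gene_of <- rep(genes, k)
    within <- sequence(k)
    probe_ids <- sprintf("%s_at%d", gene_of, within)
    offsets <- ifelse(within == 1L, 0, runif(length(within), 0.2, 1))
    pv <- v[gene_of, , drop = FALSE] - offsets
    rownames(pv) <- probe_ids
    map <- data.frame(probe_id = probe_ids, gene_symbol = gene_of)
    n_unmapped <- round(spec$unmapped_fraction * nrow(pv) /
                          (1 - spec$unmapped_fraction))
    if (n_unmapped > 0) {
      dv <- matrix(runif(n_unmapped * ncol(pv), 2, 4), nrow = n_unmapped,
                   dimnames = list(sprintf("UNMAPPED_at%d",
                                           seq_len(n_unmapped)),
                                   colnames(pv)))
      pv <- rbind(pv, dv)
      map <- rbind(map, data.frame(probe_id = rownames(dv),
                                   gene_symbol = ""))
    }
    list(expr = expression_matrix(pv, "probe"), map = map)
  })
}

#' Synthetic non-overlapping gene annotation
#'
#' Lays genes out sequentially on a small number of chromosomes with fixed
#' length and gap (BED, 0-based half-open), guaranteeing no overlaps, and
#' labels coarse cytobands by position. Synthetic stand-in for a genome
#' annotation; intended for simulation and tests only.
#'
#' @param gene_ids Character vector of gene symbols.
#' @param n_chrom Number of chromosomes to spread genes over.
#' @param gene_length,gap Interval length and inter-gene gap in bp.
#' @param genes_per_band Genes per synthetic cytoband.
#' @return data.frame with `gene_symbol`, `chrom`, `start`, `end`,
#'   `cytoband` (same shape as [read_gene_bed()]).
#' @export
simulate_gene_annotation <- function(gene_ids, n_chrom = 4,
                                     gene_length = 1000, gap = 500,
                                     genes_per_band = 50) {
  n <- length(gene_ids)
  chrom <- as.character(rep_len(seq_len(n_chrom), n))
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- (idx - 1) * (gene_length + gap)
  band <- paste0(chrom, "q", (idx - 1) %/% genes_per_band + 1)
  data.frame(gene_symbol = gene_ids, chrom = chrom, start = start,
             end = start + gene_length, cytoband = band)
}

#' Cytoband gene sets from an annotation
#'
#' @param genes A gene annotation with a `cytoband` column.
#' @return Named list of gene sets (one per cytoband), GMT-ready.
#' @export
cytoband_sets <- function(genes) {
  if (all(is.na(genes$cytoband))) stop("annotation has no cytobands")
  split(genes$gene_symbol, genes$cytoband)
}

#' Simulate segmented copy-number data consistent with planted truth
#'
#' Emits one segment per gene per simulated sample: planted amplification
#' genes get a log2 ratio in [0.3, 0.8], planted deletions the negative,
#' and background genes a ratio in (-0.1, 0.1), so the full
#' SEG -> [gene_level_cnv()] pipeline reproduces the planted calls
#' exactly. Planted events recur in every simulated sample (clonal
#' events), backgrounds are redrawn per sample.
#'
#' @param truth The `truth` element of [simulate_expression()].
#' @param genes Gene annotation covering the planted genes (e.g. from
#'   [simulate_gene_annotation()]).
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A `segment_table` (same shape as [read_seg()]).
#' @export
simulate_cnv <- function(truth, genes, spec, seed = 1L) {
  with_seed(seed, {
    planted <- truth$cnv_genes
    missing <- setdiff(names(planted), genes$gene_symbol)
    if (length(missing))
      stop("annotation does not cover planted CNV genes: ",
           paste(utils::head(missing, 3), collapse = ", "))
    call <- setNames(rep("neutral", nrow(genes)), genes$gene_symbol)
    call[names(planted)] <- planted
    amp_mag <- runif(nrow(genes), 0.3, 0.8)
    out <- vector("list", spec$n_cnv_samples)
    for (s in seq_len(spec$n_cnv_samples)) {
      ratio <- runif(nrow(genes), -0.1, 0.1)
      ratio[call == "amplification"] <- amp_mag[call == "amplification"]
      ratio[call == "deletion"] <- -amp_mag[call == "deletion"]
      out[[s]] <- data.frame(sample_id = sprintf("WGS%d", s),
                             chrom = genes$chrom,
                             start = genes$start + 1,  # BED -> SEG coords
                             end = genes$end,
                             log2_ratio = ratio)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("segment_table", "data.frame")
    res
  })
}

#' Serialize planted truth as JSON
#'
#' @param truth The `truth` element of [simulate_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(modules = truth$modules, delta = truth$delta,
         delta_pax7 = truth$delta_pax7,
         cnv_genes = as.list(truth$cnv_genes), seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
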