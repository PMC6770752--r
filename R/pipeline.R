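#' Run the full co-expression analysis pipeline
#'
#' Orchestrates preprocess (read, probe collapse, variance filter), module
#' mining (pooled "consensus" network over all samples, optionally also
#' per fusion group), the differential module scan, overlap analysis of
#' the largest up/down modules, CNV/module overlap (when SEG + BED inputs
#' are given) and gene-set over-representation (when a GMT is given). All
#' outputs are TSV/JSON files in `out_dir`; `manifest.json` records the
#' config and the MD5 of every output, so a re-run with the same config
#' and inputs reproduces the directory byte-for-byte.
#'
#' @param config A named list or the path of a YAML file. Recognised
#'   entries: `expression` (path; TSV or series matrix), `format`,
#'   `feature_kind` (`"probe"` or `"gene"`), `probe_map`, `annotation`
#'   (both paths; `probe_map` required for probe input), `seg`, `bed`,
#'   `gmt` (optional paths), `drop_fraction`, lmQCM parameters (`gamma`,
#'   `lambda`, `t`, `beta`, `min_size`, `corr`, `absolute`,
#'   `normalize_weights`), `contrast`, `n_perm`, `seed`, `alpha`,
#'   `cnv_threshold`, `per_group` (also mine each fusion group
#'   separately), `out_dir`.
#' @return Invisibly, a list with the in-memory results (`expr`,
#'   `modules`, `diff`, and when computed `per_group`, `overlap`,
#'   `cnv`, `enrichment`) plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- "config"
  fail <- function(e) stop("pipeline stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE)
  tryCatch({
    out_dir <- config$out_dir %||% stop("config needs `out_dir`")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

    stage <- "preprocess"
    if (is.null(config$expression) || !file.exists(config$expression))
      stop("expression matrix not found: ",
           config$expression %||% "<missing>")
    if (is.null(config$annotation) || !file.exists(config$annotation))
      stop("sample annotation not found: ",
           config$annotation %||% "<missing>")
    expr <- read_expression(config$expression,
                            format = config$format %||% "tsv",
                            feature_kind = config$feature_kind %||% "gene")
    ann <- read_sample_annotation(config$annotation)
    if (expr$feature_kind == "probe") {
      if (is.null(config$probe_map))
        stop("probe-level input needs `probe_map`")
      expr <- collapse_probes(expr, read_probe_map(config$probe_map),
                              collapse = config$collapse %||%
                                "max-elementwise")
    }
    expr <- variance_filter(expr,
                            drop_fraction = config$drop_fraction %||% 1 / 3)
    check_annotation(expr, ann)
    write_expression_tsv(expr, file.path(out_dir, "expression_filtered.tsv"))

    stage <- "mine"
    params <- lmqcm_params(
      gamma = config$gamma %||% 0.7, lambda = config$lambda %||% 1,
      t = config$t %||% 1, beta = config$beta %||% 0.4,
      min_size = config$min_size %||% 10,
      corr = config$corr %||% "spearman",
      absolute = config$absolute %||% TRUE,
      normalize_weights = config$normalize_weights %||% FALSE)
    modules <- mine_modules(expr, params)
    write_modules_tsv(modules, file.path(out_dir, "modules_consensus.tsv"))
    write_gmt(modules$modules, file.path(out_dir, "modules_consensus.gmt"))

    per_group <- NULL
    if (isTRUE(config$per_group)) {
      grp <- setNames(ann$fusion_group, ann$sample_id)[sample_ids(expr)]
      split_ids <- list(negative = sample_ids(expr)[grp == "negative"],
                        positive = sample_ids(expr)[grp != "negative"])
      per_group <- lapply(names(split_ids), function(g) {
        ids <- split_ids[[g]]
        if (length(ids) < 3L) return(NULL)
        ms <- mine_modules(expression_matrix(
          expr$values[, ids, drop = FALSE], expr$feature_kind), params)
        write_modules_tsv(ms, file.path(out_dir,
                                        sprintf("modules_%s.tsv", g)))
        ms
      })
      names(per_group) <- names(split_ids)
    }

    stage <- "diff"
    contrast <- config$contrast %||% "neg_vs_pos"
    diff <- diff_module_scan(expr, modules, ann, contrast = contrast,
                             n_perm = config$n_perm %||% 999,
                             seed = config$seed %||% 17,
                             alpha = config$alpha %||% 0.05)
    write.table(diff, file.path(out_dir, "diff_modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "overlap"
    overlap <- NULL
    sig <- diff[diff$significant, , drop = FALSE]
    for (dir_ in c("up", "down")) {
      ids <- sig$module_id[sig$direction == dir_]
      ids <- ids[seq_len(min(4L, length(ids)))]  # largest first (sorted)
      if (length(ids) >= 2L) {
        ov <- module_overlap(modules, ids)
        write.table(ov, file.path(out_dir,
                                  sprintf("overlap_%s.tsv", dir_)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        overlap <- c(overlap, setNames(list(ov), dir_))
      }
    }

    universe <- feature_ids(expr)
    cnv_res <- NULL
    if (!is.null(config$seg)) {
      stage <- "cnv-overlap"
      segs <- read_seg(config$seg)
      genes <- read_gene_bed(config$bed %||%
                               stop("`seg` input needs `bed` annotation"))
      cnv <- gene_level_cnv(segs, genes,
                            threshold = config$cnv_threshold %||% 0.2)
      write.table(cnv, file.path(out_dir, "gene_cnv.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cnv_res <- cnv_module_overlap(cnv, modules, universe)
      write.table(cnv_res, file.path(out_dir, "cnv_module_overlap.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    enrich <- NULL
    if (!is.null(config$gmt)) {
      stage <- "enrich"
      sets <- read_gmt(config$gmt)
      enrich <- lapply(sig$module_id, function(id)
        overrepresentation_scan(intersect(modules$modules[[id]], universe),
                                sets, universe,
                                alpha_fdr = config$alpha_fdr %||% 0.05))
      names(enrich) <- sig$module_id
      flat <- do.call(rbind, lapply(names(enrich), function(id)
        if (nrow(enrich[[id]])) cbind(module_id = id, enrich[[id]])))
      if (!is.null(flat))
        write.table(flat, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    files <- lex_sort(setdiff(list.files(out_dir), "manifest.json"))
    manifest <- list(
      config = config[lex_sort(names(config))],
      outputs = as.list(setNames(
        unname(tools::md5sum(file.path(out_dir, files))), files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(expr = expr, modules = modules, per_group = per_group,
                   diff = diff, overlap = overlap, cnv = cnv_res,
                   enrichment = enrich, out_dir = out_dir))
  }, error = fail)
}
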