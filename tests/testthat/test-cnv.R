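write_seg_lines <- function(path, rows) {
  writeLines(c("sample\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               rows), path)
}

test_that("SEG files parse with chromosome normalisation", {
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg_lines(path, c("s1\tchr1\t100\t200\t5\t0.5",
                          "s1\t1\t300\t400\t5\t-0.1",
                          "s1\tchrX\t10\t20\t2\t0.0"))
  segs <- read_seg(path)
  expect_identical(nrow(segs), 3L)
  expect_setequal(unique(segs$chrom), c("1", "X"))  # chr1/1 one key
  expect_equal(segs$log2_ratio, c(0.5, -0.1, 0))

  # 1-row file
  write_seg_lines(path, "s1\t2\t1\t10\t1\t0.3")
  expect_identical(nrow(read_seg(path)), 1L)
})

test_that("invalid SEG input is rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg_lines(path, c("s1\t1\t100\t200\t5\t0.5",
                          "s1\tchr1\t150\t250\t5\t0.1"))
  expect_error(read_seg(path), "overlapping segments")
  # same coordinates in different samples are fine
  write_seg_lines(path, c("s1\t1\t100\t200\t5\t0.5",
                          "s2\t1\t100\t200\t5\t0.1"))
  expect_identical(nrow(read_seg(path)), 2L)
  write_seg_lines(path, "s1\t1\t300\t200\t5\t0.5")
  expect_error(read_seg(path), "start > end at line 2")
  write_seg_lines(path, "s1\t1\t100\t200\t5\tabc")
  expect_error(read_seg(path), "non-numeric seg.mean at line 2")
})

test_that("gene-level CNV is the overlap-weighted segment mean", {
  genes <- data.frame(gene_symbol = c("GA", "GB", "GC"),
                      chrom = c("1", "1", "2"),
                      start = c(100, 1000, 50),   # BED half-open
                      end = c(200, 1400, 150),
                      cytoband = NA_character_)
  segs <- data.frame(
    sample_id = "s1",
    chrom = c("1", "1", "1"),
    start = c(1, 1101, 1201),      # SEG 1-based inclusive
    end = c(1100, 1200, 2000),
    log2_ratio = c(0.5, 0.5, 0.0))
  cnv <- gene_level_cnv(segs, genes)
  byg <- setNames(cnv$value, cnv$gene_symbol)
  # GA (101..200) inside the 0.5 segment: inherits 0.5, amplification
  expect_equal(byg[["GA"]], 0.5)
  expect_identical(cnv$call[cnv$gene_symbol == "GA"], "amplification")
  # GB (1001..1400): 100 bp at 0.5, 100 bp at 0.5, 200 bp at 0.0
  # -> (100*0.5 + 100*0.5 + 200*0) / 400 = 0.25
  expect_equal(byg[["GB"]], 0.25)
  # GC on chrom 2: no segment -> 0, neutral, flagged uncovered
  expect_equal(byg[["GC"]], 0)
  expect_identical(cnv$call[cnv$gene_symbol == "GC"], "neutral")
  expect_true(cnv$uncovered[cnv$gene_symbol == "GC"])
  expect_false(any(cnv$uncovered[cnv$gene_symbol != "GC"]))
})

test_that("split-gene weighted averaging and the deletion call hold", {
  genes <- data.frame(gene_symbol = "G", chrom = "1",
                      start = 1000, end = 1400, cytoband = NA)
  segs <- data.frame(sample_id = "s1", chrom = "1",
                     start = c(901, 1101), end = c(1100, 2000),
                     log2_ratio = c(0.5, 0.0))
  # gene 1001..1400: 100 bp over the 0.5 segment, 300 bp over 0.0
  cnv <- gene_level_cnv(segs, genes)
  expect_equal(cnv$value, 0.125)
  expect_identical(cnv$call, "neutral")

  segs <- data.frame(sample_id = "s1", chrom = "1",
                     start = 1, end = 5000, log2_ratio = -0.3)
  expect_identical(gene_level_cnv(segs, genes)$call, "deletion")
})

test_that("boundary reconciliation between BED and SEG is exact", {
  # BED [100, 200) = bases 101..200; a SEG segment 101..200 covers it all
  genes <- data.frame(gene_symbol = "G", chrom = "1",
                      start = 100, end = 200, cytoband = NA)
  exact <- data.frame(sample_id = "s", chrom = "1", start = 101,
                      end = 200, log2_ratio = 1)
  expect_equal(gene_level_cnv(exact, genes)$value, 1)
  # segment ending at 100 touches only the base before the gene
  before <- data.frame(sample_id = "s", chrom = "1", start = 1,
                       end = 100, log2_ratio = 1)
  res <- gene_level_cnv(before, genes)
  expect_equal(res$value, 0)
  expect_true(res$uncovered)
  # one-base overlap at each end
  one_left <- data.frame(sample_id = "s", chrom = "1", start = 1,
                         end = 101, log2_ratio = 1)
  expect_false(gene_level_cnv(one_left, genes)$uncovered)
  one_right <- data.frame(sample_id = "s", chrom = "1", start = 200,
                          end = 300, log2_ratio = 1)
  expect_false(gene_level_cnv(one_right, genes)$uncovered)
})

test_that("gene CNV output is independent of segment row order", {
  set.seed(77)
  genes <- simulate_gene_annotation(sprintf("g%02d", 1:30))
  segs <- data.frame(sample_id = "s1", chrom = genes$chrom,
                     start = genes$start + 1, end = genes$end,
                     log2_ratio = round(runif(30, -0.5, 0.5), 3))
  a <- gene_level_cnv(segs, genes)
  b <- gene_level_cnv(segs[sample(30), ], genes)
  expect_equal(a[order(a$gene_symbol), c("value", "call")],
               b[order(b$gene_symbol), c("value", "call")],
               ignore_attr = TRUE)
})

test_that("calls partition genes at the +/-0.2 thresholds", {
  genes <- data.frame(gene_symbol = sprintf("g%d", 1:5), chrom = "1",
                      start = seq(0, 4000, 1000),
                      end = seq(500, 4500, 1000), cytoband = NA)
  segs <- data.frame(sample_id = "s", chrom = "1",
                     start = genes$start + 1, end = genes$end,
                     log2_ratio = c(0.2, 0.19, -0.2, -0.19, 0))
  cnv <- gene_level_cnv(segs, genes)
  expect_identical(cnv$call, c("amplification", "neutral", "deletion",
                               "neutral", "neutral"))
})

test_that("module/CNV overlap flags only truly enriched modules", {
  universe <- sprintf("g%03d", 1:200)
  modules <- as_module_set(list(hot = universe[1:10],
                                cold = universe[11:20]))
  # all of "hot" amplified, background rate 5/180 elsewhere
  aber <- c(universe[1:10], universe[c(30, 60, 90, 120, 150)])
  cnv <- data.frame(gene_symbol = universe, sample_id = "s1",
                    value = ifelse(universe %in% aber, 0.5, 0),
                    call = ifelse(universe %in% aber, "amplification",
                                  "neutral"),
                    uncovered = FALSE)
  res <- cnv_module_overlap(cnv, modules, universe)
  expect_lt(res$p_value[res$module_id == "hot"], 1e-6)
  expect_gte(res$p_value[res$module_id == "cold"], 0.05)
  expect_identical(res$cnv_overlap, c(10L, 0L))
})
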