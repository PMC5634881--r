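make_models <- function(exons, strand = "+", chrom = "chr1") {
  genes <- data.frame(gene_id = unique(exons$gene_id), chrom = chrom,
                      strand = strand,
                      start = min(exons$start), end = max(exons$end),
                      biotype = "protein_coding")
  gene_models(genes, exons)
}

test_that("introns are the gaps between merged exons", {
  m <- make_models(data.frame(gene_id = "g", start = c(0, 200),
                              end = c(100, 300)))
  intr <- extract_introns(m)
  expect_equal(nrow(intr), 1)
  expect_equal(c(intr$start, intr$end), c(100, 200))

  ## single exon: no intron
  m1 <- make_models(data.frame(gene_id = "g", start = 0, end = 500))
  expect_equal(nrow(extract_introns(m1)), 0)

  ## overlapping exon records are merged first
  m2 <- make_models(data.frame(gene_id = "g", start = c(0, 100, 400),
                               end = c(150, 300, 500)))
  intr2 <- extract_introns(m2)
  expect_equal(nrow(intr2), 1)
  expect_equal(c(intr2$start, intr2$end), c(300, 400))

  ## exons within a simulated model are sorted, disjoint and in-span
  cfg <- sim_config(seed = 4)
  sim <- simulate_gene_models(cfg, n_genes = 50)
  for (id in sim$genes$gene_id) {
    e <- sim$exons[sim$exons$gene_id == id, ]
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
    g <- sim$genes[sim$genes$gene_id == id, ]
    expect_true(all(e$start >= g$start & e$end <= g$end))
  }
})

test_that("retention coefficients are density ratios", {
  fi <- data.frame(
    feature_id = c("g:exon_1", "g:intron_1"),
    gene_id = "g", type = c("exon", "intron"), length = c(200, 100))
  counts <- matrix(c(100, 50), 2, 1,
                   dimnames = list(fi$feature_id, "s1"))
  expect_equal(unname(retention_coefficient(counts, fi)["g:intron_1", ]), 1)

  counts[2, 1] <- 0
  expect_equal(unname(retention_coefficient(counts, fi)["g:intron_1", ]), 0)

  fi2 <- data.frame(
    feature_id = c("g:exon_1", "g:exon_2", "g:intron_1"),
    gene_id = "g", type = c("exon", "exon", "intron"),
    length = c(600, 400, 200))
  counts2 <- matrix(c(300, 200, 30), 3, 1,
                    dimnames = list(fi2$feature_id, "s1"))
  expect_equal(unname(retention_coefficient(counts2, fi2)["g:intron_1", ]),
               0.3)

  ## invariance under uniform count scaling (ratio of densities)
  expect_equal(retention_coefficient(counts2 * 5, fi2),
               retention_coefficient(counts2, fi2))

  ## zero exon signal: undefined, marked NA
  counts3 <- counts2
  counts3[1:2, 1] <- 0
  expect_true(is.na(retention_coefficient(counts3, fi2)["g:intron_1", 1]))
})

test_that("differential retention matches a Welch t oracle", {
  ir_a <- matrix(c(2, 2.1, 1.9), 1, 3, dimnames = list("i1", NULL))
  ir_b <- matrix(c(1, 1.05, 0.95), 1, 3, dimnames = list("i1", NULL))
  tab <- differential_retention(ir_a, ir_b)
  expect_equal(tab$modulation, log2(2 / 1), tolerance = 0.01)
  oracle <- stats::t.test(ir_a[1, ], ir_b[1, ])
  expect_equal(tab$p_raw, oracle$p.value, tolerance = 1e-12)

  ## swapping the conditions negates the coefficient
  rev <- differential_retention(ir_b, ir_a)
  expect_equal(rev$modulation, -tab$modulation)

  ## identical replicate vectors: zero variance, flagged and untested
  same <- matrix(c(1, 1, 1), 1, 3, dimnames = list("i1", NULL))
  tz <- differential_retention(same, same)
  expect_identical(tz$flag, "zero_variance")
  expect_equal(tz$modulation, 0)
  expect_true(is.na(tz$p_raw))
  expect_false(tz$significant)
})

test_that("modulation bins tile the line with the stated edges", {
  tab <- differential_retention(
    matrix(2^c(-2.5, -2, -1.7, 0, 1.7, 2, 2.5) + 0,
           7, 3, dimnames = list(paste0("i", 1:7), NULL)),
    matrix(1, 7, 3, dimnames = list(paste0("i", 1:7), NULL)))
  expect_identical(as.character(tab$bin),
                   c("<-2", "[-2,-1.5]", "[-2,-1.5]", "(-1.5,1.5)",
                     "[1.5,2]", "[1.5,2]", ">2"))
})

test_that("null retention data give uniform p-values and no calls", {
  cfg <- sim_config(seed = 12, n_genes = 200, ir_shift_log2 = 0,
                    baseline_mean = 200)
  nas <- simulate_nascent_counts(cfg, simulate_gene_models(cfg))
  ir <- retention_coefficient(nas$counts, nas$feature_info)
  cols <- function(cond) nas$design$sample[nas$design$condition == cond]
  tab <- differential_retention(ir[, cols("case"), drop = FALSE],
                                ir[, cols("ctrl"), drop = FALSE])
  p <- tab$p_raw[!is.na(tab$p_raw)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  expect_lte(sum(tab$significant), ceiling(0.02 * nrow(tab)))
})

test_that("reversal fractions count opposite-sign significant events per bin", {
  er <- data.frame(
    intron_id = sprintf("i%02d", 1:10),
    mean_ir_a = 1, mean_ir_b = 1,
    modulation = rep(3, 10),            # all in the > 2 bin
    p_raw = 0.001, p_adj = 0.001, significant = TRUE,
    bin = ripflow:::ir_bin(rep(3, 10)), flag = "",
    stringsAsFactors = FALSE)
  class(er) <- c("retention_table", "data.frame")
  kd <- er
  kd$modulation <- c(rep(-3, 7), rep(3, 2), -3)
  kd$p_adj <- c(rep(0.001, 9), 0.5)     # last one flips but not significant
  rv <- reversal_analysis(er, kd)
  expect_equal(rv$fraction[rv$bin == ">2"], 0.7)
  expect_equal(rv$percent[rv$bin == ">2"], 70)
  ## empty bins report NA, never 0
  expect_true(is.na(rv$fraction[rv$bin == "<-2"]))

  ## without the significance requirement the non-significant flip counts
  rv2 <- reversal_analysis(er, kd, require_significant = FALSE)
  expect_equal(rv2$fraction[rv2$bin == ">2"], 0.8)
})

test_that("event filtering against a control set is a set difference", {
  expect_identical(event_filter_vs_control(c("a", "b"), c("c", "d")),
                   c("a", "b"))
  expect_identical(event_filter_vs_control(c("a", "b"), c("a", "b")),
                   character(0))
  a <- sprintf("i%02d", 1:10)
  b <- sprintf("i%02d", 7:10)
  expect_equal(length(event_filter_vs_control(a, b)), 6)
})
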