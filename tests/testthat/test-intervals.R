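test_that("BED round-trips byte-identically and rejects malformed records", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1\t5\t+",
               "chr1\t300\t400\tp2\t7\t-",
               "chr2\t0\t50\tp3\t0\t."), f)
  s <- read_bed(f)
  expect_equal(s$start, c(100, 300, 0))
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, f2)
  expect_identical(readLines(f2), readLines(f))

  ## header lines are skipped with a warning
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=peaks", "chr1\t10\t20\tp\t0\t+"), f3)
  expect_warning(s3 <- read_bed(f3), "header")
  expect_equal(nrow(s3), 1)

  ## inverted coordinates name the offending line
  f4 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\ta\t0\t+", "chr1\t50\t40\tb\t0\t+"), f4)
  expect_error(read_bed(f4), "line 2")

  ## beyond the declared chromosome
  f5 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t2000\ta\t0\t+", f5)
  expect_error(read_bed(f5, genome = c(chr1 = 1000)), "chromosome length")
})

test_that("TSS annotation is signed, strand-aware, and windowed", {
  models <- gene_models(
    data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
               strand = c("+", "-"), start = c(10000, 50000),
               end = c(12000, 52000), biotype = "protein_coding"),
    data.frame(gene_id = c("gp", "gp", "gm", "gm"),
               start = c(10000, 11500, 50000, 51500),
               end = c(10500, 12000, 50500, 52000)))
  tss <- gene_tss(models)
  expect_equal(tss$tss[tss$gene_id == "gp"], 10000)
  expect_equal(tss$tss[tss$gene_id == "gm"], 51999)

  mk_peak <- function(mid) interval_set("chr1", mid - 50, mid + 50, id = "p")
  at <- function(mid) annotate_to_tss(mk_peak(mid), models)

  expect_equal(at(10000)$distance, 0)
  expect_identical(at(10000)$label, "promoter")
  ## 500 bp upstream of the + strand TSS
  expect_equal(at(9500)$distance, -500)
  expect_identical(at(9500)$label, "promoter")
  ## +150 downstream: outside the -1000/+100 window
  expect_equal(at(10150)$distance, 150)
  expect_false(at(10150)$label == "promoter")
  ## boundary: exactly -1000 and +100 are inside
  expect_identical(at(9000)$label, "promoter")
  expect_identical(at(10100)$label, "promoter")

  ## on the - strand, upstream (larger coordinate) is negative
  m <- annotate_to_tss(mk_peak(52399), models)
  expect_equal(m$distance, -400)
  expect_identical(m$label, "promoter")
  expect_identical(m$nearest_gene, "gm")
})

test_that("proximity pairing is inclusive at the stated window", {
  a <- interval_set("chr1", c(1000, 10000, 20000),
                    c(1100, 10100, 20100), id = c("a1", "a2", "a3"))
  ## midpoints at 1050, 10050, 20050
  b <- interval_set("chr1", c(1000, 11050 - 50, 21051 - 50),
                    c(1100, 11050 + 50, 21051 + 50),
                    id = c("b1", "b2", "b3"))
  ## b1 at distance 0; b2 at exactly 1000; b3 at 1001
  pp <- proximity_pairs(a, b, window = 1000)
  expect_identical(pp$id_a, c("a1", "a2"))
  expect_equal(pp$distance, c(0, 1000))
  expect_equal(attr(pp, "n_distinct_a"), 2)
})

test_that("exact intersection is half-open and matches the quadratic oracle", {
  a <- interval_set("chr1", 0, 100, id = "a")
  b1 <- interval_set("chr1", 99, 200, id = "b")
  b2 <- interval_set("chr1", 100, 200, id = "b")
  expect_equal(nrow(intersect_exact(a, b1)), 1)
  expect_equal(intersect_exact(a, b1)$overlap_bp, 1)
  expect_equal(nrow(intersect_exact(a, b2)), 0)

  set.seed(77)
  genome <- c(chr1 = 20000, chr2 = 15000)
  for (i in 1:3) {
    sa <- random_interval_set(50, genome)
    sa$id <- paste0("a", seq_len(nrow(sa)))
    sb <- random_interval_set(50, genome)
    sb$id <- paste0("b", seq_len(nrow(sb)))
    got <- intersect_exact(sa, sb)
    want <- intersect_oracle(sa, sb)
    key <- function(d) sort(paste(d$id_a, d$id_b, d$overlap_bp))
    expect_identical(key(got), key(want))
  }
})

test_that("permutation overlap p-values are bounded, seeded, and powered", {
  genome <- c(chr1 = 5e6)
  ws <- genome_workspace(genome)
  a <- interval_set("chr1", seq(1000, 290000, by = 10000),
                    seq(1000, 290000, by = 10000) + 200, genome = genome)
  ## identical sets: observed is maximal, null never attains it
  res <- permutation_overlap_test(a, a, ws, n_sims = 199, seed = 3)
  expect_equal(res$observed, nrow(a))
  expect_equal(res$p_value, 1 / 200)

  ## same seed, same answer
  res2 <- permutation_overlap_test(a, a, ws, n_sims = 199, seed = 3)
  expect_identical(res, res2)

  ## planted co-localization is detected at modest simulation depth
  cfg <- sim_config(seed = 21, coloc_fraction = 0.5)
  iv <- simulate_interval_sets(cfg, n_ref = 300, n_query = 300)
  pw <- permutation_overlap_test(iv$query, iv$reference, iv$workspace,
                                 n_sims = 1000, seed = 4)
  expect_lt(pw$p_value, 0.01)

  ## an interval longer than its chromosome cannot be placed
  tiny <- genome_workspace(c(chr1 = 100))
  bad <- interval_set("chr1", 0, 90)
  long_iv <- structure(data.frame(chrom = "chr1", start = 0, end = 150,
                                  id = "x", score = 0, strand = "."),
                       class = c("interval_set", "data.frame"))
  expect_error(permutation_overlap_test(long_iv, bad, tiny, n_sims = 10,
                                        seed = 1),
               "placement error")
})

test_that("segment enrichment folds behave at the null and the extreme", {
  genome <- c(chr1 = 1e6)
  ws <- genome_workspace(genome, data.frame(
    chrom = "chr1", start = c(0, 1e5), end = c(1e5, 1e6),
    label = c("target", "rest")))

  ## all peaks inside a class covering 10% of the workspace
  inside <- interval_set(rep("chr1", 40), seq(500, 95000, length.out = 40),
                         seq(500, 95000, length.out = 40) + 500,
                         genome = genome)
  se <- segment_enrichment(inside, ws, n_sims = 400, seed = 2)
  expect_equal(se$fold[se$label == "target"], 10, tolerance = 0.15)
  expect_true(se$enriched[se$label == "target"])

  ## uniform peaks: fold near 1 everywhere (the peak placement itself
  ## is random, so the tolerance covers its sampling noise too)
  set.seed(5)
  unif <- random_interval_set(200, genome, width_range = c(400, 600))
  se2 <- segment_enrichment(unif, ws, n_sims = 400, seed = 2)
  expect_equal(se2$fold, c(1, 1), tolerance = 0.4)
  expect_false(any(se2$enriched))

  ## class absent from the sampled space: fold marked NA, never infinite
  ws3 <- genome_workspace(c(chr1 = 1e6, chr2 = 1e6), data.frame(
    chrom = c("chr1", "chr2"), start = 0, end = c(1e6, 1e6),
    label = c("everything", "unreachable")))
  on1 <- interval_set(rep("chr1", 10), seq(0, 9e5, 1e5),
                      seq(0, 9e5, 1e5) + 100, genome = c(chr1 = 1e6))
  se3 <- segment_enrichment(on1, ws3, n_sims = 100, seed = 9)
  expect_true(is.na(se3$fold[se3$label == "unreachable"]))
  expect_true(all(is.finite(se3$fold[se3$label == "everything"])))
})

test_that("interval sets validate coordinates against the workspace", {
  expect_error(interval_set("chr1", 10, 5), "start < end")
  expect_error(interval_set("chr1", 10, 2000, genome = c(chr1 = 1000)),
               "beyond chromosome length")
  expect_error(interval_set("chrX", 0, 10, genome = c(chr1 = 1000)),
               "not present")
})
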