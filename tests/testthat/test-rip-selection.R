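test_that("candidate gate is strict on EF and inclusive on adjusted p", {
  tab <- make_enr_table(c("a", "b", "c", "d"),
                        ef = c(1.0, 2, 2, 0.5),
                        p_adj = c(0.01, 0.05, 0.051, 0.01))
  cand <- select_candidates(tab)
  expect_identical(cand$feature_id, "b")  # a: EF not > 1; c: p > 0.05

  empty <- make_enr_table(character(0), numeric(0))
  expect_equal(nrow(select_candidates(empty)), 0)
})

test_that("percentile gate uses type-7 interpolation with strict pass", {
  p <- selection_params()
  g <- percentile_gate(make_enr_table(as.character(1:100), ef = 1:100), p)
  expect_equal(g$cutoff, 75.25)
  expect_equal(nrow(g$gated), 25)

  g4 <- percentile_gate(make_enr_table(as.character(1:4), ef = 1:4), p)
  expect_equal(g4$cutoff, 3.25)
  expect_equal(nrow(g4$gated), 1)

  ## degenerate distribution: nothing is strictly above the cutoff
  gd <- percentile_gate(make_enr_table(as.character(1:5), ef = rep(2, 5)), p)
  expect_equal(nrow(gd$gated), 0)

  expect_error(percentile_gate(make_enr_table(character(0), numeric(0)), p),
               "at least one candidate")
})

test_that("specificity split follows the control-detection rule", {
  p <- selection_params()
  gated <- make_enr_table(c("x", "y", "z"), ef = c(5, 5, 5))

  ## empty control: everything is specific
  empty <- make_enr_table(character(0), numeric(0))
  sp <- specificity_split(gated, empty, p)
  expect_equal(nrow(sp$specific), 3)

  ## enriched in both lines: shared; control EF <= 0 does not count as
  ## detected under the default rule
  ctrl <- make_enr_table(c("x", "y"), ef = c(2, -0.5))
  sp2 <- specificity_split(gated, ctrl, p)
  expect_identical(sort(sp2$specific$feature_id), c("y", "z"))
  expect_identical(sp2$shared$feature_id, "x")
})

test_that("rescue follows the ratio-or-negative-enrichment rule", {
  p <- selection_params()
  shared <- make_enr_table(c("r1", "r2", "r3", "r4"), ef = c(8, 6, 6, 6))
  case <- shared
  ctrl <- make_enr_table(c("r1", "r2", "r3", "r4"),
                         ef = c(1.5, -1.5, 2, 0))
  resc <- rescue_by_control_contrast(shared, case, ctrl, p)
  ## r1: 8/1.5 = 5.33 >= 4; r2: control EF -1.5 < -1;
  ## r3: ratio 3 < 4 and control EF > -1; r4: EF 0 skips the ratio branch
  expect_identical(sort(resc$feature_id), c("r1", "r2"))

  ## boundary: ratio exactly 4 rescues by default, not in strict mode
  ctrl2 <- make_enr_table("r2", ef = 1.5)
  shared2 <- make_enr_table("r2", ef = 6)
  expect_equal(nrow(rescue_by_control_contrast(shared2, shared2, ctrl2, p)), 1)
  p_strict <- selection_params(ratio_strict = TRUE)
  expect_equal(nrow(rescue_by_control_contrast(shared2, shared2, ctrl2,
                                               p_strict)), 0)
})

test_that("cascade replays the published stage arithmetic", {
  fx <- cascade_fixture(4556, 614, 264, 261)
  rep <- rip_select(fx$case, fx$control, selection_params())
  expect_equal(rep$n_above_percentile, 1139)
  expect_equal(rep$n_specific, 614)
  expect_equal(rep$n_remaining, 525)
  expect_equal(rep$n_rescued, 264)
  expect_equal(rep$n_selected, 878)
  expect_equal(rep$n_selected, rep$n_specific + rep$n_rescued)
  expect_equal(rep$n_remaining, rep$n_above_percentile - rep$n_specific)
})

test_that("selection accounting and monotonicity hold on random inputs", {
  set.seed(202)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    ids <- sprintf("r%03d", seq_len(n))
    case <- make_enr_table(ids, ef = round(runif(n, -2, 6), 3),
                           p_adj = runif(n, 0, 0.1))
    ctrl <- make_enr_table(sample(ids, n %/% 2),
                           ef = round(runif(n %/% 2, -3, 4), 3),
                           detected = sample(c(TRUE, FALSE), n %/% 2,
                                             replace = TRUE))
    rep <- rip_select(case, ctrl, selection_params())
    ## disjoint-union accounting
    expect_equal(rep$n_selected, rep$n_specific + rep$n_rescued)
    expect_equal(rep$n_remaining, rep$n_above_percentile - rep$n_specific)
    expect_equal(anyDuplicated(rep$selected$feature_id), 0)

    ## raising thresholds never adds a selected RNA
    stricter <- rip_select(case, ctrl,
                           selection_params(ef_min = 1.5, ratio_min = 6))
    expect_true(all(stricter$selected$feature_id %in%
                      rep$selected$feature_id))
  }
})

test_that("null candidate gate calls are bounded by the FDR level", {
  cfg <- sim_config(seed = 5, n_genes = 1000, enriched_fraction = 0,
                    carryover_fraction = 0)
  rip <- simulate_rip_counts(cfg)
  tab <- enrichment_test(rip$counts, c("IP", "input"), cell_line = "case")
  cand <- select_candidates(tab, selection_params())
  ## BH at 0.05 on a fully null table: expected calls near zero
  expect_lte(nrow(cand), ceiling(0.05 * 1000))
})

test_that("miRNA cascade applies its own thresholds without a percentile gate", {
  p <- selection_params()
  case <- make_enr_table(c("m1", "m2", "m3", "m4"),
                         ef = c(1.4, 2, 2, 2), p_raw = 0.01, p_adj = 0.2)
  ctrl <- make_enr_table(c("m2", "m3", "m4"), ef = c(0.9, -0.1, 1.5))
  rep <- select_mirnas(case, ctrl, p)
  ## m1 fails EF > 1.5; m2 ratio 2/0.9 = 2.2 >= 2; m3 control EF < 0
  ## (not detected -> specific); m4 ratio 1.33 < 2 -> dropped
  expect_identical(sort(rep$selected$feature_id), c("m2", "m3"))
  ## raw p is the default gate: adjusted p of 0.2 did not exclude them
  expect_equal(rep$n_candidates, 4)
  expect_equal(rep$n_above_percentile, 3)  # EF > 1.5 stage
})

test_that("miRNA negative-EF rescue branch fires for any negative control EF", {
  ## force the shared path by marking the control RNA as detected with
  ## positive EF off, using the expression-only detection rule
  p <- selection_params(control_detect = "expressed")
  case <- make_enr_table("m1", ef = 2, p_raw = 0.01, p_adj = 0.2)
  ctrl <- make_enr_table("m1", ef = -0.1)
  rep <- select_mirnas(case, ctrl, p)
  expect_identical(rep$selected$feature_id, "m1")
  expect_equal(rep$n_rescued, 1)
})

test_that("biotype enrichment matches hypergeometric enumeration", {
  ## closed-form corner: all 5 draws from a class of 5 in a pool of 20
  bt <- data.frame(feature_id = sprintf("f%02d", 1:20),
                   biotype = rep(c("A", "B"), c(5, 15)))
  res <- biotype_enrichment(sprintf("f%02d", 1:5), bt)
  expect_equal(res$p_hyper[res$biotype == "A"], 1 / choose(20, 5),
               tolerance = 1e-12)
  ## k = 0 for class B among the same draws -> P(X >= 0) = 1
  expect_equal(res$p_hyper[res$biotype == "B"], 1)

  ## whole population selected: p = 1 for every class
  res_all <- biotype_enrichment(bt$feature_id, bt)
  expect_true(all(res_all$p_hyper == 1))

  ## random instances against explicit summation (population <= 25)
  set.seed(33)
  for (i in 1:10) {
    n_pop <- sample(10:25, 1)
    k_class <- sample(2:(n_pop - 2), 1)
    n_draw <- sample(2:(n_pop - 1), 1)
    bt2 <- data.frame(feature_id = sprintf("x%02d", seq_len(n_pop)),
                      biotype = sample(rep(c("A", "B"),
                                           c(k_class, n_pop - k_class))))
    sel <- sample(bt2$feature_id, n_draw)
    res2 <- biotype_enrichment(sel, bt2)
    k <- sum(bt2$biotype[match(sel, bt2$feature_id)] == "A")
    expect_equal(res2$p_hyper[res2$biotype == "A"],
                 hyper_oracle(k, k_class, n_pop, n_draw), tolerance = 1e-12)
  }
})
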