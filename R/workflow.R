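#' End-to-end synthetic demonstration run
#'
#' Simulates every data type from one seed and pushes each through its
#' analysis track: RIP-Seq counts through enrichment testing and the
#' selection cascade; nascent counts through retention quantification,
#' differential retention and the knock-down reversal analysis;
#' interval sets through proximity pairing, exact intersection and the
#' permutation overlap test; and the LFQ matrix through bait
#' normalization and the permutation-FDR differential test. Returns a
#' run report with per-stage counts, a parameter echo and the config
#' fingerprint; re-running with the same seed reproduces the report
#' byte for byte (wall-clock time is deliberately kept out of it).
#'
#' Problem sizes (1200 genes, 250 gene models, 300 x 300 intervals, 200
#' proteins, 500 overlap permutations) are chosen so a run completes in
#' well under five minutes on one CPU while leaving every planted
#' signal recoverable.
#'
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, stage outputs (TSV),
#'   the truth tables (JSON) and the report (JSON) are written there.
#' @return List of class `run_report`.
#' @export
run_demo <- function(seed = 1, out_dir = NULL) {
  cfg <- sim_config(seed = seed, n_genes = 1200)

  ## --- RIP track -------------------------------------------------
  rip <- simulate_rip_counts(cfg)
  case_tab <- enrichment_test(rip$counts, c("IP", "input"),
                              cell_line = "case")
  ctrl_tab <- enrichment_test(rip$counts, c("IP", "input"),
                              cell_line = "control")
  sel <- rip_select(case_tab, ctrl_tab, selection_params())

  ## --- nascent track ---------------------------------------------
  cfg_n <- sim_config(seed = seed, n_genes = 250, ir_shift_log2 = 2.5,
                      ir_shift_fraction = 0.4, reversal_fraction = 0.6,
                      baseline_mean = 200)
  models <- simulate_gene_models(cfg_n)
  nas <- simulate_nascent_counts(cfg_n, models)
  ir <- retention_coefficient(nas$counts, nas$feature_info)
  cols_of <- function(cond) nas$design$sample[nas$design$condition == cond]
  er_tab <- differential_retention(ir[, cols_of("case"), drop = FALSE],
                                   ir[, cols_of("ctrl"), drop = FALSE])
  kd_tab <- differential_retention(ir[, cols_of("case_kd"), drop = FALSE],
                                   ir[, cols_of("case"), drop = FALSE])
  rev_tab <- reversal_analysis(er_tab, kd_tab)

  ## --- interval track --------------------------------------------
  iv <- simulate_interval_sets(cfg, n_ref = 300, n_query = 300)
  pairs <- proximity_pairs(iv$query, iv$reference, window = 1000)
  inter <- intersect_exact(iv$query, iv$reference)
  ov_test <- permutation_overlap_test(iv$query, iv$reference,
                                      iv$workspace, n_sims = 500,
                                      seed = derive_seed(seed, "ovtest"))

  ## --- interactome track -----------------------------------------
  lfq <- simulate_lfq_matrix(cfg, n_proteins = 200)
  norm <- bait_normalize(lfq$matrix, lfq$bait_id)
  diff <- permutation_fdr_test(norm[rownames(norm) != lfq$bait_id, ],
                               lfq$groups, fdr_cut = 0.01)
  dep <- dependence_summary(diff)

  report <- list(
    seed = seed,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("ripflow")),
    parameters = cfg[setdiff(names(cfg), "genome_lengths")],
    rip = list(n_candidates = sel$n_candidates,
               n_above_percentile = sel$n_above_percentile,
               n_specific = sel$n_specific,
               n_rescued = sel$n_rescued,
               n_selected = sel$n_selected,
               n_planted = length(rip$truth$enriched_ids$case),
               n_planted_recovered = length(intersect(
                 sel$selected$feature_id, rip$truth$enriched_ids$case))),
    nascent = list(n_introns = nrow(er_tab),
                   n_significant = sum(er_tab$significant),
                   reversal = rev_tab),
    intervals = list(n_pairs = attr(pairs, "n_pairs"),
                     n_distinct_query = attr(pairs, "n_distinct_a"),
                     n_intersecting = length(unique(inter$id_a)),
                     overlap_p = ov_test$p_value),
    interactome = list(n_tested = sum(diff$tested),
                       n_significant = sum(diff$significant),
                       dependent_percent = dep$percent)
  )
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_matrix(rip$counts,
                       file.path(out_dir, "rip_counts.tsv"),
                       file.path(out_dir, "rip_design.tsv"))
    write.table(sel$selected, file.path(out_dir, "selected_rnas.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(er_tab, file.path(out_dir, "retention_case_vs_ctrl.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rev_tab, file.path(out_dir, "reversal_by_bin.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_gtf(models, file.path(out_dir, "gene_models.gtf"))
    write_bed(iv$reference, file.path(out_dir, "reference.bed"))
    write_bed(iv$query, file.path(out_dir, "query.bed"))
    jsonlite::write_json(
      list(rip_enriched = rip$truth$enriched_ids,
           ir_shifted = nas$truth$shifted,
           ir_reverted = nas$truth$reverted,
           coloc_pairs = iv$truth,
           lfq_dependent = lfq$truth$dependent),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("ripflow demo run (seed", x$seed, ", config", x$config_hash, ")\n")
  cat(sprintf("  RIP: %d selected (%d specific + %d rescued), %d/%d planted recovered\n",
              x$rip$n_selected, x$rip$n_specific, x$rip$n_rescued,
              x$rip$n_planted_recovered, x$rip$n_planted))
  cat(sprintf("  nascent: %d/%d introns significant\n",
              x$nascent$n_significant, x$nascent$n_introns))
  cat(sprintf("  intervals: %d proximity-paired queries, overlap p = %.4g\n",
              x$intervals$n_distinct_query, x$intervals$overlap_p))
  cat(sprintf("  interactome: %d/%d significant (%s%% dependent)\n",
              x$interactome$n_significant, x$interactome$n_tested,
              format(x$interactome$dependent_percent)))
  invisible(x)
}

#' Validate analysis input files
#'
#' Schema checks with file- and line-anchored messages: the design table
#' must carry the required columns; the count table must have a
#' `feature_id` first column and non-negative integer counts; BED
#' records must parse and fit the declared genome. Returns a
#' diagnostics data.frame (zero rows = clean); `fatal = TRUE` entries
#' indicate the file cannot be used.
#'
#' @param counts_path,design_path optional count/design TSV paths.
#' @param bed_path optional BED path.
#' @param genome optional named chromosome lengths for BED validation.
#' @return data.frame with columns `file`, `line`, `fatal`, `message`.
#' @export
validate_inputs <- function(counts_path = NULL, design_path = NULL,
                            bed_path = NULL, genome = NULL) {
  diag <- data.frame(file = character(0), line = integer(0),
                     fatal = logical(0), message = character(0),
                     stringsAsFactors = FALSE)
  add <- function(file, line, fatal, message) {
    diag <<- rbind(diag, data.frame(file = file, line = line,
                                    fatal = fatal, message = message,
                                    stringsAsFactors = FALSE))
  }
  if (!is.null(design_path)) {
    if (!file.exists(design_path)) {
      add(design_path, NA, TRUE, "file does not exist")
    } else {
      d <- read.table(design_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
      needed <- c("sample", "cell_line", "fraction", "condition",
                  "replicate")
      for (col in setdiff(needed, names(d)))
        add(design_path, 1, TRUE,
            sprintf("design is missing required column `%s`", col))
    }
  }
  if (!is.null(counts_path)) {
    if (!file.exists(counts_path)) {
      add(counts_path, NA, TRUE, "file does not exist")
    } else {
      df <- read.table(counts_path, sep = "\t", header = TRUE,
                       check.names = FALSE, stringsAsFactors = FALSE)
      if (names(df)[1] != "feature_id") {
        add(counts_path, 1, TRUE, "first column must be `feature_id`")
      } else {
        vals <- as.matrix(df[, -1, drop = FALSE])
        bad <- which(apply(vals, 1, function(r)
          any(is.na(r) | r < 0 | r != floor(r))))
        for (i in head(bad, 10))
          add(counts_path, i + 1, TRUE,
              "counts must be non-negative integers")
      }
    }
  }
  if (!is.null(bed_path)) {
    res <- tryCatch({
      suppressWarnings(read_bed(bed_path, genome = genome))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      ln <- sub(".* line (\\d+):.*", "\\1", res)
      add(bed_path, suppressWarnings(as.integer(ln)), TRUE, res)
    }
  }
  diag
}
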