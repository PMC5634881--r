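#' Parameters of the RIP-Seq selection cascade
#'
#' Thresholds driving the multi-stage selection of protein-associated
#' RNAs from IP/input enrichment tables. Defaults mirror the published
#' convention: candidates need EF > 1 (strict) with adjusted p <= 0.05,
#' the percentile gate keeps EFs above the 75th percentile of the
#' candidate distribution, and shared RNAs are rescued when the
#' case/control EF ratio reaches 4 (inclusive) or the control shows a
#' negative enrichment below -1. The miRNA variant skips the percentile
#' gate and uses EF > 1.5 with an EF ratio of 2; its negative-EF rescue
#' branch triggers on any control EF below 0.
#'
#' @param ef_min candidate gate: EF must exceed this (strict `>`).
#' @param padj_max candidate gate: adjusted p-value cutoff (inclusive).
#' @param percentile percentile (as a proportion in (0, 1)) of the
#'   candidate EF distribution used as the gate cutoff.
#' @param ratio_min case/control EF ratio for rescue; compared with `>=`
#'   unless `ratio_strict`.
#' @param neg_ef_max rescue when control EF is below this (long RNAs: -1).
#' @param mirna_ef_min miRNA EF threshold (strict `>`).
#' @param mirna_ratio_min miRNA case/control EF ratio.
#' @param mirna_neg_ef_max miRNA negative-EF rescue threshold (0: any
#'   negative control EF rescues).
#' @param mirna_p_type miRNA candidate gate p-value: `"raw"` (p <= 0.05,
#'   the default preset) or `"adjusted"` (adjusted p < 0.1 preset, in
#'   which case `mirna_p_max` should be set to 0.1).
#' @param mirna_p_max miRNA candidate p-value cutoff.
#' @param ratio_strict use strict `>` instead of `>=` for the EF ratio.
#' @param control_detect rule declaring an RNA "detected" in the control
#'   line for the specificity split: `"ef_pos"` (expression filter pass
#'   AND control EF > 0, the default) or `"expressed"` (expression
#'   filter pass alone).
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(ef_min = 1, padj_max = 0.05, percentile = 0.75,
                             ratio_min = 4, neg_ef_max = -1,
                             mirna_ef_min = 1.5, mirna_ratio_min = 2,
                             mirna_neg_ef_max = 0,
                             mirna_p_type = c("raw", "adjusted"),
                             mirna_p_max = 0.05,
                             ratio_strict = FALSE,
                             control_detect = c("ef_pos", "expressed")) {
  if (percentile <= 0 || percentile >= 1)
    stopf("`percentile` must lie strictly inside (0, 1)")
  if (ratio_min <= 0) stopf("`ratio_min` must be positive")
  structure(list(ef_min = ef_min, padj_max = padj_max,
                 percentile = percentile, ratio_min = ratio_min,
                 neg_ef_max = neg_ef_max, mirna_ef_min = mirna_ef_min,
                 mirna_ratio_min = mirna_ratio_min,
                 mirna_neg_ef_max = mirna_neg_ef_max,
                 mirna_p_type = match.arg(mirna_p_type),
                 mirna_p_max = mirna_p_max,
                 ratio_strict = ratio_strict,
                 control_detect = match.arg(control_detect)),
            class = "selection_params")
}

#' Candidate RNAs from an enrichment table
#'
#' Stage one of the cascade: RNAs with EF strictly above `ef_min` and
#' adjusted p-value at or below `padj_max`.
#'
#' @param case an `enrichment_table` (see [enrichment_test()]).
#' @param params a [selection_params()].
#' @return The rows of `case` passing the gate.
#' @export
select_candidates <- function(case, params = selection_params()) {
  keep <- !is.na(case$ef) & !is.na(case$p_adj) &
    case$ef > params$ef_min & case$p_adj <= params$padj_max
  out <- case[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentile gate on candidate enrichment factors
#'
#' The cutoff is the linear-interpolation (type 7) percentile of the
#' candidate EF distribution; RNAs pass with EF strictly above it.
#'
#' @param candidates candidate rows (output of [select_candidates()]).
#' @param params a [selection_params()].
#' @return List with `cutoff` (numeric) and `gated` (the passing rows).
#' @export
percentile_gate <- function(candidates, params = selection_params()) {
  if (nrow(candidates) < 1)
    stopf("percentile gate needs at least one candidate")
  cutoff <- unname(quantile(candidates$ef, params$percentile, type = 7))
  gated <- candidates[candidates$ef > cutoff, , drop = FALSE]
  rownames(gated) <- NULL
  list(cutoff = cutoff, gated = gated)
}

## ids of features counted as "detected" in the control line
control_detected_ids <- function(control, params) {
  if (is.null(control) || nrow(control) == 0) return(character(0))
  det <- control$detected
  if (params$control_detect == "ef_pos")
    det <- det & !is.na(control$ef) & control$ef > 0
  control$feature_id[det]
}

#' Split gated RNAs into control-specific and shared
#'
#' An RNA is specific when it is absent from the set of RNAs detected in
#' the negative-control line (see `control_detect` in
#' [selection_params()]); the remainder is shared and goes on to the
#' rescue stage.
#'
#' @param gated gated rows (from [percentile_gate()]).
#' @param control control-line `enrichment_table`.
#' @param params a [selection_params()].
#' @return List with data.frames `specific` and `shared`.
#' @export
specificity_split <- function(gated, control, params = selection_params()) {
  ctrl_ids <- control_detected_ids(control, params)
  is_specific <- !(gated$feature_id %in% ctrl_ids)
  list(specific = gated[is_specific, , drop = FALSE],
       shared = gated[!is_specific, , drop = FALSE])
}

## rescue predicate shared by the long-RNA and miRNA cascades
rescue_keep <- function(case_ef, ctrl_ef, ratio_min, neg_ef_max,
                        ratio_strict) {
  ratio_ok <- !is.na(ctrl_ef) & ctrl_ef > 0 & case_ef > 0 &
    (if (ratio_strict) case_ef / ctrl_ef > ratio_min
     else case_ef / ctrl_ef >= ratio_min)
  neg_ok <- !is.na(ctrl_ef) & ctrl_ef < neg_ef_max
  ratio_ok | neg_ok
}

#' Rescue shared RNAs by the control contrast
#'
#' Shared RNAs (already above the case percentile gate) are rescued when
#' the case/control EF ratio reaches `ratio_min` -- evaluated only when
#' both EFs are strictly positive -- or when the control EF shows a
#' negative enrichment below `neg_ef_max`. A control EF of exactly 0
#' skips the ratio branch.
#'
#' @param shared shared rows from [specificity_split()].
#' @param case,control the two `enrichment_table`s.
#' @param params a [selection_params()].
#' @return The rescued rows (taken from `shared`).
#' @export
rescue_by_control_contrast <- function(shared, case, control,
                                       params = selection_params()) {
  if (nrow(shared) == 0) return(shared)
  ctrl_ef <- control$ef[match(shared$feature_id, control$feature_id)]
  keep <- rescue_keep(shared$ef, ctrl_ef, params$ratio_min,
                      params$neg_ef_max, params$ratio_strict)
  out <- shared[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full long-RNA selection cascade
#'
#' Chains [select_candidates()], [percentile_gate()],
#' [specificity_split()] and [rescue_by_control_contrast()] and returns
#' a selection report with stage counts, the percentile cutoff value and
#' a per-RNA audit trail recording where each candidate left or entered
#' the selection. By construction `n_selected = n_specific + n_rescued`
#' and `n_remaining = n_above_percentile - n_specific`.
#'
#' @param case,control `enrichment_table`s for the case and
#'   negative-control cell lines.
#' @param params a [selection_params()].
#' @return A list of class `selection_report`.
#' @export
rip_select <- function(case, control, params = selection_params()) {
  candidates <- select_candidates(case, params)
  gate <- percentile_gate(candidates, params)
  split <- specificity_split(gate$gated, control, params)
  rescued <- rescue_by_control_contrast(split$shared, case, control, params)

  audit <- data.frame(feature_id = candidates$feature_id,
                      stage = "below_percentile",
                      stringsAsFactors = FALSE)
  audit$stage[audit$feature_id %in% split$specific$feature_id] <- "specific"
  audit$stage[audit$feature_id %in% split$shared$feature_id] <-
    "shared_not_rescued"
  audit$stage[audit$feature_id %in% rescued$feature_id] <- "rescued"

  selected <- rbind(split$specific, rescued)
  rownames(selected) <- NULL
  structure(list(
    n_candidates = nrow(candidates),
    percentile_cutoff_value = gate$cutoff,
    n_above_percentile = nrow(gate$gated),
    n_specific = nrow(split$specific),
    n_remaining = nrow(gate$gated) - nrow(split$specific),
    n_rescued = nrow(rescued),
    n_selected = nrow(selected),
    selected = selected,
    audit = audit,
    params = params
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("RIP-Seq selection cascade\n")
  cat(sprintf("  candidates (EF/p gate) : %d\n", x$n_candidates))
  cat(sprintf("  percentile cutoff (EF) : %.3f\n", x$percentile_cutoff_value))
  cat(sprintf("  above percentile       : %d\n", x$n_above_percentile))
  cat(sprintf("  control-specific       : %d\n", x$n_specific))
  cat(sprintf("  remaining (shared)     : %d\n", x$n_remaining))
  cat(sprintf("  rescued by contrast    : %d\n", x$n_rescued))
  cat(sprintf("  selected               : %d\n", x$n_selected))
  invisible(x)
}

#' miRNA selection cascade
#'
#' Same cascade shape as [rip_select()] but with the miRNA thresholds
#' and no percentile gate: candidates need EF > `ef_min` with p-value at
#' or below `mirna_p_max` (raw by default; an adjusted-p preset is
#' available via `mirna_p_type`), then EF > `mirna_ef_min`; shared
#' miRNAs are rescued when the case/control EF ratio reaches
#' `mirna_ratio_min` or the control EF is negative.
#'
#' @inheritParams rip_select
#' @return A list of class `selection_report` (without a percentile
#'   cutoff).
#' @export
select_mirnas <- function(case, control, params = selection_params()) {
  p <- if (params$mirna_p_type == "raw") case$p_raw else case$p_adj
  cand_keep <- !is.na(case$ef) & !is.na(p) &
    case$ef > params$ef_min & p <= params$mirna_p_max
  candidates <- case[cand_keep, , drop = FALSE]
  gated <- candidates[candidates$ef > params$mirna_ef_min, , drop = FALSE]
  split <- specificity_split(gated, control, params)
  shared <- split$shared
  ctrl_ef <- control$ef[match(shared$feature_id, control$feature_id)]
  keep <- rescue_keep(shared$ef, ctrl_ef, params$mirna_ratio_min,
                      params$mirna_neg_ef_max, params$ratio_strict)
  rescued <- shared[keep, , drop = FALSE]
  selected <- rbind(split$specific, rescued)
  rownames(selected) <- NULL
  structure(list(
    n_candidates = nrow(candidates),
    percentile_cutoff_value = NA_real_,
    n_above_percentile = nrow(gated),
    n_specific = nrow(split$specific),
    n_remaining = nrow(gated) - nrow(split$specific),
    n_rescued = nrow(rescued),
    n_selected = nrow(selected),
    selected = selected,
    audit = NULL,
    params = params
  ), class = "selection_report")
}

#' Biotype class enrichment of a selected RNA set
#'
#' For every biotype class, counts the overlap between the selected set
#' and the class and computes an upper-tail hypergeometric p-value
#' P(X >= k) with the full annotation table as the population.
#'
#' @param selected character vector of selected feature ids.
#' @param biotypes data.frame with columns `feature_id` and `biotype`
#'   covering the background population.
#' @return data.frame with one row per class: `biotype`, `n_class`,
#'   `n_selected_in_class`, `fraction_of_selected`, `p_hyper`.
#' @export
biotype_enrichment <- function(selected, biotypes) {
  stopifnot(all(c("feature_id", "biotype") %in% names(biotypes)))
  selected <- intersect(selected, biotypes$feature_id)
  n_pop <- nrow(biotypes)
  n_draw <- length(selected)
  cls <- sort(unique(biotypes$biotype))
  sel_bt <- biotypes$biotype[match(selected, biotypes$feature_id)]
  out <- do.call(rbind, lapply(cls, function(cl) {
    k_class <- sum(biotypes$biotype == cl)
    k <- sum(sel_bt == cl)
    data.frame(
      biotype = cl,
      n_class = k_class,
      n_selected_in_class = k,
      fraction_of_selected = if (n_draw > 0) k / n_draw else NA_real_,
      p_hyper = phyper(k - 1, k_class, n_pop - k_class, n_draw,
                       lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
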