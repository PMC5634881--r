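#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. One integer `seed`
#' drives every generator through a documented splitting scheme (the
#' seed is hashed together with a per-stage stream name), so a fixed
#' seed gives byte-identical outputs while the stages stay mutually
#' independent. Defaults emulate the study designs the package targets:
#' triplicate IP/input experiments in a case and a negative-control
#' cell line, a planted enrichment of 2^3 (matching the scale of a
#' 75th-percentile EF cutoff near 3 on log2), moderate RNA-seq
#' overdispersion, and a two-fold spread of library depths so size
#' factors are non-trivial.
#'
#' @param seed integer master seed.
#' @param n_genes number of simulated features.
#' @param n_replicates biological replicates per condition (default 3).
#' @param nb_dispersion negative-binomial dispersion; counts are drawn
#'   with `size = 1 / nb_dispersion` so the variance is
#'   `mu + nb_dispersion * mu^2`.
#' @param baseline_mean baseline expected count per feature (for the
#'   nascent generator, expected reads per 300 bp of exon).
#' @param enriched_fraction proportion of features planted as enriched
#'   in the case line IP.
#' @param enrichment_log2fc planted log2 IP/input enrichment.
#' @param control_enriched_fraction proportion planted as enriched in
#'   the control line (default 0).
#' @param carryover_fraction proportion of features with nonspecific
#'   IP carryover -- background binding present in both cell lines,
#'   emulating the broad enrichment-factor spectrum of real IP
#'   libraries that the percentile gate is designed to trim. Set to 0
#'   (together with `enriched_fraction = 0`) for a fully null
#'   configuration.
#' @param carryover_log2_range range of the uniform log2 carryover
#'   enrichment.
#' @param library_size_spread sample depth factors are drawn
#'   log-uniformly in `[1/spread, spread]`.
#' @param ir_shift_log2 magnitude of the planted intron-retention shift
#'   (log2); planted introns get a signed shift of this size, half up,
#'   half down.
#' @param ir_shift_fraction proportion of introns carrying a planted
#'   shift.
#' @param ir_base baseline intron retention level relative to exon
#'   coverage.
#' @param reversal_fraction share of planted shifts inverted under the
#'   simulated knock-down.
#' @param coloc_fraction share of query intervals placed near a
#'   reference interval.
#' @param coloc_distance maximum planted midpoint offset (bp) for
#'   co-localized query intervals.
#' @param genome_lengths named numeric vector of chromosome lengths.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 2000, n_replicates = 3,
                       nb_dispersion = 0.05, baseline_mean = 100,
                       enriched_fraction = 0.05, enrichment_log2fc = 3,
                       control_enriched_fraction = 0,
                       carryover_fraction = 0.4,
                       carryover_log2_range = c(1.0, 2.4),
                       library_size_spread = 2,
                       ir_shift_log2 = 1, ir_shift_fraction = 0.3,
                       ir_base = 0.2, reversal_fraction = 0.6,
                       coloc_fraction = 0.3, coloc_distance = 500,
                       genome_lengths = c(chr1 = 2e6, chr2 = 1.5e6)) {
  if (n_genes < 1) stopf("configuration error: `n_genes` must be >= 1")
  assert_positive(nb_dispersion, "nb_dispersion")
  assert_positive(baseline_mean, "baseline_mean")
  assert_positive(library_size_spread, "library_size_spread")
  assert_proportion(enriched_fraction, "enriched_fraction")
  assert_proportion(control_enriched_fraction, "control_enriched_fraction")
  assert_proportion(carryover_fraction, "carryover_fraction")
  assert_proportion(ir_shift_fraction, "ir_shift_fraction")
  assert_proportion(reversal_fraction, "reversal_fraction")
  assert_proportion(coloc_fraction, "coloc_fraction")
  if (is.null(names(genome_lengths)) || !length(genome_lengths))
    stopf("configuration error: `genome_lengths` must be a named vector")
  structure(list(seed = seed, n_genes = n_genes,
                 n_replicates = n_replicates,
                 nb_dispersion = nb_dispersion,
                 baseline_mean = baseline_mean,
                 enriched_fraction = enriched_fraction,
                 enrichment_log2fc = enrichment_log2fc,
                 control_enriched_fraction = control_enriched_fraction,
                 carryover_fraction = carryover_fraction,
                 carryover_log2_range = carryover_log2_range,
                 library_size_spread = library_size_spread,
                 ir_shift_log2 = ir_shift_log2,
                 ir_shift_fraction = ir_shift_fraction,
                 ir_base = ir_base,
                 reversal_fraction = reversal_fraction,
                 coloc_fraction = coloc_fraction,
                 coloc_distance = coloc_distance,
                 genome_lengths = genome_lengths),
            class = "sim_config")
}

## depth factors, log-uniform in [1/spread, spread]
sim_depths <- function(n, spread) {
  exp(runif(n, -log(spread), log(spread)))
}

#' Simulate IP/input RIP-Seq count pairs with planted enrichment
#'
#' Two cell lines (`case`, `control`) x two fractions (`input`, `IP`) x
#' replicates. Baseline expression per feature is log-normal around
#' `baseline_mean`; a planted subset of features has its IP mean
#' multiplied by `2^enrichment_log2fc` in the case line (and optionally
#' an independent subset in the control line). Counts are
#' negative-binomial with the configured dispersion, scaled by
#' per-sample depth factors.
#'
#' @param cfg a [sim_config()].
#' @return List with `counts` (a [count_matrix()]) and `truth` (list
#'   with `enriched_ids` per cell line and the per-sample
#'   `depth_factors`).
#' @export
simulate_rip_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "rip"))
  n <- cfg$n_genes
  ids <- sprintf("gene_%05d", seq_len(n))
  base <- rlnorm(n, meanlog = log(cfg$baseline_mean), sdlog = 1)

  enriched <- list(
    case = sample(ids, round(cfg$enriched_fraction * n)),
    control = sample(ids, round(cfg$control_enriched_fraction * n))
  )
  ## nonspecific carryover: background binding of the same strength in
  ## both lines, drawn per feature; specific planted enrichment
  ## overrides it
  carry <- setNames(rep(0, n), ids)
  pool <- setdiff(ids, c(enriched$case, enriched$control))
  carry_ids <- sample(pool, min(length(pool),
                                round(cfg$carryover_fraction * n)))
  carry[carry_ids] <- runif(length(carry_ids),
                            cfg$carryover_log2_range[1],
                            cfg$carryover_log2_range[2])

  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        fraction = c("input", "IP"),
                        cell_line = c("case", "control"),
                        stringsAsFactors = FALSE)
  design$condition <- "none"
  design$sample <- with(design, paste(cell_line, fraction, replicate,
                                      sep = "_"))
  design <- design[, c("sample", "cell_line", "fraction", "condition",
                       "replicate")]
  depth <- sim_depths(nrow(design), cfg$library_size_spread)
  names(depth) <- design$sample

  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(ids, design$sample))
  fc <- 2^cfg$enrichment_log2fc
  for (j in seq_len(nrow(design))) {
    mu <- base
    if (design$fraction[j] == "IP") {
      hit <- ids %in% enriched[[design$cell_line[j]]]
      mu <- mu * ifelse(hit, fc, 2^carry)
    }
    counts[, j] <- rnbinom(n, mu = mu * depth[j],
                           size = 1 / cfg$nb_dispersion)
  }
  list(counts = count_matrix(counts, design),
       truth = list(enriched_ids = enriched, depth_factors = depth))
}

#' Simulate non-overlapping gene models
#'
#' Genes are laid down left to right on each chromosome with random
#' intergenic gaps; each gene has 2-6 exons of 150-400 bp separated by
#' introns of 200-1500 bp, a random strand, and a biotype drawn from a
#' configurable class distribution (default matching a transcriptome
#' dominated by protein-coding genes and antisense lncRNAs).
#'
#' @param cfg a [sim_config()].
#' @param n_genes number of genes (default `cfg$n_genes`).
#' @param biotype_probs named probability vector over biotype classes.
#' @return A [gene_models()].
#' @export
simulate_gene_models <- function(cfg, n_genes = cfg$n_genes,
                                 biotype_probs = c(
                                   protein_coding = 0.38, antisense = 0.26,
                                   pseudogene = 0.13,
                                   processed_transcript = 0.08,
                                   lincRNA = 0.07, sense_intronic = 0.04,
                                   other = 0.04)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "models"))
  lens <- cfg$genome_lengths
  chroms <- names(lens)
  cursor <- setNames(rep(1000, length(lens)), chroms)

  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  chrom_i <- 1L
  for (g in seq_len(n_genes)) {
    n_ex <- sample(2:6, 1)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(200:1500, n_ex - 1, replace = TRUE)
              else integer(0)
    g_len <- sum(ex_len) + sum(in_len)
    if (g_len > min(lens))
      stopf("configuration error: gene longer than chromosome")
    placed <- FALSE
    for (try in seq_along(chroms)) {
      ch <- chroms[chrom_i]
      chrom_i <- chrom_i %% length(chroms) + 1L
      gap <- sample(500:2000, 1)
      start <- cursor[ch] + gap
      if (start + g_len <= lens[ch] - 1000) {
        cursor[ch] <- start + g_len
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("configuration error: genome too small for %d genes", n_genes)
    ex_start <- start + cumsum(c(0, head(ex_len, -1) + in_len))
    id <- sprintf("gene_%05d", g)
    genes[[g]] <- data.frame(
      gene_id = id, chrom = ch,
      strand = sample(c("+", "-"), 1),
      start = start, end = start + g_len,
      biotype = sample(names(biotype_probs), 1, prob = biotype_probs),
      stringsAsFactors = FALSE
    )
    exons[[g]] <- data.frame(gene_id = id, start = ex_start,
                             end = ex_start + ex_len,
                             stringsAsFactors = FALSE)
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

#' Simulate nascent-RNA exon/intron counts with planted retention shifts
#'
#' Three conditions x replicates: `ctrl` (baseline), `case`, and
#' `case_kd` (case plus simulated knock-down). Exon counts are
#' proportional to exon length and a per-gene transcription rate;
#' intron counts additionally carry the baseline retention level
#' `ir_base`. A planted fraction of introns has its retention
#' multiplied by `2^(+-ir_shift_log2)` in `case` (half shifted up, half
#' down); of those, `reversal_fraction` revert to baseline retention
#' under the knock-down while the rest keep the shifted level.
#'
#' @param cfg a [sim_config()].
#' @param models a [gene_models()] (default: simulated from `cfg`).
#' @return List with `counts` (feature x sample matrix), `design`,
#'   `feature_info` (for [retention_coefficient()]) and `truth`
#'   (`shifted`: data.frame intron_id/shift; `reverted`: intron ids).
#' @export
simulate_nascent_counts <- function(cfg, models = simulate_gene_models(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "nascent"))
  introns <- extract_introns(models)
  ex <- models$exons
  ex$feature_id <- paste0(ex$gene_id, ":exon_",
                          stats::ave(ex$start, ex$gene_id,
                                     FUN = seq_along))
  feature_info <- rbind(
    data.frame(feature_id = ex$feature_id, gene_id = ex$gene_id,
               type = "exon", length = ex$end - ex$start,
               stringsAsFactors = FALSE),
    data.frame(feature_id = introns$intron_id, gene_id = introns$gene_id,
               type = "intron", length = introns$length,
               stringsAsFactors = FALSE)
  )

  n_int <- nrow(introns)
  n_shift <- round(cfg$ir_shift_fraction * n_int)
  shifted_ids <- sample(introns$intron_id, n_shift)
  sign_up <- rep(c(1, -1), length.out = n_shift)
  shift <- setNames(rep(0, n_int), introns$intron_id)
  shift[shifted_ids] <- sign_up * cfg$ir_shift_log2
  reverted_ids <- sample(shifted_ids,
                         round(cfg$reversal_fraction * n_shift))

  conds <- c("ctrl", "case", "case_kd")
  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        condition = conds, stringsAsFactors = FALSE)
  design$sample <- with(design, paste(condition, replicate, sep = "_"))
  design$cell_line <- ifelse(design$condition == "ctrl", "control", "case")
  design$fraction <- "nascent"
  design <- design[, c("sample", "cell_line", "fraction", "condition",
                       "replicate")]
  depth <- sim_depths(nrow(design), cfg$library_size_spread)

  rate <- rlnorm(nrow(models$genes), 0, 0.5)
  names(rate) <- models$genes$gene_id
  size <- 1 / cfg$nb_dispersion
  per_bp <- cfg$baseline_mean / 300

  counts <- matrix(0L, nrow = nrow(feature_info), ncol = nrow(design),
                   dimnames = list(feature_info$feature_id, design$sample))
  ir_factor_for <- function(cond) {
    f <- 2^shift  # case level
    if (cond == "ctrl") f[] <- 1
    if (cond == "case_kd") f[names(f) %in% reverted_ids] <- 1
    f
  }
  is_exon <- feature_info$type == "exon"
  g_of <- feature_info$gene_id
  len <- feature_info$length
  gene_ids <- models$genes$gene_id
  for (j in seq_len(nrow(design))) {
    ## biological replicate noise acts on the per-gene transcription
    ## rate (gamma multiplier, mean 1, variance = dispersion) and hits
    ## exons and introns of a gene together, as in real nascent
    ## libraries -- the retention ratio cancels most of it; feature
    ## counts are then Poisson, so marginals stay negative-binomial
    gene_mult <- stats::rgamma(length(gene_ids), shape = size,
                               rate = size)
    names(gene_mult) <- gene_ids
    mu <- per_bp * len * rate[g_of] * gene_mult[g_of] * depth[j]
    f <- ir_factor_for(design$condition[j])
    mu[!is_exon] <- mu[!is_exon] * cfg$ir_base *
      f[feature_info$feature_id[!is_exon]]
    counts[, j] <- stats::rpois(length(mu), mu)
  }
  list(counts = counts, design = design, feature_info = feature_info,
       truth = list(
         shifted = data.frame(intron_id = shifted_ids,
                              shift = shift[shifted_ids],
                              stringsAsFactors = FALSE),
         reverted = reverted_ids
       ))
}

#' Simulate reference and query interval sets with planted co-location
#'
#' The reference set is uniform on the workspace. A `coloc_fraction` of
#' query intervals is placed with its midpoint within `coloc_distance`
#' bases of a randomly chosen reference midpoint; the remainder is
#' uniform.
#'
#' @param cfg a [sim_config()].
#' @param n_ref,n_query set sizes.
#' @param width interval width in bp.
#' @return List with `reference`, `query` ([interval_set()]s),
#'   `workspace` and `truth` (data.frame `query_id`, `ref_id`).
#' @export
simulate_interval_sets <- function(cfg, n_ref = 500, n_query = 500,
                                   width = 200) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "intervals"))
  lens <- cfg$genome_lengths
  uniform_set <- function(n, prefix) {
    ch <- sample(names(lens), n, replace = TRUE,
                 prob = lens / sum(lens))
    start <- floor(runif(n, 0, lens[ch] - width))
    interval_set(ch, start, start + width,
                 id = paste0(prefix, "_", seq_len(n)), genome = lens)
  }
  reference <- uniform_set(n_ref, "ref")
  n_col <- round(cfg$coloc_fraction * n_query)
  query <- uniform_set(n_query, "qry")
  truth <- NULL
  if (n_col > 0) {
    pick <- sample(nrow(reference), n_col, replace = TRUE)
    offset <- round(runif(n_col, -cfg$coloc_distance, cfg$coloc_distance))
    mid <- midpoints(reference)[pick] + offset
    start <- pmax(0, pmin(mid - floor(width / 2),
                          lens[reference$chrom[pick]] - width))
    query$chrom[seq_len(n_col)] <- reference$chrom[pick]
    query$start[seq_len(n_col)] <- start
    query$end[seq_len(n_col)] <- start + width
    truth <- data.frame(query_id = query$id[seq_len(n_col)],
                        ref_id = reference$id[pick],
                        stringsAsFactors = FALSE)
  }
  list(reference = reference, query = query,
       workspace = genome_workspace(lens),
       truth = truth %||% data.frame(query_id = character(0),
                                     ref_id = character(0)))
}

#' Simulate an LFQ protein-intensity matrix with a bait-dependent subset
#'
#' Log-normal intensities for two arms (`ctrl`, `kd`) x replicates,
#' with a per-replicate pull-down efficiency factor that the bait
#' normalization is expected to absorb. A planted subset of proteins
#' loses `reduction_log2` log2 units of intensity in the knock-down
#' arm; the bait itself is unaffected and present in every replicate.
#'
#' @param cfg a [sim_config()].
#' @param n_proteins number of proteins beside the bait.
#' @param dependent_fraction proportion of proteins planted as
#'   bait-dependent.
#' @param reduction_log2 planted intensity loss (log2) in the
#'   knock-down arm; 0 gives a null matrix.
#' @param noise_sd replicate noise on the log2 scale.
#' @param missing_rate proportion of non-bait intensities set missing.
#' @param bait_id rowname of the bait.
#' @return List with `matrix` (proteins x samples, NA = missing),
#'   `groups` (factor, levels `ctrl`, `kd`) and `truth` (dependent
#'   protein ids).
#' @export
simulate_lfq_matrix <- function(cfg, n_proteins = 300,
                                dependent_fraction = 0.7,
                                reduction_log2 = 2, noise_sd = 0.3,
                                missing_rate = 0, bait_id = "BAIT") {
  stopifnot(inherits(cfg, "sim_config"))
  assert_proportion(dependent_fraction, "dependent_fraction")
  assert_proportion(missing_rate, "missing_rate")
  set.seed(derive_seed(cfg$seed, "lfq"))
  ids <- sprintf("prot_%04d", seq_len(n_proteins))
  dependent <- sample(ids, round(dependent_fraction * n_proteins))
  reps <- cfg$n_replicates
  samples <- c(paste0("ctrl_", seq_len(reps)), paste0("kd_", seq_len(reps)))
  groups <- factor(rep(c("ctrl", "kd"), each = reps),
                   levels = c("ctrl", "kd"))

  base <- rnorm(n_proteins, mean = 25, sd = 2)
  col_eff <- rnorm(length(samples), 0, 0.25)  # pull-down efficiency
  m <- matrix(NA_real_, n_proteins + 1, length(samples),
              dimnames = list(c(bait_id, ids), samples))
  m[bait_id, ] <- 2^(30 + col_eff + rnorm(length(samples), 0, noise_sd / 4))
  for (j in seq_along(samples)) {
    eff <- ifelse(groups[j] == "kd" & ids %in% dependent,
                  -reduction_log2, 0)
    m[ids, j] <- 2^(base + col_eff[j] + eff +
                      rnorm(n_proteins, 0, noise_sd))
  }
  if (missing_rate > 0) {
    idx <- which(rownames(m) != bait_id)
    drop <- sample(length(idx) * ncol(m),
                   round(missing_rate * length(idx) * ncol(m)))
    mm <- m[idx, ]
    mm[drop] <- NA_real_
    m[idx, ] <- mm
  }
  list(matrix = m, groups = groups, bait_id = bait_id,
       truth = list(dependent = dependent))
}
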