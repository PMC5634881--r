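#' Gene model collection
#'
#' A light container for gene structures: a gene table (id, chromosome,
#' strand, span, biotype) plus an exon table. Coordinates are 0-based
#' half-open throughout (BED convention); GTF input/output converts at
#' the boundary. The TSS is the leftmost exon start on the + strand and
#' the rightmost exon end on the - strand.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `biotype`.
#' @param exons data.frame with columns `gene_id`, `start`, `end`.
#' @return List of class `gene_models` with elements `genes`, `exons`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end", "biotype")
                %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (any(exons$start >= exons$end)) stopf("exon with start >= end")
  bad <- !exons$gene_id %in% genes$gene_id
  if (any(bad)) stopf("exons reference unknown gene ids")
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Transcription start sites of a gene model collection
#'
#' @param models a [gene_models()].
#' @return data.frame `gene_id`, `chrom`, `strand`, `tss` (0-based
#'   position of the first transcribed base).
#' @export
gene_tss <- function(models) {
  g <- models$genes
  ex <- models$exons
  first <- vapply(g$gene_id, function(id) {
    e <- ex[ex$gene_id == id, ]
    if (g$strand[g$gene_id == id] == "+") min(e$start) else max(e$end) - 1
  }, numeric(1))
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = unname(first), stringsAsFactors = FALSE)
}

#' Derive intron intervals from exon structures
#'
#' Introns are the complement of the merged exons within the gene span:
#' overlapping or book-ended exon records are merged first, then the
#' gaps between consecutive merged exons become introns. Single-exon
#' genes yield no introns.
#'
#' @param models a [gene_models()].
#' @return data.frame with columns `intron_id` (`gene:intron_k`, ordered
#'   by genomic position), `gene_id`, `chrom`, `start`, `end`, `length`.
#' @export
extract_introns <- function(models) {
  out <- lapply(models$genes$gene_id, function(id) {
    e <- models$exons[models$exons$gene_id == id, ]
    g <- models$genes[models$genes$gene_id == id, ]
    ir <- IRanges::reduce(IRanges::IRanges(e$start + 1, e$end))
    gaps <- IRanges::gaps(ir,
                          start = min(IRanges::start(ir)),
                          end = max(IRanges::end(ir)))
    if (length(gaps) == 0) return(NULL)
    data.frame(
      intron_id = paste0(id, ":intron_", seq_along(gaps)),
      gene_id = id, chrom = g$chrom,
      start = IRanges::start(gaps) - 1, end = IRanges::end(gaps),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(intron_id = character(0), gene_id = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Intron retention coefficients
#'
#' For each intron and sample, the read density of the intron (reads per
#' base pair) divided by the pooled read density over all exons of the
#' same gene. A value near 1 means unspliced-like intronic coverage; 0
#' means no intronic reads. When a gene has zero exon reads in a sample
#' the coefficient is undefined and returned as NA for all its introns
#' in that sample.
#'
#' @param counts numeric matrix, features x samples; rownames are
#'   feature ids present in `feature_info`.
#' @param feature_info data.frame with columns `feature_id`, `gene_id`,
#'   `type` (`"exon"` or `"intron"`) and `length` (bp).
#' @return Numeric matrix, introns x samples, rownames = intron ids.
#' @export
retention_coefficient <- function(counts, feature_info) {
  stopifnot(all(c("feature_id", "gene_id", "type", "length")
                %in% names(feature_info)))
  counts <- as.matrix(counts)
  fi <- feature_info[match(rownames(counts), feature_info$feature_id), ]
  if (any(is.na(fi$feature_id)))
    stopf("count rows missing from `feature_info`")
  ex <- fi$type == "exon"
  ## per-gene exon density: sum(reads) / sum(length), per sample
  exon_reads <- rowsum(counts[ex, , drop = FALSE], fi$gene_id[ex])
  exon_len <- rowsum(fi$length[ex], fi$gene_id[ex])[, 1]
  exon_dens <- exon_reads / exon_len
  introns <- which(!ex)
  dens <- counts[introns, , drop = FALSE] / fi$length[introns]
  gd <- exon_dens[match(fi$gene_id[introns], rownames(exon_dens)), ,
                  drop = FALSE]
  ir <- dens / gd
  ir[gd == 0] <- NA_real_  # zero exon signal: undefined
  ir[dens == 0 & !is.na(gd) & gd > 0] <- 0
  rownames(ir) <- fi$feature_id[introns]
  ir
}

## bin labels for the cross-condition modulation coefficient; the
## spec'd edges are +-1.5 and +-2 with the middle bin open -- the value
## -1.5 itself is assigned to the lower flank so the bins tile the line
ir_bin <- function(x) {
  lv <- c("<-2", "[-2,-1.5]", "(-1.5,1.5)", "[1.5,2]", ">2")
  lab <- ifelse(x < -2, lv[1],
         ifelse(x <= -1.5, lv[2],
         ifelse(x < 1.5, lv[3],
         ifelse(x <= 2, lv[4], lv[5]))))
  factor(lab, levels = lv)
}

#' Differential intron retention between two conditions
#'
#' Per intron, a Welch two-sample t-test on the retention coefficients
#' across replicates, BH adjustment over testable introns, and a
#' modulation coefficient: the log2 ratio of mean retention in condition
#' A over condition B. A positive modulation means higher retention in A
#' (reduced splicing efficiency); swapping the conditions negates it.
#' When one of the means is zero, the smallest positive retention value
#' observed in either table is added to both means before the log so
#' the coefficient stays finite (flagged `zero_mean`). Introns whose
#' replicate values are constant in both conditions are flagged
#' `zero_variance` and not tested.
#'
#' @param ir_a,ir_b retention matrices (introns x replicates) from
#'   [retention_coefficient()], same rownames.
#' @param fdr BH cutoff for the `significant` flag (default 0.05).
#' @return A `retention_table` data.frame: `intron_id`, `mean_ir_a`,
#'   `mean_ir_b`, `modulation`, `p_raw`, `p_adj`, `significant`, `bin`,
#'   `flag`.
#' @export
differential_retention <- function(ir_a, ir_b, fdr = 0.05) {
  stopifnot(identical(rownames(ir_a), rownames(ir_b)))
  ma <- rowMeans(ir_a)
  mb <- rowMeans(ir_b)
  va <- apply(ir_a, 1, var)
  vb <- apply(ir_b, 1, var)
  na <- ncol(ir_a)
  nb <- ncol(ir_b)

  floor_ir <- suppressWarnings(min(c(ir_a[ir_a > 0], ir_b[ir_b > 0]),
                                   na.rm = TRUE))
  if (!is.finite(floor_ir)) floor_ir <- 1e-6
  zero_mean <- !is.na(ma) & !is.na(mb) & (ma == 0 | mb == 0)
  modulation <- ifelse(zero_mean,
                       log2((ma + floor_ir) / (mb + floor_ir)),
                       log2(ma / mb))

  se <- sqrt(va / na + vb / nb)
  tstat <- (ma - mb) / se
  df <- (va / na + vb / nb)^2 /
    (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * pt(-abs(tstat), df)
  zero_var <- !is.na(se) & se == 0
  p[zero_var] <- NA_real_
  flag <- ifelse(is.na(ma) | is.na(mb), "undefined",
                 ifelse(zero_var, "zero_variance",
                        ifelse(zero_mean, "zero_mean", "")))
  p[flag == "undefined"] <- NA_real_
  modulation[flag == "undefined"] <- NA_real_

  padj <- bh_adjust(p)
  out <- data.frame(
    intron_id = rownames(ir_a),
    mean_ir_a = ma, mean_ir_b = mb,
    modulation = modulation,
    p_raw = p, p_adj = padj,
    significant = !is.na(padj) & padj <= fdr,
    bin = ir_bin(modulation),
    flag = flag,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("retention_table", "data.frame")
  out
}

#' Knock-down reversal analysis of retention events
#'
#' Takes the significant retention events of a primary contrast (e.g.
#' case vs control cell line) and asks, per modulation bin, in what
#' fraction of events the knock-down contrast moves the coefficient the
#' opposite way. By default a reversal requires the knock-down
#' modulation to be significant (adjusted p <= `fdr`) and of opposite
#' sign; set `require_significant = FALSE` to count sign flips alone.
#' Empty bins report `NA`, never 0.
#'
#' @param er_events `retention_table` of the primary contrast.
#' @param kd_events `retention_table` of the knock-down contrast,
#'   computed on (at least) the same introns.
#' @param fdr significance cutoff applied to the knock-down events.
#' @param require_significant require knock-down significance for a
#'   reversal call.
#' @return data.frame with one row per bin: `bin`, `n_events`,
#'   `n_reverted`, `fraction`, `percent`.
#' @export
reversal_analysis <- function(er_events, kd_events, fdr = 0.05,
                              require_significant = TRUE) {
  ev <- er_events[er_events$significant, , drop = FALSE]
  idx <- match(ev$intron_id, kd_events$intron_id)
  kd_mod <- kd_events$modulation[idx]
  kd_sig <- kd_events$p_adj[idx] <= fdr
  reverted <- !is.na(kd_mod) & sign(kd_mod) == -sign(ev$modulation) &
    (!require_significant | (!is.na(kd_sig) & kd_sig))
  bins <- levels(ir_bin(0))
  out <- do.call(rbind, lapply(bins, function(b) {
    in_bin <- as.character(ev$bin) == b
    n <- sum(in_bin)
    k <- sum(reverted[in_bin])
    data.frame(bin = b, n_events = n, n_reverted = k,
               fraction = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$percent <- round_half_up(100 * out$fraction)
  rownames(out) <- NULL
  out
}

#' Filter events against a control event set
#'
#' Set difference on intron ids: events of A not observed in B. Inputs
#' may be `retention_table`s (their significant events are used) or
#' plain id vectors.
#'
#' @param events_a,events_b `retention_table`s or character vectors.
#' @return Character vector of A-specific intron ids.
#' @export
event_filter_vs_control <- function(events_a, events_b) {
  ids <- function(x) {
    if (inherits(x, "retention_table"))
      x$intron_id[x$significant]
    else as.character(x)
  }
  setdiff(ids(events_a), ids(events_b))
}
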