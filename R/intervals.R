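#' Genomic interval set
#'
#' A data.frame of strand-aware intervals (0-based, half-open) on a
#' declared genome workspace. Interval bounds are validated against the
#' chromosome lengths when a workspace is attached.
#'
#' @param chrom,start,end vectors describing the intervals; 0-based
#'   half-open coordinates.
#' @param id interval identifiers (defaults to `iv_1`, `iv_2`, ...).
#' @param score,strand optional BED score and strand columns.
#' @param genome optional named numeric vector of chromosome lengths.
#' @return data.frame of class `interval_set` with attribute `genome`.
#' @export
interval_set <- function(chrom, start, end, id = NULL, score = NULL,
                         strand = NULL, genome = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n)
  id <- id %||% paste0("iv_", seq_len(n))
  score <- score %||% rep(0, n)
  strand <- strand %||% rep(".", n)
  if (any(start < 0) || any(start >= end))
    stopf("intervals must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    if (any(!chrom %in% names(genome)))
      stopf("interval chromosome not present in genome workspace")
    if (any(end > genome[chrom]))
      stopf("interval end beyond chromosome length")
  }
  structure(
    data.frame(chrom = as.character(chrom), start = as.numeric(start),
               end = as.numeric(end), id = as.character(id),
               score = score, strand = as.character(strand),
               stringsAsFactors = FALSE),
    genome = genome,
    class = c("interval_set", "data.frame")
  )
}

#' Genome workspace
#'
#' Chromosome lengths plus an optional segment annotation (labels such
#' as `promoter`, `exonic`, `intronic`, `intergenic`, `5UTR`, `3UTR`,
#' `TSS`) used by [segment_enrichment()] and [annotate_to_tss()].
#'
#' @param lengths named numeric vector of chromosome lengths (bp).
#' @param segments optional data.frame with columns `chrom`, `start`,
#'   `end`, `label` (0-based half-open), within chromosome bounds.
#' @return List of class `genome_workspace`.
#' @export
genome_workspace <- function(lengths, segments = NULL) {
  stopifnot(is.numeric(lengths), !is.null(names(lengths)), all(lengths > 0))
  if (!is.null(segments)) {
    stopifnot(all(c("chrom", "start", "end", "label") %in% names(segments)))
    if (any(!segments$chrom %in% names(lengths)) ||
        any(segments$start < 0) ||
        any(segments$end > lengths[segments$chrom]))
      stopf("segments must lie within chromosome bounds")
  }
  structure(list(lengths = lengths, segments = segments),
            class = "genome_workspace")
}

## interval_set (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x, genome = NULL) {
  genome <- genome %||% attr(x, "genome")
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    id = x$id
  )
}

midpoints <- function(x) floor((x$start + x$end) / 2)

#' Read / write BED interval files
#'
#' Reads BED3-BED6 (tab-separated, 0-based half-open). `track`,
#' `browser` and `#` header lines are skipped with a warning. Malformed
#' records (fewer than 3 fields, non-numeric or inverted coordinates,
#' coordinates beyond the declared genome) abort with the offending
#' line number. Writing emits the same number of columns that were
#' read, so a canonical file round-trips byte-identically.
#'
#' @param path file path.
#' @param genome optional named vector of chromosome lengths used to
#'   validate coordinates.
#' @return `read_bed()` returns an [interval_set()] with attribute
#'   `bed_cols` (number of columns seen).
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  is_header <- grepl("^(track|browser|#)", lines)
  if (any(is_header))
    warning(sprintf("%s: skipped %d header line(s)", path, sum(is_header)))
  keep <- which(!is_header & nzchar(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- if (length(fields)) min(vapply(fields, length, integer(1))) else 3L
  ncols <- min(ncols, 6L)
  rec <- function(i, j) fields[[i]][j]
  n <- length(fields)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  id <- character(n); score <- numeric(n); strand <- character(n)
  for (i in seq_len(n)) {
    ln <- keep[i]
    f <- fields[[i]]
    if (length(f) < 3)
      stopf("%s line %d: expected at least 3 tab-separated fields", path, ln)
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stopf("%s line %d: non-numeric coordinates", path, ln)
    if (s < 0 || s >= e)
      stopf("%s line %d: start must satisfy 0 <= start < end", path, ln)
    if (!is.null(genome)) {
      if (!f[1] %in% names(genome))
        stopf("%s line %d: unknown chromosome %s", path, ln, f[1])
      if (e > genome[f[1]])
        stopf("%s line %d: end %s beyond chromosome length %s",
              path, ln, format(e), format(genome[f[1]]))
    }
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    id[i] <- if (length(f) >= 4) f[4] else paste0("iv_", i)
    score[i] <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
    strand[i] <- if (length(f) >= 6) f[6] else "."
  }
  out <- interval_set(chrom, start, end, id, score, strand, genome)
  attr(out, "bed_cols") <- ncols
  out
}

#' @param x an [interval_set()].
#' @param n_cols number of BED columns to write (3-6); defaults to the
#'   number seen at read time, else 6.
#' @rdname read_bed
#' @export
write_bed <- function(x, path, n_cols = NULL) {
  n_cols <- n_cols %||% attr(x, "bed_cols") %||% 6L
  fmt_num <- function(v) format(v, scientific = FALSE, trim = TRUE)
  cols <- list(x$chrom, fmt_num(x$start), fmt_num(x$end),
               x$id, fmt_num(x$score), x$strand)[seq_len(n_cols)]
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(x)
}

#' Annotate peaks to the nearest TSS
#'
#' For each peak, finds the nearest transcription start site, reports
#' the signed midpoint-to-TSS distance (sign flipped on the - strand so
#' upstream is always negative) and labels the peak `promoter` when the
#' distance falls within the promoter window (default -1000 to +100
#' bases around the TSS). Peaks outside the window are labelled by
#' overlap of their midpoint with the workspace segments using the
#' priority exon > intron > intergenic.
#'
#' @param peaks an [interval_set()].
#' @param models a [gene_models()] supplying TSS positions.
#' @param promoter_window numeric length-2, bases around the TSS
#'   (inclusive at both ends).
#' @param workspace optional [genome_workspace()] whose segments supply
#'   non-promoter labels.
#' @return data.frame: `id`, `nearest_gene`, `distance`, `label`.
#' @export
annotate_to_tss <- function(peaks, models, promoter_window = c(-1000, 100),
                            workspace = NULL) {
  tss <- gene_tss(models)
  mid <- midpoints(peaks)
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    on_chrom <- tss$chrom == peaks$chrom[i]
    if (!any(on_chrom))
      return(data.frame(id = peaks$id[i], nearest_gene = NA_character_,
                        distance = NA_real_, label = "intergenic",
                        stringsAsFactors = FALSE))
    cand <- tss[on_chrom, ]
    d <- mid[i] - cand$tss
    d <- ifelse(cand$strand == "-", -d, d)
    j <- which.min(abs(d))
    data.frame(id = peaks$id[i], nearest_gene = cand$gene_id[j],
               distance = d[j], label = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  in_prom <- !is.na(out$distance) &
    out$distance >= promoter_window[1] & out$distance <= promoter_window[2]
  out$label[in_prom] <- "promoter"
  need <- which(is.na(out$label))
  if (length(need)) {
    segs <- if (!is.null(workspace)) workspace$segments else NULL
    priority <- c("exonic", "exon", "intronic", "intron")
    for (i in need) {
      lab <- "intergenic"
      if (!is.null(segs)) {
        hit <- segs$label[segs$chrom == peaks$chrom[i] &
                            segs$start <= mid[i] & segs$end > mid[i]]
        for (p in priority) if (p %in% hit) { lab <- p; break }
        if (lab == "intergenic" && length(hit)) lab <- hit[1]
      }
      out$label[i] <- lab
    }
  }
  rownames(out) <- NULL
  out
}

#' Midpoint proximity pairing of two interval sets
#'
#' Pairs (a, b) whose midpoints lie within `window` bases of each other
#' (inclusive) on the same chromosome. An interval of A may pair with
#' several of B; the summary reports both the number of pairs and the
#' number of distinct A intervals paired.
#'
#' @param set_a,set_b [interval_set()]s.
#' @param window maximum midpoint distance in bp (default 1000).
#' @return data.frame of pairs (`id_a`, `id_b`, `distance`), with
#'   attributes `n_pairs` and `n_distinct_a`.
#' @export
proximity_pairs <- function(set_a, set_b, window = 1000) {
  ga <- GenomicRanges::GRanges(set_a$chrom,
                               IRanges::IRanges(midpoints(set_a) + 1,
                                                width = 1))
  gb <- GenomicRanges::GRanges(set_b$chrom,
                               IRanges::IRanges(midpoints(set_b) + 1,
                                                width = 1))
  hits <- GenomicRanges::findOverlaps(ga, gb, maxgap = window + 1)
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  d <- abs(midpoints(set_a)[qa] - midpoints(set_b)[qb])
  keep <- d <= window
  out <- data.frame(id_a = set_a$id[qa[keep]], id_b = set_b$id[qb[keep]],
                    distance = d[keep], stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pairs") <- nrow(out)
  attr(out, "n_distinct_a") <- length(unique(out$id_a))
  out
}

#' Exact (>= 1 bp) interval intersection
#'
#' All pairs of intervals from the two sets sharing at least one base,
#' half-open semantics: `[0,100)` and `[100,200)` do not overlap.
#'
#' @param set_a,set_b [interval_set()]s.
#' @return data.frame `id_a`, `id_b`, `overlap_bp`.
#' @export
intersect_exact <- function(set_a, set_b) {
  ga <- as_granges(set_a)
  gb <- as_granges(set_b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1)
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  ov <- pmin(set_a$end[qa], set_b$end[qb]) -
    pmax(set_a$start[qa], set_b$start[qb])
  out <- data.frame(id_a = set_a$id[qa], id_b = set_b$id[qb],
                    overlap_bp = ov, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## place intervals uniformly within their chromosomes, preserving
## lengths and per-chromosome counts; `sims` placements at once, each
## mapped to an artificial "<sim>|<chrom>" seqname so one findOverlaps
## call covers all simulations
random_placement_granges <- function(x, lengths, sims) {
  w <- x$end - x$start
  if (any(w > lengths[x$chrom]))
    stopf("placement error: interval longer than its chromosome")
  n <- nrow(x)
  max_start <- lengths[x$chrom] - w
  starts <- floor(runif(n * sims, min = 0, max = rep(max_start + 1, sims)))
  starts <- pmin(starts, rep(max_start, sims))  # guard the open edge
  sim_id <- rep(seq_len(sims), each = n)
  GenomicRanges::GRanges(
    paste0(sim_id, "|", rep(x$chrom, sims)),
    IRanges::IRanges(start = starts + 1, width = rep(w, sims))
  )
}

#' Permutation test of interval-set overlap
#'
#' The observed statistic is the number of distinct intervals of A
#' overlapping (>= 1 bp) at least one interval of B. Under the null,
#' intervals are re-placed uniformly at random within their own
#' chromosomes, preserving lengths and per-chromosome counts; by
#' default both sets are shuffled. The p-value uses the plus-one
#' estimator `p = (1 + #{sim >= observed}) / (1 + n_sims)` and is
#' therefore never zero.
#'
#' @param set_a,set_b [interval_set()]s.
#' @param workspace a [genome_workspace()].
#' @param n_sims number of random placements (default 1000; scale up
#'   for publication-grade p-values).
#' @param shuffle_both shuffle B as well as A (default TRUE).
#' @param seed integer seed for the placement RNG.
#' @return List: `observed`, `null_mean`, `p_value`, `n_sims`.
#' @export
permutation_overlap_test <- function(set_a, set_b, workspace,
                                     n_sims = 1000, shuffle_both = TRUE,
                                     seed = 1) {
  lengths <- workspace$lengths
  obs <- length(unique(intersect_exact(set_a, set_b)$id_a))
  set.seed(seed)
  chunk <- max(1L, floor(2e5 / max(nrow(set_a) + nrow(set_b), 1)))
  sims_left <- n_sims
  null_counts <- numeric(0)
  offset <- 0L
  while (sims_left > 0) {
    k <- min(chunk, sims_left)
    ga <- random_placement_granges(set_a, lengths, k)
    gb <- if (shuffle_both) random_placement_granges(set_b, lengths, k)
    else {
      fixed <- as_granges(set_b)
      rep_b <- rep(seq_len(k), each = nrow(set_b))
      GenomicRanges::GRanges(
        paste0(rep_b, "|", rep(set_b$chrom, k)),
        IRanges::IRanges(rep(set_b$start + 1, k), rep(set_b$end, k))
      )
    }
    hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1)
    qa <- unique(S4Vectors::queryHits(hits))
    sim_of_a <- rep(seq_len(k), each = nrow(set_a))
    cnt <- tabulate(sim_of_a[qa], nbins = k)
    null_counts <- c(null_counts, cnt)
    sims_left <- sims_left - k
    offset <- offset + k
  }
  list(observed = obs,
       null_mean = mean(null_counts),
       p_value = (1 + sum(null_counts >= obs)) / (1 + n_sims),
       n_sims = n_sims)
}

#' Segment-class enrichment of a peak set
#'
#' For each segment label of the workspace, compares the observed
#' overlap of the peaks with that class against random placements of
#' the peaks within their chromosomes. Overlap is measured in base
#' pairs by default (`measure = "count"` counts peaks touching the
#' class instead). Fold = observed / expected (NA when the expected
#' overlap is zero); the empirical p-value is two-sided with the
#' plus-one correction, and q-values are BH across classes. A class is
#' flagged `enriched` when fold > 2 and q <= 0.05.
#'
#' @param peaks an [interval_set()].
#' @param workspace a [genome_workspace()] with segments.
#' @param n_sims number of random placements (default 1000).
#' @param seed integer seed.
#' @param measure `"bp"` (default) or `"count"`.
#' @return data.frame per class: `label`, `observed`, `expected`,
#'   `fold`, `p_value`, `q_value`, `enriched`.
#' @export
segment_enrichment <- function(peaks, workspace, n_sims = 1000, seed = 1,
                               measure = c("bp", "count")) {
  measure <- match.arg(measure)
  segs <- workspace$segments
  if (is.null(segs)) stopf("workspace carries no segment annotation")
  labels <- sort(unique(segs$label))

  overlap_by_label <- function(ph, sh, ov, sims, sim_of_peak) {
    ## ph/sh: hit indices into peaks/segments; ov: bp overlaps
    m <- matrix(0, nrow = sims, ncol = length(labels),
                dimnames = list(NULL, labels))
    if (!length(ph)) return(m)
    lab <- segs$label[sh]
    sim <- sim_of_peak[ph]
    if (measure == "bp") {
      agg <- rowsum(ov, group = paste(sim, lab, sep = "\r"))
    } else {
      key <- !duplicated(paste(sim, ph, lab))  # one count per peak/label
      agg <- rowsum(rep(1, sum(key)),
                    group = paste(sim, lab, sep = "\r")[key])
    }
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    for (r in seq_along(parts))
      m[as.integer(parts[[r]][1]), parts[[r]][2]] <- agg[r, 1]
    m
  }

  seg_gr_for <- function(sims) GenomicRanges::GRanges(
    paste0(rep(seq_len(sims), each = nrow(segs)), "|", rep(segs$chrom, sims)),
    IRanges::IRanges(rep(segs$start + 1, sims), rep(segs$end, sims))
  )

  ## observed
  g_obs <- GenomicRanges::GRanges(paste0("1|", peaks$chrom),
                                  IRanges::IRanges(peaks$start + 1,
                                                   peaks$end))
  gs1 <- seg_gr_for(1)
  h <- GenomicRanges::findOverlaps(g_obs, gs1, minoverlap = 1)
  ph <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
  ov <- pmin(peaks$end[ph], segs$end[sh]) - pmax(peaks$start[ph],
                                                 segs$start[sh])
  observed <- overlap_by_label(ph, sh, ov, 1, rep(1L, nrow(peaks)))[1, ]

  ## null placements, chunked
  set.seed(seed)
  chunk <- max(1L, floor(2e5 / max(nrow(peaks) + nrow(segs), 1)))
  null_mat <- matrix(0, nrow = 0, ncol = length(labels))
  sims_left <- n_sims
  while (sims_left > 0) {
    k <- min(chunk, sims_left)
    gp <- random_placement_granges(peaks, workspace$lengths, k)
    gs <- seg_gr_for(k)
    h <- GenomicRanges::findOverlaps(gp, gs, minoverlap = 1)
    ph <- S4Vectors::queryHits(h); sh0 <- S4Vectors::subjectHits(h)
    sh <- (sh0 - 1) %% nrow(segs) + 1  # back to segment row
    ps <- GenomicRanges::start(gp)[ph] - 1
    pe <- GenomicRanges::end(gp)[ph]
    ov <- pmin(pe, segs$end[sh]) - pmax(ps, segs$start[sh])
    sim_of_peak <- rep(seq_len(k), each = nrow(peaks))
    null_mat <- rbind(null_mat,
                      overlap_by_label(ph, sh, ov, k, sim_of_peak))
    sims_left <- sims_left - k
  }

  expected <- colMeans(null_mat)
  fold <- ifelse(expected > 0, observed / expected, NA_real_)
  p_hi <- (1 + colSums(sweep(null_mat, 2, observed, ">="))) / (1 + n_sims)
  p_lo <- (1 + colSums(sweep(null_mat, 2, observed, "<="))) / (1 + n_sims)
  p <- pmin(1, 2 * pmin(p_hi, p_lo))
  q <- bh_adjust(p)
  out <- data.frame(label = labels, observed = unname(observed),
                    expected = unname(expected), fold = unname(fold),
                    p_value = unname(p), q_value = unname(q),
                    enriched = !is.na(fold) & fold > 2 & q <= 0.05,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
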