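#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over
#' reference features, of the ratio between the feature's count in that
#' sample and its geometric mean across samples. Reference features are
#' those with strictly positive counts in every sample (the geometric
#' mean of anything containing a zero is zero and would give an
#' undefined ratio).
#'
#' @param m a [count_matrix()] or a bare numeric matrix.
#' @return Named numeric vector of positive factors, one per sample.
#' @examples
#' size_factors(matrix(c(100, 10, 40, 200, 20, 80), 3, 2,
#'                     dimnames = list(paste0("g", 1:3), c("a", "b"))))
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stopf(paste("normalization error: no reference feature -- every feature",
                "has a zero count in at least one sample"))
  x <- counts[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(x)))
  apply(x / geo, 2, median)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' clipped to \[0, 1\]. NA p-values propagate as NA and do not count
#' towards the number of tests.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Expression detection filter
#'
#' A feature counts as expressed when it reaches `min_reads` reads,
#' boundary inclusive. By default reads are summed across all samples of
#' the matrix; `per_sample = TRUE` instead requires the maximum single
#' sample to reach the threshold.
#'
#' @param m a [count_matrix()] or numeric matrix.
#' @param min_reads detection threshold (default 10).
#' @param per_sample use the per-sample maximum instead of the total.
#' @return Character vector of detected feature ids.
#' @export
expression_filter <- function(m, min_reads = 10, per_sample = FALSE) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  stat <- if (per_sample) apply(counts, 1, max) else rowSums(counts)
  rownames(counts)[stat >= min_reads]
}

## method-of-moments NB dispersion pooled across the two groups,
## floored; normalized counts in, scalar per feature out
mom_dispersion <- function(a, b, min_disp = 1e-8) {
  est <- function(x) {
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  }
  da <- est(a)
  db <- est(b)
  wa <- ncol(a) - 1
  wb <- ncol(b) - 1
  d <- (ifelse(is.na(da), 0, da) * wa + ifelse(is.na(db), 0, db) * wb) /
    (wa + wb)
  pmax(d, min_disp)
}

#' Enrichment test between two sample groups
#'
#' Computes a per-feature enrichment factor (EF), the log2 ratio of mean
#' normalized counts in group A over group B, together with a
#' negative-binomial Wald p-value. This is a deliberately simple,
#' documented surrogate for a full shrinkage-based differential engine:
#' dispersion is a per-feature method-of-moments estimate (floored at
#' `min_disp`), the Wald statistic is referred to a t distribution with
#' Satterthwaite degrees of freedom to keep small-replicate designs
#' honest, and no outlier filtering or shrinkage is applied.
#'
#' EF is computed without pseudocount whenever both group means are
#' positive; when one of them is zero, `pseudocount` is added to both so
#' that the displayed EF stays finite. Features whose counts are all
#' zero in both groups are flagged, given `ef = NA` and `p_raw = 1`.
#'
#' @param m a [count_matrix()].
#' @param contrast length-2 character vector `(A, B)` naming the values
#'   of the `by` design column to contrast (EF is A over B), e.g.
#'   `c("IP", "input")`.
#' @param by design column holding the contrast: `"fraction"` (default)
#'   or `"condition"`.
#' @param cell_line optional cell line to subset to before testing.
#' @param pseudocount added to both means only when one of them is zero
#'   (default 0.5).
#' @param min_disp dispersion floor (default 1e-8).
#' @param min_reads detection threshold forwarded to
#'   [expression_filter()], computed over the contrasted samples.
#' @return An `enrichment_table` data.frame with columns `feature_id`,
#'   `base_mean`, `ef`, `p_raw`, `p_adj`, `detected`, `flag`.
#' @export
enrichment_test <- function(m, contrast, by = c("fraction", "condition"),
                            cell_line = NULL, pseudocount = 0.5,
                            min_disp = 1e-8, min_reads = 10) {
  by <- match.arg(by)
  stopifnot(length(contrast) == 2)
  if (!is.null(cell_line)) m <- subset_samples(m, cell_line = cell_line)
  grp <- m$design[[by]]
  in_a <- grp == contrast[1]
  in_b <- grp == contrast[2]
  if (!any(in_a) || !any(in_b))
    stopf("contrast groups must each have at least one sample (%s vs %s)",
          contrast[1], contrast[2])
  sub <- m$counts[, in_a | in_b, drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  a <- norm[, grp[in_a | in_b] == contrast[1], drop = FALSE]
  b <- norm[, grp[in_a | in_b] == contrast[2], drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)

  ef <- ifelse(ma > 0 & mb > 0, log2(ma / mb),
               log2((ma + pseudocount) / (mb + pseudocount)))
  ef[ma == 0 & mb == 0] <- NA_real_

  disp <- mom_dispersion(a, b, min_disp)
  ## Var(log mean) by the delta method under Var(y) = mu + disp mu^2
  va <- 1 / (na * ma) + disp / na
  vb <- 1 / (nb * mb) + disp / nb
  w <- (log(ma) - log(mb)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / max(na - 1, 1) + vb^2 / max(nb - 1, 1))
  p <- 2 * pt(-abs(w), df = df)
  degenerate <- ma == 0 & mb == 0
  untestable <- !degenerate & (ma == 0 | mb == 0)
  p[degenerate] <- 1
  p[untestable] <- NA_real_
  flag <- ifelse(degenerate, "all_zero",
                 ifelse(untestable, "one_group_zero", ""))

  out <- data.frame(
    feature_id = rownames(sub),
    base_mean = rowMeans(norm),
    ef = ef,
    p_raw = p,
    p_adj = bh_adjust(p),
    detected = rownames(sub) %in% expression_filter(sub, min_reads),
    flag = flag,
    stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- contrast
  attr(out, "by") <- by
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Differentially transcribed features
#'
#' Applies [enrichment_test()] to a condition contrast and keeps the
#' features passing an absolute fold-change cut and an FDR cut, with
#' their direction.
#'
#' @param m a [count_matrix()].
#' @param contrast length-2 character vector of condition values (A, B).
#' @param fc_cut linear fold-change cutoff (default 1.5); a feature must
#'   satisfy |log2FC| >= log2(fc_cut).
#' @param fdr BH-adjusted p-value cutoff (default 0.05).
#' @param ... forwarded to [enrichment_test()].
#' @return Subset of the enrichment table with a `direction` column
#'   (`"up"`/`"down"`, A relative to B).
#' @export
differential_transcription <- function(m, contrast, fc_cut = 1.5,
                                       fdr = 0.05, ...) {
  tab <- enrichment_test(m, contrast, by = "condition", ...)
  keep <- !is.na(tab$ef) & !is.na(tab$p_adj) &
    abs(tab$ef) >= log2(fc_cut) & tab$p_adj <= fdr
  out <- tab[keep, , drop = FALSE]
  out$direction <- ifelse(out$ef > 0, "up", "down")
  rownames(out) <- NULL
  out
}
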