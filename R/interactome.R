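#' Bait normalization of an LFQ intensity matrix
#'
#' Divides every intensity by the bait protein's intensity in the same
#' replicate (column), so relative abundances are comparable across
#' pull-downs of varying efficiency. The bait row becomes 1 everywhere;
#' the operation is idempotent. The bait must be quantified in every
#' replicate -- a missing bait intensity aborts with the replicate
#' named.
#'
#' @param m numeric matrix, proteins x samples; rownames are protein
#'   ids, NA marks a missing intensity.
#' @param bait_id rowname of the bait protein.
#' @return The normalized matrix.
#' @export
bait_normalize <- function(m, bait_id) {
  m <- as.matrix(m)
  if (!bait_id %in% rownames(m))
    stopf("bait protein %s not present in the matrix", bait_id)
  bait <- m[bait_id, ]
  if (anyNA(bait)) {
    miss <- colnames(m)[is.na(bait)] %||% which(is.na(bait))
    stopf("bait %s intensity missing in replicate(s): %s",
          bait_id, paste(miss, collapse = ", "))
  }
  if (any(bait <= 0)) stopf("bait intensities must be positive")
  sweep(m, 2, bait, "/")
}

## Welch t statistics for every row of x between the two column groups;
## rows with < 2 non-missing values in either group get NA
row_welch_t <- function(x, in_a, in_b) {
  stat <- function(cols) {
    v <- x[, cols, drop = FALSE]
    n <- rowSums(!is.na(v))
    m <- rowMeans(v, na.rm = TRUE)
    s2 <- apply(v, 1, var, na.rm = TRUE)
    list(n = n, m = m, s2 = s2)
  }
  a <- stat(in_a); b <- stat(in_b)
  ok <- a$n >= 2 & b$n >= 2
  se <- sqrt(a$s2 / a$n + b$s2 / b$n)
  t <- (a$m - b$m) / se
  t[!ok | is.na(se) | se == 0] <- NA_real_
  t
}

#' Two-sample t-test with permutation-based FDR
#'
#' Per-protein Welch t-test on log2 bait-normalized intensities between
#' two sample groups, with a SAM-style permutation FDR: group labels
#' are permuted (all distinct splits enumerated when their number is at
#' most `enum_max`, otherwise `n_perms` random splits), and for each
#' protein's observed |t| the FDR is the median, over permutations, of
#' the number of permuted |t| values at or above it, divided by the
#' number of observed |t| values at or above it. Proteins with fewer
#' than two non-missing intensities in either group are not tested.
#'
#' @param norm bait-normalized intensity matrix (proteins x samples).
#' @param groups factor/character of length `ncol(norm)` with exactly
#'   two levels; the reported `log2_ratio` is the second level minus
#'   the first (call with levels `c(control, treatment)` so the ratio
#'   reads treatment vs control).
#' @param fdr_cut FDR threshold for the `significant` flag (default
#'   0.01).
#' @param n_perms number of random permutations when enumeration is not
#'   feasible.
#' @param seed RNG seed for sampled permutations.
#' @param enum_max enumerate all distinct splits when `choose(n, n_a)`
#'   is at most this (default 1000); enumeration makes the FDR
#'   deterministic.
#' @param log2_transform log2 the intensities before testing (default
#'   TRUE; set FALSE if already on log scale).
#' @return A `diff_table` data.frame: `protein_id`, `log2_ratio`,
#'   `t_stat`, `fdr`, `significant`, `tested`.
#' @export
permutation_fdr_test <- function(norm, groups, fdr_cut = 0.01,
                                 n_perms = 1000, seed = 1,
                                 enum_max = 1000, log2_transform = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stopf("`groups` must have exactly two levels")
  if (length(groups) != ncol(norm))
    stopf("`groups` length must match the number of samples")
  x <- if (log2_transform) log2(norm) else norm
  lv <- levels(groups)
  in_a <- which(groups == lv[1])
  in_b <- which(groups == lv[2])

  t_obs <- row_welch_t(x, in_a, in_b)
  mean_b <- rowMeans(x[, in_b, drop = FALSE], na.rm = TRUE)
  mean_a <- rowMeans(x[, in_a, drop = FALSE], na.rm = TRUE)
  ratio <- mean_b - mean_a

  n <- ncol(x)
  na <- length(in_a)
  n_all <- choose(n, na)
  if (n_all <= enum_max) {
    splits <- combn(n, na, simplify = FALSE)
  } else {
    set.seed(seed)
    splits <- replicate(n_perms, sample(n, na), simplify = FALSE)
  }

  abs_obs <- abs(t_obs)
  tested <- !is.na(abs_obs)
  th <- abs_obs[tested]
  ## counts of permuted |t| >= each observed |t|, per permutation;
  ## #{v >= x} = length(v) - #{v < x} via findInterval on sorted v
  n_geq <- function(v, x) length(v) - findInterval(x, v, left.open = TRUE)
  exceed <- vapply(splits, function(ia) {
    tp <- abs(row_welch_t(x, ia, setdiff(seq_len(n), ia)))
    n_geq(sort(tp[!is.na(tp)]), th)
  }, numeric(sum(tested)))
  exceed <- matrix(exceed, nrow = sum(tested))
  n_called <- n_geq(sort(th), th)
  fdr_tested <- pmin(1, apply(exceed, 1, median) / n_called)

  fdr <- rep(NA_real_, nrow(x))
  fdr[tested] <- fdr_tested
  out <- data.frame(
    protein_id = rownames(x),
    log2_ratio = ratio,
    t_stat = t_obs,
    fdr = fdr,
    significant = !is.na(fdr) & fdr <= fdr_cut,
    tested = tested,
    stringsAsFactors = FALSE
  )
  attr(out, "n_permutations") <- length(splits)
  attr(out, "enumerated") <- n_all <= enum_max
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Dependence summary of an interactome
#'
#' Fraction of quantified interactors whose association is
#' significantly reduced in the perturbation arm (significant and
#' negative log2 ratio). Percentages are rounded half away from zero.
#'
#' @param diff a `diff_table` from [permutation_fdr_test()].
#' @param interactors optional character vector restricting the summary
#'   to a marked subset (e.g. previously known partners); defaults to
#'   all tested proteins.
#' @param bait_id optional bait id to drop from the summary.
#' @return List: `n_quantified`, `n_reduced`, `fraction`, `percent`.
#' @export
dependence_summary <- function(diff, interactors = NULL, bait_id = NULL) {
  keep <- diff$tested
  if (!is.null(interactors)) keep <- keep & diff$protein_id %in% interactors
  if (!is.null(bait_id)) keep <- keep & diff$protein_id != bait_id
  sub <- diff[keep, , drop = FALSE]
  n_red <- sum(sub$significant & sub$log2_ratio < 0)
  frac <- if (nrow(sub) > 0) n_red / nrow(sub) else NA_real_
  list(n_quantified = nrow(sub), n_reduced = n_red,
       fraction = frac,
       percent = round_half_up(100 * frac))
}
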