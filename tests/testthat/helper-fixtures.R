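# Fixture builders and brute-force oracles shared across the suite.
# Oracles are deliberately naive (enumeration / O(n^2)) and independent
# of the implementation paths they check.

make_enr_table <- function(feature_id, ef, p_adj = 0.01, p_raw = p_adj,
                           detected = TRUE) {
  n <- length(feature_id)
  out <- data.frame(
    feature_id = as.character(feature_id),
    base_mean = rep(100, n),
    ef = ef,
    p_raw = rep_len(p_raw, n),
    p_adj = rep_len(p_adj, n),
    detected = rep_len(detected, n),
    flag = character(n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_table", "data.frame")
  out
}

## median-of-ratios by direct transcription of the definition
sf_oracle <- function(counts) {
  ref <- apply(counts, 1, function(r) all(r > 0))
  x <- counts[ref, , drop = FALSE]
  geo <- apply(x, 1, function(r) prod(r)^(1 / length(r)))
  apply(sweep(x, 1, geo, "/"), 2, median)
}

## BH step-up from the definition: q_(i) = min_{j >= i} m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

## upper-tail hypergeometric by explicit summation
hyper_oracle <- function(k, class_size, pop_size, draws) {
  kk <- k:min(class_size, draws)
  sum(choose(class_size, kk) * choose(pop_size - class_size, draws - kk)) /
    choose(pop_size, draws)
}

## O(n^2) interval intersection (0-based half-open)
intersect_oracle <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        min(a$end[i], b$end[j]) > max(a$start[i], b$start[j]))
      hits[[length(hits) + 1]] <- data.frame(
        id_a = a$id[i], id_b = b$id[j],
        overlap_bp = min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]),
        stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(id_a = character(0), id_b = character(0),
                      overlap_bp = numeric(0)))
  do.call(rbind, hits)
}

random_interval_set <- function(n, genome, width_range = c(50, 400)) {
  ch <- sample(names(genome), n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  start <- floor(runif(n, 0, genome[ch] - w))
  interval_set(ch, start, start + w, genome = genome)
}

## enrichment tables engineered so the cascade reproduces a chosen set
## of stage counts: the top quarter of distinct-EF candidates passes
## the percentile gate; a control table covers exactly the shared part
## (control-detected under the default rule: expressed and EF > 0),
## with small positive control EFs where the ratio branch must rescue
## and a blocking control EF where it must not
cascade_fixture <- function(n_candidates, n_specific, n_rescued,
                            n_not_rescued) {
  n_gated <- n_specific + n_rescued + n_not_rescued
  stopifnot(n_gated == round(n_candidates / 4))
  ef <- 1 + seq_len(n_candidates) / 1000
  ids <- sprintf("rna_%05d", seq_len(n_candidates))
  case <- make_enr_table(ids, ef)
  gated_ids <- ids[(n_candidates - n_gated + 1):n_candidates]
  shared <- setdiff(gated_ids, gated_ids[seq_len(n_specific)])
  ratio_ids <- shared[seq_len(n_rescued)]
  ctrl <- make_enr_table(
    shared,
    ef = ifelse(shared %in% ratio_ids, 0.2, 1.5)
  )
  list(case = case, control = ctrl,
       gated_ids = gated_ids, shared_ids = shared)
}
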