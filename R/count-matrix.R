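#' Assemble a count matrix with its sample design
#'
#' Bundles an integer read-count matrix (features x samples) with the
#' per-sample design table used by the enrichment and differential
#' stages. The design must describe every column of the matrix, in
#' order, with a cell line, a fraction (`"input"` or `"IP"`), a
#' condition and a replicate label.
#'
#' @param counts integer matrix, features x samples, with feature ids as
#'   rownames. Non-negative; fractional values are rejected.
#' @param design data.frame with columns `sample`, `cell_line`,
#'   `fraction`, `condition`, `replicate`; one row per column of
#'   `counts`, in column order.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `design`.
#' @examples
#' m <- count_matrix(
#'   matrix(c(10L, 20L, 5L, 8L), 2, 2,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   data.frame(sample = c("s1", "s2"), cell_line = "case",
#'              fraction = c("input", "IP"), condition = "none",
#'              replicate = c(1, 1))
#' )
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stopf("`counts` must carry feature ids as rownames")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stopf("`counts` must be non-negative integers")
  storage.mode(counts) <- "integer"
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  needed <- c("sample", "cell_line", "fraction", "condition", "replicate")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols))
    stopf("design is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(design) != ncol(counts))
    stopf("design has %d rows but `counts` has %d samples",
          nrow(design), ncol(counts))
  if (is.null(colnames(counts))) colnames(counts) <- design$sample
  key <- interaction(design$cell_line, design$fraction, design$condition,
                     design$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stopf("replicate labels must be unique within (cell_line, fraction, condition)")
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("cell lines:", paste(unique(x$design$cell_line), collapse = ", "), "\n")
  cat("fractions: ", paste(unique(x$design$fraction), collapse = ", "), "\n")
  invisible(x)
}

## subset a count_matrix to the samples matching the given design values
subset_samples <- function(m, cell_line = NULL, fraction = NULL,
                           condition = NULL) {
  keep <- rep(TRUE, nrow(m$design))
  if (!is.null(cell_line)) keep <- keep & m$design$cell_line %in% cell_line
  if (!is.null(fraction)) keep <- keep & m$design$fraction %in% fraction
  if (!is.null(condition)) keep <- keep & m$design$condition %in% condition
  if (!any(keep)) stopf("no samples match the requested design subset")
  structure(list(counts = m$counts[, keep, drop = FALSE],
                 design = m$design[keep, , drop = FALSE]),
            class = "count_matrix")
}

#' Write / read a count matrix as TSV
#'
#' The counts file has a `feature_id` column followed by one column per
#' sample; the design file mirrors the design table.
#'
#' @param m a [count_matrix()].
#' @param counts_path,design_path file paths.
#' @return `read_count_matrix()` returns a [count_matrix()];
#'   `write_count_matrix()` returns its input invisibly.
#' @export
write_count_matrix <- function(m, counts_path, design_path) {
  df <- data.frame(feature_id = rownames(m$counts), m$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(m)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, design_path) {
  df <- read.table(counts_path, sep = "\t", header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stopf("%s: first column must be `feature_id`", counts_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$feature_id
  design <- read.table(design_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  count_matrix(counts, design)
}
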