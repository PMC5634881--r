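#' Write gene models as GTF
#'
#' One `gene` record per gene plus its `exon` records, with `gene_id`
#' and `gene_biotype` attributes. Internal 0-based half-open
#' coordinates are converted to the GTF 1-based closed convention on
#' the way out.
#'
#' @param models a [gene_models()].
#' @param path output file.
#' @return `models`, invisibly.
#' @export
write_gtf <- function(models, path) {
  g <- models$genes
  attr_str <- function(id) {
    bt <- g$biotype[match(id, g$gene_id)]
    sprintf('gene_id "%s"; gene_biotype "%s";', id, bt)
  }
  gene_lines <- sprintf("%s\tripflow\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, g$start + 1, g$end, g$strand,
                        attr_str(g$gene_id))
  e <- models$exons
  ge <- g[match(e$gene_id, g$gene_id), ]
  exon_lines <- sprintf("%s\tripflow\texon\t%d\t%d\t.\t%s\t.\t%s",
                        ge$chrom, e$start + 1, e$end, ge$strand,
                        attr_str(e$gene_id))
  writeLines(c(gene_lines, exon_lines), path)
  invisible(models)
}

#' Read gene models from GTF
#'
#' Imports `gene` and `exon` records through `rtracklayer`; requires
#' `gene_id` attributes and reads `gene_biotype` when present (else
#' `"unknown"`). 1-based closed GTF coordinates are converted to the
#' internal 0-based half-open convention. When `gene` records are
#' absent, gene spans are inferred from the exons.
#'
#' @param path GTF file.
#' @return A [gene_models()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(md) || anyNA(md$gene_id))
    stopf("%s: record without gene_id attribute", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = md$gene_id,
    biotype = if ("gene_biotype" %in% names(md))
      as.character(md$gene_biotype) else NA_character_,
    stringsAsFactors = FALSE
  )
  gg <- df[df$type == "gene", ]
  ee <- df[df$type == "exon", ]
  if (nrow(gg)) {
    genes <- data.frame(gene_id = gg$gene_id, chrom = gg$chrom,
                        strand = gg$strand, start = gg$start, end = gg$end,
                        biotype = ifelse(is.na(gg$biotype), "unknown",
                                         gg$biotype),
                        stringsAsFactors = FALSE)
  } else {
    sp_start <- tapply(ee$start, ee$gene_id, min)
    ids <- names(sp_start)
    first <- match(ids, ee$gene_id)
    genes <- data.frame(gene_id = ids, chrom = ee$chrom[first],
                        strand = ee$strand[first],
                        start = as.numeric(sp_start),
                        end = as.numeric(tapply(ee$end, ee$gene_id, max)),
                        biotype = "unknown", stringsAsFactors = FALSE)
  }
  exons <- data.frame(gene_id = ee$gene_id, start = ee$start, end = ee$end,
                      stringsAsFactors = FALSE)
  gene_models(genes, exons)
}
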