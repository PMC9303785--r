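# Fixture constructors shared across test files.

make_ann <- function(genes, exons = NULL, mirnas = NULL, matures = NULL) {
  genes$symbol <- genes$symbol %||% genes$gene_id
  genes$is_mirna_host <- genes$is_mirna_host %||% FALSE
  genes$is_snorna_host <- genes$is_snorna_host %||% FALSE
  ann <- list(
    genes = genes, exons = exons, mirnas = mirnas, matures = matures,
    chrom_len = vapply(split(genes$end, genes$chrom),
                       function(e) max(e) + 10000, 1)
  )
  class(ann) <- "mirfuse_annotation"
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_events <- function(sample_id, gene5_id, gene3_id,
                        chrom5 = "chr1", pos5 = 100L, strand5 = "+",
                        chrom3 = "chr1", pos3 = 200L, strand3 = "+",
                        flags = "", spanning_reads = 5L,
                        host3 = NULL, host5 = NULL) {
  ev <- data.frame(
    sample_id = sample_id, gene5_id = gene5_id, gene3_id = gene3_id,
    symbol5 = gene5_id, symbol3 = gene3_id,
    chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
    chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
    flags = flags, spanning_reads = spanning_reads,
    stringsAsFactors = FALSE
  )
  if (!is.null(host3)) ev$host3 <- host3
  if (!is.null(host5)) ev$host5 <- host5
  ev
}
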