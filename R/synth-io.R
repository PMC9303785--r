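# On-disk representation of a synthetic cohort: standard text formats that the
# package's readers (and any external tool) can consume.

#' Write gene annotation as GTF
#'
#' Emits one `gene` feature per gene plus `exon` features. miRNA-host and
#' snoRNA-host status are carried as attributes so the round trip preserves
#' them.
#'
#' @param annotation a `mirfuse_annotation`.
#' @param path output GTF file.
#' @export
write_genes_gtf <- function(annotation, path) {
  g <- annotation$genes
  attr_str <- sprintf(
    'gene_id "%s"; gene_name "%s"; gene_biotype "protein_coding"; mirna_host "%d"; snorna_host "%d";',
    g$gene_id, g$symbol, as.integer(g$is_mirna_host),
    as.integer(g$is_snorna_host))
  gene_lines <- sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, g$start, g$end, g$strand, attr_str)
  e <- annotation$exons
  exon_lines <- sprintf('%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                        e$chrom, e$start, e$end, e$strand, e$gene_id)
  writeLines(c(gene_lines, exon_lines), path)
  invisible(path)
}

#' Write miRNA annotation as miRBase-dialect GFF3
#'
#' `miRNA_primary_transcript` features for precursors and `miRNA` features
#' with `Derives_from` for mature products.
#'
#' @param annotation a `mirfuse_annotation`.
#' @param path output GFF3 file.
#' @export
write_mirna_gff3 <- function(annotation, path) {
  p <- annotation$mirnas
  m <- annotation$matures
  lines <- "##gff-version 3"
  if (nrow(p)) {
    lines <- c(lines, sprintf(
      "%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      p$chrom, p$start, p$end, p$strand, p$precursor_id, p$name))
  }
  if (nrow(m)) {
    lines <- c(lines, sprintf(
      "%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
      m$chrom, m$start, m$end, m$strand, m$mature_id, m$mature_id,
      m$precursor_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write fusion events as a FusionCatcher-dialect TSV
#'
#' @param fusions fusion event data frame.
#' @param path output TSV.
#' @export
write_fusions_tsv <- function(fusions, path) {
  df <- data.frame(
    sample_id = fusions$sample_id,
    `Gene_1_symbol(5end_fusion_partner)` = fusions$symbol5,
    `Gene_2_symbol(3end_fusion_partner)` = fusions$symbol3,
    Fusion_description = fusions$flags,
    `Fusion_point_for_gene_1(5end_fusion_partner)` =
      sprintf("%s:%d:%s", fusions$chrom5, fusions$pos5, fusions$strand5),
    `Fusion_point_for_gene_2(3end_fusion_partner)` =
      sprintf("%s:%d:%s", fusions$chrom3, fusions$pos3, fusions$strand3),
    Spanning_unique_reads = fusions$spanning_reads,
    `Gene_1_id(5end_fusion_partner)` = fusions$gene5_id,
    `Gene_2_id(3end_fusion_partner)` = fusions$gene3_id,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Converts from the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention. Column 4 carries the feature name.
#'
#' @param df data frame with chrom, start, end and a name column.
#' @param path output BED file.
#' @param name_col which column to put in BED column 4.
#' @export
write_bed4 <- function(df, path, name_col = 4) {
  out <- data.frame(df$chrom, df$start - 1L, df$end,
                    df[[name_col]], stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of gene-id vectors.
#' @param path output GMT file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param path GMT file.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a complete synthetic cohort to a directory
#'
#' Produces genes.gtf, mirna.gff3, fusions.tsv, clinical.tsv, fpkm.tsv,
#' meth_beta.tsv, cpg_islands.bed, mirna_counts.tsv, mirna_lib_sizes.tsv,
#' genesets.gmt, tfbs.bed and one SAM file per fused sample under wgs/.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genes_gtf(cohort$annotation, file.path(dir, "genes.gtf"))
  write_mirna_gff3(cohort$annotation, file.path(dir, "mirna.gff3"))
  write_fusions_tsv(cohort$fusions, file.path(dir, "fusions.tsv"))
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(cohort$expression, file.path(dir, "fpkm.tsv"), "gene_id")
  write_matrix_tsv(cohort$methylation$beta, file.path(dir, "meth_beta.tsv"),
                   "island_id")
  write_bed4(cohort$methylation$islands, file.path(dir, "cpg_islands.bed"),
             name_col = "island_id")
  write_matrix_tsv(cohort$mirna$counts, file.path(dir, "mirna_counts.tsv"),
                   "mature_id")
  write.table(
    data.frame(sample_id = names(cohort$mirna$lib_sizes),
               lib_size = as.integer(cohort$mirna$lib_sizes)),
    file.path(dir, "mirna_lib_sizes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$genesets, file.path(dir, "genesets.gmt"))
  write_bed4(cohort$tfbs, file.path(dir, "tfbs.bed"), name_col = "tf")
  wdir <- file.path(dir, "wgs")
  dir.create(wdir, showWarnings = FALSE)
  for (s in names(cohort$wgs)) {
    writeLines(cohort$wgs[[s]], file.path(wdir, paste0(s, ".sam")))
  }
  invisible(dir)
}

#' Read gene annotation from a GTF file
#'
#' Uses [rtracklayer::import()]; recognises the host-status attributes written
#' by [write_genes_gtf()] when present (otherwise host status must come from a
#' miRNA annotation via [assign_hosts()]).
#'
#' @param path GTF file with `gene` (and optionally `exon`) features.
#' @return a `mirfuse_annotation` list (without miRNA records).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  gg <- gr[is_gene]
  gmd <- S4Vectors::mcols(gg)
  genes <- data.frame(
    gene_id = gmd$gene_id,
    symbol = if (!is.null(gmd$gene_name)) gmd$gene_name else gmd$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg), end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)),
    is_mirna_host = if (!is.null(gmd$mirna_host))
      gmd$mirna_host == "1" else NA,
    is_snorna_host = if (!is.null(gmd$snorna_host))
      gmd$snorna_host == "1" else FALSE,
    stringsAsFactors = FALSE
  )
  ee <- gr[md$type == "exon"]
  exons <- if (length(ee)) {
    data.frame(
      gene_id = S4Vectors::mcols(ee)$gene_id,
      chrom = as.character(GenomicRanges::seqnames(ee)),
      start = GenomicRanges::start(ee), end = GenomicRanges::end(ee),
      strand = as.character(GenomicRanges::strand(ee)),
      stringsAsFactors = FALSE
    )
  } else NULL
  chrom_len <- vapply(split(genes$end, genes$chrom),
                      function(e) max(e) + 10000, 1)
  ann <- list(genes = genes, exons = exons, mirnas = NULL, matures = NULL,
              chrom_len = chrom_len)
  class(ann) <- "mirfuse_annotation"
  ann
}

#' Read miRNA annotation from a miRBase-dialect GFF3 file
#'
#' @param path GFF3 with `miRNA_primary_transcript` and `miRNA` features
#'   (`Derives_from` linking matures to precursors).
#' @return list with data frames `mirnas` (precursors) and `matures`.
#' @export
read_mirna_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  pp <- gr[md$type == "miRNA_primary_transcript"]
  mm <- gr[md$type == "miRNA"]
  mirnas <- data.frame(
    precursor_id = S4Vectors::mcols(pp)$ID,
    name = S4Vectors::mcols(pp)$Name,
    chrom = as.character(GenomicRanges::seqnames(pp)),
    start = GenomicRanges::start(pp), end = GenomicRanges::end(pp),
    strand = as.character(GenomicRanges::strand(pp)),
    stringsAsFactors = FALSE
  )
  derives <- S4Vectors::mcols(mm)$Derives_from
  if (!is.character(derives)) {
    derives <- vapply(as.list(derives), function(x) x[1], character(1))
  }
  matures <- data.frame(
    mature_id = S4Vectors::mcols(mm)$ID,
    precursor_id = derives,
    chrom = as.character(GenomicRanges::seqnames(mm)),
    start = GenomicRanges::start(mm), end = GenomicRanges::end(mm),
    strand = as.character(GenomicRanges::strand(mm)),
    stringsAsFactors = FALSE
  )
  list(mirnas = mirnas, matures = matures)
}

#' Read BED4 intervals into 1-based inclusive coordinates
#'
#' @param path BED file (0-based half-open).
#' @param name_col name to give the 4th column.
#' @return data frame chrom, start, end, <name_col>.
#' @export
read_bed4 <- function(path, name_col = "name") {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = df[[2]] + 1L, end = df[[3]],
                    stringsAsFactors = FALSE)
  out[[name_col]] <- df[[4]]
  out
}
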