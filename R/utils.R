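#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; cohort summaries in this package
#' report shares rounded half-up at the displayed precision (251 from 250.9,
#' 5.9 from 5.93), so the rule is made explicit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.5)    # 3
#' round_half_up(5.935, 1) # 5.9
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic per-section sub-seed so adding a generator section never
# perturbs the draws of earlier sections. Kept below 2^31 - 1.
derive_seed <- function(seed, section) {
  offsets <- c(
    annotation = 11L, clinical = 23L, fusions = 37L, expression = 53L,
    methylation = 67L, mirna = 79L, genesets = 97L, tfbs = 113L, wgs = 131L
  )
  off <- offsets[[section]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a feature-by-sample matrix as TSV
#'
#' First column holds the feature identifier, remaining columns are samples.
#'
#' @param mat numeric matrix with rownames (features) and colnames (samples).
#' @param path output file.
#' @param id_col name for the identifier column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' @param path TSV with a header row; first column = feature ids.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
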