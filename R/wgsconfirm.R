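# DNA-level fusion confirmation from discordant WGS read pairs.

# Load a SAM/BAM file into a data frame of primary, mapped alignments.
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flt <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE,
                                isUnmappedQuery = FALSE,
                                isDuplicate = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = flt,
      what = c("qname", "rname", "pos", "mapq", "mrnm", "mpos")))[[1]]
  data.frame(qname = res$qname, rname = as.character(res$rname),
             pos = res$pos, mapq = res$mapq,
             mrnm = as.character(res$mrnm), mpos = res$mpos,
             stringsAsFactors = FALSE)
}

in_span <- function(chrom, pos, span) {
  !is.na(chrom) & !is.na(pos) &
    chrom == span$chrom & pos >= span$start & pos <= span$end
}

#' Confirm a fusion at the DNA level from discordant read pairs
#'
#' A qualifying pair has one primary, non-duplicate, mapq >= `min_mapq` mate
#' aligned inside `spanA` and the other inside `spanB` (the mate side is
#' taken from the pairing fields, so one-sided records suffice). Pairs are
#' counted once by read name; the fusion is confirmed when at least one such
#' pair exists.
#'
#' @param alignments SAM/BAM path or a pre-loaded alignment data frame.
#' @param spanA,spanB lists with chrom, start, end (gene spans of the two
#'   partners).
#' @param min_mapq minimum mapping quality (default 1, excluding ambiguous
#'   placements).
#' @param max_names cap on audit read names returned.
#' @return object of class `pair_evidence`: list with n_bridging_pairs,
#'   confirmed, read_names.
#' @export
confirm_fusion_dna <- function(alignments, spanA, spanB, min_mapq = 1,
                               max_names = 20) {
  aln <- if (is.character(alignments)) read_alignments(alignments) else
    alignments
  aln <- aln[!is.na(aln$mapq) & aln$mapq >= min_mapq, , drop = FALSE]
  bridge <- (in_span(aln$rname, aln$pos, spanA) &
               in_span(aln$mrnm, aln$mpos, spanB)) |
    (in_span(aln$rname, aln$pos, spanB) &
       in_span(aln$mrnm, aln$mpos, spanA))
  names_hit <- unique(aln$qname[bridge])
  out <- list(n_bridging_pairs = length(names_hit),
              confirmed = length(names_hit) >= 1,
              read_names = head(names_hit, max_names))
  class(out) <- "pair_evidence"
  out
}

#' @export
print.pair_evidence <- function(x, ...) {
  cat("DNA-level evidence:", x$n_bridging_pairs, "bridging pair(s);",
      if (x$confirmed) "confirmed" else "not confirmed", "\n")
  invisible(x)
}

#' Batch DNA-level confirmation of fusion events
#'
#' One evidence row per (sample, fusion) with available alignments; events in
#' samples without an alignment file are marked untested.
#'
#' @param events fusion event data frame.
#' @param alignments_by_sample named vector/list sample_id -> SAM/BAM path.
#' @param annotation a `mirfuse_annotation` (gene spans).
#' @param min_mapq minimum mapping quality.
#' @return data frame with sample_id, gene5_id, gene3_id, tested,
#'   n_bridging_pairs, confirmed.
#' @export
batch_confirm <- function(events, alignments_by_sample, annotation,
                          min_mapq = 1) {
  genes <- annotation$genes
  span_of <- function(gid) {
    i <- match(gid, genes$gene_id)
    list(chrom = genes$chrom[i], start = genes$start[i], end = genes$end[i])
  }
  if (!nrow(events)) {
    return(data.frame(sample_id = character(), gene5_id = character(),
                      gene3_id = character(), tested = logical(),
                      n_bridging_pairs = integer(), confirmed = logical(),
                      stringsAsFactors = FALSE))
  }
  cache <- new.env(parent = emptyenv())
  get_aln <- function(path) {
    if (!exists(path, envir = cache)) {
      assign(path, read_alignments(path), envir = cache)
    }
    get(path, envir = cache)
  }
  rows <- lapply(seq_len(nrow(events)), function(k) {
    s <- events$sample_id[k]
    base <- data.frame(sample_id = s, gene5_id = events$gene5_id[k],
                       gene3_id = events$gene3_id[k], tested = FALSE,
                       n_bridging_pairs = NA_integer_, confirmed = NA,
                       stringsAsFactors = FALSE)
    path <- alignments_by_sample[[s]] %||% NA_character_
    if (is.na(path)) return(base)
    ev <- confirm_fusion_dna(get_aln(path), span_of(events$gene5_id[k]),
                             span_of(events$gene3_id[k]), min_mapq)
    base$tested <- TRUE
    base$n_bridging_pairs <- ev$n_bridging_pairs
    base$confirmed <- ev$confirmed
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
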