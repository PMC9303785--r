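# Reading FusionCatcher-style fusion calls and the artefact filters applied
# before any analysis.

#' Default FusionCatcher artefact-flag blacklist
#'
#' The 44 description flags that mark likely false-positive fusion calls
#' (read-through transcripts, paralogs, overlaps with normal-tissue fusion
#' catalogues, etc.). An event carrying any of these flags is removed by
#' [filter_by_flags()]. Flags are matched by exact string equality after
#' trimming and lower-casing; the list is a closed vocabulary, not a set of
#' substrings.
#'
#' @return character vector of lower-case flag names.
#' @export
fusioncatcher_blacklist <- function() {
  c("1000genomes", "1k<gap<10k", "adjacent", "ambiguous", "duplicates",
    "ensembl_partially_overlapping", "gap<1k", "gencode_fully_overlapping",
    "gencode_partially_overlapping", "gencode_same_strand_overlapping",
    "healthy", "m0", "multi", "non_cancer_tissues", "non_tumor_cells",
    "refseq_partially_overlapping", "tcga-normal", "ucsc_partially_overlapping",
    "banned", "bodymap2", "cacg", "conjoing", "cta_gene", "ctb_gene",
    "ctc_gene", "ctd_gene", "distance1000bp", "ensembl_fully_overlapping",
    "ensembl_same_strand_overlapping", "gtex", "hpa", "mt",
    "pair_pseudo_genes", "paralogs", "readthrough",
    "refseq_fully_overlapping", "refseq_same_strand_overlapping",
    "rp_gene", "rp11_gene", "rrna", "similar_reads", "similar_symbols",
    "ucsc_fully_overlapping", "ucsc_same_strand_overlapping")
}

# Column aliases: canonical name -> accepted header names (several historical
# FusionCatcher layouts).
.fusion_column_aliases <- list(
  symbol5 = c("Gene_1_symbol(5end_fusion_partner)", "symbol5", "gene_5"),
  symbol3 = c("Gene_2_symbol(3end_fusion_partner)", "symbol3", "gene_3"),
  flags = c("Fusion_description", "Description", "flags"),
  bp5 = c("Fusion_point_for_gene_1(5end_fusion_partner)", "bp5",
          "fusion_point_1"),
  bp3 = c("Fusion_point_for_gene_2(3end_fusion_partner)", "bp3",
          "fusion_point_2"),
  spanning_reads = c("Spanning_unique_reads", "spanning_reads",
                     "Spanning_pairs"),
  gene5_id = c("Gene_1_id(5end_fusion_partner)", "gene5_id", "ensembl_1"),
  gene3_id = c("Gene_2_id(3end_fusion_partner)", "gene3_id", "ensembl_2"),
  sample_id = c("sample_id", "sample", "Sample")
)

parse_breakpoints <- function(x, field, lines) {
  parts <- strsplit(x, ":", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    stop("malformed breakpoint in column '", field, "' at line ",
         paste(lines[bad], collapse = ", "), ": '", x[which(bad)[1]], "'",
         call. = FALSE)
  }
  chrom <- vapply(parts, `[`, character(1), 1)
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  strand <- vapply(parts, `[`, character(1), 3)
  if (anyNA(pos) || !all(strand %in% c("+", "-"))) {
    bad <- which(is.na(pos) | !(strand %in% c("+", "-")))
    stop("malformed breakpoint in column '", field, "' at line ",
         paste(lines[bad], collapse = ", "), call. = FALSE)
  }
  list(chrom = chrom, pos = pos, strand = strand)
}

#' Read FusionCatcher-style fusion calls from TSV
#'
#' One fusion event per row. Breakpoints are `chrom:pos:strand` strings;
#' description flags are split on commas, trimmed and lower-cased. The sample
#' identifier comes from a `sample_id` column when present, otherwise from
#' `sample_id` (argument) or the file name.
#'
#' @param path TSV file with a header row. Column names are matched against a
#'   small alias map covering historical FusionCatcher layouts.
#' @param sample_id sample identifier used when the file has no sample column.
#' @return data frame of fusion events (columns sample_id, gene5_id, gene3_id,
#'   symbol5, symbol3, chrom5/pos5/strand5, chrom3/pos3/strand3, flags,
#'   spanning_reads). Duplicate (sample, partners, breakpoints) rows are
#'   collapsed to one event keeping the maximum read count.
#' @export
read_fusion_calls <- function(path, sample_id = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  find_col <- function(canon, required = TRUE) {
    hits <- intersect(.fusion_column_aliases[[canon]], colnames(df))
    if (!length(hits)) {
      if (required) stop("required fusion column missing: expected one of ",
                         paste(.fusion_column_aliases[[canon]],
                               collapse = ", "), call. = FALSE)
      return(NULL)
    }
    df[[hits[1]]]
  }
  n <- nrow(df)
  lines <- seq_len(n) + 1L  # header is line 1
  sid <- find_col("sample_id", required = FALSE)
  if (is.null(sid)) {
    sid <- rep(sample_id %||% sub("\\.[^.]*$", "", basename(path)), n)
  }
  flags_raw <- find_col("flags", required = FALSE)
  if (is.null(flags_raw)) flags_raw <- rep("", n)
  flags <- vapply(strsplit(flags_raw, ","), function(f) {
    f <- tolower(trimws(f))
    paste(f[nzchar(f)], collapse = ",")
  }, character(1))
  if (n == 0) return(empty_fusion_frame()[0, 1:13])
  bp5 <- parse_breakpoints(find_col("bp5"), "bp5", lines)
  bp3 <- parse_breakpoints(find_col("bp3"), "bp3", lines)
  gene5 <- find_col("gene5_id", required = FALSE)
  gene3 <- find_col("gene3_id", required = FALSE)
  sym5 <- find_col("symbol5")
  sym3 <- find_col("symbol3")
  span <- find_col("spanning_reads", required = FALSE)
  span <- if (is.null(span)) rep(NA_integer_, n) else
    suppressWarnings(as.integer(span))
  ev <- data.frame(
    sample_id = sid,
    gene5_id = gene5 %||% sym5, gene3_id = gene3 %||% sym3,
    symbol5 = sym5, symbol3 = sym3,
    chrom5 = bp5$chrom, pos5 = bp5$pos, strand5 = bp5$strand,
    chrom3 = bp3$chrom, pos3 = bp3$pos, strand3 = bp3$strand,
    flags = flags, spanning_reads = span,
    stringsAsFactors = FALSE
  )
  # collapse fully identical (sample, partners, breakpoints) rows, max reads
  key <- paste(ev$sample_id, ev$gene5_id, ev$gene3_id,
               ev$chrom5, ev$pos5, ev$chrom3, ev$pos3, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    mx <- tapply(ev$spanning_reads, key, function(x)
      if (all(is.na(x))) NA_integer_ else max(x, na.rm = TRUE))
    ev <- ev[keep, , drop = FALSE]
    ev$spanning_reads <- as.integer(mx[key[keep]])
    rownames(ev) <- NULL
  }
  ev
}

split_flags <- function(flags) {
  lapply(strsplit(flags, ",", fixed = TRUE), function(f) {
    f <- tolower(trimws(f))
    f[nzchar(f)]
  })
}

#' Remove fusion events carrying blacklisted flags
#'
#' An event survives iff its flag set has an empty intersection with the
#' blacklist (exact match after trim/lower-case). An empty blacklist is the
#' identity filter.
#'
#' @param events fusion event data frame.
#' @param blacklist character vector of banned flags; defaults to
#'   [fusioncatcher_blacklist()].
#' @return list with `events` (survivors), `removed` and `report` (count of
#'   removed events per blacklisted flag).
#' @export
filter_by_flags <- function(events, blacklist = fusioncatcher_blacklist()) {
  blacklist <- tolower(trimws(blacklist))
  fl <- split_flags(events$flags)
  hit <- vapply(fl, function(f) any(f %in% blacklist), logical(1))
  removed_flags <- unlist(lapply(fl[hit], function(f) intersect(f, blacklist)))
  report <- if (length(removed_flags)) {
    tb <- table(removed_flags)
    data.frame(flag = names(tb), n_events = as.integer(tb),
               stringsAsFactors = FALSE)
  } else {
    data.frame(flag = character(), n_events = integer(),
               stringsAsFactors = FALSE)
  }
  list(events = events[!hit, , drop = FALSE],
       removed = events[hit, , drop = FALSE],
       report = report)
}

#' Remove proximal intra-chromosomal fusion events
#'
#' Intra-chromosomal events whose partner gene spans are separated by less
#' than `min_distance` bases (gap between nearest span edges; overlapping
#' spans count as distance 0), or that carry the `adjacent` flag, are removed
#' as probable read-through artefacts. Inter-chromosomal events always
#' survive. Events whose partners are absent from the annotation are
#' quarantined with a warning rather than silently dropped.
#'
#' @param events fusion event data frame.
#' @param annotation a `mirfuse_annotation` providing gene spans.
#' @param min_distance removal threshold in bases (strict `<`; a gap of
#'   exactly `min_distance` is kept).
#' @return list with `events`, `removed`, `quarantined` and `report`.
#' @export
filter_proximal <- function(events, annotation, min_distance = 10000) {
  genes <- annotation$genes
  i5 <- match(events$gene5_id, genes$gene_id)
  i3 <- match(events$gene3_id, genes$gene_id)
  # fall back to symbols for calls that only carry symbols
  i5[is.na(i5)] <- match(events$symbol5[is.na(i5)], genes$symbol)
  i3[is.na(i3)] <- match(events$symbol3[is.na(i3)], genes$symbol)
  unknown <- is.na(i5) | is.na(i3)
  if (any(unknown)) {
    warning(sum(unknown), " event(s) quarantined: partner gene absent from ",
            "annotation", call. = FALSE)
  }
  adjacent_flag <- vapply(split_flags(events$flags),
                          function(f) "adjacent" %in% f, logical(1))
  same_chrom <- !unknown & genes$chrom[i5] == genes$chrom[i3]
  gap <- rep(NA_real_, nrow(events))
  gs5 <- genes$start[i5]; ge5 <- genes$end[i5]
  gs3 <- genes$start[i3]; ge3 <- genes$end[i3]
  w <- which(same_chrom)
  gap[w] <- pmax(pmax(gs3[w] - ge5[w] - 1, gs5[w] - ge3[w] - 1), 0)
  remove <- (!unknown & adjacent_flag) |
    (same_chrom & !is.na(gap) & gap < min_distance)
  list(
    events = events[!remove & !unknown, , drop = FALSE],
    removed = events[remove & !unknown, , drop = FALSE],
    quarantined = events[unknown, , drop = FALSE],
    report = data.frame(
      n_input = nrow(events),
      n_removed = sum(remove & !unknown),
      n_quarantined = sum(unknown),
      min_distance = min_distance,
      distance_convention = "gap between gene-span edges, strict <",
      stringsAsFactors = FALSE
    )
  )
}
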