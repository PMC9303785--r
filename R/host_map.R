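# Assigning miRNA precursors to host genes and classifying, per fusion event,
# whether the intronic miRNA falls inside the retained part of the fusion
# transcript.

#' Assign miRNA precursors to host genes
#'
#' A precursor is assigned to a gene iff its interval is fully contained in
#' the gene span and the strands match. When several genes qualify (nested
#' genes), the smallest span wins; remaining ties go to the lexicographically
#' smallest gene id. `intronic` is `TRUE` when the precursor overlaps no exon
#' of the chosen gene; if the annotation carries no exon structure it is
#' `TRUE` by assumption and flagged as such in the report.
#'
#' @param genes gene data frame (gene_id, chrom, start, end, strand) or a
#'   `mirfuse_annotation`.
#' @param mirnas precursor data frame (precursor_id, chrom, start, end,
#'   strand), e.g. from [read_mirna_annotation()].
#' @param exons optional exon data frame (gene_id, chrom, start, end); taken
#'   from `genes$exons` when `genes` is an annotation object.
#' @return object of class `host_assignment`: list with `loci` (one row per
#'   precursor: host_gene_id is `NA` for unassignable precursors), maps
#'   `gene_to_precursors` / `precursor_to_gene`, and `report`.
#' @export
assign_hosts <- function(genes, mirnas, exons = NULL) {
  if (inherits(genes, "mirfuse_annotation")) {
    exons <- exons %||% genes$exons
    genes <- genes$genes
  }
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end),
                                 strand = genes$strand)
  m_gr <- GenomicRanges::GRanges(mirnas$chrom,
                                 IRanges::IRanges(mirnas$start, mirnas$end),
                                 strand = mirnas$strand)
  hits <- GenomicRanges::findOverlaps(m_gr, g_gr, type = "within",
                                      ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  host <- rep(NA_character_, nrow(mirnas))
  tie_logged <- character(0)
  for (q in unique(qh)) {
    cand <- sh[qh == q]
    if (length(cand) > 1) {
      span <- genes$end[cand] - genes$start[cand]
      cand <- cand[span == min(span)]
      if (length(cand) > 1) {
        cand <- cand[order(genes$gene_id[cand])]
        tie_logged <- c(tie_logged, mirnas$precursor_id[q])
      }
    }
    host[q] <- genes$gene_id[cand[1]]
  }
  intronic <- rep(NA, nrow(mirnas))
  exon_based <- !is.null(exons) && nrow(exons) > 0
  if (exon_based) {
    e_gr <- GenomicRanges::GRanges(exons$chrom,
                                   IRanges::IRanges(exons$start, exons$end))
    for (q in which(!is.na(host))) {
      ge <- which(exons$gene_id == host[q])
      if (!length(ge)) { intronic[q] <- TRUE; next }
      ov <- IRanges::overlapsAny(m_gr[q], e_gr[ge], ignore.strand = TRUE)
      intronic[q] <- !any(ov)
    }
  } else {
    intronic[!is.na(host)] <- TRUE
  }
  loci <- data.frame(
    precursor_id = mirnas$precursor_id,
    chrom = mirnas$chrom, start = mirnas$start, end = mirnas$end,
    strand = mirnas$strand, host_gene_id = host, intronic = intronic,
    stringsAsFactors = FALSE
  )
  assigned <- loci[!is.na(loci$host_gene_id), , drop = FALSE]
  out <- list(
    loci = loci,
    gene_to_precursors = split(assigned$precursor_id, assigned$host_gene_id),
    precursor_to_gene = setNames(assigned$host_gene_id,
                                 assigned$precursor_id),
    report = list(
      n_precursors = nrow(mirnas),
      n_assigned = nrow(assigned),
      unassigned = loci$precursor_id[is.na(loci$host_gene_id)],
      ties_broken_lexicographically = tie_logged,
      intronic_by_assumption = !exon_based
    )
  )
  class(out) <- "host_assignment"
  out
}

#' @export
print.host_assignment <- function(x, ...) {
  cat("Host assignment:", x$report$n_assigned, "of", x$report$n_precursors,
      "precursors assigned to", length(x$gene_to_precursors), "host genes\n")
  invisible(x)
}

# Retained-side inclusion test for one precursor against one junction.
# role: "3prime" keeps junction -> transcription end (in gene orientation),
# "5prime" keeps transcription start -> junction. The junction base itself is
# treated as disrupted, so "strictly within" excludes it.
precursor_included <- function(prec_start, prec_end, junction, gene_start,
                               gene_end, strand, role) {
  # downstream of the junction is kept for a 3' partner on +, or a 5' on -
  downstream_kept <- (role == "3prime") == (strand == "+")
  if (downstream_kept) {
    prec_start > junction & prec_end <= gene_end
  } else {
    prec_end < junction & prec_start >= gene_start
  }
}

#' Classify miRNA inclusion of host-partner fusion events
#'
#' For each event whose 3' (resp. 5') partner is a miRNA host, decides
#' whether the intronic precursor is retained in the fusion transcript. The
#' 3' partner retains junction-to-transcription-end in the host's own
#' orientation (on `+` downstream means larger coordinates, on `-` smaller);
#' the 5' partner retains transcription-start-to-junction. The event is
#' `INCLUDED` iff at least one of the host's precursors lies strictly within
#' the retained region (a precursor touching the junction base is
#' `MIREXCL`, the junction base being disrupted); otherwise `MIREXCL`.
#' Non-host partners get `NA`.
#'
#' @param events fusion event data frame.
#' @param assignment a `host_assignment`.
#' @param annotation a `mirfuse_annotation` (gene spans).
#' @return `events` with columns host3, host5, inclusion3, inclusion5 and
#'   bp_outside_gene added; per-precursor detail in
#'   `attr(, "precursor_detail")`.
#' @export
classify_inclusion <- function(events, assignment, annotation) {
  genes <- annotation$genes
  loci <- assignment$loci[!is.na(assignment$loci$host_gene_id), , drop = FALSE]
  n <- nrow(events)
  host3 <- events$gene3_id %in% loci$host_gene_id
  host5 <- events$gene5_id %in% loci$host_gene_id
  inclusion3 <- rep(NA_character_, n)
  inclusion5 <- rep(NA_character_, n)
  bp_outside <- rep(FALSE, n)
  detail <- list()

  classify_side <- function(k, gene_id, junction, role) {
    gi <- match(gene_id, genes$gene_id)
    pl <- loci[loci$host_gene_id == gene_id, , drop = FALSE]
    inc <- precursor_included(pl$start, pl$end, junction,
                              genes$start[gi], genes$end[gi],
                              genes$strand[gi], role)
    if (junction < genes$start[gi] || junction > genes$end[gi]) {
      bp_outside[k] <<- TRUE
    }
    detail[[length(detail) + 1L]] <<- data.frame(
      event = k, role = role, gene_id = gene_id,
      precursor_id = pl$precursor_id, included = inc,
      stringsAsFactors = FALSE
    )
    if (any(inc)) "INCLUDED" else "MIREXCL"
  }
  for (k in seq_len(n)) {
    if (host3[k]) {
      inclusion3[k] <- classify_side(k, events$gene3_id[k], events$pos3[k],
                                     "3prime")
    }
    if (host5[k]) {
      inclusion5[k] <- classify_side(k, events$gene5_id[k], events$pos5[k],
                                     "5prime")
    }
  }
  events$host3 <- host3
  events$host5 <- host5
  events$inclusion3 <- inclusion3
  events$inclusion5 <- inclusion5
  events$bp_outside_gene <- bp_outside
  attr(events, "precursor_detail") <-
    if (length(detail)) do.call(rbind, detail) else NULL
  events
}

#' Convergent recurrence of host-gene fusions
#'
#' Recurrence of a miRNA-convergent fusion is defined on the host gene, not
#' the partner pair: one record per host gene appearing as 3' partner, with
#' event, sample and unique-5'-partner counts and the partner list ordered by
#' per-partner event count (ties broken lexicographically).
#'
#' @param events classified fusion events (after filtering).
#' @param assignment a `host_assignment`.
#' @return data frame host_gene_id, n_events, n_samples,
#'   n_unique_5prime_partners, partner_list (comma-separated, ordered).
#' @export
convergent_recurrence <- function(events, assignment) {
  hosts <- names(assignment$gene_to_precursors)
  ev <- events[events$gene3_id %in% hosts, , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(host_gene_id = character(), n_events = integer(),
                      n_samples = integer(),
                      n_unique_5prime_partners = integer(),
                      partner_list = character(), stringsAsFactors = FALSE))
  }
  recs <- lapply(split(ev, ev$gene3_id), function(e) {
    cnt <- table(e$gene5_id)
    ord <- order(-as.integer(cnt), names(cnt))
    data.frame(
      host_gene_id = e$gene3_id[1],
      n_events = nrow(e),
      n_samples = length(unique(e$sample_id)),
      n_unique_5prime_partners = length(cnt),
      partner_list = paste(names(cnt)[ord], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  out <- out[order(-out$n_events, out$host_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort-level fusion event accounting
#'
#' Totals and shares (1 decimal, rounded half-up) of miRNA-including and
#' -excluding host fusions on either side, inter- vs intra-chromosomal
#' counts, unique partner genes and genes recurring in more than one sample.
#'
#' @param events classified fusion events.
#' @return list of totals and percentage shares.
#' @export
event_accounting <- function(events) {
  n <- nrow(events)
  pct <- function(k) if (n == 0) 0 else round_half_up(100 * k / n, 1)
  n3inc <- sum(events$host3 & events$inclusion3 == "INCLUDED", na.rm = TRUE)
  n3exc <- sum(events$host3 & events$inclusion3 == "MIREXCL", na.rm = TRUE)
  n5inc <- sum(events$host5 & events$inclusion5 == "INCLUDED", na.rm = TRUE)
  n5exc <- sum(events$host5 & events$inclusion5 == "MIREXCL", na.rm = TRUE)
  intra <- sum(events$chrom5 == events$chrom3)
  partners <- c(events$gene5_id, events$gene3_id)
  gene_samples <- unique(data.frame(
    gene = partners, sample = c(events$sample_id, events$sample_id),
    stringsAsFactors = FALSE))
  per_gene <- table(gene_samples$gene)
  list(
    n_events = n,
    n_samples = length(unique(events$sample_id)),
    n_host3_included = n3inc, pct_host3_included = pct(n3inc),
    n_host3_mirexcl = n3exc, pct_host3_mirexcl = pct(n3exc),
    n_host5_included = n5inc, pct_host5_included = pct(n5inc),
    n_host5_mirexcl = n5exc, pct_host5_mirexcl = pct(n5exc),
    n_inter = n - intra, pct_inter = pct(n - intra),
    n_intra = intra, pct_intra = pct(intra),
    n_unique_partner_genes = length(unique(partners)),
    n_genes_recurrent = sum(per_gene > 1)
  )
}
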