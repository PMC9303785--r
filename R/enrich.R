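# Gene-set and TF-target overrepresentation with balanced non-host
# subsampling.

#' Expressed-gene universe
#'
#' A gene is in the universe iff its per-gene 95th-percentile FPKM across the
#' cohort (linear-interpolation quantile) exceeds the cutoff.
#'
#' @param expression genes x samples FPKM matrix.
#' @param probs quantile (default 0.95).
#' @param cutoff FPKM cutoff (strict `>`, default 1).
#' @return object of class `universe`: character vector of gene ids with a
#'   `rule` attribute.
#' @export
expressed_universe <- function(expression, probs = 0.95, cutoff = 1.0) {
  q <- apply(expression, 1, quantile, probs = probs, names = FALSE, type = 7)
  u <- rownames(expression)[q > cutoff]
  attr(u, "rule") <- sprintf("%gth percentile FPKM > %g", 100 * probs, cutoff)
  class(u) <- c("universe", class(u))
  u
}

#' Partner gene lists for overrepresentation analysis
#'
#' Unique 5' partners of 3'-host fusions; unique 5' partners of 3'-non-host
#' fusions, with partners of snoRNA-host 3' genes excluded (snoRNA hosts are
#' themselves overrepresented among fusions and would contaminate the
#' non-host contrast); mirrored 3'-partner lists for 5'-host fusions. When
#' `groups` is given (sample_id -> subgroup label), per-subgroup lists are
#' returned as well.
#'
#' @param events classified fusion events.
#' @param annotation a `mirfuse_annotation` (snoRNA-host flags).
#' @param groups optional named vector sample_id -> subgroup.
#' @return named list of character vectors: `host5`, `nonhost5`, `host3`,
#'   `nonhost3`, plus `<subgroup>.host5` etc. when `groups` is given.
#' @export
partner_gene_lists <- function(events, annotation, groups = NULL) {
  sno <- annotation$genes$gene_id[annotation$genes$is_snorna_host]
  build <- function(ev) {
    list(
      host5 = unique(ev$gene5_id[ev$host3]),
      nonhost5 = unique(ev$gene5_id[!ev$host3 & !(ev$gene3_id %in% sno)]),
      host3 = unique(ev$gene3_id[ev$host5]),
      nonhost3 = unique(ev$gene3_id[!ev$host5 & !(ev$gene5_id %in% sno)])
    )
  }
  out <- build(events)
  if (!is.null(groups)) {
    gl <- groups[events$sample_id]
    for (g in unique(stats::na.omit(gl))) {
      sub <- build(events[!is.na(gl) & gl == g, , drop = FALSE])
      names(sub) <- paste(g, names(sub), sep = ".")
      out <- c(out, sub)
    }
  }
  out
}

#' Hypergeometric overrepresentation of a gene list in set collections
#'
#' Classic one-sided ORA: for each set, `p = P(X >= k)` with
#' `X ~ Hypergeom(N, K, n)` where `N` is the universe size, `K` the set size
#' within the universe, `n` the list size within the universe and `k` the
#' overlap. BH adjustment is applied across the sets of the collection.
#'
#' @param gene_list character vector of gene ids (intersected with the
#'   universe before testing).
#' @param collection named list of gene-id vectors (each intersected with the
#'   universe).
#' @param universe character vector of testable gene ids.
#' @param min_set_size sets smaller than this (within the universe) are
#'   skipped.
#' @return data frame: set, k, n_list, K_set, N_universe, p, p_adj.
#' @export
hypergeom_overrep <- function(gene_list, collection, universe,
                              min_set_size = 5) {
  u <- unique(universe)
  lst <- intersect(unique(gene_list), u)
  if (!length(lst)) {
    warning("gene list is empty after intersection with the universe",
            call. = FALSE)
    return(data.frame(set = character(), k = integer(), n_list = integer(),
                      K_set = integer(), N_universe = integer(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), u)
    if (length(s) < min_set_size) return(NULL)
    k <- length(intersect(lst, s))
    p <- phyper(k - 1, length(s), length(u) - length(s), length(lst),
                lower.tail = FALSE)
    data.frame(set = nm, k = k, n_list = length(lst), K_set = length(s),
               N_universe = length(u), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), k = integer(), n_list = integer(),
                      K_set = integer(), N_universe = integer(),
                      p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Balanced non-host enrichment by repeated subsampling
#'
#' The non-host 5' partner list is much larger than the host list, which
#' makes raw overrepresentation p-values incomparable between the two
#' classes. Draws `reps` uniform subsamples of the non-host list matched to
#' the host list's size, runs [hypergeom_overrep()] on each, and reports the
#' per-set mean of the BH-adjusted p-values across draws (together with the
#' mean raw p and per-draw results).
#'
#' @param nonhost_list character vector of non-host partner gene ids.
#' @param k_target target list size (the host list's size).
#' @param collection,universe,min_set_size as in [hypergeom_overrep()].
#' @param reps number of subsamples (default 3).
#' @param seed integer seed for the draws.
#' @return data frame: set, mean_p, mean_p_adj, reps; per-draw tables in
#'   `attr(, "draws")`; `attr(, "flagged_short_list")` is `TRUE` when the
#'   non-host list was smaller than `k_target` (single run on the full list).
#' @export
balanced_nonhost_enrichment <- function(nonhost_list, k_target, collection,
                                        universe, reps = 3, seed = 1,
                                        min_set_size = 5) {
  nonhost_list <- unique(nonhost_list)
  short <- length(nonhost_list) < k_target
  draws <- with_seed(as.integer(seed), {
    if (short) {
      warning("non-host list smaller than k_target; single run on the full ",
              "list", call. = FALSE)
      list(nonhost_list)
    } else {
      lapply(seq_len(reps), function(i) sample(nonhost_list, k_target))
    }
  })
  tabs <- lapply(seq_along(draws), function(i) {
    t <- hypergeom_overrep(draws[[i]], collection, universe, min_set_size)
    t$replicate_id <- i
    t
  })
  all <- do.call(rbind, tabs)
  if (!nrow(all)) {
    out <- data.frame(set = character(), mean_p = numeric(),
                      mean_p_adj = numeric(), reps = integer(),
                      stringsAsFactors = FALSE)
  } else {
    agg <- aggregate(cbind(p, p_adj) ~ set, data = all, FUN = mean)
    out <- data.frame(set = agg$set, mean_p = agg$p, mean_p_adj = agg$p_adj,
                      reps = length(draws), stringsAsFactors = FALSE)
  }
  attr(out, "draws") <- tabs
  attr(out, "flagged_short_list") <- short
  out
}

#' Map TF binding sites to target genes via promoter windows
#'
#' A gene is a target of a TF iff at least one of the TF's binding intervals
#' overlaps the gene's strand-aware promoter window (TSS-1000 to TSS+200 in
#' the gene's orientation; on the minus strand the window extends 1000 bases
#' to the right of the TSS and 200 to the left). Closed-interval overlap.
#' The resulting sets feed [hypergeom_overrep()] unchanged.
#'
#' @param tfbs data frame chrom, start, end, tf (1-based inclusive; use
#'   [read_bed4()] for BED input).
#' @param annotation a `mirfuse_annotation`.
#' @param upstream,downstream window extents around the TSS.
#' @return named list TF -> character vector of target gene ids; intervals on
#'   chromosomes absent from the annotation are skipped and counted in
#'   `attr(, "n_skipped")`.
#' @export
tf_target_map <- function(tfbs, annotation, upstream = 1000,
                          downstream = 200) {
  genes <- annotation$genes
  known <- tfbs$chrom %in% genes$chrom
  n_skipped <- sum(!known)
  tfbs <- tfbs[known, , drop = FALSE]
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  win_start <- ifelse(genes$strand == "+", tss - upstream, tss - downstream)
  win_end <- ifelse(genes$strand == "+", tss + downstream, tss + upstream)
  w_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(win_start, 1), win_end))
  t_gr <- GenomicRanges::GRanges(tfbs$chrom,
                                 IRanges::IRanges(tfbs$start, tfbs$end))
  hits <- GenomicRanges::findOverlaps(t_gr, w_gr)
  pairs <- unique(data.frame(
    tf = tfbs$tf[S4Vectors::queryHits(hits)],
    gene = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  out <- split(pairs$gene, pairs$tf)
  attr(out, "n_skipped") <- n_skipped
  out
}
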