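# Gene-level association analyses: logistic host-overrepresentation model,
# partner-distance analysis, expression and promoter-methylation contrasts.

#' Build the per-gene fusion-role table
#'
#' One row per expressed protein-coding gene (the model universe) with
#' host-status, span size and fusion-role indicators derived from the
#' annotated event table.
#'
#' @param events classified fusion events.
#' @param annotation a `mirfuse_annotation`.
#' @param universe character vector of gene ids (e.g. from
#'   [expressed_universe()]); `NULL` uses all annotated genes.
#' @return data frame with gene_id, is_mirna_host, is_snorna_host, gene_size,
#'   fused_any and per-role indicators.
#' @export
build_gene_fusion_table <- function(events, annotation, universe = NULL) {
  genes <- annotation$genes
  if (!is.null(universe)) {
    genes <- genes[genes$gene_id %in% universe, , drop = FALSE]
  }
  host3_events <- events$host3 %||% (events$gene3_id %in%
    genes$gene_id[genes$is_mirna_host])
  host5_events <- events$host5 %||% (events$gene5_id %in%
    genes$gene_id[genes$is_mirna_host])
  data.frame(
    gene_id = genes$gene_id,
    is_mirna_host = genes$is_mirna_host,
    is_snorna_host = genes$is_snorna_host,
    gene_size = genes$end - genes$start + 1L,
    fused_any = genes$gene_id %in% c(events$gene5_id, events$gene3_id),
    fused_as_5prime = genes$gene_id %in% events$gene5_id,
    fused_as_3prime = genes$gene_id %in% events$gene3_id,
    fused_as_5prime_of_host = genes$gene_id %in% events$gene5_id[host3_events],
    fused_as_5prime_of_nonhost = genes$gene_id %in%
      events$gene5_id[!host3_events],
    fused_as_3prime_of_host = genes$gene_id %in% events$gene3_id[host5_events],
    fused_as_3prime_of_nonhost = genes$gene_id %in%
      events$gene3_id[!host5_events],
    stringsAsFactors = FALSE
  )
}

#' Logistic model of host-gene overrepresentation among fusion partners
#'
#' Fits `fused ~ host + log10(gene_size) + host:log10(gene_size)` by maximum
#' likelihood (binomial GLM) with Wald tests per coefficient. Gene size
#' enters on the log10 scale, centred at its mean, so that with the
#' interaction in the model the host main effect is the host log-odds-ratio
#' at the average gene size rather than an extrapolation to size zero. The
#' host main effect is the headline test of whether miRNA host genes are
#' overrepresented beyond what their size explains.
#'
#' @param table from [build_gene_fusion_table()].
#' @param response which indicator to model (default `fused_any`).
#' @return object of class `host_logit`: coefficient table (estimate, SE,
#'   Wald z, p), headline host p-value, n, the fitted `glm`, and a
#'   `separation` flag (set when estimates diverge; a ridge-penalised refit is
#'   then reported and labelled).
#' @export
host_overrepresentation <- function(table, response = "fused_any") {
  stopifnot(response %in% colnames(table))
  log_size <- log10(table$gene_size)
  d <- data.frame(
    y = as.integer(table[[response]]),
    host = as.integer(table$is_mirna_host),
    log_size = log_size - mean(log_size)
  )
  if (length(unique(d$host)) < 2) {
    stop("need both host and non-host genes to fit the model", call. = FALSE)
  }
  fit <- suppressWarnings(glm(y ~ host + log_size + host:log_size,
                              family = binomial(), data = d))
  separation <- !fit$converged || any(abs(coef(fit)) > 15)
  penalized <- FALSE
  if (separation) {
    # simple ridge fallback: augment with pseudo-observations at weight eps
    d2 <- rbind(d, transform(d, y = 1 - y))
    w <- c(rep(1, nrow(d)), rep(1e-3, nrow(d)))
    fit <- suppressWarnings(glm(y ~ host + log_size + host:log_size,
                                family = binomial(), data = d2, weights = w))
    penalized <- TRUE
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  coefs <- data.frame(term = names(est), estimate = est, se = se,
                      z = z, p = p, row.names = NULL,
                      stringsAsFactors = FALSE)
  out <- list(coefficients = coefs,
              host_p = coefs$p[coefs$term == "host"],
              host_coef = coefs$estimate[coefs$term == "host"],
              n = nrow(table), separation = separation,
              penalized = penalized, fit = fit)
  class(out) <- "host_logit"
  out
}

#' @export
print.host_logit <- function(x, ...) {
  cat("Host overrepresentation (logistic, n =", x$n, "genes)\n")
  if (x$penalized) cat("  [perfect separation: ridge-penalised refit]\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("Headline host effect: coef = %.4f, Wald p = %.3g\n",
              x$host_coef, x$host_p))
  invisible(x)
}

#' Partner-distance analysis for intra-chromosomal fusions
#'
#' Distance is measured junction-to-junction (`|pos3 - pos5|`). Medians are
#' reported per 3'-host class. The primary test dichotomises distances at the
#' pooled median and tests the 2x2 host-by-above/below table with Fisher's
#' exact test; a rank-sum (Wilcoxon) test is reported as a sensitivity check.
#'
#' @param events classified fusion events (needs `host3`).
#' @return list with per-class medians and n, `fisher_p`, `wilcox_p`.
#' @export
partner_distance_analysis <- function(events) {
  intra <- events[events$chrom5 == events$chrom3, , drop = FALSE]
  d <- abs(intra$pos3 - intra$pos5)
  host <- intra$host3
  med <- function(v) if (length(v)) median(v) else NA_real_
  out <- list(
    n_host = sum(host), n_nonhost = sum(!host),
    median_host = med(d[host]), median_nonhost = med(d[!host]),
    distance_convention = "junction-to-junction, absolute"
  )
  if (sum(host) < 2 || sum(!host) < 2) {
    warning("fewer than 2 intra-chromosomal events in a class; tests ",
            "not computed", call. = FALSE)
    out$fisher_p <- NA_real_
    out$wilcox_p <- NA_real_
    return(out)
  }
  pooled <- median(d)
  above <- d > pooled
  tab <- table(factor(host, c(FALSE, TRUE)), factor(above, c(FALSE, TRUE)))
  out$fisher_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
    fisher.test(tab)$p.value
  out$wilcox_p <- if (length(unique(d)) == 1) 1 else
    suppressWarnings(wilcox.test(d[host], d[!host])$p.value)
  out
}

welch_contrast <- function(x, y, label_x, label_y) {
  nx <- sum(!is.na(x)); ny <- sum(!is.na(y))
  if (nx < 2 || ny < 2) {
    return(data.frame(group1 = label_x, group2 = label_y,
                      mean1 = if (nx) mean(x, na.rm = TRUE) else NA_real_,
                      mean2 = if (ny) mean(y, na.rm = TRUE) else NA_real_,
                      n1 = nx, n2 = ny, t = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  if (sd(x, na.rm = TRUE) == 0 && sd(y, na.rm = TRUE) == 0) {
    tt <- list(statistic = c(t = NA_real_),
               p.value = if (mean(x, na.rm = TRUE) == mean(y, na.rm = TRUE))
                 1 else NA_real_)
  } else {
    tt <- t.test(x, y)  # Welch by default
  }
  data.frame(group1 = label_x, group2 = label_y,
             mean1 = mean(x, na.rm = TRUE), mean2 = mean(y, na.rm = TRUE),
             n1 = nx, n2 = ny, t = unname(tt$statistic), p = tt$p.value,
             stringsAsFactors = FALSE)
}

# Per-gene mean of `value_fun(gene, samples)` over the samples where the gene
# plays the given fusion role, for each category of partner event.
partner_category_values <- function(events, side = c("5prime", "3prime")) {
  side <- match.arg(side)
  if (side == "5prime") {
    gene <- events$gene5_id
    host <- events$host3
    incl <- events$inclusion3
  } else {
    gene <- events$gene3_id
    host <- events$host5
    incl <- events$inclusion5
  }
  data.frame(gene = gene, sample = events$sample_id,
             category = ifelse(!host, "nonhost",
                               ifelse(!is.na(incl) & incl == "INCLUDED",
                                      "host_included", "host_mirexcl")),
             stringsAsFactors = FALSE)
}

mean_in_samples <- function(mat, gene, samples) {
  v <- mat[gene, samples, drop = TRUE]
  mean(v, na.rm = TRUE)
}

contrast_by_category <- function(per_gene_values) {
  cats <- split(per_gene_values$value, per_gene_values$category)
  pairs <- utils::combn(names(cats), 2, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    welch_contrast(cats[[pr[1]]], cats[[pr[2]]], pr[1], pr[2])
  }))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res
}

#' Expression contrast of fusion partners by partner category
#'
#' For each 5' partner gene, computes its mean log2(FPKM+1) across the
#' samples where it is 5' of a 3'-host (miRNA-including / miRNA-excluding)
#' or 3'-non-host fusion, and across samples where it is not fused at all
#' ("unfused" category). Categories are compared with two-sided Welch tests,
#' BH-adjusted. `side = "3prime"` runs the mirrored analysis for 3' partners
#' of 5'-host fusions.
#'
#' @param expression genes x samples FPKM matrix.
#' @param events classified fusion events.
#' @param side "5prime" (default) or "3prime".
#' @return object of class `contrast_result`: list with `per_gene` values and
#'   the `contrasts` table.
#' @export
expression_contrast <- function(expression, events, side = "5prime") {
  pcv <- partner_category_values(events, side)
  pcv <- pcv[pcv$gene %in% rownames(expression) &
               pcv$sample %in% colnames(expression), , drop = FALSE]
  l2 <- log2(expression + 1)
  per_gene <- do.call(rbind, lapply(
    split(pcv, paste(pcv$gene, pcv$category, sep = "\r")),
    function(g) data.frame(gene = g$gene[1], category = g$category[1],
                           value = mean_in_samples(l2, g$gene[1],
                                                   unique(g$sample)),
                           stringsAsFactors = FALSE)))
  # unfused category: the same genes, in samples with no fusion involving them
  fused_samples <- split(pcv$sample, pcv$gene)
  all_fused <- split(c(events$sample_id, events$sample_id),
                     c(events$gene5_id, events$gene3_id))
  genes_used <- unique(pcv$gene)
  unfused <- do.call(rbind, lapply(genes_used, function(g) {
    s <- setdiff(colnames(expression), all_fused[[g]])
    if (!length(s)) return(NULL)
    data.frame(gene = g, category = "unfused",
               value = mean_in_samples(l2, g, s), stringsAsFactors = FALSE)
  }))
  per_gene <- rbind(per_gene, unfused)
  rownames(per_gene) <- NULL
  out <- list(per_gene = per_gene, contrasts = contrast_by_category(per_gene),
              side = side, measure = "mean log2(FPKM+1)")
  class(out) <- "contrast_result"
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("Partner contrast (", x$side, " partners, ", x$measure, ")\n", sep = "")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Promoter methylation contrast of fusion partners
#'
#' Per gene: mean beta over CpG islands overlapping the strand-aware promoter
#' window (TSS-1000 to TSS+200, closed-interval overlap), averaged over the
#' relevant samples; categories as in [expression_contrast()]. Welch tests on
#' log2(beta + eps).
#'
#' @param beta islands x samples methylation matrix.
#' @param islands island coordinates (island_id, chrom, start, end; 1-based
#'   inclusive).
#' @param annotation a `mirfuse_annotation` (for TSS and strand).
#' @param events classified fusion events.
#' @param side "5prime" (default) or "3prime".
#' @param eps offset added to beta before the log2 transform.
#' @param upstream,downstream promoter window extents around the TSS.
#' @return a `contrast_result`; genes with no promoter island are counted in
#'   `$n_without_island`.
#' @export
methylation_contrast <- function(beta, islands, annotation, events,
                                 side = "5prime", eps = 1e-3,
                                 upstream = 1000, downstream = 200) {
  genes <- annotation$genes
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  win_start <- ifelse(genes$strand == "+", tss - upstream, tss - downstream)
  win_end <- ifelse(genes$strand == "+", tss + downstream, tss + upstream)
  w_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(win_start, 1), win_end))
  i_gr <- GenomicRanges::GRanges(islands$chrom,
                                 IRanges::IRanges(islands$start, islands$end))
  hits <- GenomicRanges::findOverlaps(i_gr, w_gr)
  gene_islands <- split(islands$island_id[S4Vectors::queryHits(hits)],
                        genes$gene_id[S4Vectors::subjectHits(hits)])
  pcv <- partner_category_values(events, side)
  pcv <- pcv[pcv$sample %in% colnames(beta), , drop = FALSE]
  n_without <- length(setdiff(unique(pcv$gene), names(gene_islands)))
  pcv <- pcv[pcv$gene %in% names(gene_islands), , drop = FALSE]
  gene_beta <- function(g, samples) {
    mean(beta[gene_islands[[g]], samples, drop = FALSE], na.rm = TRUE)
  }
  per_gene <- do.call(rbind, lapply(
    split(pcv, paste(pcv$gene, pcv$category, sep = "\r")),
    function(g) data.frame(gene = g$gene[1], category = g$category[1],
                           value = log2(gene_beta(g$gene[1],
                                                  unique(g$sample)) + eps),
                           stringsAsFactors = FALSE)))
  all_fused <- split(c(events$sample_id, events$sample_id),
                     c(events$gene5_id, events$gene3_id))
  unfused <- do.call(rbind, lapply(unique(pcv$gene), function(g) {
    s <- setdiff(colnames(beta), all_fused[[g]])
    if (!length(s)) return(NULL)
    data.frame(gene = g, category = "unfused",
               value = log2(gene_beta(g, s) + eps), stringsAsFactors = FALSE)
  }))
  per_gene <- rbind(per_gene, unfused)
  rownames(per_gene) <- NULL
  out <- list(per_gene = per_gene, contrasts = contrast_by_category(per_gene),
              side = side, measure = sprintf("mean log2(beta + %g)", eps),
              n_without_island = n_without)
  class(out) <- "contrast_result"
  out
}
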