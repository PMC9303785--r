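# Mature-miRNA count aggregation, fusion-conditioned exact-test differential
# expression, and miRNA-target correlation.

#' Aggregate isoform quantifications to mature miRNA counts
#'
#' Each isoform row is assigned to the mature miRNA whose interval contains
#' the isoform's 5' end (strand-aware: the larger coordinate on the minus
#' strand) on the same chromosome and strand; counts are summed per mature
#' miRNA and sample.
#'
#' @param isoforms data frame with sample_id, chrom, start, end, strand,
#'   count.
#' @param matures mature miRNA coordinates (mature_id, chrom, start, end,
#'   strand), e.g. from [read_mirna_annotation()].
#' @return integer matrix matures x samples; unassignable isoforms are
#'   counted in `attr(, "n_unassigned")`.
#' @export
aggregate_mirna_counts <- function(isoforms, matures) {
  samples <- sort(unique(isoforms$sample_id))
  out <- matrix(0L, nrow(matures), length(samples),
                dimnames = list(matures$mature_id, samples))
  if (!nrow(isoforms)) {
    attr(out, "n_unassigned") <- 0L
    return(out)
  }
  pos5 <- ifelse(isoforms$strand == "+", isoforms$start, isoforms$end)
  assigned <- rep(NA_integer_, nrow(isoforms))
  for (i in seq_len(nrow(matures))) {
    hit <- isoforms$chrom == matures$chrom[i] &
      isoforms$strand == matures$strand[i] &
      pos5 >= matures$start[i] & pos5 <= matures$end[i]
    assigned[hit & is.na(assigned)] <- i
  }
  ok <- !is.na(assigned)
  for (j in which(ok)) {
    out[assigned[j], isoforms$sample_id[j]] <-
      out[assigned[j], isoforms$sample_id[j]] + as.integer(isoforms$count[j])
  }
  attr(out, "n_unassigned") <- sum(!ok)
  out
}

#' Counts per million
#'
#' @param counts features x samples count matrix.
#' @param lib_sizes per-sample library sizes (default: column sums).
#' @return CPM matrix.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  stopifnot(all(lib_sizes > 0))
  sweep(counts, 2, lib_sizes / 1e6, "/")
}

#' Split samples by fusion status of a host gene
#'
#' `fused`: tumour samples with at least one surviving event where
#' `host_gene` is the 3' partner. `unfused`: tumour samples with no surviving
#' event involving `host_gene` in either role. Samples whose only events with
#' the gene are 5'-role are excluded from both groups, as are normal-tissue
#' samples.
#'
#' @param events classified, filtered fusion events.
#' @param host_gene gene id.
#' @param clinical sample table with sample_id and tissue.
#' @return list with `fused` and `unfused` character vectors.
#' @export
fusion_conditioned_groups <- function(events, host_gene, clinical) {
  tumours <- clinical$sample_id[clinical$tissue == "tumour"]
  fused <- intersect(unique(events$sample_id[events$gene3_id == host_gene]),
                     tumours)
  any_role <- unique(events$sample_id[events$gene3_id == host_gene |
                                        events$gene5_id == host_gene])
  unfused <- setdiff(tumours, any_role)
  list(fused = fused, unfused = unfused)
}

#' Method-of-moments common dispersion
#'
#' Estimates a single negative-binomial dispersion shared by all features:
#' per feature, `(var - mean) / mean^2` on library-size-equalised counts; the
#' estimate is the median over features with positive mean, clamped to
#' `[0, 5]`.
#'
#' @param counts features x samples count matrix.
#' @param lib_sizes per-sample library sizes (default: column sums).
#' @return non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, lib_sizes = colSums(counts)) {
  ref <- exp(mean(log(lib_sizes)))
  adj <- sweep(counts, 2, ref / lib_sizes, "*")
  m <- rowMeans(adj)
  v <- apply(adj, 1, var)
  ok <- m > 0
  if (!any(ok)) return(0)
  phi <- median((v[ok] - m[ok]) / m[ok]^2)
  min(max(phi, 0), 5)
}

# Conditional two-sided exact p for the split (a, t - a) of the total t
# between nA and nB libraries sharing per-library mean and dispersion phi.
# Sum of nA iid NB(1/phi, p) is NB(nA/phi, p) with p free of nA, so the
# conditional distribution of a given t is free of the mean; phi -> 0 gives
# Binomial(t, nA/(nA+nB)). Two-sided by summing outcomes no more likely than
# the observed one.
exact_nb_test <- function(a, t, nA, nB, phi) {
  if (t == 0) return(1)
  x <- 0:t
  lf <- if (phi < 1e-10) {
    dbinom(x, t, nA / (nA + nB), log = TRUE)
  } else {
    dnbinom(x, size = nA / phi, prob = 0.5, log = TRUE) +
      dnbinom(t - x, size = nB / phi, prob = 0.5, log = TRUE)
  }
  lf <- lf - max(lf)
  f <- exp(lf)
  f <- f / sum(f)
  p <- sum(f[f <= f[a + 1] * (1 + 1e-8)])
  min(p, 1)
}

#' Exact-test differential expression for count features
#'
#' Two-group negative-binomial exact test in the edgeR exactTest tradition,
#' in simplified form: library sizes are equalised by scaling every column to
#' the geometric-mean library size; a common dispersion is estimated by the
#' method of moments (unless supplied); for each feature the group totals of
#' the equalised counts are rounded and the split is tested conditionally on
#' the total, summing the probabilities of all outcomes at most as likely as
#' the observed one (two-sided, capped at 1). In the dispersion-to-zero limit
#' the conditional law is exactly Binomial. The log2 fold-change uses
#' dispersion-free group means with a prior count of 0.125 per library.
#'
#' @param counts features x samples count matrix.
#' @param group1,group2 sample id (or column index) vectors; group1 is the
#'   numerator of the fold-change (e.g. fused samples).
#' @param lib_sizes per-sample library sizes (default: column sums).
#' @param dispersion common NB dispersion; `NULL` (default) estimates it via
#'   [estimate_common_dispersion()] on the tested samples.
#' @param min_group minimum samples per group.
#' @return object of class `de_result`: data frame feature, logFC, p, p_adj,
#'   n_group1, n_group2, flagged (zero-total features get p = 1, logFC = 0),
#'   with the dispersion used as an attribute.
#' @export
exact_test_de <- function(counts, group1, group2,
                          lib_sizes = colSums(counts), dispersion = NULL,
                          min_group = 3) {
  if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(counts)
  stopifnot(all(group1 %in% colnames(counts)),
            all(group2 %in% colnames(counts)),
            !any(group1 %in% group2))
  if (length(group1) < min_group || length(group2) < min_group) {
    stop("fewer than ", min_group, " samples in a group", call. = FALSE)
  }
  sub <- counts[, c(group1, group2), drop = FALSE]
  ls <- lib_sizes[c(group1, group2)]
  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(sub, ls)
  ref <- exp(mean(log(ls)))
  adj <- sweep(sub, 2, ref / ls, "*")
  nA <- length(group1); nB <- length(group2)
  yA <- rowSums(adj[, group1, drop = FALSE])
  yB <- rowSums(adj[, group2, drop = FALSE])
  a <- round(yA); b <- round(yB)
  t_tot <- a + b
  p <- vapply(seq_along(a), function(i) {
    if (t_tot[i] == 0) return(1)
    exact_nb_test(a[i], t_tot[i], nA, nB, dispersion)
  }, numeric(1))
  logFC <- log2((yA / nA + 0.125) / (yB / nB + 0.125))
  logFC[t_tot == 0] <- 0
  out <- data.frame(
    feature = rownames(sub) %||% as.character(seq_along(a)),
    logFC = logFC, p = p, p_adj = p.adjust(p, method = "BH"),
    n_group1 = nA, n_group2 = nB, flagged_zero_total = t_tot == 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dispersion") <- dispersion
  class(out) <- c("de_result", class(out))
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat("Exact-test differential expression:", nrow(x), "features,",
      x$n_group1[1], "vs", x$n_group2[1], "samples, dispersion",
      signif(attr(x, "dispersion"), 3), "\n")
  print.data.frame(head(x[order(x$p), ], 10), digits = 3)
  invisible(x)
}

#' Correlate miRNA expression with predicted targets
#'
#' Pearson correlation of each (mature miRNA, target) prediction pair across
#' the shared samples. miRNA CPM values are log2(x+1)-transformed; target
#' values are log2(x+1)-transformed at the mRNA level and used untransformed
#' at the protein level (protein arrays report already-normalised scores).
#' BH adjustment across all tested pairs.
#'
#' @param mirna_cpm matures x samples CPM matrix.
#' @param target_matrix targets x samples matrix (FPKM or protein scores).
#' @param predictions data frame with mature_id and target_id (extra columns
#'   such as context scores are carried through as annotation).
#' @param level "mRNA" or "protein".
#' @param samples optional sample subset (e.g. tumours only).
#' @param min_obs minimum complete observations per pair.
#' @return data frame mature_id, target_id, level, r, p, p_adj, n; pairs
#'   referencing absent features are skipped and counted in
#'   `attr(, "n_skipped")`.
#' @export
target_correlation <- function(mirna_cpm, target_matrix, predictions,
                               level = c("mRNA", "protein"), samples = NULL,
                               min_obs = 10) {
  level <- match.arg(level)
  samples <- samples %||% intersect(colnames(mirna_cpm),
                                    colnames(target_matrix))
  x_mat <- log2(mirna_cpm[, samples, drop = FALSE] + 1)
  y_mat <- target_matrix[, samples, drop = FALSE]
  if (level == "mRNA") y_mat <- log2(y_mat + 1)
  present <- predictions$mature_id %in% rownames(x_mat) &
    predictions$target_id %in% rownames(y_mat)
  n_skipped <- sum(!present)
  pred <- predictions[present, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pred)), function(i) {
    x <- x_mat[pred$mature_id[i], ]
    y <- y_mat[pred$target_id[i], ]
    ok <- complete.cases(x, y)
    if (sum(ok) < min_obs) return(NULL)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NULL)
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(mature_id = pred$mature_id[i], target_id = pred$target_id[i],
               level = level, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mature_id = character(), target_id = character(),
                      level = character(), r = numeric(), p = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  attr(out, "n_skipped") <- n_skipped
  out
}
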