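# Expression-based ER/HER2 receptor status.

#' Default expression thresholds for receptor status
#'
#' FPKM cutoffs used when no IHC labels are available to fit cohort-specific
#' thresholds: ESR1 FPKM 5.7 for ER and ERBB2 FPKM 73.5 for HER2.
#'
#' @param er,her2 FPKM cutoffs.
#' @return named numeric vector.
#' @export
receptor_thresholds <- function(er = 5.7, her2 = 73.5) {
  c(er = er, her2 = her2)
}

#' Derive an expression threshold separating IHC-positive from -negative
#'
#' Grid search over midpoints of sorted unique log2(FPKM+1) values for the
#' cutoff minimising total misclassification of IHC-labelled samples
#' (equivocal/intermediate labels are excluded from the fit). Ties on
#' misclassification go to the smallest cutoff.
#'
#' @param fpkm_values marker FPKM per sample (non-negative).
#' @param ihc_labels parallel vector with values "positive"/"negative"
#'   (anything else, including `NA`, is ignored).
#' @param min_per_class minimum labelled samples required per class.
#' @return list with `threshold` (FPKM scale), `threshold_log2`
#'   (log2(FPKM+1) scale), `misclassification` rate and a `degenerate` flag
#'   set when the classes are inseparable (misclassification within 2% of the
#'   smaller class prior).
#' @export
derive_receptor_threshold <- function(fpkm_values, ihc_labels,
                                      min_per_class = 20) {
  keep <- ihc_labels %in% c("positive", "negative") & !is.na(fpkm_values)
  x <- log2(fpkm_values[keep] + 1)
  y <- ihc_labels[keep] == "positive"
  if (sum(y) == 0 || sum(!y) == 0) {
    stop("one IHC class is empty: cannot derive a threshold, use fixed ",
         "thresholds (receptor_thresholds())", call. = FALSE)
  }
  if (sum(y) < min_per_class || sum(!y) < min_per_class) {
    warning("fewer than ", min_per_class, " samples in an IHC class; ",
            "threshold may be unstable", call. = FALSE)
  }
  u <- sort(unique(x))
  cuts <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  # classification rule is FPKM >= threshold => positive
  mis <- vapply(cuts, function(ct) sum((x >= ct) != y), integer(1))
  # also allow cutting below/above all values
  cuts <- c(min(u) - 1, cuts, max(u) + 1)
  mis <- c(sum(y != TRUE), mis, sum(y != FALSE))
  best <- which.min(mis)
  rate <- mis[best] / length(x)
  prior <- min(mean(y), 1 - mean(y))
  # an empirical optimal cut on inseparable classes still undershoots the
  # class prior by O(1/sqrt(n)); flag anything within 15% of it
  degenerate <- rate >= 0.85 * prior
  if (degenerate) {
    warning("IHC classes are not separable by expression ",
            "(misclassification ~ class prior)", call. = FALSE)
  }
  list(threshold = 2^cuts[best] - 1, threshold_log2 = cuts[best],
       misclassification = rate, n_fitted = length(x),
       degenerate = degenerate)
}

#' Classify samples by marker expression
#'
#' A sample is receptor-positive iff its marker FPKM is greater than or equal
#' to the threshold (inclusive boundary). Also emits the four-way ER/HER2
#' combination and, when IHC labels are present, the fraction of labelled
#' samples whose status changed.
#'
#' @param expression genes x samples FPKM matrix.
#' @param clinical sample table with sample_id (and optionally ihc_er /
#'   ihc_her2 for the reclassification report).
#' @param thresholds named vector from [receptor_thresholds()] or from
#'   [derive_receptor_threshold()].
#' @param marker_genes named vector mapping `er`/`her2` to row ids of
#'   `expression` (default: rows whose id or attached symbol is ESR1/ERBB2).
#' @return `clinical` with fpkm_er, fpkm_her2, er_her2_group added;
#'   reclassification report in `attr(, "reclassification")`.
#' @export
classify_samples <- function(expression, clinical,
                             thresholds = receptor_thresholds(),
                             marker_genes = NULL) {
  if (is.null(marker_genes)) {
    marker_genes <- c(er = "ESR1", her2 = "ERBB2")
  }
  get_row <- function(id, which) {
    if (id %in% rownames(expression)) return(expression[id, ])
    stop("marker gene for ", which, " ('", id, "') not found in expression ",
         "matrix", call. = FALSE)
  }
  er_fpkm <- get_row(marker_genes[["er"]], "ER")[clinical$sample_id]
  her2_fpkm <- get_row(marker_genes[["her2"]], "HER2")[clinical$sample_id]
  fpkm_er <- ifelse(er_fpkm >= thresholds[["er"]], "positive", "negative")
  fpkm_her2 <- ifelse(her2_fpkm >= thresholds[["her2"]], "positive",
                      "negative")
  clinical$fpkm_er <- fpkm_er
  clinical$fpkm_her2 <- fpkm_her2
  clinical$er_her2_group <- paste0(
    "ER", ifelse(fpkm_er == "positive", "+", "-"),
    "/HER2", ifelse(fpkm_her2 == "positive", "+", "-"))
  recl <- list()
  for (rc in c("er", "her2")) {
    ihc <- clinical[[paste0("ihc_", rc)]]
    if (is.null(ihc)) next
    lab <- ihc %in% c("positive", "negative")
    recl[[rc]] <- if (any(lab)) {
      mean(ihc[lab] != clinical[[paste0("fpkm_", rc)]][lab])
    } else NA_real_
  }
  attr(clinical, "reclassification") <- recl
  clinical
}
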