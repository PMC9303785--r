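# End-to-end orchestration: filter -> annotate -> classify-samples -> assoc ->
# enrich -> mir-de -> wgs-confirm, plus the cohort-level share summary.

#' Per-host fusion-conditioned differential miRNA expression
#'
#' For every miRNA host gene with at least `min_group` fused tumour samples,
#' tests the host's mature miRNAs between fused (host as 3' partner) and
#' unfused samples with the NB exact test; BH adjustment is applied jointly
#' across all tested miRNAs. Hosts with too few fused samples are skipped and
#' listed.
#'
#' @param counts matures x samples count matrix.
#' @param lib_sizes per-sample library sizes.
#' @param events classified, filtered fusion events.
#' @param assignment a `host_assignment`.
#' @param matures mature miRNA table (mature_id, precursor_id).
#' @param clinical sample table (sample_id, tissue).
#' @param min_group minimum fused samples (default 3).
#' @param dispersion common dispersion; `NULL` estimates it once from the
#'   tumour samples.
#' @return data frame host_gene_id, feature, logFC, p, p_adj, n_fused,
#'   n_unfused; skipped hosts in `attr(, "skipped")`.
#' @export
host_fusion_de <- function(counts, lib_sizes, events, assignment, matures,
                           clinical, min_group = 3, dispersion = NULL) {
  hosts <- intersect(names(assignment$gene_to_precursors),
                     unique(events$gene3_id))
  tumours <- intersect(clinical$sample_id[clinical$tissue == "tumour"],
                       colnames(counts))
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(
      counts[, tumours, drop = FALSE], lib_sizes[tumours])
  }
  skipped <- character()
  rows <- list()
  for (h in hosts) {
    grp <- fusion_conditioned_groups(events, h, clinical)
    grp$fused <- intersect(grp$fused, colnames(counts))
    grp$unfused <- intersect(grp$unfused, colnames(counts))
    if (length(grp$fused) < min_group || length(grp$unfused) < min_group) {
      skipped <- c(skipped, h)
      next
    }
    precs <- assignment$gene_to_precursors[[h]]
    mats <- matures$mature_id[matures$precursor_id %in% precs]
    mats <- intersect(mats, rownames(counts))
    if (!length(mats)) next
    de <- exact_test_de(counts[mats, , drop = FALSE], grp$fused, grp$unfused,
                        lib_sizes, dispersion = dispersion,
                        min_group = min_group)
    de$host_gene_id <- h
    rows[[h]] <- de
  }
  if (!length(rows)) {
    out <- data.frame(host_gene_id = character(), feature = character(),
                      logFC = numeric(), p = numeric(), p_adj = numeric(),
                      n_fused = integer(), n_unfused = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(d) {
    data.frame(host_gene_id = d$host_gene_id, feature = d$feature,
               logFC = d$logFC, p = d$p, n_fused = d$n_group1,
               n_unfused = d$n_group2, stringsAsFactors = FALSE)
  }))
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "dispersion") <- dispersion
  out
}

#' Pipeline configuration from a cohort directory
#'
#' Builds a [run_pipeline()] configuration pointing at the files written by
#' [write_cohort()].
#'
#' @param dir cohort directory.
#' @param outdir output directory (default `<dir>/results`).
#' @param ... overrides for any configuration field.
#' @return named list configuration.
#' @export
pipeline_config_from_dir <- function(dir, outdir = file.path(dir, "results"),
                                     ...) {
  sams <- list.files(file.path(dir, "wgs"), pattern = "\\.sam$",
                     full.names = TRUE)
  cfg <- list(
    fusions = file.path(dir, "fusions.tsv"),
    gtf = file.path(dir, "genes.gtf"),
    mirna_gff3 = file.path(dir, "mirna.gff3"),
    clinical = file.path(dir, "clinical.tsv"),
    expr = file.path(dir, "fpkm.tsv"),
    meth = file.path(dir, "meth_beta.tsv"),
    islands = file.path(dir, "cpg_islands.bed"),
    mirna_counts = file.path(dir, "mirna_counts.tsv"),
    mirna_lib_sizes = file.path(dir, "mirna_lib_sizes.tsv"),
    genesets = file.path(dir, "genesets.gmt"),
    tfbs = file.path(dir, "tfbs.bed"),
    wgs = setNames(sams, sub("\\.sam$", "", basename(sams))),
    outdir = outdir,
    blacklist = fusioncatcher_blacklist(),
    min_distance = 10000,
    thresholds = receptor_thresholds(),
    derive_thresholds = TRUE,
    subsample_reps = 3,
    de_min_group = 3,
    seed = 1,
    stages = c(filter = TRUE, annotate = TRUE, classify = TRUE,
               assoc = TRUE, enrich = TRUE, mirde = TRUE, wgs = TRUE)
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full fusion-analysis pipeline
#'
#' Executes filter, annotate, classify-samples, assoc, enrich, mir-de and
#' (when alignments are configured) wgs-confirm off a single configuration,
#' writing per-stage TSVs, an accounting JSON and a provenance log to
#' `config$outdir`. A disabled stage makes any dependent stage fail fast with
#' a dependency message; a stage failure halts the run naming the stage while
#' earlier outputs are retained on disk.
#'
#' @param config configuration list, e.g. from [pipeline_config_from_dir()].
#' @return object of class `mirfuse_report`: list of stage results.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages %||% c(filter = TRUE, annotate = TRUE,
                                 classify = TRUE, assoc = TRUE,
                                 enrich = TRUE, mirde = TRUE, wgs = TRUE)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config)
  need <- function(what, for_stage) {
    if (is.null(bundle[[what]])) {
      stop("stage '", for_stage, "' requires output of a disabled or failed ",
           "upstream stage ('", what, "')", call. = FALSE)
    }
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  annotation <- read_gene_annotation(config$gtf)
  mir <- read_mirna_annotation(config$mirna_gff3)
  clinical <- read.delim(config$clinical, stringsAsFactors = FALSE)
  expression <- read_matrix_tsv(config$expr)

  if (isTRUE(stages[["filter"]])) {
    bundle$filter <- run_stage("filter", {
      events <- read_fusion_calls(config$fusions)
      ff <- filter_by_flags(events, config$blacklist %||%
                              fusioncatcher_blacklist())
      fp <- filter_proximal(ff$events, annotation,
                            config$min_distance %||% 10000)
      tsv(fp$events, "fusions_filtered.tsv")
      list(events = fp$events, flag_report = ff$report,
           proximal_report = fp$report,
           n_input = nrow(events), n_surviving = nrow(fp$events))
    })
  }

  if (isTRUE(stages[["annotate"]])) {
    bundle$annotate <- run_stage("annotate", {
      need("filter", "annotate")
      assignment <- assign_hosts(annotation, mir$mirnas)
      events <- classify_inclusion(bundle$filter$events, assignment,
                                   annotation)
      conv <- convergent_recurrence(events, assignment)
      acc <- event_accounting(events)
      acc$host_sample_counts <- setNames(conv$n_samples, conv$host_gene_id)
      tsv(events, "fusions_annotated.tsv")
      tsv(conv, "convergence.tsv")
      jsonlite::write_json(acc, file.path(outdir, "accounting.json"),
                           auto_unbox = TRUE, digits = NA)
      list(events = events, assignment = assignment, convergence = conv,
           accounting = acc, matures = mir$matures)
    })
  }

  if (isTRUE(stages[["classify"]])) {
    bundle$classify <- run_stage("classify", {
      thresholds <- config$thresholds %||% receptor_thresholds()
      # resolve marker rows: by symbol in the annotation, else by row id
      marker <- vapply(c(er = "ESR1", her2 = "ERBB2"), function(sym) {
        hit <- annotation$genes$gene_id[annotation$genes$symbol == sym]
        if (length(hit) && hit[1] %in% rownames(expression)) hit[1] else sym
      }, character(1))
      fits <- NULL
      if (isTRUE(config$derive_thresholds) &&
          all(c("ihc_er", "ihc_her2") %in% colnames(clinical)) &&
          all(marker %in% rownames(expression))) {
        fits <- list(
          er = try(derive_receptor_threshold(
            expression[marker[["er"]], clinical$sample_id], clinical$ihc_er),
            silent = TRUE),
          her2 = try(derive_receptor_threshold(
            expression[marker[["her2"]], clinical$sample_id],
            clinical$ihc_her2), silent = TRUE))
        if (!inherits(fits$er, "try-error")) {
          thresholds[["er"]] <- fits$er$threshold
        }
        if (!inherits(fits$her2, "try-error")) {
          thresholds[["her2"]] <- fits$her2$threshold
        }
      }
      cls <- classify_samples(expression, clinical, thresholds,
                              marker_genes = marker)
      tsv(cls, "clinical_classified.tsv")
      list(clinical = cls, thresholds = thresholds, threshold_fits = fits)
    })
  }

  universe <- expressed_universe(expression)

  if (isTRUE(stages[["assoc"]])) {
    bundle$assoc <- run_stage("assoc", {
      need("annotate", "assoc")
      ann2 <- annotation
      if (anyNA(ann2$genes$is_mirna_host)) {
        ann2$genes$is_mirna_host <- ann2$genes$gene_id %in%
          names(bundle$annotate$assignment$gene_to_precursors)
      }
      gft <- build_gene_fusion_table(bundle$annotate$events, ann2, universe)
      logit <- host_overrepresentation(gft)
      dist <- partner_distance_analysis(bundle$annotate$events)
      expr_c <- expression_contrast(expression, bundle$annotate$events)
      meth_c <- NULL
      if (!is.null(config$meth)) {
        beta <- read_matrix_tsv(config$meth)
        islands <- read_bed4(config$islands, name_col = "island_id")
        rownames(beta) <- rownames(beta)
        meth_c <- methylation_contrast(beta, islands, annotation,
                                       bundle$annotate$events)
        tsv(meth_c$contrasts, "methylation_contrasts.tsv")
      }
      tsv(expr_c$contrasts, "expression_contrasts.tsv")
      jsonlite::write_json(
        list(coefficients = logit$coefficients, host_p = logit$host_p,
             n = logit$n, separation = logit$separation),
        file.path(outdir, "host_logit.json"), auto_unbox = TRUE, digits = NA)
      list(gene_table = gft, logit = logit, distance = dist,
           expression_contrast = expr_c, methylation_contrast = meth_c)
    })
  }

  if (isTRUE(stages[["enrich"]])) {
    bundle$enrich <- run_stage("enrich", {
      need("annotate", "enrich")
      ann2 <- annotation
      if (anyNA(ann2$genes$is_mirna_host)) {
        ann2$genes$is_mirna_host <- ann2$genes$gene_id %in%
          names(bundle$annotate$assignment$gene_to_precursors)
      }
      lists <- partner_gene_lists(bundle$annotate$events, ann2)
      sets <- read_gmt(config$genesets)
      host_res <- hypergeom_overrep(lists$host5, sets, universe)
      non_res <- balanced_nonhost_enrichment(
        lists$nonhost5, length(intersect(lists$host5, universe)), sets,
        universe, reps = config$subsample_reps %||% 3,
        seed = config$seed %||% 1)
      tf_res <- NULL
      if (!is.null(config$tfbs)) {
        tf_sets <- tf_target_map(read_bed4(config$tfbs, name_col = "tf"),
                                 annotation)
        tf_res <- hypergeom_overrep(lists$host5, tf_sets, universe)
        tsv(tf_res, "tf_enrichment.tsv")
      }
      tsv(host_res, "geneset_enrichment_host5.tsv")
      tsv(non_res, "geneset_enrichment_nonhost5_balanced.tsv")
      list(lists = lists, host = host_res, nonhost_balanced = non_res,
           tf = tf_res, universe = universe)
    })
  }

  if (isTRUE(stages[["mirde"]])) {
    bundle$mirde <- run_stage("mirde", {
      need("annotate", "mirde")
      counts <- read_matrix_tsv(config$mirna_counts)
      lib <- read.delim(config$mirna_lib_sizes, stringsAsFactors = FALSE)
      lib_sizes <- setNames(lib$lib_size, lib$sample_id)
      de <- host_fusion_de(counts, lib_sizes, bundle$annotate$events,
                           bundle$annotate$assignment,
                           bundle$annotate$matures, clinical,
                           min_group = config$de_min_group %||% 3)
      tsv(de, "mirna_de.tsv")
      list(de = de)
    })
  }

  if (isTRUE(stages[["wgs"]]) && length(config$wgs)) {
    bundle$wgs <- run_stage("wgs", {
      need("annotate", "wgs")
      evd <- batch_confirm(bundle$annotate$events, as.list(config$wgs),
                           annotation)
      tsv(evd, "wgs_evidence.tsv")
      list(evidence = evd)
    })
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("mirfuse")),
    seed = config$seed %||% NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages_run = names(stages)[vapply(stages, isTRUE, logical(1))],
    min_distance = config$min_distance %||% 10000,
    universe_rule = attr(universe, "rule")
  )
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  class(bundle) <- "mirfuse_report"
  bundle
}

#' @export
print.mirfuse_report <- function(x, ...) {
  cat("mirfuse pipeline report; stages:",
      paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  if (!is.null(x$annotate)) {
    s <- summarize_shares(x$annotate$accounting)
    cat("  events:", x$annotate$accounting$n_events,
        "| mean fusions/sample:", s$mean_fusions_per_sample,
        "| 3' host incl.:", s$pct_host3_included, "%\n")
  }
  invisible(x)
}

#' Cohort-level share summary
#'
#' Formats the accounting numbers the way cohort papers print them: mean
#' fusions per sample to the nearest integer, inclusion-class and
#' inter/intra-chromosomal shares to one decimal, and the sample-share of
#' fusions per host gene to one decimal — all rounded half-up at the printed
#' precision.
#'
#' @param accounting list with n_events, n_samples and the class counts from
#'   [event_accounting()]; optionally `host_sample_counts` (named: samples
#'   with a 3' fusion of that host).
#' @return list of formatted summary numbers.
#' @export
summarize_shares <- function(accounting) {
  n <- accounting$n_events
  ns <- accounting$n_samples
  pct <- function(k) if (is.null(k) || n == 0) 0 else
    round_half_up(100 * k / n, 1)
  host_share <- NULL
  if (!is.null(accounting$host_sample_counts) && ns > 0) {
    host_share <- vapply(accounting$host_sample_counts,
                         function(k) round_half_up(100 * k / ns, 1), 1)
  }
  list(
    mean_fusions_per_sample = if (ns > 0) round_half_up(n / ns, 0) else 0,
    pct_host3_included = pct(accounting$n_host3_included),
    pct_host3_mirexcl = pct(accounting$n_host3_mirexcl),
    pct_host5_included = pct(accounting$n_host5_included),
    pct_host5_mirexcl = pct(accounting$n_host5_mirexcl),
    pct_inter = pct(accounting$n_inter),
    pct_intra = pct(accounting$n_intra),
    host_sample_share_pct = host_share
  )
}
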