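#' Configuration for the synthetic fusion cohort generator
#'
#' Collects the cohort dimensions and planted effect sizes used by all
#' `generate_*()` functions. Every downstream stage of the package can be
#' exercised on a cohort drawn from this configuration, with known truth.
#'
#' @param n_samples number of samples (tumour + normal).
#' @param n_genes number of genes in the annotation.
#' @param frac_mirna_hosts fraction of genes hosting one intronic miRNA.
#' @param frac_snorna_hosts fraction of genes flagged as canonical snoRNA
#'   hosts (disjoint from miRNA hosts).
#' @param host_fusion_odds_ratio planted odds ratio with which a miRNA host
#'   gene is chosen as the 3' fusion partner, relative to a non-host of the
#'   same expression rank.
#' @param mean_fusions_per_sample Poisson mean of fusion events per tumour
#'   sample.
#' @param expr_uplift_log2fc planted log2 expression uplift of the 5' partner
#'   of a host fusion, in the fused sample.
#' @param meth_shift planted additive shift of the promoter-island beta value
#'   of those same 5' partners (negative = hypomethylation), in (-1, 1).
#' @param mir_fusion_log2fc planted log2 fold-change of the mature miRNAs of a
#'   host gene in samples where that host is a 3' fusion partner.
#' @param nb_dispersion negative-binomial dispersion of the miRNA counts
#'   (0 gives Poisson counts).
#' @param frac_normal fraction of samples labelled normal tissue.
#' @param frac_blacklisted fraction of fusion events carrying at least one
#'   blacklisted artefact flag.
#' @param frac_intra fraction of events that are intra-chromosomal.
#' @param intra_host_distance_power exponent of a distance weight applied when
#'   sampling intra-chromosomal 3' host partners; 0 (default) means partner
#'   distance carries no extra weight, positive values plant larger partner
#'   distances for host fusions.
#' @param allow_partial_overlap_breakpoints if `FALSE` (default), breakpoints
#'   are resampled so they never fall inside a mature miRNA, keeping the
#'   inclusion classifier's boundary branches testable in isolation.
#' @param n_chromosomes number of chromosomes the genes are laid out on.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_samples = 100, n_genes = 400,
                         frac_mirna_hosts = 0.10, frac_snorna_hosts = 0.03,
                         host_fusion_odds_ratio = 3,
                         mean_fusions_per_sample = 20,
                         expr_uplift_log2fc = 1.0, meth_shift = -0.15,
                         mir_fusion_log2fc = 2, nb_dispersion = 0.2,
                         frac_normal = 0.10, frac_blacklisted = 0.15,
                         frac_intra = 0.092, intra_host_distance_power = 0,
                         allow_partial_overlap_breakpoints = FALSE,
                         n_chromosomes = 4, seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    frac_mirna_hosts = frac_mirna_hosts,
    frac_snorna_hosts = frac_snorna_hosts,
    host_fusion_odds_ratio = host_fusion_odds_ratio,
    mean_fusions_per_sample = mean_fusions_per_sample,
    expr_uplift_log2fc = expr_uplift_log2fc, meth_shift = meth_shift,
    mir_fusion_log2fc = mir_fusion_log2fc, nb_dispersion = nb_dispersion,
    frac_normal = frac_normal, frac_blacklisted = frac_blacklisted,
    frac_intra = frac_intra,
    intra_host_distance_power = intra_host_distance_power,
    allow_partial_overlap_breakpoints = allow_partial_overlap_breakpoints,
    n_chromosomes = as.integer(n_chromosomes), seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_samples >= 1, cfg$n_genes >= 1, cfg$n_chromosomes >= 2,
    cfg$frac_mirna_hosts >= 0, cfg$frac_mirna_hosts <= 1,
    cfg$frac_snorna_hosts >= 0, cfg$frac_snorna_hosts <= 1,
    cfg$frac_mirna_hosts + cfg$frac_snorna_hosts <= 1,
    cfg$host_fusion_odds_ratio > 0, cfg$mean_fusions_per_sample > 0,
    cfg$meth_shift > -1, cfg$meth_shift < 1, cfg$nb_dispersion >= 0,
    cfg$frac_normal >= 0, cfg$frac_normal < 1,
    cfg$frac_blacklisted >= 0, cfg$frac_blacklisted <= 1,
    cfg$frac_intra >= 0, cfg$frac_intra <= 1
  )
  class(cfg) <- "synth_config"
  cfg
}

# Maximum chromosome length the layout may use; genes that cannot be packed
# within it raise a sizing error.
.MAX_CHROM_LEN <- 268435456L

#' Generate synthetic gene and miRNA annotation
#'
#' Lays out non-overlapping genes on several chromosomes (both strands),
#' plants one intronic miRNA precursor (with 5p/3p mature products) in a
#' configured fraction of genes, and flags a disjoint fraction as snoRNA
#' hosts. Host genes get a two-exon structure whose intron contains the
#' precursor; other genes are single-exon. The first two genes carry the
#' marker symbols ESR1 and ERBB2 used for receptor-status classification and
#' are never hosts.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `mirfuse_annotation`: a list with data frames
#'   `genes` (gene_id, symbol, chrom, start, end, strand, is_mirna_host,
#'   is_snorna_host, base_log2_fpkm), `exons`, `mirnas` (precursors, with the
#'   planted `host_gene_id` truth) and `matures`, plus `chrom_len`.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(derive_seed(cfg$seed, "annotation"), {
    n <- cfg$n_genes
    gene_id <- sprintf("G%04d", seq_len(n))
    symbol <- gene_id
    if (n >= 1) symbol[1] <- "ESR1"
    if (n >= 2) symbol[2] <- "ERBB2"
    chrom <- paste0("chr", 1 + (seq_len(n) - 1) %% cfg$n_chromosomes)
    # interleave so every chromosome gets genes of all expression ranks
    size <- as.integer(pmin(pmax(round(rlnorm(n, log(20000), 0.6)), 2000),
                            200000))
    gap <- as.integer(pmax(round(rlnorm(n, log(15000), 0.5)), 1000))
    start <- integer(n); end <- integer(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos <- 10000L
      for (i in idx) {
        start[i] <- pos
        end[i] <- pos + size[i] - 1L
        pos <- end[i] + gap[i]
      }
      if (pos > .MAX_CHROM_LEN) {
        stop("synthetic genes do not fit on chromosome ", ch,
             ": reduce n_genes or gene sizes", call. = FALSE)
      }
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    base_log2_fpkm <- rnorm(n, 3, 1.5)

    eligible <- setdiff(seq_len(n), 1:2)  # marker genes are never hosts
    n_host <- round(cfg$frac_mirna_hosts * n)
    n_sno <- round(cfg$frac_snorna_hosts * n)
    host_idx <- sort(sample(eligible, min(n_host, length(eligible))))
    sno_idx <- sort(sample(setdiff(eligible, host_idx),
                           min(n_sno, length(eligible) - length(host_idx))))
    is_mirna_host <- seq_len(n) %in% host_idx
    is_snorna_host <- seq_len(n) %in% sno_idx

    genes <- data.frame(
      gene_id = gene_id, symbol = symbol, chrom = chrom,
      start = start, end = end, strand = strand,
      is_mirna_host = is_mirna_host, is_snorna_host = is_snorna_host,
      base_log2_fpkm = base_log2_fpkm, stringsAsFactors = FALSE
    )

    # exon structure: hosts get two terminal exons with an intron between
    h <- which(is_mirna_host)
    nh <- length(h)
    span_h <- end[h] - start[h] + 1L
    elen <- pmax(200L, as.integer(round(span_h * 0.1)))
    ex1_end <- start[h] + elen - 1L
    ex2_start <- end[h] - elen + 1L
    nonhost <- which(!is_mirna_host)
    exons <- data.frame(
      gene_id = c(gene_id[nonhost], rep(gene_id[h], 2)),
      chrom = c(chrom[nonhost], rep(chrom[h], 2)),
      start = c(start[nonhost], start[h], ex2_start),
      end = c(end[nonhost], ex1_end, end[h]),
      strand = c(strand[nonhost], rep(strand[h], 2)),
      stringsAsFactors = FALSE
    )
    if (nh > 0) {
      plen <- 80L
      intron_lo <- ex1_end + 1L
      intron_hi <- ex2_start - 1L
      room <- intron_hi - intron_lo - plen
      pstart <- intron_lo + as.integer(floor(runif(nh) * room)) + 1L
      pend <- pstart + plen - 1L
      mirnas <- data.frame(
        precursor_id = sprintf("MI%04d", h), name = sprintf("mir-%04d", h),
        chrom = chrom[h], start = pstart, end = pend, strand = strand[h],
        host_gene_id = gene_id[h], stringsAsFactors = FALSE
      )
      # 5p mature sits at the 5' end of the precursor in its orientation
      low_s <- pstart + 4L; low_e <- pstart + 25L
      high_s <- pend - 25L; high_e <- pend - 4L
      plus <- strand[h] == "+"
      matures <- data.frame(
        mature_id = c(sprintf("miR-%04d-5p", h), sprintf("miR-%04d-3p", h)),
        precursor_id = rep(sprintf("MI%04d", h), 2),
        chrom = rep(chrom[h], 2),
        start = c(ifelse(plus, low_s, high_s), ifelse(plus, high_s, low_s)),
        end = c(ifelse(plus, low_e, high_e), ifelse(plus, high_e, low_e)),
        strand = rep(strand[h], 2), stringsAsFactors = FALSE
      )
    } else {
      mirnas <- data.frame(precursor_id = character(), name = character(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           host_gene_id = character(), stringsAsFactors = FALSE)
      matures <- data.frame(mature_id = character(),
                            precursor_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), stringsAsFactors = FALSE)
    }

    chrom_len <- vapply(split(end, chrom), function(e) max(e) + 10000L, 1)
    ann <- list(genes = genes, exons = exons, mirnas = mirnas,
                matures = matures, chrom_len = chrom_len)
    class(ann) <- "mirfuse_annotation"
    ann
  })
}

#' Generate a synthetic clinical table
#'
#' Samples are labelled tumour/normal; per-sample marker expression for the
#' ESR1 and ERBB2 genes is drawn from two shifted log-normal components per
#' receptor so that the expression-based threshold derivation has a
#' recoverable intersection (placed near FPKM 5.7 for ER and 73.5 for HER2).
#' IHC labels equal the generating component with a small label-noise,
#' missing and equivocal fraction.
#'
#' @param cfg a [synth_config()].
#' @param annotation from [generate_annotation()] (unused fields reserved).
#' @return data frame with sample_id, tissue, ihc_er, ihc_her2, pam50 and the
#'   underlying er_fpkm / her2_fpkm marker values (consumed by
#'   [generate_expression()]).
#' @export
generate_clinical <- function(cfg, annotation) {
  with_seed(derive_seed(cfg$seed, "clinical"), {
    n <- cfg$n_samples
    sample_id <- sprintf("S%04d", seq_len(n))
    tissue <- ifelse(runif(n) < cfg$frac_normal, "normal", "tumour")
    if (!any(tissue == "tumour")) tissue[1] <- "tumour"
    er_true <- runif(n) < 0.75
    her2_true <- runif(n) < 0.145
    # components on log2(FPKM + 1); midpoints sit at log2(5.7+1), log2(73.5+1)
    er_l2 <- rnorm(n, ifelse(er_true, 4.744, 0.744), 1.0)
    her2_l2 <- rnorm(n, ifelse(her2_true, 8.219, 4.219), 1.0)
    er_fpkm <- pmax(2^er_l2 - 1, 0)
    her2_fpkm <- pmax(2^her2_l2 - 1, 0)
    ihc_label <- function(truth) {
      lab <- ifelse(truth, "positive", "negative")
      flip <- runif(n) < 0.03
      lab[flip] <- ifelse(lab[flip] == "positive", "negative", "positive")
      lab[runif(n) < 0.02] <- "equivocal"
      lab[runif(n) < 0.04] <- NA
      lab
    }
    pam50 <- ifelse(
      tissue == "tumour",
      sample(c("LumA", "LumB", "Her2", "Basal", "Normal-like"), n,
             replace = TRUE, prob = c(0.52, 0.20, 0.08, 0.17, 0.03)),
      NA_character_
    )
    data.frame(
      sample_id = sample_id, tissue = tissue,
      ihc_er = ihc_label(er_true), ihc_her2 = ihc_label(her2_true),
      pam50 = pam50, er_fpkm = er_fpkm, her2_fpkm = her2_fpkm,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate synthetic fusion calls
#'
#' Per tumour sample, a Poisson number of events. The 5' partner is sampled
#' with weight proportional to the gene's expression rank (rank/n), encoding
#' that fusion detection depends on expression; the 3' partner weight is
#' additionally multiplied by `host_fusion_odds_ratio` for miRNA host genes.
#' A configured fraction of events is intra-chromosomal; breakpoints are
#' uniform inside each partner's span (avoiding mature miRNAs unless
#' configured otherwise); a configured fraction of events carries blacklisted
#' artefact flags.
#'
#' @param cfg a [synth_config()].
#' @param annotation from [generate_annotation()].
#' @param clinical from [generate_clinical()].
#' @return data frame of fusion events with planted truth columns `host3`,
#'   `host5` and `blacklisted`.
#' @export
generate_fusions <- function(cfg, annotation, clinical) {
  genes <- annotation$genes
  n <- nrow(genes)
  stopifnot(n >= 2)
  with_seed(derive_seed(cfg$seed, "fusions"), {
    rank_w <- rank(genes$base_log2_fpkm, ties.method = "first") / n
    w3 <- rank_w * ifelse(genes$is_mirna_host, cfg$host_fusion_odds_ratio, 1)
    tumours <- clinical$sample_id[clinical$tissue == "tumour"]
    n_ev <- rpois(length(tumours), cfg$mean_fusions_per_sample)
    total <- sum(n_ev)
    if (total == 0) {
      return(empty_fusion_frame())
    }
    sample_id <- rep(tumours, n_ev)
    blk <- fusioncatcher_blacklist()
    benign <- c("known", "exon-exon", "in-frame")

    g5 <- integer(total); g3 <- integer(total)
    for (k in seq_len(total)) {
      i5 <- sample.int(n, 1L, prob = rank_w)
      intra <- runif(1) < cfg$frac_intra
      cand <- if (intra) {
        setdiff(which(genes$chrom == genes$chrom[i5]), i5)
      } else {
        setdiff(which(genes$chrom != genes$chrom[i5]), i5)
      }
      if (!length(cand)) cand <- setdiff(seq_len(n), i5)
      wc <- w3[cand]
      if (intra && cfg$intra_host_distance_power > 0) {
        d <- abs((genes$start[cand] + genes$end[cand]) / 2 -
                 (genes$start[i5] + genes$end[i5]) / 2)
        wc <- wc * ifelse(genes$is_mirna_host[cand],
                          (d / max(d))^cfg$intra_host_distance_power, 1)
      }
      i3 <- cand[sample.int(length(cand), 1L, prob = wc)]
      g5[k] <- i5; g3[k] <- i3
    }

    draw_bp <- function(i) {
      lo <- genes$start[i] + 1L; hi <- genes$end[i] - 1L
      pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      if (!cfg$allow_partial_overlap_breakpoints && genes$is_mirna_host[i]) {
        mm <- annotation$matures[
          annotation$matures$precursor_id ==
            annotation$mirnas$precursor_id[annotation$mirnas$host_gene_id ==
                                             genes$gene_id[i]], , drop = FALSE]
        for (try in 1:50) {
          if (!any(pos >= mm$start & pos <= mm$end)) break
          pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        }
      }
      pos
    }
    pos5 <- as.integer(vapply(g5, draw_bp, 1))
    pos3 <- as.integer(vapply(g3, draw_bp, 1))

    blacklisted <- runif(total) < cfg$frac_blacklisted
    flags <- character(total)
    for (k in seq_len(total)) {
      fl <- if (blacklisted[k]) sample(blk, sample(1:2, 1)) else
        sample(benign, sample(0:2, 1))
      flags[k] <- paste(fl, collapse = ",")
    }

    ev <- data.frame(
      sample_id = sample_id,
      gene5_id = genes$gene_id[g5], gene3_id = genes$gene_id[g3],
      symbol5 = genes$symbol[g5], symbol3 = genes$symbol[g3],
      chrom5 = genes$chrom[g5], pos5 = pos5, strand5 = genes$strand[g5],
      chrom3 = genes$chrom[g3], pos3 = pos3, strand3 = genes$strand[g3],
      flags = flags,
      spanning_reads = 2L + rpois(total, 5),
      host5 = genes$is_mirna_host[g5], host3 = genes$is_mirna_host[g3],
      blacklisted = blacklisted,
      stringsAsFactors = FALSE
    )
    ev
  })
}

empty_fusion_frame <- function() {
  data.frame(
    sample_id = character(), gene5_id = character(), gene3_id = character(),
    symbol5 = character(), symbol3 = character(),
    chrom5 = character(), pos5 = integer(), strand5 = character(),
    chrom3 = character(), pos3 = integer(), strand3 = character(),
    flags = character(), spanning_reads = integer(),
    host5 = logical(), host3 = logical(), blacklisted = logical(),
    stringsAsFactors = FALSE
  )
}

#' Generate the synthetic FPKM expression matrix
#'
#' Log-normal baseline per gene; the planted log2 uplift is added to the 5'
#' partner of every host fusion in the fused sample. Marker rows (ESR1,
#' ERBB2) are taken from the clinical table's mixture components so that
#' receptor classification is recoverable.
#'
#' @param cfg,annotation,clinical,fusions generator inputs.
#' @return genes x samples FPKM matrix.
#' @export
generate_expression <- function(cfg, annotation, clinical, fusions) {
  genes <- annotation$genes
  with_seed(derive_seed(cfg$seed, "expression"), {
    l2 <- matrix(rnorm(nrow(genes) * nrow(clinical), 0, 0.5),
                 nrow(genes), nrow(clinical)) + genes$base_log2_fpkm
    rownames(l2) <- genes$gene_id
    colnames(l2) <- clinical$sample_id
    if (nrow(fusions)) {
      hf <- fusions[fusions$host3, , drop = FALSE]
      for (k in seq_len(nrow(hf))) {
        l2[hf$gene5_id[k], hf$sample_id[k]] <-
          l2[hf$gene5_id[k], hf$sample_id[k]] + cfg$expr_uplift_log2fc
      }
    }
    fpkm <- 2^l2
    esr1 <- genes$gene_id[genes$symbol == "ESR1"]
    erbb2 <- genes$gene_id[genes$symbol == "ERBB2"]
    if (length(esr1)) fpkm[esr1, ] <- clinical$er_fpkm
    if (length(erbb2)) fpkm[erbb2, ] <- clinical$her2_fpkm
    fpkm
  })
}

#' Generate synthetic promoter methylation (beta) values
#'
#' One CpG island per gene, placed inside the strand-aware promoter window
#' (TSS-1000 to TSS+200). Per-island baselines are Beta-distributed; the
#' planted `meth_shift` is added to the island mean of the 5' partner of a
#' host fusion in the fused sample (clamped to (0, 1)).
#'
#' @param cfg,annotation,clinical,fusions generator inputs.
#' @return list with `beta` (islands x samples matrix) and `islands`
#'   (island_id, chrom, start, end, gene_id; 1-based inclusive coordinates).
#' @export
generate_methylation <- function(cfg, annotation, clinical, fusions) {
  genes <- annotation$genes
  with_seed(derive_seed(cfg$seed, "methylation"), {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    ist <- ifelse(genes$strand == "+", tss - 600L, tss + 200L)
    ien <- ifelse(genes$strand == "+", tss - 200L, tss + 600L)
    islands <- data.frame(
      island_id = sprintf("CGI%04d", seq_len(nrow(genes))),
      chrom = genes$chrom, start = pmax(ist, 1L), end = pmax(ien, 1L),
      gene_id = genes$gene_id, stringsAsFactors = FALSE
    )
    m0 <- rbeta(nrow(genes), 2, 6)
    m0 <- pmin(pmax(m0, 0.02), 0.98)
    kappa <- 30
    shift <- matrix(0, nrow(genes), nrow(clinical),
                    dimnames = list(genes$gene_id, clinical$sample_id))
    if (nrow(fusions)) {
      hf <- fusions[fusions$host3, , drop = FALSE]
      for (k in seq_len(nrow(hf)))
        shift[hf$gene5_id[k], hf$sample_id[k]] <- cfg$meth_shift
    }
    m <- pmin(pmax(m0 + shift, 0.01), 0.99)
    beta <- matrix(rbeta(length(m), m * kappa, (1 - m) * kappa),
                   nrow(genes), nrow(clinical))
    dimnames(beta) <- list(islands$island_id, clinical$sample_id)
    list(beta = beta, islands = islands)
  })
}

#' Generate synthetic mature-miRNA counts
#'
#' Negative-binomial counts per mature miRNA and sample, with library sizes
#' varying at most two-fold. The planted log2 fold-change is applied to the
#' mature products of a host gene in samples where that host is the 3'
#' partner of a fusion event.
#'
#' @param cfg,annotation,clinical,fusions generator inputs.
#' @return list with integer `counts` (matures x samples) and `lib_sizes`.
#' @export
generate_mirna_counts <- function(cfg, annotation, clinical, fusions) {
  mat <- annotation$matures
  with_seed(derive_seed(cfg$seed, "mirna"), {
    nmat <- nrow(mat); ns <- nrow(clinical)
    lib <- round(runif(ns, 7.5e5, 1.5e6))
    names(lib) <- clinical$sample_id
    if (nmat == 0) {
      return(list(counts = matrix(0L, 0, ns,
                                  dimnames = list(NULL, clinical$sample_id)),
                  lib_sizes = lib))
    }
    base <- rnorm(nmat, 6, 1.5)
    lfc <- matrix(0, nmat, ns,
                  dimnames = list(mat$mature_id, clinical$sample_id))
    if (nrow(fusions)) {
      hf <- fusions[fusions$host3, , drop = FALSE]
      prec_of_host <- split(annotation$mirnas$precursor_id,
                            annotation$mirnas$host_gene_id)
      for (k in seq_len(nrow(hf))) {
        precs <- prec_of_host[[hf$gene3_id[k]]]
        rows <- which(mat$precursor_id %in% precs)
        lfc[rows, hf$sample_id[k]] <- cfg$mir_fusion_log2fc
      }
    }
    mu <- 2^(base + lfc) * rep(lib / 1e6, each = nmat)
    counts <- if (cfg$nb_dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
             nmat, ns)
    } else {
      matrix(rpois(length(mu), mu), nmat, ns)
    }
    dimnames(counts) <- list(mat$mature_id, clinical$sample_id)
    list(counts = counts, lib_sizes = lib)
  })
}

#' Generate synthetic gene-set collections
#'
#' @param cfg,annotation generator inputs.
#' @param n_sets,min_size,max_size collection shape.
#' @return named list of gene-id vectors (one GMT-style collection).
#' @export
generate_genesets <- function(cfg, annotation, n_sets = 20,
                              min_size = 10, max_size = 40) {
  with_seed(derive_seed(cfg$seed, "genesets"), {
    ids <- annotation$genes$gene_id
    sizes <- sample(min_size:min(max_size, length(ids)), n_sets, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(ids, s))
    names(sets) <- sprintf("SET%02d", seq_len(n_sets))
    sets
  })
}

#' Generate a synthetic TF binding-site track
#'
#' Each TF gets one binding interval inside the promoter window of a random
#' subset of genes, plus decoy intervals inside gene bodies.
#'
#' @param cfg,annotation generator inputs.
#' @param n_tfs number of transcription factors.
#' @param frac_targets fraction of genes targeted per TF.
#' @return data frame chrom, start, end, tf (1-based inclusive coordinates).
#' @export
generate_tfbs <- function(cfg, annotation, n_tfs = 8, frac_targets = 0.25) {
  genes <- annotation$genes
  with_seed(derive_seed(cfg$seed, "tfbs"), {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    rows <- list()
    for (t in seq_len(n_tfs)) {
      tf <- sprintf("TF%02d", t)
      targ <- sample(nrow(genes), max(1, round(frac_targets * nrow(genes))))
      off <- sample(-900:100, length(targ), replace = TRUE)
      st <- ifelse(genes$strand[targ] == "+", tss[targ] + off,
                   tss[targ] - off - 11L)
      rows[[t]] <- data.frame(chrom = genes$chrom[targ],
                              start = pmax(st, 1L), end = pmax(st, 1L) + 11L,
                              tf = tf, stringsAsFactors = FALSE)
    }
    decoy_idx <- sample(nrow(genes), min(20, nrow(genes)))
    mid <- (genes$start[decoy_idx] + genes$end[decoy_idx]) %/% 2L
    rows[[n_tfs + 1]] <- data.frame(
      chrom = genes$chrom[decoy_idx], start = mid, end = mid + 11L,
      tf = sample(sprintf("TF%02d", seq_len(n_tfs)), length(decoy_idx),
                  replace = TRUE),
      stringsAsFactors = FALSE
    )
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic WGS alignments with planted discordant pairs
#'
#' For a configured fraction of fusion events, 1-10 read pairs are planted
#' with one mate inside each partner gene span (the DNA-level confirmation
#' signal); the rest of the reads are concordant background pairs within
#' single genes. Output is valid SAM text per sample.
#'
#' @param cfg,fusions,annotation generator inputs.
#' @param frac_confirmed fraction of events receiving bridging pairs.
#' @param n_background concordant background pairs per sample.
#' @return list with `sam` (named list of character vectors, one SAM file per
#'   fused sample) and `confirmed` (logical per fusion row).
#' @export
generate_wgs_reads <- function(cfg, fusions, annotation, frac_confirmed = 1,
                               n_background = 50) {
  genes <- annotation$genes
  with_seed(derive_seed(cfg$seed, "wgs"), {
    nev <- nrow(fusions)
    confirmed <- rep(FALSE, nev)
    if (nev > 0 && frac_confirmed > 0) {
      n_conf <- if (frac_confirmed >= 1) nev else round(frac_confirmed * nev)
      confirmed[sample.int(nev, n_conf)] <- TRUE
    }
    header <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", names(annotation$chrom_len),
              as.integer(annotation$chrom_len))
    )
    seq50 <- strrep("A", 50)
    qual50 <- strrep("I", 50)
    aln <- function(qname, flag, chrom, pos, rnext, pnext) {
      rn <- if (rnext == chrom) "=" else rnext
      sprintf("%s\t%d\t%s\t%d\t60\t50M\t%s\t%d\t0\t%s\t%s",
              qname, flag, chrom, pos, rn, pnext, seq50, qual50)
    }
    span_of <- function(gid) {
      i <- match(gid, genes$gene_id)
      c(genes$start[i], genes$end[i], i)
    }
    sams <- list()
    for (s in unique(fusions$sample_id)) {
      rows <- which(fusions$sample_id == s)
      lines <- character()
      for (k in rows) {
        if (!confirmed[k]) next
        sp5 <- span_of(fusions$gene5_id[k])
        sp3 <- span_of(fusions$gene3_id[k])
        npair <- sample(1:10, 1)
        for (j in seq_len(npair)) {
          p5 <- sp5[1] + sample.int(max(sp5[2] - sp5[1] - 49L, 1L), 1L) - 1L
          p3 <- sp3[1] + sample.int(max(sp3[2] - sp3[1] - 49L, 1L), 1L) - 1L
          qn <- sprintf("bridge_%s_e%d_%d", s, k, j)
          lines <- c(lines,
            aln(qn, 97L, fusions$chrom5[k], p5, fusions$chrom3[k], p3),
            aln(qn, 145L, fusions$chrom3[k], p3, fusions$chrom5[k], p5))
        }
      }
      bg_gene <- sample.int(nrow(genes), n_background, replace = TRUE)
      for (j in seq_len(n_background)) {
        i <- bg_gene[j]
        w <- max(genes$end[i] - genes$start[i] - 350L, 1L)
        p1 <- genes$start[i] + sample.int(w, 1L) - 1L
        p2 <- p1 + 300L
        qn <- sprintf("bg_%s_%d", s, j)
        lines <- c(lines,
          aln(qn, 99L, genes$chrom[i], p1, genes$chrom[i], p2),
          aln(qn, 147L, genes$chrom[i], p2, genes$chrom[i], p1))
      }
      sams[[s]] <- c(header, lines)
    }
    list(sam = sams, confirmed = confirmed)
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs every generator section off one configuration; each section draws
#' from its own deterministically derived sub-seed, so the cohort is a pure
#' function of the configuration and adding sections never perturbs earlier
#' output.
#'
#' @param cfg a [synth_config()].
#' @param frac_confirmed fraction of fusion events given DNA-level support.
#' @return object of class `synth_cohort`.
#' @export
generate_cohort <- function(cfg, frac_confirmed = 1) {
  annotation <- generate_annotation(cfg)
  clinical <- generate_clinical(cfg, annotation)
  fusions <- generate_fusions(cfg, annotation, clinical)
  expression <- generate_expression(cfg, annotation, clinical, fusions)
  methylation <- generate_methylation(cfg, annotation, clinical, fusions)
  mirna <- generate_mirna_counts(cfg, annotation, clinical, fusions)
  genesets <- generate_genesets(cfg, annotation)
  tfbs <- generate_tfbs(cfg, annotation)
  wgs <- generate_wgs_reads(cfg, fusions, annotation, frac_confirmed)
  fusions$confirmed <- wgs$confirmed
  out <- list(config = cfg, annotation = annotation, clinical = clinical,
              fusions = fusions, expression = expression,
              methylation = methylation, mirna = mirna,
              genesets = genesets, tfbs = tfbs, wgs = wgs$sam)
  class(out) <- "synth_cohort"
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic fusion cohort:",
      nrow(x$clinical), "samples,",
      nrow(x$annotation$genes), "genes (",
      sum(x$annotation$genes$is_mirna_host), "miRNA hosts ),",
      nrow(x$fusions), "fusion events\n")
  invisible(x)
}
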