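test_that("gene fusion table derives role indicators from events", {
  genes <- data.frame(gene_id = c("A", "B", "H", "N"), chrom = "chr1",
                      start = c(1L, 1000L, 2000L, 3000L),
                      end = c(500L, 1500L, 2500L, 3500L), strand = "+",
                      is_mirna_host = c(FALSE, FALSE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  ann <- make_ann(genes)
  ev <- make_events("S1", c("A", "B"), c("H", "N"),
                    host3 = c(TRUE, FALSE), host5 = c(FALSE, FALSE))
  tab <- build_gene_fusion_table(ev, ann, universe = c("A", "B", "H"))
  expect_equal(nrow(tab), 3)  # universe intersection
  expect_true(tab$fused_as_5prime_of_host[tab$gene_id == "A"])
  expect_false(tab$fused_as_5prime_of_host[tab$gene_id == "B"])
  expect_true(tab$fused_any[tab$gene_id == "H"])
  expect_equal(tab$gene_size[tab$gene_id == "A"], 500L)
})

test_that("logistic fit matches a hand-written IRLS oracle to 1e-6", {
  set.seed(42)
  n <- 50
  tab <- data.frame(
    gene_id = paste0("G", 1:n),
    is_mirna_host = rep(c(TRUE, FALSE), c(15, 35)),
    is_snorna_host = FALSE,
    gene_size = round(10^runif(n, 3.5, 5.5)),
    stringsAsFactors = FALSE
  )
  eta <- -1 + 1.2 * tab$is_mirna_host + 0.3 * scale(log10(tab$gene_size))
  tab$fused_any <- runif(n) < plogis(as.numeric(eta))
  fit <- host_overrepresentation(tab)
  ls <- log10(tab$gene_size) - mean(log10(tab$gene_size))
  X <- cbind(1, as.integer(tab$is_mirna_host), ls,
             as.integer(tab$is_mirna_host) * ls)
  oracle <- irls_logistic(X, as.integer(tab$fused_any))
  expect_equal(unname(fit$coefficients$estimate), unname(oracle$coef),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$se), unname(oracle$se),
               tolerance = 1e-6)
  expect_false(fit$separation)
})

test_that("perfect separation is flagged and handled by a penalised refit", {
  tab <- data.frame(
    gene_id = paste0("G", 1:40),
    is_mirna_host = rep(c(TRUE, FALSE), each = 20),
    is_snorna_host = FALSE,
    gene_size = rep(10000L, 40),
    fused_any = rep(c(TRUE, FALSE), each = 20),
    stringsAsFactors = FALSE
  )
  fit <- host_overrepresentation(tab)
  expect_true(fit$separation)
  expect_true(fit$penalized)
  # non-aliased terms have finite (shrunken) estimates
  expect_true(all(is.finite(fit$coefficients$estimate[1:2])))
  expect_true(is.finite(fit$host_p))
})

test_that("distance analysis: hand-checked medians, degenerate and swap invariance", {
  ev <- make_events("S1", paste0("A", 1:5), paste0("B", 1:5),
                    pos5 = c(100L, 100L, 100L, 100L, 100L),
                    pos3 = c(1100L, 2100L, 3100L, 4100L, 5100L),
                    host3 = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  res <- partner_distance_analysis(ev)
  expect_equal(res$median_host, 1500)   # median(1000, 2000)
  expect_equal(res$median_nonhost, 4000) # median(3000, 4000, 5000)
  # swapping breakpoint roles leaves distances unchanged
  ev_sw <- ev
  ev_sw$pos5 <- ev$pos3; ev_sw$pos3 <- ev$pos5
  res_sw <- partner_distance_analysis(ev_sw)
  expect_equal(res_sw$median_host, res$median_host)
  expect_equal(res_sw$fisher_p, res$fisher_p)
  # all distances equal: both tests degenerate to p = 1
  ev_eq <- ev
  ev_eq$pos3 <- ev_eq$pos5 + 500L
  res_eq <- partner_distance_analysis(ev_eq)
  expect_equal(res_eq$fisher_p, 1)
  expect_equal(res_eq$wilcox_p, 1)
  # inter-chromosomal events are ignored
  ev_inter <- ev
  ev_inter$chrom3 <- "chr9"
  expect_warning(res_i <- partner_distance_analysis(ev_inter))
  expect_true(is.na(res_i$fisher_p))
})

test_that("planted distance shifts are detected by the Fisher dichotomy", {
  set.seed(7)
  hits <- 0
  for (s in 1:10) {
    d_host <- round(rlnorm(500, log(2e7), 0.6) + 5e6)
    d_non <- round(rlnorm(500, log(2e7), 0.6))
    ev <- make_events("S1", paste0("A", 1:1000), paste0("B", 1:1000),
                      pos5 = 1L, pos3 = as.integer(c(d_host, d_non) + 1L),
                      host3 = rep(c(TRUE, FALSE), each = 500))
    if (partner_distance_analysis(ev)$fisher_p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("Welch contrast is symmetric under group swap", {
  set.seed(3)
  x <- rnorm(20); y <- rnorm(25, 1)
  a <- mirfuse:::welch_contrast(x, y, "x", "y")
  b <- mirfuse:::welch_contrast(y, x, "y", "x")
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("expression contrast recovers the planted 5' uplift", {
  cfg <- synth_config(n_samples = 120, n_genes = 300,
                      mean_fusions_per_sample = 15,
                      expr_uplift_log2fc = 1.0, frac_blacklisted = 0,
                      seed = 21)
  ann <- generate_annotation(cfg)
  cl <- generate_clinical(cfg, ann)
  fu <- generate_fusions(cfg, ann, cl)
  expr <- generate_expression(cfg, ann, cl, fu)
  asg <- assign_hosts(ann, ann$mirnas)
  evc <- classify_inclusion(fu, asg, ann)
  ec <- expression_contrast(expr, evc)
  ctr <- ec$contrasts
  diff_hn <- ctr$mean1[ctr$group1 == "host_included" &
                         ctr$group2 == "nonhost"] -
    ctr$mean2[ctr$group1 == "host_included" & ctr$group2 == "nonhost"]
  expect_lt(abs(diff_hn - 1.0), 0.35)
  expect_lt(ctr$p[ctr$group1 == "host_included" & ctr$group2 == "nonhost"],
            0.01)
})

test_that("single-gene categories yield NA without crashing", {
  expr <- matrix(2^rnorm(40, 3), 4, 10,
                 dimnames = list(c("A", "B", "H", "N"), paste0("S", 1:10)))
  ev <- make_events("S1", "A", "H", host3 = TRUE, host5 = FALSE)
  ev$inclusion3 <- "INCLUDED"; ev$inclusion5 <- NA_character_
  ec <- expression_contrast(expr, ev)
  expect_true(all(is.na(ec$contrasts$t) | is.finite(ec$contrasts$t)))
  expect_true(any(is.na(ec$contrasts$p)))
})

test_that("methylation contrast recovers the planted promoter shift", {
  cfg <- synth_config(n_samples = 120, n_genes = 300,
                      mean_fusions_per_sample = 15, meth_shift = -0.15,
                      frac_blacklisted = 0, seed = 22)
  ann <- generate_annotation(cfg)
  cl <- generate_clinical(cfg, ann)
  fu <- generate_fusions(cfg, ann, cl)
  meth <- generate_methylation(cfg, ann, cl, fu)
  asg <- assign_hosts(ann, ann$mirnas)
  evc <- classify_inclusion(fu, asg, ann)
  mc <- methylation_contrast(meth$beta, meth$islands, ann, evc)
  pg <- mc$per_gene
  beta_of <- function(cat) mean(2^pg$value[pg$category == cat] - 1e-3)
  recovered <- beta_of("host_included") - beta_of("nonhost")
  expect_lt(abs(recovered - (-0.15)), 0.05)
})

test_that("zero-variance methylation gives p of 1 or NA", {
  beta <- matrix(0.5, 2, 6,
                 dimnames = list(c("I1", "I2"), paste0("S", 1:6)))
  islands <- data.frame(island_id = c("I1", "I2"), chrom = "chr1",
                        start = c(400L, 1400L), end = c(500L, 1500L),
                        stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("A", "B", "H", "N"), chrom = "chr1",
                      start = c(1000L, 2000L, 3000L, 4000L),
                      end = c(1900L, 2900L, 3900L, 4900L), strand = "+",
                      stringsAsFactors = FALSE)
  ann <- make_ann(genes)
  ev <- make_events(c("S1", "S2"), c("A", "B"), c("H", "N"),
                    host3 = c(TRUE, FALSE), host5 = c(FALSE, FALSE))
  ev$inclusion3 <- c("INCLUDED", NA); ev$inclusion5 <- NA_character_
  mc <- methylation_contrast(beta, islands, ann, ev)
  expect_true(all(is.na(mc$contrasts$p) | mc$contrasts$p == 1))
})
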