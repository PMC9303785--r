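test_that("expressed universe applies the 95th-percentile rule", {
  expr <- rbind(
    zero = rep(0, 100),
    two = rep(2, 100),
    sparse = c(rep(0, 96), rep(100, 4)),
    borderline = rep(1, 100)
  )
  colnames(expr) <- paste0("S", 1:100)
  u <- expressed_universe(expr)
  expect_true("two" %in% u)
  expect_false("zero" %in% u)
  # 95th percentile of 96 zeros + 4 large values is 0 under type-7 quantiles
  expect_false("sparse" %in% u)
  # strict > cutoff
  expect_false("borderline" %in% u)
})

test_that("partner lists separate host and non-host 5' partners and drop snoRNA hosts", {
  genes <- data.frame(gene_id = c("A", "B", "H", "S", "N"), chrom = "chr1",
                      start = seq(1000L, 5000L, 1000L),
                      end = seq(1900L, 5900L, 1000L), strand = "+",
                      is_mirna_host = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                      is_snorna_host = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  ann <- make_ann(genes)
  ev <- make_events("S1", c("A", "B", "A", "H"), c("H", "S", "N", "N"),
                    host3 = c(TRUE, FALSE, FALSE, FALSE),
                    host5 = c(FALSE, FALSE, FALSE, TRUE))
  lists <- partner_gene_lists(ev, ann)
  expect_equal(lists$host5, "A")
  # B excluded (its 3' partner is a snoRNA host); A deduplicated
  expect_setequal(lists$nonhost5, c("A", "H"))
  expect_equal(lists$host3, "N")
})

test_that("hypergeometric p matches the closed form and exhaustive enumeration", {
  # all 5 drawn from a 5-gene set in a 20-gene universe
  universe <- paste0("G", 1:20)
  set5 <- paste0("G", 1:5)
  res <- hypergeom_overrep(set5, list(s = set5), universe, min_set_size = 5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)
  # k = 0 has p = 1
  res0 <- hypergeom_overrep(paste0("G", 6:10), list(s = set5), universe)
  expect_equal(res0$p, 1)
  # exhaustive enumeration oracle on all N <= 12 fixtures
  set.seed(5)
  for (i in 1:12) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    u <- paste0("g", 1:N)
    s <- paste0("g", 1:K)
    lst <- sample(u, n)
    k <- length(intersect(lst, s))
    res <- hypergeom_overrep(lst, list(s = s), u, min_set_size = 1)
    expect_equal(res$p, hyper_enum(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone in rank and identity for a single set", {
  universe <- paste0("G", 1:50)
  coll <- list(a = paste0("G", 1:10), b = paste0("G", 11:30),
               c = paste0("G", 31:50), d = paste0("G", 1:25))
  res <- hypergeom_overrep(paste0("G", c(1:8, 40)), coll, universe)
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  one <- hypergeom_overrep(paste0("G", 1:8), coll["a"], universe)
  expect_equal(one$p_adj, one$p)
})

test_that("small sets are skipped and an empty intersected list warns", {
  universe <- paste0("G", 1:50)
  coll <- list(small = paste0("G", 1:3), big = paste0("G", 1:10))
  res <- hypergeom_overrep(paste0("G", 1:5), coll, universe)
  expect_equal(res$set, "big")
  expect_warning(res2 <- hypergeom_overrep("ZZZ", coll, universe), "empty")
  expect_equal(nrow(res2), 0)
})

test_that("balanced subsampling is deterministic and reduces to a plain run", {
  universe <- paste0("G", 1:100)
  coll <- list(a = paste0("G", 1:20), b = paste0("G", 21:60))
  nonhost <- paste0("G", seq(1, 99, 2))
  r1 <- balanced_nonhost_enrichment(nonhost, 10, coll, universe,
                                    reps = 1, seed = 99)
  draw <- local({set.seed(99L); sample(nonhost, 10)})
  plain <- hypergeom_overrep(draw, coll, universe)
  expect_equal(r1$mean_p_adj, plain$p_adj)
  r3a <- balanced_nonhost_enrichment(nonhost, 10, coll, universe,
                                     reps = 3, seed = 7)
  r3b <- balanced_nonhost_enrichment(nonhost, 10, coll, universe,
                                     reps = 3, seed = 7)
  expect_identical(r3a, r3b)
  # short list: flagged, single run on the full list
  expect_warning(
    rs <- balanced_nonhost_enrichment(paste0("G", 1:5), 10, coll, universe),
    "smaller")
  expect_true(attr(rs, "flagged_short_list"))
})

test_that("a planted enrichment in the non-host pool survives balanced subsampling", {
  set.seed(31)
  universe <- paste0("G", 1:600)
  target <- paste0("G", 1:60)
  coll <- list(target = target, decoy = paste0("G", 301:400))
  # non-host pool overrepresents the target set threefold
  pool <- c(sample(target, 45), sample(setdiff(universe, target), 155))
  hits <- 0
  for (s in 1:10) {
    res <- balanced_nonhost_enrichment(pool, 150, coll, universe,
                                       reps = 3, seed = s)
    if (res$mean_p_adj[res$set == "target"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("TF target windows are strand-aware with closed boundaries", {
  genes <- data.frame(gene_id = c("P", "M"), chrom = "chr1",
                      start = c(10000L, 30000L), end = c(12000L, 32000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  ann <- make_ann(genes)
  # + strand: TSS 10000, window [9000, 10200]
  # - strand: TSS 32000, window [31800, 33000]
  tfbs <- data.frame(
    chrom = "chr1",
    start = c(9100L, 8950L, 8980L, 32900L, 31700L, 33001L, 500L),
    end = c(9120L, 8999L, 9000L, 32950L, 31799L, 33020L, 520L),
    tf = c("TFA", "TFB", "TFC", "TFD", "TFE", "TFF", "TFG"),
    stringsAsFactors = FALSE
  )
  tm <- tf_target_map(tfbs, ann)
  expect_equal(tm$TFA, "P")              # wholly inside the window
  expect_null(tm$TFB)                    # ends 1 base before the window
  expect_equal(tm$TFC, "P")              # touches the window edge (closed)
  expect_equal(tm$TFD, "M")              # inside the minus-strand window
  expect_null(tm$TFE)                    # 1 base upstream of minus window
  expect_null(tm$TFF)                    # 1 base past the minus window
  # brute-force base-set oracle over every TFBS/gene pair
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  for (g in seq_len(nrow(genes))) {
    win <- if (genes$strand[g] == "+") {
      seq(tss[g] - 1000, tss[g] + 200)
    } else {
      seq(tss[g] - 200, tss[g] + 1000)
    }
    for (t in seq_len(nrow(tfbs))) {
      expected <- length(intersect(seq(tfbs$start[t], tfbs$end[t]), win)) > 0
      got <- genes$gene_id[g] %in% tm[[tfbs$tf[t]]]
      expect_equal(got, expected,
                   info = sprintf("gene %s vs %s", genes$gene_id[g],
                                  tfbs$tf[t]))
    }
  }
})

test_that("TF intervals on unknown chromosomes are skipped and counted", {
  genes <- data.frame(gene_id = "P", chrom = "chr1", start = 10000L,
                      end = 12000L, strand = "+", stringsAsFactors = FALSE)
  tfbs <- data.frame(chrom = c("chr1", "chrUn"), start = c(9500L, 10L),
                     end = c(9520L, 30L), tf = c("TFA", "TFZ"),
                     stringsAsFactors = FALSE)
  tm <- tf_target_map(tfbs, make_ann(genes))
  expect_equal(attr(tm, "n_skipped"), 1L)
  expect_null(tm$TFZ)
})

test_that("growing the universe never shrinks the overlap count", {
  u_small <- paste0("G", 1:30)
  u_big <- paste0("G", 1:60)
  coll <- list(s = paste0("G", 1:15))
  lst <- paste0("G", c(1:6, 40:45))
  k_small <- hypergeom_overrep(lst, coll, u_small)$k
  k_big <- hypergeom_overrep(lst, coll, u_big)$k
  expect_gte(k_big, k_small)
})
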