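toy_matures <- function() {
  data.frame(
    mature_id = c("miR-X-5p", "miR-X-3p"),
    precursor_id = "MIX", chrom = "chr1",
    start = c(100L, 160L), end = c(121L, 181L), strand = "+",
    stringsAsFactors = FALSE
  )
}

test_that("isoform aggregation sums counts by containing mature interval", {
  iso <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2"),
    chrom = "chr1", start = c(100L, 105L, 140L, 102L),
    end = c(121L, 125L, 200L, 122L), strand = "+",
    count = c(3L, 4L, 9L, 5L), stringsAsFactors = FALSE
  )
  m <- aggregate_mirna_counts(iso, toy_matures())
  expect_equal(m["miR-X-5p", "S1"], 7L)   # 3 + 4 by 5' start
  expect_equal(m["miR-X-5p", "S2"], 5L)
  expect_equal(m["miR-X-3p", "S1"], 0L)
  # the isoform starting at 140 spans into 3p territory but starts in neither
  expect_equal(attr(m, "n_unassigned"), 1L)
})

test_that("isoforms spanning an arm boundary are assigned by the 5' start", {
  iso <- data.frame(sample_id = "S1", chrom = "chr1", start = 110L,
                    end = 170L, strand = "+", count = 2L,
                    stringsAsFactors = FALSE)
  m <- aggregate_mirna_counts(iso, toy_matures())
  expect_equal(m["miR-X-5p", "S1"], 2L)
  expect_equal(m["miR-X-3p", "S1"], 0L)
  # on the minus strand the 5' end is the larger coordinate
  mat_minus <- toy_matures()
  mat_minus$strand <- "-"
  iso_m <- data.frame(sample_id = "S1", chrom = "chr1", start = 110L,
                      end = 170L, strand = "-", count = 2L,
                      stringsAsFactors = FALSE)
  m2 <- aggregate_mirna_counts(iso_m, mat_minus)
  expect_equal(m2["miR-X-3p", "S1"], 2L)
})

test_that("empty isoform tables give a zero matrix", {
  iso <- data.frame(sample_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    strand = character(), count = integer(),
                    stringsAsFactors = FALSE)
  m <- aggregate_mirna_counts(iso, toy_matures())
  expect_equal(sum(m), 0)
})

test_that("fusion-conditioned grouping excludes 5'-role and normal samples", {
  clin <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                     tissue = c("tumour", "tumour", "tumour", "normal"),
                     stringsAsFactors = FALSE)
  ev <- make_events(c("S1", "S2", "S4"), c("A", "H", "B"), c("H", "B", "H"))
  grp <- fusion_conditioned_groups(ev, "H", clin)
  expect_equal(grp$fused, "S1")
  expect_equal(grp$unfused, "S3")  # S2 only 5'-role, S4 normal
  # never-fused host: empty fused group, all tumours unfused
  grp2 <- fusion_conditioned_groups(ev, "Q", clin)
  expect_equal(grp2$fused, character(0))
  expect_setequal(grp2$unfused, c("S1", "S2", "S3"))
})

test_that("exact test degenerates correctly and is symmetric", {
  counts <- matrix(rep(c(5L, 5L, 5L, 5L, 5L, 5L), 2), nrow = 2, byrow = TRUE,
                   dimnames = list(c("m1", "m2"), paste0("S", 1:6)))
  libs <- setNames(rep(1e6, 6), paste0("S", 1:6))
  de <- exact_test_de(counts, paste0("S", 1:3), paste0("S", 4:6),
                      lib_sizes = libs, dispersion = 0.1)
  expect_equal(de$logFC, c(0, 0))
  expect_equal(de$p, c(1, 1))
  set.seed(8)
  counts2 <- matrix(rnbinom(40, mu = 30, size = 5), 4, 10,
                    dimnames = list(paste0("m", 1:4), paste0("S", 1:10)))
  libs2 <- setNames(runif(10, 8e5, 1.5e6), paste0("S", 1:10))
  a <- exact_test_de(counts2, paste0("S", 1:4), paste0("S", 5:10),
                     lib_sizes = libs2, dispersion = 0.2)
  b <- exact_test_de(counts2, paste0("S", 5:10), paste0("S", 1:4),
                     lib_sizes = libs2, dispersion = 0.2)
  expect_equal(a$logFC, -b$logFC)
  expect_equal(a$p, b$p)
  # global library rescaling leaves p unchanged
  c2 <- exact_test_de(counts2, paste0("S", 1:4), paste0("S", 5:10),
                      lib_sizes = libs2 * 3, dispersion = 0.2)
  expect_equal(a$p, c2$p, tolerance = 1e-12)
  # zero-total features are flagged with p = 1, logFC = 0
  counts3 <- counts2; counts3[1, ] <- 0L
  z <- exact_test_de(counts3, paste0("S", 1:4), paste0("S", 5:10),
                     lib_sizes = libs2, dispersion = 0.2)
  expect_true(z$flagged_zero_total[1])
  expect_equal(z$p[1], 1)
  expect_equal(z$logFC[1], 0)
})

test_that("the dispersion-zero limit matches the conditional binomial", {
  set.seed(12)
  for (i in 1:5) {
    nA <- sample(2:5, 1); nB <- sample(3:8, 1)
    t <- sample(10:80, 1); a <- sample(0:t, 1)
    expect_equal(mirfuse:::exact_nb_test(a, t, nA, nB, 0),
                 binom_two_sided(a, t, nA / (nA + nB)), tolerance = 1e-9)
  }
})

test_that("exact test agrees with edgeR's exactTest as an independent cross-check", {
  set.seed(2)
  n1 <- 4; n2 <- 5
  counts <- matrix(rnbinom(30 * (n1 + n2), mu = 50, size = 5), 30,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:9)))
  libs <- setNames(rep(1e6, n1 + n2), colnames(counts))
  mine <- exact_test_de(counts, paste0("s", 1:n1),
                        paste0("s", (n1 + 1):(n1 + n2)),
                        lib_sizes = libs, dispersion = 0.2, min_group = 2)
  d <- edgeR::DGEList(counts = counts, lib.size = rep(1e6, 9),
                      group = rep(1:2, c(n1, n2)))
  et <- edgeR::exactTest(d, dispersion = 0.2)
  expect_lt(max(abs(mine$p - et$table$PValue)), 0.05)
  expect_equal(mine$logFC, -et$table$logFC, tolerance = 1e-8)
  expect_gt(cor(mine$p, et$table$PValue), 0.995)
})

test_that("method-of-moments dispersion recovers the simulated value", {
  set.seed(9)
  counts <- matrix(rnbinom(500 * 40, mu = 100, size = 1 / 0.3), 500, 40)
  colnames(counts) <- paste0("S", 1:40)
  phi <- estimate_common_dispersion(counts,
                                    setNames(rep(1e6, 40), colnames(counts)))
  expect_lt(abs(phi - 0.3), 0.08)
})

test_that("target correlation handles exact anticorrelation and planted coupling", {
  set.seed(14)
  n <- 300
  mir <- matrix(2^rnorm(n, 6), 1, n, dimnames = list("miR-X-5p", NULL))
  colnames(mir) <- paste0("S", 1:n)
  # target exactly -x on the log scale
  tgt_exact <- matrix(2^(12 - log2(mir[1, ] + 1)) - 1, 1, n,
                      dimnames = list("T1", colnames(mir)))
  pred <- data.frame(mature_id = "miR-X-5p", target_id = "T1",
                     stringsAsFactors = FALSE)
  res <- target_correlation(mir, tgt_exact, pred)
  expect_equal(res$r, -1, tolerance = 1e-12)
  # planted negative coupling is recovered
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    x <- rnorm(n, 6, 1)
    y <- 10 - 0.5 * x + rnorm(n, 0, 1)
    mir2 <- matrix(2^x - 1, 1, n,
                   dimnames = list("miR-X-5p", paste0("S", 1:n)))
    tgt2 <- matrix(2^y - 1, 1, n, dimnames = list("T1", paste0("S", 1:n)))
    r <- target_correlation(mir2, tgt2, pred)
    if (r$r < 0 && r$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 10 * 0.95)
  # pairs referencing absent features are skipped, short overlap dropped
  pred2 <- rbind(pred, data.frame(mature_id = "miR-X-5p", target_id = "ZZ"))
  res2 <- target_correlation(mir, tgt_exact, pred2)
  expect_equal(attr(res2, "n_skipped"), 1L)
})

test_that("independent pairs have calibrated raw p-values", {
  set.seed(77)
  n <- 60; npairs <- 400
  mir <- matrix(2^rnorm(npairs * n, 6), npairs, n,
                dimnames = list(paste0("m", 1:npairs), paste0("S", 1:n)))
  tgt <- matrix(2^rnorm(npairs * n, 5), npairs, n,
                dimnames = list(paste0("t", 1:npairs), paste0("S", 1:n)))
  pred <- data.frame(mature_id = paste0("m", 1:npairs),
                     target_id = paste0("t", 1:npairs),
                     stringsAsFactors = FALSE)
  res <- target_correlation(mir, tgt, pred)
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / npairs))
})

test_that("cpm scales counts by library size", {
  counts <- matrix(c(10L, 90L, 20L, 180L), 2,
                   dimnames = list(c("a", "b"), c("S1", "S2")))
  out <- cpm(counts, lib_sizes = c(S1 = 1e6, S2 = 2e6))
  expect_equal(out["a", "S1"], 10)
  expect_equal(out["a", "S2"], 10)
})
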