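test_that("TPM normalization follows the closed form and sums to one million", {
  tpm <- tpm_from_counts(c(10, 10), c(1000, 2000))
  expect_equal(unname(tpm), c(666666.67, 333333.33), tolerance = 1e-6)
  expect_equal(unname(tpm_from_counts(5, 800)), 1e6)
  set.seed(51)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    t <- tpm_from_counts(rpois(n, 50), sample(200:3000, n))
    expect_equal(sum(t), 1e6, tolerance = 1e-3)
  }
  expect_warning(z <- tpm_from_counts(c(0, 0), c(100, 100)), "zero")
  expect_identical(unname(z), c(0, 0))
  expect_error(tpm_from_counts(1, 0), "positive")
})

test_that("Welch t-test reproduces hand-computed values and symmetries", {
  w <- welch_t(c(10, 12), c(20, 22))
  expect_equal(round(w$t, 3), -7.071)
  expect_equal(w$df, 2, tolerance = 1e-9)
  ## identical groups
  same <- welch_t(c(3, 4, 5), c(3, 4, 5))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  ## sign flips under swap, p unchanged
  a <- c(1.2, 3.4, 2.2); b <- c(5.5, 4.1, 6.0)
  w1 <- welch_t(a, b); w2 <- welch_t(b, a)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)
  ## agreement with stats::t.test on non-degenerate data
  set.seed(52)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1), 10, 2); y <- rnorm(sample(2:6, 1), 12, 3)
    ref <- t.test(x, y)
    mine <- welch_t(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-6)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  }
  expect_error(welch_t(1, c(2, 3)), "at least 2")
})

test_that("BH adjustment reproduces the step-up values and handles NA", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.031), 0.031)
  set.seed(53)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  q <- bh_fdr(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], stats::p.adjust(c(0.01, 0.5), "BH"))
  expect_true(all(q >= c(0.01, NA, 0.5), na.rm = TRUE))
})

make_table <- function(vals) {
  ## vals: list of gene -> list(A = c(...), B = c(...)) at one timepoint
  do.call(rbind, lapply(names(vals), function(g) {
    do.call(rbind, lapply(c("A", "B"), function(s) {
      v <- vals[[g]][[s]]
      data.frame(gene_id = g, strain = s, timepoint = "T1",
                 replicate = seq_along(v), tpm = v, stringsAsFactors = FALSE)
    }))
  }))
}

test_that("DE flags use inclusive thresholds on fold change and FDR", {
  ## mean ratio with pseudocount exactly 2.0 and a minuscule p
  tab <- make_table(list(
    hit = list(A = c(9, 9), B = c(19, 19)),
    near = list(A = c(9, 9), B = c(18.9, 18.9)),
    null1 = list(A = c(50, 52), B = c(51, 49))))
  de <- flag_de(tab, c("A", "B"))
  expect_true(de$significant[de$gene_id == "hit"])
  expect_false(de$significant[de$gene_id == "near"])   # fc 1.99 < 2
  expect_false(de$significant[de$gene_id == "null1"])
  expect_equal(de$log2_fc[de$gene_id == "hit"], 1)
  ## q >= p within the timepoint family
  expect_true(all(de$q >= de$p))

  ## identical strains: nothing significant
  tab2 <- make_table(list(g1 = list(A = c(5, 6), B = c(5, 6)),
                          g2 = list(A = c(100, 110), B = c(100, 110))))
  expect_false(any(flag_de(tab2, c("A", "B"))$significant))

  ## genes without two replicates are skipped with a message
  tab3 <- rbind(tab, data.frame(gene_id = "lonely", strain = "A",
                                timepoint = "T1", replicate = 1, tpm = 5))
  expect_message(de3 <- flag_de(tab3, c("A", "B")), "skipping")
  expect_false("lonely" %in% de3$gene_id)
})

test_that("significance sets shrink as the FDR threshold tightens", {
  sim <- sim_fixture()
  expr <- simulate_expression(sim)
  de05 <- flag_de(expr, c("A", "B"), q_threshold = 0.05)
  de01 <- flag_de(expr, c("A", "B"), q_threshold = 0.01)
  s05 <- paste(de05$gene_id, de05$timepoint)[de05$significant]
  s01 <- paste(de01$gene_id, de01$timepoint)[de01$significant]
  expect_true(all(s01 %in% s05))
})

test_that("overlay joins insertion differences to flanking-gene DE flags", {
  feat <- data.frame(seqid = "A", source = "s", type = "CDS",
                     start = c(1000L, 6000L, 7600L, 9200L, 20000L),
                     end = c(1900L, 7000L, 8600L, 10200L, 20900L),
                     score = ".", strand = c("+", "+", "+", "+", "+"),
                     phase = "0",
                     gene_id = c("up1", "dn1", "dn2", "dn3", "far"),
                     product = NA, stringsAsFactors = FALSE)
  impacts <- data.frame(type = "insertion", carrier = "B",
                        site_in_other = 5000L, start = 1L, end = 2L,
                        length = 2L, inserted_seq = "NN",
                        matched_element = "IS1634-like",
                        context = "intergenic", hit_gene = NA,
                        stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("dn1", "dn2", "dn3", "up1", "far"),
                   timepoint = "T1", mean_a = 1, mean_b = 1,
                   log2_fc = c(-3.2, -3.1, -3.4, 0.1, 0),
                   t = 1, df = 2, p = 0.001, q = c(0.01, 0.01, 0.01, 0.9, 0.9),
                   significant = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  ov <- overlay_expression(impacts, de, feat, window_genes = 4,
                           window_nt = 5500)
  ## three silenced downstream genes flagged; distant gene excluded
  expect_setequal(ov$gene_id[ov$role == "downstream"], c("dn1", "dn2", "dn3"))
  expect_true(all(ov$significant[ov$role == "downstream"]))
  expect_false("far" %in% ov$gene_id)
  expect_true("up1" %in% ov$gene_id)  # immediate neighbor

  ## intragenic insertion always includes the hit gene
  imp2 <- impacts
  imp2$context <- "intragenic"; imp2$hit_gene <- "far"
  imp2$site_in_other <- 20500L
  ov2 <- overlay_expression(imp2, de, feat)
  expect_true("far" %in% ov2$gene_id[ov2$role == "hit"])

  ## no genes anywhere near the site
  imp3 <- impacts; imp3$site_in_other <- 1L
  ov3 <- overlay_expression(imp3, de, feat[0, ])
  expect_identical(nrow(ov3), 0L)
})
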