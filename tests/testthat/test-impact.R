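features_fixture <- function() {
  data.frame(seqid = "g", source = "sim", type = "CDS",
             start = c(1000L, 3000L, 5000L), end = c(1999L, 3899L, 5599L),
             score = ".", strand = c("+", "+", "-"), phase = "0",
             gene_id = c("gA", "gB", "gC"),
             product = NA_character_, stringsAsFactors = FALSE)
}

test_that("insertion sites classify as intragenic only strictly inside a CDS", {
  feat <- features_fixture()
  inside <- classify_insertion(1500L, feat)
  expect_identical(inside$context, "intragenic")
  expect_identical(inside$hit_gene, "gA")

  ## a junction at the CDS's first base is a boundary: intergenic, distance 0
  edge <- classify_insertion(1000L, feat)
  expect_identical(edge$context, "intergenic")
  expect_identical(edge$downstream_gene, "gA")
  expect_identical(edge$downstream_distance, 0L)

  between <- classify_insertion(2500L, feat)
  expect_identical(between$context, "intergenic")
  expect_identical(between$upstream_gene, "gA")
  expect_identical(between$downstream_gene, "gB")
  expect_identical(between$upstream_distance, 500L)

  ## invariant to feature order
  expect_identical(classify_insertion(1500L, feat[c(3, 1, 2), ]), inside)

  ## featureless genome
  none <- classify_insertion(100L, feat[0, ])
  expect_identical(none$context, "intergenic")
  expect_true(is.na(none$upstream_gene) && is.na(none$downstream_gene))

  ## overlapping CDS at the site -> all reported, flagged ambiguous
  ovl <- rbind(feat, within(feat[1, ], { start <- 1400L; end <- 2399L
                                         gene_id <- "gA2" }))
  amb <- classify_insertion(1500L, ovl)
  expect_true(amb$ambiguous)
  expect_setequal(amb$hit_gene, c("gA", "gA2"))
})

## independent oracle: build the interrupted transcript, translate codon by
## codon to the first stop at/after the junction, then exhaustively find the
## longest ATG-ORF in the remainder
split_oracle <- function(cds, off, ins) {
  tx <- paste0(substr(cds, 1, off), ins, substr(cds, off + 1, nchar(cds)))
  codons <- substring(tx, seq(1, nchar(tx) - 2, 3), seq(3, nchar(tx), 3))
  stop_i <- which(codons %in% c("TAA", "TAG", "TGA") &
                    (seq_along(codons) * 3) > off)
  if (length(stop_i) == 0) return(NULL)
  p1 <- stop_i[1] - 1L
  rest <- substr(tx, stop_i[1] * 3 + 1, nchar(tx))
  ## longest plus-strand ATG-initiated ORF in the remainder
  best <- 0L
  n <- nchar(rest)
  for (offr in 0:2) {
    if (n - 2 < offr + 1) next
    starts <- seq(offr + 1, n - 2, by = 3)
    if (length(starts) < 2) next
    cods <- substring(rest, starts, starts + 2)
    atg <- NA
    for (ci in seq_along(cods)) {
      if (cods[ci] %in% c("TAA", "TAG", "TGA")) {
        if (!is.na(atg)) {
          span <- starts[ci] + 2 - starts[atg] + 1
          if (span >= 30) best <- max(best, span)
        }
        atg <- NA
      } else if (is.na(atg) && cods[ci] == "ATG") atg <- ci
    }
  }
  c(p1, if (best > 0) best %/% 3 - 1 else NA)
}

test_that("split products match translate-then-scan on random CDS/element pairs", {
  set.seed(41)
  for (i in 1:50) {
    cds <- mobilome:::random_cds(3L * sample(60:200, 1))
    elem <- random_genome(sample(150:400, 1), seed = 1100 + i)
    off <- sample(seq(0, nchar(cds), by = 1), 1)
    mine <- split_products(cds, off, elem)
    orac <- split_oracle(cds, off, elem)
    if (is.null(orac)) {
      expect_true(mine$runthrough)
    } else {
      expect_identical(mine$product1_aa, as.integer(orac[1]))
      expect_identical(mine$product2_aa, as.integer(orac[2]))
    }
  }
})

test_that("a stop-leading element at offset zero gives a zero-length first product", {
  cds <- mobilome:::random_cds(90L)
  elem <- paste0("TAA", random_genome(60, seed = 1200))
  sp <- split_products(cds, 0L, elem)
  expect_identical(sp$product1_aa, 0L)
  expect_false(sp$runthrough)
})

test_that("the interrupted sulfate-transport gene in the fixture splits as the oracle predicts", {
  sim <- sim_fixture()
  d <- diff_fixture()
  imp <- annotate_impacts(d$indels, sim$features_a, sim$features_b,
                          sim$genomes["A"], sim$genomes["B"])
  sbp_gene <- sim$genes$gene_id[which(sim$genes$role == "sbp")]
  row <- imp[!is.na(imp$hit_gene) & imp$hit_gene == sbp_gene, ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$context, "intragenic")
  cds <- sim$features_a[sim$features_a$gene_id == sbp_gene, ][1, ]
  cseq <- substr(sim$genomes[["A"]], cds$start, cds$end)
  orac <- split_oracle(cseq, row$site_in_other - cds$start, row$inserted_seq)
  expect_identical(row$product1_aa, as.integer(orac[1]))
  expect_identical(row$product2_aa, as.integer(orac[2]))
  ## truncated product: shorter than the intact 347-aa-equivalent protein
  expect_lt(row$product1_aa, nchar(cseq) / 3 - 1)
})

test_that("cds_delta re-runs frame extension and is zero outside the CDS", {
  set.seed(42)
  cds <- mobilome:::random_cds(300L)
  ## insertion after the stop codon leaves the CDS untouched
  expect_identical(cds_delta(cds, 300L, random_genome(99, seed = 1300),
                             downstream_seq = random_genome(300, seed = 1301)),
                   0L)
  ## in-frame stop-free insertion inside the CDS extends it by its length
  insert <- paste(sample(setdiff(mobilome:::SENSE_CODONS, "ATG"), 33,
                         replace = TRUE), collapse = "")
  expect_identical(cds_delta(cds, 150L, insert), 99L)
  ## stop ablation: insertion straddling the stop shifts the frame so
  ## translation runs into downstream sequence until its first stop
  down <- paste0(paste(sample(setdiff(mobilome:::SENSE_CODONS, "ATG"), 26,
                              replace = TRUE), collapse = ""), "TAA",
                 random_genome(60, seed = 1302))
  ins2 <- substr(insert, 1, 98)  # 98 nt: knocks translation out of frame
  d2 <- cds_delta(cds, 150L, ins2, downstream_seq = down)
  orac <- {
    tx <- paste0(substr(cds, 1, 150), ins2, substr(cds, 151, 300), down)
    cods <- substring(tx, seq(1, nchar(tx) - 2, 3), seq(3, nchar(tx), 3))
    st <- which(cods %in% c("TAA", "TAG", "TGA"))[1]
    as.integer(st * 3 - 300)
  }
  expect_identical(d2, orac)
  expect_gt(d2, 0L)
})
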