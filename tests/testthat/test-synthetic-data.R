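test_that("the generator is deterministic in its seed", {
  s1 <- simulate_genome_pair(sim_spec(seed = 9, backbone_len = 600000,
                                      n_genes = 160, inversion_len = 60000,
                                      cassette_len = 3000, mite_shared = 8))
  s2 <- simulate_genome_pair(sim_spec(seed = 9, backbone_len = 600000,
                                      n_genes = 160, inversion_len = 60000,
                                      cassette_len = 3000, mite_shared = 8))
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genome_pair(sim_spec(seed = 10, backbone_len = 600000,
                                      n_genes = 160, inversion_len = 60000,
                                      cassette_len = 3000, mite_shared = 8))
  expect_false(identical(s1$genomes[["A"]], s3$genomes[["A"]]))
})

test_that("zero planted differences produce identical strains", {
  sp <- sim_spec(seed = 5, backbone_len = 600000, n_genes = 160,
                 inversion_len = 0, mite_b_extra = 0)
  for (i in seq_along(sp$elements)) {
    sp$elements[[i]]$a_extra <- 0L
    sp$elements[[i]]$b_extra <- 0L
  }
  sim <- simulate_genome_pair(sp)
  expect_identical(sim$genomes[["A"]], sim$genomes[["B"]])
  expect_identical(nrow(sim$truth$inversion), 0L)
  expect_null(sim$truth$diffs)
})

test_that("planted copy numbers are reproduced exactly in the emitted genomes", {
  sim <- sim_fixture()
  expect_identical(count_copies(sim$genomes["A"], sim$mite_seq), 31L)
  expect_identical(count_copies(sim$genomes["B"], sim$mite_seq), 33L)
  want <- list("ISL3-like" = c(3L, 3L), "IS1634-like" = c(8L, 10L),
               "IS200-like" = c(16L, 14L), "IS1-like" = c(6L, 5L))
  for (nm in names(want)) {
    s <- sim$library$seq[sim$library$name == nm]
    expect_identical(count_copies(sim$genomes["A"], s), want[[nm]][1])
    expect_identical(count_copies(sim$genomes["B"], s), want[[nm]][2])
  }
  expect_identical(count_copies(sim$genomes["A"], sim$cassette_seq), 3L)
  expect_identical(count_copies(sim$genomes["B"], sim$cassette_seq), 3L)
})

test_that("truth coordinates address the emitted sequences exactly", {
  sim <- sim_fixture()
  te <- sim$truth$elements
  mite_rows <- te[te$name == "MITE187", ]
  for (i in seq_len(nrow(mite_rows))) {
    g <- sim$genomes[[mite_rows$genome[i]]]
    s <- substr(g, mite_rows$start[i], mite_rows$end[i])
    expect_identical(if (mite_rows$strand[i] == "+") s else revcomp(s),
                     sim$mite_seq)
  }
  ## every TSD-bearing locus shows its duplication in situ
  tsd_rows <- te[te$tsd_len > 0, ]
  for (i in seq_len(nrow(tsd_rows))) {
    g <- sim$genomes[[tsd_rows$genome[i]]]
    call <- detect_tsd(g, tsd_rows$start[i], tsd_rows$end[i])
    expect_true(call$present)
    expect_identical(call$length, tsd_rows$tsd_len[i])
  }
  ## gene features address full CDSs (start codon, in-frame stop at end)
  fa <- sim$features_a[sim$features_a$type == "CDS", ][1:10, ]
  for (i in seq_len(nrow(fa))) {
    cds <- substr(sim$genomes[["A"]], fa$start[i], fa$end[i])
    if (fa$strand[i] == "-") cds <- revcomp(cds)
    p <- translate_cds(cds)
    expect_identical(substr(p, 1, 1), "M")
    expect_identical(substr(p, nchar(p), nchar(p)), "*")
    expect_false(grepl("*", substr(p, 1, nchar(p) - 1), fixed = TRUE))
  }
})

test_that("expression tables are normalized per sample and carry planted effects", {
  sim <- sim_fixture()
  expr <- simulate_expression(sim)
  sums <- tapply(expr$tpm, paste(expr$strain, expr$timepoint, expr$replicate),
                 sum)
  expect_true(all(abs(sums - 1e6) <= 1e3))

  ## no effects -> strain means track each other
  flat <- simulate_expression(sim, effects = data.frame(
    gene_id = character(0), strain = character(0), factor = numeric(0)))
  ma <- tapply(flat$tpm[flat$strain == "A"], flat$gene_id[flat$strain == "A"],
               mean)
  mb <- tapply(flat$tpm[flat$strain == "B"], flat$gene_id[flat$strain == "B"],
               mean)
  expect_true(all(abs(log2(ma / mb)) < 1))

  ## planted silencing shows up as a large shift in the carrier strain
  eff <- sim$truth$expression
  sil <- eff$gene_id[eff$factor < 1][1]
  de <- flag_de(expr, c("A", "B"))
  expect_true(all(de$log2_fc[de$gene_id == sil] < -2))
})

test_that("simulation output files round-trip through the standard readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_genome_pair(sim_spec(seed = 11, backbone_len = 600000,
                                       n_genes = 160, inversion_len = 60000,
                                       cassette_len = 3000, mite_shared = 6))
  write_simulation(sim, dir)
  ga <- read_fasta(file.path(dir, "genome_A.fasta"))
  expect_identical(unname(ga), sim$genomes[["A"]])
  feats <- read_gff(file.path(dir, "genome_A.gff3"))
  expect_identical(nrow(feats), nrow(sim$features_a))
  expect_identical(feats$start, sim$features_a$start)
  lib <- read_element_library(file.path(dir, "is_library.fasta"))
  expect_identical(lib$seq, sim$library$seq)
  expect_identical(lib$family, sim$library$family)
  expr <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_true(all(c("gene_id", "strain", "timepoint", "replicate", "tpm")
                  %in% names(expr)))
})
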