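test_that("high-copy repeat mining recovers a planted unit exactly", {
  set.seed(31)
  unit <- random_genome(187, seed = 200)
  host <- random_genome(100000, seed = 201)
  sites <- 2000L + 1200L * seq_len(8)
  seqs <- ifelse(seq_len(8) %% 3 == 0, revcomp(unit), unit)
  g <- plant_at(host, sites, seqs)
  reps <- find_high_copy_repeats(g, min_copies = 5)
  expect_identical(nrow(reps), 1L)
  expect_identical(reps$length, 187L)
  expect_identical(reps$copies, 8L)
  expect_true(reps$seq %in% c(unit, revcomp(unit)))

  ## no repeat planted -> nothing at min_copies = 5
  expect_identical(nrow(find_high_copy_repeats(host, min_copies = 5)), 0L)

  ## a single copy is not a repeat
  expect_identical(nrow(find_high_copy_repeats(unit, min_copies = 5)), 0L)
})

test_that("TSD detection returns the largest duplicated window and errors on short flanks", {
  set.seed(32)
  elem <- random_genome(100, seed = 202)
  tsd <- "ACGTACGT"
  left <- random_genome(50, seed = 203)
  right <- random_genome(50, seed = 204)
  ## guard the construction against accidental 9-mer extension
  g <- paste0(left, "T", tsd, elem, tsd, "A", right)
  start <- nchar(left) + 1L + 9L
  call <- detect_tsd(g, start, start + 99L)
  expect_true(call$present)
  expect_identical(call$length, 8L)
  expect_identical(call$seq, tsd)
  expect_identical(call$left_interval, c(start - 8L, start - 1L))

  ## flanks sharing nothing -> absent
  g2 <- paste0(strrep("A", 30), elem, strrep("C", 30))
  call2 <- detect_tsd(g2, 31L, 130L)
  expect_false(call2$present)
  expect_identical(call2$length, 0L)

  expect_error(detect_tsd(g, 3L, 40L), "flank")
})

test_that("TIR detection matches a brute-force scan over all lengths", {
  tir_oracle <- function(s, min_len = 7L, max_mm = 2L) {
    n <- nchar(s)
    best <- 0L; bmm <- NA_integer_
    for (L in min_len:(n %/% 2L)) {
      pre <- strsplit(substr(s, 1, L), "")[[1]]
      suf <- strsplit(revcomp(substr(s, n - L + 1L, n)), "")[[1]]
      mm <- sum(pre != suf)
      if (mm <= max_mm && L > best) { best <- L; bmm <- mm }
    }
    list(length = best, mismatches = bmm)
  }
  seed9 <- "GGCTCTTCG"
  el <- paste0(seed9, random_genome(100, seed = 205), revcomp(seed9))
  call <- detect_tir(el)
  expect_true(call$present)
  expect_gte(call$length, 9L)
  ## at zero mismatch tolerance the planted 9-nt termini are recovered
  strict <- detect_tir(el, max_mismatch = 0L)
  expect_gte(strict$length, 9L)
  expect_identical(strict$mismatches, 0L)

  expect_false(detect_tir(strrep("A", 60))$present)

  set.seed(33)
  for (i in 1:100) {
    s <- random_genome(sample(20:80, 1), seed = 300 + i)
    mine <- detect_tir(s)
    orac <- tir_oracle(s)
    expect_identical(mine$length, orac$length)
    if (orac$length > 0) expect_identical(mine$mismatches, orac$mismatches)
  }
})

test_that("ORF scanning honors the 30-nt boundary and a six-frame oracle", {
  set.seed(34)
  sense <- setdiff(mobilome:::SENSE_CODONS, "ATG")
  body <- paste(sample(sense, 8, replace = TRUE), collapse = "")
  orf30 <- paste0("ATG", body, "TAA")
  pad <- "CCCCC"
  o <- scan_orfs(paste0(pad, orf30, pad))
  o <- o[o$strand == "+", ]
  expect_identical(nrow(o), 1L)
  expect_identical(o$span_nt, 30L)
  expect_identical(nchar(o$peptide), 9L)
  expect_identical(o$start, 6L)

  ## 29-nt construct (in-frame stop arrives one codon early) -> nothing
  orf27 <- paste0("ATG", substr(body, 1, 21), "TAA")
  expect_identical(nrow(scan_orfs(paste0(pad, orf27, pad))), 0L)

  for (i in 1:50) {
    s <- random_genome(300, seed = 400 + i)
    mine <- scan_orfs(s)
    orac <- orf_oracle(s)
    expect_identical(nrow(mine), nrow(orac))
    expect_identical(sort(mine$span_nt), sort(as.integer(orac[, 1])))
    expect_identical(sort(mine$start), sort(as.integer(orac[, 2])))
  }
})

test_that("fold_score maximizes nested pairs like exhaustive enumeration", {
  expect_identical(fold_score("GGGAAACCC")$max_pairs, 3L)
  expect_identical(fold_score(strrep("A", 50))$max_pairs, 0L)
  stem <- random_genome(20, seed = 500)
  hp <- paste0(stem, "AAAAA", revcomp(stem))
  expect_gte(fold_score(hp)$max_pairs, 20L)
  expect_equal(fold_score(hp)$pairing_fraction,
               2 * fold_score(hp)$max_pairs / nchar(hp))
  set.seed(35)
  for (i in 1:120) {
    s <- random_genome(sample(10:14, 1), seed = 600 + i)
    expect_identical(fold_score(s)$max_pairs, fold_oracle(s))
  }
})

test_that("MITE classification applies the four structural criteria in order", {
  sim <- sim_fixture()
  cand <- characterize_repeat(sim$genomes, sim$mite_seq)
  cand <- classify_mite(cand)
  expect_identical(cand$verdict, "MITE")
  expect_true(cand$tir$present)
  expect_identical(mobilome:::modal_tsd_len(cand), 8L)
  expect_identical(unname(cand$copies), c(31L, 33L))
  expect_true(all(cand$orfs$span_nt < 600))

  ## a transposase-bearing element is rejected as coding
  isl3 <- sim$library$seq[sim$library$name == "ISL3-like"]
  tpase <- classify_mite(characterize_repeat(sim$genomes, isl3),
                         min_copies = 3)
  expect_identical(tpase$verdict, "rejected")
  expect_identical(tpase$reason, "coding")
  expect_true(any(tpase$orfs$span_nt >= 1000))

  ## a TIR-less high-copy repeat is rejected first for its termini
  is200 <- sim$library$seq[sim$library$name == "IS200-like"]
  t2 <- classify_mite(characterize_repeat(sim$genomes, is200))
  expect_identical(t2$reason, "no_TIR")

  ## low copy number
  lc <- characterize_repeat(sim$genomes["A"],
                            substr(sim$genomes[["A"]], 1000, 1186))
  lc$tir$present <- TRUE
  lc$loci$tsd_present <- TRUE
  expect_identical(classify_mite(lc)$reason, "low_copy")
})

test_that("family linking requires matching termini AND matching TSD length", {
  sim <- sim_fixture()
  mites <- mites_fixture()
  mite <- Filter(function(m) identical(m$verdict, "MITE"), mites)[[1]]
  expect_identical(mite$linked_family, "ISL3")
  expect_false(mite$ambiguous_family)

  ## decoy: same termini, but a 4-nt TSD -> not linked
  seed9 <- substr(mite$seq, 1, 9)
  set.seed(36)
  decoy <- paste0(seed9, random_genome(800, seed = 700), revcomp(seed9))
  host <- random_genome(30000, seed = 701)
  tsd4 <- substr(host, 9997, 10000)
  g <- c(gX = plant_at(host, c(10000L, 20000L),
                       c(paste0(decoy, tsd4), decoy)))
  hits <- data.frame(element = "decoy", family = "decoyfam", genome_id = "gX",
                     start = 10001L, end = 10000L + nchar(decoy),
                     strand = "+", length = nchar(decoy),
                     identity = 1, coverage = 1, stringsAsFactors = FALSE)
  linked <- link_family(mite, hits, g)
  expect_true(is.na(linked$linked_family))

  ## no transposase sharing the termini at all -> none
  none <- link_family(mite, hits[0, ], sim$genomes)
  expect_true(is.na(none$linked_family))
})

test_that("TSD and TIR calls are invariant under reverse-complementing the genome", {
  set.seed(37)
  elem <- paste0("GGCTCTTCG", random_genome(120, seed = 800),
                 revcomp("GGCTCTTCG"))
  host <- random_genome(4000, seed = 801)
  tsd <- substr(host, 1993, 2000)
  g <- plant_at(host, 2000L, paste0(elem, tsd))
  st <- 2001L; en <- 2000L + nchar(elem)
  fwd_call <- detect_tsd(g, st, en)
  grc <- revcomp(g)
  n <- nchar(g)
  rc_call <- detect_tsd(grc, n - en + 1L, n - st + 1L)
  expect_identical(fwd_call$length, rc_call$length)
  expect_identical(rc_call$seq, revcomp(fwd_call$seq))
  expect_identical(detect_tir(elem)$length, detect_tir(revcomp(elem))$length)
})
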