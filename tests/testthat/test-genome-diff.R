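test_that("anchoring identical genomes yields one full-length collinear anchor", {
  g <- random_genome(50000, seed = 900)
  a <- build_anchors(g, g)
  expect_identical(nrow(a), 1L)
  expect_identical(a$pos_a, 1L)
  expect_identical(a$length, 50000L)
  expect_identical(a$orientation, "same")
  ## full diff of a genome against itself: nothing called
  d <- compare_genomes(g, g)
  expect_identical(nrow(d$inversions), 0L)
  expect_identical(nrow(d$indels), 0L)
  expect_gte(sum(d$anchors$length) / nchar(g), 0.999)
})

test_that("a reverse-complemented partner yields one full-length inverted anchor", {
  g <- random_genome(30000, seed = 901)
  a <- build_anchors(g, revcomp(g))
  expect_identical(nrow(a), 1L)
  expect_identical(a$orientation, "inverted")
  expect_identical(a$length, 30000L)
  expect_identical(a$pos_b, 1L)
})

test_that("an internal reverse-complemented segment splits the anchors around it", {
  g <- random_genome(20000, seed = 902)
  b <- paste0(substr(g, 1, 8000), revcomp(substr(g, 8001, 9000)),
              substr(g, 9001, 20000))
  a <- build_anchors(g, b)
  expect_gte(nrow(a), 3L)
  expect_identical(a$orientation[2], "inverted")
  ## direct string check of the planted segment
  expect_identical(substr(b, 8001, 9000), revcomp(substr(g, 8001, 9000)))
})

test_that("a cassette-flanked inversion is called at the planted boundaries with copy number 3", {
  ## handcrafted pair: backbone with cassette C at one boundary, revcomp(C)
  ## at the other, a third distal copy, and the spanned segment
  ## reverse-complemented in strain B
  host <- random_genome(120000, seed = 903)
  C <- random_genome(2000, seed = 904)
  p1 <- 30000L; p2 <- 52000L; p3 <- 90000L
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  ## boundary guards so the maximal inverted interval stops at the cassettes
  stopifnot(substr(host, p1, p1) != comp1(substr(host, p2 + 1, p2 + 1)),
            substr(host, p1 + 1, p1 + 1) != comp1(substr(host, p2, p2)))
  A <- plant_at(host, c(p1, p2, p3), c(C, revcomp(C), C))
  inv_s <- p1 + 2000L + 1L          # after left cassette in A
  inv_e <- p2 + 2000L               # end of segment before right cassette
  B <- paste0(substr(A, 1, inv_s - 1),
              revcomp(substr(A, inv_s, inv_e)),
              substr(A, inv_e + 1, nchar(A)))
  d <- compare_genomes(A, B, min_inversion_len = 5000)
  expect_identical(nrow(d$inversions), 1L)
  ## maximal inverted interval runs cassette start to cassette end
  expect_identical(d$inversions$start_a, p1 + 1L)
  expect_identical(d$inversions$end_a, p2 + 2L * 2000L)
  expect_identical(d$inversions$flank_repeat_len, 2000L)
  expect_identical(d$inversions$flank_copy_number_a, 3L)
  expect_identical(d$inversions$flank_copy_number_b, 3L)
  expect_identical(nrow(d$indels), 0L)

  ## mirror consistency: swapping the genomes swaps the intervals
  d2 <- compare_genomes(B, A, min_inversion_len = 5000)
  expect_identical(d2$inversions$start_a, d$inversions$start_b)
  expect_identical(d2$inversions$end_b, d$inversions$end_a)
})

test_that("strain-specific insertions are recovered with exact intervals and contents", {
  host <- random_genome(80000, seed = 905)
  set.seed(38)
  lens <- c(50L, 120L, 333L, 500L, 777L, 1000L, 1250L, 1500L, 1746L, 2000L)
  seqs <- vapply(seq_along(lens),
                 function(i) random_genome(lens[i], seed = 1000 + i),
                 character(1))
  sites <- 5000L + 7000L * (seq_along(lens) - 1L)
  ## no-microhomology guard: shift any site whose junction bases continue
  ## the planted sequence, so leftmost normalization equals the plan
  for (i in seq_along(sites)) {
    while (substr(host, sites[i], sites[i]) ==
             substr(seqs[i], lens[i], lens[i]) ||
           substr(host, sites[i] + 1L, sites[i] + 1L) ==
             substr(seqs[i], 1L, 1L)) sites[i] <- sites[i] + 1L
  }
  B <- plant_at(host, sites, seqs)
  d <- compare_genomes(host, B)
  ins <- d$indels[d$indels$type == "insertion", ]
  expect_identical(nrow(ins), 10L)
  expect_true(all(ins$carrier == "B"))
  shift <- cumsum(c(0L, head(lens, -1L)))
  expect_identical(ins$start, sites + shift + 1L)
  expect_identical(ins$length, lens)
  expect_identical(ins$inserted_seq, seqs)
  expect_identical(ins$site_in_other, sites + 1L)

  ## identical genomes -> no indels (covered above); single element case
  one <- plant_at(host, 40001L, seqs[9])
  d1 <- compare_genomes(host, one)
  expect_identical(d1$indels$length, 1746L)
  expect_identical(d1$indels$carrier, "B")
})

test_that("large intra-genome duplications are found exactly and random genomes are clean", {
  g <- random_genome(100000, seed = 906)
  expect_identical(nrow(find_self_duplication(g, min_len = 2000)), 0L)
  ## boundary guard: the copy must not extend by chance microhomology with
  ## the bases flanking the insertion point
  ds <- 20000L
  while (substr(g, ds - 1L, ds - 1L) == substr(g, 70000L, 70000L) ||
         substr(g, ds + 30000L, ds + 30000L) ==
           substr(g, 70001L, 70001L)) ds <- ds + 1L
  dup <- substr(g, ds, ds + 29999L)
  gd <- paste0(substr(g, 1, 70000), dup, substr(g, 70001, 100000))
  calls <- find_self_duplication(gd, min_len = 20000)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$length, 30000L)
  expect_identical(calls$start_1, ds)
  expect_identical(calls$start_2, 70001L)
  expect_identical(calls$identity, 1.0)
})
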