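## Shared lazily-built fixtures: the full synthetic strain pair and its
## derived analyses are expensive, so they are computed once per test run
## and reused across files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- expr
  .fixture_cache[[name]]
}

sim_fixture <- function() {
  cached("sim", simulate_genome_pair(sim_spec(seed = 42)))
}

catalog_fixture <- function() {
  cached("catalog", {
    sim <- sim_fixture()
    list(A = dedupe_overlaps(match_library(sim$genomes["A"], sim$library)),
         B = dedupe_overlaps(match_library(sim$genomes["B"], sim$library)))
  })
}

mites_fixture <- function() {
  cached("mites", {
    sim <- sim_fixture()
    cat_ <- catalog_fixture()
    discover_mites(sim$genomes, element_hits = rbind(cat_$A, cat_$B))
  })
}

diff_fixture <- function() {
  cached("diff", {
    sim <- sim_fixture()
    compare_genomes(sim$genomes["A"], sim$genomes["B"],
                    elements = sim$elements_all)
  })
}

random_genome <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## plant seqs into a host at given 1-based sites (insert after site), no
## TSD; returns new genome; sites must be increasing and well separated
plant_at <- function(host, sites, seqs) {
  ord <- order(sites)
  sites <- sites[ord]; seqs <- seqs[ord]
  bounds <- c(0L, sites, nchar(host))
  pieces <- character(2L * length(sites) + 1L)
  for (i in seq_len(length(sites) + 1L)) {
    pieces[2L * i - 1L] <- substr(host, bounds[i] + 1L, bounds[i + 1L])
  }
  pieces[2L * seq_along(sites)] <- seqs
  paste(pieces, collapse = "")
}

## independent brute-force maximizer of nested base pairs (min loop 3),
## written as plain recursion with memoisation over (i, j)
fold_oracle <- function(seq, min_loop = 3L) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(x)
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  memo <- new.env(parent = emptyenv())
  best <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    ## i unpaired, or i paired with some jp
    b <- best(i + 1L, j)
    for (jp in (i + min_loop + 1L):j) {
      if (pairs_ok(x[i], x[jp])) {
        b <- max(b, 1L + best(i + 1L, jp - 1L) + best(jp + 1L, j))
      }
    }
    memo[[key]] <- b
    b
  }
  best(1L, n)
}

## independent six-frame ORF oracle: for every frame on both strands,
## enumerate codons, track the first ATG after each stop, emit spans
orf_oracle <- function(seq, min_len_nt = 30L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  spans <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "",
                         fixed = TRUE)[[1]]), collapse = "")
    for (off in 0:2) {
      starts <- seq(off + 1L, n - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      atg <- NA
      for (ci in seq_along(codons)) {
        if (codons[ci] %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(atg)) {
            span <- starts[ci] + 2L - starts[atg] + 1L
            if (span >= min_len_nt) {
              spans[[length(spans) + 1L]] <-
                c(span, if (strand == "+") starts[atg] else
                  n - (starts[ci] + 2L) + 1L)
            }
          }
          atg <- NA
        } else if (is.na(atg) && codons[ci] == "ATG") atg <- ci
      }
    }
  }
  if (length(spans) == 0L) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, spans)
}

## all-pairs reference filter for overlap de-duplication: a hit survives
## iff no other hit of the ORIGINAL set dominates it (sufficient overlap
## and better (span, identity, -start) rank)
dedupe_oracle <- function(hits, frac = 0.5) {
  n <- nrow(hits)
  if (n <= 1L) return(hits)
  span <- hits$end - hits$start + 1L
  dominates <- function(i, j) {
    ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
    if (ov <= 0L || ov < frac * min(span[i], span[j])) return(FALSE)
    if (span[i] != span[j]) return(span[i] > span[j])
    if (hits$identity[i] != hits$identity[j])
      return(hits$identity[i] > hits$identity[j])
    if (hits$start[i] != hits$start[j]) return(hits$start[i] < hits$start[j])
    i < j
  }
  keep <- vapply(seq_len(n), function(j) {
    !any(vapply(seq_len(n)[-j], function(i) dominates(i, j), logical(1)))
  }, logical(1))
  hits[keep, , drop = FALSE]
}

random_hits <- function(n, glen = 5000L) {
  start <- sample.int(glen - 600L, n, replace = TRUE)
  len <- sample(50:500, n, replace = TRUE)
  data.frame(element = sprintf("e%02d", seq_len(n)), family = "f",
             genome_id = "g", start = start, end = start + len - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             length = len,
             identity = round(runif(n, 0.9, 1), 4), coverage = 1,
             stringsAsFactors = FALSE)
}
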