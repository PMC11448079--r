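#' Find primer annealing sites on a genome
#'
#' Locates matches of the primer on the plus strand and of its reverse
#' complement on the plus strand (i.e. minus-strand annealing), allowing up
#' to `max_mismatch` substitutions but requiring the `three_prime_exact`
#' 3'-terminal bases (where the polymerase extends) to match exactly.
#'
#' @param genome genome sequence (character scalar or named vector of 1).
#' @param primer primer sequence, 5'->3'.
#' @param max_mismatch substitutions tolerated (default 0).
#' @param three_prime_exact 3'-terminal bases that must match exactly
#'   (default 3).
#' @return data.frame `start`, `end` (1-based inclusive footprint),
#'   `strand` (`+`: primer extends rightwards; `-`: leftwards),
#'   `mismatches`.
#' @export
find_primer_sites <- function(genome, primer, max_mismatch = 0L,
                              three_prime_exact = 3L) {
  g <- as_genome_vec(genome)[[1L]]
  primer <- normalize_dna(primer)
  np <- nchar(primer)
  stopifnot(np >= 1L, three_prime_exact <= np)
  subj <- Biostrings::DNAString(g)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
    if (length(m) == 0L) next
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    keep <- logical(length(m))
    mm <- integer(length(m))
    for (i in seq_along(m)) {
      hit <- substr(g, st[i], en[i])
      mism <- which(strsplit(hit, "", fixed = TRUE)[[1]] !=
                      strsplit(pat, "", fixed = TRUE)[[1]])
      mm[i] <- length(mism)
      ## 3' end of the primer footprint: right end on +, left end on -
      tail3 <- if (strand == "+") (np - three_prime_exact + 1L):np else
        seq_len(three_prime_exact)
      keep[i] <- mm[i] <= max_mismatch && !any(mism %in% tail3)
    }
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        start = st[keep], end = en[keep], strand = strand,
        mismatches = mm[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict PCR amplicons for a primer pair
#'
#' Every pairing of a plus-strand site of one primer with a downstream
#' minus-strand site of the other primer within `max_product_len` yields an
#' amplicon. Both primer orderings are searched, so swapping `fwd` and
#' `rev` gives the same products. Product length is measured from the
#' forward primer's 5' base through the reverse primer's 5' base inclusive
#' — the gel-facing convention that includes both primer footprints.
#'
#' @param genome genome sequence (character scalar or named vector of 1).
#' @param fwd,rev primer sequences, each written 5'->3'.
#' @param max_mismatch,three_prime_exact see [find_primer_sites()].
#' @param max_product_len largest product reported (default 10000).
#' @return data.frame `start`, `end` (1-based inclusive product interval),
#'   `length`, `fwd_mismatches`, `rev_mismatches`, `fwd_primer`
#'   (`"fwd"`/`"rev"`: which primer annealed on the plus strand).
#' @export
predict_amplicons <- function(genome, fwd, rev, max_mismatch = 0L,
                              three_prime_exact = 3L,
                              max_product_len = 10000L) {
  sites <- list(
    fwd = find_primer_sites(genome, fwd, max_mismatch, three_prime_exact),
    rev = find_primer_sites(genome, rev, max_mismatch, three_prime_exact))
  rows <- list()
  for (ori in c("fwd", "rev")) {
    other <- if (ori == "fwd") "rev" else "fwd"
    plus <- sites[[ori]][sites[[ori]]$strand == "+", , drop = FALSE]
    minus <- sites[[other]][sites[[other]]$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        if (minus$start[j] <= plus$start[i]) next
        len <- minus$end[j] - plus$start[i] + 1L
        if (len > max_product_len) next
        rows[[length(rows) + 1L]] <- data.frame(
          start = plus$start[i], end = minus$end[j], length = len,
          fwd_mismatches = plus$mismatches[i],
          rev_mismatches = minus$mismatches[j],
          fwd_primer = ori, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0), fwd_primer = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
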