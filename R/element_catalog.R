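#' Read an IS-element reference library
#'
#' Library FASTA headers are `>name|family`; a header without `|` gets
#' family `NA`.
#'
#' @param path FASTA file.
#' @return data.frame with columns `name`, `family`, `seq`, `length`.
#' @export
read_element_library <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  name <- sub("\\|.*$", "", ids)
  family <- ifelse(grepl("|", ids, fixed = TRUE), sub("^[^|]*\\|", "", ids),
                   NA_character_)
  if (anyDuplicated(name)) stop("duplicate element names in library", call. = FALSE)
  data.frame(name = name, family = family, seq = unname(seqs),
             length = nchar(seqs), row.names = NULL, stringsAsFactors = FALSE)
}

element_library_df <- function(library) {
  if (is.character(library)) {
    return(data.frame(name = names(library), family = NA_character_,
                      seq = unname(library), length = nchar(library),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(library), all(c("name", "seq") %in% names(library)))
  if (is.null(library$family)) library$family <- NA_character_
  library$length <- nchar(library$seq)
  library
}

empty_hits <- function() {
  data.frame(element = character(0), family = character(0),
             genome_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), length = integer(0),
             identity = numeric(0), coverage = numeric(0),
             stringsAsFactors = FALSE)
}

#' Locate known elements in a genome
#'
#' Seed-and-extend search: exact k-mer seeds tiled along each library
#' element anchor candidate loci, which are then scored by local alignment
#' of the element against the candidate window. Both strands are searched.
#' Hits passing the identity and coverage thresholds are returned sorted by
#' `(genome_id, start)`. Significance is expressed as identity + coverage
#' thresholds (deterministic and self-contained) rather than an e-value.
#'
#' @param genome named character vector of genome sequences (or a single
#'   unnamed sequence).
#' @param library element library: data.frame from [read_element_library()]
#'   or a named character vector of sequences.
#' @param min_identity minimum fraction of element positions matching
#'   (default 0.90).
#' @param min_coverage minimum fraction of the element length aligned
#'   (default 0.5).
#' @param seed_k exact seed length (default 13).
#' @return data.frame of hits: `element`, `family`, `genome_id`, `start`,
#'   `end` (1-based inclusive), `strand`, `length`, `identity`, `coverage`.
#' @export
match_library <- function(genome, library, min_identity = 0.90,
                          min_coverage = 0.5, seed_k = 13L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  lib <- element_library_df(library)
  if (nrow(lib) == 0L) stop("empty element library", call. = FALSE)
  genome <- as_genome_vec(genome)
  out <- list()
  for (gid in names(genome)) {
    gseq <- genome[[gid]]
    if (!nzchar(gseq)) next
    subj <- Biostrings::DNAString(gseq)
    for (i in seq_len(nrow(lib))) {
      for (strand in c("+", "-")) {
        eseq <- if (strand == "+") lib$seq[i] else revcomp(lib$seq[i])
        cand <- seed_candidates(subj, eseq, seed_k)
        if (length(cand) == 0L) next
        h <- score_candidates(gseq, subj, eseq, cand, lib$name[i],
                              lib$family[i], gid, strand,
                              min_identity, min_coverage)
        if (!is.null(h)) out[[length(out) + 1L]] <- h
      }
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  ## collapse duplicate intervals found from both strands of a palindrome,
  ## or the same locus reached from several seeds
  key <- paste(hits$element, hits$genome_id, hits$start, hits$end)
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(hits$genome_id, hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

as_genome_vec <- function(genome) {
  if (is.character(genome) && is.null(names(genome)) && length(genome) == 1L) {
    genome <- c(genome_1 = genome)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome
}

## candidate element start positions (1-based) from non-overlapping exact seeds
seed_candidates <- function(subj, eseq, seed_k) {
  elen <- nchar(eseq)
  k <- min(seed_k, elen)
  offs <- seq(1L, elen - k + 1L, by = k)
  cand <- integer(0)
  for (o in offs) {
    seed <- substr(eseq, o, o + k - 1L)
    if (grepl("N", seed, fixed = TRUE)) next
    m <- Biostrings::matchPattern(seed, subj)
    if (length(m) == 0L) next
    cand <- c(cand, Biostrings::start(m) - (o - 1L))
  }
  if (length(cand) == 0L) return(integer(0))
  cand <- sort(unique(cand))
  ## cluster candidate starts closer than half the element length
  grp <- cumsum(c(TRUE, diff(cand) > max(10L, elen %/% 2L)))
  vapply(split(cand, grp), function(x) x[1L], integer(1))
}

score_candidates <- function(gseq, subj, eseq, cand, name, family, gid,
                             strand, min_identity, min_coverage) {
  elen <- nchar(eseq)
  glen <- nchar(gseq)
  pat <- Biostrings::DNAString(eseq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  rows <- list()
  for (s in cand) {
    pad <- max(20L, elen %/% 20L)
    ws <- max(1L, s - pad)
    we <- min(glen, s + elen - 1L + pad)
    win <- Biostrings::subseq(subj, ws, we)
    aln <- Biostrings::pairwiseAlignment(pat, win, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    pr <- Biostrings::pattern(aln)
    sr <- Biostrings::subject(aln)
    aligned <- Biostrings::end(pr) - Biostrings::start(pr) + 1L
    identity <- Biostrings::nmatch(aln) / elen
    coverage <- aligned / elen
    if (identity >= min_identity && coverage >= min_coverage) {
      st <- ws + Biostrings::start(sr) - 1L
      en <- ws + Biostrings::end(sr) - 1L
      if (en - st + 1L <= ceiling(elen * 1.1)) {
        rows[[length(rows) + 1L]] <- data.frame(
          element = name, family = family, genome_id = gid,
          start = st, end = en, strand = strand, length = en - st + 1L,
          identity = identity, coverage = coverage, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Remove redundant overlapping hits
#'
#' Whenever two hits of the input overlap by at least `containment_frac`
#' of the shorter hit's span, the shorter hit is dropped (ties broken by
#' higher identity, then leftmost start). Removal is simultaneous over all
#' pairs of the input — a hit dominated by any longer overlapping hit is
#' removed even if that hit is itself removed — which makes the filter
#' order-independent and idempotent. This mirrors manual redundancy
#' screening in which small elements nested inside longer ones are removed.
#'
#' @param hits hit data.frame from [match_library()], all on one genome.
#' @param containment_frac overlap fraction of the shorter span that
#'   triggers removal (default 0.5).
#' @return filtered hit data.frame.
#' @export
dedupe_overlaps <- function(hits, containment_frac = 0.5) {
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$genome_id)) > 1L) {
    stop("dedupe_overlaps expects hits on a single genome", call. = FALSE)
  }
  span <- hits$end - hits$start + 1L
  ## rank: longer better, then higher identity, then leftmost, then row
  rank_ <- order(order(-span, -hits$identity, hits$start))
  n <- nrow(hits)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ov <- min(hits$end[i], hits$end[j]) -
        max(hits$start[i], hits$start[j]) + 1L
      if (ov <= 0L) next
      if (ov >= containment_frac * min(span[i], span[j])) {
        keep[if (rank_[i] < rank_[j]) j else i] <- FALSE
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count copies of an element sequence in a genome
#'
#' Exact mode counts distinct non-overlapping occurrences of `element_seq`
#' or its reverse complement (leftmost-greedy; hits identical on both
#' strands, i.e. palindromes, are collapsed). Approximate mode counts
#' deduplicated [match_library()] hits at the given thresholds.
#'
#' @param genome single genome sequence (character scalar) or named vector of
#'   length 1.
#' @param element_seq the element sequence.
#' @param mode `"exact"` or `"approximate"`.
#' @param min_identity,min_coverage thresholds for approximate mode.
#' @return integer copy count.
#' @export
count_copies <- function(genome, element_seq, mode = c("exact", "approximate"),
                         min_identity = 0.90, min_coverage = 0.5) {
  mode <- match.arg(mode)
  if (!nzchar(element_seq)) stop("empty element sequence", call. = FALSE)
  genome <- as_genome_vec(genome)
  stopifnot(length(genome) == 1L)
  gseq <- genome[[1L]]
  if (mode == "exact") {
    iv <- locate_exact(gseq, element_seq)
    return(nrow(iv))
  }
  hits <- match_library(genome, c(elt = element_seq),
                        min_identity = min_identity,
                        min_coverage = min_coverage)
  nrow(dedupe_overlaps(hits))
}

#' Locate exact occurrences of a sequence on either strand
#'
#' Returns non-overlapping occurrences, leftmost-greedy across strands;
#' same-interval hits on both strands (palindromes) are collapsed to one.
#'
#' @param gseq genome sequence (character scalar).
#' @param element_seq query sequence.
#' @return data.frame `start`, `end`, `strand` sorted by start.
#' @export
locate_exact <- function(gseq, element_seq) {
  ## matchPattern caps pattern length at 20 kb; long queries (duplicated
  ## regions, cassettes) fall back to fixed-string search
  find_starts <- function(patt) {
    if (nchar(patt) <= 10000L) {
      m <- Biostrings::matchPattern(patt, Biostrings::DNAString(gseq))
      return(Biostrings::start(m))
    }
    hits <- gregexpr(patt, gseq, fixed = TRUE)[[1]]
    if (hits[1L] == -1L) return(integer(0))
    ## gregexpr reports non-overlapping matches only; rescan after each
    ## hit start to recover overlapping tandem copies
    starts <- integer(0)
    from <- 1L
    while (TRUE) {
      h <- regexpr(patt, substr(gseq, from, nchar(gseq)), fixed = TRUE)
      if (h == -1L) break
      starts <- c(starts, from + h - 1L)
      from <- from + h
    }
    starts
  }
  rc <- revcomp(element_seq)
  fwd_s <- find_starts(element_seq)
  rev_s <- if (identical(rc, toupper(element_seq))) integer(0) else
    find_starts(rc)
  w <- nchar(element_seq)
  df <- data.frame(
    start = c(fwd_s, rev_s),
    end = c(fwd_s, rev_s) + w - 1L,
    strand = c(rep("+", length(fwd_s)), rep("-", length(rev_s))),
    stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(df)
  df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  ## leftmost-greedy non-overlapping selection
  keep <- logical(nrow(df))
  last_end <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- df$end[i]
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit element hits as GFF3 `mobile_genetic_element` features
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_gff <- function(hits, path) {
  feat <- data.frame(
    seqid = hits$genome_id, source = "mobilome",
    type = "mobile_genetic_element",
    start = hits$start, end = hits$end, score = ".",
    strand = hits$strand, phase = ".",
    attributes = sprintf("ID=%s_%d;Name=%s;family=%s;identity=%.4f;coverage=%.4f",
                         hits$element, seq_len(nrow(hits)), hits$element,
                         hits$family, hits$identity, hits$coverage),
    stringsAsFactors = FALSE)
  write_gff(feat, path)
}
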