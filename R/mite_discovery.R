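#' Find high-copy exact repeats in a genome
#'
#' Mines maximal repeated substrings in a length window that occur at least
#' `min_copies` times (counting both strands), using exact k-mer anchoring:
#' every k-mer is counted over both strands, positions whose k-mer reaches
#' the copy threshold are merged into maximal runs, and each resulting
#' region is re-counted as a whole. Exact-match mining is appropriate for
#' young, homogeneous MITE families whose copies are identical; diverged
#' homologs can be recovered downstream with [match_library()] at relaxed
#' identity.
#'
#' @param genome genome sequence (character scalar or named vector of 1).
#' @param min_len,max_len length window for reported repeats
#'   (defaults 80 and 500 nt, the canonical MITE size range).
#' @param min_copies minimum copy number (default 5).
#' @param k anchor k-mer size (default 21).
#' @return data.frame `seq` (canonical strand: lexicographically smaller of
#'   the two), `length`, `copies`, ordered longest first.
#' @export
find_high_copy_repeats <- function(genome, min_len = 80L, max_len = 500L,
                                   min_copies = 5L, k = 21L) {
  stopifnot(min_len >= 50L, min_len <= max_len, max_len <= 1000L,
            min_copies >= 2L)
  genome <- as_genome_vec(genome)
  g <- genome[[1L]]
  n <- nchar(g)
  empty <- data.frame(seq = character(0), length = integer(0),
                      copies = integer(0), stringsAsFactors = FALSE)
  if (n < max(min_len, k)) return(empty)
  pos <- seq_len(n - k + 1L)
  kf <- substring(g, pos, pos + k - 1L)
  kr <- substring(revcomp(g), pos, pos + k - 1L)
  cnt <- data.table::data.table(km = c(kf, kr))[, .N, by = "km"]
  nf <- cnt$N[match(kf, cnt$km)]
  flag <- nf >= min_copies & !grepl("N", kf, fixed = TRUE)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  if (length(hi) == 0L) return(empty)
  ## trim each run to its modal-count core: k-mers crossing a repeat
  ## boundary are shared only by the subset of copies whose flanks agree,
  ## so their counts drop below the modal (interior) count, and trimming
  ## to the modal count recovers the exact repeat unit
  reg_start <- integer(0); reg_end <- integer(0)
  for (ri in hi) {
    idx <- starts[ri]:ends[ri]
    cnts <- nf[idx]
    tab <- table(cnts)
    mode_cnt <- as.integer(names(tab)[which.max(tab)])
    core <- which(cnts >= mode_cnt)
    if (length(core) == 0L) next
    reg_start <- c(reg_start, idx[core[1L]])
    reg_end <- c(reg_end, idx[core[length(core)]] + k - 1L)
  }
  reg_len <- reg_end - reg_start + 1L
  sel <- reg_len >= min_len & reg_len <= max_len
  if (!any(sel)) return(empty)
  seqs <- substring(g, reg_start[sel], reg_end[sel])
  rcs <- revcomp_vec(seqs)
  canon <- ifelse(seqs <= rcs, seqs, rcs)
  canon <- unique(canon)
  copies <- vapply(canon, function(s) count_copies(g, s, mode = "exact"),
                   integer(1))
  keep <- copies >= min_copies
  out <- data.frame(seq = canon[keep], length = nchar(canon[keep]),
                    copies = unname(copies[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$length, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect a target-site duplication flanking an element locus
#'
#' Returns the largest window width `w` in `[w_min, w_max]` for which the
#' `w` nucleotides immediately left of the locus equal the `w` nucleotides
#' immediately right of it — the signature left by transposases that
#' duplicate their target site. The locus interval excludes the TSD copies.
#'
#' @param genome genome sequence (character scalar or named vector of 1).
#' @param start,end 1-based inclusive element interval.
#' @param w_min,w_max TSD length search range (defaults 2 and 16).
#' @return list `present`, `length` (0 if absent), `seq`, `left_interval`,
#'   `right_interval` (each `c(start, end)`).
#' @export
detect_tsd <- function(genome, start, end, w_min = 2L, w_max = 16L) {
  genome <- as_genome_vec(genome)
  g <- genome[[1L]]
  n <- nchar(g)
  stopifnot(start >= 1L, end >= start, end <= n)
  if (start - w_max < 1L || end + w_max > n) {
    stop("insufficient flank for TSD detection (need ", w_max,
         " nt on both sides)", call. = FALSE)
  }
  for (w in seq(w_max, w_min)) {
    left <- substr(g, start - w, start - 1L)
    right <- substr(g, end + 1L, end + w)
    if (identical(left, right)) {
      return(list(present = TRUE, length = w, seq = left,
                  left_interval = c(start - w, start - 1L),
                  right_interval = c(end + 1L, end + w)))
    }
  }
  list(present = FALSE, length = 0L, seq = "",
       left_interval = NULL, right_interval = NULL)
}

#' Detect terminal inverted repeats of an element
#'
#' Finds the longest ungapped alignment of the element's 5' prefix against
#' the reverse complement of its 3' suffix with at most `max_mismatch`
#' substitutions.
#'
#' @param elem_seq element sequence; must be at least `2 * min_len` long.
#' @param min_len minimum reported TIR length (default 7).
#' @param max_mismatch maximum substitutions tolerated (default 2).
#' @return list `present`, `length`, `mismatches`, `left_seq`, `right_seq`.
#' @export
detect_tir <- function(elem_seq, min_len = 7L, max_mismatch = 2L) {
  elem_seq <- normalize_dna(elem_seq)
  n <- nchar(elem_seq)
  stopifnot(n >= 2L * min_len)
  half <- n %/% 2L
  pre <- strsplit(substr(elem_seq, 1L, half), "", fixed = TRUE)[[1]]
  suf_rc <- strsplit(revcomp(substr(elem_seq, n - half + 1L, n)),
                     "", fixed = TRUE)[[1]]
  mm_cum <- cumsum(pre != suf_rc)
  ok <- which(mm_cum <= max_mismatch & seq_len(half) >= min_len)
  if (length(ok) == 0L) {
    return(list(present = FALSE, length = 0L, mismatches = NA_integer_,
                left_seq = "", right_seq = ""))
  }
  L <- max(ok)
  list(present = TRUE, length = L, mismatches = mm_cum[L],
       left_seq = substr(elem_seq, 1L, L),
       right_seq = substr(elem_seq, n - L + 1L, n))
}

#' Scan all six frames for open reading frames
#'
#' An ORF runs from an ATG (only ATG starts are considered) to the next
#' in-frame stop codon; the stop is included in the span. Nested ATGs
#' report only the longest ORF per stop. ORFs spanning fewer than
#' `min_len_nt` nucleotides (stop included) are excluded, and ORFs with no
#' downstream stop are not reported.
#'
#' @param seq DNA sequence.
#' @param min_len_nt minimum ORF span in nucleotides (default 30).
#' @return data.frame `strand` (+/-), `frame` (1..3 within the strand),
#'   `start`, `end` (1-based inclusive on the forward axis of `seq`),
#'   `span_nt`, `peptide` (stop excluded).
#' @export
scan_orfs <- function(seq, min_len_nt = 30L) {
  stopifnot(min_len_nt >= 6L)
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 2L) next
      cod_start <- off + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, cod_start, cod_start + 2L)
      first_atg <- NA_integer_
      for (ci in seq_len(ncod)) {
        cd <- codons[ci]
        if (cd %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(first_atg)) {
            p1 <- cod_start[first_atg]
            p2 <- cod_start[ci] + 2L
            span <- p2 - p1 + 1L
            if (span >= min_len_nt) {
              pep <- translate_cds(substr(s, p1, p2 - 3L))
              if (strand == "+") {
                st <- p1; en <- p2
              } else {
                st <- n - p2 + 1L; en <- n - p1 + 1L
              }
              rows[[length(rows) + 1L]] <- data.frame(
                strand = strand, frame = off + 1L, start = st, end = en,
                span_nt = span, peptide = pep, stringsAsFactors = FALSE)
            }
          }
          first_atg <- NA_integer_
        } else if (is.na(first_atg) && cd == "ATG") {
          first_atg <- ci
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      span_nt = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$span_nt, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stem-loop folding potential by base-pair maximization
#'
#' Nussinov-style dynamic program maximizing the number of nested
#' Watson-Crick plus G·U wobble pairs with a minimum hairpin loop of
#' `min_loop` unpaired bases. T is read as U. This scores the hairpin
#' potential that secondary-structure folders report for MITEs, without
#' a thermodynamic model.
#'
#' @param seq DNA sequence; sequences too short to form any pair score 0.
#' @param min_loop minimum loop length (default 3).
#' @return list `max_pairs` (integer), `pairing_fraction`
#'   (`2 * max_pairs / nchar(seq)`).
#' @export
fold_score <- function(seq, min_loop = 3L) {
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  if (n < min_loop + 2L) {
    return(list(max_pairs = 0L, pairing_fraction = 0))
  }
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  can_pair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  F <- matrix(0L, n, n)
  for (l in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - l)) {
      j <- i + l
      best <- 0L
      if (can_pair(x[i], x[j])) {
        inner <- if (j - 1L >= i + 1L) F[i + 1L, j - 1L] else 0L
        best <- inner + 1L
      }
      ks <- i:(j - 1L)
      split_best <- max(F[i, ks] + F[cbind(ks + 1L, j)])
      F[i, j] <- max(best, split_best)
    }
  }
  mp <- F[1L, n]
  list(max_pairs = as.integer(mp), pairing_fraction = 2 * mp / n)
}

#' Characterize a candidate repeat across genomes
#'
#' Locates exact occurrences of `seq` in each genome, calls the TSD at every
#' locus, the TIR, the six-frame ORFs and the folding potential, and bundles
#' the evidence into a candidate object ready for [classify_mite()].
#' Loci too close to a contig end for TSD detection are recorded with an
#' `NA` TSD call.
#'
#' @param genomes named character vector of genome sequences.
#' @param seq candidate element sequence.
#' @param w_min,w_max TSD search range (see [detect_tsd()]).
#' @param tir_min_len,tir_max_mismatch TIR parameters (see [detect_tir()]).
#' @param orf_min_len_nt minimum ORF span (see [scan_orfs()]).
#' @return an object of class `mite_candidate`: list with `seq`, `length`,
#'   `loci` (data.frame `genome_id`, `start`, `end`, `strand`, `tsd_present`,
#'   `tsd_len`, `tsd_seq`), `copies` (named per-genome counts), `tir`,
#'   `orfs`, `fold`, plus `verdict`/`reason`/`linked_family` slots filled by
#'   later stages.
#' @export
characterize_repeat <- function(genomes, seq, w_min = 2L, w_max = 16L,
                                tir_min_len = 7L, tir_max_mismatch = 2L,
                                orf_min_len_nt = 30L) {
  genomes <- as_genome_vec(genomes)
  seq <- normalize_dna(seq)
  loci <- list()
  copies <- integer(length(genomes))
  names(copies) <- names(genomes)
  for (gid in names(genomes)) {
    occ <- locate_exact(genomes[[gid]], seq)
    copies[gid] <- nrow(occ)
    if (nrow(occ) == 0L) next
    tsd <- lapply(seq_len(nrow(occ)), function(i) {
      tryCatch(detect_tsd(genomes[[gid]], occ$start[i], occ$end[i],
                          w_min = w_min, w_max = w_max),
               error = function(e) list(present = NA, length = NA_integer_,
                                        seq = NA_character_))
    })
    loci[[gid]] <- data.frame(
      genome_id = gid, start = occ$start, end = occ$end, strand = occ$strand,
      tsd_present = vapply(tsd, function(t) as.logical(t$present), logical(1)),
      tsd_len = vapply(tsd, function(t) as.integer(t$length), integer(1)),
      tsd_seq = vapply(tsd, function(t) as.character(t$seq), character(1)),
      stringsAsFactors = FALSE)
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(genome_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), tsd_present = logical(0),
               tsd_len = integer(0), tsd_seq = character(0),
               stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  structure(list(
    seq = seq, length = nchar(seq), loci = loci, copies = copies,
    tir = detect_tir(seq, min_len = tir_min_len,
                     max_mismatch = tir_max_mismatch),
    orfs = scan_orfs(seq, min_len_nt = orf_min_len_nt),
    fold = fold_score(seq),
    verdict = NA_character_, reason = NA_character_,
    linked_family = NA_character_, ambiguous_family = FALSE
  ), class = "mite_candidate")
}

#' @export
print.mite_candidate <- function(x, ...) {
  cat(sprintf("mite_candidate: %d nt, copies [%s], TIR %s (%d nt, %s mm), TSD mode %s nt\n",
              x$length,
              paste(sprintf("%s=%d", names(x$copies), x$copies), collapse = ", "),
              if (isTRUE(x$tir$present)) "present" else "absent",
              x$tir$length, format(x$tir$mismatches),
              format(modal_tsd_len(x))))
  cat(sprintf("  ORFs >= threshold: %d scanned; fold %d pairs (%.2f paired)\n",
              nrow(x$orfs), x$fold$max_pairs, x$fold$pairing_fraction))
  cat(sprintf("  verdict: %s%s; linked family: %s\n",
              format(x$verdict),
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else "",
              format(x$linked_family)))
  invisible(x)
}

modal_tsd_len <- function(candidate) {
  tl <- candidate$loci$tsd_len
  tl <- tl[!is.na(tl) & tl > 0L]
  if (length(tl) == 0L) return(NA_integer_)
  tab <- table(tl)
  as.integer(names(tab)[which.max(tab)])
}

#' Classify a candidate repeat as a MITE or reject it
#'
#' A candidate is called a MITE iff (i) it carries a terminal inverted
#' repeat, (ii) at least one locus shows a target-site duplication, (iii) no
#' ORF reaches the transposase-length threshold (non-autonomy), and (iv) its
#' total copy number reaches the minimum. Otherwise the verdict is
#' `rejected` with the first failed criterion as reason (`no_TIR`,
#' `no_TSD`, `coding`, `low_copy`).
#'
#' @param candidate `mite_candidate` from [characterize_repeat()].
#' @param transposase_orf_min_nt ORF span that disqualifies a candidate as
#'   non-autonomous (default 600 nt).
#' @param min_copies minimum total copy number (default 5).
#' @return the candidate with `verdict` and `reason` filled.
#' @export
classify_mite <- function(candidate, transposase_orf_min_nt = 600L,
                          min_copies = 5L) {
  stopifnot(inherits(candidate, "mite_candidate"))
  reason <- NA_character_
  if (!isTRUE(candidate$tir$present)) {
    reason <- "no_TIR"
  } else if (!any(candidate$loci$tsd_present %in% TRUE)) {
    reason <- "no_TSD"
  } else if (nrow(candidate$orfs) > 0L &&
             any(candidate$orfs$span_nt >= transposase_orf_min_nt)) {
    reason <- "coding"
  } else if (sum(candidate$copies) < min_copies) {
    reason <- "low_copy"
  }
  candidate$verdict <- if (is.na(reason)) "MITE" else "rejected"
  candidate$reason <- reason
  candidate
}

#' Link a MITE to a candidate mobilizing transposase family
#'
#' MITEs are mobilized in trans by an autonomous element with matching
#' termini. For each (deduplicated) transposase hit, both termini are
#' extracted in element orientation; a family is linked when the 5' terminus
#' matches the MITE's TIR seed and the 3' terminus matches its reverse
#' complement, each with at most `max_mismatch` substitutions, AND the
#' element's own target-site duplication length at that locus equals the
#' MITE's modal TSD length. Several qualifying families are all reported and
#' flagged ambiguous.
#'
#' @param mite `mite_candidate`.
#' @param element_hits deduplicated hit data.frame from [match_library()].
#' @param genomes named character vector holding the hit genomes.
#' @param seed_len terminus length compared (default 9).
#' @param max_mismatch per-terminus mismatch tolerance (default 1).
#' @return the candidate with `linked_family` (comma-joined if several, `NA`
#'   if none) and `ambiguous_family` filled.
#' @export
link_family <- function(mite, element_hits, genomes, seed_len = 9L,
                        max_mismatch = 1L) {
  stopifnot(inherits(mite, "mite_candidate"))
  genomes <- as_genome_vec(genomes)
  seed <- substr(mite$seq, 1L, seed_len)
  mite_tsd <- modal_tsd_len(mite)
  fams <- character(0)
  if (!is.null(element_hits) && nrow(element_hits) > 0L) {
    for (i in seq_len(nrow(element_hits))) {
      gid <- element_hits$genome_id[i]
      if (!gid %in% names(genomes)) next
      g <- genomes[[gid]]
      st <- element_hits$start[i]; en <- element_hits$end[i]
      elem <- substr(g, st, en)
      if (element_hits$strand[i] == "-") elem <- revcomp(elem)
      if (nchar(elem) < 2L * seed_len) next
      term5 <- substr(elem, 1L, seed_len)
      term3 <- revcomp(substr(elem, nchar(elem) - seed_len + 1L, nchar(elem)))
      if (hamming(term5, seed) > max_mismatch ||
          hamming(term3, seed) > max_mismatch) next
      tsd <- tryCatch(detect_tsd(g, st, en), error = function(e) NULL)
      if (is.null(tsd) || !isTRUE(tsd$present)) next
      if (!is.na(mite_tsd) && tsd$length == mite_tsd) {
        fams <- c(fams, element_hits$family[i])
      }
    }
  }
  fams <- unique(fams[!is.na(fams)])
  mite$linked_family <- if (length(fams) == 0L) NA_character_ else
    paste(fams, collapse = ",")
  mite$ambiguous_family <- length(fams) > 1L
  mite
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Discover and classify MITEs across a set of genomes
#'
#' End-to-end driver: mines high-copy repeats in each genome, pools the
#' candidate sequences, characterizes each across all genomes, classifies,
#' and (when an element hit table is supplied) links verdict-MITE candidates
#' to a mobilizing transposase family.
#'
#' @inheritParams find_high_copy_repeats
#' @param genomes named character vector of genome sequences.
#' @param element_hits optional deduplicated hits from [match_library()] for
#'   family linking.
#' @param transposase_orf_min_nt see [classify_mite()].
#' @param seed_len,max_link_mismatch see [link_family()].
#' @return list of `mite_candidate` objects, longest first.
#' @export
discover_mites <- function(genomes, element_hits = NULL, min_len = 80L,
                           max_len = 500L, min_copies = 5L, k = 21L,
                           transposase_orf_min_nt = 600L, seed_len = 9L,
                           max_link_mismatch = 1L) {
  genomes <- as_genome_vec(genomes)
  cand_seqs <- character(0)
  for (gid in names(genomes)) {
    rep_df <- find_high_copy_repeats(genomes[gid], min_len = min_len,
                                     max_len = max_len,
                                     min_copies = min_copies, k = k)
    cand_seqs <- c(cand_seqs, rep_df$seq)
  }
  cand_seqs <- unique(cand_seqs)
  out <- lapply(cand_seqs, function(s) {
    cand <- characterize_repeat(genomes, s)
    cand <- classify_mite(cand, transposase_orf_min_nt = transposase_orf_min_nt,
                          min_copies = min_copies)
    if (identical(cand$verdict, "MITE") && !is.null(element_hits)) {
      cand <- link_family(cand, element_hits, genomes, seed_len = seed_len,
                          max_mismatch = max_link_mismatch)
    }
    cand
  })
  out[order(-vapply(out, function(x) x$length, integer(1)))]
}

#' Summarize MITE candidates as a table
#'
#' @param candidates list of `mite_candidate` objects.
#' @return data.frame, one row per candidate: length, per-genome copies
#'   (comma-joined `genome=count`), TIR length/mismatches, modal TSD length,
#'   fold pairs, verdict, reason, linked family, and the sequence.
#' @export
mite_summary <- function(candidates) {
  do.call(rbind, lapply(candidates, function(x) {
    data.frame(
      length = x$length,
      copies = paste(sprintf("%s=%d", names(x$copies), x$copies),
                     collapse = ","),
      total_copies = sum(x$copies),
      tir_len = x$tir$length, tir_mismatches = x$tir$mismatches,
      tsd_len = modal_tsd_len(x),
      fold_pairs = x$fold$max_pairs,
      pairing_fraction = x$fold$pairing_fraction,
      verdict = x$verdict, reason = x$reason,
      linked_family = x$linked_family,
      seq = x$seq, stringsAsFactors = FALSE)
  }))
}
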