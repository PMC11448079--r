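## k-mer table for one genome: data.table(pos, km, canon, strand)
## strand "+" when the forward k-mer is the canonical (lexicographically
## smaller) form, "-" otherwise. K-mers containing N are dropped.
kmer_table <- function(g, k) {
  n <- nchar(g)
  if (n < k) {
    return(data.table::data.table(pos = integer(0), canon = character(0),
                                  strand = character(0)))
  }
  pos <- seq_len(n - k + 1L)
  kf <- substring(g, pos, pos + k - 1L)
  kr <- substring(revcomp(g), pos, pos + k - 1L)
  ## reverse complement of the k-mer at pos i is the k-mer at position
  ## n - k + 2 - i of the reverse-complemented genome
  krc <- kr[n - k + 2L - pos]
  fwd_canon <- kf <= krc
  dt <- data.table::data.table(pos = pos,
                               canon = ifelse(fwd_canon, kf, krc),
                               strand = ifelse(fwd_canon, "+", "-"))
  dt[!grepl("N", canon, fixed = TRUE)]
}

#' Build exact unique-k-mer anchors between two genomes
#'
#' Every k-mer that occurs exactly once in each genome (counting both
#' strands) is matched across genomes and maximal exact co-linear runs are
#' merged into anchors. Because the assemblies compared are nearly
#' identical, unique anchors tile essentially everything; repeated regions
#' (the interesting parts) fall between anchors by construction. K-mers
#' containing N are excluded.
#'
#' @param genome_a,genome_b genome sequences (character scalar or named
#'   vector of length 1).
#' @param k anchor k-mer length, odd (default 21). Odd k cannot be its own
#'   reverse complement, which keeps strand assignment unambiguous.
#' @return data.frame `pos_a`, `pos_b` (1-based starts), `length`,
#'   `orientation` (`same`/`inverted`), sorted by `pos_a`. For inverted
#'   anchors `pos_b` is the start of the matching interval on the forward
#'   strand of genome B.
#' @export
build_anchors <- function(genome_a, genome_b, k = 21L) {
  stopifnot(k %% 2L == 1L)
  a <- as_genome_vec(genome_a)[[1L]]
  b <- as_genome_vec(genome_b)[[1L]]
  ta <- kmer_table(a, k)
  tb <- kmer_table(b, k)
  ua <- ta[, .N, by = "canon"][N == 1L, canon]
  ub <- tb[, .N, by = "canon"][N == 1L, canon]
  shared <- intersect(ua, ub)
  empty <- data.frame(pos_a = integer(0), pos_b = integer(0),
                      length = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  if (length(shared) == 0L) return(empty)
  ja <- ta[canon %in% shared]
  jb <- tb[canon %in% shared]
  data.table::setkey(ja, canon)
  data.table::setkey(jb, canon)
  m <- ja[jb]
  ## ja columns: pos, strand; jb's arrive as i.pos, i.strand
  m <- data.table::data.table(pos_a = m$pos, pos_b = m$i.pos,
                              orientation = ifelse(m$strand == m$i.strand,
                                                   "same", "inverted"))
  data.table::setorder(m, pos_a)
  ## merge co-linear runs: same orientation, constant (anti)diagonal,
  ## step at most k so the merged interval is exactly identical
  diag_ <- ifelse(m$orientation == "same", m$pos_b - m$pos_a,
                  m$pos_b + m$pos_a)
  step <- c(Inf, diff(m$pos_a))
  brk <- step > k | c(TRUE, diff(diag_) != 0) |
    c(TRUE, m$orientation[-1L] != m$orientation[-nrow(m)])
  m[, grp := cumsum(brk)]
  res <- m[, .(pos_a = pos_a[1L],
               pos_b = min(pos_b),
               length = pos_a[.N] - pos_a[1L] + k,
               orientation = orientation[1L]), by = "grp"]
  out <- data.frame(pos_a = res$pos_a, pos_b = res$pos_b,
                    length = res$length, orientation = res$orientation,
                    stringsAsFactors = FALSE)
  out[order(out$pos_a), , drop = FALSE]
}

#' Call large inversions from anchors
#'
#' Maximal runs of inverted-orientation anchors spanning at least `min_len`
#' seed inversion calls. Each call is then refined to the maximal inverted
#' interval: the boundaries are pushed outward while the base left of the
#' interval in genome A still complements the base right of the interval in
#' genome B (and vice versa), so the reported interval is the full
#' reverse-complemented segment including the recombinogenic repeat copies
#' at its edges. The flanking repeat is the maximal prefix of the interval
#' equal to the reverse complement of its suffix (the inverted-repeat pair
#' that mediated the inversion); its genome-wide copy number is counted in
#' each genome when it is at least 20 nt.
#'
#' @param anchors data.frame from [build_anchors()].
#' @param genome_a,genome_b the two genome sequences.
#' @param min_len minimum anchored inverted span in genome A (default
#'   10000).
#' @param max_flank largest flanking repeat searched (default 20000).
#' @return data.frame `start_a`, `end_a`, `start_b`, `end_b` (1-based
#'   inclusive), `length`, `flank_repeat_len`, `flank_copy_number_a`,
#'   `flank_copy_number_b`, `flank_seq`.
#' @export
call_inversions <- function(anchors, genome_a, genome_b, min_len = 10000L,
                            max_flank = 20000L) {
  a <- as_genome_vec(genome_a)[[1L]]
  b <- as_genome_vec(genome_b)[[1L]]
  empty <- data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      length = integer(0), flank_repeat_len = integer(0),
                      flank_copy_number_a = integer(0),
                      flank_copy_number_b = integer(0),
                      flank_seq = character(0), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0L) return(empty)
  anchors <- anchors[order(anchors$pos_a), , drop = FALSE]
  r <- rle(anchors$orientation)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inv <- which(r$values == "inverted")
  rows <- list()
  for (ri in inv) {
    idx <- starts[ri]:ends[ri]
    s_a <- min(anchors$pos_a[idx])
    e_a <- max(anchors$pos_a[idx] + anchors$length[idx] - 1L)
    if (e_a - s_a + 1L < min_len) next
    s_b <- min(anchors$pos_b[idx])
    e_b <- max(anchors$pos_b[idx] + anchors$length[idx] - 1L)
    ## refine to the maximal inverted interval: A[s_a..e_a] must equal
    ## revcomp(B[s_b..e_b]); push each boundary pair outward while the
    ## relation still holds
    comp1 <- function(g, p) chartr("ACGTN", "TGCAN", substr(g, p, p))
    while (s_a > 1L && e_b < nchar(b) &&
           substr(a, s_a - 1L, s_a - 1L) == comp1(b, e_b + 1L)) {
      s_a <- s_a - 1L; e_b <- e_b + 1L
    }
    while (e_a < nchar(a) && s_b > 1L &&
           substr(a, e_a + 1L, e_a + 1L) == comp1(b, s_b - 1L)) {
      e_a <- e_a + 1L; s_b <- s_b - 1L
    }
    fl <- flank_repeat(a, s_a, e_a, max_flank)
    rows[[length(rows) + 1L]] <- data.frame(
      start_a = s_a, end_a = e_a, start_b = s_b, end_b = e_b,
      length = e_a - s_a + 1L,
      flank_repeat_len = fl$len,
      flank_copy_number_a = if (fl$len >= 20L)
        count_copies(a, fl$seq, mode = "exact") else 0L,
      flank_copy_number_b = if (fl$len >= 20L)
        count_copies(b, fl$seq, mode = "exact") else 0L,
      flank_seq = fl$seq, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## maximal w with A[s .. s+w-1] == revcomp(A[e-w+1 .. e]): the interval's
## own terminal inverted repeat. Per-position comparison
## prefix[j] == comp(rev(suffix))[j] is monotone in w, so scan outward.
flank_repeat <- function(a, s, e, max_flank) {
  w_max <- min(max_flank, (e - s + 1L) %/% 2L)
  if (w_max < 1L) return(list(len = 0L, seq = ""))
  left <- strsplit(substr(a, s, s + w_max - 1L), "", fixed = TRUE)[[1]]
  right <- rev(strsplit(chartr("ACGTN", "TGCAN",
                               substr(a, e - w_max + 1L, e)),
                        "", fixed = TRUE)[[1]])
  neq <- which(left != right)
  w <- if (length(neq) == 0L) w_max else neq[1L] - 1L
  list(len = w, seq = if (w > 0L) substr(a, s, s + w - 1L) else "")
}

#' Call strain-specific insertions from anchors
#'
#' Between adjacent same-orientation anchors, a gap of at least `min_len`
#' in exactly one genome accompanied by a gap within `slack` nucleotides in
#' the other is an insertion in the gapped (carrier) genome. A negative gap
#' in the non-carrier (anchors overlapping by up to a target-site
#' duplication length) is resolved leftmost: the reported carrier interval
#' then includes one copy of the duplicated target site, so its length is
#' the full length gained by the carrier. Gap pairs failing the asymmetry
#' test are reported as `complex` rather than forced into either class.
#'
#' @param anchors data.frame from [build_anchors()].
#' @param genome_a,genome_b the two genome sequences.
#' @param min_len minimum insertion length (default 50).
#' @param slack largest absolute gap tolerated in the non-carrier genome
#'   (default 10; negative gaps down to `-max_tsd` are also accepted).
#' @param max_tsd largest anchor overlap interpreted as a target-site
#'   duplication (default 16).
#' @param elements optional element catalog (data.frame `name`, `seq`) used
#'   to label `matched_element` when an element occurs as an exact substring
#'   (either strand) of the inserted sequence and covers most of it.
#' @return data.frame `type` (`insertion`/`complex`), `carrier` (`A`/`B`,
#'   NA for complex), `site_in_other` (1-based position before which the
#'   insertion sits), `start`, `end` (carrier interval), `length`,
#'   `inserted_seq`, `matched_element`.
#' @export
call_indels <- function(anchors, genome_a, genome_b, min_len = 50L,
                        slack = 10L, max_tsd = 16L, elements = NULL) {
  a <- as_genome_vec(genome_a)[[1L]]
  b <- as_genome_vec(genome_b)[[1L]]
  empty <- data.frame(type = character(0), carrier = character(0),
                      site_in_other = integer(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      inserted_seq = character(0),
                      matched_element = character(0), stringsAsFactors = FALSE)
  same <- anchors[anchors$orientation == "same", , drop = FALSE]
  if (nrow(same) < 2L) return(empty)
  same <- same[order(same$pos_a), , drop = FALSE]
  ## keep only anchors co-linear in B as well (greedy monotone filter)
  keep <- same$pos_b >= cummax(c(0L, head(same$pos_b, -1L)))
  same <- same[keep, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(same) - 1L)) {
    aL_end <- same$pos_a[i] + same$length[i] - 1L
    bL_end <- same$pos_b[i] + same$length[i] - 1L
    gap_a <- same$pos_a[i + 1L] - aL_end - 1L
    gap_b <- same$pos_b[i + 1L] - bL_end - 1L
    if (gap_a <= 0L && gap_b <= 0L) next
    ins_in_b <- gap_b >= min_len && gap_a <= slack && gap_a >= -max_tsd
    ins_in_a <- gap_a >= min_len && gap_b <= slack && gap_b >= -max_tsd
    if (ins_in_b || ins_in_a) {
      if (ins_in_b) {
        carrier <- "B"; g <- b
        shift <- min(gap_a, 0L)
        st <- bL_end + 1L + shift
        en <- same$pos_b[i + 1L] - 1L
        site <- aL_end + 1L + shift
      } else {
        carrier <- "A"; g <- a
        shift <- min(gap_b, 0L)
        st <- aL_end + 1L + shift
        en <- same$pos_a[i + 1L] - 1L
        site <- bL_end + 1L + shift
      }
      seq <- substr(g, st, en)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "insertion", carrier = carrier, site_in_other = site,
        start = st, end = en, length = en - st + 1L, inserted_seq = seq,
        matched_element = match_inserted(seq, elements, max_tsd),
        stringsAsFactors = FALSE)
    } else if (gap_a > slack && gap_b > slack) {
      ## anchor gaps caused by repeats carry identical (or, across an
      ## inversion, reverse-complemented) content in both genomes; only
      ## gaps whose content actually differs are reported as complex
      ga_seq <- substr(a, aL_end + 1L, same$pos_a[i + 1L] - 1L)
      gb_seq <- substr(b, bL_end + 1L, same$pos_b[i + 1L] - 1L)
      if (identical(ga_seq, gb_seq)) next
      if (nchar(ga_seq) == nchar(gb_seq) &&
          identical(ga_seq, revcomp(gb_seq))) next
      rows[[length(rows) + 1L]] <- data.frame(
        type = "complex", carrier = NA_character_,
        site_in_other = NA_integer_, start = aL_end + 1L,
        end = same$pos_a[i + 1L] - 1L, length = gap_a,
        inserted_seq = NA_character_, matched_element = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

match_inserted <- function(seq, elements, max_tsd) {
  if (is.null(elements) || nrow(elements) == 0L || is.na(seq))
    return(NA_character_)
  for (i in seq_len(nrow(elements))) {
    es <- elements$seq[i]
    if (nchar(seq) - nchar(es) <= 2L * max_tsd && nchar(es) <= nchar(seq) &&
        (grepl(es, seq, fixed = TRUE) || grepl(revcomp(es), seq, fixed = TRUE))) {
      return(elements$name[i])
    }
  }
  NA_character_
}

#' Find large intra-genome duplications
#'
#' Maximal regions whose k-mers all recur elsewhere in the genome (either
#' strand) are merged from runs of multi-copy k-mers; regions of at least
#' `min_len` are located genome-wide and paired into duplication calls.
#' Detection is driven by exact k-mer runs, so the reported copies are
#' identical (identity 1.0); copies diverged below 100% identity fragment
#' into several adjacent calls rather than one.
#'
#' @param genome genome sequence.
#' @param min_len minimum duplicated length (default 20000).
#' @param k k-mer size (default 21).
#' @return data.frame `start_1`, `end_1`, `start_2`, `end_2`, `length`,
#'   `identity`, longest first.
#' @export
find_self_duplication <- function(genome, min_len = 20000L, k = 21L) {
  g <- as_genome_vec(genome)[[1L]]
  n <- nchar(g)
  empty <- data.frame(start_1 = integer(0), end_1 = integer(0),
                      start_2 = integer(0), end_2 = integer(0),
                      length = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < min_len) return(empty)
  tg <- kmer_table(g, k)
  cnt <- tg[, .N, by = "canon"]
  tg <- cnt[tg, on = "canon"]
  flagged <- logical(n - k + 1L)
  flagged[tg$pos[tg$N >= 2L]] <- TRUE
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  rows <- list()
  seen <- character(0)
  for (ri in hi) {
    reg_len <- ends[ri] - starts[ri] + k
    if (reg_len < min_len) next
    rs <- starts[ri]; re <- ends[ri] + k - 1L
    rseq <- substr(g, rs, re)
    canon <- min(rseq, revcomp(rseq))
    if (canon %in% seen) next
    seen <- c(seen, canon)
    occ <- locate_exact(g, rseq)
    if (nrow(occ) < 2L) next
    for (j in 2:nrow(occ)) {
      rows[[length(rows) + 1L]] <- data.frame(
        start_1 = occ$start[1L], end_1 = occ$end[1L],
        start_2 = occ$start[j], end_2 = occ$end[j],
        length = reg_len, identity = 1.0, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two genome assemblies end to end
#'
#' Convenience wrapper: builds anchors, then calls inversions and
#' strain-specific insertions.
#'
#' @param genome_a,genome_b genome sequences.
#' @param k anchor k-mer size.
#' @param min_inversion_len,min_indel_len call thresholds.
#' @param elements optional element catalog for insertion labelling.
#' @return list with components `anchors`, `inversions`, `indels`.
#' @export
compare_genomes <- function(genome_a, genome_b, k = 21L,
                            min_inversion_len = 10000L, min_indel_len = 50L,
                            elements = NULL) {
  anchors <- build_anchors(genome_a, genome_b, k = k)
  inversions <- call_inversions(anchors, genome_a, genome_b,
                                min_len = min_inversion_len)
  indels <- call_indels(anchors, genome_a, genome_b,
                        min_len = min_indel_len, elements = elements)
  ## complex regions that are just the anchor shadow of a called inversion
  ## are redundant with the inversion call
  if (nrow(inversions) > 0L && nrow(indels) > 0L) {
    drop <- indels$type == "complex" &
      vapply(seq_len(nrow(indels)), function(i) {
        any(indels$start[i] <= inversions$end_a &
              indels$end[i] >= inversions$start_a)
      }, logical(1))
    indels <- indels[!drop, , drop = FALSE]
  }
  list(anchors = anchors, inversions = inversions, indels = indels)
}
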