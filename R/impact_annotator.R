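#' Classify an insertion difference as intragenic or intergenic
#'
#' The insertion site (a junction before position `site` in the non-carrier
#' genome) is intragenic iff it lies strictly inside a CDS interval:
#' junctions at a CDS's exact boundaries count as intergenic with distance
#' 0, matching how elements "situated before" a gene are described. For
#' intergenic sites the nearest stranded neighbors and their distances are
#' reported. Overlapping CDS at the site are all reported and flagged
#' ambiguous. Deterministic and invariant to feature input order.
#'
#' @param site 1-based position in the non-carrier genome; the inserted
#'   material sits between positions `site - 1` and `site`.
#' @param features feature data.frame (see [read_gff()]); only rows with
#'   `type == "CDS"` (or `"gene"` when no CDS rows exist) are used.
#' @return list `context` (`intragenic`/`intergenic`), `hit_gene` (character
#'   vector, possibly several), `ambiguous`, `upstream_gene`,
#'   `upstream_distance`, `downstream_gene`, `downstream_distance`
#'   (upstream = nearest feature ending before the site, downstream =
#'   nearest feature starting at/after it; NA when absent).
#' @export
classify_insertion <- function(site, features) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) cds <- features[features$type == "gene", , drop = FALSE]
  cds <- cds[order(cds$start, cds$end), , drop = FALSE]
  res <- list(context = "intergenic", hit_gene = NA_character_,
              ambiguous = FALSE,
              upstream_gene = NA_character_, upstream_distance = NA_integer_,
              downstream_gene = NA_character_, downstream_distance = NA_integer_)
  if (nrow(cds) == 0L) return(res)
  ## strictly inside: junction between site-1 and site within [start, end]
  inside <- which(cds$start <= site - 1L & cds$end >= site)
  if (length(inside) > 0L) {
    res$context <- "intragenic"
    res$hit_gene <- cds$gene_id[inside]
    res$ambiguous <- length(inside) > 1L
    return(res)
  }
  up <- which(cds$end < site)
  if (length(up) > 0L) {
    i <- up[which.max(cds$end[up])]
    res$upstream_gene <- cds$gene_id[i]
    res$upstream_distance <- site - cds$end[i] - 1L
  }
  dn <- which(cds$start >= site)
  if (length(dn) > 0L) {
    i <- dn[which.min(cds$start[dn])]
    res$downstream_gene <- cds$gene_id[i]
    res$downstream_distance <- cds$start[i] - site
  }
  res
}

#' Coding products of a CDS interrupted by an insertion
#'
#' Models translation of the interrupted transcript. Product 1 runs from
#' the original start codon to the first in-frame stop at or after the
#' junction; product 2 is the longest ATG-initiated ORF (>= `min_orf_nt`,
#' stop included) in the remainder of the transcript after that stop.
#' Lengths are in amino acids and exclude the stop.
#'
#' @param cds_seq the original CDS (start through stop codon).
#' @param insertion_offset_nt number of CDS nucleotides preceding the
#'   insertion (0 to `nchar(cds_seq)`).
#' @param inserted_seq the inserted sequence.
#' @param min_orf_nt minimum span for product 2 (default 30).
#' @return list `lengths` (aa; product 2 omitted when absent),
#'   `runthrough` (TRUE when product 1 never reaches a stop),
#'   `product1_aa`, `product2_aa` (NA when absent).
#' @export
split_products <- function(cds_seq, insertion_offset_nt, inserted_seq,
                           min_orf_nt = 30L) {
  cds_seq <- normalize_dna(cds_seq)
  inserted_seq <- normalize_dna(inserted_seq)
  n <- nchar(cds_seq)
  stopifnot(insertion_offset_nt >= 0L, insertion_offset_nt <= n)
  transcript <- paste0(substr(cds_seq, 1L, insertion_offset_nt), inserted_seq,
                       substr(cds_seq, insertion_offset_nt + 1L, n))
  tn <- nchar(transcript)
  ncod <- tn %/% 3L
  cod_start <- 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(transcript, cod_start, cod_start + 2L)
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  ## first in-frame stop whose codon is not wholly before the junction
  stops <- stops[cod_start[stops] + 2L > insertion_offset_nt]
  runthrough <- length(stops) == 0L
  if (runthrough) {
    p1 <- ncod
    rest_from <- tn + 1L
  } else {
    p1 <- stops[1L] - 1L
    rest_from <- cod_start[stops[1L]] + 3L
  }
  p2 <- NA_integer_
  if (rest_from <= tn - min_orf_nt + 1L) {
    rest <- substr(transcript, rest_from, tn)
    orfs <- scan_orfs(rest, min_len_nt = min_orf_nt)
    orfs <- orfs[orfs$strand == "+", , drop = FALSE]
    if (nrow(orfs) > 0L) p2 <- max(orfs$span_nt) %/% 3L - 1L
  }
  lens <- c(p1, if (!is.na(p2)) p2)
  list(lengths = as.integer(lens), runthrough = runthrough,
       product1_aa = as.integer(p1), product2_aa = p2)
}

#' Change in CDS length caused by an insertion
#'
#' Re-runs reading-frame extension from the original start codon through
#' the mutated sequence (CDS with the insertion applied, followed by
#' downstream context) until the first in-frame stop; the signed difference
#' to the original CDS span (stop included on both sides) is returned.
#' An insertion wholly outside the CDS (`insertion_offset_nt == nchar(cds_seq)`
#' with an intact stop) yields 0; an insertion that ablates the stop and
#' lets the frame run into downstream sequence yields the gained
#' nucleotides (e.g. +80).
#'
#' @param cds_seq the original CDS (start through stop codon).
#' @param insertion_offset_nt number of CDS nucleotides preceding the
#'   insertion.
#' @param inserted_seq the inserted sequence.
#' @param downstream_seq genomic context following the CDS, scanned when no
#'   stop is found within the mutated CDS (default "").
#' @return signed nucleotide difference (new span - old span); NA when no
#'   stop is reached even within `downstream_seq`.
#' @export
cds_delta <- function(cds_seq, insertion_offset_nt, inserted_seq,
                      downstream_seq = "") {
  cds_seq <- normalize_dna(cds_seq)
  inserted_seq <- normalize_dna(inserted_seq)
  downstream_seq <- normalize_dna(downstream_seq)
  n <- nchar(cds_seq)
  stopifnot(insertion_offset_nt >= 0L, insertion_offset_nt <= n)
  mutated <- paste0(substr(cds_seq, 1L, insertion_offset_nt), inserted_seq,
                    substr(cds_seq, insertion_offset_nt + 1L, n),
                    downstream_seq)
  tn <- nchar(mutated)
  ncod <- tn %/% 3L
  cod_start <- 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(mutated, cod_start, cod_start + 2L)
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(stops) == 0L) return(NA_integer_)
  new_span <- cod_start[stops[1L]] + 2L
  as.integer(new_span - n)
}

#' Annotate the genic impact of insertion differences
#'
#' For each insertion row from [call_indels()], classifies the site against
#' the non-carrier genome's features and, for intragenic hits, computes the
#' split coding products.
#'
#' @param indels data.frame from [call_indels()] (insertion rows are used).
#' @param features_a,features_b feature tables of genomes A and B.
#' @param genome_a,genome_b the genome sequences.
#' @return data.frame, one row per insertion: the indel columns plus
#'   `context`, `hit_gene`, `ambiguous`, `upstream_gene`,
#'   `upstream_distance`, `downstream_gene`, `downstream_distance`,
#'   `product1_aa`, `product2_aa`.
#' @export
annotate_impacts <- function(indels, features_a, features_b,
                             genome_a, genome_b) {
  ins <- indels[indels$type == "insertion", , drop = FALSE]
  a <- as_genome_vec(genome_a)[[1L]]
  b <- as_genome_vec(genome_b)[[1L]]
  rows <- lapply(seq_len(nrow(ins)), function(i) {
    other_feat <- if (ins$carrier[i] == "B") features_a else features_b
    other_seq <- if (ins$carrier[i] == "B") a else b
    cl <- classify_insertion(ins$site_in_other[i], other_feat)
    p1 <- NA_integer_; p2 <- NA_integer_
    if (cl$context == "intragenic" && !cl$ambiguous) {
      cds <- other_feat[other_feat$gene_id %in% cl$hit_gene &
                          other_feat$type %in% c("CDS", "gene"), , drop = FALSE]
      cds <- cds[1L, ]
      if (cds$strand %in% c("+", "-")) {
        cseq <- substr(other_seq, cds$start, cds$end)
        offset <- ins$site_in_other[i] - cds$start
        iseq <- ins$inserted_seq[i]
        if (cds$strand == "-") {
          cseq <- revcomp(cseq)
          offset <- cds$end - ins$site_in_other[i] + 1L
          iseq <- revcomp(iseq)
        }
        sp <- split_products(cseq, offset, iseq)
        p1 <- sp$product1_aa; p2 <- sp$product2_aa
      }
    }
    cbind(ins[i, , drop = FALSE],
          data.frame(context = cl$context,
                     hit_gene = paste(cl$hit_gene, collapse = ","),
                     ambiguous = cl$ambiguous,
                     upstream_gene = cl$upstream_gene,
                     upstream_distance = cl$upstream_distance,
                     downstream_gene = cl$downstream_gene,
                     downstream_distance = cl$downstream_distance,
                     product1_aa = p1, product2_aa = p2,
                     stringsAsFactors = FALSE))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(ins, data.frame(context = character(0), hit_gene = character(0),
                          ambiguous = logical(0),
                          upstream_gene = character(0),
                          upstream_distance = integer(0),
                          downstream_gene = character(0),
                          downstream_distance = integer(0),
                          product1_aa = integer(0), product2_aa = integer(0)))
  rownames(out) <- NULL
  out
}
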