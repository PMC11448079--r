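#' @import data.table
#' @importFrom stats pt rbinom rlnorm runif setNames var
#' @importFrom utils head tail write.table read.delim
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate and normalize a DNA sequence
#'
#' Uppercases `seq` and checks that it contains only A, C, G, T or N.
#' Ambiguity codes other than N are rejected so that downstream exact
#' matching stays well defined.
#'
#' @param seq character scalar.
#' @param what label used in error messages.
#' @return the normalized sequence.
#' @keywords internal
normalize_dna <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop(sprintf("illegal character '%s' in %s (alphabet is A/C/G/T/N)",
                 substr(bad, 1L, 1L), what), call. = FALSE)
  }
  seq
}

#' Read a (multi-)FASTA file of DNA sequences
#'
#' Sequences are uppercased on input; lowercase files are accepted.
#' Characters outside A/C/G/T/N raise a parse error naming the record.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA sequences, in file order.
#'   An empty file yields a zero-length vector.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  out <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path, call. = FALSE)
  for (i in seq_along(out)) {
    out[i] <- normalize_dna(out[i], what = sprintf("record '%s'", ids[i]))
  }
  setNames(out, ids)
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @param width line width, default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq(1L, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Coordinates on disk are 1-based inclusive and are kept 1-based inclusive
#' in memory (the IRanges convention used throughout the package). The `ID`
#' attribute, falling back to `locus_tag`, is exposed as `gene_id`. Records
#' with `end < start` are skipped with a warning rather than aborting the
#' whole file.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `seqid`, `source`, `type`, `start`, `end`,
#'   `score`, `strand`, `phase`, `gene_id`, `product` (NA when absent) and
#'   `attributes` (the raw column 9 text).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty_features())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    stop(sprintf("malformed GFF3 line (expected 9 fields, got %d): %s",
                 nf[nf != 9L][1L],
                 substr(lines[which(nf != 9L)[1L]], 1L, 60L)), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  attr9 <- m[, 9L]
  feat <- data.frame(
    seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
    start = start, end = end, score = m[, 6L], strand = m[, 7L],
    phase = m[, 8L],
    gene_id = gff_attr(attr9, "ID"),
    product = gff_attr(attr9, "product"),
    attributes = attr9,
    stringsAsFactors = FALSE
  )
  lt <- gff_attr(attr9, "locus_tag")
  feat$gene_id[is.na(feat$gene_id)] <- lt[is.na(feat$gene_id)]
  bad <- is.na(start) | is.na(end) | end < start
  if (any(bad)) {
    warning(sprintf("skipping %d GFF record(s) with end < start or unparsable coordinates",
                    sum(bad)), call. = FALSE)
    feat <- feat[!bad, , drop = FALSE]
  }
  rownames(feat) <- NULL
  feat
}

gff_attr <- function(attr9, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(attr9, regexpr(pat, attr9, perl = TRUE))
  out <- rep(NA_character_, length(attr9))
  hit <- grepl(pat, attr9, perl = TRUE)
  out[hit] <- sub(pat, "\\1", regmatches(attr9, regexpr(pat, attr9, perl = TRUE)),
                  perl = TRUE)
  out
}

empty_features <- function() {
  data.frame(seqid = character(0), source = character(0), type = character(0),
             start = integer(0), end = integer(0), score = character(0),
             strand = character(0), phase = character(0),
             gene_id = character(0), product = character(0),
             attributes = character(0), stringsAsFactors = FALSE)
}

#' Write features to a GFF3 file
#'
#' Inverse of [read_gff()]: coordinates are emitted 1-based inclusive.
#' If the input carries an `attributes` column it is written verbatim, so
#' `write_gff(read_gff(x))` round-trips record-for-record.
#'
#' @param features data.frame as returned by [read_gff()], or at least with
#'   `seqid`, `type`, `start`, `end`, `strand` (and optionally `gene_id`,
#'   `product`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) == 0L) return(invisible(path))
  src <- if ("source" %in% names(features)) features$source else "mobilome"
  score <- if ("score" %in% names(features)) features$score else "."
  phase <- if ("phase" %in% names(features)) features$phase else "."
  if (!is.null(features$attributes)) {
    attr9 <- features$attributes
  } else {
    attr9 <- sprintf("ID=%s", features$gene_id)
    if (!is.null(features$product)) {
      has_prod <- !is.na(features$product)
      attr9[has_prod] <- paste0(attr9[has_prod], ";product=",
                                features$product[has_prod])
    }
  }
  writeLines(paste(features$seqid, src, features$type, features$start,
                   features$end, score, features$strand, phase, attr9,
                   sep = "\t"), con)
  invisible(path)
}

#' Reverse complement a DNA sequence
#'
#' N maps to N. The empty string maps to itself.
#'
#' @param seq character scalar over A/C/G/T/N (lowercase accepted).
#' @return reverse complement, uppercase.
#' @export
#' @examples
#' revcomp("GGCTCTTCG")
revcomp <- function(seq) {
  seq <- normalize_dna(seq)
  if (!nzchar(seq)) return(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

## vectorized, no validation; used on k-mer tables where speed matters
revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a CDS with the bacterial genetic code (table 11)
#'
#' Stop codons are rendered `*`. GTG/TTG start codons are translated as
#' written (V/L), not forced to M: start-codon handling is the caller's job.
#'
#' @param seq in-frame coding sequence; length must be divisible by 3.
#' @return protein string.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")
translate_cds <- function(seq) {
  seq <- normalize_dna(seq)
  if (nchar(seq) %% 3L != 0L) {
    stop("CDS length not divisible by 3: ", nchar(seq), call. = FALSE)
  }
  if (!nzchar(seq)) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(seq),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

## fast substring for a single long character scalar
subseq_chr <- function(seq, start, end) {
  substring(seq, start, end)
}
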