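#' Specification for a synthetic genome-pair simulation
#'
#' Returns the default "paper-mimic" specification: a 1-Mb backbone carrying
#' a 187-nt MITE (9-nt TIR seed `GGCTCTTCG`, 8-nt TSDs) at 31 shared + 2
#' mutant-specific copies (so 31 in strain A, 33 in strain B), an ISL3-like
#' 1,215-nt transposase sharing the MITE termini and TSD length, an
#' IS1634-like 1,746-nt element (8 shared + 2 B-specific), an IS200-like
#' 444-nt TIR-less transposase gene (13 shared, 3 A-specific, 1 B-specific:
#' 16 in A, 14 in B), an IS1-like 737-nt element (5 shared + 1 A-specific),
#' and one large inversion in strain B flanked by a 10-kb cassette present
#' in 3 copies. Strain A plays the wildtype, strain B the mutant.
#' Expression effects are multiplicative factors applied to genes downstream
#' of (or hit by) the strain-specific insertions.
#'
#' @param seed integer seed; every random draw in the simulation derives
#'   from it.
#' @param backbone_len backbone length in nucleotides.
#' @param gc GC fraction of the random backbone.
#' @param n_genes number of protein-coding genes written into the backbone.
#' @param inversion_len target inversion length (realized length snaps to
#'   the nearest intergenic site).
#' @param cassette_len flanking-cassette length.
#' @param mite_shared,mite_b_extra MITE copy numbers (shared and
#'   B-specific).
#' @param expression list: `timepoints`, `n_replicates`, `cv`,
#'   `baseline_meanlog`, `baseline_sdlog`.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(seed = 42L, backbone_len = 1000000L, gc = 0.43,
                     n_genes = 200L, inversion_len = 200000L,
                     cassette_len = 10000L, mite_shared = 31L,
                     mite_b_extra = 2L,
                     expression = list(timepoints = c("T1", "T7", "T8", "T10"),
                                       n_replicates = 2L, cv = 0.1,
                                       baseline_meanlog = 3,
                                       baseline_sdlog = 1.2)) {
  stopifnot(backbone_len >= 100000L, gc > 0, gc < 1, n_genes >= 30L)
  structure(list(
    seed = as.integer(seed), backbone_len = as.integer(backbone_len),
    gc = gc, n_genes = as.integer(n_genes),
    inversion_len = as.integer(inversion_len),
    cassette_len = as.integer(cassette_len),
    mite = list(name = "MITE187", length = 187L, tir_seed = "GGCTCTTCG",
                tsd_len = 8L, shared = as.integer(mite_shared),
                b_extra = as.integer(mite_b_extra)),
    elements = list(
      list(name = "ISL3-like", family = "ISL3", length = 1215L,
           tsd_len = 8L, termini = "GGCTCTTCG", orf_span = 1002L,
           shared = 3L, a_extra = 0L, b_extra = 0L),
      list(name = "IS1634-like", family = "IS1634", length = 1746L,
           tsd_len = 6L, termini = NULL, orf_span = 1602L,
           shared = 8L, a_extra = 0L, b_extra = 2L),
      list(name = "IS200-like", family = "IS200/IS605", length = 444L,
           tsd_len = 0L, termini = NULL, orf_span = 402L,
           shared = 13L, a_extra = 3L, b_extra = 1L),
      list(name = "IS1-like", family = "IS1", length = 737L,
           tsd_len = 9L, termini = NULL, orf_span = 702L,
           shared = 5L, a_extra = 1L, b_extra = 0L)),
    expression = expression
  ), class = "sim_spec")
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## ATG + sense codons + stop, total span nt (multiple of 3, >= 9)
random_cds <- function(span_nt) {
  stopifnot(span_nt %% 3L == 0L, span_nt >= 9L)
  paste0("ATG",
         paste(sample(SENSE_CODONS, span_nt / 3L - 2L, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

## element with given termini (5' terminus t, 3' terminus revcomp(t)) and an
## internal ORF of orf_span nt; tirless elements get deliberately
## non-complementary poly-purine/poly-pyrimidine caps
make_element <- function(len, termini = NULL, orf_span = NULL, gc = 0.45,
                         tirless = FALSE) {
  if (tirless) {
    cap5 <- "AAGAAGAAG"; cap3 <- "AAGAAGAAG"
  } else if (!is.null(termini)) {
    cap5 <- termini; cap3 <- revcomp(termini)
  } else {
    cap5 <- random_dna(9L, gc); cap3 <- revcomp(cap5)
  }
  interior_len <- len - nchar(cap5) - nchar(cap3)
  stopifnot(interior_len >= 0L)
  if (!is.null(orf_span)) {
    stopifnot(orf_span %% 3L == 0L, orf_span <= interior_len)
    pad <- interior_len - orf_span
    pad5 <- pad %/% 2L
    interior <- paste0(random_dna(pad5, gc), random_cds(orf_span),
                       random_dna(pad - pad5, gc))
  } else {
    interior <- random_dna(interior_len, gc)
  }
  paste0(cap5, interior, cap3)
}

## MITE: TIR seed + interior + revcomp(seed); regenerated until it carries
## no ORF above the non-autonomy threshold (trivially true at 187 nt) and
## no internal exact copy of the seed
make_mite <- function(len, tir_seed, gc = 0.45) {
  w <- nchar(tir_seed)
  for (i in 1:50) {
    interior <- random_dna(len - 2L * w, gc)
    il <- nchar(interior)
    ## the perfect terminal repeat must be exactly the seed: the first
    ## interior base must not pair with the last one
    if (substr(interior, 1L, 1L) ==
        chartr("ACGT", "TGCA", substr(interior, il, il))) next
    s <- paste0(tir_seed, interior, revcomp(tir_seed))
    inner <- substr(s, 2L, len - 1L)
    if (!grepl(tir_seed, inner, fixed = TRUE) &&
        !grepl(revcomp(tir_seed), inner, fixed = TRUE)) return(s)
  }
  stop("could not build MITE without internal seed copies")
}

## Apply a set of insertions (element + duplicated target site) to a
## sequence. ins: data.frame(site, seq, tsd_len, name, ...). The element is
## placed after `site`, followed by a copy of the tsd_len bases ending at
## `site`. Returns the new sequence, the per-insertion coordinates in the
## new frame, and a shift function for mapping old coordinates.
apply_insertions <- function(seq, ins) {
  ins <- ins[order(ins$site), , drop = FALSE]
  n <- nchar(seq)
  stopifnot(!anyDuplicated(ins$site), all(ins$site >= ins$tsd_len),
            all(ins$site <= n))
  tsd_seq <- substring(seq, ins$site - ins$tsd_len + 1L, ins$site)
  tsd_seq[ins$tsd_len == 0L] <- ""
  block <- paste0(ins$seq, tsd_seq)
  block_len <- nchar(block)
  shift_before <- cumsum(c(0L, head(block_len, -1L)))
  ## assemble: backbone pieces between sites interleaved with blocks
  bounds <- c(0L, ins$site, n)
  pieces <- character(2L * nrow(ins) + 1L)
  for (i in seq_len(nrow(ins) + 1L)) {
    pieces[2L * i - 1L] <- substr(seq, bounds[i] + 1L, bounds[i + 1L])
  }
  pieces[2L * seq_len(nrow(ins))] <- block
  out_seq <- paste(pieces, collapse = "")
  elem_len <- nchar(ins$seq)
  ins$elem_start <- ins$site + shift_before + 1L
  ins$elem_end <- ins$elem_start + elem_len - 1L
  ins$tsd_seq <- tsd_seq
  ## leftmost insertion interval including one TSD copy (what an
  ## anchor-based caller reports)
  ins$diff_start <- ins$elem_start - ins$tsd_len
  ins$diff_end <- ins$elem_end
  sites <- ins$site
  lens <- block_len
  shift_fun <- function(x) {
    x + vapply(x, function(p) sum(lens[sites < p]), numeric(1))
  }
  list(seq = out_seq, ins = ins, shift = shift_fun)
}

shift_features <- function(features, shift_fun) {
  features$start <- as.integer(shift_fun(features$start))
  features$end <- as.integer(shift_fun(features$end))
  features
}

## reverse-complement seq[s..e] in place; remap features and any extra
## coordinate columns that fall inside
invert_segment <- function(seq, s, e) {
  paste0(substr(seq, 1L, s - 1L), revcomp(substr(seq, s, e)),
         substr(seq, e + 1L, nchar(seq)))
}

invert_coords <- function(start, end, strand, s, e) {
  inside <- start >= s & end <= e
  new_start <- ifelse(inside, s + e - end, start)
  new_end <- ifelse(inside, s + e - start, end)
  new_strand <- ifelse(inside, ifelse(strand == "+", "-", "+"), strand)
  list(start = as.integer(new_start), end = as.integer(new_end),
       strand = new_strand, inside = inside)
}

#' Simulate a pair of closely related genomes with planted mobile elements
#'
#' Builds a random backbone with non-overlapping protein-coding genes, then
#' derives two strains from it: shared element copies (inserted with
#' target-site duplication), strain-specific insertions (including
#' designated intragenic hits), and, in strain B, one large inversion
#' bounded by a repeated cassette (one forward copy at the left boundary,
#' one inverted copy at the right boundary, plus one distal copy — the
#' geometry produced by recombination between inverted repeats). All
#' strain-specific differences are planted outside the inversion so that
#' every planted feature has well-defined coordinates in both strains.
#' Deterministic for a fixed seed.
#'
#' @param spec a [sim_spec()].
#' @return list of class `sim_pair`: `genomes` (named character vector
#'   `A`, `B`), `features_a`, `features_b`, `genes` (gene metadata with
#'   designated roles), `library` (IS library data.frame), `elements_all`
#'   (library plus the MITE, for insertion labelling), `mite_seq`,
#'   `cassette_seq`, `truth` (list: `elements`, `diffs`, `inversion`,
#'   `expression`), and `spec`.
#' @export
simulate_genome_pair <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)

  ## --- element sequences -------------------------------------------------
  mite_seq <- make_mite(spec$mite$length, spec$mite$tir_seed, spec$gc)
  elements <- lapply(spec$elements, function(el) {
    el$seq <- make_element(el$length, termini = el$termini,
                           orf_span = el$orf_span, gc = spec$gc,
                           tirless = is.null(el$termini) &&
                             el$tsd_len == 0L)
    el
  })
  cassette_seq <- random_dna(spec$cassette_len, spec$gc)

  ## --- gene layout on the backbone --------------------------------------
  ## genes laid down sequentially with random intergenic gaps; the
  ## remainder of the backbone is gene-free tail
  roles <- designated_roles(spec$n_genes)
  gene_len <- 3L * sample(100:1000, spec$n_genes, replace = TRUE)
  gene_len[roles$idx] <- roles$len
  strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
  strand[roles$idx] <- "+"
  gaps <- sample(300:2200, spec$n_genes, replace = TRUE)
  gaps[roles$idx[roles$role %in% c("cysT", "cysW", "cysA")]] <- 150L
  gaps[roles$idx[roles$role %in% c("lipo", "duf1995", "methyl")]] <- 200L
  gene_start <- cumsum(gaps + c(0L, head(gene_len, -1L))) + 1L
  gene_end <- gene_start + gene_len - 1L
  if (gene_end[spec$n_genes] > spec$backbone_len - 20000L) {
    stop("infeasible packing: genes exceed backbone", call. = FALSE)
  }
  gene_id <- sprintf("g%04d", seq_len(spec$n_genes))
  genes <- data.frame(gene_id = gene_id, start = gene_start, end = gene_end,
                      strand = strand, length = gene_len,
                      role = NA_character_, stringsAsFactors = FALSE)
  genes$role[roles$idx] <- roles$role
  genes$product <- ifelse(is.na(genes$role), "hypothetical protein",
                          roles$product[match(genes$role, roles$role)])

  ## --- backbone with genes written in -----------------------------------
  pieces <- character(2L * spec$n_genes + 1L)
  prev_end <- 0L
  for (i in seq_len(spec$n_genes)) {
    pieces[2L * i - 1L] <- random_dna(gene_start[i] - prev_end - 1L, spec$gc)
    cds <- random_cds(gene_len[i])
    pieces[2L * i] <- if (strand[i] == "+") cds else revcomp(cds)
    prev_end <- gene_end[i]
  }
  pieces[2L * spec$n_genes + 1L] <-
    random_dna(spec$backbone_len - prev_end, spec$gc)
  g0 <- paste(pieces, collapse = "")

  ## --- choose insertion sites -------------------------------------------
  ## inversion zone: from the gap after gene iz1 to the first gap past
  ## inversion_len; designated genes all lie beyond it
  with_inversion <- spec$inversion_len > 0L
  if (with_inversion) {
    iz1 <- 30L
    p1 <- gene_end[iz1] + (gene_start[iz1 + 1L] - gene_end[iz1]) %/% 2L
    iz2 <- min(which(gene_end > p1 + spec$inversion_len))
    if (is.infinite(iz2) || iz2 >= min(roles$idx)) {
      stop("infeasible packing: inversion does not fit before designated genes",
           call. = FALSE)
    }
    p2 <- gene_end[iz2] + (gene_start[iz2 + 1L] - gene_end[iz2]) %/% 2L
    ## boundary guards: the maximal inverted interval must stop exactly at
    ## the cassette pair, so the base outside each cassette must not pair
    ## with its counterpart (outer guard), and the first/last bases of the
    ## inverted segment must not pair either (inner guard)
    comp1 <- function(x) chartr("ACGT", "TGCA", x)
    while (substr(g0, p1, p1) == comp1(substr(g0, p2 + 1L, p2 + 1L)) ||
           substr(g0, p1 + 1L, p1 + 1L) == comp1(substr(g0, p2, p2))) {
      p2 <- p2 + 1L
    }
  } else {
    p1 <- -1000L; p2 <- -1000L
  }

  site_env <- new.env()
  site_env$taken <- c(p1, p2)
  intergenic_site <- function(exclude_zone = TRUE) {
    for (try in 1:2000) {
      i <- sample(spec$n_genes, 1L)
      lo <- gene_end[i] + 150L
      hi <- if (i < spec$n_genes) gene_start[i + 1L] - 150L else
        spec$backbone_len - 200L
      if (hi - lo < 30L) next
      s <- sample(lo:hi, 1L)
      if (exclude_zone && s >= p1 - 100L && s <= p2 + 100L) next
      if (any(abs(site_env$taken - s) < 100L)) next
      site_env$taken <- c(site_env$taken, s)
      return(s)
    }
    stop("infeasible packing: could not place an intergenic site",
         call. = FALSE)
  }
  ## site guards: (i) detect_tsd must report exactly tsd_len, so the base
  ## just outside the would-be TSD must differ from the base just after the
  ## site; (ii) no microhomology between the element termini and the
  ## flanking bases, so the leftmost-normalized insertion interval an
  ## anchor-based caller reports coincides with the planted one
  tsd_ok <- function(s, tsd, elem) {
    el <- nchar(elem)
    (tsd == 0L ||
       substr(g0, s - tsd, s - tsd) != substr(g0, s + 1L, s + 1L)) &&
      substr(g0, s - tsd, s - tsd) != substr(elem, el, el) &&
      substr(g0, s + 1L, s + 1L) != substr(elem, 1L, 1L)
  }
  guarded_site <- function(tsd, elem, exclude_zone = TRUE) {
    for (try in 1:200) {
      s <- intergenic_site(exclude_zone)
      if (tsd_ok(s, tsd, elem)) return(s)
      site_env$taken <- setdiff(site_env$taken, s)
    }
    stop("could not satisfy TSD guard", call. = FALSE)
  }
  ## intragenic site at a given CDS offset (in-frame steps if nudged)
  intragenic_site <- function(role, offset, tsd, elem) {
    i <- which(genes$role %in% role)[1L]
    s <- gene_start[i] + offset - 1L
    for (nudge in c(0L, 3L, -3L, 6L, -6L, 9L, -9L)) {
      if (tsd_ok(s + nudge, tsd, elem) &&
          !any(abs(site_env$taken - (s + nudge)) < 30L)) {
        site_env$taken <- c(site_env$taken, s + nudge)
        return(s + nudge)
      }
    }
    stop("could not satisfy TSD guard in gene ", role, call. = FALSE)
  }

  ins_rows <- list()
  add_ins <- function(name, seq, tsd, site, scope, context, target = NA) {
    ins_rows[[length(ins_rows) + 1L]] <<- data.frame(
      name = name, seq = seq, tsd_len = tsd, site = site, scope = scope,
      context = context, target_gene = target, stringsAsFactors = FALSE)
  }
  ## cassettes (shared): left forward, right inverted, one distal copy
  if (with_inversion) {
    add_ins("cassette", cassette_seq, 0L, p1, "shared", "cassette_left")
    add_ins("cassette", revcomp(cassette_seq), 0L, p2, "shared",
            "cassette_right")
    add_ins("cassette", cassette_seq, 0L, intergenic_site(), "shared",
            "cassette_distal")
  }
  ## shared elements
  for (i in seq_len(spec$mite$shared)) {
    add_ins(spec$mite$name, mite_seq, spec$mite$tsd_len,
            guarded_site(spec$mite$tsd_len, mite_seq, exclude_zone = FALSE),
            "shared", "intergenic")
  }
  for (el in elements) {
    for (i in seq_len(el$shared)) {
      add_ins(el$name, el$seq, el$tsd_len,
              guarded_site(el$tsd_len, el$seq, exclude_zone = FALSE),
              "shared", "intergenic")
    }
  }
  ## strain-specific insertions (all outside the inversion zone)
  ## B-specific MITEs: one in the sbp-like gene at CDS offset 858, one in
  ## the livG-like gene
  mite_b_sites <- list(
    list(context = "intragenic", target = "sbp",
         site = intragenic_site("sbp", 858L, spec$mite$tsd_len, mite_seq)),
    list(context = "intragenic", target = "livG",
         site = intragenic_site("livG", 600L, spec$mite$tsd_len, mite_seq)))
  for (i in seq_len(spec$mite$b_extra)) {
    slot <- if (i <= length(mite_b_sites)) mite_b_sites[[i]] else
      list(context = "intergenic", target = NA,
           site = guarded_site(spec$mite$tsd_len, mite_seq))
    tgt <- slot$target
    add_ins(spec$mite$name, mite_seq, spec$mite$tsd_len, slot$site,
            "b_only", slot$context,
            if (!is.na(tgt)) genes$gene_id[which(genes$role == tgt)[1L]] else NA)
  }
  specific_plan <- list(
    "IS1634-like" = list(
      b = list(list(context = "intergenic_cluster", before = "lipo"),
               list(context = "intergenic")),
      a = list()),
    "IS200-like" = list(
      b = list(list(context = "intragenic", target = "slc")),
      a = list(list(context = "intragenic", target = "trkH"),
               list(context = "intragenic", target = "glyco"),
               list(context = "intergenic"))),
    "IS1-like" = list(
      b = list(),
      a = list(list(context = "intergenic_before", before = "unchar"))),
    "ISL3-like" = list(a = list(), b = list()))
  for (el in elements) {
    plan <- specific_plan[[el$name]]
    for (scope in c("a", "b")) {
      want <- if (scope == "a") el$a_extra else el$b_extra
      slots <- plan[[scope]]
      for (i in seq_len(want)) {
        slot <- if (i <= length(slots)) slots[[i]] else
          list(context = "intergenic")
        if (slot$context == "intragenic") {
          idx <- which(genes$role == slot$target)[1L]
          off <- max(150L, 3L * (genes$length[idx] %/% 6L))
          s <- intragenic_site(slot$target, off, el$tsd_len, el$seq)
          add_ins(el$name, el$seq, el$tsd_len, s, paste0(scope, "_only"),
                  "intragenic", genes$gene_id[idx])
        } else if (slot$context %in% c("intergenic_cluster",
                                       "intergenic_before")) {
          idx <- which(genes$role == slot$before)[1L]
          ## between the previous gene and this one, upstream of it
          s <- genes$start[idx] - 120L
          while (!tsd_ok(s, el$tsd_len, el$seq) ||
                 any(abs(site_env$taken - s) < 30L)) s <- s - 1L
          site_env$taken <- c(site_env$taken, s)
          add_ins(el$name, el$seq, el$tsd_len, s, paste0(scope, "_only"),
                  "intergenic", genes$gene_id[idx])
        } else {
          add_ins(el$name, el$seq, el$tsd_len,
                  guarded_site(el$tsd_len, el$seq),
                  paste0(scope, "_only"), "intergenic")
        }
      }
    }
  }
  ins <- do.call(rbind, ins_rows)

  ## --- build the two strains ---------------------------------------------
  feat0 <- data.frame(seqid = NA_character_, source = "sim",
                      type = "CDS", start = genes$start, end = genes$end,
                      score = ".", strand = genes$strand, phase = "0",
                      gene_id = genes$gene_id, product = genes$product,
                      stringsAsFactors = FALSE)
  feat0$attributes <- sprintf("ID=%s;product=%s", feat0$gene_id, feat0$product)

  build_strain <- function(scopes) {
    sel <- ins[ins$scope %in% scopes, , drop = FALSE]
    ap <- apply_insertions(g0, sel)
    list(seq = ap$seq, ins = ap$ins, shift = ap$shift,
         features = shift_features(feat0, ap$shift))
  }
  A <- build_strain(c("shared", "a_only"))
  B <- build_strain(c("shared", "b_only"))

  ## inversion in B between the boundary cassettes
  if (with_inversion) {
    cassB <- B$ins[B$ins$context %in% c("cassette_left", "cassette_right"), ]
    inv_s <- cassB$elem_end[cassB$context == "cassette_left"] + 1L
    inv_e <- cassB$elem_start[cassB$context == "cassette_right"] - 1L
    b_seq <- invert_segment(B$seq, inv_s, inv_e)
    fb <- invert_coords(B$features$start, B$features$end, B$features$strand,
                        inv_s, inv_e)
    B$features$start <- fb$start; B$features$end <- fb$end
    B$features$strand <- fb$strand
    B$features <- B$features[order(B$features$start), , drop = FALSE]
    eb <- invert_coords(B$ins$elem_start, B$ins$elem_end,
                        rep("+", nrow(B$ins)), inv_s, inv_e)
    B$ins$elem_start <- eb$start; B$ins$elem_end <- eb$end
    B$ins$strand <- eb$strand
  } else {
    b_seq <- B$seq
    B$ins$strand <- if (nrow(B$ins)) "+" else character(0)
  }
  A$ins$strand <- if (nrow(A$ins)) "+" else character(0)

  A$features$seqid <- "A"; B$features$seqid <- "B"

  ## --- truth tables -------------------------------------------------------
  truth_elements <- rbind(
    data.frame(genome = "A", name = A$ins$name, start = A$ins$elem_start,
               end = A$ins$elem_end, strand = A$ins$strand,
               tsd_len = A$ins$tsd_len, tsd_seq = A$ins$tsd_seq,
               scope = A$ins$scope, context = A$ins$context,
               stringsAsFactors = FALSE),
    data.frame(genome = "B", name = B$ins$name, start = B$ins$elem_start,
               end = B$ins$elem_end, strand = B$ins$strand,
               tsd_len = B$ins$tsd_len, tsd_seq = B$ins$tsd_seq,
               scope = B$ins$scope, context = B$ins$context,
               stringsAsFactors = FALSE))

  ## strain-specific insertion diffs with carrier coordinates and the
  ## leftmost site in the other strain
  diff_rows <- list()
  for (carrier in c("A", "B")) {
    own <- if (carrier == "A") A else B
    other <- if (carrier == "A") B else A
    sp <- own$ins[own$ins$scope == paste0(tolower(carrier), "_only"), ,
                  drop = FALSE]
    if (nrow(sp) == 0L) next
    ## leftmost junction in g0 frame is site - tsd_len + 1; sites are
    ## spaced so no other-strain insertion falls inside a TSD
    site_other <- as.integer(other$shift(sp$site - sp$tsd_len + 1L))
    diff_rows[[length(diff_rows) + 1L]] <- data.frame(
      carrier = carrier, name = sp$name,
      start = sp$diff_start, end = sp$diff_end,
      length = sp$diff_end - sp$diff_start + 1L,
      site_in_other = site_other, context = sp$context,
      target_gene = sp$target_gene, stringsAsFactors = FALSE)
  }
  truth_diffs <- do.call(rbind, diff_rows)

  ## the planted inverted interval under the maximal convention: it runs
  ## from the start of the left boundary cassette to the end of the right
  ## one (the whole segment that maps onto its own reverse complement)
  if (with_inversion) {
    cassA <- A$ins[A$ins$context %in% c("cassette_left", "cassette_right"), ]
    truth_inversion <- data.frame(
      start_a = cassA$elem_start[cassA$context == "cassette_left"],
      end_a = cassA$elem_end[cassA$context == "cassette_right"],
      start_b = cassB$elem_start[cassB$context == "cassette_left"],
      end_b = cassB$elem_end[cassB$context == "cassette_right"],
      cassette_len = spec$cassette_len, cassette_copies = 3L,
      stringsAsFactors = FALSE)
  } else {
    truth_inversion <- data.frame(start_a = integer(0), end_a = integer(0),
                                  start_b = integer(0), end_b = integer(0),
                                  cassette_len = integer(0),
                                  cassette_copies = integer(0),
                                  stringsAsFactors = FALSE)
  }

  ## expression effects mirroring the planted differences: the interrupted
  ## sulfate cluster derepressed in B, genes downstream of the B-specific
  ## IS1634 silenced in B, and the pair behind the A-specific IS1 more
  ## highly expressed in B (where the element is absent)
  eff <- function(role, factor) {
    idx <- which(genes$role == role)
    if (length(idx) == 0L) return(NULL)
    data.frame(gene_id = genes$gene_id[idx[1L]], strain = "B",
               factor = factor, stringsAsFactors = FALSE)
  }
  truth_expr <- do.call(rbind, c(
    lapply(c("sbp", "cysT", "cysW", "cysA"), eff, factor = 8),
    lapply(c("lipo", "duf1995", "methyl"), eff, factor = 0.1),
    lapply(c("unchar", "mbl"), eff, factor = 10)))

  lib <- data.frame(
    name = vapply(elements, function(e) e$name, character(1)),
    family = vapply(elements, function(e) e$family, character(1)),
    seq = vapply(elements, function(e) e$seq, character(1)),
    stringsAsFactors = FALSE)
  lib$length <- nchar(lib$seq)
  elements_all <- rbind(lib, data.frame(name = spec$mite$name, family = "MITE",
                                        seq = mite_seq,
                                        length = nchar(mite_seq),
                                        stringsAsFactors = FALSE))

  structure(list(
    genomes = c(A = A$seq, B = b_seq),
    features_a = A$features, features_b = B$features,
    genes = genes, library = lib, elements_all = elements_all,
    mite_seq = mite_seq, cassette_seq = cassette_seq,
    truth = list(elements = truth_elements, diffs = truth_diffs,
                 inversion = truth_inversion, expression = truth_expr),
    spec = spec
  ), class = "sim_pair")
}

## gene indices and metadata for the designated target genes; indices are
## placed past the inversion zone
designated_roles <- function(n_genes) {
  idx <- c(sbp = 110L, cysT = 111L, cysW = 112L, cysA = 113L,
           livG = 120L, flavo = 130L, lipo = 131L, duf1995 = 132L,
           methyl = 133L, unchar = 140L, mbl = 141L,
           trkH = 150L, glyco = 152L, slc = 154L)
  stopifnot(n_genes > max(idx))
  data.frame(
    idx = unname(idx), role = names(idx),
    len = c(1044L, 831L, 792L, 1038L, 900L, 1206L, 522L, 825L, 903L,
            660L, 846L, 1455L, 1101L, 1284L),
    product = c("sulfate-binding protein", "sulfate ABC transporter permease CysT",
                "sulfate ABC transporter permease CysW",
                "sulfate ABC transporter ATP-binding protein CysA",
                "branched-chain amino acid ABC transporter ATP-binding protein LivG",
                "diflavin flavoprotein", "putative lipoprotein",
                "DUF1995 domain-containing protein",
                "adenine-specific SAM-dependent methyltransferase",
                "uncharacterized protein", "MBL-fold metallo-hydrolase",
                "potassium uptake protein TrkH", "glycosyltransferase",
                "SLC superfamily permease"),
    stringsAsFactors = FALSE)
}

#' Simulate a replicate expression table for a genome pair
#'
#' Each gene draws a lognormal baseline TPM shared by both strains; genes
#' with planted effects have their mean multiplied by the effect factor in
#' the affected strain (all timepoints); replicates add multiplicative
#' lognormal noise with the given coefficient of variation; finally every
#' sample is renormalized to sum to one million.
#'
#' @param sim a `sim_pair` from [simulate_genome_pair()], or a character
#'   vector of gene ids.
#' @param effects data.frame `gene_id`, `strain`, `factor`; defaults to the
#'   simulation's planted expression truth (none for a bare gene-id vector).
#' @param seed seed for the expression draws (defaults to the simulation
#'   seed + 1).
#' @param timepoints,n_replicates,cv,baseline_meanlog,baseline_sdlog
#'   sampling parameters; default from the simulation spec.
#' @return long-format data.frame `gene_id`, `strain`, `timepoint`,
#'   `replicate`, `tpm`.
#' @export
simulate_expression <- function(sim, effects = NULL, seed = NULL,
                                timepoints = NULL, n_replicates = NULL,
                                cv = NULL, baseline_meanlog = NULL,
                                baseline_sdlog = NULL) {
  if (inherits(sim, "sim_pair")) {
    gene_ids <- sim$genes$gene_id
    if (is.null(effects)) effects <- sim$truth$expression
    ex <- sim$spec$expression
    if (is.null(seed)) seed <- sim$spec$seed + 1L
  } else {
    gene_ids <- as.character(sim)
    ex <- list(timepoints = c("T1", "T7", "T8", "T10"), n_replicates = 2L,
               cv = 0.1, baseline_meanlog = 3, baseline_sdlog = 1.2)
    if (is.null(seed)) stop("seed required when sim is a gene-id vector",
                            call. = FALSE)
  }
  timepoints <- timepoints %||% ex$timepoints
  n_replicates <- n_replicates %||% ex$n_replicates
  cv <- cv %||% ex$cv
  baseline_meanlog <- baseline_meanlog %||% ex$baseline_meanlog
  baseline_sdlog <- baseline_sdlog %||% ex$baseline_sdlog
  set.seed(seed)
  ng <- length(gene_ids)
  base <- rlnorm(ng, baseline_meanlog, baseline_sdlog)
  sdlog_noise <- sqrt(log(1 + cv^2))
  fac <- matrix(1, nrow = ng, ncol = 2,
                dimnames = list(gene_ids, c("A", "B")))
  if (!is.null(effects) && nrow(effects) > 0L) {
    for (i in seq_len(nrow(effects))) {
      fac[effects$gene_id[i], effects$strain[i]] <-
        fac[effects$gene_id[i], effects$strain[i]] * effects$factor[i]
    }
  }
  rows <- list()
  for (strain in c("A", "B")) {
    for (tp in timepoints) {
      for (rep_ in seq_len(n_replicates)) {
        vals <- base * fac[, strain] *
          rlnorm(ng, -sdlog_noise^2 / 2, sdlog_noise)
        vals <- vals / sum(vals) * 1e6
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_ids, strain = strain, timepoint = tp,
          replicate = rep_, tpm = vals, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated genome pair to disk
#'
#' Emits FASTA and GFF3 per strain, the IS library FASTA, the truth tables
#' (TSV + JSON) and, when requested, a simulated expression TSV.
#'
#' @param sim `sim_pair` object.
#' @param dir output directory (created if needed).
#' @param expression logical: also write `expression.tsv`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, expression = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(A = unname(sim$genomes["A"])), file.path(dir, "genome_A.fasta"))
  write_fasta(c(B = unname(sim$genomes["B"])), file.path(dir, "genome_B.fasta"))
  write_gff(sim$features_a, file.path(dir, "genome_A.gff3"))
  write_gff(sim$features_b, file.path(dir, "genome_B.gff3"))
  write_fasta(setNames(sim$library$seq,
                       paste(sim$library$name, sim$library$family, sep = "|")),
              file.path(dir, "is_library.fasta"))
  for (nm in c("elements", "diffs", "inversion", "expression")) {
    write.table(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (expression) {
    write.table(simulate_expression(sim), file.path(dir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
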