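#' Run the full comparative-mobilome pipeline
#'
#' Orchestrates catalog -> MITE discovery -> genome differencing -> impact
#' annotation -> expression overlay -> in-silico PCR over two genomes, and
#' writes versioned outputs plus a machine-readable summary and MANIFEST
#' into `out_dir`. Stages lacking their inputs (no library, no expression
#' table, no primers) are skipped with a log message; the remaining stages
#' still run. Reruns with the same config are byte-identical.
#'
#' @param config list with entries:
#'   \describe{
#'     \item{genome_a, genome_b}{FASTA paths or named character sequences.}
#'     \item{gff_a, gff_b}{GFF3 paths or feature data.frames (optional).}
#'     \item{library}{IS library FASTA path or data.frame (optional).}
#'     \item{expression}{expression TSV path or data.frame (optional).}
#'     \item{primers}{list(fwd=, rev=) (optional).}
#'     \item{min_identity, min_coverage}{catalog thresholds (0.90, 0.5).}
#'     \item{k}{anchor k-mer size (21).}
#'     \item{min_inversion_len, min_indel_len}{diff thresholds (10000, 50).}
#'     \item{mite_min_len, mite_max_len, mite_min_copies}{repeat mining
#'       window (80, 500, 5).}
#'     \item{fc_threshold, q_threshold}{DE thresholds (2, 0.05).}
#'     \item{strain_pair}{strains contrasted in the expression table
#'       (c("A","B")).}
#'   }
#' @param out_dir output directory.
#' @return (invisibly) list with `catalog_a`, `catalog_b`, `mites`, `diff`,
#'   `impacts`, `de`, `overlay`, `pcr`, `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(list(
    min_identity = 0.90, min_coverage = 0.5, k = 21L,
    min_inversion_len = 10000L, min_indel_len = 50L,
    mite_min_len = 80L, mite_max_len = 500L, mite_min_copies = 5L,
    fc_threshold = 2, q_threshold = 0.05, strain_pair = c("A", "B")),
    config)
  logmsg <- function(...) message("[mobilome] ", sprintf(...))
  load_genome <- function(x, id) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      g <- read_fasta(x)
      setNames(paste(g, collapse = ""), id)
    } else setNames(as_genome_vec(x)[[1L]], id)
  }
  ga <- load_genome(cfg$genome_a, "A")
  gb <- load_genome(cfg$genome_b, "B")
  load_feat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_gff(x) else x
  }
  fa <- load_feat(cfg$gff_a); fb <- load_feat(cfg$gff_b)
  lib <- if (is.null(cfg$library)) NULL else if (is.character(cfg$library))
    read_element_library(cfg$library) else cfg$library

  res <- list()
  ## 1. element catalog
  if (!is.null(lib)) {
    logmsg("cataloguing %d library elements", nrow(lib))
    res$catalog_a <- dedupe_overlaps(match_library(ga, lib,
                                                   cfg$min_identity,
                                                   cfg$min_coverage))
    res$catalog_b <- dedupe_overlaps(match_library(gb, lib,
                                                   cfg$min_identity,
                                                   cfg$min_coverage))
    for (s in c("a", "b")) {
      h <- res[[paste0("catalog_", s)]]
      write.table(h, file.path(out_dir, sprintf("catalog_%s.tsv", s)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_hits_gff(h, file.path(out_dir, sprintf("catalog_%s.gff3", s)))
    }
  } else logmsg("no element library; catalog stage skipped")

  ## 2. MITE discovery
  logmsg("mining high-copy repeats")
  hits_all <- rbind(res$catalog_a, res$catalog_b)
  res$mites <- discover_mites(c(ga, gb), element_hits = hits_all,
                              min_len = cfg$mite_min_len,
                              max_len = cfg$mite_max_len,
                              min_copies = cfg$mite_min_copies, k = cfg$k)
  if (length(res$mites) > 0L) {
    ms <- mite_summary(res$mites)
    write.table(ms, file.path(out_dir, "mite_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fasta(setNames(ms$seq, sprintf("candidate_%03d", seq_len(nrow(ms)))),
                file.path(out_dir, "mite_candidates.fasta"))
  }

  ## 3. genome differencing
  logmsg("anchoring genomes (k=%d)", cfg$k)
  elements_cat <- local({
    e <- lib
    mseqs <- vapply(res$mites, function(x) x$seq, character(1))
    if (length(mseqs) > 0L) {
      e <- rbind(if (is.null(e)) NULL else e[, c("name", "seq")],
                 data.frame(name = sprintf("repeat_%03d", seq_along(mseqs)),
                            seq = mseqs, stringsAsFactors = FALSE))
    }
    if (is.null(e)) NULL else e
  })
  res$diff <- compare_genomes(ga, gb, k = cfg$k,
                              min_inversion_len = cfg$min_inversion_len,
                              min_indel_len = cfg$min_indel_len,
                              elements = elements_cat)
  write.table(res$diff$inversions, file.path(out_dir, "inversions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$diff$indels, file.path(out_dir, "indels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedpe(res$diff$inversions, file.path(out_dir, "inversions.bedpe"))
  write_indels_gff(res$diff$indels, file.path(out_dir, "indels.gff3"))

  ## 4. impact annotation
  if (!is.null(fa) && !is.null(fb)) {
    res$impacts <- annotate_impacts(res$diff$indels, fa, fb, ga, gb)
    write.table(res$impacts, file.path(out_dir, "impacts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else logmsg("no annotations; impact stage skipped")

  ## 5. expression overlay
  expr <- if (is.null(cfg$expression)) NULL else if (is.character(cfg$expression))
    read_expression_table(cfg$expression) else cfg$expression
  if (!is.null(expr) && !is.null(res$impacts)) {
    res$de <- flag_de(expr, cfg$strain_pair, fc_threshold = cfg$fc_threshold,
                      q_threshold = cfg$q_threshold)
    write.table(res$de, file.path(out_dir, "de_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    feats_for_overlay <- fa
    res$overlay <- overlay_expression(res$impacts, res$de, feats_for_overlay)
    write.table(res$overlay, file.path(out_dir, "overlay.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else logmsg("no expression table; overlay stage skipped")

  ## 6. in-silico PCR
  if (!is.null(cfg$primers)) {
    res$pcr <- rbind(
      cbind(genome = "A", predict_amplicons(ga, cfg$primers$fwd,
                                            cfg$primers$rev)),
      cbind(genome = "B", predict_amplicons(gb, cfg$primers$fwd,
                                            cfg$primers$rev)))
    write.table(res$pcr, file.path(out_dir, "pcr_products.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## summary + manifest
  count_by <- function(h) {
    if (is.null(h) || nrow(h) == 0L) return(list())
    as.list(table(h$family))
  }
  res$summary <- list(
    genome_lengths = list(A = nchar(ga[[1L]]), B = nchar(gb[[1L]])),
    element_family_hits = list(A = count_by(res$catalog_a),
                               B = count_by(res$catalog_b)),
    mite_verdicts = if (length(res$mites))
      vapply(res$mites, function(x) x$verdict, character(1)) else character(0),
    n_inversions = nrow(res$diff$inversions),
    n_insertions = sum(res$diff$indels$type == "insertion"),
    n_overlay_rows = if (is.null(res$overlay)) 0L else nrow(res$overlay))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- c(
    sprintf("mobilome version: %s",
            as.character(utils::packageVersion("mobilome"))),
    "status: complete",
    sprintf("config.%s: %s", names(cfg),
            vapply(cfg, function(x) paste(format(x), collapse = ","),
                   character(1))))
  writeLines(manifest, file.path(out_dir, "MANIFEST"))
  invisible(res)
}

write_bedpe <- function(inversions, path) {
  if (nrow(inversions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("A\t%d\t%d\tB\t%d\t%d\tinversion_%d\t.\t+\t-",
                   inversions$start_a - 1L, inversions$end_a,
                   inversions$start_b - 1L, inversions$end_b,
                   seq_len(nrow(inversions)))
  writeLines(lines, path)
  invisible(path)
}

write_indels_gff <- function(indels, path) {
  ins <- indels[indels$type == "insertion", , drop = FALSE]
  feat <- data.frame(
    seqid = ifelse(ins$carrier == "B", "B", "A"),
    source = "mobilome", type = "insertion_site",
    start = ins$start, end = ins$end, score = ".", strand = "+", phase = ".",
    attributes = sprintf("ID=ins_%d;matched_element=%s;site_in_other=%d",
                         seq_len(nrow(ins)), ins$matched_element,
                         ins$site_in_other),
    stringsAsFactors = FALSE)
  write_gff(feat, path)
}
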