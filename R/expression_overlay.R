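#' TPM from raw counts
#'
#' `TPM_i = (c_i / l_i) / sum_j (c_j / l_j) * 1e6`: the per-gene read rate
#' scaled so rates sum to one million within the sample.
#'
#' @param counts non-negative counts per gene.
#' @param lengths gene lengths in nucleotides, all positive.
#' @return numeric TPM vector (named like `counts`). All-zero counts return
#'   all-zero TPM with a warning.
#' @export
tpm_from_counts <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) {
    warning("all counts zero; returning all-zero TPM", call. = FALSE)
    return(setNames(rep(0, length(counts)), names(counts)))
  }
  setNames(rate / tot * 1e6, names(counts))
}

#' Welch's unequal-variance t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-sided p
#' from the t distribution. Zero-variance groups are handled with a
#' variance floor `eps = var_floor_frac * mean(c(a, b))^2` instead of being
#' dropped (duplicate TPM values tie frequently at n = 2); two
#' zero-variance groups with equal means give p = 1.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @param var_floor_frac relative variance floor (default 1e-8).
#' @return list `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t(c(10, 12), c(20, 22))  # t = -7.071, df = 2
welch_t <- function(a, b, var_floor_frac = 1e-8) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  }
  eps <- var_floor_frac * mean(c(a, b))^2
  va <- max(va, eps); vb <- max(vb, eps)
  sa <- va / length(a); sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1L) + sb^2 / (length(b) - 1L))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## vectorized Welch over matrix rows (genes x replicates)
welch_t_rows <- function(ma, mb, var_floor_frac = 1e-8) {
  na <- ncol(ma); nb <- ncol(mb)
  mu_a <- rowMeans(ma); mu_b <- rowMeans(mb)
  va <- apply(ma, 1L, var); vb <- apply(mb, 1L, var)
  eps <- var_floor_frac * ((mu_a + mu_b) / 2)^2
  tied <- va == 0 & vb == 0 & mu_a == mu_b
  va <- pmax(va, eps); vb <- pmax(vb, eps)
  sa <- va / na; sb <- vb / nb
  t <- (mu_a - mu_b) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1L) + sb^2 / (nb - 1L))
  p <- 2 * pt(-abs(t), df)
  t[tied] <- 0; p[tied] <- 1; df[tied] <- na + nb - 2
  ## both groups all-zero (gene absent in both): no evidence either way
  zero <- mu_a == 0 & mu_b == 0 & va == 0 & vb == 0
  t[zero] <- 0; p[zero] <- 1
  list(t = t, df = df, p = p, mean_a = mu_a, mean_b = mu_b)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; `NA`/`NaN` entries are excluded from the
#' family size and returned as `NA`.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  stopifnot(all(p[ok] >= 0 & p[ok] <= 1))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Read a long-format expression table
#'
#' Expected TSV columns: `gene_id`, `strain`, `timepoint`, `replicate`,
#' `tpm`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "strain", "timepoint", "replicate", "tpm")
  if (!all(need %in% names(tab))) {
    stop("expression table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Per-gene differential-expression flags between two strains
#'
#' For every gene and timepoint, a Welch t-test contrasts the replicate TPM
#' values of the two strains; fold change is computed on replicate means
#' with a pseudocount of 1 TPM; p-values are Benjamini-Hochberg adjusted
#' within each timepoint (each timepoint is a separate testing family).
#' A gene is significant at a timepoint when its fold change (larger of the
#' two ratios) is at least `fc_threshold` AND its q-value is at most
#' `q_threshold` — both thresholds inclusive. Genes lacking two replicates
#' in either strain at a timepoint are skipped with a message.
#'
#' @param table long-format expression data.frame (see
#'   [read_expression_table()]).
#' @param strain_pair character of length 2: reference strain A, contrast
#'   strain B; `log2_fc` is `log2((mean_B + 1) / (mean_A + 1))`.
#' @param timepoints timepoints to test (default: all in the table).
#' @param fc_threshold fold-change threshold (default 2).
#' @param q_threshold FDR threshold (default 0.05).
#' @param var_floor_frac see [welch_t()].
#' @return data.frame `gene_id`, `timepoint`, `mean_a`, `mean_b`,
#'   `log2_fc`, `t`, `df`, `p`, `q`, `significant`.
#' @export
flag_de <- function(table, strain_pair, timepoints = NULL, fc_threshold = 2,
                    q_threshold = 0.05, var_floor_frac = 1e-8) {
  stopifnot(length(strain_pair) == 2L)
  tab <- table[table$strain %in% strain_pair, , drop = FALSE]
  if (is.null(timepoints)) timepoints <- sort(unique(tab$timepoint))
  out <- list()
  for (tp in timepoints) {
    tt <- tab[tab$timepoint == tp, , drop = FALSE]
    dt <- data.table::as.data.table(tt)
    wide <- dt[, .(n = .N, vals = list(tpm)), by = .(gene_id, strain)]
    cnt <- wide[, .(ok = sum(n >= 2L) == 2L && .N == 2L), by = "gene_id"]
    skip <- cnt$gene_id[!cnt$ok]
    if (length(skip) > 0L) {
      message(sprintf("timepoint %s: skipping %d gene(s) with missing replicates",
                      tp, length(skip)))
    }
    genes <- cnt$gene_id[cnt$ok]
    if (length(genes) == 0L) next
    ga <- dt[strain == strain_pair[1L] & gene_id %in% genes]
    gb <- dt[strain == strain_pair[2L] & gene_id %in% genes]
    data.table::setorder(ga, gene_id, replicate)
    data.table::setorder(gb, gene_id, replicate)
    na <- ga[, .N, by = "gene_id"]$N
    nb <- gb[, .N, by = "gene_id"]$N
    if (length(unique(na)) == 1L && length(unique(nb)) == 1L) {
      ma <- matrix(ga$tpm, ncol = na[1L], byrow = TRUE)
      mb <- matrix(gb$tpm, ncol = nb[1L], byrow = TRUE)
      genes_o <- unique(ga$gene_id)
      w <- welch_t_rows(ma, mb, var_floor_frac)
    } else {
      genes_o <- genes
      wl <- lapply(genes, function(g) {
        r <- welch_t(ga$tpm[ga$gene_id == g], gb$tpm[gb$gene_id == g],
                     var_floor_frac)
        c(r$t, r$df, r$p,
          mean(ga$tpm[ga$gene_id == g]), mean(gb$tpm[gb$gene_id == g]))
      })
      wm <- do.call(rbind, wl)
      w <- list(t = wm[, 1], df = wm[, 2], p = wm[, 3],
                mean_a = wm[, 4], mean_b = wm[, 5])
    }
    ratio <- (w$mean_b + 1) / (w$mean_a + 1)
    q <- bh_fdr(w$p)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = genes_o, timepoint = tp,
      mean_a = w$mean_a, mean_b = w$mean_b,
      log2_fc = log2(ratio), t = w$t, df = w$df, p = w$p, q = q,
      significant = pmax(ratio, 1 / ratio) >= fc_threshold & q <= q_threshold,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), timepoint = character(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      log2_fc = numeric(0), t = numeric(0), df = numeric(0),
                      p = numeric(0), q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Join insertion differences to differential-expression flags
#'
#' For each annotated insertion difference, collects the affected genes —
#' the hit gene for intragenic insertions (always included), otherwise up
#' to `window_genes` downstream genes within `window_nt` whose transcription
#' points away from the site (candidates for polar effects), plus both
#' immediate neighbors — and joins their differential-expression results.
#' One row is emitted per (insertion, gene); genes tested at several
#' timepoints are summarized by their strongest result.
#'
#' @param impacts data.frame from [annotate_impacts()].
#' @param de_results data.frame from [flag_de()].
#' @param features feature table of the non-carrier genome (gene positions
#'   used for the windows).
#' @param window_genes maximum downstream genes collected (default 4).
#' @param window_nt window size in nucleotides (default 5000).
#' @return data.frame `diff_id`, `carrier`, `site_in_other`, `context`,
#'   `matched_element`, `gene_id`, `role` (`hit`/`downstream`/`neighbor`),
#'   `min_q`, `max_abs_log2fc`, `n_significant`, `significant`.
#' @export
overlay_expression <- function(impacts, de_results, features,
                               window_genes = 4L, window_nt = 5000L) {
  cds <- features[features$type %in% c("CDS", "gene"), , drop = FALSE]
  cds <- cds[!is.na(cds$gene_id), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(impacts))) {
    site <- impacts$site_in_other[i]
    genes <- character(0); role <- character(0)
    if (impacts$context[i] == "intragenic") {
      hit <- strsplit(impacts$hit_gene[i], ",", fixed = TRUE)[[1]]
      genes <- c(genes, hit); role <- c(role, rep("hit", length(hit)))
    }
    ## downstream candidates: transcription carries away from the site
    plus_dn <- cds[cds$strand == "+" & cds$start >= site &
                     cds$start - site <= window_nt, , drop = FALSE]
    plus_dn <- head(plus_dn[order(plus_dn$start), ], window_genes)
    minus_dn <- cds[cds$strand == "-" & cds$end <= site &
                      site - cds$end <= window_nt, , drop = FALSE]
    minus_dn <- head(minus_dn[order(-minus_dn$end), ], window_genes)
    dn <- setdiff(c(plus_dn$gene_id, minus_dn$gene_id), genes)
    genes <- c(genes, dn); role <- c(role, rep("downstream", length(dn)))
    nb <- c(cds$gene_id[cds$end < site][which.max(cds$end[cds$end < site])],
            cds$gene_id[cds$start >= site][which.min(cds$start[cds$start >= site])])
    nb <- setdiff(nb, genes)
    genes <- c(genes, nb); role <- c(role, rep("neighbor", length(nb)))
    if (length(genes) == 0L) {
      message(sprintf("insertion at site %s: no genes in window", site))
      next
    }
    for (j in seq_along(genes)) {
      de <- de_results[de_results$gene_id == genes[j], , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        diff_id = i, carrier = impacts$carrier[i], site_in_other = site,
        context = impacts$context[i],
        matched_element = impacts$matched_element[i],
        gene_id = genes[j], role = role[j],
        min_q = if (nrow(de)) suppressWarnings(min(de$q, na.rm = TRUE)) else NA_real_,
        max_abs_log2fc = if (nrow(de)) max(abs(de$log2_fc)) else NA_real_,
        n_significant = if (nrow(de)) sum(de$significant) else NA_integer_,
        significant = if (nrow(de)) any(de$significant) else NA,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(diff_id = integer(0), carrier = character(0),
                      site_in_other = integer(0), context = character(0),
                      matched_element = character(0), gene_id = character(0),
                      role = character(0), min_q = numeric(0),
                      max_abs_log2fc = numeric(0), n_significant = integer(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
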