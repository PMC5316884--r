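#' Reads-per-million log2 normalization of miRNA counts
#'
#' value = log2(count / library_total x 1e6 + 1), with a pseudocount of 1
#' inside the log so zero counts map to zero. 5p and 3p strands are
#' treated as distinct features; library totals are computed per sample
#' over all features.
#'
#' @param counts features x samples matrix of non-negative integer
#'   counts.
#' @return log2-RPM matrix.
#' @export
rpm_log <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- which(totals == 0)[1]
    label <- if (is.null(colnames(counts))) bad else colnames(counts)[bad]
    stop(sprintf("sample '%s' has zero total counts", label))
  }
  log2(sweep(counts, 2, totals, "/") * 1e6 + 1)
}

#' Differential miRNA expression
#'
#' The moderated two-group test of [moderated_de()] on log2-RPM values,
#' without a stratum term by default. Constant (zero-variance) miRNAs
#' are excluded with a warning before testing.
#'
#' @param logrpm features x samples log2-RPM matrix.
#' @param grades grade labels per sample.
#' @param strata optional stratification factor.
#' @return [moderated_de()] result over the retained miRNAs.
#' @export
mirna_de <- function(logrpm, grades, strata = NULL) {
  keep <- apply(logrpm, 1, stats::sd) > 0
  if (!all(keep)) {
    warning(sprintf("excluding %d constant miRNA(s)", sum(!keep)))
    logrpm <- logrpm[keep, , drop = FALSE]
  }
  moderated_de(logrpm, grades, strata)
}

#' Infer a miRNA-mRNA regulatory network
#'
#' For each candidate (miRNA, gene) pair supported by at least `min_dbs`
#' distinct prediction databases, computes the Spearman correlation over
#' the shared samples and retains the pair as a regulatory edge iff the
#' correlation is negative and its p-value is below `alpha`.
#'
#' @param mirna_logrpm miRNAs x samples log2-RPM matrix.
#' @param gene_matrix genes x samples expression matrix.
#' @param evidence data frame with `mirna_id`, `gene_id`, `source_db`
#'   (one row per database call; duplicated (mirna, gene, db) rows are
#'   collapsed).
#' @param min_dbs minimum distinct supporting databases (default 3).
#' @param alpha correlation p-value cutoff (default 0.05, unadjusted).
#' @return data frame of edges: `mirna_id`, `gene_id`, `spearman_rho`,
#'   `p`, `n_supporting_dbs`.
#' @export
infer_network <- function(mirna_logrpm, gene_matrix, evidence,
                          min_dbs = 3, alpha = 0.05) {
  shared <- intersect(colnames(mirna_logrpm), colnames(gene_matrix))
  if (length(shared) < 5) stop("need at least 5 shared samples")
  evidence <- unique(evidence[, c("mirna_id", "gene_id", "source_db")])
  support <- stats::aggregate(source_db ~ mirna_id + gene_id, evidence,
                              function(x) length(unique(x)))
  names(support)[3] <- "n_supporting_dbs"
  cand <- support[support$n_supporting_dbs >= min_dbs &
                    support$mirna_id %in% rownames(mirna_logrpm) &
                    support$gene_id %in% rownames(gene_matrix), ,
                  drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      spearman_rho = numeric(), p = numeric(),
                      n_supporting_dbs = integer()))
  }
  res <- lapply(seq_len(nrow(cand)), function(i) {
    ct <- pair_correlation(cand$mirna_id[i], cand$gene_id[i],
                           mirna_logrpm[, shared, drop = FALSE],
                           gene_matrix[, shared, drop = FALSE])
    data.frame(mirna_id = cand$mirna_id[i], gene_id = cand$gene_id[i],
               spearman_rho = ct$rho, p = ct$p,
               n_supporting_dbs = cand$n_supporting_dbs[i])
  })
  edges <- do.call(rbind, res)
  edges <- edges[!is.na(edges$p) & edges$spearman_rho < 0 &
                   edges$p < alpha, , drop = FALSE]
  rownames(edges) <- NULL
  stopifnot(all(edges$spearman_rho < 0), all(edges$p < alpha),
            all(edges$n_supporting_dbs >= min_dbs))
  edges
}

#' Negative versus positive target counts per miRNA
#'
#' For every miRNA with database-supported candidate targets, counts
#' targets with significant negative and significant positive Spearman
#' correlation (raw p < `alpha`), then compares the per-miRNA counts
#' with a paired Wilcoxon signed-rank test.
#'
#' @inheritParams infer_network
#' @param alternative alternative for the paired test (default
#'   `"greater"`: more negative than positive targets).
#' @return list with `counts` (data frame: `mirna_id`, `n_negative`,
#'   `n_positive`) and `p` (paired Wilcoxon p, NA with a warning if
#'   fewer than 2 miRNAs).
#' @export
neg_vs_pos_counts <- function(mirna_logrpm, gene_matrix, evidence,
                              min_dbs = 3, alpha = 0.05,
                              alternative = "greater") {
  shared <- intersect(colnames(mirna_logrpm), colnames(gene_matrix))
  if (length(shared) < 5) stop("need at least 5 shared samples")
  evidence <- unique(evidence[, c("mirna_id", "gene_id", "source_db")])
  support <- stats::aggregate(source_db ~ mirna_id + gene_id, evidence,
                              function(x) length(unique(x)))
  cand <- support[support[[3]] >= min_dbs &
                    support$mirna_id %in% rownames(mirna_logrpm) &
                    support$gene_id %in% rownames(gene_matrix), ,
                  drop = FALSE]
  mirnas <- unique(cand$mirna_id)
  counts <- do.call(rbind, lapply(mirnas, function(m) {
    genes <- cand$gene_id[cand$mirna_id == m]
    neg <- 0L; pos <- 0L
    for (g in genes) {
      ct <- pair_correlation(m, g, mirna_logrpm[, shared, drop = FALSE],
                             gene_matrix[, shared, drop = FALSE])
      if (is.na(ct$p) || ct$p >= alpha) next
      if (ct$rho < 0) neg <- neg + 1L else pos <- pos + 1L
    }
    data.frame(mirna_id = m, n_negative = neg, n_positive = pos)
  }))
  if (is.null(counts) || nrow(counts) < 2) {
    warning("fewer than 2 miRNAs with candidate targets; test skipped")
    return(list(counts = counts, p = NA_real_))
  }
  p <- suppressWarnings(stats::wilcox.test(counts$n_negative,
                                           counts$n_positive,
                                           paired = TRUE,
                                           alternative = alternative)$p.value)
  list(counts = counts, p = p)
}

#' miRNAs in a chromosomal band, with CNV-driven flags
#'
#' Members are the miRNAs whose coordinates fall inside the band
#' interval (for example the frequently deleted 14q32 cluster). If the
#' band's per-sample loss status is supplied, each member is additionally
#' flagged CNV-driven when its expression is significantly lower in
#' band-loss samples (one-sided rank-sum p < 0.05).
#'
#' @param coords data frame with `mirna_id`, `chrom`, `start`, `end`.
#' @param band list or data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param logrpm optional miRNAs x samples matrix for the CNV-driven
#'   test.
#' @param band_loss optional named logical vector (sample -> band lost).
#' @return data frame with `mirna_id` and, when testable, `cnv_driven`
#'   and `p`.
#' @export
band_cluster <- function(coords, band, logrpm = NULL, band_loss = NULL) {
  member <- coords$chrom == band$chrom & coords$start >= band$start &
    coords$end <= band$end
  out <- data.frame(mirna_id = coords$mirna_id[member])
  if (is.null(logrpm) || is.null(band_loss)) return(out)
  samples <- intersect(colnames(logrpm), names(band_loss))
  if (length(unique(band_loss[samples])) < 2) return(out)
  res <- t(vapply(out$mirna_id, function(m) {
    if (!m %in% rownames(logrpm)) return(c(NA_real_, NA_real_))
    x <- logrpm[m, samples]
    p <- suppressWarnings(stats::wilcox.test(
      x[band_loss[samples]], x[!band_loss[samples]],
      alternative = "less")$p.value)
    c(p, as.numeric(p < 0.05))
  }, numeric(2)))
  out$p <- res[, 1]
  out$cnv_driven <- res[, 2] == 1
  out
}

#' Spearman correlation between one miRNA and one gene
#'
#' @param mirna_id,gene_id row names into the two matrices.
#' @param mirna_matrix,gene_matrix feature x sample matrices sharing at
#'   least 5 sample columns.
#' @return list with `rho` and `p` (exact where n permits, asymptotic
#'   otherwise).
#' @export
pair_correlation <- function(mirna_id, gene_id, mirna_matrix, gene_matrix) {
  shared <- intersect(colnames(mirna_matrix), colnames(gene_matrix))
  if (length(shared) < 5) stop("need at least 5 shared samples")
  ct <- suppressWarnings(stats::cor.test(mirna_matrix[mirna_id, shared],
                                         gene_matrix[gene_id, shared],
                                         method = "spearman"))
  list(rho = as.numeric(ct$estimate), p = ct$p.value)
}
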