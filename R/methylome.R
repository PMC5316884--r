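#' Methylation site quality control
#'
#' Removes, in order of reporting: sites with any missing beta value,
#' sites whose probe overlaps a SNP, sites on the sex chromosomes, and
#' sites failing detection (detection p > 0.05) in at least half of the
#' samples. Removal counts by reason are attached as the `removed`
#' attribute.
#'
#' @param beta sites x samples beta-value matrix in \[0, 1\].
#' @param site_info data frame aligned with `rownames(beta)`: `site_id`,
#'   `chrom`, plus optional logical `snp_overlap`.
#' @param detection_p optional sites x samples detection p-value matrix.
#' @param detection_alpha per-call detection threshold (default 0.05).
#' @param max_fail_fraction removal threshold on the failing-sample
#'   fraction (default 0.5, i.e. at least 50% failing).
#' @return list with `beta` (filtered matrix) and `site_info` (filtered,
#'   aligned); attribute `removed` on the list gives counts per reason.
#' @export
site_qc <- function(beta, site_info, detection_p = NULL,
                    detection_alpha = 0.05, max_fail_fraction = 0.5) {
  stopifnot(nrow(beta) == nrow(site_info))
  reasons <- c(missing = 0L, snp_overlap = 0L, sex_chrom = 0L,
               detection = 0L)
  drop <- rep(FALSE, nrow(beta))
  miss <- rowSums(is.na(beta)) > 0
  reasons["missing"] <- sum(miss & !drop); drop <- drop | miss
  if ("snp_overlap" %in% names(site_info)) {
    snp <- site_info$snp_overlap %in% TRUE
    reasons["snp_overlap"] <- sum(snp & !drop); drop <- drop | snp
  }
  sex <- site_info$chrom %in% c("chrX", "chrY", "X", "Y")
  reasons["sex_chrom"] <- sum(sex & !drop); drop <- drop | sex
  if (!is.null(detection_p)) {
    fail <- rowMeans(detection_p > detection_alpha) >= max_fail_fraction
    reasons["detection"] <- sum(fail & !drop); drop <- drop | fail
  }
  out <- list(beta = beta[!drop, , drop = FALSE],
              site_info = site_info[!drop, , drop = FALSE])
  attr(out, "removed") <- reasons
  out
}

#' Beta to M-value transform
#'
#' M = log2(beta / (1 - beta)) with beta clipped to
#' \[`clip`, 1 - `clip`\] to stabilize the logit at the extremes.
#'
#' @param beta beta-value matrix.
#' @param clip clipping bound (default 0.01).
#' @return M-value matrix.
#' @export
beta_to_m <- function(beta, clip = 0.01) {
  b <- pmin(pmax(beta, clip), 1 - clip)
  log2(b / (1 - b))
}

#' Differentially methylated sites
#'
#' Moderated two-group test on M-values (variance-stabilized logit of
#' beta) combined with an effect-size gate on the beta scale: a site is
#' called hyper- or hypomethylated iff the adjusted p-value is below
#' `alpha` AND the absolute difference of group median beta values
#' exceeds `min_delta_beta`, signed by the median difference.
#'
#' @param beta sites x samples beta matrix (post-QC).
#' @param groups two-level grouping per sample; the reported delta is
#'   second level minus first (benign/atypical ordered as
#'   benign-reference).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_delta_beta minimum |delta median beta| (default 0.1).
#' @return data frame with `site_id`, `delta_beta`, `p`, `adj_p`, `call`
#'   in {"hyper", "hypo", "none"}.
#' @export
diff_methylation <- function(beta, groups, alpha = 0.05,
                             min_delta_beta = 0.1) {
  de <- moderated_de(beta_to_m(beta), groups)
  g <- as.character(groups)
  lev <- if (setequal(unique(g), c("benign", "atypical"))) {
    c("benign", "atypical")
  } else {
    sort(unique(g))
  }
  med1 <- apply(beta[, g == lev[1], drop = FALSE], 1, stats::median)
  med2 <- apply(beta[, g == lev[2], drop = FALSE], 1, stats::median)
  delta <- med2 - med1
  call <- ifelse(de$adj_p < alpha & abs(delta) > min_delta_beta,
                 ifelse(delta > 0, "hyper", "hypo"), "none")
  data.frame(site_id = de$feature, delta_beta = as.numeric(delta),
             p = de$p, adj_p = de$adj_p, call = call, row.names = NULL)
}

#' Consensus clustering by subsampled hierarchical clustering
#'
#' Repeatedly subsamples a fraction of the samples without replacement,
#' clusters them by average-linkage hierarchical clustering on the
#' Pearson correlation distance (1 - r), and cuts at each k. The
#' consensus index of a sample pair is the fraction of co-subsampled
#' iterations in which the pair co-clustered; final labels come from
#' average-linkage clustering of 1 - consensus. Deterministic for a
#' fixed seed.
#'
#' @param matrix features x samples matrix (e.g. beta values).
#' @param k_range integer vector of cluster counts to evaluate.
#' @param n_iter number of subsampling iterations (default 1000).
#' @param subsample fraction of samples drawn per iteration
#'   (default 0.8).
#' @param seed integer RNG seed.
#' @return list keyed by k (as character): each entry has `consensus`
#'   (samples x samples matrix in \[0, 1\], unit diagonal), `labels`
#'   (named integer cluster labels), and `mean_consensus` (mean
#'   within-cluster consensus, a per-k summary).
#' @export
consensus_cluster <- function(matrix, k_range = 2:4, n_iter = 1000,
                              subsample = 0.8, seed = 1) {
  n <- ncol(matrix)
  if (max(k_range) * 2 > n) {
    stop("need at least 2 * max(k_range) samples")
  }
  m_sub <- max(2L, ceiling(subsample * n))
  set.seed(seed)
  draws <- lapply(seq_len(n_iter), function(i) sort(sample.int(n, m_sub)))
  hits <- stats::setNames(
    lapply(k_range, function(k) matrix(0, n, n)), as.character(k_range))
  pair_n <- matrix(0, n, n)
  for (idx in draws) {
    d <- stats::as.dist(1 - stats::cor(matrix[, idx, drop = FALSE]))
    hc <- stats::hclust(d, method = "average")
    pair_n[idx, idx] <- pair_n[idx, idx] + 1
    for (k in k_range) {
      lab <- stats::cutree(hc, k = k)
      same <- outer(lab, lab, "==")
      hits[[as.character(k)]][idx, idx] <-
        hits[[as.character(k)]][idx, idx] + same
    }
  }
  out <- lapply(as.character(k_range), function(kc) {
    cons <- hits[[kc]] / pmax(pair_n, 1)
    cons[pair_n == 0] <- 0
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(matrix), colnames(matrix))
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    labels <- stats::cutree(hc, k = as.integer(kc))
    names(labels) <- colnames(matrix)
    within <- mean(cons[outer(labels, labels, "==") & upper.tri(cons)])
    list(consensus = cons, labels = labels, mean_consensus = within)
  })
  stats::setNames(out, as.character(k_range))
}

#' Hypermethylation burden and its correlation with PGA
#'
#' Per sample, the hypermethylation fraction is the proportion of
#' QC-passing sites whose beta exceeds the reference-group median by
#' more than `delta`; the function then reports the Pearson correlation
#' of this fraction with the per-sample percentage of genome altered.
#'
#' @param beta sites x samples beta matrix.
#' @param reference_samples column names of the reference group (e.g.
#'   benign non-NF2 samples).
#' @param pga named numeric vector of PGA percents per sample.
#' @param delta hypermethylation margin over the reference median
#'   (default 0.1).
#' @return list with `fraction` (named per-sample vector), `rho`, `p`
#'   (both NA with a warning when PGA is constant).
#' @export
hypermeth_pga_correlation <- function(beta, reference_samples, pga,
                                      delta = 0.1) {
  if (length(reference_samples) == 0) stop("reference group is empty")
  ref_med <- apply(beta[, reference_samples, drop = FALSE], 1,
                   stats::median)
  frac <- colMeans(beta > ref_med + delta)
  shared <- intersect(names(frac), names(pga))
  if (stats::sd(pga[shared]) == 0) {
    warning("PGA is constant across samples; correlation undefined")
    return(list(fraction = frac, rho = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(frac[shared], pga[shared], method = "pearson")
  list(fraction = frac, rho = as.numeric(ct$estimate), p = ct$p.value)
}

#' Basal-plus-extension regulatory domains
#'
#' Assigns each gene a basal domain (`basal_up` bp upstream to
#' `basal_down` bp downstream of its TSS, strand-aware) and extends it on
#' both sides up to the nearest neighbouring basal domain, at most
#' `max_extension` bp, never shrinking the basal domain.
#'
#' @param genes data frame with `gene`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @param basal_up,basal_down basal domain extents in bp (defaults 5000
#'   and 1000).
#' @param max_extension maximum extension in bp (default 1e6).
#' @return data frame with `gene`, `chrom`, `start`, `end` of the
#'   regulatory domain.
#' @export
regulatory_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                               max_extension = 1e6) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  b_start <- ifelse(genes$strand == "+", tss - basal_up, tss - basal_down)
  b_end <- ifelse(genes$strand == "+", tss + basal_down, tss + basal_up)
  b_start <- pmax(b_start, 1)
  out <- data.frame(gene = genes$gene, chrom = genes$chrom,
                    start = b_start, end = b_end)
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    for (i in idx) {
      others <- setdiff(idx, i)
      left <- others[b_end[others] < b_start[i]]
      lim_l <- if (length(left)) max(b_end[left]) + 1 else 1
      right <- others[b_start[others] > b_end[i]]
      lim_r <- if (length(right)) min(b_start[right]) - 1 else Inf
      out$start[i] <- min(b_start[i],
                          max(b_start[i] - max_extension, lim_l))
      out$end[i] <- max(b_end[i], min(b_end[i] + max_extension, lim_r))
    }
  }
  out
}

#' Regulatory-domain gene-set enrichment of genomic sites
#'
#' A site hits a gene set iff it falls inside the regulatory domain of
#' any member gene; enrichment of query-site hits against
#' background-site hits is tested with the hypergeometric tail and
#' BH-adjusted across sets.
#'
#' @param query_sites data frame with `chrom`, `pos` (must be a subset
#'   of the background).
#' @param background_sites data frame with `chrom`, `pos`.
#' @param gene_sets named list of character vectors of member genes.
#' @param domains regulatory domain table from [regulatory_domains()].
#' @return data frame with `set`, `query_hits`, `background_hits`,
#'   `fold`, `p`, `fdr`, sorted by p.
#' @export
region_enrichment <- function(query_sites, background_sites, gene_sets,
                              domains) {
  if (nrow(background_sites) == 0) stop("background is empty")
  site_gr <- function(sites) {
    GenomicRanges::GRanges(sites$chrom,
                           IRanges::IRanges(sites$pos, sites$pos))
  }
  q_gr <- site_gr(query_sites)
  b_gr <- site_gr(background_sites)
  n_q <- nrow(query_sites)
  n_b <- nrow(background_sites)
  rows <- lapply(names(gene_sets), function(set) {
    dom <- domains[domains$gene %in% gene_sets[[set]], , drop = FALSE]
    if (nrow(dom) == 0) {
      return(data.frame(set = set, query_hits = 0L, background_hits = 0L,
                        fold = NA_real_, p = 1))
    }
    d_gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(dom$chrom, IRanges::IRanges(dom$start, dom$end)))
    qh <- sum(IRanges::overlapsAny(q_gr, d_gr))
    bh <- sum(IRanges::overlapsAny(b_gr, d_gr))
    p <- stats::phyper(qh - 1, bh, n_b - bh, n_q, lower.tail = FALSE)
    fold <- if (bh > 0) (qh / n_q) / (bh / n_b) else NA_real_
    data.frame(set = set, query_hits = qh, background_hits = bh,
               fold = fold, p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Clustering robustness to masking chromosomes
#'
#' Re-runs consensus clustering after removing all sites on the excluded
#' chromosomes and reports the adjusted Rand index between the masked
#' and unmasked cluster labels (the published robustness check masks the
#' chromosomes carrying large-scale events: chr1, chr14, chr22).
#'
#' @param beta sites x samples beta matrix.
#' @param site_info site table aligned with `rownames(beta)` (needs
#'   `chrom`).
#' @param excluded_chroms chromosomes to mask (may be empty).
#' @param reference_labels cluster labels from the unmasked run.
#' @param k number of clusters.
#' @param ... passed to [consensus_cluster()] (`n_iter`, `subsample`,
#'   `seed`).
#' @return list with `ari`, `labels` (masked-run labels), and
#'   `n_sites_kept`.
#' @export
region_mask_sensitivity <- function(beta, site_info, excluded_chroms,
                                    reference_labels, k = 2, ...) {
  keep <- !(site_info$chrom %in% excluded_chroms)
  if (mean(keep) < 0.1) {
    warning("masking removes more than 90% of sites")
  }
  cc <- consensus_cluster(beta[keep, , drop = FALSE], k_range = k, ...)
  labels <- cc[[as.character(k)]]$labels
  ari <- mclust::adjustedRandIndex(labels[names(reference_labels)],
                                   reference_labels)
  list(ari = ari, labels = labels, n_sites_kept = sum(keep))
}
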