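#' Stitch H3K27ac peaks into enhancer regions
#'
#' Peaks whose midpoint lies within `tss_exclude_bp` of a transcription
#' start site are removed (promoter exclusion), then remaining peaks on
#' the same chromosome are merged whenever the gap between consecutive
#' peaks is at most `stitch_bp`; each stitched region spans the union of
#' its constituents. Coordinates are 0-based half-open (BED convention).
#' Stitching is idempotent: stitching the stitched regions changes
#' nothing.
#'
#' @param peaks data frame with `chrom`, `start`, `end` (0-based
#'   half-open), sorted within chromosome, plus optional extra columns.
#' @param tss data frame with `chrom`, `pos` of TSSs (may have zero
#'   rows).
#' @param stitch_bp maximum gap merged (default 12500).
#' @param tss_exclude_bp promoter exclusion half-window (default 2000).
#' @return data frame with `chrom`, `start`, `end`, `n_constituents`.
#' @export
stitch_peaks <- function(peaks, tss = NULL, stitch_bp = 12500,
                         tss_exclude_bp = 2000) {
  if (nrow(peaks) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_constituents = integer()))
  }
  keep <- rep(TRUE, nrow(peaks))
  if (!is.null(tss) && nrow(tss) > 0) {
    mid <- (peaks$start + peaks$end) / 2
    for (i in seq_len(nrow(peaks))) {
      near <- tss$chrom == peaks$chrom[i] &
        abs(tss$pos - mid[i]) <= tss_exclude_bp
      if (any(near)) keep[i] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_constituents = integer()))
  }
  out <- lapply(unique(peaks$chrom), function(ch) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    if (is.unsorted(p$start)) stop("peaks must be sortable by start")
    grp <- cumsum(c(1, ifelse(
      p$start[-1] - cummax(p$end[-nrow(p)]) > stitch_bp, 1, 0)))
    do.call(rbind, lapply(split(seq_len(nrow(p)), grp), function(idx) {
      data.frame(chrom = ch, start = min(p$start[idx]),
                 end = max(p$end[idx]), n_constituents = length(idx))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Separate super-enhancers from typical enhancers
#'
#' Regions are ranked ascending by background-subtracted signal and both
#' axes are scaled to \[0, 1\]; the cutoff is the first rank at which the
#' slope of the scaled signal curve reaches 1 (the slope of the
#' diagonal), found by scanning consecutive segments. All regions ranked
#' strictly above the cutoff point are flagged super-enhancers. With
#' all-equal signals no region qualifies and a warning is raised.
#'
#' @param signal numeric vector of per-region background-subtracted
#'   signal.
#' @return logical vector aligned with `signal`: `TRUE` for
#'   super-enhancers.
#' @export
call_super_enhancers <- function(signal) {
  n <- length(signal)
  if (n < 2) stop("need at least 2 regions")
  rng <- max(signal) - min(signal)
  if (rng == 0) {
    warning("all signals equal; no super-enhancers called")
    return(rep(FALSE, n))
  }
  o <- order(signal)
  ys <- (signal[o] - min(signal)) / rng
  xs <- (seq_len(n) - 1) / (n - 1)
  slopes <- diff(ys) / diff(xs)
  cut_idx <- which(slopes >= 1)[1]
  flags_sorted <- rep(FALSE, n)
  if (!is.na(cut_idx)) flags_sorted[seq_len(n) > cut_idx] <- TRUE
  flags <- logical(n)
  flags[o] <- flags_sorted
  flags
}

#' Background-subtracted region signal
#'
#' Region signal = max(0, ChIP rpm - input rpm).
#'
#' @param chip_rpm,input_rpm numeric vectors or matrices of matching
#'   shape.
#' @return background-subtracted signal.
#' @export
subtract_input <- function(chip_rpm, input_rpm) {
  pmax(chip_rpm - input_rpm, 0)
}

#' Differential ChIP binding between grades
#'
#' Moderated two-group test on log2(signal + 1) per region, reusing the
#' shared differential engine; regions with zero signal everywhere are
#' filtered with a warning.
#'
#' @param signal regions x samples matrix of background-subtracted
#'   signal (linear scale).
#' @param grades grade labels per sample.
#' @return [moderated_de()] result over the retained regions.
#' @export
differential_binding <- function(signal, grades) {
  keep <- rowSums(signal) > 0
  if (!all(keep)) {
    warning(sprintf("filtering %d all-zero region(s)", sum(!keep)))
    signal <- signal[keep, , drop = FALSE]
  }
  moderated_de(log2(signal + 1), grades)
}

#' Assign each region its nearest gene by TSS distance
#'
#' Distance is measured from the region centre to the gene TSS; ties
#' break to the first gene in table order.
#'
#' @param regions data frame with `chrom`, `start`, `end`.
#' @param genes data frame with `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return character vector of gene names (NA when the chromosome has no
#'   gene).
#' @export
nearest_gene <- function(regions, genes) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  centre <- (regions$start + regions$end) / 2
  vapply(seq_len(nrow(regions)), function(i) {
    cand <- which(genes$chrom == regions$chrom[i])
    if (length(cand) == 0) return(NA_character_)
    genes$gene[cand[which.min(abs(tss[cand] - centre[i]))]]
  }, character(1))
}

#' Concordance of differential enhancers with expression
#'
#' A region-gene pair is concordant iff the region's differential
#' binding and the nearest gene's differential expression are both
#' significant (adjusted p < `alpha`) with the same fold-change sign.
#'
#' @param region_de [moderated_de()] result for regions (features are
#'   region ids).
#' @param regions data frame of the same regions (`chrom`, `start`,
#'   `end`, and rownames/ids aligned with `region_de$feature`).
#' @param gene_de [moderated_de()] result for genes.
#' @param genes gene coordinate table (see [nearest_gene()]).
#' @param alpha significance cutoff (default 0.05).
#' @return data frame with one row per significant region: `region`,
#'   `gene`, `region_logFC`, `region_adj_p`, `gene_logFC`, `gene_adj_p`,
#'   `concordant`; regions whose nearest gene is absent from the
#'   expression test are skipped with a warning.
#' @export
expression_concordance <- function(region_de, regions, gene_de, genes,
                                   alpha = 0.05) {
  regions$gene <- nearest_gene(regions, genes)
  sig <- region_de[region_de$adj_p < alpha, , drop = FALSE]
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(sig))) {
    ridx <- match(sig$feature[i], rownames(regions))
    g <- regions$gene[ridx]
    gidx <- match(g, gene_de$feature)
    if (is.na(gidx)) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      region = sig$feature[i], gene = g,
      region_logFC = sig$logFC[i], region_adj_p = sig$adj_p[i],
      gene_logFC = gene_de$logFC[gidx], gene_adj_p = gene_de$adj_p[gidx],
      concordant = gene_de$adj_p[gidx] < alpha &
        sign(sig$logFC[i]) == sign(gene_de$logFC[gidx]))
  }
  if (skipped > 0) {
    warning(sprintf("%d region(s) skipped: nearest gene not in DE table",
                    skipped))
  }
  if (length(rows) == 0) {
    return(data.frame(region = character(), gene = character(),
                      region_logFC = numeric(), region_adj_p = numeric(),
                      gene_logFC = numeric(), gene_adj_p = numeric(),
                      concordant = logical()))
  }
  do.call(rbind, rows)
}

#' Differential broad-domain (H3K27me3) signal and global shift
#'
#' Per fixed-width bin, the moderated two-group test on log2(signal+1);
#' the global summary is the fraction of significant bins whose fold
#' change is positive (toward the second group), close to 1 under a
#' genome-wide gain in atypical samples and near 0.5 under the null.
#'
#' @param bin_signal bins x samples matrix of binned signal (linear
#'   scale).
#' @param grades grade labels per sample.
#' @param alpha significance cutoff for the summary (default 0.05).
#' @return list with `de` (per-bin result) and `fraction_up` (global
#'   shift summary; NA when no bin is significant).
#' @export
broad_domain_differential <- function(bin_signal, grades, alpha = 0.05) {
  de <- differential_binding(bin_signal, grades)
  sig <- de[de$adj_p < alpha, , drop = FALSE]
  frac <- if (nrow(sig) == 0) NA_real_ else mean(sig$logFC > 0)
  list(de = de, fraction_up = frac)
}
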