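#' Toy autosome arm table
#'
#' A reduced genome model for arm-fraction rules: 22 autosomes of
#' `chrom_bp` each, split into a p arm covering the first
#' `p_fraction` of the chromosome and a q arm covering the rest.
#' Coordinates are 1-based inclusive.
#'
#' @param n_chrom number of autosomes (default 22).
#' @param chrom_bp chromosome length in bp (default 130e6).
#' @param p_fraction fraction of the chromosome assigned to the p arm
#'   (default 6/13, i.e. a 60 Mb p arm on a 130 Mb chromosome).
#' @return data frame with `chrom`, `arm`, `start`, `end`; the attribute
#'   `genome_total_bp` holds the summed arm length.
#' @export
default_arm_table <- function(n_chrom = 22, chrom_bp = 130e6,
                              p_fraction = 6 / 13) {
  p_len <- round(chrom_bp * p_fraction)
  tab <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    data.frame(chrom = rep(paste0("chr", i), 2), arm = c("p", "q"),
               start = c(1, p_len + 1), end = c(p_len, chrom_bp))
  }))
  attr(tab, "genome_total_bp") <- sum(tab$end - tab$start + 1)
  tab
}

.genome_total_bp <- function(arms) {
  tot <- attr(arms, "genome_total_bp")
  if (is.null(tot)) tot <- sum(arms$end - arms$start + 1)
  tot
}

#' Estimate tumour purity from copy-loss BAF deviation
#'
#' In a single-copy loss region, the expected B-allele frequency at a
#' blood-heterozygous SNP in an admixed tumour of purity p is
#' (1 - p)/(2 - p) (or its mirror), so the mean deviation from 0.5 is
#' d = 0.5 - (1 - p)/(2 - p). Inverting gives the purity estimator
#' p = 4d / (1 + 2d), the degree of deviation from homozygosity in loss
#' regions.
#'
#' @param loss_segments data frame of segments with columns `baf_dev`,
#'   `n_snps`, and `event_class`; only rows with class `large_loss` or
#'   `focal_loss` and at least `min_snps` SNPs are used.
#' @param min_snps minimum informative SNPs per segment (default 10).
#' @return purity estimate in (0, 1].
#' @export
estimate_purity <- function(loss_segments, min_snps = 10) {
  use <- loss_segments$event_class %in% c("large_loss", "focal_loss") &
    loss_segments$n_snps >= min_snps
  if (!any(use)) {
    stop("no qualifying copy-loss segments for purity estimation")
  }
  seg <- loss_segments[use, , drop = FALSE]
  d <- stats::weighted.mean(seg$baf_dev, seg$n_snps)
  min(max(4 * d / (1 + 2 * d), .Machine$double.eps), 1)
}

#' Classify a CNV segment against its chromosomal arm
#'
#' Event classes follow arm-fraction and intensity rules: with f the
#' fraction of the arm covered by the segment, an event is large-scale if
#' f > 1/3 and focal if 1/10 < f <= 1/3. Loss requires logR < -0.1, gain
#' logR > 0.1, and either additionally requires the mean heterozygous-SNP
#' BAF deviation to be at least 0.05 (the BAF false-positive correction:
#' any intensity-qualifying segment with baf_dev < 0.05 is classed
#' `none`). Copy-neutral LOH is f > 1/3 with |logR| <= 0.1 and
#' baf_dev >= 0.05.
#'
#' @param seg one-row data frame (or list) with `chrom`, `start`, `end`
#'   (1-based inclusive), `logR`, `baf_dev`.
#' @param arms arm table from [default_arm_table()] or equivalent.
#' @param logr_gain,logr_loss logR thresholds (defaults 0.1, -0.1).
#' @param baf_dev_min minimum BAF deviation (default 0.05).
#' @return event class string: `large_loss`, `large_gain`, `focal_loss`,
#'   `focal_gain`, `cn_loh`, or `none`.
#' @export
classify_segment <- function(seg, arms, logr_gain = 0.1, logr_loss = -0.1,
                             baf_dev_min = 0.05) {
  ov <- arms$chrom == seg$chrom & arms$start <= seg$end & arms$end >= seg$start
  if (!any(ov)) stop("segment falls outside the arm table")
  if (sum(ov) > 1) {
    stop("segment spans an arm boundary; split it with `split_at_arms()`")
  }
  arm <- arms[ov, ]
  ov_bp <- min(seg$end, arm$end) - max(seg$start, arm$start) + 1
  f <- ov_bp / (arm$end - arm$start + 1)
  scale <- if (f > 1 / 3) "large" else if (f > 1 / 10) "focal" else NA
  if (seg$baf_dev < baf_dev_min) return("none")
  if (is.na(scale)) return("none")
  if (seg$logR < logr_loss) return(paste0(scale, "_loss"))
  if (seg$logR > logr_gain) return(paste0(scale, "_gain"))
  if (scale == "large") return("cn_loh")
  "none"
}

#' Split segments at arm boundaries
#'
#' Segments spanning a centromere (or any arm boundary) are split into
#' per-arm pieces before classification; `logR`, `baf_dev` and other
#' columns are carried over, and `n_snps` is apportioned by length.
#'
#' @param segments data frame with `chrom`, `start`, `end` plus any other
#'   columns.
#' @param arms arm table.
#' @return data frame of per-arm segment pieces.
#' @export
split_at_arms <- function(segments, arms) {
  out <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, , drop = FALSE]
    ov <- arms$chrom == seg$chrom & arms$start <= seg$end &
      arms$end >= seg$start
    if (!any(ov)) stop("segment falls outside the arm table")
    hits <- arms[ov, , drop = FALSE]
    pieces <- lapply(seq_len(nrow(hits)), function(j) {
      p <- seg
      p$start <- max(seg$start, hits$start[j])
      p$end <- min(seg$end, hits$end[j])
      if ("n_snps" %in% names(p)) {
        p$n_snps <- round(seg$n_snps * (p$end - p$start + 1) /
                            (seg$end - seg$start + 1))
      }
      p
    })
    do.call(rbind, pieces)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify a segment table
#'
#' [split_at_arms()] followed by per-piece [classify_segment()]; adds an
#' `event_class` column.
#'
#' @inheritParams split_at_arms
#' @inheritParams classify_segment
#' @return classified per-arm segment data frame.
#' @export
classify_segments <- function(segments, arms, logr_gain = 0.1,
                              logr_loss = -0.1, baf_dev_min = 0.05) {
  pieces <- split_at_arms(segments, arms)
  pieces$event_class <- vapply(seq_len(nrow(pieces)), function(i) {
    classify_segment(pieces[i, , drop = FALSE], arms, logr_gain, logr_loss,
                     baf_dev_min)
  }, character(1))
  pieces
}

# Union length of 1-based inclusive intervals within one chromosome set.
.union_bp <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1)
}

#' Percentage of genome altered
#'
#' PGA = 100 x (base pairs in copy-loss or copy-gain segments) / (total
#' genome length). Copy-neutral LOH does not count as altered by default;
#' overlapping altered segments are counted once.
#'
#' @param segments classified segment data frame (needs `chrom`, `start`,
#'   `end`, `event_class`).
#' @param arms arm table supplying the genome length.
#' @param include_cn_loh also count `cn_loh` segments (default FALSE).
#' @return PGA in percent, in \[0, 100\].
#' @export
compute_pga <- function(segments, arms, include_cn_loh = FALSE) {
  classes <- c("large_loss", "large_gain", "focal_loss", "focal_gain")
  if (include_cn_loh) classes <- c(classes, "cn_loh")
  alt <- segments[segments$event_class %in% classes, , drop = FALSE]
  bp <- sum(vapply(unique(alt$chrom), function(ch) {
    sel <- alt$chrom == ch
    .union_bp(alt$start[sel], alt$end[sel])
  }, numeric(1)))
  100 * bp / .genome_total_bp(arms)
}

#' CNV-high / CNV-low status from PGA
#'
#' A sample is CNV-high iff its PGA strictly exceeds the threshold; the
#' threshold is either a fixed percentage (the published reference value
#' is 4.8%) or the mean PGA of the input cohort (`"cohort_mean"`).
#'
#' @param pga_by_sample named numeric vector of per-sample PGA percents.
#' @param threshold numeric percent, or `"cohort_mean"` (default).
#' @return named character vector: `"high"` or `"low"` per sample.
#' @export
cnv_status <- function(pga_by_sample, threshold = "cohort_mean") {
  if (identical(threshold, "cohort_mean")) {
    if (length(pga_by_sample) < 2) {
      stop("cohort-mean threshold needs at least 2 samples")
    }
    threshold <- mean(pga_by_sample)
  }
  stats::setNames(ifelse(pga_by_sample > threshold, "high", "low"),
                  names(pga_by_sample))
}

#' Arm-level event association with grade
#'
#' For each (chromosome arm, event class) observed in the cohort, tests
#' association between event presence and grade with a two-sided Fisher
#' exact test, then adjusts across tested events by Benjamini-Hochberg.
#'
#' @param events data frame with `sample_id`, `chrom`, `arm`,
#'   `event_class` (one row per event; `none` rows ignored).
#' @param grades named character vector (sample -> `benign`/`atypical`)
#'   covering every sample in the cohort, including event-free ones.
#' @return data frame with `chrom`, `arm`, `event_class`, counts per
#'   grade, `p`, `fdr`, sorted by p.
#' @export
arm_event_association <- function(events, grades) {
  if (length(unique(grades)) < 2) stop("need both grades present")
  samples <- names(grades)
  events <- events[events$event_class != "none", , drop = FALSE]
  key <- unique(events[, c("chrom", "arm", "event_class")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    hit_samples <- unique(events$sample_id[
      events$chrom == key$chrom[i] & events$arm == key$arm[i] &
        events$event_class == key$event_class[i]])
    hit <- samples %in% hit_samples
    atyp <- grades[samples] == "atypical"
    tab <- matrix(c(sum(hit & atyp), sum(!hit & atyp),
                    sum(hit & !atyp), sum(!hit & !atyp)), 2, byrow = TRUE)
    data.frame(chrom = key$chrom[i], arm = key$arm[i],
               event_class = key$event_class[i],
               n_atypical = sum(hit & atyp), n_benign = sum(hit & !atyp),
               p = stats::fisher.test(tab)$p.value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Map gene intervals to segment logR
#'
#' Per gene and sample, the length-weighted mean logR over overlapping
#' segments; genes with no overlapping segment get logR 0 (copy-neutral)
#' with a warning.
#'
#' @param genes data frame with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param segments data frame with `sample_id`, `chrom`, `start`, `end`,
#'   `logR`.
#' @return genes x samples numeric matrix of logR values.
#' @export
gene_logr_matrix <- function(genes, segments) {
  samples <- unique(segments$sample_id)
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  out <- matrix(0, nrow(genes), length(samples),
                dimnames = list(genes$gene, samples))
  missed <- rep(TRUE, nrow(genes))
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    s_gr <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start, seg$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(g_gr, s_gr))
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(g_gr)[qi],
                                            IRanges::ranges(s_gr)[si]))
    num <- tapply(w * seg$logR[si], qi, sum)
    den <- tapply(w, qi, sum)
    rows <- as.integer(names(num))
    out[rows, s] <- as.numeric(num / den)
    missed[rows] <- FALSE
  }
  if (any(missed)) {
    warning(sprintf("%d gene(s) had no overlapping segment; logR set to 0",
                    sum(missed)))
  }
  out
}

# Two-sided rank-sum p. For small samples the exact permutation
# distribution of the rank sum is enumerated (valid with ties, where
# wilcox.test falls back to a normal approximation); larger samples use
# wilcox.test.
.ranksum_p <- function(a, b, max_enum = 20000) {
  n1 <- length(a); n <- n1 + length(b)
  if (choose(n, n1) <= max_enum) {
    r <- rank(c(a, b))
    w_obs <- sum(r[seq_len(n1)])
    e <- n1 * (n + 1) / 2
    combs <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    return(mean(abs(w_all - e) >= abs(w_obs - e) - 1e-9))
  }
  suppressWarnings(stats::wilcox.test(a, b)$p.value)
}

#' Per-gene CNV association with grade
#'
#' Two-sided Wilcoxon rank-sum test per gene on logR between atypical and
#' benign samples, BH-adjusted; direction reported as the difference of
#' group medians (atypical - benign).
#'
#' @param gene_logr genes x samples logR matrix (see
#'   [gene_logr_matrix()]).
#' @param grades named character vector (sample -> grade).
#' @return data frame with `gene`, `median_diff`, `p`, `fdr`, sorted by p.
#' @export
gene_cnv_association <- function(gene_logr, grades) {
  atyp <- colnames(gene_logr)[grades[colnames(gene_logr)] == "atypical"]
  ben <- colnames(gene_logr)[grades[colnames(gene_logr)] == "benign"]
  if (length(atyp) < 2 || length(ben) < 2) {
    stop("need at least 2 samples per grade")
  }
  res <- apply(gene_logr, 1, function(x) {
    a <- x[atyp]; b <- x[ben]
    p <- .ranksum_p(a, b)
    c(median_diff = stats::median(a) - stats::median(b), p = p)
  })
  out <- data.frame(gene = rownames(gene_logr), median_diff = res[1, ],
                    p = res[2, ], row.names = NULL)
  out$fdr <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Build per-sample chromosomal instability profiles
#'
#' Classifies each sample's segments, computes PGA, and attaches the
#' event list; CNV-high/low status is assigned across the cohort.
#'
#' @param segments data frame with `sample_id`, `chrom`, `start`, `end`,
#'   `logR`, `baf_dev`, `n_snps`.
#' @param arms arm table.
#' @param status_threshold passed to [cnv_status()].
#' @return list with `profiles` (data frame: `sample_id`, `pga`,
#'   `cnv_status`) and `events` (classified per-arm segment table with an
#'   `arm` column).
#' @export
instability_profiles <- function(segments, arms,
                                 status_threshold = "cohort_mean") {
  samples <- unique(segments$sample_id)
  all_events <- lapply(samples, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    cls <- classify_segments(seg, arms)
    cls$arm <- vapply(seq_len(nrow(cls)), function(i) {
      ov <- arms$chrom == cls$chrom[i] & arms$start <= cls$end[i] &
        arms$end >= cls$start[i]
      arms$arm[ov][1]
    }, character(1))
    cls
  })
  events <- do.call(rbind, all_events)
  pga <- vapply(all_events, function(ev) compute_pga(ev, arms), numeric(1))
  names(pga) <- samples
  status <- cnv_status(pga, status_threshold)
  list(profiles = data.frame(sample_id = samples, pga = as.numeric(pga),
                             cnv_status = as.character(status[samples])),
       events = events)
}
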