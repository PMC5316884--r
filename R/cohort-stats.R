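#' Fisher's exact test with relative risk and odds ratio
#'
#' Tests a 2x2 exposure-by-outcome table (rows = exposure, columns =
#' outcome) with Fisher's exact test and reports the relative risk
#' RR = \[a/(a+b)\] / \[c/(c+d)\] and odds ratio OR = ad/bc. The RR is
#' oriented as P(outcome | exposed) / P(outcome | unexposed), i.e. the
#' risk of the first-column outcome given the first-row exposure, which is
#' the orientation used when quoting the risk of a tumour being atypical
#' given its genotype.
#'
#' @param table a 2x2 integer matrix; rows are exposure (exposed first),
#'   columns are outcome (event first).
#' @param sided `"two"` (default), `"greater"` or `"less"`; passed to the
#'   exact test as the alternative on the odds ratio.
#' @param continuity if `TRUE`, add 0.5 to every cell before computing
#'   RR/OR when any cell is zero (Haldane-Anscombe); the p-value is always
#'   computed on the raw counts.
#' @return a list with `p`, `odds_ratio` (ad/bc), `relative_risk`, and the
#'   input `table`.
#' @examples
#' fisher_rr(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))$relative_risk  # 4
#' @export
fisher_rr <- function(table, sided = c("two", "greater", "less"),
                      continuity = FALSE) {
  sided <- match.arg(sided)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("`table` must be 2x2")
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("`table` must contain non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("undefined statistic: a margin of `table` is all zero")
  }
  alternative <- switch(sided, two = "two.sided", greater = "greater",
                        less = "less")
  p <- stats::fisher.test(table, alternative = alternative)$p.value
  w <- table
  if (continuity && any(w == 0)) w <- w + 0.5
  a <- w[1, 1]; b <- w[1, 2]; c <- w[2, 1]; d <- w[2, 2]
  rr <- (a / (a + b)) / (c / (c + d))
  or <- (a * d) / (b * c)
  list(p = p, odds_ratio = or, relative_risk = rr, table = table)
}

#' One-sided Fisher test for gene co-occurrence or mutual exclusivity
#'
#' Given the samples hit in two genes, tests whether the overlap is larger
#' (co-occurrence) or smaller (mutual exclusivity) than expected under
#' independent hypergeometric sampling.
#'
#' @param gene_a_hits,gene_b_hits character or integer vectors of sample
#'   identifiers mutated in each gene.
#' @param n_samples total cohort size; both hit sets must be subsets of it.
#' @param direction `"cooccurrence"` (overlap enrichment) or
#'   `"exclusivity"` (overlap depletion).
#' @return one-sided Fisher p-value.
#' @export
cooccurrence_test <- function(gene_a_hits, gene_b_hits, n_samples,
                              direction = c("cooccurrence", "exclusivity")) {
  direction <- match.arg(direction)
  gene_a_hits <- unique(gene_a_hits)
  gene_b_hits <- unique(gene_b_hits)
  if (length(gene_a_hits) > n_samples || length(gene_b_hits) > n_samples) {
    stop("hit sets cannot exceed `n_samples`")
  }
  both <- length(intersect(gene_a_hits, gene_b_hits))
  a_only <- length(gene_a_hits) - both
  b_only <- length(gene_b_hits) - both
  neither <- n_samples - both - a_only - b_only
  tab <- matrix(c(both, a_only, b_only, neither), 2, byrow = TRUE)
  alternative <- if (direction == "cooccurrence") "greater" else "less"
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, preserving the
#' input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Map a promoter offset to a genomic coordinate
#'
#' Converts a signed base-pair offset relative to a transcription start
#' site into a 1-based genomic position. Negative offsets are upstream of
#' the TSS: on the minus strand upstream means larger coordinates, on the
#' plus strand smaller ones. With the TERT TSS at chr5:1,295,104 on the
#' minus strand, the hotspot offsets -124 and -146 map to chr5:1,295,228
#' (C228T) and chr5:1,295,250 (C250T).
#'
#' @param tss_pos 1-based TSS coordinate.
#' @param strand `"+"` or `"-"`.
#' @param offset signed offset in bp; negative = upstream.
#' @return 1-based genomic position.
#' @export
tert_offset_to_coord <- function(tss_pos, strand, offset) {
  if (!strand %in% c("+", "-")) stop("`strand` must be '+' or '-'")
  if (strand == "-") tss_pos - offset else tss_pos + offset
}

#' Recover the promoter offset from a genomic coordinate
#'
#' Inverse of [tert_offset_to_coord()]; the round trip is the identity on
#' either strand.
#'
#' @inheritParams tert_offset_to_coord
#' @param genomic_pos 1-based genomic position.
#' @return signed offset in bp.
#' @export
tert_coord_to_offset <- function(tss_pos, strand, genomic_pos) {
  if (!strand %in% c("+", "-")) stop("`strand` must be '+' or '-'")
  if (strand == "-") tss_pos - genomic_pos else genomic_pos - tss_pos
}

#' Promoter-hotspot screening frequency report
#'
#' Tabulates promoter-mutation carriers by recurrence status: per-status
#' screened and positive counts, the pooled fraction and the percentage
#' rounded half-up to the nearest integer (so 4 carriers among 31
#' recurrent samples reports 13%).
#'
#' @param calls data frame of positive calls with a `sample_id` column
#'   (zero rows allowed).
#' @param sample_sheet data frame with `sample_id` and `recurrence`
#'   columns listing every screened sample.
#' @return data frame with one row per recurrence status: `recurrence`,
#'   `n_screened`, `n_positive`, `fraction`, `percent`.
#' @export
tert_recurrence_report <- function(calls, sample_sheet) {
  if (nrow(sample_sheet) == 0) {
    return(data.frame(recurrence = character(), n_screened = integer(),
                      n_positive = integer(), fraction = numeric(),
                      percent = numeric()))
  }
  if (nrow(calls) > 0 && !all(calls$sample_id %in% sample_sheet$sample_id)) {
    stop("every call must refer to a sample in the sample sheet")
  }
  statuses <- unique(sample_sheet$recurrence)
  rows <- lapply(statuses, function(st) {
    ids <- sample_sheet$sample_id[sample_sheet$recurrence == st]
    hit <- if (nrow(calls)) sum(unique(calls$sample_id) %in% ids) else 0L
    frac <- hit / length(ids)
    data.frame(recurrence = st, n_screened = length(ids),
               n_positive = hit, fraction = frac,
               percent = floor(100 * frac + 0.5))
  })
  do.call(rbind, rows)
}
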