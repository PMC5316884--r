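#' Genotype-likelihood-based somatic score
#'
#' Phred-scaled probability that tumour and matched-normal genotypes are
#' identical, computed from the two genotype log10-likelihood triplets
#' (hom-ref, het, hom-alt) under a flat prior and independence:
#' score = -10 log10 sum_g P(g | tumour) P(g | normal). Uninformative
#' triplets give posteriors of 1/3 each, hence a score of about 4.77;
#' disjoint support gives an infinite score, capped at `max_score`.
#'
#' @param tumour_gl,normal_gl numeric length-3 genotype log10-likelihoods
#'   (hom-ref, het, hom-alt); any common scaling constant cancels.
#' @param max_score cap on the phred score (default 255).
#' @return non-negative somatic score.
#' @export
somatic_score <- function(tumour_gl, normal_gl, max_score = 255) {
  for (gl in list(tumour_gl, normal_gl)) {
    if (length(gl) != 3L || any(!is.finite(gl))) {
      stop("genotype likelihoods must be 3 finite values")
    }
  }
  post <- function(gl) {
    w <- 10^(gl - max(gl))
    w / sum(w)
  }
  p_same <- sum(post(tumour_gl) * post(normal_gl))
  if (p_same <= 0) return(max_score)
  min(max(-10 * log10(p_same), 0), max_score)
}

#' Default thresholds for the somatic filter cascade
#'
#' @param somatic_score_min minimum somatic score (default 20).
#' @param qual_min minimum site quality (default 30).
#' @param qd_min minimum quality-by-depth (default 1).
#' @param mq0_max maximum count of mapping-quality-zero reads (default 4).
#' @param strand_bias_max maximum phred-scaled strand-bias score
#'   (default 60).
#' @param cluster_size_max largest allowed mutation-cluster size
#'   (default 2; clusters of size > 2 fail).
#' @param cluster_window_bp gap window for mutation clustering
#'   (default 100).
#' @param homopolymer_len minimum homopolymer run length (default 10).
#' @param homopolymer_flank_bp window around the variant searched for a
#'   homopolymer (default 5).
#' @param clipping_rank_sum_range allowed ClippingRankSum interval
#'   (default c(-3, 3)).
#' @param pop_af_max maximum population allele frequency (default 0.01).
#' @param internal_allele_count_max maximum internal-cohort variant
#'   alleles in the gene (default 150).
#' @return named list of thresholds.
#' @export
filter_thresholds <- function(somatic_score_min = 20,
                              qual_min = 30,
                              qd_min = 1,
                              mq0_max = 4,
                              strand_bias_max = 60,
                              cluster_size_max = 2,
                              cluster_window_bp = 100,
                              homopolymer_len = 10,
                              homopolymer_flank_bp = 5,
                              clipping_rank_sum_range = c(-3, 3),
                              pop_af_max = 0.01,
                              internal_allele_count_max = 150) {
  list(somatic_score_min = somatic_score_min, qual_min = qual_min,
       qd_min = qd_min, mq0_max = mq0_max,
       strand_bias_max = strand_bias_max,
       cluster_size_max = cluster_size_max,
       cluster_window_bp = cluster_window_bp,
       homopolymer_len = homopolymer_len,
       homopolymer_flank_bp = homopolymer_flank_bp,
       clipping_rank_sum_range = clipping_rank_sum_range,
       pop_af_max = pop_af_max,
       internal_allele_count_max = internal_allele_count_max)
}

# Longest homopolymer run that overlaps the window [lo, hi] (1-based
# positions within `seq`), or starts at position `right_of`.
.homopolymer_hit <- function(seq, lo, hi, right_of, min_len) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n == 0) return(FALSE)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$lengths >= min_len & r$values %in% c("A", "C", "G", "T"))
  for (i in long) {
    if (starts[i] <= hi && ends[i] >= lo) return(TRUE)
    if (starts[i] == right_of) return(TRUE)
  }
  FALSE
}

#' Apply the somatic variant filter cascade
#'
#' Evaluates every quality filter on a variant record and records all
#' failures (no short-circuiting), so the verdict is independent of
#' filter order. The filters, in reporting order: somatic score below
#' threshold; RepeatMasker/segmental-duplication overlap; low site
#' quality or quality-by-depth; excess mapping-quality-zero reads; strand
#' bias; membership in a mutation cluster of size > 2; a homopolymer run
#' of at least 10 bp within +/- 5 bp of the variant or starting
#' immediately to its right; ClippingRankSum outside \[-3, 3\]; population
#' allele frequency above 1%; more than 150 internal-cohort variant
#' alleles in the gene.
#'
#' @param record a one-row data frame (or list) with fields
#'   `tumour_gl`, `normal_gl` (length-3 numeric, possibly inside a list
#'   column) or a precomputed `somatic_score`; `repeat_masked`, `segdup`
#'   (logical); `qual`, `qd`, `mq0`, `strand_bias_phred`,
#'   `clipping_rank_sum`, `pop_af_max`, `internal_gene_allele_count`
#'   (numeric); `cluster_size` (integer, from [cluster_variants()]);
#'   `context_seq` (string of odd length with the variant base at its
#'   centre).
#' @param thresholds list from [filter_thresholds()].
#' @return list with `passed` (flag) and `failed_filters` (character
#'   vector, empty iff passed).
#' @export
apply_filter_cascade <- function(record, thresholds = filter_thresholds()) {
  get1 <- function(name) {
    v <- record[[name]]
    if (is.list(v)) v <- v[[1]]
    if (is.null(v) || (is.atomic(v) && length(v) == 0)) {
      stop(sprintf("missing annotation field `%s`", name))
    }
    v
  }
  score <- if (!is.null(record[["somatic_score"]]) &&
               !is.na(record[["somatic_score"]][1])) {
    record[["somatic_score"]][1]
  } else {
    somatic_score(get1("tumour_gl"), get1("normal_gl"))
  }
  ctx <- as.character(get1("context_seq"))
  if (nchar(ctx) %% 2 != 1) {
    stop("`context_seq` must have odd length with the variant at centre")
  }
  centre <- (nchar(ctx) + 1L) %/% 2L
  flank <- thresholds$homopolymer_flank_bp
  failed <- character()
  if (score < thresholds$somatic_score_min) failed <- c(failed, "somatic_score")
  if (isTRUE(get1("repeat_masked")) || isTRUE(get1("segdup"))) {
    failed <- c(failed, "repeat_segdup")
  }
  if (get1("qual") < thresholds$qual_min || get1("qd") < thresholds$qd_min) {
    failed <- c(failed, "quality")
  }
  if (get1("mq0") > thresholds$mq0_max) failed <- c(failed, "mq0")
  if (get1("strand_bias_phred") > thresholds$strand_bias_max) {
    failed <- c(failed, "strand_bias")
  }
  cl <- record[["cluster_size"]]
  if (!is.null(cl) && !is.na(cl[1]) && cl[1] > thresholds$cluster_size_max) {
    failed <- c(failed, "mutation_cluster")
  }
  if (.homopolymer_hit(ctx, centre - flank, centre + flank, centre + 1L,
                       thresholds$homopolymer_len)) {
    failed <- c(failed, "homopolymer")
  }
  crs <- get1("clipping_rank_sum")
  if (crs < thresholds$clipping_rank_sum_range[1] ||
      crs > thresholds$clipping_rank_sum_range[2]) {
    failed <- c(failed, "clipping_rank_sum")
  }
  if (get1("pop_af_max") > thresholds$pop_af_max) {
    failed <- c(failed, "population_frequency")
  }
  if (get1("internal_gene_allele_count") > thresholds$internal_allele_count_max) {
    failed <- c(failed, "internal_cohort_frequency")
  }
  list(passed = length(failed) == 0L, failed_filters = failed)
}

#' Annotate variants with their mutation-cluster size
#'
#' Within each sample and chromosome, a cluster is a maximal run of
#' variants whose consecutive position gaps are all at most `window_bp`.
#' Records gain a `cluster_size` column; the cascade fails variants in
#' clusters of size > 2.
#'
#' @param records data frame with `sample_id` (optional, single sample
#'   assumed if absent), `chrom` and `pos`, sorted by (chrom, pos) within
#'   sample.
#' @param window_bp maximum gap between consecutive cluster members
#'   (default 100).
#' @return `records` with a `cluster_size` integer column.
#' @export
cluster_variants <- function(records, window_bp = 100) {
  if (nrow(records) == 0) {
    records$cluster_size <- integer(0)
    return(records)
  }
  sample <- if ("sample_id" %in% names(records)) records$sample_id else ""
  key <- paste(sample, records$chrom, sep = "\r")
  size <- integer(nrow(records))
  for (k in unique(key)) {
    idx <- which(key == k)
    pos <- records$pos[idx]
    if (is.unsorted(pos)) stop("records must be sorted by (chrom, pos)")
    brk <- c(0L, which(diff(pos) > window_bp), length(pos))
    for (j in seq_len(length(brk) - 1L)) {
      members <- idx[(brk[j] + 1L):brk[j + 1L]]
      size[members] <- length(members)
    }
  }
  records$cluster_size <- size
  records
}

#' Consequence severity ranking
#'
#' The fixed severity ordering used to pick the most-deleterious
#' consequence of a variant. Terms in this list are deleterious; any
#' other term ranks below all of them.
#'
#' @return character vector, most severe first.
#' @export
consequence_severity <- function() {
  c("transcript_ablation",
    "splice_acceptor_variant",
    "splice_donor_variant",
    "stop_gained",
    "frameshift_variant",
    "stop_lost",
    "splice_region_variant",
    "initiator_codon_variant",
    "missense_damaging",
    "inframe_deletion",
    "inframe_insertion")
}

#' Select the most severe consequence for a variant
#'
#' @param consequence_terms character vector of consequence terms.
#' @return list with `top_term` (most severe term; among non-deleterious
#'   terms the first listed is returned) and `deleterious` (flag: top
#'   term is in [consequence_severity()]).
#' @export
select_consequence <- function(consequence_terms) {
  if (length(consequence_terms) == 0) {
    stop("`consequence_terms` must be non-empty")
  }
  sev <- consequence_severity()
  ranks <- match(consequence_terms, sev)
  if (all(is.na(ranks))) {
    return(list(top_term = consequence_terms[1], deleterious = FALSE))
  }
  top <- consequence_terms[which.min(ranks)]
  list(top_term = top, deleterious = TRUE)
}

#' Six-category mutational signature
#'
#' Folds single-nucleotide substitutions into the six strand-symmetric
#' categories T>C/A>G, A>C/T>G, G>C/C>G, C>T/G>A, A>T/T>A, G>T/C>A and
#' returns their fractions among filtered SNVs (all zero when no SNV is
#' present). Indels are ignored.
#'
#' @param records data frame with `ref` and `alt` allele columns.
#' @return named numeric length-6 vector of fractions summing to 1 (or
#'   all zero).
#' @export
mutational_signature <- function(records) {
  cats <- c("T>C/A>G", "A>C/T>G", "G>C/C>G", "C>T/G>A", "A>T/T>A", "G>T/C>A")
  out <- stats::setNames(numeric(6), cats)
  if (nrow(records) == 0) return(out)
  snv <- nchar(records$ref) == 1 & nchar(records$alt) == 1 &
    records$ref %in% c("A", "C", "G", "T") &
    records$alt %in% c("A", "C", "G", "T") & records$ref != records$alt
  if (!any(snv)) return(out)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- records$ref[snv]
  alt <- records$alt[snv]
  sub <- paste0(ref, ">", alt)
  folded <- paste0(sub, "/", comp[ref], ">", comp[alt])
  # each category lists both strand representations
  key <- c("T>C/A>G" = "T>C", "A>G/T>C" = "T>C",
           "A>C/T>G" = "A>C", "T>G/A>C" = "A>C",
           "G>C/C>G" = "G>C", "C>G/G>C" = "G>C",
           "C>T/G>A" = "C>T", "G>A/C>T" = "C>T",
           "A>T/T>A" = "A>T", "T>A/A>T" = "A>T",
           "G>T/C>A" = "G>T", "C>A/G>T" = "G>T")
  canon <- key[folded]
  label <- c("T>C" = "T>C/A>G", "A>C" = "A>C/T>G", "G>C" = "G>C/C>G",
             "C>T" = "C>T/G>A", "A>T" = "A>T/T>A", "G>T" = "G>T/C>A")
  tab <- table(factor(label[canon], levels = cats))
  out[] <- as.numeric(tab) / sum(tab)
  out
}

#' Assign a sample to a mutually exclusive driver subgroup
#'
#' Meningioma driver subgroups in priority order: NF2/SMARCB1 (an NF2 hit
#' together with SMARCB1 p.Arg383Gln or p.Arg386His), NF2 (a deleterious
#' NF2 variant, or NF2 loss through a chr22 deletion), TRAF7/PI3K (TRAF7
#' plus PIK3CA, PIK3R1 or AKT1 p.Glu17Lys), TRAF7/KLF4 (TRAF7 plus KLF4
#' p.Lys409Gln), Hedgehog (SMO, SUFU or PRKAR1A), POLR2A (p.Gln403Lys or
#' p.Leu438_His439del), otherwise unknown. Conflicting evidence is
#' resolved by this priority.
#'
#' @param variants data frame of deleterious-filtered variants for one
#'   sample with `gene` and `protein_change` columns.
#' @param chr22_loss flag: sample carries a chr22/NF2 locus deletion.
#' @return subgroup label string.
#' @export
assign_driver_subgroup <- function(variants, chr22_loss = FALSE) {
  hit <- function(gene) any(variants$gene == gene)
  hit_pc <- function(gene, pcs) {
    any(variants$gene == gene & variants$protein_change %in% pcs)
  }
  nf2_hit <- hit("NF2") || isTRUE(chr22_loss)
  if (nf2_hit && hit_pc("SMARCB1", c("p.Arg383Gln", "p.Arg386His"))) {
    return("NF2/SMARCB1")
  }
  if (nf2_hit) return("NF2")
  if (hit("TRAF7") &&
      (hit("PIK3CA") || hit("PIK3R1") || hit_pc("AKT1", "p.Glu17Lys"))) {
    return("TRAF7/PI3K")
  }
  if (hit("TRAF7") && hit_pc("KLF4", "p.Lys409Gln")) return("TRAF7/KLF4")
  if (hit("SMO") || hit("SUFU") || hit("PRKAR1A")) return("Hedgehog")
  if (hit_pc("POLR2A", c("p.Gln403Lys", "p.Leu438_His439del"))) {
    return("POLR2A")
  }
  "unknown"
}

#' Clonality (cancer cell fraction) of a somatic mutation
#'
#' Converts a variant allele frequency into the fraction of tumour cells
#' carrying the mutation, correcting for tumour purity and local copy
#' number. With VAF = alt/(alt+ref) and effective copies
#' D = purity * cn + (1 - purity) * 2, the mutated-copy multiplicity is
#' m = clamp(round(VAF * D / purity), 1, cn) and
#' ccf = VAF * D / (purity * m), clamped to \[0, 1.05\].
#'
#' @param tumour_alt_depth,tumour_ref_depth tumour read counts.
#' @param purity tumour purity in (0, 1\].
#' @param tumour_cn local tumour copy number (>= 1).
#' @return list with `vaf`, `purity`, `tumour_cn`, `multiplicity`, `ccf`.
#' @export
clonality <- function(tumour_alt_depth, tumour_ref_depth, purity,
                      tumour_cn = 2) {
  if (purity <= 0 || purity > 1) stop("`purity` must be in (0, 1]")
  if (tumour_cn < 1) stop("`tumour_cn` must be >= 1")
  depth <- tumour_alt_depth + tumour_ref_depth
  if (depth <= 0) stop("tumour depth must be positive")
  vaf <- tumour_alt_depth / depth
  d_eff <- purity * tumour_cn + (1 - purity) * 2
  m <- max(1, min(tumour_cn, round(vaf * d_eff / purity)))
  ccf <- max(0, min(1.05, vaf * d_eff / (purity * m)))
  list(vaf = vaf, purity = purity, tumour_cn = tumour_cn,
       multiplicity = m, ccf = ccf)
}

#' Filter a variant table through the somatic cascade
#'
#' Convenience wrapper: annotates cluster sizes per sample, applies
#' [apply_filter_cascade()] to every row, and appends `passed` and
#' `failed_filters` columns.
#'
#' @param variants variant data frame (see [apply_filter_cascade()] for
#'   required columns; `sample_id`, `chrom`, `pos` are needed for
#'   clustering).
#' @param thresholds list from [filter_thresholds()].
#' @return the input with `cluster_size`, `passed` and `failed_filters`
#'   (semicolon-joined) columns added.
#' @export
filter_variant_table <- function(variants, thresholds = filter_thresholds()) {
  variants <- cluster_variants(variants, thresholds$cluster_window_bp)
  verdicts <- lapply(seq_len(nrow(variants)), function(i) {
    apply_filter_cascade(variants[i, , drop = FALSE], thresholds)
  })
  variants$passed <- vapply(verdicts, `[[`, logical(1), "passed")
  variants$failed_filters <- vapply(verdicts, function(v) {
    paste(v$failed_filters, collapse = ";")
  }, character(1))
  variants
}
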