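#' Synthetic cohort configuration
#'
#' Bundles and validates the parameters of the synthetic meningioma
#' cohort generator. The defaults describe the cohort structure the
#' pipeline is designed for: two grades with grade-linked chromosomal
#' instability, driver subgroups dominated by NF2 loss, admixture-diluted
#' BAFs, a deleted 14q32 miRNA cluster, hypermethylation coupled to CNV
#' burden, and enhancer signal coupled to expression.
#'
#' @param n_atypical,n_benign samples per grade (each >= 2; defaults 10).
#' @param seed integer master seed; all generated assays derive from it.
#' @param purity_range tumour purity interval (values in (0, 1\];
#'   default c(0.5, 0.9)).
#' @param arm_table chromosome arm table (default
#'   [default_arm_table()]); arm intervals must not overlap within a
#'   chromosome.
#' @param planted_effects named list of per-assay effect sizes:
#'   `expr_logfc` (log2 fold change of planted genes, default 2),
#'   `expr_sd` (expression noise SD, default 0.5), `n_de_genes`
#'   (default 100), `n_genes` (default 2000), `mirna_logfc` (14q32 and
#'   planted miRNA shift, default -1), `n_mirna` (default 300),
#'   `mirna_size` (negative-binomial size, default 10), `delta_beta`
#'   (methylation shift, default 0.25), `n_meth_sites` (default 2000),
#'   `n_dm_sites` (default 200), `beta_sd` (default 0.05),
#'   `enhancer_multiplier` (super-enhancer signal multiplier, default
#'   10), `n_regions` (default 200), `batch_shift` (additive expression
#'   batch effect, default 1).
#' @param batch_assignment optional character vector of batch labels per
#'   sample (length `n_atypical + n_benign`); default alternates two
#'   batches.
#' @param fraction_cnv_high named fractions of CNV-high samples per
#'   grade (default c(benign = 0.15, atypical = 0.7)).
#' @param missing_rate fraction of missing values planted in matrices
#'   (default 0).
#' @return validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_atypical = 10, n_benign = 10, seed = 1,
                          purity_range = c(0.5, 0.9),
                          arm_table = default_arm_table(),
                          planted_effects = list(),
                          batch_assignment = NULL,
                          fraction_cnv_high = c(benign = 0.15,
                                                atypical = 0.7),
                          missing_rate = 0) {
  if (n_atypical < 2 || n_benign < 2) {
    stop("configuration error: n_atypical and n_benign must be >= 2")
  }
  if (any(purity_range <= 0) || any(purity_range > 1)) {
    stop("configuration error: purity_range values must be in (0, 1]")
  }
  for (ch in unique(arm_table$chrom)) {
    a <- arm_table[arm_table$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1 && any(a$start[-1] <= a$end[-nrow(a)])) {
      stop("configuration error: arm_table arms overlap within ", ch)
    }
  }
  if (any(fraction_cnv_high < 0) || any(fraction_cnv_high > 1)) {
    stop("configuration error: fraction_cnv_high must be in [0, 1]")
  }
  defaults <- list(expr_logfc = 2, expr_sd = 0.5, n_de_genes = 100,
                   n_genes = 2000, mirna_logfc = -1, n_mirna = 300,
                   mirna_size = 10, delta_beta = 0.25, n_meth_sites = 2000,
                   n_dm_sites = 200, beta_sd = 0.05,
                   enhancer_multiplier = 10, n_regions = 200,
                   batch_shift = 1)
  unknown <- setdiff(names(planted_effects), names(defaults))
  if (length(unknown)) {
    stop("configuration error: unknown planted_effects field '",
         unknown[1], "'")
  }
  effects <- utils::modifyList(defaults, planted_effects)
  n <- n_atypical + n_benign
  if (is.null(batch_assignment)) {
    batch_assignment <- rep(c("batch1", "batch2"), length.out = n)
  }
  if (length(batch_assignment) != n) {
    stop("configuration error: batch_assignment length must equal ",
         "n_atypical + n_benign")
  }
  structure(list(n_atypical = n_atypical, n_benign = n_benign, seed = seed,
                 purity_range = purity_range, arm_table = arm_table,
                 planted_effects = effects,
                 batch_assignment = batch_assignment,
                 fraction_cnv_high = fraction_cnv_high,
                 missing_rate = missing_rate),
            class = "cohort_config")
}

#' Simulate B-allele frequencies at blood-heterozygous SNPs
#'
#' Each SNP's BAF is a binomial draw at the admixture-weighted allele
#' fraction. With tumour copy number `tumour_cn`, purity p and an
#' allele-specific tumour genotype of (cn - b, b) B copies (b = 0 for
#' losses, the minor count for gains), the expected BAF is
#' (p b + (1 - p)) / (p cn + 2(1 - p)); which parental allele is
#' affected is flipped with probability 1/2 per SNP. At purity 1 and
#' cn 1 the BAFs concentrate on {0, 1}; at purity 0 the mean BAF is 0.5.
#'
#' @param depth read depth per SNP (>= 1).
#' @param purity tumour purity in \[0, 1\].
#' @param tumour_cn integer copy number in {0, 1, 2, 3, 4}.
#' @param n_snps number of SNPs.
#' @param seed integer RNG seed.
#' @return numeric vector of BAF values in \[0, 1\].
#' @export
simulate_baf <- function(depth, purity, tumour_cn, n_snps, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (!tumour_cn %in% 0:4) stop("tumour_cn must be in {0, 1, 2, 3, 4}")
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
  b_copies <- c(`0` = 0, `1` = 0, `2` = 1, `3` = 1, `4` = 1)[
    as.character(tumour_cn)]
  total <- purity * tumour_cn + 2 * (1 - purity)
  if (total == 0) return(rep(0.5, n_snps))  # pure tumour, homozygous loss
  f <- (purity * b_copies + (1 - purity)) / total
  set.seed(seed)
  flip <- stats::runif(n_snps) < 0.5
  fr <- ifelse(flip, 1 - f, f)
  stats::rbinom(n_snps, depth, fr) / depth
}

# internal: deterministic coordinates for n features over the arm table
.scatter_coords <- function(n, arms, prefix) {
  arm_len <- arms$end - arms$start + 1
  pick <- sample.int(nrow(arms), n, replace = TRUE, prob = arm_len)
  pos <- arms$start[pick] +
    floor(stats::runif(n) * (arm_len[pick] - 1000))
  data.frame(feature_id = sprintf("%s%04d", prefix, seq_len(n)),
             chrom = arms$chrom[pick], start = pos, end = pos + 999,
             strand = rep(c("+", "-"), length.out = n))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.write_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Generate a synthetic multi-omics meningioma cohort
#'
#' Writes a complete per-sample input bundle (sample sheet, somatic
#' variant table, CNV segments with BAF tables, expression and miRNA
#' matrices with coordinate sidecars, methylation beta matrix, miRNA
#' target-evidence table, H3K27ac peak BEDs with region signal, and
#' binned H3K27me3 signal) with planted ground truth, reproducibly from
#' `(config, seed)`: the same configuration yields byte-identical files.
#'
#' Planted structure: CNV-high samples carry large-scale arm losses
#' (chr22q in every NF2 sample; chr14q, chr1p and extras in CNV-high
#' ones) giving high PGA; expression has `n_de_genes` grade-shifted
#' genes (EZH2 up in atypical) plus an additive batch shift; the 28
#' miRNAs of the 14q32 cluster are down-shifted in samples with 14q
#' loss and let-7 family members are down in atypical with EZH2
#' anti-correlated; methylation has two planted clusters with
#' hypermethylation proportional to CNV burden; enhancer regions include
#' planted super-enhancers and grade-differential regions whose nearest
#' genes shift concordantly.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `files` (named vector of written
#'   paths) and `truth` (ground-truth list: `samples` with true purity,
#'   subgroup, CNV status and methylation cluster; `events`; `pga`;
#'   `de_genes`; `de_mirnas`; `mirna_cluster_14q32`; `true_pairs`;
#'   `dm_sites`; `super_regions`; `de_regions`).
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  set.seed(config$seed)
  eff <- config$planted_effects
  arms <- config$arm_table
  n <- config$n_atypical + config$n_benign
  samples <- sprintf("S%03d", seq_len(n))
  grade <- c(rep("atypical", config$n_atypical),
             rep("benign", config$n_benign))
  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  cnv_high <- unlist(lapply(c("atypical", "benign"), function(g) {
    ns <- sum(grade == g)
    k <- round(config$fraction_cnv_high[[g]] * ns)
    sample(c(rep(TRUE, k), rep(FALSE, ns - k)))
  }))
  cnv_high <- cnv_high[order(c(which(grade == "atypical"),
                               which(grade == "benign")))]
  # driver subgroups: NF2 dominates; a couple of NF2/SMARCB1 atypicals;
  # benign non-NF2 split over the remaining subgroups
  subgroup <- character(n)
  atyp_idx <- which(grade == "atypical")
  ben_idx <- which(grade == "benign")
  subgroup[atyp_idx] <- "NF2"
  if (length(atyp_idx) >= 5) {
    subgroup[atyp_idx[seq_len(max(1, round(length(atyp_idx) * 0.15)))]] <-
      "NF2/SMARCB1"
  }
  ben_pool <- c("NF2", "NF2", "TRAF7/KLF4", "TRAF7/PI3K", "Hedgehog",
                "POLR2A")
  subgroup[ben_idx] <- rep(ben_pool, length.out = length(ben_idx))
  batch <- config$batch_assignment

  sheet <- data.frame(sample_id = samples, grade = grade,
                      recurrence = "primary", batch = batch,
                      included = TRUE)

  ## ---- CNV segments, BAF tables, PGA truth -------------------------
  q14 <- arms[arms$chrom == "chr14" & arms$arm == "q", ]
  p1 <- arms[arms$chrom == "chr1" & arms$arm == "p", ]
  q22 <- arms[arms$chrom == "chr22" & arms$arm == "q", ]
  extra_arms <- arms[!(paste(arms$chrom, arms$arm) %in%
                         c("chr14 q", "chr1 p", "chr22 q")), ]
  seg_rows <- list()
  baf_rows <- list()
  truth_events <- list()
  has_14q_loss <- logical(n)
  loss_logr <- function(p) log2((p * 1 + (1 - p) * 2) / 2)
  for (i in seq_len(n)) {
    p <- purity[i]
    dev <- 0.5 - (1 - p) / (2 - p)
    ev <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), cn = integer())
    if (startsWith(subgroup[i], "NF2")) {
      ev <- rbind(ev, data.frame(chrom = q22$chrom, start = q22$start,
                                 end = q22$end, cn = 1L))
    }
    if (cnv_high[i]) {
      ev <- rbind(ev,
                  data.frame(chrom = q14$chrom, start = q14$start,
                             end = q14$end, cn = 1L),
                  data.frame(chrom = p1$chrom, start = p1$start,
                             end = p1$end, cn = 1L))
      has_14q_loss[i] <- TRUE
      k_extra <- 2 + sample.int(2, 1)
      picks <- extra_arms[sample.int(nrow(extra_arms), k_extra), ]
      ev <- rbind(ev, data.frame(chrom = picks$chrom, start = picks$start,
                                 end = picks$end,
                                 cn = sample(c(1L, 3L), k_extra,
                                             replace = TRUE)))
    } else if (stats::runif(1) < 0.5) {
      # CNV-low samples may carry one small focal event
      a <- extra_arms[sample.int(nrow(extra_arms), 1), ]
      len <- round((a$end - a$start + 1) * 0.15)
      st <- a$start + sample.int(a$end - a$start - len, 1)
      ev <- rbind(ev, data.frame(chrom = a$chrom, start = st,
                                 end = st + len - 1, cn = 1L))
    }
    if (nrow(ev) > 0) {
      for (j in seq_len(nrow(ev))) {
        n_snps <- 120
        cn <- ev$cn[j]
        baf <- simulate_baf(500, p, cn, n_snps,
                            seed = config$seed + i * 1000 + j)
        logr <- if (cn == 1) loss_logr(p) else
          log2((p * cn + (1 - p) * 2) / 2)
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          sample_id = samples[i], chrom = ev$chrom[j], start = ev$start[j],
          end = ev$end[j], logR = round(logr + stats::rnorm(1, 0, 0.02), 4),
          baf_dev = round(mean(abs(baf - 0.5)), 4), n_snps = n_snps)
        pos <- round(seq(ev$start[j] + 500, ev$end[j] - 500,
                         length.out = n_snps))
        baf_rows[[length(baf_rows) + 1]] <- data.frame(
          sample_id = samples[i], chrom = ev$chrom[j], pos = pos,
          baf = round(baf, 4))
        truth_events[[length(truth_events) + 1]] <- data.frame(
          sample_id = samples[i], chrom = ev$chrom[j], start = ev$start[j],
          end = ev$end[j], cn = cn)
      }
    }
    # one neutral segment so every sample has a table entry
    a <- arms[1, ]
    baf <- simulate_baf(500, p, 2, 60, seed = config$seed + i * 1000 + 999)
    seg_rows[[length(seg_rows) + 1]] <- data.frame(
      sample_id = samples[i], chrom = a$chrom, start = a$start,
      end = a$start + 9999999, logR = round(stats::rnorm(1, 0, 0.02), 4),
      baf_dev = round(mean(abs(baf - 0.5)), 4), n_snps = 60)
  }
  segments <- do.call(rbind, seg_rows)
  bafs <- do.call(rbind, baf_rows)
  events_truth <- if (length(truth_events)) do.call(rbind, truth_events)
    else data.frame()
  genome_bp <- .genome_total_bp(arms)
  true_pga <- vapply(samples, function(s) {
    ev <- events_truth[events_truth$sample_id == s, , drop = FALSE]
    if (nrow(ev) == 0) return(0)
    100 * sum(ev$end - ev$start + 1) / genome_bp
  }, numeric(1))

  ## ---- somatic variant table ---------------------------------------
  var_rows <- list()
  clean_ctx <- "ACGTACGTACGTACGTACGTACGTACGTACG"
  gl_som <- function() list(t = c(-20, 0, -20), n = c(0, -20, -40))
  add_var <- function(sample_i, gene, chrom, pos, pc, cons, ref = "C",
                      alt = "T") {
    p <- purity[sample_i]
    depth <- 150L
    alt_d <- stats::rbinom(1, depth, p / 2)
    gl <- gl_som()
    data.frame(sample_id = samples[sample_i], chrom = chrom, pos = pos,
               ref = ref, alt = alt, tumour_ref_depth = depth - alt_d,
               tumour_alt_depth = alt_d, normal_ref_depth = 140L,
               normal_alt_depth = 0L,
               tumour_gl = paste(gl$t, collapse = ","),
               normal_gl = paste(gl$n, collapse = ","),
               qual = 200, qd = 10, mq0 = 0, strand_bias_phred = 5,
               clipping_rank_sum = 0, repeat_masked = FALSE,
               segdup = FALSE, context_seq = clean_ctx, pop_af_max = 0,
               internal_gene_allele_count = 3L,
               consequence_terms = cons, gene = gene, protein_change = pc)
  }
  driver_pos <- list(NF2 = c("chr22", 90e6), SMARCB1 = c("chr22", 85e6),
                     TRAF7 = c("chr16", 2e6), KLF4 = c("chr9", 1.1e8),
                     PIK3CA = c("chr3", 1.2e8), SMO = c("chr7", 1.28e8),
                     POLR2A = c("chr17", 7e6))
  for (i in seq_len(n)) {
    sg <- subgroup[i]
    if (startsWith(sg, "NF2")) {
      var_rows[[length(var_rows) + 1]] <- add_var(
        i, "NF2", "chr22", 9e7 + i, "p.Lys79fs", "frameshift_variant")
    }
    if (sg == "NF2/SMARCB1") {
      var_rows[[length(var_rows) + 1]] <- add_var(
        i, "SMARCB1", "chr22", 8.5e7 + i, "p.Arg383Gln",
        "missense_damaging")
    }
    if (sg %in% c("TRAF7/KLF4", "TRAF7/PI3K")) {
      var_rows[[length(var_rows) + 1]] <- add_var(
        i, "TRAF7", "chr16", 2e6 + i, "p.Asn520Ser", "missense_damaging")
    }
    if (sg == "TRAF7/KLF4") {
      var_rows[[length(var_rows) + 1]] <- add_var(
        i, "KLF4", "chr9", 1.1e8 + i, "p.Lys409Gln", "missense_damaging")
    }
    if (sg == "TRAF7/PI3K") {
      var_rows[[length(var_rows) + 1]] <- add_var(
        i, "PIK3CA", "chr3", 1.2e8 + i, "p.His1047Arg",
        "missense_damaging")
    }
    if (sg == "Hedgehog") {
      var_rows[[length(var_rows) + 1]] <- add_var(
        i, "SMO", "chr7", 1.28e8 + i, "p.Leu412Phe", "missense_damaging")
    }
    if (sg == "POLR2A") {
      var_rows[[length(var_rows) + 1]] <- add_var(
        i, "POLR2A", "chr17", 7e6 + i, "p.Gln403Lys", "missense_damaging")
    }
    # passenger SNVs with random substitution types
    n_pass <- 3 + sample.int(4, 1)
    for (k in seq_len(n_pass)) {
      arm_i <- sample.int(nrow(arms), 1)
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      var_rows[[length(var_rows) + 1]] <- add_var(
        i, sprintf("PASS%02d", k), arms$chrom[arm_i],
        arms$start[arm_i] + sample.int(1e6, 1), "p.?",
        "synonymous_variant", ref, alt)
    }
    # one artifact that the cascade should remove (low somatic score)
    art <- add_var(i, "ARTIFACT", "chr2", 5e6 + i, "p.?",
                   "missense_damaging")
    art$tumour_gl <- "-0.05,-1,-10"
    art$normal_gl <- "0,-1.2,-10"
    var_rows[[length(var_rows) + 1]] <- art
  }
  variants <- do.call(rbind, var_rows)
  variants <- variants[order(variants$sample_id, variants$chrom,
                             variants$pos), ]

  ## ---- expression matrix -------------------------------------------
  n_genes <- eff$n_genes
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  gene_ids[1] <- "EZH2"
  base <- stats::rnorm(n_genes, 8, 1)
  expr <- matrix(stats::rnorm(n_genes * n, 0, eff$expr_sd), n_genes, n,
                 dimnames = list(gene_ids, samples)) + base
  de_idx <- seq_len(eff$n_de_genes)
  de_dir <- rep(c(1, -1), length.out = eff$n_de_genes)
  de_dir[1] <- 1  # EZH2 up in atypical
  expr[de_idx, grade == "atypical"] <-
    expr[de_idx, grade == "atypical"] + de_dir * eff$expr_logfc
  expr <- expr + matrix(rep(ifelse(batch == "batch2", eff$batch_shift, 0),
                            each = n_genes), n_genes, n)
  gene_coords <- .scatter_coords(n_genes, arms, "G")
  gene_coords$feature_id <- gene_ids
  names(gene_coords)[1] <- "gene"

  ## ---- miRNA counts -------------------------------------------------
  n_mirna <- eff$n_mirna
  mirna_ids <- sprintf("mir%03d-5p", seq_len(n_mirna))
  let7 <- c("let-7a-5p", "let-7b-5p", "let-7c-5p", "let-7d-5p",
            "let-7e-5p")
  mirna_ids[seq_along(let7)] <- let7
  n_cluster <- 28
  cluster_idx <- 6:(5 + n_cluster)
  mirna_coords <- .scatter_coords(n_mirna, arms, "mir")
  mirna_coords$feature_id <- mirna_ids
  names(mirna_coords)[1] <- "mirna_id"
  band <- list(chrom = "chr14", start = 95e6, end = 107e6)
  cl_pos <- round(seq(band$start + 1e5, band$end - 1e5,
                      length.out = n_cluster))
  mirna_coords$chrom[cluster_idx] <- "chr14"
  mirna_coords$start[cluster_idx] <- cl_pos
  mirna_coords$end[cluster_idx] <- cl_pos + 80
  base_mu <- exp(stats::rnorm(n_mirna, log(200), 1))
  log_mu <- matrix(log2(base_mu), n_mirna, n,
                   dimnames = list(mirna_ids, samples))
  # 14q32 cluster follows 14q loss; let-7 (except let-7a) down in atypical
  log_mu[cluster_idx, has_14q_loss] <-
    log_mu[cluster_idx, has_14q_loss] + eff$mirna_logfc
  log_mu[2:5, grade == "atypical"] <-
    log_mu[2:5, grade == "atypical"] + eff$mirna_logfc * 0.8
  log_mu[1, grade == "atypical"] <- log_mu[1, grade == "atypical"] + 0.66
  # extra planted DE miRNAs off the cluster
  extra_de <- (5 + n_cluster + 1):(5 + n_cluster + 10)
  extra_dir <- rep(c(-1, 1), length.out = 10)
  log_mu[extra_de, grade == "atypical"] <-
    log_mu[extra_de, grade == "atypical"] + extra_dir * abs(eff$mirna_logfc)
  # let-7 members anti-correlate with EZH2 expression across samples
  ezh2_c <- scale(expr["EZH2", ])[, 1]
  log_mu[2:5, ] <- log_mu[2:5, ] - 0.4 * matrix(rep(ezh2_c, each = 4), 4, n)
  counts <- matrix(stats::rnbinom(n_mirna * n, mu = 2^log_mu,
                                  size = eff$mirna_size),
                   n_mirna, n, dimnames = list(mirna_ids, samples))

  ## ---- miRNA target evidence ---------------------------------------
  dbs <- c("miranda", "mirbase", "mirtarget2", "pictar", "tarbase",
           "targetscan")
  # true regulatory pairs: cluster miRNAs target up-in-atypical planted
  # genes (their loss derepresses the targets); let-7c/d/e target EZH2
  up_genes <- gene_ids[de_idx[de_dir == 1]]
  true_pairs <- data.frame(
    mirna_id = c(mirna_ids[cluster_idx], let7[3:5]),
    gene_id = c(rep(up_genes, length.out = n_cluster), rep("EZH2", 3)))
  # couple the target genes to the realized miRNA abundances so the
  # anti-correlation survives sampling noise
  lc <- log2(counts + 1)
  for (j in seq_len(n_cluster)) {
    g <- true_pairs$gene_id[j]
    m <- true_pairs$mirna_id[j]
    if (stats::sd(lc[m, ]) > 0) {
      expr[g, ] <- expr[g, ] - 0.5 * scale(lc[m, ])[, 1]
    }
  }
  decoy_pairs <- data.frame(
    mirna_id = mirna_ids[sample.int(n_mirna, 40, replace = TRUE)],
    gene_id = gene_ids[sample(seq(eff$n_de_genes + 1, n_genes), 40)])
  weak_pairs <- data.frame(
    mirna_id = mirna_ids[sample.int(n_mirna, 20, replace = TRUE)],
    gene_id = gene_ids[sample(seq(eff$n_de_genes + 1, n_genes), 20)])
  ev_rows <- rbind(
    do.call(rbind, lapply(seq_len(nrow(true_pairs)), function(i) {
      data.frame(mirna_id = true_pairs$mirna_id[i],
                 gene_id = true_pairs$gene_id[i],
                 source_db = sample(dbs, 4))
    })),
    do.call(rbind, lapply(seq_len(nrow(decoy_pairs)), function(i) {
      data.frame(mirna_id = decoy_pairs$mirna_id[i],
                 gene_id = decoy_pairs$gene_id[i],
                 source_db = sample(dbs, 3))
    })),
    do.call(rbind, lapply(seq_len(nrow(weak_pairs)), function(i) {
      data.frame(mirna_id = weak_pairs$mirna_id[i],
                 gene_id = weak_pairs$gene_id[i],
                 source_db = sample(dbs, 2))
    })))
  evidence <- unique(ev_rows)

  ## ---- methylation beta matrix --------------------------------------
  n_sites <- eff$n_meth_sites
  site_ids <- sprintf("cg%06d", seq_len(n_sites))
  site_coords <- .scatter_coords(n_sites, arms, "cg")
  site_coords$feature_id <- site_ids
  names(site_coords)[1] <- "site_id"
  base_beta <- stats::runif(n_sites, 0.1, 0.9)
  beta <- matrix(stats::rnorm(n_sites * n, 0, eff$beta_sd), n_sites, n,
                 dimnames = list(site_ids, samples)) + base_beta
  # cluster 1 = hypermethylated phenotype (CNV-high or NF2/SMARCB1)
  meth_cluster <- ifelse(cnv_high | subgroup == "NF2/SMARCB1", 1L, 2L)
  dm_idx <- seq_len(eff$n_dm_sites)
  # hypermethylation scales with CNV burden, except in NF2/SMARCB1
  # samples, which are hypermethylated despite genomic stability
  hyper_scale <- 0.3 + 0.7 * true_pga / max(true_pga, 1)
  hyper_scale[subgroup == "NF2/SMARCB1"] <- 1
  for (i in which(meth_cluster == 1L)) {
    beta[dm_idx, i] <- beta[dm_idx, i] + eff$delta_beta * hyper_scale[i]
  }
  beta <- pmin(pmax(beta, 0.001), 0.999)
  if (config$missing_rate > 0) {
    nas <- stats::runif(length(beta)) < config$missing_rate
    beta[nas] <- NA
  }

  ## ---- H3K27ac enhancer regions ------------------------------------
  n_regions <- eff$n_regions
  reg_coords <- .scatter_coords(n_regions, arms, "E")
  reg_coords$end <- reg_coords$start + 5000
  region_ids <- sprintf("E%04d", seq_len(n_regions))
  reg_coords$feature_id <- region_ids
  names(reg_coords)[1] <- "region_id"
  base_sig <- exp(stats::rnorm(n_regions, log(5), 0.4))
  n_super <- 15
  super_idx <- seq_len(n_super)
  base_sig[super_idx] <- base_sig[super_idx] * eff$enhancer_multiplier
  sig <- matrix(exp(stats::rnorm(n_regions * n, 0, 0.25)), n_regions, n,
                dimnames = list(region_ids, samples)) * base_sig
  # differential regions tied to planted DE genes: place region near the
  # gene TSS and scale signal with the grade effect
  n_diff_reg <- 20
  diff_reg_idx <- (n_super + 1):(n_super + n_diff_reg)
  for (k in seq_len(n_diff_reg)) {
    g_row <- de_idx[k]
    ri <- diff_reg_idx[k]
    reg_coords$chrom[ri] <- gene_coords$chrom[g_row]
    reg_coords$start[ri] <- max(1, gene_coords$start[g_row] - 20000)
    reg_coords$end[ri] <- reg_coords$start[ri] + 5000
    mult <- 2^(de_dir[k] * 2)
    sig[ri, grade == "atypical"] <- sig[ri, grade == "atypical"] * mult
  }
  ## ---- H3K27me3 binned signal ---------------------------------------
  n_bins <- 300
  bin_ids <- sprintf("bin%04d", seq_len(n_bins))
  me3 <- matrix(exp(stats::rnorm(n_bins * n, log(10), 0.3)), n_bins, n,
                dimnames = list(bin_ids, samples))
  me3[, grade == "atypical"] <- me3[, grade == "atypical"] * 2^0.5

  ## ---- write files ---------------------------------------------------
  f <- c(
    samples = .write_tsv(sheet, file.path(dir, "samples.tsv")),
    variants = .write_tsv(variants, file.path(dir, "variants.tsv")),
    segments = .write_tsv(segments, file.path(dir, "segments.tsv")),
    baf = .write_tsv(bafs, file.path(dir, "baf.tsv")),
    expression = .write_matrix(round(expr, 4),
                               file.path(dir, "expression.tsv")),
    expression_coords = .write_tsv(gene_coords,
                                   file.path(dir, "expression_coords.tsv")),
    mirna_counts = .write_matrix(counts,
                                 file.path(dir, "mirna_counts.tsv")),
    mirna_coords = .write_tsv(mirna_coords,
                              file.path(dir, "mirna_coords.tsv")),
    mirna_evidence = .write_tsv(evidence,
                                file.path(dir, "mirna_evidence.tsv")),
    beta = .write_matrix(round(beta, 4), file.path(dir, "beta.tsv")),
    beta_coords = .write_tsv(site_coords,
                             file.path(dir, "beta_coords.tsv")),
    enhancer_signal = .write_matrix(round(sig, 4),
                                    file.path(dir, "enhancer_signal.tsv")),
    enhancer_coords = .write_tsv(reg_coords,
                                 file.path(dir, "enhancer_coords.tsv")),
    h3k27me3_bins = .write_matrix(round(me3, 4),
                                  file.path(dir, "h3k27me3_bins.tsv")),
    arm_table = .write_tsv(arms, file.path(dir, "arm_table.tsv")))
  # per-sample peak BEDs (0-based half-open) with signal
  for (i in seq_len(n)) {
    bed <- data.frame(chrom = reg_coords$chrom,
                      start = reg_coords$start - 1,
                      end = reg_coords$end,
                      name = region_ids,
                      score = round(sig[, i], 4))
    path <- file.path(dir, "peaks",
                      paste0(samples[i], "_H3K27ac.bed"))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }

  truth <- list(
    samples = data.frame(sample_id = samples, grade = grade,
                         subgroup = subgroup, purity = purity,
                         cnv_status = ifelse(cnv_high, "high", "low"),
                         meth_cluster = meth_cluster,
                         has_14q_loss = has_14q_loss,
                         batch = batch),
    events = events_truth,
    pga = stats::setNames(true_pga, samples),
    de_genes = data.frame(gene = gene_ids[de_idx], direction = de_dir),
    de_mirnas = data.frame(
      mirna_id = c(mirna_ids[cluster_idx], let7[2:5],
                   mirna_ids[extra_de]),
      direction = c(rep(-1, n_cluster), rep(-1, 4), extra_dir)),
    mirna_cluster_14q32 = mirna_ids[cluster_idx],
    band_14q32 = band,
    true_pairs = true_pairs,
    dm_sites = site_ids[dm_idx],
    super_regions = region_ids[super_idx],
    de_regions = region_ids[diff_reg_idx])
  invisible(list(files = f, truth = truth))
}

#' Read a variant table written by [generate_cohort()]
#'
#' Parses the genotype-likelihood triplet columns (comma-separated
#' strings) into list columns usable by [apply_filter_cascade()].
#'
#' @param path path to `variants.tsv`.
#' @return data frame with `tumour_gl` and `normal_gl` list columns.
#' @export
read_variant_table <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  v$tumour_gl <- lapply(strsplit(v$tumour_gl, ","), as.numeric)
  v$normal_gl <- lapply(strsplit(v$normal_gl, ","), as.numeric)
  v
}

#' Read a feature x sample matrix written by [generate_cohort()]
#'
#' @param path path to a matrix TSV whose first column is `feature_id`.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
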