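# Shared fixture builders for the test suite. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# A minimal clean variant record that passes every cascade filter.
clean_variant <- function(...) {
  rec <- list(
    sample_id = "S1", chrom = "chr1", pos = 1000L, ref = "C", alt = "T",
    tumour_ref_depth = 60L, tumour_alt_depth = 40L,
    normal_ref_depth = 80L, normal_alt_depth = 0L,
    tumour_gl = list(c(-20, 0, -20)), normal_gl = list(c(0, -20, -40)),
    qual = 100, qd = 5, mq0 = 0, strand_bias_phred = 10,
    clipping_rank_sum = 0, repeat_masked = FALSE, segdup = FALSE,
    context_seq = "ACGTACGTACGTACGTACGTACGTACGTACG", pop_af_max = 0,
    internal_gene_allele_count = 3L, cluster_size = 1L)
  dots <- list(...)
  rec[names(dots)] <- dots
  rec
}

# Two-group matrix with planted mean shifts on the first `n_de` rows.
planted_matrix <- function(n_feat, n_per_group, effect, sd = 1,
                           n_de = 0, seed = 1, prefix = "F") {
  set.seed(seed)
  n <- 2 * n_per_group
  m <- matrix(rnorm(n_feat * n, 0, sd), n_feat, n)
  rownames(m) <- sprintf("%s%04d", prefix, seq_len(n_feat))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  grades <- rep(c("benign", "atypical"), each = n_per_group)
  if (n_de > 0) {
    m[seq_len(n_de), grades == "atypical"] <-
      m[seq_len(n_de), grades == "atypical"] + effect
  }
  list(matrix = m, grades = grades)
}

# Beta matrix with two planted sample clusters differing on the first
# `n_dm` sites.
planted_beta <- function(n_sites = 400, n_per_cluster = 6, delta = 0.3,
                         sd = 0.03, n_dm = 120, seed = 1,
                         chroms = paste0("chr", 1:4)) {
  set.seed(seed)
  n <- 2 * n_per_cluster
  base <- runif(n_sites, 0.2, 0.8)
  beta <- matrix(rnorm(n_sites * n, 0, sd), n_sites, n) + base
  cluster <- rep(1:2, each = n_per_cluster)
  beta[seq_len(n_dm), cluster == 1] <-
    beta[seq_len(n_dm), cluster == 1] + delta
  beta <- pmin(pmax(beta, 0.01), 0.99)
  rownames(beta) <- sprintf("cg%05d", seq_len(n_sites))
  colnames(beta) <- sprintf("S%03d", seq_len(n))
  site_info <- data.frame(site_id = rownames(beta),
                          chrom = rep(chroms, length.out = n_sites))
  list(beta = beta, cluster = cluster, site_info = site_info)
}
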