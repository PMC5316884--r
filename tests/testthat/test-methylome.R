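test_that("site QC removes sites by reason and reports counts", {
  set.seed(30)
  beta <- matrix(runif(10 * 6), 10, 6,
                 dimnames = list(sprintf("cg%02d", 1:10),
                                 sprintf("S%d", 1:6)))
  info <- data.frame(site_id = rownames(beta),
                     chrom = c("chr1", "chr2", "chrX", "chr3", "chrY",
                               rep("chr4", 5)),
                     snp_overlap = c(FALSE, TRUE, rep(FALSE, 8)))
  beta[4, 2] <- NA
  det <- matrix(0.01, 10, 6)
  det[6, 1:3] <- 0.5   # fails detection in 3/6 samples (50%)
  det[7, 1:2] <- 0.5   # fails in 2/6 (below the 50% rule)
  qc <- site_qc(beta, info, det)
  kept <- rownames(qc$beta)
  expect_false(any(c("cg02", "cg03", "cg04", "cg05", "cg06") %in% kept))
  expect_true(all(c("cg01", "cg07", "cg08", "cg09", "cg10") %in% kept))
  removed <- attr(qc, "removed")
  expect_equal(unname(removed["missing"]), 1)
  expect_equal(unname(removed["snp_overlap"]), 1)
  expect_equal(unname(removed["sex_chrom"]), 2)
  expect_equal(unname(removed["detection"]), 1)
})

test_that("differential methylation applies the dual p and effect gate", {
  set.seed(31)
  n <- 20
  groups <- rep(c("benign", "atypical"), each = 10)
  beta <- matrix(runif(300, 0.2, 0.6), 300, n,
                 dimnames = list(sprintf("cg%03d", 1:300),
                                 sprintf("S%03d", 1:n)))
  beta <- beta + rnorm(length(beta), 0, 0.02)
  # planted hyper sites: delta +0.3
  beta[1:30, groups == "atypical"] <- beta[1:30, groups == "atypical"] +
    0.3
  # significant but small effect: delta 0.05 with tiny variance
  beta[31:40, ] <- 0.4 + rnorm(10 * n, 0, 0.004)
  beta[31:40, groups == "atypical"] <-
    beta[31:40, groups == "atypical"] + 0.05
  beta <- pmin(pmax(beta, 0.01), 0.99)
  dm <- diff_methylation(beta, groups)
  expect_gte(mean(dm$call[1:30] == "hyper"), 0.9)
  # effect-size gate: small-delta sites are significant but not called
  expect_true(all(dm$adj_p[31:40] < 0.05))
  expect_true(all(dm$call[31:40] == "none"))
  # null sites: calls at most at the nominal rate
  expect_lte(mean(dm$call[41:300] != "none"), 0.05)
  # calls invariant to sample ordering
  perm <- sample(n)
  dm2 <- diff_methylation(beta[, perm], groups[perm])
  expect_identical(dm$call, dm2$call)
})

test_that("consensus clustering recovers planted clusters deterministically", {
  pb <- planted_beta(n_sites = 300, n_per_cluster = 6, delta = 0.3,
                     seed = 32)
  cc <- consensus_cluster(pb$beta, k_range = 2, n_iter = 100, seed = 5)
  res <- cc[["2"]]
  expect_equal(mclust::adjustedRandIndex(res$labels, pb$cluster), 1.0)
  # consensus near 1 within and near 0 between planted clusters
  same <- outer(pb$cluster, pb$cluster, "==")
  expect_gte(min(res$consensus[same]), 0.9)
  expect_lte(max(res$consensus[!same]), 0.1)
  expect_true(isSymmetric(res$consensus))
  expect_true(all(diag(res$consensus) == 1))
  expect_true(all(res$consensus >= 0 & res$consensus <= 1))
  # duplicated samples always co-cluster
  dup <- cbind(pb$beta, pb$beta[, 1])
  colnames(dup) <- c(colnames(pb$beta), "DUP")
  cc2 <- consensus_cluster(dup, k_range = 2, n_iter = 50, seed = 6)
  expect_equal(cc2[["2"]]$consensus["S001", "DUP"], 1)
  # same seed twice: identical consensus
  cc3 <- consensus_cluster(pb$beta, k_range = 2, n_iter = 50, seed = 7)
  cc4 <- consensus_cluster(pb$beta, k_range = 2, n_iter = 50, seed = 7)
  expect_identical(cc3[["2"]]$consensus, cc4[["2"]]$consensus)
  expect_error(consensus_cluster(pb$beta, k_range = 10), "samples")
})

test_that("hypermethylation fraction couples to PGA as planted", {
  set.seed(33)
  n_sites <- 500
  n <- 50
  samples <- sprintf("S%03d", 1:n)
  base <- runif(n_sites, 0.2, 0.5)
  beta <- matrix(rnorm(n_sites * n, 0, 0.02), n_sites, n,
                 dimnames = list(sprintf("cg%04d", 1:n_sites), samples)) +
    base
  pga <- setNames(runif(n, 0, 20), samples)
  # plant hypermethylation proportional to PGA
  target_frac <- pga / 40
  for (j in seq_len(n)) {
    k <- round(target_frac[j] * n_sites)
    if (k > 0) beta[seq_len(k), j] <- beta[seq_len(k), j] + 0.25
  }
  beta <- pmin(pmax(beta, 0.01), 0.99)
  ref <- samples[pga < 2]
  res <- hypermeth_pga_correlation(beta, ref, pga)
  expect_gt(res$rho, 0.8)
  expect_lt(res$p, 0.01)
  # a sample identical to the reference medians scores fraction ~ 0
  ref_med <- apply(beta[, ref, drop = FALSE], 1, median)
  beta2 <- cbind(beta, REF = ref_med)
  res2 <- hypermeth_pga_correlation(beta2, ref, c(pga, REF = 0))
  expect_equal(unname(res2$fraction["REF"]), 0)
  # constant PGA: NA with warning
  expect_warning(res3 <- hypermeth_pga_correlation(
    beta, ref, setNames(rep(5, n), samples)), "constant")
  expect_true(is.na(res3$rho))
})

test_that("regulatory domains extend to neighbours up to 1 Mb", {
  genes <- data.frame(
    gene = c("A", "B", "C"), chrom = "chr1",
    start = c(1e6, 1.5e6, 5e6), end = c(1.01e6, 1.51e6, 5.01e6),
    strand = c("+", "+", "+"))
  dom <- regulatory_domains(genes)
  # A has no left neighbour: extends 1 Mb upstream, floored at 1
  expect_equal(dom$start[dom$gene == "A"], max(1, 1e6 - 5e3 - 1e6))
  # A extends right to B's basal start minus 1 (nearer than 1 Mb)
  expect_equal(dom$end[dom$gene == "A"], 1.5e6 - 5e3 - 1)
  # B extends right toward C but capped at 1 Mb past its basal end
  expect_equal(dom$end[dom$gene == "B"], 1.5e6 + 1e3 + 1e6)
  # C's left extension caps at 1 Mb before reaching B's basal domain
  expect_equal(dom$start[dom$gene == "C"], 5e6 - 5e3 - 1e6)
})

test_that("region enrichment equals the exact hypergeometric oracle", {
  set.seed(34)
  # toy genome: 2000 background sites, gene domains covering known sites
  bg <- data.frame(chrom = "chr1", pos = seq(1e4, 2e7, length.out = 2000))
  genes <- data.frame(gene = sprintf("G%d", 1:5), chrom = "chr1",
                      start = seq(2e6, 18e6, length.out = 5),
                      end = seq(2e6, 18e6, length.out = 5) + 1e4,
                      strand = "+")
  dom <- regulatory_domains(genes, max_extension = 5e5)
  sets <- list(SET1 = c("G1", "G2"), SET2 = c("G4"),
               EMPTY = character())
  # query enriched in SET1 domains
  in_set1 <- bg$pos >= dom$start[1] & bg$pos <= dom$end[2] |
    (bg$pos >= dom$start[2] & bg$pos <= dom$end[2])
  query <- rbind(bg[in_set1, ][1:40, ], bg[!in_set1, ][1:20, ])
  res <- region_enrichment(query, bg, sets, dom)
  expect_identical(res$set[1], "SET1")
  # p equals brute-force enumeration
  r1 <- res[res$set == "SET1", ]
  expect_equal(r1$p, enum_hyper_tail(r1$query_hits, r1$background_hits,
                                     nrow(query), nrow(bg)),
               tolerance = 1e-12)
  # query = background: fold 1, p = 1 (for non-degenerate sets)
  res_all <- region_enrichment(bg, bg, sets["SET1"], dom)
  expect_equal(res_all$fold, 1)
  expect_equal(res_all$p, 1, tolerance = 1e-9)
  expect_error(region_enrichment(query, bg[0, ], sets, dom), "empty")
})

test_that("clustering is robust to masking uninvolved chromosomes", {
  pb <- planted_beta(n_sites = 400, n_per_cluster = 6, delta = 0.3,
                     seed = 35, chroms = paste0("chr", 1:8))
  cc <- consensus_cluster(pb$beta, k_range = 2, n_iter = 100, seed = 8)
  ref_labels <- cc[["2"]]$labels
  # empty mask: identical run, ARI 1
  res0 <- region_mask_sensitivity(pb$beta, pb$site_info, character(),
                                  ref_labels, k = 2, n_iter = 100,
                                  seed = 8)
  expect_equal(res0$ari, 1)
  # masking chromosomes that carry only a fraction of the signal
  res1 <- region_mask_sensitivity(pb$beta, pb$site_info,
                                  c("chr1", "chr2"), ref_labels, k = 2,
                                  n_iter = 100, seed = 8)
  expect_gte(res1$ari, 0.9)
  # negative control: clusters driven solely by masked chromosomes
  pb2 <- planted_beta(n_sites = 400, n_per_cluster = 6, delta = 0,
                      seed = 36, chroms = paste0("chr", 1:8))
  driver <- pb2$site_info$chrom %in% c("chr1", "chr2")
  pb2$beta[driver, pb2$cluster == 1] <-
    pmin(pb2$beta[driver, pb2$cluster == 1] + 0.35, 0.99)
  cc2 <- consensus_cluster(pb2$beta, k_range = 2, n_iter = 100, seed = 9)
  expect_equal(mclust::adjustedRandIndex(cc2[["2"]]$labels, pb2$cluster),
               1.0)
  res2 <- suppressWarnings(region_mask_sensitivity(
    pb2$beta, pb2$site_info, c("chr1", "chr2"), cc2[["2"]]$labels,
    k = 2, n_iter = 100, seed = 9))
  expect_lte(res2$ari, 0.3)
})
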