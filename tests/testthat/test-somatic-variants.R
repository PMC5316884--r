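test_that("somatic score follows the flat-prior posterior agreement model", {
  # uninformative triplets: P(same genotype) = 1/3
  expect_equal(somatic_score(c(0, 0, 0), c(0, 0, 0)), -10 * log10(1 / 3),
               tolerance = 1e-10)
  # disjoint support: capped at the configured maximum
  expect_equal(somatic_score(c(-100, 0, -100), c(0, -100, -100)), 255)
  expect_equal(somatic_score(c(-100, 0, -100), c(0, -100, -100),
                             max_score = 99), 99)
  # tumour posterior (0.9 hom-ref, 0.1 het) vs certain hom-ref normal
  t_gl <- log10(c(0.9, 0.1, 1e-30))
  n_gl <- c(0, -100, -100)
  expect_equal(somatic_score(t_gl, n_gl), -10 * log10(0.9),
               tolerance = 1e-6)
  # scaling a triplet by a constant leaves the score unchanged
  expect_equal(somatic_score(c(-5, -3, -8) + 7, c(-1, -2, -3)),
               somatic_score(c(-5, -3, -8), c(-1, -2, -3)))
  expect_error(somatic_score(c(0, NA, 0), c(0, 0, 0)), "finite")
})

test_that("filter cascade records every failure without short-circuiting", {
  thr <- filter_thresholds()
  # clean record passes
  v <- apply_filter_cascade(clean_variant(), thr)
  expect_true(v$passed)
  expect_length(v$failed_filters, 0)
  # somatic score below 20 fails exactly that filter
  low <- clean_variant(tumour_gl = list(log10(c(0.97, 0.03, 1e-30))),
                       normal_gl = list(c(0, -100, -100)))
  v <- apply_filter_cascade(low, thr)
  expect_false(v$passed)
  expect_identical(v$failed_filters, "somatic_score")
  # homopolymer run overlapping the +/- 5 bp window
  homo <- clean_variant(context_seq = "ACGTACGAAAAAAAAAACGTACGTACGTACG")
  expect_true("homopolymer" %in%
                apply_filter_cascade(homo, thr)$failed_filters)
  # run of 10 starting immediately right of the variant (position 17)
  right <- clean_variant(context_seq = "ACGTACGTACGTACGTGGGGGGGGGGACGTA")
  expect_true("homopolymer" %in%
                apply_filter_cascade(right, thr)$failed_filters)
  # run of 9 does not trigger
  nine <- clean_variant(context_seq = "ACGTACGTACGTACGTGGGGGGGGGACGTAC")
  expect_false("homopolymer" %in%
                 apply_filter_cascade(nine, thr)$failed_filters)
  # multiple simultaneous failures are all recorded
  multi <- clean_variant(qual = 10, pop_af_max = 0.2, repeat_masked = TRUE,
                         clipping_rank_sum = -5,
                         internal_gene_allele_count = 200L)
  v <- apply_filter_cascade(multi, thr)
  expect_setequal(v$failed_filters,
                  c("quality", "population_frequency", "repeat_segdup",
                    "clipping_rank_sum", "internal_cohort_frequency"))
  # idempotent: same record, same verdict
  expect_identical(apply_filter_cascade(multi, thr),
                   apply_filter_cascade(multi, thr))
  expect_error(apply_filter_cascade(clean_variant(qual = NULL)), "qual")
})

test_that("boundary thresholds follow the published strict inequalities", {
  thr <- filter_thresholds()
  # score exactly 20 passes ("less than 20")
  rec <- clean_variant()
  rec$somatic_score <- 20
  expect_true(apply_filter_cascade(rec, thr)$passed)
  # qual exactly 30 and qd exactly 1 pass ("<30", "<1")
  expect_true(apply_filter_cascade(clean_variant(qual = 30, qd = 1),
                                   thr)$passed)
  # pop_af exactly 1% passes ("more than 1%")
  expect_true(apply_filter_cascade(clean_variant(pop_af_max = 0.01),
                                   thr)$passed)
  # exactly 150 internal alleles passes ("greater than 150")
  expect_true(apply_filter_cascade(
    clean_variant(internal_gene_allele_count = 150L), thr)$passed)
  # ClippingRankSum exactly -3 or 3 passes ("< -3 or > 3")
  expect_true(apply_filter_cascade(clean_variant(clipping_rank_sum = 3),
                                   thr)$passed)
  expect_true(apply_filter_cascade(clean_variant(clipping_rank_sum = -3),
                                   thr)$passed)
})

test_that("mutation clusters chain on gaps and flag only size > 2", {
  thr <- filter_thresholds()
  recs <- data.frame(sample_id = "S1", chrom = "chr1",
                     pos = c(100L, 150L, 180L))
  out <- cluster_variants(recs, 100)
  expect_identical(out$cluster_size, c(3L, 3L, 3L))
  flagged <- vapply(1:3, function(i) {
    "mutation_cluster" %in% apply_filter_cascade(
      utils::modifyList(clean_variant(), as.list(out[i, ])),
      thr)$failed_filters
  }, logical(1))
  expect_true(all(flagged))
  # far-apart variants are singletons
  out2 <- cluster_variants(data.frame(sample_id = "S1", chrom = "chr1",
                                      pos = c(100L, 5000L)), 100)
  expect_identical(out2$cluster_size, c(1L, 1L))
  # a pair is a cluster of size 2 and is NOT flagged (rule is > 2)
  out3 <- cluster_variants(data.frame(sample_id = "S1", chrom = "chr1",
                                      pos = c(100L, 150L)), 100)
  expect_identical(out3$cluster_size, c(2L, 2L))
  rec <- utils::modifyList(clean_variant(), as.list(out3[1, ]))
  expect_false("mutation_cluster" %in%
                 apply_filter_cascade(rec, thr)$failed_filters)
  # clusters never chain across samples or chromosomes
  out4 <- cluster_variants(data.frame(sample_id = c("S1", "S2", "S2"),
                                      chrom = c("chr1", "chr1", "chr2"),
                                      pos = c(100L, 150L, 160L)), 100)
  expect_identical(out4$cluster_size, c(1L, 1L, 1L))
})

test_that("consequence selection follows the fixed severity ordering", {
  out <- select_consequence(c("synonymous_variant", "stop_gained"))
  expect_identical(out$top_term, "stop_gained")
  expect_true(out$deleterious)
  out <- select_consequence("synonymous_variant")
  expect_identical(out$top_term, "synonymous_variant")
  expect_false(out$deleterious)
  # frameshift outranks in-frame loss/gain
  out <- select_consequence(c("inframe_deletion", "frameshift_variant"))
  expect_identical(out$top_term, "frameshift_variant")
  expect_true(out$deleterious)
  # splice region is deleterious but below stop lost
  out <- select_consequence(c("splice_region_variant", "stop_lost"))
  expect_identical(out$top_term, "stop_lost")
  expect_error(select_consequence(character()), "non-empty")
})

test_that("mutational signatures fold strand-symmetric categories", {
  recs <- data.frame(ref = c("C", "G", "A"), alt = c("T", "A", "G"))
  sig <- mutational_signature(recs)
  expect_equal(unname(sig["C>T/G>A"]), 2 / 3)
  expect_equal(unname(sig["T>C/A>G"]), 1 / 3)
  expect_equal(sum(sig), 1)
  # no SNVs: all zero
  expect_equal(sum(mutational_signature(
    data.frame(ref = "AT", alt = "A"))), 0)
  expect_equal(sum(mutational_signature(
    data.frame(ref = character(), alt = character()))), 0)
  # uniform draws over the 12 substitution types approach 1/6 each
  set.seed(42)
  ref <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1), character(1))
  sig <- mutational_signature(data.frame(ref = ref, alt = alt))
  expect_true(all(abs(sig - 1 / 6) < 0.06))
  expect_equal(sum(sig), 1)
})

test_that("driver subgroup assignment respects the priority ladder", {
  v <- function(gene, pc = "p.?") data.frame(gene = gene,
                                             protein_change = pc)
  expect_identical(assign_driver_subgroup(
    rbind(v("NF2", "p.Lys79fs"), v("SMARCB1", "p.Arg383Gln"))),
    "NF2/SMARCB1")
  expect_identical(assign_driver_subgroup(
    rbind(v("TRAF7"), v("KLF4", "p.Lys409Gln"))), "TRAF7/KLF4")
  # TRAF7/PI3K outranks TRAF7/KLF4 when both co-mutations present
  expect_identical(assign_driver_subgroup(
    rbind(v("TRAF7"), v("PIK3CA"), v("KLF4", "p.Lys409Gln"))),
    "TRAF7/PI3K")
  # NF2 loss via chr22 deletion alone is an NF2 subgroup call
  expect_identical(assign_driver_subgroup(v("OTHER"), chr22_loss = TRUE),
                   "NF2")
  # SMARCB1 hotspot without any NF2 hit does not make NF2/SMARCB1
  expect_identical(assign_driver_subgroup(v("SMARCB1", "p.Arg383Gln")),
                   "unknown")
  expect_identical(assign_driver_subgroup(v("SUFU")), "Hedgehog")
  expect_identical(assign_driver_subgroup(v("POLR2A", "p.Gln403Lys")),
                   "POLR2A")
  # POLR2A without a recurrent hotspot change does not qualify
  expect_identical(assign_driver_subgroup(v("POLR2A", "p.Ala100Thr")),
                   "unknown")
  expect_identical(assign_driver_subgroup(v("NOTHING")), "unknown")
})

test_that("clonality implements the purity- and ploidy-corrected CCF", {
  # clonal het in a pure diploid tumour
  est <- clonality(50, 50, purity = 1, tumour_cn = 2)
  expect_equal(est$multiplicity, 1)
  expect_equal(est$ccf, 1.0)
  # VAF 0.25 at purity 0.5, cn 2: D = 2, m = 1, ccf = 1
  est <- clonality(25, 75, purity = 0.5, tumour_cn = 2)
  expect_equal(est$ccf, 1.0)
  # subclonal: VAF 0.2 in a pure diploid gives ccf 0.4
  est <- clonality(20, 80, purity = 1, tumour_cn = 2)
  expect_equal(est$ccf, 0.4)
  # multiplicity is clamped into [1, cn]
  est <- clonality(95, 5, purity = 1, tumour_cn = 3)
  expect_lte(est$multiplicity, 3)
  expect_gte(est$multiplicity, 1)
  expect_lte(est$ccf, 1.05)
  expect_error(clonality(10, 10, purity = 0), "purity")
  expect_error(clonality(0, 0, purity = 0.5), "depth")
})

test_that("subgroups and clonal NF2 mutations are recovered on a synthetic cohort", {
  cfg <- cohort_config(n_atypical = 6, n_benign = 8, seed = 11)
  dir <- withr::local_tempdir()
  gen <- generate_cohort(cfg, dir)
  variants <- read_variant_table(file.path(dir, "variants.tsv"))
  filtered <- do.call(rbind, lapply(split(variants, variants$sample_id),
                                    filter_variant_table))
  pass <- filtered[filtered$passed, ]
  # the planted low-score artifact is removed, drivers survive
  expect_false(any(pass$gene == "ARTIFACT"))
  expect_true(all(c("NF2", "TRAF7") %in% pass$gene))
  del <- pass[vapply(strsplit(pass$consequence_terms, ","), function(tt) {
    select_consequence(tt)$deleterious
  }, logical(1)), ]
  truth <- gen$truth$samples
  called <- vapply(truth$sample_id, function(s) {
    assign_driver_subgroup(del[del$sample_id == s, , drop = FALSE],
                           chr22_loss = startsWith(
                             truth$subgroup[truth$sample_id == s], "NF2"))
  }, character(1))
  expect_identical(unname(called), truth$subgroup)
  # planted clonal NF2 mutations at purity >= 0.5, depth >= 100:
  # median estimated ccf near 1
  nf2 <- del[del$gene == "NF2", ]
  ccfs <- vapply(seq_len(nrow(nf2)), function(i) {
    p <- truth$purity[truth$sample_id == nf2$sample_id[i]]
    clonality(nf2$tumour_alt_depth[i], nf2$tumour_ref_depth[i], p, 2)$ccf
  }, numeric(1))
  expect_gte(median(ccfs), 0.9)
  expect_lte(median(ccfs), 1.05)
})
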