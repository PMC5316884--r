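arms2 <- data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                    arm = rep(c("p", "q"), 2),
                    start = rep(c(1, 60e6 + 1), 2),
                    end = rep(c(60e6, 130e6), 2))
attr(arms2, "genome_total_bp") <- 4 * 6.5e7  # 260 Mb toy genome

seg <- function(chrom = "chr1", start = 1, end = 24e6, logR = -0.3,
                baf_dev = 0.2, n_snps = 100) {
  data.frame(chrom = chrom, start = start, end = end, logR = logR,
             baf_dev = baf_dev, n_snps = n_snps)
}

test_that("purity follows the closed form p = 4d/(1+2d)", {
  loss <- function(d) data.frame(baf_dev = d, n_snps = 100,
                                 event_class = "large_loss")
  expect_equal(estimate_purity(loss(0.5)), 1.0)
  expect_equal(estimate_purity(loss(0.25)), 2 / 3)
  expect_equal(estimate_purity(loss(0.1)), 1 / 3)
  # weighting by SNP count
  two <- rbind(loss(0.1), loss(0.5))
  two$n_snps <- c(100, 300)
  d <- (0.1 * 100 + 0.5 * 300) / 400
  expect_equal(estimate_purity(two), 4 * d / (1 + 2 * d))
  # no qualifying segments
  expect_error(estimate_purity(data.frame(baf_dev = 0.2, n_snps = 5,
                                          event_class = "large_loss")),
               "no qualifying")
  expect_error(estimate_purity(data.frame(baf_dev = 0.2, n_snps = 100,
                                          event_class = "large_gain")),
               "no qualifying")
})

test_that("purity is recovered from simulated BAF cohorts within 0.05", {
  for (p in c(0.3, 0.5, 0.8)) {
    baf <- simulate_baf(500, p, 1, 300, seed = round(1000 * p))
    d <- mean(abs(baf - 0.5))
    p_hat <- estimate_purity(data.frame(baf_dev = d, n_snps = 300,
                                        event_class = "large_loss"))
    expect_lt(abs(p_hat - p), 0.05)
  }
})

test_that("simulated BAFs match the admixture algebra", {
  # pure tumour, hemizygous loss: BAFs on {0, 1}, deviation 0.5
  b <- simulate_baf(1000, 1, 1, 200, seed = 1)
  expect_true(all(b %in% c(0, 1)))
  expect_equal(mean(abs(b - 0.5)), 0.5)
  # no tumour signal: mean BAF about 0.5
  b <- simulate_baf(1000, 0, 1, 500, seed = 2)
  expect_lt(abs(mean(b) - 0.5), 0.01)
  # purity 0.5, cn 1: mean deviation 0.5 - (1-p)/(2-p) = 1/6
  b <- simulate_baf(1000, 0.5, 1, 500, seed = 3)
  se <- sqrt(1 / 6 * 5 / 6 / 1000 / 500) * 500  # loose bound
  expect_lt(abs(mean(abs(b - 0.5)) - 1 / 6), 0.01)
  # determinism
  expect_identical(simulate_baf(100, 0.6, 1, 50, seed = 9),
                   simulate_baf(100, 0.6, 1, 50, seed = 9))
  expect_error(simulate_baf(100, 0.5, 5, 10), "tumour_cn")
})

test_that("segment classification implements the rule table", {
  cases <- list(
    # f, logR, baf_dev -> class (arm chr1p is 60 Mb)
    list(0.40, -0.30, 0.20, "large_loss"),
    list(0.40, 0.30, 0.20, "large_gain"),
    list(0.20, 0.15, 0.08, "focal_gain"),
    list(0.20, -0.15, 0.08, "focal_loss"),
    list(0.40, -0.30, 0.02, "none"),   # BAF false-positive correction
    list(0.40, 0.05, 0.20, "cn_loh"),
    list(0.40, -0.10, 0.20, "cn_loh"), # logR exactly at the bound
    list(0.20, 0.05, 0.20, "none"),    # focal cn-LOH is not a class
    list(1 / 3, -0.30, 0.20, "focal_loss"),  # f = 1/3 boundary: focal
    list(0.334, -0.30, 0.20, "large_loss"),
    list(0.10, -0.30, 0.20, "none"),   # f = 1/10 boundary: below focal
    list(0.101, -0.30, 0.20, "focal_loss"),
    list(0.05, -0.50, 0.30, "none"),
    list(0.40, 0.10, 0.02, "none"),
    list(0.20, 0.00, 0.20, "none"))
  for (cs in cases) {
    s <- seg(end = round(6e7 * cs[[1]]), logR = cs[[2]], baf_dev = cs[[3]])
    expect_identical(classify_segment(s, arms2), cs[[4]],
                     label = sprintf("f=%.3f logR=%.2f dev=%.2f",
                                     cs[[1]], cs[[2]], cs[[3]]))
  }
  expect_error(classify_segment(seg(chrom = "chr9"), arms2), "arm table")
})

test_that("segments spanning the centromere are split before classification", {
  spanning <- seg(start = 30e6, end = 90e6, logR = -0.4, baf_dev = 0.2,
                  n_snps = 120)
  pieces <- split_at_arms(spanning, arms2)
  expect_equal(nrow(pieces), 2)
  expect_equal(pieces$end[1], 60e6)
  expect_equal(pieces$start[2], 60e6 + 1)
  expect_equal(sum(pieces$n_snps), 120)
  cls <- classify_segments(spanning, arms2)
  expect_identical(cls$event_class, c("large_loss", "large_loss"))
})

test_that("PGA counts loss/gain once and excludes copy-neutral LOH", {
  # one 26 Mb loss on the 260 Mb toy genome -> 10%
  s <- classify_segments(seg(end = 26e6), arms2)
  expect_equal(compute_pga(s, arms2), 10, tolerance = 1e-9)
  # no events -> 0
  s0 <- classify_segments(seg(logR = 0, baf_dev = 0.01), arms2)
  expect_equal(compute_pga(s0, arms2), 0)
  # loss + gain + cn-LOH: cn-LOH excluded unless requested
  s3 <- classify_segments(rbind(
    seg(end = 26e6, logR = -0.4),                      # 26 Mb loss
    seg(chrom = "chr2", end = 13e6, logR = 0.4),       # 13 Mb gain
    seg(start = 60e6 + 1, end = 112e6, logR = 0)),     # 52 Mb cn-LOH
    arms2)
  expect_identical(sort(s3$event_class),
                   c("cn_loh", "focal_gain", "large_loss"))
  expect_equal(compute_pga(s3, arms2), 100 * 39e6 / 260e6)
  expect_equal(compute_pga(s3, arms2, include_cn_loh = TRUE),
               100 * 91e6 / 260e6)
  # invariance under segment splitting
  whole <- classify_segments(seg(end = 40e6), arms2)
  halves <- classify_segments(rbind(seg(end = 20e6),
                                    seg(start = 20e6 + 1, end = 40e6)),
                              arms2)
  expect_equal(compute_pga(whole, arms2), compute_pga(halves, arms2))
  # overlapping altered segments counted once
  overlap <- classify_segments(rbind(seg(end = 30e6),
                                     seg(start = 10e6, end = 40e6)),
                               arms2)
  expect_equal(compute_pga(overlap, arms2), 100 * 40e6 / 260e6)
})

test_that("CNV status uses a strict threshold and the cohort mean", {
  pga <- c(a = 10, b = 0, c = 2, d = 8)
  expect_identical(unname(cnv_status(pga, 5)),
                   c("high", "low", "low", "high"))
  expect_identical(unname(cnv_status(pga, "cohort_mean")),
                   c("high", "low", "low", "high"))
  # all-equal PGA: nothing exceeds the mean strictly
  expect_identical(unname(cnv_status(c(a = 3, b = 3, c = 3))),
                   c("low", "low", "low"))
  expect_error(cnv_status(c(a = 1), "cohort_mean"), "2 samples")
  # planted cohort separation (atypical ~12%, benign ~1%) is exact
  set.seed(5)
  pga2 <- c(rnorm(10, 12, 1), abs(rnorm(10, 1, 0.5)))
  names(pga2) <- sprintf("S%02d", 1:20)
  st <- cnv_status(pga2)
  expect_identical(unname(st), rep(c("high", "low"), each = 10))
})

test_that("arm-level event association ranks planted enrichment first", {
  # extreme 10/10 vs 0/10 split reproduces the exact Fisher p
  ev <- data.frame(sample_id = sprintf("A%02d", 1:10), chrom = "chr14",
                   arm = "q", event_class = "large_loss")
  grades <- setNames(rep(c("atypical", "benign"), each = 10),
                     c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10)))
  res <- arm_event_association(ev, grades)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  # identical frequencies give p = 1
  ev2 <- data.frame(sample_id = c("A01", "B01"), chrom = "chr1",
                    arm = "p", event_class = "large_loss")
  expect_equal(arm_event_association(ev2, grades)$p, 1)
  # planted 14q enrichment (60% vs 10%, n = 30/30) ranks 14q first
  set.seed(7)
  g3 <- setNames(rep(c("atypical", "benign"), each = 30),
                 sprintf("S%03d", 1:60))
  rows <- list()
  for (s in names(g3)) {
    p14 <- if (g3[[s]] == "atypical") 0.6 else 0.1
    if (runif(1) < p14) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, chrom = "chr14", arm = "q",
        event_class = "large_loss")
    }
    if (runif(1) < 0.2) {  # background arm events at equal rates
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, chrom = sample(paste0("chr", 1:10), 1),
        arm = sample(c("p", "q"), 1), event_class = "large_gain")
    }
  }
  res3 <- arm_event_association(do.call(rbind, rows), g3)
  expect_identical(res3$chrom[1], "chr14")
})

test_that("per-gene CNV association matches the exact rank-sum test", {
  m <- matrix(c(-0.3, -0.3, -0.3, 0, 0, 0), 1,
              dimnames = list("PTEN", sprintf("S%d", 1:6)))
  grades <- setNames(rep(c("atypical", "benign"), each = 3),
                     colnames(m))
  m <- rbind(m, OTHER = rep(0.01, 6))
  res <- gene_cnv_association(m, grades)
  # complete separation at n = 3/3: exact two-sided p = 2/choose(6,3)
  expect_equal(res$p[res$gene == "PTEN"], 0.1, tolerance = 1e-12)
  expect_equal(res$median_diff[res$gene == "PTEN"], -0.3)
  expect_equal(res$p[res$gene == "OTHER"], 1)
  # length-weighted gene logR mapping
  genes <- data.frame(gene = "PTEN", chrom = "chr1", start = 100,
                      end = 1099)
  segs <- rbind(
    data.frame(sample_id = "S1", chrom = "chr1", start = 1, end = 599,
               logR = -0.4),
    data.frame(sample_id = "S1", chrom = "chr1", start = 600, end = 2000,
               logR = 0))
  glr <- gene_logr_matrix(genes, segs)
  expect_equal(glr["PTEN", "S1"], (500 * -0.4 + 500 * 0) / 1000)
  expect_warning(gene_logr_matrix(
    data.frame(gene = "MISS", chrom = "chr9", start = 1, end = 10), segs),
    "no overlapping segment")
})

test_that("instability profiles recover planted CNV labels end to end", {
  cfg <- cohort_config(n_atypical = 5, n_benign = 5, seed = 21,
                       fraction_cnv_high = c(benign = 0, atypical = 1))
  dir <- withr::local_tempdir()
  gen <- generate_cohort(cfg, dir)
  segments <- utils::read.delim(file.path(dir, "segments.tsv"))
  arms <- utils::read.delim(file.path(dir, "arm_table.tsv"))
  prof <- instability_profiles(segments, arms)
  truth <- gen$truth$samples
  got <- prof$profiles
  expect_identical(got$cnv_status[match(truth$sample_id, got$sample_id)],
                   truth$cnv_status)
  # recovered PGA tracks the planted PGA closely
  expect_lt(max(abs(got$pga[match(truth$sample_id, got$sample_id)] -
                      gen$truth$pga)), 1)
  # estimated purity from loss-segment BAFs is close to truth
  for (s in truth$sample_id) {
    ev <- prof$events[prof$events$sample_id == s, ]
    p_hat <- tryCatch(estimate_purity(ev), error = function(e) NA)
    if (!is.na(p_hat)) {
      expect_lt(abs(p_hat - truth$purity[truth$sample_id == s]), 0.08)
    }
  }
})
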