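# Independent brute-force oracles used to validate the implementations.

# Two-sided Fisher p by direct hypergeometric enumeration: sum of the
# probabilities of all tables (with the observed margins) no more likely
# than the observed one.
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the step-up definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Super-enhancer cutoff by an explicit scan over consecutive segments of
# the scaled rank curve.
oracle_super <- function(signal) {
  n <- length(signal)
  if (max(signal) == min(signal)) return(rep(FALSE, n))
  o <- order(signal)
  y <- (signal[o] - min(signal)) / (max(signal) - min(signal))
  x <- (seq_len(n) - 1) / (n - 1)
  cut <- NA
  for (i in seq_len(n - 1)) {
    if ((y[i + 1] - y[i]) / (x[i + 1] - x[i]) >= 1) {
      cut <- i
      break
    }
  }
  fl <- rep(FALSE, n)
  if (!is.na(cut)) fl[o[(cut + 1):n]] <- TRUE
  fl
}

# Hypergeometric upper-tail sum from the definition.
enum_hyper_tail <- function(q_hits, bg_hits, n_query, n_bg) {
  ks <- q_hits:min(n_query, bg_hits)
  sum(choose(bg_hits, ks) * choose(n_bg - bg_hits, n_query - ks)) /
    choose(n_bg, n_query)
}

# Planted one-regulator/one-decoy miRNA network instance.
planted_network <- function(n_samples = 22, noise = 0.5, seed = 1) {
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  mirna <- matrix(rnorm(n_samples, 5, 1), 1,
                  dimnames = list("mir-1", samples))
  target <- -mirna[1, ] + rnorm(n_samples, 0, noise)
  decoy <- rnorm(n_samples, 0, 1)
  genes <- rbind(TARGET = target, DECOY = decoy)
  colnames(genes) <- samples
  evidence <- rbind(
    data.frame(mirna_id = "mir-1", gene_id = "TARGET",
               source_db = c("miranda", "pictar", "targetscan",
                             "tarbase")),
    data.frame(mirna_id = "mir-1", gene_id = "DECOY",
               source_db = c("miranda", "pictar", "targetscan")))
  list(mirna = mirna, genes = genes, evidence = evidence)
}
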