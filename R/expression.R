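#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution:
#' after normalization each sample's sorted values equal the cross-sample
#' mean quantile vector, with tied values sharing their mean quantile.
#'
#' @param matrix features x samples numeric matrix.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2) stop("need at least 2 samples")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Location/scale batch adjustment
#'
#' Per feature, shifts each batch to the grand mean and rescales each
#' batch standard deviation to the pooled (within-batch) standard
#' deviation. This is a simplified batch correction without
#' empirical-Bayes shrinkage across features; it matches the additive
#' batch shifts the synthetic cohort plants. A single batch is returned
#' unchanged.
#'
#' @param matrix features x samples numeric matrix.
#' @param batch_labels character/factor of length `ncol(matrix)`.
#' @return adjusted matrix.
#' @export
batch_adjust <- function(matrix, batch_labels) {
  batch_labels <- as.character(batch_labels)
  if (length(batch_labels) != ncol(matrix)) {
    stop("`batch_labels` must match the number of samples")
  }
  batches <- unique(batch_labels)
  if (length(batches) == 1) return(matrix)
  sizes <- table(batch_labels)
  if (any(sizes < 2)) {
    stop(sprintf("batch '%s' has fewer than 2 samples",
                 names(sizes)[which(sizes < 2)[1]]))
  }
  grand <- rowMeans(matrix)
  b_mean <- sapply(batches, function(b) {
    rowMeans(matrix[, batch_labels == b, drop = FALSE])
  })
  b_var <- sapply(batches, function(b) {
    apply(matrix[, batch_labels == b, drop = FALSE], 1, stats::var)
  })
  df <- as.numeric(sizes[batches]) - 1
  pooled_sd <- sqrt(as.vector(b_var %*% df) / sum(df))
  out <- matrix
  for (b in batches) {
    cols <- batch_labels == b
    sb <- sqrt(b_var[, b])
    scale <- ifelse(sb > 0, pooled_sd / sb, 1)
    out[, cols] <- (matrix[, cols, drop = FALSE] - b_mean[, b]) * scale + grand
  }
  out
}

# Inverse of trigamma by Newton iteration on 1/trigamma (approximately
# linear), following the standard construction for moment estimation of
# the prior degrees of freedom.
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# Method-of-moments fit of the scaled inverse-chi-square prior for
# residual variances: returns d0 (prior df, possibly Inf) and s02 (prior
# variance) from per-feature variances s2 on df residual degrees of
# freedom, using the moments of log s2.
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = stats::median(s2, na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar <= 0) {
    return(list(d0 = Inf, s02 = exp(emean)))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group differential test, optionally stratified
#'
#' Per feature, fits the additive linear model
#' `value ~ grade (+ stratum)` and computes a moderated t-statistic for
#' the grade coefficient: the residual variance s^2 on d degrees of
#' freedom is shrunk toward a prior, s_tilde^2 = (d0 s0^2 + d s^2) /
#' (d0 + d), with the prior (d0, s0^2) estimated by method of moments on
#' the distribution of log s^2 across features; t = coef / (s_tilde *
#' SE-factor) is referred to a t distribution on d0 + d degrees of
#' freedom, and p-values are Benjamini-Hochberg adjusted.
#'
#' @param matrix features x samples numeric matrix (log2 scale for
#'   expression).
#' @param grades character/factor of length `ncol(matrix)` with exactly
#'   two levels. When the levels are benign/atypical the reported log
#'   fold change is atypical - benign; otherwise it is second versus
#'   first level in sorted order.
#' @param strata optional stratification factor (e.g. NF2 status); the
#'   design must not alias grade with stratum.
#' @param prior optional list(d0=, s02=) overriding the estimated
#'   hyperparameters (d0 may be 0 for the ordinary t or Inf for the fully
#'   pooled prior).
#' @return data frame with `feature`, `logFC`, `t`, `p`, `adj_p`;
#'   attributes `d0`, `s02`, `df_residual`.
#' @export
moderated_de <- function(matrix, grades, strata = NULL, prior = NULL) {
  g <- as.character(grades)
  lev <- if (setequal(unique(g), c("benign", "atypical"))) {
    c("benign", "atypical")
  } else {
    sort(unique(g))
  }
  if (length(lev) != 2) stop("grades must have exactly two levels")
  grades <- factor(g, levels = lev)
  if (min(table(grades)) < 2) stop("need at least 2 samples per grade")
  if (is.null(strata)) {
    design <- stats::model.matrix(~grades)
  } else {
    strata <- factor(as.character(strata))
    design <- stats::model.matrix(~ grades + strata)
  }
  if (qr(design)$rank < ncol(design)) {
    stop("confounded design: grade is aliased with stratum")
  }
  n <- ncol(matrix)
  d <- n - ncol(design)
  if (d < 1) stop("no residual degrees of freedom")
  fit <- stats::lm.fit(design, t(matrix))
  coefs <- t(fit$coefficients)
  logfc <- coefs[, 2]
  s2 <- colSums(fit$residuals^2) / d
  xtxinv <- chol2inv(chol(crossprod(design)))
  v_grade <- xtxinv[2, 2]
  pr <- if (is.null(prior)) .fit_variance_prior(s2, d) else prior
  d0 <- pr$d0
  s02 <- pr$s02
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- rep(d0 + d, length(s2))
  }
  tstat <- logfc / sqrt(s2_post * v_grade)
  p <- 2 * stats::pt(-abs(tstat), df_total)
  feats <- rownames(matrix)
  if (is.null(feats)) feats <- sprintf("feature%d", seq_len(nrow(matrix)))
  out <- data.frame(feature = feats, logFC = as.numeric(logfc),
                    t = as.numeric(tstat), p = as.numeric(p),
                    row.names = NULL)
  out$adj_p <- bh_fdr(out$p)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_residual") <- d
  out
}

# Mean silhouette width of `labels` on a coordinate matrix (rows =
# samples), Euclidean distance.
.mean_silhouette <- function(coords, labels) {
  labels <- as.character(labels)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  widths <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}

#' Differential-expression signature, PCA and grade separation
#'
#' The signature is the set of features significant at adjusted p < 0.05.
#' Principal components are computed on the signature submatrix (features
#' centred and unit-scaled); the mean silhouette width of the grade
#' labels on the first two components quantifies grade separation.
#'
#' @param de result of [moderated_de()].
#' @param matrix the features x samples matrix the test was run on.
#' @param grades grade labels per sample.
#' @param alpha adjusted-p cutoff for the signature (default 0.05).
#' @return list with `signature` (feature ids), `pca` (samples x PC
#'   coordinate matrix, or NULL), `silhouette` (mean width by grade on
#'   PC1-2, or NA).
#' @export
signature_and_pca <- function(de, matrix, grades, alpha = 0.05) {
  signature <- de$feature[de$adj_p < alpha]
  sub <- matrix[rownames(matrix) %in% signature, , drop = FALSE]
  sub <- sub[apply(sub, 1, stats::sd) > 0, , drop = FALSE]
  if (nrow(sub) < 2) {
    warning("signature too small for PCA; skipping")
    return(list(signature = signature, pca = NULL, silhouette = NA_real_))
  }
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = TRUE)
  coords <- pc$x[, 1:2, drop = FALSE]
  list(signature = signature, pca = pc$x,
       silhouette = .mean_silhouette(coords, grades))
}

#' Random-forest grade classifier on top differential genes
#'
#' Selects the `n_top` genes with smallest adjusted p from the
#' differential test, trains a random forest on them, and reports the
#' out-of-bag error rate; optionally evaluates on a held-out set.
#'
#' @param matrix features x samples training matrix.
#' @param grades grade labels per training sample.
#' @param de result of [moderated_de()] on the training data.
#' @param n_top number of top genes to use (default 25); must not exceed
#'   the number of significant genes (adjusted p < 0.05).
#' @param n_trees number of trees (default 5000).
#' @param seed integer RNG seed; the same seed reproduces the same model
#'   and OOB error.
#' @param test_matrix,test_grades optional held-out features x samples
#'   matrix and labels for external evaluation.
#' @return list with `model`, `features`, `oob_error` (fraction), and
#'   `external_accuracy` (fraction or NA).
#' @export
rf_grade_classifier <- function(matrix, grades, de, n_top = 25,
                                n_trees = 5000, seed = 1,
                                test_matrix = NULL, test_grades = NULL) {
  grades <- factor(as.character(grades))
  if (nlevels(grades) < 2) stop("training labels contain a single class")
  n_sig <- sum(de$adj_p < 0.05)
  if (n_top > n_sig) {
    stop(sprintf("n_top (%d) exceeds the %d significant genes", n_top, n_sig))
  }
  feats <- de$feature[order(de$adj_p, de$p)][seq_len(n_top)]
  x <- t(matrix[feats, , drop = FALSE])
  set.seed(seed)
  model <- randomForest::randomForest(x, grades, ntree = n_trees)
  oob <- as.numeric(model$err.rate[n_trees, "OOB"])
  ext <- NA_real_
  if (!is.null(test_matrix)) {
    pred <- stats::predict(model, t(test_matrix[feats, , drop = FALSE]))
    ext <- mean(as.character(pred) == as.character(test_grades))
  }
  list(model = model, features = feats, oob_error = oob,
       external_accuracy = ext)
}
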