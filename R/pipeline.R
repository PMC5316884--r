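#' Default pipeline configuration
#'
#' Builds a validated pipeline configuration. Inputs come either from a
#' synthetic cohort generated on the fly (`cohort` = a
#' [cohort_config()]) or from an existing input directory laid out like
#' [generate_cohort()] output.
#'
#' @param out_dir output directory for stage results and the manifest.
#' @param cohort a [cohort_config()], or NULL when `input_dir` is given.
#' @param input_dir directory of existing inputs (ignored when `cohort`
#'   is given).
#' @param stages named logical vector toggling stages; defaults enable
#'   all of `variants`, `cnv`, `clonality`, `expression`, `mirna`,
#'   `methylation`, `chip`, `tert`.
#' @param seed master seed for stage-level randomness (consensus
#'   clustering, random forest).
#' @param thresholds named list of threshold overrides; recognised keys:
#'   `de_alpha` (default 0.05), `min_dbs` (3), `stitch_bp` (12500),
#'   `tss_exclude_bp` (2000), `cnv_status_threshold` ("cohort_mean"),
#'   `consensus_iter` (200), `consensus_k` (2), `rf_trees` (1000),
#'   `rf_top` (25).
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = NULL, input_dir = NULL,
                            stages = NULL, seed = 1, thresholds = list()) {
  stage_names <- c("variants", "cnv", "clonality", "expression", "mirna",
                   "methylation", "chip", "tert")
  st <- stats::setNames(rep(TRUE, length(stage_names)), stage_names)
  if (!is.null(stages)) {
    unknown <- setdiff(names(stages), stage_names)
    if (length(unknown)) stop("unknown stage '", unknown[1], "'")
    st[names(stages)] <- stages
  }
  if (is.null(cohort) && is.null(input_dir)) {
    stop("either `cohort` or `input_dir` is required")
  }
  if (!is.null(input_dir) && is.null(cohort) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  defaults <- list(de_alpha = 0.05, min_dbs = 3, stitch_bp = 12500,
                   tss_exclude_bp = 2000,
                   cnv_status_threshold = "cohort_mean",
                   consensus_iter = 200, consensus_k = 2,
                   rf_trees = 1000, rf_top = 25)
  thresholds <- utils::modifyList(defaults, thresholds)
  structure(list(out_dir = out_dir, cohort = cohort,
                 input_dir = input_dir, stages = st, seed = seed,
                 thresholds = thresholds),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML mirrors [pipeline_config()] arguments; a `cohort` block is
#' passed to [cohort_config()].
#'
#' @param path YAML file path.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) do.call(cohort_config, y$cohort)
  pipeline_config(out_dir = y$out_dir, cohort = cohort,
                  input_dir = y$input_dir,
                  stages = unlist(y$stages), seed = y$seed %||% 1,
                  thresholds = y$thresholds %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the integrated analysis pipeline
#'
#' Executes the enabled stages in dependency order on one input bundle:
#' variant filtering and driver-subgroup assignment; CNV classification,
#' purity, PGA and CNV status; per-variant clonality (requires the CNV
#' stage for purity); expression normalization, batch adjustment,
#' differential expression, signature PCA and the random-forest grade
#' classifier; miRNA differential expression and target-network
#' inference; methylation differential sites and consensus clustering;
#' enhancer stitching, super-enhancer calling, differential binding and
#' expression concordance; and the promoter-hotspot recurrence report.
#' Every stage writes a TSV under `out_dir` and is recorded in a JSON
#' manifest together with the seed and all thresholds used; re-running
#' an identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param dry_run if TRUE, print the stage plan and return it without
#'   writing anything.
#' @return invisibly, a named list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  if (st[["clonality"]] && !st[["cnv"]]) {
    stop("dependency error: stage 'clonality' requires stage 'cnv' ",
         "(tumour purity)")
  }
  if (st[["clonality"]] && !st[["variants"]]) {
    stop("dependency error: stage 'clonality' requires stage 'variants'")
  }
  plan <- names(st)[st]
  if (dry_run) {
    message("stage plan: ", paste(plan, collapse = " -> "))
    return(invisible(plan))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  results <- list()
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs[[name]] <<- path
  }

  in_dir <- config$input_dir
  if (!is.null(config$cohort)) {
    in_dir <- file.path(config$out_dir, "inputs")
    gen <- generate_cohort(config$cohort, in_dir)
    results$truth <- gen$truth
  }
  sheet <- utils::read.delim(file.path(in_dir, "samples.tsv"))
  grades <- stats::setNames(sheet$grade, sheet$sample_id)
  arms <- utils::read.delim(file.path(in_dir, "arm_table.tsv"))

  variants <- NULL
  if (st[["variants"]]) {
    variants <- read_variant_table(file.path(in_dir, "variants.tsv"))
    variants <- do.call(rbind, lapply(split(variants, variants$sample_id),
                                      filter_variant_table))
    emit(variants[, setdiff(names(variants),
                            c("tumour_gl", "normal_gl"))], "variants_filtered")
    results$variants <- variants
  }

  profiles <- NULL
  purity <- NULL
  if (st[["cnv"]]) {
    segments <- utils::read.delim(file.path(in_dir, "segments.tsv"))
    prof <- instability_profiles(segments, arms,
                                 thr$cnv_status_threshold)
    purity <- vapply(split(prof$events, prof$events$sample_id),
                     function(ev) {
                       tryCatch(estimate_purity(ev), error = function(e)
                         NA_real_)
                     }, numeric(1))
    prof$profiles$purity <- as.numeric(purity[prof$profiles$sample_id])
    emit(prof$profiles, "cnv_profiles")
    emit(prof$events, "cnv_events")
    results$cnv <- prof
    profiles <- prof$profiles
  }

  if (st[["clonality"]]) {
    pass <- variants[variants$passed, , drop = FALSE]
    deleterious <- vapply(strsplit(pass$consequence_terms, ","),
                          function(terms) {
                            select_consequence(terms)$deleterious
                          }, logical(1))
    pur <- stats::setNames(profiles$purity, profiles$sample_id)
    cl <- do.call(rbind, lapply(which(deleterious), function(i) {
      p <- pur[[pass$sample_id[i]]]
      if (is.na(p)) return(NULL)
      est <- clonality(pass$tumour_alt_depth[i], pass$tumour_ref_depth[i],
                       p, 2)
      data.frame(sample_id = pass$sample_id[i], gene = pass$gene[i],
                 vaf = est$vaf, multiplicity = est$multiplicity,
                 ccf = est$ccf)
    }))
    emit(cl, "clonality")
    results$clonality <- cl
  }

  if (st[["variants"]]) {
    pass <- variants[variants$passed, , drop = FALSE]
    deleterious <- vapply(strsplit(pass$consequence_terms, ","),
                          function(terms) {
                            select_consequence(terms)$deleterious
                          }, logical(1))
    del <- pass[deleterious, , drop = FALSE]
    chr22_loss <- if (!is.null(results$cnv)) {
      ev <- results$cnv$events
      vapply(sheet$sample_id, function(s) {
        any(ev$sample_id == s & ev$chrom == "chr22" &
              ev$event_class %in% c("large_loss", "focal_loss"))
      }, logical(1))
    } else {
      stats::setNames(rep(FALSE, nrow(sheet)), sheet$sample_id)
    }
    sub <- data.frame(
      sample_id = sheet$sample_id,
      subgroup = vapply(sheet$sample_id, function(s) {
        assign_driver_subgroup(del[del$sample_id == s, , drop = FALSE],
                               chr22_loss[[s]])
      }, character(1)))
    emit(sub, "driver_subgroups")
    results$subgroups <- sub
    sig <- do.call(rbind, lapply(split(pass, pass$sample_id), function(v) {
      as.data.frame(t(mutational_signature(v)))
    }))
    sig <- data.frame(sample_id = rownames(sig), sig, check.names = FALSE)
    emit(sig, "mutational_signatures")
    results$signatures <- sig
  }

  expr_de <- NULL
  expr <- NULL
  if (st[["expression"]]) {
    expr <- read_matrix_tsv(file.path(in_dir, "expression.tsv"))
    expr <- quantile_normalize(expr)
    expr <- batch_adjust(expr, sheet$batch[match(colnames(expr),
                                                 sheet$sample_id)])
    strata <- if (!is.null(results$subgroups)) {
      ifelse(startsWith(results$subgroups$subgroup[
        match(colnames(expr), results$subgroups$sample_id)], "NF2"),
        "NF2", "non-NF2")
    } else NULL
    expr_de <- moderated_de(expr, grades[colnames(expr)], strata)
    emit(expr_de, "expression_de")
    sp <- signature_and_pca(expr_de, expr, grades[colnames(expr)])
    rf <- rf_grade_classifier(expr, grades[colnames(expr)], expr_de,
                              n_top = min(thr$rf_top,
                                          sum(expr_de$adj_p < 0.05)),
                              n_trees = thr$rf_trees, seed = config$seed)
    results$expression <- list(de = expr_de, signature = sp,
                               rf_oob = rf$oob_error)
    emit(data.frame(metric = c("n_signature", "silhouette", "rf_oob"),
                    value = c(length(sp$signature), sp$silhouette,
                              rf$oob_error)), "expression_summary")
  }

  if (st[["mirna"]]) {
    counts <- read_matrix_tsv(file.path(in_dir, "mirna_counts.tsv"))
    logrpm <- rpm_log(counts)
    mde <- suppressWarnings(mirna_de(logrpm, grades[colnames(logrpm)]))
    emit(mde, "mirna_de")
    evidence <- utils::read.delim(file.path(in_dir, "mirna_evidence.tsv"))
    gene_mat <- if (!is.null(expr)) expr else
      read_matrix_tsv(file.path(in_dir, "expression.tsv"))
    edges <- infer_network(logrpm, gene_mat, evidence,
                           min_dbs = thr$min_dbs, alpha = thr$de_alpha)
    emit(edges, "mirna_network")
    results$mirna <- list(de = mde, edges = edges)
  }

  if (st[["methylation"]]) {
    beta <- read_matrix_tsv(file.path(in_dir, "beta.tsv"))
    coords <- utils::read.delim(file.path(in_dir, "beta_coords.tsv"))
    qc <- site_qc(beta, data.frame(site_id = coords$site_id,
                                   chrom = coords$chrom))
    dm <- diff_methylation(qc$beta, grades[colnames(qc$beta)])
    emit(dm, "methylation_dm")
    cc <- consensus_cluster(qc$beta, k_range = thr$consensus_k,
                            n_iter = thr$consensus_iter,
                            seed = config$seed)
    labels <- cc[[as.character(thr$consensus_k)]]$labels
    emit(data.frame(sample_id = names(labels), cluster = labels),
         "methylation_clusters")
    results$methylation <- list(dm = dm, clusters = labels,
                                consensus = cc)
  }

  if (st[["chip"]]) {
    sig <- read_matrix_tsv(file.path(in_dir, "enhancer_signal.tsv"))
    rcoords <- utils::read.delim(file.path(in_dir, "enhancer_coords.tsv"))
    rownames(rcoords) <- rcoords$region_id
    super <- call_super_enhancers(rowMeans(sig))
    cde <- differential_binding(sig, grades[colnames(sig)])
    out <- data.frame(region_id = rownames(sig), is_super = super)
    emit(out, "super_enhancers")
    emit(cde, "enhancer_de")
    results$chip <- list(is_super = stats::setNames(super, rownames(sig)),
                         de = cde)
    if (!is.null(expr_de)) {
      gcoords <- utils::read.delim(file.path(in_dir,
                                             "expression_coords.tsv"))
      conc <- expression_concordance(cde, rcoords, expr_de, gcoords,
                                     alpha = thr$de_alpha)
      emit(conc, "enhancer_concordance")
      results$chip$concordance <- conc
    }
  }

  if (st[["tert"]]) {
    calls <- data.frame(sample_id = character())
    tert_path <- file.path(in_dir, "tert_calls.tsv")
    if (file.exists(tert_path)) calls <- utils::read.delim(tert_path)
    rep_df <- tert_recurrence_report(calls, sheet)
    emit(rep_df, "tert_report")
    results$tert <- rep_df
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("meningiomics")),
    seed = config$seed, stages = as.list(st), thresholds = thr,
    input_dir = in_dir,
    outputs = as.list(outputs),
    output_md5 = as.list(tools::md5sum(unlist(outputs))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
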