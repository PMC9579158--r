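## End-to-end orchestration: synthesize/load -> QC -> per-dataset DE ->
## desirability scoring -> ranking -> pre-ranked GSEA (+ label-permutation
## control) -> report. Every stage writes its outputs under the run directory
## and is recorded, with file hashes and seeds, in a run manifest.

#' Pipeline configuration
#'
#' Exactly one of `input_dir` (a cohort written by [write_cohort()]) or
#' `cohort` (a [cohort_spec()] to synthesize) must be supplied.
#'
#' @param output_dir run directory (created).
#' @param cohort a [cohort_spec()], or `NULL`.
#' @param input_dir directory of on-disk datasets, or `NULL`.
#' @param hk_list housekeeping genes for QC; defaults to the synthetic ground
#'   truth when a cohort is generated.
#' @param midbrain named logical midbrain-detection flags; same default.
#' @param genesets a [geneset_collection()] or GMT path; defaults to a
#'   synthetic collection with one planted set when a cohort is generated.
#' @param qc a [qc_thresholds()].
#' @param desirability a [desirability_params()].
#' @param gsea_min_size,gsea_max_size,gsea_n_perm,gsea_weight GSEA settings.
#' @param run_control also run the label-permutation negative control.
#' @param seed master seed for GSEA permutations and the control shuffle.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            cohort = NULL, input_dir = NULL,
                            hk_list = NULL, midbrain = NULL, genesets = NULL,
                            qc = qc_thresholds(),
                            desirability = desirability_params(),
                            gsea_min_size = 15, gsea_max_size = 500,
                            gsea_n_perm = 1000, gsea_weight = 1,
                            run_control = TRUE, seed = 1L) {
  if (is.null(cohort) && is.null(input_dir))
    abort_param("cohort", "either a cohort spec or an input directory is required")
  if (!is.null(cohort) && !is.null(input_dir))
    abort_param("cohort", "supply a cohort spec or an input directory, not both")
  structure(list(output_dir = output_dir, cohort = cohort,
                 input_dir = input_dir, hk_list = hk_list,
                 midbrain = midbrain, genesets = genesets, qc = qc,
                 desirability = desirability,
                 gsea_min_size = gsea_min_size, gsea_max_size = gsea_max_size,
                 gsea_n_perm = gsea_n_perm, gsea_weight = gsea_weight,
                 run_control = run_control, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `cohort` is a
#' mapping of [cohort_spec()] arguments; `genesets` is a GMT path; `qc` a
#' mapping of [qc_thresholds()] arguments (`--qc-config` on the CLI).
#'
#' @param path YAML file.
#' @param output_dir overrides the file's `output_dir` when non-NULL.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, output_dir = NULL) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) do.call(cohort_spec, y$cohort)
  qc <- if (!is.null(y$qc)) do.call(qc_thresholds, y$qc) else qc_thresholds()
  des <- if (!is.null(y$desirability))
    do.call(desirability_params, y$desirability) else desirability_params()
  pipeline_config(
    output_dir = output_dir %||% y$output_dir,
    cohort = cohort, input_dir = y$input_dir,
    genesets = y$genesets, qc = qc, desirability = des,
    gsea_min_size = y$gsea_min_size %||% 15,
    gsea_max_size = y$gsea_max_size %||% 500,
    gsea_n_perm = y$gsea_n_perm %||% 1000,
    gsea_weight = y$gsea_weight %||% 1,
    run_control = y$run_control %||% TRUE,
    seed = y$seed %||% 1L)
}

#' Pseudobulk (artificial bulk) aggregation
#'
#' Sums read counts across all cells of each subject, yielding one bulk-style
#' column per subject; TPM is recomputed from the summed counts.
#'
#' @param dataset a single-cell [expression_dataset()] (QC-passing cells).
#' @param subject_labels per-cell subject assignment; defaults to the
#'   dataset's metadata `subject` column.
#' @param gene_lengths lengths for TPM recomputation (default 1 kb).
#' @return a bulk [expression_dataset()] with one column per subject.
#' @export
artificial_bulk <- function(dataset, subject_labels = dataset$meta$subject,
                            gene_lengths = 1000) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(subject_labels) != ncol(dataset$counts) ||
      any(is.na(subject_labels)) || any(!nzchar(subject_labels)))
    stop("every cell must be mapped to a subject", call. = FALSE)
  subjects <- unique(subject_labels)
  counts <- vapply(subjects, function(s)
    rowSums(dataset$counts[, subject_labels == s, drop = FALSE]),
    numeric(nrow(dataset$counts)))
  colnames(counts) <- subjects
  storage.mode(counts) <- "integer"
  first <- match(subjects, subject_labels)
  meta <- data.frame(sample_id = subjects, subject = subjects,
                     condition = dataset$meta$condition[first],
                     mapping_rate = vapply(subjects, function(s)
                       mean(dataset$meta$mapping_rate[subject_labels == s]),
                       numeric(1)),
                     stringsAsFactors = FALSE)
  expression_dataset(paste0(dataset$name, "-pseudobulk"), "bulk", counts,
                     tpm_from_counts(counts, gene_lengths), meta)
}

stage_record <- function(stage, files, seeds = NA, note = "") {
  data.frame(stage = stage,
             files = paste(basename(files), collapse = ";"),
             md5 = paste(unname(tools::md5sum(files)), collapse = ";"),
             seed = paste(seeds, collapse = ";"),
             note = note, stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Stages run in order (simulate/load, qc, de, score, gsea, control, report);
#' all outputs are written under `config$output_dir` and recorded in the
#' returned manifest. Rerunning with an identical configuration reproduces
#' all outputs bit for bit. A stage failure aborts with the stage name, and
#' any outputs written so far are moved to a `failed/` subdirectory.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (data.frame of stages, files, hashes, seeds),
#'   `scores`, `enrichment`, `control`, `qc_reports`, `de`, `report_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  current_stage <- "init"

  res <- tryCatch({
    ## stage 1: inputs
    current_stage <- "input"
    if (!is.null(config$cohort)) {
      sim <- generate_cohort(config$cohort)
      datasets <- sim$datasets
      gt <- sim$ground_truth
      hk <- config$hk_list %||% gt$housekeeping_genes
      midbrain <- config$midbrain %||% gt$midbrain_detected
      genesets <- config$genesets %||%
        generate_genesets(gt, seed = child_seed(config$seed, 101))
      man_files <- write_cohort(datasets, gt, file.path(out, "cohort"))
      manifest$input <- stage_record("input", man_files$file,
                                     seeds = config$cohort$seed,
                                     note = "synthetic cohort")
    } else {
      datasets <- read_cohort(config$input_dir)
      gt <- NULL
      hk <- config$hk_list %||% default_hk_genes()
      midbrain <- config$midbrain %||%
        stats::setNames(logical(0), character(0))
      genesets <- config$genesets
      manifest$input <- stage_record("input", config$input_dir,
                                     note = "loaded from disk")
    }
    if (is.character(genesets)) genesets <- read_gmt(genesets)
    if (is.null(genesets)) stop("no gene-set collection available")

    ## stage 2: QC
    current_stage <- "qc"
    qc_reports <- list()
    for (i in seq_along(datasets)) {
      res_qc <- apply_qc(datasets[[i]], config$qc, hk_list = hk)
      datasets[[i]] <- res_qc$dataset
      qc_reports[[datasets[[i]]$name]] <- res_qc$report
      write_qc_report(res_qc$report,
                      file.path(out, sprintf("qc_%s.tsv", datasets[[i]]$name)))
    }
    qc_files <- file.path(out, sprintf("qc_%s.tsv",
                                       vapply(datasets, `[[`, "", "name")))
    manifest$qc <- stage_record(
      "qc", qc_files,
      note = sprintf("%d samples excluded",
                     sum(vapply(qc_reports, function(r) sum(!r$pass), 0L))))

    ## stage 3: DE per dataset
    current_stage <- "de"
    de_list <- list()
    for (ds in datasets) {
      de_list[[ds$name]] <- run_de(ds)
      write_de_result(de_list[[ds$name]],
                      file.path(out, sprintf("de_%s.tsv", ds$name)))
    }
    de_files <- file.path(out, sprintf("de_%s.tsv", names(de_list)))
    manifest$de <- stage_record("de", de_files)

    ## stage 4: scoring and ranking
    current_stage <- "score"
    scores <- score_genes(de_list, midbrain, config$desirability)
    utils::write.table(scores, file.path(out, "gene_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_rnk(scores, file.path(out, "ranked.rnk"))
    manifest$score <- stage_record(
      "score", file.path(out, c("gene_scores.tsv", "ranked.rnk")),
      note = sprintf("%d genes in ranked universe", nrow(scores)))

    ## stage 5: enrichment
    current_stage <- "gsea"
    ranked <- stats::setNames(scores$D_overall, scores$gene)
    ranked <- ranked[order(-ranked, names(ranked))]
    restricted <- restrict_and_filter(genesets, names(ranked),
                                      config$gsea_min_size,
                                      config$gsea_max_size)
    enrichment <- preranked_gsea(ranked, restricted,
                                 n_permutations = config$gsea_n_perm,
                                 seed = child_seed(config$seed, 201),
                                 weight_exponent = config$gsea_weight)
    write_enrichment(enrichment, file.path(out, "enrichment.tsv"))
    manifest$gsea <- stage_record("gsea", file.path(out, "enrichment.tsv"),
                                  seeds = child_seed(config$seed, 201))

    ## stage 6: negative control
    control <- NULL
    if (config$run_control) {
      current_stage <- "control"
      control <- label_permutation_control(
        ranked, restricted, seed = child_seed(config$seed, 301),
        n_permutations = config$gsea_n_perm,
        weight_exponent = config$gsea_weight)
      write_enrichment(control, file.path(out, "enrichment_control.tsv"))
      manifest$control <- stage_record(
        "control", file.path(out, "enrichment_control.tsv"),
        seeds = child_seed(config$seed, 301))
    }

    ## stage 7: report
    current_stage <- "report"
    manifest_df <- do.call(rbind, manifest)
    outputs <- list(qc_reports = qc_reports, de = de_list, scores = scores,
                    enrichment = enrichment, control = control)
    report_path <- file.path(out, "report.md")
    writeLines(report(manifest_df, outputs), report_path)
    manifest_df <- rbind(manifest_df, stage_record("report", report_path))
    utils::write.table(manifest_df, file.path(out, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(manifest = manifest_df, scores = scores, enrichment = enrichment,
         control = control, qc_reports = qc_reports, de = de_list,
         ground_truth = gt, report_path = report_path)
  }, error = function(e) {
    failed <- file.path(out, "failed")
    dir.create(failed, showWarnings = FALSE)
    for (f in list.files(out, full.names = TRUE)) {
      if (basename(f) != "failed")
        file.rename(f, file.path(failed, basename(f)))
    }
    stop(sprintf("pipeline failed at stage '%s': %s",
                 current_stage, conditionMessage(e)), call. = FALSE)
  })
  res
}

#' Human-readable run summary
#'
#' @param manifest data.frame of stage records.
#' @param outputs list with `qc_reports`, `de`, `scores`, `enrichment` and
#'   optionally `control`.
#' @param top_n genes to show in the top-ranked section.
#' @return character vector of markdown lines.
#' @export
report <- function(manifest, outputs, top_n = 10) {
  if (is.null(outputs$scores) || is.null(outputs$qc_reports))
    stop("missing stage outputs; run the pipeline first", call. = FALSE)
  lines <- c("# Dysregulation pipeline report", "",
             "## Stages", paste0("- ", manifest$stage,
                                 ifelse(nzchar(manifest$note),
                                        paste0(" (", manifest$note, ")"), "")),
             "", "## Samples excluded by QC")
  for (nm in names(outputs$qc_reports)) {
    r <- outputs$qc_reports[[nm]]
    excl <- sum(!r$pass)
    reasons <- table(unlist(strsplit(r$fail_reasons[!r$pass], ";")))
    lines <- c(lines, sprintf("- %s: %d/%d excluded%s", nm, excl, nrow(r),
                              if (excl) paste0(" [",
                                paste(sprintf("%s=%d", names(reasons),
                                              as.integer(reasons)),
                                      collapse = ", "), "]") else ""))
  }
  lines <- c(lines, "", "## Genes expressed per dataset")
  for (nm in names(outputs$de))
    lines <- c(lines, sprintf("- %s: %d expressed of %d", nm,
                              sum(outputs$de[[nm]]$expressed),
                              nrow(outputs$de[[nm]])))
  top <- utils::head(outputs$scores[order(-outputs$scores$D_overall), ], top_n)
  lines <- c(lines, "", sprintf("## Top %d genes by D_overall", top_n),
             sprintf("- %s: D_overall = %.4f (rank %d)",
                     top$gene, top$D_overall, top$rank))
  enr <- utils::head(outputs$enrichment[order(outputs$enrichment$fdr_q), ], 5)
  lines <- c(lines, "", "## Enrichment (top 5 by FDR-q)",
             sprintf("- %s: NES = %.2f, p = %.4g, FDR-q = %.4g, FWER-p = %.4g",
                     enr$set, enr$nes, enr$p_nominal, enr$fdr_q, enr$fwer_p))
  if (!is.null(outputs$control)) {
    n_sig <- sum(outputs$control$fdr_q < 0.01)
    lines <- c(lines, "", "## Label-permutation control",
               sprintf("- sets at FDR-q < 0.01 after label shuffling: %d",
                       n_sig))
  }
  lines
}
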