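## Sample- and cell-level quality control.
##
## Inclusion rules follow the study: cells need a read mapping rate of at
## least 50%, at least 1000 detected genes, adequate housekeeping-gene
## detection, and must not exceed doublet cut-offs (> 8000 genes or > 37,500
## UMIs). Bulk samples are screened on detected genes and housekeeping genes
## only. Two housekeeping dialects coexist in the source protocols: droplet
## single-cell data are filtered on the *fraction* of the housekeeping list
## detected (< 66% fails) while plate/bulk data use an absolute count
## (< 65 fails); both are carried in the thresholds object.

#' Curated housekeeping gene list (synthetic stand-in)
#'
#' A 98-member list of placeholder gene identifiers used by QC as the
#' detection-based housekeeping criterion. Real analyses supply their own
#' curated list (a published 98-gene list is the usual choice); synthetic
#' cohorts pass the generator's planted housekeeping genes.
#'
#' @param genes optional character vector to use as the list.
#' @return character vector of gene ids.
#' @export
default_hk_genes <- function(genes = NULL) {
  if (!is.null(genes)) return(unique(as.character(genes)))
  sprintf("HK%03d", seq_len(98))
}

#' QC thresholds
#'
#' @param min_mapping_rate_sc minimum read mapping rate for cells (inclusive).
#' @param min_genes minimum detected genes (a sample with fewer fails).
#' @param max_genes doublet cut-off on detected genes (strictly more fails).
#' @param max_umis doublet cut-off on total UMIs (strictly more fails).
#' @param min_hk_genes absolute housekeeping-detection threshold
#'   (plate-based single-cell and bulk dialect; fewer than this fails).
#' @param min_hk_fraction fractional housekeeping-detection threshold
#'   (droplet single-cell dialect; less than this fraction of the list fails).
#' @param hk_gene_list character vector of housekeeping gene ids.
#' @param min_mapping_rate_bulk optional mapping-rate cut for bulk samples;
#'   `NULL` (default) disables it, matching the study's retention of a
#'   57%-mapped bulk library.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_mapping_rate_sc = 0.50,
                          min_genes = 1000,
                          max_genes = 8000,
                          max_umis = 37500,
                          min_hk_genes = 65,
                          min_hk_fraction = 0.66,
                          hk_gene_list = default_hk_genes(),
                          min_mapping_rate_bulk = NULL) {
  check_prob(min_mapping_rate_sc, "min_mapping_rate_sc")
  check_prob(min_hk_fraction, "min_hk_fraction")
  if (min_genes >= max_genes)
    abort_param("min_genes", "must be smaller than max_genes")
  if (min_hk_genes > length(hk_gene_list))
    abort_param("min_hk_genes", "exceeds the housekeeping list length")
  if (!is.null(min_mapping_rate_bulk))
    check_prob(min_mapping_rate_bulk, "min_mapping_rate_bulk")
  structure(list(min_mapping_rate_sc = min_mapping_rate_sc,
                 min_genes = min_genes, max_genes = max_genes,
                 max_umis = max_umis, min_hk_genes = min_hk_genes,
                 min_hk_fraction = min_hk_fraction,
                 hk_gene_list = hk_gene_list,
                 min_mapping_rate_bulk = min_mapping_rate_bulk),
            class = "qc_thresholds")
}

#' Compute per-sample QC metrics
#'
#' A gene counts as detected in a sample iff its count is at least 1.
#'
#' @param dataset an [expression_dataset()].
#' @param hk_list housekeeping gene ids.
#' @return data.frame (class `qc_report`) with one row per sample/cell:
#'   `sample_id`, `mapping_rate`, `n_genes_detected`, `n_hk_detected`,
#'   `n_umis`; pass/fail columns are unset until a filter is applied.
#' @export
compute_qc_metrics <- function(dataset, hk_list = default_hk_genes()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(hk_list) == 0) abort_param("hk_list", "must be non-empty")
  counts <- dataset$counts
  hk_present <- intersect(hk_list, rownames(counts))
  if (length(hk_present) == 0)
    warning("housekeeping list shares no gene ids with the count matrix; ",
            "n_hk_detected will be 0 for every sample")
  detected <- counts >= 1
  rep <- data.frame(
    sample_id = colnames(counts),
    mapping_rate = dataset$meta$mapping_rate,
    n_genes_detected = colSums(detected),
    n_hk_detected = if (length(hk_present))
      colSums(detected[hk_present, , drop = FALSE]) else 0L,
    n_umis = colSums(counts),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(rep, "hk_list_size") <- length(hk_list)
  attr(rep, "modality") <- dataset$modality
  class(rep) <- c("qc_report", "data.frame")
  rep
}

reasons_to_string <- function(lst) {
  vapply(lst, function(r) paste(r, collapse = ";"), "")
}

finalize_report <- function(report, reasons) {
  report$fail_reasons <- reasons_to_string(reasons)
  report$pass <- !nzchar(report$fail_reasons)
  report
}

#' Flag cells against single-cell inclusion criteria
#'
#' Boundary semantics follow the stated rules exactly: a mapping rate of
#' exactly 0.50 passes ("at least 50%"), 1000 detected genes pass ("< 1000"
#' fails), 8000 genes and 37,500 UMIs pass (">" fails).
#'
#' @param report a `qc_report` from [compute_qc_metrics()].
#' @param thresholds a [qc_thresholds()].
#' @param hk_rule `"fraction"` (droplet dialect, default) or `"count"`
#'   (plate-based dialect) for the housekeeping criterion.
#' @return the report with `fail_reasons` (semicolon-joined codes among
#'   `LOW_MAPPING`, `LOW_GENES`, `LOW_HK`, `DOUBLET_GENES`, `DOUBLET_UMI`)
#'   and logical `pass` columns set.
#' @export
filter_cells <- function(report, thresholds = qc_thresholds(),
                         hk_rule = c("fraction", "count")) {
  hk_rule <- match.arg(hk_rule)
  hk_size <- attr(report, "hk_list_size") %||% length(thresholds$hk_gene_list)
  reasons <- lapply(seq_len(nrow(report)), function(i) {
    r <- character()
    if (report$mapping_rate[i] < thresholds$min_mapping_rate_sc)
      r <- c(r, "LOW_MAPPING")
    if (report$n_genes_detected[i] < thresholds$min_genes)
      r <- c(r, "LOW_GENES")
    hk_fail <- if (hk_rule == "fraction")
      report$n_hk_detected[i] / hk_size < thresholds$min_hk_fraction
    else report$n_hk_detected[i] < thresholds$min_hk_genes
    if (hk_fail) r <- c(r, "LOW_HK")
    if (report$n_genes_detected[i] > thresholds$max_genes)
      r <- c(r, "DOUBLET_GENES")
    if (report$n_umis[i] > thresholds$max_umis)
      r <- c(r, "DOUBLET_UMI")
    r
  })
  finalize_report(report, reasons)
}

#' Flag bulk samples against inclusion criteria
#'
#' Bulk samples are evaluated on detected genes and housekeeping genes only;
#' doublet rules do not apply. A mapping-rate cut is applied only if
#' `thresholds$min_mapping_rate_bulk` is set.
#'
#' @inheritParams filter_cells
#' @return the flagged report.
#' @export
filter_bulk_samples <- function(report, thresholds = qc_thresholds()) {
  reasons <- lapply(seq_len(nrow(report)), function(i) {
    r <- character()
    if (!is.null(thresholds$min_mapping_rate_bulk) &&
        report$mapping_rate[i] < thresholds$min_mapping_rate_bulk)
      r <- c(r, "LOW_MAPPING")
    if (report$n_genes_detected[i] < thresholds$min_genes)
      r <- c(r, "LOW_GENES")
    if (report$n_hk_detected[i] < thresholds$min_hk_genes)
      r <- c(r, "LOW_HK")
    r
  })
  finalize_report(report, reasons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run QC on a dataset and drop failing samples
#'
#' @param dataset an [expression_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @param hk_list housekeeping list; defaults to the thresholds' list.
#' @return list with `dataset` (failing columns removed) and `report`.
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds(),
                     hk_list = thresholds$hk_gene_list) {
  report <- compute_qc_metrics(dataset, hk_list)
  report <- if (dataset$modality == "single_cell")
    filter_cells(report, thresholds) else filter_bulk_samples(report, thresholds)
  keep <- report$pass
  if (!any(keep))
    stop("dataset '", dataset$name, "' has no samples passing QC (reasons: ",
         paste(unique(unlist(strsplit(report$fail_reasons[!keep], ";"))),
               collapse = ", "), ")", call. = FALSE)
  filtered <- expression_dataset(
    dataset$name, dataset$modality,
    dataset$counts[, keep, drop = FALSE],
    dataset$tpm[, keep, drop = FALSE],
    dataset$meta[keep, , drop = FALSE])
  list(dataset = filtered, report = report)
}

#' Write a QC report as TSV
#' @param report a flagged `qc_report`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
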