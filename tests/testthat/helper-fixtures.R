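# Shared fixtures: small synthetic cohorts with QC thresholds scaled to the
# toy gene universe, a brute-force enrichment-score oracle, and a cached
# full-size cohort pipeline for the acceptance checks.

# A compact cohort: 800 genes, so the default 1000-detected-genes rule is
# replaced by a proportional one; matched thresholds are returned alongside.
toy_cohort <- function(seed = 7, n_genes = 800, n_true_de_genes = 40,
                       n_housekeeping = 50,
                       qc_failure_rates = c(low_mapping = 0.05,
                                            low_genes = 0.05,
                                            low_hk = 0.03,
                                            doublet_umi = 0.05), ...) {
  spec <- cohort_spec(n_genes = n_genes, n_true_de_genes = n_true_de_genes,
                      n_housekeeping = n_housekeeping,
                      n_subjects_per_condition = c(2, 2, 5, 5, 5, 5),
                      cells_per_subject = 25,
                      cell_library_size_mean = 5000,
                      qc_failure_rates = qc_failure_rates,
                      seed = seed, ...)
  cohort <- generate_cohort(spec)
  thresholds <- qc_thresholds(
    min_genes = 300, max_genes = 800, max_umis = 37500,
    min_hk_genes = 40, min_hk_fraction = 0.66,
    hk_gene_list = cohort$ground_truth$housekeeping_genes)
  list(spec = spec, cohort = cohort, thresholds = thresholds)
}

# Build a qc_report row set directly from stated metrics (for boundary tests).
manual_qc_report <- function(mapping_rate, n_genes_detected, n_hk_detected,
                             n_umis, hk_list_size = 98) {
  rep <- data.frame(sample_id = sprintf("S%d", seq_along(mapping_rate)),
                    mapping_rate = mapping_rate,
                    n_genes_detected = n_genes_detected,
                    n_hk_detected = n_hk_detected,
                    n_umis = n_umis, stringsAsFactors = FALSE)
  attr(rep, "hk_list_size") <- hk_list_size
  class(rep) <- c("qc_report", "data.frame")
  rep
}

# Independent brute-force enrichment-score oracle: explicit walk over every
# position of the ranked list, no shared code with the implementation.
es_bruteforce <- function(ranked, members, weight_exponent = 1) {
  hit <- names(ranked) %in% members
  n <- length(ranked)
  nh <- sum(hit)
  w <- abs(ranked)^weight_exponent
  nr <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) unname(w[i]) / nr else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# The acceptance-scale cohort pipeline (default study conditions) is needed by
# several acceptance checks; compute it once per test run.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function(seed = 20260921) {
  key <- paste0("run_", seed)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  spec <- cohort_spec(seed = seed)
  cohort <- generate_cohort(spec)
  gt <- cohort$ground_truth
  th <- qc_thresholds(hk_gene_list = gt$housekeeping_genes)
  qc <- lapply(cohort$datasets, apply_qc, thresholds = th)
  de_list <- lapply(qc, function(x) run_de(x$dataset))
  names(de_list) <- vapply(cohort$datasets, function(d) d$name, "")
  scores <- score_genes(de_list, gt$midbrain_detected)
  ranked <- stats::setNames(scores$D_overall, scores$gene)
  ranked <- ranked[order(-ranked, names(ranked))]
  gsc <- generate_genesets(gt, n_random_sets = 20, size_range = c(15, 200),
                           seed = seed, universe = names(ranked))
  restricted <- restrict_and_filter(gsc, names(ranked), 15, 500)
  out <- list(spec = spec, cohort = cohort, gt = gt, qc = qc,
              de_list = de_list, scores = scores, ranked = ranked,
              restricted = restricted)
  .acceptance_cache[[key]] <- out
  out
}
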