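test_that("null configuration plants nothing and every sample passes QC", {
  tc <- toy_cohort(seed = 3, n_true_de_genes = 0,
                   qc_failure_rates = c(low_mapping = 0, low_genes = 0,
                                        low_hk = 0, doublet_umi = 0))
  expect_equal(nrow(tc$cohort$ground_truth$de_genes), 0)
  expect_equal(nrow(tc$cohort$ground_truth$planted_qc_failures), 0)
  for (ds in tc$cohort$datasets) {
    res <- apply_qc(ds, tc$thresholds)
    expect_true(all(res$report$pass))
  }
})

test_that("generation is bit-identical under a fixed seed", {
  a <- toy_cohort(seed = 7)$cohort
  b <- toy_cohort(seed = 7)$cohort
  for (i in seq_along(a$datasets)) {
    expect_identical(a$datasets[[i]]$counts, b$datasets[[i]]$counts)
    expect_identical(a$datasets[[i]]$tpm, b$datasets[[i]]$tpm)
    expect_identical(a$datasets[[i]]$meta, b$datasets[[i]]$meta)
  }
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("counts are non-negative integers and TPM columns sum to 1e6", {
  tc <- toy_cohort(seed = 5)
  for (ds in tc$cohort$datasets) {
    expect_true(is.integer(ds$counts))
    expect_true(all(ds$counts >= 0))
    sums <- colSums(ds$tpm)
    nonzero <- colSums(ds$counts) > 0
    expect_equal(sums[nonzero], rep(1e6, sum(nonzero)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("adding a dataset does not perturb earlier datasets (child seeds)", {
  five <- cohort_spec(n_genes = 300, modality = rep("bulk", 5),
                      n_subjects_per_condition = 3, n_true_de_genes = 10,
                      n_housekeeping = 20, seed = 9)
  six <- cohort_spec(n_genes = 300, modality = rep("bulk", 6),
                     n_subjects_per_condition = 3, n_true_de_genes = 10,
                     n_housekeeping = 20, seed = 9)
  a <- generate_cohort(five)$datasets
  b <- generate_cohort(six)$datasets
  for (i in 1:5) expect_identical(a[[i]]$counts, b[[i]]$counts)
})

test_that("planted effects are recoverable: Wilcoxon p of planted genes is small", {
  # bulk modality, 20 subjects per condition, |log2FC| = 2, replicate cohorts
  meds <- vapply(1:10, function(r) {
    spec <- cohort_spec(n_genes = 300, modality = "bulk",
                        n_subjects_per_condition = 20, n_true_de_genes = 20,
                        effect_log2fc = 2, n_housekeeping = 30,
                        qc_failure_rates = c(low_genes = 0), seed = 100 + r)
    ch <- generate_cohort(spec)
    ds <- ch$datasets[[1]]
    is_pd <- ds$meta$condition == "PD"
    p <- vapply(ch$ground_truth$de_genes$gene, function(g)
      wilcoxon_test(ds$tpm[g, is_pd], ds$tpm[g, !is_pd]), numeric(1))
    median(p)
  }, numeric(1))
  expect_lt(median(meds), 0.05)
})

test_that("housekeeping genes show near-zero realized fold change", {
  lfc <- unlist(lapply(1:5, function(r) {
    spec <- cohort_spec(n_genes = 300, modality = "bulk",
                        n_subjects_per_condition = 20, n_true_de_genes = 20,
                        n_housekeeping = 30,
                        qc_failure_rates = c(low_genes = 0), seed = 200 + r)
    ch <- generate_cohort(spec)
    ds <- ch$datasets[[1]]
    is_pd <- ds$meta$condition == "PD"
    hk <- ch$ground_truth$housekeeping_genes
    log2_fold_change(rowMeans(ds$tpm[hk, is_pd]),
                     rowMeans(ds$tpm[hk, !is_pd]), pseudocount = 0.01)
  }))
  expect_lt(abs(mean(lfc)), 0.2)
})

test_that("every planted QC failure violates at least its planted rule", {
  tc <- toy_cohort(seed = 13)
  gt <- tc$cohort$ground_truth
  expect_gt(nrow(gt$planted_qc_failures), 0)
  names(tc$cohort$datasets) <- vapply(tc$cohort$datasets, `[[`, "", "name")
  for (i in seq_len(nrow(gt$planted_qc_failures))) {
    row <- gt$planted_qc_failures[i, ]
    ds <- tc$cohort$datasets[[row$dataset]]
    met <- compute_qc_metrics(ds, gt$housekeeping_genes)
    m <- met[met$sample_id == row$sample, ]
    th <- tc$thresholds
    violated <- switch(row$reason,
      LOW_MAPPING = m$mapping_rate < th$min_mapping_rate_sc,
      LOW_GENES = m$n_genes_detected < th$min_genes,
      LOW_HK = m$n_hk_detected < th$min_hk_genes,
      DOUBLET_UMI = m$n_umis > th$max_umis,
      DOUBLET_GENES = m$n_genes_detected > th$max_genes)
    expect_true(violated, label = paste(row$dataset, row$sample, row$reason))
  }
})

test_that("cohorts round-trip exactly through write and read", {
  tc <- toy_cohort(seed = 21)
  dir <- withr::local_tempdir()
  man <- write_cohort(tc$cohort$datasets, tc$cohort$ground_truth, dir)
  expect_true(all(file.exists(man$file)))
  sc_dir <- file.path(dir, tc$cohort$datasets[[1]]$name)
  expect_true(all(file.exists(file.path(sc_dir,
    c("counts.mtx", "tpm.mtx", "genes.tsv", "barcodes.tsv")))))
  back <- read_cohort(dir)
  names(back) <- vapply(back, `[[`, "", "name")
  for (ds in tc$cohort$datasets) {
    expect_identical(unname(back[[ds$name]]$counts), unname(ds$counts))
    expect_equal(back[[ds$name]]$tpm, ds$tpm, tolerance = 0)
    expect_equal(back[[ds$name]]$meta$condition, ds$meta$condition)
  }
})

test_that("writing an empty gene list errors before any file is written", {
  tc <- toy_cohort(seed = 2)
  ds <- tc$cohort$datasets[[3]]
  empty <- expression_dataset(ds$name, ds$modality,
                              ds$counts[0, , drop = FALSE],
                              ds$tpm[0, , drop = FALSE], ds$meta)
  dir <- file.path(withr::local_tempdir(), "fresh")
  expect_error(write_cohort(list(empty), tc$cohort$ground_truth, dir),
               "empty gene list")
  expect_false(dir.exists(dir))
})

test_that("generated gene-set collections honor their contract", {
  tc <- toy_cohort(seed = 2)
  gt <- tc$cohort$ground_truth
  only_planted <- generate_genesets(gt, n_random_sets = 0)
  expect_length(only_planted, 1)
  expect_setequal(only_planted$sets$PLANTED_DE, gt$de_genes$gene)

  gsc <- generate_genesets(gt, n_random_sets = 15, size_range = c(10, 60),
                           seed = 4)
  sizes <- lengths(gsc$sets[startsWith(names(gsc$sets), "RANDOM")])
  expect_true(all(sizes >= 10 & sizes <= 60))
  again <- generate_genesets(gt, n_random_sets = 15, size_range = c(10, 60),
                             seed = 4)
  expect_identical(gsc$sets, again$sets)
  expect_error(generate_genesets(gt, size_range = c(0, 10)), "size_range")
  expect_error(generate_genesets(gt, size_range = c(10, 1e6)), "size_range")
})

test_that("invalid cohort specifications name the violated field", {
  expect_error(cohort_spec(n_genes = 10, n_true_de_genes = 8,
                           n_housekeeping = 8), "n_true_de_genes")
  expect_error(cohort_spec(qc_failure_rates = c(low_genes = 1.2)),
               "qc_failure_rates")
  expect_error(cohort_spec(modality = c("bulk", "nanopore")), "modality")
  expect_error(cohort_spec(effect_log2fc = -1), "effect_log2fc")
})
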