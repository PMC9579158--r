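## Synthetic multi-dataset cohort generator.
##
## Emulates the structure of the study cohort (two single-cell-like and four
## bulk-like PD-vs-control datasets) with known ground truth: planted
## differentially expressed genes, stable housekeeping genes, planted
## QC-failing samples/cells and per-gene midbrain-detection flags. Counts are
## drawn from a negative-binomial (gamma-Poisson) model with log-normal
## library-size variation; TPM is computed from counts and gene lengths.

QC_REASONS <- c("LOW_MAPPING", "LOW_GENES", "LOW_HK", "DOUBLET_GENES", "DOUBLET_UMI")

#' Specify a synthetic multi-dataset cohort
#'
#' Defaults mirror the study design: six datasets (two single-cell, four
#' bulk), ten subjects per condition per bulk dataset (80 bulk samples in
#' total), three subjects per condition with 60 cells each for single-cell
#' datasets, 98 housekeeping genes, and 200 planted DE genes at a mean
#' magnitude of |log2FC| = 2.
#'
#' @param n_genes number of genes simulated.
#' @param modality character vector, one of `"single_cell"`/`"bulk"` per dataset.
#' @param n_subjects_per_condition integer vector (recycled) of subjects per
#'   condition per dataset.
#' @param cells_per_subject cells sequenced per subject (single-cell only).
#' @param n_true_de_genes number of planted differentially expressed genes.
#' @param effect_log2fc planted |log2 fold change| of DE genes.
#' @param concordant_fraction fraction of planted DE genes whose direction is
#'   identical in every dataset; the rest flip sign independently per dataset
#'   with probability 0.5.
#' @param n_housekeeping number of planted stable housekeeping genes.
#' @param qc_failure_rates named probabilities for planting QC failures, names
#'   among `low_mapping`, `low_genes`, `low_hk`, `doublet_umi`, `doublet_genes`.
#' @param dispersion NB dispersion of DE/background genes.
#' @param hk_dispersion NB dispersion of housekeeping genes.
#' @param library_size_mean expected bulk library size (reads).
#' @param cell_library_size_mean expected per-cell library size (UMIs/reads).
#' @param gene_lengths gene lengths in bases; a single value is recycled.
#'   The default 1000 makes TPM proportional to CPM.
#' @param midbrain_detected_rate probability that a gene is flagged as detected
#'   in adult midbrain tissue.
#' @param seed master seed; per-dataset child seeds are derived from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 5000,
                        modality = c("single_cell", "single_cell",
                                     "bulk", "bulk", "bulk", "bulk"),
                        n_subjects_per_condition = c(3, 3, 10, 10, 10, 10),
                        cells_per_subject = 60,
                        n_true_de_genes = 200,
                        effect_log2fc = 2,
                        concordant_fraction = 1,
                        n_housekeeping = 98,
                        qc_failure_rates = c(low_mapping = 0.02, low_genes = 0.02,
                                             low_hk = 0.01, doublet_umi = 0.02),
                        dispersion = 0.1,
                        hk_dispersion = 0.01,
                        library_size_mean = 1e6,
                        cell_library_size_mean = 15000,
                        gene_lengths = 1000,
                        midbrain_detected_rate = 0.8,
                        seed = 1L) {
  check_pos(n_genes, "n_genes", integer = TRUE)
  if (!all(modality %in% c("single_cell", "bulk")))
    abort_param("modality", "entries must be 'single_cell' or 'bulk'")
  n_datasets <- length(modality)
  check_pos(n_datasets, "n_datasets", integer = TRUE)
  n_subjects_per_condition <- rep_len(n_subjects_per_condition, n_datasets)
  check_pos(n_subjects_per_condition, "n_subjects_per_condition", integer = TRUE)
  check_pos(cells_per_subject, "cells_per_subject", integer = TRUE)
  if (n_true_de_genes < 0 || n_true_de_genes != round(n_true_de_genes))
    abort_param("n_true_de_genes", "must be a non-negative integer")
  if (n_housekeeping < 0 || n_housekeeping != round(n_housekeeping))
    abort_param("n_housekeeping", "must be a non-negative integer")
  if (n_true_de_genes + n_housekeeping > n_genes)
    abort_param("n_true_de_genes", "n_true_de_genes + n_housekeeping exceeds n_genes")
  check_pos(effect_log2fc, "effect_log2fc")
  check_prob(concordant_fraction, "concordant_fraction")
  check_prob(unname(qc_failure_rates), "qc_failure_rates")
  if (length(qc_failure_rates) &&
      !all(names(qc_failure_rates) %in%
           c("low_mapping", "low_genes", "low_hk", "doublet_umi", "doublet_genes")))
    abort_param("qc_failure_rates", "unknown failure reason name")
  check_pos(dispersion, "dispersion")
  check_pos(hk_dispersion, "hk_dispersion")
  check_pos(library_size_mean, "library_size_mean")
  check_pos(cell_library_size_mean, "cell_library_size_mean")
  check_pos(gene_lengths, "gene_lengths")
  if (!length(gene_lengths) %in% c(1L, n_genes))
    abort_param("gene_lengths", "must have length 1 or n_genes")
  check_prob(midbrain_detected_rate, "midbrain_detected_rate")

  structure(list(
    n_genes = as.integer(n_genes),
    n_datasets = n_datasets,
    modality = modality,
    n_subjects_per_condition = as.integer(n_subjects_per_condition),
    cells_per_subject = as.integer(cells_per_subject),
    n_true_de_genes = as.integer(n_true_de_genes),
    effect_log2fc = effect_log2fc,
    concordant_fraction = concordant_fraction,
    n_housekeeping = as.integer(n_housekeeping),
    qc_failure_rates = qc_failure_rates,
    dispersion = dispersion,
    hk_dispersion = hk_dispersion,
    library_size_mean = library_size_mean,
    cell_library_size_mean = cell_library_size_mean,
    gene_lengths = rep_len(gene_lengths, n_genes),
    midbrain_detected_rate = midbrain_detected_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Construct an expression dataset container
#'
#' @param name dataset label.
#' @param modality `"single_cell"` or `"bulk"`.
#' @param counts gene-by-sample integer matrix.
#' @param tpm matched TPM matrix (each column sums to 1e6).
#' @param meta data.frame with one row per sample: `sample_id`, `subject`,
#'   `condition` (`PD`/`control`), `mapping_rate`, optionally `planted_fail`.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(name, modality, counts, tpm, meta) {
  stopifnot(is.matrix(counts) || methods::is(counts, "Matrix"),
            identical(dim(counts), dim(tpm)),
            nrow(meta) == ncol(counts),
            all(colnames(counts) == meta$sample_id),
            modality %in% c("single_cell", "bulk"))
  structure(list(name = name, modality = modality, counts = counts,
                 tpm = tpm, meta = meta),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s [%s]: %d genes x %d %s\n",
              x$name, x$modality, nrow(x$counts), ncol(x$counts),
              if (x$modality == "single_cell") "cells" else "samples"))
  invisible(x)
}

#' Compute TPM from counts and gene lengths
#'
#' @param counts gene-by-sample count matrix.
#' @param lengths gene lengths in bases (recycled).
#' @return matrix whose non-empty columns each sum to 1e6.
#' @export
tpm_from_counts <- function(counts, lengths = 1000) {
  rate <- counts / (rep_len(lengths, nrow(counts)) / 1000)
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # all-zero column stays all-zero
  sweep(rate, 2, tot, "/") * 1e6
}

## Picks at most one planted failure reason per sample, iterating reasons in
## a fixed order so results are reproducible.
plant_failures <- function(n, rates, applicable) {
  planted <- rep(NA_character_, n)
  for (r in intersect(names(rates), applicable)) {
    hit <- is.na(planted) & stats::runif(n) < rates[[r]]
    planted[hit] <- toupper(r)
  }
  planted
}

#' Generate a synthetic multi-dataset cohort with ground truth
#'
#' Counts follow a negative-binomial model with log-normal library-size
#' variation; the condition effect is applied multiplicatively to planted DE
#' genes in PD samples. Housekeeping genes have no planted effect, elevated
#' baseline expression and low dispersion. Planted QC failures are realized as
#' low mapping rate (< 0.5), tiny libraries (< 1000 detected genes), zeroed
#' housekeeping genes, or doublet-scale libraries (> 37,500 total counts), and
#' are enforced deterministically so each planted sample violates its rule.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `datasets` (list of [expression_dataset()]) and
#'   `ground_truth` (planted DE genes with per-dataset directions, housekeeping
#'   genes, midbrain flags, planted QC failures).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  genes <- sprintf("G%05d", seq_len(spec$n_genes))

  gene_stage <- withr::with_seed(child_seed(spec$seed, 0), {
    base_lambda <- stats::rlnorm(spec$n_genes, meanlog = 0, sdlog = 1)
    idx <- sample.int(spec$n_genes, spec$n_true_de_genes + spec$n_housekeeping)
    de_idx <- idx[seq_len(spec$n_true_de_genes)]
    hk_idx <- idx[seq_len(spec$n_housekeeping) + spec$n_true_de_genes]
    # housekeeping genes are highly and stably expressed
    base_lambda[hk_idx] <- stats::rlnorm(spec$n_housekeeping, meanlog = 2, sdlog = 0.3)
    n_conc <- round(spec$concordant_fraction * spec$n_true_de_genes)
    concordant <- seq_len(spec$n_true_de_genes) <= n_conc
    base_dir <- sample(c(-1, 1), spec$n_true_de_genes, replace = TRUE)
    # per-dataset direction: concordant genes keep base_dir everywhere,
    # discordant genes flip independently per dataset with probability 0.5
    dir_mat <- matrix(rep(base_dir, spec$n_datasets), ncol = spec$n_datasets)
    if (any(!concordant) && spec$n_datasets > 0) {
      flips <- matrix(sample(c(-1, 1), sum(!concordant) * spec$n_datasets,
                             replace = TRUE), ncol = spec$n_datasets)
      dir_mat[!concordant, ] <- base_dir[!concordant] * flips
    }
    midbrain <- stats::runif(spec$n_genes) < spec$midbrain_detected_rate
    list(base_lambda = base_lambda, de_idx = de_idx, hk_idx = hk_idx,
         concordant = concordant, dir_mat = dir_mat, midbrain = midbrain)
  })

  rho <- gene_stage$base_lambda / sum(gene_stage$base_lambda)
  size_vec <- rep(1 / spec$dispersion, spec$n_genes)
  size_vec[gene_stage$hk_idx] <- 1 / spec$hk_dispersion
  hk_genes <- genes[gene_stage$hk_idx]
  midbrain <- stats::setNames(gene_stage$midbrain, genes)

  datasets <- vector("list", spec$n_datasets)
  fail_records <- list()

  for (d in seq_len(spec$n_datasets)) {
    sc <- spec$modality[d] == "single_cell"
    n_sub <- spec$n_subjects_per_condition[d]
    per_sub <- if (sc) spec$cells_per_subject else 1L
    cond_sub <- rep(c("control", "PD"), each = n_sub)
    subjects <- sprintf("D%d_S%02d", d, seq_len(2 * n_sub))
    cond <- rep(cond_sub, each = per_sub)
    subject <- rep(subjects, each = per_sub)
    n_samp <- length(subject)
    samp_id <- if (sc) sprintf("D%d_C%04d", d, seq_len(n_samp)) else subjects

    ds <- withr::with_seed(child_seed(spec$seed, d), {
      # log2FC applied multiplicatively to PD samples of planted DE genes
      fc <- rep(1, spec$n_genes)
      mu_base <- if (sc) spec$cell_library_size_mean else spec$library_size_mean
      subj_fac <- stats::setNames(stats::rlnorm(length(subjects), 0, 0.1), subjects)
      lib <- stats::rlnorm(n_samp, log(mu_base) + log(subj_fac[subject]), 0.2)

      planted <- plant_failures(
        n_samp, spec$qc_failure_rates,
        applicable = if (sc) c("low_mapping", "low_genes", "low_hk",
                               "doublet_umi", "doublet_genes")
                     else c("low_genes", "low_hk"))
      lib[planted %in% "LOW_GENES"] <- 400
      lib[planted %in% "DOUBLET_UMI"] <- 80000

      counts <- matrix(0L, spec$n_genes, n_samp,
                       dimnames = list(genes, samp_id))
      for (j in seq_len(n_samp)) {
        fc_j <- fc
        if (cond[j] == "PD" && spec$n_true_de_genes > 0)
          fc_j[gene_stage$de_idx] <-
            2 ^ (gene_stage$dir_mat[, d] * spec$effect_log2fc)
        mu <- lib[j] * rho * fc_j
        counts[, j] <- stats::rnbinom(spec$n_genes, mu = mu, size = size_vec)
      }

      mapping <- if (sc) stats::runif(n_samp, 0.55, 0.92)
                 else stats::runif(n_samp, 0.70, 0.95)
      mapping[planted %in% "LOW_MAPPING"] <- stats::runif(
        sum(planted %in% "LOW_MAPPING"), 0.20, 0.45)

      # deterministic enforcement of planted violations
      for (j in which(planted %in% "LOW_HK"))
        counts[gene_stage$hk_idx, j] <- 0L
      if (any(planted %in% "LOW_GENES")) {
        # thin planted columns to a quarter of the clean detection level
        # (capped below the 1000-gene rule) so they are unambiguous failures
        clean_det <- stats::median(colSums(counts[, is.na(planted),
                                                  drop = FALSE] > 0))
        if (!is.finite(clean_det)) clean_det <- spec$n_genes
        target <- min(999L, max(1L, floor(clean_det / 4)))
        for (j in which(planted %in% "LOW_GENES")) {
          det <- which(counts[, j] > 0)
          if (length(det) > target) {
            drop <- det[order(counts[det, j])][seq_len(length(det) - target)]
            counts[drop, j] <- 0L
          }
        }
      }
      for (j in which(planted %in% "DOUBLET_UMI"))
        while (sum(counts[, j]) <= 37500) counts[, j] <- counts[, j] * 2L
      for (j in which(planted %in% "DOUBLET_GENES")) {
        if (spec$n_genes > 8000)
          counts[seq_len(8001), j] <- pmax(counts[seq_len(8001), j], 1L)
      }

      meta <- data.frame(sample_id = samp_id, subject = subject,
                         condition = cond, mapping_rate = mapping,
                         planted_fail = planted, stringsAsFactors = FALSE)
      list(counts = counts, meta = meta)
    })

    storage.mode(ds$counts) <- "integer"
    tpm <- tpm_from_counts(ds$counts, spec$gene_lengths)
    name <- sprintf("%s-%d", if (sc) "sc" else "bulk", d)
    datasets[[d]] <- expression_dataset(name, spec$modality[d],
                                        ds$counts, tpm, ds$meta)
    pf <- ds$meta[!is.na(ds$meta$planted_fail), c("sample_id", "planted_fail")]
    if (nrow(pf))
      fail_records[[d]] <- data.frame(dataset = name, sample = pf$sample_id,
                                      reason = pf$planted_fail,
                                      stringsAsFactors = FALSE)
  }

  dir_mat <- gene_stage$dir_mat
  dimnames(dir_mat) <- list(genes[gene_stage$de_idx],
                            vapply(datasets, function(x) x$name, ""))
  ground_truth <- list(
    de_genes = data.frame(gene = genes[gene_stage$de_idx],
                          log2fc = rep(spec$effect_log2fc,
                                       length(gene_stage$de_idx)),
                          concordant = gene_stage$concordant,
                          stringsAsFactors = FALSE),
    de_directions = dir_mat,
    housekeeping_genes = hk_genes,
    midbrain_detected = midbrain,
    planted_qc_failures = if (length(fail_records))
      do.call(rbind, fail_records)
    else data.frame(dataset = character(), sample = character(),
                    reason = character(), stringsAsFactors = FALSE)
  )
  list(datasets = datasets, ground_truth = ground_truth)
}

#' Write a cohort to disk
#'
#' Bulk datasets are written as TSV (genes in rows, samples in columns);
#' single-cell datasets as MatrixMarket coordinate triplets (1-based indices)
#' with `genes.tsv`/`barcodes.tsv` index files. Metadata and ground truth go
#' to TSV. Returns a manifest of written files with MD5 hashes.
#'
#' @param datasets list of [expression_dataset()].
#' @param ground_truth as returned by [generate_cohort()].
#' @param dir_path output directory (created if missing).
#' @return data.frame manifest: `file`, `md5`.
#' @export
write_cohort <- function(datasets, ground_truth, dir_path) {
  for (ds in datasets)
    if (nrow(ds$counts) == 0)
      stop("dataset '", ds$name, "' has an empty gene list; nothing written",
           call. = FALSE)
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (ds in datasets) {
    sub <- file.path(dir_path, ds$name)
    dir.create(sub, showWarnings = FALSE)
    if (ds$modality == "single_cell") {
      write_mtx_full(ds$counts, file.path(sub, "counts.mtx"))
      write_mtx_full(ds$tpm, file.path(sub, "tpm.mtx"))
      writeLines(rownames(ds$counts), file.path(sub, "genes.tsv"))
      writeLines(colnames(ds$counts), file.path(sub, "barcodes.tsv"))
      files <- c(files, file.path(sub, c("counts.mtx", "tpm.mtx",
                                         "genes.tsv", "barcodes.tsv")))
    } else {
      write_matrix_tsv(ds$counts, file.path(sub, "counts.tsv"))
      write_matrix_tsv(ds$tpm, file.path(sub, "tpm.tsv"))
      files <- c(files, file.path(sub, c("counts.tsv", "tpm.tsv")))
    }
    utils::write.table(ds$meta, file.path(sub, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(ds$modality, file.path(sub, "modality.txt"))
    files <- c(files, file.path(sub, c("meta.tsv", "modality.txt")))
  }
  gt_dir <- file.path(dir_path, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  utils::write.table(ground_truth$de_genes, file.path(gt_dir, "de_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(ground_truth$de_directions,
                   file.path(gt_dir, "de_directions.tsv"))
  writeLines(ground_truth$housekeeping_genes,
             file.path(gt_dir, "housekeeping.tsv"))
  utils::write.table(
    data.frame(gene = names(ground_truth$midbrain_detected),
               detected = ground_truth$midbrain_detected),
    file.path(gt_dir, "midbrain.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(ground_truth$planted_qc_failures,
                     file.path(gt_dir, "qc_failures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, file.path(gt_dir, c("de_genes.tsv", "de_directions.tsv",
                                        "housekeeping.tsv", "midbrain.tsv",
                                        "qc_failures.tsv")))
  data.frame(file = files, md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}

#' Read one dataset written by [write_cohort()]
#'
#' @param sub_dir dataset directory.
#' @param name dataset label; defaults to the directory name.
#' @return an [expression_dataset()].
#' @export
read_expression_dataset <- function(sub_dir, name = basename(sub_dir)) {
  modality <- readLines(file.path(sub_dir, "modality.txt"))[1]
  meta <- utils::read.delim(file.path(sub_dir, "meta.tsv"),
                            stringsAsFactors = FALSE)
  if (modality == "single_cell") {
    genes <- readLines(file.path(sub_dir, "genes.tsv"))
    barcodes <- readLines(file.path(sub_dir, "barcodes.tsv"))
    counts <- as.matrix(Matrix::readMM(file.path(sub_dir, "counts.mtx")))
    tpm <- as.matrix(Matrix::readMM(file.path(sub_dir, "tpm.mtx")))
    dimnames(counts) <- dimnames(tpm) <- list(genes, barcodes)
    storage.mode(counts) <- "integer"
  } else {
    counts <- read_matrix_tsv(file.path(sub_dir, "counts.tsv"))
    storage.mode(counts) <- "integer"
    tpm <- read_matrix_tsv(file.path(sub_dir, "tpm.tsv"))
  }
  expression_dataset(name, modality, counts, tpm, meta)
}

#' Read a full cohort directory
#' @param dir_path directory written by [write_cohort()].
#' @return list of [expression_dataset()].
#' @export
read_cohort <- function(dir_path) {
  subs <- setdiff(list.dirs(dir_path, recursive = FALSE, full.names = TRUE),
                  file.path(dir_path, "ground_truth"))
  lapply(subs, read_expression_dataset)
}

#' Generate a gene-set collection with one planted set
#'
#' The planted set is the cohort's true DE genes; the remaining sets are
#' uniform random draws from the gene universe, standing in for pathway or
#' phenotype GMT collections during testing.
#'
#' @param ground_truth as returned by [generate_cohort()].
#' @param n_random_sets number of random decoy sets.
#' @param size_range integer range of random set sizes.
#' @param seed RNG seed.
#' @param universe gene universe to draw from; defaults to all simulated genes.
#' @return a [geneset_collection()].
#' @export
generate_genesets <- function(ground_truth, n_random_sets = 20,
                              size_range = c(15, 200), seed = 1L,
                              universe = names(ground_truth$midbrain_detected)) {
  if (size_range[1] < 1 || size_range[2] > length(universe) ||
      size_range[1] > size_range[2])
    abort_param("size_range", "must lie within [1, n_genes]")
  sets <- list(PLANTED_DE = ground_truth$de_genes$gene)
  desc <- c(PLANTED_DE = "planted differentially expressed genes")
  if (n_random_sets > 0) {
    rand <- withr::with_seed(seed, {
      lapply(seq_len(n_random_sets), function(i) {
        sz <- sample(seq(size_range[1], size_range[2]), 1)
        sample(universe, sz)
      })
    })
    names(rand) <- sprintf("RANDOM_%03d", seq_len(n_random_sets))
    sets <- c(sets, rand)
    desc <- c(desc, stats::setNames(rep("uniform random gene set",
                                        n_random_sets), names(rand)))
  }
  geneset_collection(sets, desc)
}
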