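## Dual differential-expression testing per dataset.
##
## Each dataset is tested twice, PD versus control: once on the count scale
## (negative-binomial Wald test for bulk, Wilcoxon rank-sum on
## library-size-normalized counts for single-cell, where cells are the units
## of replication) and once on raw TPM (Wilcoxon rank-sum). The two p-values
## are combined with the logit method and the two log2 fold changes by
## arithmetic mean. Genes not expressed (>= 1 TPM in at least 10% of samples)
## carry p = 1 and log2FC = 0.

#' Expressed-gene mask
#'
#' A gene is expressed iff its TPM is at least `min_tpm` in at least
#' `ceiling(min_fraction * n_samples)` samples.
#'
#' @param tpm_matrix non-negative gene-by-sample TPM matrix.
#' @param min_tpm expression threshold (default 1 TPM).
#' @param min_fraction minimum fraction of samples (default 0.10).
#' @return named logical vector over genes.
#' @export
expressed_mask <- function(tpm_matrix, min_tpm = 1, min_fraction = 0.10) {
  if (is.null(dim(tpm_matrix)) || ncol(tpm_matrix) == 0 || nrow(tpm_matrix) == 0)
    stop("empty TPM matrix", call. = FALSE)
  if (any(tpm_matrix < 0)) abort_param("tpm_matrix", "must be non-negative")
  need <- ceiling(min_fraction * ncol(tpm_matrix))
  rowSums(tpm_matrix >= min_tpm) >= need
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact null distribution when both groups have at most 8
#' observations and there are no ties, and the midrank normal approximation
#' with tie-corrected variance and continuity correction otherwise.
#' Zero-variance input (all values identical) returns p = 1.
#'
#' @param x,y numeric vectors for the two groups.
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  m <- length(x); n <- length(y)
  v <- c(x, y)
  if (all(v == v[1])) return(1)
  r <- rank(v)
  ties <- any(duplicated(v))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (!ties && m <= 8 && n <= 8) {
    p <- if (U > m * n / 2)
      stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    else stats::pwilcox(U, m, n)
    return(min(1, 2 * p))
  }
  mu <- m * n / 2
  tab <- table(r)
  sigma2 <- (m * n / 12) *
    ((m + n + 1) - sum(tab^3 - tab) / ((m + n) * (m + n - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

## Row-wise Wilcoxon over a matrix; thin loop over the scalar test so the
## exact/approximate dispatch is identical for every caller.
wilcoxon_rows <- function(mat, is_a) {
  vapply(seq_len(nrow(mat)), function(i)
    wilcoxon_test(mat[i, is_a], mat[i, !is_a]), numeric(1))
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors computed against the geometric mean reference over
#' genes with all-positive counts; falls back to library-size ratios when no
#' such gene exists.
#'
#' @param counts gene-by-sample count matrix.
#' @return numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  log_counts <- log(counts)
  ok <- rowSums(is.finite(log_counts)) == ncol(counts)
  if (!any(ok)) {
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls[ls > 0]))))
  }
  ref <- rowMeans(log_counts[ok, , drop = FALSE])
  apply(log_counts[ok, , drop = FALSE], 2,
        function(lc) exp(stats::median(lc - ref)))
}

#' Negative-binomial Wald test for a two-group bulk comparison
#'
#' Self-contained approximation to the standard bulk count test:
#' median-of-ratios normalization, per-gene method-of-moments dispersion
#' (floored at 1e-8) pooled across the two groups, group abundances estimated
#' with size-factor offsets, and a Wald z statistic on the log abundance
#' difference. Operates on a whole matrix at once.
#'
#' @param counts gene-by-sample non-negative integer matrix.
#' @param is_a logical vector marking group A (e.g. PD) columns.
#' @return list with `p` (two-sided p-values; all-zero genes get 1),
#'   `log2fc` (log2 abundance ratio A/B of normalized means, pseudocount 1),
#'   `dispersion`.
#' @export
nb_wald_test <- function(counts, is_a) {
  if (sum(is_a) < 2 || sum(!is_a) < 2)
    stop("the bulk NB Wald test needs at least 2 samples per group",
         call. = FALSE)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")

  mom_disp <- function(g) {
    m <- rowMeans(norm[, g, drop = FALSE])
    v <- apply(norm[, g, drop = FALSE], 1, stats::var)
    # Var(K/s) = mu/s + alpha mu^2, so the Poisson part scales by mean(1/s)
    ifelse(m > 0, (v - m * mean(1 / sf[g])) / m^2, 0)
  }
  w <- c(sum(is_a) - 1, sum(!is_a) - 1)
  disp <- pmin(pmax(
    (mom_disp(is_a) * w[1] + mom_disp(!is_a) * w[2]) / sum(w), 1e-8), 10)

  group_q <- function(g) {
    tot <- rowSums(counts[, g, drop = FALSE])
    pmax(tot, 0.5) / sum(sf[g])  # 0.5-count floor avoids log(0)
  }
  wald_var <- function(q, g) {
    mu <- q %o% sf[g]
    1 / rowSums(mu / (1 + disp * mu))
  }
  q_a <- group_q(is_a); q_b <- group_q(!is_a)
  z <- (log(q_a) - log(q_b)) / sqrt(wald_var(q_a, is_a) + wald_var(q_b, !is_a))
  # t reference with n - 2 df: the Wald variance uses estimated dispersion,
  # and the normal reference is anticonservative at small sample sizes
  p <- 2 * stats::pt(-abs(z), df = ncol(counts) - 2)
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- 1
  mean_a <- rowMeans(norm[, is_a, drop = FALSE])
  mean_b <- rowMeans(norm[, !is_a, drop = FALSE])
  list(p = pmin(pmax(p, 1e-300), 1),
       log2fc = log2_fold_change(mean_a, mean_b, pseudocount = 1),
       dispersion = disp)
}

#' Count-scale test dispatcher
#'
#' Single-cell data are tested by Wilcoxon rank-sum on library-size-normalized
#' counts; bulk data by the NB Wald test.
#'
#' @param counts gene-by-sample count matrix (one gene = one row; a numeric
#'   vector is treated as a single gene).
#' @param is_a logical vector marking group A columns.
#' @param modality `"single_cell"` or `"bulk"`.
#' @return numeric vector of two-sided p-values.
#' @export
count_test <- function(counts, is_a, modality = c("bulk", "single_cell")) {
  modality <- match.arg(modality)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (any(counts < 0)) abort_param("counts", "must be non-negative")
  if (modality == "single_cell") {
    ls <- colSums(counts)
    sf <- ls / stats::median(ls[ls > 0])
    sf[sf == 0] <- 1
    norm <- sweep(counts, 2, sf, "/")
    p <- stats::setNames(wilcoxon_rows(norm, is_a), rownames(counts))
  } else {
    p <- nb_wald_test(counts, is_a)$p
  }
  p[rowSums(counts) == 0] <- 1
  p
}

#' Combine two p-values by the logit method
#'
#' Mudholkar-George combination for k = 2: with L = -sum(log(p/(1-p))),
#' t = L * sqrt(3 (5k+4) / (k pi^2 (5k+2))), the combined p-value is the
#' upper tail of Student's t with 5k+4 = 14 degrees of freedom. Inputs are
#' clamped to [1e-15, 1 - 1e-15]. Vectorized over both arguments.
#'
#' @param p_a,p_b p-values in (0, 1).
#' @return combined p-values in (0, 1).
#' @export
combine_pvalues_logit <- function(p_a, p_b) {
  eps <- 1e-15
  for (p in list(p_a, p_b))
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
      stop("p-values must lie in (0, 1]", call. = FALSE)
  p_a <- pmin(pmax(p_a, eps), 1 - eps)
  p_b <- pmin(pmax(p_b, eps), 1 - eps)
  k <- 2
  L <- -(log(p_a / (1 - p_a)) + log(p_b / (1 - p_b)))
  t_stat <- L * sqrt(3 * (5 * k + 4) / (k * pi^2 * (5 * k + 2)))
  stats::pt(t_stat, df = 5 * k + 4, lower.tail = FALSE)
}

#' Log2 fold change of group means with pseudocount
#'
#' @param mean_a,mean_b non-negative group means (A = PD, B = control).
#' @param pseudocount added to both means; default 1 suits the count scale,
#'   0.01 the TPM scale.
#' @return log2((mean_a + c) / (mean_b + c)).
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (any(mean_a < 0) || any(mean_b < 0))
    abort_param("means", "must be non-negative")
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Run dual differential-expression testing on one dataset
#'
#' @param dataset a QC-filtered [expression_dataset()] whose metadata
#'   `condition` column has levels `PD` and `control`.
#' @param min_tpm,min_fraction expressed-gene rule (see [expressed_mask()]).
#' @param pseudocount_counts,pseudocount_tpm fold-change pseudocounts.
#' @return data.frame (one row per gene): `gene`, `expressed`, `p_count`,
#'   `p_tpm`, `p_combined`, `log2fc_count`, `log2fc_tpm`, `log2fc_mean`.
#'   Unexpressed genes have all p-values 1 and fold changes 0.
#' @export
run_de <- function(dataset, min_tpm = 1, min_fraction = 0.10,
                   pseudocount_counts = 1, pseudocount_tpm = 0.01) {
  stopifnot(inherits(dataset, "expression_dataset"))
  cond <- dataset$meta$condition
  if (!all(cond %in% c("PD", "control")))
    stop("condition labels must be 'PD' or 'control'", call. = FALSE)
  n_sub <- tapply(dataset$meta$subject, cond, function(s) length(unique(s)))
  if (length(n_sub) < 2 || any(n_sub < 2))
    stop("dataset '", dataset$name,
         "' has fewer than 2 subjects per condition", call. = FALSE)
  is_pd <- cond == "PD"
  counts <- as.matrix(dataset$counts)
  tpm <- as.matrix(dataset$tpm)
  genes <- rownames(counts)
  expressed <- expressed_mask(tpm, min_tpm, min_fraction)

  p_count <- p_tpm <- rep(1, length(genes))
  l2_count <- l2_tpm <- rep(0, length(genes))
  if (any(expressed)) {
    ce <- counts[expressed, , drop = FALSE]
    te <- tpm[expressed, , drop = FALSE]
    p_tpm[expressed] <- wilcoxon_rows(te, is_pd)
    if (dataset$modality == "bulk") {
      nb <- nb_wald_test(ce, is_pd)
      p_count[expressed] <- nb$p
      l2_count[expressed] <- nb$log2fc
    } else {
      p_count[expressed] <- count_test(ce, is_pd, "single_cell")
      ls <- colSums(counts)
      sf <- ls / stats::median(ls[ls > 0])
      norm <- sweep(ce, 2, sf, "/")
      l2_count[expressed] <- log2_fold_change(
        rowMeans(norm[, is_pd, drop = FALSE]),
        rowMeans(norm[, !is_pd, drop = FALSE]), pseudocount_counts)
    }
    l2_tpm[expressed] <- log2_fold_change(
      rowMeans(te[, is_pd, drop = FALSE]),
      rowMeans(te[, !is_pd, drop = FALSE]), pseudocount_tpm)
  }
  p_comb <- rep(1, length(genes))
  p_comb[expressed] <- combine_pvalues_logit(p_count[expressed],
                                             p_tpm[expressed])
  data.frame(gene = genes, expressed = unname(expressed),
             p_count = p_count, p_tpm = p_tpm, p_combined = p_comb,
             log2fc_count = l2_count, log2fc_tpm = l2_tpm,
             log2fc_mean = (l2_count + l2_tpm) / 2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a DE result table as TSV
#' @param de data.frame from [run_de()].
#' @param path output file.
#' @export
write_de_result <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
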