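## Desirability-based gene dysregulation scoring.
##
## Per dataset, the combined p-value, the mean log2 fold change and a binary
## adult-midbrain detection flag are each mapped to a desirability on
## [0.01, 1] and combined by a weighted geometric mean (weights 1, 0.5, 0.01)
## into D_dataset. Across datasets, D_overall is the weighted geometric mean
## of all D_dataset values (equal weights) together with a fold-change
## direction-concordance desirability carrying one-tenth of the total weight.

#' Desirability-scoring parameters
#'
#' @param p_high_cut p-values above this get minimum desirability (default 0.05).
#' @param p_low_cut p-values at or below this get maximum desirability;
#'   `"min"` (default) resolves to the dataset's minimum observed combined p.
#' @param fc_low_cut fold changes at or below this get minimum desirability.
#' @param fc_high_cut fold changes at or above this get maximum desirability.
#' @param d_min,d_max desirability floor and ceiling (defaults 0.01 and 1).
#' @param midbrain_detected_score,midbrain_undetected_score desirabilities for
#'   the midbrain-detection flag (defaults 1 and 0.25).
#' @param weights weights of the p-value, fold-change and midbrain
#'   desirabilities in the per-dataset geometric mean.
#' @param concordance_weight_share share of the total weight carried by the
#'   concordance desirability in D_overall (default 0.10).
#' @return object of class `desirability_params`.
#' @export
desirability_params <- function(p_high_cut = 0.05, p_low_cut = "min",
                                fc_low_cut = 1.25, fc_high_cut = 2.0,
                                d_min = 0.01, d_max = 1.0,
                                midbrain_detected_score = 1.0,
                                midbrain_undetected_score = 0.25,
                                weights = c(w_p = 1, w_fc = 0.5, w_mb = 0.01),
                                concordance_weight_share = 0.10) {
  if (!(d_min > 0 && d_min < d_max && d_max <= 1))
    abort_param("d_min", "need 0 < d_min < d_max <= 1")
  if (fc_low_cut >= fc_high_cut)
    abort_param("fc_low_cut", "must be below fc_high_cut")
  if (any(weights <= 0)) abort_param("weights", "must be positive")
  check_prob(p_high_cut, "p_high_cut")
  check_prob(concordance_weight_share, "concordance_weight_share")
  structure(list(p_high_cut = p_high_cut, p_low_cut = p_low_cut,
                 fc_low_cut = fc_low_cut, fc_high_cut = fc_high_cut,
                 d_min = d_min, d_max = d_max,
                 midbrain_detected_score = midbrain_detected_score,
                 midbrain_undetected_score = midbrain_undetected_score,
                 weights = weights,
                 concordance_weight_share = concordance_weight_share),
            class = "desirability_params")
}

resolve_p_low_cut <- function(params, p_values) {
  cut <- params$p_low_cut
  if (identical(cut, "min")) cut <- min(p_values)
  if (!is.numeric(cut) || cut >= params$p_high_cut)
    stop("p_low_cut must resolve to a number below p_high_cut", call. = FALSE)
  cut
}

#' P-value desirability
#'
#' The most significant gene (p at or below `p_low_cut`) receives maximum
#' desirability; genes with p above `p_high_cut` (0.05) receive the floor
#' (0.01); in between, desirability falls linearly in p.
#'
#' @param p combined p-values in (0, 1].
#' @param params a [desirability_params()].
#' @param p_low_cut resolved lower cut; defaults to `min(p)` when the params
#'   hold the `"min"` sentinel.
#' @return desirabilities in `[d_min, d_max]`.
#' @export
desirability_pvalue <- function(p, params = desirability_params(),
                                p_low_cut = resolve_p_low_cut(params, p)) {
  check_prob(p, "p")
  hi <- params$p_high_cut
  d <- params$d_max + (p - p_low_cut) * (params$d_min - params$d_max) /
    (hi - p_low_cut)
  d[p <= p_low_cut] <- params$d_max
  d[p > hi] <- params$d_min
  pmin(pmax(d, params$d_min), params$d_max)
}

#' Fold-change desirability
#'
#' Works on the fold-change magnitude FC = 2^|log2fc|: FC at or above
#' `fc_high_cut` (2) maps to the maximum, FC at or below `fc_low_cut` (1.25)
#' to the floor, linear in FC between the cuts. Direction is ignored here and
#' enters only through the cross-dataset concordance factor.
#'
#' @param log2fc log2 fold changes (any sign).
#' @param params a [desirability_params()].
#' @return desirabilities in `[d_min, d_max]`.
#' @export
desirability_foldchange <- function(log2fc, params = desirability_params()) {
  if (any(!is.finite(log2fc))) abort_param("log2fc", "must be finite")
  fc <- 2^abs(log2fc)
  d <- params$d_min + (fc - params$fc_low_cut) *
    (params$d_max - params$d_min) / (params$fc_high_cut - params$fc_low_cut)
  pmin(pmax(d, params$d_min), params$d_max)
}

#' Midbrain-detection desirability
#'
#' @param detected logical: transcript detected in adult midbrain.
#' @param params a [desirability_params()].
#' @return 1 for detected genes, 0.25 otherwise (defaults).
#' @export
desirability_midbrain <- function(detected, params = desirability_params()) {
  ifelse(detected, params$midbrain_detected_score,
         params$midbrain_undetected_score)
}

#' Per-dataset dysregulation score
#'
#' Weighted geometric mean of the three desirabilities with weights 1 (p),
#' 0.5 (fold change) and 0.01 (midbrain). Genes not expressed in the dataset
#' receive the floor `d_min` (0.01).
#'
#' @param d_p,d_fc,d_mb desirabilities in (0, 1] (vectorized).
#' @param params a [desirability_params()].
#' @param expressed logical; unexpressed genes get `d_min`.
#' @return D_dataset values in `[d_min, 1]`.
#' @export
d_dataset <- function(d_p, d_fc, d_mb, params = desirability_params(),
                      expressed = TRUE) {
  if (any(d_p <= 0) || any(d_fc <= 0) || any(d_mb <= 0))
    stop("desirabilities must be positive", call. = FALSE)
  w <- params$weights
  d <- exp((w[1] * log(d_p) + w[2] * log(d_fc) + w[3] * log(d_mb)) / sum(w))
  ifelse(rep_len(expressed, length(d)), d, params$d_min)
}

#' Fold-change direction concordance across datasets
#'
#' Over the datasets in which the gene is expressed (and has a nonzero fold
#' change), concordance is the signed-majority fraction
#' `|n_up - n_down| / (n_up + n_down)`; its desirability rescales it to
#' `[d_min, 1]`. A single expressed dataset (or none with nonzero fold
#' change) gives full concordance; no expressed dataset at all gives the
#' floor and sets the `undefined` flag.
#'
#' @param log2fc numeric vector of per-dataset mean log2 fold changes,
#'   restricted to the datasets in which the gene is expressed.
#' @param params a [desirability_params()].
#' @return list with `concordance` in `[0, 1]` (NA when undefined),
#'   `desirability` in `[d_min, 1]`, and logical `undefined`.
#' @export
concordance_factor <- function(log2fc, params = desirability_params()) {
  if (length(log2fc) == 0)
    return(list(concordance = NA_real_, desirability = params$d_min,
                undefined = TRUE))
  n_up <- sum(log2fc > 0)
  n_down <- sum(log2fc < 0)
  c_val <- if (n_up + n_down == 0) 1 else abs(n_up - n_down) / (n_up + n_down)
  list(concordance = c_val,
       desirability = params$d_min + c_val * (1 - params$d_min),
       undefined = FALSE)
}

#' Overall (multi-dataset) dysregulation score
#'
#' Weighted geometric mean of all per-dataset scores (weight 1 each) and the
#' concordance desirability, whose weight is chosen so that it carries
#' `concordance_weight_share` of the total weight (for six datasets and a
#' share of 0.10: 2/3).
#'
#' @param d_datasets numeric vector of D_dataset values in (0, 1].
#' @param concordance_desirability scalar in (0, 1].
#' @param params a [desirability_params()].
#' @return D_overall in (0, 1].
#' @export
d_overall <- function(d_datasets, concordance_desirability,
                      params = desirability_params()) {
  if (length(d_datasets) == 0) stop("empty dataset score list", call. = FALSE)
  if (any(d_datasets <= 0) || concordance_desirability <= 0)
    stop("scores must be positive", call. = FALSE)
  share <- params$concordance_weight_share
  w_c <- share * length(d_datasets) / (1 - share)
  geometric_mean(c(d_datasets, concordance_desirability),
                 c(rep(1, length(d_datasets)), w_c))
}

#' Group dysregulation score over a dataset subset
#'
#' Unweighted geometric mean of the subset's D_dataset values (no concordance
#' term); used for modality groups such as the single-cell iPSC pair.
#'
#' @param d_datasets numeric vector (non-empty) of D_dataset values.
#' @return geometric mean in (0, 1].
#' @export
group_score <- function(d_datasets) {
  if (length(d_datasets) == 0) stop("empty dataset subset", call. = FALSE)
  if (any(d_datasets <= 0)) stop("scores must be positive", call. = FALSE)
  geometric_mean(d_datasets)
}

#' Score genes across datasets
#'
#' Applies the desirability mappings per dataset, combines them to D_dataset,
#' computes the concordance factor over expressed datasets, and integrates to
#' D_overall. The gene universe is the union of genes expressed in at least
#' one dataset; genes expressed nowhere are excluded.
#'
#' @param de_list named list of [run_de()] tables, one per dataset.
#' @param midbrain_detected named logical vector over genes; genes missing
#'   from it are treated as not detected.
#' @param params a [desirability_params()].
#' @return data.frame (class `gene_score_table`): per-dataset `D_<name>`
#'   columns, `n_expressed_datasets`, `concordance`,
#'   `concordance_desirability`, `D_overall`, `rank`.
#' @export
score_genes <- function(de_list, midbrain_detected,
                        params = desirability_params()) {
  stopifnot(length(de_list) >= 1)
  if (is.null(names(de_list)) || any(!nzchar(names(de_list))))
    names(de_list) <- sprintf("dataset%d", seq_along(de_list))
  expressed_any <- unique(unlist(lapply(de_list, function(de)
    de$gene[de$expressed])))
  universe <- sort(expressed_any)
  n <- length(universe)
  if (n == 0) stop("no gene is expressed in any dataset", call. = FALSE)

  D <- matrix(params$d_min, n, length(de_list),
              dimnames = list(universe, names(de_list)))
  lfc <- matrix(NA_real_, n, length(de_list),
                dimnames = list(universe, names(de_list)))
  expr <- matrix(FALSE, n, length(de_list),
                 dimnames = list(universe, names(de_list)))
  psum <- stats::setNames(rep(0, n), universe)

  mb <- rep(FALSE, n)
  names(mb) <- universe
  common <- intersect(universe, names(midbrain_detected))
  mb[common] <- midbrain_detected[common]

  for (nm in names(de_list)) {
    de <- de_list[[nm]]
    de <- de[de$gene %in% universe, , drop = FALSE]
    idx <- match(de$gene, universe)
    e <- de$expressed
    p_low <- if (any(e)) resolve_p_low_cut(params, de$p_combined[e]) else NA
    d_p <- if (any(e))
      desirability_pvalue(de$p_combined, params, p_low_cut = p_low)
    else rep(params$d_min, nrow(de))
    d_fc <- desirability_foldchange(de$log2fc_mean, params)
    d_mb <- desirability_midbrain(mb[idx], params)
    D[idx, nm] <- d_dataset(d_p, d_fc, d_mb, params, expressed = e)
    lfc[idx[e], nm] <- de$log2fc_mean[e]
    expr[idx, nm] <- e
    psum[idx] <- psum[idx] + de$p_combined
  }

  conc <- t(vapply(seq_len(n), function(i) {
    cf <- concordance_factor(lfc[i, expr[i, ]], params)
    c(cf$concordance, cf$desirability)
  }, numeric(2)))
  d_over <- vapply(seq_len(n), function(i)
    d_overall(D[i, ], conc[i, 2], params), numeric(1))

  tab <- data.frame(gene = universe, stringsAsFactors = FALSE)
  for (nm in colnames(D)) tab[[paste0("D_", nm)]] <- D[, nm]
  tab$n_expressed_datasets <- rowSums(expr)
  tab$concordance <- conc[, 1]
  tab$concordance_desirability <- conc[, 2]
  tab$D_overall <- d_over
  tab$p_combined_sum <- unname(psum)
  tab <- rank_genes(tab)
  class(tab) <- c("gene_score_table", "data.frame")
  tab
}

#' Rank genes by decreasing overall dysregulation
#'
#' Ties in D_overall are broken by the smaller sum of combined p-values across
#' datasets, then lexicographically by gene id, so ordering is deterministic.
#'
#' @param score_table data.frame with `gene`, `D_overall` and (optionally)
#'   `p_combined_sum` columns.
#' @return the table sorted by decreasing D_overall with a `rank` column
#'   (1 = most dysregulated).
#' @export
rank_genes <- function(score_table) {
  psum <- score_table$p_combined_sum %||% rep(0, nrow(score_table))
  o <- order(-score_table$D_overall, psum, score_table$gene)
  out <- score_table[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export a ranked list as RNK (gene TAB score)
#'
#' @param score_table a ranked `gene_score_table`.
#' @param path output file.
#' @param score column used as the ranking score.
#' @export
write_rnk <- function(score_table, path, score = "D_overall") {
  utils::write.table(score_table[order(-score_table[[score]]),
                                 c("gene", score)],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an RNK file
#' @param path RNK file (gene TAB score).
#' @return named numeric vector sorted by decreasing score.
#' @export
read_rnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  v <- stats::setNames(as.numeric(df[[2]]), df[[1]])
  sort(v, decreasing = TRUE)
}
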