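## Pre-ranked gene-set enrichment analysis.
##
## Classic weighted Kolmogorov-Smirnov-like running-sum statistic with
## gene-permutation null: per set, null ES values come from random same-size
## member draws from the ranked universe; NES divides ES by the mean |null ES|
## of matching sign (mean-division normalization); FDR-q follows the standard
## NES-pooled, sign-stratified tail-ratio procedure with cumulative-minimum
## monotonization; FWER-p uses the per-permutation maximum same-sign |NES|
## over all sets.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member gene ids, unique
#'   within a set).
#' @param descriptions named character vector (recycled empty if missing).
#' @return object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  dup <- vapply(sets, function(g) anyDuplicated(g) > 0, logical(1))
  if (any(dup)) {
    warning("duplicate members removed in set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets[dup] <- lapply(sets[dup], unique)
  }
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d sets, sizes %s\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' Read a GMT file
#'
#' Each line is `name TAB description TAB member...`; blank trailing fields
#' are dropped; duplicate members within a line are removed with a warning.
#'
#' @param path GMT file.
#' @return a [geneset_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields",
                 bad[1], path), call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2), nm)
  sets <- stats::setNames(
    lapply(fields, function(f) {
      members <- f[-(1:2)]
      members[nzchar(members)]
    }), nm)
  geneset_collection(sets, desc)
}

#' Write a GMT file
#' @param collection a [geneset_collection()].
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict sets to a universe and filter on size
#'
#' Members absent from the ranked universe are removed; sets whose remaining
#' size falls outside `[min_size, max_size]` (inclusive) are dropped.
#'
#' @param collection a [geneset_collection()].
#' @param universe character vector of ranked gene ids.
#' @param min_size,max_size inclusive size bounds (defaults 15 and 500, the
#'   pre-ranked tool's defaults).
#' @return filtered [geneset_collection()] with a `sizes` attribute.
#' @export
restrict_and_filter <- function(collection, universe,
                                min_size = 15, max_size = 500) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  sets <- lapply(collection$sets, intersect, universe)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  out <- geneset_collection(sets[keep], collection$descriptions[keep])
  attr(out, "sizes") <- lengths(sets[keep])
  out
}

## Fast ES from sorted hit positions. With hit weights w_i = |s_i|^exponent,
## running sum after hit k is cumsum(w)/NR - (pos_k - k)/(N - nh); just before
## hit k it is cumsum(w)[k-1]/NR - (pos_k - 1 - (k-1))/(N - nh). The extremum
## over the whole walk is attained at one of these 2*nh points.
es_from_positions <- function(pos, weights, n_total) {
  nh <- length(pos)
  nr <- sum(weights)
  if (nr <= 0) stop("all hit scores are zero; ES undefined", call. = FALSE)
  miss_unit <- if (n_total > nh) 1 / (n_total - nh) else 0
  cw <- cumsum(weights) / nr
  after <- cw - (pos - seq_len(nh)) * miss_unit
  before <- c(0, cw[-nh]) - (pos - seq_len(nh)) * miss_unit
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, member genes ("hits") add
#' `|score|^weight_exponent / N_R` and non-members subtract `1/(N - N_hits)`;
#' ES is the running-sum value of maximal absolute deviation (sign retained).
#' The leading edge contains the hits at or before the extremum for positive
#' ES, and at or after it for negative ES.
#'
#' @param ranked named numeric vector of scores, sorted decreasing.
#' @param set_members character vector of member gene ids (must be a subset
#'   of the ranked universe).
#' @param weight_exponent exponent on |score| (default 1, the "weighted"
#'   statistic; 0 gives the classic unweighted KS form).
#' @return list with `es`, `running_sum` (length N) and `leading_edge`.
#' @export
enrichment_score <- function(ranked, set_members, weight_exponent = 1) {
  n <- length(ranked)
  hit <- names(ranked) %in% set_members
  if (!any(hit)) stop("no set member is present in the ranked list",
                      call. = FALSE)
  if (length(setdiff(set_members, names(ranked))))
    stop("set members must be a subset of the ranked universe", call. = FALSE)
  w <- abs(ranked)^weight_exponent
  nr <- sum(w[hit])
  if (nr <= 0) stop("all hit scores are zero; ES undefined", call. = FALSE)
  nh <- sum(hit)
  step <- ifelse(hit, w / nr, -(if (n > nh) 1 / (n - nh) else 0))
  running <- cumsum(step)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) names(ranked)[hit & seq_len(n) <= i_max]
             else names(ranked)[hit & seq_len(n) >= i_max]
  list(es = unname(es), running_sum = unname(running), leading_edge = leading)
}

#' Pre-ranked GSEA with gene-permutation significance
#'
#' For each set, `n_permutations` random same-size draws from the universe
#' provide the null ES distribution. NES = ES / mean(|null ES| of the same
#' sign); nominal p is the same-sign null tail fraction; FDR-q and FWER-p
#' follow the standard sign-stratified pooled-NES procedures. Draws consume
#' the seeded generator in set-name sorted order, so results are reproducible
#' and independent of input set order.
#'
#' @param ranked named numeric vector of scores, sorted decreasing (ties must
#'   already be resolved deterministically upstream).
#' @param collection a [geneset_collection()], already restricted/filtered.
#' @param n_permutations number of random gene-set draws (default 1000).
#' @param seed RNG seed.
#' @param weight_exponent see [enrichment_score()].
#' @return data.frame (one row per set): `set`, `size`, `es`, `nes`,
#'   `p_nominal`, `fdr_q`, `fwer_p`, `leading_edge` (semicolon-joined).
#' @export
preranked_gsea <- function(ranked, collection, n_permutations = 1000,
                           seed = 1L, weight_exponent = 1) {
  if (n_permutations < 10)
    abort_param("n_permutations", "must be at least 10")
  if (length(collection$sets) == 0)
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_nominal = numeric(),
                      fdr_q = numeric(), fwer_p = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE))
  ranked <- sort(ranked, decreasing = TRUE)
  n <- length(ranked)
  set_names <- sort(names(collection$sets))
  sizes <- lengths(collection$sets)[set_names]
  w_abs <- abs(ranked)^weight_exponent

  obs <- lapply(set_names, function(nm)
    enrichment_score(ranked, collection$sets[[nm]], weight_exponent))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  # null ES matrix: permutations x sets, drawn in set-name sorted order
  null_es <- withr::with_seed(seed, {
    vapply(seq_along(set_names), function(si) {
      sz <- sizes[si]
      vapply(seq_len(n_permutations), function(j) {
        pos <- sort(sample.int(n, sz))
        es_from_positions(pos, w_abs[pos], n)
      }, numeric(1))
    }, numeric(n_permutations))
  })
  if (is.null(dim(null_es))) null_es <- matrix(null_es, nrow = n_permutations)

  norm_null <- matrix(NA_real_, n_permutations, length(set_names))
  nes <- p_nom <- rep(NA_real_, length(set_names))
  for (si in seq_along(set_names)) {
    nulls <- null_es[, si]
    pos_mean <- mean(nulls[nulls >= 0])
    neg_mean <- mean(abs(nulls[nulls < 0]))
    denom <- ifelse(nulls >= 0, pos_mean, neg_mean)
    norm_null[, si] <- nulls / denom
    own <- if (es_obs[si] >= 0) pos_mean else neg_mean
    nes[si] <- if (is.finite(own) && own > 0) es_obs[si] / own else 0
    same <- if (es_obs[si] >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    p_nom[si] <- if (length(same) == 0) 1 / n_permutations
      else sum(abs(same) >= abs(es_obs[si])) / length(same)
  }
  p_nom <- pmax(p_nom, 1 / n_permutations)

  fdr_q <- gsea_fdr(nes, norm_null)
  fwer_p <- gsea_fwer(nes, norm_null)

  data.frame(set = set_names, size = unname(sizes), es = es_obs, nes = nes,
             p_nominal = p_nom, fdr_q = fdr_q, fwer_p = fwer_p,
             leading_edge = vapply(obs, function(o)
               paste(o$leading_edge, collapse = ";"), ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

## Sign-stratified pooled-NES FDR (2005 procedure): for each observed NES*,
## q = [fraction of pooled same-sign null NES at least as extreme] /
##     [fraction of observed same-sign NES at least as extreme],
## clamped to [0,1] and monotonized by cumulative minimum from the tail.
gsea_fdr <- function(nes, norm_null) {
  q <- rep(NA_real_, length(nes))
  for (sgn in c(1, -1)) {
    idx <- if (sgn > 0) which(nes >= 0) else which(nes < 0)
    if (!length(idx)) next
    pool <- norm_null[if (sgn > 0) norm_null >= 0 else norm_null < 0]
    for (i in idx) {
      tail_null <- if (length(pool)) mean(abs(pool) >= abs(nes[i])) else 0
      tail_obs <- mean(abs(nes[idx]) >= abs(nes[i]))
      q[i] <- min(1, tail_null / max(tail_obs, .Machine$double.eps))
    }
    # monotonize: traversing from least to most extreme NES, q never increases
    o <- order(abs(nes[idx]))
    q[idx][o] <- cummin(q[idx][o])
  }
  q
}

## Sign-stratified max-NES FWER: fraction of permutations whose maximum
## same-sign |NES| over all sets reaches the observed |NES|.
gsea_fwer <- function(nes, norm_null) {
  pos <- norm_null; pos[pos < 0] <- 0
  neg <- norm_null; neg[neg > 0] <- 0
  max_pos <- apply(pos, 1, max)
  max_neg <- apply(abs(neg), 1, max)
  vapply(seq_along(nes), function(i) {
    mx <- if (nes[i] >= 0) max_pos else max_neg
    mean(mx >= abs(nes[i]))
  }, numeric(1))
}

#' Random-label negative control
#'
#' Shuffles the gene-to-score assignment (destroying the gene label / score
#' relationship) and reruns [preranked_gsea()] on the permuted ranking; with
#' a real signal the planted enrichments should vanish.
#'
#' @param ranked named numeric vector of scores.
#' @param collection a [geneset_collection()], already restricted/filtered.
#' @param seed seed for both the label shuffle and the permutation null.
#' @param ... passed to [preranked_gsea()].
#' @return an enrichment result table.
#' @export
label_permutation_control <- function(ranked, collection, seed = 1L, ...) {
  shuffled <- withr::with_seed(seed, {
    stats::setNames(ranked, sample(names(ranked)))
  })
  preranked_gsea(sort(shuffled, decreasing = TRUE), collection,
                 seed = seed, ...)
}

#' Write an enrichment result table as TSV
#' @param result data.frame from [preranked_gsea()].
#' @param path output file.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
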