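#' @keywords internal
"_PACKAGE"

## Shared helpers: argument checks, seeded evaluation, TSV matrix IO.

abort_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort_param(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field, integer = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0))
    abort_param(field, "must be positive")
  if (integer && any(x != round(x)))
    abort_param(field, "must be a whole number")
  invisible(x)
}

## Child seeds are derived as (master + 7919 * k) mod (2^31 - 1) so each
## dataset (and the gene-level stage, k = 0) has an independent stream and
## adding a dataset never perturbs the previous ones.
child_seed <- function(master, k) {
  as.integer((as.double(master) + 7919 * k) %% 2147483647)
}

geometric_mean <- function(x, w = rep(1, length(x))) {
  exp(sum(w * log(x)) / sum(w))
}

#' Write a gene-by-sample matrix as TSV
#'
#' First column `gene` carries row names; remaining columns are samples.
#' @param m numeric matrix with row and column names.
#' @param path output file.
#' @keywords internal
write_matrix_tsv <- function(m, path) {
  body <- if (is.double(m)) sprintf("%.17g", m) else format(m, trim = TRUE)
  body <- matrix(body, nrow = nrow(m))
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## MatrixMarket coordinate writer with full double precision (1-based
## indices); Matrix::writeMM truncates doubles to ~%g precision, which breaks
## lossless round-trips. Reading is done with Matrix::readMM.
write_mtx_full <- function(m, path) {
  nz <- which(m != 0, arr.ind = TRUE)
  int_valued <- is.integer(m) || all(m[nz] == round(m[nz]))
  vals <- if (int_valued) format(m[nz], trim = TRUE, scientific = FALSE)
          else sprintf("%.17g", m[nz])
  lines <- c(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                     if (int_valued) "integer" else "real"),
             sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz)),
             sprintf("%d %d %s", nz[, 1], nz[, 2], vals))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
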