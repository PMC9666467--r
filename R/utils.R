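#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
#' @importFrom Rcpp sourceCpp
#' @useDynLib transectr, .registration = TRUE
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Convert a wide count tibble to a sample-by-ASV matrix
#'
#' Count tables are carried as wide tibbles whose first column, `sample_id`,
#' identifies the sample and whose remaining columns hold non-negative
#' integer read counts, one column per ASV. This helper validates that
#' contract and returns the plain numeric matrix (samples in rows) used by
#' the numerical routines.
#'
#' @param counts A count tibble (`sample_id` plus one integer column per ASV).
#' @param require_integer Check that all counts are whole numbers.
#' @return A numeric matrix with `sample_id` row names and ASV column names.
#' @export
count_matrix <- function(counts, require_integer = FALSE) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort("`counts` must be a data frame with a `sample_id` column and at least one ASV column.")
  }
  id_col <- if ("sample_id" %in% names(counts)) "sample_id" else names(counts)[1]
  ids <- as.character(counts[[id_col]])
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated sample IDs: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mat <- as.matrix(counts[setdiff(names(counts), id_col)])
  if (anyDuplicated(colnames(mat))) {
    abort(paste0("Duplicated ASV IDs: ",
                 paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", ")))
  }
  if (!is.numeric(mat)) abort("Count columns must be numeric.")
  if (any(is.na(mat))) abort("Counts contain missing values.")
  if (any(mat < 0)) abort("Counts must be non-negative.")
  if (require_integer && any(abs(mat - round(mat)) > 1e-8)) {
    bad <- which(abs(mat - round(mat)) > 1e-8, arr.ind = TRUE)[1, ]
    abort(sprintf("Non-integer count at sample '%s', ASV '%s'.",
                  ids[bad[1]], colnames(mat)[bad[2]]))
  }
  rownames(mat) <- ids
  storage.mode(mat) <- "double"
  mat
}

# Inverse of count_matrix().
count_tibble <- function(mat) {
  tibble::as_tibble(cbind(
    tibble::tibble(sample_id = rownames(mat)),
    tibble::as_tibble(mat)
  ))
}

#' Long pairwise table from a square dissimilarity matrix
#'
#' All pairwise statistics in the package are returned as long tibbles with
#' one row per unordered sample pair (`sample_a` precedes `sample_b` in the
#' input's sample order). `dist_matrix()` is the inverse operation.
#'
#' @param mat A symmetric matrix with matching row/column names (or a
#'   `dist` object).
#' @param metric Optional metric name stored in the `metric` attribute.
#' @return A tibble with columns `sample_a`, `sample_b`, `value`.
#' @export
pairwise_tbl <- function(mat, metric = NULL) {
  if (inherits(mat, "dist")) mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat))
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(mat)))
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  out <- tibble::tibble(
    sample_a = ids[idx[, 1]],
    sample_b = ids[idx[, 2]],
    value = mat[idx]
  )
  attr(out, "metric") <- metric
  class(out) <- c("pairwise_dist", class(out))
  out
}

#' @rdname pairwise_tbl
#' @param pw A pairwise tibble as returned by [pairwise_tbl()].
#' @export
dist_matrix <- function(pw) {
  if (is.matrix(pw)) return(pw)
  if (inherits(pw, "dist")) return(as.matrix(pw))
  stopifnot(all(c("sample_a", "sample_b", "value") %in% names(pw)))
  ids <- unique(c(pw$sample_a, pw$sample_b))
  n <- length(ids)
  mat <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- match(pw$sample_a, ids); ib <- match(pw$sample_b, ids)
  mat[cbind(ia, ib)] <- pw$value
  mat[cbind(ib, ia)] <- pw$value
  mat
}

# Accept a pairwise tibble, dist or matrix and return a square matrix.
as_square <- function(x) {
  if (is.matrix(x)) x else dist_matrix(x)
}

# Row-wise minima of a matrix without apply() overhead.
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

# Write a small provenance sidecar next to an output file.
write_provenance <- function(path, params) {
  params$package_version <- as.character(utils::packageVersion("transectr"))
  yaml::write_yaml(params, paste0(path, ".provenance.yml"))
  invisible(path)
}
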