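#' Read an ASV count table from TSV
#'
#' The file must have one header row. With `orientation = "samples"` the
#' first column holds sample IDs and the remaining columns ASVs; with
#' `orientation = "asvs"` rows are ASVs and columns samples, and the table
#' is transposed on read so that the returned tibble is always
#' sample-major.
#'
#' @param path Path to a TSV file.
#' @param orientation Whether file rows are `"samples"` or `"asvs"`.
#' @return A count tibble (`sample_id` plus one integer column per ASV).
#' @export
read_count_table <- function(path, orientation = c("samples", "asvs")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[-1])
  if (any(is.na(mat))) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric or missing count at row '%s', column '%s' of %s.",
                  ids[bad[1]], colnames(mat)[bad[2]], path))
  }
  if (any(abs(mat - round(mat)) > 1e-8)) {
    bad <- which(abs(mat - round(mat)) > 1e-8, arr.ind = TRUE)[1, ]
    abort(sprintf("Non-integer count at row '%s', column '%s' of %s.",
                  ids[bad[1]], colnames(mat)[bad[2]], path))
  }
  rownames(mat) <- ids
  if (orientation == "asvs") mat <- t(mat)
  if (anyDuplicated(rownames(mat))) {
    abort(paste0("Duplicated sample IDs: ",
                 paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(mat))) {
    abort(paste0("Duplicated ASV IDs: ",
                 paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", ")))
  }
  count_tibble(mat)
}

#' Write an ASV count table to TSV
#'
#' Round-trips losslessly with [read_count_table()]. A YAML provenance
#' sidecar (`<path>.provenance.yml`) records the orientation and package
#' version.
#'
#' @inheritParams count_matrix
#' @inheritParams read_count_table
#' @param path Output TSV path.
#' @param sidecar Write the provenance sidecar.
#' @export
write_count_table <- function(counts, path, orientation = c("samples", "asvs"),
                              sidecar = TRUE) {
  orientation <- match.arg(orientation)
  mat <- count_matrix(counts, require_integer = TRUE)
  storage.mode(mat) <- "integer"
  if (orientation == "asvs") {
    out <- tibble::as_tibble(t(mat), rownames = "asv_id")
  } else {
    out <- tibble::as_tibble(mat, rownames = "sample_id")
  }
  readr::write_tsv(out, path, progress = FALSE)
  if (sidecar) write_provenance(path, list(writer = "write_count_table",
                                           orientation = orientation))
  invisible(counts)
}

#' Read sample metadata from TSV
#'
#' Expects a `sample_id` column; all other columns are read with type
#' guessing (environmental variables numeric, province/size fraction
#' character).
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(meta)) {
    abort("Metadata must contain a `sample_id` column.")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("Duplicated sample IDs in metadata: ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")))
  }
  meta
}

#' @rdname read_sample_metadata
#' @param meta A metadata tibble.
#' @param path Output TSV path.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(meta)
}

#' Three-clause prevalence/abundance filter rule
#'
#' Constructs the rule object consumed by [abundance_filter()]. The
#' defaults reproduce the standard marine amplicon filter: an ASV is kept
#' when its share of all reads in the dataset exceeds `global_min_fraction`
#' (0.001%) *and* it satisfies at least one of three clauses: (i) relative
#' abundance > 1% in at least 2 samples, (ii) relative abundance > 0.1% in
#' at least 2% of samples, (iii) present (any abundance) in at least 5% of
#' samples.
#'
#' @param global_min_fraction Whole-dataset read-fraction threshold
#'   (strict).
#' @param clause1_min_samples,clause1_min_rel_abund Clause (i) thresholds.
#' @param clause2_min_sample_fraction,clause2_min_rel_abund Clause (ii)
#'   thresholds; the sample count is `ceiling(fraction * n_samples)`.
#' @param clause3_min_sample_fraction Clause (iii) prevalence threshold.
#' @return A `filter_rule` list.
#' @export
filter_rule <- function(global_min_fraction = 1e-5,
                        clause1_min_samples = 2, clause1_min_rel_abund = 0.01,
                        clause2_min_sample_fraction = 0.02, clause2_min_rel_abund = 0.001,
                        clause3_min_sample_fraction = 0.05) {
  vals <- c(global_min_fraction, clause1_min_rel_abund,
            clause2_min_sample_fraction, clause2_min_rel_abund,
            clause3_min_sample_fraction)
  if (any(vals < 0 | vals > 1)) abort("All filter thresholds must lie in [0, 1].")
  structure(list(global_min_fraction = global_min_fraction,
                 clause1_min_samples = clause1_min_samples,
                 clause1_min_rel_abund = clause1_min_rel_abund,
                 clause2_min_sample_fraction = clause2_min_sample_fraction,
                 clause2_min_rel_abund = clause2_min_rel_abund,
                 clause3_min_sample_fraction = clause3_min_sample_fraction),
            class = "filter_rule")
}

#' Apply the three-clause abundance filter to a count table
#'
#' Keeps exactly the ASVs whose whole-dataset read fraction strictly
#' exceeds the global threshold and that satisfy at least one of the three
#' prevalence/abundance clauses of the rule (see [filter_rule()]). Samples
#' are never removed; the filter is idempotent.
#'
#' @inheritParams count_matrix
#' @param rule A [filter_rule()] object.
#' @return The filtered count tibble.
#' @export
abundance_filter <- function(counts, rule = filter_rule()) {
  mat <- count_matrix(counts)
  if (nrow(mat) == 0 || ncol(mat) == 0 || sum(mat) == 0) {
    abort("Cannot filter an empty count table.")
  }
  n_samples <- nrow(mat)
  rel <- mat / pmax(rowSums(mat), 1)
  global_ok <- colSums(mat) / sum(mat) > rule$global_min_fraction
  c1 <- colSums(rel > rule$clause1_min_rel_abund) >= rule$clause1_min_samples
  c2 <- colSums(rel > rule$clause2_min_rel_abund) >=
    ceiling(rule$clause2_min_sample_fraction * n_samples)
  c3 <- colSums(mat > 0) >= ceiling(rule$clause3_min_sample_fraction * n_samples)
  keep <- global_ok & (c1 | c2 | c3)
  count_tibble(mat[, keep, drop = FALSE])
}

#' Rarefy all samples to a common read depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`. Samples whose total is below `depth`
#' are dropped with a warning naming them; samples at exactly `depth` are
#' returned unchanged.
#'
#' @inheritParams count_matrix
#' @param depth Target reads per sample (default 8000).
#' @param seed Optional RNG seed for reproducibility.
#' @return The rarefied count tibble.
#' @export
rarefy <- function(counts, depth = 8000, seed = NULL) {
  if (length(depth) != 1 || depth < 1) abort("`depth` must be a positive integer.")
  mat <- count_matrix(counts, require_integer = TRUE)
  totals <- rowSums(mat)
  drop <- totals < depth
  if (any(drop)) {
    warn(paste0("Dropped ", sum(drop), " sample(s) with fewer than ", depth,
                " reads: ", paste(rownames(mat)[drop], collapse = ", ")))
    mat <- mat[!drop, , drop = FALSE]
  }
  if (nrow(mat) == 0) abort("No samples left after depth filtering.")
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(mat, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ))
  storage.mode(out) <- "double"
  count_tibble(out)
}

#' Relative abundances per sample
#'
#' @inheritParams count_matrix
#' @return A tibble of the same shape with each sample's row summing to 1.
#' @export
relative_abundance <- function(counts) {
  mat <- count_matrix(counts)
  totals <- rowSums(mat)
  if (any(totals == 0)) {
    abort(paste0("Zero-sum sample(s): ",
                 paste(rownames(mat)[totals == 0], collapse = ", ")))
  }
  count_tibble(mat / totals)
}

#' Inverse Simpson diversity (effective number of ASVs)
#'
#' For a single count (or proportion) vector returns `1 / sum(p^2)`; for a
#' count tibble returns one value per sample. Scale- and
#' permutation-invariant; equals the number of ASVs when all are equally
#' abundant.
#'
#' @param x A numeric vector of counts or a count tibble.
#' @return A scalar, or a tibble with columns `sample_id`, `inverse_simpson`.
#' @export
inverse_simpson <- function(x) {
  if (is.numeric(x)) {
    if (all(x == 0)) abort("Cannot compute diversity of an all-zero vector.")
    if (any(x < 0)) abort("Counts must be non-negative.")
    return(as.numeric(vegan::diversity(x, index = "invsimpson")))
  }
  mat <- count_matrix(x)
  if (any(rowSums(mat) == 0)) {
    abort(paste0("All-zero sample(s): ",
                 paste(rownames(mat)[rowSums(mat) == 0], collapse = ", ")))
  }
  tibble::tibble(
    sample_id = rownames(mat),
    inverse_simpson = as.numeric(vegan::diversity(mat, index = "invsimpson"))
  )
}
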