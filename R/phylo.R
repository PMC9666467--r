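#' Cophenetic (patristic) distances between tree tips
#'
#' Sum of branch lengths on the path between each pair of tips of a rooted
#' tree with branch lengths.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return A symmetric tip-by-tip matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape `phylo` object.")
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    abort(sprintf("Missing branch length on edge %d (%d -> %d).",
                  bad, tree$edge[bad, 1], tree$edge[bad, 2]))
  }
  if (anyDuplicated(tree$tip.label)) abort("Tree tip labels must be unique.")
  ape::cophenetic.phylo(tree)
}

# Edge-by-tip descendant indicator matrix, rows in tree$edge order.
# Row e is TRUE for the tips descending from the child node of edge e.
edge_tip_matrix <- function(tree) {
  n_tip <- length(tree$tip.label)
  po <- ape::postorder(tree)
  desc <- matrix(FALSE, max(tree$edge), n_tip)
  desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in po) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[parent, ] <- desc[parent, ] | desc[child, ]
  }
  out <- desc[tree$edge[, 2], , drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

# Weighted beta mean nearest taxon distance between two communities given
# the cophenetic submatrix D over (ia x ib) index sets and weights.
bmntd_pair <- function(D, ia, ib, wa, wb) {
  M <- D[ia, ib, drop = FALSE]
  0.5 * (sum(wa * row_mins(M)) + sum(wb * row_mins(t(M))))
}

#' Beta mean nearest taxon distance between all sample pairs
#'
#' For each pair of samples, the mean phylogenetic distance from each ASV
#' in one sample to its closest relative in the other, averaged
#' symmetrically over both directions. With `weighted = TRUE` each ASV is
#' weighted by its relative abundance, otherwise uniformly by 1/richness.
#'
#' @inheritParams count_matrix
#' @param coph Cophenetic distance matrix covering all ASVs of the table
#'   (see [cophenetic_distances()]).
#' @param weighted Use relative-abundance weights.
#' @return A pairwise tibble (`sample_a`, `sample_b`, `value`).
#' @export
beta_mntd <- function(counts, coph, weighted = TRUE) {
  mat <- count_matrix(counts)
  missing <- setdiff(colnames(mat), rownames(coph))
  if (length(missing) > 0) {
    abort(paste0("ASVs absent from the cophenetic matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  D <- coph[colnames(mat), colnames(mat), drop = FALSE]
  n <- nrow(mat)
  pres <- lapply(seq_len(n), function(i) which(mat[i, ] > 0))
  if (any(lengths(pres) == 0)) {
    abort(paste0("Sample(s) with no ASVs present: ",
                 paste(rownames(mat)[lengths(pres) == 0], collapse = ", ")))
  }
  w <- lapply(seq_len(n), function(i) {
    x <- mat[i, pres[[i]]]
    if (weighted) x / sum(x) else rep(1 / length(x), length(x))
  })
  out <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- bmntd_pair(D, pres[[i]], pres[[j]], w[[i]], w[[j]])
    }
  }
  pairwise_tbl(out, metric = if (weighted) "bmntd_weighted" else "bmntd_unweighted")
}

#' Unweighted UniFrac distances between all sample pairs
#'
#' Fraction of branch length unique to either sample on the subtree
#' spanned by the tips present in the pair (tips absent from both samples
#' are pruned, as are branches rootward of the pair's most recent common
#' ancestor).
#'
#' @inheritParams beta_mntd
#' @param tree An `ape::phylo` tree containing every ASV of the table as a
#'   tip.
#' @return A pairwise tibble with values in \[0, 1\].
#' @export
unweighted_unifrac <- function(counts, tree) {
  mat <- count_matrix(counts)
  missing <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("ASVs absent from the tree: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  pres <- mat > 0
  if (any(rowSums(pres) == 0)) {
    abort(paste0("Sample(s) with no ASVs present: ",
                 paste(rownames(mat)[rowSums(pres) == 0], collapse = ", ")))
  }
  E <- edge_tip_matrix(tree)           # edges x tips
  len <- tree$edge.length
  tipnames <- tree$tip.label
  occ <- matrix(0, length(tipnames), nrow(mat), dimnames = list(tipnames, rownames(mat)))
  occ[colnames(mat), ] <- t(pres)
  edge_cnt <- E %*% occ                # edges x samples: present descendants
  n <- nrow(mat)
  out <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- edge_cnt[, i] > 0
      b <- edge_cnt[, j] > 0
      in_union <- a | b
      # union size below each edge vs total union -> drop edges at/above MRCA
      u_tot <- sum(occ[, i] > 0 | occ[, j] > 0)
      u_below <- E %*% (as.numeric(occ[, i] > 0 | occ[, j] > 0))
      keep <- in_union & (u_below < u_tot)
      unique_len <- sum(len[keep & xor(a, b)])
      total_len <- sum(len[keep])
      if (total_len == 0) {
        out[i, j] <- out[j, i] <- 0
      } else {
        out[i, j] <- out[j, i] <- unique_len / total_len
      }
    }
  }
  pairwise_tbl(out, metric = "unweighted_unifrac")
}

#' Per-ASV environmental niches as abundance-weighted means
#'
#' The niche of an ASV for an environmental variable is the mean of that
#' variable over the samples where the ASV occurs, weighted by the ASV's
#' relative abundances. Optionally the first principal-component axes of
#' the standardized environmental variables are added as synthetic niche
#' axes.
#'
#' @inheritParams count_matrix
#' @param meta Sample metadata tibble (must contain `sample_id` and the
#'   requested variables).
#' @param variables Character vector of metadata columns; defaults to all
#'   numeric columns except coordinates and depth.
#' @param pca_axes Number of PCA axes (0 to disable) computed from the
#'   standardized `variables` and averaged like any other variable.
#' @return A tibble with `asv_id` and one niche column per variable.
#' @export
asv_niche <- function(counts, meta, variables = NULL, pca_axes = 0) {
  mat <- count_matrix(counts)
  if (!"sample_id" %in% names(meta)) abort("`meta` must contain `sample_id`.")
  meta <- meta[match(rownames(mat), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) abort("Metadata is missing some samples of the table.")
  if (is.null(variables)) {
    num <- names(meta)[vapply(meta, is.numeric, logical(1))]
    variables <- setdiff(num, c("latitude", "longitude", "depth"))
  }
  if (length(variables) == 0) abort("No environmental variables selected.")
  env <- as.matrix(meta[, variables, drop = FALSE])
  if (pca_axes > 0) {
    pc <- stats::prcomp(env, center = TRUE, scale. = TRUE)
    k <- min(pca_axes, ncol(pc$x))
    ax <- pc$x[, seq_len(k), drop = FALSE]
    colnames(ax) <- paste0("PC", seq_len(k))
    env <- cbind(env, ax)
  }
  rel <- mat / rowSums(mat)
  absent <- colSums(rel) == 0
  if (any(absent)) {
    inform(paste0("Excluding ", sum(absent), " ASV(s) absent from all samples."))
    rel <- rel[, !absent, drop = FALSE]
  }
  if (anyNA(env)) abort("Environmental variables contain missing values.")
  w_sum <- colSums(rel)
  niches <- t(rel) %*% env / w_sum
  tibble::as_tibble(cbind(tibble::tibble(asv_id = colnames(rel)),
                          tibble::as_tibble(niches)))
}

#' Binned phylogenetic signal across ASV pairs
#'
#' Bins all ASV pairs into equal-width cophenetic-distance bins and
#' reports the mean absolute niche difference and pair count per bin. An
#' increase of the bin means over short phylogenetic distances indicates
#' niche conservatism.
#'
#' @param coph Cophenetic distance matrix.
#' @param niches Niche tibble from [asv_niche()].
#' @param variable Niche column to analyze.
#' @param n_bins Number of equal-width distance bins (default 100).
#' @return A tibble with `bin`, `phylo_dist_mid`, `mean_abs_diff`, `n_pairs`.
#' @export
phylo_signal_asv <- function(coph, niches, variable, n_bins = 100) {
  ids <- intersect(rownames(coph), niches$asv_id)
  if (length(ids) < 2) abort("Need at least two ASVs present in both inputs.")
  n_pairs <- choose(length(ids), 2)
  if (n_pairs < n_bins) {
    abort(sprintf("Only %d ASV pairs for %d bins; reduce `n_bins`.",
                  n_pairs, n_bins))
  }
  D <- coph[ids, ids]
  z <- niches[[variable]][match(ids, niches$asv_id)]
  iu <- which(upper.tri(D))
  d <- D[iu]
  dz <- abs(outer(z, z, "-"))[iu]
  breaks <- seq(0, max(d), length.out = n_bins + 1)
  bin_of_pair <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1),
                      n_bins)
  bin_f <- factor(bin_of_pair, levels = seq_len(n_bins))
  tibble::tibble(
    bin = seq_len(n_bins),
    phylo_dist_mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
    mean_abs_diff = as.numeric(tapply(dz, bin_f, mean)),
    n_pairs = as.integer(table(bin_f))
  )
}

#' Mantel correlogram of habitat difference over phylogenetic distance
#'
#' Tests, per phylogenetic-distance class, whether habitat differences
#' within the class deviate from the matrix-wide expectation (positive
#' values = niche similarity among close relatives). Distance classes are
#' equal-frequency bins; p-values come from permutations with progressive
#' Holm correction. This is the phylogenetic-signal precondition of the
#' null-model framework.
#'
#' @param d_phylo,d_habitat Conformable symmetric matrices or pairwise
#'   tibbles of phylogenetic and habitat (niche) distances.
#' @param n_bins Number of distance classes (default 40).
#' @param n_perm Permutations per class (default 999).
#' @param seed Optional RNG seed.
#' @return A `mantel_correlogram` tibble: `bin`, `class_index` (class
#'   center), `n_dist`, `mantel_r`, `p_value`, `p_corrected`.
#' @export
mantel_correlogram <- function(d_phylo, d_habitat, n_bins = 40, n_perm = 999,
                               seed = NULL) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  Dp <- as_square(d_phylo); Dh <- as_square(d_habitat)
  if (!all(dim(Dp) == dim(Dh))) abort("Distance matrices are not conformable.")
  if (!is.null(rownames(Dp)) && !is.null(rownames(Dh))) {
    Dh <- Dh[rownames(Dp), rownames(Dp)]
  }
  v <- Dp[upper.tri(Dp)]
  qs <- stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1), names = FALSE)
  qs[1] <- qs[1] - 1e-9; qs[length(qs)] <- qs[length(qs)] + 1e-9
  breaks <- unique(qs)
  if (length(breaks) - 1 < n_bins) {
    inform(sprintf("Tied distances reduced the correlogram to %d classes.",
                   length(breaks) - 1))
  }
  if (length(breaks) - 1 < 2) {
    # a single distance class contains every pair: the class-membership
    # indicator is constant and the Mantel statistic undefined
    inform("Single distance class: Mantel statistic undefined, returning NA.")
    out <- tibble::tibble(bin = 1L, class_index = mean(v), n_dist = length(v),
                          mantel_r = NA_real_, p_value = NA_real_,
                          p_corrected = NA_real_)
    class(out) <- c("mantel_correlogram", class(out))
    return(out)
  }
  res <- with_seed(seed, vegan::mantel.correlog(
    D.eco = stats::as.dist(Dh), D.geo = stats::as.dist(Dp),
    break.pts = breaks, cutoff = FALSE, nperm = n_perm,
    mult = "holm", progressive = TRUE
  ))
  m <- as.data.frame(res$mantel.res)
  out <- tibble::tibble(
    bin = seq_len(nrow(m)),
    class_index = m[[1]],
    n_dist = m[[2]],
    mantel_r = m[[3]],
    p_value = m[[4]],
    p_corrected = m[[5]]
  )
  class(out) <- c("mantel_correlogram", class(out))
  out
}
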