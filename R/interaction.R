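#' SparCC configuration
#'
#' @param n_resamples Dirichlet posterior draws over which the final
#'   correlation estimate is the median (default 20).
#' @param n_exclusion_rounds Iterations of strongly-correlated-pair
#'   exclusion (default 10).
#' @param exclusion_threshold Correlation magnitude above which the
#'   strongest pair is excluded from the basis-variance system each round
#'   (default 0.1).
#' @param seed Optional RNG seed.
#' @return A `sparcc_config` list.
#' @export
sparcc_config <- function(n_resamples = 20, n_exclusion_rounds = 10,
                          exclusion_threshold = 0.1, seed = NULL) {
  if (n_resamples < 1) abort("`n_resamples` must be at least 1.")
  if (exclusion_threshold <= 0 || exclusion_threshold >= 1) {
    abort("`exclusion_threshold` must lie in (0, 1).")
  }
  structure(list(n_resamples = as.integer(n_resamples),
                 n_exclusion_rounds = as.integer(n_exclusion_rounds),
                 exclusion_threshold = exclusion_threshold,
                 seed = seed),
            class = "sparcc_config")
}

# One SparCC basis-correlation estimate from a fractions matrix
# (samples x taxa). Solves the log-ratio variance system with iterative
# exclusion of the most strongly correlated pair.
sparcc_one <- function(frac, n_exclusion_rounds, exclusion_threshold) {
  lf <- log(frac)
  p <- ncol(lf)
  V <- stats::var(lf)                      # covariance of log fractions
  d <- diag(V)
  Tmat <- outer(d, d, "+") - 2 * V         # t_ij = var(log(x_i/x_j))
  include <- matrix(TRUE, p, p); diag(include) <- FALSE
  estimate <- function() {
    d_i <- rowSums(include)
    A <- include * 1; diag(A) <- d_i
    t_i <- rowSums(Tmat * include)
    omega2 <- tryCatch(solve(A, t_i), error = function(e) rep(NA_real_, p))
    omega2 <- pmax(omega2, 1e-12)
    om <- sqrt(omega2)
    rho <- (outer(omega2, omega2, "+") - Tmat) / (2 * outer(om, om))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }
  rho <- estimate()
  for (r in seq_len(n_exclusion_rounds)) {
    cand <- abs(rho) * include
    m <- max(cand)
    if (m <= exclusion_threshold) break
    idx <- which(cand == m, arr.ind = TRUE)[1, ]
    include[idx[1], idx[2]] <- include[idx[2], idx[1]] <- FALSE
    # a taxon must keep at least 3 included pairs for the system to stay
    # informative; re-include its weakest exclusion would overfit, so stop
    if (any(rowSums(include) < 3)) break
    rho <- estimate()
  }
  rho
}

#' SparCC compositional correlations
#'
#' Estimates basis (latent absolute-abundance) correlations between ASVs
#' from compositional counts. Each of `n_resamples` draws smooths the
#' counts with a Dirichlet posterior (counts + 1), computes all pairwise
#' log-ratio variances, solves the sparse basis-variance approximation
#' with iterative exclusion of strongly correlated pairs, and converts
#' basis variances to correlations; the final estimate is the
#' element-wise median across draws, clamped to \[-1, 1\].
#'
#' @inheritParams count_matrix
#' @param config A [sparcc_config()].
#' @return A `sparcc_fit` object; `$correlations` is the symmetric ASV
#'   association matrix with unit diagonal. Use [tidy()] for a long
#'   tibble.
#' @export
sparcc <- function(counts, config = sparcc_config()) {
  mat <- count_matrix(counts)
  p <- ncol(mat)
  if (p < 4) abort("SparCC needs at least 4 ASVs (basis system is underdetermined below that).")
  if (nrow(mat) < 10) warn("Fewer than 10 samples; SparCC estimates will be unstable.")
  allzero <- colSums(mat) == 0
  if (any(allzero)) {
    abort(paste0("ASV(s) with zero counts in every sample: ",
                 paste(colnames(mat)[allzero], collapse = ", ")))
  }
  rhos <- with_seed(config$seed, {
    lapply(seq_len(config$n_resamples), function(r) {
      # Dirichlet(counts + 1) draw per sample via normalized gammas
      g <- matrix(stats::rgamma(length(mat), shape = mat + 1), nrow(mat), p)
      frac <- g / rowSums(g)
      sparcc_one(frac, config$n_exclusion_rounds, config$exclusion_threshold)
    })
  })
  arr <- array(unlist(rhos), dim = c(p, p, length(rhos)))
  med <- apply(arr, c(1, 2), stats::median)
  med <- (med + t(med)) / 2
  med <- pmin(pmax(med, -1), 1)
  diag(med) <- 1
  dimnames(med) <- list(colnames(mat), colnames(mat))
  structure(list(correlations = med, config = config,
                 n_samples = nrow(mat), n_taxa = p),
            class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat("SparCC fit:", x$n_taxa, "ASVs,", x$n_samples, "samples,",
      x$config$n_resamples, "resamples\n")
  off <- x$correlations[upper.tri(x$correlations)]
  cat(sprintf("correlations: median %.3f, range [%.3f, %.3f]\n",
              stats::median(off), min(off), max(off)))
  invisible(x)
}

# Shared TINA/PINA machinery: project samples through a similarity matrix
# and take pairwise cosine dissimilarities of the projected profiles.
interaction_dissimilarity <- function(mat, S, weighted, metric) {
  ids <- colnames(mat)
  S <- S[ids, ids, drop = FALSE]
  pres <- mat > 0
  if (any(rowSums(pres) == 0)) {
    abort(paste0("Sample(s) with no ASVs in the association matrix: ",
                 paste(rownames(mat)[rowSums(pres) == 0], collapse = ", ")))
  }
  W <- if (weighted) mat / rowSums(mat) else pres / rowSums(pres)
  U <- W %*% S                           # samples x taxa association profiles
  G <- U %*% t(U)
  nrm <- sqrt(diag(G))
  C <- G / outer(nrm, nrm)
  D <- 1 - C
  D[D < 0] <- 0; D[D > 1] <- 1
  diag(D) <- 0
  dimnames(D) <- list(rownames(mat), rownames(mat))
  pairwise_tbl(D, metric = metric)
}

#' Taxon interaction-adjusted dissimilarity (TINA)
#'
#' Projects each sample's (relative-abundance or presence) profile through
#' the co-occurrence similarity matrix S = (rho + 1)/2 and returns one
#' minus the cosine similarity of the projected profiles. Samples whose
#' ASVs co-occur strongly with each other are similar under TINA even when
#' they share no ASVs.
#'
#' @inheritParams count_matrix
#' @param assoc A `sparcc_fit` or an ASV-by-ASV correlation matrix in
#'   \[-1, 1\] covering all ASVs of the table.
#' @param weighted Use relative-abundance weights (default) or
#'   presence/richness weights.
#' @return A pairwise tibble with values in \[0, 1\].
#' @export
tina <- function(counts, assoc, weighted = TRUE) {
  mat <- count_matrix(counts)
  S_rho <- if (inherits(assoc, "sparcc_fit")) assoc$correlations else assoc
  missing <- setdiff(colnames(mat), rownames(S_rho))
  if (length(missing) > 0) {
    abort(paste0("ASVs absent from the association matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  S <- (S_rho + 1) / 2
  interaction_dissimilarity(mat, S, weighted,
                            if (weighted) "tina_weighted" else "tina_unweighted")
}

#' Phylogenetic interaction-adjusted dissimilarity (PINA)
#'
#' Identical machinery to [tina()], with phylogenetic similarity
#' S = 1 - d/max(d) from the cophenetic distance matrix in place of the
#' co-occurrence similarity.
#'
#' @inheritParams tina
#' @param coph Cophenetic distance matrix covering all ASVs of the table.
#' @return A pairwise tibble with values in \[0, 1\].
#' @export
pina <- function(counts, coph, weighted = TRUE) {
  mat <- count_matrix(counts)
  missing <- setdiff(colnames(mat), rownames(coph))
  if (length(missing) > 0) {
    abort(paste0("ASVs absent from the cophenetic matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  S <- 1 - coph / max(coph)
  interaction_dissimilarity(mat, S, weighted,
                            if (weighted) "pina_weighted" else "pina_unweighted")
}
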