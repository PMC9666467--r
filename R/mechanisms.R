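#' Null-model configuration for the assembly-mechanism analysis
#'
#' @param n_null Number of null randomizations per sample pair (default
#'   999).
#' @param seed Optional RNG seed.
#' @param pool_scope Taxa pool for the tip-shuffling null of the betaNTI
#'   model: `"whole_matrix"` shuffles tip identities across all ASVs of
#'   the table (the regional-pool null of the classical framework),
#'   `"pairwise"` restricts the shuffle to the union of taxa present in
#'   the pair.
#' @return A `null_config` list.
#' @export
null_config <- function(n_null = 999, seed = NULL,
                        pool_scope = c("whole_matrix", "pairwise")) {
  if (n_null < 1) abort("`n_null` must be at least 1.")
  structure(list(n_null = as.integer(n_null), seed = seed,
                 pool_scope = match.arg(pool_scope)),
            class = "null_config")
}

#' Beta nearest taxon index (betaNTI) for all sample pairs
#'
#' For each sample pair, the observed abundance-weighted beta mean nearest
#' taxon distance (betaMNTD) is standardized against a null distribution
#' obtained by shuffling ASV identities across the tips of the cophenetic
#' matrix (abundances follow their ASV labels): betaNTI = (observed -
#' mean(null)) / sd(null). Values below -2 indicate phylogenetically more
#' similar pairs than expected (homogeneous selection), above +2 less
#' similar (heterogeneous selection).
#'
#' Phylogenetic signal (see [mantel_correlogram()]) should be verified on
#' the data subset before interpreting betaNTI.
#'
#' @inheritParams beta_mntd
#' @param config A [null_config()].
#' @return A pairwise tibble with columns `sample_a`, `sample_b`,
#'   `bmntd_obs`, `null_mean`, `null_sd`, `bnti`. Pairs with zero null
#'   standard deviation get `NA` with a warning.
#' @export
bnti <- function(counts, coph, config = null_config()) {
  mat <- count_matrix(counts)
  missing <- setdiff(colnames(mat), rownames(coph))
  if (length(missing) > 0) {
    abort(paste0("ASVs absent from the cophenetic matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (nrow(mat) < 2) abort("Need at least two samples.")
  D <- coph[colnames(mat), colnames(mat), drop = FALSE]
  n <- nrow(mat); p <- ncol(mat)
  pres <- lapply(seq_len(n), function(i) which(mat[i, ] > 0))
  w <- lapply(seq_len(n), function(i) {
    x <- mat[i, pres[[i]]]; x / sum(x)
  })
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- with_seed(config$seed, {
    if (config$pool_scope == "whole_matrix") {
      # Pre-draw the whole-matrix null permutations once: the same
      # shuffled tip assignment is applied to every pair within a
      # replicate, as when the full table is reassembled on a randomized
      # tree.
      perms <- replicate(config$n_null, sample.int(p) - 1L)
      eng <- bnti_engine(D, lapply(pres, function(x) x - 1L), w,
                         cbind(pairs[, 1] - 1L, pairs[, 2] - 1L), perms)
      cbind(eng, ifelse(eng[, 3] > 0, (eng[, 1] - eng[, 2]) / eng[, 3],
                        NA_real_))
    } else {
      out <- matrix(NA_real_, nrow(pairs), 4)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        ia <- pres[[i]]; ib <- pres[[j]]
        obs <- bmntd_pair(D, ia, ib, w[[i]], w[[j]])
        nulls <- numeric(config$n_null)
        pool <- union(ia, ib)
        for (r in seq_len(config$n_null)) {
          pm <- pool[sample.int(length(pool))]
          map <- integer(p); map[pool] <- pm
          nulls[r] <- bmntd_pair(D, map[ia], map[ib], w[[i]], w[[j]])
        }
        mu <- mean(nulls); sdev <- stats::sd(nulls)
        out[k, ] <- c(obs, mu, sdev, if (sdev > 0) (obs - mu) / sdev else NA_real_)
      }
      out
    }
  })
  if (anyNA(res[, 4])) {
    warn(sprintf("%d pair(s) had zero null standard deviation; betaNTI set to NA.",
                 sum(is.na(res[, 4]))))
  }
  out <- tibble::tibble(
    sample_a = rownames(mat)[pairs[, 1]],
    sample_b = rownames(mat)[pairs[, 2]],
    bmntd_obs = res[, 1],
    null_mean = res[, 2],
    null_sd = res[, 3],
    bnti = res[, 4]
  )
  class(out) <- c("pairwise_dist", class(out))
  attr(out, "metric") <- "bnti"
  out
}

# One probabilistic reassembly of a community: draw the observed richness
# of ASVs with probability proportional to occupancy, give each one
# individual, then fill the remaining reads in proportion to mean relative
# abundance of the drawn ASVs.
rc_null_community <- function(n_taxa_pool, richness, reads, occupancy, mean_relabund) {
  # exponential-race draw: equivalent to successive probability-
  # proportional-to-size sampling without replacement, but O(p log p)
  sel <- order(stats::rexp(n_taxa_pool) / occupancy)[seq_len(richness)]
  cnt <- rep(1L, richness)
  extra <- reads - richness
  if (extra > 0) {
    pr <- mean_relabund[sel]
    if (sum(pr) <= 0) pr <- rep(1, richness)
    cnt <- cnt + as.integer(stats::rmultinom(1, extra, pr))
  }
  list(idx = sel, cnt = cnt)
}

bray_pair_sparse <- function(ia, ca, ib, cb) {
  ids <- union(ia, ib)
  a <- numeric(length(ids)); b <- numeric(length(ids))
  a[match(ia, ids)] <- ca
  b[match(ib, ids)] <- cb
  sum(abs(a - b)) / sum(a + b)
}

#' Abundance-adjusted Raup-Crick index (RC-bray) for all sample pairs
#'
#' Each pair is probabilistically reassembled `n_null` times maintaining
#' each sample's observed richness and read total: ASVs enter with
#' probability proportional to their occupancy across the table, and reads
#' are allocated in proportion to mean relative abundance. Bray-Curtis
#' dissimilarity is computed per reassembly and the observed value is
#' located in that null distribution, scaled to \[-1, +1\]: RC-bray =
#' 2 ((number of null values below observed) + 0.5 (ties)) / n_null - 1.
#' Values above +0.95 indicate dispersal limitation, below -0.95
#' homogenizing dispersal.
#'
#' @inheritParams count_matrix
#' @param config A [null_config()].
#' @param occupancy,mean_relabund Optional reference occupancy counts and
#'   mean relative abundances per ASV (in table column order), e.g. from
#'   a wider survey that the analyzed samples belong to, or from the
#'   generating pool in a calibration study. By default both are
#'   estimated from `counts`.
#' @return A pairwise tibble with columns `sample_a`, `sample_b`,
#'   `bray_obs`, `rc_bray`.
#' @export
rc_bray <- function(counts, config = null_config(), occupancy = NULL,
                    mean_relabund = NULL) {
  mat <- count_matrix(counts, require_integer = TRUE)
  if (nrow(mat) < 2) abort("Need at least two samples.")
  n <- nrow(mat); p <- ncol(mat)
  if (is.null(occupancy)) occupancy <- colSums(mat > 0)
  if (is.null(mean_relabund)) mean_relabund <- colMeans(mat / rowSums(mat))
  if (length(occupancy) != p || length(mean_relabund) != p) {
    abort("`occupancy` and `mean_relabund` must have one entry per ASV column.")
  }
  pres <- lapply(seq_len(n), function(i) which(mat[i, ] > 0))
  richness <- lengths(pres)
  reads <- round(rowSums(mat))
  if (any(richness > p)) abort("Sample richness exceeds the taxa pool size.")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- with_seed(config$seed, {
    out <- matrix(NA_real_, nrow(pairs), 2)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      obs <- bray_pair_sparse(pres[[i]], mat[i, pres[[i]]],
                              pres[[j]], mat[j, pres[[j]]])
      nulls <- numeric(config$n_null)
      for (r in seq_len(config$n_null)) {
        ca <- rc_null_community(p, richness[i], reads[i], occupancy, mean_relabund)
        cb <- rc_null_community(p, richness[j], reads[j], occupancy, mean_relabund)
        nulls[r] <- bray_pair_sparse(ca$idx, ca$cnt, cb$idx, cb$cnt)
      }
      n_less <- sum(nulls < obs - 1e-10)
      n_tie <- sum(abs(nulls - obs) <= 1e-10)
      out[k, ] <- c(obs, 2 * (n_less + 0.5 * n_tie) / config$n_null - 1)
    }
    out
  })
  out <- tibble::tibble(
    sample_a = rownames(mat)[pairs[, 1]],
    sample_b = rownames(mat)[pairs[, 2]],
    bray_obs = res[, 1],
    rc_bray = res[, 2]
  )
  class(out) <- c("pairwise_dist", class(out))
  attr(out, "metric") <- "rc_bray"
  out
}

#' Classify the assembly mechanism of a sample pair
#'
#' Applies the hierarchical rule of the null-model framework: betaNTI
#' above +2 is heterogeneous selection and below -2 homogeneous selection;
#' only when the phylogenetic null is not exceeded is RC-bray consulted
#' (above +0.95 dispersal limitation, below -0.95 homogenizing dispersal);
#' drift is inferred when neither null is exceeded.
#'
#' @param bnti,rc_bray Numeric vectors of the two standardized indices.
#' @return A character vector of mechanism labels (`NA` where either
#'   input is undefined).
#' @export
classify_mechanism <- function(bnti, rc_bray) {
  stopifnot(length(bnti) == length(rc_bray))
  out <- rep(NA_character_, length(bnti))
  ok <- !is.na(bnti) & !is.na(rc_bray)
  out[ok & bnti > 2] <- "heterogeneous_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  rest <- ok & abs(bnti) <= 2
  out[rest & rc_bray > 0.95] <- "dispersal_limitation"
  out[rest & rc_bray < -0.95] <- "homogenizing_dispersal"
  out[rest & abs(rc_bray) <= 0.95] <- "drift"
  out
}

mechanism_levels <- c("heterogeneous_selection", "homogeneous_selection",
                      "dispersal_limitation", "homogenizing_dispersal", "drift")

#' Full mechanism table for a count table
#'
#' Convenience wrapper running [bnti()] and [rc_bray()] with the same
#' configuration and classifying every sample pair.
#'
#' @inheritParams bnti
#' @return A tibble with one row per unordered pair: `sample_a`,
#'   `sample_b`, `bnti`, `rc_bray`, `label`.
#' @export
mechanism_table <- function(counts, coph, config = null_config()) {
  b <- bnti(counts, coph, config)
  r <- rc_bray(counts, config)
  out <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(b), "sample_a", "sample_b", "bnti"),
    dplyr::select(tibble::as_tibble(r), "sample_a", "sample_b", "rc_bray"),
    by = c("sample_a", "sample_b")
  )
  out$label <- classify_mechanism(out$bnti, out$rc_bray)
  class(out) <- c("mechanism_tbl", class(out))
  out
}

#' Mechanism fractions, optionally per metadata group
#'
#' Counts the fraction of classified sample pairs per mechanism label.
#' When `group_by` names a metadata column, only pairs whose two samples
#' share the same value are retained and fractions are reported per group
#' (as when partitioning by depth, layer or size fraction). Unclassified
#' pairs are excluded from denominators.
#'
#' @param mech A mechanism tibble from [mechanism_table()].
#' @param meta Optional sample metadata (required with `group_by`).
#' @param group_by Optional metadata column name.
#' @return A tibble with (optional) `group`, `label`, `n_pairs`,
#'   `fraction`; fractions sum to 1 within each group over the five
#'   labels.
#' @export
mechanism_fractions <- function(mech, meta = NULL, group_by = NULL) {
  mech <- dplyr::filter(tibble::as_tibble(mech), !is.na(.data$label))
  if (nrow(mech) == 0) abort("No classified pairs.")
  if (!is.null(group_by)) {
    if (is.null(meta)) abort("`meta` is required when grouping.")
    if (!group_by %in% names(meta)) abort(sprintf("Column '%s' not in metadata.", group_by))
    key <- meta[[group_by]][match(mech$sample_a, meta$sample_id)]
    key_b <- meta[[group_by]][match(mech$sample_b, meta$sample_id)]
    same <- !is.na(key) & !is.na(key_b) & key == key_b
    mech <- mech[same, , drop = FALSE]
    mech$group <- key[same]
    if (nrow(mech) == 0) {
      warn("No within-group pairs; returning empty table.")
      return(tibble::tibble(group = character(), label = character(),
                            n_pairs = integer(), fraction = numeric()))
    }
    out <- mech %>%
      dplyr::count(.data$group, .data$label, name = "n_pairs") %>%
      tidyr::complete(group = unique(mech$group),
                      label = mechanism_levels,
                      fill = list(n_pairs = 0L)) %>%
      dplyr::group_by(.data$group) %>%
      dplyr::mutate(fraction = .data$n_pairs / sum(.data$n_pairs)) %>%
      dplyr::ungroup()
  } else {
    out <- mech %>%
      dplyr::count(.data$label, name = "n_pairs") %>%
      tidyr::complete(label = mechanism_levels, fill = list(n_pairs = 0L)) %>%
      dplyr::mutate(fraction = .data$n_pairs / sum(.data$n_pairs))
  }
  out$label <- factor(out$label, levels = mechanism_levels)
  dplyr::arrange(out, dplyr::across(dplyr::any_of("group")), .data$label)
}

#' Mechanism fractions across temperature-difference bins
#'
#' Bins sample pairs by the absolute temperature difference between their
#' samples and reports the label fractions per bin, the diagnostic used to
#' show how the balance between homogeneous selection and dispersal
#' limitation shifts along an environmental gradient.
#'
#' @inheritParams mechanism_fractions
#' @param meta Sample metadata with a numeric `temperature` column.
#' @param bin_width Bin width in degrees Celsius (default 2).
#' @return A tibble with `bin`, `dT_lower`, `dT_upper`, `label`,
#'   `n_pairs`, `fraction` (`NA` fractions in empty bins).
#' @export
fractions_by_temperature_difference <- function(mech, meta, bin_width = 2) {
  if (!"temperature" %in% names(meta)) abort("Metadata must contain `temperature`.")
  mech <- tibble::as_tibble(mech)
  ta <- meta$temperature[match(mech$sample_a, meta$sample_id)]
  tb <- meta$temperature[match(mech$sample_b, meta$sample_id)]
  miss <- is.na(ta) | is.na(tb)
  if (any(miss)) {
    warn(sprintf("Excluded %d pair(s) with missing temperature.", sum(miss)))
  }
  keep <- !miss & !is.na(mech$label)
  dT <- abs(ta - tb)[keep]
  lab <- mech$label[keep]
  if (length(dT) == 0) abort("No classifiable pairs with temperature data.")
  n_bins <- max(1, ceiling(max(dT) / bin_width + 1e-12))
  bin <- pmin(floor(dT / bin_width) + 1, n_bins)
  grid <- tidyr::expand_grid(bin = seq_len(n_bins), label = mechanism_levels)
  counts <- tibble::tibble(bin = bin, label = lab) %>%
    dplyr::count(.data$bin, .data$label, name = "n_pairs")
  out <- dplyr::left_join(grid, counts, by = c("bin", "label")) %>%
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L)) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::mutate(
      bin_total = sum(.data$n_pairs),
      fraction = dplyr::if_else(.data$bin_total > 0,
                                .data$n_pairs / .data$bin_total, NA_real_)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      dT_lower = (.data$bin - 1) * bin_width,
      dT_upper = .data$bin * bin_width,
      label = factor(.data$label, levels = mechanism_levels)
    ) %>%
    dplyr::select("bin", "dT_lower", "dT_upper", "label", "n_pairs", "fraction")
  class(out) <- c("mechanism_fractions", class(out))
  out
}

#' Reassemble every sample under the Raup-Crick null's assumptions
#'
#' Rebuilds each sample with the same two-stage process used by the
#' [rc_bray()] null model (occupancy-weighted richness draw, then
#' abundance-proportional filling), maintaining each sample's observed
#' richness and read total. The result is a table whose pairs are, by
#' construction, assembled under the null models' own generative
#' assumptions — the reference fixture for calibrating betaNTI and
#' RC-bray.
#'
#' @inheritParams count_matrix
#' @param seed Optional RNG seed.
#' @return A count tibble of the same dimensions.
#' @export
resample_under_null <- function(counts, seed = NULL) {
  mat <- count_matrix(counts, require_integer = TRUE)
  occupancy <- colSums(mat > 0)
  mean_relabund <- colMeans(mat / rowSums(mat))
  p <- ncol(mat)
  with_seed(seed, {
    out <- matrix(0, nrow(mat), p, dimnames = dimnames(mat))
    for (i in seq_len(nrow(mat))) {
      ns <- rc_null_community(p, sum(mat[i, ] > 0), round(sum(mat[i, ])),
                              occupancy, mean_relabund)
      out[i, ns$idx] <- ns$cnt
    }
    count_tibble(out)
  })
}
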