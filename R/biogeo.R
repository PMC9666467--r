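#' Bray-Curtis dissimilarities between all sample pairs
#'
#' With `transform = "total_sum_sqrt"` (default) counts are first
#' normalized by their sample totals and square-root transformed, the
#' standard preprocessing before compositional ordination.
#'
#' @inheritParams count_matrix
#' @param transform `"total_sum_sqrt"` or `"none"`.
#' @return A pairwise tibble with values in \[0, 1\].
#' @export
bray_curtis <- function(counts, transform = c("total_sum_sqrt", "none")) {
  transform <- match.arg(transform)
  mat <- count_matrix(counts)
  totals <- rowSums(mat)
  if (any(totals == 0)) {
    abort(paste0("Zero-sum sample(s): ",
                 paste(rownames(mat)[totals == 0], collapse = ", ")))
  }
  if (transform == "total_sum_sqrt") mat <- sqrt(mat / totals)
  D <- as.matrix(vegan::vegdist(mat, method = "bray"))
  pairwise_tbl(D, metric = paste0("bray_curtis_", transform))
}

#' Great-circle distance in kilometres (Haversine)
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km on a sphere of radius 6371 km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(c(lon1, lon2) < -180 | c(lon1, lon2) > 180)) {
    abort("Coordinates out of range: latitude in [-90, 90], longitude in (-180, 180].")
  }
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371))
}

#' Pairwise geographic distances between samples
#'
#' Uses station coordinates only; depth is ignored.
#'
#' @param meta Sample metadata with `sample_id`, `latitude`, `longitude`.
#' @return A pairwise tibble of distances in km.
#' @export
geo_distance <- function(meta) {
  stopifnot(all(c("sample_id", "latitude", "longitude") %in% names(meta)))
  n <- nrow(meta)
  D <- matrix(0, n, n, dimnames = list(meta$sample_id, meta$sample_id))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    D[i, j] <- D[j, i] <- haversine_km(meta$latitude[i], meta$longitude[i],
                                       meta$latitude[j], meta$longitude[j])
  }
  pairwise_tbl(D, metric = "haversine_km")
}

#' Fit a distance-decay curve by local regression
#'
#' Loess (tricube-weighted local linear) regression of community
#' dissimilarity on geographic distance, evaluated at `grid_size`
#' equidistant points spanning the observed distance range.
#'
#' @param d_comm,d_geo Pairwise tibbles (or square matrices) of community
#'   dissimilarity and geographic distance over the same samples.
#' @param span Loess span (default 0.75).
#' @param grid_size Number of prediction points (default 100).
#' @param degree Local polynomial degree (default 1).
#' @return A `decay_curve` tibble: `distance_km`, `fitted`.
#' @export
distance_decay_curve <- function(d_comm, d_geo, span = 0.75, grid_size = 100,
                                 degree = 1) {
  Dc <- as_square(d_comm); Dg <- as_square(d_geo)
  if (!is.null(rownames(Dc)) && !is.null(rownames(Dg))) {
    common <- intersect(rownames(Dc), rownames(Dg))
    Dc <- Dc[common, common]; Dg <- Dg[common, common]
  }
  iu <- upper.tri(Dc)
  x <- Dg[iu]; y <- Dc[iu]
  if (length(x) < 10) abort("Need at least 10 sample pairs to fit a decay curve.")
  if (diff(range(x)) == 0) abort("All pairs lie at the same geographic distance.")
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = grid_size)
  out <- tibble::tibble(distance_km = grid,
                        fitted = stats::predict(fit, newdata = data.frame(x = grid)))
  attr(out, "span") <- span
  attr(out, "n_pairs") <- length(x)
  class(out) <- c("decay_curve", class(out))
  out
}

# Average silhouette width for a hard partition under a distance matrix.
avg_silhouette <- function(clusters, D) {
  sil <- cluster::silhouette(clusters, dmatrix = as.matrix(D))
  mean(sil[, "sil_width"])
}

#' Cluster a set of curves by shape
#'
#' Hierarchical (Ward) clustering of curves sampled on a common grid,
#' with the number of clusters chosen by the average silhouette width
#' over `k_range`.
#'
#' @param curves A matrix (curves in rows, grid points in columns) or a
#'   long tibble with columns `id`, `distance_km`, `fitted`.
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param method Agglomeration method passed to [stats::hclust()].
#' @return A `curve_clusters` object with `$assignments` (tibble: `id`,
#'   `cluster`, `sil_width`), `$k`, `$silhouettes` (tibble over
#'   `k_range`), `$mean_curves`.
#' @export
curve_clusters <- function(curves, k_range = 2:10, method = "ward.D2") {
  if (is.data.frame(curves)) {
    stopifnot(all(c("id", "distance_km", "fitted") %in% names(curves)))
    wide <- tidyr::pivot_wider(curves, id_cols = "id",
                               names_from = "distance_km", values_from = "fitted")
    m <- as.matrix(wide[-1]); rownames(m) <- wide$id
    grid <- as.numeric(names(wide)[-1])
  } else {
    m <- as.matrix(curves)
    grid <- seq_len(ncol(m))
    if (is.null(rownames(m))) rownames(m) <- paste0("curve", seq_len(nrow(m)))
  }
  if (nrow(m) < 2) abort("Need at least 2 curves to cluster.")
  if (nrow(m) == 2) {
    # silhouette cannot choose k between two curves; report them as two
    # singleton clusters
    grid_d <- stats::dist(m)
    return(structure(list(
      assignments = tibble::tibble(id = rownames(m), cluster = 1:2,
                                   sil_width = c(0, 0)),
      k = 2L,
      silhouettes = tibble::tibble(k = 2L, avg_sil_width = 0),
      mean_curves = tibble::tibble(
        cluster = rep(1:2, each = length(grid)),
        distance_km = rep(grid, 2),
        fitted = as.numeric(t(m))
      ),
      hclust = NULL
    ), class = "curve_clusters"))
  }
  k_range <- k_range[k_range < nrow(m) & k_range >= 2]
  if (length(k_range) == 0) abort("`k_range` leaves no admissible cluster number.")
  D <- stats::dist(m)
  hc <- stats::hclust(D, method = method)
  sils <- vapply(k_range, function(k) avg_silhouette(stats::cutree(hc, k), D),
                 numeric(1))
  k <- k_range[which.max(sils)]
  cl <- stats::cutree(hc, k)
  sil <- cluster::silhouette(cl, dmatrix = as.matrix(D))
  means <- vapply(sort(unique(cl)), function(g) colMeans(m[cl == g, , drop = FALSE]),
                  numeric(ncol(m)))
  structure(list(
    assignments = tibble::tibble(id = rownames(m), cluster = as.integer(cl),
                                 sil_width = sil[, "sil_width"]),
    k = k,
    silhouettes = tibble::tibble(k = k_range, avg_sil_width = sils),
    mean_curves = tibble::tibble(
      cluster = rep(sort(unique(cl)), each = length(grid)),
      distance_km = rep(grid, length(unique(cl))),
      fitted = as.numeric(means)
    ),
    hclust = hc
  ), class = "curve_clusters")
}

#' @export
print.curve_clusters <- function(x, ...) {
  cat("Curve clustering:", nrow(x$assignments), "curves,", x$k,
      "clusters (average silhouette",
      sprintf("%.3f)\n", max(x$silhouettes$avg_sil_width)))
  print(table(x$assignments$cluster))
  invisible(x)
}

# Maximum geographic extent (km) of a run of consecutively occupied
# stations, stations ordered by latitude.
sequential_span_km <- function(occupied, station_meta) {
  ord <- order(station_meta$latitude)
  occ <- occupied[ord]
  lat <- station_meta$latitude[ord]; lon <- station_meta$longitude[ord]
  best <- 0
  i <- 1
  while (i <= length(occ)) {
    if (occ[i]) {
      j <- i
      while (j < length(occ) && occ[j + 1]) j <- j + 1
      best <- max(best, haversine_km(lat[i], lon[i], lat[j], lon[j]))
      i <- j + 1
    } else i <- i + 1
  }
  best
}

#' Cluster per-family UniFrac distance-decay curves
#'
#' Reproduces the family-level phylogenetic distance-decay analysis:
#' families are retained when they hold more than `min_asvs` ASVs and
#' occur over at least `min_span_km` of consecutive stations along the
#' transect; per family, unweighted UniFrac distances are computed between
#' samples of the same size fraction and depth group whose ASV overlap is
#' strictly between 0 and 100%; each family's distances are z-scored,
#' fitted by loess against geographic distance, predicted on a common
#' grid, and the resulting curves are clustered with [curve_clusters()].
#'
#' @inheritParams count_matrix
#' @param taxonomy Tibble mapping `asv_id` to `family`.
#' @param tree Phylogenetic tree covering the ASVs.
#' @param meta Sample metadata (`sample_id`, `latitude`, `longitude`,
#'   `size_fraction`, and `layer` or `depth`).
#' @param min_asvs Families must have strictly more ASVs than this
#'   (default 10).
#' @param min_span_km Minimum sequential occurrence span (default 10000).
#' @param k_range Candidate cluster numbers.
#' @param depth_group Column defining the depth grouping of admissible
#'   pairs (`"layer"` by default, or `"depth"` for exact depths).
#' @param span,grid_size Loess parameters (see [distance_decay_curve()]).
#' @return A `curve_clusters` object (families as curve IDs) with an
#'   extra `$families` tibble describing the filter outcome.
#' @export
family_decay_clusters <- function(counts, taxonomy, tree, meta,
                                  min_asvs = 10, min_span_km = 10000,
                                  k_range = 2:10, depth_group = "layer",
                                  span = 0.75, grid_size = 50) {
  stopifnot(all(c("asv_id", "family") %in% names(taxonomy)))
  if (!depth_group %in% names(meta)) {
    abort(sprintf("Column '%s' not in metadata.", depth_group))
  }
  mat <- count_matrix(counts)
  meta <- meta[match(rownames(mat), meta$sample_id), , drop = FALSE]
  stations <- dplyr::distinct(meta, .data$latitude, .data$longitude)
  fam_of <- taxonomy$family[match(colnames(mat), taxonomy$asv_id)]
  families <- unique(stats::na.omit(fam_of))
  info <- list(); curves <- list()
  for (fam in families) {
    asvs <- colnames(mat)[which(fam_of == fam)]
    n_asv <- length(asvs)
    sub <- mat[, asvs, drop = FALSE]
    present_station <- vapply(seq_len(nrow(stations)), function(s) {
      in_station <- meta$latitude == stations$latitude[s] &
        meta$longitude == stations$longitude[s]
      any(sub[in_station, , drop = FALSE] > 0)
    }, logical(1))
    span_km <- sequential_span_km(present_station, stations)
    keep <- n_asv > min_asvs && span_km >= min_span_km
    info[[fam]] <- tibble::tibble(family = fam, n_asvs = n_asv,
                                  span_km = span_km, retained = keep)
    if (!keep) next
    smp <- rownames(sub)[rowSums(sub) > 0]
    if (length(smp) < 5) { info[[fam]]$retained <- FALSE; next }
    sub2 <- sub[smp, , drop = FALSE]
    uf <- dist_matrix(unweighted_unifrac(count_tibble(sub2),
                                         ape::keep.tip(tree, asvs)))
    msub <- meta[match(smp, meta$sample_id), ]
    pres <- sub2 > 0
    vals <- list()
    for (i in seq_len(length(smp) - 1)) {
      for (j in (i + 1):length(smp)) {
        if (msub$size_fraction[i] != msub$size_fraction[j]) next
        if (msub[[depth_group]][i] != msub[[depth_group]][j]) next
        shared <- sum(pres[i, ] & pres[j, ])
        tot <- sum(pres[i, ] | pres[j, ])
        if (shared == 0 || shared == tot) next   # overlap must be in (0,1)
        vals[[length(vals) + 1]] <- c(
          haversine_km(msub$latitude[i], msub$longitude[i],
                       msub$latitude[j], msub$longitude[j]),
          uf[i, j]
        )
      }
    }
    if (length(vals) < 10) { info[[fam]]$retained <- FALSE; next }
    v <- do.call(rbind, vals)
    if (stats::sd(v[, 2]) == 0) {
      inform(sprintf("Family '%s' dropped: zero UniFrac variance.", fam))
      info[[fam]]$retained <- FALSE
      next
    }
    z <- (v[, 2] - mean(v[, 2])) / stats::sd(v[, 2])
    curves[[fam]] <- tibble::tibble(id = fam, x = v[, 1], y = z)
  }
  if (length(curves) < 2) abort("Fewer than 2 eligible families after filtering.")
  all_x <- unlist(lapply(curves, function(cc) cc$x))
  grid <- seq(min(all_x), max(all_x), length.out = grid_size)
  fitted <- purrr::map_dfr(curves, function(cc) {
    fit <- stats::loess(y ~ x, data = cc, span = span, degree = 1,
                        control = stats::loess.control(surface = "direct"))
    tibble::tibble(id = cc$id[1], distance_km = grid,
                   fitted = stats::predict(fit, newdata = data.frame(x = grid)))
  })
  res <- curve_clusters(fitted, k_range = k_range)
  res$families <- dplyr::bind_rows(info)
  res
}

# All permutations of 1..n (n <= 8), one per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- do.call(rbind, lapply(seq_len(n), function(pos) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE] else sub[, 0, drop = FALSE]
    cbind(left, n, right)
  }))
  storage.mode(out) <- "integer"
  out
}

permanova_one <- function(G, x, n_perm, seed, permutations) {
  n <- nrow(G)
  X <- stats::model.matrix(~x)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  trG <- sum(diag(G))
  df1 <- ncol(X) - 1
  df2 <- n - ncol(X)
  f_stat <- function(Gp) {
    ss_exp <- sum(H * Gp)          # tr(H Gp), H symmetric
    ss_res <- sum(diag(Gp)) - ss_exp
    (ss_exp / df1) / (ss_res / df2)
  }
  ss_exp_obs <- sum(H * G)
  F_obs <- f_stat(G)
  if (permutations == "exact") {
    if (n > 8) abort("Exact enumeration supported only for n <= 8 samples.")
    perms <- all_permutations(n)
    F_perm <- vapply(seq_len(nrow(perms)), function(k) {
      pm <- perms[k, ]; f_stat(G[pm, pm])
    }, numeric(1))
    p <- mean(F_perm >= F_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    F_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      pm <- sample.int(n); f_stat(G[pm, pm])
    }, numeric(1)))
    p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  tibble::tibble(df = df1, ss_explained = ss_exp_obs, ss_total = trG,
                 r_squared = ss_exp_obs / trG, pseudo_f = F_obs,
                 p_value = p, n_perm = n_used)
}

#' Single-variable PERMANOVA with BH correction across variables
#'
#' Partitions the sum of squared dissimilarities explained by each
#' variable on its own (one model per variable, as when screening
#' environmental drivers), with permutation p-values and
#' Benjamini-Hochberg adjustment across the variable set.
#'
#' @param d A pairwise tibble, `dist`, or square distance matrix.
#' @param meta Sample metadata covering all samples of `d`.
#' @param variables Metadata columns to test (each in its own model).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional RNG seed.
#' @param permutations `"random"` (Monte Carlo) or `"exact"` (full
#'   enumeration; only for 8 or fewer samples).
#' @return A `permanova_tbl` tibble: `variable`, `df`, `r_squared`,
#'   `pseudo_f`, `p_value`, `p_adjusted`, `significant` (BH-adjusted p
#'   below 0.05).
#' @export
permanova <- function(d, meta, variables, n_perm = 999, seed = NULL,
                      permutations = c("random", "exact")) {
  permutations <- match.arg(permutations)
  D <- as_square(d)
  ids <- rownames(D)
  if (!is.null(ids)) {
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    if (anyNA(meta$sample_id)) abort("Metadata is missing some samples of `d`.")
  }
  n <- nrow(D)
  A <- -0.5 * D^2
  Cn <- diag(n) - matrix(1 / n, n, n)
  G <- Cn %*% A %*% Cn
  rows <- purrr::map_dfr(variables, function(v) {
    if (!v %in% names(meta)) abort(sprintf("Column '%s' not in metadata.", v))
    x <- meta[[v]]
    if (anyNA(x)) abort(sprintf("Variable '%s' has missing values.", v))
    if (length(unique(x)) < 2) abort(sprintf("Variable '%s' is constant.", v))
    if (is.character(x)) x <- factor(x)
    dplyr::bind_cols(tibble::tibble(variable = v),
                     permanova_one(G, x, n_perm, seed, permutations))
  })
  rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$p_adjusted <= 0.05
  class(rows) <- c("permanova_tbl", class(rows))
  rows
}

#' Analysis of similarities (ANOSIM)
#'
#' Wrapper around [vegan::anosim()] returning a tidy one-row result.
#'
#' @inheritParams permanova
#' @param grouping A factor (or metadata column values) with at least two
#'   groups of two.
#' @return A tibble with `statistic` (ANOSIM R), `p_value`, `n_perm`.
#' @export
anosim_test <- function(d, grouping, n_perm = 999, seed = NULL) {
  D <- as_square(d)
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2) abort("Need at least two groups.")
  if (all(table(grouping) < 2)) abort("All groups are singletons.")
  fit <- with_seed(seed, vegan::anosim(stats::as.dist(D), grouping,
                                       permutations = n_perm))
  tibble::tibble(statistic = unname(fit$statistic),
                 p_value = fit$signif, n_perm = n_perm)
}

#' Z-scored oligotype profiles with hierarchical clustering
#'
#' For a count table restricted to one lineage (e.g., the ASVs of a named
#' clade), z-scores every ASV's abundance profile across samples and
#' clusters the ASVs hierarchically on Bray-Curtis dissimilarities of
#' their relative-abundance profiles, with the cluster number chosen by
#' average silhouette width. Constant-profile ASVs are dropped with a
#' message.
#'
#' @inheritParams count_matrix
#' @param k_range Candidate cluster numbers.
#' @param method Agglomeration method for [stats::hclust()].
#' @return A list with `$zscores` (long tibble: `asv_id`, `sample_id`,
#'   `zscore`), `$assignments` (tibble: `asv_id`, `cluster`,
#'   `sil_width`), `$k`, `$silhouettes`.
#' @export
oligotype_clusters <- function(counts, k_range = 2:10, method = "ward.D2") {
  mat <- count_matrix(counts)
  prof <- t(mat)                          # ASVs x samples
  sds <- apply(prof, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    inform(paste0("Dropped constant-profile ASV(s): ",
                  paste(rownames(prof)[flat], collapse = ", ")))
    prof <- prof[!flat, , drop = FALSE]
  }
  if (nrow(prof) < 2) abort("Need at least 2 ASVs with variable profiles.")
  z <- t(scale(t(prof)))
  relprof <- prof / rowSums(prof)
  D <- vegan::vegdist(relprof, method = "bray")
  hc <- stats::hclust(D, method = method)
  k_range <- k_range[k_range < nrow(prof) & k_range >= 2]
  if (length(k_range) == 0) abort("`k_range` leaves no admissible cluster number.")
  sils <- vapply(k_range, function(k) avg_silhouette(stats::cutree(hc, k), D),
                 numeric(1))
  k <- k_range[which.max(sils)]
  cl <- stats::cutree(hc, k)
  sil <- cluster::silhouette(cl, dmatrix = as.matrix(D))
  list(
    zscores = tibble::tibble(
      asv_id = rep(rownames(z), ncol(z)),
      sample_id = rep(colnames(z), each = nrow(z)),
      zscore = as.numeric(z)
    ),
    assignments = tibble::tibble(asv_id = rownames(prof),
                                 cluster = as.integer(cl),
                                 sil_width = sil[, "sil_width"]),
    k = k,
    silhouettes = tibble::tibble(k = k_range, avg_sil_width = sils)
  )
}
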