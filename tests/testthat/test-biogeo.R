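test_that("Bray-Curtis distances match hand computation and bounds", {
  m <- matrix(c(2, 0, 2,
                1, 1, 0,
                2, 0, 2,
                0, 5, 0), 4, 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), c("A", "B", "C")))
  D <- dist_matrix(bray_curtis(as_ct(m), transform = "none"))
  expect_equal(D["S1", "S2"], 4 / 6)
  expect_equal(D["S1", "S3"], 0)
  expect_equal(D["S1", "S4"], 1)
  expect_true(all(D >= 0 & D <= 1))

  # total-sum + square-root transform equals vegdist on transformed data
  Dt <- dist_matrix(bray_curtis(as_ct(m)))
  ref <- as.matrix(vegan::vegdist(sqrt(m / rowSums(m)), "bray"))
  expect_equal(Dt, ref[rownames(Dt), colnames(Dt)], tolerance = 1e-12)

  m[2, ] <- 0
  expect_error(bray_curtis(as_ct(m)), "S2")
})

test_that("Haversine distances match closed forms on the 6371 km sphere", {
  expect_equal(haversine_km(12, 40, 12, 40), 0)
  expect_equal(haversine_km(0, 0, 0, 90), pi * 6371 / 2, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 1, 0), 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_error(haversine_km(95, 0, 0, 0), "out of range")

  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         latitude = c(0, 0, 1), longitude = c(0, 90, 0))
  g <- dist_matrix(geo_distance(meta))
  expect_equal(g["a", "b"], pi * 6371 / 2, tolerance = 1e-6)
  expect_equal(g["a", "c"], 2 * pi * 6371 / 360, tolerance = 1e-6)
})

test_that("distance-decay loess reproduces constants, lines and planted peaks", {
  set.seed(80)
  n <- 18
  ids <- paste0("S", 1:n)
  x <- runif(n, 0, 50)
  geo <- outer(x, x, function(a, b) abs(a - b))
  dimnames(geo) <- list(ids, ids)

  cst <- matrix(0.42, n, n, dimnames = list(ids, ids)); diag(cst) <- 0
  # constant dissimilarity everywhere off-diagonal
  dc <- distance_decay_curve(pairwise_tbl(cst), pairwise_tbl(geo), grid_size = 25)
  expect_lt(max(abs(dc$fitted - 0.42)), 1e-9)

  lin <- 0.1 + 0.004 * geo; diag(lin) <- 0
  dl <- distance_decay_curve(pairwise_tbl(lin), pairwise_tbl(geo), grid_size = 25)
  expect_lt(max(abs(dl$fitted - (0.1 + 0.004 * dl$distance_km))), 1e-6)

  bell <- 0.2 + 0.5 * exp(-(geo - 25)^2 / 50); diag(bell) <- 0
  db <- distance_decay_curve(pairwise_tbl(bell), pairwise_tbl(geo),
                             span = 0.4, grid_size = 41)
  step <- diff(db$distance_km[1:2])
  expect_lt(abs(db$distance_km[which.max(db$fitted)] - 25), step + 1e-9)

  # affine equivariance: fit(a*y + b) = a*fit(y) + b
  da <- distance_decay_curve(pairwise_tbl(3 * lin + 1), pairwise_tbl(geo),
                             grid_size = 25)
  expect_equal(da$fitted, 3 * dl$fitted + 1, tolerance = 1e-8)

  one <- matrix(1, 3, 3); diag(one) <- 0; dimnames(one) <- list(ids[1:3], ids[1:3])
  expect_error(distance_decay_curve(pairwise_tbl(one), pairwise_tbl(one * 0)),
               "10 sample pairs")
})

test_that("PERMANOVA agrees with vegan::adonis2 and enumerates exactly", {
  set.seed(81)
  m <- rand_counts(12, 10, seed = 81, lambda = 8)
  meta <- tibble::tibble(sample_id = rownames(m),
                         grp = rep(c("x", "y", "z"), each = 4),
                         temp = rnorm(12))
  d <- bray_curtis(as_ct(m), transform = "none")
  pv <- permanova(d, meta, c("grp", "temp"), n_perm = 199, seed = 1)
  ref_g <- vegan::adonis2(stats::as.dist(dist_matrix(d)) ~ grp,
                          data = as.data.frame(meta), permutations = 99)
  ref_t <- vegan::adonis2(stats::as.dist(dist_matrix(d)) ~ temp,
                          data = as.data.frame(meta), permutations = 99)
  expect_equal(pv$pseudo_f[1], ref_g$F[1], tolerance = 1e-10)
  expect_equal(pv$r_squared[1], ref_g$R2[1], tolerance = 1e-10)
  expect_equal(pv$pseudo_f[2], ref_t$F[1], tolerance = 1e-10)
  expect_true(all(pv$r_squared >= 0 & pv$r_squared <= 1))
  expect_equal(pv$p_adjusted, p.adjust(pv$p_value, "BH"))

  # exact enumeration on two internally identical, far-separated clusters:
  # p equals the fraction of permutations preserving the partition,
  # computed from the direct within-group sum-of-squares oracle
  ids <- paste0("S", 1:8)
  D8 <- matrix(10, 8, 8, dimnames = list(ids, ids))
  D8[1:4, 1:4] <- 0.1; D8[5:8, 5:8] <- 0.1; diag(D8) <- 0
  meta8 <- tibble::tibble(sample_id = ids, grp = rep(c("a", "b"), each = 4))
  pe <- permanova(D8, meta8, "grp", permutations = "exact")
  # oracle: enumerate all assignments of 4 labels among 8 positions
  f_oracle <- function(g) {
    sst <- sum(D8[upper.tri(D8)]^2) / 8
    ssw <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      sub <- D8[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / 6)
  }
  combs <- combn(8, 4)
  f_obs <- f_oracle(meta8$grp)
  n_ge <- 0
  for (k in seq_len(ncol(combs))) {
    g <- rep("b", 8); g[combs[, k]] <- "a"
    if (f_oracle(g) >= f_obs - 1e-12) n_ge <- n_ge + 1
  }
  expect_equal(pe$p_value, n_ge / ncol(combs), tolerance = 1e-12)

  expect_error(permanova(D8, meta8, "missing_col", n_perm = 9), "missing_col")
  meta8$const <- 1
  expect_error(permanova(D8, meta8, "const", n_perm = 9), "constant")
})

test_that("PERMANOVA p-values are invariant to consistent relabeling", {
  m <- rand_counts(10, 8, seed = 82)
  meta <- tibble::tibble(sample_id = rownames(m), grp = rep(c("u", "v"), 5))
  d <- dist_matrix(bray_curtis(as_ct(m), transform = "none"))
  p1 <- permanova(d, meta, "grp", n_perm = 99, seed = 7)
  ord <- sample(10)
  p2 <- permanova(d[ord, ord], meta[ord, ], "grp", n_perm = 99, seed = 7)
  expect_equal(p1$pseudo_f, p2$pseudo_f, tolerance = 1e-12)
  expect_equal(p1$r_squared, p2$r_squared, tolerance = 1e-12)
})

test_that("ANOSIM separates perfect groups and matches hand-computed ranks", {
  ids <- paste0("S", 1:6)
  D <- matrix(5, 6, 6, dimnames = list(ids, ids))
  D[1:3, 1:3] <- 1; D[4:6, 4:6] <- 1; diag(D) <- 0
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(D, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)

  # two groups of two, hand-computed: ranks of {1,4,4,4,4,2} pairwise
  ids4 <- paste0("S", 1:4)
  D4 <- matrix(0, 4, 4, dimnames = list(ids4, ids4))
  D4[1, 2] <- D4[2, 1] <- 1
  D4[3, 4] <- D4[4, 3] <- 2
  D4[1, 3] <- D4[3, 1] <- 3; D4[1, 4] <- D4[4, 1] <- 3
  D4[2, 3] <- D4[3, 2] <- 3; D4[2, 4] <- D4[4, 2] <- 3
  g4 <- c("a", "a", "b", "b")
  # within ranks: 1, 2; between ranks: mean of tied 3s = 4.5
  # R = (4.5 - 1.5) / (6/2) = 1
  res4 <- anosim_test(D4, g4, n_perm = 23, seed = 1)
  expect_equal(res4$statistic, 1)
  expect_error(anosim_test(D4, rep("a", 4)), "two groups")
})

test_that("ANOSIM R is near zero under random grouping", {
  inside <- 0
  for (s in 1:100) {
    set.seed(400 + s)
    m <- matrix(rpois(30 * 12, 5), 30, 12,
                dimnames = list(paste0("S", 1:30), paste0("A", 1:12)))
    D <- as.matrix(vegan::vegdist(m, "bray"))
    g <- sample(rep(c("a", "b"), 15))
    r <- anosim_test(D, g, n_perm = 19, seed = s)$statistic
    inside <- inside + (abs(r) < 0.2)
  }
  expect_gte(inside, 90)   # >= 90% of 100 sims
})

test_that("oligotype z-scoring and planted-block clustering behave", {
  set.seed(83)
  n_st <- 20
  stations <- paste0("S", 1:n_st)
  peak1 <- exp(-((1:n_st) - 4)^2 / 6); peak2 <- exp(-((1:n_st) - 16)^2 / 6)
  m <- rbind(
    t(replicate(5, rpois(n_st, 200 * peak1 + 0.5))),
    t(replicate(5, rpois(n_st, 200 * peak2 + 0.5)))
  )
  rownames(m) <- paste0("ASV", 1:10); colnames(m) <- stations
  counts <- as_ct(t(m))
  res <- oligotype_clusters(counts, k_range = 2:5)
  expect_equal(res$k, 2)
  expect_equal(rand_index(res$assignments$cluster, rep(1:2, each = 5)), 1)
  z <- tidyr::pivot_wider(res$zscores, names_from = "sample_id",
                          values_from = "zscore")
  zm <- as.matrix(z[-1])
  expect_lt(max(abs(rowMeans(zm))), 1e-9)
  expect_lt(max(abs(apply(zm, 1, sd) - 1)), 1e-9)

  flat <- t(m); flat[, 1] <- 7   # constant profile dropped with a message
  expect_message(oligotype_clusters(as_ct(flat), k_range = 2:3), "ASV1")
  one <- t(m)[, 1:2]; one[, 1] <- 3
  expect_error(suppressMessages(oligotype_clusters(as_ct(one))), "at least 2")
})

test_that("curve clustering recovers planted shapes by silhouette", {
  set.seed(84)
  grid <- seq(0, 100, length.out = 30)
  shape1 <- sin(grid / 30); shape2 <- (grid / 100)^2 * 2
  curves <- rbind(
    t(replicate(10, shape1 + rnorm(30, 0, 0.05))),
    t(replicate(10, shape2 + rnorm(30, 0, 0.05)))
  )
  rownames(curves) <- paste0("fam", 1:20)
  cc <- curve_clusters(curves, k_range = 2:8)
  expect_equal(cc$k, 2)
  expect_equal(rand_index(cc$assignments$cluster, rep(1:2, each = 10)), 1)
  expect_named(glance(cc), c("k", "n_curves", "avg_sil_width"))
})

test_that("sequential station span and the family filters are literal set operations", {
  station_meta <- tibble::tibble(latitude = seq(-40, 40, length.out = 9),
                                 longitude = rep(0, 9))
  # occupied run of stations 3..7 spans stations 3 to 7 only
  occ <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  got <- transectr:::sequential_span_km(occ, station_meta)
  expect_equal(got, haversine_km(-20, 0, 20, 0), tolerance = 1e-9)
  # single occupied station spans zero km
  expect_equal(transectr:::sequential_span_km(c(TRUE, rep(FALSE, 8)), station_meta), 0)
})

test_that("family decay clustering filters families and clusters their curves", {
  set.seed(85)
  n_st <- 12
  lats <- seq(-50, 50, length.out = n_st)
  tr <- rand_tree(24, seed = 85)
  fams <- rep(c("F1", "F2"), each = 12)
  taxonomy <- tibble::tibble(asv_id = tr$tip.label, family = fams)
  meta <- tibble::tibble(sample_id = paste0("S", 1:n_st), latitude = lats,
                         longitude = 0, size_fraction = "FL", layer = "epi")
  m <- matrix(rpois(n_st * 24, 0.9), n_st, 24,
              dimnames = list(meta$sample_id, tr$tip.label))
  m[rowSums(m) == 0, 1] <- 1
  res <- family_decay_clusters(as_ct(m), taxonomy, tr, meta,
                               min_asvs = 10, min_span_km = 5000,
                               k_range = 2:3, grid_size = 15)
  expect_true(all(res$families$n_asvs == 12))
  expect_true(all(res$families$retained))
  expect_equal(sort(res$assignments$id), c("F1", "F2"))

  # a family confined to one station fails the span filter
  m2 <- m
  m2[2:n_st, taxonomy$family == "F2"] <- 0
  expect_error(
    family_decay_clusters(as_ct(m2), taxonomy, tr, meta,
                          min_asvs = 10, min_span_km = 5000, k_range = 2:3),
    "eligible families")
})
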