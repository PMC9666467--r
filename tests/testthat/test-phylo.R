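test_that("cophenetic distances equal explicit root-path sums", {
  two <- ape::read.tree(text = "(a:0.1,b:0.2);")
  expect_equal(cophenetic_distances(two)["a", "b"], 0.3)
  for (s in 1:20) {
    tr <- rand_tree(10, seed = s)
    D <- cophenetic_distances(tr)
    expect_true(isSymmetric(D))
    expect_equal(unname(diag(D)), rep(0, 10))
    expect_equal(D, oracle_cophenetic(tr)[rownames(D), colnames(D)],
                 tolerance = 1e-12)
  }
  bad <- rand_tree(4, seed = 1); bad$edge.length[2] <- NA
  expect_error(cophenetic_distances(bad), "branch length")
})

test_that("beta MNTD matches the exhaustive double-loop oracle", {
  for (s in 1:25) {
    tr <- rand_tree(6, seed = 200 + s)
    m <- rand_counts(4, 6, seed = 300 + s)
    D <- cophenetic_distances(tr)
    for (weighted in c(TRUE, FALSE)) {
      got <- dist_matrix(beta_mntd(as_ct(m), D, weighted = weighted))
      for (i in 1:3) for (j in (i + 1):4) {
        expect_equal(got[i, j], oracle_bmntd(m[i, ], m[j, ], D, weighted),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("beta MNTD basic identities hold", {
  tr <- rand_tree(6, seed = 7)
  D <- cophenetic_distances(tr)
  m <- rand_counts(2, 6, seed = 8)
  m[2, ] <- m[1, ]
  expect_equal(dist_matrix(beta_mntd(as_ct(m), D))[1, 2], 0)

  # single-taxon samples reduce to the plain patristic distance
  m2 <- matrix(0, 2, 6, dimnames = dimnames(m))
  m2[1, 1] <- 5; m2[2, 3] <- 2
  expect_equal(dist_matrix(beta_mntd(as_ct(m2), D))[1, 2],
               D[colnames(m2)[1], colnames(m2)[3]])

  # weighted variant is invariant to per-sample count scaling
  m3 <- rand_counts(3, 6, seed = 9)
  m4 <- m3 * c(10, 1, 7)
  expect_equal(beta_mntd(as_ct(m3), D)$value, beta_mntd(as_ct(m4), D)$value)

  skip_if_not_installed("picante")
  got <- dist_matrix(beta_mntd(as_ct(m3), D))
  ref <- as.matrix(picante::comdistnt(m3, D, abundance.weighted = TRUE))
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-12)
})

test_that("unweighted UniFrac matches the per-branch descendant-set oracle", {
  for (s in 1:25) {
    tr <- rand_tree(10, seed = 400 + s)
    m <- rand_counts(4, 10, seed = 500 + s, lambda = 1)
    got <- dist_matrix(unweighted_unifrac(as_ct(m), tr))
    expect_true(all(got >= 0 & got <= 1))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(got[i, j], oracle_unifrac(m[i, ], m[j, ], tr),
                   tolerance = 1e-12)
    }
  }
})

test_that("UniFrac boundary cases: identity and disjoint cherries", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  m <- matrix(0, 2, 4, dimnames = list(c("S1", "S2"), c("a", "b", "c", "d")))
  m[1, c("a", "b")] <- 1; m[2, c("c", "d")] <- 1
  expect_equal(dist_matrix(unweighted_unifrac(as_ct(m), tr))[1, 2], 1)
  m[2, ] <- m[1, ]
  expect_equal(dist_matrix(unweighted_unifrac(as_ct(m), tr))[1, 2], 0)

  skip_if_not_installed("picante")
  tr2 <- rand_tree(8, seed = 11)
  m2 <- rand_counts(4, 8, seed = 12, lambda = 1)
  got <- dist_matrix(unweighted_unifrac(as_ct(m2), tr2))
  ref <- as.matrix(picante::unifrac(m2, tr2))
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-12)
})

test_that("ASV niches are abundance-weighted means of the environment", {
  meta <- tibble::tibble(sample_id = c("S1", "S2"), temperature = c(10, 20))
  # A has equal relative abundance in both samples -> niche is the midpoint
  m <- matrix(c(5, 5, 3, 3), 2, 2, dimnames = list(c("S1", "S2"), c("A", "B")))
  niche <- asv_niche(as_ct(m), meta, variables = "temperature")
  expect_equal(niche$temperature[niche$asv_id == "A"], 15)

  m2 <- matrix(c(4, 0), 1, 2, dimnames = list("S1", c("A", "B")))
  meta2 <- tibble::tibble(sample_id = "S1", temperature = 12)
  n2 <- suppressMessages(asv_niche(as_ct(m2), meta2, variables = "temperature"))
  expect_equal(n2$temperature[n2$asv_id == "A"], 12)
  expect_false("B" %in% n2$asv_id)   # absent everywhere -> excluded

  # random fixtures against the direct weighted mean
  for (s in 1:10) {
    mm <- rand_counts(6, 5, seed = 600 + s)
    env <- tibble::tibble(sample_id = rownames(mm), temperature = rnorm(6, 15, 5))
    got <- asv_niche(as_ct(mm), env, variables = "temperature")
    rel <- mm / rowSums(mm)
    for (k in seq_len(ncol(mm))) {
      expect_equal(got$temperature[got$asv_id == colnames(mm)[k]],
                   sum(rel[, k] * env$temperature) / sum(rel[, k]),
                   tolerance = 1e-12)
    }
    # niche lies within the variable's range over occupied samples
    expect_true(all(got$temperature >= min(env$temperature) &
                    got$temperature <= max(env$temperature)))
  }
})

test_that("binned phylogenetic signal behaves on degenerate and Brownian inputs", {
  tr <- rand_tree(12, seed = 13)
  D <- cophenetic_distances(tr)
  niches <- tibble::tibble(asv_id = tr$tip.label, trait = rep(5, 12))
  ps <- phylo_signal_asv(D, niches, "trait", n_bins = 10)
  expect_equal(ps$mean_abs_diff[ps$n_pairs > 0], rep(0, sum(ps$n_pairs > 0)))
  expect_equal(sum(ps$n_pairs), choose(12, 2))

  two <- tibble::tibble(asv_id = tr$tip.label[1:2], trait = c(1, 4))
  one <- phylo_signal_asv(D[1:2, 1:2], two, "trait", n_bins = 1)
  expect_equal(one$mean_abs_diff, 3)

  expect_error(phylo_signal_asv(D[1:3, 1:3], niches, "trait", n_bins = 100),
               "n_bins")

  # Brownian traits: increasing niche difference over the short-distance bins
  hits <- 0
  for (s in 1:50) {
    tr2 <- transectr::simulate_tree(60, seed = 700 + s)
    D2 <- cophenetic_distances(tr2)
    z <- transectr::simulate_traits(tr2, rate = 10, seed = 800 + s)
    names(z)[2] <- "trait"
    ps2 <- phylo_signal_asv(D2, z, "trait", n_bins = 25)
    first <- ps2[ps2$bin <= 5 & ps2$n_pairs > 0, ]
    rho <- suppressWarnings(cor(first$bin, first$mean_abs_diff, method = "spearman"))
    hits <- hits + (!is.na(rho) && rho > 0)
  }
  expect_gte(hits, 45)  # >= 90% of 50 seeded simulations
})

test_that("Mantel correlogram finds signal planted as a monotone transform", {
  hits <- 0
  for (s in 1:50) {
    set.seed(900 + s)
    n <- 25
    x <- matrix(rnorm(n * 2), n, 2)
    Dp <- as.matrix(dist(x)); rownames(Dp) <- colnames(Dp) <- paste0("S", 1:n)
    Dh <- sqrt(Dp) + 0.05 * as.matrix(dist(rnorm(n)))
    dimnames(Dh) <- dimnames(Dp)
    mc <- mantel_correlogram(Dp, Dh, n_bins = 6, n_perm = 199, seed = s)
    hits <- hits + (mc$mantel_r[1] > 0 && !is.na(mc$p_corrected[1]) &&
                      mc$p_corrected[1] <= 0.05)
  }
  expect_gte(hits, 48)  # >= 95% of 50 runs

  # degenerate one-bin case runs and returns a single class
  Dp <- as.matrix(dist(rnorm(12))); dimnames(Dp) <- list(paste0("S", 1:12), paste0("S", 1:12))
  mc1 <- suppressWarnings(mantel_correlogram(Dp, Dp, n_bins = 1, n_perm = 99, seed = 1))
  expect_equal(nrow(mc1), 1)
  expect_error(mantel_correlogram(Dp, Dp, n_perm = 0), "n_perm")
})
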