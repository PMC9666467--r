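test_that("betaNTI is zero-centred when observed equals the null mean and flags degenerate pairs", {
  tr <- rand_tree(8, seed = 20)
  D <- cophenetic_distances(tr)
  m <- rand_counts(3, 8, seed = 21)

  b <- suppressWarnings(bnti(as_ct(m), D, null_config(n_null = 99, seed = 1)))
  expect_equal(b$bnti, (b$bmntd_obs - b$null_mean) / b$null_sd)

  # a duplicated sample: observed and every null betaMNTD are 0 (shared
  # taxa keep zero distance under a coupled relabeling), so the pair is
  # flagged undefined rather than coerced
  m2 <- rbind(m, S4 = m[1, ])
  rownames(m2) <- paste0("S", 1:4)
  expect_warning(b2 <- bnti(as_ct(m2), D, null_config(n_null = 49, seed = 2)),
                 "zero null standard deviation")
  expect_true(is.na(b2$bnti[b2$sample_a == "S1" & b2$sample_b == "S4"]))

  # symmetric in sample order: reversing rows gives the same pair values
  b3 <- bnti(as_ct(m[3:1, ]), D, null_config(n_null = 99, seed = 1))
  key <- function(x) paste(pmin(x$sample_a, x$sample_b), pmax(x$sample_a, x$sample_b))
  expect_equal(b$bmntd_obs[order(key(b))], b3$bmntd_obs[order(key(b3))])
})

test_that("pairwise pool scope shuffles within the union of the pair", {
  tr <- rand_tree(10, seed = 22)
  D <- cophenetic_distances(tr)
  m <- rand_counts(3, 10, seed = 23, lambda = 1)
  b <- suppressWarnings(
    bnti(as_ct(m), D, null_config(n_null = 99, seed = 3, pool_scope = "pairwise"))
  )
  expect_equal(nrow(b), 3)
  expect_true(all(is.finite(b$bmntd_obs)))
})

test_that("RC-bray hits its documented boundaries and matches enumeration", {
  # all-ones samples with richness equal to the pool: the null is forced to
  # reproduce the observation exactly, ties count half, RC = 0
  m <- matrix(1, 2, 3, dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  r0 <- rc_bray(as_ct(m), null_config(n_null = 25, seed = 1))
  expect_equal(r0$rc_bray, 0)
  expect_equal(r0$bray_obs, 0)

  # the scaling formula itself: all nulls below -> +1; all above -> -1
  rc_scale <- function(n_less, n_tie, n_null) 2 * (n_less + 0.5 * n_tie) / n_null - 1
  expect_equal(rc_scale(199, 0, 199), 1)
  expect_equal(rc_scale(0, 0, 199), -1)
  expect_equal(rc_scale(0, 199, 199), 0)

  # 3-ASV two-sample toy: Monte Carlo RC within 3 SE of exhaustive enumeration
  mm <- matrix(c(4, 1, 0,
                 0, 2, 3), 2, 3, byrow = TRUE,
               dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  occ <- colSums(mm > 0); relab <- colMeans(mm / rowSums(mm))
  reads <- rowSums(mm); rich <- rowSums(mm > 0)
  # enumerate one sample's null communities: ordered richness draws + fills
  enum_sample <- function(richness, reads) {
    taxa <- 1:3
    out <- list()
    sets <- combn(3, richness, simplify = FALSE)
    for (sel in sets) {
      # probability of drawing this unordered set (sum over orders)
      p_set <- 0
      perms <- if (richness == 1) list(sel) else
        lapply(seq_along(sel), function(k) c(sel[k], sel[-k]))
      for (ord in perms) {
        p <- 1; remaining <- occ
        for (t in ord) { p <- p * remaining[t] / sum(remaining); remaining[t] <- 0 }
        p_set <- p_set + p
      }
      extra <- reads - richness
      fills <- as.matrix(expand.grid(rep(list(0:extra), richness)))
      fills <- fills[rowSums(fills) == extra, , drop = FALSE]
      pr <- relab[sel] / sum(relab[sel])
      for (f in seq_len(nrow(fills))) {
        cnt <- 1 + fills[f, ]
        p_fill <- dmultinom(fills[f, ], extra, pr)
        v <- numeric(3); v[sel] <- cnt
        out[[length(out) + 1]] <- list(p = p_set * p_fill, v = v)
      }
    }
    out
  }
  eA <- enum_sample(rich[1], reads[1]); eB <- enum_sample(rich[2], reads[2])
  obs <- oracle_bray(mm[1, ], mm[2, ])
  p_less <- 0; p_tie <- 0
  for (a in eA) for (b in eB) {
    bc <- oracle_bray(a$v, b$v)
    pp <- a$p * b$p
    if (bc < obs - 1e-10) p_less <- p_less + pp
    else if (abs(bc - obs) <= 1e-10) p_tie <- p_tie + pp
  }
  rc_exact <- 2 * (p_less + 0.5 * p_tie) - 1
  n_null <- 4000
  rc_mc <- rc_bray(as_ct(mm), null_config(n_null = n_null, seed = 5))$rc_bray
  se <- 2 * sqrt(max(p_less + 0.5 * p_tie, 1e-6) *
                   (1 - min(p_less + 0.5 * p_tie, 1 - 1e-6)) / n_null)
  expect_lt(abs(rc_mc - rc_exact), 3 * se + 1e-9)
})

test_that("mechanism classification follows the hierarchical threshold rule", {
  expect_equal(classify_mechanism(2.3, 0), "heterogeneous_selection")
  expect_equal(classify_mechanism(-2.3, 0), "homogeneous_selection")
  expect_equal(classify_mechanism(-0.5, 0.97), "dispersal_limitation")
  expect_equal(classify_mechanism(-0.5, -0.97), "homogenizing_dispersal")
  expect_equal(classify_mechanism(-0.5, 0.20), "drift")
  # selection takes precedence over the compositional null
  expect_equal(classify_mechanism(2.5, 0.99), "heterogeneous_selection")
  expect_equal(classify_mechanism(c(0, NA), c(NA, 0.2)), c(NA_character_, NA_character_))
  # boundary values are not significant (strict inequalities)
  expect_equal(classify_mechanism(2, 0.95), "drift")
})

test_that("mechanism fractions count labels per group and sum to one", {
  mech <- tibble::tibble(
    sample_a = c("A", "A", "B", "C"), sample_b = c("B", "C", "C", "D"),
    bnti = 0, rc_bray = 0,
    label = c("homogeneous_selection", "homogeneous_selection",
              "dispersal_limitation", "drift")
  )
  fr <- mechanism_fractions(mech)
  expect_equal(fr$fraction[fr$label == "homogeneous_selection"], 0.5)
  expect_equal(fr$fraction[fr$label == "dispersal_limitation"], 0.25)
  expect_equal(fr$fraction[fr$label == "drift"], 0.25)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)

  mech$label <- "drift"
  expect_equal(mechanism_fractions(mech)$fraction[5], 1)

  meta <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                         layer = c("epi", "epi", "meso", "meso"))
  fg <- mechanism_fractions(mech, meta, group_by = "layer")
  # only within-layer pairs retained: A-B (epi), C-D (meso)
  expect_equal(sort(unique(fg$group)), c("epi", "meso"))
  sums <- tapply(fg$fraction, fg$group, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
})

test_that("temperature-difference partition reproduces planted label structure", {
  ids <- paste0("S", 1:6)
  temps <- c(0, 0, 4, 4, 9, 9)
  meta <- tibble::tibble(sample_id = ids, temperature = temps)
  pairs <- t(combn(6, 2))
  dT <- abs(temps[pairs[, 1]] - temps[pairs[, 2]])
  lab <- ifelse(dT < 2, "homogeneous_selection",
                ifelse(dT < 6, "drift", "dispersal_limitation"))
  mech <- tibble::tibble(sample_a = ids[pairs[, 1]], sample_b = ids[pairs[, 2]],
                         bnti = 0, rc_bray = 0, label = lab)
  ft <- fractions_by_temperature_difference(mech, meta, bin_width = 2)
  f <- function(bin, label) ft$fraction[ft$bin == bin & ft$label == label]
  expect_equal(f(1, "homogeneous_selection"), 1)
  expect_equal(f(3, "drift"), 1)           # dT = 4 and 5 pairs land in bin [4,6)
  expect_equal(f(5, "dispersal_limitation"), 1)
  # empty bins report zero pairs and undefined fractions
  empty <- ft[ft$bin == 2, ]
  expect_true(all(is.na(empty$fraction)) || all(empty$n_pairs == 0))

  # all pairs at dT = 0 collapse to a single bin with fractions summing to 1
  meta0 <- tibble::tibble(sample_id = ids, temperature = 5)
  f0 <- fractions_by_temperature_difference(mech, meta0, bin_width = 2)
  expect_equal(max(f0$bin), 1)
  expect_equal(sum(f0$fraction), 1, tolerance = 1e-12)
})
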