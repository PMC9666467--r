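# Independent brute-force oracles used to verify the package's numerical
# routines on small fixtures. These deliberately take the slow, explicit
# path (double loops, explicit path enumeration) so that they share no
# code with the implementations they check.

rand_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

rand_counts <- function(n_samples, n_taxa, seed, lambda = 3,
                        taxa = paste0("t", seq_len(n_taxa))) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(paste0("S", seq_len(n_samples)), taxa))
  # guarantee no empty sample
  for (i in seq_len(n_samples)) if (sum(m[i, ]) == 0) m[i, sample(n_taxa, 1)] <- 1
  m
}

as_ct <- function(m) {
  tibble::as_tibble(cbind(tibble::tibble(sample_id = rownames(m)),
                          tibble::as_tibble(m)))
}

# Patristic distance by explicit root-path intersection.
oracle_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1
  parent <- integer(max(tree$edge)); elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    p <- c()
    while (node != root) { p <- c(p, node); node <- parent[node] }
    p
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi <- path_to_root(i); pj <- path_to_root(j)
    shared <- intersect(pi, pj)
    D[i, j] <- D[j, i] <- sum(elen[setdiff(pi, shared)]) + sum(elen[setdiff(pj, shared)])
  }
  D
}

# Exhaustive nearest-taxon scan.
oracle_bmntd <- function(xa, xb, D, weighted = TRUE) {
  ia <- which(xa > 0); ib <- which(xb > 0)
  wa <- if (weighted) xa[ia] / sum(xa[ia]) else rep(1 / length(ia), length(ia))
  wb <- if (weighted) xb[ib] / sum(xb[ib]) else rep(1 / length(ib), length(ib))
  sa <- 0
  for (k in seq_along(ia)) {
    best <- Inf
    for (l in seq_along(ib)) best <- min(best, D[ia[k], ib[l]])
    sa <- sa + wa[k] * best
  }
  sb <- 0
  for (l in seq_along(ib)) {
    best <- Inf
    for (k in seq_along(ia)) best <- min(best, D[ib[l], ia[k]])
    sb <- sb + wb[l] * best
  }
  unname(0.5 * (sa + sb))
}

# Per-branch descendant-set accounting on the pruned pair subtree.
oracle_unifrac <- function(xa, xb, tree) {
  present <- tree$tip.label[xa > 0 | xb > 0]
  sub <- ape::keep.tip(tree, present)
  a_tips <- tree$tip.label[xa > 0]; b_tips <- tree$tip.label[xb > 0]
  n <- length(sub$tip.label)
  tips_below <- function(node) {
    if (node <= n) return(sub$tip.label[node])
    kids <- sub$edge[sub$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  unique_len <- 0; total_len <- 0
  for (e in seq_len(nrow(sub$edge))) {
    tips <- tips_below(sub$edge[e, 2])
    in_a <- any(tips %in% a_tips); in_b <- any(tips %in% b_tips)
    if (!in_a && !in_b) next
    total_len <- total_len + sub$edge.length[e]
    if (xor(in_a, in_b)) unique_len <- unique_len + sub$edge.length[e]
  }
  if (total_len == 0) 0 else unique_len / total_len
}

oracle_bray <- function(a, b) sum(abs(a - b)) / sum(a + b)

# Direct per-pair profile computation.
oracle_interaction_dissim <- function(m, S, weighted = TRUE) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  profiles <- matrix(0, n, ncol(m))
  for (i in seq_len(n)) {
    w <- if (weighted) m[i, ] / sum(m[i, ]) else (m[i, ] > 0) / sum(m[i, ] > 0)
    for (k in seq_len(ncol(m))) profiles[i, k] <- sum(w * S[, k])
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cs <- sum(profiles[i, ] * profiles[j, ]) /
      (sqrt(sum(profiles[i, ]^2)) * sqrt(sum(profiles[j, ]^2)))
    out[i, j] <- out[j, i] <- 1 - cs
  }
  out
}

# Literal three-clause evaluation, one ASV at a time.
oracle_filter_keep <- function(m, rule) {
  n_samples <- nrow(m)
  keep <- logical(ncol(m))
  for (k in seq_len(ncol(m))) {
    global <- sum(m[, k]) / sum(m) > rule$global_min_fraction
    n1 <- 0; n2 <- 0; n3 <- 0
    for (i in seq_len(n_samples)) {
      rel <- m[i, k] / sum(m[i, ])
      if (rel > rule$clause1_min_rel_abund) n1 <- n1 + 1
      if (rel > rule$clause2_min_rel_abund) n2 <- n2 + 1
      if (m[i, k] > 0) n3 <- n3 + 1
    }
    c1 <- n1 >= rule$clause1_min_samples
    c2 <- n2 >= ceiling(rule$clause2_min_sample_fraction * n_samples)
    c3 <- n3 >= ceiling(rule$clause3_min_sample_fraction * n_samples)
    keep[k] <- global && (c1 || c2 || c3)
  }
  keep
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  agree <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / tot
}
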