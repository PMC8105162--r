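# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's internal code paths.

# exact k nearest neighbours by full distance matrix
brute_knn <- function(query, ref, k) {
  d <- as.matrix(stats::dist(rbind(query, ref)))
  nq <- nrow(query)
  d <- d[seq_len(nq), nq + seq_len(nrow(ref)), drop = FALSE]
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

# union-of-spheres membership along a visited seed path
sphere_union_members <- function(coords, path, r1) {
  hit <- rep(FALSE, nrow(coords))
  for (i in seq_len(nrow(path))) {
    d <- sqrt(rowSums((coords - rep(path[i, ], each = nrow(coords)))^2))
    hit <- hit | d <= r1
  }
  which(hit)
}

# closed-form 2x2 entropic plan for two points one cost-unit apart:
# by symmetry the scalings are equal, so m_off = c^2 e^-eps, m_diag = c^2
# with c^2 (1 + e^-eps) = 1/2.
closed_form_2pt <- function(eps) {
  c2 <- 0.5 / (1 + exp(-eps))
  matrix(c(c2, c2 * exp(-eps), c2 * exp(-eps), c2), 2, 2)
}

# exhaustive MRF minimum over all labelings of <= ~8 free points
exhaustive_mrf_min <- function(problem) {
  ids <- problem$instance_ids
  nf <- problem$n_free
  grid <- do.call(expand.grid, rep(list(seq_along(ids)), nf))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    e <- mrf_energy(problem, ids[as.integer(grid[r, ])])
    if (e < best) best <- e
  }
  best
}

# hand replay of the top-down assignment recomputing argmin from the full
# distance matrix at every step (dist_fun(p, q) vectorised over q)
replay_top_down <- function(coords, inst_members, unseg, dist_mat) {
  z <- coords[, 3]
  ord <- unseg[order(-z[unseg], unseg)]
  labels <- integer(nrow(coords))
  for (i in seq_along(inst_members)) labels[inst_members[[i]]] <- i
  for (p in ord) {
    d_best <- Inf; i_best <- NA_integer_
    for (i in seq_along(inst_members)) {
      di <- min(dist_mat[p, inst_members[[i]]])
      if (di < d_best) { d_best <- di; i_best <- i }
    }
    inst_members[[i_best]] <- c(inst_members[[i_best]], p)
    labels[p] <- i_best
  }
  labels
}

# a tiny two-organ test shoot: vertical stem plus two separated leaf blobs
toy_shoot <- function() {
  stem <- cbind(0, 0, seq(0, 100, length.out = 21))
  leaf_a <- cbind(seq(5, 60, length.out = 15), 0,
                  90 - 0.4 * seq(5, 60, length.out = 15))
  leaf_b <- cbind(-seq(5, 60, length.out = 15), 0,
                  50 - 0.4 * seq(5, 60, length.out = 15))
  coords <- rbind(stem, leaf_a, leaf_b)
  labels <- c(rep(1L, 21), rep(2L, 15), rep(3L, 15))
  list(cloud = labeled_cloud(coords, labels),
       stem = seq_len(21),
       leaf_a = 21 + seq_len(15),
       leaf_b = 36 + seq_len(15))
}
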