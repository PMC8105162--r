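# Internal exact nearest-neighbour helpers.
#
# Clouds in this package stay small (the pipeline recommends < 15,000 points
# after simplification), so exact chunked brute force via the
# |q|^2 + |r|^2 - 2 q.r expansion is both simple and fast enough; no spatial
# index dependency is available in the target environment.

# k nearest neighbours of each row of `query` among rows of `ref`.
# Returns list(idx, dist): n_query x k matrices. Ties broken by lower ref index
# (stable order()). When query and ref are the same matrix the point itself is
# its own first neighbour.
.knn <- function(query, ref, k, chunk = 2048L) {
  query <- rbind(query)
  ref <- rbind(ref)
  nq <- nrow(query)
  nr <- nrow(ref)
  k <- min(as.integer(k), nr)
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  rn2 <- rowSums(ref^2)
  for (start in seq(1L, nq, by = chunk)) {
    rows <- start:min(start + chunk - 1L, nq)
    qb <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(qb^2), rn2, "+") - 2 * tcrossprod(qb, ref)
    d2[d2 < 0] <- 0
    for (j in seq_along(rows)) {
      o <- order(d2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(d2[j, o])
    }
  }
  list(idx = idx, dist = dst)
}

# Indices (into ref) of all neighbours within `radius` of each query row,
# excluding exact self-matches when self_index is supplied.
.radius_neighbors <- function(query, ref, radius, chunk = 2048L) {
  query <- rbind(query)
  ref <- rbind(ref)
  nq <- nrow(query)
  rn2 <- rowSums(ref^2)
  r2 <- radius^2 + 1e-12
  out <- vector("list", nq)
  for (start in seq(1L, nq, by = chunk)) {
    rows <- start:min(start + chunk - 1L, nq)
    qb <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(qb^2), rn2, "+") - 2 * tcrossprod(qb, ref)
    for (j in seq_along(rows)) out[[rows[j]]] <- which(d2[j, ] <= r2)
  }
  out
}

# Minimum Euclidean distance from each query row to the point set `ref`.
.min_dist <- function(query, ref) {
  .knn(query, ref, k = 1L)$dist[, 1L]
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}

.row_unit <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}
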