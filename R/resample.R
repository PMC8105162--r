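#' Voxel-grid simplification
#'
#' Overlays an axis-aligned voxel grid with its origin at the cloud's minimum
#' corner and keeps one representative per occupied voxel: the member point
#' nearest the voxel's point centroid (ties to the lower index). Because the
#' representative is an original point, its label and any attributes stay
#' meaningful. A dense-to-representative mapping is retained so labels can be
#' transferred back.
#'
#' @param cloud a [labeled_cloud()].
#' @param voxel_mm voxel edge length in mm, positive.
#' @return list with `cloud` (the simplified [labeled_cloud()]), `index`
#'   (dense indices of the representatives, parallel to the sparse cloud) and
#'   `mapping` (for every dense point, the dense index of its voxel's
#'   representative).
#' @export
voxel_downsample <- function(cloud, voxel_mm) {
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) stop("voxel_mm must be positive")
  p <- cloud$coords
  lo <- apply(p, 2, min)
  v <- pmax(floor(sweep(p, 2, lo) / voxel_mm), 0)
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "/")
  groups <- split(seq_len(nrow(p)), key)
  reps <- vapply(groups, function(g) {
    if (length(g) == 1L) return(g)
    ctr <- colMeans(p[g, , drop = FALSE])
    d2 <- rowSums((p[g, , drop = FALSE] - rep(ctr, each = length(g)))^2)
    g[which.min(d2)]
  }, integer(1))
  reps <- sort(unname(reps))
  mapping <- integer(nrow(p))
  for (g in groups) {
    r <- intersect(g, reps)[1L]
    mapping[g] <- r
  }
  sparse <- labeled_cloud(p[reps, , drop = FALSE], cloud$labels[reps],
                          normals = if (is.null(cloud$normals)) NULL else
                            cloud$normals[reps, , drop = FALSE],
                          source_path = cloud$source_path)
  list(cloud = sparse, index = reps, mapping = mapping)
}

#' Pick a voxel size landing at or below a target point count
#'
#' Bisection on the voxel edge length; the segmentation pipeline recommends
#' fewer than 15,000 points per shoot, so the default cap is 13,000.
#'
#' @param cloud a [labeled_cloud()].
#' @param target_points maximum simplified size.
#' @param iters bisection iterations.
#' @return voxel edge length in mm.
#' @export
choose_voxel_size <- function(cloud, target_points = 13000L, iters = 40L) {
  if (n_points(cloud) <= target_points) return(0)
  p <- cloud$coords
  lo <- 1e-6
  hi <- sqrt(sum((apply(p, 2, max) - apply(p, 2, min))^2))
  count_at <- function(v) length(unique(paste(
    floor((p[, 1] - min(p[, 1])) / v),
    floor((p[, 2] - min(p[, 2])) / v),
    floor((p[, 3] - min(p[, 3])) / v), sep = "/")))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (count_at(mid) > target_points) lo <- mid else hi <- mid
  }
  hi
}

#' Transfer labels from a segmented sparse cloud to its dense original
#'
#' For every dense point the `k` nearest sparse points vote with their
#' labels; the majority label wins. Ties go to the label of the single
#' nearest neighbour when it is among the tied labels, then to the smaller
#' label id. The sparse cloud must be fully labeled.
#'
#' @param sparse a fully labeled [labeled_cloud()].
#' @param dense the [labeled_cloud()] to label.
#' @param k number of voting neighbours, default 5.
#' @return `dense` with transferred labels.
#' @export
transfer_labels <- function(sparse, dense, k = 5L) {
  if (any(sparse$labels == -1L)) {
    stop("sparse cloud has unlabeled points; segment it fully first")
  }
  k <- max(1L, as.integer(k))
  nn <- .knn(dense$coords, sparse$coords, k = k)
  lab_mat <- matrix(sparse$labels[nn$idx], nrow = nrow(nn$idx))
  out <- integer(nrow(lab_mat))
  for (i in seq_len(nrow(lab_mat))) {
    labs <- lab_mat[i, ]
    cnt <- table(labs)
    top <- as.integer(names(cnt)[cnt == max(cnt)])
    out[i] <- if (length(top) == 1L) top
              else if (labs[1L] %in% top) labs[1L]  # nearest-neighbour tiebreak
              else min(top)
  }
  dense$labels <- out
  dense
}
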