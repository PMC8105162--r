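#' Stem-growing parameters
#'
#' Bundles the two user-supplied stem endpoints with the region-growing and
#' median-trimming controls. The growth direction at each step mixes the
#' direction toward the top endpoint (weight `beta`) with the median direction
#' from the already-grown stem points to the current seed (weight `alpha`);
#' `alpha = 0.2`, `beta = 0.8` keeps the growth locked onto the stem across a
#' range of radii.
#'
#' @param s0 bottom stem endpoint (3-vector, mm).
#' @param sn top stem endpoint (3-vector, mm).
#' @param r1 growth-sphere radius (mm), positive.
#' @param alpha weight of the median direction, default 0.2.
#' @param beta weight of the endpoint direction, default 0.8.
#' @param n_median_segments number of equal-length bins `M` used by
#'   [median_trim()], default 10.
#' @param n_median_ops how many times the median trim is applied by the
#'   pipeline (0 = skip), default 1.
#' @return an object of class `stem_params`.
#' @export
stem_params <- function(s0, sn, r1, alpha = 0.2, beta = 0.8,
                        n_median_segments = 10L, n_median_ops = 1L) {
  s0 <- as.numeric(s0); sn <- as.numeric(sn)
  if (length(s0) != 3L || length(sn) != 3L) stop("s0 and sn must be 3-vectors")
  if (all(s0 == sn)) stop("s0 and sn must differ")
  if (!is.numeric(r1) || r1 <= 0) stop("r1 must be positive")
  if (n_median_segments < 1L) stop("n_median_segments must be >= 1")
  if (n_median_ops < 0L) stop("n_median_ops must be >= 0")
  structure(
    list(s0 = s0, sn = sn, r1 = as.numeric(r1),
         alpha = as.numeric(alpha), beta = as.numeric(beta),
         n_median_segments = as.integer(n_median_segments),
         n_median_ops = as.integer(n_median_ops)),
    class = "stem_params"
  )
}

#' Median-directed stem region growing
#'
#' Grows the stem from the bottom endpoint `s0` toward the top endpoint `sn`.
#' At iteration `k` with seed `s_k`: (1) every eligible point within `r1` of
#' `s_k` is classified as stem; (2) the growth direction is
#' `v_k = (alpha v1 + beta v) / ||alpha v1 + beta v||`, where `v` points from
#' `s_k` to `sn` and `v1` is the renormalised componentwise median of the
#' unit vectors `(p_A - s_k) / ||p_A - s_k||` from `s_k` toward the
#' already-grown stem points (on the first iteration, with nothing grown yet,
#' `v_k = v`). The `v1` term is what keeps the growth centred: whenever the
#' seed strays off the stem axis, the median direction toward the grown
#' points pulls it back. (3) the seed advances to
#' `s_{k+1} = s_k + r1 v_k`; (4) growth stops when the orthogonal projection
#' of `s_{k+1}` onto the segment from `s0` to `sn` leaves that segment.
#'
#' @param cloud a [labeled_cloud()].
#' @param params a [stem_params()].
#' @param exclude indices never to classify (points already owned by other
#'   instances).
#' @return sorted integer vector of stem point indices.
#' @export
grow_stem <- function(cloud, params, exclude = integer(0)) {
  stopifnot(inherits(params, "stem_params"))
  pts <- cloud$coords
  eligible <- setdiff(seq_len(nrow(pts)), as.integer(exclude))
  if (!length(eligible)) stop("no eligible points to grow from")
  ep <- pts[eligible, , drop = FALSE]

  s0 <- params$s0; sn <- params$sn; r1 <- params$r1
  axis <- sn - s0
  len <- sqrt(sum(axis^2))
  u <- axis / len
  s <- s0
  grown <- integer(0)
  max_iter <- ceiling(len / r1) * 10L + 20L  # hard safety stop

  for (k in seq_len(max_iter)) {
    d <- sqrt(rowSums((ep - rep(s, each = nrow(ep)))^2))
    hit <- eligible[d <= r1]
    if (k == 1L && !length(hit)) {
      stop("empty growth: no point within r1 of the bottom seed s0")
    }
    grown <- union(grown, hit)

    to_top <- sn - s
    nt <- sqrt(sum(to_top^2))
    if (nt == 0) break
    v <- to_top / nt
    if (length(grown)) {
      unit_to_grown <- .row_unit(sweep(pts[grown, , drop = FALSE], 2, s))
      v1 <- apply(unit_to_grown, 2, median)
      nv1 <- sqrt(sum(v1^2))
      v1 <- if (nv1 > 0) v1 / nv1 else c(0, 0, 0)
    } else {
      v1 <- c(0, 0, 0)
    }
    w <- params$alpha * v1 + params$beta * v
    nw <- sqrt(sum(w^2))
    vk <- if (nw < 1e-12) {
      message("degenerate growth direction; falling back to endpoint direction")
      v
    } else w / nw

    s <- s + r1 * vk
    t <- sum((s - s0) * u)
    if (t < 0 || t > len) break
  }
  sort(grown)
}

#' Median-axis trimming of a grown stem set
#'
#' Removes over-segmented points (leaf bases, bulges at stem bends) from a
#' grown stem set. The stem points are binned into `M` equal-length intervals
#' along the `s0 -> sn` direction (half-open bins, last bin closed); per bin a
#' central axis is fitted by total least squares (first principal direction
#' through the bin centroid) and only points strictly closer to that axis than
#' the bin's mean point-to-axis distance are retained. Removed points return
#' to the unsegmented set and are re-captured by the later organ assignment.
#' Bins with fewer than 2 points are kept untouched.
#'
#' @param cloud a [labeled_cloud()].
#' @param stem_set integer indices of the current stem points.
#' @param params a [stem_params()] (`n_median_segments` is the bin count `M`).
#' @param times how many times to apply the filter (default
#'   `params$n_median_ops`); 0 returns `stem_set` unchanged.
#' @return sorted integer vector of retained stem indices.
#' @export
median_trim <- function(cloud, stem_set, params,
                        times = params$n_median_ops) {
  stopifnot(inherits(params, "stem_params"))
  stem_set <- sort(as.integer(stem_set))
  if (!length(stem_set)) stop("stem_set must be nonempty")
  times <- as.integer(times)
  if (times <= 0L) return(stem_set)
  u <- .unit(params$sn - params$s0)
  M <- params$n_median_segments
  for (rep_i in seq_len(times)) {
    if (length(stem_set) < 2L) break
    pts <- cloud$coords[stem_set, , drop = FALSE]
    t <- as.vector(pts %*% u)
    rng <- range(t)
    width <- (rng[2] - rng[1]) / M
    bin <- if (width == 0) rep(1L, length(t)) else {
      pmin(floor((t - rng[1]) / width) + 1L, M)  # last bin closed
    }
    keep <- logical(length(stem_set))
    for (b in unique(bin)) {
      in_b <- which(bin == b)
      if (length(in_b) < 2L) {
        keep[in_b] <- TRUE  # too few points to fit an axis; retain
        next
      }
      p <- pts[in_b, , drop = FALSE]
      ctr <- colMeans(p)
      pc <- sweep(p, 2, ctr)
      ax <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)$vectors[, 1L]
      proj <- as.vector(pc %*% ax)
      d <- sqrt(pmax(rowSums(pc^2) - proj^2, 0))
      keep[in_b] <- d < mean(d)
    }
    stem_set <- stem_set[keep]
    if (!length(stem_set)) break
  }
  sort(stem_set)
}
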