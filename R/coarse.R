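#' Classify pot points by height
#'
#' After shoot alignment, every unassigned point strictly lower than the
#' lowest stem point is classified as pot. A point exactly at the stem minimum
#' is not a pot point.
#'
#' @param cloud an aligned [labeled_cloud()] (z is height).
#' @param stem_set integer indices of stem points (nonempty).
#' @param candidates indices eligible for classification; defaults to all
#'   points outside `stem_set`.
#' @return sorted integer vector of pot indices (possibly empty).
#' @export
detect_pot <- function(cloud, stem_set, candidates = NULL) {
  stem_set <- as.integer(stem_set)
  if (!length(stem_set)) stop("stem_set must be nonempty")
  if (is.null(candidates)) candidates <- setdiff(seq_len(n_points(cloud)), stem_set)
  z <- cloud$coords[, 3]
  zmin <- min(z[stem_set])
  sort(candidates[z[candidates] < zmin])
}

#' Single-linkage organ clusters
#'
#' Connected components of the radius graph over the candidate points,
#' with radius `2 x` the median nearest-neighbour spacing. Used only to report
#' how many spatially discrete point groups remain after stem removal; it does
#' not restrict the organ assignment (connected groups can hold several
#' organs).
#'
#' @param cloud a [labeled_cloud()].
#' @param candidates indices to cluster.
#' @param radius optional connectivity radius (mm); default
#'   `2 * median NN spacing`.
#' @return integer cluster membership vector parallel to `candidates`.
#' @export
cluster_organs <- function(cloud, candidates, radius = NULL) {
  candidates <- as.integer(candidates)
  p <- cloud$coords[candidates, , drop = FALSE]
  n <- nrow(p)
  if (n < 2L) return(rep(1L, n))
  if (is.null(radius)) {
    nn <- .knn(p, p, k = 2L)$dist[, 2L]
    radius <- 2 * median(nn)
  }
  nbrs <- .radius_neighbors(p, p, radius)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- nbrs[[i]]; j <- j[j > i]
    if (length(j)) cbind(i, j) else NULL
  }))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  as.integer(igraph::components(g)$membership)
}

#' Detect organ seed points as suppressed height maxima
#'
#' The highest point of each organ serves as its seed. Candidate seeds are
#' the z-local maxima of the non-stem, non-pot points at the organ-separation
#' scale: a point qualifies only when no point within `min_sep` of it is
#' higher (exact height ties go to the lower point index). This directly
#' encodes the working assumption that the highest points of any two organs
#' are more than 5 cm apart -- a point overtopped within 5 cm cannot be an
#' organ's highest point. Greedy non-maximum suppression then walks the
#' candidates in descending z and keeps a candidate only if it lies more than
#' `min_sep` from every already-kept seed. Instance ids are assigned in
#' descending-z order starting at 2.
#'
#' @param cloud an aligned [labeled_cloud()].
#' @param exclude indices to ignore (stem and pot points).
#' @param min_sep minimum tip separation in mm (default 50, the 5 cm rule).
#' @return a `seed_set`: data.frame with columns `point` (cloud index), `id`,
#'   `role`, `z`, ordered by descending z, with attributes
#'   `min_tip_separation` and `n_clusters`.
#' @export
detect_organ_seeds <- function(cloud, exclude = integer(0), min_sep = 50) {
  stopifnot(min_sep > 0)
  candidates <- setdiff(seq_len(n_points(cloud)), as.integer(exclude))
  if (!length(candidates)) {
    warning("no candidate points for seed detection")
    return(.seed_set(integer(0), integer(0), character(0), numeric(0),
                     min_sep, 0L))
  }
  p <- cloud$coords[candidates, , drop = FALSE]
  z <- p[, 3]
  nbrs <- .radius_neighbors(p, p, min_sep)
  is_max <- vapply(seq_along(candidates), function(i) {
    j <- setdiff(nbrs[[i]], i)
    !any(z[j] > z[i] | (z[j] == z[i] & j < i))
  }, logical(1))
  cand <- which(is_max)
  cand <- cand[order(-z[cand], candidates[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) ||
        all(sqrt(rowSums((p[kept, , drop = FALSE] -
                            rep(p[i, ], each = length(kept)))^2)) > min_sep)) {
      kept <- c(kept, i)
    }
  }
  clusters <- cluster_organs(cloud, candidates)
  .seed_set(point = candidates[kept],
            id = seq_along(kept) + 1L,
            role = rep("organ", length(kept)),
            z = z[kept],
            min_sep = min_sep,
            n_clusters = max(clusters, 0L))
}

.seed_set <- function(point, id, role, z, min_sep, n_clusters = NA_integer_) {
  out <- data.frame(point = as.integer(point), id = as.integer(id),
                    role = as.character(role), z = as.numeric(z),
                    stringsAsFactors = FALSE)
  attr(out, "min_tip_separation") <- min_sep
  attr(out, "n_clusters") <- n_clusters
  class(out) <- c("seed_set", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# entropic optimal transport

#' Entropic optimal-transport plan of a cloud onto itself (Sinkhorn)
#'
#' Computes the `n x n` transport plan `M` minimising
#' `sum m_uv H_uv + (1/eps) sum m_uv log m_uv` subject to uniform marginals
#' `row sums = col sums = 1/n`, where `H` is the pairwise Euclidean distance
#' matrix scaled by its maximum. The Sinkhorn matrix-scaling iteration
#' `h <- 1 / (J (a / (h'K)'))` with `K = exp(-eps H)`, `J = diag(1/a) K` runs
#' until the scaling vector changes by less than `tol` or `max_iter` is hit
#' (then a warning is raised and the current plan returned). If `K` underflows
#' to zero anywhere, the equivalent log-domain stabilised scaling is used.
#'
#' Small `eps` smooths mass toward dense regions; for `eps` above ~100 the
#' induced nearest-neighbour ranking coincides with the Euclidean one.
#'
#' @param coords `n x 3` coordinate matrix, `n >= 2`.
#' @param epsilon regularisation parameter, default 5.
#' @param max_iter maximum scaling iterations, default 10000.
#' @param tol convergence tolerance on the scaling vector, default 1e-9.
#' @param point_index optional mapping from plan row/col to cloud point index
#'   (defaults to `1:n`).
#' @return an object of class `transport_plan` with fields `plan`, `cost`,
#'   `epsilon`, `point_index`, `iterations`, `converged`.
#' @export
sinkhorn_plan <- function(coords, epsilon = 5, max_iter = 10000L, tol = 1e-9,
                          point_index = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (is.null(point_index)) point_index <- seq_len(n)
  H <- as.matrix(dist(coords))
  mx <- max(H)
  if (mx == 0) stop("all points coincide; transport cost is degenerate")
  H <- H / mx
  K <- exp(-epsilon * H)
  a <- rep(1 / n, n)

  if (min(K) == 0) {
    message("Sinkhorn kernel underflow; switching to log-domain scaling")
    res <- .sinkhorn_log(H, epsilon, a, max_iter, tol)
  } else {
    h <- a
    J <- n * K  # diag(1/a) %*% K with uniform a
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      Kh <- as.vector(crossprod(K, h))  # (h'K)'
      hn <- 1 / as.vector(J %*% (a / Kh))
      delta <- max(abs(hn - h))
      h <- hn
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    z <- a / as.vector(crossprod(K, h))
    res <- list(plan = K * tcrossprod(h, z), iterations = iter,
                converged = converged)
  }
  if (!res$converged) {
    warning(sprintf("Sinkhorn did not reach tol=%.1e within %d iterations; returning current plan",
                    tol, max_iter))
  }
  structure(
    list(plan = res$plan, cost = H, epsilon = epsilon,
         point_index = as.integer(point_index),
         iterations = res$iterations, converged = res$converged),
    class = "transport_plan"
  )
}

# log-domain stabilised Sinkhorn; same fixed point as the direct scaling
.sinkhorn_log <- function(H, epsilon, a, max_iter, tol) {
  n <- length(a)
  la <- log(a)
  G <- -epsilon * H
  f <- rep(0, n)
  g <- rep(0, n)
  lse <- function(m) {  # row-wise log-sum-exp
    mx <- apply(m, 1, max)
    mx + log(rowSums(exp(m - mx)))
  }
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    f_new <- la - lse(sweep(G, 2, g, "+"))
    g_new <- la - lse(sweep(t(G), 2, f_new, "+"))
    delta <- max(abs(exp(f_new) - exp(f)), abs(exp(g_new) - exp(g)))
    f <- f_new; g <- g_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(plan = exp(outer(f, g, "+") + G), iterations = iter,
       converged = converged)
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("<transport_plan> n=%d, epsilon=%g, %d iteration(s)%s\n",
              nrow(x$plan), x$epsilon, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Row/column marginals of a transport plan
#' @param plan a [sinkhorn_plan()] result.
#' @return list with `rows` and `cols` sums (each should equal `1/n`).
#' @export
plan_marginals <- function(plan) {
  list(rows = rowSums(plan$plan), cols = colSums(plan$plan))
}

#' Optimal-transport distance between two cloud points
#'
#' `D_s(p_u, p_v) = 1 / m_uv`: the more mass the plan moves between two
#' points, the closer they are. An underflowed zero mass maps to `Inf` so the
#' pair is never selected as nearest.
#'
#' @param plan a [sinkhorn_plan()] result.
#' @param u,v cloud point indices covered by `plan$point_index`.
#' @return a nonnegative number (possibly `Inf`).
#' @export
ot_distance <- function(plan, u, v) {
  ru <- match(as.integer(u), plan$point_index)
  rv <- match(as.integer(v), plan$point_index)
  if (is.na(ru) || is.na(rv)) stop("point not covered by the transport plan")
  m <- plan$plan[ru, rv]
  if (m <= 0) Inf else 1 / m
}

# ---------------------------------------------------------------------------
# top-down assignment

#' Initialise a segmentation state from stem, pot and organ seeds
#'
#' Instance 1 is the stem; each detected organ becomes an instance holding
#' only its seed point (ids follow the seed order, i.e. descending height);
#' the pot, when nonempty, is appended as the last instance.
#'
#' @param cloud a [labeled_cloud()].
#' @param stem_set stem point indices.
#' @param pot_set pot point indices (possibly empty).
#' @param seeds a `seed_set` from [detect_organ_seeds()] (or built manually).
#' @return a [segmentation_state()].
#' @export
initialize_state <- function(cloud, stem_set, pot_set, seeds) {
  instances <- c(list(sort(as.integer(stem_set))),
                 lapply(seeds$point, identity))
  roles <- c("stem", ifelse(seeds$role == "organ", "leaf", seeds$role))
  if (length(pot_set)) {
    instances <- c(instances, list(sort(as.integer(pot_set))))
    roles <- c(roles, "pot")
  }
  segmentation_state(cloud, instances, roles)
}

#' Top-down coarse assignment of the remaining points
#'
#' Walks the unsegmented points in strictly descending height (z ties broken
#' by ascending point index). For each point `p` the distance to instance `i`
#' is `d^i = min_{q in instance i} D_s(p, q)` -- the optimal-transport
#' distance to the instance's nearest member, i.e. the member receiving the
#' most plan mass -- and `p` joins the instance with the smallest `d^i`.
#' Instances grow during the pass, so earlier (higher) assignments pull later
#' points. All instances compete, including stem and pot. With
#' `method = "euclidean"` the same sequential procedure runs with plain
#' Euclidean point-to-member distances; for `epsilon > 100` the two variants
#' produce the same labeling.
#'
#' If every `d^i` is infinite for a point (total plan-mass underflow), that
#' point falls back to the Euclidean rule.
#'
#' @param state a [segmentation_state()] with stem/pot populated and every
#'   organ instance holding (at least) its seed.
#' @param plan a [sinkhorn_plan()] covering every unsegmented point (required
#'   for `method = "ot"`).
#' @param method `"ot"` (default) or `"euclidean"`.
#' @return the completed [segmentation_state()] (empty unsegmented set).
#' @export
assign_top_down <- function(state, plan = NULL,
                            method = c("ot", "euclidean")) {
  method <- match.arg(method)
  stopifnot(inherits(state, "segmentation_state"))
  n_inst <- length(state$instances)
  if (n_inst < 1L) stop("state has no instances")
  unseg <- state$unsegmented
  if (!length(unseg)) return(state)
  z <- state$cloud$coords[, 3]
  ord <- unseg[order(-z[unseg], unseg)]

  if (method == "ot") {
    if (is.null(plan)) stop("method='ot' requires a transport plan")
    pi_map <- plan$point_index
    if (!all(unseg %in% pi_map)) {
      stop("transport plan must cover every unsegmented point")
    }
    P <- plan$plan
    npart <- nrow(P)
    row_of <- match(seq_len(n_points(state$cloud)), pi_map)
    # best plan mass from each participant to each instance (0 = none yet)
    B <- matrix(0, npart, n_inst)
    for (i in seq_len(n_inst)) {
      mem <- row_of[state$instances[[i]]]
      mem <- mem[!is.na(mem)]
      if (length(mem) == 1L) B[, i] <- P[, mem]
      else if (length(mem) > 1L) {
        B[, i] <- do.call(pmax, c(asplit(P[, mem, drop = FALSE], 2),
                                  list(na.rm = FALSE)))
      }
    }
    coords <- state$cloud$coords
    assign_to <- integer(length(ord))
    for (j in seq_along(ord)) {
      p <- ord[j]
      r <- row_of[p]
      b <- B[r, ]
      if (all(b <= 0)) {
        # plan mass underflowed everywhere: Euclidean nearest instance
        message(sprintf("point %d: all OT distances infinite; using Euclidean fallback", p))
        dmin <- vapply(seq_len(n_inst), function(i) {
          mem <- state$instances[[i]]
          if (!length(mem)) return(Inf)
          min(.min_dist(coords[p, , drop = FALSE],
                        coords[mem, , drop = FALSE]))
        }, numeric(1))
        i_star <- which.min(dmin)
      } else {
        i_star <- which.max(b)  # max mass == min D_s; ties -> lowest id
      }
      assign_to[j] <- i_star
      state$instances[[i_star]] <- c(state$instances[[i_star]], p)
      B[, i_star] <- pmax(B[, i_star], P[, r])
    }
  } else {
    coords <- state$cloud$coords
    Bd <- matrix(Inf, length(ord), n_inst)
    pos <- integer(n_points(state$cloud))
    pos[ord] <- seq_along(ord)
    for (i in seq_len(n_inst)) {
      mem <- state$instances[[i]]
      if (length(mem)) {
        Bd[, i] <- .min_dist(coords[ord, , drop = FALSE],
                             coords[mem, , drop = FALSE])
      }
    }
    for (j in seq_along(ord)) {
      p <- ord[j]
      i_star <- which.min(Bd[j, ])
      state$instances[[i_star]] <- c(state$instances[[i_star]], p)
      dp <- sqrt(rowSums((coords[ord, , drop = FALSE] -
                            rep(coords[p, ], each = length(ord)))^2))
      Bd[, i_star] <- pmin(Bd[, i_star], dp)
    }
  }
  state$unsegmented <- integer(0)
  state$instances <- lapply(state$instances, function(i) sort(unique(i)))
  sync_labels(state)
}
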