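#' Build an MRF refinement problem over a region of interest
#'
#' Fine segmentation relabels a chosen region of interest among `n >= 2`
#' instances by minimising a multi-label MRF energy. The graph is the
#' symmetrised k-nearest-neighbour graph over the ROI plus the per-instance
#' seed sets; seed points are removed from the ROI and pinned to their labels.
#' The data term for labeling point `p` with instance `i` is the Euclidean
#' distance from `p` to the nearest point of seed set `i`. The pairwise term
#' on an edge `(p, q)` is
#' `V = (d(p,q) / d')^tau * (a(n_p, n_q) / pi)^phi`, charged only when the two
#' endpoint labels differ (Potts gating), where `d'` is the largest edge
#' length in the graph (so the distance factor lies in (0, 1]) and
#' `a(n_p, n_q) = acos(|n_p . n_q|)` is the normal angle folded to
#' `[0, pi/2]` (normal orientation is arbitrary); the paper's `pi` denominator
#' is kept.
#'
#' @param cloud a [labeled_cloud()]; normals are estimated with
#'   [estimate_normals()] if absent.
#' @param instance_ids the ids of the `n >= 2` instances being refined.
#' @param roi integer indices of the region of interest.
#' @param seeds list of nonempty integer index vectors parallel to
#'   `instance_ids`.
#' @param gamma data-term weight, default 1.
#' @param tau distance-factor exponent, default 1.
#' @param phi angle-factor exponent, default 1.
#' @param k neighbourhood size for the graph, default 10.
#' @return an object of class `mrf_problem`.
#' @export
mrf_problem <- function(cloud, instance_ids, roi, seeds,
                        gamma = 1, tau = 1, phi = 1, k = 10L) {
  instance_ids <- as.integer(instance_ids)
  if (length(instance_ids) < 2L) stop("need n > 1 instances to refine")
  if (length(seeds) != length(instance_ids)) {
    stop("one seed set per instance id is required")
  }
  seeds <- lapply(seeds, function(s) sort(unique(as.integer(s))))
  if (any(lengths(seeds) == 0L)) stop("configuration error: empty seed set")
  seed_all <- unlist(seeds, use.names = FALSE)
  if (anyDuplicated(seed_all)) stop("seed sets must be disjoint")
  roi <- setdiff(sort(unique(as.integer(roi))), seed_all)
  if (any(c(gamma, tau, phi) <= 0)) stop("gamma, tau, phi must be positive")

  if (is.null(cloud$normals)) cloud <- estimate_normals(cloud, k = max(k, 10L))

  nodes <- c(roi, seed_all)
  nn <- length(nodes)
  pts <- cloud$coords[nodes, , drop = FALSE]
  kk <- min(as.integer(k) + 1L, nn)  # +1: self is its own first neighbour
  knn <- .knn(pts, pts, k = kk)
  pairs <- do.call(rbind, lapply(seq_len(nn), function(i) {
    j <- setdiff(knn$idx[i, ], i)
    cbind(pmin(i, j), pmax(i, j))
  }))
  pairs <- unique(pairs)  # symmetrised: keep edge if either endpoint saw it
  d_edge <- sqrt(rowSums((pts[pairs[, 1], , drop = FALSE] -
                            pts[pairs[, 2], , drop = FALSE])^2))
  d_prime <- max(d_edge)
  nrm <- cloud$normals[nodes, , drop = FALSE]
  cosang <- abs(rowSums(nrm[pairs[, 1], , drop = FALSE] *
                          nrm[pairs[, 2], , drop = FALSE]))
  ang <- acos(pmin(pmax(cosang, 0), 1))
  w <- (d_edge / d_prime)^tau * (ang / pi)^phi

  n_lab <- length(instance_ids)
  Dmat <- matrix(0, length(roi), n_lab)
  if (length(roi)) {
    for (i in seq_len(n_lab)) {
      Dmat[, i] <- .min_dist(cloud$coords[roi, , drop = FALSE],
                             cloud$coords[seeds[[i]], , drop = FALSE])
    }
  }
  fixed_label <- rep(seq_len(n_lab), lengths(seeds))  # label position per seed node

  structure(
    list(cloud = cloud, instance_ids = instance_ids,
         roi = roi, seeds = seeds,
         nodes = nodes, n_free = length(roi),
         edges = pairs, edge_w = w, d_prime = d_prime,
         data = Dmat, fixed_label = fixed_label,
         gamma = gamma, tau = tau, phi = phi, k = as.integer(k)),
    class = "mrf_problem"
  )
}

#' @export
print.mrf_problem <- function(x, ...) {
  cat(sprintf("<mrf_problem> %d free points, %d labels, %d edges, d'=%.3f\n",
              x$n_free, length(x$instance_ids), nrow(x$edges), x$d_prime))
  invisible(x)
}

# label position (1..n) of each node under a free labeling (positions)
.node_labels <- function(problem, free_pos) {
  c(free_pos, problem$fixed_label)
}

#' MRF energy of a labeling
#'
#' `E(f) = gamma * sum_p D_p(f(p)) + sum_{(p,q)} V(f(p), f(q))`, with `V`
#' charged only on label-disagreeing edges.
#'
#' @param problem an [mrf_problem()].
#' @param labeling integer vector over the free ROI points (in `problem$roi`
#'   order) holding instance ids.
#' @return the scalar energy.
#' @export
mrf_energy <- function(problem, labeling) {
  pos <- match(as.integer(labeling), problem$instance_ids)
  if (length(pos) != problem$n_free || any(is.na(pos))) {
    stop("labeling must assign a selected instance id to every ROI point")
  }
  lab <- .node_labels(problem, pos)
  data_e <- if (problem$n_free) {
    sum(problem$data[cbind(seq_len(problem$n_free), pos)])
  } else 0
  disagree <- lab[problem$edges[, 1]] != lab[problem$edges[, 2]]
  problem$gamma * data_e + sum(problem$edge_w[disagree])
}

# optimal alpha-expansion move via a single s-t min cut (igraph max_flow).
# free_pos: current label positions of free nodes. Returns new free_pos.
.expand_label <- function(problem, free_pos, alpha) {
  nf <- problem$n_free
  movable <- which(free_pos != alpha)
  if (!length(movable)) return(free_pos)
  # cost0 = keep current label, cost1 = switch to alpha (per movable node)
  id_of <- integer(nf)
  id_of[movable] <- seq_along(movable)
  cost0 <- problem$gamma * problem$data[cbind(movable, free_pos[movable])]
  cost1 <- problem$gamma * problem$data[cbind(movable, rep(alpha, length(movable)))]
  lab <- .node_labels(problem, free_pos)
  ef <- numeric(0); et <- numeric(0); ecap <- numeric(0)  # inter-node edges
  for (e in seq_len(nrow(problem$edges))) {
    p <- problem$edges[e, 1]; q <- problem$edges[e, 2]
    w <- problem$edge_w[e]
    p_mov <- p <= nf && free_pos[p] != alpha
    q_mov <- q <= nf && free_pos[q] != alpha
    if (!p_mov && !q_mov) next
    if (p_mov && q_mov) {
      A <- w * (lab[p] != lab[q])  # theta(0,0)
      # E = A + (C-A) xp + (D-C) xq + (B+C-A-D)(1-xp)xq; B = C = w, D = 0
      i <- id_of[p]; j <- id_of[q]
      cost1[i] <- cost1[i] + (w - A)
      cost1[j] <- cost1[j] - w
      cost0[i] <- cost0[i] + A  # constant A folded into a cut-side cost
      cost1[i] <- cost1[i] + A
      ef <- c(ef, i); et <- c(et, j); ecap <- c(ecap, 2 * w - A)
    } else {
      mov <- if (p_mov) p else q
      oth <- if (p_mov) q else p
      i <- id_of[mov]
      if (lab[oth] == alpha) {
        cost0[i] <- cost0[i] + w           # staying disagrees with alpha
      } else {
        cost1[i] <- cost1[i] + w           # switching disagrees with fixed label
        if (lab[mov] != lab[oth]) cost0[i] <- cost0[i] + w
      }
    }
  }
  shift <- pmin(cost0, cost1)
  cap_s <- cost1 - shift  # cut when node ends on sink side (x = 1)
  cap_t <- cost0 - shift
  nm <- length(movable)
  s <- nm + 1L; t <- nm + 2L
  from <- c(rep(s, nm), seq_len(nm), ef)
  to <- c(seq_len(nm), rep(t, nm), et)
  cap <- c(cap_s, cap_t, ecap)
  keep <- cap > 0
  g <- igraph::make_empty_graph(nm + 2L, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from[keep], to[keep]))
  fl <- igraph::max_flow(g, source = s, target = t,
                         capacity = cap[keep])
  switch_to_alpha <- movable[!(seq_len(nm) %in% as.integer(fl$partition1))]
  new_pos <- free_pos
  new_pos[switch_to_alpha] <- alpha
  new_pos
}

# iterated conditional modes fallback (greedy local relabeling)
.icm <- function(problem, free_pos, max_sweeps = 20L) {
  ids <- problem$instance_ids
  for (s in seq_len(max_sweeps)) {
    changed <- FALSE
    for (p in seq_len(problem$n_free)) {
      best <- free_pos[p]; best_e <- Inf
      for (l in seq_along(ids)) {
        trial <- free_pos; trial[p] <- l
        e <- mrf_energy(problem, ids[trial])
        if (e < best_e) { best_e <- e; best <- l }
      }
      if (best != free_pos[p]) { free_pos[p] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  free_pos
}

#' Solve an MRF refinement problem by alpha-expansion
#'
#' Starts from the Euclidean nearest-seed-set labeling and cycles over the
#' labels in id order, solving each binary "expand label alpha" subproblem as
#' an s-t min cut; a move is accepted only if it strictly lowers the energy,
#' so the energy is non-increasing. Cycling stops when a full cycle accepts
#' no move or after `max_cycles`. If the graph-cut solver fails, the solver
#' falls back to iterated conditional modes with a warning.
#'
#' @param problem an [mrf_problem()].
#' @param max_cycles maximum expansion cycles, default 10.
#' @return list with `labeling` (instance ids over `problem$roi`), `energy`,
#'   `initial_energy`, and `cloud` (the problem cloud with ROI labels written
#'   back).
#' @export
solve_mrf <- function(problem, max_cycles = 10L) {
  stopifnot(inherits(problem, "mrf_problem"))
  ids <- problem$instance_ids
  if (problem$n_free == 0L) {
    return(list(labeling = integer(0), energy = 0, initial_energy = 0,
                cloud = problem$cloud))
  }
  free_pos <- apply(problem$data, 1, which.min)  # nearest seed set; ties -> lower id
  e_init <- mrf_energy(problem, ids[free_pos])
  e_cur <- e_init
  for (cycle in seq_len(max_cycles)) {
    improved <- FALSE
    for (alpha in seq_along(ids)) {
      cand <- tryCatch(
        .expand_label(problem, free_pos, alpha),
        error = function(err) {
          warning("graph-cut solver failed (", conditionMessage(err),
                  "); falling back to ICM")
          .icm(problem, free_pos)
        }
      )
      e_new <- mrf_energy(problem, ids[cand])
      if (e_new < e_cur - 1e-12) {
        stopifnot(e_new <= e_cur)  # monotone solver contract
        free_pos <- cand
        e_cur <- e_new
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  cloud <- problem$cloud
  cloud$labels[problem$roi] <- ids[free_pos]
  list(labeling = ids[free_pos], energy = e_cur, initial_energy = e_init,
       cloud = cloud)
}

#' Assign one instance label to a whole region of interest
#'
#' The direct shortcut to MRF refinement: every ROI point is moved into the
#' given instance and the partition invariant is restored. Idempotent.
#'
#' @param state a [segmentation_state()].
#' @param roi nonempty integer index vector.
#' @param instance_id an existing instance id.
#' @return the updated [segmentation_state()].
#' @export
assign_label_direct <- function(state, roi, instance_id) {
  stopifnot(inherits(state, "segmentation_state"))
  roi <- as.integer(roi)
  if (!length(roi)) stop("roi must be nonempty")
  instance_id <- as.integer(instance_id)
  if (instance_id < 1L || instance_id > length(state$instances)) {
    stop("unknown instance id: ", instance_id)
  }
  .move_points(state, roi, instance_id)
}
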