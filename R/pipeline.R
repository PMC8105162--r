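#' End-to-end shoot segmentation
#'
#' Chains the pipeline stages on a single shoot: optional voxel
#' simplification, median-directed stem growing plus median-axis trimming,
#' stem-axis alignment, height-based pot classification, organ seed
#' detection (or user-supplied seeds), Sinkhorn transport plan, top-down
#' coarse assignment, and -- when the input was simplified -- k-NN label
#' transfer back to the dense original. MRF fine refinement is a separate,
#' interactive-style step ([mrf_problem()] / [solve_mrf()] /
#' [assign_label_direct()]) and is marked `"skipped"` in the run report.
#'
#' The transport plan is computed once over all points taking part in organ
#' assignment: the unsegmented points, every organ seed, and at most
#' `plan_cap` evenly spaced representatives each of the stem and pot
#' instances (the full plan over 13,000+ points would be large; the
#' representatives keep stem and pot competitive without it).
#'
#' @param input a [labeled_cloud()] or a file path readable by
#'   [read_cloud()].
#' @param stem a [stem_params()] with the shoot's bottom/top stem endpoints
#'   in input coordinates.
#' @param epsilon Sinkhorn regularisation (default 5).
#' @param min_tip_sep minimum organ tip separation in mm (default 50).
#' @param seeds optional organ seeds: a matrix/data.frame of xyz rows in
#'   input coordinates (snapped to the nearest eligible cloud point) or a
#'   `seed_set` of point indices; `NULL` (default) detects seeds
#'   automatically.
#' @param method `"ot"` (default) or `"euclidean"` coarse assignment.
#' @param target_points simplify the cloud below this size first (default
#'   13000; the toolkit guidance is < 15,000 points per shoot).
#' @param k_transfer voting neighbours for the label upsampling (default 5).
#' @param plan_cap cap on stem/pot representatives in the transport plan
#'   (default 500).
#' @param units input coordinate units (rescaled to mm).
#' @param out optional path for the labeled output cloud (`x y z label`
#'   rows).
#' @param report_path optional path for the JSON run report.
#' @return list with `cloud` (the input-resolution labeled cloud), `state`
#'   (the sparse [segmentation_state()]), `frame`, `seeds`, and `report`.
#' @export
run_pipeline <- function(input, stem,
                         epsilon = 5,
                         min_tip_sep = 50,
                         seeds = NULL,
                         method = c("ot", "euclidean"),
                         target_points = 13000L,
                         k_transfer = 5L,
                         plan_cap = 500L,
                         units = c("mm", "cm", "m"),
                         out = NULL,
                         report_path = NULL) {
  method <- match.arg(method)
  units <- match.arg(units)
  stopifnot(inherits(stem, "stem_params"))
  t_start <- proc.time()[["elapsed"]]
  stages <- list()
  mark <- local({
    last <- t_start
    function(name, n) {
      now <- proc.time()[["elapsed"]]
      stages[[length(stages) + 1L]] <<- list(stage = name, n_points = n,
                                             elapsed_s = round(now - last, 3))
      last <<- now
    }
  })

  dense <- if (inherits(input, "labeled_cloud")) input else
    read_cloud(input, units = units)
  dense$labels <- rep(-1L, n_points(dense))
  mark("read", n_points(dense))

  simplified <- n_points(dense) > target_points
  if (simplified) {
    voxel <- choose_voxel_size(dense, target_points)
    ds <- voxel_downsample(dense, voxel)
    sparse <- ds$cloud
  } else {
    voxel <- 0
    sparse <- dense
  }
  mark("downsample", n_points(sparse))

  stem_grown <- grow_stem(sparse, stem)
  stem_set <- median_trim(sparse, stem_grown, stem)
  mark("stem", length(stem_set))

  frame <- fit_frame(sparse, stem_set, up = stem$sn - stem$s0)
  aligned <- apply_frame(sparse, frame)
  mark("align", n_points(aligned))

  pot_set <- detect_pot(aligned, stem_set)
  mark("pot", length(pot_set))

  # seed candidacy excludes the whole grown stem column: points the median
  # trim returned to the unsegmented set are still stem-surface points, and
  # the topmost of them would otherwise masquerade as an organ maximum
  if (is.null(seeds)) {
    seed_set <- detect_organ_seeds(aligned,
                                   exclude = c(stem_grown, stem_set, pot_set),
                                   min_sep = min_tip_sep)
  } else {
    seed_set <- .coerce_seeds(seeds, aligned, frame,
                              exclude = c(stem_set, pot_set),
                              min_sep = min_tip_sep)
  }
  if (!nrow(seed_set)) stop("no organ seeds found or supplied")
  mark("seeds", nrow(seed_set))

  state <- initialize_state(aligned, stem_set, pot_set, seed_set)

  participants <- sort(unique(c(state$unsegmented, seed_set$point,
                                .cap_sample(stem_set, plan_cap),
                                .cap_sample(pot_set, plan_cap))))
  plan <- if (method == "ot") {
    sinkhorn_plan(aligned$coords[participants, , drop = FALSE],
                  epsilon = epsilon, point_index = participants)
  } else NULL
  mark("sinkhorn", length(participants))

  state <- assign_top_down(state, plan, method = method)
  mark("coarse", n_points(aligned))
  mark("fine (skipped)", 0L)

  result <- dense
  if (simplified) {
    sparse_labeled <- sparse
    sparse_labeled$labels <- state$cloud$labels
    result <- transfer_labels(sparse_labeled, dense, k = k_transfer)
    mark("upsample", n_points(result))
  } else {
    result$labels <- state$cloud$labels
  }

  report <- list(
    parameters = list(
      alpha = stem$alpha, beta = stem$beta, r1 = stem$r1,
      n_median_segments = stem$n_median_segments,
      n_median_ops = stem$n_median_ops,
      epsilon = epsilon, min_tip_sep = min_tip_sep,
      gamma = NA, tau = NA, phi = NA, k = k_transfer,
      voxel_mm = voxel, target_points = target_points,
      plan_cap = plan_cap, method = method,
      stem_bottom = stem$s0, stem_top = stem$sn,
      seeds = seed_set$point
    ),
    n_instances = length(state$instances),
    roles = state$roles,
    instance_sizes = vapply(state$instances, length, integer(1)),
    fine_segmentation = "skipped",
    stages = stages,
    total_elapsed_s = round(proc.time()[["elapsed"]] - t_start, 3)
  )

  if (!is.null(out)) write_cloud(result, out)
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(cloud = result, state = state, frame = frame, seeds = seed_set,
       report = report)
}

# deterministic evenly spaced subsample of an index set
.cap_sample <- function(idx, cap) {
  idx <- sort(as.integer(idx))
  if (length(idx) <= cap) return(idx)
  idx[unique(round(seq(1L, length(idx), length.out = cap)))]
}

# user-supplied seeds: xyz rows (input frame) snapped to the nearest eligible
# aligned point, or a seed_set of indices passed through
.coerce_seeds <- function(seeds, aligned, frame, exclude, min_sep) {
  if (inherits(seeds, "seed_set")) return(seeds)
  xyz <- as.matrix(as.data.frame(seeds)[, 1:3])
  storage.mode(xyz) <- "double"
  xyz_aligned <- sweep(xyz, 2, frame$origin) %*% t(frame$rotation)
  eligible <- setdiff(seq_len(n_points(aligned)), as.integer(exclude))
  nn <- .knn(xyz_aligned, aligned$coords[eligible, , drop = FALSE], k = 1L)
  pts <- eligible[nn$idx[, 1L]]
  if (anyDuplicated(pts)) stop("two seeds snapped to the same cloud point")
  z <- aligned$coords[pts, 3]
  ord <- order(-z)
  .seed_set(point = pts[ord], id = seq_along(pts) + 1L,
            role = rep("organ", length(pts)), z = z[ord],
            min_sep = min_sep)
}
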