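#' Segmentation bookkeeping state
#'
#' Tracks the exact partition of a cloud into the unsegmented set and the
#' instance sets during the pipeline. Instance 1 is always the stem; the pot,
#' when present, is the last instance id `N` (for a shoot with `n1` ears and
#' `n2` leaves, `N = 3 + n1 + n2`). Segmentation is complete when the
#' unsegmented set is empty.
#'
#' @param cloud a [labeled_cloud()].
#' @param instances list of integer index vectors, one per instance id
#'   (position in the list is the id). May contain empty vectors.
#' @param roles character vector parallel to `instances`; each one of
#'   `"stem"`, `"leaf"`, `"tassel"`, `"ear"`, `"pot"`, `"organ"`.
#' @return an object of class `segmentation_state`.
#' @export
segmentation_state <- function(cloud, instances, roles) {
  if (length(instances) != length(roles)) {
    stop("instances and roles must have equal length")
  }
  instances <- lapply(instances, function(i) sort(unique(as.integer(i))))
  assigned <- unlist(instances, use.names = FALSE)
  if (anyDuplicated(assigned)) stop("instances must be pairwise disjoint")
  n <- n_points(cloud)
  if (length(assigned) && (min(assigned) < 1L || max(assigned) > n)) {
    stop("instance indices out of range")
  }
  if (length(roles) && roles[1] != "stem") stop("instance 1 must be the stem")
  if ("pot" %in% roles && roles[length(roles)] != "pot") {
    stop("the pot must be the last instance")
  }
  state <- structure(
    list(cloud = cloud,
         instances = instances,
         roles = as.character(roles),
         unsegmented = setdiff(seq_len(n), assigned)),
    class = "segmentation_state"
  )
  sync_labels(state)
}

#' @export
print.segmentation_state <- function(x, ...) {
  cat(sprintf("<segmentation_state> %d points, %d instance(s), %d unsegmented\n",
              n_points(x$cloud), length(x$instances), length(x$unsegmented)))
  sizes <- vapply(x$instances, length, integer(1))
  for (i in seq_along(x$instances)) {
    cat(sprintf("  [%d] %-6s %d points\n", i, x$roles[i], sizes[i]))
  }
  invisible(x)
}

#' Check the exact-partition invariant of a state
#'
#' The instance sets must be pairwise disjoint and, together with the
#' unsegmented set, cover every point index exactly once.
#'
#' @param state a [segmentation_state()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_partition <- function(state) {
  all_idx <- sort(c(unlist(state$instances, use.names = FALSE),
                    state$unsegmented))
  if (!identical(all_idx, seq_len(n_points(state$cloud)))) {
    stop("partition invariant violated: instances + unsegmented must tile the cloud")
  }
  invisible(TRUE)
}

#' Write instance memberships into the cloud's label vector
#' @param state a [segmentation_state()].
#' @return the state with `cloud$labels` synchronised.
#' @export
sync_labels <- function(state) {
  labels <- rep(-1L, n_points(state$cloud))
  for (i in seq_along(state$instances)) labels[state$instances[[i]]] <- i
  state$cloud$labels <- labels
  check_partition(state)
  state
}

# move `idx` into instance `id`, removing them from wherever they were
.move_points <- function(state, idx, id) {
  idx <- as.integer(idx)
  state$unsegmented <- setdiff(state$unsegmented, idx)
  for (i in seq_along(state$instances)) {
    if (i != id) state$instances[[i]] <- setdiff(state$instances[[i]], idx)
  }
  state$instances[[id]] <- sort(union(state$instances[[id]], idx))
  sync_labels(state)
}
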