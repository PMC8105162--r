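#' Organ-level agreement between two labelings
#'
#' Compares a predicted labeling against a reference labeling of the same
#' cloud. Per-instance true/false positives and negatives come from the
#' confusion matrix; `precision` and `recall` are the unweighted means of the
#' per-instance values (the shoot-organ averages), `macro_f1` is the mean of
#' the per-instance F1 scores, and `micro_f1` is the F1 of the pooled
#' (shoot-level) precision and recall -- which, for two partitions over the
#' same id set, equals the overall point accuracy. With
#' `matching = "hungarian"` the predicted instance ids are first matched to
#' the reference ids by a maximum-weight bipartite matching on the confusion
#' matrix (useful when the two labelings number their instances differently);
#' `"identity"` compares ids as-is.
#'
#' An instance predicted but never true (or vice versa) contributes
#' precision/recall 0 on its undefined side.
#'
#' @param pred predicted labels: a [labeled_cloud()] or integer vector.
#' @param truth reference labels, same length/order.
#' @param matching `"identity"` (default) or `"hungarian"`.
#' @return an `eval_report`: list with `per_instance` (data.frame of id,
#'   n_true, n_pred, precision, recall, f1), `overall_accuracy`, `precision`,
#'   `recall`, `micro_f1`, `macro_f1`, `confusion` (truth rows x pred
#'   columns) and `matching` (pred id -> matched id map).
#' @examples
#' r <- evaluate_segmentation(c(1, 1, 2, 2, 2), c(1, 1, 1, 2, 2))
#' r$overall_accuracy  # 0.8
#' @export
evaluate_segmentation <- function(pred, truth,
                                  matching = c("identity", "hungarian")) {
  matching <- match.arg(matching)
  if (inherits(pred, "labeled_cloud")) pred <- pred$labels
  if (inherits(truth, "labeled_cloud")) truth <- truth$labels
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (any(pred == -1L) || any(truth == -1L)) {
    stop("both labelings must be complete (no -1)")
  }

  map <- NULL
  if (matching == "hungarian") {
    map <- .match_instances(pred, truth)
    pred <- unname(map[as.character(pred)])
  }

  ids <- sort(union(unique(truth), unique(pred)))
  ft <- factor(truth, levels = ids)
  fp <- factor(pred, levels = ids)
  confusion <- table(truth = ft, pred = fp)
  tp <- diag(confusion)
  n_true <- rowSums(confusion)
  n_pred <- colSums(confusion)
  precision_i <- ifelse(n_pred > 0, tp / n_pred, 0)
  recall_i <- ifelse(n_true > 0, tp / n_true, 0)
  f1_i <- ifelse(precision_i + recall_i > 0,
                 2 * precision_i * recall_i / (precision_i + recall_i), 0)
  present <- n_true > 0 | n_pred > 0
  per_instance <- data.frame(
    id = ids[present],
    n_true = as.integer(n_true[present]),
    n_pred = as.integer(n_pred[present]),
    precision = unname(precision_i[present]),
    recall = unname(recall_i[present]),
    f1 = unname(f1_i[present])
  )
  total <- length(truth)
  micro_p <- sum(tp) / sum(n_pred)  # == accuracy for a partition
  micro_r <- sum(tp) / sum(n_true)
  structure(
    list(per_instance = per_instance,
         overall_accuracy = sum(tp) / total,
         precision = mean(per_instance$precision),
         recall = mean(per_instance$recall),
         micro_f1 = if (micro_p + micro_r > 0)
           2 * micro_p * micro_r / (micro_p + micro_r) else 0,
         macro_f1 = mean(per_instance$f1),
         confusion = confusion,
         matching = map),
    class = "eval_report"
  )
}

# maximum-trace matching of predicted ids onto truth ids via weighted
# bipartite matching; unmatched predicted ids keep fresh ids past the truth's.
.match_instances <- function(pred, truth) {
  tids <- sort(unique(truth))
  pids <- sort(unique(pred))
  C <- table(factor(truth, levels = tids), factor(pred, levels = pids))
  nt <- length(tids); np <- length(pids)
  edges <- which(C > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(nt + np, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges[, 1], nt + edges[, 2]))
    weights <- C[edges]
  } else {
    weights <- NULL
  }
  types <- c(rep(FALSE, nt), rep(TRUE, np))
  m <- igraph::max_bipartite_match(g, types = types, weights = weights)
  match_of_pred <- m$matching[nt + seq_len(np)]  # truth vertex or NA
  out <- integer(np)
  next_id <- if (length(tids)) max(tids) else 0L
  for (j in seq_len(np)) {
    if (is.na(match_of_pred[j])) {
      next_id <- next_id + 1L
      out[j] <- next_id
    } else {
      out[j] <- tids[match_of_pred[j]]
    }
  }
  stats::setNames(out, pids)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> overall accuracy %.4f | precision %.4f | ",
                     "recall %.4f | micro-F1 %.4f | macro-F1 %.4f\n"),
              x$overall_accuracy, x$precision, x$recall,
              x$micro_f1, x$macro_f1))
  print(x$per_instance, row.names = FALSE)
  invisible(x)
}
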