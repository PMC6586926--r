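# Validation scoring: a temperature estimate is "correct" (score 1) when the
# true exposure temperature falls inside the assigned cluster's range, with
# the upper bound open (+Inf) for the calcined clusters; otherwise score 0.
# Accuracy is the percentage of correct scores per test-set partition, plus an
# overall mean.

#' Score temperature estimates against known exposure temperatures
#'
#' Score 1 when `t_min <= true_T <= t_max` of the assigned cluster (upper
#' bound unbounded for the open clusters 6 and 7), else 0. "Correctly
#' estimated" is interpreted as range containment; note that under this rule a
#' cluster-1 assignment (range starting at 0 C) is correct for a genuinely
#' unheated sample.
#'
#' @param true_T Numeric vector of true exposure temperatures (degrees C).
#' @param cluster Integer vector of assigned cluster ids (1..7), or a
#'   data.frame with a `cluster` column (e.g. from
#'   [classify_measurement()]).
#' @param model A [decision_model()].
#' @return Integer vector of 0/1 scores.
#' @export
score_prediction <- function(true_T, cluster, model = decision_model()) {
  if (is.data.frame(cluster)) cluster <- cluster$cluster
  cluster <- as.integer(cluster)
  if (any(cluster < 1L | cluster > 7L, na.rm = TRUE))
    stop("cluster id must be in 1..7", call. = FALSE)
  n <- max(length(true_T), length(cluster))
  true_T <- rep_len(true_T, n)
  cluster <- rep_len(cluster, n)
  tab <- model$clusters
  lo <- tab$t_min[cluster]
  hi <- ifelse(tab$open[cluster], Inf, tab$t_max[cluster])
  as.integer(true_T >= lo & true_T <= hi)
}

#' Per-partition and overall accuracy of temperature estimation
#'
#' Partition accuracy is 100 * mean(score). Two conventions for the overall
#' figure are reported, since published totals have been computed both ways:
#' `"weighted"` (the default) pools all samples, i.e. weights partitions by
#' size; `"unweighted"` averages the partition accuracies.
#'
#' @param score Integer 0/1 scores (e.g. from [score_prediction()]).
#' @param partition Partition labels, recycled against `score`; a single
#'   label gives a one-partition report.
#' @param overall `"weighted"` or `"unweighted"` convention for the `overall`
#'   element.
#' @return An object of class `accuracy_report`: a list with `partitions`
#'   (data.frame of `partition`, `n`, `accuracy` in percent), `overall`,
#'   `overall_weighted` and `overall_unweighted`.
#' @export
accuracy_report <- function(score, partition = "all",
                            overall = c("weighted", "unweighted")) {
  overall <- match.arg(overall)
  n <- length(score)
  partition <- rep_len(partition, n)
  keep <- !is.na(score)
  if (any(!keep)) {
    warning(sum(!keep), " predictions without scores excluded")
    score <- score[keep]
    partition <- partition[keep]
  }
  if (!length(score)) stop("no scored predictions", call. = FALSE)
  labs <- unique(partition)
  acc <- vapply(labs, function(p) 100 * mean(score[partition == p]),
                numeric(1))
  sizes <- vapply(labs, function(p) sum(partition == p), integer(1))
  parts <- data.frame(partition = labs, n = sizes, accuracy = unname(acc),
                      row.names = NULL, stringsAsFactors = FALSE)
  w <- 100 * mean(score)
  u <- mean(parts$accuracy)
  structure(list(partitions = parts,
                 overall = if (overall == "weighted") w else u,
                 overall_weighted = w, overall_unweighted = u,
                 convention = overall),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 1, ...) {
  cat("Temperature-estimation accuracy\n")
  tab <- x$partitions
  tab$accuracy <- round(tab$accuracy, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("overall: %.1f%% (%s; weighted %.1f%%, unweighted %.1f%%)\n",
              x$overall, x$convention, x$overall_weighted,
              x$overall_unweighted))
  invisible(x)
}

#' Evaluate a decision model on a test dataset
#'
#' Convenience wrapper: assigns clusters to every record, scores them against
#' the true temperatures, and reports accuracy per partition.
#'
#' @param ds A colour dataset with columns `temperature`, `L`, `B` and
#'   optionally `partition`.
#' @param model A [decision_model()].
#' @param partition Column name holding partition labels (default
#'   `"partition"`; a missing column yields a single partition).
#' @inheritParams accuracy_report
#' @return An `accuracy_report` with the scored predictions attached as
#'   attribute `"scores"`.
#' @export
evaluate_dataset <- function(ds, model = decision_model(),
                             partition = "partition",
                             overall = c("weighted", "unweighted")) {
  pred <- predict(model, ds)
  sc <- score_prediction(ds$temperature, pred$cluster, model)
  labs <- if (partition %in% names(ds)) ds[[partition]] else "all"
  rep <- accuracy_report(sc, labs, overall = match.arg(overall))
  attr(rep, "scores") <- data.frame(
    sample_id = if (!is.null(ds$sample_id)) ds$sample_id else seq_along(sc),
    true_T = ds$temperature, cluster = pred$cluster,
    t_min = pred$t_min, t_max = pred$t_max, open = pred$open,
    score = sc, partition = rep_len(labs, length(sc)),
    stringsAsFactors = FALSE)
  rep
}
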