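# The seven-cluster L*/B* threshold decision model for estimating the
# exposure temperature of burned bone.
#
# The model partitions the (L*, B*) plane with fixed published thresholds:
# two colour parameters suffice because the A* coordinate carries almost no
# additional information (it is strongly correlated with B*). Each cluster
# maps to an exposure-temperature range (degrees C) and a heat-induced-change
# (HI) stage.
#
# As printed, the rules overlap (clusters 4 and 5 both admit B* < 6.5) and
# leave exact-threshold ties open. The implementation resolves them to a
# total, mutually exclusive partition; ties go to the lower-temperature
# cluster, which is the forensically conservative choice:
#
#   B >  11: L >= 40 -> 1, else 2
#   B <= 11: L < 32.5            -> 3
#            32.5 <= L < 75      -> 4 if B >= 6.5, else 5
#            L >= 75             -> 6 if L <= -25 B + 200, else 7

#' Decision thresholds of the burned-bone temperature model
#'
#' The published constants: L* thresholds 40 (cluster 1 vs 2), 32.5 (charred)
#' and 75 (calcined); B* thresholds 11 and 6.5; and the linear boundary
#' L* = -25 B* + 200 separating the two calcined clusters. Overrides are
#' intended for sensitivity analysis only.
#'
#' @param L_cluster12 L* threshold between clusters 1 and 2 (default 40).
#' @param L_charred Upper L* bound of the completely charred cluster
#'   (default 32.5).
#' @param L_calcined Lower L* bound of the calcined clusters (default 75).
#' @param B_upper B* threshold separating clusters 1-2 from 3-7 (default 11).
#' @param B_grey B* threshold between clusters 4 and 5 (default 6.5).
#' @param line_slope,line_intercept Coefficients of the cluster 6/7 boundary
#'   L* = slope * B* + intercept (defaults -25 and 200).
#' @return An object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(L_cluster12 = 40, L_charred = 32.5,
                                L_calcined = 75, B_upper = 11, B_grey = 6.5,
                                line_slope = -25, line_intercept = 200) {
  th <- list(L_cluster12 = L_cluster12, L_charred = L_charred,
             L_calcined = L_calcined, B_upper = B_upper, B_grey = B_grey,
             line_slope = line_slope, line_intercept = line_intercept)
  if (!all(vapply(th, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1))))
    stop("all thresholds must be single finite numbers", call. = FALSE)
  structure(th, class = "decision_thresholds")
}

# Cluster id -> temperature range (degrees C) and HI stage. The upper bound of
# clusters 6 and 7 is open: 900 C was the highest exposure used to define the
# ranges, so it is reported as ">= 900".
.cluster_table <- data.frame(
  cluster = 1:7,
  t_min = c(0, 250, 300, 450, 450, 700, 800),
  t_max = c(350, 350, 600, 600, 700, 900, 900),
  open = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
  stage = c("Unheated - carbonization", "Carbonization",
            "Completely charred", "Inversion", "Inversion - calcination",
            "Completely calcined", "Completely calcined"),
  stringsAsFactors = FALSE
)

#' Cluster temperature ranges and HI stages
#'
#' @return A data.frame with one row per cluster: `cluster`, `t_min`, `t_max`
#'   (both degrees C), `open` (`TRUE` when the upper bound is ">= 900", i.e.
#'   unbounded above), and `stage`.
#' @export
cluster_table <- function() .cluster_table

#' The burned-bone temperature decision model
#'
#' Bundles the decision thresholds with the cluster temperature ranges and HI
#' stages; [predict.decision_model()] and [assign_cluster()] apply it.
#'
#' @param thresholds A [decision_thresholds()] object.
#' @return An object of class `decision_model`.
#' @export
decision_model <- function(thresholds = decision_thresholds()) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  structure(list(thresholds = thresholds, clusters = .cluster_table),
            class = "decision_model")
}

#' @export
print.decision_model <- function(x, ...) {
  th <- x$thresholds
  cat("Burned-bone temperature decision model (7 clusters in L*/B* space)\n")
  cat(sprintf("  B* > %g:  L* >= %g -> cluster 1, else cluster 2\n",
              th$B_upper, th$L_cluster12))
  cat(sprintf("  B* <= %g: L* < %g -> 3; %g <= L* < %g -> 4 (B* >= %g) or 5; ",
              th$B_upper, th$L_charred, th$L_charred, th$L_calcined, th$B_grey))
  cat(sprintf("L* >= %g -> 6 if L* <= %g*B* + %g, else 7\n",
              th$L_calcined, th$line_slope, th$line_intercept))
  tab <- x$clusters
  tab$t_max <- ifelse(tab$open, ">=900", as.character(tab$t_max))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Assign colour measurements to temperature clusters
#'
#' Applies the threshold rules to L* and B* values (A* is accepted elsewhere
#' but carries no weight in the model). Vectorised; ties at threshold values
#' resolve to the lower-temperature cluster.
#'
#' @param L Numeric vector of L* values in \[0, 100\].
#' @param B Numeric vector of B* values (finite), recycled against `L`.
#' @param model A [decision_model()] (or [decision_thresholds()]).
#' @return Integer vector of cluster ids in 1..7.
#' @export
assign_cluster <- function(L, B, model = decision_model()) {
  if (inherits(model, "decision_thresholds")) model <- decision_model(model)
  stopifnot(inherits(model, "decision_model"))
  th <- model$thresholds
  n <- max(length(L), length(B))
  L <- rep_len(as.numeric(L), n)
  B <- rep_len(as.numeric(B), n)
  if (any(!is.finite(L)) || any(!is.finite(B)))
    stop("non-finite L* or B* value", call. = FALSE)
  if (any(L < 0 | L > 100))
    stop("L* outside [0, 100]", call. = FALSE)
  out <- integer(n)
  high_b <- B > th$B_upper
  out[high_b] <- ifelse(L[high_b] >= th$L_cluster12, 1L, 2L)
  lb <- !high_b
  out[lb & L < th$L_charred] <- 3L
  mid <- lb & L >= th$L_charred & L < th$L_calcined
  out[mid] <- ifelse(B[mid] >= th$B_grey, 4L, 5L)
  calc <- lb & L >= th$L_calcined
  out[calc] <- ifelse(L[calc] <= th$line_slope * B[calc] + th$line_intercept,
                      6L, 7L)
  out
}

#' Temperature range of a cluster
#'
#' @param cluster_id Integer vector of cluster ids in 1..7.
#' @return A data.frame with `cluster`, `t_min`, `t_max` (degrees C) and
#'   `open`; for clusters 6 and 7 `open` is `TRUE` and `t_max` is the highest
#'   temperature used in defining the range (900 C), with no true upper bound.
#' @export
temperature_range <- function(cluster_id) {
  cluster_id <- as.integer(cluster_id)
  if (any(is.na(cluster_id)) || any(cluster_id < 1L | cluster_id > 7L))
    stop("cluster id must be in 1..7", call. = FALSE)
  .cluster_table[cluster_id, c("cluster", "t_min", "t_max", "open")]
}

#' @param object A `decision_model`.
#' @param newdata A data.frame with columns `L` and `B` (e.g. a
#'   `colour_measurement` or a colour dataset), or an n x 3 L*a*b* matrix.
#' @param ... Unused.
#' @return A data.frame: `sample_id` (when available), `L`, `B`, `cluster`,
#'   `t_min`, `t_max`, `open`, `stage`, and `flags` when present in the input.
#' @rdname decision_model
#' @export
predict.decision_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    cn <- colnames(newdata)
    newdata <- if (!is.null(cn) && all(c("L", "B") %in% cn))
      data.frame(L = newdata[, "L"], B = newdata[, "B"])
    else data.frame(L = newdata[, 1], B = newdata[, 3])
  }
  if (!all(c("L", "B") %in% names(newdata)))
    stop("newdata must contain columns L and B", call. = FALSE)
  cl <- assign_cluster(newdata$L, newdata$B, object)
  rng <- object$clusters[cl, ]
  out <- data.frame(L = newdata$L, B = newdata$B, cluster = cl,
                    t_min = rng$t_min, t_max = rng$t_max, open = rng$open,
                    stage = rng$stage, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(newdata$sample_id))
    out <- cbind(sample_id = newdata$sample_id, out)
  if (!is.null(newdata$flags)) out$flags <- newdata$flags
  out
}

#' Classify colour measurements
#'
#' Binds one or more [measure_mean_colour()] results (or any table with `L`
#' and `B` columns) to cluster assignments with temperature range and HI
#' stage. Order-preserving; measurement flags are copied through.
#'
#' @param m A `colour_measurement` or data.frame with columns `L` and `B`.
#' @param model A [decision_model()].
#' @return A data.frame of assignment reports, one row per measurement.
#' @export
classify_measurement <- function(m, model = decision_model()) {
  predict(model, m)
}
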