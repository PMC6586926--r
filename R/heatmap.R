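# Per-pixel cluster assignment over a bone-surface image: a heat map of the
# thermal gradient the fragment was exposed to. Per-pixel classification is
# noisier than the ROI-mean pathway, so each pixel's L*a*b* is locally
# averaged (within the mask) before the thresholds are applied.

#' Classify every foreground pixel into a temperature cluster
#'
#' Converts the image to L*a*b*, averages each channel over a
#' `smooth_px` x `smooth_px` window restricted to the mask (suppressing sensor
#' noise before thresholding), and assigns each foreground pixel a cluster.
#'
#' @param img A [sample_image()].
#' @param mask An `roi_mask` aligned with `img`.
#' @param smooth_px Odd window size in pixels (default 5; 1 disables
#'   smoothing).
#' @param corr Optional colour correction applied first.
#' @param model A [decision_model()].
#' @return A `cluster_map`: an integer matrix (0 = background, 1-7 = cluster)
#'   with attributes `fractions` (per-cluster share of foreground pixels) and
#'   `envelope` (see [summarise_map()]).
#' @export
classify_pixels <- function(img, mask, smooth_px = 5, corr = NULL,
                            model = decision_model()) {
  stopifnot(inherits(img, "sample_image"), inherits(mask, "roi_mask"))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  if (smooth_px < 1 || smooth_px %% 2 == 0)
    stop("smooth_px must be a positive odd integer", call. = FALSE)
  flat <- matrix(img$pixels, ncol = 3L)
  if (!is.null(corr)) flat <- apply_colour_correction(flat, corr)
  lab <- srgb_to_lab(flat)
  d <- dim(img$pixels)[1:2]
  m <- matrix(as.numeric(mask), d[1], d[2])
  if (smooth_px > 1) {
    kern <- matrix(1, smooth_px, smooth_px)
    den <- EBImage::filter2(m, kern, boundary = 0)
    sm <- sapply(1:3, function(ch) {
      num <- EBImage::filter2(matrix(lab[, ch], d[1], d[2]) * m, kern,
                              boundary = 0)
      val <- num / pmax(den, .Machine$double.eps)
      as.vector(val)
    })
    lab <- sm
    colnames(lab) <- c("L", "A", "B")
  }
  fg <- as.vector(mask)
  Lv <- pmin(pmax(lab[fg, "L"], 0), 100)
  cl <- assign_cluster(Lv, lab[fg, "B"], model)
  cm <- matrix(0L, d[1], d[2])
  cm[fg] <- cl
  counts <- tabulate(cl, nbins = 7L)
  fractions <- counts / sum(counts)
  names(fractions) <- as.character(1:7)
  out <- structure(cm, class = c("cluster_map", class(cm)),
                   fractions = fractions)
  attr(out, "envelope") <- .map_envelope(fractions, model)
  out
}

.map_envelope <- function(fractions, model = decision_model()) {
  present <- unname(which(fractions > 0))
  tab <- model$clusters[present, , drop = FALSE]
  list(clusters = present,
       t_min = min(tab$t_min), t_max = max(tab$t_max),
       open = any(tab$open))
}

#' Summarise a cluster map
#'
#' Per-cluster pixel fractions and the combined temperature envelope: the
#' minimum over present clusters' range minima and the maximum over their
#' maxima, flagged open when either calcined cluster (6 or 7) is present.
#'
#' @param cm A `cluster_map` from [classify_pixels()].
#' @param model A [decision_model()].
#' @return A list with `fractions`, `clusters` (present ids), `t_min`,
#'   `t_max` and `open`.
#' @export
summarise_map <- function(cm, model = decision_model()) {
  stopifnot(inherits(cm, "cluster_map"))
  fractions <- attr(cm, "fractions")
  env <- .map_envelope(fractions, model)
  c(list(fractions = fractions), env)
}

#' @export
print.cluster_map <- function(x, ...) {
  s <- summarise_map(x)
  cat(sprintf("cluster_map: %d x %d px, clusters present: %s\n",
              nrow(x), ncol(x), paste(s$clusters, collapse = ", ")))
  cat(sprintf("temperature envelope: %g to %s degrees C\n", s$t_min,
              if (s$open) ">= 900" else format(s$t_max)))
  invisible(x)
}

# fixed legend: background white, then one colour per cluster 1..7
.heatmap_palette <- c("#FFFFFF", "#2166AC", "#67A9CF", "#D1E5F0", "#FDDBC7",
                      "#EF8A62", "#B2182B", "#67001F")

#' Render a cluster map to an indexed PNG
#'
#' Writes the map with a fixed 7-colour legend plus white background.
#'
#' @param cm A `cluster_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_cluster_map <- function(cm, path) {
  stopifnot(inherits(cm, "cluster_map"))
  cols <- grDevices::col2rgb(.heatmap_palette) / 255
  idx <- as.vector(cm) + 1L
  img <- array(0, dim = c(nrow(cm), ncol(cm), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(cols[ch, idx], nrow(cm), ncol(cm))
  png::writePNG(img, path)
  invisible(path)
}
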