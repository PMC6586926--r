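# sRGB <-> CIE 1976 L*a*b* conversion and colour-chart calibration.
#
# All internal colour processing is floating point on [0,1] ("unit" scale);
# 8-bit channel values ("byte" scale, 0-255) are accepted and converted at the
# boundary. L* is kept on the 0-100 scale and a*/b* are signed, the scales on
# which the burned-bone decision thresholds (40, 32.5, 75, 11, 6.5) are
# defined.

# Linear-RGB -> XYZ matrices for the sRGB primaries. The reference white used
# throughout is the one implied by the matrix (its row sums), so that
# greyscale inputs are exactly neutral (a* = b* = 0).
.rgb2xyz <- list(
  D65 = matrix(c(0.4124564, 0.3575761, 0.1804375,
                 0.2126729, 0.7151522, 0.0721750,
                 0.0193339, 0.1191920, 0.9503041),
               nrow = 3, byrow = TRUE),
  D50 = matrix(c(0.4360747, 0.3850649, 0.1430804,
                 0.2225045, 0.7168786, 0.0606169,
                 0.0139322, 0.0971045, 0.7141733),
               nrow = 3, byrow = TRUE)
)

.white_point <- function(white_point = c("D65", "D50")) {
  white_point <- match.arg(white_point)
  rowSums(.rgb2xyz[[white_point]])
}

# Coerce a colour argument (length-3 vector, n x 3 matrix or data.frame) to an
# n x 3 numeric matrix.
.as_colour_matrix <- function(x, what = "colour") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      stop(what, " must be a length-3 vector or an n x 3 matrix", call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L)
    stop(what, " must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

.check_rgb_range <- function(rgb, scale) {
  hi <- if (scale == "byte") 255 else 1
  tol <- 1e-9 * hi
  for (ch in 1:3) {
    v <- rgb[, ch]
    if (anyNA(v) || any(!is.finite(v)))
      stop("non-finite value in channel ", c("R", "G", "B")[ch], call. = FALSE)
    if (any(v < -tol) || any(v > hi + tol))
      stop("channel ", c("R", "G", "B")[ch], " outside [0, ", hi,
           "] for scale '", scale, "'", call. = FALSE)
  }
  invisible(rgb)
}

# sRGB companding (IEC 61966-2-1)
.srgb_decompand <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

.srgb_compand <- function(v) {
  v <- pmax(v, 0) # guard tiny negative linear values from numerical noise
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

.lab_f <- function(t) {
  d3 <- (6 / 29)^3
  ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

.lab_finv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert sRGB colours to CIE 1976 L*a*b*
#'
#' Applies the standard sRGB decompanding, the linear-RGB to XYZ matrix for
#' the chosen reference white, and the CIE 1976 L*a*b* equations. The
#' conversion is deterministic and vectorised over rows.
#'
#' @param rgb A length-3 vector or an n x 3 matrix/data.frame of sRGB channel
#'   values (columns R, G, B).
#' @param scale Scale the channels are stored on: `"unit"` (real values in
#'   \[0,1\], the default) or `"byte"` (integers 0-255).
#' @param white_point Reference white, `"D65"` (default, the sRGB native
#'   white and common flatbed-scanner convention) or `"D50"`.
#' @return An n x 3 matrix with columns `L` (0-100), `A`, `B`. A single input
#'   triple gives a single row.
#' @examples
#' srgb_to_lab(c(255, 255, 255), scale = "byte") # L* = 100, a* = b* = 0
#' @export
srgb_to_lab <- function(rgb, scale = c("unit", "byte"),
                        white_point = c("D65", "D50")) {
  scale <- match.arg(scale)
  white_point <- match.arg(white_point)
  rgb <- .as_colour_matrix(rgb, "rgb")
  .check_rgb_range(rgb, scale)
  if (scale == "byte") rgb <- rgb / 255
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  lin <- .srgb_decompand(rgb)
  M <- .rgb2xyz[[white_point]]
  xyz <- lin %*% t(M)
  wp <- rowSums(M)
  fx <- .lab_f(xyz[, 1] / wp[1])
  fy <- .lab_f(xyz[, 2] / wp[2])
  fz <- .lab_f(xyz[, 3] / wp[3])
  out <- cbind(L = 116 * fy - 16, A = 500 * (fx - fy), B = 200 * (fy - fz))
  rownames(out) <- rownames(rgb)
  out
}

#' Convert CIE 1976 L*a*b* colours to sRGB
#'
#' Exact inverse of [srgb_to_lab()] for in-gamut colours. Out-of-gamut results
#' are clipped to the channel range and flagged: the returned matrix carries a
#' logical attribute `"clipped"`, one entry per row.
#'
#' @param lab A length-3 vector or n x 3 matrix with columns L, A, B.
#' @param scale Output scale, `"unit"` or `"byte"`.
#' @inheritParams srgb_to_lab
#' @return An n x 3 matrix with columns `R`, `G`, `B` and attribute
#'   `"clipped"`.
#' @export
lab_to_srgb <- function(lab, scale = c("unit", "byte"),
                        white_point = c("D65", "D50")) {
  scale <- match.arg(scale)
  white_point <- match.arg(white_point)
  lab <- .as_colour_matrix(lab, "lab")
  if (any(!is.finite(lab)))
    stop("non-finite L*a*b* value", call. = FALSE)
  M <- .rgb2xyz[[white_point]]
  wp <- rowSums(M)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(.lab_finv(fx) * wp[1], .lab_finv(fy) * wp[2],
               .lab_finv(fz) * wp[3])
  lin <- xyz %*% t(solve(M))
  clipped <- rowSums(lin < -1e-9 | lin > 1 + 1e-9) > 0
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  out <- .srgb_compand(lin)
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (scale == "byte") out <- out * 255
  colnames(out) <- c("R", "G", "B")
  rownames(out) <- rownames(lab)
  attr(out, "clipped") <- unname(clipped)
  out
}

#' Euclidean colour difference in L*a*b* (Delta E*ab)
#'
#' @param lab1,lab2 Colours as accepted by [lab_to_srgb()]; either may be a
#'   single triple, which is recycled against the other argument.
#' @return Numeric vector of Delta E*ab values.
#' @export
delta_e <- function(lab1, lab2) {
  lab1 <- .as_colour_matrix(lab1, "lab1")
  lab2 <- .as_colour_matrix(lab2, "lab2")
  if (nrow(lab1) == 1L && nrow(lab2) > 1L)
    lab1 <- lab1[rep(1L, nrow(lab2)), , drop = FALSE]
  if (nrow(lab2) == 1L && nrow(lab1) > 1L)
    lab2 <- lab2[rep(1L, nrow(lab1)), , drop = FALSE]
  sqrt(rowSums((lab1 - lab2)^2))
}

#' Per-patch observations of a colour reference chart
#'
#' Pairs the measured colours of an imaged reference chart (e.g. a 24-patch
#' ColorChecker) with the corresponding reference colours, the input to
#' [fit_colour_correction()].
#'
#' @param measured n x 3 matrix of measured sRGB colours.
#' @param reference n x 3 matrix of reference sRGB colours, same row order.
#' @param patch_id Character or integer patch identifiers; must be unique.
#' @param scale Scale of both colour matrices (`"unit"` or `"byte"`).
#' @return An object of class `chart_observation`.
#' @export
chart_observation <- function(measured, reference,
                              patch_id = seq_len(nrow(.as_colour_matrix(measured))),
                              scale = c("unit", "byte")) {
  scale <- match.arg(scale)
  measured <- .as_colour_matrix(measured, "measured")
  reference <- .as_colour_matrix(reference, "reference")
  if (nrow(measured) != nrow(reference))
    stop("measured and reference must have the same number of patches",
         call. = FALSE)
  if (anyDuplicated(patch_id))
    stop("patch ids must be unique", call. = FALSE)
  if (nrow(measured) < 4L)
    stop("at least 4 patches are required", call. = FALSE)
  structure(list(measured = measured, reference = reference,
                 patch_id = patch_id, scale = scale),
            class = "chart_observation")
}

#' Reference colours of the 24-patch ColorChecker Classic chart
#'
#' Nominal sRGB coordinates of the 24 patches, shipped as a packaged CSV, for
#' use as the `reference` side of a [chart_observation()].
#'
#' @return A data.frame with columns `patch`, `name`, `R`, `G`, `B`
#'   (byte scale).
#' @export
colorchecker_reference <- function() {
  path <- system.file("extdata", "colorchecker_classic_srgb.csv",
                      package = "bonetemp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fit a chart-based colour correction
#'
#' Least-squares fit of a linear (3 x 3) or affine (3 x 3 plus offset) map
#' from measured to reference colours, performed in linearised RGB space. The
#' affine default absorbs a scanner black-level offset. Residuals are
#' summarised as per-patch Delta E*ab between corrected and reference colours.
#'
#' @param obs A [chart_observation()], or an n x 3 matrix of measured colours
#'   if `reference` is supplied.
#' @param reference Optional n x 3 reference matrix when `obs` is a matrix.
#' @param model `"affine"` (default) or `"linear"`.
#' @param scale Scale of matrix inputs when `obs` is not a `chart_observation`.
#' @inheritParams srgb_to_lab
#' @return An object of class `colour_correction` with elements `matrix`
#'   (3 x 3), `offset` (length 3, zero for the linear model), `model`,
#'   `residual_deltaE` (per patch), `rmse`, `mean_deltaE_before` and
#'   `mean_deltaE_after`.
#' @export
fit_colour_correction <- function(obs, reference = NULL,
                                  model = c("affine", "linear"),
                                  scale = c("unit", "byte"),
                                  white_point = c("D65", "D50")) {
  model <- match.arg(model)
  white_point <- match.arg(white_point)
  if (!inherits(obs, "chart_observation")) {
    if (is.null(reference))
      stop("supply a chart_observation or both measured and reference",
           call. = FALSE)
    obs <- chart_observation(obs, reference, scale = match.arg(scale))
  }
  meas <- obs$measured
  ref <- obs$reference
  if (obs$scale == "byte") {
    meas <- meas / 255
    ref <- ref / 255
  }
  X <- .srgb_decompand(meas)
  Y <- .srgb_decompand(ref)
  n_par <- if (model == "affine") 4L else 3L
  if (nrow(X) < n_par)
    stop("need at least ", n_par, " patches for the ", model, " model",
         call. = FALSE)
  D <- if (model == "affine") cbind(1, X) else X
  qrD <- qr(D)
  if (qrD$rank < n_par)
    stop("rank-deficient patch set: cannot fit ", model, " correction",
         call. = FALSE)
  B <- qr.coef(qrD, Y) # n_par x 3
  if (model == "affine") {
    offset <- B[1, ]
    A <- t(B[-1, , drop = FALSE])
  } else {
    offset <- c(0, 0, 0)
    A <- t(B)
  }
  if (abs(det(A)) < 1e-12)
    stop("fitted correction matrix is singular", call. = FALSE)
  corr <- structure(list(matrix = A, offset = unname(offset), model = model,
                         white_point = white_point),
                    class = "colour_correction")
  corrected <- apply_colour_correction(meas, corr, scale = "unit")
  lab_ref <- srgb_to_lab(ref, white_point = white_point)
  de_after <- delta_e(srgb_to_lab(corrected, white_point = white_point), lab_ref)
  de_before <- delta_e(srgb_to_lab(meas, white_point = white_point), lab_ref)
  corr$residual_deltaE <- de_after
  corr$rmse <- sqrt(mean(de_after^2))
  corr$mean_deltaE_before <- mean(de_before)
  corr$mean_deltaE_after <- mean(de_after)
  corr
}

#' @export
print.colour_correction <- function(x, ...) {
  cat("Colour correction (", x$model, ", fitted in linear RGB)\n", sep = "")
  cat("matrix:\n")
  print(round(x$matrix, 6))
  cat("offset:", format(round(x$offset, 6)), "\n")
  if (!is.null(x$mean_deltaE_after))
    cat(sprintf("mean Delta E*ab: %.3f before, %.3f after correction\n",
                x$mean_deltaE_before, x$mean_deltaE_after))
  invisible(x)
}

#' Apply a fitted colour correction
#'
#' Linearises the input, applies the fitted map, and recompands. Results
#' falling outside the channel range are clipped and flagged via a `"clipped"`
#' attribute. An identity correction returns the input to within one least
#' significant bit.
#'
#' @param x Colours (length-3 vector or n x 3 matrix) or a [sample_image()].
#' @param corr A `colour_correction` from [fit_colour_correction()].
#' @param scale Scale of `x` when it is a colour matrix.
#' @return Corrected colours of the same form as `x`.
#' @export
apply_colour_correction <- function(x, corr, scale = c("unit", "byte")) {
  stopifnot(inherits(corr, "colour_correction"))
  if (inherits(x, "sample_image")) {
    px <- x$pixels
    dm <- dim(px)
    flat <- matrix(px, ncol = 3L)
    out <- apply_colour_correction(flat, corr, scale = "unit")
    clipped <- attr(out, "clipped")
    x$pixels <- array(out, dim = dm)
    x$flags <- unique(c(x$flags, if (any(clipped)) "clipped"))
    return(x)
  }
  scale <- match.arg(scale)
  x <- .as_colour_matrix(x, "colour")
  v <- if (scale == "byte") x / 255 else x
  lin <- .srgb_decompand(v)
  lin <- lin %*% t(corr$matrix) +
    matrix(corr$offset, nrow(lin), 3L, byrow = TRUE)
  clipped <- rowSums(lin < -1e-9 | lin > 1 + 1e-9) > 0
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  out <- .srgb_compand(lin)
  out[out > 1] <- 1
  if (scale == "byte") out <- out * 255
  colnames(out) <- c("R", "G", "B")
  attr(out, "clipped") <- unname(clipped)
  out
}

#' @export
predict.colour_correction <- function(object, newdata, scale = c("unit", "byte"),
                                      ...) {
  apply_colour_correction(newdata, object, scale = scale)
}

#' Serialize a colour correction to JSON
#'
#' @param corr A `colour_correction`.
#' @param path File to write; if `NULL`, the JSON string is returned.
#' @return `path`, invisibly, or the JSON string.
#' @export
write_colour_correction <- function(corr, path = NULL) {
  stopifnot(inherits(corr, "colour_correction"))
  obj <- list(model = corr$model, matrix = corr$matrix, offset = corr$offset,
              white_point = corr$white_point,
              rmse = corr$rmse)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a colour correction from JSON
#'
#' @param path File written by [write_colour_correction()].
#' @return A `colour_correction`.
#' @export
read_colour_correction <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(matrix = matrix(unlist(obj$matrix), 3L, 3L),
                 offset = as.numeric(obj$offset), model = obj$model,
                 white_point = obj$white_point, rmse = obj$rmse),
            class = "colour_correction")
}
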