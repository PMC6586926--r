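# Segmentation of bone samples scanned on a white background, rim exclusion,
# and mean-colour measurement.
#
# Images are stored as height x width x 3 arrays of sRGB values on [0,1]
# together with their resolution in dots per inch; the dpi converts the
# physical rim width (mm) into an erosion radius (px).

#' Bone sample image
#'
#' Container for a scanned or photographed sample: an RGB pixel grid with its
#' resolution and colour-space tag.
#'
#' @param pixels Height x width x 3 numeric array of sRGB values in \[0,1\].
#' @param dpi Scan resolution in dots per inch (> 0).
#' @param colour_space Colour-space tag, default `"sRGB"`.
#' @param id Optional sample identifier.
#' @return An object of class `sample_image`.
#' @export
sample_image <- function(pixels, dpi, colour_space = "sRGB", id = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be a height x width x 3 array", call. = FALSE)
  if (any(dim(pixels)[1:2] == 0L))
    stop("image grid is empty", call. = FALSE)
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0)
    stop("dpi must be a single positive number", call. = FALSE)
  structure(list(pixels = pixels, dpi = dpi, colour_space = colour_space,
                 id = id, flags = character()),
            class = "sample_image")
}

#' @export
print.sample_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("sample_image %s: %d x %d px at %g dpi (%s)\n",
              if (is.null(x$id)) "" else x$id, d[1], d[2], x$dpi,
              x$colour_space))
  invisible(x)
}

#' Read a sample image from a TIFF or PNG file
#'
#' 8- and 16-bit RGB images are accepted and converted to floating point on
#' \[0,1\]. For TIFF files the resolution is taken from the file metadata when
#' present; a `dpi` argument overrides it and is required for PNG files
#' without one.
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param dpi Resolution in dots per inch; overrides file metadata.
#' @param id Optional sample identifier (defaults to the file name).
#' @return A [sample_image()].
#' @export
read_sample_image <- function(path, dpi = NULL, id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    if (is.null(dpi)) {
      xres <- attr(img, "x.resolution")
      unit <- attr(img, "resolution.unit")
      if (!is.null(xres)) {
        dpi <- if (!is.null(unit) && identical(unit, "cm")) xres * 2.54 else xres
      }
    }
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (is.null(dpi)) {
      info <- attr(img, "info")
      if (!is.null(info$dpi)) dpi <- info$dpi[1]
    }
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (is.null(dpi) || !is.finite(dpi))
    stop("resolution not found in file metadata; pass dpi explicitly",
         call. = FALSE)
  if (length(dim(img)) == 2L) # greyscale
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  sample_image(img, dpi = dpi, id = id)
}

#' Write a sample image to TIFF or PNG
#'
#' @param img A [sample_image()].
#' @param path Destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_sample_image <- function(img, path) {
  stopifnot(inherits(img, "sample_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img$pixels, path, reduce = TRUE,
                    compression = "none")
    # resolution metadata is not preserved by writeTIFF; callers keep dpi
  } else if (ext == "png") {
    png::writePNG(img$pixels, path, dpi = img$dpi)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  invisible(path)
}

.new_roi_mask <- function(mask, provenance) {
  structure(mask, class = c("roi_mask", class(mask)),
            provenance = provenance, n_pixels = sum(mask))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d x %d px, %d foreground\n",
              nrow(x), ncol(x), attr(x, "n_pixels")))
  invisible(x)
}

# Per-pixel L* as a matrix aligned with the image grid.
.pixel_lightness <- function(img) {
  flat <- matrix(img$pixels, ncol = 3L)
  matrix(srgb_to_lab(flat)[, "L"], dim(img$pixels)[1], dim(img$pixels)[2])
}

#' Segment a bone sample from its white background
#'
#' Thresholds per-pixel lightness against the bright background, keeps the
#' largest connected component and fills its holes. The default treats
#' L* > 90 as background; `method = "otsu"` derives the threshold from the
#' lightness histogram instead.
#'
#' @param img A [sample_image()] with a bright background.
#' @param bg_lightness_threshold Pixels with L* below this value are candidate
#'   foreground (default 90).
#' @param method `"threshold"` (default) or `"otsu"`.
#' @return An `roi_mask`: a logical matrix with segmentation provenance.
#' @export
segment_sample <- function(img, bg_lightness_threshold = 90,
                           method = c("threshold", "otsu")) {
  stopifnot(inherits(img, "sample_image"))
  method <- match.arg(method)
  Lmat <- .pixel_lightness(img)
  if (method == "otsu") {
    bg_lightness_threshold <- 100 * EBImage::otsu(Lmat / 100, range = c(0, 1))
  }
  fg <- Lmat < bg_lightness_threshold
  if (!any(fg))
    stop("empty ROI: no foreground pixels below L* = ",
         bg_lightness_threshold, call. = FALSE)
  labs <- EBImage::bwlabel(fg)
  counts <- tabulate(labs[labs > 0])
  keep <- which.max(counts)
  mask <- EBImage::fillHull(1L * (labs == keep)) > 0
  .new_roi_mask(mask, list(method = method,
                           bg_lightness_threshold = bg_lightness_threshold,
                           rim_mm = 0, erosion_px = 0L))
}

#' Import a manually drawn ROI mask
#'
#' For fidelity with manual region selection, a mask can be supplied as a PNG
#' (non-zero pixels are foreground) or a logical matrix.
#'
#' @param mask Path to a PNG file, or a logical/numeric matrix.
#' @param img Optional [sample_image()] to validate the mask shape against.
#' @return An `roi_mask`.
#' @export
import_roi_mask <- function(mask, img = NULL) {
  if (is.character(mask)) {
    m <- png::readPNG(mask)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    mask <- m > 0
  } else {
    mask <- mask > 0
  }
  if (!is.null(img) && !all(dim(mask) == dim(img$pixels)[1:2]))
    stop("mask shape does not match the image", call. = FALSE)
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  .new_roi_mask(mask, list(method = "manual", rim_mm = 0, erosion_px = 0L))
}

#' Exclude the outer rim of an ROI
#'
#' Morphological erosion of the mask by a Euclidean disk whose radius is the
#' physical rim width converted to pixels, `round(rim_mm * dpi / 25.4)`.
#' Excluding a 1-2 mm rim avoids overexposure and chromatic aberration at the
#' sample edge (and surface soot creeping over the edge); 1.5 mm is the
#' default.
#'
#' @param mask An `roi_mask`.
#' @param rim_mm Rim width to exclude, in millimetres (>= 0).
#' @param dpi Image resolution in dots per inch.
#' @param min_pixels Minimum acceptable ROI size after erosion (default 100).
#' @return The eroded `roi_mask` (a subset of the input mask).
#' @export
erode_rim <- function(mask, rim_mm = 1.5, dpi, min_pixels = 100) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!is.numeric(rim_mm) || rim_mm < 0)
    stop("rim_mm must be non-negative", call. = FALSE)
  prov <- attr(mask, "provenance")
  r <- as.integer(round(rim_mm * dpi / 25.4))
  if (r > 0L) {
    m <- unclass(mask)
    attributes(m) <- list(dim = dim(mask))
    dist <- EBImage::distmap(m * 1)
    eroded <- m & (dist > r)
  } else {
    eroded <- unclass(mask)
    attributes(eroded) <- list(dim = dim(mask))
  }
  n <- sum(eroded)
  if (n < min_pixels)
    stop(sprintf(
      "ROI too small after excluding a %.2g mm rim (%d px radius): %d px left of %d (minimum %d)",
      rim_mm, r, n, attr(mask, "n_pixels"), min_pixels), call. = FALSE)
  prov$rim_mm <- rim_mm
  prov$erosion_px <- r
  .new_roi_mask(eroded, prov)
}

#' Measure the mean colour of a masked sample
#'
#' Applies an optional colour correction, converts every masked pixel to
#' CIE L*a*b*, and returns the arithmetic mean RGB and the mean of the
#' per-pixel L*a*b* values (the convention of common image-analysis plugins;
#' on textured samples this differs from the Lab of the mean RGB).
#'
#' @param img A [sample_image()].
#' @param mask An `roi_mask` aligned with `img` (typically after
#'   [erode_rim()]).
#' @param corr Optional [fit_colour_correction()] result applied before
#'   measurement.
#' @param min_pixels Minimum mask size (default 100).
#' @return A `colour_measurement`: a one-row data.frame with columns
#'   `sample_id`, `n_pixels`, `red`, `green`, `blue` (byte scale), `L`, `A`,
#'   `B`, `rim_mm`, `flags`.
#' @export
measure_mean_colour <- function(img, mask, corr = NULL, min_pixels = 100) {
  stopifnot(inherits(img, "sample_image"), inherits(mask, "roi_mask"))
  if (!all(dim(mask) == dim(img$pixels)[1:2]))
    stop("mask shape does not match the image", call. = FALSE)
  n <- sum(mask)
  if (n == 0L) stop("empty ROI mask", call. = FALSE)
  flags <- img$flags
  if (n < min_pixels) flags <- c(flags, "too_small_roi")
  flat <- matrix(img$pixels, ncol = 3L)
  px <- flat[as.vector(mask), , drop = FALSE]
  if (!is.null(corr)) {
    px <- apply_colour_correction(px, corr, scale = "unit")
    if (any(attr(px, "clipped"))) flags <- c(flags, "clipped")
  }
  lab <- srgb_to_lab(px)
  mean_rgb <- colMeans(px) * 255
  mean_lab <- colMeans(lab)
  prov <- attr(mask, "provenance")
  structure(
    data.frame(sample_id = if (is.null(img$id)) NA_character_ else img$id,
               n_pixels = n,
               red = mean_rgb[1], green = mean_rgb[2], blue = mean_rgb[3],
               L = mean_lab["L"], A = mean_lab["A"], B = mean_lab["B"],
               rim_mm = prov$rim_mm,
               flags = paste(unique(flags), collapse = ";"),
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("colour_measurement", "data.frame"))
}

#' Measure a sample image end to end
#'
#' Convenience pipeline: segment, erode the rim, and measure.
#'
#' @inheritParams measure_mean_colour
#' @inheritParams erode_rim
#' @inheritParams segment_sample
#' @return A `colour_measurement`.
#' @export
measure_sample <- function(img, rim_mm = 1.5, corr = NULL,
                           bg_lightness_threshold = 90, min_pixels = 100) {
  mask <- segment_sample(img, bg_lightness_threshold)
  mask <- erode_rim(mask, rim_mm = rim_mm, dpi = img$dpi,
                    min_pixels = min_pixels)
  measure_mean_colour(img, mask, corr = corr, min_pixels = min_pixels)
}
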