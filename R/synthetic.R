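# Synthetic colour datasets and bone-slice images with the statistical
# structure of a heated-bone learning set: a temperature-dependent L*/B*
# trajectory (ivory -> brownish-black/carbonized -> grey -> calcined white)
# with small within-subgroup spread, small additive duration and medium
# effects, and a factorial temperature x duration x medium design.

# Default trajectory anchors. Each anchor mean lies inside the decision-model
# region of a cluster whose temperature range contains the anchor temperature,
# at a Euclidean distance of at least ~2.5 default noise standard deviations
# (sigma = 2) from every decision boundary — including the oblique calcined
# boundary L = -25 B + 200, whose steep slope makes it very sensitive to B*
# noise — so that generated subgroups classify overwhelmingly into that
# cluster. B* is non-increasing above 250 C and L* falls to the charring
# anchors then rises to calcination, mirroring the regression sign structure
# of real learning sets. Illustrative defaults, not measured values.
.default_anchors <- data.frame(
  temperature = c(20, 300, 500, 650, 800, 900),
  L = c(65, 25, 26, 58, 85, 92),
  A = c(6, 4, 1.5, 0.8, 0.3, 0.2),
  B = c(18, 17, 6, 1, -0.5, -1),
  cluster = c(1L, 2L, 3L, 5L, 6L, 6L)
)

#' Temperature-to-colour trajectory model
#'
#' Piecewise-linear interpolation between temperature anchors in L*a*b*, plus
#' Gaussian per-channel noise and small additive duration and medium shifts
#' (an order of magnitude below the temperature effect, so that temperature
#' dominates, as in real heated-bone data).
#'
#' @param anchors Data.frame with columns `temperature` (strictly increasing,
#'   degrees C), `L`, `A`, `B`, and optionally `cluster` (the cluster each
#'   anchor is expected to classify into).
#' @param sigma Per-channel noise standard deviation in Lab units (default 2,
#'   a small within-subgroup spread).
#' @param duration_coef Named vector: additive Lab shift per minute of
#'   exposure relative to `duration_ref` (defaults `L` -0.03, `B` -0.02, `A`
#'   0; longer exposure darkens slightly).
#' @param duration_ref Reference duration in minutes (default 20).
#' @param medium_shift Named vector added when the medium is adipose rather
#'   than air (defaults `L` +1, `B` +0.4: soft tissue slightly delays the
#'   colour change).
#' @return An object of class `trajectory_model`.
#' @export
trajectory_model <- function(anchors = .default_anchors, sigma = 2,
                             duration_coef = c(L = -0.03, A = 0, B = -0.02),
                             duration_ref = 20,
                             medium_shift = c(L = 1, A = 0.2, B = 0.4)) {
  if (!all(c("temperature", "L", "A", "B") %in% names(anchors)))
    stop("anchors need temperature, L, A, B columns", call. = FALSE)
  if (is.unsorted(anchors$temperature, strictly = TRUE))
    stop("anchor temperatures must be strictly increasing", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  structure(list(anchors = anchors, sigma = sigma,
                 duration_coef = duration_coef, duration_ref = duration_ref,
                 medium_shift = medium_shift),
            class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat("Heated-bone colour trajectory,", nrow(x$anchors), "anchors, sigma =",
      x$sigma, "\n")
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

# Noise-free mean Lab at given temperature/duration/medium.
.trajectory_mean <- function(model, temperature, duration, medium) {
  a <- model$anchors
  rng <- range(a$temperature)
  if (any(temperature < rng[1] | temperature > rng[2]))
    stop("temperature outside the anchor span [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  n <- max(length(temperature), length(duration), length(medium))
  temperature <- rep_len(temperature, n)
  duration <- rep_len(duration, n)
  medium <- rep_len(medium, n)
  out <- sapply(c("L", "A", "B"), function(ch) {
    base <- stats::approx(a$temperature, a[[ch]], xout = temperature)$y
    shift <- model$duration_coef[[ch]] * (duration - model$duration_ref) +
      model$medium_shift[[ch]] * (medium == "adipose")
    base + shift
  })
  if (n == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, c("L", "A", "B")))
  out
}

#' Draw synthetic colour values for a heated sample
#'
#' @param temperature Exposure temperature in degrees C, within the anchor
#'   span.
#' @param duration Exposure duration in minutes.
#' @param medium `"air"` or `"adipose"`.
#' @param n Number of draws.
#' @param model A [trajectory_model()].
#' @return An n x 3 matrix of L*, A*, B* values. Uses the R random number
#'   generator; fix the seed for reproducibility.
#' @export
sample_colour <- function(temperature, duration = 20, medium = "air", n = 1,
                          model = trajectory_model()) {
  stopifnot(inherits(model, "trajectory_model"))
  mu <- .trajectory_mean(model, temperature, duration, medium)
  if (nrow(mu) == 1L && n > 1L) mu <- mu[rep(1L, n), , drop = FALSE]
  out <- mu + matrix(stats::rnorm(length(mu), sd = model$sigma),
                     nrow(mu), 3L)
  out[, 1] <- pmin(pmax(out[, 1], 0), 100)
  colnames(out) <- c("L", "A", "B")
  out
}

#' Experimental design for synthetic datasets
#'
#' Defaults mirror a heated-bone learning set: temperatures spanning room
#' temperature to 900 C, exposure durations of 10-30 minutes, heating in air,
#' and 10 samples per temperature-duration subgroup. Heating in adipose tissue
#' is limited to 450 C (above that, autoignition makes the exposure
#' uncontrolled), so adipose combinations above 450 C are dropped.
#'
#' @param temperatures Temperature levels in degrees C.
#' @param durations Duration levels in minutes.
#' @param media Subset of `c("air", "adipose")`.
#' @param n_per_group Samples per temperature x duration x medium subgroup.
#' @param seed Optional integer seed, recorded in the generated dataset.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(temperatures = .default_anchors$temperature,
                        durations = c(10, 20, 30), media = "air",
                        n_per_group = 10, seed = NULL) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (!all(media %in% c("air", "adipose")))
    stop("media must be 'air' and/or 'adipose'", call. = FALSE)
  structure(list(temperatures = temperatures, durations = durations,
                 media = media, n_per_group = as.integer(n_per_group),
                 seed = seed),
            class = "design_spec")
}

#' Generate a synthetic colour dataset
#'
#' One record per draw, with sample metadata (skeletal element, sex, age
#' group) assigned uniformly at random — these variables have no colour
#' effect, matching the null finding in real heated-bone data. RGB columns are
#' derived from the Lab draw via [lab_to_srgb()].
#'
#' @param spec A [design_spec()].
#' @param model A [trajectory_model()].
#' @param role `"learning"` or `"test"`, recorded as an attribute.
#' @return A `colour_dataset`: a data.frame with columns `sample_id`,
#'   `temperature`, `duration`, `medium`, `element`, `sex`, `age_group`,
#'   `red`, `green`, `blue` (byte scale), `L`, `A`, `B`; attributes `role` and
#'   `seed`.
#' @export
generate_dataset <- function(spec = design_spec(), model = trajectory_model(),
                             role = c("learning", "test")) {
  stopifnot(inherits(spec, "design_spec"))
  role <- match.arg(role)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  grid <- expand.grid(temperature = spec$temperatures,
                      duration = spec$durations, medium = spec$media,
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$medium == "adipose" & grid$temperature > 450), ,
               drop = FALSE]
  grid <- grid[rep(seq_len(nrow(grid)), each = spec$n_per_group), ]
  n <- nrow(grid)
  lab <- sample_colour(grid$temperature, grid$duration, grid$medium,
                       n = n, model = model)
  rgb <- lab_to_srgb(lab, scale = "byte")
  ds <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                   temperature = grid$temperature, duration = grid$duration,
                   medium = grid$medium,
                   element = sample(c("radius", "ulna", "humerus"), n,
                                    replace = TRUE),
                   sex = sample(c("F", "M"), n, replace = TRUE),
                   age_group = sample(c("<60", "60-80", ">80"), n,
                                      replace = TRUE),
                   red = rgb[, "R"], green = rgb[, "G"], blue = rgb[, "B"],
                   L = lab[, "L"], A = lab[, "A"], B = lab[, "B"],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(ds, class = c("colour_dataset", "data.frame"), role = role,
            seed = spec$seed)
}

#' Read a per-sample colour dataset from CSV
#'
#' Accepts arbitrary column layouts via a mapping from the canonical names
#' (`sample_id`, `temperature`, `duration`, `medium`, `element`, `sex`,
#' `age_group`, `red`, `green`, `blue`, `L`, `A`, `B`) to the file's column
#' names, so that externally supplied tables (e.g. published supplementary
#' data) can be run through the statistics and validation pipeline.
#'
#' @param path CSV file path.
#' @param column_map Named character vector or list, `canonical = file_column`;
#'   unmapped canonical columns are taken verbatim when present.
#' @param role `"learning"` or `"test"`.
#' @return A `colour_dataset`.
#' @export
read_colour_dataset <- function(path, column_map = NULL,
                                role = c("learning", "test")) {
  role <- match.arg(role)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop("mapped column not in file: ", src, call. = FALSE)
      raw[[canon]] <- raw[[src]]
    }
  }
  structure(raw, class = c("colour_dataset", "data.frame"), role = role)
}

#' Write a colour dataset to CSV
#'
#' @param ds A `colour_dataset` or data.frame.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_colour_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' Render a synthetic bone-slice image
#'
#' An elliptical "transverse slice" of the given mean colour on a white
#' background, with optional per-pixel Gaussian Lab noise and an optional
#' contaminated rim of stated physical width (e.g. soot), the fixture for
#' testing rim-excluding measurement.
#'
#' @param mean_lab Length-3 L*a*b* mean colour of the slice interior.
#' @param radius_mm Semi-major axis in millimetres (default 4).
#' @param axis_ratio Semi-minor/semi-major axis ratio (default 1: a disk).
#' @param dpi Resolution (default 300).
#' @param noise_sigma Per-channel Lab noise standard deviation (default 0).
#' @param rim_lab Optional length-3 Lab colour of a contaminated rim.
#' @param rim_width_mm Physical width of the contaminated rim (default 1).
#' @param margin_px White margin around the ellipse (default 20).
#' @param id Optional sample id.
#' @return A [sample_image()].
#' @export
render_sample_image <- function(mean_lab, radius_mm = 4, axis_ratio = 1,
                                dpi = 300, noise_sigma = 0, rim_lab = NULL,
                                rim_width_mm = 1, margin_px = 20, id = NULL) {
  a <- radius_mm * dpi / 25.4
  b <- a * axis_ratio
  if (a * b <= 0) stop("ellipse area must be positive", call. = FALSE)
  h <- as.integer(2 * ceiling(b) + 2 * margin_px + 1)
  w <- as.integer(2 * ceiling(a) + 2 * margin_px + 1)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
  px <- array(1, dim = c(h, w, 3L)) # white background
  n_fg <- sum(inside)
  lab <- matrix(rep(as.numeric(mean_lab), each = n_fg), n_fg, 3L)
  if (!is.null(rim_lab)) {
    rim_px <- rim_width_mm * dpi / 25.4
    dist <- EBImage::distmap(inside * 1)
    rim <- (dist <= rim_px)[inside]
    lab[rim, ] <- matrix(rep(as.numeric(rim_lab), each = sum(rim)),
                         sum(rim), 3L)
  }
  if (noise_sigma > 0) {
    lab <- lab + matrix(stats::rnorm(length(lab), sd = noise_sigma), n_fg, 3L)
    lab[, 1] <- pmin(pmax(lab[, 1], 0), 100)
  }
  rgb <- lab_to_srgb(lab)
  flat <- matrix(px, ncol = 3L)
  flat[as.vector(inside), ] <- rgb
  sample_image(array(flat, dim = c(h, w, 3L)), dpi = dpi, id = id)
}

#' Render a synthetic colour chart image
#'
#' Lays the given patch colours out on a rectangular grid (row-major), the
#' fixture for end-to-end chart-calibration tests.
#'
#' @param colours n x 3 matrix of patch sRGB colours.
#' @param scale Scale of `colours` (`"unit"` or `"byte"`).
#' @param nrow,ncol Grid layout (defaults 4 x 6 for a 24-patch chart).
#' @param patch_px Patch side length in pixels (default 20).
#' @param dpi Resolution tag (default 300).
#' @return A [sample_image()].
#' @export
render_chart_image <- function(colours, scale = c("unit", "byte"), nrow = 4,
                               ncol = 6, patch_px = 20, dpi = 300) {
  scale <- match.arg(scale)
  colours <- .as_colour_matrix(colours, "colours")
  if (scale == "byte") colours <- colours / 255
  if (nrow(colours) != nrow * ncol)
    stop("need ", nrow * ncol, " patch colours", call. = FALSE)
  px <- array(0, dim = c(nrow * patch_px, ncol * patch_px, 3L))
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
    k <- (i - 1) * ncol + j
    rows <- ((i - 1) * patch_px + 1):(i * patch_px)
    cols <- ((j - 1) * patch_px + 1):(j * patch_px)
    for (ch in 1:3) px[rows, cols, ch] <- colours[k, ch]
  }
  sample_image(px, dpi = dpi, id = "chart")
}

#' Measure the patch colours of a chart image
#'
#' Means the central portion of each grid cell (row-major patch order),
#' trimming a border fraction to avoid patch-boundary pixels.
#'
#' @param img A [sample_image()] laid out as by [render_chart_image()].
#' @inheritParams render_chart_image
#' @param trim Fraction of each patch side trimmed from every edge
#'   (default 0.25).
#' @return n x 3 matrix of measured sRGB colours (unit scale).
#' @export
chart_patch_means <- function(img, nrow = 4, ncol = 6, trim = 0.25) {
  stopifnot(inherits(img, "sample_image"))
  d <- dim(img$pixels)
  ph <- d[1] / nrow
  pw <- d[2] / ncol
  out <- matrix(0, nrow * ncol, 3L, dimnames = list(NULL, c("R", "G", "B")))
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
    rows <- ceiling((i - 1) * ph + trim * ph):floor(i * ph - trim * ph)
    cols <- ceiling((j - 1) * pw + trim * pw):floor(j * pw - trim * pw)
    out[(i - 1) * ncol + j, ] <-
      apply(img$pixels[rows, cols, , drop = FALSE], 3, mean)
  }
  out
}
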