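#' Region-of-interest specification
#'
#' Rectangle or ellipse in (1-based) voxel coordinates of a 2D image/slice.
#'
#' @param name label used in reports.
#' @param shape `"rectangle"` or `"ellipse"`.
#' @param center length-2 voxel coordinates of the ROI center.
#' @param extents length-2 half-sizes in voxels (semi-axes for ellipses).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, shape = c("rectangle", "ellipse"), center, extents) {
  shape <- match.arg(shape)
  if (length(center) != 2L || length(extents) != 2L || any(extents <= 0))
    .stop_validation("center and extents must be length-2, extents > 0")
  structure(list(name = name, shape = shape, center = as.numeric(center),
                 extents = as.numeric(extents)), class = "roi_spec")
}

#' Logical mask of an ROI on a 2D grid
#'
#' @param roi an [roi_spec()].
#' @param dim image dimensions (length 2).
#' @return Logical matrix; errors if the ROI leaves the image or covers
#'   fewer than 4 pixels.
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "roi_spec"), length(dim) >= 2L)
  lo <- roi$center - roi$extents; hi <- roi$center + roi$extents
  if (any(lo < 0.5) || hi[1] > dim[1] + 0.5 || hi[2] > dim[2] + 0.5)
    .stop_validation("ROI '", roi$name, "' is not fully inside the image")
  X <- matrix(seq_len(dim[1]), dim[1], dim[2])
  Y <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  m <- if (roi$shape == "rectangle") {
    abs(X - roi$center[1]) <= roi$extents[1] &
      abs(Y - roi$center[2]) <= roi$extents[2]
  } else {
    ((X - roi$center[1]) / roi$extents[1])^2 +
      ((Y - roi$center[2]) / roi$extents[2])^2 <= 1
  }
  if (sum(m) < 4L) .stop_validation("ROI '", roi$name, "' covers < 4 pixels")
  m
}

.as_image <- function(image) {
  if (inherits(image, c("attenuation_map", "recon_image")))
    image <- image$values
  if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] != 1L)
      .stop_validation("metrics operate on 2D images or single slices")
    image <- image[, , 1L]
  }
  if (!is.matrix(image)) .stop_validation("expected a 2D image")
  image
}

#' Within-ROI normalized noise (coefficient of variation)
#'
#' The reference-free noise measure
#' `NRMSE = (1/mu) * sqrt( (1/N) * sum (x_i - mu)^2 )` over the ROI pixels,
#' where `mu` is the ROI mean and the variance is the population (1/N) form.
#' Despite the conventional name this is the within-ROI coefficient of
#' variation: it needs no reference image, is invariant to scaling the
#' pixels by a positive constant, and (deliberately, as a property of the
#' formula) changes under intensity offsets.
#'
#' @param image 2D matrix, single-slice [attenuation_map()] or `recon_image`.
#' @param roi an [roi_spec()].
#' @return Non-negative noise value; errors when the ROI mean is zero.
#' @examples
#' img <- matrix(c(1, 3, 1, 3), 2, 2)
#' nrmse(img, roi_spec("r", "rectangle", c(1.5, 1.5), c(1, 1))) # 0.5
#' @export
nrmse <- function(image, roi) {
  x <- .as_image(image)[roi_mask(roi, dim(.as_image(image)))]
  mu <- mean(x)
  if (mu == 0) stop("ROI mean is zero; the normalized noise is undefined",
                    call. = FALSE)
  sqrt(mean((x - mu)^2)) / mu
}

#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with a Gaussian window (sigma 1.5, 11 x 11 taps), standard
#' stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with dynamic range `L`
#' taken from the reference image, and nearest-edge padding. The local SSIM
#' map is averaged over the full image (minus a window-radius border) or
#' over an ROI.
#'
#' @param image,reference 2D matrices (or single-slice map objects) of equal
#'   shape; `reference` defines the dynamic range.
#' @param roi optional [roi_spec()] restricting the average.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param stabilizers length-2 `(K1, K2)` constants.
#' @param data_range dynamic range override; default `diff(range(reference))`.
#' @return SSIM value in [-1, 1]; 1 exactly for identical images.
#' @export
ssim <- function(image, reference, roi = NULL, sigma = 1.5,
                 stabilizers = c(0.01, 0.03), data_range = NULL) {
  x <- .as_image(image); y <- .as_image(reference)
  if (!all(dim(x) == dim(y)))
    .stop_validation("image and reference must have the same shape")
  if (is.null(data_range)) data_range <- diff(range(y))
  if (data_range <= 0) data_range <- 1
  radius <- as.integer(3.5 * sigma + 0.5)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  f <- function(z) .sepconv2(z, k)
  ux <- f(x); uy <- f(y)
  vx <- f(x * x) - ux * ux
  vy <- f(y * y) - uy * uy
  cxy <- f(x * y) - ux * uy
  C1 <- (stabilizers[1] * data_range)^2
  C2 <- (stabilizers[2] * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux * ux + uy * uy + C1) * (vx + vy + C2))
  keep <- matrix(FALSE, nrow(S), ncol(S))
  keep[(radius + 1):(nrow(S) - radius), (radius + 1):(ncol(S) - radius)] <- TRUE
  if (!is.null(roi)) keep <- keep & roi_mask(roi, dim(S))
  if (!any(keep)) .stop_validation("SSIM region is empty after border crop")
  mean(S[keep])
}

# Separable 2D convolution with nearest-edge (replicate) padding.
.sepconv2 <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  pad_rows <- function(m) m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), ,
                            drop = FALSE]
  conv_cols_of <- function(m) { # filter along dim 1
    mp <- pad_rows(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k))
      out <- out + k[t] * mp[t:(t + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv_cols_of(t(conv_cols_of(x))))
}

#' Extract a line profile
#'
#' @param image 2D matrix or single-slice map object.
#' @param axis `"row"` (values along a fixed first-axis index) or
#'   `"column"` (fixed second-axis index).
#' @param index 1-based index of the row/column.
#' @return Numeric vector of pixel values along the line.
#' @export
line_profile <- function(image, axis = c("row", "column"), index) {
  axis <- match.arg(axis)
  img <- .as_image(image)
  n <- if (axis == "row") nrow(img) else ncol(img)
  if (length(index) != 1L || !is.finite(index) || index != round(index) ||
      index < 1 || index > n)
    .stop_validation("index must be an integer in [1, ", n, "]")
  if (axis == "row") img[index, ] else img[, index]
}

#' Assemble an image-quality report
#'
#' Per-ROI pixel count, mean, and normalized noise; global and per-ROI SSIM
#' against a designated reference image; named line profiles.
#'
#' @param image 2D image under evaluation.
#' @param reference reference image for SSIM (same shape).
#' @param rois list of [roi_spec()].
#' @param profiles list of lists with `axis` and `index`.
#' @return A list (class `quality_report`) ready for JSON serialization.
#' @export
quality_report <- function(image, reference, rois = list(), profiles = list()) {
  img <- .as_image(image)
  roi_stats <- lapply(rois, function(r) {
    m <- roi_mask(r, dim(img))
    list(name = r$name, n = sum(m), mean = mean(img[m]),
         nrmse = nrmse(img, r),
         ssim = ssim(img, reference, roi = r))
  })
  profs <- lapply(profiles, function(p) {
    list(axis = p$axis, index = p$index,
         values = as.numeric(line_profile(img, p$axis, p$index)))
  })
  structure(list(rois = roi_stats, ssim_global = ssim(img, reference),
                 profiles = profs),
            class = "quality_report")
}

#' Write a quality report to JSON (and profiles to CSV)
#'
#' @param report a [quality_report()].
#' @param json_path JSON output path.
#' @param profiles_csv optional CSV path for the line profiles (long format).
#' @return `json_path`, invisibly.
#' @export
write_quality_report <- function(report, json_path, profiles_csv = NULL) {
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(profiles_csv) && length(report$profiles) > 0) {
    rows <- do.call(rbind, lapply(seq_along(report$profiles), function(i) {
      p <- report$profiles[[i]]
      data.frame(profile = i, axis = p$axis, index = p$index,
                 position = seq_along(p$values), value = p$values)
    }))
    write.csv(rows, profiles_csv, row.names = FALSE)
  }
  invisible(json_path)
}
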