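#' Calibrated 2D image
#'
#' Light container for a single-channel 2D image with physical pixel
#' calibration. Rows index y, columns index x; `dx`/`dy` are the pixel sizes
#' in micrometres. All image operators in the package accept and return this
#' class and are required to preserve the calibration.
#'
#' @param data numeric matrix of finite, non-negative intensities (rows = y).
#' @param dx,dy pixel size in micrometres, both > 0.
#' @return An object of class `image2d` with fields `data`, `dx`, `dy`.
#' @export
image2d <- function(data, dx, dy) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(dx) == 1L, length(dy) == 1L)
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("pixel sizes dx, dy must be positive and finite")
  if (any(!is.finite(data)))
    stop("image intensities must be finite")
  structure(list(data = data, dx = dx, dy = dy), class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d px (%.3g x %.3g um/px), range [%.4g, %.4g]\n",
              nrow(x$data), ncol(x$data), x$dx, x$dy,
              min(x$data), max(x$data)))
  invisible(x)
}

is_binary_image <- function(img) {
  inherits(img, "image2d") && all(img$data %in% c(0, 1))
}

#' Calibrated multi-channel image stack
#'
#' The universal input of the pipeline: a 4D voxel grid with dimensions
#' (y, x, z, channel), voxel calibration in micrometres, and unique ordered
#' channel names (e.g. `"Hoechst"`, `"Iba1"`, `"GFAP"`, `"Casp3"`,
#' `"Abeta"`, `"pTau"`). The default axial step is 0.5 um, the z-step used
#' for confocal acquisition of retinal slices.
#'
#' @param voxels 4D numeric array `(y, x, z, channel)`, finite, >= 0.
#' @param channels character vector of unique channel names, length =
#'   `dim(voxels)[4]`.
#' @param dx,dy lateral pixel size, um.
#' @param dz axial step, um (default 0.5).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, channels, dx, dy, dz = 0.5) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4L)
  if (length(channels) != dim(voxels)[4])
    stop("number of channel names must match the 4th dimension")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (any(c(dx, dy, dz) <= 0)) stop("voxel sizes must be positive")
  if (any(!is.finite(voxels))) stop("voxel intensities must be finite")
  dimnames(voxels) <- list(NULL, NULL, NULL, channels)
  structure(list(voxels = voxels, channels = as.character(channels),
                 dx = dx, dy = dy, dz = dz),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d px, %d slices, %d channels (%s)\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", ")))
  cat(sprintf("  voxel: %.3g x %.3g x %.3g um\n", x$dx, x$dy, x$dz))
  invisible(x)
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return 3D array (y, x, z).
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% stack$channels)
    stop(sprintf("unknown channel '%s'; stack has: %s", channel,
                 paste(stack$channels, collapse = ", ")))
  stack$voxels[, , , match(channel, stack$channels), drop = FALSE][, , , 1]
}

stack_sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.json")

#' Write a stack to multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...),
#' i.e. channels appear in their declared order. TIFF stores 32-bit floats in
#' \[0, 1\], so intensities are divided by a global scale factor recorded,
#' together with calibration and channel names, in a JSON sidecar named after
#' the TIFF.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  scale <- max(stack$voxels, 1e-12)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (ci in seq_len(d[4])) for (zi in seq_len(d[3])) {
    pages[[k]] <- stack$voxels[, , zi, ci] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(format_version = "1.0",
               channels = stack$channels, n_slices = d[3],
               dx = stack$dx, dy = stack$dy, dz = stack$dz,
               intensity_scale = scale)
  jsonlite::write_json(meta, stack_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated stack from TIFF
#'
#' Reads a multi-page TIFF written by [write_stack()] (calibration and
#' channel names taken from the JSON sidecar) or any plain multi-page TIFF,
#' in which case a calibration override `calibration = c(dx, dy, dz)` is
#' required and pages are interpreted as z-slices of the given `channels`
#' (default: one channel).
#'
#' @param path TIFF path.
#' @param calibration optional numeric `c(dx, dy, dz)` um, overriding or
#'   supplying missing metadata.
#' @param channels optional channel names for sidecar-less files.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, calibration = NULL, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("not a TIFF file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  side <- stack_sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  if (is.null(meta)) {
    if (is.null(calibration))
      stop("TIFF has no calibration sidecar; supply calibration = c(dx, dy, dz)")
    if (is.null(channels)) channels <- "ch1"
    nz <- length(pages) / length(channels)
    if (nz != round(nz)) stop("page count is not a multiple of channel count")
    scale <- 1
    dxyz <- calibration
  } else {
    channels <- meta$channels
    nz <- meta$n_slices
    scale <- meta$intensity_scale
    dxyz <- c(meta$dx, meta$dy, meta$dz)
    if (!is.null(calibration)) dxyz <- calibration
  }
  nc <- length(channels)
  d1 <- dim(pages[[1]])
  vox <- array(0, c(d1[1], d1[2], nz, nc))
  k <- 1L
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    vox[, , zi, ci] <- pages[[k]] * scale
    k <- k + 1L
  }
  image_stack(vox, channels, dxyz[1], dxyz[2], dxyz[3])
}

#' Maximum-intensity projection of one channel
#'
#' Collapses the z axis by the per-pixel maximum, the projection applied to
#' every z-series before 2D analysis. Calibration (dx, dy) is carried over.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return An [image2d()].
#' @export
max_projection <- function(stack, channel) {
  arr <- get_channel(stack, channel)
  proj <- arr[, , 1]
  nz <- dim(arr)[3]
  if (nz > 1) for (zi in 2:nz) proj <- pmax(proj, arr[, , zi])
  image2d(proj, stack$dx, stack$dy)
}

#' Despeckle: 3x3 median filter
#'
#' Removes single-pixel background fluorescence before binarization, the
#' conventional "de-speckle" step. Uses a 3x3 median with replicate padding
#' at the borders.
#'
#' @param img an [image2d()].
#' @return Filtered [image2d()].
#' @export
despeckle <- function(img) {
  stopifnot(inherits(img, "image2d"))
  image2d(median_filter_3x3(img$data), img$dx, img$dy)
}

#' Otsu threshold from a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over the 255 cut points
#' of a 256-bin histogram spanning the intensity range. The returned value is
#' the upper edge of the optimal background bin, to be used with a strict
#' `>` comparison.
#'
#' @param values numeric vector of intensities.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  lo <- min(values); hi <- max(values)
  if (hi <= lo)
    stop("constant image: Otsu threshold undefined; use method = 'fixed'")
  nb <- 256L
  bin <- pmin(floor((values - lo) / (hi - lo) * nb) + 1L, nb)
  h <- as.numeric(tabulate(bin, nbins = nb))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nb))
  n <- w[nb]; mt <- mu[nb]
  w0 <- w[-nb]; w1 <- n - w0
  m0 <- mu[-nb] / w0
  m1 <- (mt - mu[-nb]) / w1
  bc <- w0 * w1 * (m0 - m1)^2
  bc[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(bc) # last full background bin
  lo + (hi - lo) * k / nb
}

#' Robust background threshold (median + k * MAD)
#'
#' Threshold for sparse punctate signal over a dominant background: the
#' background level and spread are estimated robustly by the median and the
#' median absolute deviation, and the threshold set `k` MADs above the
#' median. Unlike Otsu, this stays above the noise when a channel contains
#' no real signal at all, so an empty channel yields no detections.
#'
#' @param values numeric intensities.
#' @param k number of MADs above the median (default 8).
#' @return Scalar threshold.
#' @export
robust_threshold <- function(values, k = 8) {
  v <- as.numeric(values)
  # median/MAD on a deterministic stride subsample; quantile estimates are
  # insensitive to this and it avoids sorting tens of millions of voxels
  if (length(v) > 500000L) v <- v[seq.int(1L, length(v), length.out = 500000L)]
  med <- median(v)
  med + k * mad(v, center = med)
}

#' Convert an image to binary
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold. With `method = "otsu"` the threshold is computed from a 256-bin
#' histogram of the image; a constant image is an error (use a fixed
#' threshold instead). With `method = "fixed"` the caller supplies
#' `threshold`, preserving the manual-threshold workflow used for GFAP.
#'
#' @param img an [image2d()].
#' @param method `"otsu"`, `"fixed"`, or `"robust"` (see
#'   [robust_threshold()]).
#' @param threshold numeric, required for `method = "fixed"`.
#' @return A binary [image2d()] with values in \{0, 1\}.
#' @export
binarize <- function(img, method = c("otsu", "fixed", "robust"),
                     threshold = NULL) {
  stopifnot(inherits(img, "image2d"))
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsu_threshold(img$data),
    robust = robust_threshold(img$data),
    fixed = {
      if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
      threshold
    })
  out <- image2d((img$data > thr) * 1, img$dx, img$dy)
  attr(out, "threshold") <- thr
  out
}

#' Foreground area fraction
#'
#' Fraction of foreground pixels over the image, or over a region of
#' interest when `roi` is given; this is the astrogliosis readout (area
#' occupied by fluorescent processes over total area).
#'
#' @param binary a binary [image2d()].
#' @param roi optional logical/0-1 matrix of the same shape.
#' @return Fraction in \[0, 1\].
#' @export
area_fraction <- function(binary, roi = NULL) {
  stopifnot(inherits(binary, "image2d"))
  if (!is_binary_image(binary)) stop("area_fraction expects a binary image")
  fg <- binary$data > 0
  if (is.null(roi)) return(sum(fg) / length(fg))
  roi <- roi > 0
  if (!identical(dim(roi), dim(fg))) stop("roi shape must match the image")
  n <- sum(roi)
  if (n == 0) stop("empty roi")
  sum(fg & roi) / n
}

#' Percentile contrast stretch
#'
#' Optional enhancement used before skeleton analysis to make faint distal
#' processes visible: intensities are linearly rescaled so that the `lower`
#' and `upper` percentiles map to 0 and the original maximum. Off by default
#' in quantitative branches.
#'
#' @param img an [image2d()].
#' @param lower,upper percentiles in \[0, 100\], default 0.1 and 99.9.
#' @return Stretched [image2d()].
#' @export
contrast_stretch <- function(img, lower = 0.1, upper = 99.9) {
  stopifnot(inherits(img, "image2d"), lower < upper)
  q <- quantile(img$data, c(lower, upper) / 100, names = FALSE)
  if (q[2] <= q[1]) return(img)
  out <- (pmin(pmax(img$data, q[1]), q[2]) - q[1]) / (q[2] - q[1]) * max(img$data)
  image2d(out, img$dx, img$dy)
}

#' 2D connected-component labelling
#'
#' 8-connected labelling of a logical/0-1 matrix; thin wrapper over the
#' package's union-find labeller (the 2D case of the 26-connected 3D one).
#'
#' @param mask logical or 0/1 matrix.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask) {
  m <- mask > 0
  lab <- label_components_3d(as.logical(m), nrow(m), ncol(m), 1L)
  matrix(lab, nrow(m), ncol(m))
}
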