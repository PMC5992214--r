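#' Microglia density per cubic millimetre
#'
#' The cell count of one field divided by slice area times slice thickness,
#' scaled by 1e9 to convert um^3 to mm^3.
#'
#' @param n_cells cell count (>= 0).
#' @param field_area_um2 field area, um^2 (> 0).
#' @param thickness_um slice thickness, um (> 0).
#' @return Density in cells/mm^3.
#' @export
cell_density <- function(n_cells, field_area_um2, thickness_um) {
  if (any(field_area_um2 <= 0) || any(thickness_um <= 0))
    stop("field area and thickness must be positive")
  if (any(n_cells < 0)) stop("cell count must be non-negative")
  n_cells / (field_area_um2 * thickness_um) * 1e9
}

#' Positive cells as a percentage of ganglion neurons
#'
#' @param n_positive caspase-3-positive count.
#' @param n_total_ganglion total ganglion neurons in the slice (> 0).
#' @return Percentage in \[0, 100\].
#' @export
positive_fraction <- function(n_positive, n_total_ganglion) {
  if (any(n_total_ganglion <= 0)) stop("total ganglion count must be positive")
  if (any(n_positive > n_total_ganglion))
    stop("positive count exceeds total ganglion count")
  if (any(n_positive < 0)) stop("positive count must be non-negative")
  100 * n_positive / n_total_ganglion
}

#' Count caspase-3-positive ganglion neurons
#'
#' Detects caspase-3 puncta on the despeckled maximum projection of the
#' caspase channel (binarize, label, centroid) and marks a ganglion neuron
#' positive iff at least one punctum centroid lies within `radius_um` of its
#' nucleus centroid — the perinuclear-localization rule.
#'
#' @param stack an [image_stack()] containing the caspase channel.
#' @param nuclei data frame with columns `x_um`, `y_um` of ganglion nucleus
#'   centroids (e.g. ground truth, or centroids from a TUJ1 segmentation).
#' @param channel caspase channel name (default `"Casp3"`).
#' @param radius_um proximity radius, um (default 5).
#' @param method,threshold binarization, passed to [binarize()]; the
#'   default `"robust"` background threshold keeps an all-background
#'   channel at zero detections.
#' @return Integer count, with attribute `positive` = logical per nucleus.
#' @export
count_positive_cells <- function(stack, nuclei, channel = "Casp3",
                                 radius_um = 5, method = "robust",
                                 threshold = NULL) {
  proj <- despeckle(max_projection(stack, channel))
  if (nrow(nuclei) == 0) return(structure(0L, positive = logical()))
  if (max(proj$data) == min(proj$data)) {
    # empty channel: no puncta
    pos <- rep(FALSE, nrow(nuclei))
    return(structure(0L, positive = pos))
  }
  bin <- binarize(proj, method = method, threshold = threshold)
  lab <- label_components(bin$data)
  n <- max(lab)
  pos <- rep(FALSE, nrow(nuclei))
  if (n > 0) {
    w <- which(lab > 0, arr.ind = TRUE)
    cx <- tapply((w[, 2] - 0.5) * proj$dx, lab[lab > 0], mean)
    cy <- tapply((w[, 1] - 0.5) * proj$dy, lab[lab > 0], mean)
    for (i in seq_len(nrow(nuclei))) {
      d <- sqrt((cx - nuclei$x_um[i])^2 + (cy - nuclei$y_um[i])^2)
      pos[i] <- any(d <= radius_um)
    }
  }
  structure(sum(pos), positive = pos)
}

#' Detect protein aggregates in 3D
#'
#' Thresholds the chosen channel (one global threshold computed from the
#' whole channel and applied to every slice; the default `"robust"`
#' median + 8 MAD background threshold returns nothing on an all-background
#' channel, `"otsu"` uses the 256-bin histogram), labels foreground voxels
#' as 26-connected 3D components, converts
#' voxel counts to um^3 volumes and equivalent spherical diameters
#' `(6 V / pi)^(1/3)`, and removes components whose equivalent diameter
#' falls below the channel's minimum-diameter floor — 0.58 um for
#' amyloid-beta, 0.68 um for pTau by default.
#'
#' @param stack calibrated [image_stack()].
#' @param channel channel name.
#' @param method `"robust"`, `"otsu"` or `"fixed"`.
#' @param threshold for `method = "fixed"`.
#' @param min_diameter_um floor on the equivalent spherical diameter;
#'   `NULL` picks the channel default (0.58 Abeta / 0.68 pTau / 0 other).
#' @return Data frame of `AggregateRecord`s: label, n_vox, volume_um3,
#'   equiv_diameter_um, x_um, y_um, z_um; attribute `n_unfiltered` holds
#'   the component count before the diameter floor.
#' @export
detect_aggregates <- function(stack, channel,
                              method = c("robust", "otsu", "fixed"),
                              threshold = NULL, min_diameter_um = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  arr <- get_channel(stack, channel)
  if (is.null(min_diameter_um))
    min_diameter_um <- switch(channel, Abeta = 0.58, pTau = 0.68, 0)
  empty <- data.frame(label = integer(), n_vox = integer(),
                      volume_um3 = numeric(), equiv_diameter_um = numeric(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric())
  attr(empty, "n_unfiltered") <- 0L
  if (max(arr) == min(arr)) return(empty) # empty channel
  thr <- switch(method,
    otsu = otsu_threshold(arr),
    robust = robust_threshold(arr),
    fixed = { if (is.null(threshold)) stop("fixed method requires threshold"); threshold })
  mask <- arr > thr
  d <- dim(arr)
  lab <- label_components_3d(as.logical(mask), d[1], d[2], d[3])
  k <- max(lab)
  if (k == 0) return(empty)
  vox_vol <- stack$dx * stack$dy * stack$dz
  sel <- lab > 0
  li <- lab[sel]
  pos <- which(sel) - 1L
  z <- pos %/% (d[1] * d[2]); r <- pos %% (d[1] * d[2])
  x <- r %/% d[1]; y <- r %% d[1]
  n_vox <- tabulate(li, nbins = k)
  rec <- data.frame(
    label = seq_len(k),
    n_vox = n_vox,
    volume_um3 = n_vox * vox_vol,
    equiv_diameter_um = (6 * n_vox * vox_vol / pi)^(1 / 3),
    x_um = as.numeric(tapply((x + 0.5) * stack$dx, li, mean)),
    y_um = as.numeric(tapply((y + 0.5) * stack$dy, li, mean)),
    z_um = as.numeric(tapply((z + 0.5) * stack$dz, li, mean)))
  out <- rec[rec$equiv_diameter_um >= min_diameter_um, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unfiltered") <- k
  out
}

#' Assign an aggregate to a retinal layer
#'
#' The centroid's y coordinate decides the band: IL or OL, given the
#' horizontal layer boundaries (from ground truth or a per-field annotation
#' file).
#'
#' @param records data frame from [detect_aggregates()] (needs `y_um`).
#' @param boundaries named list of `c(ymin, ymax)` bands, e.g.
#'   `list(IL = c(0, 80), OL = c(80, 160))`.
#' @return `records` with a `layer` column added.
#' @export
assign_layer <- function(records, boundaries) {
  stopifnot(is.list(boundaries), length(boundaries) >= 1)
  layer_of <- function(y) {
    for (nm in names(boundaries)) {
      b <- boundaries[[nm]]
      if (y >= b[1] && y < b[2]) return(nm)
    }
    # allow the top edge of the last band
    last <- boundaries[[length(boundaries)]]
    if (y == last[2]) return(names(boundaries)[length(boundaries)])
    stop(sprintf("aggregate centroid y = %.2f um lies outside all layer bands", y))
  }
  records$layer <- if (nrow(records)) vapply(records$y_um, layer_of, "") else character()
  records
}

#' Measure one field end to end
#'
#' Computes the field-level biomarker panel from a stack: microglia density
#' (count of segmented Iba1 cells over field volume), caspase-3-positive
#' percentage of ganglion neurons, GFAP area fraction, and per-channel
#' aggregate records with layer assignment.
#'
#' @param stack an [image_stack()] with the standard channels.
#' @param nuclei ganglion nucleus centroids (see [count_positive_cells()]);
#'   usually the generator's ground truth or a segmentation of a
#'   TUJ1/Hoechst channel.
#' @param boundaries layer bands for [assign_layer()].
#' @param config parameter list; see [default_config()]. Only the
#'   `quantify` entries are used.
#' @return List with `measurement` (one-row data frame: n_microglia,
#'   microglia_density_mm3, caspase_pct, gfap_fraction, n_abeta, n_ptau)
#'   and `aggregates` (records of both channels with a `channel` column).
#' @export
summarize_field <- function(stack, nuclei, boundaries,
                            config = default_config()) {
  q <- config$quantify
  d <- dim(stack$voxels)
  area <- d[1] * d[2] * stack$dx * stack$dy
  thick <- d[3] * stack$dz

  iba <- despeckle(max_projection(stack, "Iba1"))
  n_mg <- if (max(iba$data) > min(iba$data)) {
    cells <- segment_cells(iba, min_area_um2 = q$min_cell_area_um2)
    length(cells)
  } else 0L
  dens <- cell_density(n_mg, area, thick)

  casp <- count_positive_cells(stack, nuclei, radius_um = q$caspase_radius_um)
  casp_pct <- if (nrow(nuclei)) positive_fraction(as.integer(casp), nrow(nuclei)) else 0

  gf <- despeckle(max_projection(stack, "GFAP"))
  gfap_frac <- if (max(gf$data) > min(gf$data))
    area_fraction(binarize(gf, method = "otsu")) else 0

  aggs <- list()
  for (chn in c("Abeta", "pTau")) {
    rec <- detect_aggregates(stack, chn,
                             min_diameter_um = q$min_diameter_um[[chn]])
    if (nrow(rec)) {
      rec <- assign_layer(rec, boundaries)
      rec$channel <- chn
      aggs[[chn]] <- rec
    }
  }
  aggs <- if (length(aggs)) do.call(rbind, aggs) else
    cbind(assign_layer(detect_aggregates(stack, "Abeta"), boundaries)[0, ],
          channel = character())
  rownames(aggs) <- NULL

  list(measurement = data.frame(
         n_microglia = n_mg,
         microglia_density_mm3 = dens,
         caspase_pct = casp_pct,
         gfap_fraction = gfap_frac,
         n_abeta = sum(aggs$channel == "Abeta"),
         n_ptau = sum(aggs$channel == "pTau")),
       aggregates = aggs)
}
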