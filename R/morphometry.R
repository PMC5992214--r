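#' Segment whole microglia from a despeckled projection
#'
#' Binarizes the projection, labels 8-connected components, discards
#' components below a minimum area, and flags components touching the image
#' border. Border-touching cells are kept in the list (they still count for
#' density) but are excluded from per-cell morphometry, mirroring the rule
#' that only cells whose body and processes are fully contained in the
#' field are analyzed.
#'
#' @param projection despeckled [image2d()].
#' @param min_area_um2 minimum component area in um^2 (default 30).
#' @param method,threshold passed to [binarize()]; the default `"robust"`
#'   background threshold handles the sparse-foreground regime (a few
#'   cells on a large dark field) where Otsu's criterion collapses onto
#'   the soma/process contrast.
#' @return List of `cell_mask` objects: `mask` (logical matrix), `bbox`
#'   (ymin, ymax, xmin, xmax in px), `area_um2`, `border_touching`, `dx`,
#'   `dy`, `id`.
#' @export
segment_cells <- function(projection, min_area_um2 = 30,
                          method = "robust", threshold = NULL) {
  stopifnot(inherits(projection, "image2d"))
  bin <- binarize(projection, method = method, threshold = threshold)
  lab <- label_components(bin$data)
  n <- max(lab)
  if (n == 0) return(list())
  px_area <- projection$dx * projection$dy
  nr <- nrow(lab); nc <- ncol(lab)
  out <- list()
  id <- 0L
  for (k in seq_len(n)) {
    sel <- lab == k
    area <- sum(sel) * px_area
    if (area < min_area_um2) next
    w <- which(sel, arr.ind = TRUE)
    id <- id + 1L
    out[[id]] <- structure(list(
      id = id,
      mask = sel,
      bbox = c(ymin = min(w[, 1]), ymax = max(w[, 1]),
               xmin = min(w[, 2]), xmax = max(w[, 2])),
      area_um2 = area,
      border_touching = any(w[, 1] %in% c(1L, nr)) || any(w[, 2] %in% c(1L, nc)),
      dx = projection$dx, dy = projection$dy), class = "cell_mask")
  }
  out
}

#' Soma area of one cell
#'
#' Automated surrogate for the manual freehand outline of the cell body:
#' the soma is the bright intensity mode of the cell (Iba1 somata image
#' brighter than processes), so the in-mask intensities are split by Otsu's
#' criterion and the bright class taken as the soma core; the largest
#' connected core component is morphologically closed and its pixel count
#' converted to um^2. A cell of uniform intensity (no contrast to split)
#' falls back to the whole mask. Alternatively a fixed in-mask intensity
#' quantile can be requested via `core_quantile`; note that a quantile
#' threshold shifts with the soma-to-process pixel ratio, which varies
#' strongly with ramification, so the bimodal split is the default.
#'
#' @param projection intensity [image2d()] (same grid the mask came from).
#' @param cell a `cell_mask` from [segment_cells()].
#' @param core_quantile optional in-mask intensity quantile defining the
#'   soma core instead of the Otsu split (e.g. 0.9); default `NA` = Otsu.
#' @return Soma area, um^2, with attribute `center_um` = c(x, y).
#' @export
soma_area <- function(projection, cell, core_quantile = NA) {
  stopifnot(inherits(projection, "image2d"), inherits(cell, "cell_mask"))
  vals <- projection$data[cell$mask]
  thr <- if (is.na(core_quantile)) {
    if (max(vals) <= min(vals)) min(vals) else otsu_threshold(vals)
  } else quantile(vals, core_quantile, names = FALSE)
  core <- cell$mask & projection$data >= thr
  if (!any(core)) stop(sprintf("cell %d: empty soma core at quantile %.2f",
                               cell$id, core_quantile))
  lab <- label_components(core)
  sizes <- tabulate(lab[lab > 0])
  core <- lab == which.max(sizes)
  core <- EBImage::closing(core, EBImage::makeBrush(5, "disc")) > 0
  w <- which(core, arr.ind = TRUE)
  area <- sum(core) * cell$dx * cell$dy
  attr(area, "center_um") <- c(x = (mean(w[, 2]) - 0.5) * cell$dx,
                               y = (mean(w[, 1]) - 0.5) * cell$dy)
  area
}

# shoelace polygon area of the convex hull of 2D points (um^2)
convex_hull_area <- function(xy) {
  if (nrow(xy) < 3) return(0)
  h <- chull(xy)
  if (length(h) < 3) return(0)
  x <- xy[h, 1]; y <- xy[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Arborization (scanning-domain) area
#'
#' Area of the polygon circumscribed by the distal ends of the processes,
#' automated as the convex hull of the skeleton endpoints. Fewer than three
#' endpoints (or a collinear set) give 0.
#'
#' @param graph a [build_skeleton_graph()] result.
#' @return Area in um^2.
#' @export
arborization_area <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  convex_hull_area(graph$endpoints_um)
}

#' Morphological index
#'
#' Ratio of the arborization area to the soma area; decreases as microglia
#' de-ramify during disease progression.
#'
#' @param arborization_area_um2,soma_area_um2 areas in um^2; soma must be > 0.
#' @return Dimensionless ratio.
#' @export
morphological_index <- function(arborization_area_um2, soma_area_um2) {
  if (any(soma_area_um2 <= 0)) stop("soma area must be positive")
  arborization_area_um2 / soma_area_um2
}

#' Full morphometry of one cell
#'
#' Skeletonizes the cell mask, builds the skeleton graph, measures soma and
#' arborization areas and assembles one morphometry record. `n_primary` is
#' the number of branches leaving the soma core region (primary processes),
#' reported alongside the total branch count.
#'
#' @param projection intensity [image2d()].
#' @param cell a `cell_mask`; must not be border-touching.
#' @param core_quantile passed to [soma_area()] (default NA = in-mask Otsu split).
#' @return One-row data frame: cell_id, soma_area_um2, arborization_area_um2,
#'   morphological_index, n_branches, n_primary, n_endpoints, n_junctions,
#'   n_triple_junctions, total_length_um.
#' @export
analyze_cell <- function(projection, cell, core_quantile = NA) {
  stopifnot(inherits(cell, "cell_mask"))
  if (cell$border_touching)
    stop(sprintf("cell %d touches the field border and must be excluded", cell$id))
  skel <- skeletonize(cell$mask)
  g <- build_skeleton_graph(skel, dx = cell$dx, dy = cell$dy)
  soma <- soma_area(projection, cell, core_quantile)
  ctr <- attr(soma, "center_um")
  soma_r <- sqrt(as.numeric(soma) / pi)
  arb <- arborization_area(g)
  # primary processes: branches with an end at a node within the soma region
  n_primary <- 0L
  if (g$n_branches > 0) {
    node_xy <- rbind(g$endpoints_um, g$junctions_um)
    near <- which(sqrt((node_xy[, 1] - ctr["x"])^2 +
                       (node_xy[, 2] - ctr["y"])^2) <= soma_r + 1)
    n_primary <- sum(g$branches$from %in% near | g$branches$to %in% near)
  }
  data.frame(cell_id = cell$id,
             soma_area_um2 = as.numeric(soma),
             arborization_area_um2 = arb,
             morphological_index = morphological_index(arb, as.numeric(soma)),
             n_branches = g$n_branches,
             n_primary = n_primary,
             n_endpoints = g$n_endpoints,
             n_junctions = g$n_junctions,
             n_triple_junctions = g$n_triple_junctions,
             total_length_um = g$total_length_um)
}

#' Morphometry of every fully-contained cell in a projection
#'
#' Despeckles (optionally contrast-stretches) the projection, segments
#' cells, and returns one record per non-border-touching cell.
#'
#' @param projection raw [image2d()] Iba1 projection.
#' @param min_area_um2 passed to [segment_cells()].
#' @param core_quantile passed to [soma_area()] (default NA = in-mask Otsu split).
#' @param enhance apply [contrast_stretch()] first (default FALSE).
#' @return Data frame of [analyze_cell()] records (possibly 0 rows) with
#'   attribute `n_cells_total` = all segmented cells including border
#'   touchers.
#' @export
analyze_field_morphometry <- function(projection, min_area_um2 = 30,
                                      core_quantile = NA, enhance = FALSE) {
  img <- if (enhance) contrast_stretch(projection) else projection
  img <- despeckle(img)
  cells <- segment_cells(img, min_area_um2 = min_area_um2)
  keep <- Filter(function(cc) !cc$border_touching, cells)
  recs <- lapply(keep, function(cc) analyze_cell(projection, cc, core_quantile))
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(cell_id = integer(), soma_area_um2 = numeric(),
               arborization_area_um2 = numeric(), morphological_index = numeric(),
               n_branches = integer(), n_primary = integer(),
               n_endpoints = integer(), n_junctions = integer(),
               n_triple_junctions = integer(), total_length_um = numeric())
  attr(out, "n_cells_total") <- length(cells)
  out
}
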