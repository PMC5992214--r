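#' Parameters for one synthetic microglia
#'
#' Ramified microglia are modelled as recursive bifurcating trees grown
#' radially from the soma: each of `n_primary` primary processes owns an
#' angular wedge of the cell; a process tip at depth `d < max_depth`
#' bifurcates with probability `branch_prob` into two children confined to
#' the two halves of the parent wedge, which guarantees that subtrees never
#' cross and that the rendered topology equals the bookkept one. Segment
#' lengths shrink geometrically with depth.
#'
#' @param n_primary number of primary processes (0 = soma only).
#' @param max_depth maximum branching depth (1 = unbranched primaries).
#' @param branch_prob probability that a non-terminal tip bifurcates.
#' @param seg_len_um mean segment length, um.
#' @param seg_len_sd_um sd of segment length, um.
#' @param len_decay child-segment length multiplier per depth.
#' @param soma_radius_um soma disk radius, um.
#' @param thickness_px stroke thickness of processes, pixels.
#' @param intensity process fluorescence, arbitrary units.
#' @param soma_intensity_factor soma brightness relative to processes.
#' @return List of class `cell_params`.
#' @export
cell_params <- function(n_primary = 4, max_depth = 2, branch_prob = 0.6,
                        seg_len_um = 7, seg_len_sd_um = 1, len_decay = 0.85,
                        soma_radius_um = 3, thickness_px = 3,
                        intensity = 1, soma_intensity_factor = 2) {
  stopifnot(n_primary >= 0, max_depth >= 1, branch_prob >= 0, branch_prob <= 1,
            seg_len_um > 0, soma_radius_um > 0, thickness_px >= 1)
  structure(as.list(environment()), class = "cell_params")
}

# Sample the centerline tree of one cell in um coordinates centred on the
# soma. Returns segments (one row per edge) and the exact topology counts of
# the contracted graph (degree-2 soma suppressed).
sample_cell_tree <- function(params) {
  p <- params
  segs <- list()
  n_tip <- 0L; n_bif <- 0L
  if (p$n_primary > 0) {
    rot <- runif(1, 0, 2 * pi)
    wedge_full <- 2 * pi / p$n_primary
    wedge <- wedge_full * 0.8
    for (k in seq_len(p$n_primary)) {
      ctr <- rot + (k - 1) * wedge_full
      # queue entries: Cartesian start point, radius of the start point,
      # wedge centre angle, wedge half-width, depth
      queue <- list(list(x = 0, y = 0, r = 0, a = ctr, w = wedge / 2, d = 0))
      while (length(queue)) {
        nd <- queue[[1]]; queue <- queue[-1]
        len <- max(2, rnorm(1, p$seg_len_um * p$len_decay^nd$d,
                            p$seg_len_sd_um))
        r2 <- nd$r + len
        a2 <- if (nd$d == 0) nd$a else nd$a + runif(1, -0.25, 0.25) * nd$w
        x2 <- r2 * cos(a2); y2 <- r2 * sin(a2)
        segs[[length(segs) + 1L]] <- c(
          x0 = nd$x, y0 = nd$y, x1 = x2, y1 = y2, depth = nd$d + 1)
        if (nd$d + 1 < p$max_depth && runif(1) < p$branch_prob) {
          n_bif <- n_bif + 1L
          hw <- nd$w / 2
          queue <- c(queue,
                     list(list(x = x2, y = y2, r = r2,
                               a = a2 - hw / 2 - runif(1, 0.05, 0.2) * hw,
                               w = hw * 0.85, d = nd$d + 1),
                          list(x = x2, y = y2, r = r2,
                               a = a2 + hw / 2 + runif(1, 0.05, 0.2) * hw,
                               w = hw * 0.85, d = nd$d + 1)))
        } else {
          n_tip <- n_tip + 1L
        }
      }
    }
  }
  segs <- if (length(segs)) as.data.frame(do.call(rbind, segs)) else
    data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
               depth = numeric())
  np <- p$n_primary
  counts <- if (np == 0) {
    list(n_branches = 0L, n_endpoints = 0L, n_junctions = 0L,
         n_triple_junctions = 0L)
  } else {
    list(n_branches = nrow(segs) - (np == 2),
         n_endpoints = n_tip + (np == 1),
         n_junctions = n_bif + (np >= 3),
         n_triple_junctions = n_bif + (np == 3))
  }
  c(list(segments = segs), counts)
}

# Stamp a thick line segment (um endpoints) onto a matrix; pixel (i, j)
# centre is at ((j - 0.5) dx, (i - 0.5) dy). Sets value where the distance
# to the segment is <= halfwidth.
stamp_segment <- function(mat, x0, y0, x1, y1, halfwidth_um, value, dx, dy) {
  nr <- nrow(mat); nc <- ncol(mat)
  jmin <- max(1L, floor((min(x0, x1) - halfwidth_um) / dx)); jmax <- min(nc, ceiling((max(x0, x1) + halfwidth_um) / dx) + 1L)
  imin <- max(1L, floor((min(y0, y1) - halfwidth_um) / dy)); imax <- min(nr, ceiling((max(y0, y1) + halfwidth_um) / dy) + 1L)
  if (jmin > jmax || imin > imax) return(mat)
  jj <- jmin:jmax; ii <- imin:imax
  px <- outer(rep(1, length(ii)), (jj - 0.5) * dx)
  py <- outer((ii - 0.5) * dy, rep(1, length(jj)))
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx * vx + vy * vy
  t <- if (L2 == 0) 0 else pmin(pmax(((px - x0) * vx + (py - y0) * vy) / L2, 0), 1)
  d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
  sub <- mat[ii, jj, drop = FALSE]
  hit <- d2 <= halfwidth_um^2
  sub[hit] <- pmax(sub[hit], value)
  mat[ii, jj] <- sub
  mat
}

stamp_disk <- function(mat, cx, cy, radius_um, value, dx, dy) {
  stamp_segment(mat, cx, cy, cx, cy, radius_um, value, dx, dy)
}

#' Generate one synthetic microglia patch with exact ground truth
#'
#' Samples a bifurcating process tree, renders soma disk and processes at
#' the requested stroke thickness onto a square patch, and returns the
#' raster together with a `CellSpec` whose branch/endpoint/junction/triple-
#' junction counts are the exact topology of the emitted centerline tree.
#'
#' @param params a [cell_params()] list.
#' @param patch_size_um side of the square patch, um.
#' @param dx,dy pixel size, um (default 0.1).
#' @param seed integer seed for this cell.
#' @return List with `patch` (intensity matrix), `spec` (list of class
#'   `cell_spec`: soma centre/radius, `segments` in patch um coordinates,
#'   the four topology counts, intensity), `dx`, `dy`.
#' @export
generate_cell <- function(params = cell_params(), patch_size_um = 60,
                          dx = 0.1, dy = 0.1, seed = 1) {
  stopifnot(inherits(params, "cell_params"))
  set.seed(seed)
  tree <- sample_cell_tree(params)
  half <- patch_size_um / 2
  hw <- params$thickness_px * dx / 2
  segs <- tree$segments
  if (nrow(segs)) {
    lim <- half - hw - dx
    out_of_bounds <- with(segs, pmax(abs(x0), abs(x1), abs(y0), abs(y1))) > lim
    if (any(out_of_bounds))
      stop(sprintf("segment %d exceeds the patch bounds (|coord| > %.2f um); enlarge patch_size_um",
                   which(out_of_bounds)[1], lim))
    segs$x0 <- segs$x0 + half; segs$x1 <- segs$x1 + half
    segs$y0 <- segs$y0 + half; segs$y1 <- segs$y1 + half
  }
  n <- round(patch_size_um / dx)
  patch <- matrix(0, n, n)
  if (nrow(segs))
    for (k in seq_len(nrow(segs)))
      patch <- stamp_segment(patch, segs$x0[k], segs$y0[k], segs$x1[k], segs$y1[k],
                             hw, params$intensity, dx, dy)
  patch <- stamp_disk(patch, half, half, params$soma_radius_um,
                      params$intensity * params$soma_intensity_factor, dx, dy)
  spec <- structure(list(
    soma_center_um = c(x = half, y = half),
    soma_radius_um = params$soma_radius_um,
    segments = segs,
    n_branches = tree$n_branches,
    n_endpoints = tree$n_endpoints,
    n_junctions = tree$n_junctions,
    n_triple_junctions = tree$n_triple_junctions,
    intensity = params$intensity,
    border_touching = FALSE), class = "cell_spec")
  list(patch = patch, spec = spec, dx = dx, dy = dy)
}
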