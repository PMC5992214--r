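#' Specification of one synthetic confocal field
#'
#' Describes everything [generate_field()] needs to render a multi-channel
#' retinal field: geometry and voxel calibration, microglia content (number
#' of cells and their [cell_params()]), ganglion nuclei with a Bernoulli
#' cleaved-caspase-3 mark, a GFAP target area fraction, per-channel
#' aggregate lists, and the noise model (Poisson shot noise on the signal
#' plus Gaussian background). The field is split by a horizontal boundary
#' into an inner (IL, low y) and outer (OL) band; ganglion nuclei live in
#' the IL band. The default axial step is 0.5 um and the default lateral
#' pixel 0.1 um.
#'
#' @param size_um field side lengths c(x, y), um.
#' @param nz number of z slices.
#' @param dx,dy,dz voxel size, um.
#' @param n_microglia number of microglia.
#' @param microglia_params a [cell_params()] shared by the field's cells.
#' @param n_primary_sd per-cell jitter (sd) on the number of primaries.
#' @param n_ganglion number of ganglion nuclei (IL band).
#' @param caspase_p Bernoulli probability that a ganglion neuron is
#'   caspase-3 positive.
#' @param gfap_fraction target GFAP area fraction in \[0, 1\].
#' @param aggregates data frame with columns `channel` ("Abeta"/"pTau"),
#'   `layer` ("IL"/"OL"), `r_um` (sphere radius); one row per aggregate.
#' @param il_fraction fraction of the y extent belonging to the IL band.
#' @param photon_scale Poisson photon scale (0 disables shot noise).
#' @param bg_mean,bg_sd Gaussian background parameters (0 disables).
#' @param min_separation_um minimum distance between microglia somata;
#'   placements violating it after rejection sampling trigger a warning.
#' @param seed integer seed; all randomness derives from it via
#'   counter-based seed splitting, so per-object draws are independent of
#'   iteration order.
#' @return List of class `field_spec`.
#' @export
field_spec <- function(size_um = c(100, 100), nz = 6, dx = 0.1, dy = 0.1,
                       dz = 0.5, n_microglia = 4,
                       microglia_params = cell_params(),
                       n_primary_sd = 0.7,
                       n_ganglion = 30, caspase_p = 0.05,
                       gfap_fraction = 0.1,
                       aggregates = data.frame(channel = character(),
                                               layer = character(),
                                               r_um = numeric()),
                       il_fraction = 0.5,
                       photon_scale = 20, bg_mean = 0.05, bg_sd = 0.02,
                       min_separation_um = NULL, seed = 1) {
  stopifnot(length(size_um) == 2, all(size_um > 0), nz >= 1,
            dx > 0, dy > 0, dz > 0,
            gfap_fraction >= 0, gfap_fraction <= 1,
            caspase_p >= 0, caspase_p <= 1)
  if (nrow(aggregates) && !all(aggregates$layer %in% c("IL", "OL")))
    stop("every aggregate must have layer 'IL' or 'OL'")
  if (nrow(aggregates) && !all(aggregates$channel %in% c("Abeta", "pTau")))
    stop("aggregate channel must be 'Abeta' or 'pTau'")
  structure(as.list(environment()), class = "field_spec")
}

field_channels <- c("Hoechst", "Iba1", "GFAP", "Casp3", "Abeta", "pTau")

# conservative estimate of a cell's maximal radial extent, um
cell_extent_um <- function(p, n_primary_sd = 0) {
  reach <- p$soma_radius_um
  len <- p$seg_len_um + 2 * p$seg_len_sd_um
  for (d in seq_len(p$max_depth)) reach <- reach + len * p$len_decay^(d - 1)
  reach + 2
}

# best-candidate (Mitchell) sampling: each point is the candidate with the
# largest nearest-neighbour distance, giving an even spread; a warning is
# raised if even the best candidate violates the minimum separation
place_points <- function(n, xlim, ylim, min_sep, n_candidates = 60,
                         what = "objects") {
  xs <- numeric(0); ys <- numeric(0); clash <- FALSE
  for (k in seq_len(n)) {
    cx <- runif(n_candidates, xlim[1], xlim[2])
    cy <- runif(n_candidates, ylim[1], ylim[2])
    if (!length(xs)) {
      best <- 1L
    } else {
      dmin <- vapply(seq_len(n_candidates), function(i)
        min(sqrt((xs - cx[i])^2 + (ys - cy[i])^2)), numeric(1))
      best <- which.max(dmin)
      if (dmin[best] < min_sep) clash <- TRUE
    }
    xs <- c(xs, cx[best]); ys <- c(ys, cy[best])
  }
  if (clash) warning(sprintf("could not separate all %s by %.1f um; overlaps possible",
                             what, min_sep))
  cbind(x = xs, y = ys)
}

# render a (possibly anisotropic-voxel) sphere into a 3D array; returns the
# array and the exact voxel count
stamp_sphere <- function(arr, cx, cy, cz, r_um, value, dx, dy, dz) {
  d <- dim(arr)
  ii <- max(1L, floor((cy - r_um) / dy)):min(d[1], ceiling((cy + r_um) / dy) + 1L)
  jj <- max(1L, floor((cx - r_um) / dx)):min(d[2], ceiling((cx + r_um) / dx) + 1L)
  kk <- max(1L, floor((cz - r_um) / dz)):min(d[3], ceiling((cz + r_um) / dz) + 1L)
  py <- (ii - 0.5) * dy; px <- (jj - 0.5) * dx; pz <- (kk - 0.5) * dz
  n_vox <- 0L
  for (k in kk) {
    z2 <- (pz[k - kk[1] + 1] - cz)^2
    if (z2 > r_um^2) next
    r2d <- outer((py - cy)^2, (px - cx)^2, "+")
    hit <- r2d + z2 <= r_um^2
    if (any(hit)) {
      sl <- arr[ii, jj, k]
      sl[hit] <- pmax(sl[hit], value)
      arr[ii, jj, k] <- sl
      n_vox <- n_vox + sum(hit)
    }
  }
  attr(arr, "n_vox") <- n_vox
  arr
}

#' Render one synthetic field and its ground truth
#'
#' Deterministic for a fixed spec and seed. Channels are rendered in the
#' fixed order Hoechst, Iba1, GFAP, Casp3, Abeta, pTau; with noise disabled
#' (`photon_scale = 0`, `bg_mean = bg_sd = 0`) the binary support of each
#' channel equals the ground-truth mask.
#'
#' @param spec a [field_spec()].
#' @return List with `stack` (an [image_stack()]) and `truth`, a
#'   `ground_truth` list: per-cell `cell_spec`s with placements, microglia /
#'   ganglion / caspase-positive counts, ganglion nuclei table, realized
#'   GFAP fraction, aggregate table with exact voxelized volumes, and the
#'   IL/OL layer boundaries in um.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  sx <- spec$size_um[1]; sy <- spec$size_um[2]
  nx <- round(sx / spec$dx); ny <- round(sy / spec$dy)
  nz <- spec$nz
  # channels rendered as separate 3D arrays; per-slice planes are extracted
  # once, stamped repeatedly, and written back once. Channels that stay
  # empty are left NULL and materialized only on assembly.
  chan <- setNames(vector("list", length(field_channels)), field_channels)
  touch <- function(nm) {
    if (is.null(chan[[nm]])) chan[[nm]] <<- array(0, c(ny, nx, nz))
  }
  for (nm in c("Hoechst", "Iba1", "GFAP", "Casp3")) touch(nm)
  il_y <- spec$il_fraction * sy
  mid_z <- ceiling(nz / 2)

  # --- microglia (Iba1) ------------------------------------------------
  p0 <- spec$microglia_params
  extent <- cell_extent_um(p0)
  min_sep <- if (is.null(spec$min_separation_um)) 2 * extent + 2 else
    spec$min_separation_um
  cells <- list()
  if (spec$n_microglia > 0) {
    set.seed(rng_child_seed(spec$seed, 1))
    margin <- min(extent + 1, min(sx, sy) / 2 - 1)
    pos <- place_points(spec$n_microglia, c(margin, sx - margin),
                        c(margin, sy - margin), min_sep, what = "somata")
    zc <- sample(seq_len(nz), spec$n_microglia, replace = TRUE)
    for (i in seq_len(spec$n_microglia)) {
      set.seed(rng_child_seed(spec$seed, 100 + i))
      pc <- p0
      if (spec$n_primary_sd > 0 && pc$n_primary > 0)
        pc$n_primary <- max(1L, min(8L, round(rnorm(1, p0$n_primary,
                                                    spec$n_primary_sd))))
      tree <- sample_cell_tree(pc)
      segs <- tree$segments
      if (nrow(segs)) {
        segs$x0 <- segs$x0 + pos[i, "x"]; segs$x1 <- segs$x1 + pos[i, "x"]
        segs$y0 <- segs$y0 + pos[i, "y"]; segs$y1 <- segs$y1 + pos[i, "y"]
      }
      hw <- pc$thickness_px * spec$dx / 2
      plane <- chan$Iba1[, , zc[i]]
      if (nrow(segs))
        for (k in seq_len(nrow(segs)))
          plane <- stamp_segment(plane, segs$x0[k], segs$y0[k],
                                 segs$x1[k], segs$y1[k], hw,
                                 pc$intensity, spec$dx, spec$dy)
      plane <- stamp_disk(plane, pos[i, "x"], pos[i, "y"], pc$soma_radius_um,
                          pc$intensity * pc$soma_intensity_factor,
                          spec$dx, spec$dy)
      chan$Iba1[, , zc[i]] <- plane
      # microglial nucleus in the Hoechst channel
      chan$Hoechst[, , zc[i]] <-
        stamp_disk(chan$Hoechst[, , zc[i]], pos[i, "x"], pos[i, "y"],
                   min(2, pc$soma_radius_um * 0.7), 1, spec$dx, spec$dy)
      br <- any(c(segs$x0, segs$x1) < hw | c(segs$x0, segs$x1) > sx - hw |
                c(segs$y0, segs$y1) < hw | c(segs$y0, segs$y1) > sy - hw)
      cells[[i]] <- structure(list(
        soma_center_um = c(x = unname(pos[i, "x"]), y = unname(pos[i, "y"])),
        soma_radius_um = pc$soma_radius_um,
        z_slice = zc[i],
        segments = segs,
        n_branches = tree$n_branches,
        n_endpoints = tree$n_endpoints,
        n_junctions = tree$n_junctions,
        n_triple_junctions = tree$n_triple_junctions,
        intensity = pc$intensity,
        border_touching = isTRUE(br)), class = "cell_spec")
    }
  }

  # --- ganglion nuclei (Hoechst) + caspase-3 puncta --------------------
  ganglion <- data.frame(x_um = numeric(), y_um = numeric(),
                         caspase_positive = logical())
  if (spec$n_ganglion > 0) {
    set.seed(rng_child_seed(spec$seed, 2))
    nuc_r <- 2.5
    gpos <- place_points(spec$n_ganglion, c(nuc_r + 1, sx - nuc_r - 1),
                         c(nuc_r + 1, max(il_y - nuc_r - 1, nuc_r + 2)),
                         min_sep = 10, what = "ganglion nuclei")
    pos_flag <- runif(spec$n_ganglion) < spec$caspase_p
    nuc_z <- unique(c(mid_z, min(mid_z + 1, nz)))
    nuc_planes <- lapply(nuc_z, function(z) chan$Hoechst[, , z])
    casp_plane <- chan$Casp3[, , mid_z]
    for (i in seq_len(spec$n_ganglion)) {
      for (zi in seq_along(nuc_z))
        nuc_planes[[zi]] <- stamp_disk(nuc_planes[[zi]], gpos[i, "x"],
                                       gpos[i, "y"], nuc_r, 1,
                                       spec$dx, spec$dy)
      if (pos_flag[i]) {
        n_pun <- sample(1:2, 1)
        for (q in seq_len(n_pun)) {
          ang <- runif(1, 0, 2 * pi); rad <- runif(1, 1, 2.5)
          casp_plane <- stamp_disk(casp_plane,
                                   min(max(gpos[i, "x"] + rad * cos(ang), 1), sx - 1),
                                   min(max(gpos[i, "y"] + rad * sin(ang), 1), sy - 1),
                                   0.5, 1, spec$dx, spec$dy)
        }
      }
    }
    for (zi in seq_along(nuc_z)) chan$Hoechst[, , nuc_z[zi]] <- nuc_planes[[zi]]
    chan$Casp3[, , mid_z] <- casp_plane
    ganglion <- data.frame(x_um = gpos[, "x"], y_um = gpos[, "y"],
                           caspase_positive = pos_flag)
  }

  # --- GFAP filaments to a target area fraction ------------------------
  gfap_realized <- 0
  if (spec$gfap_fraction > 0) {
    set.seed(rng_child_seed(spec$seed, 3))
    plane <- matrix(0, ny, nx)
    target_px <- spec$gfap_fraction * ny * nx
    it <- 0L; covered <- 0
    # recount coverage often enough that the overshoot stays well below
    # the +/- 0.02 fidelity band on the realized fraction
    seg_px <- 18 / (spec$dx * spec$dy)
    step <- max(1L, floor(0.004 * ny * nx / seg_px))
    while (covered < target_px && it < 20000L) {
      it <- it + 1L
      x0 <- runif(1, 0, sx); y0 <- runif(1, 0, sy)
      ang <- runif(1, 0, pi); len <- runif(1, 10, 30)
      plane <- stamp_segment(plane, x0, y0,
                             x0 + len * cos(ang), y0 + len * sin(ang),
                             0.45, 1, spec$dx, spec$dy)
      if (it %% step == 0L) covered <- sum(plane)
    }
    chan$GFAP[, , mid_z] <- plane
    gfap_realized <- sum(plane) / (ny * nx)
  }

  # --- aggregates (Abeta / pTau spheres) -------------------------------
  agg <- data.frame(channel = character(), layer = character(),
                    x_um = numeric(), y_um = numeric(), z_um = numeric(),
                    r_um = numeric(), n_vox = integer(), volume_um3 = numeric())
  if (nrow(spec$aggregates)) {
    set.seed(rng_child_seed(spec$seed, 4))
    placed <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(spec$aggregates))) {
      a <- spec$aggregates[i, ]
      r <- a$r_um
      ylim <- if (a$layer == "IL") c(r + 0.5, il_y - r - 0.5) else
        c(il_y + r + 0.5, sy - r - 0.5)
      for (t in 1:2000) {
        x <- runif(1, r + 0.5, sx - r - 0.5)
        y <- runif(1, ylim[1], max(ylim))
        if (!nrow(placed) ||
            min(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2)) >
              r + max(spec$aggregates$r_um) + 1) break
      }
      placed <- rbind(placed, c(x, y))
      touch(a$channel)
      zc <- min(max(r, nz * spec$dz / 2), nz * spec$dz - r)
      res <- stamp_sphere(chan[[a$channel]], x, y, zc, r, 1,
                          spec$dx, spec$dy, spec$dz)
      nvx <- attr(res, "n_vox"); attr(res, "n_vox") <- NULL
      chan[[a$channel]] <- res
      agg <- rbind(agg, data.frame(channel = a$channel, layer = a$layer,
                                   x_um = x, y_um = y, z_um = zc, r_um = r,
                                   n_vox = nvx,
                                   volume_um3 = nvx * spec$dx * spec$dy * spec$dz))
    }
  }

  # --- noise (per channel, in the fixed channel order) and assembly ----
  if (spec$photon_scale > 0) {
    set.seed(rng_child_seed(spec$seed, 5))
    for (nm in field_channels) {
      if (is.null(chan[[nm]])) next
      nzv <- which(chan[[nm]] > 0)
      if (length(nzv))
        chan[[nm]][nzv] <- rpois(length(nzv), chan[[nm]][nzv] * spec$photon_scale) /
          spec$photon_scale
    }
  }
  vox <- array(0, c(ny, nx, nz, length(field_channels)))
  if (spec$bg_mean > 0 || spec$bg_sd > 0) {
    set.seed(rng_child_seed(spec$seed, 6))
    vox[] <- rnorm(length(vox), spec$bg_mean, spec$bg_sd)
  }
  for (ci in seq_along(field_channels)) {
    nm <- field_channels[ci]
    if (!is.null(chan[[nm]])) {
      sl <- vox[, , , ci] + chan[[nm]]
      vox[, , , ci] <- sl
    }
  }
  rm(chan)
  vox[vox < 0] <- 0

  truth <- structure(list(
    cells = cells,
    n_microglia = spec$n_microglia,
    n_ganglion_neurons = spec$n_ganglion,
    n_caspase_positive = sum(ganglion$caspase_positive),
    ganglion_nuclei = ganglion,
    gfap_fraction_target = spec$gfap_fraction,
    gfap_fraction_realized = gfap_realized,
    aggregates = agg,
    layer_boundaries = list(IL = c(0, il_y), OL = c(il_y, sy)),
    thickness_um = nz * spec$dz,
    seed = spec$seed), class = "ground_truth")

  list(stack = image_stack(vox, field_channels, spec$dx, spec$dy, spec$dz),
       truth = truth)
}

#' Write / read a ground-truth sidecar
#'
#' Serializes a `ground_truth` object to versioned JSON next to the field's
#' TIFF so measurement results can be benchmarked offline.
#'
#' @param truth a `ground_truth` list from [generate_field()].
#' @param path output JSON path.
#' @return `path` invisibly, or for the reader the `ground_truth` list.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- unclass(truth)
  out$cells <- lapply(out$cells, unclass)
  out$schema_version <- "1.0"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$ganglion_nuclei <- as.data.frame(x$ganglion_nuclei)
  x$aggregates <- as.data.frame(x$aggregates)
  x$cells <- lapply(x$cells, function(cc) {
    cc$segments <- as.data.frame(cc$segments)
    structure(cc, class = "cell_spec")
  })
  structure(x, class = "ground_truth")
}
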