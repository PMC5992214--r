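#' Skeletonize a binary image
#'
#' Homotopic medial-axis thinning (Guo-Hall two-subiteration algorithm,
#' 8-connected foreground). The result is one pixel wide, preserves the
#' number of connected components and any holes, and leaves an already-thin
#' line unchanged.
#'
#' @param mask binary [image2d()] or logical/0-1 matrix.
#' @return Same type as the input, skeletonized.
#' @export
skeletonize <- function(mask) {
  if (inherits(mask, "image2d")) {
    if (!is_binary_image(mask)) stop("skeletonize expects a binary image")
    return(image2d(thin_guo_hall(mask$data > 0) * 1, mask$dx, mask$dy))
  }
  thin_guo_hall(mask > 0)
}

# 8-neighbour linear offsets for an nr x nc matrix (column-major).
neighbour_offsets <- function(nr) c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)

#' Build the topological graph of a skeleton
#'
#' Classifies every skeleton pixel by its number of 8-connected skeleton
#' neighbours — endpoint (1), slab (2), junction (>= 3); isolated pixels (0)
#' form their own degenerate node — then merges 8-adjacent junction pixels
#' into single junction nodes and traces the maximal slab paths between node
#' terminals as branches. Branch lengths are the summed pixel-to-pixel step
#' lengths in micrometres. A triple junction is a junction node with exactly
#' three incident branches.
#'
#' Thinning a stroke several pixels wide can split what is topologically one
#' junction into two clusters bridged by a one-or-two-pixel slab path, or
#' leave a pixel-scale loop at an X-crossing. Junction-to-junction branches
#' (including self-loops) shorter than `merge_junctions_um` are therefore
#' contracted, fusing their end nodes; genuine inter-junction paths are far
#' longer than this scale in ramified cells. Set `merge_junctions_um = 0` to
#' disable.
#'
#' @param skel binary [image2d()] or logical/0-1 matrix, one pixel wide
#'   (a fully filled 3x3 block is an error; irreducible 2x2 junction blocks
#'   are merged into their junction node).
#' @param dx,dy pixel size um, taken from `skel` when it is an [image2d()].
#' @param merge_junctions_um contract junction-junction branches shorter
#'   than this (um, default 1).
#' @return Object of class `skeleton_graph`: list with `n_endpoints`,
#'   `n_junctions`, `n_branches`, `n_triple_junctions`, `total_length_um`,
#'   `branches` (data frame: from, to, n_steps, length_um), `endpoints_um`
#'   (matrix of endpoint x/y coordinates in um), `junctions_um`, and the
#'   pixel classification matrix `classes` (0 bg, 1 endpoint, 2 slab,
#'   3 junction, 4 isolated).
#' @export
build_skeleton_graph <- function(skel, dx = NULL, dy = NULL,
                                 merge_junctions_um = 1) {
  if (inherits(skel, "image2d")) {
    dx <- skel$dx; dy <- skel$dy
    m <- skel$data > 0
  } else {
    if (is.null(dx)) dx <- 1
    if (is.null(dy)) dy <- 1
    m <- skel > 0
  }
  nr <- nrow(m); nc <- ncol(m)
  # non-thin input guard: a pixel whose full 8-neighbourhood is set (i.e. a
  # filled 3x3 block) cannot occur in a thinned image. Filled 2x2 blocks are
  # tolerated: homotopic thinning provably cannot reduce an X-crossing whose
  # four incident branches each attach to a different block pixel, and such
  # blocks are junction pixels that merge into one junction node below.
  if (nr > 2 && nc > 2) {
    deg0 <- neighbour_count_8(m)
    if (any(m & deg0 == 8L)) {
      w <- which(m & deg0 == 8L, arr.ind = TRUE)[1, ]
      stop(sprintf("input is not one pixel wide: filled 3x3 block around (row %d, col %d)",
                   w[1], w[2]))
    }
  }
  deg <- neighbour_count_8(m)
  classes <- matrix(0L, nr, nc)
  classes[m & deg == 1] <- 1L
  classes[m & deg == 2] <- 2L
  classes[m & deg >= 3] <- 3L
  classes[m & deg == 0] <- 4L

  idx <- which(m)
  if (length(idx) == 0) {
    return(empty_skeleton_graph(classes, dx, dy))
  }

  # node ids: each endpoint its own node; junction pixels share their
  # 8-connected cluster's node id
  node_id <- matrix(0L, nr, nc)
  ep_idx <- which(classes == 1L)
  n_ep <- length(ep_idx)
  if (n_ep) node_id[ep_idx] <- seq_len(n_ep)
  jmask <- classes == 3L
  jlab <- if (any(jmask)) label_components(jmask) else matrix(0L, nr, nc)
  n_j <- max(jlab)
  if (n_j) node_id[jmask] <- n_ep + jlab[jmask]

  offs <- neighbour_offsets(nr)
  row_of <- function(i) ((i - 1L) %% nr) + 1L
  col_of <- function(i) ((i - 1L) %/% nr) + 1L
  nbrs <- function(i) {
    r <- row_of(i); cl <- col_of(i)
    cand <- i + offs
    keep <- c(r > 1, r < nr, cl > 1, cl < nc,
              r > 1 & cl > 1, r < nr & cl > 1, r > 1 & cl < nc, r < nr & cl < nc)
    cand <- cand[keep]
    cand[m[cand]]
  }
  step_um <- function(a, b) {
    sqrt(((row_of(a) - row_of(b)) * dy)^2 + ((col_of(a) - col_of(b)) * dx)^2)
  }

  terminal <- classes == 1L | classes == 3L
  visited <- matrix(FALSE, nr, nc) # slab pixels consumed by a trace
  branches <- list()
  add_branch <- function(from, to, n_steps, len) {
    branches[[length(branches) + 1L]] <<- c(from = from, to = to,
                                            n_steps = n_steps, length_um = len)
  }

  term_idx <- which(terminal)
  # deterministic order: lexicographic by linear (column-major) index
  for (t in sort(term_idx)) {
    for (nb in sort(nbrs(t))) {
      if (classes[nb] == 2L) {
        if (visited[nb]) next
        # walk the slab chain
        len <- step_um(t, nb); n_steps <- 1L
        prev <- t; cur <- nb
        visited[cur] <- TRUE
        repeat {
          if (terminal[cur]) break
          nxt <- nbrs(cur)
          nxt <- nxt[nxt != prev]
          # at a junction entrance a slab can touch several cluster pixels;
          # also drop terminals adjacent to prev already counted via prev
          if (length(nxt) > 1L) {
            tn <- nxt[terminal[nxt]]
            nxt <- if (length(tn)) min(tn) else min(nxt)
          } else if (length(nxt) == 0L) {
            break # dead-ends cannot happen on consistent skeletons
          } else {
            nxt <- nxt[1]
          }
          len <- len + step_um(cur, nxt); n_steps <- n_steps + 1L
          prev <- cur; cur <- nxt
          if (classes[cur] == 2L) {
            if (visited[cur]) break # closed slab loop back onto the chain
            visited[cur] <- TRUE
          }
        }
        if (terminal[cur]) {
          add_branch(node_id[t], node_id[cur], n_steps, len)
        } else {
          add_branch(node_id[t], node_id[t], n_steps, len) # loop
        }
      } else if (terminal[nb]) {
        # direct terminal-terminal adjacency; record once, skip intra-cluster
        if (node_id[nb] == node_id[t]) next
        if (nb > t) add_branch(node_id[t], node_id[nb], 1L, step_um(t, nb))
      }
    }
  }

  # pure slab cycles never touching a terminal
  left <- which(classes == 2L & !visited)
  while (length(left)) {
    start <- min(left)
    visited[start] <- TRUE
    len <- 0; n_steps <- 0L
    prev <- start; cur <- nbrs(start)[1]
    repeat {
      len <- len + step_um(prev, cur); n_steps <- n_steps + 1L
      if (cur == start) break
      visited[cur] <- TRUE
      nxt <- nbrs(cur); nxt <- nxt[nxt != prev]
      prev <- cur; cur <- nxt[1]
    }
    add_branch(0L, 0L, n_steps, len)
    left <- which(classes == 2L & !visited)
  }

  br <- if (length(branches)) as.data.frame(do.call(rbind, branches))
        else data.frame(from = integer(), to = integer(),
                        n_steps = integer(), length_um = numeric())

  # contract short junction-junction branches (thinning artifacts)
  if (merge_junctions_um > 0 && nrow(br)) {
    is_j <- function(id) id > n_ep
    parent <- seq_len(n_ep + n_j)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    repeat {
      f <- vapply(br$from, function(i) if (i >= 1) find(i) else 0L, numeric(1))
      t2 <- vapply(br$to, function(i) if (i >= 1) find(i) else 0L, numeric(1))
      short <- which(br$length_um < merge_junctions_um &
                     is_j(pmax(f, 1L)) & is_j(pmax(t2, 1L)) &
                     f > n_ep & t2 > n_ep)
      if (!length(short)) break
      k <- short[1]
      a <- f[k]; b <- t2[k]
      if (a != b) parent[max(a, b)] <- min(a, b)
      br <- br[-k, , drop = FALSE]
      if (!nrow(br)) break
    }
    if (nrow(br)) {
      br$from <- vapply(br$from, function(i) if (i >= 1) find(i) else i, numeric(1))
      br$to <- vapply(br$to, function(i) if (i >= 1) find(i) else i, numeric(1))
    }
    kept <- unique(c(br$from, br$to))
    n_j <- length(unique(vapply(which(jlab > 0), function(i) find(n_ep + jlab[i]), numeric(1))))
    # remap jlab to surviving representatives for centroid reporting
    if (n_j > 0) {
      reps <- sort(unique(vapply(seq_len(max(jlab)), function(j) find(n_ep + j), numeric(1))))
      newlab <- matrix(0L, nr, nc)
      for (i in which(jlab > 0))
        newlab[i] <- match(find(n_ep + jlab[i]), reps)
      jlab <- newlab
      remap <- function(i) if (i > n_ep) n_ep + match(find(i), reps) else i
      if (nrow(br)) {
        br$from <- vapply(br$from, function(i) if (i >= 1) remap(i) else i, numeric(1))
        br$to <- vapply(br$to, function(i) if (i >= 1) remap(i) else i, numeric(1))
      }
    }
  }

  # branch incidence per junction node
  n_nodes <- n_ep + n_j
  inc <- integer(n_nodes)
  if (nrow(br)) {
    for (k in seq_len(nrow(br))) {
      f <- br$from[k]; to <- br$to[k]
      if (f >= 1) inc[f] <- inc[f] + 1L
      if (to >= 1) inc[to] <- inc[to] + 1L
    }
  }
  j_ids <- if (n_j) n_ep + seq_len(n_j) else integer()
  n_triple <- sum(inc[j_ids] == 3L)

  to_um <- function(ii) {
    if (!length(ii)) return(cbind(x_um = numeric(), y_um = numeric()))
    cbind(x_um = (col_of(ii) - 0.5) * dx, y_um = (row_of(ii) - 0.5) * dy)
  }
  jcent <- if (n_j) {
    t(vapply(seq_len(n_j), function(j) colMeans(to_um(which(jlab == j))),
             numeric(2)))
  } else cbind(x_um = numeric(), y_um = numeric())

  structure(list(
    n_endpoints = n_ep,
    n_junctions = n_j,
    n_branches = nrow(br),
    n_triple_junctions = n_triple,
    total_length_um = sum(br$length_um),
    branches = br,
    endpoints_um = to_um(sort(ep_idx)),
    junctions_um = jcent,
    classes = classes,
    dx = dx, dy = dy
  ), class = "skeleton_graph")
}

empty_skeleton_graph <- function(classes, dx, dy) {
  structure(list(n_endpoints = 0L, n_junctions = 0L, n_branches = 0L,
                 n_triple_junctions = 0L, total_length_um = 0,
                 branches = data.frame(from = integer(), to = integer(),
                                       n_steps = integer(), length_um = numeric()),
                 endpoints_um = cbind(x_um = numeric(), y_um = numeric()),
                 junctions_um = cbind(x_um = numeric(), y_um = numeric()),
                 classes = classes, dx = dx, dy = dy),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d endpoints, %d junctions (%d triple), %d branches, %.2f um total\n",
              x$n_endpoints, x$n_junctions, x$n_triple_junctions,
              x$n_branches, x$total_length_um))
  invisible(x)
}
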