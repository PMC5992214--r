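# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force and must stay free of the package's own
# implementation paths.

# per-pixel loop maximum projection
oracle_max_projection <- function(arr3d) {
  out <- matrix(0, dim(arr3d)[1], dim(arr3d)[2])
  for (i in seq_len(dim(arr3d)[1]))
    for (j in seq_len(dim(arr3d)[2]))
      out[i, j] <- max(arr3d[i, j, ])
  out
}

# naive sliding-window 3x3 median with replicate padding
oracle_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- pmin(pmax(i + (-1:1), 1), nr)
    jj <- pmin(pmax(j + (-1:1), 1), nc)
    out[i, j] <- median(as.vector(m[ii, jj]))
  }
  out
}

# exhaustive search over the 255 cut points of a 256-bin histogram,
# maximizing between-class variance directly from the definition
oracle_otsu <- function(v) {
  lo <- min(v); hi <- max(v)
  nb <- 256L
  bin <- pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb)
  best <- -Inf; best_k <- 1L
  for (k in 1:(nb - 1)) {
    g0 <- v[bin <= k]; g1 <- v[bin > k]
    if (!length(g0) || !length(g1)) next
    bc <- length(g0) * length(g1) / length(v)^2 * (mean(g0) - mean(g1))^2
    if (bc > best) { best <- bc; best_k <- k }
  }
  lo + (hi - lo) * best_k / nb
}

# graph traversal of emitted centerline polylines: node degrees from the
# segment endpoint multiset, degree-2 nodes suppressed
oracle_tree_counts <- function(segments) {
  if (nrow(segments) == 0)
    return(list(n_endpoints = 0L, n_junctions = 0L, n_branches = 0L,
                n_triple_junctions = 0L))
  key <- function(x, y) paste(round(x, 6), round(y, 6))
  nodes <- c(key(segments$x0, segments$y0), key(segments$x1, segments$y1))
  deg <- table(nodes)
  list(n_endpoints = sum(deg == 1),
       n_junctions = sum(deg >= 3),
       n_branches = nrow(segments) - sum(deg == 2),
       n_triple_junctions = sum(deg == 3))
}

# gift-wrapping (Jarvis march) convex hull + shoelace, independent of chull
oracle_hull_area <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(xy[, 1] + 1e-9 * xy[, 2])
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p || r == q) next
      cr <- cross(xy[p, ], xy[q, ], xy[r, ])
      if (cr < 0 ||
          (abs(cr) < 1e-12 &&
           sum((xy[r, ] - xy[p, ])^2) > sum((xy[q, ] - xy[p, ])^2)))
        q <- r
    }
    p <- q
    if (p == start || length(hull) > n) break
  }
  if (length(hull) < 3) return(0)
  x <- xy[hull, 1]; y <- xy[hull, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# projection-matrix type II ANOVA oracle
oracle_anova_F <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  PB <- proj(model.matrix(~B)); PA <- proj(model.matrix(~A))
  PAB <- proj(model.matrix(~A + B)); PF <- proj(model.matrix(~A * B))
  qf <- function(P) as.numeric(t(y) %*% P %*% y)
  ss_a <- qf(PAB) - qf(PB)
  ss_b <- qf(PAB) - qf(PA)
  ss_i <- qf(PF) - qf(PAB)
  df_res <- length(y) - qr(model.matrix(~A * B))$rank
  ms_res <- (sum(y^2) - qf(PF)) / df_res
  c(genotype = ss_a / (nlevels(A) - 1) / ms_res,
    stage = ss_b / (nlevels(B) - 1) / ms_res,
    interaction = ss_i / ((nlevels(A) - 1) * (nlevels(B) - 1)) / ms_res)
}

# a tiny noise-free field spec used by several tests
quiet_field <- function(..., seed = 1) {
  field_spec(..., photon_scale = 0, bg_mean = 0, bg_sd = 0, seed = seed)
}
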