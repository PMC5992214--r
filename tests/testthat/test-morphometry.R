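make_projection <- function(cellgen) {
  image2d(cellgen$patch, cellgen$dx, cellgen$dy)
}

test_that("segmentation: blank image, a centered cell, and border-touching exclusion", {
  blank <- image2d(matrix(0, 50, 50), 0.5, 0.5)
  expect_length(segment_cells(blank, method = "fixed", threshold = 0), 0)

  cg <- generate_cell(cell_params(n_primary = 3, thickness_px = 3),
                      patch_size_um = 60, dx = 0.2, dy = 0.2, seed = 8)
  cells <- segment_cells(make_projection(cg), method = "fixed", threshold = 0)
  expect_length(cells, 1)
  expect_false(cells[[1]]$border_touching)

  # shift the same cell across the edge
  shifted <- cg$patch[, c(120:300, 1:119)]
  shifted[, 1] <- shifted[, 2] # ensure contact with column 1
  cut <- segment_cells(image2d(shifted, 0.2, 0.2), method = "fixed", threshold = 0)
  expect_true(any(vapply(cut, `[[`, TRUE, "border_touching")))
  btc <- Filter(function(x) x$border_touching, cut)[[1]]
  expect_error(analyze_cell(make_projection(cg), btc), "border")
})

test_that("soma area recovers an analytic disk and is local to the cell body", {
  cg <- generate_cell(cell_params(n_primary = 0, soma_radius_um = 3),
                      patch_size_um = 20, dx = 0.1, dy = 0.1, seed = 2)
  pr <- make_projection(cg)
  cell <- segment_cells(pr, method = "fixed", threshold = 0,
                        min_area_um2 = 10)[[1]]
  a <- soma_area(pr, cell)
  expect_equal(as.numeric(a), pi * 9, tolerance = 0.1)
  ctr <- attr(a, "center_um")
  expect_equal(unname(ctr), c(10, 10), tolerance = 0.5)

  # same soma, different trees: areas within 5%
  areas <- vapply(c(11, 12), function(s) {
    g <- generate_cell(cell_params(n_primary = 2 + s %% 3, soma_radius_um = 3,
                                   thickness_px = 4),
                       patch_size_um = 60, dx = 0.2, dy = 0.2, seed = s)
    p2 <- make_projection(g)
    cc <- segment_cells(p2, method = "fixed", threshold = 0)[[1]]
    as.numeric(soma_area(p2, cc))
  }, numeric(1))
  expect_lt(abs(diff(areas)) / mean(areas), 0.05)
})

test_that("arborization area: square hull, collinear degeneracy, and the gift-wrapping oracle", {
  sq <- structure(list(endpoints_um = cbind(x_um = c(0, 0, 10, 10),
                                            y_um = c(0, 10, 0, 10))),
                  class = "skeleton_graph")
  expect_equal(arborization_area(sq), 100)
  col <- structure(list(endpoints_um = cbind(x_um = c(0, 1, 2),
                                             y_um = c(0, 1, 2))),
                   class = "skeleton_graph")
  expect_equal(arborization_area(col), 0)
  set.seed(4)
  for (k in 1:5) {
    pts <- cbind(x_um = runif(10, 0, 40), y_um = runif(10, 0, 40))
    g <- structure(list(endpoints_um = pts), class = "skeleton_graph")
    expect_equal(arborization_area(g), oracle_hull_area(pts), tolerance = 1e-10)
  }
})

test_that("morphological index is the area ratio and errors on non-positive soma", {
  expect_equal(morphological_index(900, 45), 20)
  expect_equal(morphological_index(0, 30), 0)
  expect_error(morphological_index(10, 0), "positive")
})

test_that("analyze_cell composes the record, matches generator truth, and is deterministic", {
  soma_only <- generate_cell(cell_params(n_primary = 0), patch_size_um = 20,
                             dx = 0.1, dy = 0.1, seed = 3)
  pr <- make_projection(soma_only)
  cell <- segment_cells(pr, method = "fixed", threshold = 0,
                        min_area_um2 = 10)[[1]]
  rec <- analyze_cell(pr, cell)
  expect_equal(rec$n_branches, 0L)
  expect_equal(rec$morphological_index, 0)

  cg <- generate_cell(cell_params(n_primary = 4, max_depth = 2,
                                  branch_prob = 1, thickness_px = 4),
                      patch_size_um = 70, seed = 21)
  p2 <- make_projection(cg)
  c2 <- segment_cells(p2, method = "fixed", threshold = 0)[[1]]
  r1 <- analyze_cell(p2, c2)
  expect_equal(r1$n_branches, cg$spec$n_branches)
  expect_equal(r1$n_endpoints, cg$spec$n_endpoints)
  expect_equal(r1$n_junctions, cg$spec$n_junctions)
  expect_equal(r1$n_triple_junctions, cg$spec$n_triple_junctions)
  expect_gte(r1$n_primary, 1L)
  r2 <- analyze_cell(p2, c2)
  expect_identical(r1, r2)
})

test_that("mean morphological index separates high- from low-ramification presets", {
  high <- cell_params(n_primary = 5, max_depth = 3, branch_prob = 0.8,
                      thickness_px = 3)
  low <- cell_params(n_primary = 3, max_depth = 1, seg_len_um = 5,
                     thickness_px = 3)
  mi <- function(p, seeds) vapply(seeds, function(s) {
    g <- generate_cell(p, patch_size_um = 80, dx = 0.2, dy = 0.2, seed = s)
    pr <- make_projection(g)
    cc <- segment_cells(pr, method = "fixed", threshold = 0)[[1]]
    analyze_cell(pr, cc)$morphological_index
  }, numeric(1))
  expect_gt(mean(mi(high, 1:6)), mean(mi(low, 1:6)))
})
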