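test_that("generate_cell bookkeeping: soma-only, single process, and the graph-traversal oracle", {
  soma <- generate_cell(cell_params(n_primary = 0), seed = 7)
  expect_equal(soma$spec$n_branches, 0L)
  expect_equal(soma$spec$n_endpoints, 0L)
  expect_equal(soma$spec$n_junctions, 0L)

  one <- generate_cell(cell_params(n_primary = 1, max_depth = 1), seed = 1)
  expect_equal(one$spec$n_branches, 1L)
  expect_equal(one$spec$n_endpoints, 2L) # soma-side tip counted
  expect_equal(one$spec$n_junctions, 0L)

  four <- generate_cell(cell_params(n_primary = 4, max_depth = 2,
                                    branch_prob = 1), seed = 42)
  ora <- oracle_tree_counts(four$spec$segments)
  expect_equal(four$spec$n_branches, ora$n_branches)
  expect_equal(four$spec$n_endpoints, ora$n_endpoints)
  expect_equal(four$spec$n_junctions, ora$n_junctions)
  expect_equal(four$spec$n_triple_junctions, ora$n_triple_junctions)
})

test_that("emitted CellSpec counts match the polyline-graph oracle across random parameterizations", {
  for (s in 1:25) {
    p <- cell_params(n_primary = s %% 6, max_depth = 1 + s %% 3,
                     branch_prob = 0.7)
    cell <- generate_cell(p, patch_size_um = 90, seed = 100 + s)
    ora <- oracle_tree_counts(cell$spec$segments)
    expect_equal(cell$spec$n_endpoints, ora$n_endpoints, info = paste("seed", s))
    expect_equal(cell$spec$n_junctions, ora$n_junctions, info = paste("seed", s))
    expect_equal(cell$spec$n_branches, ora$n_branches, info = paste("seed", s))
    expect_equal(cell$spec$n_triple_junctions, ora$n_triple_junctions,
                 info = paste("seed", s))
    # degree-1/degree-3 trees: endpoints = triple junctions + 2 whenever the
    # soma itself is degree 1 or 3
    np <- if (nrow(cell$spec$segments)) sum(cell$spec$segments$depth == 1) else 0
    if (np %in% c(1, 3))
      expect_equal(cell$spec$n_endpoints, cell$spec$n_triple_junctions + 2L)
  }
})

test_that("out-of-bounds geometry errors name the offending segment", {
  expect_error(
    generate_cell(cell_params(n_primary = 4, seg_len_um = 40), patch_size_um = 40,
                  seed = 2),
    "segment [0-9]+ exceeds")
})

test_that("an empty noise-free field renders all-zero channels", {
  sp <- quiet_field(size_um = c(20, 20), nz = 3, n_microglia = 0,
                    n_ganglion = 0, gfap_fraction = 0)
  f <- generate_field(sp)
  expect_true(all(f$stack$voxels == 0))
  expect_equal(f$truth$n_microglia, 0)
  expect_equal(nrow(f$truth$aggregates), 0L)
})

test_that("identical spec and seed give voxelwise-identical stacks and ground truth", {
  sp <- field_spec(size_um = c(40, 40), nz = 3, dx = 0.25, dy = 0.25,
                   n_microglia = 2, n_ganglion = 8, caspase_p = 0.3,
                   gfap_fraction = 0.08,
                   aggregates = data.frame(channel = "Abeta", layer = "IL",
                                           r_um = 0.8),
                   seed = 33)
  f1 <- generate_field(sp); f2 <- generate_field(sp)
  expect_identical(f1$stack$voxels, f2$stack$voxels)
  expect_identical(f1$truth$aggregates, f2$truth$aggregates)
  expect_identical(f1$truth$ganglion_nuclei, f2$truth$ganglion_nuclei)
})

test_that("voxelized sphere volumes approach the analytic ball volume", {
  sp <- quiet_field(size_um = c(14, 14), nz = 8, dx = 0.1, dy = 0.1,
                    n_microglia = 0, n_ganglion = 0, gfap_fraction = 0,
                    aggregates = data.frame(channel = "Abeta", layer = "IL",
                                            r_um = rep(1, 3)),
                    il_fraction = 1, seed = 4)
  f <- generate_field(sp)
  expect_equal(nrow(f$truth$aggregates), 3L)
  expect_equal(f$truth$aggregates$volume_um3, rep(4 / 3 * pi, 3),
               tolerance = 0.2)
  expect_true(all(f$truth$aggregates$volume_um3 > 0))
})

test_that("noise-free channel support equals the ground-truth rendering and GFAP hits its target fraction", {
  sp <- quiet_field(size_um = c(50, 50), nz = 3, dx = 0.25, dy = 0.25,
                    n_microglia = 1, n_ganglion = 6, caspase_p = 1,
                    gfap_fraction = 0.25, seed = 9)
  f <- generate_field(sp)
  expect_lt(abs(f$truth$gfap_fraction_realized - 0.25), 0.02)
  gf <- max_projection(f$stack, "GFAP")
  expect_equal(mean(gf$data > 0), f$truth$gfap_fraction_realized)
  # every caspase-positive nucleus has nearby signal in the caspase channel
  cs <- max_projection(f$stack, "Casp3")
  expect_gt(sum(cs$data > 0), 0)
})

test_that("stage presets reproduce the designed orderings in ground truth and manifest sizes", {
  res <- generate_stage_series(n_fields = 2, seed = 3,
                               size_um = c(80, 80), nz = 3)
  man <- res$manifest
  expect_equal(nrow(man), 12L)
  expect_true(all(table(paste(man$genotype, man$stage)) == 2))
  expect_true(all(man$n_aggregates[man$genotype == "nonTg"] == 0))
  pre3x <- man$genotype == "3xTg" & man$stage == "pre"
  expect_true(all(man$n_aggregates[pre3x] > 0))
  # pre-stage aggregates confined to IL
  agg <- do.call(rbind, lapply(res$fields[which(pre3x)],
                               function(f) f$truth$aggregates))
  expect_true(all(agg$layer == "IL"))
  il_top <- res$fields[[which(pre3x)[1]]]$truth$layer_boundaries$IL[2]
  expect_true(all(agg$y_um < il_top))
  # ramification ordering in emitted ground truth
  mean_br <- function(sel) mean(unlist(lapply(res$fields[sel], function(f)
    sapply(f$truth$cells, `[[`, "n_branches"))))
  expect_gt(mean_br(pre3x), mean_br(man$genotype == "nonTg" & man$stage == "pre"))
  expect_lt(mean_br(man$genotype == "3xTg" & man$stage == "late"),
            mean_br(man$genotype == "nonTg" & man$stage == "late"))
})

test_that("a preset table missing a design cell is rejected", {
  pr <- stage_presets()[-2, ]
  expect_error(generate_stage_series(presets = pr, n_fields = 1, seed = 1),
               "missing design cells")
})

test_that("ground truth JSON sidecar round-trips", {
  sp <- quiet_field(size_um = c(30, 30), nz = 3, dx = 0.25, dy = 0.25,
                    n_microglia = 1, n_ganglion = 4, caspase_p = 0.5,
                    gfap_fraction = 0.05,
                    aggregates = data.frame(channel = "pTau", layer = "OL",
                                            r_um = 0.9),
                    seed = 6)
  f <- generate_field(sp)
  p <- file.path(tempdir(), "truth.json")
  write_ground_truth(f$truth, p)
  tr <- read_ground_truth(p)
  expect_equal(tr$n_microglia, f$truth$n_microglia)
  expect_equal(tr$aggregates$volume_um3, f$truth$aggregates$volume_um3)
  expect_equal(tr$cells[[1]]$n_branches, f$truth$cells[[1]]$n_branches)
  expect_equal(unlist(tr$layer_boundaries),
               unlist(f$truth$layer_boundaries))
  unlink(p)
})
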