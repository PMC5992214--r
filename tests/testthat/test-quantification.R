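test_that("cell density follows the per-mm^3 formula exactly and scales linearly", {
  expect_equal(cell_density(0, 1e4, 20), 0)
  expect_equal(cell_density(1, 1e8, 10), 1) # 1 cell in 10^9 um^3
  expect_equal(cell_density(15, 212 * 212, 20), 15 / (212 * 212 * 20) * 1e9)
  expect_equal(cell_density(30, 212 * 212, 20), 2 * cell_density(15, 212 * 212, 20))
  expect_error(cell_density(3, 0, 10), "positive")
  expect_error(cell_density(-1, 10, 10), "non-negative")
})

test_that("positive fraction is an exact percentage with guarded inputs", {
  expect_equal(positive_fraction(0, 80), 0)
  expect_equal(positive_fraction(4, 80), 5)
  expect_error(positive_fraction(10, 5), "exceeds")
  expect_error(positive_fraction(1, 0), "positive")
})

test_that("caspase-positive recovery matches the generator's Bernoulli truth on noise-free fields", {
  sp <- quiet_field(size_um = c(70, 70), nz = 3, dx = 0.25, dy = 0.25,
                    n_microglia = 0, n_ganglion = 20, caspase_p = 0.4,
                    gfap_fraction = 0, seed = 5)
  f <- generate_field(sp)
  n <- count_positive_cells(f$stack, f$truth$ganglion_nuclei)
  expect_equal(as.integer(n), f$truth$n_caspase_positive)
  expect_equal(attr(n, "positive"), f$truth$ganglion_nuclei$caspase_positive)
  # no puncta at all
  sp0 <- quiet_field(size_um = c(30, 30), nz = 2, dx = 0.25, dy = 0.25,
                     n_microglia = 0, n_ganglion = 5, caspase_p = 0,
                     gfap_fraction = 0, seed = 2)
  f0 <- generate_field(sp0)
  expect_equal(as.integer(count_positive_cells(f0$stack, f0$truth$ganglion_nuclei)), 0L)
})

test_that("measured positive percentage sits inside the binomial 99% interval of the Bernoulli rate", {
  sp <- field_spec(size_um = c(220, 110), nz = 2, dx = 0.5, dy = 0.5,
                   n_microglia = 0, n_ganglion = 250, caspase_p = 0.1,
                   gfap_fraction = 0, seed = 5)
  f <- generate_field(sp)
  pct <- positive_fraction(f$truth$n_caspase_positive, 250)
  ci <- qbinom(c(0.005, 0.995), 250, 0.1) / 250 * 100
  expect_gte(pct, ci[1]); expect_lte(pct, ci[2])
})

test_that("aggregate detection: empty channel, single-voxel filtering, and sphere recovery", {
  sp <- quiet_field(size_um = c(12, 12), nz = 8, dx = 0.1, dy = 0.1,
                    n_microglia = 0, n_ganglion = 0, gfap_fraction = 0,
                    il_fraction = 1, seed = 3)
  f <- generate_field(sp)
  expect_equal(nrow(detect_aggregates(f$stack, "Abeta")), 0L)

  # one voxel: volume 0.005 um^3, equivalent diameter ~0.212 um -> filtered
  vox <- array(0, c(40, 40, 4, 1)); vox[20, 20, 2, 1] <- 5
  st <- image_stack(vox, "Abeta", 0.1, 0.1, 0.5)
  rec0 <- detect_aggregates(st, "Abeta", method = "fixed", threshold = 0)
  expect_equal(nrow(rec0), 0L)
  expect_equal(attr(rec0, "n_unfiltered"), 1L)
  keep <- detect_aggregates(st, "Abeta", method = "fixed", threshold = 0,
                            min_diameter_um = 0)
  expect_equal(keep$volume_um3, 0.005)
  expect_equal(keep$equiv_diameter_um, (6 * 0.005 / pi)^(1 / 3))

  sp2 <- quiet_field(size_um = c(12, 12), nz = 8, dx = 0.1, dy = 0.1,
                     n_microglia = 0, n_ganglion = 0, gfap_fraction = 0,
                     aggregates = data.frame(channel = "Abeta", layer = "IL",
                                             r_um = 1.5),
                     il_fraction = 1, seed = 3)
  f2 <- generate_field(sp2)
  rec <- detect_aggregates(f2$stack, "Abeta", method = "fixed", threshold = 0)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$volume_um3, 4 / 3 * pi * 1.5^3, tolerance = 0.15)
})

test_that("volume conservation and filter monotonicity hold", {
  sp <- quiet_field(size_um = c(25, 25), nz = 6, dx = 0.25, dy = 0.25,
                    n_microglia = 0, n_ganglion = 0, gfap_fraction = 0,
                    aggregates = data.frame(channel = "Abeta",
                                            layer = c("IL", "IL", "OL"),
                                            r_um = c(0.4, 0.9, 1.4)),
                    seed = 8)
  f <- generate_field(sp)
  all_rec <- detect_aggregates(f$stack, "Abeta", method = "fixed",
                               threshold = 0, min_diameter_um = 0)
  fg_vol <- sum(get_channel(f$stack, "Abeta") > 0) * 0.25 * 0.25 * 0.5
  expect_equal(sum(all_rec$volume_um3), fg_vol)
  floors <- c(0, 0.3, 0.58, 1, 2, 3.5)
  counts <- vapply(floors, function(d)
    nrow(detect_aggregates(f$stack, "Abeta", method = "fixed", threshold = 0,
                           min_diameter_um = d)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("layer assignment follows the centroid band, partitions records, and flags strays", {
  rec <- data.frame(y_um = c(10, 70), volume_um3 = 1, equiv_diameter_um = 1)
  b <- list(IL = c(0, 40), OL = c(40, 80))
  out <- assign_layer(rec, b)
  expect_equal(out$layer, c("IL", "OL"))
  expect_error(assign_layer(data.frame(y_um = 95), b), "outside")
  sp <- quiet_field(size_um = c(40, 40), nz = 4, dx = 0.25, dy = 0.25,
                    n_microglia = 0, n_ganglion = 0, gfap_fraction = 0,
                    aggregates = data.frame(channel = "Abeta",
                                            layer = c("IL", "OL", "OL"),
                                            r_um = 0.8),
                    seed = 12)
  f <- generate_field(sp)
  rec2 <- detect_aggregates(f$stack, "Abeta", method = "fixed", threshold = 0)
  out2 <- assign_layer(rec2, f$truth$layer_boundaries)
  expect_equal(sort(out2$layer), sort(f$truth$aggregates$layer))
  expect_true(all(out2$layer %in% c("IL", "OL")))
})

test_that("summarize_field: empty field zeros, determinism, and genotype density ordering", {
  sp0 <- quiet_field(size_um = c(30, 30), nz = 3, dx = 0.25, dy = 0.25,
                     n_microglia = 0, n_ganglion = 0, gfap_fraction = 0,
                     seed = 1)
  f0 <- generate_field(sp0)
  s0 <- summarize_field(f0$stack, f0$truth$ganglion_nuclei,
                        f0$truth$layer_boundaries)
  expect_equal(s0$measurement$microglia_density_mm3, 0)
  expect_equal(s0$measurement$caspase_pct, 0)
  expect_equal(s0$measurement$gfap_fraction, 0)
  expect_equal(nrow(s0$aggregates), 0L)

  pr <- stage_presets()
  late3x <- retinaquant:::preset_field_spec(pr[pr$genotype == "3xTg" & pr$stage == "late", ],
                                            seed = 5, size_um = c(120, 120), nz = 4)
  latent <- retinaquant:::preset_field_spec(pr[pr$genotype == "nonTg" & pr$stage == "late", ],
                                            seed = 5, size_um = c(120, 120), nz = 4)
  f1 <- suppressWarnings(generate_field(late3x))
  f2 <- suppressWarnings(generate_field(latent))
  m1 <- summarize_field(f1$stack, f1$truth$ganglion_nuclei, f1$truth$layer_boundaries)
  m2 <- summarize_field(f2$stack, f2$truth$ganglion_nuclei, f2$truth$layer_boundaries)
  expect_gt(m1$measurement$microglia_density_mm3,
            m2$measurement$microglia_density_mm3)
  m1b <- summarize_field(f1$stack, f1$truth$ganglion_nuclei, f1$truth$layer_boundaries)
  expect_identical(m1$measurement, m1b$measurement)
})
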