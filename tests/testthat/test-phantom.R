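test_that("phantom generation is a pure function of config and seed", {
  cfg <- phantom_config(n_collateral_voxels = 800L, seed = 42)
  a <- generate_axon_phantom(cfg)
  b <- generate_axon_phantom(cfg)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$voxels, b$truth$voxels)
  c <- generate_axon_phantom(phantom_config(n_collateral_voxels = 800L, seed = 43))
  expect_false(identical(a$truth$voxels, c$truth$voxels))
})

test_that("fully contralateral phantoms put every collateral across the plane", {
  cfg <- phantom_config(contralateral_fraction = 1, noise_rate = 0,
                        n_collateral_voxels = 500L, seed = 1)
  ph <- generate_axon_phantom(cfg)
  coll <- ph$truth$voxels[ph$truth$voxels$kind == "collateral", ]
  expect_equal(nrow(coll), 500)
  fr <- phantom_frame(cfg)
  d <- signed_distance(fr, (as.matrix(coll[, c("cell_1", "cell_2", "cell_3")]) + 0.5) *
                         cfg$voxel_size_um)
  expect_true(all(d * fr$injection_side_sign < 0))  # strictly opposite side
  expect_equal(ph$truth$LI, -1)
})

test_that("collateral-free phantoms contain only the tract", {
  cfg <- phantom_config(n_collateral_voxels = 0L, noise_rate = 0, seed = 8)
  ph <- generate_axon_phantom(cfg)
  expect_true(all(ph$truth$voxels$kind == "tract"))
  expect_true(all(ph$truth$region_counts$n_ipsi == 0))
  expect_true(all(ph$truth$region_counts$n_contra == 0))
  expect_equal(sum(ph$volume$values == cfg$probability_levels[["foreground"]]),
               ph$truth$n_tract)
})

test_that("the realized contralateral fraction follows the binomial oracle", {
  f <- 0.87; n <- 10000L
  cfg <- phantom_config(contralateral_fraction = f, n_collateral_voxels = n,
                        noise_rate = 0, seed = 99)
  ph <- generate_axon_phantom(cfg)
  fhat <- ph$truth$n_collateral_contra / n
  expect_lt(abs(fhat - f), 3 * sqrt(f * (1 - f) / n))
})

test_that("the mean fraction over many seeds matches the setting", {
  f <- 0.7; n <- 2000L
  fhats <- vapply(0:19, function(s) {
    ph <- generate_axon_phantom(
      phantom_config(contralateral_fraction = f, n_collateral_voxels = n,
                     noise_rate = 0, seed = s))
    ph$truth$n_collateral_contra / n
  }, 0)
  sd_mean <- sqrt(f * (1 - f) / n) / sqrt(20)
  expect_lt(abs(mean(fhats) - f), 3 * sd_mean)
})

test_that("truth sides are reproduced by reclassifying truth voxels", {
  cfg <- phantom_config(n_collateral_voxels = 1500L, noise_rate = 50, seed = 17)
  ph <- generate_axon_phantom(cfg)
  fr <- phantom_frame(cfg)
  vox <- ph$truth$voxels
  recls <- classify_side(fr, (as.matrix(vox[, c("cell_1", "cell_2", "cell_3")]) + 0.5) *
                           cfg$voxel_size_um)
  expect_equal(recls, vox$side)
  # Region counts are exactly the collateral rows aggregated by side.
  coll <- vox[vox$kind == "collateral", ]
  expect_equal(sum(ph$truth$region_counts$n_ipsi), sum(coll$side == "ipsi"))
  expect_equal(sum(ph$truth$region_counts$n_contra), sum(coll$side == "contra"))
  expect_equal(sum(ph$truth$region_counts$n_ipsi + ph$truth$region_counts$n_contra),
               cfg$n_collateral_voxels)
})

test_that("invalid phantom geometry is rejected before generation", {
  expect_error(phantom_config(grid_shape = c(10, 10, 10)), "configuration error")
  expect_error(phantom_config(contralateral_fraction = 1.2), "configuration error")
  expect_error(phantom_config(noise_rate = -1), "configuration error")
  # More collateral voxels than an ellipsoid can hold.
  cfg <- phantom_config(n_collateral_voxels = 200000L, contralateral_fraction = 1,
                        seed = 0)
  expect_error(generate_axon_phantom(cfg), "configuration error")
})

test_that("the optional caudal loop crosses the midline at the caudal end", {
  cfg <- phantom_config(n_collateral_voxels = 0L, noise_rate = 0,
                        caudal_loop = TRUE, seed = 0)
  ph <- generate_axon_phantom(cfg)
  tract <- ph$truth$voxels
  expect_true(any(tract$side == "contra"))
  base <- generate_axon_phantom(phantom_config(n_collateral_voxels = 0L,
                                               noise_rate = 0, seed = 0))
  expect_gt(nrow(tract), base$truth$n_tract)
})

test_that("generated neurons honour the requested laterality class", {
  cfg <- phantom_config()
  ph <- generate_axon_phantom(phantom_config(n_collateral_voxels = 0L,
                                             noise_rate = 0, seed = 0))
  fr <- phantom_frame(cfg)
  trig <- cfg$regions[cfg$regions$acronym %in% c("PrV", "SpVi", "SpVc"), ]
  in_trig_side <- function(tree, side_sgn) {
    leaves <- tree[!(tree$id %in% tree$parent), ]
    hit <- FALSE
    for (i in seq_len(nrow(trig))) {
      r <- trig[i, ]
      ctr <- c(cfg$midline_coordinate_um + side_sgn * r$ml_offset_um, r$dv_um, r$rc_um)
      q <- ((leaves$x - ctr[1]) / r$a_ml)^2 + ((leaves$y - ctr[2]) / r$a_dv)^2 +
        ((leaves$z - ctr[3]) / r$a_rc)^2
      hit <- hit || any(q < 1)
    }
    hit
  }
  for (s in 1:5) {
    bil <- generate_neuron_swc(cfg, "bilateral", seed = s)
    expect_true(in_trig_side(bil$tree, +1))
    expect_true(in_trig_side(bil$tree, -1))
    con <- generate_neuron_swc(cfg, "contra", seed = s)
    expect_false(in_trig_side(con$tree, +1))
    expect_true(in_trig_side(con$tree, -1))
  }
  # Determinism: byte-identical SWC text for the same seed.
  expect_identical(generate_neuron_swc(cfg, "ipsi", seed = 3)$swc,
                   generate_neuron_swc(cfg, "ipsi", seed = 3)$swc)
})

test_that("soma tables have the requested composition and pairing", {
  st <- generate_soma_table(7, 1, 0, seed = 1)
  expect_equal(nrow(st), 8)
  expect_true(all(st$channel == "A"))
  cfg <- phantom_config()
  fr <- phantom_frame(cfg)
  cls <- classify_side(fr, as.matrix(st[, c("x_um", "y_um", "z_um")]))
  expect_equal(sum(cls == "contra"), 7)
  expect_equal(sum(cls == "ipsi"), 1)

  # Double-labelled pairs co-located within the jitter.
  st2 <- generate_soma_table(0, 0, 2, jitter_um = 5, seed = 2)
  expect_equal(nrow(st2), 4)
  a <- as.matrix(st2[st2$channel == "A", 1:3])
  b <- as.matrix(st2[st2$channel == "B", 1:3])
  d <- sqrt(rowSums((a - b)^2))
  expect_true(all(d < 5))

  expect_identical(generate_soma_table(1, 0, 0, seed = 5),
                   generate_soma_table(1, 0, 0, seed = 5))
})
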