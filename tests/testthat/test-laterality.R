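test_that("binarize thresholds closed at the threshold value", {
  v <- volume_from_voxels(rbind(c(1, 1, 1, 0.4), c(2, 2, 2, 0.96)),
                          grid = c(3, 3, 3))
  expect_equal(sum(binarize(v, 0.95)$values), 1)   # only the 0.96 voxel
  expect_equal(sum(binarize(v, 0.96)$values), 1)   # closed at the threshold
  all_pos <- axon_volume(array(0.2, c(2, 2, 2)), 10)
  expect_equal(sum(binarize(all_pos, 0)$values), 8)
  expect_equal(sum(binarize(all_pos, 1)$values), 0)
  expect_error(binarize(v, 1.2), "threshold")
  expect_error(binarize(v, -0.1), "threshold")
})

test_that("positives are monotone non-increasing in the threshold", {
  set.seed(5)
  v <- axon_volume(array(runif(10 * 10 * 10), c(10, 10, 10)), 10)
  thresholds <- sort(runif(8))
  prev <- NULL
  for (t in thresholds) {
    pos <- which(binarize(v, t)$values != 0)
    if (!is.null(prev)) expect_true(all(pos %in% prev))
    prev <- pos
  }
})

test_that("downsampling maps voxel centres to floor(coord / resolution) cells", {
  # Voxel centres at (5,5,5) and (15,15,15) um both floor to cell (0,0,0).
  v <- volume_from_voxels(rbind(c(1, 1, 1, 1), c(2, 2, 2, 1)),
                          grid = c(4, 4, 4), voxel_size_um = 10)
  cl <- extract_and_downsample(v, 25)
  expect_equal(nrow(cl$cells), 1)
  expect_equal(cl$cells[1, ], c(0L, 0L, 0L))
  expect_equal(cl$source_count, 2L)

  # Centre at (35,35,35) -> cell (1,1,1); and at 30 um exactly -> floor = 1.
  v2 <- volume_from_voxels(rbind(c(4, 4, 4, 1)), grid = c(4, 4, 4),
                           voxel_size_um = 10)
  expect_equal(extract_and_downsample(v2, 25)$cells[1, ], c(1L, 1L, 1L))
  cl3 <- voxel_cloud(rbind(c(1, 1, 1)), 30)  # centre (45,45,45)
  expect_equal(extract_and_downsample(cl3, 45)$cells[1, ], c(1L, 1L, 1L))

  empty <- axon_volume(array(0, c(3, 3, 3)), 10)
  cle <- extract_and_downsample(empty, 25)
  expect_equal(nrow(cle$cells), 0)
  expect_equal(cle$source_count, 0L)

  expect_error(extract_and_downsample(v, 5), "target resolution")
})

test_that("downsampling at the cloud's own resolution is the identity", {
  set.seed(21)
  cells <- unique(matrix(sample.int(40, 300, replace = TRUE) - 1L, ncol = 3))
  cl <- voxel_cloud(cells, 25)
  cl2 <- extract_and_downsample(cl, 25)
  expect_setequal(apply(cl2$cells, 1, paste, collapse = ","),
                  apply(cl$cells, 1, paste, collapse = ","))
})

test_that("apply_mask keeps exactly the cells on nonzero mask voxels", {
  set.seed(31)
  cells <- unique(matrix(sample.int(10, 150, replace = TRUE) - 1L, ncol = 3))
  cl <- voxel_cloud(cells, 25)
  ones <- axon_volume(array(1, c(10, 10, 10)), 25)
  expect_equal(apply_mask(cl, ones)$cells, cl$cells)
  zeros <- axon_volume(array(0, c(10, 10, 10)), 25)
  expect_equal(nrow(apply_mask(cl, zeros)$cells), 0)

  # Half-space mask: brute-force per-cell lookup oracle.
  half <- array(0, c(10, 10, 10))
  half[1:5, , ] <- 1
  hv <- axon_volume(half, 25)
  got <- apply_mask(cl, hv)$cells
  want <- cl$cells[apply(cl$cells, 1, function(c) half[c[1] + 1, c[2] + 1, c[3] + 1] != 0), ,
                   drop = FALSE]
  expect_equal(got, want)

  bad <- axon_volume(array(1, c(10, 10, 10)), 20)
  expect_error(apply_mask(cl, bad), "space mismatch")
})

test_that("the lateralization index follows (n_ipsi - n_contra)/(n_ipsi + n_contra)", {
  fr <- make_frame(mid = 1000)
  res <- 25
  contra_cells <- cbind(10L, 0:99, 0L)         # ML centre 262.5 um < 1000
  ipsi_cells <- cbind(60L, 0:99, 0L)           # ML centre 1512.5 um > 1000
  # maximal contralateral bias
  lat <- laterality(voxel_cloud(contra_cells, res), fr)
  expect_equal(lat$n_contra, 100)
  expect_equal(lat$LI, -1)
  # perfect symmetry
  lat2 <- laterality(voxel_cloud(rbind(contra_cells[1:50, ], ipsi_cells[1:50, ]), res), fr)
  expect_equal(lat2$LI, 0)
  # 30 ipsi vs 70 contra
  lat3 <- laterality(voxel_cloud(rbind(ipsi_cells[1:30, ], contra_cells[1:70, ]), res), fr)
  expect_equal(lat3$LI, -0.4)
  # undefined when nothing is classified
  empty <- laterality(voxel_cloud(NULL, res), fr)
  expect_false(empty$LI_defined)
  expect_true(is.na(empty$LI))
})

test_that("counts are conserved and LI is antisymmetric under mirroring", {
  set.seed(17)
  for (rep in 1:10) {
    fr <- make_frame(mid = 40 * 25, w = sample(c(0, 100), 1))  # boundary cell 40
    cells <- unique(matrix(sample.int(80, 600, replace = TRUE) - 1L, ncol = 3))
    cl <- voxel_cloud(cells, 25)
    lat <- laterality(cl, fr)
    expect_equal(lat$n_ipsi + lat$n_contra + lat$n_on_plane + lat$n_excluded,
                 nrow(cl$cells))
    mir <- laterality(voxel_cloud(mirror_cells(cl$cells, 40), 25), fr)
    expect_equal(mir$n_ipsi, lat$n_contra)
    expect_equal(mir$n_excluded, lat$n_excluded)
    if (lat$LI_defined && lat$n_on_plane == 0 && lat$n_excluded == 0) {
      expect_equal(mir$LI, -lat$LI)
    }
  }
})

test_that("per-region fractions match the phantom generator truth exactly", {
  cfg <- phantom_config(n_collateral_voxels = 4000L, noise_rate = 0,
                        contralateral_fraction = 0.87, seed = 5)
  ph <- generate_axon_phantom(cfg)
  fr <- phantom_frame(cfg)
  cloud <- apply_mask(extract_and_downsample(binarize(ph$volume, 0.95), 25),
                      ph$mask)
  reg <- region_laterality(cloud, fr, ph$atlas)
  truth <- ph$truth$region_counts
  for (i in seq_len(nrow(reg))) {
    t <- truth[truth$region == reg$region[i], ]
    expect_equal(reg$n_ipsi[i], t$n_ipsi)
    expect_equal(reg$n_contra[i], t$n_contra)
    expect_equal(reg$contralateral_fraction[i], t$n_contra / (t$n_ipsi + t$n_contra))
  }
})

test_that("region fractions hit the boundary cases", {
  cfg <- phantom_config(n_collateral_voxels = 300L, noise_rate = 0,
                        contralateral_fraction = 1, seed = 2)
  ph <- generate_axon_phantom(cfg)
  fr <- phantom_frame(cfg)
  cloud <- extract_and_downsample(binarize(ph$volume, 0.95), 25)
  reg <- region_laterality(cloud, fr, ph$atlas)
  expect_true(all(reg$contralateral_fraction == 1))

  # A region with no cells is flagged undefined.
  empty <- region_laterality(voxel_cloud(NULL, 25), fr, ph$atlas)
  expect_true(all(is.na(empty$contralateral_fraction)))

  expect_error(region_laterality(cloud, fr, ph$atlas, regions = "XYZ"), "absent")
})

test_that("mediolateral profiles centre the midline and normalize to one", {
  fr <- make_frame(mid = 1000)
  # All cells on the plane-adjacent column: signed distance constant.
  on_mid <- voxel_cloud(cbind(39L, 0:9, 0L), 25)  # centres at 987.5, d = -12.5
  pr <- mediolateral_profile(on_mid, fr, n_bins = 11, reference_length_um = 2000)
  expect_equal(sum(pr$density), 1)
  expect_equal(which.max(pr$density), 6)  # central bin of 11
  expect_equal(max(pr$density), 1)

  # Uniform cloud over +/- reference/2: multinomial oracle.
  set.seed(23)
  n <- 4000
  cells <- cbind(sample.int(80, n, replace = TRUE) - 1L,
                 sample.int(50, n, replace = TRUE) - 1L,
                 sample.int(50, n, replace = TRUE) - 1L)
  cl <- voxel_cloud(cells, 25)
  m <- nrow(cl$cells)
  pru <- mediolateral_profile(cl, fr, n_bins = 10, reference_length_um = 2000)
  p0 <- 1 / 10
  tol <- 3 * sqrt(p0 * (1 - p0) / m)
  expect_true(all(abs(pru$density - p0) < tol))

  # A mirror-symmetric cloud gives a palindromic profile.
  sym <- voxel_cloud(rbind(cl$cells, mirror_cells(cl$cells, 40)), 25)
  prs <- mediolateral_profile(sym, fr, n_bins = 20, reference_length_um = 2000)
  expect_equal(prs$density, rev(prs$density))

  pe <- mediolateral_profile(voxel_cloud(NULL, 25), fr, n_bins = 10,
                             reference_length_um = 2000)
  expect_true(pe$empty)
  expect_equal(pe$density, rep(0, 10))
})

test_that("averaged density maps equal per-cell occupancy fractions at sigma 0", {
  set.seed(29)
  clouds <- lapply(1:4, function(i) {
    voxel_cloud(unique(matrix(sample.int(12, 90, replace = TRUE) - 1L, ncol = 3)), 25)
  })
  m <- average_density_maps(clouds, smoothing_sigma_cells = 0,
                            cell_origin = c(0, 0, 0), grid_shape = c(12, 12, 12))
  # Brute-force occupancy count oracle.
  for (probe in list(c(0, 0, 0), c(3, 5, 7), c(11, 11, 11))) {
    n_occ <- sum(vapply(clouds, function(cl) {
      any(cl$cells[, 1] == probe[1] & cl$cells[, 2] == probe[2] &
            cl$cells[, 3] == probe[3])
    }, TRUE))
    expect_equal(m$values[probe[1] + 1, probe[2] + 1, probe[3] + 1], n_occ / 4)
  }
  # Two identical clouds: the mean map is the occupancy grid itself.
  m2 <- average_density_maps(clouds[c(1, 1)], smoothing_sigma_cells = 0,
                             cell_origin = c(0, 0, 0), grid_shape = c(12, 12, 12))
  expect_setequal(unique(as.vector(m2$values)), c(0, 1))
  # One occupied, one empty: 0.5 at occupied cells.
  m3 <- average_density_maps(list(clouds[[1]], voxel_cloud(NULL, 25)),
                             smoothing_sigma_cells = 0,
                             cell_origin = c(0, 0, 0), grid_shape = c(12, 12, 12))
  expect_setequal(unique(as.vector(m3$values)), c(0, 0.5))
  # Smoothing keeps the map inside [0, 1].
  ms <- average_density_maps(clouds, smoothing_sigma_cells = 1,
                             cell_origin = c(0, 0, 0), grid_shape = c(12, 12, 12))
  expect_true(all(ms$values >= 0 & ms$values <= 1))
  expect_error(average_density_maps(list(clouds[[1]], voxel_cloud(cbind(0L, 0L, 0L), 10))),
               "resolution")
})
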