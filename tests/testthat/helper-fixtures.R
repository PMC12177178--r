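# Shared fixtures: all synthetic, built in code at test time.

# Midline frame for a plane ML = mid (world um), canonical normal +ML.
make_frame <- function(mid = 1500, side = "positive", w = 0) {
  fr <- fit_plane(c(mid, 0, 0), c(mid, 1, 0), c(mid, 0, 1),
                  exclusion_halfwidth_um = w)
  set_injection_side(fr, side)
}

# A small probability volume from explicit voxel values.
# vals: data.frame/matrix of (i, j, k, value) with 1-based indices.
volume_from_voxels <- function(vals, grid, voxel_size_um = 10, background = 0) {
  arr <- array(background, grid)
  vals <- as.matrix(vals)
  arr[vals[, 1:3, drop = FALSE]] <- vals[, 4]
  axon_volume(arr, voxel_size_um)
}

# Reflect 0-based cells across a plane lying on cell boundary `b` (in cells)
# along axis 1; exact mirror for the (c + 0.5) voxel-centre convention.
mirror_cells <- function(cells, boundary_cell) {
  out <- cells
  out[, 1] <- 2L * as.integer(boundary_cell) - 1L - cells[, 1]
  out
}

# Independent exact Mann-Whitney oracle: direct enumeration over group
# assignments using the definitional U (count of x > y pairs), kept separate
# from the package's rank-sum implementation.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  idx <- utils::combn(N, n1)
  u_of <- function(xx, yy) sum(outer(xx, yy, `>`))
  U_obs <- u_of(x, y)
  U_all <- apply(idx, 2L, function(sel) u_of(pooled[sel], pooled[-sel]))
  min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
}
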