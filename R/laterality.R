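#' Binarize a probability volume
#'
#' Thresholds an axon-probability volume into an occupancy volume: a voxel is
#' positive iff its value is greater than or equal to `threshold` (closed at
#' the threshold), so the number of positives is non-increasing in the
#' threshold. Typical thresholds are 0.5 for whole-brain segmentation masks
#' and 0.95 for the stricter brainstem laterality analysis.
#'
#' @param volume an [axon_volume()] with values in `[0, 1]`.
#' @param threshold probability threshold in `[0, 1]`.
#' @return a binary [axon_volume()] with the same metadata.
#' @export
binarize <- function(volume, threshold) {
  stopifnot(inherits(volume, "axon_volume"))
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  }
  out <- volume
  out$values <- array(as.numeric(volume$values >= threshold), dim(volume$values))
  out
}

#' Extract positive voxels and downsample to an isotropic grid
#'
#' Maps every positive voxel's world centre to the cell
#' `floor(coordinate / target_resolution_um)` of an isotropic grid and keeps
#' each occupied cell once (set semantics), matching the downsampling of
#' positive-pixel coordinates to a 25 um grid used for hemisphere
#' quantification. Applied to a [voxel_cloud()] already at the target
#' resolution this is the identity on cells.
#'
#' @param x a binary [axon_volume()] (any nonzero voxel counts as positive)
#'   or a [voxel_cloud()].
#' @param target_resolution_um isotropic target pitch in micrometres; must be
#'   at least the native voxel size.
#' @return a [voxel_cloud()] at `target_resolution_um`; `source_count`
#'   records the number of raw positive voxels.
#' @export
extract_and_downsample <- function(x, target_resolution_um) {
  UseMethod("extract_and_downsample")
}

#' @export
extract_and_downsample.axon_volume <- function(x, target_resolution_um) {
  target_resolution_um <- as.numeric(target_resolution_um)
  if (target_resolution_um < max(x$voxel_size_um) - 1e-9) {
    stop("target resolution must be >= the native voxel size", call. = FALSE)
  }
  idx <- which(x$values != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(voxel_cloud(NULL, target_resolution_um, source_count = 0L))
  }
  world <- voxel_centres(x, idx)
  cells <- floor(world / target_resolution_um)
  voxel_cloud(cells, target_resolution_um, source_count = nrow(idx))
}

#' @export
extract_and_downsample.voxel_cloud <- function(x, target_resolution_um) {
  target_resolution_um <- as.numeric(target_resolution_um)
  if (target_resolution_um < x$resolution_um - 1e-9) {
    stop("target resolution must be >= the cloud resolution", call. = FALSE)
  }
  cells <- floor(cell_centres(x) / target_resolution_um)
  voxel_cloud(cells, target_resolution_um, source_count = x$source_count)
}

#' Apply a mask volume to a voxel cloud
#'
#' Retains the cells whose mask voxel is nonzero; used to restrict the
#' downsampled axon coordinates to the hindbrain. The mask must live on the
#' cloud's grid: equal (isotropic) voxel size and an origin aligned to whole
#' cells.
#'
#' @param cloud a [voxel_cloud()].
#' @param mask an [axon_volume()] whose nonzero voxels define the kept
#'   region, at the cloud's resolution. Cells outside the mask extent are
#'   dropped.
#' @return a [voxel_cloud()] that is a subset of the input.
#' @export
apply_mask <- function(cloud, mask) {
  stopifnot(inherits(cloud, "voxel_cloud"), inherits(mask, "axon_volume"))
  res <- cloud$resolution_um
  if (any(abs(mask$voxel_size_um - res) > 1e-9)) {
    stop(sprintf("space mismatch: mask voxel size (%g um) != cloud resolution (%g um)",
                 mask$voxel_size_um[1], res), call. = FALSE)
  }
  off <- mask$origin_um / res
  if (any(abs(off - round(off)) > 1e-9)) {
    stop("space mismatch: mask origin is not aligned to the cloud grid",
         call. = FALSE)
  }
  off <- as.integer(round(off))
  if (nrow(cloud$cells) == 0L) return(cloud)
  idx <- sweep(cloud$cells, 2L, off, `-`) + 1L
  dm <- dim(mask$values)
  inside <- idx[, 1] >= 1L & idx[, 1] <= dm[1] &
    idx[, 2] >= 1L & idx[, 2] <= dm[2] &
    idx[, 3] >= 1L & idx[, 3] <= dm[3]
  keep <- inside
  keep[inside] <- mask$values[idx[inside, , drop = FALSE]] != 0
  voxel_cloud(cloud$cells[keep, , drop = FALSE], res,
              source_count = cloud$source_count)
}

#' Lateralization of a voxel cloud
#'
#' Classifies every cell centre with [classify_side()] and computes the
#' lateralization index
#' `LI = (n_ipsi - n_contra) / (n_ipsi + n_contra)`:
#' `-1` for a maximal contralateral bias, `+1` for a maximal ipsilateral
#' bias, `0` for perfectly symmetric collaterals. Cells inside the CST
#' exclusion band or exactly on the plane are counted separately and do not
#' enter the index.
#'
#' @param cloud a [voxel_cloud()] (typically masked).
#' @param frame a [midline_frame()] with injection side set.
#' @return an object of class `laterality_result` with counts `n_ipsi`,
#'   `n_contra`, `n_on_plane`, `n_excluded` and `LI` (`NA` with
#'   `LI_defined = FALSE` when no cell falls in either hemisphere).
#' @export
laterality <- function(cloud, frame) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  if (nrow(cloud$cells) == 0L) {
    cls <- character(0)
  } else {
    cls <- classify_side(frame, cell_centres(cloud))
  }
  n_ipsi <- sum(cls == "ipsi")
  n_contra <- sum(cls == "contra")
  denom <- n_ipsi + n_contra
  structure(
    list(n_ipsi = n_ipsi,
         n_contra = n_contra,
         n_on_plane = sum(cls == "on_plane"),
         n_excluded = sum(cls == "excluded"),
         n_total = length(cls),
         LI = if (denom > 0) (n_ipsi - n_contra) / denom else NA_real_,
         LI_defined = denom > 0),
    class = "laterality_result"
  )
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("<laterality_result> ipsi %d | contra %d | on-plane %d | excluded %d\n",
              x$n_ipsi, x$n_contra, x$n_on_plane, x$n_excluded))
  cat(if (x$LI_defined) sprintf("  LI = %.6f\n", x$LI) else "  LI undefined (no classified cells)\n")
  invisible(x)
}

#' @export
as.data.frame.laterality_result <- function(x, ...) {
  data.frame(n_ipsi = x$n_ipsi, n_contra = x$n_contra,
             n_on_plane = x$n_on_plane, n_excluded = x$n_excluded,
             LI = x$LI)
}

#' Per-region laterality against a label atlas
#'
#' Assigns each cell to the region labelled at its own grid position (cells
#' on background are ignored), determines each cell's hemisphere from its
#' own geometric side of the midline plane, and reports per-region
#' ipsilateral/contralateral counts and the contralateral fraction
#' `n_contra / (n_ipsi + n_contra)`. The fraction is `NA` for regions with
#' no classified cells. Cells excluded by the CST band or exactly on the
#' plane count toward neither hemisphere.
#'
#' @param cloud a [voxel_cloud()].
#' @param frame a [midline_frame()] with injection side set.
#' @param atlas a [label_atlas()] at the cloud's resolution.
#' @param regions character vector of region acronyms to report; all must
#'   appear in the atlas region table.
#' @return a data.frame of class `region_laterality` with one row per
#'   requested region: `region`, `n_ipsi`, `n_contra`,
#'   `contralateral_fraction`.
#' @export
region_laterality <- function(cloud, frame, atlas,
                              regions = atlas$region_table$acronym) {
  stopifnot(inherits(cloud, "voxel_cloud"), inherits(atlas, "label_atlas"))
  res <- cloud$resolution_um
  if (any(abs(atlas$voxel_size_um - res) > 1e-9)) {
    stop("space mismatch: atlas voxel size differs from cloud resolution",
         call. = FALSE)
  }
  off <- atlas$origin_um / res
  if (any(abs(off - round(off)) > 1e-9)) {
    stop("space mismatch: atlas origin is not aligned to the cloud grid",
         call. = FALSE)
  }
  unknown <- setdiff(regions, atlas$region_table$acronym)
  if (length(unknown)) {
    stop(sprintf("regions absent from the atlas region table: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(cloud$cells)
  if (n > 0L) {
    idx <- sweep(cloud$cells, 2L, as.integer(round(off)), `-`) + 1L
    dm <- dim(atlas$labels)
    inside <- idx[, 1] >= 1L & idx[, 1] <= dm[1] &
      idx[, 2] >= 1L & idx[, 2] <= dm[2] &
      idx[, 3] >= 1L & idx[, 3] <= dm[3]
    lab <- integer(n)
    lab[inside] <- atlas$labels[idx[inside, , drop = FALSE]]
    cls <- classify_side(frame, cell_centres(cloud))
  } else {
    lab <- integer(0)
    cls <- character(0)
  }
  rt <- atlas$region_table
  out <- data.frame(region = regions,
                    n_ipsi = NA_integer_, n_contra = NA_integer_,
                    contralateral_fraction = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    lid <- rt$label[match(regions[i], rt$acronym)]
    sel <- lab == lid
    ni <- sum(sel & cls == "ipsi")
    nc <- sum(sel & cls == "contra")
    out$n_ipsi[i] <- ni
    out$n_contra[i] <- nc
    out$contralateral_fraction[i] <- if (ni + nc > 0) nc / (ni + nc) else NA_real_
  }
  class(out) <- c("region_laterality", "data.frame")
  out
}

#' Mediolateral density profile
#'
#' Histograms the cloud along the axis perpendicular to the midline plane.
#' Each cell's signed distance to the plane is divided by
#' `reference_length_um` (e.g. the mediolateral extent of a reference-age
#' scan, so profiles from brains of different sizes are comparable) and
#' affinely mapped so the midline sits at normalized coordinate 0.5; values
#' are then counted into `n_bins` equal bins on `[0, 1]`, clipping
#' out-of-range cells into the end bins. Densities are normalized to sum to
#' one (default) or to unit maximum.
#'
#' @param cloud a [voxel_cloud()].
#' @param frame a [midline_frame()] (the injection side is not needed).
#' @param n_bins number of bins, at least 2 (default 100).
#' @param reference_length_um normalization length in micrometres, > 0.
#' @param normalization `"sum"` (densities sum to 1) or `"max"` (peak = 1).
#' @return an object of class `ml_profile` with `bin_edges` (length
#'   `n_bins + 1` on `[0, 1]`), `counts`, `density`, `reference_length_um`,
#'   `n` and an `empty` flag (all-zero profile for an empty cloud).
#' @export
mediolateral_profile <- function(cloud, frame, n_bins = 100,
                                 reference_length_um,
                                 normalization = c("sum", "max")) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  normalization <- match.arg(normalization)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  reference_length_um <- as.numeric(reference_length_um)
  if (reference_length_um <= 0) stop("reference_length_um must be > 0", call. = FALSE)
  if (nrow(cloud$cells) > 0L) {
    d <- signed_distance(frame, cell_centres(cloud))
    u <- 0.5 + d / reference_length_um
    bin <- pmin(n_bins, pmax(1L, floor(u * n_bins) + 1L))
    counts <- tabulate(bin, nbins = n_bins)
  } else {
    counts <- integer(n_bins)
  }
  total <- sum(counts)
  density <- if (total == 0) {
    rep(0, n_bins)
  } else if (normalization == "sum") {
    counts / total
  } else {
    counts / max(counts)
  }
  structure(
    list(bin_edges = seq(0, 1, length.out = n_bins + 1L),
         counts = counts, density = density,
         reference_length_um = reference_length_um,
         normalization = normalization,
         n = total, empty = total == 0),
    class = "ml_profile"
  )
}

#' @export
print.ml_profile <- function(x, ...) {
  cat(sprintf("<ml_profile> %d bins, %d cells, normalization: %s%s\n",
              length(x$density), x$n, x$normalization,
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Average occupancy density maps across brains
#'
#' Renders each cloud as a 0/1 occupancy grid over a common cell window,
#' optionally smooths it with a separable Gaussian kernel (row-normalized,
#' so values stay in `[0, 1]`), and averages voxelwise across brains —
#' the group-average projection-density map.
#'
#' @param clouds list of [voxel_cloud()] objects sharing one resolution and
#'   world frame.
#' @param smoothing_sigma_cells Gaussian sigma in cells; 0 disables
#'   smoothing (default 1).
#' @param cell_origin,grid_shape the common cell window (0-based origin cell
#'   and extent in cells); derived from the union bounding box when `NULL`.
#' @return an object of class `density_map`: `values` (3D array in
#'   `[0, 1]`), `resolution_um`, `cell_origin`, `n_brains`.
#' @export
average_density_maps <- function(clouds, smoothing_sigma_cells = 1,
                                 cell_origin = NULL, grid_shape = NULL) {
  if (!length(clouds) || !all(vapply(clouds, inherits, TRUE, "voxel_cloud"))) {
    stop("clouds must be a non-empty list of voxel_cloud objects", call. = FALSE)
  }
  res <- unique(vapply(clouds, function(c) c$resolution_um, 0))
  if (length(res) != 1L) {
    stop("space mismatch: clouds have different resolutions", call. = FALSE)
  }
  if (smoothing_sigma_cells < 0) stop("smoothing sigma must be >= 0", call. = FALSE)
  occupied <- do.call(rbind, lapply(clouds, function(c) c$cells))
  if (is.null(cell_origin)) {
    cell_origin <- if (nrow(occupied)) apply(occupied, 2L, min) else c(0L, 0L, 0L)
  }
  cell_origin <- as.integer(cell_origin)
  if (is.null(grid_shape)) {
    grid_shape <- if (nrow(occupied)) {
      apply(occupied, 2L, max) - cell_origin + 1L
    } else {
      c(1L, 1L, 1L)
    }
  }
  grid_shape <- as.integer(grid_shape)
  acc <- array(0, grid_shape)
  for (cl in clouds) {
    occ <- array(0, grid_shape)
    if (nrow(cl$cells)) {
      idx <- sweep(cl$cells, 2L, cell_origin, `-`) + 1L
      inside <- idx[, 1] >= 1L & idx[, 1] <= grid_shape[1] &
        idx[, 2] >= 1L & idx[, 2] <= grid_shape[2] &
        idx[, 3] >= 1L & idx[, 3] <= grid_shape[3]
      if (!all(inside)) {
        stop("space mismatch: cloud cells fall outside the common window",
             call. = FALSE)
      }
      occ[idx] <- 1
    }
    if (smoothing_sigma_cells > 0) {
      occ <- gaussian_smooth_3d(occ, smoothing_sigma_cells)
    }
    acc <- acc + occ
  }
  structure(
    list(values = acc / length(clouds), resolution_um = res,
         cell_origin = cell_origin, n_brains = length(clouds),
         smoothing_sigma_cells = smoothing_sigma_cells),
    class = "density_map"
  )
}

# Separable Gaussian smoothing via banded row-normalized kernel matrices.
# Row normalization makes the operator an average, so the output range never
# exceeds the input range (edges included).
gaussian_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  for (axis in 1:3) {
    n <- d[axis]
    if (n == 1L) next
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = sigma)
    radius <- ceiling(4 * sigma)
    K[abs(outer(seq_len(n), seq_len(n), `-`)) > radius] <- 0
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    p <- aperm(arr, perm)
    m <- K %*% matrix(p, nrow = n)
    arr <- aperm(array(m, dim(p)), order(perm))
  }
  arr
}
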