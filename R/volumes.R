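#' Axon volume container
#'
#' A 3D scalar field of axon probability (values in `[0, 1]`) or occupancy
#' (`{0, 1}`), together with the metadata needed to place every voxel in a
#' world coordinate frame in micrometres. The centre of voxel `(i, j, k)`
#' (1-based array index) sits at world position
#' `origin_um + (c(i, j, k) - 0.5) * voxel_size_um`, so mirror reflection
#' across a plane lying on a voxel boundary is exact.
#'
#' @param values 3D numeric array with finite values in `[0, 1]`.
#' @param voxel_size_um voxel pitch in micrometres, scalar (isotropic) or one
#'   value per array axis; all positive.
#' @param axis_map named integer vector mapping anatomical axes to array
#'   dimensions; must name `ML` (mediolateral), `DV` (dorsoventral) and `RC`
#'   (rostrocaudal).
#' @param origin_um world position of the corner of voxel `(1, 1, 1)`
#'   (i.e. voxel centre minus half a voxel), length 3.
#' @return an object of class `axon_volume`.
#' @export
axon_volume <- function(values, voxel_size_um,
                        axis_map = c(ML = 1L, DV = 2L, RC = 3L),
                        origin_um = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("non-3D data: an axon volume requires a 3D array", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("volume values must be finite (found NaN/NA/Inf)", call. = FALSE)
  }
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 1) {
    stop(sprintf("volume values must lie in [0, 1] (found range [%g, %g])",
                 rng[1], rng[2]), call. = FALSE)
  }
  voxel_size_um <- as_len3(voxel_size_um, "voxel_size_um")
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  axis_map <- check_axis_map(axis_map)
  structure(
    list(values = values,
         voxel_size_um = voxel_size_um,
         axis_map = axis_map,
         origin_um = as_len3(origin_um, "origin_um")),
    class = "axon_volume"
  )
}

check_axis_map <- function(axis_map) {
  am <- as.integer(axis_map)
  names(am) <- names(axis_map)
  if (!setequal(names(am), c("ML", "DV", "RC")) || !setequal(am, 1:3)) {
    stop("axis_map must map ML, DV, RC onto array dims 1:3", call. = FALSE)
  }
  am[c("ML", "DV", "RC")]
}

#' @export
print.axon_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<axon_volume> %d x %d x %d voxels @ (%g, %g, %g) um\n",
              d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  cat(sprintf("  value range [%g, %g]; ML axis = dim %d\n",
              min(x$values), max(x$values), x$axis_map[["ML"]]))
  invisible(x)
}

# World coordinates (um) of voxel centres for a matrix of 1-based array
# indices.
voxel_centres <- function(vol, index_matrix) {
  idx <- as_point_matrix(index_matrix)
  sweep(sweep(idx - 0.5, 2L, vol$voxel_size_um, `*`), 2L, vol$origin_um, `+`)
}

#' Label atlas container
#'
#' A 3D integer label grid in the same space as an [axon_volume()], plus a
#' region table naming each label. Label 0 is reserved for background and
#' every nonzero label present in the grid must appear in the table. Labels
#' are symmetric across hemispheres (the same label tags a nucleus on both
#' sides, as in CCFv3-style annotations); hemisphere assignment is always
#' geometric, via the midline plane.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param region_table data.frame with columns `label`, `acronym`, `name`.
#' @inheritParams axon_volume
#' @return an object of class `label_atlas`.
#' @export
label_atlas <- function(labels, region_table, voxel_size_um,
                        axis_map = c(ML = 1L, DV = 2L, RC = 3L),
                        origin_um = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("non-3D data: a label atlas requires a 3D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("atlas labels must not contain NA", call. = FALSE)
  need <- c("label", "acronym", "name")
  if (!is.data.frame(region_table) || !all(need %in% names(region_table))) {
    stop("region_table must have columns label, acronym, name", call. = FALSE)
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, region_table$label)
  if (length(missing)) {
    stop(sprintf("labels present in grid but absent from region_table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  voxel_size_um <- as_len3(voxel_size_um, "voxel_size_um")
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  structure(
    list(labels = labels,
         region_table = region_table,
         voxel_size_um = voxel_size_um,
         axis_map = check_axis_map(axis_map),
         origin_um = as_len3(origin_um, "origin_um")),
    class = "label_atlas"
  )
}

#' @export
print.label_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_atlas> %d x %d x %d voxels, %d regions\n",
              d[1], d[2], d[3], nrow(x$region_table)))
  cat(" ", paste(x$region_table$acronym, collapse = ", "), "\n")
  invisible(x)
}

#' Voxel cloud at an isotropic resolution
#'
#' The set of occupied cells of an isotropic grid, each counted once
#' (set semantics). Cell indices are 0-based: cell `c` covers world
#' coordinates `[c * resolution_um, (c + 1) * resolution_um)` on each axis,
#' and its centre sits at `(c + 0.5) * resolution_um`. Duplicate input rows
#' collapse to a single cell.
#'
#' @param cells integer matrix with 3 columns (0-based cell indices); may
#'   have zero rows.
#' @param resolution_um isotropic grid pitch in micrometres, > 0.
#' @param source_count number of raw positive voxels before downsampling.
#' @return an object of class `voxel_cloud`.
#' @export
voxel_cloud <- function(cells, resolution_um, source_count = NULL) {
  if (is.null(cells) || length(cells) == 0L) {
    cells <- matrix(integer(0), ncol = 3L)
  }
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 3L, byrow = TRUE)
  cells <- as.matrix(cells)
  if (ncol(cells) != 3L) stop("cells must have 3 columns", call. = FALSE)
  if (anyNA(cells)) stop("cells must not contain NA", call. = FALSE)
  storage.mode(cells) <- "integer"
  cells <- unique(cells)
  dimnames(cells) <- NULL
  resolution_um <- as.numeric(resolution_um)
  if (length(resolution_um) != 1L || !is.finite(resolution_um) || resolution_um <= 0) {
    stop("resolution_um must be a single positive number", call. = FALSE)
  }
  source_count <- as.integer(source_count %||% nrow(cells))
  if (source_count < nrow(cells)) {
    stop("source_count cannot be smaller than the number of occupied cells",
         call. = FALSE)
  }
  structure(
    list(cells = cells, resolution_um = resolution_um,
         source_count = source_count),
    class = "voxel_cloud"
  )
}

#' @export
print.voxel_cloud <- function(x, ...) {
  cat(sprintf("<voxel_cloud> %d cells @ %g um (from %d source voxels)\n",
              nrow(x$cells), x$resolution_um, x$source_count))
  invisible(x)
}

# World coordinates (um) of cell centres.
cell_centres <- function(cloud) {
  (cloud$cells + 0.5) * cloud$resolution_um
}
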