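#' Default brainstem region layout for phantoms
#'
#' Ellipsoidal stand-ins for the five nuclei targeted by corticobulbar
#' collaterals: pontine nuclei (P), principal trigeminal (PrV), facial motor
#' nucleus (VII), and the interpolaris (SpVi) and caudalis (SpVc)
#' subdivisions of the spinal trigeminal nucleus. Each region is defined on
#' the injection side by its mediolateral offset from the midline plus a
#' dorsoventral and rostrocaudal centre, and is mirrored exactly across the
#' midline. Centres are spaced so the ellipsoids are pairwise disjoint and
#' clear of both the midline exclusion band and the descending tract.
#'
#' @return data.frame with columns `label`, `acronym`, `name`,
#'   `ml_offset_um`, `dv_um`, `rc_um`, `a_ml`, `a_dv`, `a_rc` (semi-axes,
#'   um).
#' @export
default_regions <- function() {
  data.frame(
    label = 1:5,
    acronym = c("P", "PrV", "VII", "SpVi", "SpVc"),
    name = c("Pontine nuclei",
             "Principal sensory nucleus of the trigeminal",
             "Facial motor nucleus",
             "Spinal nucleus of the trigeminal, interpolar part",
             "Spinal nucleus of the trigeminal, caudal part"),
    ml_offset_um = c(600, 900, 650, 900, 900),
    dv_um = rep(1300, 5),
    rc_um = c(500, 1000, 1500, 2000, 2500),
    a_ml = rep(250, 5),
    a_dv = rep(250, 5),
    a_rc = rep(250, 5),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Describes the synthetic world the phantom generator emulates: an
#' isotropic brainstem-sized grid, a midline plane lying on a voxel boundary
#' (so mirror reflection is exact), a descending corticobulbar/corticospinal
#' tract running parallel to the midline on the injection side, bilateral
#' collateral clusters inside mirrored target-nucleus ellipsoids with a
#' controllable contralateral fraction, probability-valued voxels and
#' uniform speckle noise.
#'
#' @param grid_shape voxels per array axis (ML, DV, RC), positive integers.
#' @param voxel_size_um isotropic voxel pitch, > 0 (default 25 um, the
#'   quantification resolution).
#' @param midline_coordinate_um mediolateral world position of the true
#'   midline plane (default centres it on a voxel boundary).
#' @param tract_offset_um mediolateral distance of the descending tract from
#'   the midline, on the injection side. The default (100 um) places the
#'   tract inside the default 150 um CST exclusion band, as the pyramidal
#'   tract hugs the ventral midline.
#' @param tract_depth_um dorsoventral position of the tract.
#' @param n_collateral_voxels number of collateral voxels to place, >= 0.
#' @param contralateral_fraction probability in `[0, 1]` that a collateral
#'   voxel is placed on the non-injection side (default 0.87, the adult
#'   contralateral fraction in the principal trigeminal nucleus).
#' @param regions region table as from [default_regions()].
#' @param noise_rate expected false-positive voxels per 1e6 voxels, >= 0.
#' @param probability_levels named pair `c(foreground=, background=)` in
#'   `[0, 1]`; noise voxels carry the foreground level.
#' @param injection_side_sign `+1` or `-1`: hemisphere of the injection,
#'   as the sign of the mediolateral coordinate minus the midline.
#' @param caudal_loop if `TRUE`, adds the caudal decussation loop: the tract
#'   crosses the midline at the caudal end and ascends on the contralateral
#'   side.
#' @param axis_map array-axis convention (see [axon_volume()]).
#' @param seed integer seed making generation fully deterministic.
#' @return validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(120L, 80L, 120L),
                           voxel_size_um = 25,
                           midline_coordinate_um = NULL,
                           tract_offset_um = 100,
                           tract_depth_um = 600,
                           n_collateral_voxels = 5000L,
                           contralateral_fraction = 0.87,
                           regions = default_regions(),
                           noise_rate = 20,
                           probability_levels = c(foreground = 0.99, background = 0.01),
                           injection_side_sign = 1,
                           caudal_loop = FALSE,
                           axis_map = c(ML = 1L, DV = 2L, RC = 3L),
                           seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("configuration error: grid_shape must be 3 positive integers", call. = FALSE)
  }
  if (voxel_size_um <= 0) stop("configuration error: voxel_size_um must be > 0", call. = FALSE)
  if (is.null(midline_coordinate_um)) {
    # Midline on the central voxel boundary.
    midline_coordinate_um <- floor(grid_shape[1] / 2) * voxel_size_um
  }
  extent <- grid_shape * voxel_size_um
  if (midline_coordinate_um <= 0 || midline_coordinate_um >= extent[1]) {
    stop("configuration error: midline must lie inside the grid", call. = FALSE)
  }
  if (contralateral_fraction < 0 || contralateral_fraction > 1) {
    stop("configuration error: contralateral_fraction must be in [0, 1]", call. = FALSE)
  }
  if (n_collateral_voxels < 0) {
    stop("configuration error: n_collateral_voxels must be >= 0", call. = FALSE)
  }
  if (noise_rate < 0) stop("configuration error: noise_rate must be >= 0", call. = FALSE)
  pl <- probability_levels
  if (!all(c("foreground", "background") %in% names(pl)) ||
      any(pl < 0) || any(pl > 1)) {
    stop("configuration error: probability_levels must be named values in [0, 1]",
         call. = FALSE)
  }
  if (!injection_side_sign %in% c(-1, 1)) {
    stop("configuration error: injection_side_sign must be +1 or -1", call. = FALSE)
  }
  # Tract must fit on the injection side.
  tr_ml <- midline_coordinate_um + injection_side_sign * tract_offset_um
  if (tr_ml <= 0 || tr_ml >= extent[1] ||
      tract_depth_um <= 0 || tract_depth_um >= extent[2]) {
    stop("configuration error: grid too small to contain the tract", call. = FALSE)
  }
  # Every region ellipsoid, on both sides, must lie inside the grid and
  # strictly off the midline.
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$ml_offset_um <= r$a_ml) {
      stop(sprintf("configuration error: region %s touches the midline", r$acronym),
           call. = FALSE)
    }
    for (s in c(-1, 1)) {
      ctr <- c(midline_coordinate_um + s * r$ml_offset_um, r$dv_um, r$rc_um)
      semi <- c(r$a_ml, r$a_dv, r$a_rc)
      if (any(ctr - semi < 0) || any(ctr + semi > extent)) {
        stop(sprintf("configuration error: grid too small to contain region %s",
                     r$acronym), call. = FALSE)
      }
    }
  }
  structure(
    list(grid_shape = grid_shape, voxel_size_um = voxel_size_um,
         midline_coordinate_um = midline_coordinate_um,
         tract_offset_um = tract_offset_um, tract_depth_um = tract_depth_um,
         n_collateral_voxels = as.integer(n_collateral_voxels),
         contralateral_fraction = contralateral_fraction,
         regions = regions, noise_rate = noise_rate,
         probability_levels = pl,
         injection_side_sign = injection_side_sign,
         caudal_loop = caudal_loop,
         axis_map = check_axis_map(axis_map),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# 0-based cells whose centres lie strictly inside the ellipsoid.
ellipsoid_cells <- function(centre_um, semi_um, voxel_size_um, grid_shape) {
  lo <- pmax(0L, floor((centre_um - semi_um) / voxel_size_um))
  hi <- pmin(grid_shape - 1L, ceiling((centre_um + semi_um) / voxel_size_um))
  g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  dimnames(g) <- NULL
  ctr <- (g + 0.5) * voxel_size_um
  q <- ((ctr[, 1] - centre_um[1]) / semi_um[1])^2 +
    ((ctr[, 2] - centre_um[2]) / semi_um[2])^2 +
    ((ctr[, 3] - centre_um[3]) / semi_um[3])^2
  g[q < 1, , drop = FALSE]
}

#' True midline frame of a phantom configuration
#'
#' The exact plane the generator used, as a [midline_frame()] with the
#' phantom's injection side already set; useful for quantifying phantoms
#' against their ground truth.
#'
#' @param config a [phantom_config()].
#' @param exclusion_halfwidth_um CST exclusion half-width carried by the
#'   returned frame (default 0).
#' @return a [midline_frame()].
#' @export
phantom_frame <- function(config, exclusion_halfwidth_um = 0) {
  n <- c(0, 0, 0)
  n[1] <- 1
  midline_frame(n, -config$midline_coordinate_um,
                injection_side_sign = config$injection_side_sign,
                exclusion_halfwidth_um = exclusion_halfwidth_um)
}

#' Generate a ground-truthed axon phantom
#'
#' Builds a probability volume containing a contiguous descending tract at
#' `tract_offset_um` on the injection side, collateral voxels placed without
#' replacement inside target-nucleus ellipsoids (each voxel assigned to the
#' contralateral side with probability `contralateral_fraction`), and
#' uniform speckle noise outside the regions; plus a matching label atlas, an
#' all-ones hindbrain mask, and an exact record of every placement. Because
#' collateral voxels are distinct and the ellipsoids are disjoint from each
#' other and from the tract, set-semantics downsampling at the native
#' resolution recovers the truth counts exactly.
#'
#' @param config a [phantom_config()].
#' @return list of class `axon_phantom` with elements `volume`
#'   ([axon_volume()]), `atlas` ([label_atlas()]), `mask` (binary
#'   [axon_volume()]), `truth` (see Details) and `config`.
#' @details `truth` contains `voxels` (one row per foreground voxel: `kind`
#'   in tract/collateral/noise, `region`, `side`, 0-based cells
#'   `cell_1..cell_3`), `region_counts` (per-region ipsi/contra counts),
#'   `LI` (the lateralization index over collateral voxels), `plane`
#'   (true coefficients) and `n_tract`, `n_noise`.
#' @export
generate_axon_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, generate_axon_phantom_impl(config))
}

generate_axon_phantom_impl <- function(config) {
  gs <- config$grid_shape
  v <- config$voxel_size_um
  regions <- config$regions
  sgn <- config$injection_side_sign
  mid <- config$midline_coordinate_um

  # --- descending tract ------------------------------------------------
  tr_ml_cell <- floor((mid + sgn * config$tract_offset_um) / v)
  tr_dv_cell <- floor(config$tract_depth_um / v)
  tract <- cbind(tr_ml_cell, tr_dv_cell, 0:(gs[3] - 1L))
  if (config$caudal_loop) {
    # Decussation at the caudal end, then a rostral run on the contra side.
    contra_ml_cell <- floor((mid - sgn * config$tract_offset_um) / v)
    cross_cells <- sort(unique(c(tr_ml_cell, contra_ml_cell,
                                 seq(min(tr_ml_cell, contra_ml_cell),
                                     max(tr_ml_cell, contra_ml_cell)))))
    loop <- rbind(
      cbind(cross_cells, tr_dv_cell, gs[3] - 1L),
      cbind(contra_ml_cell, tr_dv_cell, (gs[3] - 2L):max(0L, floor(min(regions$rc_um) / v)))
    )
    tract <- rbind(tract, loop)
  }
  tract <- unique(tract)
  dimnames(tract) <- NULL

  # --- collaterals ------------------------------------------------------
  n_coll <- config$n_collateral_voxels
  coll_list <- list()
  if (n_coll > 0L) {
    reg_draw <- sample.int(nrow(regions), n_coll, replace = TRUE)
    contra_draw <- stats::runif(n_coll) < config$contralateral_fraction
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      semi <- c(r$a_ml, r$a_dv, r$a_rc)
      for (side in c("ipsi", "contra")) {
        side_sgn <- if (side == "ipsi") sgn else -sgn
        want <- sum(reg_draw == i & (contra_draw == (side == "contra")))
        if (want == 0L) next
        ctr <- c(mid + side_sgn * r$ml_offset_um, r$dv_um, r$rc_um)
        cand <- ellipsoid_cells(ctr, semi, v, gs)
        if (want > nrow(cand)) {
          stop(sprintf(
            "configuration error: region %s (%s) can hold %d voxels but %d requested",
            r$acronym, side, nrow(cand), want), call. = FALSE)
        }
        pick <- cand[sample.int(nrow(cand), want), , drop = FALSE]
        coll_list[[length(coll_list) + 1L]] <-
          data.frame(kind = "collateral", region = r$acronym, side = side,
                     cell_1 = pick[, 1], cell_2 = pick[, 2], cell_3 = pick[, 3],
                     stringsAsFactors = FALSE)
      }
    }
  }
  coll <- if (length(coll_list)) do.call(rbind, coll_list) else
    data.frame(kind = character(0), region = character(0), side = character(0),
               cell_1 = integer(0), cell_2 = integer(0), cell_3 = integer(0))

  # --- speckle noise (outside all ellipsoids and off the tract) ---------
  n_noise <- stats::rpois(1L, config$noise_rate * prod(gs) / 1e6)
  frame0 <- phantom_frame(config)
  noise <- matrix(integer(0), ncol = 3L)
  if (n_noise > 0L) {
    taken <- rbind(tract, as.matrix(coll[, c("cell_1", "cell_2", "cell_3")]))
    taken_key <- paste(taken[, 1], taken[, 2], taken[, 3])
    got <- 0L
    guard <- 0L
    acc <- matrix(integer(0), ncol = 3L)
    while (got < n_noise && guard < 50L) {
      guard <- guard + 1L
      m <- cbind(sample.int(gs[1], n_noise, replace = TRUE) - 1L,
                 sample.int(gs[2], n_noise, replace = TRUE) - 1L,
                 sample.int(gs[3], n_noise, replace = TRUE) - 1L)
      ctrs <- (m + 0.5) * v
      in_region <- rep(FALSE, nrow(m))
      for (i in seq_len(nrow(regions))) {
        r <- regions[i, ]
        for (side_sgn in c(-1, 1)) {
          rc <- c(mid + side_sgn * r$ml_offset_um, r$dv_um, r$rc_um)
          q <- ((ctrs[, 1] - rc[1]) / r$a_ml)^2 +
            ((ctrs[, 2] - rc[2]) / r$a_dv)^2 +
            ((ctrs[, 3] - rc[3]) / r$a_rc)^2
          in_region <- in_region | q < 1
        }
      }
      key <- paste(m[, 1], m[, 2], m[, 3])
      ok <- !in_region & !(key %in% taken_key) & !duplicated(key)
      m <- m[ok, , drop = FALSE]
      if (nrow(m)) {
        acc <- rbind(acc, m)
        acc <- acc[!duplicated(paste(acc[, 1], acc[, 2], acc[, 3])), , drop = FALSE]
        got <- nrow(acc)
        taken_key <- c(taken_key, paste(m[, 1], m[, 2], m[, 3]))
      }
    }
    noise <- acc[seq_len(min(n_noise, nrow(acc))), , drop = FALSE]
  }

  # --- assemble truth table --------------------------------------------
  side_of <- function(cells) {
    if (!nrow(cells)) return(character(0))
    classify_side(frame0, (cells + 0.5) * v)
  }
  truth_voxels <- rbind(
    data.frame(kind = "tract", region = NA_character_, side = side_of(tract),
               cell_1 = tract[, 1], cell_2 = tract[, 2], cell_3 = tract[, 3],
               stringsAsFactors = FALSE),
    coll,
    if (nrow(noise)) {
      data.frame(kind = "noise", region = NA_character_, side = side_of(noise),
                 cell_1 = noise[, 1], cell_2 = noise[, 2], cell_3 = noise[, 3],
                 stringsAsFactors = FALSE)
    }
  )
  region_counts <- data.frame(
    region = regions$acronym,
    n_ipsi = vapply(regions$acronym, function(a)
      sum(coll$region == a & coll$side == "ipsi"), 0L),
    n_contra = vapply(regions$acronym, function(a)
      sum(coll$region == a & coll$side == "contra"), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  n_ci <- sum(coll$side == "ipsi")
  n_cc <- sum(coll$side == "contra")
  truth <- list(
    voxels = truth_voxels,
    region_counts = region_counts,
    n_collateral_ipsi = n_ci,
    n_collateral_contra = n_cc,
    LI = if (n_ci + n_cc > 0) (n_ci - n_cc) / (n_ci + n_cc) else NA_real_,
    plane = list(normal = frame0$normal, offset = frame0$offset),
    injection_side_sign = config$injection_side_sign,
    n_tract = nrow(tract),
    n_noise = nrow(noise)
  )

  # --- volumes ----------------------------------------------------------
  fg <- config$probability_levels[["foreground"]]
  bg <- config$probability_levels[["background"]]
  vol <- array(bg, gs)
  fg_cells <- as.matrix(truth_voxels[, c("cell_1", "cell_2", "cell_3")]) + 1L
  vol[fg_cells] <- fg
  labels <- array(0L, gs)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    semi <- c(r$a_ml, r$a_dv, r$a_rc)
    for (side_sgn in c(-1, 1)) {
      ctr <- c(mid + side_sgn * r$ml_offset_um, r$dv_um, r$rc_um)
      cells <- ellipsoid_cells(ctr, semi, v, gs)
      labels[cells + 1L] <- r$label
    }
  }
  structure(
    list(volume = axon_volume(vol, v, axis_map = config$axis_map),
         atlas = label_atlas(labels, regions[, c("label", "acronym", "name")],
                             v, axis_map = config$axis_map),
         mask = axon_volume(array(1, gs), v, axis_map = config$axis_map),
         truth = truth,
         config = config),
    class = "axon_phantom"
  )
}

#' Generate a single-neuron SWC reconstruction with known laterality
#'
#' Builds a rooted tree emulating a layer-5 neuron: a soma in the cortex
#' zone on the injection side, a trunk descending to the tract depth and
#' running caudally parallel to the midline, and terminal collaterals whose
#' endpoints lie strictly inside trigeminal-region ellipsoids (PrV, SpVi,
#' SpVc) on the side(s) dictated by the requested class. Every parent
#' precedes its child and there is exactly one root, so the text is valid
#' SWC; identical seeds give byte-identical text.
#'
#' @param config a [phantom_config()] providing the world geometry.
#' @param laterality_class `"ipsi"`, `"contra"` or `"bilateral"`.
#' @param seed integer seed.
#' @return list with `swc` (character scalar, SWC text), `class` (the true
#'   laterality class) and `tree` (the parsed [neuron tree][read_swc]).
#' @export
generate_neuron_swc <- function(config, laterality_class, seed = 0L) {
  stopifnot(inherits(config, "phantom_config"))
  laterality_class <- match.arg(laterality_class, c("ipsi", "contra", "bilateral"))
  with_seed(seed, generate_neuron_swc_impl(config, laterality_class))
}

generate_neuron_swc_impl <- function(config, laterality_class) {
  sgn <- config$injection_side_sign
  mid <- config$midline_coordinate_um
  regions <- config$regions
  trig <- regions[regions$acronym %in% c("PrV", "SpVi", "SpVc"), , drop = FALSE]
  extent <- config$grid_shape * config$voxel_size_um

  nodes <- list()
  add <- function(type, xyz, parent, radius = 1) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- c(id = id, type = type, x = xyz[1], y = xyz[2], z = xyz[3],
                      radius = radius, parent = parent)
    id
  }
  soma_ml <- mid + sgn * (config$tract_offset_um + stats::runif(1, -50, 50))
  soma <- add(1L, c(soma_ml, 80, 150), -1L, radius = 6)
  # Descend to the tract depth.
  tract_ml <- mid + sgn * config$tract_offset_um
  drop1 <- add(2L, c(tract_ml, config$tract_depth_um, 180), soma)
  # Trunk: caudal run at tract depth; one node per 300 um so collaterals can
  # branch near each region's rostrocaudal level.
  rc_steps <- seq(300, extent[3] - 200, by = 300)
  trunk_ids <- integer(length(rc_steps))
  parent <- drop1
  for (i in seq_along(rc_steps)) {
    parent <- add(2L, c(tract_ml, config$tract_depth_um, rc_steps[i]), parent)
    trunk_ids[i] <- parent
  }
  sides <- switch(laterality_class,
                  ipsi = "ipsi", contra = "contra",
                  bilateral = c("ipsi", "contra"))
  for (side in sides) {
    side_sgn <- if (side == "ipsi") sgn else -sgn
    n_branches <- sample.int(nrow(trig), 1L)
    chosen <- sample.int(nrow(trig), n_branches)
    for (ri in chosen) {
      r <- trig[ri, ]
      ctr <- c(mid + side_sgn * r$ml_offset_um, r$dv_um, r$rc_um)
      semi <- c(r$a_ml, r$a_dv, r$a_rc) * 0.8
      # Uniform point strictly inside the (shrunken) ellipsoid.
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
      tip <- ctr + semi * u
      branch_at <- trunk_ids[which.min(abs(rc_steps - r$rc_um))]
      bp <- nodes[[branch_at]]
      mid_pt <- (c(bp[["x"]], bp[["y"]], bp[["z"]]) + tip) / 2
      inter <- add(2L, mid_pt, branch_at)
      add(2L, tip, inter)
    }
  }
  tab <- do.call(rbind, nodes)
  swc <- paste(
    c("# synthetic single-neuron reconstruction (axolat phantom)",
      sprintf("%d %d %.3f %.3f %.3f %.3f %d",
              as.integer(tab[, "id"]), as.integer(tab[, "type"]),
              tab[, "x"], tab[, "y"], tab[, "z"], tab[, "radius"],
              as.integer(tab[, "parent"]))),
    collapse = "\n")
  swc <- paste0(swc, "\n")
  tree <- parse_swc(strsplit(swc, "\n", fixed = TRUE)[[1]])
  list(swc = swc, class = laterality_class, tree = tree)
}

#' Generate a retrograde soma table
#'
#' Emulates bilateral retrograde tracing: somas in the cortex zone carrying
#' channel labels A or B. `n_contra`/`n_ipsi` channel-A somas are placed on
#' the contralateral/ipsilateral side of the phantom midline; each of the
#' `n_double` double-labelled cells contributes one record per channel,
#' co-located within `jitter_um`.
#'
#' @param n_contra,n_ipsi,n_double non-negative counts.
#' @param jitter_um maximum distance between the two records of a
#'   double-labelled pair (default 5).
#' @param seed integer seed.
#' @param config a [phantom_config()] providing the world geometry.
#' @return data.frame with columns `x_um`, `y_um`, `z_um`, `channel`.
#' @export
generate_soma_table <- function(n_contra, n_ipsi, n_double, jitter_um = 5,
                                seed = 0L, config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"),
            n_contra >= 0, n_ipsi >= 0, n_double >= 0, jitter_um >= 0)
  with_seed(seed, {
    mid <- config$midline_coordinate_um
    sgn <- config$injection_side_sign
    extent <- config$grid_shape * config$voxel_size_um
    place <- function(n, side_sgn) {
      if (n == 0L) return(matrix(numeric(0), ncol = 3L))
      cbind(mid + side_sgn * stats::runif(n, 300, min(1200, extent[1] / 3)),
            stats::runif(n, 50, 150),
            stats::runif(n, 100, 400))
    }
    contra <- place(n_contra, -sgn)
    ipsi <- place(n_ipsi, sgn)
    dbl <- place(n_double, -sgn)
    rows <- list()
    emit <- function(xyz, channel) {
      if (!nrow(xyz)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
        channel = channel, stringsAsFactors = FALSE)
    }
    emit(contra, "A")
    emit(ipsi, "A")
    if (n_double > 0L) {
      emit(dbl, "A")
      # Channel-B record of each pair: displaced by < jitter_um.
      u <- matrix(stats::rnorm(3 * n_double), ncol = 3L)
      u <- u / sqrt(rowSums(u^2)) * stats::runif(n_double)^(1 / 3)
      emit(dbl + u * jitter_um * 0.9, "B")
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                 channel = character(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
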