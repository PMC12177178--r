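#' Classify a single neuron's projection laterality
#'
#' Determines whether a reconstructed neuron projects ipsilaterally,
#' contralaterally or bilaterally to a set of target nuclei. Terminals are
#' the leaf nodes of the tree; a terminal counts when its position falls on
#' a listed region's atlas label, and its hemisphere is the geometric side
#' of the midline plane (no exclusion band — single-axon reconstructions
#' are traced, not segmented, so no CST contamination needs removing). A
#' neuron is `bilateral` when both sides reach the terminal threshold,
#' `none` when neither does.
#'
#' @param tree a `neuron_tree` from [read_swc()].
#' @param frame a [midline_frame()] with injection side set (the exclusion
#'   half-width is ignored: terminals are classified with `w = 0`).
#' @param atlas a [label_atlas()] sharing the tree's world frame.
#' @param regions character vector of target-region acronyms.
#' @param min_terminals minimum number of in-region terminals on a side for
#'   the neuron to count as projecting there (default 1).
#' @return an object of class `neuron_laterality`: `n_terminals_ipsi`,
#'   `n_terminals_contra` (within target regions), `n_leaves`, and `class`
#'   in `{"ipsi", "contra", "bilateral", "none"}`.
#' @export
classify_neuron <- function(tree, frame, atlas, regions, min_terminals = 1L) {
  stopifnot(inherits(tree, "neuron_tree"), inherits(atlas, "label_atlas"))
  unknown <- setdiff(regions, atlas$region_table$acronym)
  if (length(unknown)) {
    stop(sprintf("regions absent from the atlas region table: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  frame0 <- frame
  frame0$exclusion_halfwidth_um <- 0
  leaves <- tree_leaves(tree)
  if (nrow(leaves) == 0L || nrow(tree) == 1L) {
    warning("tree has no branches; classifying as 'none'")
    return(neuron_laterality_result(0L, 0L, nrow(leaves), "none"))
  }
  pos <- as.matrix(leaves[, c("x", "y", "z")])
  idx <- floor(sweep(pos, 2L, atlas$origin_um, `-`) %*%
                 diag(1 / atlas$voxel_size_um)) + 1L
  storage.mode(idx) <- "integer"
  dm <- dim(atlas$labels)
  inside <- idx[, 1] >= 1L & idx[, 1] <= dm[1] &
    idx[, 2] >= 1L & idx[, 2] <= dm[2] &
    idx[, 3] >= 1L & idx[, 3] <= dm[3]
  lab <- integer(nrow(idx))
  lab[inside] <- atlas$labels[idx[inside, , drop = FALSE]]
  target_labels <- atlas$region_table$label[
    atlas$region_table$acronym %in% regions]
  in_target <- lab %in% target_labels
  cls <- classify_side(frame0, pos)
  ni <- sum(in_target & cls == "ipsi")
  nc <- sum(in_target & cls == "contra")
  class <- if (ni >= min_terminals && nc >= min_terminals) "bilateral"
  else if (ni >= min_terminals) "ipsi"
  else if (nc >= min_terminals) "contra"
  else "none"
  neuron_laterality_result(ni, nc, nrow(leaves), class)
}

neuron_laterality_result <- function(ni, nc, n_leaves, class) {
  structure(list(n_terminals_ipsi = as.integer(ni),
                 n_terminals_contra = as.integer(nc),
                 n_leaves = as.integer(n_leaves),
                 class = class),
            class = "neuron_laterality")
}

#' @export
print.neuron_laterality <- function(x, ...) {
  cat(sprintf("<neuron_laterality> %s (%d ipsi / %d contra in-target terminals)\n",
              x$class, x$n_terminals_ipsi, x$n_terminals_contra))
  invisible(x)
}

#' Count retrogradely labelled somas per hemisphere
#'
#' Counts somas from a bilateral retrograde tracing experiment. Cross-channel
#' record pairs closer than `pair_radius_um` are treated as double-labelled
#' (bilaterally projecting) cells, matched greedily nearest-first so no soma
#' is used twice, and counted once under `n_double`. The remaining somas of
#' the reference channel are assigned ipsi/contra by their geometric side of
#' the midline relative to that channel's injection.
#'
#' @param somas data.frame with columns `x_um`, `y_um`, `z_um`, `channel`
#'   (labels `"A"`/`"B"`).
#' @param frame a [midline_frame()] with the injection side of the reference
#'   channel set.
#' @param pair_radius_um maximum distance for a double-label match
#'   (default 10).
#' @param channel reference channel whose singleton somas are counted
#'   (default `"A"`).
#' @return an object of class `soma_counts`: `n_contra`, `n_ipsi`,
#'   `n_double`, `contralateral_percentage` = `100 * n_contra /
#'   (n_contra + n_ipsi)` (`NA` when no singleton somas).
#' @export
count_somas <- function(somas, frame, pair_radius_um = 10, channel = "A") {
  need <- c("x_um", "y_um", "z_um", "channel")
  if (!is.data.frame(somas) || !all(need %in% names(somas))) {
    stop("somas must have columns x_um, y_um, z_um, channel", call. = FALSE)
  }
  bad <- setdiff(unique(somas$channel), c("A", "B"))
  if (length(bad)) {
    stop(sprintf("unknown channel label: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  a_idx <- which(somas$channel == "A")
  b_idx <- which(somas$channel == "B")
  pos <- as.matrix(somas[, c("x_um", "y_um", "z_um")])
  # Greedy nearest-first cross-channel matching.
  n_double <- 0L
  used_a <- logical(length(a_idx))
  used_b <- logical(length(b_idx))
  if (length(a_idx) && length(b_idx)) {
    d2 <- outer(seq_along(a_idx), seq_along(b_idx), function(i, j) {
      rowSums((pos[a_idx[i], , drop = FALSE] - pos[b_idx[j], , drop = FALSE])^2)
    })
    d2 <- matrix(d2, nrow = length(a_idx))
    repeat {
      d2[used_a, ] <- Inf
      d2[, used_b] <- Inf
      m <- which.min(d2)
      if (!length(m) || !is.finite(d2[m]) || d2[m] > pair_radius_um^2) break
      i <- (m - 1L) %% length(a_idx) + 1L
      j <- (m - 1L) %/% length(a_idx) + 1L
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      n_double <- n_double + 1L
    }
  }
  ref_idx <- if (channel == "A") a_idx[!used_a] else b_idx[!used_b]
  if (length(ref_idx)) {
    cls <- classify_side(frame, pos[ref_idx, , drop = FALSE])
  } else {
    cls <- character(0)
  }
  n_contra <- sum(cls == "contra")
  n_ipsi <- sum(cls == "ipsi")
  structure(
    list(n_contra = n_contra, n_ipsi = n_ipsi, n_double = n_double,
         contralateral_percentage = if (n_contra + n_ipsi > 0)
           100 * n_contra / (n_contra + n_ipsi) else NA_real_),
    class = "soma_counts"
  )
}

#' @export
print.soma_counts <- function(x, ...) {
  cat(sprintf("<soma_counts> contra %d | ipsi %d | double %d",
              x$n_contra, x$n_ipsi, x$n_double))
  if (!is.na(x$contralateral_percentage)) {
    cat(sprintf(" | %.1f%% contralateral", x$contralateral_percentage))
  }
  cat("\n")
  invisible(x)
}
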