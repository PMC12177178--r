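#' Read a neuron reconstruction in SWC format
#'
#' Parses the standard seven-column SWC text format (`id`, structure `type`,
#' `x`, `y`, `z`, `radius`, `parent`; coordinates in micrometres; parent of
#' the root is `-1`). Comment lines starting with `#` are skipped. The node
#' table is validated as a rooted tree: unique ids, every non-root parent
#' present, exactly one root, connected and acyclic. Structure type codes
#' are not interpreted beyond soma identification.
#'
#' @param path path to an SWC text file.
#' @return an object of class `neuron_tree`: a data.frame with columns
#'   `id`, `type`, `x`, `y`, `z`, `radius`, `parent`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read SWC file: %s", path), call. = FALSE)
  parse_swc(readLines(path, warn = FALSE))
}

parse_swc <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  body <- lines[keep]
  if (!length(body)) stop("SWC parse error: no nodes", call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop(sprintf("SWC parse error at line %d: expected 7 columns, found %d",
                 line_no[bad[1]], length(fields[[bad[1]]])), call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7L, byrow = TRUE)
  nan_row <- which(apply(m, 1L, anyNA))
  if (length(nan_row)) {
    stop(sprintf("SWC parse error at line %d: non-numeric field", line_no[nan_row[1]]),
         call. = FALSE)
  }
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  dup <- which(duplicated(nodes$id))
  if (length(dup)) {
    stop(sprintf("SWC parse error at line %d: duplicate id %d",
                 line_no[dup[1]], nodes$id[dup[1]]), call. = FALSE)
  }
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0L) stop("SWC parse error: no root node", call. = FALSE)
  if (length(roots) > 1L) {
    stop(sprintf("SWC parse error at line %d: second root (id %d)",
                 line_no[roots[2]], nodes$id[roots[2]]), call. = FALSE)
  }
  missing <- which(nodes$parent != -1L & !(nodes$parent %in% nodes$id))
  if (length(missing)) {
    stop(sprintf("SWC parse error at line %d: parent %d does not exist",
                 line_no[missing[1]], nodes$parent[missing[1]]), call. = FALSE)
  }
  # n nodes, n-1 parent edges: the graph is a tree iff every node is
  # reachable from the root (otherwise some component holds a cycle).
  children <- split(seq_len(nrow(nodes)), match(nodes$parent, nodes$id))
  seen <- logical(nrow(nodes))
  frontier <- roots
  seen[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(seen)) {
    bad_id <- nodes$id[which(!seen)[1]]
    stop(sprintf("SWC parse error: cycle or disconnected subtree at id %d", bad_id),
         call. = FALSE)
  }
  class(nodes) <- c("neuron_tree", "data.frame")
  nodes
}

#' Write a neuron tree to SWC text
#'
#' @param tree a `neuron_tree` (see [read_swc()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     tree$id, tree$type, tree$x, tree$y, tree$z,
                     tree$radius, tree$parent),
             path)
  invisible(path)
}

# Leaf nodes: nodes that are nobody's parent.
tree_leaves <- function(tree) {
  tree[!(tree$id %in% tree$parent), , drop = FALSE]
}
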