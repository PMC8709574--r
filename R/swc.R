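#' Neuron reconstruction tree (SWC semantics)
#'
#' A rooted 3-D neurite reconstruction: one row per node with the standard
#' SWC columns (id, structure type, x, y, z in micrometers, radius, parent).
#' Exactly one root (parent -1) is required and the graph must be a
#' connected, acyclic tree. The soma node is the first node with structure
#' code 1, falling back to the root.
#'
#' @param nodes Data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @param soma_id Optional node id to use as the soma center.
#' @return An object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes, soma_id = NULL) {
  nodes <- as.data.frame(nodes)
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    stop("`nodes` must have columns id, type, x, y, z, radius, parent",
         call. = FALSE)
  }
  nodes <- nodes[, need]
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id in reconstruction", call. = FALSE)
  }
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L) {
    stop(sprintf("reconstruction must have exactly one root, found %d",
                 length(roots)), call. = FALSE)
  }
  idx <- match(nodes$parent, nodes$id)
  orphans <- which(nodes$parent != -1 & is.na(idx))
  if (length(orphans)) {
    stop(sprintf("node %d references missing parent %d",
                 nodes$id[orphans[1]], nodes$parent[orphans[1]]), call. = FALSE)
  }
  # connectivity / acyclicity: walk each node to the root
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    seen <- 0L
    j <- i
    while (nodes$parent[j] != -1) {
      j <- idx[j]
      seen <- seen + 1L
      if (seen > n) stop("cycle detected in reconstruction", call. = FALSE)
    }
  }
  if (is.null(soma_id)) {
    hit <- which(nodes$type == 1)
    soma_id <- if (length(hit)) nodes$id[hit[1]] else nodes$id[roots]
  }
  if (!soma_id %in% nodes$id) stop("`soma_id` is not a node id", call. = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, soma_id = soma_id), class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d nodes, soma id %d, total length %.1f um\n",
              nrow(x$nodes), x$soma_id, total_length(x)))
  invisible(x)
}

#' Read a neuron reconstruction from an SWC file
#'
#' Whitespace-delimited, 1-based ids, `#` comment lines; unknown structure
#' codes are accepted.
#'
#' @param path File path.
#' @return A [neuron_tree()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("no nodes in SWC file %s", path), call. = FALSE)
  d <- utils::read.table(text = lines, header = FALSE,
                         col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  neuron_tree(d)
}

#' Write a neuron reconstruction to an SWC file
#'
#' @param tree A [neuron_tree()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  n <- tree$nodes
  lines <- sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                   n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# SWC reconstruction", lines), path)
  invisible(path)
}

# parent-child segments as start/end coordinate matrices (soma-internal
# segments flagged); used by morphometry
tree_segments <- function(tree) {
  n <- tree$nodes
  child <- which(n$parent != -1)
  pidx <- match(n$parent[child], n$id)
  list(
    p1 = as.matrix(n[pidx, c("x", "y", "z")]),
    p2 = as.matrix(n[child, c("x", "y", "z")]),
    soma_internal = n$type[child] == 1 & n$type[pidx] == 1
  )
}

soma_center <- function(tree) {
  i <- match(tree$soma_id, tree$nodes$id)
  as.numeric(tree$nodes[i, c("x", "y", "z")])
}
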