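#' Total dendritic length of a reconstruction
#'
#' Sum of Euclidean lengths of all parent-child segments. Segments whose
#' two endpoints both carry the soma structure code are excluded by default
#' so that multi-node somas do not inflate neurite length.
#'
#' @param tree A [neuron_tree()].
#' @param include_soma Include soma-internal segments?
#' @return Length in micrometers.
#' @export
total_length <- function(tree, include_soma = FALSE) {
  seg <- tree_segments(tree)
  if (!nrow(seg$p1)) return(0)
  len <- sqrt(rowSums((seg$p2 - seg$p1)^2))
  if (!include_soma) len <- len[!seg$soma_internal]
  sum(len)
}

#' Sholl intersection profile
#'
#' Counts, for each radius `r = k * increment`, the neurite segments
#' crossing the sphere of radius `r` centered on the soma node. Because
#' reconstructions are 3-D the crossing test is against spheres; for planar
#' tracings (constant z) this reduces to the classical concentric circles.
#' Crossings are found analytically from the quadratic for
#' `|p1 + t (p2 - p1) - soma| = r`, so a segment that dips inside a sphere
#' and exits again counts twice. Tie rules: a node lying exactly on a
#' sphere counts with its outward-going segment only, and tangencies do not
#' count. Radii run to the first multiple of `increment` at or beyond the
#' maximal neurite extent, where the count is zero by construction.
#'
#' @param tree A [neuron_tree()].
#' @param increment Radius increment in micrometers.
#' @return An object of class `sholl_profile`: data frame with `radius` and
#'   `intersections`.
#' @export
sholl_profile <- function(tree, increment = 20) {
  if (!is.numeric(increment) || increment <= 0) {
    stop("`increment` must be a positive radius step", call. = FALSE)
  }
  ctr <- soma_center(tree)
  seg <- tree_segments(tree)
  nd <- tree$nodes
  extent <- max(sqrt((nd$x - ctr[1])^2 + (nd$y - ctr[2])^2 + (nd$z - ctr[3])^2))
  n_r <- ceiling(extent / increment)
  radii <- increment * seq_len(max(n_r, 0))
  counts <- integer(length(radii))
  if (nrow(seg$p1)) {
    u <- sweep(seg$p1, 2L, ctr)
    v <- seg$p2 - seg$p1
    a <- rowSums(v^2)
    bq <- 2 * rowSums(u * v)
    uu <- rowSums(u^2)
    live <- a > 0
    for (i in seq_along(radii)) {
      counts[i] <- sum(segment_sphere_crossings(a[live], bq[live],
                                                uu[live] - radii[i]^2))
    }
  }
  structure(
    list(profile = data.frame(radius = radii, intersections = counts),
         increment = increment),
    class = "sholl_profile"
  )
}

# number of sphere crossings per segment given quadratic coefficients
# a t^2 + b t + c = 0 for |p(t) - center|^2 - r^2; roots in (0, 1) count,
# a root at t = 0 counts only when the segment leaves outward (b > 0),
# a root at t = 1 is left to the on-sphere node's outward segment,
# tangency (double root) does not count
segment_sphere_crossings <- function(a, b, c, eps = 1e-9) {
  disc <- b^2 - 4 * a * c
  out <- integer(length(a))
  pos <- which(disc > 0)
  if (!length(pos)) return(out)
  sq <- sqrt(disc[pos])
  t1 <- (-b[pos] - sq) / (2 * a[pos])
  t2 <- (-b[pos] + sq) / (2 * a[pos])
  cnt <- function(t) {
    interior <- t > eps & t < 1 - eps
    at_start <- abs(t) <= eps & b[pos] > 0
    as.integer(interior | at_start)
  }
  out[pos] <- cnt(t1) + cnt(t2)
  out
}

#' @export
print.sholl_profile <- function(x, ...) {
  p <- x$profile
  cat(sprintf("<sholl_profile> increment %g um, %d radii, max %d intersections\n",
              x$increment, nrow(p), if (nrow(p)) max(p$intersections) else 0L))
  invisible(x)
}

#' Branching complexity of a reconstruction
#'
#' @param tree A [neuron_tree()].
#' @return Named integer vector: `n_branch_points` (nodes with >= 2
#'   children), `n_tips` (non-root leaves) and `max_branch_order` (number
#'   of branch points on the soma-to-node path, maximized over nodes; an
#'   unbranched cable has order 0).
#' @export
branching_complexity <- function(tree) {
  nd <- tree$nodes
  n <- nrow(nd)
  pidx <- match(nd$parent, nd$id) # NA at root
  n_children <- tabulate(pidx[!is.na(pidx)], nbins = n)
  is_root <- nd$parent == -1
  branch_pts <- n_children >= 2L
  tips <- n_children == 0L & !is_root

  order_ <- integer(n)
  # nodes in root-first order: repeatedly follows parents already ordered
  todo <- order(vapply(seq_len(n), function(i) {
    d <- 0L
    j <- i
    while (!is.na(pidx[j])) {
      j <- pidx[j]
      d <- d + 1L
    }
    d
  }, integer(1)))
  for (i in todo) {
    if (!is.na(pidx[i])) {
      p <- pidx[i]
      order_[i] <- order_[p] + as.integer(branch_pts[p])
    }
  }
  c(
    n_branch_points = sum(branch_pts),
    n_tips = sum(tips),
    max_branch_order = max(order_)
  )
}

#' Laminar boundaries for dendritic-reach classification
#'
#' Radial distances (from the soma) at which the granule cell layer gives
#' way to the inner molecular layer, and the inner to the medial/outer
#' molecular layer. These are measured on the image per cell and supplied
#' as inputs.
#'
#' @param gcl_iml_boundary,iml_moml_boundary Distances in micrometers,
#'   `0 < gcl_iml_boundary < iml_moml_boundary`.
#' @return An object of class `laminar_bounds`.
#' @export
laminar_bounds <- function(gcl_iml_boundary, iml_moml_boundary) {
  if (!(gcl_iml_boundary > 0 && iml_moml_boundary > gcl_iml_boundary)) {
    stop("need 0 < gcl_iml_boundary < iml_moml_boundary", call. = FALSE)
  }
  structure(list(gcl_iml_boundary = gcl_iml_boundary,
                 iml_moml_boundary = iml_moml_boundary),
            class = "laminar_bounds")
}

#' Short- versus long-reach classification of an immature neuron
#'
#' Doublecortin-positive cells are split by how far their dendritic tree
#' reaches: cells whose dendrites stay within the inner molecular layer are
#' "short", cells reaching the medial/outer molecular layer are "long".
#' The maximal radial node distance from the soma is compared against the
#' layer boundaries; reach must strictly exceed `iml_moml_boundary` to be
#' long (a tree ending exactly on the boundary is short). A tree that never
#' passes `gcl_iml_boundary` is not a classifiable cell and yields
#' `"unclassifiable"`.
#'
#' @param tree A [neuron_tree()].
#' @param bounds A [laminar_bounds()].
#' @return `"short"`, `"long"`, or `"unclassifiable"`.
#' @export
classify_dcx_extent <- function(tree, bounds) {
  stopifnot(inherits(bounds, "laminar_bounds"))
  ctr <- soma_center(tree)
  nd <- tree$nodes
  reach <- max(sqrt((nd$x - ctr[1])^2 + (nd$y - ctr[2])^2 + (nd$z - ctr[3])^2))
  if (reach <= bounds$gcl_iml_boundary) return("unclassifiable")
  if (reach > bounds$iml_moml_boundary) "long" else "short"
}

#' Cell density from counts and region area
#'
#' @param n_cells Non-negative cell count(s).
#' @param region_area Region area(s) in square millimeters.
#' @return Cells per square millimeter.
#' @examples
#' cell_density(10, 0.5) # 20 cells/mm^2
#' @export
cell_density <- function(n_cells, region_area) {
  if (any(n_cells < 0)) stop("`n_cells` must be non-negative", call. = FALSE)
  if (any(region_area <= 0)) stop("`region_area` must be positive", call. = FALSE)
  n_cells / region_area
}
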