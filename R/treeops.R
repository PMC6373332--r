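#' Arc length of a pathline
#'
#' Sum of consecutive Euclidean point distances; 0 for a single point.
#'
#' @param p A pathline (list with `points`) or an n x 3 point matrix.
#' @return Length in mm.
#' @export
pathline_length <- function(p) {
  pts <- if (is.list(p) && !is.null(p$points)) p$points else p
  .poly_length(.as_points(pts))
}

#' Bifurcation angle between a parent and a side branch
#'
#' Angle (degrees, in `[0, 180]`) between the parent branch direction along the
#' blood-flow (proximal-to-distal) direction and the side branch direction.
#' A side branch is flagged for removal when this angle exceeds 120 degrees.
#'
#' @param parent_dir,branch_dir Numeric length-3 direction vectors (not
#'   necessarily unit length; zero length is an error).
#' @return Angle in degrees.
#' @export
bifurcation_angle <- function(parent_dir, branch_dir) {
  u <- .unit(parent_dir); v <- .unit(branch_dir)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# direction of polyline `pts` at arc position s, estimated as the chord over
# [s - arc, s + arc] clamped to the polyline ends
.chord_direction <- function(pts, s, arc = 3) {
  L <- .poly_length(pts)
  a <- .point_at_arc(pts, max(0, s - arc))
  b <- .point_at_arc(pts, min(L, s + arc))
  d <- b - a
  if (.vnorm(d) < 1e-9) stop("degenerate direction: polyline too short for chord estimation")
  .unit(d)
}

# bifurcation angle of pathline i against its parent, chord arc in mm;
# NA for roots and degenerate geometry
.tree_branch_angle <- function(tree, i, arc = 3) {
  p <- tree$parent[i]
  if (is.na(p)) return(NA_real_)
  ppts <- tree$pathlines[[p]]$points
  bpts <- tree$pathlines[[i]]$points
  if (nrow(bpts) < 2 || nrow(ppts) < 2) return(NA_real_)
  s_att <- .cum_arc(ppts)[tree$attach[i]]
  pd <- tryCatch(.chord_direction(ppts, s_att, arc), error = function(e) NULL)
  Lb <- .poly_length(bpts)
  bd <- tryCatch({
    d <- .point_at_arc(bpts, min(arc, Lb)) - bpts[1, ]
    .unit(d)
  }, error = function(e) NULL)
  if (is.null(pd) || is.null(bd)) return(NA_real_)
  bifurcation_angle(pd, bd)
}

#' Partition a tree into ostium-connected pathlines and orphans
#'
#' A pathline is connected when walking its parent links reaches a root whose
#' first point lies within `tol` of the left or right ostium; every other
#' pathline is an orphan.
#'
#' @param tree A `cat_tree`.
#' @param tol Connection tolerance in mm (convention: twice the largest voxel
#'   spacing of the accompanying volume).
#' @return List with integer index vectors `connected` and `orphans`.
#' @export
connected_components <- function(tree, tol = 1) {
  validate_tree(tree)
  n <- .tree_n(tree)
  side <- vapply(seq_len(n), function(i) .tree_root_side(tree, i, tol), character(1))
  list(connected = which(!is.na(side)), orphans = which(is.na(side)))
}

#' Split a labeled tree into the three coronary sub-trees
#'
#' Assigns every ostium-connected pathline to the sub-tree (RCA, LAD or LCX) of
#' the main branch it descends from, using the anatomical labels: a pathline
#' inherits the sub-tree of its own label, or of its nearest labeled ancestor.
#' Pathlines attached exactly at the LM bifurcation follow the child label
#' found at their attachment arc position.
#'
#' @param tree A labeled `cat_tree`.
#' @param model The `cat_model` whose labels are present in the tree.
#' @param tol Ostium connection tolerance in mm.
#' @return Named list `RCA`/`LAD`/`LCX` of pathline index vectors.
#' @export
split_subtrees <- function(tree, model, tol = 1) {
  labs <- .tree_labels(tree)
  df <- model$labels
  for (st in c("RCA", "LAD", "LCX")) {
    main <- .main_sequence(model, st)
    if (!any(labs %in% main))
      stop("main branch missing for sub-tree ", st, "; cannot split")
  }
  conn <- connected_components(tree, tol)$connected
  assign_one <- function(i) {
    cur <- i
    repeat {
      l <- labs[cur]
      if (!is.na(l) && l %in% df$name) return(df$subtree[match(l, df$name)])
      if (is.na(tree$parent[cur])) return(NA_character_)
      cur <- tree$parent[cur]
    }
  }
  st <- vapply(seq_len(.tree_n(tree)), assign_one, character(1))
  out <- lapply(c(RCA = "RCA", LAD = "LAD", LCX = "LCX"),
                function(s) intersect(which(st == s), conn))
  out
}

#' Prune a pathline to a maximum arc length
#'
#' Returns the prefix of the pathline with arc length at most `max_len`; the cut
#' point is interpolated on the offending segment. Idempotent.
#'
#' @param p A pathline (list with `points`, `label`) or point matrix.
#' @param max_len Maximum arc length in mm (>= 0).
#' @return Object of the same shape as `p`, pruned.
#' @export
prune_to_length <- function(p, max_len) {
  stopifnot(max_len >= 0)
  is_pl <- is.list(p) && !is.null(p$points)
  pts <- .as_points(if (is_pl) p$points else p)
  cum <- .cum_arc(pts)
  if (cum[length(cum)] <= max_len + 1e-12) return(p)
  keep <- which(cum <= max_len)
  last <- keep[length(keep)]
  out <- pts[seq_len(last), , drop = FALSE]
  if (cum[last] < max_len - 1e-12 && last < nrow(pts)) {
    out <- rbind(out, .point_at_arc(pts, max_len))
    dimnames(out) <- NULL
  }
  if (is_pl) { p$points <- out; p } else out
}

#' Symmetric Hausdorff distance between two trees
#'
#' Both trees are resampled at `step` mm along every pathline and the symmetric
#' Hausdorff distance between the two point clouds is returned.
#'
#' @param a,b `cat_tree` objects.
#' @param step Resampling step in mm.
#' @return Distance in mm.
#' @export
tree_hausdorff <- function(a, b, step = 0.25) {
  sample_tree <- function(tr) {
    do.call(rbind, lapply(tr$pathlines, function(p) .resample_polyline(p$points, step)))
  }
  A <- sample_tree(a); B <- sample_tree(b)
  if (is.null(A) || is.null(B) || nrow(A) == 0 || nrow(B) == 0) return(Inf)
  .hausdorff_sets(A, B)
}
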