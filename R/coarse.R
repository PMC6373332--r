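#' Coarse improvement of a coronary tree
#'
#' Removes incorrectly extracted structure in three ordered steps applied to
#' all vessels:
#' \enumerate{
#'   \item structures not connected to the left or right ostium are removed;
#'   \item pathlines longer than the model's global maximum length are pruned
#'     to that maximum, and pathlines strictly shorter than 1 mm are removed
#'     (a pathline of exactly 1 mm is kept);
#'   \item side branches whose bifurcation angle with the parent blood-flow
#'     direction strictly exceeds 120 degrees are removed.
#' }
#' Removing a pathline removes its attached descendants. The operation is
#' idempotent and leaves an empty tree unchanged.
#'
#' @param tree A `cat_tree`.
#' @param model A `cat_model` supplying the global constraints.
#' @param tol Ostium connection tolerance in mm.
#' @return The coarsely improved `cat_tree`.
#' @export
coarse_improve <- function(tree, model, tol = 1) {
  if (.tree_n(tree) == 0) return(tree)
  # step 1: orphans
  cc <- connected_components(tree, tol)
  tree <- .tree_drop(tree, cc$orphans, cascade = TRUE)
  # step 2: overlong pathlines pruned, sub-millimetre pathlines removed
  gmax <- model$global$max_pathline_length
  gmin <- model$global$min_pathline_length
  i <- 1L
  while (i <= .tree_n(tree)) {
    pts <- tree$pathlines[[i]]$points
    L <- .poly_length(pts)
    if (L > gmax + 1e-9) {
      cum <- .cum_arc(pts)
      keep_n <- max(1L, sum(cum <= gmax + 1e-9))
      lost <- which(!is.na(tree$parent) & tree$parent == i & tree$attach > keep_n)
      tree$pathlines[[i]]$points <- prune_to_length(pts, gmax)
      if (length(lost)) { tree <- .tree_drop(tree, lost, cascade = TRUE); next }
    } else if (L < gmin - 1e-9) {
      tree <- .tree_drop(tree, i, cascade = TRUE)
      next
    }
    i <- i + 1L
  }
  # step 3: bifurcation angles strictly above the maximum
  repeat {
    bad <- integer(0)
    for (i in seq_len(.tree_n(tree))) {
      a <- .tree_branch_angle(tree, i)
      if (!is.na(a) && a > model$global$max_angle_deg + 1e-9) bad <- c(bad, i)
    }
    if (!length(bad)) break
    tree <- .tree_drop(tree, bad, cascade = TRUE)
  }
  tree
}
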