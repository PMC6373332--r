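#' Construct a coronary artery tree
#'
#' A coronary artery tree (CAT) is a rooted geometric forest of centerline
#' pathlines in world millimetre coordinates. Each pathline is an ordered 3-D
#' polyline with an optional anatomical label; connectivity is stored as, per
#' pathline, the index of its parent pathline and the index of the attachment
#' point on that parent. Root pathlines (parent `NA`) are anchored at one of the
#' two coronary ostia when their first point lies within tolerance of it.
#'
#' @param ostium_left,ostium_right Numeric length-3 world coordinates (mm) of
#'   the left and right coronary ostia.
#' @param pathlines List of pathlines; each is a list with `points` (an n x 3
#'   numeric matrix, n >= 1) and `label` (a label name or `NA`).
#' @param parent Integer vector, one entry per pathline: index of the parent
#'   pathline or `NA` for roots/fragments.
#' @param attach Integer vector, one entry per pathline: index of the attachment
#'   point on the parent pathline, `NA` for roots/fragments.
#' @return An object of class `cat_tree`.
#' @export
cat_tree <- function(ostium_left, ostium_right, pathlines = list(),
                     parent = rep(NA_integer_, length(pathlines)),
                     attach = rep(NA_integer_, length(pathlines))) {
  pathlines <- lapply(pathlines, function(p) {
    list(points = .as_points(p$points),
         label = if (is.null(p$label) || is.na(p$label[1])) NA_character_ else as.character(p$label))
  })
  tree <- structure(list(
    ostium_left = as.numeric(ostium_left),
    ostium_right = as.numeric(ostium_right),
    pathlines = pathlines,
    parent = as.integer(parent),
    attach = as.integer(attach)
  ), class = "cat_tree")
  validate_tree(tree)
  tree
}

#' Validate the structural invariants of a coronary tree
#'
#' Checks finite coordinates, valid parent indices, valid attachment point
#' indices, and absence of cycles in the parent links.
#'
#' @param tree A `cat_tree`.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  n <- length(tree$pathlines)
  stopifnot(length(tree$ostium_left) == 3, length(tree$ostium_right) == 3)
  if (!all(is.finite(c(tree$ostium_left, tree$ostium_right))))
    stop("ostium coordinates must be finite")
  if (length(tree$parent) != n || length(tree$attach) != n)
    stop("parent/attach vectors must have one entry per pathline")
  for (i in seq_len(n)) {
    pts <- tree$pathlines[[i]]$points
    if (nrow(pts) < 1 || ncol(pts) != 3) stop("pathline ", i, ": needs an n x 3 point matrix")
    if (!all(is.finite(pts))) stop("pathline ", i, ": non-finite coordinates")
    p <- tree$parent[i]
    if (!is.na(p)) {
      if (p < 1 || p > n || p == i) stop("pathline ", i, ": invalid parent index ", p)
      a <- tree$attach[i]
      if (is.na(a) || a < 1 || a > nrow(tree$pathlines[[p]]$points))
        stop("pathline ", i, ": invalid attachment point index")
    }
  }
  # cycle check over parent links
  for (i in seq_len(n)) {
    seen <- logical(n); cur <- i
    while (!is.na(tree$parent[cur])) {
      if (seen[cur]) stop("cycle in pathline parent links at pathline ", i)
      seen[cur] <- TRUE
      cur <- tree$parent[cur]
    }
  }
  invisible(tree)
}

#' @export
print.cat_tree <- function(x, ...) {
  labs <- vapply(x$pathlines, function(p) p$label, character(1))
  cat("<cat_tree>", length(x$pathlines), "pathlines,",
      sum(!is.na(labs)), "labeled; total length",
      round(sum(vapply(x$pathlines, function(p) .poly_length(p$points), numeric(1))), 1),
      "mm\n")
  invisible(x)
}

# ---- internal tree utilities ------------------------------------------------

.tree_labels <- function(tree) vapply(tree$pathlines, function(p) p$label, character(1))

.tree_n <- function(tree) length(tree$pathlines)

# all descendants (direct and transitive) of pathline indices `idx`
.tree_descendants <- function(tree, idx) {
  out <- integer(0); frontier <- idx
  while (length(frontier)) {
    kids <- which(tree$parent %in% frontier)
    kids <- setdiff(kids, c(out, idx))
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# drop pathlines (plus descendants when cascade) and reindex parent links
.tree_drop <- function(tree, idx, cascade = TRUE) {
  if (!length(idx)) return(tree)
  idx <- unique(as.integer(idx))
  if (cascade) idx <- unique(c(idx, .tree_descendants(tree, idx)))
  keep <- setdiff(seq_len(.tree_n(tree)), idx)
  remap <- match(seq_len(.tree_n(tree)), keep)
  tree$pathlines <- tree$pathlines[keep]
  newpar <- remap[tree$parent[keep]]
  tree$parent <- as.integer(newpar)
  tree$attach <- as.integer(ifelse(is.na(newpar), NA_integer_, tree$attach[keep]))
  tree
}

# truncate pathline i at point index a (keep points 1..a); children attached
# beyond a are dropped with their descendants
.tree_truncate_at <- function(tree, i, a) {
  npts <- nrow(tree$pathlines[[i]]$points)
  a <- max(1L, min(as.integer(a), npts))
  lost <- which(!is.na(tree$parent) & tree$parent == i & tree$attach > a)
  tree$pathlines[[i]]$points <- tree$pathlines[[i]]$points[seq_len(a), , drop = FALSE]
  if (length(lost)) tree <- .tree_drop(tree, lost, cascade = TRUE)
  tree
}

# matrix of all points in the tree (possibly restricted to pathline indices)
.tree_points <- function(tree, idx = seq_len(.tree_n(tree))) {
  if (!length(idx)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, lapply(tree$pathlines[idx], function(p) p$points))
}

# which ostium (if any) anchors the root of pathline i: "left", "right" or NA
.tree_root_side <- function(tree, i, tol) {
  cur <- i
  while (!is.na(tree$parent[cur])) cur <- tree$parent[cur]
  first <- tree$pathlines[[cur]]$points[1, ]
  dl <- .vnorm(first - tree$ostium_left)
  dr <- .vnorm(first - tree$ostium_right)
  if (min(dl, dr) > tol) return(NA_character_)
  if (dl <= dr) "left" else "right"
}

# canonical JSON serialization used for snapshots, revert checks and equality
.tree_canonical <- function(tree) {
  .tree_json_string(tree, digits = 6)
}

#' Test two trees for equality
#'
#' Compares geometry (to `tol` mm per coordinate), labels and connectivity.
#'
#' @param a,b `cat_tree` objects.
#' @param tol Coordinate tolerance in mm.
#' @return Logical.
#' @export
tree_equal <- function(a, b, tol = 1e-6) {
  if (.tree_n(a) != .tree_n(b)) return(FALSE)
  if (max(abs(a$ostium_left - b$ostium_left), abs(a$ostium_right - b$ostium_right)) > tol)
    return(FALSE)
  if (!identical(is.na(a$parent), is.na(b$parent))) return(FALSE)
  if (any(a$parent != b$parent, na.rm = TRUE) || any(a$attach != b$attach, na.rm = TRUE))
    return(FALSE)
  for (i in seq_len(.tree_n(a))) {
    pa <- a$pathlines[[i]]; pb <- b$pathlines[[i]]
    if (!identical(is.na(pa$label), is.na(pb$label))) return(FALSE)
    if (!is.na(pa$label) && pa$label != pb$label) return(FALSE)
    if (nrow(pa$points) != nrow(pb$points)) return(FALSE)
    if (max(abs(pa$points - pb$points)) > tol) return(FALSE)
  }
  TRUE
}
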