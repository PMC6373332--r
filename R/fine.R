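# Fine improvement: detection of inaccurate labeled segments, the deletion and
# extension operations, and the improved branch searching on the binary
# vesselness volume.

#' Search parameters for the improved branch searching
#'
#' The search radius starts at `d_init` and grows by `d_step` each iteration up
#' to the maximum searching distance `d_max` (default 15 mm, which also bounds
#' the occlusion gap length the method can bridge). `kappa_min` is the discrete
#' curvature (Menger, 3-point stencil at 1 mm resampling) above which a point
#' counts as a "large curvature" start-point candidate.
#'
#' @param d_init Initial searching distance, mm.
#' @param d_step Increment per search iteration, mm.
#' @param d_max Maximum searching distance, mm.
#' @param kappa_min Curvature threshold, 1/mm.
#' @return Named list.
#' @export
search_params <- function(d_init = 2, d_step = 1, d_max = 15, kappa_min = 0.1) {
  stopifnot(d_init > 0, d_init <= d_max, d_step > 0)
  list(d_init = d_init, d_step = d_step, d_max = d_max, kappa_min = kappa_min)
}

# the deepest (most distal) present label of a main chain, or NA
.deepest_present <- function(present, seq_labels) {
  hit <- seq_labels[seq_labels %in% present]
  if (!length(hit)) NA_character_ else hit[length(hit)]
}

#' Detect inaccurate labeled segments
#'
#' Traverses the model label forest sub-tree by sub-tree, root to leaf. A
#' present label whose total length exceeds its model maximum is marked
#' `too_long` (deletion); shorter than its minimum, `too_short` (extension); a
#' labeled segment with bifurcation angle above the model maximum is marked
#' `bad_angle` (deletion). An absent label yields an `absent` finding
#' (extension) only when its weight reaches the model's weight threshold. On
#' main chains, a segment with a present child is skipped in favour of the
#' child (its proximal boundary is arbitrary); an absent side label whose
#' parent label is also absent escalates to the parent's finding.
#'
#' @param tree A labeled `cat_tree`.
#' @param model The `cat_model`.
#' @param tol Ostium connection tolerance in mm.
#' @return List of findings: each a list with `label`, `kind` (`absent`,
#'   `too_short`, `too_long`, `bad_angle`), `op` (`deletion`/`extension`) and
#'   `rule` (start-point rule 1, 2 or 3 for extensions, `NA` otherwise).
#' @export
detect_inaccuracies <- function(tree, model, tol = 1) {
  labs <- .tree_labels(tree)
  conn <- connected_components(tree, tol)$connected
  present <- unique(labs[intersect(which(!is.na(labs)), conn)])
  findings <- list()
  emit <- function(label, kind, op, rule = NA_integer_) {
    findings[[length(findings) + 1]] <<- list(label = label, kind = kind,
                                              op = op, rule = rule)
  }
  lab_length <- function(l) {
    idx <- intersect(which(labs == l), conn)
    sum(vapply(idx, function(i) .poly_length(tree$pathlines[[i]]$points), numeric(1)))
  }
  check_present <- function(l) {
    r <- .model_range(model, l)
    L <- lab_length(l)
    if (L > r[2] + 1e-9) emit(l, "too_long", "deletion")
    else if (L < r[1] - 1e-9) emit(l, "too_short", "extension", 3L)
    for (i in intersect(which(labs == l), conn)) {
      a <- .tree_branch_angle(tree, i)
      if (!is.na(a) && a > model$global$max_angle_deg) {
        emit(l, "bad_angle", "deletion")
        break
      }
    }
  }
  wth <- model$global$weight_threshold
  for (st in c("RCA", "LAD", "LCX")) {
    mseq <- .main_sequence(model, st)
    main_present <- mseq %in% present
    if (!any(main_present)) {
      # whole main branch absent: one rule-2 finding for its root label
      if (.model_weight(model, mseq[1]) >= wth)
        emit(mseq[1], "absent", "extension", 2L)
    } else {
      deepest <- .deepest_present(present, mseq)
      # child-skip rule: only the deepest present main segment is evaluated
      check_present(deepest)
      # absent main segments below the deepest present one
      di <- match(deepest, mseq)
      below <- if (di < length(mseq)) mseq[(di + 1):length(mseq)] else character(0)
      for (l in below) {
        if (!(l %in% present) && .model_weight(model, l) >= wth) {
          emit(l, "absent", "extension", 2L)
          break
        }
      }
    }
    # side labels of this subtree, in main-chain order then config order
    for (pl in mseq) {
      for (sl in .side_labels_of(model, pl)) {
        if (sl %in% present) {
          check_present(sl)
        } else if (.model_weight(model, sl) >= wth) {
          if (pl %in% present) emit(sl, "absent", "extension", 1L)
          # parent absent: escalated to the parent's own finding
        }
      }
    }
  }
  findings
}

#' Delete or truncate a segment flagged by a finding
#'
#' `too_long` findings truncate the labeled segment where it starts exceeding
#' the model maximum length (descendants attached beyond the cut are removed);
#' `bad_angle` findings remove the labeled segment and its descendants
#' entirely. Angles should be recomputed afterwards since the topology changed.
#'
#' @param tree A labeled `cat_tree`.
#' @param finding A finding with `kind` in `too_long`/`bad_angle`.
#' @param model The `cat_model`.
#' @return The modified tree.
#' @export
delete_segment <- function(tree, finding, model) {
  stopifnot(finding$kind %in% c("too_long", "bad_angle"))
  labs <- .tree_labels(tree)
  idx <- which(labs == finding$label)
  if (!length(idx)) stop("label not found in tree: ", finding$label)
  if (finding$kind == "bad_angle") return(.tree_drop(tree, idx, cascade = TRUE))
  lmax <- .model_range(model, finding$label)[2]
  # truncate the distal-most pathline carrying the label so the total length
  # drops to the maximum
  total <- sum(vapply(idx, function(i) .poly_length(tree$pathlines[[i]]$points),
                      numeric(1)))
  over <- total - lmax
  if (over <= 0) return(tree)
  i <- idx[length(idx)]
  pts <- tree$pathlines[[i]]$points
  keep_len <- max(0, .poly_length(pts) - over)
  cum <- .cum_arc(pts)
  keep_n <- max(1L, sum(cum <= keep_len + 1e-9))
  lost <- which(!is.na(tree$parent) & tree$parent == i & tree$attach > keep_n)
  tree$pathlines[[i]]$points <- prune_to_length(pts, keep_len)
  if (length(lost)) tree <- .tree_drop(tree, lost, cascade = TRUE)
  tree
}

#' Select start points for the improved branch searching
#'
#' Rule dispatch: (1) absent side branch label: all points on the parent label
#' with large curvature; (2) absent main branch label: all points with large
#' curvature on the extracted main branch of that subtree (its identification
#' may be unreliable when a segment is missing, so the whole chain is used);
#' (3) labeled segment too short: the single end point of that segment.
#'
#' @param finding An extension finding from [detect_inaccuracies()].
#' @param tree The labeled `cat_tree`.
#' @param model The `cat_model`.
#' @param params See [search_params()].
#' @return Data frame with columns `x`, `y`, `z`, `pathline`, `point` (the
#'   pathline index and nearest original point index of each start).
#' @export
select_start_points <- function(finding, tree, model, params = search_params()) {
  labs <- .tree_labels(tree)
  df <- model$labels
  starts_from_curvature <- function(idx) {
    rows <- list()
    for (i in idx) {
      pts <- tree$pathlines[[i]]$points
      rs <- .resample_polyline(pts, 1)
      kap <- .menger_curvature(rs)
      sel <- which(kap > params$kappa_min) + 1L
      for (s in sel) {
        d <- sqrt(colSums((t(pts) - rs[s, ])^2))
        rows[[length(rows) + 1]] <- data.frame(
          x = rs[s, 1], y = rs[s, 2], z = rs[s, 3],
          pathline = i, point = which.min(d))
      }
      # bends at pathline junctions: parent tail -> attachment -> child head
      p <- tree$parent[i]
      if (!is.na(p) && p %in% idx) {
        ppts <- tree$pathlines[[p]]$points
        a <- tree$attach[i]
        s_att <- .cum_arc(ppts)[a]
        prev <- .point_at_arc(ppts, max(0, s_att - 1))
        nxt <- .point_at_arc(pts, min(1, .poly_length(pts)))
        att <- ppts[a, ]
        k3 <- .menger_curvature(rbind(prev, att, nxt))
        if (length(k3) && k3[1] > params$kappa_min) {
          rows[[length(rows) + 1]] <- data.frame(
            x = att[1], y = att[2], z = att[3], pathline = p, point = a)
        }
      }
    }
    if (!length(rows)) return(NULL)
    unique(do.call(rbind, rows))
  }
  if (finding$kind == "too_short") {
    idx <- which(labs == finding$label)
    if (!length(idx)) stop("label not found in tree: ", finding$label)
    i <- idx[length(idx)]
    pts <- tree$pathlines[[i]]$points
    return(data.frame(x = pts[nrow(pts), 1], y = pts[nrow(pts), 2],
                      z = pts[nrow(pts), 3], pathline = i, point = nrow(pts)))
  }
  stopifnot(finding$kind == "absent")
  pos <- df$position_class[match(finding$label, df$name)]
  if (identical(finding$rule, 1L) || pos == "side") {
    parent_lab <- df$parent[match(finding$label, df$name)]
    idx <- which(labs == parent_lab)
    if (!length(idx)) stop("parent label also absent for rule 1: ", parent_lab)
  } else {
    st <- df$subtree[match(finding$label, df$name)]
    mseq <- .main_sequence(model, st)
    idx <- which(labs %in% mseq)
    if (!length(idx)) {
      # whole main branch missing: search from the whole connected tree
      idx <- connected_components(tree, 1)$connected
      if (!length(idx)) stop("no connected geometry to start a search from")
    }
  }
  sp <- starts_from_curvature(idx)
  if (is.null(sp))
    sp <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                     pathline = integer(0), point = integer(0))
  sp
}

#' Search for unconnected vessel-like structures near start points
#'
#' Wave-propagation search on the binary vesselness volume: at radius `d`
#' (starting at `d_init`, incremented by `d_step` per iteration, capped at
#' `d_max`), foreground voxels within Euclidean distance `d` of any start point
#' that are not covered by the current tree are candidate hits. On the first
#' radius with a hit, the 26-connected foreground component (with tree voxels
#' removed) of the closest hit voxel is traced into a pathline ordered away
#' from the start, and the gap is bridged with a straight connector from the
#' nearest start point to the entry voxel. Ties between equally distant hits
#' are broken by lexicographic voxel index. Returns an empty result when
#' `d_max` is exhausted.
#'
#' Traced paths are lightly smoothed so the staircase of voxel centres does not
#' inflate the recovered arc length; components whose traced path is shorter
#' than `min_len` (rasterization crumbs) are skipped.
#'
#' @param image A `vessel_image`.
#' @param tree The current `cat_tree` (its voxels are excluded).
#' @param starts Data frame of start points as from [select_start_points()].
#' @param params See [search_params()].
#' @param min_len Minimum traced path length worth attaching, mm.
#' @return List with `found` (logical); when found also `radius`, `points`
#'   (the bridged pathline, first point = the chosen start), `start_pathline`,
#'   `start_point` (attachment pathline/point index in `tree`).
#' @export
branch_search <- function(image, tree, starts, params = search_params(),
                          min_len = 1) {
  empty <- list(found = FALSE)
  if (is.null(starts) || nrow(starts) == 0) return(empty)
  fg <- which(image$voxels == 1L)
  if (!length(fg)) return(empty)
  tree_vox <- rasterize_tree(tree, image, clip = TRUE)
  cand <- setdiff(fg, tree_vox)
  if (!length(cand)) return(empty)
  cand <- sort(cand)
  cand_ijk <- .linear_to_ijk(image, cand)
  cand_w <- .ijk_to_world(image, cand_ijk)
  S <- as.matrix(starts[, c("x", "y", "z")])
  # distance from every candidate voxel to its nearest start, and which start
  n_s <- nrow(S)
  best_s <- integer(nrow(cand_w))
  dmin <- rep(Inf, nrow(cand_w))
  chunk <- max(1L, floor(2e6 / max(1, n_s)))
  i <- 1L
  while (i <= nrow(cand_w)) {
    j <- min(i + chunk - 1L, nrow(cand_w))
    a <- cand_w[i:j, , drop = FALSE]
    dd <- outer(rowSums(a * a), rowSums(S * S), "+") - 2 * tcrossprod(a, S)
    dd[dd < 0] <- 0
    wm <- max.col(-dd, ties.method = "first")
    dmin[i:j] <- sqrt(dd[cbind(seq_len(j - i + 1L), wm)])
    best_s[i:j] <- wm
    i <- j + 1L
  }
  radii <- seq(params$d_init, params$d_max, by = params$d_step)
  alive <- rep(TRUE, length(cand))
  for (d in radii) {
    repeat {
      hits <- which(alive & dmin <= d)
      if (!length(hits)) break
      entry <- hits[order(dmin[hits], cand[hits])][1]
      comp <- .voxel_component(image, cand, entry)
      trace <- .trace_component(image, cand, comp, entry)
      # rasterization crumbs (leftover voxels shorter than any meaningful
      # vessel) are not worth attaching; exclude and keep searching
      if (.poly_length(trace) < min_len) { alive[comp] <- FALSE; next }
      s_idx <- best_s[entry]
      start_pt <- S[s_idx, ]
      pts <- rbind(start_pt, .smooth_path(trace))
      keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                               pts[-nrow(pts), , drop = FALSE])^2) > 1e-12)
      return(list(found = TRUE, radius = d, points = pts[keep, , drop = FALSE],
                  start_pathline = starts$pathline[s_idx],
                  start_point = starts$point[s_idx],
                  component = cand[comp]))
    }
  }
  empty
}

# indices (into cand) of the 26-connected component containing cand[entry]
.voxel_component <- function(image, cand, entry) {
  ijk <- .linear_to_ijk(image, cand)
  key <- cand
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  in_comp <- logical(length(cand))
  in_comp[entry] <- TRUE
  frontier <- entry
  while (length(frontier)) {
    nb_ijk <- do.call(rbind, lapply(frontier, function(f) {
      sweep(offs, 2, ijk[f, ], "+")
    }))
    ok <- nb_ijk[, 1] >= 1 & nb_ijk[, 1] <= image$size[1] &
          nb_ijk[, 2] >= 1 & nb_ijk[, 2] <= image$size[2] &
          nb_ijk[, 3] >= 1 & nb_ijk[, 3] <= image$size[3]
    nb <- unique(.ijk_to_linear(image, nb_ijk[ok, , drop = FALSE]))
    pos <- match(nb, key)
    pos <- pos[!is.na(pos)]
    pos <- pos[!in_comp[pos]]
    in_comp[pos] <- TRUE
    frontier <- pos
  }
  which(in_comp)
}

# trace a component into an ordered voxel-centre path: BFS from the entry voxel
# to the farthest voxel (graph distance), path read back through BFS parents
.trace_component <- function(image, cand, comp, entry) {
  sub <- cand[comp]
  ijk <- .linear_to_ijk(image, sub)
  start <- match(entry, comp)
  npts <- length(sub)
  dist <- rep(NA_integer_, npts); par <- rep(NA_integer_, npts)
  dist[start] <- 0L
  frontier <- start
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      nb_ijk <- sweep(offs, 2, ijk[f, ], "+")
      nb <- .ijk_to_linear(image, nb_ijk)
      pos <- match(nb, sub)
      pos <- pos[!is.na(pos)]
      pos <- pos[is.na(dist[pos])]
      if (length(pos)) {
        dist[pos] <- dist[f] + 1L
        par[pos] <- f
        nxt <- c(nxt, pos)
      }
    }
    frontier <- nxt
  }
  far <- which.max(dist)
  path <- far
  while (!is.na(par[path[1]])) path <- c(par[path[1]], path)
  .ijk_to_world(image, ijk[path, , drop = FALSE])
}

#' Extend a tree by bridging to an unconnected vessel-like structure
#'
#' Runs the improved branch searching for an extension finding and, on success,
#' attaches the recovered pathline at the chosen start point; labels should be
#' re-assigned afterwards so the recovered structure can receive the missing
#' label. On search failure the tree is returned unchanged.
#'
#' @param tree A labeled `cat_tree`.
#' @param image A `vessel_image`.
#' @param finding An extension finding.
#' @param model The `cat_model`.
#' @param params See [search_params()].
#' @return List with `tree` and `found` (logical).
#' @export
extend_tree <- function(tree, image, finding, model, params = search_params()) {
  starts <- tryCatch(select_start_points(finding, tree, model, params),
                     error = function(e) NULL)
  if (is.null(starts) || nrow(starts) == 0) return(list(tree = tree, found = FALSE))
  res <- branch_search(image, tree, starts, params)
  if (!res$found) return(list(tree = tree, found = FALSE))
  if (finding$kind == "too_short" && !is.na(res$start_pathline)) {
    i <- res$start_pathline
    pts <- tree$pathlines[[i]]$points
    if (res$start_point == nrow(pts)) {
      # rule 3: grow the too-short segment itself from its end point
      tree$pathlines[[i]]$points <- rbind(pts, res$points[-1, , drop = FALSE])
      return(list(tree = tree, found = TRUE))
    }
  }
  tree$pathlines[[length(tree$pathlines) + 1]] <- list(points = res$points,
                                                       label = NA_character_)
  tree$parent <- c(tree$parent, as.integer(res$start_pathline))
  tree$attach <- c(tree$attach, as.integer(res$start_point))
  list(tree = tree, found = TRUE)
}
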