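# Phantom generator: ground-truth labeled coronary trees following the AHA
# RD/LD segment topology, rasterized into continuous binary skeleton volumes,
# plus controlled degradations emulating the failure modes of automatic
# centerline extraction (pruned branches, gaps, veins, fragments, overlong
# tails).

#' Specify a coronary phantom
#'
#' Segment lengths are drawn uniformly within each label's model length range;
#' side branches leave their parent at angles drawn in 20-70 degrees. Main
#' branches are piecewise straight with deliberate bends (12-20 degrees) at
#' junctions and side-branch origins, mirroring how real vessels change
#' direction at bifurcations; this also gives the curvature-based start-point
#' selection of the branch search real anchors.
#'
#' @param dominance `"RD"`, `"LD"` or `"balanced"` (treated as RD).
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @param spacing Voxel spacing in mm (length 3, anisotropic allowed).
#' @param size Volume size in voxels (length 3) or `NULL` to auto-fit the
#'   generated tree with `margin_mm` of padding.
#' @param origin World coordinate of voxel (1,1,1); only used with explicit
#'   `size` (auto-fit computes its own origin).
#' @param margin_mm Padding around the tree for auto-fit volumes.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dominance = "RD", seed = 1,
                         spacing = c(0.5, 0.5, 0.5),
                         size = NULL, origin = NULL, margin_mm = 3) {
  if (dominance == "balanced") dominance <- "RD"
  stopifnot(dominance %in% c("RD", "LD"), length(spacing) == 3, all(spacing > 0))
  structure(list(dominance = dominance, seed = as.integer(seed),
                 spacing = as.numeric(spacing), size = size, origin = origin,
                 margin_mm = margin_mm),
            class = "phantom_spec")
}

.sample1 <- function(v) if (length(v) == 1) v else sample(v, 1)

# run code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# fixed geometric layout: base directions, attachment fractions and azimuths.
# Ostia: right at (0,0,0), left at (70,0,0); anterior is -y, feet are -z.
.phantom_layout <- function(dominance) {
  main <- list(
    list(label = "pRCA", chain = "RCA", dir = c(-0.15, 0.45, -1.00)),
    list(label = "mRCA", chain = "RCA", dir = c( 0.25, 0.75, -0.85)),
    list(label = "dRCA", chain = "RCA", dir = c( 0.70, 0.55, -0.35)),
    list(label = "LM",   chain = "LM",  dir = c( 0.10, 0.25, -1.00)),
    list(label = "pLAD", chain = "LAD", dir = c( 0.15, -0.55, -1.00)),
    list(label = "mLAD", chain = "LAD", dir = c( 0.05, -0.70, -0.85)),
    list(label = "dLAD", chain = "LAD", dir = c(-0.15, -0.55, -0.90)),
    list(label = "pLCX", chain = "LCX", dir = c(-0.25, 0.70, -0.75)),
    list(label = "dLCX", chain = "LCX", dir = c( 0.05, 0.85, -0.50))
  )
  side <- list(
    list(label = "D1",  parent = "pLAD", frac = 0.65, phi = pi / 2),
    list(label = "D2",  parent = "mLAD", frac = 0.60, phi = 3 * pi / 2),
    list(label = "OM1", parent = "pLCX", frac = 0.65, phi = 0),
    list(label = "OM2", parent = "dLCX", frac = 0.55, phi = pi)
  )
  if (dominance == "RD") {
    side <- c(side, list(
      list(label = "RPDA", parent = "dRCA", frac = 0.55, phi = 0),
      list(label = "RPLB", parent = "dRCA", frac = 0.80, phi = pi)
    ))
  } else {
    side <- c(side, list(
      list(label = "LPLB", parent = "dLCX", frac = 0.80, phi = pi / 2),
      list(label = "LPDA", parent = "dLCX", frac = 1.00, phi = 0)
    ))
  }
  list(main = main, side = side)
}

# piecewise-straight path from `start` along `dir0`, length `len`, bending at
# interior arc fractions `bend_fracs`; ~1 mm sampling. Returns the points and
# the point index of each bend fraction (including frac 1 -> last index).
.build_path <- function(start, dir0, len, bend_fracs = numeric(0), bend_phis = numeric(0)) {
  dir <- .unit(dir0)
  breaks <- sort(unique(pmin(pmax(bend_fracs, 0.05), 0.95))) * len
  s_vals <- sort(unique(c(seq(0, len, by = 1), breaks, len)))
  pts <- matrix(0, nrow = length(s_vals), ncol = 3)
  pts[1, ] <- start
  frac_idx <- stats::setNames(rep(NA_integer_, length(bend_fracs)),
                              format(bend_fracs))
  bi <- 1L
  for (k in seq_along(s_vals)[-1]) {
    pts[k, ] <- pts[k - 1, ] + dir * (s_vals[k] - s_vals[k - 1])
    if (bi <= length(breaks) && abs(s_vals[k] - breaks[bi]) < 1e-9) {
      theta <- stats::runif(1, 12, 20) * pi / 180
      phi <- (if (length(bend_phis) >= bi) bend_phis[bi] else 0) + stats::runif(1, -0.2, 0.2)
      dir <- .unit(.rotate3(dir, .perp_at(dir, phi), theta))
      bi <- bi + 1L
    }
  }
  at_index <- function(frac) {
    if (frac >= 1) return(nrow(pts))
    s <- min(max(frac, 0.05), 0.95) * len
    which.min(abs(s_vals - s))
  }
  list(points = pts, at_index = at_index)
}

#' Generate a coronary phantom
#'
#' Produces a ground-truth labeled coronary artery tree following the model's
#' segment topology and a binary vesselness volume containing its rasterized,
#' 26-connected skeleton. Deterministic for a given spec.
#'
#' @param spec A [phantom_spec()].
#' @param model Optional `cat_model`; defaults to the shipped model for the
#'   spec's dominance.
#' @return List with elements `tree` (ground-truth `cat_tree`), `image`
#'   (`vessel_image`) and `model`.
#' @export
generate_phantom <- function(spec = phantom_spec(), model = NULL) {
  if (is.null(model)) model <- load_model(dominance = spec$dominance)
  .with_seed(spec$seed, function() .generate_phantom_impl(spec, model))
}

.generate_phantom_impl <- function(spec, model) {
  layout <- .phantom_layout(spec$dominance)
  ostium_right <- c(0, 0, 0)
  ostium_left <- c(70, 0, 0)
  draw_len <- function(label) {
    r <- .model_range(model, label)
    stats::runif(1, r[1] + 0.05 * (r[2] - r[1]), r[2] - 0.05 * (r[2] - r[1]))
  }
  pathlines <- list(); parent <- integer(0); attach <- integer(0)
  built <- list()  # label -> list(index, path)

  add_pathline <- function(label, pts, par_idx, att_idx) {
    pathlines[[length(pathlines) + 1]] <<- list(points = pts, label = label)
    parent <<- c(parent, if (is.null(par_idx)) NA_integer_ else as.integer(par_idx))
    attach <<- c(attach, if (is.null(att_idx)) NA_integer_ else as.integer(att_idx))
    length(pathlines)
  }

  side_by_parent <- split(layout$side, vapply(layout$side, `[[`, "", "parent"))

  # main segments, in layout order; each chain starts at its ostium or at the
  # end of the previous segment (LAD and LCX chains start at the LM end)
  prev_end <- list()   # chain -> list(point, dir, index, npts)
  for (seg in layout$main) {
    lab <- seg$label
    len <- draw_len(lab)
    kids <- side_by_parent[[lab]]
    fracs <- if (is.null(kids)) numeric(0) else
      vapply(kids, `[[`, 0, "frac")
    interior <- fracs[fracs < 1]
    phis <- if (is.null(kids)) numeric(0) else
      vapply(kids, `[[`, 0, "phi")[fracs < 1]
    base_dir <- .unit(seg$dir)
    # +/- 5 degree seeded jitter on the base direction
    jit_ax <- .perp_at(base_dir, stats::runif(1, 0, 2 * pi))
    dir0 <- .unit(.rotate3(base_dir, jit_ax, stats::runif(1, -5, 5) * pi / 180))
    if (seg$chain == "RCA" && lab == "pRCA") {
      start <- ostium_right; par <- NULL; att <- NULL
    } else if (lab == "LM") {
      start <- ostium_left; par <- NULL; att <- NULL
    } else if (lab %in% c("pLAD", "pLCX")) {
      lm <- prev_end[["LM"]]
      start <- lm$point; par <- lm$index; att <- lm$npts
    } else {
      pe <- prev_end[[seg$chain]]
      start <- pe$point; par <- pe$index; att <- pe$npts
    }
    bp <- .build_path(start, dir0, len, interior, phis)
    idx <- add_pathline(lab, bp$points, par, att)
    built[[lab]] <- list(index = idx, path = bp)
    prev_end[[seg$chain]] <- list(point = bp$points[nrow(bp$points), ],
                                  index = idx, npts = nrow(bp$points))
    if (lab == "LM") prev_end[["LM"]] <- prev_end[["LM"]]
  }

  # side branches: straight, at 20-70 degrees from the local parent direction
  for (sb in layout$side) {
    pb <- built[[sb$parent]]
    att_idx <- pb$path$at_index(sb$frac)
    ppts <- pb$path$points
    att_pt <- ppts[att_idx, ]
    loc_dir <- if (att_idx < nrow(ppts)) .unit(ppts[min(att_idx + 2, nrow(ppts)), ] - att_pt)
               else .unit(att_pt - ppts[max(1, att_idx - 2), ])
    alpha <- stats::runif(1, 25, 60) * pi / 180
    if (sb$frac >= 1) alpha <- stats::runif(1, 25, 40) * pi / 180
    phi <- sb$phi + stats::runif(1, -0.15, 0.15)
    bdir <- .unit(.rotate3(loc_dir, .perp_at(loc_dir, phi), alpha))
    len <- draw_len(sb$label)
    bp <- .build_path(att_pt, bdir, len)
    add_pathline(sb$label, bp$points, pb$index, att_idx)
  }

  tree <- cat_tree(ostium_left, ostium_right, pathlines, parent, attach)

  # self-check: generated tree satisfies its own model
  for (i in seq_len(.tree_n(tree))) {
    lab <- tree$pathlines[[i]]$label
    r <- .model_range(model, lab)
    L <- pathline_length(tree$pathlines[[i]])
    if (L < r[1] - 1e-6 || L > r[2] + 1e-6)
      stop("phantom self-check failed: ", lab, " length ", round(L, 2), " outside range")
    ang <- .tree_branch_angle(tree, i)
    if (!is.na(ang) && ang > model$global$max_angle_deg)
      stop("phantom self-check failed: ", lab, " bifurcation angle ", round(ang, 1))
  }

  image <- .rasterize_phantom_volume(tree, spec)
  list(tree = tree, image = image, model = model)
}

.rasterize_phantom_volume <- function(tree, spec) {
  pts <- .tree_points(tree)
  if (is.null(spec$size)) {
    lo <- apply(pts, 2, min) - spec$margin_mm
    hi <- apply(pts, 2, max) + spec$margin_mm
    size <- as.integer(ceiling((hi - lo) / spec$spacing)) + 1L
    origin <- lo
  } else {
    size <- as.integer(spec$size)
    origin <- if (is.null(spec$origin)) apply(pts, 2, min) - spec$margin_mm
              else as.numeric(spec$origin)
  }
  img <- vessel_image(array(0L, dim = size), spec$spacing, origin)
  lin <- rasterize_tree(tree, img, clip = FALSE)
  img$voxels[lin] <- 1L
  img
}

#' Rasterize a tree into the voxel grid of a volume
#'
#' Samples every pathline edge densely (well below the voxel spacing) and maps
#' the samples to nearest voxel centres; along each pathline the resulting
#' skeleton is 26-connected and covers the voxel of every tree point.
#'
#' @param tree A `cat_tree`.
#' @param img A `vessel_image` providing the grid geometry.
#' @param clip Drop out-of-bounds samples (`TRUE`) or raise a generation error
#'   (`FALSE`).
#' @return Sorted unique linear voxel indices.
#' @export
rasterize_tree <- function(tree, img, clip = FALSE) {
  step <- 0.35 * min(img$spacing)
  samples <- do.call(rbind, lapply(tree$pathlines, function(p) {
    pts <- p$points
    if (nrow(pts) == 1) return(pts)
    do.call(rbind, lapply(seq_len(nrow(pts) - 1), function(k) {
      a <- pts[k, ]; b <- pts[k + 1, ]
      n <- max(2L, ceiling(.vnorm(b - a) / step) + 1L)
      t <- seq(0, 1, length.out = n)
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]), a[3] + t * (b[3] - a[3]))
    }))
  }))
  if (is.null(samples) || nrow(samples) == 0) return(integer(0))
  ijk <- .world_to_ijk(img, samples)
  inb <- .ijk_in_bounds(img, ijk)
  if (!clip && !all(inb)) stop("tree exceeds volume bounds during rasterization")
  ijk <- ijk[inb, , drop = FALSE]
  if (nrow(ijk) == 0) return(integer(0))
  sort(unique(.ijk_to_linear(img, ijk)))
}

# ---- degradation ------------------------------------------------------------

#' Specify a degradation of a phantom into a realistic initial extraction
#'
#' All entries are optional. `prune` shortens or removes labeled segments from
#' the tree (the volume keeps the full skeleton); `gap` removes foreground
#' voxels from the volume along a labeled span; `fragments`/`veins`/`stubs` add
#' spurious structure to the tree (disconnected fragments, branches with
#' bifurcation angles above 120 degrees, sub-millimetre stubs); `overlong`
#' extends labeled segments beyond their model maximum length.
#'
#' @param prune List of `list(label=, fraction=)`; `fraction >= 1` removes the
#'   segment and its descendants, otherwise the kept arc-length fraction.
#' @param gap List of `list(label=, gap_mm=, at=)` removing volume voxels along
#'   the label starting at arc fraction `at`.
#' @param fragments,veins,stubs Counts of spurious additions.
#' @param overlong List of `list(label=, extra_mm=)`.
#' @param seed Seed for the stochastic placements.
#' @return A list of class `degradation_spec`.
#' @export
degradation_spec <- function(prune = list(), gap = list(), fragments = 0,
                             veins = 0, stubs = 0, overlong = list(), seed = 1) {
  structure(list(prune = prune, gap = gap, fragments = as.integer(fragments),
                 veins = as.integer(veins), stubs = as.integer(stubs),
                 overlong = overlong, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a phantom tree/volume pair into an "initial extraction"
#'
#' @param tree Ground-truth `cat_tree` (not modified).
#' @param image Ground-truth `vessel_image`.
#' @param dspec A [degradation_spec()].
#' @return List with degraded `tree` and `image`.
#' @export
degrade_phantom <- function(tree, image, dspec = degradation_spec()) {
  .with_seed(dspec$seed, function() .degrade_impl(tree, image, dspec))
}

.degrade_impl <- function(tree, image, dspec) {
  find_label <- function(tr, lab) {
    idx <- which(.tree_labels(tr) == lab)
    if (!length(idx)) stop("cannot degrade label absent from tree: ", lab)
    idx[1]
  }
  for (pr in dspec$prune) {
    i <- find_label(tree, pr$label)
    if (is.null(pr$fraction) || pr$fraction >= 1) {
      if (is.na(tree$parent[i]))
        stop("refusing to prune an ostium-rooted segment entirely: ", pr$label)
      tree <- .tree_drop(tree, i, cascade = TRUE)
    } else {
      pts <- tree$pathlines[[i]]$points
      new_len <- .poly_length(pts) * pr$fraction
      cum <- .cum_arc(pts)
      keep_n <- max(1L, sum(cum <= new_len + 1e-9))
      lost <- which(!is.na(tree$parent) & tree$parent == i & tree$attach > keep_n)
      tree$pathlines[[i]]$points <- prune_to_length(pts, new_len)
      if (length(lost)) tree <- .tree_drop(tree, lost, cascade = TRUE)
    }
  }
  for (gp in dspec$gap) {
    i <- find_label(tree, gp$label)
    pts <- tree$pathlines[[i]]$points
    L <- .poly_length(pts)
    at <- if (is.null(gp$at)) 0.4 else gp$at
    s0 <- min(at * L, max(0, L - gp$gap_mm))
    s_samp <- seq(s0, min(L, s0 + gp$gap_mm), by = 0.3 * min(image$spacing))
    span <- t(vapply(s_samp, function(s) .point_at_arc(pts, s), numeric(3)))
    fg_lin <- which(image$voxels == 1L)
    fg_w <- .ijk_to_world(image, .linear_to_ijk(image, fg_lin))
    hit <- .min_dist_to_set(fg_w, span) <= 0.75 * max(image$spacing)
    image$voxels[fg_lin[hit]] <- 0L
  }
  labeled <- which(!is.na(.tree_labels(tree)))
  rand_point_on <- function() {
    i <- .sample1(labeled)
    pts <- tree$pathlines[[i]]$points
    k <- .sample1(seq(2, max(2, nrow(pts) - 1)))
    list(i = i, k = k, pt = pts[k, ],
         dir = .unit(pts[min(k + 1, nrow(pts)), ] - pts[max(1, k - 1), ]))
  }
  add_branch <- function(i, k, pt, dir, len) {
    bp <- .build_path(pt, dir, len)
    tree$pathlines[[length(tree$pathlines) + 1]] <<- list(points = bp$points,
                                                          label = NA_character_)
    tree$parent <<- c(tree$parent, i)
    tree$attach <<- c(tree$attach, as.integer(k))
    invisible(NULL)
  }
  for (f in seq_len(dspec$fragments)) {
    rp <- rand_point_on()
    off <- .perp_at(rp$dir, stats::runif(1, 0, 2 * pi)) * stats::runif(1, 8, 15)
    dir <- .perp_at(rp$dir, stats::runif(1, 0, 2 * pi))
    bp <- .build_path(rp$pt + off, dir, stats::runif(1, 3, 8))
    tree$pathlines[[length(tree$pathlines) + 1]] <- list(points = bp$points,
                                                         label = NA_character_)
    tree$parent <- c(tree$parent, NA_integer_)
    tree$attach <- c(tree$attach, NA_integer_)
  }
  for (v in seq_len(dspec$veins)) {
    rp <- rand_point_on()
    theta <- stats::runif(1, 135, 170) * pi / 180
    dir <- .unit(.rotate3(rp$dir, .perp_at(rp$dir, stats::runif(1, 0, 2 * pi)), theta))
    add_branch(rp$i, rp$k, rp$pt, dir, stats::runif(1, 5, 15))
  }
  for (s in seq_len(dspec$stubs)) {
    rp <- rand_point_on()
    theta <- stats::runif(1, 30, 80) * pi / 180
    dir <- .unit(.rotate3(rp$dir, .perp_at(rp$dir, stats::runif(1, 0, 2 * pi)), theta))
    add_branch(rp$i, rp$k, rp$pt, dir, stats::runif(1, 0.3, 0.9))
  }
  for (ov in dspec$overlong) {
    i <- find_label(tree, ov$label)
    pts <- tree$pathlines[[i]]$points
    end_dir <- .unit(pts[nrow(pts), ] - pts[max(1, nrow(pts) - 2), ])
    ext_dir <- .unit(.rotate3(end_dir, .perp_at(end_dir, stats::runif(1, 0, 2 * pi)),
                              8 * pi / 180))
    bp <- .build_path(pts[nrow(pts), ], ext_dir, ov$extra_mm)
    tree$pathlines[[i]]$points <- rbind(pts, bp$points[-1, , drop = FALSE])
  }
  validate_tree(tree)
  list(tree = tree, image = image)
}

#' Draw a randomized degradation specification
#'
#' Samples a plausible mixture of extraction failures for robustness testing:
#' one or two prunes (full removal of a side branch, or distal shortening of a
#' main segment), up to two vein-like branches, up to two floating fragments,
#' and occasionally a sub-millimetre stub or an overlong tail.
#'
#' @param model The `cat_model` the phantom was generated from.
#' @param seed Integer seed.
#' @return A [degradation_spec()].
#' @export
random_degradation_spec <- function(model, seed = 1) {
  .with_seed(seed, function() {
    df <- model$labels
    side <- df$name[df$position_class == "side"]
    distal <- df$name[df$position_class == "distal"]
    prune <- list()
    n_pr <- sample(1:2, 1)
    used <- character(0)
    for (k in seq_len(n_pr)) {
      if (stats::runif(1) < 0.6) {
        pool <- setdiff(side, used)
        if (!length(pool)) next
        lab <- .sample1(pool)
        prune[[length(prune) + 1]] <- list(label = lab, fraction = 1)
      } else {
        pool <- setdiff(distal, used)
        if (!length(pool)) next
        lab <- .sample1(pool)
        prune[[length(prune) + 1]] <- list(label = lab,
                                           fraction = stats::runif(1, 0.3, 0.6))
      }
      used <- c(used, lab)
    }
    # full removals first so a later shortening cannot orphan a chosen label
    if (length(prune) > 1)
      prune <- prune[order(-vapply(prune, function(p) p$fraction, numeric(1)))]
    pruned <- vapply(prune, `[[`, "", "label")
    overlong <- list()
    # avoid labels removed above, or side branches a shortened parent may drop
    free_side <- setdiff(side, pruned)
    free_side <- free_side[!df$parent[match(free_side, df$name)] %in% pruned]
    if (stats::runif(1) < 0.3 && length(free_side)) {
      lab <- .sample1(free_side)
      overlong[[1]] <- list(label = lab,
                            extra_mm = df$length_max[match(lab, df$name)] +
                              stats::runif(1, 5, 15))
    }
    degradation_spec(prune = prune,
                     fragments = sample(0:2, 1),
                     veins = sample(0:2, 1),
                     stubs = sample(0:1, 1),
                     overlong = overlong,
                     seed = seed + 7919L)
  })
}
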