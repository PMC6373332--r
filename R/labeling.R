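# Baseline anatomical labeler and dominance determination. This is a
# deterministic stand-in with a pluggable surface: main branches are identified
# as the longest ostium-to-leaf pathline chains, divided into proximal/mid/
# distal segments, and side branches are matched by attachment position along
# their parent segment.

#' Parameters for the baseline labeler
#'
#' @param anterior_axis Unit direction used to disambiguate the LAD (more
#'   anterior/apical) from the LCX after the left main bifurcation.
#' @param tol Ostium connection tolerance in mm.
#' @return A named list.
#' @export
labeling_params <- function(anterior_axis = c(0, -1, 0), tol = 1) {
  list(anterior_axis = .unit(anterior_axis), tol = tol)
}

# ostium-to-leaf pathline chains with arc lengths. Returns, per leaf pathline,
# list(chain = pathline indices root..leaf, arc = traversed arc length in mm)
.tree_chains <- function(tree, roots) {
  n <- .tree_n(tree)
  kids <- lapply(seq_len(n), function(i) which(!is.na(tree$parent) & tree$parent == i))
  out <- list()
  walk <- function(i, chain, arc) {
    ch <- kids[[i]]
    full <- .poly_length(tree$pathlines[[i]]$points)
    if (length(ch) == 0) {
      out[[length(out) + 1]] <<- list(chain = c(chain, i), arc = arc + full)
      return(invisible(NULL))
    }
    # the pathline's own distal end is also a leaf unless a child attaches there
    cum <- .cum_arc(tree$pathlines[[i]]$points)
    ends_open <- all(tree$attach[ch] < nrow(tree$pathlines[[i]]$points))
    if (ends_open)
      out[[length(out) + 1]] <<- list(chain = c(chain, i), arc = arc + full)
    for (c2 in ch) walk(c2, c(chain, i), arc + cum[tree$attach[c2]])
  }
  for (r in roots) walk(r, integer(0), 0)
  out
}

#' Assign anatomical labels to a coronary tree
#'
#' Clears existing labels and reassigns them under `model`: the RCA main branch
#' is the longest ostium-to-leaf chain of the right tree; on the left, the LM is
#' the root pathline and the two longest chains through distinct LM children
#' become the LAD (larger projection onto the anterior axis) and the LCX. Main
#' chains are divided into proximal/mid/distal segments by assigning the
#' segment labels to the chain pathlines in order; chain pathlines beyond the
#' distal label join the side-branch pool. Side branches are matched to the model's
#' side labels of the main segment they attach to, in attachment order.
#' Disconnected pathlines and unmatched branches stay unlabeled.
#'
#' @param tree A `cat_tree` connected to at least one ostium.
#' @param model A `cat_model`.
#' @param params See [labeling_params()].
#' @return The tree with labels assigned.
#' @export
assign_labels <- function(tree, model, params = labeling_params()) {
  n <- .tree_n(tree)
  for (i in seq_len(n)) tree$pathlines[[i]]$label <- NA_character_
  if (n == 0) return(tree)
  side <- vapply(seq_len(n), function(i) .tree_root_side(tree, i, params$tol), character(1))
  if (all(is.na(side))) stop("no pathline reaches an ostium; cannot assign labels")
  roots <- which(is.na(tree$parent) & !is.na(side))

  set_label <- function(i, lab) tree$pathlines[[i]]$label <<- lab

  assign_main <- function(chain_idx, seq_labels) {
    k <- length(chain_idx); m <- length(seq_labels)
    # the first chain pathlines take the segment labels in order; chain
    # pathlines beyond the distal label fall into the side-branch pool
    for (j in seq_len(min(k, m))) set_label(chain_idx[j], seq_labels[j])
    if (k > m) chain_idx[(m + 1):k] else integer(0)
  }

  # ---- right tree: RCA ----
  r_roots <- roots[side[roots] == "right"]
  if (length(r_roots)) {
    chains <- .tree_chains(tree, r_roots)
    best <- chains[[which.max(vapply(chains, `[[`, 0, "arc"))]]
    assign_main(best$chain, .main_sequence(model, "RCA"))
  }

  # ---- left tree: LM, LAD, LCX ----
  l_roots <- roots[side[roots] == "left"]
  if (length(l_roots)) {
    # LM root pathline: the left root nearest the left ostium
    d <- vapply(l_roots, function(i)
      .vnorm(tree$pathlines[[i]]$points[1, ] - tree$ostium_left), numeric(1))
    lm <- l_roots[which.min(d)]
    set_label(lm, "LM")
    lm_kids <- which(!is.na(tree$parent) & tree$parent == lm)
    if (length(lm_kids)) {
      kid_best <- lapply(lm_kids, function(k) {
        chains <- .tree_chains(tree, k)
        chains[[which.max(vapply(chains, `[[`, 0, "arc"))]]
      })
      ord <- order(vapply(kid_best, `[[`, 0, "arc"), decreasing = TRUE)
      picks <- kid_best[ord[seq_len(min(2, length(ord)))]]
      mean_dir <- function(chain) {
        pts <- .tree_points(tree, chain)
        .unit(pts[nrow(pts), ] - pts[1, ])
      }
      proj <- vapply(picks, function(p) sum(mean_dir(p$chain) * params$anterior_axis),
                     numeric(1))
      if (length(picks) == 2) {
        lad <- picks[[which.max(proj)]]; lcx <- picks[[which.min(proj)]]
        assign_main(lad$chain, .main_sequence(model, "LAD")[-1])
        assign_main(lcx$chain, .main_sequence(model, "LCX"))
      } else if (length(picks) == 1) {
        if (proj[1] >= 0) assign_main(picks[[1]]$chain, .main_sequence(model, "LAD")[-1])
        else assign_main(picks[[1]]$chain, .main_sequence(model, "LCX"))
      }
    }
  }

  # ---- side branches: match by attachment position on labeled main segments ----
  labs <- .tree_labels(tree)
  main_labels <- unique(unlist(lapply(c("RCA", "LAD", "LCX"),
                                      function(s) .main_sequence(model, s))))
  cand <- which(is.na(labs) & !is.na(tree$parent) & !is.na(side))
  cand <- cand[labs[tree$parent[cand]] %in% main_labels]
  if (length(cand)) {
    par_lab <- labs[tree$parent[cand]]
    att_arc <- vapply(seq_along(cand), function(j) {
      p <- tree$parent[cand[j]]
      .cum_arc(tree$pathlines[[p]]$points)[tree$attach[cand[j]]]
    }, numeric(1))
    for (pl in unique(par_lab)) {
      slots <- .side_labels_of(model, pl)
      if (!length(slots)) next
      here <- cand[par_lab == pl]
      here <- here[order(att_arc[par_lab == pl])]
      for (j in seq_len(min(length(here), length(slots)))) set_label(here[j], slots[j])
    }
  }
  tree
}

#' Determine the dominance type of a coronary tree
#'
#' The dominance is decided by the presence of the posterior descending artery
#' (PDA): labeled under the RD model, a present RPDA in the RCA subtree means
#' right dominance; otherwise, labeled under the LD model, a present LPDA in
#' the LCX subtree means left dominance. When neither PDA is found (e.g. both
#' distal territories incompletely extracted) the tree is classified RD and
#' flagged provisional so the caller can re-check after improvement.
#'
#' @param tree A `cat_tree`.
#' @param model_rd,model_ld The RD and LD `cat_model`s.
#' @param params See [labeling_params()].
#' @return List with `dominance` (`"RD"`/`"LD"`), `provisional` (logical) and
#'   `tree` (the tree labeled under the chosen model).
#' @export
determine_dominance <- function(tree, model_rd = load_model(dominance = "RD"),
                                model_ld = load_model(dominance = "LD"),
                                params = labeling_params()) {
  t_rd <- assign_labels(tree, model_rd, params)
  if ("RPDA" %in% .tree_labels(t_rd))
    return(list(dominance = "RD", provisional = FALSE, tree = t_rd))
  t_ld <- assign_labels(tree, model_ld, params)
  if ("LPDA" %in% .tree_labels(t_ld))
    return(list(dominance = "LD", provisional = FALSE, tree = t_ld))
  list(dominance = "RD", provisional = TRUE, tree = t_rd)
}
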