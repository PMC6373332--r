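# Quality score of a labeled coronary tree against the anatomical statistical
# model, plus the score-delta state machine that drives keep / keep-with-debt /
# revert decisions.

#' Quality score of a labeled coronary tree
#'
#' Weighted-coverage score in `[0, 100]` (formula version `wcov-1`):
#'
#' \deqn{S = 100 \cdot \max(0, \min(1, \sum_l w_l c_l / \sum_l w_l - P))}
#'
#' where `l` ranges over the model labels, `w_l` is the label weight and the
#' correctness term `c_l` is 0 when the label is absent, 1 when present with
#' total length inside its `[length_min, length_max]` range, and linearly
#' discounted (clamped to `[0, 1]`) by the relative length violation otherwise:
#' `L/length_min` when too short, `1 - (L - length_max)/length_max` when too
#' long. The penalty `P` adds `0.5 * U / (U + T)` for unlabeled pathline length
#' `U` against labeled length `T`, plus `0.05` per labeled segment whose
#' bifurcation angle exceeds the model maximum. A tree with exactly the model
#' topology, all lengths in range and no unlabeled structure scores exactly
#' 100; an empty tree scores 0. Adding a missing in-range label never lowers
#' the score, and removing unlabeled spurious structure never lowers it.
#'
#' @param tree A labeled `cat_tree`.
#' @param model The `cat_model` matching the tree's dominance labels.
#' @param tol Ostium connection tolerance in mm.
#' @return Numeric score in `[0, 100]`, with attribute `"breakdown"` (a data
#'   frame of per-label weight, length, and correctness).
#' @export
quality_score <- function(tree, model, tol = 1) {
  labs <- .tree_labels(tree)
  known <- labs[!is.na(labs)]
  if (length(setdiff(known, model$labels$name)))
    stop("tree labels not in model (dominance mismatch?): ",
         paste(setdiff(known, model$labels$name), collapse = ", "))
  conn <- connected_components(tree, tol)$connected
  df <- model$labels
  lab_len <- vapply(df$name, function(l) {
    idx <- intersect(which(labs == l), conn)
    if (!length(idx)) return(NA_real_)
    sum(vapply(idx, function(i) .poly_length(tree$pathlines[[i]]$points), numeric(1)))
  }, numeric(1))
  cl <- vapply(seq_len(nrow(df)), function(k) {
    L <- lab_len[k]
    if (is.na(L)) return(0)
    if (L < df$length_min[k]) return(max(0, min(1, L / df$length_min[k])))
    if (L > df$length_max[k]) return(max(0, 1 - (L - df$length_max[k]) / df$length_max[k]))
    1
  }, numeric(1))
  coverage <- sum(df$weight * cl) / sum(df$weight)
  lab_total <- sum(lab_len, na.rm = TRUE)
  unlab_idx <- which(is.na(labs))
  U <- if (length(unlab_idx))
    sum(vapply(unlab_idx, function(i) .poly_length(tree$pathlines[[i]]$points), numeric(1)))
  else 0
  spur_pen <- if (U > 0) 0.5 * U / (U + lab_total) else 0
  ang_bad <- 0L
  for (i in intersect(which(!is.na(labs)), conn)) {
    a <- .tree_branch_angle(tree, i)
    if (!is.na(a) && a > model$global$max_angle_deg) ang_bad <- ang_bad + 1L
  }
  score <- 100 * max(0, min(1, coverage - spur_pen - 0.05 * ang_bad))
  attr(score, "breakdown") <- data.frame(
    label = df$name, weight = df$weight, length_mm = lab_len,
    correctness = cl, stringsAsFactors = FALSE)
  attr(score, "penalty") <- c(unlabeled = spur_pen, angle = 0.05 * ang_bad)
  score
}

#' Initialize the quality-score state machine
#'
#' Tracks `S_old`/`S_new`/`S_delta` per operation, the accumulated score change
#' over kept operations, the revert threshold `T_S_delta < 0`, and the
#' best-scoring tree snapshot seen so far.
#'
#' @param tree The current tree (stored as the first snapshot).
#' @param score Its quality score.
#' @param t_s_delta Negative revert threshold.
#' @return A list of class `quality_state`.
#' @export
quality_state <- function(tree, score, t_s_delta = -2) {
  stopifnot(t_s_delta < 0)
  structure(list(tree = tree, score = as.numeric(score),
                 t_s_delta = t_s_delta, s_delta_sum = 0,
                 best_score = as.numeric(score), best_tree = tree,
                 last = NULL),
            class = "quality_state")
}

# classify a score change: keep / keep-with-debt / revert
.scored_decision <- function(s_delta, t_s_delta, tol = 1e-9) {
  if (s_delta > tol) "kept"
  else if (s_delta >= t_s_delta) "kept-with-debt"
  else "reverted"
}

#' Apply a scored improvement operation to the quality state
#'
#' Implements the keep / keep-with-debt / revert rule: a positive score change
#' is kept; a decrease no worse than the threshold `T_S_delta` is kept and its
#' debt added to the accumulated score change (a small decrease may be improved
#' by a later operation); a decrease below the threshold reverts the tree to the
#' stored snapshot and the operation is marked skipped. After every decision
#' the snapshot is refreshed and the best-scoring tree is updated.
#'
#' @param state A `quality_state`.
#' @param new_tree The tree after the candidate operation.
#' @param new_score Its quality score.
#' @return Updated state; `state$last` holds `decision`, `s_old`, `s_new`,
#'   `s_delta`, and `state$stop_accumulated` is `TRUE` once the accumulated
#'   score change has fallen below `T_S_delta`.
#' @export
apply_scored <- function(state, new_tree, new_score) {
  s_old <- state$score
  s_delta <- as.numeric(new_score) - s_old
  decision <- .scored_decision(s_delta, state$t_s_delta)
  if (decision == "reverted") {
    # tree and score stay at the stored snapshot
  } else {
    state$tree <- new_tree
    state$score <- as.numeric(new_score)
    state$s_delta_sum <- state$s_delta_sum + s_delta
    if (state$score > state$best_score + 1e-12) {
      state$best_score <- state$score
      state$best_tree <- new_tree
    }
  }
  state$last <- list(decision = decision, s_old = s_old,
                     s_new = as.numeric(new_score), s_delta = s_delta)
  state$stop_accumulated <- state$s_delta_sum < state$t_s_delta
  state
}
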