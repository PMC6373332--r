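# The improvement controller: orchestrates coarse improvement, main-branch
# recovery, dominance/PDA evaluation and the sub-tree traversal over
# iterations, with every operation passing through the quality-score state
# machine and its keep / keep-with-debt / revert rule.

#' Controller parameters
#'
#' @param t_s_delta Negative revert threshold on the per-operation score change.
#' @param max_iterations Maximum number of improvement iterations (one
#'   iteration = one pass over all sub-trees); guards against over-extraction.
#' @param search See [search_params()].
#' @param labeling See [labeling_params()] (the ostium tolerance is derived
#'   from the volume spacing at run time).
#' @return A named list of class `controller_params`.
#' @export
controller_params <- function(t_s_delta = -2, max_iterations = 10,
                              search = search_params(),
                              labeling = labeling_params()) {
  stopifnot(t_s_delta < 0, max_iterations >= 1)
  structure(list(t_s_delta = t_s_delta, max_iterations = as.integer(max_iterations),
                 search = search, labeling = labeling),
            class = "controller_params")
}

#' Automatically improve an extracted coronary artery tree
#'
#' Runs the full model-guided correction: per iteration, (a) the coarse
#' improvement (orphans, global lengths, bifurcation angles) as one scored
#' operation; (b) recovery of absent main branches by extension; (c) dominance
#' determination, checked against the presence and length of the posterior
#' descending artery, with PDA repair and model re-selection if the dominance
#' flips; (d) the sub-tree traversal root-to-leaf with the child-skip rule,
#' applying deletion/extension per finding. Every operation is kept, kept with
#' debt, or reverted according to its score change against `t_s_delta`; a
#' reverted finding is skipped for the rest of the run. The process stops when
#' an iteration leaves the score unchanged, when the accumulated score change
#' falls below the threshold, or at `max_iterations`; the stored snapshot with
#' the highest score is returned, so the final score is never below the
#' initial one.
#'
#' @param tree The initial extracted `cat_tree`.
#' @param image The binary vesselness `vessel_image`.
#' @param params See [controller_params()].
#' @param model_rd,model_ld The RD and LD anatomical statistical models.
#' @return List with `tree` (final labeled tree), `log` (data frame, one row
#'   per operation), `initial_score`, `final_score`, `iterations`, `dominance`
#'   and `stop_reason`.
#' @export
improve <- function(tree, image, params = controller_params(),
                    model_rd = load_model(dominance = "RD"),
                    model_ld = load_model(dominance = "LD")) {
  validate_tree(tree)
  tol <- 2 * max(image$spacing)
  lp <- params$labeling; lp$tol <- tol
  models <- list(RD = model_rd, LD = model_ld)

  relabel_score <- function(tr, model) {
    tr2 <- tryCatch(assign_labels(tr, model, lp), error = function(e) tr)
    list(tree = tr2, score = as.numeric(tryCatch(quality_score(tr2, model, tol),
                                                 error = function(e) 0)))
  }

  dom <- tryCatch(determine_dominance(tree, model_rd, model_ld, lp),
                  error = function(e) list(dominance = "RD", provisional = TRUE))
  model <- models[[dom$dominance]]
  cur <- relabel_score(tree, model)
  state <- quality_state(cur$tree, cur$score, params$t_s_delta)
  initial_score <- cur$score
  log <- list()
  skipped <- character(0)
  stop_reason <- NULL
  iterations <- 0L
  it <- 0L

  present_labels <- function() {
    labs <- .tree_labels(state$tree)
    conn <- connected_components(state$tree, tol)$connected
    unique(labs[intersect(which(!is.na(labs)), conn)])
  }

  # run one candidate operation through the score state machine; returns a list
  # with `changed`, `decision`
  do_op <- function(stage, label, kind, rule, fun) {
    key <- paste0(label, "|", kind)
    if (!is.na(label) && key %in% skipped)
      return(list(changed = FALSE, decision = "skipped"))
    new_tree <- tryCatch(fun(state$tree), error = function(e) NULL)
    if (is.null(new_tree)) return(list(changed = FALSE, decision = "failed"))
    rs <- relabel_score(new_tree, model)
    changed <- !identical(.tree_canonical(rs$tree), .tree_canonical(state$tree))
    if (!changed) {
      log[[length(log) + 1]] <<- data.frame(
        iteration = it, stage = stage, label = label, kind = kind,
        rule = if (is.null(rule) || is.na(rule)) NA_integer_ else as.integer(rule),
        dominance = model$dominance,
        s_old = state$score, s_new = state$score, s_delta = 0,
        decision = "no-change", s_delta_sum = state$s_delta_sum,
        stringsAsFactors = FALSE)
      return(list(changed = FALSE, decision = "no-change"))
    }
    state <<- apply_scored(state, rs$tree, rs$score)
    dec <- state$last$decision
    if (dec == "reverted" && !is.na(label)) skipped <<- c(skipped, key)
    log[[length(log) + 1]] <<- data.frame(
      iteration = it, stage = stage, label = label, kind = kind,
      rule = if (is.null(rule) || is.na(rule)) NA_integer_ else as.integer(rule),
      dominance = model$dominance,
      s_old = state$last$s_old, s_new = state$last$s_new,
      s_delta = state$last$s_delta, decision = dec,
      s_delta_sum = state$s_delta_sum, stringsAsFactors = FALSE)
    list(changed = TRUE, decision = dec)
  }

  apply_finding <- function(stage, f) {
    if (f$op == "deletion") {
      do_op(stage, f$label, f$kind, f$rule,
            function(tr) delete_segment(tr, f, model))
    } else {
      do_op(stage, f$label, f$kind, f$rule,
            function(tr) extend_tree(tr, image, f, model, params$search)$tree)
    }
  }

  sync_model <- function(new_dom) {
    if (new_dom != model$dominance) {
      model <<- models[[new_dom]]
      rs <- relabel_score(state$tree, model)
      state$tree <<- rs$tree
      state$score <<- rs$score
      if (rs$score > state$best_score) {
        state$best_score <<- rs$score; state$best_tree <<- rs$tree
      }
    }
  }

  for (it_i in seq_len(params$max_iterations)) {
    it <- it_i
    iterations <- it
    log_before <- length(log)

    # coarse improvement on all vessels, as one scored operation
    do_op("coarse", NA_character_, "coarse", NA_integer_,
          function(tr) coarse_improve(tr, model, tol))
    if (isTRUE(state$stop_accumulated)) { stop_reason <- "accumulated_decrease"; break }

    # L1: the three main branches
    for (st in c("RCA", "LAD", "LCX")) {
      mseq <- .main_sequence(model, st)
      for (attempt in 1:3) {
        if (any(mseq %in% present_labels())) break
        f <- list(label = mseq[1], kind = "absent", op = "extension", rule = 2L)
        r <- apply_finding("main", f)
        if (!r$changed || r$decision == "reverted") break
      }
      if (isTRUE(state$stop_accumulated)) break
    }
    if (isTRUE(state$stop_accumulated)) { stop_reason <- "accumulated_decrease"; break }

    # L2: dominance type, checked via the presence and correctness of the PDA
    pda_done <- character(0)
    try_pda <- function() {
      # improve the current model's PDA until present with a correct length;
      # returns TRUE when it is
      pda <- .pda_label(model)
      for (attempt in 1:4) {
        pres <- present_labels()
        r <- .model_range(model, pda)
        if (pda %in% pres) {
          labs <- .tree_labels(state$tree)
          L <- sum(vapply(which(labs == pda), function(i)
            .poly_length(state$tree$pathlines[[i]]$points), numeric(1)))
          if (L >= r[1] - 1e-9 && L <= r[2] + 1e-9) return(TRUE)
          f <- if (L < r[1]) list(label = pda, kind = "too_short",
                                  op = "extension", rule = 3L)
               else list(label = pda, kind = "too_long", op = "deletion",
                         rule = NA_integer_)
        } else {
          f <- list(label = pda, kind = "absent", op = "extension", rule = 1L)
        }
        pda_done <<- c(pda_done, paste0(f$label, "|", f$kind))
        res <- apply_finding("pda", f)
        if (!res$changed || res$decision == "reverted") break
        if (isTRUE(state$stop_accumulated)) break
      }
      .pda_label(model) %in% present_labels()
    }
    dm <- tryCatch(determine_dominance(state$tree, model_rd, model_ld, lp),
                   error = function(e) list(dominance = model$dominance,
                                            provisional = TRUE))
    sync_model(dm$dominance)
    pda_ok <- try_pda()
    if (!pda_ok && isTRUE(dm$provisional) && !isTRUE(state$stop_accumulated)) {
      # RD was only a default (neither PDA extracted): hypothesize the other
      # dominance and search for its PDA before settling
      sync_model(setdiff(c("RD", "LD"), model$dominance))
      if (!try_pda()) sync_model(dm$dominance)
    }
    dm2 <- tryCatch(determine_dominance(state$tree, model_rd, model_ld, lp),
                    error = function(e) list(dominance = model$dominance))
    sync_model(dm2$dominance)
    if (isTRUE(state$stop_accumulated)) { stop_reason <- "accumulated_decrease"; break }

    # L3: sub-tree traversal, root label to leaf label
    fs <- detect_inaccuracies(state$tree, model, tol)
    for (f in fs) {
      key <- paste0(f$label, "|", f$kind)
      if (key %in% c(skipped, pda_done)) next
      apply_finding("subtree", f)
      if (isTRUE(state$stop_accumulated)) break
    }
    if (isTRUE(state$stop_accumulated)) { stop_reason <- "accumulated_decrease"; break }

    # stopping: no score change across the whole iteration
    new_entries <- if (length(log) > log_before)
      do.call(rbind, log[(log_before + 1):length(log)]) else NULL
    if (is.null(new_entries) ||
        all(abs(new_entries$s_delta) <= 1e-9)) {
      stop_reason <- "no_change"
      break
    }
  }
  if (is.null(stop_reason)) stop_reason <- "max_iterations"

  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(iteration = integer(0), stage = character(0), label = character(0),
               kind = character(0), rule = integer(0), dominance = character(0),
               s_old = numeric(0), s_new = numeric(0), s_delta = numeric(0),
               decision = character(0), s_delta_sum = numeric(0),
               stringsAsFactors = FALSE)
  list(tree = state$best_tree, log = log_df,
       initial_score = initial_score, final_score = state$best_score,
       iterations = iterations, dominance = model$dominance,
       stop_reason = stop_reason)
}

#' Replay the kept operations of an improvement log
#'
#' Re-applies, in order, every operation the controller kept (including
#' kept-with-debt) to the initial tree, skipping reverted and no-change
#' entries, and returns the reconstructed tree states. Because all operations
#' and tie-breaks are deterministic, the snapshot with the highest score equals
#' the tree returned by [improve()].
#'
#' @param tree The same initial tree passed to [improve()].
#' @param image The same vesselness volume.
#' @param log The log data frame returned by [improve()].
#' @param params The same [controller_params()].
#' @param model_rd,model_ld The same models.
#' @return List with `final` (the best-scoring reconstructed tree) and
#'   `scores` (numeric vector: initial score followed by the score after each
#'   kept operation).
#' @export
replay_improvement <- function(tree, image, log, params = controller_params(),
                               model_rd = load_model(dominance = "RD"),
                               model_ld = load_model(dominance = "LD")) {
  tol <- 2 * max(image$spacing)
  lp <- params$labeling; lp$tol <- tol
  models <- list(RD = model_rd, LD = model_ld)
  dom <- tryCatch(determine_dominance(tree, model_rd, model_ld, lp),
                  error = function(e) list(dominance = "RD"))
  model <- models[[dom$dominance]]
  cur <- assign_labels(tree, model, lp)
  score <- as.numeric(quality_score(cur, model, tol))
  best_tree <- cur; best_score <- score
  scores <- score
  kept <- log[log$decision %in% c("kept", "kept-with-debt"), , drop = FALSE]
  if (nrow(kept)) {
    for (r in seq_len(nrow(kept))) {
      model <- models[[kept$dominance[r]]]
      cur <- assign_labels(cur, model, lp)
      if (kept$stage[r] == "coarse") {
        cur <- coarse_improve(cur, model, tol)
      } else {
        f <- list(label = kept$label[r], kind = kept$kind[r],
                  rule = kept$rule[r],
                  op = if (kept$kind[r] %in% c("too_long", "bad_angle"))
                    "deletion" else "extension")
        cur <- if (f$op == "deletion") delete_segment(cur, f, model)
               else extend_tree(cur, image, f, model, params$search)$tree
      }
      cur <- assign_labels(cur, model, lp)
      score <- as.numeric(quality_score(cur, model, tol))
      scores <- c(scores, score)
      if (score > best_score + 1e-12) { best_score <- score; best_tree <- cur }
    }
  }
  list(final = best_tree, scores = scores, final_score = best_score)
}
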