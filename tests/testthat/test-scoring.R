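test_that("a model-identical tree scores exactly 100 and an empty tree 0", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  expect_equal(as.numeric(quality_score(ph$tree, ph$model)), 100)
  empty <- cat_tree(c(70, 0, 0), c(0, 0, 0), list())
  expect_equal(as.numeric(quality_score(empty, ph$model)), 0)
})

test_that("removing one label lowers the score by its normalized weight", {
  ph <- generate_phantom(phantom_spec(dominance = "RD", seed = 2))
  df <- ph$model$labels
  w_sum <- sum(df$weight)
  # leaf side slots: the removed label is exactly the one reported missing
  for (lab in c("RPLB", "D2")) {
    deg <- degrade_phantom(ph$tree, ph$image,
                           degradation_spec(prune = list(list(label = lab,
                                                              fraction = 1))))
    relab <- assign_labels(deg$tree, ph$model)
    got <- as.numeric(quality_score(relab, ph$model))
    w <- df$weight[df$name == lab]
    # hand evaluation of the documented formula: 100 * (1 - w / sum(w))
    expect_equal(got, 100 * (1 - w / w_sum), tolerance = 1e-9)
    expect_equal(w_sum, 12.4)
  }
  # removing a non-leaf side slot (RPDA) shifts the later slot onto its branch,
  # so the reported missing label is the last slot (RPLB)
  deg <- degrade_phantom(ph$tree, ph$image,
                         degradation_spec(prune = list(list(label = "RPDA",
                                                            fraction = 1))))
  relab <- assign_labels(deg$tree, ph$model)
  br <- attr(quality_score(relab, ph$model), "breakdown")
  expect_equal(br$correctness[br$label == "RPLB"], 0)
})

test_that("score is monotone in adding missing labels and removing spurious ones", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  deg <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(prune = list(list(label = "RPDA", fraction = 1),
                                  list(label = "RPLB", fraction = 1)),
                     fragments = 1, seed = 3))
  partial <- assign_labels(deg$tree, ph$model)
  s_partial <- as.numeric(quality_score(partial, ph$model))
  # removing the unlabeled spurious fragment never decreases the score
  frag <- which(is.na(tree_labels(partial)))
  no_frag <- catimprove:::.tree_drop(partial, frag)
  expect_gte(as.numeric(quality_score(no_frag, ph$model)), s_partial - 1e-12)
  # the full tree (all labels present, in range) dominates both
  expect_gte(as.numeric(quality_score(ph$tree, ph$model)),
             as.numeric(quality_score(no_frag, ph$model)))
})

test_that("length violations discount the label's correctness term", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  deg <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(overlong = list(list(label = "OM1", extra_mm = 30)), seed = 4))
  relab <- assign_labels(deg$tree, ph$model)
  s <- quality_score(relab, ph$model)
  br <- attr(s, "breakdown")
  expect_lt(br$correctness[br$label == "OM1"], 1)
  expect_lt(as.numeric(s), 100)
})

test_that("scoring a tree under the wrong-dominance model errors", {
  ld <- generate_phantom(phantom_spec(dominance = "LD", seed = 1))
  rd_model <- load_model(dominance = "RD")
  expect_error(quality_score(ld$tree, rd_model), "mismatch|not in model")
})

test_that("scores stay within [0, 100] on arbitrary degraded trees", {
  for (s in 1:5) {
    ph <- generate_phantom(phantom_spec(seed = 400 + s))
    deg <- degrade_phantom(ph$tree, ph$image,
                           random_degradation_spec(ph$model, seed = s))
    relab <- assign_labels(deg$tree, ph$model)
    sc <- as.numeric(quality_score(relab, ph$model))
    expect_gte(sc, 0); expect_lte(sc, 100)
  }
})

test_that("apply_scored keeps, keeps with debt, or reverts per the threshold", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  st <- quality_state(ph$tree, 90, t_s_delta = -2)
  better <- catimprove:::.tree_drop(ph$tree, 15)
  # S_delta = +3 -> kept
  st <- apply_scored(st, better, 93)
  expect_identical(st$last$decision, "kept")
  expect_equal(st$score, 93)
  # S_delta = -1 (within threshold) -> kept with debt, accumulated sum drops
  st <- apply_scored(st, ph$tree, 92)
  expect_identical(st$last$decision, "kept-with-debt")
  expect_equal(st$s_delta_sum, 2)
  expect_false(isTRUE(st$stop_accumulated))
  # S_delta = -5 (below threshold) -> reverted, tree byte-identical to snapshot
  snap <- catimprove:::.tree_canonical(st$tree)
  st <- apply_scored(st, better, 87)
  expect_identical(st$last$decision, "reverted")
  expect_identical(catimprove:::.tree_canonical(st$tree), snap)
  expect_equal(st$score, 92)
})

test_that("repeated small decreases trip the accumulated-decrease stop", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  st <- quality_state(ph$tree, 95, t_s_delta = -2)
  scripted <- c(94, 93, 92)  # three S_delta = -1 steps
  stops <- logical(3)
  for (i in seq_along(scripted)) {
    st <- apply_scored(st, ph$tree, scripted[i])
    stops[i] <- isTRUE(st$stop_accumulated)
  }
  expect_identical(stops, c(FALSE, FALSE, TRUE))  # -3 < T only at the third
  # the best snapshot still points at the initial, highest-scoring tree
  expect_equal(st$best_score, 95)
})
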