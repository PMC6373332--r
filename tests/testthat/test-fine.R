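test_that("a model-identical phantom yields no findings", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  expect_length(detect_inaccuracies(ph$tree, ph$model), 0)
})

test_that("length violations and low-weight absences are classified correctly", {
  ph <- generate_phantom(phantom_spec(dominance = "RD", seed = 2))
  # overlong OM1 -> too_long finding prescribing deletion
  deg <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(overlong = list(list(label = "OM1", extra_mm = 20)), seed = 2))
  relab <- assign_labels(deg$tree, ph$model)
  fs <- detect_inaccuracies(relab, ph$model)
  om1 <- Filter(function(f) f$label == "OM1", fs)
  expect_length(om1, 1)
  expect_identical(om1[[1]]$kind, "too_long")
  expect_identical(om1[[1]]$op, "deletion")
  # absent D2 has weight 0.3 < 0.4: no finding
  deg2 <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(prune = list(list(label = "D2", fraction = 1))))
  relab2 <- assign_labels(deg2$tree, ph$model)
  fs2 <- detect_inaccuracies(relab2, ph$model)
  expect_length(Filter(function(f) f$label == "D2", fs2), 0)
  # too-short dLAD -> extension with rule 3
  deg3 <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(prune = list(list(label = "dLAD", fraction = 0.6))))
  relab3 <- assign_labels(deg3$tree, ph$model)
  fs3 <- detect_inaccuracies(relab3, ph$model)
  dlad <- Filter(function(f) f$label == "dLAD", fs3)
  expect_length(dlad, 1)
  expect_identical(dlad[[1]]$kind, "too_short")
  expect_identical(dlad[[1]]$rule, 3L)
})

test_that("start-point rules dispatch on the finding", {
  ph <- generate_phantom(phantom_spec(dominance = "RD", seed = 3))
  deg <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(prune = list(list(label = "RPDA", fraction = 1),
                                  list(label = "RPLB", fraction = 1))))
  relab <- assign_labels(deg$tree, ph$model)
  labs <- tree_labels(relab)
  # rule 1: absent side branch -> candidate points on the parent label (dRCA)
  f1 <- list(label = "RPDA", kind = "absent", op = "extension", rule = 1L)
  sp <- select_start_points(f1, relab, ph$model)
  expect_gt(nrow(sp), 0)
  expect_true(all(labs[sp$pathline] == "dRCA"))
  # rule 3: too-short segment -> exactly its end point
  deg3 <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(prune = list(list(label = "dLAD", fraction = 0.3))))
  relab3 <- assign_labels(deg3$tree, ph$model)
  f3 <- list(label = "dLAD", kind = "too_short", op = "extension", rule = 3L)
  sp3 <- select_start_points(f3, relab3, ph$model)
  expect_equal(nrow(sp3), 1)
  i <- which(tree_labels(relab3) == "dLAD")
  endp <- relab3$pathlines[[i]]$points[nrow(relab3$pathlines[[i]]$points), ]
  expect_equal(as.numeric(sp3[1, c("x", "y", "z")]), endp)
})

test_that("rule 2 uses the whole extracted main branch of the subtree", {
  ph <- generate_phantom(phantom_spec(dominance = "RD", seed = 4))
  relab <- assign_labels(ph$tree, ph$model)
  f <- list(label = "mRCA", kind = "absent", op = "extension", rule = 2L)
  sp <- select_start_points(f, relab, ph$model)
  expect_gt(nrow(sp), 0)
  expect_true(all(tree_labels(relab)[sp$pathline] %in% c("pRCA", "mRCA", "dRCA")))
})

test_that("deletion truncates where the maximum length is exceeded", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  deg <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(overlong = list(list(label = "OM1", extra_mm = 25)), seed = 5))
  relab <- assign_labels(deg$tree, ph$model)
  f <- list(label = "OM1", kind = "too_long", op = "deletion", rule = NA_integer_)
  out <- delete_segment(relab, f, ph$model)
  lmax <- ph$model$labels$length_max[ph$model$labels$name == "OM1"]
  i <- which(tree_labels(out) == "OM1")
  expect_equal(pathline_length(out$pathlines[[i]]), lmax, tolerance = 1e-6)
  # the truncation point equals the prune_to_length oracle
  j <- which(tree_labels(relab) == "OM1")
  oracle <- prune_to_length(relab$pathlines[[j]]$points, lmax)
  expect_equal(out$pathlines[[i]]$points, oracle)
  # an in-range segment is a no-op
  out2 <- delete_segment(assign_labels(ph$tree, ph$model), f, ph$model)
  expect_true(tree_equal(out2, assign_labels(ph$tree, ph$model)))
  expect_error(delete_segment(relab, list(label = "ZZZ", kind = "too_long"),
                              ph$model), "not found")
})

test_that("branch search follows the radius schedule on toy volumes", {
  # tree: a line along x; unconnected component beyond a 3 mm gap
  tree_line <- seg(c(5, 20, 20), c(20, 20, 20))
  comp_line <- seg(c(23, 20, 20), c(40, 20, 20))
  img <- toy_volume(list(tree_line, comp_line))
  tr <- line_tree(list(tree_line), ostium_left = c(60, 60, 60),
                  ostium_right = c(5, 20, 20))
  starts <- data.frame(x = 20, y = 20, z = 20, pathline = 1L, point = 2L)
  res <- branch_search(img, tr, starts, search_params(d_init = 2, d_step = 1))
  expect_true(res$found)
  expect_equal(res$radius, 3)
  # every returned point after the straight connector lies on a foreground voxel
  pts <- res$points[-1, , drop = FALSE]
  ijk <- catimprove:::.world_to_ijk(img, pts)
  lin <- catimprove:::.ijk_to_linear(img, ijk)
  expect_true(all(img$voxels[lin] == 1L))

  # component adjacent to the start: found at the first radius
  img2 <- toy_volume(list(tree_line, seg(c(21, 21, 20), c(30, 30, 20))))
  res2 <- branch_search(img2, tr, starts, search_params(d_init = 2, d_step = 1))
  expect_true(res2$found)
  expect_equal(res2$radius, 2)

  # a 20 mm gap exceeds the 15 mm maximum searching distance
  img3 <- toy_volume(list(tree_line, seg(c(40, 20, 20), c(55, 20, 20))))
  res3 <- branch_search(img3, tr, starts, search_params())
  expect_false(res3$found)
})

test_that("branch search never returns structure already on the tree", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  deg <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(prune = list(list(label = "RPDA", fraction = 1),
                                  list(label = "RPLB", fraction = 1))))
  relab <- assign_labels(deg$tree, ph$model)
  f <- list(label = "RPDA", kind = "absent", op = "extension", rule = 1L)
  sp <- select_start_points(f, relab, ph$model)
  res <- branch_search(deg$image, relab, sp)
  expect_true(res$found)
  tree_vox <- rasterize_tree(relab, deg$image, clip = TRUE)
  expect_length(intersect(res$component, tree_vox), 0)
})

test_that("extension recovers pruned branches and does not re-emit the finding", {
  ph <- generate_phantom(phantom_spec(dominance = "RD", seed = 7))
  deg <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(prune = list(list(label = "RPDA", fraction = 1),
                                  list(label = "RPLB", fraction = 1))))
  relab <- assign_labels(deg$tree, ph$model)
  f <- list(label = "RPDA", kind = "absent", op = "extension", rule = 1L)
  ext <- extend_tree(relab, deg$image, f, ph$model)
  expect_true(ext$found)
  relab2 <- assign_labels(ext$tree, ph$model)
  fs <- detect_inaccuracies(relab2, ph$model)
  expect_length(Filter(function(x) x$label == "RPDA" && x$kind == "absent", fs), 0)
  # extension against a structure absent from the volume leaves the tree unchanged
  img0 <- deg$image
  img0$voxels[] <- 0L
  lin <- rasterize_tree(relab, img0, clip = TRUE)
  img0$voxels[lin] <- 1L  # only the current tree, nothing to find
  ext0 <- extend_tree(relab, img0, f, ph$model)
  expect_false(ext0$found)
  expect_true(tree_equal(ext0$tree, relab, tol = 0))
})
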