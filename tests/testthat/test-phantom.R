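test_that("generation is deterministic given the seed", {
  a <- generate_phantom(phantom_spec(seed = 9))
  b <- generate_phantom(phantom_spec(seed = 9))
  expect_true(tree_equal(a$tree, b$tree, tol = 0))
  expect_identical(a$image$voxels, b$image$voxels)
  c3 <- generate_phantom(phantom_spec(seed = 10))
  expect_false(tree_equal(a$tree, c3$tree))
})

test_that("dominance controls where the PDA is generated", {
  rd <- generate_phantom(phantom_spec(dominance = "RD", seed = 2))
  expect_true("RPDA" %in% tree_labels(rd$tree))
  expect_false("LPDA" %in% tree_labels(rd$tree))
  ld <- generate_phantom(phantom_spec(dominance = "LD", seed = 2))
  expect_true("LPDA" %in% tree_labels(ld$tree))
  expect_false("RPDA" %in% tree_labels(ld$tree))
})

test_that("every generated tree satisfies its model and scores 100", {
  for (dm in c("RD", "LD")) for (s in c(21, 22, 23)) {
    ph <- generate_phantom(phantom_spec(dominance = dm, seed = s))
    df <- ph$model$labels
    for (i in seq_along(ph$tree$pathlines)) {
      lab <- ph$tree$pathlines[[i]]$label
      L <- pathline_length(ph$tree$pathlines[[i]])
      k <- match(lab, df$name)
      expect_gte(L, df$length_min[k]); expect_lte(L, df$length_max[k])
    }
    expect_equal(as.numeric(quality_score(ph$tree, ph$model)), 100)
  }
})

test_that("the rasterized skeleton is 26-connected and covers every tree point", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  img <- ph$image
  # every tree vertex sits on a foreground voxel
  pts <- do.call(rbind, lapply(ph$tree$pathlines, function(p) p$points))
  ijk <- catimprove:::.world_to_ijk(img, pts)
  lin <- catimprove:::.ijk_to_linear(img, ijk)
  expect_true(all(img$voxels[lin] == 1L))
  # along each pathline, consecutive sample voxels differ by at most 1 per axis
  for (p in ph$tree$pathlines) {
    rs <- catimprove:::.resample_polyline(p$points, 0.3 * min(img$spacing))
    v <- catimprove:::.world_to_ijk(img, rs)
    v <- v[c(TRUE, rowSums(abs(diff(v))) > 0), , drop = FALSE]
    expect_true(all(abs(diff(v)) <= 1))
  }
})

test_that("degrade removes pruned labels from the tree but not the volume", {
  ph <- generate_phantom(phantom_spec(dominance = "RD", seed = 6))
  deg <- degrade_phantom(ph$tree, ph$image,
                         degradation_spec(prune = list(list(label = "RPDA",
                                                            fraction = 1))))
  expect_false("RPDA" %in% tree_labels(deg$tree))
  # the RPDA skeleton voxels are still foreground
  rpda <- ph$tree$pathlines[[which(tree_labels(ph$tree) == "RPDA")]]$points
  ijk <- catimprove:::.world_to_ijk(deg$image, rpda)
  lin <- catimprove:::.ijk_to_linear(deg$image, ijk)
  expect_true(all(deg$image$voxels[lin] == 1L))
  expect_error(degrade_phantom(ph$tree, ph$image,
                               degradation_spec(prune = list(list(label = "LPDA",
                                                                  fraction = 1)))),
               "absent")
})

test_that("an empty degradation is the identity", {
  ph <- generate_phantom(phantom_spec(seed = 7))
  deg <- degrade_phantom(ph$tree, ph$image, degradation_spec())
  expect_true(tree_equal(ph$tree, deg$tree, tol = 0))
  expect_identical(ph$image$voxels, deg$image$voxels)
})

test_that("fractional pruning halves the arc length to within a voxel", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  orig <- tree_lengths(ph$tree)[tree_labels(ph$tree) == "dLAD"]
  deg <- degrade_phantom(ph$tree, ph$image,
                         degradation_spec(prune = list(list(label = "dLAD",
                                                            fraction = 0.5))))
  new <- tree_lengths(deg$tree)[tree_labels(deg$tree) == "dLAD"]
  expect_equal(new, orig * 0.5, tolerance = max(ph$image$spacing) / orig)
})

test_that("gap degradation removes volume voxels along the labeled span", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  before <- sum(ph$image$voxels)
  deg <- degrade_phantom(ph$tree, ph$image,
                         degradation_spec(gap = list(list(label = "dLAD",
                                                          gap_mm = 5, at = 0.4))))
  expect_lt(sum(deg$image$voxels), before)
  expect_true(tree_equal(ph$tree, deg$tree, tol = 0))
})

test_that("a tree exceeding a fixed volume errors during generation", {
  expect_error(generate_phantom(phantom_spec(seed = 1, size = c(20, 20, 20),
                                             origin = c(0, 0, 0))),
               "bounds")
})
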