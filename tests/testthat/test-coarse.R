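coarse_postconditions_hold <- function(tree, model, tol = 1) {
  cc <- connected_components(tree, tol)
  lens <- tree_lengths(tree)
  angs <- vapply(seq_along(tree$pathlines),
                 function(i) catimprove:::.tree_branch_angle(tree, i), numeric(1))
  length(cc$orphans) == 0 &&
    all(lens <= model$global$max_pathline_length + 1e-6) &&
    all(lens >= model$global$min_pathline_length - 1e-6) &&
    all(is.na(angs) | angs <= model$global$max_angle_deg + 1e-6)
}

test_that("a floating fragment is removed and the rest left unchanged", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  deg <- degrade_phantom(ph$tree, ph$image, degradation_spec(fragments = 1, seed = 1))
  out <- coarse_improve(deg$tree, ph$model)
  expect_true(tree_equal(out, ph$tree))
})

test_that("sub-millimetre pathlines are removed; the 1 mm boundary is kept", {
  model <- load_model(dominance = "RD")
  stub <- rbind(c(0, 0, -10), c(0.5, 0, -10))           # 0.5 mm: removed
  exact <- rbind(c(0, 0, -15), c(1, 0, -15))            # exactly 1 mm: kept
  tr <- cat_tree(c(70, 0, 0), c(0, 0, 0),
                 list(list(points = rbind(c(0, 0, 0), c(0, 0, -10), c(0, 0, -15),
                                          c(0, 0, -20)), label = NA),
                      list(points = stub, label = NA),
                      list(points = exact, label = NA)),
                 parent = c(NA, 1L, 1L), attach = c(NA, 2L, 3L))
  out <- coarse_improve(tr, model)
  expect_length(out$pathlines, 2)
  expect_equal(min(tree_lengths(out)), 1)
})

test_that("overlong pathlines are pruned to the global maximum as a prefix", {
  model <- load_model(dominance = "RD")
  long <- rbind(c(0, 0, 0), c(300, 0, 0))
  tr <- cat_tree(c(70, 50, 0), c(0, 0, 0),
                 list(list(points = long, label = NA)))
  out <- coarse_improve(tr, model)
  expect_equal(pathline_length(out$pathlines[[1]]), 250)
  expect_equal(out$pathlines[[1]]$points[1, ], c(0, 0, 0))
})

test_that("side branches above 120 degrees are removed, at or below kept", {
  model <- load_model(dominance = "RD")
  main <- rbind(c(0, 0, 0), c(0, 0, -10), c(0, 0, -20))
  mk <- function(theta_deg) {
    d <- c(sin(theta_deg * pi / 180), 0, -cos(theta_deg * pi / 180))
    rbind(c(0, 0, -10), c(0, 0, -10) + 8 * d)
  }
  tr <- cat_tree(c(70, 0, 0), c(0, 0, 0),
                 list(list(points = main, label = NA),
                      list(points = mk(150), label = NA),
                      list(points = mk(90), label = NA),
                      list(points = mk(120), label = NA)),
                 parent = c(NA, 1L, 1L, 1L), attach = c(NA, 2L, 2L, 2L))
  out <- coarse_improve(tr, model)
  expect_length(out$pathlines, 3)  # 150-degree branch gone, 90 and 120 kept
})

test_that("removing a parent cascades to its descendants", {
  model <- load_model(dominance = "RD")
  far <- rbind(c(40, 40, 40), c(45, 40, 40))      # orphan parent
  child <- rbind(c(45, 40, 40), c(45, 45, 40))
  tr <- cat_tree(c(70, 0, 0), c(0, 0, 0),
                 list(list(points = rbind(c(0, 0, 0), c(0, 0, -10)), label = NA),
                      list(points = far, label = NA),
                      list(points = child, label = NA)),
                 parent = c(NA, NA, 2L), attach = c(NA, NA, 2L))
  out <- coarse_improve(tr, model)
  expect_length(out$pathlines, 1)
})

test_that("coarse improvement satisfies its postconditions and is idempotent", {
  for (s in 1:5) {
    ph <- generate_phantom(phantom_spec(seed = 500 + s))
    deg <- degrade_phantom(ph$tree, ph$image,
      degradation_spec(fragments = 2, veins = 2, stubs = 1,
                       overlong = list(list(label = "D1", extra_mm = 260)),
                       seed = s))
    out <- coarse_improve(deg$tree, ph$model)
    expect_true(coarse_postconditions_hold(out, ph$model))
    out2 <- coarse_improve(out, ph$model)
    expect_true(tree_equal(out, out2, tol = 0))
  }
  # an empty tree passes through unchanged
  empty <- cat_tree(c(70, 0, 0), c(0, 0, 0), list())
  expect_length(coarse_improve(empty, load_model(dominance = "RD"))$pathlines, 0)
})
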