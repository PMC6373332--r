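# Shared fixtures: all test data is generated in code.

tree_labels <- function(tree) {
  vapply(tree$pathlines, function(p) p$label, character(1))
}

tree_lengths <- function(tree) {
  vapply(tree$pathlines, function(p) pathline_length(p), numeric(1))
}

# a minimal forest of straight polylines wrapped as a cat_tree (geometry only)
line_tree <- function(lines, ostium_left = c(0, 0, 0), ostium_right = c(0, 0, 0)) {
  cat_tree(ostium_left, ostium_right,
           lapply(lines, function(m) list(points = m, label = NA_character_)))
}

# rasterize straight segments into a small binary volume
toy_volume <- function(lines, dim = c(64, 64, 64), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  img <- vessel_image(array(0L, dim = dim), spacing, origin)
  lin <- rasterize_tree(line_tree(lines), img, clip = FALSE)
  img$voxels[lin] <- 1L
  img
}

# straight line as a 2 x 3 matrix
seg <- function(a, b) rbind(a, b)

# the Fig-2-style pruned-recovery fixture: RD phantom with its posterior
# branches removed from the tree while the volume keeps the full skeleton
pruned_rd_phantom <- function(seed) {
  ph <- generate_phantom(phantom_spec(dominance = "RD", seed = seed))
  deg <- degrade_phantom(ph$tree, ph$image,
    degradation_spec(prune = list(list(label = "RPDA", fraction = 1),
                                  list(label = "RPLB", fraction = 1)),
                     seed = seed))
  list(truth = ph$tree, image = ph$image, initial = deg$tree, model = ph$model)
}

voxel_diag <- function(img) sqrt(sum(img$spacing^2))
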