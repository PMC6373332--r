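test_that("tree JSON round-trips geometry, labels and connectivity", {
  tr <- cat_tree(
    ostium_left = c(70, 0, 0), ostium_right = c(0, 0, 0),
    pathlines = list(
      list(points = rbind(c(0, 0, 0), c(0, 0, -10), c(1, 2, -15)), label = "pRCA"),
      list(points = rbind(c(0, 0, -10), c(5, 0, -12)), label = NA),
      list(points = rbind(c(70, 0, 0), c(70, 1, -8)), label = "LM")),
    parent = c(NA, 1L, NA), attach = c(NA, 2L, NA))
  f <- tempfile(fileext = ".json")
  write_tree(tr, f)
  tr2 <- read_tree(f)
  expect_true(tree_equal(tr, tr2))
  expect_true(is.na(tr2$pathlines[[2]]$label))  # null label preserved
  # canonical serialization: write -> read -> write is byte-identical
  f2 <- tempfile(fileext = ".json")
  write_tree(tr2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("phantom ground truth survives a write/read/write byte-compare", {
  ph <- generate_phantom(phantom_spec(seed = 11))
  f <- tempfile(fileext = ".json")
  write_tree(ph$tree, f)
  f2 <- tempfile(fileext = ".json")
  write_tree(read_tree(f), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed tree files give parse errors naming the JSON path", {
  f <- tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(read_tree(f), "malformed")
  writeLines('{"format": "something-else"}', f)
  expect_error(read_tree(f), "\\$\\.format")
  writeLines('{"format": "coronary-tree", "version": 1,
    "ostia": {"left": [0,0,0], "right": [1,0,0]},
    "pathlines": [{"points": []}]}', f)
  expect_error(read_tree(f), "points")
})

test_that("volumes round-trip through NIfTI and MetaImage with anisotropic spacing", {
  v <- array(0L, dim = c(10, 10, 10))
  v[2, 1, 1] <- 1L; v[5, 6, 7] <- 1L
  img <- vessel_image(v, spacing = c(0.3, 0.3, 0.25), origin = c(-4, 2, 7))
  # world offset of voxel (2,1,1) relative to (1,1,1) is one x-spacing
  w <- catimprove:::.ijk_to_world(img, rbind(c(2, 1, 1), c(1, 1, 1)))
  expect_equal(w[1, 1] - w[2, 1], 0.3)
  for (ext in c(".nii.gz", ".nii", ".mha")) {
    f <- tempfile(fileext = ext)
    write_volume(img, f)
    r <- read_volume(f)
    expect_equal(r$spacing, img$spacing, tolerance = 1e-5)
    expect_equal(r$origin, img$origin, tolerance = 1e-4)
    expect_identical(which(r$voxels == 1L), which(img$voxels == 1L))
  }
})

test_that("an all-zero volume reads back as a valid empty image", {
  img <- vessel_image(array(0L, dim = c(5, 5, 5)), c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(img, f)
  r <- read_volume(f)
  expect_equal(sum(r$voxels), 0)
})

test_that("rotated direction cosines are rejected", {
  arr <- array(0L, dim = c(6, 6, 6))
  nii <- RNifti::asNifti(arr)
  th <- 20 * pi / 180
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  RNifti::qform(nii) <- structure(rot, code = 2L)
  RNifti::sform(nii) <- structure(rot, code = 2L)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(nii, f)
  expect_error(read_volume(f), "orientation")
})

test_that("world/voxel conversions are inverses within half a voxel", {
  img <- vessel_image(array(0L, dim = c(30, 25, 20)),
                      spacing = c(0.4, 0.55, 0.3), origin = c(-3, 8, 1))
  set.seed(42)
  pts <- cbind(runif(200, -3, 8), runif(200, 8, 20), runif(200, 1, 6))
  ijk <- catimprove:::.world_to_ijk(img, pts)
  back <- catimprove:::.ijk_to_world(img, ijk)
  err <- abs(back - pts)
  expect_true(all(sweep(err, 2, img$spacing / 2, "<=") + 1e-9 > 0))
  expect_true(all(err[, 1] <= img$spacing[1] / 2 + 1e-9))
  expect_true(all(err[, 2] <= img$spacing[2] / 2 + 1e-9))
  expect_true(all(err[, 3] <= img$spacing[3] / 2 + 1e-9))
})

test_that("VTK export writes one cell per pathline with a label array", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  f <- tempfile(fileext = ".vtk")
  export_vtk(ph$tree, f)
  txt <- readLines(f)
  npts <- sum(vapply(ph$tree$pathlines, function(p) nrow(p$points), integer(1)))
  expect_true(any(grepl(sprintf("^POINTS %d float$", npts), txt)))
  expect_true(any(grepl(sprintf("^LINES %d ", length(ph$tree$pathlines)), txt)))
  expect_true(any(grepl("SCALARS label_id int", txt)))
})
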