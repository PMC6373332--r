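#' Construct a binary vesselness image
#'
#' A binary 3-D voxel grid marking the central axes of vessel-like structures,
#' with anisotropic spacing support. World coordinates follow
#' `world = origin + (index - 1) * spacing` for 1-based voxel indices; no
#' direction-matrix rotation is supported.
#'
#' @param voxels 3-D array; coerced to binary via `> 0`.
#' @param spacing Numeric length-3, mm per axis (> 0).
#' @param origin Numeric length-3, world coordinate (mm) of voxel (1,1,1).
#' @return An object of class `vessel_image`.
#' @export
vessel_image <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  vox <- array(as.integer(voxels > 0), dim = dim(voxels))
  structure(list(voxels = vox, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), size = dim(vox)),
            class = "vessel_image")
}

#' @export
print.vessel_image <- function(x, ...) {
  cat("<vessel_image>", paste(x$size, collapse = " x "), "voxels; spacing",
      paste(signif(x$spacing, 4), collapse = " x "), "mm;",
      sum(x$voxels), "foreground voxels\n")
  invisible(x)
}

# 1-based voxel indices (n x 3) of world points, rounded to nearest voxel centre
.world_to_ijk <- function(img, pts) {
  pts <- .as_points(pts)
  ijk <- sweep(sweep(pts, 2, img$origin, "-"), 2, img$spacing, "/")
  round(ijk) + 1
}

# world coordinates (n x 3) of 1-based voxel indices
.ijk_to_world <- function(img, ijk) {
  ijk <- .as_points(ijk)
  sweep(sweep(ijk - 1, 2, img$spacing, "*"), 2, img$origin, "+")
}

.ijk_in_bounds <- function(img, ijk) {
  ijk[, 1] >= 1 & ijk[, 1] <= img$size[1] &
  ijk[, 2] >= 1 & ijk[, 2] <= img$size[2] &
  ijk[, 3] >= 1 & ijk[, 3] <= img$size[3]
}

.ijk_to_linear <- function(img, ijk) {
  as.integer((ijk[, 3] - 1) * img$size[1] * img$size[2] +
             (ijk[, 2] - 1) * img$size[1] + ijk[, 1])
}

.linear_to_ijk <- function(img, lin) {
  lin0 <- lin - 1
  nx <- img$size[1]; nxy <- img$size[1] * img$size[2]
  cbind(lin0 %% nx + 1, (lin0 %/% nx) %% img$size[2] + 1, lin0 %/% nxy + 1)
}

# ---- tree JSON I/O ----------------------------------------------------------

.tree_json_string <- function(tree, digits = 6) {
  pls <- lapply(seq_len(.tree_n(tree)), function(i) {
    p <- tree$pathlines[[i]]
    list(
      label = if (is.na(p$label)) NULL else p$label,
      parent = if (is.na(tree$parent[i])) NULL else tree$parent[i] - 1L,
      attach_index = if (is.na(tree$attach[i])) NULL else tree$attach[i] - 1L,
      points = round(unname(p$points), digits)
    )
  })
  obj <- list(
    format = "coronary-tree", version = 1L,
    ostia = list(left = round(tree$ostium_left, digits),
                 right = round(tree$ostium_right, digits)),
    pathlines = pls
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Write a coronary tree to JSON
#'
#' The on-disk schema (see `inst/schema/tree.schema.json`) stores coordinates in
#' world mm and 0-based pathline/point indices; labels are strings or `null`.
#' Serialization is canonical (fixed coordinate precision of 1e-6 mm), so two
#' writes of equal trees are byte-identical.
#'
#' @param tree A `cat_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  writeLines(.tree_json_string(tree), path)
  invisible(path)
}

#' Read a coronary tree from JSON
#'
#' @param path Path to a tree JSON file as written by [write_tree()].
#' @return A `cat_tree`.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed tree JSON at $: ", conditionMessage(e)))
  if (is.null(obj$format) || obj$format != "coronary-tree")
    stop("schema violation at $.format: expected 'coronary-tree'")
  if (is.null(obj$ostia) || is.null(obj$ostia$left) || is.null(obj$ostia$right))
    stop("schema violation at $.ostia: left and right ostium coordinates required")
  pls <- obj$pathlines
  if (is.null(pls)) stop("schema violation at $.pathlines: required")
  pathlines <- vector("list", length(pls))
  parent <- attach <- rep(NA_integer_, length(pls))
  for (i in seq_along(pls)) {
    pl <- pls[[i]]
    if (is.null(pl$points) || length(pl$points) < 1)
      stop("schema violation at $.pathlines[", i - 1, "].points: at least one point required")
    pts <- do.call(rbind, lapply(pl$points, function(q) {
      if (length(q) != 3) stop("schema violation at $.pathlines[", i - 1,
                               "].points: each point needs 3 coordinates")
      as.numeric(q)
    }))
    pathlines[[i]] <- list(points = pts,
                           label = if (is.null(pl$label)) NA_character_ else as.character(pl$label))
    if (!is.null(pl$parent)) parent[i] <- as.integer(pl$parent) + 1L
    if (!is.null(pl$attach_index)) attach[i] <- as.integer(pl$attach_index) + 1L
  }
  cat_tree(as.numeric(obj$ostia$left), as.numeric(obj$ostia$right),
           pathlines, parent, attach)
}

# ---- volume I/O -------------------------------------------------------------

#' Read a binary vesselness volume
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mhd`, `.mha`). Voxel
#' values are thresholded at `> 0` to binary on read. Only axis-aligned volumes
#' are supported: files whose direction cosines are not the identity are
#' rejected with an unsupported-orientation error.
#'
#' @param path Input file path.
#' @return A `vessel_image`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    .read_nifti_volume(path)
  } else if (grepl("\\.(mhd|mha)$", path)) {
    .read_metaimage_volume(path)
  } else stop("unsupported volume format (expect .nii, .nii.gz, .mhd or .mha): ", path)
}

#' Write a binary vesselness volume
#'
#' @param img A `vessel_image`.
#' @param path Output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    .write_nifti_volume(img, path)
  } else if (grepl("\\.mha$", path)) {
    .write_metaimage_volume(img, path)
  } else stop("unsupported output volume format: ", path)
  invisible(path)
}

.read_nifti_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  xf <- RNifti::xform(nii)
  rot <- xf[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  dir <- sweep(rot, 2, sp, "/")
  # NIfTI xforms are RAS-based; accept plain identity or the LAS flip that
  # corresponds to our axis-aligned convention, reject anything rotated
  if (max(abs(abs(dir) - diag(3))) > 1e-3)
    stop("unsupported orientation: non-identity direction cosines in ", path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3) stop("expected a 3-D volume: ", path)
  pix <- attr(nii, "pixdim")
  if (is.null(pix)) pix <- sp
  origin <- xf[1:3, 4]
  # fold axis flips into the origin by re-expressing in our +axis convention
  for (ax in 1:3) {
    if (dir[ax, ax] < 0) origin[ax] <- origin[ax] + dir[ax, ax] * pix[ax] * (dim(arr)[ax] - 1)
  }
  vessel_image(arr, abs(pix[1:3]), origin)
}

.write_nifti_volume <- function(img, path) {
  arr <- array(as.integer(img$voxels), dim = img$size)
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- img$spacing
  m <- diag(4)
  m[1, 1] <- img$spacing[1]; m[2, 2] <- img$spacing[2]; m[3, 3] <- img$spacing[3]
  m[1:3, 4] <- img$origin
  RNifti::qform(nii) <- structure(m, code = 2L)
  RNifti::sform(nii) <- structure(m, code = 2L)
  RNifti::writeNifti(nii, path)
}

.read_metaimage_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); data_file <- NULL
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) stop("expected 3-D MetaImage: ", path)
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.null(hdr$TransformMatrix)) {
    tm <- as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]])
    if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-6)
      stop("unsupported orientation: non-identity TransformMatrix in ", path)
  }
  etype <- if (is.null(hdr$ElementType)) "MET_UCHAR" else hdr$ElementType
  n <- prod(dims)
  raw_reader <- function(con) {
    switch(etype,
      MET_UCHAR = as.integer(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
      MET_CHAR = readBin(con, "integer", n = n, size = 1, signed = TRUE),
      MET_SHORT = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
      MET_USHORT = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
      MET_INT = readBin(con, "integer", n = n, size = 4, endian = "little"),
      MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = "little"),
      MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = "little"),
      stop("unsupported MetaImage ElementType: ", etype))
  }
  if (identical(data_file, "LOCAL")) {
    vals <- raw_reader(con)
  } else {
    raw_path <- file.path(dirname(path), data_file)
    con2 <- file(raw_path, "rb"); on.exit(close(con2), add = TRUE)
    vals <- raw_reader(con2)
  }
  if (length(vals) != n) stop("MetaImage pixel data truncated: ", path)
  vessel_image(array(vals, dim = dims), spacing, origin)
}

.write_metaimage_volume <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(img$origin, trim = TRUE), collapse = " ")),
    paste("ElementSpacing =", paste(format(img$spacing, trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(img$size, collapse = " ")),
    "ElementType = MET_UCHAR",
    "ElementDataFile = LOCAL"
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.raw(as.integer(img$voxels)), con)
}

# ---- VTK export -------------------------------------------------------------

#' Export a coronary tree as VTK legacy polydata
#'
#' Writes an ASCII legacy `.vtk` polydata file with one polyline cell per
#' pathline and a per-cell integer `label_id` array; the id-to-label-name table
#' is embedded in the header comment line. Intended for visualization (e.g.
#' ParaView); not a round-trip format.
#'
#' @param tree A `cat_tree`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(tree, path) {
  pts <- .tree_points(tree)
  labs <- .tree_labels(tree)
  ulabs <- unique(labs[!is.na(labs)])
  lab_id <- ifelse(is.na(labs), -1L, match(labs, ulabs) - 1L)
  counts <- vapply(tree$pathlines, function(p) nrow(p$points), integer(1))
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vtk DataFile Version 3.0", con)
  writeLines(paste("coronary tree; labels:",
                   paste(sprintf("%d=%s", seq_along(ulabs) - 1L, ulabs), collapse = " ")), con)
  writeLines(c("ASCII", "DATASET POLYDATA"), con)
  writeLines(sprintf("POINTS %d float", nrow(pts)), con)
  writeLines(apply(pts, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", length(counts), sum(counts) + length(counts)), con)
  for (i in seq_along(counts)) {
    writeLines(paste(c(counts[i], offsets[i] + seq_len(counts[i]) - 1L), collapse = " "), con)
  }
  writeLines(sprintf("CELL_DATA %d", length(counts)), con)
  writeLines(c("SCALARS label_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(lab_id, collapse = " "), con)
  invisible(path)
}
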