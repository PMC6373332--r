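#' Load an anatomical statistical model
#'
#' Reads a model configuration describing the AHA segment topology for one
#' dominance type: per-label importance weights, expected length ranges, the
#' parent-child label forest, and global constraints (maximum pathline length,
#' maximum bifurcation angle, minimum pathline length, and the weight threshold
#' above which an absent label is treated as a missed extraction).
#'
#' The package ships default configurations for right-dominant (RD) and
#' left-dominant (LD) anatomy. In the RD model the posterior descending artery
#' (RPDA) belongs to the RCA subtree; in the LD model it (LPDA) belongs to the
#' LCX subtree. Balanced dominance is resolved to RD, the most prevalent type.
#'
#' @param path Path to a JSON model config. If `NULL`, the shipped default for
#'   `dominance` is used.
#' @param dominance One of `"RD"`, `"LD"`, `"balanced"`. Ignored when the config
#'   file itself declares a dominance and `path` is given.
#' @return An object of class `cat_model`: a list with elements `dominance`,
#'   `global` (named list of global constraints) and `labels` (a data frame with
#'   columns `name`, `weight`, `length_min`, `length_max`, `parent`, `subtree`,
#'   `position_class`, in config order).
#' @export
load_model <- function(path = NULL, dominance = c("RD", "LD", "balanced")) {
  dominance <- match.arg(dominance)
  if (dominance == "balanced") dominance <- "RD"
  if (is.null(path)) {
    fname <- if (dominance == "RD") "model_rd.json" else "model_ld.json"
    path <- system.file("extdata", fname, package = "catimprove", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("model config not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .validate_model_config(cfg, path)
  labs <- cfg$labels
  df <- data.frame(
    name = names(labs),
    weight = vapply(labs, function(l) as.numeric(l$weight), numeric(1)),
    length_min = vapply(labs, function(l)
      as.numeric(if (is.null(l$length_min_mm)) 10 else l$length_min_mm), numeric(1)),
    length_max = vapply(labs, function(l)
      as.numeric(if (is.null(l$length_max_mm)) 50 else l$length_max_mm), numeric(1)),
    parent = vapply(labs, function(l)
      if (is.null(l$parent)) NA_character_ else as.character(l$parent), character(1)),
    subtree = vapply(labs, function(l) as.character(l$subtree), character(1)),
    position_class = vapply(labs, function(l) as.character(l$position_class), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  model <- structure(list(
    dominance = cfg$dominance,
    global = list(
      max_pathline_length = as.numeric(cfg$global$max_pathline_length_mm),
      max_angle_deg = as.numeric(cfg$global$max_angle_deg),
      min_pathline_length = as.numeric(cfg$global$min_pathline_length_mm),
      weight_threshold = as.numeric(cfg$global$weight_threshold)
    ),
    labels = df
  ), class = "cat_model")
  .validate_model(model)
  model
}

.validate_model_config <- function(cfg, path) {
  for (key in c("dominance", "global", "labels")) {
    if (is.null(cfg[[key]])) stop("model config ", path, ": missing top-level key '", key, "'")
  }
  if (!cfg$dominance %in% c("RD", "LD"))
    stop("model config ", path, ": dominance must be 'RD' or 'LD'")
  for (nm in names(cfg$labels)) {
    l <- cfg$labels[[nm]]
    for (key in c("weight", "subtree", "position_class")) {
      if (is.null(l[[key]])) stop("model config label '", nm, "': missing field '", key, "'")
    }
  }
  invisible(TRUE)
}

.validate_model <- function(model) {
  df <- model$labels
  if (any(df$weight < 0 | df$weight > 1))
    stop("label weights must lie in [0, 1]: ",
         paste(df$name[df$weight < 0 | df$weight > 1], collapse = ", "))
  bad <- df$length_min > df$length_max | df$length_min < 0
  if (any(bad))
    stop("invalid length range (length_min > length_max or negative) for label(s): ",
         paste(df$name[bad], collapse = ", "))
  unknown <- !is.na(df$parent) & !(df$parent %in% df$name)
  if (any(unknown))
    stop("parent label not in roster for label(s): ", paste(df$name[unknown], collapse = ", "))
  if (!all(df$subtree %in% c("RCA", "LAD", "LCX")))
    stop("subtree must be one of RCA, LAD, LCX")
  # forest: exactly three roots, one per subtree, all of class proximal
  roots <- df$name[is.na(df$parent)]
  if (length(roots) != 3)
    stop("label forest must have exactly 3 roots, found: ", paste(roots, collapse = ", "))
  if (!setequal(df$subtree[match(roots, df$name)], c("RCA", "LAD", "LCX")))
    stop("label forest roots must cover the RCA, LAD and LCX subtrees")
  # every label reaches its subtree root; parent stays within subtree
  for (i in seq_len(nrow(df))) {
    cur <- df$name[i]; seen <- character(0)
    while (!is.na(df$parent[match(cur, df$name)])) {
      if (cur %in% seen) stop("cycle in parent links at label '", cur, "'")
      seen <- c(seen, cur)
      p <- df$parent[match(cur, df$name)]
      if (df$subtree[match(p, df$name)] != df$subtree[i])
        stop("label '", df$name[i], "' has parent chain crossing subtrees")
      cur <- p
    }
  }
  invisible(TRUE)
}

#' Direct children of a label in the model forest
#'
#' Returns the direct children of `label`, the non-side (main-branch
#' continuation) child first, then side branches in config order.
#'
#' @param model A `cat_model`.
#' @param label A label name present in the model.
#' @return Character vector of child label names (possibly empty).
#' @export
children_of <- function(model, label) {
  df <- model$labels
  if (!label %in% df$name) stop("unknown label: ", label)
  kids <- df[!is.na(df$parent) & df$parent == label, , drop = FALSE]
  c(kids$name[kids$position_class != "side"], kids$name[kids$position_class == "side"])
}

# ordered main-branch (non-side) label sequence for a subtree, root to distal
.main_sequence <- function(model, subtree) {
  df <- model$labels
  main <- df[df$subtree == subtree & df$position_class != "side", , drop = FALSE]
  root <- main$name[is.na(main$parent)]
  seq <- root
  repeat {
    nxt <- main$name[!is.na(main$parent) & main$parent == seq[length(seq)]]
    if (length(nxt) == 0) break
    seq <- c(seq, nxt[1])
  }
  seq
}

# side labels whose parent is `parent_label`, in config order
.side_labels_of <- function(model, parent_label) {
  df <- model$labels
  df$name[!is.na(df$parent) & df$parent == parent_label & df$position_class == "side"]
}

.model_weight <- function(model, label) {
  model$labels$weight[match(label, model$labels$name)]
}

.model_range <- function(model, label) {
  i <- match(label, model$labels$name)
  c(model$labels$length_min[i], model$labels$length_max[i])
}

# the dominance-defining posterior descending artery label of a model
.pda_label <- function(model) if (model$dominance == "RD") "RPDA" else "LPDA"

#' Serialize a model back to its JSON config form
#'
#' @param model A `cat_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  df <- model$labels
  labs <- stats::setNames(lapply(seq_len(nrow(df)), function(i) {
    list(weight = df$weight[i],
         length_min_mm = df$length_min[i],
         length_max_mm = df$length_max[i],
         parent = if (is.na(df$parent[i])) NULL else df$parent[i],
         subtree = df$subtree[i],
         position_class = df$position_class[i])
  }), df$name)
  cfg <- list(
    dominance = model$dominance,
    global = list(
      max_pathline_length_mm = model$global$max_pathline_length,
      max_angle_deg = model$global$max_angle_deg,
      min_pathline_length_mm = model$global$min_pathline_length,
      weight_threshold = model$global$weight_threshold
    ),
    labels = labs
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.cat_model <- function(x, ...) {
  cat("<cat_model> dominance:", x$dominance, "|", nrow(x$labels), "labels\n")
  cat("  global: max pathline", x$global$max_pathline_length, "mm; max angle",
      x$global$max_angle_deg, "deg; min pathline", x$global$min_pathline_length,
      "mm; weight threshold", x$global$weight_threshold, "\n")
  invisible(x)
}
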