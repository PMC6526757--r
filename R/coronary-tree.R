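#' Coronary segment trees
#'
#' A `coronary_tree` is a reduced (centerline-graph) representation of a
#' patient's epicardial coronary anatomy: a forest of at most three rooted
#' trees, one per main artery (RCA, LAD, LCX). Each segment carries a length,
#' proximal and distal diameters (linear taper in between), and — for RCA
#' segments only — a perfusion-territory tag (RV or LV) used by the
#' length-based outlet resistance model.
#'
#' @param patient_id Character identifier.
#' @param segments A data.frame with columns `id`, `artery` (one of
#'   `"RCA"`, `"LAD"`, `"LCX"`), `parent_id` (`NA` for the root of an
#'   artery), `length_mm`, `d_prox_mm`, `d_dist_mm`, `territory`
#'   (`"RV"`/`"LV"` for RCA segments, `"NA"` otherwise).
#' @param inlet_pressure_ref Aortic mean pressure in mmHg; may be `NA` and
#'   set at solve time.
#' @return An object of class `coronary_tree`.
#' @examples
#' seg <- data.frame(id = "lad1", artery = "LAD", parent_id = NA,
#'                   length_mm = 100, d_prox_mm = 3, d_dist_mm = 2.5,
#'                   territory = "NA")
#' coronary_tree("demo", seg)
#' @export
coronary_tree <- function(patient_id, segments, inlet_pressure_ref = NA_real_) {
  cols <- c("id", "artery", "parent_id", "length_mm", "d_prox_mm",
            "d_dist_mm", "territory")
  if (nrow(segments) == 0) {
    segments <- data.frame(id = character(), artery = character(),
                           parent_id = character(), length_mm = numeric(),
                           d_prox_mm = numeric(), d_dist_mm = numeric(),
                           territory = character(), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(cols, names(segments))
  if (length(missing_cols) > 0)
    stop("segment table missing column(s): ", paste(missing_cols, collapse = ", "))
  segments <- segments[, cols, drop = FALSE]
  segments$id <- as.character(segments$id)
  segments$artery <- as.character(segments$artery)
  segments$parent_id <- as.character(segments$parent_id)
  segments$territory <- as.character(segments$territory)
  segments$territory[is.na(segments$territory)] <- "NA"
  rownames(segments) <- NULL
  tree <- structure(list(patient_id = as.character(patient_id),
                         segments = segments,
                         inlet_pressure_ref = as.numeric(inlet_pressure_ref)),
                    class = "coronary_tree")
  validate_tree(tree)
  tree
}

#' Validate a coronary tree
#'
#' Checks per-segment geometry (positive lengths and diameters, bounded
#' distal/proximal diameter ratio), territory tagging (RV/LV on RCA segments
#' only), and topology (every `parent_id` resolves within the same artery,
#' no cycles, exactly one root per artery present).
#'
#' @param tree A `coronary_tree`.
#' @param taper_bound Maximum allowed `d_dist / d_prox` ratio (sanity bound).
#' @return `tree`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_tree <- function(tree, taper_bound = 1.5) {
  stopifnot(inherits(tree, "coronary_tree"))
  s <- tree$segments
  if (nrow(s) == 0) return(invisible(tree))
  if (anyDuplicated(s$id))
    stop("duplicate segment id: ", s$id[duplicated(s$id)][1])
  for (i in seq_len(nrow(s))) {
    id <- s$id[i]
    if (!s$artery[i] %in% c("RCA", "LAD", "LCX"))
      stop("segment '", id, "': field 'artery' must be RCA, LAD or LCX, got '",
           s$artery[i], "'")
    for (f in c("length_mm", "d_prox_mm", "d_dist_mm")) {
      v <- s[[f]][i]
      if (!is.finite(v) || v <= 0)
        stop("segment '", id, "': field '", f, "' must be a positive number")
    }
    if (s$d_dist_mm[i] > s$d_prox_mm[i] * taper_bound)
      stop("segment '", id, "': field 'd_dist_mm' exceeds ", taper_bound,
           " x proximal diameter")
    if (s$artery[i] == "RCA") {
      if (!s$territory[i] %in% c("RV", "LV"))
        stop("segment '", id, "': field 'territory' must be RV or LV for RCA segments")
    } else if (s$territory[i] != "NA") {
      stop("segment '", id, "': field 'territory' must be NA for ",
           s$artery[i], " segments")
    }
  }
  # topology: parent resolution, one root per artery, acyclic parent chains
  idx <- stats::setNames(seq_len(nrow(s)), s$id)
  for (i in seq_len(nrow(s))) {
    p <- s$parent_id[i]
    if (is.na(p)) next
    if (!p %in% s$id)
      stop("segment '", s$id[i], "': parent_id '", p, "' does not resolve")
    if (s$artery[idx[p]] != s$artery[i])
      stop("segment '", s$id[i], "': parent belongs to a different artery")
  }
  for (i in seq_len(nrow(s))) {
    seen <- character()
    cur <- s$id[i]
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop("cycle detected in segment graph at '", cur, "'")
      seen <- c(seen, cur)
      cur <- s$parent_id[idx[cur]]
    }
  }
  for (a in unique(s$artery)) {
    roots <- s$id[s$artery == a & is.na(s$parent_id)]
    if (length(roots) != 1)
      stop("artery ", a, " must have exactly one root segment, found ",
           length(roots))
  }
  invisible(tree)
}

#' @export
print.coronary_tree <- function(x, ...) {
  s <- x$segments
  cat("coronary_tree: patient '", x$patient_id, "', ", nrow(s),
      " segment(s)\n", sep = "")
  for (a in c("RCA", "LAD", "LCX")) {
    n <- sum(s$artery == a)
    if (n > 0)
      cat(sprintf("  %s: %d segment(s), total length %.1f mm\n",
                  a, n, sum(s$length_mm[s$artery == a])))
  }
  invisible(x)
}

.tree_json_list <- function(tree) {
  s <- tree$segments
  seg_list <- lapply(seq_len(nrow(s)), function(i) {
    list(id = s$id[i], artery = s$artery[i],
         parent_id = if (is.na(s$parent_id[i])) NULL else s$parent_id[i],
         length_mm = s$length_mm[i], d_prox_mm = s$d_prox_mm[i],
         d_dist_mm = s$d_dist_mm[i], territory = s$territory[i])
  })
  list(patient_id = tree$patient_id, segments = seg_list)
}

#' Write a coronary tree to its JSON file format
#'
#' The file format is a JSON document
#' `{"patient_id": ..., "segments": [{"id", "artery", "parent_id",
#' "length_mm", "d_prox_mm", "d_dist_mm", "territory"}, ...]}` with keys in
#' that order, UTF-8, 2-space indent; a root segment has `parent_id: null`.
#' Output is byte-deterministic for a given tree.
#'
#' @param tree A valid `coronary_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_tree()]
#' @export
save_tree <- function(tree, path) {
  validate_tree(tree)
  txt <- jsonlite::toJSON(.tree_json_list(tree), auto_unbox = TRUE,
                          digits = NA, pretty = 2, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, useBytes = TRUE)
  invisible(path)
}

#' Read a coronary tree from its JSON file format
#'
#' @param path Path to a tree JSON file written by [save_tree()] (or
#'   conforming to the same schema).
#' @return A validated `coronary_tree`.
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$patient_id) || is.null(doc$segments))
    stop("tree file must contain 'patient_id' and 'segments'")
  segs <- doc$segments
  row1 <- function(sg, i) {
    need <- c("id", "artery", "length_mm", "d_prox_mm", "d_dist_mm", "territory")
    for (f in need)
      if (is.null(sg[[f]]))
        stop("segment #", i, ": missing field '", f, "'")
    data.frame(id = as.character(sg$id), artery = as.character(sg$artery),
               parent_id = if (is.null(sg$parent_id)) NA_character_
                           else as.character(sg$parent_id),
               length_mm = as.numeric(sg$length_mm),
               d_prox_mm = as.numeric(sg$d_prox_mm),
               d_dist_mm = as.numeric(sg$d_dist_mm),
               territory = as.character(sg$territory),
               stringsAsFactors = FALSE)
  }
  segments <- if (length(segs) == 0) {
    data.frame(id = character(), artery = character(), parent_id = character(),
               length_mm = numeric(), d_prox_mm = numeric(),
               d_dist_mm = numeric(), territory = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_along(segs), function(i) row1(segs[[i]], i)))
  }
  coronary_tree(doc$patient_id, segments)
}

.segment_row <- function(tree, segment_id) {
  i <- match(segment_id, tree$segments$id)
  if (is.na(i)) stop("unknown segment id: ", segment_id)
  tree$segments[i, , drop = FALSE]
}

#' Summed qualifying vessel lengths per artery
#'
#' Sums segment lengths per artery over segments whose proximal diameter
#' strictly exceeds `diameter_threshold`; RCA lengths are split by perfusion
#' territory (RV vs LV). These are the `l` quantities consumed by the
#' length-based outlet resistance allocation.
#'
#' @param tree A `coronary_tree`.
#' @param diameter_threshold Qualification threshold in mm (strict `>` on the
#'   proximal diameter); default 1.5 mm.
#' @return A `summed_lengths` list with fields `l_LAD`, `l_LCX`, `l_RCA_RV`,
#'   `l_RCA_LV` (mm) and `diameter_threshold`.
#' @export
summed_lengths <- function(tree, diameter_threshold = 1.5) {
  stopifnot(diameter_threshold > 0)
  s <- tree$segments
  q <- s[s$d_prox_mm > diameter_threshold, , drop = FALSE]
  tot <- function(sel) if (any(sel)) sum(q$length_mm[sel]) else 0
  structure(list(
    l_LAD = tot(q$artery == "LAD"),
    l_LCX = tot(q$artery == "LCX"),
    l_RCA_RV = tot(q$artery == "RCA" & q$territory == "RV"),
    l_RCA_LV = tot(q$artery == "RCA" & q$territory == "LV"),
    diameter_threshold = diameter_threshold), class = "summed_lengths")
}

#' Path from an artery root to a segment
#'
#' @param tree A `coronary_tree`.
#' @param segment_id Segment id present in the tree.
#' @return Character vector of segment ids, root first, query segment last.
#' @export
path_to_root <- function(tree, segment_id) {
  s <- tree$segments
  idx <- stats::setNames(seq_len(nrow(s)), s$id)
  if (!segment_id %in% s$id) stop("unknown segment id: ", segment_id)
  path <- character()
  cur <- segment_id
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- s$parent_id[idx[cur]]
  }
  path
}

#' Terminal (outlet) segments of a tree
#'
#' @param tree A `coronary_tree`.
#' @param artery Optional artery filter.
#' @return Character vector of ids of segments with no children.
#' @export
terminal_segments <- function(tree, artery = NULL) {
  s <- tree$segments
  if (!is.null(artery)) s <- s[s$artery == artery, , drop = FALSE]
  s$id[!(s$id %in% tree$segments$parent_id)]
}

# total downstream length (segment itself plus all descendants), in mm
.subtree_length <- function(tree, segment_id) {
  s <- tree$segments
  kids <- s$id[!is.na(s$parent_id) & s$parent_id == segment_id]
  len <- s$length_mm[match(segment_id, s$id)]
  for (k in kids) len <- len + .subtree_length(tree, k)
  len
}

#' Local lumen diameter at a fractional position along a segment
#'
#' Diameters taper linearly from the proximal to the distal end.
#'
#' @param tree A `coronary_tree`.
#' @param segment_id Segment id.
#' @param position Fraction in \[0, 1\] from the proximal end.
#' @return Diameter in mm.
#' @export
local_diameter <- function(tree, segment_id, position) {
  stopifnot(position >= 0, position <= 1)
  seg <- .segment_row(tree, segment_id)
  seg$d_prox_mm + position * (seg$d_dist_mm - seg$d_prox_mm)
}
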