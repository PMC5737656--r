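#' @useDynLib gcell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp rnorm runif rexp kmeans sd lm coef nls
#' @importFrom utils read.table write.table modifyList
NULL

# --- condition helpers -------------------------------------------------------

gc_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gcell_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Region labels of the granule-cell model
#'
#' The model distinguishes seven regions: the soma, the axon proper, the axon
#' initial segment (AIS) and four dendritic bands stacked from the granule
#' cell layer outward: GCL, IML, MML and OML (inner/middle/outer molecular
#' layer). Channel densities and synapse placement are keyed on these labels.
#'
#' @return Character vector of the seven region labels.
#' @export
region_labels <- function() {
  c("soma", "axon", "AIS", "GCL", "IML", "MML", "OML")
}

#' @rdname region_labels
#' @export
dendritic_labels <- function() c("GCL", "IML", "MML", "OML")

# --- morph_tree class --------------------------------------------------------

#' Construct a labelled neuronal tree
#'
#' A `morph_tree` is an ordered node table with SWC semantics: each node has
#' an id, a parent id (`-1` for the root), 3D coordinates in micrometres, a
#' radius in micrometres and a region label (see [region_labels()]). Exactly
#' one root is allowed, every parent must precede its children, radii must be
#' positive and coordinates finite.
#'
#' @param nodes data.frame with columns `id`, `parent`, `x`, `y`, `z`,
#'   `radius`, `region`.
#' @param name,species,provenance free-form metadata strings.
#' @param validate logical; check invariants (default `TRUE`).
#' @return An object of class `morph_tree`.
#' @export
morph_tree <- function(nodes, name = "tree", species = NA_character_,
                       provenance = NA_character_, validate = TRUE) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "parent", "x", "y", "z", "radius", "region")
  if (!all(need %in% names(nodes)))
    gc_error("morph_bad_table", "node table must have columns: %s",
             paste(need, collapse = ", "))
  nodes <- nodes[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$region <- as.character(nodes$region)
  rownames(nodes) <- NULL
  tr <- structure(
    list(nodes = nodes,
         metadata = list(name = name, species = species,
                         provenance = provenance)),
    class = "morph_tree"
  )
  if (validate) validate_morph_tree(tr)
  tr
}

#' Validate a morph_tree's structural invariants
#'
#' Checks: single root, parent-before-child ordering, connectivity, positive
#' radii, finite coordinates and known region labels. Raises classed errors
#' (`morph_multiple_roots`, `swc_forward_reference`, `morph_bad_radius`,
#' `morph_bad_region`, `morph_bad_coords`).
#'
#' @param tree a `morph_tree`.
#' @return The tree, invisibly.
#' @export
validate_morph_tree <- function(tree) {
  n <- tree$nodes
  if (nrow(n) == 0L) gc_error("morph_empty", "tree has no nodes")
  if (anyDuplicated(n$id))
    gc_error("morph_duplicate_id", "duplicated node ids")
  roots <- which(n$parent == -1L)
  if (length(roots) != 1L)
    gc_error("morph_multiple_roots", "tree must have exactly one root, found %d",
             length(roots))
  pos <- match(n$parent, n$id)
  nonroot <- n$parent != -1L
  if (any(nonroot & is.na(pos)))
    gc_error("swc_forward_reference",
             "node %d references unknown parent %d",
             n$id[which(nonroot & is.na(pos))[1]],
             n$parent[which(nonroot & is.na(pos))[1]])
  bad <- which(nonroot & pos >= seq_len(nrow(n)))
  if (length(bad))
    gc_error("swc_forward_reference",
             "node %d references parent %d that does not precede it",
             n$id[bad[1]], n$parent[bad[1]])
  if (any(!is.finite(n$radius)) || any(n$radius <= 0))
    gc_error("morph_bad_radius", "radii must be positive and finite")
  if (any(!is.finite(as.matrix(n[, c("x", "y", "z")]))))
    gc_error("morph_bad_coords", "coordinates must be finite")
  if (!all(n$region %in% region_labels()))
    gc_error("morph_bad_region", "unknown region label(s): %s",
             paste(unique(setdiff(n$region, region_labels())), collapse = ", "))
  invisible(tree)
}

#' @export
print.morph_tree <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("<morph_tree> %s (%s): %d nodes, regions: %s\n",
              x$metadata$name,
              ifelse(is.na(x$metadata$species), "?", x$metadata$species),
              nrow(n),
              paste(names(table(n$region)), collapse = "/")))
  invisible(x)
}

# 0-based parent index vector (root -> 0 in R terms: NA)
parent_index <- function(tree) match(tree$nodes$parent, tree$nodes$id)

children_list <- function(tree) {
  pi <- parent_index(tree)
  split(seq_len(nrow(tree$nodes))[!is.na(pi)], pi[!is.na(pi)])
}

segment_lengths <- function(tree) {
  n <- tree$nodes
  pi <- parent_index(tree)
  len <- numeric(nrow(n))
  ok <- !is.na(pi)
  len[ok] <- sqrt((n$x[ok] - n$x[pi[ok]])^2 +
                  (n$y[ok] - n$y[pi[ok]])^2 +
                  (n$z[ok] - n$z[pi[ok]])^2)
  len
}

# --- SWC I/O -----------------------------------------------------------------

#' Default SWC type-code mapping
#'
#' Standard SWC codes 1/2/3/4 map onto soma, axon and dendrite; SWC has no
#' native codes for the AIS or molecular-layer bands, so an extended mapping
#' assigns custom codes to all seven regions (used when writing annotated
#' trees and by the synthetic-morphology generator).
#'
#' @return Named integer vector mapping region label to SWC type code.
#' @export
swc_extended_mapping <- function() {
  c(soma = 1L, axon = 2L, GCL = 3L, IML = 4L, MML = 5L, OML = 6L, AIS = 7L)
}

swc_default_read_mapping <- function() {
  # 3 and 4 are generic dendrite: carried as GCL until layers are assigned
  c(`1` = "soma", `2` = "axon", `3` = "GCL", `4` = "GCL")
}

#' Read a neuronal morphology from an SWC file
#'
#' Parses standard 7-column SWC (`id type x y z radius parent`, `#` comments).
#' Type codes map to region labels via `mapping`; by default 1 is soma, 2
#' axon and 3/4 generic dendrite (carried as GCL until [assign_regions()] is
#' applied). Unknown codes are an error unless a fallback mapping covering
#' them is supplied.
#'
#' @param path file path.
#' @param mapping named character vector: names are SWC type codes, values
#'   region labels. Defaults to the standard codes; pass
#'   `swc_inverse_mapping(swc_extended_mapping())` for files written with the
#'   extended codes.
#' @param name tree name (defaults to the file base name).
#' @return A validated [morph_tree()].
#' @export
read_swc <- function(path, mapping = swc_default_read_mapping(),
                     name = sub("\\.swc$", "", basename(path))) {
  if (!file.exists(path)) gc_error("swc_missing_file", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) gc_error("swc_malformed_line", "no data lines in %s", path)
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    gc_error("swc_malformed_line", "line %d has %d fields, expected 7",
             which(nf != 7L)[1], nf[nf != 7L][1])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (any(!is.finite(m[, c(1:6)])) || any(!is.finite(m[, 7])))
    gc_error("swc_malformed_line", "non-numeric field on line %d",
             which(rowSums(!is.finite(m)) > 0)[1])
  type <- as.character(as.integer(m[, 2]))
  unknown <- setdiff(unique(type), names(mapping))
  if (length(unknown))
    gc_error("swc_unknown_type", "unmapped SWC type code(s): %s",
             paste(unknown, collapse = ", "))
  if (any(m[, 6] <= 0))
    gc_error("swc_bad_radius", "nonpositive radius on line %d",
             which(m[, 6] <= 0)[1])
  nodes <- data.frame(
    id = as.integer(m[, 1]), parent = as.integer(m[, 7]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    region = unname(mapping[type]),
    stringsAsFactors = FALSE
  )
  roots <- sum(nodes$parent == -1L)
  if (roots > 1L)
    gc_error("swc_multiple_roots", "file contains %d roots", roots)
  morph_tree(nodes, name = name, provenance = path)
}

#' Invert a region-to-code SWC mapping
#' @param mapping named integer vector region -> code.
#' @return Named character vector code -> region, suitable for [read_swc()].
#' @export
swc_inverse_mapping <- function(mapping) {
  stats::setNames(names(mapping), as.character(mapping))
}

#' Write a morph_tree to an SWC file
#'
#' Emits standard 7-column SWC. The region-to-code mapping must cover every
#' region present in the tree; the basic default covers soma/axon/GCL only
#' (all written with their standard codes), so trees carrying AIS or layered
#' labels need `mapping = swc_extended_mapping()`.
#'
#' @param tree a `morph_tree`.
#' @param path output path.
#' @param mapping named integer vector region label -> SWC type code.
#' @param digits significant digits for coordinates/radii (default 6).
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path,
                      mapping = c(soma = 1L, axon = 2L, GCL = 3L),
                      digits = 6) {
  validate_morph_tree(tree)
  n <- tree$nodes
  miss <- setdiff(unique(n$region), names(mapping))
  if (length(miss))
    gc_error("swc_unmappable_region",
             "no SWC code for region(s): %s", paste(miss, collapse = ", "))
  fmt <- function(v) formatC(signif(v, digits), format = "g", digits = digits)
  out <- sprintf("%d %d %s %s %s %s %d",
                 n$id, unname(mapping[n$region]),
                 fmt(n$x), fmt(n$y), fmt(n$z), fmt(n$radius), n$parent)
  writeLines(c(sprintf("# SWC written by gcell (%s)", tree$metadata$name), out),
             path)
  invisible(path)
}

# --- region assignment -------------------------------------------------------

#' Layer specification for dendritic region assignment
#'
#' Two conventions are supported. The fractional convention (default)
#' normalizes molecular-layer depth per cell: the GCL/IML border sits at
#' `gcl_thickness` micrometres from the soma along the principal axis of the
#' dendritic arbor, the maximal dendritic extent defines depth 1, and the
#' IML/MML/OML are the equal thirds of that span. The explicit convention
#' gives boundary ranges in micrometres along the same axis, e.g.
#' `list(IML = c(0, 40), MML = c(40, 80), OML = c(80, Inf))` measured from the
#' GCL/IML border.
#'
#' @param mode `"fraction"` or `"explicit"`.
#' @param gcl_thickness GCL band thickness in um (fractional mode).
#' @param boundaries named list of `c(lower, upper)` um ranges for IML, MML,
#'   OML (explicit mode), measured from the GCL/IML border.
#' @param axis optional length-3 unit vector overriding the principal axis.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(mode = c("fraction", "explicit"), gcl_thickness = 10,
                       boundaries = NULL, axis = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit" && is.null(boundaries))
    gc_error("layer_spec_invalid", "explicit mode needs boundaries")
  structure(list(mode = mode, gcl_thickness = gcl_thickness,
                 boundaries = boundaries, axis = axis),
            class = "layer_spec")
}

principal_axis <- function(tree) {
  n <- tree$nodes
  dend <- n$region %in% dendritic_labels()
  root <- which(n$parent == -1L)
  xyz <- as.matrix(n[dend, c("x", "y", "z")])
  if (nrow(xyz) < 2L) return(c(0, 1, 0))
  ctr <- c(n$x[root], n$y[root], n$z[root])
  rel <- sweep(xyz, 2, ctr)
  v <- prcomp(rel, center = FALSE)$rotation[, 1]
  if (mean(rel %*% v) < 0) v <- -v   # orient away from the soma
  v / sqrt(sum(v^2))
}

#' Assign molecular-layer regions to dendritic nodes
#'
#' Every dendritic node gets exactly one of GCL/IML/MML/OML according to its
#' depth along the arbor's principal axis; soma, axon and AIS labels are
#' preserved. See [layer_spec()] for the two depth conventions.
#'
#' @param tree a `morph_tree`.
#' @param spec a [layer_spec()].
#' @return The relabelled `morph_tree`.
#' @export
assign_regions <- function(tree, spec = layer_spec()) {
  validate_morph_tree(tree)
  n <- tree$nodes
  dend <- which(n$region %in% dendritic_labels())
  if (!length(dend)) return(tree)
  ax <- spec$axis
  if (is.null(ax)) ax <- principal_axis(tree)
  ax <- ax / sqrt(sum(ax^2))
  root <- which(n$parent == -1L)
  proj <- (as.matrix(n[dend, c("x", "y", "z")]) -
           matrix(c(n$x[root], n$y[root], n$z[root]),
                  length(dend), 3, byrow = TRUE)) %*% ax
  proj <- drop(proj)
  if (spec$mode == "fraction") {
    border <- spec$gcl_thickness
    depth <- (proj - border) / max(max(proj) - border, .Machine$double.eps)
    lab <- ifelse(depth <= 0, "GCL",
           ifelse(depth < 1 / 3, "IML",
           ifelse(depth < 2 / 3, "MML", "OML")))
  } else {
    d <- proj - spec$gcl_thickness   # depth from the GCL/IML border
    lab <- rep(NA_character_, length(d))
    lab[d < 0] <- "GCL"
    for (ly in c("IML", "MML", "OML")) {
      b <- spec$boundaries[[ly]]
      if (!is.null(b)) lab[d >= b[1] & d < b[2]] <- ly
    }
    if (anyNA(lab))
      gc_error("region_outside_layers",
               "dendritic node %d (depth %.2f um) lies outside all layers",
               n$id[dend[which(is.na(lab))[1]]], d[which(is.na(lab))[1]])
  }
  n$region[dend] <- lab
  tree$nodes <- n
  tree
}

# --- morphometrics -----------------------------------------------------------

#' Morphometric summary of a neuronal tree
#'
#' Computes total dendritic length, per-layer dendritic length, number of
#' dendritic branch points, maximal branch order, van Pelt tree asymmetry,
#' membrane surface area under the frustum model, maximal Euclidean extent
#' and a Sholl intersection profile.
#'
#' Surface area treats each parent-child segment as a conical frustum with
#' lateral area `pi * (r1 + r2) * slant`; a degenerate single-node tree
#' yields zeros.
#'
#' @param tree a `morph_tree`.
#' @param sholl_spacing ring spacing in um for the Sholl profile (default 20).
#' @return A list of class `morpho_stats`.
#' @export
morphometrics <- function(tree, sholl_spacing = 20) {
  validate_morph_tree(tree)
  n <- tree$nodes
  pi_idx <- parent_index(tree)
  len <- segment_lengths(tree)
  dend <- n$region %in% dendritic_labels()
  dlen <- len * dend                      # segment belongs to its child node
  per_layer <- vapply(dendritic_labels(),
                      function(l) sum(dlen[n$region == l]), 0)
  kids <- tabulate(pi_idx[!is.na(pi_idx) & dend], nbins = nrow(n))
  branch_nodes <- which(kids >= 2L & dend)
  n_branch <- length(branch_nodes)
  # branch order: 1 at the stem, +1 after each dendritic branch point
  ord <- integer(nrow(n))
  for (i in seq_len(nrow(n))) {
    p <- pi_idx[i]
    if (is.na(p)) { ord[i] <- 0L; next }
    ord[i] <- ord[p] + as.integer(kids[p] >= 2L)
  }
  max_order <- if (any(dend)) max(ord[dend]) + 1L else 0L
  # van Pelt partition asymmetry over dendritic branch points
  tips <- integer(nrow(n))
  tips[kids == 0L & dend] <- 1L
  for (i in rev(seq_len(nrow(n)))) {
    p <- pi_idx[i]
    if (!is.na(p)) tips[p] <- tips[p] + tips[i]
  }
  asym <- NA_real_
  if (n_branch > 0) {
    ap <- vapply(branch_nodes, function(b) {
      ch <- which(pi_idx == b & dend)
      # multifurcations contribute the partition of their two largest
      # subtrees
      tt <- sort(tips[ch], decreasing = TRUE)[1:2]
      if (anyNA(tt) || sum(tt) <= 2) return(0)
      abs(tt[1] - tt[2]) / (tt[1] + tt[2] - 2)
    }, 0)
    asym <- mean(ap)
  }
  # frustum surface area over all non-root segments
  r <- n$radius
  ok <- !is.na(pi_idx)
  slant <- sqrt(len[ok]^2 + (r[ok] - r[pi_idx[ok]])^2)
  area <- sum(pi * (r[ok] + r[pi_idx[ok]]) * slant)
  root <- which(n$parent == -1L)
  eucl <- sqrt((n$x - n$x[root])^2 + (n$y - n$y[root])^2 + (n$z - n$z[root])^2)
  extent <- if (any(dend)) max(eucl[dend]) else 0
  sholl <- NULL
  if (any(dend) && extent > 0) {
    radii <- seq(sholl_spacing, extent + sholl_spacing, by = sholl_spacing)
    dd <- which(dend & !is.na(pi_idx))
    crossings <- vapply(radii, function(rr)
      sum((eucl[dd] >= rr) != (eucl[pi_idx[dd]] >= rr)), 0L)
    sholl <- data.frame(radius = radii, intersections = crossings)
  }
  structure(list(
    total_length = sum(dlen),
    layer_length = per_layer,
    n_branch_points = n_branch,
    max_branch_order = max_order,
    asymmetry = asym,
    surface_area = area,
    euclidean_extent = extent,
    sholl = sholl
  ), class = "morpho_stats")
}

#' @export
print.morpho_stats <- function(x, ...) {
  cat(sprintf(paste0("<morpho_stats> length %.1f um (GCL %.1f, IML %.1f, ",
                     "MML %.1f, OML %.1f), %d branch points, order %d, ",
                     "area %.1f um^2, extent %.1f um\n"),
              x$total_length, x$layer_length[["GCL"]], x$layer_length[["IML"]],
              x$layer_length[["MML"]], x$layer_length[["OML"]],
              x$n_branch_points, x$max_branch_order, x$surface_area,
              x$euclidean_extent))
  invisible(x)
}

#' Flatten morphometric summaries into a table
#'
#' @param stats_list list of `morpho_stats`.
#' @return data.frame, one row per tree, scalar metrics as columns.
#' @export
morpho_table <- function(stats_list) {
  rows <- lapply(stats_list, function(s) {
    c(total_length = s$total_length,
      stats::setNames(as.numeric(s$layer_length),
                      paste0("length_", names(s$layer_length))),
      n_branch_points = s$n_branch_points,
      max_branch_order = s$max_branch_order,
      asymmetry = s$asymmetry,
      surface_area = s$surface_area,
      euclidean_extent = s$euclidean_extent)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Path and Euclidean distance of a node from the root
#'
#' @param tree a `morph_tree`.
#' @param node a node id present in the tree.
#' @return list with `path_distance` (summed inter-node segment lengths along
#'   the root path) and `euclidean_distance` (straight line to the root), um.
#' @export
node_distances <- function(tree, node) {
  validate_morph_tree(tree)
  n <- tree$nodes
  i <- match(node, n$id)
  if (is.na(i)) gc_error("morph_unknown_node", "unknown node id %s", node)
  pi_idx <- parent_index(tree)
  len <- segment_lengths(tree)
  pd <- 0
  j <- i
  while (!is.na(pi_idx[j])) {
    pd <- pd + len[j]
    j <- pi_idx[j]
  }
  root <- which(n$parent == -1L)
  ed <- sqrt((n$x[i] - n$x[root])^2 + (n$y[i] - n$y[root])^2 +
             (n$z[i] - n$z[root])^2)
  list(path_distance = pd, euclidean_distance = ed)
}

# path distances for all nodes at once (used by the engine and protocols)
all_path_distances <- function(tree) {
  pi_idx <- parent_index(tree)
  len <- segment_lengths(tree)
  pd <- numeric(nrow(tree$nodes))
  for (i in seq_along(pd)) {
    p <- pi_idx[i]
    pd[i] <- if (is.na(p)) 0 else pd[p] + len[i]
  }
  pd
}
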