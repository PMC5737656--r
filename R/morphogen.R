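# Synthetic granule-cell morphologies: cone sampling + greedy MST + pruning,
# stretching, taper, jitter, soma profile and axon attachment.

#' Run an expression with a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parameters of the synthetic granule-cell generator
#'
#' Target points are sampled uniformly inside a 3D cone whose apex sits at
#' the soma, complemented by directed points placed between k-means clusters
#' of the targets and the soma. Points are connected by a greedy
#' minimum-spanning-tree rule balancing cable length against conduction path
#' length (`balancing_factor`), terminal segments shorter than
#' `prune_threshold` are pruned, the young tree is stretched to mature size,
#' diameters taper from root to tip, positions are jittered with band-limited
#' noise, and a soma profile plus axon with AIS are attached.
#'
#' @param n_target_points number of random target points in the cone.
#' @param cone list: `half_angle_deg`, `height` (um, young tree).
#' @param directed_point_rule list: `clusters` (k-means k), `fraction`
#'   (position along the cluster-centroid-to-soma segment, from the soma).
#' @param balancing_factor dimensionless in `[0, 1]`; 0 gives the classical
#'   Euclidean MST, larger values favour short conduction paths.
#' @param prune_threshold um; terminal segments shorter than this are pruned
#'   (default 20).
#' @param stretch per-axis scale factors applied young-to-mature.
#' @param taper list: `root_diam`, `tip_diam` (um), `law` (`"quadratic"` or
#'   `"linear"` in normalized path distance).
#' @param jitter list: `amplitude` (um, s.d.), `scale` (um, correlation
#'   length along the tree).
#' @param soma_profile list: `length`, `max_diam` (um).
#' @param axon_template list: `length`, `diam`, `ais_length` (um).
#' @param seed RNG seed.
#' @return An `mst_params` list.
#' @export
mst_params <- function(n_target_points = 30,
                       cone = list(half_angle_deg = 35, height = 300),
                       directed_point_rule = list(clusters = 4, fraction = 0.5),
                       balancing_factor = 0.5,
                       prune_threshold = 20,
                       stretch = c(x = 1, y = 1.35, z = 1),
                       taper = list(root_diam = 2.2, tip_diam = 0.8,
                                    law = "quadratic"),
                       jitter = list(amplitude = 3, scale = 20),
                       soma_profile = list(length = 15, max_diam = 12),
                       axon_template = list(length = 100, diam = 0.7,
                                            ais_length = 30),
                       seed = 1L) {
  p <- list(n_target_points = n_target_points, cone = cone,
            directed_point_rule = directed_point_rule,
            balancing_factor = balancing_factor,
            prune_threshold = prune_threshold, stretch = stretch,
            taper = taper, jitter = jitter, soma_profile = soma_profile,
            axon_template = axon_template, seed = seed)
  if (p$prune_threshold < 0) gc_error("mst_params_invalid", "prune_threshold < 0")
  if (p$balancing_factor < 0 || p$balancing_factor > 1)
    gc_error("mst_params_invalid", "balancing_factor must be in [0,1]")
  if (p$cone$height <= 0 || p$cone$half_angle_deg <= 0)
    gc_error("mst_degenerate_cone", "cone must have positive height and angle")
  structure(p, class = "mst_params")
}

#' Sample dendritic target points inside the growth cone
#'
#' Draws `n_target_points` points uniformly in the cone volume (apex at the
#' soma/origin, axis +y) and appends directed points placed between k-means
#' clusters of the targets and the soma.
#'
#' @param params an [mst_params()].
#' @param seed RNG seed (defaults to `params$seed`).
#' @return list with `targets` (n x 3 matrix) and `directed` (k x 3 matrix).
#' @export
sample_target_points <- function(params, seed = params$seed) {
  if (params$cone$height <= 0 || params$cone$half_angle_deg <= 0)
    gc_error("mst_degenerate_cone", "cone must have positive height and angle")
  h <- params$cone$height
  tanth <- tan(params$cone$half_angle_deg * pi / 180)
  with_seed(seed, {
    n <- params$n_target_points
    # uniform in cone volume: height ~ h * u^(1/3), disc radius scales with y
    y <- h * runif(n)^(1 / 3)
    rr <- y * tanth * sqrt(runif(n))
    ph <- runif(n, 0, 2 * pi)
    targets <- cbind(x = rr * cos(ph), y = y, z = rr * sin(ph))
    k <- min(params$directed_point_rule$clusters, n)
    km <- kmeans(targets, centers = k, nstart = 1)
    directed <- km$centers * params$directed_point_rule$fraction
    colnames(directed) <- c("x", "y", "z")
    list(targets = targets, directed = directed)
  })
}

#' Connect points to a dendritic tree by the greedy balanced MST rule
#'
#' Starting from the soma, repeatedly attaches the unconnected point that
#' minimizes Euclidean distance to an attachment node plus
#' `balancing_factor` times that node's path distance to the root. With
#' `balancing_factor = 0` this is Prim's algorithm and yields the classical
#' Euclidean minimum spanning tree. Ties attach to the lowest node id.
#'
#' @param points n x 3 matrix of target points (um).
#' @param soma length-3 soma position (default origin).
#' @param balancing_factor dimensionless in `[0, 1]`.
#' @param radius radius given to all nodes (um, placeholder before taper).
#' @return A `morph_tree` rooted at the soma; all points labelled GCL
#'   (generic dendrite) until [assign_regions()] is applied.
#' @export
connect_mst <- function(points, soma = c(0, 0, 0), balancing_factor = 0,
                        radius = 0.5) {
  points <- rbind(points)
  np <- nrow(points)
  if (np < 1L) gc_error("mst_no_points", "empty point set")
  pos <- rbind(soma, points)            # node 1 = soma
  parent <- integer(np + 1L); parent[1] <- -1L
  pathd <- numeric(np + 1L)
  order_added <- integer(np + 1L); order_added[1] <- 1L
  connected <- c(TRUE, rep(FALSE, np))
  # best attachment cost per unconnected point, updated as nodes join
  best_cost <- rep(Inf, np + 1L)
  best_attach <- integer(np + 1L)
  update_against <- function(node) {
    un <- which(!connected)
    if (!length(un)) return()
    d <- sqrt(rowSums((pos[un, , drop = FALSE] -
                       matrix(pos[node, ], length(un), 3, byrow = TRUE))^2))
    cost <- d + balancing_factor * pathd[node]
    # strict < keeps the earlier (lower-id) attachment node on ties
    better <- cost < best_cost[un]
    best_cost[un[better]] <<- cost[better]
    best_attach[un[better]] <<- node
  }
  update_against(1L)
  added <- 1L
  while (added <= np) {
    un <- which(!connected)
    i <- un[which.min(best_cost[un])]
    a <- best_attach[i]
    connected[i] <- TRUE
    parent[i] <- a
    pathd[i] <- pathd[a] + sqrt(sum((pos[i, ] - pos[a, ])^2))
    added <- added + 1L
    order_added[i] <- added
    update_against(i)
  }
  # emit in attachment order so parents precede children
  ord <- order(order_added)
  newid <- integer(np + 1L); newid[ord] <- seq_len(np + 1L)
  nodes <- data.frame(
    id = seq_len(np + 1L),
    parent = ifelse(parent[ord] == -1L, -1L, newid[pmax(parent[ord], 1L)]),
    x = pos[ord, 1], y = pos[ord, 2], z = pos[ord, 3],
    radius = radius,
    region = c("soma", rep("GCL", np)),   # soma is always added first
    stringsAsFactors = FALSE
  )
  morph_tree(nodes, name = "mst")
}

#' Prune short terminal dendritic segments
#'
#' Iteratively removes terminal segments (from a tip back to the nearest
#' branch point) whose length is below `threshold`, until none remain. Only
#' dendritic segments are touched.
#'
#' @param tree a `morph_tree`.
#' @param threshold um (default 20; 0 leaves the tree unchanged).
#' @return The pruned `morph_tree`.
#' @export
prune_short_terminals <- function(tree, threshold = 20) {
  if (threshold < 0) gc_error("mst_params_invalid", "threshold < 0")
  if (threshold == 0) return(tree)
  repeat {
    segs <- terminal_segments(tree)
    short <- segs[vapply(segs, function(s) s$length < threshold, TRUE)]
    if (!length(short)) break
    drop <- unique(unlist(lapply(short, `[[`, "nodes")))
    keep <- setdiff(seq_len(nrow(tree$nodes)), drop)
    nodes <- tree$nodes[keep, , drop = FALSE]
    rownames(nodes) <- NULL
    tree$nodes <- nodes
  }
  validate_morph_tree(tree)
  tree
}

# terminal dendritic segments: list of (nodes = row indices tip..below branch
# point, length). The branch point (or soma) itself is not included.
terminal_segments <- function(tree) {
  n <- tree$nodes
  pi_idx <- parent_index(tree)
  dend <- n$region %in% dendritic_labels()
  kids <- tabulate(pi_idx[!is.na(pi_idx)], nbins = nrow(n))
  len <- segment_lengths(tree)
  tips <- which(kids == 0L & dend)
  lapply(tips, function(tp) {
    idx <- integer(0); L <- 0; j <- tp
    repeat {
      idx <- c(idx, j); L <- L + len[j]
      p <- pi_idx[j]
      if (is.na(p) || kids[p] >= 2L || !dend[p]) break
      j <- p
    }
    list(nodes = idx, length = L)
  })
}

#' Generate a synthetic granule-cell morphology
#'
#' Full pipeline: cone sampling, greedy balanced-MST connection, pruning of
#' terminal segments shorter than `prune_threshold`, young-to-mature
#' stretching, monotone root-to-tip diameter taper, band-limited positional
#' jitter, soma diameter profile and a synthetic axon with AIS; dendritic
#' layers (GCL/IML/MML/OML) are then assigned by [assign_regions()].
#' Identical `params` (including seed) give identical trees.
#'
#' @param params an [mst_params()].
#' @return A region-labelled `morph_tree`.
#' @export
generate_granule_cell <- function(params = mst_params()) {
  pts <- sample_target_points(params)
  tree <- connect_mst(rbind(pts$targets, pts$directed),
                      balancing_factor = params$balancing_factor)
  tree <- prune_short_terminals(tree, params$prune_threshold)
  n <- tree$nodes
  # stretch young -> mature
  s <- params$stretch
  n$x <- n$x * s[[1]]; n$y <- n$y * s[[2]]; n$z <- n$z * s[[3]]
  tree$nodes <- n
  # taper: diameter as a monotone decreasing function of normalized path dist
  pd <- all_path_distances(tree)
  dmax <- max(pd, 1e-9)
  u <- pd / dmax
  tp <- params$taper
  fall <- if (identical(tp$law, "linear")) (1 - u) else (1 - u)^2
  diam <- tp$tip_diam + (tp$root_diam - tp$tip_diam) * fall
  tree$nodes$radius <- diam / 2
  # band-limited jitter: AR(1) noise along the tree, zero mean, no root shift
  tree <- with_seed(params$seed + 1L, jitter_tree(tree, params$jitter))
  # jitter can re-shorten a terminal, so the pruning invariant is enforced
  # once more on the final geometry
  tree <- prune_short_terminals(tree, params$prune_threshold)
  # soma profile + axon
  tree <- attach_soma_axon(tree, params)
  tree <- assign_regions(tree, layer_spec())
  tree$metadata$name <- sprintf("syngc_seed%d", params$seed)
  tree$metadata$species <- "mouse"
  tree$metadata$provenance <- "gcell synthetic morphology generator"
  validate_morph_tree(tree)
  tree
}

jitter_tree <- function(tree, jit) {
  if (jit$amplitude <= 0) return(tree)
  n <- tree$nodes
  pi_idx <- parent_index(tree)
  len <- segment_lengths(tree)
  eps <- matrix(rnorm(3 * nrow(n), 0, jit$amplitude), ncol = 3)
  s <- matrix(0, nrow(n), 3)
  for (i in seq_len(nrow(n))) {
    p <- pi_idx[i]
    if (is.na(p)) next   # root stays put
    a <- exp(-len[i] / jit$scale)
    s[i, ] <- a * s[p, ] + sqrt(1 - a^2) * eps[i, ]
  }
  n$x <- n$x + s[, 1]; n$y <- n$y + s[, 2]; n$z <- n$z + s[, 3]
  tree$nodes <- n
  tree
}

attach_soma_axon <- function(tree, params) {
  n <- tree$nodes
  sp <- params$soma_profile; ax <- params$axon_template
  n$radius[1] <- sp$max_diam / 2
  n$region[1] <- "soma"
  nid <- max(n$id)
  soma_pts <- data.frame(
    id = nid + 1:2, parent = c(n$id[1], n$id[1]),
    x = 0, y = c(sp$length / 2, -sp$length / 2), z = 0,
    radius = sp$max_diam / 4, region = "soma", stringsAsFactors = FALSE)
  # axon grows downward (-y) from the lower soma point, AIS first
  step <- 10
  ys <- seq(-sp$length / 2 - step, -sp$length / 2 - ax$length, by = -step)
  axon_pts <- data.frame(
    id = nid + 2 + seq_along(ys),
    parent = c(soma_pts$id[2], nid + 2 + seq_along(ys)[-length(ys)]),
    x = 0, y = ys, z = 0, radius = ax$diam / 2,
    region = ifelse(abs(ys + sp$length / 2) <= ax$ais_length, "AIS", "axon"),
    stringsAsFactors = FALSE)
  tree$nodes <- rbind(n, soma_pts, axon_pts)
  rownames(tree$nodes) <- NULL
  tree
}

#' Compare two morphometric populations
#'
#' Per-metric mean, standard deviation and overlap summary (Cohen's d on the
#' pooled s.d.); no hypothesis-test machinery.
#'
#' @param stats_a,stats_b lists of `morpho_stats` (see [morphometrics()]).
#' @return data.frame, one row per metric.
#' @export
compare_populations <- function(stats_a, stats_b) {
  if (!length(stats_a) || !length(stats_b))
    gc_error("empty_population", "both populations must be non-empty")
  ta <- morpho_table(stats_a); tb <- morpho_table(stats_b)
  metrics <- intersect(names(ta), names(tb))
  rows <- lapply(metrics, function(m) {
    a <- ta[[m]][is.finite(ta[[m]])]; b <- tb[[m]][is.finite(tb[[m]])]
    if (!length(a) || !length(b))
      return(data.frame(metric = m, mean_a = NA_real_, sd_a = NA_real_,
                        mean_b = NA_real_, sd_b = NA_real_,
                        effect_size = NA_real_, stringsAsFactors = FALSE))
    sa <- if (length(a) > 1) sd(a) else 0
    sb <- if (length(b) > 1) sd(b) else 0
    pooled <- sqrt((sa^2 + sb^2) / 2)
    d <- if (isTRUE(pooled > 0)) (mean(a) - mean(b)) / pooled
         else if (isTRUE(all.equal(mean(a), mean(b)))) 0 else Inf
    data.frame(metric = m, mean_a = mean(a), sd_a = sa,
               mean_b = mean(b), sd_b = sb, effect_size = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
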