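# SWC reading/writing, validation, layer assignment and tree measurements.

test_that("read_swc parses a minimal file and validates structure", {
  f <- write_tmp_swc(c("# comment",
                       "1 1 0 0 0 5 -1",
                       "2 3 0 10 0 1 1",
                       "3 3 0 20 0 1 2"))
  tr <- read_swc(f)
  expect_s3_class(tr, "morph_tree")
  expect_equal(nrow(tr$nodes), 3L)
  expect_equal(tr$nodes$region[1], "soma")
  expect_true(all(tr$nodes$region[2:3] %in% dendritic_labels()))

  # forward-referenced parent
  fbad <- write_tmp_swc(c("1 1 0 0 0 5 -1", "2 3 0 10 0 1 9",
                          "3 3 0 20 0 1 2"))
  expect_error(read_swc(fbad), class = "swc_forward_reference")
  # multiple roots
  f2 <- write_tmp_swc(c("1 1 0 0 0 5 -1", "2 1 0 50 0 5 -1"))
  expect_error(read_swc(f2), class = "swc_multiple_roots")
  # nonpositive radius
  f3 <- write_tmp_swc(c("1 1 0 0 0 0 -1"))
  expect_error(read_swc(f3), class = "swc_bad_radius")
  # unknown type code without fallback
  f4 <- write_tmp_swc(c("1 7 0 0 0 5 -1"))
  expect_error(read_swc(f4), class = "swc_unknown_type")
  # malformed line
  f5 <- write_tmp_swc(c("1 1 0 0 0 5"))
  expect_error(read_swc(f5), class = "swc_malformed_line")
})

test_that("write_swc round trip is the identity on the node table", {
  f <- write_tmp_swc(c("1 1 0 0 0 5.25 -1",
                       "2 3 1.5 10.125 -3 1.0625 1",
                       "3 3 0 20 0.5 0.75 2",
                       "4 2 0 -8 0 0.5 1"))
  tr <- read_swc(f)
  f2 <- tempfile(fileext = ".swc")
  write_swc(tr, f2)
  tr2 <- read_swc(f2)
  expect_equal(tr2$nodes, tr$nodes, tolerance = 1e-6)

  # single-node soma emits parent -1
  f3 <- tempfile(fileext = ".swc")
  write_swc(ball_tree(5), f3)
  ln <- grep("^#", readLines(f3), invert = TRUE, value = TRUE)
  expect_length(ln, 1L)
  expect_match(ln, "-1$")

  # AIS label cannot be written without an extended mapping
  ais <- morph_tree(data.frame(id = 1:2, parent = c(-1L, 1L), x = 0,
                               y = c(0, -10), z = 0, radius = c(5, 0.5),
                               region = c("soma", "AIS")))
  expect_error(write_swc(ais, tempfile()), class = "swc_unmappable_region")
  f4 <- tempfile(fileext = ".swc")
  write_swc(ais, f4, mapping = swc_extended_mapping())
  back <- read_swc(f4, mapping = swc_inverse_mapping(swc_extended_mapping()))
  expect_equal(back$nodes$region, c("soma", "AIS"))
})

vertical_tree <- function(depths, gcl = 10) {
  # soma at origin, dendritic nodes straight up at the given depths (um)
  morph_tree(data.frame(
    id = seq_len(length(depths) + 1L),
    parent = c(-1L, seq_len(length(depths))),
    x = 0, y = c(0, depths), z = 0, radius = 1,
    region = c("soma", rep("GCL", length(depths)))))
}

test_that("assign_regions implements both depth conventions", {
  # fractional thirds: extent 10 (GCL border) + 300; depth 0.5 -> MML
  tr <- vertical_tree(c(10, 10 + 150, 10 + 300))
  tr <- assign_regions(tr, layer_spec(gcl_thickness = 10))
  expect_equal(tr$nodes$region[-1], c("GCL", "MML", "OML"))

  tr2 <- vertical_tree(c(5, 110, 220, 310))
  tr2 <- assign_regions(tr2, layer_spec(gcl_thickness = 10))
  expect_equal(tr2$nodes$region[2], "GCL")    # below the IML onset
  expect_equal(tr2$nodes$region[5], "OML")

  # explicit boundaries from the GCL/IML border; 75 um -> MML
  sp <- layer_spec("explicit", gcl_thickness = 0,
                   boundaries = list(IML = c(0, 40), MML = c(40, 80),
                                     OML = c(80, Inf)))
  tr3 <- vertical_tree(c(20, 75, 120))
  tr3 <- assign_regions(tr3, sp)
  expect_equal(tr3$nodes$region[-1], c("IML", "MML", "OML"))

  # a node outside all explicit layers names itself in the error
  sp2 <- layer_spec("explicit", gcl_thickness = 0,
                    boundaries = list(IML = c(0, 40), MML = c(40, 80),
                                      OML = c(80, 100)))
  expect_error(assign_regions(vertical_tree(c(20, 150)), sp2),
               class = "region_outside_layers")

  # idempotent and total over dendritic nodes
  tr4 <- assign_regions(tr, layer_spec(gcl_thickness = 10))
  expect_identical(tr4$nodes, tr$nodes)
  expect_true(all(tr$nodes$region[-1] %in% dendritic_labels()))
})

test_that("morphometrics matches closed forms on constructed trees", {
  # unbranched 2-node path of 100 um
  tr <- morph_tree(data.frame(id = 1:2, parent = c(-1L, 1L), x = 0,
                              y = c(0, 100), z = 0, radius = 1,
                              region = c("soma", "GCL")))
  st <- morphometrics(tr)
  expect_equal(st$total_length, 100)
  expect_equal(st$n_branch_points, 0L)

  # symmetric Y: stem + two 50 um arms
  ytr <- y_tree(stem = 50, arm = 50, step = 10)
  sty <- morphometrics(ytr)
  expect_equal(sty$n_branch_points, 1L)
  expect_equal(sty$max_branch_order, 2L)
  expect_equal(sty$total_length, 150)
  expect_equal(sty$asymmetry, 0)

  # lateral area of a single non-tapering cylinder r=1, L=10
  cyl <- morph_tree(data.frame(id = 1:2, parent = c(-1L, 1L), x = 0,
                               y = c(0, 10), z = 0, radius = 1,
                               region = c("GCL", "GCL")))
  expect_equal(morphometrics(cyl)$surface_area, 2 * pi * 1 * 10,
               tolerance = 1e-12)

  # degenerate single-node tree
  st1 <- morphometrics(ball_tree(5))
  expect_equal(st1$total_length, 0)
  expect_equal(st1$n_branch_points, 0L)

  # additivity and rigid-motion invariance on a generated tree
  tr5 <- generate_granule_cell(mst_params(seed = 11))
  s5 <- morphometrics(tr5)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- tr5
  xyz <- as.matrix(tr5$nodes[, c("x", "y", "z")]) %*% R
  rot$nodes$x <- xyz[, 1] + 5; rot$nodes$y <- xyz[, 2] - 3
  rot$nodes$z <- xyz[, 3] + 1
  s5r <- morphometrics(rot)
  expect_equal(s5r$total_length, s5$total_length, tolerance = 1e-9)
  expect_equal(s5r$surface_area, s5$surface_area, tolerance = 1e-9)
  expect_equal(s5r$n_branch_points, s5$n_branch_points)
})

test_that("node distances follow the geometry", {
  # straight path: path distance equals Euclidean
  tr <- vertical_tree(c(30, 60, 90))
  d <- node_distances(tr, 4)
  expect_equal(d$path_distance, d$euclidean_distance)

  # right-angle elbow: two 50 um legs
  elbow <- morph_tree(data.frame(id = 1:3, parent = c(-1L, 1L, 2L),
                                 x = c(0, 0, 50), y = c(0, 50, 50), z = 0,
                                 radius = 1,
                                 region = c("soma", "GCL", "GCL")))
  d2 <- node_distances(elbow, 3)
  expect_equal(d2$path_distance, 100)
  expect_equal(d2$euclidean_distance, 50 * sqrt(2), tolerance = 1e-12)

  # root
  d3 <- node_distances(tr, 1)
  expect_equal(unlist(d3), c(path_distance = 0, euclidean_distance = 0))
  expect_error(node_distances(tr, 99), class = "morph_unknown_node")

  # path >= Euclidean across a generated tree
  g <- gc_fix()$tree
  for (id in g$nodes$id[seq(2, nrow(g$nodes), by = 5)]) {
    dd <- node_distances(g, id)
    expect_gte(dd$path_distance, dd$euclidean_distance - 1e-9)
  }
})
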