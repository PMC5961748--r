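test_that("graph extraction recovers line, Y and cross topologies", {
  # straight line
  line <- skeleton_from_coords(cbind(15L, 3:27))
  net <- extract_graph(line, 1)
  expect_identical(nrow(net$nodes), 2L)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$length_um, 24)
  expect_identical(sort(net$nodes$degree), c(1L, 1L))

  # symmetric Y: stem plus two diagonal arms
  y <- skeleton_from_coords(rbind(cbind(15L, 3:15),
                                  cbind(15L - 1:8, 15L + 1:8),
                                  cbind(15L + 1:8, 15L + 1:8)))
  net <- extract_graph(y, 1)
  expect_identical(nrow(net$edges), 3L)
  expect_identical(sort(net$nodes$degree), c(1L, 1L, 1L, 3L))
  expect_length(diagnose_overlaps(net), 0L)

  # plus: two crossing lines
  pl <- skeleton_from_coords(rbind(cbind(15L, 3:27), cbind(c(3:14, 16:27), 15L)))
  net <- extract_graph(pl, 1)
  expect_identical(nrow(net$edges), 4L)
  expect_identical(sort(net$nodes$degree), c(1L, 1L, 1L, 1L, 4L))
  expect_identical(diagnose_overlaps(net),
                   net$nodes$id[net$nodes$degree == 4L])

  # diagonal steps count sqrt(2)
  diag_sk <- skeleton_from_coords(cbind(3:12, 3:12))
  net <- extract_graph(diag_sk, 2)
  expect_equal(net$edges$length_um, 9 * sqrt(2) * 2)
})

test_that("a pure loop becomes a single self-loop edge with a warning", {
  ring <- skeleton_from_coords(rbind(cbind(5L, 5:10), cbind(10L, 5:10),
                                     cbind(6:9, 5L), cbind(6:9, 10L)))
  expect_warning(net <- extract_graph(ring, 1), "self-loop")
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$from, net$edges$to)
})

test_that("radius estimation matches the strip oracle", {
  m <- make_tube_mask(21, 200, "horizontal", pixel_size = 1)
  net <- estimate_radii(m, extract_graph(skeletonize_mask(m), 1))
  expect_equal(net$edges$radius_um, 10.5)   # EDT 11 at centre, -0.5 px

  m5 <- make_tube_mask(5, 60, "horizontal", pixel_size = 2)
  net5 <- estimate_radii(m5, extract_graph(skeletonize_mask(m5), 2))
  expect_equal(net5$edges$radius_um, 5.0)   # (3 - 0.5) px * 2 um
})

test_that("radius and length are recovered for all tube orientations", {
  for (w in c(5L, 9L, 13L)) {
    for (ori in c("horizontal", "vertical", "diagonal")) {
      m <- make_tube_mask(w, 120L, ori)
      net <- build_network(m)
      expect_identical(nrow(net$edges), 1L)
      expect_gte(net$edges$radius_um, w / 2 - 1)
      expect_lte(net$edges$radius_um, w / 2 + 1)
      expect_gte(net$edges$length_um, 120 - w - 1)  # -1: n px span n-1 steps
      expect_lte(net$edges$length_um, 120 + 1)
    }
  }
})

test_that("pruning removes spur hairs, is idempotent, errors on wipeout", {
  # strip with a 3-px hair poking from the centerline
  m <- make_tube_mask(21, 120, "horizontal")
  sk <- skeletonize_mask(m)
  centre <- which(sk, arr.ind = TRUE)
  row0 <- centre[1L, 1L]
  sk[row0 - 1:3, 60L] <- TRUE              # hair inside the strip
  net <- estimate_radii(m, extract_graph(sk, 1))
  expect_identical(nrow(net$edges), 3L)    # hair split the line
  pruned <- prune_network(net)
  expect_identical(nrow(pruned$edges), 1L) # 3 px < 2 * 10.5 um
  expect_identical(sort(pruned$nodes$degree), c(1L, 1L))

  # idempotence and no-op behaviour
  again <- prune_network(pruned)
  expect_equal(again$edges, pruned$edges)
  expect_equal(again$paths, pruned$paths)
  y <- y_network()
  expect_equal(prune_network(y, 0.1)$edges, y$edges)  # nothing below threshold

  tube <- single_tube_network(10, 15)      # shorter than 2 * radius
  expect_error(prune_network(tube), "degenerate")
})

test_that("degree-4 diagnostics flag crossings but not trees or the plexus", {
  net <- build_network(make_crossing_mask("medium"))
  expect_length(diagnose_overlaps(net), 1L)
  expect_length(diagnose_overlaps(y_network()), 0L)
  expect_length(diagnose_overlaps(vav_fixture()$net), 0L)
})

test_that("caliber histogram weights and conserves as specified", {
  net <- y_network(r_parent = 10, r_daughter = 5, L = 100)
  net$edges$radius_um <- c(10, 5, 10)      # diameters 20, 10, 20
  h <- caliber_histogram(net, bins = c(0, 15, 30))
  expect_equal(h$counts, c(100, 200))      # length-weighted split
  expect_equal(sum(h$counts), sum(net$edges$length_um))
  h1 <- caliber_histogram(single_tube_network(10.5, 80), bins = 5)
  expect_equal(sum(h1$counts > 0), 1L)     # single edge: one bin holds all
  hu <- caliber_histogram(net, bins = c(0, 15, 30), weighted = FALSE)
  expect_equal(sum(hu$counts), nrow(net$edges))
  no_radii <- extract_graph(skeleton_from_coords(cbind(15L, 3:27)), 1)
  expect_error(caliber_histogram(no_radii), "not estimated")
})

test_that("networks round-trip through GraphML/CSV files", {
  net <- vav_fixture()$net
  prefix <- file.path(withr::local_tempdir(), "net")
  write_network(net, prefix)
  expect_true(file.exists(paste0(prefix, ".graphml")))
  back <- read_network(prefix)
  expect_equal(back$edges$radius_um, net$edges$radius_um)
  expect_equal(back$edges$length_um, net$edges$length_um)
  expect_equal(back$paths, lapply(net$paths, function(p) {
    storage.mode(p) <- "integer"; p
  }))
  expect_equal(back$pixel_size, net$pixel_size)
})
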