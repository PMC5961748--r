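test_that("tube masks have exact footprints and odd-width guards", {
  m <- make_tube_mask(21, 200, "horizontal")
  expect_equal(sum(m$pixels), 21 * 200)
  m2 <- make_tube_mask(5, 50, "vertical")
  expect_equal(sum(m2$pixels), 5 * 50)
  expect_error(make_tube_mask(6, 50), "odd")
  # diagonal tube: perpendicular width within +/- 1 px of nominal
  d <- make_tube_mask(21, 200, "diagonal")
  width_est <- 2 * max(distance_transform(d$pixels))  # diameter at the core
  expect_gte(width_est, 20)
  expect_lte(width_est, 23)
})

test_that("crossing presets all produce exactly one degree-4 junction", {
  for (sz in c("small", "medium", "large")) {
    net <- build_network(make_crossing_mask(sz))
    expect_length(diagnose_overlaps(net), 1L)
  }
})

test_that("the V-A-V plexus meets its structural contract", {
  fx <- vav_fixture()
  net <- fx$net
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)            # connected
  expect_length(diagnose_overlaps(net), 0L)            # all junctions <= 3-way
  r_art <- net$edges$radius_um[net$edges$radius_um > 7 &
                                 net$edges$radius_um < 10]
  r_cap <- net$edges$radius_um[net$edges$radius_um <= 7]
  expect_gt(min(r_art), max(0, max(r_cap) - 2))
  expect_gt(stats::median(r_art), stats::median(r_cap))
  expect_error(vav_spec(row_spacing_px = 10), "spacing too small")
})

test_that("V-A-V hemodynamics: artery shear exceeds capillaries, flow conserves", {
  fx <- vav_fixture()
  sol <- vav_solution()
  art <- fx$net$edges$radius_um > 7 & fx$net$edges$radius_um < 10
  cap <- fx$net$edges$radius_um <= 7
  expect_gt(stats::median(sol$edges$tau_pa[art]),
            stats::median(sol$edges$tau_pa[cap]))
  # all flow entering at the artery leaves through the veins
  bal <- node_imbalance(fx$net, sol)
  inlet <- fx$bcs$node[fx$bcs$role == "inlet"]
  outlets <- fx$bcs$node[fx$bcs$role == "outlet"]
  expect_equal(-bal[inlet], sum(bal[outlets]), tolerance = 1e-9)
})

test_that("cell sampling is seed-reproducible and honours kappa limits", {
  fx <- vav_fixture()
  sol <- vav_solution()
  a <- sample_cells(fx$net, sol, 300, seed = 11)
  b <- sample_cells(fx$net, sol, 300, seed = 11)
  expect_identical(a$cells, b$cells)                   # byte-identical
  expect_false(identical(a$cells,
                         sample_cells(fx$net, sol, 300, seed = 12)$cells))
  expect_error(sample_cells(fx$net, sol, 0), "positive")

  # kappa -> infinity: every cell against the flow
  hi <- sample_cells(fx$net, sol, 400,
                     response = list(type = "vonmises", kappa_max = 5e4,
                                     tau_half = 1e-6), seed = 13)
  prs <- map_cells_to_flow(load_cell_points(hi$cells, fx$net$pixel_size),
                           fx$net, sol)
  tab <- directionality_table(prs)
  expect_gt(tab$ratio[tab$group == "all"], 0.95)

  # kappa = 0: uniform angles, ratio ~ 1/4
  un <- sample_cells(fx$net, sol, 3000,
                     response = list(type = "vonmises", kappa_max = 0,
                                     tau_half = 1), seed = 14)
  pu <- map_cells_to_flow(load_cell_points(un$cells, fx$net$pixel_size),
                          fx$net, sol)
  tbu <- directionality_table(pu)
  expect_lt(abs(tbu$ratio[tbu$group == "all"] - 0.25), 0.03)
})

test_that("von Mises sampler matches its analytic first moment", {
  set.seed(15)
  for (kap in c(0.5, 2, 8)) {
    x <- rvonmises(50000, pi / 3, kap)
    # mean resultant length of vM(kappa) is I1(kappa)/I0(kappa)
    rbar <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
    expect_lt(abs(rbar - besselI(kap, 1) / besselI(kap, 0)), 0.01)
    mdir <- atan2(mean(sin(x)), mean(cos(x)))
    expect_lt(abs(mdir - pi / 3), 0.02)
  }
})

test_that("a stated kappa(tau) response is recovered by the sensor analysis", {
  # independent oracle: P(against | tau) by numerical integration of the
  # von Mises density, crossing found by root-finding
  p_against <- function(kap) {
    if (kap < 1e-12) return(0.25)
    stats::integrate(function(x) exp(kap * cos(x)) /
                       (2 * pi * besselI(kap, 0)), -pi / 4, pi / 4)$value
  }
  kmax <- 4; khalf <- 1
  kfun <- function(tau) kmax * tau / (khalf + tau)
  tau_star_oracle <- stats::uniroot(function(tau) p_against(kfun(tau)) - 0.6,
                                    c(0.05, 3))$root
  n <- 5000
  pairs <- vaspol:::with_local_seed(99, {
    tau <- stats::runif(n, 0.05, 1.5)
    th <- rvonmises(n, pi, kfun(tau)) * 180 / pi
    p <- simulate_polarity_pairs(n, intercept = 0.5, slope = 0, seed = 1)
    p$t_mag_pa <- tau; p$tx <- tau; p$ty <- 0
    p$theta_deg <- th
    p
  })
  sc <- sensor_analysis(pairs, n_bins = 8)
  i <- findInterval(tau_star_oracle, c(sc$bins$tau_lo, max(sc$bins$tau_hi)),
                    all.inside = TRUE)
  bin_width <- sc$bins$tau_hi[i] - sc$bins$tau_lo[i]
  expect_lt(abs(sc$tau_star - tau_star_oracle), max(bin_width, 0.2))
})

test_that("reconstruction closes the loop on generated tubes", {
  m <- make_tube_mask(21, 200, "horizontal", pixel_size = 1)
  net <- build_network(m)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$radius_um, 10.5, tolerance = 1)
  expect_gte(net$edges$length_um, 200 - 21 - 1)
  expect_lte(net$edges$length_um, 200)
})
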