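#' Synthetic tube mask
#'
#' An ideal straight vessel: a rectangle of exact odd width, horizontal,
#' vertical, or rotated 45 degrees. Widths must be odd so the centerline is
#' unambiguous.
#'
#' @param width_px odd width >= 3 (perpendicular to the axis).
#' @param length_px length along the axis.
#' @param orientation `"horizontal"`, `"vertical"` or `"diagonal"`.
#' @param pixel_size micrometres per pixel.
#' @param margin background border in px.
#' @return a [binary_mask].
#' @export
make_tube_mask <- function(width_px, length_px,
                           orientation = c("horizontal", "vertical",
                                           "diagonal"),
                           pixel_size = 1, margin = 8L) {
  orientation <- match.arg(orientation)
  if (width_px < 3L || width_px %% 2L == 0L)
    stop("width must be odd and >= 3 (even widths have no centre row)")
  if (orientation == "horizontal") {
    px <- matrix(FALSE, width_px + 2L * margin, length_px + 2L * margin)
    px[margin + seq_len(width_px), margin + seq_len(length_px)] <- TRUE
  } else if (orientation == "vertical") {
    px <- matrix(FALSE, length_px + 2L * margin, width_px + 2L * margin)
    px[margin + seq_len(length_px), margin + seq_len(width_px)] <- TRUE
  } else {
    half <- (width_px - 1) / 2
    span <- ceiling(length_px / sqrt(2))
    side <- span + 2L * margin + width_px
    px <- matrix(FALSE, side, side)
    a <- c(margin + half + 1, margin + half + 1)
    b <- a + span
    co <- cbind(rep(seq_len(side), side),
                rep(seq_len(side), each = side))  # (row, col)
    d <- dist_point_segment(co[, 2L], co[, 1L], a[1L], a[2L], b[1L], b[2L])
    px[d <= half + 1e-9] <- TRUE
  }
  binary_mask(px, pixel_size)
}

dist_point_segment <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  tt <- pmin(pmax(((x - x1) * dx + (y - y1) * dy) / (dx^2 + dy^2), 0), 1)
  sqrt((x - (x1 + tt * dx))^2 + (y - (y1 + tt * dy))^2)
}

#' Synthetic crossing mask
#'
#' Two perpendicular tubes crossing at the centre — the planar appearance of
#' vessels passing at different depths. Guaranteed to trigger the degree-4
#' coplanarity diagnostic.
#'
#' @param size preset: `"small"`, `"medium"` or `"large"`.
#' @param pixel_size micrometres per pixel.
#' @return a [binary_mask].
#' @export
make_crossing_mask <- function(size = c("small", "medium", "large"),
                               pixel_size = 1) {
  size <- match.arg(size)
  par <- switch(size,
                small = c(w = 5L, l = 61L),
                medium = c(w = 9L, l = 121L),
                large = c(w = 13L, l = 201L))
  m <- 10L
  side <- par[["l"]] + 2L * m
  px <- matrix(FALSE, side, side)
  mid <- m + (par[["l"]] + 1L) %/% 2L
  hw <- (par[["w"]] - 1L) %/% 2L
  px[(mid - hw):(mid + hw), m + seq_len(par[["l"]])] <- TRUE
  px[m + seq_len(par[["l"]]), (mid - hw):(mid + hw)] <- TRUE
  binary_mask(px, pixel_size)
}

#' Specification of the synthetic vein-artery-vein plexus
#'
#' Geometry of the V-A-V fixture: a wide central artery flanked by two
#' capillary panels drained by lateral veins — the configuration of a
#' retinal wedge with pressure inlets/outlets at the radial vessels. The
#' capillary bed is a staggered (brick-like) lattice, so every junction is
#' three-way by construction.
#'
#' @param n_rows capillary rows per panel (default 8).
#' @param panel_width_px artery-to-vein distance in px.
#' @param row_spacing_px vertical spacing of capillary rows in px.
#' @param conn_spacing_px horizontal spacing of inter-row connectors.
#' @param capillary_width_px,artery_width_px,vein_width_px odd widths in px.
#' @param pixel_size micrometres per pixel (default 2).
#' @param p_inlet_pa,p_outlet_pa boundary pressures (gauge, Pa). The 150 Pa
#'   default drop is a desk-scale choice landing capillary WSS near the
#'   ~1 Pa literature value; it is a configuration default, not a measured
#'   quantity.
#' @return a `vav_spec` list.
#' @export
vav_spec <- function(n_rows = 8L, panel_width_px = 190L, row_spacing_px = 44L,
                     conn_spacing_px = 44L, capillary_width_px = 5L,
                     artery_width_px = 9L, vein_width_px = 11L,
                     pixel_size = 2, p_inlet_pa = 150, p_outlet_pa = 0) {
  if (conn_spacing_px < 4L * capillary_width_px ||
      row_spacing_px < 4L * capillary_width_px)
    stop("lattice spacing too small for the capillary width")
  if (panel_width_px < 2L * conn_spacing_px)
    stop("panel too narrow for the connector spacing")
  structure(as.list(environment()), class = "vav_spec")
}

#' Synthetic vein-artery-vein plexus mask
#'
#' Rasterizes the [vav_spec()] geometry and returns the mask together with
#' suggested boundary conditions (pixel positions of the artery inlet and
#' the two vein outlets, with pressures from the spec).
#'
#' @param spec a [vav_spec()].
#' @return list: `mask` ([binary_mask]), `bc_hints` (data frame `x`, `y` in
#'   px, `pressure`, `role`), `spec`.
#' @export
make_vav_plexus <- function(spec = vav_spec()) {
  stopifnot(inherits(spec, "vav_spec"))
  margin <- 16L
  x_l <- margin + 6L
  x_a <- x_l + spec$panel_width_px
  x_r <- x_a + spec$panel_width_px
  y_top <- margin + 6L
  rows_l <- y_top + (seq_len(spec$n_rows) - 1L) * spec$row_spacing_px
  rows_r <- rows_l + spec$row_spacing_px %/% 2L
  y_bot <- max(rows_r) + 30L
  w <- x_r + margin + 6L
  h <- y_bot + margin
  px <- matrix(FALSE, h, w)
  hrect <- function(y, x1, x2, width) {
    hw <- (width - 1L) %/% 2L
    px[(y - hw):(y + hw), x1:x2] <<- TRUE
  }
  vrect <- function(x, y1, y2, width) {
    hw <- (width - 1L) %/% 2L
    px[y1:y2, (x - hw):(x + hw)] <<- TRUE
  }
  # radial vessels
  vrect(x_a, min(rows_l), y_bot, spec$artery_width_px)
  vrect(x_l, min(rows_l), y_bot, spec$vein_width_px)
  vrect(x_r, min(rows_r), y_bot, spec$vein_width_px)
  # capillary rows
  for (y in rows_l) hrect(y, x_l, x_a, spec$capillary_width_px)
  for (y in rows_r) hrect(y, x_a, x_r, spec$capillary_width_px)
  # staggered inter-row connectors
  conn_x <- function(x0, x1, gap_index) {
    base <- seq(x0 + spec$conn_spacing_px %/% 2L, x1 - 16L,
                by = spec$conn_spacing_px)
    if (gap_index %% 2L == 1L) base <- base + spec$conn_spacing_px %/% 2L
    base[base <= x1 - 16L & base >= x0 + 16L]
  }
  for (j in seq_len(spec$n_rows - 1L)) {
    for (xc in conn_x(x_l, x_a, j))
      vrect(xc, rows_l[j], rows_l[j + 1L], spec$capillary_width_px)
    for (xc in conn_x(x_a, x_r, j))
      vrect(xc, rows_r[j], rows_r[j + 1L], spec$capillary_width_px)
  }
  bc_hints <- data.frame(
    x = c(x_a, x_l, x_r) - 1L, y = y_bot - 1L,
    pressure = c(spec$p_inlet_pa, spec$p_outlet_pa, spec$p_outlet_pa),
    role = c("inlet", "outlet", "outlet"))
  list(mask = binary_mask(px, spec$pixel_size), bc_hints = bc_hints,
       spec = spec)
}

#' Match boundary-condition hints to network terminals
#'
#' Finds, for each hinted position, the nearest degree-1 node of the
#' reconstructed network.
#'
#' @param network a [vessel_network].
#' @param bc_hints data frame `x`, `y` (px), `pressure`, `role`.
#' @param max_distance_px matching radius (default 30).
#' @return [boundary_conditions].
#' @export
match_bc_nodes <- function(network, bc_hints, max_distance_px = 30) {
  deg <- node_degrees(network$nodes, network$edges)
  term <- network$nodes[deg == 1L, , drop = FALSE]
  if (!nrow(term)) stop("network has no terminal nodes")
  pick <- integer(nrow(bc_hints))
  for (i in seq_len(nrow(bc_hints))) {
    d <- sqrt((term$x - bc_hints$x[i])^2 + (term$y - bc_hints$y[i])^2)
    j <- which.min(d)
    if (d[j] > max_distance_px)
      stop("no terminal node within ", max_distance_px, " px of hint ", i)
    pick[i] <- term$id[j]
  }
  boundary_conditions(pick, bc_hints$pressure, bc_hints$role)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler; the canonical noise model for directional
#' data. `kappa = 0` gives the uniform circular distribution.
#'
#' @param n sample size.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); may be a vector of length `n`.
#' @return angles in radians in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-8
  out[unif] <- stats::runif(sum(unif), -pi, pi)
  todo <- which(!unif)
  if (length(todo)) {
    k <- kappa[todo]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    pend <- rep(TRUE, length(todo))
    theta <- numeric(length(todo))
    while (any(pend)) {
      i <- which(pend)
      u1 <- stats::runif(length(i)); u2 <- stats::runif(length(i))
      u3 <- stats::runif(length(i))
      z <- cos(pi * u1)
      f <- (1 + r[i] * z) / (r[i] + z)
      cc <- k[i] * (r[i] - f)
      acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      ai <- i[acc]
      theta[ai] <- sign(u3[acc] - 0.5) * acos(pmin(pmax(f[acc], -1), 1))
      pend[ai] <- FALSE
    }
    out[todo] <- theta
  }
  ang <- out + mu
  ang <- ((ang + pi) %% (2 * pi)) - pi
  ang[ang <= -pi] <- pi
  ang
}

#' Sample synthetic endothelial cells coupled to the flow field
#'
#' Places `n` cells on perfused centerlines (uniformly over WSS sample
#' points, i.e. approximately length-weighted) and draws each cell's
#' relative polarity angle from a stated response model, then constructs
#' nucleus/Golgi points so that `golgi = nucleus + |p| * R(theta) f_hat`
#' with `f_hat` the local flow direction. Two response models:
#'
#' * `list(type = "vonmises", kappa_max, tau_half)`: theta ~ von Mises with
#'   mean 180 degrees and saturating concentration
#'   `kappa(tau) = kappa_max * tau / (tau_half + tau)` (Michaelis form, so
#'   both low- and high-WSS regimes are exercised; defaults
#'   `kappa_max = 6`, `tau_half = 0.5` Pa put the half-saturation inside
#'   the capillary WSS range).
#' * `list(type = "window", intercept, slope)`: the cell is against-flow
#'   (theta uniform in 180 +/- 45) with probability
#'   `intercept + slope * tau`, otherwise uniform in the complement.
#'
#' @param network a [vessel_network].
#' @param solution a converged `flow_solution`.
#' @param n number of cells (> 0).
#' @param response response model list (see above).
#' @param p_mag_um polarity vector length in micrometres (default 5,
#'   a typical nucleus-Golgi separation).
#' @param jitter_um perpendicular nucleus jitter off the centerline.
#' @param seed RNG seed (applied locally; same seed, identical cells).
#' @return list: `cells` (data frame in pixel coordinates with columns
#'   `cell_id`, `nucleus_x`, `nucleus_y`, `golgi_x`, `golgi_y`), `truth`
#'   (per cell: matched edge, tau, true theta), `response`, `seed`.
#' @export
sample_cells <- function(network, solution, n,
                         response = list(type = "vonmises", kappa_max = 6,
                                         tau_half = 0.5),
                         p_mag_um = 5, jitter_um = 2, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  samp <- wss_vector_field(network, solution, sample_spacing = 2)
  samp <- samp[samp$tau_pa > 0, , drop = FALSE]
  if (!nrow(samp)) stop("no perfused centerline to place cells on")
  ps <- network$pixel_size
  out <- with_local_seed(seed, {
    idx <- sample.int(nrow(samp), n, replace = TRUE)
    tau <- samp$tau_pa[idx]
    theta <- switch(response$type,
      vonmises = {
        kap <- response$kappa_max * tau / (response$tau_half + tau)
        rvonmises(n, pi, kap) * 180 / pi
      },
      window = {
        prob <- response$intercept + response$slope * tau
        if (any(prob < 0 | prob > 1))
          stop("window response probabilities outside [0, 1]")
        agx <- stats::runif(n) < prob
        th <- numeric(n)
        u <- stats::runif(sum(agx), 135, 225)
        th[agx] <- ifelse(u > 180, u - 360, u)
        th[!agx] <- stats::runif(sum(!agx), -135, 135)
        th
      },
      stop("unknown response type: ", response$type))
    fdir <- atan2(samp$ty[idx], samp$tx[idx])
    jit <- stats::runif(n, -jitter_um, jitter_um)
    nx <- samp$x_um[idx] - sin(fdir) * jit
    ny <- samp$y_um[idx] + cos(fdir) * jit
    pang <- fdir + theta * pi / 180
    gx <- nx + p_mag_um * cos(pang)
    gy <- ny + p_mag_um * sin(pang)
    list(cells = data.frame(cell_id = seq_len(n),
                            nucleus_x = nx / ps, nucleus_y = ny / ps,
                            golgi_x = gx / ps, golgi_y = gy / ps),
         truth = data.frame(cell_id = seq_len(n),
                            edge_id = samp$edge_id[idx],
                            tau_pa = tau, theta_true_deg = theta))
  })
  c(out, list(response = response, seed = seed))
}

#' Simulate a cell-flow pair table directly
#'
#' Bypasses the imaging pipeline: draws WSS magnitudes from `tau_range`
#' uniformly and relative angles from the `"window"` response (against-flow
#' with probability `intercept + slope * tau`), returning a ready
#' `cell_flow_pairs` table. Useful for exercising the statistical analyses
#' against a known ground truth, e.g. a 60% crossing at
#' tau = (0.6 - intercept)/slope.
#'
#' @param n number of cells.
#' @param intercept,slope parameters of P(against | tau).
#' @param tau_range range of WSS magnitudes (Pa).
#' @param p_mag_um polarity vector length.
#' @param seed RNG seed (applied locally).
#' @return a `cell_flow_pairs` data frame.
#' @export
simulate_polarity_pairs <- function(n, intercept = 0.2, slope = 0.2,
                                    tau_range = c(0, 3), p_mag_um = 5,
                                    seed = 1L) {
  with_local_seed(seed, {
    tau <- stats::runif(n, tau_range[1L], tau_range[2L])
    prob <- intercept + slope * tau
    if (any(prob < 0 | prob > 1)) stop("P(against | tau) outside [0, 1]")
    agx <- stats::runif(n) < prob
    th <- numeric(n)
    u <- stats::runif(sum(agx), 135, 225)
    th[agx] <- ifelse(u > 180, u - 360, u)
    th[!agx] <- stats::runif(sum(!agx), -135, 135)
    px <- p_mag_um * cos(th * pi / 180)
    py <- p_mag_um * sin(th * pi / 180)
    res <- data.frame(cell_id = seq_len(n), region = "unassigned",
                      px = px, py = py, p_mag_um = p_mag_um,
                      edge_id = NA_integer_, s_um = NA_real_,
                      tx = tau, ty = 0, t_mag_pa = tau,
                      theta_deg = th, s = px * tau,
                      dist_um = 0, matched = TRUE, zero_polarity = FALSE)
    class(res) <- c("cell_flow_pairs", "data.frame")
    res
  })
}

#' Analytic single-tube network
#'
#' Builds a one-edge network directly (no imaging), for analytic
#' Hagen-Poiseuille checks: Q = pi r^4 dP / (8 mu L), tau = r dP / (2 L).
#'
#' @param radius_um,length_um tube dimensions in micrometres.
#' @param pixel_size micrometres per pixel for the stored path.
#' @return a [vessel_network] with two terminal nodes and one edge.
#' @export
single_tube_network <- function(radius_um, length_um, pixel_size = 1) {
  npx <- max(2L, as.integer(round(length_um / pixel_size)) + 1L)
  path <- cbind(x = seq_len(npx) - 1L, y = 0L)
  nodes <- data.frame(id = 1:2, x = c(0L, npx - 1L), y = 0L, degree = 1L)
  edges <- data.frame(id = 1L, from = 1L, to = 2L,
                      length_um = length_um, radius_um = radius_um)
  new_vessel_network(nodes, edges, list(path),
                     list(rep(radius_um, npx)), pixel_size)
}
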