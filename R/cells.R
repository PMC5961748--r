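#' Load endothelial-cell nucleus/Golgi point pairs
#'
#' Reads a table with columns `cell_id`, `nucleus_x`, `nucleus_y`,
#' `golgi_x`, `golgi_y` (pixel coordinates) and computes each cell's
#' polarity vector `p = golgi - nucleus` in micrometres. Cells whose two
#' points coincide have no defined polarity axis; they are kept but flagged
#' (`zero_polarity`) and excluded from angle-based analyses.
#'
#' @param table a data frame or path to a CSV file.
#' @param pixel_size micrometres per pixel.
#' @return data frame of class `cell_records`: `cell_id`, nucleus/golgi
#'   positions in um, `px`, `py` (polarity vector, um), `p_mag_um`,
#'   `zero_polarity`, `region` (initially `"unassigned"`).
#' @export
load_cell_points <- function(table, pixel_size) {
  if (is.character(table)) table <- utils::read.csv(table)
  need <- c("cell_id", "nucleus_x", "nucleus_y", "golgi_x", "golgi_y")
  missing_col <- setdiff(need, names(table))
  if (length(missing_col))
    stop("missing column(s): ", paste(missing_col, collapse = ", "))
  if (anyDuplicated(table$cell_id))
    stop("duplicate cell_id: ",
         paste(unique(table$cell_id[duplicated(table$cell_id)]), collapse = ", "))
  stopifnot(pixel_size > 0)
  px <- (table$golgi_x - table$nucleus_x) * pixel_size
  py <- (table$golgi_y - table$nucleus_y) * pixel_size
  out <- data.frame(cell_id = table$cell_id,
                    nucleus_x_um = table$nucleus_x * pixel_size,
                    nucleus_y_um = table$nucleus_y * pixel_size,
                    golgi_x_um = table$golgi_x * pixel_size,
                    golgi_y_um = table$golgi_y * pixel_size,
                    px = px, py = py,
                    p_mag_um = sqrt(px^2 + py^2))
  out$zero_polarity <- out$p_mag_um == 0
  out$region <- "unassigned"
  class(out) <- c("cell_records", "data.frame")
  out
}

#' Signed angle from the flow vector to the polarity vector
#'
#' Angle in degrees in (-180, 180], measured from `t` to `p`,
#' counterclockwise positive in the image coordinate frame; exact
#' antiparallel returns +180. Vectorized over rows.
#'
#' @param p,t two-column matrices (or length-2 vectors) of x/y components.
#' @return numeric vector of angles in degrees.
#' @export
relative_angle <- function(p, t) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  if (is.null(dim(t))) t <- matrix(t, ncol = 2L)
  if (any(rowSums(p^2) == 0) || any(rowSums(t^2) == 0))
    stop("zero-length vector has no direction")
  cross <- t[, 1L] * p[, 2L] - t[, 2L] * p[, 1L]
  dot <- t[, 1L] * p[, 1L] + t[, 2L] * p[, 2L]
  ang <- atan2(cross, dot) * 180 / pi
  # atan2(0, -1) is +pi already; map any -180 representation to +180
  ang[ang <= -180] <- 180
  ang
}

#' Match cells to their local WSS vector
#'
#' For each cell, finds the nearest WSS sample point (on perfused,
#' flow-carrying edges) to the nucleus. Cells farther than `max_distance`
#' from any such point are flagged unmatched and excluded from analyses;
#' ties between equidistant samples are broken towards the lower edge id.
#'
#' @param cells a `cell_records` table from [load_cell_points()].
#' @param network a [vessel_network].
#' @param solution the matching `flow_solution`.
#' @param max_distance matching radius in micrometres (default 25).
#' @param sample_spacing WSS sampling step along centerlines (um).
#' @return data frame of class `cell_flow_pairs`: cell id, region, polarity
#'   vector, matched edge and arclength, WSS vector `tx`, `ty`, `t_mag_pa`,
#'   signed angle `theta_deg`, scalar product `s` (Pa um), nucleus-to-match
#'   distance and flags.
#' @export
map_cells_to_flow <- function(cells, network, solution, max_distance = 25,
                              sample_spacing = 2) {
  stopifnot(inherits(cells, "data.frame"))
  samp <- wss_vector_field(network, solution, sample_spacing)
  samp <- samp[samp$tau_pa > 0, , drop = FALSE]
  n <- nrow(cells)
  res <- data.frame(cell_id = cells$cell_id, region = cells$region,
                    px = cells$px, py = cells$py, p_mag_um = cells$p_mag_um,
                    edge_id = NA_integer_, s_um = NA_real_,
                    tx = NA_real_, ty = NA_real_, t_mag_pa = NA_real_,
                    theta_deg = NA_real_, s = NA_real_,
                    dist_um = NA_real_,
                    matched = FALSE, zero_polarity = cells$zero_polarity)
  if (nrow(samp)) {
    # deterministic tie-break: ordered by (edge_id, s); which.min takes first
    samp <- samp[order(samp$edge_id, samp$s_um), , drop = FALSE]
    for (i in seq_len(n)) {
      d2 <- (samp$x_um - cells$nucleus_x_um[i])^2 +
            (samp$y_um - cells$nucleus_y_um[i])^2
      j <- which.min(d2)
      d <- sqrt(d2[j])
      if (d > max_distance) next
      res$edge_id[i] <- samp$edge_id[j]
      res$s_um[i] <- samp$s_um[j]
      res$tx[i] <- samp$tx[j]; res$ty[i] <- samp$ty[j]
      res$t_mag_pa[i] <- samp$tau_pa[j]
      res$dist_um[i] <- d
      res$matched[i] <- TRUE
    }
  }
  ok <- res$matched & !res$zero_polarity
  if (any(ok)) {
    res$theta_deg[ok] <- relative_angle(
      cbind(res$px[ok], res$py[ok]), cbind(res$tx[ok], res$ty[ok]))
    res$s[ok] <- res$px[ok] * res$tx[ok] + res$py[ok] * res$ty[ok]
  }
  class(res) <- c("cell_flow_pairs", "data.frame")
  res
}

# even-odd point-in-polygon, boundary counts as inside
point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  out <- logical(length(x))
  for (i in seq_along(x)) {
    inside <- FALSE
    on_edge <- FALSE
    j <- n
    for (k in seq_len(n)) {
      x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[k]; y2 <- vy[k]
      # boundary test: point within the segment's bounding box and collinear
      if (min(x1, x2) - 1e-12 <= x[i] && x[i] <= max(x1, x2) + 1e-12 &&
          min(y1, y2) - 1e-12 <= y[i] && y[i] <= max(y1, y2) + 1e-12) {
        cr <- (x2 - x1) * (y[i] - y1) - (y2 - y1) * (x[i] - x1)
        if (abs(cr) < 1e-9 * max(1, abs(x2 - x1) + abs(y2 - y1)))
          on_edge <- TRUE
      }
      if ((y1 > y[i]) != (y2 > y[i])) {
        xint <- x1 + (y[i] - y1) / (y2 - y1) * (x2 - x1)
        if (x[i] < xint) inside <- !inside
      }
      j <- k
    }
    out[i] <- inside || on_edge
  }
  out
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

validate_polygon <- function(vx, vy, label) {
  n <- length(vx)
  if (n < 3L) stop("polygon '", label, "' needs at least 3 vertices")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1L || (i == 1L && j == n) || (i == n && j == 1L)) next
      a <- c(vx[i], vy[i]); b <- c(vx[i %% n + 1L], vy[i %% n + 1L])
      c_ <- c(vx[j], vy[j]); d_ <- c(vx[j %% n + 1L], vy[j %% n + 1L])
      if (segments_intersect(a, b, c_, d_))
        stop("polygon '", label, "' is self-intersecting")
    }
  }
  invisible(TRUE)
}

#' Assign vascular-bed region labels from polygons
#'
#' Labels each cell by the polygon containing its nucleus (even-odd rule;
#' points on a boundary count as inside). Cells covered by no polygon are
#' labelled `"unassigned"`; when polygons overlap, the first label in input
#' order wins, with a warning.
#'
#' @param cells a `cell_records` or `cell_flow_pairs` table with nucleus
#'   positions in micrometres (for pair tables, pass the originating
#'   `cell_records`).
#' @param polygons list of `list(label=, x=, y=)` with vertices in
#'   micrometres, or a path to a CSV (`label,x,y`) / GeoJSON file.
#' @return `cells` with its `region` column filled.
#' @export
assign_regions <- function(cells, polygons) {
  if (is.character(polygons)) polygons <- read_polygons(polygons)
  for (pg in polygons) validate_polygon(pg$x, pg$y, pg$label)
  region <- rep("unassigned", nrow(cells))
  hit_count <- integer(nrow(cells))
  for (pg in polygons) {
    inside <- point_in_polygon(cells$nucleus_x_um, cells$nucleus_y_um,
                               pg$x, pg$y)
    hit_count[inside] <- hit_count[inside] + 1L
    take <- inside & region == "unassigned"
    region[take] <- pg$label
  }
  if (any(hit_count > 1L))
    warning(sum(hit_count > 1L),
            " cell(s) fall in overlapping polygons; first label wins")
  cells$region <- region
  cells
}

read_polygons <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "geojson")) {
    gj <- jsonlite::read_json(path)
    lapply(gj$features, function(f) {
      ring <- f$geometry$coordinates[[1L]]
      list(label = f$properties$label,
           x = vapply(ring, function(v) as.numeric(v[[1L]]), 0),
           y = vapply(ring, function(v) as.numeric(v[[2L]]), 0))
    })
  } else {
    df <- utils::read.csv(path)
    lapply(split(df, factor(df$label, levels = unique(df$label))),
           function(d) list(label = d$label[1L], x = d$x, y = d$y))
  }
}
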