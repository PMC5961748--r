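#' @title Vessel network container
#' @description
#' A `vessel_network` is the graph form of a skeletonized lumen mask:
#' `nodes` (id, 0-based pixel position, degree), `edges` (id, endpoint node
#' ids, length and radius in micrometres), plus the ordered centerline pixel
#' path of every edge. Radii are `NA` until [estimate_radii()] runs.
#' @name vessel_network
NULL

new_vessel_network <- function(nodes, edges, paths, path_radii, pixel_size) {
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 path_radii = path_radii, pixel_size = pixel_size),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(
    "<vessel_network> %d nodes, %d edges, pixel_size %.4g um, total length %.1f um\n",
    nrow(x$nodes), nrow(x$edges), x$pixel_size, sum(x$edges$length_um)))
  invisible(x)
}

polyline_length_px <- function(path) {
  if (nrow(path) < 2L) return(0)
  d <- diff(path)
  sum(sqrt(d[, 1L]^2 + d[, 2L]^2))
}

#' Extract a vascular graph from a skeleton
#'
#' Skeleton pixels with other than two neighbours become nodes (branch points
#' and endpoints; mutually adjacent branch pixels are merged into a single
#' junction node), and maximal chains of two-neighbour pixels between them
#' become edges carrying their ordered centerline path. Diagonal steps count
#' \eqn{\sqrt 2} pixels towards edge length. A cyclic component without any
#' branch point is kept as a single self-loop edge anchored at an arbitrary
#' loop pixel, with a warning.
#'
#' @param skeleton logical matrix from [skeletonize_mask()].
#' @param pixel_size micrometres per pixel.
#' @return a [vessel_network].
#' @export
extract_graph <- function(skeleton, pixel_size) {
  stopifnot(is.logical(skeleton))
  if (!any(skeleton)) stop("no foreground")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  h <- nrow(skeleton)
  pid <- which(skeleton)                      # linear (column-major) indices
  np <- length(pid)
  id_of <- integer(h * ncol(skeleton)); id_of[pid] <- seq_len(np)
  rr <- ((pid - 1L) %% h) + 1L
  cc <- ((pid - 1L) %/% h) + 1L

  # --- pixel adjacency (8-connectivity, redundant diagonals removed) -------
  off <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  at <- function(r, c) {
    ok <- r >= 1L & r <= h & c >= 1L & c <= ncol(skeleton)
    out <- logical(length(r)); out[ok] <- skeleton[cbind(r[ok], c[ok])]
    out
  }
  pairs <- list()
  for (o in off) {
    r2 <- rr + o[1L]; c2 <- cc + o[2L]
    hit <- at(r2, c2)
    if (!any(hit)) next
    a <- seq_len(np)[hit]
    b <- id_of[(c2[hit] - 1L) * h + r2[hit]]
    if (all(o != 0L)) {
      # drop a diagonal link when an orthogonal two-step path exists
      redundant <- at(rr[a], c2[hit]) | at(r2[hit], cc[a])
      a <- a[!redundant]; b <- b[!redundant]
    }
    if (length(a)) pairs[[length(pairs) + 1L]] <- cbind(a, b)
  }
  adj_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(), 0L, 2L)
  deg_px <- tabulate(c(adj_pairs[, 1L], adj_pairs[, 2L]), nbins = np)
  nbr <- vector("list", np)
  if (nrow(adj_pairs)) {
    both <- rbind(adj_pairs, adj_pairs[, 2:1, drop = FALSE])
    both <- both[order(both[, 1L], both[, 2L]), , drop = FALSE]
    nbr_split <- split(both[, 2L], both[, 1L])
    nbr[as.integer(names(nbr_split))] <- nbr_split
  }

  # --- node pixels and junction clusters -----------------------------------
  is_node_px <- deg_px != 2L
  node_px <- which(is_node_px)
  cluster_of <- integer(np)
  if (length(node_px)) {
    sub <- adj_pairs[is_node_px[adj_pairs[, 1L]] & is_node_px[adj_pairs[, 2L]], ,
                     drop = FALSE]
    remap <- integer(np); remap[node_px] <- seq_along(node_px)
    g <- igraph::make_empty_graph(n = length(node_px), directed = FALSE)
    if (nrow(sub)) g <- igraph::add_edges(g, t(cbind(remap[sub[, 1L]],
                                                     remap[sub[, 2L]])))
    memb <- igraph::components(g)$membership
    cluster_of[node_px] <- memb
    ncl <- max(memb)
  } else ncl <- 0L

  # representative pixel per cluster: member nearest the cluster centroid,
  # clusters ordered in raster order for determinism
  cl_rep <- integer(ncl)
  if (ncl) {
    for (k in seq_len(ncl)) {
      mem <- node_px[cluster_of[node_px] == k]
      cy <- mean(rr[mem]); cx <- mean(cc[mem])
      cl_rep[k] <- mem[which.min((rr[mem] - cy)^2 + (cc[mem] - cx)^2)]
    }
    ord <- order(rr[cl_rep], cc[cl_rep])
    renum <- integer(ncl); renum[ord] <- seq_len(ncl)
    cluster_of[node_px] <- renum[cluster_of[node_px]]
    cl_rep[renum] <- cl_rep
  }

  # --- trace edges ----------------------------------------------------------
  visited <- logical(np)          # interior chain pixels already consumed
  seen_direct <- character(0L)    # node-node adjacency dedupe keys
  e_from <- integer(0L); e_to <- integer(0L); e_paths <- list()
  start_order <- order(rr[node_px], cc[node_px])
  for (s in node_px[start_order]) {
    for (m in nbr[[s]]) {
      if (is_node_px[m]) {
        if (cluster_of[m] == cluster_of[s]) next       # inside one junction
        key <- paste(min(s, m), max(s, m))
        if (key %in% seen_direct) next
        seen_direct <- c(seen_direct, key)
        e_from <- c(e_from, cluster_of[s]); e_to <- c(e_to, cluster_of[m])
        e_paths[[length(e_paths) + 1L]] <- c(s, m)
      } else {
        if (visited[m]) next
        path <- c(s, m); prev <- s; cur <- m
        while (!is_node_px[cur]) {
          visited[cur] <- TRUE
          nx <- nbr[[cur]]
          nx <- nx[nx != prev]
          if (length(nx) != 1L) stop("internal error: broken chain trace")
          prev <- cur; cur <- nx
          path <- c(path, cur)
        }
        e_from <- c(e_from, cluster_of[s]); e_to <- c(e_to, cluster_of[cur])
        e_paths[[length(e_paths) + 1L]] <- path
      }
    }
  }

  # --- pure loops (components with no node pixel) --------------------------
  loop_px <- which(!is_node_px & !visited)
  if (length(loop_px)) {
    warning("skeleton contains cyclic component(s) without branch points; ",
            "kept as self-loop edge(s)")
    remaining <- rep(TRUE, np); remaining[-loop_px] <- FALSE
    while (any(remaining)) {
      anchor <- which(remaining)[1L]
      ncl <- ncl + 1L
      cl_rep <- c(cl_rep, anchor)
      cluster_of[anchor] <- ncl
      path <- anchor; prev <- anchor; cur <- nbr[[anchor]][1L]
      while (cur != anchor) {
        path <- c(path, cur)
        nx <- nbr[[cur]]; nx <- nx[nx != prev]
        prev <- cur; cur <- nx[1L]
      }
      path <- c(path, anchor)
      remaining[path] <- FALSE
      e_from <- c(e_from, ncl); e_to <- c(e_to, ncl)
      e_paths[[length(e_paths) + 1L]] <- path
    }
  }

  paths <- lapply(e_paths, function(p) cbind(x = cc[p] - 1L, y = rr[p] - 1L))
  lens <- vapply(paths, polyline_length_px, 0) * pixel_size
  ne <- length(paths)
  nodes <- data.frame(id = seq_len(ncl),
                      x = cc[cl_rep] - 1L, y = rr[cl_rep] - 1L,
                      degree = 0L)
  edges <- data.frame(id = seq_len(ne),
                      from = e_from, to = e_to,
                      length_um = lens, radius_um = NA_real_)
  nodes$degree <- node_degrees(nodes, edges)
  new_vessel_network(nodes, edges, paths, vector("list", ne), pixel_size)
}

node_degrees <- function(nodes, edges) {
  tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
}

#' Estimate per-edge vessel radii from the mask distance transform
#'
#' The radius of an edge is the median, over its centerline path, of the
#' Euclidean distance-transform value minus half a pixel (pixel-centre
#' correction), scaled to micrometres and clamped to at least half a pixel.
#' The median resists inflation near junctions; a circular cross section is
#' assumed throughout.
#'
#' @param mask the [binary_mask] the skeleton came from.
#' @param network a [vessel_network] whose paths lie inside the mask.
#' @return the network with `edges$radius_um` and per-pixel path radii filled.
#' @export
estimate_radii <- function(mask, network) {
  assert_nonempty_mask(mask)
  stopifnot(inherits(network, "vessel_network"))
  if (nrow(network$edges) == 0L) stop("network has no edges")
  dt <- distance_transform(mask$pixels)
  ps <- network$pixel_size
  for (i in seq_len(nrow(network$edges))) {
    p <- network$paths[[i]]
    if (nrow(p) == 0L) stop("edge path of length 0")
    r_px <- pmax(dt[cbind(p[, "y"] + 1L, p[, "x"] + 1L)] - 0.5, 0.5)
    network$path_radii[[i]] <- r_px * ps
    network$edges$radius_um[i] <- stats::median(r_px) * ps
  }
  network
}

other_end <- function(edge, node) if (edge$from == node) edge$to else edge$from

# reverse an edge path so that it *ends* at node `at`
orient_path_to <- function(path, radii, from, to, at) {
  if (to == at) list(path = path, radii = radii, start = from)
  else list(path = path[rev(seq_len(nrow(path))), , drop = FALSE],
            radii = rev(radii), start = to)
}

#' Prune skeleton spurs from a network
#'
#' Removes terminal edges (one endpoint of degree 1) shorter than
#' `min_spur_factor` times their own radius — the hair-like artefacts that
#' thinning produces at boundary bumps — then re-merges any resulting
#' degree-2 chains, repeating to a fixed point, so the operation is
#' idempotent.
#'
#' @param network a [vessel_network] with radii estimated.
#' @param min_spur_factor spur threshold as a multiple of local radius
#'   (default 2).
#' @return the pruned [vessel_network].
#' @export
prune_network <- function(network, min_spur_factor = 2) {
  stopifnot(inherits(network, "vessel_network"))
  if (any(is.na(network$edges$radius_um)))
    stop("radii must be estimated before pruning (run estimate_radii)")
  nodes <- network$nodes; edges <- network$edges
  paths <- network$paths; radii <- network$path_radii
  repeat {
    deg <- node_degrees(nodes, edges)
    term <- edges$from != edges$to &
      (deg[edges$from] == 1L | deg[edges$to] == 1L)
    drop <- term & edges$length_um < min_spur_factor * edges$radius_um
    if (any(drop)) {
      if (all(drop)) stop("network degenerate after pruning")
      keep <- !drop
      edges <- edges[keep, , drop = FALSE]
      paths <- paths[keep]; radii <- radii[keep]
    }
    # merge chains through degree-2 nodes
    deg <- node_degrees(nodes, edges)
    merged <- FALSE
    for (nd in nodes$id[deg == 2L]) {
      inc <- which(edges$from == nd | edges$to == nd)
      if (length(inc) != 2L) next       # a self-loop occupies both slots
      e1 <- inc[1L]; e2 <- inc[2L]
      o1 <- orient_path_to(paths[[e1]], radii[[e1]],
                           edges$from[e1], edges$to[e1], at = nd)
      o2 <- orient_path_to(paths[[e2]], radii[[e2]],
                           edges$from[e2], edges$to[e2], at = nd)
      # o2 oriented to end at nd; flip it to start there
      p2 <- o2$path[rev(seq_len(nrow(o2$path))), , drop = FALSE]
      r2 <- rev(o2$radii)
      newp <- rbind(o1$path, p2[-1L, , drop = FALSE])
      newr <- c(o1$radii, r2[-1L])
      edges$from[e1] <- o1$start
      edges$to[e1] <- o2$start
      edges$length_um[e1] <- polyline_length_px(newp) * network$pixel_size
      edges$radius_um[e1] <- stats::median(newr)
      paths[[e1]] <- newp; radii[[e1]] <- newr
      edges <- edges[-e2, , drop = FALSE]
      paths <- paths[-e2]; radii <- radii[-e2]
      merged <- TRUE
      break                              # degrees changed; recompute
    }
    if (!merged && !any(drop)) break
  }
  if (nrow(edges) == 0L) stop("network degenerate after pruning")
  # drop now-isolated nodes and renumber
  deg <- node_degrees(nodes, edges)
  keep_nodes <- deg > 0L
  remap <- integer(nrow(nodes)); remap[keep_nodes] <- seq_len(sum(keep_nodes))
  nodes <- nodes[keep_nodes, , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  edges$from <- remap[edges$from]; edges$to <- remap[edges$to]
  edges$id <- seq_len(nrow(edges))
  rownames(nodes) <- rownames(edges) <- NULL
  nodes$degree <- node_degrees(nodes, edges)
  new_vessel_network(nodes, edges, paths, radii, network$pixel_size)
}

#' Flag putative non-coplanar vessel crossings
#'
#' Junctions with four or more incident segments usually indicate vessels
#' that pass at different depths but appear connected in the planar
#' projection — the planar-plexus assumption is then violated and simulated
#' hemodynamics around these nodes are unreliable.
#'
#' @param network a simplified [vessel_network].
#' @return integer vector of node ids with degree >= 4 (empty if the
#'   coplanarity check passes).
#' @export
diagnose_overlaps <- function(network) {
  stopifnot(inherits(network, "vessel_network"))
  deg <- node_degrees(network$nodes, network$edges)
  network$nodes$id[deg >= 4L]
}

#' Vessel caliber histogram
#'
#' Histogram of per-edge diameters (2r, micrometres), each edge weighted by
#' its centerline length by default (set `weighted = FALSE` for a plain
#' per-segment count).
#'
#' @param network a [vessel_network] with radii estimated.
#' @param bins number of bins, or a numeric vector of breaks spanning the
#'   observed diameters.
#' @param weighted length-weight each edge (default) or count segments.
#' @return list with `breaks`, `counts`, `weighted`, class
#'   `caliber_histogram`.
#' @export
caliber_histogram <- function(network, bins = 10, weighted = TRUE) {
  stopifnot(inherits(network, "vessel_network"))
  if (nrow(network$edges) == 0L) stop("empty network")
  if (any(is.na(network$edges$radius_um))) stop("radii not estimated")
  d <- 2 * network$edges$radius_um
  w <- if (weighted) network$edges$length_um else rep(1, length(d))
  breaks <- if (length(bins) == 1L)
    seq(min(d) - 1e-9, max(d) + 1e-9, length.out = bins + 1L) else sort(bins)
  if (min(d) < breaks[1L] || max(d) > breaks[length(breaks)])
    stop("breaks do not span the observed diameters")
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- vapply(seq_len(length(breaks) - 1L),
                   function(b) sum(w[bin == b]), 0)
  structure(list(breaks = breaks, counts = counts, weighted = weighted),
            class = "caliber_histogram")
}

#' Build a radius-annotated network from a mask in one call
#'
#' Convenience wrapper: skeletonize, extract the graph, estimate radii and
#' prune spurs.
#'
#' @param mask a [binary_mask].
#' @param min_spur_factor forwarded to [prune_network()].
#' @return a pruned [vessel_network].
#' @export
build_network <- function(mask, min_spur_factor = 2) {
  skel <- skeletonize_mask(mask)
  net <- extract_graph(skel, mask$pixel_size)
  net <- estimate_radii(mask, net)
  prune_network(net, min_spur_factor)
}

encode_path <- function(path)
  paste(sprintf("%d:%d", path[, "x"], path[, "y"]), collapse = ";")

decode_path <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("x", "y")
  m
}

#' Write a vessel network to GraphML and flat CSV tables
#'
#' Writes `<prefix>_nodes.csv`, `<prefix>_edges.csv` (centerline paths
#' encoded as `x:y;x:y;...`), `<prefix>_meta.json` and `<prefix>.graphml`.
#'
#' @param network a [vessel_network].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "vessel_network"))
  nodes <- network$nodes
  edges <- network$edges
  edges$path <- vapply(network$paths, encode_path, "")
  utils::write.csv(nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(edges, paste0(prefix, "_edges.csv"), row.names = FALSE)
  jsonlite::write_json(list(pixel_size = network$pixel_size),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "id", "radius_um", "length_um", "path")],
    directed = FALSE,
    vertices = nodes[, c("id", "x", "y", "degree")])
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}

#' Read a vessel network written by [write_network()]
#'
#' @param prefix the path prefix used at write time.
#' @return a [vessel_network].
#' @export
read_network <- function(prefix) {
  nodes <- utils::read.csv(paste0(prefix, "_nodes.csv"))
  edges <- utils::read.csv(paste0(prefix, "_edges.csv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  paths <- lapply(edges$path, decode_path)
  edges$path <- NULL
  net <- new_vessel_network(nodes, edges, paths,
                            vector("list", nrow(edges)), meta$pixel_size)
  net$nodes$degree <- node_degrees(net$nodes, net$edges)
  net
}
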