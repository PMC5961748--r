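# Shared fixtures, built once per test run (everything is generated in code;
# no data files). Heavy fixtures are cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

vav_fixture <- function() {
  cached("vav", function() {
    vav <- make_vav_plexus()
    net <- build_network(vav$mask)
    bcs <- match_bc_nodes(net, vav$bc_hints)
    list(vav = vav, net = net, bcs = bcs)
  })
}

vav_solution <- function() {
  cached("vav_sol", function() {
    fx <- vav_fixture()
    solve_flow(fx$net, fx$bcs, newtonian(3.5e-3))
  })
}

# hand-built network: one parent tube splitting into two identical daughters
y_network <- function(r_parent = 10, r_daughter = 6, L = 100) {
  path1 <- cbind(x = 0:100, y = 0L)
  path2 <- cbind(x = 100 + 0:100, y = 0:100)
  path3 <- cbind(x = 100 + 0:100, y = -(0:100))
  nodes <- data.frame(id = 1:4,
                      x = c(0L, 100L, 200L, 200L),
                      y = c(0L, 0L, 100L, -100L),
                      degree = c(1L, 3L, 1L, 1L))
  edges <- data.frame(id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 4L),
                      length_um = c(L, L, L),
                      radius_um = c(r_parent, r_daughter, r_daughter))
  vaspol:::new_vessel_network(nodes, edges, list(path1, path2, path3),
                              vector("list", 3L), 1)
}

# hand-drawn skeleton matrices for graph-extraction unit tests
skeleton_from_coords <- function(coords, dim = c(30L, 30L)) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[coords] <- TRUE
  m
}

# independent oracle: dense base-R solve of the Kirchhoff system
dense_flow_oracle <- function(net, bcs, mu) {
  nn <- nrow(net$nodes)
  r <- net$edges$radius_um * 1e-6
  L <- net$edges$length_um * 1e-6
  g <- pi * r^4 / (8 * mu * L)
  A <- matrix(0, nn, nn)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    A[a, a] <- A[a, a] + g[i]; A[b, b] <- A[b, b] + g[i]
    A[a, b] <- A[a, b] - g[i]; A[b, a] <- A[b, a] - g[i]
  }
  p <- numeric(nn)
  p[bcs$node] <- bcs$pressure
  free <- setdiff(seq_len(nn), bcs$node)
  if (length(free)) {
    rhs <- -A[free, bcs$node, drop = FALSE] %*% bcs$pressure
    p[free] <- solve(A[free, free, drop = FALSE], rhs)
  }
  list(pressure = p,
       Q = g * (p[net$edges$from] - p[net$edges$to]))
}

# brute-force node imbalance, independent of the solver internals
node_imbalance <- function(net, sol) {
  bal <- numeric(nrow(net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    bal[net$edges$from[i]] <- bal[net$edges$from[i]] - sol$edges$q_m3s[i]
    bal[net$edges$to[i]] <- bal[net$edges$to[i]] + sol$edges$q_m3s[i]
  }
  bal
}
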