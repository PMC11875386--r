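# Independent oracles and shared fixtures for the test-suite.
# Oracles are deliberately naive (O(n^2) scans, BFS, dense algebra) and never
# share code with the implementation paths they check.

# Brute-force voxel graph: enumerate pore voxels in raster order and test all
# pairs for Manhattan distance 1.
brute_force_graph <- function(image) {
  dims <- image$dims
  idx <- which(image$values == 0L)
  coords <- arrayInd(idx, dims) - 1L
  n <- length(idx)
  edges <- matrix(integer(), 0L, 2L)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (sum(abs(coords[a, ] - coords[b, ])) == 1L)
          edges <- rbind(edges, c(a, b))
      }
    }
  }
  if (nrow(edges) > 1L)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  list(n = n, coords = coords, edges = edges,
       degrees = tabulate(edges, nbins = max(n, 1L))[seq_len(n)])
}

# Flood-fill (BFS) connected components over a voxel graph's edge list.
flood_components <- function(graph) {
  n <- graph$n
  adj <- vector("list", n)
  if (nrow(graph$edges) > 0L) {
    for (r in seq_len(nrow(graph$edges))) {
      i <- graph$edges[r, 1L]; j <- graph$edges[r, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- integer(n)
  label <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    label <- label + 1L
    queue <- s
    comp[s] <- label
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- label
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# Dense matrix-exponential solution of the graph diffusion equation.
expm_solution <- function(M0, L, D, t) {
  as.numeric(Matrix::expm(-D * t * Matrix::Matrix(as.matrix(L))) %*% M0)
}

# Random small binary image with the given pore probability.
random_image <- function(dims, p_pore = 0.5) {
  pore_image(array(as.integer(runif(prod(dims)) > p_pore), dims))
}

# Shared fixtures, built once per session.
.fixtures <- new.env(parent = emptyenv())
get_fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 16^3 connected ball packing used by the diffusion-scheme tests.
fixture_packing16 <- function() {
  get_fixture("packing16", function() {
    pk <- generate_ball_packing(dims = 16L, n_balls = 6L,
                                radius_range = c(2.5, 4), seed = 160L)
    g <- build_voxel_graph(pk$image)
    list(balls = pk$balls, image = pk$image, graph = g,
         L = laplacian(g))
  })
}

# 32^3 connected packing for the whole-run conservation checks.
fixture_packing32 <- function() {
  get_fixture("packing32", function() {
    pk <- generate_ball_packing(dims = 32L, n_balls = 12L,
                                radius_range = c(4, 7), seed = 320L)
    list(balls = pk$balls, image = pk$image,
         graph = build_voxel_graph(pk$image))
  })
}

# 48^3 / 20-ball packing for the conductance-learning experiments.
fixture_packing48 <- function() {
  get_fixture("packing48", function() {
    pk <- generate_ball_packing(dims = 48L, n_balls = 20L,
                                radius_range = c(4, 8), seed = 480L)
    g <- build_voxel_graph(pk$image)
    net <- build_ball_network(pk$balls)
    part <- map_voxels_to_balls(g, pk$balls)
    list(balls = pk$balls, image = pk$image, graph = g, net = net,
         partition = part, L = laplacian(g))
  })
}

# Small ball network (5-ball chain) for learning tests: path of overlapping
# balls along x.
fixture_ball_chain <- function() {
  get_fixture("ball_chain", function() {
    centers <- cbind(x = c(6, 11, 16, 21, 26), y = rep(8, 5), z = rep(8, 5))
    balls <- ball_set(centers, radii = rep(3.5, 5))
    net <- build_ball_network(balls)
    img <- voxelize_balls(balls, c(32L, 16L, 16L))
    g <- build_voxel_graph(img)
    part <- map_voxels_to_balls(g, balls)
    list(balls = balls, net = net, image = img, graph = g, partition = part)
  })
}
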