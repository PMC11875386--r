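#' A set of balls approximating a pore space
#'
#' Geometrical primitives of the pore-network model: balls with continuous
#' centers (voxel units) and radii. The analytic volume `4/3*pi*r^3` is
#' attached per ball.
#'
#' @param centers numeric `q x 3` matrix of centers (columns x, y, z).
#' @param radii positive radii, length `q`.
#' @return a `data.frame` of class `ball_set` with columns `x, y, z, r, v`.
#' @export
ball_set <- function(centers, radii) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  radii <- as.numeric(radii)
  stopifnot(nrow(centers) == length(radii), all(radii > 0),
            all(is.finite(centers)), all(is.finite(radii)))
  structure(
    data.frame(x = centers[, 1L], y = centers[, 2L], z = centers[, 3L],
               r = radii, v = 4 / 3 * pi * radii^3),
    class = c("ball_set", "data.frame")
  )
}

# Contact surface of two overlapping spheres: area of the intersection disc.
# For partial overlap (|r1-r2| < d < r1+r2) the disc radius follows from
# standard sphere-sphere geometry; when one sphere is contained in the other
# (d <= |r1-r2|) there is no intersection circle and the great disc of the
# smaller sphere is used.
.contact_surface <- function(d, r1, r2) {
  contained <- d <= abs(r1 - r2)
  rc2 <- (4 * d^2 * r1^2 - (d^2 - r2^2 + r1^2)^2) / (4 * d^2)
  ifelse(contained, pi * pmin(r1, r2)^2, pi * pmax(rc2, 0))
}

#' Build the adjacency network of a ball set
#'
#' Two balls are adjacent iff they strictly overlap (center distance
#' `d < r_i + r_j`; tangent balls are not adjacent). Each edge carries the
#' contact surface `S_ij`, the center distance `d_ij` and the diffusional
#' conductance, initialized to the classical geometric value
#' `theta_ij = S_ij / d_ij`. Optionally a global calibration factor `alpha`
#' scales that initialization (`alpha * S/d`, the legacy calibrated form;
#' `alpha = 1` by default).
#'
#' With `surface = "voxel"` the contact surface is instead counted as the
#' number of voxel faces shared between the two balls' partition cells
#' (requires `graph` and `partition`).
#'
#' @param balls a [ball_set()].
#' @param surface `"analytic"` (intersection-disc area, default) or
#'   `"voxel"` (shared partition faces).
#' @param alpha optional global factor on the `S/d` initialization.
#' @param graph,partition required for `surface = "voxel"`: the voxel graph
#'   of the ball image and its [map_voxels_to_balls()] partition.
#' @return an object of class `ball_network`: `balls`, `q`, `volumes`, and
#'   `edges` (data.frame `i, j, d, s, theta` with `i < j`; conductances are
#'   symmetric and stored once).
#' @examples
#' b <- ball_set(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 1))
#' net <- build_ball_network(b)
#' net$edges$s      # 3*pi/4
#' @export
build_ball_network <- function(balls, surface = c("analytic", "voxel"),
                               alpha = 1, graph = NULL, partition = NULL) {
  surface <- match.arg(surface)
  stopifnot(inherits(balls, "ball_set"), nrow(balls) >= 1L, alpha > 0)
  q <- nrow(balls)
  dm <- as.matrix(dist(as.matrix(balls[, c("x", "y", "z")])))
  rs <- balls$r
  pair <- which(upper.tri(dm) & dm < outer(rs, rs, "+"), arr.ind = TRUE)
  if (nrow(pair) > 0L && any(dm[pair] == 0))
    stop("coincident ball centers: center distance 0 is undefined")
  i <- pair[, 1L]; j <- pair[, 2L]
  d <- dm[pair]
  s <- if (nrow(pair) > 0L) .contact_surface(d, rs[i], rs[j]) else numeric()
  edges <- data.frame(i = as.integer(i), j = as.integer(j), d = d, s = s)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  if (surface == "voxel") {
    if (is.null(graph) || is.null(partition))
      stop("surface = \"voxel\" needs both `graph` and `partition`")
    edges$s <- .voxel_contact_surface(edges, graph, partition)
  }
  edges$theta <- alpha * edges$s / edges$d
  structure(list(balls = balls, q = q, volumes = balls$v, edges = edges),
            class = "ball_network")
}

# Count voxel faces between the partition cells of each adjacent ball pair.
.voxel_contact_surface <- function(edges, graph, partition) {
  of <- partition$ball_of
  e <- graph$edges
  cross <- of[e[, 1L]] != of[e[, 2L]]
  if (!any(cross)) return(numeric(nrow(edges)))
  a <- pmin(of[e[cross, 1L]], of[e[cross, 2L]])
  b <- pmax(of[e[cross, 1L]], of[e[cross, 2L]])
  key <- paste(a, b)
  cnt <- table(key)
  out <- numeric(nrow(edges))
  m <- match(paste(edges$i, edges$j), names(cnt))
  out[!is.na(m)] <- as.numeric(cnt[m[!is.na(m)]])
  out
}

#' @export
print.ball_network <- function(x, ...) {
  cat("ball_network:", x$q, "balls,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Voxelize a ball set into a binary pore image
#'
#' A voxel is tagged pore (0) iff its center `(i+0.5, j+0.5, k+0.5)` (0-based
#' voxel indices, voxel units) lies inside at least one ball; overlapping
#' balls union naturally.
#'
#' @param balls a [ball_set()] (centers in voxel units).
#' @param dims image dimensions `(nx, ny, nz)` (a scalar is recycled).
#' @return a [pore_image()].
#' @export
voxelize_balls <- function(balls, dims) {
  stopifnot(inherits(balls, "ball_set"))
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  dims <- as.integer(dims)
  vals <- array(1L, dims)
  for (k in seq_len(nrow(balls))) {
    cx <- balls$x[k]; cy <- balls$y[k]; cz <- balls$z[k]; r <- balls$r[k]
    rng <- function(c, nmax) {
      lo <- max(0L, as.integer(floor(c - r - 0.5)))
      hi <- min(nmax - 1L, as.integer(ceiling(c + r - 0.5)))
      if (lo > hi) integer() else lo:hi
    }
    ix <- rng(cx, dims[1L]); iy <- rng(cy, dims[2L]); iz <- rng(cz, dims[3L])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ix + 0.5 - cx)^2
    dy2 <- (iy + 0.5 - cy)^2
    dz2 <- (iz + 0.5 - cz)^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    sub <- vals[ix + 1L, iy + 1L, iz + 1L, drop = FALSE]
    sub[inside] <- 0L
    vals[ix + 1L, iy + 1L, iz + 1L] <- sub
  }
  pore_image(vals)
}

#' Assign each pore voxel to a ball
#'
#' Partitions the voxel-graph nodes among the balls: a voxel inside exactly
#' one ball goes to it; a voxel inside several goes to the ball whose center
#' is nearest (ties broken toward the lowest ball index). Every pore voxel
#' must be covered by at least one ball — true by construction for images
#' produced by [voxelize_balls()].
#'
#' @param graph the voxel graph of the ball image.
#' @param balls the [ball_set()] that generated it.
#' @return a list of class `ball_partition`: `ball_of` (node -> ball index),
#'   `sets` (list of node-id vectors per ball), `counts`, `q`, `n`.
#' @export
map_voxels_to_balls <- function(graph, balls) {
  stopifnot(inherits(graph, "voxel_graph"), inherits(balls, "ball_set"))
  n <- graph$n
  q <- nrow(balls)
  pts <- graph$coords + 0.5
  assign <- integer(n)
  best <- rep(Inf, n)
  for (k in seq_len(q)) {
    d2 <- (pts[, 1L] - balls$x[k])^2 + (pts[, 2L] - balls$y[k])^2 +
          (pts[, 3L] - balls$z[k])^2
    hit <- d2 <= balls$r[k]^2 & d2 < best   # strict <: ties keep lowest index
    assign[hit] <- k
    best[hit] <- d2[hit]
  }
  if (any(assign == 0L)) {
    bad <- which(assign == 0L)
    stop("pore voxels not covered by any ball, e.g. at (x,y,z) = (",
         paste(graph$coords[bad[1L], ], collapse = ","), ") and ",
         length(bad) - 1L, " more")
  }
  sets <- split(seq_len(n), factor(assign, levels = seq_len(q)))
  structure(list(ball_of = assign, sets = sets,
                 counts = lengths(sets), q = q, n = n),
            class = "ball_partition")
}

#' Aggregate voxel masses to ball masses, and spread them back
#'
#' `ball_masses_from_voxels()` sums the voxel masses of each ball's
#' partition cell; `uniform_voxel_masses_from_balls()` divides each ball's
#' mass equally over its voxels. The round trip aggregate(spread(B)) = B is
#' exact algebra. A ball with no voxels is an error.
#'
#' @param M per-node voxel mass vector.
#' @param partition a [map_voxels_to_balls()] result.
#' @return `ball_masses_from_voxels`: numeric vector of length `q`.
#' @export
ball_masses_from_voxels <- function(M, partition) {
  stopifnot(inherits(partition, "ball_partition"),
            length(M) == partition$n)
  if (any(partition$counts == 0L))
    stop("ball ", which(partition$counts == 0L)[1L], " covers no voxels")
  B <- numeric(partition$q)
  sums <- rowsum(as.numeric(M), partition$ball_of)
  B[as.integer(rownames(sums))] <- sums[, 1L]
  B
}

#' @rdname ball_masses_from_voxels
#' @param B per-ball mass vector of length `q`.
#' @return `uniform_voxel_masses_from_balls`: numeric vector of length `n`.
#' @export
uniform_voxel_masses_from_balls <- function(B, partition) {
  stopifnot(inherits(partition, "ball_partition"),
            length(B) == partition$q)
  if (any(partition$counts == 0L))
    stop("ball ", which(partition$counts == 0L)[1L], " covers no voxels")
  (B / partition$counts)[partition$ball_of]
}

# Dense symmetric conductance Laplacian in concentration space:
# (L_theta c)_i = sum_j theta_ij (c_i - c_j). q is small, dense is fine.
.theta_laplacian <- function(net, theta) {
  q <- net$q
  L <- matrix(0, q, q)
  e <- net$edges
  if (nrow(e) > 0L) {
    idx_ij <- cbind(e$i, e$j)
    L[idx_ij] <- L[idx_ij] - theta
    L[idx_ij[, 2:1, drop = FALSE]] <- L[cbind(e$j, e$i)] - theta
    dg <- numeric(q)
    acc <- rowsum(c(theta, theta), c(e$i, e$j))
    dg[as.integer(rownames(acc))] <- acc[, 1L]
    diag(L) <- dg
  }
  L
}

# Explicit PNGM prediction for a batch: X is l x q, returns l x q.
# Shared between the stepper and the learning losses so that data generated
# by the stepper has exactly zero residual at the generating conductances.
.pngm_predict_explicit <- function(X, theta, net, k) {
  Lth <- .theta_laplacian(net, theta)
  C <- sweep(X, 2L, net$volumes, "/")
  X - k * (C %*% Lth)   # L_theta symmetric: rows are (L_theta c_p)'
}

# Left-hand side of the implicit scheme applied to Y: Y + k * L_theta (Y/v).
.pngm_implicit_lhs <- function(Y, theta, net, k) {
  Lth <- .theta_laplacian(net, theta)
  C <- sweep(Y, 2L, net$volumes, "/")
  Y + k * (C %*% Lth)
}

#' Explicit diffusion step on a ball network
#'
#' Advances the per-ball masses by one forward-Euler step of the
#' pore-network diffusion model:
#' `m_i' = m_i - Dc*dt * sum_j theta_ij (m_i/v_i - m_j/v_j)`.
#' The pairwise fluxes are antisymmetric, so total mass is conserved. A
#' negative output signals an unstable `Dc*dt` and raises an error.
#'
#' @param B per-ball mass vector.
#' @param net a [build_ball_network()] result.
#' @param Dc diffusion coefficient, per the time unit of `dt`.
#' @param dt time step.
#' @param theta per-edge conductances (default: the network's stored ones).
#' @return the updated mass vector.
#' @export
pngm_explicit_step <- function(B, net, Dc, dt, theta = net$edges$theta) {
  stopifnot(inherits(net, "ball_network"), length(B) == net$q,
            length(theta) == nrow(net$edges))
  B2 <- as.numeric(.pngm_predict_explicit(matrix(B, 1L), theta, net, Dc * dt))
  if (any(B2 < 0))
    stop(sprintf(
      "explicit ball-network step produced a negative mass; Dc*dt = %g is too large",
      Dc * dt))
  B2
}

#' Implicit diffusion step on a ball network
#'
#' Backward-Euler counterpart of [pngm_explicit_step()]: solves
#' `m_i = m_i' + Dc*dt * sum_j theta_ij (m_i'/v_i - m_j'/v_j)` for the new
#' masses. In concentration variables the system matrix
#' `diag(v) + Dc*dt*L_theta` is symmetric positive definite (for
#' `theta >= 0`), and is solved by the Jacobi-preconditioned conjugate
#' gradient; the solver's residual mass defect is redistributed uniformly so
#' each step conserves mass to floating precision.
#'
#' @inheritParams pngm_explicit_step
#' @param tol relative PCG tolerance.
#' @return the updated mass vector.
#' @export
pngm_implicit_step <- function(B, net, Dc, dt, theta = net$edges$theta,
                               tol = 1e-10) {
  stopifnot(inherits(net, "ball_network"), length(B) == net$q,
            length(theta) == nrow(net$edges))
  k <- Dc * dt
  v <- net$volumes
  Lth <- .theta_laplacian(net, theta)
  A <- function(cvec) v * cvec + k * as.numeric(Lth %*% cvec)
  cn <- pcg_solve(A, as.numeric(B), precond_diag = 1 / (v + k * diag(Lth)),
                  tol = tol, maxiter = max(1000L, net$q))
  attributes(cn) <- NULL
  B2 <- v * cn
  B2 + (sum(B) - sum(B2)) / net$q
}
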