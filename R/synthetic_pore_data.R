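#' Generate a seeded random ball packing and its binary image
#'
#' Desk-scale stand-in for a segmented micro-CT pore space: a connected
#' cluster of overlapping random balls. The first ball is placed uniformly
#' (with a margin so it fits); each subsequent ball is attached to a
#' uniformly chosen existing ball at a center distance of 40–90% of the
#' radius sum, which guarantees a pairwise chain of overlaps, i.e. a
#' connected ball network by construction. When `connected = TRUE` the voxel
#' graph of the voxelized image is additionally required to form a single
#' component (resampled up to `max_tries` times).
#'
#' Radii are drawn uniformly from `radius_range` (minimum 2 voxels so the
#' voxelization is non-degenerate). When `porosity_target` is given, balls
#' are added until the voxelized porosity reaches the target (to within half
#' a percentage point from below, so the overshoot is at most one ball's
#' volume); otherwise exactly `n_balls` are placed.
#'
#' @param dims image dimensions (scalar recycled; default 48^3).
#' @param n_balls number of balls (default 20).
#' @param radius_range radii range in voxels (default `c(4, 8)`).
#' @param porosity_target optional pore fraction to reach instead of a ball
#'   count.
#' @param connected require a single voxel-graph component (default TRUE).
#' @param seed RNG seed.
#' @param max_tries resampling attempts before giving up.
#' @return a list with `balls` (a [ball_set()]) and `image` (a
#'   [pore_image()]).
#' @export
generate_ball_packing <- function(dims = c(48L, 48L, 48L), n_balls = 20L,
                                  radius_range = c(4, 8),
                                  porosity_target = NULL, connected = TRUE,
                                  seed = NULL, max_tries = 50L) {
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  dims <- as.integer(dims)
  stopifnot(all(radius_range >= 2), radius_range[1L] <= radius_range[2L])
  if (!is.null(seed)) set.seed(seed)

  draw_ball <- function(parent = NULL) {
    r <- runif(1L, radius_range[1L], radius_range[2L])
    for (a in 1:200) {
      if (is.null(parent)) {
        c0 <- runif(3L, r, dims - r)
      } else {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        d <- runif(1L, 0.4, 0.9) * (parent$r + r)
        c0 <- c(parent$x, parent$y, parent$z) + d * u
      }
      if (all(c0 >= r) && all(c0 <= dims - r))
        return(list(x = c0[1L], y = c0[2L], z = c0[3L], r = r))
    }
    stop("could not place a ball inside the image bounds; enlarge dims or ",
         "shrink the radii")
  }

  for (try in seq_len(max_tries)) {
    blist <- list(draw_ball())
    repeat {
      done <- if (is.null(porosity_target)) {
        length(blist) >= n_balls
      } else {
        bs <- ball_set(t(vapply(blist, function(b) c(b$x, b$y, b$z),
                                numeric(3L))),
                       vapply(blist, `[[`, numeric(1L), "r"))
        porosity(voxelize_balls(bs, dims)) >= porosity_target - 0.005
      }
      if (done) break
      parent <- blist[[sample.int(length(blist), 1L)]]
      blist[[length(blist) + 1L]] <- draw_ball(parent)
    }
    balls <- ball_set(t(vapply(blist, function(b) c(b$x, b$y, b$z),
                               numeric(3L))),
                      vapply(blist, `[[`, numeric(1L), "r"))
    image <- voxelize_balls(balls, dims)
    if (!connected) return(list(balls = balls, image = image))
    g <- build_voxel_graph(image)
    if (g$n > 0L && max(graph_components(g)) == 1L)
      return(list(balls = balls, image = image))
  }
  stop("failed to generate a connected packing in ", max_tries, " tries")
}

#' Random dissolved-organic-matter distribution over a voxel graph
#'
#' Draws a total mass uniformly from `total_mass_range` and splits it over
#' the pore voxels with random nonnegative shares (independent uniform
#' weights normalized to one), preserving the drawn total exactly.
#'
#' @param graph a nonempty [build_voxel_graph()] result.
#' @param total_mass_range range for the uniform draw of the total mass.
#' @param seed optional RNG seed.
#' @return numeric per-node mass vector.
#' @export
random_dom_distribution <- function(graph, total_mass_range = c(50, 150),
                                    seed = NULL) {
  stopifnot(inherits(graph, "voxel_graph"), graph$n > 0L)
  if (!is.null(seed)) set.seed(seed)
  total <- runif(1L, total_mass_range[1L], total_mass_range[2L])
  w <- runif(graph$n)
  total * w / sum(w)
}
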