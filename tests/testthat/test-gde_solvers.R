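two_node_L <- function() laplacian(build_voxel_graph(chain_image(2L)))

test_that("explicit step: hand example, uniform invariance, conservation", {
  L <- two_node_L()
  expect_equal(explicit_step(c(1, 0), L, D = 1, dt = 0.25), c(0.75, 0.25))

  fx <- fixture_packing16()
  u <- rep(3.7, fx$graph$n)
  expect_equal(explicit_step(u, fx$L, 1, 0.05), u)

  set.seed(1)
  M <- runif(fx$graph$n)
  dt <- 0.5 * stable_timestep(fx$graph, 1)
  M2 <- explicit_step(M, fx$L, 1, dt)
  expect_lt(abs(sum(M2) - sum(M)), 1e-10 * sum(M))
  # maximum principle at a stable step
  expect_gte(min(M2), min(M))
  expect_lte(max(M2), max(M))
})

test_that("explicit step nonnegativity holds below the stability bound and fails above it", {
  fx <- fixture_packing16()
  D <- 1
  dtmax <- stable_timestep(fx$graph, D)
  set.seed(2)
  for (rep in 1:1000) {
    M <- runif(fx$graph$n)
    expect_gte(min(explicit_step(M, fx$L, D, 0.99 * dtmax)), 0)
  }
  # indicator mass on a maximum-degree node at 3x the bound goes negative
  M <- numeric(fx$graph$n)
  M[which.max(fx$graph$degrees)] <- 1
  expect_error(explicit_step(M, fx$L, D, 3 * dtmax), "unstable")
  expect_error(explicit_step(M, fx$L, D, 3 * dtmax), "stable_timestep")
})

test_that("implicit step: hand example, uniform invariance, dense-solve oracle", {
  L <- two_node_L()
  # (I + 0.5*L) M' = (1,0)  =>  M' = (0.75, 0.25)
  expect_equal(implicit_step(c(1, 0), L, 1, 0.5), c(0.75, 0.25),
               tolerance = 1e-10)

  g <- build_voxel_graph(full_pore_image(4L))
  L4 <- laplacian(g)
  u <- rep(2.5, g$n)
  expect_equal(implicit_step(u, L4, 1, 10), u, tolerance = 1e-9)

  set.seed(3)
  M <- runif(g$n)
  x <- implicit_step(M, L4, 1, 10, tol = 1e-13)
  xd <- solve(diag(g$n) + 10 * as.matrix(L4), M)
  expect_lt(max(abs(x - xd)) / max(abs(xd)), 1e-10)
  expect_lt(abs(sum(x) - sum(M)), 1e-12 * sum(M))
  expect_gte(min(x), 0)  # B^-1 is a nonnegative operator for this M-matrix
})

test_that("PCG solves SPD systems to the requested residual", {
  # identity: one iteration
  x <- pcg_solve(function(v) v, c(3, -2, 7))
  expect_equal(as.numeric(x), c(3, -2, 7))
  expect_equal(attr(x, "iterations"), 1L)

  # 2x2 closed form
  A <- matrix(c(2, 1, 1, 2), 2L)
  x <- pcg_solve(function(v) A %*% v, c(1, 0), 1 / diag(A))
  expect_equal(as.numeric(x), c(2 / 3, -1 / 3), tolerance = 1e-10)

  # random SPD 50x50 vs dense solve
  set.seed(4)
  R <- matrix(rnorm(50 * 50), 50L)
  A <- crossprod(R) + 50 * diag(50L)
  b <- rnorm(50L)
  x <- pcg_solve(function(v) A %*% v, b, 1 / diag(A), tol = 1e-12)
  expect_lt(max(abs(as.numeric(x) - solve(A, b))), 1e-9)

  # non-convergence carries the residual history
  err <- tryCatch(
    pcg_solve(function(v) A %*% v, b, 1 / diag(A), tol = 1e-300, maxiter = 3L),
    error = identity)
  expect_s3_class(err, "poresim_pcg_error")
  expect_length(err$residuals, 3L)
})

test_that("stable_timestep returns 1/(D*deg_max)", {
  g <- build_voxel_graph(full_pore_image(3L))  # deg_max = 6
  expect_equal(stable_timestep(g, 1), 1 / 6)
  g2 <- build_voxel_graph(chain_image(2L))     # deg_max = 1
  expect_equal(stable_timestep(g2, 2), 0.5)
  g0 <- build_voxel_graph(pore_image(array(1L, c(2L, 2L, 2L))))
  expect_error(stable_timestep(g0, 1), "empty")
})

test_that("diffusion runs conserve mass, reach the uniform steady state, and match exp(-D t L)", {
  g <- build_voxel_graph(full_pore_image(3L))
  L <- laplacian(g)
  set.seed(5)
  M0 <- runif(27L)

  # zero steps return the initial state
  r0 <- simulate_diffusion(M0, L, 1, 0.01, 0L)
  expect_equal(r0$states[, 1L], M0)
  expect_equal(r0$times, 0)

  # long implicit run converges to total/27 per node
  r <- simulate_diffusion(M0, L, 1, 5, 60L)
  expect_lt(max(abs(r$states[, ncol(r$states)] - sum(M0) / 27)), 1e-8)
  expect_lt(max(abs(colSums(r$states) - sum(M0))), 1e-9 * sum(M0))

  # both schemes approximate the matrix exponential with first-order error
  gch <- build_voxel_graph(chain_image(10L))
  Lch <- laplacian(gch)
  set.seed(6)
  M0 <- runif(10L)
  t_end <- 0.5
  exact <- expm_solution(M0, Lch, 1, t_end)
  for (scheme in c("explicit", "implicit")) {
    errs <- sapply(c(16L, 32L, 64L, 128L), function(ns) {
      r <- simulate_diffusion(M0, Lch, 1, t_end / ns, ns, scheme = scheme,
                              tol = 1e-13)
      max(abs(r$states[, ncol(r$states)] - exact))
    })
    slope <- coef(lm(log(errs) ~ log(t_end / c(16, 32, 64, 128))))[[2L]]
    expect_gt(slope, 0.8)
    expect_lt(slope, 1.2)
  }
})

test_that("layer profiles aggregate mass by image layer", {
  fx <- fixture_packing16()
  g <- fx$graph
  # all mass on one node at a known z layer
  z0 <- g$coords[1L, 3L]
  node <- which(g$coords[, 3L] == z0)[1L]
  M <- numeric(g$n); M[node] <- 2.5
  prof <- layer_mass_profile(M, g, "z")
  expect_length(prof, 16L)
  expect_equal(prof[z0 + 1L], 2.5)   # 0-based layer index
  expect_equal(sum(prof != 0), 1L)

  # uniform mass in a full cube gives a constant profile
  gc <- build_voxel_graph(full_pore_image(4L))
  expect_equal(layer_mass_profile(rep(1, 64L), gc, "x"), rep(16, 4L))

  # conservation for a random state
  set.seed(8)
  M <- runif(g$n)
  expect_equal(sum(layer_mass_profile(M, g, "y")), sum(M))
})

test_that("intercorrelation is the cosine of profile curves", {
  set.seed(9)
  C <- runif(12L)
  expect_equal(intercorrelation(C, C), 1)
  expect_equal(intercorrelation(C, 3.7 * C), 1)
  expect_equal(intercorrelation(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(intercorrelation(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(intercorrelation(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(intercorrelation(c(1, 0), c(1, 1, 0)), "equal length")
})

test_that("explicit and implicit layer profiles agree after equal simulated time", {
  # the scheme-agreement property: coarse implicit stepping tracks fine
  # explicit stepping on a fixed 16^3 packing
  fx <- fixture_packing16()
  g <- fx$graph
  D <- per_second(100950)
  dtmax <- stable_timestep(g, D)
  M0 <- numeric(g$n)
  zs <- sort(unique(g$coords[, 3L]))
  sel <- g$coords[, 3L] %in% zs[1:2]   # lowest two occupied layers
  M0[sel] <- 100 / sum(sel)

  # horizon long enough for the coarse scheme to take ~30 steps, as in the
  # reference layer-profile comparisons
  n_imp <- 30L
  n_exp <- n_imp * 40L
  t_end <- n_exp * (dtmax / 2)
  r_exp <- simulate_diffusion(M0, fx$L, D, dtmax / 2, n_exp,
                              scheme = "explicit")
  r_imp <- simulate_diffusion(M0, fx$L, D, 20 * dtmax, n_imp,
                              scheme = "implicit")
  expect_equal(n_imp * 20 * dtmax, t_end)  # equal elapsed time
  p1 <- layer_mass_profile(r_exp$states[, ncol(r_exp$states)], g, "z")
  p2 <- layer_mass_profile(r_imp$states[, ncol(r_imp$states)], g, "z")
  expect_gte(intercorrelation(p1, p2), 0.999)
})

test_that("rate unit conversion is centralized and exact", {
  expect_equal(per_second(86400), 1)
  expect_equal(per_day(per_second(100950)), 100950)
})
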