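test_that("scenario initialization places DOM and bacterial spots as configured", {
  # 2x2x2 all-pore cube: the first two z layers hold all 8 voxels
  g <- build_voxel_graph(full_pore_image(2L))
  s <- initialize_scenario(g, dom_total = 8)
  expect_equal(s[, "dom"], rep(1, 8L), ignore_attr = TRUE)

  # spots from cell count x per-cell carbon: 5.2e7 * 5.41e-8 ug = 2.8132 ug
  gc <- build_voxel_graph(full_pore_image(12L))
  s <- initialize_scenario(gc, dom_total = 289.5, dom_placement = "uniform",
                           n_spots = 1000L, cells = 5.2e7,
                           mass_per_cell = 5.41e-8, seed = 77L)
  expect_equal(sum(s[, "mb"]), 2.8132, tolerance = 1e-12)
  expect_equal(sum(s[, "mb"] > 0), 1000L)  # distinct voxels
  expect_equal(max(s[, "mb"]), 2.8132 / 1000)

  # determinism: equal seeds give identical states
  s2 <- initialize_scenario(gc, dom_total = 289.5, dom_placement = "uniform",
                            n_spots = 1000L, cells = 5.2e7,
                            mass_per_cell = 5.41e-8, seed = 77L)
  expect_identical(unclass(s), unclass(s2))

  # errors: more spots than pore voxels; no pore voxels in the loaded layers
  expect_error(initialize_scenario(g, n_spots = 9L, mb_total = 1),
               "fewer pore voxels")
  img <- slab_image(c(4L, 4L, 6L), thickness = 2L)      # pore at z in {0,1}
  solid_first <- pore_image(1L - img$values)            # pore at z >= 2
  expect_error(initialize_scenario(build_voxel_graph(solid_first),
                                   dom_total = 1), "no pore voxels")
})

test_that("compound fractions reproduce the initial-state arithmetic", {
  s <- pore_state(1L, mb = 2.8132, dom = 289.5)
  fr <- 100 * compound_fractions(s)
  expect_equal(round(fr[["dom"]], 4), 99.0376)
  expect_equal(round(fr[["mb"]], 3), 0.962)
  expect_equal(sum(compound_fractions(s)), 1)

  one <- pore_state(1L, som = 5)
  expect_equal(compound_fractions(one)[["som"]], 1)
  expect_error(compound_fractions(pore_state(2L)), "zero total")
})

test_that("a zero-duration run returns only the initial record", {
  fx <- fixture_packing16()
  s0 <- initialize_scenario(fx$graph, dom_total = 10,
                            dom_placement = "uniform", n_spots = 5L,
                            mb_total = 1, seed = 1L)
  rec <- run_coupled(s0, fx$graph, bio_params(), duration = 0)
  expect_equal(nrow(rec$totals), 1L)
  expect_equal(rec$totals[1L, ], pool_totals(s0))
  expect_equal(rec$times, 0)
})

test_that("with D = 0 the coupled run reduces to pure transformation kinetics", {
  fx <- fixture_packing16()
  s0 <- initialize_scenario(fx$graph, dom_total = 0, n_spots = 3L,
                            mb_total = 1, fom_total = 50, seed = 2L)
  rec <- run_coupled(s0, fx$graph, bio_params(), D = 0,
                     dt_diffusion = 450, dt_transformation = 450,
                     duration = 2 * 86400, cadence = 86400,
                     mode = "synchronous")
  fom_exact <- closed_form_fom(50, 0.3, 2)   # rates per day, t in days
  expect_equal(rec$totals[3L, "fom"], fom_exact, tolerance = 1e-2,
               ignore_attr = TRUE)
  expect_lt(rec$drift, 1e-12)
})

test_that("with inert biology the coupled run equals the plain diffusion solver", {
  fx <- fixture_packing16()
  g <- fx$graph
  inert <- bio_params(rho = 0, mu = 0, beta = 0, v_som = 0, v_fom = 0,
                      v_dom = 0, k_dom = 1)
  s0 <- initialize_scenario(g, dom_total = 100, dom_placement = "uniform",
                            n_spots = 2L, mb_total = 1, seed = 3L)
  rec <- run_coupled(s0, g, inert, D = 100950, dt_diffusion = 30,
                     dt_transformation = 30, duration = 600, cadence = 600)
  ref <- simulate_diffusion(s0[, "dom"], fx$L, per_second(100950), 30, 20L)
  expect_equal(rec$state[, "dom"], ref$states[, ncol(ref$states)],
               tolerance = 1e-12, ignore_attr = TRUE)
  # non-diffusing pools untouched
  expect_equal(rec$totals[, "mb"], rep(1, 2L), ignore_attr = TRUE)
  expect_equal(rec$totals[, "co2"], rep(0, 2L), ignore_attr = TRUE)
})

test_that("diffusion never crosses disconnected pore components", {
  # two disjoint pore boxes; biomass in one, DOM in the other
  vals <- array(1L, c(9L, 4L, 4L))
  vals[1:3, , ] <- 0L
  vals[7:9, , ] <- 0L
  g <- build_voxel_graph(pore_image(vals))
  comp <- graph_components(g)
  expect_equal(max(comp), 2L)
  dom <- ifelse(comp == 1L, 1, 0)
  s0 <- pore_state(g$n, dom = dom,
                   mb = ifelse(comp == 2L, 0.05, 0))
  rec <- run_coupled(s0, g, bio_params(), D = 100950,
                     dt_diffusion = 60, dt_transformation = 60,
                     duration = 3600, cadence = 3600)
  carbon_by_comp <- function(state) rowsum(rowSums(state), comp)[, 1L]
  expect_equal(carbon_by_comp(rec$state), carbon_by_comp(s0),
               tolerance = 1e-9)
  # no DOM appears in component 2 beyond its own turnover; component 1 DOM
  # total is untouched (no biomass, no sources there)
  dom1 <- sum(rec$state[comp == 1L, "dom"])
  expect_equal(dom1, sum(comp == 1L) * 0 + sum(dom), tolerance = 1e-9)
})

test_that("coupled totals converge at first order when both time steps halve", {
  fx <- fixture_packing16()
  g <- fx$graph
  s0 <- initialize_scenario(g, dom_total = 50, dom_placement = "uniform",
                            n_spots = 10L, mb_total = 0.5,
                            fom_total = 10, seed = 4L)
  run_dt <- function(dt) {
    rec <- run_coupled(s0, g, bio_params(), D = 100950, dt_diffusion = dt,
                       dt_transformation = dt, duration = 7200,
                       cadence = 7200, mode = "asynchronous")
    rec$totals[2L, ]
  }
  t1 <- run_dt(1200); t2 <- run_dt(600); t3 <- run_dt(300)
  e1 <- max(abs(t1 - t2)); e2 <- max(abs(t2 - t3))
  expect_gt(log2(e1 / e2), 0.8)
})

test_that("CO2 totals never decrease over a coupled run", {
  fx <- fixture_packing16()
  s0 <- initialize_scenario(fx$graph, dom_total = 20,
                            dom_placement = "uniform", n_spots = 10L,
                            mb_total = 0.5, seed = 5L)
  rec <- run_coupled(s0, fx$graph, bio_params(), D = 100950,
                     dt_diffusion = 600, dt_transformation = 600,
                     duration = 6 * 3600, cadence = 3600)
  expect_true(all(diff(rec$totals[, "co2"]) >= 0))
  expect_lt(rec$drift, 1e-9)
})

test_that("run_scenario drives a full configuration end to end", {
  cfg <- yaml::read_yaml(system.file("extdata", "example-scenario.yaml",
                                     package = "poresim"))
  cfg$duration <- 3600
  res <- run_scenario(cfg)
  expect_s3_class(res$record, "decomposition_record")
  expect_equal(nrow(res$record$totals), 2L)
  expect_lt(res$record$drift, 1e-9)
  expect_equal(sum(res$record$totals[1L, ]), 289.5 + 2.8132,
               tolerance = 1e-6)
})
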