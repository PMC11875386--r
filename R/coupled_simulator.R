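#' Build the initial pore state of a decomposition scenario
#'
#' Distributes the initial compounds over the pore voxels following the
#' usual experimental designs:
#' * DOM — either spread uniformly over the pore voxels of the first
#'   `n_layers` layers along `axis` (layer indices `0..n_layers-1`), or
#'   uniformly over all pore voxels, or given explicitly per voxel;
#' * MB — `n_spots` point spots of equal mass placed at distinct pore
#'   voxels sampled uniformly without replacement (seeded). The total spot
#'   mass can be given directly (`mb_total`) or as a cell count times a
#'   per-cell carbon mass (`cells * mass_per_cell`), e.g. the classic
#'   `5.2e7 * 5.41e-8 = 2.8132` ug C for 1000 spots;
#' * SOM / FOM — optional uniform totals; CO2 starts at zero.
#'
#' @param graph a [build_voxel_graph()] result.
#' @param dom_total total DOM mass to place (ignored when `dom_values` is
#'   given).
#' @param dom_placement `"first_layers"` or `"uniform"`.
#' @param axis axis of the loaded layers (default `"z"`).
#' @param n_layers number of loaded layers (default 2).
#' @param dom_values optional explicit per-node DOM vector.
#' @param n_spots number of bacterial spots (0 for none).
#' @param mb_total total MB mass over all spots.
#' @param cells,mass_per_cell alternative way to give `mb_total`.
#' @param som_total,fom_total optional uniform totals.
#' @param seed RNG seed for spot placement (set for reproducibility).
#' @return a [pore_state()] with one row per graph node.
#' @export
initialize_scenario <- function(graph, dom_total = 0,
                                dom_placement = c("first_layers", "uniform"),
                                axis = "z", n_layers = 2L, dom_values = NULL,
                                n_spots = 0L, mb_total = NULL, cells = NULL,
                                mass_per_cell = NULL, som_total = 0,
                                fom_total = 0, seed = NULL) {
  stopifnot(inherits(graph, "voxel_graph"))
  n <- graph$n
  if (n == 0L) stop("cannot initialize a scenario on an empty graph")
  dom <- numeric(n)
  if (!is.null(dom_values)) {
    stopifnot(length(dom_values) == n, all(dom_values >= 0))
    dom <- as.numeric(dom_values)
  } else if (dom_total > 0) {
    dom_placement <- match.arg(dom_placement)
    if (dom_placement == "first_layers") {
      ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
      sel <- graph$coords[, ax] < n_layers
      if (!any(sel))
        stop("no pore voxels in the first ", n_layers, " ", axis, " layers")
      dom[sel] <- dom_total / sum(sel)
    } else {
      dom[] <- dom_total / n
    }
  }
  mb <- numeric(n)
  if (n_spots > 0L) {
    if (is.null(mb_total)) {
      if (is.null(cells) || is.null(mass_per_cell))
        stop("give either mb_total or both cells and mass_per_cell")
      mb_total <- cells * mass_per_cell
    }
    if (n_spots > n)
      stop("fewer pore voxels (", n, ") than bacterial spots (", n_spots, ")")
    if (!is.null(seed)) set.seed(seed)
    spots <- sample.int(n, n_spots)
    mb[spots] <- mb_total / n_spots
  }
  pore_state(n, mb = mb, dom = dom, som = som_total / n, fom = fom_total / n)
}

#' Shares of total carbon per compound
#'
#' @param state a [pore_state()] with positive total carbon.
#' @return named fractions (`mb`, `dom`, `som`, `fom`, `co2`) summing to 1.
#' @examples
#' s <- pore_state(1, mb = 2.8132, dom = 289.5)
#' round(100 * compound_fractions(s), 4)
#' @export
compound_fractions <- function(state) {
  tot <- pool_totals(state)
  s <- sum(tot)
  if (s <= 0) stop("compound fractions are undefined for zero total carbon")
  tot / s
}

.near_multiple <- function(a, b) {
  r <- a / b
  abs(r - round(r)) < 1e-9 && round(r) >= 1
}

#' Coupled transformation–diffusion simulation on a voxel graph
#'
#' Operator-split integration of the full decomposition model: inside each
#' macro time step the transformation kinetics ([transform_step()]) and the
#' DOM diffusion ([explicit_step()] / [implicit_step()]) are advanced
#' alternately, the process with the smaller time step being sub-stepped so
#' that both cover the same elapsed time. DOM is the only diffusing
#' compound. The pore space is a closed system, so total carbon is conserved
#' over the whole run (checked; the relative drift is reported).
#'
#' Time bookkeeping: `dt_diffusion`, `dt_transformation`, `cadence` and
#' `duration` are all in seconds; each `dt` must divide the macro step
#' `max(dt_diffusion, dt_transformation)`, which in turn must divide the
#' output `cadence`. Rates in `bio` are per day and `D` is in
#' voxel^2 day^-1; both are converted internally.
#'
#' @param state0 initial [pore_state()].
#' @param graph a [build_voxel_graph()] result.
#' @param bio a [bio_params()].
#' @param D DOM diffusion coefficient, voxel^2 day^-1 (default 100950, the
#'   aqueous diffusion of a small organic molecule at a 24 um voxel edge).
#' @param dt_diffusion,dt_transformation sub-step lengths in seconds.
#' @param duration simulated time in seconds (a multiple of `cadence`).
#' @param cadence recording interval in seconds (default 3600).
#' @param scheme diffusion scheme, `"implicit"` (default) or `"explicit"`.
#' @param mode transformation mode, `"asynchronous"` (default) or
#'   `"synchronous"`.
#' @param order `"transform_first"` (default) or `"diffuse_first"` within a
#'   macro step.
#' @param record_layers optional axis name; when given, the DOM layer
#'   profile is recorded at every output time.
#' @param tol PCG tolerance of the implicit solver.
#' @return a list of class `decomposition_record`: `times` (seconds),
#'   `totals` (one row per output time, columns `mb,dom,som,fom,co2`),
#'   `profiles` (matrix or `NULL`), `state` (final [pore_state()]), and
#'   `drift` (relative carbon conservation error over the run).
#' @export
run_coupled <- function(state0, graph, bio, D = 100950,
                        dt_diffusion = 30, dt_transformation = 30,
                        duration, cadence = 3600,
                        scheme = c("implicit", "explicit"),
                        mode = c("asynchronous", "synchronous"),
                        order = c("transform_first", "diffuse_first"),
                        record_layers = NULL, tol = 1e-10) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  order <- match.arg(order)
  stopifnot(inherits(graph, "voxel_graph"), nrow(state0) == graph$n,
            dt_diffusion > 0, dt_transformation > 0, duration >= 0,
            cadence > 0, D >= 0)

  macro <- max(dt_diffusion, dt_transformation)
  if (!.near_multiple(macro, dt_diffusion) ||
      !.near_multiple(macro, dt_transformation))
    stop("the smaller time step must divide the larger one")
  if (duration > 0 && !.near_multiple(cadence, macro))
    stop("the macro step (", macro, " s) must divide the cadence (",
         cadence, " s)")
  if (duration > 0 && !.near_multiple(duration, cadence))
    stop("duration must be a multiple of the cadence")

  L <- laplacian(graph)
  D_s <- per_second(D)
  n_diff <- round(macro / dt_diffusion)
  n_trans <- round(macro / dt_transformation)
  dt_trans_days <- dt_transformation / 86400

  n_out <- if (duration > 0) round(duration / cadence) else 0L
  n_macro <- if (duration > 0) round(cadence / macro) else 0L
  times <- seq(0, by = cadence, length.out = n_out + 1L)
  totals <- matrix(NA_real_, n_out + 1L, 5L,
                   dimnames = list(NULL, POOLS))
  profiles <- NULL
  if (!is.null(record_layers)) {
    ax <- match.arg(record_layers, c("x", "y", "z"))
    nlay <- graph$dims[match(ax, c("x", "y", "z"))]
    profiles <- matrix(NA_real_, n_out + 1L, nlay)
  }

  state <- state0
  totals[1L, ] <- pool_totals(state)
  if (!is.null(profiles))
    profiles[1L, ] <- layer_mass_profile(state[, "dom"], graph, ax)
  c0 <- sum(totals[1L, ])

  do_transform <- function(state) {
    for (s in seq_len(n_trans))
      state <- transform_step(state, bio, dt_trans_days, mode = mode)
    state
  }
  do_diffuse <- function(state) {
    if (D == 0) return(state)   # transformation-only run
    dom <- state[, "dom"]
    for (s in seq_len(n_diff))
      dom <- if (scheme == "explicit")
        explicit_step(dom, L, D_s, dt_diffusion)
      else implicit_step(dom, L, D_s, dt_diffusion, tol = tol)
    state[, "dom"] <- dom
    state
  }

  if (n_out > 0L) {
    for (o in seq_len(n_out)) {
      for (m in seq_len(n_macro)) {
        if (order == "transform_first") {
          state <- do_transform(state)
          state <- do_diffuse(state)
        } else {
          state <- do_diffuse(state)
          state <- do_transform(state)
        }
      }
      totals[o + 1L, ] <- pool_totals(state)
      if (!is.null(profiles))
        profiles[o + 1L, ] <- layer_mass_profile(state[, "dom"], graph, ax)
    }
  }

  drift <- if (c0 > 0) max(abs(rowSums(totals) - c0)) / c0 else 0
  structure(list(times = times, totals = totals, profiles = profiles,
                 state = state, drift = drift, scheme = scheme, mode = mode,
                 D = D, dt_diffusion = dt_diffusion,
                 dt_transformation = dt_transformation),
            class = "decomposition_record")
}

#' @export
print.decomposition_record <- function(x, ...) {
  cat("decomposition_record: ", length(x$times), " output times over ",
      x$times[length(x$times)], " s (", x$scheme, " diffusion, ", x$mode,
      " transformation)\n", sep = "")
  cat("final totals:", paste(sprintf("%s %.6g", POOLS,
                                     x$totals[nrow(x$totals), ]),
                             collapse = ", "), "\n")
  cat("carbon conservation drift:", format(x$drift), "\n")
  invisible(x)
}
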