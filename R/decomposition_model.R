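POOLS <- c("mb", "dom", "som", "fom", "co2")

#' Biological rate parameters of the five-pool decomposition model
#'
#' Rates of the transformation model: microbial respiration and mortality,
#' the fraction of dead biomass recycled to dissolved organic matter, Monod
#' growth on DOM, and first-order hydrolysis of soil and fresh organic
#' matter. All rates are in day^-1; `beta` is dimensionless; `k_dom` is in
#' the same carbon-mass unit as the pool states.
#'
#' The defaults are the *Arthrobacter* sp. 9R set calibrated on experimental
#' growth/respiration curves: `rho = 0.2`, `mu = 0.5`, `beta = 0.55`,
#' `v_som = 0.01`, `v_fom = 0.3`, `v_dom = 9.6`, `k_dom = 0.001`. The same
#' set ships as a YAML file, see [read_bio_params()].
#'
#' @param rho respiration rate (day^-1): MB -> CO2.
#' @param mu mortality rate (day^-1): MB -> DOM/SOM.
#' @param beta fraction of dead biomass going to DOM (rest to SOM), in
#'   `[0, 1]`.
#' @param v_som,v_fom hydrolysis rates of SOM and FOM (day^-1): -> DOM.
#' @param v_dom maximum Monod growth rate of MB on DOM (day^-1).
#' @param k_dom DOM half-saturation constant (carbon-mass units).
#' @return an object of class `bio_params`.
#' @export
bio_params <- function(rho = 0.2, mu = 0.5, beta = 0.55, v_som = 0.01,
                       v_fom = 0.3, v_dom = 9.6, k_dom = 0.001) {
  p <- list(rho = rho, mu = mu, beta = beta, v_som = v_som, v_fom = v_fom,
            v_dom = v_dom, k_dom = k_dom)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                   !is.finite(v) || v < 0, logical(1L))))
    stop("all biological parameters must be single finite nonnegative numbers")
  if (beta > 1) stop("beta must lie in [0, 1]")
  structure(p, class = "bio_params")
}

#' @export
print.bio_params <- function(x, ...) {
  cat("bio_params (day^-1): rho =", x$rho, " mu =", x$mu, " beta =", x$beta,
      "\n  v_som =", x$v_som, " v_fom =", x$v_fom, " v_dom =", x$v_dom,
      " k_dom =", x$k_dom, "\n")
  invisible(x)
}

#' Read biological parameters from a YAML file
#'
#' The package bundles the default set at
#' `system.file("extdata", "arthrobacter.yaml", package = "poresim")`.
#'
#' @param path YAML file with keys `rho, mu, beta, v_som, v_fom, v_dom,
#'   k_dom`.
#' @return a [bio_params()] object.
#' @export
read_bio_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(bio_params)))
  do.call(bio_params, cfg[keep])
}

#' Per-node carbon pool state
#'
#' An `n x 5` matrix of carbon masses with columns `mb` (microbial biomass),
#' `dom` (dissolved organic matter), `som` (soil organic matter), `fom`
#' (fresh organic matter) and `co2` (respired carbon), one row per graph
#' node, all in one common carbon-mass unit (conventionally ug C).
#'
#' @param n number of nodes; or omit and give equal-length vectors.
#' @param mb,dom,som,fom,co2 per-node masses (recycled to length `n`).
#' @return a numeric matrix of class `pore_state`.
#' @export
pore_state <- function(n = NULL, mb = 0, dom = 0, som = 0, fom = 0, co2 = 0) {
  if (is.null(n))
    n <- max(length(mb), length(dom), length(som), length(fom), length(co2))
  s <- cbind(mb = rep_len(as.numeric(mb), n),
             dom = rep_len(as.numeric(dom), n),
             som = rep_len(as.numeric(som), n),
             fom = rep_len(as.numeric(fom), n),
             co2 = rep_len(as.numeric(co2), n))
  if (any(!is.finite(s)) || any(s < 0))
    stop("pool masses must be finite and nonnegative")
  class(s) <- c("pore_state", class(s))
  s
}

#' Total carbon of a state
#'
#' @param state a [pore_state()].
#' @return the sum of all five pools over all nodes.
#' @export
total_carbon <- function(state) sum(state)

#' Per-pool total masses
#'
#' @param state a [pore_state()].
#' @return named numeric vector of length 5.
#' @export
pool_totals <- function(state) colSums(state[, POOLS, drop = FALSE])

#' Monod uptake of DOM by microbial biomass
#'
#' Mass transferred DOM -> MB over a step `dt`:
#' `v_dom * dom / (k_dom + dom) * mb * dt`, capped at the DOM present so a
#' finite step can never extract more than a voxel holds.
#'
#' @param mb,dom nonnegative masses (vectors allowed).
#' @param p a [bio_params()]; rates per the time unit of `dt`.
#' @param dt time step (same unit as the rates in `p`).
#' @return transferred mass, same length as the inputs.
#' @export
monod_uptake <- function(mb, dom, p, dt) {
  pmin(p$v_dom * dom / (p$k_dom + dom) * mb * dt, dom)
}

#' One transformation step of the five-pool model
#'
#' Advances every node by `dt` under the decomposition kinetics: Monod
#' growth of MB on DOM, first-order mortality (a fraction `beta` of the dead
#' biomass returns to DOM, the rest to SOM), respiration MB -> CO2, and
#' first-order hydrolysis SOM -> DOM and FOM -> DOM. Each transfer moves
#' carbon between pools of the same node, so total carbon per node is
#' conserved exactly in the rate algebra.
#'
#' Two update modes are offered:
#' * `"synchronous"` — all five pools are updated from the time-`t` values
#'   only (one explicit Euler step of the kinetic ODE system);
#' * `"asynchronous"` — the processes are applied in the fixed order
#'   growth, mortality, respiration, hydrolysis, each process reading the
#'   state left by the previous one (a process-sweep across all nodes).
#'
#' The two modes differ by O(dt^2). A step large enough to drive a pool
#' negative is an error (naming the node and pool), not a clip.
#'
#' @param state a [pore_state()].
#' @param p a [bio_params()]; rates per the time unit of `dt`.
#' @param dt time step (days when the rates are per day).
#' @param mode `"synchronous"` or `"asynchronous"`.
#' @return the updated [pore_state()].
#' @export
transform_step <- function(state, p, dt,
                           mode = c("synchronous", "asynchronous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "bio_params"), dt > 0)
  mb <- state[, "mb"]; dom <- state[, "dom"]; som <- state[, "som"]
  fom <- state[, "fom"]; co2 <- state[, "co2"]

  if (mode == "synchronous") {
    u    <- monod_uptake(mb, dom, p, dt)
    dead <- p$mu * mb * dt
    resp <- p$rho * mb * dt
    hs   <- p$v_som * som * dt
    hf   <- p$v_fom * fom * dt
    mb2  <- mb + u - dead - resp
    dom2 <- dom - u + p$beta * dead + hs + hf
    som2 <- som + (1 - p$beta) * dead - hs
    fom2 <- fom - hf
    co22 <- co2 + resp
  } else {
    # growth
    u <- monod_uptake(mb, dom, p, dt)
    mb1 <- mb + u
    dom1 <- dom - u
    # mortality
    dead <- p$mu * mb1 * dt
    mb2 <- mb1 - dead
    dom2 <- dom1 + p$beta * dead
    som1 <- som + (1 - p$beta) * dead
    # respiration
    resp <- p$rho * mb2 * dt
    mb2 <- mb2 - resp
    co22 <- co2 + resp
    # hydrolysis
    hs <- p$v_som * som1 * dt
    hf <- p$v_fom * fom * dt
    som2 <- som1 - hs
    fom2 <- fom - hf
    dom2 <- dom2 + hs + hf
  }

  out <- cbind(mb = mb2, dom = dom2, som = som2, fom = fom2, co2 = co22)
  neg <- which(out < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf(
      "transformation step drove pool '%s' negative at node %d; dt = %g is too large",
      POOLS[neg[1L, 2L]], neg[1L, 1L], dt))
  class(out) <- c("pore_state", class(out))
  out
}

#' Closed-form fresh-organic-matter decay
#'
#' Exact solution `f0 * exp(-v_fom * t)` of the FOM equation
#' `df/dt = -v_fom * f`, used as an analytic oracle for the discretized
#' kinetics.
#'
#' @param f0 initial FOM mass.
#' @param v_fom hydrolysis rate (per time unit of `t`).
#' @param t elapsed time (>= 0).
#' @return FOM mass at time `t`.
#' @export
closed_form_fom <- function(f0, v_fom, t) {
  stopifnot(all(t >= 0))
  f0 * exp(-v_fom * t)
}
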