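#' One explicit (forward Euler) step of the graph diffusion equation
#'
#' Advances `M' = M - D*dt * L %*% M`. Total mass is conserved exactly up to
#' floating error because the Laplacian rows sum to zero. Under the stability
#' bound `D*dt*deg_max <= 1` the update is a convex combination of
#' neighbouring values, so the output stays within `[min(M), max(M)]`
#' componentwise (maximum principle) and never goes negative for nonnegative
#' input. A negative output therefore signals an unstable time step and
#' raises an error rather than being clipped (clipping would destroy
#' conservation).
#'
#' @param M numeric vector of per-node masses (nonnegative).
#' @param L graph Laplacian from [laplacian()].
#' @param D diffusion coefficient, in voxel^2 per the time unit of `dt`.
#' @param dt time step.
#' @return the updated mass vector.
#' @seealso [stable_timestep()] for the sufficient bound on `dt`.
#' @export
explicit_step <- function(M, L, D, dt) {
  stopifnot(length(M) == nrow(L), D > 0, dt > 0)
  M2 <- as.numeric(M - (D * dt) * (L %*% M))
  if (any(M2 < 0)) {
    degmax <- max(Matrix::diag(L))
    stop(sprintf(paste0(
      "explicit diffusion step produced a negative mass: dt = %g is ",
      "unstable; stable_timestep() bound is %g"), dt, 1 / (D * degmax)))
  }
  M2
}

#' One implicit (backward Euler) step of the graph diffusion equation
#'
#' Solves `(I + D*dt*L) %*% M' = M` with a Jacobi-preconditioned conjugate
#' gradient ([pcg_solve()]). The system matrix is symmetric positive
#' definite for any `dt`, so the scheme is unconditionally stable. Because
#' the Laplacian rows sum to zero the exact solution conserves total mass;
#' the tiny defect left by the iterative solve (at most of the order of
#' `tol`) is redistributed uniformly so that conservation holds to floating
#' precision per step.
#'
#' @inheritParams explicit_step
#' @param tol relative-residual tolerance of the inner PCG solve.
#' @param maxiter iteration cap; default `max(1000, n)`.
#' @return the updated mass vector.
#' @export
implicit_step <- function(M, L, D, dt, tol = 1e-10, maxiter = NULL) {
  n <- length(M)
  stopifnot(n == nrow(L), D > 0, dt > 0)
  k <- D * dt
  dg <- 1 + k * Matrix::diag(L)
  apply_B <- function(v) as.numeric(v + k * (L %*% v))
  x <- pcg_solve(apply_B, as.numeric(M), precond_diag = 1 / dg,
                 tol = tol, maxiter = if (is.null(maxiter)) max(1000L, n) else maxiter)
  attributes(x) <- NULL
  x + (sum(M) - sum(x)) / n
}

#' Preconditioned conjugate gradient for SPD systems
#'
#' Solves `A x = b` for symmetric positive definite `A` supplied as a
#' matrix-free operator, using the Jacobi (diagonal) preconditioner
#' `t_ii = 1/a_ii`. Iterates until the relative residual
#' `||A x - b|| / ||b||` drops below `tol`.
#'
#' @param apply_A function of one vector returning `A %*% v`.
#' @param b right-hand side.
#' @param precond_diag diagonal of the preconditioner, i.e. `1/diag(A)`
#'   (default: identity preconditioner).
#' @param tol relative-residual tolerance.
#' @param maxiter iteration cap; exceeding it raises an error of class
#'   `poresim_pcg_error` carrying the residual history.
#' @return the solution vector, with attributes `iterations` and `residual`.
#' @examples
#' A <- matrix(c(2, 1, 1, 2), 2)
#' pcg_solve(function(v) A %*% v, c(1, 0), 1 / diag(A))
#' @export
pcg_solve <- function(apply_A, b, precond_diag = NULL, tol = 1e-10,
                      maxiter = max(1000L, length(b))) {
  n <- length(b)
  if (is.null(precond_diag)) precond_diag <- rep(1, n)
  stopifnot(length(precond_diag) == n, all(is.finite(precond_diag)))
  bnorm <- sqrt(sum(b * b))
  x <- numeric(n)
  if (bnorm == 0) {
    attr(x, "iterations") <- 0L
    attr(x, "residual") <- 0
    return(x)
  }
  r <- b
  z <- precond_diag * r
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(maxiter)) {
    Ap <- as.numeric(apply_A(p))
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r * r)) / bnorm
    hist <- c(hist, res)
    if (res <= tol) {
      attr(x, "iterations") <- it
      attr(x, "residual") <- res
      return(x)
    }
    z <- precond_diag * r
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  stop(errorCondition(
    sprintf("PCG did not converge in %d iterations (final relative residual %g)",
            maxiter, hist[length(hist)]),
    residuals = hist, class = c("poresim_pcg_error", "error", "condition")))
}

#' Largest stable explicit time step
#'
#' Sufficient bound `dt_max = 1 / (D * deg_max)` for componentwise
#' nonnegativity (and the maximum principle) of the explicit scheme: at this
#' step each node retains a nonnegative fraction of its own mass. The bound
#' is expressed in the time unit of `D`. A graph with no edges imposes no
#' restriction (`Inf`).
#'
#' @param graph a [build_voxel_graph()] result.
#' @param D diffusion coefficient (voxel^2 per time unit).
#' @return the bound `dt_max`.
#' @export
stable_timestep <- function(graph, D) {
  stopifnot(inherits(graph, "voxel_graph"), D > 0)
  if (graph$n == 0L) stop("stable_timestep is undefined on an empty graph")
  degmax <- max(graph$degrees)
  if (degmax == 0L) return(Inf)
  1 / (D * degmax)
}

#' Run the graph diffusion equation for many steps
#'
#' Applies [explicit_step()] or [implicit_step()] `n_steps` times, recording
#' the state every `record_every` steps (always including the initial and
#' final states).
#'
#' @inheritParams explicit_step
#' @param M0 initial mass vector.
#' @param n_steps number of steps (>= 0).
#' @param scheme `"implicit"` (default) or `"explicit"`.
#' @param record_every recording cadence in steps (default: only first/last).
#' @param tol,maxiter passed to [implicit_step()].
#' @return a list of class `diffusion_record` with `times` (in the unit of
#'   `dt`) and `states` (an `n x n_records` matrix).
#' @export
simulate_diffusion <- function(M0, L, D, dt, n_steps,
                               scheme = c("implicit", "explicit"),
                               record_every = NULL, tol = 1e-10,
                               maxiter = NULL) {
  scheme <- match.arg(scheme)
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 0L)
  if (is.null(record_every)) record_every <- max(n_steps, 1L)
  record_every <- as.integer(record_every)
  stopifnot(record_every >= 1L)
  rec_steps <- sort(unique(c(
    0L,
    if (record_every <= n_steps)
      seq.int(record_every, n_steps, by = record_every),
    n_steps)))
  states <- matrix(NA_real_, length(M0), length(rec_steps))
  states[, 1L] <- M0
  M <- as.numeric(M0)
  ri <- 1L
  if (n_steps > 0L) {
    for (s in seq_len(n_steps)) {
      M <- if (scheme == "explicit") explicit_step(M, L, D, dt)
           else implicit_step(M, L, D, dt, tol = tol, maxiter = maxiter)
      if (s == rec_steps[ri + 1L]) {
        ri <- ri + 1L
        states[, ri] <- M
      }
    }
  }
  structure(list(times = rec_steps * dt, states = states, scheme = scheme,
                 D = D, dt = dt),
            class = "diffusion_record")
}

#' Per-layer mass profile along an image axis
#'
#' Sums node masses over each constant-coordinate layer of the image, the
#' curve used to compare simulation methods. The profile has one entry per
#' layer (including empty ones) and sums to the total mass.
#'
#' @param M numeric per-node mass vector.
#' @param graph a [build_voxel_graph()] result.
#' @param axis `"z"` (default), `"x"` or `"y"`.
#' @return numeric vector of length `dims[axis]`; entry `k` holds the mass in
#'   layer `k - 1` (0-based layer index).
#' @export
layer_mass_profile <- function(M, graph, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(graph, "voxel_graph"), length(M) == graph$n)
  ax <- match(axis, c("x", "y", "z"))
  prof <- numeric(graph$dims[ax])
  if (graph$n > 0L) {
    sums <- rowsum(as.numeric(M), graph$coords[, ax])
    prof[as.integer(rownames(sums)) + 1L] <- sums[, 1L]
  }
  prof
}

#' Intercorrelation (cosine similarity) of two profile curves
#'
#' `sum(c1*c2) / (||c1|| * ||c2||)`, the standard metric for comparing
#' per-layer mass profiles of two simulations. Equals 1 for proportional
#' curves and 0 for orthogonal ones.
#'
#' @param c1,c2 numeric vectors of equal length, each with nonzero norm.
#' @return scalar in `[-1, 1]`.
#' @export
intercorrelation <- function(c1, c2) {
  if (length(c1) != length(c2))
    stop("profiles must have equal length")
  n1 <- sqrt(sum(c1^2))
  n2 <- sqrt(sum(c2^2))
  if (n1 == 0 || n2 == 0)
    stop("intercorrelation is undefined for a zero-norm curve")
  sum(c1 * c2) / (n1 * n2)
}
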