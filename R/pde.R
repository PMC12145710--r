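#' Uniform Cartesian grid for the reaction-diffusion model
#'
#' Node-centred grid including the boundary faces: along axis i the nodes
#' sit at `0, h, ..., extents[i]` with spacing `h = extents[i] / (n[i] - 1)`.
#'
#' @param extents Box side lengths \[m\], length 3 (recycled from length 1).
#' @param n Node counts per axis, each >= 3 (recycled from length 1).
#' @param boundary `"no-flux"` (sealed gel; mirror-ghost reflection) or
#'   `"fixed-concentration"` (boundary nodes pinned to `bc_value`).
#' @param bc_value Boundary concentration \[mg/mL\] for the fixed case.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(extents, n, boundary = c("no-flux", "fixed-concentration"),
                      bc_value = 0) {
  boundary <- match.arg(boundary)
  extents <- rep_len(as.numeric(extents), 3L)
  n <- rep_len(as.integer(n), 3L)
  if (any(!is.finite(extents)) || any(extents <= 0))
    stop("grid_spec: extents must be > 0", call. = FALSE)
  if (any(n < 3L))
    stop("grid_spec: need at least 3 nodes per axis", call. = FALSE)
  if (boundary == "fixed-concentration" && (!is.finite(bc_value) || bc_value < 0))
    stop("grid_spec: bc_value must be >= 0", call. = FALSE)
  structure(list(extents = extents, n = n, boundary = boundary,
                 bc_value = bc_value, h = extents / (n - 1)),
            class = "grid_spec")
}

#' Concentration field on a grid
#'
#' @param c Non-negative concentration values \[mg/mL\]: a 3-d array matching
#'   `grid$n`, or a vector of length `prod(grid$n)`.
#' @param grid A [grid_spec()].
#' @param t Time stamp \[s\].
#' @return An object of class `concentration_field` (a 3-d array with
#'   attributes `grid` and `t`).
#' @export
concentration_field <- function(c, grid, t = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(dim(c))) {
    if (length(c) == 1L) c <- rep(c, prod(grid$n))
    if (length(c) != prod(grid$n))
      stop("concentration_field: length does not match grid", call. = FALSE)
    c <- array(c, dim = grid$n)
  } else if (!identical(dim(c), as.integer(grid$n))) {
    stop("concentration_field: array shape does not match grid", call. = FALSE)
  }
  if (any(c < 0))
    stop("concentration_field: concentrations must be >= 0", call. = FALSE)
  structure(c, grid = grid, t = t, class = c("concentration_field", "array"))
}

# 7-point second-order Laplacian with mirror-ghost no-flux reflection.
# For the fixed-concentration case the boundary nodes are pinned by the RHS
# (their time derivative is zeroed), so the same stencil applies.
laplacian3 <- function(a, h) {
  n <- dim(a)
  ixp <- c(2:n[1], n[1] - 1L); ixm <- c(2L, 1:(n[1] - 1L))
  iyp <- c(2:n[2], n[2] - 1L); iym <- c(2L, 1:(n[2] - 1L))
  izp <- c(2:n[3], n[3] - 1L); izm <- c(2L, 1:(n[3] - 1L))
  (a[ixp, , ] - 2 * a + a[ixm, , ]) / h[1]^2 +
    (a[, iyp, ] - 2 * a + a[, iym, ]) / h[2]^2 +
    (a[, , izp] - 2 * a + a[, , izm]) / h[3]^2
}

# trapezoidal quadrature weights (1 inside, 1/2 on faces, products on
# edges/corners); exactly the quadrature conserved by the mirror-ghost
# no-flux Laplacian, so mass conservation is limited only by time stepping
trapezoid_weights <- function(n) {
  w1 <- function(m) { w <- rep(1, m); w[c(1, m)] <- 0.5; w }
  outer(outer(w1(n[1]), w1(n[2])), w1(n[3]))
}

#' Total solute mass of a field \[mg\]
#'
#' Trapezoidal integral of the concentration over the box; concentrations in
#' mg/mL are converted with 1 mg/mL = 1e6 mg/m^3.
#'
#' @param field A [concentration_field()] or plain array.
#' @param grid A [grid_spec()]; defaults to the field's own grid.
#' @return Mass \[mg\].
#' @export
total_mass <- function(field, grid = attr(field, "grid")) {
  stopifnot(inherits(grid, "grid_spec"))
  sum(trapezoid_weights(grid$n) * field) * prod(grid$h) * 1e6
}

# Dormand-Prince 5(4) adaptive step integrator (method of lines time
# stepper). f(t, y) returns dy/dt; integrates to each time in t_out exactly.
# Explicit on purpose: the diffusion CFL limit sets the step, and adaptive
# error control finds it automatically.
rk45 <- function(f, y0, t_out, rtol = 1e-6, atol = 1e-9, max_steps = 2e6,
                 h_init = NULL) {
  A <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  )
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  cc <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)

  t <- t_out[1]
  y <- y0
  out <- vector("list", length(t_out))
  out[[1]] <- y0
  k1 <- f(t, y)
  h <- if (is.null(h_init)) {
    # crude initial step from the RHS scale
    sc <- atol + rtol * abs(y)
    d0 <- sqrt(mean((y / sc)^2)); d1 <- sqrt(mean((k1 / sc)^2))
    if (d1 < 1e-10) 1e-6 else 0.01 * d0 / d1
  } else h_init
  steps <- 0L
  for (j in seq_along(t_out)[-1]) {
    t_target <- t_out[j]
    while (t < t_target) {
      if (steps >= max_steps)
        stop(sprintf("rk45: step budget exhausted at t = %g (h = %g); the problem may be too stiff for an explicit integrator",
                     t, h), call. = FALSE)
      h <- min(h, t_target - t)
      k <- vector("list", 7L)
      k[[1]] <- k1
      for (s in 1:6) {
        ys <- y
        for (m in seq_len(s)) ys <- ys + h * A[[s]][m] * k[[m]]
        k[[s + 1]] <- f(t + cc[s + 1] * h, ys)
      }
      y5 <- y
      for (m in 1:7) if (b5[m] != 0) y5 <- y5 + h * b5[m] * k[[m]]
      y4 <- y
      for (m in 1:7) if (b4[m] != 0) y4 <- y4 + h * b4[m] * k[[m]]
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      steps <- steps + 1L
      if (err <= 1 || h <= 1e-14 * max(abs(t_target), 1)) {
        t <- t + h
        y <- y5
        k1 <- k[[7]]       # FSAL
      } else {
        k1 <- k[[1]]
      }
      fac <- if (err == 0) 5 else 0.9 * err^(-0.2)
      h <- h * min(5, max(0.2, fac))
    }
    out[[j]] <- y
  }
  list(t = t_out, y = out, n_steps = steps)
}

#' Solve the dextran reaction-diffusion model by the method of lines
#'
#' Integrates \deqn{\partial c/\partial t = D_{app}(t)\,\nabla^2 c - k_r c_0}
#' on a uniform Cartesian grid (second-order central 7-point Laplacian,
#' mirror-ghost no-flux or pinned fixed-concentration boundaries) with an
#' adaptive explicit Dormand-Prince integrator. The zero-order sink is
#' switched off wherever `c = 0` and concentrations are clamped at 0, so the
#' solution stays non-negative.
#'
#' @param grid A [grid_spec()].
#' @param params A [transport_params()] (uses `k_r`, `c0`).
#' @param D_schedule Apparent diffusion coefficient: a single number or a
#'   function of time returning \[m^2/s\].
#' @param t_span Output times \[s\], increasing, first element is the initial
#'   time.
#' @param initial Initial [concentration_field()] (or array/scalar coerced
#'   through it).
#' @param rtol,atol Integrator tolerances.
#' @param max_steps Step budget before the solver aborts with diagnostics.
#' @return An object of class `simulation_result`: `times`, `fields` (list of
#'   [concentration_field()]), `D_app_trace`, `xi_trace` (NA unless produced
#'   by [coupled_virtual_test()]), `total_mass` \[mg\], `n_steps`.
#' @export
solve_reaction_diffusion <- function(grid, params, D_schedule, t_span,
                                     initial, rtol = 1e-6, atol = 1e-9,
                                     max_steps = 2e6) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "transport_params"))
  if (!inherits(initial, "concentration_field"))
    initial <- concentration_field(initial, grid, t = t_span[1])
  if (length(t_span) < 2L || any(diff(t_span) <= 0))
    stop("solve_reaction_diffusion: t_span must be increasing with >= 2 times",
         call. = FALSE)
  Dfun <- if (is.function(D_schedule)) D_schedule else function(t) D_schedule
  D0 <- stokes_einstein(params)
  Dvals <- vapply(t_span, Dfun, numeric(1))
  if (any(!is.finite(Dvals)) || any(Dvals <= 0))
    stop("solve_reaction_diffusion: D_schedule must be finite and > 0",
         call. = FALSE)
  if (any(Dvals > D0 * (1 + 1e-9)))
    stop("solve_reaction_diffusion: D_app exceeds the Stokes-Einstein free diffusivity",
         call. = FALSE)
  n <- grid$n
  h <- grid$h
  sink_rate <- params$k_r * params$c0
  fixed <- grid$boundary == "fixed-concentration"
  boundary_mask <- if (fixed) {
    m <- array(FALSE, dim = n)
    m[c(1, n[1]), , ] <- TRUE; m[, c(1, n[2]), ] <- TRUE; m[, , c(1, n[3])] <- TRUE
    m
  } else NULL

  y0 <- array(as.numeric(initial), dim = n)
  if (fixed) y0[boundary_mask] <- grid$bc_value

  rhs <- function(t, y) {
    a <- array(y, dim = n)
    d <- Dfun(t) * laplacian3(a, h)
    if (sink_rate > 0) d <- d - sink_rate * (a > 0)
    if (fixed) d[boundary_mask] <- 0
    as.numeric(d)
  }

  sol <- rk45(rhs, as.numeric(y0), t_span, rtol = rtol, atol = atol,
              max_steps = max_steps)
  fields <- vector("list", length(t_span))
  mass <- numeric(length(t_span))
  for (j in seq_along(t_span)) {
    a <- array(pmax(sol$y[[j]], 0), dim = n)   # clamp round-off negatives
    fields[[j]] <- concentration_field(a, grid, t = t_span[j])
    mass[j] <- total_mass(a, grid)
  }
  structure(list(times = t_span, fields = fields, D_app_trace = Dvals,
                 xi_trace = rep(NA_real_, length(t_span)), total_mass = mass,
                 n_steps = sol$n_steps),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Reaction-diffusion simulation: %d output times over [%g, %g] s\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  total mass: %.6g -> %.6g mg (%d integrator steps)\n",
              x$total_mass[1], x$total_mass[length(x$total_mass)], x$n_steps))
  invisible(x)
}

#' One-way coupled virtual epsilon-dot test
#'
#' Runs the full in-silico pipeline for one formulation: the aSLS modulus
#' `E(t)` under the constant-strain-rate protocol sets the mesh size
#' `xi_avg(E(t))`, which sets the apparent diffusion coefficient, which
#' parameterises the reaction-diffusion model piecewise-constantly over each
#' output interval (value taken at the interval's left endpoint; at `t = 0`
#' the modulus is the instantaneous `E0 + E1`). Mechanics is not fed back
#' from transport. With `strain_rate = 0` the gel is unloaded and the model
#' reduces to [solve_reaction_diffusion()] at constant `D_app`
#' evaluated at the instantaneous modulus.
#'
#' @param protocol A [loading_protocol()] (`strain_rate >= 0`).
#' @param asls An [asls_params()] object.
#' @param transport A [transport_params()] object.
#' @param grid A [grid_spec()].
#' @param initial Initial concentration; defaults to uniform `transport$c0`.
#' @param rtol,atol Integrator tolerances.
#' @return A list with `curve` (the [mechanical_curve()], `NULL` when
#'   `strain_rate = 0`) and `transport` (the [solve_reaction_diffusion()]
#'   result with `xi_trace` filled in).
#' @export
coupled_virtual_test <- function(protocol, asls, transport, grid,
                                 initial = NULL, rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(protocol, "loading_protocol"),
            inherits(asls, "asls_params"),
            inherits(transport, "transport_params"),
            inherits(grid, "grid_spec"))
  tt <- seq(0, protocol$t_end, length.out = protocol$n_samples)
  E_trace <- asls_modulus(tt, asls)
  if (protocol$strain_rate == 0)       # unloaded: modulus stays instantaneous
    E_trace <- rep(asls_modulus(0, asls), length(tt))
  xi_trace <- mesh_size(E_trace, transport)
  D_trace <- apparent_diffusion(xi_trace, transport)

  if (is.null(initial)) initial <- concentration_field(transport$c0, grid)
  if (!inherits(initial, "concentration_field"))
    initial <- concentration_field(initial, grid)

  # piecewise-constant D over each interval, value at the left endpoint
  field <- initial
  fields <- vector("list", length(tt))
  mass <- numeric(length(tt))
  fields[[1]] <- field
  mass[1] <- total_mass(field, grid)
  n_steps <- 0L
  for (j in seq_along(tt)[-1]) {
    seg <- solve_reaction_diffusion(grid, transport, D_trace[j - 1],
                                    c(tt[j - 1], tt[j]), field,
                                    rtol = rtol, atol = atol)
    field <- seg$fields[[2]]
    fields[[j]] <- field
    mass[j] <- seg$total_mass[2]
    n_steps <- n_steps + seg$n_steps
  }
  res <- structure(list(times = tt, fields = fields, D_app_trace = D_trace,
                        xi_trace = xi_trace, total_mass = mass,
                        n_steps = n_steps),
                   class = "simulation_result")
  curve <- if (protocol$strain_rate > 0) stress_response(protocol, asls) else NULL
  list(curve = curve, transport = res)
}
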