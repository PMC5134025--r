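#' Initialize a field state on a grid
#'
#' Allocates all flow and species fields at time zero: zero velocity and
#' pressure, unit porosity, platelets at their inlet values (resting
#' platelets at the physiological inlet concentration, activated platelets
#' at the 5% background activation level), and zero residence time,
#' coagulant and bound platelets.
#'
#' @param grid a `case_grid`
#' @param props a [fluid_props()] object
#' @param params a [thrombosis_params()] object
#' @return an object of class `field_state` with staggered velocities `u`
#'   (`(nx+1) x ny`), `v` (`nx x (ny+1)`), and cell fields `p`, `mu`,
#'   `gamma`, `eps`, `RT`, `RP_rel`, `AP_rel`, `C`, `BP`
#' @export
field_state <- function(grid, props = fluid_props(),
                        params = thrombosis_params()) {
  nx <- grid$nx; ny <- grid$ny
  cellm <- function(val) matrix(val, nx, ny)
  fl <- grid$mask == 1L
  st <- structure(list(
    u = matrix(0, nx + 1, ny),
    v = matrix(0, nx, ny + 1),
    p = cellm(0),
    mu = cellm(0), gamma = cellm(0), eps = cellm(1),
    RT = cellm(0),
    RP_rel = cellm(0), AP_rel = cellm(0),
    C = cellm(0), BP = cellm(0),
    gamma_avg = cellm(0),
    dep_kind = matrix(0L, nx, ny),
    dep_tawss = cellm(NA_real_), dep_gavg = cellm(NA_real_),
    t = 0, div_max = 0,
    clips = c(RT = 0L, RP_rel = 0L, AP_rel = 0L, C = 0L)
  ), class = "field_state")
  st$RP_rel[fl] <- 1
  st$AP_rel[fl] <- params$ap_inlet
  st$mu[fl] <- quemada_viscosity(0, props)
  st
}

# Inlet velocity vector (one value per row j of the left boundary).
# Plug profile from the waveform unless `inlet_fn(y, t)` is supplied.
inlet_velocity <- function(grid, bc, t, inlet_fn = NULL) {
  uin <- numeric(grid$ny)
  if (length(grid$inlet_j) == 0) return(uin)
  yj <- grid$y[grid$inlet_j]
  if (is.null(inlet_fn)) {
    h_in <- length(grid$inlet_j) * grid$dy
    uin[grid$inlet_j] <- inflow_rate(t, bc) / h_in
  } else {
    uin[grid$inlet_j] <- inlet_fn(yj, t)
  }
  uin
}

#' Advance the flow field one time step
#'
#' Fractional-step (projection) update of the incompressible momentum
#' equations on the staggered grid, with the porosity-scaled storage term,
#' explicit upwind-biased convection, explicit variable-viscosity
#' diffusion, a pointwise-implicit Brinkman sink `-k_M * phi_BP * u`, and
#' a pressure projection solved by IC(0)-preconditioned conjugate
#' gradients to a relative residual of `tol`.  Boundary conditions: plug
#' (or caller-supplied) inlet velocity, zero relative pressure at the
#' outlet, no-slip rigid walls.
#'
#' @param state a `field_state` (its `eps` and `mu` fields are used as-is;
#'   the growth coupler refreshes them from BP and the shear rate)
#' @param grid a `case_grid`
#' @param dt time step (s); must respect [cfl_dt()]
#' @param bc a [waveform_params()] object
#' @param props a [fluid_props()] object
#' @param params a [thrombosis_params()] object
#' @param inlet_fn optional function `(y, t) -> u` overriding the plug
#'   inlet profile (used by the analytic verification cases)
#' @param tol relative pressure-solve tolerance
#' @return the updated `field_state`; `$div_max` holds the post-projection
#'   maximum cell divergence
#' @export
step_flow <- function(state, grid, dt, bc, props = fluid_props(),
                      params = thrombosis_params(), inlet_fn = NULL,
                      tol = 1e-10) {
  uin <- inlet_velocity(grid, bc, state$t + dt, inlet_fn)
  sinkc <- params$k_M * switch_up(state$BP, params$BP_t, params$n_sw)
  res <- .step_flow_cpp(state$u, state$v, state$p, grid$mask,
                        state$mu, state$eps, sinkc,
                        grid$dx, grid$dy, dt, props$rho,
                        grid$inlet_j, grid$outlet_j, uin, tol, 20000L,
                        grid$cache)
  if (!all(is.finite(res$u)) || !all(is.finite(res$v))) {
    stop("step_flow: non-finite velocity detected at t = ", state$t + dt)
  }
  state$u <- res$u; state$v <- res$v; state$p <- res$p
  state$t <- state$t + dt
  state$div_max <- res$div_max
  state
}

#' Shear-rate and wall-shear-stress fields
#'
#' Computes the shear-rate magnitude `sqrt(2 D:D)` of the symmetric
#' velocity-gradient tensor at cell centers, and the instantaneous wall
#' shear stress magnitude `mu * |du_t/dn|` at each wall face by a
#' one-sided difference.
#'
#' @param state a `field_state`
#' @param grid a `case_grid`
#' @return list with `gamma` (`nx x ny` matrix, 1/s) and `wss` (vector
#'   over `grid$wall_faces`, Pa)
#' @export
shear_fields <- function(state, grid) {
  wf <- grid$wall_faces
  .shear_fields_cpp(state$u, state$v, grid$mask, state$mu,
                    grid$dx, grid$dy, grid$inlet_j, grid$outlet_j,
                    wf$i, wf$j, wf$side)
}

#' Stable time step
#'
#' `dt = safety * min(convective, viscous, scalar-diffusive[, sink])`
#' stability limits.  The sink limit `rho * eps / (k_M * phi_BP)` applies
#' to an explicit treatment of the Brinkman term; [run_case()] integrates
#' the sink implicitly and therefore excludes it (`include_sink = FALSE`).
#'
#' @param state a `field_state`
#' @param grid a `case_grid`
#' @param props a [fluid_props()] object
#' @param params a [thrombosis_params()] object
#' @param safety safety factor in (0, 1]
#' @param include_sink include the explicit-sink stability limit
#' @return time step (s)
#' @export
cfl_dt <- function(state, grid, props = fluid_props(),
                   params = thrombosis_params(), safety = 0.4,
                   include_sink = TRUE) {
  stopifnot(safety > 0, safety <= 1)
  umax <- max(abs(state$u)); vmax <- max(abs(state$v))
  conv <- min(ifelse(umax > 0, grid$dx / umax, Inf),
              ifelse(vmax > 0, grid$dy / vmax, Inf))
  fl <- grid$mask == 1L
  nu_max <- max(state$mu[fl] * state$eps[fl]) / props$rho
  Dmax <- max(params$D_c_eff, params$D_p, params$D_RT)
  kdiff <- max(nu_max, Dmax)
  visc <- if (kdiff > 0) {
    0.5 / (kdiff * (1 / grid$dx^2 + 1 / grid$dy^2))
  } else Inf
  lim <- min(conv, visc)
  if (include_sink) {
    phi <- switch_up(state$BP[fl], params$BP_t, params$n_sw)
    act <- phi > 0
    if (any(act)) {
      lim <- min(lim, min(props$rho * state$eps[fl][act] /
                            (params$k_M * phi[act])))
    }
  }
  safety * lim
}

#' Per-face wall shear state
#'
#' Holds the running cycle integral of the instantaneous wall shear stress
#' and the previous-cycle time-averaged wall shear stress (TAWSS) used by
#' the coagulant flux law.
#'
#' @param grid a `case_grid`
#' @param init_tawss initial TAWSS value used before the first full cycle
#'   completes (set by the spin-up protocol)
#' @return an object of class `wall_state`
#' @export
wall_state <- function(grid, init_tawss = 0) {
  n <- nrow(grid$wall_faces)
  structure(list(integral = numeric(n),
                 tawss = rep(init_tawss, n)),
            class = "wall_state")
}

#' Accumulate wall shear and refresh TAWSS at cycle boundaries
#'
#' Adds `wss_now * dt` to the running cycle integral; when
#' `at_cycle_end = TRUE`, sets `tawss = integral / T` and resets the
#' integral.  The TAWSS consumed by the flux law is therefore always the
#' previous cycle's average.
#'
#' @param wall a [wall_state()] object
#' @param wss_now instantaneous WSS magnitudes (vector over wall faces, Pa)
#' @param dt time step (s)
#' @param at_cycle_end logical flag
#' @param T cycle period (s)
#' @return the updated `wall_state`
#' @export
update_tawss <- function(wall, wss_now, dt, at_cycle_end, T) {
  stopifnot(dt > 0)
  wall$integral <- wall$integral + wss_now * dt
  if (at_cycle_end) {
    wall$tawss <- wall$integral / T
    wall$integral <- wall$integral * 0
  }
  wall
}
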