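# Analytic benchmarks and canned case configurations.  Everything is
# generated in code; no external data.

#' Plane Poiseuille verification case
#'
#' Channel flow with the Newtonian viscosity override and the analytic
#' parabolic profile `u(y) = 6 U y (h - y) / h^2` imposed at the inlet.
#' The returned `analytic` closure evaluates the exact profile.
#'
#' @param ny cells across the channel
#' @param U mean velocity (m/s)
#' @param h channel height (m)
#' @param mu constant viscosity (Pa s)
#' @return list with `config` and `analytic(y)`
#' @export
poiseuille_case <- function(ny = 64, U = 0.05, h = 0.01, mu = 3.5e-3) {
  L <- 3 * h
  config <- list(
    fluid = list(newtonian = TRUE, mu_newtonian = mu),
    geometry = list(kind = "channel", length = L, height = h,
                    nx = max(8L, as.integer(ny * 0.75)), ny = as.integer(ny)),
    waveform = list(T = 1, Q_mean = U * h, peak_mult = 1, retro_frac = 0),
    run = list(inlet_fn = function(y, t) 6 * U * y * (h - y) / h^2,
               n_cycles = 0, spinup_cycles = 2)
  )
  list(config = config, analytic = function(y) 6 * U * y * (h - y) / h^2,
       U = U, h = h)
}

#' Analytic oscillatory (Womersley) channel profile
#'
#' Exact velocity of laminar flow between parallel plates driven by the
#' oscillatory pressure gradient `-G cos(omega t)`:
#' `u(y,t) = Re[ (i G / (rho omega)) (1 - cosh(k (y - h/2)) / cosh(k h/2))
#' e^{i omega t} ]` with `k = sqrt(i omega / nu)`.
#'
#' @param y wall-normal positions (m), vectorized
#' @param t time (s), scalar
#' @param h channel height (m)
#' @param G pressure-gradient amplitude (Pa/m)
#' @param rho density (kg/m^3)
#' @param nu kinematic viscosity (m^2/s)
#' @param omega angular frequency (rad/s)
#' @return velocity (m/s)
#' @export
womersley_profile <- function(y, t, h, G, rho, nu, omega) {
  ch <- function(z) (exp(z) + exp(-z)) / 2
  k <- sqrt(1i * omega / nu)
  amp <- (1i * G / (rho * omega)) *
    (1 - ch(k * (y - h / 2)) / ch(k * h / 2))
  Re(amp * exp(1i * omega * t))
}

#' Womersley verification case
#'
#' Pulsatile channel flow at Womersley number `alpha`, with the analytic
#' profile imposed at the inlet and used as the initial condition; the
#' interior solution must then reproduce the analytic series.
#'
#' @param alpha Womersley number (<= 10)
#' @param ny cells across the channel
#' @return list with `config`, `analytic(y, t)`, `h`, `T`
#' @export
womersley_case <- function(alpha = 5, ny = 64) {
  stopifnot(alpha <= 10)
  h <- 0.01
  rho <- 1060; mu <- 3.5e-3
  nu <- mu / rho
  omega <- (2 * alpha / h)^2 * nu
  T <- 2 * pi / omega
  U0 <- 0.05
  G <- rho * omega * U0
  ana <- function(y, t) womersley_profile(y, t, h, G, rho, nu, omega)
  config <- list(
    fluid = list(rho = rho, newtonian = TRUE, mu_newtonian = mu),
    geometry = list(kind = "channel", length = 2 * h, height = h,
                    nx = 16L, ny = as.integer(ny)),
    waveform = list(T = T, Q_mean = U0 * h, peak_mult = 1, retro_frac = 0),
    run = list(inlet_fn = ana, n_cycles = 0, spinup_cycles = 2)
  )
  list(config = config, analytic = ana, h = h, T = T, nu = nu,
       omega = omega)
}

#' Backward-facing-step thrombosis calibration case
#'
#' Steady inflow over a backward-facing step with the accelerated
#' coagulant kinetics (augmentation factor 150), run for 40 s of
#' simulated time.  The geometry and Reynolds number are package
#' assumptions (documented in the methods vignette): a 2.5 mm step with
#' expansion ratio 2 at a hydraulic-diameter Reynolds number of about
#' 265, chosen so that the laminar reattachment point lies 4-8 step
#' heights downstream and the wall shear stress drops below the 0.2 Pa
#' growth threshold only inside the recirculation bubble (upstream and
#' redeveloped downstream walls stay above it).
#'
#' @param sim_time simulated time after spin-up (s)
#' @param resolution cell size (m)
#' @param U inlet mean velocity (m/s)
#' @return a configuration list for [run_case()]
#' @export
bfs_thrombosis_case <- function(sim_time = 40, resolution = 5e-4,
                                U = 0.2) {
  h_in <- 0.0025; h_s <- 0.0025
  T <- 1
  list(
    fluid = list(newtonian = FALSE),
    thrombosis = list(f_aug = 150),
    geometry = list(kind = "backward_facing_step", inlet_height = h_in,
                    step_height = h_s, upstream_len = 0.01,
                    downstream_len = 0.03, resolution = resolution),
    waveform = list(T = T, Q_mean = U * h_in, peak_mult = 1,
                    retro_frac = 0),
    run = list(n_cycles = as.integer(round(sim_time / T)),
               spinup_cycles = 2, snapshots_per_cycle = 1)
  )
}

#' Single-tear (early-stage) idealized dissection case
#'
#' One proximal tear connecting the true lumen to an otherwise closed
#' false lumen; 20-cycle protocol with 2 spin-up cycles at the
#' physiological period of 1.054 s.
#'
#' @param n_cycles cardiac cycles with the full thrombosis model
#' @param resolution cell size (m)
#' @return a configuration list for [run_case()]
#' @export
dissection_s1_case <- function(n_cycles = 20, resolution = 5e-4) {
  list(
    geometry = list(kind = "idealized_dissection",
                    lumen_height = 0.010, fl_height = 0.004,
                    flap_thickness = 0.002,
                    tear_positions = 0.012, tear_widths = 0.006,
                    length = 0.08, resolution = resolution),
    waveform = list(T = 1.054, Q_mean = 1.5e-3, peak_mult = 3,
                    retro_frac = 0.2),
    run = list(n_cycles = as.integer(n_cycles), spinup_cycles = 2,
               snapshots_per_cycle = 8)
  )
}

#' Two-tear (later-stage) idealized dissection case
#'
#' Adds a middle tear, a pre-thrombosed proximal false-lumen cap, and the
#' restart protocol: an initial wall coagulant concentration equal to 1%
#' of the maximum wall coagulant recorded in a single-tear run, with two
#' coagulant-only cycles before bound-platelet growth is enabled.
#'
#' @param s1_max_wall_C maximum wall coagulant concentration from a
#'   single-tear run (nmol/l); the seeded value is 1% of this
#' @param n_cycles cardiac cycles with the full thrombosis model
#' @param resolution cell size (m)
#' @return a configuration list for [run_case()]
#' @export
dissection_s4_case <- function(s1_max_wall_C, n_cycles = 20,
                               resolution = 5e-4) {
  tear1 <- 0.012
  cfg <- dissection_s1_case(n_cycles, resolution)
  cfg$geometry$tear_positions <- c(tear1, 0.036)
  cfg$geometry$tear_widths <- c(0.006, 0.006)
  cfg$run$coagulant_precycles <- 2
  cfg$run$init_wall_C <- 0.01 * s1_max_wall_C
  cfg$run$pre_thrombosed <- function(grid) {
    grid$regions$false_lumen &
      matrix(grid$x < tear1 - 0.003, grid$nx, grid$ny)
  }
  cfg
}

# steady reattachment length (in step heights) from a flow state on a
# backward-facing-step grid: first sign change of near-wall streamwise
# velocity downstream of the step
bfs_reattachment <- function(state, grid) {
  meta <- grid$meta
  stopifnot(meta$kind == "backward_facing_step")
  jwall <- 1L
  ucell <- 0.5 * (state$u[-1, ] + state$u[-(grid$nx + 1), ])
  ds <- which(grid$x > meta$upstream_len + grid$dx)
  uw <- ucell[ds, jwall]
  neg <- which(uw < 0)
  if (length(neg) == 0) return(0)
  k <- max(neg)
  if (k >= length(uw)) return(Inf)
  x0 <- grid$x[ds[k]]; x1 <- grid$x[ds[k + 1]]
  u0 <- uw[k]; u1 <- uw[k + 1]
  xr <- x0 + (0 - u0) / (u1 - u0) * (x1 - x0)
  (xr - meta$upstream_len) / meta$step_height
}

#' Run the analytic benchmark suite
#'
#' Exercises the solver and transport kernels against closed-form
#' solutions: plane Poiseuille flow, oscillatory Womersley flow, pure
#' residence-time accumulation in a stagnant box, the PAS constant-stress
#' closed form, and the unit properties of the constitutive laws.
#'
#' @param fast if `TRUE`, run the flow benchmarks at reduced resolution
#'   (`ny = 32`) with correspondingly looser thresholds
#' @return data frame with columns `check`, `value`, `threshold`, `pass`
#' @export
validate_solver <- function(fast = FALSE) {
  ny <- if (fast) 32L else 64L
  res <- list()
  add <- function(check, value, threshold) {
    res[[length(res) + 1]] <<- data.frame(check = check, value = value,
                                          threshold = threshold,
                                          pass = value < threshold)
  }

  pc <- poiseuille_err(ny)
  add("poiseuille_centerline_rel_err", pc$center,
      if (fast) 0.02 else 0.005)
  add("poiseuille_wss_rel_err", pc$wss, if (fast) 0.05 else 0.01)
  add("womersley_l2_rel_err", womersley_err(alpha = 5, ny = ny),
      if (fast) 0.05 else 0.02)
  add("stagnant_rt_rel_err", stagnant_rt_err(), 0.001)
  pasv <- pas_index(c(1, 1), c(0, 1))
  add("pas_constant_unit_rel_err", abs(pasv - 1e-5) / 1e-5, 1e-3)
  add("porosity_endpoint_err",
      max(abs(clot_porosity(0) - 1), abs(clot_porosity(20) - 0.75),
          abs(clot_porosity(200) - 0.75)), 1e-12)
  add("wall_flux_err",
      max(abs(coagulant_wall_flux(0.05, 0) - 20),
          abs(coagulant_wall_flux(0.5, 0)),
          abs(coagulant_wall_flux(0.05, 250))), 1e-12)
  add("switch_partition_err",
      max(abs(switch_up(c(0, 3, 50), 10) + switch_down(c(0, 3, 50), 10) - 1)),
      1e-12)
  do.call(rbind, res)
}

# relative errors of the steady Poiseuille solution
poiseuille_err <- function(ny = 64) {
  pz <- poiseuille_case(ny)
  cfg <- normalize_config(pz$config)
  props <- do.call(fluid_props, cfg$fluid)
  params <- do.call(thrombosis_params, cfg$thrombosis)
  bc <- do.call(waveform_params, cfg$waveform)
  grid <- build_case_grid(cfg$geometry)
  st <- field_state(grid, props, params)
  t_end <- 2.5 * grid$Lx / pz$U
  while (st$t < t_end) {
    dt <- min(cfl_dt(st, grid, props, params, 0.4, include_sink = FALSE),
              t_end - st$t)
    st <- step_flow(st, grid, dt, bc, props, params,
                    inlet_fn = cfg$run$inlet_fn)
  }
  icol <- round(grid$nx * 0.75)
  uprof <- st$u[icol, ]
  uexact <- pz$analytic(grid$y)
  center <- abs(max(uprof) - 1.5 * pz$U) / (1.5 * pz$U)
  sh <- shear_fields(st, grid)
  wf <- grid$wall_faces
  sel <- wf$side >= 3 & abs(wf$x - grid$x[icol]) < grid$dx
  wss_num <- mean(sh$wss[sel])
  wss_exact <- 6 * props$mu_newtonian * pz$U / pz$h
  flux_in <- sum(st$u[1, grid$inlet_j]) * grid$dy
  flux_out <- sum(st$u[grid$nx + 1, grid$outlet_j]) * grid$dy
  list(center = center, wss = abs(wss_num - wss_exact) / wss_exact,
       profile = sqrt(mean((uprof - uexact)^2)) / sqrt(mean(uexact^2)),
       flux_in = flux_in, flux_out = flux_out)
}

# time-and-space L2 relative error of the oscillatory channel solution
womersley_err <- function(alpha = 5, ny = 64) {
  wz <- womersley_case(alpha, ny)
  cfg <- normalize_config(wz$config)
  props <- do.call(fluid_props, cfg$fluid)
  params <- do.call(thrombosis_params, cfg$thrombosis)
  bc <- do.call(waveform_params, cfg$waveform)
  grid <- build_case_grid(cfg$geometry)
  st <- field_state(grid, props, params)
  # start from the analytic solution so only scheme error remains
  for (i in seq_len(grid$nx + 1)) st$u[i, ] <- wz$analytic(grid$y, 0)
  st$p[] <- 0
  icol <- round(grid$nx / 2)
  t_end <- 2 * wz$T
  err2 <- 0; ref2 <- 0
  n_sample <- 0
  sample_every <- wz$T / 32
  t_next <- wz$T + sample_every
  while (st$t < t_end - 1e-12) {
    dt <- min(cfl_dt(st, grid, props, params, 0.4, include_sink = FALSE),
              t_next - st$t, t_end - st$t)
    st <- step_flow(st, grid, dt, bc, props, params,
                    inlet_fn = cfg$run$inlet_fn)
    if (st$t >= t_next - 1e-12) {
      ue <- wz$analytic(grid$y, st$t)
      un <- st$u[icol, ]
      err2 <- err2 + sum((un - ue)^2)
      ref2 <- ref2 + sum(ue^2)
      n_sample <- n_sample + 1
      t_next <- t_next + sample_every
    }
  }
  sqrt(err2 / ref2)
}

# residence time in a stagnant closed box must equal elapsed time
stagnant_rt_err <- function() {
  grid <- build_channel(0.01, 0.01, 8, 8, closed = TRUE)
  props <- fluid_props(); params <- thrombosis_params()
  st <- field_state(grid, props, params)
  T <- 1; t_end <- 5 * T; dt <- 0.01
  nstep <- round(t_end / dt)
  for (k in seq_len(nstep)) {
    st <- update_residence_time(st, grid, dt, params)
    st$t <- st$t + dt
  }
  max(abs(st$RT[grid$mask == 1L] / T - 5)) / 5
}
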