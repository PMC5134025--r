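# Growth coupler: orchestrates the per-step flow + transport updates and
# the per-cycle refresh of time-averaged quantities (TAWSS, cycle-averaged
# shear rate) that gate thrombus growth.

# gross and net volumetric flux (m^2/s) across the top faces of a region
# (used to monitor flow through a tear into the false lumen)
region_top_flux <- function(state, grid, region) {
  cols <- which(apply(region, 1, any))
  if (length(cols) == 0) return(c(gross = 0, net = 0))
  gross <- 0; net <- 0
  for (i in cols) {
    jtop <- max(which(region[i, ]))
    vf <- state$v[i, jtop + 1]
    gross <- gross + abs(vf) * grid$dx
    net <- net + vf * grid$dx
  }
  c(gross = gross, net = net)
}

# one inner step of the coupled model; returns updated state
coupled_step <- function(state, grid, wall, dt, bc, props, params,
                         thrombosis_on, bp_growth_on, gate, inlet_fn,
                         tol) {
  state <- step_flow(state, grid, dt, bc, props, params, inlet_fn, tol)
  sh <- shear_fields(state, grid)
  state$gamma <- sh$gamma
  fl <- grid$mask == 1L
  state$mu[fl] <- quemada_viscosity(sh$gamma[fl], props)
  state <- update_residence_time(state, grid, dt, params)
  state <- update_platelets(state, grid, dt, params, dBP = state$last_dBP)
  if (thrombosis_on) {
    state <- update_coagulant(state, grid, wall, dt, params)
    if (bp_growth_on) {
      state <- update_bound_platelets(state, grid, wall, dt, params, gate)
    } else {
      state$last_dBP <- NULL
    }
    state$eps <- clot_porosity(state$BP, params)
    state$eps[!fl] <- 1
  }
  attr(state, "wss") <- sh$wss
  state
}

#' Run a coupled thrombus-growth case
#'
#' Executes the full feedback loop: a spin-up period with the thrombosis
#' model off (to obtain a periodic flow solution and initialize the
#' time-averaged wall shear stress and shear rate), optionally a number of
#' coagulant-only pre-cycles (the two-tear restart protocol), then
#' `n_cycles` cardiac cycles of the complete model.  Within each step the
#' update order is flow, shear fields, residence time, platelets,
#' coagulant, bound platelets, porosity/sink refresh; TAWSS and the
#' cycle-averaged shear rate are refreshed only at cycle boundaries and
#' always lag one full cycle.
#'
#' @param config a configuration list as returned by [load_config()] or
#'   one of the case fixtures ([dissection_s1_case()] etc.)
#' @param checkpoint optional path to a checkpoint written by a previous
#'   run to resume from
#' @return an object of class `run_result`: final `state`, `grid`, `wall`,
#'   per-cycle summary data frame `cycles`, stored velocity `snapshots`,
#'   and the expanded configuration
#' @export
run_case <- function(config, checkpoint = NULL) {
  config <- normalize_config(config)
  props <- do.call(fluid_props, config$fluid)
  params <- do.call(thrombosis_params, config$thrombosis)
  bc <- do.call(waveform_params, config$waveform)
  grid <- build_case_grid(config$geometry)
  run <- config$run

  if (!is.null(checkpoint)) {
    ck <- readRDS(checkpoint)
    state <- ck$state; wall <- ck$wall
    cycles <- ck$cycles; snapshots <- ck$snapshots
    cyc0 <- ck$cycle_next
  } else {
    state <- field_state(grid, props, params)
    wall <- wall_state(grid)
    cycles <- NULL; snapshots <- list()
    cyc0 <- 1L
  }

  n_spin <- run$spinup_cycles
  n_pre <- run$coagulant_precycles
  n_total <- n_spin + n_pre + run$n_cycles
  T <- bc$T
  snap_frac <- seq(0, 1, length.out = run$snapshots_per_cycle + 1)[-1]
  gate <- NULL

  for (cyc in seq(cyc0, length.out = max(0, n_total - cyc0 + 1))) {
    spin <- cyc <= n_spin
    pre <- !spin && cyc <= n_spin + n_pre
    # two-tear restart protocol: seed wall coagulant when the
    # coagulant-only phase begins
    if (!spin && cyc == n_spin + 1 && !is.null(run$init_wall_C)) {
      state <- seed_wall_coagulant(state, grid, run$init_wall_C)
    }
    if (!spin && cyc == n_spin + 1 && !is.null(run$pre_thrombosed)) {
      ptm <- run$pre_thrombosed(grid)
      state$BP[ptm] <- 1.05 * params$BP_complete
      state$eps <- clot_porosity(state$BP, params)
      state$eps[grid$mask != 1L] <- 1
    }
    if (!spin && is.null(gate)) {
      gate <- growth_gate(state, grid, wall, params)
    }
    t_end <- cyc * T
    gam_acc <- matrix(0, grid$nx, grid$ny)
    wss_prev <- NULL
    snap_next <- 1L
    while (state$t < t_end - 1e-12) {
      dt <- min(cfl_dt(state, grid, props, params, run$safety,
                       include_sink = FALSE),
                run$max_dt, t_end - state$t)
      state <- coupled_step(state, grid, wall, dt, bc, props, params,
                            thrombosis_on = !spin,
                            bp_growth_on = !spin && !pre,
                            gate = gate, inlet_fn = run$inlet_fn,
                            tol = run$tol)
      wss_now <- attr(state, "wss")
      at_end <- state$t >= t_end - 1e-12
      wall <- update_tawss(wall, wss_now, dt, at_end, T)
      gam_acc <- gam_acc + state$gamma * dt
      if (snap_next <= length(snap_frac) &&
          state$t >= t_end - T + snap_frac[snap_next] * T - 1e-12) {
        snapshots[[length(snapshots) + 1]] <-
          list(t = state$t, u = state$u, v = state$v,
               mu = state$mu, gamma = state$gamma)
        snap_next <- snap_next + 1L
      }
      wss_prev <- wss_now
    }
    state$gamma_avg <- gam_acc / T
    gate <- if (spin) NULL else growth_gate(state, grid, wall, params)
    cycles <- rbind(cycles, cycle_summary(state, grid, wall, params, cyc,
                                          phase = if (spin) "spinup"
                                                  else if (pre) "coagulant"
                                                  else "full"))
    if (!is.null(run$outdir)) {
      write_cycle_outputs(state, grid, wall, cycles, run$outdir, cyc)
    }
    if (!is.null(run$checkpoint_path)) {
      saveRDS(list(state = state, wall = wall, cycles = cycles,
                   snapshots = snapshots, cycle_next = cyc + 1L),
              run$checkpoint_path)
    }
  }
  structure(list(state = state, grid = grid, wall = wall,
                 cycles = as.data.frame(cycles), snapshots = snapshots,
                 config = config, props = props, params = params, bc = bc),
            class = "run_result")
}

# initial wall coagulant for the two-tear restart protocol: value per
# wall-adjacent cell (scalar, nmol/l)
seed_wall_coagulant <- function(state, grid, value) {
  wf <- grid$wall_faces
  state$C[cbind(wf$i, wf$j)] <- value
  state
}

cycle_summary <- function(state, grid, wall, params, cyc, phase) {
  fl_mask <- grid$regions$false_lumen
  if (is.null(fl_mask)) fl_mask <- grid$regions$step_recirculation
  fluid <- grid$mask == 1L
  thromb <- state$BP > params$BP_t
  T <- if (state$t > 0) state$t / cyc else 1
  row <- data.frame(
    cycle = cyc, phase = phase, t = state$t,
    max_BP = max(state$BP),
    thrombosed_frac = if (!is.null(fl_mask) && any(fl_mask)) {
      sum(thromb & fl_mask) / sum(fl_mask)
    } else sum(thromb) / sum(fluid),
    max_RT_cycles = if (!is.null(fl_mask) && any(fl_mask)) {
      max(state$RT[fl_mask]) / T
    } else max(state$RT[fluid]) / T,
    mean_RT_fl_cycles = if (!is.null(fl_mask) && any(fl_mask)) {
      mean(state$RT[fl_mask]) / T
    } else NA_real_,
    div_max = state$div_max
  )
  wf <- grid$wall_faces
  if (!is.null(fl_mask) && any(fl_mask)) {
    on_fl <- fl_mask[cbind(wf$i, wf$j)]
    row$min_tawss_fl <- if (any(on_fl)) min(wall$tawss[on_fl]) else NA_real_
    row$max_tawss_fl <- if (any(on_fl)) max(wall$tawss[on_fl]) else NA_real_
  } else {
    row$min_tawss_fl <- NA_real_; row$max_tawss_fl <- NA_real_
  }
  tear <- grid$regions$tear_1
  if (!is.null(tear)) {
    fx <- region_top_flux(state, grid, tear)
    row$tear_flux_gross <- fx["gross"]
    row$tear_flux_net <- fx["net"]
    tl <- grid$regions$true_lumen
    ucell <- 0.5 * (state$u[-1, ] + state$u[-nrow(state$u), ])
    vcell <- 0.5 * (state$v[, -1] + state$v[, -ncol(state$v)])
    sp <- sqrt(ucell^2 + vcell^2)
    row$mean_speed_fl <- mean(sp[fl_mask])
    row$mean_speed_tl <- mean(sp[tl])
  }
  row
}

#' Per-cycle growth summary of a run
#'
#' @param run a `run_result` from [run_case()]
#' @return data frame with one row per simulated cycle: thrombosed area
#'   fraction of the false lumen (`BP > BP_t`), maximum BP, maximum
#'   normalized residence time, TAWSS extrema on false-lumen walls and
#'   tear flux diagnostics
#' @export
growth_report <- function(run) {
  stopifnot(inherits(run, "run_result"))
  run$cycles
}

#' Rough equivalent real time of an accelerated simulation
#'
#' With coagulant kinetics accelerated by the diffusivity augmentation
#' factor, simulated time multiplied by that factor roughly estimates the
#' equivalent physiological time.  The calibration comes from steady-flow
#' conditions and is only an order-of-magnitude guide under pulsatile
#' flow.
#'
#' @param sim_time simulated time (s)
#' @param f_aug augmentation factor (dimensionless)
#' @return estimated equivalent real time (s)
#' @export
time_scale_estimate <- function(sim_time, f_aug) {
  stopifnot(sim_time >= 0, f_aug >= 0)
  sim_time * f_aug
}
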