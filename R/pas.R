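# Lagrangian particle tracing through stored velocity snapshots and
# integration of the platelet activation state (PAS) index along
# trajectories.

# Bilinear interpolation of the staggered u field at points (x, y).
# u lives on vertical faces: x-nodes i*dx (i = 0..nx), y-nodes (j-1/2)*dy.
interp_u <- function(u, grid, x, y) {
  nx <- grid$nx; ny <- grid$ny
  xs <- pmin(pmax(x / grid$dx, 0), nx)
  ys <- pmin(pmax(y / grid$dy - 0.5, 0), ny - 1)
  i0 <- pmin(floor(xs), nx - 1); j0 <- pmin(floor(ys), ny - 2)
  fx <- xs - i0; fy <- ys - j0
  i0 <- i0 + 1; j0 <- j0 + 1  # 1-based
  u[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    u[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    u[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    u[cbind(i0 + 1, j0 + 1)] * fx * fy
}

interp_v <- function(v, grid, x, y) {
  nx <- grid$nx; ny <- grid$ny
  xs <- pmin(pmax(x / grid$dx - 0.5, 0), nx - 1)
  ys <- pmin(pmax(y / grid$dy, 0), ny)
  i0 <- pmin(floor(xs), nx - 2); j0 <- pmin(floor(ys), ny - 1)
  fx <- xs - i0; fy <- ys - j0
  i0 <- i0 + 1; j0 <- j0 + 1
  v[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    v[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    v[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    v[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# bilinear interpolation of a cell-centered field
interp_cell <- function(f, grid, x, y) {
  nx <- grid$nx; ny <- grid$ny
  xs <- pmin(pmax(x / grid$dx - 0.5, 0), nx - 1)
  ys <- pmin(pmax(y / grid$dy - 0.5, 0), ny - 1)
  i0 <- pmin(floor(xs), nx - 2); j0 <- pmin(floor(ys), ny - 2)
  fx <- xs - i0; fy <- ys - j0
  i0 <- i0 + 1; j0 <- j0 + 1
  f[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    f[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    f[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    f[cbind(i0 + 1, j0 + 1)] * fx * fy
}

#' Build a periodic velocity record from run snapshots
#'
#' Collects the snapshots covering the final simulated cycle of a run and
#' wraps them periodically, for use by [trace_particles()].
#'
#' @param run a `run_result` from [run_case()] (snapshots enabled)
#' @return a list with snapshot times (mapped into `[0, T)`), velocity and
#'   stress-related fields, and the period `T`
#' @export
velocity_record <- function(run) {
  T <- run$bc$T
  t_end <- run$state$t
  keep <- vapply(run$snapshots, function(s) s$t > t_end - T + 1e-9,
                 logical(1))
  snaps <- run$snapshots[keep]
  if (length(snaps) < 2) {
    stop("velocity_record: need at least 2 snapshots over the final cycle")
  }
  list(times = vapply(snaps, `[[`, numeric(1), "t") - (t_end - T),
       snaps = snaps, T = T, grid = run$grid)
}

# velocity (and scalar shear stress) at arbitrary time by periodic linear
# interpolation between snapshots
record_fields_at <- function(rec, tq) {
  tm <- tq %% rec$T
  ts <- rec$times
  n <- length(ts)
  k2 <- findInterval(tm, ts) + 1L
  if (k2 > n) { k1 <- n; k2 <- 1L; span <- rec$T - ts[n] + ts[1]
                w <- (tm - ts[n]) %% rec$T / span
  } else { k1 <- if (k2 == 1L) n else k2 - 1L
           t1 <- if (k2 == 1L) ts[n] - rec$T else ts[k1]
           w <- (tm - t1) / (ts[k2] - t1) }
  list(s1 = rec$snaps[[k1]], s2 = rec$snaps[[k2]], w = w)
}

#' Trace particles through a periodic velocity record
#'
#' Fourth-order Runge-Kutta advection with bilinear interpolation in
#' space and linear interpolation in time; the stored velocity record is
#' extended periodically.  Tracing terminates when a particle leaves the
#' domain through the outlet (`left domain`), reaches `max_cycles`
#' periods (`max-time`), or has effectively stopped moving (`stuck`).
#'
#' @param rec a [velocity_record()]
#' @param seeds two-column matrix of seed positions (m)
#' @param release_times release times (s), recycled over seeds if scalar
#' @param dt_particle integration step (s)
#' @param max_cycles maximum number of periods to integrate
#' @return a list of `particle_trajectory` objects with fields `times`,
#'   `xy`, `tau` (scalar shear stress along the path, Pa) and `exit`
#' @export
trace_particles <- function(rec, seeds, release_times = 0,
                            dt_particle = rec$T / 200, max_cycles = 10) {
  grid <- rec$grid
  np <- nrow(seeds)
  release_times <- rep_len(release_times, np)
  sol <- grid$mask == 0L
  in_solid <- function(x, y) {
    i <- pmin(pmax(ceiling(x / grid$dx), 1), grid$nx)
    j <- pmin(pmax(ceiling(y / grid$dy), 1), grid$ny)
    sol[cbind(i, j)]
  }
  # vectorized field evaluations over all particles at one shared time
  vel <- function(t, x, y) {
    f <- record_fields_at(rec, t)
    list(u = (1 - f$w) * interp_u(f$s1$u, grid, x, y) +
           f$w * interp_u(f$s2$u, grid, x, y),
         v = (1 - f$w) * interp_v(f$s1$v, grid, x, y) +
           f$w * interp_v(f$s2$v, grid, x, y))
  }
  tau_at <- function(t, x, y) {
    f <- record_fields_at(rec, t)
    (1 - f$w) * interp_cell(f$s1$mu * f$s1$gamma, grid, x, y) +
      f$w * interp_cell(f$s2$mu * f$s2$gamma, grid, x, y)
  }
  out <- vector("list", np)
  # particles sharing a release time advance together
  for (t0 in unique(release_times)) {
    grp <- which(release_times == t0)
    x <- seeds[grp, 1]; y <- seeds[grp, 2]
    bad <- in_solid(x, y)
    for (p in grp[bad]) {
      out[[p]] <- structure(list(release = t0, times = numeric(0),
                                 xy = matrix(0, 0, 2), tau = numeric(0),
                                 exit = "seed-in-solid"),
                            class = "particle_trajectory")
    }
    grp <- grp[!bad]
    if (length(grp) == 0) next
    x <- seeds[grp, 1]; y <- seeds[grp, 2]
    ng <- length(grp)
    nmax <- ceiling(max_cycles * rec$T / dt_particle)
    xs <- matrix(NA_real_, nmax + 1, ng)
    ys <- matrix(NA_real_, nmax + 1, ng)
    taus <- matrix(NA_real_, nmax + 1, ng)
    xs[1, ] <- x; ys[1, ] <- y; taus[1, ] <- tau_at(t0, x, y)
    active <- rep(TRUE, ng)
    nlast <- rep(1L, ng)
    exit <- rep("max-time", ng)
    h <- dt_particle
    for (k in seq_len(nmax)) {
      if (!any(active)) break
      t <- t0 + (k - 1) * h
      xa <- xs[k, active]; ya <- ys[k, active]
      k1 <- vel(t, xa, ya)
      k2 <- vel(t + h / 2, xa + h / 2 * k1$u, ya + h / 2 * k1$v)
      k3 <- vel(t + h / 2, xa + h / 2 * k2$u, ya + h / 2 * k2$v)
      k4 <- vel(t + h, xa + h * k3$u, ya + h * k3$v)
      xn <- xa + h / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
      yn <- ya + h / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
      idx <- which(active)
      xs[k + 1, idx] <- xn; ys[k + 1, idx] <- yn
      nlast[idx] <- k + 1L
      gone <- xn >= grid$Lx - 1e-12 | xn <= 1e-12 |
        yn <= 1e-12 | yn >= grid$Ly - 1e-12
      if (any(gone)) {
        taus[k + 1, idx[gone]] <- taus[k, idx[gone]]
        exit[idx[gone]] <- "left domain"
        active[idx[gone]] <- FALSE
      }
      stay <- idx[!gone]
      if (length(stay)) {
        taus[k + 1, stay] <- tau_at(t + h, xs[k + 1, stay], ys[k + 1, stay])
      }
    }
    for (q in seq_len(ng)) {
      n <- nlast[q]
      ex <- exit[q]
      if (ex == "max-time") {
        disp <- sqrt((xs[n, q] - xs[1, q])^2 + (ys[n, q] - ys[1, q])^2)
        if (disp < 0.01 * min(grid$dx, grid$dy)) ex <- "stuck"
      }
      out[[grp[q]]] <- structure(
        list(release = t0, times = t0 + (seq_len(n) - 1) * h,
             xy = cbind(xs[seq_len(n), q], ys[seq_len(n), q]),
             tau = taus[seq_len(n), q], exit = ex),
        class = "particle_trajectory")
    }
  }
  out
}

#' Platelet activation state along a shear-stress history
#'
#' Grigioni cumulative power-law load model:
#' `PAS(t) = C * [ (PAS_0/C)^(1/a) + integral_0^t tau(s)^(b/a) ds ]^a`,
#' evaluated by trapezoidal quadrature and clipped at 1.  For constant
#' shear stress and zero initial activation this reduces to the
#' closed form `C * tau^b * t^a`.
#'
#' @param tau shear-stress samples (Pa), non-negative
#' @param times sample times (s), strictly increasing, same length
#' @param params a [pas_params()] object
#' @param cumulative if `TRUE` return PAS at every sample time; otherwise
#'   the final value
#' @return PAS value(s) in `[0, 1]`
#' @export
pas_index <- function(tau, times, params = pas_params(),
                      cumulative = FALSE) {
  if (any(tau < 0) || any(!is.finite(tau))) {
    stop("pas_index: shear stress samples must be finite and non-negative")
  }
  stopifnot(length(tau) == length(times), !is.unsorted(times))
  a <- params$a; b <- params$b; C <- params$C_pas
  f <- tau^(b / a)
  n <- length(tau)
  if (n < 2) return(min(params$PAS_0, 1))
  inc <- diff(times) * (f[-1] + f[-n]) / 2
  load0 <- (params$PAS_0 / C)^(1 / a)
  loads <- load0 + cumsum(c(0, inc))
  pas <- pmin(C * loads^a, 1)
  if (cumulative) pas else pas[n]
}

#' Scalar shear stress along a traced path
#'
#' Returns the viscous shear-stress magnitude `mu * gamma_dot`
#' interpolated at the trajectory positions and times (already recorded
#' by [trace_particles()]); exposed for recomputation against other field
#' records.
#'
#' @param traj a `particle_trajectory`
#' @param rec a [velocity_record()] with `mu` and `gamma` snapshot fields
#' @return shear-stress samples (Pa) at the trajectory times
#' @export
shear_along_path <- function(traj, rec) {
  grid <- rec$grid
  vapply(seq_along(traj$times), function(k) {
    f <- record_fields_at(rec, traj$times[k])
    (1 - f$w) * interp_cell(f$s1$mu * f$s1$gamma, grid, traj$xy[k, 1],
                            traj$xy[k, 2]) +
      f$w * interp_cell(f$s2$mu * f$s2$gamma, grid, traj$xy[k, 1],
                        traj$xy[k, 2])
  }, numeric(1))
}

#' Trajectory seeds across the inlet
#'
#' Evenly spaced seed points just inside the inlet boundary, optionally
#' jittered.
#'
#' @param grid a `case_grid`
#' @param n number of seeds
#' @param jitter relative jitter amplitude (fraction of seed spacing);
#'   uses the current RNG state
#' @return an `n x 2` matrix of positions
#' @export
inlet_seeds <- function(grid, n = 24, jitter = 0) {
  jy <- grid$inlet_j
  if (length(jy) == 0) stop("inlet_seeds: grid has no inlet")
  y0 <- (min(jy) - 1) * grid$dy; y1 <- max(jy) * grid$dy
  ys <- seq(y0, y1, length.out = n + 2)[-c(1, n + 2)]
  if (jitter > 0) {
    ys <- ys + stats::runif(n, -jitter, jitter) * (y1 - y0) / (n + 1)
    ys <- pmin(pmax(ys, y0 + 0.1 * grid$dy), y1 - 0.1 * grid$dy)
  }
  cbind(rep(1.5 * grid$dx, n), ys)
}

#' Write traced pathlines as legacy VTK polylines colour-coded by PAS
#'
#' @param trajs list of `particle_trajectory` objects
#' @param params a [pas_params()] object used to compute per-point PAS
#' @param path output VTK path
#' @return `path`, invisibly
#' @export
write_pathlines_vtk <- function(trajs, params = pas_params(), path) {
  trajs <- Filter(function(tr) length(tr$times) >= 2, trajs)
  npts <- sum(vapply(trajs, function(tr) length(tr$times), integer(1)))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("thromboflow pathlines")
  w("ASCII")
  w("DATASET POLYDATA")
  w("POINTS ", npts, " double")
  for (tr in trajs) {
    writeLines(paste(fmt(tr$xy[, 1]), fmt(tr$xy[, 2]), "0"), con)
  }
  sizes <- vapply(trajs, function(tr) length(tr$times), integer(1))
  w("LINES ", length(trajs), " ", length(trajs) + npts)
  off <- 0L
  for (s in sizes) {
    w(paste(c(s, seq(off, off + s - 1)), collapse = " "))
    off <- off + s
  }
  w("POINT_DATA ", npts)
  w("SCALARS PAS double 1")
  w("LOOKUP_TABLE default")
  for (tr in trajs) {
    writeLines(fmt(pas_index(tr$tau, tr$times, params, cumulative = TRUE)),
               con)
  }
  invisible(path)
}
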