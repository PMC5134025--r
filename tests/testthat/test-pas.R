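# Lagrangian tracer and the platelet activation state index.

test_that("tracing through a uniform field is exact and exits the outlet", {
  rec <- uniform_record(U = 0.1)
  tr <- trace_particles(rec, cbind(0.005, 0.01), release_times = 0,
                        dt_particle = 1e-3, max_cycles = 10)[[1]]
  expect_equal(tr$exit, "left domain")
  n <- length(tr$times)
  expect_equal(tr$xy[n - 1, 1], 0.005 + 0.1 * (tr$times[n - 1]),
               tolerance = 1e-12)
  expect_equal(tr$xy[n - 1, 2], 0.01, tolerance = 1e-12)
})

test_that("solid-body rotation returns the particle to its start", {
  grid <- build_channel(0.1, 0.1, 40, 40, closed = TRUE)
  xc <- 0.05; yc <- 0.05; omega <- 2 * pi
  xf <- seq(0, grid$Lx, by = grid$dx)
  yf <- seq(0, grid$Ly, by = grid$dy)
  u <- outer(xf, grid$y, function(x, y) -omega * (y - yc))
  v <- outer(grid$x, yf, function(x, y) omega * (x - xc))
  mk <- function(t) list(t = t, u = u, v = v,
                         mu = matrix(3.5e-3, grid$nx, grid$ny),
                         gamma = matrix(0, grid$nx, grid$ny))
  rec <- list(times = c(0.25, 0.75), snaps = list(mk(0.25), mk(0.75)),
              T = 1, grid = grid)
  r0 <- 0.02
  tr <- trace_particles(rec, cbind(xc + r0, yc), release_times = 0,
                        dt_particle = 1 / 1000, max_cycles = 1)[[1]]
  n <- length(tr$times)
  expect_equal(tr$times[n], 1, tolerance = 1e-9)
  drift <- sqrt((tr$xy[n, 1] - (xc + r0))^2 + (tr$xy[n, 2] - yc)^2)
  expect_lt(drift / r0, 1e-6)
  # radius conserved along the whole orbit
  r <- sqrt((tr$xy[, 1] - xc)^2 + (tr$xy[, 2] - yc)^2)
  expect_lt(max(abs(r - r0)) / r0, 1e-6)
})

test_that("a particle in stagnant fluid terminates as stuck", {
  rec <- uniform_record(U = 0)
  tr <- trace_particles(rec, cbind(0.05, 0.01), release_times = 0,
                        dt_particle = 0.01, max_cycles = 2)[[1]]
  expect_equal(tr$exit, "stuck")
})

test_that("seeds inside solid cells are reported, not fatal", {
  grid <- build_idealized_dissection(resolution = 1e-3)
  mk <- function(t) list(t = t, u = matrix(0, grid$nx + 1, grid$ny),
                         v = matrix(0, grid$nx, grid$ny + 1),
                         mu = matrix(1e-3, grid$nx, grid$ny),
                         gamma = matrix(0, grid$nx, grid$ny))
  rec <- list(times = c(0.25, 0.75), snaps = list(mk(0.25), mk(0.75)),
              T = 1, grid = grid)
  # a point inside the flap (solid) and one in the lumen
  trs <- trace_particles(rec, rbind(c(0.05, 0.011), c(0.05, 0.005)),
                         release_times = 0, dt_particle = 0.05,
                         max_cycles = 1)
  expect_equal(trs[[1]]$exit, "seed-in-solid")
  expect_equal(trs[[2]]$exit, "stuck")
})

test_that("PAS closed form holds for constant shear stress", {
  p <- pas_params()
  t <- seq(0, 1, length.out = 101)
  expect_equal(pas_index(rep(1, 101), t, p), 1e-5, tolerance = 1e-3)
  # tau = 2 Pa for 1 s: C * 2^b, hand-evaluated 1.5429e-5
  expect_equal(pas_index(rep(2, 101), t, p), 1.5429e-5, tolerance = 1e-3)
  expect_equal(pas_index(rep(0, 101), t, p), 0)
  # nonzero initial activation is recovered at tau = 0
  p2 <- pas_params(PAS_0 = 0.01)
  expect_equal(pas_index(rep(0, 11), seq(0, 1, length.out = 11), p2), 0.01,
               tolerance = 1e-9)
  expect_error(pas_index(c(1, -1), c(0, 1), p), "non-negative")
})

test_that("PAS matches the piecewise-constant closed form and is monotone", {
  p <- pas_params()
  # three segments: tau = 0.5, 3, 1.2 Pa over 2, 1, 3 s
  taus <- c(0.5, 3, 1.2); durs <- c(2, 1, 3)
  ts <- seq(0, sum(durs), by = 1e-3)
  tau_t <- taus[findInterval(ts, cumsum(c(0, durs)), rightmost.closed = TRUE,
                             left.open = TRUE)]
  tau_t[1] <- taus[1]
  exact_load <- sum(taus^(p$b / p$a) * durs)
  exact <- p$C_pas * exact_load^p$a
  expect_equal(pas_index(tau_t, ts, p), exact, tolerance = 1e-3)
  # monotone in time
  cum <- pas_index(tau_t, ts, p, cumulative = TRUE)
  expect_true(all(diff(cum) >= 0))
  # halving the sampling step changes the result by < 1%
  ts2 <- seq(0, sum(durs), by = 2e-3)
  tau2 <- taus[findInterval(ts2, cumsum(c(0, durs)), rightmost.closed = TRUE,
                            left.open = TRUE)]
  tau2[1] <- taus[1]
  expect_equal(pas_index(tau2, ts2, p), pas_index(tau_t, ts, p),
               tolerance = 0.01)
})

test_that("platelets entering the false lumen carry the highest activation", {
  # trace through the pre-thrombosis periodic flow of the two-tear case
  # (the activation analysis motivates the background-activation initial
  # condition, so it runs on the clean spin-up flow)
  run <- s4_test_run()
  g <- run$grid; T <- run$bc$T
  keep <- vapply(run$snapshots,
                 function(s) s$t > T + 1e-9 && s$t <= 2 * T + 1e-9,
                 logical(1))
  snaps <- run$snapshots[keep]
  rec <- list(times = vapply(snaps, `[[`, numeric(1), "t") - T,
              snaps = snaps, T = T, grid = g)
  fl_y0 <- g$meta$lumen_height + g$meta$flap_thickness
  yy <- seq(0.6, 0.995, length.out = 50) * g$meta$lumen_height
  seeds <- cbind(rep(1.5 * g$dx, 50), yy)
  trajs <- list()
  for (f in c(0, 0.15, 0.3, 0.45)) {
    trajs <- c(trajs, trace_particles(rec, seeds, release_times = f * T,
                                      dt_particle = T / 400,
                                      max_cycles = 3))
  }
  entered <- vapply(trajs, function(tr) any(tr$xy[, 2] > fl_y0 - 1e-9),
                    logical(1))
  pas <- vapply(trajs, function(tr) pas_index(tr$tau, tr$times),
                numeric(1))
  expect_gte(sum(entered), 5)
  expect_gt(mean(pas[entered]), mean(pas[!entered]))
})

test_that("shear stress along a Poiseuille streamline matches the linear law", {
  pz <- poiseuille_case(ny = 32)
  cfg <- normalize_config(pz$config)
  props <- do.call(fluid_props, cfg$fluid)
  params <- do.call(thrombosis_params, cfg$thrombosis)
  bc <- do.call(waveform_params, cfg$waveform)
  grid <- thromboflow:::build_case_grid(cfg$geometry)
  st <- field_state(grid, props, params)
  for (i in seq_len(grid$nx + 1)) st$u[i, ] <- pz$analytic(grid$y)
  sh <- shear_fields(st, grid)
  st$gamma <- sh$gamma
  snap <- list(t = 0.5, u = st$u, v = st$v, mu = st$mu, gamma = st$gamma)
  rec <- list(times = c(0.25, 0.75), snaps = list(snap, snap), T = 1,
              grid = grid)
  mu <- props$mu_newtonian
  h <- pz$h; U <- pz$U
  for (yq in c(0.2, 0.35) * h) {
    tr <- trace_particles(rec, cbind(0.5 * grid$Lx, yq), release_times = 0,
                          dt_particle = 0.01, max_cycles = 0.05)[[1]]
    tau_exact <- mu * 6 * U * abs(h - 2 * yq) / h^2
    expect_equal(mean(tr$tau), tau_exact, tolerance = 0.02)
  }
  # centerline shear stress is (nearly) zero; wall-adjacent paths load most
  tr_mid <- trace_particles(rec, cbind(0.5 * grid$Lx, h / 2),
                            release_times = 0, dt_particle = 0.01,
                            max_cycles = 0.05)[[1]]
  tau_wallish <- mu * 6 * U * abs(h - 2 * 0.1 * h) / h^2
  expect_lt(mean(tr_mid$tau), 0.1 * tau_wallish)
})
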