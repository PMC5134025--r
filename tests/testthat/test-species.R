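# Species transport: residence time, platelets, coagulant, bound
# platelets and their gating.

make_box <- function(nx = 8, ny = 8) {
  grid <- build_channel(0.016, 0.016, nx, ny, closed = TRUE)
  props <- fluid_props(); params <- thrombosis_params()
  list(grid = grid, props = props, params = params,
       st = field_state(grid, props, params))
}

test_that("residence time accumulates wall-clock time in a stagnant box", {
  b <- make_box()
  dt <- 0.02
  for (k in 1:250) b$st <- update_residence_time(b$st, b$grid, dt, b$params)
  fl <- b$grid$mask == 1L
  expect_equal(max(abs(b$st$RT[fl] - 5)), 0, tolerance = 5e-3)
})

test_that("residence time at the outlet approximates the transit time", {
  # prescribed uniform plug flow (divergence-free), RT transport only
  grid <- build_channel(0.1, 0.02, 50, 8)
  props <- fluid_props(); params <- thrombosis_params()
  st <- field_state(grid, props, params)
  U <- 0.05
  st$u[] <- U
  dt <- 0.4 * grid$dx / U
  t_end <- 3 * 0.1 / U
  nstep <- ceiling(t_end / dt)
  for (k in seq_len(nstep)) st <- update_residence_time(st, grid, dt, params)
  outlet_rt <- mean(st$RT[grid$nx, ])
  expect_equal(outlet_rt, 0.1 / U, tolerance = 0.03)
  # inlet cells stay near zero
  expect_lt(mean(st$RT[1, ]), 0.15 * 0.1 / U)
})

test_that("platelet fields hold their inlet values and depletion is AP-first", {
  b <- make_box()
  st <- update_platelets(b$st, b$grid, 0.01, b$params)
  fl <- b$grid$mask == 1L
  expect_equal(st$RP_rel[fl], rep(1, sum(fl)))
  expect_equal(st$AP_rel[fl], rep(b$params$ap_inlet, sum(fl)))
  # depletion: forming dBP consumes lambda_dep * dBP, AP first then RP
  dBP <- matrix(0, b$grid$nx, b$grid$ny)
  dBP[4, 4] <- 100  # needs 100 * 2.5e-4 = 0.025 relative units
  st2 <- update_platelets(st, b$grid, 0.01, b$params, dBP = dBP)
  expect_equal(st2$AP_rel[4, 4], 0.05 - 0.025, tolerance = 1e-12)
  expect_equal(st2$RP_rel[4, 4], 1)
  dBP[4, 4] <- 400  # needs 0.1 > AP pool: remainder from RP
  st3 <- update_platelets(st, b$grid, 0.01, b$params, dBP = dBP)
  expect_equal(st3$AP_rel[4, 4], 0, tolerance = 1e-12)
  expect_equal(st3$RP_rel[4, 4], 1 - (0.1 - 0.05), tolerance = 1e-12)
})

test_that("steady platelet throughflow balances inlet and outlet fluxes", {
  grid <- build_channel(0.1, 0.02, 50, 8)
  props <- fluid_props(); params <- thrombosis_params()
  st <- field_state(grid, props, params)
  U <- 0.05
  st$u[] <- U
  st$RP_rel[] <- 0.3 # perturb, then let the inlet refill the channel
  dt <- 0.4 * grid$dx / U
  for (k in seq_len(ceiling(4 * 0.1 / U / dt))) {
    st <- update_platelets(st, grid, dt, params)
  }
  flux_in <- sum(U * 1 * grid$dy * length(grid$inlet_j))
  flux_out <- sum(U * st$RP_rel[grid$nx, ] * grid$dy)
  expect_equal(flux_out / (U * 1 * grid$dy * grid$ny), 1, tolerance = 0.01)
  expect_equal(flux_out, flux_in / length(grid$inlet_j) * grid$ny,
               tolerance = 0.01)
})

test_that("coagulant grows at the wall-flux rate in a quiescent box", {
  b <- make_box()
  wall <- wall_state(b$grid)
  wf <- b$grid$wall_faces
  # one low-TAWSS face, all others above threshold
  wall$tawss <- rep(0.5, nrow(wf))
  wall$tawss[1] <- 0.05
  dt <- 0.002
  nstep <- 50
  for (k in seq_len(nstep)) {
    b$st <- update_coagulant(b$st, b$grid, wall, dt, b$params)
  }
  total_C <- sum(b$st$C) * b$grid$dx * b$grid$dy
  expected <- b$params$k_c_wall * wf$len[1] * dt * nstep
  expect_equal(total_C, expected, tolerance = 1e-6)
  # all faces above threshold: C stays identically zero
  b2 <- make_box()
  wall2 <- wall_state(b2$grid)
  wall2$tawss <- rep(0.5, nrow(wf))
  b2$st <- update_coagulant(b2$st, b2$grid, wall2, dt, b2$params)
  expect_equal(max(b2$st$C), 0)
})

test_that("coagulant is consumed at high cycle-averaged shear", {
  b <- make_box()
  wall <- wall_state(b$grid)
  wall$tawss <- rep(0.5, nrow(b$grid$wall_faces)) # no wall source
  b$st$C[] <- 5
  b$st$C[b$grid$mask != 1L] <- 0
  b$st$gamma_avg[] <- 500
  dt <- 1e-3
  st2 <- update_coagulant(b$st, b$grid, wall, dt, b$params)
  # one explicit step reproduces the pointwise rate exactly (uniform field,
  # no gradients): dC = dt * eps * (-k_c C/C_t switch_up(500, 50, 2))
  rate <- coagulant_bulk_source(5, 0, 500, b$params)
  expect_lt(rate, 0)
  fl <- b$grid$mask == 1L
  expect_equal(st2$C[fl], rep(5 + dt * rate, sum(fl)), tolerance = 1e-12)
})

test_that("bound platelets grow only where the shear gates allow", {
  b <- make_box()
  wall <- wall_state(b$grid)
  nf <- nrow(b$grid$wall_faces)
  dt <- 0.01
  # ineligible: wall faces above TAWSS threshold, bulk above 50 1/s
  wall$tawss <- rep(0.25, nf)
  b$st$C[] <- 1e6; b$st$C[b$grid$mask != 1L] <- 0
  b$st$gamma_avg[] <- 80
  st2 <- update_bound_platelets(b$st, b$grid, wall, dt, b$params)
  expect_equal(max(st2$BP), 0)
  # eligible wall cells at rest: dBP ~ k_BP * dt at saturating coagulant
  wall$tawss <- rep(0.05, nf)
  b$st$gamma_avg[] <- 0
  st3 <- update_bound_platelets(b$st, b$grid, wall, dt, b$params)
  wcells <- unique(cbind(b$grid$wall_faces$i, b$grid$wall_faces$j))
  expect_equal(st3$BP[wcells], rep(b$params$k_BP * dt, nrow(wcells)),
               tolerance = 1e-3)
  # interior (non wall-adjacent) cells are bulk-gated: eligible at rest
  expect_gt(st3$BP[4, 4], 0)
  # monotone and immobile: zero source leaves BP untouched
  st3$C[] <- 0
  st4 <- update_bound_platelets(st3, b$grid, wall, dt, b$params)
  expect_identical(st4$BP, st3$BP)
})

test_that("thrombus can expand into neighbors of existing deposits", {
  b <- make_box()
  wall <- wall_state(b$grid)
  wall$tawss <- rep(0.5, nrow(b$grid$wall_faces)) # walls ineligible
  b$st$gamma_avg[] <- 80                          # bulk ineligible
  b$st$C[] <- 1e6; b$st$C[b$grid$mask != 1L] <- 0
  b$st$BP[4, 4] <- 2 * b$params$BP_t              # existing thrombus
  st2 <- update_bound_platelets(b$st, b$grid, wall, 0.01, b$params)
  grew <- which(st2$BP > b$st$BP, arr.ind = TRUE)
  expect_setequal(paste(grew[, 1], grew[, 2]),
                  c("3 4", "5 4", "4 3", "4 5"))
})

test_that("cycle-averaged shear is the arithmetic mean of samples", {
  m <- function(v) matrix(v, 2, 2)
  expect_equal(cycle_averaged_shear(list(m(50), m(50))), m(50))
  th <- seq(0, pi, length.out = 2001)
  samples <- lapply(th, function(t) m(abs(sin(t))))
  avg <- cycle_averaged_shear(samples)
  expect_equal(avg[1, 1], 2 / pi, tolerance = 1e-3)
})
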