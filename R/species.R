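# Species transport: residence time, platelets, coagulant and the
# immobile bound-platelet (thrombus) field.
#
# All mobile scalars obey d(eps*phi)/dt + s * div(u phi) = div(D grad phi)
# + source on the staggered grid (conservative MUSCL advection, explicit
# diffusion).  Reaction rates are per unit fluid volume, so volumetric
# sources carry a factor eps.

# shared wrapper over the C++ kernel with non-negativity clipping
advect_scalar <- function(state, grid, field, D, dt, phi_in, src = NULL,
                          conv_scale = NULL, eps_old = NULL) {
  nx <- grid$nx; ny <- grid$ny
  if (is.null(src)) src <- matrix(0, nx, ny)
  if (is.null(conv_scale)) conv_scale <- matrix(1, nx, ny)
  if (is.null(eps_old)) eps_old <- state$eps
  phi <- .scalar_step_cpp(state[[field]], state$u, state$v, grid$mask,
                          eps_old, state$eps, D, grid$dx, grid$dy, dt,
                          grid$inlet_j, grid$outlet_j, phi_in, src,
                          conv_scale)
  neg <- phi < 0 & grid$mask == 1L
  if (any(neg)) {
    phi[neg] <- 0
    state$clips[field] <- state$clips[field] + sum(neg)
  }
  state[[field]] <- phi
  state
}

#' Advance the residence-time field
#'
#' `dRT/dt + div(u RT) = div(D_RT grad RT) + 1`, with `RT = 0` at the
#' inlet.  In a stagnant region RT therefore accumulates wall-clock time;
#' reports normalize by the cardiac period to express RT in cycles.
#'
#' @param state a `field_state`
#' @param grid a `case_grid`
#' @param dt time step (s)
#' @param params a [thrombosis_params()] object
#' @return the updated `field_state`
#' @export
update_residence_time <- function(state, grid, dt,
                                  params = thrombosis_params()) {
  src <- state$eps
  src[grid$mask != 1L] <- 0
  advect_scalar(state, grid, "RT", params$D_RT, dt, phi_in = 0, src = src)
}

#' Advance resting and activated platelet fields
#'
#' Both platelet fields are advected and diffused with diffusivity `D_p`;
#' inlet values are `RP_rel = 1` (the physiological inlet concentration)
#' and `AP_rel = ap_inlet` (the 5% background activation level).  Where
#' bound platelets form, free platelets are consumed in proportion
#' `lambda_dep` per nmol/l of BP, taken from the activated pool first.
#'
#' @param state a `field_state`
#' @param grid a `case_grid`
#' @param dt time step (s)
#' @param params a [thrombosis_params()] object
#' @param dBP bound-platelet increment formed over this step (nmol/l
#'   matrix), used as the platelet sink; defaults to zero
#' @return the updated `field_state`
#' @export
update_platelets <- function(state, grid, dt, params = thrombosis_params(),
                             dBP = NULL) {
  state <- advect_scalar(state, grid, "RP_rel", params$D_p, dt, phi_in = 1)
  state <- advect_scalar(state, grid, "AP_rel", params$D_p, dt,
                         phi_in = params$ap_inlet)
  if (!is.null(dBP) && any(dBP > 0)) {
    need <- params$lambda_dep * dBP
    from_ap <- pmin(state$AP_rel, need)
    state$AP_rel <- state$AP_rel - from_ap
    state$RP_rel <- pmax(state$RP_rel - (need - from_ap), 0)
  }
  state
}

# volumetric source (nmol/l/s) applied to wall-adjacent cells by the
# coagulant wall-flux law: flux * face_length / cell_area per wall face.
coagulant_wall_source <- function(state, grid, wall,
                                  params = thrombosis_params()) {
  src <- matrix(0, grid$nx, grid$ny)
  wf <- grid$wall_faces
  bp_wall <- state$BP[cbind(wf$i, wf$j)]
  flux <- coagulant_wall_flux(wall$tawss, bp_wall, params)
  contrib <- flux * wf$len / (grid$dx * grid$dy)
  lin <- (wf$j - 1L) * grid$nx + wf$i
  s <- rowsum(contrib, lin)
  src[as.integer(rownames(s))] <- s[, 1]
  src
}

#' Advance the coagulant field
#'
#' Convection-diffusion-reaction update of the coagulant with (i) the
#' augmented diffusivity `f_aug * D_c`, (ii) a Neumann wall source given
#' by [coagulant_wall_flux()] on wall faces whose previous-cycle TAWSS is
#' below threshold, (iii) the bulk production/consumption term of
#' [coagulant_bulk_source()], and (iv) convection suppressed in low-shear
#' diffusion-limited zones by the factor
#' `switch_up(gamma_avg, gamma_t)` (transport is simplified by region).
#'
#' @param state a `field_state` (uses `state$gamma_avg`)
#' @param grid a `case_grid`
#' @param wall a [wall_state()] carrying previous-cycle TAWSS
#' @param dt time step (s)
#' @param params a [thrombosis_params()] object
#' @return the updated `field_state`
#' @export
update_coagulant <- function(state, grid, wall, dt,
                             params = thrombosis_params()) {
  fl <- grid$mask == 1L
  src <- coagulant_wall_source(state, grid, wall, params)
  bulk <- matrix(0, grid$nx, grid$ny)
  bulk[fl] <- state$eps[fl] *
    coagulant_bulk_source(state$C[fl], state$BP[fl], state$gamma_avg[fl],
                          params)
  sconv <- switch_up(state$gamma_avg, params$gamma_t, params$n_sw)
  advect_scalar(state, grid, "C", params$D_c_eff, dt, phi_in = 0,
                src = src + bulk, conv_scale = sconv)
}

#' Per-cycle growth gate
#'
#' Precomputes the parts of the bound-platelet eligibility mask that only
#' change at cycle boundaries: wall-adjacent cells whose minimum adjacent
#' wall-face TAWSS is below the 0.2 Pa threshold, and bulk (non
#' wall-adjacent) cells whose cycle-averaged shear rate is below the
#' 50 1/s threshold.
#'
#' @param state a `field_state` (uses `state$gamma_avg`)
#' @param grid a `case_grid`
#' @param wall a [wall_state()]
#' @param params a [thrombosis_params()] object
#' @return list with logical matrices `wall_low`, `bulk_low` and the
#'   per-cell minimum adjacent TAWSS `min_tawss` (`Inf` away from walls)
#' @export
growth_gate <- function(state, grid, wall, params = thrombosis_params()) {
  nx <- grid$nx; ny <- grid$ny
  fl <- grid$mask == 1L
  wf <- grid$wall_faces
  min_tawss <- matrix(Inf, nx, ny)
  lin <- (wf$j - 1L) * nx + wf$i
  mt <- tapply(wall$tawss, lin, min)
  min_tawss[as.integer(names(mt))] <- mt
  wall_low <- fl & is.finite(min_tawss) & min_tawss < params$tau_w_t
  bulk_low <- fl & !is.finite(min_tawss) & state$gamma_avg < params$gamma_t
  list(wall_low = wall_low, bulk_low = bulk_low, min_tawss = min_tawss)
}

# thrombosed-neighbor mask (changes every step as BP grows)
thrombus_neighbors <- function(BP, mask, BP_t) {
  nx <- nrow(BP); ny <- ncol(BP)
  thromb <- BP > BP_t
  nb <- matrix(FALSE, nx, ny)
  nb[-1, ] <- nb[-1, ] | thromb[-nx, ]
  nb[-nx, ] <- nb[-nx, ] | thromb[-1, ]
  nb[, -1] <- nb[, -1] | thromb[, -ny]
  nb[, -ny] <- nb[, -ny] | thromb[, -1]
  nb & mask == 1L
}

#' Advance the bound-platelet (thrombus) field
#'
#' Bound platelets are immobile (neither advected nor diffused):
#' `dBP/dt = bound_platelet_source`, applied only on eligible cells:
#' wall-adjacent cells whose previous-cycle TAWSS is below 0.2 Pa, bulk
#' cells whose cycle-averaged shear rate is below 50 1/s, or cells
#' adjacent to existing thrombus (`BP > BP_t`), which lets a clot expand
#' contiguously.  BP is monotone non-decreasing.  At first deposition the
#' gate values are recorded in `dep_kind`/`dep_tawss`/`dep_gavg` for
#' growth-gating audits.
#'
#' @param state a `field_state`
#' @param grid a `case_grid`
#' @param wall a [wall_state()] carrying previous-cycle TAWSS
#' @param dt time step (s)
#' @param params a [thrombosis_params()] object
#' @param gate optional precomputed [growth_gate()] (refreshed once per
#'   cycle by the coupler)
#' @return the updated `field_state`; `state$last_dBP` holds the applied
#'   increment (used as the platelet sink)
#' @export
update_bound_platelets <- function(state, grid, wall, dt,
                                   params = thrombosis_params(),
                                   gate = growth_gate(state, grid, wall,
                                                      params)) {
  fl <- grid$mask == 1L
  nb <- thrombus_neighbors(state$BP, grid$mask, params$BP_t)
  mask_ok <- gate$wall_low | gate$bulk_low | nb
  rate <- matrix(0, grid$nx, grid$ny)
  rate[fl] <- bound_platelet_source(state$AP_rel[fl] / params$ap_inlet,
                                    state$C[fl], state$gamma_avg[fl], params)
  dBP <- rate * dt
  dBP[!mask_ok] <- 0
  newdep <- dBP > 0 & state$BP == 0
  if (any(newdep)) {
    kind <- ifelse(gate$wall_low, 1L, ifelse(gate$bulk_low, 2L, 3L))
    state$dep_kind[newdep] <- kind[newdep]
    wallrec <- newdep & gate$wall_low
    state$dep_tawss[wallrec] <- gate$min_tawss[wallrec]
    bulkrec <- newdep & !gate$wall_low & gate$bulk_low
    state$dep_gavg[bulkrec] <- state$gamma_avg[bulkrec]
  }
  state$BP <- state$BP + dBP
  state$last_dBP <- dBP
  state
}

#' Arithmetic cycle average of shear-rate samples
#'
#' Time average of per-cell shear-rate fields sampled over one cardiac
#' cycle; the growth coupler refreshes `state$gamma_avg` with this at each
#' cycle boundary.
#'
#' @param samples a list of `nx x ny` shear-rate matrices (uniformly
#'   spaced samples over the previous cycle)
#' @return the element-wise mean matrix
#' @export
cycle_averaged_shear <- function(samples) {
  stopifnot(length(samples) >= 1)
  Reduce(`+`, samples) / length(samples)
}
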