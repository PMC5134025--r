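#' Blood fluid properties
#'
#' Container for the fluid constants used by the flow solver: density, the
#' Quemada rheology constants and a shear-rate floor below which the
#' viscosity is evaluated at `gamma_min` (the Quemada law diverges as the
#' shear rate tends to zero for haematocrit above the critical packing).
#'
#' Defaults are standard literature values for whole blood at 45%
#' haematocrit: plasma viscosity 1.2 mPa s, intrinsic viscosity constants
#' `k0 = 4.33`, `kinf = 2.07` and critical shear rate 1.88 1/s.  The
#' default shear-rate floor of 0.05 1/s caps the low-shear viscosity at
#' about 0.13 Pa s, the measured low-shear plateau of whole blood, which
#' also bounds the explicit viscous stability limit in stagnant regions.
#'
#' @param rho blood density (kg/m^3)
#' @param mu_p plasma viscosity (Pa s)
#' @param H haematocrit (volume fraction, 0 < H < 1)
#' @param k0 Quemada intrinsic viscosity at zero shear (dimensionless)
#' @param kinf Quemada intrinsic viscosity at infinite shear (dimensionless)
#' @param gamma_c Quemada critical shear rate (1/s)
#' @param gamma_min shear-rate floor used when evaluating the viscosity (1/s)
#' @param newtonian if `TRUE` the solver uses the constant viscosity
#'   `mu_newtonian` everywhere (used by the analytic verification cases)
#' @param mu_newtonian constant viscosity for the Newtonian override (Pa s)
#' @return an object of class `fluid_props`
#' @export
fluid_props <- function(rho = 1060, mu_p = 1.2e-3, H = 0.45,
                        k0 = 4.33, kinf = 2.07, gamma_c = 1.88,
                        gamma_min = 0.05,
                        newtonian = FALSE, mu_newtonian = 3.5e-3) {
  stopifnot(rho > 0, mu_p > 0, H >= 0, H < 1, gamma_c > 0, gamma_min > 0,
            mu_newtonian > 0)
  structure(list(rho = rho, mu_p = mu_p, H = H, k0 = k0, kinf = kinf,
                 gamma_c = gamma_c, gamma_min = gamma_min,
                 newtonian = isTRUE(newtonian), mu_newtonian = mu_newtonian),
            class = "fluid_props")
}

#' Thrombosis model parameters
#'
#' All constants of the thrombus formation model: kinetic constants for the
#' coagulant and bound platelets, the momentum-source constant of the
#' porous clot, species diffusivities, the shear and concentration
#' thresholds that gate growth, and the clot porosity bounds.
#'
#' The wall flux of coagulant is released only on wall faces whose
#' previous-cycle time-averaged wall shear stress (TAWSS) is below
#' `tau_w_t` (0.2 Pa) and shuts off once the local bound-platelet
#' concentration exceeds `BP_complete` (200 nmol/l).  Bulk growth away from
#' the wall is gated on the cycle-averaged shear rate threshold `gamma_t`
#' (50 1/s).  Clot porosity falls linearly from 1 to `eps_min` (0.75) as BP
#' rises to `BP_t` (20 nmol/l).
#'
#' The coagulant diffusivity actually used in transport is the augmented
#' value `f_aug * D_c`; the augmentation factor (default 150) artificially
#' accelerates the clotting kinetics so that thrombosis completes within
#' tens of cardiac cycles instead of hours.
#'
#' @param k_c coagulant kinetic constant (nmol/l/s)
#' @param k_c_wall coagulant wall-kinetic constant (nmol/m/l/s)
#' @param k_M momentum source constant (kg/m^3/s)
#' @param D_c base coagulant diffusivity (m^2/s)
#' @param f_aug coagulant diffusivity augmentation factor (dimensionless)
#' @param BP_t bound-platelet threshold identifying formed thrombus (nmol/l)
#' @param BP_complete bound-platelet level of complete thrombosis (nmol/l)
#' @param tau_w_t TAWSS threshold for wall growth (Pa)
#' @param gamma_t cycle-averaged bulk shear-rate threshold (1/s)
#' @param eps_min porosity of a completely formed clot (dimensionless)
#' @param C_t coagulant switching scale (nmol/l)
#' @param k_BP bound-platelet kinetic constant (nmol/l/s)
#' @param D_p platelet diffusivity (m^2/s)
#' @param D_RT residence-time diffusivity (m^2/s)
#' @param n_sw switching-function exponent (dimensionless, >= 1)
#' @param ap_inlet inlet activated-platelet fraction (relative to the inlet
#'   platelet concentration)
#' @param lambda_dep platelet depletion coefficient: relative platelet units
#'   consumed per nmol/l of bound platelets formed.  The default
#'   `ap_inlet / BP_complete` makes complete local thrombosis exhaust
#'   exactly the local background activated-platelet pool.
#' @return an object of class `thrombosis_params`
#' @export
thrombosis_params <- function(k_c = 200, k_c_wall = 20, k_M = 1e7,
                              D_c = 1e-8, f_aug = 150,
                              BP_t = 20, BP_complete = 200,
                              tau_w_t = 0.2, gamma_t = 50,
                              eps_min = 0.75, C_t = 10, k_BP = 2,
                              D_p = 1e-9, D_RT = 1e-9, n_sw = 2,
                              ap_inlet = 0.05,
                              lambda_dep = ap_inlet / BP_complete) {
  stopifnot(k_c >= 0, k_c_wall >= 0, k_M >= 0, D_c >= 0, f_aug >= 0,
            D_p >= 0, D_RT >= 0, k_BP >= 0,
            eps_min > 0, eps_min <= 1,
            BP_t > 0, BP_complete > BP_t,
            tau_w_t > 0, gamma_t > 0, C_t > 0, n_sw >= 1,
            ap_inlet > 0, ap_inlet <= 1, lambda_dep >= 0)
  structure(list(k_c = k_c, k_c_wall = k_c_wall, k_M = k_M,
                 D_c = D_c, f_aug = f_aug, D_c_eff = f_aug * D_c,
                 BP_t = BP_t, BP_complete = BP_complete,
                 tau_w_t = tau_w_t, gamma_t = gamma_t,
                 eps_min = eps_min, C_t = C_t, k_BP = k_BP,
                 D_p = D_p, D_RT = D_RT, n_sw = n_sw,
                 ap_inlet = ap_inlet, lambda_dep = lambda_dep),
            class = "thrombosis_params")
}

#' Platelet activation state (PAS) model constants
#'
#' Constants of the Grigioni power-law cumulative shear-load model, as
#' calibrated in vivo by Nobili and co-workers: `PAS = C * [ (PAS0/C)^(1/a)
#' + integral of tau^(b/a) dt ]^a`.
#'
#' @param a time exponent (dimensionless)
#' @param b shear-stress exponent (dimensionless)
#' @param C_pas scale constant (dimensionless)
#' @param PAS_0 initial activation state in `[0, 1)`
#' @return an object of class `pas_params`
#' @export
pas_params <- function(a = 1.3198, b = 0.6256, C_pas = 1e-5, PAS_0 = 0) {
  stopifnot(a > 0, b > 0, C_pas > 0, PAS_0 >= 0, PAS_0 < 1)
  structure(list(a = a, b = b, C_pas = C_pas, PAS_0 = PAS_0),
            class = "pas_params")
}

#' Quemada viscosity of whole blood
#'
#' Shear-thinning viscosity `mu = mu_p * (1 - k(g)*H/2)^-2` with intrinsic
#' viscosity `k(g) = (k0 + kinf*sqrt(g/gc)) / (1 + sqrt(g/gc))`.  Shear
#' rates below the floor `props$gamma_min` are clamped to the floor, which
#' bounds the viscosity in stagnant regions.
#'
#' @param gamma_dot shear rate (1/s), vectorized, must be non-negative
#'   and finite
#' @param props a [fluid_props()] object
#' @return viscosity (Pa s), same shape as `gamma_dot`
#' @export
quemada_viscosity <- function(gamma_dot, props = fluid_props()) {
  if (any(!is.finite(gamma_dot))) {
    stop("quemada_viscosity: shear rate must be finite")
  }
  if (any(gamma_dot < 0)) {
    stop("quemada_viscosity: shear rate must be non-negative")
  }
  if (props$newtonian) {
    return(rep_len(props$mu_newtonian, length(gamma_dot)) + 0 * gamma_dot)
  }
  g <- pmax(gamma_dot, props$gamma_min)
  s <- sqrt(g / props$gamma_c)
  k <- (props$k0 + props$kinf * s) / (1 + s)
  props$mu_p * (1 - 0.5 * k * props$H)^-2
}

#' Clot porosity as a function of bound-platelet concentration
#'
#' Linear ramp from 1 (no thrombus) down to `eps_min` (0.75, completely
#' formed clot) reached at the bound-platelet threshold `BP_t`:
#' `eps = 1 - (1 - eps_min) * min(BP/BP_t, 1)`.
#'
#' @param BP bound-platelet concentration (nmol/l), vectorized
#' @param params a [thrombosis_params()] object
#' @return porosity in `[eps_min, 1]`
#' @export
clot_porosity <- function(BP, params = thrombosis_params()) {
  if (any(!is.finite(BP)) || any(BP < 0)) {
    stop("clot_porosity: BP must be finite and non-negative")
  }
  1 - (1 - params$eps_min) * pmin(BP / params$BP_t, 1)
}

#' Saturation (switching) functions
#'
#' Bounded sigmoids used to gate reaction terms on thresholds of bound
#' platelets, coagulant or cycle-averaged shear rate:
#' `switch_up(x) = x^n / (x^n + x_t^n)` rises from 0 to 1 and equals 1/2 at
#' the threshold; `switch_down = 1 - switch_up`.
#'
#' @param x non-negative input, vectorized
#' @param x_t positive threshold scale
#' @param n exponent (>= 1); larger values sharpen the gate
#' @return weight in `[0, 1]`
#' @export
switch_up <- function(x, x_t, n = 2) {
  if (!is.finite(x_t) || x_t <= 0) {
    stop("switch_up: threshold x_t must be positive")
  }
  stopifnot(n >= 1)
  r <- (pmax(x, 0) / x_t)^n
  r / (r + 1)
}

#' @rdname switch_up
#' @export
switch_down <- function(x, x_t, n = 2) {
  1 - switch_up(x, x_t, n)
}

#' Porous-clot momentum sink
#'
#' Brinkman-type resistance opposing flow through a forming clot:
#' `S_M = -k_M * phi_BP(BP) * u`, with `phi_BP = switch_up(BP, BP_t)`.
#' Zero in clot-free blood, saturating at `-k_M * u` in a fully formed
#' thrombus.
#'
#' @param BP bound-platelet concentration (nmol/l)
#' @param u velocity component (m/s); the sink acts on each component
#'   independently
#' @param params a [thrombosis_params()] object
#' @return force density (kg/m^2/s^2), same sign convention as `-u`
#' @export
momentum_sink <- function(BP, u, params = thrombosis_params()) {
  if (any(!is.finite(BP)) || any(BP < 0)) {
    stop("momentum_sink: BP must be finite and non-negative")
  }
  -params$k_M * switch_up(BP, params$BP_t, params$n_sw) * u
}

#' Coagulant wall flux
#'
#' Flux of coagulant released at a wall face, per unit wall length in 2D.
#' The flux takes the constant value `k_c_wall` (20 nmol/m/l/s) wherever
#' the previous-cycle TAWSS is below the growth threshold (0.2 Pa), and is
#' identically zero on faces at or above the threshold or once complete
#' thrombosis is reached locally (`BP > BP_complete`, 200 nmol/l).
#'
#' @param TAWSS previous-cycle time-averaged wall shear stress (Pa)
#' @param BP_wall bound-platelet concentration in the wall-adjacent cell
#'   (nmol/l)
#' @param params a [thrombosis_params()] object
#' @return flux (nmol/m/l/s), vectorized
#' @export
coagulant_wall_flux <- function(TAWSS, BP_wall, params = thrombosis_params()) {
  if (any(!is.finite(TAWSS)) || any(TAWSS < 0)) {
    stop("coagulant_wall_flux: TAWSS must be finite and non-negative")
  }
  if (any(!is.finite(BP_wall)) || any(BP_wall < 0)) {
    stop("coagulant_wall_flux: BP_wall must be finite and non-negative")
  }
  params$k_c_wall * as.numeric(TAWSS < params$tau_w_t) *
    as.numeric(BP_wall <= params$BP_complete)
}

#' Coagulant bulk source
#'
#' Net volumetric production/consumption of coagulant:
#' production `k_c * phi_BP * switch_down(gamma_avg)` inside forming
#' thrombus at low cycle-averaged shear, and consumption
#' `k_c * (C/C_t) * switch_up(gamma_avg)` that prevents coagulant from
#' accumulating in regions of high shear.
#'
#' @param C coagulant concentration (nmol/l)
#' @param BP bound-platelet concentration (nmol/l)
#' @param gamma_avg cycle-averaged shear rate (1/s)
#' @param params a [thrombosis_params()] object
#' @return net rate (nmol/l/s), vectorized
#' @export
coagulant_bulk_source <- function(C, BP, gamma_avg,
                                  params = thrombosis_params()) {
  if (any(C < 0) || any(BP < 0) || any(gamma_avg < 0)) {
    stop("coagulant_bulk_source: inputs must be non-negative")
  }
  n <- params$n_sw
  params$k_c * switch_up(BP, params$BP_t, n) *
    switch_down(gamma_avg, params$gamma_t, n) -
    params$k_c * (C / params$C_t) * switch_up(gamma_avg, params$gamma_t, n)
}

#' Bound-platelet formation rate
#'
#' Rate of platelet binding into thrombus:
#' `k_BP * AP_rel * switch_up(C, C_t) * switch_down(gamma_avg, gamma_t)`.
#' `AP_rel` here is the activated-platelet concentration normalized by its
#' inlet value, so the rate is linearly proportional to local activated
#' platelet levels and saturates at `k_BP` where coagulant is abundant and
#' the averaged shear rate is low.
#'
#' @param AP_rel activated platelets relative to the inlet level
#'   (dimensionless; 1 at the inlet)
#' @param C coagulant concentration (nmol/l)
#' @param gamma_avg cycle-averaged shear rate (1/s)
#' @param params a [thrombosis_params()] object
#' @return rate (nmol/l/s), vectorized
#' @export
bound_platelet_source <- function(AP_rel, C, gamma_avg,
                                  params = thrombosis_params()) {
  if (any(AP_rel < 0) || any(C < 0) || any(gamma_avg < 0)) {
    stop("bound_platelet_source: inputs must be non-negative")
  }
  n <- params$n_sw
  params$k_BP * AP_rel * switch_up(C, params$C_t, n) *
    switch_down(gamma_avg, params$gamma_t, n)
}
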