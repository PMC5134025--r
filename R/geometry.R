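#' @useDynLib thromboflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal constructor: assemble a case_grid from a mask and boundary tags.
# mask: nx x ny integer matrix, 1 = fluid, 0 = solid.
# inlet_j / outlet_j: row indices (j) of left/right domain boundary faces
# tagged as inlet/outlet; all other boundary faces of fluid cells are walls.
new_case_grid <- function(mask, dx, dy, inlet_j, outlet_j,
                          regions = list(), meta = list(),
                          check_reachable = TRUE) {
  nx <- nrow(mask); ny <- ncol(mask)
  stopifnot(nx >= 2, ny >= 2, dx > 0, dy > 0)
  storage.mode(mask) <- "integer"
  inlet_j <- as.integer(inlet_j[mask[1, inlet_j] == 1L])
  outlet_j <- as.integer(outlet_j[mask[nx, outlet_j] == 1L])
  g <- structure(list(
    nx = nx, ny = ny, dx = dx, dy = dy,
    Lx = nx * dx, Ly = ny * dy,
    x = (seq_len(nx) - 0.5) * dx,
    y = (seq_len(ny) - 0.5) * dy,
    mask = mask,
    inlet_j = inlet_j, outlet_j = outlet_j,
    regions = regions, meta = meta,
    # per-grid scratch environment: holds the cached pressure-solver
    # factorization (reference semantics survive list copies)
    cache = new.env(parent = emptyenv())
  ), class = "case_grid")
  g$wall_faces <- find_wall_faces(g)
  if (check_reachable && length(inlet_j) > 0) {
    reach <- flood_fill(mask, cbind(1L, inlet_j))
    if (any(mask == 1L & !reach)) {
      stop("case_grid: some fluid cells are unreachable from the inlet")
    }
  }
  for (rn in names(regions)) {
    if (any(regions[[rn]] & mask != 1L)) {
      stop("case_grid: region '", rn, "' includes solid cells")
    }
  }
  g
}

# Breadth-first flood fill over fluid-cell 4-adjacency.
flood_fill <- function(mask, seeds) {
  nx <- nrow(mask); ny <- ncol(mask)
  reach <- matrix(FALSE, nx, ny)
  queue <- seeds[mask[seeds] == 1L, , drop = FALSE]
  reach[queue] <- TRUE
  while (nrow(queue) > 0) {
    nxt <- rbind(cbind(queue[, 1] + 1L, queue[, 2]),
                 cbind(queue[, 1] - 1L, queue[, 2]),
                 cbind(queue[, 1], queue[, 2] + 1L),
                 cbind(queue[, 1], queue[, 2] - 1L))
    ok <- nxt[, 1] >= 1L & nxt[, 1] <= nx & nxt[, 2] >= 1L & nxt[, 2] <= ny
    nxt <- nxt[ok, , drop = FALSE]
    nxt <- nxt[mask[nxt] == 1L & !reach[nxt], , drop = FALSE]
    if (nrow(nxt) == 0) break
    nxt <- nxt[!duplicated(nxt), , drop = FALSE]
    reach[nxt] <- TRUE
    queue <- nxt
  }
  reach
}

# Enumerate wall faces: faces of fluid cells adjacent to a solid cell or to
# an untagged domain boundary. side: 1 west, 2 east, 3 south, 4 north.
find_wall_faces <- function(g) {
  mask <- g$mask; nx <- g$nx; ny <- g$ny
  res <- list()
  fl <- which(mask == 1L, arr.ind = TRUE)
  i <- fl[, 1]; j <- fl[, 2]
  west <- (i == 1L & !(j %in% g$inlet_j)) |
    (i > 1L & mask[cbind(pmax(i - 1L, 1L), j)] == 0L)
  east <- (i == nx & !(j %in% g$outlet_j)) |
    (i < nx & mask[cbind(pmin(i + 1L, nx), j)] == 0L)
  south <- (j == 1L) | (j > 1L & mask[cbind(i, pmax(j - 1L, 1L))] == 0L)
  north <- (j == ny) | (j < ny & mask[cbind(i, pmin(j + 1L, ny))] == 0L)
  mk <- function(sel, side) {
    if (!any(sel)) return(NULL)
    ii <- i[sel]; jj <- j[sel]
    fx <- switch(side, (ii - 1L) * g$dx, ii * g$dx,
                 (ii - 0.5) * g$dx, (ii - 0.5) * g$dx)
    fy <- switch(side, (jj - 0.5) * g$dy, (jj - 0.5) * g$dy,
                 (jj - 1L) * g$dy, jj * g$dy)
    data.frame(i = ii, j = jj, side = side, x = fx, y = fy,
               len = if (side <= 2) g$dy else g$dx)
  }
  out <- rbind(mk(west, 1L), mk(east, 2L), mk(south, 3L), mk(north, 4L))
  rownames(out) <- NULL
  out
}

#' Build a rectangular channel grid
#'
#' Straight 2D channel: fluid everywhere, no-slip top and bottom walls,
#' inlet on the left boundary and outlet on the right.  With
#' `closed = TRUE` all four boundaries are walls (a stagnant box used by
#' the transport benchmarks).
#'
#' @param length,height channel dimensions (m)
#' @param nx,ny number of cells in x and y (each >= 4)
#' @param closed if `TRUE`, build a closed box with no inlet or outlet
#' @return a `case_grid` object
#' @export
build_channel <- function(length, height, nx, ny, closed = FALSE) {
  if (length <= 0 || height <= 0) stop("build_channel: dimensions must be positive")
  if (nx < 4 || ny < 4) stop("build_channel: need nx, ny >= 4")
  mask <- matrix(1L, nx, ny)
  jall <- seq_len(ny)
  new_case_grid(mask, length / nx, height / ny,
                inlet_j = if (closed) integer() else jall,
                outlet_j = if (closed) integer() else jall,
                regions = list(),
                meta = list(kind = if (closed) "box" else "channel",
                            height = height, length = length))
}

#' Build a backward-facing step grid
#'
#' L-shaped domain: an inlet channel of height `inlet_height` expands over
#' a step of height `step_height` into a channel of height
#' `inlet_height + step_height`.  The region `step_recirculation` tags the
#' rectangle extending 8 step heights downstream of the step below the
#' step lip, where the laminar separation bubble sits.
#'
#' @param inlet_height inlet channel height (m)
#' @param step_height step height (m)
#' @param upstream_len length of the inlet channel upstream of the step (m)
#' @param downstream_len length downstream of the step (m); must be at
#'   least 10 step heights so the recirculation bubble closes inside the
#'   domain
#' @param resolution target cell size (m)
#' @return a `case_grid` object; `meta$expansion_ratio` records
#'   `(inlet_height + step_height) / inlet_height`
#' @export
build_backward_facing_step <- function(inlet_height, step_height,
                                       upstream_len, downstream_len,
                                       resolution) {
  if (step_height <= 0 || inlet_height <= 0) {
    stop("build_backward_facing_step: heights must be positive")
  }
  if (downstream_len < 10 * step_height) {
    stop("build_backward_facing_step: downstream length must be >= 10 step heights")
  }
  H <- inlet_height + step_height
  L <- upstream_len + downstream_len
  nx <- max(8L, round(L / resolution))
  ny <- max(6L, round(H / resolution))
  dx <- L / nx; dy <- H / ny
  mask <- matrix(1L, nx, ny)
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  solid <- outer(xc < upstream_len, yc < step_height, "&")
  mask[solid] <- 0L
  inlet_j <- which(yc >= step_height)
  recirc <- outer(xc >= upstream_len & xc < upstream_len + 8 * step_height,
                  yc < step_height, "&")
  new_case_grid(mask, dx, dy, inlet_j = inlet_j, outlet_j = seq_len(ny),
                regions = list(step_recirculation = recirc & mask == 1L),
                meta = list(kind = "backward_facing_step",
                            inlet_height = inlet_height,
                            step_height = step_height,
                            upstream_len = upstream_len,
                            downstream_len = downstream_len,
                            expansion_ratio = H / inlet_height))
}

#' Build an idealized 2D dissection grid
#'
#' Two parallel channels separated by a solid flap: the true lumen (TL,
#' bottom) is open at both ends (inlet left, outlet right); the false
#' lumen (FL, top) is closed at both ends and communicates with the TL
#' only through one or two tears piercing the flap.  One proximal tear
#' emulates the early-stage dissection topology; adding a second, middle
#' tear emulates the later-stage topology.
#'
#' @param lumen_height TL channel height (m)
#' @param fl_height FL channel height (m)
#' @param flap_thickness thickness of the solid flap (m); resolved by at
#'   least two cell layers
#' @param tear_positions numeric vector (length 1 or 2) of tear center
#'   x-positions (m), strictly inside the flap span
#' @param tear_widths tear widths (m), recycled to match `tear_positions`
#' @param length domain length (m)
#' @param resolution target cell size (m)
#' @return a `case_grid` with regions `true_lumen`, `false_lumen` and
#'   `tear_1` (and `tear_2` for a two-tear case)
#' @export
build_idealized_dissection <- function(lumen_height = 0.010,
                                       fl_height = 0.004,
                                       flap_thickness = 0.002,
                                       tear_positions = 0.012,
                                       tear_widths = 0.006,
                                       length = 0.08,
                                       resolution = 5e-4) {
  nt <- length(tear_positions)
  if (nt < 1 || nt > 2) stop("build_idealized_dissection: need 1 or 2 tears")
  tear_widths <- rep_len(tear_widths, nt)
  lo <- tear_positions - tear_widths / 2
  hi <- tear_positions + tear_widths / 2
  if (any(lo <= 0) || any(hi >= length)) {
    stop("build_idealized_dissection: tears must lie strictly inside the flap span")
  }
  if (nt == 2) {
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    if (hi[1] >= lo[2]) stop("build_idealized_dissection: tears overlap")
  }
  H <- lumen_height + flap_thickness + fl_height
  nx <- max(8L, round(length / resolution))
  ny <- max(8L, round(H / resolution))
  dx <- length / nx; dy <- H / ny
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  tl_band <- yc < lumen_height
  flap_band <- yc >= lumen_height & yc < lumen_height + flap_thickness
  if (sum(flap_band) < 2) {
    stop("build_idealized_dissection: resolution too coarse to resolve the flap")
  }
  fl_band <- yc >= lumen_height + flap_thickness
  mask <- matrix(1L, nx, ny)
  mask[, flap_band] <- 0L
  tears <- vector("list", nt)
  for (k in seq_len(nt)) {
    in_tear <- xc >= lo[k] & xc < hi[k]
    mask[in_tear, flap_band] <- 1L
    tears[[k]] <- outer(in_tear, flap_band, "&")
  }
  regions <- list(true_lumen = outer(rep(TRUE, nx), tl_band, "&"),
                  false_lumen = outer(rep(TRUE, nx), fl_band, "&"))
  for (k in seq_len(nt)) regions[[paste0("tear_", k)]] <- tears[[k]]
  inlet_j <- which(tl_band)
  new_case_grid(mask, dx, dy, inlet_j = inlet_j, outlet_j = which(tl_band),
                regions = regions,
                meta = list(kind = "idealized_dissection",
                            lumen_height = lumen_height,
                            fl_height = fl_height,
                            flap_thickness = flap_thickness,
                            tear_positions = tear_positions,
                            tear_widths = tear_widths,
                            length = length))
}

#' Pulsatile inlet waveform parameters
#'
#' Parameterized analytic cardiac pulse: a systolic half-sine of duration
#' `systolic_frac * T` peaking at `peak_mult` times the cycle-mean flow
#' rate, a small retrograde lobe in early diastole of relative amplitude
#' `retro_frac * peak_mult`, and a constant diastolic baseline solved so
#' the waveform integrates exactly to `Q_mean * T` over one period.  With
#' `peak_mult = 1` and `retro_frac = 0` the waveform is steady.
#'
#' @param T cardiac period (s)
#' @param Q_mean cycle-mean flow rate (m^2/s in 2D: flow per unit depth)
#' @param peak_mult peak systolic flow as a multiple of `Q_mean`
#' @param systolic_frac systolic duration as a fraction of the period
#' @param retro_frac retrograde lobe amplitude as a fraction of the peak
#' @return an object of class `waveform_params`; `$Q_dia` holds the solved
#'   diastolic baseline
#' @export
waveform_params <- function(T = 1.054, Q_mean = 1.5e-3, peak_mult = 3,
                            systolic_frac = 1 / 3, retro_frac = 0.2) {
  stopifnot(T > 0, Q_mean > 0, peak_mult >= 1,
            systolic_frac > 0, systolic_frac < 0.8,
            retro_frac >= 0, retro_frac < 1)
  t_s <- systolic_frac * T
  t_w <- 0.2 * T
  A_r <- retro_frac * peak_mult * Q_mean
  # Q(t) = Q_dia + A sin(pi t/t_s) in systole, Q_dia - A_r sin(...) in the
  # retrograde lobe, Q_dia elsewhere; A = peak_mult*Q_mean - Q_dia.
  # Cycle mean Q_mean fixes Q_dia.
  c1 <- (2 / pi) * (t_s / T)
  c2 <- (2 / pi) * (t_w / T)
  Q_dia <- (Q_mean - c1 * peak_mult * Q_mean + c2 * A_r) / (1 - c1)
  structure(list(T = T, Q_mean = Q_mean, peak_mult = peak_mult,
                 systolic_frac = systolic_frac, retro_frac = retro_frac,
                 t_s = t_s, t_w = t_w, A = peak_mult * Q_mean - Q_dia,
                 A_r = A_r, Q_dia = Q_dia),
            class = "waveform_params")
}

#' Inlet flow rate at time t
#'
#' Periodic analytic pulse defined by [waveform_params()].  The inlet
#' velocity profile applied by the solver is flat (plug flow), so the
#' inlet velocity is `inflow_rate(t, w) / inlet_height`.
#'
#' @param t time (s), vectorized
#' @param w a [waveform_params()] object
#' @return flow rate (m^2/s), same shape as `t`
#' @export
inflow_rate <- function(t, w) {
  tm <- t %% w$T
  q <- rep_len(w$Q_dia, length(tm))
  sys <- tm < w$t_s
  q[sys] <- w$Q_dia + w$A * sin(pi * tm[sys] / w$t_s)
  retro <- !sys & tm < w$t_s + w$t_w
  q[retro] <- w$Q_dia - w$A_r * sin(pi * (tm[retro] - w$t_s) / w$t_w)
  q
}

#' Womersley number
#'
#' `alpha = half_height * sqrt(2*pi / (T * nu))`, the ratio of the channel
#' half-height to the oscillatory Stokes-layer thickness.
#'
#' @param half_height channel half-height (m)
#' @param T oscillation period (s)
#' @param nu kinematic viscosity (m^2/s)
#' @return Womersley number (dimensionless)
#' @export
womersley_number <- function(half_height, T, nu) {
  stopifnot(half_height > 0, T > 0, nu > 0)
  half_height * sqrt(2 * pi / (T * nu))
}
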