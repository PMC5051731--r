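#' Closed-form mean microtubule length under dynamic instability
#'
#' In the bounded regime (`v_s f_cat > v_g f_res`) the steady-state length
#' distribution of the four-parameter dynamic-instability model is
#' exponential with mean
#' \deqn{\langle L \rangle = \frac{v_g v_s}{v_s f_{cat} - v_g f_{res}}}
#'
#' @param v_g,v_s Growth and shrinkage speeds (um/s).
#' @param f_cat,f_res Catastrophe and rescue frequencies (1/s).
#' @return Mean length (um).
#' @examples
#' mt_mean_length(0.178, 0.205, 0.075, 0.023)  # ~3.23 um
#' @export
mt_mean_length <- function(v_g, v_s, f_cat, f_res) {
  denom <- v_s * f_cat - v_g * f_res
  if (denom <= 0) {
    abort("unbounded growth regime: v_s * f_cat must exceed v_g * f_res",
          class = "asterdrift_invalid_params")
  }
  (v_g * v_s) / denom
}

#' Single-filament dynamic-instability simulation
#'
#' Simulates one filament switching stochastically between growth and
#' shrinkage; catastrophes occur with per-step probability
#' `1 - exp(-f_cat dt)` and rescues with `1 - exp(-f_res dt)`. A filament
#' hitting zero length immediately re-enters growth (the nucleation site
#' persists).
#'
#' @inheritParams mt_mean_length
#' @param total_time,dt Duration and step (s).
#' @param init_len Initial length (um).
#' @param seed Optional integer seed.
#' @return A tibble with `t_s` and `length_um`.
#' @export
simulate_filament_length <- function(v_g, v_s, f_cat, f_res,
                                     total_time = 1e4, dt = 0.1,
                                     init_len = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- di_simulate_cpp(v_g, v_s, f_cat, f_res, total_time, dt, init_len)
  tibble::tibble(t_s = seq(0, total_time, by = dt), length_um = len)
}

#' Piecewise-linear motor force-velocity relation
#'
#' Minus-end-directed motors (dynein-like) step at full speed under zero or
#' assisting load, slow linearly under opposing load, and stall at `f_0`.
#'
#' @param f_parallel Load component opposing motion (pN); negative values
#'   (assisting) give full speed.
#' @param f_0 Stall force (pN), positive.
#' @param v_m Unloaded speed (um/s).
#' @return Speed (um/s).
#' @export
motor_load_velocity <- function(f_parallel, f_0, v_m = 2) {
  if (any(f_0 <= 0)) abort("`f_0` must be positive", class = "asterdrift_invalid_params")
  v <- v_m * (1 - pmax(f_parallel, 0) / f_0)
  pmax(v, 0)
}

#' Force-dependent (Kramers) motor detachment rate
#'
#' `r_detach = r'_detach * exp(|f_ex| / f_0)`: the unbinding rate grows
#' exponentially with the spring extension force.
#'
#' @param f_ex Extension force (pN).
#' @param f_0 Stall force (pN).
#' @param r_detach_basal Basal (zero-force) detachment rate (1/s).
#' @return Detachment rate (1/s).
#' @export
motor_detach_rate <- function(f_ex, f_0, r_detach_basal = 1.5) {
  r_detach_basal * exp(abs(f_ex) / f_0)
}

#' Area density of motors in the cell
#'
#' @param n Motors per cell.
#' @param r_cell Cell radius (um).
#' @return Density (motors/um^2).
#' @export
motor_density <- function(n, r_cell = 40) {
  n / (pi * r_cell^2)
}

#' Sample immobilized-motor anchor positions from an attractive gradient
#'
#' Rejection sampling over the cell disk with acceptance proportional to the
#' attractive field evaluated at the distance from the chromatin edge (so
#' motors concentrate around the chromatin, falling off with the sigmoid).
#'
#' @param n Number of anchors.
#' @param field An attractive [drift_field()].
#' @param r_cell,r_chr Geometry (um).
#' @param seed Optional integer seed.
#' @return A tibble with `x_um`, `y_um`.
#' @export
sample_motor_gradient <- function(n, field, r_cell = 40, r_chr = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out_x <- numeric(n); out_y <- numeric(n)
  i <- 0L
  while (i < n) {
    m <- max(2L * (n - i), 16L)
    rr <- r_cell * sqrt(runif(m))
    th <- runif(m, 0, 2 * pi)
    acc <- runif(m) < field_weight(field, pmax(0, rr - r_chr))
    keep <- which(acc)
    if (length(keep)) {
      take <- head(keep, n - i)
      out_x[i + seq_along(take)] <- (rr * cos(th))[take]
      out_y[i + seq_along(take)] <- (rr * sin(th))[take]
      i <- i + length(take)
    }
  }
  tibble::tibble(x_um = out_x, y_um = out_y)
}

#' Dynamic-instability parameters mapped through a stabilization gradient
#'
#' At distance `r` from the chromatin edge the catastrophe and rescue
#' frequencies interpolate between the stabilized values (near chromatin,
#' where the attractive weight approaches 1) and the cytoplasmic values
#' (far away): `f(r) = phi_a(r) f_stab + (1 - phi_a(r)) f_cyto`.
#'
#' @param r Distance from the chromatin edge (um).
#' @param field An attractive [drift_field()].
#' @param di_cyto,di_stab Named lists with `f_cat`, `f_res` (1/s).
#' @return A tibble with `r`, `f_cat`, `f_res`.
#' @export
map_di_gradient <- function(r, field,
                            di_cyto = list(f_cat = 0.075, f_res = 0.023),
                            di_stab = list(f_cat = 0.0397, f_res = 0.0122)) {
  phi <- field_weight(field, r)
  tibble::tibble(r = r,
                 f_cat = phi * di_stab$f_cat + (1 - phi) * di_cyto$f_cat,
                 f_res = phi * di_stab$f_res + (1 - phi) * di_cyto$f_res)
}

#' Discrete bending forces on a filament polyline
#'
#' Forces from the discretized worm-like-chain bending energy
#' `E = kappa/(2 L^3) sum_i |x_{i-1} - 2 x_i + x_{i+1}|^2` with segment
#' length `L`. Collinear vertices give exactly zero force.
#'
#' @param vx,vy Vertex coordinates (um).
#' @param kappa Bending modulus (pN um^2).
#' @param seg Segment length (um).
#' @return A matrix (n x 2) of forces (pN); rows sum to zero.
#' @export
bending_forces <- function(vx, vy, kappa = 20, seg = 0.5) {
  n <- length(vx)
  f <- matrix(0, n, 2)
  if (n < 3) return(f)
  k <- kappa / seg^3
  for (i in 2:(n - 1)) {
    bx <- vx[i - 1] - 2 * vx[i] + vx[i + 1]
    by <- vy[i - 1] - 2 * vy[i] + vy[i + 1]
    f[i - 1, ] <- f[i - 1, ] - k * c(bx, by)
    f[i, ] <- f[i, ] + 2 * k * c(bx, by)
    f[i + 1, ] <- f[i + 1, ] - k * c(bx, by)
  }
  f
}

#' Cortical confinement forces on a filament polyline
#'
#' Vertices outside the cell radius receive an inward harmonic restoring
#' force; the summed force per filament is capped at the Euler buckling load
#' `pi^2 kappa / (4 L^2)`, the maximum force a growing filament of length
#' `L` clamped at the aster can exert before buckling.
#'
#' @inheritParams bending_forces
#' @param r_cell Cell radius (um).
#' @param k_conf Confinement stiffness (pN/um).
#' @param len Filament contour length (um), used for the buckling cap.
#' @return A matrix (n x 2) of forces (pN).
#' @export
cortical_forces <- function(vx, vy, r_cell = 40, kappa = 20, k_conf = 10,
                            len = NULL) {
  n <- length(vx)
  f <- matrix(0, n, 2)
  r <- sqrt(vx^2 + vy^2)
  out <- which(r > r_cell)
  for (i in out) {
    f[i, ] <- -k_conf * (r[i] - r_cell) * c(vx[i], vy[i]) / r[i]
  }
  if (length(out)) {
    len <- len %||% (0.5 * (n - 1))
    f_euler <- pi^2 * kappa / (4 * max(len, 0.5)^2)
    tot <- sqrt(sum(colSums(f)^2))
    if (tot > f_euler) f <- f * f_euler / tot
  }
  f
}

#' Spring force pair exerted by a doubly bound cross-linking complex
#'
#' The two heads of a bound complex are connected by a zero-rest-length
#' Hookean spring of stiffness `k_mot`; the force pulls the two attachment
#' points together and is applied equal-and-opposite to the two filaments.
#'
#' @param p1,p2 Head positions (length-2, um).
#' @param k_mot Spring stiffness (pN/nm).
#' @return A list with `f1` and `f2` (pN, length-2); `f1 + f2 = 0`.
#' @export
clustering_force <- function(p1, p2, k_mot = 0.1) {
  k <- k_mot * 1e3  # pN/nm -> pN/um
  f1 <- k * (p2 - p1)
  list(f1 = f1, f2 = -f1)
}

#' Configuration for the microtubule-motor aster engine
#'
#' Bundles geometry, mechanics, dynamic-instability, motor and scenario
#' settings with literature defaults (dynein-like motors; centrosomal-MT
#' polymerization parameters giving a 3.2 um mean length). Five scenarios
#' are available: `"no_gradient"` (uniform immobilized motors), `"clustering"`
#' (diffusible cross-linking complexes only), `"di_gradient"` (uniform
#' motors, stabilization gradient of f_cat/f_res), `"motor_gradient"`
#' (immobilized motors placed in the chromatin-centred attractive gradient),
#' and `"hybrid"` (motor gradient plus clustering complexes). Cortical
#' confinement acts in every scenario.
#'
#' The `preset` argument switches between the full study scale (80 MTOCs,
#' 1200 s) and a reduced `"smoke"` scale (10 MTOCs, 20 MTs each, 120 s) used
#' for fast property checks.
#'
#' @param scenario One of the five scenario names.
#' @param preset `"full"` or `"smoke"`.
#' @param n_mtoc MTOCs per cell.
#' @param n_mt Microtubules per MTOC (20-120).
#' @param f_0 Motor stall force (pN); 2 and 7 are the literature extremes.
#' @param n_mi Immobilized motors per cell.
#' @param n_mc Diffusible motor complexes per cell.
#' @param total_time,dt Duration and integration step (s).
#' @param r_cell,r_chr Geometry (um).
#' @param eta Cytoplasmic viscosity (Pa s).
#' @param kappa Microtubule bending modulus (N m^2).
#' @param k_B_T Thermal energy (N m).
#' @param v_g,v_s,f_cat,f_res Cytoplasmic dynamic-instability parameters.
#' @param f_cat_stab,f_res_stab Stabilized values used by the gradient.
#' @param k_mot Motor stiffness (pN/nm).
#' @param v_m Motor speed (um/s).
#' @param r_attach Attachment rate (1/s).
#' @param r_detach Basal detachment rate (1/s).
#' @param r_detach_end Detachment rate at a filament end (1/s).
#' @param d_attach Attachment capture distance (um).
#' @param d_c Complex diffusion coefficient (um^2/s).
#' @param attract Attractive [drift_field()] used for gradient mapping.
#' @param record_interval Sampling interval of MTOC centre tracks (s).
#' @return An object of class `aster_config`.
#' @export
aster_config <- function(scenario = c("no_gradient", "clustering", "di_gradient",
                                      "motor_gradient", "hybrid"),
                         preset = c("full", "smoke"),
                         n_mtoc = NULL, n_mt = NULL, f_0 = 7,
                         n_mi = 1000, n_mc = 10000,
                         total_time = NULL, dt = 0.01,
                         r_cell = 40, r_chr = 10,
                         eta = 0.05, kappa = 2e-23, k_B_T = 4.1e-21,
                         v_g = 0.178, v_s = 0.205,
                         f_cat = 0.075, f_res = 0.023,
                         f_cat_stab = 0.0397, f_res_stab = 0.0122,
                         k_mot = 0.1, v_m = 2, r_attach = 12,
                         r_detach = 1.5, r_detach_end = 1,
                         d_attach = 0.02, d_c = 20,
                         attract = drift_field(10, 1),
                         record_interval = 5) {
  scenario <- match.arg(scenario)
  preset <- match.arg(preset)
  if (preset == "smoke") {
    n_mtoc <- n_mtoc %||% 10L
    n_mt <- n_mt %||% 20L
    total_time <- total_time %||% 120
  } else {
    n_mtoc <- n_mtoc %||% 80L
    n_mt <- n_mt %||% 40L
    total_time <- total_time %||% 1200
  }
  structure(list(scenario = scenario, preset = preset,
                 n_mtoc = as.integer(n_mtoc), n_mt = as.integer(n_mt),
                 f_0 = f_0, n_mi = as.integer(n_mi), n_mc = as.integer(n_mc),
                 total_time = total_time, dt = dt,
                 r_cell = r_cell, r_chr = r_chr,
                 eta = eta, kappa = kappa, k_B_T = k_B_T,
                 v_g = v_g, v_s = v_s, f_cat = f_cat, f_res = f_res,
                 f_cat_stab = f_cat_stab, f_res_stab = f_res_stab,
                 k_mot = k_mot, v_m = v_m, r_attach = r_attach,
                 r_detach = r_detach, r_detach_end = r_detach_end,
                 d_attach = d_attach, d_c = d_c, attract = attract,
                 record_interval = record_interval),
            class = "aster_config")
}

#' Run a microtubule-motor scenario
#'
#' Simulates `n_mtoc` aster-nucleating MTOCs with dynamic-instability
#' filaments, immobilized minus-end-directed motors (Kramers force-dependent
#' detachment, piecewise-linear force-velocity) and/or diffusible
#' cross-linking complexes in a rigid circular cell. The chromatin disk is
#' mechanically passive: capture is a measurement (an MTOC centre crossing
#' the chromatin radius), not a dynamical event.
#'
#' @param config An [aster_config()].
#' @param seed Optional integer seed.
#' @param start Optional matrix/data frame of initial MTOC centres (columns
#'   x, y in um), one row per MTOC; defaults to uniform-by-area placement in
#'   the cytoplasmic annulus. Fixed nucleation cohorts (e.g. all MTOCs at a
#'   common nucleation distance) are used for sensitivity analyses.
#' @return An object of class `aster_run`: a list with `tracks` (MTOC-centre
#'   trajectories as an `aster_tracks` tibble), `capture_fraction` (fraction
#'   of MTOCs whose centre entered the chromatin disk), `summary` (per-MTOC
#'   capture/velocity table), `mean_filament_length` (time series, um),
#'   `diagnostics`, and the `config`.
#' @export
run_scenario <- function(config, seed = NULL, start = NULL) {
  stopifnot(inherits(config, "aster_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(start)) {
    start <- as.matrix(start)
    stopifnot(ncol(start) == 2L, nrow(start) == config$n_mtoc)
  }
  use_mi <- config$scenario %in% c("no_gradient", "di_gradient",
                                   "motor_gradient", "hybrid")
  use_mc <- config$scenario %in% c("clustering", "hybrid")
  res <- aster_run_cpp(
    n_mtoc = config$n_mtoc, n_mt = config$n_mt,
    total_time = config$total_time, dt = config$dt,
    r_cell = config$r_cell, r_chr = config$r_chr,
    eta = config$eta,                      # Pa s == pN s / um^2
    kappa = config$kappa * 1e24,           # N m^2 -> pN um^2
    kBT = config$k_B_T * 1e18,             # N m -> pN um
    vg_c = config$v_g, vs_c = config$v_s,
    fcat_c = config$f_cat, fres_c = config$f_res,
    vg_s = config$v_g, vs_s = config$v_s,
    fcat_s = config$f_cat_stab, fres_s = config$f_res_stab,
    di_gradient = config$scenario == "di_gradient",
    n_mi = if (use_mi) config$n_mi else 0L,
    motor_gradient = config$scenario %in% c("motor_gradient", "hybrid"),
    n_mc = if (use_mc) config$n_mc else 0L,
    a_rhalf = config$attract$r_half, a_s = config$attract$s,
    k_mot = config$k_mot, v_m = config$v_m, f0 = config$f_0,
    r_attach = config$r_attach, r_detach0 = config$r_detach,
    r_detach_end = config$r_detach_end,
    d_attach = config$d_attach, D_c = config$d_c,
    record_interval = config$record_interval,
    mtoc_x0 = if (is.null(start)) numeric(0) else as.numeric(start[, 1]),
    mtoc_y0 = if (is.null(start)) numeric(0) else as.numeric(start[, 2]),
    init_len = mt_mean_length(config$v_g, config$v_s,
                              config$f_cat, config$f_res))
  n_rec <- length(res$t)
  tracks <- tibble::tibble(
    track_id = rep(seq_len(config$n_mtoc), each = n_rec),
    t_s = rep(res$t, times = config$n_mtoc),
    x_um = as.numeric(res$x), y_um = as.numeric(res$y))
  tracks <- as_aster_tracks(tracks, config$r_cell, config$r_chr)
  summ <- track_summary(tracks)
  structure(list(
    tracks = tracks,
    capture_fraction = mean(!is.na(summ$t_c)),
    summary = summ,
    mean_filament_length = tibble::tibble(
      t_s = res$t[-1][seq_along(res$mean_filament_length)],
      length_um = res$mean_filament_length),
    diagnostics = list(bound_motors_final = res$bound_motors_final,
                       any_crosslink = res$any_crosslink,
                       max_pair_imbalance = res$max_pair_imbalance),
    config = config), class = "aster_run")
}

#' @export
print.aster_run <- function(x, ...) {
  cat(sprintf(paste0("<aster_run> scenario %s (%s scale): %d MTOCs x %d MTs, ",
                     "T = %g s\n  capture fraction: %.3f\n"),
              x$config$scenario, x$config$preset, x$config$n_mtoc,
              x$config$n_mt, x$config$total_time, x$capture_fraction))
  invisible(x)
}
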