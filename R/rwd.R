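#' Parameters for the random-walk-with-drift (RWD) model
#'
#' Defaults are the reference parameter set for mouse oocyte meiosis I:
#' a 40 um cell with a 10 um central chromatin disk, 100 MTOC particles
#' followed for 8000 s at a 0.1 s step, with effective diffusion coefficient
#' 0.006 um^2/s and effective directed speed 0.008 um/s (both obtained in the
#' source system by msd fits to experimental tracks).
#'
#' @param r_cell Cell radius (um).
#' @param r_chr Chromatin (absorbing) radius (um); the cytoplasmic annulus
#'   has width `r_cell - r_chr`.
#' @param total_time Total simulated time (s).
#' @param dt Integration step (s).
#' @param n_particles Number of MTOC particles.
#' @param d_eff Effective diffusion coefficient (um^2/s).
#' @param v_eff Effective directed speed (um/s).
#' @return An object of class `rwd_params`.
#' @export
rwd_params <- function(r_cell = 40, r_chr = 10, total_time = 8000, dt = 0.1,
                       n_particles = 100, d_eff = 0.006, v_eff = 0.008) {
  num1 <- function(x, nm, strict_pos = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
        (strict_pos && x <= 0)) {
      abort(sprintf("`%s` must be a %s number", nm,
                    if (strict_pos) "positive" else "non-negative"),
            class = "asterdrift_invalid_params")
    }
    x
  }
  num1(r_cell, "r_cell", TRUE); num1(r_chr, "r_chr")
  num1(total_time, "total_time", TRUE); num1(dt, "dt", TRUE)
  num1(d_eff, "d_eff"); num1(v_eff, "v_eff")
  if (r_chr >= r_cell) {
    abort("`r_chr` must be smaller than `r_cell`", class = "asterdrift_invalid_params")
  }
  if (dt >= total_time) {
    abort("`dt` must be smaller than `total_time`",
          class = "asterdrift_invalid_timestep")
  }
  structure(list(r_cell = r_cell, r_chr = r_chr, r_cyto = r_cell - r_chr,
                 total_time = total_time, dt = dt,
                 n_particles = as.integer(n_particles),
                 d_eff = d_eff, v_eff = v_eff),
            class = "rwd_params")
}

#' @export
print.rwd_params <- function(x, ...) {
  cat(sprintf(paste0("<rwd_params> r_cell = %g um (chromatin %g um), ",
                     "T = %g s, dt = %g s, %d particles\n",
                     "  D_eff = %g um^2/s, v_eff = %g um/s\n"),
              x$r_cell, x$r_chr, x$total_time, x$dt, x$n_particles,
              x$d_eff, x$v_eff))
  invisible(x)
}

#' Brownian step speed for a 2D walk
#'
#' The speed assigned to the Brownian component over one step of duration
#' `dt`, `sqrt(4 D_eff / dt)`, so that a step displaces the particle by
#' `sqrt(4 D_eff dt)` and the ensemble obeys the 2D diffusion law
#' `<dr^2> = 4 D dt`.
#'
#' @param d_eff Diffusion coefficient (um^2/s).
#' @param dt Step duration (s), positive.
#' @return Speed (um/s).
#' @export
brownian_speed <- function(d_eff, dt) {
  if (!is.numeric(dt) || any(dt <= 0)) {
    abort("`dt` must be positive", class = "asterdrift_invalid_timestep")
  }
  if (any(d_eff < 0)) abort("`d_eff` must be >= 0", class = "asterdrift_invalid_params")
  sqrt(4 * d_eff / dt)
}

#' One RWD step-state at a position
#'
#' Computes the weights, angles and speed governing a single step at
#' `position`, mirroring the simulator's update rule. The speed is the nested
#' mixture `phi_a v_eff + (1 - phi_a) (phi_r v_eff + (1 - phi_r) v_B)` and
#' the net angle is the circular weighted average (angle of the weighted sum
#' of unit vectors) of the directed angle -- toward the cell centre -- and a
#' fresh uniform Brownian angle, with the same nesting of weights.
#'
#' Mainly useful for inspecting the model; the simulation loop itself runs in
#' compiled code.
#'
#' @param position Numeric length-2, cell-centred coordinates (um).
#' @param params An [rwd_params()].
#' @param attract,repel [drift_field()]s, or `NULL` to disable.
#' @return A one-row tibble with `w_a`, `w_r`, `theta_dr`, `theta_df`,
#'   `theta_net` (radians in `[0, 2pi)`) and `speed` (um/s).
#' @export
step_state <- function(position, params, attract = NULL, repel = NULL) {
  stopifnot(inherits(params, "rwd_params"), length(position) == 2L)
  r <- sqrt(sum(position^2))
  if (r > params$r_cell) {
    abort("position lies outside the cell", class = "asterdrift_domain_error")
  }
  w_a <- if (is.null(attract)) 0 else field_weight(attract, max(0, r - params$r_chr))
  w_r <- if (is.null(repel)) 0 else field_weight(repel, max(0, params$r_cell - r))
  v_b <- brownian_speed(params$d_eff, params$dt)
  speed <- w_a * params$v_eff + (1 - w_a) * (w_r * params$v_eff + (1 - w_r) * v_b)
  theta_dr <- atan2(-position[2], -position[1]) %% (2 * pi)
  theta_df <- runif(1, 0, 2 * pi)
  inner <- c(w_r * cos(theta_dr) + (1 - w_r) * cos(theta_df),
             w_r * sin(theta_dr) + (1 - w_r) * sin(theta_df))
  inner <- inner / max(sqrt(sum(inner^2)), .Machine$double.eps)
  netv <- c(w_a * cos(theta_dr) + (1 - w_a) * inner[1],
            w_a * sin(theta_dr) + (1 - w_a) * inner[2])
  theta_net <- atan2(netv[2], netv[1]) %% (2 * pi)
  tibble::tibble(w_a = w_a, w_r = w_r, theta_dr = theta_dr,
                 theta_df = theta_df, theta_net = theta_net, speed = speed)
}

#' Simulate MTOC particles as a random walk in a drift field
#'
#' Point particles are nucleated uniformly by area in the cytoplasmic annulus
#' and advanced in steps of `params$dt`. At each step the attractive field
#' (centred on the chromatin edge) and the repulsive field (centred on the
#' cell boundary) set position-dependent weights mixing directed centripetal
#' motion at `v_eff` with Brownian motion at `sqrt(4 D_eff / dt)`. A particle
#' whose radial distance drops to the chromatin radius is captured: the
#' crossing sample is recorded and the track ends. The cortex reflects.
#'
#' @param params An [rwd_params()].
#' @param attract,repel [drift_field()]s, or `NULL` to disable either field.
#' @param seed Integer seed; if supplied, `set.seed(seed)` is called so the
#'   output is bit-reproducible.
#' @param record_interval Interval (s) between recorded samples (the capture
#'   sample is always recorded). Defaults to 5 s to keep outputs compact;
#'   set to `params$dt` for every step.
#' @param boundary `"standard"` (reflecting cortex, absorbing chromatin) or
#'   `"none"` for a free, unbounded walk (used for timestep validation and
#'   estimator self-consistency checks).
#' @param start Optional matrix/data frame of initial positions (columns x, y
#'   in um), one row per particle; otherwise drawn uniformly in the annulus.
#' @return A tibble of class `aster_tracks` with columns `track_id`, `t_s`,
#'   `x_um`, `y_um`, carrying `r_cell` and `r_chr` as attributes.
#' @examples
#' p <- rwd_params(n_particles = 5, total_time = 500)
#' trk <- simulate_rwd(p, attract = drift_field(10, 1), seed = 1)
#' track_summary(trk)
#' @export
simulate_rwd <- function(params, attract = NULL, repel = NULL, seed = NULL,
                         record_interval = 5,
                         boundary = c("standard", "none"), start = NULL) {
  stopifnot(inherits(params, "rwd_params"))
  boundary <- match.arg(boundary)
  if (!is.null(attract)) stopifnot(inherits(attract, "drift_field"))
  if (!is.null(repel)) stopifnot(inherits(repel, "drift_field"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(start)) {
    start <- as.matrix(start)
    stopifnot(ncol(start) == 2L, nrow(start) == params$n_particles)
    x0 <- as.numeric(start[, 1]); y0 <- as.numeric(start[, 2])
    r0 <- sqrt(x0^2 + y0^2)
    if (boundary == "standard" &&
        any(r0 > params$r_cell | r0 <= params$r_chr)) {
      abort("start positions must lie in the cytoplasmic annulus",
            class = "asterdrift_domain_error")
    }
  } else {
    x0 <- numeric(0); y0 <- numeric(0)
  }
  res <- rwd_simulate_cpp(
    n_p = params$n_particles, total_time = params$total_time, dt = params$dt,
    r_cell = params$r_cell, r_chr = params$r_chr,
    d_eff = params$d_eff, v_eff = params$v_eff,
    a_on = !is.null(attract),
    a_rhalf = if (is.null(attract)) 0 else attract$r_half,
    a_s = if (is.null(attract)) 1 else attract$s,
    r_on = !is.null(repel),
    r_rhalf = if (is.null(repel)) 0 else repel$r_half,
    r_s = if (is.null(repel)) 1 else repel$s,
    record_interval = record_interval, open_domain = boundary == "none",
    x_start = x0, y_start = y0)
  out <- tibble::tibble(track_id = res$track_id, t_s = res$t_s,
                        x_um = res$x_um, y_um = res$y_um)
  as_aster_tracks(out, r_cell = params$r_cell, r_chr = params$r_chr)
}

#' @rdname simulate_rwd
#' @param x A data frame with columns `track_id`, `t_s`, `x_um`, `y_um`.
#' @param r_cell,r_chr Geometry (um) attached as attributes.
#' @export
as_aster_tracks <- function(x, r_cell = 40, r_chr = 10) {
  need <- c("track_id", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("missing trajectory columns: ", paste(miss, collapse = ", ")),
          class = "asterdrift_parse_error")
  }
  out <- tibble::as_tibble(x)
  attr(out, "r_cell") <- r_cell
  attr(out, "r_chr") <- r_chr
  class(out) <- c("aster_tracks", class(tibble::tibble()))
  out
}

#' Validate an integration timestep against the free-diffusion law
#'
#' Simulates an unbounded 2D random walk with diffusion coefficient `d` at
#' step `dt`, fits the ensemble msd to `4 D lag` (a straight line through the
#' origin), and reports the relative error of the fitted coefficient. Used to
#' choose a numerically safe `dt`.
#'
#' @param dt Step duration (s).
#' @param d Diffusion coefficient (um^2/s).
#' @param n_particles Ensemble size (>= 2).
#' @param total_time Simulated duration (s).
#' @param seed Optional integer seed.
#' @return Relative error `|D_fit - d| / d` (0 when `d = 0`).
#' @export
validate_timestep <- function(dt, d, n_particles = 100, total_time = 8000,
                              seed = NULL) {
  if (n_particles < 2) {
    abort("need at least 2 particles", class = "asterdrift_insufficient_sample")
  }
  p <- rwd_params(total_time = total_time, dt = dt, n_particles = n_particles,
                  d_eff = d, v_eff = 0)
  trk <- simulate_rwd(p, seed = seed, boundary = "none",
                      record_interval = max(dt, total_time / 400))
  if (d == 0) return(0)
  curve <- ensemble_msd(trk)
  d_fit <- coef(lm(msd_um2 ~ 0 + lag_s, data = curve,
                   weights = curve$n_pairs))[[1]] / 4
  abs(d_fit - d) / d
}
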