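#' Modified weighted root-mean-square error between simulation and reference
#'
#' The error for one compared variable is
#' \deqn{\epsilon = \sqrt{\frac{1}{n}\sum_i w_i (e_i - s_i)^2}}
#' where the weight of point `i` is `n_i / n_max` when the simulated value
#' lies within one standard deviation of the reference mean, and the penalty
#' `w_m` (default 2) otherwise. Points backed by fewer reference
#' observations thus contribute less when the simulation already agrees,
#' while disagreement anywhere is penalized uniformly and strongly
#' (`n_i/n_max <= 1 < w_m`).
#'
#' @param sim_values Simulated values, one per compared point.
#' @param exp_means,exp_sds,exp_counts Reference means, standard deviations
#'   and observation counts, same length as `sim_values`.
#' @param w_m Penalty weight for out-of-band points.
#' @return A list with `epsilon` and the per-point `weights`.
#' @export
weighted_error <- function(sim_values, exp_means, exp_sds, exp_counts, w_m = 2) {
  n <- length(sim_values)
  if (n < 1 || length(exp_means) != n || length(exp_sds) != n ||
      length(exp_counts) != n) {
    abort("inputs must be equal-length vectors with n >= 1",
          class = "asterdrift_invalid_params")
  }
  n_max <- max(exp_counts)
  inside <- sim_values >= exp_means - exp_sds & sim_values <= exp_means + exp_sds
  weights <- ifelse(inside, exp_counts / n_max, w_m)
  list(epsilon = sqrt(mean(weights * (exp_means - sim_values)^2)),
       weights = weights)
}

#' Build a drift-field parameter grid
#'
#' Crosses attractive and repulsive sigmoid parameters into a parameter-set
#' table for [rank_scan()]. The default axes give the standard 600-set scan
#' (6 x 5 attractive by 4 x 5 repulsive combinations).
#'
#' @param a_rhalf,a_s Attractive-field half distances and steepness values (um).
#' @param r_rhalf,r_s Repulsive-field axes (um).
#' @return A tibble with `k`, `a_rhalf`, `a_s`, `r_rhalf`, `r_s`.
#' @export
param_grid <- function(a_rhalf = c(0, 5, 10, 15, 20, 25),
                       a_s = c(0.5, 1, 2, 4, 8),
                       r_rhalf = c(0, 2, 4, 8),
                       r_s = c(0.5, 1, 2, 4, 8)) {
  g <- tidyr::expand_grid(a_rhalf = a_rhalf, a_s = a_s,
                          r_rhalf = r_rhalf, r_s = r_s)
  dplyr::mutate(g, k = dplyr::row_number(), .before = 1)
}

#' Rank-minimization scan of drift-field parameters
#'
#' For every parameter set in `grid`, runs the RWD simulation (`replicates`
#' times, pooled), computes the binned directionality profile chi(r) and the
#' capture-time distribution, scores each against the reference with
#' [weighted_error()], ranks each variable's error across the grid
#' (ascending, average ranks for ties) and returns the table sorted by the
#' sum rank \eqn{R_s = \sum_v R_v(k)}. The top-ranked set is the optimum.
#'
#' @param grid A parameter table from [param_grid()].
#' @param reference A reference list as produced by
#'   [generate_pseudo_experiment()]: `chi` (tibble `r_lo, r_hi, mean, sd, n`)
#'   and `t_c` (tibble `t_lo, t_hi, mean, sd, n` of capture-time
#'   proportions).
#' @param params An [rwd_params()] used for every simulation.
#' @param replicates Simulations pooled per parameter set.
#' @param seed Integer seed for the whole scan.
#' @param record_interval Recording interval (s) passed to [simulate_rwd()].
#' @return An object of class `rank_result`: the grid tibble with `eps_chi`,
#'   `eps_tc`, `rank_chi`, `rank_tc`, `sum_rank`, sorted by `sum_rank`; the
#'   best set is attached as attribute `best`.
#' @export
rank_scan <- function(grid, reference, params = rwd_params(), replicates = 3,
                      seed = NULL, record_interval = 30) {
  stopifnot(is.data.frame(grid),
            all(c("k", "a_rhalf", "a_s", "r_rhalf", "r_s") %in% names(grid)),
            nrow(grid) >= 1)
  if (!all(c("chi", "t_c") %in% names(reference))) {
    abort("reference must contain `chi` and `t_c` tables",
          class = "asterdrift_invalid_params")
  }
  if (!is.null(seed)) set.seed(seed)
  chi_ref <- reference$chi
  tc_ref <- reference$t_c
  scores <- purrr::pmap_dfr(
    grid,
    function(k, a_rhalf, a_s, r_rhalf, r_s) {
      sims <- purrr::map(seq_len(replicates), function(i) {
        simulate_rwd(params,
                     attract = drift_field(a_rhalf, a_s),
                     repel = drift_field(r_rhalf, r_s, origin = "cell_boundary"),
                     record_interval = record_interval)
      })
      pooled <- dplyr::bind_rows(
        purrr::imap(sims, function(s, i) {
          dplyr::mutate(s, track_id = .data$track_id + (i - 1L) * 100000L)
        }))
      pooled <- as_aster_tracks(pooled, params$r_cell, params$r_chr)
      summ <- track_summary(pooled)
      sim_chi <- bin_means(summ$r_start, summ$chi, chi_ref$r_lo, chi_ref$r_hi)
      sim_tc <- bin_props(summ$t_c, tc_ref$t_lo, tc_ref$t_hi, nrow(summ))
      ok_chi <- !is.na(sim_chi) & !is.na(chi_ref$mean)
      ok_tc <- !is.na(tc_ref$mean)
      tibble::tibble(
        k = k,
        eps_chi = weighted_error(sim_chi[ok_chi], chi_ref$mean[ok_chi],
                                 chi_ref$sd[ok_chi], chi_ref$n[ok_chi])$epsilon,
        eps_tc = weighted_error(sim_tc[ok_tc], tc_ref$mean[ok_tc],
                                tc_ref$sd[ok_tc], tc_ref$n[ok_tc])$epsilon)
    })
  out <- grid |>
    dplyr::left_join(scores, by = "k") |>
    dplyr::mutate(rank_chi = rank(.data$eps_chi, ties.method = "average"),
                  rank_tc = rank(.data$eps_tc, ties.method = "average"),
                  sum_rank = .data$rank_chi + .data$rank_tc) |>
    dplyr::arrange(.data$sum_rank, .data$k)
  attr(out, "best") <- out[1, ]
  class(out) <- c("rank_result", class(tibble::tibble()))
  out
}

# mean of `value` within each [lo, hi) bin of `r`
bin_means <- function(r, value, lo, hi) {
  vapply(seq_along(lo), function(i) {
    sel <- !is.na(value) & r >= lo[i] & r < hi[i]
    if (any(sel)) mean(value[sel]) else NA_real_
  }, numeric(1))
}

# proportion of all tracks captured within each [lo, hi) time bin
bin_props <- function(t_c, lo, hi, n_total) {
  vapply(seq_along(lo), function(i) {
    sum(!is.na(t_c) & t_c >= lo[i] & t_c < hi[i]) / n_total
  }, numeric(1))
}

#' @export
print.rank_result <- function(x, ...) {
  b <- attr(x, "best")
  cat(sprintf(paste0("<rank_result> %d parameter sets; best (R_s = %g): ",
                     "attract (r_half = %g, s = %g), repel (r_half = %g, s = %g)\n"),
              nrow(x), b$sum_rank, b$a_rhalf, b$a_s, b$r_rhalf, b$r_s))
  NextMethod()
}
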