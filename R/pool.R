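#' Build a synthetic motoneuron pool
#'
#' Draws a pool of motor units (MUs) with recruitment thresholds spread over a
#' force range, per-unit de-recruitment thresholds offset by a normal
#' hysteresis draw, and a linear-above-threshold rate model with hard
#' saturation. Units are returned sorted by recruitment threshold, so the row
#' order is the size-principle recruitment order under any common drive.
#'
#' The default pool emulates the statistics of MU populations tracked in
#' low-force (0-10 %MVC) dorsiflexion ramps: about 11 units, and a
#' de-recruitment threshold on average 1.11 %MVC below the recruitment
#' threshold with a 2.44 %MVC spread, so roughly two thirds of units
#' de-recruit below their recruitment threshold (reversed hysteresis).
#'
#' @param n_units Number of motor units (>= 2).
#' @param threshold_range Length-2 numeric, recruitment-threshold range in
#'   %MVC; thresholds are drawn uniformly and sorted ascending.
#' @param hysteresis_mean,hysteresis_sd Mean and sd (in %MVC) of the normal
#'   draw added to `theta_on` to obtain `theta_off`. Negative mean means
#'   units tend to de-recruit below their recruitment threshold. Draws are
#'   floored so `theta_off` stays positive (0.01 %MVC floor).
#' @param r_min_range Range (pps) of the discharge rate at recruitment.
#' @param rate_gain_range Range (pps per %MVC) of the rate-drive gain above
#'   threshold.
#' @param r_sat_excess_range Range (pps) of the saturation rate in excess of
#'   `r_min`.
#' @param isi_cov Coefficient of variation of inter-spike intervals
#'   (dimensionless), recycled across units.
#' @param seed Integer seed; identical seeds give identical pools.
#'
#' @return A tibble of class `mu_pool` with one row per unit: `unit_id`,
#'   `theta_on`, `theta_off`, `r_min`, `rate_gain`, `r_sat`, `isi_cov`.
#' @examples
#' pool <- mu_pool(n_units = 11, seed = 1)
#' pool
#' @export
mu_pool <- function(n_units = 11,
                    threshold_range = c(0.5, 9.5),
                    hysteresis_mean = -1.11,
                    hysteresis_sd = 2.44,
                    r_min_range = c(6, 9),
                    rate_gain_range = c(0.5, 1.5),
                    r_sat_excess_range = c(4, 8),
                    isi_cov = 0.15,
                    seed = NULL) {
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 2)
    abort("`n_units` must be a single number >= 2.")
  if (length(threshold_range) != 2L || any(!is.finite(threshold_range)) ||
      threshold_range[1] <= 0 || threshold_range[2] >= 100 ||
      threshold_range[1] > threshold_range[2])
    abort("`threshold_range` must lie within (0, 100) %MVC and be ordered.")
  stopifnot_scalar_num(hysteresis_sd, "hysteresis_sd")
  if (hysteresis_sd < 0) abort("`hysteresis_sd` must be >= 0.")
  if (any(isi_cov < 0)) abort("`isi_cov` must be >= 0.")
  n_units <- as.integer(n_units)

  local_rng(seed, {
    theta_on <- sort(runif(n_units, threshold_range[1], threshold_range[2]))
    # clip (not resample) at a small positive floor: clipped values remain
    # below theta_on, so the reversed-hysteresis fraction stays Phi(-mu/sd)
    theta_off <- pmax(theta_on + rnorm(n_units, hysteresis_mean, hysteresis_sd),
                      0.01)
    pool <- tibble(
      unit_id = paste0("MU", seq_len(n_units)),
      theta_on = theta_on,
      theta_off = theta_off,
      r_min = runif(n_units, r_min_range[1], r_min_range[2]),
      rate_gain = runif(n_units, rate_gain_range[1], rate_gain_range[2]),
      r_sat = NA_real_,
      isi_cov = rep_len(isi_cov, n_units)
    )
    pool$r_sat <- pool$r_min +
      runif(n_units, r_sat_excess_range[1], r_sat_excess_range[2])
    new_mu_pool(pool)
  })
}

new_mu_pool <- function(df) {
  df <- as_tibble(df)
  needed <- c("unit_id", "theta_on", "theta_off", "r_min", "rate_gain",
              "r_sat", "isi_cov")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    abort(paste0("pool is missing columns: ", paste(miss, collapse = ", ")))
  if (any(df$theta_on <= 0)) abort("`theta_on` must be > 0 for every unit.")
  if (any(df$r_min <= 0)) abort("`r_min` must be > 0.")
  if (any(df$r_sat < df$r_min)) abort("`r_sat` must be >= `r_min`.")
  class(df) <- unique(c("mu_pool", class(df)))
  df
}

#' Construct a motor-unit pool from explicit parameters
#'
#' Companion to [mu_pool()] for tests and designed scenarios: pass the unit
#' parameters directly instead of drawing them.
#'
#' @param theta_on,theta_off Recruitment / de-recruitment thresholds, %MVC.
#' @param r_min Discharge rate at recruitment, pps.
#' @param rate_gain Rate increase per %MVC above threshold, pps/%MVC.
#' @param r_sat Saturation rate, pps.
#' @param isi_cov ISI coefficient of variation.
#' @param unit_id Optional unit labels.
#' @return A `mu_pool` tibble (rows ordered as given, not re-sorted).
#' @examples
#' pool_from_params(theta_on = c(3, 4), theta_off = c(2.5, 1.5),
#'                  r_min = 12, rate_gain = 0, r_sat = 12, isi_cov = 0)
#' @export
pool_from_params <- function(theta_on, theta_off = theta_on, r_min = 8,
                             rate_gain = 1, r_sat = r_min + 6, isi_cov = 0,
                             unit_id = NULL) {
  n <- length(theta_on)
  if (is.null(unit_id)) unit_id <- paste0("MU", seq_len(n))
  new_mu_pool(tibble(
    unit_id = unit_id,
    theta_on = theta_on,
    theta_off = rep_len(theta_off, n),
    r_min = rep_len(r_min, n),
    rate_gain = rep_len(rate_gain, n),
    r_sat = rep_len(r_sat, n),
    isi_cov = rep_len(isi_cov, n)
  ))
}

# Instantaneous discharge rate (pps) of one unit at drive level d (%MVC),
# valid while the unit is active: linear above threshold, floored at r_min,
# hard-saturated at r_sat.
unit_rate <- function(unit, d) {
  pmin(unit$r_sat, pmax(unit$r_min, unit$r_min + unit$rate_gain * (d - unit$theta_on)))
}
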