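#' Tidy the per-buffer stream of a trial
#' @param x A `mu_trial`.
#' @param ... Unused.
#' @return The trial's cursor stream as a tibble with the region label.
#' @export
tidy.mu_trial <- function(x, ...) {
  st <- as_tibble(x$stream)
  st$region <- point_region(st$x, st$y, x$geometry)
  st
}

#' One-row summary of a trial
#' @param x A `mu_trial`.
#' @param ... Unused.
#' @return One-row tibble with target, outcome and hit buffers.
#' @export
glance.mu_trial <- function(x, ...) {
  tibble(target = x$target, outcome = x$outcome,
         n_buffers = x$n_buffers,
         target_hit_buffer = x$target_hit_buffer,
         angle_hit_buffer = x$angle_hit_buffer)
}

#' Tidy a session's trial table
#' @param x A `mu_session`.
#' @param ... Unused.
#' @return The per-trial info tibble.
#' @export
tidy.mu_session <- function(x, ...) x$info

#' One-row summary of a session
#' @param x A `mu_session`.
#' @param ... Unused.
#' @return One-row tibble with trial counts and hit totals.
#' @export
glance.mu_session <- function(x, ...) {
  tibble(n_trials = nrow(x$info),
         target_hits = sum(!is.na(x$info$target_hit_buffer)),
         angle_hits = sum(!is.na(x$info$angle_hit_buffer)))
}

#' Tidy a rate-of-agreement result
#' @param x A `mu_roa`.
#' @param ... Unused.
#' @return One-row tibble of counts and the agreement percentage.
#' @export
tidy.mu_roa <- function(x, ...) {
  tibble(n_common = x$n_common, n_a_only = x$n_a_only,
         n_b_only = x$n_b_only, roa = x$roa)
}

#' @export
print.mu_roa <- function(x, ...) {
  cat(sprintf("Rate of agreement: %.1f%% (%d common, %d A-only, %d B-only)\n",
              x$roa, x$n_common, x$n_a_only, x$n_b_only))
  invisible(x)
}

#' @export
print.mu_trial <- function(x, ...) {
  cat(sprintf("Trial towards %s: %s (%d buffers", x$target, x$outcome,
              x$n_buffers))
  if (!is.na(x$angle_hit_buffer))
    cat(sprintf(", angle hit at buffer %d", x$angle_hit_buffer))
  if (!is.na(x$target_hit_buffer))
    cat(sprintf(", target hit at buffer %d", x$target_hit_buffer))
  cat(")\n")
  invisible(x)
}

#' @export
print.mu_summary <- function(x, ...) {
  cat("Hit rates (%):\n")
  print(as.data.frame(x$hit_rates))
  cat("\nNormalised performance:\n")
  print(as.data.frame(x$performance))
  invisible(x)
}
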