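#' Per-trial metrics table of a session
#'
#' Computes, for every trial of a session, the raw and normalised
#' performance, hit flags, direct-movement classification and nearest miss,
#' returning one tidy row per trial.
#'
#' @param session A `mu_session` from [run_session()].
#' @param cfg A [buffer_config()]; defaults to the session's.
#' @param variant Performance-metric variant, see [performance_raw()].
#' @return Tibble: `trial`, `target`, `outcome`, `target_hit`, `angle_hit`,
#'   `direct`, `raw`, `normalized`, `nearest_miss_x`, `nearest_miss_y`.
#' @export
trial_metrics <- function(session, cfg = NULL,
                          variant = c("sum_of_squares", "rss")) {
  variant <- arg_match(variant)
  if (is.null(cfg)) cfg <- session$config
  bounds <- purrr::map(setNames(nm = c("TI", "TII", "TIII")),
                       performance_bounds, cfg = cfg, variant = variant)
  purrr::imap_dfr(session$trials, function(tr, i) {
    raw <- performance_raw(tr, variant = variant)
    b <- bounds[[tr$target]]
    nm_pos <- if (is.na(tr$target_hit_buffer))
      nearest_miss(tr, cfg = cfg) else tibble()
    tibble(
      trial = i,
      target = tr$target,
      outcome = tr$outcome,
      target_hit = !is.na(tr$target_hit_buffer),
      angle_hit = !is.na(tr$angle_hit_buffer),
      direct = if (!is.null(tr$spikes)) classify_direct(tr, cfg = cfg) else NA,
      raw = raw,
      normalized = performance_normalized(raw, b),
      nearest_miss_x = if (nrow(nm_pos)) nm_pos$x else NA_real_,
      nearest_miss_y = if (nrow(nm_pos)) nm_pos$y else NA_real_
    )
  })
}

#' Summarise a session
#'
#' Aggregates trial metrics into per-target hit rates (percent), direct
#' fractions, performance medians and quartiles, and unintended-hit rates
#' (which can exceed 100% through re-entries).
#'
#' @param metrics A trial-metrics tibble from [trial_metrics()], or a
#'   `mu_session` (metrics are computed).
#' @param session Optional `mu_session` for unintended-hit counting.
#' @param cfg A [buffer_config()].
#' @return A list of class `mu_summary`: `hit_rates`, `performance`,
#'   `unintended` tibbles.
#' @export
summarize_session <- function(metrics, session = NULL, cfg = buffer_config()) {
  if (inherits(metrics, "mu_session")) {
    session <- metrics
    cfg <- session$config
    metrics <- trial_metrics(session)
  }
  if (!nrow(metrics)) abort("no trials to summarise.")
  hit_rates <- metrics %>%
    group_by(.data$target) %>%
    summarise(
      n_trials = n(),
      target_hits = sum(.data$target_hit),
      angle_hits = sum(.data$angle_hit),
      target_rate = 100 * mean(.data$target_hit),
      angle_rate = 100 * mean(.data$angle_hit),
      direct_fraction = if (all(is.na(.data$direct))) NA_real_
        else 100 * mean(.data$direct[!is.na(.data$direct)]),
      .groups = "drop"
    )
  performance <- metrics %>%
    group_by(.data$target) %>%
    summarise(
      median = median(.data$normalized),
      q1 = quantile(.data$normalized, 0.25),
      q3 = quantile(.data$normalized, 0.75),
      .groups = "drop"
    )
  unintended <- NULL
  if (!is.null(session)) {
    unintended <- purrr::imap_dfr(session$trials, function(tr, i) {
      mutate(unintended_hits(tr, cfg), trial = i, shown = tr$target)
    }) %>%
      group_by(.data$shown, .data$target, .data$region) %>%
      summarise(count = sum(.data$count), n_trials = dplyr::n_distinct(.data$trial),
                .groups = "drop") %>%
      mutate(rate = 100 * .data$count / .data$n_trials)
  }
  structure(list(hit_rates = hit_rates, performance = performance,
                 unintended = unintended),
            class = "mu_summary")
}

#' Paired two-sided Wilcoxon signed-rank test (tidy)
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble `statistic`, `p.value`, `n`, `method`.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired.")
  if (all(x == y))  # no effect at all: the test statistic is degenerate
    return(tibble(statistic = 0, p.value = 1, n = length(x),
                  method = "Wilcoxon signed-rank (two-sided)"))
  res <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
  tibble(statistic = unname(res$statistic), p.value = res$p.value,
         n = length(x), method = "Wilcoxon signed-rank (two-sided)")
}

#' Friedman test with Bonferroni-corrected post-hoc Wilcoxon tests (tidy)
#'
#' @param mat Numeric matrix: rows = blocks (sessions/subjects), columns =
#'   conditions.
#' @return List with `friedman` (one-row tibble) and `posthoc` (tibble of
#'   pairwise comparisons with Bonferroni-adjusted p values).
#' @export
friedman_posthoc <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("C", seq_len(ncol(mat)))
  fr <- friedman.test(mat)
  pairs <- utils::combn(colnames(mat), 2, simplify = FALSE)
  ph <- purrr::map_dfr(pairs, function(p) {
    w <- suppressWarnings(
      wilcox.test(mat[, p[1]], mat[, p[2]], paired = TRUE, exact = FALSE))
    tibble(group1 = p[1], group2 = p[2],
           statistic = unname(w$statistic), p.value = w$p.value)
  })
  ph$p.adjusted <- pmin(1, ph$p.value * nrow(ph))
  list(
    friedman = tibble(statistic = unname(fr$statistic),
                      df = unname(fr$parameter), p.value = fr$p.value,
                      n = nrow(mat), method = "Friedman"),
    posthoc = ph
  )
}

#' Spearman correlation (tidy)
#'
#' @param x,y Numeric vectors.
#' @return One-row tibble `estimate`, `p.value`, `n`, `method`.
#' @export
spearman_trend <- function(x, y) {
  res <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(estimate = unname(res$estimate), p.value = res$p.value,
         n = length(x), method = "Spearman")
}

#' Session-level statistical report
#'
#' Runs the report statistics over a long table of per-block condition
#' values: a Friedman test across conditions with Bonferroni-corrected
#' post-hoc Wilcoxon tests, and paired Wilcoxon tests for two-condition
#' tables. (Paired nonparametric tests stand in for mixed-model summaries
#' throughout the reports.)
#'
#' @param data Tibble with columns `block`, `condition`, `value`.
#' @return A list: `test` tibble(s) as in [friedman_posthoc()] /
#'   [wilcoxon_paired()].
#' @export
report_stats <- function(data) {
  need <- c("block", "condition", "value")
  if (!all(need %in% names(data)))
    abort("`data` must have columns block, condition, value.")
  wide <- tidyr::pivot_wider(data, id_cols = "block",
                             names_from = "condition",
                             values_from = "value")
  mat <- as.matrix(wide[setdiff(names(wide), "block")])
  if (anyNA(mat)) abort("unpaired observations: every block needs every condition.")
  if (ncol(mat) == 2) {
    list(test = wilcoxon_paired(mat[, 1], mat[, 2]))
  } else {
    friedman_posthoc(mat)
  }
}
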