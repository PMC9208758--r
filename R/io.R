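#' Write a simulated session to a directory
#'
#' Writes the standard plain-text session layout: spike trains as CSV
#' (`unit_id`, `time_s`), drive and force traces as CSV (`time_s`,
#' `value`), pool ground truth as JSON and the configuration as YAML. All
#' files carry a `format_version` field or header comment.
#'
#' @param dir Session directory (created if needed).
#' @param spikes A `mu_spikes` tibble.
#' @param drive,force `mu_trace`s (optional).
#' @param pool A `mu_pool` (optional).
#' @param config A named list written as YAML (optional).
#' @return `dir`, invisibly.
#' @export
write_session <- function(dir, spikes, drive = NULL, force = NULL,
                          pool = NULL, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(spikes)[c("unit_id", "time_s")],
                   file.path(dir, "spikes.csv"))
  if (!is.null(drive))
    readr::write_csv(as_tibble(drive), file.path(dir, "drive.csv"))
  if (!is.null(force))
    readr::write_csv(as_tibble(force), file.path(dir, "force.csv"))
  if (!is.null(pool))
    jsonlite::write_json(c(list(format_version = 1L),
                           list(units = as.data.frame(pool))),
                         file.path(dir, "pool.json"),
                         auto_unbox = TRUE, digits = NA)
  cfg <- c(list(format_version = 1L), config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a session directory
#'
#' @param dir Directory written by [write_session()].
#' @return List with `spikes`, `drive`, `force`, `pool`, `config`
#'   (missing pieces are `NULL`).
#' @export
read_session <- function(dir) {
  if (!file.exists(file.path(dir, "spikes.csv")))
    abort(sprintf("'%s' is not a session directory (no spikes.csv).", dir))
  read_trace <- function(f) {
    if (!file.exists(f)) return(NULL)
    df <- readr::read_csv(f, show_col_types = FALSE)
    fs <- 1 / median(diff(df$time_s))
    new_mu_trace(df$time_s, df$value, fs)
  }
  pool <- NULL
  pf <- file.path(dir, "pool.json")
  if (file.exists(pf)) {
    pj <- jsonlite::read_json(pf, simplifyVector = TRUE)
    pool <- new_mu_pool(as_tibble(pj$units))
  }
  cfg <- NULL
  cf <- file.path(dir, "config.yaml")
  if (file.exists(cf)) cfg <- yaml::read_yaml(cf)
  sp <- readr::read_csv(file.path(dir, "spikes.csv"), show_col_types = FALSE)
  class(sp) <- unique(c("mu_spikes", class(sp)))
  list(
    spikes = sp,
    drive = read_trace(file.path(dir, "drive.csv")),
    force = read_trace(file.path(dir, "force.csv")),
    pool = pool,
    config = cfg
  )
}

#' Write a thresholds table as CSV
#' @param thresholds A `mu_thresholds` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  readr::write_csv(as_tibble(thresholds), path)
  invisible(path)
}
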