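# Tabular output: per-pair CSV, JSON sidecar with full provenance, and
# analytic curves for overlay plots.

#' Write paired first-passage samples as CSV
#'
#' One row per pair: `run_id, t1_s, t2_s, delta_s, censored`.  Censored
#' members are written as empty cells, `censored = TRUE`.
#'
#' @param pr a [simulate_paired()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(pr, path) {
  stopifnot(inherits(pr, "paired_result"))
  cens <- is.na(pr$t1) | is.na(pr$t2)
  df <- data.frame(
    run_id = seq_len(pr$n_runs),
    t1_s = pr$t1,
    t2_s = pr$t2,
    delta_s = ifelse(cens, NA_real_, pr$t1 - pr$t2),
    censored = cens
  )
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a JSON sidecar with parameters and summary
#'
#' @param pr a [simulate_paired()] result.
#' @param p1,p2 the [cleft_params()] used.
#' @param w1,w2 the [wall_params()] used.
#' @param cfg the [sim_config()] used.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_sidecar <- function(pr, p1, p2, w1, w2, cfg, path) {
  stopifnot(inherits(pr, "paired_result"))
  strip <- function(x) unclass(x)
  payload <- list(
    cleft1 = strip(p1), cleft2 = strip(p2),
    wall1 = strip(w1), wall2 = strip(w2),
    sim = strip(cfg),
    n_pairs_censored = pr$n_pairs_censored,
    summary = pr$summary
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Tabulate the analytic first-passage law
#'
#' Density and CDF of [fpt_density()]/[fpt_cdf()] on a log-spaced time
#' grid, plus the closed-form difference std as an attribute; suitable for
#' CSV export and plot overlays.
#'
#' @param a an [analytic_fpt()] object.
#' @param n number of grid points.
#' @param t_range length-2 time range (s); default spans the density
#'   support from 1e-3 to ~1e2 times the mean.
#' @return `data.frame` with columns `t_s`, `density_per_s`, `cdf`.
#' @export
analytic_curves <- function(a, n = 400L, t_range = NULL) {
  stopifnot(inherits(a, "analytic_fpt"))
  if (is.null(t_range)) t_range <- c(1e-3 * a$mu, min(.t_cut(a), 100 * a$mu))
  t <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n))
  out <- data.frame(t_s = t, density_per_s = fpt_density(t, a),
                    cdf = fpt_cdf(t, a))
  attr(out, "delta_std") <- delta_std(a)
  out
}

#' Write a sweep table as CSV
#'
#' @param rows a sweep `data.frame` from [sweep_symmetric_D()] and friends.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
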