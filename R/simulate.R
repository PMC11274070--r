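# Monte-Carlo first-passage sampling.

#' One Euler--Maruyama step
#'
#' Advances a position by
#' `x + total_force(x)/zeta * dt + sqrt(2 D dt) * z`, the Euler--Maruyama
#' discretization of the overdamped Langevin equation (additive noise, so
#' there is no Ito/Stratonovich ambiguity).  Exposed mainly for testing and
#' didactic use; the production integrator runs the identical update in
#' compiled code.
#'
#' @param x current position(s) (m).
#' @param p a [cleft_params()] object.
#' @param w a [wall_params()] object.
#' @param dt time step (s).
#' @param z standard-normal draw(s), same length as `x`.
#' @return New position(s) (m).
#' @export
em_step <- function(x, p, w, dt, z) {
  stopifnot(is.numeric(dt), dt > 0, is.numeric(z), all(is.finite(z)))
  x + (total_force(x, p, w) / p$zeta) * dt + sqrt(2 * p$D * dt) * z
}

#' Simulate single-cleft first-passage times
#'
#' Runs `cfg$n_runs` independent trajectories from `cfg$x_start`, each with
#' its own deterministic noise substream, until absorption at `x >= d` or
#' the censoring horizon `t_max`.  If `cfg$interpolate_crossing`, the
#' crossing time is linearly interpolated inside the final step.
#'
#' @param p a [cleft_params()] object.
#' @param w a [wall_params()] object.
#' @param cfg a [sim_config()] object.
#' @param member internal substream selector (0 for single-cleft samples;
#'   [simulate_paired()] uses 1 and 2).  Same `(seed, member)` gives
#'   bit-identical output.
#' @return An object of class `fpt_sample`: list with `times` (uncensored
#'   first-passage times, s), `n_censored`, `n_runs`, `below_frac` (fraction
#'   of trajectory steps spent at `x < -2 x0`, a wall-efficacy diagnostic)
#'   and `params_fingerprint`.
#' @examples
#' p <- cleft_params(); w <- wall_params()
#' s <- simulate_fpt(p, w, sim_config(n_runs = 200, seed = 7))
#' mean(s$times)   # of order d / v_drift ~ 8 us
#' @export
simulate_fpt <- function(p, w, cfg, member = 0L) {
  stopifnot(inherits(p, "cleft_params"), inherits(w, "wall_params"),
            inherits(cfg, "sim_config"))
  if (cfg$x_start >= p$d) {
    stop("'x_start' must be below the absorbing boundary d", call. = FALSE)
  }
  res <- sim_fpt_cpp(cfg$n_runs, cfg$x_start, p$d, cfg$dt, cfg$t_max,
                     p$drift_force, p$zeta, p$D,
                     w$Fmax, w$x0, w$lC, .wall_variant_code(w$variant),
                     cfg$interpolate_crossing, cfg$seed, as.integer(member),
                     -2 * w$x0)
  .warn_censoring(res$n_censored, cfg$n_runs)
  out <- list(
    times = res$times[!is.na(res$times)],
    n_censored = res$n_censored,
    n_runs = cfg$n_runs,
    below_frac = if (res$total_steps > 0) res$below_steps / res$total_steps else 0,
    params_fingerprint = .params_fingerprint(p, w, cfg)
  )
  class(out) <- "fpt_sample"
  out
}

.warn_censoring <- function(n_censored, n_runs) {
  frac <- n_censored / n_runs
  if (frac > 0.5) {
    warning(sprintf(
      "%.1f%% of runs censored at t_max: horizon far too short for these parameters",
      100 * frac), call. = FALSE)
  } else if (frac > 0.001) {
    warning(sprintf(
      "censored fraction %.3g exceeds 0.1%%; consider raising t_max",
      frac), call. = FALSE)
  }
  invisible(frac)
}

#' @export
print.fpt_sample <- function(x, ...) {
  cat(sprintf(
    "First-passage sample: %d runs, %d censored; mean = %.4g us, sd = %.4g us\n",
    x$n_runs, x$n_censored,
    from_si(mean(x$times), "us"), from_si(sd(x$times), "us")))
  invisible(x)
}

#' Simulate paired releases in two clefts
#'
#' Two neurotransmitters are released simultaneously (t = 0) into two
#' clefts with parameters `(p1, w1)` and `(p2, w2)`; each pair member uses
#' an independent noise substream derived from the master seed.  Pairs in
#' which either member is censored are excluded from the difference sample
#' and counted.
#'
#' @param p1,p2 [cleft_params()] for cleft 1 and 2.
#' @param w1,w2 [wall_params()] for cleft 1 and 2 (defaults: `w1` reused).
#' @param cfg a [sim_config()] object; `n_runs` is the number of pairs.
#' @param .shared_noise test hook: if `TRUE`, both members reuse the same
#'   substream, so identical clefts give identical paths and all
#'   differences are exactly zero.
#' @return An object of class `paired_result`: `delta_times` (t1 - t2 over
#'   uncensored pairs, s), `t1`, `t2` (per-pair times, `NA` when censored),
#'   `n_pairs_censored`, `n_runs`, and `summary` from [summarize_delta()].
#' @export
simulate_paired <- function(p1, p2, w1 = wall_params(), w2 = w1, cfg,
                            .shared_noise = FALSE) {
  stopifnot(inherits(p1, "cleft_params"), inherits(p2, "cleft_params"),
            inherits(w1, "wall_params"), inherits(w2, "wall_params"),
            inherits(cfg, "sim_config"))
  m1 <- 1L
  m2 <- if (.shared_noise) 1L else 2L
  run_member <- function(p, w, member) {
    sim_fpt_cpp(cfg$n_runs, cfg$x_start, p$d, cfg$dt, cfg$t_max,
                p$drift_force, p$zeta, p$D,
                w$Fmax, w$x0, w$lC, .wall_variant_code(w$variant),
                cfg$interpolate_crossing, cfg$seed, member, -2 * w$x0)
  }
  r1 <- run_member(p1, w1, m1)
  r2 <- run_member(p2, w2, m2)
  t1 <- r1$times
  t2 <- r2$times
  ok <- !is.na(t1) & !is.na(t2)
  n_cens <- sum(!ok)
  .warn_censoring(n_cens, cfg$n_runs)
  delta <- t1[ok] - t2[ok]
  out <- list(
    delta_times = delta,
    t1 = t1, t2 = t2,
    n_pairs_censored = n_cens,
    n_runs = cfg$n_runs,
    summary = if (length(delta) >= 3 && sd(delta) > 0)
      summarize_delta(delta) else NULL,
    params_fingerprint = .params_fingerprint(p1, p2, w1, w2, cfg)
  )
  class(out) <- "paired_result"
  out
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("Paired first-passage result: %d pairs (%d censored)\n",
              x$n_runs, x$n_pairs_censored))
  if (!is.null(x$summary)) {
    cat(sprintf("  dT = t1 - t2: mean = %.4g us, sd = %.4g us, skewness = %.3f\n",
                from_si(x$summary$mean, "us"), from_si(x$summary$sd, "us"),
                x$summary$skewness))
  }
  invisible(x)
}

#' Time-step convergence diagnostic
#'
#' Estimates the systematic effect of the integration step on the mean
#' first-passage time by running, for each trajectory, a coarse path at
#' `cfg$dt` and a fine path at `cfg$dt / 2` driven by the same Gaussian
#' increments (the coarse Gaussians are the Brownian-consistent pairwise
#' sums of the fine ones).  Because the two estimators share noise, their
#' difference in means reflects the discretization effect, not Monte-Carlo
#' scatter.
#'
#' @inheritParams simulate_fpt
#' @return List with `mean_coarse`, `mean_fine` (s, over pairs where both
#'   paths were absorbed), `rel_change` = |mean_coarse - mean_fine| /
#'   mean_coarse, `se_diff` (standard error of the paired mean difference)
#'   and `n_used`.
#' @export
dt_convergence <- function(p, w, cfg) {
  stopifnot(inherits(p, "cleft_params"), inherits(w, "wall_params"),
            inherits(cfg, "sim_config"))
  res <- sim_fpt_coupled_cpp(cfg$n_runs, cfg$x_start, p$d, cfg$dt, cfg$t_max,
                             p$drift_force, p$zeta, p$D,
                             w$Fmax, w$x0, w$lC,
                             .wall_variant_code(w$variant),
                             cfg$interpolate_crossing, cfg$seed, 0L)
  ok <- !is.na(res$t_coarse) & !is.na(res$t_fine)
  tc <- res$t_coarse[ok]
  tf <- res$t_fine[ok]
  if (length(tc) < 2) stop("too few uncensored coupled pairs", call. = FALSE)
  diffs <- tc - tf
  list(mean_coarse = mean(tc),
       mean_fine = mean(tf),
       rel_change = abs(mean(diffs)) / mean(tc),
       se_diff = sd(diffs) / sqrt(length(diffs)),
       n_used = length(tc))
}
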