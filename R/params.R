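# Parameter containers.  Everything is stored in SI; constructors validate
# and derive the drag coefficient and drift velocity once so downstream code
# never recomputes them inconsistently.

.check_positive_finite <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("'", field, "' must be a single finite number", call. = FALSE)
  }
  if (value <= 0) {
    stop("'", field, "' must be positive (got ", format(value), ")",
         call. = FALSE)
  }
  invisible(value)
}

.check_finite <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("'", field, "' must be a single finite number", call. = FALSE)
  }
  invisible(value)
}

#' Physical description of one synaptic cleft
#'
#' Holds the cleft width `d`, diffusion coefficient `D`, trans-cleft voltage
#' `V` (negative under physiological conditions) and thermal energy `T`
#' (Joule; `kB * temperature`).  The carrier is glutamate with fixed charge
#' `q = -e`.  Derived fields follow the Einstein relation:
#' drag `zeta = T / D`, and drift velocity
#' `v_drift = (-e V / d) / zeta` (positive, i.e. toward the post-synaptic
#' membrane, for `V < 0`).
#'
#' @param d cleft width (m). Default 20 nm.
#' @param D diffusion coefficient (m^2/s). Default 0.33 um^2/ms.
#' @param V trans-cleft voltage (V). Default -4 mV.
#' @param T_energy thermal energy (J). Default `kB * 310 K` (physiological
#'   temperature); enters only through `zeta = T/D`.
#' @return An object of class `cleft_params`.
#' @examples
#' p <- cleft_params()
#' p$zeta          # ~1.30e-11 kg/s
#' p$v_drift       # ~2.47e-3 m/s
#' @export
cleft_params <- function(d = to_si(20, "nm"),
                         D = to_si(0.33, "um2/ms"),
                         V = to_si(-4, "mV"),
                         T_energy = cleft_constants[["kB"]] * 310) {
  .check_positive_finite(d, "d")
  .check_positive_finite(D, "D")
  .check_finite(V, "V")
  .check_positive_finite(T_energy, "T_energy")
  e <- cleft_constants[["e"]]
  zeta <- T_energy / D
  drift_F <- -e * V / d          # force on charge -e in field V/d
  p <- list(
    d = d, D = D, V = V, T_energy = T_energy,
    q = -e,
    zeta = zeta,
    drift_force = drift_F,
    v_drift = drift_F / zeta
  )
  class(p) <- "cleft_params"
  p
}

#' @export
print.cleft_params <- function(x, ...) {
  cat("Synaptic cleft parameters (SI internally):\n")
  cat(sprintf("  d        = %g nm\n", from_si(x$d, "nm")))
  cat(sprintf("  D        = %g um2/ms\n", from_si(x$D, "um2/ms")))
  cat(sprintf("  V        = %g mV\n", from_si(x$V, "mV")))
  cat(sprintf("  T        = %.4g J (kB * %.1f K)\n",
              x$T_energy, x$T_energy / cleft_constants[["kB"]]))
  cat(sprintf("  zeta     = %.4g kg/s   (T/D)\n", x$zeta))
  cat(sprintf("  v_drift  = %.4g m/s    (-eV/d / zeta)\n", x$v_drift))
  invisible(x)
}

#' Soft-wall force parameters
#'
#' The wall is a localized force near the pre-synaptic membrane (centred
#' about x = 0) that pushes the neurotransmitter back into the cleft without
#' a hard reflection.  It is built from two sech^2 bumps of peak force
#' `Fmax` centred at `x = -x0` and `x = +x0`, with steepness set by `lC`:
#' \eqn{b(u) = \frac{1}{4}\mathrm{sech}^2(u / 4 l_C)} (even in both `u` and
#' `lC`).
#'
#' Variants:
#' \describe{
#'   \item{`"anti_return"` (default)}{`F_W(x) = 4 Fmax [b(x - x0) + b(x + x0)]`:
#'     a one-signed soft ramp over the wall region `|x| < ~x0`, peak force
#'     `Fmax` at both flanks, vanishing in the cleft interior.  A
#'     neurotransmitter wandering back toward (or behind) the membrane is
#'     pushed into the cleft; the finite ramp energy (~5 kT at the default
#'     parameters) makes the wall penetrable — soft, not reflecting.  This
#'     is the variant that realizes the intended anti-return behaviour; it
#'     shortens the passage relative to the free walk because transport here
#'     is diffusion-dominated (Peclet `v d / D` ~ 0.15).}
#'   \item{`"zero_offset"`}{`F_W(x) = 4 Fmax [b(x - x0) - b(x + x0)]`: the
#'     bump *difference*, an odd function of x.  Kept selectable for
#'     comparison; note that for x < 0 it pushes *away* from the cleft.}
#'   \item{`"literal"`}{as `"zero_offset"` with the constant `-Fmax` tail
#'     retained; the far-field offset (300x the drift force) makes passage
#'     essentially impossible and is retained only for completeness.}
#'   \item{`"off"`}{no wall force.}
#' }
#'
#' @param Fmax peak force (N), >= 0. Default 9.6e-12 N.
#' @param x0 effective wall-region half-width (m), > 0. Default 2 nm.
#' @param lC steepness length (m), nonzero; only |lC| matters since
#'   sech^2 is even. Default -0.3 nm.
#' @param variant one of `"anti_return"`, `"zero_offset"`, `"literal"`,
#'   `"off"`.
#' @return An object of class `wall_params`.
#' @export
wall_params <- function(Fmax = 9.6e-12,
                        x0 = 2e-9,
                        lC = -3e-10,
                        variant = c("anti_return", "zero_offset", "literal",
                                    "off")) {
  variant <- match.arg(variant)
  .check_finite(Fmax, "Fmax")
  if (Fmax < 0) stop("'Fmax' must be >= 0", call. = FALSE)
  .check_positive_finite(x0, "x0")
  .check_finite(lC, "lC")
  if (lC == 0) stop("'lC' must be nonzero", call. = FALSE)
  w <- list(Fmax = Fmax, x0 = x0, lC = lC, variant = variant)
  class(w) <- "wall_params"
  w
}

#' @export
print.wall_params <- function(x, ...) {
  cat(sprintf("Soft-wall force: variant=%s, Fmax=%g N, x0=%g nm, lC=%g nm\n",
              x$variant, x$Fmax, from_si(x$x0, "nm"), from_si(x$lC, "nm")))
  invisible(x)
}

#' Numerical protocol for the Langevin simulation
#'
#' @param dt time step (s). Default 10 ns.
#' @param n_runs number of independent trajectories (or pairs). Default 50000.
#' @param t_max censoring horizon (s): a trajectory not absorbed by `t_max`
#'   is censored and reported, not included in the FPT sample. Default 5 ms.
#' @param x_start initial position (m). Default 0 (pre-synaptic membrane).
#' @param interpolate_crossing if `TRUE`, the recorded passage time is
#'   linearly interpolated within the crossing step; if `FALSE` (default)
#'   the step-end time is used (bias <= dt, negligible against us-scale FPTs).
#' @param seed master seed (non-negative integer); every trajectory derives
#'   its own reproducible noise substream from it, so results do not depend
#'   on batching.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = to_si(10, "ns"),
                       n_runs = 50000L,
                       t_max = to_si(5, "ms"),
                       x_start = 0,
                       interpolate_crossing = FALSE,
                       seed = 1L) {
  .check_positive_finite(dt, "dt")
  if (!is.numeric(n_runs) || length(n_runs) != 1L || n_runs < 1 ||
      n_runs != round(n_runs)) {
    stop("'n_runs' must be a positive integer", call. = FALSE)
  }
  .check_positive_finite(t_max, "t_max")
  if (t_max < dt) stop("'t_max' must be >= dt", call. = FALSE)
  .check_finite(x_start, "x_start")
  stopifnot(is.logical(interpolate_crossing), length(interpolate_crossing) == 1L)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed < 0 || seed != round(seed)) {
    stop("'seed' must be a non-negative integer", call. = FALSE)
  }
  cfg <- list(dt = dt, n_runs = as.integer(n_runs), t_max = t_max,
              x_start = x_start,
              interpolate_crossing = interpolate_crossing,
              seed = as.numeric(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation protocol: dt=%g ns, n_runs=%d, t_max=%g ms, x_start=%g nm,\n  interpolate_crossing=%s, seed=%.0f\n",
    from_si(x$dt, "ns"), x$n_runs, from_si(x$t_max, "ms"),
    from_si(x$x_start, "nm"), x$interpolate_crossing, x$seed))
  invisible(x)
}

# Compact deterministic fingerprint of a parameter set; used for
# provenance bookkeeping on FPT samples.
.params_fingerprint <- function(...) {
  parts <- unlist(lapply(list(...), function(obj) {
    vapply(obj[!vapply(obj, is.function, logical(1))],
           function(v) paste(format(v, digits = 17), collapse = ","),
           character(1))
  }))
  paste(names(parts), parts, sep = "=", collapse = ";")
}
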