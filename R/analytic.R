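# Closed-form benchmarks for the wall-free drifted Wiener process.
# The first-passage law of Brownian motion with drift v > 0 and diffusion D
# to a barrier at distance d is inverse-Gaussian with mean mu = d/v and
# shape lambda = d^2 / (2 D); all quantities here are derived from that law
# and cross-checked by quadrature.

#' Analytic first-passage model (drifted Wiener process)
#'
#' @param d barrier distance (m).
#' @param D diffusion coefficient (m^2/s).
#' @param v drift speed (m/s); must be positive for the first-passage
#'   distribution to be proper (normalized).
#' @return Object of class `analytic_fpt` with fields `d`, `D`, `v` and the
#'   equivalent inverse-Gaussian parameters `mu = d/v`, `lambda = d^2/(2D)`.
#' @examples
#' a <- analytic_fpt_from_params(cleft_params())
#' a$mu        # mean first-passage time, ~8.1e-6 s
#' @export
analytic_fpt <- function(d, D, v) {
  .check_positive_finite(d, "d")
  .check_positive_finite(D, "D")
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    stop("'v' must be a single finite number", call. = FALSE)
  }
  if (v <= 0) {
    stop("divergence: drift speed v must be > 0 for a proper first-passage ",
         "distribution (pure diffusion has no finite moments)", call. = FALSE)
  }
  a <- list(d = d, D = D, v = v, mu = d / v, lambda = d^2 / (2 * D))
  class(a) <- "analytic_fpt"
  a
}

#' @rdname analytic_fpt
#' @param p a [cleft_params()] object; requires `V < 0` so the drift pushes
#'   toward the absorbing boundary.
#' @export
analytic_fpt_from_params <- function(p) {
  stopifnot(inherits(p, "cleft_params"))
  analytic_fpt(p$d, p$D, p$v_drift)
}

#' @export
print.analytic_fpt <- function(x, ...) {
  cat(sprintf(
    "Wiener first-passage law: d=%g nm, D=%g um2/ms, v=%.4g m/s\n  inverse-Gaussian mu=%.4g us, lambda=%.4g us\n",
    from_si(x$d, "nm"), from_si(x$D, "um2/ms"), x$v,
    from_si(x$mu, "us"), from_si(x$lambda, "us")))
  invisible(x)
}

#' First-passage time density
#'
#' \deqn{\gamma(t) = \frac{d}{\sqrt{4\pi D t^3}}
#'       \exp\!\left(-\frac{(d - v t)^2}{4 D t}\right),}
#' evaluated in log space so it is stable from nanoseconds out to the deep
#' exponential tail.
#'
#' @param t time(s), strictly positive (s).
#' @param a an [analytic_fpt()] object.
#' @return Density values (1/s).
#' @export
fpt_density <- function(t, a) {
  stopifnot(inherits(a, "analytic_fpt"), is.numeric(t))
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("fpt_density requires t > 0", call. = FALSE)
  }
  lg <- log(a$d) - 0.5 * log(4 * pi * a$D * t^3) -
    (a$d - a$v * t)^2 / (4 * a$D * t)
  exp(lg)
}

#' First-passage time distribution function
#'
#' Standard inverse-Gaussian CDF,
#' `Phi(sqrt(lambda/t)(t/mu - 1)) + exp(2 lambda/mu) Phi(-sqrt(lambda/t)(t/mu + 1))`,
#' with the second term assembled in log space (`2 lambda / mu = v d / D`
#' can exceed 100 at physiological parameters).
#'
#' @param t time(s) >= 0 (s).
#' @param a an [analytic_fpt()] object.
#' @return Probabilities in [0, 1].
#' @export
fpt_cdf <- function(t, a) {
  stopifnot(inherits(a, "analytic_fpt"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("fpt_cdf requires finite t >= 0", call. = FALSE)
  }
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  s <- sqrt(a$lambda / tp)
  q1 <- s * (tp / a$mu - 1)
  q2 <- s * (tp / a$mu + 1)
  out[pos] <- pnorm(q1) +
    exp(2 * a$lambda / a$mu + pnorm(-q2, log.p = TRUE))
  pmin(pmax(out, 0), 1)
}

# Survival 1 - CDF, assembled from upper tails so it does not lose
# precision where the CDF saturates at 1; used for quadrature cutoffs.
.fpt_survival <- function(t, a) {
  s <- sqrt(a$lambda / t)
  q1 <- s * (t / a$mu - 1)
  q2 <- s * (t / a$mu + 1)
  pnorm(q1, lower.tail = FALSE) -
    exp(2 * a$lambda / a$mu + pnorm(-q2, log.p = TRUE))
}

# Mode of the inverse-Gaussian density (the sharp peak the quadrature
# must not step over).
.ig_mode <- function(a) {
  r <- 3 * a$mu / (2 * a$lambda)
  a$mu * (sqrt(1 + r^2) - r)
}

# Upper integration cutoff: beyond the point where the survival drops
# below ~1e-16 the integrands here decay exponentially; doubling once more
# makes the omitted mass irrelevant at 1e-12 relative accuracy.
.t_cut <- function(a) {
  t <- a$mu
  while (.fpt_survival(t, a) > 1e-16 && t < 1e12 * a$mu) t <- 2 * t
  2 * t
}

# Adaptive quadrature of f over (0, t_cut), split at the density mode and
# at 10*mu so the peak and the slow power-law shoulder are each resolved.
.quad_fpt <- function(f, a, rel.tol = 1e-12) {
  cut <- .t_cut(a)
  brk <- sort(unique(pmin(c(.ig_mode(a), 10 * a$mu, cut), cut)))
  lo <- 0
  total <- 0
  for (b in brk) {
    total <- total + integrate(f, lo, b, rel.tol = rel.tol, abs.tol = 0,
                               subdivisions = 400L)$value
    lo <- b
  }
  total
}

# k-th raw moment of the first-passage density by quadrature.
.fpt_moment <- function(a, k, rel.tol = 1e-12) {
  .quad_fpt(function(t) t^k * fpt_density(t, a), a, rel.tol = rel.tol)
}

#' Variance of the paired first-passage difference, by quadrature
#'
#' The variance of `dT = t1 - t2` for two i.i.d. first-passage times is
#' \deqn{\delta^2 = \int\!\!\int (t_1 - t_2)^2 \gamma(t_1)\gamma(t_2)
#'       \, dt_1 dt_2 = 2\,\mathrm{Var}_\gamma(t).}
#' `method = "moments"` (default) evaluates the separable form from
#' single-dimension quadrature moments; `method = "double"` performs the
#' literal iterated two-dimensional quadrature (slower; kept as an
#' independent route for cross-checking the identity).
#'
#' @param a an [analytic_fpt()] object.
#' @param method `"moments"` or `"double"`.
#' @return Variance (s^2).
#' @export
delta_var_quadrature <- function(a, method = c("moments", "double")) {
  stopifnot(inherits(a, "analytic_fpt"))
  method <- match.arg(method)
  if (method == "moments") {
    m1 <- .fpt_moment(a, 1)
    m2 <- .fpt_moment(a, 2)
    return(2 * (m2 - m1^2))
  }
  inner <- function(t1) {
    vapply(t1, function(u) {
      .quad_fpt(function(t2) (u - t2)^2 * fpt_density(t2, a), a,
                rel.tol = 1e-10)
    }, numeric(1))
  }
  .quad_fpt(function(t1) fpt_density(t1, a) * inner(t1), a, rel.tol = 1e-9)
}

#' Closed-form standard deviation of the paired difference
#'
#' For the wall-free drifted Wiener process,
#' \deqn{\delta = 2\,(T / e|V|)^{3/2}\, d^2 / D
#'             = \sqrt{4 D d / v^3},}
#' the two parametrizations being related through `v = e|V| D / (T d)`.
#' Diverges as `V -> 0`: pure diffusion has an infinite-variance
#' first-passage difference.
#'
#' @param x an [analytic_fpt()] or [cleft_params()] object.
#' @param ... unused.
#' @return Standard deviation (s).
#' @export
delta_std <- function(x, ...) UseMethod("delta_std")

#' @export
delta_std.analytic_fpt <- function(x, ...) {
  sqrt(4 * x$D * x$d / x$v^3)
}

#' @export
delta_std.cleft_params <- function(x, ...) {
  if (x$V >= 0) {
    stop("divergence: delta_std requires V < 0 (drift toward the ",
         "post-synaptic boundary)", call. = FALSE)
  }
  e <- cleft_constants[["e"]]
  2 * (x$T_energy / (e * abs(x$V)))^1.5 * x$d^2 / x$D
}

#' Draw exact first-passage times from the analytic law
#'
#' Inverse-Gaussian sampling by the Michael--Schucany--Haas transform;
#' used as the independent oracle for validating the Langevin simulator.
#'
#' @param a an [analytic_fpt()] object.
#' @param n number of draws.
#' @param seed optional integer; if given, draws use a local RNG state that
#'   is restored on exit.
#' @return An `fpt_sample` object with `n` uncensored times.
#' @export
sample_analytic_fpt <- function(a, n, seed = NULL) {
  stopifnot(inherits(a, "analytic_fpt"), n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  mu <- a$mu
  lam <- a$lambda
  y <- rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lam) -
    mu / (2 * lam) * sqrt(4 * mu * lam * y + mu^2 * y^2)
  u <- runif(n)
  t <- ifelse(u <= mu / (mu + x), x, mu^2 / x)
  out <- list(times = t, n_censored = 0L, n_runs = as.integer(n),
              below_frac = 0,
              params_fingerprint = .params_fingerprint(a))
  class(out) <- "fpt_sample"
  out
}
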