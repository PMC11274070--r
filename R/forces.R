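# Deterministic force field: constant electrostatic drift plus the
# localized soft wall.  The wall profile is evaluated in compiled code (the
# same routine the integrator steps with), so R-level forces and the
# simulator can never disagree.

#' Electrostatic drift force on a glutamate carrier
#'
#' Constant across the cleft: `F = -e V / d` for charge `-e` in the uniform
#' field `V/d`.  Positive (toward the post-synaptic membrane) when `V < 0`.
#'
#' @param p a [cleft_params()] object.
#' @return Force in Newton.
#' @export
drift_force <- function(p) {
  stopifnot(inherits(p, "cleft_params"))
  p$drift_force
}

#' Soft-wall force profile
#'
#' Evaluates the anti-return wall force at positions `x`.  See
#' [wall_params()] for the functional form and variants.  Numerically
#' stable for `|x / (2 lC)|` up to ~700: the bump is computed through the
#' even form `b(u) = sech^2(u / 4 lC) / 4`.
#'
#' @param x numeric vector of positions (m).
#' @param w a [wall_params()] object.
#' @return Numeric vector of forces (N), same length as `x`.
#' @examples
#' w <- wall_params()
#' wall_force(0, w)                    # exactly 0 for the default variant
#' wall_force(c(-1e-9, 1e-9), w)       # push-back is odd in x
#' @export
wall_force <- function(x, w) {
  stopifnot(inherits(w, "wall_params"), is.numeric(x), all(is.finite(x)))
  wall_force_cpp(as.numeric(x), w$Fmax, w$x0, w$lC,
                 .wall_variant_code(w$variant))
}

.wall_variant_code <- function(variant) {
  switch(variant, off = 0L, zero_offset = 1L, literal = 2L,
         anti_return = 3L,
         stop("unknown wall variant '", variant, "'", call. = FALSE))
}

#' Total deterministic force
#'
#' `drift_force(p) + wall_force(x, w)`, vectorized over `x`.
#'
#' @inheritParams wall_force
#' @param p a [cleft_params()] object.
#' @return Numeric vector of forces (N).
#' @export
total_force <- function(x, p, w) {
  drift_force(p) + wall_force(x, w)
}
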