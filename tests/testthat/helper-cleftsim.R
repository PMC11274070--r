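# Shared fixtures.  Physical constants are re-derived here independently of
# the package's own definitions so tests cross-check rather than echo them.
E_CHARGE <- 1.602176634e-19 # C
KB <- 1.380649e-23          # J/K

phys_cleft <- function(...) cleft_params(...)

quick_cfg <- function(n = 2000L, dt_ns = 10, seed = 42, ...) {
  sim_config(dt = to_si(dt_ns, "ns"), n_runs = as.integer(n), seed = seed,
             ...)
}

# Independent evaluation of the logistic-density bump
# b(u) = exp(u/2lC) / (exp(u/2lC) + 1)^2, straight from the defining
# expression (the package computes it through the even sech^2 form).
bump_ref <- function(u, lC) {
  s <- u / (2 * lC)
  e <- exp(s)
  e / (e + 1)^2
}
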