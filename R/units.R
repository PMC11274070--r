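# Unit handling: all internal computation is SI (m, s, V, N, J).
# Convenience units (the ones used in the neuroscience literature for cleft
# geometry and diffusivity) are accepted at the interface boundary only.

.si_factors <- c(
  "nm"       = 1e-9,   # length
  "m"        = 1,
  "um2/ms"   = 1e-9,   # diffusivity: 1 um^2/ms = 1e-12 m^2 / 1e-3 s
  "m2/s"     = 1,
  "mV"       = 1e-3,   # voltage
  "V"        = 1,
  "ns"       = 1e-9,   # time
  "us"       = 1e-6,
  "ms"       = 1e-3,
  "s"        = 1,
  "N"        = 1       # force
)

# UTF-8 spellings accepted as aliases of the ASCII unit names.
.unit_aliases <- c(
  "μm²/ms" = "um2/ms",
  "µm²/ms" = "um2/ms",
  "um^2/ms"          = "um2/ms",
  "m²/s"        = "m2/s",
  "m^2/s"            = "m2/s",
  "μs"          = "us",
  "µs"          = "us"
)

.normalize_unit <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  if (unit %in% names(.unit_aliases)) unit <- .unit_aliases[[unit]]
  if (!unit %in% names(.si_factors)) {
    stop("unknown unit '", unit, "'; supported units: ",
         paste(names(.si_factors), collapse = ", "),
         " (plus UTF-8 spellings of um2/ms, m2/s, us)", call. = FALSE)
  }
  unit
}

#' Convert a value from a literature-convention unit to SI
#'
#' Exact power-of-ten conversion.  Supported units: `nm`, `m`, `um2/ms`
#' (micrometre squared per millisecond, also accepted spelled with Greek mu),
#' `m2/s`, `mV`, `V`, `ns`, `us`, `ms`, `s`, `N`.
#'
#' @param value numeric vector.
#' @param unit single unit name.
#' @return `value` expressed in the corresponding SI unit.
#' @examples
#' to_si(0.33, "um2/ms")  # 3.3e-10 m^2/s
#' to_si(20, "nm")        # 2e-08 m
#' @export
to_si <- function(value, unit) {
  value * .si_factors[[.normalize_unit(unit)]]
}

#' @rdname to_si
#' @export
from_si <- function(value, unit) {
  value / .si_factors[[.normalize_unit(unit)]]
}
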