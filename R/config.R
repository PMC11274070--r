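# Flat section/key=value configuration files.  Keys are named in the
# units practitioners quote (d_nm, D_um2_per_ms, V_mV, ...); conversion to
# SI happens here, at the boundary, and nowhere else.

.parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) {
        stop("config line outside any [section]: ", ln, call. = FALSE)
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      val <- gsub('^"|"$', "", val)
      out[[section]][[key]] <- val
    } else {
      stop("unparseable config line: ", ln, call. = FALSE)
    }
  }
  out
}

.cfg_num <- function(section, key, default = NULL) {
  v <- section[[key]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing config key '", key, "'", call. = FALSE)
    return(default)
  }
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop("config key '", key, "' is not numeric: ", v,
                     call. = FALSE)
  x
}

.cfg_bool <- function(section, key, default) {
  v <- section[[key]]
  if (is.null(v)) return(default)
  tolower(v) %in% c("true", "1", "yes")
}

.cleft_from_section <- function(sec) {
  cleft_params(
    d = to_si(.cfg_num(sec, "d_nm", 20), "nm"),
    D = to_si(.cfg_num(sec, "D_um2_per_ms", 0.33), "um2/ms"),
    V = to_si(.cfg_num(sec, "V_mV", -4), "mV"),
    T_energy = cleft_constants[["kB"]] * .cfg_num(sec, "T_kelvin", 310)
  )
}

#' Read a simulation configuration file
#'
#' Flat INI-style file with sections `[cleft1]`, `[cleft2]`, `[wall]`,
#' `[sim]` and keys `d_nm`, `D_um2_per_ms`, `V_mV`, `T_kelvin`; `Fmax_N`,
#' `x0_m`, `lC_m`, `wall_variant`; `dt_ns`, `n_runs`, `t_max_ms`,
#' `x_start_nm`, `interpolate_crossing`, `seed`.  Missing keys and sections
#' fall back to the physiological defaults; a missing `[cleft2]` copies
#' `[cleft1]`.  See `system.file("extdata", "physiological.ini",
#' package = "cleftsim")` for a complete example.
#'
#' @param path config file path.
#' @return List with elements `cleft1`, `cleft2` ([cleft_params()]),
#'   `wall` ([wall_params()]) and `sim` ([sim_config()]).
#' @export
read_config <- function(path) {
  raw <- .parse_ini(path)
  c1 <- .cleft_from_section(raw[["cleft1"]] %||% list())
  c2 <- if (is.null(raw[["cleft2"]])) c1 else
    .cleft_from_section(raw[["cleft2"]])
  wsec <- raw[["wall"]] %||% list()
  wall <- wall_params(
    Fmax = .cfg_num(wsec, "Fmax_N", 9.6e-12),
    x0 = .cfg_num(wsec, "x0_m", 2e-9),
    lC = .cfg_num(wsec, "lC_m", -3e-10),
    variant = wsec[["wall_variant"]] %||% "anti_return"
  )
  ssec <- raw[["sim"]] %||% list()
  sim <- sim_config(
    dt = to_si(.cfg_num(ssec, "dt_ns", 10), "ns"),
    n_runs = as.integer(.cfg_num(ssec, "n_runs", 50000)),
    t_max = to_si(.cfg_num(ssec, "t_max_ms", 5), "ms"),
    x_start = to_si(.cfg_num(ssec, "x_start_nm", 0), "nm"),
    interpolate_crossing = .cfg_bool(ssec, "interpolate_crossing", FALSE),
    seed = .cfg_num(ssec, "seed", 1)
  )
  list(cleft1 = c1, cleft2 = c2, wall = wall, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
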