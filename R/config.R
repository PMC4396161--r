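#' Default simulation configuration
#'
#' The full standard parameter set of the coupled model: myocardium
#' membrane constants (`Cm = 2` uF/cm^2, `S = 0.2` um^-1,
#' `rho = 162` Ohm*cm, `phi_rest = 0`, `phi0 = -80` mV), the six-species
#' table (see [species_table()]), suicide-substrate rate constants
#' (`k1 = 2, k_1 = 4, k2 = 12, k3 = 10, k4 = 2` s^-1,
#' `e0 = s0 = 0.5` uM), a single -200 uA/cm^2 pulse of 1 ms starting at
#' `t = 120e-5` s at the cell centre, time stepping `dt = 1e-5` s to
#' `T = 0.006` s, and an ellipse mesh with semi-axes `a = 2`, `b = 1` at
#' target mesh size `h = 0.15`.
#'
#' @return A nested list of class `run_config` with sections `constants`,
#'   `species`, `kinetics`, `stimulus`, `time`, `mesh`, `output`, `seed`.
#' @export
default_run_config <- function() {
  sp <- species_table()
  structure(list(
    constants = list(Cm = 2.0, S = 0.2, rho = 162,
                     phi_rest = 0, phi0 = -80, Fa = 1, R = 1, Te = 1,
                     g_leak = 0),
    species = lapply(seq_len(nrow(sp)), function(i) {
      list(name = sp$name[i], d = sp$d[i], z = sp$z[i], c0 = sp$c0[i])
    }),
    kinetics = list(k1 = 2, k_1 = 4, k2 = 12, k3 = 10, k4 = 2),
    stimulus = list(kind = "pulse", amplitude = -200, onset = 120e-5,
                    duration = 1e-3, center = c(0, 0), sharpness = 1000,
                    frequency = NULL),
    time = list(dt = 1e-5, T = 0.006, picard_tol = 1e-10, picard_max = 50L),
    mesh = list(a = 2, b = 1, h = 0.15),
    output = list(probes = list(c(0, 0)), snapshot_every = 0L,
                  format = "vtk"),
    seed = 1L
  ), class = "run_config")
}

.merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("load_config: unknown configuration key '", full, "'",
           call. = FALSE)
    }
    bv <- base[[key]]
    uv <- user[[key]]
    if (key %in% c("species", "probes")) {
      base[[key]] <- uv                 # whole-list replacement sections
    } else if (is.list(bv) && is.list(uv)) {
      base[[key]] <- .merge_config(bv, uv, full)
    } else {
      base[[key]] <- uv
    }
  }
  base
}

#' Load (and validate) a simulation configuration
#'
#' Reads a YAML configuration file and merges it over the defaults of
#' [default_run_config()]: an empty file yields the full default
#' configuration, unknown keys are rejected by name, and the result is
#' checked by [validate_run_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  if (!is.null(user)) {
    if (!is.list(user)) stop("load_config: top level must be a mapping", call. = FALSE)
    cfg <- .merge_config(unclass(cfg), user)
    class(cfg) <- "run_config"
  }
  validate_run_config(cfg)
}

#' Save a simulation configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- validate_run_config(config)
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Validate a simulation configuration
#'
#' Checks positivity and cross-field consistency: the species count must
#' match the arity of the kinetic network (6), every probe must lie inside
#' the elliptical domain, and all solver settings must be admissible.
#' Errors name the offending key.
#'
#' @param config a `run_config` (or plain nested list with the same shape).
#' @return The validated config (class `run_config`), invisibly usable.
#' @export
validate_run_config <- function(config) {
  cfg <- unclass(config)
  need <- c("constants", "species", "kinetics", "stimulus", "time",
            "mesh", "output")
  for (s in need) {
    if (is.null(cfg[[s]])) stop("config: missing section '", s, "'", call. = FALSE)
  }
  # delegated constructors perform the per-field checks
  do.call(physical_constants, cfg$constants)
  do.call(suicide_params, cfg$kinetics)
  sp <- config_species(config)
  if (nrow(sp) != 6L) {
    stop("config: species count (", nrow(sp),
         ") does not match the 6-species kinetic network", call. = FALSE)
  }
  stim <- cfg$stimulus
  proto <- do.call(stimulus_protocol, stim)
  cfg$stimulus$frequency <- proto$frequency   # normalise the NULL default
  tm <- cfg$time
  if (!is.finite(tm$dt) || tm$dt <= 0) stop("config: time.dt must be > 0", call. = FALSE)
  if (!is.finite(tm$T) || tm$T < 0) stop("config: time.T must be >= 0", call. = FALSE)
  if (!is.finite(tm$picard_tol) || tm$picard_tol <= 0) {
    stop("config: time.picard_tol must be > 0", call. = FALSE)
  }
  if (tm$picard_max < 1) stop("config: time.picard_max must be >= 1", call. = FALSE)
  ms <- cfg$mesh
  if (!(ms$a >= ms$b) || ms$b <= 0) stop("config: mesh requires a >= b > 0", call. = FALSE)
  if (ms$h <= 0 || ms$h >= ms$b) stop("config: mesh.h must satisfy 0 < h < b", call. = FALSE)
  for (p in cfg$output$probes) {
    if (length(p) != 2L || (p[1L] / ms$a)^2 + (p[2L] / ms$b)^2 > 1 + 1e-12) {
      stop("config: output.probes entry (", paste(p, collapse = ", "),
           ") lies outside the elliptical domain", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$output$snapshot_every) || cfg$output$snapshot_every < 0) {
    stop("config: output.snapshot_every must be >= 0", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Species table of a configuration
#'
#' @param config a `run_config`.
#' @return The configuration's species as a [species_table()] data.frame.
#' @export
config_species <- function(config) {
  sp <- config$species
  species_table(name = vapply(sp, `[[`, "", "name"),
                d = vapply(sp, function(x) as.numeric(x$d), 0),
                z = vapply(sp, function(x) as.numeric(x$z), 0),
                c0 = vapply(sp, function(x) as.numeric(x$c0), 0))
}
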