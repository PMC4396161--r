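#' Stimulation protocol
#'
#' Describes the external stimulus current applied at a point of the cell
#' (spatially mollified as `exp(-sharpness * |x - center|^2)`). Three time
#' courses are supported inside the window `[onset, onset + duration]`:
#' \describe{
#'   \item{pulse}{constant `amplitude` (default: a 1 ms pulse of
#'     -200 uA/cm^2 starting at t = 120e-5 s);}
#'   \item{alternating}{`amplitude * (-1)^step_index`, the sign flipping at
#'     every time step;}
#'   \item{sinusoidal}{`amplitude * sin(frequency * (t - onset))`, by
#'     default one full period over the stimulus duration.}
#' }
#'
#' @param kind one of `"pulse"`, `"alternating"`, `"sinusoidal"`.
#' @param amplitude stimulus strength (uA/cm^2).
#' @param onset stimulus start time (s), >= 0.
#' @param duration stimulus length (s), > 0.
#' @param center 2D stimulation site (default the cell centre, the origin).
#' @param sharpness spatial Gaussian decay rate (default 1000).
#' @param frequency angular frequency (rad/s) for the sinusoidal kind;
#'   default `2*pi/duration`.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(kind = c("pulse", "alternating", "sinusoidal"),
                              amplitude = -200, onset = 120e-5,
                              duration = 1e-3, center = c(0, 0),
                              sharpness = 1000, frequency = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(onset) || onset < 0) stop("stimulus_protocol: onset must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0) stop("stimulus_protocol: duration must be > 0", call. = FALSE)
  if (!is.finite(sharpness) || sharpness <= 0) stop("stimulus_protocol: sharpness must be > 0", call. = FALSE)
  if (length(center) != 2L || any(!is.finite(center))) {
    stop("stimulus_protocol: center must be a finite 2D point", call. = FALSE)
  }
  if (is.null(frequency)) frequency <- 2 * pi / duration
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 duration = duration, center = as.numeric(center),
                 sharpness = sharpness, frequency = frequency),
            class = "stimulus_protocol")
}

#' Stimulus amplitude at a given time
#'
#' Zero outside `[onset, onset + duration]`; inside, the value prescribed
#' by the protocol kind (see [stimulus_protocol()]). The alternating kind
#' depends on the solver's `step_index` (sign flips each step).
#'
#' @param protocol a `stimulus_protocol`.
#' @param t time (s), >= 0; vectorised.
#' @param step_index integer time-step counter (alternating kind).
#' @return Stimulus current value(s).
#' @export
stim_amplitude <- function(protocol, t, step_index = 0L) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (any(t < 0)) stop("stim_amplitude: t must be >= 0", call. = FALSE)
  inside <- t >= protocol$onset & t <= protocol$onset + protocol$duration
  val <- switch(protocol$kind,
    pulse = rep_len(protocol$amplitude, length(t)),
    alternating = protocol$amplitude * (-1)^(rep_len(step_index, length(t))),
    sinusoidal = protocol$amplitude *
      sin(protocol$frequency * (t - protocol$onset)),
    stop("stim_amplitude: unknown stimulus kind", call. = FALSE))
  ifelse(inside, val, 0)
}

#' Assembled stimulus load at a given time
#'
#' The spatial Gaussian point-source load (see [assemble_point_source()])
#' scaled by [stim_amplitude()]. The purely spatial part can be
#' precomputed once and passed via `base_load` (the solver does this).
#'
#' @param protocol a `stimulus_protocol`.
#' @param mesh a `triangle_mesh` (ignored when `base_load` is given).
#' @param t time (s).
#' @param step_index integer time-step counter.
#' @param base_load optional precomputed spatial load vector.
#' @return Nodal load vector.
#' @export
stim_field <- function(protocol, mesh, t, step_index = 0L, base_load = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (is.null(base_load)) {
    base_load <- assemble_point_source(mesh, center = protocol$center,
                                       sharpness = protocol$sharpness)
  }
  stim_amplitude(protocol, t, step_index) * base_load
}
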