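#' Rate constants of the suicide-substrate mechanism
#'
#' The mechanism-based (suicide-substrate) inhibition scheme
#' `E + S <-> X -> Y`, with `Y -> E + P` (productive, rate k3) or
#' `Y -> Ei` (inactivating, rate k4), is parameterised by five positive
#' rate constants. Defaults are the standard configuration
#' `k1 = 2, k_1 = 4, k2 = 12, k3 = 10, k4 = 2` (s^-1 scale).
#'
#' @param k1 forward binding rate E + S -> X.
#' @param k_1 dissociation rate X -> E + S.
#' @param k2 conversion rate X -> Y.
#' @param k3 productive turnover rate Y -> E + P.
#' @param k4 inactivation rate Y -> Ei.
#' @return An object of class `suicide_params`.
#' @examples
#' suicide_params()
#' @export
suicide_params <- function(k1 = 2, k_1 = 4, k2 = 12, k3 = 10, k4 = 2) {
  ks <- c(k1 = k1, k_1 = k_1, k2 = k2, k3 = k3, k4 = k4)
  if (!all(is.finite(ks)) || any(ks <= 0)) {
    stop("suicide_params: all rate constants must be strictly positive",
         call. = FALSE)
  }
  structure(as.list(ks), class = "suicide_params")
}

.species_names <- c("E", "S", "X", "Y", "P", "Ei")

#' Mass-action production rates of the suicide-substrate system
#'
#' Applies the law of mass action to the inhibition scheme, giving one
#' production rate per reactant in the fixed order (E, S, X, Y, P, Ei):
#' \deqn{F_E = -k_1 e s + k_{-1} x + k_3 y,\quad F_S = -k_1 e s + k_{-1} x,}
#' \deqn{F_X = k_1 e s - (k_{-1}+k_2) x,\quad F_Y = k_2 x - (k_3+k_4) y,}
#' \deqn{F_P = k_3 y,\quad F_{Ei} = k_4 y.}
#' Both conserved moieties follow algebraically:
#' `F_E + F_X + F_Y + F_Ei = 0` (enzyme) and
#' `F_S + F_X + F_Y + F_P + F_Ei = 0` (substrate; the inactivated
#' complex Ei retains the substrate-derived inhibitor, so it belongs to
#' both moieties).
#'
#' @param conc concentrations: a length-6 vector or an n x 6 matrix
#'   (columns E, S, X, Y, P, Ei), all non-negative.
#' @param params a [suicide_params()] object.
#' @return Rates with the same shape as `conc`.
#' @export
reaction_rates <- function(conc, params) {
  stopifnot(inherits(params, "suicide_params"))
  vec <- is.null(dim(conc))
  Cm <- if (vec) matrix(conc, nrow = 1L) else as.matrix(conc)
  if (ncol(Cm) != 6L) stop("reaction_rates: expected 6 species", call. = FALSE)
  if (any(!is.finite(Cm))) stop("reaction_rates: non-finite concentration", call. = FALSE)
  if (any(Cm < 0)) {
    stop("reaction_rates: negative concentration (clipping is the caller's policy)",
         call. = FALSE)
  }
  e <- Cm[, 1L]; s <- Cm[, 2L]; x <- Cm[, 3L]; y <- Cm[, 4L]
  p <- params
  bind <- p$k1 * e * s
  Fm <- cbind(-bind + p$k_1 * x + p$k3 * y,
              -bind + p$k_1 * x,
              bind - (p$k_1 + p$k2) * x,
              p$k2 * x - (p$k3 + p$k4) * y,
              p$k3 * y,
              p$k4 * y)
  colnames(Fm) <- .species_names
  if (vec) Fm[1L, ] else Fm
}

#' Analytic Jacobian of the reaction rates
#'
#' 6 x 6 matrix of partial derivatives of [reaction_rates()] with respect
#' to the six concentrations, used by Newton variants of the implicit
#' transport step and validated against finite differences in the test
#' suite.
#'
#' @param conc length-6 concentration vector.
#' @param params a [suicide_params()] object.
#' @return A 6 x 6 numeric matrix (rows: rates, columns: species).
#' @export
reaction_jacobian <- function(conc, params) {
  stopifnot(inherits(params, "suicide_params"), length(conc) == 6L)
  e <- conc[1L]; s <- conc[2L]
  p <- params
  J <- matrix(0, 6L, 6L, dimnames = list(.species_names, .species_names))
  J["E", ]  <- c(-p$k1 * s, -p$k1 * e,  p$k_1,            p$k3,         0, 0)
  J["S", ]  <- c(-p$k1 * s, -p$k1 * e,  p$k_1,            0,            0, 0)
  J["X", ]  <- c( p$k1 * s,  p$k1 * e, -(p$k_1 + p$k2),   0,            0, 0)
  J["Y", ]  <- c( 0,         0,         p$k2,            -(p$k3 + p$k4), 0, 0)
  J["P", ]  <- c( 0,         0,         0,                p$k3,          0, 0)
  J["Ei", ] <- c( 0,         0,         0,                p$k4,          0, 0)
  J
}

#' Partition ratio r = k3/k4
#'
#' Ratio of productive turnover to inactivation from the committed
#' intermediate Y; the key dimensionless number of suicide-substrate
#' kinetics.
#'
#' @param params a [suicide_params()] object.
#' @return Scalar `r`.
#' @export
partition_ratio <- function(params) {
  stopifnot(inherits(params, "suicide_params"))
  params$k3 / params$k4
}

#' Predicted long-time outcome of a suicide-substrate reaction
#'
#' Computes `mu = e0/s0` and the Tatsunami factor `(1+r)*mu`: when it
#' exceeds 1 the substrate is exhausted before the enzyme is fully
#' inactivated; below 1 all the enzyme is inactivated; at exactly 1 both
#' occur. The Waley factor `r*mu` is reported alongside.
#'
#' @param r partition ratio (or a `suicide_params` object).
#' @param e0 initial enzyme concentration, > 0.
#' @param s0 initial substrate concentration, > 0.
#' @return A list with `outcome` (one of `"substrate_exhausted"`,
#'   `"enzyme_inactivated"`, `"boundary"`), `tatsunami`, `waley`, `mu`, `r`.
#' @examples
#' classify_outcome(5, 0.5, 0.5)  # (1+5)*1 = 6 -> substrate exhausted
#' @export
classify_outcome <- function(r, e0, s0) {
  if (inherits(r, "suicide_params")) r <- partition_ratio(r)
  if (!is.finite(s0) || s0 <= 0) stop("classify_outcome: s0 must be > 0", call. = FALSE)
  if (!is.finite(e0) || e0 <= 0) stop("classify_outcome: e0 must be > 0", call. = FALSE)
  if (!is.finite(r) || r < 0) stop("classify_outcome: r must be >= 0", call. = FALSE)
  mu <- e0 / s0
  ta <- (1 + r) * mu
  outcome <- if (ta > 1) "substrate_exhausted"
             else if (ta < 1) "enzyme_inactivated"
             else "boundary"
  list(outcome = outcome, tatsunami = ta, waley = r * mu, mu = mu, r = r)
}

#' Well-mixed (zero-dimensional) reference integration
#'
#' Classical fixed-step fourth-order Runge-Kutta integration of the
#' mass-action ODE system `dC/dt = F(C)`. This is the spatially uniform
#' limit of the PDE model and serves as the reference oracle for the
#' coupled solver. A step-halving (Richardson) error estimate at the final
#' time is attached, along with an empirical outcome classification
#' (substrate exhausted / enzyme inactivated) using the operational
#' thresholds `s(T) < 1e-3 * s0` and `e + x + y < 1e-3 * e0`.
#'
#' @param params a [suicide_params()] object.
#' @param init length-6 non-negative initial concentrations (E,S,X,Y,P,Ei).
#' @param T final time, `>= dt`.
#' @param dt time step, > 0.
#' @param keep_every store every k-th step in the returned trajectory
#'   (the final state is always stored exactly).
#' @return A list of class `well_mixed_run`: `trajectory` (data.frame with
#'   `time` and the six species), `final`, `error_estimate` (max abs
#'   endpoint difference vs a half-step run), `outcome`.
#' @examples
#' run <- simulate_well_mixed(suicide_params(), c(0.5, 0.5, 0, 0, 0, 0),
#'                            T = 25, dt = 5e-3)
#' run$outcome
#' @export
simulate_well_mixed <- function(params, init = c(0.5, 0.5, 0, 0, 0, 0),
                                T = 25, dt = 1e-3, keep_every = 10L) {
  stopifnot(inherits(params, "suicide_params"))
  if (!is.finite(dt) || dt <= 0 || !is.finite(T) || T < dt) {
    stop("simulate_well_mixed: require dt > 0 and T >= dt", call. = FALSE)
  }
  if (length(init) != 6L || any(init < 0)) {
    stop("simulate_well_mixed: init must be 6 non-negative concentrations",
         call. = FALSE)
  }
  run_rk4 <- function(h) {
    nstep <- ceiling(T / h)
    u <- as.numeric(init)
    keep <- max(1L, as.integer(keep_every))
    nkeep <- nstep %/% keep + 2L
    out <- matrix(NA_real_, nkeep, 7L)
    out[1L, ] <- c(0, u)
    row <- 1L
    f <- function(v) reaction_rates(pmax(v, 0), params)
    for (n in seq_len(nstep)) {
      k1 <- f(u)
      k2 <- f(u + h / 2 * k1)
      k3 <- f(u + h / 2 * k2)
      k4 <- f(u + h * k3)
      u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(u))) {
        stop("simulate_well_mixed: integration blew up (NaN) at t = ",
             format(n * h), call. = FALSE)
      }
      if (n %% keep == 0L || n == nstep) {
        row <- row + 1L
        out[row, ] <- c(n * h, u)
      }
    }
    list(traj = out[seq_len(row), , drop = FALSE], final = u)
  }
  full <- run_rk4(dt)
  half <- run_rk4(dt / 2)
  err <- max(abs(full$final - half$final))
  traj <- as.data.frame(full$traj)
  names(traj) <- c("time", .species_names)
  fin <- full$final
  names(fin) <- .species_names
  s0 <- init[2L]; e0 <- init[1L]
  s_gone <- s0 > 0 && fin[["S"]] < 1e-3 * s0
  e_gone <- e0 > 0 && (fin[["E"]] + fin[["X"]] + fin[["Y"]]) < 1e-3 * e0
  outcome <- if (s_gone && !e_gone) "substrate_exhausted"
             else if (e_gone && !s_gone) "enzyme_inactivated"
             else if (s_gone && e_gone) "boundary"
             else "incomplete"
  structure(list(trajectory = traj, final = fin, error_estimate = err,
                 outcome = outcome, params = params, dt = dt, T = T),
            class = "well_mixed_run")
}
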