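#' Mesh-weighted L2 error of a nodal field
#'
#' `sqrt(e' M e)` where `e` is the nodal difference between a computed
#' field and a reference (a function of `(x, y)` or a nodal vector) and
#' `M` is the consistent P1 mass matrix. This is the spatial error norm
#' used by all convergence reports in the package.
#'
#' @param mesh a `triangle_mesh`.
#' @param values nodal field values.
#' @param exact reference: either `function(x, y)` or a nodal vector
#'   (default 0, giving the plain L2 norm).
#' @param M optional precomputed mass matrix.
#' @return Scalar L2 error.
#' @export
l2_error <- function(mesh, values, exact = 0, M = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- nrow(mesh$nodes)
  if (length(values) != n) stop("l2_error: field length != node count", call. = FALSE)
  ref <- if (is.function(exact)) exact(mesh$nodes[, 1L], mesh$nodes[, 2L])
         else rep_len(exact, n)
  e <- values - ref
  if (is.null(M)) M <- assemble_mass(mesh)
  sqrt(max(0, sum(e * as.vector(M %*% e))))
}

#' Convergence order from a sequence of (h, error) pairs
#'
#' Least-squares slope of `log(error)` against `log(h)`; with exactly two
#' points this reduces to the classical two-point formula
#' `log(e1/e2) / log(h1/h2)`.
#'
#' @param h mesh sizes (positive, decreasing).
#' @param err errors (positive).
#' @return Fitted order (scalar).
#' @export
fitted_order <- function(h, err) {
  stopifnot(length(h) == length(err), length(h) >= 2L,
            all(h > 0), all(err > 0))
  as.numeric(stats::coef(stats::lm(log(err) ~ log(h)))[2L])
}

#' Manufactured-solution spatial convergence study
#'
#' Verifies the spatial accuracy of the P1 Galerkin discretisation on the
#' pure-diffusion subproblem using the method of manufactured solutions:
#' the smooth field `u(x,y,t) = exp(-t/2) cos(0.9 x) cos(0.7 y)` is made
#' an exact solution of `u_t = D Lap(u) + S` by injecting the compensating
#' source `S = (D (0.9^2 + 0.7^2) - 1/2) u`, with the exact trace imposed
#' as a Dirichlet boundary value. Each level is integrated by backward
#' Euler with `dt` refined proportionally to `h^2`, so the O(dt) time
#' error matches the expected O(h^2) spatial error and the fitted
#' log-log slope measures the spatial order (2 for P1 elements).
#'
#' @param h_levels decreasing mesh-size targets (default
#'   `c(0.2, 0.15, 0.1)`); at least 3 recommended.
#' @param a,b ellipse semi-axes of the domain.
#' @param D diffusion coefficient of the subproblem (default 1).
#' @param T final time (default 0.05).
#' @param dt_coarse time step at the coarsest level (refined as
#'   `dt_coarse * (h/h[1])^2`); default `T/40`.
#' @return A list of class `convergence_report`: `table` (data.frame with
#'   `h_target`, `h_achieved`, `dt`, `error`, `error_max`), `order`
#'   (fitted), `norm`, `monotone` (logical flag; `FALSE` signals a
#'   non-asymptotic regime).
#' @export
mms_convergence_study <- function(h_levels = c(0.2, 0.15, 0.1),
                                  a = 2, b = 1, D = 1,
                                  T = 0.05, dt_coarse = T / 40) {
  stopifnot(length(h_levels) >= 2L, all(diff(h_levels) < 0))
  kx <- 0.9; ky <- 0.7
  uex <- function(x, y, t) exp(-t / 2) * cos(kx * x) * cos(ky * y)
  src_coeff <- D * (kx^2 + ky^2) - 1 / 2

  rows <- vector("list", length(h_levels))
  for (lev in seq_along(h_levels)) {
    h <- h_levels[lev]
    dt <- dt_coarse * (h / h_levels[1L])^2
    mesh <- ellipse_mesh(a, b, h)
    M <- assemble_mass(mesh)
    K <- assemble_stiffness(mesh, D)
    Sys <- M + dt * K
    bnd <- mesh$boundary_nodes
    Sys_bcols <- Sys[, bnd, drop = FALSE]
    Sysd <- Sys
    Sysd[bnd, ] <- 0
    Sysd[, bnd] <- 0
    dg <- Matrix::diag(Sysd)
    dg[bnd] <- 1
    Matrix::diag(Sysd) <- dg
    lu <- Matrix::lu(methods::as(Sysd, "CsparseMatrix"))
    x <- mesh$nodes[, 1L]; y <- mesh$nodes[, 2L]
    u <- uex(x, y, 0)
    nstep <- as.integer(ceiling(T / dt - 1e-12))
    err_max <- 0
    for (n in seq_len(nstep)) {
      t1 <- n * dt
      s_nodal <- src_coeff * uex(x, y, t1)
      rhs <- as.vector(M %*% u) + dt * as.vector(M %*% s_nodal)
      g <- uex(x[bnd], y[bnd], t1)
      rhs <- rhs - as.vector(Sys_bcols %*% g)
      rhs[bnd] <- g
      u <- as.vector(Matrix::solve(lu, rhs))
      err_max <- max(err_max,
                     l2_error(mesh, u, uex(x, y, t1), M = M))
    }
    errT <- l2_error(mesh, u, uex(x, y, nstep * dt), M = M)
    rows[[lev]] <- data.frame(h_target = h, h_achieved = mesh_size(mesh),
                              dt = dt, error = errT, error_max = err_max)
  }
  tab <- do.call(rbind, rows)
  ord <- fitted_order(tab$h_achieved, tab$error)
  structure(list(table = tab, order = ord, norm = "L2 at final time",
                 monotone = all(diff(tab$error) < 0)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("MMS convergence study (", x$norm, "):\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("fitted order:", format(x$order, digits = 4),
      if (!x$monotone) " [warning: errors not monotone -- non-asymptotic regime]" else "",
      "\n")
  invisible(x)
}

#' Time-step stability study
#'
#' Runs the full coupled scenario on one fixed mesh for a sequence of
#' decreasing time steps and reports the pairwise max-norm differences of
#' the final-time fields between consecutive time steps, together with
#' their ratios: a stable, convergent scheme shows small differences that
#' shrink as `dt` decreases.
#'
#' @param config a `run_config` (default [default_run_config()]).
#' @param dts decreasing time steps (default `c(1e-5, 5e-6, 2.5e-6)` s).
#' @return A list of class `stability_report`: `dts`, `table` (data.frame
#'   with `dt_coarse`, `dt_fine`, `dphi_max`, `dC_max`), `ratios`
#'   (consecutive `dphi_max` ratios), `runs` (final `system_state` per dt).
#' @export
stability_study <- function(config = default_run_config(),
                            dts = c(1e-5, 5e-6, 2.5e-6)) {
  stopifnot(length(dts) >= 2L, all(diff(dts) < 0))
  cfg <- validate_run_config(config)
  sys <- build_system(cfg)
  finals <- vector("list", length(dts))
  for (i in seq_along(dts)) {
    sy <- sys
    sy$config$time$dt <- dts[i]
    finals[[i]] <- run_simulation(sy$config, sys = sy)$final_state
  }
  rows <- lapply(seq_len(length(dts) - 1L), function(i) {
    data.frame(dt_coarse = dts[i], dt_fine = dts[i + 1L],
               dphi_max = max(abs(finals[[i]]$phi - finals[[i + 1L]]$phi)),
               dC_max = max(abs(finals[[i]]$C - finals[[i + 1L]]$C)))
  })
  tab <- do.call(rbind, rows)
  ratios <- if (nrow(tab) >= 2L) tab$dphi_max[-1L] / tab$dphi_max[-nrow(tab)]
            else numeric(0)
  structure(list(dts = dts, table = tab, ratios = ratios, runs = finals),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Time-step stability study:\n")
  print(x$table, row.names = FALSE)
  if (length(x$ratios)) {
    cat("difference ratios (should be < 1):",
        paste(format(x$ratios, digits = 3), collapse = ", "), "\n")
  }
  invisible(x)
}

.ap_metrics <- function(t, dev, half_level = 0.5, plateau_level = 0.95) {
  peak <- max(abs(dev))
  ipk <- which.max(abs(dev))
  if (peak == 0) {
    return(list(peak_deviation = 0, peak_phi_deviation = 0,
                time_to_peak = NA_real_, duration = 0,
                plateau_fraction = 0, repolarized = TRUE))
  }
  above <- abs(dev) >= half_level * peak
  idx <- which(above)
  dur <- t[idx[length(idx)]] - t[idx[1L]]
  top <- abs(dev) >= plateau_level * peak
  # time within 5% of peak, as a fraction of the AP duration
  tw <- if (sum(top) > 1L) sum(diff(t)[top[-length(top)] & top[-1L]]) else 0
  plateau <- if (dur > 0) tw / dur else 0
  list(peak_deviation = peak,
       peak_phi_deviation = dev[ipk],
       time_to_peak = t[ipk],
       duration = dur,
       plateau_fraction = min(1, plateau),
       repolarized = abs(dev[length(dev)]) < half_level * peak)
}

#' Electrophysiological validation: excitability, all-or-none, morphology
#'
#' Runs the three classical single-cell validation checks on the coupled
#' model:
#' \describe{
#'   \item{excitability}{with the stimulus turned off, the centre-probe
#'     potential must stay at its resting trajectory (within `rest_tol`
#'     mV of the initial potential) for the entire run;}
#'   \item{all-or-none}{an action potential is declared when the probe
#'     deviation from the no-stimulus baseline reaches at least half the
#'     peak deviation of the full-amplitude (supra-threshold) run; the
#'     threshold amplitude is located by bisection between 0 and the
#'     configured amplitude, and a half-threshold stimulus must produce
#'     no AP;}
#'   \item{morphology}{AP shape metrics of the supra-threshold run; a
#'     triangular AP (no sustained plateau) has `plateau_fraction`
#'     (time within 5 percent of peak over AP duration) below 0.2.}
#' }
#'
#' @param config a `run_config` (default [default_run_config()]).
#' @param rest_tol rest tolerance (mV, default 0.5).
#' @param bisect_iters bisection iterations for the threshold (default 7).
#' @return A list of class `ep_validation`: `excitable`,
#'   `ap_at_full_amplitude`, `threshold_amplitude`,
#'   `no_ap_at_half_threshold`, `metrics` (AP morphology of the supra
#'   run), `baseline_drift`, plus the probe series of the baseline and
#'   supra runs.
#' @export
validate_electrophysiology <- function(config = default_run_config(),
                                       rest_tol = 0.5, bisect_iters = 7L) {
  cfg <- validate_run_config(config)
  sys <- build_system(cfg)
  run_amp <- function(amp) {
    sy <- sys
    sy$config$stimulus$amplitude <- amp
    sy$stimulus$amplitude <- amp
    run_simulation(sy$config, sys = sy)
  }
  base <- run_amp(0)
  supra <- run_amp(cfg$stimulus$amplitude)
  tb <- base$probes[[1L]]$t
  phib <- base$probes[[1L]]$phi
  phis <- supra$probes[[1L]]$phi
  baseline_drift <- max(abs(phib - phib[1L]))
  excitable <- baseline_drift < rest_tol
  dev_supra <- phis - phib
  peak_supra <- max(abs(dev_supra))
  onset <- cfg$stimulus$onset
  pre <- tb < onset
  quiescent_before_onset <- max(abs(dev_supra[pre])) < 0.5 * peak_supra
  has_ap <- function(run) {
    max(abs(run$probes[[1L]]$phi - phib)) >= 0.5 * peak_supra
  }
  lo <- 0; hi <- abs(cfg$stimulus$amplitude)
  sgn <- sign(cfg$stimulus$amplitude)
  for (k in seq_len(bisect_iters)) {
    mid <- (lo + hi) / 2
    if (has_ap(run_amp(sgn * mid))) hi <- mid else lo <- mid
  }
  threshold <- sgn * hi
  half <- run_amp(threshold / 2)
  metrics <- .ap_metrics(tb, dev_supra)
  structure(list(excitable = excitable,
                 baseline_drift = baseline_drift,
                 quiescent_before_onset = quiescent_before_onset,
                 ap_at_full_amplitude = peak_supra > 0,
                 threshold_amplitude = threshold,
                 no_ap_at_half_threshold = !has_ap(half),
                 metrics = metrics,
                 baseline_probe = base$probes[[1L]],
                 supra_probe = supra$probes[[1L]]),
            class = "ep_validation")
}

#' @export
print.ep_validation <- function(x, ...) {
  cat("Electrophysiological validation:\n")
  cat("  excitable (rest without stimulus):", x$excitable,
      "(baseline drift", format(x$baseline_drift, digits = 3), "mV)\n")
  cat("  AP at full amplitude:", x$ap_at_full_amplitude,
      "; threshold ~", format(x$threshold_amplitude, digits = 4), "\n")
  cat("  no AP at half threshold:", x$no_ap_at_half_threshold, "\n")
  m <- x$metrics
  cat("  morphology: peak dev", format(m$peak_phi_deviation, digits = 4),
      "mV at t =", format(m$time_to_peak),
      "; plateau fraction", format(m$plateau_fraction, digits = 3),
      "; repolarized:", m$repolarized, "\n")
  invisible(x)
}
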