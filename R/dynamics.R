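#' Assemble the discrete coupled system for a configuration
#'
#' Builds (or reuses) the mesh, precomputes the P1 operators (mass,
#' stiffness, stimulus load), the boundary/interior node split with a
#' cached Cholesky factorisation of the interior mass matrix, and all
#' derived physical parameters: the cable diffusion coefficient (in
#' cm^2/s, the solver's time unit being the second), the per-species
#' Einstein mobilities and the ionic-current coefficient `Fa/Cm`.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param mesh optional pre-built `triangle_mesh` (otherwise generated
#'   from the config's `mesh` section).
#' @return A list of class `npcable_system` holding the operators and
#'   parameters consumed by the stepping routines.
#' @export
build_system <- function(config, mesh = NULL) {
  cfg <- validate_run_config(config)
  pc <- do.call(physical_constants, cfg$constants)
  sp <- config_species(cfg)
  kin <- do.call(suicide_params, cfg$kinetics)
  stim <- do.call(stimulus_protocol, cfg$stimulus)
  if (is.null(mesh)) mesh <- ellipse_mesh(cfg$mesh$a, cfg$mesh$b, cfg$mesh$h)
  geom <- fem_geometry(mesh)
  M <- assemble_mass(mesh)
  K <- assemble_stiffness(mesh, 1)
  bload <- assemble_point_source(mesh, stim$center, stim$sharpness)
  n <- nrow(mesh$nodes)
  bnd <- mesh$boundary_nodes
  free <- setdiff(seq_len(n), bnd)
  cholMff <- Matrix::Cholesky(Matrix::forceSymmetric(M[free, free]))
  D <- cable_diffusion(pc$rho, pc$S, pc$Cm, unit = "cm2_per_s")
  mob <- einstein_mobility(sp$d, sp$z, pc$Fa, pc$R, pc$Te)
  structure(list(config = cfg, constants = pc, species = sp, kinetics = kin,
                 stimulus = stim, mesh = mesh, geom = geom,
                 M = M, K = K, bload = bload,
                 trip = .tri_rows(geom$tri),
                 mvals = .mass_vals(geom), kvals = .stiffness_vals(geom),
                 hmin = min(.element_diameters(mesh)),
                 n = n, bnd = bnd, free = free, cholMff = cholMff,
                 D = D, mob = mob, ionic_coeff = pc$Fa / pc$Cm),
            class = "npcable_system")
}

#' Initial system state
#'
#' Potential set to `phi0` in the interior and to `phi_rest` on the
#' boundary (the Dirichlet value); concentrations spatially uniform at the
#' species' initial values.
#'
#' @param sys an `npcable_system` from [build_system()].
#' @return A list of class `system_state`: `t`, `step_index`, `phi`
#'   (nodal), `C` (nodes x 6 matrix).
#' @export
initial_state <- function(sys) {
  stopifnot(inherits(sys, "npcable_system"))
  phi <- rep(sys$constants$phi0, sys$n)
  phi[sys$bnd] <- sys$constants$phi_rest
  C <- matrix(rep(sys$species$c0, each = sys$n), sys$n, 6L)
  colnames(C) <- sys$species$name
  structure(list(t = 0, step_index = 0L, phi = phi, C = C),
            class = "system_state")
}

#' Right-hand side of the semi-discrete potential equation
#'
#' Weak-form Galerkin right-hand side of
#' `dphi/dt = D Lap(phi) - (Fa/Cm) sum_i z_i F_i(C) + (1/Cm) I_stim(t) f(x)`
#' with `phi` held at the Dirichlet boundary value: the returned nodal
#' time derivative solves the interior consistent-mass system and is zero
#' on the boundary.
#'
#' @param sys an `npcable_system`.
#' @param phi nodal potential.
#' @param C nodes x 6 concentration matrix.
#' @param t time (s).
#' @param step_index integer step counter (alternating stimulus).
#' @return Nodal `dphi/dt` vector.
#' @export
potential_rhs <- function(sys, phi, C, t, step_index = 0L) {
  pc <- sys$constants
  Fmat <- reaction_rates(pmax(C, 0), sys$kinetics)
  ionic <- sys$ionic_coeff * drop(Fmat %*% sys$species$z)
  if (pc$g_leak > 0) {
    ionic <- ionic + (pc$g_leak / pc$Cm) * (phi - pc$phi_rest)
  }
  amp <- stim_amplitude(sys$stimulus, t, step_index)
  r <- as.vector(-sys$D * (sys$K %*% phi)) -
       as.vector(sys$M %*% ionic) +
       (amp / pc$Cm) * sys$bload
  dphi <- numeric(sys$n)
  dphi[sys$free] <- as.vector(Matrix::solve(sys$cholMff, r[sys$free]))
  dphi
}

#' Explicit second-order Runge-Kutta (Heun) potential step
#'
#' `phi* = phi + dt * Phi(phi)`, `phi_new = phi + dt/2 (Phi(phi) + Phi(phi*))`,
#' with the boundary value re-imposed after each stage and the
#' concentrations held at their start-of-step values. Warns when `dt`
#' exceeds a simple explicit-diffusion (CFL-type) bound; errors on NaN
#' blow-up.
#'
#' @param sys an `npcable_system`.
#' @param state a `system_state`.
#' @param dt time step (s).
#' @return The nodal potential at the end of the step.
#' @export
rk2_potential_step <- function(sys, state, dt) {
  phi <- state$phi
  if (dt > sys$hmin^2 / (2 * sys$D)) {
    warning("rk2_potential_step: dt exceeds the explicit diffusion ",
            "stability estimate h_min^2/(2D); expect instability")
  }
  k1 <- potential_rhs(sys, phi, state$C, state$t, state$step_index)
  phis <- phi + dt * k1
  phis[sys$bnd] <- sys$constants$phi_rest
  k2 <- potential_rhs(sys, phis, state$C, state$t + dt, state$step_index)
  phinew <- phi + dt / 2 * (k1 + k2)
  phinew[sys$bnd] <- sys$constants$phi_rest
  if (any(!is.finite(phinew))) {
    stop("rk2_potential_step: potential blew up (NaN) at step ",
         state$step_index + 1L, call. = FALSE)
  }
  phinew
}

#' Implicit (backward-Euler) Picard-iterated transport step
#'
#' Solves, for each species i, the backward-Euler Galerkin system
#' `(M + dt K_i + dt A_i(phi_new)) C_i_new = M C_i_old + dt M F_i(C_k)`
#' with the reaction lagged (Picard fixed point over k) until the maximal
#' relative update over species drops below `picard_tol` or `picard_max`
#' iterations are reached (then an error reporting the residual history is
#' raised). Species carry no-flux boundary conditions, so no boundary term
#' appears and the discrete total mass of each conserved moiety is exact
#' up to linear-solver roundoff.
#'
#' @param sys an `npcable_system`.
#' @param C nodes x 6 start-of-step concentrations.
#' @param phi_new end-of-step nodal potential (drives the drift).
#' @param dt time step (s).
#' @param picard_tol relative Picard tolerance (default from config).
#' @param picard_max iteration cap (default from config).
#' @return A list: `C` (updated concentrations), `iterations`,
#'   `residuals` (relative update history).
#' @export
implicit_transport_step <- function(sys, C, phi_new, dt,
                                    picard_tol = NULL, picard_max = NULL) {
  tmcfg <- sys$config$time
  if (is.null(picard_tol)) picard_tol <- tmcfg$picard_tol
  if (is.null(picard_max)) picard_max <- tmcfg$picard_max
  # M, K and A(phi) share the element-triplet layout, so each species'
  # system matrix is assembled in a single pass over the value vectors
  avals <- .drift_vals(sys$geom, phi_new)
  lus <- vector("list", 6L)
  for (i in 1:6) {
    Si <- Matrix::sparseMatrix(
      i = sys$trip$i, j = sys$trip$j,
      x = sys$mvals + dt * (sys$species$d[i] * sys$kvals +
                            sys$mob[i] * avals),
      dims = c(sys$n, sys$n))
    lus[[i]] <- Matrix::lu(Si)
  }
  MC <- as.matrix(sys$M %*% C)
  Ck <- C
  res_hist <- numeric(0)
  for (k in seq_len(picard_max)) {
    Fmat <- reaction_rates(pmax(Ck, 0), sys$kinetics)
    MF <- as.matrix(sys$M %*% Fmat)
    Cn <- Ck
    for (i in 1:6) {
      Cn[, i] <- as.vector(Matrix::solve(lus[[i]], MC[, i] + dt * MF[, i]))
    }
    upd <- sqrt(colSums((Cn - Ck)^2))
    ref <- pmax(sqrt(colSums(Ck^2)), .Machine$double.eps)
    res <- max(upd / ref)
    res_hist <- c(res_hist, res)
    Ck <- Cn
    if (res <= picard_tol) {
      return(list(C = Ck, iterations = k, residuals = res_hist))
    }
  }
  stop("implicit_transport_step: Picard iteration failed to converge in ",
       picard_max, " iterations; relative-update history: ",
       paste(format(res_hist, digits = 3), collapse = ", "), call. = FALSE)
}

#' Advance the coupled system by one time step
#'
#' The splitting order of the time-marching algorithm: (1) the potential
#' is advanced explicitly (RK2/Heun) using the start-of-step
#' concentrations; (2) the six transport equations are advanced implicitly
#' using the end-of-step potential. The coupling is not re-iterated within
#' the step.
#'
#' @param sys an `npcable_system`.
#' @param state a `system_state`.
#' @param dt time step (s; default from the config).
#' @return The `system_state` at `t + dt`, with an attribute
#'   `picard_iterations`.
#' @export
step_system <- function(sys, state, dt = NULL) {
  if (is.null(dt)) dt <- sys$config$time$dt
  phinew <- rk2_potential_step(sys, state, dt)
  tr <- implicit_transport_step(sys, state$C, phinew, dt)
  if (any(!is.finite(tr$C))) {
    stop("step_system: concentrations blew up (NaN) at step ",
         state$step_index + 1L, call. = FALSE)
  }
  out <- structure(list(t = state$t + dt,
                        step_index = state$step_index + 1L,
                        phi = phinew, C = tr$C),
                   class = "system_state")
  attr(out, "picard_iterations") <- tr$iterations
  out
}

#' Run a full coupled simulation
#'
#' Executes `ceiling(T/dt)` IMEX steps from the initial state, recording a
#' probe time series (potential and all six concentrations at the node
#' nearest each probe point), discrete totals of the two conserved
#' moieties (enzyme `E + X + Y + Ei` and substrate `S + X + Y + P + Ei`;
#' the inactivated complex retains the substrate-derived inhibitor, so it
#' belongs to both), mass-matrix weighted, at every step, and optional
#' field snapshots.
#'
#' @param config a `run_config`.
#' @param mesh optional pre-built mesh (see [build_system()]).
#' @param sys optional pre-built `npcable_system` (overrides `config`
#'   and `mesh`); useful to amortise assembly over repeated runs.
#' @return A list of class `npcable_run`: `config`, `mesh`, `times`,
#'   `probes` (list of data.frames, one per probe, columns
#'   `t, phi, C1..C6`), `probe_nodes`, `conservation` (data.frame of
#'   moiety totals per step), `snapshots` (list of `system_state`, if
#'   requested), `final_state`, `summary`.
#' @examples
#' \donttest{
#' cfg <- default_run_config()
#' cfg$mesh$h <- 0.35
#' cfg$time$T <- 5e-4
#' run <- run_simulation(cfg)
#' run$summary$steps
#' }
#' @export
run_simulation <- function(config, mesh = NULL, sys = NULL) {
  if (is.null(sys)) sys <- build_system(config, mesh)
  cfg <- sys$config
  dt <- cfg$time$dt
  Tend <- cfg$time$T
  nstep <- if (Tend <= 0) 0L else as.integer(ceiling(Tend / dt - 1e-12))
  state <- initial_state(sys)

  probes <- cfg$output$probes
  pnode <- vapply(probes, function(p) {
    which.min((sys$mesh$nodes[, 1L] - p[1L])^2 +
              (sys$mesh$nodes[, 2L] - p[2L])^2)
  }, 0L)
  nprob <- length(pnode)
  prec <- lapply(seq_len(nprob), function(i) matrix(NA_real_, nstep + 1L, 8L))
  onesM <- as.vector(Matrix::colSums(sys$M))  # 1'M weights (M symmetric)
  cons <- matrix(NA_real_, nstep + 1L, 3L)
  snap_every <- as.integer(cfg$output$snapshot_every)
  snapshots <- if (snap_every > 0L) list() else NULL
  picard <- integer(nstep)

  record <- function(row, st) {
    for (i in seq_len(nprob)) {
      prec[[i]][row, ] <<- c(st$t, st$phi[pnode[i]], st$C[pnode[i], ])
    }
    moi_e <- sum(onesM * (st$C[, 1L] + st$C[, 3L] + st$C[, 4L] + st$C[, 6L]))
    moi_s <- sum(onesM * (st$C[, 2L] + st$C[, 3L] + st$C[, 4L] +
                          st$C[, 5L] + st$C[, 6L]))
    cons[row, ] <<- c(st$t, moi_e, moi_s)
  }
  record(1L, state)
  if (!is.null(snapshots)) snapshots[[1L]] <- state

  for (nstp in seq_len(nstep)) {
    state <- step_system(sys, state, dt)
    picard[nstp] <- attr(state, "picard_iterations")
    record(nstp + 1L, state)
    if (!is.null(snapshots) && nstp %% snap_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <- state
    }
  }

  probe_df <- lapply(prec, function(m) {
    df <- as.data.frame(m)
    names(df) <- c("t", "phi", paste0("C", 1:6))
    df
  })
  cons_df <- as.data.frame(cons)
  names(cons_df) <- c("t", "enzyme_moiety", "substrate_moiety")

  ph <- probe_df[[1L]]$phi
  dev <- ph - ph[1L]
  ipk <- which.max(abs(dev))
  summ <- list(steps = nstep, dt = dt, T = Tend,
               h_achieved = mesh_size(sys$mesh),
               nodes = sys$n,
               peak_phi = ph[ipk], time_of_peak = probe_df[[1L]]$t[ipk],
               peak_deviation = dev[ipk],
               enzyme_moiety_drift = if (nstep > 0)
                 abs(cons_df$enzyme_moiety[nstep + 1L] / cons_df$enzyme_moiety[1L] - 1)
               else 0,
               substrate_moiety_drift = if (nstep > 0)
                 abs(cons_df$substrate_moiety[nstep + 1L] / cons_df$substrate_moiety[1L] - 1)
               else 0,
               picard_mean = if (nstep > 0) mean(picard) else NA_real_,
               picard_max = if (nstep > 0) max(picard) else NA_integer_)

  structure(list(config = cfg, mesh = sys$mesh, system = sys,
                 times = cons_df$t, probes = probe_df, probe_nodes = pnode,
                 conservation = cons_df, snapshots = snapshots,
                 picard_iterations = picard,
                 final_state = state, summary = summ),
            class = "npcable_run")
}

#' @export
print.npcable_run <- function(x, ...) {
  s <- x$summary
  cat("npcable_run:", s$steps, "steps of dt =", format(s$dt),
      "s on", s$nodes, "nodes (h =", format(s$h_achieved, digits = 3), ")\n")
  cat("  centre-probe peak phi:", format(s$peak_phi, digits = 6),
      "mV at t =", format(s$time_of_peak), "s\n")
  cat("  moiety drift (enzyme, substrate):",
      format(s$enzyme_moiety_drift, digits = 3),
      format(s$substrate_moiety_drift, digits = 3), "\n")
  invisible(x)
}
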