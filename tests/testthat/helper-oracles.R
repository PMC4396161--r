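# Independent oracles used across the suite. These deliberately avoid the
# package's assembly code paths: P1 basis functions are recovered per
# element by solving the 3x3 Vandermonde system, and element integrals are
# evaluated by the mid-edge quadrature rule (exact for degree <= 2, which
# covers every P1 x P1 product the package assembles).

# coefficients (a, bx, by) of the three affine basis functions of the
# triangle with vertex matrix V (3 x 2): column k solves psi_k(v_m)=delta
p1_coefs <- function(V) solve(cbind(1, V))  # 3x3: rows (a,bx,by), cols k

tri_area <- function(V) {
  abs((V[2, 1] - V[1, 1]) * (V[3, 2] - V[1, 2]) -
      (V[3, 1] - V[1, 1]) * (V[2, 2] - V[1, 2])) / 2
}

# mid-edge (3-point) rule: integral over the triangle of f(x, y)
tri_quad_midedge <- function(V, f) {
  pts <- rbind((V[1, ] + V[2, ]) / 2, (V[2, ] + V[3, ]) / 2,
               (V[3, ] + V[1, ]) / 2)
  tri_area(V) / 3 * sum(f(pts[, 1], pts[, 2]))
}

# Brute-force quadrature assembly of mass / stiffness / drift matrices.
oracle_assemble <- function(mesh, kind = c("mass", "stiffness", "drift"),
                            phi = NULL, coeff = 1) {
  kind <- match.arg(kind)
  n <- nrow(mesh$nodes)
  out <- matrix(0, n, n)
  for (e in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[e, ]
    V <- mesh$nodes[tri, , drop = FALSE]
    cf <- p1_coefs(V)                     # cf[,k]: (a, bx, by) of psi_k
    psi <- function(k, x, y) cf[1, k] + cf[2, k] * x + cf[3, k] * y
    if (kind == "drift") {
      gphi <- as.vector(cf[2:3, ] %*% phi[tri])  # constant grad of interpolant
    }
    for (i in 1:3) for (j in 1:3) {
      val <- switch(kind,
        mass = tri_quad_midedge(V, function(x, y) psi(i, x, y) * psi(j, x, y)),
        stiffness = tri_area(V) * sum(cf[2:3, i] * cf[2:3, j]),
        drift = tri_quad_midedge(V, function(x, y) {
          psi(j, x, y) * sum(gphi * cf[2:3, i])
        }))
      out[tri[i], tri[j]] <- out[tri[i], tri[j]] + coeff * val
    }
  }
  out
}

# brute-force squared-L2 of a nodal field (P1 interpolant) by quadrature
oracle_l2 <- function(mesh, values) {
  acc <- 0
  for (e in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[e, ]
    V <- mesh$nodes[tri, , drop = FALSE]
    cf <- p1_coefs(V)
    acc <- acc + tri_quad_midedge(V, function(x, y) {
      psi <- matrix(cf[1, ], length(x), 3, byrow = TRUE) +
        outer(x, cf[2, ]) + outer(y, cf[3, ])
      as.vector(psi %*% values[tri])^2
    })
  }
  sqrt(acc)
}

# single reference triangle used across tests
unit_right_mesh <- function() {
  triangle_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), rbind(c(1L, 2L, 3L)))
}

# a small ellipse mesh shared by assembly tests
small_ellipse <- function() ellipse_mesh(2, 1, 0.6)

# quick coarse run config for dynamics tests
coarse_config <- function(h = 0.35, T = 1e-3, dt = 1e-5) {
  cfg <- default_run_config()
  cfg$mesh$h <- h
  cfg$time$T <- T
  cfg$time$dt <- dt
  cfg
}
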