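# Independent oracles used across the suite: finite-difference forces,
# brute-force contact metrics, quadrature expectations.

# Total restraint energy of a pose, going only through the angle functions.
pose_energy <- function(coords, spec) {
  b <- spec$beads
  x <- if (spec$kind == "bend") {
    bend_angle(coords[b[1], ], coords[b[2], ], coords[b[3], ])
  } else {
    dihedral_angle(coords[b[1], ], coords[b[2], ], coords[b[3], ], coords[b[4], ])
  }
  restraint_energy(x, spec)
}

# Central finite-difference force matrix (kJ/mol/nm).
fd_forces <- function(coords, spec, h = 1e-6) {
  F <- matrix(0, nrow(coords), 3)
  for (a in spec$beads) {
    for (d in 1:3) {
      cp <- coords; cp[a, d] <- cp[a, d] + h
      cm <- coords; cm[a, d] <- cm[a, d] - h
      F[a, d] <- -(pose_energy(cp, spec) - pose_energy(cm, spec)) / (2 * h)
    }
  }
  F
}

# Random non-degenerate pose of n beads (internal angles kept off 0/180).
random_pose <- function(n) {
  repeat {
    P <- matrix(runif(3 * n, -1, 1), n, 3)
    ok <- TRUE
    for (i in seq_len(n - 2)) {
      a <- tryCatch(bend_angle(P[i, ], P[i + 1, ], P[i + 2, ]),
                    error = function(e) NA_real_)
      if (is.na(a) || a < 10 || a > 170) { ok <- FALSE; break }
    }
    if (ok) return(P)
  }
}

net_torque <- function(coords, forces) {
  tq <- c(0, 0, 0)
  for (a in seq_len(nrow(coords))) {
    r <- coords[a, ]; f <- forces[a, ]
    tq <- tq + c(r[2] * f[3] - r[3] * f[2],
                 r[3] * f[1] - r[1] * f[3],
                 r[1] * f[2] - r[2] * f[1])
  }
  tq
}

# Exhaustive double-loop minimum-image distance scan.
brute_min_distances <- function(frame) {
  P <- frame$protein; Q <- frame$phosphate; box <- frame$box
  out <- numeric(nrow(P))
  for (r in seq_len(nrow(P))) {
    best <- Inf
    for (q in seq_len(nrow(Q))) {
      d2 <- 0
      for (dim in 1:3) {
        dd <- P[r, dim] - Q[q, dim]
        dd <- dd - box[dim] * round(dd / box[dim])
        d2 <- d2 + dd^2
      }
      best <- min(best, d2)
    }
    out[r] <- sqrt(best)
  }
  out
}

# Boltzmann expectation of the angle by trapezoidal quadrature, optionally
# with the sin(theta) measure induced by Cartesian sampling of a bend.
quadrature_mean <- function(spec, temperature, sin_jacobian = FALSE) {
  dens <- boltzmann_density(spec, temperature)
  w <- dens$density
  if (sin_jacobian) w <- w * sin(dens$x * pi / 180)
  sum(w * dens$x) / sum(w)
}

random_frame <- function(n_res, n_phos, box = c(10, 10, 10)) {
  labeled_frame(matrix(runif(3 * n_res, 0, 10), n_res, 3),
                matrix(runif(3 * n_phos, 0, 10), n_phos, 3),
                box)
}
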