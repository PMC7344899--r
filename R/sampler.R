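## Minimal samplers used to validate the restraints statistically:
## a scalar internal-coordinate Metropolis chain and an overdamped
## (Brownian) Cartesian integrator on a bead chain.

#' Sampler configuration
#'
#' @param temperature Temperature in K.
#' @param n_steps Total number of steps.
#' @param step_size Proposal half-width in degrees (Metropolis) or time step
#'   in ps (Brownian dynamics).
#' @param seed Integer RNG seed.
#' @param burn_in Steps discarded before recording (< `n_steps`).
#' @param thinning Record every `thinning`-th step (>= 1).
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 310, n_steps = 1e4, step_size = 3,
                           seed = 1, burn_in = 0, thinning = 1) {
  if (n_steps <= burn_in || burn_in < 0) abort("Require n_steps > burn_in >= 0.")
  if (step_size <= 0) abort("`step_size` must be positive.")
  if (thinning < 1) abort("`thinning` must be >= 1.")
  structure(list(temperature = temperature, n_steps = as.integer(n_steps),
                 step_size = step_size, seed = as.integer(seed),
                 burn_in = as.integer(burn_in), thinning = as.integer(thinning)),
            class = "sampler_config")
}

#' Boltzmann density of a restraint at a temperature
#'
#' The normalized density `exp(-V(x)/kT)` of the restrained internal
#' coordinate over its domain (trapezoidal normalization). This is the
#' reference distribution that internal-coordinate Metropolis sampling of the
#' restraint must reproduce. `kB = 0.0083145` kJ/mol/K.
#'
#' @param spec A [restraint_spec()].
#' @param temperature Temperature in K.
#' @param grid Optional grid in degrees covering the domain; default step 0.05.
#' @return Tibble with columns `x` (degrees) and `density` (1/degree).
#' @export
boltzmann_density <- function(spec, temperature, grid = NULL) {
  dom <- .spec_domain(spec)
  if (is.null(grid)) grid <- seq(dom[1], dom[2], by = 0.05)
  kT <- .kB * temperature
  w <- exp(-restraint_energy(grid, spec) / kT)
  dx <- diff(grid)
  Z <- sum(dx * (head(w, -1) + tail(w, -1)) / 2)
  tibble(x = grid, density = w / Z)
}

## Trapezoidal CDF of a density tibble, evaluated at its own grid.
.density_cdf <- function(dens) {
  dx <- diff(dens$x)
  inc <- dx * (head(dens$density, -1) + tail(dens$density, -1)) / 2
  cdf <- c(0, cumsum(inc))
  cdf / cdf[length(cdf)]
}

#' Metropolis sampling of a restrained angle
#'
#' Scalar Markov chain on the bend or dihedral coordinate with symmetric
#' uniform proposals and Metropolis acceptance on [restraint_energy()].
#' Dihedral proposals wrap into `(-180, 180]`; bend proposals leaving
#' `[0, 180]` are rejected. Reproducible given `config$seed`.
#'
#' @param spec A [restraint_spec()].
#' @param config A [sampler_config()].
#' @param x0 Starting angle (degrees); defaults to the well center.
#' @return List of class `sample_set`: `values` (recorded angles, degrees),
#'   `config`, and `acceptance_rate`.
#' @export
metropolis_sample <- function(spec, config, x0 = NULL) {
  stopifnot(inherits(spec, "restraint_spec"), inherits(config, "sampler_config"))
  dom <- .spec_domain(spec)
  is_dih <- spec$kind == "dihedral"
  centers <- c(spec$center, spec$images)
  K <- spec$depth
  sig <- spec$sigma
  kT <- .kB * config$temperature
  n <- config$n_steps
  cur <- x0 %||% spec$center
  set.seed(config$seed)
  dx <- runif(n, -config$step_size, config$step_size)
  logu <- log(runif(n))
  keep <- seq(config$burn_in + 1L, n, by = config$thinning)
  vals <- numeric(length(keep))
  ener <- function(x) {
    v <- 0
    for (ctr in centers) v <- v - K * exp(-(x - ctr)^2 / sig)
    v
  }
  e_cur <- ener(cur)
  acc <- 0L
  ki <- 1L
  nk <- length(keep)
  next_keep <- keep[1L]
  for (s in seq_len(n)) {
    prop <- cur + dx[s]
    ok <- TRUE
    if (is_dih) {
      if (prop > 180) prop <- prop - 360 else if (prop <= -180) prop <- prop + 360
    } else if (prop < dom[1] || prop > dom[2]) {
      ok <- FALSE
    }
    if (ok) {
      e_prop <- ener(prop)
      if (logu[s] < (e_cur - e_prop) / kT) {
        cur <- prop
        e_cur <- e_prop
        acc <- acc + 1L
      }
    }
    if (s == next_keep) {
      vals[ki] <- cur
      ki <- ki + 1L
      next_keep <- if (ki <= nk) keep[ki] else n + 1L
    }
  }
  structure(list(values = vals, config = config, acceptance_rate = acc / n),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d values, acceptance %.1f%%, T = %g K\n",
              length(x$values), 100 * x$acceptance_rate, x$config$temperature))
  invisible(x)
}

#' Kolmogorov-Smirnov distance between samples and the Boltzmann reference
#'
#' Sup-distance between the empirical CDF of a sample set and the trapezoidal
#' CDF of [boltzmann_density()], a direct check that the sampler reproduces
#' the restraint's equilibrium distribution.
#'
#' @param samples A `sample_set` or numeric vector of angles (degrees).
#' @param spec A [restraint_spec()].
#' @param temperature Temperature in K.
#' @return KS distance (scalar in `[0, 1]`).
#' @export
ks_against_boltzmann <- function(samples, spec, temperature) {
  x <- if (inherits(samples, "sample_set")) samples$values else samples
  dens <- boltzmann_density(spec, temperature)
  cdf <- .density_cdf(dens)
  xs <- sort(x)
  Fth <- approx(dens$x, cdf, xout = xs, rule = 2)$y
  n <- length(xs)
  Femp_hi <- seq_len(n) / n
  Femp_lo <- (seq_len(n) - 1) / n
  max(abs(Femp_hi - Fth), abs(Femp_lo - Fth))
}

## Harmonic bond forces: bonds tibble(i, j, b0, kb); V = kb/2 (r - b0)^2.
.bond_forces <- function(coords, bonds) {
  F <- matrix(0, nrow(coords), 3)
  e <- 0
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    d <- coords[j, ] - coords[i, ]
    r <- .vnorm(d)
    dev <- r - bonds$b0[b]
    e <- e + 0.5 * bonds$kb[b] * dev^2
    f <- bonds$kb[b] * dev * d / r
    F[i, ] <- F[i, ] + f
    F[j, ] <- F[j, ] - f
  }
  list(energy = e, forces = F)
}

#' Default harmonic bond terms for a chain
#'
#' Consecutive-bead bonds at CG backbone scale (b0 = 0.35 nm,
#' kb = 1250 kJ/mol/nm^2).
#'
#' @param n_residues Number of beads.
#' @param b0 Equilibrium length (nm).
#' @param kb Force constant (kJ/mol/nm^2).
#' @return Tibble with columns `i`, `j`, `b0`, `kb`.
#' @export
chain_bonds <- function(n_residues, b0 = 0.35, kb = 1250) {
  tibble(i = seq_len(n_residues - 1L), j = seq_len(n_residues - 1L) + 1L,
         b0 = b0, kb = kb)
}

#' Brownian (overdamped Langevin) dynamics on a restrained bead chain
#'
#' First-order integrator `r <- r + mu F dt + sqrt(2 mu kB T dt) xi` with
#' forces from the restraint set plus harmonic bonds. No solvent, thermostat
#' or barostat: this sampler exists to validate the restraints, not binding
#' thermodynamics. Reproducible given `config$seed`; frames are recorded
#' every `config$thinning` steps after `config$burn_in`.
#'
#' @param chain Starting [bead_chain()].
#' @param restraints A `restraint_set` tibble (may have zero rows).
#' @param bonds Bond tibble from [chain_bonds()]; defaults to consecutive
#'   bonds.
#' @param config [sampler_config()]; `step_size` is the time step in ps.
#'   With the default restraint and bond scales the integrator is stable for
#'   time steps up to about 5e-4 ps; the default config uses 1e-4 ps.
#' @param mobility Bead mobility in nm^2/(kJ/mol)/ps (default 0.01).
#' @param force_cap Abort threshold on any force component (kJ/mol/nm).
#' @return List of class `bd_trajectory`: `frames` (list of n x 3 matrices),
#'   `config`, `sequence`.
#' @export
brownian_dynamics <- function(chain, restraints, bonds = NULL,
                              config = sampler_config(step_size = 1e-4),
                              mobility = 0.01, force_cap = 1e5) {
  coords <- chain_coords(chain)
  n <- nrow(coords)
  if (is.null(bonds)) bonds <- chain_bonds(n)
  specs <- restraint_specs(restraints)
  dt <- config$step_size
  kT <- .kB * config$temperature
  noise_sd <- sqrt(2 * mobility * kT * dt)
  set.seed(config$seed)
  keep <- seq(config$burn_in + 1L, config$n_steps, by = config$thinning)
  frames <- vector("list", length(keep))
  ki <- 1L
  for (s in seq_len(config$n_steps)) {
    F <- matrix(0, n, 3)
    for (spec in specs) F <- F + cartesian_forces(coords, spec)$forces
    F <- F + .bond_forces(coords, bonds)$forces
    if (any(abs(F) > force_cap)) {
      abort(sprintf("Force blow-up at step %d (|F| > %g kJ/mol/nm).", s, force_cap),
            class = "cgmelt_integration_error")
    }
    coords <- coords + mobility * F * dt
    if (noise_sd > 0) coords <- coords + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
    if (ki <= length(keep) && s == keep[ki]) {
      frames[[ki]] <- coords
      ki <- ki + 1L
    }
  }
  structure(list(frames = frames, config = config,
                 sequence = if (inherits(chain, "data.frame")) chain$name else NULL),
            class = "bd_trajectory")
}

#' Internal coordinates along a Brownian-dynamics trajectory
#'
#' @param traj A `bd_trajectory`.
#' @return Tibble with columns `frame`, `kind`, `index`, `angle_deg`.
#' @export
trajectory_internal_coords <- function(traj) {
  purrr::map_dfr(seq_along(traj$frames), function(f) {
    dplyr::mutate(chain_internal_coords(traj$frames[[f]]), frame = f, .before = 1)
  })
}
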