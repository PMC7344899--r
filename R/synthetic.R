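## Synthetic multi-temperature peptide-membrane campaigns with known ground
## truth. The generator models occupancy, not physics: each residue is a
## two-state (bound/unbound) Markov chain whose stationary bound probability
## decays logistically with temperature, modulated by a per-residue affinity
## weight. Rendered frames place phosphates on a planar grid and residues at
## bound/unbound heights so that contact analysis recovers the generated
## states exactly.

#' Parameters of the synthetic two-state binding model
#'
#' @param tm_true True melting temperature (K): logistic midpoint of the
#'   bound probability (default 380, the middle of the 310-450 K ladder).
#' @param steepness Logistic width in K (default 10, one ladder step).
#' @param n_residues Number of residues (default 30).
#' @param weights Per-residue affinity weights in `[0, 1]` scaling the bound
#'   probability. Default mimics N-terminal-dominated binding: 1 for the
#'   first 7 residues, then a linear decrease to 0.3 at the C-terminus. Use
#'   `rep(1, n)` for a uniform (helical-like) profile.
#' @param k_on Per-frame unbound-to-bound transition rate (default 0.05,
#'   giving frame-to-frame correlation so segment-based convergence
#'   estimates are exercised nontrivially).
#' @param bound_distance_mean Mean residue-phosphate distance when bound
#'   (nm, < 1).
#' @param unbound_distance_mean Mean distance when unbound (nm, > 1).
#' @param distance_jitter Gaussian jitter on rendered distances (nm).
#' @return List of class `binding_params`.
#' @export
binding_params <- function(tm_true = 380, steepness = 10, n_residues = 30,
                           weights = NULL, k_on = 0.05,
                           bound_distance_mean = 0.5,
                           unbound_distance_mean = 2.5,
                           distance_jitter = 0.1) {
  if (steepness <= 0) abort("`steepness` must be positive.")
  if (!(bound_distance_mean > 0 && bound_distance_mean < 1 &&
        unbound_distance_mean > 1)) {
    abort("Require 0 < bound_distance_mean < 1 < unbound_distance_mean (nm).")
  }
  if (is.null(weights)) {
    n <- n_residues
    weights <- if (n <= 7) rep(1, n) else c(rep(1, 7), seq(1, 0.3, length.out = n - 7 + 1)[-1])
  }
  if (length(weights) != n_residues || any(weights < 0 | weights > 1)) {
    abort("`weights` must be n_residues values in [0, 1].")
  }
  structure(list(tm_true = tm_true, steepness = steepness,
                 n_residues = as.integer(n_residues), weights = weights,
                 k_on = k_on, bound_distance_mean = bound_distance_mean,
                 unbound_distance_mean = unbound_distance_mean,
                 distance_jitter = distance_jitter),
            class = "binding_params")
}

#' Stationary bound probability of a residue at a temperature
#'
#' `p = w_r / (1 + exp((T - Tm)/s))`, clamped to `[0, 1]`.
#'
#' @param temperature Temperature in K (vectorised).
#' @param residue Residue index (1-based).
#' @param params [binding_params()].
#' @return Bound probability in `[0, 1]`.
#' @export
bound_probability <- function(temperature, residue, params) {
  w <- params$weights[residue]
  p <- w / (1 + exp((temperature - params$tm_true) / params$steepness))
  pmin(1, pmax(0, p))
}

## Per-frame transition rates hitting a target stationary bound probability.
## k_off = k_on (1 - p) / p; when that exceeds 1 the pair is rescaled to
## keep rates in (0, 1] while preserving p.
.chain_rates <- function(p, k_on) {
  if (p <= 0) return(c(on = 0, off = 1))
  if (p >= 1) return(c(on = 1, off = 0))
  k_off <- k_on * (1 - p) / p
  if (k_off > 1) {
    k_off <- 1
    k_on <- p / (1 - p)
  }
  c(on = k_on, off = k_off)
}

#' Simulate the bound/unbound state chain of one residue
#'
#' Two-state Markov chain in discrete frames whose stationary bound fraction
#' equals [bound_probability()]; the off-rate is derived from `k_on` and the
#' target probability. The initial state is drawn from the stationary
#' distribution. Target probabilities of exactly 0 or 1 yield absorbing
#' all-unbound / all-bound chains.
#'
#' @param params [binding_params()].
#' @param temperature Temperature in K.
#' @param residue Residue index.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of 0/1 states, length `n_frames`.
#' @export
simulate_state_chain <- function(params, temperature, residue, n_frames, seed = 1) {
  set.seed(as.integer(seed))
  p <- bound_probability(temperature, residue, params)
  r <- .chain_rates(p, params$k_on)
  s <- integer(n_frames)
  s[1] <- as.integer(runif(1) < p)
  if (n_frames > 1) {
    u <- runif(n_frames - 1)
    for (f in 2:n_frames) {
      s[f] <- if (s[f - 1] == 1L) {
        as.integer(u[f - 1] >= r["off"])
      } else {
        as.integer(u[f - 1] < r["on"])
      }
    }
  }
  s
}

## All residues at one temperature, vectorised across residues.
.simulate_states_matrix <- function(params, temperature, n_frames, seed) {
  set.seed(as.integer(seed))
  n <- params$n_residues
  p <- vapply(seq_len(n), function(r) bound_probability(temperature, r, params), 0)
  rates <- vapply(p, .chain_rates, c(on = 0, off = 0), k_on = params$k_on)
  S <- matrix(0L, n, n_frames)
  S[, 1] <- as.integer(runif(n) < p)
  if (n_frames > 1) {
    for (f in 2:n_frames) {
      u <- runif(n)
      prev <- S[, f - 1]
      S[, f] <- ifelse(prev == 1L, as.integer(u >= rates["off", ]),
                       as.integer(u < rates["on", ]))
    }
  }
  S
}

#' Render state chains as labeled 3D frames
#'
#' Phosphate beads sit on a planar grid at z = 0; each residue is placed in
#' xy directly above a grid node, at height `bound_distance_mean` (bound) or
#' `unbound_distance_mean` (unbound) plus truncated Gaussian jitter. The
#' truncation keeps bound distances strictly below 1 nm and unbound strictly
#' above, so [contact_matrix()] at the 1 nm threshold reproduces the state
#' matrix exactly.
#'
#' @param states residues x frames 0/1 matrix.
#' @param params [binding_params()].
#' @param box Box edges in nm (default `c(10, 10, 12)`).
#' @param grid_spacing Phosphate grid spacing in nm (default 1).
#' @param seed Integer seed for the jitter.
#' @return List of [labeled_frame()]s, one per column of `states`.
#' @export
render_frames <- function(states, params, box = c(10, 10, 12),
                          grid_spacing = 1, seed = 1) {
  states <- as.matrix(states)
  n_res <- nrow(states)
  if (n_res != params$n_residues) {
    abort("`states` row count does not match `params$n_residues`.")
  }
  jit <- params$distance_jitter
  lo <- params$bound_distance_mean
  hi <- params$unbound_distance_mean
  if (lo + 3 * jit >= 1 || hi - 3 * jit <= 1) {
    abort(paste("`distance_jitter` is large enough to mix bound and unbound",
                "distances across the 1 nm threshold."),
          class = "cgmelt_config_error")
  }
  gx <- seq(grid_spacing / 2, box[1] - 1e-9, by = grid_spacing)
  gy <- seq(grid_spacing / 2, box[2] - 1e-9, by = grid_spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  phosphate <- cbind(grid, z = 0)
  node <- ((seq_len(n_res) - 1) %% nrow(grid)) + 1
  res_xy <- grid[node, , drop = FALSE]
  set.seed(as.integer(seed))
  n_f <- ncol(states)
  lapply(seq_len(n_f), function(f) {
    z_jit <- rnorm(n_res, sd = jit)
    z_jit <- pmin(3 * jit, pmax(-3 * jit, z_jit))
    z <- ifelse(states[, f] == 1L,
                pmin(0.999, pmax(0.02, lo + z_jit)),
                pmax(1.001, hi + z_jit))
    labeled_frame(cbind(res_xy, z = z), phosphate, box)
  })
}

## Deterministic per-temperature sub-seed below 2^31.
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

#' Generate a synthetic multi-temperature binding campaign
#'
#' One state matrix (and contact matrix) per temperature of the ladder, with
#' independent RNG streams derived deterministically from `seed`, plus the
#' ground-truth record. With `render = TRUE` each temperature also carries
#' rendered [labeled_frame()]s for file export and loader round trips.
#'
#' @param params [binding_params()].
#' @param temperatures Ladder in K (default `seq(310, 450, by = 10)`).
#' @param n_frames Frames per temperature.
#' @param seed Campaign seed.
#' @param render Also render 3D frames (default `FALSE`).
#' @return Object of class `binding_campaign`: list with `contacts` (list of
#'   [contact_matrix()]s), `frames` (list of frame lists or `NULL`),
#'   `temperatures`, `params`, `truth` (tibble: `tm_true`, `steepness`),
#'   `seed`.
#' @export
generate_campaign <- function(params, temperatures = seq(310, 450, by = 10),
                              n_frames = 1000, seed = 1, render = FALSE) {
  if (length(temperatures) < 2) abort("At least two temperatures are required.")
  contacts <- vector("list", length(temperatures))
  frames <- if (render) vector("list", length(temperatures)) else NULL
  for (i in seq_along(temperatures)) {
    si <- .derive_seed(seed, i)
    S <- .simulate_states_matrix(params, temperatures[i], n_frames, si)
    contacts[[i]] <- new_contact_matrix(S, threshold = 1.0,
                                        temperature = temperatures[i])
    if (render) frames[[i]] <- render_frames(S, params, seed = si + 1L)
  }
  structure(list(contacts = contacts, frames = frames,
                 temperatures = temperatures, params = params,
                 truth = tibble(tm_true = params$tm_true,
                                steepness = params$steepness),
                 seed = as.integer(seed)),
            class = "binding_campaign")
}

#' @export
print.binding_campaign <- function(x, ...) {
  cat(sprintf("<binding_campaign> %d temperatures (%g-%g K), %d residues x %d frames, true Tm %g K\n",
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              x$params$n_residues, ncol(x$contacts[[1]]$contacts),
              x$params$tm_true))
  invisible(x)
}

#' Construct sequences of the alpha-synuclein N-terminal panel
#'
#' The nine construct sequences of the membrane-binding panel: the wild-type
#' N-terminal 30 residues of alpha-synuclein, six N-terminal deletion
#' constructs, the C-terminal control (residues 111-140) and the F4A point
#' mutant.
#'
#' @return Tibble with columns `name`, `sequence`, `length`.
#' @examples
#' construct_fixtures()
#' @export
construct_fixtures <- function() {
  out <- tibble(
    name = c("WT", "Del 2", "Del 2-3", "Del 2-4", "Del 2-5", "Del 2-7",
             "Del 2-11", "CT", "F4A"),
    sequence = c(
      "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAA",
      "MVFMKGLSKAKEGVVAAAEKTKQGVAEAA",
      "MFMKGLSKAKEGVVAAAEKTKQGVAEAA",
      "MMKGLSKAKEGVVAAAEKTKQGVAEAA",
      "MKGLSKAKEGVVAAAEKTKQGVAEAA",
      "MLSKAKEGVVAAAEKTKQGVAEAA",
      "MKEGVVAAAEKTKQGVAEAA",
      "GILEDMPVDPDNEAYEMPSEEGYQDYEPEA",
      "MDVAMKGLSKAKEGVVAAAEKTKQGVAEAA"
    )
  )
  dplyr::mutate(out, length = nchar(.data$sequence))
}
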