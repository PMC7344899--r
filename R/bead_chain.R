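## Ordered backbone-bead chains: one bead per residue, coordinates in nm.

#' Construct a bead chain
#'
#' An ordered backbone-bead chain: one bead per residue with a 1-based residue
#' id, a one-letter residue name and a position in nm.
#'
#' @param positions n x 3 numeric matrix of bead positions (nm).
#' @param sequence Optional one-letter sequence string or character vector;
#'   defaults to `"A"` per residue.
#' @return Tibble of class `bead_chain` with columns `residue`, `name`,
#'   `x`, `y`, `z`.
#' @export
bead_chain <- function(positions, sequence = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || !all(is.finite(positions))) {
    abort("`positions` must be a finite n x 3 matrix.")
  }
  n <- nrow(positions)
  names <- if (is.null(sequence)) {
    rep("A", n)
  } else {
    s <- if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
      strsplit(sequence, "")[[1]]
    } else {
      as.character(sequence)
    }
    if (length(s) != n) abort("Sequence length must match the number of beads.")
    s
  }
  out <- tibble(residue = seq_len(n), name = names,
                x = positions[, 1], y = positions[, 2], z = positions[, 3])
  class(out) <- c("bead_chain", class(out))
  out
}

#' Coordinate matrix of a chain
#'
#' @param chain A [bead_chain()] or an n x 3 numeric matrix.
#' @return n x 3 numeric matrix (nm).
#' @export
chain_coords <- function(chain) {
  if (is.matrix(chain)) return(chain)
  if (inherits(chain, "data.frame")) {
    return(cbind(chain$x, chain$y, chain$z))
  }
  abort("`chain` must be a bead_chain or an n x 3 matrix.")
}

## Place bead D given A, B, C, a bond length (nm), a bend angle at C (deg,
## between B-C-D) and a dihedral A-B-C-D (deg). Natural-extension reference
## frame; signs chosen so the measured dihedral_angle() equals `dihedral`.
.place_next_bead <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  th <- angle_deg / .deg
  ph <- dihedral_deg / .deg
  bc <- C - B
  bc <- bc / .vnorm(bc)
  ab <- B - A
  n <- .cross(ab, bc)
  nn <- .vnorm(n)
  if (nn < 1e-12) abort("Collinear reference beads in chain construction.")
  n <- n / nn
  m <- .cross(n, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Build a chain posed at given internal coordinates
#'
#' Constructs an n-bead chain with uniform bond length, all bend angles at
#' `bend_deg` and all dihedrals at `dihedral_deg` — e.g. the ideal pose of a
#' helical (96/60) or extended-disordered (124/100) restraint set.
#'
#' @param n_residues Number of beads (>= 3).
#' @param bend_deg Bend angle at every triple (degrees).
#' @param dihedral_deg Dihedral at every quadruple (degrees).
#' @param bond Bond length in nm (default 0.35, a typical CG backbone spacing).
#' @param sequence Optional sequence for [bead_chain()].
#' @return A [bead_chain()].
#' @export
build_ideal_chain <- function(n_residues, bend_deg, dihedral_deg,
                              bond = 0.35, sequence = NULL) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 3) abort("Need at least 3 residues.")
  P <- matrix(0, n_residues, 3)
  P[1, ] <- c(0, 0, 0)
  P[2, ] <- c(bond, 0, 0)
  th <- bend_deg / .deg
  P[3, ] <- P[2, ] + bond * c(-cos(th), sin(th), 0)
  if (n_residues >= 4) {
    for (r in 4:n_residues) {
      P[r, ] <- .place_next_bead(P[r - 3, ], P[r - 2, ], P[r - 1, ],
                                 bond, bend_deg, dihedral_deg)
    }
  }
  bead_chain(P, sequence)
}

#' Measure all internal coordinates of a chain
#'
#' @param chain A [bead_chain()] or coordinate matrix.
#' @return Tibble with columns `kind` ("bend"/"dihedral"), `index` (first bead
#'   of the triple/quadruple) and `angle_deg`.
#' @export
chain_internal_coords <- function(chain) {
  P <- chain_coords(chain)
  n <- nrow(P)
  bends <- if (n >= 3) {
    purrr::map_dbl(seq_len(n - 2), function(i) bend_angle(P[i, ], P[i + 1, ], P[i + 2, ]))
  } else numeric(0)
  dihs <- if (n >= 4) {
    purrr::map_dbl(seq_len(n - 3), function(i) {
      dihedral_angle(P[i, ], P[i + 1, ], P[i + 2, ], P[i + 3, ])
    })
  } else numeric(0)
  dplyr::bind_rows(
    tibble(kind = rep("bend", length(bends)), index = seq_along(bends), angle_deg = bends),
    tibble(kind = rep("dihedral", length(dihs)), index = seq_along(dihs), angle_deg = dihs)
  )
}
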