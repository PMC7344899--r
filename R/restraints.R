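## Gaussian restraint wells on bend and dihedral angles.
##
## The well is V(x) = -K * exp(-(x - x_min)^2 / sigma), with x in degrees and
## sigma the printed width constant (degrees-squared-valued denominator).
## Dihedral wells carry two periodic images at x_min +/- 360 so the energy is
## continuous across the atan2 boundary.

#' Construct a single angle-restraint specification
#'
#' One Gaussian well on a backbone bend or dihedral angle. Dihedral restraints
#' automatically carry the two periodic-image centers at `center_deg` +/- 360
#' degrees so the potential is continuous across the +/-180 degree boundary.
#'
#' @param kind `"bend"` or `"dihedral"`.
#' @param center_deg Well center (degrees): the restrained minimum. Bends in
#'   `(0, 180)`, dihedrals in `[-180, 180]`.
#' @param width_sigma Width constant `sigma` dividing the squared-degree
#'   deviation, as conventionally printed (default 14). The effective 1/e
#'   half-width is `sqrt(sigma)` degrees.
#' @param depth_k Well depth `K` in kJ/mol (default 50).
#' @param beads Optional integer bead indices into a chain: 3 for bends,
#'   4 for dihedrals.
#' @return An object of class `restraint_spec`.
#' @examples
#' restraint_spec("bend", 96)
#' restraint_spec("dihedral", 60, beads = 1:4)
#' @export
restraint_spec <- function(kind = c("bend", "dihedral"), center_deg,
                           width_sigma = 14, depth_k = 50, beads = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(center_deg), length(center_deg) == 1)
  if (width_sigma <= 0) abort("`width_sigma` must be positive.")
  if (depth_k <= 0) abort("`depth_k` must be positive.")
  if (kind == "bend" && (center_deg <= 0 || center_deg >= 180)) {
    abort("Bend center must lie in (0, 180) degrees.")
  }
  if (kind == "dihedral" && (center_deg < -180 || center_deg > 180)) {
    abort("Dihedral center must lie in [-180, 180] degrees.")
  }
  n_beads <- if (kind == "bend") 3L else 4L
  if (!is.null(beads)) {
    beads <- as.integer(beads)
    if (length(beads) != n_beads || anyDuplicated(beads) || any(beads < 1)) {
      abort(sprintf("`beads` must be %d distinct positive indices.", n_beads))
    }
  }
  images <- if (kind == "dihedral") c(center_deg - 360, center_deg + 360) else numeric(0)
  structure(
    list(kind = kind, center = center_deg, sigma = width_sigma,
         depth = depth_k, beads = beads, images = images),
    class = "restraint_spec"
  )
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat(sprintf("<restraint_spec> %s well at %g deg (sigma %g, K %g kJ/mol)%s\n",
              x$kind, x$center, x$sigma, x$depth,
              if (is.null(x$beads)) "" else paste0(" beads ", paste(x$beads, collapse = "-"))))
  invisible(x)
}

#' Restraint energy at an angle
#'
#' Evaluates the Gaussian well `V(x) = -K exp(-(x - c)^2 / sigma)` summed over
#' the center and its periodic images. The minimum value `-K` is attained at
#' the center; the energy decays to 0 far from all centers.
#'
#' @param x_deg Angle(s) in degrees (vectorised).
#' @param spec A [restraint_spec()].
#' @return Energy in kJ/mol, same length as `x_deg`.
#' @export
restraint_energy <- function(x_deg, spec) {
  stopifnot(inherits(spec, "restraint_spec"))
  centers <- c(spec$center, spec$images)
  v <- 0
  for (ctr in centers) {
    v <- v - spec$depth * exp(-(x_deg - ctr)^2 / spec$sigma)
  }
  v
}

#' Analytic derivative of the restraint energy with respect to the angle
#'
#' `dV/dx = sum over centers of 2 K (x - c) exp(-(x - c)^2 / sigma) / sigma`,
#' in kJ/mol per degree. Zero at each center and odd around it.
#'
#' @inheritParams restraint_energy
#' @return Gradient in kJ/mol/degree, same length as `x_deg`.
#' @export
restraint_internal_gradient <- function(x_deg, spec) {
  stopifnot(inherits(spec, "restraint_spec"))
  centers <- c(spec$center, spec$images)
  g <- 0
  for (ctr in centers) {
    g <- g + 2 * spec$depth * (x_deg - ctr) *
      exp(-(x_deg - ctr)^2 / spec$sigma) / spec$sigma
  }
  g
}

## Measure the restrained internal coordinate on a coordinate matrix.
.spec_angle <- function(coords, spec) {
  b <- spec$beads
  if (spec$kind == "bend") {
    bend_angle(coords[b[1], ], coords[b[2], ], coords[b[3], ])
  } else {
    dihedral_angle(coords[b[1], ], coords[b[2], ], coords[b[3], ], coords[b[4], ])
  }
}

#' Energy and Cartesian forces of one restraint on a bead chain
#'
#' Applies the chain rule `F = -dV/dx * dx/dr` to obtain per-bead Cartesian
#' forces from the analytic internal gradient and the analytic gradient of the
#' bend or dihedral angle with respect to the bead positions. Beads not
#' involved in the restraint receive zero force. The per-restraint forces sum
#' to zero and exert zero net torque.
#'
#' @param chain A [bead_chain()] (or plain n x 3 coordinate matrix in nm).
#' @param spec A [restraint_spec()] with `beads` set.
#' @return A list of class `energy_force` with elements `energy` (kJ/mol),
#'   `angle_deg`, `internal_gradient` (kJ/mol/deg) and `forces`
#'   (n x 3 matrix, kJ/mol/nm).
#' @export
cartesian_forces <- function(chain, spec) {
  stopifnot(inherits(spec, "restraint_spec"))
  if (is.null(spec$beads)) abort("`spec` has no bead indices.")
  coords <- chain_coords(chain)
  if (max(spec$beads) > nrow(coords)) abort("Bead indices exceed chain length.")
  b <- spec$beads
  x <- .spec_angle(coords, spec)
  grad_x <- if (spec$kind == "bend") {
    .bend_angle_grad(coords[b[1], ], coords[b[2], ], coords[b[3], ])
  } else {
    .dihedral_angle_grad(coords[b[1], ], coords[b[2], ], coords[b[3], ], coords[b[4], ])
  }
  dV <- restraint_internal_gradient(x, spec)
  forces <- matrix(0, nrow(coords), 3)
  forces[b, ] <- -dV * grad_x
  structure(
    list(energy = restraint_energy(x, spec), angle_deg = x,
         internal_gradient = dV, forces = forces),
    class = "energy_force"
  )
}

#' Build the full restraint set for a conformational mode
#'
#' One bend restraint per consecutive backbone triple and one dihedral
#' restraint per consecutive quadruple. The helical mode centers bends at 96
#' degrees and dihedrals at 60 degrees; the extended-disordered mode uses 124
#' and 100 degrees. A chain of `n` residues yields `n - 2` bends and `n - 3`
#' dihedrals.
#'
#' @param n_residues Number of backbone beads (>= 3).
#' @param mode `"helical"` or `"extended"`.
#' @param sigma Width constant (degrees-squared denominator), default 14.
#' @param depth_k Well depth K in kJ/mol, default 50.
#' @return A tibble of class `restraint_set` with one row per restraint:
#'   `kind`, `i`, `j`, `k`, `l` (NA for bends), `center`, `sigma`, `depth`.
#' @examples
#' build_conformation_restraints(30, "helical")
#' @export
build_conformation_restraints <- function(n_residues, mode = c("helical", "extended"),
                                          sigma = 14, depth_k = 50) {
  mode <- match.arg(mode)
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 3) {
    abort("At least 3 residues are required to define a bend restraint.")
  }
  bend_center <- if (mode == "helical") 96 else 124
  dih_center <- if (mode == "helical") 60 else 100
  bends <- tibble(
    kind = "bend",
    i = seq_len(n_residues - 2L), j = .data$i + 1L, k = .data$i + 2L, l = NA_integer_,
    center = bend_center, sigma = sigma, depth = depth_k
  )
  dihs <- if (n_residues >= 4L) {
    tibble(
      kind = "dihedral",
      i = seq_len(n_residues - 3L), j = .data$i + 1L, k = .data$i + 2L, l = .data$i + 3L,
      center = dih_center, sigma = sigma, depth = depth_k
    )
  } else {
    tibble(kind = character(), i = integer(), j = integer(), k = integer(),
           l = integer(), center = numeric(), sigma = numeric(), depth = numeric())
  }
  out <- dplyr::bind_rows(bends, dihs)
  attr(out, "mode") <- mode
  class(out) <- c("restraint_set", class(out))
  out
}

## One row of a restraint_set tibble -> restraint_spec
.row_spec <- function(row) {
  beads <- if (row$kind == "bend") c(row$i, row$j, row$k) else c(row$i, row$j, row$k, row$l)
  restraint_spec(row$kind, row$center, row$sigma, row$depth, beads = beads)
}

#' Restraint specs of a restraint set
#'
#' @param set A `restraint_set` tibble from [build_conformation_restraints()].
#' @return List of [restraint_spec()] objects, one per row.
#' @export
restraint_specs <- function(set) {
  lapply(seq_len(nrow(set)), function(r) .row_spec(as.list(set[r, ])))
}

#' Total restraint energy and forces of a set on a chain
#'
#' @param chain A [bead_chain()] or n x 3 coordinate matrix (nm).
#' @param set A `restraint_set` tibble.
#' @return `energy_force` list: total `energy` and summed n x 3 `forces`.
#' @export
restraint_set_forces <- function(chain, set) {
  coords <- chain_coords(chain)
  energy <- 0
  forces <- matrix(0, nrow(coords), 3)
  for (spec in restraint_specs(set)) {
    ef <- cartesian_forces(coords, spec)
    energy <- energy + ef$energy
    forces <- forces + ef$forces
  }
  structure(list(energy = energy, forces = forces), class = "energy_force")
}

.spec_domain <- function(spec) {
  if (spec$kind == "bend") c(0, 180) else c(-180, 180)
}

#' Export a restraint as a tabulated bonded potential
#'
#' Writes a three-column whitespace-separated table (angle in degrees, V in
#' kJ/mol, -dV/dx in kJ/mol/deg) on a regular grid over the variable's domain
#' ([0, 180] for bends, [-180, 180] for dihedrals), in the tabulated
#' bonded-interaction dialect used by mainstream MD engines (x, f, -f').
#' One comment header line records the restraint parameters.
#'
#' @param spec A [restraint_spec()].
#' @param grid_spacing Grid step in degrees; must divide the domain span.
#' @param path Output file path; if `NULL`, the table is returned invisibly
#'   without writing.
#' @return A tibble with columns `x`, `V`, `minus_dV` (invisibly when written).
#' @export
export_tabulated_potential <- function(spec, grid_spacing = 1, path = NULL) {
  stopifnot(inherits(spec, "restraint_spec"))
  dom <- .spec_domain(spec)
  span <- dom[2] - dom[1]
  n_int <- span / grid_spacing
  if (abs(n_int - round(n_int)) > 1e-9) {
    abort(sprintf("grid_spacing %g does not divide the %s domain [%g, %g].",
                  grid_spacing, spec$kind, dom[1], dom[2]))
  }
  x <- seq(dom[1], dom[2], by = grid_spacing)
  tab <- tibble(x = x,
                V = restraint_energy(x, spec),
                minus_dV = -restraint_internal_gradient(x, spec))
  if (!is.null(path)) {
    header <- sprintf("# tabulated %s restraint: center %g deg, sigma %g, K %g kJ/mol; columns: angle_deg V_kJmol minus_dVdx",
                      spec$kind, spec$center, spec$sigma, spec$depth)
    lines <- c(header, sprintf("%12.4f %18.10e %18.10e", tab$x, tab$V, tab$minus_dV))
    writeLines(lines, path)
  }
  invisible(tab)
}

#' Read a tabulated potential written by [export_tabulated_potential()]
#'
#' @param path File path.
#' @return Tibble with columns `x`, `V`, `minus_dV`.
#' @export
read_tabulated_potential <- function(path) {
  df <- utils::read.table(path, comment.char = "#", col.names = c("x", "V", "minus_dV"))
  as_tibble(df)
}

#' Serialize a restraint set to a plain-text config
#'
#' Key-value text listing mode, centers, sigma, K and bead index ranges.
#'
#' @param set A `restraint_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraint_config <- function(set, path) {
  mode <- attr(set, "mode") %||% "custom"
  bends <- dplyr::filter(set, .data$kind == "bend")
  dihs <- dplyr::filter(set, .data$kind == "dihedral")
  lines <- c(
    paste0("mode: ", mode),
    paste0("n_bend: ", nrow(bends)),
    paste0("n_dihedral: ", nrow(dihs)),
    paste0("bend_center_deg: ", paste(unique(bends$center), collapse = ",")),
    paste0("dihedral_center_deg: ", paste(unique(dihs$center), collapse = ",")),
    paste0("sigma: ", paste(unique(set$sigma), collapse = ",")),
    paste0("depth_k_kJmol: ", paste(unique(set$depth), collapse = ",")),
    paste0("bend_triples: ", if (nrow(bends)) sprintf("%d-%d", min(bends$i), max(bends$k)) else "none"),
    paste0("dihedral_quadruples: ", if (nrow(dihs)) sprintf("%d-%d", min(dihs$i), max(dihs$l)) else "none")
  )
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
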