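## Readers and writers. Internal coordinates are always nm; GRO files are
## nm-native, PDB/DCD are Angstrom-native and divided by 10 on load.

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

#' Write labeled frames as a multi-frame GRO file
#'
#' Protein backbone beads are written as atom `BB` with their residue names;
#' phosphate beads as atom `PO4` of residue `LIP`. Coordinates in nm
#' (GRO-native).
#'
#' @param frames List of [labeled_frame()]s.
#' @param path Output path.
#' @param sequence Optional one-letter sequence for protein residue names.
#' @return `path`, invisibly.
#' @export
write_gro_frames <- function(frames, path, sequence = NULL) {
  n_res <- nrow(frames[[1]]$protein)
  resnames <- if (is.null(sequence)) {
    rep("ALA", n_res)
  } else {
    s <- strsplit(sequence, "")[[1]]
    if (length(s) != n_res) abort("Sequence length must match residue count.")
    unname(.aa3[s])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    n_p <- nrow(fr$phosphate)
    writeLines(sprintf("cgmelt frame %d", f), con)
    writeLines(sprintf("%5d", n_res + n_p), con)
    at <- 0L
    prot <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    seq_len(n_res), resnames, "BB", seq_len(n_res),
                    fr$protein[, 1], fr$protein[, 2], fr$protein[, 3])
    lip <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   n_res + seq_len(n_p), "LIP", "PO4", n_res + seq_len(n_p),
                   fr$phosphate[, 1], fr$phosphate[, 2], fr$phosphate[, 3])
    writeLines(c(prot, lip), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

## Parse one GRO atom block into name/resname/coord fields.
.parse_gro_atoms <- function(lines) {
  list(resname = trimws(substr(lines, 6, 10)),
       name = trimws(substr(lines, 11, 15)),
       x = as.numeric(substr(lines, 21, 28)),
       y = as.numeric(substr(lines, 29, 36)),
       z = as.numeric(substr(lines, 37, 44)))
}

#' Read a (multi-frame) GRO file into labeled frames
#'
#' @param path GRO file path.
#' @param backbone_selection Atom name(s) selecting protein backbone beads
#'   (default `"BB"`).
#' @param phosphate_selection Atom name(s) selecting phosphate beads
#'   (default `"PO4"`).
#' @return List of [labeled_frame()]s.
#' @export
read_gro_frames <- function(path, backbone_selection = "BB",
                            phosphate_selection = "PO4") {
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos + 1L]))) abort("Malformed GRO file.")
    n_atoms <- as.integer(trimws(lines[pos + 1L]))
    atoms <- .parse_gro_atoms(lines[(pos + 2L):(pos + 1L + n_atoms)])
    box_line <- as.numeric(strsplit(trimws(lines[pos + 2L + n_atoms]), "\\s+")[[1]])
    if (length(box_line) < 3 || any(is.na(box_line[1:3])) || any(box_line[1:3] <= 0)) {
      abort("Missing or invalid box in GRO file; periodic distances require a box.")
    }
    bb <- atoms$name %in% backbone_selection
    po <- atoms$name %in% phosphate_selection
    if (!any(bb) || !any(po)) {
      abort(sprintf(
        "Selection matched no beads (backbone '%s', phosphate '%s'). Available atom names: %s",
        paste(backbone_selection, collapse = ","),
        paste(phosphate_selection, collapse = ","),
        paste(sort(unique(atoms$name)), collapse = ", ")))
    }
    frames[[length(frames) + 1L]] <- labeled_frame(
      cbind(atoms$x[bb], atoms$y[bb], atoms$z[bb]),
      cbind(atoms$x[po], atoms$y[po], atoms$z[po]),
      box_line[1:3])
    pos <- pos + 3L + n_atoms
  }
  frames
}

#' Load labeled frames from standard MD structure/trajectory files
#'
#' Supports nm-native multi-frame GRO (read directly) and Angstrom-native
#' PDB structures, optionally with a DCD trajectory (read through bio3d and
#' converted to nm). Selections are atom names; an unresolvable selection
#' raises an error listing the available names. A box is required: periodic
#' minimum-image distances cannot be computed without one.
#'
#' @param structure_path GRO or PDB file.
#' @param trajectory_path Optional DCD trajectory (with a PDB structure).
#' @param backbone_selection,phosphate_selection Atom name(s) for the two
#'   bead groups (defaults `"BB"`, `"PO4"`).
#' @return List of [labeled_frame()]s, coordinates in nm.
#' @export
load_labeled_frames <- function(structure_path, trajectory_path = NULL,
                                backbone_selection = "BB",
                                phosphate_selection = "PO4") {
  if (!file.exists(structure_path)) {
    abort(sprintf("Structure file not found: %s", structure_path))
  }
  ext <- tolower(tools::file_ext(structure_path))
  if (!is.null(trajectory_path)) {
    text <- tolower(tools::file_ext(trajectory_path))
    if (text %in% c("xtc", "trr")) {
      abort("XTC/TRR trajectories are not supported; convert to DCD or multi-frame GRO.")
    }
  }
  if (ext == "gro") {
    return(read_gro_frames(structure_path, backbone_selection, phosphate_selection))
  }
  if (ext != "pdb") abort(sprintf("Unsupported structure format '.%s'; use GRO or PDB.", ext))
  pdb <- bio3d::read.pdb(structure_path, verbose = FALSE)
  names_all <- trimws(pdb$atom$elety)
  bb <- which(names_all %in% backbone_selection)
  po <- which(names_all %in% phosphate_selection)
  if (length(bb) == 0 || length(po) == 0) {
    abort(sprintf(
      "Selection matched no atoms (backbone '%s', phosphate '%s'). Available atom names: %s",
      paste(backbone_selection, collapse = ","),
      paste(phosphate_selection, collapse = ","),
      paste(sort(unique(names_all)), collapse = ", ")))
  }
  cryst <- grep("^CRYST1", readLines(structure_path), value = TRUE)
  if (length(cryst) == 0) {
    abort("PDB has no CRYST1 box; periodic distances require one.")
  }
  box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33)))
  angles <- as.numeric(c(substr(cryst[1], 34, 40), substr(cryst[1], 41, 47),
                         substr(cryst[1], 48, 54)))
  if (any(!is.finite(box)) || any(box <= 0)) {
    abort("PDB CRYST1 box is invalid; periodic distances require one.")
  }
  if (any(abs(angles - 90) > 1e-3)) {
    abort("Triclinic boxes are not supported; only orthorhombic cells.")
  }
  box <- box / 10
  frame_from_xyz <- function(xyz) {
    M <- matrix(xyz, ncol = 3, byrow = TRUE) / 10
    labeled_frame(M[bb, , drop = FALSE], M[po, , drop = FALSE], box)
  }
  if (is.null(trajectory_path)) {
    return(list(frame_from_xyz(pdb$xyz)))
  }
  trj <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
  lapply(seq_len(nrow(trj)), function(f) frame_from_xyz(trj[f, ]))
}

#' Write a rendered campaign to disk
#'
#' One multi-frame GRO file per temperature (`T<temp>.gro`) plus a
#' `ground_truth.csv` sidecar (true Tm, steepness, per-residue weights).
#' The campaign must have been generated with `render = TRUE`.
#'
#' @param campaign A `binding_campaign` with rendered frames.
#' @param dir Output directory (created if needed).
#' @param sequence Optional one-letter sequence for residue names.
#' @return Tibble with columns `temperature`, `path`, invisibly.
#' @export
write_campaign <- function(campaign, dir, sequence = NULL) {
  if (is.null(campaign$frames)) {
    abort("Campaign has no rendered frames; regenerate with render = TRUE.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(seq_along(campaign$temperatures), function(i) {
    p <- file.path(dir, sprintf("T%g.gro", campaign$temperatures[i]))
    write_gro_frames(campaign$frames[[i]], p, sequence = sequence)
    p
  })
  truth <- tibble(
    tm_true = campaign$params$tm_true,
    steepness = campaign$params$steepness,
    seed = campaign$seed
  )
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"))
  readr::write_csv(tibble(residue = seq_along(campaign$params$weights),
                          weight = campaign$params$weights),
                   file.path(dir, "weights.csv"))
  invisible(tibble(temperature = campaign$temperatures, path = paths))
}
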