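## Peptide-membrane contact metrics: per-residue and global contact indices,
## melting curves, TAGCI and segment-based convergence estimates.

#' Construct a labeled frame
#'
#' One trajectory frame holding the protein backbone-bead positions (one per
#' residue), the lipid phosphate-bead positions and the orthorhombic box.
#'
#' @param protein n_res x 3 matrix of backbone-bead coordinates (nm).
#' @param phosphate m x 3 matrix of phosphate-bead coordinates (nm).
#' @param box Length-3 positive edge lengths (nm). Triclinic boxes are not
#'   supported.
#' @return List of class `labeled_frame`.
#' @export
labeled_frame <- function(protein, phosphate, box) {
  protein <- as.matrix(protein)
  phosphate <- as.matrix(phosphate)
  if (nrow(phosphate) < 1) abort("At least one phosphate bead is required.")
  if (length(box) != 3 || any(box <= 0)) {
    abort("`box` must be 3 positive orthorhombic edge lengths (nm).")
  }
  structure(list(protein = protein, phosphate = phosphate, box = as.numeric(box)),
            class = "labeled_frame")
}

#' Minimum residue-phosphate distances in one frame
#'
#' For each residue, the minimum over all phosphate beads of the
#' minimum-image Euclidean distance under the orthorhombic box.
#'
#' @param frame A [labeled_frame()].
#' @return Numeric vector (nm), one value per residue.
#' @export
residue_min_distances <- function(frame) {
  stopifnot(inherits(frame, "labeled_frame"))
  P <- frame$protein
  Q <- frame$phosphate
  box <- frame$box
  d2 <- matrix(0, nrow(P), nrow(Q))
  for (dim in 1:3) {
    dd <- outer(P[, dim], Q[, dim], "-")
    dd <- dd - box[dim] * round(dd / box[dim])
    d2 <- d2 + dd * dd
  }
  sqrt(apply(d2, 1, min))
}

#' Binary membrane-contact matrix of a trajectory
#'
#' Entry (r, f) is 1 when residue r's backbone bead lies within `threshold`
#' (inclusive) of any phosphate bead in frame f, else 0. The conventional
#' threshold is 1 nm.
#'
#' @param frames List of [labeled_frame()]s.
#' @param threshold Contact distance in nm (default 1).
#' @param temperature Optional temperature label in K.
#' @return Object of class `contact_matrix`: list with `contacts`
#'   (residues x frames 0/1 matrix), `threshold`, `temperature`.
#' @export
contact_matrix <- function(frames, threshold = 1.0, temperature = NA_real_) {
  if (length(frames) < 1) abort("At least one frame is required.")
  if (threshold <= 0) abort("`threshold` must be positive.")
  cm <- vapply(frames, function(fr) {
    as.integer(residue_min_distances(fr) <= threshold)
  }, integer(nrow(frames[[1]]$protein)))
  cm <- matrix(cm, nrow = nrow(frames[[1]]$protein))
  new_contact_matrix(cm, threshold, temperature)
}

#' Wrap an existing 0/1 matrix as a contact matrix
#'
#' @param contacts residues x frames binary matrix.
#' @param threshold Contact threshold in nm.
#' @param temperature Optional temperature label in K.
#' @return `contact_matrix` object.
#' @export
new_contact_matrix <- function(contacts, threshold = 1.0, temperature = NA_real_) {
  contacts <- as.matrix(contacts)
  if (!all(contacts %in% c(0L, 1L))) abort("Contact entries must be 0 or 1.")
  storage.mode(contacts) <- "integer"
  structure(list(contacts = contacts, threshold = threshold,
                 temperature = temperature),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d residues x %d frames, threshold %g nm%s\n",
              nrow(x$contacts), ncol(x$contacts), x$threshold,
              if (is.na(x$temperature)) "" else sprintf(", T = %g K", x$temperature)))
  invisible(x)
}

#' Per-residue contact index
#'
#' The fraction of frames in which each residue contacts the membrane: the
#' row mean of the contact matrix.
#'
#' @param matrix A [contact_matrix()].
#' @return Tibble with columns `residue`, `temperature`, `index`.
#' @export
residue_contact_index <- function(matrix) {
  stopifnot(inherits(matrix, "contact_matrix"))
  tibble(residue = seq_len(nrow(matrix$contacts)),
         temperature = matrix$temperature,
         index = rowMeans(matrix$contacts))
}

## Resolve a window argument to residue indices.
.resolve_window <- function(window, n_res) {
  if (is.null(window)) return(seq_len(n_res))
  window <- as.integer(window)
  if (any(window < 1) || any(window > n_res)) {
    abort(sprintf("Window exceeds sequence (1..%d).", n_res))
  }
  window
}

#' Global contact index
#'
#' Unweighted mean of per-residue contact indices over a residue window
#' (the full sequence when `window` is `NULL`).
#'
#' @param per_residue Tibble from [residue_contact_index()] (or a bare numeric
#'   vector of per-residue indices).
#' @param window Optional integer vector of residue ids (e.g. `1:15`).
#' @return Scalar fraction in `[0, 1]`.
#' @export
global_contact_index <- function(per_residue, window = NULL) {
  v <- if (is.numeric(per_residue)) per_residue else per_residue$index
  idx <- .resolve_window(window, length(v))
  mean(v[idx])
}

#' Segment-based convergence estimate
#'
#' Splits the frames into `n_segments` consecutive near-equal blocks (earlier
#' blocks take the remainder), computes the windowed global contact index in
#' each block, and the population standard deviation across blocks.
#'
#' @param matrix A [contact_matrix()].
#' @param n_segments Number of consecutive blocks (default 3).
#' @param window Optional residue window.
#' @return List with `segments` (tibble: `segment`, `n_frames`, `gci`) and
#'   `sd` (population standard deviation across segments).
#' @export
convergence_segments <- function(matrix, n_segments = 3, window = NULL) {
  stopifnot(inherits(matrix, "contact_matrix"))
  nf <- ncol(matrix$contacts)
  if (nf < n_segments) {
    abort(sprintf("Need at least %d frames for %d segments.", n_segments, n_segments))
  }
  sizes <- rep(nf %/% n_segments, n_segments)
  rem <- nf %% n_segments
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1) + 1L)
  idx <- .resolve_window(window, nrow(matrix$contacts))
  gci <- purrr::map_dbl(seq_len(n_segments), function(s) {
    mean(matrix$contacts[idx, starts[s]:stops[s], drop = FALSE])
  })
  list(segments = tibble(segment = seq_len(n_segments), n_frames = sizes, gci = gci),
       sd = sqrt(mean((gci - mean(gci))^2)))
}

#' Melting curve from per-temperature contact matrices
#'
#' The windowed global contact index at each temperature, with the
#' three-segment convergence spread attached. Output rows are sorted by
#' temperature regardless of input order.
#'
#' @param matrices List of [contact_matrix()] objects, one per temperature
#'   (each must carry its `temperature`).
#' @param window Optional residue window.
#' @param n_segments Segments for the convergence spread (default 3).
#' @return Tibble of class `melting_curve`: `temperature`, `gci`,
#'   `segment_sd`, `n_frames`.
#' @export
melting_curve <- function(matrices, window = NULL, n_segments = 3) {
  if (length(matrices) < 2) abort("At least two temperatures are required.")
  temps <- purrr::map_dbl(matrices, "temperature")
  if (anyNA(temps)) abort("Every contact matrix must carry a temperature.")
  out <- purrr::map_dfr(matrices, function(cm) {
    seg <- convergence_segments(cm, n_segments = n_segments, window = window)
    tibble(temperature = cm$temperature,
           gci = global_contact_index(residue_contact_index(cm), window),
           segment_sd = seg$sd,
           n_frames = ncol(cm$contacts))
  })
  out <- dplyr::arrange(out, .data$temperature)
  class(out) <- c("melting_curve", class(out))
  out
}

#' Temperature-averaged global contact index (TAGCI)
#'
#' The global contact index of a fixed window of `window_len` residues
#' starting at the first residue of the construct, averaged with equal
#' weights over the temperature ladder. One scalar per construct; the
#' conventional window is 15 residues over 15 temperatures.
#'
#' @param matrices List of per-temperature [contact_matrix()] objects.
#' @param construct_name Construct label for the output.
#' @param window_len Window length in residues (default 15).
#' @param n_temperatures Required ladder length (default 15); set `NULL` to
#'   accept any.
#' @return Tibble of class `tagci_result`: `construct`, `window_start`,
#'   `window_len`, `tagci`.
#' @export
tagci <- function(matrices, construct_name = "construct", window_len = 15,
                  n_temperatures = 15) {
  n_res <- nrow(matrices[[1]]$contacts)
  if (n_res < window_len) {
    abort(sprintf(
      "Construct has %d residues but the TAGCI window requires at least %d.",
      n_res, window_len))
  }
  if (!is.null(n_temperatures) && length(matrices) != n_temperatures) {
    abort(sprintf("Expected %d temperatures, got %d.", n_temperatures, length(matrices)))
  }
  curve <- melting_curve(matrices, window = seq_len(window_len))
  out <- tibble(construct = construct_name, window_start = 1L,
                window_len = as.integer(window_len), tagci = mean(curve$gci))
  class(out) <- c("tagci_result", class(out))
  out
}
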