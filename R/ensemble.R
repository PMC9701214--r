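# Ensemble container: an ordered atom topology plus an F x A x 3 coordinate
# array in Angstroms. All analysis stages consume this one type.

#' Construct a conformational ensemble
#'
#' An ensemble couples a fixed atom topology with a stack of coordinate
#' frames. Every frame must carry exactly the topology's atoms, in topology
#' order; this is the interchange format between the trajectory reader, the
#' synthetic generator, and every analysis stage.
#'
#' @param topology A tibble with one row per atom and columns `serial`,
#'   `atom_name`, `residue_name`, `chain_id`, `residue_number`, `element`,
#'   `record_class` (`"polymer"` or `"hetero"`).
#' @param coords Numeric array of dimension `F x A x 3` (frames, atoms, xyz),
#'   in Angstroms, or an `A x 3` matrix for a single frame.
#' @param frame_labels Optional character vector of length `F`.
#'
#' @return An object of class `ensemble`.
#' @export
#' @examples
#' top <- tibble::tibble(
#'   serial = 1L, atom_name = "CA", residue_name = "GLY", chain_id = "A",
#'   residue_number = 1L, element = "C", record_class = "polymer"
#' )
#' ensemble(top, matrix(c(1, 2, 3), nrow = 1))
ensemble <- function(topology, coords, frame_labels = NULL) {
  topology <- tibble::as_tibble(topology)
  required <- c(
    "serial", "atom_name", "residue_name", "chain_id",
    "residue_number", "element", "record_class"
  )
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0) {
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be an F x A x 3 array", call. = FALSE)
  }
  if (dim(coords)[2] != nrow(topology)) {
    stop(
      "coords has ", dim(coords)[2], " atoms per frame but topology has ",
      nrow(topology), " atoms",
      call. = FALSE
    )
  }
  if (dim(coords)[1] < 1L) stop("ensemble needs at least one frame", call. = FALSE)
  if (!all(is.finite(coords))) stop("coords contain non-finite values", call. = FALSE)
  if (any(topology$residue_number < 1L)) {
    stop("residue numbers must be >= 1", call. = FALSE)
  }
  key <- paste(topology$chain_id, topology$residue_number, topology$atom_name,
    sep = "|"
  )
  if (anyDuplicated(key)) {
    stop("(chain_id, residue_number, atom_name) must be unique within a topology",
      call. = FALSE
    )
  }
  if (!is.null(frame_labels) && length(frame_labels) != dim(coords)[1]) {
    stop("frame_labels length must equal the number of frames", call. = FALSE)
  }
  structure(
    list(topology = topology, coords = coords, frame_labels = frame_labels),
    class = "ensemble"
  )
}

#' Number of frames in an ensemble
#' @param x An `ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  dim(x$coords)[1]
}

#' Number of atoms in an ensemble topology
#' @param x An `ensemble`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  nrow(x$topology)
}

#' Extract one frame's coordinates as an A x 3 matrix
#' @param x An `ensemble`.
#' @param i Frame index (1-based).
#' @return Numeric `A x 3` matrix.
#' @export
frame_coords <- function(x, i) {
  stopifnot(inherits(x, "ensemble"), i >= 1, i <= n_frames(x))
  matrix(x$coords[i, , ], ncol = 3L)
}

#' Subset an ensemble to a set of frames
#' @param x An `ensemble`.
#' @param idx Integer frame indices, each in `[1, F]`.
#' @return An `ensemble` with `length(idx)` frames, in the given order.
#' @export
subset_frames <- function(x, idx) {
  stopifnot(inherits(x, "ensemble"))
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > n_frames(x))) {
    stop("frame indices out of range", call. = FALSE)
  }
  ensemble(
    x$topology,
    x$coords[idx, , , drop = FALSE],
    frame_labels = if (!is.null(x$frame_labels)) x$frame_labels[idx]
  )
}

#' Concatenate ensembles sharing one topology
#' @param ... Ensembles with identical topologies.
#' @return One `ensemble` with the frames of all inputs, in argument order.
#' @export
bind_frames <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, logical(1), "ensemble")))
  first <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(first$topology, p$topology)) {
      stop("ensembles to bind must share an identical topology", call. = FALSE)
    }
  }
  coords <- do.call(abind3, lapply(parts, function(p) p$coords))
  labels <- unlist(lapply(parts, function(p) {
    if (is.null(p$frame_labels)) rep(NA_character_, n_frames(p)) else p$frame_labels
  }))
  if (all(is.na(labels))) labels <- NULL
  ensemble(first$topology, coords, frame_labels = labels)
}

# bind F x A x 3 arrays along the frame axis
abind3 <- function(...) {
  arrs <- list(...)
  a <- dim(arrs[[1]])[2]
  total <- sum(vapply(arrs, function(x) dim(x)[1], integer(1)))
  out <- array(NA_real_, dim = c(total, a, 3L))
  at <- 0L
  for (x in arrs) {
    f <- dim(x)[1]
    out[at + seq_len(f), , ] <- x
    at <- at + f
  }
  out
}

#' @export
print.ensemble <- function(x, ...) {
  cat(
    "<ensemble> ", n_frames(x), " frame(s), ", n_atoms(x), " atoms (",
    sum(x$topology$record_class == "polymer"), " polymer, ",
    sum(x$topology$record_class == "hetero"), " hetero), chains: ",
    paste(unique(x$topology$chain_id), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}
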