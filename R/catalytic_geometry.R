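# Hydride-transfer geometry: per-frame donor-acceptor distance between the
# nicotinamide C4 (hydride donor) and the flavin N5 (acceptor), classified
# into active/inactive poses at a distance threshold. Frames beyond the
# threshold typically correspond to the cofactor having left the binding
# cavity, so no capping is applied to raw distances: only the binary
# classification aggregates them.

#' Per-frame donor-acceptor distance
#'
#' Euclidean distance in Angstroms between two single-atom selections for
#' every frame. No periodic-image handling: inputs are whole-molecule
#' ensembles, never wrapped simulation boxes.
#'
#' @param x An [ensemble()].
#' @param donor An `atom_selection` resolving to exactly one atom
#'   (e.g. the nicotinamide C4).
#' @param acceptor An `atom_selection` resolving to exactly one atom
#'   (e.g. the FAD N5).
#' @return Numeric vector of length `F` (frames), Angstroms.
#' @export
distance_series <- function(x, donor, acceptor) {
  stopifnot(inherits(x, "ensemble"))
  i <- resolve_single_atom(x, donor, "donor selection")
  j <- resolve_single_atom(x, acceptor, "acceptor selection")
  d <- x$coords[, i, , drop = FALSE] - x$coords[, j, , drop = FALSE]
  sqrt(rowSums(matrix(d, ncol = 3L)^2))
}

#' Classify poses as catalytically active by distance threshold
#'
#' Frames with donor-acceptor distance at or below the threshold are
#' active; the occupancy is the active fraction. Equality counts as active,
#' so the documented default threshold classifies a frame sitting exactly
#' at 4.5 Angstroms deterministically.
#'
#' @param distances Numeric vector of positive, finite distances (Angstroms).
#' @param threshold Distance cutoff in Angstroms (default 4.5).
#' @return A `distance_series` object: list with `series` (tibble of
#'   `frame`, `distance`, `active`), `threshold`, `occupancy`, `n_frames`.
#' @export
#' @examples
#' active_occupancy(c(3, 4, 5))$occupancy # 2/3
active_occupancy <- function(distances, threshold = 4.5) {
  if (length(distances) == 0) stop("empty distance series", call. = FALSE)
  if (!all(is.finite(distances))) {
    stop("distances must all be finite", call. = FALSE)
  }
  if (any(distances <= 0)) {
    stop("distances must be positive", call. = FALSE)
  }
  active <- distances <= threshold
  structure(
    list(
      series = tibble::tibble(
        frame = seq_along(distances),
        distance = as.numeric(distances),
        active = active
      ),
      threshold = threshold,
      occupancy = mean(active),
      n_frames = length(distances)
    ),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf(
    "<distance_series> %d frames, threshold %.2f Angstrom, active-pose occupancy %.1f%%\n",
    x$n_frames, x$threshold, 100 * x$occupancy
  ))
  invisible(x)
}

#' @export
tidy.distance_series <- function(x, ...) x$series

#' @export
glance.distance_series <- function(x, ...) {
  tibble::tibble(
    occupancy = x$occupancy, threshold = x$threshold, n_frames = x$n_frames,
    mean_distance = mean(x$series$distance),
    median_distance = stats::median(x$series$distance)
  )
}

#' One-call hydride-transfer occupancy for an ensemble
#'
#' Convenience wrapper chaining [distance_series()] and
#' [active_occupancy()].
#'
#' @inheritParams distance_series
#' @inheritParams active_occupancy
#' @return A `distance_series` object.
#' @export
hydride_occupancy <- function(x, donor, acceptor, threshold = 4.5) {
  active_occupancy(distance_series(x, donor, acceptor), threshold = threshold)
}
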