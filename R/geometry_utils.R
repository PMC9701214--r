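# Row-wise vector geometry on N x 3 matrices. Used by the torsion measurer,
# the internal-coordinate backbone builder, and the distance stage.

vcross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

vnorm <- function(a) sqrt(rowSums(a^2))

vunit <- function(a) a / vnorm(a)

as_row3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3L) else p
}

#' Torsion (dihedral) angle of four points
#'
#' Computes the signed dihedral about the 2-3 axis in the IUPAC convention:
#' right-handed, cis = 0 degrees, values in (-180, 180]. Inputs may be single
#' 3-vectors or N x 3 matrices (one torsion per row).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors or N x 3 matrices.
#' @return Numeric vector of angles in degrees.
#' @export
#' @examples
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)) # -90
torsion_angle <- function(p1, p2, p3, p4) {
  p1 <- as_row3(p1); p2 <- as_row3(p2); p3 <- as_row3(p3); p4 <- as_row3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  x <- rowSums(n1 * n2)
  y <- rowSums(vcross(n1, n2) * vunit(b2))
  ang <- atan2(y, x) * 180 / pi
  # principal range (-180, 180]
  ifelse(ang <= -180, ang + 360, ang)
}

# Place atom D from A-B-C internal coordinates: bond |C-D| = r, angle
# B-C-D = theta_deg, torsion A-B-C-D = tau_deg (IUPAC sign, matching
# torsion_angle). Vectorized over rows; tau may vary per row.
nerf_place <- function(a, b, c, r, theta_deg, tau_deg) {
  a <- as_row3(a); b <- as_row3(b); c <- as_row3(c)
  nr <- max(nrow(a), length(tau_deg))
  if (nrow(a) == 1L && nr > 1L) {
    a <- a[rep(1L, nr), , drop = FALSE]
    b <- b[rep(1L, nr), , drop = FALSE]
    c <- c[rep(1L, nr), , drop = FALSE]
  }
  theta <- theta_deg * pi / 180
  tau <- rep_len(tau_deg, nr) * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- cbind(-r * cos(theta), r * sin(theta) * cos(tau), r * sin(theta) * sin(tau))
  c + d2[, 1] * bc + d2[, 2] * m + d2[, 3] * n
}
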