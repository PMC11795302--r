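# Internal vector geometry on point chains. All angles in radians here;
# user-facing twist/supertwist angles are converted to degrees at the surface.

.vnorm <- function(v) sqrt(sum(v * v))

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Bond lengths, bond angles and dihedral angles of a point chain
#'
#' These measure the internal coordinates used by the bonded force field:
#' distances between points `order` apart, the planar angle at every interior
#' point of consecutive triples, and the torsion (dihedral) angle of every
#' consecutive quadruple using the standard atan2 convention (signed,
#' in (-pi, pi]).
#'
#' @param frame a [filament_frame()] or n x 3 matrix.
#' @param order integer neighbour offset for `chain_bond_lengths`.
#' @return numeric vector of lengths (nm) or angles (rad). Dihedrals of
#'   collinear quadruples are `NA`.
#' @export
chain_bond_lengths <- function(frame, order = 1L) {
  p <- frame_points(frame)
  n <- nrow(p)
  if (order >= n) return(numeric(0))
  idx <- seq_len(n - order)
  sqrt(rowSums((p[idx + order, , drop = FALSE] - p[idx, , drop = FALSE])^2))
}

#' @rdname chain_bond_lengths
#' @export
chain_angles <- function(frame) {
  p <- frame_points(frame)
  n <- nrow(p)
  if (n < 3L) return(numeric(0))
  vapply(seq_len(n - 2L), function(i) {
    u <- p[i, ] - p[i + 1L, ]
    v <- p[i + 2L, ] - p[i + 1L, ]
    cth <- sum(u * v) / (.vnorm(u) * .vnorm(v))
    acos(min(1, max(-1, cth)))
  }, numeric(1))
}

#' @rdname chain_bond_lengths
#' @export
chain_dihedrals <- function(frame) {
  p <- frame_points(frame)
  n <- nrow(p)
  if (n < 4L) return(numeric(0))
  vapply(seq_len(n - 3L), function(i) {
    b1 <- p[i + 1L, ] - p[i, ]
    b2 <- p[i + 2L, ] - p[i + 1L, ]
    b3 <- p[i + 3L, ] - p[i + 2L, ]
    n1 <- .cross(b1, b2)
    n2 <- .cross(b2, b3)
    n1n <- .vnorm(n1); n2n <- .vnorm(n2)
    if (n1n < 1e-12 || n2n < 1e-12) return(NA_real_)
    m1 <- .cross(n1, b2 / .vnorm(b2))
    atan2(sum(m1 * n2), sum(n1 * n2))
  }, numeric(1))
}

# Rotation matrix for angle theta (rad) about the +x axis, right-handed.
.rot_x <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(1, 0, 0,
           0, ct, -st,
           0, st, ct), 3L, 3L, byrow = TRUE)
}

# Signed angle (rad) from vector a to vector b measured right-handed about
# unit axis ax; a and b are assumed perpendicular to ax.
.signed_angle_about <- function(a, b, ax) {
  atan2(sum(.cross(a, b) * ax), sum(a * b))
}
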