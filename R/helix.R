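#' Helical lattice geometry of the monomer-scale chain
#'
#' Describes the ideal single-start helix on which monomer beads are placed:
#' axial rise per subunit, signed azimuthal twist per subunit (negative for a
#' left-handed lattice, as in actin's short-pitch helix), radius of the bead
#' track around the axis, and subunit count. Defaults are canonical actin
#' geometry: 2.74 nm rise and -166.7 degrees twist per subunit at 1 nm radius.
#'
#' @param rise_per_subunit axial rise per subunit (nm), > 0.
#' @param twist_per_subunit signed twist per subunit (degrees).
#' @param helix_radius radius of the bead helix (nm), >= 0.
#' @param n_subunits number of beads, >= 4 (minimum for one dihedral).
#' @return An object of class `helix_geometry`.
#' @seealso [build_ideal_helix()]
#' @export
helix_geometry <- function(rise_per_subunit = 2.74,
                           twist_per_subunit = -166.7,
                           helix_radius = 1.0,
                           n_subunits = 50L) {
  if (!is.numeric(rise_per_subunit) || rise_per_subunit <= 0)
    stop("rise_per_subunit must be > 0")
  if (helix_radius < 0)
    stop("helix_radius must be >= 0")
  n_subunits <- as.integer(n_subunits)
  if (is.na(n_subunits) || n_subunits < 4L)
    stop("n_subunits must be an integer >= 4 (one dihedral needs 4 beads)")
  structure(
    list(rise_per_subunit = as.numeric(rise_per_subunit),
         twist_per_subunit = as.numeric(twist_per_subunit),
         helix_radius = as.numeric(helix_radius),
         n_subunits = n_subunits),
    class = "helix_geometry"
  )
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat(sprintf(
    "<helix_geometry> %d subunits, rise %.3g nm, twist %.4g deg, radius %.3g nm\n",
    x$n_subunits, x$rise_per_subunit, x$twist_per_subunit, x$helix_radius))
  invisible(x)
}

#' Place beads on an ideal helix
#'
#' Builds the reference (zero-force) structure of the monomer-scale chain:
#' bead k (0-based) sits at x = k * rise, at azimuth k * twist on a circle of
#' the given radius around the +x axis, starting at azimuth 0 (the +y
#' direction) at the origin end. With radius 0 the helix degenerates to a
#' straight line of equally spaced beads on +x. Consecutive-bead spacing is
#' constant by construction (screw symmetry).
#'
#' @param geometry a [helix_geometry()].
#' @return A [filament_frame()] of `n_subunits` bead positions.
#' @examples
#' h <- build_ideal_helix(helix_geometry(n_subunits = 10))
#' range(segment_lengths(h))  # constant chord length
#' @export
build_ideal_helix <- function(geometry) {
  if (!inherits(geometry, "helix_geometry"))
    geometry <- do.call(helix_geometry, as.list(geometry))
  k <- seq_len(geometry$n_subunits) - 1
  phi <- k * geometry$twist_per_subunit * pi / 180
  pts <- cbind(
    x = k * geometry$rise_per_subunit,
    y = geometry$helix_radius * cos(phi),
    z = geometry$helix_radius * sin(phi)
  )
  # place the axis through the origin: shift the circle centre to y = z = 0
  frame <- filament_frame(pts, time = 0)
  attr(frame, "geometry") <- geometry
  frame
}

#' Closed-form chord length between beads on an ideal helix
#'
#' The distance between beads `order` subunits apart:
#' sqrt((order * rise)^2 + (2 r sin(order * twist / 2))^2). Used as the
#' analytic oracle for bond-length tests and for equilibrium bond targets.
#'
#' @param geometry a [helix_geometry()].
#' @param order integer subunit offset.
#' @return chord length in nm.
#' @export
helix_chord_length <- function(geometry, order = 1L) {
  dphi <- order * geometry$twist_per_subunit * pi / 180
  sqrt((order * geometry$rise_per_subunit)^2 +
       (2 * geometry$helix_radius * sin(dphi / 2))^2)
}
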