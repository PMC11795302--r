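#' Bonded force field for a filament bead chain
#'
#' Holds the bonded-interaction constants and equilibrium targets that enforce
#' filament structure: harmonic bonds between beads at each neighbour offset in
#' `neighbor_orders`, harmonic angles on consecutive bead triples, and cosine
#' dihedrals on consecutive bead quadruples. The dihedral potential is
#' `U = k * (1 + cos(phi - phi0 - pi))`, which has its minimum at `phi = phi0`.
#' A force field is chiral exactly when it carries dihedral terms: dihedrals
#' encode the handedness of the helical lattice and are what couples bending
#' to axial twist.
#'
#' Equilibrium targets are per-term vectors (one entry per bond/angle/dihedral
#' along the chain) so that arbitrary reference structures are representable;
#' for an ideal helix all entries of a class coincide by screw symmetry.
#'
#' @param bond_constants named numeric: stiffness (pN/nm) per neighbour order,
#'   names `"1"`, `"2"`, ...
#' @param equilibrium_bonds list of numeric vectors (nm), same names.
#' @param angle_constant stiffness of consecutive-triple angles (pN nm / rad^2).
#' @param equilibrium_angles numeric vector (rad), length n - 2.
#' @param dihedral_constant cosine-dihedral amplitude (pN nm); 0 or `NULL` for
#'   an achiral chain.
#' @param equilibrium_dihedrals numeric vector (rad), length n - 3, or `NULL`.
#' @return An object of class `force_field`.
#' @seealso [derive_topology_targets()], [compute_forces()]
#' @export
force_field <- function(bond_constants, equilibrium_bonds,
                        angle_constant = 0, equilibrium_angles = numeric(0),
                        dihedral_constant = 0,
                        equilibrium_dihedrals = NULL) {
  bond_constants <- unlist(bond_constants)
  if (is.null(names(bond_constants)) || any(names(bond_constants) == ""))
    stop("bond_constants must be named by neighbour order (\"1\", \"2\", ...)")
  if (any(bond_constants < 0) || angle_constant < 0)
    stop("stiffnesses must be >= 0")
  if (!is.null(dihedral_constant) && length(dihedral_constant) &&
      dihedral_constant < 0)
    stop("dihedral_constant must be >= 0")
  if (!setequal(names(bond_constants), names(equilibrium_bonds)))
    stop("equilibrium_bonds must have the same neighbour orders as bond_constants")
  if (!all(vapply(equilibrium_bonds, function(b) all(is.finite(b)), logical(1))))
    stop("equilibrium bond targets must be finite")
  if (!all(is.finite(equilibrium_angles)))
    stop("equilibrium angle targets must be finite")
  chiral <- !is.null(dihedral_constant) && length(dihedral_constant) == 1L &&
    dihedral_constant > 0 && length(equilibrium_dihedrals) > 0
  if (chiral && !all(is.finite(equilibrium_dihedrals)))
    stop("a chiral force field needs finite equilibrium dihedral targets ",
         "(is the reference structure collinear?)")
  structure(
    list(
      neighbor_orders = sort(as.integer(names(bond_constants))),
      bond_constants = bond_constants[order(as.integer(names(bond_constants)))],
      equilibrium_bonds = equilibrium_bonds[
        order(as.integer(names(equilibrium_bonds)))],
      angle_constant = as.numeric(angle_constant),
      equilibrium_angles = as.numeric(equilibrium_angles),
      dihedral_constant = if (chiral) as.numeric(dihedral_constant) else 0,
      equilibrium_dihedrals = if (chiral) as.numeric(equilibrium_dihedrals)
                              else numeric(0),
      chiral = chiral
    ),
    class = "force_field"
  )
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("<force_field> %s, neighbour orders {%s}\n",
              if (x$chiral) "chiral (dihedrals present)" else "achiral",
              paste(x$neighbor_orders, collapse = ",")))
  for (o in x$neighbor_orders)
    cat(sprintf("  bonds order %d: k = %g pN/nm, r0 ~ %.3f nm (%d terms)\n",
                o, x$bond_constants[[as.character(o)]],
                mean(x$equilibrium_bonds[[as.character(o)]]),
                length(x$equilibrium_bonds[[as.character(o)]])))
  if (x$angle_constant > 0)
    cat(sprintf("  angles: k = %g pN nm/rad^2, theta0 ~ %.3f rad (%d terms)\n",
                x$angle_constant, mean(x$equilibrium_angles),
                length(x$equilibrium_angles)))
  if (x$chiral)
    cat(sprintf("  dihedrals: k = %g pN nm, phi0 ~ %.3f rad (%d terms)\n",
                x$dihedral_constant, mean(x$equilibrium_dihedrals),
                length(x$equilibrium_dihedrals)))
  invisible(x)
}

#' Measure equilibrium targets from a reference structure
#'
#' Reads the equilibrium bond lengths, angles and dihedrals off a reference
#' (ideal) structure so that this structure is a zero-force configuration of
#' the resulting force field. A collinear reference yields angle targets of pi
#' and undefined dihedrals; asking for a chiral force field
#' (`dihedral_constant > 0`) from such a reference is an error.
#'
#' @param ideal the reference structure, a [filament_frame()] with >= 4 points.
#' @param neighbor_orders integer offsets to bond, e.g. `c(1, 2)` for the
#'   monomer-scale chain, `1` for the fiber-scale chain.
#' @param bond_constants numeric stiffness per order (recycled if scalar).
#' @param angle_constant,dihedral_constant stiffnesses; see [force_field()].
#' @return A [force_field()] whose equilibrium targets reproduce `ideal`.
#' @examples
#' helix <- build_ideal_helix(helix_geometry(n_subunits = 12))
#' ff <- derive_topology_targets(helix, c(1, 2),
#'                               bond_constants = 100, angle_constant = 5000,
#'                               dihedral_constant = 300)
#' max(abs(compute_forces(helix, ff)))  # ~0: ideal structure is a minimum
#' @export
derive_topology_targets <- function(ideal, neighbor_orders = c(1L, 2L),
                                    bond_constants = 100,
                                    angle_constant = 0,
                                    dihedral_constant = 0) {
  p <- frame_points(ideal)
  n <- nrow(p)
  neighbor_orders <- sort(as.integer(neighbor_orders))
  if (n < 4L)
    stop("reference structure needs at least 4 points (one dihedral)")
  if (max(neighbor_orders) >= n)
    stop("neighbour order ", max(neighbor_orders),
         " needs more than ", n, " points")
  if (length(bond_constants) == 1L)
    bond_constants <- rep(bond_constants, length(neighbor_orders))
  names(bond_constants) <- as.character(neighbor_orders)
  eq_bonds <- lapply(neighbor_orders, function(o) chain_bond_lengths(ideal, o))
  names(eq_bonds) <- as.character(neighbor_orders)
  eq_angles <- if (angle_constant > 0) chain_angles(ideal) else numeric(0)
  eq_dih <- NULL
  if (!is.null(dihedral_constant) && dihedral_constant > 0) {
    eq_dih <- chain_dihedrals(ideal)
    if (anyNA(eq_dih))
      stop("reference structure has collinear quadruples: ",
           "dihedral targets are undefined; use dihedral_constant = 0")
  }
  force_field(bond_constants, eq_bonds,
              angle_constant = angle_constant, equilibrium_angles = eq_angles,
              dihedral_constant = dihedral_constant,
              equilibrium_dihedrals = eq_dih)
}

# Expand a force_field into flat per-term index/parameter vectors for the
# C++ kernels. Indices are 0-based.
.ff_terms <- function(ff, n) {
  bonds_i <- integer(0); bonds_j <- integer(0)
  bonds_k <- numeric(0); bonds_r0 <- numeric(0)
  for (o in ff$neighbor_orders) {
    key <- as.character(o)
    r0 <- ff$equilibrium_bonds[[key]]
    if (length(r0) != n - o)
      stop("force field expects ", length(r0) + o,
           " points for order-", o, " bonds, frame has ", n)
    idx <- seq_len(n - o)
    bonds_i <- c(bonds_i, idx - 1L)
    bonds_j <- c(bonds_j, idx + o - 1L)
    bonds_k <- c(bonds_k, rep(ff$bond_constants[[key]], n - o))
    bonds_r0 <- c(bonds_r0, r0)
  }
  ang_idx <- integer(0); ang_k <- numeric(0); ang_t0 <- numeric(0)
  if (ff$angle_constant > 0) {
    if (length(ff$equilibrium_angles) != n - 2L)
      stop("force field expects ", length(ff$equilibrium_angles) + 2L,
           " points for angles, frame has ", n)
    ang_idx <- seq_len(n - 2L) - 1L
    ang_k <- rep(ff$angle_constant, n - 2L)
    ang_t0 <- ff$equilibrium_angles
  }
  dih_idx <- integer(0); dih_k <- numeric(0); dih_p0 <- numeric(0)
  if (ff$chiral) {
    if (length(ff$equilibrium_dihedrals) != n - 3L)
      stop("force field expects ", length(ff$equilibrium_dihedrals) + 3L,
           " points for dihedrals, frame has ", n)
    dih_idx <- seq_len(n - 3L) - 1L
    dih_k <- rep(ff$dihedral_constant, n - 3L)
    dih_p0 <- ff$equilibrium_dihedrals
  }
  list(bonds_i = bonds_i, bonds_j = bonds_j,
       bonds_k = bonds_k, bonds_r0 = bonds_r0,
       ang_i = ang_idx, ang_k = ang_k, ang_t0 = ang_t0,
       dih_i = dih_idx, dih_k = dih_k, dih_p0 = dih_p0)
}

#' Bonded forces on a filament frame
#'
#' Returns the exact negative gradient of the total bonded energy (harmonic
#' bonds, harmonic angles, cosine dihedrals) with respect to every bead
#' position. Being internal forces, they sum to zero and exert zero net
#' torque.
#'
#' @param frame a [filament_frame()] matching the force-field topology.
#' @param ff a [force_field()].
#' @return An n x 3 matrix of forces (pN), with attribute `"energy"` holding
#'   the total bonded energy (pN nm).
#' @export
compute_forces <- function(frame, ff) {
  p <- frame_points(frame)
  seglen <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                          p[-nrow(p), , drop = FALSE])^2))
  if (any(seglen < 1e-12)) {
    bad <- which(seglen < 1e-12)[1L]
    stop("degenerate geometry: particles ", bad, " and ", bad + 1L,
         " coincide")
  }
  terms <- .ff_terms(ff, nrow(p))
  res <- forces_cpp(p, terms)
  f <- res$forces
  colnames(f) <- c("x", "y", "z")
  attr(f, "energy") <- res$energy
  f
}

#' Total bonded energy of a frame
#'
#' @inheritParams compute_forces
#' @return Scalar energy in pN nm.
#' @export
bonded_energy <- function(frame, ff) {
  attr(compute_forces(frame, ff), "energy")
}
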