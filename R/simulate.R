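#' Thermal bath for overdamped Brownian dynamics
#'
#' Parameters of the overdamped Langevin (Euler-Maruyama) integrator: thermal
#' energy kT in pN nm (4.1 pN nm at room temperature), isotropic per-particle
#' drag coefficient in pN s / nm, and the integer seed of the package's own
#' counter-based random number generator (identical seeds give bitwise
#' identical trajectories).
#'
#' @param kT thermal energy (pN nm), >= 0; 0 disables noise.
#' @param drag_per_particle drag coefficient gamma (pN s / nm), > 0.
#' @param seed integer RNG seed.
#' @return An object of class `thermal_model`.
#' @export
thermal_model <- function(kT = 4.1, drag_per_particle = stokes_drag(2), seed = 1L) {
  if (kT < 0) stop("kT must be >= 0")
  if (drag_per_particle <= 0) stop("drag_per_particle must be > 0")
  structure(list(kT = as.numeric(kT),
                 drag_per_particle = as.numeric(drag_per_particle),
                 seed = as.numeric(seed)),
            class = "thermal_model")
}

#' Stokes drag of a sphere
#'
#' gamma = 6 pi eta r, converted to pN s / nm, with optional scale factor
#' (used to rescale the monomer-bead drag; see the methods vignette).
#'
#' @param radius_nm bead radius in nm.
#' @param viscosity_mPas dynamic viscosity in mPa s (water: 1).
#' @param scale dimensionless multiplier.
#' @return drag coefficient in pN s / nm.
#' @export
stokes_drag <- function(radius_nm, viscosity_mPas = 1, scale = 1) {
  6 * pi * viscosity_mPas * 1e-3 * radius_nm * 1e-6 * scale
}

#' Translate/relax compression protocol
#'
#' The anchored-end compression protocol: one end of the filament is held
#' fixed while the other end's anchor particles are translated along -x for
#' one time step, then allowed to relax for nine; the cycle repeats until the
#' x-projected end-to-end distance reaches
#' `compression_fraction * initial_end_to_end`. The displacement applied
#' during the translation step equals `velocity * timestep * 10` so that the
#' end moves at the nominal compression velocity on average.
#'
#' @param velocity_um_s compression velocity (µm/s), > 0.
#' @param timestep_s protocol time step (s), > 0.
#' @param translate_steps number of translation steps per cycle (1).
#' @param relax_steps number of relaxation steps per cycle (9).
#' @param initial_end_to_end_nm initial end-to-end distance (nm).
#' @param compression_fraction target fraction of the initial end-to-end
#'   distance (0.7 compresses to 70 %).
#' @param fixed_end_particles anchor particles held fixed at the barbed end.
#' @param moved_end_particles anchor particles translated at the pointed end.
#' @return An object of class `compression_protocol`.
#' @export
compression_protocol <- function(velocity_um_s,
                                 timestep_s,
                                 translate_steps = 1L,
                                 relax_steps = 9L,
                                 initial_end_to_end_nm = 500,
                                 compression_fraction = 0.7,
                                 fixed_end_particles = 3L,
                                 moved_end_particles = 3L) {
  if (velocity_um_s <= 0) stop("velocity_um_s must be > 0")
  if (timestep_s <= 0) stop("timestep_s must be > 0")
  if (compression_fraction <= 0 || compression_fraction >= 1)
    stop("compression_fraction must be in (0, 1)")
  if (translate_steps < 1L || relax_steps < 0L)
    stop("need at least one translate step per cycle")
  structure(list(
    velocity_um_s = as.numeric(velocity_um_s),
    timestep_s = as.numeric(timestep_s),
    translate_steps = as.integer(translate_steps),
    relax_steps = as.integer(relax_steps),
    initial_end_to_end_nm = as.numeric(initial_end_to_end_nm),
    compression_fraction = as.numeric(compression_fraction),
    fixed_end_particles = as.integer(fixed_end_particles),
    moved_end_particles = as.integer(moved_end_particles)
  ), class = "compression_protocol")
}

#' @export
print.compression_protocol <- function(x, ...) {
  cat(sprintf(
    "<compression_protocol> %g um/s, dt %g s, %d+%d cycle, %g nm -> %.0f%%\n",
    x$velocity_um_s, x$timestep_s, x$translate_steps, x$relax_steps,
    x$initial_end_to_end_nm, 100 * x$compression_fraction))
  cat(sprintf("  per-cycle displacement %g um, total time %g s\n",
              per_cycle_displacement_um(x), total_compression_time(x)))
  invisible(x)
}

#' Protocol arithmetic
#'
#' `per_cycle_displacement_um` is the distance the moved anchors travel per
#' translate/relax cycle, `velocity * timestep * (translate + relax)`, in µm
#' (e.g. 7.5e-5 µm per cycle at 15 µm/s with a 5e-7 s timestep).
#' `total_compression_time` is the time to reach the target compression at
#' the nominal velocity, `(1 - fraction) * initial_end_to_end / velocity`, in
#' seconds.
#'
#' @param protocol a [compression_protocol()].
#' @return numeric scalar.
#' @export
per_cycle_displacement_um <- function(protocol) {
  protocol$velocity_um_s * protocol$timestep_s *
    (protocol$translate_steps + protocol$relax_steps)
}

#' @rdname per_cycle_displacement_um
#' @export
total_compression_time <- function(protocol) {
  (1 - protocol$compression_fraction) * protocol$initial_end_to_end_nm *
    1e-3 / protocol$velocity_um_s
}

#' One overdamped Euler-Maruyama step
#'
#' Moves each free particle by `F / gamma * dt + sqrt(2 kT dt / gamma) * xi`
#' with `xi` a standard normal per coordinate; particles listed in `fixed` do
#' not move. Exposed mainly for testing the integrator against closed-form
#' drift and diffusion.
#'
#' @param frame a [filament_frame()].
#' @param forces n x 3 force matrix (pN), e.g. from [compute_forces()].
#' @param thermal a [thermal_model()]; its seed determines the noise.
#' @param dt time step (s), > 0.
#' @param fixed integer indices (1-based) of particles that do not move.
#' @return A new [filament_frame()] at `time + dt`.
#' @export
step_overdamped <- function(frame, forces, thermal, dt, fixed = integer(0)) {
  if (dt <= 0) stop("dt must be > 0")
  p <- frame_points(frame)
  out <- step_cpp(p, as.matrix(forces), thermal$kT, thermal$drag_per_particle,
                  dt, as.integer(fixed) - 1L, thermal$seed)
  filament_frame(out, time = frame$time + dt,
                 is_axis_curve = is_filament_frame(frame) && frame$is_axis_curve)
}

# default bonded constants of the monomer-scale chain; the angle and dihedral
# stiffnesses were calibrated so the chain's persistence length lands in the
# 10-25 um range at kT = 4.1 pN nm (see the methods vignette)
.monomer_defaults <- list(
  k_bond = 100,        # pN/nm, neighbour orders 1 and 2
  k_angle = 12000,     # pN nm / rad^2
  k_dihedral = 6000,   # pN nm
  drag_scale = 10,     # x Stokes drag of a 2 nm bead
  bead_radius_nm = 2,
  timestep_s = 5e-11
)

#' Build the chiral monomer-scale chain
#'
#' Places beads on the ideal actin helix ([build_ideal_helix()]) and derives a
#' chiral force field: harmonic bonds to the first and second neighbour in
#' each direction, harmonic angles on consecutive triples, and cosine
#' dihedrals on consecutive quadruples, all with equilibrium targets measured
#' from the ideal helix. The dihedral terms make the chain chiral: they store
#' the handedness of the lattice and couple bending to axial rotation.
#'
#' @param n_subunits bead count; alternatively give `length_nm` and the count
#'   is `round(length_nm / rise) + 1`.
#' @param length_nm approximate filament length (nm), used when `n_subunits`
#'   is missing.
#' @param geometry a [helix_geometry()] (subunit count is overridden).
#' @param k_bond,k_angle,k_dihedral bonded stiffnesses; defaults calibrated so
#'   the chain's persistence length is in the 10-25 µm range at kT = 4.1 pN nm.
#' @param mirror if `TRUE`, mirror the ideal structure (z -> -z) before
#'   deriving targets, flipping the chain's handedness.
#' @return list with elements `frame` (the ideal structure), `ff` (the
#'   [force_field()]), and `geometry`.
#' @export
build_monomer_chain <- function(n_subunits = NULL, length_nm = 150,
                                geometry = helix_geometry(),
                                k_bond = .monomer_defaults$k_bond,
                                k_angle = .monomer_defaults$k_angle,
                                k_dihedral = .monomer_defaults$k_dihedral,
                                mirror = FALSE) {
  if (is.null(n_subunits))
    n_subunits <- as.integer(round(length_nm / geometry$rise_per_subunit)) + 1L
  geometry$n_subunits <- as.integer(n_subunits)
  frame <- build_ideal_helix(geometry)
  if (mirror) {
    p <- frame$points
    p[, "z"] <- -p[, "z"]
    frame <- filament_frame(p)
  }
  ff <- derive_topology_targets(frame, neighbor_orders = c(1L, 2L),
                                bond_constants = k_bond,
                                angle_constant = k_angle,
                                dihedral_constant = k_dihedral)
  list(frame = frame, ff = ff, geometry = geometry)
}

#' Build the achiral fiber-scale chain
#'
#' A straight discrete worm-like chain along +x: `n_segments` segments of
#' `segment_length` nm, harmonic stretching bonds between first neighbours and
#' harmonic angles with stiffness `k_angle = bend_rigidity / segment_length`
#' (so the chain's persistence length is `bend_rigidity / kT`). No dihedrals:
#' the chain is achiral.
#'
#' @param n_segments number of segments, >= 3.
#' @param segment_length segment length (nm); 10 nm matches the fiber-scale
#'   anchor spacing.
#' @param bend_rigidity bending rigidity kappa (pN nm^2); default corresponds
#'   to a 10 µm persistence length at kT = 4.1 pN nm.
#' @param k_bond stretching stiffness (pN/nm).
#' @return list with elements `frame` and `ff` as in [build_monomer_chain()].
#' @export
build_fiber_chain <- function(n_segments, segment_length = 10,
                              bend_rigidity = 10e3 * 4.1,
                              k_bond = 100) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 3L) stop("n_segments must be >= 3")
  pts <- cbind(x = (0:n_segments) * segment_length, y = 0, z = 0)
  frame <- filament_frame(pts)
  ff <- derive_topology_targets(frame, neighbor_orders = 1L,
                                bond_constants = k_bond,
                                angle_constant = bend_rigidity / segment_length,
                                dihedral_constant = 0)
  list(frame = frame, ff = ff,
       bend_rigidity = bend_rigidity, segment_length = segment_length)
}

.trajectory <- function(frames, times, protocol, resolution_label, replicate,
                        seed, reached_target = NA) {
  structure(list(frames = frames, times = times, protocol = protocol,
                 resolution_label = resolution_label,
                 replicate = as.integer(replicate), seed = seed,
                 reached_target = reached_target),
            class = "filament_trajectory")
}

#' @export
print.filament_trajectory <- function(x, ...) {
  cat(sprintf("<filament_trajectory> %s replicate %d: %d frames x %d points, %g s\n",
              x$resolution_label, x$replicate, length(x$frames),
              nrow(x$frames[[1L]]$points), max(x$times)))
  invisible(x)
}

.frames_from_sim <- function(res, n_points, times) {
  lapply(seq_along(times), function(i) {
    filament_frame(matrix(res$frames[i, ], n_points, 3L, byrow = TRUE),
                   time = times[i])
  })
}

#' Simulate filament compression
#'
#' Runs the translate/relax protocol on a bead chain under overdamped
#' Brownian dynamics. The first `fixed_end_particles` beads are held fixed;
#' the last `moved_end_particles` beads are translated along -x by
#' `velocity * timestep * 10` per 10-step cycle. The run stops at the first
#' cycle where the x-projected end-to-end distance reaches
#' `compression_fraction` times its initial value. Each protocol step can be
#' integrated with `n_sub` Euler-Maruyama substeps (`n_sub > 1` is how the
#' fiber-scale model keeps the printed 5e-7 s protocol step while staying
#' inside the explicit integrator's stability bound).
#'
#' @param ff a [force_field()].
#' @param protocol a [compression_protocol()].
#' @param thermal a [thermal_model()].
#' @param init initial [filament_frame()]; its x extent defines the actual
#'   initial end-to-end distance.
#' @param n_frames_out number of evenly spaced frames to keep.
#' @param n_sub Euler-Maruyama substeps per protocol step.
#' @param resolution_label `"monomer"`, `"fiber"` or another tag stored on the
#'   trajectory.
#' @param replicate replicate index stored on the trajectory.
#' @return A `filament_trajectory`: frames, times (s), protocol, labels, and
#'   whether the target compression was reached.
#' @export
simulate_compression <- function(ff, protocol, thermal, init,
                                 n_frames_out = 60L, n_sub = 1L,
                                 resolution_label = "monomer",
                                 replicate = 1L) {
  p <- frame_points(init)
  n <- nrow(p)
  nf <- protocol$fixed_end_particles
  nm <- protocol$moved_end_particles
  if (nf + nm >= n) stop("more anchor particles than beads")
  fixed_idx <- seq_len(nf) - 1L
  moved_idx <- (n - nm):(n - 1L)
  delta_cycle_nm <- per_cycle_displacement_um(protocol) * 1e3
  min_bond <- min(segment_lengths(init))
  if (delta_cycle_nm > min_bond)
    warning("per-cycle displacement (", signif(delta_cycle_nm, 3),
            " nm) exceeds one bond length (", signif(min_bond, 3),
            " nm); the protocol velocity is too high for this timestep")
  x_extent0 <- p[n, 1L] - p[1L, 1L]
  target <- protocol$compression_fraction * x_extent0
  n_cycles <- ceiling((x_extent0 - target) / delta_cycle_nm)
  save_cycles <- unique(round(seq(0, n_cycles, length.out = n_frames_out)))
  terms <- .ff_terms(ff, n)
  res <- simulate_cpp(p, terms,
                      anchored = c(fixed_idx, moved_idx), moved = moved_idx,
                      delta_cycle = delta_cycle_nm,
                      translate_steps = protocol$translate_steps,
                      relax_steps = protocol$relax_steps,
                      n_sub = as.integer(n_sub),
                      dt_protocol = protocol$timestep_s,
                      kT = thermal$kT, gamma = thermal$drag_per_particle,
                      seed = thermal$seed, save_cycles = save_cycles,
                      max_cycles = n_cycles + 10, target_x_extent = target)
  cycle_time <- protocol$timestep_s *
    (protocol$translate_steps + protocol$relax_steps)
  # the run can stop a cycle or two before the last scheduled save; drop the
  # padded duplicates of the final state
  keep <- !duplicated(res$frame_cycles)
  res$frames <- res$frames[keep, , drop = FALSE]
  times <- res$frame_cycles[keep] * cycle_time
  .trajectory(.frames_from_sim(res, n, times), times, protocol,
              resolution_label, replicate, thermal$seed,
              reached_target = res$reached_target)
}

#' Free relaxation (no compression)
#'
#' Integrates the chain under thermal noise with no protocol displacement,
#' e.g. to equilibrate before compression or to sample conformations for
#' persistence-length estimation.
#'
#' @inheritParams simulate_compression
#' @param t_total_s simulated time (s).
#' @param timestep_s integration step written to the trajectory clock.
#' @param anchored integer indices (1-based) of particles held fixed
#'   (default none: a free chain).
#' @return A `filament_trajectory` with `resolution_label` as given.
#' @export
simulate_relaxation <- function(ff, thermal, init, t_total_s, timestep_s,
                                n_frames_out = 50L, n_sub = 1L,
                                anchored = integer(0),
                                resolution_label = "monomer",
                                replicate = 1L) {
  p <- frame_points(init)
  n <- nrow(p)
  cycle_time <- 10 * timestep_s
  n_cycles <- max(1, ceiling(t_total_s / cycle_time))
  save_cycles <- unique(round(seq(0, n_cycles, length.out = n_frames_out)))
  terms <- .ff_terms(ff, n)
  res <- simulate_cpp(p, terms,
                      anchored = as.integer(anchored) - 1L,
                      moved = integer(0),
                      delta_cycle = 0, translate_steps = 1L, relax_steps = 9L,
                      n_sub = as.integer(n_sub), dt_protocol = timestep_s,
                      kT = thermal$kT, gamma = thermal$drag_per_particle,
                      seed = thermal$seed, save_cycles = save_cycles,
                      max_cycles = n_cycles, target_x_extent = -1)
  times <- res$frame_cycles * cycle_time
  .trajectory(.frames_from_sim(res, n, times), times, protocol = NULL,
              resolution_label, replicate, thermal$seed)
}
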