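# Shared oracles and small builders used across the test files.

# wrap an angle series back to (-180, 180]
wrap180 <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

# central-difference gradient of the bonded energy: the independent oracle
# for compute_forces
fd_forces <- function(points, ff, eps = 1e-6) {
  num <- matrix(0, nrow(points), 3L)
  for (i in seq_len(nrow(points))) {
    for (d in 1:3) {
      pp <- points
      pp[i, d] <- pp[i, d] + eps
      e1 <- bonded_energy(filament_frame(pp), ff)
      pp[i, d] <- pp[i, d] - 2 * eps
      e2 <- bonded_energy(filament_frame(pp), ff)
      num[i, d] <- -(e1 - e2) / (2 * eps)
    }
  }
  num
}

# random rigid rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# apply a rigid motion to a frame
rigid_move <- function(frame, rot = diag(3), shift = c(0, 0, 0)) {
  filament_frame(sweep(frame$points %*% t(rot), 2L, -shift),
                 time = frame$time, is_axis_curve = frame$is_axis_curve)
}

# small chiral test chain (cheap enough for force/energy loops)
tiny_helix_ff <- function(n = 12, k_bond = 100, k_angle = 5000,
                          k_dihedral = 300, twist = -166.7) {
  h <- build_ideal_helix(helix_geometry(twist_per_subunit = twist,
                                        n_subunits = n))
  list(frame = h,
       ff = derive_topology_targets(h, c(1L, 2L), k_bond, k_angle,
                                    k_dihedral))
}
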