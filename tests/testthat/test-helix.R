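test_that("degenerate zero-radius helix is a straight line of equal spacing", {
  h <- build_ideal_helix(helix_geometry(rise_per_subunit = 2.7,
                                        twist_per_subunit = -166.7,
                                        helix_radius = 0, n_subunits = 10))
  expect_equal(h$points[, "x"], (0:9) * 2.7)
  expect_equal(max(abs(h$points[, c("y", "z")])), 0)
  expect_equal(segment_lengths(h), rep(2.7, 9))
})

test_that("helix bond lengths match the closed-form chord formula", {
  geo <- helix_geometry(rise_per_subunit = 2.74, twist_per_subunit = -166.7,
                        helix_radius = 1, n_subunits = 4)
  h <- build_ideal_helix(geo)
  for (o in 1:2) {
    expect_equal(chain_bond_lengths(h, o),
                 rep(helix_chord_length(geo, o), 4 - o), tolerance = 1e-12)
  }
  # x-coordinate of bead k is k * rise by construction
  expect_equal(h$points[, "x"], (0:3) * 2.74)
})

test_that("helix geometry is validated", {
  expect_error(helix_geometry(n_subunits = 3), "n_subunits")
  expect_error(helix_geometry(rise_per_subunit = 0), "rise_per_subunit")
  expect_error(helix_geometry(helix_radius = -1), "helix_radius")
})

test_that("equilibrium targets make the reference structure force-free", {
  tin <- tiny_helix_ff()
  f <- compute_forces(tin$frame, tin$ff)
  expect_lt(max(abs(f)), 1e-6)
  # screw symmetry: all order-1 bonds and all dihedrals identical
  expect_lt(diff(range(tin$ff$equilibrium_bonds[["1"]])), 1e-9)
  expect_lt(diff(range(tin$ff$equilibrium_dihedrals)), 1e-9)
})

test_that("straight reference chain gives pi angles and no dihedral targets", {
  line <- filament_frame(cbind(x = (0:9) * 3, y = 0, z = 0))
  ff <- derive_topology_targets(line, 1L, 100, angle_constant = 50,
                                dihedral_constant = 0)
  expect_equal(ff$equilibrium_angles, rep(pi, 8))
  expect_false(ff$chiral)
  expect_true(all(is.na(chain_dihedrals(line))))
  # asking for chirality from a collinear reference is an error
  expect_error(derive_topology_targets(line, 1L, 100, 50, 10), "collinear")
})

test_that("too-short chains are rejected", {
  expect_error(derive_topology_targets(
    filament_frame(cbind(0:2, 0, 0)), 1L, 100), "4 points")
})

test_that("mirroring the reference flips dihedral targets only", {
  a <- build_monomer_chain(n_subunits = 12)
  b <- build_monomer_chain(n_subunits = 12, mirror = TRUE)
  expect_equal(a$ff$equilibrium_bonds, b$ff$equilibrium_bonds)
  expect_equal(a$ff$equilibrium_angles, b$ff$equilibrium_angles)
  expect_equal(a$ff$equilibrium_dihedrals, -b$ff$equilibrium_dihedrals)
})
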