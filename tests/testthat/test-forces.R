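test_that("a stretched bond pulls both particles together with k * delta", {
  line <- filament_frame(cbind(x = c(0, 3, 6, 9), y = 0, z = 0))
  ff <- derive_topology_targets(line, 1L, bond_constants = 50)
  p <- line$points
  p[4, 1] <- 9 + 0.2  # stretch the last bond by delta = 0.2 nm
  f <- compute_forces(filament_frame(p), ff)
  expect_equal(unname(f[4, ]), c(-50 * 0.2, 0, 0))
  expect_equal(unname(f[3, ]), c(50 * 0.2, 0, 0))
  expect_equal(f[1:2, ], matrix(0, 2, 3), ignore_attr = TRUE)
})

test_that("forces equal the central-difference energy gradient", {
  tin <- tiny_helix_ff()
  set.seed(11)
  for (rep in 1:5) {
    p <- tin$frame$points + matrix(rnorm(36, sd = 0.15), ncol = 3)
    f <- compute_forces(filament_frame(p), tin$ff)
    num <- fd_forces(p, tin$ff)
    expect_lt(max(abs(f - num)) / max(abs(f)), 1e-6)
  }
})

test_that("bonded forces are internal: zero net force and torque", {
  tin <- tiny_helix_ff()
  set.seed(12)
  p <- tin$frame$points + matrix(rnorm(36, sd = 0.2), ncol = 3)
  f <- compute_forces(filament_frame(p), tin$ff)
  expect_lt(max(abs(colSums(f))), 1e-9)
  torque <- colSums(t(vapply(seq_len(nrow(p)), function(i)
    filacomp:::.cross(p[i, ], f[i, ]), numeric(3))))
  expect_lt(max(abs(torque)), 1e-8)
})

test_that("coincident consecutive points are reported by particle index", {
  tin <- tiny_helix_ff()
  p <- tin$frame$points
  p[5, ] <- p[4, ]
  expect_error(compute_forces(p, tin$ff), "4 and 5")
})

test_that("achiral force field carries no dihedral terms", {
  fb <- build_fiber_chain(6)
  expect_false(fb$ff$chiral)
  expect_equal(fb$ff$dihedral_constant, 0)
  # bending the chain produces a restoring force consistent with the oracle
  p <- fb$frame$points
  p[, 2] <- 0.5 * sin(seq(0, pi, length.out = nrow(p)))
  f <- compute_forces(filament_frame(p), fb$ff)
  expect_lt(max(abs(f - fd_forces(p, fb$ff))) / max(abs(f)), 1e-6)
})

test_that("force field validation catches inconsistencies", {
  expect_error(force_field(c("1" = -5), list("1" = 3)), "stiffnesses")
  expect_error(force_field(c("1" = 5), list("2" = 3)), "neighbour orders")
  tin <- tiny_helix_ff(n = 12)
  short <- filament_frame(tin$frame$points[1:8, ])
  expect_error(compute_forces(short, tin$ff), "expects")
})
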