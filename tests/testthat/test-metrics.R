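test_that("resampling a straight 500 nm line gives exact 10 nm spacing", {
  line <- generate_parametric_shape("straight", length = 500, n_points = 37)
  rs <- resample_polyline(line, 51)
  expect_equal(rs$points[, "x"], seq(0, 500, by = 10))
  expect_equal(segment_lengths(rs), rep(10, 50))
})

test_that("resampling an already uniform chain is the identity", {
  line <- generate_parametric_shape("straight", length = 120, n_points = 25)
  expect_equal(resample_polyline(line, 25)$points, line$points)
})

test_that("resampled contour length matches dense arc length of a semicircle", {
  # semicircle of radius 100: true arc length = pi * 100
  th <- seq(0, pi, length.out = 400)
  semi <- filament_frame(cbind(x = 100 * cos(th), y = 100 * sin(th), z = 0))
  rs <- resample_polyline(semi, 50)
  expect_equal(contour_length(rs), pi * 100, tolerance = 0.01)
  # endpoints preserved exactly
  expect_identical(rs$points[c(1, 50), ], semi$points[c(1, 400), ])
})

test_that("sliding-window smoothing recovers the helix axis within 0.2 nm", {
  h <- build_ideal_helix(helix_geometry(n_subunits = 40))
  ax <- monomers_to_axis(h, window = 13)
  expect_true(ax$is_axis_curve)
  expect_equal(nrow(ax$points), 40 - 12)  # count drops by window - 1
  # the true axis is the x-axis (y = z = 0)
  expect_lt(max(sqrt(ax$points[, "y"]^2 + ax$points[, "z"]^2)), 0.2)
})

test_that("smoothing a collinear chain returns a line; bad windows error", {
  line <- generate_parametric_shape("straight", length = 100, n_points = 21)
  ax <- monomers_to_axis(line, 5)
  expect_lt(max(abs(ax$points[, c("y", "z")])), 1e-12)
  expect_error(monomers_to_axis(line, 4), "odd")
  expect_error(monomers_to_axis(line, 23), "larger than chain")
})

test_that("compression ratio is 0.30 at 350/500 nm and rigid-motion invariant", {
  arc <- generate_parametric_shape("planar_arc", chord = 350, height = 60)
  cm <- compression_metrics(arc, initial_end_to_end = 500)
  expect_equal(cm$end_to_end, 350, tolerance = 1e-12)
  expect_equal(cm$compression_ratio, 0.30, tolerance = 1e-12)
  set.seed(3)
  moved <- rigid_move(arc, random_rotation(), shift = c(12, -40, 7))
  cm2 <- compression_metrics(moved, initial_end_to_end = 500)
  expect_equal(cm2$compression_ratio, cm$compression_ratio)
  line <- generate_parametric_shape("straight", length = 500)
  expect_equal(compression_metrics(line, 500)$compression_ratio, 0)
})

test_that("peak asymmetry: 0 for symmetric arcs, closed-form for skewed", {
  sym <- generate_parametric_shape("planar_arc", chord = 350, height = 80)
  expect_equal(peak_asymmetry(sym), 0, tolerance = 0.02)
  skew <- generate_parametric_shape("planar_arc", chord = 350, height = 80,
                                    peak_fraction = 0.25)
  truth <- attr(skew, "truth")$peak_asymmetry
  expect_equal(peak_asymmetry(skew), truth, tolerance = 0.02)
  expect_gt(truth, 0.3)  # quarter-chord apex is well off-centre
  # straight rod: defined as 0 by the degenerate-case rule
  line <- generate_parametric_shape("straight")
  expect_identical(peak_asymmetry(line), 0)
})

test_that("non-coplanarity: 0 for planar, 1/3 for isotropic, eigen oracle", {
  arc <- generate_parametric_shape("planar_arc", chord = 350, height = 80)
  expect_equal(non_coplanarity(arc), 0, tolerance = 1e-12)
  # six points at +/- e1, e2, e3: isotropic covariance forces 1/3
  octa <- filament_frame(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  expect_equal(non_coplanarity(octa, n_points = NULL), 1 / 3)
  # random 3D chain vs brute-force covariance eigendecomposition
  set.seed(21)
  for (i in 1:5) {
    p <- matrix(rnorm(30), 10, 3) + (1:10) %o% c(1, 0, 0)
    ev <- eigen(stats::cov(p), symmetric = TRUE)$values
    expect_equal(non_coplanarity(filament_frame(p), n_points = NULL),
                 ev[3] / sum(ev), tolerance = 1e-12)
  }
})

test_that("supertwist matches analytic winding and is mirror-antisymmetric", {
  right <- generate_parametric_shape("helical_coil", winding_deg = 60,
                                     n_points = 400)
  expect_equal(supertwist_angle(right, n_points = NULL), 60, tolerance = 0.5)
  left <- generate_parametric_shape("helical_coil", winding_deg = -60,
                                    n_points = 400)
  expect_equal(supertwist_angle(left, n_points = NULL), -60, tolerance = 0.5)
  # mirroring z -> -z flips the sign exactly
  pm <- right$points; pm[, "z"] <- -pm[, "z"]
  expect_equal(supertwist_angle(filament_frame(pm), n_points = NULL),
               -supertwist_angle(right, n_points = NULL), tolerance = 1e-9)
})

test_that("supertwist degenerate cases: straight NA, planar tilt 0, buckle 180", {
  line <- generate_parametric_shape("straight")
  expect_true(is.na(supertwist_angle(line)))
  # both end tangents tilting towards +y (monotone planar tilt): projections
  # parallel, no winding
  x <- seq(0, 300, length.out = 80)
  jcurve <- filament_frame(cbind(x = x, y = (x / 300)^2 * 60 + 0.1 * x, z = 0))
  expect_equal(supertwist_angle(jcurve), 0, tolerance = 1e-9)
  # a chord-closed planar buckle has antiparallel projections: the signed
  # angle sits exactly at the 180-degree branch point
  arc <- generate_parametric_shape("planar_arc", chord = 350, height = 80)
  expect_equal(abs(supertwist_angle(arc)), 180, tolerance = 1e-9)
})

test_that("supertwist is invariant when frame and axis are co-rotated", {
  coil <- generate_parametric_shape("helical_coil", winding_deg = 75,
                                    n_points = 300)
  set.seed(8)
  rot <- random_rotation()
  moved <- rigid_move(coil, rot)
  expect_equal(supertwist_angle(moved, axis = as.numeric(rot %*% c(1, 0, 0)),
                                n_points = NULL),
               supertwist_angle(coil, n_points = NULL), tolerance = 1e-8)
})

test_that("any frame with measurable supertwist is non-coplanar", {
  set.seed(13)
  for (w in c(30, 90, 150)) {
    coil <- generate_parametric_shape("helical_coil", winding_deg = w,
                                      radius = 20, n_points = 120)
    expect_gt(non_coplanarity(coil), 0)
  }
})

test_that("angle unwrapping follows nearest-branch continuity through NAs", {
  expect_equal(unwrap_angles(c(170, -175, -160)), c(170, 185, 200))
  expect_equal(unwrap_angles(c(-170, 175, NA, 160)), c(-170, -185, NA, -200))
  expect_equal(unwrap_angles(c(NA, 10)), c(NA, 10))
})

test_that("normalized compression time: 10 ms total for 500 nm at 15 um/s", {
  pr <- compression_protocol(15, 5e-7, initial_end_to_end_nm = 500,
                             compression_fraction = 0.7)
  expect_equal(total_compression_time(pr), 0.010)
  expect_equal(normalized_time(c(0, 0.005, 0.010, 0.02), pr),
               c(0, 0.5, 1, 1))
})

test_that("persistence length recovers an exact exponential tangent field", {
  # planar arcs with curvature at Cauchy quantiles: the Cauchy characteristic
  # function makes the pooled tangent correlation exactly exp(-ds/Lp)
  arc_frame <- function(a, n, ds) {
    s <- (0:(n - 1)) * ds
    if (abs(a) < 1e-12) pts <- cbind(x = s, y = 0, z = 0)
    else pts <- cbind(x = sin(a * s) / a, y = (1 - cos(a * s)) / a, z = 0)
    filament_frame(pts)
  }
  Lp0 <- 10000  # nm
  N <- 8000
  u <- (seq_len(N) - 0.5) / N
  frames <- lapply(tan(pi * (u - 0.5)) / Lp0, arc_frame, n = 26, ds = 10)
  est <- persistence_length(list(frames))
  expect_equal(est$Lp_um, 10, tolerance = 0.01)
})

test_that("a rigid straight chain is flagged rigid (infinite Lp)", {
  line <- generate_parametric_shape("straight", length = 200, n_points = 21)
  est <- persistence_length(list(list(line, line, line)))
  expect_true(est$rigid)
  expect_identical(est$Lp_um, Inf)
})

test_that("metric table covers every frame with unwrapped supertwist", {
  frames <- lapply(seq(0, 120, by = 30), function(w) {
    fr <- generate_parametric_shape("helical_coil", winding_deg = w + 1,
                                    n_points = 80)
    fr$time <- w / 1200
    fr
  })
  traj <- filacomp:::.trajectory(frames, times = seq(0, 120, by = 30) / 1200,
                                 protocol = NULL, resolution_label = "external",
                                 replicate = 1L, seed = NA)
  m <- measure_trajectory(traj)
  expect_equal(nrow(m), 5)
  expect_equal(m$supertwist_deg, c(1, 31, 61, 91, 121), tolerance = 0.5)
  expect_true(all(m$normalized_time >= 0 & m$normalized_time <= 1))
})
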