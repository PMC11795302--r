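# family of straight chains at varying compression along x: a one-mode family
compression_family <- function(n = 30, n_points = 20) {
  lapply(seq(500, 350, length.out = n), function(L)
    generate_parametric_shape("straight", length = L, n_points = n_points))
}

test_that("alignment rotates the furthest yz point onto +y, x untouched", {
  arc <- generate_parametric_shape("planar_arc", chord = 350, height = 80)
  p <- arc$points
  rotated <- filament_frame(cbind(x = p[, 1], y = 0, z = p[, 2]))  # bulge +z
  al <- align_filament(rotated)
  expect_equal(al$points[, "x"], p[, 1])
  expect_lt(max(abs(al$points[, "z"])), 1e-9)
  r <- sqrt(al$points[, "y"]^2 + al$points[, "z"]^2)
  expect_gte(al$points[which.max(r), "y"], 0)
  expect_equal(attr(al, "rotation_rad"), -pi / 2, tolerance = 1e-12)
  # idempotence
  al2 <- align_filament(al)
  expect_equal(al2$points, al$points, tolerance = 1e-12)
})

test_that("alignment preserves lengths, planarity measures and chirality", {
  coil <- generate_parametric_shape("helical_coil", winding_deg = 80,
                                    phase = 120, n_points = 200)
  al <- align_filament(coil)
  expect_equal(contour_length(al), contour_length(coil), tolerance = 1e-9)
  expect_equal(end_to_end(al), end_to_end(coil), tolerance = 1e-9)
  expect_equal(non_coplanarity(al), non_coplanarity(coil), tolerance = 1e-12)
  expect_equal(supertwist_angle(al, n_points = NULL),
               supertwist_angle(coil, n_points = NULL), tolerance = 1e-9)
  # all points on the x-axis: identity rotation
  line <- generate_parametric_shape("straight")
  expect_equal(align_filament(line)$points, line$points)
})

test_that("PCA on a compression-only family loads everything on PC1", {
  shapes <- shape_matrix(compression_family(), n_points = 20)
  sp <- fit_shape_space(shapes, n_components = 3)
  expect_gt(sp$explained_variance_ratio[1], 0.999)
  expect_true(all(diff(sp$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(sp$explained_variance_ratio), 1 + 1e-9)
  # orthonormality of the component basis
  g <- crossprod(sp$components)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("full-rank reconstruction reproduces every sample", {
  set.seed(5)
  frames <- lapply(1:12, function(i)
    generate_parametric_shape("helical_coil", winding_deg = runif(1, -90, 90),
                              radius = runif(1, 5, 40), n_points = 60))
  shapes <- shape_matrix(frames, n_points = 15)
  sp <- fit_shape_space(shapes, n_components = 11)
  scores <- as.matrix(project_shapes(shapes, sp))
  recon <- sweep(scores %*% t(sp$components), 2, sp$mean_shape, "+")
  expect_equal(recon, shapes, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("projection obeys orthonormal score identities", {
  shapes <- shape_matrix(compression_family(), n_points = 20)
  sp <- fit_shape_space(shapes, n_components = 3)
  # the mean shape scores to zero
  expect_equal(as.numeric(project_shapes(rbind(sp$mean_shape), sp)),
               rep(0, 3), tolerance = 1e-9)
  # mean + c * component_k scores to c on axis k and 0 elsewhere
  for (k in 1:2) {
    v <- sp$mean_shape + 7.5 * sp$components[, k]
    sc <- as.numeric(project_shapes(rbind(v), sp))
    expect_equal(sc[k], 7.5, tolerance = 1e-9)
    expect_lt(max(abs(sc[-k])), 1e-9)
  }
  expect_error(project_shapes(matrix(0, 2, 9), sp), "dimensionality")
})

test_that("fewer samples than components is an error", {
  shapes <- shape_matrix(compression_family(n = 2), n_points = 10)
  expect_error(fit_shape_space(shapes[1, , drop = FALSE], 2), "2 samples")
})

test_that("latent walk along a compression-only PC1 shortens end-to-end", {
  shapes <- shape_matrix(compression_family(), n_points = 20)
  sp <- fit_shape_space(shapes, n_components = 2)
  walk <- latent_walk(sp, 1, score_values = seq(-40, 40, length.out = 5))
  ee <- vapply(walk, end_to_end, numeric(1))
  # PC1 is oriented so higher scores mean more compression (sign fixed by
  # dominant loading here); end-to-end must be strictly monotone either way
  expect_true(all(diff(ee) < 0) || all(diff(ee) > 0))
  # score 0 reproduces the mean shape
  w0 <- latent_walk(sp, 1, 0)[[1]]
  expect_equal(as.vector(w0$points), as.numeric(sp$mean_shape),
               tolerance = 1e-12)
  # +s and -s are symmetric about the mean
  wp <- latent_walk(sp, 1, 20)[[1]]$points
  wm <- latent_walk(sp, 1, -20)[[1]]$points
  expect_equal((wp + wm) / 2, matrix(sp$mean_shape, ncol = 3,
                                     dimnames = dimnames(wp)),
               tolerance = 1e-12)
})

test_that("feature correlations: exact for constructed modes, NA when undefined", {
  fam <- compression_family(n = 40)
  shapes <- shape_matrix(fam, n_points = 20)
  cr <- 1 - vapply(fam, end_to_end, numeric(1)) / 500
  sp <- fit_shape_space(shapes, n_components = 2,
                        sign_features = data.frame(f1 = cr))
  tab <- project_shapes(shapes, sp)
  tab$compression_ratio <- cr
  tab$supertwist_deg <- NA_real_          # flagged-missing metric
  tab$non_coplanarity <- 0                # constant column
  set.seed(99)
  tab$peak_asymmetry <- rnorm(40)         # independent noise
  fc <- feature_correlation(tab)
  expect_equal(fc["PC1", "compression_ratio"], 1, tolerance = 1e-6)
  expect_true(is.na(fc["PC1", "supertwist_deg"]))
  expect_true(is.na(fc["PC1", "non_coplanarity"]))
  expect_lt(abs(fc["PC1", "peak_asymmetry"]), 3 / sqrt(40))
  expect_equal(stats::cor(tab$PC1, tab$PC1), 1)
})

test_that("sign convention orients PC1 positively with its sign feature", {
  fam <- compression_family(n = 25)
  shapes <- shape_matrix(fam, n_points = 20)
  cr <- 1 - vapply(fam, end_to_end, numeric(1)) / 500
  sp <- fit_shape_space(shapes, 2, sign_features = data.frame(f1 = cr))
  sc <- project_shapes(shapes, sp)
  expect_gt(stats::cor(sc$PC1, cr), 0)
})
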