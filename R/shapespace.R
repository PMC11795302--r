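#' Align a filament for shape-space analysis
#'
#' Translates the chain so its fixed end sits at the origin, then rotates
#' about the x-axis (only) so that the point furthest from the origin in the
#' yz-plane lands on the positive y-axis (z = 0, y >= 0). x-coordinates, arc
#' length, end-to-end distance, non-coplanarity and the magnitude of the
#' supertwist angle are all unchanged; the rotation is proper, so chirality
#' (the supertwist sign) is preserved. A chain lying entirely on the x-axis
#' gets the identity rotation.
#'
#' @param frame a [filament_frame()] with the compression axis along +x.
#' @param n_points if not `NULL`, resample to this many points first (all
#'   samples entering one PCA must share the count).
#' @return A [filament_frame()] with attributes `"rotation_rad"` (applied
#'   angle) and `"aligned" = TRUE`.
#' @export
align_filament <- function(frame, n_points = NULL) {
  fr <- if (is.null(n_points)) as_filament_frame(frame)
        else resample_polyline(frame, n_points)
  p <- sweep(fr$points, 2L, fr$points[1L, ])
  r_yz <- sqrt(p[, "y"]^2 + p[, "z"]^2)
  i <- which.max(r_yz)
  theta <- if (r_yz[i] < 1e-12) 0
           else unname(atan2(p[i, "z"], p[i, "y"]))
  # rotate by -theta about +x: brings the furthest point to (y > 0, z = 0)
  if (theta != 0) p <- p %*% t(.rot_x(-theta))
  out <- filament_frame(p, time = fr$time, is_axis_curve = fr$is_axis_curve)
  attr(out, "rotation_rad") <- -theta
  attr(out, "aligned") <- TRUE
  out
}

#' Assemble a shape matrix from frames
#'
#' Aligns ([align_filament()]) and resamples every frame to a common point
#' count and flattens each to a row `(x1..xn, y1..yn, z1..zn)` of the shape
#' matrix handed to [fit_shape_space()].
#'
#' @param frames list of [filament_frame()]s.
#' @param n_points common resampling count (50 matches a 10 nm segmentation
#'   of a 500 nm filament).
#' @param align apply the y-axis alignment rotation (disable only for
#'   pre-aligned input).
#' @return numeric matrix, one row per frame, `3 * n_points` columns.
#' @export
shape_matrix <- function(frames, n_points = 50L, align = TRUE) {
  rows <- vapply(frames, function(fr) {
    fr2 <- if (align) align_filament(fr, n_points)
           else resample_polyline(fr, n_points)
    as.vector(fr2$points)  # column-major: x block, y block, z block
  }, numeric(3L * n_points))
  t(rows)
}

#' Fit the filament shape space (PCA)
#'
#' Principal component analysis of aligned, resampled filament shapes pooled
#' across simulators, velocities, replicates and time points. Coordinates are
#' centered but not scaled (they share units of nm). Component signs are
#' ambiguous in PCA; they are fixed deterministically, by positive correlation
#' with the columns of `sign_features` (e.g. compression ratio for PC1 and
#' the chiral model's supertwist for PC2) where given, otherwise by making
#' each component's largest-magnitude loading positive.
#'
#' @param shapes shape matrix from [shape_matrix()] (rows = samples).
#' @param n_components number of components to keep.
#' @param sign_features optional data.frame/matrix with one row per sample;
#'   column k (if present and correlating) orients component k.
#' @return An object of class `shape_space`: `mean_shape`, `components`
#'   (columns, orthonormal), `explained_variance_ratio`, `sdev`, `n_points`.
#' @export
fit_shape_space <- function(shapes, n_components = 8L, sign_features = NULL) {
  shapes <- as.matrix(shapes)
  if (nrow(shapes) < 2L) stop("need at least 2 samples to fit a shape space")
  n_components <- min(as.integer(n_components), nrow(shapes) - 1L,
                      ncol(shapes))
  if (n_components < 1L) stop("fewer samples than components")
  pc <- stats::prcomp(shapes, center = TRUE, scale. = FALSE)
  comps <- pc$rotation[, seq_len(n_components), drop = FALSE]
  sdev <- pc$sdev[seq_len(n_components)]
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  # deterministic sign convention
  for (k in seq_len(n_components)) {
    s <- 0
    if (!is.null(sign_features) && k <= ncol(sign_features)) {
      feat <- as.numeric(sign_features[[k]])
      ok <- is.finite(feat) & is.finite(scores[, k])
      if (sum(ok) > 2L && stats::sd(feat[ok]) > 0 &&
          stats::sd(scores[ok, k]) > 0)
        s <- sign(stats::cor(scores[ok, k], feat[ok]))
    }
    if (is.na(s) || s == 0)
      s <- sign(comps[which.max(abs(comps[, k])), k])
    if (s < 0) comps[, k] <- -comps[, k]
  }
  structure(list(mean_shape = pc$center, components = comps,
                 explained_variance_ratio = evr[seq_len(n_components)],
                 sdev = sdev, n_points = ncol(shapes) / 3L,
                 n_samples = nrow(shapes)),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("<shape_space> %d components over %d-point shapes (%d samples)\n",
              ncol(x$components), x$n_points, x$n_samples))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio), collapse = " "),
      "\n")
  invisible(x)
}

#' Project shapes into a fitted shape space
#'
#' @param shapes shape matrix (same column layout as the fit).
#' @param space a fitted `shape_space`.
#' @return data.frame of per-sample scores, columns `PC1`, `PC2`, ...
#' @export
project_shapes <- function(shapes, space) {
  shapes <- as.matrix(shapes)
  if (ncol(shapes) != length(space$mean_shape))
    stop("shape dimensionality (", ncol(shapes),
         ") does not match the fitted space (", length(space$mean_shape), ")")
  sc <- sweep(shapes, 2L, space$mean_shape) %*% space$components
  out <- as.data.frame(sc)
  names(out) <- paste0("PC", seq_len(ncol(sc)))
  out
}

#' Latent walk along one principal component
#'
#' Inverse-transforms `mean + score * component` back into 3D chains at the
#' requested scores (defaults: -2 to +2 standard deviations of that
#' component in 5 steps), visualising what shape variation the component
#' encodes.
#'
#' @param space a fitted `shape_space`.
#' @param component_index which component to walk (1-based).
#' @param score_values numeric scores in nm-PCA units; default
#'   `c(-2, -1, 0, 1, 2) * sdev\[k\]`.
#' @return list of [filament_frame()]s, one per score, with attribute
#'   `"scores"`.
#' @export
latent_walk <- function(space, component_index = 1L, score_values = NULL) {
  k <- as.integer(component_index)
  if (k < 1L || k > ncol(space$components))
    stop("component_index out of range")
  if (is.null(score_values))
    score_values <- seq(-2, 2, length.out = 5L) * space$sdev[k]
  frames <- lapply(score_values, function(s) {
    flat <- space$mean_shape + s * space$components[, k]
    filament_frame(matrix(flat, ncol = 3L,
                          dimnames = list(NULL, c("x", "y", "z"))))
  })
  attr(frames, "scores") <- score_values
  frames
}

#' Correlation of PC scores with shape metrics
#'
#' Pearson correlation of each principal-component score with each shape
#' metric, pairwise-complete so frames with undefined (flagged `NA`)
#' supertwist drop out of that column only. Constant columns yield `NA`
#' (undefined), not 0.
#'
#' @param score_table data.frame holding `PC*` columns and metric columns.
#' @param metrics character vector of metric column names present in
#'   `score_table`.
#' @return matrix of correlations, components x metrics.
#' @export
feature_correlation <- function(score_table,
                                metrics = c("compression_ratio",
                                            "supertwist_deg",
                                            "non_coplanarity",
                                            "peak_asymmetry",
                                            "normalized_time")) {
  pcs <- grep("^PC[0-9]+$", names(score_table), value = TRUE)
  metrics <- intersect(metrics, names(score_table))
  out <- matrix(NA_real_, length(pcs), length(metrics),
                dimnames = list(pcs, metrics))
  for (p in pcs) for (m in metrics) {
    x <- score_table[[p]]; y <- score_table[[m]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) > 2L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      out[p, m] <- stats::cor(x[ok], y[ok])
  }
  out
}
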