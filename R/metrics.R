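#' Resample a polyline at equal arc-length spacing
#'
#' Linear interpolation along the chain at `n_points` equally spaced
#' arc-length stations; the two endpoints are preserved exactly. Used to give
#' every filament the same dimensionality before metrics and PCA.
#'
#' @param frame a [filament_frame()] or n x 3 matrix.
#' @param n_points number of output points, >= 3.
#' @return A [filament_frame()] with `n_points` points.
#' @export
resample_polyline <- function(frame, n_points = 50L) {
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be >= 3")
  p <- frame_points(frame)
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) stop("zero-length polyline cannot be resampled")
  s <- c(0, cumsum(seg))
  st <- seq(0, L, length.out = n_points)
  out <- vapply(1:3, function(d) stats::approx(s, p[, d], xout = st,
                                               ties = "ordered")$y,
                numeric(n_points))
  out[1L, ] <- p[1L, ]
  out[n_points, ] <- p[nrow(p), ]
  filament_frame(out,
                 time = if (is_filament_frame(frame)) frame$time else 0,
                 is_axis_curve = is_filament_frame(frame) && frame$is_axis_curve)
}

#' Smooth monomer beads into an axis curve
#'
#' Centered sliding-window mean over the bead positions. With a window close
#' to one helical crossover (13 subunits for the actin lattice) the zigzag of
#' the monomer track averages out and the output follows the filament axis.
#' The output has `window - 1` fewer points and carries
#' `is_axis_curve = TRUE`.
#'
#' @param frame a [filament_frame()] of raw bead positions.
#' @param window odd integer window length, at least a helical half-turn.
#' @return A [filament_frame()] axis curve.
#' @export
monomers_to_axis <- function(frame, window = 13L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  p <- frame_points(frame)
  n <- nrow(p)
  if (window > n) stop("window (", window, ") larger than chain (", n, ")")
  if (window == 1L) return(as_filament_frame(frame))
  k <- n - window + 1L
  cs <- rbind(0, apply(p, 2L, cumsum))
  out <- (cs[(window + 1L):(n + 1L), , drop = FALSE] -
          cs[1L:k, , drop = FALSE]) / window
  filament_frame(out,
                 time = if (is_filament_frame(frame)) frame$time else 0,
                 is_axis_curve = TRUE)
}

#' End-to-end distance and compression ratio
#'
#' The compression ratio is `1 - end_to_end / initial_end_to_end`, i.e. 0 for
#' the uncompressed filament and 0.30 once a 500 nm filament has been brought
#' to 350 nm. Both quantities are invariant under rigid motions.
#'
#' @param frame a [filament_frame()].
#' @param initial_end_to_end initial end-to-end distance (nm), > 0.
#' @return list with `end_to_end` (nm) and `compression_ratio`.
#' @export
compression_metrics <- function(frame, initial_end_to_end) {
  if (initial_end_to_end <= 0) stop("initial_end_to_end must be > 0")
  ee <- end_to_end(frame)
  list(end_to_end = ee, compression_ratio = 1 - ee / initial_end_to_end)
}

#' Peak asymmetry of a buckled filament
#'
#' Measures how far the filament's largest excursion sits from the middle of
#' the chain: with `d(s)` the perpendicular distance of each resampled point
#' from the end-to-end chord and `s*` the arc-length fraction of the maximum,
#' the metric is `|2 s* - 1|`, 0 for a symmetric buckle and approaching 1 for
#' an end-localised bulge. A filament whose maximum deviation is below
#' `tol` times the chord length (effectively straight — e.g. the residual
#' lattice wobble of an uncompressed chain) returns 0, keeping time series
#' complete at t = 0.
#'
#' @param frame a [filament_frame()].
#' @param n_points resampling resolution.
#' @param tol straightness tolerance, relative to the chord length.
#' @return dimensionless value in \[0, 1\].
#' @export
peak_asymmetry <- function(frame, n_points = 200L, tol = 1e-3) {
  rs <- resample_polyline(frame, n_points)
  p <- rs$points
  chord <- p[nrow(p), ] - p[1L, ]
  cl <- .vnorm(chord)
  rel <- sweep(p, 2L, p[1L, ])
  if (cl < 1e-9) {
    d <- sqrt(rowSums(rel^2))
    cl <- contour_length(rs)
  } else {
    u <- chord / cl
    proj <- rel %*% u
    d <- sqrt(pmax(0, rowSums(rel^2) - proj^2))
  }
  if (max(d) < tol * cl) return(0)
  seg <- segment_lengths(rs)
  s <- c(0, cumsum(seg)) / sum(seg)
  abs(2 * s[which.max(d)] - 1)
}

#' Non-coplanarity of a filament shape
#'
#' The fraction of positional variance along the third principal axis of the
#' filament's own point cloud: `lambda3 / (lambda1 + lambda2 + lambda3)` from
#' the eigendecomposition of the 3 x 3 covariance of the (resampled) points.
#' Exactly 0 for any planar shape, with maximum 1/3 for an isotropic cloud.
#'
#' @param frame a [filament_frame()].
#' @param n_points resampling resolution (`NULL` uses the points as given).
#' @return dimensionless value in \[0, 1/3\].
#' @export
non_coplanarity <- function(frame, n_points = 50L) {
  p <- if (is.null(n_points)) frame_points(frame)
       else resample_polyline(frame, n_points)$points
  cv <- stats::cov(p)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  tot <- sum(ev)
  if (tot <= 0) return(0)
  max(0, ev[3L]) / tot
}

#' Signed supertwist angle
#'
#' The signed angle between the projections of the first and last tangent
#' vectors of the chain onto the plane perpendicular to the compression axis,
#' measured right-handed about the axis: positive for a right-handed coil.
#' Per frame the raw value lies in (-180, 180] degrees; across a trajectory
#' use [unwrap_angles()] to track accumulated coiling beyond half a turn.
#' When either projected tangent is shorter than `tol` times the tangent
#' norm (tangent parallel to the axis, e.g. a straight filament) the metric
#' is undefined and `NA` is returned.
#'
#' @param frame a [filament_frame()]; for raw monomer beads smooth with
#'   [monomers_to_axis()] first.
#' @param axis unit 3-vector of the compression axis (default +x).
#' @param n_points resampling resolution before taking end tangents
#'   (`NULL` uses the chain as given).
#' @param tol relative tolerance for "tangent parallel to axis".
#' @return signed angle in degrees, or `NA` if undefined.
#' @export
supertwist_angle <- function(frame, axis = c(1, 0, 0), n_points = 50L,
                             tol = 1e-6) {
  axis <- axis / .vnorm(axis)
  p <- if (is.null(n_points)) frame_points(frame)
       else resample_polyline(frame, n_points)$points
  t0 <- p[2L, ] - p[1L, ]
  t1 <- p[nrow(p), ] - p[nrow(p) - 1L, ]
  proj <- function(v) v - sum(v * axis) * axis
  p0 <- proj(t0); p1 <- proj(t1)
  if (.vnorm(p0) < tol * .vnorm(t0) || .vnorm(p1) < tol * .vnorm(t1))
    return(NA_real_)
  .signed_angle_about(p0, p1, axis) * 180 / pi
}

#' Unwrap a wrapped angle series
#'
#' Nearest-branch continuity: each successive angle is shifted by a multiple
#' of 360 degrees to minimise the jump from its predecessor, so accumulated
#' coiling beyond +/-180 degrees is tracked. `NA`s are carried through; the
#' first non-`NA` value anchors the branch.
#'
#' @param deg numeric vector of angles in degrees (may contain `NA`).
#' @return unwrapped angles in degrees.
#' @export
unwrap_angles <- function(deg) {
  out <- deg
  last <- NA_real_
  for (i in seq_along(deg)) {
    if (is.na(deg[i])) next
    if (!is.na(last)) {
      out[i] <- deg[i] + 360 * round((last - deg[i]) / 360)
    }
    last <- out[i]
  }
  out
}

#' Normalized compression time
#'
#' Elapsed time divided by the total time needed to reach the target
#' compression at the protocol velocity,
#' `t_total = (1 - fraction) * initial_end_to_end / velocity`, clipped to
#' \[0, 1\]. For the 500 nm / 70 % protocol at 15 µm/s, `t_total` is 10 ms.
#'
#' @param times numeric vector of times (s).
#' @param protocol a [compression_protocol()].
#' @return numeric vector in \[0, 1\].
#' @export
normalized_time <- function(times, protocol) {
  pmin(1, pmax(0, times / total_compression_time(protocol)))
}

#' Persistence length from tangent correlations
#'
#' Fits the worm-like-chain decay `<t(s) . t(s + ds)> = exp(-ds / Lp)` to
#' tangent pairs pooled over the frames of each trajectory: correlations are
#' binned by arc-length separation and `1/Lp` is the least-squares slope of
#' `-log` of the positive bin means through the origin. The per-replicate
#' estimates are averaged and their standard deviation reported. If the mean
#' correlation never falls below `1 - tol` the chain is effectively rigid and
#' `Lp` is reported as `Inf` with a `rigid` flag.
#'
#' @param trajectories a `filament_trajectory`, a list of them, or a list of
#'   [filament_frame()]s (treated as one replicate).
#' @param smooth_window if > 1, frames that are raw bead chains are smoothed
#'   with [monomers_to_axis()] first.
#' @param max_fraction largest tangent separation used, as a fraction of
#'   contour length.
#' @param tol rigidity tolerance.
#' @return An object of class `persistence_length_estimate`: `Lp_um`,
#'   `sd_um`, `n_samples`, `per_replicate_um`, `rigid`.
#' @export
persistence_length <- function(trajectories, smooth_window = 1L,
                               max_fraction = 0.5, tol = 1e-9) {
  reps <- .as_trajectory_list(trajectories)
  per_rep <- vapply(reps, function(traj) {
    frames <- if (inherits(traj, "filament_trajectory")) traj$frames else traj
    .lp_one_replicate(frames, smooth_window, max_fraction)
  }, numeric(1))
  n_samples <- sum(vapply(reps, function(traj) {
    frames <- if (inherits(traj, "filament_trajectory")) traj$frames else traj
    length(frames)
  }, numeric(1)))
  rigid <- all(!is.finite(per_rep))
  est <- if (rigid) Inf else mean(per_rep[is.finite(per_rep)])
  sdv <- if (sum(is.finite(per_rep)) > 1L) stats::sd(per_rep[is.finite(per_rep)])
         else NA_real_
  structure(list(Lp_um = est, sd_um = sdv, n_samples = n_samples,
                 per_replicate_um = per_rep, rigid = rigid),
            class = "persistence_length_estimate")
}

#' @export
print.persistence_length_estimate <- function(x, ...) {
  if (x$rigid) cat("<persistence_length_estimate> rigid (no measurable decay)\n")
  else cat(sprintf("<persistence_length_estimate> %.2f +/- %.2f um (n = %d)\n",
                   x$Lp_um, if (is.na(x$sd_um)) 0 else x$sd_um, x$n_samples))
  invisible(x)
}

.as_trajectory_list <- function(x) {
  if (inherits(x, "filament_trajectory")) return(list(x))
  if (is_filament_frame(x)) return(list(list(x)))
  if (is.list(x) && length(x) && is_filament_frame(x[[1L]])) return(list(x))
  x
}

.lp_one_replicate <- function(frames, smooth_window, max_fraction) {
  # pooled tangent-correlation bins across frames; assumes equal layout
  corr_sum <- NULL
  corr_n <- NULL
  ds_ref <- NULL
  for (fr in frames) {
    if (smooth_window > 1L && !(is_filament_frame(fr) && fr$is_axis_curve))
      fr <- monomers_to_axis(fr, smooth_window)
    p <- frame_points(fr)
    seg <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    tang <- seg / len
    ns <- nrow(tang)
    smid <- c(0, cumsum(len))[-(ns + 1L)] + len / 2
    kmax <- max(1L, floor((ns - 1L) * max_fraction * 2))
    kmax <- min(kmax, ns - 1L)
    cors <- numeric(kmax); dss <- numeric(kmax)
    for (k in seq_len(kmax)) {
      i <- seq_len(ns - k)
      cors[k] <- mean(rowSums(tang[i, , drop = FALSE] *
                              tang[i + k, , drop = FALSE]))
      dss[k] <- mean(smid[i + k] - smid[i])
    }
    if (is.null(corr_sum)) {
      corr_sum <- cors; corr_n <- rep(1, kmax); ds_ref <- dss
    } else {
      m <- min(length(corr_sum), kmax)
      corr_sum[1:m] <- corr_sum[1:m] + cors[1:m]
      ds_ref[1:m] <- ds_ref[1:m] + dss[1:m]
      corr_n[1:m] <- corr_n[1:m] + 1
    }
  }
  cmean <- corr_sum / corr_n
  ds_mean <- ds_ref / corr_n
  keep <- cmean > 0
  if (!any(keep)) return(NA_real_)
  y <- -log(cmean[keep])
  s <- ds_mean[keep]
  if (all(y < 1e-9)) return(Inf)
  slope <- sum(s * y) / sum(s * s)  # through-origin least squares
  if (slope <= 0) return(Inf)
  (1 / slope) * 1e-3  # nm -> um
}

#' Per-frame metric table for a trajectory
#'
#' Computes every shape metric for each frame of a trajectory: end-to-end
#' distance, compression ratio, peak asymmetry, non-coplanarity and the
#' (unwrapped) supertwist angle, plus normalized compression time when the
#' trajectory carries a protocol. End-to-end distance and compression ratio
#' are measured between the raw chain's end points (the protocol-level
#' definition of compression); the shape metrics are taken on the smoothed
#' and/or trimmed representation, since raw monomer zigzag or axis-pinned
#' anchor segments would corrupt their tangents.
#'
#' @param trajectory a `filament_trajectory`.
#' @param smooth_window window for [monomers_to_axis()] applied to raw bead
#'   frames (`1` disables smoothing; the fiber-scale chain needs none).
#' @param trim_ends number of beads dropped from each chain end before
#'   measuring. The fiber-scale chain's outermost anchor bead pins its end
#'   segment exactly onto the compression axis, which would leave the
#'   supertwist tangent projection identically zero; dropping one bead per
#'   end exposes the first thermally fluctuating segment instead.
#' @param n_points resampling resolution for the metrics.
#' @param initial_end_to_end reference end-to-end distance (nm); defaults to
#'   the first frame's.
#' @return A data.frame with one row per frame and columns `time_s`,
#'   `normalized_time`, `end_to_end_nm`, `compression_ratio`,
#'   `peak_asymmetry`, `non_coplanarity`, `supertwist_deg` (unwrapped; `NA`
#'   where undefined), `contour_length_nm`.
#' @export
measure_trajectory <- function(trajectory, smooth_window = 1L,
                               trim_ends = 0L, n_points = 50L,
                               initial_end_to_end = NULL) {
  frames <- trajectory$frames
  mframes <- lapply(frames, function(fr) {
    if (trim_ends > 0L) {
      p <- fr$points
      keep <- (1L + trim_ends):(nrow(p) - trim_ends)
      fr <- filament_frame(p[keep, , drop = FALSE], time = fr$time,
                           is_axis_curve = fr$is_axis_curve)
    }
    if (smooth_window > 1L && !fr$is_axis_curve)
      monomers_to_axis(fr, smooth_window) else fr
  })
  if (is.null(initial_end_to_end))
    initial_end_to_end <- end_to_end(frames[[1L]])
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    mfr <- mframes[[i]]
    cm <- compression_metrics(fr, initial_end_to_end)
    data.frame(
      time_s = fr$time,
      end_to_end_nm = cm$end_to_end,
      compression_ratio = cm$compression_ratio,
      peak_asymmetry = peak_asymmetry(mfr),
      non_coplanarity = non_coplanarity(mfr, n_points),
      supertwist_deg = supertwist_angle(mfr, n_points = n_points),
      contour_length_nm = contour_length(mfr)
    )
  })
  out <- do.call(rbind, rows)
  out$supertwist_deg <- unwrap_angles(out$supertwist_deg)
  out$normalized_time <- if (!is.null(trajectory$protocol))
    normalized_time(out$time_s, trajectory$protocol)
  else out$time_s / max(out$time_s[length(out$time_s)], .Machine$double.eps)
  out[, c("time_s", "normalized_time", "end_to_end_nm", "compression_ratio",
          "peak_asymmetry", "non_coplanarity", "supertwist_deg",
          "contour_length_nm")]
}
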