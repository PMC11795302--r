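#' Read and write trajectories as plain-text CSV
#'
#' One file per replicate with header `time_s,point_index,x_nm,y_nm,z_nm`
#' (full double precision, so trajectories round-trip bit-exactly), plus a
#' YAML sidecar (`<file>.yaml`) capturing the protocol, resolution label,
#' replicate and seed.
#'
#' @param trajectory a `filament_trajectory`.
#' @param path output CSV path.
#' @param sidecar write the YAML sidecar next to the CSV.
#' @return `path`, invisibly (writer); a `filament_trajectory` (reader).
#' @export
write_trajectory_csv <- function(trajectory, path, sidecar = TRUE) {
  rows <- lapply(seq_along(trajectory$frames), function(i) {
    p <- trajectory$frames[[i]]$points
    sprintf("%.17g,%d,%.17g,%.17g,%.17g",
            trajectory$times[i], seq_len(nrow(p)) - 1L,
            p[, 1L], p[, 2L], p[, 3L])
  })
  writeLines(c("time_s,point_index,x_nm,y_nm,z_nm", unlist(rows)), path)
  if (sidecar) {
    meta <- list(
      resolution = trajectory$resolution_label,
      replicate = trajectory$replicate,
      seed = trajectory$seed,
      reached_target = trajectory$reached_target,
      protocol = if (!is.null(trajectory$protocol))
        unclass(trajectory$protocol) else NULL
    )
    yaml::write_yaml(meta, paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("time_s", "point_index", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(df)))
    stop("not a trajectory CSV (expected header ",
         paste(need, collapse = ","), "): ", path)
  meta <- NULL
  sc <- paste0(path, ".yaml")
  if (file.exists(sc)) meta <- yaml::read_yaml(sc)
  times <- unique(df$time_s)
  frames <- lapply(times, function(tt) {
    sub <- df[df$time_s == tt, ]
    sub <- sub[order(sub$point_index), ]
    filament_frame(cbind(x = sub$x_nm, y = sub$y_nm, z = sub$z_nm), time = tt)
  })
  protocol <- NULL
  if (!is.null(meta$protocol))
    protocol <- structure(meta$protocol, class = "compression_protocol")
  .trajectory(frames, times, protocol,
              resolution_label = if (!is.null(meta$resolution))
                meta$resolution else "external",
              replicate = if (!is.null(meta$replicate)) meta$replicate else 1L,
              seed = meta$seed,
              reached_target = if (!is.null(meta$reached_target))
                meta$reached_target else NA)
}

#' Read and write per-frame metric tables
#'
#' CSV with header `resolution,velocity_um_s,replicate,time_s,
#' normalized_time,end_to_end_nm,compression_ratio,peak_asymmetry,
#' non_coplanarity,supertwist_deg`. Numbers are written at full double
#' precision so identical runs produce byte-identical files.
#'
#' @param metrics data.frame with the columns above.
#' @param path CSV path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_metrics_csv <- function(metrics, path) {
  cols <- c("resolution", "velocity_um_s", "replicate", "time_s",
            "normalized_time", "end_to_end_nm", "compression_ratio",
            "peak_asymmetry", "non_coplanarity", "supertwist_deg")
  metrics <- metrics[, cols]
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- sprintf("%s,%s,%d,%s,%s,%s,%s,%s,%s,%s",
                   metrics$resolution, num(metrics$velocity_um_s),
                   metrics$replicate, num(metrics$time_s),
                   num(metrics$normalized_time), num(metrics$end_to_end_nm),
                   num(metrics$compression_ratio), num(metrics$peak_asymmetry),
                   num(metrics$non_coplanarity), num(metrics$supertwist_deg))
  writeLines(c(paste(cols, collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write a fitted shape space as JSON
#'
#' Stores the mean shape, the component basis, explained variance ratios and
#' component standard deviations.
#'
#' @param space a `shape_space`.
#' @param path JSON path.
#' @return `path` invisibly (writer); a `shape_space` (reader).
#' @export
write_shape_space_json <- function(space, path) {
  obj <- list(mean_shape = as.numeric(space$mean_shape),
              components = unname(as.matrix(space$components)),
              explained_variance_ratio =
                as.numeric(space$explained_variance_ratio),
              sdev = as.numeric(space$sdev),
              n_points = space$n_points,
              n_samples = space$n_samples)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shape_space_json
#' @export
read_shape_space_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_shape = obj$mean_shape,
                 components = as.matrix(obj$components),
                 explained_variance_ratio = obj$explained_variance_ratio,
                 sdev = obj$sdev, n_points = obj$n_points,
                 n_samples = obj$n_samples),
            class = "shape_space")
}
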