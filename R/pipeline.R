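#' Configuration of a simulate/measure/pca run
#'
#' The `"paper"` preset runs the full-scale protocol geometry: a 500 nm
#' filament compressed to 70 % at 4.7, 15, 47 and 150 µm/s, five replicates
#' each. The `"desk"` preset (default) is the package's scaled-down study:
#' a 120 nm filament at the two fastest velocities (47 and 150 µm/s), five
#' replicates, which runs on one CPU in minutes while preserving the
#' chiral-versus-achiral contrast.
#'
#' @param preset `"desk"` or `"paper"`; explicit arguments override preset
#'   values.
#' @param resolutions subset of `c("monomer", "fiber")`.
#' @param velocities compression velocities (µm/s).
#' @param replicates replicates per condition, >= 1.
#' @param filament_length_nm initial filament length (nm).
#' @param compression_fraction target end-to-end fraction.
#' @param base_seed integer; run seeds are derived deterministically from it.
#' @param output_dir pipeline output directory.
#' @param n_frames_out frames kept per trajectory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = c("desk", "paper"),
                       resolutions = c("monomer", "fiber"),
                       velocities = NULL, replicates = NULL,
                       filament_length_nm = NULL,
                       compression_fraction = 0.7,
                       base_seed = 1L, output_dir = "filacomp_run",
                       n_frames_out = 60L) {
  preset <- match.arg(preset)
  if (is.null(velocities))
    velocities <- if (preset == "paper") c(4.7, 15, 47, 150) else c(47, 150)
  if (is.null(replicates)) replicates <- 5L
  if (is.null(filament_length_nm))
    filament_length_nm <- if (preset == "paper") 500 else 120
  if (replicates < 1L) stop("replicates must be >= 1")
  if (any(velocities <= 0)) stop("velocities must be > 0")
  structure(list(preset = preset,
                 resolutions = match.arg(resolutions,
                                         c("monomer", "fiber"),
                                         several.ok = TRUE),
                 velocities = velocities,
                 replicates = as.integer(replicates),
                 filament_length_nm = filament_length_nm,
                 compression_fraction = compression_fraction,
                 base_seed = as.integer(base_seed),
                 output_dir = output_dir,
                 n_frames_out = as.integer(n_frames_out)),
            class = "run_config")
}

# deterministic per-run seed from the base seed and run counter
.run_seed <- function(base_seed, counter) base_seed + 7919 * counter

#' Simulate one compression run at a given resolution
#'
#' Convenience wrapper that builds the chain for the requested resolution
#' (`"monomer"`: chiral helical bead chain, default timestep 5e-11 s;
#' `"fiber"`: achiral 10 nm-segment worm-like chain, protocol timestep
#' 5e-7 s integrated with 2500 substeps) and runs [simulate_compression()].
#'
#' @param resolution `"monomer"` or `"fiber"`.
#' @param velocity_um_s compression velocity (µm/s).
#' @param length_nm initial filament length (nm).
#' @param seed RNG seed for this run.
#' @param compression_fraction target end-to-end fraction.
#' @param replicate replicate index stored on the trajectory.
#' @param n_frames_out frames kept.
#' @param kT thermal energy (pN nm); 0 disables noise.
#' @param mirror build the mirror-image (left-handed) monomer chain.
#' @return A `filament_trajectory`.
#' @export
simulate_filament <- function(resolution = c("monomer", "fiber"),
                              velocity_um_s, length_nm = 120, seed = 1L,
                              compression_fraction = 0.7, replicate = 1L,
                              n_frames_out = 60L, kT = 4.1, mirror = FALSE) {
  resolution <- match.arg(resolution)
  if (resolution == "monomer") {
    chain <- build_monomer_chain(length_nm = length_nm, mirror = mirror)
    thermal <- thermal_model(
      kT = kT,
      drag_per_particle = stokes_drag(.monomer_defaults$bead_radius_nm,
                                      scale = .monomer_defaults$drag_scale),
      seed = seed)
    protocol <- compression_protocol(
      velocity_um_s, timestep_s = .monomer_defaults$timestep_s,
      initial_end_to_end_nm = end_to_end(chain$frame),
      compression_fraction = compression_fraction,
      fixed_end_particles = 3L, moved_end_particles = 3L)
    simulate_compression(chain$ff, protocol, thermal, chain$frame,
                         n_frames_out = n_frames_out, n_sub = 1L,
                         resolution_label = "monomer", replicate = replicate)
  } else {
    chain <- build_fiber_chain(n_segments = max(3L, round(length_nm / 10)),
                               segment_length = 10)
    thermal <- thermal_model(
      kT = kT, drag_per_particle = stokes_drag(5), seed = seed)
    protocol <- compression_protocol(
      velocity_um_s, timestep_s = 5e-7,
      initial_end_to_end_nm = end_to_end(chain$frame),
      compression_fraction = compression_fraction,
      fixed_end_particles = 2L, moved_end_particles = 2L)
    simulate_compression(chain$ff, protocol, thermal, chain$frame,
                         n_frames_out = n_frames_out, n_sub = 2500L,
                         resolution_label = "fiber", replicate = replicate)
  }
}

.traj_filename <- function(resolution, velocity, replicate) {
  sprintf("%s_v%g_r%d.csv", resolution, velocity, replicate)
}

#' Run the simulate -> measure -> pca -> report pipeline
#'
#' Executes the full comparison for a [run_config()]: simulates every
#' (resolution, velocity, replicate) combination, measures the per-frame
#' shape metrics, fits the pooled shape space, writes latent walks and PC
#' scores, and renders a markdown report. The output directory layout is
#' deterministic: `trajectories/`, `metrics.csv`, `shape_space.json`,
#' `pc_scores.csv`, `latent_walk_pc1.csv`, `latent_walk_pc2.csv`,
#' `report.md`, `manifest.json` (config, per-run seeds, content hashes).
#' Completed trajectory files are reused on rerun, so interrupted runs
#' resume at the first missing file.
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress.
#' @param make_plots also render PNG panels next to the report (skipped
#'   silently if no graphics device is available).
#' @return Invisibly, a list with the metric table, the fitted `shape_space`,
#'   the score table and the manifest.
#' @export
run_pipeline <- function(config, verbose = FALSE, make_plots = FALSE) {
  out <- config$output_dir
  dir.create(file.path(out, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...))
  runs <- expand.grid(replicate = seq_len(config$replicates),
                      velocity = config$velocities,
                      resolution = config$resolutions,
                      stringsAsFactors = FALSE)
  runs$counter <- seq_len(nrow(runs))
  runs$seed <- .run_seed(config$base_seed, runs$counter)
  runs$file <- file.path(out, "trajectories",
                         mapply(.traj_filename, runs$resolution,
                                runs$velocity, runs$replicate))

  # --- stage 1: simulate ---------------------------------------------------
  t0 <- Sys.time()
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (file.exists(r$file)) next
    say("simulate %s v=%g rep=%d (seed %d)", r$resolution, r$velocity,
        r$replicate, r$seed)
    traj <- simulate_filament(r$resolution, r$velocity,
                              length_nm = config$filament_length_nm,
                              seed = r$seed,
                              compression_fraction =
                                config$compression_fraction,
                              replicate = r$replicate,
                              n_frames_out = config$n_frames_out)
    write_trajectory_csv(traj, r$file)
  }
  say("simulate stage done (%.1f s)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  # --- stage 2: measure ----------------------------------------------------
  t0 <- Sys.time()
  metrics <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    traj <- read_trajectory_csv(r$file)
    sw <- if (r$resolution == "monomer") 13L else 1L
    tr_ends <- if (r$resolution == "fiber") 1L else 0L
    m <- measure_trajectory(traj, smooth_window = sw, trim_ends = tr_ends)
    cbind(data.frame(resolution = r$resolution, velocity_um_s = r$velocity,
                     replicate = r$replicate), m)
  }))
  write_metrics_csv(metrics, file.path(out, "metrics.csv"))
  say("measure stage done (%.1f s)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  # --- stage 3: shape space ------------------------------------------------
  t0 <- Sys.time()
  # shapes enter the PCA at full length (raw bead chains, resampled): axis
  # smoothing would shorten the monomer chains by one window relative to the
  # fiber chains and leak model identity into PC1
  frames <- list(); keys <- list()
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    traj <- read_trajectory_csv(r$file)
    fs <- traj$frames
    frames <- c(frames, fs)
    keys <- c(keys, lapply(seq_along(fs), function(j)
      data.frame(resolution = r$resolution, velocity_um_s = r$velocity,
                 replicate = r$replicate)))
  }
  keys <- do.call(rbind, keys)
  sm <- shape_matrix(frames, n_points = 50L)
  sign_feats <- data.frame(
    f1 = metrics$compression_ratio,
    f2 = ifelse(metrics$resolution == "monomer", metrics$supertwist_deg,
                NA_real_))
  space <- fit_shape_space(sm, n_components = 8L, sign_features = sign_feats)
  scores <- project_shapes(sm, space)
  score_table <- cbind(keys, scores,
                       metrics[, c("time_s", "normalized_time",
                                   "compression_ratio", "peak_asymmetry",
                                   "non_coplanarity", "supertwist_deg")])
  write_shape_space_json(space, file.path(out, "shape_space.json"))
  utils::write.csv(score_table, file.path(out, "pc_scores.csv"),
                   row.names = FALSE)
  for (k in 1:2) {
    walk <- latent_walk(space, k)
    wdf <- do.call(rbind, lapply(seq_along(walk), function(j) {
      p <- walk[[j]]$points
      data.frame(score = attr(walk, "scores")[j],
                 point_index = seq_len(nrow(p)) - 1L,
                 x_nm = p[, 1L], y_nm = p[, 2L], z_nm = p[, 3L])
    }))
    utils::write.csv(wdf, file.path(out, sprintf("latent_walk_pc%d.csv", k)),
                     row.names = FALSE)
  }
  say("pca stage done (%.1f s)",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  # --- stage 4: report -----------------------------------------------------
  fc <- feature_correlation(score_table)
  .write_report(out, config, metrics, space, score_table, fc, make_plots)

  manifest <- list(
    config = unclass(config),
    runs = runs[, c("resolution", "velocity", "replicate", "seed")],
    hashes = as.list(tools::md5sum(
      file.path(out, c("metrics.csv", "shape_space.json", "pc_scores.csv"))))
  )
  names(manifest$hashes) <- basename(names(manifest$hashes))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(list(metrics = metrics, space = space,
                 score_table = score_table,
                 feature_correlation = fc, manifest = manifest))
}

.write_report <- function(out, config, metrics, space, score_table, fc,
                          make_plots) {
  late <- score_table[score_table$normalized_time >= 0.75, ]
  agg <- stats::aggregate(
    cbind(peak_asymmetry, non_coplanarity, supertwist_deg) ~ resolution,
    data = metrics[metrics$normalized_time >= 0.75, ],
    FUN = function(x) stats::median(x, na.rm = TRUE), na.action = stats::na.pass)
  lines <- c(
    "# Filament compression comparison report", "",
    sprintf("Preset: %s; filament %g nm compressed to %.0f%% at %s um/s; %d replicates.",
            config$preset, config$filament_length_nm,
            100 * config$compression_fraction,
            paste(config$velocities, collapse = ", "), config$replicates), "",
    "## Late-time (normalized time >= 0.75) metric medians", "",
    paste(utils::capture.output(print(agg, row.names = FALSE)),
          collapse = "\n"), "",
    "## Shape-space explained variance", "",
    paste(sprintf("PC%d: %.1f%%", seq_along(space$explained_variance_ratio),
                  100 * space$explained_variance_ratio), collapse = "; "), "",
    "## PC-score / metric correlations", "",
    paste(utils::capture.output(print(round(fc, 3))), collapse = "\n"), "",
    "## Late-time PC2 by simulator", "",
    paste(utils::capture.output(print(stats::aggregate(
      PC2 ~ resolution, data = late, FUN = stats::median))),
      collapse = "\n"), ""
  )
  writeLines(lines, file.path(out, "report.md"))
  if (make_plots) {
    try({
      grDevices::png(file.path(out, "metrics_vs_time.png"), 1200, 800,
                     res = 120)
      graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
      for (m in c("compression_ratio", "peak_asymmetry", "non_coplanarity",
                  "supertwist_deg")) {
        graphics::plot(NA, xlim = c(0, 1),
                       ylim = range(metrics[[m]], na.rm = TRUE),
                       xlab = "normalized time", ylab = m, main = m)
        for (res in unique(metrics$resolution)) {
          for (rep in unique(metrics$replicate)) {
            for (v in unique(metrics$velocity_um_s)) {
              sub <- metrics[metrics$resolution == res &
                             metrics$replicate == rep &
                             metrics$velocity_um_s == v, ]
              graphics::lines(sub$normalized_time, sub[[m]],
                              col = if (res == "monomer") "#d95f02"
                                    else "#1b9e77")
            }
          }
        }
      }
      grDevices::dev.off()
      grDevices::png(file.path(out, "pc_space.png"), 900, 700, res = 120)
      graphics::plot(score_table$PC1, score_table$PC2,
                     col = ifelse(score_table$resolution == "monomer",
                                  "#d95f02", "#1b9e77"),
                     pch = 16, cex = 0.5, xlab = "PC1", ylab = "PC2")
      graphics::legend("topleft", legend = c("monomer", "fiber"),
                       col = c("#d95f02", "#1b9e77"), pch = 16)
      grDevices::dev.off()
    }, silent = TRUE)
  }
  invisible(NULL)
}

#' Write the parametric test fixtures
#'
#' Writes the analytic shapes (straight rod, symmetric and skewed planar
#' arcs, right- and left-handed coils) as single-frame trajectory CSVs with
#' their ground-truth metric values in a `fixtures.json` manifest.
#'
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the generated frames.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  shapes <- list(
    straight = generate_parametric_shape("straight", length = 500,
                                         n_points = 50L),
    arc_symmetric = generate_parametric_shape("planar_arc", chord = 350,
                                              height = 80),
    arc_skewed = generate_parametric_shape("planar_arc", chord = 350,
                                           height = 80, peak_fraction = 0.25),
    coil_right = generate_parametric_shape("helical_coil", winding_deg = 60),
    coil_left = generate_parametric_shape("helical_coil", winding_deg = -60)
  )
  truths <- list()
  for (nm in names(shapes)) {
    traj <- .trajectory(list(shapes[[nm]]), times = 0, protocol = NULL,
                        resolution_label = "parametric", replicate = 1L,
                        seed = NA)
    write_trajectory_csv(traj, file.path(out_dir, paste0(nm, ".csv")),
                         sidecar = FALSE)
    truths[[nm]] <- attr(shapes[[nm]], "truth")
  }
  jsonlite::write_json(truths, file.path(out_dir, "fixtures.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(shapes)
}
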