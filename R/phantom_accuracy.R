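# In-silico checkerboard-phantom accuracy study: phantom generation, the
# repeated-localization protocol over several projector standoff distances,
# per-divot error Err = ||real - virtual||, and RMS reporting.

#' Checkerboard accuracy-phantom specification
#'
#' The default is a CNC-machined acrylic plate bearing a 5 x 5 grid of
#' conical divots at 20 mm pitch over a 10 mm checker pattern; the four
#' corner divots double as registration fiducials.
#'
#' @param rows,cols divot grid counts.
#' @param divot_spacing center-to-center divot pitch (mm).
#' @param checker_square checker square edge (mm); independent of the divot
#'   pitch (divots occupy alternating squares on the physical plate).
#' @param registration_divots labels of divots used as registration
#'   fiducials; at least 3 non-collinear (default: the 4 outer corners).
#' @param plane_pose `rigid_transform` placing the phantom plane (phantom
#'   frame -> tracker frame); the divots lie in the plane z = 0 of the
#'   phantom frame.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 5, cols = 5, divot_spacing = 20,
                         checker_square = 10,
                         registration_divots = NULL,
                         plane_pose = identity_transform("phantom", "tracker")) {
  stopifnot(rows >= 1, cols >= 1, divot_spacing > 0, checker_square > 0,
            inherits(plane_pose, "rigid_transform"))
  if (is.null(registration_divots))
    registration_divots <- c("r1c1", paste0("r1c", cols), paste0("r", rows, "c1"),
                             paste0("r", rows, "c", cols))
  registration_divots <- unique(registration_divots)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 divot_spacing = divot_spacing, checker_square = checker_square,
                 registration_divots = registration_divots,
                 plane_pose = plane_pose),
            class = "phantom_spec")
}

#' Generate the phantom geometry
#'
#' Divots are laid out row-major on a centered grid in the phantom plane
#' (z = 0), labelled `r<i>c<j>`; the plane and the registration-fiducial
#' subset are returned in both the phantom and the tracker frame.
#' Deterministic: no randomness is involved.
#'
#' @param spec `phantom_spec`.
#' @return List: `divots` (data.frame with labels, phantom- and tracker-frame
#'   coordinates), `fiducials_phantom` / `fiducials_tracker` (`fiducial_set`
#'   of the registration divots), `plane` (`plane_surface` in the tracker
#'   frame), and `checker` (0/1 pattern matrix at `checker_square` pitch).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ij <- expand.grid(col = seq_len(spec$cols), row = seq_len(spec$rows))
  x <- (ij$col - (spec$cols + 1) / 2) * spec$divot_spacing
  y <- (ij$row - (spec$rows + 1) / 2) * spec$divot_spacing
  pts <- cbind(x, y, 0)
  labels <- paste0("r", ij$row, "c", ij$col)
  world <- apply_transform(spec$plane_pose, pts)
  reg_idx <- match(spec$registration_divots, labels)
  if (anyNA(reg_idx))
    stop("generate_phantom: unknown registration divot label(s): ",
         paste(spec$registration_divots[is.na(reg_idx)], collapse = ", "))
  # grids too small to carry 3 fiducials are still generated (geometry only);
  # registration-based protocols will refuse them downstream
  has_fids <- length(reg_idx) >= 3
  if (has_fids) {
    ctr <- sweep(pts[reg_idx, 1:2, drop = FALSE],
                 2, colMeans(pts[reg_idx, 1:2, drop = FALSE]))
    if (svd(ctr)$d[2] <= 1e-6)
      stop("generate_phantom: registration divots are collinear")
  }
  nrml <- as.vector(spec$plane_pose$rotation %*% c(0, 0, 1))
  ncheck <- ceiling(max(spec$cols, spec$rows) * spec$divot_spacing /
                      spec$checker_square)
  checker <- outer(seq_len(ncheck), seq_len(ncheck),
                   function(i, j) (i + j) %% 2)
  list(divots = data.frame(label = labels, x = pts[, 1], y = pts[, 2],
                           z = pts[, 3], wx = world[, 1], wy = world[, 2],
                           wz = world[, 3]),
       fiducials_phantom = if (has_fids)
         fiducial_set(labels[reg_idx], pts[reg_idx, , drop = FALSE],
                      frame = "image"),
       fiducials_tracker = if (has_fids)
         fiducial_set(labels[reg_idx], world[reg_idx, , drop = FALSE],
                      frame = "tracker"),
       plane = plane_surface(apply_transform(spec$plane_pose, c(0, 0, 0)),
                             nrml, frame = "tracker"),
       checker = checker)
}

#' Euclidean localization error (mm)
#'
#' `Err = ||real - virtual||`, the distance between the physically localized
#' ("real") divot position and the position the projected AR image places it
#' at ("virtual").
#'
#' @param real,virtual 3-vectors (mm) in a common frame.
#' @return Distance in mm.
#' @export
localization_error <- function(real, virtual) {
  real <- as.numeric(real); virtual <- as.numeric(virtual)
  stopifnot(length(real) == 3, length(virtual) == 3)
  if (!all(is.finite(real)) || !all(is.finite(virtual)))
    stop("localization_error: non-finite coordinates")
  sqrt(sum((real - virtual)^2))
}

# a random pointer orientation within a cone about the phantom normal, so
# that repeated divot touches vary realistically in approach angle
random_pointer_pose <- function(tip_world, tool, max_tilt_deg = 20) {
  tilt <- stats::runif(1, 0, max_tilt_deg)
  azim <- stats::runif(1, 0, 360)
  spin <- stats::runif(1, 0, 360)
  R <- rot_z(azim) %*% rot_y(tilt) %*% rot_z(spin)
  tr <- tip_world - as.vector(R %*% tool$tip_offset)
  rigid_transform(R, tr, from = tool$tool_id, to = "tracker")
}

# one noisy pointer-tip sample at a known physical point
sample_pointer <- function(point_world, tool, noise) {
  pose <- random_pointer_pose(point_world, tool)
  meas <- measure_pose(tool, pose, noise)
  tip <- pointer_tip(meas, tool)
  if (noise$pointer_extra_sigma > 0)
    tip <- tip + stats::rnorm(3, 0, noise$pointer_extra_sigma)
  tip
}

#' Run the phantom localization protocol
#'
#' Simulates the full accuracy study. Image-to-tracker registration is
#' performed once per run from noisy pointer samples of the registration
#' divots (its FRE is recorded); then, for each projector standoff distance,
#' the projector is placed facing the phantom center at that distance and
#' every divot is localized `reps` times with the noisy tracked pointer (the
#' "real" location is the mean of the repetitions). The "virtual" location
#' is obtained by the physical projection mechanism: the navigation platform
#' computes the divot's pixel from the *measured* (noisy) projector pose and
#' the estimated registration, but the light physically leaves the projector
#' at its *true* pose, so the virtual point is that pixel's ray cast from the
#' true pose intersected with the true phantom plane.
#'
#' @param spec `phantom_spec`.
#' @param model `projector_model` (ground-truth device).
#' @param noise `noise_model`.
#' @param distances projector standoff distances (mm).
#' @param reps pointer repetitions per divot per distance.
#' @param seed RNG seed for the whole run.
#' @param pointer_tool,projector_tool tracked-tool geometries.
#' @return Object of class `protocol_run`: `records` (one row per divot x
#'   distance x rep: samples, real/virtual points, `err_mm`), `fre` (mm),
#'   `registration` (the estimated transform), plus the run configuration.
#' @export
run_protocol <- function(spec = phantom_spec(),
                         model = default_projector_model(),
                         noise = noise_model(),
                         distances = c(200, 300, 400),
                         reps = 3, seed = 1,
                         pointer_tool = default_pointer_tool(),
                         projector_tool = default_projector_tool()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(model, "projector_model"),
            inherits(noise, "noise_model"), reps >= 1, all(distances > 0))
  set.seed(as.integer(seed))
  ph <- generate_phantom(spec)
  if (is.null(ph$fiducials_tracker))
    stop("run_protocol: the phantom spec provides fewer than 3 registration divots")
  nd <- nrow(ph$divots)

  # --- registration: one noisy pointer pick per registration divot (the
  # repeated localization of the protocol applies to the accuracy divots;
  # fiducial registration uses a single pick per landmark, as in practice)
  reg_world <- ph$fiducials_tracker$points
  reg_meas <- t(vapply(seq_len(nrow(reg_world)), function(i)
    sample_pointer(reg_world[i, ], pointer_tool, noise), numeric(3)))
  reg_fit <- rigid_register(ph$fiducials_phantom,
                            fiducial_set(ph$fiducials_tracker$labels, reg_meas,
                                         frame = "tracker"))
  T_reg <- reg_fit$transform # image -> tracker (estimated)

  # divot coordinates as known in the image (phantom CBCT) frame
  divots_image <- as.matrix(ph$divots[, c("x", "y", "z")])
  divots_world <- as.matrix(ph$divots[, c("wx", "wy", "wz")])
  plane_center <- ph$plane$point
  nrml <- ph$plane$normal

  rows <- vector("list", nd * reps * length(distances))
  k <- 0L
  for (d in distances) {
    # true projector pose: optical center at distance d along the plane
    # normal, looking down the -normal direction at the phantom
    zax <- -nrml
    xax <- spec$plane_pose$rotation[, 1]
    xax <- xax - sum(xax * zax) * zax
    xax <- xax / sqrt(sum(xax^2))
    yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
             zax[3] * xax[1] - zax[1] * xax[3],
             zax[1] * xax[2] - zax[2] * xax[1])
    T_proj_true <- rigid_transform(cbind(xax, yax, zax), plane_center + d * nrml,
                                   from = "projector", to = "tracker")
    T_sensor_true <- compose_transform(
      T_proj_true, invert_transform(model$t_sensor_to_projector))
    pose_true <- tracked_pose(projector_tool$tool_id, T_sensor_true)
    pose_meas <- measure_pose(projector_tool, T_sensor_true, noise)
    if (noise$projector_orientation_sigma_deg > 0) {
      J <- jitter_rotation(noise$projector_orientation_sigma_deg)
      pose_meas$transform$rotation <- pose_meas$transform$rotation %*% J
    }

    for (i in seq_len(nd)) {
      # virtual divot: pixel from measured pose + estimated registration,
      # ray physically cast from the true pose onto the true plane
      p_est <- apply_transform(T_reg, divots_image[i, ])
      pix <- project_point(model, pose_meas, p_est)
      virtual <- intersect_ray(cast_ray(model, pose_true, pix), ph$plane)

      samples <- t(vapply(seq_len(reps), function(r)
        sample_pointer(divots_world[i, ], pointer_tool, noise), numeric(3)))
      real <- colMeans(samples)
      err <- localization_error(real, virtual)
      for (r in seq_len(reps)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          divot_id = ph$divots$label[i], distance_mm = d, rep = r,
          sample_x = samples[r, 1], sample_y = samples[r, 2],
          sample_z = samples[r, 3],
          real_x = real[1], real_y = real[2], real_z = real[3],
          virtual_x = virtual[1], virtual_y = virtual[2],
          virtual_z = virtual[3], err_mm = err)
      }
    }
  }
  structure(list(records = do.call(rbind, rows), fre = reg_fit$fre,
                 registration = T_reg, spec = spec, noise = noise,
                 distances = distances, reps = reps, seed = as.integer(seed)),
            class = "protocol_run")
}

#' @export
print.protocol_run <- function(x, ...) {
  cat(sprintf("<protocol_run %d records, FRE = %.3f mm, seed %d>\n",
              nrow(x$records), x$fre, x$seed))
  invisible(x)
}

#' Aggregate per-distance RMS values into the overall system figure
#'
#' The overall accuracy figure is the unweighted arithmetic mean of the
#' per-distance RMS values (each distance condition contributes equally,
#' regardless of divot count).
#'
#' @param rms_values numeric vector of per-distance RMS values (mm).
#' @return Overall RMS figure (mm).
#' @export
aggregate_distance_rms <- function(rms_values) {
  stopifnot(length(rms_values) > 0, all(is.finite(rms_values)))
  mean(rms_values)
}

#' Summarize a protocol run into an accuracy report
#'
#' Per distance: RMS and SD of the per-divot errors. Overall: the unweighted
#' mean of the per-distance RMS values (see [aggregate_distance_rms()]);
#' a pooled RMS (root of the mean squared error over all divots and
#' distances) and the pooled SD are also reported for transparency.
#'
#' @param run `protocol_run`, or a records data.frame plus `fre`.
#' @param fre FRE (mm) if `run` is a bare data.frame.
#' @return Object of class `accuracy_report`: `fre`, `per_distance`
#'   (data.frame distance/rms/sd/n), `overall_rms`, `overall_sd`,
#'   `pooled_rms`, `n_localizations`.
#' @export
summarize_accuracy <- function(run, fre = NULL) {
  if (inherits(run, "protocol_run")) {
    records <- run$records; fre <- run$fre
  } else {
    records <- run
    if (is.null(fre)) stop("summarize_accuracy: fre required with a bare data.frame")
  }
  if (is.null(records) || nrow(records) == 0)
    stop("summarize_accuracy: no localization records")
  per_divot <- unique(records[, c("divot_id", "distance_mm", "err_mm")])
  ds <- sort(unique(per_divot$distance_mm))
  per_distance <- do.call(rbind, lapply(ds, function(d) {
    e <- per_divot$err_mm[per_divot$distance_mm == d]
    data.frame(distance_mm = d, rms_mm = sqrt(mean(e^2)),
               sd_mm = if (length(e) > 1) stats::sd(e) else 0,
               n_divots = length(e))
  }))
  all_err <- per_divot$err_mm
  structure(list(fre = fre, per_distance = per_distance,
                 overall_rms = aggregate_distance_rms(per_distance$rms_mm),
                 overall_sd = if (length(all_err) > 1) stats::sd(all_err) else 0,
                 pooled_rms = sqrt(mean(all_err^2)),
                 n_localizations = nrow(records)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report FRE = %.3f mm, %d localizations>\n",
              x$fre, x$n_localizations))
  for (i in seq_len(nrow(x$per_distance)))
    cat(sprintf("  %4.0f mm: RMS %.3f +/- %.3f mm (n = %d divots)\n",
                x$per_distance$distance_mm[i], x$per_distance$rms_mm[i],
                x$per_distance$sd_mm[i], x$per_distance$n_divots[i]))
  cat(sprintf("  overall: %.3f +/- %.3f mm (pooled RMS %.3f mm)\n",
              x$overall_rms, x$overall_sd, x$pooled_rms))
  invisible(x)
}

#' Write an accuracy report (JSON) and protocol records (CSV)
#' @param report `accuracy_report`.
#' @param run `protocol_run` (for the records and run configuration).
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @export
write_accuracy_report <- function(report, run = NULL, json_path = NULL,
                                  csv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(
      fre_mm = report$fre,
      per_distance = report$per_distance,
      overall_rms_mm = report$overall_rms,
      overall_sd_mm = report$overall_sd,
      pooled_rms_mm = report$pooled_rms,
      n_localizations = report$n_localizations)
    if (!is.null(run))
      payload$run <- list(seed = run$seed, reps = run$reps,
                          distances = run$distances,
                          marker_sigma_mm = run$noise$marker_sigma,
                          pointer_extra_sigma_mm = run$noise$pointer_extra_sigma)
    jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  if (!is.null(csv_path) && !is.null(run))
    utils::write.csv(run$records, csv_path, row.names = FALSE)
  invisible(report)
}
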