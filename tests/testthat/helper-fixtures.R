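# Shared fixtures, all built in code.

# a random proper rigid transform (rotation via QR of a Gaussian matrix)
random_rigid <- function(from = "a", to = "b", t_scale = 100) {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr(M)
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rigid_transform(R, rnorm(3, 0, t_scale), from, to)
}

random_points <- function(n, scale = 100) {
  matrix(runif(3 * n, -scale, scale), n, 3)
}

# a voxelized sphere mask: radius mm, spacing mm, centered grid
sphere_mask <- function(radius = 10, spacing = 0.6, pad = 3,
                        structure = "tumour") {
  half <- radius + pad
  n <- ceiling(2 * half / spacing)
  org <- rep(-(n - 1) * spacing / 2, 3)
  g <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1))) * spacing +
    rep(org, each = n^3)
  label_mask(array(as.numeric(rowSums(g^2) <= radius^2), c(n, n, n)),
             rep(spacing, 3), org, structure)
}

# poses rotating about a fixed pivot with a given tip offset (for pivot
# calibration): orientations span a wide cone
pivot_poses <- function(n, pivot, tip_offset, t_sigma = 0) {
  lapply(seq_len(n), function(i) {
    R <- rot_z(runif(1, 0, 360)) %*% rot_y(runif(1, 5, 50)) %*%
      rot_x(runif(1, 0, 360))
    tr <- pivot - as.vector(R %*% tip_offset)
    if (t_sigma > 0) tr <- tr + rnorm(3, 0, t_sigma)
    tracked_pose("pointer", rigid_transform(R, tr, "pointer", "tracker"),
                 timestamp = i)
  })
}

# a sensor pose and matched pixel/world correspondences generated exactly
# from a known projector model
dlt_fixture <- function(model = default_projector_model(), n = 20) {
  sensor_pose <- tracked_pose(
    "projector_sensor",
    rigid_transform(rot_y(12) %*% rot_x(-20), c(80, 40, -350),
                    "sensor", "tracker"))
  T_p2t <- compose_transform(sensor_pose$transform, model$t_sensor_to_projector)
  W_proj <- cbind(runif(n, -120, 120), runif(n, -90, 90), runif(n, 250, 600))
  world <- apply_transform(T_p2t, W_proj)
  pixels <- project_point(model, sensor_pose, world)
  list(model = model, sensor_pose = sensor_pose, world = world,
       pixels = pixels, T_p2t = T_p2t)
}
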