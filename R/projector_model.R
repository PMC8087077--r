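# Pinhole model of the tracked pico-projector: DLT calibration from
# pixel <-> 3-D correspondences, point projection, and pixel-ray casting.
#
# Pixel convention: 0-based, origin at the top-left pixel center, +u right,
# +v down; the projector looks along +z of its own frame. Zero skew, no lens
# distortion (laser pico-projectors are near distortion-free at the error
# scale of interest).

#' Calibrated pinhole model of the tracked projector
#'
#' The projector is modelled as an inverse camera: a virtual camera with the
#' same intrinsics renders the scene, and the physical device emits each
#' rendered pixel along the matching ray. `t_sensor_to_projector` is the fixed
#' rigid transform between the optical-sensor attachment on the enclosure and
#' the projector's optical center (projector frame -> sensor frame); chaining
#' it with the live tracked sensor pose places the virtual camera.
#'
#' @param fu,fv focal lengths (px).
#' @param cu,cv principal point (px); must lie inside the image.
#' @param width,height image size (px).
#' @param t_sensor_to_projector `rigid_transform`, projector frame -> sensor
#'   frame.
#' @return Object of class `projector_model`.
#' @export
projector_model <- function(fu, fv, cu, cv, width, height,
                            t_sensor_to_projector) {
  stopifnot(fu > 0, fv > 0, width > 0, height > 0,
            cu >= 0, cu < width, cv >= 0, cv < height,
            inherits(t_sensor_to_projector, "rigid_transform"))
  structure(list(fu = fu, fv = fv, cu = cu, cv = cv,
                 width = as.integer(width), height = as.integer(height),
                 t_sensor_to_projector = t_sensor_to_projector),
            class = "projector_model")
}

#' @export
print.projector_model <- function(x, ...) {
  cat(sprintf("<projector_model %dx%d px, f=(%.1f, %.1f), c=(%.1f, %.1f)>\n",
              x$width, x$height, x$fu, x$fv, x$cu, x$cv))
  invisible(x)
}

#' A half-line in 3-D
#' @param origin 3-vector (mm).
#' @param direction 3-vector; normalized internally.
#' @param frame frame label.
#' @return Object of class `ray3`.
#' @export
ray3 <- function(origin, direction, frame = "tracker") {
  direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("ray3: zero-length direction")
  structure(list(origin = as.numeric(origin), direction = direction / n,
                 frame = as.character(frame)),
            class = "ray3")
}

#' An infinite plane given by a point and a normal
#' @param point 3-vector on the plane (mm).
#' @param normal 3-vector normal; normalized internally.
#' @param frame frame label.
#' @export
plane_surface <- function(point, normal, frame = "tracker") {
  normal <- as.numeric(normal)
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("plane_surface: zero-length normal")
  structure(list(point = as.numeric(point), normal = normal / n,
                 frame = as.character(frame)),
            class = "plane_surface")
}

## ---- DLT calibration -------------------------------------------------------

# RQ decomposition of a 3x3 matrix: M = K R with K upper triangular and R a
# rotation, via QR of the row/column-reversed transpose.
rq3 <- function(M) {
  P <- diag(3)[3:1, ]
  qr_res <- qr(t(P %*% M))
  Q1 <- qr.Q(qr_res)
  R1 <- qr.R(qr_res)
  K <- P %*% t(R1) %*% P
  R <- P %*% t(Q1)
  # make the intrinsic diagonal positive
  D <- diag(sign(diag(K)))
  list(K = K %*% D, R = D %*% R)
}

#' Calibrate the projector by the normalized direct linear transform
#'
#' Estimates the 3x4 projection matrix from at least 6 pixel <-> 3-D
#' correspondences (world points in the tracker frame), after isotropic
#' normalization of both pixels and points for numerical conditioning, then
#' decomposes it into pinhole intrinsics (zero skew enforced) and the
#' projector pose. The simultaneously tracked sensor pose is used to express
#' the extrinsics as the fixed sensor-to-projector mounting transform, which
#' is what makes the calibration valid at any later projector position.
#'
#' @param pixels n x 2 matrix of pixel coordinates (px).
#' @param world_points n x 3 matrix of tracker-frame points (mm).
#' @param sensor_pose `tracked_pose` of the sensor during calibration.
#' @param width,height projector image size (px).
#' @return A list: `model` (a `projector_model`) and `reprojection_rms` (px).
#' @export
dlt_calibrate <- function(pixels, world_points, sensor_pose,
                          width = 800, height = 600) {
  pixels <- as.matrix(pixels); world_points <- as.matrix(world_points)
  n <- nrow(pixels)
  if (n < 6) stop("dlt_calibrate: need at least 6 correspondences, got ", n)
  stopifnot(nrow(world_points) == n, ncol(pixels) == 2, ncol(world_points) == 3,
            inherits(sensor_pose, "tracked_pose"), sensor_pose$valid)
  # coplanarity check: smallest singular value of the centered point cloud
  ctr <- sweep(world_points, 2, colMeans(world_points))
  sv <- svd(ctr)$d
  if (sv[3] < 1e-6 * max(sv[1], 1))
    stop("dlt_calibrate: world points are coplanar; the DLT system is degenerate")

  # isotropic normalization (pixels to mean distance sqrt(2), points sqrt(3))
  cp <- colMeans(pixels)
  sp <- sqrt(2) / mean(sqrt(rowSums(sweep(pixels, 2, cp)^2)))
  Tp <- rbind(c(sp, 0, -sp * cp[1]), c(0, sp, -sp * cp[2]), c(0, 0, 1))
  cw <- colMeans(world_points)
  sw <- sqrt(3) / mean(sqrt(rowSums(ctr^2)))
  Tw <- rbind(cbind(diag(3) * sw, -sw * cw), c(0, 0, 0, 1))

  pn <- sweep(pixels, 2, cp) * sp
  wn <- ctr * sw
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- c(wn[i, ], 1)
    A[2 * i - 1, ] <- c(X, rep(0, 4), -pn[i, 1] * X)
    A[2 * i, ] <- c(rep(0, 4), X, -pn[i, 2] * X)
  }
  s <- svd(A)
  Pn <- matrix(s$v[, 12], 3, 4, byrow = TRUE)
  P <- solve(Tp) %*% Pn %*% Tw
  # sign: points must have positive depth
  depths <- P[3, ] %*% t(cbind(world_points, 1))
  if (mean(depths > 0) < 0.5) P <- -P
  M <- P[, 1:3]
  kr <- rq3(M)
  K <- kr$K / kr$K[3, 3]
  R <- kr$R
  t_ext <- as.vector(solve(kr$K, P[, 4]))
  # extrinsics map tracker -> projector; express as projector -> sensor using
  # the sensor pose recorded during calibration
  t_tracker_to_proj <- rigid_transform(R, t_ext, from = "tracker", to = "projector")
  t_proj_to_tracker <- invert_transform(t_tracker_to_proj)
  t_s2p <- compose_transform(invert_transform(sensor_pose$transform),
                             t_proj_to_tracker)
  t_s2p$from <- "projector"; t_s2p$to <- "sensor"
  model <- projector_model(fu = K[1, 1], fv = K[2, 2], cu = K[1, 3], cv = K[2, 3],
                           width = width, height = height,
                           t_sensor_to_projector = t_s2p)
  reproj <- project_point(model, sensor_pose, world_points)
  rms <- sqrt(mean(rowSums((reproj - pixels)^2)))
  list(model = model, reprojection_rms = rms)
}

## ---- projection and ray casting --------------------------------------------

tracker_to_projector <- function(model, pose) {
  stopifnot(inherits(pose, "tracked_pose"))
  if (!pose$valid) stop("projector pose is invalid (tool not tracked)")
  # the tracked tool IS the sensor attachment: adopt its frame label so the
  # chain tracker -> sensor -> projector composes regardless of tool id
  ps <- pose$transform
  ps$from <- model$t_sensor_to_projector$to
  compose_transform(invert_transform(model$t_sensor_to_projector),
                    invert_transform(ps))
}

#' Project tracker-frame points into the projector image
#'
#' Chains world (tracker) -> sensor -> projector and applies the pinhole
#' mapping `u = fu x/z + cu`, `v = fv y/z + cv`. Points must lie in front of
#' the projector (positive depth).
#'
#' @param model `projector_model`.
#' @param pose valid `tracked_pose` of the projector's sensor.
#' @param world_points 3-vector or n x 3 matrix (mm, tracker frame).
#' @return 2-vector or n x 2 matrix of pixel coordinates.
#' @export
project_point <- function(model, pose, world_points) {
  vec <- is.null(dim(world_points))
  T <- tracker_to_projector(model, pose)
  p <- apply_transform(T, world_points)
  if (vec) p <- matrix(p, 1, 3)
  if (any(p[, 3] <= 0))
    stop("project_point: point at or behind the projector (non-positive depth)")
  out <- cbind(model$fu * p[, 1] / p[, 3] + model$cu,
               model$fv * p[, 2] / p[, 3] + model$cv)
  if (vec) as.vector(out) else out
}

#' Cast the ray a pixel is emitted along
#'
#' @param model `projector_model`.
#' @param pose valid `tracked_pose` of the projector's sensor.
#' @param pixel 2-vector (px), within the image bounds.
#' @return A `ray3` in the tracker frame through the projector center.
#' @export
cast_ray <- function(model, pose, pixel) {
  pixel <- as.numeric(pixel)
  if (pixel[1] < -0.5 || pixel[1] > model$width - 0.5 ||
      pixel[2] < -0.5 || pixel[2] > model$height - 0.5)
    stop("cast_ray: pixel outside the image bounds")
  d_proj <- c((pixel[1] - model$cu) / model$fu,
              (pixel[2] - model$cv) / model$fv, 1)
  T <- invert_transform(tracker_to_projector(model, pose)) # projector -> tracker
  ray3(origin = apply_transform(T, c(0, 0, 0)),
       direction = as.vector(T$rotation %*% d_proj),
       frame = "tracker")
}

#' Intersect a ray with a plane or triangle mesh
#'
#' For a plane the closed-form line-plane solution is used; rays parallel to
#' the plane or hitting it behind the origin are an error. For a mesh,
#' Moeller-Trumbore intersection is evaluated for every triangle and the
#' nearest positive hit returned.
#'
#' @param ray `ray3`.
#' @param surface `plane_surface` or `surface_mesh`.
#' @return 3-vector intersection point (mm).
#' @export
intersect_ray <- function(ray, surface) {
  stopifnot(inherits(ray, "ray3"))
  if (inherits(surface, "plane_surface")) {
    denom <- sum(ray$direction * surface$normal)
    if (abs(denom) < 1e-9)
      stop("intersect_ray: ray is parallel to the plane")
    tt <- sum((surface$point - ray$origin) * surface$normal) / denom
    if (tt <= 0) stop("intersect_ray: plane is behind the ray origin")
    return(ray$origin + tt * ray$direction)
  }
  if (inherits(surface, "surface_mesh")) {
    V <- surface$vertices; Tr <- surface$triangles
    if (nrow(Tr) == 0) stop("intersect_ray: empty mesh")
    v0 <- V[Tr[, 1], , drop = FALSE]
    e1 <- V[Tr[, 2], , drop = FALSE] - v0
    e2 <- V[Tr[, 3], , drop = FALSE] - v0
    d <- ray$direction
    h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
               d[3] * e2[, 1] - d[1] * e2[, 3],
               d[1] * e2[, 2] - d[2] * e2[, 1])
    a <- rowSums(e1 * h)
    ok <- abs(a) > 1e-12
    s <- sweep(-v0, 2, ray$origin, "+")
    u <- rowSums(s * h) / a
    q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
               s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
               s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
    v <- (q %*% d)[, 1] / a
    tt <- rowSums(q * e2) / a
    hit <- ok & u >= -1e-12 & v >= -1e-12 & (u + v) <= 1 + 1e-12 & tt > 1e-9
    if (!any(hit)) stop("intersect_ray: ray does not hit the mesh")
    tbest <- min(tt[hit])
    return(ray$origin + tbest * ray$direction)
  }
  stop("intersect_ray: unsupported surface type")
}

#' Read / write a projector model as JSON
#' @param model `projector_model`.
#' @param path JSON path.
#' @export
write_projector_json <- function(model, path) {
  jsonlite::write_json(list(
    fu = model$fu, fv = model$fv, cu = model$cu, cv = model$cv,
    width = model$width, height = model$height,
    t_sensor_to_projector = list(
      rotation = model$t_sensor_to_projector$rotation,
      translation = model$t_sensor_to_projector$translation,
      from = model$t_sensor_to_projector$from,
      to = model$t_sensor_to_projector$to)),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_projector_json
#' @export
read_projector_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- j$t_sensor_to_projector$rotation
  if (!is.matrix(R)) R <- matrix(unlist(R), 3, 3, byrow = TRUE)
  tf <- rigid_transform(R, j$t_sensor_to_projector$translation,
                        j$t_sensor_to_projector$from, j$t_sensor_to_projector$to)
  projector_model(j$fu, j$fv, j$cu, j$cv, j$width, j$height, tf)
}

#' A reference projector model for simulation studies
#'
#' An 800 x 600 px pinhole with 1000 px focal length (about 44 degrees
#' horizontal throw) and a plausible sensor-mount offset; used as the ground
#' truth device in simulated studies and as a convenient default elsewhere.
#' @return `projector_model`.
#' @export
default_projector_model <- function() {
  mount <- rigid_transform(rot_x(8) %*% rot_y(-5), c(30, 20, -40),
                           from = "projector", to = "sensor")
  projector_model(fu = 1000, fv = 1000, cu = 400, cv = 300,
                  width = 800, height = 600, t_sensor_to_projector = mount)
}
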