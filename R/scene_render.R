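# The AR "virtual camera": software rasterization of surgical-plan content
# (meshes, fused slices, point markers) into the projector framebuffer from
# the tracked projector pose; pointer-driven slice scrolling; safety-margin
# proximity alerts.
#
# Flat colors only (the overlays are flat-colored contours and slices);
# z-buffered rasterization at projector resolution; semi-transparent
# structures composited back-to-front by centroid depth, slices first.

#' A surgical plan: structures to overlay plus an optional fused slice
#'
#' @param structures list of entries `list(geometry =, role =, color =,
#'   opacity =)` where `geometry` is a `surface_mesh` (meshes with zero
#'   triangles are rendered as point markers), `role` is one of `"target"`,
#'   `"margin"`, `"critical"`, `"bone"`, `color` is an RGB triple in \[0,1\]
#'   and `opacity` is in \[0,1\].
#' @param slice_display optional list `list(anat =, func =, axis =, index =,
#'   alpha =, colormap =, opacity =)` describing a fused slice quad placed at
#'   its true world position (see [fuse_slice()]).
#' @return Object of class `surgical_plan`.
#' @export
surgical_plan <- function(structures = list(), slice_display = NULL) {
  roles <- c("target", "margin", "critical", "bone")
  for (s in structures) {
    stopifnot(inherits(s$geometry, "surface_mesh"))
    if (!s$role %in% roles)
      stop("surgical_plan: unknown role '", s$role, "'")
    stopifnot(length(s$color) == 3, all(s$color >= 0 & s$color <= 1),
              s$opacity >= 0, s$opacity <= 1)
  }
  structure(list(structures = structures, slice_display = slice_display),
            class = "surgical_plan")
}

# perspective-correct triangle rasterization into fb/zbuf (environments are
# avoided by returning updated buffers)
rasterize_triangle <- function(img, zbuf, px, z, color, opacity,
                               tex = NULL, uv = NULL) {
  w <- dim(img)[2]; h <- dim(img)[1]
  if (any(z <= 1e-9)) return(list(img = img, zbuf = zbuf)) # behind projector
  xmin <- max(0L, floor(min(px[, 1]))); xmax <- min(w - 1L, ceiling(max(px[, 1])))
  ymin <- max(0L, floor(min(px[, 2]))); ymax <- min(h - 1L, ceiling(max(px[, 2])))
  if (xmin > xmax || ymin > ymax) return(list(img = img, zbuf = zbuf))
  xs <- xmin:xmax; ys <- ymin:ymax
  PX <- rep(xs, times = length(ys)); PY <- rep(ys, each = length(xs))
  d <- (px[2, 2] - px[3, 2]) * (px[1, 1] - px[3, 1]) +
    (px[3, 1] - px[2, 1]) * (px[1, 2] - px[3, 2])
  if (abs(d) < 1e-12) return(list(img = img, zbuf = zbuf))
  l1 <- ((px[2, 2] - px[3, 2]) * (PX - px[3, 1]) +
           (px[3, 1] - px[2, 1]) * (PY - px[3, 2])) / d
  l2 <- ((px[3, 2] - px[1, 2]) * (PX - px[3, 1]) +
           (px[1, 1] - px[3, 1]) * (PY - px[3, 2])) / d
  l3 <- 1 - l1 - l2
  eps <- -1e-9
  inside <- l1 >= eps & l2 >= eps & l3 >= eps
  if (!any(inside)) return(list(img = img, zbuf = zbuf))
  l1 <- l1[inside]; l2 <- l2[inside]; l3 <- l3[inside]
  PX <- PX[inside]; PY <- PY[inside]
  izs <- l1 / z[1] + l2 / z[2] + l3 / z[3]
  zp <- 1 / izs
  rows <- PY + 1L; cols <- PX + 1L
  lin <- rows + (cols - 1L) * h
  zcur <- zbuf[lin]
  vis <- zp <= zcur + 1e-9
  if (!any(vis)) return(list(img = img, zbuf = zbuf))
  lin <- lin[vis]; zp <- zp[vis]
  if (is.null(tex)) {
    rgb <- matrix(color, sum(vis), 3, byrow = TRUE)
  } else {
    # perspective-correct texture lookup (nearest texel)
    u <- (l1 * uv[1, 1] / z[1] + l2 * uv[2, 1] / z[2] + l3 * uv[3, 1] / z[3])[vis] * zp
    v <- (l1 * uv[1, 2] / z[1] + l2 * uv[2, 2] / z[2] + l3 * uv[3, 2] / z[3])[vis] * zp
    ti <- pmin(pmax(round(u * (dim(tex)[1] - 1)), 0), dim(tex)[1] - 1) + 1
    tj <- pmin(pmax(round(v * (dim(tex)[2] - 1)), 0), dim(tex)[2] - 1) + 1
    rgb <- cbind(tex[, , 1][cbind(ti, tj)], tex[, , 2][cbind(ti, tj)],
                 tex[, , 3][cbind(ti, tj)])
  }
  npx <- h * w
  for (ch in 1:3) {
    off <- (ch - 1L) * npx
    img[lin + off] <- (1 - opacity) * img[lin + off] + opacity * rgb[, ch]
  }
  zbuf[lin] <- pmin(zbuf[lin], zp)
  list(img = img, zbuf = zbuf)
}

#' Render the surgical plan into the projector framebuffer
#'
#' Implements the virtual camera: plan content is mapped image frame ->
#' tracker frame (via the registration transform) -> projector frame (via
#' the tracked pose and calibrated mounting transform), then rasterized with
#' z-buffering. The fused slice quad is drawn first at its true world
#' position; mesh structures follow back-to-front by centroid depth with
#' alpha compositing. Meshes without triangles are drawn as point markers
#' (one pixel each); their continuous (sub-pixel) image coordinates are kept
#' in the result for quantitative use.
#'
#' @param plan `surgical_plan`.
#' @param model `projector_model`.
#' @param projector_pose valid `tracked_pose` of the projector sensor.
#' @param registration `rigid_transform` mapping image frame -> tracker frame.
#' @param background RGB background triple (default black).
#' @return Object of class `framebuffer`: `image` (height x width x 3 array
#'   in \[0,1\]), `zbuffer`, and `point_pixels` (continuous pixel coordinates
#'   of rendered point markers, one row per point, with structure index).
#' @export
render_scene <- function(plan, model, projector_pose, registration,
                         background = c(0, 0, 0)) {
  stopifnot(inherits(plan, "surgical_plan"),
            inherits(model, "projector_model"),
            inherits(projector_pose, "tracked_pose"),
            inherits(registration, "rigid_transform"))
  if (!projector_pose$valid)
    stop("render_scene: projector pose is invalid (tool not tracked)")
  w <- model$width; h <- model$height
  img <- array(rep(background, each = h * w), c(h, w, 3))
  zbuf <- matrix(Inf, h, w)
  T_img_to_proj <- compose_transform(
    tracker_to_projector(model, projector_pose), registration)

  to_pixels <- function(p_proj) {
    cbind(model$fu * p_proj[, 1] / p_proj[, 3] + model$cu,
          model$fv * p_proj[, 2] / p_proj[, 3] + model$cv)
  }

  # slice quad first
  if (!is.null(plan$slice_display)) {
    sd <- plan$slice_display
    tex <- fuse_slice(sd$anat, sd$func, sd$axis, sd$index,
                      alpha = if (is.null(sd$alpha)) 0.5 else sd$alpha,
                      colormap = if (is.null(sd$colormap)) "hot" else sd$colormap)
    ax <- attr(tex, "axis")
    inplane <- setdiff(1:3, ax)
    dvol <- dim(sd$anat$data)
    # world-space quad corners of the slice (voxel-center extents)
    corner <- function(i1, i2) {
      idx <- numeric(3)
      idx[ax] <- attr(tex, "index")
      idx[inplane[1]] <- i1 * (dvol[inplane[1]] - 1)
      idx[inplane[2]] <- i2 * (dvol[inplane[2]] - 1)
      sd$anat$origin + idx * sd$anat$spacing
    }
    quad <- rbind(corner(0, 0), corner(1, 0), corner(1, 1), corner(0, 1))
    uvq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    p_proj <- apply_transform(T_img_to_proj, quad)
    if (all(p_proj[, 3] > 0)) {
      px <- to_pixels(p_proj)
      op <- if (is.null(sd$opacity)) 1 else sd$opacity
      for (tri in list(c(1, 2, 3), c(1, 3, 4))) {
        res <- rasterize_triangle(img, zbuf, px[tri, ], p_proj[tri, 3],
                                  color = NULL, opacity = op,
                                  tex = tex, uv = uvq[tri, ])
        img <- res$img; zbuf <- res$zbuf
      }
    }
  }

  point_pixels <- NULL
  if (length(plan$structures) > 0) {
    # back-to-front by centroid depth
    depths <- vapply(plan$structures, function(s) {
      mean(apply_transform(T_img_to_proj, s$geometry$vertices)[, 3])
    }, numeric(1))
    for (si in order(-depths)) {
      s <- plan$structures[[si]]
      p_proj <- apply_transform(T_img_to_proj, s$geometry$vertices)
      if (nrow(s$geometry$triangles) == 0) {
        ok <- p_proj[, 3] > 0
        if (!any(ok)) next
        px <- to_pixels(p_proj[ok, , drop = FALSE])
        point_pixels <- rbind(point_pixels,
                              cbind(structure_index = si, u = px[, 1],
                                    v = px[, 2], z = p_proj[ok, 3]))
        pc <- round(px)
        keep <- pc[, 1] >= 0 & pc[, 1] <= w - 1 & pc[, 2] >= 0 &
          pc[, 2] <= h - 1
        if (!any(keep)) next
        lin <- (pc[keep, 2] + 1L) + pc[keep, 1] * h
        zv <- p_proj[ok, 3][keep]
        vis <- zv <= zbuf[lin] + 1e-9
        lin <- lin[vis]
        npx <- h * w
        for (ch in 1:3) {
          off <- (ch - 1L) * npx
          img[lin + off] <- (1 - s$opacity) * img[lin + off] +
            s$opacity * s$color[ch]
        }
        zbuf[lin] <- pmin(zbuf[lin], zv[vis])
      } else {
        px_all <- to_pixels(p_proj)
        for (ti in seq_len(nrow(s$geometry$triangles))) {
          id <- s$geometry$triangles[ti, ]
          res <- rasterize_triangle(img, zbuf, px_all[id, , drop = FALSE],
                                    p_proj[id, 3], color = s$color,
                                    opacity = s$opacity)
          img <- res$img; zbuf <- res$zbuf
        }
      }
    }
  }
  structure(list(image = img, zbuffer = zbuf, width = w, height = h,
                 background = background, point_pixels = point_pixels),
            class = "framebuffer")
}

#' @export
print.framebuffer <- function(x, ...) {
  lit <- sum(x$zbuffer < Inf)
  cat(sprintf("<framebuffer %dx%d px, %d lit pixels>\n", x$width, x$height, lit))
  invisible(x)
}

#' Write a framebuffer as PNG
#' @param fb `framebuffer` from [render_scene()].
#' @param path output path.
#' @export
write_framebuffer_png <- function(fb, path) {
  write_rgb_png(fb$image, path)
  invisible(path)
}

#' Slice index under the tracked pointer
#'
#' Maps the pointer tip from the tracker frame into the image frame and
#' returns the 0-based slice index along the chosen axis (nearest voxel
#' plane), the mechanism behind pointer-driven scrolling through the
#' projected image stack.
#'
#' @param registration `rigid_transform`, image frame -> tracker frame.
#' @param volume `volume_image`.
#' @param tip 3-vector (mm, tracker frame).
#' @param axis slice axis (1/2/3 or "sagittal"/"coronal"/"axial").
#' @param clamp if TRUE, out-of-bounds tips are clamped to the first/last
#'   slice instead of raising an error.
#' @return Integer 0-based slice index.
#' @export
pointer_to_slice <- function(registration, volume, tip, axis = "coronal",
                             clamp = FALSE) {
  stopifnot(inherits(volume, "volume_image"))
  ax <- slice_axis_index(axis)
  p_img <- apply_transform(invert_transform(registration), tip)
  idx <- round((p_img[ax] - volume$origin[ax]) / volume$spacing[ax])
  nmax <- dim(volume$data)[ax] - 1
  if (idx < 0 || idx > nmax) {
    if (!clamp)
      stop("pointer_to_slice: tip outside volume (slice ", idx,
           ", valid 0..", nmax, "); use clamp = TRUE to clamp")
    idx <- min(max(idx, 0), nmax)
  }
  as.integer(idx)
}

#' Safety-margin proximity alert
#'
#' Reports whether the tracked instrument tip is inside the safety-margin
#' volume and its Euclidean distance to the margin (0 when inside; otherwise
#' the distance to the nearest margin voxel center).
#'
#' @param tip 3-vector (mm, tracker frame).
#' @param margin `label_mask` of the safety-margin volume.
#' @param registration `rigid_transform`, image frame -> tracker frame.
#' @return List `inside` (logical) and `distance_to_margin` (mm).
#' @export
proximity_alert <- function(tip, margin, registration) {
  stopifnot(inherits(margin, "label_mask"))
  idx_on <- which(margin$data == 1, arr.ind = TRUE)
  if (nrow(idx_on) == 0) stop("proximity_alert: empty margin mask")
  p_img <- apply_transform(invert_transform(registration), tip)
  vox <- round(world_to_index(margin, p_img))
  d <- dim(margin$data)
  inside <- all(vox >= 0) && all(vox <= d - 1) &&
    margin$data[matrix(vox + 1, 1)] == 1
  if (inside) return(list(inside = TRUE, distance_to_margin = 0))
  centers <- index_to_world(margin, idx_on - 1)
  dist <- sqrt(min(rowSums(sweep(centers, 2, p_img)^2)))
  list(inside = FALSE, distance_to_margin = dist)
}
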