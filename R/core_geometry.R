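# Rigid 3-D transforms, tracked poses, and frame chaining.
#
# Conventions (package-wide): right-handed frames, all lengths in mm, the
# optical-tracker frame is the world frame. Transforms are stored child ->
# parent (tool -> tracker, image -> tracker), matching how optical trackers
# report tool poses. Rotations are 3x3 matrices internally; quaternions appear
# only at I/O boundaries (pose-stream CSV) and are normalized on entry.

ORTHO_TOL <- 1e-9

#' Rigid 3-D transform between two named frames
#'
#' A proper rigid transform `p_to = R %*% p_from + t` with all lengths in mm.
#' The rotation must be orthonormal with determinant +1 (no reflections).
#'
#' @param rotation 3x3 orthonormal rotation matrix (dimensionless).
#' @param translation numeric length-3 translation (mm).
#' @param from,to frame labels (character scalars), e.g. `"image"`,
#'   `"tracker"`. The transform maps coordinates expressed in `from` into
#'   coordinates expressed in `to`.
#' @return An object of class `rigid_transform` with fields `rotation`,
#'   `translation`, `from`, `to`.
#' @examples
#' Tz <- rigid_transform(rot_z(90), c(10, 0, 0), "tool", "tracker")
#' apply_transform(Tz, c(1, 0, 0)) # (10, 1, 0)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            from = "a", to = "b") {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite rotation or translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rigid_transform: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rigid_transform: rotation determinant is not +1 (reflection?)")
  structure(list(rotation = rotation, translation = translation,
                 from = as.character(from), to = as.character(to)),
            class = "rigid_transform")
}

#' Identity transform between two frames
#' @param from,to frame labels.
#' @return A `rigid_transform` with identity rotation and zero translation.
#' @export
identity_transform <- function(from = "a", to = from) {
  rigid_transform(diag(3), c(0, 0, 0), from, to)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s -> %s>\n", x$from, x$to))
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(c("x", "y", "z"), c("r1", "r2", "r3", "t_mm"))
  print(round(m, 6))
  invisible(x)
}

#' Elementary rotations (degrees)
#'
#' Right-handed rotations about the coordinate axes.
#' @param deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Compose two rigid transforms
#'
#' Returns the transform that first applies `b`, then `a`; frames must chain
#' (`b` lands in the frame `a` starts from).
#'
#' @param a,b `rigid_transform` objects with `a$from == b$to`.
#' @return `rigid_transform` mapping `b$from -> a$to`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (!identical(a$from, b$to))
    stop(sprintf("compose_transform: frame mismatch: a maps %s->%s but b maps %s->%s",
                 a$from, a$to, b$from, b$to))
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation,
                  b$from, a$to)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse transform, with `from` and `to` swapped.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% t$translation), t$to, t$from)
}

#' Apply a rigid transform to 3-D points
#'
#' @param t a `rigid_transform`.
#' @param points length-3 vector or n x 3 matrix of points (mm), expressed in
#'   `t$from`.
#' @return Points in `t$to`, same shape as the input.
#' @export
apply_transform <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  if (ncol(p) != 3) stop("apply_transform: points must be length 3 or n x 3")
  if (!all(is.finite(p))) stop("apply_transform: non-finite points")
  out <- p %*% t(t$rotation)
  out <- sweep(out, 2, t$translation, "+")
  if (vec) as.vector(out) else out
}

## ---- quaternions (scalar-first, unit) --------------------------------------

#' Convert a unit quaternion to a rotation matrix
#'
#' Scalar-first convention `(qw, qx, qy, qz)`. The quaternion is normalized;
#' deviations from unit length beyond 1e-6 are an error (corrupt pose record).
#' @param q numeric length 4.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotation <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4)
  n <- sqrt(sum(q^2))
  if (!is.finite(n) || abs(n - 1) > 1e-3)
    stop("quat_to_rotation: quaternion is not close to unit length")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Convert a rotation matrix to a unit quaternion
#' @param R 3x3 rotation matrix.
#' @return numeric length 4 `(qw, qx, qy, qz)` with `qw >= 0`.
#' @export
rotation_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

## ---- poses -----------------------------------------------------------------

#' A tracked-tool pose at one instant
#'
#' @param tool_id tool label.
#' @param transform `rigid_transform` mapping tool frame -> tracker frame.
#' @param timestamp time in seconds.
#' @param valid logical; `FALSE` when the tracker lost the tool (fewer than 3
#'   markers visible). Invalid poses carry no usable transform.
#' @return Object of class `tracked_pose`.
#' @export
tracked_pose <- function(tool_id, transform, timestamp = 0, valid = TRUE) {
  if (valid) stopifnot(inherits(transform, "rigid_transform"))
  structure(list(tool_id = as.character(tool_id), transform = transform,
                 timestamp = as.numeric(timestamp), valid = isTRUE(valid)),
            class = "tracked_pose")
}

#' @export
print.tracked_pose <- function(x, ...) {
  cat(sprintf("<tracked_pose tool=%s t=%.3fs valid=%s>\n",
              x$tool_id, x$timestamp, x$valid))
  if (x$valid) print(x$transform)
  invisible(x)
}

#' Read / write a pose-stream CSV
#'
#' Columns `timestamp,tool_id,qw,qx,qy,qz,tx,ty,tz,valid` (mm, scalar-first
#' unit quaternion, `valid` in \{0,1\}). Invalid rows keep their numeric
#' placeholders but yield poses with `valid = FALSE`.
#'
#' @param path CSV file path.
#' @param tracker_frame frame label to assign as the parent (`to`) frame.
#' @return A list of `tracked_pose` objects.
#' @export
read_pose_stream <- function(path, tracker_frame = "tracker") {
  if (!file.exists(path)) stop("read_pose_stream: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "tool_id", "qw", "qx", "qy", "qz", "tx", "ty", "tz", "valid")
  if (!all(need %in% names(df)))
    stop("read_pose_stream: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    ok <- df$valid[i] == 1
    tf <- if (ok) {
      rigid_transform(quat_to_rotation(c(df$qw[i], df$qx[i], df$qy[i], df$qz[i])),
                      c(df$tx[i], df$ty[i], df$tz[i]),
                      from = df$tool_id[i], to = tracker_frame)
    } else NULL
    tracked_pose(df$tool_id[i], tf, df$timestamp[i], ok)
  })
}

#' @rdname read_pose_stream
#' @param poses list of `tracked_pose` objects.
#' @export
write_pose_stream <- function(poses, path) {
  rows <- lapply(poses, function(p) {
    if (p$valid) {
      q <- rotation_to_quat(p$transform$rotation)
      tr <- p$transform$translation
    } else {
      q <- c(1, 0, 0, 0); tr <- c(0, 0, 0)
    }
    data.frame(timestamp = p$timestamp, tool_id = p$tool_id,
               qw = q[1], qx = q[2], qy = q[3], qz = q[4],
               tx = tr[1], ty = tr[2], tz = tr[3],
               valid = as.integer(p$valid))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Transform JSON serialization
#'
#' Writes/reads a transform as row-major 3x3 rotation + translation + frames.
#' @param t `rigid_transform` to write.
#' @param path JSON file path.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  jsonlite::write_json(list(rotation = t$rotation, translation = t$translation,
                            from = t$from, to = t$to),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- j$rotation
  if (!is.matrix(R)) R <- matrix(unlist(R), 3, 3, byrow = TRUE)
  rigid_transform(R, j$translation, j$from, j$to)
}
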