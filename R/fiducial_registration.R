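# Paired-point rigid registration (image -> tracker), FRE, and pivot
# calibration of the tracked pointer tip.

#' A labelled set of fiducial points in one frame
#'
#' Fiducials are physical landmarks identifiable both in the image volume and
#' on the subject; pairing them across frames drives rigid registration.
#' At least 3 non-collinear points are required (collinearity is tested on the
#' smallest singular value of the centered point matrix).
#'
#' @param labels character vector of fiducial labels.
#' @param points n x 3 matrix of coordinates (mm).
#' @param frame frame label the coordinates are expressed in.
#' @return Object of class `fiducial_set`.
#' @export
fiducial_set <- function(labels, points, frame) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, length(labels) == nrow(points))
  if (nrow(points) < 3) stop("fiducial_set: need at least 3 fiducials")
  if (!all(is.finite(points))) stop("fiducial_set: non-finite coordinates")
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr)$d
  if (sv[2] <= 1e-6)
    stop("fiducial_set: points are collinear (degenerate geometry)")
  structure(list(labels = as.character(labels), points = points,
                 frame = as.character(frame)),
            class = "fiducial_set")
}

#' Read / write a fiducial CSV (`label,x_mm,y_mm,z_mm,frame`)
#' @param path CSV path.
#' @return `fiducial_set` (the frame is taken from the file's first row).
#' @export
read_fiducials <- function(path) {
  if (!file.exists(path)) stop("read_fiducials: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm", "frame")
  if (!all(need %in% names(df)))
    stop("read_fiducials: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  fiducial_set(df$label, cbind(df$x_mm, df$y_mm, df$z_mm), df$frame[1])
}

#' @rdname read_fiducials
#' @param fids `fiducial_set` to write.
#' @export
write_fiducials <- function(fids, path) {
  df <- data.frame(label = fids$labels, x_mm = fids$points[, 1],
                   y_mm = fids$points[, 2], z_mm = fids$points[, 3],
                   frame = fids$frame)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

check_paired <- function(moving, fixed, what) {
  stopifnot(inherits(moving, "fiducial_set"), inherits(fixed, "fiducial_set"))
  if (nrow(moving$points) != nrow(fixed$points))
    stop(what, ": point counts differ (", nrow(moving$points), " vs ",
         nrow(fixed$points), ")")
  if (!identical(moving$labels, fixed$labels))
    stop(what, ": fiducial labels do not match between sets")
}

#' Paired-point rigid registration
#'
#' Least-squares rigid fit of `moving` onto `fixed` (matched by label order)
#' using centroid subtraction and SVD of the cross-covariance, with a
#' determinant sign correction so that a proper rotation (no reflection) is
#' always returned. This is the standard closed-form solution for landmark
#' registration of image space to tracker space.
#'
#' @param moving,fixed `fiducial_set` objects with identical labels in the
#'   same order (correspondence is by label order; no automatic matching).
#' @return Object of class `registration_result`: `transform` (a
#'   `rigid_transform` moving-frame -> fixed-frame), `fre` (root-mean-square
#'   residual, mm) and per-fiducial `residuals` (mm).
#' @examples
#' m <- fiducial_set(letters[1:4],
#'                   rbind(c(0,0,0), c(10,0,0), c(0,10,0), c(0,0,10)), "image")
#' f <- fiducial_set(letters[1:4],
#'                   apply_transform(rigid_transform(rot_z(90), c(5,-2,3),
#'                                                   "image", "tracker"),
#'                                   m$points), "tracker")
#' rigid_register(m, f)$fre # ~0
#' @export
rigid_register <- function(moving, fixed) {
  check_paired(moving, fixed, "rigid_register")
  A <- moving$points; B <- fixed$points
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cb - as.vector(R %*% ca)
  tf <- rigid_transform(R, tr, from = moving$frame, to = fixed$frame)
  res <- sqrt(rowSums((apply_transform(tf, A) - B)^2))
  structure(list(transform = tf, fre = sqrt(mean(res^2)), residuals = res),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result FRE = %.4f mm over %d fiducials>\n",
              x$fre, length(x$residuals)))
  print(x$transform)
  invisible(x)
}

#' Fiducial registration error of a given transform
#'
#' FRE = sqrt(mean_i ||T m_i - f_i||^2), the RMS residual distance between
#' paired fiducials after applying the registration transform.
#'
#' @param transform `rigid_transform` mapping the moving frame to the fixed.
#' @param moving,fixed matched `fiducial_set` objects.
#' @return FRE in mm.
#' @export
compute_fre <- function(transform, moving, fixed) {
  check_paired(moving, fixed, "compute_fre")
  res2 <- rowSums((apply_transform(transform, moving$points) - fixed$points)^2)
  sqrt(mean(res2))
}

#' Pivot calibration of a tracked pointer tip
#'
#' The pointer pivots about a fixed physical point while the tracker records
#' tool poses; the tip offset `p_tip` (tool frame) and the pivot point
#' `p_pivot` (tracker frame) jointly satisfy `R_k p_tip + t_k = p_pivot` for
#' every pose k. Both are solved in one linear least-squares system
#' `[R_k | -I] (p_tip; p_pivot) = -t_k`.
#'
#' @param poses list of `tracked_pose` objects (invalid poses are dropped);
#'   at least 10 valid poses spanning a sufficient range of orientations.
#' @return Object of class `pivot_result`: `tip_offset` (mm, tool frame),
#'   `pivot_point` (mm, tracker frame) and `rms_residual` (mm).
#' @export
pivot_calibrate <- function(poses) {
  poses <- Filter(function(p) p$valid, poses)
  n <- length(poses)
  if (n < 10) stop("pivot_calibrate: need at least 10 valid poses, got ", n)
  A <- matrix(0, 3 * n, 6)
  b <- numeric(3 * n)
  for (k in seq_len(n)) {
    i <- (3 * k - 2):(3 * k)
    A[i, 1:3] <- poses[[k]]$transform$rotation
    A[i, 4:6] <- -diag(3)
    b[i] <- -poses[[k]]$transform$translation
  }
  sv <- svd(A)
  if (sv$d[1] / sv$d[6] > 1e6)
    stop("pivot_calibrate: insufficient orientation variation (degenerate system)")
  x <- sv$v %*% (crossprod(sv$u, b) / sv$d)
  resid <- A %*% x - b
  rms <- sqrt(mean(colSums(matrix(resid^2, 3))))
  structure(list(tip_offset = as.vector(x[1:3]), pivot_point = as.vector(x[4:6]),
                 rms_residual = rms),
            class = "pivot_result")
}

#' @export
print.pivot_result <- function(x, ...) {
  cat(sprintf("<pivot_result tip=(%.3f, %.3f, %.3f) mm, rms=%.4f mm>\n",
              x$tip_offset[1], x$tip_offset[2], x$tip_offset[3], x$rms_residual))
  invisible(x)
}
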