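# Volume image handling: NIfTI I/O, trilinear resampling, threshold
# segmentation, iso-surface extraction, multimodality slice fusion, NMI rigid
# registration, and the synthetic multimodality subject generator.
#
# World mapping is axis-aligned: world = origin + spacing * index with
# 0-based indices and origin at the center of voxel (0,0,0). Oblique NIfTI
# direction matrices are rejected with a clear error.

#' A gridded 3-D scalar image
#'
#' @param data 3-D numeric array (nx, ny, nz).
#' @param spacing length-3 voxel spacing (mm), strictly positive.
#' @param origin length-3 world coordinate (mm) of the center of voxel
#'   (0,0,0).
#' @param modality one of `"CT"`, `"PET"`, `"MRI"`, `"SPECT"`, `"synthetic"`.
#' @return Object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = "synthetic") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("volume_image: spacing must be positive")
  if (!all(is.finite(data))) stop("volume_image: non-finite voxel data")
  modality <- match.arg(modality, c("CT", "PET", "MRI", "SPECT", "synthetic"))
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image %s %dx%dx%d, spacing (%.3g, %.3g, %.3g) mm>\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' A binary structure mask aligned with a volume
#'
#' @param data 3-D array with values in \{0, 1\}.
#' @param spacing,origin grid geometry, as in [volume_image()].
#' @param structure one of `"tumour"`, `"bone"`, `"margin"`, `"critical"`.
#' @return Object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       structure = "tumour") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(data %in% c(0, 1))) stop("label_mask: values must be 0 or 1")
  structure_lbl <- match.arg(structure, c("tumour", "bone", "margin", "critical"))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), structure = structure_lbl),
            class = "label_mask")
}

# world <-> 0-based voxel index (continuous)
world_to_index <- function(geom, pts) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1, 3) else as.matrix(pts)
  out <- sweep(sweep(p, 2, geom$origin), 2, geom$spacing, "/")
  if (vec) as.vector(out) else out
}

index_to_world <- function(geom, idx) {
  vec <- is.null(dim(idx))
  p <- if (vec) matrix(idx, 1, 3) else as.matrix(idx)
  out <- sweep(sweep(p, 2, geom$spacing, "*"), 2, geom$origin, "+")
  if (vec) as.vector(out) else out
}

## ---- NIfTI I/O -------------------------------------------------------------

#' Read / write a volume as NIfTI-1
#'
#' Round trips preserve data, spacing, and origin exactly for float64 data.
#' Only axis-aligned geometries (diagonal direction matrix with positive
#' scales) are supported; oblique volumes are rejected.
#'
#' @param path `.nii` or `.nii.gz` path.
#' @param modality modality label to attach on read.
#' @return [read_volume()] returns a `volume_image`.
#' @export
read_volume <- function(path, modality = "synthetic") {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("read_volume: expected a 3-D volume, got ",
                           length(d), "-D")
  x <- RNifti::xform(img)
  if (attr(x, "code") > 0) {
    M <- x[1:3, 1:3]
    if (max(abs(M - diag(diag(M)))) > 1e-6 || any(diag(M) <= 0))
      stop("read_volume: only axis-aligned volumes with positive spacing ",
           "are supported (oblique direction matrix found)")
    spacing <- diag(M); origin <- x[1:3, 4]
  } else {
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- c(0, 0, 0)
  }
  volume_image(array(as.numeric(img), dim = d), spacing, origin, modality)
}

#' @rdname read_volume
#' @param volume `volume_image` or `label_mask` to write.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image") || inherits(volume, "label_mask"))
  img <- RNifti::asNifti(volume$data, datatype = "double",
                         pixdim = volume$spacing)
  m <- diag(4)
  m[1, 1] <- volume$spacing[1]; m[2, 2] <- volume$spacing[2]
  m[3, 3] <- volume$spacing[3]; m[1:3, 4] <- volume$origin
  RNifti::sform(img) <- base::structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask stored as NIfTI
#' @param path NIfTI path.
#' @param structure structure label, as in [label_mask()].
#' @export
read_mask <- function(path, structure = "tumour") {
  v <- read_volume(path)
  label_mask(array(as.numeric(v$data > 0.5), dim(v$data)),
             v$spacing, v$origin, structure)
}

## ---- resampling ------------------------------------------------------------

# Trilinear interpolation of `arr` at fractional 0-based voxel coords (n x 3),
# with edge clamping.
interp_trilinear <- function(arr, idx) {
  d <- dim(arr)
  ix <- pmin(pmax(idx[, 1], 0), d[1] - 1)
  iy <- pmin(pmax(idx[, 2], 0), d[2] - 1)
  iz <- pmin(pmax(idx[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(ix), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(iy), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(iz), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, length(ix))
  if (d[2] == 1) y0 <- rep(0, length(iy))
  if (d[3] == 1) z0 <- rep(0, length(iz))
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  c000 <- at(x0, y0, z0); c100 <- at(x1, y0, z0)
  c010 <- at(x0, y1, z0); c110 <- at(x1, y1, z0)
  c001 <- at(x0, y0, z1); c101 <- at(x1, y0, z1)
  c011 <- at(x0, y1, z1); c111 <- at(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Resample a volume to a new spacing
#'
#' Trilinear interpolation on the world-aligned grid. The output keeps the
#' input origin and its extent covers the input extent:
#' `dims = ceiling(old_dim * old_spacing / new_spacing)`.
#'
#' @param volume `volume_image`.
#' @param new_spacing length-3 (or scalar, recycled) target spacing (mm).
#' @return Resampled `volume_image`.
#' @export
resample_volume <- function(volume, new_spacing) {
  stopifnot(inherits(volume, "volume_image"))
  new_spacing <- rep(as.numeric(new_spacing), length.out = 3)
  if (any(new_spacing <= 0)) stop("resample_volume: spacing must be positive")
  d <- dim(volume$data)
  nd <- as.integer(ceiling(d * volume$spacing / new_spacing))
  g <- as.matrix(expand.grid(x = seq_len(nd[1]) - 1, y = seq_len(nd[2]) - 1,
                             z = seq_len(nd[3]) - 1))
  world <- sweep(sweep(g, 2, new_spacing, "*"), 2, volume$origin, "+")
  idx <- world_to_index(volume, world)
  vals <- interp_trilinear(volume$data, idx)
  volume_image(array(vals, nd), new_spacing, volume$origin, volume$modality)
}

## ---- segmentation ----------------------------------------------------------

#' Threshold segmentation
#'
#' Voxel-intensity windowing, the standard automatic bone/soft-tissue
#' segmentation for CT (Hounsfield-unit windows).
#'
#' @param volume `volume_image`.
#' @param low,high inclusive intensity window, `low <= high`.
#' @param structure structure label for the resulting mask.
#' @return `label_mask` with 1 where `low <= voxel <= high`.
#' @export
threshold_segment <- function(volume, low = -Inf, high = Inf,
                              structure = "bone") {
  stopifnot(inherits(volume, "volume_image"))
  if (low > high) stop("threshold_segment: low > high")
  label_mask(array(as.numeric(volume$data >= low & volume$data <= high),
                   dim(volume$data)),
             volume$spacing, volume$origin, structure)
}

## ---- iso-surface extraction ------------------------------------------------

#' A triangle mesh in world coordinates
#'
#' @param vertices n x 3 matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#'   Zero-area triangles are dropped at construction.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0) {
    if (max(triangles) > nrow(vertices) || min(triangles) < 1)
      stop("surface_mesh: triangle index out of range")
    a <- vertices[triangles[, 2], , drop = FALSE] -
      vertices[triangles[, 1], , drop = FALSE]
    b <- vertices[triangles[, 3], , drop = FALSE] -
      vertices[triangles[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- sqrt(rowSums(cr^2))
    triangles <- triangles[area2 > 1e-12, , drop = FALSE]
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh `surface_mesh`.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(0)
  a <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE] -
    mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE] -
    mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Read / write a triangle mesh as ASCII PLY
#' @param mesh `surface_mesh` to write.
#' @param path `.ply` path.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nrow(mesh$vertices) > 0)
    writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 17), 1,
                     paste, collapse = " "), con)
  if (nrow(mesh$triangles) > 0)
    writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                     mesh$triangles[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("read_ply: no such file: ", path)
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("read_ply: only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 lines, value = TRUE)))
  body <- which(lines == "end_header") + 1
  verts <- if (nv > 0)
    matrix(scan(text = lines[body:(body + nv - 1)], quiet = TRUE),
           nv, 3, byrow = TRUE)
  else matrix(numeric(0), 0, 3)
  tris <- if (nf > 0) {
    f <- matrix(scan(text = lines[(body + nv):(body + nv + nf - 1)],
                     quiet = TRUE), nf, 4, byrow = TRUE)
    f[, 2:4, drop = FALSE] + 1
  } else matrix(integer(0), 0, 3)
  surface_mesh(verts, tris)
}

# Kuhn (Freudenthal) 6-tetrahedron decomposition of the unit cube (vertex
# ids 0..7 with bit order x + 2y + 4z); conforming across the lattice, so the
# extracted surface is watertight.
TET6 <- matrix(c(0, 1, 3, 7,
                 0, 1, 5, 7,
                 0, 2, 3, 7,
                 0, 2, 6, 7,
                 0, 4, 5, 7,
                 0, 4, 6, 7) + 1L, ncol = 4, byrow = TRUE)
CUBE_OFFSETS <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                      c(0, 0, 1, 1, 0, 0, 1, 1),
                      c(0, 0, 0, 0, 1, 1, 1, 1))

#' Extract the 0.5-level iso-surface of a binary mask
#'
#' Marching tetrahedra on the 6-tetrahedron cube decomposition. The binary
#' mask is first smoothed with a separable 3-voxel box filter so the level
#' set interpolates the true structure boundary rather than the voxel
#' staircase (set `smooth = FALSE` for the raw mid-edge surface). Vertices
#' are returned in world coordinates (mm); the mesh is closed (watertight)
#' for structures away from the volume border.
#'
#' @param mask `label_mask`.
#' @param smooth logical; apply the 3-voxel box pre-filter (default TRUE).
#' @return `surface_mesh`; empty mask yields an empty mesh (0 triangles).
#' @export
extract_isosurface <- function(mask, smooth = TRUE) {
  stopifnot(inherits(mask, "label_mask"))
  f <- mask$data
  if (sum(f) == 0)
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  if (smooth) f <- box_smooth3(f)
  level <- 0.5
  d <- dim(f)
  # cells whose 2x2x2 corner block straddles the level
  inside <- f > level
  cs <- inside[-d[1], -d[2], -d[3]] + inside[-1, -d[2], -d[3]] +
    inside[-d[1], -1, -d[3]] + inside[-1, -1, -d[3]] +
    inside[-d[1], -d[2], -1] + inside[-1, -d[2], -1] +
    inside[-d[1], -1, -1] + inside[-1, -1, -1]
  mixed <- which(cs > 0 & cs < 8, arr.ind = TRUE)
  if (nrow(mixed) == 0)
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))

  vvals <- list(); vindex <- new.env(hash = TRUE)
  tris <- vector("list", 12 * nrow(mixed)); ntri <- 0L

  edge_vertex <- function(ga, gb, fa, fb) {
    # interpolated vertex on grid edge ga-gb (0-based integer grid nodes)
    ka <- paste(ga, collapse = ","); kb <- paste(gb, collapse = ",")
    key <- if (ka < kb) paste(ka, kb, sep = "|") else paste(kb, ka, sep = "|")
    id <- vindex[[key]]
    if (!is.null(id)) return(id)
    t <- (level - fa) / (fb - fa)
    p <- ga + t * (gb - ga)
    id <- length(vvals) + 1L
    vvals[[id]] <<- p
    assign(key, id, envir = vindex)
    id
  }

  for (ci in seq_len(nrow(mixed))) {
    base <- c(mixed[ci, 1] - 1L, mixed[ci, 2] - 1L, mixed[ci, 3] - 1L)
    corners <- sweep(CUBE_OFFSETS, 2, base, "+")
    fv <- f[corners + 1L]
    for (ti in 1:6) {
      vid <- TET6[ti, ]
      vals <- fv[vid]
      ins <- vals > level
      ni <- sum(ins)
      if (ni == 0 || ni == 4) next
      gi <- corners[vid, , drop = FALSE]
      if (ni == 1 || ni == 3) {
        apex <- if (ni == 1) which(ins) else which(!ins)
        others <- setdiff(1:4, apex)
        ids <- vapply(others, function(o)
          edge_vertex(gi[apex, ], gi[o, ], vals[apex], vals[o]), integer(1))
        ntri <- ntri + 1L; tris[[ntri]] <- ids
      } else {
        a <- which(ins); b <- which(!ins)
        e11 <- edge_vertex(gi[a[1], ], gi[b[1], ], vals[a[1]], vals[b[1]])
        e12 <- edge_vertex(gi[a[1], ], gi[b[2], ], vals[a[1]], vals[b[2]])
        e21 <- edge_vertex(gi[a[2], ], gi[b[1], ], vals[a[2]], vals[b[1]])
        e22 <- edge_vertex(gi[a[2], ], gi[b[2], ], vals[a[2]], vals[b[2]])
        ntri <- ntri + 1L; tris[[ntri]] <- c(e11, e12, e21)
        ntri <- ntri + 1L; tris[[ntri]] <- c(e21, e12, e22)
      }
    }
  }
  verts_idx <- do.call(rbind, vvals)
  verts <- index_to_world(mask, verts_idx)
  surface_mesh(verts, do.call(rbind, tris[seq_len(ntri)]))
}

# separable 3-voxel box filter with edge replication
box_smooth3 <- function(a) {
  d <- dim(a)
  sm_axis <- function(x, axis) {
    idx_lo <- pmax(seq_len(d[axis]) - 1, 1)
    idx_hi <- pmin(seq_len(d[axis]) + 1, d[axis])
    if (axis == 1) (x[idx_lo, , , drop = FALSE] + x +
                      x[idx_hi, , , drop = FALSE]) / 3
    else if (axis == 2) (x[, idx_lo, , drop = FALSE] + x +
                           x[, idx_hi, , drop = FALSE]) / 3
    else (x[, , idx_lo, drop = FALSE] + x + x[, , idx_hi, drop = FALSE]) / 3
  }
  sm_axis(sm_axis(sm_axis(a, 1), 2), 3)
}

## ---- slice fusion ----------------------------------------------------------

#' Fixed 256-entry colormaps
#'
#' `hot` ramps black -> red -> yellow -> white; `rainbow` sweeps HSV hue from
#' blue to red; `gray` is the identity ramp; `purple` ramps black -> purple ->
#' white (used for bone surface overlays).
#'
#' @param name one of `"hot"`, `"rainbow"`, `"gray"`, `"purple"`.
#' @return 256 x 3 matrix of RGB values in \[0, 1\].
#' @export
colormap_table <- function(name = c("hot", "rainbow", "gray", "purple")) {
  name <- match.arg(name)
  s <- seq(0, 1, length.out = 256)
  lut <- switch(name,
    gray = cbind(s, s, s),
    hot = cbind(pmin(1, 3 * s), pmin(1, pmax(0, 3 * s - 1)),
                pmin(1, pmax(0, 3 * s - 2))),
    rainbow = t(grDevices::col2rgb(grDevices::hsv(2 / 3 * (1 - s), 1, 1))) / 255,
    purple = {
      mid <- c(0.6, 0.2, 0.8)
      lo <- pmin(2 * s, 1); hi <- pmax(2 * s - 1, 0)
      cbind(mid[1] * lo + (1 - mid[1]) * hi,
            mid[2] * lo + (1 - mid[2]) * hi,
            mid[3] * lo + (1 - mid[3]) * hi)
    })
  dimnames(lut) <- NULL
  lut
}

slice_axis_index <- function(axis) {
  if (is.numeric(axis)) {
    stopifnot(axis %in% 1:3); return(as.integer(axis))
  }
  switch(match.arg(axis, c("sagittal", "coronal", "axial", "x", "y", "z")),
         sagittal = 1L, x = 1L, coronal = 2L, y = 2L, axial = 3L, z = 3L)
}

extract_slice <- function(volume, axis, index) {
  ax <- slice_axis_index(axis)
  d <- dim(volume$data)
  if (index < 0 || index > d[ax] - 1)
    stop("slice index ", index, " out of range 0..", d[ax] - 1)
  i <- index + 1
  sl <- switch(ax, volume$data[i, , ], volume$data[, i, ], volume$data[, , i])
  matrix(sl, nrow = dim(volume$data)[setdiff(1:3, ax)][1])
}

norm01 <- function(x, rng) {
  if (diff(rng) <= 0) return(array(0, dim(x)))
  pmin(pmax((x - rng[1]) / diff(rng), 0), 1)
}

#' Fuse an anatomical and a functional slice into an RGB image
#'
#' The anatomical slice is rendered in grayscale, the functional slice through
#' a colormap, and the two alpha-blended:
#' `(1 - alpha) * gray(anat) + alpha * colormap(func)`. Both volumes must lie
#' on the same world-aligned grid (resample first otherwise). Intensities are
#' windowed to each volume's full range by default.
#'
#' @param anat,func `volume_image` objects on identical grids.
#' @param axis slice axis: 1/2/3 or "sagittal"/"coronal"/"axial".
#' @param index 0-based slice index.
#' @param alpha functional opacity in \[0, 1\].
#' @param colormap colormap name for the functional layer, see
#'   [colormap_table()].
#' @param anat_window,func_window optional length-2 intensity windows.
#' @return An `nrow x ncol x 3` RGB array in \[0, 1\], with the slice's world
#'   geometry in attributes `axis`, `index`, `origin`, `spacing`.
#' @export
fuse_slice <- function(anat, func, axis = "coronal", index, alpha = 0.5,
                       colormap = "hot",
                       anat_window = range(anat$data),
                       func_window = range(func$data)) {
  stopifnot(inherits(anat, "volume_image"), inherits(func, "volume_image"))
  if (alpha < 0 || alpha > 1) stop("fuse_slice: alpha must be in [0, 1]")
  same <- identical(dim(anat$data), dim(func$data)) &&
    max(abs(anat$spacing - func$spacing)) < 1e-9 &&
    max(abs(anat$origin - func$origin)) < 1e-9
  if (!same)
    stop("fuse_slice: volumes are on different grids; resample the ",
         "functional volume onto the anatomical grid first ",
         "(see resample_volume)")
  a <- norm01(extract_slice(anat, axis, index), anat_window)
  f <- norm01(extract_slice(func, axis, index), func_window)
  lut <- colormap_table(colormap)
  fi <- pmin(pmax(round(f * 255), 0), 255) + 1
  out <- array(0, c(dim(a), 3))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * a + alpha * matrix(lut[fi, ch], nrow(a))
  ax <- slice_axis_index(axis)
  attr(out, "axis") <- ax
  attr(out, "index") <- index
  attr(out, "origin") <- anat$origin
  attr(out, "spacing") <- anat$spacing
  out
}

#' Write an RGB array (values in \[0,1\]) as PNG
#' @param img H x W x 3 array, or W x H x 3 slice from [fuse_slice()].
#' @param path output path.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

## ---- NMI registration ------------------------------------------------------

#' Normalized mutual information of two intensity samples
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` from a joint histogram with `bins x bins`
#' cells over each sample's range. Identical images give 2; independent
#' images approach 1.
#'
#' @param a,b numeric vectors of paired intensities.
#' @param bins histogram bins per axis (default 64).
#' @return NMI value in \[1, 2\].
#' @export
nmi_score <- function(a, b, bins = 64) {
  stopifnot(length(a) == length(b), length(a) > 0)
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0)
    stop("nmi_score: constant image (degenerate histogram)")
  ia <- pmin(floor((a - ra[1]) / diff(ra) * bins), bins - 1)
  ib <- pmin(floor((b - rb[1]) / diff(rb) * bins), bins - 1)
  joint <- tabulate(ia * bins + ib + 1, nbins = bins * bins)
  p <- joint / sum(joint)
  p <- p[p > 0]
  hj <- -sum(p * log(p))
  pa <- tabulate(ia + 1, nbins = bins); pa <- pa / sum(pa); pa <- pa[pa > 0]
  pb <- tabulate(ib + 1, nbins = bins); pb <- pb / sum(pb); pb <- pb[pb > 0]
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  (ha + hb) / hj
}

# NMI with partial-volume (bilinear) bin weighting: each sample spreads over
# the 2x2 neighboring histogram cells, making the score C1-smooth in the
# transform parameters. Used internally as the optimization surrogate of
# nmi_score (whose hard binning is kept for reporting).
nmi_score_soft <- function(a, b, bins = 64) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(NA_real_)
  xa <- (a - ra[1]) / diff(ra) * (bins - 1)
  xb <- (b - rb[1]) / diff(rb) * (bins - 1)
  i0 <- pmin(floor(xa), bins - 2); wa <- xa - i0
  j0 <- pmin(floor(xb), bins - 2); wb <- xb - j0
  joint <- numeric(bins * bins)
  add <- function(i, j, w) {
    idx <- i * bins + j + 1
    s <- rowsum(w, idx)
    joint[as.integer(rownames(s))] <<- joint[as.integer(rownames(s))] + s
  }
  add(i0, j0, (1 - wa) * (1 - wb))
  add(i0 + 1, j0, wa * (1 - wb))
  add(i0, j0 + 1, (1 - wa) * wb)
  add(i0 + 1, j0 + 1, wa * wb)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins, byrow = TRUE) # rows: a-bins, cols: b-bins
  pa <- rowSums(pm); pb <- colSums(pm)
  pz <- p[p > 0]
  hj <- -sum(pz * log(pz))
  pa <- pa[pa > 0]; pb <- pb[pb > 0]
  (-sum(pa * log(pa)) - sum(pb * log(pb))) / hj
}

# build the rigid transform (moving world -> fixed world) from 6 parameters:
# translation mm + rotation degrees about the fixed-volume center
params_to_transform <- function(par, center) {
  R <- rot_z(par[6]) %*% rot_y(par[5]) %*% rot_x(par[4])
  tr <- par[1:3] + center - as.vector(R %*% center)
  rigid_transform(R, tr, from = "moving", to = "fixed")
}

#' Rigid registration by normalized mutual information
#'
#' Maximizes `NMI = (H(A)+H(B))/H(A,B)` (64 x 64 joint histogram) over the 6
#' rigid parameters, the standard intensity-based approach for multimodality
#' (PET/CT, SPECT/CT, PET/MRI) volume alignment. Optimization is a
#' coarse-to-fine translation grid (3 levels) followed by Nelder-Mead over
#' all 6 parameters; rotations are parameterized about the fixed-volume
#' center. The fixed grid is subsampled to at most `max_samples` voxels.
#'
#' @param moving,fixed `volume_image` objects with overlapping fields of view.
#' @param init optional initial `rigid_transform` (moving -> fixed world);
#'   identity by default.
#' @param bins joint-histogram bins (default 64).
#' @param max_samples maximum fixed-grid samples used per NMI evaluation.
#' @param coarse_range half-width (mm) of the coarse translation search.
#' @param pyramid register a smoothed, 2x-downsampled level first and use its
#'   result to initialize the full-resolution refinement (default TRUE; the
#'   coarse level decouples rotation from translation and avoids capture in
#'   off-axis local optima).
#' @return A list: `transform` (`rigid_transform`, moving world -> fixed
#'   world), `nmi` (value at the optimum), `par` (the 6 parameters).
#' @export
nmi_register <- function(moving, fixed, init = NULL, bins = 64,
                         max_samples = 40000, coarse_range = 6,
                         pyramid = TRUE) {
  stopifnot(inherits(moving, "volume_image"), inherits(fixed, "volume_image"))
  if (diff(range(moving$data)) == 0 || diff(range(fixed$data)) == 0)
    stop("nmi_register: constant image cannot be registered")
  d <- dim(fixed$data)
  g <- as.matrix(expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                             z = seq_len(d[3]) - 1))
  if (nrow(g) > max_samples) {
    step <- ceiling(nrow(g) / max_samples)
    g <- g[seq(1, nrow(g), by = step), , drop = FALSE]
  }
  fixed_world <- index_to_world(fixed, g)
  fixed_vals <- fixed$data[g + 1]
  center <- fixed$origin + (d - 1) / 2 * fixed$spacing
  dm <- dim(moving$data)

  init_par <- if (is.null(init)) rep(0, 6) else {
    # recover (t, angles) assuming init was built by params_to_transform
    ang <- rotation_to_euler_zyx(init$rotation)
    tr <- init$translation - center + as.vector(init$rotation %*% center)
    c(tr, ang)
  }

  from_pyramid <- FALSE
  if (pyramid && all(dim(fixed$data) >= 16) && all(dim(moving$data) >= 16)) {
    smooth2 <- function(v) resample_volume(
      volume_image(box_smooth3(v$data), v$spacing, v$origin, v$modality),
      v$spacing * 2)
    lo <- nmi_register(smooth2(moving), smooth2(fixed), init = init,
                       bins = bins, max_samples = max_samples,
                       coarse_range = coarse_range, pyramid = FALSE)
    init_par <- lo$par
    from_pyramid <- TRUE
  }

  sample_pair <- function(par) {
    Tf <- params_to_transform(par, center)
    inv <- invert_transform(Tf)
    mv_idx <- world_to_index(moving, apply_transform(inv, fixed_world))
    inb <- mv_idx[, 1] >= 0 & mv_idx[, 1] <= dm[1] - 1 &
      mv_idx[, 2] >= 0 & mv_idx[, 2] <= dm[2] - 1 &
      mv_idx[, 3] >= 0 & mv_idx[, 3] <= dm[3] - 1
    if (sum(inb) < 200) return(NULL)
    mv <- interp_trilinear(moving$data, mv_idx[inb, , drop = FALSE])
    fv <- fixed_vals[inb]
    if (diff(range(mv)) == 0 || diff(range(fv)) == 0) return(NULL)
    list(fv = fv, mv = mv)
  }
  objective <- function(par) {
    s <- sample_pair(par)
    if (is.null(s)) return(-1)
    val <- nmi_score_soft(s$fv, s$mv, bins)
    if (is.na(val)) -1 else val
  }

  best <- init_par
  if (!from_pyramid) {
    # 3-level coarse-to-fine translation grid
    step <- coarse_range / 2
    for (level in 1:3) {
      offs <- expand.grid(dx = c(-step, 0, step), dy = c(-step, 0, step),
                          dz = c(-step, 0, step))
      scores <- apply(offs, 1, function(o)
        objective(best + c(o[1], o[2], o[3], 0, 0, 0)))
      k <- which.max(scores)
      best[1:3] <- best[1:3] + as.numeric(offs[k, ])
      step <- step / 2
    }
    # 3-level coarse-to-fine rotation grid (several axes may be off at once;
    # the joint grid avoids capture in an off-axis local optimum)
    astep <- 3
    for (level in 1:3) {
      offs <- expand.grid(rx = c(-astep, 0, astep), ry = c(-astep, 0, astep),
                          rz = c(-astep, 0, astep))
      scores <- apply(offs, 1, function(o)
        objective(best + c(0, 0, 0, o[1], o[2], o[3])))
      k <- which.max(scores)
      best[4:6] <- best[4:6] + as.numeric(offs[k, ])
      astep <- astep / 2
    }
  }
  # cyclic coordinate descent over all 6 parameters with shrinking steps:
  # robust against the histogram-induced roughness of the NMI surface that
  # makes a bare simplex search stall
  fbest <- objective(best)
  cd_steps <- if (from_pyramid) c(1, 0.5, 0.25, 0.1) else c(2, 1, 0.5, 0.25, 0.1)
  for (step in cd_steps) {
    for (sweep_i in 1:8) {
      moved <- FALSE
      for (j in 1:6) {
        for (dir in c(-1, 1)) {
          cand <- best
          cand[j] <- cand[j] + dir * step
          fc <- objective(cand)
          if (fc > fbest + 1e-12) {
            best <- cand; fbest <- fc; moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
  }
  # simplex polish
  opt <- stats::optim(best, function(p) -objective(p), method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10,
                                     parscale = c(0.5, 0.5, 0.5, 0.25, 0.25, 0.25)))
  if (-opt$value < fbest) opt <- list(par = best, value = -fbest)
  # report the hard-binned NMI at the optimum (the soft-binned score is only
  # the optimization surrogate)
  s <- sample_pair(opt$par)
  nmi_final <- if (is.null(s)) NA_real_ else nmi_score(s$fv, s$mv, bins)
  list(transform = params_to_transform(opt$par, center),
       nmi = nmi_final, par = opt$par)
}

rotation_to_euler_zyx <- function(R) {
  # angles (deg) such that R = Rz(c) Ry(b) Rx(a); R[3,1] = -sin(b)
  b <- asin(pmin(pmax(-R[3, 1], -1), 1))
  a <- atan2(R[3, 2], R[3, 3])
  cc <- atan2(R[2, 1], R[1, 1])
  c(a, b, cc) * 180 / pi
}

## ---- synthetic subject -----------------------------------------------------

#' Default parameters for the synthetic multimodality subject
#'
#' A mouse-like geometry: an ellipsoidal soft-tissue body with a rod-like
#' "spine" plus two lateral rods (high intensity, CT bone), an off-axis
#' liver-like organ, a spherical tumour, and a functional (PET/SPECT-like)
#' volume whose hotspot is co-located with the tumour over a faint whole-body
#' background with elevated liver uptake. Intensities are Hounsfield-like for
#' the CT channel (air -1000, soft tissue 40, tumour 60, liver 90, bone 700).
#' The asymmetric organ layout leaves no rotational near-symmetry, so rigid
#' registration of the subject is well posed about every axis.
#'
#' @return Named list of generator parameters.
#' @export
synthetic_subject_params <- function() {
  list(
    spacing = c(0.3, 0.3, 0.3),          # mm; matches a down-sampled micro-CT
    body_semiaxes = c(9, 7, 25),         # mm ellipsoid semi-axes
    margin = 2.4,                        # mm air border around the body
    tumour_center = c(3, 0, 8),          # mm, body-centered coords
    tumour_radius = 4,                   # mm
    bone_rod_radius = 1.2,               # mm (spine rod along z)
    side_rod_radius = 1.2,               # mm (two lateral rods)
    liver_center = c(-3.5, 1.5, -6),     # mm; off-axis organ
    liver_semiaxes = c(4, 3, 5),         # mm
    hu_air = -1000, hu_soft = 40, hu_tumour = 60, hu_liver = 90, hu_bone = 700,
    func_background = 1, func_liver = 3, func_amplitude = 10,
    noise_sigma_ct = 15,                 # HU
    noise_sigma_func = 0.1
  )
}

#' Generate a synthetic multimodality subject
#'
#' Builds world-aligned CT-like and functional volumes plus exact tumour and
#' bone label masks. The tumour mask is exactly the voxelized sphere
#' (`||x - center|| <= r` at voxel centers) and the functional hotspot is a
#' Gaussian bump centered on the tumour, so the functional maximum falls
#' inside the tumour mask by construction.
#'
#' @param seed integer RNG seed (noise reproducibility).
#' @param params parameter list, see [synthetic_subject_params()]; entries
#'   you supply override the defaults.
#' @return List with `ct`, `func` (`volume_image`), `tumour_mask`,
#'   `bone_mask` (`label_mask`) and the expanded `params`.
#' @export
make_synthetic_subject <- function(seed = 1, params = list()) {
  p <- utils::modifyList(synthetic_subject_params(), params)
  if (sum((p$tumour_center / p$body_semiaxes)^2) > 1)
    stop("make_synthetic_subject: tumour center lies outside the body ellipsoid")
  set.seed(as.integer(seed))
  half <- p$body_semiaxes + p$margin
  nd <- as.integer(ceiling(2 * half / p$spacing))
  origin <- -half
  g <- as.matrix(expand.grid(x = seq_len(nd[1]) - 1, y = seq_len(nd[2]) - 1,
                             z = seq_len(nd[3]) - 1))
  w <- sweep(sweep(g, 2, p$spacing, "*"), 2, origin, "+")
  body <- rowSums(sweep(w, 2, p$body_semiaxes, "/")^2) <= 1
  dt2 <- rowSums(sweep(w, 2, p$tumour_center)^2)
  tumour <- dt2 <= p$tumour_radius^2
  spine <- (w[, 1]^2 + w[, 2]^2 <= p$bone_rod_radius^2) &
    abs(w[, 3]) <= 0.85 * p$body_semiaxes[3]
  side <- ((w[, 1] - 0.6 * p$body_semiaxes[1])^2 + w[, 2]^2 <=
             p$side_rod_radius^2 |
           (w[, 1] + 0.6 * p$body_semiaxes[1])^2 + w[, 2]^2 <=
             p$side_rod_radius^2) &
    abs(w[, 3]) <= 0.5 * p$body_semiaxes[3]
  liver <- rowSums(sweep(sweep(w, 2, p$liver_center), 2,
                         p$liver_semiaxes, "/")^2) <= 1
  # the tumour takes precedence so its mask is exactly the voxelized sphere
  bone <- (spine | side) & body & !tumour
  liver <- liver & body & !tumour & !bone
  if (any(tumour & !body))
    stop("make_synthetic_subject: tumour lies (partly) outside the body")

  ct <- rep(p$hu_air, nrow(w))
  ct[body] <- p$hu_soft
  ct[liver] <- p$hu_liver
  ct[bone] <- p$hu_bone
  ct[tumour] <- p$hu_tumour
  if (p$noise_sigma_ct > 0) ct <- ct + stats::rnorm(length(ct), 0, p$noise_sigma_ct)

  fn <- numeric(nrow(w))
  fn[body] <- p$func_background
  fn[liver] <- p$func_liver
  fn <- fn + p$func_amplitude * exp(-dt2 / (2 * (p$tumour_radius / 2)^2))
  if (p$noise_sigma_func > 0)
    fn <- fn + stats::rnorm(length(fn), 0, p$noise_sigma_func)

  list(ct = volume_image(array(ct, nd), p$spacing, origin, "CT"),
       func = volume_image(array(fn, nd), p$spacing, origin, "PET"),
       tumour_mask = label_mask(array(as.numeric(tumour), nd), p$spacing,
                                origin, "tumour"),
       bone_mask = label_mask(array(as.numeric(bone), nd), p$spacing,
                              origin, "bone"),
       params = p)
}
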