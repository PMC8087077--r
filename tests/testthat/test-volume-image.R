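test_that("NIfTI round trip preserves data and geometry", {
  set.seed(41)
  v <- volume_image(array(rnorm(16^3), c(16, 16, 16)),
                    c(0.154, 0.154, 0.154), c(-1.2, 3.4, 5.6), "CT")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  back <- read_volume(f, "CT")
  expect_identical(back$data, v$data) # float64 voxels survive bit-exactly
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(back$origin, v$origin, tolerance = 1e-6)
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
})

test_that("mask round trip and construction invariants", {
  mk <- sphere_mask(radius = 5, spacing = 1)
  f <- withr::local_tempfile(fileext = ".nii")
  write_volume(mk, f)
  back <- read_mask(f, "margin")
  expect_identical(back$data, mk$data)
  expect_identical(back$structure, "margin")
  expect_error(label_mask(array(2, c(2, 2, 2))), "0 or 1")
})

test_that("resampling follows the extent-covering dimension rule", {
  v <- volume_image(array(0, c(366, 4, 4)), c(0.154, 1, 1))
  out <- resample_volume(v, c(0.3, 1, 1))
  expect_identical(dim(out$data)[1], 188L) # ceil(366 * 0.154 / 0.3)
  expect_error(resample_volume(v, c(-1, 1, 1)), "positive")
})

test_that("resampling is exact for constant volumes and idempotent at equal spacing", {
  set.seed(42)
  vc <- volume_image(array(7.5, c(9, 11, 8)), c(0.7, 0.5, 1.1), c(1, 2, 3))
  out <- resample_volume(vc, c(0.4, 0.9, 0.6))
  expect_true(all(out$data == 7.5))

  v <- volume_image(array(rnorm(10 * 12 * 9), c(10, 12, 9)), c(0.5, 0.5, 0.5))
  same <- resample_volume(v, v$spacing)
  expect_equal(same$data, v$data, tolerance = 1e-12)
  expect_identical(dim(same$data), dim(v$data))
})

test_that("threshold segmentation windows intensities and checks bounds", {
  set.seed(43)
  v <- volume_image(array(runif(8^3, 0, 100), c(8, 8, 8)))
  expect_true(all(threshold_segment(v, -Inf, Inf)$data == 1))
  expect_true(all(threshold_segment(v, 200, 300)$data == 0))
  expect_error(threshold_segment(v, 10, 5), "low > high")
  mk <- threshold_segment(v, 20, 60)
  expect_identical(mk$data, array(as.numeric(v$data >= 20 & v$data <= 60),
                                  dim(v$data)))
})

test_that("sphere mask voxel count matches the analytic volume", {
  sp <- 0.5
  mk <- sphere_mask(radius = 10, spacing = sp)
  analytic <- (4 / 3) * pi * 10^3 / sp^3
  expect_lt(abs(sum(mk$data) - analytic) / analytic, 0.02)
})

test_that("iso-surface of a sphere has the analytic area and Euler characteristic 2", {
  mk <- sphere_mask(radius = 10, spacing = 0.6)
  mesh <- extract_isosurface(mk)
  expect_gt(nrow(mesh$triangles), 0)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  edges <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
                 mesh$triangles[, c(1, 3)])
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  euler <- nrow(mesh$vertices) - nrow(edges) + nrow(mesh$triangles)
  expect_identical(euler, 2L)
  # empty mask -> empty mesh
  empty <- label_mask(array(0, c(4, 4, 4)))
  expect_identical(nrow(extract_isosurface(empty)$triangles), 0L)
})

test_that("PLY meshes round trip, preserving geometry", {
  mk <- sphere_mask(radius = 6, spacing = 1)
  mesh <- extract_isosurface(mk)
  f <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, f)
  back <- read_ply(f)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$triangles, mesh$triangles)
  expect_equal(mesh_area(back), mesh_area(mesh), tolerance = 1e-12)
  expect_error(read_ply(file.path(tempdir(), "nope.ply")), "no such file")
})

test_that("slice fusion obeys the alpha-blending contract", {
  set.seed(44)
  d <- c(6, 7, 8)
  anat <- volume_image(array(runif(prod(d)), d))
  func <- volume_image(array(runif(prod(d)), d))
  # alpha = 0: the grayscale anatomical slice
  f0 <- fuse_slice(anat, func, 3, 2, alpha = 0, colormap = "hot",
                   anat_window = c(0, 1), func_window = c(0, 1))
  expect_equal(f0[, , 1], anat$data[, , 3], tolerance = 1e-12)
  expect_equal(f0[, , 2], anat$data[, , 3], tolerance = 1e-12)
  # alpha = 1: the colormapped functional slice
  f1 <- fuse_slice(anat, func, 3, 2, alpha = 1, colormap = "gray",
                   anat_window = c(0, 1), func_window = c(0, 1))
  expect_equal(f1[, , 1], matrix(colormap_table("gray")[
    pmin(pmax(round(func$data[, , 3] * 255), 0), 255) + 1, 1], d[1]),
    tolerance = 1e-12)
  # hand-computed blend: gray 0.4 with colormap value (1, 0.2, 0) at alpha 0.5
  a1 <- volume_image(array(0.4, c(2, 2, 2)))
  fn <- volume_image(array(1, c(2, 2, 2)))
  lut <- colormap_table("hot")
  expect_equal(lut[256, ], c(1, 1, 1))
  fb <- fuse_slice(a1, fn, 3, 0, alpha = 0.5, colormap = "hot",
                   anat_window = c(0, 1), func_window = c(0, 2))
  # func value 1 in window (0,2) -> LUT midpoint (~(1, 0.5, 0) for hot)
  mid <- lut[round(0.5 * 255) + 1, ]
  expect_equal(as.vector(fb[1, 1, ]), 0.5 * 0.4 + 0.5 * mid, tolerance = 1e-9)

  # misaligned grids are refused with a resample hint
  shifted <- volume_image(array(runif(prod(d)), d), origin = c(1, 0, 0))
  expect_error(fuse_slice(anat, shifted, 3, 2), "resample")
  expect_error(fuse_slice(anat, func, 3, 2, alpha = 2), "alpha")
})

test_that("colormap tables are valid and anchored", {
  for (nm in c("hot", "rainbow", "gray", "purple")) {
    lut <- colormap_table(nm)
    expect_identical(dim(lut), c(256L, 3L))
    expect_true(all(lut >= 0 & lut <= 1))
  }
  expect_equal(colormap_table("gray")[1, ], c(0, 0, 0))
  expect_equal(colormap_table("hot")[1, ], c(0, 0, 0))
  expect_equal(colormap_table("hot")[256, ], c(1, 1, 1))
  # rainbow sweeps blue -> red
  expect_equal(colormap_table("rainbow")[1, ], c(0, 0, 1))
  expect_equal(colormap_table("rainbow")[256, ], c(1, 0, 0))
})

test_that("NMI score: identical images give 2, independent noise about 1", {
  set.seed(45)
  x <- rnorm(40000)
  expect_equal(nmi_score(x, x), 2, tolerance = 1e-12)
  y <- runif(40000)
  z <- runif(40000)
  expect_lt(abs(nmi_score(y, z) - 1), 0.05)
  expect_error(nmi_score(rep(1, 10), rnorm(10)), "constant")
})

test_that("NMI registration of a volume to itself stays at the identity", {
  sub <- make_synthetic_subject(seed = 46, params = list(spacing = rep(0.8, 3)))
  reg <- nmi_register(sub$ct, sub$ct)
  expect_lt(max(abs(reg$par[1:3])), 0.08) # within 0.1 voxel (0.8 mm spacing)
  # at the exact optimum (zero shift) the metric attains its ceiling of 2,
  # since H(A,A) = H(A); the search result sits a fraction of a voxel away,
  # where interpolation mixes neighbors and the hard-binned score drops
  expect_equal(nmi_score(as.vector(sub$ct$data), as.vector(sub$ct$data)), 2,
               tolerance = 1e-12)
  expect_gt(reg$nmi, 1.5)
  cst <- volume_image(array(1, c(5, 5, 5)))
  expect_error(nmi_register(cst, cst), "constant")
})

test_that("NMI registration recovers a 3-voxel shift, matching the exhaustive oracle", {
  sub <- make_synthetic_subject(seed = 47, params = list(spacing = rep(0.8, 3)))
  fixed <- sub$ct
  sp <- fixed$spacing[1]
  arr <- fixed$data
  n <- dim(arr)[1]
  shifted <- array(min(arr), dim(arr))
  shifted[4:n, , ] <- arr[1:(n - 3), , ] # content moved +3 voxels along x
  moving <- volume_image(shifted, fixed$spacing, fixed$origin, "CT")

  # exhaustive integer-shift oracle on the arrays (no interpolation)
  oracle <- sapply(-5:5, function(k) {
    if (k >= 0) {
      a <- fixed$data[(1 + k):n, , ]; b <- moving$data[1:(n - k), , ]
    } else {
      a <- fixed$data[1:(n + k), , ]; b <- moving$data[(1 - k):n, , ]
    }
    nmi_score(as.vector(a), as.vector(b))
  })
  k_best <- (-5:5)[which.max(oracle)]
  expect_identical(k_best, -3L + 0L) # moving -> fixed is a -3 voxel shift

  reg <- nmi_register(moving, fixed)
  expect_lt(abs(reg$par[1] - k_best * sp), 0.5 * sp)
  expect_lt(max(abs(reg$par[2:3])), 0.5 * sp)
  expect_lt(max(abs(reg$par[4:6])), 1)
})

test_that("synthetic subject construction honours its contracts", {
  sub <- make_synthetic_subject(seed = 48)
  # functional maximum lies inside the tumour mask
  s0 <- make_synthetic_subject(seed = 48, params = list(noise_sigma_ct = 0,
                                                        noise_sigma_func = 0))
  expect_identical(s0$tumour_mask$data[which.max(s0$func$data)], 1)
  # tumour voxel count within 3% of the analytic sphere volume
  p <- s0$params
  analytic <- (4 / 3) * pi * p$tumour_radius^3 / prod(p$spacing)
  expect_lt(abs(sum(s0$tumour_mask$data) - analytic) / analytic, 0.03)
  # determinism: same seed gives bit-identical volumes
  again <- make_synthetic_subject(seed = 48)
  expect_identical(again$ct$data, sub$ct$data)
  expect_identical(again$func$data, sub$func$data)
  # tumour outside the body is rejected
  expect_error(make_synthetic_subject(1, list(tumour_center = c(30, 0, 0),
                                              noise_sigma_ct = 0)),
               "outside the body")
})

test_that("threshold segmentation recovers the generating tumour mask exactly", {
  s0 <- make_synthetic_subject(seed = 49, params = list(noise_sigma_ct = 0,
                                                        noise_sigma_func = 0))
  p <- s0$params
  mk <- threshold_segment(s0$ct, p$hu_tumour - 5, p$hu_tumour + 5, "tumour")
  expect_identical(mk$data, s0$tumour_mask$data)
})

test_that("random rigid perturbations are recovered by NMI registration", {
  set.seed(50)
  sub <- make_synthetic_subject(seed = 50) # native 0.3 mm working resolution
  fixed <- sub$ct
  d <- dim(fixed$data)
  ctr <- fixed$origin + (d - 1) / 2 * fixed$spacing
  g <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  w <- sweep(sweep(g, 2, fixed$spacing, "*"), 2, fixed$origin, "+")
  n_trials <- 20
  ok <- 0
  for (i in 1:n_trials) {
    ang <- runif(3, -4, 4); tr <- runif(3, -4, 4)
    R <- rot_z(ang[3]) %*% rot_y(ang[2]) %*% rot_x(ang[1])
    # moving(x) = fixed(R (x - ctr) + ctr + tr): the aligning transform
    # moving -> fixed is then exactly (tr, ang)
    w_src <- sweep(t(R %*% t(sweep(w, 2, ctr))), 2, ctr + tr, "+")
    idx <- sweep(sweep(w_src, 2, fixed$origin), 2, fixed$spacing, "/")
    moving <- volume_image(array(arnav:::interp_trilinear(fixed$data, idx), d),
                           fixed$spacing, fixed$origin, "CT")
    reg <- nmi_register(moving, fixed)
    t_err <- max(abs(reg$par[1:3] - tr))
    a_err <- max(abs(reg$par[4:6] - ang))
    if (t_err < 0.5 * fixed$spacing[1] && a_err < 0.5) ok <- ok + 1
  }
  expect_gte(ok / n_trials, 0.9)
})
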