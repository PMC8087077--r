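down_pose <- function(model, height = 300, jitter = c(0, 0)) {
  # projector looking straight down at the z = 0 plane from above
  T_p2t <- rigid_transform(rot_x(180), c(jitter[1], jitter[2], height),
                           "projector", "tracker")
  tracked_pose("projector_sensor",
               compose_transform(T_p2t,
                                 invert_transform(model$t_sensor_to_projector)))
}

test_that("an empty plan renders the uniform background", {
  m <- default_projector_model()
  fb <- render_scene(surgical_plan(), m, down_pose(m),
                     identity_transform("image", "tracker"),
                     background = c(0.1, 0.2, 0.3))
  expect_identical(dim(fb$image), c(600L, 800L, 3L))
  expect_true(all(fb$image[, , 1] == 0.1))
  expect_true(all(fb$image[, , 2] == 0.2))
  expect_true(all(fb$image[, , 3] == 0.3))
  expect_true(all(fb$zbuffer == Inf))
})

test_that("a point structure lights the pixel predicted by project_point", {
  set.seed(71)
  m <- default_projector_model()
  reg <- identity_transform("image", "tracker")
  for (i in 1:10) {
    wp <- c(runif(2, -40, 40), runif(1, -10, 10))
    pose <- down_pose(m, height = runif(1, 250, 400))
    plan <- surgical_plan(list(list(
      geometry = surface_mesh(matrix(wp, 1, 3), matrix(integer(0), 0, 3)),
      role = "target", color = c(0, 1, 0), opacity = 1)))
    fb <- render_scene(plan, m, pose, reg)
    pred <- project_point(m, pose, wp)
    expect_equal(as.numeric(fb$point_pixels[1, c("u", "v")]), pred,
                 tolerance = 1e-9)
    lit <- which(fb$zbuffer < Inf, arr.ind = TRUE)
    expect_identical(nrow(lit), 1L)
    # rasterized at the rounded pixel
    expect_lte(abs(lit[1, 2] - 1 - pred[1]), 0.5)
    expect_lte(abs(lit[1, 1] - 1 - pred[2]), 0.5)
  }
})

test_that("rendered mesh vertices agree with project_point to half a pixel", {
  set.seed(72)
  m <- default_projector_model()
  pose <- down_pose(m)
  reg <- identity_transform("image", "tracker")
  tri_w <- rbind(c(-15, -10, 0), c(18, -12, 0), c(2, 16, 0))
  plan <- surgical_plan(list(list(geometry = surface_mesh(tri_w, matrix(1:3, 1)),
                                  role = "target", color = c(1, 0, 0),
                                  opacity = 1)))
  fb <- render_scene(plan, m, pose, reg)
  px <- project_point(m, pose, tri_w)
  lit <- which(fb$zbuffer < Inf, arr.ind = TRUE)
  lit_uv <- cbind(lit[, 2] - 1, lit[, 1] - 1)
  # every projected vertex has a lit pixel within half a pixel (+ rounding)
  for (k in 1:3) {
    dmin <- min(sqrt((lit_uv[, 1] - px[k, 1])^2 + (lit_uv[, 2] - px[k, 2])^2))
    expect_lt(dmin, 1.5)
  }
  # all lit pixels lie inside the projected triangle (with 1 px slack)
  d <- function(p, a, b) (b[1] - a[1]) * (p[, 2] - a[2]) -
    (b[2] - a[2]) * (p[, 1] - a[1])
  s1 <- d(lit_uv, px[1, ], px[2, ]); s2 <- d(lit_uv, px[2, ], px[3, ])
  s3 <- d(lit_uv, px[3, ], px[1, ])
  inside <- (s1 >= -2 & s2 >= -2 & s3 >= -2) | (s1 <= 2 & s2 <= 2 & s3 <= 2)
  expect_true(all(inside))
})

test_that("z-buffering draws the nearer of two overlapping structures", {
  m <- default_projector_model()
  pose <- down_pose(m)
  reg <- identity_transform("image", "tracker")
  quad <- function(z) surface_mesh(
    rbind(c(-20, -20, z), c(20, -20, z), c(20, 20, z), c(-20, 20, z)),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  plan <- surgical_plan(list(
    list(geometry = quad(0), role = "bone", color = c(1, 0, 0), opacity = 1),
    list(geometry = quad(100), role = "target", color = c(0, 1, 0),
         opacity = 1))) # z=100 is 100 mm above the plane, i.e. nearer
  fb <- render_scene(plan, m, pose, reg)
  ctr <- fb$image[300, 400, ]
  expect_equal(as.numeric(ctr), c(0, 1, 0))
})

test_that("increasing opacity never decreases a structure's contribution", {
  m <- default_projector_model()
  pose <- down_pose(m)
  reg <- identity_transform("image", "tracker")
  mesh <- surface_mesh(rbind(c(-25, -25, 0), c(25, -25, 0), c(0, 25, 0)),
                       matrix(1:3, 1))
  greens <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(op) {
    plan <- surgical_plan(list(list(geometry = mesh, role = "margin",
                                    color = c(0, 1, 0), opacity = op)))
    fb <- render_scene(plan, m, pose, reg)
    fb$image[300, 400, 2]
  }, numeric(1))
  expect_true(all(diff(greens) >= 0))
  expect_equal(greens[1], 0)
  expect_equal(greens[5], 1)
})

test_that("the fused slice quad is rendered at its world position", {
  set.seed(73)
  m <- default_projector_model()
  pose <- down_pose(m)
  d <- c(12, 14, 10)
  anat <- volume_image(array(runif(prod(d)), d), spacing = c(4, 4, 4),
                       origin = c(-22, -26, -40))
  func <- volume_image(array(runif(prod(d)), d), spacing = c(4, 4, 4),
                       origin = c(-22, -26, -40))
  plan <- surgical_plan(slice_display = list(anat = anat, func = func,
                                             axis = 3, index = 5, alpha = 0.5,
                                             colormap = "hot"))
  fb <- render_scene(plan, m, pose, identity_transform("image", "tracker"))
  expect_gt(sum(fb$zbuffer < Inf), 100)
  # a pixel at the projected slice center is lit
  ctr_world <- c(-22 + 4 * (d[1] - 1) / 2, -26 + 4 * (d[2] - 1) / 2, -40 + 4 * 5)
  pc <- round(project_point(m, pose, ctr_world))
  expect_lt(fb$zbuffer[pc[2] + 1, pc[1] + 1], Inf)
})

test_that("repositioning the tracked projector leaves the world footprint unchanged", {
  set.seed(74)
  m <- default_projector_model()
  reg <- identity_transform("image", "tracker")
  plane <- plane_surface(c(0, 0, 0), c(0, 0, 1))
  pts <- cbind(runif(10, -30, 30), runif(10, -30, 30), 0)
  plan <- surgical_plan(list(list(
    geometry = surface_mesh(pts, matrix(integer(0), 0, 3)),
    role = "target", color = c(1, 1, 1), opacity = 1)))
  footprint <- function(pose) {
    fb <- render_scene(plan, m, pose, reg)
    t(apply(fb$point_pixels, 1, function(r)
      intersect_ray(cast_ray(m, pose, r[c("u", "v")]), plane)))
  }
  f1 <- footprint(down_pose(m, 280, jitter = c(-15, 10)))
  f2 <- footprint(down_pose(m, 380, jitter = c(25, -20)))
  expect_lt(max(abs(f1 - f2)), 1e-6)
  expect_lt(max(abs(f1 - pts)), 1e-6)
})

test_that("pointer position maps to the slice index contract", {
  vol <- volume_image(array(0, c(30, 30, 30)), spacing = c(0.3, 0.3, 0.3),
                      origin = c(0, 0, 0))
  reg <- identity_transform("image", "tracker")
  expect_identical(pointer_to_slice(reg, vol, c(0.1, 0.1, 3.0), "axial"), 10L)
  expect_identical(pointer_to_slice(reg, vol, c(0, 0, 0), "axial"), 0L)
  expect_identical(pointer_to_slice(reg, vol, c(0, 0, 99), "axial",
                                    clamp = TRUE), 29L)
  expect_error(pointer_to_slice(reg, vol, c(0, 0, 99), "axial"), "clamp")
  # registration offset is honoured
  reg2 <- rigid_transform(diag(3), c(0, 0, 100), "image", "tracker")
  expect_identical(pointer_to_slice(reg2, vol, c(0, 0, 103.0), "axial"), 10L)
})

test_that("proximity alert reports inside state and distance to the margin", {
  mk <- sphere_mask(radius = 5, spacing = 0.5, pad = 5, structure = "margin")
  reg <- identity_transform("image", "tracker")
  inside <- proximity_alert(c(1, 0, 0), mk, reg)
  expect_true(inside$inside)
  expect_identical(inside$distance_to_margin, 0)
  out <- proximity_alert(c(8, 0, 0), mk, reg)
  expect_false(out$inside)
  half_diag <- sqrt(3) * 0.5 / 2
  expect_lt(abs(out$distance_to_margin - 3), half_diag + 1e-9)
  # a tip outside the volume still gets a distance
  far <- proximity_alert(c(60, 0, 0), mk, reg)
  expect_false(far$inside)
  expect_gt(far$distance_to_margin, 40)
  empty <- label_mask(array(0, c(4, 4, 4)), structure = "margin")
  expect_error(proximity_alert(c(0, 0, 0), empty, reg), "empty margin")
})
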