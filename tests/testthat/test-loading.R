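# Occlusal load construction, projection identities, rigid-motion
# metrics, and foundation calibration.

test_that("projected area follows the sin(beta) closed forms", {
  b <- mesh_box(c(3, 2, 1), n = c(3, 2, 1))
  expect_equal(projected_area(b, "zmax"), 6, tolerance = 1e-12)  # horizontal
  expect_equal(projected_area(b, "xmax"), 0, tolerance = 1e-12)  # vertical
  h <- hemisphere_surface(r = 1.5)
  # S = 2 pi r^2 projects to the disc pi r^2
  expect_equal(projected_area(h, "hemisphere"), pi * 1.5^2,
               tolerance = 0.01 * pi * 1.5^2)
})

test_that("block pressure is force over area", {
  expect_equal(block_pressure(100, 100), 1)   # molar-scale area
  expect_equal(block_pressure(100, 10), 10)   # canine-scale area
  expect_equal(block_pressure(100, 50), 2 * block_pressure(100, 100))
  expect_error(block_pressure(100, 0), "positive")
})

test_that("single-block loads act only on that block and sum to F0", {
  m <- fast_mesh()
  f <- build_load_case(load_case("II", "asymmetric-right"), m)
  expect_equal(sum(f), -100, tolerance = 1e-9)
  loaded <- which(matrix(f, ncol = 3, byrow = TRUE)[, 3] != 0)
  canine <- unique(as.vector(m$facets[m$facet_patch == "occlusal_II_right", ]))
  expect_true(all(loaded %in% canine))
  # horizontal components are never loaded
  expect_true(all(f[-seq(3, length(f), by = 3)] == 0))
  expect_error(build_load_case(load_case("II"), mesh_box()), "missing patch")
})

test_that("uniform-all distributes force by projected patch area", {
  m <- fast_mesh()
  f <- build_load_case(load_case(sidedness = "uniform-all", F0 = 80), m)
  fz <- matrix(f, ncol = 3, byrow = TRUE)[, 3]
  patches <- rcdlife:::case_patches(load_case(sidedness = "uniform-all"))
  S0 <- vapply(patches, function(p) projected_area(m, p), 0)
  Fp <- vapply(patches, function(p) {
    ids <- unique(as.vector(m$facets[m$facet_patch == p, ]))
    -sum(fz[ids])
  }, 0)
  expect_equal(sum(Fp), 80, tolerance = 1e-9)
  expect_equal(Fp / sum(Fp), S0 / sum(S0), tolerance = 1e-9)
})

test_that("curved and flat occlusal surfaces carry the same total force", {
  flat <- patch_only_mesh(rbind(c(0, 0, 1), c(2, 0, 1),
                                c(2, 2, 1), c(0, 2, 1)))
  warped <- patch_only_mesh(rbind(c(0, 0, 1), c(2, 0, 1.8),
                                  c(2, 2, 1.1), c(0, 2, 0.4)))
  cs <- load_case("I", "asymmetric-right", F0 = 50)
  for (mm in list(flat, warped)) {
    f <- build_load_case(cs, mm)
    expect_equal(sum(f), -50, tolerance = 1e-9)
  }
  # the warped patch has a larger true area but the same projection-scaled
  # resultant: the F = int P sin(beta) dS = F0 identity
  expect_gt(patch_area(warped, "occlusal_I_right"),
            projected_area(warped, "occlusal_I_right"))
})

test_that("implausible pressures are flagged", {
  m <- fast_mesh()
  expect_warning(build_load_case(load_case("IV", "symmetric", F0 = 1), m),
                 "plausible")
})

test_that("rigid-motion fit recovers synthetic motions", {
  m <- fast_mesh()
  n <- nrow(m$nodes)
  # pure vertical translation
  t3 <- 0.37
  u <- structure(cbind(rep(0, n), 0, t3), class = "displacement_field")
  mm <- rigid_motion_metrics(u, m)
  expect_equal(mm$translation, c(0, 0, t3), tolerance = 1e-12)
  expect_lt(abs(mm$pitch) + abs(mm$roll) + abs(mm$yaw), 1e-12)
  expect_lt(mm$residual, 1e-12)
  expect_equal(mm$range_z, 0)
  # 1 degree roll (rotation about the anteroposterior y axis)
  th <- pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  u2 <- structure(m$nodes %*% t(R) - m$nodes, class = "displacement_field")
  mm2 <- rigid_motion_metrics(u2, m)
  expect_equal(mm2$roll, 1, tolerance = 1e-3)
  expect_lt(abs(mm2$pitch), 1e-3)
})

test_that("vertical-only loading produces no significant yaw", {
  m <- fast_mesh()
  sys <- fast_system()
  for (cs in list(load_case("I", "symmetric"),
                  load_case("III", "asymmetric-right"))) {
    u <- solve_system(sys, build_load_case(cs, m))
    expect_lt(abs(rigid_motion_metrics(u, m)$yaw), 0.01)
  }
})

test_that("calibration nulls pitch/roll and bounds the movement range", {
  m <- fast_mesh()
  mats <- material_set()
  cal <- fast_calibrated()
  rep <- attr(cal, "report")
  expect_lt(abs(rep$after$pitch), 0.01)
  expect_lt(abs(rep$after$roll), 0.01)
  expect_lte(rep$after$range_z, 0.02)
  # a calibrated spec is a fixed point: recalibration returns it unchanged
  cal2 <- calibrate_foundation(m, mats, cal)
  expect_identical(cal2$k_segments, cal$k_segments)
  expect_identical(attr(cal2, "report")$evaluations, 1L)
})

test_that("a perturbed segment unbalances pitch and is recalibrated", {
  m <- fast_mesh()
  mats <- material_set()
  cal <- fast_calibrated()
  ks <- cal$k_segments
  ks["1"] <- ks["1"] / 2      # soften the anterior mucosa segments
  pert <- foundation_spec(k_segments = ks, k_seal = cal$k_seal,
                          k_retention = cal$k_retention)
  u <- solve_static(m, mats, pert, load_case(sidedness = "uniform-all"))$u
  before <- rigid_motion_metrics(u, m)
  expect_gt(abs(before$pitch), 0.01)
  fixed <- calibrate_foundation(m, mats, pert)
  after <- attr(fixed, "report")$after
  expect_lt(abs(after$pitch), 0.01)
  expect_lte(after$range_z, 0.02)
})

test_that("displacement-dependent compliance converges by secant iteration", {
  m <- fast_mesh()
  mats <- material_set()
  base <- fast_calibrated()
  nl <- foundation_spec(k_segments = base$k_segments, k_seal = base$k_seal,
                        k_retention = base$k_retention, c1 = 2)
  lin <- solve_static(m, mats, base, load_case(sidedness = "uniform-all"))
  expect_identical(lin$iterations, 1L)
  s <- solve_static(m, mats, nl, load_case(sidedness = "uniform-all"))
  expect_gt(s$iterations, 1L)
  expect_true(all(is.finite(unclass(s$u))))
  # growing compliance softens the support: larger settlement than linear
  expect_gt(max(abs(unclass(s$u)[, 3])), max(abs(unclass(lin$u)[, 3])))
})
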