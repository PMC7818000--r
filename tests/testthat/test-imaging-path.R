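# the 4f relay with equal small lenses and a camera, used throughout
relay_path <- function(d1 = 10, d2 = 10, camera = 10)
  widefield_path(d1 = d1, d2 = d2, camera = camera)

test_that("single-ray tracing records planes and applies the blocking rule", {
  path <- relay_path()
  tr <- trace_path(path, ray(6, 0))
  expect_true(tr$blocked)
  expect_equal(tr$blocked_at, 50)        # first lens, |y| = 6 > 5
  expect_true(all(diff(tr$samples$z) >= 0))
  frozen <- tr$samples[tr$samples$z >= 50, ]
  expect_true(all(frozen$y == frozen$y[1L]))

  tr <- trace_path(path, ray(0, 0.05))
  expect_false(tr$blocked)
  expect_equal(tr$ray$z, 200)
  expect_equal(c(tr$ray$y, tr$ray$theta), c(0, -0.05), tolerance = 1e-12)

  open_path <- imaging_path(optical_space(50), lens(50), optical_space(50))
  expect_false(trace_path(open_path, ray(40, 0.3))$blocked)
})

test_that("aperture stop follows the height-to-diameter ratio rule", {
  as_ <- aperture_stop(relay_path(10, 10))
  expect_equal(as_$z, 50)                # tie resolved toward smallest z
  expect_equal(as_$diameter, 10)
  expect_equal(as_$label, "First lens")

  as_ <- aperture_stop(relay_path(25, 12))
  expect_equal(as_$z, 150)
  expect_equal(as_$diameter, 12)
  expect_equal(as_$label, "Second lens")

  # one lens plus a trailing aperture: the ratio picks the limiting element
  p <- imaging_path(optical_space(50), lens(50, diameter = 25),
                    optical_space(25), aperture(10, "iris"),
                    optical_space(75))
  # axial test ray heights: 50 at the lens (ratio 4), 25 at the iris (ratio 5)
  expect_equal(aperture_stop(p)$label, "iris")

  expect_error(aperture_stop(imaging_path(optical_space(10))),
               "no aperture stop")
})

test_that("axial ray grazes the aperture stop and scales with its diameter", {
  expect_equal(axial_ray(relay_path(10, 10))$theta, 0.1)
  expect_equal(axial_ray(relay_path(20, 25))$theta, 0.2)  # doubled AS
  expect_equal(axial_ray(relay_path(25, 12))$theta, 0.12)
})

test_that("marginal, chief and principal rays hit their defining planes", {
  path <- relay_path(10, 10)
  mr <- marginal_rays(path, 1)
  expect_equal(sort(c(mr[[1]]$theta, mr[[2]]$theta)), c(-0.12, 0.08))
  planes_m <- compose(list(optical_space(50)))
  for (r in mr)
    expect_equal(abs(planes_m$A * r$y + planes_m$B * r$theta), 5,
                 tolerance = 1e-12)
  m0 <- marginal_rays(path, 0)
  expect_equal(m0[[1]]$theta, axial_ray(path)$theta)

  cr <- chief_ray(path, 1)
  expect_equal(cr$theta, -0.02)
  expect_equal(planes_m$A * cr$y + planes_m$B * cr$theta, 0,
               tolerance = 1e-12)
  expect_equal(chief_ray(path, 0)$theta, 0)

  pr <- principal_ray(path)
  expect_equal(pr$y, 2.5)
  expect_equal(pr$theta, -0.05)
  # the principal ray grazes the field stop edge
  fs <- field_stop(path)
  m_fs <- compose(list(optical_space(50), lens(50), optical_space(100)))
  expect_equal(abs(m_fs$A * pr$y + m_fs$B * pr$theta), fs$diameter / 2,
               tolerance = 1e-12)
})

test_that("field stop identification matches the chief-ray scan by hand", {
  fs <- field_stop(relay_path(10, 10))
  expect_equal(fs$z, 150)                 # second lens limits at y0 = 2.5
  expect_equal(fs$label, "Second lens")

  fs <- field_stop(relay_path(25, 12))
  expect_equal(fs$z, 200)
  expect_equal(fs$label, "Camera")

  # removing the camera aperture leaves the FS at the second lens
  p <- imaging_path(system4f(50, 50, diameter1 = 10, diameter2 = 10,
                             label2 = "Second lens"))
  expect_equal(field_stop(p)$label, "Second lens")
})

test_that("field of view and Lagrange invariant follow the stop geometry", {
  path <- relay_path(10, 10)
  expect_equal(field_of_view(path), 5)
  expect_equal(lagrange_invariant(path), 0.25)
  # image size = |final magnification| x FOV for the -1 relay
  conj <- intermediate_conjugates(path)
  expect_equal(abs(conj$magnification[nrow(conj)]) * field_of_view(path), 5)
  # doubling the FS diameter doubles the FOV
  p2 <- imaging_path(system4f(50, 50, diameter1 = 10, diameter2 = 20,
                              label2 = "Second lens"))
  p1 <- imaging_path(system4f(50, 50, diameter1 = 10, diameter2 = 10,
                              label2 = "Second lens"))
  expect_equal(field_of_view(p2), 2 * field_of_view(p1))
  # scaling every aperture by k scales H by k^2
  pk <- relay_path(30, 30, camera = 30)
  expect_equal(lagrange_invariant(pk), 9 * lagrange_invariant(path))
})

test_that("axial/principal rays transmit; rays beyond the envelope block", {
  for (seed in 1:20) {
    path <- random_stoppable_system(seed * 101)
    th_a <- axial_ray(path)$theta
    pr <- principal_ray(path)
    expect_false(trace_path(path, ray(0, th_a))$blocked)
    expect_false(trace_path(path, pr)$blocked)
    expect_true(trace_path(path, ray(0, th_a * (1 + 1e-6)))$blocked)
    beyond <- chief_ray(path, pr$y * (1 + 1e-6))
    expect_true(trace_path(path, beyond)$blocked)
  }
})

test_that("the principal/axial invariant is constant at every plane of a trace", {
  for (seed in 1:20) {
    path <- random_stoppable_system(seed * 211)
    H <- lagrange_invariant(path)
    t1 <- trace_path(path, principal_ray(path))
    t2 <- trace_path(path, axial_ray(path))
    inv <- t1$samples$n *
      (t1$samples$y * t2$samples$theta - t2$samples$y * t1$samples$theta)
    expect_equal(inv, rep(H, length(inv)), tolerance = 1e-9)
  }
})

test_that("conjugate planes are found at boundaries and inside spaces", {
  conj <- intermediate_conjugates(relay_path(10, 10))
  expect_equal(conj$z, 200)
  expect_equal(conj$magnification, -1)

  expect_equal(nrow(intermediate_conjugates(
    imaging_path(optical_space(80)))), 0)

  # an off-boundary conjugate: object at 2f of a lens images at 2f beyond,
  # in the middle of the trailing space
  p <- imaging_path(optical_space(100), lens(50), optical_space(250))
  conj <- intermediate_conjugates(p)
  expect_equal(conj$z[1], 200)
  expect_equal(conj$magnification[1], -1, tolerance = 1e-12)
})

test_that("subpath_from rebases the object plane and splits spaces", {
  path <- relay_path(10, 10)
  sub <- subpath_from(path, 30)
  expect_equal(path_length(sub), 170)
  # rebasing the object changes the stop geometry: the axial test ray from
  # z = 30 reaches 20 mm height at the first lens (ratio 4) but 80 mm at
  # the second (ratio 16), which becomes the AS
  expect_equal(aperture_stop(sub)$z, 120)
  expect_equal(aperture_stop(sub)$label, "Second lens")
  # a plane strictly inside a thick element cannot become an object plane
  expect_error(subpath_from(clsm_scan_path(), 650), "non-space")
})
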