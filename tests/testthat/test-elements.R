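test_that("element constructors produce the standard paraxial matrices", {
  s <- optical_space(50)
  expect_equal(c(s$A, s$B, s$C, s$D), c(1, 50, 0, 1))
  expect_equal(s$L, 50)
  expect_equal(c(optical_space(0)$B, optical_space(0)$L), c(0, 0))

  s15 <- optical_space(10, n = 1.5)
  expect_equal(c(s15$A, s15$B, s15$C, s15$D), c(1, 10, 0, 1))
  expect_equal(s15$A * s15$D - s15$B * s15$C, 1)

  l <- lens(50)
  expect_equal(c(l$A, l$B, l$C, l$D), c(1, 0, -0.02, 1))
  expect_equal(lens(-100)$C, 0.01)

  flat <- dielectric_interface(Inf, 1, 1.5)
  expect_equal(c(flat$A, flat$B, flat$C, flat$D), c(1, 0, 0, 2 / 3))
  curved <- dielectric_interface(50, 1, 1.5)
  expect_equal(curved$C, -1 / 150)
  expect_equal(curved$D, 2 / 3)
  back <- dielectric_interface(-50, 1.5, 1)
  expect_equal(back$C, -0.01)
  expect_equal(back$D, 1.5)

  expect_error(optical_space(-1), "non-negative")
  expect_error(lens(0), "nonzero")
  expect_error(dielectric_interface(0, 1, 1.5), "nonzero")
  expect_error(aperture(0), "positive")
  expect_error(aperture(Inf), "positive")
})

test_that("thick lens equals its surface/space product and the Lensmaker form", {
  tl <- thick_lens(n = 1.5, R1 = 50, R2 = -50, thickness = 10)
  oracle <- bf_product(list(dielectric_interface(50, 1, 1.5),
                            optical_space(10, 1.5),
                            dielectric_interface(-50, 1.5, 1)))
  expect_equal(as_mat(tl), oracle, tolerance = 1e-12)
  expect_equal(tl$A, 0.93333333, tolerance = 1e-7)
  expect_equal(tl$B, 6.66666667, tolerance = 1e-7)
  expect_equal(tl$C, -0.01933333, tolerance = 1e-6)
  expect_equal(-1 / tl$C, 51.724, tolerance = 1e-4)
  expect_equal(tl$L, 10)

  # degenerate flat slab of zero thickness has no optical power
  id <- thick_lens(n = 1.5, R1 = Inf, R2 = Inf, thickness = 0)
  expect_equal(as_mat(id), diag(2))

  # closed-form Lensmaker focal length over random prescriptions
  set.seed(11)
  for (i in 1:100) {
    n <- runif(1, 1.4, 1.9)
    R1 <- sample(c(-1, 1), 1) * runif(1, 30, 200)
    R2 <- sample(c(-1, 1), 1) * runif(1, 30, 200)
    t <- runif(1, 1, 15)
    f_lensmaker <- 1 / ((n - 1) * (1 / R1 - 1 / R2 + (n - 1) * t / (n * R1 * R2)))
    tl <- thick_lens(n, R1, R2, t)
    expect_equal(-1 / tl$C, f_lensmaker, tolerance = 1e-9)
  }
})

test_that("composition multiplies right-to-left and tracks length and indices", {
  relay <- list(optical_space(50), lens(50), optical_space(100),
                lens(50), optical_space(50))
  m <- compose(relay)
  expect_equal(as_mat(m), matrix(c(-1, 0, 0, -1), 2), tolerance = 1e-12)
  expect_equal(m$L, 200)

  expect_equal(as_mat(compose(list(optical_space(12), optical_space(30)))),
               as_mat(optical_space(42)))

  single <- lens(75, diameter = 20)
  expect_identical(compose(single), single)  # identity of composition

  expect_error(compose(list(optical_space(5, n = 1.5), optical_space(5))),
               "index mismatch")
  expect_error(compose(list()), "empty")
})

test_that("determinant equals n_front/n_back for constructors and random compositions", {
  parts <- list(optical_space(50), optical_space(10, 1.5), lens(50),
                lens(-100), dielectric_interface(50, 1, 1.5),
                dielectric_interface(-50, 1.5, 1),
                thick_lens(1.5, 50, -50, 10), aperture(10),
                objective_60x_water())
  for (e in parts)
    expect_equal(e$A * e$D - e$B * e$C, e$n_front / e$n_back,
                 tolerance = 1e-10)

  set.seed(21)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    els <- list()
    n_cur <- 1
    for (j in seq_len(k)) {
      pick <- sample(1:3, 1)
      els <- c(els, list(switch(pick,
        optical_space(runif(1, 0, 100), n = n_cur),
        {
          n_next <- if (n_cur == 1) runif(1, 1.3, 1.8) else 1
          e <- dielectric_interface(sample(c(-1, 1), 1) * runif(1, 20, 200),
                                    n_cur, n_next)
          n_cur <- n_next
          e
        },
        if (n_cur == 1) lens(runif(1, 20, 200)) else optical_space(1, n_cur))))
    }
    m <- compose(els)
    expect_equal(m$A * m$D - m$B * m$C, m$n_front / m$n_back,
                 tolerance = 1e-10)
  }
})

test_that("transform_ray follows the ray recurrence, blocking rule and linearity", {
  r <- transform_ray(optical_space(50), ray(0, 0.1))
  expect_equal(c(r$y, r$theta, r$z), c(5, 0.1, 50))
  r <- transform_ray(lens(50), ray(1, 0))
  expect_equal(c(r$y, r$theta), c(1, -0.02))
  r <- transform_ray(lens(50), ray(2, 0))
  expect_equal(c(r$y, r$theta), c(2, -0.04))
  r <- transform_ray(compose(list(optical_space(50), lens(50),
                                  optical_space(100), lens(50),
                                  optical_space(50))),
                     ray(2, 0.1))
  expect_equal(c(r$y, r$theta), c(-2, -0.1), tolerance = 1e-12)

  ap <- aperture(10)
  expect_false(transform_ray(ap, ray(4.9, 0))$blocked)
  expect_false(transform_ray(ap, ray(-5.0, 0))$blocked)   # edge-inclusive
  b <- transform_ray(ap, ray(5.1, 0, z = 30))
  expect_true(b$blocked)
  expect_equal(b$blocked_at, 30)
  # blocked rays pass through later elements unchanged
  b2 <- transform_ray(lens(50), b)
  expect_identical(b2, b)

  # linearity of the unblocked map
  set.seed(31)
  M <- compose(list(optical_space(runif(1, 5, 60)), lens(runif(1, 20, 90)),
                    optical_space(runif(1, 5, 60))))
  for (i in 1:20) {
    r1 <- ray(runif(1, -2, 2), runif(1, -0.2, 0.2))
    r2 <- ray(runif(1, -2, 2), runif(1, -0.2, 0.2))
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    lin <- ray(a * r1$y + b * r2$y, a * r1$theta + b * r2$theta)
    lhs <- transform_ray(M, lin)
    t1 <- transform_ray(M, r1); t2 <- transform_ray(M, r2)
    expect_equal(lhs$y, a * t1$y + b * t2$y, tolerance = 1e-12)
    expect_equal(lhs$theta, a * t1$theta + b * t2$theta, tolerance = 1e-12)
  }
})

test_that("composition agrees with sequential element-by-element tracing", {
  set.seed(41)
  for (i in 1:50) {
    path <- random_system(1000 + i)
    M <- compose(path$elements)
    for (j in 1:20) {
      y0 <- runif(1, -1, 1); th0 <- runif(1, -0.01, 0.01)
      ex <- bf_exit(path, y0, th0)
      expect_equal(M$A * y0 + M$B * th0, unname(ex["y"]), tolerance = 1e-9)
      expect_equal(M$C * y0 + M$D * th0, unname(ex["theta"]), tolerance = 1e-9)
    }
  }
})

test_that("system properties recover focal lengths, principal planes and imaging", {
  p <- system_properties(lens(50))
  expect_equal(p$effective_focal_length_back, 50)
  expect_equal(p$principal_plane_front, 0)
  expect_equal(p$principal_plane_back, 0)

  tl <- system_properties(thick_lens(1.5, 50, -50, 10))
  expect_equal(tl$effective_focal_length_back, 51.724, tolerance = 1e-4)
  expect_equal(tl$principal_plane_back, (1 - 0.93333333) / (-0.019333333),
               tolerance = 1e-6)
  expect_equal(tl$principal_plane_back, -3.448, tolerance = 1e-3)
  expect_false(tl$is_imaging)

  relay <- system_properties(compose(list(optical_space(50), lens(50),
                                          optical_space(100), lens(50),
                                          optical_space(50))))
  expect_true(relay$is_imaging)
  expect_equal(relay$transverse_magnification, -1)
  expect_equal(relay$angular_magnification, -1)

  afocal <- system_properties(optical_space(100))
  expect_true(is.infinite(afocal$effective_focal_length_back))
  expect_false(afocal$is_imaging)

  # dissimilar media: front quantities carry the index ratio
  glass <- compose(list(dielectric_interface(50, 1, 1.5)))
  gp <- system_properties(glass)
  expect_equal(gp$effective_focal_length_back, 150)
  expect_equal(gp$effective_focal_length_front, 100)
  expect_equal(gp$front_focal_distance - gp$principal_plane_front,
               gp$effective_focal_length_front, tolerance = 1e-12)
})

test_that("optical invariant is antisymmetric and conserved by unit-determinant maps", {
  r1 <- ray(1, 0.1); r2 <- ray(0, 0.05)
  expect_equal(optical_invariant(r1, r2), 0.05)
  expect_equal(optical_invariant(r1, r1), 0)
  M <- compose(list(optical_space(50), lens(50), optical_space(100),
                    lens(50), optical_space(50)))
  expect_equal(optical_invariant(transform_ray(M, r1), transform_ray(M, r2)),
               0.05, tolerance = 1e-12)
  expect_error(optical_invariant(ray(1, 0, z = 0), ray(1, 0, z = 5)),
               "same axial position")
})

test_that("gauss_image_solve matches the thin-lens imaging law", {
  g <- gauss_image_solve(50, 100)
  expect_equal(g$di, 100)
  expect_equal(g$magnification, -1)
  g <- gauss_image_solve(50, 75)
  expect_equal(g$di, 150)
  expect_equal(g$magnification, -2)
  g <- gauss_image_solve(50, 25)
  expect_equal(g$di, -50)   # virtual image
  expect_equal(g$magnification, 2)
  expect_true(is.infinite(gauss_image_solve(50, 50)$di))

  set.seed(51)
  for (i in 1:100) {
    f <- sample(c(-1, 1), 1) * runif(1, 10, 300)
    do <- runif(1, 5, 500)
    if (abs(do - f) < 1) next
    g <- gauss_image_solve(f, do)
    expect_equal(1 / do + 1 / g$di, 1 / f, tolerance = 1e-9)
    # the imaging condition itself: B = 0 and A is the magnification
    M <- compose(list(optical_space(do), lens(f)))
    expect_equal(M$B + g$di * M$D, 0, tolerance = 1e-9 * max(1, abs(g$di)))
    expect_equal(M$A + g$di * M$C, g$magnification, tolerance = 1e-9)
  }
})
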