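# Snell refraction, direction update, amplitude splitting, ray tracing
# and aperture detection.

test_that("Snell's law: matched media, arcsin branch, TIR", {
  expect_equal(snell(1.3, 1.3, 0.7), 0.7)
  expect_equal(snell(1, 1, 0.5 / sin(0.5) * 0), 0)
  # n1 sin(theta) = 0.5 into n2 = 1: refracted at pi/6
  th <- asin(0.5 / 1.2)
  expect_equal(snell(1.2, 1, th), pi / 6, tolerance = 1e-12)
  expect_true(is.na(snell(2, 1, pi / 3)))
})

test_that("direction update: normal incidence, identity, unit norm", {
  n_hat <- c(0, 0, 1)
  expect_equal(refract_direction(-n_hat, n_hat, 1, 1.5), -n_hat)
  # matched indices leave any incident direction unchanged
  dirs <- random_unit_vectors(100, seed = 2)
  for (k in seq_len(nrow(dirs))) {
    r_hat <- dirs[k, ]
    if (r_hat[3] > -1e-3) r_hat[3] <- -abs(r_hat[3]) - 1e-3
    r_hat <- r_hat / sqrt(sum(r_hat^2))
    out <- refract_direction(r_hat, n_hat, 1.4, 1.4)
    expect_equal(out, r_hat, tolerance = 1e-12)
  }
  # unit norm across the full incidence sweep
  for (deg in seq(0, 89, by = 1)) {
    th <- deg * pi / 180
    r_hat <- c(sin(th), 0, -cos(th))
    out <- refract_direction(r_hat, n_hat, 1, 1.3)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
  }
  # TIR returns NULL
  expect_null(refract_direction(c(sin(1.2), 0, -cos(1.2)), n_hat, 2, 1))
})

test_that("two refractions across a slab invert each other", {
  n_hat <- c(0, 0, 1)
  for (deg in c(5, 25, 40)) {
    th <- deg * pi / 180
    r_in <- c(sin(th), 0, -cos(th))
    inside <- refract_direction(r_in, n_hat, 1, 1.35)
    out <- refract_direction(inside, n_hat, 1.35, 1)
    expect_equal(out, r_in, tolerance = 1e-12)
  }
})

test_that("amplitude split conserves the incident amplitude exactly", {
  sp <- split_amplitude(1, 3, 3)
  expect_equal(sp$transmitted, 1)
  expect_equal(sp$reflected, 0)
  # tissue into LiNbO3: reflected 0.915, transmitted the exact remainder
  z_ln <- acoustic_impedance(get_material("LiNbO3"))
  sp2 <- split_amplitude(1, 1.5, z_ln)
  expect_equal(sp2$reflected, 0.915, tolerance = 1e-3)
  expect_equal(sp2$transmitted, 1 - sp2$reflected)
  expect_equal(sp2$transmitted + sp2$reflected, 1, tolerance = 1e-15)
  # rigid-boundary limit
  sp3 <- split_amplitude(2, 1, 1e12)
  expect_equal(sp3$reflected, 2, tolerance = 1e-11)
  expect_equal(sp3$transmitted, 0, tolerance = 1e-11)
  # the pressure-continuity alternative: T = 1 + R
  sp4 <- split_amplitude(1, 1, 3, mode = "pressure")
  expect_equal(sp4$transmitted, 1.5)
  expect_equal(sp4$reflected, 0.5)
})

test_that("mirror reflection composed twice restores the direction", {
  n_hat <- c(0, 1, 0)
  set.seed(8)
  for (k in 1:20) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    refl <- d - 2 * sum(d * n_hat) * n_hat
    back <- refl - 2 * sum(refl * n_hat) * n_hat
    expect_equal(back, d, tolerance = 1e-15)
  }
})

test_that("homogeneous scenes give straight single-segment rays", {
  sc <- synthetic_scene("homogeneous",
                        params = list(dims = c(0.04, 0.04, 0.04),
                                      voxel = 0.004, base_h = 0.01))
  scene <- sc$scene
  src <- source_transducer(center = scene$source_center,
                           normal = scene$source_normal)
  rays <- trace_rays(scene, src, 1e6, n_rays = 40, seed = 5)
  expect_equal(nrow(rays$rays), 40L)
  expect_true(all(rays$rays$reason == "exit"))
  expect_true(all(rays$rays$generation == 0L))
  # unit directions
  dn <- with(rays$rays, sqrt(dx^2 + dy^2 + dz^2))
  expect_equal(dn, rep(1, 40), tolerance = 1e-12)
  # catch every forward ray on the far wall: arrival delay must equal the
  # travelled path length over the water velocity, and the arrival
  # amplitude must equal the emitted amplitude times exp(-alpha d)
  rec <- collect_echo(rays, c(0.04, 0.02, 0.02), 10, 1e6,
                      detector_normal = c(1, 0, 0), threshold = 0)
  expect_gt(nrow(rec), 0)
  rr <- rays$rays
  crossing <- (0.04 - rr$x0) / rr$dx
  seg_len <- with(rr, sqrt((x1 - x0)^2 + (y1 - y0)^2 + (z1 - z0)^2))
  hits <- which(crossing > 0 & crossing <= seg_len * (1 + 1e-6))
  d_exp <- sort(crossing[hits])
  expect_equal(sort(rec$time), d_exp / 1482, tolerance = 1e-12)
  al <- propagation_coefficient(get_material("Water"), 1e6)$alpha
  expect_equal(sort(abs(rec$amplitude), decreasing = TRUE),
               sort((10 / 40) * exp(-al * d_exp), decreasing = TRUE),
               tolerance = 1e-12)
})

test_that("ray tracing is deterministic under a fixed seed", {
  scene <- breast_lens_scene()
  src <- source_transducer(center = scene$source_center,
                           normal = scene$source_normal)
  r1 <- trace_rays(scene, src, 2e6, n_rays = 24, seed = 42)
  r2 <- trace_rays(scene, src, 2e6, n_rays = 24, seed = 42)
  expect_identical(r1$rays, r2$rays)
  expect_gt(sum(r1$rays$reason == "interface"), 0)
})

test_that("enlarging the aperture never loses echo records", {
  scene <- breast_lens_scene()
  src <- source_transducer(center = scene$source_center,
                           normal = scene$source_normal)
  rays <- trace_rays(scene, src, 2e6, n_rays = 48, seed = 3)
  counts <- vapply(seq(0.01, 0.07, by = 0.01), function(ap) {
    nrow(collect_echo(rays, src$center, ap, 2e6,
                      detector_normal = src$normal))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(max(counts), 0)
})

test_that("geometric misses are not recorded", {
  rays <- list(rays = data.frame(
    x0 = 0.5, y0 = 1, z0 = 0, x1 = -0.5, y1 = 1, z1 = 0,
    dx = -1, dy = 0, dz = 0, amp = 1, atten = 1, delay = 1e-5,
    wavelengths = 10, generation = 0L, v = 1500, alpha = 0,
    reason = "exit"))
  class(rays) <- "us_rays"
  rec <- collect_echo(rays, c(0, 0, 0), 0.01, 1e6,
                      detector_normal = c(1, 0, 0))
  expect_equal(nrow(rec), 0L)
})

test_that("detection threshold and cap are enforced bit-exactly", {
  set.seed(31)
  n <- 1201L
  rec <- data.frame(time = stats::runif(n, 0, 1e-4),
                    amplitude = stats::runif(n, 2e-5, 1e-2))
  out <- filter_echo_records(rec, threshold = 1e-5, cap = 1200L)
  expect_identical(nrow(out), 1200L)
  # the dropped record is exactly the smallest amplitude
  expect_identical(sort(out$amplitude),
                   sort(rec$amplitude)[-1])
  # sub-threshold arrivals are dropped
  rec2 <- data.frame(time = c(1e-5, 2e-5), amplitude = c(5e-6, 2e-5))
  out2 <- filter_echo_records(rec2, threshold = 1e-5, cap = 1200L)
  expect_identical(out2$amplitude, 2e-5)
})
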