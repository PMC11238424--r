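test_that("nematic differences wrap into [-pi/2, pi/2)", {
  expect_equal(nematic_diff(0.3, 0.3), 0)
  deg <- pi / 180
  expect_equal(nematic_diff(80 * deg, -80 * deg), -20 * deg)
  grid <- seq(-180, 179, by = 1) * deg
  d <- outer(grid, grid, nematic_diff)
  expect_true(all(d >= -pi / 2 & d < pi / 2))
  expect_true(all(abs(d) <= pi / 2))
  # consistency: difference is pi-periodic in both arguments
  expect_equal(nematic_diff(grid + pi, 0), nematic_diff(grid, 0))
})

test_that("structure tensor reads stripe patterns and is rotation equivariant", {
  H <- 80; W <- 80
  xs <- (col(matrix(0, H, W)) - 0.5 - W / 2)
  ys <- (H / 2 - row(matrix(0, H, W)) + 0.5)
  stripes <- function(axis_deg, wavelength = 10) {
    a <- axis_deg * pi / 180
    cos((xs * cos(a + pi / 2) + ys * sin(a + pi / 2)) * 2 * pi / wavelength)
  }
  # varying along x only -> structure axis vertical (boundary representative)
  th_x <- structure_tensor_orientation(stripes(90), 6)
  inner <- th_x[20:60, 20:60]
  expect_lt(max(abs(abs(inner[!is.na(inner)]) - pi / 2)), 1e-6)
  th20 <- structure_tensor_orientation(stripes(20), 6)
  expect_equal(median(th20, na.rm = TRUE), 20 * pi / 180, tolerance = 0.02)
  # rotating the image by 90 deg rotates theta by 90 modulo pi
  img <- stripes(20)
  rot <- t(img)[, H:1] # 90 deg CCW in the y-up frame
  th_rot <- structure_tensor_orientation(rot, 6)
  d <- nematic_diff(th_rot[25:55, 25:55], th20[25:55, 25:55] + pi / 2)
  expect_lt(median(abs(d), na.rm = TRUE), 0.03)
})

test_that("flat regions are masked rather than assigned an angle", {
  flat <- matrix(5, 50, 50)
  th <- structure_tensor_orientation(flat, 6)
  expect_true(all(is.na(th)))
})

test_that("field orientation matches simulator ground truth", {
  # single rod at 30 degrees
  init <- list(x = 0, y = 0, angle = 30 * pi / 180, length = 4, speed = 0)
  p <- sim_params(n_rods = 1, well_radius = 6, speed = 0, noise_trans = 0,
                  noise_rot = 0, growth_rate = 0, duration = 0.0263, seed = 1)
  m <- simulate_rods(p, init = init)
  opt <- optics_params(dim_px = c(80, 80))
  st <- render_frames(m, opt, seed = 2)
  gt <- ground_truth(m, opt)
  th <- structure_tensor_orientation(st$frames[, , 1], 6)
  on_rod <- !is.na(gt$theta[, , 1])
  med <- median(th[on_rod], na.rm = TRUE)
  expect_lt(abs(med - 30 * pi / 180), 2 * pi / 180)
  # crowded scene: median error below 5 degrees
  fx <- rod_fixture(area_fraction = 0.3, seed = 4)
  f <- orientation_field(fx$stack, 6)
  err <- abs(nematic_diff(f$theta[, , 1], fx$gt$theta[, , 1]))
  expect_lt(median(err[!is.na(err)]), 5 * pi / 180)
})

test_that("orientational correlator: frozen, closed-form rotation, decorrelated", {
  set.seed(11)
  th0 <- matrix(runif(100, -pi / 2, pi / 2), 10, 10)
  frozen <- structure(list(theta = array(th0, c(10, 10, 4)), sigma_px = 6,
                           pixel_size = 1, frame_interval = 1),
                      class = "orientation_field")
  cc <- orientational_correlation(frozen, 1:2)
  expect_equal(cc$values, c(1, 1))
  # uniform field advancing pi/4 per frame: C(1 frame) = cos(pi/2) = 0
  th_rot <- array(0, c(8, 8, 3))
  for (t in 1:3) th_rot[, , t] <- ((t - 1) * pi / 4 + pi / 2) %% pi - pi / 2
  rotf <- structure(list(theta = th_rot, sigma_px = 6, pixel_size = 1,
                         frame_interval = 1), class = "orientation_field")
  cr <- orientational_correlation(rotf, 1)
  expect_equal(cr$values, 0, tolerance = 1e-12)
  # i.i.d. uniform nematic angles: C ~ 0
  set.seed(12)
  iid <- structure(list(theta = array(runif(30 * 30 * 40, -pi / 2, pi / 2),
                                      c(30, 30, 40)),
                        sigma_px = 6, pixel_size = 1, frame_interval = 1),
                   class = "orientation_field")
  ci <- orientational_correlation(iid, c(1, 5))
  expect_lt(max(abs(ci$values)), 0.02)
})

test_that("orientational correlator and chi4 match the double-loop oracle", {
  set.seed(13)
  th <- array(runif(5 * 6 * 4, -pi / 2, pi / 2), c(5, 6, 4))
  f <- structure(list(theta = th, sigma_px = 6, pixel_size = 1,
                      frame_interval = 1), class = "orientation_field")
  cc <- orientational_correlation(f, 1:2)
  chi <- chi4_orientation(cc, 0.6)
  orc <- oracle_ctheta(th, 1:2, 0.6)
  expect_equal(cc$values, orc$C, tolerance = 1e-12)
  expect_equal(chi$chi4, orc$chi4, tolerance = 1e-12)
  expect_true(all(chi$chi4 >= 0))
  # two-valued samples {-1, 1} with phi = 1 give chi4 = 1
  rc <- relaxation_curve(1, list(c(-1, 1)), type = "orientation")
  expect_equal(chi4_orientation(rc, 1)$chi4, 1)
})

test_that("orientation gradient: uniform, linear ramp, wrapped boundary", {
  expect_equal(orientation_gradient_sq(matrix(0.7, 10, 10), pixel_size = 0.5),
               matrix(0, 10, 10))
  k <- 0.02
  ramp <- outer(rep(1, 20), k * (1:20)) # theta = k * x(px)
  g <- orientation_gradient_sq(ramp, pixel_size = 1)
  expect_equal(g[5:15, 5:15], matrix(k^2, 11, 11), tolerance = 1e-10)
  # sharp 0 | 85deg boundary: wrapped difference, no pi-jump artifact
  half <- cbind(matrix(0, 12, 6), matrix(85 * pi / 180, 12, 6))
  gh <- orientation_gradient_sq(half, pixel_size = 1)
  jump <- nematic_diff(85 * pi / 180, 0) # = -95 deg wrapped
  # loop oracle on the same stencil
  oracle <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    jm <- max(1, j - 1); jp <- min(12, j + 1)
    dx <- nematic_diff(half[i, jp], half[i, jm]) / (jp - jm)
    oracle[i, j] <- dx^2
  }
  expect_equal(gh, oracle, tolerance = 1e-12)
  ridge_cols <- which(colSums(gh) > 0)
  expect_true(all(ridge_cols %in% 5:8)) # finite ridge of ~2 px
})

test_that("microdomain segmentation recovers constructed mosaics", {
  px <- 0.3
  uni <- matrix(0.2, 30, 30)
  ds <- segment_microdomains(uni, threshold = 1e-2, pixel_size = px)
  expect_equal(nrow(ds$table), 1)
  expect_equal(ds$table$area_px, 900)
  two <- cbind(matrix(0, 30, 15), matrix(1, 30, 15))
  ds2 <- segment_microdomains(two, threshold = 1e-2, pixel_size = px)
  expect_equal(nrow(ds2$table), 2)
  # Voronoi mosaic of constant-angle patches
  set.seed(14)
  H <- 120; k <- 6
  cx <- runif(k, 1, H); cy <- runif(k, 1, H)
  angles <- seq(-1.2, 1.2, length.out = k)
  idx <- matrix(0L, H, H)
  for (i in 1:H) for (j in 1:H)
    idx[i, j] <- which.min((cx - j)^2 + (cy - i)^2)
  theta <- matrix(angles[idx], H, H) + matrix(rnorm(H * H, 0, 0.005), H, H)
  ds3 <- segment_microdomains(theta, threshold = 1e-2, pixel_size = px)
  # each recovered domain should match its eroded generating patch to 5%
  expect_equal(nrow(ds3$table), k)
  interior <- function(pid) { # patch pixels whose +-1 px stencil stays inside
    m <- idx == pid
    ok <- m
    ok[2:(H - 1), 2:(H - 1)] <- m[2:(H - 1), 2:(H - 1)] &
      m[1:(H - 2), 2:(H - 1)] & m[3:H, 2:(H - 1)] &
      m[2:(H - 1), 1:(H - 2)] & m[2:(H - 1), 3:H]
    sum(ok)
  }
  for (d in seq_len(nrow(ds3$table))) {
    dom_px <- ds3$table$area_px[d]
    pid <- idx[which(ds3$labels == ds3$table$domain_id[d], arr.ind = TRUE)[1, , drop = FALSE]]
    expect_lt(abs(dom_px - interior(pid)) / interior(pid), 0.05)
  }
  # empty result under an impossible threshold
  noisy <- matrix(runif(400, -pi / 2, pi / 2), 20, 20)
  expect_warning(es <- segment_microdomains(noisy, threshold = 1e-9,
                                            pixel_size = px), "empty")
  expect_equal(nrow(es$table), 0)
})

test_that("adding a constant angle changes neither gradients nor domains", {
  set.seed(15)
  H <- 60
  idx <- matrix(sample(1:3, H * H, replace = TRUE), H, H)
  idx <- matrix(as.integer(bactglass:::gaussian_smooth(idx, 4) > 2) + 1L, H, H)
  theta <- matrix(c(-0.5, 0.4, 1.2)[idx], H, H)
  g0 <- orientation_gradient_sq(theta, pixel_size = 0.3)
  d0 <- segment_microdomains(theta, threshold = 1e-2, pixel_size = 0.3)
  for (delta in c(0.4, 1.1)) {
    shifted <- nematic_diff(theta + delta, 0)
    g1 <- orientation_gradient_sq(shifted, pixel_size = 0.3)
    expect_equal(g1, g0, tolerance = 1e-10)
    d1 <- segment_microdomains(shifted, threshold = 1e-2, pixel_size = 0.3)
    expect_equal(d1$table$area_px, d0$table$area_px)
  }
})

test_that("exponential MLE recovers the domain-area scale", {
  set.seed(16)
  A0 <- 8.3; n <- 1e4; A_min <- 0.5
  areas <- A_min + rexp(n, 1 / A0)
  fit <- fit_domain_areas(areas, A_min = A_min)
  expect_lt(abs(fit$A0 - A0), 3 * A0 / sqrt(n))
  expect_true(fit$ci[1] < A0 && A0 < fit$ci[2])
  expect_error(fit_domain_areas(areas[1:10]), "30")
  expect_warning(fit_domain_areas(rep(2, 50), A_min = 2), "degenerate")
})

test_that("the fitted area scale is insensitive to the boundary threshold", {
  set.seed(17)
  H <- 150; k <- 40
  cx <- runif(k, 1, H); cy <- runif(k, 1, H)
  angles <- runif(k, -pi / 2, pi / 2)
  idx <- matrix(0L, H, H)
  for (i in 1:H) for (j in 1:H)
    idx[i, j] <- which.min((cx - j)^2 + (cy - i)^2)
  theta <- matrix(angles[idx], H, H) + matrix(rnorm(H * H, 0, 0.005), H, H)
  a1 <- segment_microdomains(theta, threshold = 1e-2, pixel_size = 0.3)$table$area_um2
  a2 <- segment_microdomains(theta, threshold = 2e-2, pixel_size = 0.3)$table$area_um2
  f1 <- fit_domain_areas(a1)
  f2 <- fit_domain_areas(a2)
  expect_lt(abs(f2$A0 - f1$A0) / f1$A0, 0.10)
})
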