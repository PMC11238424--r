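test_that("quiescent non-overlapping rods are a fixed point of the dynamics", {
  init <- list(x = c(-3, 2, 0), y = c(0, 1, -3), angle = c(0.3, -0.8, 1.1),
               length = c(3, 4, 3.5), speed = c(0, 0, 0))
  p <- sim_params(n_rods = 3, well_radius = 10, speed = 0, noise_trans = 0,
                  noise_rot = 0, growth_rate = 0, duration = 0.5, seed = 1)
  m <- simulate_rods(p, init = init)
  last <- m[[length(m)]]
  expect_equal(last$x, init$x, tolerance = 1e-12)
  expect_equal(last$y, init$y, tolerance = 1e-12)
  expect_equal(last$angle, init$angle, tolerance = 1e-12)
})

test_that("a free rod self-propels along its body axis at its speed", {
  init <- list(x = -3, y = 0, angle = 0.4, speed = 1.5, length = 3)
  p <- sim_params(n_rods = 1, well_radius = 30, speed = 1.5, noise_trans = 0,
                  noise_rot = 0, growth_rate = 0, duration = 2, seed = 1)
  m <- simulate_rods(p, init = init)
  last <- m[[length(m)]]
  expect_equal(last$x - init$x, 1.5 * cos(0.4) * last$time, tolerance = 1e-9)
  expect_equal(last$y - init$y, 1.5 * sin(0.4) * last$time, tolerance = 1e-9)
})

test_that("total rod area grows exponentially through growth and division", {
  p <- sim_params(n_rods = 10, well_radius = 15, speed = 0, noise_trans = 0,
                  noise_rot = 0, k_rep = 50, growth_rate = 0.01,
                  division_length = 5, duration = 70, frame_interval = 0.5,
                  dt = 5e-3, seed = 7)
  m <- simulate_rods(p)
  area <- function(e) sum((e$length - p$width) * p$width + pi * (p$width / 2)^2)
  t_end <- m[[length(m)]]$time
  ratio <- area(m[[length(m)]]) / area(m[[1]])
  expect_lt(abs(ratio / exp(0.01 * t_end) - 1), 0.05)
  # daughters record their mother and rod count never decreases
  counts <- vapply(m, function(e) length(e$x), integer(1))
  expect_true(all(diff(counts) >= 0))
  last <- m[[length(m)]]
  expect_true(all(last$parent[last$id > 10] > 0))
})

test_that("rod centers never leave the well and angles stay in the nematic range", {
  p <- sim_params(area_fraction = 0.6, well_radius = 6, speed = 2,
                  duration = 1, growth_rate = 0, seed = 3)
  m <- simulate_rods(p)
  for (e in m) {
    expect_true(all(sqrt(e$x^2 + e$y^2) <= e$well_radius + 1e-9))
    expect_true(all(e$angle >= -pi / 2 & e$angle < pi / 2))
  }
})

test_that("simulation and rendering are reproducible from their seeds", {
  p <- sim_params(n_rods = 12, well_radius = 7, duration = 0.3, seed = 11)
  m1 <- simulate_rods(p); m2 <- simulate_rods(p)
  expect_identical(m1[[length(m1)]]$x, m2[[length(m2)]]$x)
  opt <- optics_params(dim_px = c(90, 90))
  s1 <- render_frames(m1, opt, seed = 5)
  s2 <- render_frames(m2, opt, seed = 5)
  expect_identical(s1$frames, s2$frames)
})

test_that("an empty scene renders as background plus noise only", {
  p <- sim_params(n_rods = 1, well_radius = 6, duration = 0.05, speed = 0,
                  noise_trans = 0, noise_rot = 0, growth_rate = 0, seed = 1)
  m <- simulate_rods(p, init = list(x = 0, y = 0, angle = 0, length = 3, speed = 0))
  for (i in seq_along(m)) m[[i]]$x <- m[[i]]$x + 100 # move rod out of frame
  opt <- optics_params(dim_px = c(50, 50), noise_sd = 0.01)
  st <- suppressWarnings(render_frames(m, opt, seed = 2, allow_partial_fov = TRUE))
  expect_lt(abs(mean(st$frames) - opt$background), 0.005)
  expect_lt(abs(sd(as.numeric(st$frames)) - opt$noise_sd), 0.002)
  expect_error(render_frames(list(), opt), "empty")
})

test_that("rendered dark area matches the analytic spherocylinder area", {
  init <- list(x = 0, y = 0, angle = 30 * pi / 180, length = 4, speed = 0)
  p <- sim_params(n_rods = 1, well_radius = 6, speed = 0, noise_trans = 0,
                  noise_rot = 0, growth_rate = 0, duration = 0.0263, seed = 1)
  m <- simulate_rods(p, init = init)
  opt <- optics_params(dim_px = c(80, 80), blur_sigma_um = 0, noise_sd = 0)
  st <- render_frames(m, opt, seed = 1)
  n_dark <- sum(st$frames[, , 1] < (opt$background + opt$rod_level) / 2)
  L <- 4; w <- 1
  analytic_px <- ((L - w) * w + pi * (w / 2)^2) / opt$pixel_size^2
  perimeter_px <- (2 * (L - w) + pi * w) / opt$pixel_size
  expect_lt(abs(n_dark - analytic_px), perimeter_px)
})

test_that("ground truth carries nematic angles, identities, and exact coverage", {
  # horizontal rod: theta = 0 on covered pixels; pi-rotated rod identical
  mk <- function(ang) {
    init <- list(x = 0, y = 0, angle = ang, length = 4, speed = 0)
    p <- sim_params(n_rods = 1, well_radius = 6, speed = 0, noise_trans = 0,
                    noise_rot = 0, growth_rate = 0, duration = 0.0263, seed = 1)
    ground_truth(simulate_rods(p, init = init), optics_params(dim_px = c(70, 70)))
  }
  gt0 <- mk(0)
  th <- gt0$theta[, , 1]
  expect_true(all(th[!is.na(th)] == 0))
  # the nematic representative of a pi-rotated rod is identical
  gt_pi <- mk(wrap_pi <- ((pi + pi / 2) %% pi) - pi / 2) # pi wraps to 0
  expect_identical(gt0$theta, gt_pi$theta)
  # area fraction equals a brute-force point-in-spherocylinder count
  fx <- rod_fixture(area_fraction = 0.25, seed = 6, duration = 0.0263)
  ens <- fx$movie[[1]]
  H <- 100; W <- 100; px <- fx$optics$pixel_size
  covered <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    xq <- (j - 0.5 - W / 2) * px; yq <- (H / 2 - i + 0.5) * px
    for (r in seq_along(ens$x)) {
      a <- (ens$length[r] - ens$width) / 2
      ux <- cos(ens$angle[r]); uy <- sin(ens$angle[r])
      t <- max(-a, min(a, (xq - ens$x[r]) * ux + (yq - ens$y[r]) * uy))
      d2 <- (xq - ens$x[r] - t * ux)^2 + (yq - ens$y[r] - t * uy)^2
      if (d2 <= (ens$width / 2)^2) { covered[i, j] <- TRUE; break }
    }
  }
  roi <- fx$gt$roi_mask
  expect_equal(fx$gt$phi[1], sum(covered & roi) / sum(roi), tolerance = 1e-12)
})

test_that("dense slow populations relax more slowly than dilute fast ones", {
  run <- function(phi, speed, seed) {
    p <- sim_params(area_fraction = phi, well_radius = 7, speed = speed,
                    duration = 4, growth_rate = 0, noise_rot = 0.1,
                    wall_reversal = TRUE, seed = seed)
    st <- render_frames(simulate_rods(p), optics_params(dim_px = c(88, 88)),
                        seed = seed + 100)
    st <- crop_roi(st, list(x = 25, y = 25, w = 40, h = 40))
    skip <- ceiling(1 / 0.0263)
    st <- image_stack(st$frames[, , skip:dim(st$frames)[3]],
                      st$pixel_size, st$frame_interval)
    fit_stretched_exponential(overlap_function(st), accept_extrapolated = TRUE)$tau
  }
  for (sd in c(5, 6)) {
    expect_gt(run(0.87, 0.3, sd), run(0.55, 1.5, sd))
  }
})

test_that("write_simulation produces TIFF, tracks CSV and JSON sidecar", {
  dir <- tempfile("sim")
  p <- sim_params(n_rods = 5, well_radius = 6, duration = 0.1, seed = 2)
  m <- simulate_rods(p)
  write_simulation(m, optics_params(dim_px = c(75, 75)), dir, seed = 3)
  expect_true(file.exists(file.path(dir, "movie.tif")))
  tracks <- read.csv(file.path(dir, "tracks.csv"))
  expect_setequal(names(tracks),
                  c("track_id", "parent_id", "frame", "t_s", "x_um", "y_um",
                    "angle_rad", "length_um", "speed_um_s"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$sim_params$seed, 2)
  # the stack reads back with the declared scales
  st <- read_image_stack(file.path(dir, "movie.tif"), 0.1724, p$frame_interval)
  expect_equal(dim(st$frames)[3], length(m))
  unlink(dir, recursive = TRUE)
})
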