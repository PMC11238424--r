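test_that("segmentation finds dilute cells with sub-pixel centroids", {
  fx <- rod_fixture(area_fraction = 0.12, seed = 3, duration = 0.0263)
  ens <- fx$movie[[1]]
  det <- segment_cells(fx$stack$frames[, , 1], fx$stack$pixel_size)
  expect_equal(nrow(det), length(ens$x))
  px <- fx$stack$pixel_size
  for (i in seq_len(nrow(det))) {
    j <- which.min((ens$x - det$x_um[i])^2 + (ens$y - det$y_um[i])^2)
    expect_lt(sqrt((ens$x[j] - det$x_um[i])^2 + (ens$y[j] - det$y_um[i])^2),
              0.5 * px)
    expect_lt(abs(nematic_diff(det$angle_rad[i], ens$angle[j])), 3 * pi / 180)
  }
  # blank frame: zero cells, not an error
  expect_equal(nrow(segment_cells(matrix(1, 40, 40), px)), 0)
})

test_that("the watershed splits a blur-bridged pair of rods", {
  gap <- 0.15 # surface gap well below the optical resolution
  init <- list(x = c(-(4 + gap) / 2, (4 + gap) / 2), y = c(0, 0),
               angle = c(0, 0), length = c(4, 4), speed = c(0, 0))
  p <- sim_params(n_rods = 2, well_radius = 8, speed = 0, noise_trans = 0,
                  noise_rot = 0, growth_rate = 0, duration = 0.0263, seed = 1)
  st <- render_frames(simulate_rods(p, init = init),
                      optics_params(dim_px = c(100, 100)), seed = 3)
  fr <- st$frames[, , 1]
  thr <- bactglass:::fcm_dark_threshold(as.numeric(fr), "low_mid")
  expect_equal(max(bactglass:::label_components4(fr < thr)), 1) # truly merged
  det <- segment_cells(fr, st$pixel_size)
  expect_equal(nrow(det), 2)
})

test_that("linking equals the brute-force minimum-cost assignment", {
  set.seed(30)
  for (rep in 1:4) {
    d1 <- data.frame(x_um = runif(5, 0, 10), y_um = runif(5, 0, 10))
    steps <- lapply(1:3, function(i)
      data.frame(x_um = runif(5, -0.4, 0.4), y_um = runif(5, -0.4, 0.4)))
    dets <- list(d1)
    for (i in 1:3) dets[[i + 1]] <- dets[[i]] + steps[[i]]
    # shuffle detection order in each frame
    dets <- lapply(dets, function(d) d[sample(nrow(d)), ])
    tr <- link_tracks(dets, max_disp_um = 1.5)
    expect_equal(length(unique(tr$track_id)), 5)
    # frame-to-frame links equal the exhaustive optimum
    for (f in 1:3) {
      src <- tr[tr$frame == f, ]; src <- src[order(src$track_id), ]
      dst <- tr[tr$frame == f + 1, ]; dst <- dst[order(dst$track_id), ]
      orc <- oracle_best_match(src, dst, 1.5)
      got <- match(src$track_id, dst$track_id)
      hand <- vapply(seq_len(nrow(src)), function(i) {
        if (orc$match[i] == 0) NA_integer_ else orc$match[i]
      }, integer(1))
      # compare total link cost (optimal assignments may tie)
      cost <- function(m) {
        c0 <- 0
        for (i in seq_along(m)) {
          c0 <- c0 + if (is.na(m[i]) || m[i] == 0) 1.5^2 else
            (src$x_um[i] - dst$x_um[m[i]])^2 + (src$y_um[i] - dst$y_um[m[i]])^2
        }
        c0 + (nrow(dst) - sum(!is.na(m) & m > 0)) * 1.5^2
      }
      expect_equal(cost(got), orc$cost, tolerance = 1e-12)
    }
  }
})

test_that("linking respects the cutoff and is permutation invariant", {
  # stationary particles: one track each, zero displacement
  d <- data.frame(x_um = c(0, 5, 9), y_um = c(0, 1, 4))
  tr <- link_tracks(list(d, d, d), max_disp_um = 1, frame_interval = 0.5)
  expect_equal(length(unique(tr$track_id)), 3)
  expect_equal(max(abs(diff(tr$x_um[tr$track_id == tr$track_id[1]]))), 0)
  expect_equal(sort(unique(tr$t_s)), c(0, 0.5, 1))
  # both particles jump farther than the cutoff: tracks end, none swap
  a <- data.frame(x_um = c(0, 4), y_um = c(0, 0))
  b <- data.frame(x_um = c(4, 0), y_um = c(1.8, -1.8))
  tr2 <- link_tracks(list(a, b), max_disp_um = 1.5)
  expect_equal(length(unique(tr2$track_id)), 4)
  # permutation of detection rows changes nothing
  set.seed(31)
  dets <- lapply(1:4, function(i) data.frame(x_um = runif(6), y_um = runif(6)))
  t1 <- link_tracks(dets, max_disp_um = 5)
  t2 <- link_tracks(lapply(dets, function(d) d[sample(nrow(d)), ]),
                    max_disp_um = 5)
  expect_equal(t1, t2)
})

test_that("ground-truth detections are relinked to the true identities", {
  fx <- rod_fixture(area_fraction = 0.2, speed = 1, duration = 0.3, seed = 5)
  gt <- fx$gt$tracks
  dets <- lapply(split(gt, gt$frame), function(d)
    data.frame(x_um = d$x_um, y_um = d$y_um, true_id = d$track_id))
  tr <- link_tracks(dets, max_disp_um = 0.5,
                    frame_interval = 0.0263)
  # each recovered track maps to exactly one true identity
  expect_true(all(tapply(tr$true_id, tr$track_id,
                         function(v) length(unique(v))) == 1))
  expect_equal(length(unique(tr$track_id)), length(unique(gt$track_id)))
})

test_that("axis-aligned motion fills the first displacement-angle bin", {
  n <- 40
  tr <- data.frame(track_id = rep(1:2, each = n), frame = rep(1:n, 2),
                   t_s = rep(1:n, 2) * 0.1,
                   x_um = c(0.3 * (1:n), 0.3 * (1:n) * cos(1)),
                   y_um = c(rep(0, n), 0.3 * (1:n) * sin(1)),
                   angle_rad = rep(c(0, 1), each = n))
  class(tr) <- c("cell_tracks", "data.frame")
  h <- displacement_orientation_histogram(tr, lag_frames = 1)
  expect_equal(h$prob[1], 1)
  # isotropic displacements with uniform axes: flat histogram
  set.seed(32)
  m <- 10000
  tr2 <- data.frame(track_id = rep(1:m, each = 2), frame = rep(1:2, m),
                    t_s = rep(c(0, 1), m),
                    x_um = as.numeric(rbind(0, cos(a2 <- runif(m, 0, 2 * pi)))),
                    y_um = as.numeric(rbind(0, sin(a2))),
                    angle_rad = rep(runif(m, -pi / 2, pi / 2), each = 2))
  class(tr2) <- c("cell_tracks", "data.frame")
  h2 <- displacement_orientation_histogram(tr2, lag_frames = 1, n_bins = 9)
  expect_true(all(abs(h2$counts - m / 9) < 4 * sqrt(m * (1 / 9) * (8 / 9))))
  # self-propelled rods move along their axis: decreasing histogram
  fx <- rod_fixture(area_fraction = 0.15, speed = 2, duration = 0.6, seed = 7,
                    noise_rot = 0.02)
  gt <- fx$gt$tracks
  tr3 <- data.frame(track_id = gt$track_id, frame = gt$frame, t_s = gt$t_s,
                    x_um = gt$x_um, y_um = gt$y_um, angle_rad = gt$angle_rad)
  class(tr3) <- c("cell_tracks", "data.frame")
  h3 <- displacement_orientation_histogram(tr3, lag_frames = 4, n_bins = 6)
  expect_gt(h3$prob[1], 0.5)
  expect_lt(h3$prob[6], h3$prob[1] / 5)
})

test_that("velocity correlation: rigid translation, nulls, hand-computed pairs", {
  # common velocity v: every bin equals |v|^2
  n <- 6
  pos <- data.frame(x = runif(n, 0, 8), y = runif(n, 0, 8))
  v <- c(0.8, -0.5)
  tr <- data.frame(track_id = rep(1:n, each = 3), frame = rep(1:3, n),
                   t_s = rep(0:2, n) * 1.0,
                   x_um = as.numeric(vapply(1:n, function(i) pos$x[i] + v[1] * (0:2),
                                            numeric(3))),
                   y_um = as.numeric(vapply(1:n, function(i) pos$y[i] + v[2] * (0:2),
                                            numeric(3))))
  class(tr) <- c("cell_tracks", "data.frame")
  vc <- velocity_correlation(tr, lag_frames = 1, bin_um = 1, frame_interval = 1)
  expect_equal(vc$corr, rep(sum(v^2), nrow(vc)), tolerance = 1e-12)
  # i.i.d. isotropic velocities: all bins within 3 stderr of 0
  set.seed(33)
  m <- 60
  vx <- rnorm(m); vy <- rnorm(m)
  tr2 <- data.frame(track_id = rep(1:m, each = 2), frame = rep(1:2, m),
                    t_s = rep(c(0, 1), m),
                    x_um = as.numeric(rbind(px0 <- runif(m, 0, 20), px0 + vx)),
                    y_um = as.numeric(rbind(py0 <- runif(m, 0, 20), py0 + vy)))
  class(tr2) <- c("cell_tracks", "data.frame")
  vc2 <- velocity_correlation(tr2, lag_frames = 1, bin_um = 4, frame_interval = 1)
  ok <- vc2$n_pairs >= 10
  expect_true(all(abs(vc2$corr[ok]) <= 3 * vc2$stderr[ok]))
  # three cells on one frame pair: equals hand-computed pair sums
  tr3 <- data.frame(track_id = rep(1:3, each = 2), frame = rep(1:2, 3),
                    t_s = rep(c(0, 0.5), 3),
                    x_um = c(0, 0.5, 2, 2.1, 0, -0.2),
                    y_um = c(0, 0, 0, 0.4, 3, 3.1))
  class(tr3) <- c("cell_tracks", "data.frame")
  vc3 <- velocity_correlation(tr3, lag_frames = 1, bin_um = 10, frame_interval = 0.5)
  v1 <- c(1, 0); v2 <- c(0.2, 0.8); v3 <- c(-0.4, 0.2)
  hand <- mean(c(sum(v1 * v2), sum(v1 * v3), sum(v2 * v3)))
  expect_equal(vc3$corr, hand, tolerance = 1e-12)
  expect_equal(vc3$n_pairs, 3L)
})

test_that("rigid rotation reproduces the omega^2 <ri.rj> closed form", {
  set.seed(34)
  n <- 8; omega <- 0.05; dt <- 0.1
  r0 <- cbind(runif(n, -5, 5), runif(n, -5, 5))
  rot <- function(p, a) cbind(cos(a) * p[, 1] - sin(a) * p[, 2],
                              sin(a) * p[, 1] + cos(a) * p[, 2])
  r1 <- rot(r0, omega * dt)
  tr <- data.frame(track_id = rep(1:n, each = 2), frame = rep(1:2, n),
                   t_s = rep(c(0, dt), n),
                   x_um = as.numeric(rbind(r0[, 1], r1[, 1])),
                   y_um = as.numeric(rbind(r0[, 2], r1[, 2])))
  class(tr) <- c("cell_tracks", "data.frame")
  vc <- velocity_correlation(tr, lag_frames = 1, bin_um = 50, frame_interval = dt)
  dots <- combn(n, 2, function(ij) sum(r0[ij[1], ] * r0[ij[2], ]))
  expect_equal(vc$corr, omega^2 * mean(dots), tolerance = 1e-3)
})

test_that("cage escapes are flagged by the windowed displacement rule", {
  t_s <- seq(0, 10, by = 0.2)
  x <- ifelse(t_s < 5, 0.05 * sin(t_s * 8), 3) # jump at t = 5
  tr <- data.frame(track_id = 1, frame = seq_along(t_s), t_s = t_s,
                   x_um = x, y_um = 0)
  class(tr) <- c("cell_tracks", "data.frame")
  ep <- flag_cage_escapes(tr, window_s = 2, threshold_um = 2)
  expect_gt(nrow(ep), 0)
  expect_true(all(ep$t_s >= 3 & ep$t_s < 5))
  still <- tr; still$x_um <- 0.05 * sin(t_s * 8)
  expect_equal(nrow(flag_cage_escapes(still, 2, 2)), 0)
})
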