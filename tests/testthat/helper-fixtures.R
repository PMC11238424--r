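# shared fixtures and independent oracles for the test suite

toy_stack <- function(frames, pixel_size = 1, frame_interval = 1) {
  image_stack(frames, pixel_size, frame_interval)
}

random_stack <- function(T, H, W, seed, pixel_size = 1, frame_interval = 1) {
  set.seed(seed)
  image_stack(array(rnorm(H * W * T), c(H, W, T)), pixel_size, frame_interval)
}

# render a small rod movie with ground truth
rod_fixture <- function(area_fraction = 0.3, well_radius = 8, speed = 1,
                        duration = 0.1, seed = 4, dim_px = 100,
                        noise_sd = 0.01, ...) {
  p <- sim_params(area_fraction = area_fraction, well_radius = well_radius,
                  speed = speed, duration = duration, growth_rate = 0,
                  seed = seed, ...)
  m <- simulate_rods(p)
  opt <- optics_params(dim_px = c(dim_px, dim_px), noise_sd = noise_sd)
  list(movie = m, optics = opt,
       stack = render_frames(m, opt, seed = seed + 100),
       gt = ground_truth(m, opt))
}

# ---- independent oracles -------------------------------------------------

# exhaustive double-loop DVA: V(lag), V_inf, Q(t, lag), chi4
oracle_dva <- function(frames, lags, phi = 1) {
  Tn <- dim(frames)[3]
  I_all <- as.numeric(frames)
  v_inf <- 2 * mean((I_all - mean(I_all))^2)
  per_t <- lapply(lags, function(l) {
    sapply(seq_len(Tn - l), function(t) {
      di <- frames[, , t + l] - frames[, , t]
      s <- 0; n <- 0
      for (i in seq_len(nrow(di))) for (j in seq_len(ncol(di))) {
        s <- s + di[i, j]^2; n <- n + 1
      }
      1 - (s / n) / v_inf
    })
  })
  Q <- vapply(per_t, mean, numeric(1))
  chi4 <- phi * vapply(per_t, function(v) mean(v^2) - mean(v)^2, numeric(1))
  list(Q = Q, chi4 = chi4, per_t = per_t, v_inf = v_inf)
}

# exhaustive orientational correlator on an angle array (no masking)
oracle_ctheta <- function(theta, lags, phi = 1) {
  Tn <- dim(theta)[3]
  per_t <- lapply(lags, function(l) {
    sapply(seq_len(Tn - l), function(t) {
      s <- 0; n <- 0
      for (i in seq_len(dim(theta)[1])) for (j in seq_len(dim(theta)[2])) {
        s <- s + cos(2 * (theta[i, j, t + l] - theta[i, j, t])); n <- n + 1
      }
      s / n
    })
  })
  list(C = vapply(per_t, mean, numeric(1)),
       chi4 = phi * vapply(per_t, function(v) mean(v^2) - mean(v)^2, numeric(1)))
}

# naive O(N^4) 2D DFT power spectrum of one mean-subtracted frame
oracle_dft_power <- function(f) {
  H <- nrow(f); W <- ncol(f)
  f <- f - mean(f)
  out <- matrix(0, H, W)
  for (u in 0:(H - 1)) for (v in 0:(W - 1)) {
    acc <- 0 + 0i
    for (i in 0:(H - 1)) for (j in 0:(W - 1)) {
      acc <- acc + f[i + 1, j + 1] * exp(-2i * pi * (u * i / H + v * j / W))
    }
    out[u + 1, v + 1] <- Mod(acc)^2
  }
  out
}

# textbook fuzzy c-means, plain loops, run to tight convergence
oracle_fcm <- function(x, k = 3, m = 2, iters = 500) {
  centers <- as.numeric(quantile(x, seq(0.1, 0.9, length.out = k)))
  n <- length(x)
  u <- matrix(0, n, k)
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) {
      d <- abs(x[i] - centers)
      if (any(d < 1e-300)) { u[i, ] <- as.numeric(d < 1e-300) / sum(d < 1e-300) }
      else {
        for (c1 in seq_len(k))
          u[i, c1] <- 1 / sum((d[c1] / d)^(2 / (m - 1)))
      }
    }
    new_c <- numeric(k)
    for (c1 in seq_len(k))
      new_c[c1] <- sum(u[, c1]^m * x) / sum(u[, c1]^m)
    if (max(abs(new_c - centers)) < 1e-12) { centers <- new_c; break }
    centers <- new_c
  }
  sort(centers)
}

# brute-force minimum-cost linking between two detection frames:
# enumerate all partial injective matchings under the cutoff, cost
# d^2 per link + max_disp^2 per unmatched point on either side
oracle_best_match <- function(src, dst, max_disp) {
  n1 <- nrow(src); n2 <- nrow(dst)
  d2 <- outer(src$x_um, dst$x_um, "-")^2 + outer(src$y_um, dst$y_um, "-")^2
  best <- list(cost = Inf, match = integer(n1))
  assign_next <- function(i, used, match, cost) {
    if (cost >= best$cost) return()
    if (i > n1) {
      cost <- cost + (n2 - sum(match > 0)) * max_disp^2
      if (cost < best$cost) best <<- list(cost = cost, match = match)
      return()
    }
    assign_next(i + 1, used, { m <- match; m[i] <- 0L; m },
                cost + max_disp^2)
    for (j in seq_len(n2)) {
      if (!used[j] && d2[i, j] <= max_disp^2) {
        assign_next(i + 1, { u <- used; u[j] <- TRUE; u },
                    { m <- match; m[i] <- j; m }, cost + d2[i, j])
      }
    }
  }
  assign_next(1, rep(FALSE, n2), integer(n1), 0)
  best
}
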