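#' Simulation parameters for the active-rod generator
#'
#' Defaults emulate the reference experimental system: a circular
#' quasi-2D well of radius 35.6 um holding E. coli-like rods of width
#' 1 um and length 2-6 um, self-propelled along the body axis at a few
#' um/s, growing exponentially and dividing symmetrically.
#'
#' @param n_rods initial rod count (ignored if `area_fraction` is given).
#' @param area_fraction target initial area fraction; rods are seeded
#'   until the summed rod area reaches this fraction of the well.
#' @param well_radius confinement radius (um).
#' @param width rod width (um).
#' @param length_range initial end-to-end lengths drawn uniformly from
#'   this interval (um).
#' @param speed self-propulsion speed scale v0 (um/s); per-rod speeds are
#'   `sign * v0 * exp(N(0, speed_sd))` with random sign.
#' @param speed_sd lognormal spread of speeds.
#' @param noise_trans translational diffusion coefficient (um^2/s).
#' @param noise_rot rotational diffusion coefficient (rad^2/s).
#' @param k_rep steric repulsion stiffness (force per um of spherocylinder
#'   overlap; mobilities are in um/s per unit force).
#' @param k_wall wall stiffness.
#' @param mobility translational mobility (um/s per unit force); the
#'   rotational mobility is `12 * mobility / L^2` (slender-rod scaling).
#' @param growth_rate exponential elongation rate (1/s); 0 disables
#'   growth and division.
#' @param division_length length at which a rod splits symmetrically into
#'   two daughters (um).
#' @param division_kick s.d. of the daughters' orientation perturbation
#'   (rad).
#' @param wall_reversal reverse a rod's run when it pushes outward at the
#'   wall (boundary run reversal); keeps confined non-interacting rods
#'   uniformly mixed instead of accumulating at the wall.
#' @param dt integration time step (s); must not exceed `frame_interval`.
#' @param frame_interval time between emitted frames (s).
#' @param duration total simulated time (s).
#' @param seed RNG seed; the full trajectory is reproducible from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_rods = 50, area_fraction = NULL,
                       well_radius = 35.6, width = 1,
                       length_range = c(2.5, 4.5),
                       speed = 2, speed_sd = 0.2,
                       noise_trans = 0.01, noise_rot = 0.05,
                       k_rep = 100, k_wall = 200, mobility = 1,
                       growth_rate = 3.5e-4, division_length = 5,
                       division_kick = 0.05, wall_reversal = FALSE,
                       dt = 1e-3, frame_interval = 0.0263,
                       duration = 5, seed = 1) {
  p <- list(n_rods = n_rods, area_fraction = area_fraction,
            well_radius = well_radius, width = width,
            length_range = length_range, speed = speed, speed_sd = speed_sd,
            noise_trans = noise_trans, noise_rot = noise_rot,
            k_rep = k_rep, k_wall = k_wall, mobility = mobility,
            growth_rate = growth_rate, division_length = division_length,
            division_kick = division_kick, wall_reversal = wall_reversal,
            dt = dt, frame_interval = frame_interval, duration = duration,
            seed = seed)
  stopifnot(p$dt > 0, p$dt <= p$frame_interval,
            p$well_radius > 0, p$width > 0,
            all(p$length_range > p$width), p$growth_rate >= 0,
            p$division_length > p$width, p$mobility > 0)
  structure(p, class = "sim_params")
}

#' Optical rendering parameters
#'
#' Defaults match the reference phase-contrast setup: pixel size
#' 0.1724 um and optical resolution 0.258 um (rendered as a Gaussian blur
#' with sigma = resolution / 2.355, i.e. resolution read as a FWHM).
#' Rods are dark on a bright background.
#'
#' @param pixel_size um per pixel.
#' @param blur_sigma_um Gaussian blur sigma (um); 0 disables blur.
#' @param background background intensity level.
#' @param rod_level rod intensity level (must be below `background`).
#' @param noise_sd additive Gaussian noise s.d.; 0 disables noise.
#' @param dim_px image height and width `c(H, W)` in pixels; defaults to
#'   the smallest square covering the well.
#' @return list of class `optics_params`.
#' @export
optics_params <- function(pixel_size = 0.1724,
                          blur_sigma_um = 0.258 / 2.355,
                          background = 1, rod_level = 0.4,
                          noise_sd = 0.01, dim_px = NULL) {
  stopifnot(pixel_size > 0, blur_sigma_um >= 0, noise_sd >= 0,
            background > rod_level)
  structure(list(pixel_size = pixel_size, blur_sigma_um = blur_sigma_um,
                 background = background, rod_level = rod_level,
                 noise_sd = noise_sd, dim_px = dim_px),
            class = "optics_params")
}

# evaluate RNG-dependent code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rod_area <- function(len, width) (len - width) * width + pi * (width / 2)^2

# shortest distance between the axis segments of two rods
seg_seg_dist <- function(x1, y1, th1, l1, x2, y2, th2, l2, width) {
  a1 <- max((l1 - width) / 2, 0); a2 <- max((l2 - width) / 2, 0)
  e1 <- a1 * c(cos(th1), sin(th1)); e2 <- a2 * c(cos(th2), sin(th2))
  # sample-based bound is enough for seeding; exact enough at fine sampling
  t <- seq(-1, 1, length.out = 9)
  p1 <- cbind(x1 + t * e1[1], y1 + t * e1[2])
  p2 <- cbind(x2 + t * e2[1], y2 + t * e2[2])
  sqrt(min(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2))
}

# random sequential seeding of non-overlapping rods (best effort: at high
# packing residual overlaps are accepted and relaxed by the dynamics)
seed_rod_ensemble <- function(p) {
  target_n <- if (is.null(p$area_fraction)) p$n_rods else Inf
  target_area <- if (is.null(p$area_fraction)) Inf
                 else p$area_fraction * pi * p$well_radius^2
  xs <- ys <- ths <- ls <- numeric(0)
  total_area <- 0
  # overlap rejection is pointless for phantom (k_rep = 0) rods; above the
  # random-sequential-addition limit residual overlaps are accepted anyway
  max_attempts <- if (p$k_rep > 0) 60L else 1L
  while (length(xs) < target_n && total_area < target_area) {
    len <- runif(1, p$length_range[1], p$length_range[2])
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- p$well_radius * sqrt(runif(1))
      phi_ang <- runif(1, 0, 2 * pi)
      x <- r * cos(phi_ang); y <- r * sin(phi_ang)
      th <- runif(1, -pi / 2, pi / 2)
      ok <- TRUE
      if (max_attempts > 1 && length(xs) > 0 && att < max_attempts) {
        near <- which((xs - x)^2 + (ys - y)^2 <
                        ((ls + len) / 2 + p$width)^2)
        for (j in near) {
          if (seg_seg_dist(x, y, th, len, xs[j], ys[j], ths[j], ls[j],
                           p$width) < p$width) { ok <- FALSE; break }
        }
      }
      if (ok || att == max_attempts) { # accept overlap on final attempt
        xs <- c(xs, x); ys <- c(ys, y); ths <- c(ths, th); ls <- c(ls, len)
        total_area <- total_area + rod_area(len, p$width)
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  n <- length(xs)
  sp <- sample(c(-1, 1), n, replace = TRUE) * p$speed * exp(rnorm(n, 0, p$speed_sd))
  list(x = xs, y = ys, angle = ths, length = ls, speed = sp,
       id = seq_len(n), parent = rep(0L, n))
}

#' Simulate self-propelled growing rods in a circular well
#'
#' Overdamped Langevin dynamics of 2D spherocylindrical rods: each rod
#' advances along its body axis at its signed speed plus translational
#' noise; overlapping pairs repel harmonically (force proportional to the
#' spherocylinder overlap, applied at the contact point, which also exerts
#' an aligning torque); a harmonic wall confines rod centers to the well.
#' Rods elongate exponentially and split symmetrically at the division
#' length into two daughters with fresh track ids, resampled speeds, and a
#' small orientation kick.  Integration is explicit Euler-Maruyama at time
#' step `dt`; one ensemble is emitted per frame interval, starting at
#' t = 0.  The whole trajectory is reproducible from `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param init optional initial state (list with `x`, `y`, `angle`,
#'   `length`, `speed`, and optionally `id`, `parent`), overriding the
#'   random seeding.
#' @return object of class `rod_movie`: a list of per-frame ensembles
#'   (each of class `rod_ensemble` with fields `x`, `y`, `angle` in
#'   `[-pi/2, pi/2)`, `length`, `speed`, `id`, `parent`, `time`, plus
#'   `width` and `well_radius`), with the parameters attached.
#' @export
simulate_rods <- function(params, init = NULL) {
  stopifnot(inherits(params, "sim_params"))
  n_fr <- floor(params$duration / params$frame_interval) + 1L
  # snap dt to an integer divisor of the frame interval so that simulated
  # time and frame timestamps agree exactly
  steps <- max(1L, round(params$frame_interval / params$dt))
  params$dt <- params$frame_interval / steps
  frames <- with_seed(params$seed, {
    state <- init %||% seed_rod_ensemble(params)
    if (length(state$x) == 0) stop("initial seeding produced no rods")
    state$id <- state$id %||% seq_along(state$x)
    state$parent <- state$parent %||% rep(0L, length(state$x))
    simulate_rods_cpp(state$x, state$y, state$angle, state$length,
                      state$speed, as.integer(state$id),
                      as.integer(state$parent),
                      params$width, params$well_radius, params$mobility,
                      params$k_rep, params$k_wall,
                      params$noise_trans, params$noise_rot,
                      params$growth_rate, params$division_length,
                      params$speed, params$speed_sd, params$division_kick,
                      params$dt, params$frame_interval, n_fr,
                      params$wall_reversal)
  })
  frames <- lapply(frames, function(f) {
    f$width <- params$width
    f$well_radius <- params$well_radius
    class(f) <- "rod_ensemble"
    f
  })
  structure(frames, class = "rod_movie", params = params)
}

#' @export
print.rod_ensemble <- function(x, ...) {
  cat(sprintf("rod_ensemble: %d rods at t = %.3f s (well radius %g um)\n",
              length(x$x), x$time, x$well_radius))
  invisible(x)
}

#' @export
as.data.frame.rod_ensemble <- function(x, ...) {
  data.frame(track_id = x$id, parent_id = x$parent,
             t_s = x$time, x_um = x$x, y_um = x$y,
             angle_rad = x$angle, length_um = x$length,
             speed_um_s = x$speed)
}

#' @export
print.rod_movie <- function(x, ...) {
  cat(sprintf("rod_movie: %d frames, %d -> %d rods, frame interval %g s\n",
              length(x), length(x[[1]]$x), length(x[[length(x)]]$x),
              attr(x, "params")$frame_interval))
  invisible(x)
}

default_dim_px <- function(well_radius, pixel_size)
  rep(2L * ceiling(well_radius / pixel_size) + 4L, 2)

#' Render a rod movie as a phase-contrast-like image stack
#'
#' Each rod is rasterized as a dark spherocylinder (pixels whose center
#' lies within width/2 of the axis segment), the frame is blurred by the
#' optical-resolution Gaussian, and seeded additive Gaussian noise is
#' applied.  Pixel (1,1) is top-left; pixel centers sit at half-integer
#' multiples of the pixel size; the well center is the image center; the
#' physical y axis points up.
#'
#' @param movie a `rod_movie` from [simulate_rods()], or a list of
#'   `rod_ensemble` objects.
#' @param optics an [optics_params()] object.
#' @param seed seed for the rendering noise (bit-identical stacks for
#'   equal seeds).
#' @param frame_interval frame interval (s); taken from the movie when
#'   available.
#' @param allow_partial_fov render a field of view smaller than the well
#'   (centered on the well center), as when imaging a sub-region of a
#'   large well; by default a field that does not cover the well is an
#'   error.
#' @return an [image_stack()].
#' @export
render_frames <- function(movie, optics = optics_params(), seed = 1,
                          frame_interval = NULL, allow_partial_fov = FALSE) {
  stopifnot(inherits(optics, "optics_params"))
  if (length(movie) == 0) stop("empty ensemble sequence")
  p <- attr(movie, "params")
  frame_interval <- frame_interval %||% p$frame_interval %||%
    stop("frame_interval not supplied")
  dim_px <- optics$dim_px %||%
    default_dim_px(movie[[1]]$well_radius, optics$pixel_size)
  if (!allow_partial_fov &&
      min(dim_px) * optics$pixel_size < 2 * movie[[1]]$well_radius)
    stop("optics dimensions do not cover the well (set allow_partial_fov = TRUE to image a sub-region)")
  H <- dim_px[1]; W <- dim_px[2]
  sig_px <- optics$blur_sigma_um / optics$pixel_size
  frames <- with_seed(seed, lapply(movie, function(ens) {
    owner <- rasterize_rods_cpp(ens$x, ens$y, ens$angle, ens$length,
                                ens$width, H, W, optics$pixel_size)
    img <- matrix(optics$background, H, W)
    img[owner > 0] <- optics$rod_level
    if (sig_px > 0) img <- gaussian_smooth(img, sig_px)
    if (optics$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, optics$noise_sd), H, W)
    img
  }))
  image_stack(frames, optics$pixel_size, frame_interval)
}

#' Ground truth of a rendered rod movie
#'
#' Per-frame pixel-level orientation truth (each covered pixel carries its
#' rod's nematic angle), the exact covered area fraction, and the true
#' track table (daughters start new ids with the mother recorded as
#' parent).
#'
#' @inheritParams render_frames
#' @param roi optional list `x, y, w, h` restricting the area-fraction
#'   count; default is the disk of the well.
#' @return object of class `rod_ground_truth`: `theta` (`H x W x T`, `NA`
#'   off-rod), `covered` (logical array), `phi` (per-frame covered
#'   fraction of the ROI), `tracks` (data frame `track_id`, `parent_id`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `angle_rad`, `length_um`,
#'   `speed_um_s`), `pixel_size`.
#' @export
ground_truth <- function(movie, optics = optics_params(), roi = NULL) {
  stopifnot(length(movie) >= 1)
  dim_px <- optics$dim_px %||%
    default_dim_px(movie[[1]]$well_radius, optics$pixel_size)
  H <- dim_px[1]; W <- dim_px[2]
  px <- optics$pixel_size
  roi_mask <- if (is.null(roi)) {
    # pixel centers, matching the rasterizer convention (1-based i, j)
    xc <- (col(matrix(0, H, W)) - 0.5 - W / 2) * px
    yc <- (H / 2 - row(matrix(0, H, W)) + 0.5) * px
    xc^2 + yc^2 <= movie[[1]]$well_radius^2
  } else {
    m <- matrix(FALSE, H, W)
    m[roi$y:(roi$y + roi$h - 1), roi$x:(roi$x + roi$w - 1)] <- TRUE
    m
  }
  Tn <- length(movie)
  theta <- array(NA_real_, c(H, W, Tn))
  covered <- array(FALSE, c(H, W, Tn))
  phi <- numeric(Tn)
  tracks <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    ens <- movie[[t]]
    owner <- rasterize_rods_cpp(ens$x, ens$y, ens$angle, ens$length,
                                ens$width, H, W, px)
    cov <- owner > 0
    th <- matrix(NA_real_, H, W)
    th[cov] <- ens$angle[owner[cov]]
    theta[, , t] <- th
    covered[, , t] <- cov
    phi[t] <- sum(cov & roi_mask) / sum(roi_mask)
    df <- as.data.frame(ens)
    df$frame <- t
    tracks[[t]] <- df
  }
  tracks <- do.call(rbind, tracks)
  tracks <- tracks[, c("track_id", "parent_id", "frame", "t_s", "x_um",
                       "y_um", "angle_rad", "length_um", "speed_um_s")]
  structure(list(theta = theta, covered = covered, phi = phi,
                 tracks = tracks, pixel_size = px, roi_mask = roi_mask),
            class = "rod_ground_truth")
}

#' Write a simulated movie to disk
#'
#' Writes the rendered frames as a 16-bit multi-page TIFF, the ground-truth
#' tracks as CSV, and a JSON sidecar with the pixel size, frame interval,
#' seed, and all simulation and optics parameters.
#'
#' @param movie a `rod_movie`.
#' @param optics an [optics_params()].
#' @param dir output directory (created if missing).
#' @param seed rendering-noise seed, recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(movie, optics = optics_params(), dir,
                             seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- attr(movie, "params")
  stack <- render_frames(movie, optics, seed = seed)
  write_image_stack(stack, file.path(dir, "movie.tif"))
  gt <- ground_truth(movie, optics)
  write.csv(gt$tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  meta <- list(pixel_size_um = optics$pixel_size,
               frame_interval_s = p$frame_interval,
               seed = seed,
               sim_params = unclass(p),
               optics_params = unclass(optics))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
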