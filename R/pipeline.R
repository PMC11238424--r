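#' Analysis configuration
#'
#' Bundles every knob of the group-wise analysis.  The movie is split into
#' groups of `group_size` consecutive frames (default 500); each group is
#' analyzed independently (area fraction, overlap function, orientational
#' correlator, susceptibilities, structure factor, stretched-exponential
#' fits) and the relaxation times of all groups feed the cross-group
#' relaxation-law fits.
#'
#' @param group_size frames per analysis group (>= 10).
#' @param pixel_size,frame_interval physical scales, required unless the
#'   input stack carries them.
#' @param roi optional crop `list(x, y, w, h)` applied before analysis.
#' @param correct_illumination divide frames by the local Gaussian mean
#'   (see [correct_illumination()]).
#' @param window_px illumination-correction window (px).
#' @param sigma_px structure-tensor scale (px).
#' @param grad_threshold microdomain boundary threshold ((rad/um)^2).
#' @param min_area_px minimum counted domain area (px).
#' @param domain_every analyze every k-th frame for domain statistics.
#' @param max_lag_frames cap on the lag grid (default group_size / 2).
#' @param vft_variant see [fit_vft()].
#' @param seed RNG seed recorded with the run.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(group_size = 500, pixel_size = NULL,
                            frame_interval = NULL, roi = NULL,
                            correct_illumination = TRUE, window_px = NULL,
                            sigma_px = 6, grad_threshold = 1e-2,
                            min_area_px = 4, domain_every = 50,
                            max_lag_frames = NULL,
                            vft_variant = "phi", seed = 1, out_dir = NULL) {
  stopifnot(group_size >= 10)
  structure(list(group_size = group_size, pixel_size = pixel_size,
                 frame_interval = frame_interval, roi = roi,
                 correct_illumination = correct_illumination,
                 window_px = window_px, sigma_px = sigma_px,
                 grad_threshold = grad_threshold, min_area_px = min_area_px,
                 domain_every = domain_every,
                 max_lag_frames = max_lag_frames,
                 vft_variant = vft_variant, seed = seed, out_dir = out_dir),
            class = "analysis_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(f))
}

# run one stage, recording failures (in the environment `errors`) instead
# of aborting the group
try_stage <- function(errors, name, expr) {
  tryCatch(expr, error = function(e) {
    assign(name, conditionMessage(e), envir = errors)
    NULL
  })
}

#' Group-wise end-to-end analysis of a movie
#'
#' Runs the full chain on each group of consecutive frames: illumination
#' correction, area fraction, overlap function \eqn{Q} and
#' \eqn{\chi_4^Q}, orientation field, \eqn{C_\theta} and
#' \eqn{\chi_4^\theta}, static structure factor, microdomain areas, and
#' stretched-exponential fits of both relaxation channels.  Across
#' groups it fits the MCT power law and the VFT law to
#' \eqn{\tau_Q(\phi)} and \eqn{\tau_\theta(\phi)} (censored groups —
#' curves that do not relax inside the window — are excluded) and an
#' exponential law to the pooled microdomain areas.  A failing stage is
#' recorded in the group's `errors` and the pipeline continues.
#'
#' @param stack an [image_stack()], or a path to a multi-page TIFF (then
#'   `config$pixel_size` and `config$frame_interval` are required).
#' @param config an [analysis_config()].
#' @return object of class `bactglass_analysis`: `groups` (per-group
#'   results), `summary` (data frame: group, phi, phi_sd, tau_q,
#'   tau_q_censored, beta_q, tau_theta, tau_theta_censored, beta_theta),
#'   `mct_q`, `mct_theta`, `vft_q`, `vft_theta`, `domain_fit`, `config`,
#'   `config_hash`.
#' @export
run_analysis <- function(stack, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(stack))
    stack <- read_image_stack(stack, config$pixel_size,
                              config$frame_interval)
  stopifnot(inherits(stack, "image_stack"))
  Tn <- n_frames(stack)
  gs <- config$group_size
  n_groups <- max(1L, Tn %/% gs)
  groups <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    idx <- ((g - 1L) * gs + 1L):min(g * gs, Tn)
    sub <- image_stack(stack$frames[, , idx, drop = FALSE],
                       stack$pixel_size, stack$frame_interval)
    if (!is.null(config$roi)) sub <- crop_roi(sub, config$roi)
    errors <- new.env()
    if (config$correct_illumination) {
      corrected <- try_stage(errors, "correct_illumination",
                             correct_illumination(sub, config$window_px))
      if (!is.null(corrected)) sub <- corrected
    }
    af <- try_stage(errors, "area_fraction", estimate_area_fraction(sub))
    lags <- lag_frames(length(idx), config$max_lag_frames)
    q_curve <- try_stage(errors, "overlap", overlap_function(sub, lags))
    chi4q <- if (!is.null(q_curve) && !is.null(af))
      try_stage(errors, "chi4_overlap", chi4_overlap(q_curve, af$phi))
    field <- try_stage(errors, "orientation_field",
                       orientation_field(sub, config$sigma_px))
    c_curve <- if (!is.null(field))
      try_stage(errors, "orientational_correlation",
                orientational_correlation(field, lags))
    chi4th <- if (!is.null(c_curve) && !is.null(af))
      try_stage(errors, "chi4_orientation", chi4_orientation(c_curve, af$phi))
    sq <- try_stage(errors, "structure_factor", static_structure_factor(sub))
    fit_q <- if (!is.null(q_curve))
      try_stage(errors, "fit_q",
                fit_stretched_exponential(q_curve, accept_extrapolated = TRUE))
    fit_th <- if (!is.null(c_curve))
      try_stage(errors, "fit_theta",
                fit_stretched_exponential(c_curve, accept_extrapolated = TRUE))
    domains <- if (!is.null(field))
      try_stage(errors, "domains", {
        fr_idx <- seq(1, dim(field$theta)[3], by = config$domain_every)
        areas <- unlist(lapply(fr_idx, function(t) {
          ds <- segment_microdomains(field$theta[, , t],
                                     threshold = config$grad_threshold,
                                     pixel_size = field$pixel_size,
                                     min_area_px = config$min_area_px)
          ds$table$area_um2
        }))
        areas
      })
    groups[[g]] <- list(frames = range(idx), phi = af, q_curve = q_curve,
                        chi4_q = chi4q, c_theta = c_curve,
                        chi4_theta = chi4th, sq = sq,
                        fit_q = fit_q, fit_theta = fit_th,
                        domain_areas = domains, errors = as.list(errors))
  }
  summary <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    gr <- groups[[g]]
    data.frame(group = g,
               phi = gr$phi$phi %||% NA,
               phi_sd = gr$phi$phi_sd %||% NA,
               tau_q = gr$fit_q$tau %||% NA,
               tau_q_censored = gr$fit_q$censored %||% NA,
               beta_q = gr$fit_q$beta %||% NA,
               tau_theta = gr$fit_theta$tau %||% NA,
               tau_theta_censored = gr$fit_theta$censored %||% NA,
               beta_theta = gr$fit_theta$beta %||% NA)
  }))
  law_fit <- function(tau_col, cens_col, fitter) {
    ok <- is.finite(summary$phi) & is.finite(summary[[tau_col]]) &
      !isTRUE_vec(summary[[cens_col]])
    if (sum(ok) < 4) return(NULL)
    tryCatch(fitter(summary$phi[ok], summary[[tau_col]][ok]),
             error = function(e) NULL)
  }
  mct_q <- law_fit("tau_q", "tau_q_censored", fit_mct)
  mct_theta <- law_fit("tau_theta", "tau_theta_censored", fit_mct)
  vft_q <- law_fit("tau_q", "tau_q_censored",
                   function(p, t) fit_vft(p, t, variant = config$vft_variant))
  vft_theta <- law_fit("tau_theta", "tau_theta_censored",
                       function(p, t) fit_vft(p, t, variant = config$vft_variant))
  all_areas <- unlist(lapply(groups, `[[`, "domain_areas"))
  domain_fit <- if (length(all_areas) >= 30)
    tryCatch(fit_domain_areas(all_areas,
                              A_min = config$min_area_px * stack$pixel_size^2),
             error = function(e) NULL)
  res <- structure(list(groups = groups, summary = summary,
                        mct_q = mct_q, mct_theta = mct_theta,
                        vft_q = vft_q, vft_theta = vft_theta,
                        domain_fit = domain_fit,
                        config = config, config_hash = config_hash(config)),
                   class = "bactglass_analysis")
  if (!is.null(config$out_dir)) write_analysis(res, config$out_dir)
  res
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.bactglass_analysis <- function(x, ...) {
  cat(sprintf("bactglass_analysis: %d groups (config %s)\n",
              nrow(x$summary), substr(x$config_hash, 1, 8)))
  print(x$summary, digits = 4)
  if (!is.null(x$mct_q)) { cat("overlap channel:      "); print(x$mct_q) }
  if (!is.null(x$mct_theta)) { cat("orientation channel:  "); print(x$mct_theta) }
  if (!is.null(x$domain_fit)) print(x$domain_fit)
  invisible(x)
}

write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  for (g in seq_along(res$groups)) {
    gr <- res$groups[[g]]
    if (!is.null(gr$q_curve)) {
      df <- as.data.frame(gr$q_curve)
      names(df)[2] <- "Q"
      if (!is.null(gr$chi4_q)) df$chi4 <- gr$chi4_q$chi4
      write.csv(df, file.path(dir, sprintf("group%03d_overlap.csv", g)),
                row.names = FALSE)
    }
    if (!is.null(gr$c_theta)) {
      df <- as.data.frame(gr$c_theta)
      names(df)[2] <- "C_theta"
      if (!is.null(gr$chi4_theta)) df$chi4 <- gr$chi4_theta$chi4
      write.csv(df, file.path(dir, sprintf("group%03d_orient.csv", g)),
                row.names = FALSE)
    }
    if (!is.null(gr$sq))
      write.csv(as.data.frame(gr$sq),
                file.path(dir, sprintf("group%03d_sq.csv", g)),
                row.names = FALSE)
  }
  fits <- list(config_hash = res$config_hash,
               mct_q = if (!is.null(res$mct_q)) coef(res$mct_q),
               mct_theta = if (!is.null(res$mct_theta)) coef(res$mct_theta),
               vft_q = if (!is.null(res$vft_q)) coef(res$vft_q),
               vft_theta = if (!is.null(res$vft_theta)) coef(res$vft_theta),
               domain_A0 = res$domain_fit$A0)
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Two-step transition report
#'
#' Compares the critical area fractions of the orientational and
#' translational channels: reports \eqn{\phi_c^\theta}, \eqn{\phi_c^Q},
#' their difference with a propagated confidence interval, and whether
#' \eqn{\phi_c^\theta < \phi_c^Q} is significant at the 95% level — the
#' signature of orientational degrees of freedom vitrifying first.
#'
#' @param analysis a [run_analysis()] result, or a list with `mct_q` and
#'   `mct_theta` fits.
#' @return list of class `two_step_report`: `phi_c_theta`, `phi_c_q`,
#'   `difference`, `difference_ci`, `ordering_detected`, `significant`,
#'   `partial`.
#' @export
compare_channels <- function(analysis) {
  fq <- analysis$mct_q; ft <- analysis$mct_theta
  if (is.null(fq) || is.null(ft)) {
    warning("one channel's fit is missing: partial report")
    return(structure(list(phi_c_theta = ft$phi_c, phi_c_q = fq$phi_c,
                          difference = NULL, difference_ci = NULL,
                          ordering_detected = NA, significant = NA,
                          partial = TRUE),
                     class = "two_step_report"))
  }
  diff <- ft$phi_c - fq$phi_c
  se <- sqrt(ft$phi_c_se^2 + fq$phi_c_se^2)
  z <- qnorm(0.975)
  ci <- diff + c(-1, 1) * z * se
  structure(list(phi_c_theta = ft$phi_c, phi_c_q = fq$phi_c,
                 phi_c_theta_ci = ft$phi_c_ci, phi_c_q_ci = fq$phi_c_ci,
                 difference = diff, difference_ci = ci,
                 ordering_detected = diff < 0,
                 significant = ci[2] < 0, partial = FALSE),
            class = "two_step_report")
}

#' @export
print.two_step_report <- function(x, ...) {
  if (isTRUE(x$partial)) {
    cat("two-step transition report (partial: one channel missing)\n")
  } else {
    cat(sprintf("phi_c(theta) = %.4g, phi_c(Q) = %.4g, difference = %.4g [%.4g, %.4g]\n",
                x$phi_c_theta, x$phi_c_q, x$difference,
                x$difference_ci[1], x$difference_ci[2]))
    cat(sprintf("orientational channel vitrifies first: %s (significant at 95%%: %s)\n",
                x$ordering_detected, x$significant))
  }
  invisible(x)
}

#' Synthetic movie series with an imposed MCT slowdown
#'
#' Builds a series of fixed-density rod movies whose relaxation times
#' follow a prescribed mode-coupling law \eqn{\tau \propto
#' (\phi_c - \phi)^{-\gamma}}: the rendered pattern decorrelates on the
#' time a rod needs to travel its own width, so per-level self-propulsion
#' speeds are set to \eqn{v(\phi) \propto (\phi_c - \phi)^{\gamma}}.
#' Steric repulsion is disabled in this series so that the speed scaling
#' is the sole density dependence of the dynamics.  Used to validate
#' end-to-end recovery of \eqn{\phi_c} by
#' [overlap_function()] + [fit_stretched_exponential()] + [fit_mct()].
#'
#' @param phi_levels area-fraction levels.
#' @param phi_c,gamma generating MCT parameters.
#' @param n_frames frames per movie.
#' @param dim_px rendered image size (square).
#' @param v_ref speed (um/s) at the lowest level.
#' @param frame_interval seconds per frame.
#' @param seed base RNG seed (level k uses `seed + k`).
#' @return list of class `mct_movie_series`: `phi` (levels), `stacks`
#'   (list of [image_stack()]), `phi_c`, `gamma`.
#' @export
mct_movie_series <- function(phi_levels = seq(0.70, 0.84, length.out = 8),
                             phi_c = 0.882, gamma = 1.6,
                             n_frames = 200, dim_px = 64, v_ref = 15,
                             frame_interval = 0.0263, seed = 1) {
  stopifnot(all(phi_levels < phi_c))
  px <- 0.1724
  well_radius <- (dim_px - 4) * px / 2
  optics <- optics_params(pixel_size = px, dim_px = c(dim_px, dim_px))
  speeds <- v_ref * ((phi_c - phi_levels) / (phi_c - phi_levels[1]))^gamma
  stacks <- lapply(seq_along(phi_levels), function(k) {
    p <- sim_params(area_fraction = phi_levels[k],
                    well_radius = well_radius,
                    length_range = c(2, 4),
                    speed = speeds[k], speed_sd = 0.1,
                    noise_trans = 0.002, noise_rot = 0.005,
                    k_rep = 0, k_wall = 200, wall_reversal = TRUE,
                    growth_rate = 0,
                    duration = (n_frames - 1) * frame_interval,
                    frame_interval = frame_interval,
                    dt = frame_interval / 2, seed = seed + k)
    movie <- simulate_rods(p)
    render_frames(movie, optics, seed = seed + 1000 + k)
  })
  structure(list(phi = phi_levels, stacks = stacks, phi_c = phi_c,
                 gamma = gamma),
            class = "mct_movie_series")
}

#' Measure and fit the relaxation times of a movie series
#'
#' Computes the overlap function of each movie, extracts \eqn{\tau_Q} by
#' a stretched-exponential fit, and fits the MCT power law to
#' \eqn{\tau_Q(\phi)}.
#'
#' @param series an [mct_movie_series()] (or any list with `phi` and
#'   `stacks`).
#' Each movie is first cropped to the central square inscribed in the
#' well, as in the experimental protocol, so that the static image
#' region outside the well does not contribute a frozen background to
#' the overlap function.
#'
#' @return list: `taus`, `betas`, `censored`, `mct` (an [fit_mct()]
#'   object on the non-censored levels).
#' @export
analyze_mct_series <- function(series) {
  fits <- lapply(series$stacks, function(s) {
    d <- dim(s$frames)
    side <- floor(min(d[1], d[2]) / sqrt(2)) - 2L # inscribed square, margin
    x0 <- floor((d[2] - side) / 2) + 1L
    y0 <- floor((d[1] - side) / 2) + 1L
    s <- crop_roi(s, list(x = x0, y = y0, w = side, h = side))
    q <- overlap_function(s)
    fit_stretched_exponential(q, accept_extrapolated = TRUE)
  })
  taus <- vapply(fits, `[[`, numeric(1), "tau")
  cens <- vapply(fits, `[[`, logical(1), "censored")
  ok <- !cens
  list(taus = taus, betas = vapply(fits, `[[`, numeric(1), "beta"),
       censored = cens,
       mct = fit_mct(series$phi[ok], taus[ok]))
}
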