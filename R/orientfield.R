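#' Nematic angle difference
#'
#' Difference of two nematic (head-tail symmetric, mod-pi) angles, wrapped
#' into `[-pi/2, pi/2)`.  Used everywhere two orientations are compared, so
#' that e.g. 80 deg and -80 deg differ by -20 deg, not 160 deg.
#'
#' @param a,b angles in radians (vectorized).
#' @return wrapped signed difference in radians.
#' @export
nematic_diff <- function(a, b) {
  d <- ((a - b + pi / 2) %% pi) - pi / 2
  # %% can return the modulus itself within rounding; keep the range half-open
  i <- which(d >= pi / 2)
  d[i] <- d[i] - pi
  d
}

# wrap a nematic angle into [-pi/2, pi/2)
wrap_nematic_angle <- function(a) nematic_diff(a, 0)

#' Structure-tensor orientation of a single frame
#'
#' Local texture orientation from the structure tensor: intensity gradients
#' are computed by Gaussian-derivative filters at scale `sigma_px`, their
#' outer products are smoothed with the same Gaussian, and the orientation
#' is the half-angle two-argument arctangent of
#' \eqn{(2\langle\Delta_x\Delta_y\rangle,\ \langle\Delta_x^2\rangle -
#' \langle\Delta_y^2\rangle)}.  The returned angle is the structure
#' (rod-axis) direction — perpendicular to the dominant gradient — in
#' `[-pi/2, pi/2)`, measured from the +x axis, counterclockwise in the
#' physical (y-up) frame.  Pixels where the tensor trace is below
#' `trace_tol` times the frame intensity variance carry no orientation
#' signal and are returned as `NA`.
#'
#' @param frame numeric matrix.
#' @param sigma_px Gaussian window of the tensor smoothing, in pixels
#'   (default 6, about one cell width at the reference optical scale).
#' @param deriv_sigma_px scale of the Gaussian-derivative gradient filters
#'   (px).  Kept well below `sigma_px`: the gradient must resolve the
#'   micron-scale lateral packing of the cells, which a derivative at the
#'   window scale would suppress; the window then pools the gradient
#'   orientation over the cell-width neighborhood.
#' @param trace_tol relative tensor-trace cutoff for masking flat regions.
#' @return matrix of nematic angles (radians) with `NA` where undefined.
#' @export
structure_tensor_orientation <- function(frame, sigma_px = 6,
                                         deriv_sigma_px = 1,
                                         trace_tol = 1e-6) {
  stopifnot(is.matrix(frame), sigma_px > 0, deriv_sigma_px > 0)
  if (min(dim(frame)) < ceiling(6 * sigma_px))
    stop("frame smaller than ~6 sigma; reduce sigma_px")
  g <- gaussian_kernel_1d(deriv_sigma_px)
  dg <- gaussian_deriv_kernel_1d(deriv_sigma_px)
  gx <- conv_sep_reflect(frame, dg, g)      # d/dx (columns)
  gy <- -conv_sep_reflect(frame, g, dg)     # rows grow downward: flip to y-up
  jxx <- gaussian_smooth(gx * gx, sigma_px)
  jyy <- gaussian_smooth(gy * gy, sigma_px)
  jxy <- gaussian_smooth(gx * gy, sigma_px)
  theta_grad <- 0.5 * atan2(2 * jxy, jxx - jyy)
  theta <- wrap_nematic_angle(theta_grad + pi / 2) # structure axis
  tr <- jxx + jyy
  thr <- trace_tol * max(var(as.numeric(frame)), .Machine$double.eps)
  theta[tr <= thr] <- NA_real_
  theta
}

#' Orientation field of an image stack
#'
#' Applies [structure_tensor_orientation()] frame by frame.
#'
#' @param stack an [image_stack()].
#' @inheritParams structure_tensor_orientation
#' @return object of class `orientation_field`: `theta` (`H x W x T` array
#'   of nematic angles, `NA` = masked), `sigma_px`, `pixel_size`,
#'   `frame_interval`.
#' @export
orientation_field <- function(stack, sigma_px = 6, deriv_sigma_px = 1,
                              trace_tol = 1e-6) {
  stopifnot(inherits(stack, "image_stack"))
  th <- stack$frames
  for (t in seq_len(n_frames(stack)))
    th[, , t] <- structure_tensor_orientation(stack$frames[, , t], sigma_px,
                                              deriv_sigma_px, trace_tol)
  structure(list(theta = th, sigma_px = sigma_px,
                 pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  d <- dim(x$theta)
  cat(sprintf("orientation_field: %d frames of %d x %d px, sigma = %g px, %.1f%% masked\n",
              d[3], d[1], d[2], x$sigma_px, 100 * mean(is.na(x$theta))))
  invisible(x)
}

#' Orientational correlation function
#'
#' \eqn{C_\theta(\Delta t) = \langle \cos 2[\theta(\vec r, t + \Delta t) -
#' \theta(\vec r, t)] \rangle_{\vec r, t}} over unmasked pixels (excluded
#' pairwise) and all admissible reference times.  Instantaneous values
#' \eqn{C_\theta(t, \Delta t)} are retained for [chi4_orientation()].
#'
#' @param field an [orientation_field()].
#' @param lags integer lags in frames; default [lag_frames()] grid.
#' @return a [relaxation_curve()] of type `"orientation"`.
#' @export
orientational_correlation <- function(field, lags = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  Tn <- dim(field$theta)[3]
  if (Tn < 2) stop("at least two frames are required")
  all_masked <- vapply(seq_len(Tn),
                       function(t) all(is.na(field$theta[, , t])), logical(1))
  if (any(all_masked))
    stop(sprintf("frame %d is fully masked", which(all_masked)[1]))
  lags <- as.integer(lags %||% lag_frames(Tn))
  if (any(lags < 1) || any(lags >= Tn)) stop("lags must lie in [1, T - 1]")
  per_t <- lapply(lags, function(l) {
    vapply(seq_len(Tn - l), function(t) {
      d <- field$theta[, , t + l] - field$theta[, , t]
      mean(cos(2 * d), na.rm = TRUE)
    }, numeric(1))
  })
  relaxation_curve(lags * field$frame_interval, per_t,
                   type = "orientation", lag_frames = lags)
}

#' @rdname chi4_curve
#' @param curve for `chi4_orientation`, a curve from
#'   [orientational_correlation()].
#' @export
chi4_orientation <- function(curve, phi) {
  if (curve$type != "orientation")
    warning("curve is not an orientational correlation curve")
  chi4_curve(curve, phi)
}

#' Squared gradient of a nematic orientation field
#'
#' \eqn{|\nabla\theta|^2} in (rad/um)^2, computed with central finite
#' differences wrapped by [nematic_diff()] on each axis (one-sided at the
#' image edge), so that a jump across the +-pi/2 representative boundary
#' does not create a spurious pi-sized gradient.  `NA` (masked) pixels
#' propagate to every stencil that touches them.
#'
#' @param field an [orientation_field()], or a single matrix of angles
#'   (then `pixel_size` must be given).
#' @param pixel_size pixel size in micrometres (taken from `field` if it is
#'   an `orientation_field`).
#' @return array (or matrix) of \eqn{|\nabla\theta|^2} values.
#' @export
orientation_gradient_sq <- function(field, pixel_size = NULL) {
  if (inherits(field, "orientation_field")) {
    px <- field$pixel_size
    th <- field$theta
    out <- th
    for (t in seq_len(dim(th)[3]))
      out[, , t] <- grad_sq_frame(th[, , t], px)
    return(out)
  }
  stopifnot(is.matrix(field), !is.null(pixel_size))
  grad_sq_frame(field, pixel_size)
}

grad_sq_frame <- function(th, px) {
  H <- nrow(th); W <- ncol(th)
  dx <- matrix(NA_real_, H, W)
  dy <- matrix(NA_real_, H, W)
  if (W >= 3)
    dx[, 2:(W - 1)] <- nematic_diff(th[, 3:W], th[, 1:(W - 2)]) / (2 * px)
  if (W >= 2) {
    dx[, 1] <- nematic_diff(th[, 2], th[, 1]) / px
    dx[, W] <- nematic_diff(th[, W], th[, W - 1]) / px
  }
  if (H >= 3)
    dy[2:(H - 1), ] <- nematic_diff(th[3:H, ], th[1:(H - 2), ]) / (2 * px)
  if (H >= 2) {
    dy[1, ] <- nematic_diff(th[2, ], th[1, ]) / px
    dy[H, ] <- nematic_diff(th[H, ], th[H - 1, ]) / px
  }
  dx^2 + dy^2
}

#' Segment nematic microdomains
#'
#' Pixels whose squared orientation gradient meets the threshold (default
#' 1e-2 (rad/um)^2) are domain boundaries; the remaining pixels are
#' partitioned into 4-connected components.  Components smaller than
#' `min_area_px` pixels are discarded as quantization debris.
#'
#' @param theta matrix of nematic angles for one frame (`NA` = masked).
#' @param grad_sq matrix from [orientation_gradient_sq()] for the same
#'   frame (computed if omitted).
#' @param threshold squared-gradient cutoff in (rad/um)^2.
#' @param pixel_size pixel size (um).
#' @param min_area_px minimum counted domain area in pixels.
#' @return object of class `domain_set`: `labels` matrix (0 =
#'   boundary/excluded), `table` data frame (`domain_id`, `area_px`,
#'   `area_um2`, `touches_border`), `threshold`, `pixel_size`.
#' @export
segment_microdomains <- function(theta, grad_sq = NULL, threshold = 1e-2,
                                 pixel_size, min_area_px = 4) {
  stopifnot(is.matrix(theta), threshold > 0, pixel_size > 0)
  grad_sq <- grad_sq %||% grad_sq_frame(theta, pixel_size)
  interior <- !(is.na(grad_sq) | is.na(theta) | grad_sq >= threshold)
  if (!any(interior)) {
    warning("threshold eliminated all pixels: empty domain set")
    return(structure(list(labels = matrix(0L, nrow(theta), ncol(theta)),
                          table = data.frame(domain_id = integer(),
                                             area_px = integer(),
                                             area_um2 = numeric(),
                                             touches_border = logical()),
                          threshold = threshold, pixel_size = pixel_size),
                     class = "domain_set"))
  }
  lab <- label_components4(interior)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_area_px)
  lab[!(lab %in% keep)] <- 0L
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  tab <- data.frame(domain_id = keep,
                    area_px = counts[keep],
                    area_um2 = counts[keep] * pixel_size^2,
                    touches_border = keep %in% border)
  structure(list(labels = lab, table = tab, threshold = threshold,
                 pixel_size = pixel_size),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("domain_set: %d domains (threshold %.3g (rad/um)^2), median area %.3g um2\n",
              nrow(x$table), x$threshold,
              if (nrow(x$table)) median(x$table$area_um2) else NA))
  invisible(x)
}

#' Fit an exponential law to microdomain areas
#'
#' Maximum-likelihood fit of a left-truncated exponential
#' \eqn{P(A) \propto e^{-A/A_0}} for \eqn{A \ge A_{min}}: the MLE is
#' `A0 = mean(A - A_min)` with standard error `A0 / sqrt(n)`; the 95%
#' confidence interval uses the normal approximation.
#'
#' @param areas domain areas (um^2), pooled over frames.
#' @param A_min truncation point: the minimum resolvable domain area
#'   (um^2).  Defaults to the smallest observed area.
#' @param conf confidence level.
#' @return object of class `domain_area_fit`: `A0`, `se`, `ci`,
#'   `n_domains`, `A_min`.
#' @export
fit_domain_areas <- function(areas, A_min = NULL, conf = 0.95) {
  areas <- areas[is.finite(areas)]
  A_min <- A_min %||% min(areas)
  areas <- areas[areas >= A_min]
  n <- length(areas)
  if (n < 30) stop("need at least 30 domain areas for a meaningful fit")
  A0 <- mean(areas - A_min)
  if (A0 <= .Machine$double.eps * max(abs(areas), 1)) {
    warning("degenerate fit: all areas equal the truncation point")
    A0 <- .Machine$double.eps
  }
  se <- A0 / sqrt(n)
  z <- qnorm(1 - (1 - conf) / 2)
  structure(list(A0 = A0, se = se, ci = c(A0 - z * se, A0 + z * se),
                 n_domains = n, A_min = A_min, conf = conf),
            class = "domain_area_fit")
}

#' @export
print.domain_area_fit <- function(x, ...) {
  cat(sprintf("exponential domain-area fit: A0 = %.3g um2 (%.0f%% CI [%.3g, %.3g], n = %d, A >= %.3g)\n",
              x$A0, 100 * x$conf, x$ci[1], x$ci[2], x$n_domains, x$A_min))
  invisible(x)
}
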