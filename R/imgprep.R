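#' Correct non-uniform illumination
#'
#' Divides each frame pixel-wise by a local threshold surface, the
#' Gaussian-weighted local mean of that frame over a square window
#' (symmetric boundary padding).  On a flat field the output is
#' identically 1, so corrected intensities are relative to the local
#' background.
#'
#' @param stack an [image_stack()].
#' @param window_px odd window size in pixels; default
#'   `2 * floor(min(H, W) / 16) + 1`, floored at 25 px so the window always
#'   exceeds the cell scale (a window smaller than a cell would flatten the
#'   cells themselves, not the illumination).  The Gaussian weight has
#'   `sigma = window_px / 4`.
#' @return corrected [image_stack()].
#' @export
correct_illumination <- function(stack, window_px = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (is.null(window_px)) {
    window_px <- max(2L * (min(d[1:2]) %/% 16L) + 1L, 25L)
    # stay below the image size for small crops
    while (window_px >= min(d[1:2])) window_px <- window_px - 2L
  }
  if (window_px %% 2 == 0) stop("window_px must be odd")
  if (window_px < 3 || window_px >= min(d[1:2]))
    stop("window_px must be >= 3 and smaller than the image dimensions")
  k <- gaussian_kernel_1d(window_px / 4, radius = (window_px - 1L) %/% 2L)
  out <- stack$frames
  for (t in seq_len(d[3])) {
    surf <- conv_sep_reflect(stack$frames[, , t], k, k)
    bad <- surf <= 0
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "local threshold surface is zero near pixel (row %d, col %d) of frame %d; all-dark window",
        idx[1], idx[2], t))
    }
    out[, , t] <- stack$frames[, , t] / surf
  }
  image_stack(out, stack$pixel_size, stack$frame_interval, roi = stack$roi)
}

#' Crop a rectangular region of interest
#'
#' @param stack an [image_stack()].
#' @param roi list or vector with `x`, `y`, `w`, `h`: 1-based top-left
#'   corner (`x` = column, `y` = row) and size in pixels.
#' @return the cropped [image_stack()]; pixel size and frame interval are
#'   preserved and the crop (composed with any previous crop) is recorded
#'   in `$roi`.
#' @export
crop_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"))
  roi <- as.list(roi)
  x <- roi$x; y <- roi$y; w <- roi$w; h <- roi$h
  d <- dim(stack$frames)
  if (is.null(x) || is.null(y) || is.null(w) || is.null(h))
    stop("roi must supply x, y, w, h")
  if (x < 1 || y < 1 || w < 1 || h < 1 || y + h - 1 > d[1] || x + w - 1 > d[2])
    stop(sprintf("roi [%d:%d, %d:%d] outside frame bounds %d x %d",
                 y, y + h - 1, x, x + w - 1, d[1], d[2]))
  prev <- stack$roi
  abs_roi <- if (is.null(prev)) list(x = x, y = y, w = w, h = h)
             else list(x = prev$x + x - 1, y = prev$y + y - 1, w = w, h = h)
  image_stack(stack$frames[y:(y + h - 1), x:(x + w - 1), , drop = FALSE],
              stack$pixel_size, stack$frame_interval, roi = abs_roi)
}

#' One-dimensional fuzzy c-means clustering
#'
#' Standard fuzzy c-means on a 1D sample (typically pixel intensities),
#' used to set the binarization threshold for area-fraction estimation.
#' Centers are initialized deterministically at the `0.1 / 0.5 / 0.9`
#' intensity quantiles (equispaced interior quantiles for other
#' `n_classes`), so the result does not depend on a random seed.
#'
#' @param values numeric sample.
#' @param n_classes number of classes (default 3).
#' @param m fuzziness exponent (> 1, default 2).
#' @param tol convergence tolerance on the maximum center shift.
#' @param max_iter iteration cap.
#' @param weights optional nonnegative sample weights (e.g. histogram
#'   counts), same length as `values`.
#' @return list with `centers` (sorted ascending), `membership`
#'   (`length(values) x n_classes`, rows summing to 1, columns ordered as
#'   `centers`), and `iterations`.
#' @export
fuzzy_cmeans_1d <- function(values, n_classes = 3, m = 2, tol = 1e-5,
                            max_iter = 300, weights = NULL) {
  values <- as.numeric(values)
  stopifnot(length(unique(values)) >= n_classes, m > 1)
  w <- weights %||% rep(1, length(values))
  stopifnot(length(w) == length(values), all(w >= 0))
  probs <- seq(0.1, 0.9, length.out = n_classes)
  centers <- as.numeric(quantile(values, probs, names = FALSE, type = 7))
  # guard identical initial centers (heavily discrete samples)
  centers <- centers + seq(0, 1e-9 * max(diff(range(values)), 1), length.out = n_classes)
  expo <- 2 / (m - 1)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- abs(outer(values, centers, "-")) # n x k distances
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-expo)
    u <- inv / rowSums(inv)
    if (any(zero)) { # exact hits get hard membership
      hit <- which(rowSums(zero) > 0)
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    um <- (u^m) * w
    new_centers <- colSums(um * values) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) {
      ord <- order(centers)
      return(list(centers = centers[ord], membership = u[, ord, drop = FALSE],
                  iterations = it))
    }
  }
  stop(sprintf("fuzzy c-means did not converge in %d iterations (last centers: %s)",
               max_iter, paste(signif(centers, 6), collapse = ", ")))
}

# Binarization threshold from 3-class fuzzy c-means on pixel intensities.
# "extremes" cuts midway between the darkest and brightest centers — the
# half-contrast contour — which tracks the true covered area on simulated
# ground truth and is robust: the middle center is bistable on nearly
# bimodal histograms, while the extreme centers are pinned by the two
# dominant modes. "mid_high" counts the two darker classes, "low_mid"
# only the darkest. Operates on a 256-bin histogram of the sample for
# speed; scale-invariant by construction.
fcm_dark_threshold <- function(values,
                               rule = c("extremes", "mid_high", "low_mid"),
                               n_bins = 256) {
  rule <- match.arg(rule)
  rng <- range(values)
  if (diff(rng) <= 0) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (br[-1] + br[-length(br)]) / 2
  cnt <- tabulate(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  keep <- cnt > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- fuzzy_cmeans_1d(mids[keep], n_classes = 3, weights = cnt[keep])
  switch(rule,
         extremes = (fit$centers[1] + fit$centers[3]) / 2,
         mid_high = (fit$centers[2] + fit$centers[3]) / 2,
         low_mid = (fit$centers[1] + fit$centers[2]) / 2)
}

#' Estimate the bacterial area fraction
#'
#' Binarizes each (pre-processed) frame at a threshold set by 3-class fuzzy
#' c-means clustering of the stack's pooled intensity histogram and counts
#' the
#' fraction of darker pixels (bacteria appear dark in phase contrast).  The
#' area fraction \eqn{\phi} is the mean of the per-frame darker fractions
#' and its quoted error the standard deviation over frames.
#'
#' @param stack an [image_stack()], ideally after [correct_illumination()].
#' @param threshold optional fixed threshold overriding the clustering.
#' @param rule how the binarization threshold is placed between the
#'   fuzzy-c-means centers: `"extremes"` (default) cuts midway between
#'   the darkest and brightest centers — the half-contrast contour, which
#'   matches the true covered area on simulated ground truth and does not
#'   depend on the (bistable) middle center; `"mid_high"` counts the two
#'   darker classes; `"low_mid"` only the darkest.
#' @return list of class `area_fraction_estimate`: `phi`, `phi_sd`,
#'   `n_frames`, `threshold`, `phi_frame` (per-frame series).
#' @export
estimate_area_fraction <- function(stack, threshold = NULL,
                                   rule = c("extremes", "mid_high",
                                            "low_mid")) {
  stopifnot(inherits(stack, "image_stack"))
  vals <- as.numeric(stack$frames)
  if (is.null(threshold)) {
    threshold <- fcm_dark_threshold(vals, rule)
    if (is.na(threshold)) {
      warning("degenerate intensity histogram; falling back to the midrange threshold")
      threshold <- mean(range(vals))
    }
  }
  Tn <- n_frames(stack)
  phi_frame <- vapply(seq_len(Tn),
                      function(t) mean(stack$frames[, , t] < threshold),
                      numeric(1))
  structure(list(phi = mean(phi_frame),
                 phi_sd = if (Tn > 1) sd(phi_frame) else 0,
                 n_frames = Tn, threshold = threshold,
                 phi_frame = phi_frame),
            class = "area_fraction_estimate")
}

#' @export
print.area_fraction_estimate <- function(x, ...) {
  cat(sprintf("area fraction phi = %.4f +/- %.4f (%d frames, threshold %.4g)\n",
              x$phi, x$phi_sd, x$n_frames, x$threshold))
  invisible(x)
}
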