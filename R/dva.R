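#' Relaxation curve container
#'
#' Holds a correlation value per lag time plus, for each lag, the set of
#' instantaneous values over reference times (needed for the chi4 dynamic
#' susceptibilities).  The headline value at each lag is the mean of the
#' per-reference-time samples.
#'
#' @param lags_s strictly increasing lag times (s).
#' @param per_t list (one element per lag) of instantaneous correlation
#'   values over reference times.
#' @param type `"overlap"` or `"orientation"`.
#' @param lag_frames integer lags in frames (metadata).
#' @return object of class `relaxation_curve` with fields `lags` (s),
#'   `values`, `per_t`, `n_ref`, `type`.
#' @export
relaxation_curve <- function(lags_s, per_t, type = "overlap",
                             lag_frames = NULL) {
  stopifnot(length(lags_s) == length(per_t), !is.unsorted(lags_s, strictly = TRUE))
  structure(list(lags = as.numeric(lags_s),
                 values = vapply(per_t, mean, numeric(1)),
                 per_t = per_t,
                 n_ref = vapply(per_t, length, integer(1)),
                 lag_frames = lag_frames,
                 type = type),
            class = "relaxation_curve")
}

#' @export
print.relaxation_curve <- function(x, ...) {
  cat(sprintf("relaxation_curve (%s): %d lags in [%g, %g] s, value range [%.4f, %.4f]\n",
              x$type, length(x$lags), min(x$lags), max(x$lags),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.relaxation_curve <- function(x, ...) {
  data.frame(lag_s = x$lags, value = x$values, n_ref = x$n_ref)
}

#' Intensity difference between two frames
#'
#' \eqn{\Delta I(\vec r, t, \Delta t) = I(\vec r, t + \Delta t) - I(\vec r, t)},
#' the elementary quantity of differential variance analysis.
#'
#' @param stack an [image_stack()].
#' @param t_index 1-based reference frame index.
#' @param lag_frames lag in frames (>= 1).
#' @return signed difference matrix (double).
#' @export
intensity_difference <- function(stack, t_index, lag_frames) {
  stopifnot(inherits(stack, "image_stack"), t_index >= 1, lag_frames >= 1)
  if (t_index + lag_frames > n_frames(stack))
    stop("lag extends beyond the end of the stack")
  stack$frames[, , t_index + lag_frames] - stack$frames[, , t_index]
}

#' Differential variance curve
#'
#' \eqn{V(\Delta t) = \langle \Delta I(\vec r,t,\Delta t)^2 \rangle_{\vec r, t}}
#' over all pixels and all admissible reference times, and the asymptote
#' \eqn{V(\infty)}, evaluated as twice the variance of the intensity pooled
#' over all pixels and frames of the stack.
#'
#' @param stack an [image_stack()].
#' @param lags integer lags in frames; default [lag_frames()] grid.
#' @return list with `lag_frames`, `lags_s`, `V` (per lag), `V_per_t`
#'   (list of per-reference-time spatial means of \eqn{\Delta I^2}), and
#'   `V_inf`.
#' @export
variance_curve <- function(stack, lags = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  Tn <- n_frames(stack)
  if (Tn < 2) stop("at least two frames are required")
  lags <- as.integer(lags %||% lag_frames(Tn))
  if (any(lags < 1) || any(lags >= Tn)) stop("lags must lie in [1, T - 1]")
  I <- stack$frames
  mu <- mean(I)
  v_inf <- 2 * mean((I - mu)^2)
  per_t <- lapply(lags, function(l) {
    ts <- seq_len(Tn - l)
    vapply(ts, function(t) mean((I[, , t + l] - I[, , t])^2), numeric(1))
  })
  list(lag_frames = lags, lags_s = lags * stack$frame_interval,
       V = vapply(per_t, mean, numeric(1)), V_per_t = per_t, V_inf = v_inf)
}

#' Overlap function Q from differential variance analysis
#'
#' \eqn{Q(\Delta t) = 1 - V(\Delta t) / V(\infty)}: an image-based proxy
#' for the fraction of material that has not moved over the lag,
#' behaving like a self-intermediate scattering function.  Instantaneous
#' overlaps \eqn{Q(t, \Delta t)} (no time average) are retained in
#' `per_t` for [chi4_overlap()].
#'
#' @inheritParams variance_curve
#' @return a [relaxation_curve()] of type `"overlap"`, with attribute
#'   fields `V_inf` and `phi` unset.
#' @export
overlap_function <- function(stack, lags = NULL) {
  vc <- variance_curve(stack, lags)
  if (vc$V_inf <= 0)
    stop("V(infinity) = 0: constant stack, overlap undefined")
  per_t <- lapply(vc$V_per_t, function(v) 1 - v / vc$V_inf)
  rc <- relaxation_curve(vc$lags_s, per_t, type = "overlap",
                         lag_frames = vc$lag_frames)
  rc$V_inf <- vc$V_inf
  rc
}

#' chi4 dynamic susceptibility of a relaxation curve
#'
#' \eqn{\chi_4(\Delta t) = \phi\,[\langle C(t,\Delta t)^2\rangle_t -
#' \langle C(t,\Delta t)\rangle_t^2]}: the area-fraction-weighted variance
#' over reference times of the instantaneous correlator, the standard
#' measure of dynamic heterogeneity.  Nonnegative by construction.
#'
#' @param curve a [relaxation_curve()] with per-reference-time samples.
#' @param phi area fraction prefactor (measured \eqn{\phi} of the group).
#' @return object of class `susceptibility_curve`: `lags` (s), `chi4`,
#'   `phi_prefactor`, `n_ref`.
#' @export
chi4_curve <- function(curve, phi) {
  stopifnot(inherits(curve, "relaxation_curve"), phi >= 0)
  if (any(curve$n_ref < 2))
    stop("chi4 requires at least two reference times at every lag")
  chi4 <- phi * vapply(curve$per_t,
                       function(v) mean(v^2) - mean(v)^2, numeric(1))
  chi4[chi4 < 0] <- 0 # guard roundoff
  structure(list(lags = curve$lags, chi4 = chi4, phi_prefactor = phi,
                 n_ref = curve$n_ref, type = curve$type),
            class = "susceptibility_curve")
}

#' @rdname chi4_curve
#' @export
chi4_overlap <- function(curve, phi) {
  if (curve$type != "overlap")
    warning("curve is not an overlap curve")
  chi4_curve(curve, phi)
}

#' @export
print.susceptibility_curve <- function(x, ...) {
  cat(sprintf("susceptibility_curve (%s): %d lags, peak chi4 = %.4g at %g s (phi = %.3f)\n",
              x$type, length(x$lags), max(x$chi4), x$lags[which.max(x$chi4)],
              x$phi_prefactor))
  invisible(x)
}

#' @export
as.data.frame.susceptibility_curve <- function(x, ...) {
  data.frame(lag_s = x$lags, chi4 = x$chi4, n_ref = x$n_ref)
}

#' @export
plot.relaxation_curve <- function(x, ...) {
  ylab <- if (x$type == "orientation") expression(C[theta](Delta * t))
          else expression(Q(Delta * t))
  graphics::plot(x$lags, x$values, log = "x", xlab = "lag (s)", ylab = ylab,
                 ylim = range(c(0, 1, x$values)), ...)
  graphics::abline(h = exp(-1), lty = 3)
  invisible(x)
}

#' @export
plot.susceptibility_curve <- function(x, ...) {
  graphics::plot(x$lags, x$chi4, log = "x", xlab = "lag (s)",
                 ylab = expression(chi[4]), type = "b", ...)
  invisible(x)
}
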