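#' Fit a stretched exponential to a relaxation curve
#'
#' Least-squares fit of \eqn{a\,e^{-(\Delta t/\tau)^\beta}} to a relaxation
#' curve (overlap function or orientational correlator) by the
#' Levenberg-Marquardt algorithm, with a deterministic multi-start over
#' \eqn{\beta \in \{0.5, 1, 1.5\}}.  95% confidence intervals come from the
#' linearized covariance at the optimum.  Internally \eqn{\tau} and
#' \eqn{\beta} are fitted on the log scale (keeping them positive, and
#' giving log-symmetric intervals); the amplitude is bounded in
#' `(0, 1.5]` and \eqn{\beta \le 2}.
#'
#' A curve that never decays below \eqn{a/e} inside the fitted window does
#' not constrain \eqn{\tau} from above.  By default this is an error
#' ("relaxation not observed within window"); with
#' `accept_extrapolated = TRUE` the fit proceeds and is flagged
#' `censored = TRUE`, meaning \eqn{\tau} should be read as a lower bound
#' (such curves are excluded from relaxation-law fits by default).
#'
#' @param curve a [relaxation_curve()], or a list/data frame with numeric
#'   `lags` and `values`.
#' @param fit_range optional `c(min, max)` lag window (s).
#' @param accept_extrapolated accept curves that do not decay below
#'   \eqn{a/e} in the window (see Details).
#' @param conf confidence level for the intervals.
#' @return object of class `stretched_exp_fit` with `tau`, `beta`,
#'   `amplitude`, their `conf`-level CIs (`tau_ci`, `beta_ci`), `censored`,
#'   `residual_norm`, `fitted`, `data`.
#' @export
fit_stretched_exponential <- function(curve, fit_range = NULL,
                                      accept_extrapolated = FALSE,
                                      conf = 0.95) {
  lags <- curve$lags
  vals <- curve$values
  stopifnot(length(lags) == length(vals), all(lags > 0))
  if (!is.null(fit_range)) {
    keep <- lags >= fit_range[1] & lags <= fit_range[2]
    lags <- lags[keep]; vals <- vals[keep]
  }
  if (length(lags) < 5) stop("need at least 5 points in the fit range")
  a0 <- min(max(vals[1], 0.05), 1.5)
  decayed <- min(vals) < a0 / exp(1)
  if (!decayed && !accept_extrapolated)
    stop("relaxation not observed within window (curve does not decay below a/e); set accept_extrapolated = TRUE for a lower-bound fit")
  # tau start: first crossing of a0/e, linearly interpolated in log-lag
  tau0 <- if (decayed) {
    i <- which(vals < a0 / exp(1))[1]
    if (i == 1) lags[1] else {
      exp(approx(vals[(i - 1):i], log(lags[(i - 1):i]),
                 xout = a0 / exp(1))$y)
    }
  } else max(lags)
  model <- function(p, t) p[1] * exp(-(t / exp(p[2]))^exp(p[3]))
  best <- NULL
  for (beta0 in c(0.5, 1, 1.5)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(a = a0, ltau = log(tau0), lbeta = log(beta0)),
      fn = function(p) model(p, lags) - vals,
      lower = c(1e-8, -Inf, log(0.01)),
      upper = c(1.5, log(1e6 * max(lags)), log(2)),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("stretched-exponential fit failed from all starts")
  p <- best$par
  n <- length(lags); npar <- 3
  dof <- max(n - npar, 1)
  sigma2 <- best$deviance / dof
  vc <- try(sigma2 * solve(best$hessian), silent = TRUE)
  se <- if (inherits(vc, "try-error")) rep(NA_real_, 3) else sqrt(pmax(diag(vc), 0))
  tq <- qt(1 - (1 - conf) / 2, dof)
  tau <- exp(p[["ltau"]]); beta <- exp(p[["lbeta"]])
  structure(list(
    tau = tau, beta = beta, amplitude = p[["a"]],
    tau_ci = exp(p[["ltau"]] + c(-1, 1) * tq * se[2]),
    beta_ci = exp(p[["lbeta"]] + c(-1, 1) * tq * se[3]),
    amplitude_ci = p[["a"]] + c(-1, 1) * tq * se[1],
    censored = !decayed,
    residual_norm = sqrt(best$deviance),
    conf = conf, dof = dof,
    data = data.frame(lag_s = lags, value = vals),
    fitted = model(p, lags)),
    class = "stretched_exp_fit")
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  cat(sprintf("stretched exponential: tau = %.4g s [%.4g, %.4g], beta = %.3g [%.3g, %.3g]%s\n",
              x$tau, x$tau_ci[1], x$tau_ci[2],
              x$beta, x$beta_ci[1], x$beta_ci[2],
              if (x$censored) "  (censored: tau is a lower bound)" else ""))
  invisible(x)
}

#' @export
coef.stretched_exp_fit <- function(object, ...) {
  c(tau = object$tau, beta = object$beta, amplitude = object$amplitude)
}

#' @export
predict.stretched_exp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$lag_s
       else if (is.list(newdata)) newdata$lag_s else newdata
  object$amplitude * exp(-(t / object$tau)^object$beta)
}

#' @export
residuals.stretched_exp_fit <- function(object, ...) {
  object$data$value - object$fitted
}

#' @export
summary.stretched_exp_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  amplitude = %.3g [%.3g, %.3g]; residual norm %.3g over %d points\n",
              object$amplitude, object$amplitude_ci[1], object$amplitude_ci[2],
              object$residual_norm, nrow(object$data)))
  invisible(object)
}

#' @export
plot.stretched_exp_fit <- function(x, ...) {
  graphics::plot(x$data$lag_s, x$data$value, log = "x",
                 xlab = "lag (s)", ylab = "correlation", ...)
  tt <- exp(seq(log(min(x$data$lag_s)), log(max(x$data$lag_s)), length.out = 200))
  graphics::lines(tt, predict(x, tt), col = 2)
  invisible(x)
}

# shared LM machinery for the relaxation-time laws (fits in log tau)
fit_tau_law <- function(phis, taus, resid_fn, starts, lower, upper,
                        par_names, conf) {
  stopifnot(length(phis) == length(taus))
  ok <- is.finite(phis) & is.finite(taus) & taus > 0
  phis <- phis[ok]; taus <- taus[ok]
  if (length(phis) < 4) stop("need at least 4 (phi, tau) pairs")
  if (any(diff(taus[order(phis)]) < 0))
    warning("tau(phi) is not monotonically increasing; fit proceeds")
  lt <- log(taus)
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = function(p) resid_fn(p, phis, lt),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("law fit failed from all starts")
  n <- length(phis); npar <- length(best$par)
  dof <- max(n - npar, 1)
  sigma2 <- best$deviance / dof
  vc <- try(sigma2 * solve(best$hessian), silent = TRUE)
  se <- if (inherits(vc, "try-error")) rep(NA_real_, npar) else sqrt(pmax(diag(vc), 0))
  names(se) <- par_names
  pred <- lt - resid_fn(best$par, phis, lt)
  r2 <- 1 - best$deviance / sum((lt - mean(lt))^2)
  list(par = setNames(best$par, par_names), se = se, dof = dof,
       tq = qt(1 - (1 - conf) / 2, dof), deviance = best$deviance,
       r_squared = r2,
       data = data.frame(phi = phis, tau = taus, log_tau_fitted = pred))
}

#' Fit the mode-coupling power law to relaxation times
#'
#' \eqn{\tau \sim (\phi_c - \phi)^{-\gamma}}: least squares of
#' \eqn{\log\tau} against \eqn{\log A - \gamma \log(\phi_c - \phi)} with
#' the critical area fraction \eqn{\phi_c} as a free (nonlinear)
#' parameter, fitted by Levenberg-Marquardt with a deterministic
#' multi-start in \eqn{\phi_c}.  Fitting in log \eqn{\tau} weights the
#' decades of slowdown evenly and makes the fit invariant under
#' \eqn{\tau \to a\tau}.
#'
#' @param phis area fractions (all strictly below the fitted \eqn{\phi_c}).
#' @param taus relaxation times (s), same length.
#' @param conf confidence level.
#' @return object of class `mct_fit`: `phi_c`, `gamma`, `amplitude`, CIs,
#'   `r_squared`, `data`.
#' @export
fit_mct <- function(phis, taus, conf = 0.95) {
  phimax <- max(phis[is.finite(phis) & is.finite(taus)])
  resid_fn <- function(p, phi, lt) lt - (p[1] - p[2] * log(pmax(p[3] - phi, 1e-12)))
  starts <- lapply(c(0.003, 0.01, 0.03, 0.08, 0.2),
                   function(d) c(logA = 0, gamma = 2,
                                 phi_c = min(phimax + d, 1)))
  f <- fit_tau_law(phis, taus, resid_fn, starts,
                   lower = c(-Inf, 1e-6, phimax + 1e-9),
                   upper = c(Inf, 50, 1),
                   par_names = c("logA", "gamma", "phi_c"), conf = conf)
  structure(list(phi_c = unname(f$par["phi_c"]), gamma = unname(f$par["gamma"]),
                 amplitude = exp(unname(f$par["logA"])),
                 phi_c_ci = f$par["phi_c"] + c(-1, 1) * f$tq * f$se["phi_c"],
                 gamma_ci = f$par["gamma"] + c(-1, 1) * f$tq * f$se["gamma"],
                 phi_c_se = unname(f$se["phi_c"]), gamma_se = unname(f$se["gamma"]),
                 r_squared = f$r_squared, conf = conf, dof = f$dof,
                 data = f$data),
            class = "mct_fit")
}

#' @export
print.mct_fit <- function(x, ...) {
  cat(sprintf("MCT power law: phi_c = %.4g [%.4g, %.4g], gamma = %.3g [%.3g, %.3g], R2(log tau) = %.3f\n",
              x$phi_c, x$phi_c_ci[1], x$phi_c_ci[2],
              x$gamma, x$gamma_ci[1], x$gamma_ci[2], x$r_squared))
  invisible(x)
}

#' @export
coef.mct_fit <- function(object, ...) {
  c(phi_c = object$phi_c, gamma = object$gamma, amplitude = object$amplitude)
}

#' @export
predict.mct_fit <- function(object, newdata = NULL, ...) {
  phi <- if (is.null(newdata)) object$data$phi
         else if (is.list(newdata)) newdata$phi else newdata
  object$amplitude * pmax(object$phi_c - phi, 1e-12)^(-object$gamma)
}

#' Fit the Vogel-Fulcher-Tammann law to relaxation times
#'
#' \eqn{\tau \sim A \exp[c\,\phi/(\phi_{VFT} - \phi)]} (default), or the
#' variant \eqn{\tau \sim A \exp[c/(\phi_{VFT} - \phi)]} with
#' `variant = "simple"`.  Fitted like [fit_mct()], in log \eqn{\tau}.
#'
#' @inheritParams fit_mct
#' @param variant `"phi"` (numerator \eqn{c\phi}) or `"simple"`
#'   (numerator \eqn{c}).
#' @return object of class `vft_fit`: `phi_vft`, `c`, `amplitude`, CIs,
#'   `r_squared`, `data`.
#' @export
fit_vft <- function(phis, taus, variant = c("phi", "simple"), conf = 0.95) {
  variant <- match.arg(variant)
  phimax <- max(phis[is.finite(phis) & is.finite(taus)])
  num <- if (variant == "phi") function(p, phi) p[2] * phi else function(p, phi) p[2]
  resid_fn <- function(p, phi, lt) lt - (p[1] + num(p, phi) / pmax(p[3] - phi, 1e-12))
  starts <- lapply(c(0.01, 0.03, 0.1, 0.3),
                   function(d) c(logA = 0, c = 1, phi_vft = phimax + d))
  f <- fit_tau_law(phis, taus, resid_fn, starts,
                   lower = c(-Inf, 1e-8, phimax + 1e-9),
                   upper = c(Inf, Inf, phimax + 10),
                   par_names = c("logA", "c", "phi_vft"), conf = conf)
  structure(list(phi_vft = unname(f$par["phi_vft"]), c = unname(f$par["c"]),
                 amplitude = exp(unname(f$par["logA"])),
                 phi_vft_ci = f$par["phi_vft"] + c(-1, 1) * f$tq * f$se["phi_vft"],
                 c_ci = f$par["c"] + c(-1, 1) * f$tq * f$se["c"],
                 r_squared = f$r_squared, variant = variant, conf = conf,
                 dof = f$dof, data = f$data),
            class = "vft_fit")
}

#' @export
print.vft_fit <- function(x, ...) {
  cat(sprintf("VFT law (%s): phi_VFT = %.4g [%.4g, %.4g], c = %.3g [%.3g, %.3g], R2(log tau) = %.3f\n",
              x$variant, x$phi_vft, x$phi_vft_ci[1], x$phi_vft_ci[2],
              x$c, x$c_ci[1], x$c_ci[2], x$r_squared))
  invisible(x)
}

#' @export
coef.vft_fit <- function(object, ...) {
  c(phi_vft = object$phi_vft, c = object$c, amplitude = object$amplitude)
}

#' @export
predict.vft_fit <- function(object, newdata = NULL, ...) {
  phi <- if (is.null(newdata)) object$data$phi
         else if (is.list(newdata)) newdata$phi else newdata
  num <- if (object$variant == "phi") object$c * phi else object$c
  object$amplitude * exp(num / pmax(object$phi_vft - phi, 1e-12))
}

#' Minimal MCT exponent gamma for thermal systems
#'
#' In mode-coupling theory the divergence exponent \eqn{\gamma =
#' 1/(2a) + 1/(2b)}, where the exponents \eqn{a \in (0, 1/2)} and
#' \eqn{b \in (0, 1]} both satisfy
#' \eqn{\lambda = \Gamma(1-a)^2/\Gamma(1-2a) = \Gamma(1+b)^2/\Gamma(1+2b)}
#' for the exponent parameter \eqn{\lambda \in [1/2, 1)}.  \eqn{\gamma}
#' increases with \eqn{\lambda}, so its minimum over thermal systems is
#' attained at \eqn{\lambda = 1/2}, where \eqn{b = 1} exactly
#' (\eqn{\Gamma(2)^2/\Gamma(3) = 1/2}) and \eqn{a} solves
#' \eqn{\Gamma(1-a)^2/\Gamma(1-2a) = 1/2}; numerically
#' \eqn{\gamma_{min} \approx 1.765}.  A measured \eqn{\gamma} below this
#' bound is impossible for a thermal glass former.
#'
#' @param lambda_grid values of \eqn{\lambda} at which to tabulate
#'   \eqn{\gamma(\lambda)} (default a grid on `[0.5, 0.99]`).
#' @param tol root-finding tolerance.
#' @return list: `gamma_min`, `a` (exponent at the bound), `b` (= 1),
#'   `lambda` (= 1/2), and `grid` (data frame `lambda`, `a`, `b`,
#'   `gamma`).
#' @export
mct_thermal_gamma_min <- function(lambda_grid = seq(0.5, 0.99, by = 0.01),
                                  tol = 1e-12) {
  lam_a <- function(a) gamma(1 - a)^2 / gamma(1 - 2 * a)
  lam_b <- function(b) gamma(1 + b)^2 / gamma(1 + 2 * b)
  solve_a <- function(lambda)
    uniroot(function(a) lam_a(a) - lambda, c(1e-9, 0.5 - 1e-9), tol = tol)$root
  solve_b <- function(lambda) {
    if (abs(lambda - 0.5) < 1e-13) return(1)
    uniroot(function(b) lam_b(b) - lambda, c(1e-9, 1), tol = tol)$root
  }
  a_min <- solve_a(0.5)
  gamma_min <- 1 / (2 * a_min) + 1 / 2
  grid <- data.frame(lambda = lambda_grid)
  grid$a <- vapply(grid$lambda, solve_a, numeric(1))
  grid$b <- vapply(grid$lambda, solve_b, numeric(1))
  grid$gamma <- 1 / (2 * grid$a) + 1 / (2 * grid$b)
  list(gamma_min = gamma_min, a = a_min, b = 1, lambda = 0.5, grid = grid)
}

#' @export
plot.mct_fit <- function(x, ...) {
  graphics::plot(x$data$phi, x$data$tau, log = "y",
                 xlab = expression(phi), ylab = expression(tau ~ "(s)"), ...)
  pp <- seq(min(x$data$phi), min(max(x$data$phi), x$phi_c - 1e-4),
            length.out = 200)
  graphics::lines(pp, predict(x, pp), col = 2)
  graphics::abline(v = x$phi_c, lty = 2)
  invisible(x)
}

#' @export
plot.vft_fit <- function(x, ...) {
  graphics::plot(x$data$phi, x$data$tau, log = "y",
                 xlab = expression(phi), ylab = expression(tau ~ "(s)"), ...)
  pp <- seq(min(x$data$phi), min(max(x$data$phi), x$phi_vft - 1e-4),
            length.out = 200)
  graphics::lines(pp, predict(x, pp), col = 2)
  invisible(x)
}
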