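#' Static structure factor of the image intensity
#'
#' Per frame, the frame mean is subtracted (removing the otherwise
#' dominant q = 0 peak), the 2D discrete Fourier transform is taken, and
#' its squared modulus — normalized by the pixel count — is averaged over
#' frames:
#' \eqn{S(\vec q) = \langle |FT[I(\vec r, t)]|^2 \rangle_t / N_{px}}.
#' Wavenumbers are physical, \eqn{q_x = 2\pi k_x / (W\,\mathrm{px})}.
#' The angle-averaged \eqn{S(q)} is computed over annular bins of width
#' one frequency step of the smaller image dimension, excluding the DC
#' bin.
#'
#' @param stack an [image_stack()] (square pixels assumed).
#' @param window apply a Hann window before transforming (default off; the
#'   bare transform matches the definition above).
#' @return object of class `structure_factor`: `sq2d` (H x W, DC at
#'   element \[1,1\] as returned by the FFT), `qx`, `qy` (1/um, FFT
#'   ordering), `q_grid` (radial bin centers, 1/um), `sq_radial`,
#'   `n_frames`.
#' @export
static_structure_factor <- function(stack, window = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; Tn <- d[3]
  px <- stack$pixel_size
  win <- if (window) {
    wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(H) / (H + 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * seq_len(W) / (W + 1))
    outer(wy, wx)
  } else NULL
  acc <- matrix(0, H, W)
  for (t in seq_len(Tn)) {
    f <- stack$frames[, , t]
    f <- f - mean(f)
    if (!is.null(win)) f <- f * win
    acc <- acc + Mod(fft(f))^2
  }
  sq2d <- acc / (Tn * H * W)
  # physical wavenumbers in FFT ordering (rows = y, columns = x)
  ky <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) # H elements
  kx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1))
  qy <- 2 * pi * ky / (H * px)
  qx <- 2 * pi * kx / (W * px)
  qmag <- sqrt(outer(qy^2, qx^2, "+"))
  dq <- 2 * pi / (min(H, W) * px)
  bin <- matrix(pmax(1L, as.integer(round(qmag / dq))), H, W)
  bin[1, 1] <- NA_integer_ # exclude DC
  nb <- max(bin, na.rm = TRUE)
  sums <- tapply(as.numeric(sq2d), as.integer(bin), sum)
  cnts <- tapply(rep(1, length(bin)), as.integer(bin), sum)
  q_grid <- as.integer(names(sums)) * dq
  keep <- q_grid <= pi / px # stay within the Nyquist disk
  structure(list(sq2d = sq2d, qx = qx, qy = qy,
                 q_grid = q_grid[keep],
                 sq_radial = (sums / cnts)[keep],
                 n_frames = Tn, pixel_size = px),
            class = "structure_factor")
}

#' @export
print.structure_factor <- function(x, ...) {
  cat(sprintf("structure_factor: %d frames, %d radial bins, q in [%.3g, %.3g] 1/um\n",
              x$n_frames, length(x$q_grid), min(x$q_grid), max(x$q_grid)))
  invisible(x)
}

#' @export
as.data.frame.structure_factor <- function(x, ...) {
  data.frame(q_inv_um = x$q_grid, S = as.numeric(x$sq_radial))
}
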