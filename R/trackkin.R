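#' Segment rod-shaped cells in a single frame
#'
#' Classical segmentation: binarize dark cells at a fuzzy-c-means
#' threshold (see [estimate_area_fraction()]), clean with a morphological
#' opening, split touching rods by a distance-transform watershed, and
#' summarize each component by its second-moment ellipse.  Coordinates
#' are physical (um), centered on the image center with the y axis
#' pointing up — the same convention as the rod simulator.
#'
#' @param frame numeric matrix (dark cells on bright background).
#' @param pixel_size um per pixel.
#' @param threshold binarization threshold; default from 3-class fuzzy
#'   c-means on the frame histogram.
#' @param min_area_px components smaller than this are discarded.
#' @param opening_size diameter of the opening brush (px); 0 disables.
#' @param watershed_tolerance tolerance of [EBImage::watershed()] on the
#'   distance map (px).
#' @return data frame with one row per detected cell: `x_um`, `y_um`,
#'   `angle_rad` (nematic), `length_um`, `area_px`.
#' @export
segment_cells <- function(frame, pixel_size, threshold = NULL,
                          min_area_px = 4, opening_size = 3,
                          watershed_tolerance = 1) {
  stopifnot(is.matrix(frame), pixel_size > 0)
  empty <- data.frame(x_um = numeric(), y_um = numeric(),
                      angle_rad = numeric(), length_um = numeric(),
                      area_px = integer())
  # the conservative darkest-class cut keeps touching cells separable
  threshold <- threshold %||% fcm_dark_threshold(as.numeric(frame), "low_mid")
  if (is.na(threshold)) return(empty)
  mask <- (frame < threshold) * 1
  if (!any(mask > 0)) return(empty)
  if (opening_size > 0)
    mask <- EBImage::opening(mask, EBImage::makeBrush(opening_size, "diamond"))
  if (!any(mask > 0)) return(empty)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance))
  H <- nrow(frame); W <- ncol(frame)
  out <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    x <- (idx[, 2] - 0.5 - W / 2) * pixel_size
    y <- (H / 2 - idx[, 1] + 0.5) * pixel_size
    cx <- mean(x); cy <- mean(y)
    mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
    mu11 <- mean((x - cx) * (y - cy))
    ang <- wrap_nematic_angle(0.5 * atan2(2 * mu11, mu20 - mu02))
    lam_max <- (mu20 + mu02) / 2 + sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    data.frame(x_um = cx, y_um = cy, angle_rad = ang,
               length_um = sqrt(12 * lam_max), area_px = nrow(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

# optimal frame-to-frame correspondence with birth/death costs, via the
# Hungarian algorithm on the standard augmented square matrix
link_assign <- function(src, dst, max_disp) {
  n1 <- nrow(src); n2 <- nrow(dst)
  BIG <- 1e12
  d2 <- outer(src$x_um, dst$x_um, "-")^2 + outer(src$y_um, dst$y_um, "-")^2
  d2[d2 > max_disp^2] <- BIG
  n <- n1 + n2
  cost <- matrix(0, n, n) # dummy-dummy block stays free
  cost[seq_len(n1), seq_len(n2)] <- d2
  if (n1 > 0) { # track death: own dummy column only
    m <- matrix(BIG, n1, n1); diag(m) <- max_disp^2
    cost[seq_len(n1), n2 + seq_len(n1)] <- m
  }
  if (n2 > 0) { # track birth: own dummy row only
    m <- matrix(BIG, n2, n2); diag(m) <- max_disp^2
    cost[n1 + seq_len(n2), seq_len(n2)] <- m
  }
  a <- hungarian_cpp(cost)
  # returns for each source row the matched destination (0 = track ends)
  match_dst <- integer(n1)
  for (i in seq_len(n1)) match_dst[i] <- if (a[i] <= n2) a[i] else 0L
  new_dst <- setdiff(seq_len(n2), match_dst)
  list(match = match_dst, new = new_dst)
}

#' Link per-frame detections into cell tracks
#'
#' Frame-to-frame correspondence minimizing the total squared displacement
#' subject to a per-link cutoff, solved exactly (Hungarian algorithm on
#' the augmented cost matrix with birth/death cost `max_disp_um^2`) — the
#' assignment strategy of classical colloid-tracking codes.  Unmatched
#' detections start new tracks; tracks that miss up to `max_gap` frames
#' are bridged when a detection reappears within the cutoff.  Detections
#' are canonically ordered internally, so the result is invariant under
#' permutation of the input rows; ties between equal-cost optima resolve
#' deterministically in that canonical order.
#'
#' @param detections list of per-frame data frames (columns `x_um`,
#'   `y_um`, extra columns are carried through), or one data frame with a
#'   `frame` column.
#' @param max_disp_um per-link displacement cutoff (um).
#' @param max_gap number of missed frames a track may bridge.
#' @param frame_interval seconds per frame (for the `t_s` column).
#' @return data frame of class `cell_tracks`: `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, plus any extra detection columns.
#' @export
link_tracks <- function(detections, max_disp_um, max_gap = 0,
                        frame_interval = 1) {
  if (is.data.frame(detections)) {
    stopifnot("frame" %in% names(detections))
    fr_ids <- sort(unique(detections$frame))
    detections <- lapply(fr_ids, function(f)
      detections[detections$frame == f, setdiff(names(detections), "frame"),
                 drop = FALSE])
  }
  Tn <- length(detections)
  if (Tn < 2) stop("need detections from at least two frames")
  detections <- lapply(detections, function(d) {
    d <- as.data.frame(d)
    d[order(d$x_um, d$y_um), , drop = FALSE]
  })
  next_id <- 0L
  # active track state: id, last frame, last row (detection data)
  active <- list()
  rows <- list()
  emit <- function(id, frame, det_row) {
    det_row$track_id <- id
    det_row$frame <- frame
    rows[[length(rows) + 1L]] <<- det_row
  }
  # start tracks from frame 1
  d1 <- detections[[1]]
  for (i in seq_len(nrow(d1))) {
    next_id <- next_id + 1L
    active[[length(active) + 1L]] <- list(id = next_id, last_frame = 1L,
                                          det = d1[i, , drop = FALSE])
    emit(next_id, 1L, d1[i, , drop = FALSE])
  }
  for (f in 2:Tn) {
    dst <- detections[[f]]
    live <- which(vapply(active, function(a) f - a$last_frame <= max_gap + 1L,
                         logical(1)))
    src <- if (length(live))
      do.call(rbind, lapply(active[live], function(a) a$det))
    else data.frame(x_um = numeric(), y_um = numeric())
    if (nrow(src) > 0 && nrow(dst) > 0) {
      res <- link_assign(src, dst, max_disp_um)
    } else {
      res <- list(match = integer(nrow(src)), new = seq_len(nrow(dst)))
    }
    for (k in seq_along(res$match)) {
      j <- res$match[k]
      if (j > 0) {
        a <- active[[live[k]]]
        a$last_frame <- f
        a$det <- dst[j, , drop = FALSE]
        active[[live[k]]] <- a
        emit(a$id, f, dst[j, , drop = FALSE])
      }
    }
    for (j in res$new) {
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <- list(id = next_id, last_frame = f,
                                            det = dst[j, , drop = FALSE])
      emit(next_id, f, dst[j, , drop = FALSE])
    }
  }
  out <- do.call(rbind, rows)
  out$t_s <- (out$frame - 1) * frame_interval
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  front <- c("track_id", "frame", "t_s", "x_um", "y_um")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  class(out) <- c("cell_tracks", "data.frame")
  attr(out, "frame_interval") <- frame_interval
  out
}

# displacement pairs (t, t + lag) available in a track table
track_steps <- function(tracks, lag) {
  do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    m <- match(tr$frame + lag, tr$frame)
    ok <- !is.na(m)
    if (!any(ok)) return(NULL)
    data.frame(track_id = tr$track_id[ok],
               frame = tr$frame[ok],
               x0 = tr$x_um[ok], y0 = tr$y_um[ok],
               x1 = tr$x_um[m[ok]], y1 = tr$y_um[m[ok]],
               a0 = if ("angle_rad" %in% names(tr)) tr$angle_rad[ok] else NA,
               a1 = if ("angle_rad" %in% names(tr)) tr$angle_rad[m[ok]] else NA)
  }))
}

#' Histogram of the displacement-orientation angle
#'
#' For each cell and reference time, the angle between the displacement
#' over the lag and the cell's nematic axis (the wrapped mean of the axis
#' at the two endpoints), folded into \[0 deg, 90 deg\] and normalized to
#' a probability histogram.  Motion guided by the orientation field
#' concentrates mass at small angles.
#'
#' @param tracks a [link_tracks()] table with an `angle_rad` column.
#' @param lag_frames displacement lag in frames.
#' @param n_bins number of equal bins on \[0, 90\] degrees.
#' @param min_disp_um displacements smaller than this are excluded (below
#'   the localization resolution) and counted in `n_excluded`.
#' @return list: `breaks_deg`, `mid_deg`, `prob`, `counts`, `n_excluded`.
#' @export
displacement_orientation_histogram <- function(tracks, lag_frames = 1,
                                               n_bins = 9,
                                               min_disp_um = 0.02) {
  st <- track_steps(tracks, lag_frames)
  if (is.null(st) || !nrow(st)) stop("no track spans cover the requested lag")
  dx <- st$x1 - st$x0; dy <- st$y1 - st$y0
  disp <- sqrt(dx^2 + dy^2)
  keep <- disp >= min_disp_um
  n_excluded <- sum(!keep)
  st <- st[keep, ]; dx <- dx[keep]; dy <- dy[keep]
  if (!nrow(st)) stop("all displacements below the resolution cutoff")
  axis <- st$a0 + nematic_diff(st$a1, st$a0) / 2 # wrapped midpoint axis
  delta <- abs(nematic_diff(atan2(dy, dx), axis)) * 180 / pi # [0, 90]
  breaks <- seq(0, 90, length.out = n_bins + 1)
  counts <- tabulate(findInterval(delta, breaks, rightmost.closed = TRUE),
                     n_bins)
  list(breaks_deg = breaks, mid_deg = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
       prob = counts / sum(counts), counts = counts,
       n_excluded = n_excluded)
}

#' Velocity correlation versus distance
#'
#' Velocities are centroid displacements over `lag_frames` divided by the
#' lag time; for every pair of concurrent cells the dot product
#' \eqn{\vec v_i \cdot \vec v_j} is accumulated into the bin of their
#' distance at the reference time.  The standard error treats all pairs
#' as independent.
#'
#' @param tracks a [link_tracks()] table.
#' @param lag_frames velocity lag in frames (default 2, about 0.053 s at
#'   the reference frame rate).
#' @param bin_um distance bin width (um).
#' @param frame_interval seconds per frame; default from the track table.
#' @return object of class `velocity_correlation`: data frame `r_um`
#'   (bin centers), `corr` ((um/s)^2), `stderr`, `n_pairs`.
#' @export
velocity_correlation <- function(tracks, lag_frames = 2, bin_um = 0.5,
                                 frame_interval = NULL) {
  dt <- frame_interval %||% attr(tracks, "frame_interval") %||% 1
  st <- track_steps(tracks, lag_frames)
  if (is.null(st) || !nrow(st)) stop("no track spans cover the requested lag")
  lag_s <- lag_frames * dt
  st$vx <- (st$x1 - st$x0) / lag_s
  st$vy <- (st$y1 - st$y0) / lag_s
  acc <- list()
  for (f in unique(st$frame)) {
    s <- st[st$frame == f, ]
    n <- nrow(s)
    if (n < 2) next
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    r <- sqrt((s$x0[ij[, 1]] - s$x0[ij[, 2]])^2 +
              (s$y0[ij[, 1]] - s$y0[ij[, 2]])^2)
    dot <- s$vx[ij[, 1]] * s$vx[ij[, 2]] + s$vy[ij[, 1]] * s$vy[ij[, 2]]
    acc[[length(acc) + 1L]] <- data.frame(bin = floor(r / bin_um), dot = dot)
  }
  if (!length(acc)) {
    warning("no concurrent cell pairs")
    return(structure(data.frame(r_um = numeric(), corr = numeric(),
                                stderr = numeric(), n_pairs = integer()),
                     class = c("velocity_correlation", "data.frame")))
  }
  d <- do.call(rbind, acc)
  agg_mean <- tapply(d$dot, d$bin, mean)
  agg_sd <- tapply(d$dot, d$bin, function(v) if (length(v) > 1) sd(v) else NA)
  agg_n <- tapply(d$dot, d$bin, length)
  bins <- as.integer(names(agg_mean))
  structure(data.frame(r_um = (bins + 0.5) * bin_um,
                       corr = as.numeric(agg_mean),
                       stderr = as.numeric(agg_sd) / sqrt(as.numeric(agg_n)),
                       n_pairs = as.integer(agg_n)),
            class = c("velocity_correlation", "data.frame"))
}

#' Flag cage-escape episodes in a track
#'
#' Descriptive utility: a cage escape is flagged whenever the displacement
#' within a sliding time window exceeds a threshold (default two cell
#' widths in 2 s), the signature of a cell breaking out of the cage formed
#' by its neighbors.
#'
#' @param tracks a [link_tracks()] table.
#' @param window_s window length (s).
#' @param threshold_um displacement threshold (um).
#' @return data frame `track_id`, `t_s` (window start), `disp_um` for
#'   every flagged window.
#' @export
flag_cage_escapes <- function(tracks, window_s = 2, threshold_um = 2) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$t_s), ]
    hits <- lapply(seq_len(nrow(tr)), function(i) {
      j <- which(tr$t_s > tr$t_s[i] & tr$t_s <= tr$t_s[i] + window_s)
      if (!length(j)) return(NULL)
      d <- sqrt((tr$x_um[j] - tr$x_um[i])^2 + (tr$y_um[j] - tr$y_um[i])^2)
      if (max(d) > threshold_um)
        data.frame(track_id = tr$track_id[1], t_s = tr$t_s[i],
                   disp_um = max(d))
      else NULL
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(track_id = integer(), t_s = numeric(),
                               disp_um = numeric())
  else { rownames(out) <- NULL; out }
}
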