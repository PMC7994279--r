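#' Interpolate a displacement field at arbitrary points
#'
#' Bilinear interpolation of the horizontal and vertical components,
#' independently, from the four grid nodes surrounding each query point.
#' Invalid nodes are excluded and the remaining weights renormalized; if all
#' four corners are invalid the point falls back to (0, 0) and is flagged.
#' Queries outside the grid's bounding box snap to the nearest node and are
#' flagged.
#'
#' @param field A `displacement_field` from [estimate_interframe_field()].
#' @param query_points n x 2 matrix of (x, y).
#' @return List with `u`, `v` (numeric vectors) and `flagged` (logical:
#'   out-of-grid fallback or no valid corner).
#' @export
interpolate_field_at <- function(field, query_points) {
  stopifnot(inherits(field, "displacement_field"))
  p <- as_points_matrix(query_points)
  gx <- field$grid_x; gy <- field$grid_y
  if (length(gx) == 0 || length(gy) == 0) stop("empty field", call. = FALSE)
  n <- nrow(p)
  u <- v <- numeric(n)
  flagged <- logical(n)
  for (q in seq_len(n)) {
    x <- p[q, 1]; y <- p[q, 2]
    out_of_hull <- x < gx[1] || x > gx[length(gx)] ||
      y < gy[1] || y > gy[length(gy)]
    xc <- min(max(x, gx[1]), gx[length(gx)])
    yc <- min(max(y, gy[1]), gy[length(gy)])
    jx <- findInterval(xc, gx, rightmost.closed = TRUE)
    jy <- findInterval(yc, gy, rightmost.closed = TRUE)
    jx <- min(max(jx, 1L), length(gx) - 1L)
    jy <- min(max(jy, 1L), length(gy) - 1L)
    if (length(gx) == 1L) jx <- 1L
    if (length(gy) == 1L) jy <- 1L
    jx1 <- min(jx + 1L, length(gx)); jy1 <- min(jy + 1L, length(gy))
    dx <- if (gx[jx1] > gx[jx]) (xc - gx[jx]) / (gx[jx1] - gx[jx]) else 0
    dy <- if (gy[jy1] > gy[jy]) (yc - gy[jy]) / (gy[jy1] - gy[jy]) else 0
    iy <- c(jy, jy1, jy, jy1); ix <- c(jx, jx, jx1, jx1)
    wt <- c((1 - dy) * (1 - dx), dy * (1 - dx), (1 - dy) * dx, dy * dx)
    ok <- field$valid[cbind(iy, ix)]
    wt[!ok] <- 0
    s <- sum(wt)
    if (s <= 0) {
      # nearest *valid* corner if any, else fallback 0
      if (any(ok)) {
        k <- which(ok)[1]
        u[q] <- field$u[iy[k], ix[k]]; v[q] <- field$v[iy[k], ix[k]]
      }
      flagged[q] <- TRUE
    } else {
      wt <- wt / s
      u[q] <- sum(wt * field$u[cbind(iy, ix)])
      v[q] <- sum(wt * field$v[cbind(iy, ix)])
      flagged[q] <- out_of_hull
    }
  }
  list(u = u, v = v, flagged = flagged)
}

#' Accumulate interframe fields into material-point trajectories
#'
#' Implements continuous (Lagrangian) tracking: the increment of a point at
#' step k is the k-th interframe field interpolated at the point's *current*
#' (moved) position — not at its original position — and the position is
#' advanced by that increment. Grid nodes play the role of the fixed "black
#' dots"; a tracked point that has moved between frames is the "green dot"
#' whose displacement is interpolated linearly from the surrounding nodes.
#' Cumulative displacement is the prefix sum of the increments, so the
#' position at frame k is exactly `points0 + (cumulative_u, cumulative_v)`.
#' A point whose trajectory leaves the image is frozen at its last position
#' and flagged from that frame onward.
#'
#' @param fields Ordered list of `displacement_field` objects for steps
#'   0 to 1, 1 to 2, ..., all on the same grid geometry.
#' @param points0 n x 2 matrix of initial (x, y) positions at frame 0.
#' @return An object of class `trajectory_set`: matrices of dimension
#'   `(n_frames, n_points)` — `x`, `y` (positions), `interframe_u`,
#'   `interframe_v` (row 1 is zero), `cumulative_u`, `cumulative_v` — plus
#'   `points0` and logical `frozen`.
#' @export
accumulate_trajectories <- function(fields, points0) {
  if (length(fields) < 1) stop("need at least one field", call. = FALSE)
  lapply(fields, function(f) stopifnot(inherits(f, "displacement_field")))
  g1 <- fields[[1]]
  same <- vapply(fields, function(f)
    identical(f$grid_x, g1$grid_x) && identical(f$grid_y, g1$grid_y),
    logical(1))
  if (!all(same)) stop("all fields must share one grid geometry",
                       call. = FALSE)
  p0 <- as_points_matrix(points0)
  npts <- nrow(p0)
  nfr <- length(fields) + 1L
  x <- y <- du <- dv <- cu <- cv <- matrix(0, nfr, npts)
  frozen <- matrix(FALSE, nfr, npts)
  x[1, ] <- p0[, 1]; y[1, ] <- p0[, 2]
  h <- g1$dim[1]; w <- g1$dim[2]
  cur <- p0
  is_frozen <- logical(npts)
  for (k in seq_along(fields)) {
    itp <- interpolate_field_at(fields[[k]], cur)
    step_u <- ifelse(is_frozen, 0, itp$u)
    step_v <- ifelse(is_frozen, 0, itp$v)
    cur <- cbind(cur[, 1] + step_u, cur[, 2] + step_v)
    exited <- cur[, 1] < 1 | cur[, 1] > w | cur[, 2] < 1 | cur[, 2] > h
    newly <- exited & !is_frozen
    if (any(newly)) {
      # retract the exiting step and freeze
      cur[newly, 1] <- cur[newly, 1] - step_u[newly]
      cur[newly, 2] <- cur[newly, 2] - step_v[newly]
      step_u[newly] <- 0; step_v[newly] <- 0
      is_frozen <- is_frozen | newly
    }
    du[k + 1L, ] <- step_u; dv[k + 1L, ] <- step_v
    cu[k + 1L, ] <- cu[k, ] + step_u
    cv[k + 1L, ] <- cv[k, ] + step_v
    x[k + 1L, ] <- cur[, 1]; y[k + 1L, ] <- cur[, 2]
    frozen[k + 1L, ] <- is_frozen
  }
  structure(list(points0 = p0, x = x, y = y,
                 interframe_u = du, interframe_v = dv,
                 cumulative_u = cu, cumulative_v = cv,
                 frozen = frozen),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d points over %d frames (%d frozen at end)\n",
              ncol(x$x), nrow(x$x), sum(x$frozen[nrow(x$frozen), ])))
  invisible(x)
}

#' Drift-correct a cumulative displacement or strain curve
#'
#' Cumulative curves drift because interframe estimation errors accumulate.
#' Over one breathing period T the diaphragm returns to its initial state, so
#' the curve should close: S(T) = 0. The correction subtracts a ramp
#' proportional to the accumulated end value inside the first period and the
#' constant S(T) afterwards:
#' \deqn{S_{corr}(t) = S(t) - \frac{S(T)}{T} t, \quad 0 \le t \le T}
#' \deqn{S_{corr}(t) = S(t) - S(T), \quad t \ge T}
#' S(T) is obtained by linear interpolation between the two frames that
#' bracket t = T; both branches agree at t = T and the corrected curve is 0
#' there by construction. When T falls between two frames, the ramp branch
#' is applied through the first frame at or beyond T, so that linear
#' interpolation of the corrected samples to t = T is exactly zero (the two
#' expressions differ at that single frame by O(step * drift)).
#'
#' @param curve Numeric vector sampled at the frame rate, `curve[1]` at
#'   t = 0; cumulative curves must start at 0.
#' @param period_T_s Breathing period T in seconds; must lie within the
#'   record.
#' @param frame_rate_hz Sampling rate (Hz).
#' @return Numeric vector, the corrected curve.
#' @export
drift_correct <- function(curve, period_T_s, frame_rate_hz) {
  curve <- as.numeric(curve)
  n <- length(curve)
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0", call. = FALSE)
  t <- (seq_len(n) - 1) / frame_rate_hz
  if (period_T_s <= 0 || period_T_s > t[n])
    stop("period_T_s must be positive and within the record (max ",
         signif(t[n], 6), " s)", call. = FALSE)
  s_T <- stats::approx(t, curve, xout = period_T_s)$y
  k1 <- which(t >= period_T_s - 1e-12)[1]  # first frame at/after T
  if (is.na(k1)) k1 <- n
  ramp <- seq_len(n) <= k1
  ifelse(ramp, curve - s_T / period_T_s * t, curve - s_T)
}

#' Estimate the breathing period from a displacement curve
#'
#' The period is normally read off M-mode imaging; when only the tracked
#' curve is available this estimator finds it in two stages. The curve is
#' first-differenced (which removes linear drift without distorting the
#' periodic component, unlike least-squares detrending over a finite
#' record) and the lag of the first prominent local maximum of the unbiased
#' autocorrelation gives a coarse period. That coarse value is then refined
#' by a harmonic regression — fundamental plus second harmonic plus a
#' linear drift term — whose residual sum of squares is minimized over a
#' bracket around the coarse lag, giving sub-frame accuracy on
#' quasi-sinusoidal breathing curves. A user-supplied period always takes
#' precedence over this estimate in the pipeline.
#'
#' @param curve Numeric vector spanning at least ~1.5 cycles.
#' @param frame_rate_hz Sampling rate (Hz).
#' @param min_corr Prominence threshold on the autocorrelation peak
#'   (default 0.2).
#' @return Estimated period in seconds.
#' @export
estimate_period <- function(curve, frame_rate_hz, min_corr = 0.2) {
  curve <- as.numeric(curve)
  n <- length(curve)
  if (n < 8) stop("curve too short to estimate a period", call. = FALSE)
  d <- diff(curve)
  d <- d - mean(d)
  if (stats::sd(d) == 0)
    stop("curve has no periodic component; pass the period explicitly",
         call. = FALSE)
  d <- d / stats::sd(d)
  m <- length(d)
  maxlag <- m - 2L
  ac <- vapply(seq_len(maxlag), function(k) {
    sum(d[1:(m - k)] * d[(k + 1):m]) / (m - k)
  }, numeric(1))
  # first local maximum after the autocorrelation has first dipped, with
  # sufficient prominence
  dipped <- FALSE
  best <- NA_integer_
  for (k in 2:(maxlag - 1)) {
    if (!dipped && ac[k] < 0) dipped <- TRUE
    if (dipped && ac[k] >= ac[k - 1] && ac[k] >= ac[k + 1] &&
        ac[k] >= min_corr) { best <- k; break }
  }
  if (is.na(best))
    stop("no prominent periodicity found; pass the period explicitly",
         call. = FALSE)
  # refine by harmonic regression around the coarse lag
  tt <- (seq_len(n) - 1) / frame_rate_hz
  rss <- function(T) {
    X <- cbind(1, tt, sin(2 * pi * tt / T), cos(2 * pi * tt / T),
               sin(4 * pi * tt / T), cos(4 * pi * tt / T))
    sum(stats::lm.fit(X, curve)$residuals^2)
  }
  T0 <- best / frame_rate_hz
  lo <- max(0.75 * T0, 3 / frame_rate_hz)
  hi <- min(1.3 * T0, tt[n])
  stats::optimize(rss, interval = c(lo, hi), tol = 1e-4)$minimum
}

#' Serialize a trajectory set to CSV
#'
#' One row per frame per point: positions, interframe and cumulative
#' displacements in px and mm, and the frozen flag.
#'
#' @param traj A `trajectory_set`.
#' @param path Output CSV path.
#' @param frame_rate_hz Sampling rate for the time column.
#' @param pixel_spacing_mm Length-2 numeric (row mm/px, column mm/px).
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(traj, path, frame_rate_hz,
                                   pixel_spacing_mm = c(1, 1)) {
  nfr <- nrow(traj$x); npts <- ncol(traj$x)
  df <- data.frame(
    frame = rep(seq_len(nfr) - 1L, npts),
    time_s = rep((seq_len(nfr) - 1) / frame_rate_hz, npts),
    point = rep(seq_len(npts), each = nfr),
    x = as.vector(traj$x), y = as.vector(traj$y),
    interframe_u_px = as.vector(traj$interframe_u),
    interframe_v_px = as.vector(traj$interframe_v),
    cumulative_u_px = as.vector(traj$cumulative_u),
    cumulative_v_px = as.vector(traj$cumulative_v),
    cumulative_u_mm = as.vector(traj$cumulative_u) * pixel_spacing_mm[2],
    cumulative_v_mm = as.vector(traj$cumulative_v) * pixel_spacing_mm[1],
    frozen = as.vector(traj$frozen))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
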