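#' Tracking configuration for NCC block matching
#'
#' Collects the parameters of the block-matching estimator. Displacement at a
#' grid node is found by correlating a kernel-sized template around the node
#' in one frame against a search region in the next, after both frames have
#' been laterally upsampled; the correlation surface is then refined to
#' sub-lag precision ("interpolate both" — the image lines and the
#' correlation function). Defaults are sized for speckle with a correlation
#' cell of a few pixels and are fully configurable; clinical loops may need a
#' larger kernel.
#'
#' @param kernel_size_px Template size (rows, cols), odd integers.
#' @param search_margin_px Search extent added around the kernel (rows,
#'   cols), in original pixels: displacements up to this magnitude are
#'   detectable.
#' @param lateral_interp_factor Integer >= 1; lateral (column) upsampling
#'   factor applied to both frames before matching. Small factors (3-5)
#'   give the best accuracy/cost trade-off on low line-density data.
#' @param axial_interp_factor Integer >= 1; axial (row) upsampling factor
#'   applied to both frames before matching. On 8-bit envelope data the
#'   axial speckle grain is only marginally sampled and correlation-surface
#'   refinement alone underestimates subpixel axial motion (pixel locking);
#'   upsampling the image lines along depth as well removes most of that
#'   bias.
#' @param corr_surface_interp_factor Integer >= 1; upsampling factor for the
#'   correlation surface around its integer peak before the parabolic vertex
#'   fit.
#' @param presmooth_sigma_px Standard deviation (px) of an isotropic
#'   Gaussian applied to both frames before matching; 0 disables. Gray-level
#'   quantization of 8-bit data correlates with the pixel grid and biases
#'   subpixel peaks toward integer lags; a sub-pixel smoothing kernel
#'   suppresses that locking at negligible resolution cost.
#' @param min_correlation Quality gate in `[-1, 1]`; nodes whose NCC peak
#'   falls below it are flagged invalid.
#' @param grid_spacing_px Default node spacing (rows, cols) when a grid is
#'   derived from an image or ROI.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(kernel_size_px = c(17, 17),
                            search_margin_px = c(10, 10),
                            lateral_interp_factor = 5L,
                            axial_interp_factor = 3L,
                            corr_surface_interp_factor = 5L,
                            min_correlation = 0.5,
                            presmooth_sigma_px = 0.8,
                            grid_spacing_px = c(8, 8)) {
  cfg <- list(kernel_size_px = as.integer(kernel_size_px),
              search_margin_px = as.integer(search_margin_px),
              lateral_interp_factor = as.integer(lateral_interp_factor),
              axial_interp_factor = as.integer(axial_interp_factor),
              corr_surface_interp_factor = as.integer(corr_surface_interp_factor),
              min_correlation = min_correlation,
              presmooth_sigma_px = presmooth_sigma_px,
              grid_spacing_px = as.integer(grid_spacing_px))
  class(cfg) <- "tracking_config"
  validate_tracking_config(cfg)
  cfg
}

validate_tracking_config <- function(cfg) {
  stopifnot(inherits(cfg, "tracking_config"))
  if (length(cfg$kernel_size_px) != 2 || any(cfg$kernel_size_px < 3) ||
      any(cfg$kernel_size_px %% 2 != 1))
    stop("kernel_size_px must be two odd integers >= 3", call. = FALSE)
  if (length(cfg$search_margin_px) != 2 || any(cfg$search_margin_px < 1))
    stop("search_margin_px must be two integers >= 1", call. = FALSE)
  if (cfg$lateral_interp_factor < 1)
    stop("lateral_interp_factor must be >= 1", call. = FALSE)
  if (cfg$axial_interp_factor < 1)
    stop("axial_interp_factor must be >= 1", call. = FALSE)
  if (cfg$presmooth_sigma_px < 0)
    stop("presmooth_sigma_px must be >= 0", call. = FALSE)
  if (cfg$corr_surface_interp_factor < 1)
    stop("corr_surface_interp_factor must be >= 1", call. = FALSE)
  if (cfg$min_correlation < -1 || cfg$min_correlation > 1)
    stop("min_correlation must lie in [-1, 1]", call. = FALSE)
  if (length(cfg$grid_spacing_px) != 2 || any(cfg$grid_spacing_px < 1))
    stop("grid_spacing_px must be two integers >= 1", call. = FALSE)
  invisible(cfg)
}

#' Normalized cross-correlation surface
#'
#' Zero-normalized cross-correlation of a template at every integer lag of a
#' larger search region: at each placement the template and the co-located
#' region window are mean-subtracted and the coefficient is their covariance
#' divided by the product of their standard deviations, so every value lies
#' in `[-1, 1]` and the measure is invariant to local gain and offset. A
#' flat (zero-variance) template yields an all-zero surface carrying
#' attribute `flat = TRUE` — the caller flags the node invalid rather than
#' receiving an exception.
#'
#' @param template Numeric matrix.
#' @param search_region Numeric matrix, strictly larger than `template` in
#'   both dimensions.
#' @return Matrix of NCC coefficients of dimension
#'   `dim(search_region) - dim(template) + 1`.
#' @export
ncc_surface <- function(template, search_region) {
  template <- as.matrix(template); search_region <- as.matrix(search_region)
  if (any(dim(search_region) <= dim(template)))
    stop("search_region must be strictly larger than template in both axes",
         call. = FALSE)
  if (stats::var(as.vector(template)) == 0) {
    out <- matrix(0, nrow(search_region) - nrow(template) + 1,
                  ncol(search_region) - ncol(template) + 1)
    attr(out, "flat") <- TRUE
    return(out)
  }
  .ncc_surface_cpp(template, search_region)
}

#' Upsample an image along the lateral (column) axis
#'
#' Cubic-spline interpolation along each row of constant depth; values at the
#' original columns are preserved exactly and `factor = 1` is the identity.
#' Output width is `(ncol(image) - 1) * factor + 1`.
#'
#' @param image Numeric matrix.
#' @param factor Integer >= 1.
#' @return The laterally upsampled matrix.
#' @export
interp_lateral <- function(image, factor) {
  image <- as.matrix(image)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(image)
  w <- ncol(image)
  xout <- seq(1, w, by = 1 / factor)
  out <- matrix(0, nrow(image), length(xout))
  for (i in seq_len(nrow(image)))
    out[i, ] <- stats::spline(seq_len(w), image[i, ], xout = xout,
                              method = "fmm")$y
  # guarantee exact sample preservation against spline round-off
  out[, (seq_len(w) - 1L) * factor + 1L] <- image
  out
}

#' Refine a correlation peak to sub-lag precision
#'
#' Locates the integer maximum of a correlation surface (ties broken by the
#' smallest Euclidean lag norm about the surface centre, then smallest row,
#' then smallest column — the least-motion candidate), upsamples a local
#' window around it by `interp_factor` with separable cubic splines, and
#' fits a parabola through the refined maximum and its neighbours along each
#' axis to return a real-valued peak location. Maxima on the surface border
#' are returned unrefined with `clipped = TRUE`.
#'
#' @param surface Numeric matrix of correlation values.
#' @param interp_factor Integer >= 1; 1 skips the upsampling stage.
#' @param refine If `FALSE`, the parabolic vertex fit is skipped;
#'   together with `interp_factor = 1` the integer peak is returned
#'   unchanged.
#' @return List with `row`, `col` (real-valued peak location in surface
#'   index units), `value` (surface value at the integer peak), and
#'   `clipped`.
#' @export
subsample_peak <- function(surface, interp_factor = 5L, refine = TRUE) {
  surface <- as.matrix(surface)
  interp_factor <- as.integer(interp_factor)
  if (interp_factor < 1) stop("interp_factor must be >= 1", call. = FALSE)
  nr <- nrow(surface); nc <- ncol(surface)
  m <- max(surface)
  cand <- which(surface == m, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    norm2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2
    cand <- cand[order(norm2, cand[, 1], cand[, 2]), , drop = FALSE]
  }
  pr <- cand[1, 1]; pc <- cand[1, 2]
  if (pr == 1 || pr == nr || pc == 1 || pc == nc)
    return(list(row = as.numeric(pr), col = as.numeric(pc), value = m,
                clipped = TRUE))
  if (interp_factor == 1L && !refine)
    return(list(row = as.numeric(pr), col = as.numeric(pc), value = m,
                clipped = FALSE))
  # a perfect match (coefficient 1) needs no refinement; spline overshoot
  # around an exact-1 peak would only move it off the true lag
  if (m >= 1 - 1e-12)
    return(list(row = as.numeric(pr), col = as.numeric(pc), value = m,
                clipped = FALSE))

  # local window (up to +/- 2 lags, clamped to the border)
  r0 <- max(1L, pr - 2L); r1 <- min(nr, pr + 2L)
  c0 <- max(1L, pc - 2L); c1 <- min(nc, pc + 2L)
  win <- surface[r0:r1, c0:c1, drop = FALSE]
  rows <- r0:r1; cols <- c0:c1
  if (interp_factor > 1L) {
    fr <- seq(r0, r1, by = 1 / interp_factor)
    fc <- seq(c0, c1, by = 1 / interp_factor)
    tmp <- matrix(0, nrow(win), length(fc))
    for (i in seq_len(nrow(win)))
      tmp[i, ] <- stats::spline(cols, win[i, ], xout = fc, method = "fmm")$y
    fine <- matrix(0, length(fr), length(fc))
    for (j in seq_len(ncol(tmp)))
      fine[, j] <- stats::spline(rows, tmp[, j], xout = fr, method = "fmm")$y
  } else {
    fine <- win; fr <- rows; fc <- cols
  }
  k <- which.max(fine)
  ki <- ((k - 1) %% nrow(fine)) + 1
  kj <- ((k - 1) %/% nrow(fine)) + 1
  h <- if (interp_factor > 1L) 1 / interp_factor else 1
  refined_r <- fr[ki]; refined_c <- fc[kj]
  if (refine) {
    if (ki > 1 && ki < nrow(fine)) {
      a <- fine[ki - 1, kj]; b <- fine[ki, kj]; d <- fine[ki + 1, kj]
      den <- a - 2 * b + d
      if (den < 0) refined_r <- fr[ki] + 0.5 * h * (a - d) / den
    }
    if (kj > 1 && kj < ncol(fine)) {
      a <- fine[ki, kj - 1]; b <- fine[ki, kj]; d <- fine[ki, kj + 1]
      den <- a - 2 * b + d
      if (den < 0) refined_c <- fc[kj] + 0.5 * h * (a - d) / den
    }
  }
  # refinement stays within one integer lag of the discrete peak
  refined_r <- min(max(refined_r, pr - 1), pr + 1)
  refined_c <- min(max(refined_c, pc - 1), pc + 1)
  list(row = refined_r, col = refined_c, value = m, clipped = FALSE)
}

#' Smooth an image with a separable Gaussian
#'
#' Isotropic Gaussian smoothing with edge replication, used to suppress
#' quantization-induced pixel locking before block matching.
#'
#' @param image Numeric matrix.
#' @param sigma_px Standard deviation in px; 0 returns the input unchanged.
#' @return The smoothed matrix.
#' @export
presmooth <- function(image, sigma_px) {
  if (sigma_px <= 0) return(image)
  r <- ceiling(3 * sigma_px)
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  smooth1 <- function(v) {
    p <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(p, k)[(r + 1):(r + length(v))])
  }
  out <- image
  for (i in seq_len(nrow(out))) out[i, ] <- smooth1(out[i, ])
  for (j in seq_len(ncol(out))) out[, j] <- smooth1(out[, j])
  out
}

#' Estimate the interframe displacement field on a grid
#'
#' For every node of a regular grid, a kernel-sized template centred on the
#' node in `frame_a` is matched by NCC within a search region in `frame_b`.
#' Both frames are first (optionally) pre-smoothed, then upsampled laterally
#' by `lateral_interp_factor` and axially by `axial_interp_factor`; the
#' correlation surface is refined to sub-lag precision with
#' [subsample_peak()]; lags are divided by the interpolation factors so
#' displacements come back in original-pixel units. Nodes whose template
#' would leave the frame, whose template is flat, whose peak clips the
#' search border, or whose peak correlation falls below the quality gate are
#' flagged invalid (displacement reported as 0, excluded from aggregation
#' downstream). Search regions near the frame border are clamped and the
#' node flagged `clamped`.
#'
#' @param frame_a,frame_b Numeric matrices of equal dimension.
#' @param grid_x,grid_y Integer vectors of node column/row coordinates; the
#'   grid is their Cartesian product.
#' @param config A [tracking_config()].
#' @return An object of class `displacement_field`: list with `grid_x`,
#'   `grid_y`, matrices `u`, `v`, `peak_corr`, `valid`, `clamped`
#'   (`length(grid_y)` x `length(grid_x)`), and `dim` (frame size).
#' @export
estimate_interframe_field <- function(frame_a, frame_b, grid_x, grid_y,
                                      config = tracking_config()) {
  validate_tracking_config(config)
  frame_a <- as.matrix(frame_a); frame_b <- as.matrix(frame_b)
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must have identical dimensions", call. = FALSE)
  grid_x <- as.integer(grid_x); grid_y <- as.integer(grid_y)
  if (length(grid_x) < 1 || length(grid_y) < 1)
    stop("grid must contain at least one node", call. = FALSE)
  L <- config$lateral_interp_factor
  A <- config$axial_interp_factor
  hr <- (config$kernel_size_px[1] - 1L) %/% 2L
  hc <- (config$kernel_size_px[2] - 1L) %/% 2L
  mr <- config$search_margin_px[1]
  mc <- config$search_margin_px[2]
  if (config$presmooth_sigma_px > 0) {
    frame_a <- presmooth(frame_a, config$presmooth_sigma_px)
    frame_b <- presmooth(frame_b, config$presmooth_sigma_px)
  }
  a2 <- t(interp_lateral(t(interp_lateral(frame_a, L)), A))
  b2 <- t(interp_lateral(t(interp_lateral(frame_b, L)), A))
  h2 <- nrow(a2); w2 <- ncol(a2)
  nx <- length(grid_x); ny <- length(grid_y)
  u <- v <- pc <- matrix(0, ny, nx)
  valid <- clamped <- matrix(FALSE, ny, nx)
  pc[] <- NA_real_
  for (ix in seq_len(nx)) {
    x <- grid_x[ix]
    cx <- (x - 1L) * L + 1L             # node column in the upsampled frames
    tc0 <- cx - hc * L; tc1 <- cx + hc * L
    for (iy in seq_len(ny)) {
      y <- grid_y[iy]
      cy <- (y - 1L) * A + 1L           # node row in the upsampled frames
      ty0 <- cy - hr * A; ty1 <- cy + hr * A
      if (ty0 < 1 || ty1 > h2 || tc0 < 1 || tc1 > w2) next  # template exits
      r0 <- max(1L, ty0 - mr * A); r1 <- min(h2, ty1 + mr * A)
      c0 <- max(1L, tc0 - mc * L); c1 <- min(w2, tc1 + mc * L)
      was_clamped <- (r0 != ty0 - mr * A) || (r1 != ty1 + mr * A) ||
        (c0 != tc0 - mc * L) || (c1 != tc1 + mc * L)
      if (r1 - r0 <= ty1 - ty0 || c1 - c0 <= tc1 - tc0) next
      tmpl <- a2[ty0:ty1, tc0:tc1, drop = FALSE]
      region <- b2[r0:r1, c0:c1, drop = FALSE]
      surf <- ncc_surface(tmpl, region)
      if (isTRUE(attr(surf, "flat"))) next
      pk <- subsample_peak(surf, config$corr_surface_interp_factor)
      dv <- ((r0 + pk$row - 1) - ty0) / A
      du <- ((c0 + pk$col - 1) - tc0) / L
      u[iy, ix] <- du; v[iy, ix] <- dv
      pc[iy, ix] <- pk$value
      clamped[iy, ix] <- was_clamped
      valid[iy, ix] <- !pk$clipped && pk$value >= config$min_correlation &&
        abs(du) <= mc + 1 && abs(dv) <= mr + 1
    }
  }
  structure(list(grid_x = grid_x, grid_y = grid_y, u = u, v = v,
                 peak_corr = pc, valid = valid, clamped = clamped,
                 dim = dim(frame_a), config = config),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %d x %d nodes, %d valid; mean (u, v) over valid = (%.3f, %.3f) px\n",
              length(x$grid_y), length(x$grid_x), sum(x$valid),
              mean(x$u[x$valid]), mean(x$v[x$valid])))
  invisible(x)
}

#' Serialize displacement fields to CSV
#'
#' One row per node per interframe step with displacements in both px and mm
#' (via the stack's pixel spacing).
#'
#' @param fields List of `displacement_field` objects (step k maps frames
#'   k-1 to k).
#' @param path Output CSV path.
#' @param pixel_spacing_mm Length-2 numeric (row mm/px, column mm/px).
#' @return `path`, invisibly.
#' @export
write_fields_csv <- function(fields, path, pixel_spacing_mm = c(1, 1)) {
  rows <- lapply(seq_along(fields), function(k) {
    f <- fields[[k]]
    g <- expand.grid(y = f$grid_y, x = f$grid_x)
    data.frame(frame_index = k, x = g$x, y = g$y,
               u_px = as.vector(f$u), v_px = as.vector(f$v),
               u_mm = as.vector(f$u) * pixel_spacing_mm[2],
               v_mm = as.vector(f$v) * pixel_spacing_mm[1],
               peak_corr = as.vector(f$peak_corr),
               valid = as.vector(f$valid))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
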