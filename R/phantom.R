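#' Specify a synthetic speckle phantom
#'
#' Builds a validated specification for a synthetic B-mode speckle cine loop
#' with analytically known motion. The phantom places random sub-resolution
#' scatterers (many per resolution cell), convolves them with an anisotropic
#' Gaussian point-spread function, takes the envelope magnitude and
#' log-compresses it to 8-bit range, emulating the appearance of a clinical
#' B-mode loop without modelling the radiofrequency signal.
#'
#' @param image_height_px,image_width_px Frame dimensions in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param frame_rate_hz Acquisition frame rate in Hz.
#' @param scatterer_density Scatterers per resolution cell. The resolution
#'   cell area is taken as `2 * pi * psf_axial_sigma_px * psf_lateral_sigma_px`.
#'   Ten or more per cell gives fully developed speckle.
#' @param psf_axial_sigma_px,psf_lateral_sigma_px Gaussian PSF standard
#'   deviations along the axial (row) and lateral (column) axes, in pixels.
#' @param motion_model One of `"rigid_translation"`,
#'   `"uniform_lateral_stretch"`, `"breathing_sinusoid"`.
#' @param motion_params Named list of model parameters:
#'   * `rigid_translation`: `du_per_frame`, `dv_per_frame` (px/frame,
#'     +u rightward, +v downward).
#'   * `uniform_lateral_stretch`: `eps_max` (peak lateral stretch as a
#'     fraction, e.g. 0.05 for 5 %), optional `center_x` (px; default image
#'     centre column). The stretch ramps linearly from 0 at frame 0 to
#'     `eps_max` at the last frame.
#'   * `breathing_sinusoid`: `amp_u_px`, `amp_v_px` (displacement amplitudes),
#'     `period_s` (breathing period). Displacement from frame 0 is
#'     `A * sin(2 * pi * t / period_s)` per axis.
#' @param pixel_spacing_mm Length-2 numeric, mm per pixel (row, column).
#' @param rng_seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height_px = 256L,
                         image_width_px = 256L,
                         n_frames = 2L,
                         frame_rate_hz = 30,
                         scatterer_density = 10,
                         psf_axial_sigma_px = 1.5,
                         psf_lateral_sigma_px = 2.0,
                         motion_model = c("rigid_translation",
                                          "uniform_lateral_stretch",
                                          "breathing_sinusoid"),
                         motion_params = list(du_per_frame = 0,
                                              dv_per_frame = 0),
                         pixel_spacing_mm = c(0.3, 0.3),
                         rng_seed = 1L) {
  motion_model <- match.arg(motion_model)
  spec <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    n_frames = as.integer(n_frames),
    frame_rate_hz = frame_rate_hz,
    scatterer_density = scatterer_density,
    psf_axial_sigma_px = psf_axial_sigma_px,
    psf_lateral_sigma_px = psf_lateral_sigma_px,
    motion_model = motion_model,
    motion_params = motion_params,
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid phantom spec: field '%s' %s", field, msg),
                  call. = FALSE)
  }
  chk(spec$image_height_px > 0, "image_height_px", "must be > 0")
  chk(spec$image_width_px > 0, "image_width_px", "must be > 0")
  chk(spec$n_frames >= 2, "n_frames", "must be >= 2")
  chk(is.numeric(spec$frame_rate_hz) && spec$frame_rate_hz > 0,
      "frame_rate_hz", "must be > 0")
  chk(is.numeric(spec$scatterer_density) && spec$scatterer_density > 0,
      "scatterer_density", "must be > 0")
  chk(spec$psf_axial_sigma_px > 0, "psf_axial_sigma_px", "must be > 0")
  chk(spec$psf_lateral_sigma_px > 0, "psf_lateral_sigma_px", "must be > 0")
  chk(length(spec$pixel_spacing_mm) == 2 && all(spec$pixel_spacing_mm > 0),
      "pixel_spacing_mm", "must be two positive numbers")
  mp <- spec$motion_params
  switch(spec$motion_model,
    rigid_translation = chk(all(c("du_per_frame", "dv_per_frame") %in%
                                  names(mp)),
                            "motion_params",
                            "needs du_per_frame and dv_per_frame"),
    uniform_lateral_stretch = chk("eps_max" %in% names(mp),
                                  "motion_params", "needs eps_max"),
    breathing_sinusoid = chk(all(c("amp_u_px", "amp_v_px", "period_s") %in%
                                   names(mp)) && mp$period_s > 0,
                             "motion_params",
                             "needs amp_u_px, amp_v_px, period_s > 0")
  )
  invisible(spec)
}

# Evaluate the analytic displacement (from frame 0) of material points at
# their rest positions. `points` is an n x 2 matrix of (x, y); returns an
# n x 2 matrix of (u, v) in px.
phantom_displacement <- function(spec, frame_index, points) {
  points <- as_points_matrix(points)
  t <- frame_index / spec$frame_rate_hz
  mp <- spec$motion_params
  n <- nrow(points)
  switch(spec$motion_model,
    rigid_translation = cbind(
      u = rep(frame_index * mp$du_per_frame, n),
      v = rep(frame_index * mp$dv_per_frame, n)
    ),
    uniform_lateral_stretch = {
      eps <- phantom_stretch_eps(spec, frame_index)
      cx <- if (!is.null(mp$center_x)) mp$center_x else
        (spec$image_width_px + 1) / 2
      cbind(u = eps * (points[, 1] - cx), v = rep(0, n))
    },
    breathing_sinusoid = {
      s <- sin(2 * pi * t / mp$period_s)
      cbind(u = rep(mp$amp_u_px * s, n), v = rep(mp$amp_v_px * s, n))
    }
  )
}

phantom_stretch_eps <- function(spec, frame_index) {
  spec$motion_params$eps_max * frame_index / (spec$n_frames - 1)
}

# Largest displacement magnitude any point in the image can undergo, used to
# pad the scatterer field so motion never imports empty space.
phantom_max_displacement <- function(spec) {
  mp <- spec$motion_params
  switch(spec$motion_model,
    rigid_translation = (spec$n_frames - 1) *
      sqrt(mp$du_per_frame^2 + mp$dv_per_frame^2),
    uniform_lateral_stretch = abs(mp$eps_max) * spec$image_width_px / 2,
    breathing_sinusoid = sqrt(mp$amp_u_px^2 + mp$amp_v_px^2)
  )
}

phantom_margin_px <- function(spec) {
  ceiling(phantom_max_displacement(spec) +
            3 * max(spec$psf_axial_sigma_px, spec$psf_lateral_sigma_px) + 2)
}

#' Generate the random scatterer set of a phantom
#'
#' Scatterer positions are uniform over the image padded by a margin of the
#' maximum motion amplitude plus three PSF sigmas, so that motion never pulls
#' empty space into the frame. Each scatterer carries a unit-mean
#' Rayleigh-distributed amplitude and a uniform random phase; the complex sum
#' of many such phasors per resolution cell is what produces fully developed
#' speckle after PSF convolution and envelope detection.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `x`, `y` (rest positions, continuous image
#'   coordinates, px), `amplitude`, `phase`, and the `margin_px` used.
#' @export
generate_scatterers <- function(spec) {
  validate_phantom_spec(spec)
  margin <- phantom_margin_px(spec)
  h <- spec$image_height_px + 2 * margin
  w <- spec$image_width_px + 2 * margin
  cell_area <- 2 * pi * spec$psf_axial_sigma_px * spec$psf_lateral_sigma_px
  n <- round(spec$scatterer_density * h * w / cell_area)
  if (n < 1) stop("invalid phantom spec: field 'scatterer_density' too low ",
                  "for the field size (no scatterers)", call. = FALSE)
  with_preserved_seed(spec$rng_seed, {
    x <- runif(n, min = 0.5 - margin, max = spec$image_width_px + 0.5 + margin)
    y <- runif(n, min = 0.5 - margin, max = spec$image_height_px + 0.5 + margin)
    # unit-mean Rayleigh amplitude: sigma * sqrt(-2 log U), sigma = sqrt(2/pi)
    amplitude <- sqrt(2 / pi) * sqrt(-2 * log(runif(n)))
    phase <- runif(n, 0, 2 * pi)
    list(x = x, y = y, amplitude = amplitude, phase = phase,
         margin_px = margin, n = n)
  })
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Bilinear splat of complex scatterer amplitudes onto the padded field grid,
# FFT convolution with the (periodised) Gaussian PSF, envelope magnitude,
# cropped back to the image. Positions are in image coordinates; the field
# grid extends `margin` px beyond the image on every side.
render_envelope <- function(scatterers, spec, frame_index) {
  margin <- scatterers$margin_px
  h <- spec$image_height_px + 2L * as.integer(margin)
  w <- spec$image_width_px + 2L * as.integer(margin)
  d <- phantom_displacement(spec, frame_index,
                            cbind(scatterers$x, scatterers$y))
  # field coordinates (1-based grid), moved positions
  fx <- scatterers$x + d[, 1] + margin
  fy <- scatterers$y + d[, 2] + margin
  keep <- fx >= 1 & fx < w & fy >= 1 & fy < h
  fx <- fx[keep]; fy <- fy[keep]
  amp <- scatterers$amplitude[keep] * exp(1i * scatterers$phase[keep])
  i0 <- floor(fy); j0 <- floor(fx)
  ry <- fy - i0; rx <- fx - j0
  idx <- c(i0 + (j0 - 1) * h,           # (i0, j0)
           i0 + 1 + (j0 - 1) * h,       # (i0+1, j0)
           i0 + j0 * h,                 # (i0, j0+1)
           i0 + 1 + j0 * h)             # (i0+1, j0+1)
  wts <- c((1 - ry) * (1 - rx), ry * (1 - rx), (1 - ry) * rx, ry * rx)
  ca <- rep(amp, 4) * wts
  agg <- rowsum(cbind(Re(ca), Im(ca)), group = idx)
  field <- matrix(0 + 0i, h, w)
  at <- as.integer(rownames(agg))
  field[at] <- complex(real = agg[, 1], imaginary = agg[, 2])
  # periodised anisotropic Gaussian PSF; margin >= 3 sigma keeps wrap-around
  # out of the image interior
  dy <- seq_len(h) - 1L; dy <- ifelse(dy > h / 2, dy - h, dy)
  dx <- seq_len(w) - 1L; dx <- ifelse(dx > w / 2, dx - w, dx)
  ky <- exp(-dy^2 / (2 * spec$psf_axial_sigma_px^2))
  kx <- exp(-dx^2 / (2 * spec$psf_lateral_sigma_px^2))
  kern <- outer(ky, kx)
  kern <- kern / sum(kern)
  conv <- stats::fft(stats::fft(field) * stats::fft(kern), inverse = TRUE) /
    (h * w)
  env <- Mod(conv)
  env[(margin + 1):(margin + spec$image_height_px),
      (margin + 1):(margin + spec$image_width_px), drop = FALSE]
}

# Log compression of the envelope to 8-bit display range with a fixed
# reference so that all frames of a sequence share one gray-level mapping.
log_compress <- function(env, ref, dynamic_range_db = 45) {
  db <- 20 * log10(pmax(env, .Machine$double.xmin) / (4 * ref))
  db <- pmin(pmax(db, -dynamic_range_db), 0)
  round(255 * (db + dynamic_range_db) / dynamic_range_db)
}

#' Render one phantom frame
#'
#' Displaces every scatterer by the motion model evaluated at its rest
#' position and the frame time, splats the complex amplitudes onto the field
#' grid, convolves with the anisotropic Gaussian PSF, takes the envelope
#' magnitude, and (optionally) log-compresses to 8-bit gray levels. The
#' compression reference is the mean rest-frame envelope so every frame of a
#' sequence shares one mapping.
#'
#' @param scatterers Output of [generate_scatterers()].
#' @param spec The matching [phantom_spec()].
#' @param frame_index Frame number in `[0, n_frames)`; frame 0 is rest.
#' @param compress If `FALSE`, return the pre-log envelope instead of the
#'   8-bit image (used for speckle-statistics checks).
#' @param ref Compression reference (mean rest envelope); computed from the
#'   rest frame when `NULL`.
#' @return A numeric matrix (`image_height_px` x `image_width_px`), gray
#'   levels in `[0, 255]` when compressed.
#' @export
render_frame <- function(scatterers, spec, frame_index, compress = TRUE,
                         ref = NULL) {
  validate_phantom_spec(spec)
  if (frame_index < 0 || frame_index >= spec$n_frames)
    stop("frame_index out of range [0, n_frames)", call. = FALSE)
  env <- render_envelope(scatterers, spec, frame_index)
  if (!compress) return(env)
  if (is.null(ref)) ref <- mean(render_envelope(scatterers, spec, 0))
  log_compress(env, ref)
}

#' Generate a full phantom sequence with ground truth
#'
#' Renders all frames of the spec and returns them as a [frame_stack()]
#' together with the analytic ground truth: a displacement function
#' `(frame_index, points) -> (u, v)` (displacement from frame 0, px) and the
#' true global-strain curve (% per frame) for a reference polyline. The
#' default reference polyline is horizontal, spanning the central half of the
#' image width at the centre row — strain for the lateral-stretch model is
#' then exactly `100 * eps(t)`, and zero for the translation models.
#'
#' @param spec A [phantom_spec()].
#' @param ref_polyline Optional n x 2 matrix of (x, y) points used for the
#'   true strain curve.
#' @return A list with `stack` ([frame_stack()]), `ground_truth` (list with
#'   `displacement_fn`, `gs_curve`, `ref_polyline`), and `scatterers`.
#' @export
generate_sequence <- function(spec, ref_polyline = NULL) {
  validate_phantom_spec(spec)
  scat <- generate_scatterers(spec)
  ref <- mean(render_envelope(scat, spec, 0))
  frames <- lapply(seq_len(spec$n_frames) - 1L, function(k)
    log_compress(render_envelope(scat, spec, k), ref))
  stack <- frame_stack(frames, frame_rate_hz = spec$frame_rate_hz,
                       pixel_spacing_mm = spec$pixel_spacing_mm)
  if (is.null(ref_polyline)) {
    w <- spec$image_width_px; h <- spec$image_height_px
    xs <- seq(round(w / 4), round(3 * w / 4))
    ref_polyline <- cbind(x = xs, y = rep(round(h / 2), length(xs)))
  }
  disp_fn <- function(frame_index, points)
    phantom_displacement(spec, frame_index, points)
  gs <- vapply(seq_len(spec$n_frames) - 1L, function(k) {
    p <- as_points_matrix(ref_polyline)
    d <- phantom_displacement(spec, k, p)
    100 * (polyline_length(p + d) / polyline_length(p) - 1)
  }, numeric(1))
  list(stack = stack,
       ground_truth = list(displacement_fn = disp_fn, gs_curve = gs,
                           ref_polyline = as_points_matrix(ref_polyline)),
       scatterers = scat)
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) stop("points must be an n x 2 matrix of (x, y)",
                              call. = FALSE)
  points
}
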