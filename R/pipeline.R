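#' Configuration for a full tracking run
#'
#' Validates and bundles everything [run_pipeline()] needs. Paths are
#' checked at construction time; the frame-rate precondition of displacement
#' normalization (`FR <= FRmax`) is enforced before any computation starts.
#'
#' @param input A [frame_stack()], or a path to a DICOM cine loop (file or
#'   directory) or a TIFF stack written by [write_framestack_tiff()].
#' @param roi Dense ROI trace: n x 2 matrix or a CSV/JSON path
#'   (see [read_roi()]).
#' @param tracking A [tracking_config()].
#' @param spacing_k ROI subsampling factor passed to [build_roi()].
#' @param period_T_s Breathing period in seconds; `NULL` to estimate it from
#'   the tracked curve with [estimate_period()].
#' @param frmax_hz Maximum acquisition frame rate across the loops being
#'   compared; defaults to this loop's rate (normalization is then the
#'   identity).
#' @param aggregate `"median"` (default) or `"mean"` point aggregation.
#' @param frame_rate_hz,pixel_spacing_mm Metadata overrides/fallbacks for
#'   file inputs.
#' @param crop Optional `c(row0, row1, col0, col1)` rectangle applied to
#'   every frame before tracking (e.g. to cut burnt-in annotations).
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param seed Integer seed recorded in the manifest (phantom runs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, roi, tracking = tracking_config(),
                       spacing_k = 1L, period_T_s = NULL, frmax_hz = NULL,
                       aggregate = c("median", "mean"),
                       frame_rate_hz = NULL, pixel_spacing_mm = NULL,
                       crop = NULL, out_dir = NULL, seed = NULL) {
  aggregate <- match.arg(aggregate)
  validate_tracking_config(tracking)
  if (is.character(input) && !file.exists(input) && !dir.exists(input))
    stop("input path does not exist: ", input, call. = FALSE)
  if (is.character(roi) && !file.exists(roi))
    stop("ROI path does not exist: ", roi, call. = FALSE)
  if (!is.null(period_T_s) && period_T_s <= 0)
    stop("period_T_s must be > 0", call. = FALSE)
  structure(list(input = input, roi = roi, tracking = tracking,
                 spacing_k = as.integer(spacing_k), period_T_s = period_T_s,
                 frmax_hz = frmax_hz, aggregate = aggregate,
                 frame_rate_hz = frame_rate_hz,
                 pixel_spacing_mm = pixel_spacing_mm,
                 crop = crop, out_dir = out_dir, seed = seed),
            class = "run_config")
}

load_input_stack <- function(config) {
  inp <- config$input
  if (inherits(inp, "frame_stack")) return(inp)
  if (dir.exists(inp))
    return(read_dicom_cine(inp, config$frame_rate_hz,
                           config$pixel_spacing_mm))
  ext <- tolower(tools::file_ext(inp))
  if (ext %in% c("tif", "tiff")) read_framestack_tiff(inp)
  else read_dicom_cine(inp, config$frame_rate_hz, config$pixel_spacing_mm)
}

#' Grid covering an ROI with motion headroom
#'
#' Builds the regular tracking grid: the bounding box of the ROI trace,
#' expanded by the expected motion amplitude plus one grid cell, snapped to
#' the configured node spacing, and kept far enough from the frame border
#' for the kernel to fit.
#'
#' @param roi_points n x 2 matrix of (x, y).
#' @param frame_dim `c(rows, cols)` of the frames.
#' @param config A [tracking_config()].
#' @param motion_pad_px Extra padding (px) for the expected excursion of the
#'   tracked points; default the search margin.
#' @return List with `grid_x`, `grid_y` (integer vectors).
#' @export
grid_for_roi <- function(roi_points, frame_dim, config = tracking_config(),
                         motion_pad_px = NULL) {
  p <- as_points_matrix(roi_points)
  if (is.null(motion_pad_px)) motion_pad_px <- max(config$search_margin_px)
  sp <- config$grid_spacing_px
  hr <- (config$kernel_size_px[1] - 1L) %/% 2L
  hc <- (config$kernel_size_px[2] - 1L) %/% 2L
  pad <- motion_pad_px + max(sp)
  x0 <- max(hc + 1, floor(min(p[, 1]) - pad))
  x1 <- min(frame_dim[2] - hc, ceiling(max(p[, 1]) + pad))
  y0 <- max(hr + 1, floor(min(p[, 2]) - pad))
  y1 <- min(frame_dim[1] - hr, ceiling(max(p[, 2]) + pad))
  if (x1 <= x0 || y1 <= y0) stop("ROI leaves no room for a tracking grid",
                                 call. = FALSE)
  list(grid_x = as.integer(seq(x0, x1, by = sp[2])),
       grid_y = as.integer(seq(y0, y1, by = sp[1])))
}

#' Run the full deformation-imaging pipeline
#'
#' Executes read -> ROI/grid setup -> interframe NCC fields -> Lagrangian
#' accumulation -> period estimation -> drift correction -> strain and
#' displacement curves -> normalization -> peak-to-peak summaries. With
#' `out_dir` set, every artifact is written (CSV fields, trajectories and
#' curves; JSON summary) together with a manifest recording the
#' configuration, package version and seed, so identical config + input
#' reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result` with `stack` metadata, `fields`
#'   (list of `displacement_field`), `trajectories` (`trajectory_set`),
#'   `curves` (`deformation_curves` data frame with attributes `period_T_s`,
#'   `corrected`), and `summary` (the strain/displacement summary list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stack <- load_input_stack(config)
  if (!is.null(config$frmax_hz) && stack$frame_rate_hz > config$frmax_hz)
    stop("acquisition frame rate exceeds frmax_hz; normalization undefined",
         call. = FALSE)
  if (!is.null(config$crop)) {
    cr <- config$crop
    stack$frames <- lapply(stack$frames, function(f)
      f[cr[1]:cr[2], cr[3]:cr[4], drop = FALSE])
  }
  dense <- if (is.character(config$roi)) read_roi(config$roi) else
    as_points_matrix(config$roi)
  roi <- build_roi(dense, config$spacing_k)
  g <- grid_for_roi(roi$points, dim(stack$frames[[1]]), config$tracking)
  nfr <- length(stack$frames)
  fields <- vector("list", nfr - 1L)
  for (k in seq_len(nfr - 1L))
    fields[[k]] <- estimate_interframe_field(stack$frames[[k]],
                                             stack$frames[[k + 1L]],
                                             g$grid_x, g$grid_y,
                                             config$tracking)
  traj <- accumulate_trajectories(fields, roi$points)
  agg <- config$aggregate
  val <- !traj$frozen
  cum_u <- aggregate_curves(traj$cumulative_u, agg, val)
  cum_v <- aggregate_curves(traj$cumulative_v, agg, val)
  int_u <- aggregate_curves(traj$interframe_u, agg, val)
  int_v <- aggregate_curves(traj$interframe_v, agg, val)
  gs <- gs_curve(traj, roi, stack$pixel_spacing_mm)
  fr <- stack$frame_rate_hz
  period <- config$period_T_s
  period_src <- "user"
  if (is.null(period)) {
    period <- estimate_period(as.numeric(cum_u), fr)
    period_src <- "autocorrelation"
  }
  t_s <- frame_times_s(stack)
  if (period > t_s[length(t_s)]) {
    warning("breathing period exceeds the record; drift correction skipped",
            call. = FALSE)
    corrected <- FALSE
    cum_u_c <- as.numeric(cum_u); cum_v_c <- as.numeric(cum_v)
    gs_c <- as.numeric(gs)
  } else {
    corrected <- TRUE
    cum_u_c <- drift_correct(as.numeric(cum_u), period, fr)
    cum_v_c <- drift_correct(as.numeric(cum_v), period, fr)
    gs_c <- drift_correct(as.numeric(gs), period, fr)
  }
  frmax <- if (is.null(config$frmax_hz)) fr else config$frmax_hz
  int_u_n <- normalize_interframe(as.numeric(int_u), fr, frmax)
  int_v_n <- normalize_interframe(as.numeric(int_v), fr, frmax)
  curves <- data.frame(frame = seq_len(nfr) - 1L, time_s = t_s,
                       interframe_u = as.numeric(int_u),
                       interframe_v = as.numeric(int_v),
                       interframe_u_norm = int_u_n,
                       interframe_v_norm = int_v_n,
                       cumulative_u = as.numeric(cum_u),
                       cumulative_v = as.numeric(cum_v),
                       cumulative_u_corr = cum_u_c,
                       cumulative_v_corr = cum_v_c,
                       gs = as.numeric(gs), gs_corr = gs_c)
  attr(curves, "period_T_s") <- period
  attr(curves, "period_source") <- period_src
  attr(curves, "corrected") <- corrected
  win <- which(t_s <= min(period, t_s[length(t_s)]) + 1e-9)
  mm <- stack$pixel_spacing_mm
  summarize <- function(v) peak_to_peak(v, win)
  l0_px <- polyline_length(roi$points)
  summary <- list(
    L0_px = l0_px,
    L0_mm = polyline_length(cbind(roi$points[, 1] * mm[2],
                                  roi$points[, 2] * mm[1])),
    spacing_k = roi$spacing_k,
    period_T_s = period,
    period_source = period_src,
    frame_rate_hz = fr, frmax_hz = frmax,
    aggregate = agg,
    gs_peak_to_peak = summarize(gs_c),
    peak_to_peak_px = list(
      interframe_u = summarize(as.numeric(int_u)),
      interframe_v = summarize(as.numeric(int_v)),
      interframe_u_norm = summarize(int_u_n),
      interframe_v_norm = summarize(int_v_n),
      cumulative_u = summarize(cum_u_c),
      cumulative_v = summarize(cum_v_c))
  )
  res <- structure(list(stack = stack, roi = roi, grid = g, fields = fields,
                        trajectories = traj, curves = curves,
                        summary = summary, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("pipeline_result: %d frames @ %.4g Hz, ROI k = %d (L0 = %.2f px)\n",
           "  period T = %.3f s (%s)\n",
           "  GS peak-to-peak = %.3f %%\n",
           "  cumulative peak-to-peak (px): u = %.3f, v = %.3f\n"),
    nrow(x$curves), s$frame_rate_hz, s$spacing_k, s$L0_px,
    s$period_T_s, s$period_source, s$gs_peak_to_peak,
    s$peak_to_peak_px$cumulative_u, s$peak_to_peak_px$cumulative_v))
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mm <- res$stack$pixel_spacing_mm
  fr <- res$stack$frame_rate_hz
  write_fields_csv(res$fields, file.path(out_dir, "fields.csv"), mm)
  write_trajectories_csv(res$trajectories,
                         file.path(out_dir, "trajectories.csv"), fr, mm)
  utils::write.csv(res$curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "speckletrack",
    version = as.character(utils::packageVersion("speckletrack")),
    tracking = unclass(res$config$tracking),
    spacing_k = res$config$spacing_k,
    aggregate = res$config$aggregate,
    period_T_s = attr(res$curves, "period_T_s"),
    period_source = attr(res$curves, "period_source"),
    seed = res$config$seed,
    input = if (is.character(res$config$input)) res$config$input else
      "in-memory frame_stack",
    frame_rate_hz = fr, pixel_spacing_mm = mm)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
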