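#' Build an ROI polyline from a dense manual trace
#'
#' The diaphragm ROI is traced manually as a dense ordered point list; the
#' working polyline keeps every `spacing_k`-th point starting from the first,
#' and always retains the last traced point so the polyline spans the same
#' anatomy at every sampling spacing (otherwise a coarser spacing would
#' shorten the initial length and bias the strain).
#'
#' @param dense_points n x 2 matrix (or data frame) of ordered (x, y)
#'   coordinates along the diaphragm at frame 0.
#' @param spacing_k Integer subsampling factor (the clinically examined
#'   values are 1, 3, 5 and 10).
#' @return An object of class `roi_polyline` with `points` and `spacing_k`.
#' @export
build_roi <- function(dense_points, spacing_k = 1L) {
  p <- as_points_matrix(dense_points)
  spacing_k <- as.integer(spacing_k)
  if (spacing_k < 1) stop("spacing_k must be >= 1", call. = FALSE)
  if (nrow(p) < spacing_k + 1)
    stop("dense trace must have at least spacing_k + 1 points", call. = FALSE)
  idx <- seq(1L, nrow(p), by = spacing_k)
  if (idx[length(idx)] != nrow(p)) idx <- c(idx, nrow(p))
  if (length(idx) < 2) stop("fewer than 2 points survive subsampling",
                            call. = FALSE)
  structure(list(points = p[idx, , drop = FALSE], spacing_k = spacing_k),
            class = "roi_polyline")
}

#' Total length of a polyline
#'
#' Sum of the Euclidean distances between consecutive points — the working
#' approximation of the diaphragm length along the traced ROI.
#'
#' @param points n x 2 matrix of ordered (x, y) (or an `roi_polyline`).
#' @return Length in the units of the coordinates (px).
#' @export
polyline_length <- function(points) {
  if (inherits(points, "roi_polyline")) points <- points$points
  p <- as_points_matrix(points)
  if (nrow(p) < 2) stop("polyline needs at least 2 points", call. = FALSE)
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  len <- sum(seg)
  if (len <= 0) stop("zero-length polyline (all points coincide)",
                     call. = FALSE)
  len
}

#' Global strain from current and initial length
#'
#' `GS = (Lt - L0) / L0 * 100` (%): the relative change of the ROI polyline
#' length against its frame-0 value. Shortening (contraction) is negative,
#' lengthening positive.
#'
#' @param Lt Current length.
#' @param L0 Initial length (> 0).
#' @return Global strain in percent (vectorized over `Lt`).
#' @export
global_strain <- function(Lt, L0) {
  if (!is.numeric(L0) || length(L0) != 1 || L0 <= 0)
    stop("L0 must be a single positive number", call. = FALSE)
  (Lt - L0) / L0 * 100
}

#' Global strain curve of a tracked ROI
#'
#' Recomputes the polyline length at every frame from the tracked positions
#' of the ROI points and converts it to strain with [global_strain()]. The
#' ROI points must be (a subset of) the trajectory set's initial points.
#' When the pixel spacing is anisotropic, coordinates are converted to mm
#' before measuring lengths, since the length ratio is unit-free only under
#' isotropic spacing.
#'
#' @param trajectories A `trajectory_set` whose columns track the ROI (and
#'   possibly other) points.
#' @param roi An `roi_polyline`; its points are matched to `points0` columns.
#' @param pixel_spacing_mm Length-2 numeric (row mm/px, column mm/px).
#' @return Numeric vector of GS (%) per frame, exactly 0 at frame 0, with
#'   attribute `unreliable` (logical per frame: some ROI point frozen).
#' @export
gs_curve <- function(trajectories, roi, pixel_spacing_mm = c(1, 1)) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(roi, "roi_polyline"))
  cols <- match_roi_columns(roi$points, trajectories$points0)
  sx <- pixel_spacing_mm[2]; sy <- pixel_spacing_mm[1]
  nfr <- nrow(trajectories$x)
  l0 <- polyline_length(cbind(roi$points[, 1] * sx, roi$points[, 2] * sy))
  gs <- vapply(seq_len(nfr), function(k) {
    p <- cbind(trajectories$x[k, cols] * sx, trajectories$y[k, cols] * sy)
    global_strain(polyline_length(p), l0)
  }, numeric(1))
  gs[1] <- 0  # Lt = L0 identically at frame 0
  attr(gs, "unreliable") <-
    apply(trajectories$frozen[, cols, drop = FALSE], 1, any)
  gs
}

match_roi_columns <- function(roi_points, points0, tol = 1e-6) {
  cols <- vapply(seq_len(nrow(roi_points)), function(i) {
    d2 <- (points0[, 1] - roi_points[i, 1])^2 +
      (points0[, 2] - roi_points[i, 2])^2
    j <- which.min(d2)
    if (d2[j] > tol) NA_integer_ else j
  }, integer(1))
  if (anyNA(cols))
    stop("ROI points must be among the tracked initial points", call. = FALSE)
  cols
}

#' Normalize interframe displacement across frame rates
#'
#' Interframe displacement scales inversely with the frame rate; to compare
#' loops acquired at different rates it is rescaled to the highest rate in
#' the data set: `D_norm = (FR / FRmax) * D`.
#'
#' @param D Interframe displacement (any numeric array).
#' @param FR Frame rate of the loop that produced `D` (Hz).
#' @param FRmax Maximum frame rate across all loops being compared (Hz),
#'   `FRmax >= FR`.
#' @return The normalized displacement, same shape as `D`.
#' @export
normalize_interframe <- function(D, FR, FRmax) {
  if (!is.numeric(FR) || FR <= 0 || !is.numeric(FRmax) || FRmax <= 0)
    stop("frame rates must be positive", call. = FALSE)
  if (FR > FRmax) stop("FR must not exceed FRmax", call. = FALSE)
  FR / FRmax * D
}

#' Peak-to-peak value of a curve over a cycle window
#'
#' The scalar summary of a deformation curve over one breathing cycle:
#' `max - min` within the window.
#'
#' @param curve Numeric vector.
#' @param cycle_window Integer indices into `curve` (default: the whole
#'   record).
#' @return A non-negative scalar.
#' @export
peak_to_peak <- function(curve, cycle_window = seq_along(curve)) {
  if (length(cycle_window) == 0) stop("empty cycle window", call. = FALSE)
  if (any(cycle_window < 1) || any(cycle_window > length(curve)))
    stop("cycle window outside the record", call. = FALSE)
  w <- curve[cycle_window]
  max(w) - min(w)
}

#' Aggregate per-point curves into one curve
#'
#' Frame-wise mean or median over the valid (non-frozen) points of the ROI.
#' Median is the default reporting choice; mean is kept for comparison.
#'
#' @param per_point_curves `(n_frames, n_points)` matrix.
#' @param method `"median"` or `"mean"`.
#' @param valid Optional logical matrix of the same shape; `FALSE` entries
#'   are excluded frame-wise.
#' @return Numeric vector of length `n_frames`, with attribute `gap`
#'   (logical: frames where no point was valid; value `NA` there).
#' @export
aggregate_curves <- function(per_point_curves, method = c("median", "mean"),
                             valid = NULL) {
  method <- match.arg(method)
  m <- as.matrix(per_point_curves)
  if (ncol(m) < 1) stop("need at least one point curve", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(m), ncol(m))
  fun <- if (method == "median") stats::median else mean
  out <- vapply(seq_len(nrow(m)), function(k) {
    vals <- m[k, valid[k, ]]
    if (length(vals) == 0) NA_real_ else fun(vals)
  }, numeric(1))
  attr(out, "gap") <- is.na(out)
  out
}

#' Read an ROI trace from CSV or JSON
#'
#' Accepts a CSV with `x`/`y` columns (or two unnamed columns) or a JSON
#' array of `[x, y]` pairs / object with `x` and `y` arrays — the manual
#' diaphragm trace at frame 0.
#'
#' @param path File path (.csv or .json).
#' @return n x 2 matrix of (x, y).
#' @export
read_roi <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    p <- if (is.list(j) && !is.null(j$x)) cbind(j$x, j$y) else as.matrix(j)
  } else {
    df <- utils::read.csv(path)
    p <- if (all(c("x", "y") %in% names(df))) cbind(df$x, df$y) else
      as.matrix(df[, 1:2])
  }
  as_points_matrix(p)
}
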