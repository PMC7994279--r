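# Shared fixtures and independent oracles. Heavy phantom computations are
# memoised so several test files can reuse one instance.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# textbook double-loop NCC, kept deliberately naive: the oracle for the
# optimized C++ implementation
ncc_brute <- function(tmpl, region) {
  kr <- nrow(tmpl); kc <- ncol(tmpl)
  nr <- nrow(region) - kr + 1; nc <- ncol(region) - kc + 1
  tm <- tmpl - mean(tmpl)
  td <- sqrt(sum(tm^2))
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      win <- region[i:(i + kr - 1), j:(j + kc - 1)]
      wm <- win - mean(win)
      wd <- sqrt(sum(wm^2))
      out[i, j] <- if (td * wd > 0) sum(tm * wm) / (td * wd) else 0
    }
  }
  out
}

# hand-built regular-grid displacement field for interpolation/accumulation
# tests
make_field <- function(grid_x, grid_y, u, v, valid = NULL,
                       dim = c(max(grid_y) + 10, max(grid_x) + 10)) {
  ny <- length(grid_y); nx <- length(grid_x)
  if (is.function(u)) u <- outer(grid_y, grid_x, function(y, x) u(x, y))
  if (is.function(v)) v <- outer(grid_y, grid_x, function(y, x) v(x, y))
  if (length(u) == 1) u <- matrix(u, ny, nx)
  if (length(v) == 1) v <- matrix(v, ny, nx)
  if (is.null(valid)) valid <- matrix(TRUE, ny, nx)
  structure(list(grid_x = as.integer(grid_x), grid_y = as.integer(grid_y),
                 u = u, v = v, peak_corr = matrix(1, ny, nx),
                 valid = valid, clamped = matrix(FALSE, ny, nx),
                 dim = as.integer(dim), config = NULL),
            class = "displacement_field")
}

# small rigid-shift phantom pair used by several tracking tests
rigid_pair <- function() {
  fixture("rigid_pair", function() {
    spec <- phantom_spec(160, 160, n_frames = 2,
                         motion_model = "rigid_translation",
                         motion_params = list(du_per_frame = 3,
                                              dv_per_frame = 1),
                         rng_seed = 101)
    sc <- generate_scatterers(spec)
    list(spec = spec,
         f0 = render_frame(sc, spec, 0),
         f1 = render_frame(sc, spec, 1))
  })
}

# 21-frame lateral-stretch phantom tracked along a dense horizontal ROI;
# shared by the strain-recovery and spacing-insensitivity checks
stretch_tracked <- function() {
  fixture("stretch_tracked", function() {
    spec <- phantom_spec(256, 256, n_frames = 21, frame_rate_hz = 30,
                         motion_model = "uniform_lateral_stretch",
                         motion_params = list(eps_max = 0.05), rng_seed = 5)
    seq_ <- generate_sequence(spec)
    dense <- cbind(x = 64:192, y = 128)
    cfg <- tracking_config(search_margin_px = c(4, 4))
    g <- grid_for_roi(dense, c(256, 256), cfg, motion_pad_px = 8)
    fields <- lapply(seq_len(20), function(k)
      estimate_interframe_field(seq_$stack$frames[[k]],
                                seq_$stack$frames[[k + 1]],
                                g$grid_x, g$grid_y, cfg))
    list(spec = spec, seq = seq_, dense = dense,
         traj = accumulate_trajectories(fields, dense))
  })
}

# write a DICOM fixture with pydicom (independent of the package's own
# reader); frames is a list of integer matrices in [0, 255]
write_dicom_fixture <- function(path, frames, frame_time_ms = NULL,
                                pixel_spacing = NULL, rgb = FALSE,
                                instance_number = NULL,
                                implicit_vr = FALSE) {
  rows <- nrow(frames[[1]]); cols <- ncol(frames[[1]])
  pxfile <- tempfile(fileext = ".bin")
  spp <- if (rgb) 3L else 1L
  con <- file(pxfile, "wb")
  for (f in frames) {
    v <- as.integer(round(t(f)))           # row-major frame
    if (rgb) v <- rep(v, each = 3L)        # gray written into R=G=B
    writeBin(as.raw(v), con)
  }
  close(con)
  py <- sprintf('
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.3.1"
meta.MediaStorageSOPInstanceUID = generate_uid()
meta.TransferSyntaxUID = %s
ds = Dataset()
ds.file_meta = meta
ds.SOPClassUID = meta.MediaStorageSOPClassUID
ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
ds.Rows = %d
ds.Columns = %d
ds.NumberOfFrames = %d
ds.SamplesPerPixel = %d
ds.PhotometricInterpretation = %s
if ds.SamplesPerPixel == 3:
    ds.PlanarConfiguration = 0
ds.BitsAllocated = 8
ds.BitsStored = 8
ds.HighBit = 7
ds.PixelRepresentation = 0
%s
%s
%s
with open(%s, "rb") as fh:
    ds.PixelData = fh.read()
ds.save_as(%s, enforce_file_format=True)
', if (implicit_vr) "ImplicitVRLittleEndian" else "ExplicitVRLittleEndian",
    rows, cols, length(frames), spp,
    if (rgb) '"RGB"' else '"MONOCHROME2"',
    if (is.null(frame_time_ms)) "" else
      sprintf("ds.FrameTime = '%g'", frame_time_ms),
    if (is.null(pixel_spacing)) "" else
      sprintf("ds.PixelSpacing = ['%g', '%g']", pixel_spacing[1],
              pixel_spacing[2]),
    if (is.null(instance_number)) "" else
      sprintf("ds.InstanceNumber = %d", instance_number),
    deparse(pxfile), deparse(path))
  script <- tempfile(fileext = ".py")
  writeLines(py, script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  unlink(c(pxfile, script))
  if (!file.exists(path))
    stop("pydicom fixture writer failed: ", paste(status, collapse = "\n"))
  invisible(path)
}
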