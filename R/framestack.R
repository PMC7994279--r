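#' Construct a frame stack (cine loop)
#'
#' The in-memory representation of a grayscale cine loop: an ordered list of
#' frames (matrices; rows = axial/vertical/depth, columns =
#' lateral/horizontal) plus the acquisition frame rate and the physical pixel
#' spacing. All downstream displacement estimates are in pixels with the
#' convention origin top-left, x = column (+right), y = row (+down);
#' conversion to millimetres happens only at reporting time via
#' `pixel_spacing_mm`.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param frame_rate_hz Acquisition frame rate (Hz), used to place frames on
#'   the time axis and to normalize interframe displacement across loops.
#' @param pixel_spacing_mm Length-2 numeric, mm per pixel as (row, column).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz, pixel_spacing_mm = c(1, 1)) {
  if (!is.list(frames) || length(frames) < 2)
    stop("frames must be a list of >= 2 matrices", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same dimensions", call. = FALSE)
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("frame_rate_hz must be > 0", call. = FALSE)
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2 || any(pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be two positive numbers", call. = FALSE)
  structure(list(frames = frames,
                 frame_rate_hz = frame_rate_hz,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack: %d frames of %d x %d px, %.4g Hz, spacing %.4g x %.4g mm/px\n",
              length(x$frames), d[1], d[2], x$frame_rate_hz,
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

frame_times_s <- function(stack) {
  (seq_along(stack$frames) - 1) / stack$frame_rate_hz
}

#' Write a frame stack as multi-page TIFF plus sidecar JSON
#'
#' Frames are scaled from `[0, 255]` to `[0, 1]` and written as a lossless
#' multi-page 8-bit TIFF; the frame rate, pixel spacing and any extra
#' metadata go into `<path>.json` so the stack round-trips through
#' [read_framestack_tiff()].
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @param extra Optional named list merged into the sidecar JSON (e.g. the
#'   phantom spec and seed).
#' @return `path`, invisibly.
#' @export
write_framestack_tiff <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  imgs <- lapply(stack$frames, function(f) f / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L, compression = "none")
  meta <- c(list(frame_rate_hz = stack$frame_rate_hz,
                 pixel_spacing_mm = stack$pixel_spacing_mm,
                 n_frames = length(stack$frames),
                 shape = dim(stack$frames[[1]])),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a frame stack written by [write_framestack_tiff()]
#'
#' @param path TIFF path; `<path>.json` must exist alongside it.
#' @return A [frame_stack()].
#' @export
read_framestack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  imgs <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    round(m * 255)
  })
  frame_stack(frames, frame_rate_hz = meta$frame_rate_hz,
              pixel_spacing_mm = meta$pixel_spacing_mm)
}

#' Read a DICOM cine loop as a frame stack
#'
#' Reads either a single multi-frame DICOM file or a directory of
#' single-frame DICOM files (ordered by instance number). Supports
#' uncompressed little-endian transfer syntaxes (explicit and implicit VR),
#' 8- or 16-bit grayscale and RGB pixel data; RGB is converted to luminance.
#' The frame rate is taken from the frame-time attribute (0018,1063), the
#' cine-rate attribute (0018,0040), or the recommended display frame rate
#' (0008,2144), in that order; pixel spacing from (0028,0030) or the imager
#' spacing (0018,1164). Missing physical metadata falls back to the
#' arguments, with a warning naming the provenance — there are no silent
#' defaults.
#'
#' @param path File or directory.
#' @param frame_rate_hz Override/fallback frame rate (Hz).
#' @param pixel_spacing_mm Override/fallback spacing, mm per px (row, col).
#' @return A [frame_stack()].
#' @export
read_dicom_cine <- function(path, frame_rate_hz = NULL,
                            pixel_spacing_mm = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0) stop("no files in DICOM directory", call. = FALSE)
    parsed <- lapply(files, parse_dicom_file)
    inst <- vapply(parsed, function(p)
      if (is.null(p$instance_number)) NA_real_ else p$instance_number,
      numeric(1))
    if (!anyNA(inst)) parsed <- parsed[order(inst)]
    shapes <- vapply(parsed, function(p) dim(p$frames[[1]]), integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      stop("inconsistent frame shapes across DICOM files", call. = FALSE)
    frames <- unlist(lapply(parsed, `[[`, "frames"), recursive = FALSE)
    meta <- parsed[[1]]
  } else {
    meta <- parse_dicom_file(path)
    frames <- meta$frames
  }
  fr <- meta$frame_rate_hz
  fr_src <- meta$frame_rate_source
  if (is.null(fr)) {
    if (is.null(frame_rate_hz))
      stop("DICOM carries no frame rate and no override was supplied; ",
           "pass frame_rate_hz", call. = FALSE)
    fr <- frame_rate_hz
    warning("frame rate not found in DICOM; using user override ",
            frame_rate_hz, " Hz", call. = FALSE)
    fr_src <- "user override"
  } else if (!is.null(frame_rate_hz)) {
    fr <- frame_rate_hz
    fr_src <- "user override"
  }
  sp <- meta$pixel_spacing_mm
  sp_src <- "DICOM PixelSpacing"
  if (is.null(sp)) {
    if (is.null(pixel_spacing_mm)) {
      warning("pixel spacing not found in DICOM and no override supplied; ",
              "assuming 1 mm/px", call. = FALSE)
      sp <- c(1, 1); sp_src <- "assumed"
    } else {
      sp <- pixel_spacing_mm; sp_src <- "user override"
    }
  } else if (!is.null(pixel_spacing_mm)) {
    sp <- pixel_spacing_mm; sp_src <- "user override"
  }
  message(sprintf("read_dicom_cine: frame rate %.4g Hz (%s); pixel spacing %.4g x %.4g mm/px (%s)",
                  fr, fr_src, sp[1], sp[2], sp_src))
  frame_stack(frames, frame_rate_hz = fr, pixel_spacing_mm = sp)
}

# --- minimal DICOM element walker --------------------------------------------
# Handles part-10 files with a 128-byte preamble + "DICM", the group-0002
# meta header (always explicit VR little endian), and uncompressed
# little-endian data sets. Only the handful of attributes the pipeline needs
# are retained; everything else is skipped by length.

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
  explicit <- TRUE
  ts_uid <- NULL
  tags <- list()
  raw_to_str <- function(b) rawToChar(b[b != as.raw(0)])
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    # the group-0002 meta header is always explicit VR little endian,
    # whatever the data-set transfer syntax
    in_meta <- group == 2L
    expl <- explicit || in_meta
    if (expl) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM elements (sequences/encapsulated pixel ",
           "data) are not supported", call. = FALSE)
    body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    tag <- sprintf("%04x,%04x", group, elem)
    if (tag == "0002,0010") {
      ts_uid <- trimws(raw_to_str(body))
      explicit <- ts_uid != "1.2.840.10008.1.2"
      if (ts_uid %in% c("1.2.840.10008.1.2.2"))
        stop("big-endian DICOM not supported", call. = FALSE)
      if (!ts_uid %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("compressed DICOM transfer syntax not supported: ", ts_uid,
             call. = FALSE)
    }
    if (tag %in% c("0008,2144", "0018,0040", "0018,1063", "0018,1164",
                   "0020,0013", "0028,0002", "0028,0004", "0028,0008",
                   "0028,0010", "0028,0011", "0028,0030", "0028,0100",
                   "7fe0,0010"))
      tags[[tag]] <- list(vr = vr, body = body)
    pos <- pos + hdr + len
  }
  txt <- function(tag) {
    t <- tags[[tag]]
    if (is.null(t)) return(NULL)
    trimws(raw_to_str(t$body))
  }
  num <- function(tag) {
    s <- txt(tag)
    if (is.null(s) || !nzchar(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us <- function(tag) {
    t <- tags[[tag]]
    if (is.null(t)) return(NULL)
    as.integer(t$body[1]) + 256L * as.integer(t$body[2])
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("DICOM lacks Rows/Columns", call. = FALSE)
  nframes <- num("0028,0008"); nframes <- if (is.null(nframes)) 1L else
    as.integer(nframes[1])
  spp <- us("0028,0002"); if (is.null(spp)) spp <- 1L
  bits <- us("0028,0100"); if (is.null(bits)) bits <- 8L
  px <- tags[["7fe0,0010"]]
  if (is.null(px)) stop("DICOM lacks PixelData", call. = FALSE)
  nvals <- rows * cols * nframes * spp
  vals <- if (bits == 8L) {
    as.integer(px$body[seq_len(nvals)])
  } else if (bits == 16L) {
    b <- px$body[seq_len(2L * nvals)]
    as.integer(b[c(TRUE, FALSE)]) + 256L * as.integer(b[c(FALSE, TRUE)])
  } else stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  frames <- vector("list", nframes)
  per <- rows * cols * spp
  for (k in seq_len(nframes)) {
    v <- vals[((k - 1L) * per + 1L):(k * per)]
    if (spp == 3L) {
      # pixel-interleaved RGB -> Rec.601 luminance
      r <- v[c(TRUE, FALSE, FALSE)]; g <- v[c(FALSE, TRUE, FALSE)]
      b <- v[c(FALSE, FALSE, TRUE)]
      v <- 0.299 * r + 0.587 * g + 0.114 * b
    }
    frames[[k]] <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  }
  ft <- num("0018,1063")      # frame time, ms
  cine <- num("0018,0040")    # cine rate, Hz
  rdfr <- num("0008,2144")    # recommended display frame rate, Hz
  fr <- NULL; fr_src <- NULL
  if (!is.null(ft) && ft[1] > 0) {
    fr <- 1000 / ft[1]; fr_src <- "DICOM FrameTime (0018,1063)"
  } else if (!is.null(cine) && cine[1] > 0) {
    fr <- cine[1]; fr_src <- "DICOM CineRate (0018,0040)"
  } else if (!is.null(rdfr) && rdfr[1] > 0) {
    fr <- rdfr[1]; fr_src <- "DICOM RecommendedDisplayFrameRate (0008,2144)"
  }
  sp <- num("0028,0030")
  if (is.null(sp)) sp <- num("0018,1164")
  inst <- num("0020,0013")
  if (is.null(inst)) {
    t <- tags[["0020,0013"]]
    if (!is.null(t) && length(t$body) >= 2) inst <- us("0020,0013")
  }
  list(frames = frames, frame_rate_hz = fr, frame_rate_source = fr_src,
       pixel_spacing_mm = sp,
       instance_number = if (is.null(inst)) NULL else inst[1])
}
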