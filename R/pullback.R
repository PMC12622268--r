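#' Construct an OCT pullback object
#'
#' A pullback is the ordered stack of square axial grayscale frames acquired
#' while the imaging catheter is withdrawn, together with its spatial
#' calibration and per-frame gating flags.
#'
#' @param frames 3-D integer array (n_frames x height x width), values 0..255,
#'   or a list of equally sized square matrices.
#' @param pixel_spacing_um in-plane microns per pixel (isotropic), > 0.
#' @param frame_spacing_mm longitudinal spacing between frames, > 0.
#' @param frame_flags data.frame with logical columns `in_guide_catheter` and
#'   `in_stent`, one row per frame. Flagged frames are carried through but
#'   never contribute to morphometry.
#' @param patient_id opaque identifier.
#' @return An object of class `oct_pullback`.
#' @export
oct_pullback <- function(frames, pixel_spacing_um, frame_spacing_mm = 0.2,
                         frame_flags = NULL, patient_id = "anonymous") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop("all frames must share one size; got mixed frame sizes")
    }
    arr <- array(0L, dim = c(length(frames), dims[[1]][1], dims[[1]][2]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  n <- dim(frames)[1]
  if (n < 1L) stop("a pullback needs at least one frame")
  if (dim(frames)[2] != dim(frames)[3]) {
    stop(sprintf("frames must be square; got %d x %d",
                 dim(frames)[2], dim(frames)[3]))
  }
  if (!is.numeric(pixel_spacing_um) || length(pixel_spacing_um) != 1L ||
      is.na(pixel_spacing_um) || pixel_spacing_um <= 0) {
    stop("calibration error: pixel_spacing_um must be a single positive number")
  }
  stopifnot(frame_spacing_mm > 0)
  if (is.null(frame_flags)) {
    frame_flags <- data.frame(in_guide_catheter = rep(FALSE, n),
                              in_stent = rep(FALSE, n))
  }
  if (nrow(frame_flags) != n) {
    stop("frame_flags must have exactly one row per frame")
  }
  storage.mode(frames) <- "integer"
  structure(
    list(frames = frames, pixel_spacing_um = pixel_spacing_um,
         frame_spacing_mm = frame_spacing_mm, frame_flags = frame_flags,
         patient_id = patient_id),
    class = "oct_pullback"
  )
}

#' @export
print.oct_pullback <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("OCT pullback '%s': %d frames of %dx%d px, %.3g um/px, %.3g mm between frames\n",
              x$patient_id, d[1], d[2], d[3],
              x$pixel_spacing_um, x$frame_spacing_mm))
  gated <- sum(x$frame_flags$in_guide_catheter | x$frame_flags$in_stent)
  if (gated > 0) cat(sprintf("  %d frame(s) flagged in guide catheter / stent\n", gated))
  invisible(x)
}

#' Number of frames in a pullback
#' @param pullback an `oct_pullback`.
#' @return integer frame count.
#' @export
n_frames <- function(pullback) dim(pullback$frames)[1]

#' Extract one frame as a matrix
#' @param pullback an `oct_pullback`.
#' @param i frame index (1-based).
#' @return numeric matrix (height x width), values 0..255.
#' @export
get_frame <- function(pullback, i) {
  stopifnot(i >= 1, i <= n_frames(pullback))
  pullback$frames[i, , ]
}

frame_paths <- function(dir) {
  p <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(p) == 0L) stop("no PNG frames found in ", dir)
  p
}

png_to_int <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1]   # tolerate gray written as RGB
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Read a pullback from disk
#'
#' Two on-disk layouts are supported: a directory of 8-bit grayscale PNG
#' frames (sorted by file name = acquisition order), or a minimal multi-frame
#' grayscale DICOM file as written by [write_pullback()]. PNG carries no
#' spatial metadata, so `pixel_spacing_um` is required for PNG stacks; for
#' DICOM an explicit override wins over file metadata.
#'
#' @param path directory (png_stack) or file (dicom).
#' @param format `"png_stack"` or `"dicom"`.
#' @param pixel_spacing_um calibration override (required for PNG).
#' @param frame_spacing_mm longitudinal spacing override.
#' @param frame_flags optional flags data.frame (see [oct_pullback()]).
#' @param patient_id identifier (PNG only; DICOM reads it from the file).
#' @return An `oct_pullback`.
#' @export
read_pullback <- function(path, format = c("png_stack", "dicom"),
                          pixel_spacing_um = NULL, frame_spacing_mm = NULL,
                          frame_flags = NULL, patient_id = "anonymous") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "png_stack") {
    if (is.null(pixel_spacing_um)) {
      stop("calibration error: PNG stacks carry no pixel spacing; ",
           "supply pixel_spacing_um")
    }
    mats <- lapply(frame_paths(path), function(f) png_to_int(png::readPNG(f)))
    sizes <- unique(lapply(mats, dim))
    if (length(sizes) != 1L) {
      stop("mixed frame sizes in PNG stack: ",
           paste(vapply(sizes, paste, "", collapse = "x"), collapse = ", "))
    }
    if (sizes[[1]][1] != sizes[[1]][2]) {
      stop(sprintf("non-square frames rejected: %d x %d",
                   sizes[[1]][1], sizes[[1]][2]))
    }
    oct_pullback(mats, pixel_spacing_um,
                 frame_spacing_mm = frame_spacing_mm %||% 0.2,
                 frame_flags = frame_flags, patient_id = patient_id)
  } else {
    dcm <- read_dicom_stack(path)
    spacing <- pixel_spacing_um %||% dcm$pixel_spacing_um
    if (is.null(spacing)) {
      stop("calibration error: DICOM has no PixelSpacing and no override given")
    }
    oct_pullback(dcm$frames, spacing,
                 frame_spacing_mm = frame_spacing_mm %||%
                   dcm$frame_spacing_mm %||% 0.2,
                 frame_flags = frame_flags,
                 patient_id = dcm$patient_id %||% patient_id)
  }
}

#' Write a pullback to disk
#'
#' @param pullback an `oct_pullback`.
#' @param path output directory (png_stack) or file (dicom).
#' @param format `"png_stack"` or `"dicom"`.
#' @return `path`, invisibly.
#' @export
write_pullback <- function(pullback, path, format = c("png_stack", "dicom")) {
  format <- match.arg(format)
  if (format == "png_stack") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n_frames(pullback))) {
      png::writePNG(get_frame(pullback, i) / 255,
                    file.path(path, sprintf("frame_%05d.png", i)))
    }
  } else {
    write_dicom_stack(pullback, path)
  }
  invisible(path)
}

#' Read a label mask
#'
#' Masks are 8-bit grayscale PNGs whose gray level is the class code of
#' [oct_classes()]. Any other gray level is rejected.
#'
#' @param path PNG file.
#' @return integer matrix of class codes.
#' @export
read_mask <- function(path) {
  m <- png_to_int(png::readPNG(path))
  bad <- setdiff(unique(as.vector(m)), oct_classes())
  if (length(bad) > 0) {
    stop("unknown class code(s) in mask: ", paste(sort(bad), collapse = ", "))
  }
  m
}

#' Write a label mask
#' @param mask integer matrix of class codes.
#' @param path PNG file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  bad <- setdiff(unique(as.vector(mask)), oct_classes())
  if (length(bad) > 0) {
    stop("refusing to write unknown class code(s): ",
         paste(sort(bad), collapse = ", "))
  }
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read all masks of a pullback from a directory
#' @param dir directory of mask PNGs (sorted by name = frame order).
#' @return list of integer class-code matrices.
#' @export
read_masks <- function(dir) lapply(frame_paths(dir), read_mask)

#' Write a list of masks to a directory
#' @param masks list of class-code matrices.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_masks <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(masks)) {
    write_mask(masks[[i]], file.path(dir, sprintf("mask_%05d.png", i)))
  }
  invisible(dir)
}

#' Read / write a paired-measurement table
#'
#' Long-format CSV with columns patient_id, frame_index, reader_id,
#' parameter_name, value, unit. Parameter names and units are restricted to
#' [measurement_units()].
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(df)
  df
}

#' @rdname read_measurements
#' @param df measurement data.frame.
#' @export
write_measurements <- function(df, path) {
  validate_measurements(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

validate_measurements <- function(df) {
  need <- c("patient_id", "frame_index", "reader_id", "parameter_name",
            "value", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  units <- measurement_units()
  bad <- setdiff(unique(df$parameter_name), names(units))
  if (length(bad) > 0) {
    stop("unknown parameter_name: ", paste(bad, collapse = ", "))
  }
  wrong <- df$unit != units[df$parameter_name]
  if (any(wrong)) {
    stop("unit mismatch for ",
         paste(unique(df$parameter_name[wrong]), collapse = ", "))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
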