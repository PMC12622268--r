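# Minimal DICOM support: explicit-VR little-endian, single file, multi-frame
# 8-bit grayscale. Covers the subset this package itself writes (no installed
# R package reads DICOM in this environment). Not a general DICOM parser.

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                   endian = "little")

dcm_element <- function(group, element, vr, value_raw) {
  n <- length(value_raw)
  if (n %% 2 == 1) {
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    n <- n + 1
  }
  head <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_uint32(n), value_raw)
  } else {
    c(head, dcm_uint16(n), value_raw)
  }
}

dcm_str <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(s))
}
dcm_us <- function(group, element, x) {
  dcm_element(group, element, "US", dcm_uint16(x))
}

write_dicom_stack <- function(pullback, path) {
  d <- dim(pullback$frames)
  nf <- d[1]; h <- d[2]; w <- d[3]
  spacing_mm <- format(pullback$pixel_spacing_um / 1000, scientific = FALSE)
  meta_body <- dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  body <- c(
    dcm_str(0x0010, 0x0020, "LO", as.character(pullback$patient_id)),
    dcm_str(0x0018, 0x0088, "DS",
            format(pullback$frame_spacing_mm, scientific = FALSE)),
    dcm_us(0x0028, 0x0002, 1),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_str(0x0028, 0x0008, "IS", as.character(nf)),
    dcm_us(0x0028, 0x0010, h),
    dcm_us(0x0028, 0x0011, w),
    dcm_str(0x0028, 0x0030, "DS", paste(spacing_mm, spacing_mm, sep = "\\")),
    dcm_us(0x0028, 0x0100, 8),
    dcm_us(0x0028, 0x0101, 8),
    dcm_us(0x0028, 0x0102, 7),
    dcm_us(0x0028, 0x0103, 0)
  )
  # pixel data: frame-major, row-major within frame
  px <- raw(nf * h * w)
  pos <- 0L
  for (i in seq_len(nf)) {
    px[pos + seq_len(h * w)] <- as.raw(as.vector(t(pullback$frames[i, , ])))
    pos <- pos + h * w
  }
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OB", px))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_u16 <- function(r, i) {
  as.integer(r[i]) + 256L * as.integer(r[i + 1L])
}
read_u32 <- function(r, i) {
  as.integer(r[i]) + 256 * as.integer(r[i + 1L]) +
    65536 * as.integer(r[i + 2L]) + 16777216 * as.integer(r[i + 3L])
}

read_dicom_stack <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 136 || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  i <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  while (i + 8L <= length(r) + 1L) {
    group <- read_u16(r, i); element <- read_u16(r, i + 2L)
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (vr %in% long_vrs) {
      len <- read_u32(r, i + 8L)
      val_start <- i + 12L
    } else {
      len <- read_u16(r, i + 6L)
      val_start <- i + 8L
    }
    key <- sprintf("%04x,%04x", group, element)
    elems[[key]] <- list(vr = vr, value = r[val_start + seq_len(len) - 1L])
    i <- val_start + len
  }
  getstr <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    trimws(rawToChar(e$value))
  }
  getus <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    read_u16(e$value, 1L)
  }
  h <- getus("0028,0010"); w <- getus("0028,0011")
  if (is.null(h) || is.null(w)) stop("DICOM missing Rows/Columns")
  nf <- as.integer(getstr("0028,0008") %||% "1")
  bits <- getus("0028,0100") %||% 8L
  if (bits != 8L) stop("only 8-bit grayscale DICOM is supported")
  spacing <- getstr("0028,0030")
  pixel_spacing_um <- NULL
  if (!is.null(spacing)) {
    parts <- as.numeric(strsplit(spacing, "\\\\")[[1]])
    if (length(parts) == 2 && abs(parts[1] - parts[2]) > 1e-9 * parts[1]) {
      stop("anisotropic PixelSpacing rejected: ", spacing)
    }
    pixel_spacing_um <- parts[1] * 1000
  }
  fs <- getstr("0018,0088")
  px <- elems[["7fe0,0010"]]
  if (is.null(px)) stop("DICOM missing PixelData")
  if (length(px$value) < nf * h * w) stop("truncated PixelData")
  frames <- array(0L, dim = c(nf, h, w))
  pos <- 0L
  for (k in seq_len(nf)) {
    frames[k, , ] <- matrix(as.integer(px$value[pos + seq_len(h * w)]),
                            nrow = h, byrow = TRUE)
    pos <- pos + h * w
  }
  list(frames = frames,
       pixel_spacing_um = pixel_spacing_um,
       frame_spacing_mm = if (is.null(fs)) NULL else as.numeric(fs),
       patient_id = getstr("0010,0020"))
}
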