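# Shared fixture builders. Everything is generated in code at test time;
# no data files are stored.

CLS <- oct_classes()

# pixel-center distance/angle grids for a square frame (0-based coords)
grid_polar <- function(size, cx = (size - 1) / 2, cy = (size - 1) / 2) {
  xg <- matrix(rep(0:(size - 1), each = size), nrow = size)
  yg <- matrix(rep(0:(size - 1), times = size), nrow = size)
  list(x = xg, y = yg, r = sqrt((xg - cx)^2 + (yg - cy)^2),
       th = (atan2(yg - cy, xg - cx) * 180 / pi) %% 360)
}

# mask with a filled lumen disc (or ellipse) at an arbitrary center
disc_mask <- function(size = 256, radius = 50, cx = (size - 1) / 2,
                      cy = (size - 1) / 2, ry = radius) {
  g <- grid_polar(size, cx, cy)
  m <- matrix(CLS[["background"]], size, size)
  m[((g$x - cx) / radius)^2 + ((g$y - cy) / ry)^2 < 1] <- CLS[["lumen"]]
  m
}

# annular mask: lumen disc + wall ring, with optional plaque sectors and a
# uniform cap band in front of lipid
annulus_mask <- function(size = 256, lumen_r = 60, wall = 60,
                         lipid = NULL, calcium = NULL, shadow = NULL,
                         cap_px = 6, cap_fun = NULL) {
  g <- grid_polar(size)
  m <- matrix(CLS[["background"]], size, size)
  m[g$r < lumen_r + wall] <- CLS[["wall"]]
  in_span <- function(iv) {
    span <- (iv[2] - iv[1]) %% 360
    if (span == 0) span <- 360
    ((g$th - iv[1]) %% 360) < span
  }
  if (!is.null(lipid)) {
    cap_r <- if (is.null(cap_fun)) {
      matrix(cap_px, size, size)
    } else {
      matrix(cap_fun(as.vector(g$th)), size, size)
    }
    sel <- in_span(lipid)
    m[sel & g$r >= lumen_r & g$r < lumen_r + cap_r] <- CLS[["cap"]]
    m[sel & g$r >= lumen_r + cap_r & g$r < lumen_r + cap_r + 30] <- CLS[["lipid"]]
  }
  if (!is.null(calcium)) {
    sel <- in_span(calcium)
    m[sel & g$r >= lumen_r + 8 & g$r < lumen_r + 38] <- CLS[["calcium"]]
  }
  if (!is.null(shadow)) {
    sel <- in_span(shadow)
    m[sel & g$r >= lumen_r] <- CLS[["shadow"]]
  }
  m[g$r < lumen_r] <- CLS[["lumen"]]
  m
}

# one-row frame-measurement stub for classifier tests
fm_row <- function(lipid_max = 0, lipid_total = NULL, calcium_max = 0,
                   fct = NA_real_, analyzable = TRUE) {
  data.frame(frame_index = 1L, lumen_area_mm2 = 5,
             lipid_arc_deg_total = if (is.null(lipid_total)) lipid_max else lipid_total,
             lipid_arc_deg_max = lipid_max,
             calcium_arc_deg_total = calcium_max,
             calcium_arc_deg_max = calcium_max,
             fct_min_um = fct, fct_mean_um = fct, analyzable = analyzable)
}

# standard single-frame lipid phantom used by several suites
std_phantom <- function(seed = 5, frame_size = 512, span = 120) {
  phantom_spec(
    n_frames = 1, frame_size = frame_size, seed = seed,
    plaques = list(list(frame_interval = c(1, 1), tissue = "lipid",
                        arc_center_deg = 90, arc_span_deg = span,
                        cap_thickness_px = 6, depth_px = 40))
  )
}

# brute-force longest circular run of TRUE (independent oracle)
brute_max_run <- function(v) {
  n <- length(v)
  if (!any(v)) return(0L)
  best <- 0L
  for (s in seq_len(n)) {
    len <- 0L
    for (k in seq_len(n)) {
      if (v[((s + k - 2) %% n) + 1]) len <- len + 1L else break
    }
    best <- max(best, len)
  }
  min(best, n)
}
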