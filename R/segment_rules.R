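# Rule-based intensity segmentation.
#
# A deliberately simple, fully deterministic stand-in for a trained
# segmentation network: it recovers lumen, wall, cap, lipid, calcium and
# guidewire shadow from the phantom intensity model (dark lumen, bright wall
# surface, low-signal pools) so the whole pipeline — including artifact
# corruption and correction — can be exercised end to end without trained
# weights. It is not intended for clinical images.

#' Rule-segmenter parameters
#'
#' @param surface_threshold smoothed intensity marking the luminal tissue
#'   surface (default 60).
#' @param dark_threshold smoothed intensity below which wall-band tissue is a
#'   low-signal pool (default 110).
#' @param calcium_max_intensity raw-mean split between calcium and lipid
#'   pools (default 58).
#' @param background_threshold smoothed intensity marking the outer signal
#'   falloff (default 30).
#' @param shadow_peak_max surface-peak intensity below which an angle is
#'   guidewire shadow (default 25).
#' @param min_pool_px minimum contiguous radial run for a pool (default 6).
#' @param max_cap_px maximum lumen-to-lipid distance still labelled as a cap
#'   (default 30).
#' @param smooth_px radial running-mean window (default 5).
#' @return list of parameters.
#' @export
rule_segmenter_params <- function(surface_threshold = 60, dark_threshold = 110,
                                  calcium_max_intensity = 58,
                                  background_threshold = 30,
                                  shadow_peak_max = 25, min_pool_px = 6,
                                  max_cap_px = 30, smooth_px = 5) {
  list(surface_threshold = surface_threshold, dark_threshold = dark_threshold,
       calcium_max_intensity = calcium_max_intensity,
       background_threshold = background_threshold,
       shadow_peak_max = shadow_peak_max, min_pool_px = min_pool_px,
       max_cap_px = max_cap_px, smooth_px = smooth_px)
}

running_mean <- function(v, w) {
  s <- as.vector(stats::filter(v, rep(1 / w, w), sides = 2))
  na <- is.na(s)
  s[na] <- v[na]
  s
}

# estimate the lumen center of a raw frame by one centroid refinement pass
estimate_center <- function(frame, params = rule_segmenter_params()) {
  sz <- dim(frame)
  center <- c((sz[2] - 1) / 2, (sz[1] - 1) / 2)
  for (pass in 1:2) {
    polar <- to_polar(frame, center, n_angles = 180, radial_step_px = 1)
    v <- polar$values
    r_in <- vapply(seq_len(nrow(v)), function(a) {
      sm <- running_mean(v[a, ], params$smooth_px)
      w <- which(sm[-(1:4)] > params$surface_threshold)
      if (length(w) == 0) ncol(v) else w[1] + 4
    }, 0)
    theta <- (seq_len(nrow(v)) - 1) * 2 * pi / nrow(v)
    # first-order boundary-centroid update toward the lumen center
    center <- c(center[1] + mean(r_in * cos(theta)),
                center[2] + mean(r_in * sin(theta)))
  }
  center
}

#' Segment a frame from intensities alone
#'
#' @param frame intensity matrix (0..255).
#' @param center optional lumen center; estimated from the image if missing.
#' @param params [rule_segmenter_params()].
#' @return integer class-code matrix.
#' @export
segment_frame_rules <- function(frame, center = NULL,
                                params = rule_segmenter_params()) {
  cls <- oct_classes()
  if (is.null(center)) center <- estimate_center(frame, params)
  polar <- to_polar(frame, center, n_angles = 360, radial_step_px = 1)
  v <- polar$values
  n_angles <- nrow(v); n_radii <- ncol(v)
  labels <- matrix(cls[["background"]], n_angles, n_radii)

  for (a in seq_len(n_angles)) {
    sm <- running_mean(v[a, ], params$smooth_px)
    w <- which(sm[-(1:4)] > params$surface_threshold)
    r_in <- if (length(w) == 0) n_radii else w[1] + 4
    labels[a, seq_len(min(r_in, n_radii))] <- cls[["lumen"]]
    if (r_in >= n_radii) next
    band <- r_in:n_radii
    peak <- stats::quantile(v[a, r_in:min(r_in + 40, n_radii)], 0.9,
                            names = FALSE)
    if (peak < params$shadow_peak_max) {
      labels[a, band] <- cls[["shadow"]]
      next
    }
    smb <- sm[band]
    # outer signal falloff -> background
    dark_tail <- which(smb < params$background_threshold)
    outer <- if (length(dark_tail) == 0) length(band) else {
      # first radius from which the signal never recovers
      cand <- dark_tail[dark_tail > 10]
      if (length(cand) == 0) length(band) else cand[1] - 1
    }
    if (outer < 1) outer <- 1
    labels[a, band[seq_len(outer)]] <- cls[["wall"]]
    if (outer < length(band)) {
      labels[a, band[(outer + 1):length(band)]] <- cls[["background"]]
    }
    # low-signal pools inside the wall
    pool <- smb[seq_len(outer)] < params$dark_threshold
    r <- rle(pool)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$lengths)) {
      if (!r$values[j] || r$lengths[j] < params$min_pool_px) next
      run <- band[starts[j]:ends[j]]
      tissue <- if (mean(v[a, run]) < params$calcium_max_intensity) {
        cls[["calcium"]]
      } else {
        cls[["lipid"]]
      }
      labels[a, run] <- tissue
      # bright band between lumen boundary and a lipid pool = fibrous cap
      if (tissue == cls[["lipid"]] &&
          (run[1] - r_in) <= params$max_cap_px && run[1] > r_in + 1) {
        labels[a, (r_in + 1):(run[1] - 1)] <- cls[["cap"]]
      }
    }
  }
  pf <- polar
  pf$values <- labels
  mask <- from_polar(pf, dim(frame), interp = "nearest",
                     fill = cls[["background"]])
  storage.mode(mask) <- "integer"
  mask
}
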