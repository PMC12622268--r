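# Correction of the effect of artifacts (gas bubble, signal dropout) on the
# vessel wall: masking -> lumen-centered polar transform -> per-sector
# detection -> histogram matching against the frame's clean sectors ->
# retransform with a feathered blend.
#
# Detection statistic: OCT artifacts attenuate the normally bright luminal
# tissue surface, while genuinely dark tissue (lipid pools, calcium) sits
# BEHIND a bright surface or cap. Each angle is therefore summarized by the
# peak intensity in a near-wall band beyond the lumen boundary; sectors are
# flagged when their mean peak falls k MADs below the sector median, or when
# their band intensities are stochastically darker than the pooled clean
# sectors (one-sided Kolmogorov-Smirnov) beyond a threshold. Guidewire-shadow
# sectors are pre-excluded: no tissue signal exists there to recover.

#' Artifact-correction parameters
#'
#' @param k_mad MAD multiplier of the sector-darkening rule (default 3).
#' @param ks_threshold one-sided KS distance above which a darker-than-median
#'   sector is flagged (default 0.3).
#' @param sector_deg sector width in degrees (default 5).
#' @param feather_deg angular feather blended at region borders (default 2).
#' @param band_px radial extent of the wall band beyond the lumen boundary
#'   used for matching (default 80).
#' @param peak_band_px near-wall band used for the detection peak (default 12).
#' @param min_clean_sectors fewer clean sectors than this declines correction.
#' @param min_reference_deg minimum clean reference span (default 30).
#' @param min_surface_intensity absolute floor on the median surface peak;
#'   below it the whole frame is considered corrupted and correction is
#'   declined (default 60).
#' @param ks_peak_guard only sectors whose surface peak falls below this
#'   fraction of the median peak are eligible for the KS criterion, so that
#'   distributional differences of legitimately dark tissue (lipid, calcium)
#'   behind an intact bright surface are never "corrected" (default 0.5).
#' @return list of parameters.
#' @export
artifact_params <- function(k_mad = 3, ks_threshold = 0.3, sector_deg = 5,
                            feather_deg = 2, band_px = 80, peak_band_px = 12,
                            min_clean_sectors = 3, min_reference_deg = 30,
                            min_surface_intensity = 60, ks_peak_guard = 0.5) {
  list(k_mad = k_mad, ks_threshold = ks_threshold, sector_deg = sector_deg,
       feather_deg = feather_deg, band_px = band_px,
       peak_band_px = peak_band_px, min_clean_sectors = min_clean_sectors,
       min_reference_deg = min_reference_deg,
       min_surface_intensity = min_surface_intensity,
       ks_peak_guard = ks_peak_guard)
}

# per-angle lumen boundary radius and shadow flags from a mask, on the same
# angular grid as a polar frame
polar_lumen_profile <- function(mask, center, n_angles, n_radii,
                                radial_step_px = 1) {
  cls <- oct_classes()
  pm <- to_polar(mask, center, n_angles = n_angles, n_radii = n_radii,
                 radial_step_px = radial_step_px, interp = "nearest")$values
  r_in <- apply(pm == cls[["lumen"]], 1, function(v) {
    w <- which(v)
    if (length(w) == 0) NA_real_ else max(w)
  })
  r_in[is.na(r_in)] <- stats::median(r_in, na.rm = TRUE)
  shadow <- apply(pm == cls[["shadow"]], 1, any)
  list(r_in = r_in, shadow = shadow)
}

# one-sided KS: how much darker is `sec` than `ref` (max of F_sec - F_ref)
ks_darker <- function(sec, ref) {
  sec <- sort(sec)
  f_ref <- findInterval(sec, sort(ref)) / length(ref)
  f_sec <- seq_along(sec) / length(sec)
  max(f_sec - f_ref)
}

#' Detect artifact-darkened angular sectors of a polar frame
#'
#' @param polar a `polar_frame` of an intensity image (1 px radial step).
#' @param lumen_radius_px per-angle lumen boundary radius (length = rows of
#'   the polar frame) or a scalar.
#' @param shadow_angles logical per-angle guidewire-shadow flags (excluded
#'   from detection and reference).
#' @param params [artifact_params()].
#' @return list: `regions` (data.frame start_deg, end_deg, r0_px, r1_px,
#'   kind), `declined` (logical: too few clean sectors or globally dark
#'   frame), `clean_angles` (logical per-angle vector).
#' @export
detect_artifact_sectors <- function(polar, lumen_radius_px,
                                    shadow_angles = NULL,
                                    params = artifact_params()) {
  v <- polar$values
  n_angles <- nrow(v); n_radii <- ncol(v)
  step <- polar$angular_step_deg
  if (length(lumen_radius_px) == 1) {
    lumen_radius_px <- rep(lumen_radius_px, n_angles)
  }
  if (is.null(shadow_angles)) shadow_angles <- rep(FALSE, n_angles)

  # per-angle surface peak in the near-wall band; the maximum is robust to
  # dark pools behind a bright surface or cap
  peak <- vapply(seq_len(n_angles), function(a) {
    r0 <- min(max(round(lumen_radius_px[a]), 1), n_radii - 1)
    r1 <- min(r0 + params$peak_band_px, n_radii)
    max(v[a, r0:r1])
  }, 0)

  sec_size <- round(params$sector_deg / step)
  sec_of <- ((seq_len(n_angles) - 1) %/% sec_size) + 1
  n_sec <- max(sec_of)
  sec_shadow <- tapply(shadow_angles, sec_of, any)
  # a multiplicative artifact darkens (nearly) every angle's surface peak,
  # while tissue composition mostly moves the lower quantiles; the 80th
  # percentile over the sector's angles tolerates one boundary angle
  sec_peak <- tapply(peak, sec_of, function(p) {
    sort(p)[ceiling(0.8 * length(p))]
  })

  eligible <- !sec_shadow
  med <- stats::median(sec_peak[eligible])
  md <- stats::mad(sec_peak[eligible])
  declined <- FALSE
  flagged <- rep(FALSE, n_sec)
  if (med < params$min_surface_intensity) {
    declined <- TRUE                       # globally dark: nothing to match to
  } else {
    flagged <- eligible & (sec_peak < med - params$k_mad * md)
    # secondary distributional criterion, surface-darkened sectors only
    cand <- which(eligible & !flagged &
                    sec_peak < params$ks_peak_guard * med)
    if (length(cand) > 0) {
      clean_ang <- !(sec_of %in% which(flagged)) & !shadow_angles
      band_vals <- function(angles) {
        unlist(lapply(angles, function(a) {
          r0 <- min(max(round(lumen_radius_px[a]), 1), n_radii - 1)
          v[a, r0:min(r0 + params$band_px, n_radii)]
        }))
      }
      ref <- band_vals(which(clean_ang))
      for (s in cand) {
        sec_vals <- band_vals(which(sec_of == s & !shadow_angles))
        if (ks_darker(sec_vals, ref) > params$ks_threshold) flagged[s] <- TRUE
      }
    }
    if (sum(eligible & !flagged) < params$min_clean_sectors) {
      declined <- TRUE
      flagged[] <- FALSE
    }
  }

  regions <- data.frame(start_deg = numeric(), end_deg = numeric(),
                        r0_px = numeric(), r1_px = numeric(),
                        kind = character())
  if (!declined && any(flagged)) {
    iv <- cbind((which(flagged) - 1) * params$sector_deg,
                which(flagged) * params$sector_deg)
    m <- merge_intervals(norm_intervals(iv))
    # join a run straddling 0/360
    if (nrow(m) > 1 && m[1, 1] <= 1e-9 && m[nrow(m), 2] >= 360 - 1e-9) {
      m[1, 1] <- m[nrow(m), 1] - 360
      m <- m[-nrow(m), , drop = FALSE]
    }
    r0 <- min(lumen_radius_px) * polar$radial_step_px
    regions <- data.frame(start_deg = m[, 1] %% 360,
                          end_deg = m[, 1] %% 360 + (m[, 2] - m[, 1]),
                          r0_px = r0,
                          r1_px = r0 + params$band_px * polar$radial_step_px,
                          kind = "dropout")
  }
  clean_angles <- !shadow_angles &
    !(sec_of %in% which(flagged)) & !declined
  list(regions = regions, declined = declined, clean_angles = clean_angles)
}

# Restrict the reference to the clean sectors whose shape-normalized radial
# band profile is closest to the region's. A multiplicative artifact leaves
# the region's normalized profile unchanged, so this selects reference tissue
# of the same composition (wall-on-wall, lipid-on-lipid) and avoids mapping a
# pure-wall region onto a mixed wall/lipid intensity distribution.
profile_matched_reference <- function(polar, region, clean_angles, params) {
  v <- polar$values
  n_angles <- nrow(v); n_radii <- ncol(v)
  step <- polar$angular_step_deg
  ang_deg <- (seq_len(n_angles) - 1) * step
  span <- region$end_deg - region$start_deg
  in_region <- ang_in_span(ang_deg, (region$start_deg + span / 2) %% 360, span)
  cols <- max(1, round(region$r0_px / polar$radial_step_px)):
    min(n_radii, round(region$r1_px / polar$radial_step_px))
  norm_profile <- function(rows) {
    p <- colMeans(v[rows, cols, drop = FALSE])
    m <- mean(p)
    if (m <= 0) return(rep(1, length(p)))
    p / m
  }
  p_reg <- norm_profile(which(in_region))
  sec_size <- max(1, round(params$sector_deg / step))
  sec_of <- ((seq_len(n_angles) - 1) %/% sec_size) + 1
  clean_secs <- setdiff(unique(sec_of[clean_angles]),
                        unique(sec_of[!clean_angles]))
  if (length(clean_secs) == 0) return(clean_angles)
  d <- vapply(clean_secs, function(s) {
    mean((norm_profile(which(sec_of == s)) - p_reg)^2)
  }, 0)
  need <- ceiling(params$min_reference_deg / params$sector_deg)
  keep <- clean_secs[order(d)][seq_len(max(need, ceiling(length(d) / 2)))]
  clean_angles & (sec_of %in% keep)
}

#' Histogram-match one angular region to the frame's clean sectors
#'
#' Monotone quantile mapping of the region's intensities onto the pooled
#' reference distribution: a pixel at empirical quantile u inside the region
#' is replaced by the reference u-quantile. Pixels outside the region are
#' untouched.
#'
#' @param polar a `polar_frame`.
#' @param region one row of the `regions` frame from
#'   [detect_artifact_sectors()] (fields start_deg, end_deg, r0_px, r1_px).
#' @param reference_angles logical per-angle vector of clean reference
#'   angles; must span at least `min_reference_deg` degrees.
#' @param min_reference_deg minimum reference span (default 30).
#' @return the corrected `polar_frame`.
#' @export
histogram_match_sector <- function(polar, region, reference_angles,
                                   min_reference_deg = 30) {
  v <- polar$values
  n_angles <- nrow(v); n_radii <- ncol(v)
  step <- polar$angular_step_deg
  ang_deg <- (seq_len(n_angles) - 1) * step
  span <- region$end_deg - region$start_deg
  in_region <- ang_in_span(ang_deg, (region$start_deg + span / 2) %% 360, span)
  if (sum(reference_angles) * step < min_reference_deg) {
    stop("insufficient clean reference: need >= ", min_reference_deg,
         " degrees")
  }
  cols <- max(1, round(region$r0_px / polar$radial_step_px)):
    min(n_radii, round(region$r1_px / polar$radial_step_px))
  ref <- as.vector(v[reference_angles, cols])
  if (length(ref) == 0) stop("empty reference")
  reg <- v[in_region, cols]
  u <- (rank(reg, ties.method = "average") - 0.5) / length(reg)
  v[in_region, cols] <- stats::quantile(ref, u, names = FALSE, type = 7)
  polar$values <- v
  polar
}

#' Correct the effect of artifacts on one frame
#'
#' Composition detect -> histogram match -> retransform. Only pixels inside
#' detected regions (plus a small angular feather) are modified; clean frames
#' are returned unchanged. Correcting an already-corrected frame is a
#' near-no-op.
#'
#' @param frame intensity matrix (0..255).
#' @param mask class-code matrix of the same frame (supplies the lumen for
#'   centering and the guidewire-shadow angles).
#' @param params [artifact_params()].
#' @return list: `frame` (corrected), `regions` (data.frame),
#'   `correction_applied`, `declined`.
#' @export
correct_frame <- function(frame, mask, params = artifact_params()) {
  center <- lumen_center(mask)
  polar <- to_polar(frame, center, n_angles = 360, radial_step_px = 1)
  prof <- polar_lumen_profile(mask, center, n_angles = 360,
                              n_radii = ncol(polar$values))
  det <- detect_artifact_sectors(polar, prof$r_in, prof$shadow, params)
  if (det$declined) {
    warning("artifact correction declined: frame too corrupted to correct")
  }
  if (det$declined || nrow(det$regions) == 0) {
    return(list(frame = frame, regions = det$regions,
                correction_applied = FALSE, declined = det$declined))
  }
  corrected <- polar
  for (i in seq_len(nrow(det$regions))) {
    ref <- profile_matched_reference(polar, det$regions[i, ],
                                     det$clean_angles, params)
    corrected <- histogram_match_sector(corrected, det$regions[i, ], ref,
                                        params$min_reference_deg)
  }
  resampled <- from_polar(corrected, dim(frame), fill = NA)

  h <- nrow(frame); w <- ncol(frame)
  xg <- matrix(rep(0:(w - 1), each = h), nrow = h)
  yg <- matrix(rep(0:(h - 1), times = w), nrow = h)
  dx <- xg - center[[1]]; dy <- yg - center[[2]]
  rr <- sqrt(dx^2 + dy^2)
  th <- (atan2(dy, dx) * 180 / pi) %% 360
  out <- frame
  for (i in seq_len(nrow(det$regions))) {
    reg <- det$regions[i, ]
    span <- reg$end_deg - reg$start_deg
    ctr <- (reg$start_deg + span / 2) %% 360
    # signed angular offset from region center, feathered outside the edges
    off <- abs(((th - ctr + 180) %% 360) - 180)
    wgt <- pmin(pmax((span / 2 + params$feather_deg - off) /
                       params$feather_deg, 0), 1)
    sel <- wgt > 0 & rr >= reg$r0_px & rr <= reg$r1_px & !is.na(resampled)
    out[sel] <- round(wgt[sel] * resampled[sel] + (1 - wgt[sel]) * out[sel])
  }
  out <- pmin(pmax(out, 0), 255)
  storage.mode(out) <- "integer"
  list(frame = out, regions = det$regions, correction_applied = TRUE,
       declined = FALSE)
}

#' Correct every frame of a pullback
#'
#' @param pullback an `oct_pullback`.
#' @param masks list of class-code matrices.
#' @param params [artifact_params()].
#' @return list: `pullback` (corrected), `regions` (per-frame list),
#'   `correction_applied` (logical per frame), `declined` (logical per frame).
#' @export
correct_pullback <- function(pullback, masks, params = artifact_params()) {
  out <- pullback
  regions <- vector("list", n_frames(pullback))
  applied <- logical(n_frames(pullback))
  declined <- logical(n_frames(pullback))
  for (i in seq_len(n_frames(pullback))) {
    res <- withCallingHandlers(
      correct_frame(get_frame(pullback, i), masks[[i]], params),
      warning = function(w) invokeRestart("muffleWarning")
    )
    out$frames[i, , ] <- res$frame
    regions[[i]] <- res$regions
    applied[i] <- res$correction_applied
    declined[i] <- res$declined
  }
  storage.mode(out$frames) <- "integer"
  list(pullback = out, regions = regions, correction_applied = applied,
       declined = declined)
}
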