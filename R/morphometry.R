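# Mask-based plaque morphometry: lumen area, lipid/calcium arcs,
# fibrous-cap thickness, lesion aggregation and high-risk flags.
#
# Angular quantities are measured on 1-degree wedges about the lumen
# centroid: an angle "sees" a tissue iff at least one pixel of that class
# falls inside its wedge between the lumen boundary and the frame edge.
# Radial positions are pixel-center distances from the centroid, so a
# boundary estimate is never below the true geometric boundary by more than
# a pixel and thickness estimates are one-sided (>= truth, within ~1 px).

#' Lumen area from a label mask
#'
#' Pixel-count area: (number of lumen pixels) x (pixel size in mm)^2.
#'
#' @param mask integer class-code matrix.
#' @param pixel_spacing_um microns per pixel.
#' @return area in mm^2.
#' @export
lumen_area <- function(mask, pixel_spacing_um) {
  n <- sum(mask == oct_classes()[["lumen"]])
  if (n == 0L) stop("unanalyzable frame: mask contains no lumen pixels")
  n * (pixel_spacing_um / 1000)^2
}

# per-pixel radius and angular bin about a center (0-based coords)
pixel_polar <- function(mask, center, n_angles) {
  h <- nrow(mask); w <- ncol(mask)
  xg <- matrix(rep(0:(w - 1), each = h), nrow = h)
  yg <- matrix(rep(0:(h - 1), times = w), nrow = h)
  dx <- xg - center[[1]]; dy <- yg - center[[2]]
  th <- (atan2(dy, dx) * 180 / pi) %% 360
  list(r = sqrt(dx^2 + dy^2),
       bin = pmin(floor(th / (360 / n_angles)), n_angles - 1) + 1L)
}

# longest circular run of TRUE in a logical vector, in bins
circular_max_run <- function(v) {
  n <- length(v)
  if (!any(v)) return(0L)
  if (all(v)) return(n)
  r <- rle(c(v, v))
  min(max(r$lengths[r$values]), n)
}

#' Angular arc subtended by a tissue class
#'
#' @param mask integer class-code matrix.
#' @param tissue `"lipid"` or `"calcium"`.
#' @param center lumen center `c(x,y)`; default the lumen centroid.
#' @param n_angles angular bins (default 360).
#' @return list: `arc_total_deg`, `arc_max_deg` (longest contiguous run,
#'   wrap-around joined), `presence` (logical per-angle vector).
#' @export
tissue_arc <- function(mask, tissue = c("lipid", "calcium"), center = NULL,
                       n_angles = 360) {
  tissue <- match.arg(tissue)
  if (is.null(center)) center <- lumen_center(mask)
  code <- oct_classes()[[tissue]]
  sel <- mask == code
  presence <- rep(FALSE, n_angles)
  if (any(sel)) {
    pp <- pixel_polar(mask, center, n_angles)
    presence[unique(pp$bin[sel])] <- TRUE
  }
  width <- 360 / n_angles
  list(arc_total_deg = sum(presence) * width,
       arc_max_deg = circular_max_run(presence) * width,
       presence = presence)
}

#' Fibrous-cap thickness over lipid
#'
#' At each angle where lipid is present behind the lumen: the radial distance
#' from the outermost lumen pixel to the innermost lipid pixel in that wedge,
#' in microns. Angles whose wedge crosses guidewire shadow are excluded.
#' Undefined angles are NA; if no angle is defined, `fct_min_um` and
#' `fct_mean_um` are NA (never 0).
#'
#' If the mask carries a fibrous-cap class, its median radial extent is used
#' as a consistency check: a discrepancy beyond 2 px raises a warning.
#'
#' @param mask integer class-code matrix.
#' @param center lumen center; default the lumen centroid.
#' @param pixel_spacing_um microns per pixel.
#' @param n_angles angular bins (default 360).
#' @return list: `fct_per_angle_um` (length `n_angles`, NA where undefined),
#'   `fct_min_um`, `fct_mean_um`.
#' @export
fibrous_cap_thickness <- function(mask, center = NULL, pixel_spacing_um,
                                  n_angles = 360) {
  if (is.null(center)) center <- lumen_center(mask)
  cls <- oct_classes()
  pp <- pixel_polar(mask, center, n_angles)
  fct <- rep(NA_real_, n_angles)

  lum <- mask == cls[["lumen"]]
  lip <- mask == cls[["lipid"]]
  if (any(lip) && any(lum)) {
    max_lum <- rep(-Inf, n_angles)
    agg <- tapply(pp$r[lum], pp$bin[lum], max)
    max_lum[as.integer(names(agg))] <- agg
    min_lip <- rep(Inf, n_angles)
    agg <- tapply(pp$r[lip], pp$bin[lip], min)
    min_lip[as.integer(names(agg))] <- agg
    shadowed <- rep(FALSE, n_angles)
    sh <- mask == cls[["shadow"]]
    if (any(sh)) shadowed[unique(pp$bin[sh])] <- TRUE
    ok <- is.finite(max_lum) & is.finite(min_lip) & !shadowed &
      min_lip > max_lum
    fct[ok] <- (min_lip[ok] - max_lum[ok]) * pixel_spacing_um

    # consistency check against an explicit cap label, when present
    cap <- mask == cls[["cap"]]
    if (any(cap) && any(ok)) {
      min_cap <- tapply(pp$r[cap], pp$bin[cap], min)
      max_cap <- tapply(pp$r[cap], pp$bin[cap], max)
      lab <- (max_cap - min_cap + 1)
      bins <- as.integer(names(min_cap))
      both <- bins[ok[bins]]
      if (length(both) > 0) {
        ray <- fct[both] / pixel_spacing_um
        labv <- lab[match(both, bins)]
        if (abs(stats::median(ray) - stats::median(labv)) > 2) {
          warning("cap-label thickness and lumen-to-lipid distance disagree by > 2 px")
        }
      }
    }
  }
  defined <- !is.na(fct)
  list(fct_per_angle_um = fct,
       fct_min_um = if (any(defined)) min(fct[defined]) else NA_real_,
       fct_mean_um = if (any(defined)) mean(fct[defined]) else NA_real_)
}

#' Measure one frame
#'
#' @param mask integer class-code matrix.
#' @param pixel_spacing_um microns per pixel.
#' @param frame_index index recorded in the output row.
#' @param analyzable FALSE for frames inside a guide catheter or stent; such
#'   frames contribute no measurements.
#' @param n_angles angular bins.
#' @return one-row data.frame of frame measurements.
#' @export
measure_frame <- function(mask, pixel_spacing_um, frame_index = 1L,
                          analyzable = TRUE, n_angles = 360) {
  if (!analyzable) {
    return(data.frame(frame_index = frame_index, lumen_area_mm2 = NA_real_,
                      lipid_arc_deg_total = NA_real_,
                      lipid_arc_deg_max = NA_real_,
                      calcium_arc_deg_total = NA_real_,
                      calcium_arc_deg_max = NA_real_,
                      fct_min_um = NA_real_, fct_mean_um = NA_real_,
                      analyzable = FALSE))
  }
  center <- lumen_center(mask)
  la <- lumen_area(mask, pixel_spacing_um)
  lip <- tissue_arc(mask, "lipid", center, n_angles)
  cal <- tissue_arc(mask, "calcium", center, n_angles)
  fct <- fibrous_cap_thickness(mask, center, pixel_spacing_um, n_angles)
  data.frame(frame_index = frame_index, lumen_area_mm2 = la,
             lipid_arc_deg_total = lip$arc_total_deg,
             lipid_arc_deg_max = lip$arc_max_deg,
             calcium_arc_deg_total = cal$arc_total_deg,
             calcium_arc_deg_max = cal$arc_max_deg,
             fct_min_um = fct$fct_min_um, fct_mean_um = fct$fct_mean_um,
             analyzable = TRUE)
}

#' Measure every analyzable frame of a pullback
#'
#' Frames flagged `in_guide_catheter` or `in_stent` are carried through as
#' unanalyzable rows (all-NA measurements) and never contribute downstream.
#'
#' @param pullback an `oct_pullback` (supplies calibration and flags).
#' @param masks list of class-code matrices, one per frame.
#' @param n_angles angular bins.
#' @return data.frame with one row per frame.
#' @export
measure_pullback <- function(pullback, masks, n_angles = 360) {
  stopifnot(length(masks) == n_frames(pullback))
  gated <- pullback$frame_flags$in_guide_catheter |
    pullback$frame_flags$in_stent
  rows <- lapply(seq_along(masks), function(i) {
    measure_frame(masks[[i]], pullback$pixel_spacing_um, frame_index = i,
                  analyzable = !gated[i], n_angles = n_angles)
  })
  do.call(rbind, rows)
}

#' Group plaque-bearing frames into lesions
#'
#' A lesion is a maximal run of analyzable frames carrying any plaque
#' (lipid or calcium arc > 0), bridging plaque-free gaps of at most
#' `gap_tolerance_frames` frames.
#'
#' @param frame_measurements data.frame from [measure_pullback()].
#' @param gap_tolerance_frames gap bridged within one lesion (default 2).
#' @param min_frames minimum lesion length in frames.
#' @return data.frame, one row per lesion: `first_frame`, `last_frame`,
#'   `mla_mm2`, `max_lipid_arc_deg`, `fct_min_um` (minimum over frames),
#'   `fct_mean_um` (mean of per-frame minima).
#' @export
segment_lesions <- function(frame_measurements, gap_tolerance_frames = 2,
                            min_frames = 1) {
  fm <- frame_measurements
  plaque <- fm$analyzable &
    ((!is.na(fm$lipid_arc_deg_total) & fm$lipid_arc_deg_total > 0) |
       (!is.na(fm$calcium_arc_deg_total) & fm$calcium_arc_deg_total > 0))
  idx <- fm$frame_index[plaque]
  empty <- data.frame(first_frame = integer(), last_frame = integer(),
                      mla_mm2 = numeric(), max_lipid_arc_deg = numeric(),
                      fct_min_um = numeric(), fct_mean_um = numeric())
  if (length(idx) == 0) return(empty)
  idx <- sort(idx)
  brk <- which(diff(idx) > gap_tolerance_frames + 1)
  starts <- c(idx[1], idx[brk + 1])
  ends <- c(idx[brk], idx[length(idx)])
  out <- list()
  for (k in seq_along(starts)) {
    member <- fm[fm$frame_index >= starts[k] & fm$frame_index <= ends[k] &
                   fm$analyzable, , drop = FALSE]
    if (nrow(member) < min_frames) next
    fdef <- member$fct_min_um[!is.na(member$fct_min_um)]
    out[[length(out) + 1]] <- data.frame(
      first_frame = starts[k], last_frame = ends[k],
      mla_mm2 = min(member$lumen_area_mm2, na.rm = TRUE),
      max_lipid_arc_deg = max(c(member$lipid_arc_deg_max, 0), na.rm = TRUE),
      fct_min_um = if (length(fdef)) min(fdef) else NA_real_,
      fct_mean_um = if (length(fdef)) mean(fdef) else NA_real_
    )
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' High-risk plaque flags for a lesion
#'
#' Strict threshold comparisons, exactly as the criteria are printed:
#' minimum lumen area < 3.5 mm^2, maximal lipid arc > 180 degrees, minimum
#' fibrous-cap thickness < 75 um. An undefined FCT yields `fct_lt_75 = FALSE`
#' (thinness cannot be asserted without a cap measurement).
#'
#' @param lesion one-row data.frame from [segment_lesions()].
#' @return list of logicals: `mla_lt_3_5`, `lipid_arc_gt_180`, `fct_lt_75`.
#' @export
risk_flags <- function(lesion) {
  list(
    mla_lt_3_5 = isTRUE(lesion$mla_mm2 < 3.5),
    lipid_arc_gt_180 = isTRUE(lesion$max_lipid_arc_deg > 180),
    fct_lt_75 = isTRUE(!is.na(lesion$fct_min_um) && lesion$fct_min_um < 75)
  )
}
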