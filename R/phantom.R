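# Synthetic pullback phantoms with analytic ground truth.
#
# The generator states a simple but OCT-like world: an annular bright vessel
# wall around a dark lumen (circular, elliptic or smoothly perturbed), lipid
# pools as low-signal diffuse-border regions behind a brighter cap band,
# calcium as low-signal sharp-border regions, guidewire shadow as a near-zero
# wedge with a bright leading reflector, and smoothed multiplicative gamma
# speckle. Every geometric quantity the morphometry module measures is known
# in closed form from the spec.

#' Describe a synthetic phantom pullback
#'
#' @param n_frames number of frames.
#' @param frame_size square frame side in pixels (default 512).
#' @param pixel_spacing_um microns per pixel (default 10, so micron
#'   thresholds land on integer pixel counts).
#' @param lumen list: `shape` ("circle", "ellipse", "perturbed"), `radius_px`,
#'   `eccentricity` (minor/major axis ratio, ellipse only), `roughness`
#'   (relative amplitude of the low-order boundary perturbation).
#' @param wall_thickness_px thickness of the bright wall annulus.
#' @param plaques list of plaques, each a list with `frame_interval`
#'   (`c(first,last)`, 1-based inclusive), `tissue` ("lipid" or "calcium"),
#'   `arc_center_deg`, `arc_span_deg`, `cap_thickness_px` (for lipid: fibrous
#'   cap; for calcium: stand-off of the deposit from the lumen), `depth_px`.
#' @param artifacts list of artifacts rendered into the frames and masks,
#'   each a list with `frame_interval`, `kind` ("shadow"), and
#'   `angular_interval_deg` (`c(start,end)` degrees). Intensity-only
#'   corruptions (bubble/dropout) are applied by [phantom_corrupt()] instead.
#' @param speckle list: `enabled`, `grain_px`, `variance`.
#' @param stent_frames,catheter_frames frame indices flagged (and painted with
#'   class 9 / 8 pixels) as in-stent / in-guide-catheter.
#' @param patient_id identifier.
#' @param seed integer; all randomness flows from it.
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(n_frames = 3, frame_size = 512, pixel_spacing_um = 10,
                         lumen = list(shape = "circle", radius_px = 120,
                                      eccentricity = 0.75, roughness = 0.06),
                         wall_thickness_px = 80,
                         plaques = list(list(frame_interval = c(1, n_frames),
                                             tissue = "lipid",
                                             arc_center_deg = 90,
                                             arc_span_deg = 120,
                                             cap_thickness_px = 6,
                                             depth_px = 40)),
                         artifacts = list(),
                         speckle = list(enabled = TRUE, grain_px = 4,
                                        variance = 0.05),
                         stent_frames = integer(), catheter_frames = integer(),
                         patient_id = "phantom", seed = 1) {
  lumen <- utils::modifyList(
    list(shape = "circle", radius_px = 120, eccentricity = 0.75,
         roughness = 0.06), lumen)
  speckle <- utils::modifyList(
    list(enabled = TRUE, grain_px = 4, variance = 0.05), speckle)
  stopifnot(n_frames >= 1, frame_size >= 32, pixel_spacing_um > 0,
            lumen$radius_px > 0, wall_thickness_px > 0)
  if (!lumen$shape %in% c("circle", "ellipse", "perturbed")) {
    stop("unknown lumen shape: ", lumen$shape)
  }
  for (p in plaques) {
    stopifnot(p$tissue %in% c("lipid", "calcium"))
    if (!(p$arc_span_deg > 0 && p$arc_span_deg <= 360)) {
      stop("arc_span_deg must be in (0, 360]")
    }
    if (p$tissue == "lipid" && p$cap_thickness_px < 1) {
      stop("lipid plaques need cap_thickness_px >= 1")
    }
    if (p$cap_thickness_px + p$depth_px > wall_thickness_px) {
      stop("invalid spec: plaque deeper than wall (cap + depth > wall thickness)")
    }
  }
  for (a in artifacts) {
    if (!identical(a$kind, "shadow")) {
      stop("generate-time artifacts must be kind 'shadow'; use phantom_corrupt() for bubble/dropout")
    }
  }
  structure(list(n_frames = n_frames, frame_size = frame_size,
                 pixel_spacing_um = pixel_spacing_um, lumen = lumen,
                 wall_thickness_px = wall_thickness_px, plaques = plaques,
                 artifacts = artifacts, speckle = speckle,
                 stent_frames = as.integer(stent_frames),
                 catheter_frames = as.integer(catheter_frames),
                 patient_id = patient_id, seed = seed),
            class = "phantom_spec")
}

# --- circular interval algebra (degrees, [start, end) on the circle) -------

# normalize to rows [s, e) with 0 <= s < e <= 360, splitting wrap-arounds
norm_intervals <- function(iv) {
  if (length(iv) == 0 || nrow(iv) == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1] %% 360
    len <- iv[i, 2] - iv[i, 1]
    stopifnot(len >= 0)
    len <- min(len, 360)
    e <- s + len
    if (e <= 360) {
      out <- rbind(out, c(s, e))
    } else {
      out <- rbind(out, c(s, 360), c(0, e - 360))
    }
  }
  out[out[, 2] > out[, 1], , drop = FALSE]
}

# merge overlapping/touching normalized intervals
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[i, 1] <= out[last, 2] + 1e-9) {
      out[last, 2] <- max(out[last, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

interval_total <- function(iv) {
  m <- merge_intervals(norm_intervals(iv))
  if (nrow(m) == 0) 0 else sum(m[, 2] - m[, 1])
}

# longest contiguous run on the circle (joins a run straddling 0/360)
interval_max_run <- function(iv) {
  m <- merge_intervals(norm_intervals(iv))
  if (nrow(m) == 0) return(0)
  lens <- m[, 2] - m[, 1]
  if (sum(lens) >= 360 - 1e-9) return(360)
  if (nrow(m) > 1 && m[1, 1] <= 1e-9 && m[nrow(m), 2] >= 360 - 1e-9) {
    joined <- lens[1] + lens[nrow(m)]
    lens <- c(lens[-c(1, nrow(m))], joined)
  }
  max(lens)
}

# a minus b, both normalized
diff_intervals <- function(a, b) {
  a <- merge_intervals(norm_intervals(a))
  b <- merge_intervals(norm_intervals(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(a))) {
    segs <- a[i, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      nxt <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1]; e <- segs[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= s || bs >= e) {
          nxt <- rbind(nxt, c(s, e))
        } else {
          if (bs > s) nxt <- rbind(nxt, c(s, bs))
          if (be < e) nxt <- rbind(nxt, c(be, e))
        }
      }
      segs <- nxt
      if (nrow(segs) == 0) break
    }
    out <- rbind(out, segs)
  }
  out
}

# angular membership test, wrap-aware: theta in [center - span/2, center + span/2)
ang_in_span <- function(theta_deg, center, span) {
  ((theta_deg - (center - span / 2)) %% 360) < span
}

frame_in_interval <- function(i, interval) {
  i >= interval[1] && i <= interval[2]
}

# smoothed multiplicative gamma speckle field, mean 1
speckle_field <- function(h, w, grain_px, variance) {
  gh <- ceiling(h / grain_px) + 2
  gw <- ceiling(w / grain_px) + 2
  shape <- 1 / variance
  coarse <- matrix(stats::rgamma(gh * gw, shape = shape, scale = 1 / shape),
                   gh, gw)
  xg <- rep((0:(w - 1)) / grain_px, each = h)
  yg <- rep((0:(h - 1)) / grain_px, times = w)
  matrix(bilinear_sample(coarse, xg, yg, fill = 1), h, w)
}

# lumen boundary radius as a function of angle (degrees), plus closed-form area
lumen_geometry <- function(lumen, frame_idx, coeffs = NULL) {
  R0 <- lumen$radius_px
  if (lumen$shape == "circle") {
    list(radius_fun = function(theta) rep(R0, length(theta)),
         area_px2 = pi * R0^2)
  } else if (lumen$shape == "ellipse") {
    a <- R0; b <- R0 * lumen$eccentricity
    list(radius_fun = function(theta) {
      t <- theta * pi / 180
      a * b / sqrt((b * cos(t))^2 + (a * sin(t))^2)
    }, area_px2 = pi * a * b)
  } else {
    # low-order sinusoidal perturbation: R(theta) = R0 (1 + sum a_k sin(k t + phi_k))
    ak <- coeffs$ak; phik <- coeffs$phik; ks <- coeffs$ks
    list(radius_fun = function(theta) {
      t <- theta * pi / 180
      mod <- rep(1, length(t))
      for (j in seq_along(ks)) mod <- mod + ak[j] * sin(ks[j] * t + phik[j])
      R0 * mod
    }, area_px2 = pi * R0^2 * (1 + sum(ak^2) / 2))
  }
}

#' Generate a phantom pullback and its ground truth
#'
#' Deterministic given `spec$seed`. Returns the rendered pullback together
#' with per-frame label masks and the analytic measurements implied by the
#' spec (lumen area; lipid/calcium total and maximal contiguous arcs after
#' subtracting any guidewire-shadow wedge; fibrous-cap thickness).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `pullback` (an `oct_pullback`), `truth` (list:
#'   `masks` — list of class-code matrices; `measurements` — data.frame of
#'   analytic per-frame values).
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, phantom_generate_impl(spec))
}

phantom_generate_impl <- function(spec) {
  n <- spec$n_frames; sz <- spec$frame_size
  cls <- oct_classes()
  cx <- (sz - 1) / 2; cy <- (sz - 1) / 2
  xg <- matrix(rep(0:(sz - 1), each = sz), nrow = sz)   # x constant per column
  yg <- matrix(rep(0:(sz - 1), times = sz), nrow = sz)
  dx <- xg - cx; dy <- yg - cy
  rr <- sqrt(dx^2 + dy^2)
  th <- (atan2(dy, dx) * 180 / pi) %% 360

  base_int <- c(background = 4, lumen = 8, wall = 170, cap = 200,
                lipid = 70, calcium = 45)
  frames <- vector("list", n)
  masks <- vector("list", n)
  meas <- vector("list", n)

  for (f in seq_len(n)) {
    coeffs <- NULL
    if (spec$lumen$shape == "perturbed") {
      ks <- 2:4
      coeffs <- list(
        ks = ks,
        ak = spec$lumen$roughness * stats::runif(length(ks), 0.4, 1) / ks,
        phik = stats::runif(length(ks), 0, 2 * pi)
      )
    }
    geom <- lumen_geometry(spec$lumen, f, coeffs)
    Rb <- matrix(geom$radius_fun(as.vector(th)), sz, sz)
    wall_out <- Rb + spec$wall_thickness_px

    mask <- matrix(cls[["background"]], sz, sz)
    mask[rr < wall_out] <- cls[["wall"]]
    mask[rr < Rb] <- cls[["lumen"]]
    img <- matrix(base_int[["background"]], sz, sz)
    img[rr < wall_out] <- base_int[["wall"]]
    img[rr < Rb] <- base_int[["lumen"]]

    lipid_iv <- matrix(numeric(0), ncol = 2)
    calcium_iv <- matrix(numeric(0), ncol = 2)
    lipid_caps <- numeric(0)       # cap thickness of lipid plaques on frame
    lipid_cap_iv <- list()

    for (p in spec$plaques) {
      if (!frame_in_interval(f, p$frame_interval)) next
      span_sel <- ang_in_span(th, p$arc_center_deg, p$arc_span_deg)
      inner <- Rb + p$cap_thickness_px
      outer <- inner + p$depth_px
      body <- span_sel & rr >= inner & rr < outer
      iv <- cbind(p$arc_center_deg - p$arc_span_deg / 2,
                  p$arc_center_deg + p$arc_span_deg / 2)
      if (p$tissue == "lipid") {
        capband <- span_sel & rr >= Rb & rr < inner
        mask[capband] <- cls[["cap"]]
        mask[body] <- cls[["lipid"]]
        img[capband] <- base_int[["cap"]]
        # diffuse radial border: blend wall -> lipid over ~4 px, plus a
        # ~3 degree angular feather
        blur <- 4
        sr <- pmin(pmax((rr - inner) / blur, 0), 1) *
          pmin(pmax((outer - rr) / blur, 0), 1)
        ang_off <- pmin(((th - (p$arc_center_deg - p$arc_span_deg / 2)) %% 360),
                        (((p$arc_center_deg + p$arc_span_deg / 2) - th) %% 360))
        sa <- pmin(ang_off / 3, 1)
        s <- sr * sa
        sel <- span_sel & rr >= inner - blur & rr < outer + blur &
          rr >= Rb & rr < wall_out
        img[sel] <- img[sel] * (1 - s[sel]) + base_int[["lipid"]] * s[sel]
        lipid_iv <- rbind(lipid_iv, iv)
        lipid_caps <- c(lipid_caps, p$cap_thickness_px)
        lipid_cap_iv <- c(lipid_cap_iv, list(iv))
      } else {
        mask[body] <- cls[["calcium"]]
        img[body] <- base_int[["calcium"]]   # sharp border
        calcium_iv <- rbind(calcium_iv, iv)
      }
    }

    # guidewire shadow wedges: near-zero signal beyond a bright reflector
    shadow_iv <- matrix(numeric(0), ncol = 2)
    for (a in spec$artifacts) {
      if (!frame_in_interval(f, a$frame_interval)) next
      s0 <- a$angular_interval_deg[1]; s1 <- a$angular_interval_deg[2]
      span <- (s1 - s0) %% 360
      if (span == 0) span <- 360
      ctr <- (s0 + span / 2) %% 360
      wedge <- ang_in_span(th, ctr, span) & rr >= Rb
      mask[wedge] <- cls[["shadow"]]
      img[wedge] <- img[wedge] * 0.02
      # leading reflector: small bright blob at the lumen boundary
      Rc <- geom$radius_fun(ctr)
      rx <- cx + Rc * cos(ctr * pi / 180)
      ry <- cy + Rc * sin(ctr * pi / 180)
      blob <- (xg - rx)^2 + (yg - ry)^2 <= 3^2
      img[blob] <- 255
      shadow_iv <- rbind(shadow_iv, c(s0, s0 + span))
    }

    # stent struts / guide catheter pixels for gating tests
    if (f %in% spec$stent_frames) {
      strut <- rr >= Rb - 4 & rr < Rb & (round(th) %% 30) < 4
      mask[strut] <- cls[["stent"]]
      img[strut] <- 240
    }
    if (f %in% spec$catheter_frames) {
      cath <- rr < 12
      mask[cath] <- cls[["catheter"]]
      img[cath] <- 220
    }

    if (isTRUE(spec$speckle$enabled)) {
      img <- img * speckle_field(sz, sz, spec$speckle$grain_px,
                                 spec$speckle$variance)
    }
    img <- round(pmin(pmax(img, 0), 255))

    # analytic truth (shadow wedges hide tissue from any angular measurement)
    px_mm <- spec$pixel_spacing_um / 1000
    lipid_vis <- diff_intervals(lipid_iv, shadow_iv)
    calcium_vis <- diff_intervals(calcium_iv, shadow_iv)
    fct_vals <- c()
    fct_spans <- c()
    for (j in seq_along(lipid_caps)) {
      vis <- diff_intervals(lipid_cap_iv[[j]], shadow_iv)
      len <- interval_total(vis)
      if (len > 0) {
        fct_vals <- c(fct_vals, lipid_caps[j] * spec$pixel_spacing_um)
        fct_spans <- c(fct_spans, len)
      }
    }
    meas[[f]] <- data.frame(
      frame_index = f,
      lumen_area_mm2 = geom$area_px2 * px_mm^2,
      lipid_arc_deg_total = interval_total(lipid_vis),
      lipid_arc_deg_max = interval_max_run(lipid_vis),
      calcium_arc_deg_total = interval_total(calcium_vis),
      calcium_arc_deg_max = interval_max_run(calcium_vis),
      fct_min_um = if (length(fct_vals)) min(fct_vals) else NA_real_,
      fct_mean_um = if (length(fct_vals)) {
        sum(fct_vals * fct_spans) / sum(fct_spans)
      } else NA_real_
    )
    frames[[f]] <- img
    masks[[f]] <- mask
  }

  flags <- data.frame(
    in_guide_catheter = seq_len(n) %in% spec$catheter_frames,
    in_stent = seq_len(n) %in% spec$stent_frames
  )
  pb <- oct_pullback(frames, spec$pixel_spacing_um, frame_spacing_mm = 0.2,
                     frame_flags = flags, patient_id = spec$patient_id)
  list(pullback = pb,
       truth = list(masks = masks, measurements = do.call(rbind, meas),
                    spec = spec))
}

#' Corrupt a pullback with intensity artifacts
#'
#' Applies bubble / signal-dropout attenuation (multiplicative) or shadow
#' wedges (near-zeroing) to angular sectors, returning the corrupted pullback
#' together with the ground-truth artifact regions for detector validation.
#'
#' @param pullback an `oct_pullback`.
#' @param artifacts list of lists with `frame_interval`, `kind`
#'   ("bubble", "dropout", "shadow"), `angular_interval_deg` `c(start,end)`,
#'   `attenuation_factor` in (0,1) (ignored for shadow).
#' @param seed unused reserve for stochastic corruptions; kept for a stable
#'   call signature.
#' @param centers optional list of per-frame `c(x,y)` wedge centers; default
#'   is the frame center.
#' @return list with `pullback` (corrupted) and `regions` (data.frame:
#'   frame_index, start_deg, end_deg, r0_px, r1_px, kind).
#' @export
phantom_corrupt <- function(pullback, artifacts, seed = 1, centers = NULL) {
  frames <- pullback$frames
  d <- dim(frames)
  sz <- d[2]
  regions <- list()
  for (a in artifacts) {
    stopifnot(a$kind %in% c("bubble", "dropout", "shadow"))
    fac <- if (a$kind == "shadow") 0.02 else a$attenuation_factor
    stopifnot(fac > 0, fac < 1)
    s0 <- a$angular_interval_deg[1]; s1 <- a$angular_interval_deg[2]
    span <- (s1 - s0) %% 360
    if (span == 0) span <- 360
    ctr_ang <- (s0 + span / 2) %% 360
    fi <- max(1, a$frame_interval[1]):min(d[1], a$frame_interval[2])
    for (f in fi) {
      c0 <- if (is.null(centers)) c((sz - 1) / 2, (sz - 1) / 2) else centers[[f]]
      xg <- matrix(rep(0:(sz - 1), each = sz), nrow = sz)
      yg <- matrix(rep(0:(sz - 1), times = sz), nrow = sz)
      th <- (atan2(yg - c0[2], xg - c0[1]) * 180 / pi) %% 360
      wedge <- ang_in_span(th, ctr_ang, span)
      fr <- frames[f, , ]
      fr[wedge] <- round(fr[wedge] * fac)
      frames[f, , ] <- fr
      regions[[length(regions) + 1]] <- data.frame(
        frame_index = f, start_deg = s0 %% 360, end_deg = (s0 %% 360) + span,
        r0_px = 0, r1_px = Inf, kind = a$kind
      )
    }
  }
  out <- pullback
  out$frames <- frames
  storage.mode(out$frames) <- "integer"
  list(pullback = out,
       regions = if (length(regions)) do.call(rbind, regions) else
         data.frame(frame_index = integer(), start_deg = numeric(),
                    end_deg = numeric(), r0_px = numeric(), r1_px = numeric(),
                    kind = character()))
}
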