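test_that("lumen area matches analytic discs and ellipses within 1%", {
  m <- disc_mask(256, radius = 50)
  expect_equal(lumen_area(m, 10), pi * 0.5^2, tolerance = 0.01)
  e <- disc_mask(256, radius = 60, ry = 40)
  expect_equal(lumen_area(e, 10), pi * 0.6 * 0.4, tolerance = 0.01)
  expect_error(lumen_area(matrix(0L, 16, 16), 10), "no lumen")
  # pullback MLA and its flag threshold (strict <)
  areas <- c(4.0, 3.2, 5.1)
  expect_equal(min(areas), 3.2)
  expect_true(min(areas) < 3.5)
})

test_that("tissue arcs recover constructed sectors", {
  m <- annulus_mask(256, lipid = c(30, 150))
  a <- tissue_arc(m, "lipid")
  expect_equal(a$arc_total_deg, 120, tolerance = 2)
  expect_equal(a$arc_max_deg, 120, tolerance = 2)
  # two disjoint sectors: 60 and 90 degrees
  m2 <- annulus_mask(256, lipid = c(0, 60))
  g <- grid_polar(256)
  sel <- ((g$th - 120) %% 360) < 90 & g$r >= 66 & g$r < 96
  m2[sel] <- CLS[["lipid"]]
  a2 <- tissue_arc(m2, "lipid")
  expect_equal(a2$arc_total_deg, 150, tolerance = 2)
  expect_equal(a2$arc_max_deg, 90, tolerance = 2)
  # full annulus is exactly 360
  m3 <- annulus_mask(256, lipid = c(0, 360))
  expect_equal(tissue_arc(m3, "lipid")$arc_total_deg, 360)
  # sector straddling 0/360
  m4 <- annulus_mask(256, lipid = c(350, 380))
  a4 <- tissue_arc(m4, "lipid")
  expect_equal(a4$arc_max_deg, 30, tolerance = 2)
  expect_equal(a4$arc_max_deg, a4$arc_total_deg)
  # absent tissue
  a5 <- tissue_arc(annulus_mask(256), "calcium")
  expect_equal(a5$arc_total_deg, 0)
  expect_false(any(a5$presence))
})

test_that("arc_max agrees with a brute-force circular-run oracle", {
  set.seed(101)
  for (i in 1:200) {
    v <- runif(60) < runif(1, 0.1, 0.9)
    expect_identical(plaquekit:::circular_max_run(v), brute_max_run(v))
  }
})

test_that("fibrous cap thickness recovers constructed caps", {
  m <- annulus_mask(512, lumen_r = 120, lipid = c(30, 150), cap_px = 6)
  f <- fibrous_cap_thickness(m, pixel_spacing_um = 10)
  expect_equal(f$fct_min_um, 60, tolerance = 5)
  expect_equal(f$fct_mean_um, 60, tolerance = 8)
  # cap thickness varying linearly 5 -> 12 px across the sector
  cap_fun <- function(th) {
    u <- ((th - 30) %% 360) / 120
    ifelse(u <= 1, 5 + 7 * u, 6)
  }
  m2 <- annulus_mask(512, lumen_r = 120, lipid = c(30, 150),
                     cap_fun = cap_fun)
  f2 <- fibrous_cap_thickness(m2, pixel_spacing_um = 10)
  expect_equal(f2$fct_min_um, 50, tolerance = 5)
  # no lipid: undefined, not zero and not an error
  f3 <- fibrous_cap_thickness(annulus_mask(256), pixel_spacing_um = 10)
  expect_true(is.na(f3$fct_min_um))
  expect_true(is.na(f3$fct_mean_um))
  expect_true(all(is.na(f3$fct_per_angle_um)))
})

test_that("rays through guidewire shadow are excluded from FCT", {
  # thinnest cap (4 px) at 60-80 deg, shadowed; clean cap 8 px elsewhere
  cap_fun <- function(th) ifelse(((th - 60) %% 360) < 20, 4, 8)
  m <- annulus_mask(512, lumen_r = 120, lipid = c(30, 150),
                    cap_fun = cap_fun, shadow = c(55, 85))
  f <- fibrous_cap_thickness(m, pixel_spacing_um = 10)
  # brute force over unshadowed angles: thinnest visible cap is 8 px
  expect_equal(f$fct_min_um, 80, tolerance = 6)
  shadow_bins <- which(((0:359 - 55) %% 360) < 30)
  expect_true(all(is.na(f$fct_per_angle_um[shadow_bins])))
})

test_that("morphometry is rotation invariant and scales with calibration", {
  spec0 <- std_phantom(seed = 31, frame_size = 256)
  spec0$plaques[[1]]$depth_px <- 30
  spec0$wall_thickness_px <- 60
  spec0$lumen$radius_px <- 60
  base <- phantom_generate(spec0)
  m0 <- measure_frame(base$truth$masks[[1]], 10)
  for (rot in c(37, 181)) {
    spec1 <- spec0
    spec1$plaques[[1]]$arc_center_deg <- (90 + rot) %% 360
    rotg <- phantom_generate(spec1)
    m1 <- measure_frame(rotg$truth$masks[[1]], 10)
    expect_equal(m1$lipid_arc_deg_total, m0$lipid_arc_deg_total, tolerance = 1)
    expect_equal(m1$fct_min_um, m0$fct_min_um, tolerance = 10)
    expect_equal(m1$lumen_area_mm2, m0$lumen_area_mm2, tolerance = 1e-9)
  }
  # doubling the pixel spacing doubles FCT and quadruples areas
  mask <- base$truth$masks[[1]]
  a1 <- measure_frame(mask, 10); a2 <- measure_frame(mask, 20)
  expect_equal(a2$lumen_area_mm2, 4 * a1$lumen_area_mm2)
  expect_equal(a2$fct_min_um, 2 * a1$fct_min_um)
  expect_equal(a2$lipid_arc_deg_total, a1$lipid_arc_deg_total)
})

test_that("lesion segmentation bridges gaps and aggregates correctly", {
  mk <- function(idx, lipid, fct = NA, area = 4) {
    data.frame(frame_index = idx, lumen_area_mm2 = area,
               lipid_arc_deg_total = lipid, lipid_arc_deg_max = lipid,
               calcium_arc_deg_total = 0, calcium_arc_deg_max = 0,
               fct_min_um = fct, fct_mean_um = fct, analyzable = TRUE)
  }
  fm <- do.call(rbind, lapply(1:35, function(i) {
    mk(i, lipid = if ((i >= 10 && i <= 20) || (i >= 24 && i <= 30)) 90 else 0)
  }))
  les2 <- segment_lesions(fm, gap_tolerance_frames = 2)
  expect_equal(nrow(les2), 2)
  expect_equal(les2$first_frame, c(10, 24))
  expect_equal(les2$last_frame, c(20, 30))
  les4 <- segment_lesions(fm, gap_tolerance_frames = 4)
  expect_equal(nrow(les4), 1)
  expect_equal(c(les4$first_frame, les4$last_frame), c(10, 30))
  # per-frame FCT minima aggregate to lesion min and mean-of-minima
  fm2 <- rbind(mk(1, 90, fct = 80), mk(2, 90, fct = 60), mk(3, 90, fct = 90))
  l <- segment_lesions(fm2)
  expect_equal(l$fct_min_um, 60)
  expect_equal(l$fct_mean_um, mean(c(80, 60, 90)), tolerance = 1e-12)
  # plaque-free pullback
  expect_equal(nrow(segment_lesions(do.call(rbind,
    lapply(1:5, function(i) mk(i, 0))))), 0)
})

test_that("risk flags use strict printed thresholds", {
  l <- data.frame(mla_mm2 = 3.4, max_lipid_arc_deg = 190, fct_min_um = 70)
  expect_equal(unlist(risk_flags(l)),
               c(mla_lt_3_5 = TRUE, lipid_arc_gt_180 = TRUE, fct_lt_75 = TRUE))
  # boundary values are exclusive
  lb <- data.frame(mla_mm2 = 3.5, max_lipid_arc_deg = 180, fct_min_um = 75)
  expect_false(any(unlist(risk_flags(lb))))
  # undefined FCT cannot assert thinness
  lu <- data.frame(mla_mm2 = 3.0, max_lipid_arc_deg = 200,
                   fct_min_um = NA_real_)
  expect_false(risk_flags(lu)$fct_lt_75)
})

test_that("flagged frames never contribute to morphometry", {
  spec <- phantom_spec(n_frames = 3, frame_size = 192, seed = 12,
                       lumen = list(radius_px = 45), wall_thickness_px = 40,
                       plaques = list(list(frame_interval = c(1, 3),
                                           tissue = "lipid",
                                           arc_center_deg = 90,
                                           arc_span_deg = 100,
                                           cap_thickness_px = 5,
                                           depth_px = 25)),
                       stent_frames = 2)
  g <- phantom_generate(spec)
  fm <- measure_pullback(g$pullback, g$truth$masks)
  expect_false(fm$analyzable[2])
  expect_true(all(is.na(unlist(fm[2, c("lumen_area_mm2", "fct_min_um")]))))
  expect_true(all(fm$analyzable[c(1, 3)]))
})
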