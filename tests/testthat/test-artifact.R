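test_that("detection localizes a generated corruption (Jaccard >= 0.9)", {
  spec <- std_phantom(seed = 5)
  g <- phantom_generate(spec)
  mask <- g$truth$masks[[1]]
  cor <- phantom_corrupt(g$pullback,
                         list(list(frame_interval = c(1, 1), kind = "dropout",
                                   angular_interval_deg = c(200, 240),
                                   attenuation_factor = 0.3)))
  res <- correct_frame(get_frame(cor$pullback, 1), mask)
  expect_true(res$correction_applied)
  expect_equal(nrow(res$regions), 1)
  # angular Jaccard between detected and injected wedge
  det <- c(res$regions$start_deg, res$regions$end_deg)
  inter <- max(0, min(det[2], 240) - max(det[1], 200))
  union <- max(det[2], 240) - min(det[1], 200)
  expect_gte(inter / union, 0.9)
})

test_that("artifact-free phantoms yield no regions", {
  for (sd in c(5, 11, 42)) {
    spec <- phantom_spec(
      n_frames = 1, frame_size = 512, seed = sd,
      plaques = list(list(frame_interval = c(1, 1), tissue = "lipid",
                          arc_center_deg = 90, arc_span_deg = 120,
                          cap_thickness_px = 6, depth_px = 40),
                     list(frame_interval = c(1, 1), tissue = "calcium",
                          arc_center_deg = 260, arc_span_deg = 70,
                          cap_thickness_px = 4, depth_px = 35)))
    g <- phantom_generate(spec)
    res <- correct_frame(get_frame(g$pullback, 1), g$truth$masks[[1]])
    expect_false(res$correction_applied)
    expect_equal(nrow(res$regions), 0)
    expect_identical(res$frame, get_frame(g$pullback, 1))
  }
})

test_that("a fully corrupted frame declines correction with a warning", {
  spec <- std_phantom(seed = 2)
  g <- phantom_generate(spec)
  cor <- phantom_corrupt(g$pullback,
                         list(list(frame_interval = c(1, 1), kind = "dropout",
                                   angular_interval_deg = c(0, 360),
                                   attenuation_factor = 0.2)))
  expect_warning(
    res <- correct_frame(get_frame(cor$pullback, 1), g$truth$masks[[1]]),
    "declined"
  )
  expect_true(res$declined)
  expect_false(res$correction_applied)
  expect_identical(res$frame, get_frame(cor$pullback, 1))
})

test_that("quantile mapping is monotone, identity-preserving and exact", {
  set.seed(9)
  vals <- matrix(round(rgamma(360 * 120, shape = 20, scale = 8)), 360, 120)
  polar <- structure(list(values = vals, center = c(x = 0, y = 0),
                          radial_step_px = 1, angular_step_deg = 1),
                     class = "polar_frame")
  region <- data.frame(start_deg = 100, end_deg = 140, r0_px = 20,
                       r1_px = 100)
  ref_angles <- rep(TRUE, 360); ref_angles[101:140] <- FALSE
  # region already distributed as the reference: near-identity
  out <- histogram_match_sector(polar, region, ref_angles)
  sel <- 101:140
  expect_lt(mean(abs(out$values[sel, 20:100] - vals[sel, 20:100])), 1)
  # region scaled by 0.3: post-correction KS distance < 0.05
  dark <- polar
  dark$values[sel, ] <- dark$values[sel, ] * 0.3
  fixed <- histogram_match_sector(dark, region, ref_angles)
  ref_vals <- as.vector(vals[ref_angles, 20:100])
  reg_vals <- as.vector(fixed$values[sel, 20:100])
  ks_post <- suppressWarnings(stats::ks.test(reg_vals, ref_vals)$statistic)
  ks_pre <- suppressWarnings(
    stats::ks.test(as.vector(dark$values[sel, 20:100]), ref_vals)$statistic
  )
  expect_lt(ks_post, 0.05)
  expect_gt(ks_pre, 0.5)
  # monotone: input order implies output order
  xin <- as.vector(dark$values[sel, 20:100])
  xout <- as.vector(fixed$values[sel, 20:100])
  ord <- order(xin)
  expect_true(all(diff(xout[ord]) >= -1e-9))
  # constant region against constant reference maps to the constant
  cpol <- polar
  cpol$values[, ] <- 55
  cpol$values[sel, 20:100] <- 12
  cfix <- histogram_match_sector(cpol, region, ref_angles)
  expect_true(all(abs(cfix$values[sel, 20:100] - 55) < 1e-9))
  # empty / insufficient reference errors
  expect_error(histogram_match_sector(polar, region, rep(FALSE, 360)),
               "reference")
})

test_that("correction restores a darkened sector and is idempotent", {
  spec <- std_phantom(seed = 5)
  g <- phantom_generate(spec)
  orig <- get_frame(g$pullback, 1)
  mask <- g$truth$masks[[1]]
  cor <- phantom_corrupt(g$pullback,
                         list(list(frame_interval = c(1, 1), kind = "dropout",
                                   angular_interval_deg = c(200, 240),
                                   attenuation_factor = 0.3)))
  bad <- get_frame(cor$pullback, 1)
  res <- correct_frame(bad, mask)
  gp <- grid_polar(512)
  sel <- ((gp$th - 202) %% 360) < 36 & gp$r >= 125 & gp$r <= 195
  mae_pre <- mean(abs(bad[sel] - orig[sel]))
  mae_post <- mean(abs(res$frame[sel] - orig[sel]))
  expect_gte(1 - mae_post / mae_pre, 0.7)
  # pixels outside the region + 2 degree feather are bit-identical
  outside <- ((gp$th - 245) %% 360) < 310
  expect_identical(res$frame[outside], bad[outside])
  # second application changes MAE < 1 intensity level
  res2 <- correct_frame(res$frame, mask)
  expect_lt(mean(abs(res2$frame - res$frame)), 1)
})

test_that("correction reduces the downstream lipid-arc error", {
  spec <- std_phantom(seed = 9)       # lipid 30-150 deg
  g <- phantom_generate(spec)
  orig <- get_frame(g$pullback, 1)
  mask <- g$truth$masks[[1]]
  arc0 <- measure_frame(segment_frame_rules(orig), 10)$lipid_arc_deg_total
  cor <- phantom_corrupt(g$pullback,
                         list(list(frame_interval = c(1, 1), kind = "dropout",
                                   angular_interval_deg = c(60, 100),
                                   attenuation_factor = 0.3)))
  bad <- get_frame(cor$pullback, 1)
  arc_bad <- measure_frame(segment_frame_rules(bad), 10)$lipid_arc_deg_total
  res <- correct_frame(bad, mask)
  arc_fix <- measure_frame(segment_frame_rules(res$frame), 10)$lipid_arc_deg_total
  err_bad <- abs(arc_bad - arc0)
  err_fix <- abs(arc_fix - arc0)
  expect_lte(err_fix, 5)
  expect_gte(err_bad, err_fix)
})
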