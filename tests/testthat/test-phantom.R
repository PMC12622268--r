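test_that("generation is deterministic and validates its spec", {
  spec <- std_phantom(seed = 8, frame_size = 128)
  spec$lumen$radius_px <- 30; spec$wall_thickness_px <- 50
  g1 <- phantom_generate(spec)
  g2 <- phantom_generate(spec)
  expect_identical(g1$pullback$frames, g2$pullback$frames)
  expect_identical(g1$truth$masks, g2$truth$masks)
  # plaque deeper than the wall is rejected
  expect_error(phantom_spec(plaques = list(list(frame_interval = c(1, 1),
                                                tissue = "lipid",
                                                arc_center_deg = 0,
                                                arc_span_deg = 90,
                                                cap_thickness_px = 10,
                                                depth_px = 200))),
               "deeper than wall")
  expect_error(phantom_spec(plaques = list(list(frame_interval = c(1, 1),
                                                tissue = "lipid",
                                                arc_center_deg = 0,
                                                arc_span_deg = 400,
                                                cap_thickness_px = 5,
                                                depth_px = 20))),
               "arc_span")
})

test_that("a plaque-free phantom measures clean and classifies NORMAL", {
  spec <- phantom_spec(n_frames = 2, frame_size = 192, seed = 6,
                       lumen = list(radius_px = 45), wall_thickness_px = 40,
                       plaques = list())
  g <- phantom_generate(spec)
  fm <- measure_pullback(g$pullback, g$truth$masks)
  expect_true(all(fm$lipid_arc_deg_total == 0))
  expect_true(all(fm$calcium_arc_deg_total == 0))
  expect_true(all(is.na(fm$fct_min_um)))
  classes <- vapply(seq_len(nrow(fm)), function(i) {
    classify_frame(fm[i, ])
  }, "")
  expect_true(all(classes == "NORMAL"))
})

test_that("pipeline morphometry on truth masks reproduces analytic truth", {
  # scaled-down version of the 100-spec acceptance sweep
  set.seed(77)
  for (i in 1:12) {
    shape <- sample(c("circle", "ellipse", "perturbed"), 1)
    spec <- phantom_spec(
      n_frames = 1, frame_size = 256, seed = 1000 + i,
      lumen = list(shape = shape, radius_px = runif(1, 45, 70),
                   eccentricity = runif(1, 0.75, 0.95),
                   roughness = runif(1, 0.02, 0.07)),
      wall_thickness_px = 50,
      plaques = list(list(frame_interval = c(1, 1), tissue = "lipid",
                          arc_center_deg = runif(1, 0, 360),
                          arc_span_deg = runif(1, 60, 200),
                          cap_thickness_px = sample(4:12, 1),
                          depth_px = sample(20:35, 1)))
    )
    g <- phantom_generate(spec)
    truth <- g$truth$measurements
    # thin caps in partially covered edge wedges can trip the informational
    # cap-consistency warning; the measurements themselves are asserted
    fm <- suppressWarnings(measure_pullback(g$pullback, g$truth$masks))
    expect_equal(fm$lipid_arc_deg_total, truth$lipid_arc_deg_total,
                 tolerance = 2.5 / max(truth$lipid_arc_deg_total, 1))
    expect_lt(abs(fm$fct_min_um - truth$fct_min_um), 10)
    expect_equal(fm$lumen_area_mm2, truth$lumen_area_mm2, tolerance = 0.01)
  }
})

test_that("corrupt applies wedges and returns ground-truth regions", {
  spec <- std_phantom(seed = 15, frame_size = 192)
  spec$lumen$radius_px <- 45; spec$wall_thickness_px <- 47
  g <- phantom_generate(spec)
  # empty artifact list is the identity
  same <- phantom_corrupt(g$pullback, list())
  expect_identical(same$pullback$frames, g$pullback$frames)
  expect_equal(nrow(same$regions), 0)
  # attenuation wedge
  cor <- phantom_corrupt(g$pullback,
                         list(list(frame_interval = c(1, 1), kind = "dropout",
                                   angular_interval_deg = c(200, 240),
                                   attenuation_factor = 0.3)))
  expect_equal(cor$regions$start_deg, 200)
  expect_equal(cor$regions$end_deg, 240)
  gp <- grid_polar(192)
  inside <- ((gp$th - 200) %% 360) < 40
  f0 <- get_frame(g$pullback, 1); f1 <- get_frame(cor$pullback, 1)
  expect_true(all(f1[inside] <= pmax(round(f0[inside] * 0.3), 1)))
  expect_identical(f1[!inside], f0[!inside])
  # shadow wedge zeroes to <= 5 intensity levels
  sh <- phantom_corrupt(g$pullback,
                        list(list(frame_interval = c(1, 1), kind = "shadow",
                                  angular_interval_deg = c(10, 40))))
  f2 <- get_frame(sh$pullback, 1)
  wedge <- ((gp$th - 10) %% 360) < 30
  expect_true(all(f2[wedge] <= 5))
})

test_that("shadow wedges hide tissue from the analytic truth", {
  spec <- phantom_spec(
    n_frames = 1, frame_size = 256, seed = 3,
    lumen = list(radius_px = 60), wall_thickness_px = 60,
    plaques = list(list(frame_interval = c(1, 1), tissue = "lipid",
                        arc_center_deg = 90, arc_span_deg = 120,
                        cap_thickness_px = 6, depth_px = 40)),
    artifacts = list(list(frame_interval = c(1, 1), kind = "shadow",
                          angular_interval_deg = c(80, 100)))
  )
  g <- phantom_generate(spec)
  truth <- g$truth$measurements
  expect_equal(truth$lipid_arc_deg_total, 100)   # 120 minus the 20 deg wedge
  expect_equal(truth$lipid_arc_deg_max, 50)      # two 50 deg visible pieces
  fm <- measure_pullback(g$pullback, g$truth$masks)
  expect_equal(fm$lipid_arc_deg_total, 100, tolerance = 0.03)
  expect_equal(fm$lipid_arc_deg_max, 50, tolerance = 0.06)
})
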