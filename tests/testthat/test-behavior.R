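test_that("singing requires a wing angle strictly above 30 degrees", {
  expect_true(detect_singing(synth_pose(theta_left = 35, theta_right = 5)))
  expect_false(detect_singing(synth_pose(theta_left = 30, theta_right = 30)))
  expect_false(detect_singing(synth_pose(theta_left = 0, theta_right = 0)))
  expect_true(detect_singing(synth_pose(theta_left = 0, theta_right = 30.01)))
})

test_that("singing is monotone in the wing extension angle", {
  state <- vapply(seq(0, 120, by = 2), function(th) {
    detect_singing(synth_pose(theta_left = th, theta_right = 0))
  }, logical(1))
  expect_false(any(diff(state) < 0))  # once on, never off as the angle grows
})

test_that("orientation is a 2.5x, +/-10 degree sector of the heading", {
  male <- synth_pose(row = 100, col = 100, head = c(80, 100))  # heading up, |hv| = 20
  at <- function(r, off_deg) {
    d <- rot2(c(-r, 0), off_deg)
    synth_pose(row = 100 + d[1], col = 100 + d[2])
  }
  expect_true(detect_orientation(male, at(25, 0)))      # dead ahead at 0.5x radius
  expect_true(detect_orientation(male, at(49.9, 0)))    # inside the 2.5x radius
  expect_false(detect_orientation(male, at(51, 0)))     # beyond 2.5x
  expect_true(detect_orientation(male, at(30, 9.9)))    # inside +/-10 degrees
  expect_false(detect_orientation(male, at(30, 11)))    # outside the sector
  degen <- synth_pose(row = 100, col = 100, head = c(100, 100))
  expect_false(detect_orientation(degen, at(20, 0)))
})

test_that("the tapping cascade resolves all three leg-contact topologies", {
  cfg <- flycourt_config()
  region <- default_region()
  preds <- rbind(c(160, 100), c(103, 115))
  for (topo in c("leg_torso", "leg_under_wing", "leg_wing")) {
    ts <- tapping_scene(topo)
    fr <- crop_arena(render_frame(ts$scene, seed = 31), region)
    body <- subtract_and_threshold(fr, build_background(fr, 61))
    ct <- split_contact(fr, keep_largest(body, 1), preds, cfg)
    expect_false(is.null(ct), label = paste(topo, "contact split"))
    wm <- extract_wings(fr, ct$male); tm <- extract_torso(ct$male, wm, 1)
    wf <- extract_wings(fr, ct$female); tf <- extract_torso(ct$female, wf, 1)
    pm <- fly_pose(tm, wm, prev_heading = deg2vec(90))
    pf <- fly_pose(tf, wf, prev_heading = deg2vec(90))
    got <- detect_tapping(body, tm, tf, fr, pm, pf, fr$mm_per_px)
    expect_equal(got, ts$expect_tapping, label = topo)
  }
})

test_that("separated flies never tap: the body-count gate fails first", {
  sep <- scene_pair(c(100, 80), 0, c(100, 180), 180)
  fr <- crop_arena(render_frame(sep, seed = 2), default_region())
  body <- subtract_and_threshold(fr, build_background(fr, 61))
  lab <- label8(body)
  m1 <- matrix(lab == 1, nrow(lab)); m2 <- matrix(lab == 2, nrow(lab))
  w1 <- extract_wings(fr, m1); t1 <- extract_torso(m1, w1, 1)
  w2 <- extract_wings(fr, m2); t2 <- extract_torso(m2, w2, 1)
  p1 <- fly_pose(t1, w1); p2 <- fly_pose(t2, w2)
  expect_false(detect_tapping(body, t1, t2, fr, p1, p2, fr$mm_per_px))
})

test_that("attempted copulation combines the 0.9x eccentricity standard and the 1-mm gate", {
  std <- structure(list(reference = 0.95, standard_value = 0.9 * 0.95, factor = 0.9),
                   class = "ecc_standard")
  expect_equal(std$standard_value, 0.855)
  mm <- 0.05  # 20 px per mm
  female_near <- synth_pose(row = 60, col = 100, head = c(40, 100), tail = c(70, 100))
  male <- synth_pose(row = 100, col = 100, head = c(80, 100), eccentricity = 0.80)
  # male head (80,100) to female tail (70,100): 10 px = 0.5 mm
  expect_true(detect_attempted_copulation(male, female_near, std, mm))
  stiff <- synth_pose(row = 100, col = 100, head = c(80, 100), eccentricity = 0.90)
  expect_false(detect_attempted_copulation(stiff, female_near, std, mm))
  female_far <- synth_pose(row = 20, col = 100, head = c(0, 100), tail = c(40, 100))
  # head (80,100) to tail (40,100): 40 px = 2 mm
  expect_false(detect_attempted_copulation(male, female_far, std, mm))
  expect_error(detect_attempted_copulation(male, female_near, list(), mm),
               "ecc_standard")
})

test_that("the ambiguous-female fallback accepts head-point proximity", {
  std <- structure(list(reference = 0.95, standard_value = 0.855, factor = 0.9),
                   class = "ecc_standard")
  male <- synth_pose(row = 100, col = 100, head = c(80, 100), eccentricity = 0.8)
  # female flipped: her true tail is reported as head, 10 px from the male head
  flipped <- synth_pose(row = 60, col = 100, head = c(70, 100), tail = c(40, 100),
                        head_ambiguous = TRUE)
  expect_true(detect_attempted_copulation(male, flipped, std, 0.05))
  flipped$head_ambiguous <- FALSE
  expect_false(detect_attempted_copulation(male, flipped, std, 0.05))
})

test_that("eccentricity calibration: manual frame, auto percentile, bent-male warning", {
  poses <- dplyr::bind_rows(lapply(0:99, function(i) {
    p <- synth_pose(eccentricity = c(rep(0.95, 80), rep(0.75, 20))[i + 1])
    p$frame <- i
    p
  }))
  man <- calibrate_standard(poses, mode = "manual", frame = 3)
  expect_equal(man$reference, 0.95)
  expect_equal(man$standard_value, 0.855)
  auto <- calibrate_standard(poses, mode = "auto", fps = 24)
  expect_equal(auto$reference, 0.95, tolerance = 0.02)
  bent <- poses; bent$eccentricity <- 0.55
  expect_warning(calibrate_standard(bent, mode = "auto", fps = 24), "0.7")
  expect_error(calibrate_standard(poses[0, ], mode = "auto"), "no valid male")
})

test_that("sustained attempted copulation promotes to copulation from the run start", {
  base <- rep("none", 100)
  run <- function(n) c(base, rep("attempted_copulation", n), rep("none", 50))
  keep <- promote_copulation(run(696), fps = 24)   # 29 s at 24 fps
  expect_false("copulation" %in% keep)
  promoted <- promote_copulation(run(744), fps = 24)  # 31 s
  expect_equal(promoted[101], "copulation")
  # the whole remainder of the recording becomes copulation
  expect_true(all(promoted[101:length(promoted)] == "copulation"))
  expect_identical(promote_copulation(base, 24), base)
  # exact boundary: 720 frames = 30 s is not strictly greater
  expect_false("copulation" %in% promote_copulation(run(720), fps = 24))
})

test_that("noise filter certifies at >5 of 12, collapses by priority, and gates none", {
  mk_flags <- function(idx, b = "singing", n = 40) {
    f <- tibble::tibble(orientation = rep(FALSE, n), tapping = FALSE,
                        singing = FALSE, attempted_copulation = FALSE,
                        copulation = FALSE)
    f[[b]][idx] <- TRUE
    f
  }
  # 6 hits inside a 12-frame window certify
  lab6 <- noise_filter(mk_flags(20:25))
  expect_true("singing" %in% lab6[20:30])
  # 5 hits do not
  lab5 <- noise_filter(mk_flags(20:24))
  expect_false("singing" %in% lab5)
  # priority: singing beats orientation when both flag the same frames
  f <- mk_flags(15:26, "singing")
  f$orientation[15:26] <- TRUE
  expect_true("singing" %in% noise_filter(f))
  expect_false("orientation" %in% noise_filter(f))
  # none appears only after 12 empty frames; shorter gaps carry the label
  f2 <- mk_flags(c(1:20, 29:48), "singing", n = 60)
  lab <- noise_filter(f2)
  expect_false("none" %in% lab[21:28])   # 8-frame gap bridged
  f3 <- mk_flags(c(1:20, 45:60), "singing", n = 60)
  lab3 <- noise_filter(f3)
  expect_true("none" %in% lab3[32:44])   # 24-frame gap goes quiet
  # determinism
  expect_identical(noise_filter(f2), noise_filter(f2))
})
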