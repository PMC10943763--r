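test_that("the moment ellipse agrees with a brute-force covariance oracle", {
  set.seed(17)
  for (i in 1:5) {
    m <- fill_ellipse(60, 60, c(30, 30) + runif(2, -5, 5), runif(1, 12, 20),
                      runif(1, 5, 9), runif(1, 0, 180))
    ft <- fit_torso(m)
    idx <- which(m, arr.ind = TRUE)
    cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)   # population covariance
    ev <- eigen(cv, symmetric = TRUE)$values
    expect_equal(ft$eccentricity, sqrt(1 - ev[2] / ev[1]), tolerance = 1e-9)
    expect_equal(ft$major_px, 4 * sqrt(ev[1]), tolerance = 1e-9)
  }
})

test_that("a disc has near-zero eccentricity and an undefined orientation", {
  ft <- fit_torso(fill_disc(50, 50, c(25, 25), 15))
  expect_lt(ft$eccentricity, 0.05)
  expect_true(ft$orientation_undefined)
})

test_that("an axis-aligned 40x16 ellipse recovers the closed-form eccentricity", {
  m <- fill_ellipse(60, 60, c(30, 30), 20, 8, 0)
  ft <- fit_torso(m)
  expect_equal(ft$eccentricity, sqrt(1 - (16 / 40)^2), tolerance = 0.02)
  expect_equal(ft$major_px, 40, tolerance = 1.5)
})

test_that("degenerate torso masks are rejected", {
  expect_error(fit_torso(blank_mask(10, 10)), "empty")
  two <- blank_mask(30, 30); two[5:10, 5:10] <- TRUE; two[20:25, 20:25] <- TRUE
  expect_error(fit_torso(two), "one connected component")
  tiny <- blank_mask(10, 10); tiny[5, 5:8] <- TRUE
  expect_error(fit_torso(tiny), "20 px")
})

test_that("heading of a rendered fly matches the scene within 3 degrees", {
  for (hd in c(30, 211)) {
    s <- seg_fly(render_single(fly_spec(c(75, 75), hd, left_wing_angle = 20,
                                        right_wing_angle = 20), seed = hd))
    err <- min(abs(s$pose$heading_deg - hd), 360 - abs(s$pose$heading_deg - hd))
    expect_lt(err, 3)
  }
})

test_that("the candidate farther from the body centroid becomes the head", {
  cand <- rbind(c(10, 10), c(10, 50))
  # body centroid displaced toward candidate B -> head is A
  ht <- assign_head_tail(cand, c(10, 30), c(10, 36))
  expect_equal(ht$head, c(10, 10))
  expect_false(ht$ambiguous)
  # near-tie resolves by previous heading
  ht2 <- assign_head_tail(cand, c(10, 30), c(10, 30.1), prev_heading = c(0, 1))
  expect_true(ht2$ambiguous)
  expect_equal(ht2$head, c(10, 50))
})

test_that("head matches ground truth in a sweep over headings", {
  ok <- 0; n <- 0
  for (hd in seq(0, 354, by = 6)) {
    spec <- fly_spec(c(75, 75), hd, left_wing_angle = 18, right_wing_angle = 18)
    fr <- render_single(spec, seed = 100 + hd)
    s <- seg_fly(fr)
    gt_head <- fr$truth$flies[[1]]$pose$head
    gt_tail <- fr$truth$flies[[1]]$pose$tail
    n <- n + 1
    if (dist2(c(s$pose$head_row, s$pose$head_col), gt_head) <
        dist2(c(s$pose$head_row, s$pose$head_col), gt_tail)) ok <- ok + 1
  }
  expect_gte(ok / n, 0.99)
})

test_that("wing angles at 35 degrees are measured within 3 degrees", {
  spec <- fly_spec(c(75, 75), 50, left_wing_angle = 35, right_wing_angle = 35)
  s <- seg_fly(render_single(spec, seed = 35))
  expect_equal(s$pose$theta_left, 35, tolerance = 3)
  expect_equal(s$pose$theta_right, 35, tolerance = 3)
})

test_that("folded wings give near-zero angles and an empty mask gives exactly zero", {
  s <- seg_fly(render_single(fly_spec(c(75, 75), 80, left_wing_angle = 0,
                                      right_wing_angle = 0), seed = 44))
  expect_lt(max(s$pose$theta_left, s$pose$theta_right), 10)
  wa <- wing_angles(blank_mask(20, 20), c(10, 10), c(0, 1))
  expect_equal(wa$theta_left, 0)
  expect_equal(wa$theta_right, 0)
})

test_that("mirroring the frame swaps left and right wing angles exactly", {
  spec <- fly_spec(c(75, 75), 90, left_wing_angle = 55, right_wing_angle = 20)
  fr <- render_single(spec, seed = 77)
  mir <- fr
  mir$pixels <- fr$pixels[, rev(seq_len(dim(fr$pixels)[2])), , drop = FALSE]
  s1 <- seg_fly(fr); s2 <- seg_fly(mir)
  expect_equal(s1$pose$theta_left, s2$pose$theta_right, tolerance = 1e-6)
  expect_equal(s1$pose$theta_right, s2$pose$theta_left, tolerance = 1e-6)
})

test_that("rotating the scene by 90 degrees rotates heading and preserves wing angles", {
  base <- fly_spec(c(75, 75), 25, left_wing_angle = 50, right_wing_angle = 30)
  rot <- fly_spec(c(75, 75), 115, left_wing_angle = 50, right_wing_angle = 30)
  s1 <- seg_fly(render_single(base, seed = 10))
  s2 <- seg_fly(render_single(rot, seed = 10))
  dh <- (s2$pose$heading_deg - s1$pose$heading_deg) %% 360
  expect_equal(dh, 90, tolerance = 2)
  expect_equal(s2$pose$theta_left, s1$pose$theta_left, tolerance = 2)
  expect_equal(s2$pose$theta_right, s1$pose$theta_right, tolerance = 2)
})
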