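# Shared fixture helpers. Rendering is the slow step, so single-fly frames
# are cached per (spec, seed) within a test run.

# internal utilities exercised directly by the tests
dist2 <- flycourt:::dist2
deg2vec <- flycourt:::deg2vec
rot2 <- flycourt:::rot2
mask_dilate <- flycourt:::mask_dilate
mask_erode <- flycourt:::mask_erode
n_components <- flycourt:::n_components
keep_largest <- flycourt:::keep_largest
remove_small <- flycourt:::remove_small
label8 <- flycourt:::label8
box_max_filter <- flycourt:::box_max_filter
mask_moments <- flycourt:::mask_moments
aligned_dice <- flycourt:::aligned_dice
parts_score <- flycourt:::parts_score
split_contact <- flycourt:::split_contact
otsu_two_thresholds <- flycourt:::otsu_two_thresholds
fill_disc <- flycourt:::fill_disc
fill_ellipse <- flycourt:::fill_ellipse
blank_mask <- flycourt:::blank_mask
mask_centroid <- flycourt:::mask_centroid
neighbor_count <- flycourt:::neighbor_count

.fixture_cache <- new.env(parent = emptyenv())

default_region <- function(radius = 115, center = c(130.5, 130.5)) {
  list(row = center[1], col = center[2], radius = radius,
       mm_per_px = 11 / (2 * radius))
}

# small uniform-background scene for fast single-fly pose tests
small_fly_scene <- function(spec) {
  scene_spec(flies = list(spec), frame_size = c(150, 150),
             arena_center = c(75.5, 75.5), arena_radius = 70,
             outside_gray = 220)
}

# segment one rendered frame into body/wings/torso and fit the pose
seg_fly <- function(frame, prev_heading = NULL, bg_window = 61) {
  body <- subtract_and_threshold(frame, build_background(frame, bg_window))
  wings <- extract_wings(frame, body)
  torso <- extract_torso(body, wings, n_flies = 1)
  pose <- fly_pose(torso, wings, prev_heading = prev_heading)
  list(body = body, wings = wings, torso = torso, pose = pose)
}

render_single <- function(spec, seed) {
  key <- paste0(rlang::hash(unclass(spec)), "_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fr <- render_frame(small_fly_scene(spec), seed = seed)
  .fixture_cache[[key]] <- fr
  fr
}

# torso-part extraction for one rendered fly (the identity-module path)
fly_parts <- function(spec, seed) {
  fr <- crop_arena(render_frame(scene_spec(flies = list(spec)), seed = seed),
                   default_region())
  s <- seg_fly(fr)
  can <- canonicalize_torso(s$torso, head = c(s$pose$head_row, s$pose$head_col))
  segment_torso_parts(can$mask)
}

# a one-row pose tibble with full control over the fields the behavior
# detectors read
synth_pose <- function(row = 100, col = 100, head = c(80, 100), tail = c(120, 100),
                       theta_left = 0, theta_right = 0, eccentricity = 0.95,
                       head_ambiguous = FALSE) {
  tibble::tibble(
    frame = 0, fly_id = "male", row = row, col = col,
    body_row = row, body_col = col,
    head_row = head[1], head_col = head[2],
    tail_row = tail[1], tail_col = tail[2],
    heading_deg = vec_heading(head - c(row, col)),
    theta_left = theta_left, theta_right = theta_right,
    eccentricity = eccentricity, major_px = 44, minor_px = 16, area_px = 460,
    head_ambiguous = head_ambiguous, orientation_undefined = FALSE
  )
}

vec_heading <- function(v) (atan2(-v[1], v[2]) * 180 / pi) %% 360

# horizontal-run mask pair with controlled aligned Dice 2*nb/(na+nb)
dice_run_pair <- function(na, nb, nr = 9, row = 5) {
  a <- matrix(FALSE, nr, max(na, nb) + 4)
  b <- a
  off <- (ncol(a) - na) %/% 2
  a[row, off + seq_len(na)] <- TRUE
  offb <- (ncol(a) - nb) %/% 2
  b[row, offb + seq_len(nb)] <- TRUE
  list(a = a, b = b)
}
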