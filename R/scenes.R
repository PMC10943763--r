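# Scripted fixture scenes: deterministic trajectories with known intended
# behavior, used for end-to-end checks of tracking and recognition.

#' Convenience two-fly scene
#'
#' @param male_pos,female_pos (row, col) torso centroids.
#' @param male_heading,female_heading Headings in degrees.
#' @param male_args,female_args Extra [fly_spec()] arguments per fly.
#' @param ... Extra [scene_spec()] arguments.
#' @return A `scene_spec` with the male first.
#' @export
scene_pair <- function(male_pos, male_heading, female_pos, female_heading,
                       male_args = list(), female_args = list(), ...) {
  m <- do.call(fly_spec, c(list(centroid = male_pos, heading_angle = male_heading), male_args))
  f <- do.call(fly_spec, c(list(centroid = female_pos, heading_angle = female_heading), female_args))
  scene_spec(flies = list(m, f), ...)
}

#' Static tapping-topology scene
#'
#' Builds the three leg-contact situations used to validate the tapping
#' cascade: `"leg_torso"` (male foreleg tip on the female's abdomen;
#' tapping), `"leg_under_wing"` (the same contact but seen through the
#' female's translucent wing; tapping), and `"leg_wing"` (foreleg tip on
#' the female's wing only; not tapping).
#'
#' @param topology One of `"leg_torso"`, `"leg_under_wing"`, `"leg_wing"`.
#' @param male_heading_offset Degrees added to the male's straight-at-tail
#'   heading (nonzero values point him away for negative controls).
#' @return List: `scene` (a [scene_spec()]), `expect_tapping` (logical).
#' @export
tapping_scene <- function(topology = c("leg_torso", "leg_under_wing", "leg_wing"),
                          male_heading_offset = 0) {
  topology <- match.arg(topology)
  fc <- c(118, 130)            # female centroid; heading 90 = facing up
  tail <- fc + c(28, 0)        # abdomen tip of the 52-px female
  geom <- switch(topology,
    leg_torso = list(
      male_ctr = fc + c(57, 0), heading = 90,
      female_wings = c(45, 45), under = FALSE,
      leg_tip = fc + c(16, 0)                       # inside the abdomen lobe
    ),
    leg_under_wing = list(
      # male approaches the abdomen flank from lower-left, his foreleg and
      # head region beneath the female's half-folded left wing
      male_ctr = c(161, 104.5), heading = 52.6,
      female_wings = c(30, 45), under = TRUE,
      leg_tip = fc + c(16, -2)
    ),
    leg_wing = list(
      male_ctr = fc + c(60, 2), heading = 90,
      female_wings = c(40, 45), under = FALSE,
      leg_tip = c(139, 146)                         # on the right wing blade only
    )
  )
  u <- deg2vec(geom$heading)
  head_pt <- geom$male_ctr + 17 * u
  leg <- list(list(attach = head_pt + 2 * u, tip = geom$leg_tip))
  sc <- scene_pair(
    male_pos = geom$male_ctr, male_heading = geom$heading + male_heading_offset,
    female_pos = fc, female_heading = 90,
    male_args = list(leg_specs = leg, torso_major = 42, torso_minor = 15,
                     left_wing_angle = 18, right_wing_angle = 18),
    female_args = list(torso_major = 52, torso_minor = 20,
                       left_wing_angle = geom$female_wings[1],
                       right_wing_angle = geom$female_wings[2]),
    leg_under_wing = geom$under
  )
  list(scene = sc, expect_tapping = topology != "leg_wing")
}

#' Scripted overlap gauntlet for identity tracking
#'
#' A 500-frame (by default) deterministic trajectory in which the male
#' repeatedly crosses straight through the stationary female, producing
#' full-overlap episodes from different approach angles; ground-truth
#' positions are returned per frame.
#'
#' @param n_frames Sequence length.
#' @param n_episodes Number of crossing episodes.
#' @param speed_px Male speed in px/frame.
#' @return List: `scenes` (for [render_sequence()]), `gt` (tibble: frame,
#'   male/female ground-truth centroids, `separated` flag).
#' @export
script_overlap_gauntlet <- function(n_frames = 500, n_episodes = 5, speed_px = 6) {
  fc <- c(130, 150)
  park <- 82
  waypoints <- list()
  for (k in seq_len(n_episodes)) {
    ang <- (k - 1) * 360 / n_episodes + 12
    dirv <- deg2vec(ang)
    waypoints[[length(waypoints) + 1]] <- fc + park * dirv
    waypoints[[length(waypoints) + 1]] <- fc - park * dirv
  }
  waypoints[[length(waypoints) + 1]] <- waypoints[[1]]
  # constant-speed traversal of the waypoint polyline
  pts <- list(); cur <- waypoints[[1]]
  wp_i <- 2
  for (t in seq_len(n_frames)) {
    pts[[t]] <- cur
    remaining <- speed_px
    while (remaining > 0 && wp_i <= length(waypoints)) {
      seg <- waypoints[[wp_i]] - cur
      len <- sqrt(sum(seg^2))
      if (len > remaining) {
        cur <- cur + (remaining / len) * seg
        remaining <- 0
      } else {
        cur <- waypoints[[wp_i]]
        remaining <- remaining - len
        wp_i <- wp_i + 1
        if (wp_i > length(waypoints)) wp_i <- 2  # loop the circuit
      }
    }
  }
  scenes <- vector("list", n_frames)
  gt <- vector("list", n_frames)
  prev <- pts[[1]]
  for (t in seq_len(n_frames)) {
    mv <- pts[[t]] - prev
    hd <- if (sqrt(sum(mv^2)) > 0.1) vec2deg(mv) else if (t > 1) gt[[t - 1]]$male_heading else 0
    prev <- pts[[t]]
    scenes[[t]] <- scene_pair(
      male_pos = pts[[t]], male_heading = hd,
      female_pos = fc, female_heading = 200,
      male_args = list(torso_major = 42, torso_minor = 15,
                       left_wing_angle = 18, right_wing_angle = 18),
      female_args = list(torso_major = 52, torso_minor = 20,
                         left_wing_angle = 20, right_wing_angle = 20),
      frame_size = c(300, 300), arena_radius = 135
    )
    gt[[t]] <- tibble::tibble(
      frame = t - 1L,
      male_row = pts[[t]][1], male_col = pts[[t]][2],
      female_row = fc[1], female_col = fc[2],
      male_heading = hd,
      separated = dist2(pts[[t]], fc) > 60
    )
  }
  list(scenes = scenes, gt = dplyr::bind_rows(gt))
}

#' Scripted courtship bout with known certified labels
#'
#' A deterministic scene sequence cycling through all five courtship
#' elements (plus quiescent stretches), with the certified label sequence
#' expected from the temporal filter computed in closed form from the
#' segment layout: after a quiescent stretch a behavior certifies on its
#' 6th frame; a behavior replacing another certifies on its 7th; a behavior
#' persists 11 frames into a quiescent stretch before `none` appears; and a
#' sustained attempted-copulation run longer than half a minute becomes
#' copulation from its certified start to the end of the recording.
#'
#' The bout runs at a reduced frame rate so the half-minute copulation rule
#' is reachable within a short sequence; all frame-count thresholds (the
#' 5-of-12 certification and 12-frame gap) are frame-based and unaffected.
#'
#' @param fps Frame rate of the scripted bout.
#' @return List: `scenes`, `gt` (tibble: frame, intended raw element,
#'   expected certified label), `fps`.
#' @export
script_courtship_bout <- function(fps = 2) {
  fc <- c(118, 130)  # female, facing up
  msz <- list(torso_major = 42, torso_minor = 15)
  fsz <- list(torso_major = 52, torso_minor = 20)
  stations <- list(
    none = list(pos = c(195, 75), heading = 225),
    # off-axis so the male sits inside his 2.5x orientation sector radius
    # while staying clear of the female's abdomen
    facing = list(pos = c(155, 158), heading = 126.9),
    attempted = list(pos = c(173, 130), heading = 90)
  )
  segs <- list(
    list(kind = "none", len = 16),
    list(kind = "orientation", len = 20),
    list(kind = "singing", len = 20),
    list(kind = "none", len = 16),
    list(kind = "tap_torso", len = 20),
    list(kind = "none", len = 16),
    list(kind = "tap_under_wing", len = 20),
    list(kind = "neg_leg_wing", len = 16),
    list(kind = "none", len = 14),
    list(kind = "attempted", len = 20),
    list(kind = "none", len = 16),
    list(kind = "attempted", len = 70)
  )
  scene_for <- function(kind) {
    st <- switch(kind,
      none = stations$none, orientation = stations$facing,
      singing = stations$facing, attempted = stations$attempted, NULL)
    switch(kind,
      tap_torso = tapping_scene("leg_torso")$scene,
      tap_under_wing = tapping_scene("leg_under_wing")$scene,
      neg_leg_wing = tapping_scene("leg_wing")$scene,
      singing = scene_pair(st$pos, st$heading, fc, 90,
                           male_args = c(msz, list(left_wing_angle = 60, right_wing_angle = 10)),
                           female_args = fsz),
      attempted = scene_pair(st$pos, st$heading, fc, 90,
                             male_args = c(msz, list(abdomen_bend = 120)),
                             female_args = fsz),
      scene_pair(st$pos, st$heading, fc, 90, male_args = msz, female_args = fsz)
    )
  }
  raw_of <- function(kind) {
    switch(kind,
      none = "none", neg_leg_wing = "none",
      orientation = "orientation", singing = "singing",
      tap_torso = "tapping", tap_under_wing = "tapping",
      attempted = "attempted_copulation"
    )
  }
  scenes <- list(); raw <- character(0)
  for (s in segs) {
    sc <- scene_for(s$kind)
    scenes <- c(scenes, rep(list(sc), s$len))
    raw <- c(raw, rep(raw_of(s$kind), s$len))
  }
  expected <- expected_certified(raw)
  # half-minute promotion: the final sustained attempted run
  n <- length(expected)
  runs <- rle(expected)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  hit <- which(runs$values == "attempted_copulation" & runs$lengths > 30 * fps)
  if (length(hit) > 0) expected[starts[hit[1]]:n] <- "copulation"
  list(
    scenes = scenes,
    gt = tibble::tibble(frame = seq_along(raw) - 1L, raw = raw, expected = expected),
    fps = fps
  )
}

# Closed-form certified labels for steady scripted segments (default filter
# parameters): independent segment arithmetic, not a re-run of the filter.
expected_certified <- function(raw) {
  r <- rle(raw)
  n <- length(raw)
  out <- rep("none", n)
  pos <- 1
  prev_kind <- "none"
  for (i in seq_along(r$values)) {
    len <- r$lengths[i]; kind <- r$values[i]
    idx <- pos:(pos + len - 1)
    if (kind == "none") {
      if (prev_kind != "none") {
        carry <- min(11, len)
        out[idx[seq_len(carry)]] <- prev_kind
        if (len > 11) out[idx[(carry + 1):len]] <- "none"
      } else {
        out[idx] <- "none"
      }
    } else {
      lag <- if (prev_kind == "none") 5 else 6
      if (lag > 0) out[idx[seq_len(min(lag, len))]] <- if (prev_kind == "none" && pos <= 11) "none" else out[max(1, pos - 1)]
      if (len > lag) out[idx[(lag + 1):len]] <- kind
    }
    prev_kind <- kind
    pos <- pos + len
  }
  out
}

#' Render a scripted sequence directly into arena crops
#'
#' Renders each scene, detects the arena on the first frame, and crops
#' immediately, so full frames and their ground-truth masks never
#' accumulate in memory; long scripted sequences (hundreds of frames) track
#' within a modest footprint.
#'
#' @param scenes List of [scene_spec()] objects.
#' @param seed Base seed; frame i uses `seed + i - 1`.
#' @param fps Frame rate stamped on the frames.
#' @return List: `crops` (single-arena `flycourt_frame` objects), `arena`
#'   (the detection row used for cropping).
#' @export
render_cropped_sequence <- function(scenes, seed = 0, fps = 24) {
  stopifnot(length(scenes) > 0)
  first <- render_frame(scenes[[1]], seed = seed, index = 0, fps = fps)
  region <- detect_arenas(first, expected_count = 1)[1, ]
  crops <- vector("list", length(scenes))
  crops[[1]] <- crop_arena(first, region)
  rm(first)
  for (i in seq_along(scenes)[-1]) {
    fr <- render_frame(scenes[[i]], seed = seed + i - 1, index = i - 1, fps = fps)
    crops[[i]] <- crop_arena(fr, region)
  }
  list(crops = crops, arena = region)
}
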