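#' Specify a synthetic fly for scene rendering
#'
#' Describes one fly in a parametric two-fly arena scene: an elongated torso
#' (optionally drawn as head/thorax/abdomen lobes so that watershed-based body
#' part segmentation has real structure to find), two triangular wings whose
#' tips sit at a controlled extension angle, and optional 1-px leg segments.
#'
#' @param centroid Numeric `(row, col)` torso centre in pixels (1-based).
#' @param heading_angle Heading in degrees; 0 points along +col,
#'   counter-clockwise positive as the image is displayed.
#' @param torso_major,torso_minor Full major/minor axis lengths of the torso
#'   in px (`torso_major >= torso_minor > 0`).
#' @param left_wing_angle,right_wing_angle Wing extension angles in degrees in
#'   `[0, 180)`, measured from the tailward major-axis direction, so folded
#'   wings are near 0 and full extension is near 90.
#' @param leg_specs List of legs, each a list with `attach` and `tip`
#'   `(row, col)` points; legs are drawn 1 px wide.
#' @param abdomen_bend Degrees the abdomen lobe is bent off-axis (0 =
#'   straight); bending lowers the torso's moment eccentricity as in a
#'   copulation attempt.
#' @param body_gray,wing_gray Paint intensities (0-255). Wings must be
#'   strictly lighter than the torso and darker than the scene background
#'   (translucent wings over a backlight).
#' @param leg_gray Leg paint intensity; intermediate like wings but drawn thin.
#' @param shape `"lobed"` draws the torso as three overlapping ellipses
#'   (head/thorax/abdomen); `"ellipse"` draws a single ellipse.
#' @param headless Omit the head lobe (decapitated female in a headless
#'   courtship test); only meaningful for the lobed shape.
#' @return A `fly_spec` list.
#' @export
fly_spec <- function(centroid,
                     heading_angle = 0,
                     torso_major = 44,
                     torso_minor = 16,
                     left_wing_angle = 8,
                     right_wing_angle = 8,
                     leg_specs = list(),
                     abdomen_bend = 0,
                     body_gray = 30,
                     wing_gray = 140,
                     leg_gray = 90,
                     shape = c("lobed", "ellipse"),
                     headless = FALSE) {
  shape <- match.arg(shape)
  stopifnot(length(centroid) == 2, is.numeric(centroid))
  if (!(torso_major >= torso_minor && torso_minor > 0)) {
    stop("torso_major >= torso_minor > 0 is required", call. = FALSE)
  }
  for (w in c(left_wing_angle, right_wing_angle)) {
    if (w < 0 || w >= 180) stop("wing angles must lie in [0, 180)", call. = FALSE)
  }
  if (!(body_gray < wing_gray)) {
    stop("wing_gray must exceed body_gray (wings are translucent)", call. = FALSE)
  }
  structure(list(
    centroid = as.numeric(centroid), heading_angle = heading_angle,
    torso_major = torso_major, torso_minor = torso_minor,
    left_wing_angle = left_wing_angle, right_wing_angle = right_wing_angle,
    leg_specs = leg_specs, abdomen_bend = abdomen_bend,
    body_gray = body_gray, wing_gray = wing_gray, leg_gray = leg_gray,
    shape = shape, headless = headless
  ), class = "fly_spec")
}

#' Specify a synthetic arena scene
#'
#' A circular backlit arena (bright disc on a darker surround) holding up to
#' two flies, male first. The pixel scale is derived from the physical 11-mm
#' arena diameter, so all mm-valued behavior thresholds exercise the same
#' calibration path as recorded video.
#'
#' @param flies List of [fly_spec()] objects, male first.
#' @param frame_size `(rows, cols)` of the rendered frame.
#' @param arena_center `(row, col)` of the arena centre; defaults to the frame
#'   centre.
#' @param arena_radius Arena radius in px.
#' @param arena_diameter_mm Physical arena diameter; 11 mm for this rig.
#' @param background_gray Backlit arena interior intensity.
#' @param outside_gray Intensity outside the arena disc.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units),
#'   applied independently per channel so R, G and B are correlated but not
#'   identical.
#' @param leg_under_wing When `TRUE`, leg pixels covered by another fly's wing
#'   are painted at the translucent composite intensity (leg seen through the
#'   wing) instead of occluding the wing; used to build leg-under-wing tapping
#'   topologies.
#' @return A `scene_spec` list; `mm_per_px` is derived from the arena size.
#' @export
scene_spec <- function(flies = list(),
                       frame_size = c(260, 260),
                       arena_center = NULL,
                       arena_radius = 115,
                       arena_diameter_mm = 11,
                       background_gray = 220,
                       outside_gray = 110,
                       noise_sd = 2,
                       leg_under_wing = FALSE) {
  if (is.null(arena_center)) arena_center <- (frame_size + 1) / 2
  stopifnot(arena_radius > 0, noise_sd >= 0)
  for (f in flies) {
    if (!inherits(f, "fly_spec")) stop("flies must be fly_spec objects", call. = FALSE)
    if (dist2(f$centroid, arena_center) >= arena_radius) {
      stop("fly centroid outside arena", call. = FALSE)
    }
    if (!(f$wing_gray < background_gray)) {
      stop("wing_gray must be below background_gray", call. = FALSE)
    }
  }
  structure(list(
    flies = flies, frame_size = as.integer(frame_size),
    arena_center = as.numeric(arena_center), arena_radius = arena_radius,
    arena_diameter_mm = arena_diameter_mm,
    mm_per_px = arena_diameter_mm / (2 * arena_radius),
    background_gray = background_gray, outside_gray = outside_gray,
    noise_sd = noise_sd, leg_under_wing = leg_under_wing
  ), class = "scene_spec")
}

# Run code with a private RNG state so rendering is bit-reproducible without
# disturbing the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Geometry of one fly's paint masks, in frame coordinates.
render_fly_masks <- function(spec, nr, nc) {
  u <- deg2vec(spec$heading_angle)
  L <- spec$torso_major; W <- spec$torso_minor
  ctr <- spec$centroid

  if (spec$shape == "ellipse" && spec$abdomen_bend == 0) {
    torso <- fill_ellipse(nr, nc, ctr, L / 2, W / 2, spec$heading_angle)
  } else if (spec$shape == "ellipse") {
    ant <- fill_ellipse(nr, nc, ctr + 0.15 * L * u, 0.35 * L, W / 2, spec$heading_angle)
    pivot <- ctr - 0.15 * L * u
    dback <- rot2(-u, spec$abdomen_bend)
    abd <- fill_ellipse(nr, nc, pivot + 0.21 * L * dback, 0.25 * L, 0.45 * W,
                        vec2deg(dback))
    torso <- ant | abd
  } else {
    # three lobes: head (small), thorax (widest), abdomen; small overlaps
    # leave necks that the distance-map watershed can find.
    head_m <- fill_ellipse(nr, nc, ctr + 0.37 * L * u, 0.13 * L, 0.26 * W, spec$heading_angle)
    thx_m <- fill_ellipse(nr, nc, ctr + 0.05 * L * u, 0.21 * L, 0.40 * W, spec$heading_angle)
    if (spec$abdomen_bend == 0) {
      abd_m <- fill_ellipse(nr, nc, ctr - 0.32 * L * u, 0.22 * L, 0.40 * W, spec$heading_angle)
    } else {
      pivot <- ctr - 0.10 * L * u
      dback <- rot2(-u, spec$abdomen_bend)
      abd_m <- fill_ellipse(nr, nc, pivot + 0.16 * L * dback, 0.22 * L, 0.40 * W,
                            vec2deg(dback))
    }
    torso <- if (isTRUE(spec$headless)) thx_m | abd_m else head_m | thx_m | abd_m
  }

  wing_one <- function(theta, side) {
    # side +1 = fly's left (positive cross product with the heading, i.e.
    # screen-up for a fly heading along +col); display-CCW rotation by -theta
    # from the tailward axis lands on that side
    tip_dir <- rot2(-u, -side * theta)
    tip <- ctr + 0.6 * L * tip_dir
    # hinge at the posterior quarter of the axis; when the abdomen is bent
    # aside the hinge retracts to the thorax so the wings stay attached
    hinge_frac <- if (spec$abdomen_bend > 0) 0.14 else 0.25
    hinge <- ctr - hinge_frac * L * u
    blade <- tip - hinge
    # rounded wing blade: thin ellipse from hinge to tip, so the farthest
    # boundary point from the torso centroid stays on the tip ray
    fill_ellipse(nr, nc, (hinge + tip) / 2, sqrt(sum(blade^2)) / 2, 0.3 * W,
                 vec2deg(blade))
  }
  wings <- wing_one(spec$left_wing_angle, +1) | wing_one(spec$right_wing_angle, -1)
  wings <- wings & !torso

  legs <- blank_mask(nr, nc)
  for (leg in spec$leg_specs) {
    legs <- legs | draw_segment(nr, nc, leg$attach, leg$tip)
  }
  legs <- legs & !torso & !wings

  list(torso = torso, wings = wings, legs = legs, body = torso | wings | legs)
}

# Ground-truth pose for a rendered fly, by construction.
truth_pose <- function(spec, masks) {
  u <- deg2vec(spec$heading_angle)
  tc <- mask_centroid(masks$torso)
  if (is.null(tc)) tc <- spec$centroid
  idx <- which(masks$torso, arr.ind = TRUE)
  ecc <- NA_real_
  if (nrow(idx) >= 5) {
    cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
    ev <- eigen(cv, symmetric = TRUE)$values
    ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  }
  proj <- as.numeric((idx[, 1] - tc[1]) * u[1] + (idx[, 2] - tc[2]) * u[2])
  head_pt <- if (nrow(idx)) as.numeric(idx[which.max(proj), ]) else tc
  tail_pt <- if (nrow(idx)) as.numeric(idx[which.min(proj), ]) else tc
  list(
    centroid = tc, heading_deg = spec$heading_angle %% 360,
    head = head_pt, tail = tail_pt,
    theta_l = spec$left_wing_angle, theta_r = spec$right_wing_angle,
    eccentricity = ecc
  )
}

#' Render one synthetic frame with full ground truth
#'
#' Draws the arena and each fly (wings, legs, then torso, darker paint wins),
#' adds per-channel Gaussian noise under a private seed, and returns the frame
#' together with the exact masks, poses and contact flags used to draw it.
#'
#' @param scene A [scene_spec()].
#' @param seed Integer seed for the noise realization.
#' @param index Frame ordinal carried on the result (0-based by convention).
#' @param fps Frame rate carried on the result (frames/s).
#' @return A `flycourt_frame`: list with `pixels` (rows x cols x 3 array,
#'   0-255), `index`, `fps`, `mm_per_px`, and `truth` (per-fly masks and
#'   poses, combined body mask, `body_contact`, `torso_contact`, `tapping`).
#' @export
render_frame <- function(scene, seed = 0, index = 0, fps = 24) {
  stopifnot(inherits(scene, "scene_spec"))
  nr <- scene$frame_size[1]; nc <- scene$frame_size[2]
  base <- matrix(scene$outside_gray, nr, nc)
  arena <- fill_disc(nr, nc, scene$arena_center, scene$arena_radius)
  base[arena] <- scene$background_gray

  fly_masks <- lapply(scene$flies, render_fly_masks, nr = nr, nc = nc)
  n_fly <- length(fly_masks)

  for (i in seq_len(n_fly)) {
    fm <- fly_masks[[i]]
    spec <- scene$flies[[i]]
    base[fm$wings] <- pmin(base[fm$wings], spec$wing_gray)
    leg_px <- fm$legs
    if (any(leg_px)) {
      other_wings <- blank_mask(nr, nc)
      for (j in setdiff(seq_len(n_fly), i)) other_wings <- other_wings | fly_masks[[j]]$wings
      if (scene$leg_under_wing && any(leg_px & other_wings)) {
        seen_through <- round(spec$leg_gray * scene$flies[[i]]$wing_gray / scene$background_gray)
        covered <- leg_px & other_wings
        base[covered] <- pmin(base[covered], seen_through)
        base[leg_px & !other_wings] <- pmin(base[leg_px & !other_wings], spec$leg_gray)
      } else {
        base[leg_px] <- pmin(base[leg_px], spec$leg_gray)
      }
    }
  }
  for (i in seq_len(n_fly)) {
    fm <- fly_masks[[i]]
    base[fm$torso] <- pmin(base[fm$torso], scene$flies[[i]]$body_gray)
  }

  pixels <- with_seed(seed, {
    arr <- array(0L, dim = c(nr, nc, 3))
    for (ch in 1:3) {
      arr[, , ch] <- as.integer(clamp255(round(base + stats::rnorm(nr * nc, 0, scene$noise_sd))))
    }
    arr
  })

  body_all <- blank_mask(nr, nc)
  for (fm in fly_masks) body_all <- body_all | fm$body
  body_contact <- FALSE; torso_contact <- FALSE; tapping <- FALSE
  if (n_fly == 2) {
    a <- fly_masks[[1]]; b <- fly_masks[[2]]
    body_contact <- any(mask_dilate(a$body, 1) & b$body)
    torso_contact <- any(mask_dilate(a$torso, 1) & b$torso)
    # tapping flag: a male leg pixel inside (or adjacent to) the female torso
    if (any(a$legs)) {
      tapping <- any(mask_dilate(a$legs, 1) & b$torso)
    }
  }

  truth <- list(
    flies = lapply(seq_len(n_fly), function(i) {
      c(fly_masks[[i]], list(pose = truth_pose(scene$flies[[i]], fly_masks[[i]])))
    }),
    body_all = body_all,
    body_contact = body_contact, torso_contact = torso_contact,
    tapping = tapping
  )

  structure(list(pixels = pixels, index = index, fps = fps,
                 mm_per_px = scene$mm_per_px, truth = truth,
                 scene = scene),
            class = "flycourt_frame")
}

#' Render a scripted sequence of scenes
#'
#' @param scenes Non-empty list of [scene_spec()] objects with a constant
#'   frame size.
#' @param seed Base seed; frame i uses `seed + i - 1` so the sequence is
#'   deterministic yet frames have independent noise.
#' @param fps Frame rate carried on every frame.
#' @return List of `flycourt_frame` objects with 0-based contiguous indices.
#' @export
render_sequence <- function(scenes, seed = 0, fps = 24) {
  if (length(scenes) == 0) stop("scenes must be a non-empty list", call. = FALSE)
  sz <- scenes[[1]]$frame_size
  for (s in scenes) {
    if (!identical(s$frame_size, sz)) stop("inconsistent frame sizes", call. = FALSE)
  }
  lapply(seq_along(scenes), function(i) {
    render_frame(scenes[[i]], seed = seed + i - 1, index = i - 1, fps = fps)
  })
}

#' Write rendered frames to a PNG sequence with JSON ground truth
#'
#' @param frames List of `flycourt_frame` objects.
#' @param dir Output directory (created if needed).
#' @param write_truth Write per-frame pose/contact ground truth as JSON.
#' @return Invisibly, the vector of PNG paths.
#' @export
write_frames <- function(frames, dir, write_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    stem <- sprintf("frame_%04d", f$index)
    paths[i] <- file.path(dir, paste0(stem, ".png"))
    png::writePNG(f$pixels / 255, paths[i])
    if (write_truth) {
      tr <- f$truth
      slim <- list(
        index = f$index, fps = f$fps, mm_per_px = f$mm_per_px,
        body_contact = tr$body_contact, torso_contact = tr$torso_contact,
        tapping = tr$tapping,
        poses = lapply(tr$flies, function(fl) fl$pose)
      )
      jsonlite::write_json(slim, file.path(dir, paste0(stem, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(paths)
}

#' Render a multi-arena sheet for arena-detection tests
#'
#' Bright circular arenas on a dark surround, as seen by the rig's camera
#' before cropping to a single arena.
#'
#' @param centers Matrix or list of `(row, col)` arena centres.
#' @param radius Common arena radius in px.
#' @param frame_size `(rows, cols)`.
#' @param background_gray,outside_gray,noise_sd As in [scene_spec()].
#' @param seed Noise seed.
#' @return A `flycourt_frame` with no flies (truth carries the circle
#'   parameters instead).
#' @export
render_arena_sheet <- function(centers, radius, frame_size = c(560, 560),
                               background_gray = 220, outside_gray = 110,
                               noise_sd = 2, seed = 0) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  nr <- frame_size[1]; nc <- frame_size[2]
  base <- matrix(outside_gray, nr, nc)
  for (i in seq_len(nrow(centers))) {
    base[fill_disc(nr, nc, centers[i, ], radius)] <- background_gray
  }
  pixels <- with_seed(seed, {
    arr <- array(0L, dim = c(nr, nc, 3))
    for (ch in 1:3) {
      arr[, , ch] <- as.integer(clamp255(round(base + stats::rnorm(nr * nc, 0, noise_sd))))
    }
    arr
  })
  structure(list(pixels = pixels, index = 0, fps = 24,
                 truth = list(centers = centers, radius = radius)),
            class = "flycourt_frame")
}
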