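#' Detect singing (unilateral wing extension)
#'
#' A male whose larger wing-extension angle exceeds the threshold (30°,
#' strict inequality) is singing.
#'
#' @param male One-row pose tibble (needs `theta_left`, `theta_right`).
#' @param threshold_deg Wing-extension threshold in degrees.
#' @return Logical flag.
#' @export
detect_singing <- function(male, threshold_deg = 30) {
  max(male$theta_left, male$theta_right) > threshold_deg
}

#' Detect orientation (male facing the female)
#'
#' The centroid-to-head vector is extended 2.5 times and swung +/- 10°,
#' defining a sector with its apex at the male's torso centroid; the male is
#' orienting when the female's torso centroid lies inside it.
#'
#' @param male,female One-row pose tibbles.
#' @param extension Radial extension factor applied to the centroid-to-head
#'   vector length.
#' @param half_angle_deg Sector half-angle in degrees.
#' @return Logical flag (FALSE for a degenerate zero-length heading).
#' @export
detect_orientation <- function(male, female, extension = 2.5, half_angle_deg = 10) {
  hv <- c(male$head_row - male$row, male$head_col - male$col)
  hlen <- sqrt(sum(hv^2))
  if (hlen == 0) return(FALSE)
  v <- c(female$row - male$row, female$col - male$col)
  r <- sqrt(sum(v^2))
  if (r > extension * hlen) return(FALSE)
  off <- angle_between(hv, v)
  is.finite(off) && off <= half_angle_deg
}

# male-head-to-female-tail distance gate in mm; falls back to the female
# head point when her head/tail call was ambiguous (a flipped female would
# otherwise invert the gate).
contact_distance_ok <- function(male, female, mm_per_px, contact_mm = 1) {
  d_tail <- dist2(c(male$head_row, male$head_col),
                  c(female$tail_row, female$tail_col)) * mm_per_px
  if (d_tail < contact_mm) return(TRUE)
  if (isTRUE(female$head_ambiguous)) {
    d_head <- dist2(c(male$head_row, male$head_col),
                    c(female$head_row, female$head_col)) * mm_per_px
    if (d_head < contact_mm) return(TRUE)
  }
  FALSE
}

#' Detect tapping (foreleg contact with the female's body)
#'
#' Implements the six-step conditional cascade: (1) the two bodies form one
#' connected silhouette; (2) the torsos stay separate; (3) the male's head is
#' within 1 mm of the female's tail. Step 4 builds a leg-exposing skeleton
#' image (filled wings/torso with legs reduced to 1-px branches, i.e. the
#' opening of the body united with the body's pruned skeleton), unions it
#' with the torsos and erodes: if the flies separate the bridge was a bare
#' leg and step 5 decides whether that leg ends on the female's torso
#' (tapping) or only on her wing (not tapping); if they stay connected the
#' bridge is wing-borne and step 6 checks for a leg seen through the
#' translucent wing by two-threshold Otsu segmentation of the foreground,
#' taking the middle-intensity (leg) class and testing whether it bridges
#' the two torsos.
#'
#' @param body_all Logical mask of both flies' silhouettes (one merged
#'   component during contact).
#' @param torso_male,torso_female Per-fly torso masks.
#' @param frame Raw `flycourt_frame` (the arena crop).
#' @param male,female One-row pose tibbles.
#' @param mm_per_px Pixel scale.
#' @param contact_mm Head-tail distance gate in mm.
#' @param skel_prune Minimum skeleton branch length kept when exposing legs.
#' @param erode_radius Disc radius of the step-4 erosion (removes 1-px
#'   skeleton bridges but not wing-width contact).
#' @param denoise_px Minimum component size kept when denoising.
#' @return Logical flag.
#' @export
detect_tapping <- function(body_all, torso_male, torso_female, frame,
                           male, female, mm_per_px,
                           contact_mm = 1, skel_prune = 5,
                           erode_radius = 2, denoise_px = 10) {
  if (!any(body_all) || !any(torso_male) || !any(torso_female)) return(FALSE)
  # step 1: bodies touch -> one silhouette
  if (n_components(body_all) != 1) return(FALSE)
  # step 2: torsos do not touch. The torso image is re-extracted jointly
  # from the merged silhouette (per-fly extraction closes each torso
  # independently and can bridge a sub-kernel gap between the flies).
  wings_all <- extract_wings(frame, body_all)
  torso_all <- extract_torso(body_all, wings_all, n_flies = 2)
  tl <- label8(torso_all)
  sizes <- tabulate(tl[tl > 0])
  big <- which(sizes >= 50)
  if (length(big) != 2) return(FALSE)
  c1 <- matrix(tl == big[1], nrow(tl)); c2 <- matrix(tl == big[2], nrow(tl))
  if (sum(c1 & torso_male) >= sum(c2 & torso_male)) {
    torso_male <- c1; torso_female <- c2
  } else {
    torso_male <- c2; torso_female <- c1
  }
  # step 3: head-tail distance gate
  if (!contact_distance_ok(male, female, mm_per_px, contact_mm)) return(FALSE)

  torsos <- torso_male | torso_female
  # step 4: leg-exposing skeleton image = filled wing/torso shapes plus legs
  # as 1-px branches; union with torsos; erode
  sk5 <- skeletonize(body_all, prune_len = skel_prune)
  leg_image <- mask_open(body_all, erode_radius) | sk5
  with_torso <- leg_image | torsos
  eroded <- mask_erode(with_torso, erode_radius)
  still_connected <- masks_connected(eroded & mask_dilate(torso_male, 1),
                                     eroded & mask_dilate(torso_female, 1),
                                     via = eroded)

  if (!still_connected) {
    # step 5: bare leg -- does the leg branch end on the female's torso?
    sk_full <- skeletonize(body_all, prune_len = 0)
    sans_legs <- leg_image & !sk_full
    tw_area <- mask_close(sans_legs, 2)
    leg_branch <- with_torso & !tw_area
    branched <- remove_small(leg_branch | torsos, denoise_px)
    masks_connected(torso_male, torso_female, via = branched)
  } else {
    # step 6: leg under the wing -- middle Otsu class bridges the torsos?
    # denoising acts on the union with the torsos so that short attached leg
    # traces survive while isolated specks are dropped
    gray <- rgb_gray(frame$pixels)
    fg <- gray * body_all
    th <- otsu_two_thresholds(fg[body_all])
    middle <- body_all & fg > th[1] & fg <= th[2]
    # legs are 1 px wide; a single-pixel dilation keeps the chain connected
    # when isolated leg pixels fall on the wrong side of a threshold
    if (any(middle)) middle <- mask_dilate(middle, 1) & body_all
    bridged <- remove_small(middle | torsos, denoise_px)
    masks_connected(torso_male, torso_female, via = bridged)
  }
}

# Two-threshold (3-class) Otsu on a vector of intensities 0-255: maximize
# between-class variance over all threshold pairs on the 256-bin histogram.
otsu_two_thresholds <- function(v) {
  h <- tabulate(pmin(255, pmax(0, floor(v))) + 1L, nbins = 256)
  p <- h / sum(h)
  lev <- 0:255
  csum <- cumsum(p)
  cmean <- cumsum(p * lev)
  total_mean <- cmean[256]
  best <- c(-Inf, 0, 0)
  for (t1 in 1:254) {
    w0 <- csum[t1]
    if (w0 <= 0) next
    m0 <- cmean[t1] / w0
    for (t2 in (t1 + 1):255) {
      w1 <- csum[t2] - csum[t1]
      w2 <- 1 - csum[t2]
      if (w1 <= 0 || w2 <= 0) next
      m1 <- (cmean[t2] - cmean[t1]) / w1
      m2 <- (total_mean - cmean[t2]) / w2
      vb <- w0 * (m0 - total_mean)^2 + w1 * (m1 - total_mean)^2 + w2 * (m2 - total_mean)^2
      if (vb > best[1]) best <- c(vb, t1 - 1, t2 - 1)
    }
  }
  best[2:3]
}

#' Calibrate the torso-eccentricity standard
#'
#' A straight (unbent) male is maximally eccentric, so the reference is
#' either taken from a user-chosen frame (`manual`) or as the 95th
#' percentile of the male's eccentricity over the first 30 s (`auto`); the
#' standard value is 0.9 x the reference.
#'
#' @param poses Pose tibble containing the male's rows (`fly_id == male_id`).
#' @param mode `"auto"` or `"manual"`.
#' @param frame Frame index of the user-selected straight male (manual mode).
#' @param fps Frames per second (converts the 30-s auto window to frames).
#' @param male_id Identity label of the male.
#' @param factor Multiplier applied to the reference (0.9).
#' @param window_s Auto-mode calibration window in seconds.
#' @return An `ecc_standard` list: `reference`, `standard_value`, `factor`.
#' @export
calibrate_standard <- function(poses, mode = c("auto", "manual"), frame = NULL,
                               fps = 24, male_id = "male", factor = 0.9,
                               window_s = 30) {
  mode <- match.arg(mode)
  mp <- poses[poses$fly_id == male_id & is.finite(poses$eccentricity), ]
  if (nrow(mp) == 0) stop("no valid male torso frames to calibrate from", call. = FALSE)
  if (mode == "manual") {
    if (is.null(frame)) stop("manual calibration needs a frame index", call. = FALSE)
    ref <- mp$eccentricity[mp$frame == frame]
    if (length(ref) != 1) stop("no male pose at calibration frame ", frame, call. = FALSE)
  } else {
    win <- mp[mp$frame < min(mp$frame) + window_s * fps, ]
    ref <- as.numeric(stats::quantile(win$eccentricity, 0.95, names = FALSE))
  }
  if (ref < 0.7) {
    warning("calibration reference eccentricity ", round(ref, 3),
            " < 0.7; the male may be bent in every calibration frame", call. = FALSE)
  }
  structure(list(reference = ref, standard_value = factor * ref, factor = factor),
            class = "ecc_standard")
}

#' Detect attempted copulation
#'
#' The male bends his abdomen to mount, so his torso's moment eccentricity
#' drops below the calibrated standard while his head is within 1 mm of the
#' female's tail; torso connectivity is irrelevant.
#'
#' @param male,female One-row pose tibbles.
#' @param standard An `ecc_standard` from [calibrate_standard()].
#' @param mm_per_px Pixel scale.
#' @param contact_mm Head-tail distance gate in mm.
#' @return Logical flag.
#' @export
detect_attempted_copulation <- function(male, female, standard, mm_per_px,
                                        contact_mm = 1) {
  if (!inherits(standard, "ecc_standard")) {
    stop("attempted-copulation detection needs a calibrated ecc_standard", call. = FALSE)
  }
  male$eccentricity < standard$standard_value &&
    contact_distance_ok(male, female, mm_per_px, contact_mm)
}

#' Temporal noise filter over raw per-frame behavior flags
#'
#' Per frame the raw flags collapse to one candidate by priority
#' (copulation > attempted copulation > tapping > singing > orientation). A
#' behavior is certified at frame t when its candidate appears in more than
#' 5 of the 12 frames ending at t (proportionally at the start of the
#' recording; ties inherit the previous certified label). A frame is
#' labeled `none` only once 12 consecutive frames carry no candidate at
#' all; shorter uncertified stretches keep the previous certified label.
#'
#' @param flags Tibble with logical columns `orientation`, `tapping`,
#'   `singing`, `attempted_copulation`, `copulation` (missing columns are
#'   treated as all-FALSE), one row per frame in order.
#' @param window Certification window length in frames.
#' @param min_hits Certification needs strictly more than this many hits in
#'   the window.
#' @param none_gap Consecutive empty frames required before `none`.
#' @return Character vector of certified labels, one per frame.
#' @export
noise_filter <- function(flags, window = 12, min_hits = 5, none_gap = 12) {
  priority <- c("copulation", "attempted_copulation", "tapping", "singing", "orientation")
  n <- nrow(flags)
  cand <- rep("none", n)
  for (b in rev(priority)) {
    if (b %in% names(flags)) cand[which(flags[[b]])] <- b
  }
  labels <- character(n)
  prev <- "none"
  empty_run <- 0L
  for (t in seq_len(n)) {
    lo <- max(1L, t - window + 1L)
    win <- cand[lo:t]
    avail <- length(win)
    need <- (min_hits / window) * avail
    counts <- table(factor(win[win != "none"], levels = priority))
    certified <- names(counts)[counts > need]
    empty_run <- if (cand[t] == "none") empty_run + 1L else 0L
    if (length(certified) > 0) {
      top <- certified[counts[certified] == max(counts[certified])]
      lab <- if (prev %in% top) prev else top[order(match(top, priority))][1]
      prev <- lab
    } else if (empty_run >= none_gap || prev == "none") {
      lab <- "none"
      prev <- "none"
    } else {
      lab <- prev
    }
    labels[t] <- lab
  }
  labels
}

#' Promote sustained attempted copulation to copulation
#'
#' A maximal run of attempted copulation lasting longer than half a minute
#' is copulation; from the start of that run to the end of the recording
#' every frame is labeled copulation (post-copulation behavior is not
#' scored).
#'
#' @param labels Character label vector from [noise_filter()].
#' @param fps Frames per second.
#' @param cop_seconds Duration threshold in seconds (30).
#' @return Relabeled character vector.
#' @export
promote_copulation <- function(labels, fps, cop_seconds = 30) {
  n <- length(labels)
  if (n == 0) return(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values == "attempted_copulation" & r$lengths > cop_seconds * fps)
  if (length(hit) == 0) return(labels)
  from <- starts[hit[1]]
  labels[from:n] <- "copulation"
  labels
}
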