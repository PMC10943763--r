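# Frame-by-frame two-fly tracker for one arena: segmentation, identity
# assignment with overlap handling, per-fly pose, and post-overlap identity
# verification by torso shape matching.

#' Track a male/female pair through an arena crop sequence
#'
#' Runs background subtraction once (spatial maximum filter on the first
#' frame), then per frame: silhouette segmentation, identity assignment by
#' rectilinear motion prediction (spectral clustering splits merged blobs
#' during overlap), wing/torso extraction, pose characterization, and --
#' on the first frames after an overlap ends -- identity verification by
#' torso shape matching, which can swap a wrong motion-prediction
#' assignment. Torso-part references refresh periodically on clean frames.
#'
#' @param crops List of single-arena `flycourt_frame` objects (see
#'   [crop_arena()]); each carries `mm_per_px`.
#' @param config A [flycourt_config()].
#' @param inject_swap_at Frame index (0-based) at which the identity
#'   assignment is deliberately swapped; used to demonstrate that
#'   verification self-corrects. `NULL` in normal operation.
#' @return List: `poses` (tibble, both flies), `track` (tibble: frame,
#'   fly_id, row, col, overlap_active, verified_this_frame,
#'   dice_head/thorax/abdomen), `tapping` (logical per frame), `gaps`
#'   (frames skipped with reasons), `mm_per_px`, `fps`.
#' @export
track_arena <- function(crops, config = flycourt_config(), inject_swap_at = NULL) {
  stopifnot(length(crops) > 0)
  fps <- crops[[1]]$fps
  mm_per_px <- crops[[1]]$mm_per_px
  if (is.null(mm_per_px)) mm_per_px <- config$arena$mm_per_px
  if (is.null(mm_per_px)) stop("crops carry no mm_per_px and none configured", call. = FALSE)

  bg <- build_background(crops[[1]], config$seg$bg_window_px)
  idc <- config$identity
  ids <- c("male", "female")
  state <- list(
    male = list(pos = NULL, heading = NULL, ref = NULL, ref_area = NA, since_ref = Inf),
    female = list(pos = NULL, heading = NULL, ref = NULL, ref_area = NA, since_ref = Inf)
  )
  overlap_prev <- FALSE
  pending_verify <- FALSE

  poses <- list(); track <- list(); gaps <- list(); vlog <- list()
  tapping <- logical(length(crops))

  for (t in seq_along(crops)) {
    crop <- crops[[t]]
    fidx <- crop$index
    body <- subtract_and_threshold(crop, bg, config$seg$threshold, config$seg$min_obj_px)
    lab <- label8(body)
    sizes <- tabulate(lab[lab > 0])
    comps <- which(sizes >= idc$min_fly_area)
    if (length(comps) == 0) {
      gaps[[length(gaps) + 1]] <- list(frame = fidx, reason = "no fly-sized components")
      next
    }
    if (length(comps) > 2) {
      warning("frame ", fidx, ": ", length(comps),
              " components; keeping the 2 largest", call. = FALSE)
      comps <- comps[order(sizes[comps], decreasing = TRUE)][1:2]
    }
    det_masks <- lapply(comps, function(k) matrix(lab == k, nrow(lab)))
    det_cent <- do.call(rbind, lapply(det_masks, mask_centroid))

    first_frame <- is.null(state$male$pos)
    if (first_frame) {
      if (length(comps) != 2) {
        gaps[[length(gaps) + 1]] <- list(frame = fidx, reason = "need two separated flies to initialize")
        next
      }
      if (!is.null(idc$male_hint)) {
        # the hint is given in full-frame coordinates (the user points at the
        # male on the raw video); map it into the crop
        hint <- idc$male_hint
        if (!is.null(crop$origin)) hint <- hint - crop$origin + 1
        d1 <- dist2(det_cent[1, ], hint); d2 <- dist2(det_cent[2, ], hint)
        ord <- if (d1 <= d2) c(1L, 2L) else c(2L, 1L)
      } else {
        ord <- order(det_cent[, 1] * 1e6 + det_cent[, 2])
      }
      fly_masks <- list(male = det_masks[[ord[1]]], female = det_masks[[ord[2]]])
      overlap_now <- FALSE
    } else {
      preds <- rbind(
        predict_position(state$male$pos),
        predict_position(state$female$pos)
      )
      if (length(comps) == 2) {
        asg <- assign_identities(det_cent, preds)
        fly_masks <- list(male = det_masks[[asg$male]], female = det_masks[[asg$female]])
        overlap_now <- FALSE
      } else {
        # one silhouette: either mere contact (two distinct torsos, e.g. a
        # leg bridging the flies) or a true overlap (torsos merged)
        contact <- split_contact(crop, det_masks[[1]], preds, config)
        if (!is.null(contact)) {
          fly_masks <- contact
          overlap_now <- FALSE
        } else {
          sp <- split_overlap(det_masks[[1]], preds, sigma = idc$sc_sigma,
                              max_points = idc$sc_max_points,
                              min_fly_area = idc$min_fly_area)
          fly_masks <- list(male = sp$male, female = sp$female)
          overlap_now <- TRUE
        }
      }
    }

    if (!is.null(inject_swap_at) && fidx == inject_swap_at) {
      fly_masks <- list(male = fly_masks$female, female = fly_masks$male)
    }

    frame_poses <- list(); frame_parts <- list(male = NULL, female = NULL)
    bad_frame <- FALSE
    for (id in ids) {
      bmask <- fly_masks[[id]]
      wings <- extract_wings(crop, bmask, config$seg$wing_divisor,
                             config$seg$open_radius, config$seg$close_radius)
      torso <- extract_torso(bmask, wings, n_flies = 1,
                             config$seg$open_radius, config$seg$close_radius)
      po <- tryCatch(
        fly_pose(torso, wings, frame_index = fidx, fly_id = id,
                 prev_heading = state[[id]]$heading),
        error = function(e) NULL
      )
      if (is.null(po)) { bad_frame <- TRUE; break }
      frame_poses[[id]] <- po
      attr(frame_poses[[id]], "torso") <- torso
    }
    if (bad_frame) {
      gaps[[length(gaps) + 1]] <- list(frame = fidx, reason = "pose fit failed")
      next
    }

    # post-overlap identity verification by torso shape matching
    verified <- FALSE
    dice <- rep(NA_real_, 3)
    if (overlap_prev && !overlap_now) pending_verify <- TRUE
    if (pending_verify && !overlap_now &&
        !is.null(state$male$ref) && !is.null(state$female$ref)) {
      cand <- lapply(ids, function(id) {
        po <- frame_poses[[id]]
        torso <- attr(po, "torso")
        if (!verify_usable(po, sum(torso), state[[id]]$ref_area, idc)) return(NULL)
        can <- canonicalize_torso(torso, head = c(po$head_row, po$head_col))
        segment_torso_parts(can$mask, tol_frac = idc$tol_frac)
      })
      if (is.null(cand[[1]]) || is.null(cand[[2]])) {
        vlog[[length(vlog) + 1]] <- tibble::tibble(
          frame = fidx, attempted = FALSE, pass = NA, swapped = NA,
          s11 = NA_real_, s22 = NA_real_, s12 = NA_real_, s21 = NA_real_)
      }
      if (!is.null(cand[[1]]) && !is.null(cand[[2]])) {
        res <- verify_identities(cand, list(state$male$ref, state$female$ref),
                                 threshold = idc$dice_threshold)
        vlog[[length(vlog) + 1]] <- tibble::tibble(
          frame = fidx, attempted = TRUE, pass = res$pass, swapped = res$swapped,
          s11 = res$scores["straight1"], s22 = res$scores["straight2"],
          s12 = res$scores["swapped1"], s21 = res$scores["swapped2"])
        if (res$pass) {
          pending_verify <- FALSE
          verified <- TRUE
          dice <- res$dice["male", ]
          if (res$swapped) {
            frame_poses <- list(male = frame_poses$female, female = frame_poses$male)
            frame_poses$male$fly_id <- "male"; frame_poses$female$fly_id <- "female"
            # kinematic histories follow the relabeled blobs; the stored
            # reference parts define identity and stay put
            for (fld in c("pos", "heading")) {
              tmp <- state$male[[fld]]
              state$male[[fld]] <- state$female[[fld]]
              state$female[[fld]] <- tmp
            }
          }
        }
      }
    }

    # update state and references
    for (id in ids) {
      po <- frame_poses[[id]]
      state[[id]]$pos <- utils::tail(rbind(state[[id]]$pos, c(po$row, po$col)), 2)
      state[[id]]$heading <- deg2vec(po$heading_deg)
      state[[id]]$since_ref <- state[[id]]$since_ref + 1
      if (!overlap_now && state[[id]]$since_ref >= idc$refresh_every) {
        torso <- attr(po, "torso")
        if (verify_usable(po, sum(torso), state[[id]]$ref_area, idc)) {
          can <- canonicalize_torso(torso, head = c(po$head_row, po$head_col))
          parts <- segment_torso_parts(can$mask, tol_frac = idc$tol_frac)
          if (!is.null(parts)) {
            state[[id]]$ref <- parts
            state[[id]]$ref_area <- sum(torso)
            state[[id]]$since_ref <- 0
          }
        }
      }
      poses[[length(poses) + 1]] <- po
      track[[length(track) + 1]] <- tibble::tibble(
        frame = fidx, fly_id = id, row = po$row, col = po$col,
        overlap_active = overlap_now, verified_this_frame = verified,
        dice_head = dice[1], dice_thorax = dice[2], dice_abdomen = dice[3]
      )
    }
    overlap_prev <- overlap_now

    # tapping needs the masks, so it is detected in-loop
    if (!overlap_now) {
      tapping[t] <- isTRUE(tryCatch(
        detect_tapping(body, attr(frame_poses$male, "torso"),
                       attr(frame_poses$female, "torso"), crop,
                       frame_poses$male, frame_poses$female, mm_per_px,
                       contact_mm = config$behavior$contact_mm,
                       skel_prune = config$behavior$tap_skel_prune,
                       erode_radius = config$behavior$tap_erode_radius,
                       denoise_px = config$behavior$tap_denoise_px),
        error = function(e) FALSE
      ))
    }
  }

  list(
    poses = dplyr::bind_rows(poses),
    track = dplyr::bind_rows(track),
    tapping = tapping,
    gaps = gaps,
    verification = dplyr::bind_rows(vlog),
    mm_per_px = mm_per_px,
    fps = fps
  )
}

# A single silhouette whose torso extraction still yields two fly-sized
# torsos is contact, not overlap: the body pixels are split by proximity to
# the nearer torso and identities follow motion prediction. Returns NULL
# when the torsos have merged (true overlap).
split_contact <- function(crop, blob, preds, config) {
  wings <- extract_wings(crop, blob, config$seg$wing_divisor,
                         config$seg$open_radius, config$seg$close_radius)
  torso <- extract_torso(blob, wings, n_flies = 2,
                         config$seg$open_radius, config$seg$close_radius)
  tl <- label8(torso)
  sizes <- tabulate(tl[tl > 0])
  big <- which(sizes >= 0.3 * config$identity$min_fly_area)
  if (length(big) != 2) return(NULL)
  t1 <- matrix(tl == big[1], nrow(tl)); t2 <- matrix(tl == big[2], nrow(tl))
  d1 <- EBImage::imageData(EBImage::distmap(1 - t1 * 1))
  d2 <- EBImage::imageData(EBImage::distmap(1 - t2 * 1))
  m1 <- blob & (d1 <= d2)
  m2 <- blob & !m1
  asg <- assign_identities(rbind(mask_centroid(t1), mask_centroid(t2)), preds)
  if (asg$male == 1) list(male = m1, female = m2) else list(male = m2, female = m1)
}

# skip-verification guard: aberrant postures (wall climbing) distort the
# torso, so matching is deferred when eccentricity or area leave the
# plausible range.
verify_usable <- function(po, area, ref_area, idc) {
  if (!is.finite(po$eccentricity)) return(FALSE)
  if (po$eccentricity < idc$ecc_skip[1] || po$eccentricity > idc$ecc_skip[2]) return(FALSE)
  if (is.finite(ref_area) && !is.na(ref_area)) {
    if (area < idc$area_skip[1] * ref_area || area > idc$area_skip[2] * ref_area) return(FALSE)
  }
  TRUE
}

#' Classify per-frame behavior from a tracking result
#'
#' Computes the raw per-frame flags (singing and orientation from poses,
#' attempted copulation from poses plus the calibrated eccentricity
#' standard, tapping from the in-loop mask cascade), applies the temporal
#' noise filter and the half-minute copulation promotion.
#'
#' @param tr Result of [track_arena()].
#' @param config A [flycourt_config()].
#' @return Tibble: `frame`, `raw_flags` (semicolon-joined), `label`.
#' @export
classify_behaviors <- function(tr, config = flycourt_config()) {
  bh <- config$behavior
  males <- tr$poses[tr$poses$fly_id == "male", ]
  females <- tr$poses[tr$poses$fly_id == "female", ]
  frames <- sort(intersect(males$frame, females$frame))
  std <- calibrate_standard(tr$poses, mode = bh$calib_mode, frame = bh$calib_frame,
                            fps = tr$fps, factor = bh$ecc_factor,
                            window_s = bh$calib_window_s)
  n <- length(frames)
  flags <- tibble::tibble(
    frame = frames,
    orientation = logical(n), tapping = logical(n), singing = logical(n),
    attempted_copulation = logical(n), copulation = logical(n)
  )
  tap_by_frame <- stats::setNames(tr$tapping, vapply(seq_along(tr$tapping), function(i) i - 1L, numeric(1)))
  for (i in seq_len(n)) {
    m <- males[males$frame == frames[i], ][1, ]
    f <- females[females$frame == frames[i], ][1, ]
    flags$singing[i] <- detect_singing(m, bh$singing_deg)
    flags$orientation[i] <- detect_orientation(m, f, bh$orient_ext, bh$orient_halfangle)
    flags$attempted_copulation[i] <- detect_attempted_copulation(
      m, f, std, tr$mm_per_px, bh$contact_mm)
  }
  # tapping vector is positional over the crop list; match on frame index
  tap_idx <- match(as.character(flags$frame), names(tap_by_frame))
  flags$tapping <- ifelse(is.na(tap_idx), FALSE, tr$tapping[tap_idx])
  labels <- noise_filter(flags, window = config$filter$window,
                         min_hits = config$filter$min_hits,
                         none_gap = config$filter$none_gap)
  labels <- promote_copulation(labels, fps = tr$fps, cop_seconds = bh$cop_seconds)
  raw <- apply(flags[, c("copulation", "attempted_copulation", "tapping",
                         "singing", "orientation")], 1, function(r) {
    paste(names(r)[as.logical(r)], collapse = ";")
  })
  tibble::tibble(frame = frames, raw_flags = raw, label = labels)
}
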