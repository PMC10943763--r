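# Second central moments of a pixel set; population covariance, no
# continuity correction, so a brute-force covariance oracle agrees exactly.
mask_moments <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  dr <- idx[, 1] - ctr[1]; dc <- idx[, 2] - ctr[2]
  cv <- matrix(c(sum(dr * dr), sum(dr * dc), sum(dr * dc), sum(dc * dc)) / n, 2, 2)
  e <- eigen(cv, symmetric = TRUE)
  list(centroid = ctr, values = e$values, vectors = e$vectors, n = n)
}

#' Fit the torso's moment-equivalent ellipse
#'
#' The torso centroid is the fly's position; axes and orientation come from
#' the second central moments, and the two major-axis endpoints are the
#' head/tail candidates.
#'
#' @param torso Logical torso mask with a single connected component of at
#'   least 20 px.
#' @return List: `centroid` (row, col), `major_px`/`minor_px`
#'   (moment-equivalent full axis lengths), `orientation_deg` (axis angle,
#'   defined up to 180°), `eccentricity`, `candidates` (2 x 2 matrix of the
#'   axis endpoints), `orientation_undefined` (TRUE for circularly symmetric
#'   masks), `area_px`.
#' @export
fit_torso <- function(torso) {
  if (!any(torso)) stop("empty torso mask", call. = FALSE)
  if (n_components(torso) != 1) stop("torso mask must have one connected component", call. = FALSE)
  mm <- mask_moments(torso)
  if (mm$n < 20) stop("torso too small to fit (< 20 px)", call. = FALSE)
  l1 <- mm$values[1]; l2 <- mm$values[2]
  undefined <- (l1 - l2) / max(l1, 1e-12) < 1e-3
  axis <- mm$vectors[, 1]
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- sqrt(max(0, 1 - l2 / max(l1, 1e-12)))
  cand <- rbind(mm$centroid + (major / 2) * axis,
                mm$centroid - (major / 2) * axis)
  list(centroid = mm$centroid, major_px = major, minor_px = minor,
       orientation_deg = vec2deg(axis) %% 180, eccentricity = ecc,
       candidates = cand, orientation_undefined = undefined, area_px = mm$n)
}

#' Assign head and tail among the major-axis endpoints
#'
#' The wings trail behind the fly, pulling the whole-body centroid tailward,
#' so the candidate farther from the body centroid is the head. Near-ties
#' (folded wings on a symmetric body) are resolved by heading continuity
#' with the previous frame.
#'
#' @param candidates 2 x 2 matrix of (row, col) endpoints from [fit_torso()].
#' @param torso_centroid Torso centroid (row, col).
#' @param body_centroid Centroid of the full body mask (torso plus wings).
#' @param prev_heading Unit heading vector from the previous frame, used only
#'   when the candidate distances tie within 0.5 px.
#' @return List: `head`, `tail` (row, col), `ambiguous` flag.
#' @export
assign_head_tail <- function(candidates, torso_centroid, body_centroid,
                             prev_heading = NULL) {
  d1 <- dist2(candidates[1, ], body_centroid)
  d2 <- dist2(candidates[2, ], body_centroid)
  ambiguous <- abs(d1 - d2) < 0.5
  if (!ambiguous) {
    hi <- if (d1 > d2) 1 else 2
  } else if (!is.null(prev_heading)) {
    dir1 <- candidates[1, ] - torso_centroid
    hi <- if (sum(dir1 * prev_heading) > 0) 1 else 2
  } else {
    hi <- 1
  }
  list(head = candidates[hi, ], tail = candidates[3 - hi, ], ambiguous = ambiguous)
}

#' Measure wing extension angles
#'
#' Edge pixels of the wing mask are split into the fly's left and right
#' sides by the sign of the cross product of the heading with each pixel's
#' wing vector (pixel minus torso centroid). Per side, the edge pixel
#' farthest from the torso centroid is the wingtip, and the extension angle
#' is measured between the tailward major-axis direction and the tip vector,
#' so folded wings give ~0° and full extension ~90°.
#'
#' @param wings Logical wings mask (may be empty).
#' @param torso_centroid Torso centroid (row, col).
#' @param heading Unit heading vector (row, col).
#' @return List: `theta_left`, `theta_right` (degrees in `[0, 180)`; 0 for an
#'   empty side), `tip_left`, `tip_right` ((row, col) or NULL).
#' @export
wing_angles <- function(wings, torso_centroid, heading) {
  if (!any(wings)) {
    return(list(theta_left = 0, theta_right = 0, tip_left = NULL, tip_right = NULL))
  }
  edge <- mask_boundary(wings)
  idx <- which(edge, arr.ind = TRUE)
  vr <- idx[, 1] - torso_centroid[1]; vc <- idx[, 2] - torso_centroid[2]
  cr <- heading[1] * vc - heading[2] * vr
  d <- sqrt(vr^2 + vc^2)
  tailward <- -heading
  one_side <- function(sel) {
    if (!any(sel)) return(list(theta = 0, tip = NULL))
    i <- which(sel)[which.max(d[sel])]
    tip <- c(idx[i, 1], idx[i, 2])
    theta <- angle_between(tailward, tip - torso_centroid)
    list(theta = min(theta, 180 - 1e-9), tip = tip)
  }
  left <- one_side(cr > 1e-9)
  right <- one_side(cr < -1e-9)
  list(theta_left = left$theta, theta_right = right$theta,
       tip_left = left$tip, tip_right = right$tip)
}

#' Full per-fly pose from its masks
#'
#' Combines [fit_torso()], [assign_head_tail()] and [wing_angles()] into one
#' tidy pose row.
#'
#' @param torso,wings Logical masks for one fly.
#' @param frame_index Frame ordinal stamped on the row.
#' @param fly_id Identity label stamped on the row.
#' @param prev_heading Optional previous unit heading for tie-breaking.
#' @return One-row tibble: `frame`, `fly_id`, `row`, `col`, `body_row`,
#'   `body_col`, `head_row`, `head_col`, `tail_row`, `tail_col`,
#'   `heading_deg`, `theta_left`, `theta_right`, `eccentricity`, `major_px`,
#'   `minor_px`, `area_px`, `head_ambiguous`, `orientation_undefined`.
#' @export
fly_pose <- function(torso, wings, frame_index = 0, fly_id = "male",
                     prev_heading = NULL) {
  ft <- fit_torso(torso)
  body_ctr <- mask_centroid(torso | wings)
  ht <- assign_head_tail(ft$candidates, ft$centroid, body_ctr, prev_heading)
  hv <- ht$head - ft$centroid
  nh <- sqrt(sum(hv^2))
  heading <- if (nh > 0) hv / nh else c(0, 1)
  wa <- wing_angles(wings, ft$centroid, heading)
  tibble::tibble(
    frame = frame_index, fly_id = fly_id,
    row = ft$centroid[1], col = ft$centroid[2],
    body_row = body_ctr[1], body_col = body_ctr[2],
    head_row = ht$head[1], head_col = ht$head[2],
    tail_row = ht$tail[1], tail_col = ht$tail[2],
    heading_deg = vec2deg(heading),
    theta_left = wa$theta_left, theta_right = wa$theta_right,
    eccentricity = ft$eccentricity,
    major_px = ft$major_px, minor_px = ft$minor_px, area_px = ft$area_px,
    head_ambiguous = ht$ambiguous,
    orientation_undefined = ft$orientation_undefined
  )
}
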