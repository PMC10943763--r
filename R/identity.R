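#' Predict a fly's next position by rectilinear motion
#'
#' Constant-velocity extrapolation over one frame interval from the last two
#' known positions; with fewer than two positions the last known position is
#' returned unchanged.
#'
#' @param positions Matrix with one (row, col) position per row, oldest
#'   first; usually the fly's last two tracked positions.
#' @return Predicted (row, col).
#' @export
predict_position <- function(positions) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (n == 0) stop("no known positions", call. = FALSE)
  if (n == 1) return(as.numeric(positions[1, ]))
  p1 <- positions[n - 1, ]; p2 <- positions[n, ]
  as.numeric(p2 + (p2 - p1))
}

#' Assign detections to fly identities
#'
#' With two detections, the pairing minimizing the total distance to the
#' motion predictions is chosen; with one detection both identities map to
#' the single merged blob and the overlap flag is raised.
#'
#' @param detections Matrix of detection centroids, one (row, col) per row
#'   (1 or 2 rows; callers trim extras to the 2 largest components).
#' @param predictions 2 x 2 matrix of predicted (row, col), male first.
#' @return List: `male`, `female` (detection indices; equal during overlap),
#'   `overlap` flag.
#' @export
assign_identities <- function(detections, predictions) {
  detections <- rbind(detections)
  if (nrow(detections) == 1) {
    return(list(male = 1L, female = 1L, overlap = TRUE))
  }
  d <- function(i, j) dist2(detections[i, ], predictions[j, ])
  straight <- d(1, 1) + d(2, 2)
  crossed <- d(1, 2) + d(2, 1)
  if (straight <= crossed) list(male = 1L, female = 2L, overlap = FALSE)
  else list(male = 2L, female = 1L, overlap = FALSE)
}

#' Split a merged two-fly silhouette by spectral clustering
#'
#' Builds a Gaussian affinity on pixel coordinates (bandwidth = half a
#' typical torso minor axis), embeds with the two leading eigenvectors of
#' the normalized affinity, and partitions with seeded k-means initialized
#' at the two most separated embedded points, so the split is deterministic.
#' Large blobs are subsampled on a regular stride and remaining pixels join
#' their nearest sampled pixel's cluster. Identities are attached by
#' proximity of cluster centroids to the motion predictions. Blobs smaller
#' than twice the minimum fly area are treated as one fly fully occluding
#' the other.
#'
#' @param body Logical mask of the merged blob.
#' @param predictions 2 x 2 matrix of predicted (row, col), male first.
#' @param sigma Affinity bandwidth in px.
#' @param max_points Subsample size for the eigen decomposition.
#' @param min_fly_area Minimum credible single-fly area in px.
#' @return List: `male`, `female` (logical masks), `single` (TRUE when the
#'   fully-occluded fallback was taken, in which case both masks equal the
#'   blob).
#' @export
split_overlap <- function(body, predictions, sigma = 8, max_points = 400,
                          min_fly_area = 150) {
  pix <- which(body, arr.ind = TRUE)
  n <- nrow(pix)
  if (n < 2 * min_fly_area) {
    return(list(male = body, female = body, single = TRUE))
  }
  take <- unique(round(seq(1, n, length.out = min(n, max_points))))
  pts <- pix[take, , drop = FALSE]
  m <- nrow(pts)
  dd <- as.matrix(stats::dist(pts))^2
  a <- exp(-dd / (2 * sigma^2))
  dg <- 1 / sqrt(rowSums(a))
  l <- a * outer(dg, dg)
  ev <- eigen(l, symmetric = TRUE)
  y <- ev$vectors[, 1:2]
  y <- y / pmax(sqrt(rowSums(y^2)), 1e-12)
  # deterministic seeding: the two embedded points farthest apart
  d1 <- rowSums((y - matrix(y[1, ], m, 2, byrow = TRUE))^2)
  i1 <- which.max(d1)
  d2 <- rowSums((y - matrix(y[i1, ], m, 2, byrow = TRUE))^2)
  i2 <- which.max(d2)
  km <- stats::kmeans(y, centers = y[c(i1, i2), , drop = FALSE], iter.max = 100)
  cl_sample <- km$cluster
  # all pixels follow their nearest sampled pixel
  cl <- cl_sample[nearest_index(pix, pts)]
  m1 <- body & FALSE; m1[pix[cl == 1, , drop = FALSE]] <- TRUE
  m2 <- body & FALSE; m2[pix[cl == 2, , drop = FALSE]] <- TRUE
  c1 <- mask_centroid(m1); c2 <- mask_centroid(m2)
  straight <- dist2(c1, predictions[1, ]) + dist2(c2, predictions[2, ])
  crossed <- dist2(c1, predictions[2, ]) + dist2(c2, predictions[1, ])
  if (straight <= crossed) list(male = m1, female = m2, single = FALSE)
  else list(male = m2, female = m1, single = FALSE)
}

# Index of the nearest row of ref for each row of q (small ref; vectorized
# over ref rows).
nearest_index <- function(q, ref) {
  best_d <- rep(Inf, nrow(q)); best_i <- rep(1L, nrow(q))
  for (i in seq_len(nrow(ref))) {
    d <- (q[, 1] - ref[i, 1])^2 + (q[, 2] - ref[i, 2])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]; best_i[upd] <- i
  }
  best_i
}

#' Rotate a torso into its canonical frame
#'
#' Rotates the mask so the major axis is horizontal, reflects if needed so
#' the head is on the left, and crops to the bounding box. Nearest-neighbour
#' resampling keeps the mask binary.
#'
#' @param torso Logical torso mask (single component).
#' @param head Optional (row, col) head point; when missing the torso is
#'   aligned by axis only and flagged head-ambiguous.
#' @return List: `mask` (cropped canonical mask), `head_known` flag.
#' @export
canonicalize_torso <- function(torso, head = NULL) {
  mm <- mask_moments(torso)
  angle <- vec2deg(mm$vectors[, 1])
  nr <- nrow(torso); nc <- ncol(torso)
  s <- ceiling(sqrt(nr^2 + nc^2)) + 2L
  out_ctr <- c((s + 1) / 2, (s + 1) / 2)
  dst <- cbind(rep(seq_len(s), times = s), rep(seq_len(s), each = s))
  rel <- cbind(dst[, 1] - out_ctr[1], dst[, 2] - out_ctr[2])
  a <- angle * pi / 180
  src_r <- round(mm$centroid[1] + rel[, 1] * cos(a) - rel[, 2] * sin(a))
  src_c <- round(mm$centroid[2] + rel[, 2] * cos(a) + rel[, 1] * sin(a))
  ok <- src_r >= 1 & src_r <= nr & src_c >= 1 & src_c <= nc
  vals <- rep(FALSE, nrow(dst))
  vals[ok] <- torso[cbind(src_r[ok], src_c[ok])]
  can <- matrix(vals, s, s)
  head_known <- !is.null(head)
  if (head_known) {
    hrel <- head - mm$centroid
    hc <- rot2(hrel, -angle) + out_ctr
    if (hc[2] > out_ctr[2]) can <- can[, rev(seq_len(s))]
  }
  idx <- which(can, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1]); c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  list(mask = can[r0:r1, c0:c1, drop = FALSE], head_known = head_known)
}

#' Segment a canonical torso into head, thorax and abdomen
#'
#' Watershed on the Euclidean distance map of the torso interior (the lobes
#' of the body become basins of the negated map). Shallow minima are
#' suppressed with an automatically chosen depth threshold of 0.3 x the
#' maximum distance value, halved once if fewer than three segments emerge;
#' if the torso still will not split (e.g. a featureless ellipse) the result
#' is `NULL` and identity verification is deferred to a later frame.
#'
#' @param aligned Canonical torso mask from [canonicalize_torso()].
#' @param tol_frac Initial minima-suppression depth as a fraction of the
#'   maximum distance value.
#' @return A `torso_parts` list (`head`, `thorax`, `abdomen` disjoint masks
#'   whose union is the torso, ordered left to right) or `NULL`.
#' @export
segment_torso_parts <- function(aligned, tol_frac = 0.3) {
  d <- EBImage::distmap(aligned * 1)
  dmax <- max(d)
  if (dmax <= 0) return(NULL)
  lab <- NULL
  for (frac in c(tol_frac, tol_frac / 2)) {
    w <- EBImage::imageData(EBImage::watershed(d, tolerance = frac * dmax))
    if (max(w) >= 3) { lab <- w; break }
  }
  if (is.null(lab)) {
    # a decapitated fly's torso is two-lobed: accept a 2-basin split with an
    # empty head part (two empty heads compare as identical)
    for (frac in c(tol_frac, tol_frac / 2)) {
      w <- EBImage::imageData(EBImage::watershed(d, tolerance = frac * dmax))
      if (max(w) == 2) { lab <- w; break }
    }
    if (is.null(lab)) return(NULL)
    sizes <- tabulate(lab[lab > 0])
    cents <- lapply(1:2, function(k) mask_centroid(lab == k))
    ord <- order(vapply(1:2, function(k) cents[[k]][2], numeric(1)))
    return(structure(list(
      head = blank_mask(nrow(lab), ncol(lab)),
      thorax = matrix(lab == ord[1], nrow(lab)),
      abdomen = matrix(lab == ord[2], nrow(lab))
    ), class = "torso_parts"))
  }
  sizes <- tabulate(lab[lab > 0])
  main <- order(sizes, decreasing = TRUE)[1:3]
  cents <- lapply(seq_along(sizes), function(k) mask_centroid(lab == k))
  # fold any extra small segments into the nearest main segment
  for (k in setdiff(which(sizes > 0), main)) {
    dmin <- vapply(main, function(j) dist2(cents[[k]], cents[[j]]), numeric(1))
    lab[lab == k] <- main[which.min(dmin)]
  }
  ord <- main[order(vapply(main, function(j) cents[[j]][2], numeric(1)))]
  structure(list(
    head = matrix(lab == ord[1], nrow(lab)),
    thorax = matrix(lab == ord[2], nrow(lab)),
    abdomen = matrix(lab == ord[3], nrow(lab))
  ), class = "torso_parts")
}

#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks count as identical (1).
#'
#' @param a,b Logical masks on a common grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Dice after centroid alignment on a shared zero-padded grid, making the
# comparison translation-invariant so shape is the only signal.
aligned_dice <- function(a, b) {
  if (!any(a) && !any(b)) return(1)
  if (!any(a) || !any(b)) return(0)
  ca <- mask_centroid(a); cb <- mask_centroid(b)
  ia <- which(a, arr.ind = TRUE); ib <- which(b, arr.ind = TRUE)
  ra <- sweep(ia, 2, round(ca)); rb <- sweep(ib, 2, round(cb))
  all_r <- c(ra[, 1], rb[, 1]); all_c <- c(ra[, 2], rb[, 2])
  off_r <- 1 - min(all_r); off_c <- 1 - min(all_c)
  nr <- max(all_r) + off_r; nc <- max(all_c) + off_c
  ma <- matrix(FALSE, nr, nc); mb <- matrix(FALSE, nr, nc)
  ma[cbind(ra[, 1] + off_r, ra[, 2] + off_c)] <- TRUE
  mb[cbind(rb[, 1] + off_r, rb[, 2] + off_c)] <- TRUE
  dice_coefficient(ma, mb)
}

# max + min of the three per-part aligned Dice values.
parts_score <- function(cand, ref) {
  dv <- c(head = aligned_dice(cand$head, ref$head),
          thorax = aligned_dice(cand$thorax, ref$thorax),
          abdomen = aligned_dice(cand$abdomen, ref$abdomen))
  list(score = max(dv) + min(dv), dice = dv)
}

#' Verify identities after an overlap by torso shape matching
#'
#' Each candidate torso's head/thorax/abdomen parts are compared to both
#' stored references with per-part, centroid-aligned Dice coefficients; a
#' pairing counts as the same identity when the sum of the maximum and
#' minimum of its three Dice values exceeds the threshold. The pairing for
#' which both flies pass is adopted (overriding motion prediction if
#' needed); when neither or both pairings pass, the motion-prediction
#' assignment is kept and verification is retried on a later frame.
#'
#' @param candidates List of two `torso_parts` (current frame, in
#'   motion-prediction order: male, female).
#' @param references List of two `torso_parts` (stored references, male,
#'   female).
#' @param threshold Identity acceptance threshold on max + min of the three
#'   Dice values (1.6).
#' @return List: `order` (`c(1, 2)` keeps the motion-prediction assignment,
#'   `c(2, 1)` swaps it), `pass`, `swapped`, and `dice` (the per-part Dice
#'   values of the adopted pairing).
#' @export
verify_identities <- function(candidates, references, threshold = 1.6) {
  s11 <- parts_score(candidates[[1]], references[[1]])
  s22 <- parts_score(candidates[[2]], references[[2]])
  s12 <- parts_score(candidates[[1]], references[[2]])
  s21 <- parts_score(candidates[[2]], references[[1]])
  scores <- c(straight1 = s11$score, straight2 = s22$score,
              swapped1 = s12$score, swapped2 = s21$score)
  pass_straight <- s11$score > threshold && s22$score > threshold
  pass_swapped <- s12$score > threshold && s21$score > threshold
  if (pass_straight && !pass_swapped) {
    list(order = c(1L, 2L), pass = TRUE, swapped = FALSE, scores = scores,
         dice = rbind(male = s11$dice, female = s22$dice))
  } else if (pass_swapped && !pass_straight) {
    list(order = c(2L, 1L), pass = TRUE, swapped = TRUE, scores = scores,
         dice = rbind(male = s21$dice, female = s12$dice))
  } else {
    list(order = c(1L, 2L), pass = FALSE, swapped = FALSE, scores = scores,
         dice = rbind(male = s11$dice, female = s22$dice))
  }
}
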