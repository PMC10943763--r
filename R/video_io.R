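#' Read frames from a numbered image sequence
#'
#' Reads a directory of numbered PNG/TIFF/JPEG frames (lexicographic order) as
#' produced by the rig's frame grabber or by [write_frames()]. Video
#' containers are not read directly; export the recording to an image
#' sequence first.
#'
#' @param source Directory containing the image sequence.
#' @param start,stop 0-based index range to read (inclusive); `stop < start`
#'   yields an empty list.
#' @param fps Frame rate to stamp on each frame (frames/s); the rig records
#'   at 24.
#' @return List of `flycourt_frame` objects with contiguous 0-based indices.
#' @export
read_frames <- function(source, start = 0, stop = Inf, fps = 24) {
  if (stop < start) return(list())
  if (file.exists(source) && !dir.exists(source)) {
    if (grepl("\\.(avi|mp4|mov|mkv)$", tolower(source))) {
      stop("video containers are not read directly; export '", source,
           "' to a PNG/TIFF image sequence first", call. = FALSE)
    }
    stop("source must be a directory of numbered images: ", source, call. = FALSE)
  }
  if (!dir.exists(source)) stop("unreadable source: ", source, call. = FALSE)
  files <- sort(list.files(source, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no image frames found in ", source, call. = FALSE)
  idx <- seq_along(files) - 1L
  keep <- idx >= start & idx <= stop
  files <- files[keep]; idx <- idx[keep]
  dims <- NULL
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    px <- read_frame_file(files[i])
    if (is.null(dims)) dims <- dim(px)
    if (!identical(dim(px), dims)) {
      stop("inconsistent frame size at ", files[i], call. = FALSE)
    }
    out[[i]] <- structure(list(pixels = px, index = idx[i], fps = fps),
                          class = "flycourt_frame")
  }
  out
}

read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF frames requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(raw)) == 2) {
    arr <- array(raw, dim = c(dim(raw), 3))
  } else {
    arr <- raw[, , 1:3, drop = FALSE]
  }
  out <- round(arr * 255)
  storage.mode(out) <- "integer"
  out
}

#' Detect circular arena regions of interest
#'
#' Circle Hough transform on the gradient of the first frame: each strong
#' edge pixel votes for circle centres along its gradient direction over the
#' candidate radius range (coarse-to-fine). Arenas appear as bright discs on
#' a darker surround, so their rims are the dominant circular edges.
#'
#' @param frame A `flycourt_frame`.
#' @param expected_count Number of arenas in view (4 on the standard rig).
#' @param radius_range Candidate radius range in px; default
#'   `c(0.12, 0.48) * min(frame dims)`.
#' @param min_coverage Minimum fraction of the circle's angular bins that
#'   must contain a fitted edge inlier before a candidate counts as an
#'   arena (rejects spurious accumulator peaks and blank frames).
#' @param arena_diameter_mm Physical arena diameter used to derive the pixel
#'   scale (11 mm on this rig).
#' @return Tibble with one row per arena, sorted row-major: `arena_id`
#'   (0-based), `row`, `col`, `radius`, `mm_per_px`.
#' @export
detect_arenas <- function(frame, expected_count = 4, radius_range = NULL,
                          min_coverage = 0.5, arena_diameter_mm = 11) {
  gray <- rgb_gray(frame$pixels)
  nr <- nrow(gray); nc <- ncol(gray)
  if (is.null(radius_range)) radius_range <- c(0.12, 0.48) * min(nr, nc)
  coarse <- seq(max(5, radius_range[1]), radius_range[2], by = 3)
  cand <- hough_circles(gray, coarse, n_peaks = max(30, expected_count * 8))
  edges <- edge_points(gray)
  # refine every accumulator candidate and rank by rim coverage, so fly-edge
  # pseudo-circles (high votes, poor circular fit) cannot displace an arena
  fits <- list()
  for (i in seq_len(nrow(cand))) {
    fit <- refine_circle(edges, c(cand$row[i], cand$col[i]), cand$radius[i])
    if (!is.null(fit) && fit$coverage >= min_coverage &&
        fit$radius >= radius_range[1] && fit$radius <= radius_range[2]) {
      fits[[length(fits) + 1]] <- fit
    }
  }
  found <- list()
  if (length(fits) > 0) {
    fits <- fits[order(vapply(fits, function(f) f$coverage, numeric(1)), decreasing = TRUE)]
    for (f in fits) {
      clash <- any(vapply(found, function(g) {
        dist2(c(f$row, f$col), c(g$row, g$col)) < 0.7 * max(f$radius, g$radius)
      }, logical(1)))
      if (!clash) found[[length(found) + 1]] <- f
      if (length(found) >= expected_count) break
    }
  }
  if (length(found) < expected_count) {
    stop(sprintf("%d of %d arenas found", length(found), expected_count), call. = FALSE)
  }
  df <- dplyr::bind_rows(lapply(found, tibble::as_tibble))
  rmed <- stats::median(df$radius)
  df <- df[order(floor((df$row - min(df$row)) / (1.2 * rmed)), df$col), ]
  tibble::tibble(
    arena_id = seq_len(nrow(df)) - 1L,
    row = df$row, col = df$col, radius = df$radius,
    mm_per_px = arena_diameter_mm / (2 * df$radius)
  )
}

# Strong gradient pixels of a grayscale image: matrix of (row, col).
edge_points <- function(gray) {
  nr <- nrow(gray); nc <- ncol(gray)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (gray[3:nr, ] - gray[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (gray[, 3:nc] - gray[, 1:(nc - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  thr <- 0.5 * stats::quantile(mag, 0.999)
  which(mag > thr, arr.ind = TRUE)
}

# Kasa algebraic circle fit on edge points near a candidate circle, iterated
# twice, plus angular-coverage scoring (fraction of 72 angular bins holding
# an inlier within 2 px of the fitted rim).
refine_circle <- function(edges, center, radius) {
  for (it in 1:2) {
    d <- sqrt((edges[, 1] - center[1])^2 + (edges[, 2] - center[2])^2)
    sel <- abs(d - radius) <= 5
    if (sum(sel) < 10) return(NULL)
    p <- edges[sel, , drop = FALSE]
    a <- cbind(2 * p[, 1], 2 * p[, 2], 1)
    b <- p[, 1]^2 + p[, 2]^2
    sol <- tryCatch(qr.solve(a, b), error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    center <- c(sol[1], sol[2])
    radius <- sqrt(max(sol[3] + sum(center^2), 1))
  }
  d <- sqrt((edges[, 1] - center[1])^2 + (edges[, 2] - center[2])^2)
  inl <- abs(d - radius) <= 2
  if (sum(inl) < 10) return(NULL)
  ang <- atan2(edges[inl, 1] - center[1], edges[inl, 2] - center[2])
  coverage <- length(unique(floor((ang + pi) / (2 * pi) * 72))) / 72
  list(row = center[1], col = center[2], radius = radius, coverage = coverage)
}

# Gradient-directed circle Hough accumulator. Returns candidate circles as a
# tibble (row, col, radius, votes), strongest first (votes normalized by r).
hough_circles <- function(gray, radii, n_peaks = 4, window = NULL) {
  nr <- nrow(gray); nc <- ncol(gray)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (gray[3:nr, ] - gray[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (gray[, 3:nc] - gray[, 1:(nc - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  thr <- 0.5 * stats::quantile(mag, 0.999)
  pts <- which(mag > thr)
  if (length(pts) == 0) return(tibble::tibble(row = numeric(0), col = numeric(0),
                                              radius = numeric(0), votes = numeric(0)))
  pr <- ((pts - 1) %% nr) + 1
  pc <- ((pts - 1) %/% nr) + 1
  ur <- gr[pts] / mag[pts]; uc <- gc[pts] / mag[pts]
  best <- list()
  for (r in radii) {
    cr <- c(round(pr + r * ur), round(pr - r * ur))
    cc <- c(round(pc + r * uc), round(pc - r * uc))
    ok <- cr >= 1 & cr <= nr & cc >= 1 & cc <= nc
    if (!is.null(window)) {
      ok <- ok & abs(cr - window$row) <= window$half & abs(cc - window$col) <= window$half
    }
    if (!any(ok)) next
    lin <- (cc[ok] - 1) * nr + cr[ok]
    tab <- tabulate(lin, nbins = nr * nc)
    # 3x3 smoothing of the accumulator via the mask machinery would be costly;
    # instead pool votes over a small neighbourhood around the top cells.
    top <- order(tab, decreasing = TRUE)[seq_len(min(30, sum(tab > 0)))]
    for (cell in top) {
      r0 <- ((cell - 1) %% nr) + 1; c0 <- ((cell - 1) %/% nr) + 1
      rr <- max(1, r0 - 2):min(nr, r0 + 2); cc2 <- max(1, c0 - 2):min(nc, c0 + 2)
      pooled <- sum(tab[as.vector(outer(rr, (cc2 - 1) * nr, "+"))])
      best[[length(best) + 1]] <- list(row = r0, col = c0, radius = r, votes = pooled)
    }
  }
  if (length(best) == 0) return(tibble::tibble(row = numeric(0), col = numeric(0),
                                               radius = numeric(0), votes = numeric(0)))
  df <- dplyr::bind_rows(lapply(best, tibble::as_tibble))
  df <- df[order(df$votes / df$radius, decreasing = TRUE), ]
  out <- df[0, ]
  for (i in seq_len(nrow(df))) {
    if (nrow(out) > 0 &&
        any(sqrt((out$row - df$row[i])^2 + (out$col - df$col[i])^2) < 0.7 * df$radius[i])) next
    out <- rbind(out, df[i, ])
    if (nrow(out) >= n_peaks) break
  }
  out
}

#' Crop a frame to one arena
#'
#' Square crop of side `2*floor(radius) + 1` centred on the arena; pixels
#' outside the arena circle are replaced by a local background estimate so
#' downstream segmentation ignores the surround.
#'
#' @param frame A `flycourt_frame`.
#' @param region One row of the tibble returned by [detect_arenas()] (or any
#'   list with `row`, `col`, `radius`, `mm_per_px`).
#' @return A `flycourt_frame` covering just the arena; carries `mm_per_px`
#'   and the crop origin (`origin`, the frame coordinates of crop pixel
#'   (1,1)).
#' @export
crop_arena <- function(frame, region) {
  nr <- dim(frame$pixels)[1]; nc <- dim(frame$pixels)[2]
  half <- floor(region$radius)
  r0 <- round(region$row) - half; r1 <- round(region$row) + half
  c0 <- round(region$col) - half; c1 <- round(region$col) + half
  if (r0 < 1 || c0 < 1 || r1 > nr || c1 > nc) {
    stop("arena region extends beyond the frame", call. = FALSE)
  }
  px <- frame$pixels[r0:r1, c0:c1, , drop = FALSE]
  side <- r1 - r0 + 1
  ctr <- (side + 1) / 2
  # keep a slightly smaller disc so rim-transition pixels (half in, half out
  # of the detected circle) cannot leak into segmentation as dark arcs
  inside <- fill_disc(side, side, c(ctr, ctr), region$radius - 2)
  ring <- inside & !fill_disc(side, side, c(ctr, ctr), 0.8 * region$radius)
  for (ch in 1:3) {
    plane <- px[, , ch]
    bg_est <- stats::median(plane[ring])
    plane[!inside] <- bg_est
    px[, , ch] <- plane
  }
  structure(list(pixels = px, index = frame$index, fps = frame$fps,
                 mm_per_px = region$mm_per_px,
                 origin = c(r0, c0)),
            class = "flycourt_frame")
}
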