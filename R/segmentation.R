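#' Build a background model with a spatial maximum filter
#'
#' Under backlighting flies are darker than the illuminated arena, so a
#' per-channel spatial maximum filter with a window larger than a fly
#' replaces every fly pixel with nearby bright background, yielding a clean
#' background estimate from a single frame.
#'
#' @param frame A `flycourt_frame` (typically an arena crop).
#' @param window_px Odd window side in px, larger than the fly's body length.
#' @return A `flycourt_background`: list with `pixels` (rows x cols x 3) and
#'   `window_px`.
#' @export
build_background <- function(frame, window_px = 61) {
  if (window_px %% 2 != 1 || window_px < 3) {
    stop("window_px must be odd and >= 3", call. = FALSE)
  }
  px <- frame$pixels
  bg <- array(0, dim = dim(px))
  for (ch in 1:3) bg[, , ch] <- box_max_filter(px[, , ch], window_px)
  structure(list(pixels = bg, window_px = window_px), class = "flycourt_background")
}

#' Segment fly silhouettes by background subtraction
#'
#' The per-pixel difference (background minus frame, maximum over the three
#' channels) is thresholded, holes are filled and small objects removed. Each
#' visible fly yields one connected component; touching flies merge into one.
#'
#' @param frame A `flycourt_frame`.
#' @param bg A `flycourt_background` of the same shape.
#' @param threshold Intensity threshold; `NULL` (default) picks it by Otsu's
#'   method on the difference image in its two-threshold (three-class) form,
#'   binarizing at the lower threshold: the silhouette holds two foreground
#'   intensity populations (translucent wings, opaque torso), so the lower
#'   Otsu cut separates background noise from wings while the upper one
#'   would split the fly itself.
#' @param min_obj_px Connected components smaller than this are discarded.
#' @return Logical body mask (rows x cols).
#' @export
subtract_and_threshold <- function(frame, bg, threshold = NULL, min_obj_px = 20) {
  if (!identical(dim(frame$pixels), dim(bg$pixels))) {
    stop("frame and background shapes differ", call. = FALSE)
  }
  d1 <- bg$pixels[, , 1] - frame$pixels[, , 1]
  d2 <- bg$pixels[, , 2] - frame$pixels[, , 2]
  d3 <- bg$pixels[, , 3] - frame$pixels[, , 3]
  diff <- pmax(d1, d2, d3, 0)
  if (is.null(threshold)) {
    th <- otsu_two_thresholds(as.vector(diff))
    if (th[2] < 30) return(blank_mask(nrow(diff), ncol(diff)))  # no foreground mode
    # keep the lower cut above the max-filter noise pedestal
    threshold <- max(th[1], 0.2 * th[2])
  }
  mask <- diff > threshold
  mask <- mask_fill_holes(mask)
  remove_small(mask, min_obj_px)
}

#' Extract wing pixels from a silhouette
#'
#' Wings are translucent, so inside the silhouette they stay bright relative
#' to the opaque torso. The wing region is the set of body pixels whose
#' scaled channel product `round((R/k) * (G/k) * (B/k))` exceeds zero
#' (k = 80 for this rig's intensity regime), cleaned by morphological
#' opening and closing. Opening also removes the 1-px legs, which share the
#' wings' intermediate intensity.
#'
#' @param frame Raw `flycourt_frame` (the arena crop).
#' @param body Logical body mask from [subtract_and_threshold()].
#' @param wing_divisor The intensity scale k in the channel-product rule.
#' @param open_radius,close_radius Disc radii for morphological cleanup.
#' @return Logical wings mask (subset of `body`).
#' @export
extract_wings <- function(frame, body, wing_divisor = 80,
                          open_radius = 1, close_radius = 2) {
  if (!any(body)) return(body)
  k <- wing_divisor
  prod <- (frame$pixels[, , 1] / k) * (frame$pixels[, , 2] / k) * (frame$pixels[, , 3] / k)
  wings <- body & (round(prod) > 0)
  if (any(wings)) wings <- mask_open(wings, open_radius)
  if (any(wings)) wings <- mask_close(wings, close_radius) & body
  wings
}

#' Extract the torso from a silhouette
#'
#' The torso is the silhouette minus the wings, with morphological cleanup
#' (opening removes residual 1-px legs, closing heals the wing boundary) and
#' selection of the largest component per visible fly.
#'
#' @param body Logical body mask.
#' @param wings Logical wings mask from [extract_wings()].
#' @param n_flies Number of torso components to keep; defaults to the number
#'   of connected components of `body`.
#' @param open_radius,close_radius Disc radii for cleanup.
#' @return Logical torso mask.
#' @export
extract_torso <- function(body, wings, n_flies = NULL,
                          open_radius = 1, close_radius = 2) {
  torso <- body & !wings
  if (!any(torso)) return(torso)
  torso <- mask_open(torso, open_radius)
  if (any(torso)) torso <- mask_close(torso, close_radius) & body & !wings
  if (!any(torso)) return(torso)
  if (is.null(n_flies)) n_flies <- max(1L, n_components(body))
  keep_largest(torso, n_flies)
}
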