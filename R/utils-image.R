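# Internal binary-mask and grayscale-image helpers built on EBImage.
# Masks are logical matrices (row, col); EBImage results are coerced back.

as_mask <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2) m <- m[, , 1]
  matrix(m > 0.5, nrow = nrow(m))
}

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")

mask_erode <- function(m, radius = 1) as_mask(EBImage::erode(m * 1, disc_brush(radius)))
mask_dilate <- function(m, radius = 1) as_mask(EBImage::dilate(m * 1, disc_brush(radius)))
mask_open <- function(m, radius = 1) as_mask(EBImage::opening(m * 1, disc_brush(radius)))
mask_close <- function(m, radius = 1) as_mask(EBImage::closing(m * 1, disc_brush(radius)))
mask_fill_holes <- function(m) as_mask(EBImage::fillHull(m * 1))

mask_boundary <- function(m) m & !mask_erode(m, 1)

# 4-connected labeling straight from EBImage.
label4 <- function(m) {
  lab <- EBImage::imageData(EBImage::bwlabel(m * 1))
  matrix(as.integer(lab), nrow = nrow(lab))
}

# 8-connected labeling: 4-connected pass, then union of labels that touch
# diagonally (EBImage's bwlabel is 4-connected).
label8 <- function(m) {
  lab <- label4(m)
  k <- max(lab)
  if (k <= 1) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right diagonal
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]      # down-left diagonal
  pairs <- rbind(
    cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
    cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2])
  )
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

n_components <- function(m, connectivity = 8) {
  if (!any(m)) return(0L)
  max(if (connectivity == 8) label8(m) else label4(m))
}

# Drop connected components smaller than min_px (8-connectivity).
remove_small <- function(m, min_px) {
  if (!any(m)) return(m)
  lab <- label8(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow = nrow(m))
}

# Keep the k largest components.
keep_largest <- function(m, k = 1) {
  if (!any(m)) return(m)
  lab <- label8(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(k, length(sizes)))]
  matrix(lab %in% keep, nrow = nrow(m))
}

# TRUE when masks a and b are 8-connected to each other through mask `via`
# (i.e. some component of a|b|via intersects both a and b).
masks_connected <- function(a, b, via = NULL) {
  u <- a | b
  if (!is.null(via)) u <- u | via
  lab <- label8(u)
  la <- unique(lab[a & lab > 0])
  lb <- unique(lab[b & lab > 0])
  length(intersect(la, lb)) > 0
}

# Separable square (box) maximum filter of odd side w, replicate padding.
# This is the spatial maximum filter used to build the backlit background.
box_max_filter <- function(x, w) {
  stopifnot(w %% 2 == 1, w >= 3)
  h <- (w - 1L) / 2L
  run1 <- function(m) { # max over rows within +-h, per column
    nr <- nrow(m)
    out <- m
    for (d in seq_len(h)) {
      up <- m[c(seq_len(d) * 0 + 1L, seq_len(nr - d)), , drop = FALSE]
      dn <- m[c(seq.int(d + 1L, nr), rep(nr, d)), , drop = FALSE]
      out <- pmax(out, up, dn)
    }
    out
  }
  t(run1(t(run1(x))))
}

clamp255 <- function(x) pmin(255, pmax(0, x))

# Grayscale reduction used for edge maps: mean of channels.
rgb_gray <- function(frame_array) {
  (frame_array[, , 1] + frame_array[, , 2] + frame_array[, , 3]) / 3
}
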