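# Morphological thinning (Zhang-Suen) with optional short-branch pruning.
# Thin structures such as 1-px legs reduce to their own pixels, wide regions
# to medial lines; connectivity is preserved, which the leg-contact detector
# relies on.

shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a 1-px-wide, connectivity-preserving skeleton,
#' optionally pruning branches shorter than `prune_len` pixels (spurs are
#' traced from their endpoints; branches reaching a junction in fewer than
#' `prune_len` steps are deleted whole).
#'
#' @param m Logical mask.
#' @param prune_len Minimum branch length to keep; 0 or `Inf`-free default
#'   keeps every branch.
#' @return Logical skeleton mask.
#' @export
skeletonize <- function(m, prune_len = 0) {
  sk <- m
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift_mask(sk, -1, 0); p3 <- shift_mask(sk, -1, 1)
      p4 <- shift_mask(sk, 0, 1);  p5 <- shift_mask(sk, 1, 1)
      p6 <- shift_mask(sk, 1, 0);  p7 <- shift_mask(sk, 1, -1)
      p8 <- shift_mask(sk, 0, -1); p9 <- shift_mask(sk, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(sk), ncol(sk))
      for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
      if (pass == 1) {
        cond <- sk & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- sk & b >= 2 & b <= 6 & a == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        sk[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (is.finite(prune_len) && prune_len > 0) sk <- prune_branches(sk, prune_len)
  sk
}

# Count of 8-neighbours for each skeleton pixel.
neighbor_count <- function(sk) {
  n <- matrix(0L, nrow(sk), ncol(sk))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + shift_mask(sk, dr, dc)
  }
  n
}

# Count of 4-neighbours; used for junction detection while walking, where
# 8-connectivity would mistake a spur pixel diagonally brushing a straight
# backbone for the junction itself.
neighbor_count4 <- function(sk) {
  shift_mask(sk, -1, 0) + shift_mask(sk, 1, 0) +
    shift_mask(sk, 0, -1) + shift_mask(sk, 0, 1)
}

# Remove skeleton branches shorter than min_len: walk from each endpoint to
# the first junction; delete the walked pixels if the junction was reached
# in fewer than min_len steps. Isolated segments (no junction) are kept.
prune_branches <- function(sk, min_len) {
  repeat {
    nc_ <- neighbor_count(sk)
    nc4 <- neighbor_count4(sk)
    ends <- which(sk & nc_ == 1, arr.ind = TRUE)
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      cur <- as.integer(ends[e, ])
      if (!sk[cur[1], cur[2]]) next
      path <- list(cur)
      prev <- c(NA_integer_, NA_integer_)
      hit_junction <- FALSE
      while (length(path) < min_len) {
        nb <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- cur[1] + dr; c <- cur[2] + dc
          if (r < 1 || c < 1 || r > nrow(sk) || c > ncol(sk)) next
          if (sk[r, c] && !(identical(r, prev[1]) && identical(c, prev[2]))) {
            nb <- rbind(nb, c(r, c))
          }
        }
        if (is.null(nb)) break                           # isolated spur end
        if (nrow(nb) > 1 || nc4[nb[1, 1], nb[1, 2]] > 2) {
          hit_junction <- TRUE
          break
        }
        prev <- cur; cur <- as.integer(nb[1, ])
        path[[length(path) + 1]] <- cur
      }
      if (hit_junction && length(path) < min_len) {
        for (p in path) sk[p[1], p[2]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(sk)
  }
}
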