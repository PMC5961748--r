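# shift a logical matrix by (dr, dc), padding with FALSE
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Skeletonize a binary mask
#'
#' Reduces the lumen mask to a one-pixel-wide, 8-connected centerline using
#' iterative topology-preserving thinning (Zhang-Suen). Connectivity is
#' preserved: the skeleton has the same number of connected components as the
#' mask (a component too small to survive thinning is represented by its
#' distance-transform maximum pixel).
#'
#' @param mask a [binary_mask] with at least one foreground pixel.
#' @return logical matrix of the same shape: the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  assert_nonempty_mask(mask)
  img <- mask$pixels
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      p2 <- shift_mat(img, -1L,  0L); p3 <- shift_mat(img, -1L,  1L)
      p4 <- shift_mat(img,  0L,  1L); p5 <- shift_mat(img,  1L,  1L)
      p6 <- shift_mat(img,  1L,  0L); p7 <- shift_mat(img,  1L, -1L)
      p8 <- shift_mat(img,  0L, -1L); p9 <- shift_mat(img, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1L) {
        cond <- img & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- img & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { img[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  # restore components thinning deleted outright (possible for tiny blobs)
  lab <- label_components(mask$pixels)
  alive <- unique(lab[img])
  lost <- setdiff(seq_len(max(lab)), alive)
  if (length(lost)) {
    dt <- distance_transform(mask$pixels)
    for (cc in lost) {
      idx <- which(lab == cc)
      img[idx[which.max(dt[idx])]] <- TRUE
    }
  }
  img
}
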