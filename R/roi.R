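#' Standard ALPS ROI pairs
#'
#' Nine left-hemisphere ROI pairs on three axial planes (z = 29, 30, 31 mm)
#' with three in-plane placements each. Projection ROIs (superior corona
#' radiata, expected fiber axis z) sit at x = -26 mm; association ROIs
#' (superior longitudinal fasciculus, expected axis y) at x = -37 mm; the
#' members of a pair share y and z. ROIs are nominally 3 mm squares,
#' refined to 2 mm for extraction.
#'
#' @param hemisphere \code{"left"} (default), \code{"right"} (mirrored x),
#'   or \code{"both"}.
#' @return data.frame of class \code{roi_pairs} with one row per pair:
#'   \code{pair_id}, \code{proj_x}, \code{assoc_x}, \code{y}, \code{z},
#'   \code{edge_nominal}, \code{edge_refined}, \code{status},
#'   \code{shift_x}, \code{shift_y}.
#' @export
standard_roi_pairs <- function(hemisphere = c("left", "right", "both")) {
  hemisphere <- match.arg(hemisphere)
  yz <- expand.grid(y = c(-17, -27, -29), z = c(29, 30, 31))
  one <- function(sgn, tag) {
    data.frame(pair_id = sprintf("%sy%d_z%d", tag, yz$y, yz$z),
               proj_x = sgn * -26, assoc_x = sgn * -37,
               y = yz$y, z = yz$z,
               edge_nominal = 3, edge_refined = 2,
               status = "active", shift_x = 0, shift_y = 0,
               stringsAsFactors = FALSE)
  }
  out <- switch(hemisphere,
                left = one(1, "L_"),
                right = one(-1, "R_"),
                both = rbind(one(1, "L_"), one(-1, "R_")))
  structure(out, class = c("roi_pairs", "data.frame"))
}

#' Voxelize an ROI cube in native space
#'
#' An ROI is the set of voxels whose centers fall inside the axis-aligned
#' half-open cube \eqn{[c - e/2, c + e/2)^3} around the (possibly shifted)
#' template-mm center, after mapping voxel indices through the affine.
#'
#' @param center_mm length-3 template-mm center.
#' @param edge_mm cube edge (mm).
#' @param affine invertible 4x4 voxel-to-mm affine.
#' @param dim grid size (voxels).
#' @return Integer matrix (n x 3) of 1-based voxel indices (possibly 0
#'   rows).
#' @export
voxelize_roi <- function(center_mm, edge_mm, affine, dim) {
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  h <- edge_mm / 2
  corners <- as.matrix(expand.grid(center_mm[1] + c(-h, h),
                                   center_mm[2] + c(-h, h),
                                   center_mm[3] + c(-h, h)))
  vc <- mm_to_vox(affine, corners)
  lo <- pmax(floor(apply(vc, 2, min)) - 1, 1)
  hi <- pmin(ceiling(apply(vc, 2, max)) + 1, dim)
  if (any(lo > hi)) return(matrix(integer(0), 0, 3))
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  mm <- vox_to_mm(affine, cand)
  inb <- mm[, 1] >= center_mm[1] - h & mm[, 1] < center_mm[1] + h &
         mm[, 2] >= center_mm[2] - h & mm[, 2] < center_mm[2] + h &
         mm[, 3] >= center_mm[3] - h & mm[, 3] < center_mm[3] + h
  cand[inb, , drop = FALSE]
}

# fraction of ROI voxels whose V1 dominant absolute component matches the
# expected fiber axis (1 = x, 2 = y, 3 = z); flagged voxels count as
# mismatches
alignment_score <- function(vox, eigenmap, axis) {
  if (nrow(vox) == 0) return(0)
  ok <- 0L
  for (r in seq_len(nrow(vox))) {
    if (isTRUE(eigenmap$flags[vox[r, 1], vox[r, 2], vox[r, 3]])) next
    v <- eigenmap$v1[vox[r, 1], vox[r, 2], vox[r, 3], ]
    if (any(is.na(v))) next
    if (which.max(abs(v)) == axis) ok <- ok + 1L
  }
  ok / nrow(vox)
}

#' Refine and validate ROI pairs against a primary-eigenvector map
#'
#' Deterministic stand-in for visual ROI quality control: each ROI of a
#' pair is evaluated at the nine in-plane shifts \{-1, 0, 1\} mm in x and
#' y. The alignment score is the fraction of ROI voxels whose V1 dominant
#' absolute component matches the ROI's expected fiber axis (z for
#' projection, y for association). The maximum-score shift is kept, with
#' ties broken by smallest shift norm, then lexicographically (x before
#' y). A pair whose best score falls below \code{threshold} for either ROI
#' is excluded (\code{"excluded(misaligned)"}); a pair whose refined ROI
#' contains no voxels is excluded (\code{"excluded(out_of_grid)"}).
#'
#' @param pairs \code{\link{standard_roi_pairs}}-style data.frame.
#' @param eigenmap an \code{\link{eigen_map}}.
#' @param threshold minimum acceptable alignment score (default 0.5).
#' @return The pairs data.frame with updated \code{status},
#'   \code{shift_x}, \code{shift_y} (shared by both ROIs of the pair) and
#'   added score columns \code{score_proj}, \code{score_assoc}.
#' @export
refine_and_validate <- function(pairs, eigenmap, threshold = 0.5) {
  stopifnot(inherits(eigenmap, "eigen_map"))
  dimg <- dim(eigenmap$flags)
  shifts <- expand.grid(sx = c(-1, 0, 1), sy = c(-1, 0, 1))
  ord <- order(shifts$sx^2 + shifts$sy^2, shifts$sx, shifts$sy)
  shifts <- shifts[ord, ]  # evaluate in tie-break preference order
  pairs$score_proj <- NA_real_
  pairs$score_assoc <- NA_real_
  for (r in seq_len(nrow(pairs))) {
    if (pairs$status[r] != "active") next
    best <- list(score = -Inf, sx = 0, sy = 0, sp = 0, sa = 0, empty = FALSE)
    for (s in seq_len(nrow(shifts))) {
      sx <- shifts$sx[s]; sy <- shifts$sy[s]
      pv <- voxelize_roi(c(pairs$proj_x[r] + sx, pairs$y[r] + sy, pairs$z[r]),
                         pairs$edge_refined[r], eigenmap$affine, dimg)
      av <- voxelize_roi(c(pairs$assoc_x[r] + sx, pairs$y[r] + sy, pairs$z[r]),
                         pairs$edge_refined[r], eigenmap$affine, dimg)
      if (nrow(pv) == 0 || nrow(av) == 0) {
        if (sx == 0 && sy == 0) best$empty <- TRUE
        next
      }
      sp <- alignment_score(pv, eigenmap, 3L)
      sa <- alignment_score(av, eigenmap, 2L)
      sc <- min(sp, sa)
      if (sc > best$score + 1e-12) {
        best <- list(score = sc, sx = sx, sy = sy, sp = sp, sa = sa,
                     empty = FALSE)
      }
    }
    if (is.infinite(best$score)) {
      pairs$status[r] <- "excluded(out_of_grid)"
      next
    }
    pairs$score_proj[r] <- best$sp
    pairs$score_assoc[r] <- best$sa
    pairs$shift_x[r] <- best$sx
    pairs$shift_y[r] <- best$sy
    if (best$score < threshold) {
      pairs$status[r] <- "excluded(misaligned)"
    } else if (best$sx != 0 || best$sy != 0) {
      pairs$status[r] <- sprintf("adjusted(%+d,%+d)", best$sx, best$sy)
    }
  }
  pairs
}
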