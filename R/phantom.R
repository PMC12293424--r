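#' @title Tensor phantoms with sleep-state modulation
#' @description Ground-truth diffusion-tensor fields emulating the geometry
#'   the ALPS index depends on: a projection-fiber block (principal axis z,
#'   superior corona radiata), an association-fiber block (principal axis y,
#'   superior longitudinal fasciculus), and a perivascular diffusivity
#'   component along x superimposed on both, all inside an isotropic
#'   background. Sleep states modulate the x component and the perpendicular
#'   component of each block.
#' @name phantom
NULL

# voxel (1-based R indices) -> template mm, NIfTI 0-based convention
vox_to_mm <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  mm <- cbind(ijk - 1, 1) %*% t(affine)
  mm[, 1:3, drop = FALSE]
}

# template mm -> continuous 1-based voxel coordinates
mm_to_vox <- function(affine, mm) {
  mm <- matrix(mm, ncol = 3L)
  v <- cbind(mm, 1) %*% t(solve(affine))
  v[, 1:3, drop = FALSE] + 1
}

#' Per-time-point sleep-state modulation trajectory
#'
#' The default trajectory applies, at each post-notification scan time, a
#' fractional change \code{a} to the x-direction diffusivities of both fiber
#' blocks and \code{b} to the perpendicular diffusivity (y in the projection
#' block, z in the association block). The defaults are the observed
#' component percent changes of the cohort study the synthetic conditions
#' emulate, at scan times 14.46--43.45 min after sleep notification.
#'
#' @return data.frame with columns \code{minutes}, \code{a}, \code{b}.
#' @export
default_state_trajectory <- function() {
  data.frame(
    minutes = c(14.46, 19.46, 25.46, 31.45, 37.45, 43.45),
    a = c(0.0633, 0.0351, 0.1057, 0.0594, 0.0639, 0.0451),
    b = c(-0.1105, -0.1432, -0.0804, -0.0335, 0.0174, -0.0953)
  )
}

#' Phantom specification
#'
#' @param dim grid size in voxels (length 3).
#' @param voxel_mm isotropic voxel size (mm).
#' @param origin_mm template-space mm coordinate of voxel (1,1,1).
#' @param proj_x_mm,assoc_x_mm half-open mm intervals (length 2) bounding the
#'   projection and association blocks along x.
#' @param y_mm,z_mm half-open mm intervals bounding both blocks along y and z.
#' @param lambda_radial baseline radial eigenvalue of the fiber tensors
#'   (mm^2/s); this is the perpendicular diffusivity entering the ALPS
#'   denominator.
#' @param lambda_axial baseline axial eigenvalue along the fiber direction.
#' @param pvs_dx perivascular x-diffusivity increment added to Dxx in both
#'   blocks; calibrates the awake ALPS ratio to
#'   (lambda_radial + pvs_dx) / lambda_radial.
#' @param background_d isotropic background diffusivity.
#' @param trajectory data.frame of per-time-point multipliers, columns
#'   \code{minutes}, \code{a}, \code{b}; see
#'   \code{\link{default_state_trajectory}}.
#' @param S0 non-diffusion-weighted signal level (a.u.).
#' @param snr signal-to-noise ratio at b = 0 (S0 / Gaussian sigma).
#' @param awake_minutes nominal time of the awake baseline scan relative to
#'   sleep notification (minutes; the awake scan precedes notification).
#' @param seed integer seed.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(dim = c(48L, 48L, 12L),
                         voxel_mm = 2,
                         origin_mm = c(-70, -60, 10),
                         proj_x_mm = c(-32, -20),
                         assoc_x_mm = c(-44, -32),
                         y_mm = c(-34, -12),
                         z_mm = c(24, 34),
                         lambda_radial = 0.699e-3,
                         lambda_axial = 1.7e-3,
                         pvs_dx = 0.301e-3,
                         background_d = 0.8e-3,
                         trajectory = default_state_trajectory(),
                         S0 = 1000,
                         snr = 30,
                         awake_minutes = -9,
                         seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 1), voxel_mm > 0,
            lambda_radial > 0, lambda_axial > 0, pvs_dx >= 0,
            background_d > 0, S0 > 0, snr > 0)
  if (!all(c("minutes", "a", "b") %in% names(trajectory)))
    stop("trajectory needs columns minutes, a, b")
  if (any(1 + trajectory$a <= 0) || any(1 + trajectory$b <= 0))
    stop("state multipliers must satisfy 1 + a > 0 and 1 + b > 0")
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- origin_mm
  structure(list(dim = as.integer(dim), voxel_mm = voxel_mm,
                 affine = affine,
                 proj_x_mm = proj_x_mm, assoc_x_mm = assoc_x_mm,
                 y_mm = y_mm, z_mm = z_mm,
                 lambda_radial = lambda_radial, lambda_axial = lambda_axial,
                 pvs_dx = pvs_dx, background_d = background_d,
                 trajectory = trajectory, S0 = S0, snr = snr,
                 awake_minutes = awake_minutes, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Tensor volume constructor
#'
#' @param D 4D array (nx, ny, nz, 6) of unique tensor elements in the order
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s).
#' @param affine invertible 4x4 voxel-to-mm affine (0-based voxel indices).
#' @param labels optional integer array (nx, ny, nz): 0 background,
#'   1 projection block, 2 association block.
#' @return Object of class \code{tensor_volume}.
#' @export
tensor_volume <- function(D, affine, labels = NULL) {
  stopifnot(length(dim(D)) == 4L, dim(D)[4] == 6L)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  if (!is.null(labels)) stopifnot(all(dim(labels) == dim(D)[1:3]))
  structure(list(D = D, affine = affine, labels = labels),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat("Tensor volume:", paste(dim(x$D)[1:3], collapse = " x "), "voxels\n")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# logical array marking voxels whose centers fall in a half-open mm box
region_mask <- function(dim, affine, x_mm, y_mm, z_mm) {
  ijk <- as.matrix(expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                               k = seq_len(dim[3])))
  mm <- vox_to_mm(affine, ijk)
  inb <- mm[, 1] >= x_mm[1] & mm[, 1] < x_mm[2] &
         mm[, 2] >= y_mm[1] & mm[, 2] < y_mm[2] &
         mm[, 3] >= z_mm[1] & mm[, 3] < z_mm[2]
  array(inb, dim)
}

#' Build a ground-truth tensor phantom
#'
#' Projection-block tensors are diagonal with principal axis z, association
#' blocks with principal axis y; both receive the perivascular x increment,
#' so the awake ALPS ratio over any in-block ROI pair equals
#' \code{(lambda_radial + pvs_dx) / lambda_radial}. The background is
#' isotropic. Errors if any standard ROI pair does not fall inside its
#' fiber block.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param check_rois validate that all standard ROI pairs land inside the
#'   fiber blocks (default TRUE).
#' @return A \code{\link{tensor_volume}} with region labels.
#' @export
build_phantom <- function(spec, check_rois = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  proj <- region_mask(d, spec$affine, spec$proj_x_mm, spec$y_mm, spec$z_mm)
  assoc <- region_mask(d, spec$affine, spec$assoc_x_mm, spec$y_mm, spec$z_mm)
  D <- array(0, c(d, 6L))
  D[, , , 1] <- spec$background_d
  D[, , , 2] <- spec$background_d
  D[, , , 3] <- spec$background_d
  # projection: axial along z, radial in x/y, plus perivascular x increment
  Dxx <- D[, , , 1]; Dyy <- D[, , , 2]; Dzz <- D[, , , 3]
  Dxx[proj] <- spec$lambda_radial + spec$pvs_dx
  Dyy[proj] <- spec$lambda_radial
  Dzz[proj] <- spec$lambda_axial
  # association: axial along y, radial in x/z, plus perivascular x increment
  Dxx[assoc] <- spec$lambda_radial + spec$pvs_dx
  Dyy[assoc] <- spec$lambda_axial
  Dzz[assoc] <- spec$lambda_radial
  D[, , , 1] <- Dxx; D[, , , 2] <- Dyy; D[, , , 3] <- Dzz
  labels <- array(0L, d)
  labels[proj] <- 1L
  labels[assoc] <- 2L
  tv <- tensor_volume(D, spec$affine, labels)
  if (check_rois) {
    pairs <- standard_roi_pairs()
    for (r in seq_len(nrow(pairs))) {
      pv <- voxelize_roi(c(pairs$proj_x[r], pairs$y[r], pairs$z[r]),
                         pairs$edge_refined[r], spec$affine, d)
      av <- voxelize_roi(c(pairs$assoc_x[r], pairs$y[r], pairs$z[r]),
                         pairs$edge_refined[r], spec$affine, d)
      if (nrow(pv) == 0 || !all(labels[pv] == 1L))
        stop("projection ROI of pair ", pairs$pair_id[r],
             " falls outside the projection block")
      if (nrow(av) == 0 || !all(labels[av] == 2L))
        stop("association ROI of pair ", pairs$pair_id[r],
             " falls outside the association block")
    }
  }
  tv
}

#' Apply sleep-state modulation to a tensor field
#'
#' Within the fiber blocks, scales the x-diagonal element by \code{1 + a}
#' and the perpendicular element of interest (Dyy in the projection block,
#' Dzz in the association block) by \code{1 + b}. Other elements and the
#' background are unchanged; the input is not mutated.
#'
#' @param tensors a labelled \code{\link{tensor_volume}}.
#' @param a fractional change of the x diffusivities (> -1).
#' @param b fractional change of the perpendicular diffusivities (> -1).
#' @return A new \code{\link{tensor_volume}}.
#' @export
apply_state_modulation <- function(tensors, a, b) {
  stopifnot(inherits(tensors, "tensor_volume"))
  if (is.null(tensors$labels))
    stop("state modulation needs a region-labelled tensor volume")
  if (1 + a <= 0 || 1 + b <= 0)
    stop("state multipliers must satisfy 1 + a > 0 and 1 + b > 0")
  D <- tensors$D
  proj <- tensors$labels == 1L
  assoc <- tensors$labels == 2L
  fiber <- proj | assoc
  Dxx <- D[, , , 1]; Dxx[fiber] <- Dxx[fiber] * (1 + a); D[, , , 1] <- Dxx
  Dyy <- D[, , , 2]; Dyy[proj] <- Dyy[proj] * (1 + b); D[, , , 2] <- Dyy
  Dzz <- D[, , , 3]; Dzz[assoc] <- Dzz[assoc] * (1 + b); D[, , , 3] <- Dzz
  tensor_volume(D, tensors$affine, tensors$labels)
}
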