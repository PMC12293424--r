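#' Read an FSL-dialect gradient table
#'
#' \code{.bval}: one space-separated row of b-values. \code{.bvec}: three
#' rows (x, y, z), one column per volume; the transposed layout (one row
#' per volume) is auto-detected by shape. Directions whose norm deviates
#' from 1 by more than 1e-6 (but less than 0.5) are renormalized with a
#' warning; b = 0 entries keep the zero vector.
#'
#' @param bval_path,bvec_path file paths.
#' @return A \code{\link{gradient_scheme}}.
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  rows <- rows[lengths(rows) > 0]
  m <- do.call(rbind, rows)
  if (nrow(m) == 3L && ncol(m) != 3L) {
    bvecs <- t(m)
  } else if (ncol(m) == 3L && nrow(m) != 3L) {
    bvecs <- m
  } else if (nrow(m) == 3L && ncol(m) == 3L) {
    bvecs <- t(m)  # ambiguous 3x3: assume FSL rows = axes
  } else {
    stop("bvec table is ", nrow(m), " x ", ncol(m),
         "; expected 3 rows (FSL) or 3 columns (transposed)")
  }
  if (nrow(bvecs) != length(bvals))
    stop("gradient table mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " directions")
  nrm <- sqrt(rowSums(bvecs^2))
  fix <- bvals > 0 & abs(nrm - 1) > 1e-6 & abs(nrm - 1) < 0.5
  if (any(fix)) {
    warning(sum(fix), " direction(s) renormalized to unit length")
    bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  }
  gradient_scheme(bvals, bvecs)
}

#' Write an FSL-dialect gradient table
#'
#' @param scheme a \code{\link{gradient_scheme}}.
#' @param bval_path,bvec_path output paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(scheme$bvecs), 1L, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " ")), bvec_path)
  invisible(NULL)
}

nifti_with_affine <- function(data, affine) {
  im <- RNifti::asNifti(data)
  pd <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(im) <- if (length(dim(data)) == 4L) c(pd, 1) else pd
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::qform(im) <- structure(affine, code = 2L)
  im
}

#' Read a NIfTI volume with its affine
#'
#' @param path NIfTI file path.
#' @return list with \code{data} (array) and \code{affine} (4x4 voxel-to-mm
#'   matrix, 0-based voxel indices).
#' @export
read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  data <- as.array(im)
  attributes(data) <- list(dim = dim(data))
  list(data = data, affine = aff)
}

#' Write an array as NIfTI with an affine
#'
#' @param data 3D or 4D array.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param path output path (.nii or .nii.gz).
#' @export
write_nifti_volume <- function(data, affine, path) {
  RNifti::writeNifti(nifti_with_affine(data, affine), path)
  invisible(path)
}

#' Write / read a DWI acquisition (NIfTI + gradient tables)
#'
#' @param dwi a \code{\link{dwi_volume}}.
#' @param prefix output prefix; writes \code{<prefix>.nii.gz},
#'   \code{<prefix>.bval}, \code{<prefix>.bvec}.
#' @export
write_dwi <- function(dwi, prefix) {
  write_nifti_volume(dwi$data, dwi$affine, paste0(prefix, ".nii.gz"))
  write_gradient_table(dwi$scheme, paste0(prefix, ".bval"),
                       paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_dwi
#' @param subject,time,minutes metadata for the restored volume.
#' @export
read_dwi <- function(prefix, subject = NA_character_, time = NA_character_,
                     minutes = NA_real_) {
  vol <- read_nifti_volume(paste0(prefix, ".nii.gz"))
  scheme <- read_gradient_table(paste0(prefix, ".bval"),
                                paste0(prefix, ".bvec"))
  if (dim(vol$data)[4] != length(scheme$bvals))
    stop("volume has ", dim(vol$data)[4], " frames but the gradient table ",
         "describes ", length(scheme$bvals))
  dwi_volume(vol$data, scheme, vol$affine, subject = subject, time = time,
             minutes = minutes)
}

#' Write a tensor volume as a 6-frame NIfTI
#'
#' Frame order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz.
#'
#' @param tensors a \code{\link{tensor_volume}}.
#' @param path output path.
#' @export
write_tensor_nifti <- function(tensors, path) {
  write_nifti_volume(tensors$D, tensors$affine, path)
}

#' @rdname write_tensor_nifti
#' @export
read_tensor_nifti <- function(path) {
  vol <- read_nifti_volume(path)
  tensor_volume(vol$data, vol$affine)
}

tsv_write <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotation grid TSV I/O
#'
#' Columns: \code{subject}, \code{epoch_1..epoch_n}; labels 0/1/N.
#'
#' @param grid an \code{annotation_grid}.
#' @param path TSV path.
#' @export
write_annotation_grid <- function(grid, path) tsv_write(grid, path)

#' @rdname write_annotation_grid
#' @export
read_annotation_grid <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  if (!"subject" %in% names(df) || !any(grepl("^epoch_", names(df))))
    stop("annotation grid needs a subject column and epoch_* columns")
  structure(df, class = c("annotation_grid", "data.frame"))
}

#' ALPS series TSV I/O
#'
#' One row per subject x time x ROI pair with the diffusivity quad and
#' index; floats printed at 6 significant digits for reproducible output.
#'
#' @param series an \code{alps_series}.
#' @param path TSV path.
#' @export
write_alps_series <- function(series, path) tsv_write(series, path)

#' @rdname write_alps_series
#' @export
read_alps_series <- function(path) {
  df <- utils::read.delim(path)
  structure(df, class = c("alps_series", "data.frame"))
}

#' ROI pair table TSV I/O (long format: one row per ROI)
#'
#' Columns: \code{pair_id}, \code{role} (proj|assoc), \code{x_mm},
#' \code{y_mm}, \code{z_mm}, \code{edge_mm}, \code{status}.
#'
#' @param pairs an ROI pairs data.frame.
#' @param path TSV path.
#' @export
write_roi_pairs <- function(pairs, path) {
  long <- rbind(
    data.frame(pair_id = pairs$pair_id, role = "proj",
               x_mm = pairs$proj_x + pairs$shift_x,
               y_mm = pairs$y + pairs$shift_y, z_mm = pairs$z,
               edge_mm = pairs$edge_refined, status = pairs$status),
    data.frame(pair_id = pairs$pair_id, role = "assoc",
               x_mm = pairs$assoc_x + pairs$shift_x,
               y_mm = pairs$y + pairs$shift_y, z_mm = pairs$z,
               edge_mm = pairs$edge_refined, status = pairs$status))
  tsv_write(long[order(long$pair_id, long$role), ], path)
}

#' Read a pipeline configuration file
#'
#' YAML with sections \code{phantom}, \code{scheme}, \code{fit},
#' \code{rois}, \code{stats}, \code{output}; a top-level integer
#' \code{seed} is mandatory.
#'
#' @param path YAML file.
#' @return list of class \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  alpha <- if (!is.null(cfg$stats$alpha)) cfg$stats$alpha else 0.05
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  cfg$stats$alpha <- alpha
  structure(cfg, class = "pipeline_config")
}

#' Build a phantom specification from a config
#'
#' @param cfg a \code{pipeline_config}.
#' @param seed optional seed override.
#' @return A \code{\link{phantom_spec}}.
#' @export
config_phantom_spec <- function(cfg, seed = NULL) {
  ph <- if (is.null(cfg$phantom)) list() else cfg$phantom
  ph$seed <- if (!is.null(seed)) seed else cfg$seed
  known <- names(formals(phantom_spec))
  do.call(phantom_spec, ph[intersect(names(ph), known)])
}
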