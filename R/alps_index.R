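#' Extract the ALPS diffusivity quad for one ROI pair
#'
#' Means, over each ROI's unflagged voxels, of the diagonal tensor elements
#' entering the ALPS ratio: Dxx over both ROIs, Dyy over the projection
#' ROI, Dzz over the association ROI.
#'
#' @param tensors a \code{\link{tensor_volume}} (fitted or ground truth).
#' @param pair one-row ROI pair (as in \code{\link{standard_roi_pairs}},
#'   with any refinement shift applied via \code{shift_x}/\code{shift_y}).
#' @param flags optional logical array of voxels to exclude (defaults to
#'   the tensor volume's fit flags, if any).
#' @return A list of class \code{diffusivity_quad}: \code{Dxx_proj},
#'   \code{Dxx_assoc}, \code{Dyy_proj}, \code{Dzz_assoc} (mm^2/s),
#'   \code{n_proj}, \code{n_assoc}.
#' @export
extract_quad <- function(tensors, pair, flags = NULL) {
  stopifnot(inherits(tensors, "tensor_volume"), nrow(pair) == 1L)
  if (!pair$status %in% "active" && !startsWith(pair$status, "adjusted"))
    stop("quad requested for non-active pair ", pair$pair_id,
         " (status ", pair$status, ")")
  if (is.null(flags)) flags <- attr(tensors, "flags")
  dimg <- dim(tensors$D)[1:3]
  pv <- voxelize_roi(c(pair$proj_x + pair$shift_x, pair$y + pair$shift_y,
                       pair$z), pair$edge_refined, tensors$affine, dimg)
  av <- voxelize_roi(c(pair$assoc_x + pair$shift_x, pair$y + pair$shift_y,
                       pair$z), pair$edge_refined, tensors$affine, dimg)
  keep <- function(vox) {
    if (is.null(flags) || nrow(vox) == 0) return(vox)
    ok <- !flags[vox]
    vox[ok, , drop = FALSE]
  }
  pv <- keep(pv); av <- keep(av)
  if (nrow(pv) == 0 || nrow(av) == 0)
    stop("empty_roi: pair ", pair$pair_id,
         " has no unflagged voxels in at least one ROI")
  elem <- function(vox, e) mean(tensors$D[cbind(vox, e)])
  structure(list(Dxx_proj = elem(pv, 1L), Dxx_assoc = elem(av, 1L),
                 Dyy_proj = elem(pv, 2L), Dzz_assoc = elem(av, 3L),
                 n_proj = nrow(pv), n_assoc = nrow(av)),
            class = "diffusivity_quad")
}

#' The ALPS index of a diffusivity quad
#'
#' \deqn{ALPS = mean(Dxx_{proj}, Dxx_{assoc}) / mean(Dyy_{proj},
#' Dzz_{assoc})}
#'
#' The ratio is dimensionless and invariant under global scaling of the
#' four diffusivities; values above 1 indicate excess x-direction
#' diffusivity attributed to perivascular water movement.
#'
#' @param quad a \code{diffusivity_quad}, or a numeric vector of length 4
#'   in the order Dxx_proj, Dxx_assoc, Dyy_proj, Dzz_assoc.
#' @return The ALPS index (numeric scalar).
#' @export
alps_index <- function(quad) {
  q <- if (inherits(quad, "diffusivity_quad"))
    c(quad$Dxx_proj, quad$Dxx_assoc, quad$Dyy_proj, quad$Dzz_assoc)
  else as.numeric(quad)
  stopifnot(length(q) == 4L)
  den <- mean(q[3:4])
  if (!is.finite(den) || den <= 0)
    stop("non-positive ALPS denominator")
  mean(q[1:2]) / den
}

#' Compute per-subject ALPS series for a simulated cohort
#'
#' Runs the measurement pipeline on every scan: low-b shell selection,
#' tensor fit, eigen-decomposition, ROI refinement against the awake
#' scan's primary-eigenvector map (refinement is per subject and reused at
#' all time points), quad extraction and the ALPS index for every active
#' pair.
#'
#' @param cohort an \code{alps_cohort} from \code{\link{simulate_cohort}},
#'   or a list of per-subject scan lists (each a named list of
#'   \code{dwi_volume}, awake first).
#' @param pairs ROI pairs (default \code{\link{standard_roi_pairs}()}).
#' @param b_target,tol shell selection, see \code{\link{select_shell}}.
#' @param method tensor estimator, see \code{\link{fit_tensor}}.
#' @param refine run \code{\link{refine_and_validate}} per subject.
#' @param mask \code{"roi"} (default) to restrict fitting to a
#'   neighbourhood of the ROIs, \code{"none"} for the full grid, or a
#'   logical array.
#' @param ground_truth if TRUE and the cohort carries ground-truth tensors,
#'   skip fitting and extract from the truth (noise-free oracle mode).
#' @return data.frame of class \code{alps_series}: one row per subject x
#'   time point x active pair, with columns \code{subject}, \code{time},
#'   \code{minutes}, \code{pair_id}, the quad, voxel counts and
#'   \code{alps}. ROI statuses per subject are attached as attribute
#'   \code{roi_status}.
#' @export
compute_alps_series <- function(cohort, pairs = standard_roi_pairs(),
                                b_target = 800, tol = 50,
                                method = "wls", refine = TRUE,
                                mask = "roi", ground_truth = FALSE) {
  subjects <- if (inherits(cohort, "alps_cohort")) cohort$subjects else cohort
  rows <- list()
  status <- list()
  for (sname in names(subjects)) {
    entry <- subjects[[sname]]
    scans <- if (!is.null(entry$scans)) entry$scans else entry
    first <- scans[[1]]
    dimg <- dim(first$data)[1:3]
    m <- roi_fit_mask(mask, pairs, first$affine, dimg)
    tensors <- vector("list", length(scans))
    if (ground_truth) {
      if (is.null(entry$truth))
        stop("cohort has no ground-truth tensors (simulate with keep_truth)")
      tensors <- entry$truth
    } else {
      for (t in seq_along(scans))
        tensors[[t]] <- fit_tensor(select_shell(scans[[t]], b_target, tol),
                                   method = method, mask = m)
    }
    sp <- pairs
    if (refine) {
      emap <- eigen_decompose(tensors[[1]], mask = m)
      sp <- refine_and_validate(sp, emap)
    }
    status[[sname]] <- sp
    active <- which(sp$status == "active" | startsWith(sp$status, "adjusted"))
    for (t in seq_along(scans)) {
      sc <- scans[[t]]
      for (r in active) {
        quad <- extract_quad(tensors[[t]], sp[r, , drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sname, time = sc$time, minutes = sc$minutes,
          pair_id = sp$pair_id[r],
          Dxx_proj = quad$Dxx_proj, Dxx_assoc = quad$Dxx_assoc,
          Dyy_proj = quad$Dyy_proj, Dzz_assoc = quad$Dzz_assoc,
          n_proj = quad$n_proj, n_assoc = quad$n_assoc,
          alps = alps_index(quad), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- structure(out, class = c("alps_series", "data.frame"))
  attr(out, "roi_status") <- status
  out
}

# bounding-box mask around the (shifted) ROI cubes, dilated by two voxels
roi_fit_mask <- function(mask, pairs, affine, dimg) {
  if (is.array(mask) || is.logical(mask)) return(mask)
  if (identical(mask, "none")) return(NULL)
  stopifnot(identical(mask, "roi"))
  m <- array(FALSE, dimg)
  for (r in seq_len(nrow(pairs))) {
    for (x in c(pairs$proj_x[r], pairs$assoc_x[r])) {
      vox <- voxelize_roi(c(x, pairs$y[r], pairs$z[r]),
                          pairs$edge_refined[r] + 4, affine, dimg)
      if (nrow(vox) > 0) m[vox] <- TRUE
    }
  }
  m
}

#' Percent change of the ALPS index relative to the awake baseline
#'
#' @param series an \code{alps_series} (or compatible data.frame with
#'   columns subject, time, pair_id, alps), awake entries labelled
#'   \code{"awake"}.
#' @return data.frame with one row per subject x pair x sleep time point:
#'   \code{subject}, \code{pair_id}, \code{time}, \code{minutes},
#'   \code{pct_change} (fraction, e.g. 0.195 for +19.5\%).
#' @export
percent_change_series <- function(series) {
  if (!any(series$time == "awake"))
    stop("series has no awake baseline entry")
  out <- list()
  for (key in unique(paste(series$subject, series$pair_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- series[series$subject == parts[1] & series$pair_id == parts[2], ]
    awake <- sub$alps[sub$time == "awake"]
    if (length(awake) != 1L)
      stop("subject ", parts[1], " pair ", parts[2],
           " lacks a unique awake entry")
    sleep <- sub[sub$time != "awake", , drop = FALSE]
    if (nrow(sleep) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      subject = parts[1], pair_id = parts[2], time = sleep$time,
      minutes = sleep$minutes, pct_change = sleep$alps / awake - 1,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(subject = character(), pair_id = character(),
                      time = character(), minutes = numeric(),
                      pct_change = numeric()))
  do.call(rbind, out)
}

#' Decompose ALPS index change into numerator and denominator changes
#'
#' For a time-ordered series of diffusivity quads with an awake baseline,
#' reports at each sleep time the fractional change of the numerator
#' mean(Dxx_proj, Dxx_assoc), of the denominator mean(Dyy_proj, Dzz_assoc),
#' and of the index itself. The three satisfy the exact identity
#' \eqn{1 + \Delta_{index} = (1 + \Delta_{num}) / (1 + \Delta_{den})}.
#'
#' @param quads data.frame with columns \code{time}, \code{Dxx_proj},
#'   \code{Dxx_assoc}, \code{Dyy_proj}, \code{Dzz_assoc}; one row per time
#'   point, awake labelled \code{"awake"}.
#' @return data.frame with columns \code{time}, \code{d_num},
#'   \code{d_den}, \code{d_index} (fractions).
#' @export
decompose_components <- function(quads) {
  iaw <- which(quads$time == "awake")
  if (length(iaw) != 1L) stop("quads need exactly one awake entry")
  num <- (quads$Dxx_proj + quads$Dxx_assoc) / 2
  den <- (quads$Dyy_proj + quads$Dzz_assoc) / 2
  sleep <- setdiff(seq_len(nrow(quads)), iaw)
  d_num <- num[sleep] / num[iaw] - 1
  d_den <- den[sleep] / den[iaw] - 1
  data.frame(time = quads$time[sleep], d_num = d_num, d_den = d_den,
             d_index = (1 + d_num) / (1 + d_den) - 1,
             stringsAsFactors = FALSE)
}
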