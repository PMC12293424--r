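#' DWI volume constructor
#'
#' @param data 4D signal array; 4th dimension indexes scheme volumes.
#' @param scheme a \code{\link{gradient_scheme}}.
#' @param affine 4x4 voxel-to-mm affine.
#' @param subject subject identifier.
#' @param time time-point label: \code{"awake"} or minutes since sleep
#'   notification (as character or numeric).
#' @param minutes numeric scan time in minutes relative to sleep
#'   notification.
#' @return Object of class \code{dwi_volume}.
#' @export
dwi_volume <- function(data, scheme, affine, subject = NA_character_,
                       time = NA_character_, minutes = NA_real_) {
  stopifnot(inherits(scheme, "gradient_scheme"), length(dim(data)) == 4L)
  if (dim(data)[4] != length(scheme$bvals))
    stop("4th dimension (", dim(data)[4], ") does not match the scheme (",
         length(scheme$bvals), " volumes)")
  if (any(!is.finite(data)) || any(data < 0))
    stop("signals must be finite and non-negative")
  structure(list(data = data, scheme = scheme, affine = affine,
                 subject = as.character(subject), time = as.character(time),
                 minutes = as.numeric(minutes)),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat("DWI volume: subject", x$subject, "time", x$time, "-",
      paste(dim(x$data), collapse = " x "), "\n")
  invisible(x)
}

#' Synthesize a noisy DWI acquisition from a tensor field
#'
#' The noiseless signal follows the monoexponential tensor model
#' \eqn{S = S_0 \exp(-b\, g^T D g)} per volume. Rician noise (the magnitude
#' MRI noise model) is applied as \eqn{\sqrt{(S+n_1)^2 + n_2^2}} with
#' \eqn{n_1, n_2} independent zero-mean Gaussians of standard deviation
#' \code{S0 / snr}. Gaussian and noise-free modes support oracle tests.
#'
#' @param tensors a \code{\link{tensor_volume}}.
#' @param scheme a \code{\link{gradient_scheme}}.
#' @param S0 non-diffusion-weighted signal level.
#' @param snr signal-to-noise ratio at b = 0; \code{Inf} disables noise.
#' @param seed integer seed, or NULL to draw from the current RNG state.
#' @param noise \code{"rician"} (default), \code{"gaussian"}, or
#'   \code{"none"}.
#' @param subject,time,minutes metadata passed to \code{\link{dwi_volume}}.
#' @return A \code{\link{dwi_volume}}.
#' @export
synthesize_dwi <- function(tensors, scheme, S0 = 1000, snr = 30, seed = NULL,
                           noise = c("rician", "gaussian", "none"),
                           subject = NA_character_, time = NA_character_,
                           minutes = NA_real_) {
  stopifnot(inherits(tensors, "tensor_volume"),
            inherits(scheme, "gradient_scheme"), S0 > 0, snr > 0)
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(tensors$D)[1:3]
  nvox <- prod(d)
  nvol <- length(scheme$bvals)
  Dmat <- matrix(tensors$D, nvox, 6L)
  g <- scheme$bvecs
  # b * g^T D g expressed on the 6 unique elements
  Q <- -scheme$bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                             2 * g[, 2] * g[, 3])
  S <- S0 * exp(Dmat %*% t(Q))
  if (any(!is.finite(S)))
    stop("non-finite synthetic signal (tensor overflow)")
  if (noise != "none" && is.finite(snr)) {
    sigma <- S0 / snr
    if (noise == "rician") {
      n1 <- matrix(stats::rnorm(nvox * nvol, sd = sigma), nvox, nvol)
      n2 <- matrix(stats::rnorm(nvox * nvol, sd = sigma), nvox, nvol)
      S <- sqrt((S + n1)^2 + n2^2)
    } else {
      S <- pmax(S + matrix(stats::rnorm(nvox * nvol, sd = sigma), nvox, nvol), 0)
    }
  }
  dwi_volume(array(S, c(d, nvol)), scheme, tensors$affine,
             subject = subject, time = time, minutes = minutes)
}

#' Simulate a multi-subject sleep DWI cohort
#'
#' Each subject receives one awake baseline scan plus one scan per entry of
#' the spec's state trajectory. Between-subject variability is log-normal
#' multiplicative on the four diffusivity components entering the ALPS
#' ratio (x and perpendicular, per block), constant across a subject's
#' scans. Deterministic given \code{seed}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n_subjects number of subjects (>= 2).
#' @param between_subject_cv coefficient of variation of the subject-level
#'   diffusivity perturbations.
#' @param seed integer seed (defaults to \code{spec$seed}).
#' @param scheme gradient scheme; default is the two-shell protocol
#'   (b = 800/2800, 30 directions each, 8 b = 0).
#' @param noise noise model passed to \code{\link{synthesize_dwi}}.
#' @param trajectory_rows indices of trajectory rows to simulate (default
#'   all); the awake scan is always included.
#' @param annotation optional annotation grid to attach verbatim (e.g. a
#'   fixture with excluded-subject patterns); by default an all-included
#'   grid (one awake epoch followed by sleep epochs) is generated.
#' @param keep_truth keep the ground-truth tensor volumes per scan.
#' @return Object of class \code{alps_cohort}: list with \code{subjects}
#'   (per subject, a list of \code{dwi_volume} in scan order and optional
#'   \code{truth}), \code{grid} (annotation grid), \code{spec},
#'   \code{scheme}.
#' @export
simulate_cohort <- function(spec, n_subjects = 9L, between_subject_cv = 0.03,
                            seed = spec$seed,
                            scheme = build_gradient_scheme(30L, c(800, 2800),
                                                           8L, seed = 1L),
                            noise = "rician",
                            trajectory_rows = seq_len(nrow(spec$trajectory)),
                            annotation = NULL,
                            keep_truth = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 2L,
            between_subject_cv >= 0)
  force(scheme)  # direction design has its own seed; keep it off our stream
  set.seed(seed)
  base <- build_phantom(spec)
  traj <- spec$trajectory[trajectory_rows, , drop = FALSE]
  sdlog <- sqrt(log(1 + between_subject_cv^2))
  subjects <- vector("list", n_subjects)
  names(subjects) <- sprintf("S%02d", seq_len(n_subjects))
  for (s in seq_len(n_subjects)) {
    # subject-level factors for Dxx(proj), Dxx(assoc), Dyy(proj), Dzz(assoc)
    f <- if (between_subject_cv > 0) exp(stats::rnorm(4L, 0, sdlog)) else rep(1, 4)
    tv <- base
    proj <- tv$labels == 1L; assoc <- tv$labels == 2L
    Dxx <- tv$D[, , , 1]; Dxx[proj] <- Dxx[proj] * f[1]
    Dxx[assoc] <- Dxx[assoc] * f[2]; tv$D[, , , 1] <- Dxx
    Dyy <- tv$D[, , , 2]; Dyy[proj] <- Dyy[proj] * f[3]; tv$D[, , , 2] <- Dyy
    Dzz <- tv$D[, , , 3]; Dzz[assoc] <- Dzz[assoc] * f[4]; tv$D[, , , 3] <- Dzz
    scans <- vector("list", nrow(traj) + 1L)
    truth <- vector("list", nrow(traj) + 1L)
    labs <- c("awake", format(traj$minutes))
    mins <- c(spec$awake_minutes, traj$minutes)
    truth[[1]] <- tv
    for (t in seq_len(nrow(traj)))
      truth[[t + 1L]] <- apply_state_modulation(tv, traj$a[t], traj$b[t])
    for (t in seq_along(truth))
      scans[[t]] <- synthesize_dwi(truth[[t]], scheme, S0 = spec$S0,
                                   snr = spec$snr, seed = NULL, noise = noise,
                                   subject = names(subjects)[s],
                                   time = labs[t], minutes = mins[t])
    names(scans) <- labs
    subjects[[s]] <- if (keep_truth) list(scans = scans, truth = truth)
                     else list(scans = scans)
  }
  if (is.null(annotation))
    annotation <- make_annotation_grid(names(subjects))
  structure(list(subjects = subjects, grid = annotation, spec = spec,
                 scheme = scheme, seed = seed), class = "alps_cohort")
}

#' @export
print.alps_cohort <- function(x, ...) {
  ns <- length(x$subjects)
  nt <- length(x$subjects[[1]]$scans)
  cat("Simulated DWI cohort:", ns, "subjects x", nt, "time points\n")
  cat("  scheme:", length(x$scheme$bvals), "volumes; SNR", x$spec$snr,
      "; seed", x$seed, "\n")
  invisible(x)
}

#' Build an all-included annotation grid
#'
#' One row per subject over 17 epochs: epoch 1 awake (0), later epochs
#' sleep (1). Specific epochs can be overridden to build excluded-subject
#' fixtures.
#'
#' @param subjects character vector of subject ids.
#' @param n_epochs number of epochs (default 17).
#' @param override optional list \code{subject -> named character vector}
#'   mapping epoch index (as name) to a label in \{"0","1","N"\}.
#' @return Object of class \code{annotation_grid} (data.frame: column
#'   \code{subject} plus \code{epoch_1..epoch_n}).
#' @export
make_annotation_grid <- function(subjects, n_epochs = 17L, override = NULL) {
  m <- matrix("1", length(subjects), n_epochs)
  m[, 1] <- "0"
  rownames(m) <- subjects
  if (!is.null(override))
    for (s in names(override)) {
      idx <- as.integer(names(override[[s]]))
      m[s, idx] <- unname(override[[s]])
    }
  grid <- data.frame(subject = subjects, m, stringsAsFactors = FALSE)
  names(grid) <- c("subject", paste0("epoch_", seq_len(n_epochs)))
  structure(grid, class = c("annotation_grid", "data.frame"))
}
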