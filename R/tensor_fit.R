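#' Select one b-shell (plus b = 0 volumes) from a DWI acquisition
#'
#' ALPS analyses conventionally restrict tensor estimation to a low-b shell;
#' this keeps the extraction a pure configuration choice of the pipeline.
#'
#' @param dwi a \code{\link{dwi_volume}}.
#' @param b_target shell b-value to keep (s/mm^2).
#' @param tol b-value tolerance; volumes with |b - b_target| <= tol are
#'   kept. b = 0 volumes are identified as b < b0_max and always kept.
#' @param b0_max threshold under which a volume counts as b = 0.
#' @return A \code{\link{dwi_volume}} containing the b = 0 volumes and the
#'   selected shell, with a consistently filtered scheme.
#' @export
select_shell <- function(dwi, b_target, tol = 50, b0_max = 50) {
  stopifnot(inherits(dwi, "dwi_volume"))
  b <- dwi$scheme$bvals
  keep <- b < b0_max | abs(b - b_target) <= tol
  sub <- which(keep)
  dw <- b[sub] >= b0_max
  dirs <- unique(round(abs(dwi$scheme$bvecs[sub[dw], , drop = FALSE]), 6))
  if (length(sub) < 7L || nrow(dirs) < 6L)
    stop("shell selection under-determined: ", length(sub), " volumes, ",
         nrow(dirs), " distinct directions (need >= 7 and >= 6)")
  dwi_volume(dwi$data[, , , sub, drop = FALSE],
             gradient_scheme(b[sub], dwi$scheme$bvecs[sub, , drop = FALSE]),
             dwi$affine, subject = dwi$subject, time = dwi$time,
             minutes = dwi$minutes)
}

# design matrix of the log-linear tensor model:
# ln S = ln S0 - b g' D g ; columns: lnS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit per-voxel diffusion tensors by (weighted) linear least squares
#'
#' Solves the log-linearised monoexponential model
#' \eqn{\ln S = \ln S_0 - b\, g^T D g} per voxel for the six unique tensor
#' elements and \eqn{\ln S_0} jointly. The default estimator is weighted
#' least squares with one reweighting pass, weights equal to the squared
#' signal predicted by the initial ordinary-least-squares fit (the standard
#' first-order variance model for log-transformed Rician magnitude data).
#' Voxels containing any non-positive signal are masked (flagged, not
#' fatal).
#'
#' @param dwi a shell-selected \code{\link{dwi_volume}} with at least one
#'   b = 0 volume.
#' @param method \code{"wls"} (default) or \code{"ols"}.
#' @param mask optional logical array (same grid) restricting the fit.
#' @return A \code{\link{tensor_volume}} with attributes
#'   \code{log_s0} (array) and \code{flags} (logical array, TRUE where the
#'   fit was skipped or invalid).
#' @export
fit_tensor <- function(dwi, method = c("wls", "ols"), mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  method <- match.arg(method)
  if (!any(dwi$scheme$bvals == 0))
    stop("at least one b = 0 volume is required to estimate S0")
  X <- tensor_design(dwi$scheme)
  if (qr(X)$rank < 7L)
    stop("rank-deficient design: the gradient scheme does not determine ",
         "the tensor")
  d <- dim(dwi$data)[1:3]
  nvox <- prod(d)
  S <- matrix(dwi$data, nvox, dim(dwi$data)[4])
  use <- rep(TRUE, nvox)
  if (!is.null(mask)) use <- use & as.logical(mask)
  bad <- rowSums(S <= 0) > 0
  use <- use & !bad
  beta <- matrix(NA_real_, nvox, 7L)
  if (any(use)) {
    Y <- log(S[use, , drop = FALSE])
    XtXi <- solve(crossprod(X))
    B <- tcrossprod(Y %*% X, XtXi)  # OLS, one solve for all voxels
    if (method == "wls") {
      W <- exp(2 * tcrossprod(B, X))  # squared predicted signals
      # per-voxel normal equations assembled by one matrix product each
      jk <- which(upper.tri(matrix(0, 7, 7), diag = TRUE), arr.ind = TRUE)
      P <- X[, jk[, 1], drop = FALSE] * X[, jk[, 2], drop = FALSE]
      A <- W %*% P           # nvox x 28 upper-triangle entries of X'WX
      Bv <- (W * Y) %*% X    # nvox x 7 entries of X'Wy
      M <- matrix(0, 7, 7)
      for (v in seq_len(nrow(A))) {
        M[upper.tri(M, diag = TRUE)] <- A[v, ]
        M[lower.tri(M)] <- t(M)[lower.tri(M)]
        B[v, ] <- solve(M, Bv[v, ])
      }
    }
    beta[use, ] <- B
  }
  D <- array(beta[, 2:7], c(d, 6L))
  tv <- tensor_volume(D, dwi$affine)
  attr(tv, "log_s0") <- array(beta[, 1], d)
  attr(tv, "flags") <- array(!use, d)
  tv
}

#' Eigen-decompose a tensor field
#'
#' Eigenvalues are sorted descending; negative eigenvalues are clamped to
#' zero and the voxel flagged. The primary eigenvector sign is fixed so its
#' largest-magnitude component is non-negative (ties broken x before y
#' before z).
#'
#' @param tensors a \code{\link{tensor_volume}} (e.g. from
#'   \code{\link{fit_tensor}}).
#' @param mask optional logical array restricting the decomposition.
#' @return Object of class \code{eigen_map}: list with \code{lambda}
#'   (nx, ny, nz, 3), \code{v1} (nx, ny, nz, 3), \code{flags} (logical
#'   array; fit failures and clamped voxels), \code{affine}.
#' @export
eigen_decompose <- function(tensors, mask = NULL) {
  stopifnot(inherits(tensors, "tensor_volume"))
  d <- dim(tensors$D)[1:3]
  nvox <- prod(d)
  Dmat <- matrix(tensors$D, nvox, 6L)
  flags <- attr(tensors, "flags")
  flags <- if (is.null(flags)) rep(FALSE, nvox) else as.logical(flags)
  use <- !flags & rowSums(!is.finite(Dmat)) == 0
  if (!is.null(mask)) use <- use & as.logical(mask)
  lam <- matrix(NA_real_, nvox, 3L)
  v1 <- matrix(NA_real_, nvox, 3L)
  M <- matrix(0, 3, 3)
  for (v in which(use)) {
    M[1, 1] <- Dmat[v, 1]; M[2, 2] <- Dmat[v, 2]; M[3, 3] <- Dmat[v, 3]
    M[1, 2] <- M[2, 1] <- Dmat[v, 4]
    M[1, 3] <- M[3, 1] <- Dmat[v, 5]
    M[2, 3] <- M[3, 2] <- Dmat[v, 6]
    e <- eigen(M, symmetric = TRUE)
    l <- e$values
    if (any(l < 0)) {
      flags[v] <- TRUE
      l <- pmax(l, 0)
    }
    lam[v, ] <- l
    vec <- e$vectors[, 1]
    dom <- which.max(abs(vec))  # which.max breaks exact ties x < y < z
    if (vec[dom] < 0) vec <- -vec
    v1[v, ] <- vec
  }
  flags[!use] <- TRUE
  structure(list(lambda = array(lam, c(d, 3L)), v1 = array(v1, c(d, 3L)),
                 flags = array(flags, d), affine = tensors$affine),
            class = "eigen_map")
}
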