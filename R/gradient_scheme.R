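#' Gradient scheme constructor
#'
#' A gradient scheme pairs one b-value (s/mm^2) with one diffusion-encoding
#' direction per acquired volume. Directions for diffusion-weighted volumes
#' must be unit vectors; b = 0 volumes carry the zero vector.
#'
#' @param bvals numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs numeric matrix, one row per volume, three columns (x, y, z).
#' @return An object of class \code{gradient_scheme}: a list with elements
#'   \code{bvals} and \code{bvecs}.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals))
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         " rows) describe different numbers of volumes")
  if (ncol(bvecs) != 3L)
    stop("bvecs must have three columns (x, y, z)")
  if (!any(bvals == 0))
    stop("at least one b = 0 volume is required")
  norms <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(abs(norms[dw] - 1) > 1e-6))
    stop("directions of diffusion-weighted volumes must have unit norm")
  if (any(norms[!dw] > 1e-6))
    stop("b = 0 volumes must carry the zero direction vector")
  structure(list(bvals = bvals, bvecs = unname(bvecs)),
            class = "gradient_scheme")
}

#' Build a multi-shell gradient scheme with well-spread directions
#'
#' Directions on each shell are spread by electrostatic repulsion on the
#' sphere with antipodal symmetry (a pair of opposite charges per
#' direction), the standard design for diffusion MRI acquisitions. The
#' optimisation is deterministic given \code{seed}.
#'
#' @param n_dirs_per_shell number of directions per shell (>= 6; six is the
#'   minimum that determines the symmetric diffusion tensor).
#' @param shell_bvals positive b-values, one per shell (s/mm^2).
#' @param n_b0 number of b = 0 volumes (>= 1).
#' @param seed integer seed for the repulsion initialisation.
#' @param n_iter repulsion iterations.
#' @return A \code{\link{gradient_scheme}} with \code{n_b0} leading b = 0
#'   volumes followed by the shells in the order given.
#' @export
build_gradient_scheme <- function(n_dirs_per_shell, shell_bvals, n_b0 = 1L,
                                  seed = 1L, n_iter = 300L) {
  if (n_dirs_per_shell < 6L)
    stop("at least 6 directions per shell are required ",
         "(the diffusion tensor is under-determined otherwise)")
  if (any(shell_bvals <= 0)) stop("shell b-values must be positive")
  if (n_b0 < 1L) stop("at least one b = 0 volume is required")
  dirs <- repulsion_directions(n_dirs_per_shell, seed = seed, n_iter = n_iter)
  bvals <- c(rep(0, n_b0), rep(shell_bvals, each = n_dirs_per_shell))
  bvecs <- rbind(matrix(0, n_b0, 3L),
                 do.call(rbind, rep(list(dirs), length(shell_bvals))))
  gradient_scheme(bvals, bvecs)
}

# Electrostatic-repulsion point set on the unit sphere with antipodal
# symmetry. Gradient descent on the Coulomb energy of the n point pairs;
# deterministic given the seed.
repulsion_directions <- function(n, seed = 1L, n_iter = 300L, step = 0.05) {
  set.seed(seed)
  x <- matrix(stats::rnorm(3L * n), n, 3L)
  x <- x / sqrt(rowSums(x^2))
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      d <- sweep(-x, 2L, -x[i, ])        # x_i - x_j
      da <- sweep(x, 2L, x[i, ], "+")    # x_i - (-x_j)
      r3 <- pmax(rowSums(d^2), 1e-12)^1.5
      ra3 <- pmax(rowSums(da^2), 1e-12)^1.5
      r3[i] <- Inf                        # self term
      f <- d / r3 + da / ra3
      force[i, ] <- colSums(f)
    }
    # project onto the tangent plane and take a normalised step
    radial <- rowSums(force * x)
    force <- force - radial * x
    nrm <- sqrt(rowSums(force^2))
    scale <- step / max(nrm, 1e-12)
    x <- x + scale * force
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

#' @export
print.gradient_scheme <- function(x, ...) {
  shells <- sort(unique(x$bvals[x$bvals > 0]))
  cat("Gradient scheme:", length(x$bvals), "volumes\n")
  cat("  b = 0:", sum(x$bvals == 0), "volumes\n")
  for (b in shells)
    cat("  b =", b, "s/mm^2:", sum(x$bvals == b), "directions\n")
  invisible(x)
}

#' Minimum pairwise angle of a direction set
#'
#' Angles are computed between axes (antipodally symmetric), in degrees.
#' Used to assess the spread of a gradient design.
#'
#' @param dirs matrix of unit row vectors.
#' @return Smallest pairwise inter-axis angle in degrees.
#' @export
min_pairwise_angle <- function(dirs) {
  g <- abs(tcrossprod(as.matrix(dirs)))
  diag(g) <- -Inf
  acos(pmin(max(g), 1)) * 180 / pi
}
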