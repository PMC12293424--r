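# Shared fixtures and independent oracles for the test suite.

# Compact phantom: identical geometry/calibration to the default, smaller
# grid, so fits stay fast in unit tests.
small_spec <- function(...) {
  phantom_spec(dim = c(26L, 25L, 11L), ...)
}

# minimal single-shell scheme for tensor fits
mini_scheme <- function(n_dirs = 12L, b = 800, n_b0 = 2L, seed = 7L) {
  build_gradient_scheme(n_dirs, b, n_b0, seed = seed)
}

# uniform tensor field with given diagonal (and optional off-diagonal)
uniform_tensor_volume <- function(diagel, offdiag = c(0, 0, 0),
                                  dim = c(4L, 4L, 4L),
                                  affine = diag(c(1, 1, 1, 1))) {
  D <- array(0, c(dim, 6L))
  for (e in 1:3) D[, , , e] <- diagel[e]
  for (e in 4:6) D[, , , e] <- offdiag[e - 3]
  tensor_volume(D, affine)
}

# brute-force oracle: all voxels whose centers fall in the half-open cube
oracle_voxels_in_cube <- function(center, edge, affine, dim) {
  h <- edge / 2
  hits <- NULL
  for (i in seq_len(dim[1])) for (j in seq_len(dim[2]))
    for (k in seq_len(dim[3])) {
      mm <- as.vector(affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]
      if (all(mm >= center - h & mm < center + h))
        hits <- rbind(hits, c(i, j, k))
    }
  if (is.null(hits)) matrix(integer(0), 0, 3) else hits
}

# literal Benjamini-Hochberg step-up, written independently of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Rician mean by numerical integration (oracle for the noise model)
oracle_rician_mean <- function(nu, sigma) {
  f <- function(x) {
    x^2 / sigma^2 * exp(-(x^2 + nu^2) / (2 * sigma^2) + x * nu / sigma^2) *
      besselI(x * nu / sigma^2, 0, expon.scaled = TRUE)
  }
  stats::integrate(f, 0, nu + 12 * sigma, rel.tol = 1e-10)$value
}

# exact Friedman p by enumeration of all within-row permutations (k <= 3)
oracle_friedman_exact_p <- function(x) {
  k <- ncol(x)
  perms <- as.matrix(expand.grid(rep(list(seq_len(factorial(k))), nrow(x))))
  allp <- gtools_permutations(k)
  obs <- alpsdti::friedman_test(x)$statistic
  cnt <- 0L
  for (r in seq_len(nrow(perms))) {
    y <- x
    for (i in seq_len(nrow(x))) y[i, ] <- x[i, allp[perms[r, i], ]]
    if (alpsdti::friedman_test(y)$statistic >= obs - 1e-9) cnt <- cnt + 1L
  }
  cnt / nrow(perms)
}

# all permutations of 1..k (tiny k), no package dependency
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
oracle_wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(Wall <= W + 1e-9), mean(Wall >= W - 1e-9)))
}

# strict-majority consensus, written as a direct count
oracle_consensus <- function(labels) {
  n <- length(labels)
  n0 <- sum(labels == "0"); n1 <- sum(labels == "1")
  if (n0 * 2 > n) "0" else if (n1 * 2 > n) "1" else "N"
}

# quad means by per-voxel accumulation over explicit voxel lists
oracle_quad <- function(tv, proj_vox, assoc_vox) {
  acc <- function(vox, e) {
    s <- 0
    for (r in seq_len(nrow(vox))) s <- s + tv$D[vox[r, 1], vox[r, 2], vox[r, 3], e]
    s / nrow(vox)
  }
  c(Dxx_proj = acc(proj_vox, 1), Dxx_assoc = acc(assoc_vox, 1),
    Dyy_proj = acc(proj_vox, 2), Dzz_assoc = acc(assoc_vox, 3))
}

table1_grid <- function() {
  read_annotation_grid(system.file("extdata",
                                   "annotations_overnight_12x17.tsv",
                                   package = "alpsdti"))
}
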