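#' Friedman rank-sum test for repeated measures
#'
#' Rank-based one-way repeated-measures test: values are ranked within each
#' subject across conditions and the tie-corrected chi-square statistic
#' \deqn{\chi^2_F = \frac{12 \sum_j (R_j - n(k+1)/2)^2}
#'   {n k (k+1) - \sum(t^3 - t)/(k-1)}}
#' is referred to the chi-square distribution with k - 1 degrees of freedom,
#' or to a seeded within-subject permutation distribution.
#'
#' @param x numeric matrix, subjects (rows) x conditions (columns); no
#'   missing cells.
#' @param method \code{"chisq"} (default) or \code{"permutation"}.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed seed for the permutation draw.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{method}.
#' @export
friedman_test <- function(x, method = c("chisq", "permutation"),
                          n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (any(!is.finite(x)))
    stop("missing or non-finite cells: the test needs complete series")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  stat <- friedman_statistic(x)
  df <- k - 1L
  if (method == "chisq") {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    if (stat == 0) p <- 1
  } else {
    set.seed(seed)
    cnt <- 0L
    perm <- x
    for (b in seq_len(n_perm)) {
      for (i in seq_len(n)) perm[i, ] <- x[i, sample.int(k)]
      if (friedman_statistic(perm) >= stat - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1L) / (n_perm + 1L)
  }
  list(statistic = stat, df = df, p_value = p, method = method)
}

# tie-corrected Friedman chi-square; 0 when all within-subject values tie
friedman_statistic <- function(x) {
  n <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1L, rank))
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  ties <- apply(r, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  den <- n * k * (k + 1) - sum(ties) / (k - 1)
  if (den <= 0) return(0)
  num / den
}

#' Wilcoxon signed-rank test with effect size
#'
#' Paired two-sided test of sleep values against the awake baseline. Zero
#' differences are dropped; with n <= 15 informative pairs the p-value is
#' exact, from full enumeration of the 2^n sign assignments conditional on
#' the observed absolute-difference ranks (ties use average ranks);
#' otherwise a normal approximation with tie and continuity corrections is
#' used. The effect size is \eqn{r = |z|/\sqrt{n}} with z the
#' normal-equivalent of the two-sided p, signed by the median difference;
#' the matched-pairs rank-biserial correlation is available as an
#' alternative convention.
#'
#' @param awake,sleep paired numeric vectors.
#' @param exact_max largest n for which the exact enumeration is used.
#' @param effect \code{"z_over_sqrt_n"} (default) or \code{"rank_biserial"}.
#' @return list with \code{W} (sum of positive-difference ranks), \code{n}
#'   (informative pairs), \code{p_value}, \code{r}, \code{method}.
#' @export
wilcoxon_signed_rank <- function(awake, sleep, exact_max = 15L,
                                 effect = c("z_over_sqrt_n",
                                            "rank_biserial")) {
  effect <- match.arg(effect)
  if (length(awake) != length(sleep)) stop("paired samples required")
  d <- sleep - awake
  d <- d[d != 0]
  if (length(d) == 0) stop("no_information: all differences are zero")
  n <- length(d)
  if (n < 5L) stop("fewer than 5 informative pairs")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= exact_max) {
    # distribution of W over all 2^n equally likely sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% rk)
    p <- min(1, 2 * min(mean(Wall <= W + 1e-9), mean(Wall >= W - 1e-9)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- sum(tapply(rk, rk, length)^3 - tapply(rk, rk, length))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - tie / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  r <- if (effect == "z_over_sqrt_n") {
    abs(stats::qnorm(p / 2)) / sqrt(n)
  } else {
    mu <- n * (n + 1) / 4
    (W - mu) / mu  # rank-biserial in [-1, 1]
  }
  r <- abs(r) * sign(stats::median(d))
  list(W = W, n = n, p_value = p, r = r, method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate control across a family of p-values: sort
#' ascending, multiply \eqn{p_{(i)}} by \eqn{m/i}, enforce monotonicity
#' from the largest down, cap at 1, and return in input order.
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Select ROI pairs driven by perivascular (x-direction) diffusivity
#'
#' Keeps pairs whose index trajectory differs significantly across time
#' (Friedman p below \code{alpha}) and whose index elevation at the pair's
#' peak time point is at least partly carried by an increased numerator
#' (positive mean x-diffusivity change), i.e. attributable to perivascular
#' water movement rather than solely to a perpendicular-diffusivity drop.
#'
#' @param reports list (or data.frame) per pair with elements/columns
#'   \code{pair_id}, \code{friedman_p}, \code{peak_d_num} (mean fractional
#'   numerator change at the peak-index time point).
#' @param alpha significance threshold.
#' @return Character vector of selected pair ids.
#' @export
select_significant_rois <- function(reports, alpha = 0.05) {
  df <- as.data.frame(reports)
  stopifnot(all(c("pair_id", "friedman_p", "peak_d_num") %in% names(df)))
  df$pair_id[df$friedman_p < alpha & df$peak_d_num > 0]
}
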