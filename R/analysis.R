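#' Full time-resolved ALPS statistical analysis
#'
#' Orchestrates the inference stage over a cohort's ALPS series: subject
#' inclusion from the EEG-consensus annotation grid, a per-pair Friedman
#' test across the analyzed time points, post hoc Wilcoxon signed-rank
#' comparisons of each sleep time point against the awake baseline with
#' Benjamini-Hochberg correction (family: the sleep-vs-awake comparisons
#' within one pair) and effect sizes, per-time mean index with standard
#' error and percent change, the numerator/denominator decomposition of
#' the index trajectory, and final ROI selection.
#'
#' @param series an \code{alps_series} (see
#'   \code{\link{compute_alps_series}}).
#' @param grid optional \code{annotation_grid} gating subject inclusion;
#'   NULL includes all subjects present in the series.
#' @param window epoch window for \code{\link{include_subjects}}.
#' @param alpha significance threshold.
#' @param effect effect-size convention, see
#'   \code{\link{wilcoxon_signed_rank}}.
#' @return Object of class \code{alps_analysis}: list with
#'   \code{subjects} (included ids), \code{pairs} (per-pair data.frame:
#'   Friedman statistic/p, peak time, peak numerator change, selection
#'   flag), \code{timepoints} (per pair x sleep time: mean index, standard
#'   error, percent change, raw/adjusted p, effect size),
#'   \code{decomposition} (per pair x time: component and index changes
#'   from subject-mean quads), \code{alpha}.
#' @export
run_full_analysis <- function(series, grid = NULL, window = 1:7,
                              alpha = 0.05, effect = "z_over_sqrt_n") {
  subjects <- sort(unique(series$subject))
  if (!is.null(grid)) {
    included <- include_subjects(grid, window)
    subjects <- intersect(subjects, included)
  }
  if (length(subjects) < 2L)
    stop("fewer than 2 included subjects")
  ser <- series[series$subject %in% subjects, , drop = FALSE]
  times <- unique(ser[ser$time != "awake", c("time", "minutes")])
  times <- times[order(times$minutes), ]
  pair_rows <- list(); tp_rows <- list(); dec_rows <- list()
  for (pid in unique(ser$pair_id)) {
    ps <- ser[ser$pair_id == pid, , drop = FALSE]
    # subjects x time matrix of indices, awake first
    labs <- c("awake", times$time)
    mat <- sapply(labs, function(tl)
      sapply(subjects, function(s) {
        v <- ps$alps[ps$subject == s & ps$time == tl]
        if (length(v) == 1) v else NA_real_
      }))
    if (any(!is.finite(mat)))
      stop("pair ", pid, ": incomplete index series for included subjects")
    fr <- friedman_test(mat)
    awake <- mat[, 1]
    per_time <- lapply(seq_len(nrow(times)), function(ti) {
      v <- mat[, ti + 1L]
      wt <- wilcoxon_signed_rank(awake, v, effect = effect)
      data.frame(pair_id = pid, time = times$time[ti],
                 minutes = times$minutes[ti],
                 mean_index = mean(v), se_index = stats::sd(v) / sqrt(length(v)),
                 pct_change = mean(v / awake - 1),
                 p_raw = wt$p_value, r = wt$r, stringsAsFactors = FALSE)
    })
    tp <- do.call(rbind, per_time)
    tp$p_adj <- bh_adjust(tp$p_raw)
    # component decomposition from subject-mean quads (identity-exact)
    qcols <- c("Dxx_proj", "Dxx_assoc", "Dyy_proj", "Dzz_assoc")
    mq <- aggregate(ps[qcols], by = list(time = ps$time), FUN = mean)
    mq <- mq[match(c("awake", times$time), mq$time), ]
    dec <- decompose_components(mq)
    dec$pair_id <- pid
    dec$minutes <- times$minutes[match(dec$time, times$time)]
    peak <- which.max(tp$mean_index)
    pair_rows[[pid]] <- data.frame(
      pair_id = pid, friedman_chisq = fr$statistic, friedman_df = fr$df,
      friedman_p = fr$p_value, peak_time = tp$time[peak],
      peak_minutes = tp$minutes[peak],
      peak_pct_change = tp$pct_change[peak],
      peak_d_num = dec$d_num[match(tp$time[peak], dec$time)],
      stringsAsFactors = FALSE)
    tp_rows[[pid]] <- tp
    dec_rows[[pid]] <- dec
  }
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL
  pairs$selected <- pairs$pair_id %in% select_significant_rois(pairs, alpha)
  structure(list(subjects = subjects, pairs = pairs,
                 timepoints = do.call(rbind, tp_rows),
                 decomposition = do.call(rbind, dec_rows),
                 alpha = alpha, n = length(subjects)),
            class = "alps_analysis")
}

#' @export
print.alps_analysis <- function(x, ...) {
  cat("ALPS time-course analysis:", x$n, "subjects,",
      nrow(x$pairs), "ROI pairs\n")
  sel <- x$pairs$pair_id[x$pairs$selected]
  cat("  selected pairs (Friedman p <", x$alpha,
      "and x-driven):", if (length(sel)) paste(sel, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
summary.alps_analysis <- function(object, digits = 3, ...) {
  cat("Included subjects (", object$n, "): ",
      paste(object$subjects, collapse = ", "), "\n\n", sep = "")
  cat("Per-pair Friedman test:\n")
  pf <- object$pairs
  pf$friedman_chisq <- round(pf$friedman_chisq, digits)
  pf$friedman_p <- signif(pf$friedman_p, digits)
  pf$peak_pct_change <- round(100 * pf$peak_pct_change, 2)
  print(pf[, c("pair_id", "friedman_chisq", "friedman_p", "peak_time",
               "peak_pct_change", "selected")], row.names = FALSE)
  sel <- object$pairs$pair_id[object$pairs$selected]
  show <- if (length(sel)) sel[1] else object$pairs$pair_id[1]
  cat("\nTime course of pair ", show, " (index mean ± SE, % change, p):\n",
      sep = "")
  tp <- object$timepoints[object$timepoints$pair_id == show, ]
  out <- data.frame(time = tp$time,
                    index = sprintf("%.2f ± %.2f", tp$mean_index,
                                    tp$se_index),
                    change = sprintf("%.2f%%", 100 * tp$pct_change),
                    p_raw = signif(tp$p_raw, digits),
                    p_adj = signif(tp$p_adj, digits),
                    r = round(tp$r, digits))
  print(out, row.names = FALSE)
  invisible(object)
}

#' Plot an ALPS analysis time course
#'
#' Mean index with standard-error bars against scan time, one panel line
#' per selected (or requested) ROI pair; the vertical line marks sleep
#' notification.
#'
#' @param x an \code{alps_analysis}.
#' @param pair_ids pairs to draw (default: selected pairs, or all if none
#'   selected).
#' @param awake_minutes x position of the awake baseline.
#' @param ... passed to \code{matplot}.
#' @export
plot.alps_analysis <- function(x, pair_ids = NULL, awake_minutes = -9, ...) {
  if (is.null(pair_ids)) {
    pair_ids <- x$pairs$pair_id[x$pairs$selected]
    if (length(pair_ids) == 0) pair_ids <- x$pairs$pair_id
  }
  tp <- x$timepoints[x$timepoints$pair_id %in% pair_ids, ]
  xs <- sort(unique(tp$minutes))
  ys <- sapply(pair_ids, function(p)
    tp$mean_index[tp$pair_id == p][order(tp$minutes[tp$pair_id == p])])
  graphics::matplot(xs, ys, type = "b", pch = 16, lty = 1,
                    xlab = "minutes since sleep notification",
                    ylab = "ALPS index", ...)
  for (p in seq_along(pair_ids)) {
    sub <- tp[tp$pair_id == pair_ids[p], ]
    graphics::arrows(sub$minutes, sub$mean_index - sub$se_index,
                     sub$minutes, sub$mean_index + sub$se_index,
                     angle = 90, code = 3, length = 0.03, col = p)
  }
  graphics::abline(v = 0, col = "red", lty = 2)
  graphics::legend("topright", legend = pair_ids, col = seq_along(pair_ids),
                   pch = 16, bty = "n")
  invisible(x)
}
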