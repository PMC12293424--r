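#' Expert-consensus label for one epoch
#'
#' Implements the two-of-three (strict-majority) rule used for EEG sleep
#' annotation: the epoch receives the awake/sleep label shared by a strict
#' majority of raters; when no readable label reaches a majority (including
#' epochs dominated by unreadable ratings) the consensus is \code{"N"}.
#'
#' @param labels character vector of one epoch's rater labels, each
#'   \code{"0"} (awake), \code{"1"} (sleep) or \code{"U"} (unreadable).
#' @return \code{"0"}, \code{"1"} or \code{"N"}.
#' @export
consensus_epoch <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("consensus needs at least two raters")
  if (!all(labels %in% c("0", "1", "U")))
    stop("labels must be in {0, 1, U}")
  n <- length(labels)
  for (lab in c("0", "1"))
    if (sum(labels == lab) > n / 2) return(lab)
  "N"
}

#' Consensus annotation grid from per-rater labels
#'
#' @param ratings data.frame with columns \code{subject}, \code{epoch},
#'   \code{rater}, \code{label} (\code{"0"}/\code{"1"}/\code{"U"}).
#' @param n_epochs number of epochs per subject.
#' @return An \code{annotation_grid} (see \code{\link{make_annotation_grid}}).
#' @export
consensus_grid <- function(ratings, n_epochs = 17L) {
  subjects <- unique(ratings$subject)
  m <- matrix("N", length(subjects), n_epochs)
  for (s in seq_along(subjects)) for (e in seq_len(n_epochs)) {
    lab <- ratings$label[ratings$subject == subjects[s] & ratings$epoch == e]
    if (length(lab) >= 2L) m[s, e] <- consensus_epoch(lab)
  }
  grid <- data.frame(subject = subjects, m, stringsAsFactors = FALSE)
  names(grid) <- c("subject", paste0("epoch_", seq_len(n_epochs)))
  structure(grid, class = c("annotation_grid", "data.frame"))
}

#' Subject inclusion filter for the ALPS analysis window
#'
#' A subject enters the analysis iff, inside the window of analyzed scans,
#' the first epoch is awake (\code{"0"}) and every later epoch is sleep
#' (\code{"1"}) — no awakenings and no unreadable/no-consensus epochs. The
#' default window is epochs 1--7 (awake baseline plus six sleep scans).
#'
#' @param grid an \code{annotation_grid}.
#' @param window integer epoch indices; the first is the awake scan.
#' @return Character vector of included subject ids.
#' @export
include_subjects <- function(grid, window = 1:7) {
  cols <- paste0("epoch_", window)
  if (!all(c("subject", cols) %in% names(grid)))
    stop("grid lacks required columns: ",
         paste(setdiff(c("subject", cols), names(grid)), collapse = ", "))
  lab <- as.matrix(grid[, cols, drop = FALSE])
  if (!all(lab %in% c("0", "1", "N")))
    stop("grid labels must be in {0, 1, N}")
  ok <- lab[, 1] == "0" &
    apply(lab[, -1, drop = FALSE] == "1", 1, all)
  grid$subject[ok]
}

#' Fleiss' kappa for a fixed panel of raters
#'
#' Chance-corrected agreement \eqn{\kappa = (\bar P - \bar P_e)/(1 - \bar
#' P_e)} over epochs rated by the same number of raters. Unreadable
#' ratings (\code{"U"}) either drop the epoch (default) or form their own
#' category.
#'
#' @param ratings character matrix, epochs x raters.
#' @param categories category labels; defaults to the sorted distinct
#'   labels present (after unreadable handling).
#' @param unreadable label marking unreadable ratings.
#' @param unreadable_action \code{"drop"} (drop epochs containing any
#'   unreadable rating) or \code{"category"}.
#' @return Kappa (numeric scalar). In the degenerate case where all raters
#'   use a single category everywhere (\eqn{\bar P_e = 1}), returns 1 with
#'   attribute \code{degenerate = TRUE}.
#' @export
fleiss_kappa <- function(ratings, categories = NULL, unreadable = "U",
                         unreadable_action = c("drop", "category")) {
  unreadable_action <- match.arg(unreadable_action)
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L) stop("Fleiss' kappa needs at least two raters")
  if (unreadable_action == "drop") {
    keep <- rowSums(ratings == unreadable) == 0
    ratings <- ratings[keep, , drop = FALSE]
    if (nrow(ratings) == 0) stop("no epochs left after dropping unreadable")
  }
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  n <- ncol(ratings)   # raters per epoch
  counts <- vapply(categories,
                   function(k) rowSums(ratings == k), numeric(nrow(ratings)))
  counts <- matrix(counts, nrow = nrow(ratings))
  if (any(rowSums(counts) != n))
    stop("ratings outside the stated categories")
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (nrow(counts) * n)
  Pe <- sum(pj^2)
  if (1 - Pe < 1e-12)
    return(structure(1, degenerate = TRUE))
  (Pbar - Pe) / (1 - Pe)
}

#' Simulate per-rater sleep annotations
#'
#' Generates a fixed panel's ratings around a consensus grid: each rater
#' reproduces the consensus label with probability \code{fidelity} and
#' otherwise draws uniformly from the remaining labels (with \code{"N"}
#' consensus mapping to unreadable \code{"U"} ground truth).
#'
#' @param grid an \code{annotation_grid}.
#' @param n_raters panel size.
#' @param fidelity per-rating probability of reproducing the consensus.
#' @param seed integer seed.
#' @return data.frame with columns \code{subject}, \code{epoch},
#'   \code{rater}, \code{label}.
#' @export
simulate_ratings <- function(grid, n_raters = 3L, fidelity = 0.9, seed = 1L) {
  set.seed(seed)
  cols <- grep("^epoch_", names(grid))
  out <- list()
  for (s in seq_len(nrow(grid))) for (e in seq_along(cols)) {
    truth <- grid[[cols[e]]][s]
    if (truth == "N") truth <- "U"
    lab <- vapply(seq_len(n_raters), function(r) {
      if (stats::runif(1) < fidelity) truth
      else sample(setdiff(c("0", "1", "U"), truth), 1L)
    }, character(1))
    out[[length(out) + 1L]] <- data.frame(
      subject = grid$subject[s], epoch = e,
      rater = paste0("R", seq_len(n_raters)), label = lab,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
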