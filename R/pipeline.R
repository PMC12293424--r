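#' alpsdti: DTI-ALPS analysis of glymphatic activity during sleep
#'
#' End-to-end synthetic-cohort pipeline for the diffusion tensor image
#' analysis along the perivascular space (ALPS) index: phantom simulation,
#' two-shell DWI synthesis with Rician noise, low-b tensor fitting,
#' template-space ROI placement and refinement, the ALPS ratio with its
#' component decomposition, EEG-consensus subject inclusion, and
#' nonparametric repeated-measures statistics.
#'
#' @keywords internal
#' @importFrom stats aggregate sd
"_PACKAGE"

#' Run the full synthetic ALPS pipeline
#'
#' Simulates a sleep cohort, measures per-subject ALPS series through the
#' fitting pipeline, and runs the statistical analysis. This is the
#' programmatic equivalent of the bundled command-line stages
#' simulate/fit/alps/stats chained together.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param n_subjects cohort size.
#' @param between_subject_cv between-subject diffusivity variability.
#' @param seed integer seed for the whole run.
#' @param scheme gradient scheme (default: two-shell 30+30 directions,
#'   8 b = 0).
#' @param noise noise model for \code{\link{synthesize_dwi}}.
#' @param trajectory_rows trajectory rows to simulate (default all).
#' @param pairs ROI pairs.
#' @param grid annotation grid; default generated all-included.
#' @param ... further arguments to \code{\link{compute_alps_series}}.
#' @return list with \code{series} (\code{alps_series}),
#'   \code{analysis} (\code{alps_analysis}), \code{grid}.
#' @export
run_alps_pipeline <- function(spec = phantom_spec(), n_subjects = 9L,
                              between_subject_cv = 0.03, seed = spec$seed,
                              scheme = build_gradient_scheme(30L, c(800, 2800),
                                                             8L, seed = 1L),
                              noise = "rician",
                              trajectory_rows = seq_len(nrow(spec$trajectory)),
                              pairs = standard_roi_pairs(), grid = NULL, ...) {
  cohort <- simulate_cohort(spec, n_subjects = n_subjects,
                            between_subject_cv = between_subject_cv,
                            seed = seed, scheme = scheme, noise = noise,
                            trajectory_rows = trajectory_rows,
                            annotation = grid)
  series <- compute_alps_series(cohort, pairs = pairs, ...)
  analysis <- run_full_analysis(series, grid = cohort$grid)
  list(series = series, analysis = analysis, grid = cohort$grid)
}
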