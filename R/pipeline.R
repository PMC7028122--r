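#' Built-in search refinement ladder
#'
#' Location subsets of increasing density used to trace precision against
#' protocol sparseness. Each rung is spatially distributed — it spans the
#' whole screen rather than one eccentricity band, the way a sparse
#' perimetry-style subsample would — so that sparser rungs differ from
#' denser ones in sampling density, not in the field region covered:
#' 4 spread locations, 12 spread locations, the 22-location refined
#' protocol, and all 62 cells.
#'
#' @param grid a \code{search_grid}.
#' @return named list of integer location vectors.
#' @export
search_ladder <- function(grid = search_grid()) {
  cells <- grid$cells
  at <- function(cc, rr) cells$loc[cells$col == cc & cells$row == rr]
  spread4 <- c(at(2, 2), at(8, 2), at(2, 6), at(8, 6))
  spread12 <- c(spread4,
                at(5, 2), at(5, 6), at(2, 4), at(8, 4),
                at(1, 1), at(9, 1), at(1, 7), at(9, 7))
  list(spread4 = sort(spread4),
       spread12 = sort(spread12),
       refined = refined_subset(grid),
       all = sort(cells$loc[!cells$is_center]))
}

#' Run the full psychometric evaluation on a cohort
#'
#' Applies the complete analysis pipeline to a two-run cohort: Bland-Altman
#' test-retest repeatability of the primary outcomes with BCa bootstrap
#' CIs; trials-versus-precision refinement curves for both tests; pooled
#' normative fits (Gaussian for face thresholds, Gamma for search median
#' RTs) with 99% cutoffs; pointwise per-location search norms with the
#' eccentricity power-law fit; and Spearman associations between test
#' scores and covariates.
#'
#' Primary outcomes follow the short-test protocol: the face threshold
#' estimate after \code{n_face_trials} trials and the median RT over the
#' refined location subset.
#'
#' @param cohort a \code{tabvis_cohort} (or equivalent structure).
#' @param n_face_trials trial count defining the short face test
#'   (default 20).
#' @param search_subset location subset defining the short search test
#'   (default the refined 22).
#' @param n_boot,seed bootstrap settings for the repeatability CIs.
#' @return an object of class \code{tabvis_evaluation}: a list with
#'   \code{faces} and \code{search} sublists (each holding
#'   \code{repeatability}, \code{normative}, \code{refinement}, and the
#'   per-run primary outcome vectors), \code{pointwise},
#'   \code{associations} and \code{usability}.
#' @export
evaluate_cohort <- function(cohort, n_face_trials = 20,
                            search_subset = NULL,
                            n_boot = 20000, seed = 1) {
  grid <- cohort$grid
  if (is.null(search_subset)) search_subset <- refined_subset(grid)

  # faces: running estimates per run, truncated to the short protocol
  f1 <- faces_estimate_matrix(cohort, 1)
  f2 <- faces_estimate_matrix(cohort, 2)
  n_face_trials <- min(n_face_trials, ncol(f1))
  faces1 <- f1[, n_face_trials]
  faces2 <- f2[, n_face_trials]

  # search: per-location RTs per run, medians over the short protocol
  s1 <- search_rt_matrix(cohort, 1)
  s2 <- search_rt_matrix(cohort, 2)
  cols <- match(as.character(search_subset), colnames(s1))
  if (anyNA(cols))
    stop("search_subset locations missing from cohort sessions",
         call. = FALSE)
  search1 <- apply(s1[, cols, drop = FALSE], 1, median_rt)
  search2 <- apply(s2[, cols, drop = FALSE], 1, median_rt)

  faces_rep <- bland_altman(faces1, faces2, n_boot = n_boot,
                            seed = derive_seed(seed, 11))
  search_rep <- bland_altman(search1, search2, n_boot = n_boot,
                             seed = derive_seed(seed, 12))

  faces_norm <- fit_normative(combine_runs(faces1, faces2), "gaussian")
  search_norm <- fit_normative(combine_runs(search1, search2), "gamma")

  n_vals <- unique(pmin(c(1, 2, 5, 10, 20, 30, 40, 50), ncol(f1)))
  faces_ref <- faces_refinement(f1, f2, n_vals)
  ladder <- search_ladder(grid)
  search_ref <- search_refinement(s1, s2, ladder)

  pooled_rt <- rbind(s1, s2)[, cols, drop = FALSE]
  pointwise <- pointwise_norms(pooled_rt, grid)

  p <- cohort$participants
  faces_mean <- rowMeans(cbind(p$faces_run1, p$faces_run2))
  search_mean <- rowMeans(cbind(p$search_run1, p$search_run2))
  dual <- is.finite(faces_mean)
  associations <- list(
    faces_vs_search = spearman_assoc(faces_mean[dual], search_mean[dual]),
    faces_vs_acuity = spearman_assoc(faces_mean[dual],
                                     p$acuity_logmar[dual]),
    search_vs_acuity = spearman_assoc(search_mean, p$acuity_logmar),
    faces_vs_contrast = spearman_assoc(faces_mean[dual],
                                       p$contrast_logcs[dual]),
    search_vs_contrast = spearman_assoc(search_mean, p$contrast_logcs),
    faces_vs_digit_span = spearman_assoc(faces_mean[dual],
                                         p$digit_span[dual]),
    search_vs_digit_span = spearman_assoc(search_mean, p$digit_span))

  structure(list(
    faces = list(run1 = faces1, run2 = faces2,
                 n_trials = n_face_trials,
                 repeatability = faces_rep, normative = faces_norm,
                 refinement = faces_ref),
    search = list(run1 = search1, run2 = search2,
                  subset = sort(search_subset),
                  repeatability = search_rep, normative = search_norm,
                  refinement = search_ref),
    pointwise = pointwise,
    associations = associations,
    usability = list(faces = mean(p$usability_faces, na.rm = TRUE),
                     search = mean(p$usability_search, na.rm = TRUE))),
    class = "tabvis_evaluation")
}

#' @export
print.tabvis_evaluation <- function(x, ...) {
  cat("Psychometric evaluation\n")
  cat(sprintf("  Faces  (first %d trials): CoR95 %.3f d {%.3f, %.3f}, 99%% cutoff %.3f d\n",
              x$faces$n_trials, x$faces$repeatability$cor95,
              x$faces$repeatability$ci95[1], x$faces$repeatability$ci95[2],
              x$faces$normative$cutoff99))
  cat(sprintf("  Search (%d locations)   : CoR95 %.3f s {%.3f, %.3f}, 99%% cutoff %.3f s\n",
              length(x$search$subset), x$search$repeatability$cor95,
              x$search$repeatability$ci95[1], x$search$repeatability$ci95[2],
              x$search$normative$cutoff99))
  pw <- attr(x$pointwise, "power")
  cat(sprintf("  Eccentricity power law: rt = %.4g * ecc^%.4g + %.4g (adj R2 %.3f)\n",
              pw$a, pw$b, pw$c, pw$adj_r_squared))
  cat(sprintf("  Faces vs search: rho = %.3f (p = %.3f, n = %d)\n",
              x$associations$faces_vs_search$rho,
              x$associations$faces_vs_search$p,
              x$associations$faces_vs_search$n))
  cat(sprintf("  Usability: faces %.2f / 10, search %.2f / 10\n",
              x$usability$faces, x$usability$search))
  invisible(x)
}
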