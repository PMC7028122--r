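#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated bootstrap interval for an arbitrary
#' statistic of a sample. The bias-correction z0 is the normal quantile of
#' the fraction of the bootstrap distribution below the point estimate
#' (ties counted at half weight); the acceleration a comes from the
#' jackknife skewness of the statistic; the percentile endpoints are
#' adjusted accordingly.
#'
#' @param data numeric vector, matrix or data.frame; resampling is by
#'   element (vector) or by row, which preserves pairing when rows are
#'   participant run-pairs.
#' @param statistic function mapping a resample of \code{data} to a scalar.
#' @param n_boot number of bootstrap resamples (the evaluation pipeline
#'   default is 20000).
#' @param level confidence level.
#' @param seed integer seed for the resampling stream.
#' @return numeric vector \code{c(low, high)} with attributes
#'   \code{estimate}, \code{z0} and \code{acceleration}.
#' @examples
#' bca_ci(rnorm(30), mean, n_boot = 2000, seed = 1)
#' @export
bca_ci <- function(data, statistic, n_boot = 20000, level = 0.95,
                   seed = NULL) {
  take <- function(d, idx) if (is.null(dim(d))) d[idx] else d[idx, , drop = FALSE]
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 3) stop("'data' must contain at least 3 observations", call. = FALSE)
  if (!is.function(statistic)) stop("'statistic' must be a function", call. = FALSE)
  assert_scalar_number(level, "level")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  theta <- statistic(data)
  assert_scalar_number(theta, "statistic(data)")

  boot_stats <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(b) statistic(take(data, sample.int(n, n, replace = TRUE))),
           numeric(1))
  })

  finish <- function(low, high, z0 = NA_real_, a = NA_real_) {
    structure(c(low = low, high = high), estimate = theta, z0 = z0,
              acceleration = a)
  }
  if (all(boot_stats == boot_stats[1])) {
    warning("degenerate bootstrap distribution (all resample statistics equal); ",
            "returning a point-mass interval", call. = FALSE)
    return(finish(boot_stats[1], boot_stats[1]))
  }

  # bias correction: midpoint handling of ties with the point estimate
  frac <- (sum(boot_stats < theta) + 0.5 * sum(boot_stats == theta)) / n_boot
  frac <- min(max(frac, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(frac)

  # acceleration from leave-one-out jackknife skewness
  jack <- vapply(seq_len(n), function(i) statistic(take(data, -i)), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)

  alpha <- (1 - level) / 2
  adj <- function(p) {
    zp <- stats::qnorm(p)
    stats::pnorm(z0 + (z0 + zp) / (1 - a * (z0 + zp)))
  }
  probs <- c(adj(alpha), adj(1 - alpha))
  # endpoints by normal-quantile-scale interpolation of the order
  # statistics (the standard convention for bootstrap percentiles)
  sorted <- sort(boot_stats)
  interp <- function(p) {
    k <- (n_boot + 1) * p
    if (k <= 1) return(sorted[1])
    if (k >= n_boot) return(sorted[n_boot])
    k1 <- floor(k)
    q1 <- stats::qnorm(k1 / (n_boot + 1))
    q2 <- stats::qnorm((k1 + 1) / (n_boot + 1))
    w <- (stats::qnorm(p) - q1) / (q2 - q1)
    sorted[k1] + w * (sorted[k1 + 1] - sorted[k1])
  }
  finish(interp(probs[1]), interp(probs[2]), z0, a)
}

#' Bland-Altman test-retest analysis
#'
#' Computes the agreement statistics between two runs of the same test on
#' the same participants: the bias (mean run2 - run1 difference), the
#' standard deviation of the paired differences (n - 1 denominator), the
#' 95% limits of agreement (bias -/+ 1.96 sd), and the 95% Coefficient of
#' Repeatability CoR95 = 1.96 sd, with a BCa bootstrap confidence interval
#' for CoR95 obtained by resampling participants (pairs), preserving the
#' pairing structure.
#'
#' An alternative convention inflates the within-subject sd by sqrt(2)
#' before scaling; this function uses the plain 1.96 x sd-of-differences
#' definition throughout.
#'
#' @param run1,run2 numeric vectors of per-participant scores, paired by
#'   position (same participant order).
#' @param ci logical; compute the bootstrap CI for CoR95.
#' @param n_boot,level,seed bootstrap settings (see \code{\link{bca_ci}}).
#' @return an object of class \code{repeatability_result}: a list with
#'   \code{bias}, \code{sd_diff}, \code{loa_low}, \code{loa_high},
#'   \code{cor95}, \code{ci95} (or NULL), \code{n_pairs}, \code{n_boot},
#'   \code{seed}.
#' @export
bland_altman <- function(run1, run2, ci = TRUE, n_boot = 20000,
                         level = 0.95, seed = NULL) {
  if (!is.numeric(run1) || !is.numeric(run2))
    stop("'run1' and 'run2' must be numeric", call. = FALSE)
  if (length(run1) != length(run2))
    stop("'run1' and 'run2' must have the same length (paired scores)",
         call. = FALSE)
  keep <- is.finite(run1) & is.finite(run2)
  run1 <- run1[keep]; run2 <- run2[keep]
  n <- length(run1)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- run2 - run1
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  cor95 <- 1.96 * sd_diff
  ci95 <- NULL
  if (ci) {
    ci95 <- bca_ci(d, function(x) 1.96 * stats::sd(x),
                   n_boot = n_boot, level = level, seed = seed)
  }
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - cor95, loa_high = bias + cor95,
                 cor95 = cor95, ci95 = ci95,
                 n_pairs = n, n_boot = if (ci) n_boot else NA_integer_,
                 level = level, seed = seed),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Bland-Altman test-retest analysis (n = %d pairs)\n", x$n_pairs))
  cat(sprintf("  bias (run2 - run1): %+.4f\n", x$bias))
  cat(sprintf("  sd of differences : %.4f\n", x$sd_diff))
  cat(sprintf("  95%% LoA           : [%.4f, %.4f]\n", x$loa_low, x$loa_high))
  cat(sprintf("  CoR95             : %.4f", x$cor95))
  if (!is.null(x$ci95))
    cat(sprintf("  {%.4f, %.4f}", x$ci95[1], x$ci95[2]))
  cat("\n")
  invisible(x)
}

#' Precision as a function of face-test length
#'
#' The adaptive face test yields an updated threshold estimate after every
#' trial, so shorter tests can be emulated post hoc by truncating each run
#' to its first N trials. For each requested N this computes the CoR95 of
#' the trial-N estimates across participants.
#'
#' @param est_run1,est_run2 numeric matrices of running threshold
#'   estimates, one row per participant, one column per trial, for the two
#'   runs (same participant order and trial count).
#' @param n_values trial counts at which to evaluate precision.
#' @return an object of class \code{refinement_curve}: a data.frame with
#'   columns \code{size} (trial count) and \code{cor95}.
#' @export
faces_refinement <- function(est_run1, est_run2,
                             n_values = c(1, 2, 5, 10, 20, 30, 40, 50)) {
  est_run1 <- as.matrix(est_run1); est_run2 <- as.matrix(est_run2)
  if (!all(dim(est_run1) == dim(est_run2)))
    stop("run matrices must have identical dimensions", call. = FALSE)
  n_values <- sort(unique(as.integer(n_values)))
  if (any(n_values < 1) || any(n_values > ncol(est_run1)))
    stop("'n_values' must lie within 1..n_trials", call. = FALSE)
  cor <- vapply(n_values, function(N) {
    bland_altman(est_run1[, N], est_run2[, N], ci = FALSE)$cor95
  }, numeric(1))
  structure(data.frame(size = n_values, cor95 = cor),
            class = c("refinement_curve", "data.frame"))
}

#' Precision as a function of search-subset sparseness
#'
#' The search test measures one RT per grid location, so sparser protocols
#' can be emulated post hoc by recomputing each run's median RT over a
#' subset of locations only. For each subset in the ladder this computes
#' the CoR95 of the subset medians across participants.
#'
#' @param rt_run1,rt_run2 numeric matrices of per-location RTs (seconds),
#'   one row per participant; columns named by location index and covering
#'   every location used in \code{ladder}.
#' @param ladder named list of integer location-index vectors, ordered or
#'   not; each subset must be duplicate-free and covered by both runs.
#' @return a \code{refinement_curve} data.frame with columns \code{size}
#'   (subset size), \code{cor95} and \code{subset} (list column).
#' @export
search_refinement <- function(rt_run1, rt_run2, ladder) {
  rt_run1 <- as.matrix(rt_run1); rt_run2 <- as.matrix(rt_run2)
  if (!all(dim(rt_run1) == dim(rt_run2)))
    stop("run matrices must have identical dimensions", call. = FALSE)
  if (is.null(colnames(rt_run1)) || is.null(colnames(rt_run2)))
    stop("RT matrices must have location-index column names", call. = FALSE)
  if (!is.list(ladder) || length(ladder) == 0)
    stop("'ladder' must be a non-empty list of location subsets", call. = FALSE)
  rows <- lapply(ladder, function(sub) {
    sub <- as.integer(sub)
    if (anyDuplicated(sub))
      stop("a ladder subset contains duplicate locations", call. = FALSE)
    cols <- match(as.character(sub), colnames(rt_run1))
    if (anyNA(cols))
      stop("ladder subset refers to locations missing from the RT matrices",
           call. = FALSE)
    m1 <- apply(rt_run1[, cols, drop = FALSE], 1, median_rt)
    m2 <- apply(rt_run2[, cols, drop = FALSE], 1, median_rt)
    data.frame(size = length(sub),
               cor95 = bland_altman(m1, m2, ci = FALSE)$cor95)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$size), ]
  out$subset <- I(lapply(ladder[order(vapply(ladder, length, 1L))],
                         as.integer))
  rownames(out) <- NULL
  structure(out, class = c("refinement_curve", "data.frame"))
}

#' Reshape cohort session data into run matrices
#'
#' Helpers extracting, from a synthetic cohort (or any session table in the
#' same long format), the participant x trial matrix of running face
#' threshold estimates or the participant x location matrix of search RTs
#' for one run.
#'
#' @param cohort a \code{tabvis_cohort} or a long session data.frame with
#'   the engine column schema.
#' @param run run index (1 or 2).
#' @return a numeric matrix, rows named by participant.
#' @export
faces_estimate_matrix <- function(cohort, run) {
  df <- if (inherits(cohort, "tabvis_cohort")) cohort$face_sessions else cohort
  df <- df[df$run_index == run, ]
  if (nrow(df) == 0) stop("no face sessions for run ", run, call. = FALSE)
  stats::xtabs(threshold_estimate_d ~ participant_id + trial_index,
               data = df) |> unclass()
}

#' @rdname faces_estimate_matrix
#' @export
search_rt_matrix <- function(cohort, run) {
  df <- if (inherits(cohort, "tabvis_cohort")) cohort$search_sessions else cohort
  df <- df[df$run_index == run, ]
  if (nrow(df) == 0) stop("no search sessions for run ", run, call. = FALSE)
  stats::xtabs(rt_s ~ participant_id + loc, data = df) |> unclass()
}
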