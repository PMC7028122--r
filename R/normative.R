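#' Fit a normative reference distribution
#'
#' Maximum-likelihood fit of a reference distribution to healthy-observer
#' scores, and the derived 99% upper cutoff: the value below which 99% of
#' the fitted population is expected to score. Face thresholds use a
#' Gaussian family; search median RTs, being right-skewed and positive,
#' use a Gamma family.
#'
#' The Gaussian sd is the pure MLE (n denominator), which matters because
#' the cutoff is sensitive to the scale estimate. The Gamma fit is full
#' maximum likelihood (via \code{MASS::fitdistr}), not moment matching.
#'
#' @param values numeric vector of scores (n >= 5; strictly positive for
#'   the gamma family).
#' @param family \code{"gaussian"} or \code{"gamma"}.
#' @return an object of class \code{normative_model}: a list with
#'   \code{family}, \code{parameters} (gaussian: mean, sd; gamma: shape,
#'   scale), \code{cutoff99}, \code{n}, \code{loglik} and
#'   \code{degenerate} (TRUE when the data had zero spread).
#' @export
fit_normative <- function(values, family = c("gaussian", "gamma")) {
  family <- match.arg(family)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric scores", call. = FALSE)
  n <- length(values)
  if (n < 5) stop("need at least 5 scores to fit normative limits",
                  call. = FALSE)
  degenerate <- FALSE
  if (family == "gaussian") {
    m <- mean(values)
    s <- sqrt(mean((values - m)^2))  # MLE, n denominator
    if (s == 0) {
      warning("all scores identical; normative fit is degenerate and the ",
              "cutoff collapses to the constant", call. = FALSE)
      degenerate <- TRUE
      cutoff <- m
      ll <- Inf
    } else {
      cutoff <- stats::qnorm(0.99, m, s)
      ll <- sum(stats::dnorm(values, m, s, log = TRUE))
    }
    pars <- c(mean = m, sd = s)
  } else {
    if (any(values <= 0))
      stop("gamma normative fits require strictly positive scores",
           call. = FALSE)
    if (stats::sd(values) == 0) {
      warning("all scores identical; normative fit is degenerate and the ",
              "cutoff collapses to the constant", call. = FALSE)
      degenerate <- TRUE
      pars <- c(shape = NA_real_, scale = NA_real_)
      cutoff <- values[1]
      ll <- Inf
    } else {
      fit <- suppressWarnings(MASS::fitdistr(values, "gamma"))
      shape <- unname(fit$estimate["shape"])
      scale <- 1 / unname(fit$estimate["rate"])
      pars <- c(shape = shape, scale = scale)
      cutoff <- stats::qgamma(0.99, shape = shape, scale = scale)
      ll <- as.numeric(fit$loglik)
    }
  }
  structure(list(family = family, parameters = pars, cutoff99 = cutoff,
                 n = n, loglik = ll, degenerate = degenerate),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model: %s fit on n = %d", x$family, x$n))
  if (x$degenerate) cat(" [degenerate]")
  cat(sprintf(", %s, 99%% cutoff %.4g>\n",
              paste(sprintf("%s = %.4g", names(x$parameters),
                            x$parameters), collapse = ", "),
              x$cutoff99))
  invisible(x)
}

#' Pool two runs into a normative sample
#'
#' Concatenates run-1 and run-2 scores into a single sample of 2n values,
#' after a paired-difference gate checking that the runs do not differ
#' systematically (in which case pooling would smear a learning or fatigue
#' effect into the norms and a warning is emitted).
#'
#' @param run1,run2 paired numeric score vectors.
#' @param gate \code{"t"} (paired t-test, default) or \code{"wilcoxon"}.
#' @param alpha significance level of the gate.
#' @return numeric vector \code{c(run1, run2)} with attribute
#'   \code{gate_p}, the gate test's p-value.
#' @export
combine_runs <- function(run1, run2, gate = c("t", "wilcoxon"),
                         alpha = 0.05) {
  gate <- match.arg(gate)
  if (length(run1) != length(run2))
    stop("'run1' and 'run2' must be paired (equal length)", call. = FALSE)
  keep <- is.finite(run1) & is.finite(run2)
  run1 <- run1[keep]; run2 <- run2[keep]
  d <- run2 - run1
  p <- if (all(d == 0)) {
    1
  } else if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    0  # every participant shifted by (numerically) the same nonzero amount
  } else if (gate == "t") {
    stats::t.test(d)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(d)$p.value)
  }
  if (is.finite(p) && p < alpha)
    warning(sprintf("systematic difference between runs (paired %s-test p = %.3g); pooled norms may be biased",
                    gate, p), call. = FALSE)
  structure(c(run1, run2), gate_p = p)
}

#' Per-location normative limits for the search test
#'
#' Computes, for every tested grid location, the normative median RT across
#' the cohort and a gamma-fit 99% upper cutoff (built the same way as the
#' whole-test norm), joined to the location's eccentricity.
#'
#' @param rt_matrix participants x locations matrix of RTs (seconds),
#'   columns named by location index; typically both runs stacked as rows.
#' @param grid the \code{search_grid} supplying eccentricities.
#' @param power_fit logical; also fit the eccentricity power law to the
#'   per-location medians.
#' @return an object of class \code{pointwise_norms}: a data.frame with
#'   columns \code{loc}, \code{col}, \code{row}, \code{ecc_deg},
#'   \code{median_rt}, \code{cutoff99}, and (when \code{power_fit}) an
#'   attribute \code{power} holding the \code{\link{fit_power}} result.
#' @export
pointwise_norms <- function(rt_matrix, grid = search_grid(),
                            power_fit = TRUE) {
  rt_matrix <- as.matrix(rt_matrix)
  if (is.null(colnames(rt_matrix)))
    stop("'rt_matrix' must have location-index column names", call. = FALSE)
  if (nrow(rt_matrix) < 5)
    stop("need at least 5 participants per location", call. = FALSE)
  locs <- as.integer(colnames(rt_matrix))
  idx <- match(locs, grid$cells$loc)
  if (anyNA(idx))
    stop("'rt_matrix' has columns not present in the grid", call. = FALSE)
  med <- apply(rt_matrix, 2, median_rt)
  cut <- apply(rt_matrix, 2,
               function(v) fit_normative(v, "gamma")$cutoff99)
  out <- data.frame(loc = locs,
                    col = grid$cells$col[idx],
                    row = grid$cells$row[idx],
                    ecc_deg = grid$cells$ecc_deg[idx],
                    median_rt = unname(med),
                    cutoff99 = unname(cut))
  out <- out[order(out$loc), ]
  rownames(out) <- NULL
  out <- structure(out, class = c("pointwise_norms", "data.frame"))
  if (power_fit)
    attr(out, "power") <- fit_power(out$ecc_deg, out$median_rt)
  out
}

#' Fit the eccentricity power law
#'
#' Nonlinear least-squares fit of \code{rt = a * ecc^b + c} to
#' per-location response times, with multi-start initialisation to avoid
#' local minima, and the adjusted R-squared for the 3-parameter model.
#'
#' @param ecc eccentricities in degrees (> 0).
#' @param rt response times in seconds.
#' @param n_starts number of random restarts around heuristic start values.
#' @param seed integer seed for the restart draws.
#' @return list with \code{a}, \code{b}, \code{c}, \code{adj_r_squared},
#'   \code{fitted}, \code{residuals} and \code{sse}.
#' @export
fit_power <- function(ecc, rt, n_starts = 40, seed = 100) {
  if (length(ecc) != length(rt))
    stop("'ecc' and 'rt' must have the same length", call. = FALSE)
  if (any(ecc <= 0)) stop("'ecc' must be strictly positive", call. = FALSE)
  n <- length(ecc)
  if (n <= 3) stop("need more than 3 points to fit a 3-parameter model",
                   call. = FALSE)
  df <- data.frame(x = ecc, y = rt)
  starts <- with_seed(seed, {
    base <- expand.grid(a = c(-10, -1, 1, 10) * stats::sd(rt),
                        b = c(-0.5, -0.05, 0.05, 0.5),
                        c = mean(rt) + c(-1, 0, 1) * stats::sd(rt))
    extra <- data.frame(a = stats::runif(n_starts, -20, 20),
                        b = stats::runif(n_starts, -1, 1),
                        c = stats::runif(n_starts, min(rt) - 1, max(rt) + 1))
    rbind(base, extra)
  })
  best <- NULL
  best_sse <- Inf
  diagnostics <- character(0)
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ a * x^b + c, data = df,
        start = as.list(starts[k, ]),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) {
        diagnostics <<- c(diagnostics, conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.finite(sse) && sse < best_sse) {
      best <- fit
      best_sse <- sse
    }
  }
  if (is.null(best))
    stop("power-law fit failed to converge from any start; last messages: ",
         paste(utils::tail(unique(diagnostics), 3), collapse = " | "),
         call. = FALSE)
  cf <- stats::coef(best)
  sst <- sum((rt - mean(rt))^2)
  r2 <- if (sst == 0) 1 else 1 - best_sse / sst
  adj <- if (sst == 0) 1 else 1 - (1 - r2) * (n - 1) / (n - 3)
  list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
       adj_r_squared = adj,
       fitted = stats::fitted(best), residuals = stats::resid(best),
       sse = best_sse)
}

#' Spearman rank association
#'
#' Rank correlation between two score vectors with midrank handling of
#' ties. P-values use the exact null distribution for small samples
#' without ties and the t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 5).
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs", call. = FALSE)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n < 20) && !ties))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Classify a score against normative limits
#'
#' A score is flagged as outside norms when it exceeds the 99% cutoff
#' strictly; a score exactly at the cutoff is within norms.
#'
#' @param score numeric score(s).
#' @param model a fitted \code{normative_model}.
#' @return character vector, \code{"within_norms"} or
#'   \code{"outside_norms"}.
#' @export
classify_score <- function(score, model) {
  if (!inherits(model, "normative_model"))
    stop("'model' must be a normative_model", call. = FALSE)
  if (!is.numeric(score) || any(!is.finite(score)))
    stop("'score' must be finite numeric", call. = FALSE)
  ifelse(score > model$cutoff99, "outside_norms", "within_norms")
}
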