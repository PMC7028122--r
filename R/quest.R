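#' Psychometric function parameters for the 4AFC face test
#'
#' Parameters of the Weibull psychometric function assumed by the adaptive
#' staircase. With four response alternatives the guessing floor is 0.25.
#' The slope and lapse rate are the conventional adaptive-psychophysics
#' defaults and are fully configurable.
#'
#' @param guess_rate gamma, probability of a correct response by guessing
#'   (0.25 for 4AFC).
#' @param slope beta, dimensionless Weibull slope.
#' @param lapse_rate delta, probability of an attention lapse (response
#'   correct with probability \code{guess_rate} regardless of level).
#' @param threshold_criterion p_th, the proportion correct defining
#'   "threshold". Defaults to the Weibull value at level == threshold,
#'   \code{guess_rate + (1 - guess_rate - lapse_rate) * (1 - exp(-1))}.
#' @return an object of class \code{psychometric_params}.
#' @export
psychometric_params <- function(guess_rate = 0.25, slope = 3.5,
                                lapse_rate = 0.01,
                                threshold_criterion = NULL) {
  assert_scalar_number(guess_rate, "guess_rate")
  assert_scalar_number(slope, "slope", positive = TRUE)
  assert_scalar_number(lapse_rate, "lapse_rate")
  if (guess_rate < 0 || guess_rate >= 1)
    stop("'guess_rate' must lie in [0, 1)", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate >= 0.5)
    stop("'lapse_rate' must lie in [0, 0.5)", call. = FALSE)
  if (is.null(threshold_criterion))
    threshold_criterion <- guess_rate +
      (1 - guess_rate - lapse_rate) * (1 - exp(-1))
  assert_scalar_number(threshold_criterion, "threshold_criterion")
  if (threshold_criterion <= guess_rate ||
      threshold_criterion >= 1 - lapse_rate)
    stop("'threshold_criterion' must lie strictly between guess_rate and 1 - lapse_rate",
         call. = FALSE)
  structure(list(guess_rate = guess_rate, slope = slope,
                 lapse_rate = lapse_rate,
                 threshold_criterion = threshold_criterion),
            class = "psychometric_params")
}

#' Probability of a correct 4AFC response
#'
#' Weibull-family psychometric function:
#' \deqn{p = \gamma + (1 - \gamma - \delta)(1 - e^{-(x/t)^\beta})}
#' where x is the presented dissimilarity level, t the observer's true
#' threshold, gamma the guess rate, beta the slope and delta the lapse rate.
#' Monotone non-decreasing in \code{level} and bounded in
#' [gamma, 1 - delta].
#'
#' @param level presented dissimilarity (d-units), non-negative scalar.
#' @param true_threshold observer threshold(s) in d-units; may be a vector
#'   (used to evaluate the likelihood over a posterior grid).
#' @param params a \code{psychometric_params} object.
#' @return probability (vectorised over \code{true_threshold}).
#' @examples
#' prob_correct(0, 3.5, psychometric_params(lapse_rate = 0))       # 0.25
#' prob_correct(3.5, 3.5, psychometric_params(lapse_rate = 0))     # ~0.724
#' @export
prob_correct <- function(level, true_threshold, params = psychometric_params()) {
  assert_scalar_number(level, "level")
  if (level < 0) stop("'level' must be non-negative", call. = FALSE)
  if (!is.numeric(true_threshold) || any(!is.finite(true_threshold)) ||
      any(true_threshold <= 0))
    stop("'true_threshold' must be positive and finite", call. = FALSE)
  g <- params$guess_rate; d <- params$lapse_rate; b <- params$slope
  g + (1 - g - d) * (1 - exp(-(level / true_threshold)^b))
}

#' Bayesian staircase state
#'
#' Holds the discretised posterior over candidate thresholds, the assumed
#' psychometric parameters, and the trial history. The prior is a broad
#' Gaussian truncated to the domain; the domain brackets the range of
#' thresholds typical for normally sighted adults (roughly 3-4 d) with wide
#' margin.
#'
#' @param domain evenly spaced, strictly increasing grid of candidate
#'   thresholds (d-units).
#' @param params a \code{psychometric_params} object.
#' @param prior_mean,prior_sd mean and sd of the truncated-Gaussian prior
#'   over the domain.
#' @param prior optional explicit prior mass vector (overrides
#'   \code{prior_mean}/\code{prior_sd}); will be normalised.
#' @return an object of class \code{quest_state} with elements
#'   \code{domain}, \code{posterior}, \code{params} and \code{history}
#'   (data.frame with columns \code{level}, \code{correct}).
#' @export
quest_state <- function(domain = seq(0.5, 8, length.out = 301),
                        params = psychometric_params(),
                        prior_mean = 3.5, prior_sd = 2.0,
                        prior = NULL) {
  if (!is.numeric(domain) || length(domain) < 2L ||
      any(!is.finite(domain)) || any(diff(domain) <= 0))
    stop("'domain' must be a strictly increasing finite numeric grid",
         call. = FALSE)
  if (any(domain <= 0))
    stop("'domain' thresholds must be positive", call. = FALSE)
  if (!inherits(params, "psychometric_params"))
    stop("'params' must be a psychometric_params object", call. = FALSE)
  if (is.null(prior)) {
    assert_scalar_number(prior_mean, "prior_mean")
    assert_scalar_number(prior_sd, "prior_sd", positive = TRUE)
    prior <- stats::dnorm(domain, prior_mean, prior_sd)
  }
  if (length(prior) != length(domain) || any(prior < 0) || sum(prior) <= 0)
    stop("'prior' must be non-negative, same length as domain, with positive mass",
         call. = FALSE)
  structure(list(domain = domain,
                 posterior = prior / sum(prior),
                 params = params,
                 history = data.frame(level = numeric(0),
                                      correct = logical(0))),
            class = "quest_state")
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf("<quest_state: %d trials, domain [%.3g, %.3g] x %d, estimate %.3f d>\n",
              nrow(x$history), min(x$domain), max(x$domain),
              length(x$domain), threshold_estimate(x)))
  invisible(x)
}

validate_quest_state <- function(state) {
  if (!inherits(state, "quest_state"))
    stop("'state' must be a quest_state object", call. = FALSE)
  if (abs(sum(state$posterior) - 1) > 1e-9)
    stop("quest_state posterior mass is not 1", call. = FALSE)
  invisible(state)
}

#' Bayesian update of the staircase posterior
#'
#' Multiplies the current posterior by the likelihood of the observed
#' response at the presented level, evaluated at every candidate threshold
#' on the grid, then renormalises. The update is order-independent
#' (likelihoods commute).
#'
#' @param state a \code{quest_state}.
#' @param level presented dissimilarity (d-units); must lie within the
#'   domain bounds.
#' @param correct logical, whether the response was correct.
#' @return the updated \code{quest_state} (history appended).
#' @export
quest_update <- function(state, level, correct) {
  validate_quest_state(state)
  assert_scalar_number(level, "level")
  if (level < min(state$domain) || level > max(state$domain))
    stop("'level' lies outside the posterior domain", call. = FALSE)
  if (!is.logical(correct) || length(correct) != 1L || is.na(correct))
    stop("'correct' must be TRUE or FALSE", call. = FALSE)
  p <- prob_correct(level, state$domain, state$params)
  lik <- if (correct) p else 1 - p
  post <- state$posterior * lik
  total <- sum(post)
  if (!is.finite(total) || total <= 0)
    stop(sprintf(paste0("posterior normalisation failed after response at ",
                        "level %.4g (total likelihood %.4g); the state is ",
                        "numerically degenerate"), level, total),
         call. = FALSE)
  state$posterior <- post / total
  state$history <- rbind(state$history,
                         data.frame(level = level, correct = correct))
  state
}

#' Posterior-mean threshold estimate
#'
#' The running outcome measure of the face test: the mean of the posterior
#' density over candidate thresholds, recomputed after every trial.
#'
#' @param state a \code{quest_state}.
#' @return scalar threshold estimate in d-units.
#' @export
threshold_estimate <- function(state) {
  validate_quest_state(state)
  sum(state$domain * state$posterior)
}

#' Stimulus level for the next trial
#'
#' Places the next stimulus at the current posterior-mean estimate, clamped
#' to the domain bounds.
#'
#' @param state a \code{quest_state}.
#' @return scalar level in d-units, always within the domain.
#' @export
next_level <- function(state) {
  est <- threshold_estimate(state)
  min(max(est, min(state$domain)), max(state$domain))
}
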