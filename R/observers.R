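#' Generative simulated observer
#'
#' A simulated participant for both engines. The face side is a true
#' discrimination threshold plus the psychometric function used to draw
#' correct/incorrect responses. The search side is a power-law mean response
#' time as a function of target eccentricity,
#' \code{rt = rt_a * ecc^rt_b + rt_c} seconds, with multiplicative lognormal
#' trial noise. The default power-law coefficients are the field fit
#' reported for normally sighted young adults
#' (\code{-13.14 * ecc^-0.05 + 13.56}). The stability component adds
#' between-run jitter so that two runs of the same observer differ the way
#' repeated human sessions do.
#'
#' @param face_threshold true face-discrimination threshold (d-units).
#' @param face_params a \code{psychometric_params} object.
#' @param deterministic logical; if TRUE the observer responds correct iff
#'   level >= true threshold (a noise-free shim useful for convergence
#'   checks).
#' @param rt_a,rt_b,rt_c power-law RT coefficients (seconds at the output).
#' @param rt_noise_sd sd of the lognormal multiplicative RT noise (log
#'   scale); 0 gives noise-free RTs equal to the mean curve.
#' @param face_stability_sd between-run jitter sd on the face threshold
#'   (d-units).
#' @param search_stability_sd between-run jitter sd on the observer's log
#'   speed factor (multiplicative on all RTs of a run).
#' @return an object of class \code{observer_model}.
#' @export
observer_model <- function(face_threshold = 3.25,
                           face_params = psychometric_params(),
                           deterministic = FALSE,
                           rt_a = -13.14, rt_b = -0.05, rt_c = 13.56,
                           rt_noise_sd = 0.45,
                           face_stability_sd = 0.05,
                           search_stability_sd = 0.15) {
  assert_scalar_number(face_threshold, "face_threshold", positive = TRUE)
  if (!inherits(face_params, "psychometric_params"))
    stop("'face_params' must be a psychometric_params object", call. = FALSE)
  for (nm in c("rt_a", "rt_b", "rt_c"))
    assert_scalar_number(get(nm), nm)
  assert_scalar_number(rt_noise_sd, "rt_noise_sd")
  assert_scalar_number(face_stability_sd, "face_stability_sd")
  assert_scalar_number(search_stability_sd, "search_stability_sd")
  if (rt_noise_sd < 0 || face_stability_sd < 0 || search_stability_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  obs <- structure(list(face_threshold = face_threshold,
                        face_params = face_params,
                        deterministic = isTRUE(deterministic),
                        rt_a = rt_a, rt_b = rt_b, rt_c = rt_c,
                        rt_noise_sd = rt_noise_sd,
                        face_stability_sd = face_stability_sd,
                        search_stability_sd = search_stability_sd),
                   class = "observer_model")
  # mean RT must stay positive over the eccentricity range any grid can reach
  probe <- seq(MIN_ECC_DEG, 25, length.out = 50)
  if (any(rt_mean(probe, obs) <= 0))
    stop("RT power law is non-positive within the plausible eccentricity range",
         call. = FALSE)
  obs
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(paste0("<observer_model: face threshold %.2f d; ",
                     "RT %.4g*ecc^%.4g + %.4g s, noise sd %.2f>\n"),
              x$face_threshold, x$rt_a, x$rt_b, x$rt_c, x$rt_noise_sd))
  invisible(x)
}

# Targets never appear at the exact centre (that slot holds the reference
# image), so the power law's singularity at 0 for negative exponents is
# unreachable by construction; the clamp guards direct misuse. 1 degree is
# well inside the inner ring of any realistic layout (the default grid's
# nearest target sits at 3.3 degrees) and the default RT curve is positive
# there, whereas it crosses zero just above 0.5 degrees.
MIN_ECC_DEG <- 1.0

#' Mean response time at a given eccentricity
#'
#' Evaluates the observer's power-law RT curve. Eccentricities below 1
#' degree are clamped to 1 degree before exponentiation (no target of the
#' default grid lies nearer than 3.3 degrees, so the clamp only guards
#' misuse).
#'
#' @param ecc eccentricity in degrees of visual angle (vectorised).
#' @param observer an \code{observer_model}.
#' @return mean RT in seconds.
#' @examples
#' rt_mean(1, observer_model())   # -13.14 + 13.56 = 0.42
#' rt_mean(10, observer_model())  # ~1.85
#' @export
rt_mean <- function(ecc, observer = observer_model()) {
  if (!is.numeric(ecc) || any(!is.finite(ecc)) || any(ecc < 0))
    stop("'ecc' must be non-negative and finite", call. = FALSE)
  ecc <- pmax(ecc, MIN_ECC_DEG)
  observer$rt_a * ecc^observer$rt_b + observer$rt_c
}

#' Draw a noisy response time
#'
#' Lognormal multiplicative noise around the mean RT curve, so draws are
#' strictly positive and their median equals the mean curve.
#'
#' @inheritParams rt_mean
#' @param speed_factor extra multiplicative factor (used for between-run
#'   stability jitter and between-participant speed differences).
#' @return RT draw(s) in seconds, one per element of \code{ecc}. Uses the
#'   current RNG stream.
#' @export
sample_rt <- function(ecc, observer = observer_model(), speed_factor = 1) {
  mu <- rt_mean(ecc, observer) * speed_factor
  if (observer$rt_noise_sd == 0) return(mu)
  mu * exp(stats::rnorm(length(mu), 0, observer$rt_noise_sd))
}

#' Simulate one run of the face-discrimination test
#'
#' Runs the Bayesian adaptive staircase against a simulated observer for a
#' fixed number of trials: each trial presents the current posterior-mean
#' level, draws a Bernoulli response from the observer's psychometric
#' function, updates the posterior, and records the running threshold
#' estimate. Fully reproducible given \code{seed}.
#'
#' @param observer an \code{observer_model}.
#' @param n_trials number of trials (the deployed test used 50).
#' @param seed integer seed for the response stream.
#' @param state initial \code{quest_state}; defaults to the standard
#'   domain/prior configuration.
#' @param threshold_override optionally replace the observer's true
#'   threshold for this run (used for between-run stability jitter).
#' @return an object of class \code{face_session} with elements
#'   \code{trials} (data.frame: trial, level, correct, threshold_estimate),
#'   \code{threshold_by_trial}, \code{final_threshold}, \code{n_trials},
#'   \code{seed} and the final \code{state}.
#' @export
run_face_session <- function(observer, n_trials = 50, seed = NULL,
                             state = quest_state(),
                             threshold_override = NULL) {
  if (!inherits(observer, "observer_model"))
    stop("'observer' must be an observer_model", call. = FALSE)
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("'n_trials' must be at least 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  truth <- if (is.null(threshold_override)) observer$face_threshold else
    threshold_override
  assert_scalar_number(truth, "threshold_override", positive = TRUE)
  with_seed(seed, {
    levels <- numeric(n_trials)
    correct <- logical(n_trials)
    ests <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      lev <- next_level(state)
      ans <- if (observer$deterministic) {
        lev >= truth
      } else {
        stats::runif(1) < prob_correct(lev, truth, observer$face_params)
      }
      state <- quest_update(state, lev, ans)
      levels[t] <- lev
      correct[t] <- ans
      ests[t] <- threshold_estimate(state)
    }
    structure(list(trials = data.frame(trial = seq_len(n_trials),
                                       level = levels,
                                       correct = correct,
                                       threshold_estimate = ests),
                   threshold_by_trial = ests,
                   final_threshold = ests[n_trials],
                   n_trials = n_trials,
                   seed = seed,
                   state = state),
              class = "face_session")
  })
}

#' @export
print.face_session <- function(x, ...) {
  cat(sprintf("<face_session: %d trials, final threshold %.3f d>\n",
              x$n_trials, x$final_threshold))
  invisible(x)
}

#' Generate a synthetic two-run cohort
#'
#' Emulates the study design the analysis pipeline expects: every
#' participant performs the search test twice over all 62 grid locations,
#' and a subset of participants additionally performs the face test twice
#' (50 trials per run). Face thresholds are drawn from a Gaussian
#' population; search speed varies between participants by a lognormal
#' multiplicative factor on the power-law mean curve, producing
#' right-skewed (Gamma-compatible) median RTs. Covariates (acuity, contrast
#' sensitivity, digit span, usability ratings) are drawn independently of
#' performance by default.
#'
#' @param n_search number of participants with search data (default 50).
#' @param n_faces number of participants (the first \code{n_faces}) with
#'   face data (default 30).
#' @param seed master integer seed; every session derives its own stream
#'   from it.
#' @param face_mean,face_sd Gaussian population for true face thresholds
#'   (d-units).
#' @param search_speed_sd sd of the between-participant log speed factor.
#' @param observer_template an \code{observer_model} supplying psychometric
#'   parameters, RT curve and noise/stability components for every
#'   participant.
#' @param n_face_trials trials per face run.
#' @param grid a \code{search_grid}.
#' @param covariate_performance_cor correlation between the acuity covariate
#'   and performance (default 0, matching the null associations seen in
#'   normally sighted young adults; settable for power studies).
#' @return an object of class \code{tabvis_cohort}: a list with
#'   \code{participants} (one row per participant: outcome summaries and
#'   covariates), \code{face_sessions} (trial-level long data.frame),
#'   \code{search_sessions} (location-level long data.frame), \code{grid}
#'   and \code{seed}.
#' @export
generate_cohort <- function(n_search = 50, n_faces = 30, seed = 1,
                            face_mean = 3.25, face_sd = 0.15,
                            search_speed_sd = 0.2,
                            observer_template = observer_model(),
                            n_face_trials = 50,
                            grid = search_grid(),
                            covariate_performance_cor = 0) {
  if (n_search < 2 || n_faces < 2)
    stop("need at least 2 participants per test", call. = FALSE)
  if (n_faces > n_search)
    stop("'n_faces' cannot exceed 'n_search'", call. = FALSE)
  assert_scalar_number(face_sd, "face_sd", positive = TRUE)

  tmpl <- observer_template
  # population draws from the master stream
  pop <- with_seed(derive_seed(seed, 0), {
    list(thresholds = stats::rnorm(n_search, face_mean, face_sd),
         log_speed = stats::rnorm(n_search, 0, search_speed_sd),
         acuity = round(pmin(stats::rnorm(n_search, -0.05, 0.08), 0.2), 2),
         logcs = round(pmax(stats::rnorm(n_search, 1.85, 0.10), 1.5), 2),
         digit_span = pmax(round(stats::rnorm(n_search, 19, 4)), 8),
         usab_faces = round(10 * stats::rbeta(n_search, 24, 1), 1),
         usab_search = round(10 * stats::rbeta(n_search, 32, 1), 1))
  })
  pop$thresholds <- pmax(pop$thresholds, 0.6)
  if (covariate_performance_cor != 0) {
    # tilt acuity towards the search speed factor for power studies
    r <- covariate_performance_cor
    z <- scale(pop$log_speed)[, 1]
    pop$acuity <- round(pmin(-0.05 + 0.08 * (r * z +
      sqrt(max(0, 1 - r^2)) * scale(pop$acuity)[, 1]), 0.2), 2)
  }

  face_rows <- vector("list", 2L * n_faces)
  search_rows <- vector("list", 2L * n_search)
  part <- data.frame(participant_id = sprintf("P%03d", seq_len(n_search)),
                     faces_run1 = NA_real_, faces_run2 = NA_real_,
                     search_run1 = NA_real_, search_run2 = NA_real_,
                     acuity_logmar = pop$acuity,
                     contrast_logcs = pop$logcs,
                     digit_span = pop$digit_span,
                     usability_faces = pop$usab_faces,
                     usability_search = pop$usab_search,
                     stringsAsFactors = FALSE)

  for (i in seq_len(n_search)) {
    obs <- observer_model(face_threshold = pop$thresholds[i],
                          face_params = tmpl$face_params,
                          deterministic = tmpl$deterministic,
                          rt_a = tmpl$rt_a, rt_b = tmpl$rt_b,
                          rt_c = tmpl$rt_c,
                          rt_noise_sd = tmpl$rt_noise_sd,
                          face_stability_sd = tmpl$face_stability_sd,
                          search_stability_sd = tmpl$search_stability_sd)
    base_speed <- exp(pop$log_speed[i])
    for (run in 1:2) {
      sseed <- derive_seed(seed, i, run, 1)
      jit <- with_seed(derive_seed(seed, i, run, 2), {
        list(face = stats::rnorm(1, 0, obs$face_stability_sd),
             speed = stats::rnorm(1, 0, obs$search_stability_sd))
      })
      ses <- run_search_session(obs, grid = grid, subset = "all",
                                seed = sseed,
                                speed_factor = base_speed * exp(jit$speed))
      search_rows[[2 * (i - 1) + run]] <-
        cbind(participant_id = part$participant_id[i], test = "search",
              run_index = run,
              trial_index = ses$trials$trial,
              ses$trials[, c("loc", "col", "row", "ecc_deg", "rt_s")],
              seed = sseed, stringsAsFactors = FALSE)
      part[[paste0("search_run", run)]][i] <- ses$median_rt

      if (i <= n_faces) {
        fseed <- derive_seed(seed, i, run, 3)
        fses <- run_face_session(obs, n_trials = n_face_trials,
                                 seed = fseed,
                                 threshold_override =
                                   max(pop$thresholds[i] + jit$face, 0.6))
        face_rows[[2 * (i - 1) + run]] <-
          data.frame(participant_id = part$participant_id[i],
                     test = "faces", run_index = run,
                     trial_index = fses$trials$trial,
                     level_d = fses$trials$level,
                     correct = as.integer(fses$trials$correct),
                     threshold_estimate_d = fses$trials$threshold_estimate,
                     seed = fseed, stringsAsFactors = FALSE)
        part[[paste0("faces_run", run)]][i] <- fses$final_threshold
      }
    }
  }

  structure(list(participants = part,
                 face_sessions = do.call(rbind, face_rows),
                 search_sessions = do.call(rbind, search_rows),
                 grid = grid,
                 seed = seed),
            class = "tabvis_cohort")
}

#' @export
print.tabvis_cohort <- function(x, ...) {
  nf <- length(unique(x$face_sessions$participant_id))
  cat(sprintf(paste0("<tabvis_cohort: %d participants (%d with face data), ",
                     "2 runs each, seed %s>\n"),
              nrow(x$participants), nf, format(x$seed)))
  invisible(x)
}
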